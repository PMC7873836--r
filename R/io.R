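#' Read a gene-by-cell expression matrix from TSV
#'
#' First column holds gene identifiers, the header row cell identifiers, the
#' body non-negative TPM (or count) values.
#'
#' @param path TSV file path.
#' @param genes Optional gene annotation tibble (as from
#'   [read_gene_annotation()]); when supplied, matrix rows without an
#'   annotation entry are reported via a message.
#' @return A numeric matrix (genes x cells) with dimnames; when `genes` is
#'   supplied it is attached as attribute `"genes"`, reordered to the matrix.
#' @export
read_expression_matrix <- function(path, genes = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) abort("no genes: expression matrix body is empty")
  if (ncol(df) < 2) abort("expression matrix has no cell columns")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    abort(paste0("duplicated gene ID(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
      abort(paste0("non-numeric value in column '", names(body)[j],
                   "', row '", ids[if (is.na(bad)) 1 else bad], "'"))
    }
  }
  mat <- as.matrix(body)
  rownames(mat) <- ids
  if (any(mat < 0, na.rm = TRUE)) abort("negative expression values")
  if (!is.null(genes)) {
    missing <- setdiff(ids, genes$gene_id)
    if (length(missing) > 0) {
      inform(paste0(length(missing), " matrix gene(s) missing from the ",
                    "annotation: ", paste(head(missing, 5), collapse = ", "),
                    if (length(missing) > 5) ", ..." else ""))
    }
    attr(mat, "genes") <- genes[match(ids, genes$gene_id), , drop = FALSE]
  }
  mat
}

#' Write an expression matrix to TSV
#'
#' @param mat Numeric genes x cells matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' BED-like TSV with header: chrom, start, end, gene_id, strand,
#' single_copy_y (0/1 flag for single-copy chrY genes). Coordinates are
#' 0-based half-open.
#'
#' @param path TSV file path.
#' @return A tibble with a derived `tss` column (strand-aware).
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gene_id", "strand", "single_copy_y")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("gene annotation lacks column(s): ", paste(miss, collapse = ", ")))
  }
  out <- as_tibble(df)
  out$single_copy_y <- as.logical(out$single_copy_y)
  check_intervals(out, "gene annotation")
  out$tss <- ifelse(out$strand == "-", out$end - 1L, out$start)
  out
}

#' Read an interval annotation (BED6 plus optional class/family columns)
#'
#' Accepts plain BED6 (chrom, start, end, name, score, strand) or the
#' package's extended form with `class` and `family` columns. Repeat
#' records must carry a non-empty family label.
#'
#' @param path BED/TSV file path (no header for plain BED; a header line
#'   beginning with `chrom` is detected and parsed).
#' @param class Default class label applied when the file has no class
#'   column (e.g. `"repeat"`, `"CGI"`, `"imprinted"`).
#' @return Tibble with columns chrom, start, end, name, class, family,
#'   strand (0-based half-open).
#' @export
read_intervals <- function(path, class = NA_character_) {
  first <- readLines(path, n = 1)
  has_header <- startsWith(first, "chrom")
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)
  if (!has_header) {
    nm <- c("chrom", "start", "end", "name", "score", "strand", "class",
            "family")[seq_len(ncol(df))]
    names(df) <- nm
  }
  out <- as_tibble(df)
  if (is.null(out[["name"]])) out$name <- paste0("iv", seq_len(nrow(out)))
  if (is.null(out[["strand"]])) out$strand <- "."
  if (is.null(out[["class"]])) out$class <- class
  if (is.null(out[["family"]])) out$family <- NA_character_
  out <- out[, c("chrom", "start", "end", "name", "class", "family", "strand")]
  check_intervals(out, "interval set")
  bad_rep <- !is.na(out$class) & out$class == "repeat" &
    (is.na(out$family) | out$family == "")
  if (any(bad_rep)) abort("repeat interval(s) without a family label")
  out
}

#' Write intervals as BED6(+class,family)
#'
#' @param intervals Tibble with chrom, start, end and optionally name,
#'   class, family, strand.
#' @param path Output path.
#' @param header Write a header line (default TRUE; the reader detects it).
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path, header = TRUE) {
  df <- data.frame(
    chrom = intervals$chrom, start = intervals$start, end = intervals$end,
    name = intervals[["name"]] %||% paste0("iv", seq_len(nrow(intervals))),
    class = intervals[["class"]] %||% NA_character_,
    family = intervals[["family"]] %||% NA_character_,
    strand = intervals[["strand"]] %||% "."
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = header)
  invisible(path)
}

#' Read Bismark-coverage-style CpG methylation calls
#'
#' Expected columns: chrom, start, end (1-based, start == end for a CpG),
#' methylation percentage, methylated count, unmethylated count. The level
#' is recomputed from the counts; a stated percentage disagreeing by more
#' than 0.5 percentage points triggers a warning naming the first offending
#' row.
#'
#' @param path TSV path (no header).
#' @return Tibble with chrom, pos (0-based position of the C), meth, total,
#'   level.
#' @export
read_cpg_table <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6) abort("coverage file needs 6 columns")
  names(df) <- c("chrom", "start", "end", "pct", "meth", "unmeth")
  if (!is.numeric(df$meth) || !is.numeric(df$unmeth)) {
    abort("non-numeric methylation counts")
  }
  if (any(df$meth < 0) || any(df$unmeth < 0)) {
    abort("negative methylation count(s)")
  }
  total <- df$meth + df$unmeth
  if (any(total == 0)) abort("CpG row(s) with zero coverage")
  level <- df$meth / total
  stated <- df$pct / 100
  off <- which(abs(level - stated) > 0.005)
  if (length(off) > 0) {
    warn(paste0(length(off), " CpG row(s) where the stated percentage ",
                "disagrees with the counts by > 0.5 pp (first: ",
                df$chrom[off[1]], ":", df$start[off[1]], ")"))
  }
  tibble(chrom = as.character(df$chrom), pos = as.integer(df$start) - 1L,
         meth = as.integer(df$meth), total = as.integer(total),
         level = level)
}

#' Write CpG methylation calls in Bismark coverage format
#'
#' @param cpgs Tibble with chrom, pos (0-based), meth, total.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cpg_table <- function(cpgs, path) {
  df <- data.frame(
    chrom = cpgs$chrom, start = cpgs$pos + 1L, end = cpgs$pos + 1L,
    pct = round(100 * cpgs$meth / cpgs$total, 6),
    meth = cpgs$meth, unmeth = cpgs$total - cpgs$meth
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-(cell, SNV) allelic read counts
#'
#' TSV with header: cell, chrom, pos, ref, alt, ref_reads, alt_reads,
#' validated, gene.
#'
#' @param path TSV path.
#' @return Tibble with a logical `validated` column.
#' @export
read_allelic_table <- function(path) {
  df <- as_tibble(utils::read.delim(path, header = TRUE,
                                    stringsAsFactors = FALSE))
  need <- c("cell", "chrom", "pos", "ref", "alt", "ref_reads", "alt_reads",
            "validated", "gene")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("allelic table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(df$ref_reads < 0) || any(df$alt_reads < 0)) {
    abort("negative allelic read count(s)")
  }
  df$validated <- as.logical(df$validated)
  df
}

#' Write an allelic count table
#' @param table Tibble as returned by [read_allelic_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allelic_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a two-column genome sizes file
#'
#' @param path TSV path: chrom, size (no header).
#' @return Tibble with chrom, size.
#' @export
read_genome_sizes <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("chrom", "size")[seq_len(ncol(df))]
  if (any(df$size <= 0)) abort("non-positive chromosome size")
  as_tibble(df[, c("chrom", "size")])
}

#' Write a genome sizes file
#' @param sizes Tibble with chrom, size.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_sizes <- function(sizes, path) {
  utils::write.table(as.data.frame(sizes[, c("chrom", "size")]), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Report chromosome-name disjointness between two sources
#'
#' Chromosome names are taken verbatim from inputs (no "chr" normalisation);
#' this validator surfaces accidental mismatches.
#'
#' @param a,b Character vectors (or tibbles with a `chrom` column).
#' @return Invisibly, a list with `only_a` and `only_b`; messages when
#'   either is non-empty.
#' @export
check_chrom_names <- function(a, b) {
  ca <- unique(if (is.data.frame(a)) a$chrom else a)
  cb <- unique(if (is.data.frame(b)) b$chrom else b)
  only_a <- setdiff(ca, cb)
  only_b <- setdiff(cb, ca)
  if (length(only_a) > 0 || length(only_b) > 0) {
    inform(paste0("chromosome names differ between sources; only in first: [",
                  paste(only_a, collapse = ", "), "], only in second: [",
                  paste(only_b, collapse = ", "), "]"))
  }
  invisible(list(only_a = only_a, only_b = only_b))
}

check_intervals <- function(df, what) {
  if (any(df$start < 0)) abort(paste0(what, ": negative start coordinate"))
  bad <- df$start >= df$end
  if (any(bad)) {
    abort(paste0(what, ": start >= end at row ", which(bad)[1]))
  }
  invisible(df)
}

# shared helper: GRanges from a chrom/start/end tibble (0-based half-open
# in, 1-based closed inside GRanges)
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}
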