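#' Coverage-weighted methylation level per interval
#'
#' For each interval, pools the methylated and total read counts of the
#' CpGs it contains: `level = sum(meth) / sum(total)` (weighted mean, the
#' roimethstat convention). With `thr$region_level = "mean"` the unweighted
#' mean of per-CpG levels is used instead. Intervals containing no covered
#' CpG report a missing level, never zero.
#'
#' @param cpgs CpG tibble (chrom, pos, meth, total) as from
#'   [read_cpg_table()] or [simulate_methylome()].
#' @param intervals Tibble with chrom, start, end (0-based half-open) and
#'   optionally name.
#' @param genome_sizes Optional genome sizes tibble; when supplied (or
#'   failing that, against the CpG table's chromosomes), intervals on
#'   unknown chromosomes raise an error.
#' @param thr A [thresholds()] object.
#' @return Tibble: the intervals plus n_cpg_covered, total_meth_reads,
#'   total_reads, level.
#' @export
region_methylation <- function(cpgs, intervals, genome_sizes = NULL,
                               thr = thresholds()) {
  intervals <- as_tibble(intervals)
  known <- if (!is.null(genome_sizes)) genome_sizes$chrom else unique(cpgs$chrom)
  bad <- setdiff(unique(intervals$chrom), known)
  if (length(bad) > 0) {
    abort(paste0("interval(s) on unknown chromosome(s): ",
                 paste(bad, collapse = ", ")))
  }
  check_intervals(intervals, "region_methylation")
  iv_gr <- as_granges0(intervals)
  cpg_gr <- GenomicRanges::GRanges(cpgs$chrom,
                                   IRanges::IRanges(cpgs$pos + 1L, width = 1L))
  hit <- GenomicRanges::findOverlaps(cpg_gr, iv_gr)
  qi <- S4Vectors::queryHits(hit)
  si <- S4Vectors::subjectHits(hit)
  n <- nrow(intervals)
  out <- intervals
  out$n_cpg_covered <- tabulate(si, nbins = n)
  out$total_meth_reads <- as.integer(rowsum_by(cpgs$meth[qi], si, n))
  out$total_reads <- as.integer(rowsum_by(cpgs$total[qi], si, n))
  out$level <- if (thr$region_level == "weighted") {
    ifelse(out$total_reads > 0, out$total_meth_reads / out$total_reads,
           NA_real_)
  } else {
    lv <- rowsum_by(cpgs$meth[qi] / cpgs$total[qi], si, n)
    ifelse(out$n_cpg_covered > 0, lv / out$n_cpg_covered, NA_real_)
  }
  out
}

rowsum_by <- function(x, index, nbins) {
  out <- numeric(nbins)
  if (length(x) > 0) {
    s <- rowsum(x, index)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Methylation level in fixed-width genomic tiles
#'
#' Non-overlapping left-closed tiles cover each chromosome; the last
#' partial tile is kept. Levels are coverage-weighted as in
#' [region_methylation()].
#'
#' @param cpgs CpG tibble.
#' @param genome_sizes Genome sizes tibble (chrom, size).
#' @param tile Tile width in bp (default `thr$tile_global` = 1,000).
#' @param thr A [thresholds()] object.
#' @return Tibble: chrom, start, end, tile_id, n_cpg_covered,
#'   total_meth_reads, total_reads, level.
#' @export
tile_methylation <- function(cpgs, genome_sizes, tile = NULL,
                             thr = thresholds()) {
  tile <- tile %||% thr$tile_global
  tiles <- genome_tiles(genome_sizes, tile)
  region_methylation(cpgs, tiles, genome_sizes = genome_sizes, thr = thr)
}

#' Genome-wide weighted methylation level
#'
#' `sum(meth) / sum(total)` over all CpGs of a sample.
#'
#' @param cpgs CpG tibble.
#' @return A single proportion.
#' @export
global_methylation <- function(cpgs) {
  sum(cpgs$meth) / sum(cpgs$total)
}

#' Scaled gene methylation metaprofile
#'
#' Mean methylation from `flank` bp upstream of the TSS, across the gene
#' body scaled to a fixed number of bins, to `flank` bp downstream of the
#' TES. Flank bins have fixed width (`flank / n_flank`); body bins scale
#' with gene length. Minus-strand genes are reversed so bin 1 is always
#' 5' upstream. Bins average coverage-weighted levels pooled across genes.
#' Genes with a body shorter than `n_body` bp are skipped with a message.
#'
#' @param cpgs CpG tibble.
#' @param genes Gene tibble with chrom, start, end, strand.
#' @param thr A [thresholds()] object (`metaprofile_flank`).
#' @param n_flank,n_body Bin counts for each flank and the body
#'   (defaults 50/100).
#' @return Tibble: bin (1..n_flank + n_body + n_flank), zone
#'   ("upstream"/"body"/"downstream"), level (pooled weighted mean),
#'   n_cpg.
#' @export
gene_metaprofile <- function(cpgs, genes, thr = thresholds(),
                             n_flank = 50L, n_body = 100L) {
  flank <- thr$metaprofile_flank
  genes <- as_tibble(genes)
  short <- genes$end - genes$start < n_body
  if (any(short)) {
    inform(paste0(sum(short), " gene(s) shorter than ", n_body,
                  " bp skipped in the metaprofile"))
    genes <- genes[!short, ]
  }
  span <- tibble(chrom = genes$chrom,
                 start = pmax(0L, genes$start - as.integer(flank)),
                 end = genes$end + as.integer(flank))
  gr <- as_granges0(span)
  cpg_gr <- GenomicRanges::GRanges(cpgs$chrom,
                                   IRanges::IRanges(cpgs$pos + 1L, width = 1L))
  hit <- GenomicRanges::findOverlaps(cpg_gr, gr)
  qi <- S4Vectors::queryHits(hit)
  gi <- S4Vectors::subjectHits(hit)
  pos <- cpgs$pos[qi]
  gstart <- genes$start[gi]
  gend <- genes$end[gi]
  glen <- gend - gstart
  minus <- genes$strand[gi] == "-"
  # oriented distance from the 5' gene start, upstream negative
  d5 <- ifelse(minus, gend - 1L - pos, pos - gstart)
  total_bins <- 2L * n_flank + n_body
  bin <- integer(length(d5))
  up <- d5 < 0
  inb <- d5 >= 0 & d5 < glen
  dn <- d5 >= glen
  fw <- flank / n_flank
  bin[up] <- n_flank + 1L + floor(d5[up] / fw)          # d5 in [-flank, 0)
  bin[inb] <- n_flank + 1L + floor(d5[inb] / glen[inb] * n_body)
  bin[dn] <- n_flank + n_body + 1L + floor((d5[dn] - glen[dn]) / fw)
  ok <- bin >= 1L & bin <= total_bins
  agg <- tibble(bin = bin[ok], meth = cpgs$meth[qi][ok],
                total = cpgs$total[qi][ok]) |>
    dplyr::group_by(bin) |>
    dplyr::summarise(level = sum(meth) / sum(total), n_cpg = dplyr::n())
  tibble(bin = seq_len(total_bins),
         zone = rep(c("upstream", "body", "downstream"),
                    times = c(n_flank, n_body, n_flank))) |>
    dplyr::left_join(agg, by = "bin") |>
    dplyr::mutate(n_cpg = dplyr::coalesce(n_cpg, 0L))
}
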