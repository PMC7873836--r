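#' Filter low-quality cells
#'
#' Removes cells with fewer than `min_mapped_reads` reads mapped to gene
#' transcripts or a mitochondrial read proportion at or above
#' `max_mito_fraction` (cells strictly below the cutoff are kept). An
#' explicit exclude list replaces non-reproducible visual outlier removal;
#' excluded cells are flagged and removed.
#'
#' @param tpm Genes x cells TPM matrix.
#' @param cells Tibble with `cell`, `mapped_read_count`, `mito_fraction`
#'   for every matrix column.
#' @param thr A [thresholds()] object.
#' @param exclude Character vector of cell ids to drop as outliers.
#' @return List with `tpm` (filtered matrix, gene set untouched) and `qc`
#'   (per-cell tibble: cell, mapped_read_count, mito_fraction, pass_reads,
#'   pass_mito, outlier_flag, kept, reason).
#' @examples
#' sim <- simulate_expression(simulate_genome(1, "tiny"),
#'   data.frame(stage = "S", n_cells = 4, sex = "F", xc_state = "XCI"),
#'   seed = 1)
#' filter_cells(sim$tpm, sim$cells, thresholds())$qc
#' @export
filter_cells <- function(tpm, cells, thr = thresholds(), exclude = character()) {
  cells <- as_tibble(cells)
  miss <- setdiff(colnames(tpm), cells$cell)
  if (length(miss) > 0) {
    abort(paste0("cell(s) missing metadata: ", paste(head(miss, 5), collapse = ", ")))
  }
  if (any(is.na(cells$mapped_read_count)) || any(is.na(cells$mito_fraction))) {
    abort("mapped_read_count / mito_fraction must be non-missing")
  }
  qc <- cells[match(colnames(tpm), cells$cell),
              c("cell", "mapped_read_count", "mito_fraction")]
  qc$pass_reads <- qc$mapped_read_count >= thr$min_mapped_reads
  qc$pass_mito <- qc$mito_fraction < thr$max_mito_fraction
  qc$outlier_flag <- qc$cell %in% exclude
  qc$kept <- qc$pass_reads & qc$pass_mito & !qc$outlier_flag
  qc$reason <- dplyr::case_when(
    !qc$pass_reads ~ "reads",
    !qc$pass_mito ~ "mito",
    qc$outlier_flag ~ "outlier",
    TRUE ~ NA_character_
  )
  list(tpm = tpm[, qc$kept, drop = FALSE], qc = qc)
}

#' Detect expressed genes
#'
#' A gene is expressed when its TPM exceeds `min_tpm` in at least
#' `min_cells_expressing` cells.
#'
#' @param tpm Genes x cells TPM matrix.
#' @param thr A [thresholds()] object.
#' @return Tibble: gene_id, n_cells_expressing, detected.
#' @export
detect_expressed_genes <- function(tpm, thr = thresholds()) {
  n <- if (ncol(tpm) == 0) integer(nrow(tpm)) else {
    as.integer(rowSums(tpm > thr$min_tpm))
  }
  tibble(gene_id = rownames(tpm) %||% character(0),
         n_cells_expressing = n,
         detected = n >= thr$min_cells_expressing)
}

#' Infer embryonic sex per cell
#'
#' Two-pass rule. Pass 1: a cell is provisionally male when the summed TPM
#' of annotated chrY single-copy genes reaches `chry_male_tpm` (default
#' 10), otherwise female. Pass 2: the chrY:chrX total-TPM ratio is computed
#' for every cell; any provisional male whose ratio is lower than the
#' maximum ratio among provisional females is reclassified female. The
#' ratio uses all chrY genes by default (`thr$yx_ratio_genes = "all"`), or
#' only single-copy ones when set to `"single_copy"`. Pass 2 is applied
#' once, not iterated.
#'
#' @param tpm Genes x cells TPM matrix.
#' @param genes Gene annotation tibble with `gene_id`, `chrom`,
#'   `single_copy_y`.
#' @param thr A [thresholds()] object.
#' @return Tibble: cell, chry_single_tpm, yx_ratio, provisional_sex,
#'   final_sex, reclassified.
#' @export
infer_sex <- function(tpm, genes, thr = thresholds()) {
  genes <- as_tibble(genes)
  g <- genes[match(rownames(tpm), genes$gene_id), ]
  if (any(is.na(g$chrom))) abort("matrix gene(s) missing from annotation")
  y_single <- which(g$chrom == "chrY" & g$single_copy_y)
  x_rows <- which(g$chrom == "chrX")
  if (length(y_single) == 0) abort("no annotated single-copy chrY genes")
  if (length(x_rows) == 0) abort("no annotated chrX genes")
  y_rows <- if (thr$yx_ratio_genes == "all") which(g$chrom == "chrY") else y_single

  chry_single <- colSums(tpm[y_single, , drop = FALSE])
  x_total <- colSums(tpm[x_rows, , drop = FALSE])
  if (any(x_total == 0)) {
    abort(paste0("zero total chrX TPM in cell(s): ",
                 paste(head(colnames(tpm)[x_total == 0], 5), collapse = ", ")))
  }
  yx <- colSums(tpm[y_rows, , drop = FALSE]) / x_total
  prov <- ifelse(chry_single >= thr$chry_male_tpm, "M", "F")

  final <- prov
  if (!any(prov == "F")) {
    warn("no provisional female cells; pass-2 reclassification skipped")
  } else if (any(prov == "M")) {
    max_f <- max(yx[prov == "F"])
    flip <- prov == "M" & yx < max_f
    final[flip] <- "F"
  }
  tibble(cell = colnames(tpm), chry_single_tpm = unname(chry_single),
         yx_ratio = unname(yx), provisional_sex = unname(prov),
         final_sex = unname(final),
         reclassified = unname(prov == "M" & final == "F"))
}

#' XIST expression per cell
#'
#' Convenience extractor: XIST is an ordinary matrix row; this returns its
#' TPM per cell (useful alongside sex and XCR state calls).
#'
#' @param tpm Genes x cells TPM matrix.
#' @param gene_id XIST row name (default "XIST").
#' @return Tibble: cell, xist_tpm.
#' @export
xist_expression <- function(tpm, gene_id = "XIST") {
  if (!gene_id %in% rownames(tpm)) abort(paste0("gene not found: ", gene_id))
  tibble(cell = colnames(tpm), xist_tpm = unname(tpm[gene_id, ]))
}
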