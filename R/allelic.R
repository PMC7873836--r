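#' Filter allelic SNV records and call allelic status
#'
#' Three filters applied in a fixed order: (1) non-validated SNV sites are
#' dropped; (2) (cell, SNV) records with fewer than `snv_min_reads`
#' (default 3) total reads are dropped; (3) SNVs that, after the coverage
#' filter, are observed in fewer than `snv_min_cells` (default 2) cells of
#' a stage are dropped. Recurrence is evaluated within each stage, after
#' the coverage filter. Surviving records receive an allelic status via
#' [call_allelic_status()]; filtered records are kept with status
#' `"filtered"` and a `filter_reason`.
#'
#' @param table Allelic count tibble (cell, chrom, pos, ref_reads,
#'   alt_reads, validated, gene).
#' @param cells Tibble with `cell` and `stage`.
#' @param thr A [thresholds()] object.
#' @return The table with added columns stage, total, status,
#'   filter_reason.
#' @export
filter_snvs <- function(table, cells, thr = thresholds()) {
  tb <- as_tibble(table)
  tb$total <- tb$ref_reads + tb$alt_reads
  tb <- dplyr::left_join(tb, as_tibble(cells)[, c("cell", "stage")],
                         by = "cell")
  if (any(is.na(tb$stage))) abort("record(s) from cells without a stage")
  tb$filter_reason <- NA_character_
  tb$filter_reason[tb$total < thr$snv_min_reads] <- "low-coverage"
  tb$filter_reason[!tb$validated] <- "not-validated"
  survives <- is.na(tb$filter_reason)
  rec <- tb[survives, ] |>
    dplyr::distinct(stage, chrom, pos, cell) |>
    dplyr::count(stage, chrom, pos, name = "n_cells")
  tb <- dplyr::left_join(tb, rec, by = c("stage", "chrom", "pos"))
  tb$n_cells <- dplyr::coalesce(tb$n_cells, 0L)
  not_rec <- survives & tb$n_cells < thr$snv_min_cells
  tb$filter_reason[not_rec] <- "not-recurrent"
  tb$n_cells <- NULL
  tb$status <- ifelse(is.na(tb$filter_reason),
                      call_allelic_status(tb$ref_reads, tb$alt_reads, thr),
                      "filtered")
  tb
}

#' Call mono- or biallelic status for SNV read counts
#'
#' A site is biallelic when the minor allele has at least
#' `allele_detect_min_reads` reads (default 2) and makes up at least
#' `allele_detect_min_frac` (default 10%) of the site's reads; otherwise it
#' is monoallelic toward the majority allele (ties broken toward ref,
#' which cannot occur for a biallelic-failing tie only at total 0).
#'
#' @param ref_reads,alt_reads Integer vectors of per-site allele counts.
#' @param thr A [thresholds()] object.
#' @return Character vector: "biallelic", "monoallelic-ref",
#'   "monoallelic-alt".
#' @examples
#' call_allelic_status(c(10, 5, 19), c(0, 5, 1), thresholds())
#' @export
call_allelic_status <- function(ref_reads, alt_reads, thr = thresholds()) {
  total <- ref_reads + alt_reads
  if (any(total == 0)) abort("site(s) with zero total reads; filter first")
  minor <- pmin(ref_reads, alt_reads)
  bi <- minor >= thr$allele_detect_min_reads &
    minor / total >= thr$allele_detect_min_frac
  ifelse(bi, "biallelic",
         ifelse(alt_reads > ref_reads, "monoallelic-alt", "monoallelic-ref"))
}

#' Identify somatic XCI-escaper genes
#'
#' X-linked genes with at least one biallelic SNV call in at least one
#' somatic female cell, with per-gene supporting SNV-call counts. These
#' genes escape X inactivation in soma and are excluded when counting
#' XCR-driven biallelic genes in germ cells.
#'
#' @param calls Output of [filter_snvs()].
#' @param cells Tibble with `cell`, `sex` (or `final_sex`/`sex_true`) and
#'   `celltype` or `stage` identifying somatic cells.
#' @param somatic Value(s) of `celltype`/`stage` marking somatic cells.
#' @return Tibble of class `"escaper_set"`: gene, n_biallelic_calls,
#'   n_cells.
#' @export
identify_escapers <- function(calls, cells, somatic = "soma") {
  cells <- as_tibble(cells)
  sex <- cells[["final_sex"]] %||% cells[["sex_true"]] %||% cells[["sex"]]
  type <- cells[["celltype"]] %||% cells[["stage"]]
  soma_f <- cells$cell[sex == "F" & type %in% somatic]
  if (length(soma_f) == 0) abort("no somatic female cells")
  esc <- calls |>
    dplyr::filter(.data$cell %in% soma_f, .data$status == "biallelic") |>
    dplyr::group_by(gene) |>
    dplyr::summarise(n_biallelic_calls = dplyr::n(),
                     n_cells = dplyr::n_distinct(cell)) |>
    dplyr::arrange(gene)
  class(esc) <- c("escaper_set", class(esc))
  esc
}

#' Count biallelic non-escaper X-linked genes per female cell
#'
#' For each female cell, the number of distinct X-linked genes with at
#' least one biallelic SNV call, excluding somatic escaper genes. Cells
#' with no biallelic calls report zero.
#'
#' @param calls Output of [filter_snvs()].
#' @param escapers An `escaper_set` (or character vector of gene ids).
#' @param cells Tibble with `cell` and a sex column; only female cells are
#'   reported.
#' @return Tibble: cell, stage, n_biallelic_genes.
#' @export
count_biallelic_genes <- function(calls, escapers, cells) {
  esc_genes <- if (is.data.frame(escapers)) escapers$gene else escapers
  cells <- as_tibble(cells)
  sex <- cells[["final_sex"]] %||% cells[["sex_true"]] %||% cells[["sex"]]
  fem <- cells[sex == "F", c("cell", "stage")]
  counts <- calls |>
    dplyr::filter(.data$status == "biallelic",
                  !.data$gene %in% esc_genes,
                  .data$cell %in% fem$cell) |>
    dplyr::group_by(cell) |>
    dplyr::summarise(n_biallelic_genes = dplyr::n_distinct(gene))
  fem |>
    dplyr::left_join(counts, by = "cell") |>
    dplyr::mutate(n_biallelic_genes = dplyr::coalesce(n_biallelic_genes, 0L))
}
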