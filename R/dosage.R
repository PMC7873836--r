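#' Per-cell chromosomal geometric mean expression
#'
#' `exp(mean(log(TPM + 1)))` over a chromosome's expressed genes, per cell.
#'
#' @param tpm Genes x cells TPM matrix.
#' @param genes Gene annotation tibble (gene_id, chrom).
#' @param chrom Chromosome id.
#' @param cells Optional subset of cell ids.
#' @param expressed Optional character vector of expressed gene ids to
#'   restrict to (default: all genes on the chromosome).
#' @param thr A [thresholds()] object (pseudocount).
#' @return Tibble: cell, chrom, geomean_tpm.
#' @export
chrom_geometric_mean <- function(tpm, genes, chrom, cells = NULL,
                                 expressed = NULL, thr = thresholds()) {
  ids <- genes$gene_id[genes$chrom == chrom]
  if (!is.null(expressed)) ids <- intersect(ids, expressed)
  ids <- intersect(ids, rownames(tpm))
  if (length(ids) == 0) abort(paste0("no (expressed) genes on ", chrom))
  if (is.null(cells)) cells <- colnames(tpm)
  sub <- tpm[ids, cells, drop = FALSE]
  gm <- exp(colMeans(log(sub + thr$geomean_pseudocount)))
  tibble(cell = cells, chrom = chrom, geomean_tpm = unname(gm))
}

shared_expressed_genes <- function(tpm, genes, chrom, f_cells, m_cells, thr) {
  ids <- intersect(genes$gene_id[genes$chrom == chrom], rownames(tpm))
  expr_in <- function(cc) {
    rowSums(tpm[ids, cc, drop = FALSE] > thr$min_tpm) >= 1
  }
  ids[expr_in(f_cells) & expr_in(m_cells)]
}

#' Chromosome-level female:male expression ratio
#'
#' Restricts to genes expressed (TPM > `min_tpm` in at least one cell) in
#' both sexes within the stage, then summarises each sex's expression per
#' chromosome — geometric mean of TPM + 1 over (gene, cell) pairs by
#' default, or summed TPM with `thr$fm_summary = "total"` — and returns the
#' female:male ratio.
#'
#' @param tpm Genes x cells TPM matrix.
#' @param genes Gene annotation tibble.
#' @param sex_calls Tibble with `cell` and `final_sex` (as from
#'   [infer_sex()]), optionally `stage`.
#' @param stage Stage label to restrict to (requires a `stage` column);
#'   NULL uses all cells.
#' @param chroms Chromosomes to evaluate.
#' @param thr A [thresholds()] object.
#' @return Tibble: stage, chrom, n_shared_genes, f_summary, m_summary,
#'   fm_ratio.
#' @export
fm_ratio <- function(tpm, genes, sex_calls, stage = NULL,
                     chroms = c("chrX", "auto1", "auto2", "auto3"),
                     thr = thresholds()) {
  sc <- as_tibble(sex_calls)
  if (!is.null(stage)) sc <- sc[sc$stage == stage, ]
  sc <- sc[sc$cell %in% colnames(tpm), ]
  f_cells <- sc$cell[sc$final_sex == "F"]
  m_cells <- sc$cell[sc$final_sex == "M"]
  if (length(f_cells) == 0 || length(m_cells) == 0) {
    abort(paste0("stage ", stage %||% "<all>", " lacks both sexes"))
  }
  purrr::map(chroms, function(ch) {
    ids <- shared_expressed_genes(tpm, genes, ch, f_cells, m_cells, thr)
    if (length(ids) == 0) {
      abort(paste0("no shared expressed genes on ", ch))
    }
    summ <- function(cc) {
      sub <- tpm[ids, cc, drop = FALSE]
      if (thr$fm_summary == "geomean") {
        exp(mean(log(sub + thr$geomean_pseudocount)))
      } else {
        sum(sub) / length(cc)
      }
    }
    f <- summ(f_cells); m <- summ(m_cells)
    tibble(stage = stage %||% NA_character_, chrom = ch,
           n_shared_genes = length(ids), f_summary = f, m_summary = m,
           fm_ratio = f / m)
  }) |> list_rbind()
}

#' Windowed female:male ratio across chrX
#'
#' Genes are binned by TSS into consecutive windows (default 1 Mb,
#' right-open: a TSS exactly on a boundary belongs to the window starting
#' there). The per-gene ratio is `(mean TPM over females + 1) / (mean TPM
#' over males + 1)`; each window reports the median over its genes.
#' Windows with fewer than `fm_min_genes` genes are reported with a
#' missing ratio, never zero.
#'
#' @param tpm Genes x cells TPM matrix.
#' @param genes Gene annotation tibble with `tss`.
#' @param sex_calls Tibble with `cell`, `final_sex`, optionally `stage`.
#' @param chrom_size Length of the chromosome (bp), to tile it fully.
#' @param stage Optional stage restriction.
#' @param chrom Chromosome (default "chrX").
#' @param thr A [thresholds()] object (`fm_window`, `fm_min_genes`).
#' @return Tibble: stage, chrom, start, end, n_genes, median_fm_ratio.
#' @export
fm_ratio_windows <- function(tpm, genes, sex_calls, chrom_size,
                             stage = NULL, chrom = "chrX",
                             thr = thresholds()) {
  sc <- as_tibble(sex_calls)
  if (!is.null(stage)) sc <- sc[sc$stage == stage, ]
  sc <- sc[sc$cell %in% colnames(tpm), ]
  f_cells <- sc$cell[sc$final_sex == "F"]
  m_cells <- sc$cell[sc$final_sex == "M"]
  if (length(f_cells) == 0 || length(m_cells) == 0) {
    abort("window ratios need both sexes")
  }
  g <- genes[genes$chrom == chrom & genes$gene_id %in% rownames(tpm), ]
  ratio <- (rowMeans(tpm[g$gene_id, f_cells, drop = FALSE]) + 1) /
    (rowMeans(tpm[g$gene_id, m_cells, drop = FALSE]) + 1)
  win <- floor(g$tss / thr$fm_window)
  starts <- seq.int(0, max(chrom_size - 1, 0), by = thr$fm_window)
  per_win <- tibble(win = win, ratio = ratio) |>
    dplyr::group_by(win) |>
    dplyr::summarise(n_genes = dplyr::n(), med = median(ratio))
  out <- tibble(
    stage = stage %||% NA_character_, chrom = chrom,
    start = as.integer(starts),
    end = as.integer(pmin(starts + thr$fm_window, chrom_size)),
    win = starts %/% thr$fm_window
  ) |>
    dplyr::left_join(per_win, by = "win") |>
    dplyr::mutate(
      n_genes = dplyr::coalesce(n_genes, 0L),
      median_fm_ratio = ifelse(n_genes >= thr$fm_min_genes, med, NA_real_)
    ) |>
    dplyr::select(stage, chrom, start, end, n_genes, median_fm_ratio)
  out
}

#' Bootstrapped X:autosome expression ratio per cell
#'
#' Per replicate, `n_genes` expressed X-linked genes and `n_genes`
#' expressed autosomal genes are drawn without replacement; the replicate
#' ratio is the summed TPM of the X draw over the summed TPM of the
#' autosomal draw. The cell's ratio is the median over `n_reps`
#' replicates. "Expressed" is determined over the cell's stage (all
#' supplied cells).
#'
#' @param tpm Genes x cells TPM matrix (cells of one stage).
#' @param genes Gene annotation tibble.
#' @param seed Integer seed.
#' @param n_genes,n_reps Draw size and replicate count (defaults from
#'   `thr`).
#' @param thr A [thresholds()] object.
#' @param autosomes Autosome ids.
#' @return Tibble: cell, x_to_alla (median replicate ratio), n_genes,
#'   n_reps.
#' @export
x_to_alla_bootstrap <- function(tpm, genes, seed,
                                n_genes = NULL, n_reps = NULL,
                                thr = thresholds(),
                                autosomes = c("auto1", "auto2", "auto3")) {
  n_genes <- n_genes %||% thr$boot_genes
  n_reps <- n_reps %||% thr$boot_reps
  det <- detect_expressed_genes(tpm, thr)
  expressed <- det$gene_id[det$detected]
  x_ids <- intersect(expressed, genes$gene_id[genes$chrom == "chrX"])
  a_ids <- intersect(expressed, genes$gene_id[genes$chrom %in% autosomes])
  if (length(x_ids) < n_genes || length(a_ids) < n_genes) {
    abort(paste0("insufficient expressed genes (X: ", length(x_ids),
                 ", autosomal: ", length(a_ids),
                 "); use a smaller n_genes"))
  }
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  xm <- tpm[x_ids, , drop = FALSE]
  am <- tpm[a_ids, , drop = FALSE]
  reps <- matrix(NA_real_, n_reps, ncol(tpm))
  for (r in seq_len(n_reps)) {
    xi <- sample.int(length(x_ids), n_genes)
    ai <- sample.int(length(a_ids), n_genes)
    reps[r, ] <- colSums(xm[xi, , drop = FALSE]) /
      colSums(am[ai, , drop = FALSE])
  }
  tibble(cell = colnames(tpm),
         x_to_alla = apply(reps, 2, median),
         n_genes = n_genes, n_reps = n_reps)
}
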