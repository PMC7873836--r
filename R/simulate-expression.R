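#' TPM from raw counts
#'
#' Length-normalises counts to transcripts-per-million:
#' `tpm_g = (c_g / l_g) / sum(c / l) * 1e6` per cell.
#'
#' @param counts Genes x cells count matrix.
#' @param lengths Gene lengths in bp, aligned to the rows.
#' @return Genes x cells TPM matrix (columns sum to 1e6 where any counts).
#' @export
tpm_from_counts <- function(counts, lengths) {
  stopifnot(nrow(counts) == length(lengths), all(lengths > 0))
  rate <- counts / (lengths / 1000)
  denom <- colSums(rate)
  denom[denom == 0] <- NA_real_
  sweep(rate, 2, denom, "/") * 1e6
}

#' Simulate a single-cell expression experiment with planted truth
#'
#' Draws per-gene negative-binomial counts (gene means lognormal across
#' genes, dispersion 0.2) and TPM-normalises them. The planted structure
#' mirrors germline X-reactivation biology: male cells express chrY
#' single-copy genes strongly and carry no XIST; female cells have zero chrY
#' output; XIST is high in XCI females and reduced tenfold in XCR females;
#' every X-linked gene's mean output is doubled in XCR cells relative to XCI
#' cells. A configurable fraction of cells is planted as QC failures
#' (mapped reads below 1 million, or mitochondrial fraction at/above 0.5).
#'
#' @param genome A `sim_genome`.
#' @param design Tibble with columns `stage`, `n_cells`, `sex` ("F"/"M"),
#'   `xc_state` ("XCI"/"XCR" for females, "male" for males).
#' @param seed Integer seed.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param base_meanlog,base_sdlog Lognormal parameters of per-gene mean TPM.
#' @param xist_tpm Mean XIST TPM in XCI females (males 0; XCR females
#'   `xist_tpm * xcr_xist_factor`).
#' @param xcr_xist_factor Residual XIST fraction in XCR females.
#' @param y_single_tpm Mean TPM of each chrY single-copy gene in males.
#' @param x_fold_xcr Fold change of X-linked gene means in XCR vs XCI cells.
#' @param qc_fail_frac Fraction of cells planted as QC failures.
#' @param n_escapers Number of X-linked genes flagged as somatic XCI
#'   escapers in the truth (biallelic in all female cells downstream).
#' @return A list with `tpm` (genes x cells matrix), `cells` (tibble: cell,
#'   stage, sex_true, xc_state, mapped_read_count, mito_fraction,
#'   qc_fail_type), and `truth` (escaper genes, design, effect parameters).
#' @export
simulate_expression <- function(genome, design, seed,
                                dispersion = 0.2,
                                base_meanlog = log(30), base_sdlog = 1,
                                xist_tpm = 100, xcr_xist_factor = 0.1,
                                y_single_tpm = 50, x_fold_xcr = 2,
                                qc_fail_frac = 0, n_escapers = 5) {
  stopifnot(inherits(genome, "sim_genome"))
  design <- as_tibble(design)
  need <- c("stage", "n_cells", "sex", "xc_state")
  if (!all(need %in% names(design))) {
    abort("design needs columns stage, n_cells, sex, xc_state")
  }
  if (any(design$n_cells < 1)) abort("each design group needs n_cells >= 1")
  bad <- design$sex == "M" & design$xc_state != "male"
  if (any(bad)) abort("male cells cannot carry an XCI/XCR state")
  if (any(design$sex == "F" & !design$xc_state %in% c("XCI", "XCR"))) {
    abort("female cells must be XCI or XCR")
  }

  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)

  g <- genome$genes
  n_gene <- nrow(g)
  base <- rlnorm(n_gene, base_meanlog, base_sdlog)
  is_y <- g$chrom == "chrY"
  is_x <- g$chrom == "chrX"
  is_xist <- g$gene_id == "XIST"
  base[is_y & g$single_copy_y] <- y_single_tpm
  base[is_y & !g$single_copy_y] <- 20

  x_ids <- setdiff(g$gene_id[is_x], "XIST")
  escapers <- sort(sample(x_ids, min(n_escapers, length(x_ids))))

  cells <- design |>
    dplyr::rowwise() |>
    dplyr::reframe(stage = stage, sex_true = sex, xc_state = xc_state,
                   idx = seq_len(n_cells)) |>
    dplyr::mutate(cell = sprintf("%s_%s_c%03d", stage, sex_true,
                                 cumsum_within(paste(stage, sex_true)))) |>
    dplyr::select(cell, stage, sex_true, xc_state)
  n_cell <- nrow(cells)

  fail_type <- rep("none", n_cell)
  if (qc_fail_frac > 0) {
    n_fail <- round(qc_fail_frac * n_cell)
    pick <- sample.int(n_cell, n_fail)
    fail_type[pick] <- sample(c("reads", "mito"), n_fail, replace = TRUE)
  }

  target_reads <- runif(n_cell, 2e6, 4e6)
  target_reads[fail_type == "reads"] <- runif(sum(fail_type == "reads"),
                                              3e5, 9e5)
  mito <- rbeta(n_cell, 2, 20)
  mito[fail_type == "mito"] <- runif(sum(fail_type == "mito"), 0.5, 0.8)

  counts <- matrix(0L, n_gene, n_cell,
                   dimnames = list(g$gene_id, cells$cell))
  for (j in seq_len(n_cell)) {
    eff <- base
    if (cells$sex_true[j] == "M") {
      eff[is_xist] <- 0
      # one active X in males: same per-gene output as an XCI female
    } else {
      eff[is_y] <- 0
      if (cells$xc_state[j] == "XCR") {
        eff[is_x & !is_xist] <- eff[is_x & !is_xist] * x_fold_xcr
        eff[is_xist] <- xist_tpm * xcr_xist_factor
      } else {
        eff[is_xist] <- xist_tpm
      }
    }
    mu_rel <- eff * g$length / 1000
    k <- target_reads[j] / sum(mu_rel)
    counts[, j] <- rnbinom(n_gene, mu = k * mu_rel, size = 1 / dispersion)
  }

  tpm <- tpm_from_counts(counts, g$length)
  cells$mapped_read_count <- colSums(counts)
  cells$mito_fraction <- mito
  cells$qc_fail_type <- fail_type

  list(
    tpm = tpm,
    cells = cells,
    truth = list(escaper_genes = escapers, design = design,
                 x_fold_xcr = x_fold_xcr, xist_tpm = xist_tpm,
                 y_single_tpm = y_single_tpm, seed = seed)
  )
}

cumsum_within <- function(key) {
  stats::ave(seq_along(key), key, FUN = seq_along)
}
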