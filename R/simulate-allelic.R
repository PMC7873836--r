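#' Simulate per-(cell, SNV) allelic read counts at X-linked SNVs
#'
#' Each female cell draws reads at every X SNV: XCI cells express one
#' haplotype (chosen at random per cell) with a small per-read error rate
#' toward the silent allele; XCR cells draw the two alleles binomially at
#' probability 0.5; SNVs in planted escaper genes are biallelic in every
#' female cell regardless of state. Male cells (one X, haplotype 1 = ref)
#' are monoallelic up to the error rate. Read totals per site are Poisson
#' with the given mean depth; zero-read sites are dropped (unobserved).
#' A configurable fraction of SNV sites is marked `validated = FALSE`
#' (emulating the dbSNP VLD flag used by the upstream filter); every
#' planted escaper gene keeps at least one validated SNV, since an escaper
#' is by definition observable through validated biallelic sites.
#'
#' @param genome A `sim_genome`.
#' @param cells Cell tibble from [simulate_expression()].
#' @param truth Truth list from [simulate_expression()] (escaper genes).
#' @param depth Mean reads per (cell, SNV).
#' @param error_rate Per-read probability of reporting the silent allele.
#' @param validated_frac Fraction of SNV sites flagged validated.
#' @param seed Integer seed.
#' @return Tibble: cell, chrom, pos, ref, alt, ref_reads, alt_reads,
#'   validated, gene.
#' @export
simulate_allelic_counts <- function(genome, cells, truth, depth = 20,
                                    error_rate = 0.001,
                                    validated_frac = 0.9, seed = 1) {
  stopifnot(inherits(genome, "sim_genome"), depth > 0)
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)

  snvs <- genome$snvs
  n_snv <- nrow(snvs)
  validated <- runif(n_snv) < validated_frac
  escaper <- snvs$gene %in% truth$escaper_genes
  # keep every escaper gene observable through >= 1 validated SNV
  for (gid in intersect(truth$escaper_genes, snvs$gene)) {
    idx <- which(snvs$gene == gid)
    if (!any(validated[idx])) validated[idx[1]] <- TRUE
  }

  grid <- tidyr::expand_grid(cell = cells$cell, i = seq_len(n_snv))
  grid <- dplyr::left_join(grid,
                           cells[, c("cell", "sex_true", "xc_state")],
                           by = "cell")
  # active haplotype per XCI female cell (1 = ref haplotype)
  xci_cells <- cells$cell[cells$xc_state == "XCI"]
  active <- setNames(sample(1:2, length(xci_cells), replace = TRUE),
                     xci_cells)

  p_alt <- numeric(nrow(grid))
  is_esc <- escaper[grid$i]
  is_male <- grid$sex_true == "M"
  is_xcr <- grid$xc_state == "XCR"
  is_xci <- grid$xc_state == "XCI"
  p_alt[is_male] <- error_rate
  p_alt[is_xcr] <- 0.5
  hap <- active[grid$cell[is_xci]]
  p_alt[is_xci] <- ifelse(hap == 1, error_rate, 1 - error_rate)
  p_alt[is_esc & !is_male] <- 0.5

  total <- rpois(nrow(grid), depth)
  keep <- total > 0
  grid <- grid[keep, ]
  total <- total[keep]
  alt_n <- rbinom(length(total), total, p_alt[keep])

  tibble(
    cell = grid$cell,
    chrom = snvs$chrom[grid$i],
    pos = snvs$pos[grid$i],
    ref = snvs$ref[grid$i],
    alt = snvs$alt[grid$i],
    ref_reads = as.integer(total - alt_n),
    alt_reads = as.integer(alt_n),
    validated = validated[grid$i],
    gene = snvs$gene[grid$i]
  )
}
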