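# Shared fixtures, built in code and cached for the session.
.fx <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(build)
  .fx[[name]]
}

fx_genome <- function() fx("genome", simulate_genome(1, "tiny"))

fx_expression <- function() {
  fx("expression", simulate_expression(fx_genome(), default_design(20),
                                       seed = 2, qc_fail_frac = 0.05))
}

fx_allelic <- function() {
  sim <- fx_expression()
  fx("allelic", simulate_allelic_counts(fx_genome(), sim$cells, sim$truth,
                                        depth = 20, seed = 3))
}

fx_methylome <- function() {
  fx("methylome", simulate_methylome(
    fx_genome(),
    tibble::tibble(name = c("pgc", "soma"), class = c("PGC", "soma"),
                   sex = "F"),
    seed = 4
  ))
}

# tiny hand-made CpG table on one chromosome
make_cpg <- function(pos, meth, total, chrom = "c1") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos),
                 meth = as.integer(meth), total = as.integer(total),
                 level = meth / total)
}

# independent naive oracle for region methylation (per-CpG loop)
naive_region_meth <- function(cpgs, intervals) {
  vapply(seq_len(nrow(intervals)), function(i) {
    sel <- cpgs$chrom == intervals$chrom[i] &
      cpgs$pos >= intervals$start[i] & cpgs$pos < intervals$end[i]
    if (!any(sel)) return(NA_real_)
    sum(cpgs$meth[sel]) / sum(cpgs$total[sel])
  }, numeric(1))
}

# independent two-sided Fisher p: sum of hypergeometric point masses not
# exceeding the observed one (stats::dhyper only; no fisher.test)
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p0 <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}
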