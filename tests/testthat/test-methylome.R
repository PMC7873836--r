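test_that("region methylation pools reads, not site means, by default", {
  cpg <- make_cpg(pos = c(10, 20, 500), meth = c(5, 0, 9),
                  total = c(10, 10, 9))
  iv <- tibble::tibble(chrom = "c1", start = 0L, end = 100L, name = "r1")
  rm1 <- region_methylation(cpg, iv, genome_sizes = NULL)
  expect_equal(rm1$level, 0.25)
  expect_equal(rm1$n_cpg_covered, 2L)

  empty <- tibble::tibble(chrom = "c1", start = 200L, end = 300L)
  expect_true(is.na(region_methylation(cpg, empty)$level))

  off <- tibble::tibble(chrom = "c9", start = 0L, end = 10L)
  expect_error(region_methylation(cpg, off), "unknown chromosome")

  thr_mean <- thresholds(region_level = "mean")
  rm2 <- region_methylation(cpg, iv, thr = thr_mean)
  expect_equal(rm2$level, 0.25)  # equal coverage: weighted == mean here
  cpg2 <- make_cpg(pos = c(10, 20), meth = c(1, 5), total = c(2, 50))
  rm3 <- region_methylation(cpg2, iv, thr = thr_mean)
  expect_equal(rm3$level, mean(c(0.5, 0.1)))
})

test_that("region methylation equals the naive per-CpG oracle exactly", {
  m <- fx_methylome()
  cpg <- m$samples$pgc
  set.seed(42)
  n <- 200
  chroms <- sample(unique(cpg$chrom), n, replace = TRUE)
  start <- floor(runif(n, 0, 9.9e5))
  iv <- tibble::tibble(chrom = chroms, start = as.integer(start),
                       end = as.integer(start + round(runif(n, 50, 5000))))
  fast <- region_methylation(cpg, iv, fx_genome()$sizes)
  slow <- naive_region_meth(cpg, iv)
  expect_identical(is.na(fast$level), is.na(slow))
  expect_equal(fast$level, slow)
})

test_that("tiling covers chromosomes with a kept partial last tile", {
  sizes <- tibble::tibble(chrom = "c1", size = 2500L)
  tiles <- genome_tiles(sizes, 1000L)
  expect_equal(nrow(tiles), 3)
  expect_equal(tiles$end, c(1000L, 2000L, 2500L))
  cpg <- make_cpg(pos = c(10, 1500, 2400), meth = c(1, 2, 3),
                  total = c(2, 4, 6))
  tm <- tile_methylation(cpg, sizes, tile = 1000L)
  expect_equal(tm$level, c(0.5, 0.5, 0.5))
})

test_that("simulated PGC and soma tile distributions recover their rates", {
  g <- fx_genome()
  m <- fx_methylome()
  tp <- tile_methylation(m$samples$pgc, g$sizes)
  ts <- tile_methylation(m$samples$soma, g$sizes)
  expect_lt(median(tp$level, na.rm = TRUE), 0.05)
  expect_gt(median(ts$level, na.rm = TRUE), 0.70)

  # genome-wide weighted levels within 3 binomial SE of the generating
  # mixture expectation
  for (cls in c("pgc", "soma")) {
    cpg <- m$samples[[cls]]
    gm <- global_methylation(cpg)
    esc_gr <- m$truth$escapee_tiles
    in_esc <- rep(FALSE, nrow(cpg))
    for (i in seq_len(nrow(esc_gr))) {
      in_esc <- in_esc | (cpg$chrom == esc_gr$chrom[i] &
                            cpg$pos >= esc_gr$start[i] &
                            cpg$pos < esc_gr$end[i])
    }
    cgi <- fx_genome()$cgi
    in_cgi <- rep(FALSE, nrow(cpg))
    for (i in seq_len(nrow(cgi))) {
      in_cgi <- in_cgi | (cpg$chrom == cgi$chrom[i] &
                            cpg$pos >= cgi$start[i] & cpg$pos < cgi$end[i])
    }
    rate <- if (cls == "pgc") ifelse(in_esc, 0.40, 0.01)
            else ifelse(in_cgi, 0.10, 0.75)
    expected <- sum(rate * cpg$total) / sum(cpg$total)
    se <- sqrt(sum(rate * (1 - rate) * cpg$total)) / sum(cpg$total)
    expect_lt(abs(gm - expected), 3 * se)
  }
})

test_that("metaprofiles are flat on uniform methylomes", {
  g <- fx_genome()
  set.seed(5)
  cpg <- g$cpg_sites
  cov <- rpois(nrow(cpg), 10)
  keep <- cov > 0
  cpg <- tibble::tibble(chrom = cpg$chrom[keep], pos = cpg$pos[keep],
                        meth = rbinom(sum(keep), cov[keep], 0.3),
                        total = cov[keep])
  prof <- suppressMessages(gene_metaprofile(cpg, g$genes))
  expect_equal(nrow(prof), 200)
  expect_true(all(abs(prof$level - 0.3) < 0.05))
})

test_that("minus-strand genes mirror their plus-strand profile", {
  # one gene, methylation ramps across it; flipping the strand must flip
  # the profile
  cpg <- make_cpg(pos = seq(1000, 4999, by = 10),
                  meth = rep(c(0, 10), each = 200),
                  total = 10, chrom = "c1")
  gplus <- tibble::tibble(chrom = "c1", start = 1000L, end = 5000L,
                          strand = "+", gene_id = "g")
  gminus <- gplus; gminus$strand <- "-"
  thr <- thresholds(metaprofile_flank = 500L)
  p_plus <- gene_metaprofile(cpg, gplus, thr, n_flank = 10, n_body = 20)
  p_minus <- gene_metaprofile(cpg, gminus, thr, n_flank = 10, n_body = 20)
  body_p <- p_plus$level[p_plus$zone == "body"]
  body_m <- p_minus$level[p_minus$zone == "body"]
  expect_equal(body_m, rev(body_p))
})

test_that("short genes are skipped with a log message", {
  cpg <- make_cpg(pos = c(10, 50), meth = c(1, 1), total = c(2, 2))
  genes <- tibble::tibble(chrom = "c1", start = c(0L, 500L),
                          end = c(40L, 2000L), strand = "+",
                          gene_id = c("short", "long"))
  expect_message(gene_metaprofile(cpg, genes, n_body = 100L), "skipped")
})
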