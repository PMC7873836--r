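one_tile_cpgs <- function(levels, coverage = 10L) {
  # place CpGs inside the first 800-nt tile of a 1600-bp chromosome
  make_cpg(pos = seq(10, by = 40, length.out = length(levels)),
           meth = as.integer(round(levels * coverage)), total = coverage)
}

tiny_sizes <- tibble::tibble(chrom = "c1", size = 1600L)

test_that("the meth+ rule is strict on the CpG fraction", {
  # 10 covered CpGs, 3 at level >= 0.15 -> frac 0.30 -> meth+
  cpg <- one_tile_cpgs(c(rep(0, 7), 0.2, 0.3, 1))
  scan <- detect_escapees(cpg, tiny_sizes)
  expect_equal(scan$class[1], "meth+")
  expect_equal(scan$frac[1], 0.3)
  # 2 of 10 qualifying -> frac 0.20 -> meth- (strictly greater required)
  cpg2 <- one_tile_cpgs(c(rep(0, 8), 0.3, 1))
  scan2 <- detect_escapees(cpg2, tiny_sizes)
  expect_equal(scan2$class[1], "meth-")
  # low-coverage CpGs are invisible to the rule
  cpg3 <- one_tile_cpgs(rep(1, 10), coverage = 4L)
  expect_equal(detect_escapees(cpg3, tiny_sizes)$class[1], "uncallable")
  # fewer than 5 callable CpGs -> uncallable
  cpg4 <- one_tile_cpgs(rep(1, 4))
  expect_equal(detect_escapees(cpg4, tiny_sizes)$class[1], "uncallable")
})

test_that("escapee calls are monotone in the methylation threshold", {
  m <- fx_methylome()
  g <- fx_genome()
  lv <- c(0.10, 0.15, 0.30, 0.50)
  scans <- lapply(lv, function(l) {
    detect_escapees(m$samples$pgc, g$sizes,
                    thresholds(escapee_meth_level = l))
  })
  n_pos <- vapply(scans, function(s) sum(s$class == "meth+"), integer(1))
  expect_true(all(diff(n_pos) <= 0))
  # no meth- tile becomes meth+ when the threshold rises
  for (i in seq_len(length(lv) - 1)) {
    was_minus <- scans[[i]]$class == "meth-"
    expect_false(any(scans[[i + 1]]$class[was_minus] == "meth+"))
  }
})

test_that("planted escapee tiles are recovered with high sensitivity", {
  m <- fx_methylome()
  g <- fx_genome()
  scan <- detect_escapees(m$samples$pgc, g$sizes)
  called <- scan$tile_id[scan$class == "meth+"]
  truth <- m$truth$escapee_tiles$tile_id
  sens <- mean(truth %in% called)
  fdr <- if (length(called) > 0) mean(!called %in% truth) else 0
  expect_gte(sens, 0.95)
  expect_lte(fdr, 0.05)
})

test_that("at saturating coverage the scan matches the generating rates", {
  g <- fx_genome()
  m <- simulate_methylome(g, tibble::tibble(name = "p", class = "PGC",
                                            sex = "F"),
                          seed = 8, coverage = 200)
  scan <- detect_escapees(m$samples$p, g$sizes)
  called <- scan$tile_id[scan$class == "meth+"]
  # rate 0.40 tiles are all meth+; rate 0.01 background has essentially
  # no CpG reaching level 0.15 at coverage ~200
  expect_setequal(called, m$truth$escapee_tiles$tile_id)
})

test_that("TE overlap fractions use union semantics", {
  tiles <- tibble::tibble(chrom = "c1", start = 0L, end = 800L,
                          tile_id = "t")
  reps <- tibble::tibble(chrom = "c1", start = c(0L, 0L, 100L),
                         end = c(50L, 79L, 129L), family = "L1")
  out <- classify_te_content(tiles, reps)
  expect_equal(out$te_overlap_frac, (79 + 29) / 800)
  expect_equal(out$te_class, "TE-rich")
  # 79 of 800 bases: 0.09875 < 0.10 -> TE-poor
  out2 <- classify_te_content(tiles, reps[2, ])
  expect_equal(out2$te_overlap_frac, 0.09875)
  expect_equal(out2$te_class, "TE-poor")
  inside <- tibble::tibble(chrom = "c1", start = 100L, end = 900L,
                           family = "L1")
  out3 <- classify_te_content(tiles[, 1:3],
                              tibble::tibble(chrom = "c1", start = 0L,
                                             end = 1600L, family = "L1"))
  expect_equal(out3$te_overlap_frac, 1)
})

test_that("enrichment scores and Fisher p match independent computation", {
  # null identity: equal overlap fractions give ES 1
  mk_tiles <- function(n, chrom = "c1") {
    tibble::tibble(chrom = chrom, start = seq(0L, by = 800L, length.out = n),
                   end = seq(800L, by = 800L, length.out = n))
  }
  esc <- mk_tiles(10)
  bg <- mk_tiles(100)
  reps <- tibble::tibble(chrom = "c1", start = c(0L, 800L),
                         end = c(50L, 850L), family = "fam")
  # first 1 of 10 escapee tiles overlap (0.1); 2 of 100 background... make
  # fractions equal: escapee tiles are a subset of background here, use
  # counts directly
  te <- te_enrichment(esc, bg, reps)
  expect_equal(te$es, (2 / 10) / (2 / 100) * 1)  # 2 of first 10, 2 of 100

  # the worked 2x2 table: 8/20 escapee vs 10/200 background -> ES 8
  a <- 8; n_e <- 20; c_ <- 10; n_b <- 200
  es <- (a / n_e) / (c_ / n_b)
  expect_equal(es, 8)
  p_pkg <- stats::fisher.test(matrix(c(a, n_e - a, c_, n_b - c_), 2))$p.value
  p_ora <- fisher_oracle(a, n_e - a, c_, n_b - c_)
  expect_equal(p_pkg, p_ora, tolerance = 1e-9)

  expect_message(te_enrichment(esc, bg, reps, families = c("fam", "ghost")),
                 "ghost")
})

test_that("the planted young family is flagged and only it", {
  g <- fx_genome()
  m <- fx_methylome()
  scan <- detect_escapees(m$samples$pgc, g$sizes)
  scan <- classify_te_content(scan, g$repeats)
  callable <- scan[scan$class != "uncallable", ]
  esc <- callable[callable$class == "meth+" & callable$te_class == "TE-rich", ]
  te <- te_enrichment(esc, callable, g$repeats)
  young <- te[te$family == m$truth$young_family, ]
  expect_true(young$enriched)
  expect_gt(young$es, 2)
  expect_lt(young$p, 0.001)
  others <- te[te$family != m$truth$young_family, ]
  expect_false(any(others$enriched))
})

test_that("RPM normalisation is linear, scale-invariant and additive", {
  counts <- tibble::tibble(name = c("r1", "r2", "r3"),
                           family = c("f1", "f1", "f2"),
                           count = c(100, 50, 25),
                           length = c(1000, 2000, 500))
  out <- repeat_expression_rpm(counts, 1e6)
  expect_equal(out$rpm, c(100, 50, 25))
  out2 <- repeat_expression_rpm(dplyr::mutate(counts, count = count * 2),
                                2e6)
  expect_equal(out2$rpm, out$rpm)
  fam <- attr(out, "family")
  expect_equal(fam$rpm[fam$family == "f1"], 150)
  outk <- repeat_expression_rpm(counts, 1e6, rpkm = TRUE)
  expect_equal(outk$rpm, c(100, 25, 50))
  expect_error(repeat_expression_rpm(counts, 0), "positive")
})
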