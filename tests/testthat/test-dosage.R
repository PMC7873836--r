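toy_genes <- function() {
  tibble::tibble(
    gene_id = c("x1", "x2", "a1", "a2"),
    chrom = c("chrX", "chrX", "auto1", "auto1"),
    tss = c(0L, 1.5e6, 0L, 100L)
  )
}

test_that("chromosomal geometric means match their closed forms", {
  m <- matrix(c(0, 3,
                0, 0,
                7, 7,
                1, 1), nrow = 4, byrow = TRUE,
              dimnames = list(c("x1", "x2", "a1", "a2"), c("c1", "c2")))
  g <- toy_genes()
  gm <- chrom_geometric_mean(m, g, "chrX")
  # TPM+1 of (0,0) and (3,0) per cell: geomean(1,1)=1, geomean(4,1)=2
  expect_equal(gm$geomean_tpm, c(1, 2))
  one <- chrom_geometric_mean(m["a1", , drop = FALSE], g, "auto1")
  expect_equal(one$geomean_tpm, c(8, 8))  # single gene TPM 7 -> 8
  expect_error(chrom_geometric_mean(m, g, "chr9"), "no .*genes")
})

test_that("F:M ratios need both sexes and shared expressed genes", {
  m <- matrix(5, 4, 4,
              dimnames = list(c("x1", "x2", "a1", "a2"), paste0("c", 1:4)))
  sex <- tibble::tibble(cell = paste0("c", 1:4),
                        final_sex = c("F", "F", "M", "M"))
  fm <- fm_ratio(m, toy_genes(), sex, chroms = c("chrX", "auto1"))
  expect_equal(fm$fm_ratio, c(1, 1))  # identical expression: exact symmetry
  sex_f <- sex; sex_f$final_sex <- "F"
  expect_error(fm_ratio(m, toy_genes(), sex_f, chroms = "chrX"),
               "lacks both sexes")
  m0 <- m * 0
  expect_error(fm_ratio(m0, toy_genes(), sex, chroms = "chrX"),
               "no shared expressed genes")
})

test_that("planted 2x X dosage is recovered chromosome-wide", {
  g <- fx_genome()
  d <- tibble::tibble(stage = "PGC", n_cells = c(25, 25), sex = c("F", "M"),
                      xc_state = c("XCR", "male"))
  sim <- simulate_expression(g, d, seed = 21)
  sex <- infer_sex(sim$tpm, g$genes)
  sex$stage <- "PGC"
  fm <- fm_ratio(sim$tpm, g$genes, sex, stage = "PGC")
  expect_gt(fm$fm_ratio[fm$chrom == "chrX"], 1.8)
  expect_lt(fm$fm_ratio[fm$chrom == "chrX"], 2.2)
  expect_true(all(abs(fm$fm_ratio[fm$chrom != "chrX"] - 1) < 0.1))
})

test_that("windowed ratios bin by TSS, report empty windows as missing", {
  # x1 TSS 0 -> window [0, 1 Mb); x2 TSS 1.5 Mb -> window [1, 2 Mb)
  m <- matrix(c(9, 9, 4, 4,
                19, 19, 9, 9,
                5, 5, 5, 5,
                5, 5, 5, 5), nrow = 4, byrow = TRUE,
              dimnames = list(c("x1", "x2", "a1", "a2"), paste0("c", 1:4)))
  sex <- tibble::tibble(cell = paste0("c", 1:4),
                        final_sex = c("F", "F", "M", "M"))
  thr1 <- thresholds(fm_min_genes = 1L)
  win <- fm_ratio_windows(m, toy_genes(), sex, chrom_size = 3e6, thr = thr1)
  expect_equal(nrow(win), 3)
  # per-gene ratio (mean_F + 1) / (mean_M + 1): x1 10/5 = 2, x2 20/10 = 2
  expect_equal(win$median_fm_ratio, c(2, 2, NA))
  expect_equal(win$n_genes, c(1L, 1L, 0L))
  # gene on a boundary belongs to the right-open bin starting there
  g2 <- toy_genes(); g2$tss[2] <- 1e6
  win2 <- fm_ratio_windows(m, g2, sex, chrom_size = 3e6, thr = thr1)
  expect_equal(win2$n_genes, c(1L, 1L, 0L))
  # permutation invariance to gene order
  ord <- c(2, 4, 1, 3)
  win3 <- fm_ratio_windows(m[ord, ], g2[match(rownames(m)[ord], g2$gene_id), ],
                           sex, chrom_size = 3e6, thr = thr1)
  expect_equal(win3, win2)
})

test_that("the X:allA bootstrap has its degenerate identity and determinism", {
  # all expressed genes drawn each replicate, X total == autosome total
  m <- matrix(c(10, 10, 10, 10), 4, 3,
              dimnames = list(c("x1", "x2", "a1", "a2"), paste0("c", 1:3)))
  thr1 <- thresholds(min_cells_expressing = 1L)
  b <- x_to_alla_bootstrap(m, toy_genes(), seed = 1, n_genes = 2,
                           n_reps = 10, thr = thr1)
  expect_equal(b$x_to_alla, rep(1, 3))
  b2 <- x_to_alla_bootstrap(m, toy_genes(), seed = 1, n_genes = 2,
                            n_reps = 10, thr = thr1)
  expect_identical(b, b2)
  expect_error(
    x_to_alla_bootstrap(m, toy_genes(), seed = 1, n_genes = 3, thr = thr1),
    "smaller n_genes"
  )
})

test_that("bootstrap medians separate planted XCI from XCR cells", {
  g <- fx_genome()
  sim <- fx_expression()
  pgc_f <- sim$cells[sim$cells$stage == "PGC" & sim$cells$sex_true == "F", ]
  b <- x_to_alla_bootstrap(sim$tpm[, pgc_f$cell], g$genes, seed = 31,
                           n_genes = 20, n_reps = 200)
  b <- dplyr::left_join(b, pgc_f[, c("cell", "xc_state")], by = "cell")
  med <- tapply(b$x_to_alla, b$xc_state, median)
  expect_gt(med[["XCR"]] / med[["XCI"]], 1.7)
  ds <- compare_dosage_groups(b, "x_to_alla", "xc_state")
  expect_lt(tidy(ds)$p_value, 0.01)
})

test_that("bootstrap medians are stable across a 2x range of n_genes", {
  g <- fx_genome()
  sim <- fx_expression()
  xcr <- sim$cells$cell[sim$cells$xc_state == "XCR"]
  b1 <- x_to_alla_bootstrap(sim$tpm[, xcr], g$genes, seed = 41,
                            n_genes = 10, n_reps = 300)
  b2 <- x_to_alla_bootstrap(sim$tpm[, xcr], g$genes, seed = 42,
                            n_genes = 20, n_reps = 300)
  expect_equal(median(b1$x_to_alla), median(b2$x_to_alla), tolerance = 0.15)
})

test_that("rank tests match exact enumeration and flag planted shifts", {
  d <- data.frame(v = c(1, 2, 3, 11, 12, 13),
                  g = rep(c("a", "b"), each = 3))
  res <- compare_dosage_groups(d, "v", "g", "mann-whitney")
  # exact two-sided p by enumerating all 3-of-6 rank assignments
  combos <- combn(6, 3)
  u_stats <- apply(combos, 2, function(ix) sum(rank(d$v)[ix]) - 6)
  u_obs <- sum(rank(d$v)[1:3]) - 6
  p_exact <- mean(pmin(u_stats, 9 - u_stats) <= min(u_obs, 9 - u_obs))
  expect_equal(tidy(res)$p_value, p_exact)
  expect_equal(p_exact, 0.1)

  same <- data.frame(v = rep(c(1, 2, 3, 4), 2),
                     g = rep(c("a", "b"), each = 4))
  expect_gt(tidy(compare_dosage_groups(same, "v", "g"))$p_value, 0.95)

  set.seed(7)
  kd <- data.frame(v = c(rnorm(15), rnorm(15) + 3, rnorm(15) + 6),
                   g = rep(c("a", "b", "c"), each = 15))
  res3 <- compare_dosage_groups(kd, "v", "g", "kruskal-dunn")
  expect_lt(glance(res3)$omnibus_p, 1e-4)
  td <- tidy(res3)
  expect_equal(nrow(td), 3)
  expect_true(all(td$p_adjusted < 0.01))
  expect_error(compare_dosage_groups(kd[kd$g == "a", ], "v", "g"),
               "at least 2 groups")

  pw <- compare_dosage_groups(kd, "v", "g", "pairwise-wilcoxon")
  expect_true(all(tidy(pw)$p_adjusted >= tidy(pw)$p_value - 1e-12))
})
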