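test_that("genome generation is deterministic and seed-sensitive", {
  g1 <- simulate_genome(1, "tiny")
  g2 <- simulate_genome(1, "tiny")
  expect_identical(g1$genes, g2$genes)
  expect_identical(g1$snvs, g2$snvs)
  expect_identical(g1$cpg_sites, g2$cpg_sites)
  g3 <- simulate_genome(2, "tiny")
  expect_false(identical(g1$snvs$pos, g3$snvs$pos))
})

test_that("genome satisfies its structural contract", {
  g <- fx_genome()
  expect_gte(nrow(g$genes), 200)
  xg <- g$genes[g$genes$chrom == "chrX", ]
  expect_gte(nrow(xg), 30)
  # every X gene carries at least one SNV, inside the gene body
  expect_setequal(unique(g$snvs$gene), xg$gene_id)
  j <- match(g$snvs$gene, g$genes$gene_id)
  expect_true(all(g$snvs$pos >= g$genes$start[j] &
                    g$snvs$pos < g$genes$end[j]))
  expect_gte(length(unique(g$repeats$family)), 4)
  expect_gte(sum(g$genes$single_copy_y), 1)
  # genes do not overlap within a chromosome
  by_chrom <- split(g$genes, g$genes$chrom)
  for (gc in by_chrom) {
    gc <- gc[order(gc$start), ]
    expect_true(all(gc$start[-1] >= gc$end[-nrow(gc)]))
  }
  # intervals honour the BED invariants the readers enforce
  for (tab in list(g$promoters, g$cgi, g$repeats, g$imprinted)) {
    expect_true(all(tab$start < tab$end))
    expect_true(all(tab$start >= 0))
    expect_true(all(tab$chrom %in% g$sizes$chrom))
  }
})

test_that("expression carries the planted sex and dosage structure", {
  g <- fx_genome()
  sim <- fx_expression()
  y_single <- g$genes$gene_id[g$genes$single_copy_y]
  ytot <- colSums(sim$tpm[y_single, , drop = FALSE])
  males <- sim$cells$sex_true == "M"
  ok_reads <- sim$cells$qc_fail_type != "reads"
  expect_true(all(ytot[males & ok_reads] >= 10))
  expect_true(all(ytot[!males] == 0))

  # XCR doubles X-linked gene output relative to XCI (within 10%)
  x_ids <- setdiff(g$genes$gene_id[g$genes$chrom == "chrX"], "XIST")
  xcr <- sim$cells$cell[sim$cells$xc_state == "XCR"]
  xci <- sim$cells$cell[sim$cells$xc_state == "XCI" &
                          sim$cells$stage == "PGC"]
  ratio <- mean(sim$tpm[x_ids, xcr]) / mean(sim$tpm[x_ids, xci])
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)

  # XIST: high in XCI females, reduced in XCR, absent in males
  expect_gt(median(sim$tpm["XIST", xci]), 5 * median(sim$tpm["XIST", xcr]))
  expect_true(all(sim$tpm["XIST", males] == 0))
})

test_that("planted QC failures violate exactly the targeted cutoff", {
  sim <- fx_expression()
  fail_reads <- sim$cells$qc_fail_type == "reads"
  fail_mito <- sim$cells$qc_fail_type == "mito"
  expect_gt(sum(fail_reads) + sum(fail_mito), 0)
  expect_true(all(sim$cells$mapped_read_count[fail_reads] < 1e6))
  expect_true(all(sim$cells$mito_fraction[fail_mito] >= 0.5))
  clean <- sim$cells$qc_fail_type == "none"
  expect_true(all(sim$cells$mapped_read_count[clean] >= 1e6))
  expect_true(all(sim$cells$mito_fraction[clean] < 0.5))
})

test_that("a male XCR design is rejected", {
  d <- tibble::tibble(stage = "s", n_cells = 2, sex = "M", xc_state = "XCR")
  expect_error(simulate_expression(fx_genome(), d, seed = 1), "male cells")
})

test_that("allelic counts express the planted XC states", {
  g <- fx_genome()
  sim <- fx_expression()
  # error rate 0: XCI cells are exactly monoallelic at non-escaper SNVs
  al0 <- simulate_allelic_counts(g, sim$cells, sim$truth, depth = 20,
                                 error_rate = 0, seed = 5)
  xci <- sim$cells$cell[sim$cells$xc_state == "XCI"]
  nesc <- al0[al0$cell %in% xci & !al0$gene %in% sim$truth$escaper_genes, ]
  expect_true(all(nesc$ref_reads == 0 | nesc$alt_reads == 0))

  # XCR cells observe both alleles at essentially every well-covered site:
  # P(monoallelic | n reads) = 2 * 0.5^n
  xcr <- sim$cells$cell[sim$cells$xc_state == "XCR"]
  deep <- al0[al0$cell %in% xcr & al0$ref_reads + al0$alt_reads >= 10, ]
  both <- deep$ref_reads > 0 & deep$alt_reads > 0
  expect_gte(mean(both), 1 - 2 * 0.5^10 - 0.01)

  # escaper SNVs are biallelic even in somatic XCI females
  soma_f <- sim$cells$cell[sim$cells$stage == "soma" &
                             sim$cells$sex_true == "F"]
  esc <- al0[al0$cell %in% soma_f & al0$gene %in% sim$truth$escaper_genes &
               al0$ref_reads + al0$alt_reads >= 10, ]
  expect_gt(nrow(esc), 0)
  expect_gte(mean(esc$ref_reads > 0 & esc$alt_reads > 0), 1 - 2 * 0.5^10 - 0.05)

  # determinism
  al_a <- simulate_allelic_counts(g, sim$cells, sim$truth, seed = 6)
  al_b <- simulate_allelic_counts(g, sim$cells, sim$truth, seed = 6)
  expect_identical(al_a, al_b)
})

test_that("methylomes recover the generating rates and plant escapees", {
  g <- fx_genome()
  m <- fx_methylome()
  # PGC global rate: escapee tiles shift the 1% mixture upward slightly
  pgc <- m$samples$pgc
  expect_gt(global_methylation(pgc), 0.007)
  expect_lt(global_methylation(pgc), 0.02)
  soma <- m$samples$soma
  expect_gt(global_methylation(soma), 0.6)

  # planted tiles behave as escapees: most covered CpGs at level >= 0.15
  esc_gr <- m$truth$escapee_tiles
  rm_esc <- region_methylation(pgc, esc_gr, g$sizes)
  expect_gt(min(rm_esc$level), 0.2)

  m2 <- simulate_methylome(g, tibble::tibble(name = "p", class = "PGC",
                                             sex = "F"), seed = 4)
  m3 <- simulate_methylome(g, tibble::tibble(name = "p", class = "PGC",
                                             sex = "F"), seed = 4)
  expect_identical(m2$samples$p, m3$samples$p)
  expect_identical(m2$truth$escapee_tiles, m3$truth$escapee_tiles)
})

test_that("generated bundles satisfy every reader invariant (round-trip)", {
  dir <- withr::local_tempdir()
  suppressMessages(run_simulate(dir, seed = 11, scale = "tiny",
                                design = default_design(4, 2, 2)))
  expect_silent({
    tpm <- read_expression_matrix(file.path(dir, "matrix.tsv"))
    sizes <- read_genome_sizes(file.path(dir, "genome.sizes"))
    reps <- read_intervals(file.path(dir, "repeats.bed"))
    al <- read_allelic_table(file.path(dir, "allelic.tsv"))
    cpg <- read_cpg_table(file.path(dir, "meth_PGC_F.cov"))
  })
  expect_true(all(reps$chrom %in% sizes$chrom))
  expect_true(all(al$ref_reads + al$alt_reads > 0))
  expect_true(all(cpg$total >= cpg$meth))
})
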