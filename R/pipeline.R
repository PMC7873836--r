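#' Default simulation design
#'
#' Germ cells at two XC states plus a somatic reference, both sexes; the
#' group sizes keep dosage and allelic comparisons powered while staying
#' desk-sized.
#'
#' @param n_pgc Cells per PGC group (female XCI, female XCR, male).
#' @param n_soma_f,n_soma_m Somatic female / male cells.
#' @return Design tibble for [simulate_expression()].
#' @export
default_design <- function(n_pgc = 20, n_soma_f = 3, n_soma_m = 3) {
  tibble(
    stage = c("PGC", "PGC", "PGC", "soma", "soma"),
    n_cells = c(n_pgc, n_pgc, n_pgc, n_soma_f, n_soma_m),
    sex = c("F", "F", "M", "F", "M"),
    xc_state = c("XCI", "XCR", "male", "XCI", "male")
  )
}

#' Simulate and write a full input bundle
#'
#' Generates the toy genome, expression matrix, allelic counts and
#' methylomes, and writes every on-disk format the analysis subcommands
#' consume, plus the ground truth as JSON. Fully deterministic per seed:
#' reruns are byte-identical.
#'
#' @param out Output directory (created if absent).
#' @param seed Integer seed.
#' @param thr A [thresholds()] object.
#' @param scale Genome scale, `"tiny"` or `"default"`.
#' @param design Simulation design (default [default_design()]).
#' @param qc_fail_frac Planted QC-failure fraction.
#' @return Invisibly, a list of written paths.
#' @export
run_simulate <- function(out, seed, thr = thresholds(), scale = "tiny",
                         design = default_design(), qc_fail_frac = 0.05) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  genome <- simulate_genome(seed, scale)
  sim <- simulate_expression(genome, design, seed = seed + 1,
                             qc_fail_frac = qc_fail_frac)
  allelic <- simulate_allelic_counts(genome, sim$cells, sim$truth,
                                     seed = seed + 2)
  meth <- simulate_methylome(
    genome,
    tibble(name = c("PGC_F", "PGC_M", "Soma_F", "Soma_M"),
           class = c("PGC", "PGC", "soma", "soma"),
           sex = c("F", "M", "F", "M")),
    seed = seed + 3
  )
  p <- function(f) file.path(out, f)
  write_expression_matrix(sim$tpm, p("matrix.tsv"))
  utils::write.table(as.data.frame(genome$genes), p("genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(sim$cells), p("cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_genome_sizes(genome$sizes, p("genome.sizes"))
  write_intervals(genome$repeats, p("repeats.bed"))
  write_intervals(genome$cgi, p("cgi.bed"))
  write_intervals(genome$promoters, p("promoters.bed"))
  write_intervals(genome$imprinted, p("imprinted.bed"))
  write_allelic_table(allelic, p("allelic.tsv"))
  for (nm in names(meth$samples)) {
    write_cpg_table(meth$samples[[nm]], p(paste0("meth_", nm, ".cov")))
  }
  truth <- list(
    escaper_genes = sim$truth$escaper_genes,
    escapee_tiles = meth$truth$escapee_tiles,
    young_family = meth$truth$young_family,
    young_tile_frac_bg = meth$truth$young_tile_frac_bg,
    cells = sim$cells[, c("cell", "stage", "sex_true", "xc_state")]
  )
  jsonlite::write_json(truth, p("truth.json"), dataframe = "columns",
                       digits = NA)
  write_manifest(out, "simulate", seed, thr,
                 outputs = list.files(out))
  invisible(lapply(list.files(out, full.names = TRUE), identity))
}

#' Run cell QC on a bundle directory
#'
#' @param dir Bundle directory (from [run_simulate()] or equivalent files).
#' @param out Output directory.
#' @param seed Integer seed (recorded in the manifest; QC is
#'   deterministic).
#' @param thr A [thresholds()] object.
#' @param exclude Outlier cell ids to drop.
#' @return Invisibly, the QC tibble.
#' @export
run_qc <- function(dir, out, seed = 0, thr = thresholds(),
                   exclude = character()) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  tpm <- read_expression_matrix(file.path(dir, "matrix.tsv"))
  cells <- as_tibble(utils::read.delim(file.path(dir, "cells.tsv")))
  fc <- filter_cells(tpm, cells, thr, exclude)
  utils::write.table(as.data.frame(fc$qc), file.path(out, "qc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out, "qc", seed, thr, outputs = "qc.tsv")
  invisible(fc$qc)
}

#' Run sex inference on a bundle directory
#'
#' QC-filters cells, then applies the two-pass chrY rule.
#'
#' @inheritParams run_qc
#' @return Invisibly, the sex-call tibble.
#' @export
run_sex <- function(dir, out, seed = 0, thr = thresholds()) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  genes <- as_tibble(utils::read.delim(file.path(dir, "genes.tsv")))
  tpm <- read_expression_matrix(file.path(dir, "matrix.tsv"))
  cells <- as_tibble(utils::read.delim(file.path(dir, "cells.tsv")))
  fc <- filter_cells(tpm, cells, thr)
  sex <- infer_sex(fc$tpm, genes, thr)
  utils::write.table(as.data.frame(sex), file.path(out, "sex_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out, "sex", seed, thr, outputs = "sex_calls.tsv")
  invisible(sex)
}

#' Run the expression-dosage XCR analysis on a bundle directory
#'
#' Chromosome-level F:M ratios per stage, windowed ratios across chrX
#' (written as BEDGraph), and per-cell bootstrapped X:autosome ratios.
#'
#' @inheritParams run_qc
#' @param n_genes Bootstrap draw size override.
#' @return Invisibly, a list with `fm`, `windows`, `x_to_alla`.
#' @export
run_xcr <- function(dir, out, seed, thr = thresholds(), n_genes = NULL) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  genes <- as_tibble(utils::read.delim(file.path(dir, "genes.tsv")))
  sizes <- read_genome_sizes(file.path(dir, "genome.sizes"))
  tpm <- read_expression_matrix(file.path(dir, "matrix.tsv"))
  cells <- as_tibble(utils::read.delim(file.path(dir, "cells.tsv")))
  fc <- filter_cells(tpm, cells, thr)
  sex <- infer_sex(fc$tpm, genes, thr)
  sex <- dplyr::left_join(sex, cells[, c("cell", "stage", "xc_state")],
                          by = "cell")
  stages <- unique(sex$stage)
  both <- stages[vapply(stages, function(s) {
    length(unique(sex$final_sex[sex$stage == s])) == 2
  }, logical(1))]
  fm <- purrr::map(both, function(s) {
    fm_ratio(fc$tpm, genes, sex, stage = s, thr = thr)
  }) |> list_rbind()
  xsz <- sizes$size[sizes$chrom == "chrX"]
  win <- purrr::map(both, function(s) {
    fm_ratio_windows(fc$tpm, genes, sex, xsz, stage = s, thr = thr)
  }) |> list_rbind()
  boot <- purrr::map(seq_along(stages), function(i) {
    cc <- sex$cell[sex$stage == stages[i]]
    sub <- fc$tpm[, cc, drop = FALSE]
    det <- detect_expressed_genes(sub, thr)
    expressed <- det$gene_id[det$detected]
    nx <- length(intersect(expressed, genes$gene_id[genes$chrom == "chrX"]))
    na_ <- length(intersect(expressed,
                            genes$gene_id[startsWith(genes$chrom, "auto")]))
    ng <- min(n_genes %||% thr$boot_genes, nx, na_)
    if (ng < (n_genes %||% thr$boot_genes)) {
      inform(paste0("stage ", stages[i], ": bootstrap draw size reduced to ",
                    ng, " (expressed X: ", nx, ", autosomal: ", na_, ")"))
    }
    b <- x_to_alla_bootstrap(sub, genes, seed = seed + i, n_genes = ng,
                             thr = thr)
    b$stage <- stages[i]
    b
  }) |> list_rbind()
  utils::write.table(as.data.frame(fm), file.path(out, "fm_ratio.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bg <- win[!is.na(win$median_fm_ratio),
            c("chrom", "start", "end", "median_fm_ratio")]
  utils::write.table(as.data.frame(bg),
                     file.path(out, "fm_windows.bedgraph"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(as.data.frame(boot), file.path(out, "x_to_alla.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out, "xcr", seed, thr,
                 outputs = c("fm_ratio.tsv", "fm_windows.bedgraph",
                             "x_to_alla.tsv"))
  invisible(list(fm = fm, windows = win, x_to_alla = boot))
}

#' Run the allelic XCR analysis on a bundle directory
#'
#' Filters SNVs, calls allelic status, identifies somatic escapers and
#' counts biallelic non-escaper genes per female cell.
#'
#' @inheritParams run_qc
#' @param somatic Stage label(s) marking somatic cells.
#' @return Invisibly, a list with `calls`, `escapers`, `counts`.
#' @export
run_allelic <- function(dir, out, seed = 0, thr = thresholds(),
                        somatic = "soma") {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  allelic <- read_allelic_table(file.path(dir, "allelic.tsv"))
  cells <- as_tibble(utils::read.delim(file.path(dir, "cells.tsv")))
  calls <- filter_snvs(allelic, cells, thr)
  esc <- identify_escapers(calls, cells, somatic)
  cnt <- count_biallelic_genes(calls, esc, cells)
  utils::write.table(as.data.frame(calls), file.path(out, "snv_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(esc), file.path(out, "escapers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(cnt),
                     file.path(out, "biallelic_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out, "allelic", seed, thr,
                 outputs = c("snv_calls.tsv", "escapers.tsv",
                             "biallelic_counts.tsv"))
  invisible(list(calls = calls, escapers = esc, counts = cnt))
}

#' Run the methylome analysis on a bundle directory
#'
#' Per coverage file: 1-kb tile levels, feature-level methylation (CGIs,
#' promoters, imprinted regions, repeats), the scaled gene metaprofile,
#' 800-nt escapee tiles with TE classes (BED), and TE-family enrichment of
#' meth+ TE-rich escapees.
#'
#' @inheritParams run_qc
#' @return Invisibly, a named list per sample.
#' @export
run_methylome <- function(dir, out, seed = 0, thr = thresholds()) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  sizes <- read_genome_sizes(file.path(dir, "genome.sizes"))
  genes <- as_tibble(utils::read.delim(file.path(dir, "genes.tsv")))
  repeats <- read_intervals(file.path(dir, "repeats.bed"))
  feats <- dplyr::bind_rows(
    read_intervals(file.path(dir, "cgi.bed")),
    read_intervals(file.path(dir, "promoters.bed")),
    read_intervals(file.path(dir, "imprinted.bed"))
  )
  covs <- list.files(dir, pattern = "^meth_.*\\.cov$")
  res <- purrr::map(covs, function(f) {
    nm <- sub("^meth_(.*)\\.cov$", "\\1", f)
    cpgs <- read_cpg_table(file.path(dir, f))
    tiles <- tile_methylation(cpgs, sizes, thr = thr)
    featm <- region_methylation(cpgs, feats, sizes, thr)
    prof <- gene_metaprofile(cpgs, genes, thr)
    scan <- detect_escapees(cpgs, sizes, thr)
    scan <- classify_te_content(scan, repeats, thr)
    callable <- scan[scan$class != "uncallable", ]
    esc <- callable[callable$class == "meth+" &
                      callable$te_class == "TE-rich", ]
    te <- if (nrow(esc) > 0) {
      te_enrichment(esc, callable, repeats, thr = thr)
    } else NULL
    w <- function(x, f2) {
      utils::write.table(as.data.frame(x), file.path(out, f2), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    w(tiles, paste0(nm, "_tiles.tsv"))
    w(featm, paste0(nm, "_features.tsv"))
    w(prof, paste0(nm, "_metaprofile.tsv"))
    bed <- scan[, c("chrom", "start", "end", "class", "frac", "n_cpg_5x",
                    "te_overlap_frac", "te_class")]
    w(bed, paste0(nm, "_escapees.bed"))
    if (!is.null(te)) w(te, paste0(nm, "_te_enrichment.tsv"))
    list(tiles = tiles, features = featm, profile = prof, scan = scan,
         te = te)
  })
  names(res) <- sub("^meth_(.*)\\.cov$", "\\1", covs)
  write_manifest(out, "methylome", seed, thr, outputs = list.files(out))
  invisible(res)
}

write_manifest <- function(out, subcommand, seed, thr, outputs) {
  manifest <- list(
    tool = "germline-reset",
    subcommand = subcommand,
    seed = seed,
    thresholds = unclass(thr),
    outputs = sort(setdiff(outputs, "manifest.json"))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
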