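#' Simulate a toy genome with annotations
#'
#' Builds a deterministic five-chromosome genome (three autosomes, X, Y)
#' with non-overlapping gene models, promoters, CpG islands, repeat
#' intervals labelled by family, imprinted regions, phased SNV positions on
#' X-linked genes, and CpG dinucleotide positions. It is a stand-in for a
#' real genome annotation, sized so the downstream statistics behave like
#' their genome-scale counterparts: CpG density is 1 per 50 bp so an 800-nt
#' tile typically carries ~16 CpGs, and five repeat families cover ~46% of
#' the genome, with `Pre0_SS` the designated low-density
#' "young" family used for planted-enrichment experiments.
#'
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param scale `"tiny"` (1 Mb chromosomes, 400 genes, 30 X-linked) or
#'   `"default"` (10 Mb chromosomes, 1,275 genes, 60 X-linked).
#' @return A list of class `"sim_genome"` with tibbles: `sizes`, `genes`
#'   (chrom, start, end, gene_id, strand, single_copy_y, tss, tes, length),
#'   `promoters`, `cgi`, `repeats` (with `family`), `imprinted`, `snvs`
#'   (chrom, pos, gene, ref, alt; hap1 carries ref, hap2 alt), `cpg_sites`
#'   (chrom, pos), and `repeat_families` (family, density, young flag).
#' @examples
#' g <- simulate_genome(1, scale = "tiny")
#' nrow(g$genes)
#' @export
simulate_genome <- function(seed, scale = c("default", "tiny")) {
  scale <- match.arg(scale)
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)

  chrom_len <- if (scale == "tiny") 1e6L else 1e7L
  chroms <- c("auto1", "auto2", "auto3", "chrX", "chrY")
  sizes <- tibble(chrom = chroms, size = chrom_len)
  # chrX carries ~5% of genes, as in mammalian genomes: TPM is
  # compositional, so a planted 2x X dosage must not visibly deflate
  # autosomal TPM
  n_genes <- if (scale == "tiny") {
    c(auto1 = 120L, auto2 = 120L, auto3 = 120L, chrX = 30L, chrY = 10L)
  } else {
    c(auto1 = 400L, auto2 = 400L, auto3 = 400L, chrX = 60L, chrY = 15L)
  }
  n_single_y <- if (scale == "tiny") 6L else 10L

  genes <- purrr::map(chroms, function(ch) {
    n <- n_genes[[ch]]
    slot <- chrom_len %/% n
    len <- round(runif(n, 1500, min(6000, slot - 200)))
    offset <- floor(runif(n, 100, slot - len - 100))
    start <- (seq_len(n) - 1L) * slot + as.integer(offset)
    tibble(
      chrom = ch, start = start, end = start + as.integer(len),
      gene_id = paste0(ch, "_g", seq_len(n)),
      strand = sample(c("+", "-"), n, replace = TRUE),
      single_copy_y = ch == "chrY" & seq_len(n) <= n_single_y
    )
  }) |> list_rbind()
  # XIST: a designated X-linked lncRNA locus
  xist_row <- which(genes$chrom == "chrX")[1]
  genes$gene_id[xist_row] <- "XIST"
  genes$tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  genes$tes <- ifelse(genes$strand == "-", genes$start, genes$end - 1L)
  genes$length <- genes$end - genes$start

  promoters <- dplyr::mutate(
    genes,
    p_start = ifelse(strand == "-", tss - 500L + 1L, tss - 1000L),
    p_end = ifelse(strand == "-", tss + 1000L + 1L, tss + 500L)
  )
  promoters <- tibble(
    chrom = promoters$chrom,
    start = pmax(0L, as.integer(promoters$p_start)),
    end = pmin(chrom_len, as.integer(promoters$p_end)),
    name = paste0("prom_", promoters$gene_id),
    class = "promoter", family = NA_character_, strand = promoters$strand
  )

  # CpG islands over ~60% of promoters, centred on the TSS
  has_cgi <- runif(nrow(genes)) < 0.6
  cgi <- tibble(
    chrom = genes$chrom[has_cgi],
    start = pmax(0L, genes$tss[has_cgi] - 300L),
    end = pmin(chrom_len, genes$tss[has_cgi] + 300L),
    name = paste0("cgi_", genes$gene_id[has_cgi]),
    class = "CGI", family = NA_character_, strand = "."
  )

  # ~46% of the genome is repetitive (mammalian-like); dense repeats also
  # keeps the TE-rich tile class common, so conditioning escapees on TE
  # richness does not by itself inflate family overlap fractions
  fams <- tibble(
    family = c("L1_SS", "PRE1_SS", "SINEA", "MIR", "Pre0_SS"),
    density = c(0.15, 0.12, 0.10, 0.06, 0.03),
    min_len = c(800, 150, 150, 150, 300),
    max_len = c(3000, 600, 600, 600, 600),
    young = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  repeats <- purrr::pmap(fams, function(family, density, min_len, max_len,
                                        young) {
    purrr::map(chroms, function(ch) {
      mean_len <- (min_len + max_len) / 2
      n <- round(density * chrom_len / mean_len)
      len <- round(runif(n, min_len, max_len))
      start <- floor(runif(n, 0, chrom_len - len))
      tibble(chrom = ch, start = as.integer(start),
             end = as.integer(start + len), family = family)
    }) |> list_rbind()
  }) |> list_rbind()
  repeats <- dplyr::arrange(repeats, family, chrom, start)
  repeats$name <- paste0(repeats$family, "_", seq_len(nrow(repeats)))
  repeats$class <- "repeat"
  repeats$strand <- "."
  repeats <- repeats[, c("chrom", "start", "end", "name", "class", "family",
                         "strand")]

  imprinted <- purrr::map(c("auto1", "auto2", "auto3"), function(ch) {
    start <- as.integer(floor(runif(2, 0, chrom_len - 2000)))
    tibble(chrom = ch, start = start, end = start + 2000L,
           name = paste0("icr_", ch, "_", 1:2), class = "imprinted",
           family = NA_character_, strand = ".")
  }) |> list_rbind()

  # one SNV per ~2 kb of X gene body, at least one per gene; hap1 = ref
  xg <- genes[genes$chrom == "chrX", ]
  bases <- c("A", "C", "G", "T")
  snvs <- purrr::pmap(
    list(xg$gene_id, xg$start, xg$end),
    function(gid, s, e) {
      n <- max(1L, sample(1:3, 1))
      pos <- sort(sample(seq.int(s, e - 1L), n))
      ref <- sample(bases, n, replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1),
                    character(1))
      tibble(chrom = "chrX", pos = pos, gene = gid, ref = ref, alt = alt)
    }
  ) |> list_rbind()

  # CpG sites: background 1 per 50 bp, CGIs boosted so ~7% of all CpGs
  # fall in islands (as in mammalian genomes)
  cpg_sites <- purrr::map(chroms, function(ch) {
    n_bg <- round(chrom_len * 0.02)
    pos <- sample.int(chrom_len, n_bg) - 1L
    ci <- cgi[cgi$chrom == ch, ]
    if (nrow(ci) > 0) {
      extra <- purrr::map2(ci$start, ci$end, function(s, e) {
        s + sample.int(e - s, round((e - s) * 0.05)) - 1L
      })
      pos <- c(pos, unlist(extra))
    }
    tibble(chrom = ch, pos = sort(unique(pos)))
  }) |> list_rbind()

  structure(
    list(sizes = sizes, genes = genes, promoters = promoters, cgi = cgi,
         repeats = repeats, imprinted = imprinted, snvs = snvs,
         cpg_sites = cpg_sites,
         repeat_families = fams[, c("family", "density", "young")],
         scale = scale, seed = seed),
    class = "sim_genome"
  )
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("<sim_genome>", x$scale, "scale, seed", x$seed, "\n")
  cat("  ", nrow(x$genes), "genes (",
      sum(x$genes$chrom == "chrX"), "X-linked,",
      sum(x$genes$single_copy_y), "single-copy Y ),",
      nrow(x$snvs), "X SNVs,", nrow(x$repeats), "repeats,",
      nrow(x$cpg_sites), "CpG sites\n")
  invisible(x)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
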