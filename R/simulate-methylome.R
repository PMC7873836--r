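#' Simulate bisulfite methylomes with planted demethylation escapees
#'
#' Per sample, each CpG site of the genome receives Poisson coverage and a
#' binomial methylated-read count at the site's true rate. PGC-class
#' samples are near-completely demethylated (default global rate 1%) except
#' at planted 800-nt escapee tiles (default rate 40%); soma-class samples
#' are hypermethylated (default 75%) except at CpG islands (default 10%,
#' mimicking unmethylated islands). Escapee tiles are placed by rejection
#' sampling so that their overlap frequency with one designated "young"
#' repeat family reaches a stated fold (default 5x) over that family's
#' genome-wide tile frequency, giving a known 2x2 enrichment table. Planted
#' tiles are restricted to tiles containing at least `min_tile_cpgs` CpG
#' sites (an escapee region by definition contains methylated CpGs).
#'
#' @param genome A `sim_genome`.
#' @param samples Tibble with columns `name`, `class` ("PGC" or "soma"),
#'   `sex`.
#' @param seed Integer seed.
#' @param rate_pgc,rate_soma Global per-CpG methylation rates by class.
#' @param rate_cgi_soma CpG-island rate in soma samples.
#' @param escapee_rate Methylation rate inside planted escapee tiles (PGC
#'   samples only).
#' @param n_escapee Number of planted 800-nt escapee tiles.
#' @param te_fold Target fold of young-family overlap among escapee tiles
#'   relative to the genome-wide tile frequency.
#' @param young_family Repeat family receiving the planted enrichment.
#' @param coverage Mean Poisson read coverage per CpG.
#' @param tile Escapee tile width in bp.
#' @param min_tile_cpgs Minimum CpG sites a tile must contain to be
#'   eligible for planting.
#' @return List with `samples` (named list of CpG tibbles: chrom, pos,
#'   meth, total, level) and `truth` (escapee tile tibble with
#'   `young_overlap` flag, the young family, rates and the achieved
#'   young-overlap fraction).
#' @export
simulate_methylome <- function(genome, samples, seed,
                               rate_pgc = 0.01, rate_soma = 0.75,
                               rate_cgi_soma = 0.10, escapee_rate = 0.40,
                               n_escapee = 50, te_fold = 5,
                               young_family = "Pre0_SS", coverage = 10,
                               tile = 800L, min_tile_cpgs = 5L) {
  stopifnot(inherits(genome, "sim_genome"))
  samples <- as_tibble(samples)
  if (!all(c("name", "class") %in% names(samples))) {
    abort("samples needs columns name and class")
  }
  if (!all(samples$class %in% c("PGC", "soma"))) {
    abort("sample class must be PGC or soma")
  }
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)

  tiles <- genome_tiles(genome$sizes, tile)
  cpg <- genome$cpg_sites
  tiles_gr <- as_granges0(tiles)
  cpg_gr <- GenomicRanges::GRanges(cpg$chrom,
                                   IRanges::IRanges(cpg$pos + 1L, width = 1L))
  hit <- GenomicRanges::findOverlaps(cpg_gr, tiles_gr)
  cpg_per_tile <- tabulate(S4Vectors::subjectHits(hit), nbins = nrow(tiles))
  young <- genome$repeats[genome$repeats$family == young_family, ]
  if (nrow(young) == 0) abort(paste0("no repeats of family ", young_family))
  young_gr <- GenomicRanges::reduce(as_granges0(young))
  tile_young <- GenomicRanges::countOverlaps(tiles_gr, young_gr) > 0
  f_bg <- mean(tile_young)
  eligible <- cpg_per_tile >= min_tile_cpgs
  if (n_escapee > sum(eligible)) abort("not enough eligible tiles to plant")
  target_frac <- min(0.9, te_fold * f_bg)
  n_young <- round(n_escapee * target_frac)
  pool_y <- which(eligible & tile_young)
  pool_n <- which(eligible & !tile_young)
  n_young <- min(n_young, length(pool_y))
  pick <- c(sample(pool_y, n_young),
            sample(pool_n, n_escapee - n_young))
  esc_tiles <- tiles[sort(pick), ]
  esc_tiles$young_overlap <- tile_young[sort(pick)]

  esc_gr <- as_granges0(esc_tiles)
  in_esc <- GenomicRanges::countOverlaps(cpg_gr, esc_gr) > 0
  cgi_gr <- GenomicRanges::reduce(as_granges0(genome$cgi))
  in_cgi <- GenomicRanges::countOverlaps(cpg_gr, cgi_gr) > 0

  out <- purrr::pmap(samples, function(name, class, ...) {
    rate <- if (class == "PGC") {
      ifelse(in_esc, escapee_rate, rate_pgc)
    } else {
      ifelse(in_cgi, rate_cgi_soma, rate_soma)
    }
    cov <- rpois(nrow(cpg), coverage)
    keep <- cov > 0
    meth <- rbinom(sum(keep), cov[keep], rate[keep])
    tibble(chrom = cpg$chrom[keep], pos = cpg$pos[keep],
           meth = meth, total = cov[keep], level = meth / cov[keep])
  })
  names(out) <- samples$name

  list(
    samples = out,
    truth = list(
      escapee_tiles = esc_tiles,
      young_family = young_family,
      young_tile_frac_bg = f_bg,
      young_tile_frac_escapee = mean(esc_tiles$young_overlap),
      rates = c(PGC = rate_pgc, soma = rate_soma, CGI_soma = rate_cgi_soma,
                escapee = escapee_rate),
      coverage = coverage, seed = seed
    )
  )
}

#' Non-overlapping tiles covering a genome
#'
#' Left-closed tiles of fixed width per chromosome; the last partial tile
#' is kept.
#'
#' @param sizes Genome sizes tibble (chrom, size).
#' @param tile Tile width in bp.
#' @return Tibble: chrom, start, end, tile_id.
#' @export
genome_tiles <- function(sizes, tile) {
  stopifnot(tile > 0)
  purrr::map2(sizes$chrom, sizes$size, function(ch, sz) {
    start <- seq.int(0L, sz - 1L, by = tile)
    tibble(chrom = ch, start = as.integer(start),
           end = as.integer(pmin(start + tile, sz)))
  }) |>
    list_rbind() |>
    dplyr::mutate(tile_id = paste0(chrom, ":", start, "-", end))
}
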