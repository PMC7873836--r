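#' Detect demethylation-escapee tiles
#'
#' Scans fixed-width tiles (default 800 nt) across the genome. In each
#' tile, only CpGs covered by at least `escapee_min_cov` (5) reads are
#' considered; a tile is uncallable when it has fewer than
#' `min_callable_cpgs` (5) such CpGs. Among the qualifying CpGs, `frac` is
#' the share with a pooled per-CpG methylation level at or above
#' `escapee_meth_level` (0.15 pig/mouse, 0.30 human); the tile is `meth+`
#' (a demethylation escapee) when `frac` strictly exceeds
#' `escapee_cpg_frac` (0.20), else `meth-`.
#'
#' @param cpgs CpG tibble (chrom, pos, meth, total).
#' @param genome_sizes Genome sizes tibble.
#' @param thr A [thresholds()] object.
#' @param tile Tile width override (default `thr$tile_escapee`).
#' @return Tibble of class `"escapee_scan"`: chrom, start, end, tile_id,
#'   n_cpg_5x, n_cpg_meth, frac, class ("meth+", "meth-", "uncallable").
#' @export
detect_escapees <- function(cpgs, genome_sizes, thr = thresholds(),
                            tile = NULL) {
  tile <- tile %||% thr$tile_escapee
  tiles <- genome_tiles(genome_sizes, tile)
  cov <- cpgs[cpgs$total >= thr$escapee_min_cov, ]
  cov$qual <- cov$meth / cov$total >= thr$escapee_meth_level
  tiles_gr <- as_granges0(tiles)
  cpg_gr <- GenomicRanges::GRanges(cov$chrom,
                                   IRanges::IRanges(cov$pos + 1L, width = 1L))
  hit <- GenomicRanges::findOverlaps(cpg_gr, tiles_gr)
  qi <- S4Vectors::queryHits(hit)
  si <- S4Vectors::subjectHits(hit)
  n <- nrow(tiles)
  tiles$n_cpg_5x <- tabulate(si, nbins = n)
  tiles$n_cpg_meth <- as.integer(rowsum_by(as.numeric(cov$qual[qi]), si, n))
  tiles$frac <- ifelse(tiles$n_cpg_5x > 0,
                       tiles$n_cpg_meth / tiles$n_cpg_5x, NA_real_)
  tiles$class <- dplyr::case_when(
    tiles$n_cpg_5x < thr$min_callable_cpgs ~ "uncallable",
    tiles$frac > thr$escapee_cpg_frac ~ "meth+",
    TRUE ~ "meth-"
  )
  class(tiles) <- c("escapee_scan", class(tiles))
  attr(tiles, "thr") <- thr
  tiles
}

#' Tidy an escapee scan to its callable tiles
#' @param x An `escapee_scan`.
#' @param ... Unused.
#' @return Tibble of callable tiles.
#' @export
tidy.escapee_scan <- function(x, ...) {
  out <- as_tibble(x)
  out[out$class != "uncallable", ]
}

#' One-row summary of an escapee scan
#' @param x An `escapee_scan`.
#' @param ... Unused.
#' @return Tibble: n_tiles, n_callable, n_meth_plus, n_meth_minus,
#'   frac_meth_plus.
#' @export
glance.escapee_scan <- function(x, ...) {
  tibble(n_tiles = nrow(x),
         n_callable = sum(x$class != "uncallable"),
         n_meth_plus = sum(x$class == "meth+"),
         n_meth_minus = sum(x$class == "meth-"),
         frac_meth_plus = sum(x$class == "meth+") /
           max(1L, sum(x$class != "uncallable")))
}

#' Classify tiles by transposable-element content
#'
#' `te_overlap_frac` is the unioned repeat-covered base fraction of each
#' tile (overlapping repeat records are counted once); tiles are `TE-rich`
#' when the fraction reaches `te_rich_frac` (0.10), else `TE-poor`.
#'
#' @param tiles Tile tibble (chrom, start, end), e.g. an `escapee_scan`.
#' @param repeats Repeat interval tibble (chrom, start, end, family).
#' @param thr A [thresholds()] object.
#' @return `tiles` with added te_overlap_frac and te_class columns.
#' @export
classify_te_content <- function(tiles, repeats, thr = thresholds()) {
  rep_gr <- GenomicRanges::reduce(as_granges0(repeats))
  tiles_gr <- as_granges0(tiles)
  hit <- GenomicRanges::findOverlaps(tiles_gr, rep_gr)
  ov <- GenomicRanges::pintersect(tiles_gr[S4Vectors::queryHits(hit)],
                                  rep_gr[S4Vectors::subjectHits(hit)])
  covered <- rowsum_by(GenomicRanges::width(ov),
                       S4Vectors::queryHits(hit), nrow(tiles))
  out <- tiles
  out$te_overlap_frac <- covered / (tiles$end - tiles$start)
  out$te_class <- ifelse(out$te_overlap_frac >= thr$te_rich_frac,
                         "TE-rich", "TE-poor")
  out
}

#' Transposable-element family enrichment among escapee tiles
#'
#' For each repeat family, builds the 2x2 table of tiles x overlaps-family
#' (>= 1 bp against the family's unioned intervals) for the escapee set
#' versus the background set. The enrichment score is the ratio of overlap
#' fractions, `ES = (a / n_escapee) / (c / n_background)`; the p-value is
#' the two-sided Fisher exact test of the table. Families with ES above
#' `es_cutoff` (2) and p below `es_p_cutoff` (0.001) are flagged enriched.
#' A family absent from the repeat annotation is skipped with a message;
#' zero background overlaps with non-zero escapee overlaps give ES = Inf.
#'
#' @param escapee_tiles Tibble of escapee tiles (chrom, start, end) —
#'   typically the meth+ TE-rich tiles.
#' @param background_tiles Tibble of background tiles (all callable tiles
#'   by default upstream).
#' @param repeats Repeat interval tibble with `family`.
#' @param families Families to score (default: all in `repeats`).
#' @param thr A [thresholds()] object.
#' @return Tibble of class `"te_enrichment"`: family, n_escapee_overlap,
#'   n_escapee, n_background_overlap, n_background, es, p, enriched.
#' @export
te_enrichment <- function(escapee_tiles, background_tiles, repeats,
                          families = NULL, thr = thresholds()) {
  families <- families %||% sort(unique(repeats$family))
  absent <- setdiff(families, repeats$family)
  if (length(absent) > 0) {
    inform(paste0("family(ies) absent from the annotation, skipped: ",
                  paste(absent, collapse = ", ")))
    families <- setdiff(families, absent)
  }
  esc_gr <- as_granges0(escapee_tiles)
  bg_gr <- as_granges0(background_tiles)
  out <- purrr::map(families, function(fam) {
    fam_gr <- GenomicRanges::reduce(
      as_granges0(repeats[repeats$family == fam, ]))
    a <- sum(GenomicRanges::countOverlaps(esc_gr, fam_gr) > 0)
    c_ <- sum(GenomicRanges::countOverlaps(bg_gr, fam_gr) > 0)
    n_e <- length(esc_gr)
    n_b <- length(bg_gr)
    es <- if (c_ == 0) {
      if (a == 0) NA_real_ else Inf
    } else {
      (a / n_e) / (c_ / n_b)
    }
    p <- fisher.test(matrix(c(a, n_e - a, c_, n_b - c_), 2))$p.value
    tibble(family = fam, n_escapee_overlap = a, n_escapee = n_e,
           n_background_overlap = c_, n_background = n_b,
           es = es, p = p)
  }) |> list_rbind()
  out$enriched <- !is.na(out$es) & out$es > thr$es_cutoff &
    out$p < thr$es_p_cutoff
  class(out) <- c("te_enrichment", class(out))
  out
}

#' Tidy a TE enrichment result
#' @param x A `te_enrichment`.
#' @param ... Unused.
#' @return The underlying tibble, ordered by descending ES.
#' @export
tidy.te_enrichment <- function(x, ...) {
  out <- as_tibble(x)
  out[order(-out$es), ]
}

#' One-row summary of a TE enrichment result
#' @param x A `te_enrichment`.
#' @param ... Unused.
#' @return Tibble: n_families, n_enriched, top_family, top_es.
#' @export
glance.te_enrichment <- function(x, ...) {
  top <- which.max(x$es)
  tibble(n_families = nrow(x), n_enriched = sum(x$enriched),
         top_family = x$family[top], top_es = x$es[top])
}

#' Normalise repeat-region read counts to RPM
#'
#' Reads-per-million: `count * 1e6 / library_size`. With `rpkm = TRUE` the
#' value is additionally divided by the region length in kb (the two units
#' are often conflated under the same name; reads-per-million is the
#' default here). Per-family sums are attached as attribute `"family"`.
#' Counting itself (minimum mapping quality `thr$repeat_min_mapq`) happens
#' upstream; this normalises a provided table.
#'
#' @param counts Tibble with `name`, `family`, `count` and (for RPKM)
#'   `length` or start/end columns.
#' @param library_size Total mapped reads of the library.
#' @param rpkm Also normalise by region length in kb.
#' @return `counts` with an `rpm` column; per-family sums in
#'   `attr(, "family")`.
#' @export
repeat_expression_rpm <- function(counts, library_size, rpkm = FALSE) {
  if (length(library_size) != 1 || library_size <= 0) {
    abort("library_size must be a single positive number")
  }
  counts <- as_tibble(counts)
  rpm <- counts$count * 1e6 / library_size
  if (rpkm) {
    len <- counts[["length"]]
    if (is.null(len) && !is.null(counts[["end"]])) {
      len <- counts[["end"]] - counts[["start"]]
    }
    if (is.null(len)) abort("rpkm = TRUE needs a length (or start/end)")
    rpm <- rpm / (len / 1000)
  }
  counts$rpm <- rpm
  fam <- counts |>
    dplyr::group_by(family) |>
    dplyr::summarise(rpm = sum(rpm), n_regions = dplyr::n())
  attr(counts, "family") <- fam
  counts
}
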