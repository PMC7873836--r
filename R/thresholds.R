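#' Analysis thresholds
#'
#' Every tunable cutoff used by the pipeline, collected in one validated
#' object. Defaults follow the published analysis of pig germline resetting:
#' cells need >= 1 million mapped reads and < 50% mitochondrial reads; a gene
#' is "expressed" when seen at TPM > 1 in at least 3 cells; a cell is
#' provisionally male when its chrY single-copy genes sum to >= 10 TPM;
#' methylation escapees are 800-nt tiles in which more than 20% of CpGs
#' covered at >= 5x retain a methylation level of at least 15% (pig/mouse;
#' 30% for human); TE-rich tiles overlap repeats over >= 10% of their length;
#' a TE family is enriched at ES > 2 and Fisher p < 0.001; promoters
#' (-1,000/+500 of the TSS) are HCP when some 500-bp window has CpG
#' observed/expected > 0.75 and GC > 55%, LCP when no window exceeds 0.48.
#'
#' @param ... Named overrides of any default listed in Details.
#' @param species One of `"pig"`, `"mouse"`, `"human"`; presets
#'   `escapee_meth_level` (0.15 for pig/mouse, 0.30 for human).
#'
#' @details
#' Defaults:
#' \describe{
#'   \item{min_mapped_reads}{1e6 — cell QC, minimum reads mapped to genes.}
#'   \item{max_mito_fraction}{0.5 — cell QC, mitochondrial read proportion
#'     at or above which a cell is removed.}
#'   \item{min_cells_expressing, min_tpm}{3 cells at TPM > 1 — gene
#'     detection rule.}
#'   \item{chry_male_tpm}{10 — provisional-male cutoff on summed chrY
#'     single-copy TPM.}
#'   \item{yx_ratio_genes}{"all" — chrY genes entering the pass-2
#'     chrY:chrX ratio ("all" or "single_copy").}
#'   \item{geomean_pseudocount}{1 — added to TPM before log for geometric
#'     means.}
#'   \item{fm_window, fm_min_genes}{1e6 bp windows across chrX; windows with
#'     fewer than 3 genes are reported missing.}
#'   \item{fm_summary}{"geomean" — chromosome-level F:M summary
#'     ("geomean" or "total").}
#'   \item{boot_genes, boot_reps}{100 genes per draw, 1,000 bootstrap
#'     replicates for the X:autosome ratio.}
#'   \item{snv_min_reads, snv_min_cells}{3 reads per (cell, SNV); SNVs kept
#'     only when covered in >= 2 cells of a stage.}
#'   \item{allele_detect_min_reads, allele_detect_min_frac}{minor allele
#'     needs >= 2 reads and >= 10% of site reads to call a site biallelic.}
#'   \item{tile_global, tile_escapee}{1,000-nt tiles for genome-wide
#'     methylation, 800-nt tiles for escapee detection.}
#'   \item{escapee_min_cov, escapee_cpg_frac, escapee_meth_level,
#'     min_callable_cpgs}{5x coverage; meth+ when > 20% of covered CpGs are
#'     at or above the species level; tiles with < 5 qualifying CpGs are
#'     uncallable.}
#'   \item{te_rich_frac, es_cutoff, es_p_cutoff}{0.10 repeat-overlap
#'     fraction; enrichment flagged at ES > 2 and p < 0.001.}
#'   \item{promoter_up, promoter_down, promoter_win, promoter_step}{-1,000 /
#'     +500 promoter, 500-bp sliding window, 5-bp step.}
#'   \item{hcp_cpg_ratio, hcp_gc, lcp_cpg_ratio}{0.75 / 0.55 / 0.48.}
#'   \item{metaprofile_flank}{5,000 bp each side of the gene body.}
#'   \item{repeat_min_mapq}{20 — documented minimum mapping quality of the
#'     upstream repeat read counting.}
#'   \item{expressed_scope}{"stage" — scope over which "expressed genes"
#'     are determined for dosage bootstraps.}
#'   \item{es_background}{"callable" — background tile universe for TE
#'     enrichment ("callable" or "methminus").}
#'   \item{region_level}{"weighted" — region methylation as pooled
#'     reads ("weighted") or mean of per-CpG levels ("mean").}
#' }
#'
#' @return A named list with class `"germreset_thresholds"`.
#' @examples
#' thresholds()
#' thresholds(species = "human")$escapee_meth_level
#' thresholds(boot_genes = 50)
#' @export
thresholds <- function(..., species = c("pig", "mouse", "human")) {
  species <- match.arg(species)
  defaults <- list(
    min_mapped_reads = 1e6,
    max_mito_fraction = 0.5,
    min_cells_expressing = 3L,
    min_tpm = 1,
    chry_male_tpm = 10,
    yx_ratio_genes = "all",
    geomean_pseudocount = 1,
    fm_window = 1e6,
    fm_min_genes = 3L,
    fm_summary = "geomean",
    boot_genes = 100L,
    boot_reps = 1000L,
    snv_min_reads = 3L,
    snv_min_cells = 2L,
    allele_detect_min_reads = 2L,
    allele_detect_min_frac = 0.10,
    tile_global = 1000L,
    tile_escapee = 800L,
    escapee_min_cov = 5L,
    escapee_cpg_frac = 0.20,
    escapee_meth_level = if (species == "human") 0.30 else 0.15,
    min_callable_cpgs = 5L,
    te_rich_frac = 0.10,
    es_cutoff = 2,
    es_p_cutoff = 0.001,
    promoter_up = 1000L,
    promoter_down = 500L,
    promoter_win = 500L,
    promoter_step = 5L,
    hcp_cpg_ratio = 0.75,
    hcp_gc = 0.55,
    lcp_cpg_ratio = 0.48,
    metaprofile_flank = 5000L,
    repeat_min_mapq = 20L,
    expressed_scope = "stage",
    es_background = "callable",
    region_level = "weighted"
  )
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == ""))) {
    abort("all threshold overrides must be named")
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown threshold key(s): ", paste(unknown, collapse = ", ")))
  }
  thr <- modifyList(defaults, over)
  thr$species <- species
  class(thr) <- "germreset_thresholds"
  validate_thresholds(thr)
  thr
}

validate_thresholds <- function(thr) {
  chk_prop <- function(key) {
    v <- thr[[key]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      abort(paste0("threshold '", key, "' must be a proportion in [0, 1], got ", v))
    }
  }
  chk_pos <- function(key) {
    v <- thr[[key]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 ||
        v != as.integer(v)) {
      abort(paste0("threshold '", key, "' must be a positive integer, got ", v))
    }
  }
  chk_choice <- function(key, choices) {
    if (!is.character(thr[[key]]) || !thr[[key]] %in% choices) {
      abort(paste0("threshold '", key, "' must be one of: ",
                   paste(choices, collapse = ", ")))
    }
  }
  for (k in c("max_mito_fraction", "allele_detect_min_frac",
              "escapee_cpg_frac", "escapee_meth_level", "te_rich_frac",
              "es_p_cutoff", "hcp_gc")) chk_prop(k)
  for (k in c("min_mapped_reads", "min_cells_expressing", "fm_window",
              "fm_min_genes", "boot_genes", "boot_reps", "snv_min_reads",
              "snv_min_cells", "allele_detect_min_reads", "tile_global",
              "tile_escapee", "escapee_min_cov", "min_callable_cpgs",
              "promoter_up", "promoter_down", "promoter_win",
              "promoter_step", "metaprofile_flank", "repeat_min_mapq")) {
    chk_pos(k)
  }
  if (thr$lcp_cpg_ratio >= thr$hcp_cpg_ratio) {
    abort("threshold 'lcp_cpg_ratio' must be smaller than 'hcp_cpg_ratio'")
  }
  chk_choice("yx_ratio_genes", c("all", "single_copy"))
  chk_choice("fm_summary", c("geomean", "total"))
  chk_choice("expressed_scope", c("stage", "cell"))
  chk_choice("es_background", c("callable", "methminus"))
  chk_choice("region_level", c("weighted", "mean"))
  invisible(thr)
}

#' @export
print.germreset_thresholds <- function(x, ...) {
  cat("<germreset thresholds> species:", x$species, "\n")
  keys <- setdiff(names(x), "species")
  vals <- vapply(keys, function(k) format(x[[k]]), character(1))
  cat(paste0("  ", format(keys), " = ", vals), sep = "\n")
  invisible(x)
}

#' Load thresholds from a YAML or JSON configuration file
#'
#' Absent keys fall back to the defaults of [thresholds()]; unknown keys are
#' rejected. A `species` key ("pig", "mouse", "human") switches the
#' species-specific escapee methylation level; an explicit
#' `escapee_meth_level` entry overrides the preset.
#'
#' @param path Path to a YAML (or JSON — valid YAML) file. An empty file
#'   yields all defaults.
#' @param quiet Suppress the log line echoing the resolved configuration.
#' @return A `germreset_thresholds` object.
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines("escapee_meth_level: 0.30", cfg)
#' load_config(cfg, quiet = TRUE)$escapee_meth_level
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) abort("config must be a YAML/JSON mapping")
  species <- raw$species %||% "pig"
  raw$species <- NULL
  thr <- do.call(thresholds, c(raw, list(species = species)))
  if (!quiet) {
    inform(paste0("resolved configuration (species=", thr$species, "): ",
                  jsonlite::toJSON(thr[setdiff(names(thr), "species")],
                                   auto_unbox = TRUE)))
  }
  thr
}

#' Write a thresholds object to YAML
#'
#' @param thr A `germreset_thresholds` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(thr, path) {
  stopifnot(inherits(thr, "germreset_thresholds"))
  yaml::write_yaml(unclass(thr), path)
  invisible(path)
}
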