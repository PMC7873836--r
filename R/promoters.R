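#' CpG observed/expected ratio of a sequence window
#'
#' Saxonov/Weber convention: `(#CpG * L) / (#C * #G)`, zero when the
#' sequence has no C or no G.
#'
#' @param seq A single DNA string (ACGT, case-insensitive).
#' @return Numeric scalar.
#' @examples
#' cpg_ratio(strrep("CG", 10))
#' @export
cpg_ratio <- function(seq) {
  s <- toupper(seq)
  L <- nchar(s)
  nC <- L - nchar(gsub("C", "", s, fixed = TRUE))
  nG <- L - nchar(gsub("G", "", s, fixed = TRUE))
  nCpG <- lengths(regmatches(s, gregexpr("(?=CG)", s, perl = TRUE)))
  ifelse(nC * nG == 0, 0, nCpG * L / (nC * nG))
}

#' Classify promoters by CpG content (HCP / ICP / LCP)
#'
#' Slides a 500-bp window (step `thr$promoter_step`, default 5 bp) across
#' each promoter sequence (-1,000/+500 of the TSS, 1,500 bp). HCP: some
#' window has CpG observed/expected ratio > 0.75 and GC content > 0.55.
#' LCP: no window has a ratio > 0.48. ICP: neither. Sequences shorter than
#' the window are uncallable (NA class) with a warning.
#'
#' @param promoters Tibble with `name` and `seq` (promoter DNA strings).
#' @param thr A [thresholds()] object.
#' @return Tibble: name, class ("HCP"/"ICP"/"LCP" or NA), and the CpG
#'   ratio and GC content of the best (maximum-ratio) window.
#' @export
classify_promoters <- function(promoters, thr = thresholds()) {
  promoters <- as_tibble(promoters)
  stopifnot(all(c("name", "seq") %in% names(promoters)))
  win <- thr$promoter_win
  step <- thr$promoter_step
  res <- purrr::map2(promoters$name, promoters$seq, function(nm, s) {
    s <- toupper(s)
    L <- nchar(s)
    if (L < win) {
      return(tibble(name = nm, class = NA_character_,
                    best_window_cpg_ratio = NA_real_,
                    best_window_gc = NA_real_))
    }
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    isC <- cumsum(c(0L, ch == "C"))
    isG <- cumsum(c(0L, ch == "G"))
    cg <- cumsum(c(0L, ch[-L] == "C" & ch[-1] == "G", 0L))
    starts <- seq.int(1L, L - win + 1L, by = step)
    nC <- isC[starts + win] - isC[starts]
    nG <- isG[starts + win] - isG[starts]
    # CpG dinucleotides fully inside the window: starts .. start+win-2
    nCpG <- cg[starts + win - 1L] - cg[starts]
    ratio <- ifelse(nC * nG == 0, 0, nCpG * win / (nC * nG))
    gc <- (nC + nG) / win
    best <- which.max(ratio)
    cls <- if (any(ratio > thr$hcp_cpg_ratio & gc > thr$hcp_gc)) {
      "HCP"
    } else if (!any(ratio > thr$lcp_cpg_ratio)) {
      "LCP"
    } else "ICP"
    tibble(name = nm, class = cls,
           best_window_cpg_ratio = ratio[best], best_window_gc = gc[best])
  }) |> list_rbind()
  if (anyNA(res$class)) {
    warn(paste0(sum(is.na(res$class)), " promoter(s) shorter than the ",
                win, "-bp window: uncallable"))
  }
  res
}
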