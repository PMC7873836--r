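#' Compare dosage (or any per-cell) values between groups
#'
#' Thin, reproducible wrappers over the standard rank tests: two-group
#' Mann-Whitney (`wilcox.test`, two-sided, exact where possible), pairwise
#' Wilcoxon with Holm correction, or Kruskal-Wallis followed by Dunn's
#' post hoc test (rank-based z statistics with tie correction,
#' Holm-adjusted). Ties are handled by midranks throughout; `wilcox.test`
#' falls back to its normal approximation in the presence of ties.
#'
#' @param data A data frame.
#' @param value,group Column names (strings) of the numeric values and the
#'   grouping factor.
#' @param method One of `"mann-whitney"`, `"pairwise-wilcoxon"`,
#'   `"kruskal-dunn"`.
#' @return An object of class `"dosage_test"`: a list with `method`,
#'   `comparisons` (tibble of pairwise p-values, Holm-adjusted where a
#'   family exists) and, for Kruskal-Dunn, `omnibus` (the Kruskal-Wallis
#'   result). Use [tidy()] / [glance()] to extract tibbles.
#' @examples
#' d <- data.frame(v = c(1, 2, 3, 11, 12, 13), g = rep(c("a", "b"), each = 3))
#' tidy(compare_dosage_groups(d, "v", "g"))
#' @export
compare_dosage_groups <- function(data, value, group,
                                  method = c("mann-whitney",
                                             "pairwise-wilcoxon",
                                             "kruskal-dunn")) {
  method <- match.arg(method)
  x <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) abort("need at least 2 groups")
  sizes <- table(g)
  if (any(sizes < 2)) {
    abort(paste0("group(s) with fewer than 2 values: ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  lv <- levels(g)
  res <- switch(
    method,
    "mann-whitney" = {
      if (nlevels(g) != 2) abort("mann-whitney needs exactly 2 groups")
      exact <- !anyDuplicated(x) && length(x) < 100
      w <- wilcox.test(x[g == lv[1]], x[g == lv[2]], exact = exact,
                       correct = !exact)
      list(comparisons = tibble(group1 = lv[1], group2 = lv[2],
                                statistic = unname(w$statistic),
                                p_value = w$p.value,
                                p_adjusted = w$p.value))
    },
    "pairwise-wilcoxon" = {
      pw <- pairwise.wilcox.test(x, g, p.adjust.method = "none",
                                 exact = FALSE)
      cmp <- as.data.frame(as.table(pw$p.value))
      cmp <- cmp[!is.na(cmp$Freq), ]
      raw <- cmp$Freq
      list(comparisons = tibble(group1 = as.character(cmp$Var2),
                                group2 = as.character(cmp$Var1),
                                statistic = NA_real_,
                                p_value = raw,
                                p_adjusted = p.adjust(raw, "holm")))
    },
    "kruskal-dunn" = {
      kw <- kruskal.test(x, g)
      dn <- dunn_posthoc(x, g)
      list(omnibus = tibble(statistic = unname(kw$statistic),
                            df = unname(kw$parameter),
                            p_value = kw$p.value),
           comparisons = dn)
    }
  )
  structure(c(res, list(method = method, n = length(x), k = nlevels(g))),
            class = "dosage_test")
}

# Dunn's test: z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))
# with tie correction T = sum(t^3 - t) / (12 (N - 1)); Holm-adjusted.
dunn_posthoc <- function(x, g) {
  N <- length(x)
  r <- rank(x)
  tie <- table(r)
  Tcorr <- sum(tie^3 - tie) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  z <- apply(pairs, 2, function(p) {
    (rbar[p[1]] - rbar[p[2]]) /
      sqrt((N * (N + 1) / 12 - Tcorr) * (1 / n[p[1]] + 1 / n[p[2]]))
  })
  p <- 2 * pnorm(-abs(z))
  tibble(group1 = pairs[1, ], group2 = pairs[2, ], statistic = unname(z),
         p_value = unname(p), p_adjusted = p.adjust(p, "holm"))
}

#' @export
print.dosage_test <- function(x, ...) {
  cat("<dosage_test>", x$method, "on", x$n, "values in", x$k, "groups\n")
  if (!is.null(x$omnibus)) {
    cat("  Kruskal-Wallis chi-squared =", signif(x$omnibus$statistic, 4),
        ", df =", x$omnibus$df, ", p =", signif(x$omnibus$p_value, 4), "\n")
  }
  print(x$comparisons)
  invisible(x)
}

#' Tidy a dosage_test into its pairwise comparisons
#' @param x A `dosage_test` object.
#' @param ... Unused.
#' @return Tibble: group1, group2, statistic, p_value, p_adjusted.
#' @export
tidy.dosage_test <- function(x, ...) x$comparisons

#' One-row summary of a dosage_test
#' @param x A `dosage_test` object.
#' @param ... Unused.
#' @return Tibble: method, n, k, min_p_adjusted, omnibus_p.
#' @export
glance.dosage_test <- function(x, ...) {
  tibble(method = x$method, n = x$n, k = x$k,
         min_p_adjusted = min(x$comparisons$p_adjusted),
         omnibus_p = if (!is.null(x$omnibus)) x$omnibus$p_value else NA_real_)
}
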