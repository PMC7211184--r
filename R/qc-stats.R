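# Data-point filters and statistical tests: missing-post flagging by the
# strongly-negative-net rule, single-pass one-sided Grubbs outlier removal,
# Tukey HSD region comparisons, significance tiers and coefficients of
# variation.

#' QC configuration
#'
#' @param missing_post_threshold_afu Nets strictly below this are flagged as
#'   missing posts. Default -1000 AFU.
#' @param grubbs_alpha Significance level of the Grubbs outlier test.
#'   Default 0.001 (99.9% confidence).
#' @param grubbs_iterative If `TRUE`, repeat the Grubbs test until no outlier
#'   remains; default is a single pass removing at most one point.
#' @param tukey_alpha Family-wise significance level for Tukey HSD.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(missing_post_threshold_afu = -1000,
                      grubbs_alpha = 0.001,
                      grubbs_iterative = FALSE,
                      tukey_alpha = 0.05) {
  assert_scalar_num(missing_post_threshold_afu, "missing_post_threshold_afu")
  if (missing_post_threshold_afu >= 0)
    stop_invalid("missing_post_threshold_afu must be negative")
  for (a in c(grubbs_alpha, tukey_alpha))
    if (!is.numeric(a) || a <= 0 || a >= 1)
      stop_invalid("alphas must lie in (0, 1)")
  structure(list(missing_post_threshold_afu = missing_post_threshold_afu,
                 grubbs_alpha = grubbs_alpha,
                 grubbs_iterative = isTRUE(grubbs_iterative),
                 tukey_alpha = tukey_alpha),
            class = "qc_config")
}

#' Flag missing posts by strongly negative net signal
#'
#' A lost post leaves its box at the empty-well floor while the same-well
#' negative-control post carries real signal, so the net is strongly
#' negative. Rows with `net_afu < threshold` (strict; a net of exactly
#' -1000 AFU is retained at the default) are flagged `missing_post` and
#' excluded from downstream statistics.
#'
#' @param wq Well quantification from [net_signal()].
#' @param cfg A [qc_config()].
#' @return A list with `retained` (rows passing), `flagged` (rows removed,
#'   with the flag appended) and `n_removed`.
#' @export
flag_missing_posts <- function(wq, cfg = qc_config()) {
  bad <- is.finite(wq$net_afu) &
    wq$net_afu < cfg$missing_post_threshold_afu
  flagged <- wq[bad, , drop = FALSE]
  if (nrow(flagged))
    flagged$flags <- trimws(paste(flagged$flags, "missing_post"))
  retained <- wq[!bad, , drop = FALSE]
  rownames(retained) <- rownames(flagged) <- NULL
  list(retained = retained, flagged = flagged, n_removed = sum(bad))
}

# Critical value of the one-sided Grubbs statistic at level alpha for n
# observations: ((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2)) with t the upper
# alpha/n quantile of the t distribution on n - 2 degrees of freedom.
grubbs_critical <- function(n, alpha) {
  t <- stats::qt(alpha / n, df = n - 2, lower.tail = FALSE)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' One-sided (high) Grubbs outlier filter
#'
#' Tests the largest value: `G = (max - mean) / sd`, rejected when `G`
#' exceeds the Grubbs critical value at level `alpha`. By default the test
#' is applied once, removing at most one point (debris on a post produces a
#' single high outlier); set `grubbs_iterative` in the config to repeat
#' until no outlier remains.
#'
#' @param values Numeric vector, `n >= 3`.
#' @param cfg A [qc_config()].
#' @return A list with `kept` (values retained), `outlier_indices` (indices
#'   into the input, possibly empty) and `g_statistic` of the first test.
#' @export
grubbs_filter <- function(values, cfg = qc_config()) {
  if (length(values) < 3L)
    stop_invalid("Grubbs test needs at least 3 values")
  if (anyNA(values)) stop_invalid("values must not contain NA")
  keep <- rep(TRUE, length(values))
  out_idx <- integer(0)
  g_first <- NA_real_
  repeat {
    v <- values[keep]
    n <- length(v)
    if (n < 3L) break
    s <- stats::sd(v)
    if (s == 0) break
    g <- (max(v) - mean(v)) / s
    if (is.na(g_first)) g_first <- g
    if (g <= grubbs_critical(n, cfg$grubbs_alpha)) break
    i <- which(keep)[which.max(v)]
    out_idx <- c(out_idx, i)
    keep[i] <- FALSE
    if (!cfg$grubbs_iterative) break
  }
  list(kept = values[keep], outlier_indices = out_idx,
       g_statistic = g_first)
}

#' Tukey HSD pairwise region comparisons
#'
#' All-pairs comparison of group means controlling the family-wise error
#' rate with the studentized range distribution (Tukey--Kramer adjustment
#' for unequal group sizes). The sample unit is the well: the n for each
#' region is the number of (unfiltered) wells beneath it.
#'
#' @param groups Named list of numeric vectors (one per region, each with at
#'   least 2 values) or a data frame with columns `group` and `value`.
#' @param alpha Family-wise significance level.
#' @return A data frame: `group1`, `group2`, `diff` (mean difference,
#'   group2 - group1), `lwr`, `upr` (simultaneous confidence interval),
#'   `p_adj`, `significant`, `stars`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  if (is.data.frame(groups)) {
    df <- data.frame(value = groups$value,
                     group = as.character(groups$group),
                     stringsAsFactors = FALSE)
  } else {
    if (is.null(names(groups)) || length(groups) < 2L)
      stop_invalid("need >= 2 named groups")
    df <- data.frame(
      value = unlist(groups, use.names = FALSE),
      group = rep(names(groups), lengths(groups)),
      stringsAsFactors = FALSE)
  }
  sizes <- table(df$group)
  if (length(sizes) < 2L) stop_invalid("need >= 2 groups")
  if (any(sizes < 2L))
    stop_invalid("every group needs at least 2 values")
  df$group <- factor(df$group)
  fit <- stats::aov(value ~ group, data = df)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  # row order of TukeyHSD is combn() over factor levels (2-1, 3-1, 3-2, ...);
  # reconstruct pair labels positionally so group names may contain dashes
  pairs <- t(utils::combn(levels(df$group), 2))
  stopifnot(nrow(pairs) == nrow(tk))
  out <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                    diff = tk[, "diff"], lwr = tk[, "lwr"],
                    upr = tk[, "upr"], p_adj = tk[, "p adj"],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$significant <- out$p_adj < alpha
  out$stars <- vapply(out$p_adj, significance_stars, character(1))
  out
}

#' Significance tier label
#'
#' Standard star notation with strict thresholds: `***` for p < 0.001,
#' `**` for p < 0.01, `*` for p < 0.05, otherwise `NS`.
#'
#' @param p A p-value in `[0, 1]`.
#' @return `"***"`, `"**"`, `"*"` or `"NS"`.
#' @export
significance_stars <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop_invalid("p must be a single value in [0, 1]")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "NS"
}

#' Coefficient of variation (percent)
#'
#' `100 * sample SD / mean`. Undefined for a zero mean.
#'
#' @param values Numeric vector, `n >= 2`, nonzero mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop_invalid("CV needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop_invalid("CV undefined for zero mean")
  100 * stats::sd(values) / m
}
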