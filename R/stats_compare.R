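# Group comparison of per-frame distance distributions: one-way ANOVA
# followed by Sidak-corrected pairwise comparisons.
#
# Caveat stated up front: frames from a sampling trajectory are
# autocorrelated, so frame-level p-values are anti-conservative. The module
# computes the classical frame-level statistics without an effective-sample-
# size correction; interpret significance accordingly (e.g. corroborate with
# per-simulation means, which `compare_groups` also accepts as input).

#' Sidak multiple-testing adjustment
#'
#' `p_adj = 1 - (1 - p)^m`, clamped to `[0, 1]`. With `m = 1` this is the
#' identity; the adjustment is monotone in p.
#'
#' @param p Numeric vector of raw p-values.
#' @param m Number of comparisons (default `length(p)`).
#' @return Adjusted p-values.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  pmin(1, pmax(p, 1 - (1 - p)^m))
}

#' Compare distance distributions across named groups
#'
#' Classical one-way ANOVA over all groups, followed by all pairwise
#' two-sided t comparisons with Sidak adjustment over the
#' `G(G-1)/2` comparisons. Pairwise tests use the pooled within-group
#' variance from all groups (classical post-hoc convention) by default, or
#' Welch per-pair variances with `welch = TRUE`. The degenerate case of zero
#' variance everywhere with equal means yields `F = 0`, `p = 1`.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, >= 2 values
#'   each), e.g. per-frame COM distances per simulation condition.
#' @param welch Use Welch (unpooled) pairwise t tests (default `FALSE`).
#' @return A `ComparisonResult`: `f_statistic`, `df_between`, `df_within`,
#'   `p_value`, and `pairwise` data frame (`group_i`, `group_j`, `raw_p`,
#'   `sidak_adjusted_p`, `mean_difference`).
#' @export
compare_groups <- function(groups, welch = FALSE) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a named list of at least two groups")
  if (is.null(names(groups)) || anyDuplicated(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must have unique non-empty names")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("every group needs at least two values")
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), vapply(groups, length, integer(1))),
                levels = names(groups))
  k <- length(groups); n <- length(value)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(vapply(groups, length, integer(1)) * (means - mean(value))^2)
  ssw <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2)))
  df_b <- k - 1L; df_w <- n - k
  if (ssw == 0 && ssb == 0) {
    f_stat <- 0; p_val <- 1
  } else {
    aov_res <- stats::oneway.test(value ~ grp, var.equal = TRUE)
    f_stat <- unname(aov_res$statistic); p_val <- unname(aov_res$p.value)
    if (!is.finite(f_stat) && ssb == 0) { f_stat <- 0; p_val <- 1 }
  }
  combos <- utils::combn(names(groups), 2)
  m <- ncol(combos)
  raw_p <- numeric(m); mean_diff <- numeric(m)
  if (welch) {
    for (i in seq_len(m)) {
      gi <- groups[[combos[1, i]]]; gj <- groups[[combos[2, i]]]
      mean_diff[i] <- mean(gi) - mean(gj)
      if (stats::var(gi) == 0 && stats::var(gj) == 0) {
        raw_p[i] <- if (mean_diff[i] == 0) 1 else 0
      } else {
        raw_p[i] <- stats::t.test(gi, gj, var.equal = FALSE)$p.value
      }
    }
  } else {
    ptt <- if (ssw > 0)
      stats::pairwise.t.test(value, grp, p.adjust.method = "none",
                             pool.sd = TRUE)$p.value else NULL
    for (i in seq_len(m)) {
      gi <- groups[[combos[1, i]]]; gj <- groups[[combos[2, i]]]
      mean_diff[i] <- mean(gi) - mean(gj)
      raw_p[i] <- if (is.null(ptt)) {
        if (mean_diff[i] == 0) 1 else 0
      } else {
        v <- ptt[combos[2, i], combos[1, i]]
        if (is.na(v)) { if (mean_diff[i] == 0) 1 else 0 } else v
      }
    }
  }
  pairwise <- data.frame(
    group_i = combos[1, ], group_j = combos[2, ],
    raw_p = raw_p,
    sidak_adjusted_p = sidak_adjust(raw_p, m),
    mean_difference = mean_diff,
    stringsAsFactors = FALSE
  )
  structure(
    list(f_statistic = f_stat, df_between = df_b, df_within = df_w,
         p_value = p_val, pairwise = pairwise, welch = welch),
    class = "ComparisonResult"
  )
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  cat(sprintf("Pairwise (%s, Sidak-adjusted over %d comparisons):\n",
              if (x$welch) "Welch" else "pooled variance", nrow(x$pairwise)))
  print(format(x$pairwise, digits = 4), row.names = FALSE)
  invisible(x)
}
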