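#' Pearson correlation with t-based significance
#'
#' Sample Pearson product-moment correlation with the significance of the
#' correlation computed by transforming r into a t statistic with n-2
#' degrees of freedom: `t = r * sqrt((n - 2) / (1 - r^2))`, two-sided p from
#' the t distribution.
#'
#' @param x,y numeric vectors of equal length, n >= 3, each with nonzero
#'   variance.
#' @return An object of class `correlation_result`: `r`, `n`, `t`, `df`,
#'   `p_value`.
#' @export
#' @examples
#' pearson_with_t(1:10, (1:10) + rnorm(10))
pearson_with_t <- function(x, y) {
  stop_if_not(length(x) == length(y), "`x` and `y` must have equal length")
  n <- length(x)
  stop_if_not(n >= 3, "need at least 3 observations")
  stop_if_not(all(is.finite(x)) && all(is.finite(y)),
              "inputs must be finite")
  stop_if_not(sd(x) > 0 && sd(y) > 0,
              "correlation undefined: zero variance")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    ((n - 1) * sd(x) * sd(y))
  r <- max(-1, min(1, r))
  df <- n - 2
  t <- if (abs(r) == 1) sign(r) * Inf else r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(t), df)
  structure(list(r = r, n = n, t = t, df = df, p_value = p),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f (n = %d, t = %.3f on %d df, p = %.4g)\n",
              x$r, x$n, x$t, x$df, x$p_value))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' The U statistic is the number of pairs `(x_i, y_j)` with `x_i > y_j` plus
#' half the tied pairs. The p-value is exact (from the null distribution of
#' U) when `length(x) * length(y) <= 200` and the pooled data are tie-free;
#' otherwise a tie-corrected normal approximation with continuity correction
#' is used. One-sided alternatives follow the direction of `x` relative to
#' `y`.
#'
#' @param x,y numeric samples, both nonempty.
#' @param alternative `"greater"` (x tends larger), `"less"`, or
#'   `"two.sided"`.
#' @param exact_limit largest `n1 * n2` for which the exact tie-free null
#'   distribution is used.
#' @return An object of class `mwu_result`: `U`, `p_value`, `n1`, `n2`,
#'   `method` (`"exact"` or `"normal"`), `alternative`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4), alternative = "less")
mann_whitney_u <- function(x, y,
                           alternative = c("greater", "less", "two.sided"),
                           exact_limit = 200) {
  alternative <- match.arg(alternative)
  stop_if_not(length(x) >= 1 && length(y) >= 1,
              "both samples must be nonempty")
  stop_if_not(all(is.finite(x)) && all(is.finite(y)),
              "samples must be finite")
  n1 <- length(x); n2 <- length(y)
  u <- u_statistic(x, y)
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && n1 * n2 <= exact_limit) {
    # tie-free: U coincides with the Wilcoxon W of x over y
    p <- switch(alternative,
      greater = 1 - pwilcox(u - 1, n1, n2),
      less = pwilcox(u, n1, n2),
      two.sided = min(1, 2 * min(1 - pwilcox(u - 1, n1, n2),
                                 pwilcox(u, n1, n2)))
    )
    method <- "exact"
  } else {
    n <- n1 + n2
    tie_sizes <- table(c(x, y))
    tie_term <- sum(tie_sizes^3 - tie_sizes) / (n * (n - 1))
    v <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (v <= 0) {
      # all observations identical: U is exactly its null mean
      p <- if (alternative == "two.sided") 1 else 0.5
    } else {
      mu <- n1 * n2 / 2
      p <- switch(alternative,
        greater = pnorm((u - mu - 0.5) / sqrt(v), lower.tail = FALSE),
        less = pnorm((u - mu + 0.5) / sqrt(v)),
        two.sided = min(1, 2 * pnorm((abs(u - mu) - 0.5) / sqrt(v),
                                     lower.tail = FALSE))
      )
    }
    method <- "normal"
  }
  structure(list(U = u, p_value = p, n1 = n1, n2 = n2, method = method,
                 alternative = alternative),
            class = "mwu_result")
}

u_statistic <- function(x, y) {
  # pair counting via ranks: O((n1+n2) log) rather than the n1*n2 grid
  r <- rank(c(x, y), ties.method = "average")
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (n1 = %d, n2 = %d), %s p = %.4g (%s)\n",
              x$U, x$n1, x$n2, x$alternative, x$p_value, x$method))
  invisible(x)
}

#' Pairwise correlation matrix of a score table
#'
#' Pearson r (with t-based p-values, see [pearson_with_t()]) over the
#' simulator score, the aggregate battery score, the subtest subscores and
#' the secondary-measure scores — the cross-test consistency analysis of the
#' screening battery. Cells involving a constant column are flagged
#' undefined (NA) rather than silently dropped.
#'
#' @param score_table a [score_cohort()] result with >= 3 rows.
#' @param columns score columns to include; defaults to all scored columns.
#' @return An object of class `correlation_matrix`: matrices `r` and
#'   `p_value` (unit diagonal, symmetric), `n`, and a logical matrix
#'   `defined`.
#' @export
correlation_matrix <- function(score_table, columns = NULL) {
  stop_if_not(is.data.frame(score_table), "`score_table` must be a data frame")
  if (is.null(columns)) {
    columns <- c("s_ds", "s_wbcst", "s1", "s2", "s3c", "s3p", "s4", "s5",
                 "s_speed_var", "s_lat_accel", "s_brake_time",
                 "s_dist_collision", "s_time_collision")
    columns <- intersect(columns, names(score_table))
  }
  stop_if_not(all(columns %in% names(score_table)), "unknown score column")
  n <- nrow(score_table)
  stop_if_not(n >= 3, "need at least 3 participants")
  k <- length(columns)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(columns, columns))
  defined <- matrix(TRUE, k, k, dimnames = list(columns, columns))
  const <- vapply(columns, function(cl) sd(score_table[[cl]]) == 0, logical(1))
  for (i in seq_len(k)) {
    r[i, i] <- 1
    p[i, i] <- NA_real_
    for (j in seq_len(k)) {
      if (j >= i) next
      if (const[i] || const[j]) {
        defined[i, j] <- defined[j, i] <- FALSE
        next
      }
      res <- pearson_with_t(score_table[[columns[i]]],
                            score_table[[columns[j]]])
      r[i, j] <- r[j, i] <- res$r
      p[i, j] <- p[j, i] <- res$p_value
    }
  }
  structure(list(r = r, p_value = p, n = n, defined = defined),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("Correlation matrix over %d participants\n", x$n))
  print(round(x$r, digits))
  invisible(x)
}
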