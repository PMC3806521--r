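#' Rank-based normalization of raw performance values
#'
#' Maps raw values to scores `S = (N - rank) / (N - 1)` where `rank` 1 is the
#' best performance (fewest errors when `higher_is_worse`), so 1 corresponds
#' to the best observed result and 0 to the worst. Ties receive average
#' ranks, which preserves the column-mean identity `mean(S) = 0.5`.
#'
#' @param raw_values numeric vector of finite values, length >= 2.
#' @param higher_is_worse if `TRUE` (default, appropriate for error counts)
#'   small raw values score high; if `FALSE` (safety margins such as distance
#'   or time to collision) large raw values score high.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
#' @examples
#' rank_normalize(c(0, 5, 9))      # 1.0 0.5 0.0
#' rank_normalize(c(3, 3))         # ties -> 0.5 0.5
rank_normalize <- function(raw_values, higher_is_worse = TRUE) {
  n <- length(raw_values)
  stop_if_not(n >= 2, "rank normalization needs at least 2 values")
  stop_if_not(all(is.finite(raw_values)), "raw values must be finite")
  r <- if (higher_is_worse) {
    rank(raw_values, ties.method = "average")
  } else {
    rank(-raw_values, ties.method = "average")
  }
  (n - r) / (n - 1)
}

# Scored columns and the direction of each raw measure.
score_directions <- function() {
  c(e1 = TRUE, e2 = TRUE, e3c = TRUE, e3p = TRUE, e4 = TRUE, e5 = TRUE,
    e_ds = TRUE,
    speed_var = TRUE, lat_accel = TRUE, brake_time = TRUE,
    dist_collision = FALSE, time_collision = FALSE)
}

score_table_columns <- function() {
  c("participant_id", "cohort",
    "s1", "s2", "s3c", "s3p", "s4", "s5", "s_wbcst", "s_ds",
    "s_speed_var", "s_lat_accel", "s_brake_time", "s_dist_collision",
    "s_time_collision")
}

#' Score a cohort with rank-based normalization
#'
#' Applies [rank_normalize()] to every error count and secondary driving
#' measure across the cohort and computes the aggregate battery score per
#' participant. Error counts and the risk-type secondary measures (speed
#' variability, lateral acceleration, brake time) are scored with
#' `higher_is_worse = TRUE`; distance and time to collision are safety
#' margins and scored with `higher_is_worse = FALSE`.
#'
#' @param records cohort data frame (see [generate_cohort()]).
#' @param weights optional battery subscore weights, see [aggregate_wbcst()].
#' @param six_scores see [aggregate_wbcst()].
#' @return A `score_table` data frame: per participant `s1..s5` (subtest 3 as
#'   the pair `s3c`, `s3p`), the aggregate `s_wbcst`, the simulator score
#'   `s_ds`, and one rank score per secondary measure. Every scored column
#'   lies in \[0, 1\] with mean 0.5. Cohort size is attached as attribute
#'   `"N"`.
#' @export
score_cohort <- function(records, weights = NULL, six_scores = FALSE) {
  validate_cohort(records)
  stop_if_not(nrow(records) >= 2, "scoring needs at least 2 participants")
  dirs <- score_directions()
  for (col in names(dirs)) {
    bad <- !is.finite(records[[col]])
    if (any(bad)) {
      stop(sprintf("column `%s` has non-finite values for participant(s) %s",
                   col,
                   paste(records$participant_id[bad], collapse = ", ")),
           call. = FALSE)
    }
  }
  scored <- lapply(names(dirs), function(col) {
    rank_normalize(records[[col]], higher_is_worse = dirs[[col]])
  })
  names(scored) <- names(dirs)
  out <- data.frame(
    participant_id = records$participant_id,
    cohort = records$cohort,
    s1 = scored$e1, s2 = scored$e2, s3c = scored$e3c, s3p = scored$e3p,
    s4 = scored$e4, s5 = scored$e5,
    s_wbcst = NA_real_,
    s_ds = scored$e_ds,
    s_speed_var = scored$speed_var,
    s_lat_accel = scored$lat_accel,
    s_brake_time = scored$brake_time,
    s_dist_collision = scored$dist_collision,
    s_time_collision = scored$time_collision,
    stringsAsFactors = FALSE
  )
  out$s_wbcst <- aggregate_wbcst(out, weights = weights,
                                 six_scores = six_scores)
  attr(out, "N") <- nrow(records)
  class(out) <- c("score_table", "data.frame")
  out
}

#' Aggregate battery score
#'
#' The overall battery score is the mean of the five subtest scores, with the
#' divided-attention subtest entering as the mean of its central and
#' peripheral subscores so that each subtest carries equal weight. Because
#' the battery reports six subscores for five subtests, an alternative
#' reading averages all six subscores directly; `six_scores = TRUE` selects
#' it. Non-uniform subtest weights may be supplied, but the study design this
#' package models deliberately keeps them uniform (its sample sizes cannot
#' support weight estimation).
#'
#' @param scores data frame with columns `s1`, `s2`, `s3c`, `s3p`, `s4`, `s5`
#'   (e.g. a [score_cohort()] result).
#' @param weights optional numeric vector of 5 non-negative weights (or 6
#'   when `six_scores`); normalized to sum to one. Default uniform.
#' @param six_scores average the six subscores directly instead of the five
#'   subtest means.
#' @return Numeric vector of aggregate scores in \[0, 1\], one per row.
#' @export
aggregate_wbcst <- function(scores, weights = NULL, six_scores = FALSE) {
  need <- c("s1", "s2", "s3c", "s3p", "s4", "s5")
  missing <- setdiff(need, names(scores))
  stop_if_not(length(missing) == 0,
              paste("missing subscore column(s):",
                    paste(missing, collapse = ", ")))
  m <- as.matrix(scores[, need])
  stop_if_not(all(is.finite(m)), "subscores must be present and finite; no imputation")
  cols <- if (six_scores) {
    m
  } else {
    cbind(m[, "s1"], m[, "s2"], (m[, "s3c"] + m[, "s3p"]) / 2,
          m[, "s4"], m[, "s5"])
  }
  k <- ncol(cols)
  if (is.null(weights)) weights <- rep(1, k)
  stop_if_not(length(weights) == k && all(weights >= 0) && sum(weights) > 0,
              sprintf("`weights` must be %d non-negative values", k))
  as.vector(cols %*% (weights / sum(weights)))
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("Score table: %d participants, %d scored columns\n",
              nrow(x), sum(names(x) != "participant_id" & names(x) != "cohort")))
  NextMethod()
}
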