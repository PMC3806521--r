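#' Empirical ROC analysis of a screening score
#'
#' Sweeps a score cutoff over all observed values and computes, at each, the
#' operating point of "score at or above the cutoff predicts good driving
#' performance". With the default orientation (that of the validation study
#' this package models) sensitivity is the fraction of good performers at or
#' above the cutoff and specificity the fraction of poor performers below
#' it. The area under the curve is the trapezoid area, which equals the
#' tie-adjusted probability that a randomly chosen good performer outscores
#' a randomly chosen poor performer. The AUC standard error is
#' Hanley-McNeil's ([hanley_se()]), the 95% CI a Wald interval truncated to
#' \[0, 1\] (a package choice; it is labelled in the output), and the
#' significance versus chance (AUC = 0.5) uses the Wilcoxon/Mann-Whitney
#' normal approximation.
#'
#' @param scores numeric score vector.
#' @param labels a `group_split` (see [split_by_mean_plus_sd()]) or a
#'   `good`/`poor` vector aligned with `scores`.
#' @param positive `"good"` reproduces the orientation above; `"poor"` gives
#'   the conventional impaired-as-positive orientation (sensitivity over the
#'   poor group). The AUC is identical either way.
#' @param alternative alternative for the test against chance; one-sided
#'   `"greater"` by default, matching a screening hypothesis stated a
#'   priori.
#' @return An object of class `roc_result`: `points` (data frame `cutoff`,
#'   `sensitivity`, `specificity`, swept from high to low cutoffs with a
#'   `+Inf` sentinel), `auc`, `se`, `ci` (named `lower`/`upper`,
#'   `ci_method = "wald_hanley"`), `p_value`, `n_good`, `n_poor`,
#'   `positive`.
#' @export
#' @examples
#' sc <- c(0.9, 0.8, 0.6, 0.4, 0.3)
#' lb <- group_split(c("good", "good", "good", "poor", "poor"))
#' empirical_roc(sc, lb)
empirical_roc <- function(scores, labels, positive = c("good", "poor"),
                          alternative = c("greater", "two.sided")) {
  positive <- match.arg(positive)
  alternative <- match.arg(alternative)
  labels <- as_split_labels(labels, length(scores))
  stop_if_not(all(is.finite(scores)), "scores must be finite")
  good <- scores[labels == "good"]
  poor <- scores[labels == "poor"]
  stop_if_not(length(good) >= 1 && length(poor) >= 1,
              "both classes must be present")

  cutoffs <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens_good <- vapply(cutoffs, function(cf) mean(good >= cf), numeric(1))
  spec_poor <- vapply(cutoffs, function(cf) mean(poor < cf), numeric(1))

  # trapezoid over (1 - specificity, sensitivity); ties enter as the
  # trapezoid's half credit, so this equals the pair-concordance AUC
  fpr <- 1 - spec_poor
  auc <- sum(diff(fpr) * (sens_good[-1] + sens_good[-length(sens_good)]) / 2)

  n_poor <- length(poor); n_good <- length(good)
  se <- hanley_se(auc, n_poor, n_good)
  ci <- c(lower = max(0, auc - 1.96 * se), upper = min(1, auc + 1.96 * se))
  p <- auc_p_value(auc, n_poor, n_good, alternative)

  points <- if (positive == "good") {
    data.frame(cutoff = cutoffs, sensitivity = sens_good,
               specificity = spec_poor)
  } else {
    data.frame(cutoff = cutoffs, sensitivity = 1 - fpr_flip(spec_poor),
               specificity = sens_good)
  }
  structure(
    list(points = points, auc = auc, se = se, ci = ci,
         ci_method = "wald_hanley", p_value = p, alternative = alternative,
         n_good = n_good, n_poor = n_poor, positive = positive),
    class = "roc_result"
  )
}

# with poor as positive, "sensitivity" is the poor group's below-cutoff rate
fpr_flip <- function(spec_poor) 1 - spec_poor

as_split_labels <- function(labels, n) {
  if (inherits(labels, "group_split")) labels <- labels$labels
  labels <- factor(as.character(labels), levels = c("good", "poor"))
  stop_if_not(!anyNA(labels), 'labels must be "good"/"poor"')
  stop_if_not(length(labels) == n, "labels must align with scores")
  labels
}

# Wilcoxon normal approximation for AUC vs 0.5
auc_p_value <- function(auc, n1, n2, alternative = "greater") {
  u <- auc * n1 * n2
  mu <- n1 * n2 / 2
  v <- n1 * n2 * (n1 + n2 + 1) / 12
  z <- (u - mu) / sqrt(v)
  switch(alternative,
         greater = pnorm(z, lower.tail = FALSE),
         two.sided = 2 * pnorm(-abs(z)))
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "Empirical ROC: AUC = %.3f (Hanley SE %.4f, 95%% CI %.3f-%.3f, %s)\n",
    x$auc, x$se, x$ci[["lower"]], x$ci[["upper"]], x$ci_method))
  cat(sprintf("  p vs chance (%s) = %.4g; n_good = %d, n_poor = %d\n",
              x$alternative, x$p_value, x$n_good, x$n_poor))
  invisible(x)
}

#' Hanley-McNeil standard error of an AUC
#'
#' Closed-form standard error of a trapezoid (Wilcoxon) AUC:
#' `Q1 = A / (2 - A)`, `Q2 = 2 A^2 / (1 + A)`,
#' `SE = sqrt((A(1-A) + (n1-1)(Q1-A^2) + (n2-1)(Q2-A^2)) / (n1 n2))`,
#' where `n1` is the size of the smaller (poor-performance) class and `n2`
#' the size of the good-performance class.
#'
#' @param auc area under the curve, in \[0, 1\].
#' @param n1 poor-performance group size (>= 1).
#' @param n2 good-performance group size (>= 1).
#' @return The standard error (0 at AUC = 1).
#' @export
#' @examples
#' hanley_se(0.80, 10, 70)
hanley_se <- function(auc, n1, n2) {
  stop_if_not(is.numeric(auc) && all(auc >= 0 & auc <= 1),
              "`auc` must lie in [0, 1]")
  stop_if_not(all(n1 >= 1) && all(n2 >= 1), "group sizes must be >= 1")
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
          (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
}

#' Binormal (Gaussian-based) smoothed ROC curve
#'
#' Fits a normal distribution to each class's scores and derives the smooth
#' ROC curve `TPR(t) = pnorm(a + b * qnorm(t))` with
#' `a = (mean_good - mean_poor) / sd_good` (standardized separation) and
#' `b = sd_poor / sd_good` (SD ratio); the binormal AUC is
#' `pnorm(a / sqrt(1 + b^2))`.
#'
#' @inheritParams empirical_roc
#' @return An object of class `binormal_fit`: `a`, `b`, `auc`, the class
#'   moments, and `curve(t)`, a function mapping false-positive rates to
#'   true-positive rates.
#' @export
binormal_fit <- function(scores, labels) {
  labels <- as_split_labels(labels, length(scores))
  good <- scores[labels == "good"]
  poor <- scores[labels == "poor"]
  stop_if_not(length(good) >= 2 && length(poor) >= 2,
              "each class needs >= 2 members")
  stop_if_not(sd(good) > 0 && sd(poor) > 0,
              "degenerate fit: zero within-class variance")
  a <- (mean(good) - mean(poor)) / sd(good)
  b <- sd(poor) / sd(good)
  structure(
    list(a = a, b = b, auc = pnorm(a / sqrt(1 + b^2)),
         mean_good = mean(good), sd_good = sd(good),
         mean_poor = mean(poor), sd_poor = sd(poor),
         curve = function(t) pnorm(a + b * qnorm(t))),
    class = "binormal_fit"
  )
}

#' @export
print.binormal_fit <- function(x, ...) {
  cat(sprintf("Binormal ROC fit: a = %.3f, b = %.3f, AUC = %.3f\n",
              x$a, x$b, x$auc))
  invisible(x)
}

#' Cutoff table: sensitivity, specificity and efficiency
#'
#' For each requested score cutoff, computes the operating point (orientation
#' as in [empirical_roc()]) and the efficiency — the fraction of all
#' subjects correctly classified,
#' `(n_good * sens + n_poor * spec) / (n_good + n_poor)`. Printed columns are
#' rounded to two decimals, half away from zero; exact values are retained.
#'
#' @inheritParams empirical_roc
#' @param cutoffs numeric vector of score cutoffs.
#' @return A data frame with columns `cutoff`, `sensitivity`, `specificity`,
#'   `efficiency` (exact) and `sens_print`, `spec_print`, `eff_print`
#'   (2-decimal report values); attributes `n_good`, `n_poor`.
#' @export
cutoff_table <- function(scores, labels, cutoffs, positive = "good") {
  labels <- as_split_labels(labels, length(scores))
  good <- scores[labels == "good"]
  poor <- scores[labels == "poor"]
  stop_if_not(length(good) >= 1 && length(poor) >= 1,
              "both classes must be present")
  stop_if_not(is.numeric(cutoffs) && length(cutoffs) >= 1,
              "`cutoffs` must be a nonempty numeric vector")
  sens <- vapply(cutoffs, function(cf) mean(good >= cf), numeric(1))
  spec <- vapply(cutoffs, function(cf) mean(poor < cf), numeric(1))
  if (positive == "poor") {
    tmp <- sens; sens <- spec; spec <- tmp
  }
  n_g <- length(good); n_p <- length(poor)
  eff <- if (positive == "good") {
    (n_g * sens + n_p * spec) / (n_g + n_p)
  } else {
    (n_p * sens + n_g * spec) / (n_g + n_p)
  }
  out <- data.frame(
    cutoff = cutoffs, sensitivity = sens, specificity = spec,
    efficiency = eff,
    sens_print = round_half_away(sens, 2),
    spec_print = round_half_away(spec, 2),
    eff_print = round_half_away(eff, 2)
  )
  attr(out, "n_good") <- n_g
  attr(out, "n_poor") <- n_p
  out
}

#' Reconstruct efficiency from printed sensitivity and specificity
#'
#' Verification bridge to a published cutoff table: given two-decimal
#' sensitivity and specificity and the group sizes, reconstruct the integer
#' counts of correctly classified subjects, `TP = round(sens * n_good)` and
#' `TN = round(spec * n_poor)` (half away from zero), and return
#' `(TP + TN) / (n_good + n_poor)` rounded to two decimals half away from
#' zero.
#'
#' @param sens,spec printed sensitivity and specificity in \[0, 1\]
#'   (vectorized).
#' @param n_good,n_poor group sizes (>= 1).
#' @return Reconstructed efficiency, rounded to two decimals.
#' @export
#' @examples
#' efficiency_from_printed(0.83, 0.70, 70, 10)  # 0.81
efficiency_from_printed <- function(sens, spec, n_good, n_poor) {
  stop_if_not(all(sens >= 0 & sens <= 1) && all(spec >= 0 & spec <= 1),
              "rates must lie in [0, 1]")
  stop_if_not(n_good >= 1 && n_poor >= 1, "group sizes must be >= 1")
  tp <- round_half_away(sens * n_good, 0)
  tn <- round_half_away(spec * n_poor, 0)
  round_half_away((tp + tn) / (n_good + n_poor), 2)
}

#' Published operating points of the original validation study
#'
#' The cutoff table reported by the screening battery's original validation
#' study (70 good and 10 poor driving performers): 18 score cutoffs with the
#' printed two-decimal sensitivity, specificity and efficiency. Used as a
#' worked example and as a consistency surface for
#' [efficiency_from_printed()].
#'
#' @return A data frame with columns `cutoff`, `sensitivity`, `specificity`,
#'   `efficiency`; attributes `n_good = 70`, `n_poor = 10`.
#' @export
reference_cutoff_table <- function() {
  out <- data.frame(
    cutoff      = c(0.88, 0.84, 0.83, 0.81, 0.77, 0.75, 0.73, 0.68, 0.66,
                    0.65, 0.64, 0.63, 0.61, 0.57, 0.56, 0.53, 0.52, 0.51),
    sensitivity = c(0.94, 0.91, 0.89, 0.86, 0.84, 0.83, 0.80, 0.77, 0.74,
                    0.71, 0.69, 0.69, 0.66, 0.63, 0.60, 0.57, 0.54, 0.53),
    specificity = c(0.30, 0.30, 0.30, 0.30, 0.50, 0.70, 0.70, 0.70, 0.70,
                    0.70, 0.70, 0.90, 0.90, 0.90, 0.90, 0.90, 0.90, 0.90),
    efficiency  = c(0.86, 0.84, 0.81, 0.79, 0.80, 0.81, 0.79, 0.76, 0.74,
                    0.71, 0.69, 0.71, 0.69, 0.66, 0.64, 0.61, 0.59, 0.58)
  )
  attr(out, "n_good") <- 70L
  attr(out, "n_poor") <- 10L
  out
}
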