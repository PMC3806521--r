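#' Split a cohort into good and poor driving performers
#'
#' Implements the driving-performance criterion: the cutoff is the mean plus
#' one sample standard deviation of the driving-simulator error counts, and a
#' participant is labelled a poor performer when their error count strictly
#' exceeds the cutoff. For integer error counts this realizes a threshold of
#' the form `E >= ceiling(cutoff)`; in the validation cohort this package
#' models it produced the split poor = `E_DS >= 4` (n=10) versus good =
#' `E_DS < 4` (n=70).
#'
#' With zero variance nobody lies strictly above the cutoff, so all
#' participants are labelled good.
#'
#' @param ds_errors integer vector of driving-simulator error counts,
#'   length >= 2.
#' @return An object of class `group_split`: `cutoff`, `labels` (factor
#'   `good`/`poor` aligned with the input), `n_good`, `n_poor`.
#' @export
#' @examples
#' split_by_mean_plus_sd(c(0, 1, 2, 3, 4, 14))  # cutoff ~9.06, one poor
split_by_mean_plus_sd <- function(ds_errors) {
  stop_if_not(is.numeric(ds_errors) && length(ds_errors) >= 2,
              "need at least 2 error counts (sample SD undefined otherwise)")
  stop_if_not(all(is.finite(ds_errors)) && all(ds_errors >= 0),
              "error counts must be finite and non-negative")
  cutoff <- mean(ds_errors) + sd(ds_errors)
  labels <- factor(ifelse(ds_errors > cutoff, "poor", "good"),
                   levels = c("good", "poor"))
  structure(
    list(cutoff = cutoff, labels = labels,
         n_good = sum(labels == "good"), n_poor = sum(labels == "poor")),
    class = "group_split"
  )
}

#' Construct a group split from explicit labels
#'
#' For evaluating scores against an externally given good/poor grouping
#' (e.g. when re-analysing a published split) rather than the
#' mean-plus-one-SD rule.
#'
#' @param labels character or factor vector of `"good"`/`"poor"` labels.
#' @param cutoff optional cutoff value to record alongside.
#' @return A `group_split` object.
#' @export
group_split <- function(labels, cutoff = NA_real_) {
  labels <- factor(as.character(labels), levels = c("good", "poor"))
  stop_if_not(!anyNA(labels), 'labels must all be "good" or "poor"')
  structure(
    list(cutoff = cutoff, labels = labels,
         n_good = sum(labels == "good"), n_poor = sum(labels == "poor")),
    class = "group_split"
  )
}

#' @export
print.group_split <- function(x, ...) {
  cat(sprintf("Group split: cutoff %.3f, %d good / %d poor\n",
              x$cutoff, x$n_good, x$n_poor))
  invisible(x)
}
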