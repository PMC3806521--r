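#' Configuration of a full evaluation run
#'
#' Bundles the options of [run_pipeline()]: where the cohort comes from (a
#' CSV path or a [cohort_config()]), the master seed, scoring options, ROC
#' orientation, the cutoff list for the report table, and output formats.
#'
#' @param cohort either a path to a cohort CSV or a [cohort_config()];
#'   default a fresh default-configured synthetic cohort.
#' @param seed master seed; overrides the cohort config's seed so one number
#'   pins the whole run.
#' @param weights,six_scores aggregate-score options, see
#'   [aggregate_wbcst()].
#' @param positive ROC orientation, see [empirical_roc()].
#' @param cutoffs cutoff list for the report table; `NULL` uses every
#'   observed aggregate-score value.
#' @param output_dir directory for the report bundle; `NULL` returns results
#'   without writing.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), seed = 1L, weights = NULL,
                       six_scores = FALSE, positive = "good", cutoffs = NULL,
                       output_dir = NULL) {
  stop_if_not(inherits(cohort, "cohort_config") ||
                (is.character(cohort) && length(cohort) == 1),
              "`cohort` must be a cohort_config() or a CSV path")
  stop_if_not(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "`seed` must be a single integer")
  stop_if_not(positive %in% c("good", "poor"), '`positive` must be "good" or "poor"')
  if (!is.null(cutoffs)) {
    stop_if_not(is.numeric(cutoffs) && all(is.finite(cutoffs)),
                "`cutoffs` must be numeric")
  }
  structure(
    list(cohort = cohort, seed = as.integer(seed), weights = weights,
         six_scores = six_scores, positive = positive, cutoffs = cutoffs,
         output_dir = output_dir),
    class = "run_config"
  )
}

#' Run the full screening-evaluation pipeline
#'
#' Generates (or reads) a cohort, scores it, splits it into good and poor
#' driving performers by the mean-plus-one-SD rule, compares the groups'
#' aggregate scores with a one-sided Mann-Whitney test (direction: poor
#' performers score lower), runs the empirical and binormal ROC analyses,
#' builds the cutoff table and the correlation matrix, and (optionally)
#' writes everything plus a run manifest to `output_dir`. Identical
#' configuration and seed give a byte-identical bundle.
#'
#' @param config a [run_config()].
#' @return A list of class `pipeline_result`: `cohort`, `scores`, `split`,
#'   `mwu` (good vs poor aggregate score), `roc`, `binormal`, `cutoffs`
#'   (table), `correlations`, `summary` (covariate table by split),
#'   `manifest`.
#' @export
#' @examples
#' res <- run_pipeline(run_config(seed = 7))
#' res$roc
run_pipeline <- function(config = run_config()) {
  stop_if_not(inherits(config, "run_config"),
              "`config` must come from run_config()")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  cohort <- stage("cohort", {
    if (inherits(config$cohort, "cohort_config")) {
      cc <- config$cohort
      cc$seed <- config$seed
      generate_cohort(cc)
    } else {
      read_cohort_csv(config$cohort)
    }
  })
  scores <- stage("scoring",
                  score_cohort(cohort, weights = config$weights,
                               six_scores = config$six_scores))
  split <- stage("classify", split_by_mean_plus_sd(cohort$e_ds))
  mwu <- stage("group-comparison", {
    g <- scores$s_wbcst[split$labels == "good"]
    p <- scores$s_wbcst[split$labels == "poor"]
    if (length(p) == 0 || length(g) == 0) {
      NULL  # degenerate split: no comparison possible
    } else {
      mann_whitney_u(p, g, alternative = "less")
    }
  })
  roc <- stage("roc", {
    if (split$n_poor == 0 || split$n_good == 0) NULL
    else empirical_roc(scores$s_wbcst, split, positive = config$positive)
  })
  binormal <- stage("roc-binormal", {
    if (is.null(roc) || split$n_poor < 2 || split$n_good < 2) NULL
    else binormal_fit(scores$s_wbcst, split)
  })
  cutoffs <- config$cutoffs %||% sort(unique(scores$s_wbcst))
  cut_tab <- stage("cutoff-table", {
    if (is.null(roc)) NULL
    else cutoff_table(scores$s_wbcst, split, cutoffs,
                      positive = config$positive)
  })
  cors <- stage("correlations", correlation_matrix(scores))
  summ <- stage("summary", covariate_summary(cohort, split))

  manifest <- list(
    package = "drivescreen",
    version = as.character(utils::packageVersion("drivescreen")),
    seed = config$seed,
    cohort_source = if (inherits(config$cohort, "cohort_config")) "synthetic"
                    else config$cohort,
    options = list(six_scores = config$six_scores,
                   positive = config$positive,
                   weights = config$weights),
    n = nrow(cohort), n_good = split$n_good, n_poor = split$n_poor,
    ds_cutoff = split$cutoff
  )

  result <- structure(
    list(cohort = cohort, scores = scores, split = split, mwu = mwu,
         roc = roc, binormal = binormal, cutoffs = cut_tab,
         correlations = cors, summary = summ, manifest = manifest),
    class = "pipeline_result"
  )
  if (!is.null(config$output_dir)) write_bundle(result, config$output_dir)
  result
}

write_bundle <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort_csv(result$cohort, file.path(dir, "cohort.csv"),
                   split = result$split)
  write.csv(as.data.frame(result$scores), file.path(dir, "scores.csv"),
            row.names = FALSE, quote = FALSE)
  if (!is.null(result$cutoffs)) {
    write.csv(result$cutoffs, file.path(dir, "cutoff_table.csv"),
              row.names = FALSE, quote = FALSE)
  }
  write.csv(as.data.frame(result$correlations$r),
            file.path(dir, "correlation_matrix.csv"), quote = FALSE)
  if (!is.null(result$roc)) {
    roc_out <- result$roc
    roc_out$points <- NULL
    jsonlite::write_json(
      c(roc_out[c("auc", "se", "ci", "ci_method", "p_value",
                  "n_good", "n_poor", "positive")],
        list(operating_points = result$roc$points)),
      file.path(dir, "roc.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Screening evaluation: %d participants (%d good / %d poor, DS cutoff %.2f)\n",
              m$n, m$n_good, m$n_poor, m$ds_cutoff))
  if (!is.null(x$mwu)) {
    cat(sprintf("  aggregate score, poor < good: U = %.1f, one-sided p = %.4g\n",
                x$mwu$U, x$mwu$p_value))
  }
  if (!is.null(x$roc)) {
    cat(sprintf("  AUC = %.3f (SE %.4f, 95%% CI %.3f-%.3f)\n",
                x$roc$auc, x$roc$se, x$roc$ci[["lower"]], x$roc$ci[["upper"]]))
  }
  invisible(x)
}
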