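#' Configuration for the synthetic cohort generator
#'
#' Builds a validated configuration describing the three recruitment groups of
#' the study design this package emulates: healthy younger drivers, healthy
#' older drivers, and older drivers with cognitive impairment (MoCA < 26).
#' Each group has a latent driving-relevant ability distribution, covariate
#' distributions, and an error link mapping ability to expected error counts.
#'
#' @details
#' The error link is log-linear: a participant with latent ability `z` has
#' expected count `base * exp(-slope * z)` for every error measure, so higher
#' ability means fewer errors everywhere and all subtest errors share the
#' latent factor (this induces the positive cross-test correlations a real
#' battery shows). Counts are drawn from a negative binomial with dispersion
#' `size` (`Inf` gives Poisson). Covariates are group-wise normals; MoCA is
#' rounded and clipped to 0–30 (and to below 26 for the impaired group, its
#' inclusion criterion), the clock-drawing test is rounded and clipped to its
#' 0–7 scale, and times are truncated below at 1 second. Secondary driving
#' measures are lognormal around ability-linked medians: risk measures (speed
#' variability, lateral acceleration, brake time) shrink with ability, safety
#' margins (distance and time to collision) grow with it.
#'
#' @param group_sizes named integer vector: participants per group. Names must
#'   be among `young`, `older_healthy`, `older_impaired`. Default 26/44/10,
#'   the analyzed sample of the validation study this package models.
#' @param ability_params per-group list of `mean` and `sd` for latent ability.
#' @param covariate_params per-group list of `mean`/`sd` pairs for `moca`,
#'   `tmt_a`, `tmt_b`, `cdt`, `tug`.
#' @param error_link list with `base` (named non-negative rates at ability 0
#'   for `e1`, `e2`, `e3c`, `e3p`, `e4`, `e5`, `e_ds`), `slope` (log-rate
#'   decrease per ability unit) and `size` (negative binomial dispersion,
#'   `Inf` = Poisson).
#' @param secondary_link list with `median` (named medians at ability 0 for
#'   the five secondary driving measures), `slope` and `sdlog`.
#' @param seed integer master seed.
#' @return An object of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(seed = 42)
#' cohort <- generate_cohort(cfg)
#' table(cohort$cohort)
cohort_config <- function(group_sizes = c(young = 26L, older_healthy = 44L,
                                          older_impaired = 10L),
                          ability_params = NULL,
                          covariate_params = NULL,
                          error_link = NULL,
                          secondary_link = NULL,
                          seed = 1L) {
  defaults_ability <- list(
    young          = list(mean = 1.0,  sd = 0.4),
    older_healthy  = list(mean = 0.4,  sd = 0.5),
    older_impaired = list(mean = -0.6, sd = 0.5)
  )
  defaults_cov <- list(
    young = list(
      moca  = c(mean = 29.0, sd = 1.0),
      tmt_a = c(mean = 22.0, sd = 6.0),
      tmt_b = c(mean = 48.0, sd = 15.0),
      cdt   = c(mean = 6.8,  sd = 0.5),
      tug   = c(mean = 5.5,  sd = 1.0)
    ),
    older_healthy = list(
      moca  = c(mean = 28.2, sd = 1.5),
      tmt_a = c(mean = 28.0, sd = 12.0),
      tmt_b = c(mean = 70.0, sd = 45.0),
      cdt   = c(mean = 6.5,  sd = 1.2),
      tug   = c(mean = 6.9,  sd = 2.5)
    ),
    older_impaired = list(
      moca  = c(mean = 23.0, sd = 1.8),
      tmt_a = c(mean = 36.0, sd = 14.0),
      tmt_b = c(mean = 91.0, sd = 46.0),
      cdt   = c(mean = 4.3,  sd = 2.0),
      tug   = c(mean = 7.5,  sd = 3.5)
    )
  )
  defaults_link <- list(
    base = c(e1 = 2.0, e2 = 3.0, e3c = 3.5, e3p = 2.5, e4 = 2.5, e5 = 3.0,
             e_ds = 2.2),
    slope = 0.7,
    size = 8
  )
  defaults_secondary <- list(
    median = c(speed_var = 2.0, lat_accel = 1.5, brake_time = 20,
               dist_collision = 25, time_collision = 2.5),
    slope = 0.3,
    sdlog = 0.3
  )

  ability_params   <- merge_group_params(defaults_ability, ability_params)
  covariate_params <- merge_group_params(defaults_cov, covariate_params)
  error_link       <- modifyList(defaults_link, error_link %||% list())
  secondary_link   <- modifyList(defaults_secondary, secondary_link %||% list())

  known <- c("young", "older_healthy", "older_impaired")
  stop_if_not(length(group_sizes) > 0 && !is.null(names(group_sizes)) &&
                all(names(group_sizes) %in% known),
              "`group_sizes` must be named with groups among young, older_healthy, older_impaired")
  stop_if_not(all(is.finite(group_sizes)) && all(group_sizes >= 0) &&
                all(group_sizes == round(group_sizes)),
              "group sizes must be non-negative integers")
  for (g in names(ability_params)) {
    stop_if_not(ability_params[[g]]$sd >= 0, "ability SDs must be >= 0")
    for (cv in names(covariate_params[[g]])) {
      stop_if_not(covariate_params[[g]][[cv]][["sd"]] >= 0,
                  "covariate SDs must be >= 0")
    }
  }
  stop_if_not(all(error_link$base >= 0), "error-link base rates must be >= 0")
  stop_if_not(error_link$size > 0, "negative binomial dispersion must be > 0")
  stop_if_not(all(secondary_link$median > 0) && secondary_link$sdlog >= 0,
              "secondary-measure medians must be > 0 and sdlog >= 0")

  structure(
    list(group_sizes = group_sizes, ability_params = ability_params,
         covariate_params = covariate_params, error_link = error_link,
         secondary_link = secondary_link, seed = seed),
    class = "cohort_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

merge_group_params <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  for (g in names(user)) {
    defaults[[g]] <- modifyList(defaults[[g]] %||% list(), user[[g]])
  }
  defaults
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  groups:",
      paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
            collapse = ", "), "\n")
  cat("  error link: base rates",
      paste(sprintf("%s=%.2g", names(x$error_link$base), x$error_link$base),
            collapse = ", "), "\n")
  cat(sprintf("  slope %.2f, dispersion %s, seed %d\n",
              x$error_link$slope, format(x$error_link$size), x$seed))
  invisible(x)
}

# Column set of a cohort data frame; the CSV schema is this, in this order.
cohort_columns <- function() {
  c("participant_id", "cohort",
    "e1", "e2", "e3c", "e3p", "e4", "e5", "e_ds",
    "speed_var", "lat_accel", "brake_time", "dist_collision",
    "time_collision",
    "moca", "tmt_a", "tmt_b", "cdt", "tug")
}

error_columns <- function() c("e1", "e2", "e3c", "e3p", "e4", "e5", "e_ds")

secondary_columns <- function() {
  c("speed_var", "lat_accel", "brake_time", "dist_collision", "time_collision")
}

covariate_columns <- function() c("moca", "tmt_a", "tmt_b", "cdt", "tug")

#' Generate a synthetic participant cohort
#'
#' Draws one participant record per configured slot: a latent ability from the
#' group's normal distribution, error counts whose negative-binomial means
#' follow the error link, secondary driving measures, and covariates. The
#' result is deterministic given the config (including its seed).
#'
#' @param config a [cohort_config()].
#' @return A data frame with one row per participant and the documented
#'   column set (see [write_cohort_csv()]); the latent ability is attached as
#'   attribute `"ability"` for diagnostics but is not part of the record.
#' @export
generate_cohort <- function(config) {
  stop_if_not(inherits(config, "cohort_config"),
              "`config` must be created by cohort_config()")
  with_seed(config$seed, {
    groups <- names(config$group_sizes)
    parts <- lapply(groups, function(g) {
      n <- as.integer(config$group_sizes[[g]])
      if (n == 0L) return(NULL)
      generate_group(g, n, config)
    })
    parts <- parts[!vapply(parts, is.null, logical(1))]
    out <- do.call(rbind, parts)
    out$participant_id <- sprintf("P%03d", seq_len(nrow(out)))
    ability <- out$.ability
    out$.ability <- NULL
    rownames(out) <- NULL
    out <- out[, cohort_columns()]
    attr(out, "ability") <- ability
    out
  })
}

generate_group <- function(group, n, config) {
  ab <- config$ability_params[[group]]
  z <- rnorm(n, ab$mean, ab$sd)

  link <- config$error_link
  rate <- function(base) base * exp(-link$slope * z)
  draw_count <- function(base) {
    mu <- rate(base)
    if (is.infinite(link$size)) rpois(n, mu) else rnbinom(n, mu = mu, size = link$size)
  }
  errs <- lapply(link$base, draw_count)

  sec <- config$secondary_link
  draw_lnorm <- function(median0, direction) {
    rlnorm(n, meanlog = log(median0) + direction * sec$slope * z,
           sdlog = sec$sdlog)
  }
  # risk measures fall with ability, safety margins rise with it
  sec_dir <- c(speed_var = -1, lat_accel = -1, brake_time = -1,
               dist_collision = 1, time_collision = 1)
  secondary <- lapply(names(sec_dir), function(m) {
    draw_lnorm(sec$median[[m]], sec_dir[[m]])
  })
  names(secondary) <- names(sec_dir)

  cv <- config$covariate_params[[group]]
  moca_max <- if (group == "older_impaired") 25L else 30L
  moca <- pmin(pmax(round(rnorm(n, cv$moca[["mean"]], cv$moca[["sd"]])), 0L),
               moca_max)
  cdt <- pmin(pmax(round(rnorm(n, cv$cdt[["mean"]], cv$cdt[["sd"]])), 0L), 7L)
  tmt_a <- pmax(rnorm(n, cv$tmt_a[["mean"]], cv$tmt_a[["sd"]]), 1)
  tmt_b <- pmax(rnorm(n, cv$tmt_b[["mean"]], cv$tmt_b[["sd"]]), 1)
  tug <- pmax(rnorm(n, cv$tug[["mean"]], cv$tug[["sd"]]), 1)

  data.frame(
    participant_id = NA_character_, cohort = group,
    e1 = errs$e1, e2 = errs$e2, e3c = errs$e3c, e3p = errs$e3p,
    e4 = errs$e4, e5 = errs$e5, e_ds = errs$e_ds,
    speed_var = secondary$speed_var, lat_accel = secondary$lat_accel,
    brake_time = secondary$brake_time,
    dist_collision = secondary$dist_collision,
    time_collision = secondary$time_collision,
    moca = as.integer(moca), tmt_a = tmt_a, tmt_b = tmt_b,
    cdt = as.integer(cdt), tug = tug,
    .ability = z,
    stringsAsFactors = FALSE
  )
}

#' Summarise covariates per group
#'
#' Per-group mean and SD of each neuropsychological covariate plus group
#' counts — the layout of a study's participant-characteristics table. Groups
#' default to the recruitment cohorts; pass a [split_by_mean_plus_sd()] result
#' to summarise by driving performance instead.
#'
#' @param records cohort data frame from [generate_cohort()] or
#'   [read_cohort_csv()].
#' @param split optional `group_split` (see [split_by_mean_plus_sd()]) whose
#'   labels align with `records`; when given, rows are grouped good/poor.
#' @return A data frame with one row per (group, covariate) holding `n`,
#'   `mean`, `sd`, and a logical `defined` flag (FALSE for empty groups
#'   rather than silent NaN).
#' @export
covariate_summary <- function(records, split = NULL) {
  validate_cohort(records)
  if (is.null(split)) {
    groups <- records$cohort
  } else {
    stop_if_not(inherits(split, "group_split"),
                "`split` must come from split_by_mean_plus_sd()")
    stop_if_not(length(split$labels) == nrow(records),
                "split labels do not align with records")
    groups <- split$labels
  }
  out <- list()
  for (g in unique(groups)) {
    sub <- records[groups == g, , drop = FALSE]
    for (cv in covariate_columns()) {
      defined <- nrow(sub) > 0
      out[[length(out) + 1L]] <- data.frame(
        group = g, covariate = cv, n = nrow(sub),
        mean = if (defined) mean(sub[[cv]]) else NA_real_,
        sd = if (nrow(sub) > 1) sd(sub[[cv]]) else if (defined) 0 else NA_real_,
        defined = defined, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

validate_cohort <- function(records) {
  stop_if_not(is.data.frame(records), "cohort must be a data frame")
  missing <- setdiff(cohort_columns(), names(records))
  stop_if_not(length(missing) == 0,
              paste("cohort is missing columns:",
                    paste(missing, collapse = ", ")))
  invisible(records)
}
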