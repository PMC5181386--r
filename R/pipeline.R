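#' Run the full scoring and association pipeline
#'
#' Executes the whole sequence on a participant table: validation and
#' complete-case accounting, dimension scoring under the configured threshold
#' mode, outcome coding, prevalence tables, crude and mutually adjusted
#' dimension-outcome associations, subgroup stratification, the
#' dimension-count continuum, and the threshold sensitivity sweep. All
#' randomness (the bootstrap for adjusted effects) is seeded from `seed`, so
#' repeated runs on the same inputs are identical.
#'
#' @param records Participant tibble, or a path to a participant CSV (see
#'   [read_participants()]).
#' @param mode Main-analysis threshold mode (default `"published"`).
#' @param sensitivity_modes Modes for the sensitivity sweep.
#' @param n_boot Bootstrap resamples for the adjusted effects.
#' @param seed Integer seed for the bootstrap.
#' @param satisfaction_reversed Passed to [code_outcomes()].
#' @return An object of class `sa_report`: a list of tidy tables
#'   (`dimension_prevalence`, `count_distribution`, `outcome_prevalence`,
#'   `mean_count`, `crude_associations`, `adjusted_effects`, `stratified`,
#'   `heterogeneity`, `continuum`, `sensitivity`, `exclusions`) plus a
#'   `provenance` block (seed, threshold mode, config hash, versions).
#' @examples
#' records <- generate_cohorts(sim_config(n_young = 120, n_old = 80, seed = 2))
#' report <- run_pipeline(records, n_boot = 20)
#' report$crude_associations
#' @export
run_pipeline <- function(records, mode = "published",
                         sensitivity_modes = c("tertile", "quartile", "quintile", "median"),
                         n_boot = 200, seed = 1,
                         satisfaction_reversed = FALSE) {
  if (is.character(records) && length(records) == 1L) {
    records <- read_participants(records)
  }
  validate_participants(records)
  data <- sa_analysis_data(records, mode = mode,
                           satisfaction_reversed = satisfaction_reversed)
  n_total <- nrow(data)
  n_analysis <- sum(data$analysis)
  if (n_analysis == 0L) {
    stop("no respondents with all six dimensions present after complete-case exclusion",
         call. = FALSE)
  }
  message(sprintf("analysis sample: %d of %d respondents (%d excluded for missing dimensions)",
                  n_analysis, n_total, n_total - n_analysis))

  op <- outcome_prevalence(data)
  strat <- stratified_analysis(data)
  sens <- sensitivity_sweep(records, modes = sensitivity_modes,
                            satisfaction_reversed = satisfaction_reversed)
  exclusions <- tibble::tibble(
    step = c("input records", "complete on all six dimensions"),
    n = c(n_total, n_analysis)
  )
  report <- list(
    dimension_prevalence = dimension_prevalence(data),
    count_distribution = count_distribution(data),
    outcome_prevalence = op$outcomes,
    mean_count = op$mean_count,
    crude_associations = crude_associations(data),
    adjusted_effects = adjusted_dimension_effects(data, n_boot = n_boot, seed = seed),
    stratified = strat$estimates,
    heterogeneity = strat$heterogeneity,
    continuum = continuum_table(data),
    sensitivity = sens$associations,
    sensitivity_fractions = sens$positive_fractions,
    exclusions = exclusions,
    thresholds = attr(data, "thresholds"),
    provenance = list(
      seed = as.integer(seed),
      threshold_mode = mode,
      n_boot = n_boot,
      n_records = n_total,
      n_analysis = n_analysis,
      input_hash = rlang::hash(records),
      package_version = as.character(utils::packageVersion("rowekahn")),
      r_version = as.character(getRversion())
    )
  )
  class(report) <- "sa_report"
  report
}

#' @export
print.sa_report <- function(x, ...) {
  p <- x$provenance
  cat("<sa_report>\n")
  cat(sprintf("  analysis sample: %d / %d respondents; threshold mode %s; seed %d\n",
              p$n_analysis, p$n_records, p$threshold_mode, p$seed))
  overall <- x$outcome_prevalence[x$outcome_prevalence$group == "overall", ]
  for (i in seq_len(nrow(overall))) {
    cat(sprintf("  %-22s %5.1f%% (%d/%d)\n", overall$outcome[i],
                round_half_up(overall$percent[i]), overall$numerator[i],
                overall$denominator[i]))
  }
  cat(sprintf("  crude differences: %d dimension-outcome pairs, all positive: %s\n",
              nrow(x$crude_associations), all(x$crude_associations$difference > 0)))
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits one tidy CSV per report table plus a single JSON bundle
#' (`report.json`) containing every table and the provenance block. The
#' continuum table doubles as plot-ready figure data (count level, outcome,
#' prevalence, CI bounds).
#'
#' @param report An `sa_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "sa_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- Filter(function(x) inherits(x, "data.frame"), unclass(report))
  for (name in names(tables)) {
    readr::write_csv(tables[[name]], file.path(dir, paste0(name, ".csv")))
  }
  bundle <- c(tables, list(thresholds = unclass(report$thresholds),
                           provenance = report$provenance))
  jsonlite::write_json(bundle, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
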