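#' Height-standardize grip strength and FEV1
#'
#' Grip strength and lung function scale with body size, so both are
#' standardized for height before comparing to the cohort median: within each
#' sex-by-cohort stratum the measure is regressed on height by least squares
#' and the residual kept. Residuals average zero within a stratum, so
#' "above the stratum median residual" means better than expected for a
#' person of that height, sex and cohort.
#'
#' @param records Participant tibble.
#' @param method `"residual"` (default) for least-squares residuals on
#'   height; `"ratio"` divides the measure by height before centring, for
#'   users who prefer an allometric-style adjustment.
#' @return `records` with columns `std_grip` and `std_fev1` added. Records
#'   with a missing height or measure get `NA`.
#' @export
standardize_physical <- function(records, method = c("residual", "ratio")) {
  method <- match.arg(method)
  records$std_grip <- NA_real_
  records$std_fev1 <- NA_real_
  strata <- unique(records[, c("sex", "cohort")])
  for (i in seq_len(nrow(strata))) {
    in_stratum <- records$sex == strata$sex[i] & records$cohort == strata$cohort[i]
    in_stratum[is.na(in_stratum)] <- FALSE
    for (measure in c("grip", "fev1")) {
      ok <- in_stratum & !is.na(records[[measure]]) & !is.na(records$height)
      if (sum(ok) < 2L) {
        stop(sprintf("stratum sex=%s, cohort=%s has %d complete record(s) for %s; need >= 2",
                     strata$sex[i], strata$cohort[i], sum(ok), measure), call. = FALSE)
      }
      y <- records[[measure]][ok]
      h <- records$height[ok]
      std <- if (method == "ratio") {
        r <- y / h
        r - mean(r)
      } else if (stats::var(h) < 1e-12) {
        y - mean(y)
      } else {
        stats::residuals(stats::lm(y ~ h))
      }
      records[[paste0("std_", measure)]][ok] <- std
    }
  }
  records
}

threshold_modes <- c("published", "tertile", "quartile", "quintile", "median")

nominal_fraction <- function(mode) {
  switch(mode, tertile = 1 / 3, quartile = 1 / 4, quintile = 1 / 5, median = 1 / 2,
         stop(sprintf("unknown threshold mode '%s'", mode), call. = FALSE))
}

# cutoff on the observed value grid whose classified-positive fraction is
# closest to `nominal`; ties broken toward the more inclusive (larger
# positive-fraction) cutoff. direction "low": positive iff value <= cutoff;
# "high": positive iff value >= cutoff.
grid_cutoff <- function(values, nominal, direction = c("low", "high")) {
  direction <- match.arg(direction)
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no observed values to derive a cutoff from", call. = FALSE)
  grid <- sort(unique(values))
  frac <- if (direction == "low") {
    vapply(grid, function(v) mean(values <= v), numeric(1))
  } else {
    vapply(grid, function(v) mean(values >= v), numeric(1))
  }
  dist <- abs(frac - nominal)
  best <- which(dist == min(dist))
  # more inclusive = larger fraction positive
  best <- best[which.max(frac[best])]
  grid[best]
}

#' Derive cohort-relative dimension thresholds
#'
#' Computes, within each cohort, the cutoffs defining the "positive" side of
#' each score-based successful-aging dimension. For the disability score the
#' lowest (least disabled) fraction is taken; for the cognition score the
#' highest; for the engagement blocks the most-engaged item-count minimum.
#' Each cutoff is the point on the observed value grid whose positive
#' fraction is closest to the mode's nominal fraction (tertile 1/3, quartile
#' 1/4, quintile 1/5, median 1/2); with discrete scores the achieved fraction
#' is only approximately nominal. Physical-function medians (of
#' height-standardized grip and FEV1 by sex, and of systolic blood pressure
#' and pulse by cohort) are always within-stratum medians, whatever the mode.
#'
#' `mode = "published"` fixes the categorical cutoffs at their published
#' values (disability 0 / <= 0.5, cognition 41+ / 31+, productive engagement
#' 3+ / 2+, interpersonal engagement 3+ in both cohorts for the 1952 / 1932
#' cohorts) and computes only the data-derived medians.
#'
#' @param records Participant tibble; standardized automatically if
#'   `std_grip`/`std_fev1` are absent.
#' @param mode One of `"published"`, `"tertile"`, `"quartile"`, `"quintile"`,
#'   `"median"`.
#' @return An object of class `sa_thresholds`: per-cohort cutoffs and medians.
#' @export
derive_thresholds <- function(records, mode = c("published", "tertile", "quartile",
                                                "quintile", "median")) {
  mode <- match.arg(mode)
  if (!all(c("std_grip", "std_fev1") %in% names(records))) {
    records <- standardize_physical(records)
  }
  published <- list(
    `1952` = list(opcs_cutoff = 0, ah4_cutoff = 41L, productive_min = 3L, interpersonal_min = 3L),
    `1932` = list(opcs_cutoff = 0.5, ah4_cutoff = 31L, productive_min = 2L, interpersonal_min = 3L)
  )
  cohorts <- list()
  for (coh in c("1952", "1932")) {
    rows <- records[records$cohort == coh & !is.na(records$cohort), ]
    if (nrow(rows) == 0L) stop(sprintf("cohort %s has no records", coh), call. = FALSE)
    th <- if (mode == "published") {
      published[[coh]]
    } else {
      nominal <- nominal_fraction(mode)
      inter_count <- rowSums(cbind(rows$lives_with_partner, rows$contact_4wk,
                                   rows$club_attendance))
      prod_count <- rowSums(cbind(rows$work_training, rows$voluntary_work, rows$childcare,
                                  rows$support_other, rows$group_member))
      list(
        opcs_cutoff = grid_cutoff(rows$opcs_score, nominal, "low"),
        ah4_cutoff = grid_cutoff(rows$ah4_score, nominal, "high"),
        productive_min = as.integer(grid_cutoff(prod_count, nominal, "high")),
        interpersonal_min = as.integer(grid_cutoff(inter_count, nominal, "high"))
      )
    }
    th$sbp_median <- stats::median(rows$sbp, na.rm = TRUE)
    th$pulse_median <- stats::median(rows$pulse, na.rm = TRUE)
    th$grip_median <- c(
      female = stats::median(rows$std_grip[rows$sex == "female"], na.rm = TRUE),
      male = stats::median(rows$std_grip[rows$sex == "male"], na.rm = TRUE)
    )
    th$fev1_median <- c(
      female = stats::median(rows$std_fev1[rows$sex == "female"], na.rm = TRUE),
      male = stats::median(rows$std_fev1[rows$sex == "male"], na.rm = TRUE)
    )
    cohorts[[coh]] <- th
  }
  structure(list(mode = mode, cohorts = cohorts), class = "sa_thresholds")
}

#' @export
print.sa_thresholds <- function(x, ...) {
  cat(sprintf("<sa_thresholds> mode = %s\n", x$mode))
  for (coh in names(x$cohorts)) {
    th <- x$cohorts[[coh]]
    cat(sprintf("  %s: opcs <= %s, ah4 >= %s, productive >= %d, interpersonal >= %d\n",
                coh, format(th$opcs_cutoff), format(th$ah4_cutoff),
                th$productive_min, th$interpersonal_min))
  }
  invisible(x)
}

cohort_threshold <- function(thresholds, cohort, field) {
  stopifnot(inherits(thresholds, "sa_thresholds"))
  vapply(as.character(cohort), function(coh) {
    if (is.na(coh)) return(NA_real_)
    as.numeric(thresholds$cohorts[[coh]][[field]])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Classify absence of disability
#'
#' Positive when the disability severity score is at or below the cohort
#' cutoff (the least-disabled approximate tertile).
#'
#' @param opcs_score Nonnegative disability severity score(s).
#' @param cohort Cohort label(s), `"1952"` or `"1932"`.
#' @param thresholds An `sa_thresholds`.
#' @return Logical vector with `NA` where the score is missing.
#' @export
classify_no_disability <- function(opcs_score, cohort, thresholds) {
  if (any(!is.na(opcs_score) & opcs_score < 0)) {
    stop("opcs_score must be >= 0", call. = FALSE)
  }
  opcs_score <= cohort_threshold(thresholds, cohort, "opcs_cutoff")
}

#' Classify good cognitive functioning
#'
#' Positive when the cognition test score is at or above the cohort cutoff
#' (top approximate tertile; inclusive, "41+" style).
#'
#' @inheritParams classify_no_disability
#' @param ah4_score Nonnegative integer cognition score(s).
#' @return Logical vector with `NA` where the score is missing.
#' @export
classify_cognitive <- function(ah4_score, cohort, thresholds) {
  ah4_score >= cohort_threshold(thresholds, cohort, "ah4_cutoff")
}

sex_median <- function(thresholds, cohort, sex, field) {
  mapply(function(coh, sx) {
    if (is.na(coh) || is.na(sx)) return(NA_real_)
    thresholds$cohorts[[coh]][[field]][[sx]]
  }, as.character(cohort), sex, USE.NAMES = FALSE)
}

#' Classify good physical functioning
#'
#' Counts favorable indicators out of four — height-standardized grip
#' strength and FEV1 strictly above their sex-by-cohort medians, systolic
#' blood pressure and pulse strictly below their cohort medians — and is
#' positive with 3 or more. A value exactly at its median is unfavorable.
#' All four measures must be present, else the result is missing.
#'
#' @inheritParams classify_no_disability
#' @param std_grip,std_fev1 Height-standardized residuals from
#'   [standardize_physical()].
#' @param sbp,pulse Systolic blood pressure (mmHg) and pulse (bpm).
#' @param sex Sex label(s), `"female"` or `"male"`.
#' @return Logical vector with `NA` where any measure is missing.
#' @export
classify_physical <- function(std_grip, std_fev1, sbp, pulse, cohort, sex, thresholds) {
  fav <- (std_grip > sex_median(thresholds, cohort, sex, "grip_median")) +
    (std_fev1 > sex_median(thresholds, cohort, sex, "fev1_median")) +
    (sbp < cohort_threshold(thresholds, cohort, "sbp_median")) +
    (pulse < cohort_threshold(thresholds, cohort, "pulse_median"))
  fav >= 3
}

#' Classify good interpersonal social engagement
#'
#' Positive with at least the cohort minimum (3 in both cohorts under
#' published thresholds, i.e. all three) of: living with a spouse/partner,
#' direct contact with family or friends in the last 4 weeks, regular club
#' or class attendance. Missing if any item is missing.
#'
#' @inheritParams classify_no_disability
#' @param lives_with_partner,contact_4wk,club_attendance Logical item
#'   responses.
#' @return Logical vector.
#' @export
classify_interpersonal <- function(lives_with_partner, contact_4wk, club_attendance,
                                   cohort, thresholds) {
  count <- cbind(lives_with_partner, contact_4wk, club_attendance)
  rowSums(count) >= cohort_threshold(thresholds, cohort, "interpersonal_min")
}

#' Classify good productive social engagement
#'
#' Positive with at least the cohort minimum (3 in the 1952 cohort, 2 in the
#' 1932 cohort under published thresholds) of: paid work or training,
#' voluntary work, childcare, support to another person, membership of a
#' community-type group. Missing if any item is missing.
#'
#' @inheritParams classify_no_disability
#' @param work_training,voluntary_work,childcare,support_other,group_member
#'   Logical item responses.
#' @return Logical vector.
#' @export
classify_productive <- function(work_training, voluntary_work, childcare,
                                support_other, group_member, cohort, thresholds) {
  count <- cbind(work_training, voluntary_work, childcare, support_other, group_member)
  rowSums(count) >= cohort_threshold(thresholds, cohort, "productive_min")
}

#' Build successful-aging profiles
#'
#' Applies the six dimension classifiers to each (standardized) participant
#' record: absence of chronic disease, absence of disability, good physical,
#' cognitive, interpersonal and productive functioning. The dimension count
#' is the sum of the six indicators when all are present and missing
#' otherwise; `all_six` (the conventional binary successful-aging measure) is
#' `count == 6`.
#'
#' @param records Participant tibble carrying `std_grip`/`std_fev1` (see
#'   [standardize_physical()]; [score_cohort()] handles the full sequence).
#' @param thresholds An `sa_thresholds`.
#' @param code_set Qualifying-disease code set, default [disease_code_set()].
#' @return A tibble with columns `disease_free`, `no_disability`,
#'   `physical_good`, `cognitive_good`, `interpersonal_good`,
#'   `productive_good`, `count`, `all_six`.
#' @export
build_profile <- function(records, thresholds, code_set = disease_code_set()) {
  stopifnot(all(c("std_grip", "std_fev1") %in% names(records)))
  profile <- tibble::tibble(
    disease_free = vapply(records$rcgp_codes, classify_disease_free,
                          logical(1), set = code_set, USE.NAMES = FALSE),
    no_disability = classify_no_disability(records$opcs_score, records$cohort, thresholds),
    physical_good = classify_physical(records$std_grip, records$std_fev1,
                                      records$sbp, records$pulse,
                                      records$cohort, records$sex, thresholds),
    cognitive_good = classify_cognitive(records$ah4_score, records$cohort, thresholds),
    interpersonal_good = classify_interpersonal(records$lives_with_partner,
                                                records$contact_4wk,
                                                records$club_attendance,
                                                records$cohort, thresholds),
    productive_good = classify_productive(records$work_training, records$voluntary_work,
                                          records$childcare, records$support_other,
                                          records$group_member,
                                          records$cohort, thresholds)
  )
  m <- as.matrix(profile)
  profile$count <- as.integer(rowSums(m))  # NA if any indicator missing
  profile$all_six <- profile$count == 6L
  profile
}

sa_dimensions <- c("disease_free", "no_disability", "physical_good",
                   "cognitive_good", "interpersonal_good", "productive_good")

sa_dimension_labels <- c(
  disease_free = "No chronic disease",
  no_disability = "No disability",
  physical_good = "Good physical function",
  cognitive_good = "Good cognitive function",
  interpersonal_good = "Good interpersonal engagement",
  productive_good = "Good productive engagement"
)

#' Score a cohort end to end
#'
#' Standardizes the physical measures, derives (or accepts) thresholds, and
#' builds the successful-aging profile for every record.
#'
#' @param records Participant tibble.
#' @param mode Threshold mode passed to [derive_thresholds()]; ignored when
#'   `thresholds` is supplied.
#' @param thresholds Optional pre-computed `sa_thresholds`.
#' @param code_set Qualifying-disease code set.
#' @return A list of class `sa_scored` with elements `records` (standardized),
#'   `profiles`, and `thresholds`.
#' @export
score_cohort <- function(records, mode = "published", thresholds = NULL,
                         code_set = disease_code_set()) {
  validate_participants(records)
  records <- standardize_physical(records)
  if (is.null(thresholds)) thresholds <- derive_thresholds(records, mode)
  profiles <- build_profile(records, thresholds, code_set)
  structure(list(records = records, profiles = profiles, thresholds = thresholds),
            class = "sa_scored")
}

#' @export
print.sa_scored <- function(x, ...) {
  cat(sprintf("<sa_scored> %d records, threshold mode = %s\n",
              nrow(x$records), x$thresholds$mode))
  complete <- sum(!is.na(x$profiles$count))
  cat(sprintf("  complete profiles: %d; mean dimension count %.2f\n",
              complete, mean(x$profiles$count, na.rm = TRUE)))
  invisible(x)
}
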