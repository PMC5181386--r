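#' Assemble the analysis dataset
#'
#' Scores the cohort, codes the outcomes, and marks the analysis sample:
#' respondents with all six successful-aging dimensions present. Respondents
#' with any missing dimension are excluded from every estimate (complete-case
#' analysis); per-outcome denominators additionally drop respondents missing
#' that outcome, so denominators may differ across outcomes. A
#' `negative_affect_half` column splits the analysis sample at its median
#' trait negative-affect score, with ties assigned to the "below" half.
#'
#' @param records Participant tibble.
#' @param mode Threshold mode (see [derive_thresholds()]).
#' @param thresholds Optional pre-computed `sa_thresholds`.
#' @param code_set Qualifying-disease code set.
#' @param satisfaction_reversed Passed to [code_outcomes()].
#' @param na_ties One of `"below"` (default) or `"above"`: which half receives
#'   scores exactly at the negative-affect median.
#' @return A tibble (records + standardized measures + dimension indicators +
#'   `count`/`all_six` + coded outcomes + `analysis` flag), with the
#'   `sa_thresholds` attached as attribute `"thresholds"`.
#' @export
sa_analysis_data <- function(records, mode = "published", thresholds = NULL,
                             code_set = disease_code_set(),
                             satisfaction_reversed = FALSE,
                             na_ties = c("below", "above")) {
  na_ties <- match.arg(na_ties)
  scored <- score_cohort(records, mode = mode, thresholds = thresholds, code_set = code_set)
  data <- dplyr::bind_cols(scored$records, scored$profiles,
                           code_outcomes(records, satisfaction_reversed))
  data$analysis <- !is.na(data$count)
  data$negative_affect_half <- NA_character_
  in_split <- data$analysis & !is.na(data$negative_affect)
  if (any(in_split)) {
    med <- stats::median(data$negative_affect[in_split])
    at_or_below <- data$negative_affect <= med
    below <- if (na_ties == "below") at_or_below else data$negative_affect < med
    data$negative_affect_half[in_split] <- ifelse(below[in_split], "below", "above")
  }
  attr(data, "thresholds") <- scored$thresholds
  data
}

analysis_rows <- function(data) data[data$analysis, , drop = FALSE]

#' Dimension prevalence table
#'
#' Per cohort, the number and percentage of analysis-sample respondents
#' positive on each successful-aging dimension, with Wilson 95% intervals.
#'
#' @param data Analysis tibble from [sa_analysis_data()].
#' @return Tidy tibble: `cohort`, `dimension`, `numerator`, `denominator`,
#'   `percent`, `ci_low`, `ci_high`.
#' @export
dimension_prevalence <- function(data) {
  d <- analysis_rows(data)
  purrr::map_dfr(c("1952", "1932"), function(coh) {
    rows <- d[d$cohort == coh, ]
    purrr::map_dfr(sa_dimensions, function(dim) {
      dplyr::bind_cols(
        tibble::tibble(cohort = coh, dimension = dim),
        prevalence(sum(rows[[dim]]), nrow(rows))
      )
    })
  })
}

#' Distribution of the dimension count
#'
#' @param data Analysis tibble from [sa_analysis_data()].
#' @return Tibble: `cohort`, `count` (0-6), `n`, `percent`. Frequencies sum
#'   to the analysis n within each cohort.
#' @export
count_distribution <- function(data) {
  d <- analysis_rows(data)
  purrr::map_dfr(c("1952", "1932"), function(coh) {
    counts <- d$count[d$cohort == coh]
    tibble::tibble(
      cohort = coh,
      count = 0:6,
      n = vapply(0:6, function(k) sum(counts == k), integer(1)),
      percent = 100 * vapply(0:6, function(k) mean(counts == k), numeric(1))
    )
  })
}

subgroup_levels <- function(data, variable) {
  if (variable == "overall") return("overall")
  switch(variable,
    cohort = c("1952", "1932"),
    sex = c("female", "male"),
    ses = c("nonmanual", "manual"),
    negative_affect_half = c("below", "above"),
    sort(unique(stats::na.omit(data[[variable]])))
  )
}

subgroup_rows <- function(d, variable, level) {
  if (variable == "overall") return(d)
  d[!is.na(d[[variable]]) & d[[variable]] == level, , drop = FALSE]
}

#' Favorable-outcome prevalence and mean dimension count by subgroup
#'
#' For the overall analysis sample and for each subgroup level, the
#' prevalence (Wilson 95% CI) of each favorable outcome among respondents
#' with that outcome observed, and the mean dimension count with a t-based
#' 95% interval.
#'
#' @param data Analysis tibble from [sa_analysis_data()].
#' @param by Character vector of stratifiers among `"overall"`, `"cohort"`,
#'   `"sex"`, `"ses"`, `"negative_affect_half"`.
#' @return List with `outcomes` (tidy prevalence tibble) and `mean_count`.
#' @export
outcome_prevalence <- function(data, by = c("overall", "cohort", "sex", "ses",
                                            "negative_affect_half")) {
  d <- analysis_rows(data)
  outcomes <- purrr::map_dfr(by, function(variable) {
    purrr::map_dfr(subgroup_levels(d, variable), function(level) {
      rows <- subgroup_rows(d, variable, level)
      purrr::map_dfr(sa_outcomes, function(out) {
        y <- rows[[out]][!is.na(rows[[out]])]
        if (length(y) == 0L) return(NULL)
        dplyr::bind_cols(
          tibble::tibble(group = variable, level = as.character(level), outcome = out),
          prevalence(sum(y), length(y))
        )
      })
    })
  })
  mean_count <- purrr::map_dfr(by, function(variable) {
    purrr::map_dfr(subgroup_levels(d, variable), function(level) {
      rows <- subgroup_rows(d, variable, level)
      k <- rows$count
      if (length(k) == 0L) return(NULL)
      se <- stats::sd(k) / sqrt(length(k))
      tcrit <- stats::qt(0.975, length(k) - 1)
      tibble::tibble(
        group = variable, level = as.character(level), n = length(k),
        mean_count = mean(k), ci_low = mean(k) - tcrit * se,
        ci_high = mean(k) + tcrit * se
      )
    })
  })
  list(outcomes = outcomes, mean_count = mean_count)
}

#' Crude dimension-outcome prevalence differences
#'
#' For each dimension and outcome, the difference (Newcombe 95% CI) in
#' favorable-outcome prevalence between respondents positive versus not
#' positive on the dimension, together with the prevalence in the
#' not-positive group (the bracketed baseline of the published-style table).
#'
#' @param data Analysis tibble from [sa_analysis_data()].
#' @return Tidy tibble with one row per dimension-outcome pair.
#' @export
crude_associations <- function(data) {
  d <- analysis_rows(data)
  purrr::map_dfr(sa_dimensions, function(dim) {
    purrr::map_dfr(sa_outcomes, function(out) {
      ok <- !is.na(d[[out]])
      pos <- d[[dim]][ok]
      y <- d[[out]][ok]
      if (sum(pos) == 0L || sum(!pos) == 0L) return(NULL)
      dplyr::bind_cols(
        tibble::tibble(dimension = dim, outcome = out),
        prevalence_difference(sum(y & pos), sum(pos), sum(y & !pos), sum(!pos))
      )
    })
  })
}

marginal_risk_difference <- function(fit, newdata, dim) {
  d1 <- newdata; d1[[dim]] <- TRUE
  d0 <- newdata; d0[[dim]] <- FALSE
  100 * (mean(stats::predict(fit, newdata = d1, type = "response")) -
           mean(stats::predict(fit, newdata = d0, type = "response")))
}

fit_dimension_model <- function(d, out, dims) {
  formula <- stats::as.formula(paste(out, "~", paste(dims, collapse = " + ")))
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(formula, family = stats::binomial(), data = d),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  flagged <- warned || !fit$converged || any(abs(stats::coef(fit)) > 15, na.rm = TRUE)
  list(fit = fit, flagged = flagged)
}

#' Mutually adjusted dimension effects via marginal standardization
#'
#' Fits, per outcome, one additive logistic model containing all six
#' dimension indicators, then reports each dimension's adjusted effect as a
#' marginal-standardization risk difference: the mean predicted favorable
#' probability with the dimension set positive for everyone minus the mean
#' with it set negative for everyone, in percentage points. Confidence
#' intervals are percentile intervals from a nonparametric bootstrap over
#' respondents (model refitted per resample). Fits showing separation or
#' non-convergence are reported with `flagged = TRUE` rather than dropped.
#'
#' @param data Analysis tibble from [sa_analysis_data()].
#' @param dimensions Dimension columns to adjust mutually (default all six).
#' @param n_boot Bootstrap resamples (default 200).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level.
#' @return Tidy tibble: `dimension`, `outcome`, `adjusted_difference`,
#'   `ci_low`, `ci_high`, `n`, `flagged`.
#' @export
adjusted_dimension_effects <- function(data, dimensions = sa_dimensions,
                                       n_boot = 200, seed = 1, conf = 0.95) {
  d <- analysis_rows(data)
  alpha <- (1 - conf) / 2
  withr::with_seed(as.integer(seed), {
    purrr::map_dfr(sa_outcomes, function(out) {
      rows <- d[!is.na(d[[out]]), c(out, dimensions)]
      fitted <- fit_dimension_model(rows, out, dimensions)
      point <- vapply(dimensions, marginal_risk_difference,
                      numeric(1), fit = fitted$fit, newdata = rows)
      boot <- matrix(NA_real_, nrow = n_boot, ncol = length(dimensions),
                     dimnames = list(NULL, dimensions))
      for (b in seq_len(n_boot)) {
        idx <- sample.int(nrow(rows), replace = TRUE)
        bfit <- suppressWarnings(
          stats::glm(fitted$fit$formula, family = stats::binomial(), data = rows[idx, ])
        )
        boot[b, ] <- vapply(dimensions, marginal_risk_difference,
                            numeric(1), fit = bfit, newdata = rows[idx, ])
      }
      tibble::tibble(
        dimension = dimensions,
        outcome = out,
        adjusted_difference = unname(point),
        ci_low = apply(boot, 2, stats::quantile, probs = alpha, na.rm = TRUE),
        ci_high = apply(boot, 2, stats::quantile, probs = 1 - alpha, na.rm = TRUE),
        n = nrow(rows),
        flagged = fitted$flagged
      )
    })
  })
}

#' Subgroup-stratified associations with heterogeneity tests
#'
#' Re-runs the crude dimension-outcome prevalence differences within each
#' level of each stratifier, and tests heterogeneity per dimension,
#' stratifier and outcome by the Wald test of the interaction term in a
#' logistic model `outcome ~ dimension * stratifier`. Empty strata are
#' skipped with a message.
#'
#' @param data Analysis tibble from [sa_analysis_data()].
#' @param strata Stratifier variables (default cohort, sex, ses,
#'   negative_affect_half).
#' @return List with `estimates` (stratified crude associations) and
#'   `heterogeneity` (interaction p-values).
#' @export
stratified_analysis <- function(data, strata = c("cohort", "sex", "ses",
                                                 "negative_affect_half")) {
  d <- analysis_rows(data)
  estimates <- purrr::map_dfr(strata, function(variable) {
    purrr::map_dfr(subgroup_levels(d, variable), function(level) {
      rows <- subgroup_rows(d, variable, level)
      if (nrow(rows) == 0L) {
        message(sprintf("stratum %s = %s is empty; skipped", variable, level))
        return(NULL)
      }
      rows$analysis <- TRUE
      dplyr::bind_cols(tibble::tibble(stratifier = variable, level = level),
                       crude_associations(rows))
    })
  })
  heterogeneity <- purrr::map_dfr(strata, function(variable) {
    rows <- d[!is.na(d[[variable]]), ]
    purrr::map_dfr(sa_dimensions, function(dim) {
      purrr::map_dfr(sa_outcomes, function(out) {
        ok <- !is.na(rows[[out]])
        df <- data.frame(y = rows[[out]][ok], dim = rows[[dim]][ok],
                         s = factor(rows[[variable]][ok]))
        if (nlevels(droplevels(df$s)) < 2L) return(NULL)
        fit <- suppressWarnings(
          stats::glm(y ~ dim * s, family = stats::binomial(), data = df)
        )
        coefs <- summary(fit)$coefficients
        inter <- grep("^dimTRUE:", rownames(coefs))
        if (length(inter) == 0L) return(NULL)
        tibble::tibble(
          stratifier = variable, dimension = dim, outcome = out,
          interaction_estimate = coefs[inter[1], "Estimate"],
          p_interaction = coefs[inter[1], "Pr(>|z|)"]
        )
      })
    })
  })
  list(estimates = estimates, heterogeneity = heterogeneity)
}

#' Favorable-outcome prevalence along the dimension-count continuum
#'
#' For each dimension count 0-6, the prevalence (Wilson 95% CI) of each
#' favorable outcome among analysis-sample respondents with that count.
#' Count levels with no respondents are suppressed.
#'
#' @param data Analysis tibble from [sa_analysis_data()].
#' @return Tidy tibble: `count`, `outcome`, `numerator`, `denominator`,
#'   `percent`, `ci_low`, `ci_high`.
#' @export
continuum_table <- function(data) {
  d <- analysis_rows(data)
  purrr::map_dfr(0:6, function(k) {
    rows <- d[d$count == k, ]
    if (nrow(rows) == 0L) return(NULL)
    purrr::map_dfr(sa_outcomes, function(out) {
      y <- rows[[out]][!is.na(rows[[out]])]
      if (length(y) == 0L) return(NULL)
      dplyr::bind_cols(tibble::tibble(count = k, outcome = out),
                       prevalence(sum(y), length(y)))
    })
  })
}

#' Threshold sensitivity sweep
#'
#' Recomputes thresholds, profiles and crude dimension-outcome associations
#' under each requested threshold mode, so the stability of the association
#' pattern against the positivity cutoffs can be inspected directly.
#'
#' @param records Participant tibble.
#' @param modes Subset of `"published"`, `"tertile"`, `"quartile"`,
#'   `"quintile"`, `"median"`.
#' @param code_set Qualifying-disease code set.
#' @param satisfaction_reversed Passed to [code_outcomes()].
#' @return List with `associations` (crude associations per mode, `mode`
#'   column first) and `positive_fractions` (per mode, cohort and dimension).
#' @export
sensitivity_sweep <- function(records, modes = c("published", "tertile", "quartile",
                                                 "quintile", "median"),
                              code_set = disease_code_set(),
                              satisfaction_reversed = FALSE) {
  modes <- match.arg(modes, several.ok = TRUE)
  assoc <- list()
  fracs <- list()
  for (mode in modes) {
    data <- sa_analysis_data(records, mode = mode, code_set = code_set,
                             satisfaction_reversed = satisfaction_reversed)
    assoc[[mode]] <- dplyr::bind_cols(tibble::tibble(mode = mode), crude_associations(data))
    fracs[[mode]] <- dplyr::bind_cols(tibble::tibble(mode = mode), dimension_prevalence(data))
  }
  list(associations = dplyr::bind_rows(assoc),
       positive_fractions = dplyr::bind_rows(fracs))
}
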