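#' Synthetic-cohort generator configuration
#'
#' Builds a validated configuration for [generate_cohorts()]. The generator
#' emulates two survey cohorts ("1952", aged around 57, and "1932", aged
#' around 76) in which a single standard-normal latent health factor drives
#' the physiological measures, disability, cognition, engagement items and
#' self-rated outcomes, while trait negative affect shifts only the self-rated
#' outcomes — never the successful-aging dimension variables (its slope on
#' those is structurally zero).
#'
#' Intercepts and ordinal cutpoints are calibrated at construction time, by
#' numerical quadrature over the latent mixture, so that marginal rates hit
#' the configured targets: the cohort disease-free fractions
#' (`disease_free_targets`, default 81.2% / 58.0%), the no-disability
#' fractions at the published cutoffs (44.8% / 40.3%), the top-tertile
#' cognition fractions, and the four favorable-outcome marginals (68.6%,
#' 76.2%, 80.6%, 88.5%).
#'
#' @param n_young,n_old Cohort sizes (defaults 886 and 483).
#' @param latent_sd Standard deviation of the latent health factor within a
#'   sex-by-class stratum.
#' @param disease_free_targets Length-2 probabilities, marginal disease-free
#'   fraction per cohort (`young`, `old`).
#' @param disease_logit_slope Effect of one SD of latent health on the logit
#'   of being disease-free.
#' @param physio_loadings Named numeric: change in grip (kg), FEV1 (L),
#'   systolic blood pressure (mmHg) and pulse (bpm) per SD of latent health.
#'   Blood pressure and pulse load negatively (better health, lower values).
#' @param engagement_probs Base probabilities and latent-health logit slope
#'   for the three interpersonal and five productive engagement items, per
#'   cohort. See the default for the structure.
#' @param outcome_logits Per-outcome latent-health slope, negative-affect
#'   slope, additive logit shift for the old cohort, and target favorable
#'   marginal. Cutpoints are calibrated from these.
#' @param missing_rate Probability that each maskable field is independently
#'   set missing (default 0: complete records).
#' @param mar If `TRUE`, missingness probability increases for respondents
#'   with poorer latent health (missing at random given the latent factor);
#'   default `FALSE` (missing completely at random).
#' @param seed Integer seed; a fixed seed makes [generate_cohorts()] output
#'   byte-identical across runs.
#' @return An object of class `sa_sim_config`.
#' @examples
#' cfg <- sim_config(n_young = 100, n_old = 60, seed = 1)
#' cohort <- generate_cohorts(cfg)
#' @export
sim_config <- function(n_young = 886,
                       n_old = 483,
                       latent_sd = 1,
                       disease_free_targets = c(young = 0.812, old = 0.580),
                       disease_logit_slope = 1.1,
                       physio_loadings = c(grip = 3, fev1 = 0.3, sbp = -8, pulse = -4),
                       engagement_probs = default_engagement_probs(),
                       outcome_logits = default_outcome_logits(),
                       missing_rate = 0,
                       mar = FALSE,
                       seed = 1L) {
  if (!is.numeric(n_young) || length(n_young) != 1L || is.na(n_young) || n_young < 1) {
    stop_config("n_young", "must be a count >= 1")
  }
  if (!is.numeric(n_old) || length(n_old) != 1L || is.na(n_old) || n_old < 1) {
    stop_config("n_old", "must be a count >= 1")
  }
  if (!is.numeric(latent_sd) || length(latent_sd) != 1L || is.na(latent_sd) || latent_sd <= 0) {
    stop_config("latent_sd", "must be a positive real")
  }
  assert_prob(disease_free_targets, "disease_free_targets")
  if (length(disease_free_targets) != 2L) {
    stop_config("disease_free_targets", "must have entries 'young' and 'old'")
  }
  assert_prob(missing_rate, "missing_rate")
  if (length(missing_rate) != 1L) stop_config("missing_rate", "must be a scalar")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_config("seed", "must be an integer")
  }
  if (!setequal(names(physio_loadings), c("grip", "fev1", "sbp", "pulse"))) {
    stop_config("physio_loadings", "must be named grip, fev1, sbp, pulse")
  }
  for (coh in c("young", "old")) {
    assert_prob(engagement_probs$interpersonal$base[[coh]], "engagement_probs")
    assert_prob(engagement_probs$productive$base[[coh]], "engagement_probs")
  }

  cfg <- list(
    n_young = as.integer(n_young),
    n_old = as.integer(n_old),
    latent_sd = latent_sd,
    disease_free_targets = disease_free_targets,
    disease_logit_slope = disease_logit_slope,
    physio_loadings = physio_loadings,
    engagement_probs = engagement_probs,
    outcome_logits = outcome_logits,
    missing_rate = missing_rate,
    mar = isTRUE(mar),
    seed = as.integer(seed),
    # population structure: female fraction, manual-class fraction, and the
    # latent-health mean shift attached to each label
    group_probs = c(female = 0.54, manual = 0.30),
    latent_shifts = c(female = -0.08, male = 0.10, manual = -0.60, nonmanual = 0.20),
    # disability severity: underlying normal, negated latent loading, rounded
    # to a 0.5 grid and floored at 0; targets are the published lowest-tertile
    # fractions at cutoffs 0 (young) and 0.5 (old)
    opcs = list(slope = 1.2, sd = 1.5, targets = c(young = 0.448, old = 0.403),
                cutoffs = c(young = 0, old = 0.5)),
    # cognition: integer score, top tertile at the published cutoffs
    ah4 = list(slope = 8, sd = 6, cutoffs = c(young = 41, old = 31), top_fraction = 1 / 3)
  )
  cfg <- calibrate_config(cfg)
  structure(cfg, class = "sa_sim_config")
}

#' @rdname sim_config
#' @export
default_engagement_probs <- function() {
  list(
    interpersonal = list(
      base = list(
        young = c(lives_with_partner = 0.78, contact_4wk = 0.92, club_attendance = 0.42),
        old = c(lives_with_partner = 0.62, contact_4wk = 0.90, club_attendance = 0.46)
      ),
      slope = 0.6
    ),
    productive = list(
      base = list(
        young = c(work_training = 0.65, voluntary_work = 0.15, childcare = 0.25,
                  support_other = 0.35, group_member = 0.30),
        old = c(work_training = 0.05, voluntary_work = 0.18, childcare = 0.15,
                support_other = 0.28, group_member = 0.38)
      ),
      slope = 0.6
    )
  )
}

#' @rdname sim_config
#' @export
default_outcome_logits <- function() {
  list(
    srh_recent = list(latent_slope = 1.1, na_slope = -0.5, old_shift = -0.55, target = 0.686),
    srh_for_age = list(latent_slope = 1.1, na_slope = -0.5, old_shift = 0, target = 0.762),
    sat_health = list(latent_slope = 1.0, na_slope = -0.5, old_shift = 0, target = 0.806),
    sat_life = list(latent_slope = 0.8, na_slope = -0.5, old_shift = 0, target = 0.885)
  )
}

# latent-health mixture (means and weights) over sex x class strata
latent_mixture <- function(cfg) {
  p_f <- cfg$group_probs[["female"]]
  p_m <- cfg$group_probs[["manual"]]
  sh <- cfg$latent_shifts
  grid <- expand.grid(sex = c("female", "male"), ses = c("manual", "nonmanual"),
                      stringsAsFactors = FALSE)
  w <- ifelse(grid$sex == "female", p_f, 1 - p_f) *
    ifelse(grid$ses == "manual", p_m, 1 - p_m)
  mu <- sh[grid$sex] + sh[grid$ses]
  list(mu = unname(mu), w = unname(w))
}

# solve intercepts/cutpoints so marginal rates equal configured targets
calibrate_config <- function(cfg) {
  mix <- latent_mixture(cfg)
  b <- cfg$disease_logit_slope

  cfg$disease_logit_intercepts <- vapply(c("young", "old"), function(coh) {
    calibrate_intercept(cfg$disease_free_targets[[coh]],
                        mu = b * mix$mu, sd = abs(b) * cfg$latent_sd, w = mix$w)
  }, numeric(1))

  # OPCS underlying normal: mu_c - slope * z + sd * e; score = round to 0.5
  # grid, floored at 0. P(score <= cutoff) = P(underlying < cutoff + 0.25).
  s_tot <- sqrt((cfg$opcs$slope * cfg$latent_sd)^2 + cfg$opcs$sd^2)
  cfg$opcs$mu <- vapply(c("young", "old"), function(coh) {
    thr <- cfg$opcs$cutoffs[[coh]] + 0.25
    target <- cfg$opcs$targets[[coh]]
    stats::uniroot(function(m) {
      sum(mix$w * stats::pnorm((thr - m + cfg$opcs$slope * mix$mu) / s_tot)) - target
    }, interval = c(-20, 20), tol = 1e-9)$root
  }, numeric(1))

  # AH4 integer score: round(mu_c + slope * z + sd * e), floored at 0;
  # P(score >= cutoff) = P(underlying > cutoff - 0.5) = top_fraction
  a_tot <- sqrt((cfg$ah4$slope * cfg$latent_sd)^2 + cfg$ah4$sd^2)
  cfg$ah4$mu <- vapply(c("young", "old"), function(coh) {
    thr <- cfg$ah4$cutoffs[[coh]] - 0.5
    stats::uniroot(function(m) {
      sum(mix$w * (1 - stats::pnorm((thr - m - cfg$ah4$slope * mix$mu) / a_tot))) -
        cfg$ah4$top_fraction
    }, interval = c(-50, 100), tol = 1e-9)$root
  }, numeric(1))

  # outcome cutpoints: favorable iff latent response >= cut_fav, response =
  # ls * z + ns * na + old_shift + logistic error. The Gaussian part of the
  # linear predictor has per-stratum mean ls * mu_k (+ old_shift) and sd
  # sqrt(ls^2 latent_sd^2 + ns^2); cohorts weighted by size.
  w_old <- cfg$n_old / (cfg$n_young + cfg$n_old)
  for (out in names(cfg$outcome_logits)) {
    ol <- cfg$outcome_logits[[out]]
    mu_all <- c(ol$latent_slope * mix$mu, ol$latent_slope * mix$mu + ol$old_shift)
    w_all <- c(mix$w * (1 - w_old), mix$w * w_old)
    sd_all <- sqrt((ol$latent_slope * cfg$latent_sd)^2 + ol$na_slope^2)
    cut_fav <- -calibrate_intercept(ol$target, mu = mu_all, sd = sd_all, w = w_all)
    n_levels <- if (out %in% c("srh_recent", "srh_for_age")) 4L else 7L
    if (n_levels == 4L) {
      # poor | fair | good | excellent, favorable = good or better
      cutpoints <- c(cut_fav - 1.5, cut_fav, cut_fav + 1.8)
    } else {
      # 1..7, favorable = 5 and above (three most positive)
      cutpoints <- cut_fav + 0.9 * ((1:6) - 4)
    }
    cfg$outcome_logits[[out]]$cutpoints <- cutpoints
    cfg$outcome_logits[[out]]$n_levels <- n_levels
  }
  cfg
}

#' @export
print.sa_sim_config <- function(x, ...) {
  cat("<sa_sim_config>\n")
  cat(sprintf("  cohorts: n_young = %d, n_old = %d (total %d)\n",
              x$n_young, x$n_old, x$n_young + x$n_old))
  cat(sprintf("  disease-free targets: %.1f%% / %.1f%%; missing rate %.2f (%s)\n",
              100 * x$disease_free_targets[["young"]],
              100 * x$disease_free_targets[["old"]],
              x$missing_rate, if (x$mar) "MAR" else "MCAR"))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Read a generator configuration from a JSON or YAML file
#'
#' Recognised keys are the arguments of [sim_config()]; anything omitted takes
#' its default. The file extension selects the parser (`.json` vs
#' `.yaml`/`.yml`).
#'
#' @param path Path to the configuration file.
#' @return An `sa_sim_config`.
#' @export
sim_config_from_file <- function(path) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop(sprintf("unsupported config format '.%s' (use .json or .yaml)", ext), call. = FALSE)
  )
  allowed <- setdiff(names(formals(sim_config)), "")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0L) {
    stop_config(unknown[1], "unknown configuration key")
  }
  if (!is.null(raw$disease_free_targets)) {
    raw$disease_free_targets <- unlist(raw$disease_free_targets)
  }
  if (!is.null(raw$physio_loadings)) raw$physio_loadings <- unlist(raw$physio_loadings)
  do.call(sim_config, raw)
}
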