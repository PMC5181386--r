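#' Generate a synthetic two-cohort participant table
#'
#' Draws `n_young + n_old` participant records with the dependence structure
#' the downstream analysis assumes: a per-person latent health factor (shifted
#' by sex and occupational class) loads on grip strength, FEV1, blood
#' pressure, pulse, disability, cognition, every engagement item, the
#' probability of being free of qualifying chronic disease, and the four
#' self-rated outcomes. Trait negative affect is drawn independently of latent
#' health and enters only the self-rated outcomes, so it shifts self-ratings
#' without moving the successful-aging dimensions.
#'
#' Respondents carrying a qualifying disease receive one code drawn uniformly
#' from the qualifying RCGP ranges; a fraction of disease-free respondents
#' carry an innocuous non-qualifying code.
#'
#' @param config An `sa_sim_config` from [sim_config()].
#' @return A tibble with one row per participant and the participant-schema
#'   columns (see [write_participants()]). Deterministic for a fixed
#'   `config$seed`.
#' @examples
#' head(generate_cohorts(sim_config(n_young = 50, n_old = 30, seed = 7)))
#' @export
generate_cohorts <- function(config) {
  if (!inherits(config, "sa_sim_config")) {
    stop("config must be built with sim_config()", call. = FALSE)
  }
  withr::with_seed(config$seed, generate_cohorts_impl(config))
}

generate_cohorts_impl <- function(cfg) {
  n <- cfg$n_young + cfg$n_old
  cohort <- rep(c("1952", "1932"), c(cfg$n_young, cfg$n_old))
  old <- cohort == "1932"
  coh_key <- ifelse(old, "old", "young")

  sex <- ifelse(stats::runif(n) < cfg$group_probs[["female"]], "female", "male")
  ses <- ifelse(stats::runif(n) < cfg$group_probs[["manual"]], "manual", "nonmanual")
  z <- stats::rnorm(n, cfg$latent_shifts[sex] + cfg$latent_shifts[ses], cfg$latent_sd)
  negative_affect <- stats::rnorm(n)

  # chronic disease and RCGP codes
  p_free <- stats::plogis(cfg$disease_logit_intercepts[coh_key] +
                            cfg$disease_logit_slope * z)
  disease_free <- stats::runif(n) < p_free
  qualifying <- qualifying_code_pool()
  benign <- c("0455", "0001", "0300", "1100", "2200", "3000")
  rcgp_codes <- character(n)
  has_benign <- disease_free & stats::runif(n) < 0.25
  rcgp_codes[has_benign] <- sample(benign, sum(has_benign), replace = TRUE)
  rcgp_codes[!disease_free] <- sample(qualifying, sum(!disease_free), replace = TRUE)

  # disability: underlying normal, negated latent loading, 0.5 grid, floor 0
  opcs_raw <- cfg$opcs$mu[coh_key] - cfg$opcs$slope * z + stats::rnorm(n, 0, cfg$opcs$sd)
  opcs_score <- pmax(0, round(opcs_raw * 2) / 2)

  # cognition: integer score, floor 0
  ah4_score <- pmax(0L, as.integer(round(
    cfg$ah4$mu[coh_key] + cfg$ah4$slope * z + stats::rnorm(n, 0, cfg$ah4$sd)
  )))

  # physiology; the 1932 cohort is shorter, weaker and has higher pressure
  mean_height <- ifelse(sex == "female", 160.5, 174) - 2 * old
  height <- stats::rnorm(n, mean_height, ifelse(sex == "female", 6, 7))
  load <- cfg$physio_loadings
  grip <- ifelse(sex == "female", 26, 42) - 4 * old +
    0.30 * (height - mean_height) + load[["grip"]] * z + stats::rnorm(n, 0, 4)
  fev1 <- ifelse(sex == "female", 2.4, 3.3) - 0.7 * old +
    0.035 * (height - mean_height) + load[["fev1"]] * z + stats::rnorm(n, 0, 0.35)
  sbp <- 127 + 8 * old + load[["sbp"]] * z + stats::rnorm(n, 0, 12)
  pulse <- 71 + load[["pulse"]] * z + stats::rnorm(n, 0, 8)
  grip <- pmax(grip, 1)
  fev1 <- pmax(fev1, 0.3)
  sbp <- pmax(sbp, 70)
  pulse <- pmax(pulse, 35)

  # engagement items: per-item base probability on the logit scale plus a
  # latent-health slope shared within the block
  draw_items <- function(block) {
    slope <- cfg$engagement_probs[[block]]$slope
    base <- cfg$engagement_probs[[block]]$base
    items <- names(base$young)
    out <- lapply(items, function(it) {
      b <- ifelse(old, base$old[[it]], base$young[[it]])
      stats::runif(n) < stats::plogis(stats::qlogis(b) + slope * z)
    })
    names(out) <- items
    out
  }
  interpersonal <- draw_items("interpersonal")
  productive <- draw_items("productive")

  # self-rated outcomes via an ordered-logit latent response
  draw_outcome <- function(out) {
    ol <- cfg$outcome_logits[[out]]
    u <- ol$latent_slope * z + ol$na_slope * negative_affect +
      ol$old_shift * old + stats::rlogis(n)
    level <- findInterval(u, ol$cutpoints) + 1L
    if (ol$n_levels == 4L) {
      c("poor", "fair", "good", "excellent")[level]
    } else {
      level
    }
  }

  records <- tibble::tibble(
    cohort = cohort,
    sex = sex,
    ses = ses,
    height = round(height, 1),
    grip = round(grip, 1),
    fev1 = round(fev1, 2),
    sbp = round(sbp, 1),
    pulse = round(pulse, 1),
    opcs_score = opcs_score,
    ah4_score = ah4_score,
    rcgp_codes = rcgp_codes,
    lives_with_partner = interpersonal$lives_with_partner,
    contact_4wk = interpersonal$contact_4wk,
    club_attendance = interpersonal$club_attendance,
    work_training = productive$work_training,
    voluntary_work = productive$voluntary_work,
    childcare = productive$childcare,
    support_other = productive$support_other,
    group_member = productive$group_member,
    negative_affect = round(negative_affect, 3),
    srh_recent = draw_outcome("srh_recent"),
    srh_for_age = draw_outcome("srh_for_age"),
    sat_health = draw_outcome("sat_health"),
    sat_life = draw_outcome("sat_life")
  )

  if (cfg$missing_rate > 0) {
    weights <- if (cfg$mar) stats::plogis(-z) / mean(stats::plogis(-z)) else NULL
    records <- mask_fields(records, cfg$missing_rate, weights)
  }
  records
}

# every 4-digit code inside the qualifying ranges, exclusions removed
qualifying_code_pool <- function() {
  set <- disease_code_set()
  codes <- unlist(lapply(seq_along(set$lo), function(i) set$lo[i]:set$hi[i]))
  codes <- setdiff(codes, set$exclude)
  sprintf("%04d", codes)
}

maskable_fields <- function(records) {
  setdiff(names(records), c("cohort", "sex"))
}

mask_fields <- function(records, rate, weights = NULL) {
  fields <- maskable_fields(records)
  n <- nrow(records)
  if (is.null(weights)) weights <- rep(1, n)
  p <- pmin(1, pmax(0, rate * weights))
  for (f in fields) {
    records[[f]][stats::runif(n) < p] <- NA
  }
  records
}

#' Set fields missing at random
#'
#' Independently masks each maskable field of each record with probability
#' `rate`. The `cohort` and `sex` labels are never masked. With `weights`
#' supplied, record `i`'s masking probability is `rate * weights[i]` (capped
#' at 1), which supports missingness tied to an external factor such as
#' latent health.
#'
#' @param records Participant tibble.
#' @param rate Masking probability in `[0, 1]`.
#' @param seed Optional integer; if supplied the masking is seeded and
#'   reproducible.
#' @param weights Optional per-record multiplier on `rate`.
#' @return The records with masked entries set to `NA`.
#' @export
inject_missingness <- function(records, rate, seed = NULL, weights = NULL) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0 || rate > 1) {
    stop("rate must be a probability in [0, 1]", call. = FALSE)
  }
  if (!is.null(weights) && length(weights) != nrow(records)) {
    stop("weights must have one entry per record", call. = FALSE)
  }
  if (rate == 0) return(records)
  if (is.null(seed)) {
    mask_fields(records, rate, weights)
  } else {
    withr::with_seed(as.integer(seed), mask_fields(records, rate, weights))
  }
}

participant_columns <- c(
  "cohort", "sex", "ses", "height", "grip", "fev1", "sbp", "pulse",
  "opcs_score", "ah4_score", "rcgp_codes",
  "lives_with_partner", "contact_4wk", "club_attendance",
  "work_training", "voluntary_work", "childcare", "support_other", "group_member",
  "negative_affect", "srh_recent", "srh_for_age", "sat_health", "sat_life"
)

#' Write / read the participant CSV
#'
#' One row per respondent; columns are exactly the participant-schema fields.
#' Missing values are empty cells. `rcgp_codes` is a semicolon-delimited
#' string of 4-digit codes; an empty code list (respondent with no recorded
#' morbidity codes) is written as the token `"none"` so it stays
#' distinguishable from a missing code list.
#'
#' @param records Participant tibble.
#' @param path File path.
#' @return `write_participants()` returns `path` invisibly;
#'   `read_participants()` returns the participant tibble.
#' @export
write_participants <- function(records, path) {
  validate_participants(records)
  out <- records[, participant_columns]
  out$rcgp_codes <- ifelse(is.na(out$rcgp_codes), NA,
                           ifelse(out$rcgp_codes == "", "none", out$rcgp_codes))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_participants
#' @export
read_participants <- function(path) {
  spec <- readr::cols(
    cohort = readr::col_character(),
    sex = readr::col_character(),
    ses = readr::col_character(),
    height = readr::col_double(),
    grip = readr::col_double(),
    fev1 = readr::col_double(),
    sbp = readr::col_double(),
    pulse = readr::col_double(),
    opcs_score = readr::col_double(),
    ah4_score = readr::col_integer(),
    rcgp_codes = readr::col_character(),
    lives_with_partner = readr::col_logical(),
    contact_4wk = readr::col_logical(),
    club_attendance = readr::col_logical(),
    work_training = readr::col_logical(),
    voluntary_work = readr::col_logical(),
    childcare = readr::col_logical(),
    support_other = readr::col_logical(),
    group_member = readr::col_logical(),
    negative_affect = readr::col_double(),
    srh_recent = readr::col_character(),
    srh_for_age = readr::col_character(),
    sat_health = readr::col_integer(),
    sat_life = readr::col_integer()
  )
  records <- readr::read_csv(path, col_types = spec, na = "")
  records$rcgp_codes[!is.na(records$rcgp_codes) & records$rcgp_codes == "none"] <- ""
  validate_participants(records)
  records
}

#' Validate a participant table against the schema
#'
#' Checks column presence, label levels, ordinal ranges, positivity of the
#' physiological measures and the 4-digit code format. Errors name the first
#' offending column and row.
#'
#' @param records Participant tibble.
#' @return `records`, invisibly, if valid.
#' @export
validate_participants <- function(records) {
  missing_cols <- setdiff(participant_columns, names(records))
  if (length(missing_cols) > 0L) {
    stop(sprintf("participant table is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  check_levels <- function(col, levels) {
    v <- records[[col]]
    bad <- which(!is.na(v) & !(v %in% levels))
    if (length(bad) > 0L) {
      stop(sprintf("column '%s', row %d: value '%s' not in {%s}",
                   col, bad[1], v[bad[1]], paste(levels, collapse = ", ")),
           call. = FALSE)
    }
  }
  check_levels("cohort", c("1952", "1932"))
  check_levels("sex", c("female", "male"))
  check_levels("ses", c("nonmanual", "manual"))
  check_levels("srh_recent", c("excellent", "good", "fair", "poor"))
  check_levels("srh_for_age", c("excellent", "good", "fair", "poor"))
  check_levels("sat_health", 1:7)
  check_levels("sat_life", 1:7)
  for (col in c("height", "grip", "fev1", "sbp", "pulse")) {
    bad <- which(!is.na(records[[col]]) & records[[col]] <= 0)
    if (length(bad) > 0L) {
      stop(sprintf("column '%s', row %d: must be > 0", col, bad[1]), call. = FALSE)
    }
  }
  bad <- which(!is.na(records$opcs_score) & records$opcs_score < 0)
  if (length(bad) > 0L) {
    stop(sprintf("column 'opcs_score', row %d: must be >= 0", bad[1]), call. = FALSE)
  }
  codes <- records$rcgp_codes
  for (i in which(!is.na(codes) & nzchar(codes))) {
    toks <- strsplit(codes[i], ";", fixed = TRUE)[[1]]
    bad_tok <- toks[!grepl("^[0-9]{4}$", toks)]
    if (length(bad_tok) > 0L) {
      stop(sprintf("column 'rcgp_codes', row %d: malformed code '%s'",
                   i, bad_tok[1]), call. = FALSE)
    }
  }
  invisible(records)
}
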