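# Independent oracles and small fixtures. Everything here is deliberately
# written from first principles, separate from the package's code paths.

small_cohort <- function(seed = 11, n_young = 150, n_old = 100, ...) {
  generate_cohorts(sim_config(n_young = n_young, n_old = n_old, seed = seed, ...))
}

# Wilson limits by direct numerical inversion of the score test: the limits
# are the p at which |phat - p| equals z * sqrt(p (1 - p) / n)
oracle_wilson <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  phat <- x / n
  stat <- function(p) (phat - p)^2 - z^2 * p * (1 - p) / n
  # bracket away from phat itself, where the statistic has its trivial zero
  lower <- if (x == 0) 0 else uniroot(stat, c(1e-12, phat - 1e-9), tol = 1e-12)$root
  upper <- if (x == n) 1 else uniroot(stat, c(phat + 1e-9, 1 - 1e-12), tol = 1e-12)$root
  c(lower = lower, upper = upper)
}

# Newcombe hybrid-score interval written out from the published closed form,
# with the Wilson limits obtained from the quadratic-root arrangement rather
# than the centre/half-width arrangement used in the package
oracle_newcombe <- function(x1, n1, x2, n2, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  roots <- function(x, n) {
    a <- n + z^2
    b <- -(2 * x + z^2)
    cc <- x^2 / n
    disc <- sqrt(b^2 - 4 * a * cc)
    c((-b - disc) / (2 * a), (-b + disc) / (2 * a))
  }
  r1 <- roots(x1, n1)
  r2 <- roots(x2, n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  d <- p1 - p2
  c(lower = d - sqrt((p1 - r1[1])^2 + (r2[2] - p2)^2),
    upper = d + sqrt((r1[2] - p1)^2 + (p2 - r2[1])^2))
}

# literal restatement of the published dimension rules, applied one record at
# a time on a small data frame; height standardization recomputed from
# explicit slope/intercept formulas
oracle_profiles <- function(records) {
  qual <- c(setdiff(400:540, 455), 720, 1000, 1015:1030, 1205, 1315,
            1940:1950, 2100:2115, 2420, 2490:2510)
  cuts <- list(`1952` = list(opcs = 0, ah4 = 41, prod = 3),
               `1932` = list(opcs = 0.5, ah4 = 31, prod = 2))
  # residuals by hand
  res <- matrix(NA_real_, nrow(records), 2)
  for (coh in unique(records$cohort)) {
    for (sx in unique(records$sex)) {
      idx <- which(records$cohort == coh & records$sex == sx)
      for (j in 1:2) {
        y <- records[[c("grip", "fev1")[j]]][idx]
        h <- records$height[idx]
        ok <- !is.na(y) & !is.na(h)
        if (sum(ok) < 2) next
        hv <- h[ok]; yv <- y[ok]
        slope <- if (var(hv) == 0) 0 else cov(hv, yv) / var(hv)
        intercept <- mean(yv) - slope * mean(hv)
        res[idx[ok], j] <- yv - (intercept + slope * hv)
      }
    }
  }
  out <- data.frame(matrix(NA, nrow(records), 8))
  names(out) <- c("disease_free", "no_disability", "physical_good", "cognitive_good",
                  "interpersonal_good", "productive_good", "count", "all_six")
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    cu <- cuts[[r$cohort]]
    df <- if (is.na(r$rcgp_codes)) NA else {
      codes <- strsplit(r$rcgp_codes, ";")[[1]]
      codes <- codes[nzchar(codes)]
      !any(as.integer(codes) %in% qual)
    }
    nd <- r$opcs_score <= cu$opcs
    cg <- r$ah4_score >= cu$ah4
    same <- records$cohort == r$cohort
    samesex <- same & records$sex == r$sex
    med <- function(v) median(v, na.rm = TRUE)
    fav <- sum(res[i, 1] > med(res[samesex, 1]),
               res[i, 2] > med(res[samesex, 2]),
               r$sbp < med(records$sbp[same]),
               r$pulse < med(records$pulse[same]))
    pg <- fav >= 3
    ig <- (r$lives_with_partner + r$contact_4wk + r$club_attendance) >= 3
    prg <- (r$work_training + r$voluntary_work + r$childcare +
              r$support_other + r$group_member) >= cu$prod
    vals <- c(df, nd, pg, cg, ig, prg)
    out[i, 1:6] <- vals
    out$count[i] <- if (anyNA(vals)) NA else sum(vals)
    out$all_six[i] <- if (anyNA(vals)) NA else all(vals)
  }
  out
}

# marginal favorable-outcome probability at a given latent health z, from the
# generator's ordered-logit construction, integrating out negative affect
outcome_field <- c(recent_good = "srh_recent", for_age_good = "srh_for_age",
                   health_satisfied = "sat_health", life_satisfied = "sat_life")

oracle_p_outcome_given_z <- function(cfg, outcome, z, old) {
  if (outcome %in% names(outcome_field)) outcome <- outcome_field[[outcome]]
  ol <- cfg$outcome_logits[[outcome]]
  cut <- if (ol$n_levels == 4L) ol$cutpoints[2] else ol$cutpoints[4]
  sapply(z, function(zi) {
    integrate(function(a) {
      plogis(ol$latent_slope * zi + ol$na_slope * a + ol$old_shift * old - cut) * dnorm(a)
    }, -8, 8, rel.tol = 1e-9)$value
  })
}

# closed-form (quadrature) crude prevalence difference for the disease-free
# dimension against a favorable outcome, under a generator config
oracle_disease_outcome_difference <- function(cfg, outcome) {
  mix <- rowekahn:::latent_mixture(cfg)
  w_old <- cfg$n_old / (cfg$n_young + cfg$n_old)
  acc <- c(yd = 0, d = 0, y = 0)
  for (coh in c("young", "old")) {
    old <- coh == "old"
    w_coh <- if (old) w_old else 1 - w_old
    a <- cfg$disease_logit_intercepts[[coh]]
    for (k in seq_along(mix$mu)) {
      f_yd <- integrate(function(z) {
        plogis(a + cfg$disease_logit_slope * z) *
          oracle_p_outcome_given_z(cfg, outcome, z, old) *
          dnorm(z, mix$mu[k], cfg$latent_sd)
      }, mix$mu[k] - 8, mix$mu[k] + 8, rel.tol = 1e-8)$value
      f_d <- integrate(function(z) {
        plogis(a + cfg$disease_logit_slope * z) * dnorm(z, mix$mu[k], cfg$latent_sd)
      }, mix$mu[k] - 8, mix$mu[k] + 8, rel.tol = 1e-10)$value
      f_y <- integrate(function(z) {
        oracle_p_outcome_given_z(cfg, outcome, z, old) * dnorm(z, mix$mu[k], cfg$latent_sd)
      }, mix$mu[k] - 8, mix$mu[k] + 8, rel.tol = 1e-8)$value
      wk <- w_coh * mix$w[k]
      acc <- acc + wk * c(f_yd, f_d, f_y)
    }
  }
  100 * (acc[["yd"]] / acc[["d"]] - (acc[["y"]] - acc[["yd"]]) / (1 - acc[["d"]]))
}

# expected cohort disease-free fraction by quadrature over the latent mixture
oracle_disease_free_fraction <- function(cfg, cohort = c("young", "old")) {
  cohort <- match.arg(cohort)
  mix <- rowekahn:::latent_mixture(cfg)
  a <- cfg$disease_logit_intercepts[[cohort]]
  sum(sapply(seq_along(mix$mu), function(k) {
    mix$w[k] * integrate(function(z) {
      plogis(a + cfg$disease_logit_slope * z) * dnorm(z, mix$mu[k], cfg$latent_sd)
    }, mix$mu[k] - 8, mix$mu[k] + 8, rel.tol = 1e-10)$value
  }))
}
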