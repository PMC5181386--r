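test_that("marginal standardization on a one-predictor model is the crude difference", {
  data <- sa_analysis_data(generate_cohorts(sim_config(seed = 17)))
  adj <- adjusted_dimension_effects(data, dimensions = "disease_free", n_boot = 5, seed = 1)
  for (out in unique(adj$outcome)) {
    ok <- data$analysis & !is.na(data[[out]])
    pos <- data$disease_free[ok]
    y <- data[[out]][ok]
    crude <- prevalence_difference(sum(y & pos), sum(pos), sum(y & !pos), sum(!pos))
    expect_equal(adj$adjusted_difference[adj$outcome == out], crude$difference,
                 tolerance = 1e-6)
  }
})

test_that("adjustment separates a causal from a merely correlated dimension", {
  n <- 4000
  a <- -0.4; b <- 1.2
  sim <- withr::with_seed(123, {
    z <- rnorm(n)
    d1 <- runif(n) < plogis(1.5 * z)
    d2 <- runif(n) < plogis(1.5 * z)   # correlated with d1 through z, not causal
    y <- runif(n) < plogis(a + b * d1)
    tibble::tibble(disease_free = d1, no_disability = d2,
                   recent_good = y, for_age_good = y,
                   health_satisfied = y, life_satisfied = y,
                   analysis = TRUE)
  })
  truth <- 100 * (plogis(a + b) - plogis(a))
  adj <- adjusted_dimension_effects(sim, dimensions = c("disease_free", "no_disability"),
                                    n_boot = 50, seed = 2)
  adj <- adj[adj$outcome == "recent_good", ]
  causal <- adj[adj$dimension == "disease_free", ]
  spurious <- adj[adj$dimension == "no_disability", ]
  expect_lt(abs(causal$adjusted_difference - truth), 5)
  expect_lt(abs(spurious$adjusted_difference), abs(causal$adjusted_difference) / 3)
  expect_true(spurious$ci_low < 2.5 && spurious$ci_high > -2.5)
  # and the crude difference for the spurious dimension is NOT near zero
  ok <- TRUE
  crude2 <- prevalence_difference(sum(sim$recent_good & sim$no_disability),
                                  sum(sim$no_disability),
                                  sum(sim$recent_good & !sim$no_disability),
                                  sum(!sim$no_disability))
  expect_gt(crude2$difference, 5)
})

test_that("separation is flagged, not silently returned", {
  sim <- tibble::tibble(
    disease_free = rep(c(TRUE, FALSE), each = 20),
    recent_good = rep(c(TRUE, FALSE), each = 20),  # perfectly separated
    for_age_good = rep(c(TRUE, FALSE), each = 20),
    health_satisfied = rep(c(TRUE, FALSE), each = 20),
    life_satisfied = rep(c(TRUE, FALSE), each = 20),
    analysis = TRUE
  )
  adj <- adjusted_dimension_effects(sim, dimensions = "disease_free", n_boot = 5, seed = 3)
  expect_true(all(adj$flagged))
})

test_that("a single whole-sample stratum reproduces the unstratified analysis", {
  data <- sa_analysis_data(small_cohort(seed = 19, n_young = 200, n_old = 150))
  data$everyone <- "all"
  strat <- stratified_analysis(data, strata = "everyone")
  plain <- crude_associations(data)
  expect_equal(strat$estimates[, names(plain)], plain, ignore_attr = TRUE)
})

test_that("negative-affect halves partition the analysis sample", {
  data <- sa_analysis_data(generate_cohorts(sim_config(seed = 23)))
  d <- data[data$analysis, ]
  strat <- stratified_analysis(data, strata = "negative_affect_half")
  keep <- strat$estimates$outcome == "recent_good" &
    strat$estimates$dimension == "disease_free"
  est <- strat$estimates[keep, ]
  n_split <- sum(est$n_positive) + sum(est$n_negative)
  expect_equal(n_split, sum(!is.na(d$negative_affect_half) & !is.na(d$recent_good)))
  # ties at the median go below
  med <- median(d$negative_affect)
  expect_true(all(d$negative_affect_half[d$negative_affect == med] == "below"))
})

test_that("no systematic heterogeneity arises when effects are shared", {
  data <- sa_analysis_data(generate_cohorts(sim_config(seed = 29)))
  strat <- stratified_analysis(data, strata = "cohort")
  het <- strat$heterogeneity
  expect_equal(nrow(het), 24)  # 6 dimensions x 4 outcomes
  # under a shared-effect generator, small p-values occur at the nominal rate
  expect_lte(sum(het$p_interaction < 0.05), 6)
})

test_that("continuum frequencies partition the analysis n and rise with count", {
  data <- sa_analysis_data(generate_cohorts(sim_config(seed = 31)))
  cd <- count_distribution(data)
  for (coh in c("1952", "1932")) {
    expect_equal(sum(cd$n[cd$cohort == coh]),
                 sum(data$analysis & data$cohort == coh))
    expect_equal(sum(cd$percent[cd$cohort == coh]), 100, tolerance = 1e-9)
  }
  ct <- continuum_table(data)
  expect_equal(sum(ct$denominator[ct$outcome == "recent_good"]), sum(data$analysis))

  # favorable prevalence is nondecreasing in count on pooled replicate data
  pooled <- purrr::map_dfr(1:8, function(s) {
    continuum_table(sa_analysis_data(generate_cohorts(sim_config(seed = 300 + s))))
  })
  for (out in unique(pooled$outcome)) {
    rows <- pooled[pooled$outcome == out, ]
    agg <- vapply(0:6, function(k) {
      100 * sum(rows$numerator[rows$count == k]) / sum(rows$denominator[rows$count == k])
    }, numeric(1))
    # small slack at the sparse extremes of the count distribution
    expect_true(all(diff(agg) > -3), label = sprintf("monotone continuum for %s", out))
    expect_gt(agg[6] - agg[1], 10)
  }
})

test_that("an all-equal count collapses the continuum to one level", {
  data <- sa_analysis_data(small_cohort(seed = 37, n_young = 60, n_old = 40))
  data$count <- 6L
  ct <- continuum_table(data)
  expect_setequal(unique(ct$count), 6)
})

test_that("sensitivity sweep: default mode identical, medians most inclusive, signs stable", {
  records <- generate_cohorts(sim_config(seed = 41))
  sweep <- sensitivity_sweep(records, modes = c("published", "tertile", "median"))
  main <- crude_associations(sa_analysis_data(records))
  pub <- sweep$associations[sweep$associations$mode == "published", names(main)]
  expect_equal(as.data.frame(pub), as.data.frame(main), ignore_attr = TRUE)

  frac <- sweep$positive_fractions
  for (dim in c("no_disability", "cognitive_good", "interpersonal_good", "productive_good")) {
    for (coh in c("1952", "1932")) {
      med <- frac$percent[frac$mode == "median" & frac$dimension == dim & frac$cohort == coh]
      ter <- frac$percent[frac$mode == "tertile" & frac$dimension == dim & frac$cohort == coh]
      expect_gte(med, ter)
    }
  }
  # association signs are stable across threshold modes
  expect_true(all(sweep$associations$difference > 0))
})
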