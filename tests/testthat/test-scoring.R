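published <- function(records = small_cohort(seed = 21)) {
  derive_thresholds(standardize_physical(records), "published")
}

test_that("published thresholds carry the fixed cutoffs", {
  th <- published()
  expect_equal(th$cohorts$`1952`$opcs_cutoff, 0)
  expect_equal(th$cohorts$`1932`$opcs_cutoff, 0.5)
  expect_equal(th$cohorts$`1952`$ah4_cutoff, 41L)
  expect_equal(th$cohorts$`1932`$ah4_cutoff, 31L)
  expect_equal(th$cohorts$`1952`$productive_min, 3L)
  expect_equal(th$cohorts$`1932`$productive_min, 2L)
  expect_true(all(vapply(th$cohorts, function(x) x$interpersonal_min, integer(1)) == 3L))
})

test_that("boundary conventions: inclusive printed cutoffs, strict medians", {
  th <- published()
  expect_true(classify_no_disability(0.5, "1932", th))
  expect_false(classify_no_disability(0.1, "1952", th))
  expect_true(classify_no_disability(0, "1952", th))
  expect_true(classify_no_disability(0, "1932", th))
  expect_error(classify_no_disability(-1, "1952", th), ">= 0")

  expect_true(classify_cognitive(41, "1952", th))
  expect_false(classify_cognitive(40, "1952", th))
  expect_true(classify_cognitive(31, "1932", th))
  expect_false(classify_cognitive(30, "1932", th))

  # physical: value exactly at the median is unfavorable
  gm <- th$cohorts$`1952`$grip_median[["female"]]
  fm <- th$cohorts$`1952`$fev1_median[["female"]]
  sm <- th$cohorts$`1952`$sbp_median
  pm <- th$cohorts$`1952`$pulse_median
  expect_true(classify_physical(gm + 1, fm + 1, sm - 1, pm - 1, "1952", "female", th))
  expect_false(classify_physical(gm, fm + 1, sm - 1, pm, "1952", "female", th))  # 2 of 4
  expect_true(classify_physical(gm, fm + 1, sm - 1, pm - 1, "1952", "female", th))  # 3 of 4
})

test_that("engagement classifiers honour the per-cohort minima", {
  th <- published()
  expect_true(classify_interpersonal(TRUE, TRUE, TRUE, "1952", th))
  expect_false(classify_interpersonal(TRUE, TRUE, FALSE, "1952", th))
  expect_false(classify_interpersonal(FALSE, FALSE, FALSE, "1932", th))

  two <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_true(do.call(classify_productive, c(as.list(two), list("1932", th))))
  expect_false(do.call(classify_productive, c(as.list(two), list("1952", th))))
  five <- rep(TRUE, 5)
  expect_true(do.call(classify_productive, c(as.list(five), list("1952", th))))
  expect_true(do.call(classify_productive, c(as.list(five), list("1932", th))))
})

test_that("height standardization gives least-squares residuals per stratum", {
  base <- small_cohort(seed = 31, n_young = 30, n_old = 20)
  # exact line: residuals are zero
  rec <- base[1:3, ]
  rec$cohort <- "1952"; rec$sex <- "female"
  rec$height <- c(150, 160, 170)
  rec$grip <- c(20, 25, 30)
  std <- standardize_physical(rec)
  expect_equal(std$std_grip, c(0, 0, 0), tolerance = 1e-12)

  # constant height: residual is the measure minus the stratum mean
  rec$height <- rep(160, 3)
  std <- standardize_physical(rec)
  expect_equal(std$std_grip, rec$grip - mean(rec$grip), tolerance = 1e-12)

  # residuals average zero within every stratum
  std <- standardize_physical(base)
  for (coh in c("1952", "1932")) {
    for (sx in c("female", "male")) {
      idx <- std$cohort == coh & std$sex == sx
      expect_equal(mean(std$std_grip[idx]), 0, tolerance = 1e-10)
      expect_equal(mean(std$std_fev1[idx]), 0, tolerance = 1e-10)
    }
  }

  # too-small stratum errors naming it
  tiny <- base[base$sex == "male", ]
  lone <- base[base$sex == "female", ][1, ]
  expect_error(standardize_physical(dplyr::bind_rows(tiny, lone)), "female")
})

test_that("derived cutoffs pick the grid point closest to the nominal fraction", {
  rec <- small_cohort(seed = 41, n_young = 200, n_old = 140)
  # symmetric integer grid: the median-mode cutoff classifies exactly half
  rec$ah4_score <- rep(1:10, length.out = nrow(rec))
  th <- derive_thresholds(rec, "median")
  for (coh in c("1952", "1932")) {
    scores <- rec$ah4_score[rec$cohort == coh]
    expect_equal(mean(scores >= th$cohorts[[coh]]$ah4_cutoff), 0.5)
  }

  # zero-inflated disability: tertile cutoff sticks at 0 when the zero mass
  # already exceeds a third
  rec2 <- small_cohort(seed = 42, n_young = 400, n_old = 140)
  young <- rec2$cohort == "1952"
  zeroed <- sample(which(young), round(0.81 * sum(young)))
  rec2$opcs_score[zeroed] <- 0
  rec2$opcs_score[setdiff(which(young), zeroed)] <- 0.5 + rec2$opcs_score[setdiff(which(young), zeroed)]
  th2 <- derive_thresholds(rec2, "tertile")
  expect_equal(th2$cohorts$`1952`$opcs_cutoff, 0)
  # brute-force argmin over every candidate cutoff agrees
  scores <- rec2$opcs_score[young]
  cand <- sort(unique(scores))
  frac <- sapply(cand, function(v) mean(scores <= v))
  expect_equal(mean(scores <= th2$cohorts$`1952`$opcs_cutoff),
               frac[which.min(abs(frac - 1 / 3))])
})

test_that("derived tertile minima reproduce the published engagement cutoffs", {
  rec <- generate_cohorts(sim_config(seed = 7))
  th <- derive_thresholds(rec, "tertile")
  expect_equal(th$cohorts$`1952`$interpersonal_min, 3L)
  expect_equal(th$cohorts$`1932`$interpersonal_min, 3L)
  expect_equal(th$cohorts$`1952`$productive_min, 3L)
  expect_equal(th$cohorts$`1932`$productive_min, 2L)
})

test_that("profiles satisfy the count and all-six identities", {
  for (seed in c(51, 52)) {
    records <- inject_missingness(small_cohort(seed = seed), 0.05, seed = seed)
    scored <- score_cohort(records)
    p <- scored$profiles
    m <- as.matrix(p[, c("disease_free", "no_disability", "physical_good",
                         "cognitive_good", "interpersonal_good", "productive_good")])
    complete <- !apply(m, 1, anyNA)
    expect_equal(p$count[complete], rowSums(m[complete, , drop = FALSE]),
                 ignore_attr = TRUE)
    expect_true(all(is.na(p$count[!complete])))
    expect_identical(p$all_six, p$count == 6L)
    expect_true(all(p$count[complete] >= 0 & p$count[complete] <= 6))
  }
})

test_that("a missing component makes the dimension and count missing", {
  records <- small_cohort(seed = 61, n_young = 40, n_old = 30)
  records$ah4_score[1] <- NA
  records$contact_4wk[2] <- NA
  records$pulse[3] <- NA
  scored <- score_cohort(records)
  p <- scored$profiles
  expect_true(is.na(p$cognitive_good[1]) && is.na(p$count[1]) && is.na(p$all_six[1]))
  expect_true(is.na(p$interpersonal_good[2]) && is.na(p$count[2]))
  expect_true(is.na(p$physical_good[3]) && is.na(p$count[3]))
  expect_false(anyNA(p$count[4:10]))
})

test_that("classification is invariant to record order", {
  records <- small_cohort(seed = 71)
  scored <- score_cohort(records)
  perm <- withr::with_seed(1, sample.int(nrow(records)))
  scored_perm <- score_cohort(records[perm, ])
  expect_equal(as.data.frame(scored_perm$profiles),
               as.data.frame(scored$profiles[perm, ]), ignore_attr = TRUE)
})

test_that("positive sets nest: quintile within quartile within tertile within median", {
  records <- small_cohort(seed = 81, n_young = 250, n_old = 180)
  profs <- lapply(c("quintile", "quartile", "tertile", "median"), function(mode) {
    score_cohort(records, mode = mode)$profiles
  })
  names(profs) <- c("quintile", "quartile", "tertile", "median")
  for (dim in c("no_disability", "cognitive_good", "interpersonal_good", "productive_good")) {
    for (pair in list(c("quintile", "quartile"), c("quartile", "tertile"),
                      c("tertile", "median"))) {
      narrow <- profs[[pair[1]]][[dim]]
      wide <- profs[[pair[2]]][[dim]]
      expect_true(all(!narrow | wide),
                  label = sprintf("%s: %s positives inside %s", dim, pair[1], pair[2]))
    }
  }
})

test_that("profiles agree with a brute-force restatement of the rules", {
  for (seed in c(91, 92, 93)) {
    pool <- small_cohort(seed = seed, n_young = 300, n_old = 200)
    # three records per sex-by-cohort stratum so standardization is defined
    idx <- unlist(lapply(c("1952", "1932"), function(coh) {
      lapply(c("female", "male"), function(sx) {
        which(pool$cohort == coh & pool$sex == sx)[1:3]
      })
    }))
    records <- pool[idx, ]
    scored <- score_cohort(records, mode = "published")
    expect_equal(as.data.frame(scored$profiles),
                 oracle_profiles(records), ignore_attr = TRUE)
  }
})
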