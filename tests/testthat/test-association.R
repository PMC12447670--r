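test_that("unadjusted logistic OR equals the 2x2 cross-product ratio", {
  fx <- association_fixture(30, 30, 15, 45)
  eff <- fit_gain_logistic(fx$dataset, "sym", fx$shifts,
                           covariates = "exposed")
  expect_equal(eff$estimate, 3.0, tolerance = 1e-6)  # (30*45)/(30*15)
  expect_equal(eff$scale, "odds_ratio")
  expect_lt(eff$ci_low, 3)
  expect_gt(eff$ci_high, 3)
  expect_equal(eff$n_used, 120)
})

test_that("separation and constant indicators are explicit failures", {
  fx <- association_fixture(30, 0, 0, 30)   # exposure == gain exactly
  expect_error(
    fit_gain_logistic(fx$dataset, "sym", fx$shifts, covariates = "exposed"),
    "separation|non-convergence")
  all_gain <- association_fixture(30, 0, 30, 0)
  expect_error(
    fit_gain_logistic(all_gain$dataset, "sym", all_gain$shifts,
                      covariates = "exposed"),
    "constant")
})

test_that("unadjusted mean difference equals the raw group difference", {
  fx <- association_fixture()
  set.seed(12)
  fx$dataset$covariates$final_sym <- rnorm(120, 8, 2) - 2 * fx$gained
  eff <- fit_final_score_model(fx$dataset, "sym", fx$shifts,
                               covariates = "exposed")
  un <- eff[eff$model == "unadjusted", ]
  grp <- split(fx$dataset$covariates$final_sym, fx$gained)
  expect_equal(un$estimate, mean(grp[[2]]) - mean(grp[[1]]))
  # Cohen's D consistent with its own formula on the group statistics
  pooled <- cohens_d(un$estimate,
                     vapply(grp, sd, numeric(1))[c(2, 1)],
                     vapply(grp, length, integer(1))[c(2, 1)])
  expect_equal(un$d, pooled$d)
})

test_that("zero-noise equal outcomes give a degenerate null difference", {
  fx <- association_fixture()
  fx$dataset$covariates$final_sym <- rep(7, 120)
  eff <- suppressWarnings(
    fit_final_score_model(fx$dataset, "sym", fx$shifts,
                          covariates = "exposed"))
  un <- eff[eff$model == "unadjusted", ]
  expect_equal(un$estimate, 0)
  expect_equal(un$ci_low, 0)
  expect_equal(un$ci_high, 0)
})

test_that("a single-participant gain group is insufficient data", {
  fx <- association_fixture(1, 59, 0, 60)
  fx$dataset$covariates$final_sym <- rnorm(120, 8, 2)
  expect_error(
    fit_final_score_model(fx$dataset, "sym", fx$shifts,
                          covariates = "exposed"),
    "insufficient data")
})

test_that("follow-up equal to baseline leaves no room for a gain effect", {
  fx <- association_fixture()
  set.seed(13)
  fx$dataset$covariates$baseline_sdq_total <- round(runif(120, 5, 35))
  fx$dataset$covariates$sdq_total_6m <-
    fx$dataset$covariates$baseline_sdq_total
  eff <- suppressWarnings(
    fit_followup_model(fx$dataset, "sym", fx$shifts,
                       covariates = character(0)))
  adj <- eff[eff$model == "adjusted", ]
  expect_equal(adj$estimate, 0, tolerance = 1e-8)
})

test_that("missing follow-up outcomes are excluded or fatal when total", {
  fx <- association_fixture()
  fx$dataset$covariates$baseline_sdq_total <- round(runif(120, 5, 35))
  fx$dataset$covariates$sdq_total_6m <- NA_real_
  expect_error(
    fit_followup_model(fx$dataset, "sym", fx$shifts,
                       covariates = character(0)),
    "insufficient data")
})

test_that("Cohen's D follows its closed form", {
  expect_equal(cohens_d(1, c(2, 2), c(50, 50))$d, 0.5)
  expect_equal(cohens_d(0, c(2, 3), c(10, 10))$d, 0)
  expect_equal(cohens_d(-1, c(2, 2), c(50, 50))$d, -0.5)
  expect_error(cohens_d(1, c(0, 0), c(10, 10)), "undefined")
})

test_that("null-effect logistic CI covers one at its nominal rate", {
  set.seed(2024)
  n_rep <- 200
  n <- 2000
  ids <- sprintf("P%04d", seq_len(n))
  sc <- tibble::tibble(participant_id = ids, measure = "sym",
                       session = 1L, score = 10)
  covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    x <- rbinom(n, 1, 0.5)
    gained <- rbinom(n, 1, 0.35) == 1   # independent of x: true OR = 1
    ds <- cohort_dataset(list(sym = spec_lower()),
                         make_covariates(ids, exposed = x), sc)
    shifts <- tibble::tibble(
      participant_id = ids[gained], measure = "sym", kind = "gain",
      pregain_session = 3L, shift_session = 4L, magnitude = 5,
      n_pre = 3L, n_post = 3L, reversed = FALSE,
      reversal_session = NA_integer_)
    eff <- fit_gain_logistic(ds, "sym", shifts, covariates = "exposed")
    covered[r] <- eff$ci_low <= 1 && 1 <= eff$ci_high
  }
  expect_gt(mean(covered), 0.90)
  expect_lt(mean(covered), 0.99)
})

test_that("associate_cohort collects effects and notes failures", {
  set.seed(99)
  sim <- simulate_cohort(simulation_config(n_participants = 120), seed = 99)
  el <- apply_eligibility(sim$dataset)
  sh <- detect_cohort(el$dataset)
  eff <- associate_cohort(el$dataset, sh)
  expect_true(all(c("gain_predictors", "final_score", "followup_6m") %in%
                    eff$model_family))
  ok <- eff[is.na(eff$note), ]
  expect_true(all(ok$ci_low <= ok$estimate & ok$estimate <= ok$ci_high))
  expect_true(all(ok$p >= 0 & ok$p <= 1, na.rm = TRUE))
  expect_true(all(ok$estimate[ok$scale == "odds_ratio"] > 0))
})
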