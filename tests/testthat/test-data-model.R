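measures_fix <- function() {
  list(sym = measure_spec("sym", "lower_better", 0, 20,
                          criterion1_cutoff = 2))
}

dense_scores <- function(ids = c("A", "B"), t = 6) {
  dplyr::bind_rows(lapply(ids, function(p) {
    tibble::tibble(participant_id = p, measure = "sym",
                   session = seq_len(t), score = rep(10, t))
  }))
}

test_that("direct ingestion yields one full series per participant", {
  paths <- write_fixture_files(dense_scores(), make_covariates(c("A", "B")),
                               measures_fix())
  ds <- load_cohort(paths$scores, paths$covariates, paths$measures)
  expect_length(get_series(ds, "A", "sym"), 6)
  expect_length(get_series(ds, "B", "sym"), 6)
  expect_false(anyNA(ds$scores$score))
})

test_that("session gaps are preserved, not renumbered", {
  sc <- tibble::tibble(participant_id = "A", measure = "sym",
                       session = c(1, 2, 4, 5, 6, 7), score = 8)
  paths <- write_fixture_files(sc, make_covariates("A"), measures_fix())
  ds <- load_cohort(paths$scores, paths$covariates, paths$measures)
  x <- get_series(ds, "A", "sym")
  expect_length(x, 7)
  expect_true(is.na(x[3]))
  expect_equal(sum(!is.na(x)), 6)
})

test_that("out-of-bounds scores and duplicates are rejected with detail", {
  m10 <- list(g = measure_spec("g", "higher_better", 1, 10,
                               criterion1_cutoff = 2))
  sc <- tibble::tibble(participant_id = "A", measure = "g",
                       session = 1:3, score = c(5, 12, 6))
  expect_error(cohort_dataset(m10, make_covariates("A"), sc),
               "outside \\[1, 10\\].*session 2")
  dup <- tibble::tibble(participant_id = "A", measure = "sym",
                        session = c(1, 1), score = c(5, 6))
  expect_error(cohort_dataset(measures_fix(), make_covariates("A"), dup),
               "duplicate")
  bad <- tibble::tibble(participant_id = "A", measure = "nope",
                        session = 1, score = 5)
  expect_error(cohort_dataset(measures_fix(), make_covariates("A"), bad),
               "nope")
})

test_that("ingestion then serialisation round-trips byte-identically", {
  paths <- write_fixture_files(dense_scores(), make_covariates(c("A", "B")),
                               measures_fix())
  ds <- load_cohort(paths$scores, paths$covariates, paths$measures)
  out_scores <- tempfile(fileext = ".csv")
  out_cov <- tempfile(fileext = ".csv")
  write_cohort(ds, out_scores, out_cov)
  ds2 <- load_cohort(out_scores, out_cov, measures_fix())
  out_scores2 <- tempfile(fileext = ".csv")
  out_cov2 <- tempfile(fileext = ".csv")
  write_cohort(ds2, out_scores2, out_cov2)
  expect_identical(readBin(out_scores, "raw", file.size(out_scores)),
                   readBin(out_scores2, "raw", file.size(out_scores2)))
  expect_identical(readBin(out_cov, "raw", file.size(out_cov)),
                   readBin(out_cov2, "raw", file.size(out_cov2)))
})

eligibility_fixture <- function(n_thin = 0, n_total = 25) {
  ids <- sprintf("P%02d", seq_len(n_total))
  total_sessions <- rep(10L, n_total)
  total_sessions[1] <- 5L                       # under the session minimum
  sc <- dplyr::bind_rows(lapply(seq_along(ids), function(i) {
    score <- rep(10, 8)
    if (i >= 2 && i <= 1 + n_thin) score[2:8] <- NA  # single response
    tibble::tibble(participant_id = ids[i], measure = "sym",
                   session = 1:8, score = score)
  }))
  cohort_dataset(measures_fix(),
                 make_covariates(ids, total_sessions = total_sessions), sc)
}

test_that("eligibility removes short treatment, thin series, small measures", {
  ds <- eligibility_fixture(n_thin = 2)
  res <- apply_eligibility(ds)
  expect_false("P01" %in% res$dataset$covariates$participant_id)
  expect_true(any(res$exclusions$reason == "fewer than minimum sessions" &
                    res$exclusions$participant_id == "P01"))
  # thin series dropped for the measure but participants not excluded
  expect_true(all(c("P02", "P03") %in% res$dataset$covariates$participant_id))
  expect_false(any(res$dataset$scores$participant_id %in% c("P02", "P03")))
  expect_equal(sum(res$exclusions$reason ==
                     "fewer than minimum responses on measure"), 2)
  # 25 - 1 short - 2 thin = 22 >= 21, measure retained
  expect_true("sym" %in% names(res$dataset$measures))
})

test_that("the >20 participants rule is a strict inequality", {
  # 25 total - 1 short - 4 thin = 20 retained -> measure dropped
  res20 <- apply_eligibility(eligibility_fixture(n_thin = 4))
  expect_false("sym" %in% names(res20$dataset$measures))
  expect_true(any(res20$exclusions$reason ==
                    "measure below minimum participants"))
  # 25 - 1 - 3 = 21 retained -> kept
  res21 <- apply_eligibility(eligibility_fixture(n_thin = 3))
  expect_true("sym" %in% names(res21$dataset$measures))
})

test_that("eligibility is idempotent and conserves participants", {
  ds <- eligibility_fixture(n_thin = 2)
  once <- apply_eligibility(ds)
  twice <- apply_eligibility(once$dataset)
  expect_identical(once$dataset$scores, twice$dataset$scores)
  expect_identical(once$dataset$covariates, twice$dataset$covariates)
  expect_equal(nrow(twice$exclusions), 0)
  excluded_people <- unique(once$exclusions$participant_id[
    is.na(once$exclusions$measure)])
  expect_equal(nrow(once$dataset$covariates) + length(excluded_people),
               nrow(ds$covariates))
})

test_that("withdrawals are excluded with their own reason", {
  ids <- c("A", "B", "C")
  cov <- make_covariates(ids, total_sessions = 10L,
                         withdrew = c(0L, 1L, 0L))
  sc <- dplyr::bind_rows(lapply(ids, function(p) {
    tibble::tibble(participant_id = p, measure = "sym", session = 1:8,
                   score = 10)
  }))
  ds <- cohort_dataset(measures_fix(), cov, sc)
  res <- apply_eligibility(
    ds, eligibility_config(min_participants_per_measure = 1))
  expect_false("B" %in% res$dataset$covariates$participant_id)
  expect_equal(res$exclusions$reason[res$exclusions$participant_id == "B"],
               "withdrew consent")
})
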