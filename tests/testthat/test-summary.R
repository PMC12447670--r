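summary_fixture <- function() {
  series <- list(P1 = rep(10, 8), P2 = rep(10, 8), P3 = rep(10, 8))
  make_dataset(series)
}

test_that("summary row matches a hand count", {
  ds <- summary_fixture()
  shifts <- dplyr::bind_rows(
    shift_row("P1", pregain = 3, magnitude = 4),
    shift_row("P2", pregain = 2, magnitude = 5, reversed = TRUE,
              reversal_session = 6),
    shift_row("P2", pregain = 5, magnitude = 3))
  s <- summarize_measure(ds, shifts, "sym")
  expect_equal(s$n_participants, 3)
  expect_equal(s$total_shifts, 3)
  expect_equal(s$occurrence_n, 2)
  expect_equal(s$occurrence_pct, 66.67)
  expect_equal(s$multiple_n, 1)
  expect_equal(s$multiple_pct, 33.33)
  expect_equal(s$magnitude_mean, 4)           # mean(4, 5, 3)
  expect_equal(s$magnitude_sd, 1)
  expect_equal(s$reversal_n, 1)
  expect_equal(s$reversal_pct, 50)
  expect_equal(s$n_intervals_analyzed, 3 * 7)
  # first-gain sessions: P1 shift 4, P2 shift 3 -> tie, both reported
  expect_equal(s$modal_first_shift_session[[1]], c(3L, 4L))
  expect_equal(s$modal_first_pregain_session[[1]], c(2L, 3L))
})

test_that("reversal basis first vs any can differ", {
  ds <- summary_fixture()
  shifts <- dplyr::bind_rows(
    shift_row("P2", pregain = 2, magnitude = 5),
    shift_row("P2", pregain = 5, magnitude = 3, reversed = TRUE,
              reversal_session = 8))
  s_any <- summarize_measure(ds, shifts, "sym", reversal_basis = "any")
  s_first <- summarize_measure(ds, shifts, "sym", reversal_basis = "first")
  expect_equal(s_any$reversal_n, 1)
  expect_equal(s_first$reversal_n, 0)
})

test_that("degenerate summaries: no gains, single gain", {
  ds <- summary_fixture()
  none <- shift_row("P1")[0, ]
  s0 <- summarize_measure(ds, none, "sym")
  expect_equal(s0$occurrence_n, 0)
  expect_equal(s0$occurrence_pct, 0)
  expect_true(is.na(s0$magnitude_mean))
  expect_true(is.na(s0$reversal_pct))
  s1 <- summarize_measure(ds, shift_row("P1", magnitude = 5), "sym")
  expect_equal(s1$magnitude_mean, 5)
  expect_true(is.na(s1$magnitude_sd))
  expect_error(summarize_measure(ds, none, "ghost"), "ghost")
})

test_that("summary recomputes exactly from the raw shift list", {
  set.seed(77)
  sim <- simulate_cohort(simulation_config(n_participants = 60), seed = 77)
  el <- apply_eligibility(sim$dataset)
  sh <- detect_cohort(el$dataset)
  s <- summarize_cohort(el$dataset, sh)
  for (i in seq_len(nrow(s))) {
    m <- s$measure[i]
    g <- sh[sh$measure == m & sh$kind == "gain", ]
    expect_equal(s$total_shifts[i], nrow(g))
    expect_equal(s$occurrence_n[i], length(unique(g$participant_id)))
    if (nrow(g)) {
      expect_gte(s$magnitude_mean[i], min(g$magnitude))
      expect_lte(s$magnitude_mean[i], max(g$magnitude))
      expect_equal(s$occurrence_pct[i],
                   round(100 * s$occurrence_n[i] / s$n_participants[i], 2))
    }
  }
})

test_that("gain-count bands partition the cohort", {
  ds <- summary_fixture()
  shifts <- dplyr::bind_rows(
    shift_row("P2", pregain = 2), shift_row("P2", pregain = 5),
    shift_row("P3", pregain = 2), shift_row("P3", pregain = 4),
    shift_row("P3", pregain = 6), shift_row("P3", pregain = 7))
  d <- gain_count_distribution(shifts, ds)
  expect_equal(sort(d$counts$n_gains), c(0L, 2L, 4L))
  expect_equal(d$bands$pct[d$bands$band == "2-4"], 66.67)
  expect_equal(sum(d$bands$n), 3)
  expect_equal(sum(d$bands$pct), 100, tolerance = 0.02)
  # all-zero and single-gain degenerate cases
  d0 <- gain_count_distribution(shift_row("P1")[0, ], ds)
  expect_equal(d0$bands$pct[d0$bands$band == "0"], 100)
  ds1 <- make_dataset(list(P1 = rep(10, 8)))
  d1 <- gain_count_distribution(shift_row("P1"), ds1)
  expect_equal(d1$bands$pct[d1$bands$band == "1"], 100)
})

test_that("trajectory profile aligns gains at the pregain session", {
  ds <- make_dataset(list(P1 = c(10, 10, 10, 5, 5, 5)))
  sh <- detect_shifts(list(participant_id = "P1", measure = "sym",
                           scores = c(10, 10, 10, 5, 5, 5)),
                      spec_lower())
  prof <- trajectory_profile(ds, sh, "sym")
  expect_equal(prof$mean_score, c(10, 10, 10, 5, 5, 5))
  expect_equal(prof$n, rep(1L, 6))
  expect_equal(prof$position, c("N-2", "N-1", "N", "N+1", "N+2", "N+3"))
  # two identical gains average to the same profile with n = 2
  ds2 <- make_dataset(list(P1 = c(10, 10, 10, 5, 5, 5),
                           P2 = c(10, 10, 10, 5, 5, 5)))
  sh2 <- detect_cohort(ds2, kinds = "gain")
  prof2 <- trajectory_profile(ds2, sh2, "sym")
  expect_equal(prof2$mean_score, prof$mean_score)
  expect_equal(prof2$n, rep(2L, 6))
  # a gain whose window leaves the series contributes nothing at the edge
  ds3 <- make_dataset(list(P1 = c(10, 10, 10, 10, 10, 4, 4)))
  sh3 <- detect_cohort(ds3, kinds = "gain")
  prof3 <- trajectory_profile(ds3, sh3, "sym")
  expect_equal(prof3$n[prof3$offset == 3], 0L)   # N+3 beyond the series
  expect_equal(nrow(trajectory_profile(ds, sh[0, ], "sym")), 0)
})
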