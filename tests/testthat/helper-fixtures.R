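# shared fixture builders; everything is generated in code at test time

spec_lower <- function(cutoff = 2, scale_max = 20) {
  measure_spec("sym", "lower_better", 0, scale_max,
               criterion1_cutoff = cutoff)
}

spec_higher <- function(cutoff = 2, scale_max = 10) {
  measure_spec("goal", "higher_better", 0, scale_max,
               criterion1_cutoff = cutoff)
}

# minimal covariate row(s); extra columns appended via ...
make_covariates <- function(ids, total_sessions = 10L, ...) {
  tibble::tibble(participant_id = ids, total_sessions = total_sessions, ...)
}

# dataset with one lower-better measure and the given named score vectors
make_dataset <- function(series_list, spec = spec_lower(),
                         covariates = NULL) {
  scores <- dplyr::bind_rows(lapply(names(series_list), function(p) {
    x <- series_list[[p]]
    tibble::tibble(participant_id = p, measure = spec$name,
                   session = seq_along(x), score = x)
  }))
  if (is.null(covariates)) {
    covariates <- make_covariates(names(series_list))
  }
  cohort_dataset(stats::setNames(list(spec), spec$name), covariates, scores)
}

# hand-written shifts table for summary tests
shift_row <- function(pid, measure = "sym", kind = "gain", pregain = 3,
                      magnitude = 5, reversed = FALSE,
                      reversal_session = NA_integer_) {
  tibble::tibble(participant_id = pid, measure = measure, kind = kind,
                 pregain_session = as.integer(pregain),
                 shift_session = as.integer(pregain + 1),
                 magnitude = magnitude, n_pre = 3L, n_post = 3L,
                 reversed = reversed,
                 reversal_session = as.integer(reversal_session))
}

# dataset where gain status is dictated by a hand-written shifts table;
# group sizes follow a 2x2 exposure-by-gain layout
association_fixture <- function(n_exposed_gain = 30, n_exposed_none = 30,
                                n_unexposed_gain = 15, n_unexposed_none = 45) {
  n <- n_exposed_gain + n_exposed_none + n_unexposed_gain + n_unexposed_none
  ids <- sprintf("P%03d", seq_len(n))
  exposed <- rep(c(1L, 1L, 0L, 0L),
                 c(n_exposed_gain, n_exposed_none,
                   n_unexposed_gain, n_unexposed_none))
  gained <- rep(c(1L, 0L, 1L, 0L),
                c(n_exposed_gain, n_exposed_none,
                  n_unexposed_gain, n_unexposed_none))
  cov <- make_covariates(ids, total_sessions = 10L, exposed = exposed)
  sc <- tibble::tibble(participant_id = rep(ids, each = 2),
                       measure = "sym",
                       session = rep(1:2, n), score = 10)
  ds <- cohort_dataset(list(sym = spec_lower()), cov, sc)
  shifts <- dplyr::bind_rows(lapply(ids[gained == 1], shift_row))
  list(dataset = ds, shifts = shifts, gained = gained)
}

# write a cohort's CSV fixtures into a temp dir; returns the paths
write_fixture_files <- function(scores, covariates, measures, dir = tempfile()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(scores = file.path(dir, "scores.csv"),
                covariates = file.path(dir, "covariates.csv"),
                measures = file.path(dir, "measures.json"))
  utils::write.csv(scores, paths$scores, row.names = FALSE, na = "")
  utils::write.csv(covariates, paths$covariates, row.names = FALSE, na = "")
  write_measure_config(measures, paths$measures)
  paths
}
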