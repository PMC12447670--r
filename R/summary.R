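modal_values <- function(x) {
  if (!length(x)) return(integer(0))
  tab <- table(x)
  sort(as.integer(names(tab)[tab == max(tab)]))
}

#' Summarise detected shifts on one measure
#'
#' Builds the cohort-level summary row for a measure: number of participants
#' analysed, evaluable session intervals, total shifts, occurrence rate,
#' modal session of the first shift, proportion with multiple shifts,
#' magnitude mean and SD pooled over all shifts, and the reversal rate among
#' participants who shifted. Because "the session a gain occurred in" is
#' reported under two conventions in this literature, both the modal first
#' *shift* session (N+1) and the modal first *pregain* session (N) are
#' returned; modal ties are reported in full, smallest first.
#'
#' @param dataset The (eligible) [cohort_dataset()].
#' @param shifts Tibble from [detect_cohort()].
#' @param measure Measure name.
#' @param kind `"gain"` (default) or `"loss"`.
#' @param config [detection_config()] used for interval counting.
#' @param stability_evaluable Restrict the interval denominator to intervals
#'   whose stability windows are also evaluable; default `FALSE` (both
#'   endpoints observed).
#' @param reversal_basis `"any"` (default): a participant counts as reversed
#'   when any of their shifts reversed; `"first"`: only when the first did.
#' @return One-row tibble. `modal_first_shift_session` and
#'   `modal_first_pregain_session` are list-columns holding the full tie
#'   sets; percentages are rounded to 2 decimals. Magnitude statistics are
#'   `NA` when undefined (no shifts; SD with a single shift).
#' @export
summarize_measure <- function(dataset, shifts, measure, kind = "gain",
                              config = detection_config(),
                              stability_evaluable = FALSE,
                              reversal_basis = c("any", "first")) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  reversal_basis <- match.arg(reversal_basis)
  if (!measure %in% names(dataset$measures)) {
    stop("measure '", measure, "' not present in dataset")
  }
  sc <- dataset$scores[dataset$scores$measure == measure, ]
  sl <- split(sc$score, factor(sc$participant_id,
                               levels = unique(sc$participant_id)))
  n_participants <- length(sl)
  n_intervals <- sum(vapply(sl, function(x) {
    count_intervals(x, config, stability_evaluable)
  }, integer(1)))

  sh <- shifts[shifts$measure == measure & shifts$kind == kind, ]
  gainers <- unique(sh$participant_id)
  occurrence_n <- length(gainers)
  per <- if (nrow(sh)) {
    dplyr::summarise(
      dplyr::group_by(sh, .data$participant_id),
      n_shifts = dplyr::n(),
      first_pregain = min(.data$pregain_session),
      first_shift = min(.data$shift_session),
      first_reversed = .data$reversed[[which.min(.data$pregain_session)]],
      any_reversed = any(.data$reversed),
      .groups = "drop")
  } else {
    tibble::tibble(participant_id = character(0), n_shifts = integer(0),
                   first_pregain = integer(0), first_shift = integer(0),
                   first_reversed = logical(0), any_reversed = logical(0))
  }

  pct <- function(num, den) if (den > 0) round(100 * num / den, 2) else NA_real_
  multiple_n <- sum(per$n_shifts >= 2)
  reversal_n <- if (reversal_basis == "any") {
    sum(per$any_reversed)
  } else {
    sum(per$first_reversed)
  }
  tibble::tibble(
    measure = measure, kind = kind,
    n_participants = n_participants,
    n_intervals_analyzed = n_intervals,
    total_shifts = nrow(sh),
    occurrence_n = occurrence_n,
    occurrence_pct = pct(occurrence_n, n_participants),
    modal_first_shift_session = list(modal_values(per$first_shift)),
    modal_first_pregain_session = list(modal_values(per$first_pregain)),
    multiple_n = multiple_n,
    multiple_pct = pct(multiple_n, n_participants),
    magnitude_mean = if (nrow(sh)) round(mean(sh$magnitude), 2) else NA_real_,
    magnitude_sd = if (nrow(sh) > 1) round(sd(sh$magnitude), 2) else NA_real_,
    reversal_n = reversal_n,
    reversal_pct = pct(reversal_n, occurrence_n))
}

#' Summarise all measures of a cohort
#'
#' @inheritParams summarize_measure
#' @return Tibble with one [summarize_measure()] row per measure in the
#'   dataset.
#' @export
summarize_cohort <- function(dataset, shifts, kind = "gain",
                             config = detection_config(),
                             stability_evaluable = FALSE,
                             reversal_basis = "any") {
  dplyr::bind_rows(lapply(names(dataset$measures), function(m) {
    summarize_measure(dataset, shifts, m, kind, config,
                      stability_evaluable, reversal_basis)
  }))
}

#' Flatten a summary table for CSV export
#'
#' Collapses the modal-session list-columns into `/`-separated strings.
#'
#' @param summary Tibble from [summarize_cohort()].
#' @return Plain tibble safe for [utils::write.csv()].
#' @export
flatten_summary <- function(summary) {
  for (col in c("modal_first_shift_session", "modal_first_pregain_session")) {
    if (is.list(summary[[col]])) {
      summary[[col]] <- vapply(summary[[col]], function(v) {
        if (!length(v)) NA_character_ else paste(v, collapse = "/")
      }, character(1))
    }
  }
  summary
}

#' Per-participant gain counts pooled across measures
#'
#' Counts each eligible participant's sudden gains across all measures and
#' bands the cohort into \{0, 1, 2--4, 5+\} gains; band shares sum to 100%.
#'
#' @param shifts Tibble from [detect_cohort()].
#' @param dataset The (eligible) [cohort_dataset()]; its covariate table
#'   defines the participant denominator (participants with no gain count in
#'   the 0 band).
#' @return List with `counts` (tibble `participant_id`, `n_gains`) and
#'   `bands` (tibble `band`, `n`, `pct`).
#' @export
gain_count_distribution <- function(shifts, dataset) {
  pids <- dataset$covariates$participant_id
  g <- shifts[shifts$kind == "gain", ]
  counts <- tibble::tibble(
    participant_id = pids,
    n_gains = vapply(pids, function(p) sum(g$participant_id == p),
                     integer(1), USE.NAMES = FALSE))
  band <- cut(counts$n_gains, breaks = c(-Inf, 0, 1, 4, Inf),
              labels = c("0", "1", "2-4", "5+"))
  tab <- table(band)
  bands <- tibble::tibble(
    band = names(tab), n = as.integer(tab),
    pct = round(100 * as.integer(tab) / max(1L, length(pids)), 2))
  list(counts = counts, bands = bands)
}

#' Mean trajectory around the pregain session
#'
#' Aligns every detected gain on a measure at its pregain session N and
#' averages the observed scores at relative positions N-2 .. N+3 (N+1 is the
#' session the gain occurred in). Offsets falling outside a series, or on a
#' missing session, contribute nothing to that position's n.
#'
#' @param dataset The [cohort_dataset()].
#' @param shifts Tibble from [detect_cohort()].
#' @param measure Measure name.
#' @param offsets Relative positions; default `-2:3` (N-2 .. N+3).
#' @param kind `"gain"` (default) or `"loss"`.
#' @return Tibble `offset`, `position` (label relative to N), `mean_score`,
#'   `n`; zero rows when there are no shifts.
#' @export
trajectory_profile <- function(dataset, shifts, measure, offsets = -2:3,
                               kind = "gain") {
  sh <- shifts[shifts$measure == measure & shifts$kind == kind, ]
  if (!nrow(sh)) {
    return(tibble::tibble(offset = integer(0), position = character(0),
                          mean_score = numeric(0), n = integer(0)))
  }
  sc <- dataset$scores[dataset$scores$measure == measure, ]
  sl <- split(sc$score, factor(sc$participant_id,
                               levels = unique(sc$participant_id)))
  acc <- lapply(offsets, function(o) numeric(0))
  names(acc) <- as.character(offsets)
  for (i in seq_len(nrow(sh))) {
    x <- sl[[sh$participant_id[i]]]
    for (o in offsets) {
      idx <- sh$pregain_session[i] + o
      if (idx >= 1L && idx <= length(x) && !is.na(x[idx])) {
        acc[[as.character(o)]] <- c(acc[[as.character(o)]], x[idx])
      }
    }
  }
  lab <- function(o) if (o == 0) "N" else sprintf("N%+d", o)
  tibble::tibble(
    offset = as.integer(offsets),
    position = vapply(offsets, lab, character(1)),
    mean_score = unname(vapply(acc, function(v) {
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))),
    n = unname(vapply(acc, length, integer(1))))
}
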