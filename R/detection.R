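#' Detection configuration for sudden gains and losses
#'
#' Controls the stability (criterion-three) windows and critical values. The
#' candidate interval is (N, N+1); the pre-window is sessions
#' \{N-2, N-1, N\} and the post-window \{N+1, N+2, N+3\}, clipped to the
#' series. A pooled two-sample t statistic compares the window means, and is
#' judged against a critical value that adapts to how many of the (up to)
#' three scores per side were actually observed: 2.776 with three per side
#' (df 4), 3.182 with one score missing on one side (df 3), and 4.303 with
#' one missing on each side (df 2) -- the two-sided 5% t quantiles. Intervals
#' with fewer than `min_per_side` observed scores on either side are not
#' evaluable and are excluded from the denominator of analysed intervals
#' rather than counted as non-gains.
#'
#' @param window Sessions per side of the candidate interval; default 3.
#' @param min_per_side Minimum observed scores per side; default 2.
#' @param stability_critical Named numeric vector of critical t values keyed
#'   `"<n_pre>_<n_post>"`.
#' @param zero_variance_rule How to judge a window pair with zero pooled
#'   variance: `"pass_if_mean_diff_positive"` (the t statistic diverges, so
#'   any nonzero mean change in the candidate direction is significant; no
#'   change never is).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(window = 3L, min_per_side = 2L,
                             stability_critical = c("3_3" = 2.776,
                                                    "3_2" = 3.182,
                                                    "2_3" = 3.182,
                                                    "2_2" = 4.303),
                             zero_variance_rule = "pass_if_mean_diff_positive") {
  if (min_per_side < 2L || min_per_side > window) {
    stop("min_per_side must lie in [2, window]")
  }
  if (any(stability_critical <= 0)) stop("critical t values must be positive")
  zero_variance_rule <- match.arg(zero_variance_rule,
                                  "pass_if_mean_diff_positive")
  structure(list(window = as.integer(window),
                 min_per_side = as.integer(min_per_side),
                 stability_critical = stability_critical,
                 zero_variance_rule = zero_variance_rule),
            class = "detection_config")
}

# split a (sorted, dense) long score table into per-series score vectors,
# keyed "participant\rmeasure"
split_series <- function(scores) {
  key <- paste(scores$participant_id, scores$measure, sep = "\r")
  split(scores$score, factor(key, levels = unique(key)))
}

# coerce user input into a bare numeric trajectory + identifiers
as_series <- function(series) {
  if (is.numeric(series)) {
    list(participant_id = NA_character_, measure = NA_character_,
         scores = as.numeric(series))
  } else if (is.list(series) && !is.null(series$scores)) {
    list(participant_id = as.character(series$participant_id %||% NA),
         measure = as.character(series$measure %||% NA),
         scores = as.numeric(series$scores))
  } else {
    stop("series must be a numeric vector or a list with a $scores element")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signed between-session improvement
#'
#' Orients both scale directions into a common "positive = improvement"
#' frame: on a lower-better scale an improvement is a drop,
#' `score(n) - score(n+1)`; on a higher-better scale a rise,
#' `score(n+1) - score(n)`.
#'
#' @param series Numeric trajectory (or list with `$scores`).
#' @param n Pregain session index; the interval examined is (n, n+1).
#' @param spec The [measure_spec()].
#' @return Signed improvement in points, or `NA` when either endpoint is
#'   missing (the interval is not evaluable).
#' @export
improvement <- function(series, n, spec) {
  x <- as_series(series)$scores
  if (n < 1L || n + 1L > length(x)) return(NA_real_)
  a <- x[n]; b <- x[n + 1L]
  if (is.na(a) || is.na(b)) return(NA_real_)
  if (spec$direction == "lower_better") a - b else b - a
}

#' Criterion one: large absolute change
#'
#' @inheritParams improvement
#' @return `TRUE`/`FALSE`, or `NA` when the interval is not evaluable.
#'   Boundary equality ("at least" the cutoff) passes.
#' @export
criterion_large_change <- function(series, n, spec) {
  imp <- improvement(series, n, spec)
  if (is.na(imp)) return(NA)
  imp >= spec$criterion1_cutoff
}

#' Criterion two: change relative to the pregain score
#'
#' The improvement must be at least `pregain_fraction` (default 25%) of the
#' pregain score. On higher-better scales the pregain "score" is reflected
#' into a deficit, `scale_max - score(n)`, since a fraction of the raw score
#' is only meaningful on a severity-oriented scale. A zero base passes
#' vacuously.
#'
#' @inheritParams improvement
#' @return `TRUE`/`FALSE`, or `NA` when the interval is not evaluable.
#' @export
criterion_relative_change <- function(series, n, spec) {
  x <- as_series(series)$scores
  imp <- improvement(series, n, spec)
  if (is.na(imp)) return(NA)
  base <- if (spec$direction == "lower_better") {
    x[n]
  } else {
    spec$scale_max - x[n]
  }
  if (base <= 0) return(TRUE)
  imp >= spec$pregain_fraction * base
}

# internal: observed pre/post stability windows around interval (n, n+1)
stability_windows <- function(x, n, window) {
  pre_idx <- seq.int(max(1L, n - window + 1L), n)
  post_idx <- seq.int(n + 1L, min(length(x), n + window))
  list(pre = x[pre_idx][!is.na(x[pre_idx])],
       post = x[post_idx][!is.na(x[post_idx])])
}

#' Criterion three: stability of the surrounding sessions
#'
#' Pooled-variance two-sample t test of the mean of the (up to three)
#' observed scores after the candidate gain against the mean of those before,
#' oriented so that positive t means improvement. Significant when t exceeds
#' the critical value for the observed per-side counts (see
#' [detection_config()]). With zero pooled variance the test degenerates:
#' any positive mean improvement passes (t diverges), no change fails.
#'
#' @inheritParams improvement
#' @param config A [detection_config()].
#' @return `TRUE`/`FALSE`, or `NA` when fewer than `min_per_side` scores are
#'   observed on either side (interval not evaluable).
#' @export
criterion_stability <- function(series, n, spec, config = detection_config()) {
  x <- as_series(series)$scores
  if (n < 1L || n + 1L > length(x)) return(NA)
  w <- stability_windows(x, n, config$window)
  n1 <- length(w$pre); n2 <- length(w$post)
  if (n1 < config$min_per_side || n2 < config$min_per_side) return(NA)
  crit <- config$stability_critical[paste0(n1, "_", n2)]
  if (is.na(crit)) {
    stop("no critical t value configured for window counts (",
         n1, ", ", n2, ")")
  }
  # orient: positive difference = improvement
  diff <- if (spec$direction == "lower_better") {
    mean(w$pre) - mean(w$post)
  } else {
    mean(w$post) - mean(w$pre)
  }
  ss <- sum((w$pre - mean(w$pre))^2) + sum((w$post - mean(w$post))^2)
  if (ss == 0) return(diff > 0)
  sp <- sqrt(ss / (n1 + n2 - 2))
  t_stat <- diff / (sp * sqrt(1 / n1 + 1 / n2))
  unname(t_stat > crit)
}

# workhorse shared by detect_shifts / detect_losses. `flip_direction` turns
# the machinery onto the deterioration direction (sudden losses are the
# inverse of the gain criteria).
detect_one_kind <- function(series, spec, config, kind) {
  s <- as_series(series)
  x <- s$scores
  sp <- spec
  if (kind == "loss") {
    sp$direction <- if (spec$direction == "lower_better") {
      "higher_better"
    } else {
      "lower_better"
    }
  }
  hits <- integer(0)
  n_pre <- integer(0)
  n_post <- integer(0)
  t_len <- length(x)
  if (t_len >= 2L) {
    for (n in seq_len(t_len - 1L)) {
      c1 <- criterion_large_change(x, n, sp)
      if (is.na(c1) || !c1) next
      c2 <- criterion_relative_change(x, n, sp)
      if (is.na(c2) || !c2) next
      c3 <- criterion_stability(x, n, sp, config)
      if (is.na(c3) || !c3) next
      w <- stability_windows(x, n, config$window)
      hits <- c(hits, n)
      n_pre <- c(n_pre, length(w$pre))
      n_post <- c(n_post, length(w$post))
    }
  }
  structure(
    list(participant_id = rep(s$participant_id, length(hits)),
         measure = rep(if (is.na(s$measure)) sp$name else s$measure,
                       length(hits)),
         kind = rep(kind, length(hits)),
         pregain_session = hits, shift_session = hits + 1L,
         magnitude = abs(x[hits] - x[hits + 1L]),
         n_pre = n_pre, n_post = n_post),
    class = "data.frame", row.names = seq_along(hits))
}

#' Detect sudden gains on one series
#'
#' Scans every between-session interval and records a sudden gain at
#' (N, N+1) when all three criteria hold: the improvement is at least the
#' criterion-one cutoff, at least `pregain_fraction` of the pregain score,
#' and the surrounding sessions are stable (criterion three). Intervals with
#' a missing endpoint are never evaluated (no imputation); multiple gains per
#' series are all reported. Output rows carry the gain magnitude
#' `|score(N) - score(N+1)|` and the observed window sizes, and are annotated
#' for reversals via [annotate_reversals()].
#'
#' @param series Numeric trajectory, or list with `$scores` (+ optional
#'   `$participant_id`, `$measure`).
#' @param spec The [measure_spec()].
#' @param config A [detection_config()].
#' @return Tibble of detected shifts, one row per gain, ordered by session.
#' @export
#' @examples
#' sp <- measure_spec("sym", "lower_better", 0, 20, criterion1_cutoff = 2)
#' detect_shifts(c(10, 10, 10, 5, 5, 5), sp)
detect_shifts <- function(series, spec, config = detection_config()) {
  out <- detect_one_kind(series, spec, config, "gain")
  tibble::as_tibble(annotate_reversals(series, out, spec))
}

#' Detect sudden losses on one series
#'
#' The inverse of the gain criteria: a large, rapid, stable *worsening*. The
#' identical machinery is applied in the deterioration direction (the scale
#' direction is flipped, so criterion two uses the reflected base).
#'
#' @inheritParams detect_shifts
#' @return Tibble of detected losses, one row per loss.
#' @export
detect_losses <- function(series, spec, config = detection_config()) {
  out <- detect_one_kind(series, spec, config, "loss")
  tibble::as_tibble(annotate_reversals(series, out, spec))
}

#' Annotate reversals of detected shifts
#'
#' A gain is reversed when, at any later observed session, the score has
#' moved back toward the pregain level by at least `reversal_fraction`
#' (default 50%) of the gain's magnitude; boundary equality counts. Losses
#' are annotated symmetrically (a reversal of a loss is regaining at least
#' that fraction of the lost ground). `reversal_session` is the earliest such
#' session.
#'
#' @param series The trajectory the shifts were detected on.
#' @param shifts Tibble from [detect_shifts()] / [detect_losses()].
#' @param spec The [measure_spec()].
#' @return `shifts` with logical `reversed` and integer `reversal_session`
#'   (`NA` when not reversed) columns set.
#' @export
annotate_reversals <- function(series, shifts, spec) {
  x <- as_series(series)$scores
  n_sh <- nrow(shifts)
  reversed <- logical(n_sh)
  reversal_session <- rep(NA_integer_, n_sh)
  for (i in seq_len(n_sh)) {
    n1 <- shifts$shift_session[i]
    mag <- shifts$magnitude[i]
    # direction the score moves when the shift *reverses*
    towards_worse <- (spec$direction == "lower_better") ==
      (shifts$kind[i] == "gain")
    later <- seq.int(n1 + 1L, length.out = max(0L, length(x) - n1))
    for (m in later) {
      if (is.na(x[m])) next
      hit <- if (towards_worse) {
        x[m] >= x[n1] + spec$reversal_fraction * mag
      } else {
        x[m] <= x[n1] - spec$reversal_fraction * mag
      }
      if (hit) {
        reversed[i] <- TRUE
        reversal_session[i] <- m
        break
      }
    }
  }
  shifts$reversed <- reversed
  shifts$reversal_session <- reversal_session
  shifts
}

#' Count evaluable between-session intervals
#'
#' @param series Numeric trajectory (or list with `$scores`).
#' @param config A [detection_config()]; used when
#'   `stability_evaluable = TRUE`.
#' @param stability_evaluable When `FALSE` (default) counts intervals with
#'   both endpoints observed; when `TRUE` additionally requires at least
#'   `min_per_side` observed scores in each stability window.
#' @return Integer count.
#' @export
count_intervals <- function(series, config = detection_config(),
                            stability_evaluable = FALSE) {
  x <- as_series(series)$scores
  if (length(x) < 2L) return(0L)
  n_ok <- 0L
  for (n in seq_len(length(x) - 1L)) {
    if (is.na(x[n]) || is.na(x[n + 1L])) next
    if (stability_evaluable) {
      w <- stability_windows(x, n, config$window)
      if (length(w$pre) < config$min_per_side ||
          length(w$post) < config$min_per_side) next
    }
    n_ok <- n_ok + 1L
  }
  n_ok
}

#' Detect sudden gains and losses across a cohort
#'
#' Runs [detect_shifts()] and [detect_losses()] on every series of an
#' (eligible) [cohort_dataset()].
#'
#' @param dataset A [cohort_dataset()], normally after [apply_eligibility()].
#' @param config A [detection_config()].
#' @param kinds Which shift kinds to detect; default both.
#' @return Tibble with one row per detected shift: `participant_id`,
#'   `measure`, `kind`, `pregain_session`, `shift_session`, `magnitude`,
#'   `n_pre`, `n_post`, `reversed`, `reversal_session`.
#' @export
detect_cohort <- function(dataset, config = detection_config(),
                          kinds = c("gain", "loss")) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  kinds <- match.arg(kinds, c("gain", "loss"), several.ok = TRUE)
  sl <- split_series(dataset$scores)
  ids <- strsplit(names(sl), "\r", fixed = TRUE)
  out <- vector("list", length(sl) * length(kinds))
  k <- 0L
  for (i in seq_along(sl)) {
    pid <- ids[[i]][1]
    m <- ids[[i]][2]
    spec <- dataset$measures[[m]]
    ser <- list(participant_id = pid, measure = m, scores = sl[[i]])
    for (kd in kinds) {
      rows <- detect_one_kind(ser, spec, config, kd)
      if (nrow(rows)) {
        k <- k + 1L
        out[[k]] <- annotate_reversals(ser, rows, spec)
      }
    }
  }
  res <- tibble::as_tibble(dplyr::bind_rows(out[seq_len(k)]))
  if (!nrow(res)) {
    res <- tibble::tibble(participant_id = character(0),
                          measure = character(0), kind = character(0),
                          pregain_session = integer(0),
                          shift_session = integer(0), magnitude = numeric(0),
                          n_pre = integer(0), n_post = integer(0),
                          reversed = logical(0),
                          reversal_session = integer(0))
  }
  dplyr::arrange(res, .data$participant_id, .data$measure,
                 .data$pregain_session, .data$kind)
}
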