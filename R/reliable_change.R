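#' Reliable change threshold (Jacobson--Truax)
#'
#' Computes the raw reliable change threshold for a measure from the standard
#' deviation of pretreatment scores and a reliability coefficient:
#' \deqn{RCI = z \cdot SD_{baseline} \cdot \sqrt{2 (1 - r)}}
#' A between-session change larger than this threshold is unlikely (at the
#' confidence level implied by `z`) to be measurement error alone, and is used
#' to calibrate the "large absolute change" criterion for sudden-gain
#' detection.
#'
#' @param baseline_sd Standard deviation of pretreatment scores, in scale
#'   points. Must be positive.
#' @param reliability Reliability coefficient of the measure (e.g. internal
#'   consistency or test--retest), in (0, 1). A reliability of exactly 1 is
#'   rejected: it forces a zero threshold under which every change would count
#'   as "large".
#' @param z Standard-normal critical value; default 1.96 (two-sided 5%).
#'
#' @return The raw threshold in scale points (not yet rounded).
#' @seealso [cutoff_from_threshold()] for the conservative integer rounding,
#'   [criterion1_cutoff()] for the composed convenience.
#' @export
#' @examples
#' rci_threshold(baseline_sd = 2, reliability = 0.8)
rci_threshold <- function(baseline_sd, reliability, z = 1.96) {
  stopifnot(is.numeric(baseline_sd), length(baseline_sd) == 1L,
            is.numeric(reliability), length(reliability) == 1L,
            is.numeric(z), length(z) == 1L)
  if (!is.finite(baseline_sd) || baseline_sd <= 0) {
    stop("`baseline_sd` must be a positive number, got ", baseline_sd)
  }
  if (!is.finite(reliability) || reliability <= 0 || reliability > 1) {
    stop("`reliability` must lie in (0, 1], got ", reliability)
  }
  if (reliability == 1) {
    stop("reliability = 1 gives a degenerate zero threshold: ",
         "every nonzero change would count as reliable")
  }
  if (!is.finite(z) || z <= 0) stop("`z` must be positive, got ", z)
  z * baseline_sd * sqrt(2 * (1 - reliability))
}

#' Conservative integer cutoff from a raw reliable-change threshold
#'
#' Session-by-session scales record whole numbers, so the raw threshold is
#' rounded *up* to the next whole number (a conservative choice: never easier
#' to cross than the raw threshold). Whole numbers are fixed points.
#'
#' @param raw Raw threshold in scale points; must be positive.
#' @return Integer cutoff in scale points.
#' @export
#' @examples
#' cutoff_from_threshold(2.4792) # 3
#' cutoff_from_threshold(2)      # 2
cutoff_from_threshold <- function(raw) {
  stopifnot(is.numeric(raw), length(raw) == 1L)
  if (!is.finite(raw) || raw <= 0) {
    stop("raw reliable-change threshold must be positive, got ", raw)
  }
  as.integer(ceiling(raw))
}

#' Criterion-one cutoff from reliability inputs
#'
#' Convenience composition of [rci_threshold()] and [cutoff_from_threshold()].
#'
#' @inheritParams rci_threshold
#' @return Integer cutoff in scale points.
#' @export
criterion1_cutoff <- function(baseline_sd, reliability, z = 1.96) {
  cutoff_from_threshold(rci_threshold(baseline_sd, reliability, z))
}
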