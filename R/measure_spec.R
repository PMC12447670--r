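#' Define a session-by-session measure
#'
#' A `measure_spec` records everything the detection machinery needs to know
#' about one outcome scale: which direction means improvement, the scale
#' bounds, and the three criterion constants -- the criterion-one cutoff (a
#' large absolute between-session change, usually derived from the reliable
#' change index and rounded up to a whole number), the pregain fraction
#' (criterion two: the change must be at least this fraction of the pregain
#' score), and the reversal fraction (a later session losing at least this
#' fraction of a gain's magnitude marks the gain as reversed).
#'
#' Either supply `criterion1_cutoff` directly, or supply `baseline_sd` and
#' `reliability` and the cutoff is computed via [criterion1_cutoff()].
#'
#' @param name Measure identifier (e.g. `"gbo_mean"`).
#' @param direction `"lower_better"` for symptom scales or `"higher_better"`
#'   for goal/efficacy scales.
#' @param scale_min,scale_max Scale bounds in points; `scale_min < scale_max`.
#' @param criterion1_cutoff Large-absolute-change cutoff in points (>= 1).
#'   Computed from `baseline_sd`/`reliability` when omitted.
#' @param pregain_fraction Criterion-two fraction of the pregain score,
#'   in (0, 1); default 0.25.
#' @param reversal_fraction Fraction of a gain's magnitude that must be lost
#'   for the gain to count as reversed, in (0, 1); default 0.5.
#' @param baseline_sd,reliability,z Reliability inputs consumed by
#'   [criterion1_cutoff()] when `criterion1_cutoff` is missing.
#'
#' @return An object of class `measure_spec`.
#' @export
#' @examples
#' measure_spec("sdq_sxs", "lower_better", 0, 40, criterion1_cutoff = 3)
#' measure_spec("gbo_mean", "higher_better", 1, 10,
#'              baseline_sd = 1.8, reliability = 0.75)
measure_spec <- function(name, direction = c("lower_better", "higher_better"),
                         scale_min, scale_max,
                         criterion1_cutoff = NULL,
                         pregain_fraction = 0.25,
                         reversal_fraction = 0.5,
                         baseline_sd = NULL, reliability = NULL, z = 1.96) {
  direction <- match.arg(direction)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(scale_min) || !is.numeric(scale_max) ||
      !(scale_min < scale_max)) {
    stop("measure '", name, "': scale_min must be < scale_max")
  }
  if (is.null(criterion1_cutoff)) {
    if (is.null(baseline_sd) || is.null(reliability)) {
      stop("measure '", name, "': supply either `criterion1_cutoff` or both ",
           "`baseline_sd` and `reliability`")
    }
    criterion1_cutoff <- criterion1_cutoff(baseline_sd, reliability, z)
  }
  if (!is.numeric(criterion1_cutoff) || criterion1_cutoff < 1) {
    stop("measure '", name, "': criterion1_cutoff must be >= 1, got ",
         criterion1_cutoff)
  }
  for (fr in c(pregain_fraction = pregain_fraction,
               reversal_fraction = reversal_fraction)) {
    if (!is.numeric(fr) || fr <= 0 || fr >= 1) {
      stop("measure '", name, "': criterion fractions must lie in (0, 1)")
    }
  }
  structure(
    list(name = name, direction = direction,
         scale_min = as.numeric(scale_min), scale_max = as.numeric(scale_max),
         criterion1_cutoff = as.numeric(criterion1_cutoff),
         pregain_fraction = pregain_fraction,
         reversal_fraction = reversal_fraction),
    class = "measure_spec"
  )
}

#' @export
print.measure_spec <- function(x, ...) {
  cat(sprintf(
    "<measure_spec> %s [%s, %g-%g] cutoff=%g pregain=%g reversal=%g\n",
    x$name, x$direction, x$scale_min, x$scale_max,
    x$criterion1_cutoff, x$pregain_fraction, x$reversal_fraction))
  invisible(x)
}

#' Read a measure configuration file
#'
#' Reads a JSON or YAML list of measure definitions. Each entry must carry
#' `name`, `direction`, `scale_min`, `scale_max`, and either
#' `criterion1_cutoff` or `baseline_sd` + `reliability` (the cutoff is then
#' derived through the reliable change index). Optional fields:
#' `pregain_fraction`, `reversal_fraction`, `z`.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return Named list of [measure_spec()] objects, keyed by measure name.
#' @export
read_measure_config <- function(path) {
  if (!file.exists(path)) stop("measure config not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = FALSE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported measure config format '.", ext,
         "' (use .json, .yaml or .yml)")
  )
  if (!is.null(raw$measures)) raw <- raw$measures
  specs <- lapply(raw, function(m) {
    do.call(measure_spec, m[intersect(names(m), names(formals(measure_spec)))])
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(names(specs))) {
    stop("duplicate measure names in config: ",
         paste(unique(names(specs)[duplicated(names(specs))]), collapse = ", "))
  }
  specs
}

#' Write a measure configuration file
#'
#' Inverse of [read_measure_config()]; used by the simulator so generated
#' cohorts ship with the configuration the pipeline reads back.
#'
#' @param measures Named list of [measure_spec()] objects.
#' @param path Output path (`.json`, `.yaml` or `.yml`).
#' @return `path`, invisibly.
#' @export
write_measure_config <- function(measures, path) {
  entries <- lapply(unname(measures), function(m) unclass(m))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(entries, path)
  } else {
    stop("unsupported measure config format '.", ext, "'")
  }
  invisible(path)
}
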