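#' Default covariate adjustment set
#'
#' The covariates every adjusted model conditions on: sex, age group,
#' ethnicity (white vs other), autism spectrum disorder, intellectual
#' disability, primary-caregiver employment, primary mental health disorder
#' (disruptive behaviour vs anxiety/depression), total number of therapy
#' sessions received, and the pretreatment score on the relevant measure.
#'
#' @param measure Measure name; its pretreatment column is
#'   `pretreatment_<measure>`.
#' @return Character vector of covariate column names.
#' @export
gain_covariate_set <- function(measure) {
  c("sex", "age_group", "ethnicity_white", "asd", "intellectual_disability",
    "caregiver_employed", "primary_disorder", "total_sessions",
    paste0("pretreatment_", measure))
}

# 0/1 indicator of >=1 sudden gain on the measure, for every participant
# with a series on that measure
gain_indicator <- function(dataset, measure, shifts) {
  pids <- unique(dataset$scores$participant_id[
    dataset$scores$measure == measure])
  g <- shifts[shifts$measure == measure & shifts$kind == "gain", ]
  tibble::tibble(participant_id = pids,
                 sudden_gain = as.integer(pids %in% g$participant_id))
}

# model frame: indicator + requested covariate columns, complete cases only;
# primary_disorder coded with anxiety/depression as reference
build_model_frame <- function(dataset, measure, shifts, covariates,
                              outcome = NULL) {
  ind <- gain_indicator(dataset, measure, shifts)
  frame <- dplyr::left_join(ind, dataset$covariates, by = "participant_id")
  missing_cols <- setdiff(c(covariates, outcome), names(frame))
  if (length(missing_cols)) {
    stop("covariates table lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  frame <- frame[, c("participant_id", "sudden_gain", covariates, outcome)]
  if ("primary_disorder" %in% names(frame) &&
      !is.numeric(frame$primary_disorder)) {
    frame$primary_disorder <- factor(
      frame$primary_disorder,
      levels = c("anxiety_or_depression", "disruptive_behaviour"))
  }
  n_in <- nrow(frame)
  frame <- frame[stats::complete.cases(frame), ]
  attr(frame, "n_excluded") <- n_in - nrow(frame)
  frame
}

effect_row <- function(term, scale, estimate, ci_low, ci_high, p, n_used,
                       model = NA_character_, d = NA_real_) {
  tibble::tibble(term = term, scale = scale, model = model,
                 estimate = estimate, ci_low = ci_low, ci_high = ci_high,
                 p = p, n_used = n_used, d = d)
}

#' Predictors of sudden-gain occurrence (logistic regression)
#'
#' Fits a multivariable logistic regression of "experienced at least one
#' sudden gain on the measure" on the covariate set, and reports one
#' odds-ratio row per covariate with a Wald 95% CI (on the link scale,
#' exponentiated) and two-sided p. Rows with any missing covariate are
#' excluded (complete case); the count is attached as attribute
#' `n_excluded`. Complete or quasi-complete separation and non-convergence
#' raise an error naming the offending term.
#'
#' @param dataset The (eligible) [cohort_dataset()].
#' @param measure Measure name.
#' @param shifts Tibble from [detect_cohort()].
#' @param covariates Covariate column names; default [gain_covariate_set()].
#'   Supply a single name for an unadjusted odds ratio.
#' @return Tibble of effect rows (`term`, `scale = "odds_ratio"`,
#'   `estimate`, `ci_low`, `ci_high`, `p`, `n_used`).
#' @export
fit_gain_logistic <- function(dataset, measure, shifts,
                              covariates = gain_covariate_set(measure)) {
  frame <- build_model_frame(dataset, measure, shifts, covariates)
  if (length(unique(frame$sudden_gain)) < 2) {
    stop("gain indicator is constant on measure '", measure,
         "': logistic model not identifiable")
  }
  fml <- stats::reformulate(covariates, response = "sudden_gain")
  fit <- suppressWarnings(glm(fml, data = frame, family = binomial()))
  beta <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  bad <- names(beta)[-1][!is.finite(beta[-1]) | abs(beta[-1]) > 10 |
                           se[-1] > 50]
  if (!fit$converged || length(bad)) {
    stop("logistic model failed (separation or non-convergence)",
         if (length(bad)) paste0(": term '", bad[1], "'") else "")
  }
  keep <- setdiff(names(beta), "(Intercept)")
  z <- beta[keep] / se[keep]
  out <- effect_row(
    term = keep, scale = "odds_ratio",
    estimate = unname(exp(beta[keep])),
    ci_low = unname(exp(beta[keep] - 1.96 * se[keep])),
    ci_high = unname(exp(beta[keep] + 1.96 * se[keep])),
    p = unname(2 * stats::pnorm(-abs(z))),
    n_used = nrow(frame), model = "adjusted")
  attr(out, "n_excluded") <- attr(frame, "n_excluded")
  out
}

# linear model of an outcome on the gain indicator (+ covariates); returns
# the gain term as a mean-difference effect row with Cohen's D
fit_md_model <- function(frame, outcome, covariates, model_label) {
  by_group <- split(frame[[outcome]], frame$sudden_gain)
  if (length(by_group) < 2 || any(vapply(by_group, length, 1L) < 2)) {
    stop("insufficient data: need at least 2 participants in each ",
         "gain group (have ",
         paste(vapply(by_group, length, 1L), collapse = "/"), ")")
  }
  fml <- stats::reformulate(c("sudden_gain", covariates), response = outcome)
  fit <- lm(fml, data = frame)
  est <- coef(fit)[["sudden_gain"]]
  se <- sqrt(diag(vcov(fit)))[["sudden_gain"]]
  df <- fit$df.residual
  p <- if (se > 0) 2 * stats::pt(-abs(est / se), df) else NA_real_
  ci <- est + c(-1, 1) * qt(0.975, df) * se
  d <- tryCatch(
    cohens_d(est,
             group_sds = vapply(by_group, sd, numeric(1)),
             group_ns = vapply(by_group, length, integer(1)))$d,
    error = function(e) NA_real_)
  effect_row(term = "sudden_gain", scale = "mean_difference",
             estimate = est, ci_low = ci[1], ci_high = ci[2], p = p,
             n_used = nrow(frame), model = model_label, d = d)
}

#' Association of sudden gains with the final-session score
#'
#' Linear regression of the final session-by-session score on the gain
#' indicator, unadjusted and adjusted for the covariate set. The outcome is
#' the `final_<measure>` covariate column when present, otherwise each
#' participant's last observed score on the measure. Cohen's D standardises
#' each mean difference by the pooled observed outcome SD across gain groups.
#'
#' @inheritParams fit_gain_logistic
#' @return Tibble with an unadjusted and an adjusted mean-difference row for
#'   the gain indicator; attribute `n_excluded` counts complete-case
#'   exclusions from the adjusted model.
#' @export
fit_final_score_model <- function(dataset, measure, shifts,
                                  covariates = gain_covariate_set(measure)) {
  out_col <- paste0("final_", measure)
  if (!out_col %in% names(dataset$covariates)) {
    sc <- dataset$scores[dataset$scores$measure == measure, ]
    sl <- split(sc$score, factor(sc$participant_id,
                                 levels = unique(sc$participant_id)))
    last <- vapply(sl, function(x) {
      x <- x[!is.na(x)]
      if (length(x)) x[[length(x)]] else NA_real_
    }, numeric(1))
    dataset$covariates[[out_col]] <-
      unname(last[dataset$covariates$participant_id])
  }
  un_frame <- build_model_frame(dataset, measure, shifts, character(0),
                                outcome = out_col)
  adj_frame <- build_model_frame(dataset, measure, shifts, covariates,
                                 outcome = out_col)
  out <- dplyr::bind_rows(
    fit_md_model(un_frame, out_col, character(0), "unadjusted"),
    fit_md_model(adj_frame, out_col, covariates, "adjusted"))
  attr(out, "n_excluded") <- attr(adj_frame, "n_excluded")
  out
}

#' Association of sudden gains with the 6-month follow-up outcome
#'
#' As [fit_final_score_model()], but the outcome is the 6-month SDQ total
#' difficulties score (`sdq_total_6m`) and the adjusted model additionally
#' conditions on the baseline SDQ total (`baseline_sdq_total`). Participants
#' missing the follow-up outcome are excluded; the count is attached as
#' attribute `n_missing_outcome`.
#'
#' @inheritParams fit_gain_logistic
#' @return Tibble with an unadjusted and an adjusted mean-difference row.
#' @export
fit_followup_model <- function(dataset, measure, shifts,
                               covariates = gain_covariate_set(measure)) {
  if (!all(c("sdq_total_6m", "baseline_sdq_total") %in%
             names(dataset$covariates))) {
    stop("covariates must contain sdq_total_6m and baseline_sdq_total")
  }
  n_missing <- sum(is.na(dataset$covariates$sdq_total_6m))
  adj_cov <- c(covariates, "baseline_sdq_total")
  un_frame <- build_model_frame(dataset, measure, shifts, character(0),
                                outcome = "sdq_total_6m")
  adj_frame <- build_model_frame(dataset, measure, shifts, adj_cov,
                                 outcome = "sdq_total_6m")
  if (!nrow(un_frame)) stop("insufficient data: all follow-up outcomes missing")
  out <- dplyr::bind_rows(
    fit_md_model(un_frame, "sdq_total_6m", character(0), "unadjusted"),
    fit_md_model(adj_frame, "sdq_total_6m", adj_cov, "adjusted"))
  attr(out, "n_missing_outcome") <- n_missing
  attr(out, "n_excluded") <- attr(adj_frame, "n_excluded")
  out
}

#' Cohen's D from a mean difference and group spreads
#'
#' Standardises a mean difference by the pooled standard deviation
#' \deqn{s_p = \sqrt{((n_1-1) s_1^2 + (n_2-1) s_2^2) / (n_1+n_2-2)}.}
#' The sign follows the mean difference as supplied.
#'
#' @param md Mean difference, in outcome points.
#' @param group_sds Numeric length-2: the two group SDs.
#' @param group_ns Integer length-2: the two group sizes.
#' @return List with `d` (standardised mean difference) and `pooled_sd`.
#' @export
#' @examples
#' cohens_d(1, c(2, 2), c(50, 50)) # d = 0.5
cohens_d <- function(md, group_sds, group_ns) {
  stopifnot(length(group_sds) == 2L, length(group_ns) == 2L,
            all(group_ns >= 1))
  pooled <- sqrt(sum((group_ns - 1) * group_sds^2) / (sum(group_ns) - 2))
  if (!is.finite(pooled) || pooled <= 0) {
    stop("pooled SD is zero: Cohen's D undefined")
  }
  list(d = md / pooled, pooled_sd = pooled)
}

#' Fit every association model across a cohort
#'
#' Runs [fit_gain_logistic()], [fit_final_score_model()] and (when the SDQ
#' columns are present) [fit_followup_model()] for every measure, collecting
#' all effect rows into one machine-readable table. Measures whose models
#' fail (e.g. separation, too few gains) are reported in the `note` column
#' instead of aborting the run.
#'
#' @inheritParams fit_gain_logistic
#' @return Tibble with columns `measure`, `model_family`, `term`, `scale`,
#'   `model`, `estimate`, `ci_low`, `ci_high`, `p`, `n_used`, `d`, `note`.
#' @export
associate_cohort <- function(dataset, shifts) {
  out <- list()
  for (m in names(dataset$measures)) {
    add <- function(family, expr) {
      res <- tryCatch(expr, error = function(e) {
        r <- effect_row(term = NA_character_, scale = NA_character_,
                        estimate = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_,
                        n_used = NA_integer_)
        r$note <- conditionMessage(e)
        r
      })
      res$measure <- m
      res$model_family <- family
      if (!"note" %in% names(res)) res$note <- NA_character_
      out[[length(out) + 1L]] <<- res
    }
    add("gain_predictors", fit_gain_logistic(dataset, m, shifts))
    add("final_score", fit_final_score_model(dataset, m, shifts))
    if (all(c("sdq_total_6m", "baseline_sdq_total") %in%
              names(dataset$covariates))) {
      add("followup_6m", fit_followup_model(dataset, m, shifts))
    }
  }
  res <- dplyr::bind_rows(out)
  dplyr::select(res, "measure", "model_family", "term", "scale", "model",
                "estimate", "ci_low", "ci_high", "p", "n_used", "d", "note")
}
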