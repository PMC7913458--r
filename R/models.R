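## Effect estimation: 2x2 odds ratios, multivariable logistic models, and
## log-linear (log-transformed outcome) models, all with Wald 95% intervals
## (z = 1.96), matching how administrative-data outcome studies usually
## report ORs and back-transformed Exp(B) factors.

Z95 <- 1.96

#' A 2x2 contingency table of exposure by event
#'
#' @param a exposed events.
#' @param b exposed non-events.
#' @param c unexposed events.
#' @param d unexposed non-events.
#' @return An object of class `rd_2x2`.
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  stop_if(any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells)),
          "2x2 cells must be non-negative integers")
  structure(as.list(cells), class = "rd_2x2")
}

#' Odds ratio with Wald confidence interval from a 2x2 table
#'
#' The point estimate is the cross-product ratio (a*d)/(b*c), identical to the
#' OR from an unadjusted logistic regression with one binary exposure. The 95%
#' interval is Wald-type on the log scale,
#' exp(log(OR) +/- 1.96*sqrt(1/a + 1/b + 1/c + 1/d)). Zero cells raise an
#' error naming the cell; no continuity correction is applied silently.
#'
#' @param t a `rd_2x2` from [two_by_two()].
#' @return One-row data frame: `term`, `estimate`, `ci_low`, `ci_high`,
#'   `scale`, `n`.
#' @examples
#' or_from_table(two_by_two(1082, 15969, 3202, 143602))
#' @export
or_from_table <- function(t) {
  stopifnot(inherits(t, "rd_2x2"))
  zero <- names(t)[vapply(t, function(x) x == 0, logical(1L))]
  if (t$b * t$c == 0) {
    rd_validation_error(sprintf("odds ratio undefined: zero cell(s) %s",
                                paste(zero, collapse = ", ")))
  }
  if (length(zero)) {
    rd_validation_error(sprintf("Wald interval requires all cells > 0; zero cell(s) %s",
                                paste(zero, collapse = ", ")))
  }
  or <- (t$a * t$d) / (t$b * t$c)
  se <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
  data.frame(term = "exposure",
             estimate = or,
             ci_low = exp(log(or) - Z95 * se),
             ci_high = exp(log(or) + Z95 * se),
             scale = "odds-ratio",
             n = t$a + t$b + t$c + t$d,
             stringsAsFactors = FALSE)
}

OUTCOME_COLUMNS <- c(mortality = "died_in_hospital",
                     icu_admission = "icu_admitted",
                     los = "los_days",
                     icu_los = "icu_days",
                     readmission_30d = "readmitted_30d")

#' Specify a regression model
#'
#' Encodes which outcome is modelled, the adjustment covariates (in the order
#' they enter the design matrix), optional interaction terms, and an optional
#' sex-subgroup restriction (subgroup models drop the sex covariate and keep
#' all others). Default covariates are the exposure group plus age group, sex,
#' discharge year (centered at the first study year) and the non-rare
#' diagnosis count; readmission models additionally adjust for the
#' previous-stay category and the length of stay.
#'
#' @param outcome one of `"mortality"`, `"icu_admission"`, `"los"`,
#'   `"icu_los"`, `"readmission_30d"`.
#' @param covariates character vector of column names; `NULL` for the default
#'   set for that outcome.
#' @param interactions optional character vector of interaction terms in
#'   formula syntax (e.g. `"rare_group:nonrare_dx_count"`).
#' @param subgroup_sex optional `"F"` or `"M"`.
#' @return An object of class `rd_model_spec`.
#' @export
model_spec <- function(outcome, covariates = NULL, interactions = NULL,
                       subgroup_sex = NULL) {
  stop_if(!(outcome %in% names(OUTCOME_COLUMNS)),
          sprintf("unknown outcome %s", sQuote(outcome)))
  if (is.null(covariates)) {
    covariates <- c("rare_group", "age_group", "sex", "year_c", "nonrare_dx_count")
    if (outcome == "readmission_30d") {
      covariates <- c(covariates, "previous_stay_category", "los_days")
    }
  }
  if (!is.null(subgroup_sex)) {
    stop_if(!(subgroup_sex %in% c("F", "M")), "subgroup_sex must be 'F' or 'M'")
    covariates <- setdiff(covariates, "sex")
  }
  structure(list(outcome = outcome,
                 outcome_col = unname(OUTCOME_COLUMNS[outcome]),
                 covariates = covariates,
                 interactions = interactions,
                 subgroup_sex = subgroup_sex),
            class = "rd_model_spec")
}

#' Assemble the analysis data set for modelling
#'
#' Joins the selected stays with their exposure summaries and derives the
#' model covariates with the reference levels used throughout: exposure group
#' `0`, age group `18-34`, sex `F`, previous-stay category `0`; the discharge
#' year is centered at `baseline_year` (default: the earliest year present)
#' so effects read "per additional year".
#'
#' @param selected data frame of one-stay-per-patient records.
#' @param exposure data frame from [summarize_exposure()].
#' @param baseline_year year at which `year_c = 0`.
#' @return Data frame ready for [fit_logistic()] / [fit_log_linear()].
#' @export
prepare_model_data <- function(selected, exposure, baseline_year = NULL) {
  d <- as.data.frame(merge(as.data.table(selected), as.data.table(exposure),
                           by = "stay_id", all.x = TRUE, sort = TRUE))
  no_dx <- is.na(d$rare_count)
  stop_if(any(no_dx), sprintf("stay(s) without exposure summary: %s",
                              paste(utils::head(d$stay_id[no_dx], 5L), collapse = ", ")))
  d$rare_group <- factor(as.character(d$rare_group), levels = RARE_GROUP_LEVELS)
  d$age_group <- derive_age_group(d$age_at_admission)
  d$sex <- factor(as.character(d$sex), levels = c("F", "M"))
  baseline_year <- baseline_year %||% min(d$discharge_year)
  d$year_c <- d$discharge_year - baseline_year
  if ("previous_stays_2y" %in% names(d)) {
    d$previous_stay_category <- derive_previous_stay_category(d$previous_stays_2y)
  }
  if ("unit_group" %in% names(d)) {
    d$unit_group <- factor(as.character(d$unit_group),
                           levels = c("internal-medicine-and-related",
                                      "surgical", "other"))
  }
  d
}

build_design <- function(data, spec) {
  rhs <- paste(c(spec$covariates, spec$interactions), collapse = " + ")
  form <- stats::as.formula(paste("~", rhs))
  used <- all.vars(form)
  miss <- setdiff(used, names(data))
  stop_if(length(miss) > 0L, sprintf("model data lacks column(s): %s",
                                     paste(miss, collapse = ", ")))
  if (!is.null(spec$subgroup_sex)) data <- data[data$sex == spec$subgroup_sex, , drop = FALSE]
  cc <- stats::complete.cases(data[, used, drop = FALSE])
  data <- data[cc, , drop = FALSE]
  ## degenerate factors abort before model.matrix produces cryptic errors
  for (v in used) {
    if (is.factor(data[[v]])) {
      lev <- unique(as.character(data[[v]]))
      stop_if(length(lev) < 2L, sprintf(
        "covariate %s is degenerate (single level %s) in the model data",
        v, sQuote(lev)))
    }
  }
  mm <- stats::model.matrix(form, data)
  list(mm = mm, data = data)
}

check_full_rank <- function(fit, mm, outcome) {
  if (fit$rank < ncol(mm)) {
    dropped <- colnames(mm)[fit$qr$pivot[(fit$rank + 1L):ncol(mm)]]
    rd_validation_error(sprintf(
      "design matrix for %s is rank deficient; collinear term(s): %s",
      outcome, paste(dropped, collapse = ", ")))
  }
}

## Wald estimates from a glm.fit/lm.fit style object; mirrors summary.glm's
## use of the (pivoted) qr decomposition
wald_from_fit <- function(coefs, covmat_unscaled, scale_factor, model, scale,
                          n, drop_intercept = TRUE) {
  se <- sqrt(diag(covmat_unscaled) * scale_factor)
  out <- data.frame(model = model,
                    term = names(coefs),
                    estimate = exp(coefs),
                    ci_low = exp(coefs - Z95 * se),
                    ci_high = exp(coefs + Z95 * se),
                    scale = scale,
                    n = n,
                    stringsAsFactors = FALSE)
  if (drop_intercept) out <- out[out$term != "(Intercept)", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit a multivariable logistic regression and report odds ratios
#'
#' Maximum-likelihood logistic regression of a binary outcome on the
#' covariates of `spec`; each term is reported as an odds ratio (exponentiated
#' coefficient) with a Wald 95% interval. Non-convergence and (quasi-)complete
#' separation raise explicit errors rather than returning silent output.
#'
#' @param data data frame from [prepare_model_data()] (already restricted to
#'   the outcome's cohort).
#' @param spec a `rd_model_spec`.
#' @return Data frame with columns `model`, `term`, `estimate`, `ci_low`,
#'   `ci_high`, `scale`, `n`.
#' @export
fit_logistic <- function(data, spec) {
  stopifnot(inherits(spec, "rd_model_spec"))
  des <- build_design(data, spec)
  y <- des$data[[spec$outcome_col]]
  stop_if(is.null(y), sprintf("outcome column %s missing", spec$outcome_col))
  y <- as.numeric(y)
  stop_if(!all(y %in% c(0, 1)), sprintf("outcome %s is not binary", spec$outcome_col))
  stop_if(length(unique(y)) < 2L, sprintf("outcome %s is constant", spec$outcome_col))
  fit <- glm.fit(des$mm, y, family = binomial(),
                 control = glm.control(epsilon = 1e-8, maxit = 100L))
  check_full_rank(fit, des$mm, spec$outcome)
  if (!fit$converged) {
    stop(sprintf("logistic model for %s did not converge in 100 IRLS iterations",
                 spec$outcome))
  }
  if (any(abs(fit$coefficients[-1L]) > 15)) {
    big <- names(fit$coefficients[-1L])[abs(fit$coefficients[-1L]) > 15]
    stop(sprintf("possible separation in logistic model for %s (runaway term(s): %s)",
                 spec$outcome, paste(big, collapse = ", ")))
  }
  p <- fit$rank
  covmat <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  coefs <- fit$coefficients[fit$qr$pivot[seq_len(p)]]
  model_label <- paste0(spec$outcome,
                        if (!is.null(spec$subgroup_sex)) paste0("_", tolower(spec$subgroup_sex)))
  wald_from_fit(coefs, covmat, 1, model_label, "odds-ratio", length(y))
}

#' Fit a log-linear model for a skewed positive outcome
#'
#' Ordinary least squares on the natural logarithm of the outcome (length of
#' stay or ICU length of stay). Reported effects are exponentiated
#' coefficients with exponentiated Wald 95% intervals, read as multiplicative
#' factors: 1.28 means a 28% increase per unit (or versus the reference
#' level). Non-positive outcome values must be excluded upstream (the
#' per-outcome cohort rules do this); any reaching the fit raise an error.
#'
#' @inheritParams fit_logistic
#' @param outcome_col outcome column; defaults to the one named by `spec`.
#' @return Data frame with columns `model`, `term`, `estimate`, `ci_low`,
#'   `ci_high`, `scale`, `n`.
#' @export
fit_log_linear <- function(data, spec, outcome_col = NULL) {
  stopifnot(inherits(spec, "rd_model_spec"))
  outcome_col <- outcome_col %||% spec$outcome_col
  des <- build_design(data, spec)
  y <- des$data[[outcome_col]]
  stop_if(is.null(y), sprintf("outcome column %s missing", outcome_col))
  stop_if(any(is.na(y)) || any(y <= 0),
          sprintf("outcome %s contains non-positive values; exclude them upstream",
                  outcome_col))
  fit <- lm.fit(des$mm, log(y))
  check_full_rank(fit, des$mm, spec$outcome)
  p <- fit$rank
  n <- length(y)
  sigma2 <- sum(fit$residuals^2) / (n - p)
  covmat <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  coefs <- fit$coefficients[fit$qr$pivot[seq_len(p)]]
  model_label <- paste0(spec$outcome,
                        if (!is.null(spec$subgroup_sex)) paste0("_", tolower(spec$subgroup_sex)))
  wald_from_fit(coefs, covmat, sigma2, model_label, "multiplicative", n)
}

#' Refit the mortality model under a named sensitivity analysis
#'
#' Three pre-specified modifications of the adjusted mortality model:
#' * `"stay-count-adjusted"` -- additionally adjusts for the total number of
#'   stays the patient had during the study period (`total_stays`);
#' * `"rare-by-nonrare-interaction"` -- adds the interaction between exposure
#'   group and the non-rare diagnosis count, so the exposure ORs are reported
#'   at zero non-rare diagnoses together with the interaction terms;
#' * `"rare-by-unit-interaction"` -- adds the clinical-unit group and its
#'   interaction with the exposure group (the unit factor must have at least
#'   two observed levels).
#'
#' @param analysis one of the three analysis ids above.
#' @param data mortality-cohort model data (see [prepare_model_data()]).
#' @param spec base model spec; default the adjusted mortality model.
#' @return Data frame of effect estimates, as from [fit_logistic()].
#' @export
run_sensitivity <- function(analysis, data, spec = model_spec("mortality")) {
  ids <- c("stay-count-adjusted", "rare-by-nonrare-interaction",
           "rare-by-unit-interaction")
  stop_if(!(is.character(analysis) && length(analysis) == 1L && analysis %in% ids),
          sprintf("unknown sensitivity analysis %s; expected one of %s",
                  sQuote(analysis), paste(ids, collapse = ", ")))
  spec2 <- switch(analysis,
    "stay-count-adjusted" = model_spec(spec$outcome,
      covariates = c(spec$covariates, "total_stays"),
      interactions = spec$interactions, subgroup_sex = spec$subgroup_sex),
    "rare-by-nonrare-interaction" = model_spec(spec$outcome,
      covariates = spec$covariates,
      interactions = c(spec$interactions, "rare_group:nonrare_dx_count"),
      subgroup_sex = spec$subgroup_sex),
    "rare-by-unit-interaction" = model_spec(spec$outcome,
      covariates = c(spec$covariates, "unit_group"),
      interactions = c(spec$interactions, "rare_group:unit_group"),
      subgroup_sex = spec$subgroup_sex))
  out <- fit_logistic(data, spec2)
  out$model <- paste0(out$model, "_", gsub("-", "_", analysis))
  out
}
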