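## Cohort construction: eligibility, one random stay per patient, stay-history
## derived covariates, and per-outcome sub-cohorts.

STAY_COLUMNS <- c("stay_id", "patient_id", "age_at_admission", "sex",
                  "admit_date", "discharge_date", "died_in_hospital",
                  "icu_admitted", "icu_days", "los_days", "discharge_year",
                  "unit_group")

#' Validate a table of hospital stays
#'
#' Checks the structural invariants every stay record must satisfy: discharge
#' not before admission, positive length of stay consistent with the dates,
#' ICU days only for ICU-admitted stays and never exceeding the length of
#' stay, and no stay that ended in death flagged as readmitted. Aborts naming
#' the first offending stay.
#'
#' @param stays data frame of stay records.
#' @return `stays`, invisibly.
#' @export
validate_stays <- function(stays) {
  missing_cols <- setdiff(STAY_COLUMNS, names(stays))
  stop_if(length(missing_cols) > 0L,
          sprintf("stays table lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  fail <- function(which, msg) {
    rd_validation_error(sprintf("stay %s: %s", stays$stay_id[which[1L]], msg))
  }
  adm <- as.Date(stays$admit_date)
  dis <- as.Date(stays$discharge_date)
  bad <- which(dis < adm)
  if (length(bad)) fail(bad, "discharge_date before admit_date")
  bad <- which(!(stays$los_days > 0))
  if (length(bad)) fail(bad, "los_days must be positive")
  span <- as.numeric(dis - adm)
  bad <- which(abs(pmax(1, ceiling(stays$los_days)) - span) > 1e-8)
  if (length(bad)) fail(bad, "los_days inconsistent with admit/discharge dates")
  bad <- which(stays$icu_days < 0)
  if (length(bad)) fail(bad, "icu_days must be non-negative")
  bad <- which(stays$icu_days > 0 & !stays$icu_admitted)
  if (length(bad)) fail(bad, "icu_days > 0 for a stay without ICU admission")
  bad <- which(stays$icu_days > stays$los_days + 1e-8)
  if (length(bad)) fail(bad, "icu_days exceeds los_days")
  if ("readmitted_30d" %in% names(stays)) {
    bad <- which(stays$died_in_hospital & !is.na(stays$readmitted_30d) &
                   stays$readmitted_30d)
    if (length(bad)) fail(bad, "a stay ending in death cannot be readmitted")
  }
  invisible(stays)
}

#' Filter stays to the eligible analysis population
#'
#' Keeps stays of adults (age at admission of at least 18 years) that carry
#' at least one coded diagnosis, and tallies how many stays each criterion
#' removed, for the patient-flow report.
#'
#' @param stays data frame of stay records.
#' @param diagnoses data frame with columns `stay_id`, `icd10_code`.
#' @return List with `stays` (the eligible subset), `removed` (named counts:
#'   `underage`, `no_diagnosis`), `n_in`, `n_out`.
#' @export
filter_eligible <- function(stays, diagnoses) {
  stop_if(!all(c("stay_id", "icd10_code") %in% names(diagnoses)),
          "diagnoses must have columns stay_id, icd10_code")
  adult <- stays$age_at_admission >= 18
  has_dx <- stays$stay_id %in% diagnoses$stay_id
  keep <- adult & has_dx
  list(stays = stays[keep, , drop = FALSE],
       removed = c(underage = sum(!adult),
                   no_diagnosis = sum(adult & !has_dx)),
       n_in = nrow(stays), n_out = sum(keep))
}

#' Select one stay per patient, uniformly at random
#'
#' Patients who stayed several times would otherwise be over-represented (and
#' chronically ill patients -- including those with rare diseases -- stay more
#' often), so exactly one stay per patient is drawn uniformly at random. The
#' draw is deterministic for a fixed seed and does not disturb the caller's
#' RNG state.
#'
#' @param stays data frame of (eligibility-filtered) stay records.
#' @param seed integer seed.
#' @return Data frame with exactly one row per distinct `patient_id`.
#' @export
select_one_stay_per_patient <- function(stays, seed) {
  if (nrow(stays) == 0L) return(stays)
  ord <- order(stays$patient_id, stays$stay_id, method = "radix")
  s <- stays[ord, , drop = FALSE]
  r <- rle(as.character(s$patient_id))
  sizes <- r$lengths
  starts <- cumsum(c(1L, sizes[-length(sizes)]))
  pick <- with_seed(seed, {
    u <- runif(length(sizes))
    starts + pmin(floor(u * sizes), sizes - 1L)
  })
  out <- s[pick, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive stay-history covariates from the full stay table
#'
#' Computes, for every stay and against the *complete* stay history of its
#' patient (i.e. before any one-stay-per-patient selection):
#' * `readmitted_30d` -- whether any stay of the same patient was admitted
#'   within `window_days` days after this stay's discharge (boundary
#'   inclusive);
#' * `previous_stays_2y` -- the number of the patient's admissions in the
#'   `lookback_days` days before this admission;
#' * `total_stays` -- the patient's total number of stays in the table.
#'
#' @param stays data frame of stay records (the full history).
#' @param window_days readmission window, default 30.
#' @param lookback_days lookback for the previous-stay count, default 730.
#' @return `stays` with the three columns added (or overwritten).
#' @export
annotate_stay_history <- function(stays, window_days = 30, lookback_days = 730) {
  if (nrow(stays) == 0L) return(stays)
  pid <- match(stays$patient_id, unique(stays$patient_id))
  adm <- as.numeric(as.Date(stays$admit_date))
  dis <- as.numeric(as.Date(stays$discharge_date))
  ## patient blocks are pushed far apart on a common axis so that one global
  ## sorted vector answers all per-patient window queries
  offset <- (max(dis) - min(adm) + 2 * (lookback_days + window_days) + 10)
  adm_g <- adm + pid * offset
  dis_g <- dis + pid * offset
  A <- sort(adm_g)
  n_after <- findInterval(dis_g + window_days + 0.5, A) -
    findInterval(dis_g + 0.5, A)
  n_prev <- findInterval(adm_g - 0.5, A) -
    findInterval(adm_g - lookback_days - 0.5, A)
  stays$readmitted_30d <- n_after > 0L
  stays$previous_stays_2y <- as.integer(n_prev)
  stays$total_stays <- as.integer(tabulate(pid)[pid])
  stays
}

#' Build the analysis cohort for one outcome
#'
#' Applies the per-outcome inclusion rules: mortality and ICU admission use
#' every selected stay; length of stay and 30-day readmission exclude stays
#' that ended in death; ICU length of stay additionally requires an ICU
#' admission; 30-day readmission additionally requires complete readmission
#' information.
#'
#' @param selected data frame of one-stay-per-patient records.
#' @param outcome one of `"mortality"`, `"icu_admission"`, `"los"`,
#'   `"icu_los"`, `"readmission_30d"`.
#' @return List with `cohort` (the subset), `excluded` (named tally) and
#'   `outcome`.
#' @export
build_outcome_cohort <- function(selected, outcome) {
  outcomes <- c("mortality", "icu_admission", "los", "icu_los", "readmission_30d")
  stop_if(!(is.character(outcome) && length(outcome) == 1L && outcome %in% outcomes),
          sprintf("unknown outcome %s; expected one of %s",
                  paste(sQuote(outcome), collapse = ", "),
                  paste(outcomes, collapse = ", ")))
  keep <- rep(TRUE, nrow(selected))
  excluded <- c(died = 0L, no_icu = 0L, incomplete_readmission_info = 0L)
  if (outcome %in% c("los", "icu_los", "readmission_30d")) {
    died <- selected$died_in_hospital
    excluded["died"] <- sum(keep & died)
    keep <- keep & !died
  }
  if (outcome == "icu_los") {
    excluded["no_icu"] <- sum(keep & !selected$icu_admitted)
    keep <- keep & selected$icu_admitted
  }
  if (outcome == "readmission_30d") {
    complete <- selected$readmission_info_complete & !is.na(selected$readmitted_30d)
    excluded["incomplete_readmission_info"] <- sum(keep & !complete)
    keep <- keep & complete
  }
  list(cohort = selected[keep, , drop = FALSE], excluded = excluded,
       outcome = outcome)
}

AGE_GROUP_LEVELS <- c("18-34", "35-49", "50-64", "65-79", "80+")

#' Age group at admission
#'
#' @param age integer vector of ages in years; all must be at least 18.
#' @return Factor with levels `18-34`, `35-49`, `50-64`, `65-79`, `80+`.
#' @export
derive_age_group <- function(age) {
  stop_if(any(is.na(age)) || any(age < 18), "ages must be >= 18 and non-missing")
  cut(age, breaks = c(18, 35, 50, 65, 80, Inf), right = FALSE,
      labels = AGE_GROUP_LEVELS)
}

PREV_STAY_LEVELS <- c("0", "1", "2", "3+")

#' Previous-stay category (count of stays in the prior two years)
#'
#' @param n non-negative integer vector.
#' @return Factor with levels `0`, `1`, `2`, `3+`.
#' @export
derive_previous_stay_category <- function(n) {
  stop_if(any(is.na(n)) || any(n < 0), "previous-stay counts must be non-negative")
  factor(ifelse(n >= 3, "3+", as.character(n)), levels = PREV_STAY_LEVELS)
}
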