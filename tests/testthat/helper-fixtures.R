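# Shared fixtures, built in code.

toy_catalogue <- function() {
  read_catalogue(system.file("extdata", "toy_catalogue.csv", package = "raredx"))
}

# A stay record with sensible defaults; override any field.
make_stay <- function(stay_id, patient_id = stay_id, age = 50, sex = "F",
                      admit = "2012-03-01", los = 5, died = FALSE,
                      icu = FALSE, icu_days = 0, unit = "surgical",
                      readmission_info_complete = TRUE) {
  admit <- as.Date(admit)
  data.frame(stay_id = stay_id, patient_id = patient_id,
             age_at_admission = age, sex = sex,
             admit_date = admit, discharge_date = admit + max(1, ceiling(los)),
             died_in_hospital = died, icu_admitted = icu, icu_days = icu_days,
             los_days = los, discharge_year = as.integer(format(admit, "%Y")),
             unit_group = unit,
             readmission_info_complete = readmission_info_complete,
             stringsAsFactors = FALSE)
}

make_stays <- function(...) do.call(rbind, list(...))

make_diagnoses <- function(stay_ids, codes) {
  data.frame(stay_id = rep(stay_ids, lengths(codes)),
             icd10_code = unlist(codes), stringsAsFactors = FALSE)
}

# Random syntactically valid patient codes: letter + 2 digits + 0-2 digits.
random_codes <- function(n) {
  extra <- sample(0:2, n, replace = TRUE)
  suffix <- vapply(extra, function(k) {
    paste(sample(0:9, k, replace = TRUE), collapse = "")
  }, character(1L))
  paste0(sample(LETTERS[1:20], n, replace = TRUE),
         sprintf("%02d", sample(0:99, n, replace = TRUE)), suffix)
}

# Independent brute-force oracle for the wildcard rule: try every truncation
# of the patient code and compare for equality against every catalogue code,
# keeping the longest hit.
oracle_match <- function(patient_code, cat_codes) {
  best <- NA_character_
  for (len in 3:nchar(patient_code)) {
    pre <- substr(patient_code, 1L, len)
    if (pre %in% cat_codes) best <- pre
  }
  best
}

# Small analysis-ready model data for direct model fits.
make_model_data <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    stay_id = sprintf("S%05d", seq_len(n)),
    rare_group = factor(sample(c("0", "1", ">1"), n, TRUE, c(.8, .15, .05)),
                        levels = c("0", "1", ">1")),
    age_group = factor(sample(c("18-34", "35-49", "50-64", "65-79", "80+"), n, TRUE),
                       levels = c("18-34", "35-49", "50-64", "65-79", "80+")),
    sex = factor(sample(c("F", "M"), n, TRUE), levels = c("F", "M")),
    year_c = sample(0:8, n, TRUE),
    nonrare_dx_count = rpois(n, 5),
    unit_group = factor(sample(c("internal-medicine-and-related", "surgical", "other"),
                               n, TRUE),
                        levels = c("internal-medicine-and-related", "surgical", "other")),
    total_stays = 1 + rpois(n, 0.5),
    stringsAsFactors = FALSE)
}
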