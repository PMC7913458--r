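## Delimited-text readers/writers for the pipeline's table formats: stays,
## diagnoses and catalogue as CSV/TSV (dates ISO-8601, booleans 0/1).

pick_sep <- function(path) if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","

#' Read and write the stays table
#'
#' Stays are stored as delimited text with ISO-8601 dates and 0/1 booleans;
#' reading coerces dates to `Date` and booleans to `logical` (empty cells in
#' `readmitted_30d` become `NA`, i.e. unknown).
#'
#' @param path file path (`.csv` or `.tsv`).
#' @return `read_stays()` returns the stays data frame.
#' @export
read_stays <- function(path) {
  df <- read.csv(path, sep = pick_sep(path), stringsAsFactors = FALSE,
                 fileEncoding = "UTF-8")
  miss <- setdiff(STAY_COLUMNS, names(df))
  stop_if(length(miss) > 0L,
          sprintf("stays file %s lacks column(s): %s", path, paste(miss, collapse = ", ")))
  df$admit_date <- as.Date(df$admit_date)
  df$discharge_date <- as.Date(df$discharge_date)
  for (col in c("died_in_hospital", "icu_admitted", "readmission_info_complete")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]] == 1 | df[[col]] == TRUE)
  }
  if ("readmitted_30d" %in% names(df)) {
    v <- df$readmitted_30d
    df$readmitted_30d <- ifelse(is.na(v) | v == "", NA, v == 1 | v == TRUE)
  }
  df
}

#' @rdname read_stays
#' @param stays stays data frame.
#' @export
write_stays <- function(stays, path) {
  df <- stays
  for (col in c("died_in_hospital", "icu_admitted", "readmission_info_complete",
                "readmitted_30d")) {
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
  }
  df$admit_date <- format(as.Date(df$admit_date))
  df$discharge_date <- format(as.Date(df$discharge_date))
  write.table(df, path, sep = pick_sep(path), row.names = FALSE, quote = FALSE,
              na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write the diagnoses table
#'
#' Long format, one row per coded diagnosis: columns `stay_id`, `icd10_code`.
#'
#' @param path file path.
#' @return `read_diagnoses()` returns the diagnoses data frame.
#' @export
read_diagnoses <- function(path) {
  df <- read.csv(path, sep = pick_sep(path), stringsAsFactors = FALSE,
                 fileEncoding = "UTF-8")
  stop_if(!all(c("stay_id", "icd10_code") %in% names(df)),
          sprintf("diagnoses file %s must have columns stay_id, icd10_code", path))
  df
}

#' @rdname read_diagnoses
#' @param diagnoses diagnoses data frame.
#' @export
write_diagnoses <- function(diagnoses, path) {
  write.table(diagnoses, path, sep = pick_sep(path), row.names = FALSE,
              quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a synthetic dataset to a directory
#'
#' Writes `stays.csv`, `diagnoses.csv`, `catalogue.csv` and the generating
#' configuration as `config.json` (so the dataset can be regenerated
#' bit-exactly).
#'
#' @param dataset a `rd_dataset` from [generate_population()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "rd_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stays(dataset$stays, file.path(dir, "stays.csv"))
  write_diagnoses(dataset$diagnoses, file.path(dir, "diagnoses.csv"))
  write_catalogue(dataset$catalogue, file.path(dir, "catalogue.csv"))
  jsonlite::write_json(unclass(dataset$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
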