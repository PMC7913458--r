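## Exposure classification: rare-disease counts per stay and the three-level
## exposure group (0 / 1 / >1 rare diseases).

RARE_GROUP_LEVELS <- c("0", "1", ">1")

#' Exposure group from a rare-disease count
#'
#' @param count non-negative integer vector of rare-disease counts.
#' @return Factor with levels `0`, `1`, `>1`.
#' @export
exposure_group <- function(count) {
  stop_if(any(is.na(count)) || any(count < 0), "counts must be non-negative")
  factor(ifelse(count >= 2, ">1", as.character(count)),
         levels = RARE_GROUP_LEVELS)
}

#' Summarize rare-disease exposure per stay
#'
#' Deduplicates each stay's diagnosis codes at the normalized-code level, maps
#' every distinct code through the wildcard match ([match_diagnosis()]), and
#' counts rare diseases as *distinct matched catalogue entries* -- two codes
#' truncating to the same catalogue code (say D57.1 and D57.3) are one rare
#' disease. Codes with no match make up the non-rare diagnosis count used as
#' the disease-burden covariate.
#'
#' @param diagnoses data frame with columns `stay_id`, `icd10_code` (one row
#'   per coded diagnosis; raw codes are normalized here).
#' @param cat a `rd_catalogue`.
#' @param chapter_table chapter ranges for the chapter flags, see
#'   [icd10_chapters()].
#' @return Data frame with one row per stay: `stay_id`, `rare_count`,
#'   `rare_group`, `matched_codes` (comma-separated catalogue codes),
#'   `nonrare_dx_count`, `chapters` (semicolon-separated chapter labels).
#' @export
summarize_exposure <- function(diagnoses, cat, chapter_table = icd10_chapters()) {
  stop_if(!all(c("stay_id", "icd10_code") %in% names(diagnoses)),
          "diagnoses must have columns stay_id, icd10_code")
  if (nrow(diagnoses) == 0L) {
    return(data.frame(stay_id = character(), rare_count = integer(),
                      rare_group = factor(character(), levels = RARE_GROUP_LEVELS),
                      matched_codes = character(), nonrare_dx_count = integer(),
                      chapters = character(), stringsAsFactors = FALSE))
  }
  code <- tryCatch(normalize_code(diagnoses$icd10_code), error = function(e) {
    raw <- diagnoses$icd10_code
    ok <- vapply(raw, function(z) {
      !inherits(tryCatch(normalize_code(z), error = identity), "error")
    }, logical(1L))
    rd_validation_error(sprintf(
      "malformed diagnosis code(s): %s",
      paste(sprintf("stay %s code %s", diagnoses$stay_id[!ok],
                    sQuote(raw[!ok])), collapse = "; ")))
  })
  dt <- data.table(stay_id = diagnoses$stay_id, code = code)
  dt <- unique(dt, by = c("stay_id", "code"))
  dt[, matched := match_diagnosis(code, cat)]
  entry_chapter <- setNames(chapter_of(cat$code, chapter_table), cat$code)
  nonrare <- dt[is.na(matched), .(nonrare_dx_count = .N), by = stay_id]
  rare <- unique(dt[!is.na(matched), .(stay_id, matched)], by = c("stay_id", "matched"))
  setorder(rare, stay_id, matched)
  rare_agg <- rare[, .(rare_count = .N,
                       matched_codes = paste(matched, collapse = ",")),
                   by = stay_id]
  rare[, chap := unname(entry_chapter[matched])]
  chap <- unique(rare[, .(stay_id, chap)], by = c("stay_id", "chap"))
  setorder(chap, stay_id, chap)
  chap_agg <- chap[, .(chapters = paste(chap, collapse = ";")), by = stay_id]
  agg <- merge(merge(nonrare, rare_agg, by = "stay_id", all = TRUE),
               chap_agg, by = "stay_id", all = TRUE)
  agg[is.na(rare_count), `:=`(rare_count = 0L, matched_codes = "", chapters = "")]
  agg[is.na(nonrare_dx_count), nonrare_dx_count := 0L]
  setorder(agg, stay_id)
  out <- as.data.frame(agg)
  out$rare_count <- as.integer(out$rare_count)
  out$rare_group <- exposure_group(out$rare_count)
  out[, c("stay_id", "rare_count", "rare_group", "matched_codes",
          "nonrare_dx_count", "chapters")]
}
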