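#' ICD-10 chapter ranges
#'
#' Returns the packaged table of ICD-10 chapter ranges (columns
#' `chapter_start`, `chapter_end`, `label`), covering A00--Z99. The labels of
#' the 17 chapters in which rare diseases are tabulated follow the usual
#' chapter headings of the classification.
#'
#' @return Data frame with columns `chapter_start`, `chapter_end`, `label`.
#' @export
icd10_chapters <- function() {
  path <- system.file("extdata", "icd10_chapters.tsv", package = "raredx",
                      mustWork = TRUE)
  read.csv(path, sep = "\t", stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Chapter of an ICD-10 code
#'
#' Assigns each code to the chapter whose range contains its first three
#' characters. Codes falling outside every range are labelled
#' `"unclassified"`.
#'
#' @param codes character vector of normalized ICD-10 codes.
#' @param chapter_table data frame as returned by [icd10_chapters()].
#' @return Character vector of chapter labels.
#' @examples
#' chapter_of(c("D571", "Q05", "A924"))
#' @export
chapter_of <- function(codes, chapter_table = icd10_chapters()) {
  if (length(codes) == 0L) return(character())
  bad <- !grepl(ICD10_PATTERN, codes)
  if (any(bad)) {
    rd_validation_error(sprintf("invalid ICD-10 code(s): %s",
                                paste(sQuote(unique(codes[bad])), collapse = ", ")))
  }
  root <- substr(codes, 1L, 3L)
  out <- rep("unclassified", length(codes))
  for (i in seq_len(nrow(chapter_table))) {
    in_range <- root >= chapter_table$chapter_start[i] &
      root <= chapter_table$chapter_end[i]
    out[in_range] <- chapter_table$label[i]
  }
  out
}
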