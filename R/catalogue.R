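## Rare-disease catalogue: construction, curation and wildcard matching.
##
## Catalogue codes act as prefixes ("wildcards"): a patient's longer, more
## specific ICD-10 code is truncated until it equals a catalogue code, but a
## catalogue code is never truncated to meet a shorter patient code.

ICD10_PATTERN <- "^[A-Z][0-9]{2}[A-Z0-9]{0,4}$"

#' Normalize ICD-10 codes to canonical matching form
#'
#' Strips dots and whitespace and upper-cases, yielding the dot-free canonical
#' form on which all catalogue matching operates (e.g. `"D57.1"` becomes
#' `"D571"`). Codes must then consist of one letter, two digits and up to four
#' further alphanumeric characters.
#'
#' @param x character vector of raw ICD-10 codes.
#' @return Character vector of normalized codes.
#' @examples
#' normalize_code(c("D57.1", "q05", "E11.9"))
#' @export
normalize_code <- function(x) {
  stop_if(!is.character(x) || length(x) == 0L, "expected a character vector of codes")
  out <- toupper(gsub("[.[:space:]]", "", x))
  bad <- !grepl(ICD10_PATTERN, out)
  if (any(bad)) {
    rd_validation_error(sprintf(
      "malformed ICD-10 code(s): %s",
      paste(sQuote(unique(x[bad])), collapse = ", ")))
  }
  out
}

#' Construct a rare-disease catalogue
#'
#' A catalogue is a data frame with one row per rare disease: a normalized
#' ICD-10 `code` (unique), a non-empty `label`, and a `source` tag recording
#' how the entry was curated. Parent/child prefix overlaps between entries are
#' permitted at construction time (they are reported) and are resolved by
#' [consolidate_codes()].
#'
#' @param code character vector of ICD-10 codes (normalized internally).
#' @param label character vector of disease names.
#' @param source curation source, one of `"orphadata-confirmed"`, `"walker"`,
#'   `"manual"`; recycled.
#' @param quiet suppress the prefix-overlap report.
#' @return A `rd_catalogue` data frame with columns `code`, `label`, `source`.
#' @examples
#' catalogue(c("D57", "Q05"), c("Sickle-cell disorders", "Spina bifida"))
#' @export
catalogue <- function(code, label, source = "manual", quiet = FALSE) {
  stop_if(length(code) != length(label), "code and label lengths differ")
  if (length(code) == 0L) {
    out <- data.frame(code = character(), label = character(),
                      source = character(), stringsAsFactors = FALSE)
    class(out) <- c("rd_catalogue", "data.frame")
    return(out)
  }
  code <- normalize_code(code)
  stop_if(anyDuplicated(code) > 0L, sprintf(
    "duplicate catalogue code(s): %s",
    paste(unique(code[duplicated(code)]), collapse = ", ")))
  label <- as.character(label)
  stop_if(any(is.na(label) | !nzchar(trimws(label))), "catalogue labels must be non-empty")
  source <- rep_len(as.character(source), length(code))
  stop_if(!all(source %in% c("orphadata-confirmed", "walker", "manual")),
          "source must be one of 'orphadata-confirmed', 'walker', 'manual'")
  out <- data.frame(code = code, label = label, source = source,
                    stringsAsFactors = FALSE)
  out <- out[order(out$code), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rd_catalogue", "data.frame")
  n_overlap <- count_prefix_overlaps(out$code)
  if (n_overlap > 0L && !quiet) {
    message(sprintf(
      "catalogue has %d parent/child prefix overlap(s); run consolidate_codes() to resolve",
      n_overlap))
  }
  out
}

## number of (parent, child) pairs where one code is a strict prefix of another
count_prefix_overlaps <- function(codes) {
  n <- 0L
  for (len in unique(nchar(codes))) {
    parents <- codes[nchar(codes) == len]
    longer <- codes[nchar(codes) > len]
    if (length(parents) && length(longer)) {
      n <- n + sum(substr(longer, 1L, len) %in% parents)
    }
  }
  n
}

#' @export
print.rd_catalogue <- function(x, ...) {
  cat(sprintf("Rare-disease catalogue: %d entries\n", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... and %d more entries\n", nrow(x) - 10L))
  invisible(x)
}

#' Read or write a catalogue as delimited text
#'
#' Flat-table format with a header and columns `icd10_code,label[,source]`;
#' comma- or tab-separated by file extension (`.tsv`/`.tab` means tab).
#'
#' @param path file path.
#' @return `read_catalogue()` returns a `rd_catalogue`.
#' @export
read_catalogue <- function(path) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 fileEncoding = "UTF-8")
  stop_if(!all(c("icd10_code", "label") %in% names(df)),
          sprintf("catalogue file %s must have columns icd10_code,label[,source]", path))
  catalogue(df$icd10_code, df$label, source = df$source %||% "manual")
}

#' @rdname read_catalogue
#' @param cat a `rd_catalogue`.
#' @export
write_catalogue <- function(cat, path) {
  stopifnot(inherits(cat, "rd_catalogue"))
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- data.frame(icd10_code = cat$code, label = cat$label,
                   source = cat$source, stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE,
              fileEncoding = "UTF-8")
  invisible(path)
}

norm_description <- function(x) tolower(gsub("[[:space:]]+", " ", trimws(x)))

#' Merge candidate codes into a catalogue after description validation
#'
#' Candidate (code, description) pairs -- e.g. drawn from the Orphanet/
#' Orphadata ICD-10 mapping -- are added to `base` only when the candidate's
#' description agrees with the official reference description of that code
#' (case-insensitive, whitespace-normalized). This guards against mapping
#' errors where a rare-disease name is attached to a code that officially
#' denotes a common condition. Codes absent from the lookup are reported, not
#' silently dropped.
#'
#' @param base a `rd_catalogue`.
#' @param candidates data frame with columns `code` and `description`.
#' @param lookup reference descriptions: either a named character vector
#'   (names = codes) or a data frame with columns `code`, `description`.
#' @return List with elements `catalogue` (the merged `rd_catalogue`),
#'   `rejected` (data frame: code, candidate_description,
#'   official_description) and `uncovered` (candidates missing from `lookup`).
#' @export
merge_catalogues <- function(base, candidates, lookup) {
  stopifnot(inherits(base, "rd_catalogue"))
  empty_rej <- data.frame(code = character(), candidate_description = character(),
                          official_description = character(), stringsAsFactors = FALSE)
  empty_unc <- data.frame(code = character(), candidate_description = character(),
                          stringsAsFactors = FALSE)
  if (is.null(candidates) || nrow(candidates) == 0L) {
    return(list(catalogue = base, rejected = empty_rej, uncovered = empty_unc))
  }
  stop_if(!all(c("code", "description") %in% names(candidates)),
          "candidates must have columns code, description")
  if (is.data.frame(lookup)) {
    stop_if(!all(c("code", "description") %in% names(lookup)),
            "lookup must have columns code, description")
    lookup <- setNames(as.character(lookup$description), normalize_code(lookup$code))
  } else {
    stop_if(is.null(names(lookup)), "lookup must be named by ICD-10 code")
    names(lookup) <- normalize_code(names(lookup))
  }
  cand_code <- normalize_code(candidates$code)
  cand_desc <- as.character(candidates$description)
  official <- unname(lookup[cand_code])
  uncovered_idx <- is.na(official)
  uncovered <- data.frame(code = cand_code[uncovered_idx],
                          candidate_description = cand_desc[uncovered_idx],
                          stringsAsFactors = FALSE)
  if (nrow(uncovered)) {
    message(sprintf("merge_catalogues: %d candidate code(s) not covered by the description lookup: %s",
                    nrow(uncovered), paste(uncovered$code, collapse = ", ")))
  }
  keep <- !uncovered_idx
  ok <- keep & norm_description(cand_desc) == norm_description(official)
  rejected <- data.frame(code = cand_code[keep & !ok],
                         candidate_description = cand_desc[keep & !ok],
                         official_description = official[keep & !ok],
                         stringsAsFactors = FALSE)
  add <- ok & !(cand_code %in% base$code)
  add <- add & !duplicated(cand_code)
  merged <- catalogue(c(base$code, cand_code[add]),
                      c(base$label, cand_desc[add]),
                      c(base$source, rep("orphadata-confirmed", sum(add))),
                      quiet = TRUE)
  list(catalogue = merged, rejected = rejected, uncovered = uncovered)
}

#' Consolidate child codes under their parent code
#'
#' Whenever the catalogue contains every valid child of a 3- or 4-character
#' parent code (per `children_index`), the children are replaced by the single
#' parent entry; this is applied repeatedly until a fixed point. Truncating
#' "if possible" in this sense never changes which patient codes match, it
#' only removes redundancy.
#'
#' @param cat a `rd_catalogue`.
#' @param children_index named list: parent code -> character vector of all
#'   valid child codes of that parent in the coding system.
#' @param parent_labels optional named character vector of labels for parent
#'   codes introduced by consolidation; defaults to the first child's label.
#' @return The consolidated `rd_catalogue`.
#' @export
consolidate_codes <- function(cat, children_index, parent_labels = NULL) {
  stopifnot(inherits(cat, "rd_catalogue"))
  if (nrow(cat) == 0L || length(children_index) == 0L) return(cat)
  stop_if(is.null(names(children_index)), "children_index must be named by parent code")
  parents <- normalize_code(names(children_index))
  kids <- lapply(children_index, normalize_code)
  repeat {
    changed <- FALSE
    for (i in seq_along(parents)) {
      k <- kids[[i]]
      if (length(k) == 0L) next
      if (all(k %in% cat$code) && any(k %in% cat$code)) {
        p <- parents[i]
        keep <- !(cat$code %in% k)
        lab <- if (p %in% cat$code) {
          cat$label[cat$code == p]
        } else if (!is.null(parent_labels) && p %in% names(parent_labels)) {
          unname(parent_labels[p])
        } else {
          cat$label[cat$code == k[k %in% cat$code][1L]][1L]
        }
        src <- if (p %in% cat$code) cat$source[cat$code == p] else {
          names(sort(table(cat$source[!keep]), decreasing = TRUE))[1L]
        }
        new_code <- c(cat$code[keep], if (!p %in% cat$code) p)
        new_label <- c(cat$label[keep], if (!p %in% cat$code) lab)
        new_source <- c(cat$source[keep], if (!p %in% cat$code) src)
        cat <- catalogue(new_code, new_label, new_source, quiet = TRUE)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  ## drop entries shadowed by a strict-prefix ancestor: they add no coverage
  ## and would double-count one disease as two catalogue entries
  shadowed <- rep(FALSE, nrow(cat))
  for (len in sort(unique(nchar(cat$code)))) {
    longer <- nchar(cat$code) > len
    shadowed[longer] <- shadowed[longer] |
      substr(cat$code[longer], 1L, len) %in% cat$code[nchar(cat$code) == len]
  }
  if (any(shadowed)) {
    cat <- catalogue(cat$code[!shadowed], cat$label[!shadowed],
                     cat$source[!shadowed], quiet = TRUE)
  }
  cat
}

#' Match patient diagnosis codes against the catalogue (wildcard rule)
#'
#' Returns, for each patient code, the catalogue code that is the *longest
#' prefix* of the patient code (exact equality counts as a prefix), or `NA`
#' when no catalogue code is a prefix. The match is asymmetric: a patient code
#' is truncated towards catalogue codes, but a catalogue code is never
#' truncated, so a catalogue code longer than the patient code can never
#' match. For example, patient `D571` matches catalogue entry `D57`, while
#' patient `A92` does not match catalogue entry `A924`.
#'
#' @param codes character vector of normalized patient ICD-10 codes.
#' @param cat a `rd_catalogue`.
#' @return Character vector the length of `codes`: the matched catalogue code
#'   or `NA_character_`.
#' @examples
#' cat <- catalogue(c("D57", "A924"), c("Sickle-cell disorders", "Rift Valley fever"))
#' match_diagnosis(c("D571", "A92", "A9240"), cat)
#' @export
match_diagnosis <- function(codes, cat) {
  stopifnot(inherits(cat, "rd_catalogue"))
  if (length(codes) == 0L) return(character())
  bad <- !grepl(ICD10_PATTERN, codes)
  if (any(bad)) {
    rd_validation_error(sprintf(
      "patient codes must be normalized ICD-10 codes; offending value(s): %s",
      paste(sQuote(unique(codes[bad])), collapse = ", ")))
  }
  out <- rep(NA_character_, length(codes))
  if (nrow(cat) == 0L) return(out)
  nc <- nchar(codes)
  for (len in sort(unique(nchar(cat$code)))) {
    idx <- which(nc >= len)
    if (!length(idx)) next
    hit <- match(substr(codes[idx], 1L, len), cat$code)
    found <- !is.na(hit) & nchar(cat$code[hit]) == len
    out[idx[found]] <- cat$code[hit[found]]
  }
  out
}

#' Flag catalogue entries with high observed prevalence for manual review
#'
#' A rare disease is conventionally one affecting fewer than 1 in 2,000
#' people; catalogue entries whose observed in-population prevalence reaches
#' that threshold deserve a detailed second look (miscoded or over-broad
#' codes). This is a review report only -- nothing is removed.
#'
#' @param cat a `rd_catalogue`.
#' @param matched_counts named integer vector: catalogue code -> number of
#'   patients matched.
#' @param population_size total number of patients screened.
#' @param threshold prevalence trigger, default `1/2000` (inclusive).
#' @return Data frame of flagged entries (code, label, count, prevalence),
#'   sorted by descending prevalence.
#' @export
flag_high_prevalence <- function(cat, matched_counts, population_size,
                                 threshold = 1 / 2000) {
  stopifnot(inherits(cat, "rd_catalogue"))
  stop_if(!is.numeric(population_size) || population_size <= 0,
          "population_size must be positive")
  stop_if(any(matched_counts < 0), "matched counts must be non-negative")
  counts <- matched_counts[names(matched_counts) %in% cat$code]
  prev <- as.numeric(counts) / population_size
  flag <- prev >= threshold
  out <- data.frame(code = names(counts)[flag],
                    label = cat$label[match(names(counts)[flag], cat$code)],
                    count = as.integer(counts[flag]),
                    prevalence = prev[flag],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$prevalence, out$code), , drop = FALSE]
  rownames(out) <- NULL
  out
}
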