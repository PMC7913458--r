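test_that("normalize_code canonicalizes and is idempotent", {
  expect_equal(normalize_code("D57.1"), "D571")
  expect_equal(normalize_code("q05"), "Q05")
  expect_equal(normalize_code("E11.9"), "E119")
  expect_equal(normalize_code(" a00 "), "A00")

  set.seed(11)
  raw <- random_codes(500)
  messy <- paste0(tolower(substr(raw, 1, 1)),
                  substr(raw, 2, 3),
                  ifelse(nchar(raw) > 3, ".", ""),
                  substring(raw, 4))
  once <- normalize_code(messy)
  expect_identical(normalize_code(once), once)
  expect_true(all(grepl("^[A-Z][0-9]{2}[A-Z0-9]{0,4}$", once)))
})

test_that("malformed codes are rejected with the offending value", {
  expect_error(normalize_code("XX"), "XX")
  expect_error(normalize_code(c("D57", "5D7")), "5D7")
  expect_error(normalize_code("D5"), "D5")
  expect_error(normalize_code("D57123456"), "D57123456")
})

test_that("catalogue construction enforces unique codes and non-empty labels", {
  cat0 <- catalogue(c("D57", "q05.1"), c("Sickle-cell disorders", "Spina bifida cervical"))
  expect_s3_class(cat0, "rd_catalogue")
  expect_setequal(cat0$code, c("D57", "Q051"))
  expect_error(catalogue(c("D57", "D57.0", "D570"), rep("x", 3)), "duplicate")
  expect_error(catalogue("D57", "  "), "non-empty")
  expect_message(catalogue(c("D57", "D571"), c("a", "b")), "prefix overlap")
  empty <- catalogue(character(), character())
  expect_equal(nrow(empty), 0L)
})

test_that("description-validated merge accepts matches and reports the rest", {
  base <- catalogue("D57", "Sickle-cell disorders", source = "walker")
  lookup <- c(E119 = "Type 2 diabetes mellitus without complications",
              A924 = "Rift Valley fever")
  candidates <- data.frame(
    code = c("E11.9", "A92.4", "B99"),
    description = c("Maturity Onset Diabetes of the Young",
                    "rift valley  FEVER",   # case/whitespace must not matter
                    "Some unknown disease"),
    stringsAsFactors = FALSE)
  res <- suppressMessages(merge_catalogues(base, candidates, lookup))
  expect_setequal(res$catalogue$code, c("D57", "A924"))
  expect_equal(res$catalogue$source[res$catalogue$code == "A924"],
               "orphadata-confirmed")
  expect_equal(res$rejected$code, "E119")
  expect_equal(res$rejected$official_description,
               "Type 2 diabetes mellitus without complications")
  expect_equal(res$uncovered$code, "B99")

  unchanged <- merge_catalogues(base, NULL, lookup)
  expect_identical(unchanged$catalogue, base)
  empty_cand <- candidates[0, ]
  expect_identical(merge_catalogues(base, empty_cand, lookup)$catalogue, base)
})

test_that("complete child sets consolidate to the parent code", {
  kids <- sprintf("Q05%d", 0:9)
  idx <- list(Q05 = kids)
  full <- catalogue(kids, paste("Spina bifida subtype", 0:9))
  out <- consolidate_codes(full, idx, parent_labels = c(Q05 = "Spina bifida"))
  expect_equal(out$code, "Q05")
  expect_equal(out$label, "Spina bifida")

  partial <- catalogue(c("Q050", "Q051"), c("a", "b"))
  expect_identical(consolidate_codes(partial, idx)$code, c("Q050", "Q051"))

  empty <- catalogue(character(), character())
  expect_equal(nrow(consolidate_codes(empty, idx)), 0L)
})

test_that("consolidation is idempotent, never grows, and preserves coverage", {
  set.seed(21)
  kids4 <- function(root) sprintf("%s%d", root, 0:9)
  idx <- list(Q05 = kids4("Q05"), D57 = kids4("D57"), E75 = kids4("E75"))
  codes <- unique(c(kids4("Q05"), sample(kids4("D57"), 6), "E75", "E750", "K74"))
  cat0 <- suppressMessages(catalogue(codes, paste("dx", codes)))
  once <- consolidate_codes(cat0, idx)
  twice <- consolidate_codes(once, idx)
  expect_identical(once, twice)
  expect_lte(nrow(once), nrow(cat0))

  # coverage: every probe code matches (or not) identically before and after
  probes <- c(random_codes(2000), paste0(codes, "1"), codes)
  before <- !is.na(match_diagnosis(probes, cat0))
  after <- !is.na(match_diagnosis(probes, once))
  expect_identical(after, before)
  # post-consolidation invariant: no entry is a strict prefix of another
  pairs <- outer(once$code, once$code, function(a, b) {
    a != b & substr(b, 1, nchar(a)) == a
  })
  expect_false(any(pairs))
})

test_that("wildcard matching truncates patient codes, never catalogue codes", {
  cat0 <- catalogue(c("D57", "A924", "Q05"),
                    c("Sickle-cell disorders", "Rift Valley fever", "Spina bifida"))
  expect_equal(match_diagnosis("D571", cat0), "D57")   # patient code truncated
  expect_true(is.na(match_diagnosis("A92", cat0)))     # catalogue code never truncated
  expect_equal(match_diagnosis("Q05", cat0), "Q05")    # exact equality counts
  expect_equal(match_diagnosis("A9240", cat0), "A924")
  with_children <- suppressMessages(
    catalogue(c("D57", "D571"), c("Sickle-cell disorders", "without crisis")))
  expect_equal(match_diagnosis("D5712", with_children), "D571") # longest prefix wins
  expect_error(match_diagnosis("d57.1", cat0), "normalized")
})

test_that("matching agrees with the brute-force truncate-and-compare oracle", {
  set.seed(31)
  for (rep in 1:20) {
    cat_codes <- unique(random_codes(30))
    cat0 <- suppressMessages(catalogue(cat_codes, paste("dx", cat_codes)))
    probes <- random_codes(100)
    got <- match_diagnosis(probes, cat0)
    want <- vapply(probes, oracle_match, character(1L), cat_codes = cat0$code,
                   USE.NAMES = FALSE)
    expect_identical(got, want)
  }
})

test_that("adding a longer matching code never unmatches a patient code", {
  set.seed(41)
  cat_codes <- unique(random_codes(40))
  cat_codes <- cat_codes[nchar(cat_codes) <= 4]
  cat0 <- suppressMessages(catalogue(cat_codes, paste("dx", cat_codes)))
  probes <- unique(paste0(sample(cat_codes, 200, TRUE),
                          sample(0:9, 200, TRUE)))
  before <- match_diagnosis(probes, cat0)
  longer <- paste0(sample(cat_codes, 10), "7")
  longer <- setdiff(longer, cat0$code)
  cat1 <- suppressMessages(catalogue(c(cat0$code, longer),
                                     c(cat0$label, paste("dx", longer))))
  after <- match_diagnosis(probes, cat1)
  was_matched <- !is.na(before)
  expect_true(all(!is.na(after[was_matched])))
  # and the new matches are never shorter than the old ones
  expect_true(all(nchar(after[was_matched]) >= nchar(before[was_matched])))
})

test_that("high-prevalence review flags use the inclusive 1/2000 threshold", {
  cat0 <- toy_catalogue()
  counts <- c(D57 = 100L, Q05 = 10L, A924 = 50L)
  out <- flag_high_prevalence(cat0, counts, population_size = 100000)
  expect_setequal(out$code, c("D57", "A924"))   # 1/1000 and exactly 1/2000
  expect_equal(out$code[1], "D57")              # sorted by descending prevalence
  expect_equal(out$prevalence, c(1e-3, 5e-4))
  expect_error(flag_high_prevalence(cat0, c(D57 = -1L), 1000), "non-negative")
  expect_error(flag_high_prevalence(cat0, counts, 0), "positive")
})

test_that("chapter lookup places codes in their ICD-10 chapter ranges", {
  expect_match(chapter_of("D571"), "blood-forming organs")
  expect_match(chapter_of("Q05"), "Congenital malformations")
  expect_match(chapter_of("A924"), "infectious and parasitic")
  expect_match(chapter_of("D49"), "unclassified")  # gap between D48 and D50
  expect_equal(length(chapter_of(c("A00", "Z99", "J45"))), 3L)
})

test_that("catalogue round-trips through its delimited format", {
  cat0 <- toy_catalogue()
  expect_equal(nrow(cat0), 10L)
  path <- file.path(tempdir(), "cat_roundtrip.tsv")
  write_catalogue(cat0, path)
  expect_identical(read_catalogue(path), cat0)
})
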