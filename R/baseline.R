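## Baseline characteristics table stratified by exposure group, with
## chi-squared tests for categorical rows and Kruskal-Wallis tests for
## continuous rows.

#' Baseline characteristics by exposure group
#'
#' Summarizes the one-stay-per-patient cohort per exposure group (0 / 1 / >1
#' rare diseases): counts and percentages for age groups, sex, per-chapter
#' rare-disease flags, in-hospital deaths, 30-day readmission status
#' (No/Unknown/Yes) and ICU admissions; median and interquartile range for
#' the non-rare diagnosis count and length of stay; median, IQR, mean and SD
#' for ICU days. Each categorical variable gets a chi-squared p-value, each
#' continuous variable a Kruskal-Wallis p-value. Percentages for an empty
#' group are `NA` (undefined), never zero.
#'
#' @param data model data from [prepare_model_data()].
#' @return Long-format data frame: `variable`, `level`, `type`, `group`,
#'   `group_n`, `count`, `pct`, `median`, `q1`, `q3`, `mean`, `sd`,
#'   `p_value`.
#' @export
baseline_table <- function(data) {
  g <- data$rare_group
  groups <- RARE_GROUP_LEVELS
  group_n <- as.integer(table(factor(g, levels = groups)))
  pct_of <- function(count, gi) {
    if (group_n[gi] == 0L) NA_real_ else 100 * count / group_n[gi]
  }
  rows <- list()
  add_cat <- function(variable, x, levels_shown = NULL) {
    x <- factor(x)
    if (!is.null(levels_shown)) x <- factor(x, levels = levels_shown)
    p <- tryCatch(suppressWarnings(chisq.test(table(x, g))$p.value),
                  error = function(e) NA_real_)
    for (lev in levels(x)) {
      for (gi in seq_along(groups)) {
        cnt <- sum(x == lev & g == groups[gi], na.rm = TRUE)
        rows[[length(rows) + 1L]] <<- data.frame(
          variable = variable, level = lev, type = "categorical",
          group = groups[gi], group_n = group_n[gi],
          count = cnt, pct = pct_of(cnt, gi),
          median = NA_real_, q1 = NA_real_, q3 = NA_real_,
          mean = NA_real_, sd = NA_real_, p_value = p,
          stringsAsFactors = FALSE)
      }
    }
  }
  add_cont <- function(variable, x, with_mean = FALSE) {
    p <- tryCatch(suppressWarnings(kruskal.test(x, g)$p.value),
                  error = function(e) NA_real_)
    for (gi in seq_along(groups)) {
      xi <- x[g == groups[gi]]
      xi <- xi[!is.na(xi)]
      q <- if (length(xi)) quantile(xi, c(.25, .5, .75), names = FALSE) else rep(NA_real_, 3L)
      rows[[length(rows) + 1L]] <<- data.frame(
        variable = variable, level = NA_character_, type = "continuous",
        group = groups[gi], group_n = group_n[gi],
        count = length(xi), pct = NA_real_,
        median = q[2L], q1 = q[1L], q3 = q[3L],
        mean = if (with_mean && length(xi)) mean(xi) else NA_real_,
        sd = if (with_mean && length(xi) > 1L) sd(xi) else NA_real_,
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  add_cat("age_group", data$age_group)
  add_cat("sex", data$sex)
  add_cont("nonrare_dx_count", data$nonrare_dx_count)
  chapter_levels <- sort(unique(unlist(strsplit(data$chapters[nzchar(data$chapters)], ";",
                                                fixed = TRUE))))
  for (ch in chapter_levels) {
    flag <- vapply(strsplit(data$chapters, ";", fixed = TRUE),
                   function(z) ch %in% z, logical(1L))
    p <- tryCatch(suppressWarnings(chisq.test(table(flag, g))$p.value),
                  error = function(e) NA_real_)
    for (gi in seq_along(groups)) {
      cnt <- sum(flag & g == groups[gi])
      rows[[length(rows) + 1L]] <- data.frame(
        variable = paste0("chapter: ", ch), level = "yes", type = "categorical",
        group = groups[gi], group_n = group_n[gi],
        count = cnt, pct = pct_of(cnt, gi),
        median = NA_real_, q1 = NA_real_, q3 = NA_real_,
        mean = NA_real_, sd = NA_real_, p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  add_cat("died_in_hospital", ifelse(data$died_in_hospital, "yes", "no"),
          levels_shown = c("no", "yes"))
  if ("readmitted_30d" %in% names(data)) {
    status <- ifelse(is.na(data$readmitted_30d), "Unknown",
                     ifelse(data$readmitted_30d, "Yes", "No"))
    add_cat("readmission_30d", status, levels_shown = c("No", "Unknown", "Yes"))
  }
  add_cont("los_days", data$los_days)
  add_cat("icu_admitted", ifelse(data$icu_admitted, "yes", "no"),
          levels_shown = c("no", "yes"))
  add_cont("icu_days", data$icu_days, with_mean = TRUE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format a baseline table for display
#'
#' Renders the long-format [baseline_table()] output as a wide character
#' table with one column per exposure group, percentages rounded to one
#' decimal and continuous summaries shown as `median [q1, q3]` (plus
#' `mean (sd)` where computed).
#'
#' @param bt output of [baseline_table()].
#' @return Data frame of character columns `variable`, `level`, one column
#'   per group, and `p_value`.
#' @export
format_baseline_table <- function(bt) {
  key <- paste(bt$variable, bt$level, sep = " | ")
  keys <- unique(key)
  fmt_cell <- function(r) {
    if (r$type == "categorical") {
      if (is.na(r$pct)) sprintf("%d (NA)", r$count)
      else sprintf("%d (%.1f)", r$count, r$pct)
    } else {
      base <- sprintf("%.2f [%.2f, %.2f]", r$median, r$q1, r$q3)
      if (!is.na(r$mean)) paste0(base, sprintf("; %.2f (%.2f)", r$mean, r$sd))
      else base
    }
  }
  rows <- lapply(keys, function(k) {
    sub <- bt[key == k, , drop = FALSE]
    cells <- vapply(RARE_GROUP_LEVELS, function(gr) {
      r <- sub[sub$group == gr, , drop = FALSE]
      if (nrow(r) == 0L) "" else fmt_cell(r[1L, ])
    }, character(1L))
    data.frame(variable = sub$variable[1L],
               level = ifelse(is.na(sub$level[1L]), "", sub$level[1L]),
               `0` = cells[[1L]], `1` = cells[[2L]], `>1` = cells[[3L]],
               p_value = format.pval(sub$p_value[1L], digits = 3L),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
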