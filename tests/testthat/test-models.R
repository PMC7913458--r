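test_that("2x2 odds ratios reproduce the published unadjusted estimates", {
  # one rare disease vs none: deaths/survivors from the group-wise counts
  one <- or_from_table(two_by_two(1082, 15969, 3202, 143602))
  expect_equal(round(one$estimate, 2), 3.04)
  expect_equal(round(one$ci_low, 2), 2.83)
  expect_equal(round(one$ci_high, 2), 3.26)
  # more than one rare disease vs none
  multi <- or_from_table(two_by_two(262, 1791, 3202, 143602))
  expect_equal(round(multi$estimate, 2), 6.56)
  expect_equal(round(multi$ci_low, 2), 5.74)
  expect_equal(round(multi$ci_high, 2), 7.50)
})

test_that("symmetric tables give OR 1 and zero cells fail loudly", {
  expect_equal(or_from_table(two_by_two(1, 1, 1, 1))$estimate, 1.0)
  expect_error(or_from_table(two_by_two(0, 1, 1, 1)), "zero cell")
  expect_error(or_from_table(two_by_two(1, 0, 1, 1)), "b")
  expect_error(two_by_two(1, -1, 1, 1), "non-negative")
})

test_that("cross-product OR equals the brute-force odds computation on small tables", {
  # exhaustive over all tables with cells 1..20, via vectorized arithmetic
  grid <- expand.grid(a = 1:20, b = 1:20, c = 1:20, d = 1:20)
  cross <- with(grid, (a * d) / (b * c))
  p1 <- with(grid, a / (a + b))
  p0 <- with(grid, c / (c + d))
  odds_ratio <- (p1 / (1 - p1)) / (p0 / (1 - p0))
  expect_equal(cross, odds_ratio, tolerance = 1e-12)
  # and or_from_table agrees with the oracle on a random subset of tables
  set.seed(61)
  idx <- sample(nrow(grid), 200)
  got <- vapply(idx, function(i) {
    or_from_table(do.call(two_by_two, as.list(grid[i, ])))$estimate
  }, numeric(1L))
  expect_equal(got, odds_ratio[idx], tolerance = 1e-12)
})

test_that("logistic fit with one binary covariate reproduces the 2x2 OR", {
  t <- two_by_two(40, 110, 25, 325)
  d <- data.frame(
    y = rep(c(1, 0, 1, 0), c(40, 110, 25, 325)),
    exposed = rep(c(1, 1, 0, 0), c(40, 110, 25, 325)))
  d$died_in_hospital <- d$y
  spec <- model_spec("mortality", covariates = "exposed")
  fit <- fit_logistic(d, spec)
  closed <- or_from_table(t)
  expect_equal(fit$estimate[fit$term == "exposed"], closed$estimate,
               tolerance = 1e-7)
})

test_that("null covariates estimate OR near 1 with covering intervals", {
  set.seed(71)
  n <- 20000
  d <- make_model_data(n)
  d$noise <- rnorm(n)                       # truly unrelated covariate
  d$died_in_hospital <- rbinom(n, 1, 0.05)  # outcome independent of everything
  fit <- fit_logistic(d, model_spec("mortality", covariates = c("rare_group", "noise")))
  noise_row <- fit[fit$term == "noise", ]
  expect_lt(abs(log(noise_row$estimate)), 0.1)
  expect_true(noise_row$ci_low < 1 && noise_row$ci_high > 1)
})

test_that("log-linear fits recover null effects and are scale equivariant", {
  set.seed(81)
  n <- 5000
  d <- make_model_data(n)
  d$los_days <- exp(log(5) + 0.2 * (d$rare_group == "1") + rnorm(n, 0, 0.5))
  spec <- model_spec("los", covariates = c("rare_group", "sex"))
  fit1 <- fit_log_linear(d, spec)
  sex_row <- fit1[fit1$term == "sexM", ]
  expect_lt(abs(log(sex_row$estimate)), 0.1)  # no sex effect was simulated
  # multiplying the outcome by a constant moves only the intercept
  d2 <- d; d2$los_days <- d$los_days * 7.3
  fit2 <- fit_log_linear(d2, spec)
  expect_equal(fit1$estimate, fit2$estimate, tolerance = 1e-12)
  expect_equal(fit1$ci_low, fit2$ci_low, tolerance = 1e-12)
  # non-positive outcomes must have been excluded upstream
  d3 <- d; d3$los_days[1] <- 0
  expect_error(fit_log_linear(d3, spec), "non-positive")
})

test_that("Wald intervals are symmetric around the estimate on the log scale", {
  set.seed(91)
  d <- make_model_data(3000)
  d$died_in_hospital <- rbinom(3000, 1, plogis(-3 + 0.5 * (d$rare_group != "0")))
  d$los_days <- exp(rnorm(3000, log(5), 0.6))
  for (fit in list(
    fit_logistic(d, model_spec("mortality", covariates = c("rare_group", "sex"))),
    fit_log_linear(d, model_spec("los", covariates = c("rare_group", "sex"))))) {
    expect_equal(log(fit$ci_low) + log(fit$ci_high), 2 * log(fit$estimate),
                 tolerance = 1e-10)
    expect_true(all(fit$ci_low <= fit$estimate & fit$estimate <= fit$ci_high))
    expect_true(all(fit$ci_low > 0))
  }
})

test_that("sex-subgroup models drop the sex covariate and keep the rest", {
  set.seed(101)
  d <- make_model_data(4000)
  d$died_in_hospital <- rbinom(4000, 1, 0.05)
  fit <- fit_logistic(d, model_spec("mortality", subgroup_sex = "F"))
  expect_false(any(grepl("^sex", fit$term)))
  expect_true(any(grepl("^rare_group", fit$term)))
  expect_equal(unique(fit$model), "mortality_f")
  expect_equal(unique(fit$n), sum(d$sex == "F"))
})

test_that("separation and degenerate factors raise explicit diagnostics", {
  d <- make_model_data(200)
  d$died_in_hospital <- as.integer(d$sex == "M")  # perfectly separated
  expect_error(fit_logistic(d, model_spec("mortality", covariates = "sex")),
               "separation")
  d2 <- make_model_data(200)
  d2$died_in_hospital <- rbinom(200, 1, 0.2)
  d2$unit_group <- factor("surgical",
                          levels = levels(d2$unit_group))
  expect_error(fit_logistic(d2, model_spec("mortality",
                                           covariates = c("rare_group", "unit_group"))),
               "degenerate")
})

test_that("sensitivity analyses modify the mortality model as named", {
  set.seed(111)
  n <- 8000
  d <- make_model_data(n)
  d$died_in_hospital <- rbinom(n, 1, plogis(-3.5 + 0.6 * (d$rare_group == "1") +
                                              1.0 * (d$rare_group == ">1") +
                                              0.15 * d$nonrare_dx_count))
  base <- fit_logistic(d, model_spec("mortality"))
  sc <- run_sensitivity("stay-count-adjusted", d)
  expect_true("total_stays" %in% sc$term)
  expect_equal(unique(sc$model), "mortality_stay_count_adjusted")
  # a null stay-count covariate leaves the exposure ORs essentially unchanged
  or_base <- base$estimate[base$term == "rare_group1"]
  or_sc <- sc$estimate[sc$term == "rare_group1"]
  expect_lt(abs(log(or_sc) - log(or_base)), 0.05)

  ia <- run_sensitivity("rare-by-nonrare-interaction", d)
  ia_terms <- ia$term[grepl(":", ia$term)]
  expect_length(ia_terms, 2L)
  # no interaction was simulated: its intervals should cover 1
  expect_true(all(ia$ci_low[ia$term %in% ia_terms] < 1 &
                    ia$ci_high[ia$term %in% ia_terms] > 1))

  iu <- run_sensitivity("rare-by-unit-interaction", d)
  expect_true(any(grepl("rare_group.*:unit_group", iu$term)))

  d_one_unit <- d
  d_one_unit$unit_group <- factor("surgical", levels = levels(d$unit_group))
  expect_error(run_sensitivity("rare-by-unit-interaction", d_one_unit), "degenerate")
  expect_error(run_sensitivity("leave-one-out", d), "unknown sensitivity")
})

test_that("baseline table summarizes groups with tests and honest percentages", {
  set.seed(121)
  n <- 3000
  d <- make_model_data(n)
  d$age_at_admission <- sample(18:90, n, TRUE)
  d$age_group <- derive_age_group(d$age_at_admission)
  d$died_in_hospital <- rbinom(n, 1, 0.03) == 1
  d$icu_admitted <- rbinom(n, 1, 0.12) == 1
  d$icu_days <- ifelse(d$icu_admitted, rexp(n, 1 / 2), 0)
  d$los_days <- rexp(n, 1 / 6) + 1
  d$readmitted_30d <- ifelse(runif(n) < 0.01, NA, rbinom(n, 1, 0.05) == 1)
  d$chapters <- ifelse(d$rare_group == "0", "",
                       ifelse(d$rare_group == "1", "Neoplasms",
                              "Neoplasms;Diseases of the nervous system"))
  bt <- baseline_table(d)
  # percentages recompute from counts and group sizes
  cat_rows <- bt[bt$type == "categorical" & !is.na(bt$pct), ]
  expect_equal(cat_rows$pct, 100 * cat_rows$count / cat_rows$group_n)
  # every variable carries a p-value of the right test family
  expect_true(all(is.finite(bt$p_value[bt$variable == "sex"])))
  expect_true(all(is.finite(bt$p_value[bt$variable == "los_days"])))
  # ICU days report mean and SD in addition to the quartiles
  icu_rows <- bt[bt$variable == "icu_days", ]
  expect_true(all(is.finite(icu_rows$mean)))
  # readmission has the three-level status row including Unknown
  expect_setequal(bt$level[bt$variable == "readmission_30d"],
                  c("No", "Unknown", "Yes"))
  # empty group: percentages undefined, not zero
  d0 <- d[d$rare_group != ">1", ]
  bt0 <- baseline_table(d0)
  expect_true(all(is.na(bt0$pct[bt0$group == ">1" & bt0$type == "categorical"])))
  fmt <- format_baseline_table(bt)
  expect_true(all(c("variable", "0", "1", ">1", "p_value") %in% names(fmt)))
})
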