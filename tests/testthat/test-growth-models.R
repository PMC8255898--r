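test_that("evaluate_model matches the closed model forms", {
  p <- table1_params$logistic
  # logistic value at its inflection age is exactly A/2
  expect_equal(evaluate_model(p, log(p$B) / p$k), p$A / 2)
  # direct substitution at t = 0
  v <- table1_params$von_bertalanffy
  expect_equal(evaluate_model(v, 0), 198.903 * (1 - 0.826)^3)
  g <- table1_params$gompertz
  expect_equal(evaluate_model(g, 0), 165.829 * exp(-4.141))
  # asymptote
  for (p in table1_params)
    expect_lt(abs(evaluate_model(p, 1e6) - p$A), 1e-6)
  expect_error(growth_params("richards", 1, 1, 1))
})

test_that("model curves are non-decreasing in age and bounded by A", {
  grid <- seq(0, 600, by = 1)
  for (p in table1_params) {
    w <- evaluate_model(p, grid)
    expect_true(all(diff(w) >= 0), info = p$model)
    expect_true(all(w <= p$A + 1e-12), info = p$model)
  }
})

test_that("inflection summary agrees with curve evaluation and numeric slope", {
  for (p in table1_params) {
    ip <- inflection_summary(p)
    # curve value at the inflection age equals the closed-form weight
    expect_equal(evaluate_model(p, ip$age), ip$weight, tolerance = 1e-10)
    # finite-difference slope equals the closed-form maximum gain
    h <- 1e-4
    slope <- (evaluate_model(p, ip$age + h) - evaluate_model(p, ip$age - h)) / (2 * h)
    expect_equal(slope, ip$max_daily_gain / 1000, tolerance = 1e-6)
    expect_false(ip$before_birth)
    expect_lt(ip$weight, p$A)
    expect_gt(ip$max_daily_gain, 0)
  }
})

test_that("an inflection before birth is returned with a warning, not clamped", {
  p <- growth_params("logistic", 100, 0.5, 0.02) # B < 1
  expect_warning(ip <- inflection_summary(p), "precedes birth")
  expect_lt(ip$age, 0)
  expect_true(ip$before_birth)
  expect_error(growth_params("logistic", -1, 2, 0.1))
})

test_that("goodness_of_fit implements 1 - RSE/RST", {
  expect_equal(goodness_of_fit(c(5, 7, 9), c(5, 7, 9)), 1)
  obs <- c(1, 4, 2, 8)
  expect_equal(goodness_of_fit(obs, rep(mean(obs), 4)), 0)
  expect_equal(goodness_of_fit(c(1, 2, 3), c(1, 2, 4)), 0.5)
  # invariant under a common shift
  sh <- goodness_of_fit(c(1, 2, 3) + 100, c(1, 2, 4) + 100)
  expect_equal(sh, 0.5)
  expect_error(goodness_of_fit(c(2, 2, 2), c(1, 2, 3)), "identical")
  expect_error(goodness_of_fit(1:3, 1:4), "equal length")
})

test_that("noise-free points are recovered to high precision", {
  ages <- seq(0, 400, length.out = 18)
  for (m in c("logistic", "gompertz", "von_bertalanffy")) {
    p <- table1_params[[m]]
    rec <- data.frame(animal_id = "a1", age_days = ages,
                      weight_kg = evaluate_model(p, ages))
    f <- fit_growth_curve(rec, m)
    expect_true(f$converged)
    expect_lt(abs(f$params$A - p$A) / p$A, 1e-4)
    expect_lt(abs(f$params$B - p$B) / p$B, 1e-4)
    expect_lt(abs(f$params$k - p$k) / p$k, 1e-4)
    expect_gte(f$r_squared, 1 - 1e-10)
    expect_length(f$residuals, 18)
  }
})

test_that("degenerate inputs yield a flagged fit or clear error, not a crash", {
  rec <- data.frame(animal_id = "a", age_days = 0:17, weight_kg = rep(50, 18))
  f <- fit_growth_curve(rec, "logistic")
  expect_false(f$converged)
  expect_true(is.na(f$r_squared))
  expect_error(fit_growth_curve(
    data.frame(animal_id = "a", age_days = c(0, 1, 2), weight_kg = c(1, 2, 3)),
    "logistic"), "4 distinct ages")
  expect_error(fit_growth_curve(
    data.frame(animal_id = "a", age_days = 0:4, weight_kg = c(-1, 1, 2, 3, 4)),
    "logistic"), "positive")
})

test_that("rank_models sorts by R2 with a stable lexicographic tie-break", {
  mk <- function(model, r2) structure(
    list(model = model, r_squared = r2, converged = TRUE),
    class = "growth_fit")
  fits <- list(mk("von_bertalanffy", 0.998), mk("logistic", 0.999),
               mk("gompertz", 0.996))
  expect_equal(vapply(rank_models(fits), `[[`, "", "model"),
               c("logistic", "von_bertalanffy", "gompertz"))
  expect_equal(rank_models(fits[2])[[1]]$model, "logistic")
  tied <- list(mk("von_bertalanffy", 0.5), mk("gompertz", 0.5))
  expect_equal(vapply(rank_models(tied), `[[`, "", "model"),
               c("gompertz", "von_bertalanffy"))
  # non-converged (NA) fits sort last
  fits2 <- list(mk("logistic", NA_real_), mk("gompertz", 0.1))
  expect_equal(rank_models(fits2)[[1]]$model, "gompertz")
  expect_error(rank_models(list()), "at least one")
})

test_that("weight records round-trip through CSV with validation", {
  sim <- simulate_growth_cohort(n_animals = 3, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(sim$records, path, row.names = FALSE)
  back <- read_weight_records(path)
  expect_equal(back, sim$records[order(sim$records$animal_id,
                                       sim$records$age_days), ],
               ignore_attr = TRUE)
  bad <- sim$records; bad$weight_kg[1] <- -2
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_weight_records(path), "positive")
  dup <- rbind(sim$records, sim$records[1, ])
  write.csv(dup, path, row.names = FALSE)
  expect_error(read_weight_records(path), "duplicate")
})

test_that("growth_report mirrors the fit-table layout and ranks models", {
  sim <- simulate_growth_cohort(n_animals = 20, seed = 2)
  rep <- growth_report(sim$records)
  expect_named(rep, c("model", "A", "B", "k", "R2", "inflection_day",
                      "inflection_weight_kg", "max_daily_gain_g", "converged"))
  expect_equal(nrow(rep), 3)
  expect_true(all(diff(rep$R2) <= 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fit_report(rep, path)
  back <- read.delim(path)
  expect_equal(back$model, rep$model)
  expect_equal(back$R2, rep$R2, tolerance = 1e-10)
})
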