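#' Construct a sigmoidal growth-model parameter set
#'
#' Bundles the asymptote `A` (kg), shape constant `B` (dimensionless) and
#' rate constant `k` (per day) of one of the three classical growth models:
#'
#' * logistic: \eqn{W(t) = A / (1 + B e^{-kt})}
#' * Gompertz: \eqn{W(t) = A \exp(-B e^{-kt})}
#' * Von Bertalanffy: \eqn{W(t) = A (1 - B e^{-kt})^3}
#'
#' @param model One of `"logistic"`, `"gompertz"`, `"von_bertalanffy"`.
#' @param A Asymptotic (mature) weight in kg; must be positive.
#' @param B Shape constant; must be positive.
#' @param k Rate constant per day; must be positive.
#' @return An object of class `growth_params`.
#' @examples
#' growth_params("logistic", A = 135.63, B = 22.075, k = 0.017)
#' @export
growth_params <- function(model, A, B, k) {
  model <- match.arg(model, GROWTH_MODELS)
  check_positive(A, "A"); check_positive(B, "B"); check_positive(k, "k")
  structure(list(model = model, A = A, B = B, k = k), class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("<growth_params> %s: A = %.4g kg, B = %.4g, k = %.4g /d\n",
              x$model, x$A, x$B, x$k))
  invisible(x)
}

as_growth_params <- function(params) {
  if (inherits(params, "growth_params")) return(params)
  if (is.list(params) && all(c("model", "A", "B", "k") %in% names(params)))
    return(growth_params(params$model, params$A, params$B, params$k))
  fail("expected a 'growth_params' object or a list with model, A, B, k")
}

#' Evaluate a growth model at given ages
#'
#' @param params A [growth_params()] object.
#' @param t Ages in days (non-negative numeric vector).
#' @return Predicted weights in kg, same length as `t`.
#' @examples
#' p <- growth_params("logistic", 135.63, 22.075, 0.017)
#' evaluate_model(p, c(0, 100, 200, 400))
#' @export
evaluate_model <- function(params, t) {
  params <- as_growth_params(params)
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    fail("'t' must be non-negative finite ages in days")
  A <- params$A; B <- params$B; k <- params$k
  switch(params$model,
    logistic        = A / (1 + B * exp(-k * t)),
    gompertz        = A * exp(-B * exp(-k * t)),
    von_bertalanffy = A * (1 - B * exp(-k * t))^3
  )
}

#' Closed-form inflection point of a growth model
#'
#' Returns the growth turning point: the age at which daily gain is maximal,
#' the weight at that age, and the maximum daily gain. Closed forms per model:
#'
#' | model | age (d) | weight (kg) | max daily gain (kg/d) |
#' |---|---|---|---|
#' | logistic | ln(B)/k | A/2 | k·w/2 |
#' | Gompertz | ln(B)/k | A/e | k·w |
#' | Von Bertalanffy | ln(3B)/k | 8A/27 | 3k·w/2 |
#'
#' where w is the inflection weight. Gains are reported in g/day. For the
#' Von Bertalanffy curve the analytic inflection of \eqn{A(1-Be^{-kt})^3}
#' is at \eqn{\ln(3B)/k}, which is what is implemented.
#'
#' If the shape argument (B, or 3B for Von Bertalanffy) is at most 1 the
#' inflection precedes birth; the computed (non-positive) age is returned
#' as-is with `before_birth = TRUE` and a warning, so the caller decides.
#'
#' @param params A [growth_params()] object.
#' @return A list of class `inflection_summary` with elements `age` (days),
#'   `weight` (kg), `max_daily_gain` (g/day) and `before_birth` (logical).
#' @examples
#' inflection_summary(growth_params("logistic", 135.63, 22.075, 0.017))
#' @export
inflection_summary <- function(params) {
  params <- as_growth_params(params)
  A <- params$A; B <- params$B; k <- params$k
  shape_arg <- switch(params$model,
    logistic = B, gompertz = B, von_bertalanffy = 3 * B)
  age <- log(shape_arg) / k
  weight <- switch(params$model,
    logistic        = A / 2,
    gompertz        = A / exp(1),
    von_bertalanffy = 8 * A / 27
  )
  gain_kg <- switch(params$model,
    logistic        = k * weight / 2,
    gompertz        = k * weight,
    von_bertalanffy = 3 * k * weight / 2
  )
  before_birth <- shape_arg <= 1
  if (before_birth)
    warning("inflection precedes birth (shape argument <= 1); age is non-positive",
            call. = FALSE)
  structure(
    list(age = age, weight = weight, max_daily_gain = gain_kg * 1000,
         before_birth = before_birth, model = params$model),
    class = "inflection_summary"
  )
}

#' @export
print.inflection_summary <- function(x, ...) {
  cat(sprintf("<inflection_summary> %s: day %.2f, %.2f kg, %.1f g/d%s\n",
              x$model, x$age, x$weight, x$max_daily_gain,
              if (x$before_birth) " [before birth]" else ""))
  invisible(x)
}

#' Coefficient of determination of a fitted curve
#'
#' \eqn{R^2 = 1 - RSE/RST} where RSE is the residual sum of squares and RST
#' the total sum of squares about the mean of the observations.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @return R-squared (at most 1; can be negative for fits worse than the mean).
#' @examples
#' goodness_of_fit(c(1, 2, 3), c(1, 2, 4)) # 0.5
#' @export
goodness_of_fit <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    fail("'observed' and 'predicted' must have equal length")
  if (length(observed) < 2L) fail("need at least 2 observations")
  rst <- sum((observed - mean(observed))^2)
  if (rst == 0) fail("total sum of squares is zero: observations are all identical")
  1 - sum((observed - predicted)^2) / rst
}

## Initialization for the nonlinear fit: A0 slightly above the data maximum,
## k0 from the logistic log-linearization between the 25th and 75th weight
## percentile points, B0 solved from the earliest observation.
growth_start_values <- function(age, weight, model) {
  A0 <- 1.05 * max(weight)
  qa <- quantile(weight, c(0.25, 0.75), names = FALSE, type = 7)
  i25 <- which.min(abs(weight - qa[1]))
  i75 <- which.min(abs(weight - qa[2]))
  lin <- function(w) log(pmax(A0 / pmin(w, A0 * 0.999) - 1, 1e-8))
  dt <- age[i75] - age[i25]
  k0 <- if (dt > 0) (lin(weight[i25]) - lin(weight[i75])) / dt else NA_real_
  if (!is.finite(k0) || k0 <= 0) k0 <- 0.01
  i1 <- which.min(age)
  t1 <- age[i1]; w1 <- min(weight[i1], A0 * 0.999)
  B0 <- switch(model,
    logistic        = (A0 / w1 - 1) * exp(k0 * t1),
    gompertz        = -log(w1 / A0) * exp(k0 * t1),
    von_bertalanffy = (1 - (w1 / A0)^(1 / 3)) * exp(k0 * t1)
  )
  if (!is.finite(B0) || B0 <= 0) B0 <- 1
  c(la = log(A0), lb = log(B0), lk = log(k0))
}

#' Fit a sigmoidal growth model to pooled weight records
#'
#' Damped (Levenberg--Marquardt) least squares on the pooled (age, weight)
#' points, log-parameterized so A, B and k stay positive. Convergence is
#' declared on a relative change in the sum of squared residuals below
#' `1e-10` within `maxiter` iterations; non-convergence (or a degenerate
#' input such as constant weights) is reported via `converged = FALSE`,
#' never as a silent wrong answer.
#'
#' @param records Data frame with columns `animal_id`, `age_days`,
#'   `weight_kg` (see [read_weight_records()]), or any data frame with
#'   numeric `age_days` and `weight_kg`.
#' @param model One of `"logistic"`, `"gompertz"`, `"von_bertalanffy"`.
#' @param maxiter Maximum Levenberg--Marquardt iterations.
#' @return An object of class `growth_fit`: list with `params`
#'   ([growth_params()] or `NULL` when degenerate), `r_squared`, `residuals`
#'   (kg, observed minus fitted), `converged`, `n_obs` and `model`.
#' @examples
#' p <- growth_params("logistic", 135, 22, 0.017)
#' ages <- seq(0, 400, length.out = 18)
#' rec <- data.frame(animal_id = "a1", age_days = ages,
#'                   weight_kg = evaluate_model(p, ages))
#' fit_growth_curve(rec, "logistic")
#' @export
fit_growth_curve <- function(records, model, maxiter = 500L) {
  model <- match.arg(model, GROWTH_MODELS)
  if (!all(c("age_days", "weight_kg") %in% names(records)))
    fail("'records' needs columns age_days and weight_kg")
  age <- as.numeric(records$age_days)
  weight <- as.numeric(records$weight_kg)
  keep <- is.finite(age) & is.finite(weight)
  age <- age[keep]; weight <- weight[keep]
  if (length(unique(age)) < 4L) fail("need at least 4 distinct ages")
  if (any(weight <= 0)) fail("weights must be positive")

  failed <- function() structure(
    list(params = NULL, r_squared = NA_real_,
         residuals = rep(NA_real_, length(age)), converged = FALSE,
         n_obs = length(age), model = model),
    class = "growth_fit")

  if (sd(weight) == 0) return(failed())

  rhs <- switch(model,
    logistic        = weight ~ exp(la) / (1 + exp(lb) * exp(-exp(lk) * age)),
    gompertz        = weight ~ exp(la) * exp(-exp(lb) * exp(-exp(lk) * age)),
    von_bertalanffy = weight ~ exp(la) * (1 - exp(lb) * exp(-exp(lk) * age))^3
  )
  start <- growth_start_values(age, weight, model)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rhs, data = data.frame(age = age, weight = weight),
      start = as.list(start),
      control = minpack.lm::nls.lm.control(
        maxiter = min(as.integer(maxiter), 1024L), ftol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed())

  cf <- stats::coef(fit)
  params <- growth_params(model, A = exp(cf[["la"]]), B = exp(cf[["lb"]]),
                          k = exp(cf[["lk"]]))
  pred <- evaluate_model(params, age)
  structure(
    list(params = params,
         r_squared = goodness_of_fit(weight, pred),
         residuals = weight - pred,
         converged = TRUE, n_obs = length(age), model = model),
    class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<growth_fit> %s: did not converge (n = %d)\n", x$model, x$n_obs))
  } else {
    cat(sprintf("<growth_fit> %s: A = %.3f, B = %.4f, k = %.5f, R2 = %.5f (n = %d)\n",
                x$model, x$params$A, x$params$B, x$params$k, x$r_squared, x$n_obs))
  }
  invisible(x)
}

#' Rank fitted growth models by goodness of fit
#'
#' Descending by R-squared; exact ties are broken lexicographically by model
#' name so the ordering is stable across runs. Non-converged fits (NA
#' R-squared) sort last.
#'
#' @param fits List of `growth_fit` objects.
#' @return The same list, reordered.
#' @export
rank_models <- function(fits) {
  if (length(fits) < 1L) fail("need at least one fit")
  r2 <- vapply(fits, function(f) if (is.na(f$r_squared)) -Inf else f$r_squared, 0)
  nm <- vapply(fits, function(f) f$model, "")
  fits[order(-r2, nm)]
}

#' Fit all three growth models and summarize as a Table-1-style report
#'
#' @param records Weight records (see [fit_growth_curve()]).
#' @param models Character vector of models to fit.
#' @return Data frame with one row per model (ranked by R-squared):
#'   `model, A, B, k, R2, inflection_day, inflection_weight_kg,
#'   max_daily_gain_g, converged`.
#' @export
growth_report <- function(records, models = GROWTH_MODELS) {
  fits <- lapply(models, function(m) fit_growth_curve(records, m))
  fits <- rank_models(fits)
  rows <- lapply(fits, function(f) {
    if (!f$converged)
      return(data.frame(model = f$model, A = NA_real_, B = NA_real_,
                        k = NA_real_, R2 = NA_real_, inflection_day = NA_real_,
                        inflection_weight_kg = NA_real_,
                        max_daily_gain_g = NA_real_, converged = FALSE))
    ip <- suppressWarnings(inflection_summary(f$params))
    data.frame(model = f$model, A = f$params$A, B = f$params$B, k = f$params$k,
               R2 = f$r_squared, inflection_day = ip$age,
               inflection_weight_kg = ip$weight,
               max_daily_gain_g = ip$max_daily_gain, converged = TRUE)
  })
  do.call(rbind, rows)
}
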