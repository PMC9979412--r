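#' Parametric ground truth for the synthetic illness-death cohort
#'
#' Bundles everything the synthetic-cohort generator needs: Gompertz
#' baseline intensities on the age scale for the three transitions of the
#' irreversible illness-death model (1 = healthy to CVD, 2 = healthy to
#' death, 3 = CVD to death), proportional log-hazard-ratios for the sleep
#' category and for covariates, sleep-category prevalence by sex, covariate
#' marginals, missingness rates, and the enrollment / administrative
#' censoring distributions.
#'
#' Each transition `k` has intensity
#' `lambda_k(age) = a_k * exp(b_k * (age - 40)) * exp(eta_k)`, where
#' `eta_k` is the linear predictor of the person's sleep category and
#' covariate scores. The Gompertz pair reduces to a constant hazard at
#' `shape = 0`, which is what the closed-form oracle tests exploit.
#'
#' Default values emulate a middle-aged population cohort: enrollment ages
#' 40-69 (truncated normal, mean 56.2, sd 8.1), mean follow-up 11.8 (1.3)
#' years, sleep-category prevalence roughly 60/38/2 percent
#' (healthy/intermediate/poor) with women slightly healthier, and effect
#' sizes chosen so that CVD-free life-expectancy contrasts between sleep
#' categories land in the 1-7 year range.
#'
#' @param base list of three numeric pairs `c(rate, shape)` named `cvd`,
#'   `death_healthy`, `death_cvd`; rates per year at age 40, shapes per
#'   year of age (`shape >= 0`, `rate >= 0`).
#' @param sleep_hr list of three named log-HR vectors (elements
#'   `intermediate`, `poor`; reference = healthy), same names as `base`.
#' @param covariate_effects list of three named numeric vectors; names are
#'   covariate names, values are per-unit log-HRs on the covariate score
#'   (factor level index - 1, logical 0/1, numeric value).
#' @param sleep_prevalence list with `female` and `male` probability
#'   vectors over `c(healthy, intermediate, poor)`; each sums to 1.
#' @param p_female probability a participant is female.
#' @param enrollment,followup truncated-normal parameters
#'   `list(mean, sd, min, max)` for enrollment age (years) and follow-up
#'   duration until administrative censoring (years).
#' @param prevalent_cvd probability of a baseline CVD history flag.
#' @param disorder_rates named probabilities of planting a coded
#'   sleep-disorder history (`insomnia`, `srbd`, `other`) in the lookback
#'   window before enrollment.
#' @param out_of_window_rate probability of an extra disorder code dated
#'   2-4 years before enrollment (outside the default lookback; exercises
#'   the window rule).
#' @param missing list with per-field missingness probabilities `sleep`
#'   and `covariates` (missing completely at random).
#' @param lookback years before enrollment in which planted disorder codes
#'   are dated.
#' @param seed integer seed stored with the truth; `generate_cohort()`
#'   uses it by default so the same truth yields the same cohort.
#'
#' @return An object of class `sleeple_truth`.
#' @seealso [generate_cohort()], [true_life_expectancy()]
#' @export
#' @examples
#' tr <- simulation_truth(seed = 7)
#' true_life_expectancy(tr, profile = list(sleep = "healthy"))
simulation_truth <- function(
    base = list(cvd = c(rate = 0.0035, shape = 0.07),
                death_healthy = c(rate = 0.00045, shape = 0.095),
                death_cvd = c(rate = 0.0016, shape = 0.09)),
    sleep_hr = list(cvd = c(intermediate = log(1.15), poor = log(1.6)),
                    death_healthy = c(intermediate = log(1.10), poor = log(1.45)),
                    death_cvd = c(intermediate = log(1.05), poor = log(1.2))),
    covariate_effects = list(
      cvd = c(mental_health = 0.15, smoking = 0.15, bmi_class = 0.20,
              screen_time = 0.02),
      death_healthy = c(smoking = 0.25),
      death_cvd = c(smoking = 0.10)),
    sleep_prevalence = list(female = c(healthy = 0.62, intermediate = 0.36, poor = 0.02),
                            male = c(healthy = 0.57, intermediate = 0.41, poor = 0.02)),
    p_female = 0.56,
    enrollment = list(mean = 56.2, sd = 8.1, min = 40, max = 69),
    followup = list(mean = 11.8, sd = 1.3, min = 2, max = 15),
    prevalent_cvd = 0.12,
    disorder_rates = c(insomnia = 0.009, srbd = 0.017, other = 0.046),
    out_of_window_rate = 0.01,
    missing = list(sleep = 0.03, covariates = 0.02),
    lookback = 2,
    seed = 1L) {
  tnames <- c("cvd", "death_healthy", "death_cvd")
  stopifnot(identical(names(base), tnames),
            identical(names(sleep_hr), tnames),
            identical(names(covariate_effects), tnames))
  for (k in tnames) {
    b <- base[[k]]
    if (length(b) != 2 || b[["rate"]] < 0 || b[["shape"]] < 0)
      stop("base[['", k, "']] must be c(rate >= 0, shape >= 0)")
  }
  for (sx in c("female", "male")) {
    pv <- sleep_prevalence[[sx]]
    if (length(pv) != 3 || any(pv < 0) || abs(sum(pv) - 1) > 1e-8)
      stop("sleep_prevalence$", sx, " must be 3 non-negative values summing to 1")
  }
  structure(list(base = base, sleep_hr = sleep_hr,
                 covariate_effects = covariate_effects,
                 sleep_prevalence = sleep_prevalence, p_female = p_female,
                 enrollment = enrollment, followup = followup,
                 prevalent_cvd = prevalent_cvd,
                 disorder_rates = disorder_rates,
                 out_of_window_rate = out_of_window_rate,
                 missing = missing, lookback = lookback,
                 seed = as.integer(seed)),
            class = "sleeple_truth")
}

#' @export
print.sleeple_truth <- function(x, ...) {
  cat("<sleeple_truth>\n")
  for (k in names(x$base))
    cat(sprintf("  %-14s rate %.3g /yr at 40, shape %.3g /yr\n",
                k, x$base[[k]][["rate"]], x$base[[k]][["shape"]]))
  cat("  sleep HRs (poor): ",
      paste(sprintf("%s %.2f", names(x$sleep_hr),
                    vapply(x$sleep_hr, function(b) exp(b[["poor"]]), 0)),
            collapse = ", "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# Gompertz cumulative hazard between ages s and t (vectorized in s/t):
# integral of a*exp(b*(u-40)) du; closed form, linear at b = 0.
gompertz_cumhaz <- function(rate, shape, s, t) {
  if (shape == 0) return(rate * (t - s))
  (rate / shape) * (exp(shape * (t - 40)) - exp(shape * (s - 40)))
}

gompertz_hazard <- function(rate, shape, age) rate * exp(shape * (age - 40))

# Linear predictor per transition for a profile:
# profile$sleep in {healthy, intermediate, poor}; profile$scores a named
# numeric vector matched against truth$covariate_effects names.
truth_eta <- function(truth, profile) {
  sleep <- match.arg(profile$sleep %||% "healthy",
                     c("healthy", "intermediate", "poor"))
  scores <- profile$scores %||% numeric(0)
  vapply(names(truth$base), function(k) {
    eta <- if (sleep == "healthy") 0 else truth$sleep_hr[[k]][[sleep]]
    eff <- truth$covariate_effects[[k]]
    common <- intersect(names(eff), names(scores))
    eta + sum(eff[common] * scores[common])
  }, 0)
}

#' Closed-form/numerical oracle for restricted state-specific lifetimes
#'
#' Computes, by adaptive quadrature over the parametric intensities of a
#' [simulation_truth()] object, the restricted expected years spent
#' CVD-free (`e_free`), alive with CVD (`e_with`), and alive in total
#' (`e_total`) between `age0` and the restriction age `tau`, for a given
#' exposure/covariate profile. This is the independent benchmark the
#' pipeline's Aalen-Johansen estimates are validated against.
#'
#' `e_free` integrates the healthy-state survival
#' `exp(-Lambda_1 - Lambda_2)`; `e_with` is the double integral over the
#' CVD onset age `u` and subsequent survival under the transition-3
#' intensity started at `u` (clock-forward Markov).
#'
#' @param truth a [simulation_truth()] object.
#' @param profile list with `sleep` (category) and optional `scores`
#'   (named covariate scores); defaults to healthy sleep at score zero.
#' @param age0 conditioning age (years); default 40.
#' @param tau restriction age (years); must exceed `age0`; default 81.
#' @param rel.tol relative quadrature tolerance.
#' @return named numeric vector `c(e_free, e_with, e_total)` in years.
#' @export
true_life_expectancy <- function(truth, profile = list(sleep = "healthy"),
                                 age0 = 40, tau = 81, rel.tol = 1e-8) {
  stopifnot(inherits(truth, "sleeple_truth"))
  if (!(age0 >= 40 && age0 < tau)) stop("need 40 <= age0 < tau")
  eta <- truth_eta(truth, profile)
  b <- truth$base
  lam <- function(k, u) gompertz_hazard(b[[k]]["rate"], b[[k]]["shape"], u) * exp(eta[[k]])
  cum <- function(k, s, t) gompertz_cumhaz(b[[k]]["rate"], b[[k]]["shape"], s, t) * exp(eta[[k]])

  surv_free <- function(u) exp(-(cum("cvd", age0, u) + cum("death_healthy", age0, u)))
  e_free <- integrate(surv_free, age0, tau, rel.tol = rel.tol,
                      subdivisions = 400L)$value

  # expected residual (restricted) years alive with CVD after onset at u
  resid_with <- function(u) {
    if (u >= tau) return(0)
    integrate(function(w) exp(-cum("death_cvd", u, w)), u, tau,
              rel.tol = rel.tol, subdivisions = 400L)$value
  }
  dens <- function(u) lam("cvd", u) * surv_free(u)
  if (b$cvd[["rate"]] == 0) {
    e_with <- 0
  } else {
    e_with <- integrate(function(u) dens(u) * vapply(u, resid_with, 0),
                        age0, tau, rel.tol = rel.tol,
                        subdivisions = 400L)$value
  }
  c(e_free = unname(e_free), e_with = unname(e_with),
    e_total = unname(e_free + e_with))
}

#' Write / read a simulation truth as JSON
#'
#' Serializes every field of a [simulation_truth()] object so a generated
#' cohort can be reproduced from its config file alone.
#'
#' @param truth a `sleeple_truth` object.
#' @param path file path.
#' @return `read_truth()` returns a `sleeple_truth`;
#'   `write_truth()` returns `path` invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sleeple_truth"))
  x <- unclass(truth)
  # named vectors must become objects, not bare arrays, to survive JSON
  for (f in c("base", "sleep_hr", "covariate_effects", "sleep_prevalence"))
    x[[f]] <- lapply(x[[f]], as.list)
  x$disorder_rates <- as.list(x$disorder_rates)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pair <- function(v) c(rate = unname(v[["rate"]]), shape = unname(v[["shape"]]))
  simulation_truth(
    base = lapply(x$base, pair),
    sleep_hr = lapply(x$sleep_hr, unlist),
    covariate_effects = lapply(x$covariate_effects, unlist),
    sleep_prevalence = lapply(x$sleep_prevalence, unlist),
    p_female = x$p_female, enrollment = x$enrollment,
    followup = x$followup, prevalent_cvd = x$prevalent_cvd,
    disorder_rates = unlist(x$disorder_rates),
    out_of_window_rate = x$out_of_window_rate, missing = x$missing,
    lookback = x$lookback, seed = x$seed)
}
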