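# Shared fixtures: truths with known closed forms and small hand-checked
# tables. Everything is generated in code; no binary fixtures.

# constant-hazard truth (Gompertz shape 0) with no covariate effects and
# no sleep effects: closed-form exponential world
constant_truth <- function(l1 = 0.02, l2 = 0.01, l3 = 0.05, seed = 1L) {
  simulation_truth(
    base = list(cvd = c(rate = l1, shape = 0),
                death_healthy = c(rate = l2, shape = 0),
                death_cvd = c(rate = l3, shape = 0)),
    sleep_hr = list(cvd = c(intermediate = 0, poor = 0),
                    death_healthy = c(intermediate = 0, poor = 0),
                    death_cvd = c(intermediate = 0, poor = 0)),
    covariate_effects = list(cvd = numeric(0), death_healthy = numeric(0),
                             death_cvd = numeric(0)),
    prevalent_cvd = 0, missing = list(sleep = 0, covariates = 0),
    disorder_rates = c(insomnia = 0, srbd = 0, other = 0),
    out_of_window_rate = 0, seed = seed)
}

# default-shaped truth but with clean data (no missingness, no prevalent
# CVD) so exclusion stages 1-3 remove nobody; used for recovery tests
clean_truth <- function(seed = 1L, ...) {
  simulation_truth(prevalent_cvd = 0,
                   missing = list(sleep = 0, covariates = 0),
                   seed = seed, ...)
}

# a participant row with every field healthy/complete; override with ...
make_participant <- function(id = "P1", ...) {
  out <- data.frame(
    id = id, sex = factor("female", levels = c("female", "male")),
    enrollment_age = 56, enrollment_date = as.Date("2008-06-01"),
    chronotype = "definitely_morning", sleep_duration = 7L,
    insomnia = "never_rarely", snoring = "no", sleepiness = "never_rarely",
    ses = factor("q2", levels = covariate_levels()$ses, ordered = TRUE),
    mental_health = FALSE,
    perceived_health = factor("good", levels = covariate_levels()$perceived_health,
                              ordered = TRUE),
    bmi_class = factor("lt30", levels = covariate_levels()$bmi_class,
                       ordered = TRUE),
    economic_activity = factor("employed",
                               levels = covariate_levels()$economic_activity),
    smoking = factor("never", levels = covariate_levels()$smoking,
                     ordered = TRUE),
    alcohol = factor("lt14", levels = covariate_levels()$alcohol,
                     ordered = TRUE),
    diet = factor("intermediate", levels = covariate_levels()$diet,
                  ordered = TRUE),
    screen_time = 3.5,
    physical_activity = factor("ge20",
                               levels = covariate_levels()$physical_activity,
                               ordered = TRUE),
    prevalent_cvd = FALSE, cvd_age = NA_real_, death_age = NA_real_,
    censor_age = 68, stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) out[[nm]] <- over[[nm]]
  out
}

make_participants <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

# six-row toy counting-process dataset with one binary covariate and a
# left-truncated entry; printed in full so the grid-search oracle test is
# self-contained
toy_msdata <- function() {
  data.frame(
    entry  = c(0.0, 0.0, 0.5, 1.0, 0.0, 2.0),
    exit   = c(2.0, 3.0, 4.0, 5.0, 6.0, 7.0),
    status = c(1L, 0L, 1L, 1L, 0L, 1L),
    x      = c(1, 1, 0, 1, 0, 0))
}

# step-function helper for oracle-side cumulative hazards
step_cumhaz <- function(time, increment) {
  list(time = time, increment = increment, cumhaz = cumsum(increment))
}
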