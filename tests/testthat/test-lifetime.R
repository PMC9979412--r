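# lifetime_estimator: profiles, Aalen-Johansen, restricted integrals,
# YLL, bootstrap

test_that("covariate profile follows the median/mean/mode rule", {
  d <- data.frame(
    screen_time = c(2, 4, 6),
    perceived_health = factor(rep(c("excellent", "good", "fair", "poor"),
                                  c(10, 60, 20, 10))[1:3],
                              levels = c("excellent", "good", "fair", "poor"),
                              ordered = TRUE))
  # numeric mean
  expect_equal(covariate_profile(d, "screen_time")$screen_time, 4)

  # ordered median by cumulative counts 10/60/20/10 -> "good"
  ph <- factor(rep(c("excellent", "good", "fair", "poor"),
                   c(10, 60, 20, 10)),
               levels = c("excellent", "good", "fair", "poor"),
               ordered = TRUE)
  pr <- covariate_profile(data.frame(perceived_health = ph))
  expect_equal(as.character(pr$perceived_health), "good")

  # unordered mode
  ea <- factor(rep(c("retired", "employed", "night_shift"), c(3, 5, 2)))
  expect_equal(as.character(covariate_profile(data.frame(x = ea))$x),
               "employed")
  # logical majority, ties resolve FALSE
  expect_false(covariate_profile(data.frame(m = c(TRUE, FALSE)))$m)
  expect_error(covariate_profile(data.frame(x = numeric(0))), "empty stratum")
})

test_that("Aalen-Johansen handles degenerate hazard inputs", {
  empty <- step_cumhaz(numeric(0), numeric(0))
  cv <- aalen_johansen(empty, empty, empty)
  expect_equal(nrow(cv), 1)
  expect_equal(cv$p11, 1)
  e <- restricted_expectancies(cv)
  expect_equal(unname(e), c(41, 0, 41))

  # one jump dA13 = 0.1 at age 50
  one <- aalen_johansen(empty, step_cumhaz(50, 0.1), empty)
  expect_equal(one$p11[one$age == 50], 0.9)
  expect_equal(one$p13[one$age == 50], 0.1)
  e1 <- restricted_expectancies(one)
  expect_equal(unname(e1["e_free"]), 10 + 31 * 0.9)

  expect_error(aalen_johansen(list(a = 1), empty, empty), "malformed")
})

test_that("Aalen-Johansen matches the Kolmogorov/matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  l12 <- 0.02; l13 <- 0.01; l23 <- 0.05
  m <- 2000
  grid <- seq(40, 81, length.out = m + 1)[-1]
  dt <- diff(c(40, grid))
  ch <- function(l) step_cumhaz(grid, l * dt)
  curve <- aalen_johansen(ch(l12), ch(l13), ch(l23))
  Q <- matrix(c(-(l12 + l13), l12, l13,
                0, -l23, l23,
                0, 0, 0), 3, 3, byrow = TRUE)
  sup <- 0
  for (t in c(45, 50, 60, 70, 81)) {
    P <- as.matrix(Matrix::expm(Q * (t - 40)))
    i <- max(which(curve$age <= t))
    got <- as.numeric(curve[i, c("p11", "p12", "p13")])
    sup <- max(sup, abs(got - P[1, ]))
  }
  expect_lt(sup, 1e-3)
  # exact row stochasticity at every grid age
  expect_lt(max(abs(curve$p11 + curve$p12 + curve$p13 - 1)), 1e-10)
  expect_lt(max(abs(curve$p22 + curve$p23 - 1)), 1e-10)
  # monotone occupation probabilities
  expect_true(all(diff(curve$p11) <= 1e-12))
  expect_true(all(diff(curve$p13) >= -1e-12))
})

test_that("restricted integration is exact for step curves", {
  # survival exp(-0.05 (u - 40)) sampled on a fine grid
  m <- 50000
  grid <- seq(40, 81, length.out = m + 1)[-1]
  dt <- diff(c(40, grid))
  curve <- aalen_johansen(step_cumhaz(grid, 0.03 * dt),
                          step_cumhaz(grid, 0.02 * dt),
                          step_cumhaz(numeric(0), numeric(0)))
  e <- restricted_expectancies(curve)
  expect_equal(unname(e["e_free"]), (1 - exp(-0.05 * 41)) / 0.05,
               tolerance = 1e-3)
  # additivity holds exactly for any curve
  expect_identical(unname(e["e_free"] + e["e_with"]), unname(e["e_total"]))
})

test_that("years of life lost reproduces published differences", {
  # printed CVD-free expectancies, poor vs healthy sleepers
  yll_f <- years_of_life_lost(c(e_free = 31.46, e_with = 0, e_total = 31.46),
                              c(e_free = 33.26, e_with = 0, e_total = 33.26))
  expect_equal(unname(yll_f["yll_free"]), 1.80)
  yll_m <- years_of_life_lost(c(e_free = 27.96, e_with = 0, e_total = 27.96),
                              c(e_free = 30.27, e_with = 0, e_total = 30.27))
  expect_equal(unname(yll_m["yll_free"]), 2.31)
  same <- c(e_free = 30, e_with = 1, e_total = 31)
  expect_equal(unname(years_of_life_lost(same, same)), c(0, 0))
})

test_that("zero CVD hazard forces e_free == e_total in the estimator", {
  grid <- seq(40.5, 80.5, by = 0.5)
  ch2 <- step_cumhaz(grid, rep(0.002, length(grid)))
  cv <- aalen_johansen(step_cumhaz(numeric(0), numeric(0)), ch2,
                       step_cumhaz(grid, rep(0.01, length(grid))))
  e <- restricted_expectancies(cv)
  expect_equal(unname(e["e_free"]), unname(e["e_total"]))
  expect_equal(unname(e["e_with"]), 0)
})

test_that("bootstrap is deterministic and degenerates correctly", {
  set.seed(1)
  d <- data.frame(v = rnorm(40), g = factor(rep(c("a", "b"), 20)))
  stat <- function(dd) c(m = mean(dd$v))
  b1 <- bootstrap_ci(d, stat, B = 200, seed = 9, strata = d$g)
  b2 <- bootstrap_ci(d, stat, B = 200, seed = 9, strata = d$g)
  expect_identical(b1$ci, b2$ci)
  b3 <- bootstrap_ci(d, stat, B = 200, seed = 10, strata = d$g)
  expect_false(identical(b1$ci, b3$ci))

  # degenerate data: identical persons give zero-width intervals
  dd <- d[rep(1, 30), , drop = FALSE]
  b0 <- bootstrap_ci(dd, stat, B = 50, seed = 2)
  expect_equal(unname(b0$ci["lower", ]), unname(b0$ci["upper", ]))

  # failing iterations are dropped and flagged beyond 5%
  flaky <- function(dd) if (mean(dd$v) > median(d$v)) stop("no") else c(m = 1)
  expect_warning(
    suppressMessages(bootstrap_ci(d, flaky, B = 50, seed = 3)),
    "flagged")
})

test_that("pipeline point estimates track the simulator oracle", {
  # moderate-n sanity check of the full estimation path (the full-scale
  # recovery run lives in the acceptance suite)
  tr <- clean_truth(seed = 23)
  co <- generate_cohort(tr, 8000)
  pr <- score_sleep(co$participants)
  ex <- apply_exclusions(co$participants, pr, landmark = 0)
  pp <- ex$kept[ex$kept$sex == "male", ]
  adj <- c("mental_health", "smoking", "bmi_class", "screen_time")
  fu <- build_followup(pp)
  ms <- to_multistate(fu, pp[c("id", "category", adj)])
  fits <- fit_transitions(ms, c("category", adj))
  prof_adj <- covariate_profile(pp, adj)
  # tolerance tracks group size: poor sleepers are ~2% of the cohort, so
  # their estimate is noisy at this n (the acceptance suite checks the
  # full-scale recovery against bootstrap SEs)
  for (cat in c("healthy", "poor")) {
    tol <- if (cat == "healthy") 0.03 else 0.12
    prof <- cbind(data.frame(category = factor(cat,
                    levels = c("healthy", "intermediate", "poor"))), prof_adj)
    est <- predict_expectancies(fits, prof)
    scores <- covariate_scores(
      cbind(prof_adj, make_participant()[setdiff(covariate_cols(), adj)]))[1, ]
    truth_e <- true_life_expectancy(tr, list(sleep = cat,
                                             scores = scores))
    expect_equal(unname(est["e_free"]), unname(truth_e["e_free"]),
                 tolerance = tol)
    expect_equal(unname(est["e_total"]), unname(truth_e["e_total"]),
                 tolerance = tol)
  }
})
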