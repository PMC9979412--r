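# survival_engine: partial-likelihood maximizer, Breslow baseline,
# profile prediction; cross-checked against survival::coxph and a
# brute-force grid-search oracle

test_that("toy fixture matches brute-force grid maximization", {
  d <- toy_msdata()
  X <- matrix(d$x, ncol = 1)
  grid <- seq(-5, 5, by = 1e-4)
  ll <- vapply(grid, function(b)
    cox_partial_loglik(d$entry, d$exit, d$status, X, b), 0)
  b_grid <- grid[which.max(ll)]
  fit <- fit_cox(d, covariates = "x")
  expect_true(fit$converged)
  expect_equal(unname(fit$beta), b_grid, tolerance = 1e-3)
  # the fit's optimum is at least as good as the grid's
  expect_gte(fit$loglik, max(ll) - 1e-8)
})

test_that("null effect is recovered within 3 SE at n = 5000", {
  set.seed(31)
  n <- 5000
  d <- data.frame(entry = 0, exit = rexp(n, 0.1), status = 1L,
                  x = rbinom(n, 1, 0.5))
  cens <- runif(n, 0, 15)
  d$status <- as.integer(d$exit <= cens)
  d$exit <- pmin(d$exit, cens)
  fit <- fit_cox(d, covariates = "x")
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$beta / se), 3)
})

test_that("planted transition-1 log-HR is recovered from the generator", {
  tr <- clean_truth(
    seed = 47,
    sleep_hr = list(cvd = c(intermediate = 0.2, poor = 0.5),
                    death_healthy = c(intermediate = 0, poor = 0),
                    death_cvd = c(intermediate = 0, poor = 0)),
    covariate_effects = list(cvd = numeric(0), death_healthy = numeric(0),
                             death_cvd = numeric(0)))
  co <- generate_cohort(tr, 20000)
  pr <- score_sleep(co$participants)
  ex <- apply_exclusions(co$participants, pr, landmark = 0)
  fu <- build_followup(ex$kept)
  ms <- to_multistate(fu, ex$kept[c("id", "category")])
  fit <- fit_cox(ms, transition = 1, covariates = "category")
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$beta[["categorypoor"]] - 0.5) /
              se[["categorypoor"]], 3)
  expect_lt(abs(fit$beta[["categoryintermediate"]] - 0.2) /
              se[["categoryintermediate"]], 3)
})

test_that("engine matches survival::coxph on left-truncated data", {
  set.seed(13)
  n <- 3000
  x1 <- rbinom(n, 1, 0.4); x2 <- rnorm(n)
  entry <- runif(n, 40, 60)
  t <- entry + rexp(n, 0.05 * exp(0.4 * x1 - 0.3 * x2))
  cens <- entry + runif(n, 1, 15)
  exit <- round(pmin(t, cens), 1)           # induce ties
  status <- as.integer(t <= cens)
  exit[exit <= entry] <- entry[exit <= entry] + 0.05
  d <- data.frame(entry, exit, status, x1, x2)
  w <- sample(1:3, n, replace = TRUE)

  for (ties in c("efron", "breslow")) {
    ref <- survival::coxph(survival::Surv(entry, exit, status) ~ x1 + x2,
                           data = d, ties = ties, weights = w)
    fit <- fit_cox(d, covariates = c("x1", "x2"), ties = ties, weights = w)
    expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(sqrt(diag(fit$vcov))),
                 unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  }
  # right-censored (entry = 0) cross-check, the spec's stated harness
  d0 <- d; d0$entry <- 0
  ref0 <- survival::coxph(survival::Surv(exit, status) ~ x1 + x2, data = d0)
  fit0 <- fit_cox(d0, covariates = c("x1", "x2"))
  expect_equal(unname(fit0$beta), unname(coef(ref0)), tolerance = 1e-6)
})

test_that("ties methods agree exactly when no ties exist", {
  set.seed(5)
  n <- 500
  d <- data.frame(entry = 0, exit = sort(runif(n, 1, 50)), status =
                  rbinom(n, 1, 0.4), x = rnorm(n))
  stopifnot(!anyDuplicated(d$exit[d$status == 1]))
  fe <- fit_cox(d, covariates = "x", ties = "efron")
  fb <- fit_cox(d, covariates = "x", ties = "breslow")
  expect_identical(fe$beta, fb$beta)
  expect_identical(fe$loglik, fb$loglik)
})

test_that("partial likelihood is invariant to covariate location shifts", {
  d <- toy_msdata()
  fit <- fit_cox(d, covariates = "x")
  d2 <- d; d2$x <- d$x + 7
  fit2 <- fit_cox(d2, covariates = "x")
  expect_equal(unname(fit$beta), unname(fit2$beta), tolerance = 1e-8)
  expect_equal(fit$loglik, fit2$loglik, tolerance = 1e-8)
  # baseline at shifted profile is invariant
  b1 <- predict_cumhaz(fit, list(x = 1))
  b2 <- predict_cumhaz(fit2, list(x = 8))
  expect_equal(b1$cumhaz, b2$cumhaz, tolerance = 1e-8)
})

test_that("Breslow baseline reduces to Nelson-Aalen by hand", {
  # event ages {1, 2} with risk sets of sizes {2, 1}: increments 1/2, 1
  d <- data.frame(entry = 0, exit = c(1, 2), status = c(1L, 1L))
  f0 <- fit_cox(d, covariates = NULL)
  bl <- breslow_baseline(f0)
  expect_equal(bl$time, c(1, 2))
  expect_equal(bl$increment, c(1 / 2, 1))

  # proportionality: flipping a binary covariate with beta = log 2
  # doubles every increment
  set.seed(77)
  n <- 800
  d2 <- data.frame(entry = 0, x = rbinom(n, 1, 0.5))
  d2$exit <- rexp(n, 0.1 * exp(log(2) * d2$x))
  d2$status <- 1L
  fit <- fit_cox(d2, covariates = "x")
  a0 <- predict_cumhaz(fit, list(x = 0))
  a1 <- predict_cumhaz(fit, list(x = 1))
  expect_equal(a1$increment / a0$increment,
               rep(exp(unname(fit$beta)), length(a0$increment)),
               tolerance = 1e-10)

  expect_error(predict_cumhaz(fit, list(z = 1)), "missing covariate")
})

test_that("degenerate inputs raise named errors", {
  d <- toy_msdata()
  d$status <- 0L
  expect_error(fit_cox(d, covariates = "x"), "zero events")
  d2 <- toy_msdata(); d2$x <- 1
  expect_error(fit_cox(d2, covariates = "x"), "constant covariate")
  # perfect separation flags non-convergence
  d3 <- data.frame(entry = 0, exit = c(1:6), status = c(1, 1, 1, 0, 0, 0),
                   x = c(1, 1, 1, 0, 0, 0))
  expect_warning(f3 <- fit_cox(d3, covariates = "x"),
                 "monotone likelihood")
  expect_false(f3$converged)
})
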