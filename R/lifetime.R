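# Life-expectancy estimation: covariate profiles (median/mean/healthy
# rule), Aalen-Johansen occupation curves from the three fitted
# cumulative hazards, exact step-curve integration into restricted
# state-specific expectancies, years-of-life-lost contrasts, and
# nonparametric bootstrap percentile intervals.

#' Covariate profile for marginal life-expectancy prediction
#'
#' Builds the single covariate setting at which life expectancies are
#' predicted: continuous covariates at the stratum mean, ordered
#' categorical covariates at the median category (smallest level whose
#' cumulative count reaches half), unordered categorical covariates at
#' the modal category, logicals at the majority value (ties resolve to
#' `FALSE`). When contrasting one sleep characteristic or disorder, set
#' the remaining sleep variables to their healthy/absent level before
#' prediction; helpers downstream do this automatically.
#'
#' @param data non-empty data.frame (one stratum, e.g. one sex).
#' @param covariates columns to summarize; defaults to every column.
#' @return one-row data.frame.
#' @export
covariate_profile <- function(data, covariates = names(data)) {
  if (nrow(data) == 0) stop("empty stratum")
  out <- lapply(covariates, function(cl) {
    v <- data[[cl]]
    if (is.numeric(v)) return(mean(v, na.rm = TRUE))
    if (is.logical(v)) return(mean(v, na.rm = TRUE) > 0.5)
    if (is.factor(v)) {
      tab <- table(v)
      if (is.ordered(v)) {
        lev <- names(tab)[which(cumsum(tab) >= sum(tab) / 2)[1]]
      } else {
        lev <- names(tab)[which.max(tab)]
      }
      return(factor(lev, levels = levels(v), ordered = is.ordered(v)))
    }
    stop("unsupported covariate type: ", cl)
  })
  names(out) <- covariates
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Aalen-Johansen occupation curve of the illness-death model
#'
#' Plug-in product-integral estimator of the state-transition probability
#' matrix P(age0, t) from the three predicted cumulative-hazard step
#' functions: at every jump age the matrix is multiplied by `I + dA(u)`
#' with off-diagonals from the transition increments. A row whose
#' off-diagonal increments sum above one is truncated and renormalized
#' (counted in `truncated`). States: 1 = CVD-free, 2 = alive with CVD,
#' 3 = dead (absorbing).
#'
#' @param ch1,ch2,ch3 `sleeple_cumhaz` step functions for the healthy to
#'   CVD, healthy to death, CVD to death transitions.
#' @param age0 conditioning age; jumps at or before it are ignored.
#' @param tau restriction age; jumps after it are ignored.
#' @return object of class `sleeple_ajcurve`: data.frame `age`, `p11`,
#'   `p12`, `p13`, `p22`, `p23` (first row = identity at `age0`), plus
#'   attribute `truncated`.
#' @export
aalen_johansen <- function(ch1, ch2, ch3, age0 = 40, tau = 81) {
  for (ch in list(ch1, ch2, ch3))
    if (!all(c("time", "increment") %in% names(ch)))
      stop("malformed step function: need time/increment")
  grid <- sort(unique(c(ch1$time, ch2$time, ch3$time)))
  grid <- grid[grid > age0 & grid <= tau]
  inc_on <- function(ch) {
    out <- numeric(length(grid))
    i <- match(ch$time, grid)
    ok <- !is.na(i)
    out[i[ok]] <- ch$increment[ok]
    out
  }
  if (length(grid) == 0) {
    curve <- data.frame(age = age0, p11 = 1, p12 = 0, p13 = 0,
                        p22 = 1, p23 = 0)
    attr(curve, "truncated") <- 0L
    class(curve) <- c("sleeple_ajcurve", "data.frame")
    return(curve)
  }
  res <- .aj_cpp(grid, inc_on(ch1), inc_on(ch2), inc_on(ch3))
  pr <- res$prob
  curve <- data.frame(age = c(age0, grid),
                      p11 = c(1, pr[, 1]), p12 = c(0, pr[, 2]),
                      p13 = c(0, pr[, 3]), p22 = c(1, pr[, 4]),
                      p23 = c(0, pr[, 5]))
  attr(curve, "truncated") <- res$truncated
  if (res$truncated > 0 && isTRUE(getOption("sleeple.verbose", FALSE)))
    message("aalen_johansen: ", res$truncated,
            " jump(s) truncated to keep rows stochastic")
  class(curve) <- c("sleeple_ajcurve", "data.frame")
  curve
}

#' Restricted state-specific life expectancies from an occupation curve
#'
#' Integrates the piecewise-constant, right-continuous occupation
#' probabilities exactly (sum of step width times step value):
#' `e_free = integral of P11(age0, u) du`, `e_with = integral of P12`,
#' `e_total = e_free + e_with`, all over `[age0, tau]`.
#'
#' @param curve a [aalen_johansen()] curve.
#' @param age0,tau integration limits (years of age).
#' @return named numeric `c(e_free, e_with, e_total)` in years.
#' @export
restricted_expectancies <- function(curve, age0 = 40, tau = 81) {
  stopifnot(inherits(curve, "sleeple_ajcurve") || is.data.frame(curve))
  a <- curve$age
  keep <- a >= age0 & a <= tau
  a <- a[keep]
  width <- diff(c(a, tau))
  e_free <- sum(curve$p11[keep] * width)
  e_with <- sum(curve$p12[keep] * width)
  c(e_free = e_free, e_with = e_with, e_total = e_free + e_with)
}

#' Years of life lost by an exposed group
#'
#' Difference in restricted expectancies, reference minus exposed:
#' positive values are years lost by the exposed group. `yll_free`
#' contrasts CVD-free years, `yll_total` total years alive.
#'
#' @param exposed,reference named vectors as returned by
#'   [restricted_expectancies()] (or [true_life_expectancy()]).
#' @return named numeric `c(yll_free, yll_total)`.
#' @export
#' @examples
#' years_of_life_lost(c(e_free = 31.46, e_with = 0, e_total = 31.46),
#'                    c(e_free = 33.26, e_with = 0, e_total = 33.26))
years_of_life_lost <- function(exposed, reference) {
  stopifnot(all(c("e_free", "e_total") %in% names(exposed)),
            all(c("e_free", "e_total") %in% names(reference)))
  c(yll_free = unname(reference[["e_free"]] - exposed[["e_free"]]),
    yll_total = unname(reference[["e_total"]] - exposed[["e_total"]]))
}

#' Point estimate of state-specific life expectancies at a profile
#'
#' The core analysis closure: fit the three transition-specific Cox
#' models on a multistate dataset, predict cumulative hazards at the
#' profile, run the Aalen-Johansen product integral and integrate. All
#' three fits must converge, else an error (the bootstrap treats that as
#' a dropped iteration).
#'
#' @param msdata a [to_multistate()] dataset (one stratum).
#' @param covariates covariate columns for every transition model.
#' @param profile covariate setting (see [covariate_profile()]).
#' @param age0,tau conditioning and restriction ages.
#' @param ties tie handling for [fit_cox()].
#' @return named numeric `c(e_free, e_with, e_total)`.
#' @export
estimate_life_expectancy <- function(msdata, covariates, profile,
                                     age0 = 40, tau = 81, ties = "efron") {
  fits <- fit_transitions(msdata, covariates, ties = ties)
  predict_expectancies(fits, profile, age0 = age0, tau = tau)
}

#' @rdname estimate_life_expectancy
#' @export
fit_transitions <- function(msdata, covariates, ties = "efron") {
  fits <- lapply(1:3, function(k)
    fit_cox(msdata, transition = k, covariates = covariates, ties = ties))
  if (!all(vapply(fits, `[[`, TRUE, "converged")))
    stop("transition fit did not converge")
  fits
}

#' @rdname estimate_life_expectancy
#' @param fits list of three `sleeple_coxfit` objects from
#'   [fit_transitions()].
#' @export
predict_expectancies <- function(fits, profile, age0 = 40, tau = 81) {
  ch <- lapply(fits, predict_cumhaz, profile = profile)
  restricted_expectancies(aalen_johansen(ch[[1]], ch[[2]], ch[[3]],
                                         age0 = age0, tau = tau),
                          age0 = age0, tau = tau)
}

#' Nonparametric bootstrap percentile intervals
#'
#' Resamples persons with replacement (all of a person's transition rows
#' move together), within sex strata when a `strata` factor is given,
#' re-runs the full analysis closure, and returns 2.5/97.5 empirical
#' percentile intervals (linear interpolation). Iterations whose closure
#' throws (e.g. a non-converged refit) are dropped and logged; the CI is
#' flagged when more than 5 percent dropped.
#'
#' @param data person-level data.frame handed to `statistic`.
#' @param statistic function of a resampled `data` returning a named
#'   numeric vector.
#' @param B bootstrap iterations (>= 2).
#' @param seed RNG seed; same seed, same CIs.
#' @param strata optional factor of `nrow(data)` for stratified
#'   resampling.
#' @param conf_level interval level.
#' @return list: `point` (statistic on the original data), `ci` (matrix
#'   2 x q), `se` (bootstrap standard deviation per component), `B`,
#'   `dropped`, `flagged`.
#' @export
bootstrap_ci <- function(data, statistic, B = 1000, seed = 1L,
                         strata = NULL, conf_level = 0.95) {
  stopifnot(B >= 2)
  point <- statistic(data)
  idx_by_stratum <- if (is.null(strata)) list(seq_len(nrow(data)))
                    else split(seq_len(nrow(data)), strata)
  draws <- with_seed(seed, {
    lapply(seq_len(B), function(b) {
      take <- unlist(lapply(idx_by_stratum, function(i)
        i[sample.int(length(i), length(i), replace = TRUE)]),
        use.names = FALSE)
      tryCatch(statistic(data[take, , drop = FALSE]),
               error = function(e) NULL)
    })
  })
  ok <- !vapply(draws, is.null, TRUE)
  dropped <- sum(!ok)
  if (dropped > 0)
    message("bootstrap: ", dropped, " of ", B, " iterations dropped")
  mat <- do.call(rbind, draws[ok])
  alpha <- (1 - conf_level) / 2
  ci <- apply(mat, 2, quantile, probs = c(alpha, 1 - alpha), names = FALSE,
              type = 7)
  rownames(ci) <- c("lower", "upper")
  colnames(ci) <- names(point)
  se <- apply(mat, 2, stats::sd)
  names(se) <- names(point)
  flagged <- dropped > 0.05 * B
  if (flagged) warning("bootstrap CI flagged: > 5% of iterations dropped")
  list(point = point, ci = ci, se = se, B = B, dropped = dropped,
       flagged = flagged)
}
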