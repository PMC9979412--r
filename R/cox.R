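# Transition-specific Cox proportional hazards on left-truncated
# counting-process data. The partial-likelihood maximizer (Newton-Raphson
# with step halving, Efron ties, case weights) lives in src/cox.cpp; this
# file owns design-matrix construction, validation, and the Breslow
# baseline / profile prediction interface.

build_design <- function(data, covariates) {
  if (is.null(covariates) || length(covariates) == 0)
    return(list(X = matrix(0, nrow(data), 0), columns = character(0),
                frame = data[0, 0, drop = FALSE]))
  miss <- setdiff(covariates, names(data))
  if (length(miss)) stop("covariate(s) not in data: ", paste(miss, collapse = ", "))
  d <- data[covariates]
  if (anyNA(d)) stop("missing covariate values; run the exclusion cascade first")
  X <- model.matrix(~ ., data = d)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  list(X = X, columns = colnames(X), frame = d)
}

# levels/classes needed to rebuild a design row from a profile
frame_schema <- function(frame) {
  lapply(frame, function(v) {
    if (is.factor(v)) list(type = "factor", levels = levels(v),
                           ordered = is.ordered(v))
    else if (is.logical(v)) list(type = "logical")
    else list(type = "numeric")
  })
}

# Design row(s) for one or more profiles, using the fit's stored factor
# schema; accepts a one-row or multi-row data.frame (one row per
# prediction profile).
profile_row <- function(fit, profile) {
  if (length(fit$covariates) == 0)
    return(matrix(0, max(1, NROW(profile)), 0))
  profile <- as.list(profile)
  miss <- setdiff(fit$covariates, names(profile))
  if (length(miss))
    stop("profile missing covariate(s): ", paste(miss, collapse = ", "))
  d <- lapply(fit$covariates, function(cl) {
    sc <- fit$schema[[cl]]
    v <- profile[[cl]]
    switch(sc$type,
           factor = factor(as.character(v), levels = sc$levels,
                           ordered = sc$ordered),
           logical = as.logical(v),
           as.numeric(v))
  })
  names(d) <- fit$covariates
  d <- as.data.frame(d)
  if (anyNA(d)) stop("profile value outside allowed levels")
  X <- model.matrix(~ ., data = d)
  X[, colnames(X) != "(Intercept)", drop = FALSE]
}

#' Fit a transition-specific Cox model
#'
#' Maximizes the left-truncated Cox partial likelihood (risk set at age t
#' = rows with entry < t <= exit) by Newton-Raphson with step halving,
#' converging when the relative change in log partial likelihood drops
#' below `tol` (default 1e-9) or after `max_iter` iterations. Tied event
#' ages use the Efron correction by default; bootstrap resampling
#' duplicates persons, so ties do occur even on a continuous age scale.
#' Monotone likelihoods (perfect separation) are flagged as
#' non-convergence with a diagnostic warning.
#'
#' @param msdata a [to_multistate()] data.frame (or any data.frame with
#'   `entry`, `exit`, `status` and covariate columns).
#' @param transition transition id to subset on (1 = healthy to CVD,
#'   2 = healthy to death, 3 = CVD to death), or `NULL` to use all rows.
#' @param covariates character vector of covariate column names; `NULL`
#'   fits the null model (Nelson-Aalen baseline).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param weights optional non-negative case weights.
#' @param max_iter,tol Newton-Raphson controls.
#' @return object of class `sleeple_coxfit`: named `beta`, `vcov`,
#'   `imat`, `loglik`, `loglik0`, `iter`, `converged`, `n`, `nevent`,
#'   plus the data slices needed by [predict_cumhaz()].
#' @export
fit_cox <- function(msdata, transition = NULL, covariates = NULL,
                    ties = c("efron", "breslow"), weights = NULL,
                    max_iter = 50L, tol = 1e-9) {
  ties <- match.arg(ties)
  d <- if (is.null(transition)) msdata
       else msdata[msdata$transition == transition, , drop = FALSE]
  if (nrow(d) == 0) stop("no rows for transition ", transition)
  nevent <- sum(d$status)
  if (nevent == 0) stop("zero events on transition ",
                        transition %||% "(all)")
  des <- build_design(d, covariates)
  if (ncol(des$X) > 0) {
    const <- apply(des$X, 2, function(x) diff(range(x)) == 0)
    if (any(const))
      stop("constant covariate column(s): ",
           paste(colnames(des$X)[const], collapse = ", "))
  }
  w <- weights %||% rep(1, nrow(d))
  stopifnot(length(w) == nrow(d), all(w >= 0))
  res <- .cox_fit_cpp(d$entry, d$exit, as.numeric(d$status), des$X, w,
                      as.integer(max_iter), tol, ties == "efron")
  beta <- drop(res$beta)
  names(beta) <- des$columns
  vcov <- res$vcov
  dimnames(vcov) <- list(des$columns, des$columns)
  if (res$diverged)
    warning("monotone likelihood suspected (|beta| > 20); fit flagged ",
            "non-converged")
  structure(list(
    transition = transition, beta = beta, vcov = vcov, imat = res$imat,
    loglik = res$loglik, loglik0 = res$loglik0, iter = res$iter,
    converged = res$converged, singular = res$singular,
    diverged = res$diverged, ties = ties, covariates = covariates %||% character(0),
    schema = frame_schema(des$frame), n = nrow(d), nevent = nevent,
    data = list(entry = d$entry, exit = d$exit,
                status = as.numeric(d$status), eta = drop(des$X %*% res$beta),
                weights = w)),
    class = "sleeple_coxfit")
}

#' @export
print.sleeple_coxfit <- function(x, ...) {
  cat(sprintf("<sleeple_coxfit> transition %s: n = %d, events = %d, %s\n",
              x$transition %||% "all", x$n, x$nevent,
              if (x$converged) sprintf("converged in %d iter", x$iter)
              else "NOT converged"))
  if (length(x$beta)) {
    se <- sqrt(diag(x$vcov))
    tab <- data.frame(coef = x$beta, `exp(coef)` = exp(x$beta), se = se,
                      z = x$beta / se, check.names = FALSE)
    print(round(tab, 4))
  }
  invisible(x)
}

#' Log partial likelihood at a fixed coefficient vector
#'
#' Evaluates the same left-truncated (optionally weighted, Efron- or
#' Breslow-tied) log partial likelihood that [fit_cox()] maximizes, at an
#' arbitrary `beta`. Used by the brute-force grid-search oracle in the
#' test-suite; exported because it is also handy for profiling fits.
#'
#' @inheritParams fit_cox
#' @param X design matrix (already expanded; no intercept).
#' @param entry,exit,status counting-process columns.
#' @param beta coefficient vector of length `ncol(X)`.
#' @return scalar log partial likelihood.
#' @export
cox_partial_loglik <- function(entry, exit, status, X, beta,
                               weights = NULL, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  .cox_loglik_cpp(entry, exit, as.numeric(status), X,
                  weights %||% rep(1, length(entry)), beta, ties == "efron")
}

#' Breslow baseline and profile-specific cumulative hazards
#'
#' `predict_cumhaz()` returns the right-continuous step function
#' `A_k(t | profile) = A_0k(t) exp(beta'(profile - reference))` with the
#' fit internally centered at the profile itself, so no exponential
#' overflow can occur far from the data's covariate range.
#' `breslow_baseline()` is the special case at the zero covariate value
#' (all factors at their first level, numerics at 0); with `beta = 0` and
#' no ties it reduces to the Nelson-Aalen estimator. Increments at event
#' age t equal the weighted death count over the weighted risk-set sum of
#' `exp(beta'(x - profile))`.
#'
#' @param fit a [fit_cox()] object.
#' @param profile named list / one-row data.frame covering every
#'   covariate of the fit (see [covariate_profile()]); `NULL` means the
#'   zero reference.
#' @return object of class `sleeple_cumhaz`: `time` (ascending event
#'   ages), `increment`, `cumhaz` (cumulative sum), `profile`.
#' @export
predict_cumhaz <- function(fit, profile = NULL) {
  stopifnot(inherits(fit, "sleeple_coxfit"))
  if (!fit$converged) warning("predicting from a non-converged fit")
  off <- if (is.null(profile) || length(fit$beta) == 0) 0
         else drop(profile_row(fit, profile) %*% fit$beta)
  bl <- .breslow_cpp(fit$data$entry, fit$data$exit, fit$data$status,
                     fit$data$eta - off, fit$data$weights)
  structure(list(time = drop(bl$time), increment = drop(bl$increment),
                 cumhaz = cumsum(drop(bl$increment)), profile = profile),
            class = "sleeple_cumhaz")
}

#' @rdname predict_cumhaz
#' @export
breslow_baseline <- function(fit) predict_cumhaz(fit, profile = NULL)

# fast path: predict at a precomputed linear-predictor offset
# off = beta' x0 (x0 on the model.matrix scale)
predict_cumhaz_offset <- function(fit, off) {
  bl <- .breslow_cpp(fit$data$entry, fit$data$exit, fit$data$status,
                     fit$data$eta - off, fit$data$weights)
  structure(list(time = drop(bl$time), increment = drop(bl$increment),
                 cumhaz = cumsum(drop(bl$increment)), profile = NULL),
            class = "sleeple_cumhaz")
}

#' @export
print.sleeple_cumhaz <- function(x, ...) {
  cat("<sleeple_cumhaz>", length(x$time), "jumps")
  if (length(x$time))
    cat(sprintf(", ages %.2f-%.2f, A(max) = %.4f",
                min(x$time), max(x$time), max(x$cumhaz)))
  cat("\n")
  invisible(x)
}

# Evaluate a cumulative-hazard step function at ages t (right-continuous).
eval_cumhaz <- function(ch, t) {
  if (!length(ch$time)) return(rep(0, length(t)))
  idx <- findInterval(t, ch$time)
  c(0, ch$cumhaz)[idx + 1]
}

#' Serialize a fitted transition model
#'
#' Writes coefficients, covariance and the baseline step function to a
#' JSON file so downstream stages (life-expectancy estimation, bootstrap
#' aggregation) can reuse fits without refitting.
#'
#' @param fit a `sleeple_coxfit`.
#' @param path file path.
#' @export
write_coxfit <- function(fit, path) {
  bl <- breslow_baseline(fit)
  jsonlite::write_json(list(
    transition = fit$transition, beta = as.list(fit$beta),
    vcov = fit$vcov, loglik = fit$loglik, converged = fit$converged,
    ties = fit$ties, n = fit$n, nevent = fit$nevent,
    baseline = list(time = bl$time, increment = bl$increment)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
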