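# Synthetic-cohort generator: participants with correlated sleep traits,
# a Table-1-like covariate mix, illness-death event ages drawn from the
# truth's Gompertz proportional-hazards intensities, and planted coded
# sleep-disorder events in a pre-enrollment window.

#' Covariate and questionnaire response sets
#'
#' `covariate_levels()` returns the factor levels of the categorical
#' covariates in the participant schema (all ordered except economic
#' activity); `sleep_response_sets()` returns the allowed questionnaire
#' responses for the five sleep characteristics. Sleep duration is asked
#' in whole hours.
#'
#' @return A named list of character (or integer) vectors.
#' @export
covariate_levels <- function() {
  list(
    ses = c("q1_most_deprived", "q2", "q3", "q4_least_deprived"),
    perceived_health = c("excellent", "good", "fair", "poor"),
    bmi_class = c("lt30", "b30to40", "ge40"),
    economic_activity = c("retired", "employed", "night_shift", "day_shift"),
    smoking = c("never", "former", "current"),
    alcohol = c("never", "former", "lt14", "b14to28", "ge28"),
    diet = c("poor", "intermediate", "healthy"),
    physical_activity = c("none", "lt10", "b10to20", "ge20"))
}

#' @rdname covariate_levels
#' @export
sleep_response_sets <- function() {
  list(
    chronotype = c("definitely_morning", "more_morning",
                   "more_evening", "definitely_evening"),
    sleep_duration = 1:12,
    insomnia = c("never_rarely", "sometimes", "usually"),
    snoring = c("no", "yes"),
    sleepiness = c("never_rarely", "sometimes", "often", "always"))
}

#' @rdname covariate_levels
#' @export
sleep_cols <- function() c("chronotype", "sleep_duration", "insomnia",
                           "snoring", "sleepiness")

#' @rdname covariate_levels
#' @export
covariate_cols <- function() c("ses", "mental_health", "perceived_health",
                               "bmi_class", "economic_activity", "smoking",
                               "alcohol", "diet", "screen_time",
                               "physical_activity")

#' Numeric covariate scores used by the truth's linear predictor
#'
#' Factors map to `level index - 1`, logicals to 0/1, numerics pass
#' through. The generator applies the truth's covariate log-HRs to these
#' scores; because factor dummies nest a linear-in-level effect, the
#' pipeline's factor-coded Cox fits remain correctly specified.
#'
#' @param data participant data.frame.
#' @return numeric matrix, one column per covariate.
#' @export
covariate_scores <- function(data) {
  cols <- covariate_cols()
  out <- vapply(cols, function(cl) {
    v <- data[[cl]]
    if (is.factor(v)) as.numeric(v) - 1
    else if (is.logical(v)) as.numeric(v)
    else as.numeric(v)
  }, numeric(nrow(data)))
  if (is.null(dim(out)))  # single-row input: vapply returns a bare vector
    out <- matrix(out, nrow = 1, dimnames = list(NULL, cols))
  else colnames(out) <- cols
  out
}

# truncated-normal draw
rtnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

# Vectorized bisection for H(t) = E with H elementwise non-decreasing in t.
# Returns NA where H(tmax) < E (no event before the cap).
vbisect <- function(H, E, tmax, iter = 64L) {
  lo <- rep(0, length(E))
  hi <- rep(tmax, length(E))
  none <- H(hi) < E
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    below <- H(mid) < E
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  out <- (lo + hi) / 2
  out[none] <- NA_real_
  out
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws `n` participants under a [simulation_truth()]: sex, enrollment
#' age and date, a sleep category (by sex-specific prevalence) realized
#' as five questionnaire responses, the covariate bundle, a prevalent-CVD
#' flag, and event ages from the three-state illness-death process by
#' inversion sampling of the Gompertz proportional-hazards intensities
#' (competing healthy-to-CVD / healthy-to-death exits; clock-forward
#' CVD-to-death). Event ages are raw process times; administrative
#' censoring is recorded as `censor_age` and applied downstream by
#' [build_followup()]. Coded sleep-disorder events are planted in the
#' lookback window before enrollment for a configurable fraction, plus
#' occasional out-of-window codes; missingness is injected completely at
#' random at the configured rates.
#'
#' @param truth a [simulation_truth()].
#' @param n number of participants (>= 1).
#' @param seed integer; defaults to `truth$seed`. Same truth and seed give
#'   byte-identical output.
#' @return list with `participants` (data.frame, one row per person) and
#'   `events` (data.frame of coded events: `id`, `date`, `offset_years`,
#'   `vocabulary`, `code`).
#' @export
generate_cohort <- function(truth, n, seed = truth$seed) {
  stopifnot(inherits(truth, "sleeple_truth"))
  if (length(n) != 1 || n < 1) stop("n must be a positive count")
  n <- as.integer(n)
  with_seed(seed, {
    lv <- covariate_levels()
    sex <- factor(ifelse(runif(n) < truth$p_female, "female", "male"),
                  levels = c("female", "male"))
    a0 <- rtnorm(n, truth$enrollment$mean, truth$enrollment$sd,
                 truth$enrollment$min, truth$enrollment$max)
    enroll_date <- as.Date("2006-03-01") +
      floor(runif(n, 0, as.numeric(as.Date("2010-07-31") - as.Date("2006-03-01"))))
    censor_age <- a0 + rtnorm(n, truth$followup$mean, truth$followup$sd,
                              truth$followup$min, truth$followup$max)

    # sleep category and the five responses realizing it
    cat3 <- c("healthy", "intermediate", "poor")
    category <- character(n)
    for (sx in c("female", "male")) {
      i <- which(sex == sx)
      category[i] <- sample(cat3, length(i), replace = TRUE,
                            prob = truth$sleep_prevalence[[sx]])
    }
    score <- ifelse(category == "healthy", sample(4:5, n, TRUE),
                    ifelse(category == "intermediate", sample(2:3, n, TRUE),
                           sample(0:1, n, TRUE)))
    healthy_trait <- matrix(FALSE, n, 5,
                            dimnames = list(NULL, sleep_cols()))
    for (i in seq_len(n))
      healthy_trait[i, sample.int(5, score[i])] <- TRUE
    rs <- sleep_response_sets()
    pick <- function(healthy, hset, uset)
      ifelse(healthy, sample(hset, n, TRUE), sample(uset, n, TRUE))
    chronotype <- pick(healthy_trait[, "chronotype"],
                       rs$chronotype[1:2], rs$chronotype[3:4])
    sleep_duration <- pick(healthy_trait[, "sleep_duration"],
                           7:8, c(4L, 5L, 6L, 9L, 10L, 11L))
    insomnia <- pick(healthy_trait[, "insomnia"],
                     rs$insomnia[1], rs$insomnia[2:3])
    snoring <- pick(healthy_trait[, "snoring"], "no", "yes")
    sleepiness <- pick(healthy_trait[, "sleepiness"],
                       rs$sleepiness[1:2], rs$sleepiness[3:4])

    covs <- data.frame(
      ses = factor(sample(lv$ses, n, TRUE, c(.22, .25, .26, .27)),
                   levels = lv$ses, ordered = TRUE),
      mental_health = runif(n) < 0.33,
      perceived_health = factor(sample(lv$perceived_health, n, TRUE,
                                       c(.19, .61, .17, .03)),
                                levels = lv$perceived_health, ordered = TRUE),
      bmi_class = factor(sample(lv$bmi_class, n, TRUE, c(.78, .20, .02)),
                         levels = lv$bmi_class, ordered = TRUE),
      economic_activity = factor(sample(lv$economic_activity, n, TRUE,
                                        c(.37, .53, .05, .05)),
                                 levels = lv$economic_activity),
      smoking = factor(sample(lv$smoking, n, TRUE, c(.56, .34, .10)),
                       levels = lv$smoking, ordered = TRUE),
      alcohol = factor(sample(lv$alcohol, n, TRUE, c(.04, .03, .56, .22, .15)),
                       levels = lv$alcohol, ordered = TRUE),
      diet = factor(sample(lv$diet, n, TRUE, c(.06, .62, .32)),
                    levels = lv$diet, ordered = TRUE),
      screen_time = round(pmax(0, rnorm(n, 3.8, 2.0)), 1),
      physical_activity = factor(sample(lv$physical_activity, n, TRUE,
                                        c(.15, .10, .15, .60)),
                                 levels = lv$physical_activity, ordered = TRUE))

    # linear predictors per transition (from the true, pre-missingness values)
    z <- covariate_scores(covs)
    eta <- vapply(names(truth$base), function(k) {
      e <- numeric(n)
      e[category == "intermediate"] <- truth$sleep_hr[[k]][["intermediate"]]
      e[category == "poor"] <- truth$sleep_hr[[k]][["poor"]]
      eff <- truth$covariate_effects[[k]]
      common <- intersect(names(eff), colnames(z))
      if (length(common)) e <- e + as.vector(z[, common, drop = FALSE] %*% eff[common])
      e
    }, numeric(n))

    b <- truth$base
    cap_age <- 120
    # exit from healthy: competing transitions 1 and 2
    H12 <- function(t) {
      u <- a0 + t
      exp(eta[, "cvd"]) * gompertz_cumhaz(b$cvd[["rate"]], b$cvd[["shape"]], a0, u) +
        exp(eta[, "death_healthy"]) *
          gompertz_cumhaz(b$death_healthy[["rate"]], b$death_healthy[["shape"]], a0, u)
    }
    t_exit <- vbisect(H12, rexp(n), cap_age - max(a0))
    u_exit <- a0 + t_exit
    lam1 <- exp(eta[, "cvd"]) *
      gompertz_hazard(b$cvd[["rate"]], b$cvd[["shape"]], u_exit)
    lam2 <- exp(eta[, "death_healthy"]) *
      gompertz_hazard(b$death_healthy[["rate"]], b$death_healthy[["shape"]], u_exit)
    p1 <- ifelse(lam1 + lam2 > 0, lam1 / (lam1 + lam2), 0)
    is_cvd <- !is.na(t_exit) & runif(n) < p1

    cvd_age <- ifelse(is_cvd, u_exit, NA_real_)
    death_age <- ifelse(!is.na(t_exit) & !is_cvd, u_exit, NA_real_)

    # CVD -> death, clock-forward from the onset age
    i3 <- which(is_cvd)
    if (length(i3) && b$death_cvd[["rate"]] > 0) {
      u0 <- cvd_age[i3]
      e3 <- exp(eta[i3, "death_cvd"])
      H3 <- function(t) e3 * gompertz_cumhaz(b$death_cvd[["rate"]],
                                             b$death_cvd[["shape"]], u0, u0 + t)
      t3 <- vbisect(H3, rexp(length(i3)), cap_age - max(u0))
      death_age[i3] <- u0 + t3
    }

    participants <- data.frame(
      id = sprintf("P%06d", seq_len(n)), sex = sex,
      enrollment_age = round(a0, 4), enrollment_date = enroll_date,
      chronotype = chronotype, sleep_duration = as.integer(sleep_duration),
      insomnia = insomnia, snoring = snoring, sleepiness = sleepiness,
      covs,
      prevalent_cvd = runif(n) < truth$prevalent_cvd,
      cvd_age = round(cvd_age, 4), death_age = round(death_age, 4),
      censor_age = round(censor_age, 4),
      stringsAsFactors = FALSE)

    # missingness (MCAR), injected into recorded values only
    for (cl in sleep_cols())
      participants[[cl]][runif(n) < truth$missing$sleep] <- NA
    for (cl in covariate_cols())
      participants[[cl]][runif(n) < truth$missing$covariates] <- NA

    events <- plant_disorder_events(participants, truth)
    list(participants = participants, events = events)
  })
}

# Plant coded sleep-disorder events around enrollment using the default
# illustrative code list: in-window events at offsets in [-lookback, 0],
# plus occasional out-of-window events at offsets in (-lookback-2, -lookback).
plant_disorder_events <- function(participants, truth) {
  cl <- default_codelist()
  n <- nrow(participants)
  rows <- list()
  emit <- function(i, disorder, offset) {
    sel <- cl$entries$disorder == disorder |
      (disorder == "other" & cl$entries$disorder == "prescription")
    entries <- cl$entries[sel, ]
    j <- sample.int(nrow(entries), 1)
    data.frame(id = participants$id[i],
               date = participants$enrollment_date[i] + round(offset * 365.25),
               offset_years = round(offset, 4),
               vocabulary = entries$vocabulary[j], code = entries$code[j],
               stringsAsFactors = FALSE)
  }
  for (d in names(truth$disorder_rates)) {
    hit <- which(runif(n) < truth$disorder_rates[[d]])
    for (i in hit) {
      k <- sample(1:2, 1)
      for (j in seq_len(k))
        rows[[length(rows) + 1]] <- emit(i, d, runif(1, -truth$lookback, 0))
    }
  }
  out <- which(runif(n) < truth$out_of_window_rate)
  for (i in out) {
    d <- sample(names(truth$disorder_rates), 1)
    rows[[length(rows) + 1]] <-
      emit(i, d, runif(1, -truth$lookback - 2, -truth$lookback - 1e-6))
  }
  if (!length(rows))
    return(data.frame(id = character(), date = as.Date(character()),
                      offset_years = numeric(), vocabulary = character(),
                      code = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$id, out$date), , drop = FALSE]
}

#' Write / read a cohort as delimited text
#'
#' Participant and coded-event tables as comma-separated files with a
#' header row, ISO-8601 dates, and the literal token `NA` for missing
#' values. `read_cohort()` restores the factor levels of the schema.
#'
#' @param cohort list with `participants` and `events` as returned by
#'   [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `write_cohort()` returns the two file paths invisibly;
#'   `read_cohort()` returns a cohort list.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pp <- file.path(dir, "participants.csv")
  pe <- file.path(dir, "coded_events.csv")
  write.csv(cohort$participants, pp, row.names = FALSE, na = "NA")
  write.csv(cohort$events, pe, row.names = FALSE, na = "NA")
  invisible(c(participants = pp, events = pe))
}

#' @rdname write_cohort
#' @param participants,events file paths of the two tables.
#' @export
read_cohort <- function(participants, events) {
  p <- read.csv(participants, stringsAsFactors = FALSE, na.strings = "NA")
  p$sex <- factor(p$sex, levels = c("female", "male"))
  p$enrollment_date <- as.Date(p$enrollment_date)
  lv <- covariate_levels()
  for (cl in names(lv)) {
    ord <- cl != "economic_activity"
    bad <- !is.na(p[[cl]]) & !(p[[cl]] %in% lv[[cl]])
    if (any(bad))
      stop("participants: invalid level in column '", cl, "' at row(s) ",
           paste(head(which(bad), 5), collapse = ", "))
    p[[cl]] <- factor(p[[cl]], levels = lv[[cl]], ordered = ord)
  }
  p$mental_health <- as.logical(p$mental_health)
  p$prevalent_cvd <- as.logical(p$prevalent_cvd)
  e <- read.csv(events, stringsAsFactors = FALSE, na.strings = "NA")
  if (nrow(e)) e$date <- as.Date(e$date)
  list(participants = p, events = e)
}
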