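# Cohort construction: the sequential exclusion cascade, per-person
# follow-up with the tau = 81 restriction and the 2-year landmark, and
# the counting-process expansion of the irreversible illness-death model
# on the age timescale (left truncation at enrollment).

#' Sequential exclusion cascade
#'
#' Applies the four exclusion stages in fixed order: (1) missing data in
#' any of the five sleep responses (unscorable profile), (2) prevalent
#' CVD at baseline, (3) missing covariates, (4) incident CVD or death
#' observed within the first `landmark` years of follow-up. A person
#' removed at a stage is never evaluated at later stages.
#'
#' @param participants participant table (see [generate_cohort()]).
#' @param profiles output of [score_sleep()] on the same rows.
#' @param landmark landmark window in years (0 disables stage 4).
#' @param tau restriction age used to decide whether an early event was
#'   observed.
#' @return list with `kept` (retained participant rows, with the profile
#'   columns bound on) and `report` (data.frame: `stage`, `removed`,
#'   `remaining`).
#' @export
apply_exclusions <- function(participants, profiles, landmark = 2, tau = 81) {
  stopifnot(nrow(participants) == nrow(profiles))
  n0 <- nrow(participants)
  keep <- rep(TRUE, n0)
  stages <- c("missing_sleep", "prevalent_cvd", "missing_covariates",
              "landmark_events")
  removed <- integer(4)

  s1 <- keep & !profiles$scorable
  removed[1] <- sum(s1); keep <- keep & !s1

  s2 <- keep & !is.na(participants$prevalent_cvd) & participants$prevalent_cvd
  removed[2] <- sum(s2); keep <- keep & !s2

  covs <- participants[covariate_cols()]
  s3 <- keep & Reduce(`|`, lapply(covs, is.na))
  removed[3] <- sum(s3); keep <- keep & !s3

  exit_cap <- pmin(participants$censor_age, tau)
  cvd_obs <- !is.na(participants$cvd_age) & participants$cvd_age <= exit_cap
  dth_obs <- !is.na(participants$death_age) & participants$death_age <= exit_cap
  first_ev <- pmin(ifelse(cvd_obs, participants$cvd_age, Inf),
                   ifelse(dth_obs, participants$death_age, Inf))
  s4 <- keep & is.finite(first_ev) &
    (first_ev - participants$enrollment_age) <= landmark
  if (landmark <= 0) s4 <- keep & FALSE
  removed[4] <- sum(s4); keep <- keep & !s4

  report <- data.frame(
    stage = c("input", stages),
    removed = c(0L, removed),
    remaining = c(n0, n0 - cumsum(removed)))
  kept <- cbind(participants[keep, , drop = FALSE],
                profiles[keep, setdiff(names(profiles), names(participants)),
                         drop = FALSE])
  list(kept = kept, report = report)
}

#' Per-person follow-up under the restriction age
#'
#' Builds the event summary feeding the multistate expansion: effective
#' exit age = `min(death age, administrative censoring age, tau)`; death
#' at exactly `tau` counts as an event; CVD events after the effective
#' exit are discarded; a CVD age colliding with the exit age is nudged
#' earlier by `epsilon` so intervals stay non-degenerate. Persons whose
#' interval is empty after truncation are flagged `dropped`.
#'
#' @param participants participant rows that passed exclusions.
#' @param tau restriction age (years).
#' @param epsilon same-age nudge in years (default one day).
#' @return data.frame: `id`, `entry` (enrollment age), `exit`,
#'   `cvd_status`, `cvd_age` (NA unless `cvd_status == 1`),
#'   `death_status`, `dropped`.
#' @export
build_followup <- function(participants, tau = 81, epsilon = 1 / 365.25) {
  p <- participants
  death <- ifelse(is.na(p$death_age), Inf, p$death_age)
  exit <- pmin(death, p$censor_age, tau)
  death_status <- as.integer(is.finite(death) & death <= pmin(p$censor_age, tau))
  cvd_age <- p$cvd_age
  cvd_status <- as.integer(!is.na(cvd_age) & cvd_age <= exit)
  cvd_age[cvd_status == 0] <- NA_real_
  # nudge CVD recorded at the exit age (same-day CVD + death/censoring)
  collide <- cvd_status == 1 & cvd_age >= exit - 1e-12
  cvd_age[collide] <- exit[collide] - epsilon
  dropped <- exit <= p$enrollment_age |
    (cvd_status == 1 & cvd_age <= p$enrollment_age)
  if (any(dropped))
    message(sum(dropped), " person(s) dropped: empty interval after truncation")
  data.frame(id = p$id, entry = p$enrollment_age, exit = exit,
             cvd_status = cvd_status, cvd_age = cvd_age,
             death_status = death_status, dropped = dropped,
             stringsAsFactors = FALSE)
}

#' Counting-process expansion of the illness-death model
#'
#' One row per person per at-risk transition on the age timescale with
#' left truncation at enrollment. Healthy persons contribute a row for
#' transition 1 (healthy to CVD) and transition 2 (healthy to death) over
#' (enrollment, first exit]; persons with CVD additionally contribute a
#' transition-3 row over (CVD age, death-or-censoring age]. The
#' transition-2 row of a CVD case is censored at the CVD age; the
#' transition-1 row of a death without CVD is censored at death.
#'
#' @param followup output of [build_followup()] (dropped rows are
#'   excluded automatically).
#' @param data optional data.frame with `id` plus columns to carry onto
#'   every row of that person (covariates, exposure labels, sex).
#' @param sort order rows by id and transition (cosmetic; the bootstrap
#'   path switches it off).
#' @return data.frame: `id`, `transition` (1, 2, 3), `entry`, `exit`,
#'   `status`, plus carried columns; class `sleeple_msdata`.
#' @export
to_multistate <- function(followup, data = NULL, sort = TRUE) {
  f <- followup[!followup$dropped, , drop = FALSE]
  exit1 <- ifelse(f$cvd_status == 1, f$cvd_age, f$exit)
  g <- f$cvd_status == 1  # contributes a transition-3 row
  rows <- data.frame(
    id = c(f$id, f$id, f$id[g]),
    transition = rep(1:3, c(nrow(f), nrow(f), sum(g))),
    entry = c(f$entry, f$entry, f$cvd_age[g]),
    exit = c(exit1, exit1, f$exit[g]),
    status = c(f$cvd_status,
               as.integer(f$cvd_status == 0 & f$death_status == 1),
               f$death_status[g]),
    stringsAsFactors = FALSE)
  bad <- rows$entry >= rows$exit
  if (any(bad))
    stop("multistate invariant violated (entry >= exit) for id(s): ",
         paste(unique(rows$id[bad]), collapse = ", "))
  if (!is.null(data)) {
    carry <- data[match(rows$id, data$id), setdiff(names(data), "id"),
                  drop = FALSE]
    rownames(carry) <- NULL
    rows <- cbind(rows, carry)
  }
  if (sort) {
    rows <- rows[order(rows$id, rows$transition), , drop = FALSE]
    rownames(rows) <- NULL
  }
  class(rows) <- c("sleeple_msdata", "data.frame")
  rows
}

#' Person-years at risk of death
#'
#' Total years between enrollment and effective exit over all persons in
#' a follow-up summary.
#'
#' @param followup output of [build_followup()].
#' @return numeric scalar (years).
#' @export
person_years <- function(followup) {
  f <- followup[!followup$dropped, , drop = FALSE]
  sum(f$exit - f$entry)
}
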