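# cohort_builder: cascade order, follow-up truncation, counting-process
# expansion, person-years

test_that("exclusion stages run in the stated order", {
  p <- make_participants(
    make_participant("A", snoring = NA, prevalent_cvd = TRUE),  # stage 1
    make_participant("B", prevalent_cvd = TRUE),                # stage 2
    make_participant("C", smoking = factor(NA, levels = covariate_levels()$smoking,
                                           ordered = TRUE)),    # stage 3
    make_participant("D", cvd_age = 56 + 1.9),                  # stage 4
    make_participant("E", cvd_age = 56 + 2.1),                  # kept
    make_participant("F"))                                      # kept
  pr <- score_sleep(p)
  ex <- apply_exclusions(p, pr)
  expect_equal(ex$report$stage,
               c("input", "missing_sleep", "prevalent_cvd",
                 "missing_covariates", "landmark_events"))
  expect_equal(ex$report$removed, c(0, 1, 1, 1, 1))
  expect_equal(ex$report$remaining, c(6, 5, 4, 3, 2))
  expect_setequal(ex$kept$id, c("E", "F"))
  # landmark 0 disables stage 4
  ex0 <- apply_exclusions(p, pr, landmark = 0)
  expect_equal(ex0$report$removed[5], 0)
})

test_that("follow-up applies the tau restriction and landmark edges", {
  # death after 81 with censoring after 81: alive at truncation
  a <- make_participant("A", death_age = 83, censor_age = 85)
  fa <- build_followup(a)
  expect_equal(fa$exit, 81)
  expect_equal(fa$death_status, 0L)

  # death at exactly 81 counts as an event
  b <- build_followup(make_participant("B", death_age = 81, censor_age = 85))
  expect_equal(b$death_status, 1L)

  # CVD then death inside follow-up: both transitions observed
  c_ <- build_followup(make_participant("C", enrollment_age = 56,
                                        cvd_age = 60, death_age = 70,
                                        censor_age = 82))
  expect_equal(c_$cvd_status, 1L)
  expect_equal(c_$cvd_age, 60)
  expect_equal(c_$exit, 70)
  expect_equal(c_$death_status, 1L)

  # healthy and censored early
  d <- build_followup(make_participant("D", censor_age = 68.3))
  expect_equal(d$exit, 68.3)
  expect_equal(d$cvd_status + d$death_status, 0L)

  # CVD recorded after the effective exit is discarded
  e <- build_followup(make_participant("E", cvd_age = 70, censor_age = 65))
  expect_equal(e$cvd_status, 0L)

  # same-age CVD and death: CVD nudged one day earlier
  f <- build_followup(make_participant("F", cvd_age = 70, death_age = 70,
                                       censor_age = 80))
  expect_equal(f$cvd_status, 1L)
  expect_equal(f$cvd_age, 70 - 1 / 365.25)
  expect_equal(f$exit, 70)
})

test_that("counting-process expansion covers the four state paths", {
  p <- make_participants(
    make_participant("cens", censor_age = 68.3),
    make_participant("cvd_alive", cvd_age = 60, censor_age = 70),
    make_participant("death_only", death_age = 66, censor_age = 70),
    make_participant("cvd_death", cvd_age = 60, death_age = 66,
                     censor_age = 70))
  fu <- build_followup(p)
  ms <- to_multistate(fu)

  expect_equal(sum(ms$transition == 1), 4)
  expect_equal(sum(ms$transition == 2), 4)
  expect_equal(sum(ms$transition == 3), 2)  # one per CVD case

  r <- function(id, k) ms[ms$id == id & ms$transition == k, ]
  # path (a): two censored rows over the same interval
  expect_equal(r("cens", 1)$status, 0L)
  expect_equal(r("cens", 2)$status, 0L)
  expect_equal(r("cens", 1)$exit, r("cens", 2)$exit)
  # path (d): CVD then death
  expect_equal(r("cvd_death", 1)$status, 1L)
  expect_equal(r("cvd_death", 1)$exit, 60)
  expect_equal(r("cvd_death", 2)$status, 0L)   # censored at CVD age
  expect_equal(r("cvd_death", 2)$exit, 60)
  expect_equal(r("cvd_death", 3)$entry, 60)
  expect_equal(r("cvd_death", 3)$exit, 66)
  expect_equal(r("cvd_death", 3)$status, 1L)
  # path (c): death without CVD, no transition-3 row
  expect_equal(r("death_only", 1)$status, 0L)
  expect_equal(r("death_only", 2)$status, 1L)
  expect_equal(nrow(r("death_only", 3)), 0)

  expect_true(all(ms$entry < ms$exit))
  expect_true(all(ms$exit <= 81))
  # event-count bookkeeping
  expect_equal(sum(ms$status[ms$transition == 1]), sum(fu$cvd_status))
  expect_equal(sum(ms$status[ms$transition %in% 2:3]), sum(fu$death_status))
})

test_that("person-years sums enrollment-to-exit intervals", {
  one <- build_followup(make_participant("A", enrollment_age = 50,
                                         censor_age = 61.8))
  expect_equal(person_years(one), 11.8)

  two <- build_followup(make_participants(
    make_participant("A", enrollment_age = 50, censor_age = 60),
    make_participant("B", enrollment_age = 45, death_age = 57,
                     censor_age = 60)))
  expect_equal(person_years(two), 22)

  # constructed uniform 5-year follow-up
  n <- 100
  p <- do.call(rbind, lapply(seq_len(n), function(i)
    make_participant(sprintf("P%03d", i), enrollment_age = 50 + i / 100,
                     censor_age = 55 + i / 100)))
  expect_equal(person_years(build_followup(p)), 500)
})

test_that("tau invariant holds on a generated cohort", {
  tr <- clean_truth(seed = 17, followup = list(mean = 30, sd = 5, min = 10,
                                               max = 45))
  co <- generate_cohort(tr, 1500)
  pr <- score_sleep(co$participants)
  ex <- apply_exclusions(co$participants, pr)
  fu <- build_followup(ex$kept)
  ms <- to_multistate(fu)
  expect_lte(max(ms$exit), 81)
  expect_equal(sum(ms$transition == 1), sum(ms$transition == 2))
  expect_equal(sum(ms$transition == 3), sum(ms$status[ms$transition == 1]))
})
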