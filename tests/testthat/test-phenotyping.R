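# sleep_phenotyping: composite score, code-list disorder flags, 2x2

test_that("composite score and category follow the thresholds", {
  all5 <- make_participant()
  pr <- score_sleep(all5)
  expect_equal(pr$score, 5L)
  expect_equal(as.character(pr$category), "healthy")

  # 9 h/day fails the half-open 7 <= h < 9 window but keeps category
  p9 <- make_participant(sleep_duration = 9L)
  pr9 <- score_sleep(p9)
  expect_false(pr9$healthy_sleep_duration)
  expect_equal(pr9$score, 4L)
  expect_equal(as.character(pr9$category), "healthy")

  one <- make_participant(chronotype = "definitely_evening",
                          sleep_duration = 5L, insomnia = "usually",
                          snoring = "yes")
  pr1 <- score_sleep(one)
  expect_equal(pr1$score, 1L)
  expect_equal(as.character(pr1$category), "poor")

  # boundary: 2 and 3 are intermediate, 4 is healthy
  two <- make_participant(chronotype = "more_evening", sleep_duration = 6L,
                          insomnia = "sometimes")
  expect_equal(as.character(score_sleep(two)$category), "intermediate")

  miss <- make_participant(snoring = NA)
  prm <- score_sleep(miss)
  expect_false(prm$scorable)
  expect_true(is.na(prm$score))
  expect_true(is.na(prm$category))

  expect_error(score_sleep(make_participant(insomnia = "continuously")),
               "invalid insomnia")
})

test_that("score is permutation-invariant in which traits are healthy", {
  sets <- sleep_response_sets()
  unhealthy <- list(chronotype = "definitely_evening", sleep_duration = 5L,
                    insomnia = "usually", snoring = "yes",
                    sleepiness = "often")
  set.seed(42)
  for (i in 1:20) {
    k <- sample(0:5, 1)
    which_h <- sample(sleep_cols(), k)
    args <- unhealthy
    healthy_defaults <- list(chronotype = "more_morning", sleep_duration = 8L,
                             insomnia = "never_rarely", snoring = "no",
                             sleepiness = "sometimes")
    args[which_h] <- healthy_defaults[which_h]
    pr <- score_sleep(do.call(make_participant, args))
    expect_equal(pr$score, k)
  }
})

test_that("disorder extraction honors the lookback window and mapping", {
  enrol <- as.Date("2008-06-01")
  ev <- function(offset_years, vocabulary, code)
    data.frame(date = enrol + round(offset_years * 365.25),
               vocabulary = vocabulary, code = code,
               stringsAsFactors = FALSE)

  f <- extract_disorders(ev(-1.5, "ICD10", "G47.33"), enrol)
  expect_true(f$srbd); expect_true(f$any); expect_false(f$insomnia)

  f3 <- extract_disorders(ev(-3, "ICD10", "G47.0"), enrol)
  expect_false(f3$any)

  # prescription alone -> other; with a clinical insomnia code -> no extra
  frx <- extract_disorders(ev(-0.5, "BNF", "0401"), enrol)
  expect_true(frx$other); expect_false(frx$insomnia)
  fboth <- extract_disorders(rbind(ev(-0.5, "BNF", "0401"),
                                   ev(-1, "ReadV2", "Fy00x")), enrol)
  expect_true(fboth$insomnia); expect_false(fboth$other)

  # closed window at both ends
  fedge <- extract_disorders(rbind(ev(-2, "ICD10", "G47.0"),
                                   ev(0, "CTV3", "XSDUA")), enrol)
  expect_true(fedge$insomnia); expect_true(fedge$srbd)

  expect_error(extract_disorders(ev(-1, "SNOMED", "1234"), enrol),
               "unknown vocabulary")
  expect_warning(
    f0 <- extract_disorders(ev(-1, "ICD10", "G47.0"), enrol,
                            codelist = codelist(data.frame(
                              disorder = character(), vocabulary = character(),
                              code = character(), match = character()))),
    "empty code list")
  expect_false(f0$any)
})

test_that("adding events is monotone for the flags", {
  enrol <- as.Date("2010-01-01")
  cl <- default_codelist()
  pool <- data.frame(
    date = enrol - sample(0:1100, 40, replace = TRUE),
    vocabulary = sample(c("ICD10", "ReadV2", "CTV3", "BNF"), 40, TRUE),
    code = sample(c("G47.0", "G47.3", "G47.2", "Fy03", "0401", "ZZZ"), 40,
                  TRUE), stringsAsFactors = FALSE)
  set.seed(8)
  for (i in 1:10) {
    base_idx <- sample(40, 10)
    more_idx <- union(base_idx, sample(40, 10))
    f1 <- extract_disorders(pool[base_idx, ], enrol, cl)
    f2 <- extract_disorders(pool[more_idx, ], enrol, cl)
    for (fl in c("insomnia", "srbd", "any"))
      expect_true(!f1[[fl]] || f2[[fl]])
  }
})

test_that("code list validation rejects ambiguous or malformed lists", {
  expect_error(codelist(data.frame(disorder = c("insomnia", "srbd"),
                                   vocabulary = "ICD10", code = "G47.0",
                                   match = "prefix")),
               "two disorders")
  expect_error(codelist(data.frame(disorder = "insomnia",
                                   vocabulary = "ICD11", code = "x",
                                   match = "exact")),
               "unknown vocabulary")
  cl <- default_codelist()
  path <- withr::local_tempfile(fileext = ".json")
  write_codelist(cl, path)
  expect_equal(read_codelist(path)$entries, cl$entries)
})

test_that("confusion matrix arithmetic and degenerate columns", {
  same <- c(a = TRUE, b = FALSE, c = TRUE)
  cm <- confusion_matrix(same, same)
  expect_equal(cm$sensitivity, 1); expect_equal(cm$npv, 1)
  expect_equal(cm$specificity, 1); expect_equal(cm$ppv, 1)

  # TP=10 FP=5 FN=20 TN=65
  self <- rep(c(TRUE, TRUE, FALSE, FALSE), c(10, 5, 20, 65))
  dx <- rep(c(TRUE, FALSE, TRUE, FALSE), c(10, 5, 20, 65))
  cm2 <- confusion_matrix(self, dx)
  expect_equal(cm2$tp, 10); expect_equal(cm2$tn, 65)
  expect_equal(cm2$npv, 65 / 85)
  expect_equal(cm2$sensitivity, 10 / 30)
  expect_equal(cm2$n, 100)

  cm3 <- confusion_matrix(self = c(TRUE, FALSE), dx = c(FALSE, FALSE))
  expect_equal(cm3$npv, 1)               # TN/(TN+FN) = 1/1
  expect_true(is.nan(cm3$sensitivity))   # no dx positives
  cm4 <- confusion_matrix(self = c(FALSE, FALSE), dx = c(FALSE, FALSE))
  expect_true(is.nan(cm4$ppv))
  expect_true(is.nan(cm4$sensitivity))

  expect_error(confusion_matrix(c(a = TRUE), c(b = TRUE)), "id mismatch")
})
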