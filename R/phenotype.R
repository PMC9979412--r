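# Sleep phenotyping: the 0-5 composite score from five questionnaire
# responses, and clinical sleep-disorder flags from coded EHR events via
# vocabulary-aware code-list matching with a pre-enrollment lookback.

#' Healthy-phenotype response mapping for the composite sleep score
#'
#' The five healthy sleep phenotypes: morning chronotype, adequate
#' duration (7 to < 9 h/day; whole-hour responses, so 7 or 8), no usual
#' insomnia complaints, no snoring, no frequent daytime sleepiness. The
#' response-level cutoffs for "usual" insomnia and "frequent" sleepiness
#' are configuration: override any element to change the definition.
#'
#' @return named list; each element is the set of responses counted as
#'   healthy for that characteristic.
#' @export
healthy_sleep_mapping <- function() {
  list(chronotype = c("definitely_morning", "more_morning"),
       sleep_duration = c(7L, 8L),
       insomnia = "never_rarely",
       snoring = "no",
       sleepiness = c("never_rarely", "sometimes"))
}

#' Composite sleep score and category
#'
#' Scores each row of a participant table by counting healthy sleep
#' phenotypes (0-5) and assigns the category: poor (score <= 1),
#' intermediate (2 or 3), healthy (>= 4). Rows with any missing response
#' are returned as unscorable (`scorable = FALSE`, `score` and `category`
#' `NA`) for the exclusion cascade to remove -- responses are never
#' imputed. Responses outside the allowed sets are an error.
#'
#' @param data data.frame with columns `chronotype`, `sleep_duration`,
#'   `insomnia`, `snoring`, `sleepiness` (see [sleep_response_sets()]).
#' @param mapping healthy-response sets, see [healthy_sleep_mapping()].
#' @return data.frame with one row per input row: the five healthy-trait
#'   booleans, `score`, `category` (factor healthy/intermediate/poor) and
#'   `scorable`.
#' @export
#' @examples
#' score_sleep(data.frame(chronotype = "definitely_morning",
#'                        sleep_duration = 9L, insomnia = "never_rarely",
#'                        snoring = "no", sleepiness = "sometimes"))
score_sleep <- function(data, mapping = healthy_sleep_mapping()) {
  cols <- sleep_cols()
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("missing sleep columns: ", paste(miss, collapse = ", "))
  sets <- sleep_response_sets()
  n <- nrow(data)
  traits <- matrix(NA, n, 5, dimnames = list(NULL, paste0("healthy_", cols)))
  for (j in seq_along(cols)) {
    cl <- cols[j]
    v <- data[[cl]]
    bad <- !is.na(v) & !(v %in% sets[[cl]])
    if (any(bad))
      stop("invalid ", cl, " response(s): ",
           paste(unique(v[bad]), collapse = ", "))
    traits[, j] <- v %in% mapping[[cl]]
    traits[is.na(v), j] <- NA
  }
  scorable <- rowSums(is.na(traits)) == 0
  score <- ifelse(scorable, rowSums(traits), NA_integer_)
  category <- cut(score, breaks = c(-1, 1, 3, 5),
                  labels = c("poor", "intermediate", "healthy"))
  category <- factor(as.character(category),
                     levels = c("healthy", "intermediate", "poor"))
  out <- as.data.frame(traits)
  out$score <- as.integer(score)
  out$category <- category
  out$scorable <- scorable
  if (!is.null(data$id)) out <- cbind(id = data$id, out)
  out
}

#' Sleep-disorder code list
#'
#' A code list maps each disorder to `(vocabulary, code, match-mode)`
#' entries. Recognized vocabularies: `ICD9`, `ICD10`, `ReadV2`, `CTV3`
#' (clinical) and `BNF` (prescriptions). Match mode is `prefix` for the
#' hierarchical ICD/Read systems and `exact` for BNF section codes.
#' `default_codelist()` ships a small illustrative list (one or two
#' representative codes per disorder per vocabulary); real deployments
#' plug in their full lists via [read_codelist()]. BNF entries are stored
#' under the pseudo-disorder `prescription`: a hypnotic/anxiolytic
#' prescription without any clinical sleep code in the window is
#' classified as `other`, and contributes nothing when a clinical code
#' co-occurs.
#'
#' @param entries data.frame with columns `disorder` (one of `insomnia`,
#'   `srbd`, `other`, `prescription`), `vocabulary`, `code`, `match`
#'   (`exact` or `prefix`).
#' @return object of class `sleeple_codelist`.
#' @export
codelist <- function(entries) {
  req <- c("disorder", "vocabulary", "code", "match")
  stopifnot(is.data.frame(entries), all(req %in% names(entries)))
  vocabs <- c("ICD9", "ICD10", "ReadV2", "CTV3", "BNF")
  if (any(!entries$vocabulary %in% vocabs))
    stop("unknown vocabulary: ",
         paste(setdiff(entries$vocabulary, vocabs), collapse = ", "))
  if (any(!entries$disorder %in% c("insomnia", "srbd", "other", "prescription")))
    stop("unknown disorder in code list")
  if (any(!entries$match %in% c("exact", "prefix")))
    stop("match must be 'exact' or 'prefix'")
  if (any(entries$code == "")) stop("empty code in code list")
  key <- paste(entries$vocabulary, entries$code)
  dup <- duplicated(key) & !duplicated(paste(key, entries$disorder))
  if (any(dup))
    stop("code assigned to two disorders within one vocabulary: ",
         paste(unique(key[dup]), collapse = ", "))
  structure(list(entries = entries[req]), class = "sleeple_codelist")
}

#' @rdname codelist
#' @export
default_codelist <- function() {
  e <- rbind(
    data.frame(disorder = "insomnia",
               vocabulary = c("ICD10", "ICD10", "ICD9", "ReadV2", "CTV3"),
               code = c("G47.0", "F51.0", "780.52", "Fy00", "XE0Z8"),
               match = "prefix"),
    data.frame(disorder = "srbd",
               vocabulary = c("ICD10", "ICD9", "ReadV2", "CTV3"),
               code = c("G47.3", "327.2", "Fy03", "XSDUA"),
               match = "prefix"),
    data.frame(disorder = "other",
               vocabulary = c("ICD10", "ICD10", "ICD10", "ReadV2", "CTV3"),
               code = c("G47.2", "G47.8", "F51.2", "Fy05", "XM0CT"),
               match = "prefix"),
    data.frame(disorder = "prescription", vocabulary = "BNF",
               code = "0401", match = "exact"))
  codelist(e)
}

#' @export
print.sleeple_codelist <- function(x, ...) {
  cat("<sleeple_codelist>", nrow(x$entries), "entries\n")
  print(table(x$entries$disorder, x$entries$vocabulary))
  invisible(x)
}

#' @rdname codelist
#' @param x a `sleeple_codelist`.
#' @param path JSON file path.
#' @export
write_codelist <- function(x, path) {
  stopifnot(inherits(x, "sleeple_codelist"))
  jsonlite::write_json(x$entries, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname codelist
#' @export
read_codelist <- function(path) {
  codelist(jsonlite::read_json(path, simplifyVector = TRUE))
}

# Match one vector of (vocabulary, code) against a codelist; returns the
# disorder per event or NA. Events with unknown vocabularies are an error.
match_codes <- function(vocabulary, code, cl) {
  vocabs <- c("ICD9", "ICD10", "ReadV2", "CTV3", "BNF")
  if (any(!vocabulary %in% vocabs))
    stop("unknown vocabulary in events: ",
         paste(unique(setdiff(vocabulary, vocabs)), collapse = ", "))
  out <- rep(NA_character_, length(code))
  e <- cl$entries
  for (j in seq_len(nrow(e))) {
    hit <- vocabulary == e$vocabulary[j] &
      (if (e$match[j] == "exact") code == e$code[j]
       else startsWith(code, e$code[j]))
    out[hit & is.na(out)] <- e$disorder[j]
  }
  out
}

#' Clinical sleep-disorder flags from coded events
#'
#' Flags insomnia, sleep-related breathing disorder (SRBD) and other
#' sleep disorders for one person from their coded events. An event
#' counts iff it is dated inside the closed window
#' `[enrollment - lookback, enrollment]`. Clinical codes map per the code
#' list; a BNF hypnotic/anxiolytic prescription in the window with no
#' clinical sleep code in the window maps to `other`; a prescription
#' co-occurring with any clinical sleep code contributes no extra flag.
#'
#' @param events data.frame of this person's coded events with columns
#'   `vocabulary`, `code` and either `date` (Date) or `offset_years`
#'   (years relative to enrollment, negative = before).
#' @param enrollment enrollment date (`Date`), required when events carry
#'   dates.
#' @param codelist a [codelist()]; empty list gives all-false flags with
#'   a warning.
#' @param lookback window length in years (> 0).
#' @return list with logical `insomnia`, `srbd`, `other`, `any` and an
#'   `evidence` data.frame of the in-window matched events.
#' @export
extract_disorders <- function(events, enrollment = NULL,
                              codelist = default_codelist(), lookback = 2) {
  stopifnot(lookback > 0)
  if (nrow(codelist$entries) == 0 || is.null(codelist$entries)) {
    warning("empty code list: all disorder flags false")
    return(list(insomnia = FALSE, srbd = FALSE, other = FALSE, any = FALSE,
                evidence = events[0, , drop = FALSE]))
  }
  if (is.null(events) || nrow(events) == 0)
    return(list(insomnia = FALSE, srbd = FALSE, other = FALSE, any = FALSE,
                evidence = if (is.null(events)) NULL else events[0, , drop = FALSE]))
  off <- events$offset_years
  if (is.null(off)) {
    if (is.null(enrollment)) stop("events carry dates; enrollment date required")
    off <- as.numeric(events$date - as.Date(enrollment)) / 365.25
  }
  inwin <- !is.na(off) & off >= -lookback & off <= 0
  ev <- events[inwin, , drop = FALSE]
  disorder <- if (nrow(ev)) match_codes(ev$vocabulary, ev$code, codelist)
              else character(0)
  clin_ins <- any(disorder == "insomnia", na.rm = TRUE)
  clin_srbd <- any(disorder == "srbd", na.rm = TRUE)
  clin_other <- any(disorder == "other", na.rm = TRUE)
  rx <- any(disorder == "prescription", na.rm = TRUE)
  other <- clin_other || (rx && !(clin_ins || clin_srbd || clin_other))
  flags <- list(insomnia = clin_ins, srbd = clin_srbd, other = other,
                any = clin_ins || clin_srbd || other)
  flags$evidence <- ev[!is.na(disorder), , drop = FALSE]
  flags
}

#' Disorder flags for every participant
#'
#' Vectorized wrapper around [extract_disorders()] over a participant
#' table and a coded-event table keyed by `id`.
#'
#' @param participants participant table with `id` and `enrollment_date`.
#' @param events coded-event table with `id` plus the columns
#'   [extract_disorders()] expects.
#' @inheritParams extract_disorders
#' @return data.frame with `id` and logical `insomnia`, `srbd`, `other`,
#'   `any`, one row per participant.
#' @export
disorder_flags <- function(participants, events,
                           codelist = default_codelist(), lookback = 2) {
  split_ev <- if (!is.null(events) && nrow(events))
    split(events, factor(events$id, levels = participants$id)) else NULL
  out <- lapply(seq_len(nrow(participants)), function(i) {
    ev <- if (is.null(split_ev)) NULL else split_ev[[participants$id[i]]]
    f <- extract_disorders(ev, participants$enrollment_date[i],
                           codelist = codelist, lookback = lookback)
    data.frame(insomnia = f$insomnia, srbd = f$srbd, other = f$other,
               any = f$any)
  })
  cbind(id = participants$id, do.call(rbind, out))
}

#' Two-by-two agreement between self-reported and diagnosed flags
#'
#' Cross-tabulates a self-reported indicator against a clinical-diagnosis
#' indicator on the same persons and reports sensitivity, specificity,
#' positive and negative predictive value (diagnosis as the condition,
#' self-report as the test). Metrics with a zero denominator are `NaN`,
#' never zero.
#'
#' @param self,dx logical vectors on the same id set; if both are named,
#'   they are aligned by name and the id sets must coincide.
#' @return object of class `sleeple_confusion`: counts `tp`, `fp`, `fn`,
#'   `tn`, `n` and metrics `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
#' @examples
#' confusion_matrix(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, FALSE))
confusion_matrix <- function(self, dx) {
  if (!is.null(names(self)) && !is.null(names(dx))) {
    if (!setequal(names(self), names(dx)))
      stop("id mismatch between self-reported and diagnosed flags")
    dx <- dx[names(self)]
  } else if (length(self) != length(dx)) {
    stop("flag vectors differ in length and carry no ids")
  }
  stopifnot(is.logical(self), is.logical(dx), !anyNA(self), !anyNA(dx))
  tp <- sum(self & dx); fp <- sum(self & !dx)
  fn <- sum(!self & dx); tn <- sum(!self & !dx)
  frac <- function(num, den) if (den == 0) NaN else num / den
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n = tp + fp + fn + tn,
                 sensitivity = frac(tp, tp + fn),
                 specificity = frac(tn, tn + fp),
                 ppv = frac(tp, tp + fp), npv = frac(tn, tn + fn)),
            class = "sleeple_confusion")
}

#' @export
print.sleeple_confusion <- function(x, ...) {
  cat("2x2 self-report vs diagnosis (n =", x$n, ")\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("self+", "self-"), c("dx+", "dx-")))
  print(m)
  cat(sprintf("sens %.3f  spec %.3f  ppv %.3f  npv %.3f\n",
              x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}
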