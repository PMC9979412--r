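# End-to-end orchestration: simulate or ingest a cohort, phenotype,
# exclude, expand to counting-process form, estimate sex-stratified
# restricted life expectancies with bootstrap CIs, fit Fine-Gray
# comparability models, and write tables, logs and a run manifest.

trait_cols <- function() paste0("healthy_", sleep_cols())

# Contrast specifications per exposure family. Each spec carries the
# model covariates (exposure + adjustment, mutually adjusted), the
# exposure-part of each prediction profile, and the reference label.
contrast_specs <- function(exposure, adjust) {
  if (exposure == "category") {
    lv <- c("healthy", "intermediate", "poor")
    prof <- lapply(lv, function(l)
      data.frame(category = factor(l, levels = lv)))
    names(prof) <- lv
    return(list(list(name = "category",
                     model_covs = c("category", adjust),
                     profiles = prof, reference = "healthy")))
  }
  if (exposure == "characteristic") {
    tc <- trait_cols()
    ref <- as.data.frame(as.list(setNames(rep(TRUE, 5), tc)))
    prof <- c(list(all_healthy = ref),
              setNames(lapply(tc, function(cl) {
                p <- ref; p[[cl]] <- FALSE; p
              }), paste0("unhealthy_", sub("healthy_", "", tc))))
    return(list(list(name = "characteristic",
                     model_covs = c(tc, adjust),
                     profiles = prof, reference = "all_healthy")))
  }
  if (exposure == "disorder") {
    # diagnosis flags carry a dx_ prefix to avoid clashing with the
    # questionnaire response columns of the same name
    dz <- c("dx_insomnia", "dx_srbd", "dx_other")
    ref <- as.data.frame(as.list(setNames(rep(FALSE, 3), dz)))
    prof <- c(list(no_disorder = ref),
              setNames(lapply(dz, function(cl) {
                p <- ref; p[[cl]] <- TRUE; p
              }), sub("dx_", "", dz)))
    any_prof <- list(without_any = data.frame(dx_any = FALSE),
                     any_disorder = data.frame(dx_any = TRUE))
    return(list(
      list(name = "disorder", model_covs = c(dz, adjust),
           profiles = prof, reference = "no_disorder"),
      list(name = "any_disorder", model_covs = c("dx_any", adjust),
           profiles = any_prof, reference = "without_any")))
  }
  stop("unknown exposure family: ", exposure)
}

# Statistic closure for one spec on one sex stratum: returns the named
# vector of expectancies per profile label plus YLL contrasts vs the
# reference. Resampled persons are re-identified so duplicated rows act
# as distinct persons.
make_le_statistic <- function(spec, adjust, age0, tau, timescale = "age") {
  labels <- names(spec$profiles)
  expo_frame <- do.call(rbind, spec$profiles)  # one row per label
  function(pp) {
    pp$id <- seq_len(nrow(pp))
    fu <- build_followup(pp, tau = tau)
    need <- unique(c("id", spec$model_covs, "enrollment_age"))
    ms <- to_multistate(fu, pp[intersect(need, names(pp))], sort = FALSE)
    covs <- spec$model_covs
    if (timescale == "followup") {
      start <- pp$enrollment_age[match(ms$id, pp$id)]
      ms$entry <- ms$entry - start
      ms$exit <- ms$exit - start
      covs <- unique(c(covs, "enrollment_age"))
    }
    fits <- fit_transitions(ms, covs)
    # one design-matrix build for every profile label at once
    profs <- expo_frame
    if (length(adjust)) {
      adj_prof <- covariate_profile(pp, adjust)
      profs <- cbind(profs, adj_prof[rep(1, length(labels)), , drop = FALSE])
    }
    if (timescale == "followup")
      profs$enrollment_age <- mean(pp$enrollment_age)
    X0 <- profile_row(fits[[1]], profs)
    est <- list()
    out <- numeric(0)
    for (li in seq_along(labels)) {
      ch <- lapply(fits, function(f)
        predict_cumhaz_offset(f, drop(X0[li, , drop = FALSE] %*% f$beta)))
      e <- restricted_expectancies(
        aalen_johansen(ch[[1]], ch[[2]], ch[[3]], age0 = age0, tau = tau),
        age0 = age0, tau = tau)
      est[[labels[li]]] <- e
      out <- c(out, setNames(e, paste0(names(e), "|", labels[li])))
    }
    for (label in setdiff(labels, spec$reference)) {
      yll <- years_of_life_lost(est[[label]], est[[spec$reference]])
      out <- c(out, setNames(yll, paste0(names(yll), "|", label)))
    }
    out
  }
}

#' Sex-stratified life-expectancy contrasts with bootstrap CIs
#'
#' Fits the three-state model separately per sex, predicts restricted
#' expectancies at the median/mean covariate profile for each exposure
#' level, and contrasts each level against its reference (sleep
#' categories vs healthy; single characteristics vs all-healthy;
#' disorders vs without). Percentile CIs come from person-level
#' bootstrap resampling within each sex.
#'
#' @param persons post-exclusion participant rows carrying the exposure
#'   columns (`category` and/or `healthy_*` traits and/or disorder
#'   flags), the covariates, and the event columns.
#' @param exposure one of `"category"`, `"characteristic"`,
#'   `"disorder"`.
#' @param adjust adjustment covariate columns (default: the full
#'   bundle).
#' @param B bootstrap iterations (0 or 1 = point estimates only).
#' @param seed bootstrap seed.
#' @param age0,tau conditioning and restriction ages.
#' @param timescale `"age"` (left-truncated age scale, default) or
#'   `"followup"` (time-on-study with baseline age as covariate).
#' @return data.frame, one row per sex x exposure label, with
#'   expectancies, YLL vs reference, and CI bounds.
#' @export
estimate_contrasts <- function(persons, exposure = "category",
                               adjust = covariate_cols(), B = 0,
                               seed = 1L, age0 = 40, tau = 81,
                               timescale = "age") {
  rows <- list()
  for (sx in levels(persons$sex)) {
    pp <- persons[persons$sex == sx, , drop = FALSE]
    if (nrow(pp) == 0) next
    specs <- contrast_specs(exposure, adjust)
    for (si in seq_along(specs)) {
      spec <- specs[[si]]
      stat <- make_le_statistic(spec, adjust, age0, tau, timescale)
      if (B >= 2) {
        bs <- bootstrap_ci(pp, stat, B = B,
                           seed = seed + 13L * si +
                             101L * match(sx, levels(persons$sex)))
        point <- bs$point; ci <- bs$ci; dropped <- bs$dropped
      } else {
        point <- stat(pp)
        ci <- matrix(NA_real_, 2, length(point),
                     dimnames = list(c("lower", "upper"), names(point)))
        dropped <- NA_integer_
      }
      for (label in names(spec$profiles)) {
        get <- function(metric) {
          nm <- paste0(metric, "|", label)
          if (nm %in% names(point))
            c(point[[nm]], ci["lower", nm], ci["upper", nm])
          else c(NA_real_, NA_real_, NA_real_)
        }
        v <- lapply(c("e_free", "e_with", "e_total",
                      "yll_free", "yll_total"), get)
        names(v) <- c("e_free", "e_with", "e_total",
                      "yll_free", "yll_total")
        rows[[length(rows) + 1]] <- data.frame(
          sex = sx, exposure = spec$name, label = label,
          reference = spec$reference, n = nrow(pp),
          e_free = v$e_free[1], e_free_lower = v$e_free[2],
          e_free_upper = v$e_free[3],
          e_with = v$e_with[1], e_with_lower = v$e_with[2],
          e_with_upper = v$e_with[3],
          e_total = v$e_total[1], e_total_lower = v$e_total[2],
          e_total_upper = v$e_total[3],
          yll_free = v$yll_free[1], yll_free_lower = v$yll_free[2],
          yll_free_upper = v$yll_free[3],
          yll_total = v$yll_total[1], yll_total_lower = v$yll_total[2],
          yll_total_upper = v$yll_total[3],
          B = B, dropped = dropped, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Formatted hazard-ratio table from Fine-Gray fits
#'
#' Two-decimal `HR [lower-upper]` formatting of every coefficient of a
#' set of [fit_finegray()] fits.
#'
#' @param fits named list of `sleeple_fgfit` objects (names typically
#'   sexes).
#' @return data.frame: `stratum`, `term`, `hr`, `lower`, `upper`,
#'   `formatted`.
#' @export
hazard_ratio_table <- function(fits) {
  rows <- lapply(names(fits), function(nm) {
    h <- fits[[nm]]$hr
    data.frame(stratum = nm, term = h$term, hr = h$hr, lower = h$lower,
               upper = h$upper,
               formatted = sprintf("%.2f [%.2f-%.2f]",
                                   h$hr, h$lower, h$upper),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pipeline run configuration
#'
#' @param mode `"simulate"` (generate a synthetic cohort from `truth`)
#'   or `"files"` (read `participants` / `events` CSV paths).
#' @param n cohort size in simulate mode.
#' @param truth a [simulation_truth()] or path to a truth JSON.
#' @param participants,events input CSV paths in files mode.
#' @param seed top-level seed for simulation and bootstrap.
#' @param tau restriction age; `age0` conditioning age; `landmark`
#'   years; `lookback` years for disorder phenotyping.
#' @param B bootstrap iterations (0 = point estimates only).
#' @param exposures subset of `c("category", "characteristic",
#'   "disorder")`.
#' @param adjust adjustment covariates.
#' @param codelist_path optional code-list JSON (default list used
#'   otherwise).
#' @param timescale `"age"` or `"followup"`.
#' @param outdir output directory, or `NULL` to skip writing.
#' @return list of class `sleeple_config`.
#' @export
run_config <- function(mode = c("simulate", "files"), n = 2000,
                       truth = NULL, participants = NULL, events = NULL,
                       seed = 1L, tau = 81, age0 = 40, landmark = 2,
                       lookback = 2, B = 0,
                       exposures = c("category", "disorder"),
                       adjust = covariate_cols(), codelist_path = NULL,
                       timescale = c("age", "followup"), outdir = NULL) {
  mode <- match.arg(mode)
  timescale <- match.arg(timescale)
  stopifnot(age0 < tau, B >= 0)
  if (mode == "files" && (is.null(participants)))
    stop_input("files mode needs a participants path")
  structure(list(mode = mode, n = n, truth = truth,
                 participants = participants, events = events,
                 seed = as.integer(seed), tau = tau, age0 = age0,
                 landmark = landmark, lookback = lookback, B = B,
                 exposures = exposures, adjust = adjust,
                 codelist_path = codelist_path, timescale = timescale,
                 outdir = outdir),
            class = "sleeple_config")
}

stop_input <- function(...) {
  stop(structure(class = c("sleeple_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Run the full analysis pipeline
#'
#' Executes every stage per the module contracts, sex-stratified
#' throughout: cohort acquisition, composite sleep scoring, disorder
#' phenotyping, the four-stage exclusion cascade, follow-up and
#' counting-process construction under the restriction age, restricted
#' life expectancy and years-of-life-lost per exposure with bootstrap
#' CIs, and Fine-Gray subdistribution hazard ratios for poor and
#' intermediate sleep. Writes delimited-text tables plus a JSON manifest
#' when `config$outdir` is set; reruns with the same config and seed are
#' byte-identical.
#'
#' @param config a [run_config()].
#' @return list: `cohort`, `profiles`, `flags`, `exclusions`,
#'   `followup`, `person_years`, `descriptive`, `estimates`,
#'   `confusion` (self-report vs diagnosis agreement), `hazard_ratios`,
#'   `manifest` (invisible tables also written to `outdir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "sleeple_config"))
  cl <- if (!is.null(config$codelist_path)) read_codelist(config$codelist_path)
        else default_codelist()
  if (config$mode == "simulate") {
    truth <- config$truth %||% simulation_truth(seed = config$seed)
    if (is.character(truth)) truth <- read_truth(truth)
    cohort <- generate_cohort(truth, config$n, seed = config$seed)
  } else {
    for (p in c(config$participants, config$events))
      if (!is.null(p) && !file.exists(p)) stop_input("input not found: ", p)
    cohort <- read_cohort(config$participants, config$events)
  }
  participants <- cohort$participants
  events <- cohort$events

  profiles <- score_sleep(participants)
  excl <- apply_exclusions(participants, profiles,
                           landmark = config$landmark, tau = config$tau)
  kept <- excl$kept
  flags <- NULL
  if ("disorder" %in% config$exposures) {
    flags <- disorder_flags(kept, events, codelist = cl,
                            lookback = config$lookback)
    dx <- flags[match(kept$id, flags$id),
                c("insomnia", "srbd", "other", "any")]
    names(dx) <- paste0("dx_", names(dx))
    kept <- cbind(kept, dx)
  }
  fu <- build_followup(kept, tau = config$tau)
  kept <- kept[!fu$dropped, , drop = FALSE]
  fu <- fu[!fu$dropped, , drop = FALSE]
  py <- person_years(fu)

  descriptive <- do.call(rbind, lapply(levels(kept$sex), function(sx) {
    i <- kept$sex == sx
    f <- fu[i, , drop = FALSE]
    do.call(rbind, lapply(levels(kept$category), function(cc) {
      j <- i & kept$category == cc
      data.frame(sex = sx, category = cc, n = sum(j),
                 pct = round(100 * sum(j) / sum(i), 1),
                 incident_cvd = sum(fu$cvd_status[j]),
                 deaths = sum(fu$death_status[j]),
                 person_years = round(sum(fu$exit[j] - fu$entry[j]), 1))
    }))
  }))

  estimates <- do.call(rbind, lapply(config$exposures, function(ex)
    estimate_contrasts(kept, exposure = ex, adjust = config$adjust,
                       B = config$B, seed = config$seed,
                       age0 = config$age0, tau = config$tau,
                       timescale = config$timescale)))

  # self-report vs diagnosis agreement (insomnia complaints vs clinical
  # insomnia; snoring vs sleep-related breathing disorders)
  confusion <- NULL
  if (!is.null(flags)) {
    cm_rows <- lapply(
      list(c(self = "healthy_insomnia", dx = "dx_insomnia"),
           c(self = "healthy_snoring", dx = "dx_srbd")),
      function(pair) {
        cm <- confusion_matrix(!kept[[pair[["self"]]]], kept[[pair[["dx"]]]])
        data.frame(self_report = pair[["self"]], diagnosis = pair[["dx"]],
                   tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
                   sensitivity = cm$sensitivity,
                   specificity = cm$specificity, ppv = cm$ppv,
                   npv = cm$npv)
      })
    confusion <- do.call(rbind, cm_rows)
  }

  cr <- competing_risks_data(fu, kept)
  fg <- list()
  for (sx in levels(kept$sex)) {
    d <- cr[cr$sex == sx, , drop = FALSE]
    if (sum(d$fstatus == "cvd") == 0 || sum(d$fstatus == "death") == 0) next
    fg[[sx]] <- fit_finegray(d, covariates = c("category", "enrollment_age",
                                               config$adjust))
  }
  hr_table <- if (length(fg)) hazard_ratio_table(fg) else NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("sleeple")),
    config = config[setdiff(names(config), c("truth", "outdir"))],
    stage_counts = excl$report,
    n_analyzed = nrow(kept), person_years = py,
    incident_cvd = sum(fu$cvd_status), deaths = sum(fu$death_status))

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, f) if (!is.null(x))
      write.csv(x, file.path(config$outdir, f), row.names = FALSE, na = "NA")
    wr(excl$report, "exclusion_report.csv")
    wr(descriptive, "descriptive.csv")
    wr(estimates, "life_expectancy.csv")
    wr(hr_table, "hazard_ratios.csv")
    wr(confusion, "confusion_matrix.csv")
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(cohort = cohort, profiles = profiles, flags = flags,
                 exclusions = excl, followup = fu, person_years = py,
                 descriptive = descriptive, estimates = estimates,
                 confusion = confusion, finegray = fg,
                 hazard_ratios = hr_table, manifest = manifest))
}

# ---- command line ----------------------------------------------------

cli_args_to_list <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) stop_input("unexpected argument: ", args[i])
    key <- sub("^--", "", args[i])
    if (i + 1 > length(args)) stop_input("missing value for --", key)
    out[[gsub("-", "_", key)]] <- args[i + 1]
    i <- i + 2
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort), `phenotype`
#' (sleep profiles + disorder flags), `build` (exclusions, follow-up,
#' multistate rows), `estimate` (life-expectancy tables), `finegray`
#' (HR table), `run-all` (everything). Flags mirror [run_config()]
#' (`--n`, `--seed`, `--b`, `--out`, `--participants`, `--events`,
#' `--landmark`, `--tau`, `--timescale`, `--codelist`). Returns the exit
#' status: 0 success, 2 input error, 3 convergence failure.
#'
#' @param args character vector, defaults to the process command line.
#' @return integer exit status, invisibly.
#' @export
sleeple_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0) stop_input(
      "usage: sleeple <simulate|phenotype|build|estimate|finegray|run-all> [--flags]")
    cmd <- args[1]
    a <- cli_args_to_list(args[-1])
    num <- function(x, d) if (is.null(x)) d else as.numeric(x)
    out <- a$out %||% "."
    cfg <- run_config(
      mode = if (!is.null(a$participants)) "files" else "simulate",
      n = num(a$n, 2000), participants = a$participants,
      events = a$events, seed = as.integer(num(a$seed, 1)),
      tau = num(a$tau, 81), age0 = num(a$age0, 40),
      landmark = num(a$landmark, 2), lookback = num(a$lookback, 2),
      B = num(a$b, 0), codelist_path = a$codelist,
      exposures = if (!is.null(a$exposures))
        strsplit(a$exposures, ",")[[1]] else c("category", "disorder"),
      adjust = if (is.null(a$adjust)) covariate_cols()
               else if (a$adjust == "none") character(0)
               else strsplit(a$adjust, ",")[[1]],
      timescale = a$timescale %||% "age", outdir = out)
    if (cmd == "simulate") {
      truth <- simulation_truth(seed = cfg$seed)
      cohort <- generate_cohort(truth, cfg$n)
      write_cohort(cohort, out)
      write_truth(truth, file.path(out, "truth.json"))
    } else if (cmd == "phenotype") {
      ch <- load_cli_cohort(cfg)
      prof <- score_sleep(ch$participants)
      fl <- disorder_flags(ch$participants, ch$events,
                           lookback = cfg$lookback)
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write.csv(prof, file.path(out, "sleep_profiles.csv"),
                row.names = FALSE, na = "NA")
      write.csv(fl, file.path(out, "disorder_flags.csv"),
                row.names = FALSE, na = "NA")
    } else if (cmd == "build") {
      ch <- load_cli_cohort(cfg)
      prof <- score_sleep(ch$participants)
      ex <- apply_exclusions(ch$participants, prof,
                             landmark = cfg$landmark, tau = cfg$tau)
      fu <- build_followup(ex$kept, tau = cfg$tau)
      ms <- to_multistate(fu)
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write.csv(ex$report, file.path(out, "exclusion_report.csv"),
                row.names = FALSE, na = "NA")
      write.csv(fu, file.path(out, "followup.csv"),
                row.names = FALSE, na = "NA")
      write.csv(ms, file.path(out, "multistate.csv"),
                row.names = FALSE, na = "NA")
    } else if (cmd %in% c("estimate", "finegray", "run-all")) {
      if (cmd == "estimate") cfg$exposures <- "category"
      run_pipeline(cfg)
    } else {
      stop_input("unknown subcommand: ", cmd)
    }
    0L
  },
  sleeple_input_error = function(e) { message("input error: ",
                                              conditionMessage(e)); 2L },
  error = function(e) { message("error: ", conditionMessage(e)); 3L })
  invisible(status)
}

load_cli_cohort <- function(cfg) {
  if (cfg$mode == "files") read_cohort(cfg$participants, cfg$events)
  else generate_cohort(simulation_truth(seed = cfg$seed), cfg$n)
}
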