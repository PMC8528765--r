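# End-to-end monitoring pipeline on a synthetic cohort: generate -> score ->
# boundary -> classify -> alert -> group statistics, with deterministic
# tidy-CSV reports.

#' Run the full monitoring pipeline on a synthetic cohort
#'
#' Generates an archival reference pool and a study cohort, scores every
#' instrument, computes each patient's dynamic failure boundary (sessions
#' 6-30), runs the OT/NOT state machine with the reliable-change return
#' rule, evaluates the CST alerts at the first feedback session, and runs
#' the OT-vs-NOT group analyses (signal-alert chi-squares, item-level
#' t-tests, and optionally the multilevel logistic model building). All
#' randomness derives from `seed` (archival pool: `seed`; cohort:
#' `seed + 1`), so two runs with the same seed produce byte-identical
#' reports.
#'
#' @param config a [cohort_config()].
#' @param seed integer master seed.
#' @param outdir directory for the CSV reports (`NULL` = don't write).
#' @param k neighbours per boundary update.
#' @param reliability HSCL-11 internal consistency for the reliable-change
#'   criterion (default .87, the session-six estimate).
#' @param do_model_building run the multilevel logistic model building
#'   (the slowest stage; default `TRUE`).
#' @param nAGQ passed to [fit_nested_logistic()].
#' @param catalog an [instrument_catalog()].
#' @return an object of class `rom_pipeline`: list with `pool`, `cohort`,
#'   `scored`, `boundaries`, `classification`, `alerts`, `signal_table`,
#'   `signal_tests`, `item_report`, `model_trace` (or `NULL`), `crit`, and
#'   `files` (paths written).
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1L, outdir = NULL,
                         k = 50L, reliability = 0.87,
                         do_model_building = TRUE, nAGQ = 1,
                         catalog = instrument_catalog()) {
  pool <- generate_archival(config, seed = seed)
  cohort <- generate_cohort(config, seed = seed + 1L)
  scored <- score_cohort(cohort$sessions, catalog)
  crit <- reliable_change_criterion(sd = sd(pool$patients$intake),
                                    reliability = reliability)

  h <- scored$hscl
  last_obs <- tapply(h$session[!is.na(h$hscl)],
                     h$patient_id[!is.na(h$hscl)], max)
  eligible <- as.numeric(names(last_obs))[last_obs >= 6]
  boundaries <- lapply(eligible, function(pid) {
    hist <- h[h$patient_id == pid, c("session", "hscl")]
    names(hist) <- c("session", "hscl")
    dynamic_boundary_sequence(hist, pool, k = k, patient_id = pid)
  })
  classification <- classify_cohort(boundaries, crit)
  alerts <- cohort_alerts(cohort$sessions, scored, classification,
                          at_session = 6L, catalog = catalog)
  signal_table <- session6_signal_table(alerts$crossings)
  signal_tests <- signal_table_tests(signal_table)
  item_report <- build_item_report(cohort$sessions, scored, classification,
                                   catalog)
  model_trace <- NULL
  if (do_model_building) {
    md <- regression_data(scored, classification)
    model_trace <- model_building(md, nAGQ = nAGQ)
  }
  out <- structure(list(pool = pool, cohort = cohort, scored = scored,
                        boundaries = boundaries,
                        classification = classification, alerts = alerts,
                        signal_table = signal_table,
                        signal_tests = signal_tests,
                        item_report = item_report, model_trace = model_trace,
                        crit = crit, seed = seed, files = character(0)),
                   class = "rom_pipeline")
  if (!is.null(outdir)) out$files <- write_reports(out, outdir)
  out
}

#' @export
print.rom_pipeline <- function(x, ...) {
  cat("Routine outcome monitoring pipeline (seed", x$seed, ")\n")
  print(x$classification)
  print(x$alerts)
  if (!is.null(x$model_trace))
    cat("model building retained:",
        paste(x$model_trace$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Per-session regression table for the NOT-prediction models
#'
#' Joins the per-session OT/NOT states with the carried-forward domain
#' predictors ([session_predictors()]): one row per classified session
#' (6-30), outcome `not` = 1 when the state-machine state is NOT.
#'
#' @param scored a [score_cohort()] result.
#' @param classification a [classify_cohort()] result.
#' @return data frame ready for [model_building()].
#' @export
regression_data <- function(scored, classification) {
  st <- classification$states[, c("patient_id", "session", "state")]
  d <- merge(session_predictors(scored), st,
             by = c("patient_id", "session"))
  d$not <- as.integer(d$state == "NOT")
  d <- d[stats::complete.cases(d[, c("not", "risk", "motivation", "alliance",
                                     "life_events", "social_support",
                                     "emotion_regulation")]), ]
  d[order(d$patient_id, d$session), ]
}

build_item_report <- function(sessions, scored, classification, catalog) {
  pats <- classification$patients
  rows <- list()
  for (i in seq_len(nrow(pats))) {
    pid <- pats$patient_id[i]
    b_ses <- battery_session_at(
      unique(sessions$session[sessions$patient_id == pid &
                                sessions$instrument %in% c("ASC", "ASQ")]), 6L)
    if (is.na(b_ses)) next
    bat <- sessions[sessions$patient_id == pid & sessions$session == b_ses &
                      sessions$instrument %in% c("ASC", "ASQ"),
                    c("instrument", "item", "value")]
    # recode reversals scale by scale
    for (s in catalog$scales) {
      if (!length(s$reversed)) next
      idx <- bat$instrument == s$instrument & bat$item %in% s$reversed &
        !is.na(bat$value)
      bat$value[idx] <- sum(s$range) - bat$value[idx]
    }
    rk <- scored$risk[scored$risk$patient_id == pid &
                        scored$risk$session == 6L, ]
    if (nrow(rk)) {
      bat <- rbind(bat,
                   data.frame(instrument = "HSCL11",
                              item = catalog$risk$hscl_suicide_item,
                              value = rk$hscl_suicide[1]),
                   data.frame(instrument = "OQ30", item = catalog$risk$oq_items,
                              value = c(rk$oq5[1], rk$oq18[1])))
    }
    bat$group <- pats$group[i]
    rows[[length(rows) + 1]] <- bat
  }
  item_comparison_report(do.call(rbind, rows), catalog)
}

write_reports <- function(x, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(obj, name) {
    p <- file.path(outdir, name)
    utils::write.csv(obj, p, row.names = FALSE)
    p
  }
  files <- c(
    w(x$scored$hscl, "hscl_scores.csv"),
    w(x$scored$battery, "battery_scores.csv"),
    w(do.call(rbind, lapply(x$boundaries, function(b)
      cbind(patient_id = attr(b, "patient_id"), as.data.frame(b)))),
      "boundaries.csv"),
    w(x$classification$patients, "track_groups.csv"),
    w(x$classification$states, "track_states.csv"),
    w(x$classification$signals, "signals.csv"),
    w(x$alerts$alerts, "alerts.csv"),
    w(x$signal_tests, "session6_signal_tests.csv"),
    w(x$item_report, "item_report.csv"))
  if (!is.null(x$model_trace))
    files <- c(files, w(x$model_trace$trace, "model_trace.csv"))
  files
}
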