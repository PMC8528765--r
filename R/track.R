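# OT/NOT state machine: boundary crossings generate warning signals; getting
# back on track requires falling below the boundary AND reliable improvement
# (Jacobson-Truax reliable change) relative to the impairment level at the
# first crossing.

#' Reliable change criterion
#'
#' Jacobson–Truax standard error of the difference,
#' \eqn{S_{diff} = SD \sqrt{2} \sqrt{1 - r}}, built from the archival intake
#' SD of the instrument and its reliability (HSCL-11: alpha = .87 at
#' session six).
#'
#' @param sd archival intake standard deviation of the instrument.
#' @param reliability internal consistency in (0, 1); 1 would make every
#'   change unreliable-proof and is rejected.
#' @param z reliable-change threshold (default 1.96).
#' @return an object of class `rc_criterion` with `sd`, `reliability`, `z`,
#'   `s_diff`.
#' @export
reliable_change_criterion <- function(sd, reliability = 0.87, z = 1.96) {
  stopifnot(sd > 0, reliability > 0)
  if (reliability >= 1)
    stop("reliability must be < 1 (S_diff would be zero)")
  structure(list(sd = sd, reliability = reliability, z = z,
                 s_diff = sd * sqrt(2) * sqrt(1 - reliability)),
            class = "rc_criterion")
}

#' Reliable change index
#'
#' RCI = (x_ref − x_now) / S_diff. Positive values are improvement (falling
#' impairment); improvement is reliable when RCI ≥ the criterion z (1.96).
#'
#' @param x_ref reference impairment (here: the level when the failure
#'   boundary was first surpassed).
#' @param x_now current impairment.
#' @param crit a [reliable_change_criterion()].
#' @return numeric RCI (vectorised).
#' @export
reliable_change_index <- function(x_ref, x_now, crit) {
  stopifnot(inherits(crit, "rc_criterion"))
  (x_ref - x_now) / crit$s_diff
}

new_track_status <- function(patient_id = NA) {
  structure(list(patient_id = patient_id, state = "OT",
                 first_crossing_session = NA_integer_,
                 impairment_at_first_crossing = NA_real_,
                 signal_log = data.frame(session = integer(),
                                         event = character())),
            class = "track_status")
}

#' Advance the OT/NOT state machine by one session
#'
#' Transition rules: an OT patient goes NOT when the observed HSCL strictly
#' surpasses the failure boundary (ties stay OT); the first crossing session
#' and its impairment level are recorded. A NOT patient returns OT only when
#' the observation falls below the boundary AND the improvement from the
#' first-crossing impairment is reliable (RCI ≥ crit z); otherwise the state
#' persists. Missing observations or boundary values carry the state
#' forward without an event. Events logged: `went_off_track`,
#' `stayed_off_track`, `back_on_track`.
#'
#' @param status a `track_status` (see [classify_cohort()] for cohort use).
#' @param session session number (6–30).
#' @param observed observed HSCL score.
#' @param upper failure boundary at that session.
#' @param crit a [reliable_change_criterion()].
#' @return the updated `track_status`.
#' @export
track_step <- function(status, session, observed, upper, crit) {
  stopifnot(inherits(status, "track_status"))
  if (is.na(observed) || is.na(upper)) return(status)
  log_event <- function(st, ev) {
    st$signal_log <- rbind(st$signal_log,
                           data.frame(session = as.integer(session), event = ev))
    st
  }
  if (status$state == "OT") {
    if (observed > upper) {
      status$state <- "NOT"
      if (is.na(status$first_crossing_session)) {
        status$first_crossing_session <- as.integer(session)
        status$impairment_at_first_crossing <- observed
      }
      status <- log_event(status, "went_off_track")
    }
  } else {
    rci <- reliable_change_index(status$impairment_at_first_crossing,
                                 observed, crit)
    if (observed < upper && rci >= crit$z) {
      status$state <- "OT"
      status <- log_event(status, "back_on_track")
    } else {
      status <- log_event(status, "stayed_off_track")
    }
  }
  status
}

#' Run the state machine over one patient's boundary sequence
#'
#' @param fb a [failure_boundary][dynamic_boundary_sequence()].
#' @param crit a [reliable_change_criterion()].
#' @param patient_id id stored on the result (defaults to the boundary's).
#' @return a `track_status` with an added `$by_session` data frame
#'   (session, observed, upper, state).
#' @export
track_patient <- function(fb, crit, patient_id = attr(fb, "patient_id")) {
  status <- new_track_status(patient_id)
  states <- character(nrow(fb))
  for (j in seq_len(nrow(fb))) {
    status <- track_step(status, fb$session[j], fb$observed[j], fb$upper[j],
                         crit)
    states[j] <- status$state
  }
  status$by_session <- data.frame(session = fb$session,
                                  observed = fb$observed, upper = fb$upper,
                                  state = states)
  status
}

#' @export
print.track_status <- function(x, ...) {
  cat("Patient", x$patient_id, "-", x$state,
      if (!is.na(x$first_crossing_session))
        paste0("(first crossing at session ", x$first_crossing_session, ")")
      else "(never crossed)", "\n")
  if (nrow(x$signal_log)) print(x$signal_log, row.names = FALSE)
  invisible(x)
}

#' Classify a whole cohort as on-track / not-on-track
#'
#' Runs the OT/NOT state machine over every patient's dynamic failure
#' boundary. Patients whose last observed session is before session 6 are
#' excluded. For the group analyses a patient counts as NOT when any session
#' in the 6–30 window has NOT state (ever-NOT); such cases are flagged
#' orange.
#'
#' @param boundaries list of `failure_boundary` objects.
#' @param crit a [reliable_change_criterion()].
#' @return an object of class `track_classification`: list with `patients`
#'   (patient_id, ever_not, group `"OT"`/`"NOT"`, flag_color,
#'   first_crossing_session), `states` (long: patient_id, session, state,
#'   observed, upper), and `signals` (patient_id, session, event).
#' @export
classify_cohort <- function(boundaries, crit) {
  res <- lapply(boundaries, track_patient, crit = crit)
  pat <- do.call(rbind, lapply(res, function(st) {
    data.frame(patient_id = st$patient_id,
               ever_not = any(st$by_session$state == "NOT"),
               first_crossing_session = st$first_crossing_session)
  }))
  pat$group <- ifelse(pat$ever_not, "NOT", "OT")
  pat$flag_color <- ifelse(pat$ever_not, "orange", "green")
  states <- do.call(rbind, lapply(res, function(st)
    cbind(patient_id = st$patient_id, st$by_session)))
  signals <- do.call(rbind, lapply(res, function(st)
    if (nrow(st$signal_log)) cbind(patient_id = st$patient_id, st$signal_log)))
  if (is.null(signals))
    signals <- data.frame(patient_id = integer(), session = integer(),
                          event = character())
  structure(list(patients = pat[, c("patient_id", "ever_not", "group",
                                    "flag_color", "first_crossing_session")],
                 states = states, signals = signals),
            class = "track_classification")
}

#' @export
print.track_classification <- function(x, ...) {
  n <- nrow(x$patients)
  k <- sum(x$patients$ever_not)
  cat("Track classification:", n, "patients,", k,
      sprintf("NOT (%.1f%%),", 100 * k / n), nrow(x$signals), "signals\n")
  invisible(x)
}

#' @describeIn classify_cohort per-session OT/NOT states as a data frame.
#' @param x a `track_classification`.
#' @export
track_states <- function(x) {
  stopifnot(inherits(x, "track_classification"))
  x$states
}
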