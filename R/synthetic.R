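# Synthetic-cohort generator: three-level log-time recovery trajectories
# (sessions in patients in therapists), a deteriorating (NOT) subpopulation,
# and battery item responses produced by discretising latent Gaussians, so
# the item-level cut-off logic is exercised end to end.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions: 413 patients treated by 65
#' therapists, an archival reference pool of 1234 outpatients, a
#' not-on-track latent prevalence of 140/413, group-specific treatment
#' lengths (OT 24.09 (SD 14.25), NOT 32.07 (SD 14.17) sessions, truncated
#' normal, at least 1), and a log-time HSCL-11 trajectory
#' \deqn{y_{ts} = \beta_0 + b_{therapist} + b_{patient} + \beta_1 \ln s +
#'   \beta_2 T + \beta_3 \ln(s) T + \epsilon_{ts}.}
#'
#' Deterioration is an additive bump on the latent HSCL trajectory from a
#' random onset session (uniform over sessions 4–20), default magnitude 0.8
#' HSCL points = 4 residual SDs. Battery items come from graded thresholds
#' on per-patient latent traits; the per-scale locations
#' (`battery_locations`) and the NOT trait shifts (`domain_shift`,
#' functioning scales negative = worse, risk positive = worse) are
#' calibrated once so that session-6 cut-off crossing rates match the
#' published OT/NOT marginals.
#'
#' @param n_therapists,n_patients,archival_n cohort sizes.
#' @param not_prevalence probability a patient is latently not-on-track.
#' @param sessions_ot,sessions_not,sessions_archival mean/sd of the
#'   truncated-normal total-session draw per group.
#' @param session_min,session_cap truncation bounds for total sessions.
#' @param beta fixed effects: intercept, log-session slope (negative =
#'   improvement), total-sessions effect, log-session × total interaction.
#' @param sigma_therapist,sigma_patient,sigma_residual SDs of the therapist
#'   intercept, patient intercept and session residual (HSCL units).
#' @param frac_nonimproving fraction of archival patients generated with a
#'   worsening log-time slope (`nonimproving_slope`), so pool filtering to
#'   improving patients has something to remove.
#' @param nonimproving_slope log-time slope for that fraction (positive =
#'   worsening).
#' @param bump_magnitude additive HSCL deterioration for latent NOT patients.
#' @param bump_onset inclusive range of the uniform onset-session draw.
#' @param item_sd SD of HSCL item-level noise around the latent score.
#' @param battery_locations named latent locations of the battery scales on
#'   the standard-normal item-latent scale.
#' @param domain_shift named latent-trait shifts applied to NOT patients.
#' @param battery_loading loading of the patient trait on each battery item.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(
    n_therapists = 65L, n_patients = 413L, archival_n = 1234L,
    not_prevalence = 140 / 413,
    sessions_ot = c(mean = 24.09, sd = 14.25),
    sessions_not = c(mean = 32.07, sd = 14.17),
    sessions_archival = c(mean = 27, sd = 15),
    session_min = 1L, session_cap = 60L,
    beta = c(intercept = 1.75, log_session = -0.30,
             total_sessions = 0.005, interaction = 0.004),
    sigma_therapist = 0.07, sigma_patient = 0.30, sigma_residual = 0.20,
    frac_nonimproving = 0.20, nonimproving_slope = 0.10,
    bump_magnitude = 0.80, bump_onset = c(4L, 20L),
    item_sd = 0.35,
    battery_locations = c(ASC_TA = 2.033, ASC_MO = 1.918, ASC_SS = 0.128,
                          ASC_LE = 0.830, ASQ_concealing = 0.140,
                          ASQ_tolerating = 0.160, ASQ_adjusting = -0.572,
                          oq_risk = -1.511, hscl_suicide = -0.145),
    domain_shift = c(ASC_TA = -0.452, ASC_MO = -0.111, ASC_SS = -0.459,
                     ASC_LE = -0.603, ASQ_concealing = -0.209,
                     ASQ_tolerating = -0.219, ASQ_adjusting = -0.209,
                     risk = 0.424),
    battery_loading = 0.7) {
  stopifnot(sigma_therapist >= 0, sigma_patient >= 0, sigma_residual >= 0,
            not_prevalence >= 0, not_prevalence <= 1,
            frac_nonimproving >= 0, frac_nonimproving <= 1,
            bump_onset[1] <= bump_onset[2], item_sd >= 0,
            battery_loading > 0, battery_loading < 1)
  cfg <- list(n_therapists = as.integer(n_therapists),
              n_patients = as.integer(n_patients),
              archival_n = as.integer(archival_n),
              not_prevalence = not_prevalence,
              sessions_ot = sessions_ot, sessions_not = sessions_not,
              sessions_archival = sessions_archival,
              session_min = as.integer(session_min),
              session_cap = as.integer(session_cap),
              beta = beta, sigma_therapist = sigma_therapist,
              sigma_patient = sigma_patient, sigma_residual = sigma_residual,
              frac_nonimproving = frac_nonimproving,
              nonimproving_slope = nonimproving_slope,
              bump_magnitude = bump_magnitude,
              bump_onset = as.integer(bump_onset), item_sd = item_sd,
              battery_locations = battery_locations,
              domain_shift = domain_shift,
              battery_loading = battery_loading)
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  patients:", x$n_patients, " therapists:", x$n_therapists,
      " archival pool:", x$archival_n, "\n")
  cat("  NOT prevalence:", round(x$not_prevalence, 3),
      " bump:", x$bump_magnitude, "HSCL from session",
      paste(x$bump_onset, collapse = "-"), "\n")
  cat("  fixed effects:", paste(names(x$beta), round(x$beta, 3),
                                sep = "=", collapse = ", "), "\n")
  cat("  SDs: therapist", x$sigma_therapist, " patient", x$sigma_patient,
      " residual", x$sigma_residual, "\n")
  invisible(x)
}

rtrunc_sessions <- function(n, mean, sd, lo, hi) {
  out <- integer(0)
  while (length(out) < n) {
    draw <- round(rnorm(2 * n, mean, sd))
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  as.integer(out[seq_len(n)])
}

latent_trajectory <- function(cfg, b_t, b_p, total, eff_slope = NULL) {
  s <- seq_len(total)
  slope <- eff_slope %||%
    (cfg$beta[["log_session"]] + cfg$beta[["interaction"]] * total)
  cfg$beta[["intercept"]] + b_t + b_p +
    cfg$beta[["total_sessions"]] * total + slope * log(s)
}

#' Generate the archival reference pool
#'
#' Simulates `archival_n` completed treatments under the configured log-time
#' trajectory law and wraps them as a [reference pool][as_reference_pool]
#' (HSCL score per session, intake severity, total sessions, fitted log-time
#' slope). A configurable fraction of patients is generated with a
#' worsening course so that filtering the pool to improving patients is
#' meaningful. Pool scores are continuous HSCL scale scores (the pool stores
#' scored trajectories, not item responses).
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; the same seed reproduces the pool exactly.
#' @return a `reference_pool` (see [as_reference_pool()]).
#' @export
generate_archival <- function(config = cohort_config(), seed = 1L) {
  set.seed(seed)
  cfg <- config
  n <- cfg$archival_n
  total <- rtrunc_sessions(n, cfg$sessions_archival[["mean"]],
                           cfg$sessions_archival[["sd"]],
                           cfg$session_min, cfg$session_cap)
  ther <- sample.int(cfg$n_therapists, n, replace = TRUE)
  b_t <- rnorm(cfg$n_therapists, 0, cfg$sigma_therapist)[ther]
  b_p <- rnorm(n, 0, cfg$sigma_patient)
  nonimp <- runif(n) < cfg$frac_nonimproving
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    mu <- latent_trajectory(cfg, b_t[i], b_p[i], total[i],
                            eff_slope = if (nonimp[i]) cfg$nonimproving_slope)
    y <- clamp(mu + rnorm(total[i], 0, cfg$sigma_residual), 0, 3)
    rows[[i]] <- data.frame(id = i, therapist_id = ther[i],
                            session = seq_len(total[i]), hscl = y)
  }
  as_reference_pool(do.call(rbind, rows))
}

battery_items <- function(cfg, trait, k, location) {
  # graded 1-5 responses: latent = location + loading*trait + residual
  lam <- cfg$battery_loading
  latent <- location + lam * rep(trait, each = k) +
    sqrt(1 - lam^2) * rnorm(length(trait) * k)
  1L + findInterval(latent, c(-1.5, -0.5, 0.5, 1.5))
}

#' Generate a synthetic study cohort at item level
#'
#' Produces long-format item responses for a cohort: HSCL-11 items every
#' session, and ASC/ASQ/OQ-30 risk items at intake and every fifth session
#' (sessions 1, 5, 10, 15, ...). Latent NOT patients receive an additive
#' HSCL deterioration bump from a random onset session and shifted battery
#' traits (higher risk severity, more life events, less social support,
#' slightly lower motivation) plus longer treatments, per the configured
#' group moments. The latent group labels are generator truth, returned in a
#' sidecar table for evaluation only.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @param discretize if `TRUE` (default) HSCL items are integer 0–3 responses
#'   scattered around the latent score; if `FALSE` every HSCL item equals the
#'   latent score exactly (a continuous validation mode for noise-free
#'   trajectory checks).
#' @return an object of class `synthetic_cohort`: list with `sessions`
#'   (long-format items), `truth` (patient_id, therapist_id, latent_status,
#'   onset_session, total_sessions), `latent` (patient_id, session,
#'   hscl_latent) and the `config` used.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L,
                            discretize = TRUE) {
  set.seed(seed)
  cfg <- config
  n <- cfg$n_patients
  ther <- sample.int(cfg$n_therapists, n, replace = TRUE)
  is_not <- runif(n) < cfg$not_prevalence
  total <- integer(n)
  total[!is_not] <- rtrunc_sessions(sum(!is_not), cfg$sessions_ot[["mean"]],
                                    cfg$sessions_ot[["sd"]],
                                    cfg$session_min, cfg$session_cap)
  total[is_not] <- rtrunc_sessions(sum(is_not), cfg$sessions_not[["mean"]],
                                   cfg$sessions_not[["sd"]],
                                   cfg$session_min, cfg$session_cap)
  onset <- rep(NA_integer_, n)
  onset[is_not] <- sample(seq(cfg$bump_onset[1], cfg$bump_onset[2]),
                          sum(is_not), replace = TRUE)
  b_t <- rnorm(cfg$n_therapists, 0, cfg$sigma_therapist)
  b_p <- rnorm(n, 0, cfg$sigma_patient)

  # latent battery traits (standard normal, NOT patients shifted)
  sh <- cfg$domain_shift
  traits <- list()
  for (nm in c("ASC_TA", "ASC_MO", "ASC_SS", "ASC_LE", "ASQ_concealing",
               "ASQ_tolerating", "ASQ_adjusting"))
    traits[[nm]] <- rnorm(n) + ifelse(is_not, sh[[nm]], 0)
  traits$risk <- rnorm(n) + ifelse(is_not, sh[["risk"]], 0)

  asc_items <- list(ASC_TA = 1:11, ASC_MO = 12:20, ASC_SS = 21:31,
                    ASC_LE = 32:40)
  asq_items <- list(ASQ_concealing = 1:8, ASQ_tolerating = 9:13,
                    ASQ_adjusting = 14:20)
  lam <- cfg$battery_loading
  loc <- cfg$battery_locations

  sess_rows <- vector("list", n)
  latent_rows <- vector("list", n)
  for (i in seq_len(n)) {
    Ti <- total[i]
    s <- seq_len(Ti)
    mu <- latent_trajectory(cfg, b_t[ther[i]], b_p[i], Ti)
    if (is_not[i]) mu <- mu + cfg$bump_magnitude * (s >= onset[i])
    lat <- clamp(mu + rnorm(Ti, 0, cfg$sigma_residual), 0, 3)
    if (discretize) {
      it10 <- clamp(round(rep(lat, each = 10) + rnorm(10 * Ti, 0, cfg$item_sd)),
                    0, 3)
      su_lat <- loc[["hscl_suicide"]] + lam * traits$risk[i] +
        sqrt(1 - lam^2) * rnorm(Ti)
      su <- findInterval(su_lat, c(0.5, 1.5, 2.5))
      hscl <- data.frame(session = rep(s, each = 11), instrument = "HSCL11",
                         item = rep(1:11, Ti),
                         value = as.vector(rbind(matrix(it10, nrow = 10), su)))
    } else {
      hscl <- data.frame(session = rep(s, each = 11), instrument = "HSCL11",
                         item = rep(1:11, Ti),
                         value = rep(lat, each = 11))
    }
    bat_s <- c(1L, seq(5L, 30L, by = 5L))
    bat_s <- bat_s[bat_s <= Ti]
    nb <- length(bat_s)
    bat <- NULL
    if (nb) {
      pieces <- list()
      for (nm in names(asc_items)) {
        k <- length(asc_items[[nm]])
        v <- battery_items(cfg, rep(traits[[nm]][i], nb), k, loc[[nm]])
        pieces[[nm]] <- data.frame(session = rep(bat_s, each = k),
                                   instrument = "ASC",
                                   item = rep(asc_items[[nm]], nb), value = v)
      }
      for (nm in names(asq_items)) {
        k <- length(asq_items[[nm]])
        v <- battery_items(cfg, rep(traits[[nm]][i], nb), k, loc[[nm]])
        pieces[[nm]] <- data.frame(session = rep(bat_s, each = k),
                                   instrument = "ASQ",
                                   item = rep(asq_items[[nm]], nb), value = v)
      }
      # OQ-30: only the two risk items enter the analyses; only they are
      # simulated
      v_oq <- battery_items(cfg, rep(traits$risk[i], nb), 2L, loc[["oq_risk"]])
      pieces$oq <- data.frame(session = rep(bat_s, each = 2),
                              instrument = "OQ30", item = rep(c(5L, 18L), nb),
                              value = v_oq)
      bat <- do.call(rbind, pieces)
    }
    out <- rbind(hscl, bat)
    out$patient_id <- i
    sess_rows[[i]] <- out
    latent_rows[[i]] <- data.frame(patient_id = i, session = s,
                                   hscl_latent = lat)
  }
  sessions <- do.call(rbind, sess_rows)
  sessions$therapist_id <- ther[sessions$patient_id]
  sessions <- sessions[, c("patient_id", "therapist_id", "session",
                           "instrument", "item", "value")]
  rownames(sessions) <- NULL
  truth <- data.frame(patient_id = seq_len(n), therapist_id = ther,
                      latent_status = ifelse(is_not, "NOT_latent", "OT_latent"),
                      onset_session = onset, total_sessions = total)
  structure(list(sessions = sessions, truth = truth,
                 latent = do.call(rbind, latent_rows), config = cfg,
                 seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$truth), "patients (",
      sum(x$truth$latent_status == "NOT_latent"), "latent NOT ),",
      nrow(x$sessions), "item rows, seed", x$seed, "\n")
  invisible(x)
}

#' Simulate per-session NOT indicators with known logistic coefficients
#'
#' Direct generator for parameter-recovery and calibration studies of the
#' multilevel logistic models: patient-level domain predictors are standard
#' normal (constant within patient, like battery scores carried forward),
#' and the per-session binary outcome follows
#' \deqn{logit P(y_{is} = 1) = \beta_0 + \beta_s s + x_i' \beta + b_{patient}
#'   + b_{therapist}.}
#'
#' @param n_patients,n_therapists cohort sizes.
#' @param beta named vector of domain coefficients (names become predictor
#'   columns); unnamed domains can be added via `null_domains`.
#' @param null_domains character vector of extra predictors with zero
#'   coefficient.
#' @param beta0 intercept; `beta_session` the per-session log-odds slope.
#' @param sigma_patient,sigma_therapist random-intercept SDs.
#' @param session_range inclusive range of per-patient final sessions; rows
#'   run from session 6 to the drawn final session.
#' @param seed integer seed.
#' @return data frame with `patient_id`, `therapist_id`, `session`, `not`
#'   and one column per predictor.
#' @export
simulate_session_outcomes <- function(n_patients = 200L, n_therapists = 30L,
                                      beta = c(risk = 1.5),
                                      null_domains = character(),
                                      beta0 = -3, beta_session = 0.09,
                                      sigma_patient = 1.5,
                                      sigma_therapist = 0.3,
                                      session_range = c(8L, 25L), seed = 1L) {
  set.seed(seed)
  total <- sample(seq(session_range[1], session_range[2]), n_patients,
                  replace = TRUE)
  ther <- sample.int(n_therapists, n_patients, replace = TRUE)
  doms <- c(names(beta), null_domains)
  X <- matrix(rnorm(n_patients * length(doms)), n_patients,
              dimnames = list(NULL, doms))
  b_p <- rnorm(n_patients, 0, sigma_patient)
  b_t <- rnorm(n_therapists, 0, sigma_therapist)
  pat <- rep(seq_len(n_patients), total - 5L)
  s <- unlist(lapply(total, function(tt) 6:tt))
  eta <- beta0 + beta_session * s +
    drop(X %*% c(beta, rep(0, length(null_domains))))[pat] +
    b_p[pat] + b_t[ther[pat]]
  d <- data.frame(patient_id = pat, therapist_id = ther[pat], session = s,
                  not = rbinom(length(s), 1, stats::plogis(eta)))
  for (nm in doms) d[[nm]] <- X[pat, nm]
  d
}
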