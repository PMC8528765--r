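# Expected-treatment-response engine: nearest-neighbour selection from an
# archival pool, a two-level log-time growth model on the neighbours, and
# the dynamic failure boundary (upper limit of the 90% interval) over
# sessions 6-30.

BOUNDARY_WINDOW <- c(6L, 30L)

#' Fit a patient's log-time slope
#'
#' Ordinary least squares of the HSCL score on ln(session). Sign convention:
#' impairment is regressed, so improvement (falling HSCL) yields a negative
#' coefficient. "Improving" therefore means slope < 0.
#'
#' @param hscl numeric HSCL scores.
#' @param sessions matching session numbers (default 1..n).
#' @return the OLS slope, or `NA` with fewer than 3 observed sessions.
#' @export
fit_patient_slope <- function(hscl, sessions = seq_along(hscl)) {
  ok <- !is.na(hscl) & !is.na(sessions)
  if (sum(ok) < 3) return(NA_real_)
  x <- log(sessions[ok])
  y <- hscl[ok]
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Build a reference pool from archival score trajectories
#'
#' The pool holds, per archival patient, the session-wise HSCL scores,
#' intake severity, total session count and the fitted log-time slope
#' ([fit_patient_slope()]). Patients with fewer than 3 sessions get an `NA`
#' slope and are never eligible as neighbours.
#'
#' @param scores data frame with columns `id`, `session`, `hscl`.
#' @return an object of class `reference_pool`: list with `patients`
#'   (id, intake, total_sessions, slope, improving), `mat` (patients ×
#'   sessions score matrix, `NA` beyond a patient's last session) and
#'   `scores` (the long table).
#' @export
as_reference_pool <- function(scores) {
  stopifnot(all(c("id", "session", "hscl") %in% names(scores)))
  scores <- scores[order(scores$id, scores$session), ]
  ids <- unique(scores$id)
  max_s <- max(scores$session)
  mat <- matrix(NA_real_, length(ids), max_s,
                dimnames = list(as.character(ids), NULL))
  mat[cbind(match(scores$id, ids), scores$session)] <- scores$hscl
  total <- tapply(scores$session, factor(scores$id, levels = ids), max)
  slope <- vapply(seq_along(ids), function(i) {
    obs <- which(!is.na(mat[i, ]))
    fit_patient_slope(mat[i, obs], obs)
  }, numeric(1))
  patients <- data.frame(id = ids,
                         intake = mat[, 1],
                         total_sessions = as.integer(total),
                         slope = slope,
                         improving = !is.na(slope) & slope < 0)
  rownames(patients) <- NULL
  structure(list(patients = patients, mat = mat, scores = scores),
            class = "reference_pool")
}

#' @export
print.reference_pool <- function(x, ...) {
  cat("Reference pool:", nrow(x$patients), "archival patients,",
      sum(x$patients$improving), "improving;",
      "sessions per patient:", min(x$patients$total_sessions), "-",
      max(x$patients$total_sessions), "\n")
  invisible(x)
}

#' Select nearest neighbours for a patient history
#'
#' Finds the `k` improving archival patients closest to the query patient's
#' observed HSCL course from intake up to the current session. Distance is
#' Euclidean over the jointly observed sessions, scaled by the number of
#' shared sessions (root mean square), so early and late queries are
#' comparable. Archival patients lacking any required session are excluded
#' before ranking; ties are broken by archival id.
#'
#' @param history data frame with columns `session`, `hscl`: the query
#'   patient's observed scores from intake to the current session.
#' @param pool a `reference_pool`.
#' @param k number of neighbours (default 50).
#' @param improving_only restrict to archival patients with improving
#'   (negative) log-time slopes (default `TRUE`).
#' @return integer/character vector of neighbour ids, ranked by distance,
#'   with the distances as attribute `"distances"`. Fewer than `k` eligible
#'   neighbours triggers a warning and returns all eligible; zero eligible
#'   returns an empty vector.
#' @export
select_neighbors <- function(history, pool, k = 50L, improving_only = TRUE) {
  stopifnot(inherits(pool, "reference_pool"))
  history <- history[!is.na(history$hscl), ]
  if (!nrow(history)) stop("empty patient history")
  ses <- history$session
  elig <- if (improving_only) pool$patients$improving else
    !is.na(pool$patients$slope)
  elig <- elig & pool$patients$total_sessions >= max(ses)
  sub <- pool$mat[elig, ses, drop = FALSE]
  elig_idx <- which(elig)
  complete <- rowSums(is.na(sub)) == 0
  sub <- sub[complete, , drop = FALSE]
  elig_idx <- elig_idx[complete]
  if (!length(elig_idx)) return(integer(0))
  if (length(elig_idx) < k)
    warning("only ", length(elig_idx), " eligible neighbours (k = ", k, ")",
            call. = FALSE)
  d <- sqrt(rowMeans((sub - rep(history$hscl, each = nrow(sub)))^2))
  ord <- order(d, pool$patients$id[elig_idx])
  take <- ord[seq_len(min(k, length(ord)))]
  structure(pool$patients$id[elig_idx[take]], distances = unname(d[take]))
}

#' Fit the expected-trajectory model on selected neighbours
#'
#' Two-level linear growth model on the neighbours' full score trajectories:
#' HSCL regressed on ln(session), total sessions T and the ln(session) × T
#' cross-level interaction, with a random intercept per neighbour
#' (sessions nested in patients), fitted by [lme4::lmer()]. When the
#' random-intercept variance is estimated at zero the fit falls back to
#' pooled OLS with a warning; when all neighbours share one T the design is
#' rank-deficient, so T and the interaction are dropped with a warning.
#'
#' @param pool a `reference_pool`.
#' @param ids neighbour ids from [select_neighbors()].
#' @return an object of class `etr_model`: coefficients, fixed-effect
#'   covariance, patient-intercept variance `tau2`, residual variance
#'   `sigma2`, neighbour ids, and whether T terms are present (`has_T`).
#' @export
fit_expected_model <- function(pool, ids) {
  stopifnot(inherits(pool, "reference_pool"))
  d <- pool$scores[pool$scores$id %in% ids, ]
  if (!length(unique(d$id)))
    stop("no neighbours to fit the expected-trajectory model")
  tot <- pool$patients$total_sessions[match(d$id, pool$patients$id)]
  d <- data.frame(id = factor(d$id), lns = log(d$session), hscl = d$hscl,
                  total = as.numeric(tot))
  single <- nlevels(d$id) == 1
  has_T <- length(unique(d$total)) > 1
  if (!has_T)
    warning("all neighbours share one total-session count; dropping T terms",
            call. = FALSE)
  form_fix <- if (has_T) hscl ~ lns * total else hscl ~ lns
  if (single) {
    # degenerate pool: the expected curve is that patient's own fitted curve
    warning("single neighbour: pooled OLS on its trajectory", call. = FALSE)
    ols <- lm(form_fix, data = d)
    return(structure(list(coef = coef(ols), vcov = vcov(ols), tau2 = 0,
                          sigma2 = summary(ols)$sigma^2, fit_type = "ols",
                          has_T = has_T, neighbors = ids),
                     class = "etr_model"))
  }
  form <- stats::update(form_fix, . ~ . + (1 | id))
  fit <- suppressMessages(lme4::lmer(
    form, data = d, REML = TRUE,
    control = lme4::lmerControl(calc.derivs = FALSE,
                                check.conv.singular = "ignore")))
  tau2 <- unname(lme4::VarCorr(fit)$id[1, 1])
  if (tau2 <= 0) {
    warning("random-intercept variance estimated at zero; pooled OLS fit",
            call. = FALSE)
    ols <- lm(form_fix, data = d)
    out <- list(coef = coef(ols), vcov = vcov(ols), tau2 = 0,
                sigma2 = summary(ols)$sigma^2, fit_type = "ols")
  } else {
    out <- list(coef = lme4::fixef(fit), vcov = as.matrix(vcov(fit)),
                tau2 = tau2, sigma2 = stats::sigma(fit)^2, fit_type = "lmm")
  }
  out$has_T <- has_T
  out$neighbors <- ids
  structure(out, class = "etr_model")
}

#' @export
print.etr_model <- function(x, ...) {
  cat("Expected-trajectory model (", x$fit_type, ", ",
      length(x$neighbors), " neighbours)\n", sep = "")
  print(round(x$coef, 4))
  cat("patient-intercept variance:", signif(x$tau2, 4),
      " residual variance:", signif(x$sigma2, 4), "\n")
  invisible(x)
}

etr_design <- function(model, session, total_sessions) {
  lns <- log(session)
  if (model$has_T)
    cbind(1, lns, total_sessions, lns * total_sessions)
  else
    cbind(1, lns)
}

#' @describeIn fit_expected_model predicted expected HSCL at (session, T).
#' @param object an `etr_model`.
#' @param session,total_sessions prediction points.
#' @param ... unused.
#' @export
predict.etr_model <- function(object, session, total_sessions = NA, ...) {
  drop(etr_design(object, session, total_sessions) %*% object$coef)
}

#' Expected value and failure boundary at a session
#'
#' The failure boundary is the upper limit of the 90% interval around the
#' expected recovery curve: expected + z(0.95) × SE, where the SE is a
#' new-patient prediction standard error (fixed-effect uncertainty plus
#' patient-intercept and residual variance), not a mean-only confidence
#' band. Defined for sessions 6–30 only.
#'
#' @param model an `etr_model`.
#' @param session session number(s) in 6..30.
#' @param total_sessions the query patient's (planned) total session count.
#' @param level interval level (default 0.90; the boundary is its one-sided
#'   upper limit, z = 1.645).
#' @return data frame with `session`, `expected`, `upper`.
#' @export
boundary <- function(model, session, total_sessions, level = 0.90) {
  stopifnot(inherits(model, "etr_model"))
  if (any(session < BOUNDARY_WINDOW[1] | session > BOUNDARY_WINDOW[2]))
    stop("failure boundary is defined for sessions ", BOUNDARY_WINDOW[1],
         "-", BOUNDARY_WINDOW[2], " only")
  z <- qnorm(1 - (1 - level) / 2)
  X <- etr_design(model, session, total_sessions)
  expected <- drop(X %*% model$coef)
  se <- sqrt(rowSums((X %*% model$vcov) * X) + model$tau2 + model$sigma2)
  data.frame(session = session, expected = expected, upper = expected + z * se)
}

#' Dynamic failure boundary over sessions 6-30
#'
#' For each session s from 6 up to the patient's last observed session (at
#' most 30), reselects nearest neighbours on the history from intake through
#' s, refits the expected-trajectory model, and records the expected value
#' and failure boundary at s - the session-by-session updated boundary the
#' monitoring system displays.
#'
#' @param history data frame with columns `session`, `hscl`: the patient's
#'   full observed trajectory (intake onwards).
#' @param pool a `reference_pool`.
#' @param k neighbours per update (default 50).
#' @param T_query total-session count used for prediction; `NULL` (default)
#'   uses the patient's last observed session (their planned total when the
#'   trajectory is complete); `"pool_median"` uses the median total of the
#'   improving pool patients.
#' @param level interval level (default 0.90).
#' @param patient_id optional id stored on the result.
#' @return an object of class `failure_boundary`: data frame with columns
#'   `session`, `observed`, `expected`, `upper` for sessions 6 up to
#'   min(30, last session); rows where no eligible neighbours exist are
#'   `NA`. Attributes: `patient_id`, `T_query`, `notes` (unique warnings
#'   collected from the per-session fits).
#' @export
dynamic_boundary_sequence <- function(history, pool, k = 50L, T_query = NULL,
                                      level = 0.90, patient_id = NA) {
  stopifnot(inherits(pool, "reference_pool"))
  history <- history[order(history$session), ]
  last <- max(history$session[!is.na(history$hscl)])
  if (last < BOUNDARY_WINDOW[1])
    stop("patient has fewer than ", BOUNDARY_WINDOW[1], " observed sessions")
  if (is.null(T_query)) T_query <- last
  if (identical(T_query, "pool_median"))
    T_query <- median(pool$patients$total_sessions[pool$patients$improving])
  sessions <- seq(BOUNDARY_WINDOW[1], min(BOUNDARY_WINDOW[2], last))
  out <- data.frame(session = sessions, observed = NA_real_,
                    expected = NA_real_, upper = NA_real_)
  notes <- character(0)
  # the fitted model depends only on the neighbour set; reuse the fit when
  # the reselected set is unchanged from the previous session
  prev_key <- NULL
  m <- NULL
  for (j in seq_along(sessions)) {
    s <- sessions[j]
    hist_s <- history[history$session <= s & !is.na(history$hscl), ]
    obs <- history$hscl[match(s, history$session)]
    out$observed[j] <- if (length(obs)) obs else NA_real_
    ids <- withCallingHandlers(
      select_neighbors(hist_s, pool, k = k),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    if (!length(ids)) {
      notes <- c(notes, sprintf("session %d: no eligible neighbours", s))
      next
    }
    key <- paste(sort(ids), collapse = ",")
    fitb <- withCallingHandlers({
      if (!identical(key, prev_key)) {
        m <- fit_expected_model(pool, ids)
        prev_key <- key
      }
      boundary(m, s, T_query, level = level)
    }, warning = function(w) {
      notes <<- c(notes, conditionMessage(w)); invokeRestart("muffleWarning")
    })
    out$expected[j] <- fitb$expected
    out$upper[j] <- fitb$upper
  }
  structure(out, class = c("failure_boundary", "data.frame"),
            patient_id = patient_id, T_query = T_query,
            notes = unique(notes))
}

#' @export
print.failure_boundary <- function(x, ...) {
  cat("Failure boundary, patient", attr(x, "patient_id"),
      "(T =", attr(x, "T_query"), ")\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.failure_boundary <- function(x, ...) {
  rng <- range(c(x$observed, x$expected, x$upper), na.rm = TRUE)
  plot(x$session, x$observed, type = "b", pch = 16, ylim = rng,
       xlab = "session", ylab = "HSCL-11", ...)
  graphics::lines(x$session, x$expected, lty = 2)
  graphics::lines(x$session, x$upper, lty = 1, col = 2)
  graphics::legend("topright", bty = "n", lty = c(NA, 2, 1), pch = c(16, NA, NA),
                   col = c(1, 1, 2),
                   legend = c("observed", "expected", "failure boundary"))
  invisible(x)
}
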