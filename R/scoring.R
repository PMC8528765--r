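# Vectorised cohort scoring: applies reversal, imputation and cut-off rules
# from instruments.R to long-format item data for a whole cohort.

locf <- function(v) {
  idx <- which(!is.na(v))
  if (!length(idx)) return(v)
  pos <- findInterval(seq_along(v), idx)
  out <- rep(NA_real_, length(v))
  out[pos > 0] <- v[idx[pos[pos > 0]]]
  out
}

#' Score a whole cohort from long-format item data
#'
#' Applies reversal recoding, the >80% missing-data rule and the instrument
#' aggregation rules to every patient-session, and assembles the three
#' tables the monitoring pipeline consumes: session-wise HSCL-11 scores,
#' battery-session scale scores, and the per-session risk assessment (HSCL
#' suicide item refreshed every session, OQ risk items carried forward from
#' the most recent battery).
#'
#' @param sessions long-format data frame (see [read_session_csv()]).
#' @param catalog an [instrument_catalog()].
#' @return list of class `scored_cohort` with elements `hscl` (patient_id,
#'   therapist_id, session, hscl), `battery` (one row per patient × battery
#'   session, one column per ASC/ASQ scale score, `NA` where invalid), and
#'   `risk` (per session: severity, flag, immediate).
#' @export
score_cohort <- function(sessions, catalog = instrument_catalog()) {
  x <- sessions
  x$value <- as.numeric(x$value)
  # reversal recoding (item ids are unique within an instrument)
  for (s in catalog$scales) {
    if (length(s$reversed)) {
      idx <- x$instrument == s$instrument & x$item %in% s$reversed & !is.na(x$value)
      x$value[idx] <- sum(s$range) - x$value[idx]
    }
  }

  pat_ther <- unique(x[, c("patient_id", "therapist_id")])
  if (anyDuplicated(pat_ther$patient_id))
    stop("a patient is assigned to more than one therapist")

  score_groups <- function(sub, scale) {
    if (!nrow(sub)) return(NULL)
    key <- paste(sub$patient_id, sub$session, sep = "\t")
    n_obs <- tapply(!is.na(sub$value), key, sum)
    m_obs <- tapply(sub$value, key, function(v) mean(v, na.rm = TRUE))
    k <- length(scale$items)
    valid <- n_obs / k > 0.80
    value <- ifelse(valid,
                    if (scale$aggregation == "sum") m_obs * k else m_obs,
                    NA_real_)
    ids <- do.call(rbind, strsplit(names(n_obs), "\t", fixed = TRUE))
    data.frame(patient_id = utils::type.convert(ids[, 1], as.is = TRUE),
               session = as.integer(ids[, 2]),
               value = as.numeric(value))
  }

  # session-wise HSCL
  hscl_scale <- catalog$scales$HSCL_total
  h <- score_groups(x[x$instrument == "HSCL11" &
                        x$item %in% hscl_scale$items, ], hscl_scale)
  names(h)[names(h) == "value"] <- "hscl"
  h <- merge(pat_ther, h, by = "patient_id")
  h <- h[order(h$patient_id, h$session), c("patient_id", "therapist_id",
                                           "session", "hscl")]
  rownames(h) <- NULL

  # battery scale scores (ASC + ASQ), wide
  battery_scales <- c("ASC_TA", "ASC_MO", "ASC_SS", "ASC_LE",
                      "ASQ_concealing", "ASQ_tolerating", "ASQ_adjusting")
  battery <- NULL
  for (nm in battery_scales) {
    sc <- catalog$scales[[nm]]
    g <- score_groups(x[x$instrument == sc$instrument & x$item %in% sc$items, ], sc)
    if (is.null(g)) next
    names(g)[names(g) == "value"] <- nm
    battery <- if (is.null(battery)) g else
      merge(battery, g, by = c("patient_id", "session"), all = TRUE)
  }
  if (!is.null(battery)) {
    battery <- battery[order(battery$patient_id, battery$session), ]
    rownames(battery) <- NULL
  }

  # per-session risk: HSCL suicide item each session, OQ items carried forward
  rk <- catalog$risk
  su <- x[x$instrument == "HSCL11" & x$item == rk$hscl_suicide_item,
          c("patient_id", "session", "value")]
  names(su)[3] <- "hscl_suicide"
  oq <- x[x$instrument == "OQ30" & x$item %in% rk$oq_items, ]
  risk <- h[, c("patient_id", "session")]
  risk <- merge(risk, su, by = c("patient_id", "session"), all.x = TRUE)
  for (it in rk$oq_items) {
    oi <- oq[oq$item == it, c("patient_id", "session", "value")]
    names(oi)[3] <- paste0("oq", it)
    risk <- merge(risk, oi, by = c("patient_id", "session"), all.x = TRUE)
  }
  risk <- risk[order(risk$patient_id, risk$session), ]
  for (it in rk$oq_items) {
    col <- paste0("oq", it)
    risk[[col]] <- ave(risk[[col]], risk$patient_id, FUN = locf)
  }
  hit_h <- !is.na(risk$hscl_suicide) & risk$hscl_suicide >= rk$hscl_cutoff
  hit_o <- vapply(rk$oq_items, function(it) {
    v <- risk[[paste0("oq", it)]]
    !is.na(v) & v >= rk$oq_cutoff
  }, logical(nrow(risk)))
  if (nrow(risk) == 1) hit_o <- matrix(hit_o, nrow = 1)
  all_na <- is.na(risk$hscl_suicide) &
    Reduce(`&`, lapply(rk$oq_items, function(it) is.na(risk[[paste0("oq", it)]])))
  risk$severity <- as.integer(hit_h + rowSums(hit_o))
  risk$flag <- hit_h | rowSums(hit_o) > 0
  risk$immediate <- hit_h
  risk$severity[all_na] <- NA_integer_
  risk$flag[all_na] <- NA
  risk$immediate[all_na] <- NA
  rownames(risk) <- NULL

  structure(list(hscl = h, battery = battery, risk = risk,
                 catalog_version = catalog$version),
            class = "scored_cohort")
}

#' @export
print.scored_cohort <- function(x, ...) {
  cat("Scored cohort:", length(unique(x$hscl$patient_id)), "patients,",
      nrow(x$hscl), "sessions,", nrow(x$battery %||% data.frame()),
      "battery administrations\n")
  invisible(x)
}

#' Per-session predictor table for the group analyses
#'
#' Joins the battery scale scores (carried forward between battery sessions)
#' and the per-session risk severity onto every HSCL session row, producing
#' the six CST domain predictors used by the multilevel logistic models:
#' `risk` (severity count 0–3), `motivation` (ASC_MO), `alliance` (ASC_TA),
#' `life_events` (ASC_LE), `social_support` (ASC_SS) and
#' `emotion_regulation` (mean of the three ASQ subscale means).
#'
#' @param scored a `scored_cohort`.
#' @return data frame with one row per patient-session and the six domain
#'   predictor columns (uncentered; see [grand_mean_center()]).
#' @export
session_predictors <- function(scored) {
  stopifnot(inherits(scored, "scored_cohort"))
  d <- merge(scored$hscl, scored$battery, by = c("patient_id", "session"),
             all.x = TRUE)
  d <- d[order(d$patient_id, d$session), ]
  for (col in setdiff(names(scored$battery), c("patient_id", "session")))
    d[[col]] <- ave(d[[col]], d$patient_id, FUN = locf)
  d <- merge(d, scored$risk[, c("patient_id", "session", "severity")],
             by = c("patient_id", "session"))
  d <- d[order(d$patient_id, d$session), ]
  asq <- cbind(d$ASQ_concealing, d$ASQ_tolerating, d$ASQ_adjusting)
  data.frame(
    patient_id = d$patient_id, therapist_id = d$therapist_id,
    session = d$session,
    risk = as.numeric(d$severity),
    motivation = d$ASC_MO, alliance = d$ASC_TA,
    life_events = d$ASC_LE, social_support = d$ASC_SS,
    emotion_regulation = rowMeans(asq)
  )
}
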