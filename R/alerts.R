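# Clinical-support-tool decision flow: domain flags are orange only for NOT
# patients who also cross the domain cut-off; the suicide red bar is
# status-independent.

CST_DOMAINS <- c("risk_suicidality", "motivation", "therapeutic_alliance",
                 "life_events", "social_support", "emotion_regulation")

DOMAIN_SCALES <- list(
  motivation = "ASC_MO", therapeutic_alliance = "ASC_TA",
  life_events = "ASC_LE", social_support = "ASC_SS",
  emotion_regulation = c("ASQ_concealing", "ASQ_tolerating", "ASQ_adjusting"))

na_or <- function(...) {
  v <- c(...)
  if (any(v %in% TRUE)) TRUE else if (all(is.na(v))) NA else FALSE
}

#' Map battery scores to CST domain cut-off inputs
#'
#' One battery session's scale scores become the six domain inputs:
#' risk/suicidality from the [risk_assessment()] flag, motivation from
#' ASC_MO, therapeutic alliance from ASC_TA, life events from ASC_LE,
#' social support from ASC_SS, and emotion regulation from the three ASQ
#' subscales (the domain is crossed when any constituent subscale crosses
#' its cut-off). Invalid scores propagate as `NA`.
#'
#' @param scores named numeric vector of battery scale scores (`NA` =
#'   invalid/missing), names as in the catalog.
#' @param risk_flag logical [risk_assessment()] flag.
#' @param catalog an [instrument_catalog()].
#' @return named logical vector over the six CST domains.
#' @export
map_domains <- function(scores, risk_flag, catalog = instrument_catalog()) {
  crossed <- function(scale_name) {
    sc <- catalog$scales[[scale_name]]
    v <- scores[[scale_name]] %||% NA_real_
    if (is.na(v)) return(NA)
    if (sc$cutoff_direction == "at_or_below") v <= sc$domain_cutoff
    else v >= sc$domain_cutoff
  }
  out <- c(risk_suicidality = if (is.null(risk_flag)) NA else as.logical(risk_flag),
           motivation = crossed("ASC_MO"),
           therapeutic_alliance = crossed("ASC_TA"),
           life_events = crossed("ASC_LE"),
           social_support = crossed("ASC_SS"),
           emotion_regulation = na_or(crossed("ASQ_concealing"),
                                      crossed("ASQ_tolerating"),
                                      crossed("ASQ_adjusting")))
  out[CST_DOMAINS]
}

#' Evaluate the CST decision flow for one patient at a battery session
#'
#' For on-track patients every domain stays green and no CST is accessible,
#' regardless of cut-offs. For not-on-track patients a domain is flagged
#' orange exactly when its cut-off input is crossed, and the domain's
#' critical items are attached. The immediate suicide signal (HSCL suicide
#' item at/above its cut-off) is emitted independently of track status as a
#' separate `suicide_alert` attribute, not as a domain flag.
#'
#' @param state `"OT"` or `"NOT"` at the classified session.
#' @param domain_inputs named logical vector from [map_domains()].
#' @param critical_items named list (by domain) of flagged item labels from
#'   [item_flags()].
#' @param immediate logical: the status-independent suicide red-bar signal.
#' @return data frame of class `domain_alerts` with columns `domain`,
#'   `crossed`, `flag` (orange/green), `cst_accessible`, `critical_items`
#'   (comma-separated labels); attribute `suicide_alert`.
#' @export
evaluate_alerts <- function(state, domain_inputs, critical_items = list(),
                            immediate = FALSE) {
  stopifnot(state %in% c("OT", "NOT"))
  inputs <- domain_inputs[CST_DOMAINS]
  orange <- setNames(state == "NOT" & inputs %in% TRUE, CST_DOMAINS)
  items <- vapply(CST_DOMAINS, function(d) {
    if (!orange[[d]]) return("")
    paste(critical_items[[d]] %||% character(0), collapse = ",")
  }, character(1))
  structure(data.frame(domain = CST_DOMAINS, crossed = unname(inputs),
                       flag = ifelse(orange, "orange", "green"),
                       cst_accessible = unname(orange),
                       critical_items = unname(items)),
            class = c("domain_alerts", "data.frame"),
            suicide_alert = isTRUE(immediate))
}

battery_session_at <- function(sessions_present, at_session) {
  bat <- sessions_present[sessions_present <= at_session]
  if (!length(bat)) NA_integer_ else max(bat)
}

#' Cohort-level CST alerts at a classified session
#'
#' Pairs each patient's track state at `at_session` (default 6, the first
#' feedback session) with the nearest battery administered at or before it
#' (session 5 under the 1, 5, 10, ... battery pattern), evaluates the
#' decision flow, and collects per-domain critical items.
#'
#' @param cohort_sessions long-format item data.
#' @param scored the matching [score_cohort()] result.
#' @param classification a [classify_cohort()] result.
#' @param at_session session at which track status is read (default 6).
#' @param catalog an [instrument_catalog()].
#' @return list of class `cohort_alerts`: `alerts` (per patient × domain),
#'   `crossings` (patient_id, group, domain, crossed - the signal-alert
#'   table input), `suicide_alerts` (patient ids with the immediate signal).
#' @export
cohort_alerts <- function(cohort_sessions, scored, classification,
                          at_session = 6L, catalog = instrument_catalog()) {
  pats <- classification$patients
  states <- classification$states
  bat <- scored$battery
  risk <- scored$risk
  alerts <- vector("list", nrow(pats))
  for (i in seq_len(nrow(pats))) {
    pid <- pats$patient_id[i]
    st_row <- states[states$patient_id == pid & states$session == at_session, ]
    if (!nrow(st_row)) next
    b_ses <- battery_session_at(bat$session[bat$patient_id == pid], at_session)
    if (is.na(b_ses)) next
    scores <- bat[bat$patient_id == pid & bat$session == b_ses, ]
    rk <- risk[risk$patient_id == pid & risk$session == at_session, ]
    inputs <- map_domains(as.list(scores), isTRUE(rk$flag[1]), catalog)
    # critical items from the battery session's (recoded) responses
    resp <- cohort_sessions[cohort_sessions$patient_id == pid &
                              cohort_sessions$session == b_ses, ]
    crit_items <- list()
    for (d in names(DOMAIN_SCALES)) {
      lab <- character(0)
      for (sn in DOMAIN_SCALES[[d]]) {
        sc <- catalog$scales[[sn]]
        rr <- resp[resp$instrument == sc$instrument & resp$item %in% sc$items,
                   c("item", "value")]
        if (!nrow(rr)) next
        rr <- recode_reversed(rr, sc)
        fl <- item_flags(rr, sc)
        if (length(fl)) lab <- c(lab, paste0(sc$instrument, ":", fl))
      }
      crit_items[[d]] <- lab
    }
    # risk critical items: suicide item (session) + OQ risk items (carried)
    rk_items <- character(0)
    if (nrow(rk)) {
      if (isTRUE(rk$hscl_suicide[1] >= catalog$risk$hscl_cutoff))
        rk_items <- c(rk_items, paste0("HSCL11:", catalog$risk$hscl_suicide_item))
      for (it in catalog$risk$oq_items)
        if (isTRUE(rk[[paste0("oq", it)]][1] >= catalog$risk$oq_cutoff))
          rk_items <- c(rk_items, paste0("OQ30:", it))
    }
    crit_items$risk_suicidality <- rk_items
    al <- evaluate_alerts(st_row$state[1], inputs, crit_items,
                          immediate = isTRUE(rk$immediate[1]))
    al <- cbind(patient_id = pid, group = pats$group[i], al)
    attr(al, "suicide_alert") <- isTRUE(rk$immediate[1])
    alerts[[i]] <- al
  }
  alerts <- alerts[!vapply(alerts, is.null, logical(1))]
  suicide <- vapply(alerts, attr, logical(1), which = "suicide_alert")
  tab <- do.call(rbind, lapply(alerts, as.data.frame))
  structure(list(alerts = tab,
                 crossings = tab[, c("patient_id", "group", "domain",
                                     "crossed")],
                 suicide_alerts = vapply(alerts[suicide], function(a)
                   a$patient_id[1], numeric(1))),
            class = "cohort_alerts")
}

#' @export
print.cohort_alerts <- function(x, ...) {
  cat("Cohort alerts:", length(unique(x$alerts$patient_id)), "patients,",
      sum(x$alerts$flag == "orange"), "orange domain flags,",
      length(x$suicide_alerts), "immediate suicide alerts\n")
  invisible(x)
}

#' Session-six signal-alert table
#'
#' Counts, per CST domain and for "at least one domain", how many OT and
#' NOT patients crossed the domain cut-off at the first feedback session -
#' the 2 by 2 tables behind the group comparison chi-square tests.
#'
#' @param crossings the `crossings` element of [cohort_alerts()].
#' @return data frame with one row per domain plus `any_domain`: columns
#'   `domain`, `ot_crossed`, `ot_n`, `not_crossed`, `not_n`.
#' @export
session6_signal_table <- function(crossings) {
  count_group <- function(sub, grp) {
    g <- sub[sub$group == grp & !is.na(sub$crossed), ]
    c(crossed = sum(g$crossed), n = nrow(g))
  }
  rows <- lapply(CST_DOMAINS, function(d) {
    sub <- crossings[crossings$domain == d, ]
    ot <- count_group(sub, "OT"); nt <- count_group(sub, "NOT")
    data.frame(domain = d, ot_crossed = ot["crossed"], ot_n = ot["n"],
               not_crossed = nt["crossed"], not_n = nt["n"])
  })
  # at least one domain per patient
  per_pat <- aggregate(crossed ~ patient_id + group, data = crossings,
                       FUN = function(v) any(v %in% TRUE))
  ot <- per_pat[per_pat$group == "OT", ]; nt <- per_pat[per_pat$group == "NOT", ]
  rows$any <- data.frame(domain = "any_domain",
                         ot_crossed = sum(ot$crossed), ot_n = nrow(ot),
                         not_crossed = sum(nt$crossed), not_n = nrow(nt))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
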