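# Group analyses: multilevel logistic model building for the per-session
# NOT indicator, Pearson chi-square comparisons of cut-off crossings, and
# item-level pooled t-tests with effect sizes. No multiple-testing
# correction anywhere, matching the reporting conventions of routine
# outcome monitoring studies of this design.

#' Grand-mean centering
#'
#' @param x numeric vector.
#' @return `x` minus its overall (non-missing) mean.
#' @export
grand_mean_center <- function(x) {
  stopifnot(is.numeric(x), length(x) > 0)
  x - mean(x, na.rm = TRUE)
}

#' Pearson chi-square test for a 2 x 2 table
#'
#' Plain Pearson statistic, `sum((O-E)^2/E)` with margin-based expected
#' counts, WITHOUT Yates continuity correction (the correction is
#' deliberately not applied and not configurable; the printed group
#' comparisons reproduce only without it).
#'
#' @param tab 2 x 2 matrix of non-negative integer counts (rows = groups,
#'   columns = crossed / not crossed).
#' @return object of class `contingency_result`: list with `observed`,
#'   `statistic`, `df` (= 1), `p_value`.
#' @export
pearson_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-square undefined: zero row or column margin")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(observed = tab, statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X2 = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Chi-square tests for a signal-alert table
#'
#' @param sig a [session6_signal_table()].
#' @return data frame with per-domain counts, percentages, chi-square,
#'   df and p.
#' @export
signal_table_tests <- function(sig) {
  res <- lapply(seq_len(nrow(sig)), function(i) {
    r <- sig[i, ]
    tab <- matrix(c(r$ot_crossed, r$ot_n - r$ot_crossed,
                    r$not_crossed, r$not_n - r$not_crossed),
                  nrow = 2, byrow = TRUE)
    ct <- tryCatch(pearson_chi2(tab), error = function(e)
      list(statistic = NA_real_, df = 1L, p_value = NA_real_))
    data.frame(domain = r$domain,
               ot_crossed = r$ot_crossed, ot_n = r$ot_n,
               ot_pct = 100 * r$ot_crossed / r$ot_n,
               not_crossed = r$not_crossed, not_n = r$not_n,
               not_pct = 100 * r$not_crossed / r$not_n,
               chi2 = ct$statistic, df = ct$df, p_value = ct$p_value)
  })
  do.call(rbind, res)
}

#' Pooled-variance two-sample t-test
#'
#' Student's t with the pooled-variance (equal variance) form, two-sided,
#' consistent with pooled-SD Cohen's d. Degenerate inputs: zero pooled
#' variance with equal means gives t = 0, p = 1; with unequal means the
#' statistic is undefined and rejected.
#'
#' @param a,b numeric vectors (each at least 2 non-missing values).
#' @return list with `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
two_sample_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations")
  df <- length(a) + length(b) - 2
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) / df
  if (sp2 == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = df, p_value = 1, mean_a = mean(a), mean_b = mean(b)))
    stop("zero pooled variance with unequal means: t undefined")
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Cohen's d from group moments
#'
#' d = |m2 - m1| / s_pooled with the (n-1)-weighted pooled SD, reported as a
#' magnitude.
#'
#' @param m1,sd1,n1,m2,sd2,n2 group means, SDs and sizes (n >= 2 each).
#' @return numeric effect size.
#' @export
cohens_d <- function(m1, sd1, n1, m2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp == 0) stop("zero pooled SD: d undefined")
  abs(m2 - m1) / sp
}

#' Multilevel logistic regression for the per-session NOT indicator
#'
#' Random-intercept logistic model with sessions (level 1) nested in
#' patients (level 2) nested in therapists (level 3), fitted with
#' [lme4::glmer()]. Continuous predictors are grand-mean centered before
#' entry. The level-2 ICC uses the latent-scale residual variance pi^2/3.
#'
#' @param data data frame with the outcome, predictors, and id columns.
#' @param fixed character vector of fixed-effect column names (empty =
#'   intercept-only model).
#' @param outcome name of the binary outcome column (default `"not"`).
#' @param patient,therapist id column names.
#' @param center grand-mean center the fixed effects (default `TRUE`).
#' @param nAGQ integration points passed to `glmer` (1 = Laplace, the
#'   default; 0 is faster and adequate for large simulation studies).
#' @return object of class `nested_logit`: list with `coefficients` (matrix
#'   with estimate/SE/z/p), `aic`, `bic`, `varcomp` (patient, therapist),
#'   `icc2`, `converged`, `separation`, `n_obs`, `n_patients`,
#'   `n_therapists`, `fixed`, and the underlying `fit`.
#' @export
fit_nested_logistic <- function(data, fixed = character(), outcome = "not",
                                patient = "patient_id",
                                therapist = "therapist_id",
                                center = TRUE, nAGQ = 1) {
  stopifnot(all(c(outcome, fixed, patient, therapist) %in% names(data)))
  y <- data[[outcome]]
  if (length(unique(na.omit(y))) < 2)
    stop("outcome must have both classes")
  d <- data
  if (center)
    for (v in fixed) d[[v]] <- grand_mean_center(d[[v]])
  d$.pat <- factor(d[[patient]])
  d$.ther <- factor(d[[therapist]])
  rhs <- paste(c("1", fixed, "(1 | .pat)", "(1 | .ther)"), collapse = " + ")
  form <- stats::as.formula(paste(outcome, "~", rhs))
  msgs <- character(0)
  fit <- withCallingHandlers(
    suppressMessages(lme4::glmer(form, data = d, family = stats::binomial,
                                 nAGQ = nAGQ)),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  vc <- lme4::VarCorr(fit)
  v_pat <- unname(vc$.pat[1, 1]); v_ther <- unname(vc$.ther[1, 1])
  icc2 <- v_pat / (v_pat + v_ther + pi^2 / 3)
  separation <- any(abs(co[, "Estimate"]) > 15 | co[, "Std. Error"] > 15)
  structure(list(coefficients = co, aic = stats::AIC(fit),
                 bic = stats::BIC(fit),
                 varcomp = c(patient = v_pat, therapist = v_ther),
                 icc2 = icc2,
                 converged = !any(grepl("converge", msgs)),
                 messages = msgs, separation = separation,
                 n_obs = nrow(d), n_patients = nlevels(d$.pat),
                 n_therapists = nlevels(d$.ther),
                 fixed = fixed, fit = fit),
            class = "nested_logit")
}

#' @export
print.nested_logit <- function(x, ...) {
  cat(sprintf(
    "Multilevel logistic fit: %d sessions, %d patients, %d therapists\n",
    x$n_obs, x$n_patients, x$n_therapists))
  stats::printCoefmat(x$coefficients, digits = 3)
  cat(sprintf("AIC %.1f  BIC %.1f  var(patient) %.3f  var(therapist) %.3f  ICC2 %.3f\n",
              x$aic, x$bic, x$varcomp["patient"], x$varcomp["therapist"],
              x$icc2))
  if (!x$converged) cat("NOTE: convergence warnings:",
                        paste(unique(x$messages), collapse = "; "), "\n")
  if (x$separation) cat("NOTE: possible complete separation\n")
  invisible(x)
}

#' @export
coef.nested_logit <- function(object, ...) object$coefficients[, "Estimate"]

#' Stepwise model building for predictors of going off track
#'
#' Reproduces the three-stage build: Model 1 is the intercept-only
#' (random-intercepts) model; Model 2 adds session number; the better of
#' the two by AIC goes forward. Each CST domain is then screened in a
#' separate model (base + that domain), and domains significant at the
#' liberal screen (p <= 0.10) enter the final Model 3, which is compared
#' with the earlier winner. The full trace is recorded and the procedure is
#' deterministic given the data.
#'
#' @param data per-session data with outcome and domain predictor columns
#'   (see [session_predictors()] joined with track states, or
#'   [simulate_session_outcomes()]).
#' @param domains predictor columns to screen.
#' @param screen_p liberal inclusion threshold (default 0.10).
#' @param nAGQ passed to [fit_nested_logistic()].
#' @param outcome,patient,therapist column names.
#' @return object of class `model_trace`: list with `trace` (one row per
#'   fitted model: model, predictors, AIC, BIC, domain p), `retained`,
#'   `base` (`"model1"` or `"model2"`), `final` (a `nested_logit`),
#'   `final_vs_base_aic`.
#' @export
model_building <- function(data,
                           domains = c("risk", "motivation", "alliance",
                                       "life_events", "social_support",
                                       "emotion_regulation"),
                           screen_p = 0.10, nAGQ = 1, outcome = "not",
                           patient = "patient_id",
                           therapist = "therapist_id") {
  domains <- intersect(domains, names(data))
  fit <- function(fx) fit_nested_logistic(data, fx, outcome = outcome,
                                          patient = patient,
                                          therapist = therapist, nAGQ = nAGQ)
  m1 <- fit(character())
  m2 <- fit("session")
  base_fixed <- if (m2$aic < m1$aic) "session" else character()
  base_name <- if (m2$aic < m1$aic) "model2" else "model1"
  base_aic <- min(m1$aic, m2$aic)
  trace <- data.frame(model = c("model1", "model2"),
                      predictors = c("(intercept)", "session"),
                      aic = c(m1$aic, m2$aic), bic = c(m1$bic, m2$bic),
                      domain = NA_character_, estimate = NA_real_,
                      p_value = NA_real_)
  screen <- list()
  for (dom in domains) {
    md <- fit(c(base_fixed, dom))
    p <- md$coefficients[dom, "Pr(>|z|)"]
    est <- md$coefficients[dom, "Estimate"]
    screen[[dom]] <- md
    trace <- rbind(trace, data.frame(
      model = paste0("screen_", dom),
      predictors = paste(c(base_fixed, dom), collapse = "+"),
      aic = md$aic, bic = md$bic, domain = dom, estimate = est, p_value = p))
  }
  retained <- domains[vapply(domains, function(dom)
    screen[[dom]]$coefficients[dom, "Pr(>|z|)"] <= screen_p, logical(1))]
  final <- if (length(retained)) fit(c(base_fixed, retained)) else
    (if (base_name == "model2") m2 else m1)
  trace <- rbind(trace, data.frame(
    model = "model3",
    predictors = paste(c(base_fixed, retained), collapse = "+"),
    aic = final$aic, bic = final$bic, domain = NA_character_,
    estimate = NA_real_, p_value = NA_real_))
  structure(list(trace = trace, retained = retained, base = base_name,
                 models = list(model1 = m1, model2 = m2, screen = screen),
                 final = final,
                 final_vs_base_aic = final$aic - base_aic),
            class = "model_trace")
}

#' @export
print.model_trace <- function(x, ...) {
  cat("Model building trace (base:", x$base, ")\n")
  tr <- x$trace
  tr$aic <- round(tr$aic, 1); tr$bic <- round(tr$bic, 1)
  tr$estimate <- round(tr$estimate, 3); tr$p_value <- signif(tr$p_value, 3)
  print(tr, row.names = FALSE)
  cat("retained at the p<=.10 screen:",
      if (length(x$retained)) paste(x$retained, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}

#' Item-level OT/NOT comparison
#'
#' Pooled two-sample t-tests on the recoded battery and risk items at the
#' comparison session, with pairwise deletion per item, plus the percentage
#' of each group at or past the item cut-off.
#'
#' @param items long data frame with columns `instrument`, `item`, `value`
#'   (already recoded) and `group` (`"OT"`/`"NOT"`), one row per patient ×
#'   item.
#' @param catalog an [instrument_catalog()].
#' @param alpha significance label threshold (default .05; no
#'   multiple-testing correction is applied).
#' @return data frame with one row per item: scale, group means, t, df, p,
#'   crossing percentages, and a `significant` flag. Items observed in only
#'   one group are skipped with a note in attribute `"skipped"`.
#' @export
item_comparison_report <- function(items, catalog = instrument_catalog(),
                                   alpha = 0.05) {
  scale_of <- function(instr, it) {
    for (s in catalog$scales)
      if (s$instrument == instr && it %in% s$items) return(s)
    NULL
  }
  keys <- unique(items[, c("instrument", "item")])
  keys <- keys[order(keys$instrument, keys$item), ]
  rows <- list(); skipped <- character(0)
  for (r in seq_len(nrow(keys))) {
    instr <- keys$instrument[r]; it <- keys$item[r]
    sub <- items[items$instrument == instr & items$item == it &
                   !is.na(items$value), ]
    a <- sub$value[sub$group == "OT"]; b <- sub$value[sub$group == "NOT"]
    if (length(a) < 2 || length(b) < 2) {
      skipped <- c(skipped, paste0(instr, ":", it))
      next
    }
    sc <- scale_of(instr, it)
    risk_item <- instr == "OQ30" ||
      (instr == "HSCL11" && it == catalog$risk$hscl_suicide_item)
    cutoff <- if (instr == "OQ30") catalog$risk$oq_cutoff
      else if (risk_item) catalog$risk$hscl_cutoff
      else if (!is.null(sc)) sc$item_cutoff else NA
    dirn <- if (risk_item) "at_or_above" else "at_or_below"
    pct <- function(v) {
      if (is.na(cutoff)) return(NA_real_)
      100 * mean(if (dirn == "at_or_below") v <= cutoff else v >= cutoff)
    }
    tt <- two_sample_t(a, b)
    rows[[length(rows) + 1]] <- data.frame(
      instrument = instr, item = it,
      scale = if (is.null(sc)) NA_character_ else sc$name,
      mean_ot = tt$mean_a, mean_not = tt$mean_b,
      t = tt$t, df = tt$df, p_value = tt$p_value,
      pct_crossed_ot = pct(a), pct_crossed_not = pct(b),
      significant = tt$p_value < alpha)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(instrument = character(), item = integer(),
                      scale = character(), mean_ot = numeric(),
                      mean_not = numeric(), t = numeric(), df = numeric(),
                      p_value = numeric(), pct_crossed_ot = numeric(),
                      pct_crossed_not = numeric(), significant = logical())
  structure(out, skipped = skipped)
}
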