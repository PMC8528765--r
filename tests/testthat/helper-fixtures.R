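# Shared fixtures: all built in code at test time.

resp_df <- function(items, values) data.frame(item = items, value = values)

# a complete response set for a scale, constant value
const_resp <- function(scale, value) resp_df(scale$items, rep(value, length(scale$items)))

# tiny deterministic reference pool: trajectories y = a + b*ln(s), s = 1..T
toy_pool <- function(a, b, T) {
  stopifnot(length(a) == length(b), length(b) == length(T))
  scores <- do.call(rbind, lapply(seq_along(a), function(i) {
    s <- seq_len(T[i])
    data.frame(id = i, session = s, hscl = a[i] + b[i] * log(s))
  }))
  as_reference_pool(scores)
}

# hand-rolled etr model object for boundary arithmetic tests
manual_etr <- function(coef, vcov = matrix(0, length(coef), length(coef)),
                       tau2 = 0, sigma2 = 0, has_T = length(coef) == 4) {
  structure(list(coef = coef, vcov = vcov, tau2 = tau2, sigma2 = sigma2,
                 fit_type = "manual", has_T = has_T, neighbors = integer()),
            class = "etr_model")
}

# small cohort configuration used across end-to-end tests
small_config <- function(...) {
  args <- list(n_patients = 60L, n_therapists = 12L, archival_n = 300L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_config, args)
}
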