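#' @importFrom stats aggregate ave coef lm median na.omit pchisq pnorm qnorm
#'   rbinom rnorm runif sd setNames vcov
NULL

.romnav_env <- new.env(parent = emptyenv())

#' Load the instrument catalog
#'
#' Reads the versioned YAML catalog describing the monitoring battery: item
#' sets, reversal keys, aggregation rule (sum or mean), item ranges and the
#' inclusive domain/item cut-offs for the HSCL-11, ASC, ASQ and OQ-30.
#'
#' ASQ domain cut-offs are not stored verbatim: they are constructed at load
#' time as mean − 1 SD from the archival outpatient moments recorded in the
#' catalog (concealing 3.01 − 0.74, tolerating 2.97 − 0.68, adjusting
#' 2.45 − 0.75), the same rule [compute_asq_cutoffs()] applies to raw
#' archival samples.
#'
#' @param path path to a catalog YAML; `NULL` (default) loads the catalog
#'   shipped with the package (cached after first load).
#' @return an object of class `instrument_catalog`: a list with elements
#'   `scales` (named list of `scale_definition` objects), `risk` (the
#'   suicidality/substance risk item ids and cut-offs) and `version`.
#' @export
instrument_catalog <- function(path = NULL) {
  default <- is.null(path)
  if (default) {
    if (!is.null(.romnav_env$catalog)) return(.romnav_env$catalog)
    path <- system.file("extdata", "instrument_catalog.yaml", package = "romnav")
  }
  raw <- yaml::read_yaml(path)
  scales <- lapply(names(raw$scales), function(nm) {
    s <- raw$scales[[nm]]
    def <- list(
      name = nm,
      instrument = s$instrument,
      items = as.integer(unlist(s$items)),
      reversed = as.integer(unlist(s$reversed %||% integer())),
      aggregation = s$aggregation,
      range = as.numeric(unlist(s$range)),
      domain_cutoff = if (is.null(s$domain_cutoff)) NA_real_ else as.numeric(s$domain_cutoff),
      cutoff_direction = s$cutoff_direction %||% NA_character_,
      item_cutoff = if (is.null(s$item_cutoff)) NA_real_ else as.numeric(s$item_cutoff)
    )
    if (!is.null(s$archival_mean)) {
      def$archival_moments <- c(mean = as.numeric(s$archival_mean),
                                sd = as.numeric(s$archival_sd))
      # cut-offs operate at the printed 2-dp precision
      def$domain_cutoff <- round(def$archival_moments[["mean"]] -
                                   def$archival_moments[["sd"]], 2)
    }
    if (!all(def$reversed %in% def$items))
      stop("catalog scale ", nm, ": reversed items not a subset of items")
    structure(def, class = "scale_definition")
  })
  names(scales) <- names(raw$scales)
  sizes <- c(HSCL_total = 11L, ASC_TA = 11L, ASC_MO = 9L, ASC_SS = 11L,
             ASC_LE = 9L, ASQ_concealing = 8L, ASQ_tolerating = 5L,
             ASQ_adjusting = 7L, OQ_total = 30L)
  for (nm in names(sizes)) {
    if (is.null(scales[[nm]]))
      stop("catalog is missing scale ", nm)
    if (length(scales[[nm]]$items) != sizes[[nm]])
      stop("catalog scale ", nm, " must have ", sizes[[nm]], " items")
  }
  cat <- structure(list(scales = scales, risk = raw$risk,
                        version = raw$version),
                   class = "instrument_catalog")
  if (default) .romnav_env$catalog <- cat
  cat
}

#' @export
print.instrument_catalog <- function(x, ...) {
  cat("Instrument catalog (version ", x$version, ")\n", sep = "")
  for (s in x$scales)
    cat(sprintf("  %-15s %-6s %2d items  %-4s  cutoff %s (%s)\n",
                s$name, s$instrument, length(s$items), s$aggregation,
                format(s$domain_cutoff), s$cutoff_direction))
  invisible(x)
}

#' Look up one scale definition
#'
#' @param name scale name, e.g. `"ASC_TA"`.
#' @param catalog an [instrument_catalog()].
#' @return a `scale_definition`.
#' @export
get_scale <- function(name, catalog = instrument_catalog()) {
  s <- catalog$scales[[name]]
  if (is.null(s)) stop("unknown scale: ", name)
  s
}

check_items <- function(responses, scale) {
  if (!all(c("item", "value") %in% names(responses)))
    stop("responses must have columns 'item' and 'value'")
  bad <- setdiff(responses$item, scale$items)
  if (length(bad))
    stop("unknown item id(s) for scale ", scale$name, ": ",
         paste(bad, collapse = ", "))
  invisible(responses)
}

#' Recode reverse-keyed items
#'
#' Reflects reverse-keyed items about the scale midpoint so that high values
#' indicate high functioning (on the 1–5 battery anchors, v becomes 6 − v).
#' Non-reversed items and missing values pass through unchanged.
#'
#' @param responses data frame with columns `item` and `value` (`NA` =
#'   missing), all items belonging to `scale`.
#' @param scale a `scale_definition`.
#' @return `responses` with reversed items recoded.
#' @export
recode_reversed <- function(responses, scale) {
  check_items(responses, scale)
  rev <- responses$item %in% scale$reversed & !is.na(responses$value)
  responses$value[rev] <- sum(scale$range) - responses$value[rev]
  responses
}

#' Score one scale with the 80% missing-data rule
#'
#' Aggregates item responses into the scale score (sum or mean per the
#' catalog). When more than 80% of a scale's items are observed, missing
#' items are replaced by the mean of the observed items of that scale;
#' otherwise the score is invalid (`valid = FALSE`, value `NA`). Reversals
#' must already be applied (see [recode_reversed()]).
#'
#' @param responses data frame with columns `item`, `value`; items absent
#'   from the data frame count as missing.
#' @param scale a `scale_definition`.
#' @return an object of class `scale_score`: list with `scale`, `value`,
#'   `n_observed`, `n_items`, `valid`.
#' @export
score_scale <- function(responses, scale) {
  check_items(responses, scale)
  m <- responses$value[match(scale$items, responses$item)]
  n_obs <- sum(!is.na(m))
  k <- length(scale$items)
  valid <- n_obs / k > 0.80
  value <- NA_real_
  if (valid) {
    obs_mean <- mean(m, na.rm = TRUE)
    value <- if (scale$aggregation == "sum") obs_mean * k else obs_mean
  }
  structure(list(scale = scale$name, value = value, n_observed = n_obs,
                 n_items = k, valid = valid),
            class = "scale_score")
}

#' @export
print.scale_score <- function(x, ...) {
  cat(sprintf("%s: %s (%d/%d items%s)\n", x$scale,
              if (x$valid) format(round(x$value, 3)) else "invalid",
              x$n_observed, x$n_items, if (x$valid) "" else ", <80% observed"))
  invisible(x)
}

#' Evaluate a domain cut-off
#'
#' Inclusive comparison of a valid scale score against the catalog cut-off in
#' the catalog direction (ASC/ASQ: at or below; risk: at or above).
#'
#' @param score a `scale_score`.
#' @param scale the matching `scale_definition`.
#' @return `TRUE`/`FALSE`, or `NA` when the score is invalid or the scale has
#'   no domain cut-off.
#' @export
domain_flag <- function(score, scale = get_scale(score$scale)) {
  stopifnot(inherits(score, "scale_score"))
  if (!isTRUE(score$valid) || is.na(scale$domain_cutoff)) return(NA)
  switch(scale$cutoff_direction,
         at_or_below = score$value <= scale$domain_cutoff,
         at_or_above = score$value >= scale$domain_cutoff,
         NA)
}

#' Flag critical items
#'
#' Items at or past the item cut-off (after recoding reversals): at or below
#' for the functioning-keyed ASC/ASQ items, at or above for risk items.
#' Missing items are never flagged.
#'
#' @param responses data frame with columns `item`, `value`.
#' @param scale a `scale_definition`.
#' @param cutoff item cut-off; defaults to the catalog value.
#' @param direction `"at_or_below"` or `"at_or_above"`; defaults to
#'   `"at_or_above"` only when the scale's domain direction is at_or_above.
#' @return integer vector of flagged item ids (possibly empty).
#' @export
item_flags <- function(responses, scale, cutoff = scale$item_cutoff,
                       direction = NULL) {
  check_items(responses, scale)
  if (is.null(direction))
    direction <- if (identical(scale$cutoff_direction, "at_or_above"))
      "at_or_above" else "at_or_below"
  if (is.na(cutoff)) return(integer())
  v <- responses$value
  hit <- !is.na(v) & if (direction == "at_or_below") v <= cutoff else v >= cutoff
  sort(unique(responses$item[hit]))
}

#' Construct ASQ subscale cut-offs from archival samples
#'
#' The ASQ has no published clinical cut-offs; they are constructed as
#' mean − 1 SD (SD with the n − 1 denominator) of archival outpatient
#' subscale scores. With the published archival moments this yields
#' concealing 2.27, tolerating 2.29, adjusting 1.70.
#'
#' @param samples named list of numeric vectors, one per ASQ subscale, each
#'   of length ≥ 2.
#' @return named numeric vector of cut-offs.
#' @export
compute_asq_cutoffs <- function(samples) {
  if (!length(samples)) stop("no samples supplied")
  vapply(samples, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) stop("archival sample must have at least 2 values")
    mean(x) - sd(x)
  }, numeric(1))
}

#' Suicidality / substance risk assessment
#'
#' Combines the three risk indicator items: the HSCL-11 suicide item
#' (cut-off ≥ 2, refreshed every session) and OQ-30 items 5 and 18
#' (cut-off ≥ 3, from the most recent battery). `flag` is `TRUE` when any
#' item is at or above its cut-off; `severity` counts the items at or above
#' cut-off (0–3, higher = worse); `immediate` is the status-independent
#' red-bar suicide alert, driven by the HSCL item alone.
#'
#' @param hscl_suicide,oq5,oq18 numeric item responses; `NA` = missing.
#' @param catalog an [instrument_catalog()] (source of the cut-offs).
#' @return list with `severity`, `flag`, `immediate`; all `NA` when all three
#'   items are missing.
#' @export
risk_assessment <- function(hscl_suicide, oq5, oq18,
                            catalog = instrument_catalog()) {
  rk <- catalog$risk
  v <- c(hscl_suicide, oq5, oq18)
  if (all(is.na(v)))
    return(list(severity = NA_integer_, flag = NA, immediate = NA))
  hits <- c(!is.na(hscl_suicide) && hscl_suicide >= rk$hscl_cutoff,
            !is.na(oq5) && oq5 >= rk$oq_cutoff,
            !is.na(oq18) && oq18 >= rk$oq_cutoff)
  list(severity = as.integer(sum(hits)), flag = any(hits), immediate = hits[1])
}
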