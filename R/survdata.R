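#' Time-to-event dataset in counting-process form
#'
#' Each row covers a half-open at-risk interval `(start, stop]` for one
#' subject; time 0 is the initiation of dexmedetomidine. Time-fixed data use
#' one row per subject with `start = 0`; a time-dependent covariate (e.g. the
#' post-propofol-induction state) is represented by splitting the subject's
#' follow-up into intervals with the covariate constant within each.
#'
#' @param id Subject identifier (repeated across a subject's intervals).
#' @param start Interval start times (>= 0); recycled. Default 0.
#' @param stop Interval stop times (event/censoring or covariate-change
#'   times); must exceed `start` row-wise.
#' @param status Event indicator for the interval end: 1 = event at `stop`,
#'   0 = censored / interval continues.
#' @param covariates A data.frame or matrix of covariate columns.
#' @return A data.frame of class `survival_data` with attribute
#'   `"covariates"` naming the covariate columns.
#' @export
survival_data <- function(id, start = 0, stop, status, covariates = NULL) {
  start <- rep_len(start, length(stop))
  if (any(stop <= start)) stop("stop must exceed start within intervals")
  if (any(start < 0)) stop("times must be non-negative")
  if (!all(status %in% c(0, 1))) stop("status must be 0/1")
  df <- data.frame(id = id, start = start, stop = stop, status = status)
  covnames <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    covnames <- names(covariates)
    df <- cbind(df, covariates)
  }
  attr(df, "covariates") <- covnames
  class(df) <- c("survival_data", "data.frame")
  df
}

#' Covariate column names of a survival dataset
#' @param data A [survival_data()].
#' @export
covariate_names <- function(data) attr(data, "covariates")

#' Kaplan-Meier estimate with Greenwood confidence limits
#'
#' Right-continuous product-limit estimate of the survivor function, with
#' pointwise 95% Greenwood confidence limits on the log(-log) scale, and the
#' cumulative incidence `1 - S(t)`. Backed by [survival::survfit()].
#'
#' @param data A [survival_data()].
#' @return An object of class `km_fit`: a data.frame of (`time`, `n_risk`,
#'   `n_event`, `surv`, `lower`, `upper`, `cuminc`) plus the underlying
#'   `survfit` object as an attribute.
#' @export
km_estimate <- function(data) {
  stopifnot(inherits(data, "survival_data"))
  sf <- survival::survfit(
    survival::Surv(start, stop, status) ~ 1,
    data = data, conf.type = "log-log", conf.int = 0.95)
  out <- data.frame(time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, surv = sf$surv,
                    lower = sf$lower, upper = sf$upper,
                    cuminc = 1 - sf$surv)
  attr(out, "survfit") <- sf
  class(out) <- c("km_fit", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier fit at given times
#'
#' @param km A [km_estimate()] result.
#' @param times Times at which to evaluate.
#' @param what `"surv"` (default), `"cuminc"`, `"lower"` or `"upper"`.
#' @return Numeric vector; the step function is right-continuous and equals
#'   1 (or 0 for `cuminc`) before the first event.
#' @export
km_at <- function(km, times, what = c("surv", "cuminc", "lower", "upper")) {
  what <- match.arg(what)
  ev <- km[km$n_event > 0, , drop = FALSE]
  init <- switch(what, surv = 1, cuminc = 0, lower = 1, upper = 1)
  if (nrow(ev) == 0) return(rep(init, length(times)))
  idx <- findInterval(times, ev$time)
  vals <- c(init, ev[[what]])
  vals[idx + 1]
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Monotone step-up adjustment via [stats::p.adjust()]; adjusted values are
#' never below the raw p-values.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' First hemodynamic-instability event from a vital-sign series
#'
#' The composite endpoint is hypotension (systolic or diastolic blood
#' pressure dropping more than 20% below its baseline) and/or bradycardia
#' (heart rate dropping more than 20% below baseline). "More than 20%" is
#' implemented strictly: `value < 0.8 * baseline`. Event times are read off
#' the vitals sampling grid (no interpolation); the composite event time is
#' the earliest component event.
#'
#' @param vitals A data.frame with column `time` (minutes since
#'   dexmedetomidine initiation) and any of `sbp`, `dbp`, `hr`.
#' @param baseline Named numeric vector with the pre-dose baselines for the
#'   channels present (names among `"sbp"`, `"dbp"`, `"hr"`), all > 0.
#' @param follow_up End of follow-up (completion of the operation), minutes.
#' @return A list with `time` (event or censoring time), `event` (0/1) and
#'   `type` (`"hypotension"`, `"bradycardia"`, both, or `NA` if censored).
#' @export
detect_events <- function(vitals, baseline, follow_up) {
  channels <- intersect(c("sbp", "dbp", "hr"), names(vitals))
  if (length(channels) == 0 || nrow(vitals) == 0)
    return(list(time = follow_up, event = 0L, type = NA_character_))
  if (any(baseline[channels] <= 0) || anyNA(baseline[channels]))
    stop("baselines must be positive for all channels present")
  vit <- vitals[vitals$time <= follow_up, , drop = FALSE]
  first <- Inf
  types <- character(0)
  for (ch in channels) {
    hit <- which(!is.na(vit[[ch]]) & vit[[ch]] < 0.8 * baseline[[ch]])
    if (length(hit)) {
      t_ch <- min(vit$time[hit])
      lab <- if (ch == "hr") "bradycardia" else "hypotension"
      if (t_ch < first) {
        first <- t_ch; types <- lab
      } else if (t_ch == first) {
        types <- union(types, lab)
      }
    }
  }
  if (is.finite(first))
    list(time = first, event = 1L,
         type = paste(sort(types), collapse = "+"))
  else
    list(time = follow_up, event = 0L, type = NA_character_)
}
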