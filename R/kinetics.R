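# Dwell-time kinetics: truncated-exponential maximum likelihood for
# dissociation rates, open-time-based association rates, and the
# origin-constrained concentration-series fit for k_on.

#' Rate estimate container
#'
#' @param quantity One of "rate", "v_on", "k_off", "k_on", "k_on_prime".
#' @param value Estimate (s^-1, or mM^-1 s^-1 for the k_on quantities).
#' @param stderr Standard error, same units.
#' @param n_dwells Number of dwells behind the estimate.
#' @param dead_time_used Dead time applied, s.
#' @param unit Unit string.
#' @param upper95 Optional one-sided 95\% upper bound (reported when the
#'   estimate is zero-count).
#' @return An object of class `rate_estimate`.
#' @export
rate_estimate <- function(quantity, value, stderr, n_dwells,
                          dead_time_used = 0, unit = "s^-1", upper95 = NA_real_) {
  stopifnot(is.numeric(value), is.numeric(stderr) || is.na(stderr))
  if (n_dwells > 0 && value <= 0) {
    stop("rate estimate must be positive when dwells are present", call. = FALSE)
  }
  structure(list(quantity = quantity, value = value, stderr = stderr,
                 n_dwells = as.integer(n_dwells),
                 dead_time_used = dead_time_used, unit = unit,
                 upper95 = upper95),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%s = %.4g +/- %.3g %s (n = %d dwells, dead time %g s)\n",
              x$quantity, x$value, x$stderr, x$unit, x$n_dwells,
              x$dead_time_used))
  if (!is.na(x$upper95)) cat(sprintf("  95%% upper bound: %.4g %s\n", x$upper95, x$unit))
  invisible(x)
}

#' Left-truncated exponential MLE for dwell durations
#'
#' Durations observed only above a detection dead time follow a left-truncated
#' exponential; by memorylessness the MLE of the rate is
#' `n / sum(duration - dead_time)`, with standard error `rate / sqrt(n)`.
#' With `dead_time = 0` this is exactly the naive exponential MLE.
#'
#' @param durations Dwell durations, s (all >= dead_time).
#' @param dead_time Detection dead time, s.
#' @return A [rate_estimate()] with quantity `"rate"`.
#' @export
fit_exponential <- function(durations, dead_time = 0) {
  if (!length(durations)) stop("no dwell durations supplied", call. = FALSE)
  if (any(durations < dead_time - 1e-12)) {
    stop("durations below the stated dead time", call. = FALSE)
  }
  n <- length(durations)
  if (n < 10L) warning("fewer than 10 dwells; rate estimate will be imprecise",
                       call. = FALSE)
  rate <- n / sum(durations - dead_time)
  rate_estimate("rate", rate, rate / sqrt(n), n, dead_time)
}

#' Dissociation rate constant(s) from an event table
#'
#' Applies [fit_exponential()] to adduct (blockade) durations, optionally per
#' analyte (or analyte/diastereomer) label.
#'
#' @param events An `event_table` with a `duration` column; `label` required
#'   when `per_label = TRUE`.
#' @param per_label Fit one rate per label.
#' @param dead_time Detection dead time, s; defaults to the table's
#'   `dead_time` attribute (0 if absent).
#' @return A `rate_estimate` (quantity `"k_off"`), or a named list of them.
#' @export
estimate_koff <- function(events, per_label = FALSE, dead_time = NULL) {
  if (is.null(dead_time)) dead_time <- attr(events, "dead_time") %||% 0
  if (!per_label) {
    est <- fit_exponential(events$duration, dead_time)
    est$quantity <- "k_off"
    return(est)
  }
  if (is.null(events$label) || anyNA(events$label)) {
    stop("per-label fitting requires labeled events", call. = FALSE)
  }
  out <- lapply(split(events$duration, events$label), function(d) {
    est <- fit_exponential(d, dead_time)
    est$quantity <- "k_off"
    est
  })
  out
}

#' Association rate from an event table
#'
#' The association clock runs only while the cysteine is free, so the MLE is
#' the event count divided by the open (unblockaded) time; open exposure is
#' reduced by one dead time per event, mirroring the truncation correction
#' applied to adduct dwells. With zero events the estimate is 0 and a
#' rule-of-three 95\% upper bound (`3 / open time`) is reported.
#'
#' @param events An `event_table`.
#' @param duration Total recording duration, s; defaults to the table's
#'   `duration_s` attribute.
#' @param dead_time Detection dead time, s (default: table attribute, else 0).
#' @param label Optional label: count only events with this label (open-time
#'   exposure still excludes all blockades).
#' @return A [rate_estimate()] with quantity `"v_on"`.
#' @export
estimate_von <- function(events, duration = NULL, dead_time = NULL, label = NULL) {
  if (is.null(duration)) duration <- attr(events, "duration_s")
  if (is.null(duration) || !is.finite(duration)) {
    stop("recording duration required", call. = FALSE)
  }
  if (is.null(dead_time)) dead_time <- attr(events, "dead_time") %||% 0
  n_all <- nrow(events)
  open_time <- duration - sum(events$duration) - n_all * dead_time
  if (open_time <= 0) stop("no open time left in the recording", call. = FALSE)
  n <- if (is.null(label)) n_all else sum(events$label == label, na.rm = TRUE)
  if (n == 0L) {
    return(rate_estimate("v_on", 0, NA_real_, 0L, dead_time,
                         upper95 = 3 / open_time))
  }
  rate_estimate("v_on", n / open_time, sqrt(n) / open_time, n, dead_time)
}

#' Origin-constrained fit of k_on from a concentration series
#'
#' Bimolecular kinetics imply v_on = k_on * C_tot; the slope through the
#' origin is fitted by inverse-variance weighted least squares over the
#' per-concentration v_on estimates.
#'
#' @param conc Total concentrations, mM (>= 2 distinct values).
#' @param von List of [rate_estimate()]s (or numeric v_on values, in which
#'   case weights are equal).
#' @param stderr Optional numeric standard errors when `von` is numeric.
#' @return A `rate_estimate` with quantity `"k_on"`, unit mM^-1 s^-1, and a
#'   `residuals` attribute (per-point residual v_on, s^-1).
#' @export
fit_kon <- function(conc, von, stderr = NULL) {
  if (is.list(von) && all(vapply(von, inherits, logical(1), "rate_estimate"))) {
    v <- vapply(von, `[[`, numeric(1), "value")
    se <- vapply(von, `[[`, numeric(1), "stderr")
    n_tot <- sum(vapply(von, `[[`, integer(1), "n_dwells"))
  } else {
    v <- as.numeric(von)
    se <- if (is.null(stderr)) rep(NA_real_, length(v)) else as.numeric(stderr)
    n_tot <- length(v)
  }
  conc <- as.numeric(conc)
  if (length(conc) != length(v)) stop("conc and von lengths differ", call. = FALSE)
  if (length(unique(conc)) < 2L) {
    stop("need >= 2 distinct concentrations; for a single concentration use ",
         "estimate_von() and divide by the concentration", call. = FALSE)
  }
  w <- if (all(is.finite(se)) && all(se > 0)) 1 / se^2 else rep(1, length(v))
  slope <- sum(w * conc * v) / sum(w * conc^2)
  se_slope <- if (all(is.finite(se)) && all(se > 0)) {
    1 / sqrt(sum(w * conc^2))
  } else {
    res <- v - slope * conc
    sqrt(sum(res^2) / (length(v) - 1L) / sum(conc^2))
  }
  out <- rate_estimate("k_on", slope, se_slope, n_tot, 0, unit = "mM^-1 s^-1")
  attr(out, "residuals") <- v - slope * conc
  out
}
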