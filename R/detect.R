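# Idealization of two-level traces: robust baseline estimation, threshold
# segmentation on an analysis-filtered copy, dead-time censoring, and
# extraction of the three per-event classification features (I_res%,
# duration, within-event RMS noise).

#' Idealization configuration
#'
#' @param analysis_filter_cutoff Additional low-pass applied before edge
#'   detection, Hz. Sits between the display filter and the acquisition
#'   filter; 1 kHz by default.
#' @param threshold_pct Event threshold as a percentage of the open-pore
#'   current. Samples whose normalized current falls below it are candidate
#'   blockade samples. `NULL` defers the choice to [idealize()], which then
#'   requires expected levels (see [auto_threshold()]).
#' @param dead_time Minimum detectable dwell, s. Dwells shorter than this are
#'   discarded (and compensated for downstream by truncated-likelihood
#'   fitting). A warning is issued if it is below half an analysis-filter
#'   period (`0.5 / analysis_filter_cutoff`), where edge smearing makes
#'   durations unreliable.
#' @param baseline_window Seconds of trace used for baseline estimation
#'   (`NULL` = whole trace).
#' @return An object of class `idealization_config`.
#' @export
idealization_config <- function(analysis_filter_cutoff = 1000,
                                threshold_pct = NULL,
                                dead_time = 5e-4,
                                baseline_window = NULL) {
  if (!is.null(threshold_pct) &&
      (threshold_pct <= 0 || threshold_pct >= 100)) {
    stop("threshold_pct must lie in (0, 100)", call. = FALSE)
  }
  if (dead_time < 0.5 / analysis_filter_cutoff) {
    warning("dead_time below half an analysis-filter period; dwell durations ",
            "near the filter rise time will be unreliable", call. = FALSE)
  }
  structure(list(analysis_filter_cutoff = analysis_filter_cutoff,
                 threshold_pct = threshold_pct,
                 dead_time = dead_time,
                 baseline_window = baseline_window),
            class = "idealization_config")
}

#' Default threshold from expected levels
#'
#' Midpoint between the open level (100\%) and the shallowest expected adduct
#' level, maximizing margin on both sides of the closest pair.
#'
#' @param levels Numeric vector of expected I_res\% levels (see
#'   [fixture_levels()]), or a `pore_fixture`.
#' @param analytes Optional analyte subset when `levels` is a fixture.
#' @return Threshold in \% of the open-pore current.
#' @export
auto_threshold <- function(levels, analytes = NULL) {
  if (inherits(levels, "pore_fixture")) levels <- fixture_levels(levels, analytes)
  stopifnot(is.numeric(levels), length(levels) >= 1L, all(levels < 100))
  (100 + max(levels)) / 2
}

#' Robust open-pore baseline estimate
#'
#' Median-based: an analysis-filtered copy of the trace is used to locate the
#' dominant (open) level, samples within three robust standard deviations of
#' it are retained, and their median is returned. Assumes the pore is
#' unoccupied more than half of the time.
#'
#' @param trace A `nanopore_trace`.
#' @param config An [idealization_config()].
#' @return Baseline current I_P, pA (signed).
#' @export
estimate_baseline <- function(trace, config = idealization_config()) {
  stopifnot(inherits(trace, "nanopore_trace"))
  x <- trace$current
  if (!length(x)) stop("empty trace", call. = FALSE)
  if (!is.null(config$baseline_window)) {
    x <- x[seq_len(min(length(x), round(config$baseline_window * trace$sampling_rate)))]
  }
  xf <- apply_fir(x, gaussian_fir(config$analysis_filter_cutoff, trace$sampling_rate))
  med <- stats::median(xf)
  s <- stats::mad(xf)
  sel <- if (s > 0) abs(xf - med) < 3 * s else abs(xf - med) <= 0
  if (mean(sel) < 0.01) {
    stop("baseline unavailable: trace appears fully blockaded", call. = FALSE)
  }
  stats::median(xf[sel])
}

#' Idealize a trace into blockade events
#'
#' Threshold-crossing segmentation on an analysis-filtered copy of the trace.
#' The normalized current (\% of baseline, a like-signed ratio, so ~100 when
#' open) is compared against `threshold_pct`; runs below threshold are
#' candidate events. Runs (of either level) shorter than the dead time are
#' absorbed into their neighbours, shortest first, so that noise blips neither
#' create nor split events. Event features exclude a margin of three filter
#' time constants at each edge to avoid rise-time bias; events too short to
#' retain three interior samples are kept but `flagged`.
#'
#' @param trace A `nanopore_trace`.
#' @param config An [idealization_config()]. If `config$threshold_pct` is
#'   `NULL`, `levels` must be supplied.
#' @param levels Expected adduct I_res\% levels for automatic threshold
#'   placement (see [auto_threshold()]).
#' @return An `event_table`: data.frame with `start`, `duration`, `ires_pct`,
#'   `rms_noise`, `n_samples`, `flagged`; attributes `baseline`, `duration_s`,
#'   `dead_time`, `threshold_pct`, `sampling_rate`.
#' @export
idealize <- function(trace, config = idealization_config(), levels = NULL) {
  stopifnot(inherits(trace, "nanopore_trace"))
  thr <- config$threshold_pct
  if (is.null(thr)) {
    if (is.null(levels)) {
      stop("no threshold_pct in config and no expected levels supplied; ",
           "use auto_threshold()", call. = FALSE)
    }
    thr <- auto_threshold(levels)
  }
  fs <- trace$sampling_rate
  x <- trace$current
  baseline <- estimate_baseline(trace, config)
  if (!(thr > 0 && thr < 100)) stop("threshold must lie in (0, 100)", call. = FALSE)

  xf <- apply_fir(x, gaussian_fir(config$analysis_filter_cutoff, fs))
  pct <- xf / baseline * 100          # like-signed ratio: open ~ 100
  blocked <- pct < thr
  dead_n <- max(1L, round(config$dead_time * fs))

  r <- rle(blocked)
  len <- r$lengths
  val <- r$values
  # absorb sub-dead-time runs into neighbours, shortest first
  repeat {
    short <- which(len < dead_n)
    if (!length(short) || length(len) == 1L) break
    i <- short[which.min(len[short])]
    if (i == 1L) {
      val[1L] <- val[2L]
    } else if (i == length(len)) {
      val[i] <- val[i - 1L]
    } else {
      val[i] <- val[i - 1L]
    }
    # merge consecutive equal values
    keep <- c(TRUE, val[-1L] != val[-length(val)])
    len <- as.vector(tapply(len, cumsum(keep), sum))
    val <- val[keep]
  }
  ends <- cumsum(len)
  starts <- ends - len + 1L
  ev <- which(val)
  # drop blockade runs still below dead time (unmergeable edge cases)
  ev <- ev[len[ev] >= dead_n]

  margin <- max(1L, round(3 * sqrt(log(2)) / (2 * pi * config$analysis_filter_cutoff) * fs))
  n_ev <- length(ev)
  start_s <- duration_s <- ires <- rms <- numeric(n_ev)
  nsamp <- integer(n_ev)
  flagged <- logical(n_ev)
  if (n_ev) {
    cs <- cumsum(x)
    cs2 <- cumsum(x * x)
    seg_sum <- function(a, b) cs[b] - if (a > 1L) cs[a - 1L] else 0
    seg_sum2 <- function(a, b) cs2[b] - if (a > 1L) cs2[a - 1L] else 0
    for (j in seq_len(n_ev)) {
      a <- starts[ev[j]]; b <- ends[ev[j]]
      n_run <- b - a + 1L
      ai <- a + margin; bi <- b - margin
      fl <- FALSE
      if (bi - ai + 1L < 3L) { ai <- a; bi <- b; fl <- TRUE }
      m <- bi - ai + 1L
      s1 <- seg_sum(ai, bi); s2 <- seg_sum2(ai, bi)
      mu <- s1 / m
      start_s[j] <- (a - 1L) / fs
      duration_s[j] <- n_run / fs
      ires[j] <- 100 * mu / baseline
      rms[j] <- sqrt(max(0, (s2 - m * mu^2) / max(1L, m - 1L)))
      nsamp[j] <- m
      flagged[j] <- fl
    }
  }
  out <- data.frame(start = start_s, duration = duration_s, ires_pct = ires,
                    rms_noise = rms, n_samples = nsamp, flagged = flagged)
  structure(out, class = c("event_table", "data.frame"),
            baseline = baseline, duration_s = length(x) / fs,
            dead_time = config$dead_time, threshold_pct = thr,
            sampling_rate = fs)
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("Event table: %d blockade events over %.1f s (baseline %.1f pA)\n",
              nrow(x), attr(x, "duration_s") %||% NA,
              attr(x, "baseline") %||% NA))
  if (nrow(x)) {
    cat(sprintf("  mean I_res%% %.2f, mean duration %.1f ms\n",
                mean(x$ires_pct), 1000 * mean(x$duration)))
  }
  invisible(x)
}

#' Match detected events against ground-truth dwells
#'
#' Greedy one-to-one interval matching: a detected event matches a true adduct
#' dwell when their overlap covers at least `min_overlap` of the longer of the
#' two intervals. Returns confusion counts and a miss-rate stratification by
#' true dwell duration.
#'
#' @param detected An `event_table`.
#' @param truth A `dwell_seq` on the same time base.
#' @param min_overlap Minimum overlap fraction (of the longer interval).
#' @param breaks Duration strata boundaries, s.
#' @return List with `tp`, `fp`, `fn`, `recall`, `precision`, `matches`
#'   (data.frame mapping event row to dwell row) and `by_duration`
#'   (per-stratum truth counts and misses).
#' @export
match_events <- function(detected, truth, min_overlap = 0.5,
                         breaks = c(0, 0.001, 0.002, 0.005, 0.01, Inf)) {
  stopifnot(inherits(truth, "dwell_seq"))
  tr <- truth[truth$state == "adduct", , drop = FALSE]
  nd <- nrow(detected); nt <- nrow(tr)
  matched_t <- rep(FALSE, nt)
  matched_d <- rep(FALSE, nd)
  pairs <- list()
  if (nd && nt) {
    d0 <- detected$start; d1 <- detected$start + detected$duration
    t0 <- tr$start; t1 <- tr$start + tr$duration
    for (j in seq_len(nd)) {
      ov <- pmin(d1[j], t1) - pmax(d0[j], t0)
      denom <- pmax(d1[j] - d0[j], t1 - t0)
      frac <- ifelse(ov > 0, ov / denom, 0)
      frac[matched_t] <- 0
      i <- which.max(frac)
      if (frac[i] >= min_overlap) {
        matched_t[i] <- TRUE
        matched_d[j] <- TRUE
        pairs[[length(pairs) + 1L]] <- c(event = j, dwell = i)
      }
    }
  }
  strata <- cut(tr$duration, breaks, right = FALSE)
  by_dur <- data.frame(
    stratum = levels(strata),
    n_truth = as.integer(table(strata)),
    n_missed = as.integer(table(strata[!matched_t]))
  )
  list(tp = sum(matched_d), fp = sum(!matched_d), fn = sum(!matched_t),
       recall = if (nt) sum(matched_t) / nt else NA_real_,
       precision = if (nd) sum(matched_d) / nd else NA_real_,
       matches = if (length(pairs)) as.data.frame(do.call(rbind, pairs)) else
         data.frame(event = integer(0), dwell = integer(0)),
       by_duration = by_dur)
}

#' Label detected events from ground-truth dwells
#'
#' Convenience wrapper around [match_events()]: attaches the matched dwell's
#' analyte and diastereomer to each detected event (`NA` for unmatched
#' events).
#'
#' @inheritParams match_events
#' @return `detected` with `label` and `diastereomer` columns added.
#' @export
label_events <- function(detected, truth, min_overlap = 0.5) {
  m <- match_events(detected, truth, min_overlap)
  tr <- truth[truth$state == "adduct", , drop = FALSE]
  lab <- rep(NA_character_, nrow(detected))
  dia <- rep(NA_character_, nrow(detected))
  if (nrow(m$matches)) {
    lab[m$matches$event] <- tr$analyte[m$matches$dwell]
    dia[m$matches$event] <- tr$diastereomer[m$matches$dwell]
  }
  detected$label <- lab
  detected$diastereomer <- dia
  detected
}
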