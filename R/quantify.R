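# Ratiometric quantification: per-analyte event formation rates inverted
# through the calibration k_on to total concentrations (no hydration constant
# needed at this step, since k_on is defined against total aldehyde).

#' Per-analyte concentrations from a labeled event table
#'
#' For each analyte, the labeled event count over the shared open time gives
#' v_on, and `concentration = v_on / k_on`; the standard error follows by the
#' delta method from the Poisson count. Analytes present in the calibration
#' but absent from the events are reported at 0 mM with a rule-of-three upper
#' bound.
#'
#' @param events An `event_table` with a `label` column (from a classifier or
#'   ground truth).
#' @param calibration Named list of [analyte_spec()] (e.g. `fixture$analytes`)
#'   supplying `k_on_obs` per label.
#' @param duration Recording duration, s (default: table attribute).
#' @param dead_time Detection dead time, s (default: table attribute, else 0).
#' @return A data.frame of class `concentration_estimate` with columns
#'   `analyte`, `conc_mM`, `stderr_mM`, `upper95_mM`, `v_on`, `k_on`,
#'   `n_events`.
#' @export
quantify_events <- function(events, calibration, duration = NULL,
                            dead_time = NULL) {
  if (inherits(calibration, "pore_fixture")) calibration <- calibration$analytes
  stopifnot(is.list(calibration), length(calibration) >= 1L)
  if (is.null(events$label)) stop("events must be labeled", call. = FALSE)
  labs <- unique(stats::na.omit(as.character(events$label)))
  unknown <- setdiff(labs, names(calibration))
  if (length(unknown)) {
    stop("labels missing from calibration: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(names(calibration), function(nm) {
    a <- calibration[[nm]]
    von <- estimate_von(events, duration = duration, dead_time = dead_time,
                        label = nm)
    if (a$k_on_obs <= 0) stop("calibration k_on must be positive for ", nm,
                              call. = FALSE)
    data.frame(analyte = nm,
               conc_mM = von$value / a$k_on_obs,
               stderr_mM = von$stderr / a$k_on_obs,
               upper95_mM = if (is.na(von$upper95)) NA_real_ else
                 von$upper95 / a$k_on_obs,
               v_on = von$value, k_on = a$k_on_obs,
               n_events = von$n_dwells,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("concentration_estimate", "data.frame"))
}

#' Per-segment concentrations and ratios for a segmented recording
#'
#' Applies [quantify_events()] within each segment of a recording whose
#' mixture changed mid-experiment, and reports concentration ratios against a
#' reference analyte with first-order propagated uncertainty. A single
#' segment reduces exactly to [quantify_events()].
#'
#' @param segments List of segments, each `list(start = s, end = s, events =
#'   event_table)`; event times are absolute, the quantification window is
#'   `end - start`.
#' @param calibration As in [quantify_events()].
#' @param reference Analyte name used as the ratio denominator (default: first
#'   calibration entry).
#' @param dead_time Detection dead time, s.
#' @param min_events Warn when a segment holds fewer labeled events than this
#'   for some analyte.
#' @return A data.frame: one row per segment x analyte with concentration
#'   estimates, `ratio` (to the reference analyte) and `ratio_stderr`; empty
#'   segments are flagged in the `flagged` column, not dropped.
#' @export
ratio_profile <- function(segments, calibration, reference = NULL,
                          dead_time = 0, min_events = 20L) {
  if (inherits(calibration, "pore_fixture")) calibration <- calibration$analytes
  if (is.null(reference)) reference <- names(calibration)[1L]
  stopifnot(reference %in% names(calibration))
  out <- list()
  for (k in seq_along(segments)) {
    seg <- segments[[k]]
    stopifnot(!is.null(seg$start), !is.null(seg$end), seg$end > seg$start)
    ev <- seg$events
    dur <- seg$end - seg$start
    empty <- is.null(ev) || nrow(ev) == 0L
    if (empty) {
      q <- data.frame(analyte = names(calibration), conc_mM = 0,
                      stderr_mM = NA_real_, upper95_mM = NA_real_,
                      v_on = 0, k_on = vapply(calibration, `[[`, numeric(1), "k_on_obs"),
                      n_events = 0L, stringsAsFactors = FALSE)
    } else {
      q <- quantify_events(ev, calibration, duration = dur, dead_time = dead_time)
      low <- q$n_events < min_events
      if (any(low)) {
        warning(sprintf("segment %d: fewer than %d events for %s", k, min_events,
                        paste(q$analyte[low], collapse = ", ")), call. = FALSE)
      }
    }
    ref <- q[q$analyte == reference, ]
    q$ratio <- if (ref$conc_mM > 0) q$conc_mM / ref$conc_mM else NA_real_
    q$ratio_stderr <- ifelse(
      q$conc_mM > 0 & ref$conc_mM > 0,
      q$ratio * sqrt((q$stderr_mM / q$conc_mM)^2 + (ref$stderr_mM / ref$conc_mM)^2),
      NA_real_)
    q$segment <- k
    q$seg_start <- seg$start
    q$seg_end <- seg$end
    q$flagged <- empty
    out[[k]] <- q
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
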