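# Continuous-time Markov simulator for two-level covalent-sensing recordings.
# The latent process alternates between the open pore and a hemithioacetal
# adduct: association is bimolecular in free-thiol time (total rate
# sum_i k_on_i * C_i, competing exponentials decide the entering analyte),
# dissociation is unimolecular (diastereomer-specific k_off).

#' Derive a per-stage seed from a global seed
#'
#' Fixed splitting rule so that stages rerun alone reproduce their stream.
#' Values stay below 2^31.
#'
#' @param seed Integer global seed.
#' @param stage Stage name (e.g. "dwells", "noise", "split").
#' @return A derived integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 9631) %% 2147483587)
}

#' Simulation scenario
#'
#' A pore, a piecewise-constant concentration schedule (segments emulate
#' mid-experiment solution replacement), acquisition settings and a seed.
#'
#' @param pore A [pore_spec()].
#' @param segments A [mixture_spec()] with a `duration` (single-segment
#'   shorthand), or a list of `list(duration = s, mixture = mixture_spec)`.
#' @param duration Segment duration in seconds when `segments` is a single
#'   mixture.
#' @param sampling_rate Acquisition rate, Hz.
#' @param filter_cutoff Acquisition low-pass corner frequency, Hz; must be
#'   below the Nyquist rate `sampling_rate / 2`.
#' @param seed Integer seed recorded in all outputs.
#' @return An object of class `sim_scenario`.
#' @export
simulation_scenario <- function(pore, segments, duration = NULL,
                                sampling_rate = 50000, filter_cutoff = 10000,
                                seed = 1L) {
  stopifnot(inherits(pore, "pore_spec"))
  if (inherits(segments, "mixture_spec")) {
    if (is.null(duration)) {
      stop("a single-mixture scenario needs a duration", call. = FALSE)
    }
    segments <- list(list(duration = duration, mixture = segments))
  }
  stopifnot(is.list(segments), length(segments) >= 1L)
  for (s in segments) {
    if (is.null(s$duration) || s$duration <= 0 || !is.finite(s$duration)) {
      stop("segment durations must be positive and finite", call. = FALSE)
    }
    if (!inherits(s$mixture, "mixture_spec")) {
      stop("each segment needs a mixture_spec", call. = FALSE)
    }
  }
  if (sampling_rate <= 2 * filter_cutoff) {
    stop("sampling_rate must exceed 2 * filter_cutoff", call. = FALSE)
  }
  structure(
    list(pore = pore, segments = segments,
         sampling_rate = as.numeric(sampling_rate),
         filter_cutoff = as.numeric(filter_cutoff),
         seed = as.integer(seed)),
    class = "sim_scenario"
  )
}

scenario_duration <- function(scenario) {
  sum(vapply(scenario$segments, `[[`, numeric(1), "duration"))
}

# Per-(analyte, diastereomer) entry rates for one mixture: v = k_on * C * fraction.
entry_rates <- function(mixture) {
  rows <- list()
  for (nm in names(mixture$analytes)) {
    a <- mixture$analytes[[nm]]
    v_on <- a$k_on_obs * mixture$conc[[nm]]
    for (d in a$diastereomers) {
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = nm, diastereomer = d$label,
        rate = v_on * d$fraction, k_off = d$k_off, ires_pct = d$ires_pct,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Sample the latent dwell sequence
#'
#' Gillespie-style sampling of the alternating open/adduct path. From the open
#' state the waiting time is exponential with the summed association rate; the
#' entering analyte and diastereomer are chosen with probability proportional
#' to their rate contribution. Adduct dwells are exponential with the chosen
#' diastereomer's `k_off`. Segment boundaries truncate the current dwell and
#' the process continues with the new concentrations (exact, by memorylessness);
#' dwells that straddle a boundary in the same state are reported merged so the
#' sequence strictly alternates.
#'
#' @param scenario A [simulation_scenario()].
#' @return A data.frame of class `dwell_seq` with columns `state` ("open" or
#'   "adduct"), `analyte`, `diastereomer` (NA for open dwells), `start` and
#'   `duration` (seconds). Attributes: `seed`, `duration_s`.
#' @export
sample_dwells <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  total <- scenario_duration(scenario)
  seg_rates <- lapply(scenario$segments, function(s) entry_rates(s$mixture))
  if (all(vapply(seg_rates, function(r) is.null(r) || sum(r$rate) == 0, logical(1))) &&
      !is.finite(total)) {
    stop("all association rates are zero over an infinite duration", call. = FALSE)
  }
  set.seed(derive_seed(scenario$seed, "dwells"))

  state <- character(0); analyte <- character(0); dia <- character(0)
  start <- numeric(0); dur <- numeric(0)
  t <- 0
  cur_state <- "open"          # pores start unoccupied
  cur_analyte <- NA_character_; cur_dia <- NA_character_
  cur_koff <- NA_real_
  seg_end <- cumsum(vapply(scenario$segments, `[[`, numeric(1), "duration"))
  seg_start <- c(0, seg_end[-length(seg_end)])

  emit <- function(st, an, di, s0, d) {
    n <- length(state)
    # merge with previous dwell if same state crossed a segment boundary
    if (n > 0 && state[n] == st &&
        ((st == "open") || (identical(analyte[n], an) && identical(dia[n], di)))) {
      dur[n] <<- dur[n] + d
    } else {
      state[n + 1L] <<- st; analyte[n + 1L] <<- an; dia[n + 1L] <<- di
      start[n + 1L] <<- s0; dur[n + 1L] <<- d
    }
  }

  for (k in seq_along(scenario$segments)) {
    rates <- seg_rates[[k]]
    tot_rate <- if (is.null(rates)) 0 else sum(rates$rate)
    t_end <- seg_end[k]
    while (t < t_end - 1e-12) {
      if (cur_state == "open") {
        w <- if (tot_rate > 0) stats::rexp(1L, tot_rate) else Inf
        if (t + w >= t_end) {
          emit("open", NA_character_, NA_character_, t, t_end - t)
          t <- t_end
        } else {
          emit("open", NA_character_, NA_character_, t, w)
          t <- t + w
          i <- sample.int(nrow(rates), 1L, prob = rates$rate)
          cur_state <- "adduct"
          cur_analyte <- rates$analyte[i]
          cur_dia <- rates$diastereomer[i]
          cur_koff <- rates$k_off[i]
        }
      } else {
        w <- stats::rexp(1L, cur_koff)
        if (t + w >= t_end) {
          emit("adduct", cur_analyte, cur_dia, t, t_end - t)
          t <- t_end
        } else {
          emit("adduct", cur_analyte, cur_dia, t, w)
          t <- t + w
          cur_state <- "open"
        }
      }
    }
    t <- t_end
  }
  out <- data.frame(state = state, analyte = analyte, diastereomer = dia,
                    start = start, duration = dur, stringsAsFactors = FALSE)
  structure(out, class = c("dwell_seq", "data.frame"),
            seed = scenario$seed, duration_s = total)
}

# Normalized Gaussian FIR kernel approximating a Bessel low-pass: the -3 dB
# point of exp(-(2*pi*f*sigma_t)^2/2) gives sigma_t = sqrt(log(2))/(2*pi*fc).
gaussian_fir <- function(cutoff, sampling_rate) {
  sigma <- sqrt(log(2)) / (2 * pi * cutoff) * sampling_rate
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

# Zero-phase FIR smoothing with edge padding (no NA ends).
apply_fir <- function(x, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0L || length(x) == 0L) return(x)
  xp <- c(rep(x[1L], r), x, rep(x[length(x)], r))
  y <- stats::filter(xp, kernel, method = "convolution", sides = 2L)
  as.numeric(y[(r + 1L):(r + length(x))])
}

#' Render a dwell sequence to a sampled current trace
#'
#' Open dwells are rendered at the open-pore current I_P and adduct dwells at
#' `ires_pct/100 * I_P`. Level transitions are smoothed by a linear-phase
#' Gaussian FIR approximating the acquisition Bessel filter; white Gaussian
#' noise with standard deviation `pore$rms_noise` is added per sample after
#' filtering. Deterministic given the scenario seed.
#'
#' @param dwells A `dwell_seq` from [sample_dwells()].
#' @param scenario The [simulation_scenario()] that produced it.
#' @return An object of class `nanopore_trace`: list with `current` (pA),
#'   `sampling_rate`, `potential`, `seed`.
#' @export
render_trace <- function(dwells, scenario) {
  stopifnot(inherits(dwells, "dwell_seq"), inherits(scenario, "sim_scenario"))
  fs <- scenario$sampling_rate
  pore <- scenario$pore
  total <- attr(dwells, "duration_s")
  n_total <- round(total * fs)

  level_of <- function(i) {
    if (dwells$state[i] == "open") return(pore$open_current)
    a <- NULL
    for (s in scenario$segments) {
      a <- s$mixture$analytes[[dwells$analyte[i]]]
      if (!is.null(a)) break
    }
    if (is.null(a)) stop("dwell analyte not present in scenario mixtures")
    for (d in a$diastereomers) {
      if (d$label == dwells$diastereomer[i]) return(d$ires_pct / 100 * pore$open_current)
    }
    stop("dwell diastereomer not present in analyte spec")
  }
  levels_pA <- vapply(seq_len(nrow(dwells)), level_of, numeric(1))
  ends <- round((dwells$start + dwells$duration) * fs)
  ends[length(ends)] <- n_total
  counts <- diff(c(0L, ends))
  keep <- counts > 0
  x <- rep(levels_pA[keep], counts[keep])

  x <- apply_fir(x, gaussian_fir(scenario$filter_cutoff, fs))
  if (pore$rms_noise > 0) {
    set.seed(derive_seed(scenario$seed, "noise"))
    x <- x + stats::rnorm(length(x), 0, pore$rms_noise)
  }
  structure(list(current = x, sampling_rate = fs, potential = pore$potential,
                 seed = scenario$seed),
            class = "nanopore_trace")
}

#' @export
print.nanopore_trace <- function(x, ...) {
  cat(sprintf("Single-channel trace: %d samples at %g kHz (%.1f s), %g mV, seed %d\n",
              length(x$current), x$sampling_rate / 1000,
              length(x$current) / x$sampling_rate, x$potential, x$seed))
  invisible(x)
}

#' Simulate a recording (dwells + trace)
#'
#' @param scenario A [simulation_scenario()].
#' @return List with `dwells` and `trace`.
#' @export
simulate_trace <- function(scenario) {
  dwells <- sample_dwells(scenario)
  list(dwells = dwells, trace = render_trace(dwells, scenario))
}

#' Synthesize a labeled event set directly from fixture parameters
#'
#' Generates per-event classification features without rendering full traces,
#' by sampling from the same statistical model that the simulate-and-idealize
#' path induces: durations are dead-time-truncated exponentials of the
#' diastereomer `k_off`; the event-mean residual current is the level plus a
#' Gaussian error with standard deviation `rms / (|I_P|/100) / sqrt(n)` for an
#' n-sample event (noise is white at the sampling rate); the within-event RMS
#' is a chi-distributed estimate of the baseline RMS. Events are labeled by
#' analyte; two-form analytes contribute both diastereomers at their fractions.
#'
#' @param fixture A `pore_fixture` (or list of [analyte_spec()] plus `pore`).
#' @param analytes Analyte names to include (default: all in the fixture).
#' @param n_per_class Events per analyte.
#' @param dead_time Detection dead time, s.
#' @param sampling_rate Hz.
#' @param seed Integer seed.
#' @return A data.frame with columns `ires_pct`, `duration`, `rms_noise`,
#'   `label`, `diastereomer`.
#' @export
simulate_labeled_events <- function(fixture, analytes = NULL, n_per_class = 1000,
                                    dead_time = 5e-4, sampling_rate = 50000,
                                    seed = 1L) {
  stopifnot(inherits(fixture, "pore_fixture"))
  specs <- fixture$analytes
  if (!is.null(analytes)) specs <- specs[analytes]
  stopifnot(length(specs) >= 1L, !anyNA(names(specs)))
  pore <- fixture$pore
  rms_pct <- pore$rms_noise / abs(pore$open_current) * 100
  set.seed(derive_seed(seed, "events"))
  out <- vector("list", length(specs))
  for (j in seq_along(specs)) {
    a <- specs[[j]]
    fr <- vapply(a$diastereomers, `[[`, numeric(1), "fraction")
    pick <- sample.int(length(fr), n_per_class, replace = TRUE, prob = fr)
    koff <- vapply(a$diastereomers, `[[`, numeric(1), "k_off")[pick]
    lev <- vapply(a$diastereomers, `[[`, numeric(1), "ires_pct")[pick]
    lab <- vapply(a$diastereomers, `[[`, character(1), "label")[pick]
    # survival beyond the dead time + memorylessness => shifted exponential
    dur <- dead_time + stats::rexp(n_per_class, koff)
    n <- pmax(3, round(dur * sampling_rate))
    ires <- lev + stats::rnorm(n_per_class, 0, rms_pct / sqrt(n))
    rms <- pore$rms_noise * sqrt(stats::rchisq(n_per_class, n - 1) / (n - 1))
    out[[j]] <- data.frame(ires_pct = ires, duration = dur, rms_noise = rms,
                           label = a$name, diastereomer = lab,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
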