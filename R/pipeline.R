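# Orchestration: a config-driven pipeline chaining simulate -> detect ->
# fit -> classify -> quantify, with per-stage seeds derived from one global
# seed and a manifest recording digests of every artifact.

#' Run the analysis pipeline
#'
#' Executes the requested stages in order against a scenario built from a
#' packaged fixture. Stage outputs are written as plain-text artifacts under
#' `out_dir` (dwells/events as TSV, rates and concentrations as JSON, the
#' trace as CSV only when `write_trace: true`), and a run manifest with file
#' digests is returned and written as JSON.
#'
#' Config fields (R list or YAML file): `seed`; `fixture` (name or path);
#' `analytes` (named list/vector of concentrations, mM); `duration` (s);
#' optional `segments` (list of `{duration, analytes}` overriding the two
#' previous fields); `stages` (subset of simulate, detect, fit, classify,
#' quantify; default all); `detection` (optional overrides for
#' [idealization_config()]); `classifier` ("gaussian" or "forest");
#' `write_trace` (logical).
#'
#' @param config Path to a YAML config or an R list.
#' @param out_dir Output directory (created if missing).
#' @return The run manifest (list), invisibly. Artifacts on disk.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  for (field in c("seed", "fixture")) {
    if (is.null(config[[field]])) {
      stop("config is missing required field '", field, "'", call. = FALSE)
    }
  }
  stages <- config$stages %||% c("simulate", "detect", "fit", "classify", "quantify")
  bad <- setdiff(stages, c("simulate", "detect", "fit", "classify", "quantify"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fixture <- load_pore_fixture(config$fixture)
  seed <- as.integer(config$seed)
  t0 <- Sys.time()
  artifacts <- character(0)
  log_stage <- function(...) message(sprintf("[porevoc] %s", sprintf(...)))

  mk_mixture <- function(an) {
    conc <- unlist(an)
    miss <- setdiff(names(conc), names(fixture$analytes))
    if (length(miss)) stop("analyte(s) not in fixture: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    mixture_spec(unname(fixture$analytes[names(conc)]), unname(conc))
  }
  segments <- if (!is.null(config$segments)) {
    lapply(config$segments, function(s) {
      list(duration = s$duration, mixture = mk_mixture(s$analytes))
    })
  } else {
    if (is.null(config$analytes) || is.null(config$duration)) {
      stop("config needs either 'segments' or both 'analytes' and 'duration'",
           call. = FALSE)
    }
    list(list(duration = config$duration, mixture = mk_mixture(config$analytes)))
  }
  scenario <- simulation_scenario(fixture$pore, segments, seed = seed)
  scenario_names <- unique(unlist(lapply(segments, function(s) names(s$mixture$analytes))))

  dwells <- NULL; events <- NULL; trace <- NULL

  if ("simulate" %in% stages) {
    log_stage("simulate: %d segment(s), %.0f s total, seed %d",
              length(segments), scenario_duration(scenario), seed)
    sim <- simulate_trace(scenario)
    dwells <- sim$dwells
    trace <- sim$trace
    write_dwells(dwells, file.path(out_dir, "dwells.tsv"))
    artifacts <- c(artifacts, "dwells.tsv")
    if (isTRUE(config$write_trace)) {
      write_trace(trace, file.path(out_dir, "trace.csv"))
      artifacts <- c(artifacts, "trace.csv")
    }
  }

  if ("detect" %in% stages) {
    if (is.null(trace)) {
      tp <- file.path(out_dir, "trace.csv")
      if (!file.exists(tp)) {
        stop("stage 'detect': no trace in memory and no trace.csv in ", out_dir,
             call. = FALSE)
      }
      trace <- read_trace(tp)
    }
    det <- config$detection %||% list()
    cfg <- idealization_config(
      analysis_filter_cutoff = det$analysis_filter_cutoff %||% 1000,
      threshold_pct = det$threshold_pct,
      dead_time = det$dead_time %||% 5e-4)
    events <- idealize(trace, cfg, levels = fixture_levels(fixture, scenario_names))
    log_stage("detect: %d events, baseline %.1f pA", nrow(events),
              attr(events, "baseline"))
  }

  if ("classify" %in% stages && !is.null(events) && nrow(events) > 0) {
    if (length(scenario_names) >= 2L) {
      ref <- simulate_labeled_events(
        fixture, analytes = scenario_names,
        n_per_class = config$n_reference_events %||% 500L,
        dead_time = attr(events, "dead_time"),
        sampling_rate = scenario$sampling_rate,
        seed = derive_seed(seed, "reference"))
      model <- train_event_classifier(ref, config$classifier %||% "gaussian",
                                      seed = seed)
      events$label <- predict(model, events)
      log_stage("classify: %s model over {%s}", model$kind,
                paste(model$classes, collapse = ", "))
    } else {
      events$label <- scenario_names
      log_stage("classify: single analyte, labels assigned directly")
    }
  }

  if (!is.null(events)) {
    write_events(events, file.path(out_dir, "events.tsv"))
    artifacts <- c(artifacts, "events.tsv")
  }

  if ("fit" %in% stages) {
    if (is.null(events)) {
      stop("stage 'fit': no event table (run 'detect' first or supply events.tsv)",
           call. = FALSE)
    }
    per_label <- !is.null(events$label) && length(unique(events$label)) > 1L
    koff <- estimate_koff(events, per_label = per_label)
    von <- estimate_von(events)
    rates <- list(
      v_on = list(value = von$value, stderr = von$stderr, unit = von$unit,
                  n = von$n_dwells),
      k_off = if (per_label) {
        lapply(koff, function(e) list(value = e$value, stderr = e$stderr,
                                      unit = e$unit, n = e$n_dwells))
      } else {
        list(value = koff$value, stderr = koff$stderr, unit = koff$unit,
             n = koff$n_dwells)
      },
      dead_time_s = attr(events, "dead_time"))
    jsonlite::write_json(rates, file.path(out_dir, "rates.json"),
                         auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, "rates.json")
    log_stage("fit: v_on %.3g s^-1 over %d events", von$value, von$n_dwells)
  }

  if ("quantify" %in% stages) {
    if (is.null(events) || is.null(events$label)) {
      stop("stage 'quantify': labeled events required (run 'classify' or ",
           "provide labels)", call. = FALSE)
    }
    qt <- quantify_events(events, fixture$analytes[scenario_names])
    jsonlite::write_json(
      stats::setNames(lapply(seq_len(nrow(qt)), function(i) {
        list(conc_mM = qt$conc_mM[i], stderr_mM = qt$stderr_mM[i],
             n_events = qt$n_events[i])
      }), qt$analyte),
      file.path(out_dir, "concentrations.json"), auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, "concentrations.json")
    log_stage("quantify: %s", paste(sprintf("%s %.3g mM", qt$analyte, qt$conc_mM),
                                    collapse = ", "))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("porevoc")),
    seed = seed,
    stage_seeds = list(dwells = derive_seed(seed, "dwells"),
                       noise = derive_seed(seed, "noise"),
                       reference = derive_seed(seed, "reference")),
    stages = stages,
    fixture = fixture$pore$name,
    config_digest = digest_of(config),
    artifacts = lapply(stats::setNames(artifacts, artifacts), function(f) {
      list(md5 = unname(tools::md5sum(file.path(out_dir, f))))
    }),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# md5 of the canonical JSON serialization of a config list
digest_of <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
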