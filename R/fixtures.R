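# Packaged parameter sets for the engineered nanopore variants. Each fixture
# YAML carries a provenance flag per number: "printed" (published value),
# "interpolated" (filled in by the ~0.7%/CH2 level rule or a smooth trend),
# or "derived" (computed from a published quantity).

#' List packaged nanopore fixtures
#'
#' @return Character vector of fixture names accepted by [load_pore_fixture()].
#' @export
pore_fixtures <- function() {
  files <- list.files(system.file("extdata", "fixtures", package = "porevoc"),
                      pattern = "\\.yaml$")
  sub("\\.yaml$", "", files)
}

#' Load a nanopore/analyte parameter fixture
#'
#' Reads a structured YAML parameter file describing one nanopore variant and
#' the aldehydes characterised with it, and validates it into package objects.
#' Packaged fixtures: `"ag_t115c"` (the reference (AG)6(AG-T115C) sensor with
#' all ten analytes), `"mk_t115c"`, `"ag_g137c"` and `"ag_g137c_ala3"` (the
#' engineered variants with enhanced diastereomer resolution).
#'
#' @param name Fixture name (see [pore_fixtures()]) or path to a YAML file.
#' @return A list of class `pore_fixture` with elements `pore` ([pore_spec()]),
#'   `analytes` (named list of [analyte_spec()]), `typical_conc` (named mM
#'   vector, `NA` where the fixture states none) and `provenance` (nested list
#'   of per-value provenance flags).
#' @export
load_pore_fixture <- function(name) {
  path <- if (file.exists(name)) {
    name
  } else {
    system.file("extdata", "fixtures", paste0(name, ".yaml"), package = "porevoc")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown fixture \"", name, "\"; available: ",
         paste(pore_fixtures(), collapse = ", "), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$pore) || is.null(raw$analytes)) {
    stop("fixture file must contain 'pore' and 'analytes' sections", call. = FALSE)
  }
  pore <- pore_spec(raw$pore$name, raw$pore$open_current_pA,
                    potential = raw$pore$potential_mV,
                    rms_noise = raw$pore$rms_noise_pA)
  analytes <- list()
  typical <- numeric(0)
  prov <- list(pore = raw$pore$provenance)
  for (a in raw$analytes) {
    dia <- lapply(a$diastereomers, function(d) {
      diastereomer_spec(d$label, d$ires_pct, d$k_off, d$fraction)
    })
    analytes[[a$name]] <- analyte_spec(a$name, a$khyd, a$k_on_obs, dia)
    typical[[a$name]] <- if (is.null(a$typical_conc_mM)) NA_real_ else a$typical_conc_mM
    prov$analytes[[a$name]] <- list(
      analyte = a$provenance,
      diastereomers = lapply(a$diastereomers, `[[`, "provenance")
    )
  }
  structure(list(pore = pore, analytes = analytes,
                 typical_conc = typical, provenance = prov),
            class = "pore_fixture")
}

#' @export
print.pore_fixture <- function(x, ...) {
  cat("Nanopore fixture:", x$pore$name, "\n")
  cat(sprintf("  I_P = %.1f pA at %.0f mV, baseline RMS %.2g pA\n",
              x$pore$open_current, x$pore$potential, x$pore$rms_noise))
  cat("  analytes:", paste(names(x$analytes), collapse = ", "), "\n")
  invisible(x)
}

#' Residual-current levels of a fixture
#'
#' @param fixture A `pore_fixture`.
#' @param analytes Optional subset of analyte names.
#' @return Named numeric vector of I_res\% levels, one entry per diastereomer,
#'   named `analyte` or `analyte/label` for two-form analytes.
#' @export
fixture_levels <- function(fixture, analytes = NULL) {
  stopifnot(inherits(fixture, "pore_fixture"))
  specs <- fixture$analytes
  if (!is.null(analytes)) {
    missing <- setdiff(analytes, names(specs))
    if (length(missing)) {
      stop("not in fixture: ", paste(missing, collapse = ", "), call. = FALSE)
    }
    specs <- specs[analytes]
  }
  out <- numeric(0)
  for (a in specs) {
    for (d in a$diastereomers) {
      nm <- if (length(a$diastereomers) > 1L) paste0(a$name, "/", d$label) else a$name
      out[[nm]] <- d$ires_pct
    }
  }
  out
}
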