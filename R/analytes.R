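# Chemical/kinetic data model for reversible thiol-aldehyde covalent sensing.
# Concentrations are mM throughout; association rate constants mM^-1 s^-1;
# dissociation rate constants s^-1; currents pA (signed); residual currents
# as positive percentages of the open-pore current.

#' Diastereomer specification
#'
#' One stereochemical form of a hemithioacetal adduct: its residual-current
#' level, dissociation rate constant and branching fraction. When an analyte
#' resolves into two diastereomers, form "A" carries the larger I_res\% by
#' convention.
#'
#' @param label "A" or "B".
#' @param ires_pct Residual current during the blockade as a percentage of the
#'   open-pore current (0 < ires_pct <= 100). Computed from like-signed
#'   currents, so positive regardless of the sign convention of the recording.
#' @param k_off Dissociation (adduct breakdown) rate constant, s^-1.
#' @param fraction Probability that a formation event yields this form.
#' @return An object of class `diastereomer_spec`.
#' @export
diastereomer_spec <- function(label, ires_pct, k_off, fraction = 1) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!label %in% c("A", "B")) {
    stop("diastereomer label must be \"A\" or \"B\"", call. = FALSE)
  }
  if (!is.numeric(ires_pct) || length(ires_pct) != 1L || ires_pct <= 0 || ires_pct > 100) {
    stop("ires_pct must be a single value in (0, 100]", call. = FALSE)
  }
  if (!is.numeric(k_off) || length(k_off) != 1L || k_off <= 0) {
    stop("k_off must be a single positive rate (s^-1)", call. = FALSE)
  }
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction < 0 || fraction > 1) {
    stop("fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(label = label, ires_pct = as.numeric(ires_pct),
         k_off = as.numeric(k_off), fraction = as.numeric(fraction)),
    class = "diastereomer_spec"
  )
}

#' Analyte specification
#'
#' An aldehyde species as seen by the sensor: its hydration equilibrium
#' constant, the observed association rate constant against *total* aldehyde
#' concentration, and one or two diastereomeric adduct forms.
#'
#' @param name Analyte name (unique within a mixture).
#' @param khyd Hydration equilibrium constant K_hyd, the hydrate to
#'   free-aldehyde concentration ratio (dimensionless, >= 0). Hydrates are
#'   thiol-unreactive.
#' @param k_on_obs Observed association rate constant k_on in mM^-1 s^-1,
#'   defined against total aldehyde concentration.
#' @param diastereomers A `diastereomer_spec` or list of one or two of them.
#'   Fractions must sum to 1; if two forms are given, A must carry the larger
#'   residual-current level.
#' @return An object of class `analyte_spec`.
#' @export
analyte_spec <- function(name, khyd, k_on_obs, diastereomers) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(khyd) || length(khyd) != 1L || khyd < 0) {
    stop("khyd must be a single value >= 0", call. = FALSE)
  }
  if (!is.numeric(k_on_obs) || length(k_on_obs) != 1L || k_on_obs < 0) {
    stop("k_on_obs must be a single value >= 0 (mM^-1 s^-1)", call. = FALSE)
  }
  if (inherits(diastereomers, "diastereomer_spec")) diastereomers <- list(diastereomers)
  if (!is.list(diastereomers) || length(diastereomers) < 1L || length(diastereomers) > 2L ||
      !all(vapply(diastereomers, inherits, logical(1), "diastereomer_spec"))) {
    stop("diastereomers must be one or two diastereomer_spec objects", call. = FALSE)
  }
  fr <- vapply(diastereomers, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-8) {
    stop("diastereomer fractions must sum to 1 (got ", sum(fr), ")", call. = FALSE)
  }
  if (length(diastereomers) == 2L) {
    labs <- vapply(diastereomers, `[[`, character(1), "label")
    if (anyDuplicated(labs)) stop("diastereomer labels must differ", call. = FALSE)
    a <- diastereomers[[match("A", labs)]]
    b <- diastereomers[[match("B", labs)]]
    if (a$ires_pct < b$ires_pct) {
      stop("diastereomer A must have the larger ires_pct (field convention)",
           call. = FALSE)
    }
    diastereomers <- list(a, b)
  }
  structure(
    list(name = name, khyd = as.numeric(khyd), k_on_obs = as.numeric(k_on_obs),
         diastereomers = diastereomers),
    class = "analyte_spec"
  )
}

#' Nanopore specification
#'
#' @param name Pore identifier, e.g. the heteroheptamer name.
#' @param open_current Open-pore current I_P in pA (signed; nonzero).
#' @param potential Applied transmembrane potential, mV (signed).
#' @param rms_noise Baseline RMS current noise after the acquisition filter, pA.
#' @return An object of class `pore_spec`.
#' @export
pore_spec <- function(name, open_current, potential = -50, rms_noise = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(open_current) || length(open_current) != 1L || open_current == 0) {
    stop("open_current must be a single nonzero current (pA)", call. = FALSE)
  }
  if (!is.numeric(rms_noise) || length(rms_noise) != 1L || rms_noise < 0) {
    stop("rms_noise must be >= 0 (pA)", call. = FALSE)
  }
  structure(
    list(name = name, open_current = as.numeric(open_current),
         potential = as.numeric(potential), rms_noise = as.numeric(rms_noise)),
    class = "pore_spec"
  )
}

#' Mixture specification
#'
#' Analytes at total concentrations, optionally alongside alcohols that are
#' invisible to the sensor until enzymatic oxidation converts them to their
#' target aldehydes (see [apply_oxidation()]).
#'
#' @param analytes List of [analyte_spec()] objects.
#' @param conc Numeric vector of total concentrations (mM), one per analyte.
#' @param alcohols Optional list of alcohol placeholders, each a list with
#'   elements `name` (alcohol name), `target` (an `analyte_spec` for the
#'   aldehyde it oxidises to, or NULL if unknown) and `conc` (mM).
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(analytes, conc, alcohols = NULL) {
  if (inherits(analytes, "analyte_spec")) analytes <- list(analytes)
  stopifnot(is.list(analytes),
            all(vapply(analytes, inherits, logical(1), "analyte_spec")))
  conc <- as.numeric(conc)
  if (length(conc) != length(analytes)) {
    stop("one concentration per analyte required", call. = FALSE)
  }
  if (any(conc < 0) || anyNA(conc)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  nm <- vapply(analytes, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("analyte names must be unique", call. = FALSE)
  names(analytes) <- nm
  names(conc) <- nm
  if (!is.null(alcohols)) {
    stopifnot(is.list(alcohols))
    for (al in alcohols) {
      stopifnot(is.list(al), !is.null(al$name), !is.null(al$conc))
      if (al$conc < 0) stop("alcohol concentrations must be >= 0", call. = FALSE)
    }
  }
  structure(list(analytes = analytes, conc = conc, alcohols = alcohols),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat("Analyte mixture:", length(x$analytes), "aldehyde(s)\n")
  for (nm in names(x$analytes)) {
    cat(sprintf("  %-18s %.3g mM\n", nm, x$conc[[nm]]))
  }
  if (length(x$alcohols)) {
    cat(" ", length(x$alcohols), "unconverted alcohol(s):\n")
    for (al in x$alcohols) {
      tgt <- if (is.null(al$target)) "?" else al$target$name
      cat(sprintf("  %-18s %.3g mM -> %s\n", al$name, al$conc, tgt))
    }
  }
  invisible(x)
}

#' @export
print.analyte_spec <- function(x, ...) {
  cat(sprintf("Analyte %s: K_hyd = %.3g, k_on = %.3g mM^-1 s^-1\n",
              x$name, x$khyd, x$k_on_obs))
  for (d in x$diastereomers) {
    cat(sprintf("  diastereomer %s: I_res%% = %.2f, k_off = %.3g s^-1, fraction = %.2f\n",
                d$label, d$ires_pct, d$k_off, d$fraction))
  }
  invisible(x)
}

#' Free (unhydrated) aldehyde concentration
#'
#' Aldehydes partition between free and hydrated (gem-diol) forms in water;
#' only the free form reacts with the pore thiol. Given the hydration
#' equilibrium constant K_hyd (hydrate over free), the free concentration is
#' total / (1 + K_hyd).
#'
#' @param analyte An [analyte_spec()].
#' @param total_conc Total aldehyde concentration, mM (>= 0).
#' @return Free aldehyde concentration, mM.
#' @export
free_fraction <- function(analyte, total_conc) {
  stopifnot(inherits(analyte, "analyte_spec"))
  if (!is.numeric(total_conc) || any(total_conc < 0) || anyNA(total_conc)) {
    stop("total_conc must be >= 0", call. = FALSE)
  }
  total_conc / (1 + analyte$khyd)
}

#' Hydration-corrected association rate constant
#'
#' Converts the observed association rate constant (defined against total
#' aldehyde) into the rate constant against free aldehyde:
#' k_on' = k_on * (1 + K_hyd).
#'
#' @param k_on_obs Observed rate constant, mM^-1 s^-1 (>= 0).
#' @param khyd Hydration equilibrium constant (>= 0).
#' @return Corrected rate constant k_on', mM^-1 s^-1.
#' @export
correct_kon <- function(k_on_obs, khyd) {
  if (!is.numeric(k_on_obs) || any(k_on_obs < 0) || anyNA(k_on_obs)) {
    stop("k_on_obs must be >= 0", call. = FALSE)
  }
  if (!is.numeric(khyd) || any(khyd < 0) || anyNA(khyd)) {
    stop("khyd must be >= 0", call. = FALSE)
  }
  k_on_obs * (1 + khyd)
}

#' Hydration constant from NMR peak integrals
#'
#' K_hyd is the ratio of the hydrate to the free-aldehyde 1H NMR integrals
#' recorded under sensing buffer conditions.
#'
#' @param integral_ald Integral of the free-aldehyde resonance (> 0).
#' @param integral_hyd Integral of the hydrate resonance (>= 0).
#' @return K_hyd, dimensionless.
#' @export
khyd_from_nmr <- function(integral_ald, integral_hyd) {
  if (!is.numeric(integral_ald) || length(integral_ald) != 1L || integral_ald <= 0) {
    stop("integral_ald must be a single value > 0 (zero free-aldehyde integral leaves K_hyd undefined)",
         call. = FALSE)
  }
  if (!is.numeric(integral_hyd) || length(integral_hyd) != 1L || integral_hyd < 0) {
    stop("integral_hyd must be >= 0", call. = FALSE)
  }
  integral_hyd / integral_ald
}

#' Expected adduct formation rate
#'
#' The event formation rate at a given total concentration,
#' v_on = k_on * C_tot, equivalently k_on' * C_free.
#'
#' @inheritParams free_fraction
#' @return v_on in s^-1.
#' @export
expected_on_rate <- function(analyte, total_conc) {
  stopifnot(inherits(analyte, "analyte_spec"))
  if (!is.numeric(total_conc) || any(total_conc < 0) || anyNA(total_conc)) {
    stop("total_conc must be >= 0", call. = FALSE)
  }
  analyte$k_on_obs * total_conc
}

#' Mean adduct lifetime
#'
#' The mean duration of a blockade for an analyte whose formation events
#' branch into diastereomers with distinct dissociation rates:
#' sum_d fraction_d / k_off_d.
#'
#' @param analyte An [analyte_spec()].
#' @return Mean lifetime, s.
#' @export
mean_adduct_lifetime <- function(analyte) {
  stopifnot(inherits(analyte, "analyte_spec"))
  sum(vapply(analyte$diastereomers,
             function(d) d$fraction / d$k_off, numeric(1)))
}

#' Enzymatic oxidation of alcohols to aldehydes
#'
#' Models treatment with an alcohol oxidase: each alcohol placeholder in the
#' mixture is converted quantitatively to its target aldehyde at unchanged
#' concentration. Existing aldehyde components are untouched; converted
#' amounts add to any pre-existing component of the same aldehyde.
#'
#' @param mixture A [mixture_spec()].
#' @return A `mixture_spec` with no remaining alcohols.
#' @export
apply_oxidation <- function(mixture) {
  stopifnot(inherits(mixture, "mixture_spec"))
  if (!length(mixture$alcohols)) return(mixture)
  analytes <- mixture$analytes
  conc <- mixture$conc
  for (al in mixture$alcohols) {
    if (is.null(al$target) || !inherits(al$target, "analyte_spec")) {
      stop("alcohol \"", al$name, "\" has no target analyte_spec; ",
           "cannot model its oxidation", call. = FALSE)
    }
    tnm <- al$target$name
    if (tnm %in% names(analytes)) {
      conc[[tnm]] <- conc[[tnm]] + al$conc
    } else {
      analytes[[tnm]] <- al$target
      conc <- c(conc, stats::setNames(al$conc, tnm))
    }
  }
  mixture_spec(unname(analytes), unname(conc), alcohols = NULL)
}
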