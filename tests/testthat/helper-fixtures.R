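# Shared builders and independent oracles for the test suite.

# Minimal single-level analyte.
toy_analyte <- function(name = "toy", khyd = 0, k_on = 0.5, k_off = 8,
                        ires = 97) {
  analyte_spec(name, khyd, k_on, diastereomer_spec("A", ires, k_off))
}

toy_pore <- function(rms = 1) pore_spec("toy-pore", -129, -50, rms)

# Single-analyte scenario shorthand.
toy_scenario <- function(analyte, conc, duration, seed = 1L, rms = 1,
                         sampling_rate = 50000, filter_cutoff = 10000) {
  simulation_scenario(toy_pore(rms), mixture_spec(analyte, conc),
                      duration = duration, sampling_rate = sampling_rate,
                      filter_cutoff = filter_cutoff, seed = seed)
}

# Build an event table straight from the latent adduct dwells (perfect
# detection), for estimator tests that do not exercise the trace path.
events_from_dwells <- function(dwells, ires = NA_real_, rms = NA_real_) {
  ad <- dwells[dwells$state == "adduct", , drop = FALSE]
  out <- data.frame(start = ad$start, duration = ad$duration,
                    ires_pct = ires, rms_noise = rms,
                    label = ad$analyte, diastereomer = ad$diastereomer,
                    stringsAsFactors = FALSE)
  structure(out, class = c("event_table", "data.frame"),
            duration_s = attr(dwells, "duration_s"), dead_time = 0)
}

# Independent two-clock oracle for the competing-exponentials step: each
# analyte runs its own exponential clock; the earliest fires.
two_clock_open_dwells <- function(rates, n) {
  draws <- matrix(stats::rexp(n * length(rates), rate = rep(rates, each = n)),
                  nrow = n)
  list(wait = apply(draws, 1, min),
       winner = apply(draws, 1, which.min))
}

# Brute-force per-class gaussian posterior oracle (equal priors), written
# independently of the classifier: densities via solve() and det().
brute_force_gaussian_predict <- function(train, test) {
  feat <- function(d) cbind(d$ires_pct, log(d$duration), log(d$rms_noise))
  classes <- sort(unique(train$label))
  Xtr <- feat(train); Xte <- feat(test)
  scores <- sapply(classes, function(cl) {
    Xi <- Xtr[train$label == cl, , drop = FALSE]
    mu <- colMeans(Xi)
    S <- stats::cov(Xi)
    Sinv <- solve(S)
    cst <- -0.5 * log(det(S))
    apply(Xte, 1, function(x) {
      d <- x - mu
      cst - 0.5 * drop(t(d) %*% Sinv %*% d)
    })
  })
  classes[apply(matrix(scores, nrow = nrow(Xte)), 1, which.max)]
}

ag_fixture <- function() load_pore_fixture("ag_t115c")

# Canonical seeded scenario for the Kolmogorov-Smirnov dwell-distribution
# property (n = 5000 adduct dwells at alpha = 0.01), shared by the simulator
# unit test and the acceptance property block.
ks_dwell_pvalues <- function(seed = 17) {
  a <- toy_analyte(k_on = 0.31, k_off = 7.69)
  von <- expected_on_rate(a, 100)
  need <- 5000 * (1 / von + 1 / 7.69) * 1.1
  dw <- sample_dwells(toy_scenario(a, 100, duration = need, seed = seed))
  open <- dw$duration[dw$state == "open"]; open <- open[-c(1L, length(open))]
  add <- dw$duration[dw$state == "adduct"]; add <- add[-c(1L, length(add))]
  list(open = open, adduct = add, von = von,
       p_open = suppressWarnings(stats::ks.test(open, "pexp", von))$p.value,
       p_adduct = suppressWarnings(stats::ks.test(add, "pexp", 7.69))$p.value)
}

straight_chain <- c("ethanal", "propanal", "butanal", "pentanal",
                    "hexanal", "heptanal", "octanal")
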