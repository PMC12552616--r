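# Idealization: baseline estimation, threshold segmentation, feature
# extraction and truth matching.

noiseless_trace_with_dwell <- function(dwell_ms = 50, ires = 97) {
  a <- toy_analyte(ires = ires)
  fs <- 50000
  # hand-built dwell sequence: open 1 s, adduct, open to 3 s
  d <- dwell_ms / 1000
  dw <- structure(
    data.frame(state = c("open", "adduct", "open"),
               analyte = c(NA, "toy", NA), diastereomer = c(NA, "A", NA),
               start = c(0, 1, 1 + d), duration = c(1, d, 2 - d),
               stringsAsFactors = FALSE),
    class = c("dwell_seq", "data.frame"), duration_s = 3)
  sc <- toy_scenario(a, conc = 1, duration = 3, seed = 1, rms = 0)
  list(trace = render_trace(dw, sc), dwells = dw)
}

test_that("a noiseless dwell is recovered with sample-accurate duration", {
  x <- noiseless_trace_with_dwell(50)
  ev <- idealize(x$trace, idealization_config(threshold_pct = 98.5))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration, 0.050, tolerance = 2 / 50000)
  expect_equal(ev$ires_pct, 97, tolerance = 1e-3)
  expect_equal(ev$rms_noise, 0, tolerance = 1e-6)
  expect_equal(attr(ev, "baseline"), -129, tolerance = 1e-3)
})

test_that("noiseless idealization recovers every dwell above twice the dead time", {
  a <- toy_analyte(k_on = 0.5, k_off = 8)
  sc <- toy_scenario(a, conc = 4, duration = 30, seed = 21, rms = 0)
  sim <- simulate_trace(sc)
  cfg <- idealization_config(threshold_pct = 98.5)
  ev <- idealize(sim$trace, cfg)
  truth <- sim$dwells[sim$dwells$state == "adduct", ]
  m <- match_events(ev, sim$dwells)
  big <- truth$duration >= 2 * cfg$dead_time
  # every sufficiently long dwell is matched
  missed <- setdiff(which(big), m$matches$dwell)
  expect_length(missed, 0L)
  # matched durations within 2 samples
  derr <- abs(ev$duration[m$matches$event] - truth$duration[m$matches$dwell])
  expect_true(all(derr <= 2 / 50000 + 1e-12))
})

test_that("the robust baseline tolerates occupancy below one half", {
  sc <- toy_scenario(toy_analyte(k_on = 0.31, k_off = 7.69), conc = 3,
                     duration = 30, seed = 8)
  sim <- simulate_trace(sc)
  b <- estimate_baseline(sim$trace)
  expect_equal(b, -129, tolerance = 1)
  # oracle: median over ground-truth open samples only
  fs <- sim$trace$sampling_rate
  open <- sim$dwells[sim$dwells$state == "open", ]
  idx <- unlist(lapply(seq_len(nrow(open)), function(i) {
    seq(floor(open$start[i] * fs) + 5, floor((open$start[i] + open$duration[i]) * fs) - 5)
  }))
  idx <- idx[idx >= 1 & idx <= length(sim$trace$current)]
  expect_equal(b, stats::median(sim$trace$current[idx]), tolerance = 0.2)
})

test_that("detection achieves high recall and precision on a mixture trace", {
  fx <- ag_fixture()
  mix <- mixture_spec(list(fx$analytes$butanal, fx$analytes$hexanal), c(3, 2))
  sc <- simulation_scenario(fx$pore, mix, duration = 60, seed = 14)
  sim <- simulate_trace(sc)
  ev <- idealize(sim$trace, idealization_config(),
                 levels = fixture_levels(fx, c("butanal", "hexanal")))
  truth5 <- sim$dwells[sim$dwells$state == "adduct" & sim$dwells$duration >= 0.005, ]
  class(truth5) <- class(sim$dwells)
  attr(truth5, "duration_s") <- attr(sim$dwells, "duration_s")
  m <- match_events(ev, truth5)
  expect_gte(m$recall, 0.95)
  # precision against all true dwells (short ones included)
  m_all <- match_events(ev, sim$dwells)
  expect_gte(m_all$precision, 0.95)
})

test_that("I_res% is invariant under global current scaling", {
  x <- noiseless_trace_with_dwell(50)
  tr2 <- x$trace
  tr2$current <- tr2$current * 2
  ev1 <- idealize(x$trace, idealization_config(threshold_pct = 98.5))
  ev2 <- idealize(tr2, idealization_config(threshold_pct = 98.5))
  expect_equal(ev1$ires_pct, ev2$ires_pct, tolerance = 1e-9)
})

test_that("event count is non-increasing in the dead time", {
  sc <- toy_scenario(toy_analyte(k_on = 0.5, k_off = 9), conc = 4,
                     duration = 40, seed = 9)
  sim <- simulate_trace(sc)
  counts <- vapply(c(5e-4, 1e-3, 2e-3, 5e-3, 2e-2), function(dt) {
    cfg <- suppressWarnings(idealization_config(threshold_pct = 98.5,
                                                dead_time = dt))
    nrow(idealize(sim$trace, cfg))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("truth matching reports exact agreement and sub-dead-time misses", {
  sc <- toy_scenario(toy_analyte(k_on = 0.4, k_off = 6), conc = 5,
                     duration = 30, seed = 13)
  dw <- sample_dwells(sc)
  ev <- events_from_dwells(dw)
  m <- match_events(ev, dw)
  expect_equal(m$fp, 0L)
  expect_equal(m$fn, 0L)
  expect_equal(m$recall, 1)

  # inject one sub-dead-time dwell into the truth
  extra <- dw[1, ]
  extra$state <- "adduct"; extra$analyte <- "toy"; extra$diastereomer <- "A"
  extra$start <- 29.99; extra$duration <- 2e-4
  dw2 <- rbind(dw, extra)
  class(dw2) <- class(dw)
  attr(dw2, "duration_s") <- attr(dw, "duration_s")
  m2 <- match_events(ev, dw2)
  expect_equal(m2$fn, 1L)
  expect_equal(m2$by_duration$n_missed[1], 1L)  # shortest stratum
})

test_that("labels propagate from truth to detected events", {
  sc <- toy_scenario(toy_analyte(k_on = 0.5, k_off = 8), conc = 4,
                     duration = 20, seed = 19)
  sim <- simulate_trace(sc)
  ev <- idealize(sim$trace, idealization_config(threshold_pct = 98.5))
  lab <- label_events(ev, sim$dwells)
  expect_true(all(lab$label == "toy", na.rm = TRUE))
  expect_lt(mean(is.na(lab$label)), 0.05)
})

test_that("idealization demands a threshold or expected levels", {
  x <- noiseless_trace_with_dwell(50)
  expect_error(idealize(x$trace, idealization_config()), "auto_threshold")
  expect_equal(auto_threshold(c(98.7, 96.1)), 99.35)
  expect_error(estimate_baseline(
    structure(list(current = numeric(0), sampling_rate = 5e4, potential = -50,
                   seed = 1L), class = "nanopore_trace")), "empty")
})
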