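# Latent dwell sampling (CTMC), trace rendering and trace I/O.

test_that("zero concentration yields a single open dwell over the segment", {
  sc <- toy_scenario(toy_analyte(), conc = 0, duration = 10, seed = 3)
  dw <- sample_dwells(sc)
  expect_equal(nrow(dw), 1L)
  expect_identical(dw$state, "open")
  expect_equal(dw$duration, 10)
})

test_that("dwell sequences strictly alternate and tile the recording", {
  for (seed in 1:5) {
    sc <- toy_scenario(toy_analyte(k_on = 0.5, k_off = 8), conc = 10,
                       duration = 50, seed = seed)
    dw <- sample_dwells(sc)
    expect_false(any(dw$state[-1] == dw$state[-nrow(dw)]))
    expect_equal(dw$start[-1], (dw$start + dw$duration)[-nrow(dw)],
                 tolerance = 1e-9)
    expect_equal(sum(dw$duration), 50, tolerance = 1e-9)
  }
})

test_that("dwell distributions match their exponentials (KS at alpha = 0.01)", {
  ks <- ks_dwell_pvalues()
  open <- ks$open; add <- ks$adduct
  expect_gt(length(add), 5000)
  expect_gt(ks$p_open, 0.01)
  expect_gt(ks$p_adduct, 0.01)
  # means within 3 standard errors
  expect_lt(abs(mean(open) - 1 / ks$von), 3 * stats::sd(open) / sqrt(length(open)))
  expect_lt(abs(mean(add) - 1 / 7.69), 3 * stats::sd(add) / sqrt(length(add)))
})

test_that("competing analytes are selected like independent exponential clocks", {
  a1 <- toy_analyte("fast", k_on = 0.3, k_off = 8, ires = 98)
  a2 <- analyte_spec("slow", 0, 0.1, diastereomer_spec("A", 96, 8))
  mix <- mixture_spec(list(a1, a2), c(10, 10))   # v_on ratio 3:1
  sc <- simulation_scenario(toy_pore(), mix, duration = 2000, seed = 23)
  dw <- sample_dwells(sc)
  lab <- dw$analyte[dw$state == "adduct"]
  n <- length(lab)
  expect_gt(n, 2000)
  p_fast <- mean(lab == "fast")
  expect_lt(abs(p_fast - 0.75), 3 * sqrt(0.75 * 0.25 / n))
  # independent two-clock oracle: waiting time and winner distribution
  set.seed(99)
  oracle <- two_clock_open_dwells(c(3, 1), 5000)
  expect_lt(abs(mean(oracle$winner == 1) - p_fast),
            3 * sqrt(0.75 * 0.25 * (1 / n + 1 / 5000)))
  open <- dw$duration[dw$state == "open"]
  open <- open[-c(1L, length(open))]
  ks <- suppressWarnings(stats::ks.test(open, oracle$wait))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulation is bit-identical under the same scenario and seed", {
  sc <- toy_scenario(toy_analyte(), conc = 5, duration = 5, seed = 31)
  s1 <- simulate_trace(sc)
  s2 <- simulate_trace(sc)
  expect_identical(s1$dwells, s2$dwells)
  expect_identical(s1$trace$current, s2$trace$current)
  s3 <- simulate_trace(toy_scenario(toy_analyte(), 5, 5, seed = 32))
  expect_false(identical(s1$trace$current, s3$trace$current))
})

test_that("noiseless rendering reproduces exact plateau levels", {
  a <- toy_analyte(ires = 97, k_on = 1, k_off = 2)
  sc <- toy_scenario(a, conc = 1, duration = 4, seed = 5, rms = 0)
  sim <- simulate_trace(sc)
  x <- sim$trace$current
  open_lv <- -129; add_lv <- 0.97 * -129
  # all samples lie between the two levels; plateaus are hit exactly
  expect_true(all(x >= open_lv - 1e-9 & x <= add_lv + 1e-9))
  expect_true(mean(abs(x - open_lv) < 1e-9) > 0.3)
  expect_true(any(abs(x - add_lv) < 1e-9))
})

test_that("residual-current percentages are invariant to the open-current scale", {
  a <- toy_analyte(ires = 97, k_on = 1, k_off = 2)
  mk_tr <- function(ip) {
    pore <- pore_spec("p", ip, -50, 0)
    sc <- simulation_scenario(pore, mixture_spec(a, 1), duration = 4, seed = 5)
    render_trace(sample_dwells(sc), sc)
  }
  t1 <- mk_tr(-129); t2 <- mk_tr(-258)
  expect_equal(t1$current / -129, t2$current / -258, tolerance = 1e-12)
})

test_that("trace CSV round-trips losslessly with its header", {
  sc <- toy_scenario(toy_analyte(), conc = 3, duration = 0.5, seed = 2)
  tr <- simulate_trace(sc)$trace
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$current, tr$current, tolerance = 1e-14)
  expect_equal(back$sampling_rate, 50000)
  expect_equal(back$potential, -50)
  expect_equal(back$seed, 2L)

  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(read_trace(empty), "empty")
})

test_that("dwell and event tables round-trip through TSV", {
  sc <- toy_scenario(toy_analyte(), conc = 5, duration = 10, seed = 4)
  dw <- sample_dwells(sc)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_dwells(dw, p)
  back <- read_dwells(p)
  expect_equal(back$duration, dw$duration, tolerance = 1e-12)
  expect_identical(back$state, dw$state)

  ev <- events_from_dwells(dw, ires = 97, rms = 1)
  pe <- withr::local_tempfile(fileext = ".tsv")
  write_events(ev, pe)
  bev <- read_events(pe)
  expect_equal(bev$duration, ev$duration, tolerance = 1e-12)
  expect_identical(bev$label, ev$label)
  expect_equal(attr(bev, "duration_s"), attr(ev, "duration_s"))
})

test_that("segment boundaries change rates without breaking alternation", {
  a <- toy_analyte(k_on = 0.3, k_off = 8)
  segs <- list(
    list(duration = 200, mixture = mixture_spec(a, 2)),
    list(duration = 200, mixture = mixture_spec(a, 8)))
  sc <- simulation_scenario(toy_pore(), segs, seed = 12)
  dw <- sample_dwells(sc)
  expect_false(any(dw$state[-1] == dw$state[-nrow(dw)]))
  expect_equal(sum(dw$duration), 400, tolerance = 1e-9)
  n1 <- sum(dw$state == "adduct" & dw$start < 200)
  n2 <- sum(dw$state == "adduct" & dw$start >= 200)
  expect_gt(n2, 2 * n1)  # four-fold concentration jump
})
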