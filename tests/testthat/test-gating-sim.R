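test_that("step protocols enumerate the sweep family", {
  p <- make_step_protocol(0, 0.5, -100, 80, 20, 3, 0, 0.3)
  expect_equal(nrow(p), 10L)
  expect_equal(p$test_mV, seq(-100, 80, by = 20))
  expect_equal(unique(p$holding_s + p$test_s + p$tail_s), 3.8)

  # junction-shifted grid keeps its recorded voltages
  p2 <- make_step_protocol(6, 0.5, -94, 86, 20, 3, 6, 0.3)
  expect_equal(nrow(p2), 10L)
  expect_equal(p2$test_mV[1], -94)

  expect_equal(nrow(make_step_protocol(0, 0.5, -20, -20, 20, 3)), 1L)
  expect_error(make_step_protocol(0, 0.5, -100, 85, 20, 3), "divide")
})

test_that("a channel that never opens yields baseline plus noise only", {
  m <- gating_model(1, open_rate = 1e-9, close_rate = 40,
                    conductance_pS = 95.5)
  tr <- simulate_patch_current(m, -80, noise_sd = 0.5, seed = 5,
                               duration_s = 2)
  expect_true(all(tr$n_open == 0))
  expect_lt(abs(mean(tr$current_pA)), 0.05)
  expect_lt(stats::sd(tr$current_pA), 0.5)   # filtering reduces the noise sd
})

test_that("simulation is bit-identical under a repeated seed", {
  m <- gating_model(2, po = 0.2, conductance_pS = 70)
  p <- make_step_protocol(0, 0.1, -80, -40, 20, 0.5)
  t1 <- simulate_patch_current(m, p, seed = 99)
  t2 <- simulate_patch_current(m, p, seed = 99)
  expect_identical(t1$current_pA, t2$current_pA)
  t3 <- simulate_patch_current(m, p, seed = 100)
  expect_false(identical(t3$current_pA, t1$current_pA))
})

test_that("stationary open fraction matches alpha/(alpha+beta)", {
  set.seed(1)
  for (po in c(0.05, 0.39, 0.8)) {
    m <- gating_model(1, po = po, close_rate = 40, conductance_pS = 95.5)
    dur <- 20
    tr <- simulate_patch_current(m, -80, noise_sd = 0, seed = 7 + round(100 * po),
                                 duration_s = dur, filter_hz = NULL)
    rates <- gating_at_voltage(m, -80)
    # variance of the time-averaged occupancy of a two-state chain:
    # 2 Po (1-Po) / (T (alpha+beta)); allow 3 such standard errors
    se <- sqrt(2 * po * (1 - po) / (dur * (rates$open_rate + rates$close_rate)))
    expect_lt(abs(mean(tr$n_open) - po), 3 * se + 1e-3)
  }
})

test_that("noiseless multi-channel traces have N+1 levels spaced by i(V)", {
  n_ch <- 3
  m <- gating_model(n_ch, po = 0.4, conductance_pS = 100, reversal_mV = 0)
  tr <- simulate_patch_current(m, -80, noise_sd = 0, seed = 21,
                               duration_s = 10, filter_hz = NULL)
  lev <- sort(unique(tr$current_pA))
  expect_equal(length(lev), n_ch + 1)
  expect_equal(diff(lev), rep(8, n_ch))  # |i| = 100 pS * 80 mV = 8 pA
})

test_that("total simulated charge scales linearly with channel count", {
  mean_i <- vapply(c(1L, 2L, 4L), function(n) {
    m <- gating_model(n, po = 0.3, close_rate = 100, conductance_pS = 100)
    tr <- simulate_patch_current(m, -80, noise_sd = 0, seed = 31,
                                 duration_s = 20, filter_hz = NULL)
    mean(tr$current_pA)
  }, 0)
  expect_equal(mean_i / mean_i[1], c(1, 2, 4), tolerance = 0.08)
})

test_that("the recording filter preserves DC and attenuates noise", {
  flat <- structure(
    tibble::tibble(sweep = 1L, current_pA = rep(5, 5000)),
    sampling_hz = 10000)
  f <- apply_recording_filter(flat, 2000)
  expect_equal(mean(f$current_pA), 5, tolerance = 5e-3)      # DC gain 1
  expect_equal(f$current_pA[2000], 5, tolerance = 1e-6)

  set.seed(4)
  noise <- structure(
    tibble::tibble(sweep = 1L, current_pA = stats::rnorm(20000)),
    sampling_hz = 10000)
  fn <- apply_recording_filter(noise, 2000)
  expect_lt(stats::sd(fn$current_pA), 0.75 * stats::sd(noise$current_pA))

  expect_error(apply_recording_filter(noise, 5000), "Nyquist")
})

test_that("long open-close plateaus survive filtering within 1%", {
  # square events lasting >> 1/cutoff
  sq <- rep(rep(c(0, -8), each = 2000), 3)
  tr <- structure(tibble::tibble(sweep = 1L, current_pA = sq),
                  sampling_hz = 10000)
  f <- apply_recording_filter(tr, 2000)
  # compare plateau means away from the edges
  idx_open <- rep(rep(c(FALSE, TRUE), each = 2000), 3)
  settle <- 50
  stable <- rep(c(rep(FALSE, settle), rep(TRUE, 2000 - settle)), 6)
  expect_equal(mean(f$current_pA[idx_open & stable]), -8, tolerance = 0.01)
  expect_equal(mean(f$current_pA[!idx_open & stable]), 0, tolerance = 0.08)
})

test_that("fast gating relative to the sampling rate warns about aliasing", {
  m <- gating_model(1, open_rate = 20000, close_rate = 20000,
                    conductance_pS = 95.5)
  expect_warning(simulate_patch_current(m, -80, seed = 2, duration_s = 0.05),
                 "alias")
})
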