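make_trace <- function(current, sweep = 1L) {
  tibble::tibble(sweep = sweep, current_pA = current)
}

test_that("amplitude histograms conserve samples exactly", {
  set.seed(11)
  x <- stats::rnorm(5000, -3, 1.2)
  h <- build_amplitude_histogram(make_trace(x), bin_width_pA = 0.1)
  expect_identical(sum(h$count), 5000L)
  expect_identical(attr(h, "total_samples"), 5000L)
  expect_true(all(diff(attr(h, "bin_edges")) > 0))

  # a constant trace lands in a single bin
  hc <- build_amplitude_histogram(make_trace(rep(2.5, 100)))
  expect_identical(sum(hc$count > 0), 1L)
  expect_error(build_amplitude_histogram(make_trace(numeric())), "no samples")
})

test_that("histograms are additive under trace concatenation", {
  set.seed(12)
  a <- stats::rnorm(2000, 0, 0.3)
  b <- stats::rnorm(3000, -6, 0.3)
  ha <- build_amplitude_histogram(make_trace(a))
  hb <- build_amplitude_histogram(make_trace(b))
  hab <- build_amplitude_histogram(make_trace(c(a, b)))
  # align on shared bin grid and compare counts
  for (h in list(ha, hb)) {
    m <- match(round(h$bin_mid_pA, 6), round(hab$bin_mid_pA, 6))
    expect_false(anyNA(m))
  }
  total <- stats::setNames(rep(0, nrow(hab)), round(hab$bin_mid_pA, 6))
  for (h in list(ha, hb)) {
    key <- as.character(round(h$bin_mid_pA, 6))
    total[key] <- total[key] + h$count
  }
  expect_equal(unname(total), hab$count)
})

test_that("two-level traces give bimodal histograms at the level currents", {
  m <- gating_model(1, po = 0.3, conductance_pS = 75, reversal_mV = 0)
  tr <- simulate_patch_current(m, -80, seed = 41, duration_s = 10)
  mix <- fit_peak_mixture(build_amplitude_histogram(tr))
  expect_identical(attr(mix, "n_channels"), 1L)
  expect_equal(sort(mix$centre_pA), c(-6, 0), tolerance = 0.05)
})

test_that("an analytic two-Gaussian histogram is recovered within 2%", {
  # histogram built from the exact bin integrals of the mixture
  # 0.75 N(0, 0.4) + 0.25 N(-6.4, 0.4), N = 2e5 samples
  bw <- 0.1
  edges <- seq(-8.55, 1.55, by = bw)
  n_tot <- 2e5
  p_bin <- 0.75 * diff(stats::pnorm(edges, 0, 0.4)) +
    0.25 * diff(stats::pnorm(edges, -6.4, 0.4))
  h <- structure(
    tibble::tibble(bin_mid_pA = (edges[-1] + edges[-length(edges)]) / 2,
                   count = n_tot * p_bin),
    class = c("amplitude_histogram", class(tibble::tibble())),
    bin_edges = edges, total_samples = n_tot, voltage_mV = -80,
    bin_width = bw)
  mix <- fit_peak_mixture(h, max_channels = 3)
  expect_identical(attr(mix, "n_channels"), 1L)
  expect_equal(mix$centre_pA, c(0, -6.4), tolerance = 1e-3)
  expect_equal(mix$area_fraction, c(0.75, 0.25), tolerance = 0.02)
  expect_equal(mix$sd_pA, c(0.4, 0.4), tolerance = 0.01)
  expect_equal(open_probability(mix, 1), 0.25, tolerance = 0.02 * 0.25)
})

test_that("a pure single-Gaussian histogram yields a baseline-only mixture", {
  bw <- 0.1
  edges <- seq(-2.05, 2.05, by = bw)
  p_bin <- diff(stats::pnorm(edges, 0, 0.35))
  h <- structure(
    tibble::tibble(bin_mid_pA = (edges[-1] + edges[-length(edges)]) / 2,
                   count = 1e5 * p_bin),
    class = c("amplitude_histogram", class(tibble::tibble())),
    bin_edges = edges, total_samples = 1e5, voltage_mV = -80, bin_width = bw)
  mix <- fit_peak_mixture(h, max_channels = 3)
  expect_identical(attr(mix, "n_channels"), 0L)
  expect_equal(glance(mix)$po, 0)
})

test_that("open probability follows the area-weighted level formula", {
  mk_mix <- function(centres, areas) {
    structure(
      tibble::tibble(level = seq_along(centres) - 1L, centre_pA = centres,
                     sd_pA = 0.4, area = areas,
                     area_fraction = areas / sum(areas)),
      class = c("peak_mixture", class(tibble::tibble())),
      n_channels = length(centres) - 1L)
  }
  # all samples at baseline
  expect_equal(open_probability(mk_mix(0, 1), 1), 0)
  # the printed single-channel case: closed/open areas 0.75/0.25
  expect_equal(open_probability(mk_mix(c(0, -6.42), c(0.75, 0.25)), 1), 0.25)
  # invariance under uniform area rescaling
  expect_equal(open_probability(mk_mix(c(0, -6, -12), c(6, 3, 1)), 2),
               open_probability(mk_mix(c(0, -6, -12), c(60, 30, 10)), 2))
  # NPo/N normalisation across assumed channel counts
  expect_equal(open_probability(mk_mix(c(0, -6), c(1, 1)), 2), 0.25)
  expect_error(open_probability(mk_mix(c(0, -6, -12), c(6, 3, 1)), 1),
               "smaller")
  # unitary current from the same mixtures
  expect_equal(unitary_current(mk_mix(c(0, -6.42), c(3, 1))), -6.42)
  expect_equal(unitary_current(mk_mix(c(0, -6, -12), c(6, 3, 1))), -6)
  expect_error(unitary_current(mk_mix(0, 1)), "single-peak")
})

test_that("chord conductance uses i/V at the extreme voltage", {
  expect_equal(chord_conductance_extreme_voltage(-6.42, voltage_mV = -74),
               86.75, tolerance = 1e-3)
  # ratio invariance
  expect_equal(chord_conductance_extreme_voltage(-12.84, voltage_mV = -148),
               chord_conductance_extreme_voltage(-6.42, voltage_mV = -74))
  iv <- tibble::tibble(voltage_mV = c(-80, -40, 40), current_pA = c(-8, -3, 1))
  expect_equal(chord_conductance_extreme_voltage(iv), 100)
  expect_error(chord_conductance_extreme_voltage(1, voltage_mV = 0), "V = 0")
})

test_that("I/V assembly aggregates repeats and rejects degenerate input", {
  d <- tibble::tibble(voltage_mV = rep(c(-80, -40, 0, 40), each = 3),
                      current_pA = c(-8.1, -7.9, -8.0, -3, -3.1, -2.9,
                                     0.05, -0.05, 0, 1, 1.1, 0.9))
  iv <- build_iv_curve(d)
  expect_equal(iv$n, rep(3L, 4))
  expect_equal(iv$current_pA[1], -8, tolerance = 1e-6)
  expect_true(all(diff(iv$voltage_mV) > 0))
  expect_error(build_iv_curve(d[0, ]), "empty")
  expect_error(build_iv_curve(tibble::tibble(voltage_mV = 1,
                                             current_pA = 1)), "2 distinct")
})

test_that("reversal potential interpolates the zero crossing", {
  iv <- tibble::tibble(voltage_mV = c(-20, 20), current_pA = c(-2, 2))
  expect_equal(estimate_reversal(iv), 0)
  iv2 <- tibble::tibble(voltage_mV = c(-60, -20, 20), current_pA = c(-2, 1, 4))
  expect_equal(estimate_reversal(iv2), -60 + 40 * 2 / 3)
  expect_error(estimate_reversal(tibble::tibble(voltage_mV = c(-20, 20),
                                                current_pA = c(1, 2))),
               "sign")
})

test_that("reversal of a simulated ohmic channel cohort is recovered within 1 mV", {
  e_true <- -34.9
  p <- make_step_protocol(0, 0.1, -100, 80, 20, 3, 0, 0.1)
  per_sweep <- purrr::map_dfr(1:5, function(patch) {
    m <- gating_model(4, po = 0.3, close_rate = 150, conductance_pS = 95.5,
                      reversal_mV = e_true)
    tr <- simulate_patch_current(m, p, seed = 500 + patch)
    tr |>
      dplyr::group_by(sweep) |>
      dplyr::group_modify(function(d, key) tibble::tibble(
        voltage_mV = d$voltage_mV[d$segment == "test"][1],
        current_pA = steady_state_current(d, 0.5)))
  })
  iv <- build_iv_curve(per_sweep)
  expect_lt(abs(estimate_reversal(iv) - e_true), 1)
})

test_that("Po estimates are stable under bin-width halving", {
  m <- gating_model(1, po = 0.3, conductance_pS = 95.5)
  tr <- simulate_patch_current(m, -80, seed = 61, duration_s = 10)
  po <- vapply(c(0.1, 0.05), function(bw) {
    glance(fit_peak_mixture(build_amplitude_histogram(tr, bw)))$po
  }, 0)
  expect_lt(abs(diff(po)), 0.02)
})

test_that("chord conductance of a simulated ohmic channel holds at every voltage", {
  m <- gating_model(1, po = 0.35, conductance_pS = 95.5, reversal_mV = 0)
  for (v in c(-80, -40, 40)) {
    tr <- simulate_patch_current(m, v, seed = 70 + v, duration_s = 10)
    gl <- glance(fit_peak_mixture(build_amplitude_histogram(tr)))
    expect_equal(1000 * gl$unitary_current_pA / v, 95.5, tolerance = 0.05)
  }
})
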