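test_that("membrane area comes from exactly one sizing route", {
  g <- vacuole_geometry(diameter_um = 20)
  expect_equal(g$area_m2, pi * (20e-6)^2)        # 1.257e-9 m2
  g2 <- vacuole_geometry(capacitance_pF = 12.57, specific_capacitance_mF_m2 = 10)
  expect_equal(g2$area_m2, 12.57e-12 / 0.01)
  expect_error(vacuole_geometry(), "exactly one")
  expect_error(vacuole_geometry(diameter_um = 20, capacitance_pF = 10),
               "exactly one")
})

test_that("steady-state current averages the plateau window", {
  const <- tibble::tibble(current_pA = rep(5, 1000))
  expect_equal(steady_state_current(const), 5)

  # exponential approach to a plateau: closed-form mean of the tail window
  n <- 30000; fs <- 10000
  t <- (seq_len(n) - 1) / fs
  tau <- 0.05; i_inf <- -10
  tr <- tibble::tibble(current_pA = i_inf * (1 - exp(-t / tau)))
  est <- steady_state_current(tr, 0.1)
  expect_equal(est, i_inf, tolerance = 0.01)
  expect_error(steady_state_current(tibble::tibble(current_pA = rep(1, 5))),
               "10 samples")
  expect_error(steady_state_current(const, 0.9), "window_fraction")
})

test_that("current density is I over area", {
  geo <- vacuole_geometry(diameter_um = 20)
  expect_equal(current_density(0, geo), 0)
  # 1.33 nA over a 20 um sphere is about 1.06 A/m2
  expect_equal(current_density(1330, geo), 1.06, tolerance = 0.002)
  # doubling the area halves J
  geo2 <- vacuole_geometry(diameter_um = 20 * sqrt(2))
  expect_equal(current_density(1330, geo2), current_density(1330, geo) / 2)
})

test_that("J/V aggregation is order-invariant with exact-grid matching", {
  mk <- function(j) tibble::tibble(voltage_mV = seq(-100, 80, by = 20),
                                   J_A_m2 = j)
  set.seed(9)
  curves <- purrr::map(1:4, function(i) mk(stats::rnorm(10, -0.2, 0.05)))
  agg1 <- aggregate_jv(curves)
  agg2 <- aggregate_jv(rev(curves))
  expect_equal(tibble::as_tibble(agg1), tibble::as_tibble(agg2))
  expect_equal(agg1$n, rep(4L, 10))

  # identical curves: zero SEM; single curve: SEM absent
  same <- aggregate_jv(list(mk(rep(-0.1, 10)), mk(rep(-0.1, 10))))
  expect_equal(same$sem, rep(0, 10))
  single <- aggregate_jv(list(mk(rep(-0.1, 10))))
  expect_true(all(is.na(single$sem)))

  shifted <- mk(rep(-0.1, 10))
  shifted$voltage_mV <- shifted$voltage_mV + 6
  expect_error(aggregate_jv(list(mk(rep(-0.1, 10)), shifted)), "grids")
})

test_that("an inward-rectifying population reproduces the J/V shape", {
  # Boltzmann-gated channels open at negative voltages only: |J| grows at
  # negative V while J at positive V stays near zero
  geo <- vacuole_geometry(diameter_um = 20)
  p <- make_step_protocol(0, 0.1, -100, 80, 20, 1.5, 0, 0.1)
  m <- gating_model(6, po = 0.35, close_rate = 80, conductance_pS = 95.5,
                    reversal_mV = 0, v_half = -40, slope = -18)
  jv_rows <- purrr::map_dfr(1:3, function(vac) {
    tr <- simulate_patch_current(m, p, seed = 900 + vac)
    tr |>
      dplyr::group_by(sweep) |>
      dplyr::group_modify(function(d, key) tibble::tibble(
        voltage_mV = d$voltage_mV[d$segment == "test"][1],
        J_A_m2 = current_density(steady_state_current(d), geo))) |>
      dplyr::ungroup() |>
      dplyr::mutate(vacuole = vac)
  })
  agg <- aggregate_jv(jv_rows)
  j_neg <- agg$J_A_m2[agg$voltage_mV == -100]
  j_pos <- agg$J_A_m2[agg$voltage_mV == 80]
  expect_lt(j_neg, 0)
  expect_gt(abs(j_neg), 10 * abs(j_pos))
})
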