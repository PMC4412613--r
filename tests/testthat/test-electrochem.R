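test_that("Nernst potential is zero for symmetric solutions and antisymmetric", {
  a <- recipe_vac_no3()
  expect_equal(nernst_potential("NO3", a, a), 0)
  cyt <- recipe_cyt_no3(20)
  expect_equal(nernst_potential("NO3", cyt, a),
               -nernst_potential("NO3", a, cyt))
})

test_that("tenfold nitrate gradient at equal ionic strength gives -RT/F ln 10", {
  # activity coefficients cancel exactly when both sides share one ionic
  # strength, leaving the unit-activity Nernst slope (~ -58.6 mV at 295 K)
  hi <- solution(data.frame(ion = c("Na", "NO3"), mM = c(200, 200)))
  lo <- solution(data.frame(ion = c("Na", "NO3", "K", "Cl"),
                            mM = c(20, 20, 180, 180)))
  k <- 1000 * 8.31446 * 295.15 / 96485.33
  expect_equal(nernst_potential("NO3", lo, hi), -k * log(10),
               tolerance = 1e-10)
  expect_equal(-k * log(10), -58.6, tolerance = 0.01)
})

test_that("nitrate equilibrium potential of the 200/20 gradient is near -51.6 mV", {
  e <- nernst_potential("NO3", recipe_cyt_no3(20), recipe_vac_no3())
  expect_lt(abs(e - (-51.6)), 3)
})

test_that("zero concentration on either side is an error", {
  a <- recipe_vac_no3()
  b <- solution(data.frame(ion = c("K", "Cl"), mM = c(100, 100)))
  expect_error(nernst_potential("NO3", b, a), "absent")
})

test_that("GHK with a single permeant species reduces exactly to Nernst", {
  set.seed(71)
  for (i in 1:100) {
    cyt <- random_solution()
    vac <- random_solution()
    e_ghk <- ghk_reversal_potential(c(NO3 = 1), cyt, vac)
    e_nernst <- nernst_potential("NO3", cyt, vac)
    expect_lt(abs(e_ghk - e_nernst), 1e-9)
  }
})

test_that("GHK input contracts hold", {
  a <- recipe_vac_no3()
  expect_equal(ghk_reversal_potential(c(NO3 = 1), a, a), 0)
  expect_error(ghk_reversal_potential(c(NO3 = 0), a, a), "zero")
  expect_error(ghk_reversal_potential(c(Ca = 1), a, a), "monovalent")
  expect_error(
    ghk_reversal_potential(tibble::tibble(ion = character(),
                                          permeability = numeric()), a, a),
    "at least one")
})

test_that("permeability-ratio inversion round-trips the GHK equation", {
  cyt <- recipe_cyt_no3(200)
  vac <- recipe_vac_cl()
  for (r in c(0.1, 1, 3.08, 10)) {
    e <- ghk_reversal_potential(c(NO3 = r, Cl = 1), cyt, vac)
    fit <- fit_permeability_ratio(e, "NO3", "Cl", cyt, vac)
    expect_equal(fit$permeability_ratio, r, tolerance = 1e-4)
  }
})

test_that("mirror-symmetric anion compositions give a unit permeability ratio", {
  a <- solution(data.frame(ion = c("Na", "NO3", "Cl"), mM = c(200, 150, 50)))
  b <- solution(data.frame(ion = c("Na", "NO3", "Cl"), mM = c(200, 50, 150)))
  fit <- fit_permeability_ratio(0, "NO3", "Cl", a, b)
  expect_equal(fit$permeability_ratio, 1, tolerance = 1e-6)
})

test_that("junction potentials behave like the Henderson equation", {
  a <- solution(data.frame(ion = c("K", "Cl"), mM = c(100, 100)))
  expect_equal(henderson_junction_potential(a, a), 0)
  b <- solution(data.frame(ion = c("K", "Cl"), mM = c(10, 10)))
  e <- henderson_junction_potential(a, b)
  expect_lt(abs(e), 2)     # K+ and Cl- mobilities nearly equal
  expect_gt(abs(e), 0.5)   # but not identical
  # exact antisymmetry, including on asymmetric biological recipes
  expect_identical(henderson_junction_potential(b, a), -e)
  p <- recipe_vac_no3(); q <- recipe_cyt_no3(200)
  expect_equal(henderson_junction_potential(p, q),
               -henderson_junction_potential(q, p), tolerance = 1e-12)
})

test_that("missing mobilities are reported by species name", {
  a <- solution(data.frame(ion = "X", mM = 10, charge = 1L,
                           mobility = NA_real_, ion_size = 4))
  b <- solution(data.frame(ion = "X", mM = 100, charge = 1L,
                           mobility = NA_real_, ion_size = 4))
  expect_error(henderson_junction_potential(a, b), "X")
})
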