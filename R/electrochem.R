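# Gas constant (J mol^-1 K^-1) and Faraday constant (C mol^-1)
.R_GAS <- 8.31446
.FARADAY <- 96485.33

# RT/F in mV
rt_over_f <- function(temperature) 1000 * .R_GAS * temperature / .FARADAY

# activity (mM) of one named ion in a solution, with presence checks
.ion_activity <- function(sol, ion, method) {
  act <- ion_activities(sol, method = method)
  row <- act[act$ion == ion, , drop = FALSE]
  if (nrow(row) == 0L || row$mM[1] == 0) {
    stop("ion '", ion, "' absent (or zero) in solution '",
         attr(sol, "label"), "': potential undefined", call. = FALSE)
  }
  row
}

#' Nernst equilibrium potential across the tonoplast
#'
#' \eqn{E_X = (RT/zF)\,\ln(a_{vac}/a_{cyt})} in the Bertl sign convention
#' used throughout the package: membrane voltage is cytoplasmic minus
#' vacuolar potential, and positive current is cation flux from cytoplasm to
#' vacuole. Activities are computed from each solution's own ionic strength.
#'
#' @param ion Ion name as in the solution species tables (e.g. `"NO3"`).
#' @param cytoplasmic,vacuolar [solution()] objects for the two sides.
#' @param method Activity model passed to [ion_activities()]; the default is
#'   the extended Debye-Hückel with Kielland ion sizes.
#' @return Equilibrium potential in mV.
#' @export
#' @examples
#' vac <- solution_from_salts(c(HNO3 = 200, CaCl2 = 2, MgCl2 = 2),
#'                            btp_mM = 101, pH = 5)
#' cyt <- solution_from_salts(c(HNO3 = 20, CaCl2 = 2, MgCl2 = 2),
#'                            btp_mM = 16, pH = 7)
#' nernst_potential("NO3", cyt, vac) # about -52 mV
nernst_potential <- function(ion, cytoplasmic, vacuolar,
                             method = c("edh", "davies")) {
  method <- match.arg(method)
  a_c <- .ion_activity(cytoplasmic, ion, method)
  a_v <- .ion_activity(vacuolar, ion, method)
  z <- a_c$charge[1]
  temperature <- attr(cytoplasmic, "temperature")
  rt_over_f(temperature) / z * log(a_v$activity_mM[1] / a_c$activity_mM[1])
}

#' Goldman-Hodgkin-Katz reversal potential for monovalent anions
#'
#' Solves the GHK voltage equation for a set of permeant monovalent anions
#' with relative permeabilities, using activities. In the cytoplasmic-minus-
#' vacuolar convention the anion-only form is
#' \eqn{E_{rev} = (RT/F)\,\ln\big(\sum_X P_X a_{X,cyt} / \sum_X P_X a_{X,vac}\big)}.
#' With a single permeant species this reduces exactly to
#' [nernst_potential()]. Divalent ions are not accepted as permeant species
#' (they enter only through the ionic strength).
#'
#' @param permeant Data frame with columns `ion` and `permeability`
#'   (relative, > 0), or a named numeric vector.
#' @inheritParams nernst_potential
#' @return Reversal potential in mV.
#' @export
ghk_reversal_potential <- function(permeant, cytoplasmic, vacuolar,
                                   method = c("edh", "davies")) {
  method <- match.arg(method)
  if (is.numeric(permeant) && !is.null(names(permeant))) {
    permeant <- tibble::tibble(ion = names(permeant),
                               permeability = unname(permeant))
  }
  stopifnot(is.data.frame(permeant),
            all(c("ion", "permeability") %in% names(permeant)))
  if (nrow(permeant) == 0L) stop("need at least one permeant species",
                                 call. = FALSE)
  if (all(permeant$permeability == 0)) {
    stop("all permeabilities are zero", call. = FALSE)
  }
  if (any(permeant$permeability < 0)) {
    stop("permeabilities must be > 0", call. = FALSE)
  }
  a_c <- ion_activities(cytoplasmic, method = method)
  a_v <- ion_activities(vacuolar, method = method)
  side_activity <- function(act, ion) {
    row <- act[act$ion == ion, , drop = FALSE]
    if (nrow(row) == 0L) return(0)
    if (row$charge[1] != -1L) {
      stop("GHK sum is restricted to monovalent anions; '", ion,
           "' has charge ", row$charge[1], call. = FALSE)
    }
    row$activity_mM[1]
  }
  num <- sum(purrr::map2_dbl(permeant$ion, permeant$permeability,
                             function(i, p) p * side_activity(a_c, i)))
  den <- sum(purrr::map2_dbl(permeant$ion, permeant$permeability,
                             function(i, p) p * side_activity(a_v, i)))
  if (num == 0 || den == 0) {
    stop("permeant species absent from one side: reversal undefined",
         call. = FALSE)
  }
  rt_over_f(attr(cytoplasmic, "temperature")) * log(num / den)
}

#' Permeability ratio from a measured reversal potential
#'
#' Inverts the two-anion GHK equation: finds \eqn{r = P_{test}/P_{ref}} such
#' that [ghk_reversal_potential()] with permeabilities \eqn{(r, 1)}
#' reproduces the measured reversal potential. Root-bracketing bisection to
#' |dE| < 0.01 mV on r in (1e-4, 1e4).
#'
#' @param measured_e_rev Measured reversal potential, mV (tonoplast
#'   convention).
#' @param test_ion,reference_ion Ion names; the ratio is
#'   P(test)/P(reference).
#' @inheritParams nernst_potential
#' @return A one-row tibble with `e_rev`, `permeability_ratio`,
#'   `test_ion`, `reference_ion`.
#' @export
fit_permeability_ratio <- function(measured_e_rev, test_ion, reference_ion,
                                   cytoplasmic, vacuolar,
                                   method = c("edh", "davies")) {
  method <- match.arg(method)
  stopifnot(is.finite(measured_e_rev))
  f <- function(log10r) {
    p <- stats::setNames(c(10^log10r, 1), c(test_ion, reference_ion))
    ghk_reversal_potential(p, cytoplasmic, vacuolar, method = method) -
      measured_e_rev
  }
  lo <- -4; hi <- 4
  flo <- f(lo); fhi <- f(hi)
  if (sign(flo) == sign(fhi)) {
    stop("no permeability ratio in (1e-4, 1e4) reproduces ",
         measured_e_rev, " mV", call. = FALSE)
  }
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  # polish until the reproduced potential is within 0.01 mV
  if (abs(f(root)) > 0.01) {
    root <- stats::uniroot(f, c(root - 0.1, root + 0.1), tol = 1e-14)$root
  }
  tibble::tibble(e_rev = measured_e_rev,
                 permeability_ratio = 10^root,
                 test_ion = test_ion,
                 reference_ion = reference_ion)
}

#' Henderson liquid junction potential
#'
#' Estimates the junction potential between the pipette-filling solution and
#' the bath with the Henderson equation, using the limiting equivalent
#' conductances in the solution tables as relative mobilities. The value
#' returned is the potential of the bath minus the pipette solution; it is
#' antisymmetric under swapping the two solutions. Every charged species
#' must carry a mobility.
#'
#' @param pipette,bath [solution()] objects.
#' @return Junction potential in mV.
#' @export
#' @examples
#' a <- solution(data.frame(ion = c("K", "Cl"), mM = c(100, 100)))
#' b <- solution(data.frame(ion = c("K", "Cl"), mM = c(10, 10)))
#' henderson_junction_potential(a, b) # small: K+ and Cl- mobilities nearly equal
henderson_junction_potential <- function(pipette, bath) {
  stopifnot(inherits(pipette, "solution_spec"), inherits(bath, "solution_spec"))
  ions <- union(pipette$ion, bath$ion)
  conc <- function(sol, ion) {
    i <- match(ion, sol$ion)
    if (is.na(i)) 0 else sol$mM[i] / 1000
  }
  prop <- function(sol, ion, what) {
    i <- match(ion, sol$ion)
    if (is.na(i)) NA else sol[[what]][i]
  }
  z <- u <- numeric(length(ions))
  for (k in seq_along(ions)) {
    z[k] <- prop(pipette, ions[k], "charge")
    if (is.na(z[k])) z[k] <- prop(bath, ions[k], "charge")
    u[k] <- prop(pipette, ions[k], "mobility")
    if (is.na(u[k])) u[k] <- prop(bath, ions[k], "mobility")
  }
  if (anyNA(u)) {
    stop("missing mobility for species: ",
         paste(ions[is.na(u)], collapse = ", "), call. = FALSE)
  }
  # Henderson equation written in terms of equivalent conductances
  # lambda_i = |z_i| u_i (the `mobility` column): with mobility u_i the
  # classic form is
  #   E(bath) - E(pipette) = (RT/F) *
  #     [sum u z/|z| dc / sum u |z| dc] * ln(sum u|z| c_pip / sum u|z| c_bath)
  # and substituting u = lambda/|z| gives the sums below.
  ca <- vapply(ions, function(i) conc(pipette, i), 0)
  cb <- vapply(ions, function(i) conc(bath, i), 0)
  dc <- cb - ca
  s1 <- sum(u * sign(z) / abs(z) * dc)
  s2 <- sum(u * dc)
  ga <- sum(u * ca)
  gb <- sum(u * cb)
  if (s2 == 0 || ga == 0 || gb == 0) return(0)
  rt_over_f(attr(bath, "temperature")) * (s1 / s2) * log(ga / gb)
}
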