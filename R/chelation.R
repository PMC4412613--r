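#' EGTA binding constants
#'
#' Reference stability constants for the H/Ca/Mg-EGTA system, as shipped
#' with the MaxChelator-family calculators. Values are the Martell & Smith
#' critical compilation at 0.1 M ionic strength and 20 °C; protonation
#' constants are mixed-mode (determined with a glass electrode), so the
#' equilibrium solver uses the meter pH with them directly. Reaction
#' enthalpies (kJ/mol, van't Hoff temperature correction) are the commonly
#' tabulated values: Ca-EGTA binding is exothermic, Mg-EGTA endothermic.
#'
#' @param egta_pKa Four successive protonation pK values (decreasing).
#' @param logK Named log10 stability constants `CaEGTA`, `CaHEGTA`,
#'   `MgEGTA`, `MgHEGTA` (metal + L or metal + HL association).
#' @param dH Named reaction enthalpies in kJ/mol for the same four
#'   complexes.
#' @param ionic_strength_ref,temperature_ref Conditions the constants refer
#'   to (M, K).
#' @param source Free-text provenance note.
#' @return A `binding_constants` list.
#' @export
#' @examples
#' egta_constants()
egta_constants <- function(egta_pKa = c(9.47, 8.85, 2.66, 2.00),
                           logK = c(CaEGTA = 10.86, CaHEGTA = 5.33,
                                    MgEGTA = 5.21, MgHEGTA = 3.37),
                           dH = c(CaEGTA = -33.3, CaHEGTA = 0,
                                  MgEGTA = 21.2, MgHEGTA = 0),
                           ionic_strength_ref = 0.1,
                           temperature_ref = 293.15,
                           source = "Martell & Smith, 0.1 M, 20 degC") {
  stopifnot(length(egta_pKa) == 4L, all(diff(egta_pKa) < 0),
            all(c("CaEGTA", "CaHEGTA", "MgEGTA", "MgHEGTA") %in% names(logK)),
            all(logK > 0))
  structure(list(egta_pKa = egta_pKa, logK = logK, dH = dH,
                 ionic_strength_ref = ionic_strength_ref,
                 temperature_ref = temperature_ref, source = source),
            class = "binding_constants")
}

# Davies-type correction bracket used by the Chelator family of buffer
# calculators: sqrt(I)/(1+sqrt(I)) - 0.25 I.
.chel_g <- function(I) sqrt(I) / (1 + sqrt(I)) - 0.25 * I

# Adjust the metal-complex constants from the reference ionic strength and
# temperature to the working conditions. Charge products (Dz^2 of the
# association, concentration scale): M2+ + L4- -> ML2- : 16;
# M2+ + HL3- -> MHL- : 12. Protonation constants are mixed-mode and used
# as shipped (see vignette).
.adjust_constants <- function(bc, I, temperature) {
  A <- dh_A(temperature)
  dg <- .chel_g(I) - .chel_g(bc$ionic_strength_ref)
  vt <- (1 / bc$temperature_ref - 1 / temperature) / (log(10) * .R_GAS)
  S <- c(CaEGTA = 16, CaHEGTA = 12, MgEGTA = 16, MgHEGTA = 12)
  logK <- bc$logK[names(S)] - S * A * dg + bc$dH[names(S)] * 1000 * vt
  list(logK = logK, pKa = bc$egta_pKa)
}

# total concentration (M) of one ion/ligand in a solution spec (mM storage)
.total_M <- function(sol, ion) {
  i <- match(ion, sol$ion)
  if (is.na(i)) 0 else sol$mM[i] / 1000
}

#' Solve the H/Ca/Mg-EGTA equilibrium of a solution
#'
#' Simultaneous mass-action / mass-balance solution for a buffered solution
#' containing EGTA, Ca and Mg at clamped pH (the recipes are pH-buffered, so
#' no proton balance is solved). Complexes considered: the four EGTA
#' protonation states and CaEGTA, CaHEGTA, MgEGTA, MgHEGTA. Binding
#' constants are adjusted to the solution's ionic strength and temperature
#' (see [egta_constants()]). The solver is damped Newton iteration on the
#' log concentrations of free Ca, free Mg and free (fully deprotonated)
#' EGTA, capped at 200 iterations.
#'
#' @param sol A [solution()] containing species `EGTA` and optionally
#'   `Ca`, `Mg` (totals, mM).
#' @param constants A [egta_constants()] set.
#' @param ionic_strength Working ionic strength in M; default computed from
#'   the solution itself (EGTA counted as a divalent anion).
#' @return An `equilibrium_state` tibble, one row per species
#'   (`free_Ca`, `free_Mg`, `EGTA`, `HEGTA`, ..., `CaEGTA`, ...), with
#'   columns `species`, `conc_M`; attributes carry the totals, the adjusted
#'   constants, and the mass-balance residuals. Use [glance()] for a
#'   one-row summary with `free_Ca_M` and `free_Mg_M`.
#' @export
#' @examples
#' bath <- solution_from_salts(
#'   c(HNO3 = 200, EGTA = 2, CaCl2 = 2.08, MgCl2 = 2),
#'   btp_mM = 148, pH = 7, label = "100 uM free Ca bath")
#' glance(solve_equilibrium(bath))$free_Ca_M # about 1e-4
solve_equilibrium <- function(sol, constants = egta_constants(),
                              ionic_strength = NULL) {
  stopifnot(inherits(sol, "solution_spec"),
            inherits(constants, "binding_constants"))
  temperature <- attr(sol, "temperature")
  pH <- attr(sol, "pH")
  I <- ionic_strength %||% ionic_strength(sol)
  k <- .adjust_constants(constants, I, temperature)
  h <- 10^(-pH)
  K1 <- 10^k$pKa[1]; K2 <- 10^k$pKa[2]; K3 <- 10^k$pKa[3]; K4 <- 10^k$pKa[4]
  # cumulative protonation factors of the free ligand
  prot <- c(1, K1 * h, K1 * K2 * h^2, K1 * K2 * K3 * h^3,
            K1 * K2 * K3 * K4 * h^4)
  alpha <- sum(prot)
  bCa <- 10^k$logK[["CaEGTA"]] + 10^k$logK[["CaHEGTA"]] * K1 * h
  bMg <- 10^k$logK[["MgEGTA"]] + 10^k$logK[["MgHEGTA"]] * K1 * h
  tCa <- .total_M(sol, "Ca"); tMg <- .total_M(sol, "Mg")
  tL <- .total_M(sol, "EGTA")

  if (tL == 0) {
    free <- c(Ca = tCa, Mg = tMg, L = 0)
  } else {
    # unknown x = log10 of free Ca, Mg, L (absent metals held at zero)
    resid <- function(free) {
      c(free[1] * (1 + free[3] * bCa) - tCa,
        free[2] * (1 + free[3] * bMg) - tMg,
        free[3] * (alpha + free[1] * bCa + free[2] * bMg) - tL)
    }
    active <- c(tCa > 0, tMg > 0, TRUE)
    x <- log(pmax(c(tCa, tMg, tL), 1e-30))
    for (it in 1:200) {
      free <- exp(x)
      r <- resid(free)
      if (all(abs(r[active]) < 1e-15 + 1e-12 * c(tCa, tMg, tL)[active])) break
      # Jacobian wrt log-concentrations
      J <- matrix(0, 3, 3)
      J[1, 1] <- free[1] * (1 + free[3] * bCa)
      J[1, 3] <- free[1] * free[3] * bCa
      J[2, 2] <- free[2] * (1 + free[3] * bMg)
      J[2, 3] <- free[2] * free[3] * bMg
      J[3, 1] <- free[3] * free[1] * bCa
      J[3, 2] <- free[3] * free[2] * bMg
      J[3, 3] <- free[3] * (alpha + free[1] * bCa + free[2] * bMg)
      idx <- which(active)
      step <- rep(0, 3)
      step[idx] <- tryCatch(solve(J[idx, idx, drop = FALSE], r[idx]),
                            error = function(e) r[idx] / diag(J)[idx])
      step <- pmax(pmin(step, 2), -2)   # damping in log space
      x <- x - step
    }
    free <- exp(x)
    free[!active] <- 0
    r <- resid(free)
    if (any(abs(r[active]) > 1e-9)) {
      stop(sprintf(paste0("equilibrium solver did not converge: residuals ",
                          "(M) Ca %.3g, Mg %.3g, EGTA %.3g"),
                   r[1], r[2], r[3]), call. = FALSE)
    }
    names(free) <- c("Ca", "Mg", "L")
  }

  L <- unname(free["L"])
  species <- tibble::tibble(
    species = c("free_Ca", "free_Mg", "EGTA", "HEGTA", "H2EGTA", "H3EGTA",
                "H4EGTA", "CaEGTA", "CaHEGTA", "MgEGTA", "MgHEGTA"),
    conc_M = c(free[["Ca"]], free[["Mg"]], L * prot,
               free[["Ca"]] * L * 10^k$logK[["CaEGTA"]],
               free[["Ca"]] * L * 10^k$logK[["CaHEGTA"]] * K1 * h,
               free[["Mg"]] * L * 10^k$logK[["MgEGTA"]],
               free[["Mg"]] * L * 10^k$logK[["MgHEGTA"]] * K1 * h)
  )
  resids <- c(
    Ca = sum(species$conc_M[species$species %in%
                              c("free_Ca", "CaEGTA", "CaHEGTA")]) - tCa,
    Mg = sum(species$conc_M[species$species %in%
                              c("free_Mg", "MgEGTA", "MgHEGTA")]) - tMg,
    EGTA = sum(species$conc_M[!species$species %in%
                                c("free_Ca", "free_Mg")]) - tL
  )
  structure(species,
            class = c("equilibrium_state", class(tibble::tibble())),
            totals = c(Ca = tCa, Mg = tMg, EGTA = tL),
            pH = pH, temperature = temperature, ionic_strength = I,
            adjusted_logK = k$logK, residuals = resids,
            label = attr(sol, "label"))
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf("<equilibrium_state> %s  pH %.2f, I = %.3f M\n",
              attr(x, "label"), attr(x, "pH"), attr(x, "ionic_strength")))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.equilibrium_state <- function(x, ...) {
  r <- attr(x, "residuals")
  tibble::tibble(
    free_Ca_M = x$conc_M[x$species == "free_Ca"],
    free_Mg_M = x$conc_M[x$species == "free_Mg"],
    free_EGTA_M = sum(x$conc_M[x$species %in%
                                 c("EGTA", "HEGTA", "H2EGTA", "H3EGTA",
                                   "H4EGTA")]),
    ionic_strength = attr(x, "ionic_strength"),
    max_residual_M = max(abs(r))
  )
}

#' @exportS3Method generics::tidy
tidy.equilibrium_state <- function(x, ...) tibble::as_tibble(x)

#' Total salt needed to reach a target free-ion concentration
#'
#' Inverse buffer design: finds the total CaCl2 (or MgCl2) that makes
#' [solve_equilibrium()] return the requested free concentration, by
#' monotone root-finding on the total. This is the calculation the
#' MaxChelator-style tools perform when designing EGTA-buffered baths.
#'
#' @param target_free Target free concentration, M (0 < target < 1).
#' @param target_ion `"Ca"` or `"Mg"`.
#' @param sol A [solution()] giving the fixed totals (EGTA, the other
#'   metal); any existing total of `target_ion` is ignored.
#' @param constants A [egta_constants()] set.
#' @return Total salt to add, in mM, such that the solved free
#'   concentration matches `target_free` within 0.1 %.
#' @export
#' @examples
#' base <- solution_from_salts(c(HNO3 = 200, EGTA = 2, MgCl2 = 2),
#'                             btp_mM = 148, pH = 7)
#' design_total_for_target_free(10e-6, "Ca", base) # about 1.84 mM CaCl2
design_total_for_target_free <- function(target_free, target_ion = c("Ca", "Mg"),
                                         sol, constants = egta_constants()) {
  target_ion <- match.arg(target_ion)
  stopifnot(target_free > 0, target_free < 1)
  solved_free <- function(total_mM) {
    # the added salt is the chloride (CaCl2 / MgCl2): bring its counter-ion
    # along so the working ionic strength matches the real recipe
    df <- tibble::as_tibble(sol)
    prev <- df$mM[df$ion == target_ion]
    prev <- if (length(prev)) prev[1] else 0
    df <- df[df$ion != target_ion, , drop = FALSE]
    ref <- ion_reference()
    df <- rbind(df, tibble::tibble(ion = target_ion, mM = total_mM,
                                   charge = 2L,
                                   mobility = ref$mobility[ref$ion == target_ion],
                                   ion_size = ref$ion_size[ref$ion == target_ion]))
    if ("Cl" %in% df$ion) {
      df$mM[df$ion == "Cl"] <- df$mM[df$ion == "Cl"] + 2 * (total_mM - prev)
    } else {
      df <- rbind(df, tibble::tibble(ion = "Cl", mM = 2 * total_mM,
                                     charge = -1L,
                                     mobility = ref$mobility[ref$ion == "Cl"],
                                     ion_size = ref$ion_size[ref$ion == "Cl"]))
    }
    df$mM <- pmax(df$mM, 0)
    s2 <- solution(df, pH = attr(sol, "pH"),
                   temperature = attr(sol, "temperature"),
                   label = attr(sol, "label"))
    st <- solve_equilibrium(s2, constants)
    st$conc_M[st$species == paste0("free_", target_ion)]
  }
  # free is strictly increasing in total: bracket then bisect
  lo <- 0
  hi <- max(target_free * 1000 * 2, 2 * .total_M(sol, "EGTA") * 1000 + 1)
  for (i in 1:60) {
    if (solved_free(hi) >= target_free) break
    hi <- hi * 2
    if (hi > 2000) {
      stop("target free concentration unreachable with a non-negative total",
           call. = FALSE)
    }
  }
  root <- stats::uniroot(function(t) solved_free(t) - target_free,
                         c(lo, hi), tol = 1e-10)$root
  achieved <- solved_free(root)
  if (abs(achieved - target_free) > 1e-3 * target_free) {
    stop("root-finding did not reach the target within 0.1%", call. = FALSE)
  }
  root
}
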