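#' Molar ionic strength of a solution
#'
#' \eqn{I = \tfrac12 \sum_i c_i z_i^2} with concentrations in mol/L.
#' Species with charge 0 are rejected: neutral osmolytes and buffers do not
#' belong in the species table (only their charged forms do).
#'
#' @param sol A [solution()] object.
#' @return Ionic strength in M.
#' @export
#' @examples
#' s <- solution_from_salts(c(NaNO3 = 200, CaCl2 = 2, MgCl2 = 2))
#' ionic_strength(s) # 0.212
ionic_strength <- function(sol) {
  stopifnot(inherits(sol, "solution_spec"))
  if (nrow(sol) == 0L) return(0)
  if (any(sol$mM < 0)) stop("negative concentration", call. = FALSE)
  if (any(sol$charge == 0L)) {
    stop("species with charge 0 cannot enter the ionic-strength sum: ",
         paste(sol$ion[sol$charge == 0L], collapse = ", "), call. = FALSE)
  }
  sum(sol$mM / 1000 * sol$charge^2) / 2
}

# Debye-Hückel A coefficient (mol^-1/2 L^1/2) as a function of temperature;
# polynomial fit to the standard values for water (0.4918 at 0 degC,
# 0.5092 at 25 degC).
dh_A <- function(temperature) {
  tc <- temperature - 273.15
  0.4918 + 6.6098e-4 * tc + 5.028e-6 * tc^2
}

#' Single-ion activity coefficient
#'
#' Two standard dilute-solution models:
#' \describe{
#'   \item{`"davies"`}{\eqn{\log_{10}\gamma = -A z^2 (\sqrt I/(1+\sqrt I) - 0.3 I)}.
#'     Ion-size independent; the usual quick estimate up to I ~ 0.5 M.}
#'   \item{`"edh"`}{extended Debye-Hückel,
#'     \eqn{\log_{10}\gamma = -A z^2 \sqrt I/(1 + B a \sqrt I)} with
#'     \eqn{B = 0.329} Å\eqn{^{-1}} and the Kielland ion-size parameter
#'     \eqn{a}. This is the default model used by the reversal-potential
#'     functions, the standard choice in junction-potential and selectivity
#'     work.}
#' }
#'
#' @param charge Signed ion valence.
#' @param I Molar ionic strength (>= 0). Values above 0.7 M trigger a
#'   warning: both models are extrapolating there.
#' @param temperature Kelvin; sets the A coefficient.
#' @param method `"davies"` or `"edh"`.
#' @param ion_size Kielland parameter in Å (only for `"edh"`).
#' @return Dimensionless activity coefficient in (0, 1\].
#' @export
#' @examples
#' activity_coefficient(1, 0.1)            # ~0.78
#' activity_coefficient(2, 0.1)            # the z = 1 value to the 4th power
activity_coefficient <- function(charge, I, temperature = 295.15,
                                 method = c("davies", "edh"), ion_size = 4) {
  method <- match.arg(method)
  if (any(I < 0)) stop("ionic strength must be >= 0", call. = FALSE)
  if (any(I > 0.7)) {
    warning("ionic strength > 0.7 M: activity model outside its validity range")
  }
  A <- dh_A(temperature)
  sI <- sqrt(I)
  expo <- switch(method,
    davies = -A * charge^2 * (sI / (1 + sI) - 0.3 * I),
    edh    = -A * charge^2 * sI / (1 + 0.329 * ion_size * sI)
  )
  10^expo
}

#' Ion activities of every species in a solution
#'
#' @param sol A [solution()] object.
#' @inheritParams activity_coefficient
#' @return The solution tibble with extra columns `gamma` and `activity_mM`.
#' @export
ion_activities <- function(sol, method = c("edh", "davies")) {
  method <- match.arg(method)
  I <- ionic_strength(sol)
  out <- tibble::as_tibble(sol)
  out$gamma <- activity_coefficient(out$charge, I,
                                    temperature = attr(sol, "temperature"),
                                    method = method, ion_size = out$ion_size)
  out$activity_mM <- out$gamma * out$mM
  out
}
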