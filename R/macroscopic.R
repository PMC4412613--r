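#' Vacuole membrane geometry
#'
#' Membrane area for current-density normalisation, from exactly one of two
#' sizing routes: the optical diameter (sphere area \eqn{\pi d^2}) or the
#' membrane capacitance with a specific capacitance (default 10 mF/m²,
#' the usual biological-membrane value).
#'
#' @param diameter_um Vacuole diameter in µm.
#' @param capacitance_pF Membrane capacitance in pF.
#' @param specific_capacitance_mF_m2 Specific capacitance (mF/m²).
#' @return A one-row tibble with `area_m2` and the sizing source.
#' @export
#' @examples
#' vacuole_geometry(diameter_um = 20) # 1.257e-9 m2
vacuole_geometry <- function(diameter_um = NULL, capacitance_pF = NULL,
                             specific_capacitance_mF_m2 = 10) {
  if (is.null(diameter_um) == is.null(capacitance_pF)) {
    stop("set exactly one of `diameter_um` or `capacitance_pF`",
         call. = FALSE)
  }
  if (!is.null(diameter_um)) {
    stopifnot(diameter_um > 0)
    area <- pi * (diameter_um * 1e-6)^2
    src <- "diameter"
  } else {
    stopifnot(capacitance_pF > 0, specific_capacitance_mF_m2 > 0)
    area <- capacitance_pF * 1e-12 / (specific_capacitance_mF_m2 * 1e-3)
    src <- "capacitance"
  }
  tibble::tibble(area_m2 = area, sizing = src)
}

#' Steady-state current of a test sweep
#'
#' Mean current over the final fraction of the test segment, where the
#' slowly activating whole-vacuole current has reached its plateau.
#'
#' @param sweep Tibble with `current_pA` and, if protocol segments are
#'   present, `segment` (only `"test"` samples are used).
#' @param window_fraction Final fraction of the segment to average
#'   (0 < f <= 0.5; default 0.1, the last 10 % of a 3 s pulse).
#' @return Steady-state current in pA.
#' @export
steady_state_current <- function(sweep, window_fraction = 0.1) {
  stopifnot(window_fraction > 0, window_fraction <= 0.5)
  x <- if ("segment" %in% names(sweep)) {
    sweep[sweep$segment == "test", , drop = FALSE]
  } else sweep
  n <- nrow(x)
  if (n < 10L) stop("test segment shorter than 10 samples", call. = FALSE)
  k <- max(1L, floor(n * window_fraction))
  mean(x$current_pA[(n - k + 1L):n])
}

#' Current density
#'
#' \eqn{J = I / A} in A/m² from a current in pA and a
#' [vacuole_geometry()].
#'
#' @param current_pA Current in pA.
#' @param geometry A [vacuole_geometry()] row (or anything with `area_m2`).
#' @return Current density in A/m².
#' @export
#' @examples
#' current_density(1330, vacuole_geometry(diameter_um = 20)) # ~1.06 A/m2
current_density <- function(current_pA, geometry) {
  area <- geometry$area_m2
  if (is.null(area) || any(area <= 0)) stop("invalid membrane area",
                                            call. = FALSE)
  current_pA * 1e-12 / area
}

#' Aggregate per-vacuole J/V curves
#'
#' Pointwise mean ± SEM over vacuoles, on a common voltage grid. Voltages
#' are matched exactly (junction-shifted grids such as -94...+86 mV are
#' kept as recorded and never interpolated); an error is raised if the
#' grids differ.
#'
#' @param curves A list of data frames (or one long data frame with a
#'   `vacuole` column), each with `voltage_mV` and `J_A_m2`.
#' @param label Curve label.
#' @return A `jv_curve` tibble: `voltage_mV`, `J_A_m2` (mean), `sd`, `sem`
#'   (NA when n = 1), `n`.
#' @export
aggregate_jv <- function(curves, label = "") {
  if (is.data.frame(curves)) {
    stopifnot("vacuole" %in% names(curves))
    curves <- split(curves[c("voltage_mV", "J_A_m2")], curves$vacuole)
  }
  stopifnot(length(curves) >= 1)
  grids <- purrr::map(curves, function(d) sort(d$voltage_mV))
  if (length(curves) > 1 &&
      !all(purrr::map_lgl(grids[-1], identical, grids[[1]]))) {
    stop("voltage grids differ between vacuoles; align before aggregating",
         call. = FALSE)
  }
  long <- purrr::list_rbind(purrr::map(curves, tibble::as_tibble),
                            names_to = "vacuole")
  out <- long |>
    dplyr::group_by(voltage_mV = .data$voltage_mV) |>
    dplyr::summarise(
      J_mean = mean(.data$J_A_m2),
      sd = if (dplyr::n() > 1) stats::sd(.data$J_A_m2) else NA_real_,
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(sem = .data$sd / sqrt(.data$n)) |>
    dplyr::rename(J_A_m2 = "J_mean") |>
    dplyr::arrange(.data$voltage_mV) |>
    dplyr::select("voltage_mV", "J_A_m2", "sd", "sem", "n")
  structure(out, class = c("jv_curve", class(tibble::tibble())),
            label = label)
}
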