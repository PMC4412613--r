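#' Reference table of ion properties
#'
#' Charges, limiting equivalent conductances and Debye-Hückel ion-size
#' parameters for the ions used in vacuolar patch-clamp solutions.
#'
#' * `charge` — signed valence.
#' * `mobility` — limiting equivalent conductance \eqn{\lambda_0}
#'   (S cm\eqn{^2} eq\eqn{^{-1}}, 25 °C) from standard conductance tables
#'   (Robinson & Stokes). Only relative magnitudes matter in the Henderson
#'   equation, so these are used unscaled. The bis-tris-propane cations are
#'   assigned the Tris value (no measurement exists for BTP); override by
#'   passing an explicit `mobility` column to [solution()].
#' * `ion_size` — Kielland ion-size parameter \eqn{a} (Å) for the extended
#'   Debye-Hückel activity model. Buffer cations and EGTA, which Kielland
#'   does not list, carry rounded values typical of organic ions of their
#'   size and are flagged `approximate`.
#'
#' @return A tibble with columns `ion`, `charge`, `mobility`, `ion_size`,
#'   `approximate`.
#' @export
#' @examples
#' ion_reference()
ion_reference <- function() {
  tibble::tribble(
    ~ion,     ~charge, ~mobility, ~ion_size, ~approximate,
    "H",       1L,      349.8,     9.0,      FALSE,
    "Na",      1L,       50.1,     4.5,      FALSE,
    "K",       1L,       73.5,     3.0,      FALSE,
    "NH4",     1L,       73.5,     2.5,      FALSE,
    "Ca",      2L,       59.5,     6.0,      FALSE,
    "Mg",      2L,       53.1,     8.0,      FALSE,
    "Cl",     -1L,       76.4,     3.0,      FALSE,
    "NO3",    -1L,       71.5,     3.0,      FALSE,
    "OH",     -1L,      198.6,     3.5,      FALSE,
    "BTPH",    1L,       29.5,     4.0,      TRUE,
    "BTPH2",   2L,       29.5,     4.0,      TRUE,
    "TRISH",   1L,       29.5,     4.0,      TRUE,
    "EGTA",   -2L,       25.0,     5.0,      TRUE
  )
}

#' Build a solution specification
#'
#' A solution is a tibble of ionic species (one row per ion) carrying the
#' bulk properties pH, temperature and a label as attributes. Concentrations
#' are totals in mM; charges, mobilities and ion sizes default to
#' [ion_reference()] values when omitted.
#'
#' @param species Data frame with columns `ion` and `mM`, and optionally
#'   `charge`, `mobility`, `ion_size`.
#' @param pH Solution pH (meter reading). Must lie in \[3, 10\].
#' @param temperature Absolute temperature in K (default 295.15 K = 22 °C,
#'   the growth temperature of the cultures; recording temperature is taken
#'   to be the same). Must lie in \[273, 310\].
#' @param label Free-text label.
#' @return A `solution_spec` tibble with columns `ion`, `mM`, `charge`,
#'   `mobility`, `ion_size`.
#' @export
#' @examples
#' solution(data.frame(ion = c("Na", "NO3"), mM = c(200, 200)), pH = 7)
solution <- function(species, pH = 7, temperature = 295.15, label = "") {
  stopifnot(is.data.frame(species), all(c("ion", "mM") %in% names(species)))
  if (!is.numeric(pH) || length(pH) != 1L || pH < 3 || pH > 10) {
    stop("`pH` must be a single value in [3, 10]", call. = FALSE)
  }
  if (!is.numeric(temperature) || temperature < 273 || temperature > 310) {
    stop("`temperature` must be in [273, 310] K", call. = FALSE)
  }
  if (any(!is.finite(species$mM)) || any(species$mM < 0)) {
    stop("species concentrations must be finite and non-negative", call. = FALSE)
  }
  out <- tibble::as_tibble(species)
  ref <- ion_reference()
  idx <- match(out$ion, ref$ion)
  if (!"charge" %in% names(out)) out$charge <- ref$charge[idx]
  if (!"mobility" %in% names(out)) out$mobility <- ref$mobility[idx]
  if (!"ion_size" %in% names(out)) out$ion_size <- ref$ion_size[idx]
  if (anyNA(out$charge)) {
    stop("no default charge for ion(s): ",
         paste(out$ion[is.na(out$charge)], collapse = ", "),
         "; supply a `charge` column", call. = FALSE)
  }
  out <- out[, c("ion", "mM", "charge", "mobility", "ion_size")]
  structure(out,
            class = c("solution_spec", class(tibble::tibble())),
            pH = pH, temperature = temperature, label = label)
}

#' @export
print.solution_spec <- function(x, ...) {
  cat(sprintf("<solution_spec> %s  pH %.2f, %.2f K\n",
              attr(x, "label"), attr(x, "pH"), attr(x, "temperature")))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Build a solution from salt totals
#'
#' Convenience constructor mirroring how patch-clamp recipes are written:
#' fully dissociated salts plus a bis-tris-propane (BTP) buffer. The strong
#' acids HNO3 and HCl are assumed titrated by the buffer, so their protons
#' appear as protonated buffer cations rather than free H+; BTP is
#' partitioned between BTPH+ and BTPH2(2+) from its two pKa values at the
#' solution pH. EGTA is carried as a divalent anion for ionic-strength
#' purposes (its dominant forms near pH 7 — H2EGTA(2-), CaEGTA(2-),
#' MgEGTA(2-) — all carry charge -2).
#'
#' @param salts Named numeric vector of salt totals in mM. Recognised names:
#'   `NaNO3`, `HNO3`, `HCl`, `KCl`, `NaCl`, `CaCl2`, `MgCl2`, `EGTA`.
#' @param btp_mM Total bis-tris propane in mM.
#' @param pH,temperature,label Passed to [solution()].
#' @param btp_pKa Two pKa values of BTP (first and second protonation).
#' @return A `solution_spec`.
#' @export
#' @examples
#' solution_from_salts(c(HNO3 = 200, CaCl2 = 2, MgCl2 = 2), btp_mM = 160, pH = 7)
solution_from_salts <- function(salts, btp_mM = 0, pH = 7, temperature = 295.15,
                                label = "", btp_pKa = c(9.0, 6.8)) {
  known <- list(
    NaNO3 = c(Na = 1, NO3 = 1),
    HNO3  = c(NO3 = 1),
    HCl   = c(Cl = 1),
    KCl   = c(K = 1, Cl = 1),
    NaCl  = c(Na = 1, Cl = 1),
    CaCl2 = c(Ca = 1, Cl = 2),
    MgCl2 = c(Mg = 1, Cl = 2),
    EGTA  = c(EGTA = 1)
  )
  bad <- setdiff(names(salts), names(known))
  if (length(bad)) stop("unrecognised salt(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  tot <- c(Na = 0, K = 0, Ca = 0, Mg = 0, Cl = 0, NO3 = 0, EGTA = 0)
  for (s in names(salts)) {
    contrib <- known[[s]] * salts[[s]]
    tot[names(contrib)] <- tot[names(contrib)] + contrib
  }
  df <- data.frame(ion = names(tot), mM = unname(tot))
  if (btp_mM > 0) {
    # diprotic base: fractions of BTPH+ and BTPH2(2+) at the meter pH
    k1 <- 10^(btp_pKa[1] - pH)              # [BTPH]/[BTP]
    k2 <- 10^(btp_pKa[2] - pH)              # [BTPH2]/[BTPH]
    denom <- 1 + k1 + k1 * k2
    df <- rbind(df, data.frame(
      ion = c("BTPH", "BTPH2"),
      mM  = btp_mM * c(k1, k1 * k2) / denom
    ))
  }
  df <- df[df$mM > 0, , drop = FALSE]
  solution(df, pH = pH, temperature = temperature, label = label)
}

#' Read / write a solution specification as YAML
#'
#' The on-disk form is a mapping `{label, temperature_K, pH, species:
#' [{name, charge, mM, mobility, ion_size}]}`.
#'
#' @param path File path.
#' @return `read_solution()` returns a `solution_spec`; `write_solution()`
#'   returns `path` invisibly.
#' @export
read_solution <- function(path) {
  doc <- yaml::read_yaml(path)
  sp <- purrr::map_dfr(doc$species, function(s) {
    tibble::tibble(
      ion = s$name, mM = s$mM,
      charge = if (is.null(s$charge)) NA_integer_ else as.integer(s$charge),
      mobility = if (is.null(s$mobility)) NA_real_ else s$mobility,
      ion_size = if (is.null(s$ion_size)) NA_real_ else s$ion_size
    )
  })
  ref <- ion_reference()
  idx <- match(sp$ion, ref$ion)
  sp$charge <- ifelse(is.na(sp$charge), ref$charge[idx], sp$charge)
  sp$mobility <- ifelse(is.na(sp$mobility), ref$mobility[idx], sp$mobility)
  sp$ion_size <- ifelse(is.na(sp$ion_size), ref$ion_size[idx], sp$ion_size)
  solution(sp, pH = doc$pH, temperature = doc$temperature_K,
           label = doc$label %||% "")
}

#' @rdname read_solution
#' @param sol A `solution_spec`.
#' @export
write_solution <- function(sol, path) {
  stopifnot(inherits(sol, "solution_spec"))
  doc <- list(
    label = attr(sol, "label"),
    temperature_K = attr(sol, "temperature"),
    pH = attr(sol, "pH"),
    species = purrr::pmap(
      list(sol$ion, sol$mM, sol$charge, sol$mobility, sol$ion_size),
      function(n, c_, z, u, a) list(name = n, mM = c_, charge = z,
                                    mobility = u, ion_size = a)
    )
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}
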