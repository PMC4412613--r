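#' Read and validate a pipeline run configuration
#'
#' A run configuration is a YAML document (or equivalent R list) with:
#' \describe{
#'   \item{seed}{integer, mandatory — every stochastic stage derives its
#'     RNG stream from it.}
#'   \item{protocol}{arguments for [make_step_protocol()].}
#'   \item{analysis}{`bin_width_pA`, `window_fraction`, `max_channels`,
#'     `analysis_duration_s`, `diameter_um` — all optional, defaults are
#'     filled in and echoed into the report (no silent defaults).}
#'   \item{conditions}{list of gating-model presets, each with `label` and
#'     [gating_model()] arguments plus `analysis_voltage_mV` and optional
#'     `noise_sd`.}
#'   \item{electrochem}{optional: named solution recipes (passed to
#'     [solution_from_salts()]) plus `nernst` / `permeability` requests.}
#'   \item{chelation}{optional: named recipes to run through
#'     [solve_equilibrium()].}
#' }
#'
#' @param config Path to a YAML file, or a list.
#' @return Validated config list with defaults filled in.
#' @export
read_run_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$seed)) stop("config must set `seed`", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  defaults <- list(bin_width_pA = 0.1, window_fraction = 0.1,
                   max_channels = 4, analysis_duration_s = 30,
                   diameter_um = 20, settle_s = 5e-3)
  cfg$analysis <- utils::modifyList(defaults, cfg$analysis %||% list())
  cfg$protocol <- cfg$protocol %||% list()
  cfg$conditions <- cfg$conditions %||% list()
  labs <- purrr::map_chr(cfg$conditions, function(cd) cd$label %||% "")
  if (any(labs == "") && length(cfg$conditions)) {
    stop("every condition needs a `label`", call. = FALSE)
  }
  cfg
}

.build_condition_model <- function(cd) {
  args <- cd[intersect(names(cd),
                       c("n_channels", "open_rate", "close_rate", "po",
                         "conductance_pS", "reversal_mV", "v_half", "slope"))]
  do.call(gating_model, args)
}

.solution_from_config <- function(sc) {
  solution_from_salts(
    salts = unlist(sc$salts),
    btp_mM = sc$btp_mM %||% 0,
    pH = sc$pH %||% 7,
    temperature = sc$temperature_K %||% 295.15,
    label = sc$label %||% ""
  )
}

#' Run the full simulation-and-analysis pipeline
#'
#' For each configured condition: simulate the voltage-step family, extract
#' steady-state currents into an I/V curve, simulate a long recording at
#' the analysis voltage, build the amplitude histogram, fit the Gaussian
#' mixture, and report channel count, open probability, unitary current and
#' chord conductance; optionally compute the electrochemistry (Nernst, GHK
#' permeability ratio, junction potential) and chelation (free Ca/Mg)
#' tables from the configured recipes. All intermediate artifacts (traces,
#' histograms, fits, curves) are written under `out_dir` together with a
#' machine-readable `report.json`. Deterministic for a given seed.
#'
#' @param config Path to a YAML config or a list; see [read_run_config()].
#' @param out_dir Output directory (created if needed). `NULL` keeps
#'   everything in memory.
#' @return A `run_report` list: `conditions` tibble (truth and estimates),
#'   `iv` (list of `iv_curve`s), `electrochem`, `chelation`, `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  an <- cfg$analysis
  protocol <- do.call(make_step_protocol, cfg$protocol)

  cond_rows <- list()
  ivs <- list()
  mixes <- list()
  for (ci in seq_along(cfg$conditions)) {
    cd <- cfg$conditions[[ci]]
    tick <- proc.time()[["elapsed"]]
    model <- .build_condition_model(cd)
    vstar <- cd$analysis_voltage_mV %||% -80
    noise <- cd$noise_sd %||% 0.5
    seed_i <- cfg$seed + 100000L * ci

    sweeps <- simulate_patch_current(model, protocol, noise_sd = noise,
                                     seed = seed_i)
    iv <- sweeps |>
      dplyr::group_by(.data$sweep) |>
      dplyr::group_modify(function(d, key) tibble::tibble(
        voltage_mV = d$voltage_mV[d$segment == "test"][1],
        current_pA = steady_state_current(d, an$window_fraction))) |>
      dplyr::ungroup() |>
      build_iv_curve(label = cd$label)
    e_rev <- tryCatch(estimate_reversal(iv), error = function(e) NA_real_)

    long <- simulate_patch_current(model, vstar, noise_sd = noise,
                                   seed = seed_i + 1L,
                                   duration_s = an$analysis_duration_s)
    hist <- build_amplitude_histogram(long, an$bin_width_pA,
                                      segment = "test",
                                      settle_s = an$settle_s)
    mix <- fit_peak_mixture(hist, max_channels = an$max_channels)
    g <- glance(mix)
    truth_v <- gating_at_voltage(model, vstar)
    cond_rows[[ci]] <- tibble::tibble(
      label = cd$label,
      voltage_mV = vstar,
      n_channels_true = model$n_channels,
      po_true = truth_v$po,
      g_true_pS = model$conductance_pS,
      n_channels_est = g$n_channels,
      po_est = g$po,
      unitary_current_pA = g$unitary_current_pA,
      g_est_pS = if (is.na(g$unitary_current_pA)) NA_real_ else
        chord_conductance_extreme_voltage(g$unitary_current_pA,
                                          voltage_mV = vstar),
      e_rev_iv_mV = e_rev
    )
    ivs[[cd$label]] <- iv
    mixes[[cd$label]] <- mix
    if (!is.null(out_dir)) {
      write_trace(sweeps, file.path(out_dir,
                                    paste0("traces_", cd$label, ".csv")))
      utils::write.csv(as.data.frame(hist),
                       file.path(out_dir, paste0("hist_", cd$label, ".csv")),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(iv),
                       file.path(out_dir, paste0("iv_", cd$label, ".csv")),
                       row.names = FALSE)
      jsonlite::write_json(
        list(peaks = as.data.frame(mix), n_channels = attr(mix, "n_channels"),
             po = g$po, unitary_current_pA = g$unitary_current_pA),
        file.path(out_dir, paste0("mixture_", cd$label, ".json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    timings[[paste0("condition_", cd$label)]] <-
      round(proc.time()[["elapsed"]] - tick, 3)
  }
  conditions <- if (length(cond_rows)) purrr::list_rbind(cond_rows) else
    tibble::tibble()

  electro <- NULL
  if (!is.null(cfg$electrochem)) {
    tick <- proc.time()[["elapsed"]]
    sols <- purrr::map(cfg$electrochem$solutions, .solution_from_config)
    names(sols) <- purrr::map_chr(cfg$electrochem$solutions,
                                  function(s) s$name)
    rows <- list()
    for (rq in cfg$electrochem$nernst %||% list()) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        quantity = paste0("E_", rq$ion),
        value_mV = nernst_potential(rq$ion, sols[[rq$cytoplasmic]],
                                    sols[[rq$vacuolar]]))
    }
    for (rq in cfg$electrochem$junction %||% list()) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        quantity = paste0("LJP_", rq$pipette, "_vs_", rq$bath),
        value_mV = henderson_junction_potential(sols[[rq$pipette]],
                                                sols[[rq$bath]]))
    }
    pr <- NULL
    for (rq in cfg$electrochem$permeability %||% list()) {
      pr <- fit_permeability_ratio(rq$erev_mV, rq$test_ion, rq$reference_ion,
                                   sols[[rq$cytoplasmic]],
                                   sols[[rq$vacuolar]])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        quantity = paste0("P_", rq$test_ion, "/P_", rq$reference_ion),
        value_mV = pr$permeability_ratio)
    }
    electro <- purrr::list_rbind(rows)
    timings$electrochem <- round(proc.time()[["elapsed"]] - tick, 3)
  }

  chel <- NULL
  if (!is.null(cfg$chelation)) {
    tick <- proc.time()[["elapsed"]]
    chel <- purrr::map_dfr(cfg$chelation$recipes, function(rc) {
      st <- solve_equilibrium(.solution_from_config(rc))
      gl <- glance(st)
      tibble::tibble(label = rc$label %||% rc$name %||% "",
                     free_Ca_uM = gl$free_Ca_M * 1e6,
                     free_Mg_mM = gl$free_Mg_M * 1e3,
                     ionic_strength_M = gl$ionic_strength)
    })
    timings$chelation <- round(proc.time()[["elapsed"]] - tick, 3)
  }

  timings$total <- round(proc.time()[["elapsed"]] - t0, 3)
  report <- list(
    conditions = conditions,
    iv = ivs,
    mixtures = mixes,
    electrochem = electro,
    chelation = chel,
    provenance = list(seed = cfg$seed,
                      analysis = an,
                      n_conditions = length(cfg$conditions),
                      package_version = as.character(
                        utils::packageVersion("vactrace")),
                      timings = timings)
  )
  class(report) <- "run_report"
  if (!is.null(out_dir)) {
    json <- list(
      conditions = as.data.frame(conditions),
      electrochem = if (!is.null(electro)) as.data.frame(electro),
      chelation = if (!is.null(chel)) as.data.frame(chel),
      provenance = report$provenance[c("seed", "analysis", "n_conditions",
                                       "package_version")]
    )
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$provenance$seed, "\n")
  if (nrow(x$conditions %||% tibble::tibble())) {
    print(x$conditions, ...)
  }
  if (!is.null(x$electrochem)) print(x$electrochem, ...)
  if (!is.null(x$chelation)) print(x$chelation, ...)
  invisible(x)
}
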