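#' Voltage-step protocol
#'
#' The standard stimulation pattern: a holding segment, a family of test
#' steps spanning a voltage range, and a tail segment. Defaults follow the
#' recording protocol used throughout the package's target experiments:
#' 0.5 s holding, 3 s test steps in 20 mV increments, 0.3 s tail.
#'
#' @param holding_mV,holding_s Holding voltage (mV) and duration (s).
#' @param test_start_mV,test_stop_mV,test_step_mV Test-step range; the step
#'   must divide the range exactly.
#' @param test_s Test-step duration (s).
#' @param tail_mV,tail_s Tail (post-pulse) voltage and duration.
#' @return A `step_protocol` tibble with one row per sweep: `sweep`,
#'   `holding_mV`, `test_mV`, `tail_mV` and the three durations.
#' @export
#' @examples
#' make_step_protocol(test_start_mV = -100, test_stop_mV = 80) # 10 sweeps
make_step_protocol <- function(holding_mV = 0, holding_s = 0.5,
                               test_start_mV = -100, test_stop_mV = 80,
                               test_step_mV = 20, test_s = 3,
                               tail_mV = holding_mV, tail_s = 0.3) {
  stopifnot(holding_s > 0, test_s > 0, tail_s > 0, test_step_mV != 0)
  n_steps <- (test_stop_mV - test_start_mV) / test_step_mV
  if (n_steps < 0 || abs(n_steps - round(n_steps)) > 1e-9) {
    stop("test_step_mV must divide (test_stop_mV - test_start_mV) exactly",
         call. = FALSE)
  }
  test_mV <- test_start_mV + test_step_mV * 0:round(n_steps)
  tibble::tibble(
    sweep = seq_along(test_mV),
    holding_mV = holding_mV, holding_s = holding_s,
    test_mV = test_mV, test_s = test_s,
    tail_mV = tail_mV, tail_s = tail_s
  )
}

#' Two-state gating model of an ion-channel population
#'
#' `n_channels` identical, independent channels, each switching between a
#' closed and an open state with opening rate `open_rate` (\eqn{\alpha}) and
#' closing rate `close_rate` (\eqn{\beta}); stationary open probability
#' \eqn{P_o = \alpha/(\alpha+\beta)}. The open-channel current is the linear
#' chord model \eqn{i(V) = g\,(V - E_{rev})} (conductances are reported as
#' current/voltage ratios, so no GHK flux rectification is modelled).
#' Voltage dependence, when wanted, enters as a Boltzmann factor
#' \eqn{\exp((V - V_{1/2})/s)} on the \eqn{\alpha/\beta} ratio (applied
#' symmetrically: \eqn{\alpha} is multiplied and \eqn{\beta} divided by its
#' square root).
#'
#' @param n_channels Integer >= 1.
#' @param open_rate,close_rate Rates in 1/s, both > 0.
#' @param conductance_pS Unitary conductance g in pS.
#' @param reversal_mV Reversal potential of the chord model.
#' @param v_half,slope Optional Boltzmann modulation of alpha/beta
#'   (mV; `slope` > 0 favours opening at positive voltages, < 0 at negative
#'   ones). `NULL` disables voltage dependence.
#' @param po Convenience alternative to `open_rate`: stationary open
#'   probability; `open_rate` is then derived from `close_rate`.
#' @return A `gating_model` list.
#' @export
#' @examples
#' gating_model(1, po = 0.39, conductance_pS = 95.5)
gating_model <- function(n_channels = 1, open_rate = NULL, close_rate = 40,
                         conductance_pS = 95.5, reversal_mV = 0,
                         v_half = NULL, slope = NULL, po = NULL) {
  if (!is.null(po)) {
    stopifnot(po > 0, po < 1)
    open_rate <- close_rate * po / (1 - po)
  }
  stopifnot(n_channels >= 1, open_rate > 0, close_rate > 0,
            conductance_pS > 0)
  structure(list(n_channels = as.integer(n_channels),
                 open_rate = open_rate, close_rate = close_rate,
                 conductance_pS = conductance_pS, reversal_mV = reversal_mV,
                 v_half = v_half, slope = slope),
            class = "gating_model")
}

#' @param x A `gating_model`.
#' @param voltage_mV Voltage at which to evaluate.
#' @describeIn gating_model voltage-resolved rates, stationary Po and
#'   open-channel current.
#' @export
gating_at_voltage <- function(x, voltage_mV) {
  a <- x$open_rate; b <- x$close_rate
  if (!is.null(x$v_half) && !is.null(x$slope)) {
    f <- exp((voltage_mV - x$v_half) / x$slope)
    a <- a * sqrt(f); b <- b / sqrt(f)
  }
  tibble::tibble(voltage_mV = voltage_mV, open_rate = a, close_rate = b,
                 po = a / (a + b),
                 i_pA = x$conductance_pS * (voltage_mV - x$reversal_mV) / 1000)
}

#' @export
print.gating_model <- function(x, ...) {
  cat(sprintf(
    "<gating_model> %d channel(s), alpha %.3g /s, beta %.3g /s (Po %.3g), g %.4g pS, E_rev %.3g mV\n",
    x$n_channels, x$open_rate, x$close_rate,
    x$open_rate / (x$open_rate + x$close_rate), x$conductance_pS,
    x$reversal_mV))
  invisible(x)
}

# exact two-state trajectory over [0, dur): event-driven exponential dwell
# sampling, discretised sample-and-hold onto a uniform grid. Returns the
# number of open channels at each of n samples. State at t=0 drawn from the
# stationary distribution.
.simulate_open_count <- function(n_channels, a, b, dur, rate) {
  n <- round(dur * rate)
  open_count <- integer(n)
  dt <- 1 / rate
  for (ch in seq_len(n_channels)) {
    state <- stats::runif(1) < a / (a + b)   # TRUE = open
    t <- 0
    open <- logical(n)
    while (t < dur) {
      dwell <- stats::rexp(1, if (state) b else a)
      t2 <- min(t + dwell, dur)
      if (state) {
        # sample-and-hold: sample k holds the state at time (k-1)*dt
        i1 <- max(1L, ceiling(t / dt - 1e-12) + 1L)
        i2 <- min(n, floor(t2 / dt - 1e-12) + 1L)
        if (i2 >= i1) open[i1:i2] <- TRUE
      }
      t <- t + dwell
      state <- !state
    }
    open_count <- open_count + open
  }
  open_count
}

#' Simulate patch-clamp current under a step protocol
#'
#' Per sweep, each channel's closed/open trajectory is simulated by exact
#' exponential dwell-time sampling (event-driven, so no per-sample Bernoulli
#' bias), discretised at the sampling rate by sample-and-hold. The current
#' is the summed open-channel chord current plus Gaussian baseline noise,
#' then low-pass filtered with [apply_recording_filter()] unless
#' `filter_hz = NULL`. Sweep k uses RNG seed `seed + 1000 * k`, so single
#' sweeps are reproducible in isolation.
#'
#' @param model A [gating_model()].
#' @param protocol A [make_step_protocol()] table, or a single voltage in mV
#'   (then `duration_s` applies).
#' @param noise_sd Gaussian noise sd in pA, added before filtering
#'   (default 0.5 pA, typical of the emulated recordings).
#' @param seed Mandatory integer seed.
#' @param sampling_hz,filter_hz Sampling rate and low-pass cutoff (10 kHz /
#'   2 kHz, the recording settings of the emulated experiments).
#' @param duration_s Sweep duration when `protocol` is a bare voltage.
#' @param configuration Metadata tag: `"cytoplasm-out"` or
#'   `"whole-vacuole"`.
#' @return A `trace_set` tibble with columns `sweep`, `segment`
#'   (holding/test/tail), `time_s`, `voltage_mV`, `current_pA`, `n_open`
#'   (ground truth); attributes `sampling_hz`, `filter_hz`, `seed`,
#'   `configuration`, `model`.
#' @export
#' @examples
#' m <- gating_model(1, po = 0.39, conductance_pS = 95.5)
#' tr <- simulate_patch_current(m, protocol = -80, duration_s = 1, seed = 1)
#' mean(tr$n_open) # close to 0.39
simulate_patch_current <- function(model, protocol, noise_sd = 0.5, seed,
                                   sampling_hz = 10000, filter_hz = 2000,
                                   duration_s = 3,
                                   configuration = "cytoplasm-out") {
  stopifnot(inherits(model, "gating_model"), noise_sd >= 0)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (is.numeric(protocol) && is.null(dim(protocol))) {
    protocol <- tibble::tibble(sweep = 1L, holding_mV = protocol,
                               holding_s = 0, test_mV = protocol,
                               test_s = duration_s, tail_mV = protocol,
                               tail_s = 0)
  }
  sweeps <- purrr::pmap_dfr(protocol, function(sweep, holding_mV, holding_s,
                                               test_mV, test_s, tail_mV,
                                               tail_s, ...) {
    set.seed(seed + 1000L * sweep)
    segs <- tibble::tibble(
      segment = c("holding", "test", "tail"),
      voltage = c(holding_mV, test_mV, tail_mV),
      dur = c(holding_s, test_s, tail_s)
    )
    segs <- segs[segs$dur > 0, , drop = FALSE]
    out <- purrr::pmap_dfr(segs, function(segment, voltage, dur) {
      gv <- gating_at_voltage(model, voltage)
      if (1 / (gv$open_rate + gv$close_rate) < 2 / sampling_hz) {
        warning("mean dwell time below 2 sampling intervals: ",
                "open/closed events will alias", call. = FALSE)
      }
      n_open <- .simulate_open_count(model$n_channels, gv$open_rate,
                                     gv$close_rate, dur, sampling_hz)
      n <- length(n_open)
      tibble::tibble(
        segment = segment,
        voltage_mV = voltage,
        current_pA = n_open * gv$i_pA + stats::rnorm(n, 0, noise_sd),
        n_open = n_open
      )
    })
    out$time_s <- (seq_len(nrow(out)) - 1) / sampling_hz
    out$sweep <- sweep
    out[, c("sweep", "segment", "time_s", "voltage_mV", "current_pA",
            "n_open")]
  })
  res <- structure(sweeps,
                   class = c("trace_set", class(tibble::tibble())),
                   sampling_hz = sampling_hz, filter_hz = NA_real_,
                   seed = seed, configuration = configuration, model = model,
                   noise_sd = noise_sd)
  if (!is.null(filter_hz) && is.finite(filter_hz)) {
    res <- apply_recording_filter(res, filter_hz)
  }
  res
}

# 4-pole Bessel low-pass as a digital filter (bilinear transform with
# prewarping). The analog prototype poles are the roots of the reversed
# Bessel polynomial s^4 + 10 s^3 + 45 s^2 + 105 s + 105, rescaled so the
# -3 dB point sits at w = 1; the scale factor is found numerically once.
.bessel4_coeff <- function(cutoff_hz, sampling_hz) {
  p <- polyroot(c(105, 105, 45, 10, 1))
  gain2 <- function(w) {
    h <- prod(Mod(-p)) / prod(Mod(1i * w - p))
    h^2
  }
  w3 <- stats::uniroot(function(w) gain2(w) - 0.5, c(0.5, 4), tol = 1e-12)$root
  p <- p / w3                        # 3 dB-normalised prototype poles
  warp <- 2 * sampling_hz * tan(pi * cutoff_hz / sampling_hz)
  p <- p * warp
  # bilinear transform: z = (1 + s/(2 fs)) / (1 - s/(2 fs))
  fs2 <- 2 * sampling_hz
  zp <- (1 + p / fs2) / (1 - p / fs2)
  a <- Re(poly_from_roots(zp))
  b <- Re(poly_from_roots(rep(-1 + 0i, 4)))
  b <- b * sum(a) / sum(b)           # unit DC gain
  list(b = b, a = a)
}

# monic polynomial coefficients (descending powers) from complex roots
poly_from_roots <- function(r) {
  coef <- 1
  for (rt in r) coef <- c(coef, 0) - c(0, coef * rt)
  coef
}

#' Apply the recording low-pass filter to a trace set
#'
#' Causal 4-pole Bessel-type low-pass, the digital analogue of the analog
#' filter in the recording chain. DC gain is exactly 1, so plateau levels
#' and histogram peak positions are preserved. Applied per sweep.
#'
#' @param traces A `trace_set` (or any tibble with `sweep` and
#'   `current_pA`).
#' @param cutoff_hz -3 dB cutoff; must be below Nyquist.
#' @param sampling_hz Sampling rate; taken from the trace attributes when
#'   present.
#' @return The trace set with filtered `current_pA` and the `filter_hz`
#'   attribute set.
#' @export
apply_recording_filter <- function(traces, cutoff_hz,
                                   sampling_hz = attr(traces, "sampling_hz")) {
  if (is.null(sampling_hz)) stop("sampling rate unknown", call. = FALSE)
  if (cutoff_hz >= sampling_hz / 2) {
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  }
  co <- .bessel4_coeff(cutoff_hz, sampling_hz)
  at <- attributes(traces)
  out <- traces |>
    dplyr::group_by(.data$sweep) |>
    dplyr::mutate(current_pA = as.numeric(
      signal::filter(signal::Arma(co$b, co$a), .data$current_pA))) |>
    dplyr::ungroup()
  for (nm in setdiff(names(at), c("names", "row.names"))) {
    attr(out, nm) <- at[[nm]]
  }
  attr(out, "filter_hz") <- cutoff_hz
  class(out) <- unique(c("trace_set", class(out)))
  out
}
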