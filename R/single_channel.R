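#' Amplitude histogram of a current trace
#'
#' Fixed-width binning of the current samples, the raw material for the
#' Gaussian-mixture level analysis. By default only the quasi-stationary
#' part of each test segment enters: the first `settle_s` seconds after the
#' step (ten filter time constants at the default 2 kHz cutoff) are
#' discarded so capacitive/settling samples do not blur the peaks.
#'
#' @param traces A `trace_set` tibble (or any tibble with `current_pA`;
#'   with `segment`/`time_s` columns the test-segment windowing applies).
#' @param bin_width_pA Bin width in pA (default 0.1).
#' @param segment Which protocol segment to histogram (default `"test"`;
#'   `NULL` uses every sample).
#' @param settle_s Settling time discarded at each segment start.
#' @return An `amplitude_histogram` tibble with `bin_mid_pA`, `count`;
#'   attributes `bin_edges`, `total_samples`, `voltage_mV`, `bin_width`.
#' @export
build_amplitude_histogram <- function(traces, bin_width_pA = 0.1,
                                      segment = "test", settle_s = 5e-3) {
  stopifnot(bin_width_pA > 0)
  x <- traces
  if (!is.null(segment) && "segment" %in% names(x)) {
    x <- x[x$segment == segment, , drop = FALSE]
    if ("time_s" %in% names(x) && "sweep" %in% names(x) && settle_s > 0) {
      x <- x |>
        dplyr::group_by(.data$sweep) |>
        dplyr::filter(.data$time_s >= min(.data$time_s) + settle_s) |>
        dplyr::ungroup()
    }
  }
  cur <- x$current_pA
  if (length(cur) == 0L) stop("no samples to histogram", call. = FALSE)
  lo <- floor(min(cur) / bin_width_pA) * bin_width_pA - bin_width_pA / 2
  hi <- ceiling(max(cur) / bin_width_pA) * bin_width_pA + bin_width_pA / 2
  edges <- seq(lo, hi + bin_width_pA / 2, by = bin_width_pA)
  h <- graphics::hist(cur, breaks = edges, plot = FALSE)
  voltage <- if ("voltage_mV" %in% names(x)) unique(x$voltage_mV) else NA_real_
  structure(
    tibble::tibble(bin_mid_pA = h$mids, count = h$counts),
    class = c("amplitude_histogram", class(tibble::tibble())),
    bin_edges = edges, total_samples = length(cur),
    voltage_mV = if (length(voltage) == 1L) voltage else NA_real_,
    bin_width = bin_width_pA
  )
}

#' @export
print.amplitude_histogram <- function(x, ...) {
  cat(sprintf("<amplitude_histogram> %d samples, %d bins of %.3g pA, V = %s mV\n",
              attr(x, "total_samples"), nrow(x), attr(x, "bin_width"),
              format(attr(x, "voltage_mV"))))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

# local maxima of the smoothed histogram: candidate level positions,
# ordered by height. Bridges of filtered transition samples between levels
# are monotone and create no maxima, so this is robust to them.
.detect_levels <- function(x, y, min_sep_bins = 5L, min_height = NULL) {
  sm <- as.numeric(stats::filter(y, rep(1 / 5, 5), sides = 2))
  sm[is.na(sm)] <- 0
  min_height <- min_height %||% max(2, 1e-5 * sum(y))
  n <- length(sm)
  is_max <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - min_sep_bins); hi <- min(n, i + min_sep_bins)
    sm[i] >= min_height && sm[i] == max(sm[lo:hi]) &&
      (i == which.max(sm[lo:hi] == sm[i]) + lo - 1L)  # first of a plateau
  }, TRUE)
  idx <- which(is_max)
  idx[order(sm[idx], decreasing = TRUE)]
}

# Least-squares fit of K shared-sd Gaussians plus a flat pedestal to the
# binned counts. The pedestal absorbs the between-level density left by
# low-pass-filtered gating transitions, which otherwise attracts spurious
# components during model selection. Centres are initialised at the K most
# prominent detected levels (deterministic; no random restarts).
.fit_k_gaussians <- function(hist, K) {
  x <- hist$bin_mid_pA
  y <- hist$count
  bw <- attr(hist, "bin_width")
  peaks_i <- .detect_levels(x, y)
  init_mu <- sort(x[peaks_i][seq_len(min(K, length(peaks_i)))])
  while (length(init_mu) < K) {
    # place extra components in the widest gap (or beyond the outermost)
    if (length(init_mu) == 1L) {
      init_mu <- sort(c(init_mu, init_mu + (max(x) - min(x)) / 4))
    } else {
      gaps <- diff(init_mu)
      g <- which.max(gaps)
      init_mu <- sort(c(init_mu, init_mu[g] + gaps[g] / 2))
    }
  }
  wmean <- sum(x * y) / sum(y)
  spread <- sqrt(sum(y * (x - wmean)^2) / sum(y))
  init_sd <- max(bw, spread / (2 * K))
  bin_assign <- vapply(x, function(v) which.min(abs(v - init_mu)), 0L)
  init_amp <- vapply(seq_len(K), function(k) {
    max(sum(y[bin_assign == k]) * bw / (init_sd * sqrt(2 * pi)), 1)
  }, 0)
  par <- c(init_mu, log(init_amp), log(init_sd), log(max(mean(y) * 0.01, 0.1)))
  model <- function(par) {
    mu <- par[1:K]; amp <- exp(par[(K + 1):(2 * K)])
    sd <- exp(par[2 * K + 1]); ped <- exp(par[2 * K + 2])
    ped + rowSums(vapply(seq_len(K),
                         function(k) amp[k] * exp(-(x - mu[k])^2 / (2 * sd^2)),
                         numeric(length(x))))
  }
  # Poisson-weighted residuals: each bin contributes (y - f)^2 / max(y, 1),
  # the chi-square statistic, so small peaks are not drowned by the shape
  # misfit of the dominant ones
  w <- 1 / sqrt(pmax(y, 1))
  res <- minpack.lm::nls.lm(par, fn = function(p) (y - model(p)) * w,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200))
  p <- res$par
  mu <- p[1:K]; amp <- exp(p[(K + 1):(2 * K)]); sd <- exp(p[2 * K + 1])
  fitted <- model(p)
  list(mu = mu, amp = amp, sd = rep(sd, K), pedestal = exp(p[2 * K + 2]),
       chisq = sum(res$fvec^2), rss = sum((y - fitted)^2),
       converged = res$info %in% 1:4)
}

#' Fit a Gaussian mixture to an amplitude histogram
#'
#' Least-squares sum-of-Gaussians fit to the binned counts (the GRAMS-style
#' peak fit used in single-channel work), for every component count K from
#' 1 to `max_channels + 1`, with the candidate count additionally capped by
#' the number of local maxima of the smoothed histogram (peaks are only
#' placed where the data show a mode, as an analyst would). The component
#' count is selected by the Bayesian information criterion over the binned
#' chi-square fits, ties broken toward fewer components. Because level
#' occupancies of independent identical channels are binomial (unimodal in
#' the open-level index), an interior component dwarfed by both neighbours
#' is rejected as residual transition density after selection. Components share one standard deviation, which
#' stabilises small-area peaks, and the model carries a fitted flat
#' pedestal absorbing the between-level sample density produced by
#' low-pass-filtered gating transitions (without it, model selection
#' chases that density with spurious components). Peak areas are
#' amplitude × sd × sqrt(2π) in sample counts.
#'
#' @param hist An [build_amplitude_histogram()] result.
#' @param max_channels Largest number of open levels considered.
#' @param baseline Baseline-peak identification rule. `"auto"` (default)
#'   picks the outermost component whose opposite extreme carries the
#'   smaller area — robust both to leak offsets and to multi-channel
#'   patches where one-open is more likely than all-closed. `"mode"` takes
#'   the component nearest the modal current; `"zero"` the one nearest
#'   0 pA.
#' @return A `peak_mixture` object: tibble of peaks ordered from the
#'   baseline outward (`level` 0, 1, ...; `centre_pA`, `sd_pA`, `area`,
#'   `area_fraction`), with attributes `n_channels`, `baseline_index`,
#'   `rss`, `bic`, `voltage_mV`. Methods: [tidy()], [glance()],
#'   [ggplot2::autoplot()].
#' @export
fit_peak_mixture <- function(hist, max_channels = 4,
                             baseline = c("auto", "mode", "zero")) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(hist, "amplitude_histogram"), max_channels >= 1)
  if (sum(hist$count > 0) < 3L) stop("histogram is degenerate", call. = FALSE)
  n <- nrow(hist)
  # components are only placed at modes the histogram actually shows:
  # the candidate count is capped by the number of local maxima of the
  # smoothed histogram (transition bridges between levels are monotone and
  # contribute none), then BIC arbitrates among 1..K_max
  n_modes <- length(.detect_levels(hist$bin_mid_pA, hist$count))
  k_max <- min(max_channels + 1, max(1L, n_modes))
  fits <- list()
  bics <- rep(Inf, k_max)
  for (K in 1:k_max) {
    f <- tryCatch(.fit_k_gaussians(hist, K), error = function(e) NULL)
    if (is.null(f)) next
    p <- 2 * K + 2   # centres, amplitudes, shared sd, pedestal
    # Gaussian-approximation BIC of the Poisson model: chi-square + p ln n
    bics[K] <- f$chisq + p * log(n)
    fits[[K]] <- f
  }
  if (all(!is.finite(bics))) {
    stop("mixture fit failed to converge for every component count",
         call. = FALSE)
  }
  K <- which.min(round(bics, 6))   # ties toward fewer components
  f <- fits[[K]]
  # identify the baseline component, then order components outward from it
  area_raw <- f$amp * f$sd
  base_i <- switch(baseline,
    auto = {
      # all open levels lie on one side of the baseline, so the baseline is
      # one of the two outermost components: the one whose far side carries
      # the least area (the k-channels-open peak is always a minor one)
      lo <- which.min(f$mu); hi <- which.max(f$mu)
      if (area_raw[hi] <= area_raw[lo]) lo else hi
    },
    mode = {
      mode_current <- hist$bin_mid_pA[which.max(hist$count)]
      which.min(abs(f$mu - mode_current))
    },
    zero = which.min(abs(f$mu))
  )
  ord <- order(abs(f$mu - f$mu[base_i]))
  area <- f$amp * f$sd * sqrt(2 * pi) / attr(hist, "bin_width")
  mu <- f$mu[ord]; sds <- f$sd[ord]; area <- area[ord]
  # binomial gating of independent identical channels makes the level
  # occupancies unimodal in k, so an interior component far smaller than
  # both of its neighbours cannot be a level; it is residual transition
  # density that slipped past the pedestal. Prune and renumber.
  repeat {
    k <- length(mu)
    if (k < 3L) break
    interior <- 2:(k - 1L)
    bad <- interior[area[interior] <
                      0.2 * pmin(area[interior - 1L], area[interior + 1L])]
    if (!length(bad)) break
    drop <- bad[which.min(area[bad])]
    mu <- mu[-drop]; sds <- sds[-drop]; area <- area[-drop]
  }
  peaks <- tibble::tibble(
    level = seq_along(mu) - 1L,
    centre_pA = mu,
    sd_pA = sds,
    area = area,
    area_fraction = area / sum(area)
  )
  structure(peaks,
            class = c("peak_mixture", class(tibble::tibble())),
            n_channels = length(mu) - 1L, baseline_index = 1L,
            rss = f$rss, bic = bics[K],
            voltage_mV = attr(hist, "voltage_mV"),
            total_samples = attr(hist, "total_samples"),
            histogram = hist)
}

#' @export
print.peak_mixture <- function(x, ...) {
  cat(sprintf("<peak_mixture> %d open level(s) beyond baseline, V = %s mV\n",
              attr(x, "n_channels"), format(attr(x, "voltage_mV"))))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.peak_mixture <- function(x, ...) tibble::as_tibble(x)

#' @exportS3Method generics::glance
glance.peak_mixture <- function(x, ...) {
  nc <- attr(x, "n_channels")
  tibble::tibble(
    n_channels = nc,
    po = if (nc >= 1) open_probability(x, nc) else 0,
    unitary_current_pA = if (nrow(x) >= 2) unitary_current(x) else NA_real_,
    sd_pA = x$sd_pA[1],
    rss = attr(x, "rss"),
    bic = attr(x, "bic"),
    voltage_mV = attr(x, "voltage_mV")
  )
}

#' Open probability from Gaussian peak areas
#'
#' The area under each Gaussian peak counts the samples spent at that level;
#' with peaks indexed by the number k of simultaneously open channels
#' (baseline k = 0), \eqn{P_o = \sum_k k A_k / (N \sum_k A_k)} — NPo
#' normalised per channel under the assumption of N identical independent
#' channels.
#'
#' @param mix A [fit_peak_mixture()] result.
#' @param n_channels Number of channels N in the patch. Defaults to the
#'   number of non-baseline peaks (the maximum simultaneous open level
#'   observed).
#' @return Po in \[0, 1\].
#' @export
open_probability <- function(mix, n_channels = attr(mix, "n_channels")) {
  stopifnot(inherits(mix, "peak_mixture"))
  k <- mix$level
  if (n_channels < max(k)) {
    stop("n_channels (", n_channels, ") is smaller than the number of open ",
         "levels observed (", max(k), ")", call. = FALSE)
  }
  if (n_channels < 1) stop("n_channels must be >= 1", call. = FALSE)
  sum(k * mix$area) / (n_channels * sum(mix$area))
}

#' Unitary current from peak spacing
#'
#' Mean difference between adjacent Gaussian peak centres, signed away from
#' the baseline: the single-channel current i at the histogram's voltage.
#'
#' @param mix A [fit_peak_mixture()] result with at least two peaks.
#' @return Unitary current in pA (negative for inward current).
#' @export
unitary_current <- function(mix) {
  stopifnot(inherits(mix, "peak_mixture"))
  if (nrow(mix) < 2L) {
    stop("unitary current undefined for a single-peak mixture", call. = FALSE)
  }
  mean(diff(mix$centre_pA))
}

#' Chord conductance at the most extreme voltage
#'
#' The unitary conductance reported for these channels is the
#' current/voltage ratio at the most extreme voltage applied (the I/V
#' curves are nonlinear, so a slope conductance is not used):
#' \eqn{g = i/V} in pS with i in pA and V in mV (× 1000).
#'
#' @param iv Either an `iv_curve` / data frame with `voltage_mV` and
#'   `current_pA` (the row with largest |V| is used), or a single current in
#'   pA when `voltage_mV` is given.
#' @param voltage_mV Voltage for the scalar form.
#' @return Conductance in pS.
#' @export
#' @examples
#' chord_conductance_extreme_voltage(-6.42, voltage_mV = -74) # 86.75 pS
chord_conductance_extreme_voltage <- function(iv, voltage_mV = NULL) {
  if (is.data.frame(iv)) {
    i <- which.max(abs(iv$voltage_mV))
    v <- iv$voltage_mV[i]
    cur <- iv$current_pA[i]
  } else {
    v <- voltage_mV
    cur <- iv
  }
  if (is.null(v) || v == 0) {
    stop("chord conductance undefined at V = 0", call. = FALSE)
  }
  1000 * cur / v
}

#' Assemble an I/V curve
#'
#' Aggregates per-sweep (or per-patch) current measurements by voltage into
#' an ordered I/V table with dispersion.
#'
#' @param data Data frame with `voltage_mV` and `current_pA` (one row per
#'   measurement; repeated voltages are aggregated).
#' @param label Curve label.
#' @return An `iv_curve` tibble: `voltage_mV`, `current_pA` (mean), `sd`,
#'   `sem`, `n`, ordered by voltage.
#' @export
build_iv_curve <- function(data, label = "") {
  stopifnot(is.data.frame(data),
            all(c("voltage_mV", "current_pA") %in% names(data)))
  if (nrow(data) == 0L) stop("empty input", call. = FALSE)
  out <- data |>
    dplyr::group_by(voltage_mV = .data$voltage_mV) |>
    dplyr::summarise(
      current_mean = mean(.data$current_pA),
      sd = if (dplyr::n() > 1) stats::sd(.data$current_pA) else NA_real_,
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(sem = .data$sd / sqrt(.data$n)) |>
    dplyr::rename(current_pA = "current_mean") |>
    dplyr::arrange(.data$voltage_mV) |>
    dplyr::select("voltage_mV", "current_pA", "sd", "sem", "n")
  if (nrow(out) < 2L) stop("need at least 2 distinct voltages", call. = FALSE)
  structure(out, class = c("iv_curve", class(tibble::tibble())),
            label = label)
}

#' Reversal potential from an I/V curve
#'
#' Linear interpolation between the two points bracketing the zero-current
#' crossing. If the (noisy, nonmonotone) curve crosses zero more than once,
#' the crossing nearest 0 mV is taken.
#'
#' @param iv An `iv_curve` or data frame with `voltage_mV`, `current_pA`.
#' @return Reversal potential in mV.
#' @export
estimate_reversal <- function(iv) {
  v <- iv$voltage_mV
  i <- iv$current_pA
  s <- sign(i)
  cross <- which(s[-length(s)] * s[-1] < 0)
  exact <- which(i == 0)
  cands <- c(
    if (length(exact)) v[exact],
    vapply(cross, function(k) {
      v[k] + (0 - i[k]) * (v[k + 1] - v[k]) / (i[k + 1] - i[k])
    }, 0)
  )
  if (!length(cands)) {
    stop("current does not change sign: no reversal in the sampled range",
         call. = FALSE)
  }
  cands[which.min(abs(cands))]
}
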