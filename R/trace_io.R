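#' Write / read a trace set as CSV with a JSON sidecar
#'
#' The on-disk dialect is a plain CSV with columns `sweep`, `segment`,
#' `time_s`, `voltage_mV`, `current_pA` (and `n_open` when ground truth is
#' attached), plus `<path>.json` holding the metadata: sampling rate,
#' filter cutoff, configuration, seed, and the generating gating model when
#' the trace is synthetic. `read_trace(write_trace(x))` restores samples
#' exactly and metadata field-complete.
#'
#' @param traces A `trace_set`.
#' @param path CSV path; the sidecar is written next to it as
#'   `paste0(path, ".json")`.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` a
#'   `trace_set`.
#' @export
write_trace <- function(traces, path) {
  stopifnot(inherits(traces, "trace_set") || is.data.frame(traces))
  df <- as.data.frame(traces)
  # full binary precision so write -> read restores samples exactly
  for (cl in names(df)) {
    if (is.double(df[[cl]])) df[[cl]] <- sprintf("%.17g", df[[cl]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  model <- attr(traces, "model")
  meta <- list(
    sampling_rate_hz = attr(traces, "sampling_hz"),
    filter_hz = attr(traces, "filter_hz"),
    configuration = attr(traces, "configuration"),
    seed = attr(traces, "seed"),
    noise_sd = attr(traces, "noise_sd"),
    truth = if (!is.null(model)) unclass(model)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("missing sidecar ", sidecar, "; required fields: sampling_rate_hz, ",
         "filter_hz, configuration, seed", call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  req <- c("sampling_rate_hz", "configuration", "seed")
  miss <- setdiff(req, names(meta))
  if (length(miss)) {
    stop("sidecar lacks required field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- utils::read.csv(path)
  req_cols <- c("sweep", "time_s", "voltage_mV", "current_pA")
  miss <- setdiff(req_cols, names(df))
  if (length(miss)) {
    stop("malformed trace CSV, missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  model <- meta$truth
  if (!is.null(model) && length(model)) {
    keep <- !vapply(model, is.null, TRUE)
    model <- structure(model[keep], class = "gating_model")
  } else {
    model <- NULL
  }
  structure(tibble::as_tibble(df),
            class = c("trace_set", class(tibble::tibble())),
            sampling_hz = meta$sampling_rate_hz,
            filter_hz = meta$filter_hz %||% NA_real_,
            configuration = meta$configuration,
            seed = meta$seed,
            noise_sd = meta$noise_sd %||% NA_real_,
            model = model)
}
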