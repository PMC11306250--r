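# Plain-text trace and table formats: two-column TSV per trace plus a JSON
# metadata sidecar carrying all parameters, the seed and truth intervals.

#' Write / read a trap trace
#'
#' `write_trace()` writes `<path>` as TSV (columns `x_driven_nm`,
#' `x_passive_nm`; time implicit from the sample rate) and `<path>.json` as
#' metadata sidecar (sample rate, full parameter set, seed, truth intervals).
#' `read_trace()` reverses it losslessly.
#'
#' @param trace a `trap_trace`.
#' @param path output TSV path.
#' @return `read_trace()` returns the `trap_trace`; `write_trace()` the path,
#'   invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(x_driven_nm = trace$x_driven,
                   x_passive_nm = trace$x_passive)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- list(sample_rate = trace$sample_rate,
               n_samples = length(trace$time),
               metadata = trace$metadata,
               truth = trace$truth)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("metadata sidecar missing: ", sidecar, call. = FALSE)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("x_driven_nm", "x_passive_nm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trace schema mismatch, missing column: ",
         paste(miss, collapse = ", "), call. = FALSE)
  fs <- side$sample_rate
  cfg <- side$metadata$sim_config
  tout <- if (!is.null(cfg))
    (seq_len(nrow(df)) - 1) / fs + (cfg$navg + 1) * cfg$internal_step / 2
  else (seq_len(nrow(df)) - 0.5) / fs
  truth <- side$truth
  if (!is.null(truth) && length(truth)) {
    truth <- as.data.frame(truth)
    class(truth) <- c("state_trajectory", class(truth))
  } else truth <- NULL
  structure(list(time = tout, x_driven = df$x_driven_nm,
                 x_passive = df$x_passive_nm, sample_rate = fs,
                 metadata = side$metadata, truth = truth),
            class = "trap_trace")
}

#' Write / read a binding-event table
#'
#' TSV with a `#` JSON header line carrying the table attributes
#' (total/detached time, thresholds).
#'
#' @param events a [detect_events()] table.
#' @param path TSV path.
#' @export
write_events <- function(events, path) {
  hdr <- jsonlite::toJSON(list(total_time = attr(events, "total_time"),
                               detached_time = attr(events, "detached_time"),
                               compliance_rigor = attr(events, "compliance_rigor")),
                          auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", hdr), con)
  utils::write.table(event_table(events), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  first <- readLines(path, n = 1)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  class(df) <- c("binding_events", class(df))
  if (startsWith(first, "#")) {
    meta <- jsonlite::fromJSON(sub("^#", "", first))
    attr(df, "total_time") <- meta$total_time
    attr(df, "detached_time") <- meta$detached_time
    attr(df, "compliance_rigor") <- meta$compliance_rigor
  }
  df
}

#' Write / read a stopped-flow transient (two-column TSV: t_s, signal)
#'
#' @param transient an `sf_transient` or data.frame with `time`, `signal`.
#' @param path TSV path.
#' @export
write_transient <- function(transient, path) {
  utils::write.table(data.frame(t_s = transient$time,
                                signal = transient$signal),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transient
#' @export
read_transient <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("t_s", "signal") %in% names(df)))
    stop("transient schema mismatch: need columns t_s, signal", call. = FALSE)
  out <- data.frame(time = df$t_s, signal = df$signal)
  class(out) <- c("sf_transient", class(out))
  out
}
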