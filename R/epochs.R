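# Containers shared by the EEG simulator and the ERP pipeline.

#' Construct an epoch set
#'
#' Epoched multichannel EEG: a trials x channels x time array in microvolts,
#' with per-trial condition labels and subject/group metadata. Time is in ms
#' relative to stimulus onset and must span at least -100..500 ms.
#'
#' @param data Numeric array `trials x channels x time` (microvolts).
#' @param times Numeric vector of sample times in ms (length = dim 3).
#' @param channels Character vector of channel names (length = dim 2).
#' @param condition Character vector of per-trial condition labels.
#' @param subject Subject identifier.
#' @param group Group label (e.g. "control", "patient").
#' @param sfreq Sampling frequency in Hz.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, channels, condition,
                      subject = "s01", group = "control", sfreq = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("'data' must be a 3-D array (trials x channels x time)")
  }
  d <- dim(data)
  stopifnot(length(times) == d[3], length(channels) == d[2],
            length(condition) == d[1])
  step <- stats::median(diff(times))
  if (min(times) > -100 + step / 2 || max(times) < 500 - step) {
    stop("'times' must span at least -100..500 ms")
  }
  if (is.null(sfreq)) sfreq <- 1000 / stats::median(diff(times))
  structure(
    list(data = data, times = as.numeric(times),
         channels = as.character(channels),
         condition = as.character(condition),
         subject = subject, group = group, sfreq = sfreq),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples (%g Hz)\n",
              d[1], d[2], d[3], x$sfreq))
  cat("  subject:", x$subject, " group:", x$group, "\n")
  cat("  conditions:", paste(sprintf("%s(%d)", names(table(x$condition)),
                                     table(x$condition)), collapse = " "), "\n")
  invisible(x)
}

#' Define an ERP component measurement window
#'
#' @param name Component name (e.g. "P1", "N1", "Ncl").
#' @param window_ms Length-2 numeric `c(lo, hi)` in ms, lo < hi.
#' @param electrodes Channel names over which the amplitude is measured.
#' @param polarity Expected sign of the component (+1 or -1).
#' @return An object of class `component_window`.
#' @export
component_window <- function(name, window_ms, electrodes, polarity = 1) {
  stopifnot(length(window_ms) == 2L, window_ms[1] < window_ms[2],
            polarity %in% c(-1, 1))
  structure(list(name = name, window_ms = as.numeric(window_ms),
                 electrodes = as.character(electrodes),
                 polarity = polarity),
            class = "component_window")
}

#' Default component windows for the closure task
#'
#' P1 (100-120 ms, PO5/PO6, positive) indexes initial dorsal-stream
#' activation; N1 (170-200 ms, PO7/PO8, negative) initial ventral-stream
#' processing; Ncl (300-340 ms, PO7/PO8, negative) the closure negativity.
#' Peak latencies (115, 180, 320 ms) are carried for the simulator.
#'
#' @return Named list of [component_window()] objects with a `peak_ms`
#'   attribute on each.
#' @export
default_component_windows <- function() {
  w <- list(
    P1  = component_window("P1",  c(100, 120), c("PO5", "PO6"), +1),
    N1  = component_window("N1",  c(170, 200), c("PO7", "PO8"), -1),
    Ncl = component_window("Ncl", c(300, 340), c("PO7", "PO8"), -1)
  )
  attr(w$P1, "peak_ms") <- 115
  attr(w$N1, "peak_ms") <- 180
  attr(w$Ncl, "peak_ms") <- 320
  w
}

# Hemisphere of a posterior-occipital electrode by its terminal digit
# (odd = left, even = right).
electrode_hemisphere <- function(ch) {
  digit <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", ch)))
  ifelse(is.na(digit), NA_character_,
         ifelse(digit %% 2L == 1L, "left", "right"))
}

#' Write an epoch set as a delimited array plus JSON sidecar
#'
#' The data array is flattened to a `trials*channels` x `time` table
#' (trial-major) written as TSV; the sidecar records dimensions, times,
#' channel names, condition labels and metadata so [read_epochs()] can
#' reconstruct the object exactly.
#'
#' @param epochs An [epoch_set()].
#' @param path Output TSV path; the sidecar goes to `<path>.json`.
#' @return Invisibly the paths written.
#' @export
write_epochs <- function(epochs, path) {
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = d[1] * d[2],
                 ncol = d[3], byrow = TRUE)
  utils::write.table(flat, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  sidecar <- list(
    dims = d, times_ms = epochs$times, channels = epochs$channels,
    condition = epochs$condition, subject = epochs$subject,
    group = epochs$group, sfreq = epochs$sfreq,
    layout = "rows are (trial, channel) pairs, trial-major; columns are samples"
  )
  json_path <- paste0(path, ".json")
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(table = path, header = json_path))
}

#' Read an epoch set written by [write_epochs()]
#'
#' @param path TSV path (sidecar expected at `<path>.json`).
#' @return An [epoch_set()].
#' @export
read_epochs <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  d <- sidecar$dims
  arr <- aperm(array(t(flat), dim = c(d[3], d[2], d[1])), c(3, 2, 1))
  epoch_set(arr, sidecar$times_ms, sidecar$channels, sidecar$condition,
            sidecar$subject, sidecar$group, sidecar$sfreq)
}
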