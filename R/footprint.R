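#' Construct an extracellular template
#'
#' A template (the "electrical footprint" of one sorted unit) is the
#' spike-triggered average extracellular waveform across all electrodes of a
#' high-density microelectrode array, stored as a channels x samples voltage
#' matrix in microvolts together with the sampling frequency.
#'
#' @param voltages numeric matrix, channels x samples, in uV.
#' @param fs sampling frequency in Hz.
#' @return An object of class `axon_template`: a list with elements
#'   `voltages` and `fs`.
#' @export
axon_template <- function(voltages, fs) {
  voltages <- as.matrix(voltages)
  storage.mode(voltages) <- "double"
  if (nrow(voltages) < 2L || ncol(voltages) < 2L)
    stop("template must have at least 2 channels and 2 samples, got ",
         nrow(voltages), " x ", ncol(voltages))
  if (anyNA(voltages) || any(!is.finite(voltages)))
    stop("template contains missing or non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("sampling frequency must be a single positive number (Hz)")
  structure(list(voltages = voltages, fs = as.numeric(fs)),
            class = "axon_template")
}

#' @export
print.axon_template <- function(x, ...) {
  cat(sprintf("axon_template: %d channels x %d samples @ %g kHz (%.2f ms)\n",
              nrow(x$voltages), ncol(x$voltages), x$fs / 1000,
              1000 * ncol(x$voltages) / x$fs))
  invisible(x)
}

#' Validate an electrode layout
#'
#' @param positions numeric matrix, channels x 2, electrode x-y coordinates
#'   in micrometers.
#' @param n_channels optional channel count to check against.
#' @return the validated positions matrix (with columns named `x`, `y`).
#' @export
probe_layout <- function(positions, n_channels = NULL) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 2L)
    stop("layout must be a channels x 2 matrix of x-y positions")
  if (anyNA(positions) || any(!is.finite(positions)))
    stop("layout contains missing or non-finite coordinates")
  if (anyDuplicated(positions))
    stop("layout contains duplicated electrode positions")
  if (!is.null(n_channels) && nrow(positions) != n_channels)
    stop("channel count mismatch: template has ", n_channels,
         " channels but layout has ", nrow(positions), " positions")
  colnames(positions) <- c("x", "y")
  positions
}

#' Load a template and electrode layout from disk
#'
#' The template is a plain-text numeric matrix (CSV/TSV, channels x samples,
#' uV, no header); the layout is a CSV with header `channel,x,y` (um) or a
#' headerless two-column x,y table. Channel counts must agree.
#'
#' @param path template matrix file.
#' @param layout_path electrode layout file.
#' @param fs sampling frequency in Hz.
#' @return list with elements `template` (class `axon_template`) and
#'   `locations` (channels x 2 matrix).
#' @export
load_template <- function(path, layout_path, fs) {
  if (!file.exists(path)) stop("template file not found: ", path)
  if (!file.exists(layout_path)) stop("layout file not found: ", layout_path)
  volts <- as.matrix(utils::read.table(path, sep = guess_sep(path),
                                       header = FALSE))
  dimnames(volts) <- NULL
  lay <- utils::read.table(layout_path, sep = guess_sep(layout_path),
                           header = has_layout_header(layout_path))
  if (ncol(lay) >= 3L) {
    ord <- order(lay[[1L]])
    pos <- as.matrix(lay[ord, 2:3])
  } else {
    pos <- as.matrix(lay[, 1:2])
  }
  dimnames(pos) <- NULL
  tmpl <- axon_template(volts, fs)
  list(template = tmpl,
       locations = probe_layout(pos, n_channels = nrow(tmpl$voltages)))
}

#' Save a template and layout as plain-text files
#'
#' @param template `axon_template` object.
#' @param locations channels x 2 layout matrix.
#' @param path output template CSV path.
#' @param layout_path output layout CSV path.
#' @return invisibly, the template path.
#' @export
save_template <- function(template, locations, path, layout_path) {
  stopifnot(inherits(template, "axon_template"))
  utils::write.table(template$voltages, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  lay <- data.frame(channel = seq_len(nrow(locations)) - 1L,
                    x = locations[, 1L], y = locations[, 2L])
  utils::write.table(lay, layout_path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

guess_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl(",", line, fixed = TRUE)) "," else ""
}

has_layout_header <- function(path) {
  grepl("[A-Za-z]", readLines(path, n = 1L))
}
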