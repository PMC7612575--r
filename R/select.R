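#' Amplitude (detection) filter
#'
#' Keeps channels whose peak-to-peak amplitude reaches a detection threshold,
#' either relative to the largest amplitude of the footprint (default) or as
#' an absolute value in uV. Boundary channels (amplitude equal to the cutoff)
#' are kept.
#'
#' @param features data.frame from [channel_features()].
#' @param detect_threshold fraction of the maximum amplitude (relative mode)
#'   or uV (absolute mode).
#' @param detection_type `"relative"` or `"absolute"`.
#' @return logical keep-mask.
#' @export
amplitude_filter <- function(features, detect_threshold = 0.01,
                             detection_type = c("relative", "absolute")) {
  detection_type <- match.arg(detection_type)
  stopifnot(detect_threshold >= 0)
  cutoff <- if (detection_type == "relative")
    detect_threshold * max(features$amplitude) else detect_threshold
  features$amplitude >= cutoff & features$amplitude > 0
}

#' Kurtosis filter
#'
#' Removes channels whose excess kurtosis falls below a threshold; noise
#' traces are near-Gaussian (excess kurtosis about 0) whereas spike-bearing
#' traces are supergaussian.
#'
#' @param features data.frame from [channel_features()].
#' @param kurt_threshold minimum excess kurtosis (default 0.3).
#' @return logical keep-mask.
#' @export
kurtosis_filter <- function(features, kurt_threshold = 0.3) {
  stopifnot(kurt_threshold >= 0)
  features$kurtosis >= kurt_threshold
}

#' Peak-time dispersion filter
#'
#' Keeps channels whose neighborhood peak-time standard deviation is at most
#' `peak_std_threshold`; infinite sentinels (undersized neighborhoods) fail.
#'
#' @param features data.frame from [channel_features()].
#' @param peak_std_threshold maximum dispersion in ms (default 1).
#' @return logical keep-mask.
#' @export
peak_std_filter <- function(features, peak_std_threshold = 1) {
  stopifnot(peak_std_threshold >= 0)
  is.finite(features$peak_std) & features$peak_std <= peak_std_threshold
}

#' Initial-delay filter
#'
#' The largest-amplitude channel (the *initial channel*) is assumed close to
#' the axon initial segment; channels peaking before the initial-channel peak
#' plus `init_delay` carry somatic/dendritic rather than axonal signal and
#' are removed.
#'
#' @param features data.frame from [channel_features()].
#' @param init_delay delay in ms (default 0.1).
#' @return logical keep-mask.
#' @export
init_delay_filter <- function(features, init_delay = 0.1) {
  stopifnot(init_delay >= 0)
  init <- init_channel(features)
  features$peak_time >= features$peak_time[init] + init_delay
}

#' Index of the initial channel (global amplitude maximum)
#'
#' @param features data.frame from [channel_features()].
#' @return integer channel index (1-based).
#' @export
init_channel <- function(features) {
  which.max(features$amplitude)
}

#' Intersect filter masks and remove isolated channels
#'
#' The selection is the intersection of the individual keep-masks; a single
#' pass then removes isolated channels (selected channels without another
#' selected channel within `isolation_radius`), and the initial channel is
#' force-included as the target node of all later path searches.
#'
#' @param masks named list of logical keep-masks (all the same length).
#' @param features data.frame from [channel_features()].
#' @param locations channels x 2 layout matrix (um).
#' @param isolation_radius um (default 100).
#' @param remove_isolated logical; disable to skip the isolation pass.
#' @return list of class `axon_selection` with elements `selected` (sorted
#'   integer channel indices), `init_channel`, and `masks` (the per-filter
#'   masks plus `isolated`).
#' @export
combine_and_deisolate <- function(masks, features, locations,
                                  isolation_radius = 100,
                                  remove_isolated = TRUE) {
  stopifnot(length(masks) >= 1L)
  combined <- Reduce(`&`, masks)
  init <- init_channel(features)
  sel <- which(combined)
  isolated <- logical(length(combined))
  if (remove_isolated && length(sel) > 1L) {
    r2 <- isolation_radius^2
    pos <- locations[sel, , drop = FALSE]
    for (k in seq_along(sel)) {
      d2 <- (pos[, 1L] - pos[k, 1L])^2 + (pos[, 2L] - pos[k, 2L])^2
      if (!any(d2[-k] <= r2)) isolated[sel[k]] <- TRUE
    }
  } else if (remove_isolated && length(sel) == 1L) {
    isolated[sel] <- TRUE
  }
  selected <- sort(union(setdiff(sel, which(isolated)), init))
  if (length(selected) <= 1L) {
    counts <- vapply(masks, sum, integer(1L))
    stop("no axonal channels selected (per-filter survivors: ",
         paste(names(counts), counts, sep = "=", collapse = ", "), ")")
  }
  structure(list(selected = selected, init_channel = init,
                 masks = c(masks, list(isolated = isolated))),
            class = "axon_selection")
}

#' Run the full channel-selection stage
#'
#' Applies the four filters (amplitude, kurtosis, peak-time dispersion,
#' initial delay), intersects them, and removes isolated channels. Any filter
#' can be disabled through `params`.
#'
#' @param features data.frame from [channel_features()].
#' @param locations channels x 2 layout matrix (um).
#' @param params parameter list, see [axon_tracking_params()].
#' @return `axon_selection` object, see [combine_and_deisolate()].
#' @export
select_channels <- function(features, locations,
                            params = axon_tracking_params()) {
  masks <- list()
  if (params$use_amplitude_filter)
    masks$amplitude <- amplitude_filter(features, params$detect_threshold,
                                        params$detection_type)
  if (params$use_kurtosis_filter)
    masks$kurtosis <- kurtosis_filter(features, params$kurt_threshold)
  if (params$use_peak_std_filter)
    masks$peak_std <- peak_std_filter(features, params$peak_std_threshold)
  if (params$use_init_delay_filter)
    masks$init_delay <- init_delay_filter(features, params$init_delay)
  if (length(masks) == 0L)
    masks$all <- rep(TRUE, nrow(features))
  combine_and_deisolate(masks, features, locations,
                        isolation_radius = params$isolation_radius,
                        remove_isolated = params$remove_isolated)
}
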