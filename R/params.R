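#' Default parameters for graph-based axon tracking
#'
#' Returns the full parameter set of the tracking pipeline with its default
#' values. Any parameter can be overridden by name; unknown names are
#' rejected.
#'
#' Channel selection: `detect_threshold` (fraction of the maximum
#' peak-to-peak amplitude, or uV when `detection_type = "absolute"`),
#' `kurt_threshold` (minimum excess kurtosis), `peak_std_threshold` /
#' `peak_std_radius` (maximum neighborhood peak-time dispersion in ms and the
#' neighborhood radius in um), `init_delay` (ms after the initial-channel
#' peak), `remove_isolated` / `isolation_radius` (um), and `use_*_filter`
#' switches.
#'
#' Graph construction: `alpha_init` (amplitude weight in the node heuristic
#' h_init), `n_neighbors` (maximum outgoing edges per node),
#' `max_edge_distance` (um), `init_channel_distance` (um, fallback edges to
#' the initial channel), `distance_exponent` (super-linear penalty on long
#' jumps in the normalized edge distance).
#'
#' Branch reconstruction: `local_max_radius` (um, starting-node test),
#' `neighbor_append_radius` (um, per-path neighbor set),
#' `min_points_after_branching`, `min_path_length` (um), `min_path_points`,
#' `exclusion_radius` (um, channels near an accepted branch are excluded
#' from further searches).
#'
#' Path cleaning: `mad_multiplier` (N of the N x MAD outlier rule),
#' `outlier_distance_threshold` (um), `split_jump_threshold` (ms),
#' `r2_threshold` (minimum R^2 of the velocity fit).
#'
#' @param ... named overrides of any default.
#' @return named list of parameters.
#' @examples
#' p <- axon_tracking_params(kurt_threshold = 0.1, init_delay = 0.2)
#' @export
axon_tracking_params <- function(...) {
  defaults <- list(
    # channel selection
    detect_threshold = 0.01,
    detection_type = "relative",
    kurt_threshold = 0.3,
    peak_std_threshold = 1,
    peak_std_radius = 30,
    init_delay = 0.1,
    remove_isolated = TRUE,
    isolation_radius = 100,
    use_amplitude_filter = TRUE,
    use_kurtosis_filter = TRUE,
    use_peak_std_filter = TRUE,
    use_init_delay_filter = TRUE,
    # graph construction
    alpha_init = 0.2,
    n_neighbors = 3L,
    max_edge_distance = 100,
    init_channel_distance = 200,
    distance_exponent = 2,
    # branch reconstruction
    local_max_radius = 100,
    neighbor_append_radius = 100,
    min_points_after_branching = 3L,
    min_path_length = 100,
    min_path_points = 5L,
    exclusion_radius = 50,
    # path cleaning / velocity estimation
    mad_multiplier = 8,
    outlier_distance_threshold = 30,
    split_jump_threshold = 1,
    r2_threshold = 0.9
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == ""))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    defaults[names(overrides)] <- overrides
  }
  validate_params(defaults)
  defaults
}

validate_params <- function(p) {
  stopifnot(
    p$detect_threshold >= 0,
    p$detection_type %in% c("relative", "absolute"),
    p$kurt_threshold >= 0, p$peak_std_threshold >= 0, p$peak_std_radius > 0,
    p$init_delay >= 0, p$isolation_radius > 0,
    p$alpha_init >= 0, p$alpha_init <= 1,
    p$n_neighbors >= 1, p$max_edge_distance > 0,
    p$init_channel_distance > 0, p$distance_exponent >= 1,
    p$local_max_radius > 0, p$neighbor_append_radius > 0,
    p$min_points_after_branching >= 1, p$min_path_length > 0,
    p$min_path_points >= 2, p$exclusion_radius > 0,
    p$mad_multiplier > 0, p$outlier_distance_threshold > 0,
    p$split_jump_threshold > 0,
    p$r2_threshold >= 0, p$r2_threshold <= 1
  )
  invisible(p)
}
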