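#' Track axonal branches and estimate conduction velocities
#'
#' Runs the full graph-based pipeline on one unit's extracellular template:
#' per-channel feature extraction, four-filter channel selection,
#' propagation-graph construction, minimum-cost branch reconstruction
#' towards the initial channel, and robust velocity estimation per branch.
#'
#' @param template channels x samples voltage matrix (uV) or an
#'   `axon_template` object.
#' @param locations channels x 2 electrode x-y positions (um).
#' @param fs sampling frequency in Hz (ignored when `template` is already an
#'   `axon_template`).
#' @param params parameter list, see [axon_tracking_params()].
#' @return object of class `axon_tracking`: list with `branches` (each with
#'   `channels`, `velocity` in mm/s, `offset`, `r2`, `error`, `pval`,
#'   `distances`, `peak_times`), `selected_channels`, `graph`
#'   (`axon_graph`), `features`, and `params`. An empty branch list is a
#'   valid outcome (no detectable axon).
#' @examples
#' sim <- simulate_footprint(arbor_params(preset = "straight"), seed = 1)
#' tr <- track_axons(sim$template, sim$locations)
#' length(tr$branches)
#' @export
track_axons <- function(template, locations, fs = NULL,
                        params = axon_tracking_params()) {
  if (!inherits(template, "axon_template")) {
    if (is.null(fs)) stop("sampling frequency `fs` is required")
    template <- axon_template(template, fs)
  }
  locations <- probe_layout(locations, n_channels = nrow(template$voltages))
  validate_params(params)

  features <- channel_features(template, locations, params$peak_std_radius)
  empty <- function(sel, graph) {
    structure(list(branches = list(), selected_channels = sel, graph = graph,
                   features = features, params = params,
                   raw_paths = list(), branch_points = list(),
                   starting_nodes = integer(0)),
              class = "axon_tracking")
  }
  selection <- tryCatch(select_channels(features, locations, params),
                        error = function(e) NULL)
  if (is.null(selection)) return(empty(integer(0), NULL))

  graph <- build_axon_graph(selection, features, locations, params)
  if (nrow(graph$edges) == 0L) {
    warning("propagation graph has no edges; no branches can be traced")
    return(empty(selection$selected, graph))
  }
  recon <- reconstruct_branches(graph, features, locations, params)
  branches <- estimate_velocities(recon$paths, features, locations, params)
  structure(list(branches = branches,
                 selected_channels = selection$selected,
                 graph = graph, features = features, params = params,
                 raw_paths = recon$paths,
                 branch_points = recon$branch_points,
                 starting_nodes = recon$starting_nodes),
            class = "axon_tracking")
}

#' @export
print.axon_tracking <- function(x, ...) {
  cat(sprintf("axon_tracking: %d selected channels, %d branches\n",
              length(x$selected_channels), length(x$branches)))
  for (i in seq_along(x$branches)) {
    b <- x$branches[[i]]
    cat(sprintf(
      "  branch %d: %3d channels, length %6.1f um, velocity %7.1f mm/s (r2 %.3f)\n",
      i - 1L, length(b$channels), max(b$distances), b$velocity, b$r2))
  }
  invisible(x)
}

#' Summarize a tracking result as a data.frame
#'
#' @param object `axon_tracking` result.
#' @param ... unused.
#' @return data.frame with one row per branch: `branch`, `n_channels`,
#'   `length_um`, `velocity_mms`, `offset_um`, `r2`, `error`, `pval`.
#' @export
summary.axon_tracking <- function(object, ...) {
  b <- object$branches
  data.frame(
    branch = seq_along(b) - 1L,
    n_channels = vapply(b, function(x) length(x$channels), integer(1L)),
    length_um = vapply(b, function(x) max(x$distances), numeric(1L)),
    velocity_mms = vapply(b, function(x) x$velocity, numeric(1L)),
    offset_um = vapply(b, function(x) x$offset, numeric(1L)),
    r2 = vapply(b, function(x) x$r2, numeric(1L)),
    error = vapply(b, function(x) x$error, numeric(1L)),
    pval = vapply(b, function(x) x$pval, numeric(1L))
  )
}

#' Write a tracking result to JSON
#'
#' Serializes branches (0-based channel indices), selected channels, the
#' graph edge list, and the full parameter echo. Deterministic: identical
#' inputs produce byte-identical files.
#'
#' @param tracking `axon_tracking` result.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_tracking_json <- function(tracking, path) {
  res <- list(
    schema = "axontrace/tracking/1",
    params = tracking$params,
    selected_channels = tracking$selected_channels - 1L,
    branches = lapply(tracking$branches, function(b) {
      list(channels = b$channels - 1L, velocity = b$velocity,
           offset = b$offset, r2 = b$r2, error = b$error, pval = b$pval,
           distances = b$distances, peak_times = b$peak_times)
    }),
    graph_edges = if (!is.null(tracking$graph))
      tracking$graph$edges else data.frame()
  )
  jsonlite::write_json(res, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
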