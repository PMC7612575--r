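#' Starting nodes for branch searches
#'
#' A path towards the initial channel is searched only from nodes that are
#' local maxima of h_init: nodes whose h_init is the largest among all graph
#' nodes within `local_max_radius`. This keeps the number of reconstructed
#' paths small; the maxima sit at the distal ends of axonal branches.
#' On ties the node earlier in the processing order wins and suppresses the
#' other.
#'
#' @param graph `axon_graph` from [build_axon_graph()].
#' @param locations channels x 2 layout matrix (um).
#' @param local_max_radius um (default 100).
#' @return integer vector of starting-node channels in processing order.
#' @export
find_starting_nodes <- function(graph, locations, local_max_radius = 100) {
  sel <- graph$nodes
  h <- graph$h_init
  rank_of <- match(sel, graph$order)  # position in processing order
  r2 <- local_max_radius^2
  is_max <- vapply(seq_along(sel), function(k) {
    d2 <- (locations[sel, 1L] - locations[sel[k], 1L])^2 +
          (locations[sel, 2L] - locations[sel[k], 2L])^2
    nb <- which(d2 <= r2)
    nb <- nb[nb != k]
    all(h[nb] < h[k] | (h[nb] == h[k] & rank_of[nb] > rank_of[k]))
  }, logical(1L))
  starts <- sel[is_max]
  starts[order(rank_of[is_max])]
}

#' Minimum-cost path from a starting node to the initial channel
#'
#' The path minimizing the accumulated edge cost `h_edge + d_n` over the
#' directed propagation graph. With non-negative additive costs and no
#' admissible distance-to-goal estimate available, the optimal-path search
#' runs with a zero heuristic, i.e. as Dijkstra's algorithm, which
#' guarantees the cost minimum.
#'
#' @param graph `axon_graph`.
#' @param start starting channel index.
#' @return integer vector of channels from `start` to the initial channel,
#'   or `NULL` when no path exists.
#' @export
astar_to_init <- function(graph, start) {
  stopifnot(start %in% graph$nodes)
  if (start == graph$init_channel) return(NULL)
  res <- suppressWarnings(igraph::shortest_paths(
    graph$igraph, from = as.character(start),
    to = as.character(graph$init_channel), mode = "out",
    weights = igraph::E(graph$igraph)$weight, output = "vpath"))
  vp <- res$vpath[[1L]]
  if (length(vp) == 0L) return(NULL)
  as.integer(igraph::V(graph$igraph)$name[as.integer(vp)])
}

#' Trim a new path against existing neighborhoods and attach it
#'
#' Channels of a newly found path that already lie in the neighbor set of an
#' existing path are removed; the surviving channel with the earliest peak
#' time is then connected to the closest node of the nearest existing path,
#' which becomes a *branching point* (an axonal bifurcation). A path fully
#' absorbed by existing neighborhoods is discarded.
#'
#' @param path integer channel sequence (start -> initial channel).
#' @param paths list of existing paths (each stored proximal -> distal).
#' @param neighbor_sets list of integer sets, one per existing path.
#' @param features data.frame from [channel_features()].
#' @param locations channels x 2 layout matrix.
#' @return list with `channels` (possibly empty) and `branch_point`
#'   (list `channel`, `path` or NULL).
#' @export
deduplicate_and_branch <- function(path, paths, neighbor_sets, features,
                                   locations) {
  taken <- unique(unlist(neighbor_sets))
  keep <- setdiff(path, taken)
  if (length(keep) == 0L || length(taken) == 0L || length(keep) == length(path))
    return(list(channels = keep, branch_point = NULL))
  anchor <- keep[which.min(features$peak_time[keep])]
  # nearest existing path: smallest node-to-anchor distance; ties by
  # creation order (which.min keeps the first)
  best <- vapply(paths, function(p) {
    min((locations[p, 1L] - locations[anchor, 1L])^2 +
        (locations[p, 2L] - locations[anchor, 2L])^2)
  }, numeric(1L))
  host <- which.min(best)
  hp <- paths[[host]]
  d2 <- (locations[hp, 1L] - locations[anchor, 1L])^2 +
        (locations[hp, 2L] - locations[anchor, 2L])^2
  bp <- hp[which.min(d2)]
  list(channels = keep, branch_point = list(channel = bp, path = host))
}

#' Prune branch stubs and merge chainable paths
#'
#' A path attached to a branching point is pruned (dropped) when the portion
#' extending beyond its branching point has fewer than
#' `min_points_after_branching` channels — such short stubs are artifacts
#' rather than axonal branches. Pairs of paths whose shared branching point
#' is the last channel of one path and the first channel of the other are
#' concatenated into a single branch.
#'
#' @param paths list of integer channel sequences (proximal -> distal).
#' @param branch_points list parallel to `paths`; each NULL or a list with
#'   `channel` (the branching-point channel, stored as the path's first
#'   entry) and `path` (index of the host path).
#' @param min_points_after_branching minimum channels past a branching point.
#' @return list with pruned-and-merged `paths` and `branch_points`.
#' @export
prune_and_merge <- function(paths, branch_points,
                            min_points_after_branching = 3L) {
  keep <- vapply(seq_along(paths), function(i) {
    bp <- branch_points[[i]]
    is.null(bp) || sum(paths[[i]] != bp$channel) >= min_points_after_branching
  }, logical(1L))
  paths <- paths[keep]
  branch_points <- branch_points[keep]

  # merge: branching point == last channel of the host and first of the child
  repeat {
    merged <- FALSE
    for (i in seq_along(paths)) {
      bp <- branch_points[[i]]
      if (is.null(bp) || paths[[i]][1L] != bp$channel) next
      host <- which(vapply(paths, function(p) p[length(p)] == bp$channel,
                           logical(1L)))
      host <- setdiff(host, i)
      if (length(host) == 0L) next
      host <- host[1L]
      paths[[host]] <- c(paths[[host]], paths[[i]][-1L])
      paths <- paths[-i]
      branch_points <- branch_points[-i]
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  list(paths = paths, branch_points = branch_points)
}

#' Raw-branch acceptance test
#'
#' A path is stored as a raw axonal branch only if (i) its length (sum of
#' consecutive inter-channel Euclidean distances) exceeds
#' `min_path_length` and (ii) it holds at least `min_path_points` channels.
#'
#' @param path integer channel sequence.
#' @param locations channels x 2 layout matrix.
#' @param min_path_length um (default 100).
#' @param min_path_points default 5.
#' @return logical.
#' @export
accept_raw_branch <- function(path, locations, min_path_length = 100,
                              min_path_points = 5L) {
  length(path) >= min_path_points &&
    path_length_um(path, locations) > min_path_length
}

path_length_um <- function(path, locations) {
  if (length(path) < 2L) return(0)
  p <- locations[path, , drop = FALSE]
  sum(sqrt(diff(p[, 1L])^2 + diff(p[, 2L])^2))
}

#' Reconstruct raw axonal branches from the propagation graph
#'
#' Loops over the starting nodes in processing order, searches the
#' minimum-cost path towards the initial channel, trims each new path
#' against the neighborhoods of already reconstructed paths (recording
#' branching points), prunes and merges, and keeps the paths that pass the
#' raw-branch acceptance test. Channels of an accepted branch and all
#' channels within `exclusion_radius` of it are excluded from further
#' searches so the same axonal branch is never reconstructed twice. Paths
#' are stored proximal -> distal (ascending peak time).
#'
#' @param graph `axon_graph`.
#' @param features data.frame from [channel_features()].
#' @param locations channels x 2 layout matrix.
#' @param params parameter list, see [axon_tracking_params()].
#' @return list with `paths` (raw branches, proximal -> distal),
#'   `branch_points`, and `starting_nodes`.
#' @export
reconstruct_branches <- function(graph, features, locations,
                                 params = axon_tracking_params()) {
  starts <- find_starting_nodes(graph, locations, params$local_max_radius)
  sel <- graph$nodes
  paths <- list(); branch_points <- list(); neighbor_sets <- list()
  excluded <- integer(0)

  for (s in starts) {
    if (s %in% excluded) next
    raw <- astar_to_init(graph, s)
    if (is.null(raw)) next
    ded <- deduplicate_and_branch(raw, paths, neighbor_sets, features,
                                  locations)
    if (length(ded$channels) == 0L) next
    # store proximal -> distal; prepend the branching point so it is shared
    p <- ded$channels[order(match(ded$channels, rev(raw)))]
    if (!is.null(ded$branch_point)) p <- c(ded$branch_point$channel, p)
    paths[[length(paths) + 1L]] <- p
    branch_points[length(paths)] <- list(ded$branch_point)
    # neighbor set: selected channels within neighbor_append_radius of the path
    neighbor_sets[[length(paths)]] <-
      channels_within(p, sel, locations, params$neighbor_append_radius)
    if (accept_raw_branch(p, locations, params$min_path_length,
                          params$min_path_points)) {
      excluded <- union(excluded,
                        channels_within(p, sel, locations,
                                        params$exclusion_radius))
    }
  }

  pm <- prune_and_merge(paths, branch_points,
                        params$min_points_after_branching)
  keep <- vapply(pm$paths, accept_raw_branch, logical(1L),
                 locations = locations,
                 min_path_length = params$min_path_length,
                 min_path_points = params$min_path_points)
  list(paths = pm$paths[keep], branch_points = pm$branch_points[keep],
       starting_nodes = starts)
}

channels_within <- function(path, channels, locations, radius_um) {
  r2 <- radius_um^2
  px <- locations[path, 1L]; py <- locations[path, 2L]
  hit <- vapply(channels, function(ch) {
    any((px - locations[ch, 1L])^2 + (py - locations[ch, 2L])^2 <= r2)
  }, logical(1L))
  channels[hit]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
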