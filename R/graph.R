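#' Node heuristic h_init
#'
#' Convex combination of min-max-normalized peak-to-peak amplitudes and peak
#' latencies over the selected channels:
#' `h_init = alpha * a_n + (1 - alpha) * p_n`, with later peaks getting
#' larger `p_n`. With the default `alpha_init = 0.2`, channels peaking
#' comparably late are favored, and among those the largest-amplitude ones —
#' these are the distal axonal sites where branch searches should start.
#' A degenerate normalization (all values equal) sets that component to 0.
#'
#' @param features data.frame from [channel_features()].
#' @param selected integer indices of the selected channels.
#' @param alpha_init amplitude weight in `[0, 1]`.
#' @return numeric vector of h_init values aligned with `selected`.
#' @export
compute_h_init <- function(features, selected, alpha_init = 0.2) {
  stopifnot(length(selected) >= 2L, alpha_init >= 0, alpha_init <= 1)
  a_n <- minmax_norm(features$amplitude[selected])
  p_n <- minmax_norm(features$peak_time[selected])
  alpha_init * a_n + (1 - alpha_init) * p_n
}

#' Processing order of the selected channels
#'
#' Descending h_init; ties broken by descending amplitude, then by channel
#' index (deterministic, order-independent).
#'
#' @param h_init per-channel heuristic values.
#' @param amplitude per-channel amplitudes (same length).
#' @param channels channel indices the two vectors refer to.
#' @return the channel indices in processing order.
#' @export
sort_channels <- function(h_init, amplitude, channels = seq_along(h_init)) {
  channels[order(-h_init, -amplitude, channels)]
}

#' Build the directed propagation graph
#'
#' Nodes are the selected channels. Each node gains at most `n_neighbors`
#' outgoing edges towards candidate parents: channels with a strictly
#' earlier signal peak lying within `max_edge_distance`. Among candidates,
#' the largest amplitudes are favored, ties broken by the lowest distance.
#' Nodes with no earlier-peaking candidate other than the initial channel
#' get a fallback edge to the initial channel when within
#' `init_channel_distance`. Each edge carries the mean amplitude of its two
#' endpoints; [compute_h_edge()] and [normalize_edge_distances()] then turn
#' amplitudes and distances into the additive search cost.
#'
#' @param selection `axon_selection` from [select_channels()].
#' @param features data.frame from [channel_features()].
#' @param locations channels x 2 layout matrix (um).
#' @param params parameter list, see [axon_tracking_params()].
#' @return object of class `axon_graph`: list with `nodes` (channel
#'   indices), `h_init`, `order` (processing order), `edges` (data.frame
#'   `child, parent, distance, edge_amplitude, h_edge, d_n, to_init`),
#'   `init_channel`, and `igraph` (the weighted directed graph; edge weight
#'   `h_edge + d_n`).
#' @export
build_axon_graph <- function(selection, features, locations,
                             params = axon_tracking_params()) {
  stopifnot(inherits(selection, "axon_selection"))
  sel <- selection$selected
  init <- selection$init_channel
  h_init <- compute_h_init(features, sel, params$alpha_init)
  ord <- sort_channels(h_init, features$amplitude[sel], sel)

  pt <- features$peak_time
  amp <- features$amplitude
  child <- integer(0); parent <- integer(0); dist_e <- numeric(0)
  for (i in sel) {
    d <- sqrt((locations[sel, 1L] - locations[i, 1L])^2 +
              (locations[sel, 2L] - locations[i, 2L])^2)
    earlier <- pt[sel] < pt[i] & sel != i
    cand <- sel[earlier & d <= params$max_edge_distance]
    keep <- integer(0)
    if (length(cand) > 0L) {
      dc <- d[match(cand, sel)]
      keep <- cand[order(-amp[cand], dc, cand)]
      keep <- keep[seq_len(min(params$n_neighbors, length(keep)))]
      child <- c(child, rep.int(i, length(keep)))
      parent <- c(parent, keep)
      dist_e <- c(dist_e, d[match(keep, sel)])
    }
    # orphan rule: no in-range earlier-peaking candidate besides the initial
    # channel -> connect straight to the initial channel if close enough
    if (i != init && length(setdiff(cand, init)) == 0L &&
        !(init %in% keep)) {
      d_init <- d[match(init, sel)]
      if (pt[i] > pt[init] && d_init <= params$init_channel_distance) {
        child <- c(child, i); parent <- c(parent, init)
        dist_e <- c(dist_e, d_init)
      }
    }
  }

  edges <- data.frame(child = child, parent = parent, distance = dist_e,
                      edge_amplitude = (amp[child] + amp[parent]) / 2,
                      to_init = parent == init)
  edges$h_edge <- compute_h_edge(edges$edge_amplitude, edges$to_init)
  edges$d_n <- normalize_edge_distances(edges$distance,
                                        params$distance_exponent)

  g <- igraph::make_empty_graph(n = length(sel), directed = TRUE)
  igraph::V(g)$name <- as.character(sel)
  if (nrow(edges) > 0L) {
    g <- igraph::add_edges(g, rbind(as.character(edges$child),
                                    as.character(edges$parent)))
    igraph::E(g)$weight <- edges$h_edge + edges$d_n
  }
  structure(list(nodes = sel, h_init = h_init, order = ord, edges = edges,
                 init_channel = init, igraph = g),
            class = "axon_graph")
}

#' Edge heuristic h_edge
#'
#' Edge amplitudes of non-init edges are min-max normalized and reversed so
#' the largest-amplitude edge costs 0 and the smallest costs 1; large
#' amplitudes mark the axonal path and should be cheap to traverse. All
#' edges pointing into the initial channel are set to 2 so the search enters
#' the initial channel only as a last resort. Degenerate normalization (all
#' amplitudes equal, or a single non-init edge) yields 0.
#'
#' @param edge_amplitude numeric vector of edge amplitudes (uV).
#' @param to_init logical vector, edge points into the initial channel.
#' @return numeric vector of h_edge values.
#' @export
compute_h_edge <- function(edge_amplitude, to_init) {
  h <- numeric(length(edge_amplitude))
  non <- !to_init
  if (any(non)) {
    a <- edge_amplitude[non]
    # degenerate normalization (all equal, or a single edge): cost 0
    h[non] <- if (diff(range(a)) > 0) 1 - minmax_norm(a) else 0
  }
  h[to_init] <- 2
  h
}

#' Normalized, super-linearly penalized edge distances
#'
#' `d_n = ((d - min d) / (max d - min d))^e`, with the minimum and maximum
#' taken once over all edges of the graph. An exponent above 1 penalizes
#' long jumps between nodes. Degenerate normalization yields 0.
#'
#' @param distance numeric vector of edge lengths (um).
#' @param e distance exponent (default 2).
#' @return numeric vector of normalized distances in `[0, 1]`.
#' @export
normalize_edge_distances <- function(distance, e = 2) {
  stopifnot(e >= 1)
  minmax_norm(distance)^e
}

#' @export
print.axon_graph <- function(x, ...) {
  cat(sprintf("axon_graph: %d nodes, %d edges (init channel %d)\n",
              length(x$nodes), nrow(x$edges), x$init_channel))
  invisible(x)
}

minmax_norm <- function(x) {
  if (length(x) == 0L) return(numeric(0))
  rng <- range(x)
  if (rng[2L] > rng[1L]) (x - rng[1L]) / (rng[2L] - rng[1L]) else
    numeric(length(x))
}
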