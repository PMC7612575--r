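# Independent brute-force oracles and small fixture builders.
# Everything here is deliberately naive (nested loops, exhaustive
# enumeration) so it stays independent of the package's vectorized code.

# flat trace with a negative Gaussian dip at a given time
dip_trace <- function(n_samples, fs, center_ms, amp_uv, sigma_ms = 0.1) {
  t <- (seq_len(n_samples) - 1L) * 1000 / fs
  -amp_uv * exp(-(t - center_ms)^2 / (2 * sigma_ms^2))
}

# template with one dip per channel at specified latencies/amplitudes
dip_template <- function(center_ms, amp_uv, fs = 32000, dur_ms = NULL,
                         sigma_ms = 0.1) {
  if (is.null(dur_ms)) dur_ms <- max(center_ms) + 1
  n <- ceiling(dur_ms * fs / 1000)
  v <- t(mapply(function(c, a) dip_trace(n, fs, c, a, sigma_ms),
                center_ms, amp_uv))
  axon_template(v, fs)
}

# O(n^2) neighborhood peak-time std
oracle_neighbor_std <- function(pt, loc, radius) {
  n <- length(pt)
  out <- numeric(n)
  for (i in seq_len(n)) {
    vals <- c()
    for (j in seq_len(n)) {
      d <- sqrt((loc[i, 1] - loc[j, 1])^2 + (loc[i, 2] - loc[j, 2])^2)
      if (d <= radius) vals <- c(vals, pt[j])
    }
    out[i] <- if (length(vals) < 2) Inf else sd(vals)
  }
  out
}

# exhaustive enumeration of all simple paths start -> goal; returns the
# minimum total weight (Inf when unreachable)
oracle_min_path_cost <- function(edges, start, goal) {
  best <- Inf
  recurse <- function(node, visited, cost) {
    if (cost >= best) return()
    if (node == goal) { best <<- cost; return() }
    out <- edges[edges$child == node & !(edges$parent %in% visited), ,
                 drop = FALSE]
    for (k in seq_len(nrow(out))) {
      recurse(out$parent[k], c(visited, out$parent[k]),
              cost + out$h_edge[k] + out$d_n[k])
    }
  }
  recurse(start, start, 0)
  best
}

# path cost under the graph's edge table
path_cost <- function(edges, path) {
  total <- 0
  for (k in seq_len(length(path) - 1L)) {
    row <- which(edges$child == path[k] & edges$parent == path[k + 1L])
    if (length(row) == 0L) return(Inf)
    total <- total + edges$h_edge[row] + edges$d_n[row]
  }
  total
}

# nested-loop Theil-Sen slope: median over every pair
oracle_theil_sen_slope <- function(x, y) {
  slopes <- c()
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (x[j] != x[i]) slopes <- c(slopes, (y[j] - y[i]) / (x[j] - x[i]))
  }
  median(slopes)
}

# random footprint-like feature set + layout on a jittered grid
random_instance <- function(n, seed, span = 200) {
  set.seed(seed)
  loc <- cbind(runif(n, 0, span), runif(n, 0, span))
  features <- data.frame(
    amplitude = runif(n, 10, 100),
    peak_time = round(runif(n, 0, 3), 3),
    kurtosis = runif(n, 0.5, 5),
    peak_std = runif(n, 0, 0.5)
  )
  features$amplitude[1L] <- 200  # make channel 1 the initial channel
  features$peak_time[1L] <- 0
  list(features = features, locations = loc)
}

# selection object without running the filters (all channels selected)
all_selected <- function(features) {
  structure(list(selected = seq_len(nrow(features)),
                 init_channel = which.max(features$amplitude),
                 masks = list()),
            class = "axon_selection")
}
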