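#' Regular electrode grid
#'
#' Row-major rectangular grid with the given pitch, origin at (0, 0):
#' channel 1 at (0, 0), channels increasing along x first.
#'
#' @param rows,cols grid dimensions.
#' @param pitch center-to-center electrode distance in um (default 17.5, the
#'   pitch of a 26'400-electrode HD-MEA).
#' @return channels x 2 layout matrix (um).
#' @export
make_grid <- function(rows, cols, pitch = 17.5) {
  stopifnot(rows >= 1, cols >= 1, pitch > 0)
  probe_layout(cbind(x = rep(seq_len(cols) - 1L, times = rows) * pitch,
                     y = rep(seq_len(rows) - 1L, each = cols) * pitch))
}

#' Parameters of the synthetic arbor generator
#'
#' @param branch_count number of axonal branches (default 3).
#' @param velocity_range mm/s; per-branch conduction velocities are drawn
#'   uniformly from this range (default 200-500 mm/s, the physiological
#'   range of unmyelinated cortical axons).
#' @param length_range um; per-branch arc lengths (default 380-480 um,
#'   comparable to reconstructed path lengths in culture).
#' @param segment_length um per polyline segment (default 20).
#' @param turn_sd standard deviation of the per-segment heading change in
#'   radians (default 0.08; gently curving branches).
#' @param onset_ms latency at the proximal end of each branch relative to
#'   the somatic peak (default 0.3 ms; axon-initial-segment delay).
#' @param preset `"radial"` (branches radiate from the soma with
#'   well-separated headings), `"straight"` (single straight branch), or
#'   `"Y"` (one trunk bifurcating into two daughters).
#' @return named parameter list.
#' @export
arbor_params <- function(branch_count = 3L,
                         velocity_range = c(200, 500),
                         length_range = c(380, 480),
                         segment_length = 20,
                         turn_sd = 0.08,
                         onset_ms = 0.3,
                         preset = c("radial", "straight", "Y")) {
  preset <- match.arg(preset)
  stopifnot(branch_count >= 1, all(velocity_range > 0),
            all(length_range > 0), segment_length > 0, turn_sd >= 0,
            onset_ms >= 0)
  list(branch_count = as.integer(branch_count),
       velocity_range = velocity_range, length_range = length_range,
       segment_length = segment_length, turn_sd = turn_sd,
       onset_ms = onset_ms, preset = preset)
}

#' Generate a ground-truth axonal arbor
#'
#' Produces a planar tree of polyline branches rooted at the soma, each with
#' a known conduction velocity and onset delay. All randomness is driven by
#' `seed`; the same seed always yields the same arbor.
#'
#' @param params list from [arbor_params()].
#' @param seed integer RNG seed.
#' @param soma soma position, length-2 numeric (um).
#' @return object of class `axon_arbor`: list with `branches` (each a list
#'   `xy` polyline matrix, `velocity` mm/s, `onset` ms) and `soma`.
#' @export
generate_arbor <- function(params = arbor_params(), seed = 0,
                           soma = c(0, 0)) {
  rng <- local_rng(seed)
  branches <- switch(params$preset,
    straight = {
      len <- mean(params$length_range)
      list(list(xy = polyline_walk(soma, 0, len, params$segment_length, 0,
                                   rng),
                velocity = mean(params$velocity_range),
                onset = params$onset_ms))
    },
    Y = {
      # wide (T-like) bifurcation: trunk plus two swept-back daughters, so
      # the bifurcation vertex is the closest point of the first branch to
      # every point of the second daughter
      len <- mean(params$length_range)
      v <- mean(params$velocity_range)
      trunk_len <- 0.4 * len
      daughter_len <- 0.6 * len
      trunk <- polyline_walk(soma, pi / 2, trunk_len,
                             params$segment_length, 0, rng)
      bif <- trunk[nrow(trunk), ]
      left <- polyline_walk(bif, pi / 2 + 1.2, daughter_len,
                            params$segment_length, 0, rng)
      right <- polyline_walk(bif, pi / 2 - 1.2, daughter_len,
                             params$segment_length, 0, rng)
      onset2 <- params$onset_ms + polyline_length(trunk) / v
      list(list(xy = rbind(trunk, left[-1L, ]), velocity = v,
                onset = params$onset_ms),
           list(xy = right, velocity = v, onset = onset2))
    },
    radial = {
      k <- params$branch_count
      base <- 2 * pi * (seq_len(k) - 1L) / k + rng$runif(1, 0, 2 * pi)
      headings <- base + rng$runif(k, -pi / (4 * k), pi / (4 * k))
      lapply(seq_len(k), function(i) {
        len <- rng$runif(1, params$length_range[1L], params$length_range[2L])
        v <- rng$runif(1, params$velocity_range[1L],
                       params$velocity_range[2L])
        list(xy = polyline_walk(soma, headings[i], len,
                                params$segment_length, params$turn_sd, rng),
             velocity = v, onset = params$onset_ms)
      })
    })
  structure(list(branches = branches, soma = as.numeric(soma),
                 params = params, seed = seed),
            class = "axon_arbor")
}

#' @export
print.axon_arbor <- function(x, ...) {
  cat(sprintf("axon_arbor: %d branches (preset %s, seed %s)\n",
              length(x$branches), x$params$preset, format(x$seed)))
  for (i in seq_along(x$branches)) {
    b <- x$branches[[i]]
    cat(sprintf("  branch %d: length %6.1f um, velocity %5.1f mm/s, onset %.2f ms\n",
                i - 1L, polyline_length(b$xy), b$velocity, b$onset))
  }
  invisible(x)
}

# self-avoiding-ish random walk polyline: fixed segment length, Gaussian
# heading increments
polyline_walk <- function(start, heading, total_length, segment_length,
                          turn_sd, rng) {
  n_seg <- max(1L, round(total_length / segment_length))
  turns <- if (turn_sd > 0) rng$rnorm(n_seg, 0, turn_sd) else numeric(n_seg)
  h <- heading + cumsum(c(0, turns[-1L]))
  xy <- rbind(start,
              cbind(start[1L] + cumsum(segment_length * cos(h)),
                    start[2L] + cumsum(segment_length * sin(h))))
  dimnames(xy) <- NULL
  xy
}

polyline_length <- function(xy) {
  sum(sqrt(diff(xy[, 1L])^2 + diff(xy[, 2L])^2))
}

#' Rendering parameters for synthetic footprints
#'
#' @param fs sampling frequency in Hz (default 32000, a 0.03125 ms time step).
#' @param plane_offset vertical electrode-to-tissue distance in um
#'   (default 10).
#' @param soma_peak_uv somatic peak amplitude directly above the soma
#'   (default 600 uV).
#' @param axon_peak_uv axonal peak amplitude directly above the axon
#'   (default 60 uV; an order of magnitude below the somatic signal, as in
#'   real footprints).
#' @param decay amplitude decay exponent: peak amplitude scales as
#'   `(lateral_distance^2 + plane_offset^2)^(-decay/2)` (default 2).
#' @param kernel_sigma_ms width of the negative Gaussian spike kernel in ms
#'   (default 0.1).
#' @param noise_uv white-noise standard deviation in uV (default 0).
#' @param soma_peak_ms time of the somatic peak within the window
#'   (default 0.5 ms).
#' @return named parameter list.
#' @export
render_params <- function(fs = 32000, plane_offset = 10, soma_peak_uv = 600,
                          axon_peak_uv = 60, decay = 2,
                          kernel_sigma_ms = 0.1, noise_uv = 0,
                          soma_peak_ms = 0.5) {
  stopifnot(fs > 0, plane_offset > 0, soma_peak_uv > 0, axon_peak_uv > 0,
            decay > 0, kernel_sigma_ms > 0, noise_uv >= 0, soma_peak_ms >= 0)
  list(fs = fs, plane_offset = plane_offset, soma_peak_uv = soma_peak_uv,
       axon_peak_uv = axon_peak_uv, decay = decay,
       kernel_sigma_ms = kernel_sigma_ms, noise_uv = noise_uv,
       soma_peak_ms = soma_peak_ms)
}

#' Render an arbor into an extracellular template
#'
#' Phenomenological forward model: each electrode sees (i) a somatic
#' deflection whose amplitude decays with distance from the soma and whose
#' peak sits at `soma_peak_ms`, and (ii) an axonal deflection from the
#' nearest point of the arbor, peaking at the ground-truth latency
#' `onset + arc_length / velocity` of that point, with amplitude
#' `scale / (lateral_distance^2 + plane_offset^2)^(decay/2)`. Waveforms are
#' negative Gaussian kernels; optional seeded white noise is added on top.
#' This reproduces exactly the two observables the tracking algorithm
#' consumes — per-channel peak amplitude and peak latency with axonal
#' structure — without simulating membrane biophysics.
#'
#' @param arbor `axon_arbor`.
#' @param locations channels x 2 layout matrix (um).
#' @param params list from [render_params()].
#' @param seed RNG seed for the additive noise.
#' @return list with `template` (`axon_template`), `latency_map`
#'   (data.frame per channel: `amplitude` uV, `latency` ms, `branch`,
#'   `arc_um`; latency relative to the somatic peak), and `coverage`
#'   (fraction of arbor sample points lying inside the layout's bounding
#'   box).
#' @export
render_template <- function(arbor, locations, params = render_params(),
                            seed = 0) {
  stopifnot(inherits(arbor, "axon_arbor"))
  locations <- probe_layout(locations)
  rng <- local_rng(seed)

  # resample the arbor at 2 um arc steps with per-point latency
  pts <- do.call(rbind, lapply(seq_along(arbor$branches), function(i) {
    b <- arbor$branches[[i]]
    rs <- resample_polyline(b$xy, step = 2)
    cbind(rs$xy, lat = b$onset + rs$arc / b$velocity, branch = i,
          arc = rs$arc)
  }))

  bb <- apply(locations, 2L, range)
  inside <- pts[, 1L] >= bb[1L, 1L] & pts[, 1L] <= bb[2L, 1L] &
            pts[, 2L] >= bb[1L, 2L] & pts[, 2L] <= bb[2L, 2L]
  coverage <- mean(inside)
  if (coverage < 1) {
    warning(sprintf("arbor extends outside the electrode grid (coverage %.0f%%)",
                    100 * coverage))
  }

  n_ch <- nrow(locations)
  h2 <- params$plane_offset^2
  soma_scale <- params$soma_peak_uv * params$plane_offset^params$decay
  axon_scale <- params$axon_peak_uv * params$plane_offset^params$decay

  # nearest arbor point per electrode (chunked)
  near_idx <- integer(n_ch); near_d2 <- numeric(n_ch)
  for (lo in seq(1L, n_ch, by = 512L)) {
    hi <- min(lo + 511L, n_ch)
    d2 <- outer(locations[lo:hi, 1L], pts[, 1L], "-")^2 +
          outer(locations[lo:hi, 2L], pts[, 2L], "-")^2
    near_idx[lo:hi] <- max.col(-d2, ties.method = "first")
    near_d2[lo:hi] <- d2[cbind(seq_len(hi - lo + 1L), near_idx[lo:hi])]
  }
  axon_amp <- axon_scale / (near_d2 + h2)^(params$decay / 2)
  axon_lat <- pts[near_idx, 3L]

  soma_d2 <- (locations[, 1L] - arbor$soma[1L])^2 +
             (locations[, 2L] - arbor$soma[2L])^2
  soma_amp <- soma_scale / (soma_d2 + h2)^(params$decay / 2)

  max_lat <- max(axon_lat)
  dur_ms <- params$soma_peak_ms + max_lat + 6 * params$kernel_sigma_ms + 0.5
  n_samp <- ceiling(dur_ms * params$fs / 1000)
  t_ms <- (seq_len(n_samp) - 1L) * 1000 / params$fs

  s2 <- 2 * params$kernel_sigma_ms^2
  v <- -soma_amp %o% rep(1, n_samp) *
         exp(-outer(rep(1, n_ch), (t_ms - params$soma_peak_ms)^2) / s2)
  centers <- params$soma_peak_ms + axon_lat
  v <- v - axon_amp * exp(-(outer(rep(1, n_ch), t_ms) - centers)^2 / s2)
  if (params$noise_uv > 0)
    v <- v + matrix(rng$rnorm(n_ch * n_samp, 0, params$noise_uv),
                    n_ch, n_samp)

  list(template = axon_template(v, params$fs),
       latency_map = data.frame(amplitude = axon_amp, latency = axon_lat,
                                branch = pts[near_idx, 4L],
                                arc_um = pts[near_idx, 5L]),
       coverage = coverage)
}

#' Simulate a complete synthetic footprint
#'
#' Places an arbor at the center of a regular electrode grid and renders the
#' template. One call yields everything the pipeline and the evaluation
#' need: template, layout, ground-truth arbor and latency map.
#'
#' @param params list from [arbor_params()].
#' @param seed integer seed driving both arbor generation and noise.
#' @param rows,cols,pitch grid geometry (default 64 x 64 at 17.5 um).
#' @param render list from [render_params()].
#' @return list with `template`, `locations`, `arbor`, `latency_map`,
#'   `coverage`.
#' @export
simulate_footprint <- function(params = arbor_params(), seed = 0,
                               rows = 64L, cols = 64L, pitch = 17.5,
                               render = render_params()) {
  locations <- make_grid(rows, cols, pitch)
  soma <- c(mean(range(locations[, 1L])), mean(range(locations[, 2L])))
  arbor <- generate_arbor(params, seed = seed, soma = soma)
  rt <- render_template(arbor, locations, render, seed = seed + 1L)
  c(rt["template"], list(locations = locations, arbor = arbor),
    rt[c("latency_map", "coverage")])
}

# private, restartable RNG that never touches the global .Random.seed
local_rng <- function(seed) {
  env <- new.env()
  assign("state", NULL, envir = env)
  run <- function(f, ...) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      assign("state", get(".Random.seed", globalenv()), envir = env)
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old, envir = globalenv())
    })
    if (is.null(env$state)) set.seed(seed) else
      assign(".Random.seed", env$state, envir = globalenv())
    f(...)
  }
  list(runif = function(n, min = 0, max = 1) run(stats::runif, n, min, max),
       rnorm = function(n, mean = 0, sd = 1) run(stats::rnorm, n, mean, sd))
}
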