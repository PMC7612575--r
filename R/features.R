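#' Per-channel peak-to-peak amplitude
#'
#' @param template `axon_template`.
#' @return numeric vector, max - min per channel, in uV.
#' @export
peak_to_peak <- function(template) {
  v <- template$voltages
  apply(v, 1L, max) - apply(v, 1L, min)
}

#' Per-channel peak time
#'
#' Time of the most-negative sample of each channel, in milliseconds from the
#' start of the template window. Ties are broken by the earliest sample.
#'
#' @param template `axon_template`.
#' @return numeric vector of peak times in ms.
#' @export
peak_time <- function(template) {
  idx <- apply(template$voltages, 1L, which.min)  # which.min: first minimum
  (idx - 1L) * 1000 / template$fs
}

#' Per-channel excess kurtosis
#'
#' Fourth standardized moment minus 3, with population (biased) moment
#' estimators over the full template window, so that positive values indicate
#' a supergaussian (spike-bearing) trace. Zero-variance traces get `-Inf`,
#' which always fails the kurtosis filter.
#'
#' @param template `axon_template`.
#' @return numeric vector of excess kurtosis values.
#' @export
excess_kurtosis <- function(template) {
  v <- template$voltages
  m <- rowMeans(v)
  d <- v - m
  m2 <- rowMeans(d^2)
  m4 <- rowMeans(d^4)
  k <- ifelse(m2 > 0, m4 / m2^2 - 3, -Inf)
  as.numeric(k)
}

#' Peak-time dispersion over neighboring channels
#'
#' For each channel, the standard deviation of the peak times of the channel
#' itself plus all channels within `radius_um` (Euclidean). Coherent peak
#' times in a neighborhood indicate signal; random ones indicate noise.
#' Channels whose neighborhood holds fewer than 2 values get `Inf` and thus
#' fail the dispersion filter.
#'
#' @param peak_times per-channel peak times (ms).
#' @param locations channels x 2 layout matrix (um).
#' @param radius_um neighborhood radius in um.
#' @return numeric vector of standard deviations (ms).
#' @export
neighbor_peak_std <- function(peak_times, locations, radius_um) {
  stopifnot(radius_um > 0, length(peak_times) == nrow(locations))
  n <- length(peak_times)
  r2 <- radius_um^2
  out <- numeric(n)
  # chunked so the distance matrix never exceeds 1024 x n
  for (lo in seq(1L, n, by = 1024L)) {
    hi <- min(lo + 1023L, n)
    d2 <- outer(locations[lo:hi, 1L], locations[, 1L], "-")^2 +
          outer(locations[lo:hi, 2L], locations[, 2L], "-")^2
    out[lo:hi] <- vapply(seq_len(hi - lo + 1L), function(k) {
      nb <- which(d2[k, ] <= r2)
      if (length(nb) < 2L) Inf else stats::sd(peak_times[nb])
    }, numeric(1L))
  }
  out
}

#' Compute all per-channel selection features
#'
#' @param template `axon_template`.
#' @param locations channels x 2 layout matrix (um).
#' @param peak_std_radius neighborhood radius for the peak-time dispersion
#'   feature (um).
#' @return data.frame with columns `amplitude` (uV), `peak_time` (ms),
#'   `kurtosis`, `peak_std` (ms).
#' @export
channel_features <- function(template, locations, peak_std_radius = 30) {
  probe_layout(locations, n_channels = nrow(template$voltages))
  pt <- peak_time(template)
  data.frame(
    amplitude = peak_to_peak(template),
    peak_time = pt,
    kurtosis  = excess_kurtosis(template),
    peak_std  = neighbor_peak_std(pt, locations, peak_std_radius)
  )
}
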