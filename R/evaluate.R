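#' Branch-matching parameters
#'
#' @param match_median_distance um; a ground-truth branch matches an
#'   estimated branch when the median distance of its sample points to the
#'   estimated path falls below this (default 40).
#' @param overlap_fraction fraction of sample points within
#'   `overlap_distance` above which two ground-truth branches matched to the
#'   same estimate count as overlapping (default 0.20).
#' @param overlap_distance um (default 15).
#' @param resample_step um; ground-truth polylines are resampled at this
#'   arc-length step before distance computations (default 1).
#' @return named parameter list.
#' @export
match_params <- function(match_median_distance = 40, overlap_fraction = 0.20,
                         overlap_distance = 15, resample_step = 1) {
  stopifnot(match_median_distance > 0, overlap_fraction > 0,
            overlap_fraction < 1, overlap_distance > 0, resample_step > 0)
  list(match_median_distance = match_median_distance,
       overlap_fraction = overlap_fraction,
       overlap_distance = overlap_distance, resample_step = resample_step)
}

#' Resample a polyline at fixed arc-length steps
#'
#' @param xy n x 2 polyline vertex matrix (um).
#' @param step arc-length step (um).
#' @return list with `xy` (resampled points, endpoints included) and `arc`
#'   (cumulative arc length of each point).
#' @export
resample_polyline <- function(xy, step = 1) {
  seg <- sqrt(diff(xy[, 1L])^2 + diff(xy[, 2L])^2)
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  s <- unique(c(seq(0, total, by = step), total))
  x <- stats::approx(arc, xy[, 1L], xout = s)$y
  y <- stats::approx(arc, xy[, 2L], xout = s)$y
  list(xy = cbind(x, y), arc = s)
}

#' Distance from points to a polyline
#'
#' Minimum Euclidean distance from each query point to any *segment* (not
#' vertex) of the polyline.
#'
#' @param points m x 2 query points.
#' @param xy n x 2 polyline vertices.
#' @return numeric vector of m distances.
#' @export
point_polyline_distance <- function(points, xy) {
  points <- matrix(points, ncol = 2L)
  if (nrow(xy) == 1L)
    return(sqrt((points[, 1L] - xy[1L, 1L])^2 +
                (points[, 2L] - xy[1L, 2L])^2))
  a <- xy[-nrow(xy), , drop = FALSE]
  b <- xy[-1L, , drop = FALSE]
  ab <- b - a
  len2 <- pmax(ab[, 1L]^2 + ab[, 2L]^2, .Machine$double.eps)
  best <- rep(Inf, nrow(points))
  for (s in seq_len(nrow(a))) {
    t <- ((points[, 1L] - a[s, 1L]) * ab[s, 1L] +
          (points[, 2L] - a[s, 2L]) * ab[s, 2L]) / len2[s]
    t <- pmin(pmax(t, 0), 1)
    d2 <- (points[, 1L] - (a[s, 1L] + t * ab[s, 1L]))^2 +
          (points[, 2L] - (a[s, 2L] + t * ab[s, 2L]))^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Match ground-truth branches to estimated branches
#'
#' Many-to-one matching: each ground-truth branch is assigned to the
#' estimated branch to which the median of its (resampled) point distances
#' is smallest, provided that median is below `match_median_distance` — an
#' estimated branch may thus span several ground-truth branches. Among
#' ground-truth branches matched to the same estimate, overlapping pairs
#' (more than `overlap_fraction` of either branch's points within
#' `overlap_distance` of the other) drop the shorter member.
#'
#' @param estimated list of estimated branch polylines (channel positions,
#'   n x 2 matrices).
#' @param arbor `axon_arbor` ground truth.
#' @param params list from [match_params()].
#' @return list, one element per estimated branch, each an integer vector of
#'   matched ground-truth branch indices (possibly empty).
#' @export
match_branches <- function(estimated, arbor, params = match_params()) {
  gt <- lapply(arbor$branches, function(b)
    resample_polyline(b$xy, params$resample_step))
  n_gt <- length(gt); n_est <- length(estimated)
  assign_to <- rep(NA_integer_, n_gt)
  if (n_est > 0L) {
    med <- matrix(Inf, n_gt, n_est)
    for (g in seq_len(n_gt)) for (e in seq_len(n_est))
      med[g, e] <- stats::median(
        point_polyline_distance(gt[[g]]$xy, estimated[[e]]))
    for (g in seq_len(n_gt)) {
      e <- which.min(med[g, ])
      if (med[g, e] < params$match_median_distance) assign_to[g] <- e
    }
  }
  lengths_gt <- vapply(arbor$branches, function(b) polyline_length(b$xy),
                       numeric(1L))
  lapply(seq_len(n_est), function(e) {
    ids <- which(assign_to == e)
    # drop the shorter of each overlapping pair
    drop <- logical(length(ids))
    if (length(ids) > 1L) {
      for (i in seq_along(ids)) for (j in seq_along(ids)) {
        if (i == j || drop[i] || drop[j]) next
        fi <- mean(point_polyline_distance(gt[[ids[i]]]$xy,
                                           arbor$branches[[ids[j]]]$xy) <=
                   params$overlap_distance)
        if (fi > params$overlap_fraction) {
          shorter <- if (lengths_gt[ids[i]] <= lengths_gt[ids[j]]) i else j
          drop[shorter] <- TRUE
        }
      }
    }
    ids[!drop]
  })
}

#' Tracking error of an estimated branch
#'
#' Distance from each channel of the estimated branch to the closest
#' segment of its matched ground-truth branches, summarized as mean and
#' standard deviation.
#'
#' @param est_xy n x 2 channel positions of the estimated branch.
#' @param gt_branches list of matched ground-truth branch polylines.
#' @return list with `mean` and `sd` (um).
#' @export
tracking_error <- function(est_xy, gt_branches) {
  stopifnot(length(gt_branches) > 0L)
  d <- do.call(pmin, lapply(gt_branches, function(xy)
    point_polyline_distance(est_xy, xy)))
  list(mean = mean(d), sd = stats::sd(d))
}

#' Velocity errors of an estimated branch
#'
#' The ground-truth velocity is the length-weighted average of the matched
#' ground-truth branch velocities; errors are `abs(v_gt - v_est)` and the
#' same relative to `v_gt`.
#'
#' @param v_est estimated velocity (mm/s).
#' @param gt_branches list of matched ground-truth branches (each with `xy`
#'   and `velocity`).
#' @return list with `v_gt`, `abs_error`, `rel_error`.
#' @export
velocity_errors <- function(v_est, gt_branches) {
  stopifnot(length(gt_branches) > 0L)
  l <- vapply(gt_branches, function(b) polyline_length(b$xy), numeric(1L))
  v <- vapply(gt_branches, function(b) b$velocity, numeric(1L))
  v_gt <- sum(l * v) / sum(l)
  list(v_gt = v_gt, abs_error = abs(v_gt - v_est),
       rel_error = abs(v_gt - v_est) / v_gt)
}

#' Evaluate a tracking result against ground truth
#'
#' @param tracking `axon_tracking` result from [track_axons()].
#' @param arbor `axon_arbor` ground truth.
#' @param locations channels x 2 layout matrix used for tracking.
#' @param params list from [match_params()].
#' @param model_id optional label for the first report column.
#' @return data.frame, one row per estimated branch: `model`, `branch`,
#'   `matched_gt` (comma-separated 0-based ids, empty when unmatched),
#'   `velocity_gt`, `velocity_est`, `abs_error`, `rel_error`,
#'   `tracking_error_mean`, `tracking_error_sd`.
#' @export
evaluate_tracking <- function(tracking, arbor, locations,
                              params = match_params(), model_id = "model") {
  est_xy <- lapply(tracking$branches, function(b)
    locations[b$channels, , drop = FALSE])
  matches <- match_branches(est_xy, arbor, params)
  rows <- lapply(seq_along(est_xy), function(e) {
    ids <- matches[[e]]
    if (length(ids) == 0L) {
      return(data.frame(model = model_id, branch = e - 1L, matched_gt = "",
                        velocity_gt = NA_real_,
                        velocity_est = tracking$branches[[e]]$velocity,
                        abs_error = NA_real_, rel_error = NA_real_,
                        tracking_error_mean = NA_real_,
                        tracking_error_sd = NA_real_))
    }
    gtb <- arbor$branches[ids]
    te <- tracking_error(est_xy[[e]], lapply(gtb, `[[`, "xy"))
    ve <- velocity_errors(tracking$branches[[e]]$velocity, gtb)
    data.frame(model = model_id, branch = e - 1L,
               matched_gt = paste(ids - 1L, collapse = ","),
               velocity_gt = ve$v_gt,
               velocity_est = tracking$branches[[e]]$velocity,
               abs_error = ve$abs_error, rel_error = ve$rel_error,
               tracking_error_mean = te$mean, tracking_error_sd = te$sd)
  })
  do.call(rbind, rows)
}
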