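#' Peak latencies and cumulative distances along a branch
#'
#' Peak times are referenced to the first (earliest-peaking) channel of the
#' path; cumulative distances integrate the Euclidean inter-channel
#' distances along the path. With times in ms and distances in um, the slope
#' of distance versus time is directly a velocity in mm/s (um/ms == mm/s).
#'
#' @param path integer channel sequence (proximal -> distal).
#' @param features data.frame from [channel_features()].
#' @param locations channels x 2 layout matrix (um).
#' @return list with `peak_times` (ms, first entry 0) and `distances`
#'   (um, first entry 0).
#' @export
branch_kinematics <- function(path, features, locations) {
  pt <- features$peak_time[path]
  p <- locations[path, , drop = FALSE]
  seg <- if (length(path) > 1L)
    sqrt(diff(p[, 1L])^2 + diff(p[, 2L])^2) else numeric(0)
  list(peak_times = pt - pt[1L], distances = c(0, cumsum(seg)))
}

#' Theil-Sen robust line fit
#'
#' The slope is the median of all pairwise slopes between points with
#' distinct abscissae; the intercept is the median of `y - slope * x`. This
#' estimator tolerates up to ~29% gross outliers. R^2 is the coefficient of
#' determination of the robust line's predictions; the standard error and
#' p-value come from the two-sided slope test of an ordinary least-squares
#' fit on the same points (reported alongside as conventional fit
#' diagnostics).
#'
#' @param x abscissae (here: peak times, ms).
#' @param y ordinates (here: cumulative distances, um).
#' @return list with `slope` (mm/s when x is ms and y um), `intercept`,
#'   `r2`, `stderr`, `pval`.
#' @export
theil_sen_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (length(unique(x)) < 2L)
    stop("Theil-Sen fit needs at least two distinct abscissae")
  n <- length(x)
  ij <- utils::combn(n, 2L)
  dx <- x[ij[2L, ]] - x[ij[1L, ]]
  dy <- y[ij[2L, ]] - y[ij[1L, ]]
  slopes <- dy[dx != 0] / dx[dx != 0]
  slope <- stats::median(slopes)
  intercept <- stats::median(y - slope * x)
  pred <- intercept + slope * x
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else as.numeric(ss_res == 0)
  # summary.lm warns on exactly collinear points; that case is legitimate here
  ols <- suppressWarnings(summary(stats::lm(y ~ x))$coefficients)
  list(slope = slope, intercept = intercept, r2 = r2,
       stderr = unname(ols["x", "Std. Error"]),
       pval = unname(ols["x", "Pr(>|t|)"]))
}

#' MAD-based outlier removal from a branch fit
#'
#' A channel is an outlier when its prediction error (absolute residual of
#' the robust line) exceeds both `mad_multiplier` times the raw median
#' absolute deviation of the residuals and the fixed
#' `outlier_distance_threshold`. Removal is a single pass followed by one
#' refit.
#'
#' @param peak_times,distances branch kinematics.
#' @param fit a [theil_sen_fit()] result.
#' @param mad_multiplier N of the N x MAD rule (default 8).
#' @param outlier_distance_threshold um (default 30).
#' @return list with `keep` (logical mask), refitted `fit` (or NULL when
#'   fewer than 2 points survive).
#' @export
remove_outliers <- function(peak_times, distances, fit, mad_multiplier = 8,
                            outlier_distance_threshold = 30) {
  resid <- abs(distances - (fit$intercept + fit$slope * peak_times))
  mad_r <- stats::median(abs(resid - stats::median(resid)))
  keep <- !(resid > mad_multiplier * mad_r &
            resid > outlier_distance_threshold)
  refit <- NULL
  if (sum(keep) >= 2L && length(unique(peak_times[keep])) >= 2L) {
    refit <- if (all(keep)) fit else
      theil_sen_fit(peak_times[keep], distances[keep])
  }
  list(keep = keep, fit = refit)
}

#' Split a branch at a peak-time jump
#'
#' A large gap between consecutive peak times signals a shortcut across an
#' undetected axonal section. When any consecutive gap exceeds
#' `split_jump_threshold`, the branch is split at the largest such gap and
#' both halves are refit; the split is kept only when the mean R^2 of the
#' sub-fits beats the original R^2. Splitting recurses on the halves, so
#' several jumps produce several sub-branches. Sub-branches must still hold
#' `min_points` channels.
#'
#' @param idx integer positions (into the branch) under consideration.
#' @param peak_times,distances branch kinematics (full vectors).
#' @param split_jump_threshold ms (default 1).
#' @param min_points minimum channels per sub-branch.
#' @return list of index vectors, each one a (sub-)branch.
#' @export
split_on_jump <- function(idx, peak_times, distances,
                          split_jump_threshold = 1, min_points = 5L) {
  if (length(idx) < 2L * min_points) return(list(idx))
  t <- peak_times[idx]
  gaps <- diff(t)
  if (!any(gaps > split_jump_threshold)) return(list(idx))
  cut <- which.max(gaps)  # largest gap; split between cut and cut+1
  left <- idx[seq_len(cut)]
  right <- idx[(cut + 1L):length(idx)]
  if (length(left) < min_points || length(right) < min_points ||
      length(unique(peak_times[left])) < 2L ||
      length(unique(peak_times[right])) < 2L)
    return(list(idx))
  whole <- theil_sen_fit(t, distances[idx])
  fl <- theil_sen_fit(peak_times[left], distances[left] - distances[left][1L])
  fr <- theil_sen_fit(peak_times[right],
                      distances[right] - distances[right][1L])
  if (mean(c(fl$r2, fr$r2)) > whole$r2) {
    c(split_on_jump(left, peak_times, distances, split_jump_threshold,
                    min_points),
      split_on_jump(right, peak_times, distances, split_jump_threshold,
                    min_points))
  } else {
    list(idx)
  }
}

#' Clean raw branches and estimate conduction velocities
#'
#' For each raw path: compute kinematics, fit the Theil-Sen line, remove
#' MAD outliers and refit, attempt jump splitting, and finally discard
#' branches whose R^2 falls below `r2_threshold` or whose fitted velocity
#' is not positive.
#'
#' @param paths list of raw branch channel sequences (proximal -> distal).
#' @param features data.frame from [channel_features()].
#' @param locations channels x 2 layout matrix (um).
#' @param params parameter list, see [axon_tracking_params()].
#' @return list of accepted branches; each a list with `channels`,
#'   `velocity` (mm/s), `offset` (um), `r2`, `error`, `pval`, `distances`
#'   (um), `peak_times` (ms).
#' @export
estimate_velocities <- function(paths, features, locations,
                                params = axon_tracking_params()) {
  branches <- list()
  for (path in paths) {
    kin <- branch_kinematics(path, features, locations)
    if (length(unique(kin$peak_times)) < 2L) next
    pieces <- split_on_jump(seq_along(path), kin$peak_times, kin$distances,
                            params$split_jump_threshold,
                            params$min_path_points)
    for (idx in pieces) {
      ch <- path[idx]
      t <- kin$peak_times[idx] - kin$peak_times[idx][1L]
      d <- kin$distances[idx] - kin$distances[idx][1L]
      if (length(unique(t)) < 2L) next
      fit <- theil_sen_fit(t, d)
      out <- remove_outliers(t, d, fit, params$mad_multiplier,
                             params$outlier_distance_threshold)
      if (is.null(out$fit)) next
      ch <- ch[out$keep]; t <- t[out$keep]; d <- d[out$keep]
      fit <- out$fit
      if (length(ch) < params$min_path_points) next
      if (fit$slope <= 0) next
      branches[[length(branches) + 1L]] <- list(
        channels = ch, velocity = fit$slope, offset = fit$intercept,
        r2 = fit$r2, error = fit$stderr, pval = fit$pval,
        distances = d, peak_times = t)
    }
  }
  finalize_branches(branches, params$r2_threshold)
}

#' Final R^2 gate on fitted branches
#'
#' @param branches list of fitted branch records.
#' @param r2_threshold minimum coefficient of determination (default 0.9).
#' @return the branches whose `r2` passes the threshold.
#' @export
finalize_branches <- function(branches, r2_threshold = 0.9) {
  Filter(function(b) b$r2 >= r2_threshold, branches)
}
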