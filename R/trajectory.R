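#' A fixed-rate navigation trajectory
#'
#' One participant-trial's position log: time-stamped `(x, y)` samples in vm
#' recorded at a fixed sampling interval. Construction validates the
#' fixed-rate contract (every interval within half a nominal `dt` of `dt`)
#' and strict time monotonicity.
#'
#' @param participant_id participant identifier.
#' @param trial_id trial identifier.
#' @param t numeric timestamps in seconds, strictly increasing, >= 3 samples.
#' @param x,y coordinates in vm.
#' @param dt nominal sampling interval; defaults to the median observed
#'   interval.
#' @return an object of class `nav_trajectory`: a data.frame with columns
#'   `t`, `x`, `y` and attributes `participant_id`, `trial_id`, `dt`.
#' @export
trajectory <- function(participant_id, trial_id, t, x, y, dt = NULL) {
  n <- length(t)
  if (n < 3) stop("data error: a trajectory needs at least 3 samples")
  if (length(x) != n || length(y) != n)
    stop("data error: t, x, y must have equal length")
  if (anyNA(t) || anyNA(x) || anyNA(y))
    stop("data error: trajectory contains missing values")
  dif <- diff(t)
  if (any(dif <= 0))
    stop("data error: timestamps must be strictly increasing (duplicate or ",
         "reversed timestamps at index ", which(dif <= 0)[1] + 1, ")")
  if (is.null(dt)) dt <- median(dif)
  if (any(abs(dif - dt) > 0.5 * dt))
    stop("data error: sampling violates the fixed-rate contract (interval ",
         "deviates more than dt/2 from dt=", dt, ")")
  structure(
    data.frame(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y)),
    participant_id = participant_id, trial_id = trial_id, dt = as.numeric(dt),
    class = c("nav_trajectory", "data.frame"))
}

#' @export
print.nav_trajectory <- function(x, ...) {
  cat(sprintf("<nav_trajectory> participant %s, trial %s: %d samples @ dt=%g s, %.1f s\n",
              attr(x, "participant_id"), attr(x, "trial_id"), nrow(x),
              attr(x, "dt"), diff(range(x$t))))
  invisible(x)
}

#' Path length of a trajectory
#'
#' Sum of consecutive Euclidean steps, in vm.
#'
#' @param traj a [trajectory()].
#' @return numeric scalar.
#' @export
trajectory_distance <- function(traj) {
  sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
}

#' Instantaneous speed series
#'
#' For each interior sample the instantaneous speed is the average of the two
#' adjacent-interval velocity estimates:
#' `v_i = (dist(i-1, i)/(t_i - t_{i-1}) + dist(i, i+1)/(t_{i+1} - t_i)) / 2`.
#' The first and last samples have only one adjacent interval and are
#' excluded, so the series has length `n - 2`.
#'
#' @param traj a [trajectory()].
#' @return numeric vector of non-negative speeds (vm/s), length `n - 2`.
#' @export
instantaneous_speed <- function(traj) {
  stopifnot(inherits(traj, "nav_trajectory"))
  step <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  vel <- step / diff(traj$t)
  (head(vel, -1) + tail(vel, -1)) / 2
}

#' Flag a trial as containing a route error
#'
#' A trial is error-flagged when any sample strays farther than
#' `deviation_threshold` (perpendicular distance) from the intended shortest
#' route.
#'
#' @param traj a [trajectory()].
#' @param route two-column matrix of route polyline vertices (vm).
#' @param deviation_threshold distance in vm; a sensible default is one
#'   street width.
#' @return logical scalar.
#' @export
flag_route_error <- function(traj, route, deviation_threshold) {
  stopifnot(inherits(traj, "nav_trajectory"), nrow(route) >= 2)
  if (is.infinite(deviation_threshold)) return(FALSE)
  d <- point_polyline_distance(traj$x, traj$y, route)
  max(d) > deviation_threshold
}
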