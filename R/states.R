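# Navigation-state segmentation: per-participant 1-D k-means on instantaneous
# speed. The three clusters, ordered by centroid, are interpreted as
# WAYFINDING (low speed: searching, hesitation, reorientation),
# TRANSITION (medium: directional adjustment, preparatory acceleration) and
# MOVING (high: continuous goal-directed locomotion). Clustering each
# participant separately yields individualized relative speed thresholds
# rather than one absolute cutoff for everyone.

# Deterministic initializations: sample quantiles at (2j-1)/(2k), the same
# quantiles of the distinct values, and even spacing over the data range.
# Speed distributions are heavily unbalanced (most samples sit in the moving
# regime), which can park every sample-quantile seed inside one regime and
# strand Lloyd in a poor local optimum; Lloyd is therefore run from each
# start and the lowest-SSE solution kept. All starts are deterministic, so
# repeated fits need no RNG.
candidate_centers <- function(x, k) {
  probs <- (2 * seq_len(k) - 1) / (2 * k)
  ux <- sort(unique(x))
  starts <- list(
    unname(quantile(x, probs, type = 7)),
    unname(quantile(ux, probs, type = 7)),
    min(x) + probs * (max(x) - min(x))
  )
  Filter(function(ctr) !anyDuplicated(ctr), starts)
}

#' Cluster a speed series into navigation states
#'
#' One-dimensional k-means (Lloyd iterations from a small set of
#' deterministic quantile/range seeds, best SSE kept, so repeated runs need
#' no RNG) on the interior-sample speed series.
#' For `k = 3` the ascending-centroid clusters are labelled WAYFINDING,
#' TRANSITION, MOVING.
#'
#' @param speeds numeric speed series from [instantaneous_speed()] (one
#'   trial, or a participant's trials pooled).
#' @param k number of clusters (default 3).
#' @param iter_max maximum Lloyd iterations.
#' @return object of class `state_labeling`: `cluster` (1..k by ascending
#'   centroid per sample), `state` (factor, only for `k = 3`), `centroids`
#'   (ascending), `sse` (within-cluster sum of squares), `k`.
#' @export
fit_speed_states <- function(speeds, k = 3, iter_max = 300) {
  stopifnot(is.numeric(speeds), k >= 2)
  if (length(unique(speeds)) < k)
    stop("degenerate input: fewer than k = ", k, " distinct speed values")
  starts <- candidate_centers(speeds, k)
  if (!length(starts))
    stop("degenerate input: no distinct initial centers available")
  fits <- lapply(starts, function(ctr) {
    tryCatch(
      suppressWarnings(kmeans(speeds, centers = matrix(ctr, ncol = 1),
                              iter.max = iter_max, algorithm = "Lloyd")),
      error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("degenerate input: k-means failed from every start")
  km <- fits[[which.min(vapply(fits, `[[`, numeric(1), "tot.withinss"))]]
  cent <- as.numeric(km$centers)
  if (anyDuplicated(cent))
    stop("degenerate input: k-means converged to duplicate centroids")
  ord <- order(cent)
  rank_of <- integer(k); rank_of[ord] <- seq_len(k)
  cl <- rank_of[km$cluster]
  state <- NULL
  if (k == 3)
    state <- factor(.nav_states[cl], levels = .nav_states)
  structure(list(cluster = cl, state = state,
                 centroids = cent[ord], sse = km$tot.withinss, k = k),
            class = "state_labeling")
}

#' @export
print.state_labeling <- function(x, ...) {
  cat(sprintf("<state_labeling> k=%d, n=%d, centroids: %s vm/s, SSE=%.4g\n",
              x$k, length(x$cluster),
              paste(signif(x$centroids, 4), collapse = ", "), x$sse))
  invisible(x)
}

#' Mean silhouette width for a 1-D clustering
#'
#' Exact mean silhouette coefficient computed in O(n log n) using sorted
#' prefix sums of each cluster (mean absolute deviation of a point from a
#' sorted set is a two-term prefix-sum expression), instead of the O(n^2)
#' pairwise-distance matrix. Singleton clusters contribute silhouette 0.
#'
#' @param x numeric data.
#' @param cluster integer cluster assignment.
#' @return mean silhouette width in \[-1, 1\].
#' @export
silhouette_1d <- function(x, cluster) {
  stopifnot(length(x) == length(cluster))
  ks <- sort(unique(cluster))
  if (length(ks) < 2) stop("silhouette needs >= 2 clusters")
  sorted <- lapply(ks, function(kk) sort(x[cluster == kk]))
  prefix <- lapply(sorted, function(s) c(0, cumsum(s)))
  sizes <- vapply(sorted, length, integer(1))
  # sum of |v - s_j| over sorted set s with prefix sums P
  sumdist <- function(v, s, P) {
    K <- length(s)
    idx <- findInterval(v, s)
    v * idx - P[idx + 1] + (P[K + 1] - P[idx + 1]) - v * (K - idx)
  }
  n <- length(x)
  a <- numeric(n); b <- rep(Inf, n)
  for (ci in seq_along(ks)) {
    own <- cluster == ks[ci]
    for (cj in seq_along(ks)) {
      sd_ <- sumdist(x[own], sorted[[cj]], prefix[[cj]])
      if (ci == cj) {
        a[own] <- if (sizes[cj] > 1) sd_ / (sizes[cj] - 1) else NA_real_
      } else {
        b[own] <- pmin(b[own], sd_ / sizes[cj])
      }
    }
  }
  s <- (b - a) / pmax(a, b)
  s[is.na(a)] <- 0            # singleton-cluster convention
  s[a == 0 & b == 0] <- 0
  mean(s)
}

#' Per-k clustering diagnostics for choosing the number of states
#'
#' Runs the deterministic 1-D k-means for each `k` and reports the
#' within-cluster sum of squared errors (SSE, the elbow-curve quantity) and
#' the mean silhouette coefficient. An elbow in SSE together with a high and
#' stable silhouette motivates the three-state solution.
#'
#' @param speeds numeric speed series.
#' @param k_range integer vector of candidate k (default `2:6`).
#' @return data.frame with columns `k`, `sse`, `silhouette`.
#' @export
cluster_diagnostics <- function(speeds, k_range = 2:6) {
  stopifnot(all(k_range >= 2))
  if (length(unique(speeds)) < max(k_range))
    stop("k_range exceeds the number of distinct speed values")
  res <- lapply(k_range, function(kk) {
    fit <- fit_speed_states(speeds, k = kk)
    data.frame(k = kk, sse = fit$sse,
               silhouette = silhouette_1d(speeds, fit$cluster))
  })
  do.call(rbind, res)
}

#' Classify a participant's trials into navigation states
#'
#' Speeds are pooled across all of a participant's trials so the k-means
#' thresholds are individualized but stable within the participant, then each
#' trial's interior samples are labelled. Endpoint samples (whose speed is
#' undefined) inherit the state of the nearest interior sample so the state
#' durations partition the full trial.
#'
#' @param trajs list of [trajectory()] objects from one participant.
#' @param k number of states (default 3).
#' @return list with `labeling` (the pooled [fit_speed_states()] object) and
#'   `states`: a list (one per trial) of full-length state factors.
#' @export
classify_participant <- function(trajs, k = 3) {
  stopifnot(length(trajs) >= 1)
  speeds <- lapply(trajs, instantaneous_speed)
  pooled <- unlist(speeds, use.names = FALSE)
  labeling <- fit_speed_states(pooled, k = k)
  offsets <- cumsum(c(0, vapply(speeds, length, integer(1))))
  states <- lapply(seq_along(trajs), function(i) {
    idx <- (offsets[i] + 1):offsets[i + 1]
    interior <- labeling$cluster[idx]
    full <- c(interior[1], interior, interior[length(interior)])
    if (k == 3) factor(.nav_states[full], levels = .nav_states) else full
  })
  list(labeling = labeling, states = states)
}

#' Summarise one trial's navigation behaviour
#'
#' State times are sample counts times the sampling interval, so
#' wayfinding + transition + moving time equals navigation time exactly, and
#' navigation efficiency — the fraction of time spent navigating effectively —
#' is `(moving_time + transition_time) / navigation_time`.
#'
#' @param traj a [trajectory()].
#' @param states full-length state factor for the trial (from
#'   [classify_participant()]).
#' @return one-row data.frame: `participant_id`, `trial_id`,
#'   `navigation_time`, `wayfinding_time`, `transition_time`, `moving_time`,
#'   `efficiency`, `distance`.
#' @export
summarize_navigation <- function(traj, states) {
  stopifnot(inherits(traj, "nav_trajectory"),
            length(states) == nrow(traj))
  dt <- attr(traj, "dt")
  counts <- table(factor(states, levels = .nav_states))
  times <- as.numeric(counts) * dt
  # navigation time as the literal three-term sum so the state partition is
  # exact, not merely within floating-point tolerance
  nav <- times[1] + times[2] + times[3]
  data.frame(participant_id = attr(traj, "participant_id"),
             trial_id = attr(traj, "trial_id"),
             navigation_time = nav,
             wayfinding_time = times[1],
             transition_time = times[2],
             moving_time = times[3],
             efficiency = (times[2] + times[3]) / nav,
             distance = trajectory_distance(traj))
}
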