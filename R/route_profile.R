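# Route-projected efficiency profiles: every sample is mapped to its nearest
# point on the trial's shortest route, positions are expressed as normalized
# arclength along the (concatenated) route, and group differences in per-bin
# navigation efficiency are assessed with a permutation test, bin by bin.

# run expr with a temporary RNG state seeded at `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Project samples onto a route polyline
#'
#' Each sample maps to its nearest point on the polyline; the result is that
#' point's arclength divided by the total route length, in `[0, 1]`. Ties
#' between equidistant segments resolve to the earlier segment.
#'
#' @param x,y sample coordinates (vectorised).
#' @param route two-column matrix of polyline vertices with positive total
#'   length.
#' @return numeric vector of normalized arclengths.
#' @export
project_onto_route <- function(x, y, route) {
  stopifnot(is.matrix(route), ncol(route) == 2, nrow(route) >= 2)
  seg_len <- sqrt(diff(route[, 1])^2 + diff(route[, 2])^2)
  total <- sum(seg_len)
  if (total <= 0) stop("route length must be positive")
  cum0 <- c(0, cumsum(seg_len))
  best_d <- rep(Inf, length(x))
  best_s <- rep(0, length(x))
  for (k in seq_len(nrow(route) - 1)) {
    ax <- route[k, 1]; ay <- route[k, 2]
    bx <- route[k + 1, 1]; by <- route[k + 1, 2]
    dx <- bx - ax; dy <- by - ay
    l2 <- dx * dx + dy * dy
    t <- if (l2 == 0) rep(0, length(x)) else
      pmin(1, pmax(0, ((x - ax) * dx + (y - ay) * dy) / l2))
    d <- sqrt((x - (ax + t * dx))^2 + (y - (ay + t * dy))^2)
    better <- d < best_d - 1e-12
    best_s[better] <- cum0[k] + t[better] * seg_len[k]
    best_d[better] <- d[better]
  }
  best_s / total
}

# difference of group means per column, ignoring NA; z is the logical
# indicator of group 1
col_group_diff <- function(E0, obs, z) {
  n1 <- colSums(obs * z)
  n2 <- colSums(obs * (1 - z))
  s1 <- colSums(E0 * z)
  s2 <- colSums(E0 * (1 - z))
  s1 / n1 - s2 / n2
}

#' Per-bin permutation test of group differences
#'
#' For each route bin the statistic is the difference of group means of
#' per-participant efficiency; group labels are permuted jointly across all
#' bins (one relabelling per permutation, preserving within-participant
#' structure). When the total number of distinct relabellings is at most
#' `exhaustive_max`, all of them are enumerated and the two-sided p-value is
#' the exact proportion with `|T*| >= |T|`; otherwise `n_perm` random
#' relabellings are drawn and `p = (1 + #{|T*| >= |T|}) / (1 + n_perm)`.
#' Bins with fewer than 2 observed participants in either group are skipped
#' (`NA` statistic and p).
#'
#' @param eff numeric matrix, participants x bins, `NA` where a participant
#'   contributes no data to a bin.
#' @param groups factor of length `nrow(eff)` with exactly 2 levels; the
#'   statistic is mean(level 1) - mean(level 2).
#' @param n_perm number of random permutations (default 10000).
#' @param seed optional RNG seed (restores the caller's RNG state).
#' @param exhaustive_max enumerate all relabellings when their count is at
#'   most this (default 20000).
#' @return data.frame with one row per bin: `bin`, the observed `statistic`,
#'   per-group `n`, `p_perm`, and whether enumeration was `exhaustive`.
#' @export
permutation_bin_test <- function(eff, groups, n_perm = 10000, seed = NULL,
                                 exhaustive_max = 20000) {
  eff <- as.matrix(eff)
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2, length(groups) == nrow(eff))
  P <- nrow(eff); B <- ncol(eff)
  obs <- !is.na(eff)
  E0 <- eff; E0[!obs] <- 0
  obs <- obs * 1
  z_obs <- as.numeric(groups == levels(groups)[1])
  n1 <- sum(z_obs)
  n_obs1 <- colSums(obs * z_obs)
  n_obs2 <- colSums(obs * (1 - z_obs))
  usable <- n_obs1 >= 2 & n_obs2 >= 2
  T_obs <- col_group_diff(E0, obs, z_obs)
  T_obs[!usable] <- NA_real_
  n_total <- choose(P, n1)
  exhaustive <- n_total <= exhaustive_max
  exceed <- numeric(B); n_eff_perm <- 0
  accumulate <- function(z) {
    Tp <- col_group_diff(E0, obs, z)
    hit <- !is.na(Tp) & usable & abs(Tp) >= abs(T_obs) - 1e-12
    exceed[usable & hit] <<- exceed[usable & hit] + 1
    n_eff_perm <<- n_eff_perm + 1
  }
  if (exhaustive) {
    combos <- utils::combn(P, n1)
    for (cix in seq_len(ncol(combos))) {
      z <- numeric(P); z[combos[, cix]] <- 1
      accumulate(z)
    }
    p <- exceed / n_eff_perm
  } else {
    with_seed(seed, {
      for (r in seq_len(n_perm)) accumulate(sample(z_obs))
    })
    p <- (1 + exceed) / (1 + n_eff_perm)
  }
  p[!usable] <- NA_real_
  data.frame(bin = seq_len(B), statistic = T_obs,
             n1 = n_obs1, n2 = n_obs2,
             p_perm = p, exhaustive = exhaustive)
}

#' Group efficiency profile along a normalized route
#'
#' Builds the per-participant per-bin efficiency matrix by projecting every
#' sample of every trial onto its trial's shortest route, concatenating the
#' trial routes (arclength-weighted) into one normalized `[0, 1]` axis, and
#' within each bin scoring the fraction of a participant's samples that are
#' in an effective state (MOVING or TRANSITION). Per-bin time per unit
#' distance is also accumulated. Trials flagged as route errors are excluded.
#'
#' @param participants list; one entry per participant, each a list of trials,
#'   every trial a list with elements `traj` (a [trajectory()]), `states`
#'   (full-length state factor) and `route` (two-column polyline matrix).
#' @param groups factor (2 levels) of length `length(participants)`.
#' @param bin_vm bin width in vm of route arclength (default 1).
#' @param n_perm,seed passed to [permutation_bin_test()].
#' @param deviation_threshold exclude trials whose trajectory strays farther
#'   than this from the route (default `Inf`: keep all).
#' @return object of class `route_profile`: `bins` data.frame (`bin_start`,
#'   `bin_end` on the normalized axis, per-group mean efficiency and mean
#'   time per vm, `p_perm`), plus the raw `eff` matrix and `groups`.
#' @export
route_efficiency_profile <- function(participants, groups, bin_vm = 1,
                                     n_perm = 10000, seed = NULL,
                                     deviation_threshold = Inf) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2, length(groups) == length(participants))
  # common normalized axis: use the first participant's route lengths
  route_len <- function(r) sum(sqrt(diff(r[, 1])^2 + diff(r[, 2])^2))
  lens <- vapply(participants[[1]], function(tr) route_len(tr$route), numeric(1))
  total_len <- sum(lens)
  B <- max(1L, ceiling(total_len / bin_vm))
  edges <- seq(0, 1, length.out = B + 1)
  P <- length(participants)
  eff <- matrix(NA_real_, P, B)
  tpd <- matrix(NA_real_, P, B)   # time per unit distance (s/vm)
  bin_len_vm <- total_len / B
  for (p in seq_len(P)) {
    trials <- participants[[p]]
    cumlen <- c(0, cumsum(vapply(trials, function(tr) route_len(tr$route),
                                 numeric(1))))
    tl <- cumlen[length(cumlen)]
    s_all <- numeric(0); good_all <- logical(0); dt_all <- numeric(0)
    for (i in seq_along(trials)) {
      tr <- trials[[i]]
      if (flag_route_error(tr$traj, tr$route, deviation_threshold)) next
      s <- project_onto_route(tr$traj$x, tr$traj$y, tr$route)
      s_global <- (cumlen[i] + s * (cumlen[i + 1] - cumlen[i])) / tl
      s_all <- c(s_all, s_global)
      good_all <- c(good_all, tr$states %in% c("TRANSITION", "MOVING"))
      dt_all <- c(dt_all, rep(attr(tr$traj, "dt"), nrow(tr$traj)))
    }
    if (!length(s_all)) next
    bin <- pmin(B, pmax(1L, findInterval(s_all, edges, rightmost.closed = TRUE)))
    for (b in unique(bin)) {
      sel <- bin == b
      eff[p, b] <- mean(good_all[sel])
      tpd[p, b] <- sum(dt_all[sel]) / bin_len_vm
    }
  }
  perm <- permutation_bin_test(eff, groups, n_perm = n_perm, seed = seed)
  lv <- levels(groups)
  g1 <- groups == lv[1]
  bins <- data.frame(
    bin_start = edges[-(B + 1)], bin_end = edges[-1],
    mean_eff_1 = colMeans(eff[g1, , drop = FALSE], na.rm = TRUE),
    mean_eff_2 = colMeans(eff[!g1, , drop = FALSE], na.rm = TRUE),
    mean_tpd_1 = colMeans(tpd[g1, , drop = FALSE], na.rm = TRUE),
    mean_tpd_2 = colMeans(tpd[!g1, , drop = FALSE], na.rm = TRUE),
    p_perm = perm$p_perm)
  names(bins)[3:6] <- c(paste0("mean_eff_", lv), paste0("mean_tpd_", lv))
  structure(list(bins = bins, eff = eff, tpd = tpd, groups = groups,
                 bin_vm = bin_vm, total_route_length = total_len),
            class = "route_profile")
}

#' @export
print.route_profile <- function(x, ...) {
  nsig <- sum(x$bins$p_perm < 0.05, na.rm = TRUE)
  cat(sprintf("<route_profile> %d bins over %.0f vm of route; %d bin(s) with p < 0.05\n",
              nrow(x$bins), x$total_route_length, nsig))
  invisible(x)
}
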