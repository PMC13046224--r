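# Synthetic cohort generator. Emulates the structure the analysis assumes:
# a Manhattan-grid virtual city, fixed-rate trajectories that walk the street
# network through a fixed target sequence with three latent speed regimes
# (wayfinding / transition / moving), hesitation dwells at decision points
# (intersections and trial starts) with group-specific probability, and
# cognitive scores linearly coupled to true navigation efficiency. Every
# piece of latent structure is returned as ground truth.

#' Default study-condition specification for a synthetic cohort
#'
#' Group profiles are chosen to reproduce the qualitative pattern of an
#' older/younger contrast — older participants move slower when moving
#' (1.5 vs 2.0 vm/s), hesitate more often at decision points (probability
#' 0.6 vs 0.2) and dwell longer when they do — not any particular study's
#' numeric values. Cognitive couplings follow the expected sign pattern:
#' MoCA, MMSE, ROCF and MRT increase with navigation efficiency, TMTA
#' (a completion time) decreases.
#'
#' @param n_older,n_young group sizes (default 20 each).
#' @param dt sampling interval in seconds (default 0.1).
#' @param n_trials consecutive trials per participant (default 5).
#' @return a list of generator parameters (`cohort_spec`).
#' @export
cohort_spec <- function(n_older = 20, n_young = 20, dt = 0.1, n_trials = 5) {
  profile <- function(group, moving, hesitation_p, dwell_mean) {
    list(group = group,
         # VR locomotion is controller-paced, so within-regime speed
         # variability is small; regime separation is many SDs
         speed_means = c(WAYFINDING = 0.15, TRANSITION = 0.9, MOVING = moving),
         speed_sds   = c(WAYFINDING = 0.04, TRANSITION = 0.08, MOVING = 0.05),
         hesitation_p = hesitation_p,
         dwell_mean = dwell_mean,     # mean wayfinding dwell, s
         transition_dur = 3)          # slow-down phase at each turn, s
  }
  list(
    n_older = n_older, n_young = n_young, dt = dt, n_trials = n_trials,
    profiles = list(
      older = profile("older", moving = 1.5, hesitation_p = 0.6, dwell_mean = 12),
      young = profile("young", moving = 2.0, hesitation_p = 0.2, dwell_mean = 7)
    ),
    # score = intercept + slope * efficiency + Normal(0, sd), clipped to range
    coupling = list(
      moca   = list(intercept = 10, slope =  20, sd =  2.0, range = c(0, 30)),
      mmse   = list(intercept = 20, slope =  12, sd =  1.5, range = c(0, 30)),
      rocf_c = list(intercept =  5, slope =  25, sd =  3.0, range = c(0, 36)),
      rocf_d = list(intercept =  8, slope =  22, sd =  3.0, range = c(0, 36)),
      tmta   = list(intercept = 110, slope = -80, sd = 10.0, range = c(10, 300)),
      mrt    = list(intercept = 30, slope =  55, sd =  6.0, range = c(0, 100))
    )
  )
}

#' Generate a Manhattan-grid environment
#'
#' A `width` x `height` vm urban block: evenly spaced vertical and horizontal
#' streets of constant width, rectangular building blocks as obstacles, one
#' axial line per straight street, and a fixed sequence of targets placed at
#' street intersections.
#'
#' @param width,height domain extent in vm (defaults 200 x 150).
#' @param n_streets_x number of vertical streets (default 4).
#' @param n_streets_y number of horizontal streets (default 3).
#' @param street_width street width in vm (default 5); must be smaller than
#'   the street pitch.
#' @param n_targets number of targets (default 6, giving 5 consecutive
#'   trials).
#' @param grid_resolution visibility-grid resolution in vm (default 1).
#' @param seed RNG seed for target placement.
#' @return a [env_layout()] with a `streets` attribute (street centerlines
#'   and intersections) used for route construction.
#' @export
generate_environment <- function(width = 200, height = 150,
                                 n_streets_x = 4, n_streets_y = 3,
                                 street_width = 5, n_targets = 6,
                                 grid_resolution = 1, seed = 1) {
  if (n_streets_x < 2 || n_streets_y < 2)
    stop("configuration error: need at least 2 streets per axis")
  cx <- width * seq_len(n_streets_x) / (n_streets_x + 1)
  cy <- height * seq_len(n_streets_y) / (n_streets_y + 1)
  pitch <- min(diff(c(0, cx, width)), diff(c(0, cy, height)))
  if (street_width >= pitch)
    stop("configuration error: street width (", street_width,
         ") must be below the block pitch (", pitch, ")")
  w2 <- street_width / 2
  xlo <- c(0, cx + w2); xhi <- c(cx - w2, width)
  ylo <- c(0, cy + w2); yhi <- c(cy - w2, height)
  obstacles <- list()
  for (i in seq_along(xlo)) {
    for (j in seq_along(ylo)) {
      if (xhi[i] - xlo[i] <= 1e-9 || yhi[j] - ylo[j] <= 1e-9) next
      obstacles[[length(obstacles) + 1]] <-
        matrix(c(xlo[i], ylo[j], xhi[i], ylo[j],
                 xhi[i], yhi[j], xlo[i], yhi[j]),
               ncol = 2, byrow = TRUE)
    }
  }
  axial <- data.frame(
    id = seq_len(n_streets_x + n_streets_y),
    x1 = c(cx, rep(0, n_streets_y)),
    y1 = c(rep(0, n_streets_x), cy),
    x2 = c(cx, rep(width, n_streets_y)),
    y2 = c(rep(height, n_streets_x), cy))
  inter <- expand.grid(ix = seq_len(n_streets_x), iy = seq_len(n_streets_y))
  inter$x <- cx[inter$ix]; inter$y <- cy[inter$iy]
  if (n_targets > nrow(inter))
    stop("configuration error: more targets than street intersections")
  pick <- with_seed(seed, sample(nrow(inter), n_targets))
  targets <- data.frame(id = seq_len(n_targets),
                        label = sprintf("T%d", seq_len(n_targets)),
                        x = inter$x[pick], y = inter$y[pick])
  layout <- env_layout(width, height, obstacles = obstacles,
                       targets = targets, axial_lines = axial,
                       grid_resolution = grid_resolution)
  attr(layout, "streets") <- list(cx = cx, cy = cy,
                                  street_width = street_width,
                                  intersections = inter)
  layout
}

# igraph lattice over street intersections, edge weights = distance
street_graph <- function(layout) {
  st <- attr(layout, "streets")
  if (is.null(st)) stop("layout carries no street metadata")
  inter <- st$intersections
  n <- nrow(inter)
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b <= a) next
      same_v <- inter$ix[a] == inter$ix[b] &&
        abs(inter$iy[a] - inter$iy[b]) == 1
      same_h <- inter$iy[a] == inter$iy[b] &&
        abs(inter$ix[a] - inter$ix[b]) == 1
      if (same_v || same_h) {
        from <- c(from, a); to <- c(to, b)
        wt <- c(wt, sqrt((inter$x[a] - inter$x[b])^2 +
                         (inter$y[a] - inter$y[b])^2))
      }
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = wt),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  list(graph = g, inter = inter)
}

#' Shortest street-network route between two targets
#'
#' @param layout a [generate_environment()] layout.
#' @param from_target,to_target target ids.
#' @return two-column matrix of route polyline vertices.
#' @export
shortest_street_route <- function(layout, from_target, to_target) {
  sg <- street_graph(layout)
  tg <- layout$targets
  node_of <- function(tid) {
    t <- tg[tg$id == tid, ]
    which(abs(sg$inter$x - t$x) < 1e-9 & abs(sg$inter$y - t$y) < 1e-9)
  }
  a <- node_of(from_target); b <- node_of(to_target)
  if (!length(a) || !length(b))
    stop("configuration error: target not on a street intersection")
  sp <- igraph::shortest_paths(sg$graph, from = a, to = b,
                               weights = igraph::E(sg$graph)$weight)
  nodes <- as.integer(names(sp$vpath[[1]]))
  if (length(nodes) < 2)
    stop("configuration error: target unreachable along the street network")
  cbind(sg$inter$x[nodes], sg$inter$y[nodes])
}

# inverse-CDF sampling from Normal(m, s) truncated at 0
rtrunc_speed <- function(n, m, s) {
  qnorm(runif(n, pnorm(0, m, s), 1), m, s)
}

#' Simulate one trial along a route
#'
#' A semi-Markov walk along the route polyline: at the trial start and at
#' every interior route vertex (the decision points), a wayfinding dwell is
#' injected with the profile's hesitation probability (exponential duration,
#' group-specific mean); every turn is preceded by a fixed-duration
#' transition (slow-down) phase; otherwise the walker moves at the
#' moving-regime speed until the next vertex. Per-sample speed is drawn from
#' the state's Normal distribution truncated at zero and positions are
#' integrated along the polyline at fixed `dt`.
#'
#' @param profile one group profile from [cohort_spec()].
#' @param route two-column route polyline matrix.
#' @param dt sampling interval, s.
#' @param seed RNG seed (trial-level).
#' @param participant_id,trial_id identifiers carried into the trajectory.
#' @return list with `traj` (a [trajectory()]) and `truth` (full-length
#'   factor of generating states, one per sample).
#' @export
generate_trajectory <- function(profile, route, dt, seed,
                                participant_id = "P", trial_id = 1L) {
  stopifnot(is.matrix(route), nrow(route) >= 2)
  seg_len <- sqrt(diff(route[, 1])^2 + diff(route[, 2])^2)
  cum_v <- c(0, cumsum(seg_len))
  total <- cum_v[length(cum_v)]
  m <- profile$speed_means; sdv <- profile$speed_sds
  with_seed(seed, {
    speeds <- numeric(0); states <- character(0)
    add_time_seg <- function(state, dur) {
      n <- max(1L, round(dur / dt))
      speeds <<- c(speeds, rtrunc_speed(n, m[[state]], sdv[[state]]))
      states <<- c(states, rep(state, n))
    }
    covered <- function() sum(speeds) * dt
    for (v in seq_len(nrow(route) - 1)) {
      # decision point: hesitate?
      if (runif(1) < profile$hesitation_p)
        add_time_seg("WAYFINDING", 0.3 + rexp(1, 1 / profile$dwell_mean))
      add_time_seg("TRANSITION", profile$transition_dur)
      # distance-bound moving stretch to the next vertex
      target_s <- cum_v[v + 1]
      while (covered() < target_s) {
        need <- target_s - covered()
        n_guess <- max(8L, ceiling(1.3 * need / (m[["MOVING"]] * dt)))
        vmov <- rtrunc_speed(n_guess, m[["MOVING"]], sdv[["MOVING"]])
        keep <- which(covered() + cumsum(vmov) * dt >= need + covered())
        cut <- if (length(keep)) keep[1] else n_guess
        speeds <- c(speeds, vmov[seq_len(cut)])
        states <- c(states, rep("MOVING", cut))
      }
    }
    # truncate at route completion
    s <- cumsum(speeds) * dt
    done <- which(s >= total)
    n_steps <- if (length(done)) done[1] else length(s)
    n_steps <- max(n_steps, 2L)
    speeds <- speeds[seq_len(n_steps)]
    states <- states[seq_len(n_steps)]
    s <- pmin(cumsum(speeds) * dt, total)
    s_all <- c(0, s)
    # map arclength to coordinates
    seg <- pmin(length(seg_len), pmax(1L, findInterval(s_all, cum_v,
                                                       rightmost.closed = TRUE)))
    frac <- (s_all - cum_v[seg]) / pmax(seg_len[seg], 1e-12)
    xs <- route[seg, 1] + frac * (route[seg + 1, 1] - route[seg, 1])
    ys <- route[seg, 2] + frac * (route[seg + 1, 2] - route[seg, 2])
    traj <- trajectory(participant_id, trial_id,
                       t = (seq_along(s_all) - 1) * dt, x = xs, y = ys,
                       dt = dt)
    truth <- factor(c(states[1], states), levels = .nav_states)
    list(traj = traj, truth = truth)
  })
}

#' Generate cognitive-score tables coupled to efficiency
#'
#' Each instrument score is `intercept + slope * efficiency + Normal noise`,
#' clipped to the instrument range, so the sign of every score-efficiency
#' association is known by construction. Ages and education years are drawn
#' per group (all young participants have more than 12 education years, so
#' the MoCA education adjustment only ever fires in the older group in the
#' default cohort); `moca_adjusted` applies [adjust_moca()].
#'
#' @param participant_id character vector.
#' @param group factor/character, `"older"` or `"young"`.
#' @param efficiency per-participant true navigation efficiency in `[0, 1]`.
#' @param coupling coupling spec (see [cohort_spec()]`$coupling`).
#' @param seed RNG seed.
#' @return data.frame: one row per participant with demographics and scores.
#' @export
generate_cognitive_scores <- function(participant_id, group, efficiency,
                                      coupling = cohort_spec()$coupling,
                                      seed = 1) {
  n <- length(participant_id)
  stopifnot(length(group) == n, length(efficiency) == n)
  with_seed(seed, {
    older <- group == "older"
    age <- ifelse(older, sample(65:80, n, replace = TRUE),
                  sample(21:33, n, replace = TRUE))
    education_years <- ifelse(older, sample(6:18, n, replace = TRUE),
                              sample(13:20, n, replace = TRUE))
    out <- data.frame(participant_id = participant_id,
                      group = as.character(group),
                      age = age, education_years = education_years,
                      true_efficiency = efficiency)
    for (nm in names(coupling)) {
      cp <- coupling[[nm]]
      sc <- cp$intercept + cp$slope * efficiency + rnorm(n, 0, cp$sd)
      out[[nm]] <- pmin(cp$range[2], pmax(cp$range[1], sc))
    }
    names(out)[names(out) == "moca"] <- "moca_raw"
    out$moca_raw <- round(out$moca_raw)
    out$moca_adjusted <- adjust_moca(out$moca_raw, out$education_years)
    out
  })
}

#' Generate a full synthetic cohort
#'
#' Environment, per-participant multi-trial trajectories with ground-truth
#' states, per-participant true efficiency, and coupled cognitive scores.
#' Every participant's RNG stream is derived from `(seed, participant index)`
#' so regeneration with the same seed is bit-identical and independent of
#' generation order.
#'
#' @param spec a [cohort_spec()].
#' @param layout optional [generate_environment()] layout (default one is
#'   generated from `seed`).
#' @param seed master seed.
#' @return list with `layout`, `routes` (per-trial shortest-route polylines),
#'   `participants` (data.frame with `participant_id`, `group`,
#'   `true_efficiency`), `trials` (per participant: list of
#'   `list(traj, truth)`), and `cognitive` (score table).
#' @export
generate_cohort <- function(spec = cohort_spec(), layout = NULL, seed = 1) {
  if (is.null(layout))
    layout <- generate_environment(seed = seed %% 1000003 + 1)
  n_trials <- spec$n_trials
  tg_ids <- layout$targets$id
  stopifnot(length(tg_ids) >= n_trials + 1)
  routes <- lapply(seq_len(n_trials), function(i)
    shortest_street_route(layout, tg_ids[i], tg_ids[i + 1]))
  ids <- c(sprintf("O%02d", seq_len(spec$n_older)),
           sprintf("Y%02d", seq_len(spec$n_young)))
  grp <- c(rep("older", spec$n_older), rep("young", spec$n_young))
  trials <- vector("list", length(ids))
  names(trials) <- ids
  eff <- numeric(length(ids))
  for (p in seq_along(ids)) {
    prof <- spec$profiles[[grp[p]]]
    pseed <- (seed %% 1000003) * 1009 + p * 9973
    ptrials <- lapply(seq_len(n_trials), function(i) {
      generate_trajectory(prof, routes[[i]], dt = spec$dt,
                          seed = (pseed + i * 7919) %% 2147483647,
                          participant_id = ids[p], trial_id = i)
    })
    trials[[p]] <- ptrials
    truth_all <- unlist(lapply(ptrials, function(tr) as.character(tr$truth)))
    eff[p] <- mean(truth_all != "WAYFINDING")
  }
  participants <- data.frame(participant_id = ids, group = grp,
                             true_efficiency = eff)
  cognitive <- generate_cognitive_scores(
    ids, grp, eff, coupling = spec$coupling,
    seed = (seed %% 1000003) * 31 + 17)
  list(layout = layout, routes = routes, participants = participants,
       trials = trials, cognitive = cognitive)
}
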