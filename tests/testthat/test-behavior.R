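test_that("instantaneous speed averages the two adjacent interval velocities", {
  # worked example: (0,0,0), (1,3,0), (2,3,4) -> (3 + 4)/2 = 3.5 vm/s
  tr <- trajectory("p", 1, t = c(0, 1, 2), x = c(0, 3, 3), y = c(0, 0, 4))
  expect_equal(instantaneous_speed(tr), 3.5)

  # uniform motion: every interior speed equals the common speed
  tr2 <- uniform_trajectory(n = 20, v = 1.7, dt = 0.25)
  expect_equal(instantaneous_speed(tr2), rep(1.7, 18))

  # stationary participant
  tr3 <- trajectory("p", 1, t = seq(0, 0.9, 0.1), x = rep(2, 10), y = rep(3, 10))
  expect_equal(instantaneous_speed(tr3), rep(0, 8))
})

test_that("speed series length is n - 2 for arbitrary trajectories", {
  set.seed(11)
  for (n in c(3, 7, 41)) {
    tr <- random_trajectory(n, 20, 20)
    expect_length(instantaneous_speed(tr), n - 2)
    expect_true(all(instantaneous_speed(tr) >= 0))
  }
})

test_that("trajectory construction enforces the fixed-rate contract", {
  expect_error(trajectory("p", 1, t = c(0, 1), x = c(0, 1), y = c(0, 0)),
               "at least 3")
  expect_error(trajectory("p", 1, t = c(0, 1, 1), x = 0:2, y = rep(0, 3)),
               "strictly increasing")
  expect_error(trajectory("p", 1, t = c(0, 0.1, 0.5, 0.6), x = 0:3,
                          y = rep(0, 4), dt = 0.1),
               "fixed-rate")
  expect_error(trajectory("p", 1, t = c(0, 0.1, NA), x = 0:2, y = rep(0, 3)),
               "missing")
})

test_that("k-means recovers exact well-separated groups and orders states by speed", {
  speeds <- c(rep(0.1, 3), rep(1.0, 2), rep(2.0, 3))
  fit <- fit_speed_states(speeds, k = 3)
  expect_equal(fit$centroids, c(0.1, 1.0, 2.0))
  expect_equal(as.character(fit$state),
               c(rep("WAYFINDING", 3), rep("TRANSITION", 2), rep("MOVING", 3)))
  expect_equal(fit$sse, 0)

  expect_error(fit_speed_states(rep(1, 10), k = 3), "degenerate")
})

test_that("state labels are invariant to uniform speed scaling", {
  set.seed(5)
  speeds <- c(abs(rnorm(40, 0.15, 0.05)), rnorm(30, 0.9, 0.1), rnorm(80, 2, 0.1))
  base <- fit_speed_states(speeds)$state
  for (c_scale in c(0.2, 3, 17)) {
    expect_identical(fit_speed_states(speeds * c_scale)$state, base)
  }
})

test_that("cluster diagnostics: SSE non-increasing, elbow at the true k, silhouette sane", {
  set.seed(6)
  speeds <- c(rnorm(60, 0.15, 0.03), rnorm(60, 1.0, 0.03), rnorm(60, 2, 0.03))
  diag <- cluster_diagnostics(speeds, k_range = 2:6)
  expect_true(all(diff(diag$sse) <= 1e-9))
  expect_true(all(diag$silhouette >= -1 & diag$silhouette <= 1))
  # three tight well-separated groups: big SSE drop up to k = 3, flat after
  drop23 <- diag$sse[diag$k == 2] - diag$sse[diag$k == 3]
  drop34 <- diag$sse[diag$k == 3] - diag$sse[diag$k == 4]
  expect_gt(drop23, 10 * drop34)

  # k = n gives SSE 0
  xs <- c(0.1, 0.5, 1.1, 2.3, 3.1)
  expect_equal(fit_speed_states(xs, k = 5)$sse, 0)
})

test_that("1-D silhouette matches the cluster-package oracle", {
  set.seed(8)
  x <- c(rnorm(25, 0, 0.2), rnorm(20, 3, 0.3), rnorm(15, 7, 0.25))
  cl <- rep(1:3, c(25, 20, 15))
  ours <- silhouette_1d(x, cl)
  oracle <- mean(cluster::silhouette(cl, dist(x))[, "sil_width"])
  expect_equal(ours, oracle, tolerance = 1e-10)
  # two well-separated clusters: silhouette near 1
  x2 <- c(rnorm(30, 0, 0.05), rnorm(30, 10, 0.05))
  expect_gt(silhouette_1d(x2, rep(1:2, each = 30)), 0.9)
})

test_that("state recovery against generator ground truth exceeds 95%", {
  env <- generate_environment(seed = 2)
  routes <- lapply(1:5, function(i) shortest_street_route(env, i, i + 1))
  for (grp in c("older", "young")) {
    prof <- cohort_spec()$profiles[[grp]]
    trials <- lapply(seq_along(routes), function(i)
      generate_trajectory(prof, routes[[i]], dt = 0.1, seed = 900 + i))
    truth <- unlist(lapply(trials, function(tr) as.character(tr$truth)))
    # recovery is only defined when all three regimes were emitted
    expect_setequal(unique(truth), c("WAYFINDING", "TRANSITION", "MOVING"))
    cl <- classify_participant(lapply(trials, `[[`, "traj"))
    got <- unlist(lapply(cl$states, as.character))
    expect_gt(mean(truth == got), 0.95)
  }
})

test_that("navigation summary partitions time exactly and matches the efficiency formula", {
  tr <- trajectory("p", 1, t = 0:3, x = c(0, 1, 2, 3), y = rep(0, 4))
  states <- factor(c("MOVING", "MOVING", "TRANSITION", "WAYFINDING"),
                   levels = c("WAYFINDING", "TRANSITION", "MOVING"))
  s <- summarize_navigation(tr, states)
  expect_equal(s$efficiency, 0.75)
  expect_equal(s$navigation_time, 4)
  expect_equal(s$wayfinding_time + s$transition_time + s$moving_time,
               s$navigation_time)
  expect_equal(s$distance, 3)

  all_mov <- factor(rep("MOVING", 4), levels = levels(states))
  expect_equal(summarize_navigation(tr, all_mov)$efficiency, 1)
  all_way <- factor(rep("WAYFINDING", 4), levels = levels(states))
  expect_equal(summarize_navigation(tr, all_way)$efficiency, 0)
})

test_that("route error flag triggers on perpendicular deviation only", {
  route <- cbind(c(0, 10), c(0, 0))
  on_route <- trajectory("p", 1, t = 0:5, x = 0:5, y = rep(0, 6))
  expect_false(flag_route_error(on_route, route, 5))
  off <- trajectory("p", 1, t = 0:5, x = 0:5, y = c(0, 0, 10, 0, 0, 0))
  expect_true(flag_route_error(off, route, 5))
  expect_false(flag_route_error(off, route, Inf))
})
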