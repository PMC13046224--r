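test_that("route projection maps start, end and midpoint correctly", {
  route <- cbind(c(0, 10), c(0, 0))
  expect_equal(project_onto_route(0, 0, route), 0)
  expect_equal(project_onto_route(10, 0, route), 1)
  expect_equal(project_onto_route(5, 2, route), 0.5)
  # beyond the ends clamps to 0/1
  expect_equal(project_onto_route(c(-3, 14), c(0, 0), route), c(0, 1))
  # bent route: arclength accumulates over segments
  bent <- cbind(c(0, 10, 10), c(0, 0, 10))
  expect_equal(project_onto_route(10, 5, bent), 0.75)
})

test_that("exhaustive permutation p-value matches hand enumeration", {
  eff <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1)
  groups <- factor(rep(c("a", "b"), each = 3))
  res <- permutation_bin_test(eff, groups)
  expect_true(res$exhaustive)
  # C(6,3) = 20 assignments; only the observed and its mirror reach |T| = 9
  expect_equal(res$p_perm, 2 / 20)
  expect_equal(res$statistic, -9)

  # identical groups: every relabelling ties or exceeds, p = 1
  eff2 <- matrix(rep(c(1, 2, 3), 2), ncol = 1)
  expect_equal(permutation_bin_test(eff2, groups)$p_perm, 1)
})

test_that("permutation p-values are invariant to shifts and label swaps negate the statistic", {
  set.seed(41)
  eff <- matrix(rnorm(10 * 3), 10, 3)
  groups <- factor(rep(c("a", "b"), each = 5))
  base <- permutation_bin_test(eff, groups)
  shifted <- permutation_bin_test(eff + 100, groups)
  expect_equal(base$p_perm, shifted$p_perm, tolerance = 1e-12)
  expect_equal(base$statistic, shifted$statistic, tolerance = 1e-10)

  swapped <- permutation_bin_test(eff, factor(groups, levels = c("b", "a")))
  expect_equal(swapped$statistic, -base$statistic, tolerance = 1e-12)
  expect_equal(swapped$p_perm, base$p_perm, tolerance = 1e-12)
})

test_that("bins without two participants per group are skipped", {
  eff <- matrix(rnorm(8), 4, 2)
  eff[1:3, 2] <- NA  # second bin: group a has 1 observation only
  groups <- factor(rep(c("a", "b"), each = 2))
  res <- permutation_bin_test(eff, groups)
  expect_false(is.na(res$p_perm[1]))
  expect_true(is.na(res$p_perm[2]))
})

test_that("random-permutation p-values use the add-one estimator and a seed", {
  set.seed(55)
  eff <- matrix(rnorm(40), 20, 2)   # C(20,10) >> exhaustive_max
  groups <- factor(rep(c("a", "b"), each = 10))
  r1 <- permutation_bin_test(eff, groups, n_perm = 200, seed = 9)
  r2 <- permutation_bin_test(eff, groups, n_perm = 200, seed = 9)
  expect_false(r1$exhaustive[1])
  expect_identical(r1$p_perm, r2$p_perm)
  expect_true(all(r1$p_perm >= 1 / 201))
})

test_that("route efficiency profile separates groups where they differ", {
  # synthetic two-group cohort on a short straight route; the 'slow' group
  # wayfinds in the first half of the route only
  route <- cbind(c(0, 20), c(0, 0))
  mk_participant <- function(slow, seed) {
    set.seed(seed)
    n <- 200
    x <- seq(0, 20, length.out = n)
    tr <- trajectory(paste0("p", seed), 1, t = (0:(n - 1)) * 0.1, x = x,
                     y = rep(0, n))
    states <- rep("MOVING", n)
    if (slow) states[x < 10] <- "WAYFINDING"
    list(list(traj = tr,
              states = factor(states, levels = c("WAYFINDING", "TRANSITION",
                                                 "MOVING")),
              route = route))
  }
  participants <- c(lapply(1:5, function(s) mk_participant(TRUE, s)),
                    lapply(6:10, function(s) mk_participant(FALSE, s)))
  groups <- factor(rep(c("older", "young"), each = 5))
  prof <- route_efficiency_profile(participants, groups, bin_vm = 2,
                                   n_perm = 500, seed = 3)
  bins <- prof$bins
  first_half <- bins$bin_start < 0.5
  expect_true(all(bins$mean_eff_older[first_half] <
                  bins$mean_eff_young[first_half]))
  expect_true(all(bins$p_perm[first_half] < 0.05, na.rm = TRUE))
  expect_true(all(bins$p_perm[!first_half] > 0.5, na.rm = TRUE))
})
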