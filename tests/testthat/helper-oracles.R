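# Independent oracles and in-code fixtures for the test suite.

# Hand-rolled BFS depths, independent of the package's igraph-backed path.
bfs_depths_oracle <- function(adj, origin) {
  n <- nrow(adj)
  depth <- rep(NA_integer_, n)
  depth[origin] <- 0L
  frontier <- origin
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(adj[v, ] & is.na(depth))
      depth[nb] <- d
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  depth
}

# Closed-form integration evaluated from scratch (duplicates the published
# RA/RRA arithmetic rather than calling the package).
integration_oracle <- function(depths, n) {
  md <- sum(depths) / (n - 1)
  ra <- 2 * (md - 1) / (n - 2)
  dn <- 2 * (n * (log2((n + 2) / 3) - 1) + 1) / ((n - 1) * (n - 2))
  if (ra <= 0) return(NA_real_)
  dn / ra
}

# random connected undirected graph on n nodes: random spanning tree + extras
random_connected_adj <- function(n, extra = n) {
  adj <- matrix(FALSE, n, n)
  perm <- sample(n)
  for (i in 2:n) {
    j <- perm[sample(i - 1, 1)]
    adj[perm[i], j] <- adj[j, perm[i]] <- TRUE
  }
  for (e in seq_len(extra)) {
    ij <- sample(n, 2)
    adj[ij[1], ij[2]] <- adj[ij[2], ij[1]] <- TRUE
  }
  diag(adj) <- FALSE
  adj
}

# adjacency matrix -> axial_graph object (for feeding hand-built graphs in)
adj_as_axial <- function(adj) {
  structure(list(n_lines = nrow(adj), ids = seq_len(nrow(adj)),
                 adjacency = adj),
            class = "axial_graph")
}

# obstacle-free rectangular room
room_layout <- function(width = 5, height = 5, res = 1) {
  env_layout(width, height, grid_resolution = res)
}

# two rooms separated by a full-height door-less wall
two_rooms_layout <- function() {
  wall <- matrix(c(4.4, 0, 5.6, 0, 5.6, 5, 4.4, 5), ncol = 2, byrow = TRUE)
  env_layout(10, 5, obstacles = list(wall), grid_resolution = 1)
}

# L-shaped corridor: a block fills the upper-right region of a 10x10 domain,
# leaving an L of open space whose two arms cannot see around the corner
l_corridor_layout <- function() {
  block <- matrix(c(3, 3, 9.9, 3, 9.9, 9.9, 3, 9.9), ncol = 2, byrow = TRUE)
  env_layout(10, 10, obstacles = list(block), grid_resolution = 1)
}

# straight-line constant-dt trajectory at speed v along +x
uniform_trajectory <- function(n = 10, v = 2, dt = 0.5, pid = "p", trial = 1) {
  t <- (seq_len(n) - 1) * dt
  trajectory(pid, trial, t = t, x = v * t, y = rep(0, n))
}

# small random-walk trajectory inside a box (for property tests)
random_trajectory <- function(n, width, height, dt = 0.1, margin = 0.2) {
  x <- runif(1, margin, width - margin)
  y <- runif(1, margin, height - margin)
  xs <- numeric(n); ys <- numeric(n)
  for (i in seq_len(n)) {
    x <- min(width - margin, max(margin, x + rnorm(1, 0, 0.5)))
    y <- min(height - margin, max(margin, y + rnorm(1, 0, 0.5)))
    xs[i] <- x; ys[i] <- y
  }
  trajectory("rw", 1, t = (seq_len(n) - 1) * dt, x = xs, y = ys)
}

# a layout with a handful of random rectangular obstacles clear of the border
random_blocky_layout <- function(width = 12, height = 10, n_blocks = 3,
                                 res = 1) {
  obs <- list()
  for (b in seq_len(n_blocks)) {
    w <- runif(1, 1, 3); h <- runif(1, 1, 3)
    x0 <- runif(1, 1, width - w - 1); y0 <- runif(1, 1, height - h - 1)
    obs[[b]] <- matrix(c(x0, y0, x0 + w, y0, x0 + w, y0 + h, x0, y0 + h),
                       ncol = 2, byrow = TRUE)
  }
  env_layout(width, height, obstacles = obs, grid_resolution = res)
}

# compact synthetic test environment (fast VGA) with 4 targets / 3 trials;
# 3x2 streets so the axial lines are not all equivalent by symmetry
small_test_setup <- function(seed = 1) {
  layout <- generate_environment(width = 60, height = 45,
                                 n_streets_x = 3, n_streets_y = 2,
                                 street_width = 4, n_targets = 4,
                                 grid_resolution = 1.5, seed = seed)
  spec <- cohort_spec(n_older = 4, n_young = 4, n_trials = 3)
  list(layout = layout, spec = spec)
}
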