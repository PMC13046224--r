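make_cross_layout <- function() {
  # two perpendicular streets crossing at (5, 5) in a 10x10 domain
  env_layout(10, 10, axial_lines = data.frame(
    id = 1:2, x1 = c(5, 0), y1 = c(0, 5), x2 = c(5, 10), y2 = c(10, 5)))
}

# 40x10 hall with a chain of 4 axial lines along y = 5; the off-center block
# breaks convexity so every cell's visual mean depth exceeds 1 and visual
# integration is defined
chain_layout <- function() {
  env_layout(40, 10, obstacles = list(
    matrix(c(18, 0, 22, 0, 22, 6, 18, 6), ncol = 2, byrow = TRUE)),
    axial_lines = data.frame(id = 1:4, x1 = c(0, 10, 20, 30), y1 = 5,
                             x2 = c(10, 20, 30, 40), y2 = 5),
    grid_resolution = 2)
}

test_that("points map to the nearest axial line with low-id tie-breaking", {
  lay <- make_cross_layout()
  expect_equal(assign_axial_line(5, 2, lay), 1L)   # on line 1
  expect_equal(assign_axial_line(2, 5, lay), 2L)   # on line 2
  # equidistant from both lines: tie goes to the lower id
  expect_equal(assign_axial_line(3, 3, lay), 1L)
  # far corner point still assigned (rule is total)
  expect_equal(assign_axial_line(9.5, 0.5, lay), 1L)
})

test_that("cell assignment uses the floor convention and open-cell fallback", {
  vg <- build_visibility_graph(room_layout(5, 5))
  idx <- assign_cell(0.4, 0.4, vg)
  expect_equal(unlist(vg$cells[idx, c("row", "col")], use.names = FALSE),
               c(0L, 0L))
  # a point exactly on a cell edge belongs to the lower-index cell
  idx2 <- assign_cell(1.0, 1.0, vg)
  expect_equal(unlist(vg$cells[idx2, c("row", "col")], use.names = FALSE),
               c(0L, 0L))
  expect_error(assign_cell(7, 1, vg), "outside")

  # point inside an obstacle falls back to the nearest open cell
  lay <- env_layout(6, 3, obstacles = list(
    matrix(c(2, 0, 4, 0, 4, 3, 2, 3), ncol = 2, byrow = TRUE)))
  vg2 <- build_visibility_graph(lay, metrics = "component")
  idx3 <- assign_cell(2.6, 1.5, vg2)
  expect_equal(unlist(vg2$cells[idx3, c("row", "col")], use.names = FALSE),
               c(1L, 1L))
})

test_that("experienced metrics reproduce identity and mean cases exactly", {
  # chain of 4 collinear axial lines: P4 integration 1/3, 1, 1, 1/3
  lay <- chain_layout()
  ax <- axial_metrics(build_axial_graph(lay))
  vg <- build_visibility_graph(lay)

  # stationary trajectory on line 1 (x in [0,10]): EAI = I_A(line 1) = 1/3
  still <- data.frame(x = rep(4, 5), y = rep(5, 5))
  em <- experienced_metrics(still, lay, ax, vg)
  expect_equal(em$EAI, 1 / 3, tolerance = 1e-12)
  expect_equal(em$EAC, 1)
  expect_equal(em$EMAD, 2)
  cell <- assign_cell(4, 5, vg)
  expect_equal(em$EVC, vg$metrics$connectivity[cell])
  expect_equal(em$EVMD, vg$metrics$mean_depth[cell])

  # half the samples on line 1 (I = 1/3), half on line 2 (I = 1): mean 2/3
  half <- data.frame(x = c(4, 4, 16, 16), y = rep(5, 4))
  expect_equal(experienced_metrics(half, lay, ax, vg)$EAI, 2 / 3,
               tolerance = 1e-12)
})

test_that("experienced metrics are bounded by environment min/max and ignore time indexing", {
  lay <- generate_environment(width = 60, height = 45, n_streets_x = 2,
                              n_streets_y = 2, street_width = 4,
                              n_targets = 4, grid_resolution = 1.5, seed = 3)
  ax <- axial_metrics(build_axial_graph(lay))
  vg <- build_visibility_graph(lay)
  set.seed(99)
  for (rep in 1:25) {
    tr <- random_trajectory(sample(10:60, 1), 60, 45)
    em <- experienced_metrics(tr, lay, ax, vg)
    expect_gte(em$EAI, min(ax$integration)); expect_lte(em$EAI, max(ax$integration))
    expect_gte(em$EAC, min(ax$connectivity)); expect_lte(em$EAC, max(ax$connectivity))
    expect_gte(em$EMAD, min(ax$mean_depth)); expect_lte(em$EMAD, max(ax$mean_depth))
    expect_gte(em$EVI, min(vg$metrics$integration)); expect_lte(em$EVI, max(vg$metrics$integration))
    expect_gte(em$EVC, min(vg$metrics$connectivity)); expect_lte(em$EVC, max(vg$metrics$connectivity))
    expect_gte(em$EVMD, min(vg$metrics$mean_depth)); expect_lte(em$EVMD, max(vg$metrics$mean_depth))
    # re-indexing time leaves the sample-average untouched
    tr2 <- tr; tr2$t <- tr2$t * 4 + 100
    expect_equal(experienced_metrics(tr2, lay, ax, vg), em)
  }
})

test_that("a trajectory visiting all lines equally recovers the unweighted mean integration", {
  lay <- chain_layout()
  ax <- axial_metrics(build_axial_graph(lay))
  vg <- build_visibility_graph(lay)
  pts <- data.frame(x = c(5, 15, 25, 35), y = rep(5, 4))
  expect_equal(experienced_metrics(pts, lay, ax, vg)$EAI,
               mean(ax$integration), tolerance = 1e-12)
})

test_that("visiting an element with undefined integration raises an error", {
  vg <- build_visibility_graph(room_layout(5, 5))  # md = 1, integration NA
  lay <- room_layout(5, 5)
  lay$axial_lines <- data.frame(id = 1, x1 = 0, y1 = 2.5, x2 = 5, y2 = 2.5)
  ax <- data.frame(id = 1, connectivity = 0L, mean_depth = NA_real_,
                   integration = NA_real_, integration_defined = FALSE,
                   component = 1L)
  pts <- data.frame(x = 2, y = 2)
  expect_error(experienced_metrics(pts, lay, ax, vg), "undefined")
})
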