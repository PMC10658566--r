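test_that("element classification partitions the mesh by neighbour count", {
  cls <- classify_elements(3, 3)
  expect_equal(sum(cls == "corner"), 2)
  expect_equal(sum(cls == "bottom_corner"), 2)
  expect_equal(sum(cls == "edge"), 3)
  expect_equal(sum(cls == "bottom_edge"), 1)
  expect_equal(sum(cls == "internal"), 1)

  cls2 <- classify_elements(2, 2)
  expect_equal(sort(as.vector(cls2)),
               c("bottom_corner", "bottom_corner", "corner", "corner"))

  # partition is exhaustive for an arbitrary size
  cls3 <- classify_elements(7, 5)
  expect_equal(length(cls3), 35)
  expect_true(all(cls3 %in% c("corner", "bottom_corner", "edge",
                              "bottom_edge", "internal")))
  # interior count
  expect_equal(sum(cls3 == "internal"), 5 * 3)

  expect_error(classify_elements(1, 5), "2 x 2")
})

test_that("stability limit follows the explicit-scheme bound", {
  expect_equal(stability_limit(1000, 2, 2), 0.001)
  expect_equal(stability_limit(0, 2, 2), Inf)
  # halving dx quarters the bound (square grid)
  expect_equal(stability_limit(200, 1, 1), stability_limit(200, 2, 2) / 4)
  # anisotropic grid: dx^2 dy^2 / (2 D (dx^2+dy^2))
  expect_equal(stability_limit(100, 2, 4), 4 * 16 / (2 * 100 * 20))
  # config dispatch
  cfg <- quick_config(D = 1000, dx = 2)
  expect_equal(stability_limit(cfg), 0.001)
})

test_that("a single FTCS step moves mass as the hand-computed update", {
  # 1D row (1,0,0), alpha = D dt/dx^2 = 0.1 -> (0.9, 0.1, 0)
  s <- diffusion_step(matrix(c(1, 0, 0), 1, 3), D = 0.1, dx = 1, dy = 1,
                      dt = 1)
  expect_equal(as.vector(s$conc), c(0.9, 0.1, 0))

  # two adjacent cells conserve their total
  s2 <- diffusion_step(matrix(c(0.7, 0), 1, 2), D = 0.2, dx = 1, dy = 1,
                       dt = 1)
  expect_equal(sum(s2$conc), 0.7)

  # uniform field with a closed bottom is a fixed point
  u <- matrix(0.25, 4, 4)
  s3 <- diffusion_step(u, D = 500, dx = 2, dy = 2, dt = 0.0005)
  expect_equal(s3$conc, u)
})

test_that("mass is conserved over many steps and instability is caught", {
  set.seed(7)
  u <- matrix(runif(20 * 8), 20, 8)
  tot <- sum(u)
  st <- list(conc = u, receptor_mass = 0)
  for (i in 1:200) {
    st <- diffusion_step(st$conc, D = 400, dx = 2, dy = 2, dt = 0.002,
                         bottom = "finite", receptor_mass = st$receptor_mass,
                         receptor_area = 1000)
  }
  expect_equal(sum(st$conc) + st$receptor_mass, tot, tolerance = 1e-12)
  expect_true(all(st$conc >= 0))

  # dt far above the stability bound blows up into negative concentrations
  bad <- matrix(c(1, rep(0, 63)), 8, 8)
  expect_error({
    st <- bad
    for (i in 1:200) {
      st <- diffusion_step(st, D = 400, dx = 2, dy = 2, dt = 0.02)$conc
    }
  }, "unstable")
})

test_that("run_simulation conserves mass and yields monotone curves", {
  curve <- run_simulation(quick_config())
  expect_lt(attr(curve, "mass_balance_error"), 1e-9)
  expect_true(all(diff(curve$amount_ug_per_cm2) >= 0))
  expect_true(all(diff(curve$percentage) >= 0))
  expect_true(all(curve$percentage >= 0 & curve$percentage <= 100))
})

test_that("no diffusion means no permeation; a sink eventually drains all", {
  c0 <- run_simulation(quick_config(D = 0))
  expect_equal(c0$percentage, rep(0, nrow(c0)))

  # small fast system in sink mode approaches 100%
  cfg <- quick_config(D = 1000, len = 150,
                      needle = frustum_needle(60, 100, length = 150),
                      mode = "sink", dx = 10, t_end = 4000,
                      output_times = c(0, 4000),
                      skin_thickness = 200)
  cs <- run_simulation(cfg)
  expect_gt(max(cs$percentage), 99)
})

test_that("cumulative percentage implements m_t over m_total", {
  expect_equal(cumulative_percentage(250, 1000), 25)
  expect_equal(cumulative_percentage(0, 500), 0)
  expect_equal(cumulative_percentage(500, 500), 100)
  expect_equal(cumulative_percentage(c(1, 2), 4), c(25, 50))
  expect_error(cumulative_percentage(1, 0), "positive")
  expect_error(cumulative_percentage(-1, 10), "non-negative")
})

test_that("slab release oracle has the right limits and series value", {
  expect_equal(slab_release_oracle(500, 200, 0), 0)
  expect_gt(slab_release_oracle(500, 200, 1e7), 0.999999)
  # monotone in time
  f <- slab_release_oracle(300, 150, c(1, 10, 50, 200, 1000))
  expect_true(all(diff(f) > 0))
  # brute-force series sum at Dt/L^2 = 0.5, computed term by term
  tau <- 0.5 * pi^2 / 4
  ns <- 0:2000
  ref <- 1 - sum(8 / ((2 * ns + 1)^2 * pi^2) * exp(-(2 * ns + 1)^2 * tau))
  expect_equal(slab_release_oracle(0.5, 1, 1), ref, tolerance = 1e-10)
})

test_that("the solver matches the analytic slab solution in the slab limit", {
  # needle spanning the full cell width and depth = uniformly loaded slab
  L <- 300
  cfg <- suppressWarnings(simulation_config(
    needle = frustum_needle(4, 4, length = L), D = 500, t_end = 500,
    load_per_needle = 1, n_needles = 1, dx = 2, dy = 2,
    skin_thickness = L, unit_cell_width = 4, receptor_mode = "sink",
    output_times = c(5, 20, 60, 120, 250, 500)))
  curve <- run_simulation(cfg)
  exact <- slab_release_oracle(500, L, curve$time_min)
  expect_lt(max(abs(curve$percentage / 100 - exact)), 0.01)
})

test_that("needle count does not matter at fixed total load", {
  c1 <- run_simulation(quick_config(n = 64, load = 1000))
  c2 <- run_simulation(quick_config(n = 128, load = 1000))
  expect_identical(c1$percentage, c2$percentage)
  expect_identical(c1$amount_ug_per_cm2, c2$amount_ug_per_cm2)
})

test_that("permeation responds monotonically to D, length and loading", {
  at24 <- function(cv) cv$amount_ug_per_cm2[cv$time_min == 24 * 60]
  base <- run_simulation(quick_config(D = 250))
  fastD <- run_simulation(quick_config(D = 1000))
  expect_gt(at24(fastD), at24(base))

  short <- run_simulation(quick_config(len = 700))
  long <- run_simulation(quick_config(len = 999))
  expect_gt(at24(long), at24(short))

  lo <- run_simulation(quick_config(load = 1000))
  hi <- run_simulation(quick_config(load = 10000))
  expect_gt(at24(hi), at24(lo))

  # loading sweep changes the amount proportionally more than the length
  # sweep does over the study ranges
  ratio_load <- at24(hi) / at24(lo)
  ratio_len <- at24(long) / at24(short)
  expect_gt(ratio_load, ratio_len)
})

test_that("grid refinement converges (halving dx shrinks the change)", {
  p24 <- function(dx) {
    cv <- run_simulation(quick_config(D = 500, dx = dx, t_end = 24 * 60,
                                      output_times = c(0, 24 * 60)))
    cv$percentage[2]
  }
  p20 <- p24(20); p10 <- p24(10); p5 <- p24(5)
  expect_lt(abs(p5 - p10), abs(p10 - p20))
})

test_that("plastic mode distributes the load over donor layer and cavity", {
  cfg <- quick_config(mn_type = "plastic", donor_layer_height = 500,
                      needle = pyramid_needle(75, 700))
  curve <- run_simulation(cfg)
  expect_lt(attr(curve, "mass_balance_error"), 1e-9)
  expect_true(all(diff(curve$percentage) >= 0))
  expect_gt(max(curve$percentage), 0)
})

test_that("snapshots return the concentration field at requested times", {
  cfg <- quick_config(t_end = 600, output_times = c(0, 600))
  cv <- run_simulation(cfg, snapshot_times = c(60, 600))
  sn <- attr(cv, "snapshots")
  expect_length(sn, 2)
  expect_true(all(sn[[1]] >= 0))
  # total grid mass decreases as drug moves to the receptor
  expect_gt(sum(sn[[1]]), sum(sn[[2]]))
})
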