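test_that("a stay-in-place kernel never leaves its cell", {
  area <- study_area(3, 3)
  spec <- kernel_spec(selection_free_kernel("delta"), study_area = area)
  set.seed(1)
  for (k in 1:10) {
    x <- runif(2, 0, 3)
    z <- sample_step(spec, x)
    expect_equal(floor(z), floor(x))  # same unit cell
  }
})

test_that("uniform-kernel draws have uniform cell frequencies", {
  area <- study_area(2, 2)
  spec <- kernel_spec(selection_free_kernel("uniform"), study_area = area)
  set.seed(2)
  n <- 4000
  cells <- replicate(n, {
    z <- sample_step(spec, c(1, 1))
    floor(z[1]) * 2 + floor(z[2]) + 1
  })
  counts <- tabulate(cells, 4)
  # 3-sigma binomial bounds around n/4
  bound <- 3 * sqrt(n * 0.25 * 0.75)
  expect_true(all(abs(counts - n / 4) <= bound))
})

test_that("empirical step distribution matches the exact kernel", {
  r <- small_resource(5, seed = 61)
  spec <- resource_central_place_kernel(r, c(2.5, 2.5), 0.5, 1.5, 0.3)
  ep <- replicate_endpoints(spec, c(2.5, 2.5), n_steps = 1, n_reps = 2e4,
                            seed = 3)
  counts <- tabulate(apply(ep, 1, function(p) cell_index_of(r, p)), 25)
  exact <- evaluate_kernel(spec, c(2.5, 2.5))$p
  tv <- 0.5 * sum(abs(counts / sum(counts) - exact))
  expect_lt(tv, 0.02)
})

test_that("simulations are bit-reproducible under a fixed seed", {
  r <- small_resource(6, seed = 67)
  spec <- resource_central_place_kernel(r, c(3, 3), 0.5, 1, 0.5)
  cfg <- simulation_config(spec, c(3, 3), n_steps = 50, seed = 7)
  s1 <- simulate_movement(cfg)
  s2 <- simulate_movement(cfg)
  expect_identical(s1$trajectories, s2$trajectories)
  cfg2 <- simulation_config(spec, c(3, 3), n_steps = 50, seed = 8)
  s3 <- simulate_movement(cfg2)
  expect_false(identical(s1$trajectories, s3$trajectories))
  # the caller's RNG stream is not consumed
  set.seed(123); a <- runif(1)
  set.seed(123); simulate_movement(cfg); b <- runif(1)
  expect_identical(a, b)
})

test_that("a minimal one-step run yields two fixes and a usable OD", {
  r <- small_resource(5, seed = 71)
  spec <- resource_central_place_kernel(r, c(2.5, 2.5), 0.5, 1, 0.5)
  sim <- simulate_movement(simulation_config(spec, c(2.5, 2.5), n_steps = 1,
                                             seed = 1))
  tr <- sim$trajectories[[1]]
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$t, c(0, 1))
  od <- occurrence_distribution(tr, area = spec$study_area)
  expect_equal(sum(od$values), 1, tolerance = 1e-12)
})

test_that("initial locations outside the study area are rejected", {
  r <- small_resource(5)
  spec <- resource_central_place_kernel(r, c(2.5, 2.5), 0.5, 1, 0.5)
  expect_error(simulation_config(spec, c(50, 50), n_steps = 10),
               "outside the study area")
})

test_that("the OD of a stationary animal peaks at its location", {
  area <- study_area(9, 9)
  tr <- trajectory("a", t = 0:5, x = rep(4.5, 6), y = rep(6.5, 6))
  od <- occurrence_distribution(tr, bandwidth = 1, area = area)
  expect_equal(which.max(as.vector(od$values)),
               cell_index_of(raster_layer(matrix(0, 9, 9)), c(4.5, 6.5)))
  expect_equal(sum(od$values), 1, tolerance = 1e-12)
})

test_that("the OD of a straight path concentrates along the path", {
  area <- study_area(20, 20)
  tr <- trajectory("a", t = 0:4, x = seq(2, 18, length.out = 5),
                   y = rep(10.5, 5))
  od <- occurrence_distribution(tr, stepping_stones_per_step = 10,
                                bandwidth = 0.8, area = area)
  centres <- expand.grid(y = (1:20) - 0.5, x = (1:20) - 0.5)  # column-major
  near <- abs(centres$y - 10.5) <= 2 * 0.8 &
          centres$x >= 2 - 2 * 0.8 & centres$x <= 18 + 2 * 0.8
  expect_gt(sum(od$values[matrix(near, 20, 20)]), 0.95)
})

test_that("over-smoothing flattens the OD towards uniform", {
  area <- study_area(8, 8)
  tr <- trajectory("a", t = 0:3, x = c(2, 3, 2, 3), y = c(2, 2, 3, 3))
  od <- occurrence_distribution(tr, bandwidth = 500, area = area)
  expect_lt(max(od$values) / min(od$values), 1.001)
})

test_that("replicate endpoints recover a known stationary law", {
  # flat step-length kernel with a two-cell selection layer: each step
  # samples the RSF (0.25, 0.75) afresh, so endpoints at any t follow it
  area <- study_area(1, 2)
  lay <- raster_layer(matrix(c(0, log(3)), 1, 2))
  spec <- kernel_spec(selection_free_kernel("uniform"),
                      covariates = list(covariate("z", "end", layer = lay)),
                      beta = 1, study_area = area)
  ep <- replicate_endpoints(spec, c(0.5, 0.5), n_steps = 3, n_reps = 500,
                            seed = 5)
  n_right <- sum(ep[, 1] > 1)
  expect_lt(abs(n_right - 500 * 0.75), 3 * sqrt(500 * 0.75 * 0.25))
})

test_that("endpoint KDE input contracts hold", {
  area <- study_area(5, 5)
  expect_error(endpoint_ud(matrix(c(1, 1), 1, 2), area = area),
               "at least 2")
  bump <- endpoint_ud(rbind(c(2.5, 2.5), c(2.5, 2.5)), bandwidth = 0.7,
                      area = area)
  expect_equal(which.max(as.vector(bump$values)), 13L)  # centre cell
})

test_that("a localising kernel keeps late fixes in the good-habitat core", {
  # single animal, resource + central-place attraction, long run: at least
  # half of the final-quarter fixes should lie in the top-decile region of
  # the combined habitat score exp(beta_R R - beta_C |x - x_C|)
  r <- generate_resource_layer(30, 30, smoothness = 6, seed = 73)
  x_C <- c(15, 15)
  spec <- resource_central_place_kernel(r, x_C, lambda = 0.5, beta_R = 1.5,
                                        beta_C = 0.5)
  sim <- simulate_movement(simulation_config(spec, x_C, n_steps = 2000,
                                             seed = 11))
  tr <- sim$trajectories[[1]]
  score <- function(x, y) {
    cellv <- r$values[cbind(pmin(floor(y) + 1, 30), pmin(floor(x) + 1, 30))]
    1.5 * cellv - 0.5 * sqrt((x - 15)^2 + (y - 15)^2)
  }
  grid <- expand.grid(x = (1:30) - 0.5, y = (1:30) - 0.5)
  cutoff <- quantile(score(grid$x, grid$y), 0.9)
  late <- tr[tr$t > 1500, ]
  expect_gt(mean(score(late$x, late$y) >= cutoff), 0.5)
})

test_that("mutual avoidance separates the two animals' space use", {
  flat <- raster_layer(matrix(0.5, 20, 20))
  centres <- rbind(c(6, 10), c(14, 10))
  avoid <- coupled_kernels(flat, centres, lambda = 0.5, beta_R = 0,
                           beta_C = 0.3,
                           interaction = matrix(c(0, 40, 40, 0), 2, 2))
  free <- coupled_kernels(flat, centres, lambda = 0.5, beta_R = 0,
                          beta_C = 0.3, interaction = matrix(0, 2, 2))
  ba_for <- function(specs, seed) {
    cfg <- simulation_config(specs, centres, n_steps = 150, seed = seed,
                             od_update_interval = 5, od_bandwidth = 2)
    sim <- simulate_movement(cfg)
    area <- specs[[1]]$study_area
    od1 <- occurrence_distribution(sim$trajectories[[1]], area = area)
    od2 <- occurrence_distribution(sim$trajectories[[2]], area = area)
    bhattacharyya_affinity(od1, od2)
  }
  expect_lt(ba_for(avoid, 21), ba_for(free, 21))
})
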