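test_that("uniform kernel with no selection is uniform over admissible cells", {
  area <- study_area(4, 4)
  spec <- kernel_spec(selection_free_kernel("uniform"), study_area = area)
  u <- evaluate_kernel(spec, c(2, 2))
  expect_equal(u$p, rep(1 / 16, 16))

  adm <- rep(TRUE, 16); adm[c(1, 6, 11)] <- FALSE
  area2 <- study_area(4, 4, admissible = adm)
  spec2 <- kernel_spec(selection_free_kernel("uniform"), study_area = area2)
  u2 <- evaluate_kernel(spec2, c(2, 2))
  expect_equal(sum(u2$p[!adm]), 0)  # "no go": zero mass outside
  expect_equal(u2$p[adm], rep(1 / 13, 13))
})

test_that("a single admissible cell receives all the mass", {
  area <- study_area(2, 2, admissible = c(TRUE, FALSE, FALSE, FALSE))
  spec <- kernel_spec(selection_free_kernel("exponential", rate = 1),
                      study_area = area)
  u <- evaluate_kernel(spec, c(0.5, 0.5))
  expect_equal(u$p, c(1, 0, 0, 0))
})

test_that("kernel matches the brute-force enumeration oracle on a 3x3 grid", {
  lay <- matrix(c(0.2, 0.8, 0.1, 0.5, 0.9, 0.3, 0.4, 0.6, 0.7), 3, 3)
  r <- raster_layer(lay)
  spec <- kernel_spec(
    selection_free_kernel("exponential", rate = 0.2),
    covariates = list(covariate("res", "end", layer = r)),
    beta = 1.5, study_area = as_study_area(r))
  for (x in list(c(1.5, 1.5), c(0.5, 2.5), c(2.2, 0.7))) {
    oracle <- brute_force_kernel(x, lambda = 0.2, beta = 1.5, lay)
    expect_lt(max(abs(evaluate_kernel(spec, x)$p - oracle$p)), 1e-12)
    expect_equal(normalising_constant(spec, x), oracle$K, tolerance = 1e-12)
  }
})

test_that("normalising constant counts admissible cells for a flat kernel", {
  area <- study_area(3, 5)
  spec <- kernel_spec(selection_free_kernel("uniform"), study_area = area)
  expect_equal(normalising_constant(spec, c(2, 1)), 15)
})

test_that("adding a constant to the linear predictor scales K by exp(c)", {
  r <- small_resource(4)
  spec <- kernel_spec(
    selection_free_kernel("exponential", rate = 0.5),
    covariates = list(covariate("res", "end", layer = r)),
    beta = 2, study_area = as_study_area(r))
  r_shift <- raster_layer(r$values + 3, r$cell_size, r$origin)
  spec_shift <- spec
  spec_shift$covariates[[1]]$layer <- r_shift
  x <- c(1.7, 2.3)
  expect_equal(normalising_constant(spec_shift, x),
               normalising_constant(spec, x) * exp(2 * 3),
               tolerance = 1e-10)
  # ... while the normalised kernel is unchanged (equivariance)
  expect_lt(max(abs(evaluate_kernel(spec_shift, x)$p -
                    evaluate_kernel(spec, x)$p)), 1e-12)
})

test_that("kernel normalisation and bearing-independence hold across random draws", {
  r <- small_resource(6, seed = 21)
  area <- as_study_area(r)
  spec <- kernel_spec(
    selection_free_kernel("gaussian", sd = 1.2),
    covariates = list(covariate("res", "end", layer = r),
                      covariate("den", "dist_end", point = c(3, 3))),
    beta = c(1.5, -0.4), study_area = area)
  set.seed(42)
  for (k in 1:20) {
    x <- runif(2, 0, 6)
    u <- evaluate_kernel(spec, x, bearing = runif(1, 0, 2 * pi))
    expect_lt(abs(sum(u$p) - 1), 1e-10)
    expect_true(all(u$p >= 0))
    # kappa = 0: output independent of bearing
    expect_identical(u$p, evaluate_kernel(spec, x, bearing = NULL)$p)
  }
})

test_that("turn-angle concentration shifts mass toward the previous bearing", {
  area <- study_area(5, 5)
  spec <- kernel_spec(selection_free_kernel("exponential", rate = 0.3,
                                            kappa = 3),
                      study_area = area)
  u_north <- evaluate_kernel(spec, c(2.5, 2.5), bearing = 0)
  p <- matrix(u_north$p, 5, 5)
  expect_gt(sum(p[4:5, ]), sum(p[1:2, ]))  # more mass north of the start
})

test_that("delta kernel aimed at an inadmissible cell fails loudly", {
  area <- study_area(2, 2, admissible = c(FALSE, TRUE, TRUE, TRUE))
  spec <- kernel_spec(selection_free_kernel("delta"), study_area = area)
  expect_error(evaluate_kernel(spec, c(0.5, 0.5)), "no mass")
})

test_that("resource + central-place kernel reduces and concentrates correctly", {
  r <- small_resource(7, seed = 9)
  # coefficient zeroing: reduces to pure exponential decay of step length
  spec0 <- resource_central_place_kernel(r, c(3.5, 3.5), lambda = 0.4,
                                         beta_R = 0, beta_C = 0)
  bare <- kernel_spec(selection_free_kernel("exponential", rate = 0.4),
                      study_area = as_study_area(r))
  x <- c(2.1, 5.3)
  expect_lt(max(abs(evaluate_kernel(spec0, x)$p -
                    evaluate_kernel(bare, x)$p)), 1e-14)
  # strong central-place attraction: mass concentrates at x_C's cell
  spec_big <- resource_central_place_kernel(r, c(3.5, 3.5), lambda = 0.4,
                                            beta_R = 0, beta_C = 50)
  u <- evaluate_kernel(spec_big, c(3.5, 3.5))
  expect_equal(which.max(u$p), cell_index_of(r, c(3.5, 3.5)))
  expect_gt(max(u$p), 0.999)
  expect_error(resource_central_place_kernel(r, c(3.5, 3.5), lambda = -1,
                                             beta_R = 0, beta_C = 0),
               "positive")
  expect_error(resource_central_place_kernel(r, c(99, 99), lambda = 1,
                                             beta_R = 0, beta_C = 0),
               "outside")
})

test_that("coupled kernels decouple when all interactions are zero", {
  r <- small_resource(6, seed = 4)
  centres <- rbind(c(1.5, 1.5), c(4.5, 4.5), c(1.5, 4.5), c(4.5, 1.5))
  specs <- coupled_kernels(r, centres, lambda = 0.3, beta_R = 1,
                           beta_C = 0.5, interaction = matrix(0, 4, 4))
  expect_length(specs, 4L)
  for (j in 1:4) {
    solo <- resource_central_place_kernel(r, centres[j, ], 0.3, 1, 0.5)
    x <- centres[j, ]
    expect_identical(evaluate_kernel(specs[[j]], x)$p,
                     evaluate_kernel(solo, x)$p)
  }
})

test_that("avoidance of a point-mass OD lowers kernel mass at that cell", {
  r <- small_resource(6, seed = 4)
  centres <- rbind(c(1.5, 1.5), c(4.5, 4.5))
  inter <- matrix(c(0, 5, 0, 0), 2, 2, byrow = TRUE)  # animal 1 avoids 2
  area <- as_study_area(r)
  point_mass <- local({
    p <- numeric(36); p[cell_index_of(r, c(3.5, 3.5))] <- 1
    vector_as_raster_test(p, area)
  })
  specs <- coupled_kernels(r, centres, lambda = 0.3, beta_R = 0, beta_C = 0,
                           interaction = inter)
  specs0 <- coupled_kernels(r, centres, lambda = 0.3, beta_R = 0, beta_C = 0,
                            interaction = matrix(0, 2, 2))
  ods <- list(NULL, point_mass)
  x <- c(2.5, 2.5)
  target <- cell_index_of(r, c(3.5, 3.5))
  p_avoid <- evaluate_kernel(specs[[1]], x, od_layers = ods)$p
  p_free <- evaluate_kernel(specs0[[1]], x)$p
  expect_lt(p_avoid[target], p_free[target])
})

test_that("nonzero interaction diagonal is rejected", {
  r <- small_resource(4)
  expect_error(
    coupled_kernels(r, rbind(c(1, 1), c(3, 3)), lambda = 1, beta_R = 0,
                    beta_C = 0, interaction = diag(2)),
    "zero diagonal")
})

test_that("kernel specs round-trip through the YAML config reader", {
  dir <- withr::local_tempdir()
  r <- small_resource(5, seed = 2)
  write_raster(r, file.path(dir, "res.asc"))
  yaml::write_yaml(list(
    selection_free = list(family = "exponential", rate = 0.2),
    covariates = list(
      list(name = "resource", kind = "end", path = "res.asc", beta = 1.5),
      list(name = "den", kind = "dist_end", point = c(2.5, 2.5),
           beta = -0.2))
  ), file.path(dir, "kernel.yaml"))
  spec <- read_kernel_config(file.path(dir, "kernel.yaml"))
  direct <- resource_central_place_kernel(r, c(2.5, 2.5), 0.2, 1.5, 0.2)
  x <- c(1.2, 3.3)
  expect_lt(max(abs(evaluate_kernel(spec, x)$p -
                    evaluate_kernel(direct, x)$p)), 1e-12)
})
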