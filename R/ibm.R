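#' Sample one movement step
#'
#' Draws the next location from the movement kernel: exact categorical
#' sampling over grid cells (no MCMC or rejection), followed by a uniform
#' jitter within the chosen cell so trajectories live in continuous space.
#'
#' @inheritParams evaluate_kernel
#' @return Numeric `(x, y)` of the next location.
#' @export
sample_step <- function(spec, x, bearing = NULL, t = 0, od_layers = NULL) {
  p <- evaluate_kernel(spec, x, bearing, t, od_layers)$p
  cell <- sample.int(length(p), 1L, prob = p)
  jitter_in_cell(spec$study_area, cell)
}

# Uniform point inside cell k (column-major index).
jitter_in_cell <- function(area, k) {
  i <- (k - 1L) %% area$n_rows
  j <- (k - 1L) %/% area$n_rows
  c(area$origin[1] + (j + stats::runif(1)) * area$cell_size,
    area$origin[2] + (i + stats::runif(1)) * area$cell_size)
}

#' Simulation configuration
#'
#' Bundles everything needed for a (possibly coupled) individual-based
#' simulation. Occurrence distributions (ODs) mediating between-animal
#' interaction are rebuilt every `od_update_interval` steps from each
#' animal's last `od_window` steps, interpolated with
#' `stepping_stones_per_step` stepping stones per step and smoothed with a
#' Gaussian kernel of standard deviation `od_bandwidth`; the OD entering
#' time step `t` uses only fixes strictly before `t` (recent space use is
#' causal).
#'
#' @param specs list of [kernel_spec()]s, one per animal (a single spec is
#'   wrapped).
#' @param x0 matrix of initial locations, one row per animal (or a single
#'   `(x, y)`).
#' @param n_steps number of steps (>= 1).
#' @param seed integer RNG seed (simulations are bit-reproducible under a
#'   fixed seed).
#' @param stepping_stones_per_step interpolated points per step used when
#'   building ODs (default 10).
#' @param od_window number of most recent steps contributing to an OD
#'   (default 500).
#' @param od_bandwidth Gaussian smoothing bandwidth in coordinate units
#'   (default 2 cell units).
#' @param od_update_interval steps between OD refreshes (default 1).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(specs, x0, n_steps, seed = 1,
                              stepping_stones_per_step = 10,
                              od_window = 500, od_bandwidth = 2,
                              od_update_interval = 1) {
  if (inherits(specs, "kernel_spec")) specs <- list(specs)
  for (s in specs) stopifnot(inherits(s, "kernel_spec"))
  if (is.null(dim(x0))) x0 <- matrix(x0, nrow = 1)
  x0 <- as.matrix(x0)
  if (nrow(x0) != length(specs))
    stopf("'x0' must have one row per animal (%d)", length(specs))
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L) stopf("'n_steps' must be >= 1")
  if (od_window < 1L) stopf("'od_window' must be >= 1")
  for (j in seq_along(specs)) {
    area <- specs[[j]]$study_area
    if (!point_in_area(area, x0[j, ]))
      stopf("initial location of animal %d is outside the study area", j)
  }
  structure(
    list(specs = specs, x0 = x0, n_steps = n_steps, seed = as.integer(seed),
         stepping_stones_per_step = as.integer(stepping_stones_per_step),
         od_window = as.integer(od_window),
         od_bandwidth = as.numeric(od_bandwidth),
         od_update_interval = as.integer(od_update_interval)),
    class = "simulation_config"
  )
}

# Does any spec couple to another animal's OD?
has_od_coupling <- function(specs) {
  any(vapply(specs, function(s)
    any(vapply(s$covariates, function(cv) cv$kind == "od", logical(1))),
    logical(1)))
}

#' Simulate (coupled) individual-based movement
#'
#' Runs the stochastic individual-based model: at each step, animals are
#' updated in a freshly randomised order; each samples its next location
#' from its movement kernel, with other animals' current occurrence
#' distributions entering as dynamic end-point covariates. For static
#' uncoupled kernels without a turn-angle component, per-cell step
#' distributions are cached, which makes long runs cheap without changing
#' the sampled law.
#'
#' @param config a [simulation_config()].
#' @param store_od_history also return the OD layers at every refresh.
#' @return A list with `trajectories` (list of [trajectory()]s, each with
#'   `n_steps + 1` fixes at times `0..n_steps`), `ods` (final per-animal
#'   occurrence distributions, `NULL` when never built) and, if requested,
#'   `od_history`.
#' @export
simulate_movement <- function(config, store_od_history = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  specs <- config$specs
  n <- length(specs)
  coupled <- has_od_coupling(specs)
  with_seed(config$seed, {
    pos <- config$x0
    bearings <- rep(NA_real_, n)
    fixes <- lapply(seq_len(n), function(j)
      matrix(c(0, pos[j, 1], pos[j, 2], NA), nrow = 1,
             dimnames = list(NULL, c("t", "x", "y", "bearing"))))
    ods <- vector("list", n)
    od_history <- if (store_od_history) list() else NULL
    caches <- lapply(seq_len(n), function(j) {
      if (!coupled && specs[[j]]$selection_free$kappa == 0) new.env(parent = emptyenv())
      else NULL
    })
    for (t_step in seq_len(config$n_steps)) {
      if (coupled && ((t_step - 1L) %% config$od_update_interval == 0L)) {
        for (j in seq_len(n)) {
          ods[[j]] <- if (nrow(fixes[[j]]) < 2L) {
            # before the first step the only information is the release
            # point: smooth it like any other fix set
            gaussian_point_density(fixes[[j]][, c("x", "y"), drop = FALSE],
                                   config$od_bandwidth,
                                   specs[[j]]$study_area)
          } else {
            occurrence_distribution(
              as_trajectory_matrix(fixes[[j]], j),
              window = config$od_window,
              stepping_stones_per_step = config$stepping_stones_per_step,
              bandwidth = config$od_bandwidth,
              area = specs[[j]]$study_area)
          }
        }
        if (store_od_history)
          od_history[[length(od_history) + 1L]] <-
            list(time = t_step - 1L, ods = ods)
      }
      for (j in sample.int(n)) {
        spec <- specs[[j]]
        if (!is.null(caches[[j]])) {
          cell <- cell_of(spec$study_area, pos[j, ])
          key <- as.character(cell)
          p <- caches[[j]][[key]]
          if (is.null(p)) {
            centre <- cell_centres(spec$study_area)[cell, ]
            p <- evaluate_kernel(spec, centre, t = t_step - 1L)$p
            assign(key, p, envir = caches[[j]])
          }
          new_cell <- sample.int(length(p), 1L, prob = p)
          new_pos <- jitter_in_cell(spec$study_area, new_cell)
        } else {
          new_pos <- sample_step(spec, pos[j, ], bearings[j], t_step - 1L,
                                 od_layers = ods)
        }
        bearings[j] <- step_bearing(new_pos[1] - pos[j, 1],
                                    new_pos[2] - pos[j, 2])
        pos[j, ] <- new_pos
        fixes[[j]] <- rbind(fixes[[j]],
                            c(t_step, new_pos[1], new_pos[2], bearings[j]))
      }
    }
    out <- list(
      trajectories = lapply(seq_len(n), function(j)
        trajectory(id = sprintf("animal_%d", j), t = fixes[[j]][, "t"],
                   x = fixes[[j]][, "x"], y = fixes[[j]][, "y"],
                   bearing = fixes[[j]][, "bearing"])),
      ods = ods
    )
    if (store_od_history) out$od_history <- od_history
    out
  })
}

as_trajectory_matrix <- function(m, j) {
  trajectory(id = sprintf("animal_%d", j), t = m[, "t"], x = m[, "x"],
             y = m[, "y"], bearing = m[, "bearing"])
}

#' Occurrence distribution of a trajectory
#'
#' Estimates an animal's recent space use from its path: the last `window`
#' steps are interpolated with `stepping_stones_per_step` straight-line
#' stepping stones per step (segment start points, plus the final
#' endpoint once), then smoothed with a Gaussian kernel of standard
#' deviation `bandwidth`, evaluated at cell centres and normalised to
#' sum 1.
#'
#' @param traj a [trajectory()] with at least one step inside the window.
#' @param window number of most recent steps to use.
#' @param stepping_stones_per_step interpolation points per step (>= 1).
#' @param bandwidth Gaussian bandwidth in coordinate units.
#' @param area the [study_area()] grid on which to evaluate the OD.
#' @return A [raster_layer()] of cell masses summing to 1.
#' @export
occurrence_distribution <- function(traj, window = 500,
                                    stepping_stones_per_step = 10,
                                    bandwidth = 2, area) {
  stopifnot(inherits(traj, "trajectory"), inherits(area, "study_area"))
  n_fix <- nrow(traj)
  if (n_fix < 2L) stopf("trajectory must contain at least one step")
  if (window < 1L) stopf("'window' must be >= 1")
  m <- as.integer(stepping_stones_per_step)
  if (m < 1L) stopf("'stepping_stones_per_step' must be >= 1")
  first <- max(1L, n_fix - window)
  xs <- traj$x[first:n_fix]; ys <- traj$y[first:n_fix]
  frac <- (seq_len(m) - 1L) / m
  px <- as.numeric(vapply(seq_len(length(xs) - 1L), function(k)
    xs[k] + frac * (xs[k + 1L] - xs[k]), numeric(m)))
  py <- as.numeric(vapply(seq_len(length(ys) - 1L), function(k)
    ys[k] + frac * (ys[k + 1L] - ys[k]), numeric(m)))
  px <- c(px, xs[length(xs)])  # final endpoint included once
  py <- c(py, ys[length(ys)])
  gaussian_point_density(cbind(px, py), bandwidth, area)
}

#' Endpoint UD estimate from replicate simulations
#'
#' Kernel density estimate of the time-`t` UD from the endpoints of
#' independent replicate simulations (each endpoint is an independent
#' sample of `u(x, t)`).
#'
#' @param points matrix of endpoint coordinates, one row per replicate
#'   (at least 2).
#' @param bandwidth Gaussian bandwidth in coordinate units.
#' @param area the [study_area()] grid.
#' @return A [raster_layer()] of cell masses summing to 1.
#' @export
endpoint_ud <- function(points, bandwidth = 2, area) {
  points <- as.matrix(points)
  if (nrow(points) < 2L)
    stopf("at least 2 endpoints are needed for a kernel density estimate")
  gaussian_point_density(points, bandwidth, area)
}

# Gaussian KDE of points evaluated at cell centres, normalised to sum 1.
gaussian_point_density <- function(points, bandwidth, area) {
  if (!is_scalar_num(bandwidth) || bandwidth <= 0)
    stopf("'bandwidth' must be a positive number")
  centres <- cell_centres(area)
  h2 <- 2 * bandwidth^2
  dens <- numeric(nrow(centres))
  # accumulate in blocks of points to bound the temporary matrix size
  block <- max(1L, floor(2e6 / nrow(centres)))
  for (start in seq(1L, nrow(points), by = block)) {
    idx <- start:min(start + block - 1L, nrow(points))
    d2 <- outer(centres[, 1], points[idx, 1], "-")^2 +
          outer(centres[, 2], points[idx, 2], "-")^2
    dens <- dens + rowSums(exp(-d2 / h2))
  }
  dens[!area$admissible] <- 0
  vector_as_raster(dens / sum(dens), area, name = "od")
}

#' Replicate endpoint sampling for a static kernel
#'
#' Runs `n_reps` independent realisations of a static, uncoupled movement
#' kernel for `n_steps` steps from a common start location and returns the
#' endpoints. Sampling is cell-exact categorical with per-cell step
#' distributions computed once per visited cell, so the endpoint law is
#' identical to stepping [sample_step()] `n_steps` times per replicate.
#'
#' @param spec a static [kernel_spec()] with `kappa = 0` and no dynamic
#'   covariates.
#' @param x0 `(x, y)` start location.
#' @param n_steps steps per replicate.
#' @param n_reps number of replicates.
#' @param seed integer RNG seed.
#' @return An `n_reps` x 2 matrix of endpoint coordinates (jittered
#'   uniformly within the endpoint cell).
#' @export
replicate_endpoints <- function(spec, x0, n_steps, n_reps, seed = 1) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (spec$selection_free$kappa > 0 || has_od_coupling(list(spec)))
    stopf("replicate endpoint sampling requires a static kernel (kappa = 0, no OD coupling)")
  area <- spec$study_area
  centres <- cell_centres(area)
  with_seed(seed, {
    cur <- rep(cell_of(area, x0), n_reps)
    cache <- new.env(parent = emptyenv())
    for (s in seq_len(n_steps)) {
      prev <- cur  # group replicates by their pre-step cell
      for (cell in unique(prev)) {
        key <- as.character(cell)
        p <- cache[[key]]
        if (is.null(p)) {
          p <- evaluate_kernel(spec, centres[cell, ])$p
          assign(key, p, envir = cache)
        }
        sel <- prev == cell
        cur[sel] <- sample.int(length(p), sum(sel), replace = TRUE, prob = p)
      }
    }
    i <- (cur - 1L) %% area$n_rows
    j <- (cur - 1L) %/% area$n_rows
    cbind(x = area$origin[1] + (j + stats::runif(n_reps)) * area$cell_size,
          y = area$origin[2] + (i + stats::runif(n_reps)) * area$cell_size)
  })
}
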