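#' Selection-free movement kernel component
#'
#' The intrinsic step-length (and optionally turn-angle) component
#' `psi_tau` of a movement kernel, independent of habitat selection.
#' Supported families:
#' \describe{
#'   \item{`"exponential"`}{`psi(l) = exp(-rate * l)` — exponential decay
#'     of step length, the workhorse form.}
#'   \item{`"gaussian"`}{`psi(l) = exp(-l^2 / (2 * sd^2))`.}
#'   \item{`"uniform"`}{`psi(l) = 1`: the animal can reach the whole study
#'     area in one step.}
#'   \item{`"delta"`}{the animal stays in its current cell.}
#' }
#' A concentration `kappa > 0` adds a von Mises-style turn-angle factor
#' `exp(kappa * cos(theta - bearing))` multiplying `psi` (correlated
#' movement); it is supported by the individual-based simulator but not by
#' the master-equation engine.
#'
#' @param family one of `"exponential"`, `"gaussian"`, `"uniform"`, `"delta"`.
#' @param rate decay rate (per unit length) for `"exponential"`.
#' @param sd standard deviation (length units) for `"gaussian"`.
#' @param kappa non-negative turn-angle concentration (default 0, no
#'   directional persistence).
#' @param tau step duration (default 1; trajectory times are step indices
#'   times `tau`).
#' @return An object of class `selection_free_kernel`.
#' @examples
#' selection_free_kernel("exponential", rate = 0.2)
#' @export
selection_free_kernel <- function(family = c("exponential", "gaussian",
                                             "uniform", "delta"),
                                  rate = NULL, sd = NULL, kappa = 0, tau = 1) {
  family <- match.arg(family)
  if (family == "exponential") {
    if (!is_scalar_num(rate) || rate <= 0)
      stopf("'rate' must be a positive number for the exponential family")
  } else if (family == "gaussian") {
    if (!is_scalar_num(sd) || sd <= 0)
      stopf("'sd' must be a positive number for the gaussian family")
  }
  if (!is_scalar_num(kappa) || kappa < 0) stopf("'kappa' must be >= 0")
  if (!is_scalar_num(tau) || tau <= 0) stopf("'tau' must be > 0")
  structure(
    list(family = family, rate = rate, sd = sd, kappa = kappa, tau = tau),
    class = "selection_free_kernel"
  )
}

#' @export
print.selection_free_kernel <- function(x, ...) {
  par <- switch(x$family,
    exponential = sprintf("rate %g", x$rate),
    gaussian = sprintf("sd %g", x$sd),
    uniform = "flat over the study area",
    delta = "stay in place")
  cat(sprintf("<selection_free_kernel: %s (%s), kappa %g, tau %g>\n",
              x$family, par, x$kappa, x$tau))
  invisible(x)
}

# psi evaluated at step lengths l (the delta family is handled by cell
# containment in the callers, not through a length threshold).
psi_values <- function(psi, l) {
  switch(psi$family,
    exponential = exp(-psi$rate * l),
    gaussian = exp(-l^2 / (2 * psi$sd^2)),
    uniform = rep(1, length(l)),
    delta = stopf("the delta family has no length-based density")
  )
}

#' Movement covariate
#'
#' One covariate entering the step-selection term `exp(beta . Z(x, z, t))`.
#' Kinds:
#' \describe{
#'   \item{`"end"`}{raster value at the step end point `z`.}
#'   \item{`"start"`}{raster value at the step start point `x` (constant
#'     across candidate end points, so it cancels in the normalised kernel
#'     but still contributes to the normalising constant).}
#'   \item{`"dist_end"`}{Euclidean distance from the candidate end point to
#'     a fixed point, `|z - point|` (e.g. a den or nest site).}
#'   \item{`"dist_start"`}{distance from the start point, `|x - point|`.}
#'   \item{`"od"`}{a dynamic end-point layer: another animal's occurrence
#'     distribution at the current time, resolved at evaluation time either
#'     from `od_layers` passed to [evaluate_kernel()] or from `provider`.}
#' }
#'
#' @param name covariate label.
#' @param kind one of the kinds above.
#' @param layer a [raster_layer()] (kinds `"end"`, `"start"`).
#' @param point numeric `(x, y)` (kinds `"dist_end"`, `"dist_start"`).
#' @param animal index of the animal whose OD this is (kind `"od"`).
#' @param provider optional `function(animal, t)` returning a
#'   [raster_layer()] or UD (kind `"od"`).
#' @return An object of class `covariate`.
#' @export
covariate <- function(name, kind = c("end", "start", "dist_end", "dist_start",
                                     "od"),
                      layer = NULL, point = NULL, animal = NULL,
                      provider = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("end", "start")) {
    if (!inherits(layer, "raster_layer"))
      stopf("covariate '%s' (kind %s) needs a raster 'layer'", name, kind)
  } else if (kind %in% c("dist_end", "dist_start")) {
    if (length(point) != 2L || any(!is.finite(point)))
      stopf("covariate '%s' (kind %s) needs a finite (x, y) 'point'", name, kind)
  } else {
    if (is.null(animal)) stopf("covariate '%s' (kind od) needs an 'animal' index", name)
  }
  structure(
    list(name = as.character(name)[1L], kind = kind, layer = layer,
         point = if (!is.null(point)) as.numeric(point), animal = animal,
         provider = provider),
    class = "covariate"
  )
}

#' Movement-kernel specification
#'
#' Bundles a selection-free component, an ordered covariate list with
#' coefficients, and the study area into a full parametric movement
#' kernel: the probability density of a step from `x` to `z` is
#' proportional to `psi(|z - x|) * exp(sum_i beta_i * Z_i(x, z, t))`,
#' truncated to the study area and normalised over it.
#'
#' @param selection_free a [selection_free_kernel()].
#' @param covariates list of [covariate()] objects (possibly empty).
#' @param beta numeric coefficients, one per covariate.
#' @param study_area a [study_area()].
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(selection_free, covariates = list(), beta = numeric(),
                        study_area) {
  stopifnot(inherits(selection_free, "selection_free_kernel"),
            inherits(study_area, "study_area"))
  if (inherits(covariates, "covariate")) covariates <- list(covariates)
  if (length(beta) != length(covariates))
    stopf("'beta' must have one coefficient per covariate (%d vs %d)",
          length(beta), length(covariates))
  for (cv in covariates)
    if (!inherits(cv, "covariate")) stopf("'covariates' must be covariate objects")
  structure(
    list(selection_free = selection_free, covariates = covariates,
         beta = as.numeric(beta), study_area = study_area),
    class = "kernel_spec"
  )
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec: %s selection-free component, %d covariate(s), %d x %d grid>\n",
              x$selection_free$family, length(x$covariates),
              x$study_area$n_rows, x$study_area$n_cols))
  if (length(x$covariates)) {
    for (k in seq_along(x$covariates))
      cat(sprintf("  %s (%s): beta = %g\n", x$covariates[[k]]$name,
                  x$covariates[[k]]$kind, x$beta[k]))
  }
  invisible(x)
}

# The linear predictor beta . Z(x, z, t) as a vector over candidate end
# cells (column-major cell order). `od_layers` is an optional list of
# per-animal UD/raster layers used to resolve "od" covariates.
linear_predictor <- function(spec, x, t, od_layers = NULL) {
  area <- spec$study_area
  bz <- numeric(n_cells(area))
  if (!length(spec$covariates)) return(bz)
  centres <- cell_centres(area)
  for (k in seq_along(spec$covariates)) {
    cv <- spec$covariates[[k]]
    val <- switch(cv$kind,
      end = layer_values(cv$layer, area),
      start = rep(layer_values(cv$layer, area)[cell_of(area, x)],
                  n_cells(area)),
      dist_end = sqrt((centres[, 1] - cv$point[1])^2 +
                      (centres[, 2] - cv$point[2])^2),
      dist_start = rep(sqrt(sum((x - cv$point)^2)), n_cells(area)),
      od = {
        lay <- if (!is.null(od_layers) && length(od_layers) >= cv$animal &&
                   !is.null(od_layers[[cv$animal]])) od_layers[[cv$animal]]
               else if (!is.null(cv$provider)) cv$provider(cv$animal, t)
               else stopf("covariate '%s': no OD layer available for animal %d at time %s",
                          cv$name, cv$animal, format(t))
        layer_values(lay, area)
      })
    bz <- bz + spec$beta[k] * val
  }
  bz
}

# Unnormalised kernel weights over cells (zero outside the admissible set).
kernel_weights <- function(spec, x, bearing = NULL, t = 0, od_layers = NULL) {
  area <- spec$study_area
  if (!point_in_area(area, x))
    stopf("start location (%g, %g) is outside the study area", x[1], x[2])
  psi <- spec$selection_free
  if (psi$family == "delta") {
    w <- numeric(n_cells(area))
    w[cell_of(area, x)] <- 1
  } else {
    centres <- cell_centres(area)
    dx <- centres[, 1] - x[1]
    dy <- centres[, 2] - x[2]
    l <- sqrt(dx^2 + dy^2)
    w <- psi_values(psi, l)
    if (psi$kappa > 0 && !is.null(bearing) && is.finite(bearing)) {
      turn <- exp(psi$kappa * cos(step_bearing(dx, dy) - bearing))
      turn[l == 0] <- 1  # no direction defined for a zero-length step
      w <- w * turn
    }
  }
  bz <- linear_predictor(spec, x, t, od_layers)
  # subtract the max over admissible cells before exponentiating (overflow
  # safety; a constant shift cancels in the normalisation)
  shift <- max(bz[area$admissible])
  w <- w * exp(bz - shift)
  w[!area$admissible] <- 0
  attr(w, "log_shift") <- shift
  w
}

#' Evaluate a movement kernel as a distribution over grid cells
#'
#' Computes the one-step movement kernel from start location `x`: the
#' probability, for every grid cell, that the next fix lands in that cell.
#' Mass outside the admissible study area is zero (the "no go" boundary
#' condition) and the returned distribution sums to 1.
#'
#' @param spec a [kernel_spec()].
#' @param x numeric `(x, y)` start location inside the study area.
#' @param bearing arrival bearing in radians clockwise from north, or
#'   `NULL`/`NA` when undefined (first step). Ignored unless the
#'   selection-free component has `kappa > 0`.
#' @param t current time (used by dynamic covariates).
#' @param od_layers optional list of per-animal occurrence-distribution
#'   layers resolving `"od"` covariates.
#' @return A [ud()] over the study-area grid, stamped with `t`.
#' @examples
#' area <- study_area(3, 3)
#' spec <- kernel_spec(selection_free_kernel("uniform"), study_area = area)
#' evaluate_kernel(spec, c(1.5, 1.5))$p
#' @export
evaluate_kernel <- function(spec, x, bearing = NULL, t = 0, od_layers = NULL) {
  w <- kernel_weights(spec, x, bearing, t, od_layers)
  s <- sum(w)
  if (!is.finite(s) || s <= 0)
    stopf("movement kernel has no mass on the admissible study area from (%g, %g)",
          x[1], x[2])
  ud(as.numeric(w) / s, spec$study_area, time = t)
}

#' Normalising constant of a movement kernel
#'
#' The integral (midpoint rule over cell centres, times cell area) of the
#' unnormalised kernel weight `psi(|z - x|) * exp(beta . Z(x, z, t))` over
#' the admissible study area.
#'
#' @inheritParams evaluate_kernel
#' @return A positive scalar.
#' @export
normalising_constant <- function(spec, x, bearing = NULL, t = 0,
                                 od_layers = NULL) {
  w <- kernel_weights(spec, x, bearing, t, od_layers)
  s <- sum(w) * exp(attr(w, "log_shift")) * spec$study_area$cell_size^2
  if (!is.finite(s) || s <= 0)
    stopf("movement kernel has no mass on the admissible study area from (%g, %g)",
          x[1], x[2])
  s
}

#' Resource + central-place movement kernel
#'
#' The worked kernel combining exponential step-length decay, attraction to
#' a resource layer and a localising tendency towards a central place
#' (den/nest site): unnormalised weight
#' `exp(-lambda * |z - x|) * exp(beta_R * R(z) - beta_C * |z - x_C|)`.
#' The central-place penalty is attached to the prospective end point `z`:
#' a penalty depending only on the start point would cancel in the kernel's
#' normalisation and produce no localising tendency.
#'
#' @param resource a [raster_layer()] resource map `R`.
#' @param x_C numeric `(x, y)` central place, inside the study area.
#' @param lambda positive step-length decay rate.
#' @param beta_R resource selection coefficient.
#' @param beta_C central-place attraction strength (enters with a negative
#'   sign on distance).
#' @param kappa,tau passed to [selection_free_kernel()].
#' @return A [kernel_spec()].
#' @examples
#' r <- generate_resource_layer(20, 20, smoothness = 4, seed = 1)
#' spec <- resource_central_place_kernel(r, x_C = c(10, 10), lambda = 0.2,
#'                                       beta_R = 1.5, beta_C = 0.2)
#' @export
resource_central_place_kernel <- function(resource, x_C, lambda,
                                          beta_R, beta_C, kappa = 0, tau = 1) {
  stopifnot(inherits(resource, "raster_layer"))
  if (!is_scalar_num(lambda) || lambda <= 0)
    stopf("'lambda' must be a positive number")
  area <- as_study_area(resource)
  if (!point_in_area(area, x_C))
    stopf("central place (%g, %g) is outside the study area", x_C[1], x_C[2])
  kernel_spec(
    selection_free_kernel("exponential", rate = lambda, kappa = kappa,
                          tau = tau),
    covariates = list(
      covariate("resource", "end", layer = resource),
      covariate("dist_to_centre", "dist_end", point = x_C)
    ),
    beta = c(beta_R, -beta_C),
    study_area = area
  )
}

#' Coupled movement kernels for interacting animals
#'
#' Builds one kernel per animal on a shared landscape: each animal `j` has
#' unnormalised weight
#' `exp(-lambda * |z - x|) * exp(beta_R[j] * R(z) - beta_C[j] * |z - x_C[j]|
#'  - sum_{j' != j} interaction[j, j'] * O_{j'}(z, t))`,
#' where `O_{j'}` is animal `j'`'s occurrence distribution at the current
#' time (a dynamic end-point covariate). Positive interaction entries give
#' avoidance, negative give attraction; the diagonal must be zero
#' (self-interaction is expressed through a separate dynamic covariate,
#' not this sum).
#'
#' @param resource shared [raster_layer()] resource map.
#' @param centres matrix (one row per animal) or list of `(x, y)` central
#'   places.
#' @param lambda positive step-length decay rate (shared).
#' @param beta_R,beta_C per-animal coefficients (recycled if scalar).
#' @param interaction square matrix of interaction strengths
#'   `interaction[j, j']`, zero diagonal.
#' @param od_provider optional `function(animal, t)` returning that
#'   animal's occurrence distribution, for evaluating the kernels outside
#'   a simulation.
#' @param kappa,tau passed to [selection_free_kernel()].
#' @return A list of [kernel_spec()] objects, one per animal.
#' @export
coupled_kernels <- function(resource, centres, lambda, beta_R, beta_C,
                            interaction, od_provider = NULL, kappa = 0,
                            tau = 1) {
  if (is.list(centres)) centres <- do.call(rbind, centres)
  centres <- as.matrix(centres)
  n <- nrow(centres)
  interaction <- as.matrix(interaction)
  if (nrow(interaction) != n || ncol(interaction) != n)
    stopf("'interaction' must be an %d x %d matrix", n, n)
  if (any(diag(interaction) != 0))
    stopf("'interaction' must have a zero diagonal; self-interaction is expressed via a dynamic covariate, not the between-animal sum")
  beta_R <- rep_len(beta_R, n)
  beta_C <- rep_len(beta_C, n)
  lapply(seq_len(n), function(j) {
    spec <- resource_central_place_kernel(resource, centres[j, ], lambda,
                                          beta_R[j], beta_C[j], kappa, tau)
    for (jp in seq_len(n)) {
      if (jp == j || interaction[j, jp] == 0) next
      spec$covariates <- c(spec$covariates, list(
        covariate(sprintf("od_animal_%d", jp), "od", animal = jp,
                  provider = od_provider)))
      spec$beta <- c(spec$beta, -interaction[j, jp])
    }
    spec
  })
}
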