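# Closed-form steady states for kernels whose selection-free component is
# radially symmetric and whose covariates depend only on the step end
# point, plus the small-step diffusion constant. These serve as
# independent oracles for the master-equation engine.

# Resolve end-point-only covariates to the field beta . Z~(z) over cells.
# Accepts either a list of raster layers (paired with `beta`) or a list of
# covariate objects; start-point and dynamic covariates are rejected by
# name, since the closed forms require end-point-only dependence.
endpoint_field <- function(beta, z_layers, area) {
  if (inherits(z_layers, c("raster_layer", "covariate")))
    z_layers <- list(z_layers)
  if (length(beta) != length(z_layers))
    stopf("'beta' must have one coefficient per covariate layer (%d vs %d)",
          length(beta), length(z_layers))
  bz <- numeric(n_cells(area))
  centres <- NULL
  for (k in seq_along(z_layers)) {
    zl <- z_layers[[k]]
    if (inherits(zl, "covariate")) {
      if (zl$kind %in% c("start", "dist_start", "od"))
        stopf("covariate '%s' (kind %s) is not end-point-only; the closed-form steady states require end-point covariates",
              zl$name, zl$kind)
      if (zl$kind == "dist_end") {
        if (is.null(centres)) centres <- cell_centres(area)
        val <- sqrt((centres[, 1] - zl$point[1])^2 +
                    (centres[, 2] - zl$point[2])^2)
      } else val <- layer_values(zl$layer, area)
    } else {
      val <- layer_values(zl, area)
    }
    bz <- bz + beta[k] * val
  }
  bz
}

# Extract (beta, end-point covariates, area, psi) from a kernel_spec,
# validating end-point-only structure.
spec_endpoint_parts <- function(spec) {
  list(beta = spec$beta, z_layers = spec$covariates,
       area = spec$study_area, psi = spec$selection_free)
}

#' Barnett-Moorcroft closed-form steady state
#'
#' Exact steady-state UD for movement kernels whose selection-free
#' component is a function of step length only and whose covariates depend
#' only on the step end point:
#' `u*(x)` proportional to
#' `exp(beta . Z~(x)) * integral over z of exp(beta . Z~(z)) psi(|x - z|)`,
#' normalised over the study area. The inner integral is evaluated by the
#' same midpoint rule as the kernel's normalising constant, with `psi`
#' truncated where it falls below `1e-12` of its value at zero. On the
#' discretised grid this is the exact stationary distribution of the
#' master-equation transition matrix, so agreement with
#' [steady_state_fixed_point()] is limited only by solver tolerance.
#'
#' @param psi a [selection_free_kernel()] with `kappa = 0`, or a full
#'   [kernel_spec()] (in which case `beta`, `z_layers`, `area` are taken
#'   from it).
#' @param beta coefficients, one per end-point covariate.
#' @param z_layers list of end-point [raster_layer()]s or end-point-only
#'   [covariate()]s.
#' @param area the [study_area()].
#' @return A [ud()].
#' @export
steady_state_barnett_moorcroft <- function(psi, beta = NULL, z_layers = NULL,
                                           area = NULL) {
  if (inherits(psi, "kernel_spec")) {
    parts <- spec_endpoint_parts(psi)
    beta <- parts$beta; z_layers <- parts$z_layers; area <- parts$area
    psi <- parts$psi
  }
  stopifnot(inherits(psi, "selection_free_kernel"), inherits(area, "study_area"))
  if (psi$kappa > 0)
    stopf("the closed-form steady state requires kappa = 0")
  bz <- endpoint_field(beta, z_layers, area)
  adm <- area$admissible
  w <- exp(bz - max(bz[adm]))
  w[!adm] <- 0
  a <- area$cell_size^2
  if (psi$family == "delta") {
    inner <- w * a
  } else if (psi$family == "uniform") {
    inner <- numeric(n_cells(area))
    inner[adm] <- sum(w) * a  # same inner integral everywhere: reduces to RSF
  } else {
    centres <- cell_centres(area)
    idx <- which(adm)
    # truncation radius: where psi drops below 1e-12 of psi(0)
    r_max <- psi_truncation_radius(psi)
    d_big <- max(stats::dist(rbind(
      c(min(centres[idx, 1]), min(centres[idx, 2])),
      c(max(centres[idx, 1]), max(centres[idx, 2])))))
    inner <- numeric(n_cells(area))
    if (r_max >= d_big) {
      # full dense distance computation
      D <- as.matrix(stats::dist(centres[idx, , drop = FALSE]))
      inner[idx] <- as.numeric(psi_values(psi, D) %*% w[idx]) * a
    } else {
      for (k in idx) {
        d <- sqrt((centres[idx, 1] - centres[k, 1])^2 +
                  (centres[idx, 2] - centres[k, 2])^2)
        keep <- d <= r_max
        inner[k] <- sum(psi_values(psi, d[keep]) * w[idx][keep]) * a
      }
    }
  }
  u <- w * inner
  ud(u / sum(u), area)
}

# Radius beyond which psi < 1e-12 * psi(0).
psi_truncation_radius <- function(psi) {
  switch(psi$family,
    exponential = -log(1e-12) / psi$rate,
    gaussian = psi$sd * sqrt(-2 * log(1e-12)),
    uniform = Inf,
    delta = 0)
}

#' Resource-selection-function steady state (uniform-psi limit)
#'
#' The steady-state UD in the limit where the selection-free kernel is
#' uniform over the study area (the animal can traverse the whole area in
#' one step): `u*(x) = exp(beta . Z~(x)) / sum exp(beta . Z~)`, the
#' classical resource selection function.
#'
#' @inheritParams steady_state_barnett_moorcroft
#' @return A [ud()].
#' @export
steady_state_rsf <- function(beta, z_layers, area) {
  bz <- endpoint_field(beta, z_layers, area)
  adm <- area$admissible
  w <- exp(bz - max(bz[adm]))
  w[!adm] <- 0
  ud(w / sum(w), area)
}

#' Doubled-selection steady state (narrow-psi limit)
#'
#' The steady-state UD in the limit where the selection-free kernel is
#' arbitrarily narrow (movement decisions on scales much smaller than the
#' study area): `u*(x) = exp(2 beta . Z~(x)) / sum exp(2 beta . Z~)` —
#' the resource-selection form with `beta` replaced by `2 beta`. The
#' effect of selection on space use doubles as the selection scale
#' shrinks; this is also the steady state of the advection-diffusion
#' approximation.
#'
#' @inheritParams steady_state_barnett_moorcroft
#' @return A [ud()].
#' @export
steady_state_doubled <- function(beta, z_layers, area) {
  steady_state_rsf(2 * beta, z_layers, area)
}

#' Small-step diffusion constant of a selection-free kernel
#'
#' The diffusion constant of the advection-diffusion approximation,
#' `D_tau = (1 / (4 tau)) * integral over the plane of |x'|^2 psi(|x'|)`,
#' with `psi` first normalised to a planar probability density (a
#' dimensionally meaningful diffusion constant requires a density; see
#' the package vignette). Computed by radial quadrature:
#' `D_tau = (pi / (2 tau)) * integral of r^3 psi_norm(r) dr`.
#'
#' @param psi a [selection_free_kernel()].
#' @param tau step duration; defaults to the kernel's `tau`.
#' @return A non-negative scalar. The delta family returns 0 (no
#'   movement); the uniform family is rejected (no normalisable planar
#'   density, divergent second moment).
#' @examples
#' psi <- selection_free_kernel("exponential", rate = 0.2)
#' diffusion_constant(psi)  # 3 / (2 * 0.2^2)
#' @export
diffusion_constant <- function(psi, tau = NULL) {
  stopifnot(inherits(psi, "selection_free_kernel"))
  tau <- tau %||% psi$tau
  if (!is_scalar_num(tau) || tau <= 0) stopf("'tau' must be > 0")
  if (psi$family == "delta") return(0)
  if (psi$family == "uniform")
    stopf("the uniform kernel has no normalisable density on the plane; its second moment diverges")
  f1 <- function(r) r * psi_values(psi, r)
  f3 <- function(r) r^3 * psi_values(psi, r)
  m1 <- tryCatch(stats::integrate(f1, 0, Inf, rel.tol = 1e-10),
                 error = function(e) NULL)
  m3 <- tryCatch(stats::integrate(f3, 0, Inf, rel.tol = 1e-10),
                 error = function(e) NULL)
  if (is.null(m1) || is.null(m3) || m1$value <= 0)
    stopf("second-moment quadrature did not converge for this kernel")
  # normaliser of the planar density is 2*pi*m1; D = (pi/(2 tau)) m3/(2 pi m1)
  m3$value / (4 * tau * m1$value)
}

#' Area of the highest-density region of a UD
#'
#' The area of the smallest set of cells holding at least `level` of the
#' total mass: cells are sorted by density and accumulated until the mass
#' threshold is reached (no smoothing), then counted times the cell area.
#'
#' @param u a [ud()] (or raster layer of masses).
#' @param level mass level in (0, 1], default 0.95.
#' @return Area in squared coordinate units.
#' @export
hdr_area <- function(u, level = 0.95) {
  p <- if (inherits(u, "ud")) u$p else layer_values(u, as_study_area(u))
  cs2 <- if (inherits(u, "ud")) u$area$cell_size^2 else u$cell_size^2
  p <- sort(p, decreasing = TRUE)
  n <- which(cumsum(p) >= level * sum(p))[1L]
  n * cs2
}

#' Compare closed-form steady states against a reference UD
#'
#' Summarises how the exact closed form and its two limiting formulas
#' relate to a reference UD: L1 distance to the reference and the area of
#' each distribution's 95% highest-density region. For a concentrating
#' kernel the uniform-limit (RSF) formula over-estimates the used area and
#' the narrow-limit (doubled) formula under-estimates it, so the areas
#' order `rsf >= exact >= doubled`.
#'
#' @param ud_exact,ud_rsf,ud_doubled,reference [ud()]s on one grid.
#' @param level highest-density-region mass level (default 0.95).
#' @return A data frame with one row per formula (`exact`, `rsf`,
#'   `doubled`, `reference`): `l1_to_reference` and `hdr_area`.
#' @export
compare_steady_states <- function(ud_exact, ud_rsf, ud_doubled, reference,
                                  level = 0.95) {
  uds <- list(exact = ud_exact, rsf = ud_rsf, doubled = ud_doubled,
              reference = reference)
  for (u in uds) {
    stopifnot(inherits(u, "ud"))
    check_same_grid(u$area, reference$area)
  }
  data.frame(
    formula = names(uds),
    l1_to_reference = vapply(uds, function(u) sum(abs(u$p - reference$p)),
                             numeric(1)),
    hdr_area = vapply(uds, hdr_area, numeric(1), level = level),
    row.names = NULL
  )
}
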