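#' Utilisation distribution over grid cells
#'
#' A probability distribution over the cells of a study-area grid: entry
#' `k` (column-major cell order, row index fastest) is the probability of
#' finding the animal in cell `k`. Entries are non-negative and sum to 1.
#'
#' @param p numeric vector of cell probabilities (length `n_rows * n_cols`),
#'   or a matrix of cell masses.
#' @param area the [study_area()] the distribution lives on.
#' @param time step index stamp (default 0).
#' @return An object of class `ud`.
#' @export
ud <- function(p, area, time = 0) {
  stopifnot(inherits(area, "study_area"))
  p <- as.numeric(p)
  if (length(p) != n_cells(area))
    stopf("'p' must have one entry per grid cell (%d)", n_cells(area))
  if (any(!is.finite(p)) || any(p < -1e-12))
    stopf("UD entries must be finite and non-negative")
  p[p < 0] <- 0
  s <- sum(p)
  if (abs(s - 1) > 1e-10) {
    if (s <= 0) stopf("UD has zero total mass")
    stopf("UD entries must sum to 1 (got %.12g); normalise first", s)
  }
  structure(list(p = p, area = area, time = time), class = "ud")
}

#' @export
print.ud <- function(x, ...) {
  cat(sprintf("<ud: %d x %d grid, time %s, max cell mass %.4g>\n",
              x$area$n_rows, x$area$n_cols, format(x$time), max(x$p)))
  invisible(x)
}

#' @export
plot.ud <- function(x, ...) {
  plot(as_raster(x), ...)
  invisible(x)
}

#' Convert a UD to a raster layer
#'
#' @param x a [ud()].
#' @param name layer label.
#' @return A [raster_layer()] of cell masses.
#' @export
as_raster <- function(x, name = "ud") {
  stopifnot(inherits(x, "ud"))
  vector_as_raster(x$p, x$area, name = name)
}

#' Uniform UD over the admissible cells of a study area
#'
#' @param area a [study_area()].
#' @param time step index stamp.
#' @return A [ud()].
#' @export
uniform_ud <- function(area, time = 0) {
  p <- as.numeric(area$admissible)
  ud(p / sum(p), area, time = time)
}

#' Build the discretised master-equation transition matrix
#'
#' Turns a movement kernel into a column-stochastic matrix over grid
#' cells: column `s'` is the kernel evaluated from the centre of cell
#' `s'`, so entry `[s, s']` is the probability of moving from `s'` to `s`
#' in one step and propagation is the matrix-vector product `P %*% u`.
#' Only admissible cells are represented in the matrix; the `cells` field
#' maps matrix indices back to grid cells.
#'
#' Kernels with a turn-angle component (`kappa > 0`) are rejected: a
#' bearing-augmented state space is not supported here, so correlated
#' movement must be handled by the individual-based simulator
#' ([simulate_movement()]).
#'
#' @param spec a [kernel_spec()] with `kappa = 0`.
#' @param t time at which dynamic covariates are resolved.
#' @param sparse store the matrix sparsely (entries below `threshold`
#'   dropped and columns renormalised); defaults to `TRUE` above 10^4
#'   cells.
#' @param threshold sparse drop tolerance.
#' @param od_layers optional OD layers resolving dynamic covariates.
#' @return An object of class `transition_matrix` with fields `P`
#'   (matrix), `area`, `cells` (admissible cell indices) and `time`.
#' @export
build_transition_matrix <- function(spec, t = 0, sparse = NULL,
                                    threshold = 1e-12, od_layers = NULL) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (spec$selection_free$kappa > 0)
    stopf(paste("the master-equation engine requires kappa = 0;",
                "use the individual-based simulator (simulate_movement)",
                "for turn-angle kernels"))
  area <- spec$study_area
  cells <- which(area$admissible)
  n <- length(cells)
  sparse <- sparse %||% (n > 1e4)
  centres <- cell_centres(area)
  if (sparse) {
    ii <- vector("list", n); pp <- vector("list", n)
    for (k in seq_len(n)) {
      col <- evaluate_kernel(spec, centres[cells[k], ], t = t,
                             od_layers = od_layers)$p[cells]
      keep <- which(col > threshold)
      ii[[k]] <- keep
      pp[[k]] <- col[keep] / sum(col[keep])
    }
    P <- Matrix::sparseMatrix(
      i = unlist(ii), j = rep(seq_len(n), lengths(ii)), x = unlist(pp),
      dims = c(n, n))
  } else {
    P <- matrix(0, n, n)
    for (k in seq_len(n))
      P[, k] <- evaluate_kernel(spec, centres[cells[k], ], t = t,
                                od_layers = od_layers)$p[cells]
  }
  structure(list(P = P, area = area, cells = cells, time = t),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix: %d x %d cells (%s), time %s>\n",
              length(x$cells), length(x$cells),
              if (is.matrix(x$P)) "dense" else "sparse",
              format(x$time)))
  invisible(x)
}

# u (full-grid vector) -> admissible-state vector and back.
ud_to_state <- function(u, tm) {
  check_same_grid(u$area, tm$area)
  u$p[tm$cells]
}

state_to_ud <- function(v, tm, time = 0) {
  p <- numeric(n_cells(tm$area))
  p[tm$cells] <- as.numeric(v)
  ud(p / sum(p), tm$area, time = time)
}

#' Propagate a UD forward with the master equation
#'
#' Applies `u(t + tau) = P(t) u(t)` for `n_steps` steps. `matrices` may be
#' a single static [build_transition_matrix()] result or a provider
#' `function(t)` returning the transition matrix for the step leaving
#' time `t` (time-varying kernels).
#'
#' @param u0 initial [ud()].
#' @param matrices a `transition_matrix` or a `function(t)`.
#' @param n_steps number of steps (>= 1).
#' @return A list of `n_steps + 1` UDs (including `u0`), time-stamped
#'   `u0$time + 0:n_steps`.
#' @export
propagate <- function(u0, matrices, n_steps) {
  stopifnot(inherits(u0, "ud"))
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L) stopf("'n_steps' must be >= 1")
  provider <- if (inherits(matrices, "transition_matrix")) {
    tm0 <- matrices
    function(t) tm0
  } else if (is.function(matrices)) matrices
    else stopf("'matrices' must be a transition_matrix or a function(t)")
  out <- vector("list", n_steps + 1L)
  out[[1L]] <- u0
  tm <- provider(u0$time)
  v <- ud_to_state(u0, tm)
  for (s in seq_len(n_steps)) {
    t_now <- u0$time + s - 1L
    if (s > 1L) tm <- provider(t_now)
    v <- as.numeric(tm$P %*% v)
    tot <- sum(v)
    if (abs(tot - 1) > 1e-9)
      stopf("probability mass drifted to %.12g at step %d", tot, s)
    v <- v / tot
    out[[s + 1L]] <- state_to_ud(v, tm, time = u0$time + s)
  }
  out
}

#' Cumulative (time-averaged) UD
#'
#' The discrete analogue of the cumulative utilisation distribution up to
#' time `t`: the time average `(1/T) * sum_t u(., t)` of a sequence of
#' UDs. This is what trajectory-pooling estimators of the UD measure; it
#' coincides with the instantaneous UD only at steady state.
#'
#' @param uds non-empty list of [ud()] objects on one grid.
#' @return A [ud()] stamped with the last input's time.
#' @export
cumulative_ud <- function(uds) {
  if (!length(uds)) stopf("'uds' must be a non-empty list of UDs")
  for (u in uds) stopifnot(inherits(u, "ud"))
  area <- uds[[1L]]$area
  acc <- numeric(n_cells(area))
  for (u in uds) {
    check_same_grid(u$area, area)
    acc <- acc + u$p
  }
  ud(acc / length(uds), area, time = uds[[length(uds)]]$time)
}

#' Steady-state UD by power iteration
#'
#' Iterates `u <- P u` until the L1 fixed-point residual `||P u - u||_1`
#' falls below `tol`. Requires a static (time-invariant) transition
#' matrix: no steady state can exist for a kernel that changes over time.
#' Non-convergence (e.g. oscillatory long-time behaviour) is a
#' first-class result: the best iterate is returned with
#' `converged = FALSE` rather than an error.
#'
#' @param P a static [build_transition_matrix()] result.
#' @param tol L1 residual tolerance (default 1e-10).
#' @param max_iter iteration cap (default 1e6).
#' @param u_init optional starting [ud()]; defaults to uniform over
#'   admissible cells.
#' @return An object of class `steady_state`: a list with fields `ud`,
#'   `converged`, `iterations`, `residual`, `method`.
#' @export
steady_state_fixed_point <- function(P, tol = 1e-10, max_iter = 1e6,
                                     u_init = NULL) {
  stopifnot(inherits(P, "transition_matrix"))
  v <- if (is.null(u_init)) {
    rep(1 / length(P$cells), length(P$cells))
  } else ud_to_state(u_init, P)
  res <- Inf
  it <- 0L
  while (it < max_iter) {
    v_new <- as.numeric(P$P %*% v)
    v_new <- v_new / sum(v_new)
    res <- sum(abs(v_new - v))
    v <- v_new
    it <- it + 1L
    if (res < tol) break
  }
  structure(
    list(ud = state_to_ud(v, P), converged = res < tol, iterations = it,
         residual = res, method = "power"),
    class = "steady_state"
  )
}

#' Steady-state UD by eigen decomposition
#'
#' Solves the fixed-point equation directly as the leading eigenvector
#' (eigenvalue 1) of the dense transition matrix, normalised to sum 1.
#' Tiny negative entries (below 1e-12 in magnitude, numerical noise) are
#' clipped to zero and the vector renormalised. A degenerate eigenvalue 1
#' of multiplicity above one (disconnected chain) is reported with a
#' warning and the first eigenvector returned.
#'
#' @param P a static [build_transition_matrix()] result (dense; sparse
#'   input is densified).
#' @return An object of class `steady_state` (see
#'   [steady_state_fixed_point()]); `converged` is `TRUE`, `residual` is
#'   the achieved L1 fixed-point residual.
#' @export
steady_state_eigen <- function(P) {
  stopifnot(inherits(P, "transition_matrix"))
  M <- as.matrix(P$P)
  e <- eigen(M)
  lead <- which(abs(e$values - 1) < 1e-8)
  if (!length(lead)) lead <- which.max(Re(e$values))
  if (length(lead) > 1L)
    warning(sprintf(
      "eigenvalue 1 has multiplicity %d (disconnected chain?); returning the first eigenvector",
      length(lead)), call. = FALSE)
  v <- Re(e$vectors[, lead[1L]])
  if (sum(v) < 0) v <- -v
  if (any(v < -1e-12 * max(abs(v))))
    warning("leading eigenvector has substantial negative entries", call. = FALSE)
  v[v < 0] <- 0
  v <- v / sum(v)
  structure(
    list(ud = state_to_ud(v, P), converged = TRUE, iterations = NA_integer_,
         residual = sum(abs(as.numeric(M %*% v) - v)), method = "eigen"),
    class = "steady_state"
  )
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("<steady_state (%s): %s, residual %.3g%s>\n",
              x$method,
              if (x$converged) "converged" else "NOT converged (possible oscillation)",
              x$residual,
              if (is.finite(x$iterations %||% NA))
                sprintf(", %d iterations", x$iterations) else ""))
  invisible(x)
}
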