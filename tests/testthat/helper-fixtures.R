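# Shared fixtures and independent oracles, built in code at test time.

# Wrap a raw column-stochastic matrix as a transition_matrix on a 1 x n grid.
make_tm <- function(P) {
  n <- ncol(P)
  area <- stepscale::study_area(1, n)
  structure(list(P = P, area = area, cells = seq_len(n), time = 0),
            class = "transition_matrix")
}

# The classic 2-state chain [[1-p, q], [p, 1-q]] (columns are sources).
two_state_tm <- function(p, q) make_tm(matrix(c(1 - p, p, q, 1 - q), 2, 2))

# Brute-force enumeration oracle for a movement kernel on a small grid:
# loops over every cell, computes psi(|z - x|) * exp(beta . Z(z)) from first
# principles, and normalises. Independent of evaluate_kernel's internals.
brute_force_kernel <- function(x, lambda, beta, layer_matrix, cell_size = 1,
                               x_C = NULL, beta_C = 0) {
  nr <- nrow(layer_matrix); nc <- ncol(layer_matrix)
  w <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      cx <- (j - 0.5) * cell_size
      cy <- (i - 0.5) * cell_size
      l <- sqrt((cx - x[1])^2 + (cy - x[2])^2)
      bz <- beta * layer_matrix[i, j]
      if (!is.null(x_C))
        bz <- bz - beta_C * sqrt((cx - x_C[1])^2 + (cy - x_C[2])^2)
      w[i, j] <- exp(-lambda * l) * exp(bz)
    }
  }
  list(p = as.vector(w) / sum(w), K = sum(w) * cell_size^2)
}

# Column-major index of the cell of a raster containing point p (computed
# from the grid definition, independent of package internals).
cell_index_of <- function(r, p) {
  nr <- nrow(r$values)
  j <- floor((p[1] - r$origin[1]) / r$cell_size) + 1
  i <- floor((p[2] - r$origin[2]) / r$cell_size) + 1
  as.integer((j - 1) * nr + i)
}

# Column-major cell-mass vector -> raster layer on the area's grid.
vector_as_raster_test <- function(p, area) {
  stepscale::raster_layer(matrix(p, area$n_rows, area$n_cols),
                          cell_size = area$cell_size, origin = area$origin)
}

# A small smooth test landscape (deterministic).
small_resource <- function(n = 5, seed = 11, smoothness = 2) {
  stepscale::generate_resource_layer(n, n, smoothness = smoothness, seed = seed)
}
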