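#' Read an ESRI ASCII grid raster
#'
#' Parses the plain-text ESRI ASCII grid dialect: six header lines
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`,
#' the last optional) followed by `nrows` whitespace-separated rows of
#' values, top row first.
#'
#' @param path file path.
#' @param name layer label; defaults to the file name without extension.
#' @return A [raster_layer()].
#' @export
read_raster <- function(path, name = NULL) {
  if (!file.exists(path)) stopf("raster file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  hline <- 0L
  for (k in seq_along(lines)) {
    parts <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                   "cellsize", "nodata_value")) {
      if (length(parts) != 2L)
        stopf("malformed header at line %d: '%s'", k, lines[k])
      val <- suppressWarnings(as.numeric(parts[2]))
      if (is.na(val))
        stopf("malformed header at line %d: non-numeric value '%s'", k, parts[2])
      hdr[[key]] <- val
      hline <- k
    } else break
  }
  for (req in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[req]]))
      stopf("malformed header: missing '%s' (header ends at line %d)", req, hline)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  body <- lines[(hline + 1L):length(lines)]
  if (length(body) != nr)
    stopf("expected %d data rows, found %d (after header line %d)",
          nr, length(body), hline)
  vals <- matrix(NA_real_, nrow = nr, ncol = nc)
  for (r in seq_len(nr)) {
    row <- suppressWarnings(as.numeric(strsplit(trimws(body[r]), "\\s+")[[1]]))
    if (length(row) != nc || anyNA(row))
      stopf("row %d (line %d) has %d values, expected %d",
            r, hline + r, length(row), nc)
    vals[nr - r + 1L, ] <- row  # file is top-row-first; store bottom-first
  }
  if (!is.null(hdr$nodata_value) && any(vals == hdr$nodata_value))
    stopf("raster contains NODATA cells, which are not supported")
  raster_layer(vals, cell_size = hdr$cellsize,
               origin = c(hdr$xllcorner, hdr$yllcorner),
               name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a raster layer as an ESRI ASCII grid
#'
#' @param layer a [raster_layer()].
#' @param path output file path.
#' @param digits significant digits to print (default 17, round-trip safe).
#' @return `path`, invisibly.
#' @export
write_raster <- function(layer, path, digits = 17) {
  stopifnot(inherits(layer, "raster_layer"))
  nr <- nrow(layer$values); nc <- ncol(layer$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.17g", layer$origin[1]),
    sprintf("yllcorner %.17g", layer$origin[2]),
    sprintf("cellsize %.17g", layer$cell_size),
    "NODATA_value -9999"
  ), con)
  fmt <- paste0("%.", digits, "g")
  for (r in nr:1)  # top row first
    writeLines(paste(sprintf(fmt, layer$values[r, ]), collapse = " "), con)
  invisible(path)
}

#' Read animal trajectories from CSV
#'
#' Expects columns `id`, `t`, `x`, `y` and optionally `bearing`. Rows are
#' ordered by time within each individual; if `bearing` is absent it is
#' recomputed from consecutive fixes (radians clockwise from north, `NA`
#' for the first fix).
#'
#' @param path CSV file path.
#' @return A named list of `trajectory` data frames, one per individual.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stopf("trajectory file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "t", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("trajectory CSV is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df[c("id", "t")]))
    stopf("duplicate (id, t) pairs in trajectory file")
  out <- lapply(split(df, df$id), function(d) {
    d <- d[order(d$t), , drop = FALSE]
    trajectory(id = d$id[1], t = d$t, x = d$x, y = d$y,
               bearing = if ("bearing" %in% names(d)) d$bearing else NULL)
  })
  out[order(names(out))]
}

#' Write trajectories to CSV
#'
#' @param trajs a list of `trajectory` objects (or a single one).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  df <- do.call(rbind, lapply(trajs, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Construct a trajectory
#'
#' Time-ordered fixes for one individual. Bearings are radians clockwise
#' from north (so a step due north has bearing 0 and a step due east has
#' bearing pi/2); the first fix has bearing `NA`. When `bearing` is `NULL`
#' bearings are computed from consecutive fixes.
#'
#' @param id individual identifier.
#' @param t numeric times, strictly increasing.
#' @param x,y coordinates.
#' @param bearing optional bearings; recomputed when `NULL`.
#' @return A data frame of class `trajectory` with columns
#'   `id, t, x, y, bearing`.
#' @export
trajectory <- function(id, t, x, y, bearing = NULL) {
  n <- length(t)
  if (length(x) != n || length(y) != n)
    stopf("t, x, y must have equal length")
  if (n > 1 && any(diff(t) <= 0))
    stopf("times must be strictly increasing within an individual")
  if (is.null(bearing)) {
    bearing <- rep(NA_real_, n)
    if (n > 1) bearing[-1] <- step_bearing(diff(x), diff(y))
  }
  structure(
    data.frame(id = rep(id[1], n), t = t, x = x, y = y, bearing = bearing),
    class = c("trajectory", "data.frame")
  )
}

# Bearing of a displacement (dx, dy), radians clockwise from north in [0, 2*pi).
step_bearing <- function(dx, dy) {
  b <- atan2(dx, dy)
  ifelse(b < 0, b + 2 * pi, b)
}
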