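#' Grid specification for interpolation
#'
#' @param xmin,ymin lower-left corner of the lower-left cell.
#' @param cell cell size (same units as the sample coordinates).
#' @param n_rows,n_cols grid dimensions.
#' @return list of class `grid_spec`.
#' @export
grid_spec <- function(xmin, ymin, cell, n_rows, n_cols) {
  stopifnot(cell > 0, n_rows >= 1, n_cols >= 1)
  structure(list(xmin = xmin, ymin = ymin, cell = cell,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
            class = "grid_spec")
}

#' Grid covering a sample table
#'
#' @param samples a [sample_table()].
#' @param cell cell size.
#' @param pad margin added around the bounding box (default one cell).
#' @return a [grid_spec()].
#' @export
grid_over_samples <- function(samples, cell, pad = cell) {
  xr <- range(samples$x); yr <- range(samples$y)
  xmin <- xr[1] - pad; ymin <- yr[1] - pad
  n_cols <- max(1L, ceiling((xr[2] + pad - xmin) / cell))
  n_rows <- max(1L, ceiling((yr[2] + pad - ymin) / cell))
  grid_spec(xmin, ymin, cell, n_rows, n_cols)
}

#' Inverse distance weighted interpolation
#'
#' Interpolates one metal's concentrations onto a regular grid. Each cell
#' centre takes the weighted mean of the `max_neighbors` nearest sites,
#' with weights d^(-power) on Euclidean distance over the supplied planar
#' coordinates. A cell within 1e-9 of a site takes that site's value
#' exactly. IDW is convex: every interpolated value lies within the range
#' of the input values.
#'
#' @param samples a [sample_table()].
#' @param metal analyte (or reference element) column to interpolate.
#' @param grid a [grid_spec()] (default: [grid_over_samples()] with 50
#'   columns across the bounding box).
#' @param power positive IDW exponent, default 2.
#' @param max_neighbors number of nearest sites used per cell, default all.
#' @return object of class `grid_surface`: the `grid_spec` fields plus
#'   `values` (n_rows x n_cols matrix, row 1 = northernmost row, matching
#'   ESRI ASCII grid order), `metal`, `power`, `nodata` (-9999).
#' @export
idw_interpolate <- function(samples, metal, grid = NULL, power = 2,
                            max_neighbors = Inf) {
  stopifnot(nrow(samples) >= 1, power > 0, max_neighbors >= 1)
  if (!metal %in% names(samples))
    stop("idw_interpolate: no column '", metal, "' in samples")
  if (is.null(grid)) {
    span <- max(diff(range(samples$x)), diff(range(samples$y)), 1)
    grid <- grid_over_samples(samples, cell = span / 50)
  }
  z <- as.data.frame(samples)[[metal]]
  sx <- samples$x; sy <- samples$y
  nn <- min(max_neighbors, length(z))

  cx <- grid$xmin + (seq_len(grid$n_cols) - 0.5) * grid$cell
  ## row 1 is the top (north) row, ESRI ASCII convention
  cy <- grid$ymin + (grid$n_rows - seq_len(grid$n_rows) + 0.5) * grid$cell
  vals <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  for (i in seq_len(grid$n_rows)) {
    for (j in seq_len(grid$n_cols)) {
      d <- sqrt((sx - cx[j])^2 + (sy - cy[i])^2)
      hit <- which(d < 1e-9)
      if (length(hit)) { vals[i, j] <- z[hit[1]]; next }
      use <- order(d)[seq_len(nn)]
      w <- d[use]^(-power)
      vals[i, j] <- sum(w * z[use]) / sum(w)
    }
  }
  structure(c(unclass(grid),
              list(values = vals, metal = metal, power = power,
                   nodata = -9999)),
            class = "grid_surface")
}

#' Write a surface as an ESRI ASCII grid
#'
#' Plain-text `.asc` raster readable by any GIS; no spatial dependency is
#' required to produce it.
#'
#' @param surface a `grid_surface` ([idw_interpolate()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(surface, path) {
  stopifnot(inherits(surface, "grid_surface"))
  hdr <- c(sprintf("ncols %d", surface$n_cols),
           sprintf("nrows %d", surface$n_rows),
           sprintf("xllcorner %.10g", surface$xmin),
           sprintf("yllcorner %.10g", surface$ymin),
           sprintf("cellsize %.10g", surface$cell),
           sprintf("NODATA_value %d", surface$nodata))
  v <- surface$values
  v[is.na(v)] <- surface$nodata
  body <- apply(v, 1, function(r) paste(formatC(r, format = "g", digits = 10),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_ascii_grid()]
#'
#' @param path `.asc` file path.
#' @return a `grid_surface` (without `metal`/`power` metadata).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(i) as.numeric(strsplit(trimws(hdr[i]), "\\s+")[[1]][2])
  n_cols <- as.integer(val(1)); n_rows <- as.integer(val(2))
  g <- grid_spec(val(3), val(4), val(5), n_rows, n_cols)
  nodata <- val(6)
  vals <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  vals[vals == nodata] <- NA_real_
  structure(c(unclass(g), list(values = vals, metal = NA_character_,
                               power = NA_real_, nodata = nodata)),
            class = "grid_surface")
}
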