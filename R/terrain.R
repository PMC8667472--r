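#' Build a bare-earth digital terrain model
#'
#' Grids a pre-planting (bare-earth) point cloud into a regular raster whose
#' cell value is the minimum `z` of the points falling in the cell; the
#' minimum is robust to residual low vegetation and debris. Cells that
#' receive no point are filled from the nearest populated cell, so the
#' returned model has no gaps. The terrain is assumed constant through the
#' growing season: build it once and reuse it for every canopy epoch.
#'
#' @param bare_earth Point cloud tibble with at least one point.
#' @param cell_size Cell edge in meters (> 0). The 0.25 m default resolves
#'   typical ~0.76 m crop row spacing.
#' @return A `terrain_model` object: list with `origin` (xll, yll),
#'   `cell_size`, and an elevation matrix `grid` (rows = y from south,
#'   cols = x from west).
#' @export
build_dtm <- function(bare_earth, cell_size = 0.25) {
  bare_earth <- validate_point_cloud(bare_earth)
  if (nrow(bare_earth) == 0) stop("no terrain points", call. = FALSE)
  stopifnot(cell_size > 0)
  x0 <- min(bare_earth$x); y0 <- min(bare_earth$y)
  ncols <- max(1L, ceiling((max(bare_earth$x) - x0) / cell_size + 1e-9))
  nrows <- max(1L, ceiling((max(bare_earth$y) - y0) / cell_size + 1e-9))
  ci <- pmin(ncols, floor((bare_earth$x - x0) / cell_size) + 1L)
  ri <- pmin(nrows, floor((bare_earth$y - y0) / cell_size) + 1L)
  grid <- matrix(NA_real_, nrow = nrows, ncol = ncols)
  mins <- tapply(bare_earth$z, list((ci - 1L) * nrows + ri), min)
  grid[as.integer(names(mins))] <- mins
  grid <- fill_nearest(grid, cell_size)
  structure(list(origin = c(x = x0, y = y0), cell_size = cell_size,
                 grid = grid),
            class = "terrain_model")
}

# nearest-neighbour fill of NA cells from populated cell centres
fill_nearest <- function(grid, cell_size) {
  empty <- which(is.na(grid))
  if (length(empty) == 0) return(grid)
  full <- which(!is.na(grid))
  nr <- nrow(grid)
  centres <- function(idx) {
    cbind(((idx - 1L) %/% nr) + 0.5, ((idx - 1L) %% nr) + 0.5) * cell_size
  }
  nn <- FNN::get.knnx(centres(full), centres(empty), k = 1)
  grid[empty] <- grid[full[nn$nn.index[, 1]]]
  grid
}

#' @export
print.terrain_model <- function(x, ...) {
  cat(sprintf("<terrain_model> %d x %d cells of %.3g m, origin (%.3f, %.3f)\n",
              nrow(x$grid), ncol(x$grid), x$cell_size,
              x$origin[1], x$origin[2]))
  cat(sprintf("  elevation range: %.3f .. %.3f m\n",
              min(x$grid), max(x$grid)))
  invisible(x)
}

#' Look up terrain elevation under points
#'
#' Points outside the grid extent are clamped to the nearest cell rather
#' than erroring: plot polygons may slightly exceed the bare-earth flight
#' footprint.
#'
#' @param dtm A `terrain_model`.
#' @param x,y Coordinate vectors.
#' @return Elevations (m).
#' @export
dtm_elevation <- function(dtm, x, y) {
  ci <- floor((x - dtm$origin[1]) / dtm$cell_size) + 1L
  ri <- floor((y - dtm$origin[2]) / dtm$cell_size) + 1L
  ci <- pmin(pmax(ci, 1L), ncol(dtm$grid))
  ri <- pmin(pmax(ri, 1L), nrow(dtm$grid))
  dtm$grid[cbind(ri, ci)]
}

#' Normalize point heights against a terrain model and classify ground
#'
#' Height above terrain is `h = z - DTM(x, y)`. Points with `h` below
#' `ground_threshold` are classed `ground`; `h` at or above it (including
#' exactly the threshold) are `vegetation`. The 0.10 m default encodes the
#' convention that returns under 10 cm belong to the soil surface and are
#' excluded from vegetation statistics.
#'
#' @param cloud Point cloud tibble.
#' @param dtm A `terrain_model` from [build_dtm()].
#' @param ground_threshold Meters; class boundary (default 0.10).
#' @return The cloud with columns `h` (m) and `class`
#'   (`"ground"`/`"vegetation"`) appended — a *height cloud*.
#' @export
normalize_heights <- function(cloud, dtm, ground_threshold = 0.10) {
  cloud <- validate_point_cloud(cloud)
  stopifnot(inherits(dtm, "terrain_model"))
  h <- cloud$z - dtm_elevation(dtm, cloud$x, cloud$y)
  dplyr::mutate(cloud, h = h,
                class = ifelse(h < ground_threshold, "ground", "vegetation"))
}

#' Write a terrain model as an ESRI ASCII grid
#' @param dtm A `terrain_model`.
#' @param path Output path.
#' @param nodata NODATA marker written in the header.
#' @return `path`, invisibly.
#' @export
write_dtm_ascii <- function(dtm, path, nodata = -9999) {
  hdr <- c(sprintf("ncols %d", ncol(dtm$grid)),
           sprintf("nrows %d", nrow(dtm$grid)),
           sprintf("xllcorner %.10g", dtm$origin[1]),
           sprintf("yllcorner %.10g", dtm$origin[2]),
           sprintf("cellsize %.10g", dtm$cell_size),
           sprintf("NODATA_value %g", nodata))
  g <- dtm$grid
  g[is.na(g)] <- nodata
  # ESRI rasters are written north-to-south
  rows <- apply(g[rev(seq_len(nrow(g))), , drop = FALSE], 1,
                function(r) paste(format(r, digits = 10, trim = TRUE,
                                         scientific = FALSE), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid as a terrain model
#' @param path ASCII grid path.
#' @return A `terrain_model`.
#' @export
read_dtm_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- grep(paste0("^", key, "\\s"), hdr, ignore.case = TRUE, value = TRUE)
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  ncols <- as.integer(val("ncols")); nrows <- as.integer(val("nrows"))
  nodata <- val("NODATA_value")
  body <- as.numeric(unlist(strsplit(trimws(lines[-(1:6)]), "\\s+")))
  grid <- matrix(body, nrow = nrows, ncol = ncols, byrow = TRUE)
  grid <- grid[rev(seq_len(nrows)), , drop = FALSE]   # back to south-first
  grid[grid == nodata] <- NA_real_
  structure(list(origin = c(x = val("xllcorner"), y = val("yllcorner")),
                 cell_size = val("cellsize"), grid = grid),
            class = "terrain_model")
}
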