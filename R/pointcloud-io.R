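#' Construct a point cloud tibble
#'
#' A point cloud is an ordinary tibble with numeric columns `x`, `y`, `z`
#' (meters, shared projected frame) plus any extra per-point attributes,
#' which every downstream verb carries along opaquely. Coordinates are
#' treated as a local metric (ENU-like) frame; no CRS handling is done and
#' callers must pre-project their data.
#'
#' @param x,y,z Numeric coordinate vectors of equal length (meters).
#' @param ... Further equal-length per-point attribute vectors.
#' @return A tibble with class validated by [validate_point_cloud()].
#' @examples
#' point_cloud(x = c(0, 1), y = c(0, 0), z = c(0.1, 2))
#' @export
point_cloud <- function(x = numeric(), y = numeric(), z = numeric(), ...) {
  validate_point_cloud(tibble::tibble(x = as.numeric(x), y = as.numeric(y),
                                      z = as.numeric(z), ...))
}

#' Validate a point cloud tibble
#'
#' Checks that `x`, `y`, `z` exist, are numeric, of equal length, and finite.
#'
#' @param cloud A data frame with columns `x`, `y`, `z`.
#' @return The cloud as a tibble, invisibly validated.
#' @export
validate_point_cloud <- function(cloud) {
  stopifnot(is.data.frame(cloud))
  missing_cols <- setdiff(c("x", "y", "z"), names(cloud))
  if (length(missing_cols) > 0) {
    stop("point cloud lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (cc in c("x", "y", "z")) {
    if (!is.numeric(cloud[[cc]])) {
      stop("point cloud column '", cc, "' is not numeric", call. = FALSE)
    }
    if (anyNA(cloud[[cc]]) || any(!is.finite(cloud[[cc]]))) {
      stop("point cloud column '", cc, "' contains non-finite values",
           call. = FALSE)
    }
  }
  tibble::as_tibble(cloud)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         las = "las", laz = "las",
         ply = "ply",
         csv = "csv", xyz = "csv", txt = "csv",
         stop("cannot guess point-cloud format from extension '.", ext,
              "'; pass `format`", call. = FALSE))
}

#' Read a point cloud from LAS, CSV or ASCII PLY
#'
#' CSV files use the dialect `x,y,z[,...]` with an optional header row; a
#' headerless numeric file is accepted and its first three columns are named
#' `x`, `y`, `z`. LAS support covers the common LAS 1.x header with point
#' record formats 0-3 (only coordinates are decoded). PLY must be
#' `format ascii`.
#'
#' @param path File path.
#' @param format One of `"auto"` (extension-based), `"csv"`, `"las"`, `"ply"`.
#' @return A point cloud tibble (see [point_cloud()]); point order preserved.
#' @export
read_point_cloud <- function(path, format = c("auto", "csv", "las", "ply")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read point cloud: no such file '", path,
                               "'", call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  cloud <- switch(format,
                  csv = read_cloud_csv(path),
                  ply = read_cloud_ply(path),
                  las = read_cloud_las(path))
  validate_point_cloud(cloud)
}

#' Write a point cloud to LAS, CSV or ASCII PLY
#'
#' Round-trips through [read_point_cloud()] preserve coordinates exactly for
#' CSV/PLY (full double precision printed) and to within the LAS scale
#' quantum (1 mm by default) for LAS.
#'
#' @param cloud A point cloud tibble.
#' @param path Output path.
#' @param format One of `"auto"`, `"csv"`, `"las"`, `"ply"`.
#' @param las_scale Coordinate quantum used when writing LAS (meters).
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path,
                              format = c("auto", "csv", "las", "ply"),
                              las_scale = 0.001) {
  cloud <- validate_point_cloud(cloud)
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
         csv = write_cloud_csv(cloud, path),
         ply = write_cloud_ply(cloud, path),
         las = write_cloud_las(cloud, path, scale = las_scale))
  invisible(path)
}

read_cloud_csv <- function(path) {
  if (file.size(path) == 0) return(point_cloud())
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, ",", fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(fields))))
  df <- utils::read.csv(path, header = has_header,
                        stringsAsFactors = FALSE, strip.white = TRUE)
  if (nrow(df) == 0 && !has_header) return(point_cloud())
  if (!has_header) {
    if (ncol(df) < 3) stop("CSV point cloud needs >= 3 columns", call. = FALSE)
    names(df)[1:3] <- c("x", "y", "z")
  }
  for (cc in c("x", "y", "z")) {
    if (!cc %in% names(df)) stop("CSV lacks column '", cc, "'", call. = FALSE)
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("non-numeric '", cc, "' coordinate at data record ", bad,
           " of '", path, "'", call. = FALSE)
    }
    df[[cc]] <- v
  }
  tibble::as_tibble(df)
}

write_cloud_csv <- function(cloud, path) {
  utils::write.csv(as.data.frame(cloud), path, row.names = FALSE,
                   quote = FALSE)
}

read_cloud_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) return(point_cloud())
  if (lines[1] != "ply") stop("'", path, "' is not a PLY file", call. = FALSE)
  end <- match("end_header", lines)
  if (is.na(end)) stop("PLY header not terminated in '", path, "'",
                       call. = FALSE)
  header <- lines[seq_len(end)]
  if (!any(grepl("^format\\s+ascii", header))) {
    stop("only ascii PLY is supported ('", path, "')", call. = FALSE)
  }
  vline <- grep("^element\\s+vertex\\s+", header, value = TRUE)
  if (length(vline) != 1) stop("PLY without a vertex element", call. = FALSE)
  n <- as.integer(sub("^element\\s+vertex\\s+(\\d+).*$", "\\1", vline))
  props <- sub("^property\\s+\\S+\\s+", "",
               grep("^property\\s", header, value = TRUE))
  if (n == 0) return(point_cloud())
  body <- lines[(end + 1):(end + n)]
  mat <- matrix(suppressWarnings(
    as.numeric(unlist(strsplit(trimws(body), "\\s+")))),
    nrow = n, byrow = TRUE)
  if (anyNA(mat)) {
    bad <- which(apply(is.na(mat), 1, any))[1]
    stop("non-numeric coordinate at PLY vertex ", bad, " of '", path, "'",
         call. = FALSE)
  }
  colnames(mat) <- props[seq_len(ncol(mat))]
  df <- tibble::as_tibble(as.data.frame(mat))
  validate_point_cloud(df)
}

write_cloud_ply <- function(cloud, path) {
  num_cols <- names(cloud)[vapply(cloud, is.numeric, logical(1))]
  num_cols <- union(c("x", "y", "z"), num_cols)
  header <- c("ply", "format ascii 1.0",
              sprintf("element vertex %d", nrow(cloud)),
              sprintf("property double %s", num_cols),
              "end_header")
  body <- do.call(paste, c(lapply(num_cols, function(cc) {
    format(cloud[[cc]], digits = 17, scientific = FALSE, trim = TRUE)
  }), sep = " "))
  writeLines(c(header, if (nrow(cloud) > 0) body), path)
}

# --- minimal LAS 1.2, point data record format 0 -------------------------
# No LAS reader ships with the installed stack, so the subset of the format
# the pipeline needs (header + scaled int32 XYZ) is decoded directly.

read_cloud_las <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 4, useBytes = TRUE)
  if (!identical(sig, "LASF")) stop("'", path, "' is not a LAS file",
                                    call. = FALSE)
  seek(con, 96)
  offset_to_points <- readBin(con, "integer", 1, size = 4)
  seek(con, 104)
  pdrf <- readBin(con, "integer", 1, size = 1, signed = FALSE)
  rec_len <- readBin(con, "integer", 1, size = 2, signed = FALSE)
  n <- readBin(con, "integer", 1, size = 4)
  if (!pdrf %in% 0:3) stop("unsupported LAS point format ", pdrf,
                           call. = FALSE)
  seek(con, 131)
  scales <- readBin(con, "double", 3)
  offsets <- readBin(con, "double", 3)
  if (n == 0) return(point_cloud())
  seek(con, offset_to_points)
  block <- readBin(con, "raw", n * rec_len)
  bytes <- matrix(block, nrow = rec_len)
  decode_i32 <- function(rows) {
    readBin(as.vector(bytes[rows, , drop = FALSE]), "integer", n, size = 4)
  }
  point_cloud(x = decode_i32(1:4) * scales[1] + offsets[1],
              y = decode_i32(5:8) * scales[2] + offsets[2],
              z = decode_i32(9:12) * scales[3] + offsets[3])
}

write_cloud_las <- function(cloud, path, scale = 0.001) {
  n <- nrow(cloud)
  offsets <- if (n > 0) vapply(cloud[c("x", "y", "z")], min, 0) else c(0, 0, 0)
  maxs <- if (n > 0) vapply(cloud[c("x", "y", "z")], max, 0) else c(0, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("LASF", con, eos = NULL)                   # signature
  writeBin(rep(0L, 2), con, size = 2)                  # source id, encoding
  writeBin(raw(16), con)                               # project GUID
  writeBin(c(1L, 2L), con, size = 1)                   # version 1.2
  writeChar(strrep(" ", 64), con, eos = NULL)          # system id + software
  writeBin(c(1L, 2026L), con, size = 2)                # file day/year
  writeBin(227L, con, size = 2)                        # header size
  writeBin(227L, con, size = 4)                        # offset to point data
  writeBin(0L, con, size = 4)                          # number of VLRs
  writeBin(0L, con, size = 1)                          # point format 0
  writeBin(20L, con, size = 2)                         # record length
  writeBin(n, con, size = 4)                           # number of points
  writeBin(c(n, 0L, 0L, 0L, 0L), con, size = 4)        # points by return
  writeBin(rep(scale, 3), con)                         # xyz scale
  writeBin(as.numeric(offsets), con)                   # xyz offset
  writeBin(as.numeric(c(maxs[1], offsets[1], maxs[2], offsets[2],
                        maxs[3], offsets[3])), con)    # min/max per axis
  if (n > 0) {
    q <- function(v, i) as.integer(round((v - offsets[i]) / scale))
    xb <- matrix(writeBin(q(cloud$x, 1), raw()), nrow = 4)
    yb <- matrix(writeBin(q(cloud$y, 2), raw()), nrow = 4)
    zb <- matrix(writeBin(q(cloud$z, 3), raw()), nrow = 4)
    pad <- matrix(as.raw(0), nrow = 8, ncol = n)
    writeBin(as.vector(rbind(xb, yb, zb, pad)), con)
  }
  invisible(path)
}

# --- regions --------------------------------------------------------------

#' Construct a region-of-interest table
#'
#' Regions delimit one analysis unit each (a plot or two-row block). They
#' are stored as a tibble with one row per region and a list-column
#' `polygon` holding an n x 2 matrix of ring vertices (meters, same frame
#' as the point clouds).
#'
#' @param region_id Character id.
#' @param polygon An n x 2 numeric matrix (closed or open ring; simple,
#'   positive area).
#' @param genotype,plot,rows,date,platform Optional metadata.
#' @param replicate Replicate index, 1 or 2.
#' @param das Days after sowing.
#' @return A one-row tibble; bind rows to build a region set.
#' @export
region_of_interest <- function(region_id, polygon, genotype = NA_character_,
                               replicate = 1L, plot = NA_character_,
                               rows = NA_character_, date = NA_character_,
                               das = NA_real_, platform = NA_character_) {
  polygon <- as.matrix(polygon)
  stopifnot(ncol(polygon) == 2, is.numeric(polygon))
  polygon <- close_ring(polygon)
  if (nrow(polygon) < 4 || abs(ring_area(polygon)) <= 0) {
    stop("region '", region_id, "': polygon is degenerate (zero area)",
         call. = FALSE)
  }
  if (ring_self_intersects(polygon)) {
    stop("region '", region_id, "': polygon is self-intersecting",
         call. = FALSE)
  }
  if (!replicate %in% c(1L, 2L)) {
    stop("replicate index must be 1 or 2", call. = FALSE)
  }
  tibble::tibble(region_id = as.character(region_id),
                 polygon = list(polygon),
                 genotype = genotype, replicate = as.integer(replicate),
                 plot = plot, rows = rows, date = date,
                 das = as.numeric(das), platform = platform)
}

close_ring <- function(polygon) {
  if (!all(polygon[1, ] == polygon[nrow(polygon), ])) {
    polygon <- rbind(polygon, polygon[1, ])
  }
  polygon
}

# signed shoelace area of a closed ring
ring_area <- function(ring) {
  n <- nrow(ring)
  i <- seq_len(n - 1)
  sum(ring[i, 1] * ring[i + 1, 2] - ring[i + 1, 1] * ring[i, 2]) / 2
}

ring_self_intersects <- function(ring) {
  seg <- cbind(ring[-nrow(ring), , drop = FALSE], ring[-1, , drop = FALSE])
  m <- nrow(seg)
  if (m < 4) return(FALSE)
  cross2 <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  for (i in seq_len(m - 2)) {
    js <- (i + 2):m
    js <- js[!(i == 1 & js == m)]   # first and last segment share a vertex
    for (j in js) {
      d1 <- cross2(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d2 <- cross2(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      d3 <- cross2(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d4 <- cross2(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      if (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
          ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Read regions from a GeoJSON FeatureCollection
#'
#' Each feature must be a `Polygon` with properties
#' `region_id, genotype, replicate, plot, rows, date, das, platform`
#' (missing properties become `NA`).
#'
#' @param path GeoJSON file path.
#' @return A region tibble (one row per feature).
#' @export
read_regions <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("'", path, "' is not a FeatureCollection",
                                 call. = FALSE)
  purrr::map_dfr(gj$features, function(f) {
    if (!identical(f$geometry$type, "Polygon")) {
      stop("only Polygon features are supported", call. = FALSE)
    }
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    p <- f$properties
    pick <- function(key, default) if (is.null(p[[key]])) default else p[[key]]
    region_of_interest(
      region_id = pick("region_id", NA_character_),
      polygon = ring,
      genotype = pick("genotype", NA_character_),
      replicate = as.integer(pick("replicate", 1L)),
      plot = as.character(pick("plot", NA_character_)),
      rows = as.character(pick("rows", NA_character_)),
      date = as.character(pick("date", NA_character_)),
      das = as.numeric(pick("das", NA_real_)),
      platform = as.character(pick("platform", NA_character_)))
  })
}

#' Write a region tibble to GeoJSON
#'
#' @param regions Region tibble as built by [region_of_interest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  features <- purrr::pmap(regions, function(region_id, polygon, genotype,
                                            replicate, plot, rows, date, das,
                                            platform, ...) {
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(polygon)),
                                                   function(i) polygon[i, ]))),
         properties = list(region_id = region_id, genotype = genotype,
                           replicate = replicate, plot = plot, rows = rows,
                           date = date, das = das, platform = platform))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' Clip a point cloud to one region
#'
#' Keeps exactly the points whose (x, y) falls inside or on the boundary of
#' the region polygon. Boundary points are included: the inclusive test is
#' deterministic and conservative for narrow two-row blocks whose edges may
#' graze plant crowns.
#'
#' @param cloud Point cloud tibble.
#' @param roi A one-row region tibble (or a list with a `polygon` matrix).
#' @return The retained points, order preserved; idempotent.
#' @export
clip_to_region <- function(cloud, roi) {
  cloud <- validate_point_cloud(cloud)
  ring <- if (is.data.frame(roi)) roi$polygon[[1]] else roi$polygon
  ring <- close_ring(as.matrix(ring))
  if (abs(ring_area(ring)) <= 0) {
    stop("cannot clip: region polygon has zero area", call. = FALSE)
  }
  if (nrow(cloud) == 0) return(cloud)
  status <- sp::point.in.polygon(cloud$x, cloud$y, ring[, 1], ring[, 2])
  cloud[status > 0, , drop = FALSE]
}
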