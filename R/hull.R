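# Convex-hull primitives.
#
# The canopy-volume feature needs the volume of the 3D convex hull of the
# vegetation points, and cluster areas need 2D hull areas. The 2D case uses
# grDevices::chull plus the shoelace formula. The 3D hull is computed by an
# incremental (beneath-beyond) algorithm written here: visibility tests are
# vectorized over faces, the horizon is rebuilt per inserted point, and the
# volume is accumulated as signed tetrahedra against an interior point.

#' Area of the 2D convex hull of a point set
#'
#' @param xy An n x 2 numeric matrix. Fewer than 3 distinct, non-collinear
#'   points give area 0.
#' @return Area in squared input units.
#' @export
convex_hull_area <- function(xy) {
  xy <- unique(as.matrix(xy))
  if (nrow(xy) < 3) return(0)
  idx <- grDevices::chull(xy[, 1], xy[, 2])
  if (length(idx) < 3) return(0)
  abs(ring_area(close_ring(xy[idx, , drop = FALSE])))
}

#' Volume of the 3D convex hull of a point set
#'
#' Degenerate inputs (fewer than 4 points, or all points collinear or
#' coplanar at the numerical tolerance) return 0 with a warning rather than
#' erroring, so flat early-season canopies do not abort feature extraction.
#'
#' @param pts An n x 3 numeric matrix (or data frame with x, y, z columns).
#' @return Volume in cubic input units.
#' @export
convex_hull_volume <- function(pts) {
  if (is.data.frame(pts)) pts <- as.matrix(pts[, c("x", "y", "z")])
  pts <- unique(as.matrix(pts))
  storage.mode(pts) <- "double"
  if (nrow(pts) < 4) {
    warning("fewer than 4 distinct points: hull volume is 0", call. = FALSE)
    return(0)
  }
  scale <- max(apply(pts, 2, function(v) diff(range(v))), 1e-12)
  eps <- 1e-9 * scale

  simplex <- initial_simplex(pts, eps)
  if (is.null(simplex)) {
    warning("points are collinear or coplanar: hull volume is 0",
            call. = FALSE)
    return(0)
  }
  interior <- colMeans(pts[simplex, , drop = FALSE])

  faces <- rbind(simplex[c(1, 2, 3)], simplex[c(1, 2, 4)],
                 simplex[c(1, 3, 4)], simplex[c(2, 3, 4)])
  faces <- orient_outward(faces, pts, interior)
  geom <- face_planes(faces, pts)

  for (p in setdiff(seq_len(nrow(pts)), simplex)) {
    dist <- geom$normals %*% pts[p, ] - geom$offsets
    visible <- which(dist > eps)
    if (length(visible) == 0) next
    vis_faces <- faces[visible, , drop = FALSE]
    edges <- rbind(vis_faces[, c(1, 2), drop = FALSE],
                   vis_faces[, c(2, 3), drop = FALSE],
                   vis_faces[, c(3, 1), drop = FALSE])
    keys <- paste(edges[, 1], edges[, 2])
    rev_keys <- paste(edges[, 2], edges[, 1])
    # faces are wound consistently (outward), so a directed edge lies on
    # the horizon iff its reverse does not belong to a visible face
    horizon <- edges[!(rev_keys %in% keys), , drop = FALSE]
    new_faces <- orient_outward(cbind(horizon, p), pts, interior)
    faces <- rbind(faces[-visible, , drop = FALSE], new_faces)
    new_geom <- face_planes(new_faces, pts)
    geom$normals <- rbind(geom$normals[-visible, , drop = FALSE],
                          new_geom$normals)
    geom$offsets <- c(geom$offsets[-visible], new_geom$offsets)
  }

  # each outward-wound face forms a positive tetrahedron with the interior
  a <- pts[faces[, 1], , drop = FALSE] - rep(interior, each = nrow(faces))
  b <- pts[faces[, 2], , drop = FALSE] - rep(interior, each = nrow(faces))
  c3 <- pts[faces[, 3], , drop = FALSE] - rep(interior, each = nrow(faces))
  det3 <- a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
    a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
    a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  sum(abs(det3)) / 6
}

# swap vertex order where the winding normal points toward the interior
orient_outward <- function(faces, pts, interior) {
  g <- face_planes(faces, pts)
  inward <- as.vector(g$normals %*% interior) - g$offsets > 0
  faces[inward, 2:3] <- faces[inward, 3:2, drop = FALSE]
  faces
}

# four affinely independent points, or NULL when the set is degenerate
initial_simplex <- function(pts, eps) {
  i1 <- which.min(pts[, 1])
  d1 <- rowSums(sweep(pts, 2, pts[i1, ])^2)
  i2 <- which.max(d1)
  if (sqrt(d1[i2]) <= eps) return(NULL)
  u <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2, pts[i1, ])
  cr <- cbind(rel[, 2] * u[3] - rel[, 3] * u[2],
              rel[, 3] * u[1] - rel[, 1] * u[3],
              rel[, 1] * u[2] - rel[, 2] * u[1])
  d2 <- sqrt(rowSums(cr^2)) / sqrt(sum(u^2))
  i3 <- which.max(d2)
  if (d2[i3] <= eps) return(NULL)
  nrm <- crossprod3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  nrm <- nrm / sqrt(sum(nrm^2))
  d3 <- abs(rel %*% nrm)
  i4 <- which.max(d3)
  if (d3[i4] <= eps) return(NULL)
  c(i1, i2, i3, i4)
}

crossprod3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# unit normals (by vertex winding) and plane offsets for a face matrix
face_planes <- function(faces, pts) {
  a <- pts[faces[, 1], , drop = FALSE]
  u <- pts[faces[, 2], , drop = FALSE] - a
  v <- pts[faces[, 3], , drop = FALSE] - a
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  list(normals = n, offsets = rowSums(n * a))
}
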