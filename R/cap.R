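#' Horizontal slice of a height cloud at a height quantile
#'
#' The slice height is the `quantile` of the *vegetation* heights in the
#' region (ground returns are excluded from all vegetation statistics), and
#' the slice keeps the (x, y) projection of vegetation points whose height
#' is within `half_thickness` of it. The defaults — third quartile, +/- 4 cm
#' — target the upper canopy where row crops carry enough returns for a
#' stable cross-section; lower quartiles often hold too few points.
#'
#' @param hc Height cloud (see [normalize_heights()]).
#' @param quantile Height quantile in (0, 1); default 0.75.
#' @param half_thickness Slice half-thickness in meters; default 0.04.
#' @return A tibble with columns `x`, `y` (possibly 0 rows) and attribute
#'   `slice_height`.
#' @export
take_slice <- function(hc, quantile = 0.75, half_thickness = 0.04) {
  veg <- hc[hc$class == "vegetation", , drop = FALSE]
  if (nrow(veg) == 0) stop("no vegetation points to slice", call. = FALSE)
  slice_h <- unname(stats::quantile(veg$h, quantile, type = 7))
  keep <- abs(veg$h - slice_h) <= half_thickness
  out <- tibble::tibble(x = veg$x[keep], y = veg$y[keep])
  attr(out, "slice_height") <- slice_h
  out
}

#' Region-growing clustering of a planar point set
#'
#' Builds the symmetrized k-nearest-neighbor graph restricted to `radius`:
#' points i and j are linked when j is among i's k nearest neighbors with
#' `dist(i, j) <= radius`, or vice versa. Clusters are the connected
#' components of that graph — the fixed point of iteratively joining
#' clusters that share points, found here by union-find over the neighbor
#' edges. With `k >= n - 1` the k-NN cap is vacuous and the clustering
#' equals the connected components of the plain radius graph.
#'
#' @param pts A tibble/matrix of `x`, `y` coordinates.
#' @param radius Neighbor radius in meters (> 0).
#' @param k Neighbors considered per point (>= 1).
#' @return Integer cluster labels (1-based, in order of first appearance);
#'   `integer(0)` for empty input.
#' @export
region_grow_clusters <- function(pts, radius = 0.10, k = 10) {
  stopifnot(radius > 0, k >= 1)
  xy <- as.matrix(as.data.frame(pts)[, c("x", "y")])
  n <- nrow(xy)
  if (n == 0) return(integer(0))
  if (n == 1) return(1L)
  kk <- min(k, n - 1)
  nn <- FNN::get.knn(xy, k = kk)
  from <- rep(seq_len(n), kk)
  to <- as.vector(nn$nn.index)
  ok <- as.vector(nn$nn.dist) <= radius
  labels_from_edges(n, from[ok], to[ok])
}

# union-find over undirected edges; labels renumbered by first appearance
labels_from_edges <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(from)) {
    a <- find(from[e]); b <- find(to[e])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Convex-hull area of one cluster
#'
#' The cluster footprint is measured as the area of the 2D convex hull of
#' its member points; clusters with fewer than 3 non-collinear points have
#' area 0.
#'
#' @param cluster_pts Tibble/matrix of the cluster's `x`, `y` points.
#' @return Area in m^2.
#' @export
cluster_area <- function(cluster_pts) {
  xy <- as.matrix(as.data.frame(cluster_pts)[, c("x", "y")])
  if (nrow(xy) == 0) stop("empty cluster", call. = FALSE)
  convex_hull_area(xy)
}

#' Clusters' Area Plane (CAP) feature
#'
#' Slices the canopy at a height quantile, clusters the slice by
#' region growing, measures each cluster's convex-hull area `A_i`, and sums
#' the areas exceeding the area threshold: `CAP = sum(A_i : A_i >
#' area_threshold)`. An empty slice yields `CAP = 0`. CAP summarizes the
#' horizontal distribution of canopy material at the slice height; it is
#' non-increasing in the area threshold.
#'
#' @param hc Height cloud clipped to one region.
#' @param config Settings from [feature_config()]; the relevant entries are
#'   `cap_quantile`, `cap_half_thickness`, `cap_radius`, `cap_k`,
#'   `cap_area_threshold`.
#' @return CAP in m^2.
#' @export
cap_feature <- function(hc, config = feature_config()) {
  if (!any(hc$class == "vegetation")) return(0)
  slc <- take_slice(hc, quantile = config$cap_quantile,
                    half_thickness = config$cap_half_thickness)
  sum(cap_cluster_table(slc, config)$kept_area)
}

#' Per-cluster diagnostics for a CAP slice
#'
#' Returns one row per cluster with its size, hull area, and the area
#' actually counted into CAP (0 when below the threshold) — the table
#' behind cross-section diagnostic plots.
#'
#' @param slice Slice tibble from [take_slice()].
#' @param config Settings from [feature_config()].
#' @return Tibble `label, n_points, area, kept_area`.
#' @export
cap_cluster_table <- function(slice, config = feature_config()) {
  if (nrow(slice) == 0) {
    return(tibble::tibble(label = integer(0), n_points = integer(0),
                          area = numeric(0), kept_area = numeric(0)))
  }
  labels <- region_grow_clusters(slice, radius = config$cap_radius,
                                 k = config$cap_k)
  idx_by_label <- split(seq_along(labels), labels)
  out <- tibble::tibble(
    label = as.integer(names(idx_by_label)),
    n_points = lengths(idx_by_label),
    area = vapply(idx_by_label, function(i) {
      cluster_area(cbind(x = slice$x[i], y = slice$y[i]))
    }, numeric(1)))
  out$kept_area <- ifelse(out$area > config$cap_area_threshold, out$area, 0)
  out
}
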