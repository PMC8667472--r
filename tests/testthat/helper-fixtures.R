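# Shared fixture builders and independent oracles. Everything is generated
# in code; no binary fixtures.

# a height cloud built directly (bypasses DTM machinery) from given heights
make_height_cloud <- function(h, x = NULL, y = NULL,
                              ground_threshold = 0.10) {
  n <- length(h)
  tibble::tibble(
    x = if (is.null(x)) seq_len(n) * 0.01 else x,
    y = if (is.null(y)) rep(0, n) else y,
    z = h, h = h,
    class = ifelse(h < ground_threshold, "ground", "vegetation"))
}

unit_square_roi <- function() {
  region_of_interest("sq", rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
}

# independent even-odd ray-casting point-in-polygon test (boundary handled
# separately by explicit on-segment checks)
oracle_in_polygon <- function(px, py, ring) {
  n <- nrow(ring) - 1
  on_boundary <- function(x, y) {
    for (i in seq_len(n)) {
      x1 <- ring[i, 1]; y1 <- ring[i, 2]
      x2 <- ring[i + 1, 1]; y2 <- ring[i + 1, 2]
      cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      if (abs(cross) < 1e-12 &&
          x >= min(x1, x2) - 1e-12 && x <= max(x1, x2) + 1e-12 &&
          y >= min(y1, y2) - 1e-12 && y <= max(y1, y2) + 1e-12) return(TRUE)
    }
    FALSE
  }
  vapply(seq_along(px), function(j) {
    x <- px[j]; y <- py[j]
    if (on_boundary(x, y)) return(TRUE)
    inside <- FALSE
    for (i in seq_len(n)) {
      y1 <- ring[i, 2]; y2 <- ring[i + 1, 2]
      if ((y1 > y) != (y2 > y)) {
        xint <- ring[i, 1] + (y - y1) / (y2 - y1) *
          (ring[i + 1, 1] - ring[i, 1])
        if (x < xint) inside <- !inside
      }
    }
    inside
  }, logical(1))
}

# brute-force connected components of the radius graph (the clustering
# oracle): igraph over all pairs with dist <= radius
oracle_radius_components <- function(xy, radius) {
  n <- nrow(xy)
  d <- as.matrix(stats::dist(xy))
  adj <- (d <= radius) & upper.tri(d)
  edges <- which(adj, arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(cbind(edges[, 1], edges[, 2]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::components(g)$membership
}

# canonical form of a partition labeling, for label-agnostic comparison
canon_labels <- function(labels) match(labels, unique(labels))

# a tabular synthetic dataset for the regression modules: 8 feature columns
# drawn to mimic canopy features, with a caller-chosen target
make_feature_dataset <- function(n_varieties = 40, n_replicates = 2,
                                 seed = 1,
                                 target = function(f) 3 * f$lpi,
                                 noise_sd = 0) {
  withr::with_seed(seed, {
    v <- rep(seq_len(n_varieties), each = n_replicates)
    n <- length(v)
    lai <- rep(runif(n_varieties, 0.5, 6), each = n_replicates)
    f <- tibble::tibble(
      region_id = sprintf("r%03d", seq_len(n)),
      genotype = sprintf("V%03d", v),
      replicate = rep(seq_len(n_replicates), n_varieties),
      lpi = exp(-0.5 * lai) + rnorm(n, 0, 0.01),
      h_mean = 0.3 + 0.25 * lai + rnorm(n, 0, 0.05),
      h_std = numeric(n), h_skew = rnorm(n, 0, 0.3),
      h_q3 = numeric(n), vci = plogis(rnorm(n, 1, 0.5)),
      hull_volume = numeric(n), cap = numeric(n))
    f$h_std <- 0.3 * f$h_mean + rnorm(n, 0, 0.02)
    f$h_q3 <- f$h_mean + 1.1 * f$h_std + rnorm(n, 0, 0.02)
    f$hull_volume <- 2 + 1.5 * f$h_mean + rnorm(n, 0, 0.1)
    f$cap <- 0.5 + 0.1 * lai + rnorm(n, 0, 0.05)
    f$lai_eff <- target(f) + rnorm(n, 0, noise_sd)
    f
  })
}

# small fast SVR grid used where dozens of grid-searched refits are looped
small_svr_grid <- function() {
  expand.grid(cost = c(1, 10), gamma = 1 / 8, epsilon = 0.1, degree = 3)
}
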