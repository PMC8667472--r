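test_that("slicing selects vegetation points around the height quantile", {
  # constant heights: the quantile is that height, slice keeps everything
  hc <- make_height_cloud(rep(2, 20))
  slc <- take_slice(hc)
  expect_equal(nrow(slc), 20)
  expect_equal(attr(slc, "slice_height"), 2)

  # uniform heights on [0.1, 2.1]: slice of +/- 0.04 m captures ~4%
  set.seed(1)
  h <- runif(20000, 0.1, 2.1)
  slc2 <- take_slice(make_height_cloud(h, x = runif(20000),
                                       y = runif(20000)))
  frac <- nrow(slc2) / sum(h >= 0.1)
  expect_equal(frac, 0.04, tolerance = 0.25)
  expect_equal(attr(slc2, "slice_height"),
               unname(quantile(h[h >= 0.1], 0.75)), tolerance = 0.05)

  expect_error(take_slice(make_height_cloud(rep(0.01, 5))),
               "no vegetation")
})

test_that("well-separated groups cluster apart; singletons survive", {
  set.seed(2)
  g1 <- cbind(runif(10, 0, 0.01), runif(10, 0, 0.01))
  g2 <- cbind(runif(10, 1, 1.01), runif(10, 1, 1.01))
  pts <- tibble::tibble(x = c(g1[, 1], g2[, 1]), y = c(g1[, 2], g2[, 2]))
  labels <- region_grow_clusters(pts, radius = 0.05, k = 5)
  expect_equal(length(unique(labels)), 2)
  expect_equal(length(unique(labels[1:10])), 1)
  expect_equal(length(unique(labels[11:20])), 1)

  expect_equal(region_grow_clusters(tibble::tibble(x = 1, y = 1)), 1L)
  expect_equal(region_grow_clusters(tibble::tibble(x = numeric(0),
                                                   y = numeric(0))),
               integer(0))
})

test_that("with k >= n-1 clustering equals radius-graph components", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(20:200, 1)
    xy <- cbind(runif(n), runif(n))
    radius <- runif(1, 0.03, 0.2)
    got <- region_grow_clusters(tibble::tibble(x = xy[, 1], y = xy[, 2]),
                                radius = radius, k = n - 1)
    want <- oracle_radius_components(xy, radius)
    expect_equal(canon_labels(got), canon_labels(want))
  }
})

test_that("the k-NN cap can split what the radius graph would join", {
  # four collinear points; with k = 1 each point only reaches its single
  # nearest neighbour, giving two pairs despite a generous radius
  pts <- tibble::tibble(x = c(0, 0.05, 0.11, 0.16), y = rep(0, 4))
  labels <- region_grow_clusters(pts, radius = 1, k = 1)
  expect_equal(canon_labels(labels), c(1, 1, 2, 2))
  # with k = 3 the same points form one chain-connected cluster
  labels3 <- region_grow_clusters(pts, radius = 1, k = 3)
  expect_equal(length(unique(labels3)), 1)
})

test_that("clustering is invariant to ordering and rigid motions", {
  set.seed(4)
  n <- 120
  xy <- cbind(runif(n, 0, 2), runif(n, 0, 2))
  pts <- tibble::tibble(x = xy[, 1], y = xy[, 2])
  base <- canon_labels(region_grow_clusters(pts, radius = 0.15, k = 6))

  perm <- sample(n)
  shuffled <- region_grow_clusters(pts[perm, ], radius = 0.15, k = 6)
  # map the permuted labeling back onto original point indices
  back <- integer(n); back[perm] <- shuffled
  expect_equal(canon_labels(back), base)

  th <- 0.7
  rot <- tibble::tibble(x = cos(th) * pts$x - sin(th) * pts$y + 5,
                        y = sin(th) * pts$x + cos(th) * pts$y - 3)
  expect_equal(canon_labels(region_grow_clusters(rot, radius = 0.15, k = 6)),
               base)
})

test_that("cluster areas are hull areas with degenerate conventions", {
  square <- tibble::tibble(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  expect_equal(cluster_area(square), 1)
  expect_equal(cluster_area(tibble::tibble(x = c(0, 1), y = c(0, 1))), 0)
  expect_error(cluster_area(tibble::tibble(x = numeric(0),
                                           y = numeric(0))), "empty")
})

test_that("CAP sums areas above the threshold and respects its limits", {
  cfg <- feature_config(cap_radius = 0.3, cap_k = 10)
  # one square cluster of unit area at a single height
  sq <- expand.grid(x = seq(0, 1, 0.2), y = seq(0, 1, 0.2))
  hc <- make_height_cloud(rep(1, nrow(sq)), x = sq$x, y = sq$y)
  cfg$cap_area_threshold <- 0.5
  expect_equal(cap_feature(hc, cfg), 1, tolerance = 1e-12)
  cfg$cap_area_threshold <- 1.5
  expect_equal(cap_feature(hc, cfg), 0)

  # two separated unit squares -> CAP = 2
  sq2 <- rbind(sq, data.frame(x = sq$x + 5, y = sq$y))
  hc2 <- make_height_cloud(rep(1, nrow(sq2)), x = sq2$x, y = sq2$y)
  cfg$cap_area_threshold <- 0.5
  expect_equal(cap_feature(hc2, cfg), 2, tolerance = 1e-12)

  # no vegetation at all -> empty slice -> CAP 0, not an error
  bare <- make_height_cloud(rep(0.01, 10))
  expect_equal(cap_feature(bare, cfg), 0)
})

test_that("CAP is non-increasing in the area threshold", {
  set.seed(5)
  hc <- make_height_cloud(rep(1, 300), x = runif(300, 0, 3),
                          y = runif(300, 0, 3))
  thresholds <- c(0, 0.01, 0.05, 0.2, 1)
  caps <- vapply(thresholds, function(t) {
    cap_feature(hc, feature_config(cap_area_threshold = t))
  }, numeric(1))
  expect_true(all(diff(caps) <= 1e-12))
  expect_gte(caps[1], caps[length(caps)])
})

test_that("cluster diagnostics table partitions the slice", {
  set.seed(6)
  hc <- make_height_cloud(rep(1, 100), x = runif(100), y = runif(100))
  slc <- take_slice(hc)
  tab <- cap_cluster_table(slc, feature_config())
  expect_equal(sum(tab$n_points), nrow(slc))
  expect_true(all(tab$kept_area %in% c(0, tab$area)))
})
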