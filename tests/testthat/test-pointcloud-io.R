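test_that("headerless xyz CSV parses with order preserved", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,0,0", "1,0,0", "0,1,2"), path)
  pc <- read_point_cloud(path, format = "csv")
  expect_equal(nrow(pc), 3)
  expect_equal(pc$z, c(0, 0, 2))
  expect_equal(pc$x, c(0, 1, 0))
})

test_that("empty CSV file yields an empty cloud", {
  path <- withr::local_tempfile(fileext = ".csv")
  file.create(path)
  pc <- read_point_cloud(path)
  expect_equal(nrow(pc), 0)
  expect_named(pc, c("x", "y", "z"))
})

test_that("CSV with header keeps extra attribute columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,z,intensity", "1,2,3,40", "4,5,6,50"), path)
  pc <- read_point_cloud(path)
  expect_equal(pc$intensity, c(40, 50))
})

test_that("non-numeric coordinate reports the offending record", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,z", "1,2,3", "1,oops,3"), path)
  expect_error(read_point_cloud(path), "record 2")
  expect_error(read_point_cloud("/nonexistent/file.csv"), "no such file")
})

test_that("round-trips preserve coordinates across all three formats", {
  set.seed(42)
  pc <- point_cloud(x = runif(1000, 0, 50), y = runif(1000, 0, 50),
                    z = runif(1000, 95, 105))
  for (fmt in c("csv", "ply")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_point_cloud(pc, path)
    back <- read_point_cloud(path)
    expect_equal(back$x, pc$x, tolerance = 1e-12)
    expect_equal(back$z, pc$z, tolerance = 1e-12)
  }
  path <- withr::local_tempfile(fileext = ".las")
  write_point_cloud(pc, path)
  back <- read_point_cloud(path)
  # LAS quantizes to the scale quantum (1 mm)
  expect_lte(max(abs(back$x - pc$x)), 0.001 / 2 + 1e-9)
  expect_lte(max(abs(back$y - pc$y)), 0.001 / 2 + 1e-9)
  expect_lte(max(abs(back$z - pc$z)), 0.001 / 2 + 1e-9)
})

test_that("single-point and empty clouds round-trip in every format", {
  one <- point_cloud(1.5, 2.5, 3.5)
  none <- point_cloud()
  for (fmt in c("csv", "ply", "las")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_point_cloud(one, path)
    back <- read_point_cloud(path)
    expect_equal(nrow(back), 1)
    if (fmt != "las") expect_equal(back$z, 3.5)
    write_point_cloud(none, path)
    expect_equal(nrow(read_point_cloud(path)), 0)
  }
})

test_that("region GeoJSON round-trips geometry and metadata", {
  roi <- region_of_interest("p1", rbind(c(0, 0), c(2, 0), c(2, 3), c(0, 3)),
                            genotype = "V001", replicate = 2L, plot = "A",
                            rows = "2-3", date = "2020-07-20", das = 62,
                            platform = "uav")
  path <- withr::local_tempfile(fileext = ".geojson")
  write_regions(roi, path)
  back <- read_regions(path)
  expect_equal(back$region_id, "p1")
  expect_equal(back$genotype, "V001")
  expect_equal(back$replicate, 2L)
  expect_equal(back$das, 62)
  expect_equal(back$polygon[[1]], roi$polygon[[1]], ignore_attr = TRUE)
})

test_that("degenerate and self-intersecting polygons are rejected", {
  expect_error(region_of_interest("bad", rbind(c(0, 0), c(1, 1), c(2, 2))),
               "degenerate")
  bowtie <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 1.5))
  expect_error(region_of_interest("bow", bowtie), "self-intersecting")
  expect_error(region_of_interest("rep3", rbind(c(0, 0), c(1, 0), c(1, 1)),
                                  replicate = 3L), "replicate")
})

test_that("clipping keeps interior and boundary points only", {
  roi <- unit_square_roi()
  pc <- point_cloud(x = c(0.5, 2, 1.0, 0.0), y = c(0.5, 2, 0.5, 0.0),
                    z = c(1, 1, 1, 1))
  kept <- clip_to_region(pc, roi)
  expect_equal(nrow(kept), 3)           # interior + edge + vertex
  expect_true(all(kept$x %in% c(0.5, 1.0, 0.0)))
})

test_that("clipping matches a brute-force point-in-polygon oracle", {
  set.seed(7)
  pc <- point_cloud(x = runif(1000, 0, 2), y = runif(1000, 0, 2),
                    z = rep(0, 1000))
  roi <- unit_square_roi()
  kept <- clip_to_region(pc, roi)
  oracle <- oracle_in_polygon(pc$x, pc$y, roi$polygon[[1]])
  expect_equal(nrow(kept), sum(oracle))
  # convex non-rectangular region too
  tri <- region_of_interest("tri", rbind(c(0, 0), c(2, 0), c(1, 1.8)))
  kept_tri <- clip_to_region(pc, tri)
  oracle_tri <- oracle_in_polygon(pc$x, pc$y, tri$polygon[[1]])
  expect_equal(nrow(kept_tri), sum(oracle_tri))
})

test_that("clipping is a subset operation and idempotent", {
  set.seed(8)
  pc <- point_cloud(x = runif(300, -1, 3), y = runif(300, -1, 3),
                    z = runif(300))
  roi <- unit_square_roi()
  once <- clip_to_region(pc, roi)
  twice <- clip_to_region(once, roi)
  expect_true(nrow(once) <= nrow(pc))
  expect_equal(once, twice)
  degenerate <- list(polygon = rbind(c(0, 0), c(1, 1), c(0, 0)))
  expect_error(clip_to_region(pc, degenerate), "zero area")
})
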