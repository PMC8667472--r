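#' Laser penetration index
#'
#' Fraction of returns in a region that reached the ground:
#' `LPI = n_ground / (n_ground + n_vegetation)`. Under a Beer-Lambert
#' canopy, LPI estimates the gap fraction `exp(-G * LAI_eff)` at nadir, which
#' is what makes it the strongest single LAI predictor.
#'
#' @param n_ground,n_vegetation Non-negative point counts.
#' @return LPI in `[0, 1]`.
#' @export
lpi <- function(n_ground, n_vegetation) {
  stopifnot(n_ground >= 0, n_vegetation >= 0)
  total <- n_ground + n_vegetation
  if (total <= 0) stop("empty region: no points to form LPI", call. = FALSE)
  n_ground / total
}

#' Height distribution statistics of vegetation returns
#'
#' Sample mean, sample standard deviation (n-1), adjusted Fisher-Pearson
#' skewness, third quartile (linear-interpolation / type-7 percentile) and
#' coefficient of variation. A constant sample has undefined skewness, which
#' is reported as 0 by convention.
#'
#' @param veg_heights Numeric vector of vegetation heights (m), length >= 3.
#' @return A one-row tibble: `h_mean`, `h_std`, `h_skew`, `h_q3`, `h_cv`,
#'   `h_max`.
#' @export
height_statistics <- function(veg_heights) {
  if (length(veg_heights) < 3) {
    stop("need >= 3 vegetation points for height statistics", call. = FALSE)
  }
  m <- mean(veg_heights)
  s <- stats::sd(veg_heights)
  skew <- if (s == 0) 0 else e1071::skewness(veg_heights, type = 2)
  tibble::tibble(h_mean = m, h_std = s, h_skew = skew,
                 h_q3 = unname(stats::quantile(veg_heights, 0.75, type = 7)),
                 h_cv = if (m == 0) NA_real_ else s / m,
                 h_max = max(veg_heights))
}

#' Vertical complexity index
#'
#' Normalized Shannon entropy of the vertical point histogram:
#' `VCI = -sum(p_i * log(p_i)) / log(HB)` with `p_i` the proportional
#' abundance in height bin `i` and `HB` the number of bins, taking
#' `0 * log(0) = 0`. Bins of width `bin_width` span from the ground
#' threshold up to the maximum height. VCI is 1 for a vertically uniform
#' canopy and 0 when all returns concentrate in a single bin.
#'
#' @param veg_heights Vegetation heights (m), at least one point.
#' @param bin_width Bin width in meters (default 0.10).
#' @param ground_threshold Lower edge of the first bin (m).
#' @return VCI in `[0, 1]`.
#' @export
vci <- function(veg_heights, bin_width = 0.10, ground_threshold = 0.10) {
  stopifnot(length(veg_heights) >= 1, bin_width > 0)
  hb <- max(1L, ceiling((max(veg_heights) - ground_threshold) / bin_width))
  if (hb < 2) {
    stop("insufficient vertical extent for VCI (fewer than 2 height bins)",
         call. = FALSE)
  }
  bin <- pmin(hb, pmax(1L, floor((veg_heights - ground_threshold) /
                                   bin_width) + 1L))
  p <- tabulate(bin, nbins = hb) / length(veg_heights)
  p <- p[p > 0]
  -sum(p * log(p)) / log(hb)
}

#' Convex-hull volume of the vegetation points in a region
#'
#' Wraps [convex_hull_volume()] for a height cloud: uses the (x, y, h)
#' coordinates of vegetation-classed points, i.e. the canopy envelope above
#' the terrain.
#'
#' @param hc Height cloud (see [normalize_heights()]).
#' @return Volume in cubic meters.
#' @export
hull_volume <- function(hc) {
  veg <- hc[hc$class == "vegetation", , drop = FALSE]
  if (nrow(veg) < 4) {
    warning("fewer than 4 vegetation points: hull volume is 0", call. = FALSE)
    return(0)
  }
  convex_hull_volume(cbind(veg$x, veg$y, veg$h))
}

#' Default feature-extraction configuration
#'
#' @param ground_threshold Ground/vegetation class boundary (m).
#' @param vci_bin_width VCI histogram bin width (m).
#' @param cap_quantile Height quantile of the CAP slice (fraction).
#' @param cap_half_thickness Slice half-thickness (m).
#' @param cap_radius Neighbor radius of the region-growing clustering (m).
#' @param cap_k Neighbors per point in the clustering.
#' @param cap_area_threshold Minimum cluster area counted into CAP (m^2).
#' @return A named list of settings.
#' @export
feature_config <- function(ground_threshold = 0.10, vci_bin_width = 0.10,
                           cap_quantile = 0.75, cap_half_thickness = 0.04,
                           cap_radius = 0.10, cap_k = 10,
                           cap_area_threshold = 0.01) {
  list(ground_threshold = ground_threshold, vci_bin_width = vci_bin_width,
       cap_quantile = cap_quantile, cap_half_thickness = cap_half_thickness,
       cap_radius = cap_radius, cap_k = cap_k,
       cap_area_threshold = cap_area_threshold)
}

#' Extract the per-region canopy feature record
#'
#' Computes the eight model features (`lpi`, `h_mean`, `h_std`, `h_skew`,
#' `h_q3`, `vci`, `hull_volume`, `cap`) plus the reported extras `h_cv` and
#' `h_max` from a height cloud already clipped to one region. Regions with
#' no points, or with too few vegetation points for the height statistics,
#' are flagged `missing = TRUE` with `NA` features so callers can exclude
#' them from modelling.
#'
#' @param hc Height cloud clipped to the region.
#' @param roi One-row region tibble (metadata is copied into the record).
#' @param config Settings from [feature_config()].
#' @return A one-row tibble feature record.
#' @export
extract_features <- function(hc, roi, config = feature_config()) {
  meta <- tibble::tibble(
    region_id = roi$region_id[1], date = roi$date[1], das = roi$das[1],
    platform = roi$platform[1], genotype = roi$genotype[1],
    replicate = roi$replicate[1])
  na_rec <- dplyr::bind_cols(meta, tibble::tibble(
    n_ground = NA_integer_, n_veg = NA_integer_, lpi = NA_real_,
    h_mean = NA_real_, h_std = NA_real_, h_skew = NA_real_, h_q3 = NA_real_,
    h_cv = NA_real_, h_max = NA_real_, vci = NA_real_,
    hull_volume = NA_real_, cap = NA_real_, missing = TRUE))
  if (nrow(hc) == 0) return(na_rec)

  n_ground <- sum(hc$class == "ground")
  n_veg <- sum(hc$class == "vegetation")
  veg <- hc$h[hc$class == "vegetation"]
  na_rec$n_ground <- n_ground
  na_rec$n_veg <- n_veg
  na_rec$lpi <- lpi(n_ground, n_veg)
  if (n_veg < 3) return(na_rec)

  hs <- height_statistics(veg)
  vci_val <- tryCatch(
    vci(veg, bin_width = config$vci_bin_width,
        ground_threshold = config$ground_threshold),
    error = function(e) NA_real_)
  rec <- dplyr::bind_cols(meta, tibble::tibble(
    n_ground = n_ground, n_veg = n_veg, lpi = lpi(n_ground, n_veg)), hs,
    tibble::tibble(
      vci = vci_val,
      hull_volume = suppressWarnings(hull_volume(hc)),
      cap = cap_feature(hc, config)))
  rec$missing <- anyNA(rec[c("lpi", "h_mean", "h_std", "h_skew", "h_q3",
                             "vci", "hull_volume", "cap")])
  rec[names(na_rec)]
}

#' Extract features for every region of a study epoch
#'
#' Clips the canopy cloud to each region, normalizes heights against the
#' DTM and assembles one feature record per region.
#'
#' @param canopy Canopy-epoch point cloud.
#' @param dtm Terrain model from the bare-earth epoch.
#' @param regions Region tibble (one row per plot/row block).
#' @param config Settings from [feature_config()].
#' @return A feature table: one row per region, the CSV contract columns
#'   `region_id, date, das, platform, genotype, replicate, n_ground, n_veg,
#'   lpi, h_mean, h_std, h_skew, h_q3, h_cv, h_max, vci, hull_volume, cap`
#'   plus the `missing` flag.
#' @export
extract_study_features <- function(canopy, dtm, regions,
                                   config = feature_config()) {
  canopy <- validate_point_cloud(canopy)
  purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    roi <- regions[i, , drop = FALSE]
    hc <- normalize_heights(clip_to_region(canopy, roi), dtm,
                            ground_threshold = config$ground_threshold)
    extract_features(hc, roi, config)
  })
}

#' Write / read the feature table CSV
#' @param features Feature table from [extract_study_features()].
#' @param path CSV path.
#' @return `path` (write) or the feature tibble (read).
#' @export
write_feature_table <- function(features, path) {
  cols <- c("region_id", "date", "das", "platform", "genotype", "replicate",
            "n_ground", "n_veg", "lpi", "h_mean", "h_std", "h_skew", "h_q3",
            "h_cv", "h_max", "vci", "hull_volume", "cap")
  utils::write.csv(as.data.frame(features[cols]), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
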