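# Synthetic row-crop LiDAR scenes.
#
# The generator emulates the statistical structure the feature pipeline
# assumes, not the optics of any particular sensor: single-return pulses at
# nadir, ground returns governed by Beer-Lambert transmittance
# T = exp(-G * Omega * LAI), vegetation returns drawn from a configurable
# vertical profile and laterally jittered around plant stems arranged on
# rows. Effective LAI truth is defined as Omega * LAI per plot.

#' Scene configuration for the synthetic row-canopy generator
#'
#' @param plot_length Plot extent along the rows (m).
#' @param n_rows Rows per plot (a two-row block by default).
#' @param row_spacing Distance between rows (m); 0.76 m is typical row-crop
#'   spacing.
#' @param plants_per_ha Planting density; presets: sorghum ~200000,
#'   maize ~75000 plants/hectare.
#' @param lai_true True leaf area index of the plot.
#' @param clumping Clumping index Omega in (0, 1]; effective LAI is
#'   `clumping * lai_true`.
#' @param extinction Extinction coefficient G (> 0) of the Beer-Lambert
#'   transmittance at nadir.
#' @param base_height,top_height Vertical extent of the foliage (m above
#'   ground).
#' @param profile Vertical density of vegetation returns: `"uniform"`,
#'   `"triangular"` (peak mid-canopy) or `"beta"` (Beta(2, 2), smooth
#'   mid-canopy bulge).
#' @param pulse_density Pulses per square meter; presets 70 / 500 / 1400
#'   cover sparse UAV to dense ground-vehicle acquisitions.
#' @param sensor_noise Gaussian ranging noise sigma_z (m).
#' @param stem_jitter Lateral Gaussian sd of returns around stems (m).
#' @param ground_z,ground_slope_x,ground_slope_y Analytic ground plane
#'   `z = ground_z + sx * x + sy * y`.
#' @return A named list of generator settings.
#' @export
scene_config <- function(plot_length = 3.0, n_rows = 2, row_spacing = 0.76,
                         plants_per_ha = 200000, lai_true = 3,
                         clumping = 1, extinction = 0.5,
                         base_height = 0.2, top_height = 1.8,
                         profile = c("uniform", "triangular", "beta"),
                         pulse_density = 500, sensor_noise = 0.01,
                         stem_jitter = 0.1, ground_z = 100,
                         ground_slope_x = 0, ground_slope_y = 0) {
  profile <- match.arg(profile)
  cfg <- list(plot_length = plot_length, n_rows = n_rows,
              row_spacing = row_spacing, plants_per_ha = plants_per_ha,
              lai_true = lai_true, clumping = clumping,
              extinction = extinction, base_height = base_height,
              top_height = top_height, profile = profile,
              pulse_density = pulse_density, sensor_noise = sensor_noise,
              stem_jitter = stem_jitter, ground_z = ground_z,
              ground_slope_x = ground_slope_x,
              ground_slope_y = ground_slope_y)
  stopifnot(plot_length > 0, n_rows >= 1, row_spacing > 0, plants_per_ha > 0,
            lai_true >= 0, clumping > 0, clumping <= 1, extinction > 0,
            top_height > base_height, base_height > 0, pulse_density > 0,
            sensor_noise >= 0)
  cfg
}

ground_elevation <- function(cfg, x, y) {
  cfg$ground_z + cfg$ground_slope_x * x + cfg$ground_slope_y * y
}

draw_profile_height <- function(n, cfg) {
  u <- switch(cfg$profile,
              uniform = stats::runif(n),
              triangular = {                       # peak at mid-canopy
                v <- stats::runif(n)
                ifelse(v < 0.5, sqrt(v / 2), 1 - sqrt((1 - v) / 2))
              },
              beta = stats::rbeta(n, 2, 2))
  cfg$base_height + u * (cfg$top_height - cfg$base_height)
}

#' Generate one synthetic plot scene
#'
#' Simulates a bare-earth acquisition and a canopy-epoch acquisition over a
#' single plot, together with the plot's region polygon and ground-truth
#' effective LAI. Each canopy pulse lands uniformly over the plot, returns
#' from the ground with probability `exp(-G * Omega * LAI)` and otherwise
#' from the canopy at a profile-drawn height, laterally jittered around the
#' nearest-row plant stems.
#'
#' @param cfg Settings from [scene_config()].
#' @param origin Plot lower-left corner `c(x, y)` (m).
#' @param region_id,genotype,replicate Metadata for the region record.
#' @param seed Optional integer; when given, output is reproducible.
#' @return A list: `bare_earth` and `canopy` point clouds, `region` (one-row
#'   region tibble), and `truth` (`region_id, lai_true, clumping, lai_eff`
#'   with `lai_eff = clumping * lai_true`).
#' @export
generate_scene <- function(cfg = scene_config(), origin = c(0, 0),
                           region_id = "plot-1", genotype = NA_character_,
                           replicate = 1L, seed = NULL) {
  gen <- function() generate_scene_impl(cfg, origin, region_id, genotype,
                                        replicate)
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

generate_scene_impl <- function(cfg, origin, region_id, genotype, replicate) {
  width <- cfg$n_rows * cfg$row_spacing
  x0 <- origin[1]; y0 <- origin[2]
  margin <- 0.5

  # bare-earth epoch over the plot plus a margin
  area_b <- (width + 2 * margin) * (cfg$plot_length + 2 * margin)
  n_b <- max(1L, stats::rpois(1, cfg$pulse_density * area_b))
  bx <- stats::runif(n_b, x0 - margin, x0 + width + margin)
  by <- stats::runif(n_b, y0 - margin, y0 + cfg$plot_length + margin)
  bare <- point_cloud(x = bx, y = by,
                      z = ground_elevation(cfg, bx, by) +
                        stats::rnorm(n_b, 0, cfg$sensor_noise))

  # plant stems on rows
  row_x <- x0 + (seq_len(cfg$n_rows) - 0.5) * cfg$row_spacing
  spacing <- 1e4 / (cfg$plants_per_ha * cfg$row_spacing)
  stem_y <- seq(y0 + spacing / 2, y0 + cfg$plot_length - spacing / 2,
                by = spacing)
  stems <- expand.grid(x = row_x, y = stem_y)

  # canopy epoch: Beer-Lambert split of pulses into ground and vegetation
  n_p <- max(1L, stats::rpois(1, cfg$pulse_density * width * cfg$plot_length))
  transmit <- exp(-cfg$extinction * cfg$clumping * cfg$lai_true)
  is_ground <- stats::runif(n_p) < transmit
  n_g <- sum(is_ground); n_v <- n_p - n_g
  gx <- stats::runif(n_g, x0, x0 + width)
  gy <- stats::runif(n_g, y0, y0 + cfg$plot_length)
  if (n_v > 0) {
    stem <- stems[sample.int(nrow(stems), n_v, replace = TRUE), ]
    vx <- stem$x + stats::rnorm(n_v, 0, cfg$stem_jitter)
    vy <- stem$y + stats::rnorm(n_v, 0, cfg$stem_jitter)
    vh <- draw_profile_height(n_v, cfg)
  } else {
    vx <- vy <- vh <- numeric(0)
  }
  canopy <- point_cloud(
    x = c(gx, vx), y = c(gy, vy),
    z = c(ground_elevation(cfg, gx, gy) +
            stats::rnorm(n_g, 0, cfg$sensor_noise),
          ground_elevation(cfg, vx, vy) + vh +
            stats::rnorm(n_v, 0, cfg$sensor_noise)))

  ring <- rbind(c(x0, y0), c(x0 + width, y0),
                c(x0 + width, y0 + cfg$plot_length), c(x0, y0 + cfg$plot_length))
  region <- region_of_interest(region_id, ring, genotype = genotype,
                               replicate = replicate,
                               rows = paste(seq_len(cfg$n_rows),
                                            collapse = "-"))
  truth <- tibble::tibble(region_id = region_id, lai_true = cfg$lai_true,
                          clumping = cfg$clumping,
                          lai_eff = cfg$clumping * cfg$lai_true)
  list(bare_earth = bare, canopy = canopy, region = region, truth = truth)
}

#' Generate a multi-plot synthetic study
#'
#' Emits a full experiment laid out on a plot grid: `n_varieties` genotype
#' varieties with `n_replicates` plots each (80 x 2 = 160 plots mirrors a
#' sorghum calibration trial; 44 x 2 = 88 a maize hybrid trial). Each
#' variety draws one effective LAI uniformly from `lai_eff_range` shared by
#' its replicates; plot canopy height grows with LAI
#' (`top = 0.4 + height_per_lai * lai_true`) so the height features carry
#' signal, as in a real canopy.
#'
#' @param n_varieties,n_replicates Experimental design.
#' @param lai_eff_range Range of ground-reference effective LAI (0.5-6
#'   covers a sorghum season; use 0.5-5 for maize).
#' @param cfg Base settings from [scene_config()]; per-plot LAI and canopy
#'   top override it.
#' @param height_per_lai Canopy top height gained per unit true LAI (m).
#' @param height_noise_sd Per-plot Gaussian spread of canopy top height (m)
#'   around the LAI trend. Across genotypes height is only a loose proxy
#'   for leaf area, so the default 0.3 m keeps height features informative
#'   without making them a clean stand-in for the target.
#' @param seed Integer seed; the whole bundle is reproducible from it.
#' @return A list: `bare_earth`, `canopy` (all plots merged), `regions`,
#'   `truth` (with `genotype`/`replicate`), `config`.
#' @export
generate_study <- function(n_varieties = 80, n_replicates = 2,
                           lai_eff_range = c(0.5, 6), cfg = scene_config(),
                           height_per_lai = 0.35, height_noise_sd = 0.3,
                           seed = 1) {
  stopifnot(n_varieties >= 2, n_replicates >= 1)
  withr::with_seed(seed, {
    lai_eff_v <- stats::runif(n_varieties, lai_eff_range[1], lai_eff_range[2])
    n_plots <- n_varieties * n_replicates
    per_row <- ceiling(sqrt(n_plots))
    width <- cfg$n_rows * cfg$row_spacing
    gap <- 1.0
    scenes <- vector("list", n_plots)
    i <- 0
    for (v in seq_len(n_varieties)) {
      for (r in seq_len(n_replicates)) {
        i <- i + 1
        gx <- (i - 1) %% per_row
        gy <- (i - 1) %/% per_row
        cfg_i <- cfg
        cfg_i$lai_true <- lai_eff_v[v] / cfg$clumping
        cfg_i$top_height <- max(cfg$base_height + 0.1,
                                0.4 + height_per_lai * cfg_i$lai_true +
                                  stats::rnorm(1, 0, height_noise_sd))
        scenes[[i]] <- generate_scene_impl(
          cfg_i, origin = c(gx * (width + gap),
                            gy * (cfg$plot_length + gap)),
          region_id = sprintf("plot-%03d", i),
          genotype = sprintf("V%03d", v), replicate = r)
      }
    }
    truth <- purrr::map_dfr(scenes, "truth")
    truth$genotype <- purrr::map_chr(scenes, ~ .x$region$genotype[1])
    truth$replicate <- purrr::map_int(scenes, ~ .x$region$replicate[1])
    list(bare_earth = dplyr::bind_rows(purrr::map(scenes, "bare_earth")),
         canopy = dplyr::bind_rows(purrr::map(scenes, "canopy")),
         regions = dplyr::bind_rows(purrr::map(scenes, "region")),
         truth = truth,
         config = cfg)
  })
}
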