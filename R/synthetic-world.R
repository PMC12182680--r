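#' Default climate deltas per period and scenario
#'
#' Uniform changes in mean annual temperature (degC) and precipitation (mm)
#' applied to the baseline climate fields, typical of mid-latitude ensemble
#' projections under a moderate (SSP245) and a high-emission (SSP585) pathway.
#'
#' @return Data frame with columns `period`, `ssp`, `dmat`, `dmap`.
#' @export
default_climate_deltas <- function() {
  data.frame(
    period = rep(c("2030s", "2050s", "2070s"), each = 2),
    ssp = rep(c("SSP245", "SSP585"), 3),
    dmat = c(1.0, 1.3, 1.7, 2.6, 2.2, 4.3),
    dmap = c(20, 25, 40, 50, 60, 90))
}

#' Default CO2 trajectory parameters
#'
#' Concentration is modelled as `ppm(year) = 414 + g1*(year - 2020) +
#' g2*(year - 2020)^2`: near-linear stabilising growth under SSP245
#' (about 560 ppm by 2080) and accelerating growth under SSP585 (about
#' 780 ppm by 2080).
#'
#' @return Named list of `c(g1, g2)` per scenario.
#' @export
default_co2_params <- function() {
  list(SSP245 = c(g1 = 3.0, g2 = -0.01), SSP585 = c(g1 = 2.5, g2 = 0.06))
}

#' Configuration for the synthetic world generator
#'
#' Collects every knob of the synthetic study system: grid geometry, number
#' of forest types, survey sampling, the controlled error structure of the
#' three cover products and three age products, climate change deltas, CO2
#' forcing, and the afforestation area-target series. All randomness is fixed
#' by `seed`.
#'
#' @param seed Integer RNG seed fixing every stochastic draw.
#' @param grid_rows,grid_cols Grid dimensions (>= 2).
#' @param cell_size Cell size in degrees.
#' @param lat_origin Latitude of the northern grid edge (degrees).
#' @param lon_origin Longitude of the western grid edge (degrees).
#' @param n_types Number of forest types (>= 2).
#' @param survey_n Number of survey records.
#' @param survey_noise_sd Gaussian noise sd on survey AGB (Mg/ha).
#' @param product_disagreement_rate Probability that any given pair of cover
#'   products disagrees at a cell (must be in `[0, 2/3]`; see Details).
#' @param age_null_fraction Length-3 vector: fraction of forest cells set to
#'   null in each age product.
#' @param climate_delta Data frame as [default_climate_deltas()].
#' @param co2_baseline Baseline CO2 concentration (ppm) for fertilization
#'   ratios.
#' @param co2_params List as [default_co2_params()].
#' @param n_esm Number of synthetic Earth-system-model cVeg curves.
#' @param suitable_fraction Fraction of grid cells whose suitability exceeds
#'   MTSS per type (the MTSS is set to the matching quantile).
#' @param area_target_years Years at which afforestation area targets are
#'   stated.
#' @param area_target_growth Relative growth of the forest-area target per
#'   year (fraction of baseline forest area).
#' @param area_target_noise_sd Noise sd on targets, as a fraction of baseline
#'   forest area.
#' @param periods,ssps Projection periods and climate scenarios.
#'
#' @details To make every pair of the three cover products disagree at the
#' configured rate, a cell is perturbed with probability `3/2 *
#' product_disagreement_rate`, in exactly one product chosen uniformly; a
#' given pair is then affected with probability `(3/2 r) * (2/3) = r`.
#'
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             grid_rows = 50L, grid_cols = 50L,
                             cell_size = 0.5, lat_origin = 53,
                             lon_origin = 75,
                             n_types = 5L,
                             survey_n = 600L,
                             survey_noise_sd = 10,
                             product_disagreement_rate = 0.10,
                             age_null_fraction = c(0.15, 0.25, 0.05),
                             climate_delta = default_climate_deltas(),
                             co2_baseline = 371.8,
                             co2_params = default_co2_params(),
                             n_esm = 12L,
                             suitable_fraction = 0.25,
                             area_target_years = seq(2025, 2080, by = 5),
                             area_target_growth = 0.012,
                             area_target_noise_sd = 0.005,
                             periods = c("2030s", "2050s", "2070s"),
                             ssps = c("SSP245", "SSP585")) {
  cfg <- list(seed = as.integer(seed), grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols), cell_size = cell_size,
              lat_origin = lat_origin, lon_origin = lon_origin,
              n_types = as.integer(n_types), survey_n = as.integer(survey_n),
              survey_noise_sd = survey_noise_sd,
              product_disagreement_rate = product_disagreement_rate,
              age_null_fraction = age_null_fraction,
              climate_delta = climate_delta, co2_baseline = co2_baseline,
              co2_params = co2_params, n_esm = as.integer(n_esm),
              suitable_fraction = suitable_fraction,
              area_target_years = area_target_years,
              area_target_growth = area_target_growth,
              area_target_noise_sd = area_target_noise_sd,
              periods = periods, ssps = ssps)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (is.na(cfg$seed)) stop("configuration error: seed must be an integer")
  if (cfg$grid_rows < 2 || cfg$grid_cols < 2)
    stop("configuration error: grid dims must be >= 2")
  if (cfg$n_types < 2) stop("configuration error: n_types must be >= 2")
  if (cfg$survey_n < 1) stop("configuration error: survey_n must be positive")
  if (cfg$survey_noise_sd < 0)
    stop("configuration error: survey_noise_sd must be >= 0")
  fr <- c(cfg$product_disagreement_rate, cfg$age_null_fraction,
          cfg$suitable_fraction)
  if (any(fr < 0 | fr > 1))
    stop("configuration error: fractions must lie in [0, 1]")
  if (cfg$product_disagreement_rate > 2 / 3)
    stop("configuration error: product_disagreement_rate must be <= 2/3")
  if (length(cfg$age_null_fraction) != 3)
    stop("configuration error: age_null_fraction needs one value per product")
  if (cfg$suitable_fraction <= 0 || cfg$suitable_fraction >= 1)
    stop("configuration error: suitable_fraction must lie in (0, 1)")
  if (cfg$co2_baseline <= 0)
    stop("configuration error: co2_baseline must be > 0")
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(paste0("synthetic_config: %dx%d grid (%g deg), %d types, ",
                     "%d survey records (noise sd %g), seed %d\n"),
              x$grid_rows, x$grid_cols, x$cell_size, x$n_types, x$survey_n,
              x$survey_noise_sd, x$seed))
  invisible(x)
}

# fixed generating growth truths: families cycle MM/L/MO across type codes,
# asymptotes spread 105-205 Mg/ha, common climate coefficients
.truth_growth <- function(n_types) {
  lapply(seq_len(n_types), function(j) {
    fam <- c("MM", "L", "MO")[(j - 1) %% 3 + 1]
    mu <- 80 + 25 * j
    pars <- switch(fam,
      MM = c(mu = mu, k = 120),
      L  = c(mu = mu, c = 8, alpha = 0.08),
      MO = c(mu = mu, c = 1.2, alpha = 0.04))
    list(family = fam, params = c(pars, a = 2, b = 0.05, d = 5))
  })
}

# north-south gradients spanning the domain (north cold and dry, south warm
# and wet, as over eastern continental Asia) with low-amplitude east-west
# sinusoidal texture; defined on normalised grid position so any grid size
# samples the full climate range
.climate_fields <- function(geom) {
  rowf <- matrix((seq_len(geom$nrow) - 0.5) / geom$nrow, geom$nrow, geom$ncol)
  colf <- matrix((seq_len(geom$ncol) - 0.5) / geom$ncol, geom$nrow, geom$ncol,
                 byrow = TRUE)
  mat <- -4 + 20 * rowf + 1.5 * sin(2 * pi * 3 * colf)
  map <- 600 + 1000 * rowf + 150 * sin(2 * pi * 2 * colf)
  list(mat = mat, map = pmax(map, 0))
}

# logistic suitability link in standardised climate space, type-specific optima
.suitability_link <- function(mat, map, opt) {
  stats::plogis(opt$s0 - ((mat - opt$mat) / opt$s_mat)^2 -
                  ((map - opt$map) / opt$s_map)^2)
}

# type-specific climate optima spread over the climate actually occupied by
# forest, the way niche models infer optima from occurrence cells
.type_optima <- function(n_types, mat, map) {
  qs <- (seq_len(n_types) - 0.5) / n_types
  lapply(seq_len(n_types), function(j)
    list(mat = stats::quantile(mat, qs[j], names = FALSE),
         map = stats::quantile(map, qs[n_types - j + 1], names = FALSE),
         s_mat = 6, s_map = 450, s0 = 2.5))
}

#' Generate a complete synthetic world
#'
#' Fabricates every input the projection pipeline needs, with the generating
#' truth recorded: smooth climate fields (latitudinal gradient plus
#' low-amplitude sinusoidal texture) now and under per-period/per-scenario
#' deltas; fractional tree cover; a true cover map (most-suitable type where
#' tree cover reaches the forest threshold) plus three cover products with a
#' controlled pairwise disagreement rate; a true stand-age map plus three age
#' products with controlled null fractions (the rank-3 product is shifted one
#' decade back so its ages need the +10 adjustment); per-type suitability
#' surfaces (logistic in standardised climate) with MTSS thresholds set so a
#' known fraction of cells qualifies; survey records drawn from per-type
#' growth laws plus the linear climate term and Gaussian noise; CO2
#' trajectories per scenario; a bundle of saturating cVeg response curves;
#' and a near-linear afforestation area-target series.
#'
#' @param config A [synthetic_config()].
#' @return Object of class `world_bundle`: a list with elements `config`,
#'   `geom`, `climate_now`, `climate_future` (nested period/ssp), `tree_cover`,
#'   `cover_products`, `age_products`, `suitability` (with `now`, `future`,
#'   `mtss`), `survey`, `co2` (trajectories, curves, baseline), `area_targets`
#'   and `truth`.
#' @examples
#' w <- generate_world(synthetic_config(seed = 7, grid_rows = 12,
#'                                      grid_cols = 12, survey_n = 60))
#' names(w)
#' @export
generate_world <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  validate_synthetic_config(config)
  set.seed(config$seed)
  K <- config$n_types
  geom <- grid_geom(config$grid_rows, config$grid_cols, config$cell_size,
                    config$lat_origin, config$lon_origin)
  ncell <- geom$nrow * geom$ncol
  clim <- .climate_fields(geom)

  # tree cover: wetter cells carry more trees, with seeded roughness;
  # centred so roughly a quarter of the domain clears the forest threshold
  tc_base <- stats::plogis((clim$map - 1570) / 120)
  tree_cover <- pmin(pmax(0.05 + 0.9 * tc_base +
                            stats::runif(ncell, -0.1, 0.1), 0), 1)
  tree_cover <- matrix(tree_cover, geom$nrow, geom$ncol)
  mask_true <- tree_cover >= 0.20

  # suitability truth, now and future (optima from forested-cell climate)
  optima <- .type_optima(K, clim$mat[mask_true], clim$map[mask_true])
  suit_now <- lapply(optima, function(o)
    .suitability_link(clim$mat, clim$map, o))
  names(suit_now) <- as.character(seq_len(K))
  mtss <- vapply(suit_now, function(p)
    stats::quantile(p, 1 - config$suitable_fraction, names = FALSE),
    numeric(1))
  mtss <- pmin(pmax(mtss, 1e-6), 1 - 1e-6)
  names(mtss) <- names(suit_now)

  climate_future <- list()
  suit_future <- list()
  for (per in config$periods) {
    climate_future[[per]] <- list()
    suit_future[[per]] <- list()
    for (ssp in config$ssps) {
      row <- config$climate_delta[config$climate_delta$period == per &
                                    config$climate_delta$ssp == ssp, ]
      if (nrow(row) != 1)
        stop("configuration error: climate_delta missing ", per, "/", ssp)
      cf <- list(mat = clim$mat + row$dmat, map = clim$map + row$dmap)
      climate_future[[per]][[ssp]] <- cf
      sf <- lapply(optima, function(o) .suitability_link(cf$mat, cf$map, o))
      names(sf) <- names(suit_now)
      suit_future[[per]][[ssp]] <- sf
    }
  }

  # true cover: most suitable type wherever tree cover reaches the threshold
  pm <- vapply(suit_now, as.numeric, numeric(ncell))
  type_best <- max.col(pm, ties.method = "first")
  cover_true <- matrix(ifelse(as.vector(mask_true), type_best, 0L),
                       geom$nrow, geom$ncol)

  # cover products: perturb one product per selected cell (see config docs)
  r <- config$product_disagreement_rate
  products <- list(cover_true, cover_true, cover_true)
  hit <- stats::runif(ncell) < 1.5 * r
  which_prod <- sample.int(3L, ncell, replace = TRUE)
  codes <- c(0L, seq_len(K))
  if (any(hit)) {
    for (i in which(hit)) {
      cur <- products[[which_prod[i]]][i]
      products[[which_prod[i]]][i] <- sample(setdiff(codes, cur), 1L)
    }
  }

  # true ages: right-skewed, mostly young-to-middle-aged stands
  age_true <- matrix(NA_real_, geom$nrow, geom$ncol)
  nfor <- sum(mask_true)
  age_true[mask_true] <- pmin(pmax(round(stats::rgamma(nfor, shape = 3.2,
                                                       scale = 18)), 1), 150)
  age_products <- vector("list", 3)
  for (j in 1:3) {
    aj <- age_true
    if (j == 3) aj <- pmax(aj - 10, 0)   # mapped a decade earlier
    drop_n <- round(config$age_null_fraction[j] * nfor)
    if (drop_n > 0) {
      idx <- sample(which(mask_true), drop_n)
      aj[idx] <- NA_real_
    }
    age_products[[j]] <- aj
  }

  # survey records on the generating growth laws
  tg <- .truth_growth(K)
  sv_type <- sample.int(K, config$survey_n, replace = TRUE)
  sv_cell <- sample.int(ncell, config$survey_n, replace = TRUE)
  sv_t <- stats::runif(config$survey_n, 1, 150)
  sv_mat <- as.vector(clim$mat)[sv_cell]
  sv_map <- as.vector(clim$map)[sv_cell]
  sv_mean <- vapply(seq_len(config$survey_n), function(i) {
    g <- tg[[sv_type[i]]]
    eval_growth(g$family, g$params, sv_t[i]) +
      g$params[["a"]] * sv_mat[i] + g$params[["b"]] * sv_map[i] +
      g$params[["d"]]
  }, numeric(1))
  survey <- data.frame(type = sv_type, t = sv_t,
                       agb = sv_mean + stats::rnorm(config$survey_n, 0,
                                                    config$survey_noise_sd),
                       mat = sv_mat, map = sv_map)

  # CO2 forcing: trajectories per scenario, ensemble of cVeg response curves
  years <- 2020:2080
  traj <- lapply(config$ssps, function(ssp) {
    g <- config$co2_params[[ssp]]
    if (is.null(g)) stop("configuration error: co2_params missing ", ssp)
    dy <- years - 2020
    co2_trajectory(years, 414 + g[["g1"]] * dy + g[["g2"]] * dy^2, ssp = ssp)
  })
  names(traj) <- config$ssps
  ppm_grid <- seq(280, 1100, by = 20)
  curves <- lapply(seq_len(config$n_esm), function(i) {
    cmax <- 30 * (1 + stats::runif(1, -0.15, 0.15))
    h <- 500 * (1 + stats::runif(1, -0.2, 0.2))
    cveg_curve(ppm_grid, cmax * ppm_grid / (h + ppm_grid),
               source = sprintf("esm_%02d", i))
  })

  # afforestation targets: near-linear growth from the baseline forest area
  areas <- cell_area_matrix(geom)
  a0 <- sum(areas[mask_true]) / 1e6   # Mha
  ty <- config$area_target_years
  targets <- a0 * (1 + config$area_target_growth * (ty - 2020)) +
    stats::rnorm(length(ty), 0, config$area_target_noise_sd * a0)
  area_targets <- data.frame(year = ty, area_mha = targets)

  structure(list(
    config = config, geom = geom,
    climate_now = clim, climate_future = climate_future,
    tree_cover = tree_cover,
    cover_products = products,
    age_products = age_products,
    age_offsets = c(0, 0, 10),
    suitability = list(now = suit_now, future = suit_future, mtss = mtss),
    survey = survey,
    co2 = list(trajectories = traj, curves = curves,
               baseline = config$co2_baseline),
    area_targets = area_targets,
    truth = list(growth = tg, cover = cover_true, age = age_true,
                 mask = mask_true, optima = optima)),
    class = "world_bundle")
}

#' @export
print.world_bundle <- function(x, ...) {
  cat(sprintf(paste0("world_bundle: %dx%d grid, %d types, %d survey records, ",
                     "%d forest cells (%.1f%% of grid)\n"),
              x$geom$nrow, x$geom$ncol, x$config$n_types, nrow(x$survey),
              sum(x$truth$mask),
              100 * mean(x$truth$mask)))
  invisible(x)
}

#' Write a world bundle to plain-text files
#'
#' Rasters as ESRI ASCII grids, tables as CSV, the generating truth
#' parameters and thresholds as JSON.
#'
#' @param world A [generate_world()] bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- world$geom
  write_ascii_grid(world$tree_cover, file.path(dir, "tree_cover.asc"), g)
  write_ascii_grid(world$climate_now$mat, file.path(dir, "mat_2020.asc"), g)
  write_ascii_grid(world$climate_now$map, file.path(dir, "map_2020.asc"), g)
  for (j in 1:3) {
    write_ascii_grid(world$cover_products[[j]],
                     file.path(dir, sprintf("cover_rank%d.asc", j)), g)
    write_ascii_grid(world$age_products[[j]],
                     file.path(dir, sprintf("age_rank%d.asc", j)), g)
  }
  utils::write.csv(world$survey, file.path(dir, "survey.csv"),
                   row.names = FALSE)
  utils::write.csv(world$area_targets, file.path(dir, "area_targets.csv"),
                   row.names = FALSE)
  for (ssp in names(world$co2$trajectories))
    utils::write.csv(world$co2$trajectories[[ssp]],
                     file.path(dir, sprintf("co2_%s.csv", tolower(ssp))),
                     row.names = FALSE)
  truth <- list(
    mtss = as.list(world$suitability$mtss),
    growth = lapply(world$truth$growth, function(g)
      list(family = g$family, params = as.list(g$params))),
    co2_baseline = world$co2$baseline)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
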