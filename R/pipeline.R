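#' Run the full projection pipeline on a synthetic world
#'
#' Orchestrates every stage end-to-end: generate the synthetic world; build
#' the forest mask (tree cover >= threshold) and fuse the three cover and
#' three age products into baseline maps; fit the three growth families per
#' forest type on the survey records and select the best by AIC; compute
#' period-mean CO2-fertilization ratios per scenario from the cVeg curve
#' ensemble and the concentration trajectories; project each period/scenario
#' under the nature scenario and, on top of it, the afforestation scenario
#' (area-target regression, demand, random allocation averaged over replicate
#' seeds); and assemble the summary table. Each period is projected from the
#' 2020 baseline (N measured from 2020).
#'
#' Re-running with the same config reproduces identical outputs: all
#' randomness is funnelled through the config seed and the explicit replicate
#' seeds.
#'
#' @param config A [synthetic_config()] (or a list of its arguments).
#' @param seeds Replicate seeds for the afforestation ensemble (default 1:10).
#' @param carbon_fraction Carbon fraction for totals (see [total_agb()]).
#' @param tree_cover_threshold Forest-definition threshold (default 0.20).
#' @param out_dir Optional directory; when given, writes the world, fitted
#'   parameters, summary CSV and a manifest (config hash, seeds, package
#'   version).
#' @param representative_year Named vector mapping periods to the year at
#'   which the area-target regression is evaluated (defaults to period
#'   midpoints 2030/2050/2070).
#' @return Object of class `pipeline_result`: list with `world`, `mask`,
#'   `type` and `age` (fused baseline maps), `fits`, `f_table`, `area_model`,
#'   `baseline`, `states` (nested per period/ssp: `nature` state and
#'   `afforestation` ensemble), and `summary` (data frame, one row per
#'   period x ssp x scenario plus the baseline).
#' @examples
#' \donttest{
#' res <- run_pipeline(synthetic_config(seed = 1, grid_rows = 20,
#'                                      grid_cols = 20, survey_n = 240),
#'                     seeds = 1:3)
#' res$summary
#' }
#' @export
run_pipeline <- function(config = synthetic_config(), seeds = 1:10,
                         carbon_fraction = 1, tree_cover_threshold = 0.20,
                         out_dir = NULL,
                         representative_year = c("2030s" = 2030,
                                                 "2050s" = 2050,
                                                 "2070s" = 2070)) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  world <- generate_world(config)
  geom <- world$geom
  areas <- cell_area_matrix(geom)

  # map fusion + forest definition
  mask <- forest_mask(world$tree_cover, threshold = tree_cover_threshold)
  fused <- fuse_cover(world$cover_products[[1]], world$cover_products[[2]],
                      world$cover_products[[3]])
  type <- fused
  type[!mask] <- 0L
  fmask <- type != 0L
  age <- withCallingHandlers(
    fuse_age(world$age_products[[1]], world$age_products[[2]],
             world$age_products[[3]], fmask, offsets = world$age_offsets,
             types = type),
    warning = function(w) invokeRestart("muffleWarning"))

  # growth model fitting per type
  fits <- fit_growth_by_type(world$survey)

  # fertilization ratios per period x ssp (and for the baseline year)
  f_rows <- list()
  for (per in config$periods)
    for (ssp in config$ssps)
      f_rows[[length(f_rows) + 1L]] <- data.frame(
        period = per, ssp = ssp,
        F = period_mean_F(world$co2$curves, world$co2$trajectories[[ssp]],
                          per, ppm_baseline = world$co2$baseline))
  f_table <- do.call(rbind, f_rows)
  ppm_2020 <- world$co2$trajectories[[1]]$ppm[
    world$co2$trajectories[[1]]$year == 2020]
  F_2020 <- compute_F(world$co2$curves, ppm_2020,
                      ppm_baseline = world$co2$baseline)

  baseline <- baseline_state(geom, type, age, fits, world$climate_now,
                             F_baseline = F_2020)

  area_model <- fit_area_targets(world$area_targets)

  states <- list()
  rows <- list(cbind(period = "2020", ssp = NA, scenario = "baseline",
                     summarize_state(baseline, areas, carbon_fraction),
                     ens_sd_pgc = NA_real_))
  for (per in config$periods) {
    states[[per]] <- list()
    yrs_elapsed <- c("2030s" = 10, "2050s" = 30, "2070s" = 50)[[per]]
    for (ssp in config$ssps) {
      spec <- scenario_spec(per, ssp, seeds = seeds)
      suit <- world$suitability$future[[per]][[ssp]]
      mtss <- world$suitability$mtss
      climf <- world$climate_future[[per]][[ssp]]
      Fv <- f_table$F[f_table$period == per & f_table$ssp == ssp]
      nat <- step_nature(baseline, suit, mtss, world$climate_now, climf,
                         fits, Fv, spec)
      target <- stats::predict(area_model, representative_year[[per]])
      remaining <- sum(areas[nat$type != 0]) / 1e6
      demand <- required_afforestation(target, remaining)
      ens <- withCallingHandlers(
        run_ensemble(nat, suit, mtss, demand, world$climate_now, climf,
                     fits, Fv, spec, carbon_fraction),
        warning = function(w) invokeRestart("muffleWarning"))
      states[[per]][[ssp]] <- list(nature = nat, afforestation = ens,
                                   target_mha = target, demand_mha = demand,
                                   F = Fv)
      rows[[length(rows) + 1L]] <- cbind(
        period = per, ssp = ssp, scenario = "nature",
        summarize_state(nat, areas, carbon_fraction, baseline = baseline,
                        years = yrs_elapsed),
        ens_sd_pgc = NA_real_)
      aff_mean_state <- ens$states[[1]]
      aff_row <- summarize_state(aff_mean_state, areas, carbon_fraction,
                                 baseline = baseline, years = yrs_elapsed)
      # replicate-ensemble means override the single-replicate values
      aff_row$total_agb_pgc <- ens$mean[["total_agb_pgc"]]
      aff_row$area_mha <- ens$mean[["area_mha"]]
      aff_row$mean_density <- ens$mean[["mean_density"]]
      aff_row$mean_age <- ens$mean[["mean_age"]]
      aff_row$seq_rate_tgc_yr <- sequestration_rate(
        ens$mean[["total_agb_pgc"]],
        total_agb(baseline, areas, carbon_fraction), yrs_elapsed)
      rows[[length(rows) + 1L]] <- cbind(
        period = per, ssp = ssp, scenario = "afforestation", aff_row,
        ens_sd_pgc = ens$sd[["total_agb_pgc"]])
    }
  }
  for (i in seq_along(rows)) {
    missing_cols <- setdiff(c("loss_rate", "change_rate", "seq_rate_tgc_yr"),
                            names(rows[[i]]))
    for (mc in missing_cols) rows[[i]][[mc]] <- NA_real_
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL

  res <- structure(list(world = world, mask = mask, type = type, age = age,
                        fits = fits, f_table = f_table,
                        area_model = area_model, baseline = baseline,
                        states = states, summary = summary,
                        seeds = seeds, carbon_fraction = carbon_fraction),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result on a", x$world$geom$nrow, "x", x$world$geom$ncol,
      "synthetic world\n")
  print(x$summary[, c("period", "ssp", "scenario", "total_agb_pgc",
                      "mean_density", "mean_age", "area_mha")])
  invisible(x)
}

#' Table of fitted growth models
#'
#' Flattens a named list of `growth_fit` objects into the familiar
#' one-row-per-type table (family, parameters, climate coefficients, fit
#' metrics).
#'
#' @param fits Named list of `growth_fit` objects.
#' @return Data frame.
#' @export
fits_table <- function(fits) {
  do.call(rbind, lapply(names(fits), function(ty) {
    f <- fits[[ty]]
    cf <- f$coefficients
    data.frame(type = ty, family = f$family, n = f$n,
               mu = cf[["mu"]],
               k = if ("k" %in% names(cf)) cf[["k"]] else NA_real_,
               c = if ("c" %in% names(cf)) cf[["c"]] else NA_real_,
               alpha = if ("alpha" %in% names(cf)) cf[["alpha"]] else NA_real_,
               a = cf[["a"]], b = cf[["b"]], d = cf[["d"]],
               rmse = f$rmse, r2 = f$r2, aic = f$aic)
  }))
}

#' Write pipeline outputs to a run directory
#'
#' Writes the synthetic world (plain-text rasters and tables), the fused
#' baseline maps, the fitted growth parameters (CSV), fertilization ratios,
#' the summary table (CSV) and a manifest recording the config hash, seeds
#' and package version, so a rerun with the same config is verifiably
#' identical.
#'
#' @param res A [run_pipeline()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_world(res$world, file.path(dir, "world"))
  g <- res$world$geom
  write_ascii_grid(res$type, file.path(dir, "baseline_type.asc"), g)
  write_ascii_grid(res$age, file.path(dir, "baseline_age.asc"), g)
  utils::write.csv(fits_table(res$fits), file.path(dir, "growth_fits.csv"),
                   row.names = FALSE)
  utils::write.csv(res$f_table, file.path(dir, "f_ratios.csv"),
                   row.names = FALSE)
  utils::write.csv(res$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  for (per in names(res$states))
    for (ssp in names(res$states[[per]])) {
      st <- res$states[[per]][[ssp]]$nature
      write_ascii_grid(st$type,
                       file.path(dir, sprintf("nature_type_%s_%s.asc",
                                              per, ssp)), g)
      write_ascii_grid(st$c_total,
                       file.path(dir, sprintf("nature_ctotal_%s_%s.asc",
                                              per, ssp)), g)
    }
  cfg_json <- jsonlite::toJSON(unclass(res$world$config), auto_unbox = TRUE,
                               digits = NA, force = TRUE)
  manifest <- list(
    config_md5 = .md5_string(as.character(cfg_json)),
    seed = res$world$config$seed,
    replicate_seeds = res$seeds,
    carbon_fraction = res$carbon_fraction,
    package_version = as.character(utils::packageVersion("forestcarbon")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

.md5_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}
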