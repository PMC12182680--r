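#' Total aboveground biomass of a forest state
#'
#' Area-weighted total over all pixels: `sum(density_Mg_per_ha * area_ha) *
#' carbon_fraction * 1e-9` (Mg to Pg). `carbon_fraction` defaults to 1,
#' treating input densities as already in carbon units; set 0.5 for the
#' conventional biomass-to-carbon factor if densities are dry biomass.
#'
#' @param state A [forest_state()].
#' @param cell_areas Matrix of per-cell areas in hectares (see
#'   [cell_area_matrix()]).
#' @param carbon_fraction Fraction in `(0, 1]`.
#' @return Total in PgC.
#' @export
total_agb <- function(state, cell_areas, carbon_fraction = 1) {
  if (carbon_fraction <= 0 || carbon_fraction > 1)
    stop("configuration error: carbon_fraction must lie in (0, 1]")
  sum(state$c_total * cell_areas) * carbon_fraction * 1e-9
}

.wmean <- function(x, w) sum(x * w) / sum(w)
.wsd <- function(x, w) sqrt(sum(w * (x - .wmean(x, w))^2) / sum(w))

#' Forest-area loss and structural-change rates
#'
#' Percentages of the baseline forest area that was lost (pixels that became
#' non-forest) or structurally changed (pixels replaced by another type)
#' under a projected state.
#'
#' @param state_future Projected [forest_state()] (with status flags set by
#'   [step_nature()]).
#' @param state_baseline Baseline [forest_state()].
#' @param cell_areas Matrix of per-cell areas (ha).
#' @return Named numeric: `loss_rate` and `change_rate`, in percent.
#' @export
rates <- function(state_future, state_baseline, cell_areas) {
  base <- sum(cell_areas[state_baseline$type != 0])
  if (base == 0) stop("undefined-rate error: zero baseline forest area")
  lost <- sum(cell_areas[state_future$status == .ST[["lost"]]])
  repl <- sum(cell_areas[state_future$status == .ST[["replaced"]]])
  c(loss_rate = 100 * lost / base, change_rate = 100 * repl / base)
}

#' Carbon sequestration rate
#'
#' `(AGB_t1 - AGB_t0) * 1000 / years`, in TgC per year.
#'
#' @param agb_t1,agb_t0 Totals in PgC.
#' @param years Elapsed years (> 0).
#' @return TgC/yr.
#' @export
sequestration_rate <- function(agb_t1, agb_t0, years) {
  if (any(years <= 0)) stop("configuration error: years must be > 0")
  (agb_t1 - agb_t0) * 1000 / years
}

#' Summary metrics for a forest state
#'
#' One summary row in the style of national projection tables: total AGB with
#' a spatial spread (the area-weighted standard deviation of pixel density
#' scaled to the forest area, so total and density spreads are consistent),
#' forest area, area-weighted mean density and stand age with their spatial
#' sds, loss/change rates against a baseline, the sequestration rate, and the
#' percentage shares of the age, climate and CO2 components.
#'
#' @param state A [forest_state()].
#' @param cell_areas Matrix of per-cell areas (ha).
#' @param carbon_fraction See [total_agb()].
#' @param baseline Optional baseline [forest_state()] for rates.
#' @param years Optional elapsed years for the sequestration rate.
#' @param region Optional label stored in the row.
#' @return One-row data frame.
#' @export
summarize_state <- function(state, cell_areas, carbon_fraction = 1,
                            baseline = NULL, years = NULL, region = NA) {
  fo <- state$type != 0
  w <- cell_areas[fo]
  total <- total_agb(state, cell_areas, carbon_fraction)
  dens_mean <- if (any(fo)) .wmean(state$c_total[fo], w) else 0
  dens_sd <- if (sum(fo) > 1) .wsd(state$c_total[fo], w) else 0
  area_ha <- sum(w)
  comp <- c(age = sum(state$c_age * cell_areas),
            climate = sum(state$c_climate * cell_areas),
            co2 = sum(state$c_co2 * cell_areas))
  tot_mg <- sum(comp)
  shares <- if (tot_mg != 0) 100 * comp / tot_mg else comp * 0
  row <- data.frame(
    region = region,
    area_mha = area_ha / 1e6,
    total_agb_pgc = total,
    total_agb_sd_pgc = dens_sd * area_ha * carbon_fraction * 1e-9,
    mean_density = dens_mean,
    sd_density = dens_sd,
    mean_age = if (any(fo)) .wmean(state$age[fo], w) else NA_real_,
    sd_age = if (sum(fo) > 1) .wsd(state$age[fo], w) else NA_real_,
    share_age = unname(shares["age"]),
    share_climate = unname(shares["climate"]),
    share_co2 = unname(shares["co2"]))
  if (!is.null(baseline)) {
    rt <- rates(state, baseline, cell_areas)
    row$loss_rate <- rt[["loss_rate"]]
    row$change_rate <- rt[["change_rate"]]
    if (!is.null(years)) {
      base_total <- total_agb(baseline, cell_areas, carbon_fraction)
      row$seq_rate_tgc_yr <- sequestration_rate(total, base_total, years)
    }
  }
  row
}

#' Per-region summaries
#'
#' Splits the grid on a region-label raster (e.g. climatic zones) and
#' summarises each region separately.
#'
#' @param state A [forest_state()].
#' @param regions Matrix of region labels (character or integer).
#' @param cell_areas Matrix of per-cell areas (ha).
#' @param carbon_fraction See [total_agb()].
#' @return Data frame with one row per region.
#' @export
summarize_by_region <- function(state, regions, cell_areas,
                                carbon_fraction = 1) {
  if (!all(dim(regions) == dim(state$type)))
    stop("shape error: region raster must share the grid")
  labs <- sort(unique(as.vector(regions)))
  do.call(rbind, lapply(labs, function(lb) {
    sel <- regions == lb
    sub <- state
    for (f in c("type", "status"))
      sub[[f]] <- ifelse(sel, state[[f]], 0L)
    for (f in c("c_age", "c_climate", "c_co2", "c_total"))
      sub[[f]] <- ifelse(sel, state[[f]], 0)
    sub$age <- ifelse(sel & state$type != 0, state$age, NA_real_)
    summarize_state(sub, cell_areas, carbon_fraction, region = lb)
  }))
}
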