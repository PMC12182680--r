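#' Scenario specification
#'
#' Identifies the projection period and climate scenario, the years elapsed
#' since the 2020 baseline, and the replicate seeds for the afforestation
#' allocation ensemble. The default N per period is the period midpoint minus
#' 2020 (10, 30 and 50 years for the 2030s, 2050s and 2070s), since the
#' evaluation year inside a 20-year window is a modelling choice.
#'
#' @param period `"2030s"`, `"2050s"` or `"2070s"`.
#' @param ssp `"SSP245"` or `"SSP585"` (any label is accepted).
#' @param N Years elapsed since 2020; defaults by period.
#' @param seeds Integer seeds for afforestation replicates (default 1:10).
#' @param round_ages Round replanted ages (`N/2`) to the nearest whole year
#'   (default `TRUE`); the growth curves themselves are continuous in age.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(period, ssp, N = NULL, seeds = 1:10,
                          round_ages = TRUE) {
  period <- match.arg(period, c("2030s", "2050s", "2070s"))
  if (is.null(N))
    N <- c("2030s" = 10, "2050s" = 30, "2070s" = 50)[[period]]
  if (N <= 0) stop("configuration error: N must be > 0")
  structure(list(period = period, ssp = ssp, N = N, seeds = seeds,
                 round_ages = round_ages), class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("scenario_spec: %s / %s, N = %g yr, %d replicate seeds\n",
              x$period, x$ssp, x$N, length(x$seeds)))
  invisible(x)
}

# pixel status codes
.ST <- c(nonforest = 0L, remained = 1L, replaced = 2L, lost = 3L,
         planted = 4L)

#' Construct a per-pixel forest state
#'
#' Bundles the per-pixel type, stand age, AGB components and status flags,
#' enforcing the additive decomposition `c_total = c_age + c_climate + c_co2`
#' and zero components on non-forest pixels.
#'
#' @param geom A [grid_geom()].
#' @param type Integer matrix of type codes (0 = non-forest).
#' @param age Numeric matrix of stand ages, `NA` where non-forest.
#' @param c_age,c_climate,c_co2 Component matrices (Mg/ha).
#' @param status Integer matrix of status codes (0 nonforest, 1 remained,
#'   2 replaced, 3 lost, 4 planted); defaults to remained/nonforest from
#'   `type`.
#' @return Object of class `forest_state`.
#' @export
forest_state <- function(geom, type, age, c_age, c_climate, c_co2,
                         status = NULL) {
  dims <- c(geom$nrow, geom$ncol)
  for (m in list(type, age, c_age, c_climate, c_co2))
    if (!all(dim(m) == dims)) stop("shape error: state rasters must share grid")
  nf <- type == 0L
  if (any(!is.na(age[nf])))
    stop("data error: non-forest pixels must have NA age")
  if (any(age[!nf] < 0, na.rm = TRUE))
    stop("data error: stand ages must be >= 0 where forested")
  if (any(abs(c_age[nf]) + abs(c_climate[nf]) + abs(c_co2[nf]) > 0))
    stop("data error: non-forest pixels must have zero components")
  c_total <- c_age + c_climate + c_co2
  if (is.null(status)) status <- matrix(ifelse(nf, .ST[["nonforest"]],
                                               .ST[["remained"]]), dims[1])
  structure(list(geom = geom, type = type, age = age, c_age = c_age,
                 c_climate = c_climate, c_co2 = c_co2, c_total = c_total,
                 status = status), class = "forest_state")
}

#' @export
print.forest_state <- function(x, ...) {
  tab <- table(factor(x$status, levels = .ST,
                      labels = names(.ST)))
  cat("forest_state:", paste(sprintf("%s=%d", names(tab), tab),
                             collapse = ", "), "\n")
  cat(sprintf("  forest pixels: %d, mean density %.1f Mg/ha\n",
              sum(x$type != 0),
              mean(x$c_total[x$type != 0])))
  invisible(x)
}

#' @export
plot.forest_state <- function(x, layer = c("c_total", "type", "age"), ...) {
  layer <- match.arg(layer)
  m <- x[[layer]]
  graphics::image(t(m[nrow(m):1, , drop = FALSE]), axes = FALSE,
                  main = layer, ...)
  invisible(x)
}

# per-pixel components for pixels of one type at given ages and climates
.pixel_components <- function(fit, t, mat0, map0, matf, mapf, F) {
  c_age <- age_component(fit, t, mat0, map0)
  c_ac <- as.numeric(eval_age_climate(fit, t, matf, mapf, clip = TRUE))
  list(c_age = c_age,
       c_climate = climate_component(c_ac, c_age),
       c_co2 = co2_component(F, c_age))
}

#' Baseline (2020) forest state
#'
#' Builds the baseline per-pixel state from fused type and age maps:
#' components are the fitted age+climate prediction at 2020 climate (so the
#' climate component is zero by construction) plus a CO2 component for the
#' baseline-year concentration relative to the reference concentration.
#'
#' @param geom A [grid_geom()].
#' @param type Fused cover map (0 = non-forest).
#' @param age Fused age map (years, `NA` outside forest).
#' @param fits Named list of `growth_fit` objects, keyed by type code.
#' @param climate List with `mat` and `map` matrices for 2020.
#' @param F_baseline Fertilization ratio at the baseline year (default 1).
#' @return A [forest_state()].
#' @export
baseline_state <- function(geom, type, age, fits, climate, F_baseline = 1) {
  dims <- c(geom$nrow, geom$ncol)
  z <- matrix(0, dims[1], dims[2])
  c_age <- z; c_climate <- z; c_co2 <- z
  age_out <- matrix(NA_real_, dims[1], dims[2])
  for (ty in sort(unique(type[type != 0]))) {
    fit <- fits[[as.character(ty)]]
    if (is.null(fit))
      stop("configuration error: no growth fit for type ", ty)
    idx <- which(type == ty)
    if (any(is.na(age[idx])))
      stop("data error: missing stand age on forested pixel(s)")
    ca <- age_component(fit, age[idx], climate$mat[idx], climate$map[idx])
    c_age[idx] <- ca
    c_co2[idx] <- co2_component(F_baseline, ca)
    age_out[idx] <- age[idx]
  }
  forest_state(geom, type, age_out, c_age, c_climate, c_co2)
}

#' Project one period under the nature scenario
#'
#' Per 2020 forest pixel of type A with stand age t: (i) if the future
#' suitability of A strictly exceeds A's MTSS, the pixel remains type A with
#' age `t + N` and its components are recomputed (age component at future age
#' with 2020 climate; climate component as the difference to the prediction
#' under future climate; CO2 component `(F - 1) * c_age`); (ii) otherwise, if
#' some other type qualifies, the qualifying type with the highest future
#' suitability replaces A at stand age `N/2`, with components from that
#' type's fit; (iii) otherwise the pixel is lost (becomes non-forest with
#' zero components). Non-forest baseline pixels stay non-forest: the nature
#' scenario never creates forest.
#'
#' @param state Baseline [forest_state()].
#' @param suit Per-type suitability: named list of probability matrices for
#'   the target period/ssp.
#' @param mtss Named vector of MTSS thresholds per type.
#' @param climate_now,climate_future Lists with `mat`/`map` matrices.
#' @param fits Named list of `growth_fit` per type code.
#' @param F Period-mean fertilization ratio.
#' @param spec A [scenario_spec()].
#' @return A new [forest_state()] with status flags remained/replaced/lost.
#' @export
step_nature <- function(state, suit, mtss, climate_now, climate_future,
                        fits, F, spec) {
  geom <- state$geom
  dims <- c(geom$nrow, geom$ncol)
  ncell <- prod(dims)
  tcodes <- sort(as.integer(names(suit)))
  occupied <- sort(unique(state$type[state$type != 0]))
  if (!all(occupied %in% tcodes))
    stop("configuration error: missing suitability layer for occupied type(s) ",
         paste(setdiff(occupied, tcodes), collapse = ", "))
  N <- spec$N
  age_half <- if (spec$round_ages) round(N / 2) else N / 2

  P <- vapply(as.character(tcodes), function(tc) as.numeric(suit[[tc]]),
              numeric(ncell))
  qual <- sweep(P, 2, mtss[as.character(tcodes)], ">")

  type0 <- as.vector(state$type)
  new_type <- integer(ncell)
  new_age <- rep(NA_real_, ncell)
  status <- integer(ncell)

  forest <- type0 != 0L
  col_of <- match(type0, tcodes)            # NA for non-forest
  own_ok <- rep(FALSE, ncell)
  own_ok[forest] <- qual[cbind(which(forest), col_of[forest])]

  remain <- forest & own_ok
  new_type[remain] <- type0[remain]
  new_age[remain] <- as.vector(state$age)[remain] + N
  status[remain] <- .ST[["remained"]]

  # replacement: best OTHER qualifying type
  cand <- forest & !own_ok
  if (any(cand)) {
    Pq <- P
    Pq[!qual] <- -Inf
    Pq[cbind(which(forest), col_of[forest])] <- -Inf   # exclude own type
    ci <- which(cand)
    best_col <- max.col(Pq[ci, , drop = FALSE], ties.method = "first")
    best_p <- Pq[cbind(ci, best_col)]
    has_best <- is.finite(best_p)
    rep_idx <- ci[has_best]
    new_type[rep_idx] <- tcodes[best_col[has_best]]
    new_age[rep_idx] <- age_half
    status[rep_idx] <- .ST[["replaced"]]
    lost_idx <- ci[!has_best]
    status[lost_idx] <- .ST[["lost"]]
  }

  z <- numeric(ncell)
  c_age <- z; c_climate <- z; c_co2 <- z
  mat0 <- as.vector(climate_now$mat); map0 <- as.vector(climate_now$map)
  matf <- as.vector(climate_future$mat); mapf <- as.vector(climate_future$map)
  for (ty in sort(unique(new_type[new_type != 0]))) {
    fit <- fits[[as.character(ty)]]
    if (is.null(fit))
      stop("configuration error: no growth fit for type ", ty)
    idx <- which(new_type == ty)
    cp <- .pixel_components(fit, new_age[idx], mat0[idx], map0[idx],
                            matf[idx], mapf[idx], F)
    c_age[idx] <- cp$c_age
    c_climate[idx] <- cp$c_climate
    c_co2[idx] <- cp$c_co2
  }

  forest_state(geom,
               matrix(new_type, dims[1]), matrix(new_age, dims[1]),
               matrix(c_age, dims[1]), matrix(c_climate, dims[1]),
               matrix(c_co2, dims[1]), status = matrix(status, dims[1]))
}

#' Fit the afforestation area-target regression
#'
#' Ordinary least squares line through the national forest-area target series
#' (year, Mha), used to interpolate the target for each projection period.
#'
#' @param series Data frame with columns `year` and `area_mha` (>= 2 distinct
#'   years).
#' @return Object of class `area_target_model` with `slope` (Mha/yr),
#'   `intercept` (Mha), `r2`, `rmse` and the underlying `lm` fit. Use
#'   `predict(model, year)` for interpolation.
#' @examples
#' m <- fit_area_targets(data.frame(year = c(2025, 2035),
#'                                  area_mha = c(200, 210)))
#' predict(m, 2050)
#' @export
fit_area_targets <- function(series) {
  if (!all(c("year", "area_mha") %in% names(series)))
    stop("fit error: series needs columns year and area_mha")
  if (length(unique(series$year)) < 2)
    stop("fit error: need >= 2 distinct years")
  fit <- stats::lm(area_mha ~ year, data = series)
  res <- stats::residuals(fit)
  tss <- sum((series$area_mha - mean(series$area_mha))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = if (tss > 0) 1 - sum(res^2) / tss else 1,
                 rmse = sqrt(mean(res^2)),
                 n = nrow(series), lm = fit),
            class = "area_target_model")
}

#' @export
print.area_target_model <- function(x, ...) {
  cat(sprintf("area_target_model: %.4g Mha/yr, intercept %.4g Mha (R2 %.3f, RMSE %.3g, n = %d)\n",
              x$slope, x$intercept, x$r2, x$rmse, x$n))
  invisible(x)
}

#' @export
predict.area_target_model <- function(object, year, ...) {
  object$intercept + object$slope * year
}

#' Afforestation area demand
#'
#' Area still to be planted: the target minus the forest area remaining under
#' the nature scenario, clipped at zero (no removal when the remaining area
#' already exceeds the target).
#'
#' @param target Target forest area (Mha, >= 0).
#' @param remaining_nature Remaining forest area under the nature scenario
#'   (Mha, >= 0).
#' @return Mha to plant.
#' @export
required_afforestation <- function(target, remaining_nature) {
  if (any(target < 0) || any(remaining_nature < 0))
    stop("configuration error: areas must be >= 0")
  pmax(target - remaining_nature, 0)
}

#' Allocate afforestation over suitable non-forest pixels
#'
#' Candidate pixels are the non-forest pixels of the nature-scenario result
#' on which at least one forest type's future suitability exceeds its MTSS.
#' Pixels are drawn uniformly at random without replacement until the
#' cumulative pixel area reaches the demand (or candidates run out, with a
#' warning). Each planted pixel receives the qualifying type with the highest
#' suitability at stand age `N/2`, with components from that type's fit. The
#' draw is reproducible per seed.
#'
#' @param state_nature Nature-scenario [forest_state()].
#' @param suit,mtss Per-type suitability matrices and thresholds.
#' @param area_needed_mha Demand in Mha (>= 0).
#' @param climate_now,climate_future Climate lists (`mat`, `map`).
#' @param fits Named list of `growth_fit` per type.
#' @param F Period-mean fertilization ratio.
#' @param spec A [scenario_spec()].
#' @param seed RNG seed for the random draw.
#' @return A new [forest_state()] with planted pixels flagged.
#' @export
allocate_afforestation <- function(state_nature, suit, mtss, area_needed_mha,
                                   climate_now, climate_future, fits, F,
                                   spec, seed = 1L) {
  if (area_needed_mha < 0)
    stop("configuration error: area_needed must be >= 0")
  geom <- state_nature$geom
  ncell <- geom$nrow * geom$ncol
  tcodes <- sort(as.integer(names(suit)))
  P <- vapply(as.character(tcodes), function(tc) as.numeric(suit[[tc]]),
              numeric(ncell))
  qual <- sweep(P, 2, mtss[as.character(tcodes)], ">")
  candidates <- which(as.vector(state_nature$type) == 0L & rowSums(qual) > 0)
  out <- state_nature
  if (area_needed_mha == 0 || !length(candidates)) {
    if (area_needed_mha > 0)
      warning(sprintf("afforestation shortfall: %.4g Mha unmet (no candidates)",
                      area_needed_mha))
    return(out)
  }
  areas_mha <- as.vector(cell_area_matrix(geom)) / 1e6
  set.seed(seed)
  ord <- sample(candidates)
  csum <- cumsum(areas_mha[ord])
  if (csum[length(csum)] < area_needed_mha) {
    warning(sprintf("afforestation shortfall: %.4g of %.4g Mha unmet",
                    area_needed_mha - csum[length(csum)], area_needed_mha))
    take <- ord
  } else {
    take <- ord[seq_len(which(csum >= area_needed_mha)[1])]
  }
  Pq <- P
  Pq[!qual] <- -Inf
  best_col <- max.col(Pq[take, , drop = FALSE], ties.method = "first")
  plant_type <- tcodes[best_col]
  age_half <- if (spec$round_ages) round(spec$N / 2) else spec$N / 2

  mat0 <- as.vector(climate_now$mat); map0 <- as.vector(climate_now$map)
  matf <- as.vector(climate_future$mat); mapf <- as.vector(climate_future$map)
  for (ty in sort(unique(plant_type))) {
    fit <- fits[[as.character(ty)]]
    if (is.null(fit))
      stop("configuration error: no growth fit for type ", ty)
    idx <- take[plant_type == ty]
    cp <- .pixel_components(fit, rep(age_half, length(idx)), mat0[idx],
                            map0[idx], matf[idx], mapf[idx], F)
    out$type[idx] <- ty
    out$age[idx] <- age_half
    out$c_age[idx] <- cp$c_age
    out$c_climate[idx] <- cp$c_climate
    out$c_co2[idx] <- cp$c_co2
    out$status[idx] <- .ST[["planted"]]
  }
  out$c_total <- out$c_age + out$c_climate + out$c_co2
  out
}

#' Afforestation replicate ensemble
#'
#' Repeats the random allocation once per seed in `spec$seeds` and averages:
#' the reported totals are the replicate mean with the between-replicate
#' standard deviation.
#'
#' @inheritParams allocate_afforestation
#' @param carbon_fraction Carbon fraction applied in the summaries (see
#'   [total_agb()]).
#' @return Object of class `scenario_ensemble`: list with `states` (one
#'   [forest_state()] per replicate), `replicates` (per-replicate summary
#'   table), `mean` and `sd` (named numeric summaries).
#' @export
run_ensemble <- function(state_nature, suit, mtss, area_needed_mha,
                         climate_now, climate_future, fits, F, spec,
                         carbon_fraction = 1) {
  areas <- cell_area_matrix(state_nature$geom)
  states <- lapply(spec$seeds, function(s)
    allocate_afforestation(state_nature, suit, mtss, area_needed_mha,
                           climate_now, climate_future, fits, F, spec,
                           seed = s))
  reps <- do.call(rbind, lapply(states, function(st) {
    fo <- st$type != 0
    data.frame(
      total_agb_pgc = total_agb(st, areas, carbon_fraction),
      area_mha = sum(areas[fo]) / 1e6,
      mean_density = stats::weighted.mean(st$c_total[fo], areas[fo]),
      mean_age = stats::weighted.mean(st$age[fo], areas[fo]))
  }))
  reps$seed <- spec$seeds
  mu <- colMeans(reps[, 1:4])
  sdv <- apply(reps[, 1:4], 2, stats::sd)
  structure(list(states = states, replicates = reps, mean = mu, sd = sdv,
                 spec = spec), class = "scenario_ensemble")
}

#' @export
print.scenario_ensemble <- function(x, ...) {
  cat(sprintf("scenario_ensemble: %s/%s, %d replicates\n", x$spec$period,
              x$spec$ssp, nrow(x$replicates)))
  cat(sprintf("  total AGB %.3f +/- %.3f PgC, area %.2f Mha\n",
              x$mean[["total_agb_pgc"]], x$sd[["total_agb_pgc"]],
              x$mean[["area_mha"]]))
  invisible(x)
}
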