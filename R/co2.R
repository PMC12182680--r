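#' CO2 concentration trajectory
#'
#' Ordered (year, ppm) pairs for one emission scenario.
#'
#' @param year Integer years, strictly increasing.
#' @param ppm Atmospheric CO2 concentrations (> 0).
#' @param ssp Scenario label (e.g. `"SSP245"`).
#' @return Data frame of class `co2_trajectory` with attribute `ssp`.
#' @export
co2_trajectory <- function(year, ppm, ssp = "SSP245") {
  if (length(year) != length(ppm))
    stop("configuration error: year and ppm lengths differ")
  if (any(diff(year) <= 0))
    stop("configuration error: years must be strictly increasing")
  if (any(ppm <= 0)) stop("configuration error: ppm must be > 0")
  structure(data.frame(year = as.integer(year), ppm = ppm),
            ssp = ssp, class = c("co2_trajectory", "data.frame"))
}

#' Vegetation-carbon response curve to CO2
#'
#' Tabulated cVeg (vegetation biomass carbon density) against CO2
#' concentration, as produced by an Earth-system model's idealised
#' 1-percent-per-year CO2-increase experiment. cVeg must be non-decreasing in
#' ppm for the fertilization ratio to be monotone.
#'
#' @param ppm Strictly increasing CO2 concentrations.
#' @param cveg Non-negative cVeg densities.
#' @param source Label for the producing model (or `"ensemble"`).
#' @return Data frame of class `cveg_curve` with attribute `source`.
#' @export
cveg_curve <- function(ppm, cveg, source = "ensemble") {
  if (length(ppm) != length(cveg))
    stop("configuration error: ppm and cveg lengths differ")
  if (any(diff(ppm) <= 0))
    stop("configuration error: ppm must be strictly increasing")
  if (any(cveg < 0)) stop("configuration error: cveg must be >= 0")
  structure(data.frame(ppm = ppm, cveg = cveg),
            source = source, class = c("cveg_curve", "data.frame"))
}

.interp_cveg <- function(curve, ppm) {
  if (any(ppm < min(curve$ppm)) || any(ppm > max(curve$ppm)))
    stop("extrapolation error: ppm outside the cVeg curve's tabulated range")
  stats::approx(curve$ppm, curve$cveg, xout = ppm, rule = 1)$y
}

#' CO2-fertilization ratio F
#'
#' `F = cVeg(ppm_t) / cVeg(ppm_baseline)`, with cVeg evaluated by linear
#' interpolation on the tabulated response curve. With a list of curves (a
#' multi-model ensemble) the per-curve ratios are averaged, keeping each
#' model self-normalised. Extrapolation beyond a curve's tabulated range is
#' refused.
#'
#' @param curve A [cveg_curve()] or a list of them.
#' @param ppm_t CO2 concentration(s) of interest.
#' @param ppm_baseline Baseline concentration; the default 371.8 ppm is the
#'   1978-2020 mean.
#' @return Dimensionless ratio(s), same length as `ppm_t`.
#' @examples
#' cv <- cveg_curve(seq(300, 900, 50), seq(300, 900, 50))
#' compute_F(cv, 743.6)  # linear curve: F = 743.6 / 371.8 = 2
#' @export
compute_F <- function(curve, ppm_t, ppm_baseline = 371.8) {
  if (inherits(curve, "cveg_curve")) curve <- list(curve)
  if (!length(curve)) stop("configuration error: no cVeg curves supplied")
  per <- vapply(curve, function(cv) {
    base <- .interp_cveg(cv, ppm_baseline)
    if (base == 0)
      stop("division error: cVeg at the baseline concentration is 0")
    .interp_cveg(cv, ppm_t) / base
  }, numeric(length(ppm_t)))
  if (length(ppm_t) == 1L) mean(per) else rowMeans(matrix(per,
                                                          nrow = length(ppm_t)))
}

#' Years covered by a projection period
#'
#' @param period `"2030s"`, `"2050s"` or `"2070s"` (the 2021-2040, 2041-2060
#'   and 2061-2080 windows).
#' @return Integer vector of years.
#' @export
period_years <- function(period) {
  switch(match.arg(period, c("2030s", "2050s", "2070s")),
         "2030s" = 2021:2040, "2050s" = 2041:2060, "2070s" = 2061:2080)
}

#' Period-mean CO2-fertilization ratio
#'
#' Arithmetic mean of [compute_F()] over every year of the period (inclusive
#' bounds), using the scenario's concentration trajectory.
#'
#' @param curve A [cveg_curve()] or list of them.
#' @param trajectory A [co2_trajectory()].
#' @param period Projection period (see [period_years()]).
#' @param ppm_baseline Baseline concentration (ppm).
#' @return Scalar mean ratio.
#' @export
period_mean_F <- function(curve, trajectory, period, ppm_baseline = 371.8) {
  yrs <- period_years(period)
  idx <- match(yrs, trajectory$year)
  if (anyNA(idx))
    stop("coverage error: trajectory is missing year(s) ",
         paste(yrs[is.na(idx)], collapse = ", "))
  mean(compute_F(curve, trajectory$ppm[idx], ppm_baseline))
}

#' CO2 component of future AGB
#'
#' `(F - 1) * C_age`: the extra biomass attributable to CO2 fertilization on
#' top of the age component. Negative when `F < 1`.
#'
#' @param F Fertilization ratio (> 0).
#' @param c_age Age component (Mg/ha, >= 0).
#' @return Mg/ha.
#' @export
co2_component <- function(F, c_age) {
  if (any(F <= 0)) stop("parameter error: F must be > 0")
  (F - 1) * c_age
}
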