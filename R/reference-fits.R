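#' Published growth-model parameters for China's 15 primary forest types
#'
#' A transcription of published climate-augmented growth-model fits for the
#' 15 primary forest types (five classes of evergreen/deciduous needle- and
#' broad-leaved plus mixed forest, crossed with climatic zones) used in
#' national AGB projections for China: selected family, sample size, curve
#' parameters (`mu`, and `k` or `c`/`alpha`), climate coefficients (`a`, `b`,
#' `d`) and fit metrics (RMSE, R2, AIC). Useful for worked examples: e.g. the
#' Michaelis-Menten asymptote for a type is its `mu`, and the age at half the
#' asymptote is its `k`.
#'
#' @return Data frame with columns `forest_type`, `n`, `model`, `rmse`, `r2`,
#'   `aic`, `mu`, `k`, `c`, `alpha`, `a`, `b`, `d`.
#' @examples
#' ref <- reference_growth_fits()
#' subset(ref, model == "MM")[, c("forest_type", "mu", "k")]
#' @export
reference_growth_fits <- function() {
  path <- system.file("extdata", "reference_growth_fits.csv",
                      package = "forestcarbon", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
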