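#' Evaluate a biomass-age growth function
#'
#' The three saturating growth families used for biomass-age relationships,
#' each with asymptote `mu` (Mg/ha):
#' \describe{
#'   \item{MM (Michaelis-Menten)}{`AGB = mu * t / (k + t)`; `k` (years) is the
#'     age at which half the asymptote is reached.}
#'   \item{MO (monomolecular)}{`AGB = mu * (1 - c * exp(-alpha * t))`, with
#'     `c >= 1` so growth starts at or below zero and saturates at `mu`.}
#'   \item{L (logistic)}{`AGB = mu / (1 + c * exp(-alpha * t))`, `c >= 1`.}
#' }
#'
#' @param family One of `"MM"`, `"MO"`, `"L"`.
#' @param params Named numeric vector/list: `mu` and `k` (MM) or `mu`, `c`,
#'   `alpha` (MO, L).
#' @param t Stand age(s) in years, `>= 0`.
#' @return AGB density in Mg/ha, same length as `t`.
#' @examples
#' eval_growth("MM", c(mu = 59.98, k = 357.71), c(0, 357.71, 1e9))
#' @export
eval_growth <- function(family, params, t) {
  family <- match.arg(family, c("MM", "MO", "L"))
  p <- as.list(params)
  if (any(!vapply(p, is.finite, logical(1))))
    stop("parameter error: non-finite growth parameters")
  if (p$mu <= 0) stop("parameter error: mu must be > 0")
  if (any(t < 0)) stop("parameter error: stand age must be >= 0")
  out <- switch(family,
    MM = {
      if (p$k <= 0) stop("parameter error: k must be > 0")
      p$mu * t / (p$k + t)
    },
    MO = {
      if (p$alpha <= 0) stop("parameter error: alpha must be > 0")
      if (p$c < 1) stop("parameter error: c must be >= 1")
      p$mu * (1 - p$c * exp(-p$alpha * t))
    },
    L = {
      if (p$alpha <= 0) stop("parameter error: alpha must be > 0")
      if (p$c < 1) stop("parameter error: c must be >= 1")
      p$mu / (1 + p$c * exp(-p$alpha * t))
    })
  out
}

#' Evaluate the climate-augmented growth model
#'
#' The age+climate biomass model `f(t) + a*MAT + b*MAP + d`, where `f` is one
#' of the growth families of [eval_growth()], MAT is mean annual temperature
#' (degC) and MAP mean annual precipitation (mm). The linear climate term can
#' drive predictions negative at small ages; negative values are clipped to 0
#' (with the clipped count retrievable via `attr(, "n_clipped")` when
#' `clip = TRUE`).
#'
#' @param fit A [fit_growth()] object, or a list with elements `family` and
#'   `coefficients` (named: growth parameters plus `a`, `b`, `d`).
#' @param t Stand age(s), years.
#' @param mat,map Climate covariates (degC, mm), recycled against `t`.
#' @param clip Clip negative predictions to 0 (default `TRUE`).
#' @return AGB density in Mg/ha.
#' @export
eval_age_climate <- function(fit, t, mat, map, clip = TRUE) {
  cf <- fit$coefficients
  f <- eval_growth(fit$family, cf, t)
  out <- f + cf[["a"]] * mat + cf[["b"]] * map + cf[["d"]]
  if (clip) {
    ncl <- sum(out < 0)
    out <- pmax(out, 0)
    attr(out, "n_clipped") <- ncl
  }
  out
}

.family_pars <- function(family) {
  switch(family, MM = c("mu", "k"), MO = c("mu", "c", "alpha"),
         L = c("mu", "c", "alpha"))
}

# residual sum of squares for transformed parameter vector
.growth_rss <- function(theta, family, t, agb, mat, map, climate) {
  cf <- .theta_to_coef(theta, family, climate)
  f <- switch(family,
    MM = cf[["mu"]] * t / (cf[["k"]] + t),
    MO = cf[["mu"]] * (1 - cf[["c"]] * exp(-cf[["alpha"]] * t)),
    L  = cf[["mu"]] / (1 + cf[["c"]] * exp(-cf[["alpha"]] * t)))
  pred <- f + cf[["a"]] * mat + cf[["b"]] * map + cf[["d"]]
  rss <- sum((agb - pred)^2)
  if (!is.finite(rss)) 1e300 else rss
}

# optimize log(mu), log(k)/log(alpha), log(c) (bounded below at 0 so c >= 1)
.theta_to_coef <- function(theta, family, climate) {
  ng <- if (family == "MM") 2L else 3L
  cf <- if (family == "MM") c(mu = exp(theta[1]), k = exp(theta[2]))
        else c(mu = exp(theta[1]), c = exp(theta[2]), alpha = exp(theta[3]))
  if (climate) c(cf, a = theta[ng + 1], b = theta[ng + 2], d = theta[ng + 3])
  else c(cf, a = 0, b = 0, d = theta[ng + 1])
}

.coef_to_theta <- function(cf, family, climate) {
  g <- if (family == "MM") c(log(cf[["mu"]]), log(cf[["k"]]))
       else c(log(cf[["mu"]]), log(max(cf[["c"]], 1)), log(cf[["alpha"]]))
  if (climate) c(g, cf[["a"]], cf[["b"]], cf[["d"]]) else c(g, cf[["d"]])
}

.theta_bounds <- function(family, climate) {
  ng <- if (family == "MM") 2L else 3L
  nl <- if (climate) 3L else 1L
  lower <- rep(-Inf, ng + nl)
  upper <- rep(Inf, ng + nl)
  if (family != "MM") lower[2] <- 0        # c >= 1
  lower[1] <- log(1e-6); upper[1] <- log(1e6)   # mu
  if (family == "MM") { lower[2] <- log(1e-3); upper[2] <- log(1e6) }
  else { upper[2] <- log(1e12); lower[3] <- log(1e-6); upper[3] <- log(10) }
  list(lower = lower, upper = upper)
}

#' Fit a climate-augmented biomass-age growth model
#'
#' Jointly estimates the growth-curve parameters and the linear climate
#' coefficients of `AGB = f(t) + a*MAT + b*MAP + d` by constrained nonlinear
#' least squares (subject to `mu, k, alpha > 0` and `c >= 1`). A fixed
#' multi-start grid over the nonlinear parameters (asymptote at 0.5/1/2 times
#' the observed maximum; half-saturation ages and rate constants spanning
#' decades) makes the fit deterministic and robust to local minima; the
#' linear coefficients are initialised by regressing the residual from each
#' starting curve on MAT and MAP.
#'
#' @param data Data frame with columns `t` (stand age, years, > 0), `agb`
#'   (Mg/ha, >= 0) and, unless `climate = FALSE`, `mat` (degC) and `map` (mm).
#' @param family Growth family, `"MM"`, `"MO"` or `"L"`.
#' @param climate If `FALSE`, fit the pure growth curve with `a = b = 0`
#'   (intercept `d` retained).
#' @param label Optional label (e.g. the forest type) used in messages.
#' @return An object of class `growth_fit` with components `family`,
#'   `coefficients` (`mu`, `k` or `c`/`alpha`, `a`, `b`, `d`), `rss`, `rmse`,
#'   `r2`, `aic` (Gaussian least-squares AIC `n*log(RSS/n) + 2p`, `p`
#'   counting all free parameters including the intercept), `n`, `fitted`,
#'   `residuals` and the call. Standard methods (`print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `plot`, `simulate`, `AIC`) apply.
#' @examples
#' set.seed(1)
#' t <- runif(80, 1, 150)
#' d <- data.frame(t = t, agb = 100 * t / (100 + t) + rnorm(80, 0, 5),
#'                 mat = rnorm(80, 10), map = rnorm(80, 900, 100))
#' fit <- fit_growth(d, "MM")
#' coef(fit)
#' @export
fit_growth <- function(data, family = c("MM", "MO", "L"), climate = TRUE,
                       label = NULL) {
  family <- match.arg(family)
  need <- c("t", "agb", if (climate) c("mat", "map"))
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("fit error: missing column(s) ", paste(miss, collapse = ", "),
         if (!is.null(label)) paste0(" for type ", label))
  t <- as.numeric(data$t); agb <- as.numeric(data$agb)
  mat <- if (climate) as.numeric(data$mat) else numeric(length(t))
  map <- if (climate) as.numeric(data$map) else numeric(length(t))
  if (any(!is.finite(t)) || any(!is.finite(agb)))
    stop("fit error: non-finite survey values")
  if (any(t <= 0)) stop("fit error: stand ages must be > 0")
  n <- length(t)
  p <- length(.family_pars(family)) + if (climate) 3L else 1L
  who <- if (is.null(label)) family else paste(family, "for", label)
  if (n < p + 1)
    stop("fit error: too few records (", n, ") to fit ", who)
  if (stats::var(agb) == 0)
    stop("fit error: degenerate data (constant AGB) for ", who)
  if (stats::var(t) == 0)
    stop("fit error: degenerate data (constant age) for ", who)

  mu0 <- c(0.5, 1, 2) * max(agb)
  k0 <- c(15, 50, 150, 450)
  alpha0 <- c(0.01, 0.03, 0.1, 0.3)
  c0 <- c(1, 20)
  starts <- if (family == "MM") {
    expand.grid(mu = mu0, k = k0)
  } else {
    expand.grid(mu = mu0, c = c0, alpha = alpha0)
  }
  bounds <- .theta_bounds(family, climate)
  best <- NULL
  X <- if (climate) cbind(1, mat, map) else matrix(1, n, 1)
  for (i in seq_len(nrow(starts))) {
    st <- as.list(starts[i, , drop = FALSE])
    f0 <- eval_growth(family, st, t)
    lc <- stats::.lm.fit(X, agb - f0)$coefficients
    cf0 <- if (climate) {
      c(unlist(st), a = lc[2], b = lc[3], d = lc[1])
    } else c(unlist(st), a = 0, b = 0, d = lc[1])
    names(cf0) <- sub("\\..*$", "", names(cf0))
    theta0 <- .coef_to_theta(as.list(cf0), family, climate)
    theta0 <- pmin(pmax(theta0, bounds$lower), bounds$upper)
    res <- tryCatch(
      stats::optim(theta0, .growth_rss, family = family, t = t, agb = agb,
                   mat = mat, map = map, climate = climate,
                   method = "L-BFGS-B", lower = bounds$lower,
                   upper = bounds$upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value))
      best <- res
  }
  if (is.null(best))
    stop("fit error: optimizer failed from every start for ", who)
  # polish from the winning start
  res <- tryCatch(
    stats::optim(best$par, .growth_rss, family = family, t = t, agb = agb,
                 mat = mat, map = map, climate = climate,
                 method = "L-BFGS-B", lower = bounds$lower,
                 upper = bounds$upper,
                 control = list(maxit = 1000, factr = 10)),
    error = function(e) NULL)
  if (!is.null(res) && res$value <= best$value) best <- res

  cf <- .theta_to_coef(best$par, family, climate)
  f <- eval_growth(family, cf, t)
  fitted <- f + cf[["a"]] * mat + cf[["b"]] * map + cf[["d"]]
  rss <- sum((agb - fitted)^2)
  tss <- sum((agb - mean(agb))^2)
  out <- structure(list(
    family = family,
    coefficients = cf,
    climate = climate,
    rss = rss,
    rmse = sqrt(rss / n),
    r2 = 1 - rss / tss,
    aic = n * log(rss / n) + 2 * p,
    n = n,
    n_par = p,
    fitted = fitted,
    residuals = agb - fitted,
    data = data.frame(t = t, agb = agb, mat = mat, map = map),
    label = label,
    convergence = best$convergence,
    call = match.call()), class = "growth_fit")
  out
}

#' @export
print.growth_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Climate-augmented %s growth fit%s (n = %d)\n", x$family,
              if (!is.null(x$label)) paste0(" [", x$label, "]") else "", x$n))
  print(round(x$coefficients, digits))
  cat(sprintf("RMSE %.3f Mg/ha, R2 %.3f, AIC %.2f\n", x$rmse, x$r2, x$aic))
  invisible(x)
}

#' @export
summary.growth_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.growth_fit")
}

#' @export
print.summary.growth_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  form <- switch(f$family,
    MM = sprintf("%.4g t / (%.4g + t)", f$coefficients[["mu"]],
                 f$coefficients[["k"]]),
    MO = sprintf("%.4g (1 - %.4g exp(-%.4g t))", f$coefficients[["mu"]],
                 f$coefficients[["c"]], f$coefficients[["alpha"]]),
    L = sprintf("%.4g / (1 + %.4g exp(-%.4g t))", f$coefficients[["mu"]],
                f$coefficients[["c"]], f$coefficients[["alpha"]]))
  cat("Growth curve: f(t) =", form, "\n")
  cat(sprintf("Climate term: %+.4g*MAT %+.4g*MAP %+.4g\n",
              f$coefficients[["a"]], f$coefficients[["b"]],
              f$coefficients[["d"]]))
  cat("Residual quartiles:\n")
  print(stats::quantile(f$residuals))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) object$coefficients

#' @export
fitted.growth_fit <- function(object, ...) object$fitted

#' @export
residuals.growth_fit <- function(object, ...) object$residuals

#' Predict AGB from a fitted growth model
#'
#' @param object A `growth_fit`.
#' @param newdata Data frame with columns `t`, `mat`, `map` (climate columns
#'   may be omitted for a pure growth fit). Defaults to the training data.
#' @param clip Clip negative predictions to 0 (default `TRUE`).
#' @param ... Unused.
#' @return Numeric vector of AGB densities (Mg/ha).
#' @export
predict.growth_fit <- function(object, newdata = NULL, clip = TRUE, ...) {
  if (is.null(newdata)) newdata <- object$data
  mat <- if (!is.null(newdata$mat)) newdata$mat else 0
  map <- if (!is.null(newdata$map)) newdata$map else 0
  out <- eval_age_climate(object, newdata$t, mat, map, clip = clip)
  attr_ncl <- attr(out, "n_clipped")
  out <- as.numeric(out)
  attr(out, "n_clipped") <- attr_ncl
  out
}

#' @export
AIC.growth_fit <- function(object, ..., k = 2) object$aic

#' @export
plot.growth_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$t, d$agb, xlab = "stand age (years)",
                 ylab = "AGB (Mg/ha)",
                 main = sprintf("%s fit%s", x$family,
                                if (!is.null(x$label))
                                  paste0(" [", x$label, "]") else ""), ...)
  tt <- seq(0, max(d$t) * 1.1, length.out = 200)
  cf <- x$coefficients
  curve_agb <- eval_growth(x$family, cf, tt) +
    cf[["a"]] * mean(d$mat) + cf[["b"]] * mean(d$map) + cf[["d"]]
  graphics::lines(tt, pmax(curve_agb, 0), lwd = 2)
  invisible(x)
}

#' Simulate survey responses from a fitted growth model
#'
#' Draws Gaussian noise with the fit's residual RMSE around the model
#' prediction at the training covariates.
#'
#' @param object A `growth_fit`.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return Data frame of `nsim` simulated `agb` columns.
#' @export
simulate.growth_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0,
                                                         object$rmse)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Select the best growth fit by information criterion
#'
#' Ranks candidate fits by AIC (lower is better); exact AIC ties are broken
#' by lower RMSE, then by the fixed family order MM, L, MO. Failed fits
#' (`NULL` entries) are excluded.
#'
#' @param fits List of `growth_fit` objects (typically one per family), `NULL`
#'   entries allowed for failed fits.
#' @return The selected `growth_fit`.
#' @export
select_model <- function(fits) {
  fits <- Filter(function(f) inherits(f, "growth_fit"), fits)
  if (!length(fits))
    stop("selection error: no successful growth fits to choose from")
  fam_rank <- c(MM = 1, L = 2, MO = 3)
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  rmse <- vapply(fits, function(f) f$rmse, numeric(1))
  fr <- fam_rank[vapply(fits, function(f) f$family, character(1))]
  fits[[order(aic, rmse, fr)[1]]]
}

#' Fit all three growth families and select the best
#'
#' @param data Survey records (see [fit_growth()]).
#' @param families Families to try (default all three).
#' @param climate Include the MAT/MAP term (default `TRUE`).
#' @param label Optional label for messages.
#' @return List with `fits` (named list, `NULL` for failures) and `best` (the
#'   [select_model()] winner).
#' @export
fit_growth_models <- function(data, families = c("MM", "MO", "L"),
                              climate = TRUE, label = NULL) {
  fits <- lapply(families, function(fam)
    tryCatch(fit_growth(data, fam, climate = climate, label = label),
             error = function(e) NULL))
  names(fits) <- families
  list(fits = fits, best = select_model(fits))
}

#' Fit growth models per forest type
#'
#' Splits survey records on their `type` column, fits all families per type
#' and keeps the AIC-selected model.
#'
#' @param data Survey records with a `type` column.
#' @param ... Passed to [fit_growth_models()].
#' @return Named list (by type code) of selected `growth_fit` objects.
#' @export
fit_growth_by_type <- function(data, ...) {
  if (is.null(data$type)) stop("fit error: survey records need a type column")
  sp <- split(data, data$type)
  out <- lapply(names(sp), function(ty)
    fit_growth_models(sp[[ty]], label = ty, ...)$best)
  names(out) <- names(sp)
  out
}

#' Age component of future AGB
#'
#' The part of future AGB attributable to stand aging alone: the fitted model
#' evaluated at the future stand age but with baseline-year climate,
#' `f(t_future) + a*MAT_2020 + b*MAP_2020 + d`, clipped at 0.
#'
#' @param fit A `growth_fit`.
#' @param t_future Future stand age(s), years.
#' @param mat_2020,map_2020 Baseline-year climate.
#' @return AGB density (Mg/ha).
#' @export
age_component <- function(fit, t_future, mat_2020, map_2020) {
  as.numeric(eval_age_climate(fit, t_future, mat_2020, map_2020, clip = TRUE))
}

#' Climate component of future AGB
#'
#' Difference between the age+climate prediction (future climate) and the age
#' component (baseline climate); may be negative.
#'
#' @param c_age_climate Age+climate prediction (Mg/ha).
#' @param c_age Age component (Mg/ha).
#' @return Mg/ha, possibly negative.
#' @export
climate_component <- function(c_age_climate, c_age) {
  c_age_climate - c_age
}
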