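test_that("growth families evaluate to their closed forms and limits", {
  # Michaelis-Menten: origin, half-saturation, asymptote
  expect_equal(eval_growth("MM", c(mu = 59.98, k = 357.71), 0), 0)
  expect_equal(eval_growth("MM", c(mu = 59.98, k = 357.71), 357.71),
               59.98 / 2)
  expect_equal(eval_growth("MM", c(mu = 59.98, k = 357.71), 1e9), 59.98,
               tolerance = 1e-6)
  # logistic: midpoint at t = 0 when c = 1, asymptote
  expect_equal(eval_growth("L", c(mu = 10, c = 1, alpha = 0.3), 0), 5)
  expect_equal(eval_growth("L", c(mu = 86.59, c = 8.4e5, alpha = 0.88), 1e6),
               86.59)
  # monomolecular: zero at origin when c = 1, asymptote
  expect_equal(eval_growth("MO", c(mu = 205.882, c = 1, alpha = 0.3), 0), 0)
  expect_equal(eval_growth("MO", c(mu = 205.882, c = 1, alpha = 0.3), 1e6),
               205.882)
  expect_error(eval_growth("MM", c(mu = -5, k = 10), 1), "parameter error")
  expect_error(eval_growth("L", c(mu = 5, c = 0.5, alpha = 0.1), 1),
               "parameter error")
  expect_error(eval_growth("MM", c(mu = NaN, k = 10), 1), "parameter error")
})

test_that("families stay below the asymptote and non-decreasing in age", {
  set.seed(11)
  tgrid <- seq(0, 500, by = 0.5)
  for (i in 1:25) {
    mu <- runif(1, 5, 300)
    pars <- list(
      MM = c(mu = mu, k = runif(1, 10, 500)),
      MO = c(mu = mu, c = runif(1, 1, 5), alpha = runif(1, 0.01, 0.5)),
      L = c(mu = mu, c = runif(1, 1, 1e4), alpha = runif(1, 0.01, 0.5)))
    for (fam in names(pars)) {
      y <- eval_growth(fam, pars[[fam]], tgrid)
      expect_true(all(y <= mu + 1e-9))
      expect_true(all(diff(y) >= -1e-9))
    }
  }
})

test_that("the age+climate model adds the linear term and clips at zero", {
  # f(30) = 100*30/(30+30) = 50, + 1*10 + 0.5*100 + 2 = 112
  fit <- manual_fit("MM", mu = 100, k = 30, a = 1, b = 0.5, d = 2)
  expect_equal(as.numeric(eval_age_climate(fit, 30, 10, 100)), 112)
  # reduction: a = b = d = 0 reproduces the bare curve
  fit0 <- manual_fit("MM", mu = 100, k = 30, a = 0, b = 0, d = 0)
  tt <- c(1, 10, 80, 300)
  expect_equal(as.numeric(eval_age_climate(fit0, tt, 12, 900)),
               eval_growth("MM", c(mu = 100, k = 30), tt))
  # clipping with a count
  fitneg <- manual_fit("MM", mu = 10, k = 30, a = -1000, b = 0, d = 0)
  out <- eval_age_climate(fitneg, 5, 10, 0)
  expect_equal(as.numeric(out), 0)
  expect_equal(attr(out, "n_clipped"), 1)
})

test_that("noiseless data returns the generating parameters (grid-search oracle agrees)", {
  set.seed(21)
  t <- runif(120, 1, 150)
  mat <- runif(120, -4, 16)
  mp <- runif(120, 600, 1600)
  truth <- c(mu = 80, k = 200)
  agb <- eval_growth("MM", truth, t)
  d <- data.frame(t = t, agb = agb, mat = mat, map = mp)
  fit <- fit_growth(d, "MM")
  expect_lt(abs(coef(fit)[["mu"]] - 80) / 80, 1e-3)
  expect_lt(abs(coef(fit)[["k"]] - 200) / 200, 1e-3)
  expect_lt(abs(coef(fit)[["a"]]), 1e-3)
  expect_lt(abs(coef(fit)[["b"]]), 1e-3)
  expect_lt(fit$rmse, 1e-3)
  # independent oracle: coarse grid over (mu, k), profiled linear part,
  # refined by Nelder-Mead on the raw parameters
  grid <- expand.grid(mu = seq(40, 160, by = 10), k = seq(50, 400, by = 25))
  rss_of <- function(p) {
    f <- p[1] * t / (p[2] + t)
    z <- stats::lm.fit(cbind(1, mat, mp), agb - f)
    sum(z$residuals^2)
  }
  rss <- apply(grid, 1, rss_of)
  st <- as.numeric(grid[which.min(rss), ])
  ref <- stats::optim(st, rss_of, control = list(maxit = 2000,
                                                 reltol = 1e-14))
  expect_lt(abs(coef(fit)[["mu"]] - ref$par[1]) / ref$par[1], 1e-3)
  expect_lt(abs(coef(fit)[["k"]] - ref$par[2]) / ref$par[2], 1e-2)
})

test_that("with climate frozen at zero the fit matches a pure curve fit", {
  set.seed(31)
  t <- runif(100, 1, 150)
  agb <- eval_growth("MM", c(mu = 120, k = 90), t) + rnorm(100, 0, 5)
  d <- data.frame(t = t, agb = agb)
  fit <- fit_growth(d, "MM", climate = FALSE)
  expect_equal(coef(fit)[["a"]], 0)
  expect_equal(coef(fit)[["b"]], 0)
  # oracle: nls on the bare curve with intercept
  ref <- stats::nls(agb ~ mu * t / (k + t) + d0,
                    start = list(mu = 120, k = 90, d0 = 0),
                    algorithm = "port", lower = c(1e-6, 1e-6, -Inf),
                    control = stats::nls.control(tol = 1e-10))
  expect_equal(coef(fit)[["mu"]], coef(ref)[["mu"]], tolerance = 1e-3)
  expect_equal(coef(fit)[["k"]], coef(ref)[["k"]], tolerance = 1e-3)
  expect_equal(fit$rss, sum(residuals(ref)^2), tolerance = 1e-6)
})

test_that("degenerate survey data is rejected with a fit error", {
  d <- data.frame(t = 1:10, agb = rep(50, 10), mat = rnorm(10),
                  map = rnorm(10))
  expect_error(fit_growth(d, "MM"), "fit error")
  expect_error(fit_growth(d[1:3, ], "L"), "fit error")
  d2 <- data.frame(t = rep(40, 10), agb = rnorm(10, 50), mat = rnorm(10),
                   map = rnorm(10))
  expect_error(fit_growth(d2, "MM"), "fit error")
})

test_that("model selection ranks by AIC with RMSE and family-order tie-breaks", {
  fake <- function(fam, aic, rmse)
    structure(list(family = fam, aic = aic, rmse = rmse),
              class = "growth_fit")
  expect_identical(select_model(list(fake("MM", 98, 5), fake("L", 100, 4),
                                     fake("MO", 105, 3)))$family, "MM")
  expect_identical(select_model(list(fake("MM", 100, 5),
                                     fake("L", 100, 4)))$family, "L")
  expect_identical(select_model(list(fake("MO", 100, 4),
                                     fake("L", 100, 4)))$family, "L")
  expect_identical(select_model(list(NULL, fake("MO", 105, 3)))$family, "MO")
  expect_error(select_model(list(NULL, NULL)), "selection error")
})

test_that("the selected model has the lowest AIC among the candidates", {
  set.seed(41)
  t <- runif(150, 1, 150)
  mat <- runif(150, -4, 16); mp <- runif(150, 600, 1600)
  agb <- eval_growth("L", c(mu = 150, c = 8, alpha = 0.08), t) +
    2 * mat + 0.05 * mp + 5 + rnorm(150, 0, 8)
  res <- fit_growth_models(data.frame(t = t, agb = agb, mat = mat, map = mp))
  aics <- vapply(Filter(Negate(is.null), res$fits), AIC, numeric(1))
  expect_equal(AIC(res$best), min(aics))
})

test_that("growth_fit methods are coherent with the stored data", {
  set.seed(51)
  t <- runif(80, 1, 150)
  mat <- runif(80, -4, 16); mp <- runif(80, 600, 1600)
  d <- data.frame(t = t, agb = 100 * t / (t + 100) + 2 * mat + 0.05 * mp +
                    rnorm(80, 0, 6), mat = mat, map = mp)
  fit <- fit_growth(d, "MM")
  expect_equal(fitted(fit) + residuals(fit), d$agb)
  expect_equal(as.numeric(predict(fit)),
               pmax(fitted(fit), 0))
  expect_equal(fit$rmse, sqrt(mean(residuals(fit)^2)))
  expect_equal(fit$aic, fit$n * log(fit$rss / fit$n) + 2 * 5)
  expect_output(print(fit), "MM growth fit")
  expect_output(print(summary(fit)), "Growth curve")
  sims <- simulate(fit, nsim = 3, seed = 9)
  expect_identical(dim(sims), c(80L, 3L))
})

test_that("age and climate components behave as the decomposition demands", {
  fit <- manual_fit("MM", mu = 100, k = 120, a = 2, b = 0.05, d = 5)
  # consistency: future age equal to current age reproduces the 2020 value
  now <- age_component(fit, 40, 10, 900)
  expect_equal(now, as.numeric(eval_age_climate(fit, 40, 10, 900)))
  # monotone in future age for MM
  expect_true(age_component(fit, 70, 10, 900) >= age_component(fit, 50, 10, 900))
  # climate component: zero when climate unchanged, sign follows b for a MAP rise
  c_now <- age_component(fit, 60, 10, 900)
  expect_equal(climate_component(c_now, c_now), 0)
  c_fut <- as.numeric(eval_age_climate(fit, 60, 10, 1000))
  expect_gt(climate_component(c_fut, c_now), 0)
  expect_equal(climate_component(120, 100), 20)
})
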