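# Small randomised scenario worlds with hand-built growth fits, used by the
# scenario-engine tests and the oracle-equivalence acceptance check.

manual_fit <- function(family, ...) {
  cf <- c(...)
  structure(list(family = family, coefficients = cf), class = "growth_fit")
}

random_scenario_world <- function(seed, nrow = 8, ncol = 8, n_types = 3,
                                  forest_frac = 0.6) {
  set.seed(seed)
  g <- grid_geom(nrow, ncol, cell_size = 0.5, lat_origin = 45)
  ncell <- nrow * ncol
  codes <- seq_len(n_types)
  type <- matrix(ifelse(runif(ncell) < forest_frac,
                        sample(codes, ncell, replace = TRUE), 0L),
                 nrow, ncol)
  age <- matrix(NA_real_, nrow, ncol)
  age[type != 0] <- sample(1:120, sum(type != 0), replace = TRUE)
  z <- matrix(0, nrow, ncol)
  state <- forest_state(g, type, age, z, z, z)
  suit <- lapply(codes, function(j)
    matrix(runif(ncell), nrow, ncol))
  names(suit) <- as.character(codes)
  mtss <- stats::setNames(runif(n_types, 0.3, 0.7), as.character(codes))
  climate_now <- list(mat = matrix(runif(ncell, -4, 16), nrow, ncol),
                      map = matrix(runif(ncell, 600, 1600), nrow, ncol))
  climate_future <- list(mat = climate_now$mat + 2,
                         map = climate_now$map + 50)
  fits <- lapply(codes, function(j)
    switch(1 + (j - 1) %% 3,
           manual_fit("MM", mu = 100 + 10 * j, k = 120, a = 1, b = 0.02,
                      d = -10),
           manual_fit("L", mu = 120, c = 8, alpha = 0.08, a = -0.5, b = 0.01,
                      d = 5),
           manual_fit("MO", mu = 90, c = 1.2, alpha = 0.04, a = 2, b = 0.03,
                      d = -40)))
  names(fits) <- as.character(codes)
  list(geom = g, state = state, suit = suit, mtss = mtss,
       climate_now = climate_now, climate_future = climate_future,
       fits = fits, F = 1.15)
}

expect_state_equal <- function(st, or) {
  expect_identical(st$type, or$type)
  expect_equal(st$age, or$age)
  expect_equal(st$c_age, or$c_age, tolerance = 1e-12)
  expect_equal(st$c_climate, or$c_climate, tolerance = 1e-12)
  expect_equal(st$c_co2, or$c_co2, tolerance = 1e-12)
  expect_identical(st$status, or$status)
}
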