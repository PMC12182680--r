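test_that("scenario specs carry the period-dependent horizon N", {
  expect_equal(scenario_spec("2030s", "SSP245")$N, 10)
  expect_equal(scenario_spec("2050s", "SSP245")$N, 30)
  expect_equal(scenario_spec("2070s", "SSP585")$N, 50)
  expect_equal(scenario_spec("2050s", "SSP245", N = 25)$N, 25)
  expect_error(scenario_spec("2050s", "SSP245", N = -1),
               "configuration error")
})

test_that("nature rules on a worked pixel: remain, replace, lose", {
  g <- grid_geom(2, 2, cell_size = 0.5, lat_origin = 45)
  type <- matrix(c(1L, 1L, 1L, 0L), 2, 2)
  age <- matrix(c(30, 30, 30, NA), 2, 2)
  z <- matrix(0, 2, 2)
  st <- forest_state(g, type, age, z, z, z)
  # pixel [1,1] keeps type 1; [2,1] is replaced by type 2; [1,2] is lost
  suit <- list(`1` = matrix(c(0.8, 0.2, 0.1, 0.9), 2, 2),
               `2` = matrix(c(0.1, 0.7, 0.2, 0.9), 2, 2))
  mtss <- c(`1` = 0.5, `2` = 0.5)
  cn <- list(mat = matrix(10, 2, 2), map = matrix(900, 2, 2))
  cf <- list(mat = matrix(12, 2, 2), map = matrix(950, 2, 2))
  fits <- list(`1` = manual_fit("MM", mu = 100, k = 120, a = 1, b = 0.01,
                                d = 0),
               `2` = manual_fit("MM", mu = 80, k = 100, a = 2, b = 0.02,
                                d = -5))
  spec <- scenario_spec("2030s", "SSP245")   # N = 20 would be 2040s; N = 10
  out <- step_nature(st, suit, mtss, cn, cf, fits, 1.1, spec)
  expect_identical(out$type[1, 1], 1L)
  expect_equal(out$age[1, 1], 40)            # t + N
  expect_identical(out$status[1, 1], 1L)
  expect_identical(out$type[2, 1], 2L)
  expect_equal(out$age[2, 1], 5)             # N / 2
  expect_identical(out$status[2, 1], 2L)
  expect_identical(out$type[1, 2], 0L)
  expect_identical(out$status[1, 2], 3L)
  expect_equal(out$c_total[1, 2], 0)
  expect_identical(out$status[2, 2], 0L)     # non-forest stays non-forest
  # component arithmetic on the remaining pixel
  ca <- max(100 * 40 / 160 + 1 * 10 + 0.01 * 900 + 0, 0)
  cac <- max(100 * 40 / 160 + 1 * 12 + 0.01 * 950 + 0, 0)
  expect_equal(out$c_age[1, 1], ca)
  expect_equal(out$c_climate[1, 1], cac - ca)
  expect_equal(out$c_co2[1, 1], 0.1 * ca)
  expect_equal(out$c_total[1, 1], ca + (cac - ca) + 0.1 * ca)
})

test_that("the nature engine matches the literal transcription on random worlds", {
  for (seed in c(101, 202, 303, 404, 505)) {
    w <- random_scenario_world(seed)
    spec <- scenario_spec("2050s", "SSP245", seeds = 1:3)
    got <- step_nature(w$state, w$suit, w$mtss, w$climate_now,
                       w$climate_future, w$fits, w$F, spec)
    want <- nature_oracle(w$state, w$suit, w$mtss, w$climate_now,
                          w$climate_future, w$fits, w$F, spec)
    expect_state_equal(got, want)
  }
})

test_that("nature projection never creates forest and partitions the baseline", {
  for (seed in c(7, 77)) {
    w <- random_scenario_world(seed)
    spec <- scenario_spec("2070s", "SSP585")
    out <- step_nature(w$state, w$suit, w$mtss, w$climate_now,
                       w$climate_future, w$fits, w$F, spec)
    expect_true(all(out$type[w$state$type == 0L] == 0L))
    nb <- sum(w$state$type != 0L)
    expect_identical(sum(out$status == 1L) + sum(out$status == 2L) +
                       sum(out$status == 3L), nb)
    # replaced pixels qualify and carry age N/2
    ri <- which(out$status == 2L)
    for (i in ri) {
      ty <- as.character(out$type[i])
      expect_gt(w$suit[[ty]][i], w$mtss[[ty]])
      expect_equal(out$age[i], round(spec$N / 2))
    }
  }
})

test_that("a missing suitability layer for an occupied type is refused", {
  w <- random_scenario_world(1)
  spec <- scenario_spec("2030s", "SSP245")
  expect_error(step_nature(w$state, w$suit[c("1", "2")], w$mtss[c("1", "2")],
                           w$climate_now, w$climate_future, w$fits, w$F,
                           spec),
               "configuration error")
})

test_that("area-target regression matches closed-form least squares", {
  m <- fit_area_targets(data.frame(year = c(2025, 2035),
                                   area_mha = c(200, 210)))
  expect_equal(m$slope, 1.0)
  expect_equal(predict(m, 2050), 225)
  # exactly linear series
  s <- data.frame(year = seq(2025, 2080, 5),
                  area_mha = 100 + 2 * (seq(2025, 2080, 5) - 2020))
  m2 <- fit_area_targets(s)
  expect_equal(m2$r2, 1)
  expect_equal(m2$rmse, 0, tolerance = 1e-10)
  expect_equal(m2$slope, 2)
  # noisy series against the normal equations
  set.seed(61)
  s$area_mha <- s$area_mha + rnorm(nrow(s), 0, 3)
  m3 <- fit_area_targets(s)
  X <- cbind(1, s$year)
  beta <- solve(t(X) %*% X, t(X) %*% s$area_mha)
  expect_equal(m3$intercept, beta[1], tolerance = 1e-8)
  expect_equal(m3$slope, beta[2], tolerance = 1e-8)
  expect_error(fit_area_targets(data.frame(year = c(2025, 2025),
                                           area_mha = c(1, 2))), "fit error")
})

test_that("afforestation demand is the clipped target shortfall", {
  expect_equal(required_afforestation(100, 80), 20)
  expect_equal(required_afforestation(100, 120), 0)
  expect_error(required_afforestation(-1, 0), "configuration error")
})

test_that("the allocation engine matches the literal transcription", {
  for (seed in c(11, 22, 33)) {
    w <- random_scenario_world(seed)
    spec <- scenario_spec("2050s", "SSP245")
    nat <- step_nature(w$state, w$suit, w$mtss, w$climate_now,
                       w$climate_future, w$fits, w$F, spec)
    areas <- cell_area_matrix(w$geom) / 1e6
    demand <- 0.4 * sum(areas[nat$type == 0])
    got <- allocate_afforestation(nat, w$suit, w$mtss, demand,
                                  w$climate_now, w$climate_future, w$fits,
                                  w$F, spec, seed = 99)
    want <- afforest_oracle(nat, w$suit, w$mtss, demand, w$climate_now,
                            w$climate_future, w$fits, w$F, spec, seed = 99)
    expect_state_equal(got, want)
  }
})

test_that("allocation is seed-deterministic, monotone in demand, and bookkeeps area", {
  w <- random_scenario_world(55)
  spec <- scenario_spec("2050s", "SSP585")
  nat <- step_nature(w$state, w$suit, w$mtss, w$climate_now,
                     w$climate_future, w$fits, w$F, spec)
  areas <- cell_area_matrix(w$geom)
  qual <- Reduce(`|`, mapply(function(p, m) p > m, w$suit, w$mtss,
                             SIMPLIFY = FALSE))
  cand <- nat$type == 0 & qual
  supply <- sum(areas[cand]) / 1e6
  expect_gt(supply, 0)
  alloc <- function(demand, seed = 5)
    allocate_afforestation(nat, w$suit, w$mtss, demand, w$climate_now,
                           w$climate_future, w$fits, w$F, spec, seed = seed)
  # demand 0 leaves the nature result untouched
  a0 <- alloc(0)
  expect_identical(a0$type, nat$type)
  # same seed, same allocation
  expect_identical(alloc(supply / 3)$type, alloc(supply / 3)$type)
  # demand equal to the candidate area plants every candidate
  afull <- alloc(supply)
  expect_identical(unname(afull$status[cand]), rep(4L, sum(cand)))
  # planted area overshoots demand by less than one pixel
  d <- supply / 2
  ad <- alloc(d)
  planted <- sum(areas[ad$status == 4L]) / 1e6
  expect_gte(planted, d)
  expect_lt(planted - d, max(areas) / 1e6)
  # larger demand never plants fewer pixels (same seed)
  n1 <- sum(alloc(supply / 4)$status == 4L)
  n2 <- sum(alloc(supply / 2)$status == 4L)
  expect_gte(n2, n1)
  # planted pixels carry the best qualifying type at age N/2
  pi <- which(ad$status == 4L)
  for (i in pi) {
    ty <- as.character(ad$type[i])
    expect_gt(w$suit[[ty]][i], w$mtss[[ty]])
    expect_equal(ad$age[i], round(spec$N / 2))
  }
  # shortfall beyond the candidate supply is a warning, not an error
  expect_warning(alloc(supply * 2), "shortfall")
})

test_that("the replicate ensemble averages exactly and degenerates cleanly", {
  w <- random_scenario_world(88)
  spec <- scenario_spec("2030s", "SSP245", seeds = 1:10)
  nat <- step_nature(w$state, w$suit, w$mtss, w$climate_now,
                     w$climate_future, w$fits, w$F, spec)
  areas <- cell_area_matrix(w$geom)
  qual <- Reduce(`|`, mapply(function(p, m) p > m, w$suit, w$mtss,
                             SIMPLIFY = FALSE))
  supply <- sum(areas[nat$type == 0 & qual]) / 1e6
  ens <- run_ensemble(nat, w$suit, w$mtss, supply / 3, w$climate_now,
                      w$climate_future, w$fits, w$F, spec)
  # the reported mean is the plain average of per-replicate totals
  expect_equal(ens$mean[["total_agb_pgc"]],
               mean(sapply(ens$states, function(s)
                 total_agb(s, areas))))
  expect_equal(ens$sd[["total_agb_pgc"]],
               sd(ens$replicates$total_agb_pgc))
  # replicate totals differ when supply far exceeds demand and scatter
  # sanely around the mean (at most the one 2-sd tail case expected at n=10)
  expect_gt(ens$sd[["total_agb_pgc"]], 0)
  z <- abs(ens$replicates$total_agb_pgc - ens$mean[["total_agb_pgc"]]) /
    ens$sd[["total_agb_pgc"]]
  expect_lte(sum(z > 2), 1)
  # a single-seed ensemble is that run
  e1 <- run_ensemble(nat, w$suit, w$mtss, supply / 3, w$climate_now,
                     w$climate_future, w$fits, w$F,
                     scenario_spec("2030s", "SSP245", seeds = 4))
  expect_equal(e1$mean[["total_agb_pgc"]], e1$replicates$total_agb_pgc[1])
  # zero demand: all replicates identical, sd exactly 0
  e0 <- run_ensemble(nat, w$suit, w$mtss, 0, w$climate_now,
                     w$climate_future, w$fits, w$F, spec)
  expect_equal(e0$sd[["total_agb_pgc"]], 0)
})
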