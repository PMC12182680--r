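state_from <- function(geom, dens, type = NULL, age = NULL, status = NULL) {
  if (is.null(type)) type <- matrix(ifelse(dens > 0, 1L, 0L), nrow(dens))
  if (is.null(age)) {
    age <- matrix(NA_real_, nrow(dens), ncol(dens))
    age[type != 0] <- 50
  }
  z <- matrix(0, nrow(dens), ncol(dens))
  forest_state(geom, type, age, dens, z, z, status = status)
}

test_that("total AGB follows the unit arithmetic Mg/ha x ha x fraction", {
  g <- grid_geom(2, 2, cell_size = 0.5, lat_origin = 45)
  dens <- matrix(c(100, 0, 0, 0), 2, 2)
  ones <- matrix(1, 2, 2)   # pretend 1 ha cells to isolate the unit factors
  st <- state_from(g, dens)
  expect_equal(total_agb(st, ones, carbon_fraction = 0.5), 5e-8)
  expect_equal(total_agb(st, ones, carbon_fraction = 1), 1e-7)
  expect_equal(total_agb(state_from(g, matrix(0, 2, 2),
                                    type = matrix(0L, 2, 2),
                                    age = matrix(NA_real_, 2, 2)), ones), 0)
  expect_error(total_agb(st, ones, carbon_fraction = 0), "configuration error")
})

test_that("loss and change rates are percentages of the baseline forest area", {
  g <- grid_geom(10, 10, cell_size = 0.5, lat_origin = 45)
  ones <- matrix(1, 10, 10)
  base_type <- matrix(1L, 10, 10)
  base_age <- matrix(50, 10, 10)
  z <- matrix(0, 10, 10)
  base <- forest_state(g, base_type, base_age, z, z, z)
  status <- matrix(1L, 10, 10)
  status[1, 1:2] <- 3L            # 2 lost
  status[2, 1:9] <- 2L            # 9 replaced
  fut_type <- base_type; fut_type[status == 3L] <- 0L
  fut_age <- base_age; fut_age[status == 3L] <- NA
  fut <- forest_state(g, fut_type, fut_age, z, z, z, status = status)
  rt <- rates(fut, base, ones)
  expect_equal(unname(rt), c(2, 9))
  # remained + replaced + lost covers the baseline exactly
  expect_equal(sum(status == 1L) + sum(status == 2L) + sum(status == 3L),
               100)
  none <- forest_state(g, base_type, base_age, z, z, z)
  expect_equal(unname(rates(none, base, ones)), c(0, 0))
  empty <- forest_state(g, matrix(0L, 10, 10),
                        matrix(NA_real_, 10, 10), z, z, z)
  expect_error(rates(fut, empty, ones), "undefined-rate")
})

test_that("sequestration rates convert and telescope correctly", {
  expect_equal(sequestration_rate(14.59, 11.59, 20), 150)
  expect_equal(sequestration_rate(5, 5, 30), 0)
  # duration-weighted sub-period rates equal the full-period rate
  r1 <- sequestration_rate(8, 5, 10)
  r2 <- sequestration_rate(12, 8, 30)
  expect_equal((r1 * 10 + r2 * 30) / 40, sequestration_rate(12, 5, 40))
  expect_error(sequestration_rate(1, 1, 0), "configuration error")
})

test_that("totals are invariant under 2x2 area-weighted aggregation", {
  set.seed(71)
  g <- grid_geom(8, 8, cell_size = 0.5, lat_origin = 45)
  dens <- matrix(runif(64, 0, 200), 8, 8)
  st <- state_from(g, dens)
  areas <- cell_area_matrix(g)
  fine <- total_agb(st, areas)
  # aggregate blocks of 2x2 into one cell carrying the area-weighted density
  g2 <- grid_geom(4, 4, cell_size = 1, lat_origin = 45)
  a2 <- matrix(0, 4, 4); d2 <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    ri <- (2 * i - 1):(2 * i); ci <- (2 * j - 1):(2 * j)
    a2[i, j] <- sum(areas[ri, ci])
    d2[i, j] <- sum(dens[ri, ci] * areas[ri, ci]) / a2[i, j]
  }
  coarse <- total_agb(state_from(g2, d2), a2)
  expect_equal(coarse, fine, tolerance = 1e-12)
})

test_that("summary rows are internally consistent", {
  w <- random_scenario_world(3, nrow = 10, ncol = 10)
  spec <- scenario_spec("2050s", "SSP245")
  nat <- step_nature(w$state, w$suit, w$mtss, w$climate_now,
                     w$climate_future, w$fits, w$F, spec)
  areas <- cell_area_matrix(w$geom)
  row <- summarize_state(nat, areas, baseline = w$state, years = 30)
  expect_equal(row$total_agb_pgc, total_agb(nat, areas))
  # the total's spread is the density spread scaled to the forest area
  expect_equal(row$total_agb_sd_pgc,
               row$sd_density * row$area_mha * 1e6 * 1e-9)
  # component shares sum to 100% of the (non-zero) total
  expect_equal(row$share_age + row$share_climate + row$share_co2, 100,
               tolerance = 1e-9)
  expect_true(row$loss_rate + row$change_rate <= 100)
  expect_equal(row$seq_rate_tgc_yr,
               (row$total_agb_pgc - total_agb(w$state, areas)) * 1000 / 30)
  # aggregate additivity: component totals recompose the AGB total
  comp_sum <- (sum(nat$c_age * areas) + sum(nat$c_climate * areas) +
                 sum(nat$c_co2 * areas)) * 1e-9
  expect_equal(comp_sum, row$total_agb_pgc, tolerance = 1e-12)
})

test_that("regional summaries partition the domain total", {
  w <- random_scenario_world(19, nrow = 10, ncol = 10)
  areas <- cell_area_matrix(w$geom)
  regions <- matrix(rep(c("N", "S"), each = 50), 10, 10, byrow = TRUE)
  st <- w$state
  st$c_age <- matrix(runif(100, 0, 100), 10, 10)
  st$c_age[st$type == 0] <- 0
  st$c_total <- st$c_age + st$c_climate + st$c_co2
  tab <- summarize_by_region(st, regions, areas)
  expect_identical(nrow(tab), 2L)
  expect_equal(sum(tab$total_agb_pgc), total_agb(st, areas),
               tolerance = 1e-12)
  expect_equal(sum(tab$area_mha),
               sum(areas[st$type != 0]) / 1e6, tolerance = 1e-12)
})
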