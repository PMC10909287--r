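test_that("road lattice has the expected structure on the smallest grid", {
  cfg <- scenario_config(grid_extent = 2L, cell_size = 1000,
                         walking_fraction = 0, merge_fraction = 0, seed = 1L)
  roads <- generate_road_network(cfg)
  expect_equal(nrow(roads), 4L)
  g <- build_graph(roads)
  expect_equal(igraph::vcount(g), 4L)
  expect_true(igraph::is_connected(g))
  expect_true(all(roads$speed_kmh >= 10))
})

test_that("a pure walking-road network is empty after filtering", {
  cfg <- scenario_config(grid_extent = 4L, walking_fraction = 1, seed = 2L)
  roads <- filter_walking_roads(generate_road_network(cfg))
  expect_equal(nrow(roads), 0L)
  expect_equal(igraph::vcount(build_graph(roads)), 0L)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- scenario_config(grid_extent = 10L, seed = 42L)
  expect_identical(generate_road_network(cfg), generate_road_network(cfg))
  expect_identical(generate_static_grid(cfg), generate_static_grid(cfg))
  sc <- small_scenario()
  st <- generate_static_grid(sc)
  expect_identical(generate_dynamic_observations(st, sc),
                   generate_dynamic_observations(st, sc))
  expect_identical(generate_eds(st, sc), generate_eds(st, sc))
})

test_that("invalid configurations are rejected", {
  expect_error(scenario_config(grid_extent = 1), "grid_extent")
  expect_error(scenario_config(commuting_fraction = 1.2), "commuting_fraction")
  expect_error(scenario_config(vacation_fraction = -0.1), "vacation_fraction")
  expect_error(scenario_config(privacy_floor = 0), "privacy_floor")
  expect_error(scenario_config(operator_scale = 0), "operator_scale")
  expect_error(scenario_config(hours = 24), "hours")
})

test_that("static grid follows the configured density surface", {
  # uniform density: 3x3 grid at 10 persons per cell sums to 90
  cfg <- scenario_config(grid_extent = 3L, pop_peak = 0, pop_base = 10)
  st <- generate_static_grid(cfg)
  expect_equal(sum(st$static_pop), 90)
  expect_true(all(st$static_pop == 10))
  # core-weighted density: the core cell dominates every peripheral cell
  cfg2 <- scenario_config(grid_extent = 9L, pop_peak = 500, pop_base = 5)
  st2 <- generate_static_grid(cfg2)
  core_pop <- max(st2$static_pop[st2$is_core])
  expect_gt(core_pop, max(st2$static_pop[!st2$is_core]))
})

test_that("urban classes are total, valid, and ordered by distance to core", {
  cfg <- small_scenario()
  st <- generate_static_grid(cfg)
  cl <- assign_urban_classes(st, cfg)
  expect_equal(nrow(cl), nrow(st))
  expect_true(all(cl$class %in% c("urban", "densely_populated", "rural")))
  centre <- st$cell_id[which.max(st$static_pop)]
  expect_equal(cl$class[cl$cell_id == centre], "urban")
  corner <- st$cell_id[st$col == 0 & st$row == 0]
  expect_equal(cl$class[cl$cell_id == corner], "rural")
})

test_that("movement model reproduces the forced arithmetic cases", {
  st <- two_cell_static(80, 20)
  cfg <- scenario_config(commuting_fraction = 0.5, vacation_fraction = 0.25,
                         operator_scale = 1)
  # weekday 13:00 outside July: core gains half the non-core residents
  cnt <- simulate_stratum_counts(st, cfg, month = 1L, daytype = "weekday",
                                 hour = 13L)
  expect_equal(cnt, c(80 + 0.5 * 20, 0.5 * 20))
  # July: a quarter of the core population relocates to the vacation cell
  cnt_jul <- simulate_stratum_counts(st, cfg, month = 7L, daytype = "weekend",
                                     hour = 13L)
  expect_equal(cnt_jul, c(60, 40))
  # outside office hours, nothing moves
  cnt_night <- simulate_stratum_counts(st, cfg, month = 1L, daytype = "weekday",
                                       hour = 3L)
  expect_equal(cnt_night, c(80, 20))
})

test_that("dynamic counts conserve the scaled static total at every stratum", {
  sc <- small_scenario(operator_scale = 1.37)
  st <- generate_static_grid(sc)
  dyn <- generate_dynamic_observations(st, sc)
  totals <- tapply(dyn$observations$count,
                   interaction(dyn$observations$month, dyn$observations$daytype,
                               dyn$observations$hour), sum)
  expect_true(all(abs(totals - 1.37 * sum(st$static_pop)) < 1e-6))
})

test_that("identity scenario: dynamic counts equal covered static sums", {
  sc <- identity_scenario()
  st <- generate_static_grid(sc)
  dyn <- generate_dynamic_observations(st, sc)
  fused <- fuse_grids(st, dyn$cells)
  joined <- merge(dyn$observations, fused[c("cell_id", "static_pop")],
                  by = "cell_id")
  expect_true(all(abs(joined$count - joined$static_pop) < 1e-9))
})

test_that("privacy floor holds for every emitted count when noise is off", {
  sc <- small_scenario()
  st <- generate_static_grid(sc)
  dyn <- generate_dynamic_observations(st, sc)
  expect_true(all(dyn$observations$count >= sc$privacy_floor))
  # and the grid is genuinely multi-resolution under this density surface
  expect_gt(length(unique(dyn$cells$side)), 1L)
})

test_that("dynamic cells nest in the static grid without partial overlap", {
  sc <- small_scenario()
  st <- generate_static_grid(sc)
  dyn <- generate_dynamic_observations(st, sc)
  for (i in seq_len(nrow(dyn$cells))) {
    side <- dyn$cells$side[i]
    x0 <- dyn$cells$x0[i]; y0 <- dyn$cells$y0[i]
    if (side >= 1) {
      expect_true(x0 %% 1 == 0 && y0 %% 1 == 0)
      expect_true(log2(side) %% 1 == 0)
    } else {
      expect_equal(side, 0.5)
      expect_true((x0 * 2) %% 1 == 0 && (y0 * 2) %% 1 == 0)
    }
  }
  # the dynamic cells tile the study area exactly
  expect_equal(sum(dyn$cells$side^2), sc$grid_extent^2)
})

test_that("a population too small to refine yields a single root cell", {
  sc <- scenario_config(grid_extent = 2L, pop_peak = 0, pop_base = 1,
                        privacy_floor = 5, operator_scale = 1,
                        commuting_fraction = 0, vacation_fraction = 0)
  st <- generate_static_grid(sc)
  dyn <- generate_dynamic_observations(st, sc)
  expect_equal(nrow(dyn$cells), 1L)
  expect_equal(dyn$cells$side, 2)
})

test_that("ED levels follow the configured proportions and cover the core", {
  sc <- small_scenario()
  st <- generate_static_grid(sc)
  eds <- generate_eds(st, sc)
  expect_equal(nrow(eds), sc$n_eds)
  expect_true(all(eds$level %in% 1:3))
  expect_true(any(eds$in_core))
  expect_equal(eds$level[which.max(st$static_pop[match(eds$cell_id, st$cell_id)])], 1L)
})
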