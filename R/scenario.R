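#' Scenario configuration for the synthetic study area
#'
#' Defines a square study area tiled by a homogeneous "static" population grid
#' (emulating a 1 km² residential census grid), over which the generators build
#' a road lattice, emergency departments (EDs), a variable-resolution dynamic
#' population grid with a privacy floor, and hourly dynamic population counts
#' with weekday commuting toward the urban core and a July vacation outflow
#' from the core to designated vacation cells.
#'
#' @param grid_extent integer, cells per side of the static grid (>= 2).
#' @param cell_size side of one static cell in metres.
#' @param n_eds number of EDs to place.
#' @param ed_level_props proportions of hospital levels 1..3 among EDs
#'   (level 1 = large university hospital, level 3 = small rural hospital).
#' @param commuting_fraction fraction of each non-core cell's population
#'   present in urban-core cells during weekday office hours (8-17), in [0,1].
#' @param vacation_fraction fraction of core-cell population relocated to
#'   vacation cells during July, in [0,1].
#' @param privacy_floor minimum dynamic count per dynamic grid cell (>= 1);
#'   enforced by coarsening the dynamic grid, never by truncating counts.
#' @param operator_scale multiplicative factor applied to all dynamic counts,
#'   emulating extrapolation from one operator's market share to the full
#'   population (> 0); dynamic and static totals therefore differ.
#' @param months,daytypes,hours the temporal strata to emit: every combination
#'   of month (1-12), daytype ("weekday"/"weekend") and hour (0-23).
#' @param speed_set speed limits (km/h) sampled for ordinary road segments.
#' @param walking_fraction fraction of segments emitted as walking roads
#'   (speed below 10 km/h, removed downstream).
#' @param merge_fraction fraction of collinear adjacent segment pairs merged
#'   into one polyline with a shared interior vertex, so that downstream
#'   intersection splitting is exercised.
#' @param pop_peak,pop_base parameters of the radial population density
#'   surface: cell population = round(pop_peak * exp(-d^2 / (2 sigma^2))) +
#'   pop_base with sigma = grid_extent / 8 and d the distance (in cells) to
#'   the grid centre, giving one dense metropolitan core over a sparse
#'   rural hinterland.
#' @param noise if TRUE, dynamic counts are independent Poisson draws around
#'   their deterministic expectation (the privacy floor then holds only for
#'   the expectation).
#' @param seed integer RNG seed; all generators derive their randomness from
#'   it, so identical configurations reproduce identical outputs.
#'
#' @return a validated `scenario_config` list.
#' @export
scenario_config <- function(grid_extent = 64L,
                            cell_size = 2000,
                            n_eds = 12L,
                            ed_level_props = c(`1` = 0.15, `2` = 0.35, `3` = 0.50),
                            commuting_fraction = 0.25,
                            vacation_fraction = 0.15,
                            privacy_floor = 5,
                            operator_scale = 1.2,
                            months = c(1L, 7L),
                            daytypes = c("weekday", "weekend"),
                            hours = 0:23,
                            speed_set = c(30, 50, 70, 90, 110),
                            walking_fraction = 0.05,
                            merge_fraction = 0.15,
                            pop_peak = 2000,
                            pop_base = 4,
                            noise = FALSE,
                            seed = 1L) {
  cfg <- list(
    grid_extent = as.integer(grid_extent), cell_size = cell_size,
    n_eds = as.integer(n_eds), ed_level_props = ed_level_props,
    commuting_fraction = commuting_fraction,
    vacation_fraction = vacation_fraction,
    privacy_floor = privacy_floor, operator_scale = operator_scale,
    months = as.integer(months), daytypes = daytypes, hours = as.integer(hours),
    speed_set = speed_set, walking_fraction = walking_fraction,
    merge_fraction = merge_fraction,
    pop_peak = pop_peak, pop_base = pop_base,
    noise = isTRUE(noise), seed = as.integer(seed)
  )
  validate_scenario_config(cfg)
  class(cfg) <- "scenario_config"
  cfg
}

validate_scenario_config <- function(cfg) {
  if (is.na(cfg$grid_extent) || cfg$grid_extent < 2)
    stopf("invalid config: grid_extent must be an integer >= 2, got %s",
          cfg$grid_extent)
  if (cfg$cell_size <= 0) stopf("invalid config: cell_size must be > 0")
  if (cfg$commuting_fraction < 0 || cfg$commuting_fraction > 1)
    stopf("invalid config: commuting_fraction must lie in [0,1]")
  if (cfg$vacation_fraction < 0 || cfg$vacation_fraction > 1)
    stopf("invalid config: vacation_fraction must lie in [0,1]")
  if (cfg$privacy_floor < 1) stopf("invalid config: privacy_floor must be >= 1")
  if (cfg$operator_scale <= 0) stopf("invalid config: operator_scale must be > 0")
  if (cfg$walking_fraction < 0 || cfg$walking_fraction > 1)
    stopf("invalid config: walking_fraction must lie in [0,1]")
  if (any(cfg$months < 1 | cfg$months > 12)) stopf("invalid config: months in 1..12")
  if (any(cfg$hours < 0 | cfg$hours > 23)) stopf("invalid config: hours in 0..23")
  if (!all(cfg$daytypes %in% c("weekday", "weekend")))
    stopf("invalid config: daytypes must be 'weekday'/'weekend'")
  invisible(cfg)
}

#' Temporal strata emitted by a scenario
#'
#' @param config a [scenario_config()].
#' @return tibble with columns `month`, `daytype`, `hour` (one row per stratum).
#' @export
scenario_strata <- function(config) {
  g <- expand.grid(hour = config$hours, daytype = config$daytypes,
                   month = config$months, stringsAsFactors = FALSE)
  tibble::as_tibble(g[, c("month", "daytype", "hour")])
}
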