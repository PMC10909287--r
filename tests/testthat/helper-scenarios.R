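# Small scenarios shared across tests (kept tiny so the suite stays fast).

small_scenario <- function(...) {
  scenario_config(grid_extent = 8L, cell_size = 4000, n_eds = 3L,
                  pop_peak = 300, pop_base = 10,
                  months = c(1L, 7L), daytypes = c("weekday", "weekend"),
                  hours = c(3L, 13L), walking_fraction = 0,
                  merge_fraction = 0.2, seed = 11L, ...)
}

identity_scenario <- function(operator_scale = 1, ...) {
  small_scenario(commuting_fraction = 0, vacation_fraction = 0,
                 operator_scale = operator_scale, ...)
}

# a two-cell world: A is the urban core, B the vacation destination
two_cell_static <- function(pop_a = 80, pop_b = 20) {
  tibble::tibble(
    cell_id = c("A", "B"), col = c(0, 1), row = c(0, 0),
    x0 = c(0, 1000), y0 = 0, size_m = 1000,
    cx = c(500, 1500), cy = 500,
    static_pop = c(pop_a, pop_b),
    is_core = c(TRUE, FALSE), is_vacation = c(FALSE, TRUE))
}

# segments helper: seg("id", speed, x1,y1, x2,y2, ...)
seg <- function(id, speed, ...) {
  xy <- matrix(c(...), ncol = 2, byrow = TRUE)
  tibble::tibble(segment_id = id, speed_kmh = speed, coords = list(xy))
}

# 5-node path graph A-B-C-D-E with unit edge travel times (1000 m at 60 km/h)
path_graph_segments <- function() {
  dplyr::bind_rows(lapply(1:4, function(i)
    seg(sprintf("p%d", i), 60, (i - 1) * 1000, 0, i * 1000, 0)))
}
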