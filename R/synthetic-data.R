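#' Generate a lattice road network for a scenario
#'
#' Builds a connected lattice of road segments over the static-grid cell
#' centroids. Each lattice edge becomes one polyline segment with a speed
#' limit sampled from `config$speed_set`; a configured fraction of segments
#' are emitted as walking roads (5 km/h), and a configured fraction of
#' collinear adjacent segment pairs are merged into single polylines whose
#' interior vertex coincides with another segment's endpoint — exercising the
#' downstream intersection-splitting step.
#'
#' @param config a [scenario_config()].
#' @return tibble of road segments: `segment_id`, `speed_kmh`, and `coords`
#'   (list column of n x 2 coordinate matrices, planar metres).
#' @export
generate_road_network <- function(config) {
  validate_scenario_config(config)
  n <- config$grid_extent
  cs <- config$cell_size
  cx <- function(i) (i + 0.5) * cs   # i, j are 0-based cell indices
  withr::with_seed(config$seed + 101L, {
    segs <- list()
    # horizontal edges, row by row (collinear runs allow merging)
    for (j in 0:(n - 1)) {
      i <- 0
      while (i < n - 1) {
        take <- 1
        if (i < n - 2 && stats::runif(1) < config$merge_fraction) take <- 2
        pts <- cbind(cx(i:(i + take)), rep(cx(j), take + 1))
        segs[[length(segs) + 1]] <- pts
        i <- i + take
      }
    }
    for (i in 0:(n - 1)) {
      j <- 0
      while (j < n - 1) {
        take <- 1
        if (j < n - 2 && stats::runif(1) < config$merge_fraction) take <- 2
        pts <- cbind(rep(cx(i), take + 1), cx(j:(j + take)))
        segs[[length(segs) + 1]] <- pts
        j <- j + take
      }
    }
    m <- length(segs)
    walking <- stats::runif(m) < config$walking_fraction
    speeds <- ifelse(walking, 5, sample(config$speed_set, m, replace = TRUE))
  })
  tibble::tibble(
    segment_id = sprintf("r%04d", seq_len(m)),
    speed_kmh = speeds,
    coords = segs
  )
}

#' Generate the static (residential) population grid
#'
#' Axis-aligned square cells tiling the study extent. Cell populations follow
#' a deterministic radial density surface peaking at the grid centre (the
#' urban core). Cells within `grid_extent / 8` cells of the centre are
#' flagged as urban-core commuting destinations; outer cells (beyond
#' `grid_extent / 3` of the centre) in the eastern half are flagged as
#' vacation destinations, emulating the coastal summer municipalities that
#' absorb the July outflow on one side of the country.
#'
#' @param config a [scenario_config()].
#' @return tibble of static cells: `cell_id`, `col`, `row` (0-based), `x0`,
#'   `y0`, `size_m`, `cx`, `cy` (metres), `static_pop`, `is_core`,
#'   `is_vacation`.
#' @export
generate_static_grid <- function(config) {
  validate_scenario_config(config)
  n <- config$grid_extent
  cs <- config$cell_size
  g <- expand.grid(col = 0:(n - 1), row = 0:(n - 1))
  cc <- (n - 1) / 2
  d <- sqrt((g$col - cc)^2 + (g$row - cc)^2)
  sigma <- n / 8
  pop <- round(config$pop_peak * exp(-d^2 / (2 * sigma^2))) + config$pop_base
  tibble::tibble(
    cell_id = sprintf("s_%d_%d", g$col, g$row),
    col = g$col, row = g$row,
    x0 = g$col * cs, y0 = g$row * cs, size_m = cs,
    cx = (g$col + 0.5) * cs, cy = (g$row + 0.5) * cs,
    static_pop = as.numeric(pop),
    is_core = d <= n / 8,
    is_vacation = d > n / 3 & g$col >= n / 2
  )
}

#' Assign urban / densely populated / rural classes to static cells
#'
#' Deterministic labelling by distance to the urban core: the nearest band is
#' `urban`, the middle band `densely_populated`, the remainder `rural`.
#' Deriving classes from commuting statistics (as the official municipal
#' classification does) is out of scope: downstream code treats the labels
#' as input data.
#'
#' @param static static grid tibble from [generate_static_grid()].
#' @param config a [scenario_config()].
#' @return tibble `cell_id`, `class`.
#' @export
assign_urban_classes <- function(static, config) {
  n <- config$grid_extent
  cc <- (n - 1) / 2
  d <- sqrt((static$col - cc)^2 + (static$row - cc)^2)
  cls <- ifelse(d <= n / 6, "urban",
                ifelse(d <= n / 3, "densely_populated", "rural"))
  tibble::tibble(cell_id = static$cell_id, class = cls)
}

#' Generate ED locations and hospital levels
#'
#' One level-1 ED is placed at the core centre cell; the remaining EDs are
#' sampled without replacement among non-core cells with probability
#' proportional to cell population (hospitals sit where people live). Levels
#' are assigned by local population rank according to the configured level
#' proportions, so large-city EDs get level 1 and the smallest get level 3.
#'
#' @param static static grid tibble.
#' @param config a [scenario_config()].
#' @return tibble `ed_id`, `level`, `x`, `y`, `cell_id`, `in_core`.
#' @export
generate_eds <- function(static, config) {
  n_eds <- config$n_eds
  if (n_eds < 1) stopf("invalid config: n_eds must be >= 1")
  core_centre <- static[static$is_core, ]
  core_centre <- core_centre[which.max(core_centre$static_pop), ]
  rest <- static[static$cell_id != core_centre$cell_id, ]
  withr::with_seed(config$seed + 202L, {
    k <- min(n_eds - 1, nrow(rest))
    idx <- sample.int(nrow(rest), k, prob = rest$static_pop)
  })
  cells <- dplyr::bind_rows(core_centre, rest[idx, ])
  ord <- order(-cells$static_pop)
  props <- config$ed_level_props / sum(config$ed_level_props)
  n1 <- max(1, round(props[["1"]] * nrow(cells)))
  n2 <- round(props[["2"]] * nrow(cells))
  lev <- integer(nrow(cells))
  lev[ord] <- rep(c(1L, 2L, 3L),
                  c(n1, n2, nrow(cells) - n1 - n2))
  tibble::tibble(
    ed_id = sprintf("ed%02d", seq_len(nrow(cells))),
    level = lev,
    x = cells$cx, y = cells$cy,
    cell_id = cells$cell_id,
    in_core = cells$is_core
  )
}

#' Deterministic dynamic population of each static cell at one stratum
#'
#' The movement model behind the synthetic dynamic counts. Baseline presence
#' is `static_pop * operator_scale`. In July, `vacation_fraction` of each
#' core cell's baseline moves to the vacation cells (proportionally to their
#' baseline, or equally if all vacation baselines are zero), at every hour
#' and daytype. Outside July, on weekdays between 08:00 and 17:00,
#' `commuting_fraction` of each non-core cell's baseline moves into the core
#' cells (proportionally to core baseline). Commuting is deliberately absent
#' in July: the vacation month has a flat diurnal profile.
#'
#' @param static static grid tibble (needs `static_pop`, `is_core`,
#'   `is_vacation`).
#' @param config a [scenario_config()].
#' @param month,daytype,hour the stratum.
#' @return numeric vector of present persons per static cell (same order as
#'   `static`); sums to `operator_scale * sum(static_pop)` exactly.
#' @export
simulate_stratum_counts <- function(static, config, month, daytype, hour) {
  b <- static$static_pop * config$operator_scale
  if (month == 7L && config$vacation_fraction > 0 && any(static$is_vacation)) {
    moved <- config$vacation_fraction * b * static$is_core
    recv <- b * static$is_vacation
    w <- if (sum(recv) > 0) recv / sum(recv) else
      static$is_vacation / sum(static$is_vacation)
    b <- b - moved + sum(moved) * w
  }
  office <- month != 7L && daytype == "weekday" && hour >= 8L && hour <= 17L
  if (office && config$commuting_fraction > 0 && any(static$is_core)) {
    moved <- config$commuting_fraction * b * !static$is_core
    recv <- b * static$is_core
    w <- if (sum(recv) > 0) recv / sum(recv) else
      static$is_core / sum(static$is_core)
    b <- b - moved + sum(moved) * w
  }
  b
}

# All stratum count vectors as a cells x strata matrix (noise-free).
stratum_count_matrix <- function(static, config, strata) {
  vapply(seq_len(nrow(strata)), function(k) {
    simulate_stratum_counts(static, config,
                            strata$month[k], strata$daytype[k], strata$hour[k])
  }, numeric(nrow(static)))
}

#' Generate the variable-resolution dynamic grid and hourly observations
#'
#' Emulates a privacy-preserving mobile-network population grid: a
#' quadtree over the study extent is refined — each cell split into 4 —
#' while every resulting child would still hold at least `privacy_floor`
#' persons at every emitted stratum, down to at most a quarter of a static
#' cell (the analog of 0.25 km² cells inside cities against a 1 km²
#' residential grid). Dynamic cell borders therefore align with the static
#' grid and cell areas differ by powers of 4. Counts per dynamic cell and
#' stratum are the sums of the covered static-cell presences from
#' [simulate_stratum_counts()] (quarter cells carry a quarter of their parent
#' cell's presence), optionally with independent Poisson noise.
#'
#' @param static static grid tibble.
#' @param config a [scenario_config()].
#' @return list with `cells` (tibble `cell_id`, `x0`, `y0`, `side` in static
#'   cell units, `x0_m`, `y0_m`, `size_m`, `cx`, `cy`) and `observations`
#'   (tibble `cell_id`, `month`, `daytype`, `hour`, `count`).
#' @export
generate_dynamic_observations <- function(static, config) {
  validate_scenario_config(config)
  strata <- scenario_strata(config)
  C <- stratum_count_matrix(static, config, strata)  # cells x strata
  n <- config$grid_extent
  root_side <- 2^ceiling(log2(n))

  cover_idx <- function(x0, y0, side) {
    which(static$col >= x0 & static$col < x0 + side &
          static$row >= y0 & static$row < y0 + side)
  }
  region_counts <- function(idx, frac = 1) {
    if (length(idx) == 0) rep(0, nrow(strata))
    else frac * colSums(C[idx, , drop = FALSE])
  }

  leaves <- list()
  emit <- function(x0, y0, side, counts) {
    leaves[[length(leaves) + 1]] <<- list(x0 = x0, y0 = y0, side = side,
                                          counts = counts)
  }
  refine <- function(x0, y0, side) {
    idx <- cover_idx(x0, y0, side)
    if (length(idx) == 0) return(invisible())       # outside the study extent
    if (side > 1) {
      h <- side / 2
      kids <- list(c(x0, y0), c(x0 + h, y0), c(x0, y0 + h), c(x0 + h, y0 + h))
      kc <- lapply(kids, function(k) region_counts(cover_idx(k[1], k[2], h)))
      nonempty <- vapply(kids, function(k) length(cover_idx(k[1], k[2], h)) > 0,
                         logical(1))
      ok <- all(vapply(kc[nonempty], function(v) all(v >= config$privacy_floor),
                       logical(1)))
      if (ok) {
        for (k in which(nonempty)) refine(kids[[k]][1], kids[[k]][2], h)
      } else emit(x0, y0, side, region_counts(idx))
    } else {
      # side == 1: a single static cell; split into quarters if each quarter
      # (carrying exactly a quarter of the cell's presence) clears the floor
      qc <- C[idx, ] / 4
      if (all(qc >= config$privacy_floor)) {
        h <- 0.5
        for (dx in c(0, h)) for (dy in c(0, h))
          emit(x0 + dx, y0 + dy, h, qc)
      } else emit(x0, y0, 1, C[idx, ])
    }
  }
  root_counts <- region_counts(seq_len(nrow(static)))
  if (all(root_counts >= 4 * config$privacy_floor)) {
    refine(0, 0, root_side)
  } else {
    emit(0, 0, root_side, root_counts)   # too small to refine at all
  }

  cs <- config$cell_size
  cells <- tibble::tibble(
    cell_id = vapply(leaves, function(l) sprintf("d_%g_%g_%g", l$x0, l$y0, l$side),
                     character(1)),
    x0 = vapply(leaves, `[[`, numeric(1), "x0"),
    y0 = vapply(leaves, `[[`, numeric(1), "y0"),
    side = vapply(leaves, `[[`, numeric(1), "side")
  )
  cells$x0_m <- cells$x0 * cs
  cells$y0_m <- cells$y0 * cs
  cells$size_m <- cells$side * cs
  cells$cx <- cells$x0_m + cells$size_m / 2
  cells$cy <- cells$y0_m + cells$size_m / 2

  counts <- do.call(rbind, lapply(leaves, `[[`, "counts"))
  obs <- tibble::tibble(
    cell_id = rep(cells$cell_id, each = nrow(strata)),
    month = rep(strata$month, nrow(cells)),
    daytype = rep(strata$daytype, nrow(cells)),
    hour = rep(strata$hour, nrow(cells)),
    count = as.vector(t(counts))
  )
  if (config$noise) {
    obs$count <- withr::with_seed(config$seed + 303L,
                                  stats::rpois(nrow(obs), obs$count))
  }
  list(cells = cells, observations = obs)
}
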