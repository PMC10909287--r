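#' Pipeline configuration
#'
#' Bundles a synthetic scenario with the analysis parameters: snap
#' eligibility distance, accessibility band edges, the temporal strata used
#' for the ratio figures, the two catchment comparison strata (midday in
#' January and July, on commuting-free weekend days), and the Moran
#' permutation settings.
#'
#' @param scenario a [scenario_config()].
#' @param max_snap_m snap eligibility threshold (metres).
#' @param band_edges accessibility band edges (minutes), strictly increasing.
#' @param catchment_strata named list of two stratum lists compared at
#'   catchment level.
#' @param n_permutations Moran permutation count.
#' @param stats_seed seed for the permutation test.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(scenario = scenario_config(),
                            max_snap_m = 5000,
                            band_edges = c(10, 20, 30, 60),
                            catchment_strata = list(
                              january = list(month = 1L, daytype = "weekend", hour = 13L),
                              july = list(month = 7L, daytype = "weekend", hour = 13L)),
                            n_permutations = 999,
                            stats_seed = NULL) {
  if (any(diff(band_edges) <= 0) || any(band_edges <= 0))
    stopf("invalid config: band_edges must be positive and strictly increasing")
  structure(list(scenario = scenario, max_snap_m = max_snap_m,
                 band_edges = band_edges, catchment_strata = catchment_strata,
                 n_permutations = n_permutations,
                 stats_seed = stats_seed %||% (scenario$seed + 404L)),
            class = "pipeline_config")
}

#' Run the full accessibility analysis end to end
#'
#' Simulate (or accept) inputs, build the travel-time road graph, snap and
#' route every fused cell to its closest ED, fuse the static and dynamic
#' grids, summarize static population by travel-time band and urban class,
#' compute the static/dynamic share ratios across temporal strata, the
#' per-catchment differences at the two configured strata, and the spatial
#' clustering (Moran's I) and between-level (ANOVA + Tukey) tests. All
#' tables are written as CSV/GeoJSON under `out_dir` together with a
#' manifest recording the configuration hash and seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing); `NULL` skips writing.
#' @return (invisibly) a list with every intermediate and final table.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  sc <- config$scenario
  static <- generate_static_grid(sc)
  classes <- assign_urban_classes(static, sc)
  roads <- generate_road_network(sc)
  eds <- generate_eds(static, sc)
  dyn <- generate_dynamic_observations(static, sc)

  segs <- filter_walking_roads(split_segments_at_intersections(roads))
  graph <- build_graph(segs)

  fused <- fuse_grids(static, dyn$cells)
  fused <- attach_urban_class(fused, classes)

  snap <- snap_cells(fused, graph, config$max_snap_m)
  assignments <- closest_facility(graph, eds, snap, config$max_snap_m)
  n_omitted <- sum(!assignments$reachable)
  message(sprintf("%d of %d fused cells unreachable and omitted (%.1f%%)",
                  n_omitted, nrow(fused), 100 * n_omitted / nrow(fused)))

  reach <- dplyr::inner_join(
    fused, assignments[assignments$reachable,
                       c("cell_id", "travel_time_min", "ed_id")],
    by = "cell_id")
  reach$band <- classify_band(reach$travel_time_min, config$band_edges)

  band_summary <- summarize_population_by_band(reach$static_pop, reach$band,
                                               reach$urban_class)

  strata <- c(
    lapply(sc$hours, function(h) list(daytype = "weekday", hour = h)),
    lapply(sc$hours, function(h) list(daytype = "weekend", hour = h)),
    lapply(sc$months, function(m) list(month = m, hour = 13L)))
  ratios <- ratio_table(fused, assignments, dyn$observations, strata,
                        config$band_edges)

  catchments <- derive_catchments(assignments)
  centroids <- catchment_centroids(catchments, fused)

  catch_tabs <- lapply(config$catchment_strata, function(s)
    catchment_summaries(fused, catchments, dyn$observations, s, eds))

  stats_tabs <- lapply(catch_tabs, function(tab) {
    d <- dplyr::inner_join(centroids, tab, by = "ed_id")
    moran <- if (diff(range(d$diff_pct)) > 1e-9) {
      wts <- inverse_distance_weights(d)
      morans_i(d$diff_pct, wts, config$n_permutations, config$stats_seed)
    } else NULL   # constant surface: I undefined (identity scenario)
    grp <- split(d$diff_pct, paste0("level", d$level))
    grp <- grp[lengths(grp) > 0]
    anova <- if (length(grp) >= 2 && sum(lengths(grp)) > length(grp))
      one_way_anova(grp) else NULL
    tukey <- if (!is.null(anova)) tukey_hsd(grp) else NULL
    list(moran = moran, anova = anova, tukey = tukey)
  })

  res <- list(config = config, static = static, classes = classes,
              roads = roads, eds = eds, dynamic = dyn, graph = graph,
              fused = fused, assignments = assignments,
              band_summary = band_summary, ratios = ratios,
              catchments = catchments, centroids = centroids,
              catchment_summaries = catch_tabs, stats = stats_tabs,
              n_omitted = n_omitted)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  invisible(res)
}

config_hash <- function(config) rlang::hash(config)

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_grid_geojson(res$static, p("static_grid.geojson"))
  write_grid_geojson(res$dynamic$cells, p("dynamic_grid.geojson"))
  fused_flat <- res$fused[vapply(res$fused, is.atomic, logical(1))]
  fused_flat$x0 <- fused_flat$x0 * res$static$size_m[1]
  fused_flat$y0 <- fused_flat$y0 * res$static$size_m[1]
  fused_flat$size_m <- res$fused$side * res$static$size_m[1]
  write_grid_geojson(fused_flat, p("fused_grid.geojson"))
  write_roads_geojson(res$roads, p("roads.geojson"))
  write_eds_geojson(res$eds, p("eds.geojson"))
  write_observations_csv(res$dynamic$observations, p("observations.csv"))
  utils::write.csv(res$classes, p("classes.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(res$assignments, p("assignments.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(res$band_summary, p("band_summary.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(res$ratios, p("ratios.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(res$catchments, p("catchments.csv"), row.names = FALSE,
                   quote = FALSE)
  for (nm in names(res$catchment_summaries))
    utils::write.csv(res$catchment_summaries[[nm]],
                     p(sprintf("catchment_summary_%s.csv", nm)),
                     row.names = FALSE, quote = FALSE)
  stats_rows <- lapply(names(res$stats), function(nm) {
    s <- res$stats[[nm]]
    tibble::tibble(
      stratum = nm,
      moran_i = s$moran$I %||% NA_real_,
      moran_expected = s$moran$expected %||% NA_real_,
      moran_z = s$moran$z %||% NA_real_,
      moran_p_analytic = s$moran$p_analytic %||% NA_real_,
      moran_p_perm = s$moran$p_perm %||% NA_real_,
      anova_F = s$anova$F %||% NA_real_,
      anova_df_between = s$anova$df_between %||% NA_integer_,
      anova_df_within = s$anova$df_within %||% NA_integer_,
      anova_p = s$anova$p %||% NA_real_)
  })
  utils::write.csv(dplyr::bind_rows(stats_rows), p("stats.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("dynaccess")),
    r_version = as.character(getRversion()),
    seed = res$config$scenario$seed,
    config_hash = config_hash(res$config),
    n_static_cells = nrow(res$static),
    n_dynamic_cells = nrow(res$dynamic$cells),
    n_fused_cells = nrow(res$fused),
    n_omitted_cells = res$n_omitted,
    n_eds = nrow(res$eds))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
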