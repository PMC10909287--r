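# GeoJSON and CSV readers/writers. All geometry is planar (projected metres);
# nothing is ever reprojected. Grid cells are axis-aligned squares, roads are
# LineStrings, EDs are Points.

square_ring <- function(x0, y0, size) {
  list(c(x0, y0), c(x0 + size, y0), c(x0 + size, y0 + size),
       c(x0, y0 + size), c(x0, y0))
}

feature <- function(geometry, properties) {
  list(type = "Feature", geometry = geometry, properties = properties)
}

write_feature_collection <- function(features, path) {
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Write a grid (static, dynamic, or fused) as GeoJSON polygons
#'
#' @param cells tibble with `cell_id` and either `x0`/`y0`/`size_m` in metres
#'   or `x0_m`/`y0_m`/`size_m`; all other atomic columns become feature
#'   properties.
#' @param path output file.
#' @export
write_grid_geojson <- function(cells, path) {
  x0 <- if ("x0_m" %in% names(cells)) cells$x0_m else cells$x0
  y0 <- if ("y0_m" %in% names(cells)) cells$y0_m else cells$y0
  keep <- vapply(cells, is.atomic, logical(1))
  props <- cells[keep]
  feats <- lapply(seq_len(nrow(cells)), function(i) {
    feature(list(type = "Polygon",
                 coordinates = list(square_ring(x0[i], y0[i], cells$size_m[i]))),
            as.list(props[i, ]))
  })
  write_feature_collection(feats, path)
}

#' Write road segments as GeoJSON LineStrings
#' @param segments segment tibble (`segment_id`, `speed_kmh`, `coords`).
#' @param path output file.
#' @export
write_roads_geojson <- function(segments, path) {
  feats <- lapply(seq_len(nrow(segments)), function(i) {
    m <- segments$coords[[i]]
    feature(list(type = "LineString",
                 coordinates = lapply(seq_len(nrow(m)), function(r) m[r, ])),
            list(segment_id = segments$segment_id[i],
                 speed_kmh = segments$speed_kmh[i]))
  })
  write_feature_collection(feats, path)
}

#' Write ED locations as GeoJSON points
#' @param eds ED tibble (`ed_id`, `level`, `x`, `y`).
#' @param path output file.
#' @export
write_eds_geojson <- function(eds, path) {
  feats <- lapply(seq_len(nrow(eds)), function(i) {
    feature(list(type = "Point", coordinates = c(eds$x[i], eds$y[i])),
            list(ed_id = eds$ed_id[i], level = eds$level[i]))
  })
  write_feature_collection(feats, path)
}

#' Read and validate a GeoJSON layer
#'
#' Supported kinds: `"roads"` (LineStrings, require positive `speed_kmh`),
#' `"eds"` (Points, require `level` in 1..3), `"grid"` (axis-aligned square
#' Polygons; `static_pop`, when present, must be non-negative). Coordinates
#' are taken verbatim (planar metres).
#'
#' @param path GeoJSON file.
#' @param kind one of `"roads"`, `"eds"`, `"grid"`.
#' @return a typed tibble matching the corresponding writer's input.
#' @export
read_geojson_layer <- function(path, kind = c("roads", "eds", "grid")) {
  kind <- match.arg(kind)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features %||% list()
  if (length(feats) == 0) {
    warnf("empty FeatureCollection: %s", path)
    return(switch(kind,
      roads = tibble::tibble(segment_id = character(), speed_kmh = numeric(),
                             coords = list()),
      eds = tibble::tibble(ed_id = character(), level = integer(),
                           x = numeric(), y = numeric()),
      grid = tibble::tibble(cell_id = character(), x0 = numeric(),
                            y0 = numeric(), size_m = numeric(),
                            cx = numeric(), cy = numeric())))
  }
  fid <- function(f, i) as.character(f$properties$segment_id %||%
                                       f$properties$ed_id %||%
                                       f$properties$cell_id %||% i)
  if (kind == "roads") {
    rows <- lapply(seq_along(feats), function(i) {
      f <- feats[[i]]
      sp <- f$properties$speed_kmh
      if (is.null(sp) || !is.numeric(sp) || sp <= 0)
        stopf("schema error in feature %s: missing or non-positive speed_kmh", fid(f, i))
      m <- do.call(rbind, lapply(f$geometry$coordinates, unlist))
      tibble::tibble(segment_id = fid(f, i), speed_kmh = sp, coords = list(m))
    })
    return(dplyr::bind_rows(rows))
  }
  if (kind == "eds") {
    rows <- lapply(seq_along(feats), function(i) {
      f <- feats[[i]]
      lev <- f$properties$level
      if (is.null(lev) || !lev %in% 1:3)
        stopf("schema error in feature %s: missing or invalid level (must be 1, 2 or 3)",
              fid(f, i))
      xy <- unlist(f$geometry$coordinates)
      tibble::tibble(ed_id = fid(f, i), level = as.integer(lev),
                     x = xy[1], y = xy[2])
    })
    return(dplyr::bind_rows(rows))
  }
  rows <- lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    xs <- range(ring[, 1]); ys <- range(ring[, 2])
    if (abs(diff(xs) - diff(ys)) > 1e-6)
      stopf("schema error in feature %s: grid cell is not square", fid(f, i))
    pop <- f$properties$static_pop
    if (!is.null(pop) && pop < 0)
      stopf("schema error in feature %s: negative static_pop", fid(f, i))
    tibble::tibble(cell_id = fid(f, i), x0 = xs[1], y0 = ys[1],
                   size_m = diff(xs), cx = mean(xs), cy = mean(ys),
                   static_pop = pop %||% NA_real_)
  })
  dplyr::bind_rows(rows)
}

#' Read and validate the dynamic observation stream
#'
#' @param path CSV with columns `cell_id,month,daytype,hour,count`.
#' @param dynamic_cells optional dynamic grid tibble; if given, observation
#'   cell ids must all be known.
#' @return validated observation tibble.
#' @export
read_observations_csv <- function(path, dynamic_cells = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "month", "daytype", "hour", "count")
  if (!all(need %in% names(df)))
    stopf("observations file %s lacks column(s): %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  bad <- which(is.na(df$count) | df$count < 0)
  if (length(bad)) stopf("invalid count at line %d of %s", bad[1] + 1L, path)
  bad <- which(is.na(df$hour) | df$hour < 0 | df$hour > 23)
  if (length(bad)) stopf("invalid hour at line %d of %s", bad[1] + 1L, path)
  bad <- which(is.na(df$month) | df$month < 1 | df$month > 12)
  if (length(bad)) stopf("invalid month at line %d of %s", bad[1] + 1L, path)
  bad <- which(!df$daytype %in% c("weekday", "weekend"))
  if (length(bad)) stopf("invalid daytype at line %d of %s", bad[1] + 1L, path)
  if (!is.null(dynamic_cells)) {
    unknown <- setdiff(df$cell_id, dynamic_cells$cell_id)
    if (length(unknown))
      stopf("observations reference unknown cell id(s): %s",
            paste(utils::head(unknown, 5), collapse = ", "))
  }
  tibble::as_tibble(df)
}

#' Write the observation stream as CSV
#' @param observations observation tibble.
#' @param path output file.
#' @export
write_observations_csv <- function(observations, path) {
  utils::write.csv(observations, path, row.names = FALSE, quote = FALSE)
}
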