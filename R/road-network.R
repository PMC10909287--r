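#' Split road segments at intersections
#'
#' Wherever a coordinate interior to one segment coincides exactly with any
#' vertex (endpoint or interior) of another segment, the segment is split
#' there, so that every connection in the network happens at a segment
#' endpoint. Intersections are detected by exact shared coordinates, not by
#' geometric crossing: road databases encode connectivity through shared
#' vertices, and geometric crossing would falsely connect bridges and
#' overpasses. Split pieces inherit the parent's speed limit; total length is
#' conserved; zero-length pieces are dropped with a warning.
#'
#' @param segments tibble with `segment_id`, `speed_kmh`, `coords` (list of
#'   n x 2 matrices).
#' @return tibble of the same shape, with split segments suffixed `#1`, `#2`, ...
#' @export
split_segments_at_intersections <- function(segments) {
  if (nrow(segments) == 0) return(segments)
  keys <- lapply(segments$coords, function(m) coord_key(m[, 1], m[, 2]))
  # vertex occurrence counts over all segments (each segment's vertex set
  # counted once) let us detect "appears in another segment" in O(1)
  tab <- table(unlist(lapply(keys, unique), use.names = FALSE))
  out <- vector("list", nrow(segments))
  dropped <- 0L
  for (s in seq_len(nrow(segments))) {
    m <- segments$coords[[s]]
    k <- keys[[s]]
    shared <- as.vector(tab[k]) > 1
    cut_at <- which(shared)
    cut_at <- cut_at[cut_at > 1 & cut_at < length(k)]  # interior vertices only
    bounds <- unique(c(1L, cut_at, length(k)))
    pieces <- list()
    for (p in seq_len(length(bounds) - 1)) {
      piece <- m[bounds[p]:bounds[p + 1], , drop = FALSE]
      if (polyline_length(piece) <= 0) dropped <- dropped + 1L
      else pieces[[length(pieces) + 1]] <- piece
    }
    ids <- if (length(pieces) > 1)
      sprintf("%s#%d", segments$segment_id[s], seq_along(pieces))
    else segments$segment_id[s]
    out[[s]] <- tibble::tibble(segment_id = ids,
                               speed_kmh = segments$speed_kmh[s],
                               coords = pieces)
  }
  if (dropped > 0) warnf("dropped %d zero-length piece(s) after splitting", dropped)
  dplyr::bind_rows(out)
}

#' Remove walking roads
#'
#' Walking roads are segments with a speed limit below 10 km/h; they are
#' removed before routing (strictly below: a 10 km/h segment is kept).
#'
#' @param segments segment tibble.
#' @return segments with `speed_kmh >= 10`.
#' @export
filter_walking_roads <- function(segments) {
  segments[segments$speed_kmh >= 10, ]
}

#' Build the travel-time road graph
#'
#' Nodes are the unique segment endpoints; each segment becomes one
#' undirected edge weighted by its travel time in minutes,
#' `length_m / (speed_kmh * 1000 / 60)`. Parallel edges between the same node
#' pair are collapsed keeping the minimum travel time. Segments should
#' already be split at intersections and filtered of walking roads.
#'
#' @param segments segment tibble.
#' @return an [igraph::graph] with vertex attributes `x`, `y` and edge
#'   attributes `travel_time_min`, `length_m`. Vertex names are assigned in
#'   lexicographic coordinate order (`v00001`, `v00002`, ...), giving
#'   deterministic tie-breaks downstream.
#' @export
build_graph <- function(segments) {
  if (nrow(segments) == 0)
    return(igraph::make_empty_graph(directed = FALSE))
  ends <- do.call(rbind, lapply(segments$coords, function(m)
    m[c(1, nrow(m)), , drop = FALSE]))
  pts <- unique(as.data.frame(ends))
  pts <- pts[order(pts[[1]], pts[[2]]), ]
  pts$name <- sprintf("v%05d", seq_len(nrow(pts)))
  key2name <- stats::setNames(pts$name, coord_key(pts[[1]], pts[[2]]))

  from <- vapply(segments$coords, function(m) key2name[[coord_key(m[1, 1], m[1, 2])]],
                 character(1))
  to <- vapply(segments$coords, function(m)
    key2name[[coord_key(m[nrow(m), 1], m[nrow(m), 2])]], character(1))
  len <- vapply(segments$coords, polyline_length, numeric(1))
  tt <- len / (segments$speed_kmh * 1000 / 60)

  a <- pmin(from, to); b <- pmax(from, to)
  ed <- data.frame(a = a, b = b, travel_time_min = tt, length_m = len)
  ed <- ed[order(ed$a, ed$b, ed$travel_time_min), ]
  ed <- ed[!duplicated(ed[c("a", "b")]), ]          # keep min travel time
  ed <- ed[ed$a != ed$b, ]                          # drop degenerate loops

  g <- igraph::graph_from_data_frame(
    ed, directed = FALSE,
    vertices = data.frame(name = pts$name, x = pts[[1]], y = pts[[2]]))
  g
}

#' Snap grid-cell centroids to the road network
#'
#' Each centroid is assigned its Euclidean-nearest graph node (junction).
#' Centroids farther than `max_dist_m` from every node are marked
#' unreachable and excluded from routing, mirroring the omission of cells
#' inaccessible from the road network. Ties between equidistant nodes are
#' broken by the lower node id.
#'
#' @param cells tibble with `cell_id`, `cx`, `cy`.
#' @param graph road graph from [build_graph()].
#' @param max_dist_m snap eligibility threshold in metres (default 5000).
#' @return tibble `cell_id`, `snapped_node`, `snap_distance_m`, `reachable`.
#' @export
snap_cells <- function(cells, graph, max_dist_m = 5000) {
  if (igraph::vcount(graph) == 0) {
    warnf("empty road graph: all %d cells unreachable", nrow(cells))
    return(tibble::tibble(cell_id = cells$cell_id, snapped_node = NA_character_,
                          snap_distance_m = NA_real_, reachable = FALSE))
  }
  nm <- igraph::V(graph)$name
  ord <- order(nm)
  nm <- nm[ord]
  nx <- igraph::V(graph)$x[ord]
  ny <- igraph::V(graph)$y[ord]
  res <- lapply(seq_len(nrow(cells)), function(i) {
    d <- sqrt((nx - cells$cx[i])^2 + (ny - cells$cy[i])^2)
    j <- which.min(d)                      # first minimum = lowest node id
    list(node = nm[j], dist = d[j])
  })
  dist <- vapply(res, `[[`, numeric(1), "dist")
  tibble::tibble(
    cell_id = cells$cell_id,
    snapped_node = vapply(res, `[[`, character(1), "node"),
    snap_distance_m = dist,
    reachable = dist <= max_dist_m
  )
}

#' Closest-facility analysis
#'
#' For every reachable cell, computes the minimum travel time over all EDs of
#' the shortest (quickest) path from the cell's snapped node to the ED's
#' snapped node, and records which ED attains it. Ties are broken by the
#' lower `ed_id`. Cells in graph components containing no ED are marked
#' unreachable.
#'
#' @param graph road graph.
#' @param eds tibble with `ed_id`, `x`, `y` (and optionally `level`).
#' @param assignments snap table from [snap_cells()].
#' @param max_dist_m snap threshold applied to the EDs themselves.
#' @return `assignments` with `travel_time_min` and `ed_id` columns added;
#'   `reachable` updated.
#' @export
closest_facility <- function(graph, eds, assignments, max_dist_m = 5000) {
  if (is.null(eds) || nrow(eds) == 0) stopf("closest_facility: no EDs supplied")
  eds <- eds[order(eds$ed_id), ]
  ed_snap <- snap_cells(
    tibble::tibble(cell_id = eds$ed_id, cx = eds$x, cy = eds$y),
    graph, max_dist_m)
  if (!any(ed_snap$reachable)) stopf("closest_facility: no ED could be snapped")
  ed_snap <- ed_snap[ed_snap$reachable, ]

  D <- igraph::distances(graph, v = ed_snap$snapped_node,
                         weights = igraph::E(graph)$travel_time_min)
  out <- assignments
  out$travel_time_min <- NA_real_
  out$ed_id <- NA_character_
  idx <- which(out$reachable)
  if (length(idx)) {
    cols <- match(out$snapped_node[idx], colnames(D))
    tt <- D[, cols, drop = FALSE]
    best <- apply(tt, 2, which.min)        # first minimum = lowest ed_id
    tmin <- tt[cbind(best, seq_along(cols))]
    ok <- is.finite(tmin)
    out$travel_time_min[idx[ok]] <- tmin[ok]
    out$ed_id[idx[ok]] <- ed_snap$cell_id[best[ok]]
    out$reachable[idx[!ok]] <- FALSE       # component without any ED
  }
  out
}
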