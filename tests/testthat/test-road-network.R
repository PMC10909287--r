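test_that("segments sharing only endpoints are left unchanged", {
  segs <- dplyr::bind_rows(seg("a", 50, 0, 0, 100, 0),
                           seg("b", 50, 100, 0, 200, 0))
  out <- split_segments_at_intersections(segs)
  expect_equal(out$segment_id, c("a", "b"))
  expect_equal(out$coords, segs$coords)
})

test_that("a segment is split where another segment ends on its interior vertex", {
  segs <- dplyr::bind_rows(
    seg("abc", 70, 0, 0, 100, 0, 200, 0),   # A-B-C with interior vertex B
    seg("bd", 50, 100, 0, 100, 300))        # B-D
  out <- split_segments_at_intersections(segs)
  expect_equal(nrow(out), 3L)
  expect_setequal(out$segment_id, c("abc#1", "abc#2", "bd"))
  expect_equal(sum(vapply(out$coords, dynaccess:::polyline_length, numeric(1))),
               sum(vapply(segs$coords, dynaccess:::polyline_length, numeric(1))))
  expect_true(all(out$speed_kmh[grepl("abc", out$segment_id)] == 70))
})

test_that("splitting conserves total length on a random lattice", {
  cfg <- scenario_config(grid_extent = 6L, merge_fraction = 0.5, seed = 7L)
  roads <- generate_road_network(cfg)
  out <- split_segments_at_intersections(roads)
  expect_gte(nrow(out), nrow(roads))
  len <- function(s) sum(vapply(s$coords, dynaccess:::polyline_length, numeric(1)))
  expect_equal(len(out), len(roads), tolerance = 1e-12)
  # after splitting, every interior vertex of every segment is private to it
  keys <- lapply(out$coords, function(m) dynaccess:::coord_key(m[, 1], m[, 2]))
  tab <- table(unlist(lapply(keys, unique)))
  for (k in keys) {
    interior <- k[-c(1, length(k))]
    if (length(interior)) expect_true(all(tab[interior] == 1))
  }
})

test_that("walking-road filtering uses a strict 10 km/h boundary", {
  segs <- dplyr::bind_rows(seg("slow", 5, 0, 0, 10, 0),
                           seg("edge", 10, 0, 0, 10, 0),
                           seg("fast", 90, 0, 0, 10, 0))
  out <- filter_walking_roads(segs)
  expect_setequal(out$segment_id, c("edge", "fast"))
  empty <- filter_walking_roads(segs[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("edge travel times are length over speed, in minutes", {
  g1 <- build_graph(seg("a", 60, 0, 0, 1000, 0))
  expect_equal(igraph::E(g1)$travel_time_min, 1.0)
  g2 <- build_graph(seg("b", 90, 0, 0, 1500, 0))
  expect_equal(igraph::E(g2)$travel_time_min, 1.0)
})

test_that("parallel edges collapse to the fastest segment", {
  segs <- dplyr::bind_rows(seg("slow", 30, 0, 0, 1000, 0),
                           seg("fast", 60, 0, 0, 1000, 0))
  g <- build_graph(segs)
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::E(g)$travel_time_min, 1.0)
})

test_that("snapping picks the nearest node, flags far cells, breaks ties low", {
  g <- build_graph(path_graph_segments())   # nodes at x = 0..4000, y = 0
  cells <- tibble::tibble(
    cell_id = c("on_node", "far", "tie"),
    cx = c(2000, 2000, 500), cy = c(0, 6000, 0))
  snap <- snap_cells(cells, g, max_dist_m = 5000)
  expect_equal(snap$snap_distance_m[1], 0)
  expect_false(snap$reachable[2])
  # the tie cell sits halfway between the nodes at x=0 and x=1000
  nm <- sort(igraph::V(g)$name)
  xs <- igraph::V(g)$x[match(nm, igraph::V(g)$name)]
  low_node <- nm[xs %in% c(0, 1000)][1]
  expect_equal(snap$snapped_node[3], low_node)
})

test_that("empty graph marks everything unreachable with a warning", {
  g <- build_graph(seg("a", 50, 0, 0, 10, 0)[0, ])
  expect_warning(snap <- snap_cells(tibble::tibble(cell_id = "c", cx = 0, cy = 0), g),
                 "unreachable")
  expect_false(any(snap$reachable))
})

test_that("closest facility on the path graph matches the hand solution", {
  g <- build_graph(path_graph_segments())
  # EDs at the two ends; origin cells at every node
  eds <- tibble::tibble(ed_id = c("edA", "edE"), level = c(1L, 2L),
                        x = c(0, 4000), y = c(0, 0))
  cells <- tibble::tibble(cell_id = sprintf("c%d", 0:4),
                          cx = 0:4 * 1000, cy = 0)
  snap <- snap_cells(cells, g)
  out <- closest_facility(g, eds, snap)
  expect_equal(out$travel_time_min, c(0, 1, 2, 1, 0))
  # midpoint ties to the lower ed id
  expect_equal(out$ed_id, c("edA", "edA", "edA", "edE", "edE"))
  expect_error(closest_facility(g, eds[0, ], snap), "no EDs")
})

test_that("closest facility matches brute-force simple-path enumeration", {
  withr::with_seed(99, {
    for (rep in 1:20) {
      rg <- random_small_graph(sample(4:8, 1))
      oracle <- oracle_closest_facility(rg$graph, rg$ed_nodes, rg$nodes)
      cells <- tibble::tibble(
        cell_id = rg$nodes,
        cx = igraph::V(rg$graph)$x[match(rg$nodes, igraph::V(rg$graph)$name)],
        cy = igraph::V(rg$graph)$y[match(rg$nodes, igraph::V(rg$graph)$name)])
      snap <- snap_cells(cells, rg$graph)
      eds <- tibble::tibble(ed_id = sort(names(rg$ed_nodes)), level = 1L,
                            x = igraph::V(rg$graph)$x[match(sort(names(rg$ed_nodes)),
                                                            igraph::V(rg$graph)$name)],
                            y = igraph::V(rg$graph)$y[match(sort(names(rg$ed_nodes)),
                                                            igraph::V(rg$graph)$name)])
      out <- closest_facility(rg$graph, eds, snap)
      expect_equal(out$travel_time_min, unname(oracle[, "time"]),
                   tolerance = 1e-9)
    }
  })
})

test_that("adding an ED never increases, removing an edge never decreases times", {
  withr::with_seed(123, {
    rg <- random_small_graph(8, n_eds = 1)
    cells <- tibble::tibble(
      cell_id = rg$nodes,
      cx = igraph::V(rg$graph)$x[match(rg$nodes, igraph::V(rg$graph)$name)],
      cy = igraph::V(rg$graph)$y[match(rg$nodes, igraph::V(rg$graph)$name)])
    snap <- snap_cells(cells, rg$graph)
    xy <- function(n) c(igraph::V(rg$graph)$x[match(n, igraph::V(rg$graph)$name)],
                        igraph::V(rg$graph)$y[match(n, igraph::V(rg$graph)$name)])
    e1 <- names(rg$ed_nodes)[1]
    extra <- setdiff(rg$nodes, e1)[1]
    eds1 <- tibble::tibble(ed_id = "ed1", level = 1L,
                           x = xy(e1)[1], y = xy(e1)[2])
    eds2 <- dplyr::bind_rows(eds1, tibble::tibble(ed_id = "ed2", level = 2L,
                                                  x = xy(extra)[1], y = xy(extra)[2]))
    t1 <- closest_facility(rg$graph, eds1, snap)$travel_time_min
    t2 <- closest_facility(rg$graph, eds2, snap)$travel_time_min
    expect_true(all(t2 <= t1 + 1e-12, na.rm = TRUE))

    g_less <- igraph::delete_edges(rg$graph, 1)
    snap2 <- snap_cells(cells, g_less)
    t3 <- closest_facility(g_less, eds1, snap2)$travel_time_min
    both <- !is.na(t1) & !is.na(t3)
    expect_true(all(t3[both] >= t1[both] - 1e-12))
  })
})

test_that("travel times satisfy the triangle property on adjacent nodes", {
  cfg <- scenario_config(grid_extent = 6L, walking_fraction = 0, seed = 5L)
  roads <- filter_walking_roads(split_segments_at_intersections(
    generate_road_network(cfg)))
  g <- build_graph(roads)
  nodes <- igraph::V(g)$name
  cells <- tibble::tibble(cell_id = nodes,
                          cx = igraph::V(g)$x, cy = igraph::V(g)$y)
  eds <- tibble::tibble(ed_id = "ed1", level = 1L,
                        x = cells$cx[1], y = cells$cy[1])
  out <- closest_facility(g, eds, snap_cells(cells, g))
  t <- stats::setNames(out$travel_time_min, out$cell_id)
  el <- igraph::as_data_frame(g, what = "edges")
  gap <- abs(t[el$from] - t[el$to])
  expect_true(all(gap <= el$travel_time_min + 1e-9))
})
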