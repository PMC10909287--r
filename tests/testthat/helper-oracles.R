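# Independent oracles: deliberately naive implementations used only to check
# the package's results. They never share code with the implementation.

# --- routing ----------------------------------------------------------------

# adjacency list (node name -> list of (to, w)) from an igraph object
graph_adjacency <- function(graph) {
  el <- igraph::as_data_frame(graph, what = "edges")
  adj <- list()
  add <- function(a, b, w) {
    adj[[a]] <<- c(adj[[a]], list(list(to = b, w = w)))
  }
  for (i in seq_len(nrow(el))) {
    add(el$from[i], el$to[i], el$travel_time_min[i])
    add(el$to[i], el$from[i], el$travel_time_min[i])
  }
  for (v in igraph::V(graph)$name) if (is.null(adj[[v]])) adj[[v]] <- list()
  adj
}

# minimum travel time over ALL simple paths from `from` to `to`
oracle_simple_path_time <- function(adj, from, to) {
  best <- Inf
  rec <- function(node, visited, cost) {
    if (node == to) { best <<- min(best, cost); return(invisible()) }
    for (nb in adj[[node]]) {
      if (!(nb$to %in% visited)) rec(nb$to, c(visited, nb$to), cost + nb$w)
    }
  }
  rec(from, from, 0)
  best
}

# closest-facility by exhaustive enumeration: for each origin the min over
# EDs of the simple-path minimum, with ties broken by lower ed id
oracle_closest_facility <- function(graph, ed_nodes, origins) {
  adj <- graph_adjacency(graph)
  ed_nodes <- ed_nodes[order(names(ed_nodes))]
  t(vapply(origins, function(o) {
    times <- vapply(ed_nodes, function(e) oracle_simple_path_time(adj, o, e),
                    numeric(1))
    j <- which.min(times)
    c(time = unname(times[j]), ed = j)
  }, c(time = 0, ed = 0)))
}

# random connected-ish weighted graph with <= n nodes, built as segments so
# the whole build path is exercised
random_small_graph <- function(n_nodes, n_eds = 2) {
  pts <- cbind(x = stats::runif(n_nodes, 0, 1000),
               y = stats::runif(n_nodes, 0, 1000))
  # spanning chain plus random chords
  edges <- cbind(seq_len(n_nodes - 1), 2:n_nodes)
  extra <- matrix(sample.int(n_nodes, 2 * n_nodes, replace = TRUE), ncol = 2)
  extra <- extra[extra[, 1] != extra[, 2], , drop = FALSE]
  edges <- rbind(edges, extra)
  segs <- tibble::tibble(
    segment_id = sprintf("e%02d", seq_len(nrow(edges))),
    speed_kmh = sample(c(30, 50, 70, 90), nrow(edges), replace = TRUE),
    coords = lapply(seq_len(nrow(edges)), function(i)
      pts[edges[i, ], , drop = FALSE]))
  graph <- build_graph(segs)
  nodes <- sort(igraph::V(graph)$name)
  eds <- sample(nodes, min(n_eds, length(nodes)))
  list(graph = graph, pts = pts, ed_nodes = stats::setNames(eds, eds),
       nodes = nodes)
}

# --- Moran's I --------------------------------------------------------------

# direct evaluation of the cross-product formula, written independently
oracle_moran <- function(x, w) {
  n <- length(x)
  xb <- mean(x)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + w[i, j] * (x[i] - xb) * (x[j] - xb)
  (n / sum(w)) * num / sum((x - xb)^2)
}

# --- ANOVA / Tukey ----------------------------------------------------------

oracle_anova_F <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ss_between <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                           numeric(1)))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  k <- length(groups); N <- length(all)
  (ss_between / (k - 1)) / (ss_within / (N - k))
}

# Tukey-Kramer interval half-width and adjusted p for one pair, straight from
# the studentized-range distribution
oracle_tukey_pair <- function(groups, i, j, conf = 0.95) {
  k <- length(groups); N <- sum(lengths(groups))
  msw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) /
    (N - k)
  se <- sqrt(msw / 2 * (1 / length(groups[[i]]) + 1 / length(groups[[j]])))
  d <- mean(groups[[j]]) - mean(groups[[i]])
  list(diff = d,
       half_width = stats::qtukey(conf, k, N - k) * se,
       p = stats::ptukey(abs(d) / se, k, N - k, lower.tail = FALSE))
}

# --- fusion -----------------------------------------------------------------

# random nested scenario: a static grid plus a random aligned quadtree
# partition of it into dynamic cells (sides 2^k or one half)
random_nested_grids <- function(extent = 8) {
  cfg <- scenario_config(grid_extent = extent, cell_size = 1000,
                         pop_peak = stats::runif(1, 0, 500),
                         pop_base = sample(0:30, 1), seed = sample.int(1e6, 1))
  static <- generate_static_grid(cfg)
  static$static_pop <- static$static_pop + stats::runif(nrow(static), 0, 5)
  cells <- list()
  carve <- function(x0, y0, side) {
    choice <- stats::runif(1)
    if (side > 1 && choice < 0.6) {
      h <- side / 2
      for (dx in c(0, h)) for (dy in c(0, h)) carve(x0 + dx, y0 + dy, h)
    } else if (side == 1 && choice < 0.4) {
      for (dx in c(0, 0.5)) for (dy in c(0, 0.5))
        cells[[length(cells) + 1]] <<- c(x0 + dx, y0 + dy, 0.5)
    } else {
      cells[[length(cells) + 1]] <<- c(x0, y0, side)
    }
  }
  carve(0, 0, extent)
  m <- do.call(rbind, cells)
  dynamic <- tibble::tibble(cell_id = sprintf("d%04d", seq_len(nrow(m))),
                            x0 = m[, 1], y0 = m[, 2], side = m[, 3])
  list(static = static, dynamic = dynamic)
}
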