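#' Classify travel times into accessibility bands
#'
#' Bands are the half-open intervals [0,10), [10,20), [20,30), [30,60),
#' [60, Inf) minutes — disjoint and exhaustive for non-negative times.
#'
#' @param travel_time_min non-negative travel times (minutes).
#' @param edges increasing interior band edges (default `c(10, 20, 30, 60)`).
#' @return ordered factor with levels `0-10`, `10-20`, `20-30`, `30-60`, `>60`
#'   (labels derived from `edges`).
#' @export
classify_band <- function(travel_time_min, edges = c(10, 20, 30, 60)) {
  if (any(travel_time_min < 0, na.rm = TRUE))
    stopf("classify_band: negative travel time")
  if (any(diff(edges) <= 0) || any(edges <= 0))
    stopf("classify_band: band edges must be positive and strictly increasing")
  labs <- c(paste0(c(0, edges[-length(edges)]), "-", edges),
            paste0(">", edges[length(edges)]))
  cut(travel_time_min, breaks = c(0, edges, Inf), labels = labs,
      right = FALSE, ordered_result = TRUE)
}

#' Band labels for a set of edges
#' @inheritParams classify_band
#' @return character vector of band labels, closest first.
#' @export
band_levels <- function(edges = c(10, 20, 30, 60)) {
  c(paste0(c(0, edges[-length(edges)]), "-", edges),
    paste0(">", edges[length(edges)]))
}

#' Summarize population by travel-time band and urban class
#'
#' Sums population per (class, band) cell group and per band over all
#' classes (the `Total` row), and computes each band's share of its row
#' total in percent. Works identically for static populations and for any
#' stratum's dynamic populations.
#'
#' @param population numeric population per cell.
#' @param band band factor per cell (from [classify_band()]).
#' @param class urban class per cell; if `NULL`, only the Total row is
#'   produced.
#' @return tibble `class`, `band`, `population`, `share_pct` (shares within
#'   each class row sum to 100).
#' @export
summarize_population_by_band <- function(population, band, class = NULL) {
  lv <- levels(band) %||% sort(unique(as.character(band)))
  df <- tibble::tibble(population = population,
                       band = factor(as.character(band), levels = lv))
  rows <- list()
  add_row_group <- function(label, d) {
    sums <- tapply(d$population, d$band, sum, default = 0)
    tibble::tibble(class = label, band = lv, population = as.numeric(sums),
                   share_pct = 100 * as.numeric(sums) / sum(sums))
  }
  if (!is.null(class)) {
    df$class <- as.character(class)
    for (cl in sort(unique(df$class)))
      rows[[cl]] <- add_row_group(cl, df[df$class == cl, ])
  }
  rows[["Total"]] <- add_row_group("Total", df)
  dplyr::bind_rows(rows)
}

#' Derive ED catchment areas
#'
#' The catchment of an ED is the set of reachable cells whose closest
#' (quickest-reached) ED it is; catchments partition the reachable cells.
#'
#' @param assignments closest-facility output.
#' @return tibble `cell_id`, `ed_id` over reachable cells.
#' @export
derive_catchments <- function(assignments) {
  ok <- assignments$reachable & !is.na(assignments$ed_id)
  tibble::tibble(cell_id = assignments$cell_id[ok],
                 ed_id = assignments$ed_id[ok])
}

#' Representative point of each catchment
#'
#' The static-population-weighted mean of the member cells' centroids. For a
#' catchment whose total static population is zero, the unweighted centroid
#' mean is used.
#'
#' @param catchments tibble `cell_id`, `ed_id` from [derive_catchments()].
#' @param fused fused grid (needs `cell_id`, `cx`, `cy`, `static_pop`).
#' @return tibble `ed_id`, `x`, `y`.
#' @export
catchment_centroids <- function(catchments, fused) {
  if (nrow(catchments) == 0) stopf("catchment_centroids: empty catchments")
  d <- dplyr::left_join(catchments, fused[c("cell_id", "cx", "cy", "static_pop")],
                        by = "cell_id")
  d |>
    dplyr::group_by(.data$ed_id) |>
    dplyr::summarise(
      x = if (sum(.data$static_pop) > 0)
        stats::weighted.mean(.data$cx, .data$static_pop) else mean(.data$cx),
      y = if (sum(.data$static_pop) > 0)
        stats::weighted.mean(.data$cy, .data$static_pop) else mean(.data$cy),
      .groups = "drop")
}
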