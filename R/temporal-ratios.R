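#' Mean dynamic population per cell at a temporal stratum
#'
#' A stratum is any combination of `month`, `daytype` and `hour`; fields left
#' `NULL` are pooled over. The dynamic population of a cell at the stratum is
#' the arithmetic mean of its counts over all matching observations.
#'
#' @param observations tibble `cell_id`, `month`, `daytype`, `hour`, `count`.
#' @param stratum list with any of `month`, `daytype`, `hour` set.
#' @return tibble `cell_id`, `count`.
#' @export
stratum_dynamic_population <- function(observations, stratum) {
  keep <- rep(TRUE, nrow(observations))
  for (f in c("month", "daytype", "hour")) {
    if (!is.null(stratum[[f]])) keep <- keep & observations[[f]] %in% stratum[[f]]
  }
  if (!any(keep))
    stopf("no observations match stratum (month=%s, daytype=%s, hour=%s)",
          stratum$month %||% "*", stratum$daytype %||% "*", stratum$hour %||% "*")
  observations[keep, ] |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(count = mean(.data$count), .groups = "drop")
}

#' Population share per accessibility band
#'
#' `share(b)` is the population in band `b` divided by the total population
#' over all included cells; shares sum to 1. Only reachable cells should be
#' passed in.
#'
#' @param population non-negative population per cell (total > 0).
#' @param band band factor per cell.
#' @return tibble `band`, `share` (one row per band level, zeros included).
#' @export
band_shares <- function(population, band) {
  if (any(population < 0)) stopf("band_shares: negative population")
  total <- sum(population)
  if (total <= 0) stopf("band_shares: zero total population")
  lv <- levels(band) %||% sort(unique(as.character(band)))
  sums <- tapply(population, factor(as.character(band), levels = lv),
                 sum, default = 0)
  tibble::tibble(band = lv, share = as.numeric(sums) / total)
}

#' Static/dynamic over- or underestimation ratio
#'
#' The static share divided by the dynamic share for the same spatial unit
#' and stratum. Values above 1 mean static (residential) data overestimates
#' the share of the population present; below 1, underestimates. Undefined
#' where the dynamic share is zero: reported as `NA`, never as a number.
#'
#' @param static_share,dynamic_share shares in [0,1].
#' @return numeric ratio, `NA` where `dynamic_share == 0`.
#' @export
share_ratio <- function(static_share, dynamic_share) {
  ifelse(dynamic_share > 0, static_share / dynamic_share, NA_real_)
}

#' Ratio of static to dynamic band shares across temporal strata
#'
#' The core comparison: per stratum, the static population shares by
#' accessibility band (time-invariant) are divided by the dynamic shares at
#' that stratum. Because both numerator and denominator are normalized by
#' their own dataset's total over the same (reachable) cell set, any global
#' scale difference between the datasets cancels.
#'
#' @param fused fused grid with `static_pop`.
#' @param assignments closest-facility output (bands come from
#'   `travel_time_min`).
#' @param observations dynamic observation tibble.
#' @param strata list of stratum lists (see [stratum_dynamic_population()]).
#' @param edges band edges (minutes).
#' @return tibble `month`, `daytype`, `hour` (NA where pooled), `band`,
#'   `static_share`, `dynamic_share`, `ratio`.
#' @export
ratio_table <- function(fused, assignments, observations, strata,
                        edges = c(10, 20, 30, 60)) {
  cells <- dplyr::inner_join(
    fused[c("cell_id", "static_pop")],
    assignments[assignments$reachable,
                c("cell_id", "travel_time_min")], by = "cell_id")
  cells$band <- classify_band(cells$travel_time_min, edges)
  st <- band_shares(cells$static_pop, cells$band)
  rows <- lapply(strata, function(s) {
    dyn <- stratum_dynamic_population(observations, s)
    d <- dplyr::inner_join(cells, dyn, by = "cell_id")
    dy <- band_shares(d$count, d$band)
    tibble::tibble(
      month = (s$month %||% NA_integer_)[1],
      daytype = (s$daytype %||% NA_character_)[1],
      hour = (s$hour %||% NA_integer_)[1],
      band = st$band,
      static_share = st$share,
      dynamic_share = dy$share,
      ratio = share_ratio(st$share, dy$share))
  })
  dplyr::bind_rows(rows)
}

#' Per-catchment static versus dynamic shares at a stratum
#'
#' For each ED catchment: the catchment's share of the total static
#' population, its share of the total dynamic population at the stratum, and
#' the percentage difference `(static_share / dynamic_share - 1) * 100`
#' (positive = static overestimates the population present in the
#' catchment).
#'
#' @param fused fused grid.
#' @param catchments tibble `cell_id`, `ed_id`.
#' @param observations dynamic observations.
#' @param stratum a stratum list.
#' @param eds ED tibble (`ed_id`, `level`); optional, adds the `level` column.
#' @return tibble `ed_id`, `level`, `static_share`, `dynamic_share`,
#'   `diff_pct`.
#' @export
catchment_summaries <- function(fused, catchments, observations, stratum,
                                eds = NULL) {
  dyn <- stratum_dynamic_population(observations, stratum)
  d <- dplyr::left_join(catchments, fused[c("cell_id", "static_pop")],
                        by = "cell_id")
  d <- dplyr::left_join(d, dyn, by = "cell_id")
  if (anyNA(d$count))
    stopf("catchment_summaries: %d catchment cell(s) lack dynamic observations",
          sum(is.na(d$count)))
  tot_s <- sum(d$static_pop); tot_d <- sum(d$count)
  out <- d |>
    dplyr::group_by(.data$ed_id) |>
    dplyr::summarise(static_share = sum(.data$static_pop) / tot_s,
                     dynamic_share = sum(.data$count) / tot_d,
                     .groups = "drop")
  out$diff_pct <- (share_ratio(out$static_share, out$dynamic_share) - 1) * 100
  if (!is.null(eds)) {
    missing <- setdiff(eds$ed_id, out$ed_id)
    if (length(missing))
      warnf("ED(s) with empty catchment omitted: %s", paste(missing, collapse = ", "))
    out <- dplyr::left_join(out, eds[c("ed_id", "level")], by = "ed_id")
    out <- out[c("ed_id", "level", "static_share", "dynamic_share", "diff_pct")]
  }
  out
}
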