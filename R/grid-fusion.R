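#' Fuse the static and dynamic population grids
#'
#' Produces one harmonized grid carrying both population datasets. The two
#' grids must be border-aligned and nested (dynamic cell sides are powers of
#' 2 static cells, or exactly half a static cell). Where a dynamic cell is
#' smaller than a static cell, the static cell's population is divided
#' equally among its covering quarters (uniform within-cell density); where a
#' dynamic cell is larger, the populations of all covered static cells are
#' summed. Fused geometry equals the dynamic geometry; total static
#' population is conserved exactly; fractional populations are kept as reals.
#'
#' @param static static grid tibble (`cell_id`, `col`, `row`, `size_m`,
#'   `static_pop`).
#' @param dynamic dynamic grid tibble (`cell_id`, `x0`, `y0`, `side` in
#'   static-cell units; optionally `cx`, `cy` in metres).
#' @return tibble of fused cells: `cell_id` (the dynamic id), `x0`, `y0`,
#'   `side`, `cx`, `cy`, `static_pop`, and a `members` list column of
#'   `(cell_id, pop_part)` tibbles recording the contributing static cells.
#' @export
fuse_grids <- function(static, dynamic) {
  cs <- static$size_m[1]
  members <- vector("list", nrow(dynamic))
  pops <- numeric(nrow(dynamic))
  for (i in seq_len(nrow(dynamic))) {
    x0 <- dynamic$x0[i]; y0 <- dynamic$y0[i]; side <- dynamic$side[i]
    if (side >= 1) {
      if (x0 %% 1 != 0 || y0 %% 1 != 0 || !is_power_of_two(side))
        stopf("alignment error: dynamic cell %s (origin %g,%g side %g) is not nested in the static grid",
              dynamic$cell_id[i], x0, y0, side)
      # any static cell partially overlapping but not contained breaks nesting
      part <- static$col + 1 > x0 & static$col < x0 + side &
              static$row + 1 > y0 & static$row < y0 + side
      inside <- static$col >= x0 & static$col + 1 <= x0 + side &
                static$row >= y0 & static$row + 1 <= y0 + side
      if (any(part & !inside))
        stopf("alignment error: dynamic cell %s partially overlaps static cell %s",
              dynamic$cell_id[i], static$cell_id[which(part & !inside)[1]])
      idx <- which(inside)
      members[[i]] <- tibble::tibble(cell_id = static$cell_id[idx],
                                     pop_part = static$static_pop[idx])
    } else if (side == 0.5) {
      px <- floor(x0); py <- floor(y0)
      if (!(x0 %% 0.5 == 0 && y0 %% 0.5 == 0))
        stopf("alignment error: quarter cell %s misaligned", dynamic$cell_id[i])
      idx <- which(static$col == px & static$row == py)
      if (length(idx) != 1)
        stopf("alignment error: quarter cell %s has no parent static cell",
              dynamic$cell_id[i])
      members[[i]] <- tibble::tibble(cell_id = static$cell_id[idx],
                                     pop_part = static$static_pop[idx] / 4)
    } else {
      stopf("alignment error: unsupported dynamic cell side %g (cell %s)",
            side, dynamic$cell_id[i])
    }
    pops[i] <- sum(members[[i]]$pop_part)
  }
  tibble::tibble(
    cell_id = dynamic$cell_id,
    x0 = dynamic$x0, y0 = dynamic$y0, side = dynamic$side,
    cx = (dynamic$x0 + dynamic$side / 2) * cs,
    cy = (dynamic$y0 + dynamic$side / 2) * cs,
    static_pop = pops,
    members = members
  )
}

#' Attach urban classes to fused cells
#'
#' Quarter cells inherit their parent static cell's class; aggregated cells
#' take the class of the population-majority constituent (ties resolved
#' toward the more urban class: urban > densely_populated > rural).
#'
#' @param fused fused grid from [fuse_grids()].
#' @param classes tibble `cell_id`, `class` for the static cells.
#' @return `fused` with an `urban_class` column.
#' @export
attach_urban_class <- function(fused, classes) {
  lv <- c("urban", "densely_populated", "rural")
  lookup <- stats::setNames(classes$class, classes$cell_id)
  cls <- character(nrow(fused))
  missing <- character(0)
  for (i in seq_len(nrow(fused))) {
    mem <- fused$members[[i]]
    mc <- lookup[mem$cell_id]
    if (anyNA(mc)) {
      missing <- c(missing, mem$cell_id[is.na(mc)])
      next
    }
    pop_by <- tapply(mem$pop_part, factor(mc, levels = lv), sum, default = 0)
    cls[i] <- lv[which.max(pop_by)]   # ties break toward the more urban class
  }
  if (length(missing))
    stopf("missing urban class for static cell(s): %s",
          paste(unique(missing), collapse = ", "))
  fused$urban_class <- cls
  fused
}
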