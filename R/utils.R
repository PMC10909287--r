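#' @importFrom rlang %||% abort warn .data
#' @importFrom stats aov weighted.mean rpois pnorm ptukey qtukey sd var pf setNames
#' @importFrom utils read.csv write.csv
#' @importFrom dplyr group_by summarise mutate arrange left_join bind_rows
#'   filter select n across all_of
#' @importFrom tibble tibble as_tibble
NULL

# Euclidean length of a polyline given an n x 2 coordinate matrix
polyline_length <- function(coords) {
  if (nrow(coords) < 2) return(0)
  sum(sqrt(rowSums(diff(coords)^2)))
}

coord_key <- function(x, y) sprintf("%.9g|%.9g", x, y)

is_power_of_two <- function(x) {
  x > 0 && abs(log2(x) - round(log2(x))) < 1e-9
}

stopf <- function(fmt, ...) rlang::abort(sprintf(fmt, ...))
warnf <- function(fmt, ...) rlang::warn(sprintf(fmt, ...))
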