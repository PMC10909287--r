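#' Minimal distance threshold guaranteeing every point a neighbour
#'
#' Returns the maximum over points of the distance to its nearest other
#' point: the smallest cut-off at which every point has at least one
#' neighbour in a distance-band weights scheme.
#'
#' @param points tibble/data.frame with `x`, `y` (>= 2 distinct points).
#' @return threshold distance (same units as the coordinates).
#' @export
auto_threshold <- function(points) {
  n <- nrow(points)
  if (n < 2) stopf("auto_threshold: need at least 2 points")
  D <- as.matrix(stats::dist(cbind(points$x, points$y)))
  diag(D) <- Inf
  nn <- apply(D, 1, min)
  if (any(nn == 0)) stopf("auto_threshold: duplicate points (zero distance)")
  max(nn)
}

#' Inverse-distance spatial weights
#'
#' Pairwise weights `w_ij = 1 / d_ij` for `0 < d_ij <= threshold_m`, zero
#' beyond; neighbouring areas thus weigh more than distant ones. Weights are
#' symmetric with zero diagonal and, by default, not row-standardized.
#'
#' @param points tibble with `x`, `y`.
#' @param threshold_m neighbourhood cut-off; should be at least
#'   [auto_threshold()] (a warning is issued otherwise, since some point then
#'   has no neighbour).
#' @param row_standardize divide each row by its sum.
#' @return a `spatial_weights` list: `w` (n x n matrix), `threshold_m`, `S0`.
#' @export
inverse_distance_weights <- function(points, threshold_m = NULL,
                                     row_standardize = FALSE) {
  thr_min <- auto_threshold(points)
  threshold_m <- threshold_m %||% thr_min
  if (threshold_m < thr_min)
    warnf("threshold %.6g below the minimal all-neighbour threshold %.6g: some point has no neighbour",
          threshold_m, thr_min)
  D <- as.matrix(stats::dist(cbind(points$x, points$y)))
  w <- ifelse(D > 0 & D <= threshold_m, 1 / D, 0)
  diag(w) <- 0
  if (row_standardize) {
    rs <- rowSums(w)
    w <- sweep(w, 1, ifelse(rs > 0, rs, 1), "/")
  }
  structure(list(w = w, threshold_m = threshold_m, S0 = sum(w)),
            class = "spatial_weights")
}

#' Global Moran's I with permutation and analytic inference
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z = x - mean(x)`.
#' The permutation p-value shuffles the values over the locations and is
#' two-sided: `(1 + #{|I*| >= |I|}) / (1 + n_permutations)`. The analytic
#' z-test under the randomization assumption is reported alongside
#' (expectation `-1/(n-1)`, variance from the standard S1/S2/kurtosis
#' formula).
#'
#' @param values numeric vector (one per point; variance must be > 0).
#' @param weights a `spatial_weights` object (or bare matrix).
#' @param n_permutations number of random permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return list of class `moran_result`: `I`, `expected`, `z`, `p_analytic`,
#'   `p_perm`, `n`, `n_permutations`, `seed`.
#' @export
morans_i <- function(values, weights, n_permutations = 999, seed = 1L) {
  w <- if (inherits(weights, "spatial_weights")) weights$w else weights
  n <- length(values)
  if (n != nrow(w)) stopf("morans_i: %d values for %d locations", n, nrow(w))
  if (stats::var(values) == 0)
    stopf("morans_i: constant surface, I undefined")
  S0 <- sum(w)
  stat <- function(x) {
    z <- x - mean(x)
    (n / S0) * as.numeric(t(z) %*% w %*% z) / sum(z^2)
  }
  I <- stat(values)
  expected <- -1 / (n - 1)

  # randomization-assumption variance (defined for n >= 4)
  if (n >= 4) {
    z <- values - mean(values)
    S1 <- 0.5 * sum((w + t(w))^2)
    S2 <- sum((rowSums(w) + colSums(w))^2)
    b2 <- n * sum(z^4) / sum(z^2)^2
    varI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
               b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * S0^2) - expected^2
    zscore <- (I - expected) / sqrt(varI)
    p_analytic <- 2 * stats::pnorm(-abs(zscore))
  } else {
    zscore <- NA_real_
    p_analytic <- NA_real_
  }

  p_perm <- NA_real_
  if (n_permutations > 0) {
    perm <- withr::with_seed(seed, {
      vapply(seq_len(n_permutations), function(i) stat(sample(values)),
             numeric(1))
    })
    p_perm <- (1 + sum(abs(perm) >= abs(I))) / (1 + n_permutations)
  }
  structure(list(I = I, expected = expected, z = zscore,
                 p_analytic = p_analytic, p_perm = p_perm, n = n,
                 n_permutations = n_permutations, seed = seed),
            class = "moran_result")
}

#' One-way analysis of variance
#'
#' Standard between/within sum-of-squares decomposition,
#' `F = MS_between / MS_within`, p from the F distribution. If every group is
#' internally constant but the means differ, `F` is reported as `Inf` with
#' `p = 0`.
#'
#' @param groups named list of numeric vectors (>= 2 groups, total N >
#'   number of groups).
#' @return list of class `anova_result`: `F`, `df_between`, `df_within`, `p`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stopf("one_way_anova: need >= 2 groups")
  ns <- lengths(groups)
  if (any(ns < 1)) stopf("one_way_anova: empty group")
  N <- sum(ns); k <- length(groups)
  if (N <= k) stopf("one_way_anova: no within-group degrees of freedom")
  within_ss <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (within_ss == 0) {
    means <- vapply(groups, mean, numeric(1))
    if (max(means) - min(means) > 0) { Fv <- Inf; p <- 0 } else { Fv <- 0; p <- 1 }
  } else {
    df <- data.frame(value = unlist(groups, use.names = FALSE),
                     group = factor(rep(names(groups) %||% seq_along(groups), ns)))
    tab <- summary(stats::aov(value ~ group, data = df))[[1]]
    Fv <- tab[["F value"]][1]; p <- tab[["Pr(>F)"]][1]
  }
  structure(list(F = Fv, df_between = k - 1L, df_within = as.integer(N - k),
                 p = p), class = "anova_result")
}

#' Tukey HSD post-hoc comparisons
#'
#' All pairwise group mean differences with 95% family-wise confidence
#' intervals from the studentized-range distribution (Tukey–Kramer for
#' unequal group sizes) and adjusted p-values. The interval is reported as
#' `diff` plus/minus `half_width`; the interval excludes 0 exactly when the
#' adjusted p is below 0.05.
#'
#' @param groups named list of numeric vectors.
#' @param conf_level family-wise confidence level (default 0.95).
#' @return tibble `pair`, `diff`, `half_width`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(groups, conf_level = 0.95) {
  ns <- lengths(groups)
  if (length(groups) < 2 || sum(ns) <= length(groups))
    stopf("tukey_hsd: need >= 2 groups and residual degrees of freedom")
  nm <- names(groups) %||% as.character(seq_along(groups))
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(nm, ns)))
  within_ss <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (within_ss == 0) {
    # degenerate: no residual variance; differences are exact
    pairs <- utils::combn(nm, 2)
    diffs <- apply(pairs, 2, function(p) mean(groups[[p[2]]]) - mean(groups[[p[1]]]))
    return(tibble::tibble(pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
                          diff = diffs, half_width = 0, lwr = diffs, upr = diffs,
                          p_adj = ifelse(diffs == 0, 1, 0)))
  }
  fit <- stats::aov(value ~ group, data = df)
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$group
  tibble::tibble(pair = rownames(tk),
                 diff = unname(tk[, "diff"]),
                 half_width = unname(tk[, "upr"] - tk[, "lwr"]) / 2,
                 lwr = unname(tk[, "lwr"]), upr = unname(tk[, "upr"]),
                 p_adj = unname(tk[, "p adj"]))
}
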