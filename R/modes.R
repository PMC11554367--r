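#' Modes and antimodes of a kernel density estimate
#'
#' Computes a Gaussian-kernel density estimate (Silverman's rule-of-thumb
#' bandwidth, `bw = "nrd0"`) on a 512-point grid and returns the local
#' maxima (modes) and local minima between them (antimodes). Modes and
#' antimodes strictly interleave: between any two adjacent modes lies
#' exactly one antimode.
#'
#' Finite-sample KDEs carry small wiggles, so two pruning rules clean the
#' raw extrema. Modes lower than `min_mode_height` (default 1%) of the
#' global maximum are discarded — tail ripples, not subpopulations. Then
#' shallow valleys are pruned: an antimode whose density exceeds
#' `1 / (1 + min_prominence)` of the smaller adjacent mode is dropped
#' together with that smaller mode, repeatedly, until every remaining
#' valley dips by at least `min_prominence` (default 5%) relative to both
#' neighbours. This keeps genuine subpopulation valleys while ignoring
#' sampling noise — which matters downstream, where an antimode can
#' override a truncation edge.
#'
#' @param values_transformed numeric sample, n >= 100.
#' @param n_grid density grid size.
#' @param min_prominence minimum relative dip of a retained antimode.
#' @param min_mode_height minimum mode density relative to the global
#'   mode.
#' @return A list with `modes`, `antimodes` (positions, increasing),
#'   `density` (the `stats::density` object).
#' @export
find_modes_antimodes <- function(values_transformed, n_grid = 512,
                                 min_prominence = 0.05,
                                 min_mode_height = 0.01) {
  x <- values_transformed[is.finite(values_transformed)]
  if (length(x) < 100) {
    stop("find_modes_antimodes: need at least 100 values", call. = FALSE)
  }
  d <- density(x, bw = "nrd0", n = n_grid)
  y <- d$y
  ds <- diff(sign(diff(y)))
  modes_i <- which(ds < 0) + 1L
  anti_i <- which(ds > 0) + 1L
  if (length(modes_i) == 0) modes_i <- which.max(y) # monotone edge case
  # keep only antimodes strictly between two modes (interleaving)
  if (length(anti_i) > 0 && length(modes_i) > 1) {
    anti_i <- anti_i[anti_i > min(modes_i) & anti_i < max(modes_i)]
  } else {
    anti_i <- integer(0)
  }
  # drop tail ripples: modes far below the global mode
  modes_i <- modes_i[y[modes_i] >= min_mode_height * max(y[modes_i])]
  anti_i <- rebuild_antimodes(modes_i, anti_i, y)
  # prune shallow valleys: merge across the weakest non-prominent antimode
  repeat {
    if (length(anti_i) == 0) break
    depth <- vapply(seq_along(anti_i), function(j) {
      left <- max(modes_i[modes_i < anti_i[j]])
      right <- min(modes_i[modes_i > anti_i[j]])
      min(y[left], y[right]) / y[anti_i[j]] - 1
    }, numeric(1))
    worst <- which.min(depth)
    if (depth[worst] >= min_prominence) break
    left <- max(modes_i[modes_i < anti_i[worst]])
    right <- min(modes_i[modes_i > anti_i[worst]])
    drop_mode <- if (y[left] <= y[right]) left else right
    modes_i <- setdiff(modes_i, drop_mode)
    anti_i <- rebuild_antimodes(modes_i, anti_i[-worst], y)
  }
  list(modes = d$x[modes_i], antimodes = d$x[anti_i], density = d)
}

# restore interleaving: keep the deepest antimode between each pair of
# consecutive surviving modes
rebuild_antimodes <- function(modes_i, anti_i, y) {
  if (length(modes_i) < 2 || length(anti_i) == 0) return(integer(0))
  keep <- integer(0)
  for (g in seq_len(length(modes_i) - 1)) {
    between <- anti_i[anti_i > modes_i[g] & anti_i < modes_i[g + 1]]
    if (length(between) > 0) keep <- c(keep, between[which.min(y[between])])
  }
  keep
}
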