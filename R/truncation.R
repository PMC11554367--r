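#' Choose the truncation window isolating the healthy component
#'
#' The healthy component is taken to be the mixture component with the
#' largest weight among those whose mean lies nearest the global mode of
#' the kernel density estimate. The window is grown outward from that
#' component's mean over the interval where its posterior responsibility
#' stays >= `resp_threshold`; if responsibility never drops below the
#' threshold on a side, the window edge on that side is the data extreme.
#' When the KDE has antimodes flanking the healthy mode that lie strictly
#' inside the responsibility interval, they override the responsibility
#' edges (an antimode is the natural valley between the healthy and a
#' pathological population). With k = 1 the window is the full data range.
#'
#' All quantities are computed on the transformed scale and the window is
#' reported on the raw (analyte) scale, with the edge provenance recorded
#' per side as `"posterior_responsibility"`, `"antimode"` or
#' `"data_extreme"`.
#'
#' @param mixture a `mixture_model` fitted on the transformed scale.
#' @param modes_info result of [find_modes_antimodes()] on the same values.
#' @param transform the `transform_spec` mapping raw to transformed scale.
#' @param data_range length-2 raw-scale range of the data.
#' @param resp_threshold posterior-responsibility boundary level.
#' @param n_grid resolution of the responsibility scan.
#' @return An object of class `truncation_window`: `lower`, `upper` (raw
#'   scale), `source` (length-2), `healthy_component`, plus transformed-
#'   scale edges `lower_t`, `upper_t` and the healthy-mass fractions
#'   `mass_below`, `mass_above` cut off by non-extreme edges.
#' @export
choose_truncation <- function(mixture, modes_info, transform, data_range,
                              resp_threshold = 0.1, n_grid = 4096) {
  lo_t <- apply_transform(data_range[1], transform)
  hi_t <- apply_transform(data_range[2], transform)
  if (mixture$k == 1) {
    w <- structure(list(
      lower = data_range[1], upper = data_range[2],
      source = c("data_extreme", "data_extreme"),
      healthy_component = 1L,
      lower_t = lo_t, upper_t = hi_t, mass_below = 0, mass_above = 0
    ), class = "truncation_window")
    return(w)
  }
  # healthy component: max weight among components nearest the global mode
  dens <- modes_info$density
  gmode <- dens$x[which.max(dens$y)]
  dist <- abs(mixture$means - gmode)
  near <- which(dist <= min(dist) + 1e-12)
  h <- near[which.max(mixture$weights[near])]

  grid <- seq(lo_t, hi_t, length.out = n_grid)
  rg <- responsibilities(mixture, grid, component = h)
  im <- which.min(abs(grid - mixture$means[h]))
  iu <- im
  while (iu < n_grid && rg[iu + 1] >= resp_threshold) iu <- iu + 1
  il <- im
  while (il > 1 && rg[il - 1] >= resp_threshold) il <- il - 1
  lower_t <- grid[il]
  upper_t <- grid[iu]
  src <- c(if (il == 1) "data_extreme" else "posterior_responsibility",
           if (iu == n_grid) "data_extreme" else "posterior_responsibility")
  # antimode override: flanking antimodes strictly inside the window
  anti <- modes_info$antimodes
  hm <- mixture$means[h]
  left_anti <- anti[anti < hm & anti > lower_t]
  if (length(left_anti) > 0) {
    lower_t <- max(left_anti)
    src[1] <- "antimode"
  }
  right_anti <- anti[anti > hm & anti < upper_t]
  if (length(right_anti) > 0) {
    upper_t <- min(right_anti)
    src[2] <- "antimode"
  }
  structure(list(
    lower = invert_transform(lower_t, transform),
    upper = invert_transform(upper_t, transform),
    source = src,
    healthy_component = h,
    lower_t = lower_t, upper_t = upper_t,
    mass_below = if (src[1] == "data_extreme") 0 else
      pnorm(lower_t, mixture$means[h], mixture$sds[h]),
    mass_above = if (src[2] == "data_extreme") 0 else
      pnorm(upper_t, mixture$means[h], mixture$sds[h], lower.tail = FALSE)
  ), class = "truncation_window")
}

#' @export
print.truncation_window <- function(x, ...) {
  cat(sprintf("truncation window: [%.4g, %.4g] (%s / %s), healthy comp %d\n",
              x$lower, x$upper, x$source[1], x$source[2],
              x$healthy_component))
  invisible(x)
}
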