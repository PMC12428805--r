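# Output rendering: the slab overlaid with yellow displacement arrows
# (length proportional to |d| in um) and a color-coded deformation map on
# a fixed 0-90 um blue-to-red scale, red = greatest displacement.

#' Rendering configuration
#'
#' @param arrow_stride subsample every `arrow_stride`-th grid node
#' @param arrow_color RGB triplet in \[0,1\] (default yellow)
#' @param cmap_range_um deformation color scale (default c(0, 90) um)
#' @param scale_bar append a colormap legend bar to magnitude renders
#' @param arrow_px_per_um arrow length per micrometer of displacement
#' @export
render_config <- function(arrow_stride = 2L, arrow_color = c(1, 1, 0),
                          cmap_range_um = c(0, 90), scale_bar = TRUE,
                          arrow_px_per_um = 0.5) {
  stopifnot(arrow_stride >= 1, cmap_range_um[1] < cmap_range_um[2])
  structure(list(arrow_stride = as.integer(arrow_stride),
                 arrow_color = arrow_color, cmap_range_um = cmap_range_um,
                 scale_bar = scale_bar, arrow_px_per_um = arrow_px_per_um),
            class = "RenderConfig")
}

#' Arrow geometry for a displacement grid
#'
#' One row per drawn arrow: base node, tip, and the drawn angle. Nodes
#' with zero displacement draw nothing. Exposed separately so the drawn
#' directions can be checked against analytic fields.
#'
#' @param grid a `GridDisplacement`
#' @param um_per_px physical scale
#' @param cfg a [render_config()]
#' @return data.frame(x0, y0, x1, y1, angle, mag_um)
#' @export
arrow_segments <- function(grid, um_per_px, cfg = render_config()) {
  idx <- seq(1, grid$n_side, by = cfg$arrow_stride)
  keep <- matrix(FALSE, grid$n_side, grid$n_side)
  keep[idx, idx] <- TRUE
  keep <- keep & grid$valid
  mag_um <- sqrt(grid$dx^2 + grid$dy^2) * um_per_px
  keep <- keep & mag_um > 0
  if (!any(keep)) {
    return(data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                      y1 = numeric(0), angle = numeric(0),
                      mag_um = numeric(0)))
  }
  ang <- atan2(grid$dy[keep], grid$dx[keep])
  len <- mag_um[keep] * cfg$arrow_px_per_um
  data.frame(x0 = grid$nx[keep], y0 = grid$ny[keep],
             x1 = grid$nx[keep] + len * cos(ang),
             y1 = grid$ny[keep] + len * sin(ang),
             angle = ang, mag_um = mag_um[keep])
}

draw_segment <- function(rgb, x0, y0, x1, y1, color) {
  n_r <- dim(rgb)[1]; n_c <- dim(rgb)[2]
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  ts <- seq(0, 1, length.out = max(2L, ceiling(len * 2) + 1L))
  xs <- round(x0 + ts * (x1 - x0) + 0.5)
  ys <- round(y0 + ts * (y1 - y0) + 0.5)
  ok <- xs >= 1 & xs <= n_c & ys >= 1 & ys <= n_r
  for (ch in 1:3) {
    plane <- rgb[, , ch]
    plane[cbind(ys[ok], xs[ok])] <- color[ch]
    rgb[, , ch] <- plane
  }
  rgb
}

#' Render the slab with displacement arrows
#'
#' @param slab an `EnFaceSlab` (the background)
#' @param grid a `GridDisplacement` sampled at the slab's geometry
#' @param cfg a [render_config()]
#' @return H x W x 3 array in \[0, 1\]
#' @export
render_overlay <- function(slab, grid, cfg = render_config()) {
  stopifnot(inherits(slab, "EnFaceSlab"), inherits(grid, "GridDisplacement"))
  if (grid$width != ncol(slab$pixels) || grid$height != nrow(slab$pixels))
    stop("grid geometry does not match the slab")
  n <- nrow(slab$pixels)
  rgb <- array(rep(slab$pixels, 3), c(n, n, 3))
  segs <- arrow_segments(grid, um_per_px(slab), cfg)
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    rgb <- draw_segment(rgb, s$x0, s$y0, s$x1, s$y1, cfg$arrow_color)
    # arrowhead: two barbs at +/- 150 degrees from the shaft
    hl <- max(1.5, 0.25 * sqrt((s$x1 - s$x0)^2 + (s$y1 - s$y0)^2))
    for (da in c(150, -150) * pi / 180) {
      rgb <- draw_segment(rgb, s$x1, s$y1,
                          s$x1 + hl * cos(s$angle + da),
                          s$y1 + hl * sin(s$angle + da), cfg$arrow_color)
    }
  }
  rgb
}

deformation_palette <- function(n = 256L) {
  # blue -> purple -> red, chosen so the red channel rises monotonically
  # with magnitude (red = greatest displacement)
  ramp <- grDevices::colorRamp(c("#313695", "#5A51A5", "#7B3294", "#A82C66",
                                 "#D73027"), space = "Lab")
  ramp(seq(0, 1, length.out = n)) / 255
}

#' Render a color-coded deformation map
#'
#' Magnitudes are clipped to `cmap_range_um` (default 0-90 um) and mapped
#' through a blue-to-red palette; values at or above the top of the range
#' render as the deepest red. A legend bar is appended below when
#' `cfg$scale_bar` is TRUE.
#'
#' @param mag_map matrix of displacement magnitudes (um); NAs render as 0
#' @param cfg a [render_config()]
#' @return (H + legend) x W x 3 array in \[0, 1\]
#' @export
render_magnitude <- function(mag_map, cfg = render_config()) {
  stopifnot(is.matrix(mag_map))
  m <- mag_map
  m[!is.finite(m)] <- 0
  lo <- cfg$cmap_range_um[1]; hi <- cfg$cmap_range_um[2]
  z <- (pmin(pmax(m, lo), hi) - lo) / (hi - lo)
  pal <- deformation_palette(256L)
  idx <- pmin(pmax(floor(z * 255) + 1L, 1L), 256L)
  n_r <- nrow(m); n_c <- ncol(m)
  rgb <- array(0, c(n_r, n_c, 3))
  for (ch in 1:3) rgb[, , ch] <- matrix(pal[idx, ch], n_r, n_c)
  if (cfg$scale_bar) {
    bar_h <- max(8L, round(n_r * 0.05))
    bar_idx <- pmin(pmax(floor(seq(0, 1, length.out = n_c) * 255) + 1L, 1L), 256L)
    bar <- array(0, c(bar_h, n_c, 3))
    for (ch in 1:3) bar[, , ch] <- matrix(pal[bar_idx, ch], bar_h, n_c,
                                          byrow = TRUE)
    out <- array(0, c(n_r + bar_h + 2L, n_c, 3))
    out[seq_len(n_r), , ] <- rgb
    out[n_r + 1:2, , ] <- 1  # white separator
    out[(n_r + 3):(n_r + bar_h + 2L), , ] <- bar
    return(out)
  }
  rgb
}
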