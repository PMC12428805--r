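# Pair standardization before motion estimation: grayscale conversion and
# contrast-limited tiled (local) histogram equalization. Each image of a
# pair is equalized independently.

#' Convert a raster to a grayscale `EnFaceSlab`
#'
#' Accepts a matrix (already grayscale) or an H x W x 3 array, collapsed
#' with Rec. 709 luminance weights (0.2126, 0.7152, 0.0722). Values must
#' lie in \[0, 1\].
#'
#' @param x matrix or 3-channel array
#' @param scan_width_mm,slab,timepoint metadata passed to [en_face_slab()]
#' @return an `EnFaceSlab`
#' @export
to_grayscale <- function(x, scan_width_mm = 3.0, slab = "SCP",
                         timepoint = "T0") {
  if (inherits(x, "EnFaceSlab")) return(x)
  if (is.matrix(x)) {
    g <- x
  } else if (is.array(x) && length(dim(x)) == 3 && dim(x)[3] == 3) {
    g <- 0.2126 * x[, , 1] + 0.7152 * x[, , 2] + 0.0722 * x[, , 3]
  } else {
    stop("expected a matrix or an H x W x 3 array")
  }
  if (length(g) == 0) stop("empty raster")
  if (nrow(g) != ncol(g)) stop("raster must be square")
  en_face_slab(g, scan_width_mm, slab, timepoint)
}

#' Local (tiled, contrast-limited) histogram equalization
#'
#' CLAHE-style: the image is partitioned into `tile_grid` x `tile_grid`
#' tiles; each tile's 256-bin histogram is clipped at
#' `clip_limit * tile_area` (excess redistributed uniformly) and turned
#' into a CDF mapping; per-pixel output bilinearly blends the mappings of
#' the four nearest tile centers. Output lies in \[0, 1\].
#'
#' @param img an `EnFaceSlab` (or matrix)
#' @param tile_grid number of tiles per side (default 8; needs >= 4)
#' @param clip_limit histogram clip limit as a fraction of the tile area
#'   (default 0.01); larger means stronger equalization
#' @return object of the same type with equalized pixels
#' @export
local_hist_eq <- function(img, tile_grid = 8L, clip_limit = 0.01) {
  m <- if (inherits(img, "EnFaceSlab")) img$pixels else img
  tile_grid <- as.integer(tile_grid)
  n <- nrow(m)
  tile_px <- n / tile_grid
  if (tile_px <= 1) stop("tile size must exceed 1 px")
  if (tile_grid < 4) stop("need at least a 4x4 tile grid")

  nb <- 256L
  bin <- matrix(pmin(pmax(floor(m * (nb - 1L)) + 1L, 1L), nb), n, n)

  # tile boundaries (pixel index ranges) and per-tile LUTs
  edges <- round(seq(0, n, length.out = tile_grid + 1))
  luts <- array(0, c(tile_grid, tile_grid, nb))
  centers <- numeric(tile_grid)
  for (ti in seq_len(tile_grid)) centers[ti] <- (edges[ti] + edges[ti + 1]) / 2
  for (ti in seq_len(tile_grid)) {
    rows <- (edges[ti] + 1):edges[ti + 1]
    for (tj in seq_len(tile_grid)) {
      cols <- (edges[tj] + 1):edges[tj + 1]
      h <- tabulate(bin[rows, cols], nbins = nb)
      area <- length(rows) * length(cols)
      cl <- max(1, clip_limit * area)
      excess <- sum(pmax(h - cl, 0))
      h <- pmin(h, cl) + excess / nb
      cdf <- cumsum(h) / sum(h)
      luts[ti, tj, ] <- cdf
    }
  }

  # bilinear blend of the four surrounding tile mappings (clamped at edges)
  yc <- matrix(seq_len(n) - 0.5, n, n)        # row coordinate
  xc <- t(yc)                                  # col coordinate
  pos_y <- stats::approx(centers, seq_len(tile_grid),
                         pmin(pmax(yc, centers[1]), centers[tile_grid]),
                         rule = 2)$y
  pos_x <- stats::approx(centers, seq_len(tile_grid),
                         pmin(pmax(xc, centers[1]), centers[tile_grid]),
                         rule = 2)$y
  i0 <- pmin(floor(pos_y), tile_grid - 1L); fi <- pos_y - i0
  j0 <- pmin(floor(pos_x), tile_grid - 1L); fj <- pos_x - j0
  idx <- function(i, j) luts[cbind(as.integer(i), as.integer(j), as.integer(bin))]
  out <- (1 - fi) * (1 - fj) * idx(i0, j0) +
         (1 - fi) * fj       * idx(i0, j0 + 1) +
         fi       * (1 - fj) * idx(i0 + 1, j0) +
         fi       * fj       * idx(i0 + 1, j0 + 1)
  out <- matrix(clip01(out), n, n)
  if (inherits(img, "EnFaceSlab")) slab_like(img, out) else out
}

#' Preprocess an image pair for motion estimation
#'
#' Grayscale conversion followed by independent local histogram
#' equalization of each image.
#' @param ref,mov `EnFaceSlab`s (baseline and follow-up)
#' @param tile_grid,clip_limit see [local_hist_eq()]
#' @return list(ref, mov)
#' @export
preprocess_pair <- function(ref, mov, tile_grid = 8L, clip_limit = 0.01) {
  list(ref = local_hist_eq(to_grayscale(ref), tile_grid, clip_limit),
       mov = local_hist_eq(to_grayscale(mov), tile_grid, clip_limit))
}
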