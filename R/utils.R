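# Coordinate convention used throughout the package:
#   continuous coordinates with pixel (row r, col k) centered at
#   (x, y) = (k + 0.5, r + 0.5), 1-based r/k in R matrices.
#   x grows rightward (columns), y grows downward (rows).
#   The image center is (W/2, H/2); rigid rotations are taken about it.
# cf_bilinear() expects 0-based index coordinates, hence the -0.5 shifts.

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded generators do not
#' perturb the global stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Centered 1D Gaussian kernel
#' @param sigma standard deviation in pixels
#' @param order 0 for the Gaussian, 1 for x*g(x), 2 for x^2*g(x)
#' @keywords internal
gaussian_kernel1d <- function(sigma, order = 0L, radius = NULL) {
  stopifnot(sigma > 0)
  if (is.null(radius)) radius <- as.integer(ceiling(3 * sigma))
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
    "0" = g,
    "1" = x * g,
    "2" = x^2 * g,
    stop("order must be 0, 1 or 2")
  )
}

#' Gaussian smoothing of a matrix (separable, reflected boundaries)
#' @keywords internal
gauss_smooth <- function(m, sigma) {
  k <- gaussian_kernel1d(sigma)
  cf_sep_correlate(m, k, k)
}

#' Bilinear resize of a matrix
#' @keywords internal
resize_bilinear <- function(m, nrow_out, ncol_out) {
  # map output pixel centers to input pixel centers (continuous coords)
  sx <- ncol(m) / ncol_out
  sy <- nrow(m) / nrow_out
  xc <- (seq_len(ncol_out) - 0.5) * sx - 0.5
  yc <- (seq_len(nrow_out) - 0.5) * sy - 0.5
  X <- matrix(xc, nrow_out, ncol_out, byrow = TRUE)
  Y <- matrix(yc, nrow_out, ncol_out)
  cf_bilinear(m, X, Y)
}

#' Otsu's threshold for values in [0, 1]
#'
#' Maximizes between-class variance over a 256-bin histogram. Used to
#' measure the lit-vessel fraction of generated angiograms.
#' @param v numeric vector or matrix of values in \[0, 1\]
#' @return scalar threshold in \[0, 1\]
#' @export
otsu_threshold <- function(v) {
  v <- as.numeric(v)
  stopifnot(all(is.finite(v)))
  h <- tabulate(pmin(pmax(floor(v * 255) + 1L, 1L), 256L), nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(256) - 1))
  mu_t <- mu[256]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- -Inf
  (which.max(sb2) - 0.5) / 255
}

#' Shannon entropy of an image histogram (bits, 256 bins)
#' @keywords internal
image_entropy <- function(m, nbins = 256L) {
  b <- tabulate(pmin(pmax(floor(as.numeric(m) * (nbins - 1)) + 1L, 1L), nbins),
                nbins = nbins)
  p <- b / sum(b)
  p <- p[p > 0]
  -sum(p * log2(p))
}

clip01 <- function(m) pmin(pmax(m, 0), 1)

#' Spatial autocorrelation length of an image
#'
#' 1/e decay length (px) of the mean row-wise autocorrelation of the
#' mean-removed image. Coarse but monotone in texture scale.
#' @keywords internal
autocorr_length <- function(m, max_lag = 40L) {
  m <- m - mean(m)
  ac <- sapply(0:max_lag, function(l) {
    if (l == 0) return(1)
    a <- m[, seq_len(ncol(m) - l)]
    b <- m[, seq_len(ncol(m) - l) + l]
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  })
  below <- which(ac < exp(-1))
  if (length(below) == 0) return(max_lag)
  below[1] - 1
}
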