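# Dense two-frame motion estimation by quadratic polynomial expansion
# (Farneback). Each local neighborhood is modeled as
#   f(x) ~ x' A x + b' x + c
# fitted by weighted least squares under a Gaussian applicability; the
# displacement relating two frames follows from how A and b transform
# under translation, aggregated over a Gaussian neighborhood and solved
# per pixel, iterated coarse-to-fine over an image pyramid.

#' Dense displacement field
#'
#' @param dx,dy per-pixel displacement components in px (x = columns
#'   rightward, y = rows downward); the field maps reference to moving:
#'   ref(p) corresponds to mov(p + d(p))
#' @param border width of the border band excluded from `valid`
#' @param valid optional logical matrix; defaults to TRUE outside border
#' @return object of class `DisplacementField`
#' @export
displacement_field <- function(dx, dy, border = 0L, valid = NULL) {
  stopifnot(is.matrix(dx), identical(dim(dx), dim(dy)))
  if (is.null(valid)) {
    valid <- matrix(TRUE, nrow(dx), ncol(dx))
    if (border > 0) {
      idx <- seq_len(border)
      valid[idx, ] <- FALSE; valid[nrow(dx) + 1 - idx, ] <- FALSE
      valid[, idx] <- FALSE; valid[, ncol(dx) + 1 - idx] <- FALSE
    }
  }
  if (any(!is.finite(dx[valid])) || any(!is.finite(dy[valid])))
    stop("displacement components must be finite where valid")
  structure(list(dx = dx, dy = dy, valid = valid, border = as.integer(border)),
            class = "DisplacementField")
}

#' @export
print.DisplacementField <- function(x, ...) {
  mag <- sqrt(x$dx[x$valid]^2 + x$dy[x$valid]^2)
  cat(sprintf("<DisplacementField %dx%d, mean |d| = %.3f px, border %d>\n",
              nrow(x$dx), ncol(x$dx), mean(mag), x$border))
  invisible(x)
}

#' Flow estimation parameters
#'
#' Defaults follow common Farneback practice; the motions of interest here
#' (a few px to ~2 px after alignment) are well inside their working range.
#'
#' @param sigma_app Gaussian applicability SD of the polynomial expansion (px)
#' @param agg_sigma Gaussian SD of the neighborhood aggregation window (px)
#' @param n_iter refinement iterations per pyramid level
#' @param pyramid_levels number of pyramid levels (1 = no pyramid)
#' @param pyramid_scale downscale factor between levels, in (0, 1)
#' @export
flow_params <- function(sigma_app = 1.5, agg_sigma = 7, n_iter = 3L,
                        pyramid_levels = 3L, pyramid_scale = 0.5) {
  stopifnot(sigma_app > 0, agg_sigma > 0, n_iter >= 1, pyramid_levels >= 1,
            pyramid_scale > 0, pyramid_scale < 1)
  structure(list(sigma_app = sigma_app, agg_sigma = agg_sigma,
                 n_iter = as.integer(n_iter),
                 pyramid_levels = as.integer(pyramid_levels),
                 pyramid_scale = pyramid_scale),
            class = "FlowParams")
}

#' Quadratic polynomial expansion of an image
#'
#' Fits f(x) ~ x' A x + b' x + c at every pixel by Gaussian-weighted least
#' squares, computed with separable correlations. The normal matrix G of
#' the basis (1, x, y, x^2, y^2, xy) under a Gaussian applicability is
#' constant over the image, so the fit reduces to six moment images
#' multiplied by G^-1.
#'
#' @param img an `EnFaceSlab` or numeric matrix
#' @param sigma_app applicability SD in px (> 0)
#' @return object of class `PolyExpansion` with matrices a11, a12, a22
#'   (A entries), b1, b2, c
#' @export
polynomial_expansion <- function(img, sigma_app = 1.5) {
  if (sigma_app <= 0) stop("sigma_app must be > 0")
  m <- if (inherits(img, "EnFaceSlab")) img$pixels else img
  r <- as.integer(ceiling(3 * sigma_app))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma_app^2))   # unnormalized applicability
  gx <- x * g
  gx2 <- x^2 * g

  # moment images <f, w * basis>
  m00 <- cf_sep_correlate(m, g,   g)
  m10 <- cf_sep_correlate(m, gx,  g)    # x moment
  m01 <- cf_sep_correlate(m, g,   gx)   # y moment
  m20 <- cf_sep_correlate(m, gx2, g)
  m02 <- cf_sep_correlate(m, g,   gx2)
  m11 <- cf_sep_correlate(m, gx,  gx)

  # constant normal matrix G in basis order (1, x, y, x^2, y^2, xy)
  s0 <- sum(g); s2 <- sum(gx2); s4 <- sum(x^4 * g)
  G <- matrix(0, 6, 6)
  G[1, 1] <- s0 * s0
  G[1, 4] <- G[4, 1] <- G[1, 5] <- G[5, 1] <- s2 * s0
  G[2, 2] <- G[3, 3] <- s2 * s0
  G[4, 4] <- G[5, 5] <- s4 * s0
  G[4, 5] <- G[5, 4] <- s2 * s2
  G[6, 6] <- s2 * s2
  Gi <- solve(G)

  # r = G^-1 v with v = (m00, m10, m01, m20, m02, m11)
  lin <- function(k) {
    Gi[k, 1] * m00 + Gi[k, 2] * m10 + Gi[k, 3] * m01 +
      Gi[k, 4] * m20 + Gi[k, 5] * m02 + Gi[k, 6] * m11
  }
  cc <- lin(1); b1 <- lin(2); b2 <- lin(3)
  a11 <- lin(4); a22 <- lin(5); a12 <- lin(6) / 2
  structure(list(a11 = a11, a12 = a12, a22 = a22, b1 = b1, b2 = b2, c = cc,
                 sigma_app = sigma_app),
            class = "PolyExpansion")
}

# one flow refinement at a single scale given expansions of both images
flow_update <- function(e1, e2, dx, dy, agg_sigma) {
  n_r <- nrow(e1$c); n_c <- ncol(e1$c)
  X0 <- matrix(seq_len(n_c) - 1, n_r, n_c, byrow = TRUE)  # 0-based index
  Y0 <- matrix(seq_len(n_r) - 1, n_r, n_c)
  Xs <- X0 + dx
  Ys <- Y0 + dy
  a11 <- (e1$a11 + cf_bilinear(e2$a11, Xs, Ys)) / 2
  a12 <- (e1$a12 + cf_bilinear(e2$a12, Xs, Ys)) / 2
  a22 <- (e1$a22 + cf_bilinear(e2$a22, Xs, Ys)) / 2
  db1 <- -0.5 * (cf_bilinear(e2$b1, Xs, Ys) - e1$b1) + a11 * dx + a12 * dy
  db2 <- -0.5 * (cf_bilinear(e2$b2, Xs, Ys) - e1$b2) + a12 * dx + a22 * dy

  # Gaussian aggregation of the normal equations sum w A'A d = sum w A'db
  k <- gaussian_kernel1d(agg_sigma)
  sm <- function(z) cf_sep_correlate(z, k, k)
  G11 <- sm(a11 * a11 + a12 * a12)
  G12 <- sm(a12 * (a11 + a22))
  G22 <- sm(a12 * a12 + a22 * a22)
  H1 <- sm(a11 * db1 + a12 * db2)
  H2 <- sm(a12 * db1 + a22 * db2)
  det <- G11 * G22 - G12 * G12
  ok <- is.finite(det) & abs(det) > 1e-12
  ndx <- dx; ndy <- dy
  ndx[ok] <- (G22[ok] * H1[ok] - G12[ok] * H2[ok]) / det[ok]
  ndy[ok] <- (G11[ok] * H2[ok] - G12[ok] * H1[ok]) / det[ok]
  list(dx = ndx, dy = ndy, ok = ok)
}

#' Estimate dense optical flow between two frames
#'
#' Coarse-to-fine Farneback estimation: at each pyramid level both frames
#' are polynomial-expanded once, then `n_iter` refinements sample the
#' moving frame's coefficients under the current displacement and re-solve
#' the aggregated normal equations. The returned field maps reference to
#' moving: ref(p) ~ mov(p + d(p)).
#'
#' @param ref,mov `EnFaceSlab`s or matrices of identical shape
#' @param params a [flow_params()]
#' @param prior optional `DisplacementField` warm start (full resolution)
#' @return a `DisplacementField`; `valid` excludes a ceil(3 * sigma_app)
#'   border and pixels whose aggregated normal matrix was singular
#' @export
estimate_flow <- function(ref, mov, params = flow_params(), prior = NULL) {
  m1 <- if (inherits(ref, "EnFaceSlab")) ref$pixels else ref
  m2 <- if (inherits(mov, "EnFaceSlab")) mov$pixels else mov
  if (!identical(dim(m1), dim(m2))) stop("ref and mov must share shape")
  stopifnot(inherits(params, "FlowParams"))

  # build pyramid (level 1 = full resolution)
  pyr1 <- list(m1); pyr2 <- list(m2)
  for (l in seq_len(params$pyramid_levels - 1)) {
    sz <- round(dim(pyr1[[l]]) * params$pyramid_scale)
    if (min(sz) < 16) break
    blur_sigma <- 0.5 / params$pyramid_scale
    pyr1[[l + 1]] <- resize_bilinear(gauss_smooth(pyr1[[l]], blur_sigma), sz[1], sz[2])
    pyr2[[l + 1]] <- resize_bilinear(gauss_smooth(pyr2[[l]], blur_sigma), sz[1], sz[2])
  }
  nlev <- length(pyr1)

  dx <- dy <- NULL
  ok <- NULL
  for (l in rev(seq_len(nlev))) {
    sz <- dim(pyr1[[l]])
    if (is.null(dx)) {
      if (!is.null(prior)) {
        s <- sz[2] / ncol(prior$dx)
        dx <- resize_bilinear(prior$dx, sz[1], sz[2]) * s
        dy <- resize_bilinear(prior$dy, sz[1], sz[2]) * s
      } else {
        dx <- matrix(0, sz[1], sz[2])
        dy <- matrix(0, sz[1], sz[2])
      }
    } else {
      s <- sz[2] / ncol(dx)
      dx <- resize_bilinear(dx, sz[1], sz[2]) * s
      dy <- resize_bilinear(dy, sz[1], sz[2]) * s
    }
    e1 <- polynomial_expansion(pyr1[[l]], params$sigma_app)
    e2 <- polynomial_expansion(pyr2[[l]], params$sigma_app)
    for (it in seq_len(params$n_iter)) {
      upd <- flow_update(e1, e2, dx, dy, params$agg_sigma)
      dx <- upd$dx; dy <- upd$dy
      ok <- upd$ok
    }
  }
  border <- as.integer(ceiling(3 * params$sigma_app))
  fld <- displacement_field(dx, dy, border = border)
  fld$valid <- fld$valid & ok
  fld
}

#' Per-pixel displacement magnitude in micrometers
#'
#' D = sqrt(Dx^2 + Dy^2) * um_per_px, elementwise.
#'
#' @param field a `DisplacementField` (components in px)
#' @param um_per_px micrometers per pixel (> 0)
#' @return matrix of magnitudes (um); NA where the field is invalid
#' @export
flow_magnitude <- function(field, um_per_px) {
  stopifnot(inherits(field, "DisplacementField"))
  if (um_per_px <= 0) stop("um_per_px must be > 0")
  mag <- sqrt(field$dx^2 + field$dy^2) * um_per_px
  mag[!field$valid] <- NA_real_
  mag
}
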