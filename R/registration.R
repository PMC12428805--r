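# Rigid roto-translational alignment. Acquisition misalignment between the
# two time points is removed by iterating: estimate dense flow, sample it
# on the 36x36 reporting grid, solve the closed-form 2D Procrustes (no
# scaling) roto-translation that best explains the grid vectors, resample
# the moving image under the accumulated transform, and repeat until the
# sum of squared grid displacements changes by less than 3%.

#' Rigid roto-translation
#'
#' Acts on continuous coordinates as p' = R(p - c) + c + t with c the
#' image center; theta in degrees, t in px.
#' @export
rigid_transform <- function(theta = 0, tx = 0, ty = 0) {
  if (abs(theta) >= 45) stop("|theta| must be < 45 degrees")
  structure(list(theta = theta, tx = tx, ty = ty), class = "RigidTransform")
}

#' @export
print.RigidTransform <- function(x, ...) {
  cat(sprintf("<RigidTransform theta = %.4f deg, t = (%.3f, %.3f) px>\n",
              x$theta, x$tx, x$ty))
  invisible(x)
}

# apply to centered coords u = p - c: u' = R u + t
rigid_apply_centered <- function(tf, ux, uy) {
  th <- tf$theta * pi / 180
  list(x = cos(th) * ux - sin(th) * uy + tf$tx,
       y = sin(th) * ux + cos(th) * uy + tf$ty)
}

#' Compose two rigid transforms: result(p) = a(b(p))
#' @export
rigid_compose <- function(a, b) {
  th_a <- a$theta * pi / 180
  rigid_transform(a$theta + b$theta,
                  cos(th_a) * b$tx - sin(th_a) * b$ty + a$tx,
                  sin(th_a) * b$tx + cos(th_a) * b$ty + a$ty)
}

#' Inverse of a rigid transform
#' @export
rigid_invert <- function(tf) {
  th <- -tf$theta * pi / 180
  rigid_transform(-tf$theta,
                  -(cos(th) * tf$tx - sin(th) * tf$ty),
                  -(sin(th) * tf$tx + cos(th) * tf$ty))
}

#' Resample an image under a rigid transform
#'
#' Returns out with out(p) = img(T(p)); a single bilinear interpolation
#' from the original image (coordinates clamped at the frame).
#' @param img `EnFaceSlab` or matrix
#' @param tf a `RigidTransform`
#' @export
resample_rigid <- function(img, tf) {
  m <- if (inherits(img, "EnFaceSlab")) img$pixels else img
  n_r <- nrow(m); n_c <- ncol(m)
  xc <- matrix(seq_len(n_c) - 0.5, n_r, n_c, byrow = TRUE) - n_c / 2
  yc <- matrix(seq_len(n_r) - 0.5, n_r, n_c) - n_r / 2
  p <- rigid_apply_centered(tf, xc, yc)
  out <- cf_bilinear(m, p$x + n_c / 2 - 0.5, p$y + n_r / 2 - 0.5)
  if (inherits(img, "EnFaceSlab")) slab_like(img, clip01(out)) else out
}

#' Sample a dense displacement field on the reporting grid
#'
#' Nodes sit at the centers of an `n_side` x `n_side` uniform block
#' partition of the frame: x_i = (i - 1/2) * W / n_side (continuous
#' coordinates, i = 1..n_side), likewise in y. Vectors are bilinearly
#' interpolated from the dense field; nodes falling in the field's invalid
#' border are flagged invalid.
#'
#' @param field a `DisplacementField`
#' @param n_side nodes per side (default 36)
#' @return object of class `GridDisplacement` with node coordinate
#'   matrices `nx`, `ny`, vector matrices `dx`, `dy`, validity `valid`
#' @export
sample_grid <- function(field, n_side = 36L) {
  stopifnot(inherits(field, "DisplacementField"))
  n_side <- as.integer(n_side)
  if (n_side < 2) stop("n_side must be >= 2")
  h <- nrow(field$dx); w <- ncol(field$dx)
  if (h < n_side || w < n_side) stop("field smaller than the grid")
  xs <- (seq_len(n_side) - 0.5) * w / n_side
  ys <- (seq_len(n_side) - 0.5) * h / n_side
  NX <- matrix(xs, n_side, n_side, byrow = TRUE)
  NY <- matrix(ys, n_side, n_side)
  dx <- cf_bilinear(field$dx, NX - 0.5, NY - 0.5)
  dy <- cf_bilinear(field$dy, NX - 0.5, NY - 0.5)
  vnum <- cf_bilinear(field$valid * 1.0, NX - 0.5, NY - 0.5)
  valid <- vnum > 0.999 & is.finite(dx) & is.finite(dy)
  structure(list(nx = NX, ny = NY, dx = dx, dy = dy, valid = valid,
                 n_side = n_side, width = w, height = h),
            class = "GridDisplacement")
}

#' Closed-form rigid fit to grid displacement vectors
#'
#' Finds the roto-translation minimizing
#' sum_i || R p_i + t - (p_i + d_i) ||^2 over valid nodes (2D Procrustes
#' without scaling), reported about the image center. If the valid nodes
#' are collinear the rotation is unidentifiable; a translation-only fit is
#' returned with `degenerate = TRUE`.
#'
#' @param grid a `GridDisplacement`
#' @return a `RigidTransform` (attribute `degenerate` set on fallback)
#' @export
fit_rigid <- function(grid) {
  stopifnot(inherits(grid, "GridDisplacement"))
  v <- grid$valid
  if (sum(v) < 3) stop("need at least 3 valid nodes")
  cx <- grid$width / 2; cy <- grid$height / 2
  px <- grid$nx[v] - cx; py <- grid$ny[v] - cy
  qx <- px + grid$dx[v]; qy <- py + grid$dy[v]
  pmx <- mean(px); pmy <- mean(py)
  qmx <- mean(qx); qmy <- mean(qy)
  ax <- px - pmx; ay <- py - pmy
  bx <- qx - qmx; by <- qy - qmy
  denom <- sum(ax * bx + ay * by)
  cross <- sum(ax * by - ay * bx)
  degenerate <- sum(ax^2 + ay^2) < 1e-9 ||
    (abs(denom) < 1e-12 && abs(cross) < 1e-12)
  th <- if (degenerate) 0 else atan2(cross, denom)
  tx <- qmx - (cos(th) * pmx - sin(th) * pmy)
  ty <- qmy - (sin(th) * pmx + cos(th) * pmy)
  tf <- rigid_transform(th * 180 / pi, tx, ty)
  attr(tf, "degenerate") <- degenerate
  tf
}

grid_ssd <- function(grid) {
  v <- grid$valid
  sum(grid$dx[v]^2 + grid$dy[v]^2)
}

#' Iterative rigid alignment of an image pair
#'
#' Repeats {flow, grid sampling, rigid fit, resample} accumulating the
#' rigid transform, until the sum of squared grid displacement magnitudes
#' S changes by less than `tol` (relative) between consecutive iterations,
#' or `max_iter` is reached. The moving image is always resampled once
#' from the original under the accumulated transform (no compounding
#' interpolation). The residual field is the flow between the reference
#' and the finally aligned moving image: the biological displacement with
#' the acquisition misalignment removed.
#'
#' @param ref,mov preprocessed `EnFaceSlab`s (or matrices) of equal shape
#' @param params a [flow_params()]
#' @param tol relative SSD convergence tolerance (default 0.03, the 3% rule)
#' @param max_iter iteration cap (default 50); hitting it yields
#'   `converged = FALSE` with a warning, never an error
#' @param n_side grid nodes per side (default 36)
#' @return object of class `AlignmentResult`: `transform` (cumulative
#'   `RigidTransform`), `residual_field`, `residual_grid`, `ssd_trace`,
#'   `n_iter`, `converged`
#' @export
align_iterative <- function(ref, mov, params = flow_params(), tol = 0.03,
                            max_iter = 50L, n_side = 36L) {
  cum <- rigid_transform(0, 0, 0)
  cur <- mov
  s_prev <- NA_real_
  trace <- numeric(0)
  converged <- FALSE
  flow <- NULL; grid <- NULL
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    flow <- estimate_flow(ref, cur, params)
    grid <- sample_grid(flow, n_side)
    s <- grid_ssd(grid)
    trace <- c(trace, s)
    if (s < 1e-12 || (!is.na(s_prev) && s_prev < 1e-12)) {
      converged <- TRUE
      break
    }
    if (!is.na(s_prev) && abs(s - s_prev) / s_prev < tol) {
      converged <- TRUE
      break
    }
    s_prev <- s
    step <- fit_rigid(grid)
    cum <- rigid_compose(cum, step)
    cur <- resample_rigid(mov, cum)
  }
  if (!converged)
    warning("alignment did not converge within ", max_iter, " iterations")
  structure(list(transform = cum, residual_field = flow,
                 residual_grid = grid, ssd_trace = trace, n_iter = it,
                 converged = converged),
            class = "AlignmentResult")
}

#' @export
print.AlignmentResult <- function(x, ...) {
  cat(sprintf(
    "<AlignmentResult: %d iteration(s), converged = %s>\n  cumulative ",
    x$n_iter, x$converged))
  print(x$transform)
  invisible(x)
}
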