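test_that("grid sampling follows the block-center convention", {
  n <- 304L
  f <- displacement_field(matrix(2, n, n), matrix(-1, n, n))
  g <- sample_grid(f, 36)
  expect_equal(g$nx[1, 1], (304 / 36) / 2, tolerance = 1e-12)
  expect_equal(g$ny[1, 1], (304 / 36) / 2, tolerance = 1e-12)
  expect_equal(length(g$nx), 1296)
  expect_true(all(abs(g$dx - 2) < 1e-12) && all(abs(g$dy + 1) < 1e-12))
  expect_error(sample_grid(f, 1), "n_side")
  expect_error(sample_grid(displacement_field(matrix(0, 8, 8),
                                              matrix(0, 8, 8)), 36), "smaller")
})

test_that("rotation-field grid vectors are antisymmetric about the center", {
  g <- sample_grid(rotation_field(304, 2), 36)
  n <- g$n_side
  flip <- function(m) m[n:1, n:1]
  expect_lt(max(abs(g$dx + flip(g$dx))), 0.1)
  expect_lt(max(abs(g$dy + flip(g$dy))), 0.1)
})

test_that("fit_rigid solves pure translation and pure rotation exactly", {
  n <- 160L
  ft <- displacement_field(matrix(5, n, n), matrix(-2, n, n))
  tf <- fit_rigid(sample_grid(ft, 36))
  expect_equal(tf$theta, 0, tolerance = 1e-9)
  expect_equal(c(tf$tx, tf$ty), c(5, -2), tolerance = 1e-9)

  tfr <- fit_rigid(sample_grid(rotation_field(n, 3), 36))
  expect_equal(tfr$theta, 3, tolerance = 1e-6)
  expect_lt(abs(tfr$tx) + abs(tfr$ty), 1e-6)
})

test_that("fit_rigid beats random perturbations on noisy rigid data", {
  n <- 160L
  rf <- rotation_field(n, 2)
  set.seed(21)
  fld <- displacement_field(rf$dx + 4 + matrix(rnorm(n^2, 0, 0.5), n),
                            rf$dy + 1 + matrix(rnorm(n^2, 0, 0.5), n))
  g <- sample_grid(fld, 36)
  tf <- fit_rigid(g)
  expect_lt(abs(tf$theta - 2), 0.1)
  expect_lt(abs(tf$tx - 4), 0.2)
  expect_lt(abs(tf$ty - 1), 0.2)

  ssd_of <- function(theta, tx, ty) {
    th <- theta * pi / 180
    px <- g$nx - n / 2; py <- g$ny - n / 2
    qx <- px + g$dx; qy <- py + g$dy
    rx <- cos(th) * px - sin(th) * py + tx
    ry <- sin(th) * px + cos(th) * py + ty
    sum((rx - qx)^2 + (ry - qy)^2)
  }
  best <- ssd_of(tf$theta, tf$tx, tf$ty)
  for (k in 1:100) {
    pert <- ssd_of(tf$theta + rnorm(1, 0, 0.2), tf$tx + rnorm(1, 0, 0.5),
                   tf$ty + rnorm(1, 0, 0.5))
    expect_gte(pert, best)
  }
})

test_that("rigid transform algebra composes and inverts", {
  a <- rigid_transform(2, 3, -1)
  b <- rigid_transform(-1, 0.5, 2)
  ab <- rigid_compose(a, b)
  u <- c(10, -7)
  step <- coronaflow:::rigid_apply_centered(b, u[1], u[2])
  direct <- coronaflow:::rigid_apply_centered(a, step$x, step$y)
  via <- coronaflow:::rigid_apply_centered(ab, u[1], u[2])
  expect_equal(c(via$x, via$y), c(direct$x, direct$y), tolerance = 1e-12)

  inv <- rigid_compose(a, rigid_invert(a))
  expect_lt(abs(inv$theta) + abs(inv$tx) + abs(inv$ty), 1e-12)
})

test_that("identical images align to identity immediately", {
  img <- fixture_image("SCP", 160, 3)
  al <- align_iterative(img$pixels, img$pixels)
  expect_true(al$converged)
  expect_equal(al$n_iter, 1)
  expect_lt(abs(al$transform$theta), 1e-9)
  expect_lt(abs(al$transform$tx) + abs(al$transform$ty), 1e-9)
  v <- al$residual_field$valid
  expect_lt(mean(sqrt(al$residual_field$dx[v]^2 +
                      al$residual_field$dy[v]^2)), 1e-6)
})

test_that("rigid misalignment is recovered and the trace decreases", {
  img <- fixture_image("SCP", 192, 5)
  w <- ground_truth_warp(2, c(8, -5), 0, size_px = 192)
  mov <- apply_warp(img, w, noise_sd = 0.02, seed = 9)
  pp <- preprocess_pair(img, mov)
  al <- align_iterative(pp$ref, pp$mov)
  expect_true(al$converged)
  expect_lt(abs(al$transform$theta - 2), 0.1)
  expect_lt(abs(al$transform$tx - 8), 0.3)
  expect_lt(abs(al$transform$ty + 5), 0.3)
  v <- al$residual_field$valid
  expect_lt(mean(sqrt(al$residual_field$dx[v]^2 +
                      al$residual_field$dy[v]^2)), 0.3)
  # non-increasing SSD after the first iteration (one 5% violation allowed)
  if (length(al$ssd_trace) > 2) {
    rel <- diff(al$ssd_trace[-1]) / al$ssd_trace[-c(1, length(al$ssd_trace))]
    expect_lte(sum(rel > 0.05), 1)
  }

  # idempotence: aligning the aligned pair barely moves
  aligned <- resample_rigid(mov, al$transform)
  pp2 <- preprocess_pair(img, aligned)
  al2 <- align_iterative(pp2$ref, pp2$mov)
  expect_lt(abs(al2$transform$theta), 0.05)
  expect_lt(abs(al2$transform$tx), 0.1)
  expect_lt(abs(al2$transform$ty), 0.1)
})

test_that("elastic residual survives alignment with its rigid part removed", {
  img <- fixture_image("DCP", 192, 6)
  w <- ground_truth_warp(1, c(5, 3), mean_elastic_um = 15, size_px = 192,
                         seed = 31)
  mov <- apply_warp(img, w, noise_sd = 0.02, seed = 32)
  pp <- preprocess_pair(img, mov)
  al <- align_iterative(pp$ref, pp$mov)
  s <- summarize_displacement(al$residual_grid, img)
  expect_lt(abs(s$mean_um[s$roi == "whole"] - 15) / 15, 0.20)
  resid_tf <- fit_rigid(al$residual_grid)
  expect_lt(abs(resid_tf$theta), 0.1)
  expect_lt(sqrt(resid_tf$tx^2 + resid_tf$ty^2), 0.5)
})
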