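test_that("slab image generation is deterministic and style-validated", {
  a <- generate_slab_image(slab_style("SCP"), 304, seed = 1)
  b <- generate_slab_image(slab_style("SCP"), 304, seed = 1)
  expect_identical(a$pixels, b$pixels)
  expect_s3_class(a, "EnFaceSlab")
  expect_true(all(a$pixels >= 0 & a$pixels <= 1))
  expect_error(generate_slab_image(slab_style("SCP"), 100), "size_px")
  expect_error(slab_style("SCP", vessel_density = 0.7), "vessel_density")
  expect_error(slab_style("SCP", caliber_px = 0.5), "caliber_px")
})

test_that("generated vessel density lands near the style target", {
  img <- generate_slab_image(slab_style("DCP"), 304, seed = 1)
  lit <- mean(img$pixels > otsu_threshold(img$pixels))
  target <- slab_style("DCP")$vessel_density
  expect_gt(lit, target * 0.5)
  expect_lt(lit, target * 1.5)
})

test_that("CC texture is finer-grained than SCP", {
  cc <- generate_slab_image(slab_style("CC"), 128, seed = 7)
  scp <- generate_slab_image(slab_style("SCP"), 128, seed = 7)
  expect_lt(autocorr_length_of(cc$pixels), autocorr_length_of(scp$pixels))
})

test_that("apply_warp: identity is bit-exact, translation shifts content", {
  img <- fixture_image("SCP", 160, 2)
  id <- ground_truth_warp(0, c(0, 0), 0, size_px = 160)
  out <- apply_warp(img, id, noise_sd = 0)
  expect_identical(out$pixels, img$pixels)

  tr <- ground_truth_warp(0, c(5, 0), 0, size_px = 160)
  mov <- apply_warp(img, tr, noise_sd = 0)
  # content moved +5 px in x: mov(x + 5) == ref(x) away from the frame edge
  inner_r <- 20:140
  expect_lt(max(abs(mov$pixels[inner_r, 30:140 + 5] -
                    img$pixels[inner_r, 30:140])), 1e-9)
  # cross-correlation peaks at lag 5
  lags <- sapply(0:8, function(l) {
    a <- img$pixels[inner_r, 20:120]
    b <- mov$pixels[inner_r, 20:120 + l]
    stats::cor(as.numeric(a), as.numeric(b))
  })
  expect_equal(which.max(lags) - 1, 5)
})

test_that("elastic ground truth hits the requested mean magnitude", {
  w <- ground_truth_warp(2, c(8, -5), mean_elastic_um = 15, size_px = 304,
                         seed = 3)
  upp <- 1000 * 3 / 304
  m <- mean(sqrt(w$ex^2 + w$ey^2)) * upp
  expect_lt(abs(m - 15) / 15, 0.05)
  # warp invariants enforced
  expect_error(ground_truth_warp(12, c(0, 0), size_px = 304), "theta")
  expect_error(ground_truth_warp(0, c(40, 0), size_px = 304), "tx")
})

test_that("stored displacement equals the analytic composed warp", {
  w <- ground_truth_warp(1.5, c(4, -2), mean_elastic_um = 10, size_px = 160,
                         seed = 5)
  d <- warp_displacement(w)
  set.seed(11)
  for (k in 1:20) {
    r <- sample(20:140, 1); cl <- sample(20:140, 1)
    p <- c(cl - 0.5, r - 0.5)  # continuous coords of pixel (r, cl)
    th <- 1.5 * pi / 180; c0 <- 80
    rx <- cos(th) * (p[1] - c0) - sin(th) * (p[2] - c0) + c0 + 4
    ry <- sin(th) * (p[1] - c0) + cos(th) * (p[2] - c0) + c0 - 2
    ex <- cf_bilinear_wrap(w$ex, rx - 0.5, ry - 0.5)
    ey <- cf_bilinear_wrap(w$ey, rx - 0.5, ry - 0.5)
    expect_equal(d$dx[r, cl], rx + ex - p[1], tolerance = 1e-10)
    expect_equal(d$dy[r, cl], ry + ey - p[2], tolerance = 1e-10)
  }
})

test_that("rigid-then-elastic equals the composed warp within interpolation", {
  # band-limited analytic fixture: isolates warp-composition error from
  # double-interpolation error, which dominates at sharp vessel edges
  n <- 160L
  x <- matrix(seq_len(n) - 0.5, n, n, byrow = TRUE); y <- t(x)
  px <- 0.5 + 0.2 * sin(2 * pi * x / 25) * cos(2 * pi * y / 31) +
    0.15 * sin(2 * pi * (x + y) / 41) + 0.1 * cos(2 * pi * x / 53)
  img <- en_face_slab(pmin(pmax(px, 0), 1))
  rig <- ground_truth_warp(2, c(5, -3), 0, size_px = 160)
  ela <- ground_truth_warp(0, c(0, 0), mean_elastic_um = 12, size_px = 160,
                           seed = 9)
  comp <- ground_truth_warp(2, c(5, -3), mean_elastic_um = 12, size_px = 160,
                            seed = 9)
  two_step <- apply_warp(apply_warp(img, rig, 0), ela, 0)
  one_step <- apply_warp(img, comp, 0)
  inner <- 15:145  # the frame border is boundary-handled, not content
  expect_lt(max(abs(two_step$pixels[inner, inner] -
                    one_step$pixels[inner, inner])), 2 / 255)
})

test_that("simulate_cohort honors degenerate and zero-rate specs", {
  sp <- cohort_spec(n_patients = 4, slab_means_um = c(SCP = 10, DCP = 12, CC = 14),
                    patient_sd_um = 0, residual_sd_um = 0,
                    phenotype_rates = c(rpd = 0, dped = 0, drusen = 0, irora = 0),
                    phenotype_effects_um = list())
  tb <- simulate_cohort(sp, seed = 1)
  expect_equal(nrow(tb), 12)
  expect_equal(tb$displacement_um[tb$slab == "SCP"], rep(10, 4))
  expect_equal(tb$displacement_um[tb$slab == "CC"], rep(14, 4))
  expect_false(any(tb$rpd | tb$dped | tb$drusen | tb$irora))
  expect_identical(tb, simulate_cohort(sp, seed = 1))

  # deterministic effects add to the right slab
  sp2 <- cohort_spec(n_patients = 3, slab_means_um = c(SCP = 10, DCP = 12, CC = 14),
                     patient_sd_um = 0, residual_sd_um = 0,
                     phenotype_rates = c(rpd = 1),
                     phenotype_effects_um = list(rpd = c(DCP = 6)))
  tb2 <- simulate_cohort(sp2, seed = 2)
  expect_equal(unique(tb2$displacement_um[tb2$slab == "DCP"]), 18)
})

test_that("simulated slab means match the truncated-normal expectation", {
  # oracle: closed form E[max(0, N(mu, s^2))] = mu*pnorm(mu/s) + s*dnorm(mu/s)
  sp <- cohort_spec(n_patients = 18,
                    slab_means_um = c(SCP = 13, DCP = 15, CC = 19),
                    patient_sd_um = 5, residual_sd_um = 3,
                    phenotype_rates = c(rpd = 0), phenotype_effects_um = list())
  reps <- lapply(1:500, function(s) simulate_cohort(sp, seed = s))
  tb <- do.call(rbind, reps)
  s_tot <- sqrt(5^2 + 3^2)
  for (slab in c("SCP", "DCP", "CC")) {
    mu <- sp$slab_means_um[[slab]]
    truth <- mu * pnorm(mu / s_tot) + s_tot * dnorm(mu / s_tot)
    v <- tb$displacement_um[tb$slab == slab]
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - truth), 3 * se)
  }
})
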