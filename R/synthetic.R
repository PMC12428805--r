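# Synthetic en-face angiograms with known ground truth. These stand in for
# the undeposited clinical OCTA scans: each slab style mimics the texture
# scale of its plexus (thick branching arterioles/venules superficially, a
# fine capillary mesh deeper, near-isotropic granular flow signal in the
# choriocapillaris), and image pairs are related by a known rigid
# misalignment plus a smooth elastic "biological" displacement.

#' Slab texture style
#'
#' @param name "SCP", "DCP" or "CC"; supplies field defaults which can be
#'   overridden
#' @param vessel_density target fraction of lit (vessel) pixels, in (0, 0.6)
#' @param caliber_px typical vessel width in pixels (>= 1)
#' @param texture "branching", "mesh" or "granular"
#' @return object of class `SlabStyle`
#' @export
slab_style <- function(name = c("SCP", "DCP", "CC"),
                       vessel_density = NULL, caliber_px = NULL,
                       texture = NULL) {
  name <- match.arg(name)
  def <- switch(name,
    SCP = list(vessel_density = 0.35, caliber_px = 3.0, texture = "branching"),
    DCP = list(vessel_density = 0.40, caliber_px = 1.5, texture = "mesh"),
    CC  = list(vessel_density = 0.55, caliber_px = 1.0, texture = "granular"))
  st <- list(name = name,
             vessel_density = vessel_density %||% def$vessel_density,
             caliber_px = caliber_px %||% def$caliber_px,
             texture = texture %||% def$texture)
  if (st$vessel_density <= 0 || st$vessel_density >= 0.6)
    stop("vessel_density must lie in (0, 0.6)")
  if (st$caliber_px < 1) stop("caliber_px must be >= 1")
  if (!st$texture %in% c("branching", "mesh", "granular"))
    stop("unknown texture: ", st$texture)
  structure(st, class = "SlabStyle")
}

# Random-walk stroke rasterizer shared by the branching and mesh textures.
# Walks persistently-directed strokes, occasionally branching, stamping a
# disc of radius caliber/2 at each step, until the lit fraction reaches the
# target density.
draw_strokes <- function(size, density, caliber, turn_sd, branch_p,
                         n_steps, max_strokes = 4000L) {
  canvas <- matrix(0, size, size)
  radius <- max(caliber / 2, 0.7)
  strokes <- 0L
  while (mean(canvas > 0) < density && strokes < max_strokes) {
    stack <- list(list(
      x = stats::runif(1, 1, size - 1), y = stats::runif(1, 1, size - 1),
      a = stats::runif(1, 0, 2 * pi), n = n_steps))
    while (length(stack) > 0) {
      s <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      xs <- numeric(s$n); ys <- numeric(s$n)
      x <- s$x; y <- s$y; a <- s$a
      turns <- stats::rnorm(s$n, 0, turn_sd)
      branch <- stats::runif(s$n) < branch_p
      for (i in seq_len(s$n)) {
        a <- a + turns[i]
        x <- x + cos(a); y <- y + sin(a)
        if (x < 1 || x > size - 2 || y < 1 || y > size - 2) {
          xs <- xs[seq_len(i - 1)]; ys <- ys[seq_len(i - 1)]
          break
        }
        xs[i] <- x; ys[i] <- y
        if (branch[i] && length(stack) < 16) {
          stack[[length(stack) + 1L]] <- list(
            x = x, y = y,
            a = a + sample(c(-1, 1), 1) * stats::runif(1, 0.6, 1.2),
            n = max(8L, as.integer((s$n - i) / 2)))
        }
      }
      if (length(xs) > 0)
        canvas <- cf_stamp_discs(canvas, xs, ys, radius, 1.0)
      strokes <- strokes + 1L
      if (strokes >= max_strokes) break
    }
  }
  canvas
}

#' Generate a synthetic en-face angiogram
#'
#' Deterministic given `seed`; the caller's RNG stream is untouched.
#'
#' @param style a [slab_style()]
#' @param size_px image side length (>= 128)
#' @param seed integer seed
#' @param scan_width_mm physical width represented (default 3.0)
#' @param timepoint time-point label for the produced slab
#' @return an `EnFaceSlab`
#' @export
generate_slab_image <- function(style, size_px = 304L, seed = 1L,
                                scan_width_mm = 3.0, timepoint = "T0") {
  stopifnot(inherits(style, "SlabStyle"))
  size_px <- as.integer(size_px)
  if (size_px < 128) stop("size_px must be >= 128")
  if (size_px < 8 * style$caliber_px)
    stop("size_px too small to host caliber_px = ", style$caliber_px)
  px <- with_seed(seed, {
    if (style$texture == "granular") {
      z <- gauss_smooth(matrix(stats::rnorm(size_px^2), size_px), 1.0)
      q <- stats::quantile(z, 1 - style$vessel_density)
      v <- stats::plogis((z - q) / (0.3 * stats::sd(z)))
    } else {
      pars <- if (style$texture == "branching") {
        list(turn_sd = 0.10, branch_p = 0.03, n_steps = as.integer(size_px))
      } else {
        list(turn_sd = 0.35, branch_p = 0.06,
             n_steps = as.integer(size_px / 3))
      }
      canvas <- draw_strokes(size_px, style$vessel_density, style$caliber_px,
                             pars$turn_sd, pars$branch_p, pars$n_steps)
      v <- clip01(gauss_smooth(canvas, 0.7) * 0.9 + 0.05)
    }
    speckle <- matrix(stats::rnorm(size_px^2, 0, 0.03), size_px)
    clip01(v * 0.92 + 0.04 + speckle)
  })
  en_face_slab(px, scan_width_mm, style$name, timepoint)
}

#' Ground-truth warp: rigid misalignment plus smooth elastic displacement
#'
#' The forward map is phi = phi_E o phi_R: content at reference position p
#' lands at phi(p) in the moving image. phi_R rotates by `theta` degrees
#' about the image center and translates by `t` (px); phi_E adds a smooth
#' elastic field built from Gaussian-smoothed white noise (correlation
#' length `sigma_smooth` px), rescaled so the mean elastic magnitude equals
#' `mean_elastic_um` micrometers.
#'
#' @param theta rotation in degrees, |theta| <= 10
#' @param t translation (tx, ty) in px, each |.| <= 0.05 * size_px
#' @param mean_elastic_um target mean magnitude of the elastic component
#' @param size_px image side the warp applies to
#' @param scan_width_mm physical width (converts px to um)
#' @param sigma_smooth Gaussian smoothing scale of the elastic field (px)
#' @param seed seed for the elastic field
#' @return object of class `GroundTruthWarp`
#' @export
ground_truth_warp <- function(theta = 0, t = c(0, 0), mean_elastic_um = 0,
                              size_px = 304L, scan_width_mm = 3.0,
                              sigma_smooth = 15, seed = 1L) {
  size_px <- as.integer(size_px)
  if (abs(theta) > 10) stop("|theta| must be <= 10 degrees")
  if (any(abs(t) > 0.05 * size_px))
    stop("|tx|, |ty| must be <= 0.05 * size_px")
  upp <- 1000 * scan_width_mm / size_px
  ex <- ey <- NULL
  if (mean_elastic_um > 0) {
    fld <- with_seed(seed, {
      list(x = gauss_smooth(matrix(stats::rnorm(size_px^2), size_px), sigma_smooth),
           y = gauss_smooth(matrix(stats::rnorm(size_px^2), size_px), sigma_smooth))
    })
    ex <- fld$x - mean(fld$x)
    ey <- fld$y - mean(fld$y)
    mag_um <- mean(sqrt(ex^2 + ey^2)) * upp
    ex <- ex * (mean_elastic_um / mag_um)
    ey <- ey * (mean_elastic_um / mag_um)
  }
  structure(
    list(theta = theta, t = as.numeric(t), ex = ex, ey = ey,
         mean_elastic_um = mean_elastic_um, size_px = size_px,
         scan_width_mm = scan_width_mm, sigma_smooth = sigma_smooth,
         seed = seed),
    class = "GroundTruthWarp"
  )
}

# forward rigid map in continuous coords (center at size/2)
rigid_forward <- function(x, y, theta_deg, t, size) {
  c0 <- size / 2
  th <- theta_deg * pi / 180
  xr <- x - c0; yr <- y - c0
  list(x = cos(th) * xr - sin(th) * yr + c0 + t[1],
       y = sin(th) * xr + cos(th) * yr + c0 + t[2])
}

warp_forward <- function(warp, x, y) {
  # x, y: matrices of continuous coords; returns phi(x, y)
  r <- rigid_forward(x, y, warp$theta, warp$t, warp$size_px)
  if (is.null(warp$ex)) return(r)
  ex <- cf_bilinear(warp$ex, r$x - 0.5, r$y - 0.5)
  ey <- cf_bilinear(warp$ey, r$x - 0.5, r$y - 0.5)
  list(x = r$x + ex, y = r$y + ey)
}

#' Exact forward displacement of a warp at every pixel
#'
#' Returns the displacement `phi(p) - p` (px) at each pixel center, i.e.
#' the field a perfect flow estimator would recover.
#' @param warp a `GroundTruthWarp`
#' @return a `DisplacementField`
#' @export
warp_displacement <- function(warp) {
  n <- warp$size_px
  xc <- matrix(seq_len(n) - 0.5, n, n, byrow = TRUE)
  yc <- matrix(seq_len(n) - 0.5, n, n)
  f <- warp_forward(warp, xc, yc)
  displacement_field(f$x - xc, f$y - yc, border = 0L)
}

#' Resample an image under a ground-truth warp
#'
#' Backward-maps each output pixel through the inverse warp (elastic part
#' inverted by fixed-point iteration) and samples the input bilinearly,
#' then adds Gaussian noise. The warp object itself is attached as
#' `$gt_warp` so the exact per-pixel ground truth remains recoverable via
#' [warp_displacement()].
#'
#' @param img an `EnFaceSlab`
#' @param warp a `GroundTruthWarp` matching the image size
#' @param noise_sd additive Gaussian noise SD (image units)
#' @param seed seed for the noise
#' @return an `EnFaceSlab` (the moving image), with `$gt_warp` attached
#' @export
apply_warp <- function(img, warp, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(img, "EnFaceSlab"), inherits(warp, "GroundTruthWarp"))
  n <- ncol(img$pixels)
  if (warp$size_px != n) stop("warp size does not match image size")
  identity_rigid <- warp$theta == 0 && all(warp$t == 0)
  if (identity_rigid && is.null(warp$ex) && noise_sd == 0) {
    out <- slab_like(img, img$pixels)
    out$gt_warp <- warp
    return(out)
  }
  xc <- matrix(seq_len(n) - 0.5, n, n, byrow = TRUE)
  yc <- matrix(seq_len(n) - 0.5, n, n)
  # invert elastic part: u such that u + E(u) = q
  ux <- xc; uy <- yc
  if (!is.null(warp$ex)) {
    for (i in 1:8) {
      ex <- cf_bilinear(warp$ex, ux - 0.5, uy - 0.5)
      ey <- cf_bilinear(warp$ey, ux - 0.5, uy - 0.5)
      ux <- xc - ex
      uy <- yc - ey
    }
  }
  # invert rigid part
  c0 <- n / 2
  th <- -warp$theta * pi / 180
  xr <- ux - c0 - warp$t[1]; yr <- uy - c0 - warp$t[2]
  px <- cos(th) * xr - sin(th) * yr + c0
  py <- sin(th) * xr + cos(th) * yr + c0
  out <- cf_bilinear(img$pixels, px - 0.5, py - 0.5)
  if (noise_sd > 0) {
    out <- out + with_seed(seed, matrix(stats::rnorm(n^2, 0, noise_sd), n))
  }
  res <- slab_like(img, clip01(out))
  res$timepoint <- "T6"
  res$gt_warp <- warp
  res
}

#' Cohort simulation specification
#'
#' Mirrors the structure the mixed model assumes: per-slab fixed means,
#' additive phenotype effects, a patient-level random intercept and a
#' residual term, with displacement magnitudes truncated at zero.
#'
#' @param n_patients number of patients (one eye each)
#' @param slab_means_um named true mean displacement per slab (um)
#' @param patient_sd_um between-patient random-intercept SD
#' @param residual_sd_um within-patient residual SD
#' @param phenotype_rates named Bernoulli rates for rpd, dped, drusen, irora
#' @param phenotype_effects_um named list: per phenotype, a named vector of
#'   additive shifts per slab (um)
#' @return object of class `CohortSpec`
#' @export
cohort_spec <- function(n_patients = 18L,
                        slab_means_um = c(SCP = 13.7, DCP = 15.1, CC = 19.0),
                        patient_sd_um = 5, residual_sd_um = 3,
                        phenotype_rates = c(rpd = 0.5, dped = 1 / 6,
                                            drusen = 0.8, irora = 1 / 6),
                        phenotype_effects_um = list(
                          rpd = c(SCP = 0, DCP = 6, CC = 0),
                          dped = c(SCP = 0, DCP = 0, CC = 8))) {
  stopifnot(n_patients >= 1, patient_sd_um >= 0, residual_sd_um >= 0)
  rates <- c(rpd = 0, dped = 0, drusen = 0, irora = 0)
  rates[names(phenotype_rates)] <- phenotype_rates
  if (any(rates < 0 | rates > 1)) stop("phenotype rates must lie in [0, 1]")
  stopifnot(all(c("SCP", "DCP", "CC") %in% names(slab_means_um)))
  structure(
    list(n_patients = as.integer(n_patients), slab_means_um = slab_means_um,
         patient_sd_um = patient_sd_um, residual_sd_um = residual_sd_um,
         phenotype_rates = rates, phenotype_effects_um = phenotype_effects_um),
    class = "CohortSpec"
  )
}

#' Simulate a long-format cohort table of per-eye/per-slab displacements
#'
#' y_{i,slab} = slab mean + phenotype effects + patient intercept
#' u_i ~ N(0, patient_sd^2) + eps ~ N(0, residual_sd^2), truncated at 0.
#'
#' @param spec a [cohort_spec()]
#' @param seed integer seed
#' @return data.frame with the canonical cohort columns (roi = "whole")
#' @export
simulate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "CohortSpec"))
  slabs <- c("SCP", "DCP", "CC")
  with_seed(seed, {
    np <- spec$n_patients
    flags <- sapply(c("rpd", "dped", "drusen", "irora"), function(ph) {
      stats::runif(np) < spec$phenotype_rates[[ph]]
    })
    flags <- matrix(flags, nrow = np,
                    dimnames = list(NULL, c("rpd", "dped", "drusen", "irora")))
    u <- stats::rnorm(np, 0, spec$patient_sd_um)
    rows <- lapply(seq_len(np), function(i) {
      eff <- stats::setNames(numeric(3), slabs)
      for (ph in names(spec$phenotype_effects_um)) {
        if (isTRUE(flags[i, ph])) {
          e <- spec$phenotype_effects_um[[ph]]
          eff[names(e)] <- eff[names(e)] + e
        }
      }
      y <- spec$slab_means_um[slabs] + eff[slabs] + u[i] +
        stats::rnorm(3, 0, spec$residual_sd_um)
      data.frame(
        patient_id = sprintf("P%02d", i), eye_id = sprintf("E%02d", i),
        slab = slabs, roi = "whole", displacement_um = pmax(0, as.numeric(y)),
        rpd = unname(flags[i, "rpd"]), dped = unname(flags[i, "dped"]),
        drusen = unname(flags[i, "drusen"]), irora = unname(flags[i, "irora"]),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
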