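# Shared fixtures, generated in code (no binary files). Cached per session
# so repeated tests don't regenerate identical images.

.fixture_cache <- new.env(parent = emptyenv())

fixture_image <- function(style = "SCP", size = 160L, seed = 1L) {
  key <- paste(style, size, seed, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_slab_image(slab_style(style), size, seed)
  }
  .fixture_cache[[key]]
}

# analytic displacement field of a pure rotation about the image center
rotation_field <- function(n, theta_deg) {
  th <- theta_deg * pi / 180
  xc <- matrix(seq_len(n) - 0.5, n, n, byrow = TRUE) - n / 2
  yc <- matrix(seq_len(n) - 0.5, n, n) - n / 2
  displacement_field(cos(th) * xc - sin(th) * yc - xc,
                     sin(th) * xc + cos(th) * yc - yc)
}

# radially increasing field d(p) = k * (p - c)
radial_field <- function(n, k) {
  xc <- matrix(seq_len(n) - 0.5, n, n, byrow = TRUE) - n / 2
  yc <- matrix(seq_len(n) - 0.5, n, n) - n / 2
  displacement_field(k * xc, k * yc)
}

# run the independent scikit-image flow reference on a pair of matrices
run_flow_oracle <- function(ref, mov, radius = 7L) {
  scr <- system.file("python", "flow_oracle.py", package = "coronaflow")
  td <- tempfile("oracle")
  dir.create(td)
  rp <- file.path(td, "ref.txt"); mp <- file.path(td, "mov.txt")
  write.table(ref, rp, row.names = FALSE, col.names = FALSE)
  write.table(mov, mp, row.names = FALSE, col.names = FALSE)
  status <- system2("python", c(scr, rp, mp, file.path(td, "o"), radius),
                    stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0)
  list(dx = unname(as.matrix(read.table(file.path(td, "o_dx.txt")))),
       dy = unname(as.matrix(read.table(file.path(td, "o_dy.txt")))))
}

mean_epe <- function(dx, dy, gt_dx, gt_dy, mask) {
  mean(sqrt((dx - gt_dx)^2 + (dy - gt_dy)^2)[mask])
}

# internal helpers re-exposed for tests
autocorr_length_of <- coronaflow:::autocorr_length
image_entropy_of <- coronaflow:::image_entropy

# scalar bilinear sample at 0-based index coordinates
cf_bilinear_wrap <- function(m, x, y) {
  coronaflow:::cf_bilinear(m, matrix(x, 1, 1), matrix(y, 1, 1))[1, 1]
}
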