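#' En-face OCTA slab image
#'
#' Container for one grayscale en-face angiogram with its physical scale.
#' The scan covers `scan_width_mm` millimeters of retina regardless of the
#' pixel count, so the micrometer-per-pixel factor is derived, not stored.
#'
#' @param pixels numeric matrix with values in \[0, 1\] (rows = y, cols = x)
#' @param scan_width_mm physical width of the scanned field (default 3.0,
#'   a fovea-centered 3x3 mm field)
#' @param slab one of "SCP", "DCP", "CC" (superficial capillary plexus,
#'   deep capillary plexus, choriocapillaris)
#' @param timepoint one of "T0" (baseline), "T6" (6-month follow-up)
#' @return an object of class `EnFaceSlab`
#' @export
en_face_slab <- function(pixels, scan_width_mm = 3.0,
                         slab = c("SCP", "DCP", "CC"),
                         timepoint = c("T0", "T6")) {
  slab <- match.arg(slab)
  timepoint <- match.arg(timepoint)
  if (!is.matrix(pixels) || length(pixels) == 0)
    stop("pixels must be a non-empty matrix")
  if (nrow(pixels) != ncol(pixels))
    stop("en-face slabs must be square (got ", nrow(pixels), "x", ncol(pixels), ")")
  if (!all(is.finite(pixels)))
    stop("pixels must be finite")
  if (min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9)
    stop("pixels must lie in [0, 1]")
  if (scan_width_mm <= 0) stop("scan_width_mm must be positive")
  structure(
    list(pixels = unname(pixels), scan_width_mm = scan_width_mm,
         slab = slab, timepoint = timepoint),
    class = "EnFaceSlab"
  )
}

#' Micrometers per pixel of a slab
#' @param x an `EnFaceSlab`
#' @export
um_per_px <- function(x) {
  stopifnot(inherits(x, "EnFaceSlab"))
  1000 * x$scan_width_mm / ncol(x$pixels)
}

#' @export
print.EnFaceSlab <- function(x, ...) {
  cat(sprintf("<EnFaceSlab %s %s: %dx%d px, %.1f mm field, %.3f um/px>\n",
              x$slab, x$timepoint, nrow(x$pixels), ncol(x$pixels),
              x$scan_width_mm, um_per_px(x)))
  invisible(x)
}

#' @export
dim.EnFaceSlab <- function(x) dim(x$pixels)

slab_like <- function(template, pixels) {
  en_face_slab(pixels, template$scan_width_mm, template$slab, template$timepoint)
}
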