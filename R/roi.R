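# Reporting: whole-image and concentric circular ROI displacement
# statistics in micrometers, computed over the 36x36 grid nodes. The three
# radii (0.5, 0.75, 1.5 mm) correspond to the central subfield, the inner
# parafoveal ring and the full parafovea of a 3 mm fovea-centered scan.

#' ROI specification
#'
#' @param center foveal center in continuous px coordinates; default NULL
#'   means the image center (scans are fovea-centered)
#' @param radii_mm circle radii in mm, positive and increasing
#' @param whole_image include the whole-image summary
#' @export
roi_spec <- function(center = NULL, radii_mm = c(0.5, 0.75, 1.5),
                     whole_image = TRUE) {
  stopifnot(all(radii_mm > 0), !is.unsorted(radii_mm, strictly = TRUE))
  structure(list(center = center, radii_mm = radii_mm,
                 whole_image = whole_image),
            class = "ROISpec")
}

roi_label <- function(radius_mm) sprintf("r%g", radius_mm)

#' Node-inclusion mask for one circular ROI
#'
#' A node p is included iff ||p - center|| * um_per_px <= radius_mm * 1000
#' (inclusive boundary).
#'
#' @param grid a `GridDisplacement`
#' @param radius_mm circle radius in mm
#' @param meta an `EnFaceSlab` supplying the physical scale
#' @param center optional center override (continuous px coords)
#' @return logical matrix over grid nodes
#' @export
roi_mask <- function(grid, radius_mm, meta, center = NULL) {
  stopifnot(inherits(grid, "GridDisplacement"), inherits(meta, "EnFaceSlab"))
  upp <- um_per_px(meta)
  if (radius_mm * 1000 > meta$scan_width_mm * 1000 / 2 + 1e-9)
    stop("radius ", radius_mm, " mm exceeds the scanned half-width")
  if (is.null(center)) center <- c(grid$width / 2, grid$height / 2)
  d_um <- sqrt((grid$nx - center[1])^2 + (grid$ny - center[2])^2) * upp
  d_um <= radius_mm * 1000
}

#' Summarize residual displacement over the ROIs
#'
#' Per ROI: mean and SD of node-wise displacement magnitudes
#' D = sqrt(dx^2 + dy^2) * um_per_px over included valid nodes, plus the
#' whole-image summary over all valid nodes.
#'
#' @param grid a `GridDisplacement` sampled from the post-alignment
#'   residual field
#' @param meta an `EnFaceSlab` supplying scale and labels
#' @param spec a [roi_spec()]
#' @return data.frame with columns slab, roi, mean_um, sd_um, n_nodes,
#'   timepair
#' @export
summarize_displacement <- function(grid, meta, spec = roi_spec()) {
  stopifnot(inherits(grid, "GridDisplacement"), inherits(meta, "EnFaceSlab"))
  upp <- um_per_px(meta)
  mag <- sqrt(grid$dx^2 + grid$dy^2) * upp
  rois <- list()
  if (spec$whole_image) rois[["whole"]] <- matrix(TRUE, grid$n_side, grid$n_side)
  for (r in spec$radii_mm)
    rois[[roi_label(r)]] <- roi_mask(grid, r, meta, spec$center)
  out <- lapply(names(rois), function(lab) {
    keep <- rois[[lab]] & grid$valid
    if (!any(keep)) stop("ROI '", lab, "' contains no valid nodes")
    vals <- mag[keep]
    data.frame(slab = meta$slab, roi = lab, mean_um = mean(vals),
               sd_um = stats::sd(vals), n_nodes = length(vals),
               timepair = "T0-T6", stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
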