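# Plain-text/NetPBM serialization. PNG/TIFF writers are not available in
# the offline toolchain, so images travel as 16-bit PGM (P5) and renders as
# 8-bit PPM (P6), each with a JSON sidecar carrying the physical metadata.

#' Write a grayscale matrix as 16-bit binary PGM
#' @param m numeric matrix in \[0, 1\]
#' @param path output file ending in .pgm
#' @export
write_pgm <- function(m, path) {
  stopifnot(is.matrix(m), all(is.finite(m)))
  v <- round(clip01(m) * 65535)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", paste(ncol(m), nrow(m)), "65535"), con, sep = "\n")
  # row-major scan order
  writeBin(as.integer(t(v)), con, size = 2, endian = "big")
  invisible(path)
}

#' Read a binary PGM (8- or 16-bit) into a matrix in \[0, 1\]
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(magic, "P5")) stop("not a binary PGM (P5): ", path)
  hdr <- character(0)
  while (length(hdr) < 3) {
    ln <- readLines(con, n = 1)
    ln <- sub("#.*", "", ln)
    hdr <- c(hdr, strsplit(trimws(ln), "\\s+")[[1]])
  }
  w <- as.integer(hdr[1]); h <- as.integer(hdr[2]); maxval <- as.integer(hdr[3])
  size <- if (maxval > 255) 2L else 1L
  raw <- readBin(con, "integer", n = w * h, size = size, signed = FALSE,
                 endian = "big")
  matrix(raw / maxval, nrow = h, ncol = w, byrow = TRUE)
}

#' Write an RGB array (H x W x 3, values in \[0,1\]) as binary PPM
#' @export
write_ppm <- function(a, path) {
  stopifnot(length(dim(a)) == 3, dim(a)[3] == 3)
  v <- round(clip01(a) * 255)
  h <- dim(a)[1]; w <- dim(a)[2]
  # interleave channels pixel-by-pixel in row-major order
  px <- array(0L, c(3, w, h))
  for (ch in 1:3) px[ch, , ] <- t(v[, , ch])
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P6", paste(w, h), "255"), con, sep = "\n")
  writeBin(as.raw(as.integer(px)), con)
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.[A-Za-z]+$", "", path), ".json")

#' Write an `EnFaceSlab` as PGM plus JSON sidecar
#'
#' The sidecar records scan width, slab label, time point and, when the
#' image was produced by [apply_warp()], the serialized ground-truth warp
#' parameters.
#' @export
write_slab <- function(x, path, extra = NULL) {
  stopifnot(inherits(x, "EnFaceSlab"))
  write_pgm(x$pixels, path)
  meta <- list(scan_width_mm = x$scan_width_mm, slab = x$slab,
               timepoint = x$timepoint, width_px = ncol(x$pixels))
  if (!is.null(extra)) meta <- c(meta, extra)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an `EnFaceSlab` written by [write_slab()]
#' @export
read_slab <- function(path) {
  m <- read_pgm(path)
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
    en_face_slab(m, meta$scan_width_mm, meta$slab, meta$timepoint)
  } else {
    en_face_slab(m)
  }
}

#' Serialize a displacement field as two TSV matrices plus a JSON sidecar
#'
#' Writes `<stem>_dx.tsv`, `<stem>_dy.tsv` (pixel units, full precision)
#' and `<stem>.json` with `um_per_px` and any parameters supplied.
#' @export
write_field <- function(field, stem, um_per_px = NA_real_, params = NULL) {
  stopifnot(inherits(field, "DisplacementField"))
  utils::write.table(field$dx, paste0(stem, "_dx.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(field$dy, paste0(stem, "_dy.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(um_per_px = um_per_px, border = field$border)
  if (!is.null(params)) meta$params <- params
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' Read a displacement field written by [write_field()]
#' @export
read_field <- function(stem) {
  dx <- as.matrix(utils::read.table(paste0(stem, "_dx.tsv"), sep = "\t"))
  dy <- as.matrix(utils::read.table(paste0(stem, "_dy.tsv"), sep = "\t"))
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  displacement_field(unname(dx), unname(dy), border = meta$border %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cohort_columns <- c("patient_id", "eye_id", "slab", "roi", "displacement_um",
                    "rpd", "dped", "drusen", "irora")

#' Write a cohort table as CSV with the canonical column order
#' @export
write_cohort <- function(table, path) {
  stopifnot(all(cohort_columns %in% names(table)))
  utils::write.csv(table[, cohort_columns, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort CSV written by [write_cohort()]
#' @export
read_cohort <- function(path) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (fl in c("rpd", "dped", "drusen", "irora"))
    if (fl %in% names(tb)) tb[[fl]] <- as.logical(tb[[fl]])
  tb
}
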