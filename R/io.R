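#' Read a fundus image or mask raster
#'
#' Supports PNG, TIFF and JPEG by file extension. Values are returned as
#' integers in 0-255 at the stored resolution (no silent rescaling). Gray
#' sources come back as an H x W matrix, color sources as H x W x 3, RGBA
#' sources as H x W x 4 with the alpha channel preserved.
#'
#' @param path file path.
#' @return Integer matrix or array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    # libtiff warns on alpha channels written without an ExtraSamples tag;
    # the pixel data itself round-trips exactly
    tif = , tiff = suppressWarnings(tiff::readTIFF(path)),
    jpg = , jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: .", ext)
  )
  out <- round(raw * 255)
  storage.mode(out) <- "integer"
  if (length(dim(out)) == 3L && dim(out)[3] == 1L) out <- out[, , 1]
  out
}

#' Write a raster losslessly (or as JPEG on request)
#'
#' Masks (2-D) and images (3-D, 3 or 4 channels) must be integer-valued in
#' 0-255; writing float data without explicit scaling is an error so class
#' ids survive byte-exactly. PNG and TIFF are lossless; JPEG is refused for
#' 2-D masks.
#'
#' @param image integer matrix or H x W x {3,4} array, values 0-255.
#' @param path destination; format chosen by extension (png/tif/tiff/jpg).
#' @export
write_image <- function(image, path) {
  d <- dim(image)
  if (!(length(d) == 2L || (length(d) == 3L && d[3] %in% c(3L, 4L))))
    stop("image must be 2-D or have 3/4 channels")
  if (!is.numeric(image) || any(abs(image - round(image)) > 0))
    stop("non-integer raster: scale and round explicitly before writing")
  if (min(image) < 0 || max(image) > 255) stop("values must lie in 0-255")
  x <- image / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x, path),
    tif = , tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    jpg = , jpeg = {
      if (length(d) == 2L) stop("JPEG is lossy; refuse to write a class mask")
      jpeg::writeJPEG(x, path, quality = 0.95)
    },
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}

#' Run-length encode a class mask
#'
#' Runs are taken in row-major order with 0-based start indices; adjacent runs
#' never share a class id, so the encoding is canonical and decoding
#' reproduces the mask exactly.
#'
#' @param mask 2-D integer matrix of class ids.
#' @return An `rle_mask`: list with `shape` (H, W) and a data frame `runs`
#'   with columns `start`, `length`, `class_id`.
#' @examples
#' rle_encode(matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE))
#' @export
rle_encode <- function(mask) {
  mask <- as_label_matrix(mask)
  v <- as.vector(t(mask))                      # row-major
  r <- rle(v)
  ends <- cumsum(r$lengths)
  runs <- data.frame(start = ends - r$lengths, length = r$lengths,
                     class_id = r$values)
  structure(list(shape = dim(mask), runs = runs), class = "rle_mask")
}

#' Decode a run-length encoded mask
#'
#' @param rle an `rle_mask` (or a bare data frame of runs).
#' @param shape target (H, W); defaults to the shape stored in `rle`.
#' @return Integer H x W matrix.
#' @export
rle_decode <- function(rle, shape = NULL) {
  runs <- if (inherits(rle, "rle_mask")) rle$runs else as.data.frame(rle)
  if (is.null(shape)) shape <- rle$shape
  shape <- as.integer(shape)
  n <- prod(shape)
  runs <- runs[order(runs$start), , drop = FALSE]
  if (any(runs$length <= 0)) stop("run lengths must be positive")
  ends <- runs$start + runs$length
  starts_expected <- c(0, ends[-nrow(runs)])
  if (nrow(runs) == 0 || any(runs$start != starts_expected) ||
      ends[nrow(runs)] != n)
    stop("runs must tile the mask exactly (no gaps or overlaps)")
  v <- rep(as.integer(runs$class_id), runs$length)
  matrix(v, shape[1], shape[2], byrow = TRUE)
}

#' Write / read the plain-text RLE sidecar format
#'
#' One header line "H W" followed by one "start length class" line per run.
#'
#' @param rle an `rle_mask`.
#' @param path text file path.
#' @rdname rle_sidecar
#' @export
write_rle <- function(rle, path) {
  stopifnot(inherits(rle, "rle_mask"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rle$shape[1], rle$shape[2]), con)
  writeLines(sprintf("%d %d %d", rle$runs$start, rle$runs$length,
                     rle$runs$class_id), con)
  invisible(path)
}

#' @rdname rle_sidecar
#' @export
read_rle <- function(path) {
  lines <- readLines(path)
  shape <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  body <- do.call(rbind, lapply(strsplit(trimws(lines[-1]), "\\s+"), as.integer))
  runs <- data.frame(start = body[, 1], length = body[, 2], class_id = body[, 3])
  structure(list(shape = shape, runs = runs), class = "rle_mask")
}
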