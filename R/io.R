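#' Echo cube and image volume serialization
#'
#' Complex cubes are stored in a lightweight self-describing container: a
#' JSON header (shape, axes, radar parameters, byte layout) followed by
#' the real then imaginary parts as IEEE-754 little-endian doubles. The
#' same container holds reconstructed volumes.
#'
#' @param echo An `echo_cube`.
#' @param path Output file path.
#' @return `write_echo()`/`write_volume()` return `path` invisibly; the
#'   readers return the restored object.
#' @export
write_echo <- function(echo, path) {
  stopifnot(inherits(echo, "echo_cube"))
  header <- list(kind = "echo_cube", dim = dim(echo$data),
                 x_axis = echo$x_axis, y_axis = echo$y_axis,
                 k_axis = echo$k_axis,
                 cfg = unclass(echo$cfg),
                 layout = "re_then_im_f64_le")
  write_complex_container(header, echo$data, path)
}

#' @rdname write_echo
#' @export
read_echo <- function(path) {
  parts <- read_complex_container(path, "echo_cube")
  h <- parts$header
  cfg <- do.call(radar_config, h$cfg)
  new_echo_cube(parts$data, h$x_axis, h$y_axis, h$k_axis, cfg)
}

#' @rdname write_echo
#' @param vol An `image_volume`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  header <- list(kind = "image_volume", dim = dim(vol$data),
                 x_axis = vol$x_axis, y_axis = vol$y_axis,
                 z_axis = vol$z_axis, layout = "re_then_im_f64_le")
  write_complex_container(header, vol$data, path)
}

#' @rdname write_echo
#' @export
read_volume <- function(path) {
  parts <- read_complex_container(path, "image_volume")
  h <- parts$header
  new_image_volume(parts$data, h$x_axis, h$y_axis, h$z_axis)
}

write_complex_container <- function(header, data, path) {
  hjson <- jsonlite::toJSON(header, digits = NA, auto_unbox = TRUE)
  hraw <- charToRaw(as.character(hjson))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin("OSARCPLX", con)
  writeBin(length(hraw), con, size = 8, endian = "little")
  writeBin(hraw, con)
  writeBin(as.vector(Re(data)), con, size = 8, endian = "little")
  writeBin(as.vector(Im(data)), con, size = 8, endian = "little")
  invisible(path)
}

read_complex_container <- function(path, expect_kind) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "character")
  if (!identical(magic, "OSARCPLX")) stop("not an orchardsar container file")
  hlen <- readBin(con, "integer", size = 8, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  if (!identical(header$kind, expect_kind)) {
    stop(sprintf("container holds a %s, expected %s", header$kind,
                 expect_kind))
  }
  n <- prod(header$dim)
  re <- readBin(con, "double", n, size = 8, endian = "little")
  im <- readBin(con, "double", n, size = 8, endian = "little")
  data <- array(complex(real = re, imaginary = im), dim = header$dim)
  list(header = header, data = data)
}

#' Write a detection image to 16-bit TIFF
#'
#' Pixels are clipped to `[0, 1]` and written at 16-bit depth; a JSON
#' sidecar (`<path>.json`) records the pixel pitch and provenance note.
#'
#' @param img A `detection_image`.
#' @param path Output TIFF path.
#' @param sidecar Also write the JSON sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_detection_image <- function(img, path, sidecar = TRUE) {
  stopifnot(inherits(img, "detection_image"))
  px <- pmin(pmax(img$pixels, 0), 1)
  # quantize explicitly so a read-back round trip is exact at 16 bits
  px <- round(px * 65535) / 65535
  tiff::writeTIFF(px, path, bits.per.sample = 16)
  if (sidecar) {
    jsonlite::write_json(list(pitch_m = img$pitch, note = img$note),
                         paste0(path, ".json"), digits = NA,
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_detection_image
#' @export
read_detection_image <- function(path) {
  px <- tiff::readTIFF(path)
  meta_path <- paste0(path, ".json")
  pitch <- c(1, 1); note <- ""
  if (file.exists(meta_path)) {
    meta <- jsonlite::fromJSON(meta_path)
    pitch <- meta$pitch_m
    note <- meta$note
  }
  new_detection_image(px, pitch, note)
}
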