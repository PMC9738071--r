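#' Grayscale radiograph container
#'
#' A `radiograph` wraps a rectangular matrix of non-negative integer gray
#' levels together with its bit depth and (optional) pixel spacing. Intraoral
#' radiographs from storage-phosphor systems are single-channel rasters; the
#' texture features computed by this package are pure pixel-lattice
#' quantities, so the physical pixel spacing is carried as metadata only.
#'
#' @param pixels integer matrix of gray levels, all in `[0, 2^bit_depth)`.
#' @param bit_depth 8 or 16.
#' @param pixel_spacing_mm positive pixel edge length in millimetres
#'   (default 0.07, i.e. 70 um).
#' @param image_id identifier string.
#' @return An object of class `radiograph` with fields `pixels`, `bit_depth`,
#'   `pixel_spacing_mm`, `image_id`.
#' @examples
#' img <- radiograph(matrix(0:99, 10, 10), bit_depth = 8)
#' dim(img$pixels)
#' @export
radiograph <- function(pixels, bit_depth = 8L, pixel_spacing_mm = 0.07,
                       image_id = "image") {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop_input("'pixels' must be a non-empty matrix")
  if (is.double(pixels)) {
    if (any(pixels != round(pixels), na.rm = TRUE))
      stop_input("'pixels' must contain integer gray levels")
    storage.mode(pixels) <- "integer"
  }
  if (!is.integer(pixels)) stop_input("'pixels' must be an integer matrix")
  if (anyNA(pixels)) stop_input("'pixels' must not contain missing values")
  if (!bit_depth %in% c(8L, 16L)) stop_input("'bit_depth' must be 8 or 16")
  if (min(pixels) < 0L || max(pixels) >= 2^bit_depth)
    stop_input("pixel values must lie in [0, 2^bit_depth)")
  if (!is_scalar_num(pixel_spacing_mm) || pixel_spacing_mm <= 0)
    stop_input("'pixel_spacing_mm' must be a positive number")
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         pixel_spacing_mm = pixel_spacing_mm,
         image_id = as.character(image_id)),
    class = "radiograph")
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("<radiograph '%s': %d x %d px, %d-bit, %.3f mm/px>\n",
              x$image_id, nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              x$pixel_spacing_mm))
  invisible(x)
}

#' Read a radiograph raster (PNG or PGM)
#'
#' Reads a single-channel 8- or 16-bit raster. PNG is read with the `png`
#' package; PGM (P2 plain / P5 binary, the portable graymap format) is read
#' natively and is the round-trip format for 16-bit data since no 16-bit
#' PNG/TIFF writer is available in this stack. Color or float images are
#' rejected: texture analysis is defined on raw detector gray levels and any
#' silent conversion would change the features.
#'
#' @param path file path ending in `.png`, `.pgm` or `.pnm`.
#' @param pixel_spacing_mm,image_id metadata passed to [radiograph()];
#'   `image_id` defaults to the file name without extension.
#' @return A [radiograph()].
#' @export
read_radiograph <- function(path, pixel_spacing_mm = 0.07, image_id = NULL) {
  if (!file.exists(path)) stop_input("cannot read image: '%s' does not exist", path)
  id <- image_id %||% sub("\\.[^.]+$", "", basename(path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    info <- attr(arr, "info")
    if (length(dim(arr)) != 2L)
      stop_input("unsupported format: '%s' is not single-channel grayscale", path)
    depth <- info$bit.depth
    if (!depth %in% c(8L, 16L))
      stop_input("unsupported format: '%s' has bit depth %s", path, depth)
    px <- matrix(as.integer(round(arr * (2^depth - 1))), nrow(arr), ncol(arr))
    radiograph(px, bit_depth = depth, pixel_spacing_mm = pixel_spacing_mm,
               image_id = id)
  } else if (ext %in% c("pgm", "pnm")) {
    read_pgm(path, pixel_spacing_mm = pixel_spacing_mm, image_id = id)
  } else {
    stop_input("unsupported format: '%s' (expected .png, .pgm or .pnm)", path)
  }
}

#' Write a radiograph raster
#'
#' 8-bit images can be written as PNG or PGM; 16-bit images as PGM only
#' (the available PNG writer emits 8 bits). Writing never rescales values.
#'
#' @param image a [radiograph()].
#' @param path destination ending in `.png` or `.pgm`.
#' @param ascii for PGM, write plain-text P2 (default) or binary P5.
#' @return `path`, invisibly.
#' @export
write_radiograph <- function(image, path, ascii = TRUE) {
  stopifnot(inherits(image, "radiograph"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (image$bit_depth != 8L)
      stop_input("PNG output is 8-bit only here; use PGM for 16-bit images")
    png::writePNG(image$pixels / 255, path)
  } else if (ext %in% c("pgm", "pnm")) {
    write_pgm(image, path, ascii = ascii)
  } else {
    stop_input("unsupported output format: '%s'", path)
  }
  invisible(path)
}

## -- PGM (portable graymap), P2 plain and P5 binary, maxval up to 65535 ------
## Hand-rolled because no installed package reads/writes 16-bit PGM.

read_pgm <- function(path, pixel_spacing_mm = 0.07, image_id = "image") {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5"))
    stop_input("unsupported format: '%s' is not a P2/P5 PGM", path)
  # header tokens: width height maxval, '#' comments allowed
  tok <- character(0)
  buf <- ""
  while (length(tok) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (length(ch) == 0L || ch == "") stop_input("truncated PGM header in '%s'", path)
    if (ch == "#") { # skip comment to end of line
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1L))
        if (ch %in% c("\n", "\r", "")) break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (nzchar(buf)) { tok <- c(tok, buf); buf <- "" }
    } else buf <- paste0(buf, ch)
  }
  wd <- as.integer(tok[1]); ht <- as.integer(tok[2]); mx <- as.integer(tok[3])
  if (anyNA(c(wd, ht, mx)) || wd < 1L || ht < 1L || mx < 1L || mx > 65535L)
    stop_input("invalid PGM header in '%s'", path)
  n <- wd * ht
  if (magic == "P5") {
    if (mx > 255L) {
      v <- readBin(con, "integer", n, size = 2L, signed = FALSE, endian = "big")
    } else {
      v <- as.integer(readBin(con, "raw", n))
    }
  } else {
    v <- scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(v) != n) stop_input("truncated PGM pixel data in '%s'", path)
  px <- matrix(v, nrow = ht, ncol = wd, byrow = TRUE)
  radiograph(px, bit_depth = if (mx > 255L) 16L else 8L,
             pixel_spacing_mm = pixel_spacing_mm, image_id = image_id)
}

write_pgm <- function(image, path, ascii = TRUE) {
  px <- image$pixels
  mx <- 2^image$bit_depth - 1
  if (ascii) {
    con <- file(path, "wb") # binary mode keeps newlines deterministic
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(px), nrow(px)), as.character(mx)), con)
    writeLines(apply(px, 1L, paste, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n%d\n", ncol(px), nrow(px), mx), con, eos = NULL)
    v <- as.integer(t(px))
    if (mx > 255L) {
      writeBin(v, con, size = 2L, endian = "big", useBytes = TRUE)
    } else {
      writeBin(as.raw(v), con)
    }
  }
  invisible(path)
}
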