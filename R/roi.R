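#' Region-of-interest specification
#'
#' An ROI is placed over peri-implant bone at the implant neck or over intact
#' reference bone away from the implant. The measurement protocol uses ROIs of
#' exactly 1500 pixels; other sizes are allowed (with a warning at resolution
#' time) so the toolkit remains usable on other protocols.
#'
#' Geometry is one of:
#' * `rect`: `c(r0, c0, r1, c1)`, 0-based, half-open `[r0, r1) x [c0, c1)`,
#'   matching the JSON sidecar convention;
#' * `polygon`: an n x 2 matrix of 0-based `(row, col)` vertex coordinates;
#'   pixels whose centres fall inside (or on) the polygon belong to the ROI;
#' * `mask`: a logical matrix with the dimensions of the target image.
#'
#' @param roi_id identifier string.
#' @param label `"peri_implant"` or `"reference"`.
#' @param timepoint `"initial"`, `"y5"` or `"y10"`.
#' @param rect,polygon,mask exactly one geometry (see Details).
#' @return An object of class `roi_spec`.
#' @examples
#' roi_spec("r1", "peri_implant", "initial", rect = c(0, 0, 30, 50))
#' @export
roi_spec <- function(roi_id, label = c("peri_implant", "reference"),
                     timepoint = c("initial", "y5", "y10"),
                     rect = NULL, polygon = NULL, mask = NULL) {
  label <- match.arg(label)
  timepoint <- match.arg(timepoint)
  geoms <- !vapply(list(rect, polygon, mask), is.null, logical(1))
  if (sum(geoms) != 1L)
    stop_input("exactly one of 'rect', 'polygon', 'mask' must be given")
  if (!is.null(rect)) {
    if (length(rect) != 4L || any(rect != round(rect)))
      stop_input("'rect' must be four integers c(r0, c0, r1, c1)")
    if (rect[3] <= rect[1] || rect[4] <= rect[2])
      stop_input("'rect' is empty: need r1 > r0 and c1 > c0")
    geometry <- list(type = "rect", rect = as.integer(rect))
  } else if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    if (ncol(polygon) != 2L || nrow(polygon) < 3L)
      stop_input("'polygon' must be an n x 2 matrix of (row, col) vertices, n >= 3")
    geometry <- list(type = "polygon", vertices = polygon)
  } else {
    if (!is.logical(mask) || !is.matrix(mask))
      stop_input("'mask' must be a logical matrix")
    geometry <- list(type = "mask", mask = mask)
  }
  structure(list(roi_id = as.character(roi_id), label = label,
                 timepoint = timepoint, geometry = geometry),
            class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi_spec '%s': %s, %s, %s geometry>\n", x$roi_id, x$label,
              x$timepoint, x$geometry$type))
  invisible(x)
}

#' Resolve an ROI specification to image pixels
#'
#' Maps an [roi_spec()] onto a [radiograph()], returning the ordered
#' (row-major) set of 1-based pixel coordinates it covers. A warning is
#' emitted when the pixel count differs from the 1500-pixel measurement
#' protocol; out-of-bounds geometry or an empty resolution is an error.
#'
#' @param image a [radiograph()].
#' @param spec an [roi_spec()].
#' @param protocol_pixels expected protocol ROI area (default 1500);
#'   set to `NA` to disable the size check.
#' @return An object of class `roi_pixels`: list with integer vectors `rows`,
#'   `cols` (1-based, row-major order), pixel count `n`, and the spec's
#'   `roi_id`, `label`, `timepoint`.
#' @examples
#' img <- radiograph(matrix(0L, 100, 100))
#' rp <- resolve_roi(img, roi_spec("r1", "reference", "initial",
#'                                 rect = c(0, 0, 30, 50)))
#' rp$n  # 1500
#' @export
resolve_roi <- function(image, spec, protocol_pixels = 1500L) {
  stopifnot(inherits(image, "radiograph"), inherits(spec, "roi_spec"))
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  g <- spec$geometry
  if (g$type == "rect") {
    r <- g$rect
    if (r[1] < 0L || r[2] < 0L || r[3] > nr || r[4] > nc)
      stop_input("ROI '%s': rectangle outside image bounds", spec$roi_id)
    rows <- rep((r[1] + 1L):r[3], each = r[4] - r[2])
    cols <- rep((r[2] + 1L):r[4], times = r[3] - r[1])
  } else if (g$type == "polygon") {
    v <- g$vertices
    if (min(v[, 1]) < 0 || min(v[, 2]) < 0 || max(v[, 1]) > nr - 1 ||
        max(v[, 2]) > nc - 1)
      stop_input("ROI '%s': polygon outside image bounds", spec$roi_id)
    rr <- floor(min(v[, 1])):ceiling(max(v[, 1]))
    cc <- floor(min(v[, 2])):ceiling(max(v[, 2]))
    grid_r <- rep(rr, times = length(cc))
    grid_c <- rep(cc, each = length(rr))
    inside <- sp::point.in.polygon(grid_c, grid_r, v[, 2], v[, 1]) > 0
    rows <- grid_r[inside] + 1L
    cols <- grid_c[inside] + 1L
    o <- order(rows, cols)
    rows <- rows[o]; cols <- cols[o]
  } else {
    m <- g$mask
    if (!identical(dim(m), dim(image$pixels)))
      stop_input("ROI '%s': mask dimensions %s do not match image %s",
                 spec$roi_id, paste(dim(m), collapse = "x"),
                 paste(c(nr, nc), collapse = "x"))
    idx <- which(t(m)) # row-major order
    rows <- (idx - 1L) %/% nc + 1L
    cols <- (idx - 1L) %% nc + 1L
  }
  n <- length(rows)
  if (n == 0L) stop_input("ROI '%s' resolves to zero pixels", spec$roi_id)
  if (!is.na(protocol_pixels) && n != protocol_pixels)
    warning(sprintf("ROI '%s' has %d pixels; measurement protocol expects %d",
                    spec$roi_id, n, protocol_pixels), call. = FALSE)
  structure(list(rows = as.integer(rows), cols = as.integer(cols), n = n,
                 roi_id = spec$roi_id, label = spec$label,
                 timepoint = spec$timepoint),
            class = "roi_pixels")
}

#' Read / write ROI sidecar files
#'
#' ROI specifications travel with each radiograph as a JSON sidecar: an array
#' of objects `{roi_id, label, timepoint, rect | mask_path}` with `rect` in
#' 0-based half-open `[r0, c0, r1, c1]` convention. Polygon geometries are
#' stored as a `polygon` field of `[row, col]` vertex pairs.
#'
#' @param path JSON file path.
#' @return `read_roi_specs()`: a list of [roi_spec()].
#' @export
read_roi_specs <- function(path) {
  if (!file.exists(path)) stop_input("ROI sidecar '%s' does not exist", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(x) {
    if (is.null(x$roi_id)) stop_input("ROI sidecar entry lacks 'roi_id'")
    if (!is.null(x$rect)) {
      roi_spec(x$roi_id, x$label, x$timepoint, rect = unlist(x$rect))
    } else if (!is.null(x$polygon)) {
      roi_spec(x$roi_id, x$label, x$timepoint,
               polygon = do.call(rbind, lapply(x$polygon, unlist)))
    } else if (!is.null(x$mask_path)) {
      m <- read_radiograph(file.path(dirname(path), x$mask_path))
      roi_spec(x$roi_id, x$label, x$timepoint, mask = m$pixels > 0L)
    } else {
      stop_input("ROI sidecar entry '%s' has no geometry", x$roi_id)
    }
  })
}

#' @rdname read_roi_specs
#' @param specs list of [roi_spec()] (rect or polygon geometry).
#' @export
write_roi_specs <- function(specs, path) {
  entries <- lapply(specs, function(s) {
    e <- list(roi_id = s$roi_id, label = s$label, timepoint = s$timepoint)
    if (s$geometry$type == "rect") {
      e$rect <- s$geometry$rect
    } else if (s$geometry$type == "polygon") {
      e$polygon <- unname(apply(s$geometry$vertices, 1L, as.list))
    } else {
      stop_input("mask geometries are referenced by file; write the mask image and a 'mask_path' entry instead")
    }
    e
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
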