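#' Region-of-interest sets
#'
#' An `roi_set` maps region labels (e.g. dentate gyrus/hilus, CA3, CA1, MEC,
#' LEC) to pixel masks within a frame. Regions may be supplied as boolean
#' masks or as polygons in pixel coordinates; polygons are rasterized with
#' the even-odd rule, a pixel belonging to the region when its center lies
#' inside the polygon (the ImageJ convention). Pixel coordinates are 0-based
#' `(row, col)`; polygon vertices are `(x = col, y = row)` corner coordinates.
#'
#' @param rois named list; each element either a logical matrix (mask of the
#'   full frame), or a two-column matrix of polygon vertices `(x, y)`.
#' @param frame_shape integer `(rows, cols)` of the image frames.
#' @return An `roi_set`: named list of logical masks plus `frame_shape`.
#' @export
roi_set <- function(rois, frame_shape) {
  if (is.null(names(rois)) || anyDuplicated(names(rois)) || any(names(rois) == ""))
    stop("ROI labels must be unique and non-empty")
  frame_shape <- as.integer(frame_shape)
  stopifnot(length(frame_shape) == 2L, all(frame_shape >= 1L))
  masks <- lapply(names(rois), function(lab) {
    r <- rois[[lab]]
    if (is.logical(r) && is.matrix(r)) {
      if (!identical(dim(r), frame_shape))
        stop(sprintf("ROI '%s': mask dimensions do not match frame_shape", lab))
      if (!any(r)) stop(sprintf("ROI '%s': mask has no pixels", lab))
      return(r)
    }
    r <- as.matrix(r)
    if (ncol(r) != 2L || nrow(r) < 3L)
      stop(sprintf("ROI '%s': polygon needs >= 3 (x, y) vertices", lab))
    m <- rasterize_polygon(r, frame_shape)
    if (!any(m)) stop(sprintf("ROI '%s': polygon covers no pixel centers", lab))
    m
  })
  names(masks) <- names(rois)
  structure(list(masks = masks, frame_shape = frame_shape), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROIs in %d x %d frame: %s\n", length(x$masks),
              x$frame_shape[1L], x$frame_shape[2L],
              paste(names(x$masks), collapse = ", ")))
  invisible(x)
}

# Even-odd point-in-polygon for pixel centers (x = col + 0.5, y = row + 0.5),
# restricted to the polygon's bounding box for speed.
rasterize_polygon <- function(poly, frame_shape) {
  px <- poly[, 1L]
  py <- poly[, 2L]
  mask <- matrix(FALSE, frame_shape[1L], frame_shape[2L])
  rows <- max(0L, floor(min(py))):min(frame_shape[1L] - 1L, ceiling(max(py)))
  cols <- max(0L, floor(min(px))):min(frame_shape[2L] - 1L, ceiling(max(px)))
  if (length(rows) == 0L || length(cols) == 0L) return(mask)
  n <- length(px)
  jprev <- n
  for (r in rows) {
    yc <- r + 0.5
    xc <- cols + 0.5
    inside <- logical(length(xc))
    jprev <- n
    for (j in seq_len(n)) {
      crosses <- (py[j] > yc) != (py[jprev] > yc)
      if (crosses) {
        xint <- (px[jprev] - px[j]) * (yc - py[j]) / (py[jprev] - py[j]) + px[j]
        inside <- xor(inside, xc < xint)
      }
      jprev <- j
    }
    mask[r + 1L, cols + 1L] <- inside
  }
  mask
}

#' Read ImageJ ROI files
#'
#' Parses the binary ImageJ `.roi` format (rectangle, polygon, freehand and
#' traced outlines) and `.zip` archives of such files as written by the
#' ImageJ ROI manager.
#'
#' @param path path to a `.roi` file (or `.zip` for `read_roi_zip()`).
#' @return For `read_imagej_roi()`, a two-column vertex matrix `(x, y)` with
#'   attribute `name`; for `read_roi_zip()`, a named list of such matrices.
#' @export
read_imagej_roi <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 64L || rawToChar(raw[1:4]) != "Iout")
    stop("not an ImageJ ROI file (missing 'Iout' magic)")
  rd_short <- function(off) {
    readBin(raw[(off + 1L):(off + 2L)], "integer", size = 2L, endian = "big")
  }
  type <- as.integer(raw[7L])
  top <- rd_short(8L)
  left <- rd_short(10L)
  bottom <- rd_short(12L)
  right <- rd_short(14L)
  n <- rd_short(16L)
  if (type == 1L) {  # rectangle
    poly <- cbind(x = c(left, right, right, left),
                  y = c(top, top, bottom, bottom))
  } else if (type %in% c(0L, 7L, 8L)) {  # polygon, freehand, traced
    if (n < 3L) stop("polygon ROI with fewer than 3 vertices")
    xs <- readBin(raw[65L:(64L + 2L * n)], "integer", n = n, size = 2L,
                  endian = "big")
    ys <- readBin(raw[(65L + 2L * n):(64L + 4L * n)], "integer", n = n,
                  size = 2L, endian = "big")
    poly <- cbind(x = xs + left, y = ys + top)
  } else {
    stop(sprintf("unsupported ImageJ ROI type %d", type))
  }
  attr(poly, "name") <- sub("\\.roi$", "", basename(path))
  poly
}

#' @rdname read_imagej_roi
#' @export
read_roi_zip <- function(path) {
  exdir <- tempfile("roiset")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  files <- unzip(path, exdir = exdir)
  files <- files[grepl("\\.roi$", files)]
  if (length(files) == 0L) stop("zip archive contains no .roi files")
  polys <- lapply(sort(files), read_imagej_roi)
  names(polys) <- vapply(polys, attr, "", "name")
  polys
}

#' Read an ROI set from a JSON polygon list
#'
#' The JSON document maps region labels to arrays of `[x, y]` vertices.
#'
#' @param path JSON file path.
#' @param frame_shape integer `(rows, cols)`.
#' @return An [roi_set()].
#' @export
read_roi_json <- function(path, frame_shape) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  roi_set(lapply(obj, as.matrix), frame_shape)
}

#' Extract mean-fluorescence traces from an image stack
#'
#' Each trace sample is the mean pixel intensity over the region's mask in
#' one frame; traces are returned in ROI order as raw [fluor_trace()]s.
#'
#' @param stack a TIFF file path, a list of frame matrices, or a 3-D array
#'   `(rows, cols, frames)`.
#' @param rois an [roi_set()] matching the frame shape.
#' @param frame_rate acquisition rate in Hz (default 10).
#' @param drug_onset drug application time in seconds (metadata).
#' @return list of raw `fluor_trace`, one per ROI.
#' @export
extract_roi_traces <- function(stack, rois, frame_rate = 10,
                               drug_onset = NA_real_) {
  stopifnot(inherits(rois, "roi_set"))
  if (is.character(stack)) stack <- tiff::readTIFF(stack, all = TRUE)
  if (is.array(stack) && length(dim(stack)) == 3L) {
    stack <- lapply(seq_len(dim(stack)[3L]), function(i) stack[, , i])
  }
  if (inherits(stack, "matrix")) stack <- list(stack)
  if (length(stack) == 0L) stop("image stack is empty")
  shp <- dim(stack[[1L]])
  if (!identical(as.integer(shp), rois$frame_shape))
    stop(sprintf("frame shape (%d x %d) does not match ROI set (%d x %d)",
                 shp[1L], shp[2L], rois$frame_shape[1L], rois$frame_shape[2L]))
  frames <- vapply(stack, function(f) {
    if (!identical(dim(f), shp)) stop("frames differ in shape")
    TRUE
  }, TRUE)
  stopifnot(all(frames))
  lapply(names(rois$masks), function(lab) {
    m <- rois$masks[[lab]]
    vals <- vapply(stack, function(f) mean(f[m]), 0)
    fluor_trace(vals, frame_rate = frame_rate, kind = "raw", region = lab,
                drug_onset = drug_onset)
  })
}
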