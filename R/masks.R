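#' Parametric tumor-mask stacks
#'
#' Rasterizes a stack of 2D labeled tumor masks (0 = background, 1 = enhanced
#' rim, 2 = necrotic core) from a parametric per-slice geometry, as fixtures
#' for the morphometrics module.  A pixel belongs to a shape iff its center
#' lies inside or on the boundary of the shape; pixel centers sit on the
#' integer grid.
#'
#' Each element of `geometry` describes one slice as a list with fields:
#' \describe{
#'   \item{shape}{`"disk"`, `"ellipse"` or `"multiblob"`.}
#'   \item{center}{`c(row, col)` center (disk/ellipse); defaults to the image
#'     center.}
#'   \item{radius}{outer radius in pixels (disk).}
#'   \item{core_radius}{radius of the concentric necrotic core (disk and
#'     ellipse; default 0 = no core).  Must be smaller than the outer
#'     radius/semi-axes.}
#'   \item{semi_axes}{`c(a, b)` semi-axis lengths (ellipse).}
#'   \item{angle}{rotation of the ellipse major axis in radians,
#'     counter-clockwise from the column axis (default 0).}
#'   \item{blobs}{for `"multiblob"`: a list of `list(center =, radius =)`
#'     disks, all labeled enhanced.}
#' }
#'
#' @param geometry list of per-slice shape specifications (see Details).
#' @param pixel_size pixel edge length in mm (metadata carried into feature
#'   extraction).
#' @param dim image dimensions `c(rows, cols)`.
#' @param seed integer seed (reserved for randomized geometries; the
#'   rasterization itself is deterministic).
#' @return An object of class `mask_stack`: list with `slices` (list of
#'   integer matrices) and `pixel_size`.
#' @examples
#' stk <- generate_mask_stack(list(
#'   list(shape = "disk", center = c(32, 32), radius = 10, core_radius = 6)),
#'   dim = c(64, 64))
#' table(stk$slices[[1]])
#' @export
generate_mask_stack <- function(geometry, pixel_size = 1, dim = c(64L, 64L),
                                seed = 1L) {
  stopifnot(is.list(geometry), length(geometry) >= 1L)
  set.seed(seed)
  slices <- lapply(geometry, rasterize_slice, dim = as.integer(dim))
  structure(list(slices = slices, pixel_size = as.numeric(pixel_size)),
            class = "mask_stack")
}

rasterize_slice <- function(spec, dim) {
  shape <- match.arg(spec$shape, c("disk", "ellipse", "multiblob"))
  rows <- matrix(rep(seq_len(dim[1]), dim[2]), dim[1])
  cols <- matrix(rep(seq_len(dim[2]), each = dim[1]), dim[1])
  m <- matrix(0L, dim[1], dim[2])
  center <- if (is.null(spec$center)) (dim + 1) / 2 else spec$center
  core <- if (is.null(spec$core_radius)) 0 else spec$core_radius
  if (shape == "disk") {
    r <- spec$radius
    if (is.null(r) || r <= 0) stop("disk requires a positive 'radius'")
    if (core >= r)
      stop(sprintf("core radius (%.3g) must be smaller than outer radius (%.3g)",
                   core, r))
    d2 <- (rows - center[1])^2 + (cols - center[2])^2
    m[d2 <= r^2] <- 1L
    if (core > 0) m[d2 <= core^2] <- 2L
  } else if (shape == "ellipse") {
    ax <- spec$semi_axes
    if (is.null(ax) || length(ax) != 2L || any(ax <= 0))
      stop("ellipse requires positive 'semi_axes' = c(a, b)")
    if (core >= min(ax))
      stop("core radius must be smaller than both semi-axes")
    ang <- if (is.null(spec$angle)) 0 else spec$angle
    dr <- rows - center[1]; dc <- cols - center[2]
    # rotate into the ellipse frame (u along the column-axis semi-axis a)
    u <- dc * cos(ang) + dr * sin(ang)
    v <- -dc * sin(ang) + dr * cos(ang)
    m[(u / ax[1])^2 + (v / ax[2])^2 <= 1] <- 1L
    if (core > 0) m[dr^2 + dc^2 <= core^2] <- 2L
  } else {
    if (is.null(spec$blobs) || !length(spec$blobs))
      stop("multiblob requires a non-empty 'blobs' list")
    for (b in spec$blobs) {
      if (b$radius <= 0) stop("blob radius must be > 0")
      d2 <- (rows - b$center[1])^2 + (cols - b$center[2])^2
      m[d2 <= b$radius^2] <- 1L
    }
  }
  m
}

#' @export
print.mask_stack <- function(x, ...) {
  cat(sprintf("Mask stack: %d slice(s), %dx%d px, pixel size %.3g mm\n",
              length(x$slices), nrow(x$slices[[1]]), ncol(x$slices[[1]]),
              x$pixel_size))
  invisible(x)
}

#' Read and write labeled mask slices
#'
#' Masks are stored as 8-bit grayscale PNG (label values 0, 1, 2 stored
#' directly as intensities) or as NIfTI volumes (one slice per file or a
#' 3D volume).
#'
#' @param stack a [generate_mask_stack()] result.
#' @param dir output directory (created if needed).
#' @param format `"png"` or `"nifti"`.
#' @return `write_mask_stack` returns the written file paths invisibly;
#'   `read_mask_stack` returns a `mask_stack`.
#' @export
write_mask_stack <- function(stack, dir, format = c("png", "nifti")) {
  format <- match.arg(format)
  stopifnot(inherits(stack, "mask_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(stack$slices))
  for (i in seq_along(stack$slices)) {
    m <- stack$slices[[i]]
    if (format == "png") {
      paths[i] <- file.path(dir, sprintf("slice_%03d.png", i))
      png::writePNG(m / 255, paths[i])
    } else {
      paths[i] <- file.path(dir, sprintf("slice_%03d.nii.gz", i))
      RNifti::writeNifti(RNifti::asNifti(m, pixdim = rep(stack$pixel_size, 2)),
                         paths[i])
    }
  }
  invisible(paths)
}

#' @rdname write_mask_stack
#' @param files character vector of PNG or NIfTI mask files, in slice order.
#' @param pixel_size pixel size in mm attached to the stack.
#' @export
read_mask_stack <- function(files, pixel_size = 1) {
  slices <- lapply(files, function(f) {
    if (grepl("\\.png$", f, ignore.case = TRUE)) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3L) img <- img[, , 1]
      m <- round(img * 255)
    } else {
      m <- as.array(RNifti::readNifti(f))
      if (length(dim(m)) > 2L) m <- m[, , 1]
    }
    storage.mode(m) <- "integer"
    bad <- setdiff(unique(as.vector(m)), c(0L, 1L, 2L))
    if (length(bad))
      stop("mask labels must be 0/1/2; found: ", paste(bad, collapse = ", "))
    m
  })
  if (length(unique(lapply(slices, dim))) != 1L)
    stop("all mask slices must have identical dimensions")
  structure(list(slices = slices, pixel_size = as.numeric(pixel_size)),
            class = "mask_stack")
}
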