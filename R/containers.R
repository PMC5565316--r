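## Lightweight S3 containers for the imaging data the pipeline moves around.

#' Construct a calcium time-lapse movie
#'
#' @param frames numeric T x Y x X array of raw intensities (arbitrary
#'   units, finite and non-negative).
#' @param frame_interval_s seconds between frames.
#' @param pixel_size_um lateral pixel size in micrometres.
#' @param stimulus_windows data.frame with columns `label`, `start_s`,
#'   `end_s` (half-open `[start, end)` in seconds). Labels are free text;
#'   `highK`, `DMPP` and `ES` are the conventional ones.
#' @return object of class `calcium_movie`.
#' @export
calcium_movie <- function(frames, frame_interval_s, pixel_size_um = 1,
                          stimulus_windows = NULL) {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (dim(frames)[1] < 2) stop("movie needs at least 2 frames")
  if (!all(is.finite(frames)) || any(frames < 0))
    stop("intensities must be finite and >= 0")
  stopifnot(frame_interval_s > 0, pixel_size_um > 0)
  dur <- dim(frames)[1] * frame_interval_s
  if (!is.null(stimulus_windows)) {
    stopifnot(is.data.frame(stimulus_windows),
              all(c("label", "start_s", "end_s") %in% names(stimulus_windows)))
    with(stimulus_windows, stopifnot(all(start_s >= 0), all(end_s > start_s),
                                     all(end_s <= dur)))
  }
  structure(list(frames = frames, frame_interval_s = frame_interval_s,
                 pixel_size_um = pixel_size_um,
                 stimulus_windows = stimulus_windows, registered = FALSE),
            class = "calcium_movie")
}

#' @export
print.calcium_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<calcium_movie> %d frames of %d x %d px, %.3g s/frame%s\n",
              d[1], d[2], d[3], x$frame_interval_s,
              if (isTRUE(x$registered)) ", registered" else ""))
  if (!is.null(x$stimulus_windows))
    cat(sprintf("  stimuli: %s\n",
                paste(sprintf("%s [%g, %g)s", x$stimulus_windows$label,
                              x$stimulus_windows$start_s,
                              x$stimulus_windows$end_s), collapse = "; ")))
  invisible(x)
}

#' Construct a neuron region of interest
#'
#' A ROI is a set of pixels (0-based `(y, x)` indices) drawn over one soma.
#'
#' @param id ROI identifier (coerced to character).
#' @param pixels two-column matrix of 0-based `(y, x)` pixel indices.
#' @return object of class `neuron_roi`.
#' @export
neuron_roi <- function(id, pixels) {
  pixels <- as.matrix(pixels)
  stopifnot(ncol(pixels) == 2, nrow(pixels) >= 1, all(pixels >= 0),
            all(pixels == floor(pixels)))
  structure(list(id = as.character(id), pixels = pixels), class = "neuron_roi")
}

#' Circular ROI helper
#'
#' @param id ROI identifier.
#' @param cy,cx centre in 0-based pixel coordinates.
#' @param radius_px radius in pixels.
#' @param shape_yx image extent `c(Y, X)` used to clip the disc.
#' @export
disc_roi <- function(id, cy, cx, radius_px, shape_yx) {
  ys <- max(0, floor(cy - radius_px)):min(shape_yx[1] - 1, ceiling(cy + radius_px))
  xs <- max(0, floor(cx - radius_px)):min(shape_yx[2] - 1, ceiling(cx + radius_px))
  g <- expand.grid(y = ys, x = xs)
  g <- g[(g$y - cy)^2 + (g$x - cx)^2 <= radius_px^2, , drop = FALSE]
  if (nrow(g) == 0) stop("empty ROI after clipping to image bounds")
  neuron_roi(id, as.matrix(g))
}

#' Construct a 3D (optionally time-resolved) mitochondrial stack
#'
#' @param voxels numeric Z x Y x X or T x Z x Y x X intensity array.
#' @param voxel_size_um voxel size `c(z, y, x)` in micrometres.
#' @param frame_interval_s seconds between volumes (required when T > 1).
#' @return object of class `mito_stack`.
#' @export
mito_stack <- function(voxels, voxel_size_um, frame_interval_s = NA_real_) {
  nd <- length(dim(voxels))
  stopifnot(is.array(voxels), nd %in% c(3, 4), all(is.finite(voxels)))
  stopifnot(length(voxel_size_um) == 3, all(voxel_size_um > 0))
  if (nd == 4 && dim(voxels)[1] > 1 && !is.finite(frame_interval_s))
    stop("frame_interval_s required for a time-resolved stack")
  structure(list(voxels = voxels, voxel_size_um = as.numeric(voxel_size_um),
                 frame_interval_s = frame_interval_s),
            class = "mito_stack")
}

#' @export
print.mito_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<mito_stack> [%s] voxels, voxel %.3g x %.3g x %.3g um\n",
              paste(d, collapse = " x "), x$voxel_size_um[1],
              x$voxel_size_um[2], x$voxel_size_um[3]))
  invisible(x)
}

#' Number of time points of a mito stack (1 for a plain 3D stack)
#' @noRd
stack_nt <- function(stack) {
  d <- dim(stack$voxels)
  if (length(d) == 4) d[1] else 1L
}

#' Extract volume at time t from a 3D/4D stack as a Z x Y x X array
#' @noRd
stack_frame <- function(stack, t = 1L) {
  d <- dim(stack$voxels)
  if (length(d) == 3) {
    if (t != 1L) stop("stack has a single time point")
    return(stack$voxels)
  }
  array(stack$voxels[t, , , ], dim = d[-1])
}

#' Construct a ganglion mask
#'
#' Binary Z x Y x X volume delimiting the ganglion within which mitochondria
#' are counted; its volume in um^3 follows from the voxel size.
#'
#' @param mask logical (or 0/1) Z x Y x X array.
#' @param voxel_size_um voxel size `c(z, y, x)` in micrometres.
#' @export
ganglion_mask <- function(mask, voxel_size_um) {
  mask <- array(as.logical(mask), dim = dim(mask))
  stopifnot(length(dim(mask)) == 3, length(voxel_size_um) == 3,
            all(voxel_size_um > 0))
  if (!any(mask)) stop("ganglion mask is empty")
  structure(list(mask = mask, voxel_size_um = as.numeric(voxel_size_um),
                 volume_um3 = sum(mask) * prod(voxel_size_um)),
            class = "ganglion_mask")
}

#' Ellipsoidal ganglion mask from centre and radii in micrometres
#'
#' @param dims_zyx array extent in voxels `c(Z, Y, X)`.
#' @param centre_um,radii_um ellipsoid centre and semi-axes, `c(z, y, x)` um.
#' @param voxel_size_um voxel size `c(z, y, x)` in micrometres.
#' @export
ellipsoid_mask <- function(dims_zyx, centre_um, radii_um, voxel_size_um) {
  stopifnot(all(radii_um > 0))
  zc <- ((seq_len(dims_zyx[1]) - 0.5) * voxel_size_um[1] - centre_um[1]) / radii_um[1]
  yc <- ((seq_len(dims_zyx[2]) - 0.5) * voxel_size_um[2] - centre_um[2]) / radii_um[2]
  xc <- ((seq_len(dims_zyx[3]) - 0.5) * voxel_size_um[3] - centre_um[3]) / radii_um[3]
  m <- outer(outer(zc^2, yc^2, `+`), xc^2, `+`) <= 1
  ganglion_mask(m, voxel_size_um)
}
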