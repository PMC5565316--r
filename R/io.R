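## Readers and writers: multi-page 16-bit TIFF images with a JSON metadata
## sidecar (voxel sizes, axis order, frame interval), OME-XML PhysicalSize
## parsing for externally produced OME-TIFFs, ROI label masks and polygon
## JSON, stimulus-protocol YAML, CSV/JSON outputs.

#' Write an image array as multi-page 16-bit TIFF with a metadata sidecar
#'
#' Axis order is `(t, y, x)`, `(z, y, x)` or `(t, z, y, x)`; leading axes
#' are flattened into TIFF pages (t-major). Values are rounded and clipped
#' to the 16-bit range, so integer-valued arrays round-trip bit-identically
#' through [read_image()]. A `<path>.json` sidecar records the dimensions,
#' axes and physical metadata.
#'
#' @param x numeric array (3D or 4D).
#' @param path output TIFF path.
#' @param axes axis string, one of `"tyx"`, `"zyx"`, `"tzyx"`.
#' @param pixel_size_um lateral pixel size (2D+t movies).
#' @param voxel_size_um `(z, y, x)` voxel size (3D stacks).
#' @param frame_interval_s seconds per frame where applicable.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path, axes = c("tyx", "zyx", "tzyx"),
                        pixel_size_um = NULL, voxel_size_um = NULL,
                        frame_interval_s = NULL) {
  axes <- match.arg(axes)
  d <- dim(x)
  stopifnot(length(d) == nchar(axes))
  npages <- prod(d[-c(length(d) - 1, length(d))])
  pages <- vector("list", npages)
  k <- 0L
  if (length(d) == 3) {
    for (i in seq_len(d[1])) {
      k <- k + 1L
      pages[[k]] <- pmin(pmax(round(x[i, , ]), 0), 65535) / 65535
    }
  } else {
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      k <- k + 1L
      pages[[k]] <- pmin(pmax(round(x[i, j, , ]), 0), 65535) / 65535
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "deflate")
  meta <- list(axes = axes, dim = as.integer(d),
               pixel_size_um = pixel_size_um, voxel_size_um = voxel_size_um,
               frame_interval_s = frame_interval_s)
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @noRd
parse_ome_physical_sizes <- function(desc) {
  if (is.null(desc) || !nzchar(desc) || !grepl("<OME", desc, fixed = TRUE))
    return(NULL)
  if (!requireNamespace("xml2", quietly = TRUE)) return(NULL)
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  px <- xml2::xml_find_first(doc, "//*[local-name()='Pixels']")
  if (inherits(px, "xml_missing")) return(NULL)
  g <- function(a) {
    v <- xml2::xml_attr(px, a)
    if (is.na(v)) NA_real_ else as.numeric(v)
  }
  list(PhysicalSizeX = g("PhysicalSizeX"), PhysicalSizeY = g("PhysicalSizeY"),
       PhysicalSizeZ = g("PhysicalSizeZ"), SizeZ = g("SizeZ"), SizeT = g("SizeT"))
}

#' Read a TIFF/OME-TIFF image with physical metadata
#'
#' Pages are reassembled into `(t, y, x)` / `(z, y, x)` / `(t, z, y, x)`
#' order using, in priority: the JSON sidecar written by [write_image()];
#' OME-XML in the ImageDescription (PhysicalSizeX/Y/Z, SizeZ/SizeT); or the
#' explicit arguments. Missing pixel-size metadata without an explicit
#' override is an error.
#'
#' @param path TIFF path.
#' @param expected_ndim 3 or 4.
#' @param axes axis interpretation when only page count is known.
#' @param pixel_size_um,voxel_size_um,frame_interval_s explicit overrides.
#' @return list: `data` (numeric array, integer-valued for 16-bit input),
#'   `axes`, `pixel_size_um`, `voxel_size_um`, `frame_interval_s`,
#'   `metadata_source`.
#' @export
read_image <- function(path, expected_ndim = 3, axes = NULL,
                       pixel_size_um = NULL, voxel_size_um = NULL,
                       frame_interval_s = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  npages <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  meta <- NULL; source <- "arguments"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    source <- "sidecar"
  } else {
    ome <- parse_ome_physical_sizes(attr(pages[[1]], "description"))
    if (!is.null(ome)) {
      source <- "ome-xml"
      vz <- if (is.finite(ome$PhysicalSizeZ)) ome$PhysicalSizeZ else NA_real_
      vy <- if (is.finite(ome$PhysicalSizeY)) ome$PhysicalSizeY else NA_real_
      vx <- if (is.finite(ome$PhysicalSizeX)) ome$PhysicalSizeX else NA_real_
      meta <- list(voxel_size_um = c(vz, vy, vx), pixel_size_um = vx)
      if (is.finite(ome$SizeZ) && is.finite(ome$SizeT) &&
          ome$SizeZ * ome$SizeT == npages)
        meta$dim <- c(ome$SizeT, ome$SizeZ, ny, nx)
    }
  }
  if (!is.null(meta$axes) && is.null(axes)) axes <- meta$axes
  if (is.null(axes)) axes <- if (expected_ndim == 4) "tzyx" else "zyx"
  dims <- if (!is.null(meta$dim)) as.integer(meta$dim)
          else if (nchar(axes) == 3) c(npages, ny, nx)
          else stop("4D image needs sidecar/OME dimension metadata")
  if (prod(dims[-c(length(dims) - 1, length(dims))]) != npages ||
      dims[length(dims) - 1] != ny || dims[length(dims)] != nx)
    stop("page count does not match recorded dimensions")
  if (length(dims) != expected_ndim)
    stop(sprintf("expected a %dD image, file is %dD", expected_ndim, length(dims)))
  arr <- array(0, dim = dims)
  k <- 0L
  if (length(dims) == 3) {
    for (i in seq_len(dims[1])) { k <- k + 1L; arr[i, , ] <- pages[[k]] }
  } else {
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
      k <- k + 1L; arr[i, j, , ] <- pages[[k]]
    }
  }
  px <- pixel_size_um %||% meta$pixel_size_um
  vx <- voxel_size_um %||% meta$voxel_size_um
  fi <- frame_interval_s %||% meta$frame_interval_s
  needs_voxel <- substr(axes, 1, 1) == "z" || nchar(axes) == 4
  if (needs_voxel && (is.null(vx) || any(!is.finite(vx))))
    stop("no voxel size metadata; pass voxel_size_um explicitly")
  if (!needs_voxel && (is.null(px) || !is.finite(px)))
    stop("no pixel size metadata; pass pixel_size_um explicitly")
  list(data = arr, axes = axes, pixel_size_um = px, voxel_size_um = vx,
       frame_interval_s = fi, metadata_source = source)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' ROIs from a label-mask matrix (0 = background)
#'
#' @param mask integer matrix; each positive label becomes one ROI.
#' @return list of [neuron_roi()].
#' @export
rois_from_label_mask <- function(mask) {
  labs <- sort(unique(mask[mask > 0]))
  if (length(labs) == 0) stop("label mask contains no ROIs")
  lapply(labs, function(l) {
    w <- which(mask == l, arr.ind = TRUE)
    neuron_roi(sprintf("n%03d", l), cbind(w[, 1] - 1L, w[, 2] - 1L))
  })
}

#' ROIs from polygon JSON
#'
#' Expects a JSON array of objects `{id, y: [...], x: [...]}` with polygon
#' vertices in 0-based pixel coordinates; pixels whose centres fall inside
#' the polygon (even-odd rule) form the ROI.
#'
#' @param path JSON file.
#' @param shape_yx image extent `c(Y, X)`.
#' @export
rois_from_polygon_json <- function(path, shape_yx) {
  polys <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(polys)) polys <- split(polys, seq_len(nrow(polys)))
  lapply(polys, function(p) {
    py <- unlist(p$y); px <- unlist(p$x)
    stopifnot(length(py) == length(px), length(py) >= 3)
    ys <- floor(min(py)):ceiling(max(py))
    xs <- floor(min(px)):ceiling(max(px))
    g <- expand.grid(y = ys, x = xs)
    inside <- point_in_polygon(g$y, g$x, py, px)
    g <- g[inside & g$y >= 0 & g$x >= 0 & g$y < shape_yx[1] & g$x < shape_yx[2], ]
    neuron_roi(as.character(p$id %||% "roi"), as.matrix(g))
  })
}

#' Even-odd rule point-in-polygon test (vectorised over points)
#' @noRd
point_in_polygon <- function(py, px, vy, vx) {
  n <- length(vy)
  inside <- rep(FALSE, length(py))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Read a stimulus protocol YAML
#'
#' Accepts a YAML list of `{label, start_s, end_s}` entries (or a top-level
#' `stimuli:` key holding one).
#'
#' @param path YAML file.
#' @return data.frame with `label`, `start_s`, `end_s`.
#' @export
read_protocol <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$stimuli)) y <- y$stimuli
  if (length(y) == 0) stop("protocol contains no stimuli")
  out <- do.call(rbind, lapply(y, function(s) {
    stopifnot(!is.null(s$label), !is.null(s$start_s), !is.null(s$end_s))
    data.frame(label = s$label, start_s = as.numeric(s$start_s),
               end_s = as.numeric(s$end_s), stringsAsFactors = FALSE)
  }))
  if (any(out$end_s <= out$start_s)) stop("stimulus end must be after start")
  out
}

#' Write a data.frame as UTF-8 CSV (no row names)
#' @noRd
write_csv_out <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
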