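## Array numerics shared by the simulators and detectors.
## All image arrays follow (t, y, x) / (z, y, x) / (t, z, y, x) axis order,
## 0-based pixel coordinate convention at the user surface (converted to R's
## 1-based indexing internally).

#' @noRd
fft_freq_index <- function(n) {
  ## frequency index vector 0,1,...,floor(n/2),-ceil(n/2)+1,...,-1
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  if (n == 1L) k <- 0
  k
}

#' @noRd
gaussian_kernel_fft <- function(dims, sigma_vox) {
  ## FFT of a periodised, normalised Gaussian with per-axis sigma in voxels.
  ## Separable: product of per-axis 1D kernels evaluated on the circular grid.
  stopifnot(length(dims) == length(sigma_vox))
  axes <- lapply(seq_along(dims), function(a) {
    n <- dims[a]; s <- sigma_vox[a]
    d <- fft_freq_index(n)  # signed circular distance from origin
    if (s <= 0) {
      k <- as.numeric(d == 0)
    } else {
      k <- exp(-d^2 / (2 * s^2))
      k <- k / sum(k)
    }
    fft(k)
  })
  out <- axes[[1]]
  if (length(dims) > 1) {
    for (a in 2:length(dims)) out <- outer(out, axes[[a]])
  }
  array(out, dim = dims)
}

#' Gaussian blur of a 2D or 3D array via FFT (circular boundary)
#'
#' @param x numeric array.
#' @param sigma_vox per-axis standard deviation in voxels (recycled).
#' @return blurred array, same dimensions.
#' @noRd
gaussian_blur <- function(x, sigma_vox) {
  d <- dim(x)
  sigma_vox <- rep(sigma_vox, length.out = length(d))
  if (all(sigma_vox <= 0)) return(x)
  kf <- gaussian_kernel_fft(d, sigma_vox)
  out <- Re(fft(fft(x) * kf, inverse = TRUE)) / prod(d)
  array(out, dim = d)
}

#' Translate a 2D image by a (possibly fractional) shift with edge padding
#'
#' Samples `img` at (y - dy, x - dx) using bilinear interpolation; positions
#' outside the frame take the nearest edge value.
#' @noRd
shift_image_2d <- function(img, dy, dx) {
  ny <- nrow(img); nx <- ncol(img)
  ys <- seq_len(ny) - dy
  xs <- seq_len(nx) - dx
  y0 <- floor(ys); x0 <- floor(xs)
  wy <- ys - y0; wx <- xs - x0
  cl <- function(i, n) pmin(pmax(i, 1L), n)
  y0c <- cl(y0, ny); y1c <- cl(y0 + 1, ny)
  x0c <- cl(x0, nx); x1c <- cl(x0 + 1, nx)
  a <- img[y0c, x0c, drop = FALSE]; b <- img[y0c, x1c, drop = FALSE]
  c_ <- img[y1c, x0c, drop = FALSE]; d <- img[y1c, x1c, drop = FALSE]
  top <- a * rep(1 - wx, each = ny) + b * rep(wx, each = ny)
  bot <- c_ * rep(1 - wx, each = ny) + d * rep(wx, each = ny)
  top * (1 - wy) + bot * wy
}

#' Linear voxel indices of all 26-connected neighbour pairs among foreground
#' voxels of a 3D logical mask. Returns a 2-column matrix of linear indices.
#' @noRd
adjacency_pairs_26 <- function(mask) {
  d <- dim(mask)
  idx <- array(0L, dim = d)
  fg <- which(mask)
  idx[fg] <- seq_along(fg)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[offs$dx > 0 | (offs$dx == 0 & offs$dy > 0) |
                 (offs$dx == 0 & offs$dy == 0 & offs$dz > 0), ]  # half-space
  coord <- arrayInd(fg, d)
  pairs <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    z2 <- coord[, 1] + offs$dz[i]
    y2 <- coord[, 2] + offs$dy[i]
    x2 <- coord[, 3] + offs$dx[i]
    ok <- z2 >= 1 & z2 <= d[1] & y2 >= 1 & y2 <= d[2] & x2 >= 1 & x2 <= d[3]
    if (!any(ok)) next
    lin2 <- z2[ok] + (y2[ok] - 1L) * d[1] + (x2[ok] - 1L) * d[1] * d[2]
    j2 <- idx[lin2]
    keep <- j2 > 0L
    if (!any(keep)) next
    pairs[[i]] <- cbind(idx[fg[ok]][keep], j2[keep])
  }
  do.call(rbind, pairs)
}

#' Label 26-connected components of a 3D logical mask
#'
#' @return integer array of component labels (0 = background).
#' @noRd
label_components_26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  fg <- which(mask)
  if (length(fg) == 0) return(lab)
  pr <- adjacency_pairs_26(mask)
  if (is.null(pr) || nrow(pr) == 0) {
    lab[fg] <- seq_along(fg)
    return(lab)
  }
  g <- igraph::make_graph(t(pr), n = length(fg), directed = FALSE)
  comp <- igraph::components(g)
  lab[fg] <- comp$membership
  lab
}

#' 3D local maxima (26-neighbourhood, strict against at least one neighbour,
#' >= against the rest) of an array, returned as linear indices.
#' @noRd
local_maxima_3d <- function(x, mask = NULL) {
  d <- dim(x)
  big <- -Inf
  is_max <- array(TRUE, dim = d)
  pad_get <- function(dz, dy, dx) {
    out <- array(big, dim = d)
    zs <- seq_len(d[1]) + dz; ys <- seq_len(d[2]) + dy; xs <- seq_len(d[3]) + dx
    okz <- zs >= 1 & zs <= d[1]; oky <- ys >= 1 & ys <= d[2]; okx <- xs >= 1 & xs <= d[3]
    out[okz, oky, okx] <- x[zs[okz], ys[oky], xs[okx], drop = FALSE]
    out
  }
  tie_lower <- array(FALSE, dim = d)  # a neighbour strictly exceeds, or equal with lower linear index wins
  lin <- array(seq_len(prod(d)), dim = d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    nb <- pad_get(dz, dy, dx)
    is_max <- is_max & (x >= nb)
    ## deterministic tie-break: among equal-valued plateau voxels keep the
    ## smallest linear index
    nb_lin <- array(Inf, dim = d)
    zs <- seq_len(d[1]) + dz; ys <- seq_len(d[2]) + dy; xs <- seq_len(d[3]) + dx
    okz <- zs >= 1 & zs <= d[1]; oky <- ys >= 1 & ys <= d[2]; okx <- xs >= 1 & xs <= d[3]
    nb_lin[okz, oky, okx] <- lin[zs[okz], ys[oky], xs[okx], drop = FALSE]
    tie_lower <- tie_lower | (nb == x & nb_lin < lin)
  }
  keep <- is_max & !tie_lower
  if (!is.null(mask)) keep <- keep & mask
  which(keep)
}

#' Split a labelled component among seed voxels by descending-intensity
#' region growing (marker-based watershed). `vox` are linear indices of the
#' component's voxels, `seeds` linear indices of markers inside it.
#' @return integer vector, one seed id per voxel of `vox`.
#' @noRd
flood_split <- function(vox, seeds, intensity, dims) {
  nv <- length(vox)
  pos <- match(seeds, vox)
  lab <- integer(nv)
  lab[pos] <- seq_along(seeds)
  coord <- arrayInd(vox, dims)
  ## local adjacency among component voxels
  key <- function(zyx) zyx[, 1] + (zyx[, 2] - 1) * dims[1] +
    (zyx[, 3] - 1) * dims[1] * dims[2]
  lookup <- new.env(hash = TRUE, size = nv)
  for (i in seq_len(nv)) assign(as.character(vox[i]), i, envir = lookup)
  neigh <- function(i) {
    out <- integer(0)
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      z <- coord[i, 1] + dz; y <- coord[i, 2] + dy; x <- coord[i, 3] + dx
      if (z < 1 || z > dims[1] || y < 1 || y > dims[2] || x < 1 || x > dims[3]) next
      j <- lookup[[as.character(z + (y - 1) * dims[1] + (x - 1) * dims[1] * dims[2])]]
      if (!is.null(j)) out <- c(out, j)
    }
    out
  }
  ord <- order(-intensity[vox], vox)
  ## repeated sweeps in descending-intensity order: an unlabelled voxel takes
  ## the label of its brightest already-labelled neighbour (ties: lower index)
  repeat {
    changed <- FALSE
    for (i in ord) {
      if (lab[i] > 0L) next
      nb <- neigh(i)
      nb <- nb[lab[nb] > 0L]
      if (length(nb) > 0) {
        best <- nb[order(-intensity[vox[nb]], vox[nb])][1]
        lab[i] <- lab[best]
        changed <- TRUE
      }
    }
    if (!changed || all(lab > 0L)) break
  }
  lab[lab == 0L] <- 1L  # unreachable voxels (shouldn't occur) to first seed
  lab
}
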