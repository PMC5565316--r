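## Synthetic TMRE stacks: ellipsoidal mitochondria scattered inside a
## ganglion ellipsoid, each with a mean-reverting (Ornstein-Uhlenbeck)
## temporal intensity modulation, blurred with a Gaussian PSF over a
## constant background and bleached multiplicatively with frame 1 brightest.

#' Parameters for the synthetic mitochondrial stack generator
#'
#' Defaults describe a spinning-disk TMRE acquisition: anisotropic voxels of
#' 0.5 x 0.25 x 0.25 um, mitochondria of ~0.8 um radius, 10% temporal
#' coefficient of variation with a correlation time of two frames, 16-bit
#' counts.
#'
#' @param n_mito number of mitochondria.
#' @param mito_radii_mean_um,mito_radii_sd_um per-axis `(z, y, x)` ellipsoid
#'   semi-axis mean and SD in um (Gaussian, truncated at `min_radius_um`).
#' @param min_radius_um lower truncation for drawn radii.
#' @param base_intensity mean mitochondrial intensity, arbitrary units.
#' @param fluctuation_cv_pct temporal coefficient of variation of each
#'   mitochondrion's intensity, percent (0 = static).
#' @param fluctuation_tau_s correlation time of the mean-reverting
#'   fluctuation process, seconds.
#' @param psf_sigma_um per-axis `(z, y, x)` Gaussian PSF sigma in um.
#' @param background_level constant background, arbitrary units.
#' @param bleach_rate_per_frame fractional intensity loss per frame; frame 1
#'   is always the brightest.
#' @param voxel_size_um voxel size `(z, y, x)` in um.
#' @param shape_vox array extent `(T, Z, Y, X)`; T = 1 gives a plain 3D stack.
#' @param ganglion_centre_um,ganglion_radii_um ganglion ellipsoid centre and
#'   semi-axes in um (default: centred, 90% of the half-extent).
#' @param min_separation_um minimum distance between mitochondrion centres.
#' @param frame_interval_s seconds between volumes.
#' @param seed integer seed; identical parameters and seed give bit-identical
#'   output.
#' @export
mito_sim_params <- function(n_mito = 100,
                            mito_radii_mean_um = c(0.8, 0.8, 0.8),
                            mito_radii_sd_um = c(0.15, 0.15, 0.15),
                            min_radius_um = 0.3,
                            base_intensity = 8000,
                            fluctuation_cv_pct = 10,
                            fluctuation_tau_s = 10,
                            psf_sigma_um = c(0.4, 0.15, 0.15),
                            background_level = 100,
                            bleach_rate_per_frame = 0.01,
                            voxel_size_um = c(0.5, 0.25, 0.25),
                            shape_vox = c(1, 32, 128, 128),
                            ganglion_centre_um = NULL,
                            ganglion_radii_um = NULL,
                            min_separation_um = 3.5,
                            frame_interval_s = 30,
                            seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$n_mito >= 1, length(p$shape_vox) == 4, all(p$shape_vox >= 1),
            all(p$voxel_size_um > 0), all(p$psf_sigma_um >= 0),
            all(p$mito_radii_mean_um > 0), all(p$mito_radii_sd_um >= 0),
            p$base_intensity > 0, p$fluctuation_cv_pct >= 0,
            p$fluctuation_tau_s > 0, p$background_level >= 0,
            p$bleach_rate_per_frame >= 0, p$bleach_rate_per_frame < 1,
            p$frame_interval_s > 0)
  ext <- p$shape_vox[2:4] * p$voxel_size_um
  if (is.null(p$ganglion_centre_um)) p$ganglion_centre_um <- ext / 2
  if (is.null(p$ganglion_radii_um)) p$ganglion_radii_um <- 0.45 * ext
  stopifnot(all(p$ganglion_radii_um > 0))
  structure(p, class = "mito_sim_params")
}

#' @noRd
place_mito_centres <- function(p) {
  inside <- function(z, y, x, shrink) {
    sum(((c(z, y, x) - p$ganglion_centre_um) /
           pmax(p$ganglion_radii_um - shrink, 1e-6))^2) <= 1
  }
  shrink <- max(p$mito_radii_mean_um)  # keep bodies inside the ganglion
  ctr <- matrix(NA_real_, p$n_mito, 3)
  n_placed <- 0L; tries <- 0L
  lo <- p$ganglion_centre_um - p$ganglion_radii_um
  hi <- p$ganglion_centre_um + p$ganglion_radii_um
  while (n_placed < p$n_mito) {
    z <- runif(1, lo[1], hi[1]); y <- runif(1, lo[2], hi[2]); x <- runif(1, lo[3], hi[3])
    ok <- inside(z, y, x, shrink)
    if (ok && n_placed > 0) {
      d2 <- (ctr[seq_len(n_placed), 1] - z)^2 + (ctr[seq_len(n_placed), 2] - y)^2 +
        (ctr[seq_len(n_placed), 3] - x)^2
      ok <- all(d2 > p$min_separation_um^2)
    }
    if (ok) { n_placed <- n_placed + 1L; ctr[n_placed, ] <- c(z, y, x) }
    tries <- tries + 1L
    if (tries > 20000L * p$n_mito)
      stop(sprintf("cannot place %d mitochondria %g um apart inside the ganglion",
                   p$n_mito, p$min_separation_um))
  }
  colnames(ctr) <- c("z_um", "y_um", "x_um")
  ctr
}

#' Simulate a TMRE mitochondrial stack with ground truth
#'
#' @param params a [mito_sim_params()] object.
#' @return list with
#'   \describe{
#'     \item{stack}{a [mito_stack()] (3D when T = 1, else 4D).}
#'     \item{mask}{the ganglion [ellipsoid_mask()].}
#'     \item{truth}{list: `mito` data.frame (`id`, centre um, drawn radii,
#'       `volume_um3` of the rasterised body, `n_voxels`), and
#'       `frame_intensity`, a T x n matrix of each mitochondrion's true mean
#'       intensity per frame (bleach x fluctuation x base).}
#'   }
#' @examples
#' sim <- simulate_mito_stack(mito_sim_params(n_mito = 5, seed = 3,
#'   shape_vox = c(1, 16, 48, 48)))
#' sim$truth$mito
#' @export
simulate_mito_stack <- function(params) {
  stopifnot(inherits(params, "mito_sim_params"))
  p <- params
  with_seed(p$seed, {
    nt <- p$shape_vox[1]; dz <- p$shape_vox[2]; dy <- p$shape_vox[3]; dx <- p$shape_vox[4]
    ctr <- place_mito_centres(p)
    radii <- matrix(NA_real_, p$n_mito, 3)
    for (a in 1:3) {
      r <- rnorm(p$n_mito, p$mito_radii_mean_um[a], p$mito_radii_sd_um[a])
      while (any(r < p$min_radius_um))
        r[r < p$min_radius_um] <- rnorm(sum(r < p$min_radius_um),
                                        p$mito_radii_mean_um[a], p$mito_radii_sd_um[a])
      radii[, a] <- r
    }
    ## rasterise each ellipsoid: linear voxel indices into a Z x Y x X volume
    vox_ctr <- function(n, vs) (seq_len(n) - 0.5) * vs
    zc <- vox_ctr(dz, p$voxel_size_um[1])
    yc <- vox_ctr(dy, p$voxel_size_um[2])
    xc <- vox_ctr(dx, p$voxel_size_um[3])
    vox_vol <- prod(p$voxel_size_um)
    idx_list <- vector("list", p$n_mito)
    for (i in seq_len(p$n_mito)) {
      zr <- which(abs(zc - ctr[i, 1]) <= radii[i, 1])
      yr <- which(abs(yc - ctr[i, 2]) <= radii[i, 2])
      xr <- which(abs(xc - ctr[i, 3]) <= radii[i, 3])
      if (!length(zr) || !length(yr) || !length(xr)) { idx_list[[i]] <- integer(0); next }
      g <- expand.grid(z = zr, y = yr, x = xr)
      keep <- ((zc[g$z] - ctr[i, 1]) / radii[i, 1])^2 +
        ((yc[g$y] - ctr[i, 2]) / radii[i, 2])^2 +
        ((xc[g$x] - ctr[i, 3]) / radii[i, 3])^2 <= 1
      g <- g[keep, , drop = FALSE]
      idx_list[[i]] <- g$z + (g$y - 1L) * dz + (g$x - 1L) * dz * dy
    }
    ## temporal factors: bleach decay x OU fluctuation around 1
    bleach <- (1 - p$bleach_rate_per_frame)^(seq_len(nt) - 1)
    sig <- p$fluctuation_cv_pct / 100
    fluct <- matrix(1, nt, p$n_mito)
    if (sig > 0 && nt > 1) {
      phi <- exp(-p$frame_interval_s / p$fluctuation_tau_s)
      x <- rnorm(p$n_mito, 0, sig)
      fluct[1, ] <- 1 + x
      for (t in 2:nt) {
        x <- phi * x + rnorm(p$n_mito, 0, sig * sqrt(1 - phi^2))
        fluct[t, ] <- 1 + x
      }
      fluct <- pmax(fluct, 0.05)  # intensities cannot go negative
    } else if (sig > 0) {
      fluct[1, ] <- pmax(1 + rnorm(p$n_mito, 0, sig), 0.05)
    }
    psf_vox <- p$psf_sigma_um / p$voxel_size_um
    frames <- array(0, dim = c(nt, dz, dy, dx))
    vol <- array(0, dim = c(dz, dy, dx))
    for (t in seq_len(nt)) {
      vol[] <- 0
      for (i in seq_len(p$n_mito))
        vol[idx_list[[i]]] <- vol[idx_list[[i]]] +
          p$base_intensity * bleach[t] * fluct[t, i]
      if (any(psf_vox > 0)) vol <- gaussian_blur(vol, psf_vox)
      frames[t, , , ] <- vol + p$background_level
    }
    frames[] <- round(pmin(pmax(frames, 0), 65535))
    stack <- if (nt == 1) mito_stack(array(frames[1, , , ], dim = c(dz, dy, dx)),
                                     p$voxel_size_um)
             else mito_stack(frames, p$voxel_size_um, p$frame_interval_s)
    mask <- ellipsoid_mask(c(dz, dy, dx), p$ganglion_centre_um,
                           p$ganglion_radii_um, p$voxel_size_um)
    truth_mito <- data.frame(id = seq_len(p$n_mito),
                             z_um = ctr[, 1], y_um = ctr[, 2], x_um = ctr[, 3],
                             radius_z_um = radii[, 1], radius_y_um = radii[, 2],
                             radius_x_um = radii[, 3],
                             n_voxels = vapply(idx_list, length, 1L),
                             volume_um3 = vapply(idx_list, length, 1L) * vox_vol)
    frame_int <- sweep(fluct, 1, bleach, `*`) * p$base_intensity
    list(stack = stack, mask = mask,
         truth = list(mito = truth_mito, frame_intensity = frame_int))
  })
}
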