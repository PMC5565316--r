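## TMRE-stack analysis: background and photobleach correction, ganglion-mask
## constrained volume and spot detection, density and single-mitochondrion
## volume statistics, brightest-spot selection and intensity-fluctuation
## quantification of tracked spots.

#' Estimate and subtract the background of a stack
#'
#' The background is a single low-percentile intensity (default the 5th
#' percentile of in-mask voxels, or of the whole stack when no mask is
#' given), subtracted everywhere and clipped at zero.
#'
#' @param stack a [mito_stack()].
#' @param mask optional [ganglion_mask()] restricting the estimate.
#' @param percentile percentile used as the background estimate.
#' @return list: `stack` (corrected), `background` (estimated level).
#' @export
correct_background <- function(stack, mask = NULL, percentile = 0.05) {
  stopifnot(inherits(stack, "mito_stack"))
  v <- stack$voxels
  sample_from <- if (is.null(mask)) v else {
    nt <- stack_nt(stack)
    if (nt == 1) v[mask$mask] else stack_frame(stack, 1L)[mask$mask]
  }
  bg <- as.numeric(stats::quantile(sample_from, percentile, names = FALSE))
  if (bg > 0 && bg >= max(v))
    stop("estimated background is not below the maximum intensity")
  stack$voxels <- pmax(v - bg, 0)
  list(stack = stack, background = bg)
}

#' Correct photobleaching, assuming the first frame is the brightest
#'
#' Each frame is rescaled so its global mean matches frame 1's. The raw
#' factors are passed through an isotonic (non-decreasing) fit and floored
#' at 1, so the correction can only brighten later frames: genuine bleach is
#' undone while frame-to-frame fluctuation of the global mean is not chased.
#'
#' @param stack a time-resolved [mito_stack()] (T >= 2).
#' @return list: `stack` (corrected), `factors` (per-frame multipliers).
#' @export
correct_bleach <- function(stack) {
  stopifnot(inherits(stack, "mito_stack"))
  nt <- stack_nt(stack)
  if (nt < 2) stop("bleach correction needs at least 2 frames")
  means <- vapply(seq_len(nt), function(t) mean(stack_frame(stack, t)), 1)
  if (any(means <= 0)) stop("a frame has zero mean intensity")
  raw <- means[1] / means
  iso <- stats::isoreg(seq_len(nt), raw)$yf   # monotone non-decreasing
  factors <- pmax(iso, 1)
  for (t in seq_len(nt)) stack$voxels[t, , , ] <- stack$voxels[t, , , ] * factors[t]
  list(stack = stack, factors = factors)
}

#' Total mitochondrial volume inside the ganglion mask
#'
#' Absolute-intensity thresholding: voxels inside the mask at or above the
#' threshold count as mitochondrial; volume is voxel count times voxel
#' volume, and the ratio is volume over mask volume.
#'
#' @param frame Z x Y x X numeric array (background-corrected).
#' @param mask a [ganglion_mask()].
#' @param threshold absolute intensity threshold; `NULL` uses
#'   [default_threshold()].
#' @return list: `total_mito_volume_um3`, `volume_ratio`, `threshold`.
#' @export
detect_volume <- function(frame, mask, threshold = NULL) {
  stopifnot(length(dim(frame)) == 3, inherits(mask, "ganglion_mask"))
  if (is.null(threshold)) threshold <- default_threshold(frame, mask)
  stopifnot(threshold > 0)
  n <- sum(frame[mask$mask] >= threshold)
  vol <- n * prod(mask$voxel_size_um)
  list(total_mito_volume_um3 = vol, volume_ratio = vol / mask$volume_um3,
       threshold = threshold)
}

#' Default absolute-intensity threshold: half the 99.5th percentile of
#' in-mask intensities
#'
#' @param frame Z x Y x X array; @param mask a [ganglion_mask()].
#' @export
default_threshold <- function(frame, mask) {
  as.numeric(stats::quantile(frame[mask$mask], 0.995, names = FALSE)) / 2
}

#' Detect mitochondrial spots by Laplacian-of-Gaussian filtering
#'
#' Local maxima (26-neighbourhood) of the scale-normalised LoG response at
#' scale `sigma_um` (about expected radius / sqrt(3)), inside the mask,
#' whose image intensity clears `intensity_floor`, kept greedily in
#' descending response order subject to a minimum pairwise distance.
#'
#' @param frame Z x Y x X numeric array (background-corrected).
#' @param mask a [ganglion_mask()].
#' @param sigma_um LoG scale in um (scalar or `(z, y, x)`); default 0.46,
#'   matching a ~0.8 um expected radius.
#' @param min_distance_um minimum distance between accepted spots.
#' @param intensity_floor minimum image intensity at a spot centre; `NULL`
#'   uses 0.4 x [default_threshold()].
#' @return data.frame: `id`, `z_um`, `y_um`, `x_um`, `centre_intensity`,
#'   `log_response` (one row per spot, possibly empty).
#' @export
detect_spots <- function(frame, mask, sigma_um = 0.46, min_distance_um = 1.5,
                         intensity_floor = NULL) {
  stopifnot(length(dim(frame)) == 3, inherits(mask, "ganglion_mask"))
  if (is.null(intensity_floor))
    intensity_floor <- 0.4 * default_threshold(frame, mask)
  vs <- mask$voxel_size_um
  sigma_um <- rep(sigma_um, length.out = 3)
  sm <- gaussian_blur(frame, sigma_um / vs)
  ## scale-normalised negative Laplacian (bright blobs -> positive response),
  ## second differences scaled by the anisotropic voxel size
  d <- dim(frame)
  lap <- array(0, dim = d)
  for (a in 1:3) {
    lo <- sm; hi <- sm
    if (a == 1) { lo[2:d[1], , ] <- sm[1:(d[1] - 1), , ]; lo[1, , ] <- sm[1, , ]
                  hi[1:(d[1] - 1), , ] <- sm[2:d[1], , ]; hi[d[1], , ] <- sm[d[1], , ] }
    if (a == 2) { lo[, 2:d[2], ] <- sm[, 1:(d[2] - 1), ]; lo[, 1, ] <- sm[, 1, ]
                  hi[, 1:(d[2] - 1), ] <- sm[, 2:d[2], ]; hi[, d[2], ] <- sm[, d[2], ] }
    if (a == 3) { lo[, , 2:d[3]] <- sm[, , 1:(d[3] - 1)]; lo[, , 1] <- sm[, , 1]
                  hi[, , 1:(d[3] - 1)] <- sm[, , 2:d[3]]; hi[, , d[3]] <- sm[, , d[3]] }
    lap <- lap + (2 * sm - lo - hi) / vs[a]^2
  }
  resp <- lap * mean(sigma_um)^2
  cand <- local_maxima_3d(resp, mask = mask$mask)
  cand <- cand[frame[cand] >= intensity_floor & resp[cand] > 0]
  if (length(cand) == 0)
    return(data.frame(id = integer(0), z_um = numeric(0), y_um = numeric(0),
                      x_um = numeric(0), centre_intensity = numeric(0),
                      log_response = numeric(0)))
  ord <- order(-resp[cand], cand)
  cand <- cand[ord]
  co <- arrayInd(cand, d)
  pos <- cbind((co[, 1] - 0.5) * vs[1], (co[, 2] - 0.5) * vs[2],
               (co[, 3] - 0.5) * vs[3])
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    kp <- which(keep)
    d2 <- (pos[kp, 1] - pos[i, 1])^2 + (pos[kp, 2] - pos[i, 2])^2 +
      (pos[kp, 3] - pos[i, 3])^2
    if (all(d2 >= min_distance_um^2)) keep[i] <- TRUE
  }
  sel <- which(keep)
  data.frame(id = seq_along(sel),
             z_um = pos[sel, 1], y_um = pos[sel, 2], x_um = pos[sel, 3],
             centre_intensity = frame[cand[sel]],
             log_response = resp[cand[sel]])
}

#' Mitochondrial density in spots per 1000 cubic micrometres
#'
#' @param spots spot data.frame from [detect_spots()].
#' @param mask a [ganglion_mask()].
#' @export
density_per_1000um3 <- function(spots, mask) {
  stopifnot(inherits(mask, "ganglion_mask"))
  if (mask$volume_um3 <= 0) stop("mask volume must be > 0")
  1000 * nrow(spots) / mask$volume_um3
}

#' Mean volume of single mitochondria
#'
#' Supra-threshold in-mask voxels are partitioned into 26-connected
#' components; a component containing more than one detected spot is split
#' among those spots by seeded descending-intensity region growing
#' (marker-based watershed). Returns the mean component volume.
#'
#' @param frame Z x Y x X numeric array (background-corrected).
#' @param mask a [ganglion_mask()].
#' @param threshold absolute intensity threshold; `NULL` uses
#'   [default_threshold()].
#' @param spots optional spot data.frame used as split seeds.
#' @return list: `mean_single_volume_um3`, `n_components`, `volumes_um3`.
#' @export
single_mito_volumes <- function(frame, mask, threshold = NULL, spots = NULL) {
  stopifnot(length(dim(frame)) == 3, inherits(mask, "ganglion_mask"))
  if (is.null(threshold)) threshold <- default_threshold(frame, mask)
  fg <- (frame >= threshold) & mask$mask
  if (!any(fg)) stop("no supra-threshold voxels inside the mask")
  lab <- label_components_26(fg)
  vox_vol <- prod(mask$voxel_size_um)
  d <- dim(frame)
  if (!is.null(spots) && nrow(spots) > 0) {
    vs <- mask$voxel_size_um
    sz <- pmin(pmax(ceiling(spots$z_um / vs[1]), 1L), d[1])
    sy <- pmin(pmax(ceiling(spots$y_um / vs[2]), 1L), d[2])
    sx <- pmin(pmax(ceiling(spots$x_um / vs[3]), 1L), d[3])
    seed_lin <- sz + (sy - 1L) * d[1] + (sx - 1L) * d[1] * d[2]
    seed_comp <- lab[seed_lin]
    multi <- unique(seed_comp[duplicated(seed_comp) & seed_comp > 0])
    next_lab <- max(lab)
    for (cmp in multi) {
      vox <- which(lab == cmp)
      seeds <- seed_lin[seed_comp == cmp]
      seeds <- unique(seeds)
      if (length(seeds) < 2) next
      part <- flood_split(vox, seeds, frame, d)
      for (s in 2:length(seeds)) {
        next_lab <- next_lab + 1L
        lab[vox[part == s]] <- next_lab
      }
    }
  }
  sizes <- tabulate(lab[lab > 0])
  sizes <- sizes[sizes > 0]
  vols <- sizes * vox_vol
  list(mean_single_volume_um3 = mean(vols), n_components = length(vols),
       volumes_um3 = vols)
}

#' Select the brightest spots
#'
#' Spots are sorted by centre intensity, descending, with ties broken by
#' `(z, y, x)` lexicographic centroid order, and the first `min(n, #spots)`
#' are returned (default n = 500, the per-volume selection used for
#' fluctuation tracking).
#'
#' @param spots spot data.frame from [detect_spots()].
#' @param n number of spots to keep.
#' @export
select_top_spots <- function(spots, n = 500L) {
  stopifnot(n >= 1)
  if (nrow(spots) == 0) return(spots)
  ord <- order(-spots$centre_intensity, spots$z_um, spots$y_um, spots$x_um)
  out <- spots[ord[seq_len(min(n, nrow(spots)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Track spots through time and quantify intensity fluctuation
#'
#' Each frame-1 spot is linked frame to frame to its nearest neighbour among
#' the next frame's detections within `max_step_um`; a track that loses its
#' spot is dropped. The spot's intensity is sampled each frame as the mean
#' in a fixed-radius sphere around the tracked position. Variation is
#' expressed in percent of the spot's own temporal mean,
#' `100 * (I(t) - mean(I)) / mean(I)`, and the fluctuation score is the
#' temporal standard deviation of that series (i.e. 100 x CV).
#'
#' @param stack a background/bleach-corrected time-resolved [mito_stack()].
#' @param spots frame-1 spot data.frame (e.g. [select_top_spots()] output).
#' @param mask a [ganglion_mask()] (geometry source for redetection).
#' @param sample_radius_um radius of the intensity-sampling sphere.
#' @param max_step_um maximum displacement per frame when linking.
#' @param redetect re-run [detect_spots()] per frame for linking; when
#'   `FALSE` (default) positions are held fixed, appropriate for immobile
#'   mitochondria.
#' @param ... passed to [detect_spots()] when `redetect = TRUE`.
#' @return list: `series` data.frame (`spot_id`, `frame`, `intensity`,
#'   `variation_pct`), `scores` data.frame (`spot_id`,
#'   `fluctuation_score_pct`), `mean_fluctuation_score_pct` (subject-level
#'   value), `n_tracked`.
#' @export
track_and_fluctuate <- function(stack, spots, mask, sample_radius_um = 0.5,
                                max_step_um = 1, redetect = FALSE, ...) {
  stopifnot(inherits(stack, "mito_stack"))
  nt <- stack_nt(stack)
  if (nt < 10) stop("fluctuation analysis needs at least 10 frames")
  if (nrow(spots) == 0) stop("no spots to track")
  vs <- stack$voxel_size_um
  d <- dim(stack$voxels)[-1]
  ## precompute sampling-sphere voxel offsets
  rr <- ceiling(sample_radius_um / vs)
  og <- expand.grid(dz = -rr[1]:rr[1], dy = -rr[2]:rr[2], dx = -rr[3]:rr[3])
  og <- og[(og$dz * vs[1])^2 + (og$dy * vs[2])^2 + (og$dx * vs[3])^2 <=
             sample_radius_um^2, , drop = FALSE]
  sample_at <- function(frame, z, y, x) {
    iz <- pmin(pmax(ceiling(z / vs[1]) + og$dz, 1L), d[1])
    iy <- pmin(pmax(ceiling(y / vs[2]) + og$dy, 1L), d[2])
    ix <- pmin(pmax(ceiling(x / vs[3]) + og$dx, 1L), d[3])
    mean(frame[cbind(iz, iy, ix)])
  }
  n <- nrow(spots)
  pos <- cbind(spots$z_um, spots$y_um, spots$x_um)
  alive <- rep(TRUE, n)
  intens <- matrix(NA_real_, nt, n)
  for (t in seq_len(nt)) {
    fr <- stack_frame(stack, t)
    if (redetect && t > 1) {
      det <- detect_spots(fr, mask, ...)
      for (i in which(alive)) {
        if (nrow(det) == 0) { alive[i] <- FALSE; next }
        d2 <- (det$z_um - pos[i, 1])^2 + (det$y_um - pos[i, 2])^2 +
          (det$x_um - pos[i, 3])^2
        j <- which.min(d2)
        if (d2[j] <= max_step_um^2) pos[i, ] <- c(det$z_um[j], det$y_um[j], det$x_um[j])
        else alive[i] <- FALSE
      }
    }
    for (i in which(alive))
      intens[t, i] <- sample_at(fr, pos[i, 1], pos[i, 2], pos[i, 3])
  }
  tracked <- which(alive & colSums(!is.na(intens)) == nt)
  if (length(tracked) == 0) stop("no spots survive tracking")
  series <- list(); scores <- numeric(length(tracked))
  for (k in seq_along(tracked)) {
    i <- tracked[k]
    m <- mean(intens[, i])
    var_pct <- 100 * (intens[, i] - m) / m
    scores[k] <- stats::sd(var_pct)
    series[[k]] <- data.frame(spot_id = spots$id[i], frame = seq_len(nt),
                              intensity = intens[, i], variation_pct = var_pct)
  }
  list(series = do.call(rbind, series),
       scores = data.frame(spot_id = spots$id[tracked],
                           fluctuation_score_pct = scores),
       mean_fluctuation_score_pct = mean(scores),
       n_tracked = length(tracked))
}

#' Dye dilution factor
#'
#' Ratio of the volume the dye diffuses into to the injected volume, after
#' unit conversion (`nl`, `ul`/`µl`, `mm3`; 1 mm^3 = 1 ul = 1000 nl).
#'
#' @param injected_volume,target_volume positive volumes.
#' @param injected_unit,target_unit one of `"nl"`, `"ul"`, `"mm3"`.
#' @return dimensionless dilution factor.
#' @examples
#' dilution_factor(150, 6, "nl", "mm3")    # 40
#' dilution_factor(150, 500, "nl", "ul")   # ~3.3e3
#' @export
dilution_factor <- function(injected_volume, target_volume,
                            injected_unit = "nl", target_unit = "mm3") {
  to_ul <- function(v, unit) {
    switch(match.arg(unit, c("nl", "ul", "µl", "mm3")),
           nl = v / 1000, ul = v, "µl" = v, mm3 = v)
  }
  if (injected_volume <= 0 || target_volume <= 0)
    stop("volumes must be positive")
  to_ul(target_volume, target_unit) / to_ul(injected_volume, injected_unit)
}

#' Run the full mitochondrial pipeline on one stack
#'
#' Background correction (and bleach correction when time-resolved), volume
#' detection, spot detection, density, single-mitochondrion volumes, and —
#' for time-resolved stacks — fluctuation analysis of the brightest
#' `top_n` spots.
#'
#' @param stack a [mito_stack()].
#' @param mask a [ganglion_mask()].
#' @param threshold absolute volume-detection threshold (`NULL` = default
#'   rule).
#' @param sigma_um,min_distance_um,intensity_floor passed to
#'   [detect_spots()].
#' @param top_n number of brightest spots tracked for fluctuation.
#' @param sample_radius_um,max_step_um passed to [track_and_fluctuate()].
#' @return list: `summary` (one-row data.frame with `volume_ratio`,
#'   `total_mito_volume_um3`, `density_per_1000um3`,
#'   `mean_single_volume_um3`, `n_spots`, `fluctuation_score_pct`),
#'   `spots`, `volumes`, `fluctuation` (NULL for 3D stacks), `background`,
#'   `bleach_factors`.
#' @export
analyze_mito <- function(stack, mask, threshold = NULL, sigma_um = 0.46,
                         min_distance_um = 1.5, intensity_floor = NULL,
                         top_n = 500L, sample_radius_um = 0.5,
                         max_step_um = 1) {
  stopifnot(inherits(stack, "mito_stack"), inherits(mask, "ganglion_mask"))
  bg <- correct_background(stack, mask)
  stack <- bg$stack
  factors <- NULL
  if (stack_nt(stack) > 1) {
    bl <- correct_bleach(stack)
    stack <- bl$stack
    factors <- bl$factors
  }
  fr1 <- stack_frame(stack, 1L)
  volres <- detect_volume(fr1, mask, threshold)
  spots <- detect_spots(fr1, mask, sigma_um = sigma_um,
                        min_distance_um = min_distance_um,
                        intensity_floor = intensity_floor)
  dens <- density_per_1000um3(spots, mask)
  segres <- single_mito_volumes(fr1, mask, threshold = volres$threshold,
                                spots = spots)
  fluct <- NULL
  fl_score <- NA_real_
  if (stack_nt(stack) >= 10 && nrow(spots) > 0) {
    top <- select_top_spots(spots, top_n)
    fluct <- track_and_fluctuate(stack, top, mask,
                                 sample_radius_um = sample_radius_um,
                                 max_step_um = max_step_um)
    fl_score <- fluct$mean_fluctuation_score_pct
  }
  list(summary = data.frame(volume_ratio = volres$volume_ratio,
                            total_mito_volume_um3 = volres$total_mito_volume_um3,
                            density_per_1000um3 = dens,
                            mean_single_volume_um3 = segres$mean_single_volume_um3,
                            n_spots = nrow(spots),
                            fluctuation_score_pct = fl_score),
       spots = spots, volumes = segres, fluctuation = fluct,
       background = bg$background, bleach_factors = factors)
}
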