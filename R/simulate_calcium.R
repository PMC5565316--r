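## Synthetic calcium-imaging movies with known ground truth: ganglia of a
## few to a few hundred somata, a stimulus-locked transient in a configurable
## fraction of them, additive camera noise and optional lateral drift.

#' Evaluate code with a private, seeded RNG stream
#'
#' Saves and restores `.Random.seed` so simulations never perturb (or depend
#' on) the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parameters for the synthetic calcium movie generator
#'
#' Defaults describe a typical submucous-ganglion recording: 2 Hz
#' acquisition, a 10 s depolarising stimulus after a 50 s baseline, somata of
#' 4 px radius on a 16-bit camera, trace-level noise of about 0.4% ratio
#' units.
#'
#' @param n_neurons number of somata to place.
#' @param responder_fraction fraction in \[0, 1\] of neurons that respond;
#'   the generator assigns exactly `round(fraction * n)` responders so the
#'   simulated truth is not itself a binomial draw.
#' @param true_amplitude_pct `c(mean, sd)` of responder peak amplitudes in
#'   % above baseline (Gaussian, truncated below at `min_amplitude_pct`).
#' @param min_amplitude_pct lower truncation for responder amplitudes (%).
#' @param baseline_intensity soma baseline fluorescence, arbitrary units.
#' @param background_intensity tissue background outside somata.
#' @param noise_sd per-pixel additive Gaussian noise SD, arbitrary units.
#' @param poisson_noise also apply photon-shot (Poisson) resampling.
#' @param drift_px_per_frame `c(dy, dx)` rigid drift per frame, pixels.
#' @param frame_interval_s seconds per frame (default 0.5, i.e. 2 Hz).
#' @param n_frames number of frames (>= 2).
#' @param stimulus_window `c(start_s, end_s)` of the stimulus.
#' @param stimulus_label label for the stimulus window (default "highK").
#' @param decay_tau_s single-exponential decay time constant of the
#'   transient, seconds.
#' @param soma_radius_px soma radius in pixels.
#' @param field_shape_px image extent `c(Y, X)` in pixels.
#' @param seed integer seed; identical parameters and seed give bit-identical
#'   output.
#' @return validated parameter list of class `calcium_sim_params`.
#' @export
calcium_sim_params <- function(n_neurons = 20,
                               responder_fraction = 0.6,
                               true_amplitude_pct = c(8, 2),
                               min_amplitude_pct = 4,
                               baseline_intensity = 1000,
                               background_intensity = 100,
                               noise_sd = 30,
                               poisson_noise = FALSE,
                               drift_px_per_frame = c(0, 0),
                               frame_interval_s = 0.5,
                               n_frames = 240,
                               stimulus_window = c(50, 60),
                               stimulus_label = "highK",
                               decay_tau_s = 5,
                               soma_radius_px = 4,
                               field_shape_px = c(256, 256),
                               seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$n_neurons >= 1, p$n_frames >= 2,
            p$responder_fraction >= 0, p$responder_fraction <= 1,
            length(p$true_amplitude_pct) == 2, p$true_amplitude_pct[2] >= 0,
            p$baseline_intensity > 0, p$noise_sd >= 0,
            length(p$drift_px_per_frame) == 2,
            p$frame_interval_s > 0, p$decay_tau_s > 0,
            p$soma_radius_px >= 1, length(p$field_shape_px) == 2)
  dur <- p$n_frames * p$frame_interval_s
  if (!(length(p$stimulus_window) == 2 && p$stimulus_window[1] >= 0 &&
        p$stimulus_window[2] > p$stimulus_window[1] &&
        p$stimulus_window[2] <= dur))
    stop("stimulus window must lie inside the recording")
  structure(p, class = "calcium_sim_params")
}

#' @noRd
place_somata <- function(n, shape_yx, radius, min_sep_factor = 2.2,
                         max_tries = 5000L) {
  margin <- radius + 2
  cy <- numeric(0); cx <- numeric(0)
  min_d2 <- (min_sep_factor * radius)^2
  tries <- 0L
  while (length(cy) < n) {
    y <- runif(1, margin, shape_yx[1] - 1 - margin)
    x <- runif(1, margin, shape_yx[2] - 1 - margin)
    if (length(cy) == 0 || all((cy - y)^2 + (cx - x)^2 > min_d2)) {
      cy <- c(cy, y); cx <- c(cx, x)
    }
    tries <- tries + 1L
    if (tries > max_tries * n)
      stop(sprintf("cannot place %d non-overlapping somata of radius %g in a %d x %d field",
                   n, radius, shape_yx[1], shape_yx[2]))
  }
  cbind(cy = cy, cx = cx)
}

#' Simulate a calcium-imaging movie with ground truth
#'
#' Responder somata show a stimulus-locked transient: instantaneous rise at
#' stimulus onset to `baseline * (1 + amplitude/100)`, then single-exponential
#' decay with time constant `decay_tau_s`. Non-responders stay flat. The
#' rendered movie gets additive Gaussian noise, optional Poisson resampling,
#' optional rigid drift, and is quantised to 16-bit integer counts.
#'
#' @param params a [calcium_sim_params()] object.
#' @return list with
#'   \describe{
#'     \item{movie}{a [calcium_movie()] (raw, unregistered).}
#'     \item{rois}{list of [neuron_roi()] discs matching the rendered somata
#'       at their frame-1 (drift-free) positions.}
#'     \item{truth}{data.frame: `roi_id`, `cy`, `cx` (0-based px),
#'       `responder`, `true_amplitude_pct`.}
#'     \item{drift}{T x 2 matrix of applied cumulative `(dy, dx)` drift.}
#'   }
#' @examples
#' sim <- simulate_calcium_movie(calcium_sim_params(n_neurons = 4, seed = 7,
#'   n_frames = 40, stimulus_window = c(8, 12), field_shape_px = c(64, 64)))
#' sim$truth
#' @export
simulate_calcium_movie <- function(params) {
  stopifnot(inherits(params, "calcium_sim_params"))
  p <- params
  with_seed(p$seed, {
    ctr <- place_somata(p$n_neurons, p$field_shape_px, p$soma_radius_px)
    n_resp <- round(p$responder_fraction * p$n_neurons)
    responder <- rep(FALSE, p$n_neurons)
    if (n_resp > 0) responder[sample.int(p$n_neurons, n_resp)] <- TRUE
    amp <- rep(0, p$n_neurons)
    if (n_resp > 0) {
      draw <- function(k) {
        a <- rnorm(k, p$true_amplitude_pct[1], p$true_amplitude_pct[2])
        bad <- a < p$min_amplitude_pct
        while (any(bad)) {
          a[bad] <- rnorm(sum(bad), p$true_amplitude_pct[1], p$true_amplitude_pct[2])
          bad <- a < p$min_amplitude_pct
        }
        a
      }
      amp[responder] <- draw(n_resp)
    }
    rois <- lapply(seq_len(p$n_neurons), function(i)
      disc_roi(sprintf("n%03d", i), ctr[i, 1], ctr[i, 2], p$soma_radius_px,
               p$field_shape_px))
    ## static scene: background plus somata at baseline; per-soma pixel sets
    base <- matrix(p$background_intensity, p$field_shape_px[1], p$field_shape_px[2])
    soma_idx <- lapply(rois, function(r)
      (r$pixels[, 2]) * p$field_shape_px[1] + r$pixels[, 1] + 1L)
    for (i in seq_len(p$n_neurons)) base[soma_idx[[i]]] <- p$baseline_intensity
    tt <- (seq_len(p$n_frames) - 1) * p$frame_interval_s
    on <- tt >= p$stimulus_window[1]
    frames <- array(0, dim = c(p$n_frames, p$field_shape_px[1], p$field_shape_px[2]))
    drift <- cbind(dy = (seq_len(p$n_frames) - 1) * p$drift_px_per_frame[1],
                   dx = (seq_len(p$n_frames) - 1) * p$drift_px_per_frame[2])
    for (t in seq_len(p$n_frames)) {
      img <- base
      if (on[t]) {
        f <- exp(-(tt[t] - p$stimulus_window[1]) / p$decay_tau_s)
        for (i in which(responder))
          img[soma_idx[[i]]] <- p$baseline_intensity * (1 + amp[i] / 100 * f)
      }
      if (any(drift[t, ] != 0)) img <- shift_image_2d(img, drift[t, 1], drift[t, 2])
      frames[t, , ] <- img
    }
    if (p$poisson_noise) {
      frames[] <- rpois(length(frames), lambda = pmax(frames, 0))
    }
    if (p$noise_sd > 0) {
      frames <- frames + rnorm(length(frames), sd = p$noise_sd)
    }
    quantise <- p$noise_sd > 0 || p$poisson_noise
    if (quantise) frames[] <- round(pmin(pmax(frames, 0), 65535))
    movie <- calcium_movie(frames, p$frame_interval_s,
                           stimulus_windows = data.frame(
                             label = p$stimulus_label,
                             start_s = p$stimulus_window[1],
                             end_s = p$stimulus_window[2],
                             stringsAsFactors = FALSE))
    truth <- data.frame(roi_id = vapply(rois, `[[`, "", "id"),
                        cy = ctr[, 1], cx = ctr[, 2],
                        responder = responder, true_amplitude_pct = amp,
                        stringsAsFactors = FALSE)
    list(movie = movie, rois = rois, truth = truth, drift = drift)
  })
}
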