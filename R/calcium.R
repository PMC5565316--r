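## Calcium-imaging analysis: per-ROI traces, F/F0 normalisation against a
## pre-stimulus baseline, noise-adaptive transient detection (baseline plus
## 5 times the intrinsic noise level), responder/amplitude summaries.

#' Extract the raw intensity trace of one ROI
#'
#' Per-frame mean intensity over the ROI's pixels. The movie should be
#' registered first so the ROI tracks the same soma throughout.
#'
#' @param movie a [calcium_movie()].
#' @param roi a [neuron_roi()].
#' @return numeric vector of length T.
#' @export
extract_trace <- function(movie, roi) {
  stopifnot(inherits(movie, "calcium_movie"), inherits(roi, "neuron_roi"))
  d <- dim(movie$frames)
  px <- roi$pixels
  px <- px[px[, 1] < d[2] & px[, 2] < d[3], , drop = FALSE]
  if (nrow(px) == 0) stop("ROI is empty after clipping to image bounds")
  ## linear indices into one Y x X frame
  lin <- px[, 1] + 1L + px[, 2] * d[2]
  fmat <- matrix(movie$frames, nrow = d[1])
  rowMeans(fmat[, lin, drop = FALSE])
}

#' Baseline frames preceding the first stimulus
#' @noRd
default_baseline_window <- function(movie) {
  if (is.null(movie$stimulus_windows) || nrow(movie$stimulus_windows) == 0)
    stop("movie has no stimulus windows; give baseline_window explicitly")
  first <- min(movie$stimulus_windows$start_s)
  n <- floor(first / movie$frame_interval_s + 1e-9)
  if (n < 1) stop("no frames precede the first stimulus")
  seq_len(n)
}

#' Normalise a raw trace to an F/F0 ratio
#'
#' F0 is the mean fluorescence over the baseline window (which must precede
#' the first stimulus); the returned trace is F/F0 so baseline sits at 1 and
#' a transient of amplitude a% peaks at 1 + a/100.
#'
#' @param F raw intensity series.
#' @param baseline_window integer vector of (1-based) baseline frame indices.
#' @param roi_id identifier carried through to downstream calls.
#' @param frame_interval_s seconds per frame.
#' @param noise_estimator `"sd_detrended"` (default) or `"mad"`; see
#'   [estimate_noise()].
#' @return object of class `calcium_trace` with fields `roi_id`, `F`, `F0`,
#'   `ratio`, `baseline_window`, `frame_interval_s`, `noise_sigma`.
#' @export
normalize_f0 <- function(F, baseline_window, roi_id = "roi",
                         frame_interval_s = 1,
                         noise_estimator = c("sd_detrended", "mad")) {
  stopifnot(is.numeric(F), length(F) >= 2,
            all(baseline_window >= 1), all(baseline_window <= length(F)))
  F0 <- mean(F[baseline_window])
  if (!is.finite(F0) || F0 <= 0) stop("baseline fluorescence F0 must be > 0")
  tr <- structure(list(roi_id = roi_id, F = F, F0 = F0, ratio = F / F0,
                       baseline_window = as.integer(baseline_window),
                       frame_interval_s = frame_interval_s,
                       noise_sigma = NA_real_),
                  class = "calcium_trace")
  if (length(baseline_window) >= 10)
    tr$noise_sigma <- estimate_noise(tr, estimator = match.arg(noise_estimator))
  tr
}

#' Estimate the intrinsic noise level of a trace
#'
#' The noise level (in ratio units) is the spread of the baseline-window
#' ratio samples after removing a linear trend, so a slow bleach ramp does
#' not inflate it. `"sd_detrended"` uses the residual standard deviation;
#' `"mad"` uses 1.4826 x median absolute deviation of the residuals.
#'
#' @param trace a `calcium_trace`.
#' @param estimator `"sd_detrended"` or `"mad"`.
#' @return non-negative scalar noise sigma in ratio units.
#' @export
estimate_noise <- function(trace, estimator = c("sd_detrended", "mad")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(trace, "calcium_trace"))
  w <- trace$baseline_window
  if (length(w) < 10) stop("baseline window must have at least 10 frames")
  y <- trace$ratio[w]
  x <- seq_along(y)
  res <- stats::lm.fit(cbind(1, x), y)$residuals
  if (estimator == "sd_detrended") stats::sd(res) else stats::mad(res)
}

#' Frames covered by a time window
#' @noRd
frames_in_window <- function(start_s, end_s, frame_interval_s, n_frames) {
  tt <- (seq_len(n_frames) - 1) * frame_interval_s
  which(tt >= start_s - 1e-9 & tt < end_s - 1e-9)
}

#' Detect a stimulus-locked calcium transient in one trace
#'
#' A neuron is a responder when its peak F/F0 in the evaluation window
#' strictly exceeds baseline plus 5 times the intrinsic noise level; with
#' the baseline ratio at 1 by construction the threshold is
#' `1 + 5 * noise_sigma`. A peak landing exactly on the threshold is not a
#' response. The maximum amplitude is reported as the percentage change
#' above baseline, `(peak - 1) * 100`.
#'
#' @param trace a `calcium_trace` with `noise_sigma` set.
#' @param window `c(start_s, end_s)` evaluation window (the stimulus window
#'   plus any tail), half-open.
#' @param stimulus label attached to the call.
#' @param threshold_mult noise multiplier (default 5).
#' @return object of class `transient_call`: `roi_id`, `stimulus`,
#'   `responder`, `max_amplitude_pct`, `peak_time_s`, `noise_sigma`,
#'   `threshold_ratio`.
#' @export
detect_transient <- function(trace, window, stimulus = "highK",
                             threshold_mult = 5) {
  stopifnot(inherits(trace, "calcium_trace"))
  if (!is.finite(trace$noise_sigma))
    stop("noise_sigma not set; run estimate_noise() or use a >= 10 frame baseline")
  idx <- frames_in_window(window[1], window[2], trace$frame_interval_s,
                          length(trace$ratio))
  if (length(idx) == 0) stop("evaluation window contains no frames")
  seg <- trace$ratio[idx]
  k <- which.max(seg)  # first frame on ties
  peak <- seg[k]
  thr <- 1 + threshold_mult * trace$noise_sigma
  responder <- peak > thr
  structure(list(roi_id = trace$roi_id, stimulus = stimulus,
                 responder = responder,
                 max_amplitude_pct = max(peak - 1, 0) * 100,
                 peak_time_s = (idx[k] - 1) * trace$frame_interval_s,
                 noise_sigma = trace$noise_sigma, threshold_ratio = thr),
            class = "transient_call")
}

#' Summarise transient calls for one stimulus
#'
#' @param calls list of `transient_call` objects, all for the same stimulus.
#' @param amplitude_over `"all"` (default) averages max amplitude over every
#'   analysed neuron; `"responders"` over responders only.
#' @return one-row data.frame: `stimulus`, `n_neurons`, `n_responders`,
#'   `pct_responders`, `mean_max_amplitude_pct`.
#' @export
summarize_stimulus <- function(calls, amplitude_over = c("all", "responders")) {
  amplitude_over <- match.arg(amplitude_over)
  stopifnot(length(calls) >= 1,
            all(vapply(calls, inherits, TRUE, "transient_call")))
  stim <- unique(vapply(calls, `[[`, "", "stimulus"))
  if (length(stim) != 1) stop("calls mix stimulus labels: ", paste(stim, collapse = ", "))
  resp <- vapply(calls, `[[`, TRUE, "responder")
  amp <- vapply(calls, `[[`, 1, "max_amplitude_pct")
  sel <- if (amplitude_over == "all") rep(TRUE, length(amp)) else resp
  data.frame(stimulus = stim, n_neurons = length(calls),
             n_responders = sum(resp),
             pct_responders = 100 * mean(resp),
             mean_max_amplitude_pct = if (any(sel)) mean(amp[sel]) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Run the full calcium pipeline on one movie
#'
#' Registration to the first frame, ROI trace extraction, F/F0
#' normalisation against the pre-stimulus baseline, noise estimation,
#' transient detection per stimulus window (each evaluated over the window
#' plus `tail_s`), and per-stimulus summaries.
#'
#' @param movie a [calcium_movie()] with stimulus windows.
#' @param rois list of [neuron_roi()].
#' @param register run [register_to_first()] first (default TRUE).
#' @param tail_s evaluation tail appended to each stimulus window, seconds.
#' @param threshold_mult noise multiplier for the responder rule.
#' @param noise_estimator passed to [normalize_f0()].
#' @param amplitude_over passed to [summarize_stimulus()].
#' @return list with `calls` (data.frame, one row per ROI x stimulus),
#'   `summary` (per-stimulus data.frame), `traces`, `shifts`.
#' @export
analyze_calcium <- function(movie, rois, register = TRUE, tail_s = 10,
                            threshold_mult = 5,
                            noise_estimator = "sd_detrended",
                            amplitude_over = "all") {
  stopifnot(inherits(movie, "calcium_movie"), length(rois) >= 1)
  if (is.null(movie$stimulus_windows) || nrow(movie$stimulus_windows) == 0)
    stop("movie has no stimulus windows")
  shifts <- NULL
  if (register) {
    reg <- register_to_first(movie)
    movie <- reg$movie
    shifts <- reg$shifts
  }
  bw <- default_baseline_window(movie)
  dur <- dim(movie$frames)[1] * movie$frame_interval_s
  traces <- lapply(rois, function(r)
    normalize_f0(extract_trace(movie, r), bw, roi_id = r$id,
                 frame_interval_s = movie$frame_interval_s,
                 noise_estimator = noise_estimator))
  all_calls <- list()
  summaries <- list()
  for (s in seq_len(nrow(movie$stimulus_windows))) {
    sw <- movie$stimulus_windows[s, ]
    win <- c(sw$start_s, min(sw$end_s + tail_s, dur))
    calls <- lapply(traces, detect_transient, window = win,
                    stimulus = sw$label, threshold_mult = threshold_mult)
    summaries[[s]] <- summarize_stimulus(calls, amplitude_over = amplitude_over)
    all_calls[[s]] <- data.frame(
      roi_id = vapply(calls, `[[`, "", "roi_id"),
      stimulus = sw$label,
      responder = vapply(calls, `[[`, TRUE, "responder"),
      max_amplitude_pct = vapply(calls, `[[`, 1, "max_amplitude_pct"),
      peak_time_s = vapply(calls, `[[`, 1, "peak_time_s"),
      noise_sigma = vapply(calls, `[[`, 1, "noise_sigma"),
      stringsAsFactors = FALSE)
  }
  list(calls = do.call(rbind, all_calls),
       summary = do.call(rbind, summaries),
       traces = traces, shifts = shifts)
}
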