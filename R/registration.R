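## Rigid (translation-only) registration of a time-lapse movie to its first
## frame by phase cross-correlation, refined to subpixel precision with a
## locally upsampled discrete Fourier transform.

#' @noRd
dft_upsample <- function(X, nor, noc, usfac, roff, coff) {
  ## Evaluate the inverse DFT of X on an upsampled (nor x noc) grid whose
  ## top-left corner sits at (roff, coff) in upsampled-pixel units.
  nr <- nrow(X); nc <- ncol(X)
  fr <- fft_freq_index(nr)
  fc <- fft_freq_index(nc)
  kernr <- exp((2i * pi / (nr * usfac)) * outer((0:(nor - 1)) - roff, fr))
  kernc <- exp((2i * pi / (nc * usfac)) * outer(fc, (0:(noc - 1)) - coff))
  kernr %*% X %*% kernc
}

#' Estimate the translation between two images by phase cross-correlation
#'
#' Returns the shift `(dy, dx)` such that translating `moving` by
#' `-shift` best aligns it with `reference`, i.e. `moving` looks like
#' `reference` displaced by `shift`.
#'
#' @param reference,moving numeric matrices of identical size.
#' @param upsample integer upsampling factor for subpixel refinement
#'   (1 = integer-pixel estimate).
#' @param window apply a Hann window before transforming (reduces wrap-around
#'   edge artefacts); default `TRUE`.
#' @return numeric vector `c(dy, dx)` in pixels.
#' @examples
#' img <- matrix(0, 32, 32); img[10:14, 10:14] <- 1
#' mov <- matrix(0, 32, 32); mov[13:17, 8:12] <- 1
#' round(phase_correlate(img, mov), 1)  # about c(3, -2)
#' @export
phase_correlate <- function(reference, moving, upsample = 10L, window = TRUE) {
  stopifnot(is.matrix(reference), is.matrix(moving),
            all(dim(reference) == dim(moving)))
  nr <- nrow(reference); nc <- ncol(reference)
  if (window) {
    wr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nr) - 1) / (nr - 1))
    wc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nc) - 1) / (nc - 1))
    w <- outer(wr, wc)
    reference <- reference * w
    moving <- moving * w
  }
  F1 <- fft(reference)
  F2 <- fft(moving)
  R <- F1 * Conj(F2)
  mag <- Mod(R)
  R <- R / pmax(mag, .Machine$double.eps)
  cc <- Re(fft(R, inverse = TRUE))
  peak <- which.max(cc)
  pk <- arrayInd(peak, dim(cc))
  dy <- pk[1] - 1L; dx <- pk[2] - 1L
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  shift <- c(dy, dx)
  if (upsample > 1) {
    ## refine in a 1.5-pixel neighbourhood on the upsampled grid
    usfac <- as.integer(upsample)
    side <- ceiling(usfac * 1.5)
    roff <- side %/% 2 - shift[1] * usfac
    coff <- side %/% 2 - shift[2] * usfac
    cc_up <- Mod(dft_upsample(R, side, side, usfac, roff, coff))
    pk2 <- arrayInd(which.max(cc_up), dim(cc_up))
    shift <- shift + c(pk2[1] - 1 - side %/% 2, pk2[2] - 1 - side %/% 2) / usfac
  }
  ## sign convention: moving = reference displaced by +shift
  -shift
}

#' Register a calcium movie to its first frame
#'
#' Every frame is aligned to frame 1 by translation-only phase
#' cross-correlation (subpixel, 10x upsampled by default), undoing lateral
#' drift and perfusion movement. Out-of-frame pixels are filled with the
#' nearest edge value.
#'
#' @param movie a [calcium_movie()] object.
#' @param upsample subpixel upsampling factor passed to [phase_correlate()].
#' @param max_shift_warn_frac warn when any estimated |shift| exceeds this
#'   fraction of the image width (default 0.2).
#' @return a list with `movie` (registered copy) and `shifts`, a T x 2 matrix
#'   of per-frame corrective `(dy, dx)` translations in pixels: frame t was
#'   displaced by `-shifts[t, ]` relative to frame 1 and has been translated
#'   by `+shifts[t, ]` to align it (so under constant drift the shifts are
#'   minus the cumulative drift).
#' @export
register_to_first <- function(movie, upsample = 10L, max_shift_warn_frac = 0.2) {
  stopifnot(inherits(movie, "calcium_movie"))
  fr <- movie$frames
  tdim <- dim(fr)[1]
  if (tdim < 2) stop("movie must have at least 2 frames")
  ref <- fr[1, , ]
  shifts <- matrix(0, nrow = tdim, ncol = 2,
                   dimnames = list(NULL, c("dy", "dx")))
  out <- fr
  for (t in 2:tdim) {
    sh <- -phase_correlate(ref, fr[t, , ], upsample = upsample)
    shifts[t, ] <- sh
    if (any(abs(sh) > 0)) out[t, , ] <- shift_image_2d(fr[t, , ], sh[1], sh[2])
  }
  lim <- max_shift_warn_frac * ncol(ref)
  if (any(abs(shifts) > lim)) {
    warning(sprintf("registration shift exceeds %.0f%% of image width on %d frame(s)",
                    100 * max_shift_warn_frac, sum(apply(abs(shifts) > lim, 1, any))))
  }
  movie$frames <- out
  movie$registered <- TRUE
  list(movie = movie, shifts = shifts)
}
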