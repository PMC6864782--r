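#' Hanning analysis window
#'
#' Generalized Hanning taper `W(x) = alpha - (1 - alpha) * cos(2 pi x / N)`
#' evaluated at `x = 0, ..., N - 1`. At the default `alpha = 0.5` this is
#' the periodic Hann window: zero at the frame edges, unity at the
#' midpoint, suppressing the spectral leakage a rectangular frame would
#' smear across neighboring frequency bins.
#'
#' @param alpha shape parameter in \[0, 1\] (default 0.5).
#' @param N window length in samples (>= 2).
#' @return numeric weight vector of length `N`.
#' @export
hanning_window <- function(alpha = 0.5, N) {
  if (N < 2) stop("configuration error: window length N must be >= 2",
                  call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  x <- seq_len(N) - 1
  alpha - (1 - alpha) * cos(2 * pi * x / N)
}

#' Discrete Fourier transform of one analysis frame
#'
#' Coefficients `F_u = sum_x f_x exp(-i 2 pi u x / N)`, `u = 0..N-1`
#' (computed via the FFT, which evaluates exactly this sum).
#'
#' @param frame finite real (or complex) vector.
#' @return complex coefficient vector of length `length(frame)`.
#' @export
dft <- function(frame) {
  if (!all(is.finite(Re(frame))) || !all(is.finite(Im(frame)))) {
    stop("numeric error: non-finite values in DFT input", call. = FALSE)
  }
  stats::fft(frame)
}

#' Canonical EEG band table
#'
#' The five analysis bands, inclusive at both edges: Theta 4-8 Hz, Alpha
#' 9-12 Hz, Low Beta 13-16 Hz, High Beta 17-25 Hz, Gamma 26-40 Hz.
#'
#' @return data frame with columns `name`, `lo_hz`, `hi_hz`.
#' @export
eeg_bands <- function() {
  data.frame(
    name = c("theta", "alpha", "low_beta", "high_beta", "gamma"),
    lo_hz = c(4, 9, 13, 17, 26),
    hi_hz = c(8, 12, 16, 25, 40))
}

#' Spectral energy per frequency band
#'
#' Sums `|F_u|^2` over the DFT bins whose center frequency
#' `u * fs / N` lies inside each band (inclusive edges); bins above the
#' Nyquist frequency are excluded.
#'
#' @param coefficients complex DFT coefficients from [dft()].
#' @param sampling_rate sampling frequency in Hz.
#' @param bands band table as from [eeg_bands()].
#' @return named numeric vector of per-band energies (>= 0).
#' @export
band_energies <- function(coefficients, sampling_rate, bands = eeg_bands()) {
  N <- length(coefficients)
  freq <- (seq_len(N) - 1) * sampling_rate / N
  nyquist <- sampling_rate / 2
  power <- Mod(coefficients)^2
  e <- vapply(seq_len(nrow(bands)), function(b) {
    if (bands$lo_hz[b] > nyquist) {
      stop(sprintf("empty-band error: band %s (%g-%g Hz) lies above Nyquist %g Hz",
                   bands$name[b], bands$lo_hz[b], bands$hi_hz[b], nyquist),
           call. = FALSE)
    }
    sel <- freq >= bands$lo_hz[b] & freq <= bands$hi_hz[b] & freq <= nyquist
    sum(power[sel])
  }, numeric(1))
  setNames(e, bands$name)
}

#' Build the EEG gamma-band feature sequence FD
#'
#' Short-time spectral analysis of every channel: the recording is cut
#' into frames of `window_length` samples advancing by `hop`, each frame
#' is tapered with the Hanning window, Fourier-transformed, and reduced
#' to its gamma-band (26-40 Hz) energy. One feature frame per analysis
#' window holds the per-channel gamma energies in declared channel order,
#' log-compressed as `log(1 + E)` (raw band energies span decades, which
#' destabilizes recurrent training).
#'
#' @param recording an [eeg_recording()].
#' @param window_length samples per analysis frame (default 64, i.e.
#'   0.5 s at 128 Hz, giving 2 Hz bin resolution).
#' @param hop samples between frame starts (default 32, 50% overlap).
#' @param window_alpha Hanning shape parameter (default 0.5).
#' @param band band name from [eeg_bands()] (default `"gamma"`).
#' @param log_compress apply `log(1 + E)` (default `TRUE`).
#' @return numeric matrix, frames x channels, with attribute
#'   `frame_times` (frame-start times in seconds).
#' @export
build_eeg_features <- function(recording, window_length = 64L, hop = 32L,
                               window_alpha = 0.5, band = "gamma",
                               log_compress = TRUE) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (hop < 1L || hop > window_length) {
    stop("configuration error: need 1 <= hop <= window_length", call. = FALSE)
  }
  L <- nrow(recording$data)
  if (L < window_length) {
    stop(sprintf("length error: recording has %d samples, window needs %d",
                 L, window_length), call. = FALSE)
  }
  bands <- eeg_bands()
  if (!band %in% bands$name) stop("unknown band: ", band, call. = FALSE)
  band_row <- bands[bands$name == band, , drop = FALSE]
  w <- hanning_window(window_alpha, window_length)
  n_frames <- (L - window_length) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop + 1L
  out <- matrix(0, n_frames, ncol(recording$data))
  colnames(out) <- recording$channels
  for (f in seq_len(n_frames)) {
    seg <- recording$data[starts[f]:(starts[f] + window_length - 1L), ,
                          drop = FALSE] * w
    for (ch in seq_len(ncol(seg))) {
      out[f, ch] <- band_energies(dft(seg[, ch]), recording$sampling_rate,
                                  band_row)[[1]]
    }
  }
  if (log_compress) out <- log1p(out)
  attr(out, "frame_times") <- (starts - 1L) / recording$sampling_rate
  out
}
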