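#' Normalize a signature trace for cross-device comparability
#'
#' Translates the trace so its first point is the origin and scales it
#' uniformly so the bounding-box diagonal has length 1 (aspect ratio
#' preserved). Raw screen coordinates differ across devices and sessions;
#' this canonical frame removes position and size while keeping shape and
#' dynamics.
#'
#' @param trace a [signature_trace()].
#' @return a normalized `signature_trace`.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "signature_trace"))
  p <- trace$points
  diag_len <- sqrt(diff(range(p$x))^2 + diff(range(p$y))^2)
  if (diag_len == 0) {
    stop("degenerate trace: all points identical (zero bounding box)",
         call. = FALSE)
  }
  out <- trace
  out$points$x <- (p$x - p$x[1]) / diag_len
  out$points$y <- (p$y - p$y[1]) / diag_len
  out
}

#' Writing direction at an interior trajectory point
#'
#' The local writing direction at point `j` is the direction of the chord
#' joining its two neighbors, the points `j - 1` and `j + 1`. The chord,
#' viewed as an undirected line, forms an acute angle `alpha` with the
#' x-axis and the complementary angle `beta = 90 - alpha` with the y-axis;
#' both are returned in degrees. Being line angles (not vector headings),
#' they are invariant to traversal direction, translation and uniform
#' scaling.
#'
#' @param trace a `signature_trace`.
#' @param j interior point index, `2 <= j <= n - 1` (1-based).
#' @return named numeric vector `c(alpha_deg, beta_deg)`; `NA`s when the
#'   two neighbors coincide (zero-length chord, e.g. a pen hold) — callers
#'   decide how to fill these (see [build_signature_features()]).
#' @export
writing_direction <- function(trace, j) {
  p <- trace$points
  n <- nrow(p)
  if (j < 2L || j > n - 1L) {
    stop(sprintf("j = %d is not an interior index of a %d-point trace", j, n),
         call. = FALSE)
  }
  dx <- p$x[j + 1L] - p$x[j - 1L]
  dy <- p$y[j + 1L] - p$y[j - 1L]
  if (dx == 0 && dy == 0) {
    return(c(alpha_deg = NA_real_, beta_deg = NA_real_))
  }
  ang <- atan2(dy, dx) * 180 / pi       # heading in (-180, 180]
  ang <- ang %% 180                     # undirected line angle in [0, 180)
  alpha <- min(ang, 180 - ang)          # acute angle with the x-axis
  c(alpha_deg = alpha, beta_deg = 90 - alpha)
}

#' Build the signature feature sequence FS = {T, W}
#'
#' One feature frame per trajectory point: the normalized coordinates
#' (the raw trajectory T, after [normalize_trace()]) concatenated with the
#' writing-direction angles W. Interior points use [writing_direction()];
#' the two endpoints, which lack a neighbor pair, replicate the nearest
#' interior frame's angles so the frame count equals the point count.
#' Zero-length neighbor chords (pen holds) carry the previous frame's
#' angles forward; a trace that opens with a hold uses 0/90 degrees until
#' motion starts.
#'
#' @param trace a `signature_trace` (raw; normalization is applied here).
#' @return numeric matrix with one row per point and columns
#'   `x_norm, y_norm, alpha_deg, beta_deg`.
#' @export
build_signature_features <- function(trace) {
  tr <- normalize_trace(trace)
  p <- tr$points
  n <- nrow(p)
  ang <- matrix(NA_real_, n, 2)
  for (j in 2:(n - 1L)) {
    ang[j, ] <- writing_direction(tr, j)
  }
  # pen holds: carry previous interior angles forward
  for (j in 3:(n - 1L)) {
    if (is.na(ang[j, 1])) ang[j, ] <- ang[j - 1L, ]
  }
  if (is.na(ang[2L, 1])) {   # trace opens with a hold: 0/90 until motion
    ang[2L, ] <- c(0, 90)
    for (j in 3:(n - 1L)) if (is.na(ang[j, 1])) ang[j, ] <- ang[j - 1L, ]
  }
  ang[1L, ] <- ang[2L, ]          # endpoints replicate nearest interior
  ang[n, ] <- ang[n - 1L, ]
  out <- cbind(x_norm = p$x, y_norm = p$y,
               alpha_deg = ang[, 1], beta_deg = ang[, 2])
  rownames(out) <- NULL
  out
}

#' Write a feature sequence (one frame per row) to CSV
#' @param features numeric matrix as returned by
#'   [build_signature_features()] or [build_eeg_features()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_sequence <- function(features, path) {
  write.csv(as.data.frame(features), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
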