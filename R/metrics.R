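#' Identification accuracy (percent)
#'
#' @param predictions,truths equal-length aligned label vectors.
#' @return percentage of exact matches, `100 * correct / total`.
#' @export
identification_accuracy <- function(predictions, truths) {
  if (!length(predictions) || length(predictions) != length(truths)) {
    stop("evaluation error: prediction and truth lists must be nonempty ",
         "and aligned", call. = FALSE)
  }
  100 * mean(as.character(predictions) == as.character(truths))
}

#' False acceptance and false rejection rates (percent)
#'
#' FAR is the percentage of forgery attempts accepted; FRR the percentage
#' of genuine attempts rejected. TPR = 100 - FRR.
#'
#' @param accepted logical vector, one entry per attempt.
#' @param is_forgery logical vector flagging forgery attempts.
#' @return named numeric vector `c(far, frr)`.
#' @export
far_frr <- function(accepted, is_forgery) {
  if (length(accepted) != length(is_forgery)) {
    stop("evaluation error: accepted and is_forgery must align", call. = FALSE)
  }
  n_forg <- sum(is_forgery); n_gen <- sum(!is_forgery)
  if (n_forg == 0 || n_gen == 0) {
    stop("undefined-rate error: need at least one genuine and one forgery ",
         "attempt", call. = FALSE)
  }
  c(far = 100 * sum(accepted & is_forgery) / n_forg,
    frr = 100 * sum(!accepted & !is_forgery) / n_gen)
}

#' Detection error tradeoff curve
#'
#' Sweeps a decision threshold over the pooled score range and records
#' (threshold, FAR, FRR) at each point, with acceptance meaning
#' `score > threshold`. FAR is nonincreasing and FRR nondecreasing along
#' the sweep.
#'
#' @param genuine_scores,forgery_scores nonempty numeric score vectors.
#' @param thresholds optional explicit sweep; default is every distinct
#'   observed score shifted by +/- a small epsilon.
#' @return data frame of class `det_curve` with columns `threshold`,
#'   `far`, `frr` (percent), ordered by increasing threshold.
#' @export
det_curve <- function(genuine_scores, forgery_scores, thresholds = NULL) {
  if (!length(genuine_scores) || !length(forgery_scores)) {
    stop("evaluation error: both score lists must be nonempty", call. = FALSE)
  }
  if (is.null(thresholds)) {
    s <- sort(unique(c(genuine_scores, forgery_scores)))
    eps <- max(1e-9, min(diff(c(0, s))) / 4)
    thresholds <- sort(unique(c(s - eps, s + eps)))
  }
  thresholds <- sort(thresholds)
  far <- vapply(thresholds, function(th) 100 * mean(forgery_scores > th),
                numeric(1))
  frr <- vapply(thresholds, function(th) 100 * mean(genuine_scores <= th),
                numeric(1))
  structure(data.frame(threshold = thresholds, far = far, frr = frr),
            class = c("det_curve", "data.frame"))
}

#' Half total error rate
#'
#' `HTER = (FAR + FRR) / 2`. At the zero-false-rejection operating point
#' this halves the false acceptance rate.
#'
#' @param far,frr rates in percent, each in \[0, 100\].
#' @return HTER in percent (full precision; see [truncate_rate()] for the
#'   two-decimal reporting convention).
#' @export
hter <- function(far, frr) {
  if (any(c(far, frr) < 0) || any(c(far, frr) > 100)) {
    stop("domain error: rates must lie in [0, 100]", call. = FALSE)
  }
  (far + frr) / 2
}

#' Truncate a percentage for reporting
#'
#' Reported rates are truncated (not rounded) to `digits` decimals, e.g.
#' 1.875 prints as 1.87.
#'
#' @param x numeric rates.
#' @param digits decimal places kept (default 2).
#' @return truncated values.
#' @export
truncate_rate <- function(x, digits = 2L) {
  trunc(x * 10^digits) / 10^digits
}

#' Equal error rate from a DET curve
#'
#' The rate at the operating point where FAR equals FRR, linearly
#' interpolated between the two sweep points straddling the crossing
#' (finite score sets rarely cross exactly).
#'
#' @param curve a [det_curve()] (>= 2 points).
#' @return EER in percent.
#' @export
eer <- function(curve) {
  if (!inherits(curve, "data.frame") || nrow(curve) < 2L) {
    stop("evaluation error: degenerate DET curve", call. = FALSE)
  }
  d <- curve$far - curve$frr # nonincreasing along the sweep
  exact <- which(d == 0)
  if (length(exact)) return(curve$far[exact[1]])
  i <- which(d[-nrow(curve)] > 0 & d[-1] < 0)
  if (!length(i)) {
    # no crossing: the closest approach is the best available estimate
    j <- which.min(abs(d))
    return((curve$far[j] + curve$frr[j]) / 2)
  }
  i <- i[1]
  w <- d[i] / (d[i] - d[i + 1])
  far_at <- curve$far[i] + w * (curve$far[i + 1] - curve$far[i])
  frr_at <- curve$frr[i] + w * (curve$frr[i + 1] - curve$frr[i])
  (far_at + frr_at) / 2
}

#' Summarize verification security metrics
#'
#' @param accepted,is_forgery as in [far_frr()].
#' @return named vector with `far`, `frr`, `tpr`, `hter` (percent).
#' @export
security_summary <- function(accepted, is_forgery) {
  r <- far_frr(accepted, is_forgery)
  c(far = unname(r["far"]), frr = unname(r["frr"]),
    tpr = 100 - unname(r["frr"]),
    hter = hter(unname(r["far"]), unname(r["frr"])))
}
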