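#' Calibrate per-identity acceptance thresholds
#'
#' Builds one acceptance threshold per enrolled identity from that
#' identity's genuine calibration scores (posteriors the model assigns to
#' the identity's own training samples).
#'
#' Policies:
#' * `"zero_frr"` (default): `th_i` sits an epsilon below the smallest
#'   genuine calibration score (clipped to \[0, 1)), so every calibration
#'   sample is accepted — the zero-false-rejection (100% TPR) operating
#'   point at which security is then measured by the false acceptance
#'   rate alone.
#' * `"sweep"`: scans all candidate thresholds (observed scores +/- eps)
#'   and keeps, per identity, the one maximizing TPR - FAR against the
#'   supplied `forgery_scores` proxies.
#'
#' @param genuine_scores named list: identity -> numeric vector of genuine
#'   calibration scores in \[0, 1\] (nonempty).
#' @param policy `"zero_frr"` or `"sweep"`.
#' @param epsilon threshold margin below the minimum score (default 1e-6).
#' @param forgery_scores for `"sweep"`: named list of forgery proxy scores
#'   per identity.
#' @return object of class `verification_templates`: named list with
#'   `threshold` and `calibration` per identity.
#' @export
calibrate_thresholds <- function(genuine_scores,
                                 policy = c("zero_frr", "sweep"),
                                 epsilon = 1e-6, forgery_scores = NULL) {
  policy <- match.arg(policy)
  if (!length(genuine_scores) || is.null(names(genuine_scores))) {
    stop("calibration error: need a named, nonempty score list", call. = FALSE)
  }
  templates <- lapply(names(genuine_scores), function(id) {
    s <- genuine_scores[[id]]
    if (!length(s)) {
      stop("calibration error: no genuine scores for identity ", id,
           call. = FALSE)
    }
    th <- if (policy == "zero_frr") {
      min(max(min(s) - epsilon, 0), 1 - epsilon)
    } else {
      fs <- forgery_scores[[id]]
      if (is.null(fs) || !length(fs)) {
        stop("calibration error: sweep policy needs forgery proxy scores for ",
             id, call. = FALSE)
      }
      cand <- sort(unique(c(s - epsilon, s + epsilon, fs - epsilon,
                            fs + epsilon, 0)))
      cand <- cand[cand >= 0 & cand < 1]
      obj <- vapply(cand, function(th) {
        mean(s > th) - mean(fs > th)
      }, numeric(1))
      cand[which.max(obj)]
    }
    list(identity = id, threshold = th, calibration = s)
  })
  names(templates) <- names(genuine_scores)
  structure(templates, class = "verification_templates")
}

#' @export
print.verification_templates <- function(x, ...) {
  cat(sprintf("<verification_templates> %d identities; thresholds %.4g-%.4g\n",
              length(x), min(vapply(x, `[[`, 0, "threshold")),
              max(vapply(x, `[[`, 0, "threshold"))))
  invisible(x)
}

#' Decide a verification claim
#'
#' Accepts the claim iff the matching score strictly exceeds the claimed
#' identity's calibrated threshold (`score > th_i`); an exactly-threshold
#' score is rejected.
#'
#' @param score matching score in \[0, 1\] for the claimed identity: a
#'   unimodal posterior or a rule-normalized fused score (see
#'   [normalized_fused_score()]).
#' @param claimed_identity identity label being claimed.
#' @param templates a [calibrate_thresholds()] result.
#' @param channel label recorded in the outcome (e.g. `"signature"`,
#'   `"eeg"`, `"borda"`).
#' @return object of class `verification_outcome` with fields
#'   `claimed_identity`, `score`, `threshold`, `decision`
#'   (`"accept"`/`"reject"`), `channel`.
#' @export
verify_claim <- function(score, claimed_identity, templates,
                         channel = "fused") {
  tpl <- templates[[as.character(claimed_identity)]]
  if (is.null(tpl)) {
    stop("template error: no template for identity ", claimed_identity,
         call. = FALSE)
  }
  structure(list(claimed_identity = claimed_identity, score = score,
                 threshold = tpl$threshold,
                 decision = if (score > tpl$threshold) "accept" else "reject",
                 channel = channel),
            class = "verification_outcome")
}

#' @export
print.verification_outcome <- function(x, ...) {
  cat(sprintf("<verification_outcome> claim %s [%s]: score %.4f vs th %.4f -> %s\n",
              x$claimed_identity, x$channel, x$score, x$threshold, x$decision))
  invisible(x)
}
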