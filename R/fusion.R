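#' Assemble per-classifier posteriors into a posterior set
#'
#' A posterior set collects the class-posterior vectors produced by R
#' independent classifiers (here typically R = 2: signature and EEG) for
#' one test sample, as an R x m matrix with one row per classifier.
#'
#' @param ... numeric posterior vectors of equal length, or a single
#'   matrix with classifiers in rows.
#' @return numeric matrix of class `posterior_set`.
#' @export
posterior_set <- function(...) {
  args <- list(...)
  P <- if (length(args) == 1L && is.matrix(args[[1]])) args[[1]]
       else do.call(rbind, args)
  if (is.null(P) || nrow(P) == 0L) {
    stop("configuration error: empty posterior set", call. = FALSE)
  }
  if (any(P < -1e-9) || any(abs(rowSums(P) - 1) > 1e-6)) {
    stop("each posterior vector must be nonnegative and sum to 1",
         call. = FALSE)
  }
  structure(P, class = c("posterior_set", "matrix"))
}

new_fused_decision <- function(scores, rule, classifier = NA_integer_) {
  mx <- max(scores)
  tie <- sum(abs(scores - mx) < 1e-12) > 1L
  structure(list(winner = which.max(scores), # first max = lowest index
                 scores = as.numeric(scores), rule = rule, tie = tie,
                 classifier = classifier),
            class = "fused_decision")
}

#' @export
print.fused_decision <- function(x, ...) {
  cat(sprintf("<fused_decision> rule=%s winner=class %d%s\n  scores: %s\n",
              x$rule, x$winner, if (x$tie) " (tie)" else "",
              paste(signif(x$scores, 4), collapse = " ")))
  invisible(x)
}

as_pset <- function(posteriors) {
  if (inherits(posteriors, "posterior_set")) posteriors
  else posterior_set(posteriors)
}

#' Sum-rule decision fusion
#'
#' Fused score of class j is the sum over classifiers of the posterior
#' assigned to j; the winner is the argmax (ties broken toward the lowest
#' class index).
#'
#' @param posteriors a [posterior_set()] (or matrix acceptable to it).
#' @return a `fused_decision` with fields `winner`, `scores`, `rule`,
#'   `tie`.
#' @export
sum_rule <- function(posteriors) {
  P <- as_pset(posteriors)
  new_fused_decision(colSums(P), "sum")
}

#' Borda-count decision fusion
#'
#' Each classifier ranks the m classes by descending posterior; its
#' top-ranked class receives m points, the next m - 1, and so on. Classes
#' tied within one classifier's ranking share the mean of the points of
#' the tied ranks, so the total points handed out are always
#' `R * m * (m + 1) / 2`. The class with the largest summed points wins
#' (lowest index on ties).
#'
#' @inheritParams sum_rule
#' @return a `fused_decision`.
#' @export
borda_count <- function(posteriors) {
  P <- as_pset(posteriors)
  m <- ncol(P)
  pts <- apply(P, 1, function(p) m + 1 - rank(-p, ties.method = "average"))
  new_fused_decision(rowSums(matrix(pts, nrow = m)), "borda")
}

#' Max-rule decision fusion
#'
#' The winning class is the one holding the single largest posterior over
#' all classifiers and classes. Ties break toward the lowest class index,
#' then the lowest classifier index. The reported per-class scores are
#' the column maxima.
#'
#' @inheritParams sum_rule
#' @return a `fused_decision`; `$classifier` names the classifier that
#'   supplied the winning confidence.
#' @export
max_rule <- function(posteriors) {
  P <- as_pset(posteriors)
  scores <- apply(P, 2, max)
  d <- new_fused_decision(scores, "max")
  d$classifier <- which(abs(P[, d$winner] - scores[d$winner]) < 1e-15)[1]
  d
}

#' Apply a named fusion rule
#'
#' @inheritParams sum_rule
#' @param rule one of `"sum"`, `"borda"`, `"max"`.
#' @return a `fused_decision`.
#' @export
fuse <- function(posteriors, rule = c("sum", "borda", "max")) {
  rule <- match.arg(rule)
  switch(rule,
         sum = sum_rule(posteriors),
         borda = borda_count(posteriors),
         max = max_rule(posteriors))
}

#' Normalize a fused score to the [0, 1] threshold domain
#'
#' Sum-rule scores range over \[0, R\] and Borda points over
#' (roughly) \[R, R*m\]; dividing by the rule-specific maximum (R for sum,
#' R*m for Borda; max-rule confidences are already probabilities) puts
#' all rules on the probabilistic scale used by verification thresholds.
#'
#' @param decision a `fused_decision`.
#' @param n_classifiers R, the number of fused classifiers.
#' @param class_index which class's fused score to normalize (default:
#'   the winner).
#' @return scalar in \[0, 1\].
#' @export
normalized_fused_score <- function(decision, n_classifiers,
                                   class_index = decision$winner) {
  s <- decision$scores[class_index]
  m <- length(decision$scores)
  switch(decision$rule,
         sum = s / n_classifiers,
         borda = s / (n_classifiers * m),
         max = s,
         stop("unknown rule: ", decision$rule, call. = FALSE))
}
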