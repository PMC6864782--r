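#' Extract both feature sequences from a set of multimodal samples
#'
#' @param samples list of [multimodal_sample()]s.
#' @param ... passed to [build_eeg_features()].
#' @return list with `fs` (signature feature matrices), `fd` (EEG gamma
#'   feature matrices), `labels` (user ids), `claimed`, `is_forgery`,
#'   `ids`.
#' @export
extract_features <- function(samples, ...) {
  list(fs = lapply(samples, function(s) build_signature_features(s$signature)),
       fd = lapply(samples, function(s) build_eeg_features(s$eeg, ...)),
       labels = vapply(samples, `[[`, "", "user_id"),
       claimed = vapply(samples, `[[`, "", "claimed_identity"),
       is_forgery = vapply(samples, `[[`, TRUE, "is_forgery"),
       ids = vapply(samples, `[[`, "", "sample_id"))
}

train_modality_models <- function(feats, idx, n_classes, hidden_size,
                                  seed, ...) {
  cfg_fs <- blstm_config(n_classes, hidden_size = hidden_size,
                         seed = sub_seed(seed, .STREAM[["train"]], 11L), ...)
  cfg_fd <- blstm_config(n_classes, hidden_size = hidden_size,
                         seed = sub_seed(seed, .STREAM[["train"]], 12L), ...)
  list(fs = blstm_train(feats$fs[idx], feats$labels[idx], cfg_fs),
       fd = blstm_train(feats$fd[idx], feats$labels[idx], cfg_fd))
}

#' Cross-validated person identification, unimodal and fused
#'
#' Runs stratified k-fold cross-validation over a genuine cohort: per
#' fold, one bidirectional LSTM is trained on the signature features (FS)
#' and an independent one on the EEG gamma features (FD); held-out
#' samples are identified by each unimodal argmax and by decision fusion
#' of the two posterior vectors under the requested rules.
#'
#' @param cohort a [generate_cohort()] result (or any list of genuine
#'   `multimodal_sample`s under `$samples`).
#' @param n_folds folds (default 5: train on 8 of 10 samples per user,
#'   test on 2).
#' @param rules fusion rules to evaluate.
#' @param hidden_size LSTM cells per direction (default 64).
#' @param seed seed controlling fold assignment and training.
#' @param ... further [blstm_config()] arguments (e.g. `max_epochs`).
#' @return list with `accuracy` (named percentages: `signature`, `eeg`,
#'   one per fusion rule), `per_fold` (accuracy matrix folds x systems),
#'   and `details` (per test sample: truth, predictions per system).
#' @export
run_identification_cv <- function(cohort, n_folds = 5L,
                                  rules = c("sum", "borda", "max"),
                                  hidden_size = 64L, seed = 1L, ...) {
  samples <- cohort$samples
  feats <- extract_features(samples)
  users <- sort(unique(feats$labels))
  ids_per_user <- split(feats$ids, feats$labels)
  folds <- make_fold_splits(ids_per_user, n_folds = n_folds, seed = seed)
  systems <- c("signature", "eeg", rules)
  per_fold <- matrix(NA_real_, n_folds, length(systems),
                     dimnames = list(NULL, systems))
  details <- list()
  for (k in seq_len(n_folds)) {
    tr <- match(folds[[k]]$train_ids, feats$ids)
    te <- match(folds[[k]]$test_ids, feats$ids)
    models <- train_modality_models(feats, tr, length(users), hidden_size,
                                    sub_seed(seed, .STREAM[["train"]], k),
                                    ...)
    pred <- data.frame(sample_id = feats$ids[te], truth = feats$labels[te],
                       stringsAsFactors = FALSE)
    post_fs <- t(vapply(te, function(i)
      predict_posteriors(models$fs, feats$fs[[i]]), numeric(length(users))))
    post_fd <- t(vapply(te, function(i)
      predict_posteriors(models$fd, feats$fd[[i]]), numeric(length(users))))
    pred$signature <- models$fs$classes[max.col(post_fs, "first")]
    pred$eeg <- models$fd$classes[max.col(post_fd, "first")]
    for (r in rules) {
      pred[[r]] <- vapply(seq_along(te), function(i) {
        d <- fuse(posterior_set(post_fs[i, ], post_fd[i, ]), r)
        models$fs$classes[d$winner]
      }, "")
    }
    for (sys in systems) {
      per_fold[k, sys] <- identification_accuracy(pred[[sys]], pred$truth)
    }
    details[[k]] <- pred
  }
  list(accuracy = colMeans(per_fold), per_fold = per_fold,
       details = do.call(rbind, details))
}

#' End-to-end verification experiment against forgery attacks
#'
#' Trains both modality classifiers on a calibration portion of the
#' genuine cohort (all but one fold), calibrates per-identity thresholds
#' on the training samples' own-class posteriors under the requested
#' policy, then evaluates claims: held-out genuine samples claiming their
#' own identity, plus every forgery claiming its target. Decisions are
#' made per modality and for the fused score (normalized to \[0, 1\] by
#' its rule-specific maximum).
#'
#' @param cohort a genuine [generate_cohort()] result.
#' @param forgeries a [generate_forgeries()] result.
#' @param rule fusion rule for the multimodal score (default `"borda"`).
#' @param policy threshold policy, see [calibrate_thresholds()].
#' @param n_folds fold count defining the held-out genuine test portion
#'   (default 5: calibrate on 8 of 10, test 2).
#' @param hidden_size,seed,... as in [run_identification_cv()].
#' @return list with `summary` (matrix: channels x far/frr/tpr/hter, in
#'   percent), `calibration_tpr` (percent of calibration samples their
#'   own threshold accepts), `scores` (per attempt: channel scores,
#'   claimed identity, forgery flag), `templates`, `det` (DET curves per
#'   channel).
#' @export
run_verification <- function(cohort, forgeries, rule = "borda",
                             policy = "zero_frr", n_folds = 5L,
                             hidden_size = 64L, seed = 1L, ...) {
  feats <- extract_features(cohort$samples)
  users <- sort(unique(feats$labels))
  ids_per_user <- split(feats$ids, feats$labels)
  folds <- make_fold_splits(ids_per_user, n_folds = n_folds, seed = seed)
  tr <- match(folds[[1]]$train_ids, feats$ids)
  te <- match(folds[[1]]$test_ids, feats$ids)
  models <- train_modality_models(feats, tr, length(users), hidden_size,
                                  sub_seed(seed, .STREAM[["train"]], 99L),
                                  ...)

  score_claim <- function(fs_seq, fd_seq, claimed) {
    ps <- predict_posteriors(models$fs, fs_seq)
    pd <- predict_posteriors(models$fd, fd_seq)
    d <- fuse(posterior_set(ps, pd), rule)
    c(signature = unname(ps[claimed]), eeg = unname(pd[claimed]),
      fused = normalized_fused_score(d, 2L, match(claimed, users)))
  }

  # calibration: own-class scores of the training samples
  cal <- lapply(tr, function(i)
    score_claim(feats$fs[[i]], feats$fd[[i]], feats$labels[i]))
  cal_user <- feats$labels[tr]
  channels <- c("signature", "eeg", "fused")
  templates <- lapply(channels, function(ch) {
    sc <- split(vapply(cal, `[[`, 0, ch), cal_user)
    calibrate_thresholds(sc, policy = policy)
  })
  names(templates) <- channels

  calibration_tpr <- vapply(channels, function(ch) {
    acc <- vapply(seq_along(tr), function(j) {
      verify_claim(cal[[j]][[ch]], cal_user[j], templates[[ch]],
                   ch)$decision == "accept"
    }, TRUE)
    100 * mean(acc)
  }, numeric(1))

  # attempts: held-out genuine (claiming themselves) + all forgeries
  f_feats <- extract_features(forgeries$samples)
  attempts <- rbind(
    data.frame(idx = te, pool = "genuine",
               claimed = feats$labels[te], stringsAsFactors = FALSE),
    data.frame(idx = seq_along(f_feats$ids), pool = "forgery",
               claimed = f_feats$claimed, stringsAsFactors = FALSE))
  scores <- t(vapply(seq_len(nrow(attempts)), function(r) {
    i <- attempts$idx[r]
    if (attempts$pool[r] == "genuine") {
      score_claim(feats$fs[[i]], feats$fd[[i]], attempts$claimed[r])
    } else {
      score_claim(f_feats$fs[[i]], f_feats$fd[[i]], attempts$claimed[r])
    }
  }, numeric(3)))
  is_forg <- attempts$pool == "forgery"

  summary <- t(vapply(channels, function(ch) {
    acc <- vapply(seq_len(nrow(attempts)), function(r) {
      verify_claim(scores[r, ch], attempts$claimed[r], templates[[ch]],
                   ch)$decision == "accept"
    }, TRUE)
    security_summary(acc, is_forg)
  }, numeric(4)))

  det <- lapply(channels, function(ch) {
    det_curve(scores[!is_forg, ch], scores[is_forg, ch])
  })
  names(det) <- channels

  list(summary = summary, calibration_tpr = calibration_tpr,
       scores = data.frame(attempts, scores, stringsAsFactors = FALSE),
       templates = templates, det = det, rule = rule)
}
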