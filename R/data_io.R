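#' Construct a signature trace
#'
#' A dynamic (online) signature is the time-ordered sequence of pen
#' positions captured while signing on a touch device. Coordinates are in
#' device screen units with the origin at the top-left corner and y
#' increasing downward; normalization is deferred to the feature stage.
#'
#' @param x,y numeric coordinate vectors of equal length (>= 3 points).
#' @param t optional timestamps in milliseconds, nondecreasing.
#' @param sample_id,user_id opaque labels.
#' @param is_forgery logical flag.
#' @param claimed_identity for forgeries, the targeted genuine user;
#'   defaults to `user_id` for genuine traces.
#' @return An object of class `signature_trace` with a `points` data frame.
#' @export
signature_trace <- function(x, y, t = NULL, sample_id = NA_character_,
                            user_id = NA_character_, is_forgery = FALSE,
                            claimed_identity = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  if (length(x) < 3L) {
    stop("degenerate trace: a signature needs at least 3 points ",
         "(writing direction requires two neighbors)", call. = FALSE)
  }
  if (!is.null(t)) {
    t <- as.numeric(t)
    if (length(t) != length(x)) stop("timestamps length mismatch", call. = FALSE)
    if (any(diff(t) < 0)) stop("timestamps must be nondecreasing", call. = FALSE)
  }
  if (is.null(claimed_identity)) claimed_identity <- user_id
  structure(
    list(points = data.frame(x = x, y = y),
         t = t,
         sample_id = sample_id, user_id = user_id,
         is_forgery = isTRUE(is_forgery),
         claimed_identity = claimed_identity),
    class = "signature_trace")
}

#' @export
print.signature_trace <- function(x, ...) {
  cat(sprintf("<signature_trace> %d points, user %s, sample %s%s\n",
              nrow(x$points), x$user_id, x$sample_id,
              if (x$is_forgery) sprintf(" [forgery targeting %s]",
                                        x$claimed_identity) else ""))
  invisible(x)
}

#' Number of points in a signature trace
#' @param trace a `signature_trace`.
#' @return integer point count.
#' @export
n_points <- function(trace) nrow(trace$points)

# default Emotiv-style 14-channel montage
#' Default EEG channel montage
#'
#' The 14-electrode consumer montage (10-20 system subset) used as the
#' default channel set for recordings and the synthetic generator.
#' @return character vector of 14 channel names.
#' @export
default_eeg_channels <- function() {
  c("AF3", "AF4", "F3", "F4", "F7", "F8", "FC5", "FC6",
    "P7", "P8", "T7", "T8", "O1", "O2")
}

#' Construct an EEG recording
#'
#' @param data numeric matrix, one column per channel (samples x channels),
#'   values in microvolts.
#' @param sampling_rate sampling frequency in Hz (> 0).
#' @param channels channel names; defaults to [default_eeg_channels()] when
#'   the matrix has 14 columns, else `ch1..chK`.
#' @param sample_id,user_id opaque labels.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate, channels = NULL,
                          sample_id = NA_character_, user_id = NA_character_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be > 0", call. = FALSE)
  }
  if (is.null(channels)) {
    channels <- if (ncol(data) == 14L) default_eeg_channels()
                else paste0("ch", seq_len(ncol(data)))
  }
  if (length(channels) != ncol(data)) {
    stop(sprintf("channel error: %d channel names for %d data columns",
                 length(channels), ncol(data)), call. = FALSE)
  }
  colnames(data) <- channels
  structure(list(data = data, sampling_rate = sampling_rate,
                 channels = channels,
                 sample_id = sample_id, user_id = user_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              ncol(x$data), nrow(x$data), x$sampling_rate,
              nrow(x$data) / x$sampling_rate))
  invisible(x)
}

#' Bundle a signature and its simultaneous EEG into one sample
#'
#' @param signature a `signature_trace`.
#' @param eeg an `eeg_recording`.
#' @param user_id,sample_id labels; taken from the signature if missing.
#' @param is_forgery logical; `claimed_identity` names the targeted user.
#' @param claimed_identity label of the claimed (targeted) identity.
#' @return An object of class `multimodal_sample`.
#' @export
multimodal_sample <- function(signature, eeg, user_id = signature$user_id,
                              sample_id = signature$sample_id,
                              is_forgery = signature$is_forgery,
                              claimed_identity = signature$claimed_identity) {
  stopifnot(inherits(signature, "signature_trace"),
            inherits(eeg, "eeg_recording"))
  structure(list(signature = signature, eeg = eeg, user_id = user_id,
                 sample_id = sample_id, is_forgery = isTRUE(is_forgery),
                 claimed_identity = claimed_identity),
            class = "multimodal_sample")
}

# ---- file readers / writers -------------------------------------------------

#' Read a signature trajectory from a delimited text file
#'
#' Expects a CSV with a header naming at least columns `x` and `y` and
#' optionally `t` (milliseconds); one row per time sample, rows in capture
#' order (never reordered on read).
#'
#' @param path file path.
#' @inheritParams signature_trace
#' @return a `signature_trace`.
#' @export
read_signature_trace <- function(path, sample_id = NA_character_,
                                 user_id = NA_character_, is_forgery = FALSE,
                                 claimed_identity = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("parse error in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (!all(c("x", "y") %in% names(df))) {
    stop("parse error: expected columns x,y in ", path, call. = FALSE)
  }
  for (col in intersect(c("t", "x", "y"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop(sprintf("parse error in %s: non-numeric '%s' at line %d",
                   path, col, bad[1] + 1L), call. = FALSE) # +1 for header
    }
    df[[col]] <- v
  }
  if (nrow(df) < 3L) {
    stop("degenerate trace: ", path, " has fewer than 3 points", call. = FALSE)
  }
  signature_trace(df$x, df$y, t = if ("t" %in% names(df)) df$t,
                  sample_id = sample_id, user_id = user_id,
                  is_forgery = is_forgery, claimed_identity = claimed_identity)
}

#' Write a signature trajectory to CSV
#' @param trace a `signature_trace`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signature_trace <- function(trace, path) {
  df <- trace$points
  if (!is.null(trace$t)) df <- cbind(t = trace$t, df)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a multichannel EEG recording from a delimited text file
#'
#' Expects a CSV with one column per channel and a header of channel names.
#' When `channels` is given it must match the file's columns (a named
#' subset is selected in the requested order).
#'
#' @param path file path.
#' @param sampling_rate sampling frequency in Hz (files carry no rate; it
#'   comes from a sidecar config or manifest).
#' @param channels optional channel subset to select.
#' @inheritParams eeg_recording
#' @return an `eeg_recording`.
#' @export
read_eeg_recording <- function(path, sampling_rate, channels = NULL,
                               sample_id = NA_character_,
                               user_id = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE, fill = FALSE),
                 error = function(e) stop("parse error in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  mat <- as.matrix(df)
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(df, 1, function(r)
      sum(as.numeric(r))))))[1]
    stop("parse error in ", path, ": non-numeric data",
         if (!is.na(bad)) sprintf(" at line %d", bad + 1L), call. = FALSE)
  }
  if (!is.null(channels)) {
    missing_ch <- setdiff(channels, colnames(mat))
    if (length(missing_ch)) {
      stop("channel error: ", paste(missing_ch, collapse = ", "),
           " not present in ", path, call. = FALSE)
    }
    mat <- mat[, channels, drop = FALSE]
  }
  eeg_recording(mat, sampling_rate, channels = colnames(mat),
                sample_id = sample_id, user_id = user_id)
}

#' Write an EEG recording to CSV
#' @param recording an `eeg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_eeg_recording <- function(recording, path) {
  write.csv(as.data.frame(recording$data), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

# ---- dataset manifest -------------------------------------------------------

#' Write a dataset manifest
#'
#' The manifest is a JSON file listing, per sample: `sample_id`, `user_id`,
#' `is_forgery`, `claimed_identity`, relative `signature_file` and
#' `eeg_file` paths, and the EEG `sampling_rate`.
#'
#' @param manifest data frame with the columns above.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a dataset manifest
#' @param path manifest JSON path.
#' @return data frame of sample descriptors.
#' @export
read_manifest <- function(path) {
  jsonlite::fromJSON(path)
}

#' Load a multimodal dataset from a manifest
#' @param manifest_path path to a manifest JSON; file paths inside are
#'   resolved relative to its directory.
#' @return list of `multimodal_sample` objects.
#' @export
load_dataset <- function(manifest_path) {
  mf <- read_manifest(manifest_path)
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(mf)), function(i) {
    row <- mf[i, ]
    sig <- read_signature_trace(file.path(base, row$signature_file),
                                sample_id = row$sample_id,
                                user_id = row$user_id,
                                is_forgery = row$is_forgery,
                                claimed_identity = row$claimed_identity)
    eeg <- read_eeg_recording(file.path(base, row$eeg_file),
                              sampling_rate = row$sampling_rate,
                              sample_id = row$sample_id,
                              user_id = row$user_id)
    multimodal_sample(sig, eeg)
  })
}

# ---- cross-validation folds -------------------------------------------------

#' Stratified per-user cross-validation splits
#'
#' Partitions each user's samples across `n_folds` test sets so every
#' genuine sample is tested exactly once and per-user test counts are as
#' equal as possible (exactly equal when each user's sample count is a
#' multiple of `n_folds`, e.g. 10 samples over 5 folds gives 2 test
#' samples per user per fold). Remainder samples, when counts are not
#' multiples, are assigned one per fold starting from the first fold.
#'
#' @param sample_ids_per_user named list: user id -> character vector of
#'   that user's sample ids.
#' @param n_folds number of folds (>= 2).
#' @param seed integer seed controlling the per-user shuffles.
#' @return list of `fold_split` objects with fields `fold_index`,
#'   `train_ids`, `test_ids`.
#' @export
make_fold_splits <- function(sample_ids_per_user, n_folds = 5L, seed = 1L) {
  if (n_folds < 2L) stop("configuration error: n_folds must be >= 2",
                         call. = FALSE)
  users <- names(sample_ids_per_user)
  if (is.null(users)) stop("sample_ids_per_user must be a named list",
                           call. = FALSE)
  # per-fold test id accumulator
  test_sets <- vector("list", n_folds)
  for (ui in seq_along(users)) {
    ids <- as.character(sample_ids_per_user[[ui]])
    perm <- with_rng(sub_seed(seed, .STREAM[["fold"]], ui),
                    sample(length(ids)))
    ids <- ids[perm]
    fold_of <- rep(seq_len(n_folds), length.out = length(ids))
    for (k in seq_len(n_folds)) {
      test_sets[[k]] <- c(test_sets[[k]], ids[fold_of == k])
    }
  }
  all_ids <- unlist(lapply(sample_ids_per_user, as.character),
                    use.names = FALSE)
  lapply(seq_len(n_folds), function(k) {
    structure(list(fold_index = k,
                   train_ids = setdiff(all_ids, test_sets[[k]]),
                   test_ids = test_sets[[k]]),
              class = "fold_split")
  })
}
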