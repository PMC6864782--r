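#' Configuration for the synthetic multimodal cohort generator
#'
#' Defaults reproduce the acquisition design the package emulates: 33
#' genuine users contributing 10 signing sessions each (330 genuine
#' samples) and 25 forgers attacking every genuine user twice (1650
#' forgery samples), with 14-channel EEG at 128 Hz recorded while
#' signing. Forgers practice the target signature, so forged trajectories
#' are shape-similar to the genuine template
#' (`signature_mimic_fidelity` close to 1), but their EEG carries their
#' own spectral signature (`eeg_mimic_fidelity = 0`): brain activity
#' cannot be imitated by watching a signature.
#'
#' @param n_genuine genuine users (default 33).
#' @param samples_per_user signing sessions per genuine user (default 10).
#' @param n_forgers forging users (default 25).
#' @param attempts_per_target forgery attempts per forger per genuine
#'   user (default 2).
#' @param eeg_channels EEG channel count (default 14, named per
#'   [default_eeg_channels()]).
#' @param sampling_rate EEG sampling rate in Hz (default 128).
#' @param signature_rate pen sampling rate in Hz (default 60, a typical
#'   touch-event rate).
#' @param signature_mimic_fidelity in \[0, 1\]: 1 means the forged
#'   trajectory is statistically indistinguishable from genuine; default
#'   0.9 (a practiced skilled forgery).
#' @param eeg_mimic_fidelity in \[0, 1\]: fraction of the target's
#'   stroke-locked gamma activity present in the forger's EEG; default 0.
#' @param signature_jitter per-point Gaussian noise, in units of the
#'   signature bounding box (default 0.004).
#' @param template_jitter per-sample control-point wobble (default 0.02).
#' @param eeg_background 1/f background noise amplitude, microvolts RMS
#'   (default 6).
#' @param gamma_amp_range per-channel gamma burst amplitude range,
#'   microvolts (default 4-14); each user draws a channel profile from it.
#' @param seed master integer seed; all per-user/per-sample randomness is
#'   derived from it through independent sub-streams, so regeneration is
#'   exact and adding users does not perturb existing ones.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_genuine = 33L, samples_per_user = 10L,
                          n_forgers = 25L, attempts_per_target = 2L,
                          eeg_channels = 14L, sampling_rate = 128,
                          signature_rate = 60,
                          signature_mimic_fidelity = 0.9,
                          eeg_mimic_fidelity = 0,
                          signature_jitter = 0.004, template_jitter = 0.02,
                          eeg_background = 6, gamma_amp_range = c(4, 14),
                          seed = 1L) {
  counts <- c(n_genuine, samples_per_user, n_forgers, attempts_per_target,
              eeg_channels)
  if (any(counts < 1)) stop("all counts must be >= 1", call. = FALSE)
  if (signature_mimic_fidelity < 0 || signature_mimic_fidelity > 1 ||
      eeg_mimic_fidelity < 0 || eeg_mimic_fidelity > 1) {
    stop("mimic fidelities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_genuine = as.integer(n_genuine),
                 samples_per_user = as.integer(samples_per_user),
                 n_forgers = as.integer(n_forgers),
                 attempts_per_target = as.integer(attempts_per_target),
                 eeg_channels = as.integer(eeg_channels),
                 sampling_rate = sampling_rate,
                 signature_rate = signature_rate,
                 signature_mimic_fidelity = signature_mimic_fidelity,
                 eeg_mimic_fidelity = eeg_mimic_fidelity,
                 signature_jitter = signature_jitter,
                 template_jitter = template_jitter,
                 eeg_background = eeg_background,
                 gamma_amp_range = gamma_amp_range,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# ---- identity models --------------------------------------------------------

# One user's stable traits: a signature template (2-5 cubic Bezier
# strokes with per-stroke durations) and an EEG gamma signature (a
# per-channel amplitude profile with 1-2 oscillator frequencies per
# channel in the 26-40 Hz gamma band, burst-locked to pen strokes).
user_identity_model <- function(config, model_seed) {
  with_rng(model_seed, {
    n_strokes <- sample(2:5, 1)
    duration <- runif(1, 1.5, 4)
    strokes <- replicate(n_strokes, {
      cp <- matrix(runif(8), 4, 2) # control points in the unit box
      cp
    }, simplify = FALSE)
    props <- runif(n_strokes, 0.5, 1.5)
    props <- props / sum(props)
    nch <- config$eeg_channels
    amp <- runif(nch, config$gamma_amp_range[1], config$gamma_amp_range[2])
    freqs <- lapply(seq_len(nch), function(ch) runif(sample(1:2, 1), 26, 40))
    list(strokes = strokes, props = props, duration = duration,
         eeg_amp = amp, eeg_freqs = freqs)
  })
}

bezier_points <- function(cp, n) {
  u <- seq(0, 1, length.out = n)
  b <- cbind((1 - u)^3, 3 * (1 - u)^2 * u, 3 * (1 - u) * u^2, u^3)
  b %*% cp
}

# Sample one signing act from an identity model. cp_offset is an optional
# list of per-stroke control-point offsets (the forger's residual motor
# distortion); jitter_mult scales the per-sample noise sources.
sample_signature <- function(model, config, jitter_mult = 1,
                             cp_offset = NULL) {
  n_total <- max(round(model$duration * config$signature_rate),
                 4L * length(model$strokes))
  pts <- vector("list", length(model$strokes))
  stroke_times <- matrix(0, length(model$strokes), 2)
  t0 <- 0
  for (k in seq_along(model$strokes)) {
    cp <- model$strokes[[k]] +
      matrix(rnorm(8, 0, config$template_jitter * jitter_mult), 4, 2)
    if (!is.null(cp_offset)) cp <- cp + cp_offset[[k]]
    nk <- max(4L, round(model$props[k] * n_total))
    pts[[k]] <- bezier_points(cp, nk)
    dt <- model$props[k] * model$duration
    stroke_times[k, ] <- c(t0, t0 + dt)
    t0 <- t0 + dt
  }
  xy <- do.call(rbind, pts)
  # small per-sample affine perturbation: rotation, scale, translation
  th <- rnorm(1, 0, 2 * pi / 180) * jitter_mult
  sc <- 1 + rnorm(1, 0, 0.03) * jitter_mult
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xy <- sweep(xy %*% t(rot) * sc, 2, rnorm(2, 0, 0.02) * jitter_mult, `+`)
  xy <- xy + matrix(rnorm(length(xy), 0, config$signature_jitter *
                            jitter_mult), ncol = 2)
  # map to device screen units (top-left origin, y downward)
  xy <- sweep(xy * 600, 2, c(150, 400), `+`)
  t_ms <- seq(0, model$duration, length.out = nrow(xy)) * 1000
  list(x = xy[, 1], y = xy[, 2], t = t_ms, stroke_times = stroke_times,
       duration = model$duration)
}

# 1/f (pink) background noise via spectral shaping, sd scaled to `amp`.
pink_noise <- function(n, fs, amp) {
  w <- rnorm(n)
  W <- stats::fft(w)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f) # two-sided spectrum
  W <- W / sqrt(pmax(f, 1))
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  if (sd(x) > 0) x <- x / sd(x) * amp
  x
}

# Stroke-locked gamma oscillations for one EEG component; `weight` scales
# the component (used to blend forger/target activity).
gamma_component <- function(model, stroke_times, tt, weight = 1) {
  nch <- length(model$eeg_amp)
  out <- matrix(0, length(tt), nch)
  if (weight <= 0) return(out)
  env <- rep(0, length(tt))
  for (k in seq_len(nrow(stroke_times))) {
    sel <- tt >= stroke_times[k, 1] & tt <= stroke_times[k, 2]
    if (any(sel)) {
      u <- (tt[sel] - stroke_times[k, 1]) /
        max(stroke_times[k, 2] - stroke_times[k, 1], 1e-9)
      env[sel] <- pmax(env[sel], 0.5 - 0.5 * cos(2 * pi * u))
    }
  }
  for (ch in seq_len(nch)) {
    osc <- rep(0, length(tt))
    for (f in model$eeg_freqs[[ch]]) {
      osc <- osc + sin(2 * pi * f * tt + runif(1, 0, 2 * pi))
    }
    out[, ch] <- weight * model$eeg_amp[ch] * env * osc
  }
  out
}

# One EEG recording time-locked to a signing act: 1/f background on every
# channel plus stroke-locked gamma bursts from one or two identity
# models (blended when a forger partially mimics the target's activity).
sample_eeg <- function(own_model, stroke_times, config,
                       target_model = NULL, target_weight = 0) {
  lead <- 0.25
  dur <- max(stroke_times) + 2 * lead
  n <- round(dur * config$sampling_rate)
  tt <- (seq_len(n) - 1) / config$sampling_rate - lead
  sig <- gamma_component(own_model, stroke_times, tt, 1 - target_weight)
  if (!is.null(target_model) && target_weight > 0) {
    sig <- sig + gamma_component(target_model, stroke_times, tt,
                                 target_weight)
  }
  bg <- vapply(seq_len(config$eeg_channels), function(ch) {
    pink_noise(n, config$sampling_rate, config$eeg_background)
  }, numeric(n))
  sig + bg
}

# ---- cohort -----------------------------------------------------------------

genuine_user_ids <- function(config) sprintf("u%02d", seq_len(config$n_genuine))
forger_ids <- function(config) sprintf("f%02d", seq_len(config$n_forgers))

make_sample <- function(own_model, config, subseed, user_id, sample_id,
                        is_forgery = FALSE, claimed = user_id,
                        jitter_mult = 1, cp_offset = NULL,
                        target_model = NULL, target_weight = 0) {
  with_rng(subseed, {
    sig <- sample_signature(own_model, config, jitter_mult, cp_offset)
    eeg <- sample_eeg(own_model, sig$stroke_times, config,
                      target_model, target_weight)
  })
  multimodal_sample(
    signature_trace(sig$x, sig$y, t = sig$t, sample_id = sample_id,
                    user_id = user_id, is_forgery = is_forgery,
                    claimed_identity = claimed),
    eeg_recording(eeg, config$sampling_rate,
                  channels = if (config$eeg_channels == 14L)
                    default_eeg_channels()
                  else paste0("ch", seq_len(config$eeg_channels)),
                  sample_id = sample_id, user_id = user_id))
}

#' Generate a synthetic genuine cohort
#'
#' Creates `n_genuine * samples_per_user` multimodal samples: each user's
#' signature template is redrawn with session-level jitter (control-point
#' wobble, a small affine perturbation, per-point noise) and each EEG
#' recording combines 1/f background noise with the user's stroke-locked
#' gamma oscillators over the duration of that signing act. Entirely
#' deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param dir optional directory: when given, signature/EEG CSV files and
#'   a JSON manifest are written there (see [write_cohort()]).
#' @return object of class `multimodal_cohort`: list with `samples`
#'   (list of [multimodal_sample()]), `users`, `models` (identity models,
#'   needed to derive forgeries), `manifest` (data frame) and `config`.
#' @export
generate_cohort <- function(config = cohort_config(), dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  users <- genuine_user_ids(config)
  models <- lapply(seq_along(users), function(u) {
    user_identity_model(config, sub_seed(config$seed,
                                         .STREAM[["user_template"]], u))
  })
  names(models) <- users
  samples <- list()
  for (u in seq_along(users)) {
    for (s in seq_len(config$samples_per_user)) {
      sid <- sprintf("%s_s%02d", users[u], s)
      samples[[sid]] <- make_sample(
        models[[u]], config,
        sub_seed(config$seed, .STREAM[["sample_jitter"]], u * 1000L + s),
        user_id = users[u], sample_id = sid)
    }
  }
  manifest <- cohort_manifest(samples, config)
  cohort <- structure(list(samples = samples, users = users,
                           models = models, manifest = manifest,
                           config = config),
                      class = "multimodal_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.multimodal_cohort <- function(x, ...) {
  nf <- sum(vapply(x$samples, `[[`, TRUE, "is_forgery"))
  cat(sprintf("<multimodal_cohort> %d users, %d samples (%d forgeries)\n",
              length(x$users), length(x$samples), nf))
  invisible(x)
}

#' Generate practiced forgery attacks against a cohort
#'
#' Every forger attacks every genuine user `attempts_per_target` times.
#' A forged signature blends the target's stroke template with the
#' forger's residual motor distortion, scaled by
#' `1 - signature_mimic_fidelity` (a practiced forger reproduces the
#' shape closely), plus session jitter slightly above genuine levels.
#' The forged EEG, by contrast, is built from the forger's own identity
#' model: at the default `eeg_mimic_fidelity = 0` it carries none of the
#' target's gamma signature.
#'
#' @param config the [cohort_config()] used for the cohort.
#' @param cohort the [generate_cohort()] result being attacked.
#' @return list with `samples` (list of forged [multimodal_sample()]s,
#'   `claimed_identity` naming the attacked user) and `manifest`.
#' @export
generate_forgeries <- function(config, cohort) {
  stopifnot(inherits(cohort, "multimodal_cohort"))
  if (!all(cohort$users %in% names(cohort$models))) {
    stop("configuration error: cohort lacks identity models", call. = FALSE)
  }
  forgers <- forger_ids(config)
  fmodels <- lapply(seq_along(forgers), function(f) {
    user_identity_model(config, sub_seed(config$seed,
                                         .STREAM[["forger_template"]], f))
  })
  names(fmodels) <- forgers
  fid <- config$signature_mimic_fidelity
  samples <- list()
  for (f in seq_along(forgers)) {
    for (u in seq_along(cohort$users)) {
      target <- cohort$models[[u]]
      for (a in seq_len(config$attempts_per_target)) {
        sid <- sprintf("%s_%s_a%d", forgers[f], cohort$users[u], a)
        ss <- sub_seed(config$seed, .STREAM[["forgery_jitter"]],
                       f * 100000L + u * 100L + a)
        # forger's residual distortion of the target's stroke template
        cp_offset <- with_rng(sub_seed(ss, .STREAM[["forger_template"]], 1L), {
          lapply(target$strokes, function(cp) {
            matrix(rnorm(8, 0, 0.08 * (1 - fid)), 4, 2)
          })
        })
        # forged model: target's pen template, forger's EEG traits
        forged <- target
        forged$eeg_amp <- fmodels[[f]]$eeg_amp
        forged$eeg_freqs <- fmodels[[f]]$eeg_freqs
        samples[[sid]] <- make_sample(
          forged, config, ss, user_id = forgers[f], sample_id = sid,
          is_forgery = TRUE, claimed = cohort$users[u],
          jitter_mult = 1 + (1 - fid),
          cp_offset = cp_offset,
          target_model = target,
          target_weight = config$eeg_mimic_fidelity)
      }
    }
  }
  list(samples = samples, manifest = cohort_manifest(samples, config))
}

cohort_manifest <- function(samples, config) {
  do.call(rbind, lapply(samples, function(s) {
    data.frame(sample_id = s$sample_id, user_id = s$user_id,
               is_forgery = s$is_forgery,
               claimed_identity = s$claimed_identity,
               signature_file = paste0(s$sample_id, "_sig.csv"),
               eeg_file = paste0(s$sample_id, "_eeg.csv"),
               sampling_rate = config$sampling_rate,
               stringsAsFactors = FALSE)
  })) -> mf
  rownames(mf) <- NULL
  mf
}

#' Write a cohort (or forgery set) to disk
#'
#' Emits one signature CSV and one EEG CSV per sample plus a
#' `manifest.json`, in the same dialect [load_dataset()] reads back.
#'
#' @param cohort a `multimodal_cohort` or a [generate_forgeries()] result.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$samples) {
    write_signature_trace(s$signature,
                          file.path(dir, paste0(s$sample_id, "_sig.csv")))
    write_eeg_recording(s$eeg,
                        file.path(dir, paste0(s$sample_id, "_eeg.csv")))
  }
  write_manifest(cohort$manifest, file.path(dir, "manifest.json"))
  invisible(file.path(dir, "manifest.json"))
}

#' Mean gamma-band channel profile of one sample
#'
#' The per-channel gamma energies of [build_eeg_features()] averaged over
#' analysis frames: a compact spatial fingerprint of a recording used to
#' compare users and to check that forged EEG matches the forger rather
#' than the target.
#'
#' @param sample a [multimodal_sample()] or an [eeg_recording()].
#' @param ... passed to [build_eeg_features()].
#' @return numeric vector, one mean gamma energy per channel.
#' @export
gamma_profile <- function(sample, ...) {
  eeg <- if (inherits(sample, "multimodal_sample")) sample$eeg else sample
  colMeans(build_eeg_features(eeg, ...))
}
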