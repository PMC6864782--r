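test_that("cohort and forgery counts follow the configuration products", {
  cfg <- tiny_cohort_config()
  co <- generate_cohort(cfg)
  expect_length(co$samples, cfg$n_genuine * cfg$samples_per_user)
  expect_false(any(vapply(co$samples, `[[`, TRUE, "is_forgery")))
  fo <- generate_forgeries(cfg, co)
  expect_length(fo$samples,
                cfg$n_forgers * cfg$attempts_per_target * cfg$n_genuine)
  expect_true(all(vapply(fo$samples, `[[`, TRUE, "is_forgery")))
  expect_setequal(unique(vapply(fo$samples, `[[`, "", "claimed_identity")),
                  co$users)
})

test_that("generation is exactly reproducible from the seed", {
  co1 <- generate_cohort(tiny_cohort_config(seed = 77))
  co2 <- generate_cohort(tiny_cohort_config(seed = 77))
  expect_identical(co1$manifest, co2$manifest)
  expect_identical(co1$samples[[3]]$signature$points,
                   co2$samples[[3]]$signature$points)
  expect_identical(co1$samples[[3]]$eeg$data, co2$samples[[3]]$eeg$data)
  co3 <- generate_cohort(tiny_cohort_config(seed = 78))
  expect_false(identical(co1$samples[[3]]$eeg$data,
                         co3$samples[[3]]$eeg$data))
  # byte-identical written manifests
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_manifest(co1$manifest, file.path(d1, "m.json"))
  write_manifest(co2$manifest, file.path(d2, "m.json"))
  expect_identical(readLines(file.path(d1, "m.json")),
                   readLines(file.path(d2, "m.json")))
})

test_that("samples respect the declared geometry and rates", {
  cfg <- tiny_cohort_config()
  co <- generate_cohort(cfg)
  s <- co$samples[[1]]
  expect_gte(n_points(s$signature), 3L)
  expect_equal(ncol(s$eeg$data), cfg$eeg_channels)
  expect_equal(s$eeg$sampling_rate, cfg$sampling_rate)
  # EEG covers the signing act (signature span + lead-in/out)
  sig_span <- max(s$signature$t) / 1000
  eeg_span <- nrow(s$eeg$data) / s$eeg$sampling_rate
  expect_gte(eeg_span, sig_span)
})

test_that("users carry distinct gamma-band channel profiles", {
  cfg <- cohort_config(n_genuine = 3, samples_per_user = 6, seed = 101)
  co <- generate_cohort(cfg)
  labels <- vapply(co$samples, `[[`, "", "user_id")
  profs <- t(vapply(co$samples, gamma_profile, numeric(cfg$eeg_channels)))
  centroids <- apply(profs, 2, function(col) tapply(col, labels, mean))
  between <- min(dist(centroids))
  within <- max(vapply(unique(labels), function(u) {
    p <- profs[labels == u, , drop = FALSE]
    mean(sqrt(rowSums(sweep(p, 2, colMeans(p))^2)))
  }, numeric(1)))
  expect_gt(between, within) # profiles separate users with margin
})

test_that("forged EEG matches the forger, not the target, at zero fidelity", {
  cfg <- cohort_config(n_genuine = 2, samples_per_user = 5, n_forgers = 2,
                       attempts_per_target = 2, eeg_mimic_fidelity = 0,
                       seed = 102)
  co <- generate_cohort(cfg)
  fo <- generate_forgeries(cfg, co)
  labels <- vapply(co$samples, `[[`, "", "user_id")
  profs <- t(vapply(co$samples, gamma_profile, numeric(cfg$eeg_channels)))
  target_centroid <- function(u) colMeans(profs[labels == u, , drop = FALSE])
  # forger f01's attempts on u01 across both attempts
  f_attempts <- fo$samples[grepl("^f01_u01", names(fo$samples))]
  f_profiles <- t(vapply(f_attempts, gamma_profile,
                         numeric(cfg$eeg_channels)))
  # the same forger's profile centroid from their attacks on the other user
  f_other <- t(vapply(fo$samples[grepl("^f01_u02", names(fo$samples))],
                      gamma_profile, numeric(cfg$eeg_channels)))
  d_to_forger <- sqrt(sum((colMeans(f_profiles) - colMeans(f_other))^2))
  d_to_target <- sqrt(sum((colMeans(f_profiles) - target_centroid("u01"))^2))
  expect_lt(d_to_forger, d_to_target)
})

test_that("forged signatures converge to genuine statistics as fidelity -> 1", {
  shape_spread <- function(cfg) {
    co <- generate_cohort(cfg)
    fo <- generate_forgeries(cfg, co)
    # mean normalized-trajectory distance from each forgery of u01 to the
    # genuine u01 session mean
    feat <- function(s) {
      f <- build_signature_features(s$signature)[, 1:2]
      apply(f, 2, function(col) stats::quantile(col, 1:3 / 4))
    }
    gen <- vapply(co$samples[grepl("^u01", names(co$samples))], feat,
                  matrix(0, 3, 2))
    gmean <- apply(gen, c(1, 2), mean)
    forg <- vapply(fo$samples[grepl("u01_a", names(fo$samples))], feat,
                   matrix(0, 3, 2))
    mean(apply(forg, 3, function(f) sqrt(sum((f - gmean)^2))))
  }
  base <- list(n_genuine = 2L, samples_per_user = 6L, n_forgers = 3L,
               attempts_per_target = 2L, seed = 103L)
  lo <- do.call(cohort_config, c(base, signature_mimic_fidelity = 0.2))
  hi <- do.call(cohort_config, c(base, signature_mimic_fidelity = 1))
  expect_lt(shape_spread(hi), shape_spread(lo))
})

test_that("increasing EEG noise degrades profile separability monotonically", {
  sep <- vapply(c(6, 40, 200), function(noise) {
    cfg <- cohort_config(n_genuine = 3, samples_per_user = 4,
                         eeg_background = noise, seed = 104)
    co <- generate_cohort(cfg)
    labels <- vapply(co$samples, `[[`, "", "user_id")
    profs <- t(vapply(co$samples, gamma_profile, numeric(14)))
    centroids <- apply(profs, 2, function(col) tapply(col, labels, mean))
    within <- mean(vapply(unique(labels), function(u) {
      p <- profs[labels == u, , drop = FALSE]
      mean(sqrt(rowSums(sweep(p, 2, colMeans(p))^2)))
    }, numeric(1)))
    min(dist(centroids)) / within
  }, numeric(1))
  expect_true(all(diff(sep) < 0))
})
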