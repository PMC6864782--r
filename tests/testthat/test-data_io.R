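test_that("signature files round-trip losslessly and preserve point order", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y", "0,0", "1,0", "2,0"), path)
  tr <- read_signature_trace(path)
  expect_equal(n_points(tr), 3L)
  expect_equal(tr$points$x, c(0, 1, 2))

  tr2 <- signature_trace(x = c(0.125, -3.5, 7.25, 2), y = c(1, 2, 3, 4.5),
                         t = c(0, 10, 20, 30), sample_id = "s1")
  out <- withr::local_tempfile(fileext = ".csv")
  write_signature_trace(tr2, out)
  back <- read_signature_trace(out, sample_id = "s1")
  expect_identical(back$points, tr2$points)
  expect_identical(back$t, tr2$t)
})

test_that("malformed or degenerate signature files raise informative errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y", "0,0", "1,0"), p)
  expect_error(read_signature_trace(p), "degenerate")

  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y", "0,0", "oops,1", "2,2"), p2)
  expect_error(read_signature_trace(p2), "line 3")

  expect_error(signature_trace(1:3, 1:3, t = c(3, 2, 1)), "nondecreasing")
})

test_that("EEG files round-trip and validate channel declarations", {
  p <- withr::local_tempfile(fileext = ".csv")
  m <- matrix(round(rnorm(128 * 14), 6), 128, 14)
  rec <- eeg_recording(m, sampling_rate = 128)
  write_eeg_recording(rec, p)
  back <- read_eeg_recording(p, sampling_rate = 128)
  expect_equal(unname(back$data), unname(m))
  expect_equal(back$channels, default_eeg_channels())
  expect_equal(nrow(back$data) / back$sampling_rate, 1) # 1 s duration

  # 13-column file cannot satisfy a 14-name channel request
  p13 <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(m[, 1:13]), p13, row.names = FALSE)
  expect_error(read_eeg_recording(p13, 128, channels = default_eeg_channels()),
               "channel error")
  expect_error(eeg_recording(m[, 1:13], 128,
                             channels = default_eeg_channels()),
               "channel error")

  # ragged rows are a parse error
  pr <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,c", "1,2,3", "4,5", "6,7,8"), pr)
  expect_error(read_eeg_recording(pr, 128), "parse error")
})

test_that("a written cohort loads back through its manifest", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(tiny_cohort_config(), dir = dir)
  loaded <- load_dataset(file.path(dir, "manifest.json"))
  expect_length(loaded, length(co$samples))
  i <- 5L
  expect_equal(loaded[[i]]$signature$points$x,
               co$samples[[i]]$signature$points$x, tolerance = 1e-9)
  expect_equal(unname(loaded[[i]]$eeg$data), unname(co$samples[[i]]$eeg$data),
               tolerance = 1e-9)
  expect_equal(loaded[[i]]$user_id, co$samples[[i]]$user_id)
})

test_that("fold splits partition each user's samples evenly", {
  ids <- setNames(lapply(1:33, function(u) sprintf("u%02d_s%02d", u, 1:10)),
                  sprintf("u%02d", 1:33))
  folds <- make_fold_splits(ids, n_folds = 5, seed = 9)
  expect_length(folds, 5L)
  # each fold tests exactly 2 samples per user, 66 in total
  for (f in folds) {
    expect_length(f$test_ids, 66L)
    expect_length(intersect(f$train_ids, f$test_ids), 0L)
    per_user <- table(sub("_s.*", "", f$test_ids))
    expect_true(all(per_user == 2L))
  }
  # test sets cover all 330 ids exactly once
  all_test <- unlist(lapply(folds, `[[`, "test_ids"))
  expect_length(all_test, 330L)
  expect_setequal(all_test, unlist(ids))
  expect_false(any(duplicated(all_test)))
})

test_that("fold splits are deterministic and validate configuration", {
  ids <- list(a = paste0("a", 1:7), b = paste0("b", 1:7))
  f1 <- make_fold_splits(ids, 3, seed = 4)
  f2 <- make_fold_splits(ids, 3, seed = 4)
  expect_identical(f1, f2)
  # non-multiple counts still partition exactly
  all_test <- unlist(lapply(f1, `[[`, "test_ids"))
  expect_setequal(all_test, unlist(ids))
  expect_false(any(duplicated(all_test)))
  expect_error(make_fold_splits(ids, 1), "n_folds")
})
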