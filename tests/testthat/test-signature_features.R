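trace_of <- function(x, y) signature_trace(x, y)

test_that("normalization fixes origin and bounding-box diagonal", {
  tr <- trace_of(c(0, 3, 1), c(0, 4, 2))
  nt <- normalize_trace(tr)
  expect_equal(unlist(nt$points[1, ]), c(x = 0, y = 0))
  d <- sqrt(diff(range(nt$points$x))^2 + diff(range(nt$points$y))^2)
  expect_equal(d, 1)
  # idempotent, and invariant to uniform scaling of the input
  expect_equal(normalize_trace(nt)$points, nt$points, tolerance = 1e-12)
  scaled <- trace_of(10 * tr$points$x, 10 * tr$points$y)
  expect_equal(normalize_trace(scaled)$points, nt$points, tolerance = 1e-12)
  expect_error(normalize_trace(trace_of(c(1, 1, 1), c(2, 2, 2))),
               "degenerate")
})

test_that("writing direction matches axis angles on canonical lines", {
  horiz <- trace_of(c(0, 1, 2), c(0, 0, 0))
  expect_equal(writing_direction(horiz, 2),
               c(alpha_deg = 0, beta_deg = 90))
  diag45 <- trace_of(c(0, 1, 2), c(0, 1, 2))
  expect_equal(writing_direction(diag45, 2),
               c(alpha_deg = 45, beta_deg = 45))
  vert <- trace_of(c(0, 0, 0), c(0, 1, 2))
  expect_equal(writing_direction(vert, 2),
               c(alpha_deg = 90, beta_deg = 0))
  expect_error(writing_direction(horiz, 1), "interior")
})

test_that("feature frames satisfy the angle complementarity invariant", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      n <- sample(5:40, 1)
      tr <- trace_of(cumsum(rnorm(n)), cumsum(rnorm(n)))
      fs <- build_signature_features(tr)
      expect_equal(nrow(fs), n)          # one frame per point
      expect_equal(ncol(fs), 4L)
      expect_equal(unname(fs[, "alpha_deg"] + fs[, "beta_deg"]),
                   rep(90, n), tolerance = 1e-9)
      expect_true(all(fs[, "alpha_deg"] >= 0 & fs[, "alpha_deg"] <= 90))
    }
  })
})

test_that("rotating a trace by 90 degrees swaps alpha and beta", {
  withr::with_seed(6, {
    n <- 25
    x <- cumsum(rnorm(n)); y <- cumsum(rnorm(n))
    fs <- build_signature_features(trace_of(x, y))
    fs_rot <- build_signature_features(trace_of(-y, x))
    expect_equal(fs_rot[, "alpha_deg"], fs[, "beta_deg"], tolerance = 1e-9)
    expect_equal(fs_rot[, "beta_deg"], fs[, "alpha_deg"], tolerance = 1e-9)
  })
})

test_that("angles are invariant to traversal direction, shift and scale", {
  withr::with_seed(7, {
    n <- 30
    x <- cumsum(rnorm(n)); y <- cumsum(rnorm(n))
    fs <- build_signature_features(trace_of(x, y))
    # reversed trace: same undirected lines at mirrored frame positions
    fs_rev <- build_signature_features(trace_of(rev(x), rev(y)))
    expect_equal(fs_rev[, "alpha_deg"], rev(fs[, "alpha_deg"]),
                 tolerance = 1e-9)
    # affine shift + scale leaves the W columns untouched
    fs_aff <- build_signature_features(trace_of(3 * x + 11, 3 * y - 2))
    expect_equal(fs_aff[, c("alpha_deg", "beta_deg")],
                 fs[, c("alpha_deg", "beta_deg")], tolerance = 1e-9)
  })
})

test_that("straight-line traces give constant angle columns", {
  tr <- trace_of(seq(0, 5, length.out = 12), seq(0, 5, length.out = 12))
  fs <- build_signature_features(tr)
  expect_equal(unname(fs[, "alpha_deg"]), rep(45, 12), tolerance = 1e-9)
})

test_that("pen holds carry angles forward instead of crashing", {
  # points 3 and 4 coincide -> the chord at j = 3..4 can degenerate
  tr <- trace_of(c(0, 1, 2, 2, 2, 3), c(0, 0, 0, 0, 0, 1))
  fs <- build_signature_features(tr)
  expect_false(any(is.na(fs)))
  expect_equal(nrow(fs), 6L)
  # a trace that opens with a hold starts at the 0/90 convention
  tr2 <- trace_of(c(0, 0, 0, 1, 2), c(0, 0, 0, 1, 2))
  fs2 <- build_signature_features(tr2)
  expect_equal(unname(fs2[1, c("alpha_deg", "beta_deg")]), c(0, 90))
  expect_false(any(is.na(fs2)))
})
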