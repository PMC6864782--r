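# Independent brute-force oracles used to cross-check the implementation.

# literal O(N^2) evaluation of the DFT sum
naive_dft <- function(x) {
  N <- length(x)
  vapply(0:(N - 1), function(u) {
    sum(x * exp(complex(imaginary = -2 * pi * u * (0:(N - 1)) / N)))
  }, complex(1))
}

# enumeration oracles for the three fusion rules (P: classifiers x classes)
oracle_sum_winner <- function(P) {
  totals <- vapply(seq_len(ncol(P)), function(j) sum(P[, j]), numeric(1))
  which(totals == max(totals))[1]
}

oracle_borda_points <- function(P) {
  m <- ncol(P)
  totals <- numeric(m)
  for (i in seq_len(nrow(P))) {
    # rank classes by descending posterior; tied classes share mean points
    p <- P[i, ]
    pts <- numeric(m)
    for (j in seq_len(m)) {
      n_better <- sum(p > p[j])
      n_tied <- sum(p == p[j])
      # occupied ranks n_better+1 .. n_better+n_tied; points m+1-rank
      pts[j] <- mean(m + 1 - (n_better + seq_len(n_tied)))
    }
    totals <- totals + pts
  }
  totals
}

oracle_max_winner <- function(P) {
  best <- -Inf; win <- NA_integer_
  for (j in seq_len(ncol(P))) {   # class-major: lowest class index wins ties
    for (i in seq_len(nrow(P))) {
      if (P[i, j] > best) { best <- P[i, j]; win <- j }
    }
  }
  win
}

random_posterior_set <- function(R, m) {
  P <- matrix(stats::rexp(R * m), R, m)
  P / rowSums(P)
}

# small cohort shared by several test files (built once per test run)
tiny_cohort_config <- function(seed = 42L) {
  cohort_config(n_genuine = 3L, samples_per_user = 4L, n_forgers = 2L,
                attempts_per_target = 1L, seed = seed)
}

# linearly separable toy sequence task: class k has mean shift k in the
# first feature
make_separable_sequences <- function(n_per_class, n_classes = 2L, T = 15L,
                                     D = 3L, seed = 1L) {
  withr::with_seed(seed, {
    seqs <- list(); labs <- character(0)
    for (k in seq_len(n_classes)) {
      for (r in seq_len(n_per_class)) {
        m <- matrix(rnorm(T * D, 0, 0.3), T, D)
        m[, 1] <- m[, 1] + k
        seqs[[length(seqs) + 1L]] <- m
        labs <- c(labs, paste0("class", k))
      }
    }
    list(sequences = seqs, labels = labs)
  })
}
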