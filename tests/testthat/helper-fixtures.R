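# Shared fixtures, all generated in code.

# sinusoidal multi-channel recording: channel i = sin(2*pi*f_i*t) + offset
make_sine_recording <- function(subject = "sub1", freqs = c(8, 12), fs = 160,
                                duration = 3, offsets = NULL) {
  t <- (seq_len(round(fs * duration)) - 1) / fs
  if (is.null(offsets)) offsets <- rep(0, length(freqs))
  data <- t(vapply(seq_along(freqs),
                   function(i) sin(2 * pi * freqs[i] * t) + offsets[i],
                   numeric(length(t))))
  eeg_recording(subject, data, fs, condition = "synthetic")
}

# small, quick cohort for pipeline tests (cached per session)
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(cohort_spec(
        n_subjects = 6, n_channels = 4, duration_s = 20,
        informative_channels = c(1, 2), seed = 202
      ))
    }
    cache
  }
})

small_cohort_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- extract_feature_matrix(cohort_instances(small_cohort()))
    }
    cache
  }
})

# DTLZ1 test problem (3 objectives, real genes in [0,1])
dtlz1_fitness <- function(ch) {
  x <- ch$reals
  m <- 3
  xm <- x[m:length(x)]
  k <- length(xm)
  g <- 100 * (k + sum((xm - 0.5)^2 - cos(20 * pi * (xm - 0.5))))
  c(0.5 * x[1] * x[2] * (1 + g),
    0.5 * x[1] * (1 - x[2]) * (1 + g),
    0.5 * (1 - x[1]) * (1 + g))
}

dtlz1_encoding <- function(n_var = 7) {
  nsga_encoding(real_ranges = rep(list(c(0, 1)), n_var))
}

# independent O(n^2) dominance oracle for non-dominated sorting
brute_force_fronts <- function(obj) {
  n <- nrow(obj)
  remaining <- seq_len(n)
  fronts <- list()
  while (length(remaining) > 0L) {
    nd <- remaining[vapply(remaining, function(i) {
      !any(vapply(remaining, function(j) {
        j != i && all(obj[j, ] <= obj[i, ]) && any(obj[j, ] < obj[i, ])
      }, logical(1)))
    }, logical(1))]
    fronts[[length(fronts) + 1L]] <- nd
    remaining <- setdiff(remaining, nd)
  }
  fronts
}

# independent quadratic-time LOF oracle, straight from the k-distance /
# reachability-distance / lrd definitions (novelty variant: queries scored
# against the training set only)
brute_force_lof <- function(train, query, k) {
  n <- nrow(train)
  d_tt <- as.matrix(stats::dist(train))
  nn_t <- lapply(seq_len(n), function(i) setdiff(order(d_tt[i, ]), i)[seq_len(k)])
  kdist <- vapply(seq_len(n), function(i) d_tt[i, nn_t[[i]][k]], numeric(1))
  lrd_t <- vapply(seq_len(n), function(i) {
    reach <- pmax(kdist[nn_t[[i]]], d_tt[i, nn_t[[i]]])
    1 / max(mean(reach), 1e-10)
  }, numeric(1))
  vapply(seq_len(nrow(query)), function(qi) {
    dq <- sqrt(colSums((t(train) - query[qi, ])^2))
    nb <- order(dq)[seq_len(k)]
    reach <- pmax(kdist[nb], dq[nb])
    lrd_q <- 1 / max(mean(reach), 1e-10)
    mean(lrd_t[nb]) / lrd_q
  }, numeric(1))
}
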