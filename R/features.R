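#' Feature configuration
#'
#' @param higuchi_kmax Maximum segment length k for the Higuchi curve-length
#'   sums (default 10; must be >= 2 and below the shortest sub-band length).
#' @param log_floor_epsilon Floor inside the log10 of the energy features,
#'   preventing -Inf on silent bands (default 1e-12).
#'
#' @return A list of class `feature_config`. The per-band feature order is
#'   fixed: instantaneous energy, Teager energy, Higuchi FD, Petrosian FD.
#' @export
feature_config <- function(higuchi_kmax = 10, log_floor_epsilon = 1e-12) {
  stopifnot(higuchi_kmax >= 2, log_floor_epsilon > 0)
  structure(
    list(higuchi_kmax = as.integer(higuchi_kmax),
         log_floor_epsilon = log_floor_epsilon,
         feature_order = c("instantaneous_energy", "teager_energy",
                           "higuchi_fd", "petrosian_fd")),
    class = "feature_config"
  )
}

#' Instantaneous energy
#'
#' Log-scaled mean power of the band: `log10(mean(x^2))`, floored at
#' `epsilon` so silent bands stay finite.
#'
#' @param x Numeric vector.
#' @param epsilon Log floor.
#' @return A single value.
#' @export
instantaneous_energy <- function(x, epsilon = 1e-12) {
  if (!all(is.finite(x))) stop("non-finite input")
  log10(max(mean(x^2), epsilon))
}

#' Teager energy
#'
#' Log-scaled mean of the Teager-Kaiser operator
#' `|x_n^2 - x_{n-1} x_{n+1}|` over interior samples; sensitive to both
#' amplitude and frequency modulation.
#'
#' @param x Numeric vector, length >= 3.
#' @param epsilon Log floor.
#' @return A single value.
#' @export
teager_energy <- function(x, epsilon = 1e-12) {
  if (length(x) < 3L) stop("Teager energy needs at least 3 samples")
  if (!all(is.finite(x))) stop("non-finite input")
  n <- length(x)
  op <- abs(x[2:(n - 1L)]^2 - x[1:(n - 2L)] * x[3:n])
  log10(max(mean(op), epsilon))
}

#' Higuchi fractal dimension
#'
#' Builds the normalised curve lengths `L(k)` for `k = 1..kmax`, averaging
#' over the k possible start offsets, and returns the slope of the
#' least-squares line of `ln L(k)` against `ln(1/k)`. A straight line gives
#' 1, white noise approaches 2. Constant signals return 1 by convention.
#'
#' @param x Numeric vector, length >= kmax + 1.
#' @param kmax Maximum segment length (default 10).
#' @return Estimated fractal dimension.
#' @export
higuchi_fd <- function(x, kmax = 10) {
  n <- length(x)
  if (n < kmax + 1L) stop("signal too short for kmax")
  if (max(x) - min(x) < .Machine$double.eps) return(1.0)
  lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    adk <- abs(diff(x, lag = k))            # increment of every offset curve
    grp <- ((seq_along(adk) - 1L) %% k)     # offset m each increment belongs to
    sums <- rowsum(adk, grp)
    counts <- tabulate(grp + 1L, nbins = max(grp) + 1L)
    counts <- counts[counts > 0L]
    # mean absolute increment, renormalised to the full record length
    lm <- sums[, 1L] * (n - 1) / (counts * k) / k
    lk[k] <- mean(lm)
  }
  ok <- is.finite(log(lk))
  if (sum(ok) < 2L) return(1.0)
  fit <- stats::lm.fit(cbind(1, log(1 / seq_len(kmax)[ok])), log(lk[ok]))
  unname(fit$coefficients[2L])
}

#' Petrosian fractal dimension
#'
#' Binarises the signal by the sign of its first differences and counts the
#' sign changes `N_delta` (zero differences do not break a run), then returns
#' `log10(N) / (log10(N) + log10(N / (N + 0.4 N_delta)))`. Monotone and
#' constant signals give exactly 1.
#'
#' @param x Numeric vector, length >= 2.
#' @return Estimated fractal dimension.
#' @export
petrosian_fd <- function(x) {
  n <- length(x)
  if (n < 2L) stop("Petrosian FD needs at least 2 samples")
  s <- sign(diff(x))
  s <- s[s != 0]
  n_delta <- if (length(s) > 1L) sum(diff(s) != 0) else 0L
  log10(n) / (log10(n) + log10(n / (n + 0.4 * n_delta)))
}

# the four per-band features in the fixed order
band_features <- function(band, feat_cfg) {
  c(
    instantaneous_energy = instantaneous_energy(band, feat_cfg$log_floor_epsilon),
    teager_energy = teager_energy(band, feat_cfg$log_floor_epsilon),
    higuchi_fd = higuchi_fd(band, min(feat_cfg$higuchi_kmax, length(band) - 1L)),
    petrosian_fd = petrosian_fd(band)
  )
}

#' Per-instance feature vector
#'
#' For each selected channel (in mask order): decompose the channel's window
#' into sub-bands, compute the four features per band, and concatenate bands
#' then channels. EMD (2 selected IMFs) gives 8 features per channel; the
#' 3-level DWT (4 sub-bands) gives 16.
#'
#' @param instance A channels-by-samples matrix (one window), or one row of
#'   the tibble returned by [segment_instances()].
#' @param channel_mask Integer indices or logical mask selecting >= 1 channel.
#' @param decomp_cfg A [decomposition_config()].
#' @param feat_cfg A [feature_config()].
#'
#' @return Named numeric vector, length `n_selected * bands * 4`; names are
#'   `<channel>.<band>.<feature>`.
#' @export
extract_features <- function(instance, channel_mask = NULL,
                             decomp_cfg = decomposition_config(),
                             feat_cfg = feature_config()) {
  m <- if (is.matrix(instance)) instance else instance$data[[1L]]
  if (is.null(channel_mask)) channel_mask <- seq_len(nrow(m))
  if (is.logical(channel_mask)) channel_mask <- which(channel_mask)
  if (length(channel_mask) < 1L) stop("channel mask selects no channels")
  ch_names <- rownames(m)
  if (is.null(ch_names)) ch_names <- paste0("CH", seq_len(nrow(m)))
  out <- lapply(channel_mask, function(ch) {
    bands <- decompose_signal(m[ch, ], decomp_cfg)
    v <- unlist(lapply(names(bands), function(b) {
      f <- band_features(bands[[b]], feat_cfg)
      names(f) <- paste(ch_names[ch], b, names(f), sep = ".")
      f
    }))
    v
  })
  unlist(out)
}

#' Feature matrix for a set of instances
#'
#' Applies [extract_features()] to every instance (all channels) and returns
#' a tidy feature matrix; this is the full per-channel feature cache that the
#' channel-selection fitness later column-slices, so it is computed once per
#' dataset.
#'
#' @param instances Instance tibble from [segment_instances()] (rows from
#'   several subjects may be bound together).
#' @param decomp_cfg A [decomposition_config()].
#' @param feat_cfg A [feature_config()].
#'
#' @return A tibble with `subject_id`, `instance`, and one numeric column per
#'   feature named `<channel>.<band>.<feature>`.
#' @export
extract_feature_matrix <- function(instances,
                                   decomp_cfg = decomposition_config(),
                                   feat_cfg = feature_config()) {
  stopifnot(nrow(instances) > 0)
  rows <- lapply(instances$data, extract_features,
                 channel_mask = NULL, decomp_cfg = decomp_cfg, feat_cfg = feat_cfg)
  mat <- do.call(rbind, rows)
  if (!all(is.finite(mat))) stop("non-finite feature values produced")
  dplyr::bind_cols(
    tibble::tibble(subject_id = instances$subject_id,
                   instance = instances$instance),
    tibble::as_tibble(mat)
  )
}

# feature column names belonging to the given channel names, in mask order
feature_columns_for_channels <- function(feature_names, channels) {
  unlist(lapply(channels, function(ch) {
    feature_names[startsWith(feature_names, paste0(ch, "."))]
  }))
}
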