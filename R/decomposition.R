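#' Decomposition configuration
#'
#' Settings shared by the two sub-band decompositions. EMD keeps the
#' `n_selected_imfs` intrinsic mode functions closest to the raw signal in
#' Minkowski distance of order `minkowski_p`; the DWT uses `wavelet` with
#' `levels` cascade levels plus the final approximation.
#'
#' @param method `"emd"` or `"dwt"`.
#' @param minkowski_p Minkowski order for IMF selection (>= 1, default 2).
#' @param n_selected_imfs Number of IMFs kept (default 2).
#' @param wavelet Wavelet name; only `"bior2.2"` is built in.
#' @param levels DWT cascade depth (default 3, giving bands D1, D2, D3, A3).
#' @param sift_sd_threshold Cauchy-like SD threshold stopping each sift
#'   (default 0.2).
#' @param max_imfs Cap on extracted IMFs (default 10).
#' @param max_sift_iters Cap on sifting iterations per IMF (default 100).
#'
#' @return A list of class `decomposition_config`.
#' @export
decomposition_config <- function(method = c("dwt", "emd"),
                                 minkowski_p = 2,
                                 n_selected_imfs = 2,
                                 wavelet = "bior2.2",
                                 levels = 3,
                                 sift_sd_threshold = 0.2,
                                 max_imfs = 10,
                                 max_sift_iters = 100) {
  method <- match.arg(method)
  stopifnot(minkowski_p >= 1, n_selected_imfs >= 1, levels >= 1)
  structure(
    list(method = method, minkowski_p = minkowski_p,
         n_selected_imfs = n_selected_imfs, wavelet = wavelet,
         levels = levels, sift_sd_threshold = sift_sd_threshold,
         max_imfs = max_imfs, max_sift_iters = max_sift_iters),
    class = "decomposition_config"
  )
}

# local extrema of a discrete series; plateaus contribute one extremum
find_extrema <- function(x) {
  n <- length(x)
  d <- diff(x)
  # carry the sign of the previous non-zero slope through plateaus
  s <- sign(d)
  for (i in seq_along(s)) if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  turns <- which(diff(s) != 0) + 1L
  maxima <- turns[s[turns - 1L] > 0]
  minima <- turns[s[turns - 1L] < 0]
  list(maxima = maxima, minima = minima)
}

# cubic-spline envelope through extrema, with mirrored-extrema end extension
envelope <- function(t_ext, v_ext, n) {
  k <- length(t_ext)
  take <- seq_len(min(2L, k))
  tl <- 2 - rev(t_ext[take]); vl <- rev(v_ext[take])
  take_r <- seq.int(max(1L, k - 1L), k)
  tr <- 2 * n - rev(t_ext[take_r]); vr <- rev(v_ext[take_r])
  tt <- c(tl, t_ext, tr); vv <- c(vl, v_ext, vr)
  keep <- !duplicated(tt)
  stats::splinefun(tt[keep], vv[keep], method = "natural")(seq_len(n))
}

#' Empirical mode decomposition
#'
#' Decomposes a single-channel signal into intrinsic mode functions by
#' sifting: at each step the mean of the cubic-spline envelopes through the
#' local maxima and minima is subtracted until the normalised squared change
#' between consecutive sift iterates falls below `sift_sd_threshold`.
#' Extraction stops when the residual has at most two extrema (monotone
#' remainder) or `max_imfs` is reached. By construction
#' `sum(imfs) + residual` reproduces the input to rounding error.
#'
#' @param signal Numeric vector, length >= 8, all finite.
#' @param cfg A [decomposition_config()].
#'
#' @return A list with `imfs` (list of numeric vectors, possibly empty) and
#'   `residual`.
#' @export
emd <- function(signal, cfg = decomposition_config(method = "emd")) {
  if (length(signal) < 8L) stop("EMD needs at least 8 samples")
  if (!all(is.finite(signal))) stop("EMD input contains non-finite samples")
  n <- length(signal)
  residual <- as.numeric(signal)
  imfs <- list()
  repeat {
    ext <- find_extrema(residual)
    if (length(ext$maxima) + length(ext$minima) <= 2L ||
        length(ext$maxima) < 2L || length(ext$minima) < 2L ||
        length(imfs) >= cfg$max_imfs) {
      break
    }
    h <- residual
    for (iter in seq_len(cfg$max_sift_iters)) {
      e <- find_extrema(h)
      if (length(e$maxima) < 2L || length(e$minima) < 2L) break
      upper <- envelope(e$maxima, h[e$maxima], n)
      lower <- envelope(e$minima, h[e$minima], n)
      m <- (upper + lower) / 2
      h_new <- h - m
      sd_crit <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.xmin)
      h <- h_new
      if (sd_crit < cfg$sift_sd_threshold) break
    }
    imfs[[length(imfs) + 1L]] <- h
    residual <- residual - h
  }
  list(imfs = imfs, residual = residual)
}

#' Minkowski distance between two vectors
#'
#' `(sum(|x - y|^p))^(1/p)`; with `p = 2` the Euclidean distance.
#'
#' @param x,y Numeric vectors of equal length.
#' @param p Order (>= 1).
#' @return A single distance.
#' @export
minkowski_distance <- function(x, y, p = 2) {
  stopifnot(length(x) == length(y), p >= 1)
  sum(abs(x - y)^p)^(1 / p)
}

#' Select the IMFs closest to the raw signal
#'
#' Ranks IMFs by Minkowski distance to the original signal and returns the
#' `n_selected` closest, in ascending-distance order. IMFs dominated by
#' numerical artefacts of the sifting sit far from the signal, so this keeps
#' the informative modes. If the decomposition produced fewer IMFs than
#' requested, the residual is appended so downstream feature vectors keep a
#' fixed width.
#'
#' @param signal Original signal.
#' @param imfs List of IMFs from [emd()].
#' @param n_selected Number of bands to return (default 2).
#' @param p Minkowski order (default 2).
#' @param residual Residual from [emd()], used only for padding.
#'
#' @return A list of band vectors with names `IMF_a`, `IMF_b`, ... (padding
#'   bands are named `residual`).
#' @export
select_imfs_minkowski <- function(signal, imfs, n_selected = 2, p = 2,
                                  residual = NULL) {
  if (length(imfs) == 0L) {
    if (is.null(residual)) stop("degenerate decomposition: no IMFs")
    imfs <- list(residual)
    res_pad <- TRUE
  }
  d <- vapply(imfs, minkowski_distance, numeric(1), y = signal, p = p)
  ord <- order(d)
  sel <- imfs[ord][seq_len(min(n_selected, length(imfs)))]
  names(sel) <- paste0("IMF_", letters[seq_along(sel)])
  while (length(sel) < n_selected) {
    if (is.null(residual)) stop("too few IMFs and no residual to pad with")
    sel <- c(sel, list(residual = residual))
  }
  sel
}

# bior2.2 analysis/synthesis filter bank (decomposition low/high,
# reconstruction low/high), standard published coefficients
bior22_filters <- function() {
  list(
    dec_lo = sqrt(2) / 8 * c(0, -1, 2, 6, 2, -1),
    dec_hi = sqrt(2) / 4 * c(0, 1, -2, 1, 0, 0),
    rec_lo = sqrt(2) / 4 * c(0, 1, 2, 1, 0, 0),
    rec_hi = sqrt(2) / 8 * c(0, 1, 2, -6, 2, 1)
  )
}

# symmetric (half-sample) signal extension by m samples each side
symmetric_extend <- function(x, m) {
  n <- length(x)
  left <- rev(seq_len(min(m, n)))
  right <- n + 1L - seq_len(min(m, n))
  c(x[left], x, x[right])
}

# one analysis level: convolve the symmetric extension, downsample by 2;
# output length floor((n + flen - 1) / 2)
dwt_step <- function(x, filt) {
  flen <- length(filt)
  n <- length(x)
  ext <- symmetric_extend(x, flen - 1L)
  full <- stats::convolve(ext, rev(filt), type = "open")
  full[seq.int(flen + 1L, by = 2L, length.out = (n + flen - 1L) %/% 2L)]
}

# one synthesis level: upsample by 2, convolve, sum branches, trim transient
idwt_step <- function(ca, cd, filters) {
  up <- function(c) { u <- numeric(2L * length(c)); u[seq.int(1L, by = 2L, length.out = length(c))] <- c; u }
  flen <- length(filters$rec_lo)
  ya <- stats::convolve(up(ca), rev(filters$rec_lo), type = "open")
  yd <- stats::convolve(up(cd), rev(filters$rec_hi), type = "open")
  y <- ya + yd
  out_len <- 2L * length(ca) - flen + 2L
  y[seq.int(flen - 1L, length.out = out_len)]
}

#' Discrete wavelet decomposition into sub-bands
#'
#' Three-level (by default) bior2.2 cascade with symmetric signal extension.
#' Returns the detail coefficients of each level plus the final
#' approximation, ordered `[D1, D2, D3, A3]` — four sub-bands covering, for a
#' 160 Hz signal, roughly 40–80, 20–40, 10–20 and 0–10 Hz.
#'
#' @param signal Numeric vector at least as long as the wavelet filter (6
#'   samples for bior2.2).
#' @param cfg A [decomposition_config()].
#'
#' @return A list of class `subband_set`: `bands` (named list of coefficient
#'   vectors), `band_labels`, `source_method`.
#' @export
dwt_decompose <- function(signal, cfg = decomposition_config(method = "dwt")) {
  if (cfg$wavelet != "bior2.2") stop("only the bior2.2 wavelet is built in")
  f <- bior22_filters()
  if (length(signal) < length(f$dec_lo)) {
    stop("signal shorter than the bior2.2 filter (6 samples)")
  }
  if (!all(is.finite(signal))) stop("DWT input contains non-finite samples")
  details <- vector("list", cfg$levels)
  ca <- as.numeric(signal)
  for (lev in seq_len(cfg$levels)) {
    details[[lev]] <- dwt_step(ca, f$dec_hi)
    ca <- dwt_step(ca, f$dec_lo)
  }
  bands <- c(details, list(ca))
  labels <- c(paste0("D", seq_len(cfg$levels)), paste0("A", cfg$levels))
  names(bands) <- labels
  structure(
    list(bands = bands, band_labels = labels, source_method = "dwt"),
    class = "subband_set"
  )
}

#' Inverse of [dwt_decompose()]
#'
#' Reconstructs the original signal from a `subband_set`; bior2.2 is a
#' perfect-reconstruction filter pair, so the round trip is exact to rounding
#' error.
#'
#' @param sb A `subband_set` from [dwt_decompose()].
#' @param length_out Original signal length (trims the final synthesis step).
#' @return Numeric vector.
#' @export
dwt_reconstruct <- function(sb, length_out = NULL) {
  stopifnot(inherits(sb, "subband_set"))
  f <- bior22_filters()
  bands <- sb$bands
  levels <- length(bands) - 1L
  ca <- bands[[levels + 1L]]
  for (lev in rev(seq_len(levels))) {
    cd <- bands[[lev]]
    if (length(ca) == length(cd) + 1L) ca <- ca[-length(ca)]
    ca <- idwt_step(ca, cd, f)
  }
  if (!is.null(length_out)) ca <- ca[seq_len(length_out)]
  ca
}

#' Decompose a signal into its feature sub-bands
#'
#' Dispatches on the configured method: EMD followed by Minkowski selection
#' of the two closest IMFs (2 bands), or the bior2.2 DWT (4 bands).
#'
#' @param signal Numeric vector.
#' @param cfg A [decomposition_config()].
#' @return Named list of band vectors in the fixed feature-vector order.
#' @export
decompose_signal <- function(signal, cfg = decomposition_config()) {
  if (cfg$method == "dwt") {
    dwt_decompose(signal, cfg)$bands
  } else {
    dec <- emd(signal, cfg)
    select_imfs_minkowski(signal, dec$imfs, n_selected = cfg$n_selected_imfs,
                          p = cfg$minkowski_p, residual = dec$residual)
  }
}
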