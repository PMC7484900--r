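#' Synthetic cohort specification
#'
#' Describes a download-free multi-subject EEG-like dataset: each subject's
#' recording carries a subject-specific oscillatory signature on the
#' designated informative channels, 1/f-shaped background noise on every
#' channel, and a common-mode sinusoid shared by all channels (so the common
#' average reference has something to remove). Signature frequencies are
#' assigned from an evenly spaced grid by seeded permutation, so no two
#' subjects share a frequency and separability is controlled by the grid
#' spacing.
#'
#' @param n_subjects Number of subjects (default 12).
#' @param n_channels Channels per recording (default 8).
#' @param fs Sampling rate in Hz (default 160).
#' @param duration_s Recording length in seconds (default 60, giving 60
#'   one-second instances).
#' @param informative_channels Indices of channels carrying the subject
#'   signatures (default 1:2). May be empty, producing an unidentifiable
#'   cohort for negative tests.
#' @param n_signature_freqs Sinusoids per subject signature (default 2).
#' @param freq_range Range (Hz) the signature frequency grid spans
#'   (default 5-40).
#' @param amp_range Signature amplitude range, microvolts (default 1.5-2.5).
#' @param noise_sd Standard deviation of the 1/f noise (default 1).
#' @param common_mode_amplitude Amplitude of the shared sinusoid
#'   (default 2).
#' @param common_mode_freq Frequency of the shared sinusoid, Hz
#'   (default 50).
#' @param seed Integer seed making the cohort fully reproducible.
#'
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 12, n_channels = 8, fs = 160,
                        duration_s = 60, informative_channels = c(1, 2),
                        n_signature_freqs = 2, freq_range = c(5, 40),
                        amp_range = c(1.5, 2.5), noise_sd = 1,
                        common_mode_amplitude = 2, common_mode_freq = 50,
                        seed = 1) {
  stopifnot(fs > 0, duration_s > 0, n_subjects >= 1, n_channels >= 1,
            all(informative_channels %in% seq_len(n_channels)))
  structure(
    list(n_subjects = n_subjects, n_channels = n_channels, fs = fs,
         duration_s = duration_s, informative_channels = informative_channels,
         n_signature_freqs = n_signature_freqs, freq_range = freq_range,
         amp_range = amp_range, noise_sd = noise_sd,
         common_mode_amplitude = common_mode_amplitude,
         common_mode_freq = common_mode_freq, seed = seed),
    class = "cohort_spec"
  )
}

# 1/f-shaped noise via spectral shaping of white noise, rescaled to `sd`
pink_noise <- function(n, sd = 1) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  k <- 0:(n - 1)
  f <- pmin(k, n - k)                        # two-sided frequency index
  f[1] <- 1                                  # DC kept as-is
  shaped <- spec / sqrt(f)                   # 1/sqrt(f) amplitude roll-off
  x <- Re(stats::fft(shaped, inverse = TRUE)) / n
  x <- x - mean(x)
  x / stats::sd(x) * sd
}

#' Generate a synthetic cohort of EEG-like recordings
#'
#' @param spec A [cohort_spec()].
#' @return A named list of [eeg_recording]s (one per subject, labels
#'   `S01, S02, ...`), with the spec attached as attribute `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  n_samp <- round(spec$fs * spec$duration_s)
  t <- (seq_len(n_samp) - 1) / spec$fs
  n_freqs_total <- spec$n_subjects * spec$n_signature_freqs
  grid <- seq(spec$freq_range[1], spec$freq_range[2], length.out = n_freqs_total)
  freq_assign <- matrix(sample(grid), nrow = spec$n_subjects)

  subjects <- sprintf("S%02d", seq_len(spec$n_subjects))
  cohort <- lapply(seq_len(spec$n_subjects), function(s) {
    amps <- stats::runif(spec$n_signature_freqs, spec$amp_range[1], spec$amp_range[2])
    common <- spec$common_mode_amplitude *
      sin(2 * pi * spec$common_mode_freq * t + stats::runif(1, 0, 2 * pi))
    data <- matrix(0, spec$n_channels, n_samp)
    for (ch in seq_len(spec$n_channels)) {
      x <- pink_noise(n_samp, spec$noise_sd) + common
      if (ch %in% spec$informative_channels) {
        for (i in seq_len(spec$n_signature_freqs)) {
          x <- x + amps[i] * sin(2 * pi * freq_assign[s, i] * t +
                                   stats::runif(1, 0, 2 * pi))
        }
      }
      data[ch, ] <- x
    }
    eeg_recording(subjects[s], data, spec$fs, condition = "synthetic")
  })
  names(cohort) <- subjects
  attr(cohort, "spec") <- spec
  cohort
}

#' Segment and re-reference a whole cohort
#'
#' Convenience wrapper: per recording, cut 1-second instances and apply the
#' common average reference per instance; bind all subjects into one
#' instance tibble.
#'
#' @param cohort List of [eeg_recording]s.
#' @param window_seconds Window length (default 1).
#' @return Instance tibble (see [segment_instances()]).
#' @export
cohort_instances <- function(cohort, window_seconds = 1.0) {
  dplyr::bind_rows(lapply(cohort, function(rec) {
    common_average_reference(segment_instances(rec, window_seconds))
  }))
}

#' Full-channel separability check of a cohort
#'
#' Fits one model per subject on all channels and reports TAR/TRR, so a
#' fixture can be verified to sit in a "separable" regime (both >= 0.95) or
#' deliberately in a hard one.
#'
#' @param cohort List of [eeg_recording]s from [generate_cohort()].
#' @param decomp_cfg A [decomposition_config()].
#' @param spec A [model_spec()] (default: LOF, kd-tree, 1 neighbor).
#' @param train_fraction Train split fraction (default 0.8).
#' @param split_seed Seed for the train/test split.
#' @return A `biometric_metrics` object.
#' @export
cohort_separability_check <- function(cohort,
                                      decomp_cfg = decomposition_config(),
                                      spec = model_spec("lof", "kd_tree", 1),
                                      train_fraction = 0.8,
                                      split_seed = 1) {
  inst <- cohort_instances(cohort)
  feats <- extract_feature_matrix(inst, decomp_cfg)
  split <- split_cohort(feats, train_fraction, seed = split_seed)
  feat_cols <- setdiff(names(feats), c("subject_id", "instance"))
  models <- lapply(split_names(split$train), function(s) {
    fit_subject_model(split$train[split$train$subject_id == s, feat_cols],
                      spec, subject_id = s)
  })
  names(models) <- split_names(split$train)
  evaluate_tar_trr(models, split$test)
}

split_names <- function(tbl) unique(tbl$subject_id)
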