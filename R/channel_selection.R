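#' Experiment configuration for channel selection
#'
#' @param method Feature decomposition: `"dwt"` or `"emd"`.
#' @param model_family One-class family: `"lof"` or `"ocsvm"`.
#' @param train_fraction Fraction of each subject's instances used for
#'   training (default 0.8; with 60 instances this gives 48/12).
#' @param n_runs Number of repeated random-split optimization runs
#'   (default 10).
#' @param seeds One seed per run; defaults to `base_seed + 0:(n_runs-1)`.
#' @param base_seed Base for the default seed sequence (default 1).
#' @param population NSGA-III population size N (default 20).
#' @param tolerance Objective-space termination tolerance (default 1e-4).
#' @param max_gen Generation cap (default 300).
#' @param ref_divisions Das-Dennis divisions p (default 5).
#' @param higuchi_kmax Passed to [feature_config()].
#'
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(method = c("dwt", "emd"),
                              model_family = c("lof", "ocsvm"),
                              train_fraction = 0.8, n_runs = 10,
                              seeds = NULL, base_seed = 1,
                              population = 20, tolerance = 1e-4,
                              max_gen = 300, ref_divisions = 5,
                              higuchi_kmax = 10) {
  method <- match.arg(method)
  model_family <- match.arg(model_family)
  stopifnot(train_fraction > 0, train_fraction < 1, n_runs >= 1)
  if (is.null(seeds)) seeds <- base_seed + seq_len(n_runs) - 1L
  stopifnot(length(seeds) == n_runs)
  structure(
    list(method = method, model_family = model_family,
         train_fraction = train_fraction, n_runs = n_runs, seeds = seeds,
         population = population, tolerance = tolerance, max_gen = max_gen,
         ref_divisions = ref_divisions, higuchi_kmax = higuchi_kmax),
    class = "experiment_config"
  )
}

#' Decode a mixed chromosome into a channel mask and model spec
#'
#' The first `n_channels` binary genes select channels. For LOF the two
#' extra genes are integers: the neighbor-search algorithm (1 = ball tree,
#' 2 = k-d tree, 3 = brute force) and the neighbor count (1-10). For OC-SVM
#' they are reals in `[0, 1]`: nu (repaired into `(0, 1]`) and gamma
#' (repaired to at least epsilon). An all-zero mask is repaired by setting
#' one random bit rather than failing, since it can arise during evolution.
#'
#' @param chrom Chromosome list (`bits`, `ints`, `reals`).
#' @param model_family `"lof"` or `"ocsvm"`.
#' @return List with `channel_mask` (integer indices) and `spec`
#'   ([model_spec()]).
#' @export
decode_chromosome <- function(chrom, model_family = c("lof", "ocsvm")) {
  model_family <- match.arg(model_family)
  bits <- chrom$bits
  if (sum(bits) == 0L) {
    bits[sample.int(length(bits), 1L)] <- 1L
  }
  mask <- which(bits == 1L)
  spec <- if (model_family == "lof") {
    algo <- min(max(as.integer(round(chrom$ints[1L])), 1L), 3L)
    k <- min(max(as.integer(round(chrom$ints[2L])), 1L), 10L)
    model_spec("lof", lof_algorithm = algo, n_neighbors = k)
  } else {
    eps <- 1e-6
    nu <- min(max(chrom$reals[1L], eps), 1)
    gamma <- max(chrom$reals[2L], eps)
    model_spec("ocsvm", nu = nu, gamma = gamma)
  }
  list(channel_mask = mask, spec = spec)
}

#' Per-subject random train/test split
#'
#' Independent uniform split without replacement for each subject, fixed for
#' an entire optimization run. 60 instances at the default fraction give
#' 48 training and 12 test rows.
#'
#' @param features Feature tibble from [extract_feature_matrix()] (or any
#'   tibble with a `subject_id` column).
#' @param train_fraction Default 0.8.
#' @param seed Optional seed (RNG state is restored afterwards).
#' @return List with `train` and `test` tibbles partitioning the input.
#' @export
split_cohort <- function(features, train_fraction = 0.8, seed = NULL) {
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
  }
  counts <- table(features$subject_id)
  if (any(counts < 5)) stop("every subject needs at least 5 instances to split")
  idx_train <- unlist(lapply(split(seq_len(nrow(features)), features$subject_id),
                             function(idx) {
                               n_tr <- round(length(idx) * train_fraction)
                               sample(idx, n_tr)
                             }))
  train_mask <- seq_len(nrow(features)) %in% idx_train
  list(train = features[train_mask, , drop = FALSE],
       test = features[!train_mask, , drop = FALSE])
}

# fit per-subject models on the masked feature columns and score the split;
# returns biometric_metrics or NULL on any model-fit failure
fit_and_score_split <- function(split, feat_cols, spec) {
  train_mat <- as.matrix(split$train[, feat_cols, drop = FALSE])
  train_subj <- split$train$subject_id
  subjects <- unique(train_subj)
  models <- tryCatch({
    ms <- lapply(subjects, function(s) {
      fit_subject_model(train_mat[train_subj == s, , drop = FALSE],
                        spec, subject_id = s)
    })
    names(ms) <- subjects
    ms
  }, error = function(e) NULL)
  if (is.null(models)) return(NULL)
  tryCatch(
    evaluate_tar_trr(models, split$test[, c("subject_id", feat_cols), drop = FALSE]),
    error = function(e) NULL
  )
}

#' Evaluate one chromosome: (n channels, 1 - TAR, 1 - TRR)
#'
#' Decodes the chromosome, column-slices the cached full feature matrix to
#' the selected channels (features are channel-separable, so they are
#' computed once per run and sliced per chromosome), fits one model per
#' subject, and scores the fixed train/test split. Model-fit failures yield
#' the worst objectives `(n_channels, 1, 1)` rather than aborting the run.
#'
#' @param chrom Chromosome list.
#' @param split Output of [split_cohort()] on the full feature matrix.
#' @param cfg An [experiment_config()].
#' @param channel_names Channel labels, in the order the bits encode.
#' @return Numeric objective vector `c(n_channels, 1 - tar, 1 - trr)`.
#' @export
evaluate_chromosome <- function(chrom, split, cfg, channel_names) {
  dec <- decode_chromosome(chrom, cfg$model_family)
  feat_cols <- feature_columns_for_channels(
    setdiff(names(split$train), c("subject_id", "instance")),
    channel_names[dec$channel_mask])
  metrics <- fit_and_score_split(split, feat_cols, dec$spec)
  if (is.null(metrics)) {
    return(c(length(dec$channel_mask), 1, 1))
  }
  c(length(dec$channel_mask), 1 - metrics$tar, 1 - metrics$trr)
}

#' Cross-validated NSGA-III channel selection
#'
#' The full pipeline: segment and re-reference the cohort, compute the full
#' per-channel feature cache once, then for each run draw a fresh 80/20
#' split and evolve a population of mixed chromosomes (channel bits + two
#' model genes) under the three objectives (minimize channel count, maximize
#' TAR, maximize TRR). Pareto-front members of each run are decoded into
#' records.
#'
#' @param cohort Named list of [eeg_recording]s, or a precomputed feature
#'   tibble from [extract_feature_matrix()] (then `channel_names` must be
#'   given).
#' @param cfg An [experiment_config()].
#' @param channel_names Required when `cohort` is a feature tibble.
#'
#' @return An object of class `channel_selection_result`: `records` tibble
#'   (run, chromosome, n_channels, tar, trr, channels, model genes),
#'   `evolutions` (per-run `nsga3_result`s), `config`.
#' @export
run_channel_selection <- function(cohort, cfg = experiment_config(),
                                  channel_names = NULL) {
  if (inherits(cohort, "data.frame")) {
    features <- cohort
    if (is.null(channel_names)) stop("channel_names required with a feature tibble")
  } else {
    channel_names <- cohort[[1L]]$channel_names
    inst <- cohort_instances(cohort)
    features <- extract_feature_matrix(
      inst,
      decomposition_config(method = cfg$method),
      feature_config(higuchi_kmax = cfg$higuchi_kmax))
  }
  n_channels <- length(channel_names)
  encoding <- if (cfg$model_family == "lof") {
    nsga_encoding(n_bits = n_channels, int_ranges = list(c(1, 3), c(1, 10)))
  } else {
    nsga_encoding(n_bits = n_channels, real_ranges = list(c(0, 1), c(0, 1)))
  }

  runs <- lapply(seq_len(cfg$n_runs), function(r) {
    set.seed(cfg$seeds[r])
    split <- split_cohort(features, cfg$train_fraction)
    fitness <- function(chrom) evaluate_chromosome(chrom, split, cfg, channel_names)
    res <- nsga3_evolve(fitness, encoding, n_objectives = 3,
                        n_pop = cfg$population, ref_divisions = cfg$ref_divisions,
                        tol = cfg$tolerance, max_gen = cfg$max_gen)
    records <- lapply(res$front1, function(i) {
      ch <- res$population[[i]]
      dec <- decode_chromosome(ch, cfg$model_family)
      f <- res$objectives[i, ]
      tibble::tibble(
        run = r,
        chromosome = paste(ch$bits, collapse = ""),
        n_channels = as.integer(f[1L]),
        tar = 1 - f[2L], trr = 1 - f[3L],
        channels = list(channel_names[dec$channel_mask]),
        algorithm = if (cfg$model_family == "lof") dec$spec$lof_algorithm else NA_character_,
        n_neighbors = if (cfg$model_family == "lof") dec$spec$n_neighbors else NA_integer_,
        nu = if (cfg$model_family == "ocsvm") dec$spec$nu else NA_real_,
        gamma = if (cfg$model_family == "ocsvm") dec$spec$gamma else NA_real_
      )
    })
    list(records = dplyr::bind_rows(records), evolution = res)
  })

  structure(
    list(records = dplyr::bind_rows(lapply(runs, `[[`, "records")),
         evolutions = lapply(runs, `[[`, "evolution"),
         config = cfg, channel_names = channel_names),
    class = "channel_selection_result"
  )
}

#' @export
print.channel_selection_result <- function(x, ...) {
  cat(sprintf("<channel_selection_result> %d runs, %d Pareto records (%s + %s)\n",
              x$config$n_runs, nrow(x$records), x$config$method,
              x$config$model_family))
  invisible(x)
}

#' @export
tidy.channel_selection_result <- function(x, ...) x$records

#' @export
glance.channel_selection_result <- function(x, ...) {
  tibble::tibble(
    n_runs = x$config$n_runs,
    n_records = nrow(x$records),
    best_tar = max(x$records$tar),
    best_trr = max(x$records$trr),
    min_channels = min(x$records$n_channels)
  )
}

#' Per-channel-count summary of Pareto records
#'
#' For each run and channel count, takes the best record (highest TAR, ties
#' by TRR), then reports mean and standard deviation across runs — the
#' layout of the headline result tables (No. channels, TAR +/- SD,
#' TRR +/- SD).
#'
#' @param records Records tibble from [run_channel_selection()] (or
#'   `tidy()` of its result).
#' @return A tibble with `n_channels`, `tar_mean`, `tar_sd`, `trr_mean`,
#'   `trr_sd`, `n_runs`.
#' @export
pareto_summary <- function(records) {
  if (inherits(records, "channel_selection_result")) records <- records$records
  records |>
    dplyr::group_by(.data$run, .data$n_channels) |>
    dplyr::slice_max(.data$tar, n = 1, with_ties = TRUE) |>
    dplyr::slice_max(.data$trr, n = 1, with_ties = FALSE) |>
    dplyr::group_by(.data$n_channels) |>
    dplyr::summarise(
      tar_mean = mean(.data$tar), tar_sd = stats::sd(.data$tar),
      trr_mean = mean(.data$trr), trr_sd = stats::sd(.data$trr),
      n_runs = dplyr::n(), .groups = "drop"
    )
}

#' Channel occurrence counts across Pareto records
#'
#' How often each channel appears among Pareto records, stratified by the
#' record's channel count — the tabular form of the channel-occurrence maps
#' used to propose reduced electrode montages.
#'
#' @param records Records tibble from [run_channel_selection()].
#' @return A tibble with `n_channels` (stratum), `channel`, `count`.
#' @export
channel_occurrence_map <- function(records) {
  if (inherits(records, "channel_selection_result")) records <- records$records
  stopifnot(nrow(records) >= 1)
  records |>
    dplyr::select("n_channels", "channels") |>
    tidyr::unnest_longer("channels", values_to = "channel") |>
    dplyr::count(.data$n_channels, .data$channel, name = "count") |>
    dplyr::arrange(.data$n_channels, dplyr::desc(.data$count))
}

#' Write per-generation evaluation logs as JSON lines
#'
#' One JSON object per evaluated chromosome: generation, bitstring, model
#' genes, objective triple, first-front membership. The scatter of TAR/TRR
#' candidates over a run can be regenerated from this file.
#'
#' @param result A `channel_selection_result` or single `nsga3_result`.
#' @param path Output file; one file per run gets a `_run<k>` suffix when
#'   `result` covers several runs.
#' @return The paths written, invisibly.
#' @export
write_evolution_log <- function(result, path) {
  evolutions <- if (inherits(result, "channel_selection_result")) {
    result$evolutions
  } else list(result)
  paths <- character(0)
  for (k in seq_along(evolutions)) {
    p <- if (length(evolutions) > 1L) {
      sub("(\\.[a-zA-Z]+)?$", sprintf("_run%d\\1", k), path)
    } else path
    log <- evolutions[[k]]$log
    lines <- vapply(seq_len(nrow(log)), function(i) {
      jsonlite::toJSON(list(
        generation = log$generation[i], bits = log$bits[i],
        ints = log$ints[[i]], reals = log$reals[[i]],
        objectives = log$objectives[[i]],
        in_first_front = log$in_first_front[i]
      ), auto_unbox = TRUE, digits = NA)
    }, "")
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
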