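test_that("chromosome decoding maps genes to channels and model settings", {
  ch_lof <- list(bits = rep(1L, 64), ints = c(2L, 5L), reals = numeric(0))
  dec <- decode_chromosome(ch_lof, "lof")
  expect_length(dec$channel_mask, 64L)
  expect_equal(dec$spec$lof_algorithm, "kd_tree")
  expect_equal(dec$spec$n_neighbors, 5L)

  ch1 <- list(bits = c(0L, 1L, 0L, 1L), ints = c(1L, 1L), reals = numeric(0))
  expect_equal(decode_chromosome(ch1, "lof")$channel_mask, c(2L, 4L))
  expect_equal(decode_chromosome(ch1, "lof")$spec$lof_algorithm, "ball_tree")

  # OC-SVM genes at zero are repaired to epsilon
  ch_svm <- list(bits = c(1L, 0L), ints = integer(0), reals = c(0, 0))
  dsvm <- decode_chromosome(ch_svm, "ocsvm")
  expect_gt(dsvm$spec$nu, 0)
  expect_gt(dsvm$spec$gamma, 0)

  # an all-zero mask is repaired, never an error
  set.seed(71)
  dz <- decode_chromosome(list(bits = rep(0L, 8), ints = c(1L, 1L),
                               reals = numeric(0)), "lof")
  expect_length(dz$channel_mask, 1L)
})

test_that("the per-subject split is a seeded 80/20 partition", {
  feats <- tibble::tibble(subject_id = rep(c("A", "B"), each = 60),
                          instance = rep(1:60, 2), f = rnorm(120))
  s1 <- split_cohort(feats, 0.8, seed = 7)
  expect_equal(sum(s1$train$subject_id == "A"), 48L)
  expect_equal(sum(s1$test$subject_id == "A"), 12L)
  s2 <- split_cohort(feats, 0.8, seed = 7)
  expect_identical(s1, s2)
  key <- function(d) paste(d$subject_id, d$instance)
  expect_length(intersect(key(s1$train), key(s1$test)), 0L)
  expect_setequal(c(key(s1$train), key(s1$test)), key(feats))

  expect_error(split_cohort(feats[1:3, ], 0.8), "at least 5")
})

test_that("chromosome evaluation is deterministic and uses the cached features", {
  feats <- small_cohort_features()
  cfg <- experiment_config("dwt", "lof", n_runs = 1)
  split <- split_cohort(feats, 0.8, seed = 12)
  chn <- paste0("CH", 1:4)
  chrom <- list(bits = c(1L, 1L, 0L, 0L), ints = c(2L, 1L), reals = numeric(0))

  f1 <- evaluate_chromosome(chrom, split, cfg, chn)
  f2 <- evaluate_chromosome(chrom, split, cfg, chn)
  expect_identical(f1, f2)
  expect_equal(f1[1], 2)
  expect_true(all(f1[2:3] >= 0 & f1[2:3] <= 1))

  # cache correctness: column-slicing the full feature matrix equals
  # extracting features from the raw signals with the mask applied
  inst <- cohort_instances(small_cohort())
  direct <- t(vapply(inst$data, extract_features, numeric(32),
                     channel_mask = c(1, 2)))
  cached <- as.matrix(feats[, restid:::feature_columns_for_channels(
    names(feats)[-(1:2)], c("CH1", "CH2"))])
  expect_lt(max(abs(direct - cached)), 1e-10)
})

test_that("model-fit failure yields worst-case objectives, not an error", {
  feats <- small_cohort_features()
  cfg <- experiment_config("dwt", "lof", n_runs = 1)
  split <- split_cohort(feats, 0.8, seed = 13)
  # 16 training rows per subject: k = 10 fits, but shrinking the split breaks it
  tiny <- list(train = split$train[split$train$instance <= 8, ],
               test = split$test)
  bad <- list(bits = rep(1L, 4), ints = c(3L, 10L), reals = numeric(0))
  f <- evaluate_chromosome(bad, tiny, cfg, paste0("CH", 1:4))
  expect_equal(f, c(4, 1, 1))
})

test_that("adding a pure-noise channel cannot beat the informative pair", {
  feats <- small_cohort_features()
  cfg <- experiment_config("dwt", "lof", n_runs = 1)
  split <- split_cohort(feats, 0.8, seed = 14)
  chn <- paste0("CH", 1:4)
  inform <- evaluate_chromosome(list(bits = c(1L, 1L, 0L, 0L), ints = c(2L, 1L),
                                     reals = numeric(0)), split, cfg, chn)
  wider <- evaluate_chromosome(list(bits = c(1L, 1L, 1L, 0L), ints = c(2L, 1L),
                                    reals = numeric(0)), split, cfg, chn)
  expect_lt(inform[1], wider[1])                 # strictly fewer channels
  expect_lte(inform[2], wider[2] + 0.1)          # TAR no worse beyond noise
  expect_lte(inform[3], wider[3] + 0.1)
})

test_that("short optimization runs produce valid per-run Pareto records", {
  feats <- small_cohort_features()
  cfg <- experiment_config("dwt", "lof", n_runs = 2, seeds = c(301, 302),
                           max_gen = 4)
  res <- run_channel_selection(feats, cfg, channel_names = paste0("CH", 1:4))
  recs <- tidy(res)
  expect_equal(sort(unique(recs$run)), 1:2)
  expect_true(all(recs$n_channels >= 1))
  expect_true(all(recs$tar >= 0 & recs$tar <= 1))
  expect_true(all(recs$algorithm %in% c("ball_tree", "kd_tree", "brute")))

  # records within one run are mutually non-dominated
  for (r in 1:2) {
    obj <- as.matrix(recs[recs$run == r, c("n_channels", "tar", "trr")])
    obj[, 2:3] <- 1 - obj[, 2:3]
    expect_length(non_dominated_sort(obj), 1L)
  }

  # evolution logs serialize to JSONL
  path <- withr::local_tempfile(fileext = ".jsonl")
  paths <- write_evolution_log(res, path)
  expect_length(paths, 2L)
  line1 <- jsonlite::fromJSON(readLines(paths[1], n = 1))
  expect_named(line1, c("generation", "bits", "ints", "reals", "objectives",
                        "in_first_front"), ignore.order = TRUE)

  g <- glance(res)
  expect_equal(g$n_records, nrow(recs))
})

test_that("occurrence maps and summaries aggregate records correctly", {
  recs <- tibble::tibble(
    run = c(1L, 1L, 2L),
    chromosome = c("0101", "0001", "0101"),
    n_channels = c(2L, 1L, 2L),
    tar = c(0.9, 0.8, 0.95), trr = c(0.85, 0.9, 0.8),
    channels = list(c("T8", "T10"), "T10", c("T8", "T10"))
  )
  occ <- channel_occurrence_map(recs)
  expect_equal(occ$count[occ$n_channels == 2 & occ$channel == "T8"], 2L)
  expect_equal(occ$count[occ$n_channels == 1 & occ$channel == "T10"], 1L)
  # conservation within each stratum
  tot2 <- sum(occ$count[occ$n_channels == 2])
  expect_equal(tot2, sum(recs$n_channels[recs$n_channels == 2]))
  # duplicating records doubles counts
  occ2 <- channel_occurrence_map(dplyr::bind_rows(recs, recs))
  expect_equal(occ2$count, occ$count * 2L)

  sm <- pareto_summary(recs)
  two <- sm[sm$n_channels == 2, ]
  expect_equal(two$tar_mean, mean(c(0.9, 0.95)))
  expect_equal(two$tar_sd, sd(c(0.9, 0.95)))
  expect_equal(two$n_runs, 2L)
})

test_that("summary statistics match hand-computed values on fabricated fronts", {
  recs <- tibble::tibble(
    run = rep(1:3, each = 2),
    chromosome = "x",
    n_channels = rep(c(1L, 2L), 3),
    tar = c(0.90, 0.95, 0.92, 0.97, 0.88, 0.93),
    trr = c(0.80, 0.85, 0.82, 0.87, 0.78, 0.83),
    channels = list("a", c("a", "b"), "a", c("a", "c"), "b", c("b", "c"))
  )
  sm <- pareto_summary(recs)
  expect_equal(sm$tar_mean[sm$n_channels == 1], mean(c(0.90, 0.92, 0.88)))
  expect_equal(sm$trr_sd[sm$n_channels == 2], sd(c(0.85, 0.87, 0.83)))
})
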