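#' One-class model specification
#'
#' @param family `"lof"` (local outlier factor, the main classifier) or
#'   `"ocsvm"` (one-class SVM with RBF kernel, for comparison).
#' @param lof_algorithm Neighbor-search backend for LOF: `"ball_tree"`,
#'   `"kd_tree"`, or `"brute"` (integer codes 1, 2, 3 also accepted). The
#'   backend is an index structure only; scores are identical across
#'   backends.
#' @param n_neighbors LOF neighborhood size k, in 1..10.
#' @param nu OC-SVM nu: upper bound on the fraction of training errors.
#' @param gamma OC-SVM RBF width (> 0).
#' @param lof_accept_threshold Accept a query iff its LOF score is <= this
#'   value (default 1.5); scores near 1 indicate inliers.
#'
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(family = c("lof", "ocsvm"),
                       lof_algorithm = "kd_tree",
                       n_neighbors = 1,
                       nu = 0.5, gamma = 0.5,
                       lof_accept_threshold = 1.5) {
  family <- match.arg(family)
  algos <- c("ball_tree", "kd_tree", "brute")
  if (is.numeric(lof_algorithm)) lof_algorithm <- algos[as.integer(lof_algorithm)]
  lof_algorithm <- match.arg(lof_algorithm, algos)
  if (family == "lof") {
    stopifnot(n_neighbors >= 1, n_neighbors <= 10)
  } else {
    stopifnot(nu > 0, nu <= 1, gamma > 0)
  }
  structure(
    list(family = family, lof_algorithm = lof_algorithm,
         n_neighbors = as.integer(n_neighbors), nu = nu, gamma = gamma,
         lof_accept_threshold = lof_accept_threshold),
    class = "model_spec"
  )
}

# ---- exact k-nearest-neighbor backends ------------------------------------

# hand-written exact ball tree, flattened for an iterative search: each ball
# stores its centroid and covering radius; leaves keep the transposed point
# block so distance evaluation is one vectorized colSums
build_ball_tree <- function(X, leaf_size = 16L) {
  nodes <- list()
  build <- function(idx) {
    pts <- X[idx, , drop = FALSE]
    center <- colMeans(pts)
    radius <- sqrt(max(rowSums(sweep(pts, 2L, center)^2)))
    id <- length(nodes) + 1L
    nodes[[id]] <<- list()   # reserve slot before recursing
    if (length(idx) <= leaf_size) {
      nodes[[id]] <<- list(leaf = TRUE, center = center, radius = radius,
                           idx = idx, Xt = t(pts))
    } else {
      spread <- apply(pts, 2L, function(v) max(v) - min(v))
      ord <- idx[order(X[idx, which.max(spread)])]
      half <- length(ord) %/% 2L
      left <- build(ord[seq_len(half)])
      right <- build(ord[-seq_len(half)])
      nodes[[id]] <<- list(leaf = FALSE, center = center, radius = radius,
                           left = left, right = right)
    }
    id
  }
  build(seq_len(nrow(X)))
  list(nodes = nodes, dim = ncol(X))
}

# exact kNN via depth-first ball-tree search with triangle-inequality
# pruning; results sorted by distance like the other backends
ball_tree_query <- function(tree, Q, k) {
  nodes <- tree$nodes
  m <- tree$dim
  n_q <- nrow(Q)
  idx_out <- matrix(0L, n_q, k)
  dist_out <- matrix(0, n_q, k)
  for (q in seq_len(n_q)) {
    p <- Q[q, ]
    best_d <- rep(Inf, k)
    best_i <- integer(k)
    worst <- Inf
    stack_id <- 1L
    stack_lb <- 0
    top <- 1L
    while (top > 0L) {
      id <- stack_id[top]; lb <- stack_lb[top]; top <- top - 1L
      if (lb >= worst) next
      node <- nodes[[id]]
      if (node$leaf) {
        d <- sqrt(.colSums((node$Xt - p)^2, m, length(node$idx)))
        for (j in seq_along(d)) {         # replace the current worst in place
          if (d[j] < worst) {
            wm <- which.max(best_d)
            best_d[wm] <- d[j]
            best_i[wm] <- node$idx[j]
            worst <- max(best_d)
          }
        }
      } else {
        nl <- nodes[[node$left]]; nr <- nodes[[node$right]]
        lb_l <- sqrt(sum((p - nl$center)^2)) - nl$radius
        lb_r <- sqrt(sum((p - nr$center)^2)) - nr$radius
        # push the farther child first so the nearer one is explored next
        if (lb_l <= lb_r) {
          if (lb_r < worst) { top <- top + 1L; stack_id[top] <- node$right; stack_lb[top] <- lb_r }
          if (lb_l < worst) { top <- top + 1L; stack_id[top] <- node$left; stack_lb[top] <- lb_l }
        } else {
          if (lb_l < worst) { top <- top + 1L; stack_id[top] <- node$left; stack_lb[top] <- lb_l }
          if (lb_r < worst) { top <- top + 1L; stack_id[top] <- node$right; stack_lb[top] <- lb_r }
        }
      }
    }
    ord <- order(best_d)
    idx_out[q, ] <- best_i[ord]
    dist_out[q, ] <- best_d[ord]
  }
  list(nn.index = idx_out, nn.dist = dist_out)
}

# exact kNN of `query` among rows of `train`; `tree` lets ball-tree callers
# reuse one index across calls
knn_backend <- function(train, query, k, backend, tree = NULL) {
  switch(backend,
    brute = FNN::get.knnx(train, query, k = k, algorithm = "brute"),
    kd_tree = FNN::get.knnx(train, query, k = k, algorithm = "kd_tree"),
    ball_tree = {
      if (is.null(tree)) tree <- build_ball_tree(train)
      ball_tree_query(tree, query, k)
    },
    stop("unknown backend: ", backend)
  )
}

# ---- local outlier factor --------------------------------------------------

# k-distances, neighbor sets, and local reachability densities of the
# training points (self-neighbors excluded)
lof_fit_stats <- function(train, k, backend, tree = NULL) {
  n <- nrow(train)
  if (k < 1 || k > n - 1L) stop("n_neighbors must be in [1, n_train - 1]")
  nn <- knn_backend(train, train, k + 1L, backend, tree)
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    row <- nn$nn.index[i, ]
    drop <- match(i, row)
    if (is.na(drop)) drop <- k + 1L    # duplicate points: drop the farthest
    idx[i, ] <- row[-drop]
    dst[i, ] <- nn$nn.dist[i, ][-drop]
  }
  kdist <- dst[, k]
  reach <- pmax(matrix(kdist[idx], n, k), dst)
  lrd <- 1 / pmax(rowMeans(reach), 1e-10)
  list(nn_idx = idx, kdist = kdist, lrd = lrd)
}

# LOF of query rows given precomputed training statistics
lof_query_scores <- function(st, train, query, k, backend, tree = NULL) {
  nn_q <- knn_backend(train, query, k, backend, tree)
  reach_q <- pmax(matrix(st$kdist[nn_q$nn.index], nrow(query), k), nn_q$nn.dist)
  lrd_q <- 1 / pmax(rowMeans(reach_q), 1e-10)
  lrd_nb <- matrix(st$lrd[nn_q$nn.index], nrow(query), k)
  rowMeans(lrd_nb) / lrd_q
}

#' Local outlier factor scores for query points
#'
#' Novelty scoring of `query` rows against a training set, per the standard
#' LOF definitions: the k-distance of each training point, reachability
#' distances, local reachability density (lrd), and finally the ratio of the
#' average lrd of a query's k training neighbors to the query's own lrd.
#' Inliers score near 1; isolated points score well above 1.
#'
#' @param train Numeric matrix of training rows.
#' @param query Numeric matrix of query rows (same dimensionality).
#' @param k Neighborhood size, `1 <= k <= nrow(train) - 1`.
#' @param backend `"brute"`, `"kd_tree"`, or `"ball_tree"`; all exact, so the
#'   choice does not change the scores.
#'
#' @return Numeric vector of LOF scores, one per query row.
#' @export
lof_scores <- function(train, query, k, backend = "brute") {
  train <- as.matrix(train); query <- as.matrix(query)
  if (nrow(query) == 0L) return(numeric(0))
  if (ncol(query) != ncol(train)) stop("query dimensionality mismatch")
  tree <- if (backend == "ball_tree") build_ball_tree(train) else NULL
  st <- lof_fit_stats(train, k, backend, tree)
  lof_query_scores(st, train, query, k, backend, tree)
}

# ---- per-subject models ----------------------------------------------------

#' Fit a one-class model for one subject
#'
#' LOF models store the training rows and precomputed neighborhood
#' statistics (k-distances, neighbor local reachability densities, and the
#' ball-tree index when that backend is chosen); OC-SVM models delegate the
#' decision function to an established RBF one-class SVM solver (the
#' contribution here is the pipeline, not the QP).
#'
#' @param train Numeric matrix (or data frame) of the subject's genuine
#'   training feature vectors, >= 2 rows.
#' @param spec A [model_spec()].
#' @param subject_id Optional label stored on the model.
#'
#' @return An object of class `subject_model`.
#' @export
fit_subject_model <- function(train, spec, subject_id = NA_character_) {
  train <- as.matrix(train)
  if (nrow(train) < 2L) stop("need at least 2 training rows")
  tree <- NULL
  fitted <- if (spec$family == "lof") {
    if (spec$n_neighbors >= nrow(train)) {
      stop("n_neighbors must be smaller than the training-set size")
    }
    if (spec$lof_algorithm == "ball_tree") tree <- build_ball_tree(train)
    lof_fit_stats(train, spec$n_neighbors, spec$lof_algorithm, tree)
  } else {
    e1071::svm(x = train, type = "one-classification", kernel = "radial",
               nu = spec$nu, gamma = spec$gamma, scale = FALSE)
  }
  structure(
    list(subject_id = subject_id, spec = spec, train = train,
         fitted = fitted, tree = tree),
    class = "subject_model"
  )
}

#' Accept/reject decisions for query feature vectors
#'
#' LOF: accept iff score <= `lof_accept_threshold`. OC-SVM: accept iff the
#' decision function is >= 0. Boundary ties accept, for determinism.
#'
#' @param model A `subject_model` from [fit_subject_model()].
#' @param query Numeric matrix of query rows.
#' @return Logical vector, `TRUE` = accepted as the modelled subject.
#' @export
score_instances <- function(model, query) {
  query <- as.matrix(query)
  if (nrow(query) == 0L) return(logical(0))
  if (ncol(query) != ncol(model$train)) stop("query dimensionality mismatch")
  if (model$spec$family == "lof") {
    scores <- lof_query_scores(model$fitted, model$train, query,
                               model$spec$n_neighbors,
                               model$spec$lof_algorithm, model$tree)
    scores <= model$spec$lof_accept_threshold
  } else {
    dv <- attr(stats::predict(model$fitted, query, decision.values = TRUE),
               "decision.values")
    as.numeric(dv) >= 0
  }
}

#' True acceptance and true rejection rates over a cohort
#'
#' For each subject s: TAR_s is the accepted fraction of s's genuine test
#' rows under s's model, TRR_s the rejected fraction of impostor rows
#' (by default the pooled test rows of every other subject). The overall TAR
#' and TRR are unweighted means over subjects. Subjects without test rows are
#' excluded with a warning.
#'
#' @param models Named list of `subject_model`s (or plain functions mapping a
#'   feature matrix to a logical accept vector, useful for testing), one per
#'   subject.
#' @param genuine_test Tibble with `subject_id` plus feature columns: each
#'   subject's held-out genuine rows.
#' @param impostor_test Optional tibble of the same shape; defaults to using
#'   every other subject's rows in `genuine_test` as impostors.
#'
#' @return An object of class `biometric_metrics`: `tar`, `trr`, and a
#'   `per_subject` tibble.
#' @export
evaluate_tar_trr <- function(models, genuine_test, impostor_test = NULL) {
  same_pool <- is.null(impostor_test)
  if (same_pool) impostor_test <- genuine_test
  feat_cols <- setdiff(names(genuine_test), c("subject_id", "instance"))
  gen_mat <- as.matrix(genuine_test[, feat_cols, drop = FALSE])
  gen_subj <- genuine_test$subject_id
  imp_mat <- if (same_pool) gen_mat else as.matrix(impostor_test[, feat_cols, drop = FALSE])
  imp_subj <- impostor_test$subject_id
  decide <- function(model, m) {
    if (is.function(model)) model(m) else score_instances(model, m)
  }
  subjects <- names(models)
  tar <- trr <- n_gen <- n_imp <- rep(NA_real_, length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    g_rows <- which(gen_subj == s)
    i_rows <- which(imp_subj != s)
    if (length(g_rows) == 0L) {
      warning("subject ", s, " has no genuine test rows; excluded")
      next
    }
    tar[i] <- mean(decide(models[[s]], gen_mat[g_rows, , drop = FALSE]))
    n_gen[i] <- length(g_rows)
    n_imp[i] <- length(i_rows)
    trr[i] <- if (length(i_rows)) {
      mean(!decide(models[[s]], imp_mat[i_rows, , drop = FALSE]))
    } else NA_real_
  }
  keep <- !is.na(tar)
  if (!any(keep)) stop("no subject had test rows")
  per_subject <- tibble::tibble(
    subject_id = subjects[keep], n_genuine = as.integer(n_gen[keep]),
    n_impostor = as.integer(n_imp[keep]), tar = tar[keep], trr = trr[keep]
  )
  structure(
    list(tar = mean(per_subject$tar),
         trr = mean(per_subject$trr, na.rm = TRUE),
         per_subject = per_subject),
    class = "biometric_metrics"
  )
}

#' @export
print.biometric_metrics <- function(x, ...) {
  cat(sprintf("<biometric_metrics> TAR %.3f / TRR %.3f over %d subjects\n",
              x$tar, x$trr, nrow(x$per_subject)))
  invisible(x)
}

#' @export
tidy.biometric_metrics <- function(x, ...) x$per_subject

#' @export
glance.biometric_metrics <- function(x, ...) {
  tibble::tibble(tar = x$tar, trr = x$trr, n_subjects = nrow(x$per_subject))
}
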