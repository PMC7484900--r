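#' Das-Dennis reference points
#'
#' Systematic placement of points on the unit simplex: all coordinate
#' vectors with entries in `{0, 1/p, ..., 1}` summing to 1. For M = 3
#' objectives these lie on the triangle with apexes (1,0,0), (0,1,0),
#' (0,0,1); the count is `choose(M + p - 1, p)`.
#'
#' @param n_objectives M (>= 2).
#' @param divisions p (>= 1).
#' @return A matrix with one reference point per row, rows summing to 1.
#' @export
generate_reference_points <- function(n_objectives, divisions) {
  stopifnot(n_objectives >= 2, divisions >= 1)
  recurse <- function(m, left) {
    if (m == 1L) return(matrix(left, 1L, 1L))
    do.call(rbind, lapply(0:left, function(i) {
      cbind(i, recurse(m - 1L, left - i))
    }))
  }
  z <- recurse(n_objectives, divisions) / divisions
  dimnames(z) <- NULL
  z
}

# a dominates b: <= everywhere, < somewhere (minimization)
dominates <- function(a, b) all(a <= b) && any(a < b)

#' Fast non-dominated sorting
#'
#' Partitions points into fronts: front 1 is dominated by nothing; front k
#' only by members of earlier fronts. Domination is `<=` in every objective
#' and `<` in at least one (all objectives minimized).
#'
#' @param objectives Numeric matrix, one row per point.
#' @return List of integer vectors of row indices, one per front.
#' @export
non_dominated_sort <- function(objectives) {
  n <- nrow(objectives)
  if (is.null(n) || n == 0L) return(list())
  dominated_by <- vector("list", n)
  n_dominating <- integer(n)
  for (i in seq_len(n)) {
    fi <- objectives[i, ]
    for (j in seq_len(n)) {
      if (i == j) next
      fj <- objectives[j, ]
      if (all(fj <= fi) && any(fj < fi)) n_dominating[i] <- n_dominating[i] + 1L
      else if (all(fi <= fj) && any(fi < fj)) dominated_by[[i]] <- c(dominated_by[[i]], j)
    }
  }
  fronts <- list()
  current <- which(n_dominating == 0L)
  while (length(current) > 0L) {
    fronts[[length(fronts) + 1L]] <- current
    nxt <- integer(0)
    for (i in current) {
      for (j in dominated_by[[i]]) {
        n_dominating[j] <- n_dominating[j] - 1L
        if (n_dominating[j] == 0L) nxt <- c(nxt, j)
      }
    }
    current <- sort(nxt)
  }
  fronts
}

#' Normalize objectives and associate members with reference lines
#'
#' Translates by the ideal point, scales by the intercepts of the hyperplane
#' through the ASF-selected extreme points (falling back to the per-axis
#' maximum spread when the hyperplane is degenerate), then associates each
#' member with the reference line - through the origin and a reference point
#' - at minimum perpendicular distance.
#'
#' @param objectives Numeric matrix (members of S_t), one row per member.
#' @param ref_points Matrix from [generate_reference_points()].
#' @return List: `association` (reference-point index per member),
#'   `distance` (perpendicular distance to the associated line),
#'   `normalized` (normalized objective matrix).
#' @export
normalize_and_associate <- function(objectives, ref_points) {
  stopifnot(nrow(objectives) >= 1)
  m <- ncol(objectives)
  ideal <- apply(objectives, 2L, min)
  translated <- sweep(objectives, 2L, ideal)

  # extreme point per axis by achievement scalarizing function
  extremes <- vapply(seq_len(m), function(ax) {
    w <- rep(1e-6, m); w[ax] <- 1
    which.min(apply(translated, 1L, function(x) max(x / w)))
  }, integer(1))
  E <- translated[extremes, , drop = FALSE]
  intercepts <- tryCatch({
    b <- solve(E, rep(1, m))
    a <- 1 / b
    if (any(!is.finite(a)) || any(a <= 1e-12)) stop("degenerate")
    a
  }, error = function(e) {
    spread <- apply(translated, 2L, max)
    ifelse(spread > 1e-12, spread, 1)
  })
  normalized <- sweep(translated, 2L, intercepts, "/")

  # perpendicular distance of each member to each reference line
  u <- ref_points / sqrt(rowSums(ref_points^2))
  proj <- normalized %*% t(u)                      # n x H projections
  sq <- rowSums(normalized^2)
  d2 <- pmax(outer(sq, rep(1, nrow(u))) - proj^2, 0)
  assoc <- apply(d2, 1L, which.min)
  dist <- sqrt(d2[cbind(seq_len(nrow(d2)), assoc)])
  list(association = assoc, distance = dist, normalized = normalized)
}

#' Niche-preserving selection from the last front
#'
#' Fills `K` slots from the partially accepted front `F_l`: repeatedly pick
#' the reference point with the smallest niche count (ties broken uniformly
#' at random); if its count is zero take the associated last-front member at
#' the smallest perpendicular distance, otherwise a random associated member;
#' a reference point with no remaining associated member is excluded for the
#' rest of the generation. The chosen point's count is incremented after each
#' pick.
#'
#' @param last_front Integer indices of F_l members (into the association
#'   vectors).
#' @param association,distance Per-member association / distance from
#'   [normalize_and_associate()] (covering at least the `last_front`
#'   indices).
#' @param rho Integer niche counts per reference point, computed from the
#'   already-accepted members.
#' @param k_slots Number of members to select (<= length of `last_front`).
#'
#' @return Integer vector of `k_slots` selected member indices.
#' @export
niching_select <- function(last_front, association, distance, rho, k_slots) {
  if (k_slots > length(last_front)) stop("more slots than last-front members")
  selected <- integer(0)
  pool <- last_front
  active <- rep(TRUE, length(rho))
  while (length(selected) < k_slots) {
    jmin <- which(active & rho == min(rho[active]))
    jstar <- if (length(jmin) == 1L) jmin else sample(jmin, 1L)
    members <- pool[association[pool] == jstar]
    if (length(members) == 0L) {
      active[jstar] <- FALSE        # exclude for this generation
      next
    }
    pick <- if (rho[jstar] == 0L) {
      members[which.min(distance[members])]
    } else if (length(members) == 1L) members else sample(members, 1L)
    selected <- c(selected, pick)
    pool <- setdiff(pool, pick)
    rho[jstar] <- rho[jstar] + 1L
  }
  selected
}

# ---- mixed-gene chromosomes and variation ---------------------------------

#' Chromosome encoding description
#'
#' @param n_bits Number of binary genes (channel bits).
#' @param int_ranges List of `c(lo, hi)` inclusive ranges for integer genes.
#' @param real_ranges List of `c(lo, hi)` ranges for real genes.
#' @return A list of class `nsga_encoding`.
#' @export
nsga_encoding <- function(n_bits = 0L, int_ranges = list(), real_ranges = list()) {
  structure(list(n_bits = as.integer(n_bits), int_ranges = int_ranges,
                 real_ranges = real_ranges),
            class = "nsga_encoding")
}

random_chromosome <- function(encoding) {
  bits <- if (encoding$n_bits > 0L) {
    b <- as.integer(stats::runif(encoding$n_bits) < 0.5)
    if (sum(b) == 0L) b[sample.int(length(b), 1L)] <- 1L
    b
  } else integer(0)
  ints <- vapply(encoding$int_ranges,
                 function(r) sample(seq.int(r[1], r[2]), 1L), integer(1))
  reals <- vapply(encoding$real_ranges,
                  function(r) stats::runif(1, r[1], r[2]), numeric(1))
  list(bits = bits, ints = ints, reals = reals)
}

sbx_pair <- function(x1, x2, lo, hi, eta = 30) {
  u <- stats::runif(1)
  beta <- if (u <= 0.5) (2 * u)^(1 / (eta + 1)) else (1 / (2 * (1 - u)))^(1 / (eta + 1))
  c1 <- 0.5 * ((1 + beta) * x1 + (1 - beta) * x2)
  c2 <- 0.5 * ((1 - beta) * x1 + (1 + beta) * x2)
  pmin(pmax(c(c1, c2), lo), hi)
}

poly_mutate <- function(x, lo, hi, eta = 20) {
  u <- stats::runif(1)
  delta <- if (u < 0.5) (2 * u)^(1 / (eta + 1)) - 1 else 1 - (2 * (1 - u))^(1 / (eta + 1))
  min(max(x + delta * (hi - lo), lo), hi)
}

#' Variation: tournament selection, crossover, mutation
#'
#' Binary tournaments on (front rank, then perpendicular distance to the
#' associated reference line) choose parents. Channel bits undergo uniform
#' crossover (probability `p_cross`) and per-bit flips at rate
#' `1 / total genes`; integer genes mutate by uniform resampling
#' (probability `p_int_mut`); real genes undergo simulated binary crossover
#' (eta 30) and polynomial mutation (eta 20, probability `p_real_mut`).
#' Offspring with an all-zero bit mask are repaired by setting one random
#' bit.
#'
#' @param population List of chromosomes (the N parents).
#' @param encoding An [nsga_encoding()].
#' @param rank Integer front rank per parent (1 = best).
#' @param distance Perpendicular distance per parent (tournament tiebreak).
#' @param rates List of variation rates; defaults follow the standard
#'   NSGA-II/III settings.
#'
#' @return List of N offspring chromosomes.
#' @export
vary <- function(population, encoding, rank, distance,
                 rates = list(p_cross = 0.9, p_int_mut = 0.1, p_real_mut = 0.1,
                              sbx_eta = 30, pm_eta = 20)) {
  n <- length(population)
  n_genes <- encoding$n_bits + length(encoding$int_ranges) + length(encoding$real_ranges)
  p_bit_flip <- if (!is.null(rates$p_bit)) rates$p_bit
                else if (n_genes > 0) 1 / n_genes else 0

  tournament <- function() {
    ij <- sample.int(n, 2L)
    i <- ij[1L]; j <- ij[2L]
    if (rank[i] != rank[j]) return(if (rank[i] < rank[j]) i else j)
    if (distance[i] != distance[j]) return(if (distance[i] < distance[j]) i else j)
    ij[sample.int(2L, 1L)]
  }

  offspring <- vector("list", n)
  slot <- 1L
  while (slot <= n) {
    p1 <- population[[tournament()]]
    p2 <- population[[tournament()]]
    c1 <- p1; c2 <- p2
    if (stats::runif(1) < rates$p_cross) {
      if (encoding$n_bits > 0L) {
        swap <- stats::runif(encoding$n_bits) < 0.5
        c1$bits[swap] <- p2$bits[swap]
        c2$bits[swap] <- p1$bits[swap]
      }
      for (g in seq_along(encoding$real_ranges)) {
        r <- encoding$real_ranges[[g]]
        ch <- sbx_pair(p1$reals[g], p2$reals[g], r[1], r[2], rates$sbx_eta)
        c1$reals[g] <- ch[1L]; c2$reals[g] <- ch[2L]
      }
    }
    mutate_child <- function(ch) {
      if (encoding$n_bits > 0L) {
        flip <- stats::runif(encoding$n_bits) < p_bit_flip
        ch$bits[flip] <- 1L - ch$bits[flip]
        if (sum(ch$bits) == 0L) ch$bits[sample.int(encoding$n_bits, 1L)] <- 1L
      }
      for (g in seq_along(encoding$int_ranges)) {
        if (stats::runif(1) < rates$p_int_mut) {
          r <- encoding$int_ranges[[g]]
          ch$ints[g] <- sample(seq.int(r[1], r[2]), 1L)
        }
      }
      for (g in seq_along(encoding$real_ranges)) {
        if (stats::runif(1) < rates$p_real_mut) {
          r <- encoding$real_ranges[[g]]
          ch$reals[g] <- poly_mutate(ch$reals[g], r[1], r[2], rates$pm_eta)
        }
      }
      ch
    }
    c1 <- mutate_child(c1)
    c2 <- mutate_child(c2)
    offspring[[slot]] <- c1
    if (slot + 1L <= n) offspring[[slot + 1L]] <- c2
    slot <- slot + 2L
  }
  offspring
}

#' Objective-space-tolerance termination rule
#'
#' Checked once per generation: terminate when the generation count reaches
#' `max_gen`, or - at generations divisible by `period` - when the ideal and
#' nadir points of the current first front have each moved by at most `tol`
#' in every objective since the previous check.
#'
#' @param front_history List of first-front objective matrices, one per
#'   completed generation.
#' @param tol Objective-space tolerance (default 1e-4).
#' @param period Check interval in generations (default 10).
#' @param max_gen Generation cap (default 300).
#' @return `TRUE` if the run should stop.
#' @export
check_termination <- function(front_history, tol = 1e-4, period = 10, max_gen = 300) {
  gen <- length(front_history)
  if (gen >= max_gen) return(TRUE)
  if (gen %% period != 0 || gen < 2 * period) return(FALSE)
  summ <- function(f) c(apply(f, 2L, min), apply(f, 2L, max))
  delta <- abs(summ(front_history[[gen]]) - summ(front_history[[gen - period]]))
  max(delta) <= tol
}

#' Run the NSGA-III evolutionary loop
#'
#' Random initialization, then per generation: variation, combination of
#' parents and offspring, non-dominated sorting, acceptance of whole fronts
#' into S_t until N is reached, and niche-preserving selection from the last
#' partially accepted front. Reproducible given the caller's RNG seed.
#'
#' @param fitness_fn Function mapping a chromosome (list with `bits`, `ints`,
#'   `reals`) to a numeric objective vector (all minimized).
#' @param encoding An [nsga_encoding()].
#' @param n_objectives Number of objectives M (default 3).
#' @param n_pop Population size N (default 20).
#' @param ref_divisions Das-Dennis divisions p (default 5: 21 points for
#'   M = 3).
#' @param tol,period,max_gen Termination parameters; see
#'   [check_termination()].
#' @param rates Variation rates passed to [vary()].
#'
#' @return An object of class `nsga3_result`: `population` (final
#'   chromosomes), `objectives` (matrix), `front1` (indices of the final
#'   non-dominated set), `front_history`, `log` (tibble of every evaluation),
#'   `generations`.
#' @export
nsga3_evolve <- function(fitness_fn, encoding, n_objectives = 3, n_pop = 20,
                         ref_divisions = 5, tol = 1e-4, period = 10,
                         max_gen = 300, rates = NULL) {
  if (is.null(rates)) {
    rates <- list(p_cross = 0.9, p_int_mut = 0.1, p_real_mut = 0.1,
                  sbx_eta = 30, pm_eta = 20)
  }
  ref <- generate_reference_points(n_objectives, ref_divisions)
  eval_chrom <- function(ch) {
    f <- fitness_fn(ch)
    if (length(f) != n_objectives || any(!is.finite(f))) {
      stop("fitness_fn returned an invalid objective vector for chromosome: ",
           paste(ch$bits, collapse = ""), " / ",
           paste(c(ch$ints, signif(ch$reals, 4)), collapse = ","))
    }
    f
  }

  population <- replicate(n_pop, random_chromosome(encoding), simplify = FALSE)
  objectives <- t(vapply(population, eval_chrom, numeric(n_objectives)))

  log_rows <- list()
  log_gen <- function(gen, chroms, objs, front1_idx) {
    in_front <- seq_len(nrow(objs)) %in% front1_idx
    log_rows[[length(log_rows) + 1L]] <<- tibble::tibble(
      generation = gen,
      bits = vapply(chroms, function(c) paste(c$bits, collapse = ""), ""),
      ints = lapply(chroms, `[[`, "ints"),
      reals = lapply(chroms, `[[`, "reals"),
      objectives = lapply(seq_len(nrow(objs)), function(i) objs[i, ]),
      in_first_front = in_front
    )
  }

  front_history <- list()
  fronts <- non_dominated_sort(objectives)
  log_gen(0L, population, objectives, fronts[[1L]])

  gen <- 0L
  repeat {
    gen <- gen + 1L
    # rank and association distance of current parents, for tournaments
    rank <- integer(n_pop)
    for (fi in seq_along(fronts)) rank[fronts[[fi]]] <- fi
    na_parents <- normalize_and_associate(objectives, ref)

    offspring <- vary(population, encoding, rank, na_parents$distance, rates)
    off_obj <- t(vapply(offspring, eval_chrom, numeric(n_objectives)))

    combined <- c(population, offspring)
    comb_obj <- rbind(objectives, off_obj)
    comb_fronts <- non_dominated_sort(comb_obj)

    accepted <- integer(0)
    li <- 0L
    while (length(accepted) < n_pop) {
      li <- li + 1L
      if (length(accepted) + length(comb_fronts[[li]]) <= n_pop) {
        accepted <- c(accepted, comb_fronts[[li]])
      } else break
    }
    if (length(accepted) < n_pop) {
      last_front <- comb_fronts[[li]]
      st <- c(accepted, last_front)
      na <- normalize_and_associate(comb_obj[st, , drop = FALSE], ref)
      assoc <- integer(nrow(comb_obj)); dist <- numeric(nrow(comb_obj))
      assoc[st] <- na$association; dist[st] <- na$distance
      rho <- tabulate(assoc[accepted], nbins = nrow(ref))
      k_slots <- n_pop - length(accepted)
      accepted <- c(accepted,
                    niching_select(last_front, assoc, dist, rho, k_slots))
    }

    population <- combined[accepted]
    objectives <- comb_obj[accepted, , drop = FALSE]
    fronts <- non_dominated_sort(objectives)
    front_history[[gen]] <- objectives[fronts[[1L]], , drop = FALSE]
    log_gen(gen, offspring, off_obj, integer(0))

    if (check_termination(front_history, tol, period, max_gen)) break
  }

  structure(
    list(population = population, objectives = objectives,
         front1 = fronts[[1L]], front_history = front_history,
         log = dplyr::bind_rows(log_rows), generations = gen,
         ref_points = ref),
    class = "nsga3_result"
  )
}

#' @export
print.nsga3_result <- function(x, ...) {
  cat(sprintf("<nsga3_result> %d generations, %d-member final front\n",
              x$generations, length(x$front1)))
  invisible(x)
}

#' @export
tidy.nsga3_result <- function(x, ...) {
  obj <- x$objectives[x$front1, , drop = FALSE]
  out <- tibble::as_tibble(obj, .name_repair = ~ paste0("f", seq_along(.x)))
  out$member <- x$front1
  out
}

#' @export
glance.nsga3_result <- function(x, ...) {
  tibble::tibble(generations = x$generations,
                 front_size = length(x$front1),
                 n_evaluations = nrow(x$log))
}

#' Exact hypervolume for 2- or 3-objective fronts
#'
#' Dominated volume between a point set and a reference point, all
#' objectives minimized. Points not strictly better than the reference in
#' every coordinate are ignored.
#'
#' @param points Numeric matrix of objective vectors (rows).
#' @param ref Reference point (numeric vector, length 2 or 3).
#' @return The hypervolume.
#' @export
hypervolume <- function(points, ref) {
  points <- as.matrix(points)
  m <- length(ref)
  stopifnot(ncol(points) == m, m %in% c(2L, 3L))
  keep <- apply(points, 1L, function(p) all(p < ref))
  points <- points[keep, , drop = FALSE]
  if (nrow(points) == 0L) return(0)

  area2d <- function(pts, rx, ry) {
    nd <- non_dominated_sort(pts)[[1L]]
    pts <- pts[nd, , drop = FALSE]
    pts <- pts[order(pts[, 1L]), , drop = FALSE]
    pts <- pts[!duplicated(pts[, 1L]), , drop = FALSE]
    y_prev <- ry
    a <- 0
    for (i in seq_len(nrow(pts))) {
      a <- a + (rx - pts[i, 1L]) * (y_prev - pts[i, 2L])
      y_prev <- pts[i, 2L]
    }
    a
  }
  if (m == 2L) return(area2d(points, ref[1L], ref[2L]))

  ord <- order(points[, 3L])
  points <- points[ord, , drop = FALSE]
  z <- c(points[, 3L], ref[3L])
  vol <- 0
  for (i in seq_len(nrow(points))) {
    dz <- z[i + 1L] - z[i]
    if (dz <= 0) next
    vol <- vol + dz * area2d(points[seq_len(i), 1:2, drop = FALSE], ref[1L], ref[2L])
  }
  vol
}
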