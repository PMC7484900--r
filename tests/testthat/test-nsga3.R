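test_that("Das-Dennis reference points lie on the simplex in the right count", {
  z1 <- generate_reference_points(3, 1)
  expect_equal(nrow(z1), 3L)
  expect_true(all(apply(z1, 1, function(r) any(r == 1) && sum(r) == 1)))
  # the three apexes, in some order
  expect_equal(sort(apply(z1, 1, which.max)), 1:3)

  z5 <- generate_reference_points(3, 5)
  expect_equal(nrow(z5), 21L)          # C(7, 5)
  expect_lt(max(abs(rowSums(z5) - 1)), 1e-12)
  expect_equal(nrow(unique(z5)), 21L)

  z_2_4 <- generate_reference_points(2, 4)
  expect_equal(nrow(z_2_4), 5L)
})

test_that("non-dominated sorting matches the brute-force dominance oracle", {
  expect_equal(non_dominated_sort(matrix(c(1, 2, 3), 1)), list(1L))
  chain <- rbind(c(1, 1, 1), c(2, 2, 2), c(3, 3, 3))
  expect_equal(non_dominated_sort(chain), list(1L, 2L, 3L))

  set.seed(61)
  for (rep in 1:30) {
    n <- sample(5:50, 1)
    obj <- matrix(sample(1:8, n * 3, replace = TRUE), ncol = 3)  # many ties
    got <- non_dominated_sort(obj)
    want <- brute_force_fronts(obj)
    expect_equal(lapply(got, sort), lapply(want, sort))
  }
  expect_equal(non_dominated_sort(matrix(numeric(0), 0, 3)), list())
})

test_that("normalization and association follow the reference-line geometry", {
  # extremes at (1,0) and (0,1) make the normalization the identity map
  obj <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5))
  na <- normalize_and_associate(obj, rbind(c(1, 0), c(0, 1), c(0.5, 0.5)))
  # point on an axis associates with that axis line at distance ~0
  expect_equal(na$association[1], 1L)
  expect_equal(na$association[2], 2L)
  expect_equal(na$association[3], 3L)
  # sqrt of a cancellation residual: ~1e-8 is the double-precision floor
  expect_lt(na$distance[3], 1e-6)

  # translation invariance via the ideal-point subtraction
  shift <- sweep(obj, 2, c(3, -1), "+")
  na2 <- normalize_and_associate(shift, rbind(c(1, 0), c(0, 1), c(0.5, 0.5)))
  expect_equal(na2$association, na$association)
  expect_equal(na2$distance, na$distance)

  # hand-computed toy: ideal (1,2), intercepts from extremes (5,0),(0,4) scaled
  toy <- rbind(c(6, 2), c(1, 6))
  nat <- normalize_and_associate(toy, rbind(c(1, 0), c(0, 1)))
  expect_equal(nat$normalized, rbind(c(1, 0), c(0, 1)))
  expect_equal(nat$distance, c(0, 0))

  # identical rows: fallback scale, no crash
  same <- rbind(c(1, 1), c(1, 1))
  nas <- normalize_and_associate(same, rbind(c(1, 0), c(0, 1)))
  expect_true(all(is.finite(nas$distance)))
})

test_that("niching reproduces a hand-traced selection with the exclusion rule", {
  # three reference points; members 1..3 are the last front
  assoc <- c(1L, 1L, 3L)
  dist <- c(0.5, 0.1, 0.9)
  # all niche counts zero, three slots: point 2 (closest to ref 1), then the
  # ref-3 member, then (ref 2 excluded: no member) member 1 for ref 1
  set.seed(62)
  sel <- niching_select(1:3, assoc, dist, rho = c(0L, 0L, 0L), k_slots = 3)
  expect_setequal(sel, 1:3)
  expect_equal(sel[assoc[sel] == 1][1], 2L)  # min-distance pick for empty niche

  # a reference point with rho = 0 but no associated member is skipped
  sel2 <- niching_select(1:2, c(1L, 1L), c(0.3, 0.2), rho = c(0L, 0L, 5L), 2)
  expect_setequal(sel2, 1:2)

  expect_equal(niching_select(integer(0), assoc, dist, c(0L, 0L, 0L), 0),
               integer(0))
  expect_error(niching_select(1:2, assoc, dist, c(0L, 0L, 0L), 3), "slots")
})

test_that("variation copies parents when all rates are zero and repairs masks", {
  enc <- nsga_encoding(n_bits = 6, int_ranges = list(c(1, 3)),
                       real_ranges = list(c(0, 1)))
  set.seed(63)
  parents <- replicate(8, restid:::random_chromosome(enc), simplify = FALSE)
  no_var <- list(p_cross = 0, p_int_mut = 0, p_real_mut = 0, p_bit = 0,
                 sbx_eta = 30, pm_eta = 20)
  off <- vary(parents, enc, rank = rep(1L, 8), distance = runif(8), no_var)
  expect_length(off, 8L)
  sig <- function(c) paste(c(c$bits, c$ints, signif(c$reals, 12)), collapse = "|")
  expect_true(all(vapply(off, sig, "") %in% vapply(parents, sig, "")))

  # forcing every bit to flip from a single-bit parent triggers the repair
  one_bit <- list(bits = c(1L, rep(0L, 5)), ints = 2L, reals = 0.5)
  all_flip <- list(p_cross = 0, p_int_mut = 0, p_real_mut = 0, p_bit = 1,
                   sbx_eta = 30, pm_eta = 20)
  off2 <- vary(rep(list(one_bit), 4), enc, rep(1L, 4), rep(0, 4), all_flip)
  expect_true(all(vapply(off2, function(c) sum(c$bits), integer(1)) >= 1L))

  # determinism under a fixed seed
  set.seed(64); a <- vary(parents, enc, rep(1L, 8), runif(8))
  set.seed(64); b <- vary(parents, enc, rep(1L, 8), runif(8))
  expect_identical(a, b)
})

test_that("termination fires on the period, the tolerance, and the cap", {
  f <- matrix(c(1, 2, 3, 1, 2, 3), ncol = 3)
  hist_same <- rep(list(f), 20)
  expect_true(check_termination(hist_same, tol = 1e-4, period = 10, max_gen = 300))
  expect_false(check_termination(hist_same[1:7], 1e-4, 10, 300))   # no check at gen 7
  expect_false(check_termination(hist_same[1:10], 1e-4, 10, 300))  # nothing to compare yet
  moving <- c(rep(list(f), 10), rep(list(f + 1), 10))
  expect_false(check_termination(moving, 1e-4, 10, 300))
  expect_true(check_termination(moving, tol = 2, period = 10, max_gen = 300))
  expect_true(check_termination(hist_same[1:5], 1e-4, 10, max_gen = 5))
})

test_that("the evolutionary loop is reproducible and improves DTLZ1", {
  enc <- dtlz1_encoding()
  set.seed(65)
  r1 <- nsga3_evolve(dtlz1_fitness, enc, n_pop = 20, max_gen = 15, tol = 0)
  set.seed(65)
  r2 <- nsga3_evolve(dtlz1_fitness, enc, n_pop = 20, max_gen = 15, tol = 0)
  expect_identical(r1$objectives, r2$objectives)
  expect_identical(r1$population, r2$population)
  expect_identical(r1$log, r2$log)

  # every generation keeps exactly N members and mutually non-dominated fronts
  expect_equal(nrow(r1$objectives), 20L)
  for (f in r1$front_history) {
    expect_equal(length(non_dominated_sort(f)), 1L)
  }
  # the final front strictly improves on the initial population's front
  ref <- c(500, 500, 500)
  expect_gt(hypervolume(r1$front_history[[15]], ref),
            hypervolume(r1$front_history[[1]], ref))

  # constant objectives terminate at the first tolerance comparison
  set.seed(66)
  rc <- nsga3_evolve(function(ch) c(1, 1, 1), enc, n_pop = 12, max_gen = 300)
  expect_equal(rc$generations, 20L)

  # a failing fitness function aborts with chromosome context
  set.seed(67)
  expect_error(
    nsga3_evolve(function(ch) c(NA_real_, 1, 1), enc, n_pop = 8, max_gen = 5),
    "invalid objective"
  )
})

test_that("hypervolume matches hand-computed box volumes", {
  expect_equal(hypervolume(matrix(c(0, 0), 1), c(1, 1)), 1)
  expect_equal(hypervolume(matrix(c(0.5, 0.5), 1), c(1, 1)), 0.25)
  # two staircase points in 2d: union of 0.5x1 and 1x0.3 boxes
  expect_equal(hypervolume(rbind(c(0.5, 0), c(0, 0.7)), c(1, 1)),
               0.5 * 1 + 0.5 * 0.3)
  # 3d: single point box + a dominated point adds nothing
  expect_equal(hypervolume(rbind(c(0, 0, 0), c(0.5, 0.5, 0.5)), c(1, 1, 1)), 1)
  # 3d union of two boxes: (0.5,0.5,0) and (0,0,0.5) against (1,1,1)
  expect_equal(hypervolume(rbind(c(0.5, 0.5, 0), c(0, 0, 0.5)), c(1, 1, 1)),
               0.5 * (0.5 * 0.5) + 0.5 * 1)
  expect_equal(hypervolume(matrix(c(2, 2), 1), c(1, 1)), 0)
})
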