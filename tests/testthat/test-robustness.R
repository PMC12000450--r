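test_that("dice coefficient behaves as a set-overlap score", {
  expect_equal(dice(c("a", "b"), c("a", "b")), 1)
  expect_equal(dice(c("a"), c("b")), 0)
  expect_equal(dice(c("a", "b", "c"), c("b", "c", "d")), 2 * 2 / 6)
  expect_equal(dice(character(0), character(0)), 1)
  expect_equal(dice(c("a", "a", "b"), c("a", "b")), 1)  # duplicates ignored
  # symmetry and range over random sets
  set.seed(3)
  for (i in 1:20) {
    a <- sample(letters, sample(0:10, 1))
    b <- sample(letters, sample(1:10, 1))
    d <- dice(a, b)
    expect_equal(d, dice(b, a))
    expect_gte(d, 0)
    expect_lte(d, 1)
  }
})

test_that("partition matching is the optimal assignment, with padding", {
  p <- list(c("a", "b"), c("c", "d"))
  m <- match_partitions(p, p)
  expect_equal(m$pairs$dice, c(1, 1))
  expect_equal(m$total, 2)
  # 2 vs 3 communities: three pairs, one against a padded empty community
  r <- list(c("a", "b"), c("c"), c("d"))
  m2 <- match_partitions(p, r)
  expect_equal(nrow(m2$pairs), 3)
  expect_true(any(is.na(m2$pairs$p_comm)))
  expect_equal(sum(m2$pairs$dice == 0), 1)
  # a score matrix whose greedy and optimal totals differ: the DP must pick
  # the globally best pairing (verified by enumerating both assignments)
  p3 <- list(c("a", "b", "c", "x", "y"), c("d", "e"))
  r3 <- list(c("a", "b", "d"), c("c", "x", "y", "e"))
  d11 <- dice(p3[[1]], r3[[1]]); d12 <- dice(p3[[1]], r3[[2]])
  d21 <- dice(p3[[2]], r3[[1]]); d22 <- dice(p3[[2]], r3[[2]])
  best <- max(d11 + d22, d12 + d21)
  expect_equal(match_partitions(p3, r3)$total, best)
})

test_that("partition overlap is 1 on identical partitions and penalizes splits", {
  memb <- stats::setNames(c(0, 0, 1, 1), c("a", "b", "c", "d"))
  expect_equal(partition_overlap(memb, memb), 1)
  crossed <- stats::setNames(c(0, 1, 0, 1), c("a", "b", "c", "d"))
  expect_equal(partition_overlap(memb, crossed), 0.5)  # all cross-Dice 0.5
  # subset restricted to one community's codes, identical partitions
  expect_equal(partition_overlap(memb, memb, code_subset = c("a", "b")), 1)
  expect_error(partition_overlap(memb, memb, code_subset = "zzz"),
               "empties")
})

test_that("quartile subsets follow the half-open interval convention", {
  f <- stats::setNames(c(1, 2, 3, 4), c("a", "b", "c", "d"))
  expect_equal(quantile_subset(f, "Q0"), "a")
  expect_equal(quantile_subset(f, "Q1"), "b")
  expect_equal(quantile_subset(f, "Q2"), "c")
  expect_equal(quantile_subset(f, "Q3"), "d")
  # all frequencies equal: everything lands in Q3
  g <- stats::setNames(rep(5, 4), c("a", "b", "c", "d"))
  expect_equal(quantile_subset(g, "Q3"), c("a", "b", "c", "d"))
  expect_length(quantile_subset(g, "Q0"), 0)
  expect_length(quantile_subset(g, "Q1"), 0)
  # Q3 of 1..100 is the top quarter
  h <- stats::setNames(1:100, sprintf("c%03d", 1:100))
  expect_equal(quantile_subset(h, "Q3"),
               sprintf("c%03d", which(1:100 >= stats::quantile(1:100, 0.75))))
})

test_that("shuffle experiment is stable on a graph with a unique optimum", {
  tri <- two_triangles()
  res <- shuffle_experiment(tri, n_runs = 5, seed = 2)
  expect_equal(res$mean_overlap, 1)
  expect_equal(res$sem, 0)
  expect_equal(res$n_trials, 4)
  res2 <- shuffle_experiment(tri, n_runs = 2, seed = 2)
  expect_equal(res2$n_trials, 1)
  expect_error(shuffle_experiment(tri, n_runs = 1), "at least 2")
})

test_that("experiments are reproducible from the master seed", {
  fx <- small_fixture()
  g <- build_graph(fx$sim$records, fx$cohort)
  a <- shuffle_experiment(g, n_runs = 4, seed = 5)
  b <- shuffle_experiment(g, n_runs = 4, seed = 5)
  expect_identical(a$per_trial_scores, b$per_trial_scores)
  s1 <- split_sample_experiment(fx$sim$records, fx$cohort, n_trials = 2,
                                seed = 5)
  s2 <- split_sample_experiment(fx$sim$records, fx$cohort, n_trials = 2,
                                seed = 5)
  expect_identical(s1$per_trial_scores, s2$per_trial_scores)
  expect_error(split_sample_experiment(fx$sim$records, fx$cohort,
                                       n_trials = 0), ">= 1")
})

test_that("overlap results report a consistent mean and SEM", {
  fx <- small_fixture()
  g <- build_graph(fx$sim$records, fx$cohort)
  res <- shuffle_experiment(g, n_runs = 6, seed = 9)
  expect_equal(res$mean_overlap, mean(res$per_trial_scores))
  expect_equal(res$sem,
               stats::sd(res$per_trial_scores) / sqrt(res$n_trials))
  path <- tempfile(fileext = ".csv")
  write_overlap_results(list(shuffle = res), path)
  tab <- data.table::fread(path)
  expect_equal(tab$mean_overlap, res$mean_overlap)
})

test_that("random null with one community is degenerate at 1", {
  res <- random_null(10, 1, n_trials = 20, seed = 4)
  expect_equal(res$mean_overlap, 1)
  expect_equal(res$sem, 0)
})

test_that("random null matches exhaustive enumeration at n_codes=4, k=2", {
  # independent brute force: enumerate all 2^4 x 2^4 assignment pairs and
  # score each with its own dice + explicit two-pairing maximum
  dice_bf <- function(a, b) {
    if (!length(a) && !length(b)) return(1)
    2 * length(intersect(a, b)) / (length(a) + length(b))
  }
  score_pair <- function(a, b) {
    A <- split(1:4, a)
    B <- split(1:4, b)
    n <- max(length(A), length(B))
    A <- c(A, rep(list(integer(0)), n - length(A)))
    B <- c(B, rep(list(integer(0)), n - length(B)))
    d <- function(x, y) {
      if (!length(x) || !length(y)) return(0)
      dice_bf(x, y)
    }
    if (n == 1) return(dice_bf(A[[1]], B[[1]]))
    max(d(A[[1]], B[[1]]) + d(A[[2]], B[[2]]),
        d(A[[1]], B[[2]]) + d(A[[2]], B[[1]])) / 2
  }
  vals <- numeric(0)
  for (a in 0:15) {
    for (b in 0:15) {
      vals <- c(vals, score_pair(bitwAnd(bitwShiftR(a, 0:3), 1L),
                                 bitwAnd(bitwShiftR(b, 0:3), 1L)))
    }
  }
  exact <- mean(vals)
  expect_equal(exact, 0.6254464, tolerance = 1e-6)
  sim <- random_null(4, 2, n_trials = 4000, seed = 5)
  expect_lt(abs(sim$mean_overlap - exact), 4 * stats::sd(vals) / sqrt(4000) + 0.005)
})

test_that("random null mean exceeds the 1/k baseline via matching", {
  res <- random_null(200, 4, n_trials = 200, seed = 6)
  expect_gt(res$mean_overlap, 1 / 4)
  expect_lt(res$mean_overlap, 0.5)
})

test_that("Welch one-sided test orients and degenerates correctly", {
  expect_equal(welch_one_sided(c(1, 2, 3), c(1, 2, 3)), 0.5)
  set.seed(8)
  real <- stats::rnorm(100, 0.9, 0.01)
  null <- stats::rnorm(100, 0.23, 0.02)
  expect_lt(welch_one_sided(real, null), 1e-10)
  expect_gt(welch_one_sided(null, real), 0.999)
  expect_error(welch_one_sided(1, c(1, 2)), "size >= 2")
  expect_equal(welch_one_sided(c(1, 1), c(0, 0)), 0)
  expect_equal(welch_one_sided(c(0, 0), c(1, 1)), 1)
})
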