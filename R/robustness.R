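#' Dice-Sorensen coefficient of two sets
#'
#' `2|A intersect B| / (|A| + |B|)`; two empty sets are defined as identical
#' (coefficient 1).
#'
#' @param set_a,set_b vectors treated as sets (duplicates ignored).
#' @return coefficient in `[0, 1]`.
#' @export
dice <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  if (length(a) == 0 && length(b) == 0) return(1)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

# communities of a partition (or named membership vector) as a list of
# code sets, ordered by community id
community_sets <- function(p) {
  memb <- if (inherits(p, "partition")) p$membership else p
  assert_that(!is.null(names(memb)), "membership must be a named vector")
  unname(split(names(memb), memb))
}

# Exact maximum-total assignment between the rows and columns of a square
# score matrix via dynamic programming over column subsets. Partitions carry
# few communities, so 2^k states are cheap; guarded at k <= 20.
assignment_dp <- function(score) {
  n <- nrow(score)
  assert_that(n == ncol(score), "score matrix must be square")
  assert_that(n <= 20, "assignment DP supports at most 20 communities")
  nmask <- bitwShiftL(1L, n)
  best <- rep(-Inf, nmask)
  choice <- integer(nmask)
  best[1] <- 0
  for (mask in seq_len(nmask - 1)) {
    i <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0)  # row index
    for (j in seq_len(n)) {
      bit <- bitwShiftL(1L, j - 1)
      if (bitwAnd(mask, bit) == 0) next
      prev <- bitwXor(mask, bit)
      val <- best[prev + 1] + score[i, j]
      if (val > best[mask + 1]) {
        best[mask + 1] <- val
        choice[mask + 1] <- j
      }
    }
  }
  assign_col <- integer(n)
  mask <- nmask - 1L
  for (i in rev(seq_len(n))) {
    j <- choice[mask + 1]
    assign_col[i] <- j
    mask <- bitwXor(mask, bitwShiftL(1L, j - 1))
  }
  list(cols = assign_col, total = best[nmask])
}

#' Match the communities of two partitions
#'
#' Builds the full Dice matrix between the two partitions' communities and
#' pairs them by exact maximum-total-Dice assignment (not greedily). When
#' the partitions have different community counts the smaller side is padded
#' with empty communities, which score Dice 0 against any non-empty
#' community — disagreement in community count is thereby penalized.
#'
#' @param p,r `partition` objects, named membership vectors, or lists of
#'   code sets.
#' @return list with `pairs` (data.table `p_comm`, `r_comm`, `dice`; padded
#'   slots are `NA`) and `total` (summed Dice over matched pairs).
#' @export
match_partitions <- function(p, r) {
  ps <- if (is.list(p) && !inherits(p, "partition")) p else community_sets(p)
  rs <- if (is.list(r) && !inherits(r, "partition")) r else community_sets(r)
  kp <- length(ps)
  kr <- length(rs)
  n <- max(kp, kr)
  score <- matrix(0, n, n)
  for (i in seq_len(kp)) {
    for (j in seq_len(kr)) {
      score[i, j] <- dice(ps[[i]], rs[[j]])
    }
  }
  # padded rows/columns (empty vs possibly non-empty) keep score 0
  sol <- assignment_dp(score)
  pairs <- data.table::data.table(
    p_comm = ifelse(seq_len(n) <= kp, seq_len(n) - 1L, NA_integer_),
    r_comm = ifelse(sol$cols <= kr, sol$cols - 1L, NA_integer_),
    dice = score[cbind(seq_len(n), sol$cols)]
  )
  list(pairs = pairs, total = sol$total)
}

#' Mean matched Dice-Sorensen overlap between two partitions
#'
#' Communities are optionally intersected with `code_subset` first;
#' communities emptied by the intersection are dropped before matching
#' (padding then penalizes any resulting count mismatch). The score is the
#' mean Dice over matched pairs, padded pairs included.
#'
#' @param p,r partitions (see [match_partitions()]).
#' @param code_subset optional character vector of codes to restrict to.
#' @return mean matched Dice in `[0, 1]`.
#' @export
partition_overlap <- function(p, r, code_subset = NULL) {
  ps <- if (is.list(p) && !inherits(p, "partition")) p else community_sets(p)
  rs <- if (is.list(r) && !inherits(r, "partition")) r else community_sets(r)
  if (!is.null(code_subset)) {
    ps <- lapply(ps, intersect, code_subset)
    rs <- lapply(rs, intersect, code_subset)
    ps <- ps[lengths(ps) > 0]
    rs <- rs[lengths(rs) > 0]
    assert_that(length(ps) > 0 && length(rs) > 0,
                "code_subset empties every community")
  }
  m <- match_partitions(ps, rs)
  mean(m$pairs$dice)
}

overlap_result <- function(scores, quantile_filter = "all", skipped = 0L) {
  structure(list(
    mean_overlap = mean(scores),
    sem = stats::sd(scores) / sqrt(length(scores)),
    n_trials = length(scores),
    quantile_filter = quantile_filter,
    per_trial_scores = scores,
    skipped = skipped
  ), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "Overlap [%s]: mean %.4f +/- %.4f SEM over %d trials%s\n",
    x$quantile_filter, x$mean_overlap, x$sem, x$n_trials,
    if (x$skipped > 0) sprintf(" (%d skipped)", x$skipped) else ""))
  invisible(x)
}

#' Codes whose population frequency falls in a given quartile
#'
#' Quartile boundaries are linear-interpolation percentiles
#' ([stats::quantile()] type 7) of the frequency values. Intervals are
#' half-open: `Q0 = [min, 25th)`, `Q1 = [25th, 50th)`, `Q2 = [50th, 75th)`,
#' `Q3 = [75th, max]`. With all frequencies equal, Q3 holds every code and
#' the lower quartiles are empty.
#'
#' @param code_frequencies named numeric vector, code -> frequency.
#' @param which one of `"Q0"`, `"Q1"`, `"Q2"`, `"Q3"`.
#' @return character vector of codes.
#' @export
quantile_subset <- function(code_frequencies, which = c("Q0", "Q1", "Q2", "Q3")) {
  which <- match.arg(which)
  assert_that(length(code_frequencies) > 0, "empty frequency map")
  f <- code_frequencies
  q <- stats::quantile(f, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  sel <- switch(which,
                Q0 = f < q[1],
                Q1 = f >= q[1] & f < q[2],
                Q2 = f >= q[2] & f < q[3],
                Q3 = f >= q[3])
  names(f)[sel]
}

# Scoring universe for the robustness experiments: the EIM/AID codes. The
# cohort-defining IBD index codes are kept in the graph (they anchor the
# clusters) but excluded from overlap scoring — their membership is not an
# extraintestinal finding, and their near-universal frequency in a cohort
# defined by them would distort the frequency quartiles.
resolve_subset <- function(graph, quantile_filter,
                           exclude_prefixes = c("K50", "K51", "555", "556")) {
  codes <- graph$nodes$code
  keep <- !is_ibd_code(codes, exclude_prefixes)
  if (!any(keep)) keep <- rep(TRUE, length(codes))  # pure index graph
  freqs <- stats::setNames(graph$nodes$n[keep], codes[keep])
  if (identical(quantile_filter, "all")) return(names(freqs))
  quantile_subset(freqs, quantile_filter)
}

#' Edge-shuffle stability experiment
#'
#' Quantifies the variability of Louvain communities that arises purely from
#' the algorithm's sensitivity to edge input order: the graph is fixed,
#' [louvain()] is run `n_runs` times under independently shuffled edge
#' orders, and the matched overlap of each consecutive pair of partitions is
#' scored, giving `n_runs - 1` trials.
#'
#' @param graph a `cooc_graph`.
#' @param n_runs number of Louvain runs (>= 2).
#' @param seed master seed; per-run shuffle seeds are derived from it.
#' @param quantile_filter `"all"` or one of `"Q0"`–`"Q3"`; restricts scoring
#'   to codes whose patient frequency falls in that quartile. Overlap is
#'   always scored over the EIM/AID codes only: the IBD index codes stay in
#'   the graph as cluster anchors but are not themselves manifestations, so
#'   they are excluded from the scoring universe and from the frequency
#'   quartiles.
#' @return an `overlap_result`.
#' @export
shuffle_experiment <- function(graph, n_runs = 20, seed = 1,
                               quantile_filter = "all") {
  assert_that(n_runs >= 2, "need at least 2 runs")
  subset <- resolve_subset(graph, quantile_filter)
  parts <- lapply(seq_len(n_runs), function(i) {
    louvain(graph, seed = derive_seed(seed, i))
  })
  scores <- vapply(seq_len(n_runs - 1), function(i) {
    partition_overlap(parts[[i]], parts[[i + 1]], code_subset = subset)
  }, numeric(1))
  overlap_result(scores, quantile_filter)
}

#' Split-sample stability experiment
#'
#' Quantifies the variability of the detected communities that arises from
#' patient sampling: per trial, the case patients are split into two equally
#' sized, mutually exclusive random halves; a co-occurrence graph is built
#' and Louvain run on each half with edges in fixed alphabetical order
#' (controlling algorithmic variability); the two partitions' matched
#' overlap is scored. Trials in which either half yields an edgeless graph
#' are skipped with a warning.
#'
#' @param records encounter table.
#' @param cohort labelled cohort.
#' @param n_trials number of split trials (>= 1).
#' @param seed master seed; per-trial split seeds are derived from it.
#' @param quantile_filter as in [shuffle_experiment()]; code frequencies are
#'   taken from the full-cohort graph.
#' @param cohort_tag which cohort to analyse (default `"IBD"`).
#' @param ... further arguments passed to [build_graph()].
#' @return an `overlap_result`.
#' @export
split_sample_experiment <- function(records, cohort, n_trials = 10, seed = 1,
                                    quantile_filter = "all",
                                    cohort_tag = "IBD", ...) {
  assert_that(n_trials >= 1, "n_trials must be >= 1")
  coh <- data.table::as.data.table(cohort)
  labs <- switch(cohort_tag, IBD = c("CD", "UC", "IBDU"), CD = "CD", UC = "UC")
  case_ids <- coh[label %in% labs, patient_id]
  assert_that(length(case_ids) >= 2, "need at least 2 case patients")
  rec <- data.table::as.data.table(records)
  full_graph <- build_graph(rec, coh, cohort_tag = cohort_tag, ...)
  subset <- resolve_subset(full_graph, quantile_filter)

  scores <- numeric(0)
  skipped <- 0L
  for (t in seq_len(n_trials)) {
    ids <- local_seed(derive_seed(seed, t), sample(case_ids))
    half <- length(ids) %/% 2
    halves <- list(ids[seq_len(half)], ids[(half + 1):length(ids)])
    parts <- vector("list", 2)
    ok <- TRUE
    for (h in 1:2) {
      g <- build_graph(rec[patient_id %in% halves[[h]]],
                       coh[patient_id %in% halves[[h]]],
                       cohort_tag = cohort_tag, ...)
      if (nrow(g$edges) == 0) {
        ok <- FALSE
        break
      }
      parts[[h]] <- louvain(g)  # canonical alphabetical edge order
    }
    if (!ok) {
      skipped <- skipped + 1L
      warning(sprintf("trial %d skipped: edgeless half-sample graph", t))
      next
    }
    scores <- c(scores,
                partition_overlap(parts[[1]], parts[[2]], code_subset = subset))
  }
  assert_that(length(scores) > 0, "every trial was skipped")
  overlap_result(scores, quantile_filter, skipped)
}

#' Random-assignment null distribution of partition overlap
#'
#' Per trial, two independent uniform random assignments of `n_codes` codes
#' to `n_communities` communities are drawn and their matched overlap is
#' scored exactly as for real partitions. The mean and SEM over trials give
#' the null expectation against which the stability experiments are
#' compared.
#'
#' @param n_codes number of codes (network nodes).
#' @param n_communities number of communities (>= 1).
#' @param n_trials number of trial pairs.
#' @param seed master seed; per-trial seeds are derived from it.
#' @return an `overlap_result`.
#' @export
random_null <- function(n_codes, n_communities, n_trials = 1000, seed = 1) {
  assert_that(n_communities >= 1, "n_communities must be >= 1")
  assert_that(n_codes >= n_communities, "need n_codes >= n_communities")
  assert_that(n_trials >= 1, "n_trials must be >= 1")
  codes <- sprintf("C%05d", seq_len(n_codes))
  scores <- vapply(seq_len(n_trials), function(t) {
    ab <- local_seed(derive_seed(seed, t),
                     list(a = sample.int(n_communities, n_codes, replace = TRUE),
                          b = sample.int(n_communities, n_codes, replace = TRUE)))
    pa <- stats::setNames(ab$a, codes)
    pb <- stats::setNames(ab$b, codes)
    partition_overlap(pa, pb)
  }, numeric(1))
  overlap_result(scores)
}

#' One-sided Welch's t-test
#'
#' Welch t statistic with Satterthwaite degrees of freedom; one-sided p for
#' the alternative `mean(sample_real) > mean(sample_null)`. Degenerate
#' inputs (both samples constant) are handled exactly: p is 0, 0.5 or 1
#' according to the sign of the mean difference.
#'
#' @param sample_real,sample_null numeric samples of size >= 2.
#' @return one-sided p-value.
#' @export
welch_one_sided <- function(sample_real, sample_null) {
  assert_that(length(sample_real) >= 2 && length(sample_null) >= 2,
              "both samples must have size >= 2")
  if (stats::sd(sample_real) == 0 && stats::sd(sample_null) == 0) {
    d <- mean(sample_real) - mean(sample_null)
    return(if (d > 0) 0 else if (d < 0) 1 else 0.5)
  }
  stats::t.test(sample_real, sample_null, alternative = "greater",
                var.equal = FALSE)$p.value
}

#' Write robustness results to CSV
#'
#' @param results named list of `overlap_result`s (names label the
#'   experiment/quantile combination).
#' @param path output CSV path.
#' @export
write_overlap_results <- function(results, path) {
  tab <- data.table::rbindlist(lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.table::data.table(experiment = nm,
                           quantile_filter = r$quantile_filter,
                           mean_overlap = r$mean_overlap,
                           sem = r$sem, n_trials = r$n_trials)
  }))
  data.table::fwrite(tab, path)
  invisible(path)
}
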