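# Shared fixtures and independent oracles, built in code at test time.

# Construct a cooc_graph directly from edge endpoint vectors (unit weights
# unless given). Used for algorithmic fixtures where patient-level detail is
# irrelevant.
make_graph <- function(ea, eb, w = rep(1L, length(ea))) {
  codes <- sort(unique(c(ea, eb)))
  nodes <- data.table::data.table(code = codes, n = 1L,
                                  display_size = node_size(1),
                                  domain = "unmapped")
  swap <- ea > eb
  tmp <- ea[swap]; ea[swap] <- eb[swap]; eb[swap] <- tmp
  edges <- data.table::data.table(code_a = ea, code_b = eb,
                                  m = as.integer(w),
                                  display_width = edge_width(w),
                                  a_first = 0L, b_first = 0L,
                                  same_day = as.integer(w))
  data.table::setorder(edges, code_a, code_b)
  structure(list(nodes = nodes, edges = edges, cohort_tag = "IBD",
                 cohort_sizes = NULL,
                 incidence = data.table::data.table()),
            class = "cooc_graph")
}

# two disconnected triangles: the classic fixture whose optimal partition
# (one community per triangle) has Q = 0.5
two_triangles <- function() {
  make_graph(c("A", "A", "B", "D", "D", "E"),
             c("B", "C", "C", "E", "F", "F"))
}

complete_graph <- function(n) {
  cmb <- utils::combn(LETTERS[seq_len(n)], 2)
  make_graph(cmb[1, ], cmb[2, ])
}

# Enumerate all set partitions of n elements as restricted-growth strings
# (block labels 1..k). Exhaustive-search oracle for modularity optima.
set_partitions <- function(n) {
  out <- list()
  rec <- function(i, rg, mx) {
    if (i > n) {
      out[[length(out) + 1L]] <<- rg
      return(invisible(NULL))
    }
    for (b in seq_len(mx + 1L)) rec(i + 1L, c(rg, b), max(mx, b))
  }
  rec(2L, 1L, 1L)
  out
}

# Exhaustive maximum modularity over all partitions of a small graph.
best_partition_exhaustive <- function(graph) {
  codes <- graph$nodes$code
  stopifnot(length(codes) <= 8)
  best_q <- -Inf
  best <- NULL
  for (rg in set_partitions(length(codes))) {
    q <- modularity_q(graph, stats::setNames(rg, codes))
    if (q > best_q) {
      best_q <- q
      best <- rg
    }
  }
  list(q = best_q, assignment = stats::setNames(best, codes))
}

# Brute-force pairwise co-occurrence counts from raw records: for every
# unordered code pair, count patients carrying both. Independent of the
# data.table join used by build_graph.
brute_force_m <- function(records) {
  sets <- tapply(records$icd_code, records$patient_id,
                 function(x) unique(x), simplify = FALSE)
  codes <- sort(unique(records$icd_code))
  out <- list()
  for (i in seq_along(codes)) {
    for (j in seq_along(codes)) {
      if (j <= i) next
      m <- sum(vapply(sets, function(s) {
        codes[i] %in% s && codes[j] %in% s
      }, logical(1)))
      if (m > 0) {
        out[[length(out) + 1L]] <- data.frame(code_a = codes[i],
                                              code_b = codes[j], m = m)
      }
    }
  }
  do.call(rbind, out)
}

# Memoized standard planted-structure cohort (the generator's defaults:
# 2000 patients, 4 blocks x 25 codes, p_within 0.3, p_between 0.01).
.fixtures <- new.env(parent = emptyenv())

planted_fixture <- function() {
  if (is.null(.fixtures$planted)) {
    sim <- generate_cohort(sim_config(seed = 42))
    cohort <- build_cohort(sim$records,
                           demographics = sim$truth$demographics)
    graph <- build_graph(sim$records, cohort, cohort_tag = "IBD")
    .fixtures$planted <- list(sim = sim, cohort = cohort, graph = graph)
  }
  .fixtures$planted
}

# Small cohort for cheaper end-to-end tests.
small_fixture <- function() {
  if (is.null(.fixtures$small)) {
    sim <- generate_cohort(sim_config(n_patients = 300, seed = 11))
    cohort <- build_cohort(sim$records,
                           demographics = sim$truth$demographics)
    .fixtures$small <- list(sim = sim, cohort = cohort)
  }
  .fixtures$small
}
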