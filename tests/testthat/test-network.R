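toy_records <- function() {
  data.table::data.table(
    patient_id = c("P1", "P1", "P1", "P2", "P2", "P3"),
    date = as.Date(c("2010-01-01", "2012-05-05", "2011-03-03",
                     "2010-02-02", "2010-02-02", "2010-09-09")),
    icd_code = c("F32.1", "F32.1", "M45.0", "F32.1", "M45.0", "F32.1"),
    encounter_type = "physician_claim"
  )
}

toy_cohort <- function() {
  data.table::data.table(patient_id = c("P1", "P2", "P3"),
                         label = c("CD", "UC", "CD"))
}

test_that("first diagnosis dates are per-patient minima", {
  fd <- first_diagnosis_dates(toy_records())
  expect_equal(fd[fd$patient_id == "P1" & fd$icd_code == "F32.1", ]$first_date,
               as.Date("2010-01-01"))
  expect_equal(nrow(fd), 5)  # (patient, code) pairs, repeats collapsed
  expect_equal(nrow(first_diagnosis_dates(toy_records()[0])), 0)
})

test_that("display formulas follow the published scaling", {
  expect_equal(node_size(0), 2.5)
  expect_equal(node_size(100), 5.5)
  expect_equal(node_size(10000), 32.5)
  expect_error(node_size(-1), "non-negative")
  expect_equal(edge_width(0), 0)
  expect_equal(edge_width(1), 0.01)
  expect_equal(edge_width(100), 1)
  expect_error(edge_width(-2), "non-negative")
})

test_that("graph counts unique patients and classifies edge direction", {
  g <- build_graph(toy_records(), toy_cohort())
  expect_equal(sort(g$nodes$code), c("F32.1", "M45.0"))
  expect_equal(g$nodes$n[g$nodes$code == "F32.1"], 3L)
  expect_equal(g$nodes$n[g$nodes$code == "M45.0"], 2L)
  expect_equal(g$nodes$display_size, node_size(g$nodes$n))
  e <- g$edges
  expect_equal(nrow(e), 1)
  expect_equal(e$code_a, "F32.1")  # canonical lexicographic orientation
  expect_equal(e$m, 2L)
  # P1: F32.1 (2010-01) before M45.0 (2011-03); P2: same day
  expect_equal(e$a_first, 1L)
  expect_equal(e$b_first, 0L)
  expect_equal(e$same_day, 1L)
  expect_equal(e$display_width, edge_width(e$m))
  # per-disease tooltip counts
  expect_equal(g$nodes$n_CD[g$nodes$code == "F32.1"], 2L)
  expect_equal(g$nodes$n_UC[g$nodes$code == "F32.1"], 1L)
})

test_that("nodes without shared patients yield no edges; empty cohort empty graph", {
  rec <- data.table::data.table(patient_id = c("P1", "P2"),
                                date = as.Date("2010-01-01"),
                                icd_code = "F32.1",
                                encounter_type = "ambulatory")
  coh <- data.table::data.table(patient_id = c("P1", "P2"),
                                label = c("CD", "CD"))
  g <- build_graph(rec, coh)
  expect_equal(g$nodes$n, 2L)
  expect_equal(nrow(g$edges), 0)
  g0 <- build_graph(rec, coh[0])
  expect_equal(nrow(g0$nodes), 0)
  expect_equal(nrow(g0$edges), 0)
})

test_that("graph construction is invariant to record order", {
  fx <- small_fixture()
  g1 <- build_graph(fx$sim$records, fx$cohort)
  set.seed(99)
  shuffled <- fx$sim$records[sample(nrow(fx$sim$records)), ]
  g2 <- build_graph(shuffled, fx$cohort)
  expect_equal(g1$nodes, g2$nodes)
  expect_equal(g1$edges, g2$edges)
})

test_that("edge weights match brute-force patient-set intersection", {
  sim <- generate_cohort(sim_config(n_patients = 20, seed = 31))
  cohort <- build_cohort(sim$records)
  g <- build_graph(sim$records, cohort)
  cases <- cohort$patient_id[cohort$label != "excluded"]
  bf <- brute_force_m(sim$records[sim$records$patient_id %in% cases, ])
  got <- g$edges[, c("code_a", "code_b", "m")]
  expect_equal(nrow(got), nrow(bf))
  merged <- merge(got, bf, by = c("code_a", "code_b"))
  expect_equal(nrow(merged), nrow(bf))
  expect_equal(merged$m.x, as.integer(merged$m.y))
})

test_that("direction counts conserve m and never exceed endpoint sizes", {
  fx <- small_fixture()
  g <- build_graph(fx$sim$records, fx$cohort)
  e <- g$edges
  expect_true(all(e$a_first + e$b_first + e$same_day == e$m))
  n_of <- stats::setNames(g$nodes$n, g$nodes$code)
  expect_true(all(e$m <= pmin(n_of[e$code_a], n_of[e$code_b])))
})

test_that("filter_graph applies thresholds, top-n and code truncation", {
  rec <- data.table::data.table(
    patient_id = c("P1", "P1", "P2", "P2", "P3", "P3", "P3"),
    date = as.Date("2010-01-01") + c(0, 1, 0, 1, 0, 1, 2),
    icd_code = c("K50.1", "F32.1", "K50.9", "F32.1", "K50.1", "K50.9", "M45.0"),
    encounter_type = "physician_claim"
  )
  coh <- data.table::data.table(patient_id = c("P1", "P2", "P3"),
                                label = "CD")
  g <- build_graph(rec, coh)
  # all m = 1 here: a min_pair_count of 2 empties the graph
  f <- filter_graph(g, min_pair_count = 2)
  expect_equal(nrow(f$edges), 0)
  expect_equal(nrow(f$nodes), 0)
  # top-1 keeps exactly the heaviest edge
  f1 <- filter_graph(g, top_n_pairs = 1)
  expect_equal(nrow(f1$edges), 1)
  expect_equal(nrow(f1$nodes), 2)
  # truncation at 3 characters merges K50.1/K50.9 into K50 and recomputes
  # unique patients (P3 carries both children but counts once)
  ft <- filter_graph(g, max_code_length = 3)
  expect_true("K50" %in% ft$nodes$code)
  expect_equal(ft$nodes$n[ft$nodes$code == "K50"], 3L)
  expect_false(any(grepl("^K50\\.", ft$nodes$code)))
  # domain restriction keeps only requested chapters
  fd <- filter_graph(g, domain_subset =
                       "Mental, behavioral and neurodevelopmental disorders")
  expect_equal(nrow(fd$edges), 0)  # single-domain codes share no pair here
})

test_that("graphml round trip preserves nodes and edges", {
  fx <- small_fixture()
  g <- build_graph(fx$sim$records, fx$cohort)
  p <- louvain(g)
  path <- tempfile(fileext = ".graphml")
  write_graphml(g, path, partition = p)
  back <- read_graphml(path)
  expect_equal(back$edges[, c("code_a", "code_b", "m", "a_first",
                              "b_first", "same_day")],
               g$edges[, c("code_a", "code_b", "m", "a_first",
                           "b_first", "same_day")])
  expect_equal(back$nodes$code, g$nodes$code)
  expect_equal(back$nodes$n, g$nodes$n)
  expect_equal(stats::setNames(back$nodes$community, back$nodes$code),
               p$membership[back$nodes$code])
  # edge list CSV is written with canonical columns
  csv <- tempfile(fileext = ".csv")
  write_edge_list(g, csv)
  el <- data.table::fread(csv)
  expect_equal(nrow(el), nrow(g$edges))
})
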