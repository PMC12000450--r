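#' First diagnosis date per patient and code
#'
#' @param records encounter table.
#' @return `data.table` with `patient_id`, `icd_code`, `first_date` (the
#'   minimum encounter date for that patient/code).
#' @export
first_diagnosis_dates <- function(records) {
  rec <- data.table::as.data.table(records)
  if (nrow(rec) == 0) {
    return(data.table::data.table(patient_id = character(),
                                  icd_code = character(),
                                  first_date = as.Date(character())))
  }
  rec[, .(first_date = min(date)), by = .(patient_id, icd_code)]
}

#' Display size of a code node
#'
#' `sqrt(n) * 0.3 + 2.5`, where `n` is the number of unique patients carrying
#' the code.
#'
#' @param n non-negative patient count(s).
#' @return display size(s).
#' @export
node_size <- function(n) {
  assert_that(all(n >= 0), "n must be non-negative")
  sqrt(n) * 0.3 + 2.5
}

#' Display width of a co-occurrence edge
#'
#' `m * 0.01`, where `m` is the number of unique patients carrying both
#' codes (the strength of the disease relationship).
#'
#' @param m non-negative shared-patient count(s).
#' @return display width(s).
#' @export
edge_width <- function(m) {
  assert_that(all(m >= 0), "m must be non-negative")
  m * 0.01
}

# Shared graph assembly: nodes, edges and direction counts from a
# (patient, code, first_date, label) incidence table.
graph_from_incidence <- function(fd, cohort_sizes, cohort_tag,
                                 domain_map = NULL,
                                 min_pair_count = 1, min_node_patients = 1) {
  labs <- names(cohort_sizes)
  if (nrow(fd) == 0) {
    return(structure(list(
      nodes = data.table::data.table(code = character(), n = integer(),
                                     display_size = numeric(),
                                     domain = character()),
      edges = data.table::data.table(code_a = character(),
                                     code_b = character(), m = integer(),
                                     display_width = numeric(),
                                     a_first = integer(), b_first = integer(),
                                     same_day = integer()),
      cohort_tag = cohort_tag, cohort_sizes = cohort_sizes,
      incidence = fd), class = "cooc_graph"))
  }
  nodes <- fd[, .(n = data.table::uniqueN(patient_id)), by = .(code = icd_code)]
  for (lab in labs) {
    cnt <- fd[label == lab, .(k = data.table::uniqueN(patient_id)),
              by = .(code = icd_code)]
    nodes[, (paste0("n_", lab)) := 0L]
    nodes[cnt, (paste0("n_", lab)) := i.k, on = "code"]
    nodes[, (paste0("pct_", lab)) :=
            if (cohort_sizes[[lab]] > 0)
              percent(get(paste0("n_", lab)), cohort_sizes[[lab]])
            else NA_real_]
  }
  nodes <- nodes[n >= min_node_patients]
  nodes[, display_size := node_size(n)]
  nodes[, domain := if (is.null(domain_map)) "unmapped"
        else map_code_to_domain(code, domain_map)]
  data.table::setorder(nodes, code)

  # all unordered code pairs per patient, canonical order code_a < code_b
  pairs <- merge(fd[, .(patient_id, icd_code, first_date)],
                 fd[, .(patient_id, icd_code, first_date)],
                 by = "patient_id", allow.cartesian = TRUE,
                 suffixes = c("_a", "_b"))[icd_code_a < icd_code_b]
  pairs <- pairs[icd_code_a %in% nodes$code & icd_code_b %in% nodes$code]
  edges <- pairs[, .(
    m = .N,
    a_first = sum(first_date_a < first_date_b),
    b_first = sum(first_date_a > first_date_b),
    same_day = sum(first_date_a == first_date_b)
  ), by = .(code_a = icd_code_a, code_b = icd_code_b)]
  edges <- edges[m >= min_pair_count]
  edges[, display_width := edge_width(m)]
  data.table::setorder(edges, code_a, code_b)

  structure(list(nodes = nodes, edges = edges, cohort_tag = cohort_tag,
                 cohort_sizes = cohort_sizes, incidence = fd),
            class = "cooc_graph")
}

#' Build the ICD co-occurrence ("diseasome") graph
#'
#' Nodes are ICD codes weighted by the number of unique patients carrying
#' them; undirected edges link codes co-carried by at least one patient,
#' weighted by the number of shared patients `m`. Each co-carrying patient is
#' classified by comparing the two first-diagnosis dates (strictly earlier
#' date wins; equal dates count as `same_day`), giving the temporal
#' direction counts shown in edge tooltips. Co-occurrence is lifetime
#' (ever/ever): no time window is imposed between the two diagnoses.
#'
#' IBD index codes (K50.x/K51.x) are kept as nodes — they anchor the
#' clusters — while codes mapping to no domain can be excluded by supplying
#' `domain_map` with `drop_unmapped = TRUE`.
#'
#' @param records encounter table.
#' @param cohort labelled cohort from [build_cohort()].
#' @param cohort_tag which disease cohort to build: `"IBD"` (CD + UC + IBDU),
#'   `"CD"` or `"UC"`.
#' @param domain_map optional domain map used to annotate nodes.
#' @param drop_unmapped drop codes mapping to `"unmapped"` (default `FALSE`).
#' @param min_pair_count minimum `m` for an edge to be kept (default 1: even
#'   a single shared patient creates an edge).
#' @param min_node_patients minimum `n` for a node to be kept.
#' @return an object of class `cooc_graph` with elements `nodes`, `edges`,
#'   `cohort_tag`, `cohort_sizes` and the underlying `incidence` table.
#' @export
build_graph <- function(records, cohort, cohort_tag = c("IBD", "CD", "UC"),
                        domain_map = default_domain_map(),
                        drop_unmapped = FALSE,
                        min_pair_count = 1, min_node_patients = 1) {
  cohort_tag <- match.arg(cohort_tag)
  labs <- switch(cohort_tag, IBD = c("CD", "UC", "IBDU"),
                 CD = "CD", UC = "UC")
  coh <- data.table::as.data.table(cohort)[label %in% labs]
  sizes <- vapply(labs, function(l) sum(coh$label == l), integer(1))
  fd <- first_diagnosis_dates(records)
  fd <- merge(fd, coh[, .(patient_id, label)], by = "patient_id")
  if (!is.null(domain_map) && drop_unmapped) {
    fd <- fd[map_code_to_domain(icd_code, domain_map) != "unmapped"]
  }
  graph_from_incidence(fd, sizes, cohort_tag, domain_map,
                       min_pair_count, min_node_patients)
}

#' @export
print.cooc_graph <- function(x, ...) {
  cat(sprintf("ICD co-occurrence graph [%s]: %d nodes, %d edges\n",
              x$cohort_tag, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Filter or aggregate a co-occurrence graph for display
#'
#' Applies, in order: code truncation at `max_code_length` characters
#' (re-aggregating patient counts from the raw incidence table, so merged
#' codes count shared patients once), restriction to `domain_subset`,
#' removal of edges with `m < min_pair_count`, retention of the
#' `top_n_pairs` heaviest edges (ties broken lexicographically), and removal
#' of nodes left isolated by the edge filters.
#'
#' @param graph a `cooc_graph`.
#' @param min_pair_count minimum shared-patient count for edges.
#' @param max_code_length truncate/merge codes longer than this many
#'   characters (e.g. 3 merges `K50.1` and `K50.9` into `K50`).
#' @param top_n_pairs keep only this many heaviest edges (the interactive
#'   display caps at 1000).
#' @param domain_subset character vector of domain names to keep.
#' @param domain_map map used to re-annotate truncated codes.
#' @return a filtered `cooc_graph`.
#' @export
filter_graph <- function(graph, min_pair_count = NULL, max_code_length = NULL,
                         top_n_pairs = NULL, domain_subset = NULL,
                         domain_map = default_domain_map()) {
  stopifnot(inherits(graph, "cooc_graph"))
  fd <- data.table::copy(graph$incidence)
  if (!is.null(max_code_length)) {
    assert_that(max_code_length >= 1, "max_code_length must be >= 1")
    fd[, icd_code := substr(icd_code, 1, max_code_length)]
    fd <- fd[, .(first_date = min(first_date)),
             by = .(patient_id, icd_code, label)]
  }
  if (!is.null(domain_subset)) {
    fd <- fd[map_code_to_domain(icd_code, domain_map) %in% domain_subset]
  }
  g <- graph_from_incidence(fd, graph$cohort_sizes, graph$cohort_tag,
                            domain_map)
  if (!is.null(min_pair_count)) {
    g$edges <- g$edges[m >= min_pair_count]
  }
  if (!is.null(top_n_pairs)) {
    data.table::setorder(g$edges, -m, code_a, code_b)
    g$edges <- utils::head(g$edges, top_n_pairs)
    data.table::setorder(g$edges, code_a, code_b)
  }
  keep <- union(g$edges$code_a, g$edges$code_b)
  g$nodes <- g$nodes[code %in% keep]
  g
}

#' Convert to / from igraph and standard graph formats
#'
#' `as_igraph` produces an [igraph::graph_from_data_frame()] object carrying
#' all node and edge attributes; `write_graphml`/`read_graphml` serialize a
#' `cooc_graph` losslessly at the node/edge level (the raw incidence table is
#' not part of the GraphML payload). `write_edge_list` emits a plain CSV.
#'
#' @param graph a `cooc_graph`.
#' @param partition optional [louvain()] partition; adds a `community` node
#'   attribute.
#' @param path file path.
#' @return `as_igraph`: an igraph object. `read_graphml`: a `cooc_graph`
#'   (with an empty incidence table).
#' @export
as_igraph <- function(graph, partition = NULL) {
  stopifnot(inherits(graph, "cooc_graph"))
  nodes <- data.table::copy(graph$nodes)
  if (!is.null(partition)) {
    nodes[, community := as.integer(partition$membership[code])]
  }
  igraph::graph_from_data_frame(
    d = graph$edges, directed = FALSE,
    vertices = nodes[, c("code", setdiff(names(nodes), "code")), with = FALSE]
  )
}

#' @rdname as_igraph
#' @export
write_graphml <- function(graph, path, partition = NULL) {
  igraph::write_graph(as_igraph(graph, partition), path, format = "graphml")
  invisible(path)
}

#' @rdname as_igraph
#' @export
read_graphml <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  vattrs <- igraph::as_data_frame(ig, what = "vertices")
  eattrs <- igraph::as_data_frame(ig, what = "edges")
  nodes <- data.table::as.data.table(vattrs)
  data.table::setnames(nodes, "name", "code")
  if ("id" %in% names(nodes)) nodes[, id := NULL]
  edges <- data.table::as.data.table(eattrs)
  data.table::setnames(edges, c("from", "to"), c("code_a", "code_b"))
  swap <- edges$code_a > edges$code_b
  if (any(swap)) {
    tmp <- edges$code_a[swap]
    edges$code_a[swap] <- edges$code_b[swap]
    edges$code_b[swap] <- tmp
  }
  int_cols <- intersect(c("m", "a_first", "b_first", "same_day", "n"),
                        c(names(edges), names(nodes)))
  for (cc in intersect(int_cols, names(edges))) {
    edges[[cc]] <- as.integer(edges[[cc]])
  }
  if ("n" %in% names(nodes)) nodes$n <- as.integer(nodes$n)
  for (cc in grep("^n_", names(nodes), value = TRUE)) {
    nodes[[cc]] <- as.integer(nodes[[cc]])
  }
  data.table::setorder(nodes, code)
  data.table::setorder(edges, code_a, code_b)
  structure(list(nodes = nodes, edges = edges,
                 cohort_tag = "IBD", cohort_sizes = NULL,
                 incidence = data.table::data.table()),
            class = "cooc_graph")
}

#' @rdname as_igraph
#' @export
write_edge_list <- function(graph, path) {
  data.table::fwrite(graph$edges, path)
  invisible(path)
}

utils::globalVariables(c("community", "i.k", "id"))
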