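#' Build the interactive-app network payload
#'
#' Assembles the node-link JSON payload consumed by a vis-network style
#' renderer. Node tooltips carry the ICD code, its full name (when a code
#' label table is supplied), and the absolute number and percentage of
#' patients per disease; edge tooltips carry both codes and the
#' direction-annotated shared-patient counts, where `-->`, `==` and `<--`
#' describe the order of the two first diagnoses. In `cluster` mode nodes
#' are colored by detected community; in `icd-hierarchy` mode by ICD chapter
#' domain. Node positions are deliberately absent — layout belongs to the
#' renderer's physics engine.
#'
#' @param graph a `cooc_graph`.
#' @param partition a [louvain()] partition covering every graph node
#'   (required in `cluster` mode).
#' @param color_map optional named map community id -> color (default
#'   [color_communities()]).
#' @param mode `"cluster"` (default) or `"icd-hierarchy"`.
#' @param code_labels optional named character vector, code -> full name.
#' @param domain_map domain map used in `icd-hierarchy` mode.
#' @return a list with `nodes` and `edges` (the `VisPayload`).
#' @export
vis_payload <- function(graph, partition = NULL, color_map = NULL,
                        mode = c("cluster", "icd-hierarchy"),
                        code_labels = NULL,
                        domain_map = default_domain_map()) {
  mode <- match.arg(mode)
  stopifnot(inherits(graph, "cooc_graph"))
  nodes <- graph$nodes
  if (nrow(nodes) == 0) {
    return(list(nodes = list(), edges = list()))
  }
  if (mode == "cluster") {
    assert_that(!is.null(partition), "cluster mode requires a partition")
    missing <- setdiff(nodes$code, names(partition$membership))
    if (length(missing) > 0) {
      stop("nodes missing from partition: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (is.null(color_map)) color_map <- color_communities(partition)
    colors <- unname(color_map[as.character(partition$membership[nodes$code])])
  } else {
    domains <- map_code_to_domain(nodes$code, domain_map)
    pal <- grDevices::hcl.colors(max(length(unique(domains)), 2), "Dark 3")
    colors <- pal[match(domains, unique(domains))]
  }
  pct_cols <- grep("^pct_", names(nodes), value = TRUE)
  node_list <- lapply(seq_len(nrow(nodes)), function(i) {
    code <- nodes$code[i]
    full <- if (!is.null(code_labels) && code %in% names(code_labels)) {
      code_labels[[code]]
    } else {
      code
    }
    per_disease <- paste(vapply(pct_cols, function(pc) {
      lab <- sub("^pct_", "", pc)
      sprintf("%s: %d (%.3f%%)", lab, nodes[[paste0("n_", lab)]][i],
              nodes[[pc]][i])
    }, character(1)), collapse = "; ")
    list(id = code, label = code, value = nodes$display_size[i],
         color = colors[i],
         title = sprintf("%s | %s | %s", code, full, per_disease))
  })
  edges <- graph$edges
  edge_list <- lapply(seq_len(nrow(edges)), function(i) {
    a <- edges$code_a[i]
    b <- edges$code_b[i]
    list(id = paste0(a, "|", b), from = a, to = b,
         width = edges$display_width[i],
         title = sprintf("%s/%s: %d patients (%s --> %s: %d, %s <-- %s: %d, ==: %d)",
                         a, b, edges$m[i], a, b, edges$a_first[i],
                         a, b, edges$b_first[i], edges$same_day[i]))
  })
  list(nodes = node_list, edges = edge_list)
}

#' @rdname vis_payload
#' @param payload a payload built by [vis_payload()].
#' @export
validate_vis_payload <- function(payload) {
  assert_that(is.list(payload) && all(c("nodes", "edges") %in% names(payload)),
              "payload must have nodes and edges")
  ids <- vapply(payload$nodes, function(n) n$id, character(1))
  assert_that(anyDuplicated(ids) == 0, "node ids must be unique")
  for (n in payload$nodes) {
    assert_that(all(c("id", "label", "value", "color", "title") %in% names(n)),
                "node missing required fields")
  }
  for (e in payload$edges) {
    assert_that(all(c("from", "to", "width", "title") %in% names(e)),
                "edge missing required fields")
    assert_that(e$from %in% ids && e$to %in% ids,
                sprintf("edge endpoint not among nodes: %s-%s", e$from, e$to))
  }
  invisible(TRUE)
}

#' @rdname vis_payload
#' @param path output JSON path.
#' @param ... passed to [vis_payload()].
#' @export
export_vis_json <- function(graph, partition = NULL, path, ...) {
  payload <- vis_payload(graph, partition, ...)
  validate_vis_payload(payload)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

default_pipeline_config <- function() {
  list(
    seed = 1L,
    n_patients = 2000L,
    n_communities = 4L,
    codes_per_community = 25L,
    p_within = 0.3,
    p_between = 0.01,
    case_noise = 0,
    temporal_bias = 0.9,
    cohort_tag = "IBD",
    min_pair_count = 1L,
    top_n_pairs = NULL,
    max_code_length = NULL,
    shuffle_runs = 10L,
    split_trials = 5L,
    null_trials = 200L,
    mode = "cluster"
  )
}

# write an artifact atomically: writer() targets a .partial path which is
# renamed on success, so failed stages leave only .partial files behind
write_stage <- function(path, writer) {
  partial <- paste0(path, ".partial")
  writer(partial)
  file.rename(partial, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> cohort -> frequency table -> co-occurrence graph ->
#' Louvain communities -> robustness experiments -> interactive payload
#' export, writing every artifact plus a manifest into `out_dir`. Any stage
#' failure aborts with a stage-named error; an interrupted artifact is left
#' with a `.partial` suffix. Re-running with the same configuration
#' reproduces identical artifacts (the manifest timestamp aside).
#'
#' @param config a named list overriding the defaults (seed, simulation
#'   parameters, graph filters, experiment sizes), or the path to a
#'   YAML/JSON file holding one.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  cfg <- utils::modifyList(default_pipeline_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("diseasome")),
                   config = cfg, stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  sim <- stage("simulate", {
    sc <- sim_config(n_patients = cfg$n_patients,
                     n_communities = cfg$n_communities,
                     codes_per_community = cfg$codes_per_community,
                     p_within = cfg$p_within, p_between = cfg$p_between,
                     case_noise = cfg$case_noise,
                     temporal_bias = cfg$temporal_bias, seed = cfg$seed)
    out <- generate_cohort(sc)
    write_stage(file.path(out_dir, "records.csv"),
                function(p) write_records(out$records, p))
    write_stage(file.path(out_dir, "ground_truth.json"),
                function(p) write_ground_truth(out$truth, p))
    out
  })
  manifest$stages$simulate <- list(n_records = nrow(sim$records),
                                   n_patients = cfg$n_patients)

  cohort <- stage("cohort", {
    coh <- build_cohort(sim$records, demographics = sim$truth$demographics)
    write_stage(file.path(out_dir, "cohort.csv"),
                function(p) data.table::fwrite(coh, p))
    coh
  })
  manifest$stages$cohort <- as.list(table(cohort$label))

  freq <- stage("frequencies", {
    ft <- frequency_table(sim$records, cohort)
    write_stage(file.path(out_dir, "frequencies.csv"),
                function(p) data.table::fwrite(ft, p))
    ft
  })
  manifest$stages$frequencies <- list(n_rows = nrow(freq))

  graph <- stage("graph", {
    g <- build_graph(sim$records, cohort, cohort_tag = cfg$cohort_tag,
                     min_pair_count = cfg$min_pair_count)
    if (!is.null(cfg$top_n_pairs) || !is.null(cfg$max_code_length)) {
      g <- filter_graph(g, top_n_pairs = cfg$top_n_pairs,
                        max_code_length = cfg$max_code_length)
    }
    write_stage(file.path(out_dir, "graph.graphml"),
                function(p) write_graphml(g, p))
    g
  })
  manifest$stages$graph <- list(nodes = nrow(graph$nodes),
                                edges = nrow(graph$edges))

  part <- stage("communities", {
    pp <- louvain(graph)
    write_stage(file.path(out_dir, "partition.csv"),
                function(p) write_partition(pp, p))
    pp
  })
  manifest$stages$communities <- list(n_communities = part$n_communities,
                                      modularity = part$modularity)

  rob <- stage("robustness", {
    res <- list(
      shuffle = shuffle_experiment(graph, n_runs = cfg$shuffle_runs,
                                   seed = cfg$seed),
      split = split_sample_experiment(sim$records, cohort,
                                      n_trials = cfg$split_trials,
                                      seed = cfg$seed,
                                      cohort_tag = cfg$cohort_tag),
      random_null = random_null(nrow(graph$nodes), part$n_communities,
                                n_trials = cfg$null_trials, seed = cfg$seed)
    )
    write_stage(file.path(out_dir, "robustness.csv"),
                function(p) write_overlap_results(res, p))
    res
  })
  manifest$stages$robustness <- lapply(rob, function(r) {
    list(mean = r$mean_overlap, sem = r$sem, n_trials = r$n_trials)
  })
  manifest$stages$robustness$welch_p_shuffle_vs_null <-
    welch_one_sided(rob$shuffle$per_trial_scores,
                    rob$random_null$per_trial_scores)

  stage("export", {
    write_stage(file.path(out_dir, "network.json"),
                function(p) export_vis_json(graph, part, path = p,
                                            mode = cfg$mode))
  })

  manifest$created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
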