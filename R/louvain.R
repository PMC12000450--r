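#' Weighted Newman-Girvan modularity of a partition
#'
#' `Q = sum_c [ w_in(c)/W - (s_c / 2W)^2 ]` at resolution 1, where `W` is the
#' total edge weight, `w_in(c)` the weight inside community `c` (a self-loop
#' counts once) and `s_c` the summed node strengths (a self-loop contributes
#' twice to its node's strength). Edge weight is the shared-patient count
#' `m`. Self-loops can arise from code aggregation and are handled per this
#' convention.
#'
#' @param graph a `cooc_graph` with at least one edge.
#' @param assignment named vector mapping every node code to a community id.
#' @param resolution resolution parameter (default 1, plain modularity).
#' @return modularity Q in `[-0.5, 1]`.
#' @export
modularity_q <- function(graph, assignment, resolution = 1) {
  stopifnot(inherits(graph, "cooc_graph"))
  assert_that(nrow(graph$edges) > 0, "modularity undefined on an edgeless graph")
  codes <- graph$nodes$code
  assert_that(all(codes %in% names(assignment)),
              "assignment must cover every graph node")
  memb <- assignment[codes]
  ea <- match(graph$edges$code_a, codes)
  eb <- match(graph$edges$code_b, codes)
  w <- as.numeric(graph$edges$m)
  W <- sum(w)
  loop <- ea == eb
  strength <- numeric(length(codes))
  for (k in which(!loop)) {
    strength[ea[k]] <- strength[ea[k]] + w[k]
    strength[eb[k]] <- strength[eb[k]] + w[k]
  }
  for (k in which(loop)) strength[ea[k]] <- strength[ea[k]] + 2 * w[k]
  inside <- w[memb[ea] == memb[eb]]
  w_in <- sum(inside)
  # per-community pieces
  comm <- unique(memb)
  q <- 0
  for (cc in comm) {
    sel <- memb == cc
    wc <- sum(w[memb[ea] == cc & memb[eb] == cc])
    sc <- sum(strength[sel])
    q <- q + wc / W - resolution * (sc / (2 * W))^2
  }
  q
}

# One level of Louvain local moving. Returns dense membership (1..K, ordered
# by first appearance along the visit order) and whether any move was made.
louvain_one_level <- function(N, ea, eb, w, visit, resolution, tol) {
  loop <- ea == eb
  deg <- numeric(N)
  nl <- which(!loop)
  if (length(nl)) {
    deg <- deg + as.numeric(rowsum(c(w[nl], w[nl]),
                                   factor(c(ea[nl], eb[nl]), levels = 1:N)))
  }
  lp <- which(loop)
  if (length(lp)) {
    deg <- deg + 2 * as.numeric(rowsum(w[lp], factor(ea[lp], levels = 1:N)))
  }
  adj_idx <- vector("list", N)
  adj_w <- vector("list", N)
  if (length(nl)) {
    src <- c(ea[nl], eb[nl]); dst <- c(eb[nl], ea[nl]); ww <- c(w[nl], w[nl])
    o <- order(src)
    src <- src[o]; dst <- dst[o]; ww <- ww[o]
    splits <- split(seq_along(src), src)
    for (s in names(splits)) {
      i <- as.integer(s)
      adj_idx[[i]] <- dst[splits[[s]]]
      adj_w[[i]] <- ww[splits[[s]]]
    }
  }
  m2 <- sum(deg)
  comm <- seq_len(N)
  comm_tot <- deg
  moved_any <- FALSE
  repeat {
    moved <- FALSE
    for (i in visit) {
      nb <- adj_idx[[i]]
      if (is.null(nb) || length(nb) == 0) next
      ci <- comm[i]
      cc <- comm[nb]
      links <- rowsum(adj_w[[i]], cc)
      comm_tot[ci] <- comm_tot[ci] - deg[i]
      cand <- as.integer(rownames(links))
      l_cur <- if (ci %in% cand) links[match(ci, cand), 1] else 0
      best_c <- ci
      best_gain <- l_cur - resolution * comm_tot[ci] * deg[i] / m2
      for (j in order(cand)) {
        c2 <- cand[j]
        if (c2 == ci) next
        g <- links[j, 1] - resolution * comm_tot[c2] * deg[i] / m2
        if (g > best_gain + tol) {
          best_gain <- g
          best_c <- c2
        }
      }
      comm[i] <- best_c
      comm_tot[best_c] <- comm_tot[best_c] + deg[i]
      if (best_c != ci) {
        moved <- TRUE
        moved_any <- TRUE
      }
    }
    if (!moved) break
  }
  # dense renumber by first appearance along the visit order
  first_seen <- unique(comm[visit])
  remap <- integer(max(comm))
  remap[first_seen] <- seq_along(first_seen)
  list(comm = remap[comm], moved = moved_any)
}

#' Louvain community detection with explicit edge input order
#'
#' A native implementation of the two-phase Louvain heuristic for weighted
#' modularity maximization: (1) local moving — nodes are visited in the
#' order of their first appearance in the supplied edge sequence and each is
#' greedily moved to the neighbouring community with maximal positive
#' modularity gain until no move improves; (2) communities are aggregated
#' into super-nodes (intra-community weight becomes a self-loop) and the
#' procedure repeats until no further move is made. The edge input order is
#' the single source of run-to-run variability — it is exposed so stability
#' experiments can shuffle it — and the result is deterministic given the
#' graph plus the order.
#'
#' @param graph a `cooc_graph` with at least one edge.
#' @param edge_order optional integer permutation of the edge rows; default
#'   is the graph's canonical alphabetical `(code_a, code_b)` order.
#' @param seed optional seed; when given, the edge order is an independent
#'   uniform shuffle drawn under it (ignored if `edge_order` supplied).
#' @param resolution modularity resolution (default 1).
#' @param tol minimum gain for accepting a move (default 1e-12, guarding
#'   against floating-point ping-pong).
#' @return an object of class `partition`: `membership` (named, dense
#'   0-based ids ordered by descending community size, ties broken by the
#'   lexicographically smallest member code), `modularity`,
#'   `n_communities`, and `edge_order` (the edge keys as consumed).
#' @export
louvain <- function(graph, edge_order = NULL, seed = NULL,
                    resolution = 1, tol = 1e-12) {
  stopifnot(inherits(graph, "cooc_graph"))
  assert_that(nrow(graph$edges) > 0, "louvain requires at least one edge")
  edges <- graph$edges
  ne <- nrow(edges)
  if (is.null(edge_order)) {
    if (!is.null(seed)) {
      edge_order <- local_seed(seed, sample.int(ne))
    } else {
      edge_order <- seq_len(ne)
    }
  }
  assert_that(length(edge_order) == ne &&
                all(sort(edge_order) == seq_len(ne)),
              "edge_order must be a permutation of the edge rows")
  ea_c <- edges$code_a[edge_order]
  eb_c <- edges$code_b[edge_order]
  w <- as.numeric(edges$m[edge_order])

  # node universe in visit order: first appearance in the edge scan,
  # isolated nodes appended alphabetically
  scan <- as.vector(rbind(ea_c, eb_c))
  codes <- unique(c(scan, sort(graph$nodes$code)))
  N <- length(codes)
  ea <- match(ea_c, codes)
  eb <- match(eb_c, codes)

  cur_ea <- ea; cur_eb <- eb; cur_w <- w
  visit <- seq_len(N)
  n_cur <- N
  comp <- seq_len(N)  # composed membership, original node -> current community
  repeat {
    lev <- louvain_one_level(n_cur, cur_ea, cur_eb, cur_w, visit,
                             resolution, tol)
    comp <- lev$comm[comp]
    if (!lev$moved) break
    # aggregate to super-nodes
    na <- lev$comm[cur_ea]; nb <- lev$comm[cur_eb]
    lo <- pmin(na, nb); hi <- pmax(na, nb)
    key <- paste(lo, hi)
    ukey <- unique(key)
    aggw <- as.numeric(rowsum(cur_w, factor(key, levels = ukey)))
    keep <- !duplicated(key)
    cur_ea <- lo[keep]; cur_eb <- hi[keep]; cur_w <- aggw
    n_cur <- max(lev$comm)
    seqn <- unique(as.vector(rbind(cur_ea, cur_eb)))
    visit <- c(seqn, setdiff(seq_len(n_cur), seqn))
  }

  # dense 0-based ids by descending size; ties by smallest member code
  sets <- split(codes, comp)
  sizes <- lengths(sets)
  mins <- vapply(sets, min, character(1))
  ord <- order(-sizes, mins)
  remap <- integer(length(sets))
  remap[as.integer(names(sets))[ord]] <- seq_along(ord) - 1L
  membership <- stats::setNames(remap[comp], codes)
  membership <- membership[sort(names(membership))]

  part <- structure(list(
    membership = membership,
    n_communities = length(sets),
    edge_order = paste(ea_c, eb_c, sep = "|"),
    modularity = NA_real_
  ), class = "partition")
  part$modularity <- modularity_q(graph, part$membership,
                                  resolution = resolution)
  part
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("Partition: %d nodes in %d communities, Q = %.6f\n",
              length(x$membership), x$n_communities, x$modularity))
  invisible(x)
}

#' Assign display colors to communities
#'
#' A fixed palette (blue, yellow, green, red, purple, then an overflow
#' palette) assigned by descending community size; ties are already broken
#' by [louvain()]'s id ordering (lexicographically smallest member code).
#'
#' @param partition a `partition` object.
#' @return named character vector, community id -> color name.
#' @export
color_communities <- function(partition) {
  base <- c("blue", "yellow", "green", "red", "purple")
  extra <- c("orange", "brown", "pink", "cyan", "magenta", "gray")
  k <- partition$n_communities
  pal <- c(base, extra, sprintf("color%d", seq_len(max(0, k - 11))))[seq_len(k)]
  stats::setNames(pal, as.character(seq_len(k) - 1L))
}

#' Write a partition to CSV or JSON
#'
#' @param partition a `partition`.
#' @param path output path; format chosen by extension (`.csv` or `.json`).
#' @export
write_partition <- function(partition, path) {
  tab <- data.table::data.table(code = names(partition$membership),
                                community = unname(partition$membership))
  colors <- color_communities(partition)
  tab[, color := colors[as.character(community)]]
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(modularity = partition$modularity,
                              assignment = tab),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    data.table::fwrite(tab, path)
  }
  invisible(path)
}

utils::globalVariables(c("color"))
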