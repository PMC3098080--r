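#' Build the annotation graph of one namespace
#'
#' Collects the non-obsolete terms of a namespace into a rooted DAG using
#' only the transitive `is_a` and `part_of` parent links. The graph carries
#' per-node direct annotation counts `A` (zero until [attach_counts()] is
#' called), the node count `t`, the total annotation mass and `k`, the
#' number of children of the root, which later serves as the logarithm base
#' of the complexity penalty.
#'
#' @param doc An [ontology_document()].
#' @param namespace One of `doc$namespaces`.
#' @return A list of class `"namespace_graph"` with elements `namespace`,
#'   `nodes`, `edges` (child/parent/relation), `root`, `A`,
#'   `total_annotations`, `t`, `k`, and `parents_of`/`children_of`
#'   adjacency lists.
#' @export
build_namespace_graph <- function(doc, namespace) {
  stopifnot(inherits(doc, "ontology_document"))
  if (!namespace %in% doc$namespaces) {
    stop("namespace '", namespace, "' not present in document", call. = FALSE)
  }
  in_ns <- vapply(doc$terms, function(t)
    identical(t$namespace, namespace) && !t$is_obsolete, logical(1))
  terms <- doc$terms[in_ns]
  nodes <- names(terms)

  child <- character(); parent <- character(); relation <- character()
  for (t in terms) {
    if (nrow(t$parents)) {
      child <- c(child, rep(t$term_id, nrow(t$parents)))
      parent <- c(parent, t$parents$parent)
      relation <- c(relation, t$parents$relation)
    }
  }
  dangling <- setdiff(parent, nodes)
  if (length(dangling)) {
    stop("parent link(s) leave the namespace or hit obsolete/unknown terms: ",
         paste(unique(dangling), collapse = ", "), call. = FALSE)
  }
  edges <- data.frame(child = child, parent = parent, relation = relation,
                      stringsAsFactors = FALSE)
  new_namespace_graph(namespace, nodes, edges)
}

new_namespace_graph <- function(namespace, nodes, edges,
                                A = NULL, root = NULL) {
  parents_of <- split(edges[c("parent", "relation")], factor(edges$child,
                                                            levels = nodes))
  children_of <- split(edges$child, factor(edges$parent, levels = nodes))
  n_parents <- vapply(parents_of, nrow, integer(1))

  roots <- nodes[n_parents == 0L]
  if (length(roots) != 1L) {
    stop("namespace '", namespace, "' must have exactly one parentless ",
         "root, found ", length(roots),
         if (length(roots)) paste0(": ", paste(roots, collapse = ", ")) else "",
         call. = FALSE)
  }
  if (!is.null(root) && !identical(root, roots)) {
    stop("root changed unexpectedly while rebuilding the graph",
         call. = FALSE)
  }
  order <- topological_order(nodes, parents_of, children_of)

  if (is.null(A)) A <- stats::setNames(numeric(length(nodes)), nodes)
  A <- A[nodes]
  A[is.na(A)] <- 0
  names(A) <- nodes
  if (any(A < 0) || any(A != floor(A))) {
    stop("annotation counts must be non-negative integers", call. = FALSE)
  }
  k <- length(children_of[[roots]])
  structure(list(
    namespace = namespace,
    nodes = nodes,
    edges = edges,
    root = roots,
    A = A,
    total_annotations = sum(A),
    t = length(nodes),
    k = if (k == 0L) 1L else k,
    parents_of = parents_of,
    children_of = children_of,
    topo = order
  ), class = "namespace_graph")
}

# Kahn's algorithm; `topo` lists parents before children. Errors on cycles,
# naming one offending strongly-connected remnant.
topological_order <- function(nodes, parents_of, children_of) {
  pending <- vapply(parents_of, nrow, integer(1))
  queue <- nodes[pending == 0L]
  out <- character(0)
  while (length(queue)) {
    n <- queue[1L]; queue <- queue[-1L]
    out <- c(out, n)
    for (ch in children_of[[n]]) {
      pending[ch] <- pending[ch] - 1L
      if (pending[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != length(nodes)) {
    stop("cycle detected involving: ",
         paste(nodes[pending > 0L], collapse = ", "), call. = FALSE)
  }
  out
}

#' @export
print.namespace_graph <- function(x, ...) {
  cat("<namespace_graph> ", x$namespace, ": ", x$t, " nodes, ",
      nrow(x$edges), " edges, root ", x$root, ", k = ", x$k,
      ", total annotations ", x$total_annotations, "\n", sep = "")
  invisible(x)
}

ancestors_of <- function(g, ids) {
  seen <- character(0)
  frontier <- unique(ids)
  while (length(frontier)) {
    parents <- unique(unlist(lapply(g$parents_of[frontier],
                                    function(p) p$parent),
                             use.names = FALSE))
    frontier <- setdiff(parents, seen)
    seen <- union(seen, frontier)
  }
  seen
}

#' Restrict a graph to annotation-used terms and their ancestors
#'
#' The slim is computed on the sub-graph induced by the annotation: the
#' terms actually used plus every term on any path from a used term back to
#' the root. `t`, `k` and the adjacency are recomputed on the sub-graph;
#' existing annotation counts of surviving nodes are retained.
#'
#' @param g A `"namespace_graph"`.
#' @param used_terms Character vector of term ids, all present in `g`.
#' @return A `"namespace_graph"` on the ancestor closure of `used_terms`.
#' @export
extract_annotation_subgraph <- function(g, used_terms) {
  stopifnot(inherits(g, "namespace_graph"))
  used_terms <- unique(as.character(used_terms))
  missing <- setdiff(used_terms, g$nodes)
  if (length(missing)) {
    stop("used term(s) absent from the namespace graph: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  keep <- union(used_terms, ancestors_of(g, used_terms))
  nodes <- g$nodes[g$nodes %in% keep]
  edges <- g$edges[g$edges$child %in% nodes & g$edges$parent %in% nodes, ,
                   drop = FALSE]
  rownames(edges) <- NULL
  new_namespace_graph(g$namespace, nodes, edges, A = g$A[nodes])
}

#' Attach direct annotation counts to a graph
#'
#' @param g A `"namespace_graph"`.
#' @param counts Named integer vector, term id -> direct count, e.g. from
#'   [count_direct_annotations()]. Nodes without a count get 0. A count on a
#'   term outside the graph is an error (it usually means the annotation set
#'   was not synchronized against this ontology version).
#' @return The graph with `A` and `total_annotations` populated.
#' @export
attach_counts <- function(g, counts) {
  stopifnot(inherits(g, "namespace_graph"))
  outside <- setdiff(names(counts), g$nodes)
  if (length(outside)) {
    stop("count(s) on term(s) outside the graph (was the annotation set ",
         "synchronized?): ", paste(outside, collapse = ", "), call. = FALSE)
  }
  A <- stats::setNames(numeric(g$t), g$nodes)
  A[names(counts)] <- as.numeric(counts)
  if (any(A < 0) || any(A != floor(A))) {
    stop("annotation counts must be non-negative integers", call. = FALSE)
  }
  g$A <- A
  g$total_annotations <- sum(A)
  g
}

# Interior-free first-hit search over the (node, pure-is_a-so-far) state
# space. Never materializes paths, so it is linear in the graph even when
# the number of distinct root paths is exponential.
first_hits_impl <- function(g, start, targets, include_self = TRUE) {
  targets <- unique(as.character(targets))
  if (include_self && start %in% targets) {
    return(data.frame(term_id = start, relation = "is_a",
                      stringsAsFactors = FALSE))
  }
  is_target <- stats::setNames(logical(g$t), g$nodes)
  is_target[targets] <- TRUE

  hit_pure <- list()   # target id -> TRUE if some qualifying path is all is_a
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = start, pure = TRUE))
  while (length(stack)) {
    st <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    prow <- g$parents_of[[st$node]]
    if (is.null(prow) || nrow(prow) == 0L) next
    for (i in seq_len(nrow(prow))) {
      p <- prow$parent[i]
      pure <- st$pure && prow$relation[i] == "is_a"
      if (is_target[[p]]) {
        hit_pure[[p]] <- isTRUE(hit_pure[[p]]) || pure
      } else {
        key <- paste0(p, if (pure) "|1" else "|0")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          stack[[length(stack) + 1L]] <- list(node = p, pure = pure)
        }
      }
    }
  }
  ids <- sort(names(hit_pure))
  data.frame(
    term_id = ids,
    relation = unname(ifelse(vapply(hit_pure[ids], isTRUE, logical(1)),
                             "is_a", "part_of")),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Nearest slim terms above an annotation term
#'
#' Returns every target term `s` such that some directed path from `start`
#' to `s` contains no other target in its interior — the "closest slim
#' term(s) on each path to the root" rule. A start term that is itself a
#' target maps to itself. The returned relation is `is_a` when at least one
#' qualifying path to that target uses only `is_a` edges, and `part_of`
#' when every qualifying path crosses at least one `part_of` edge.
#'
#' @param g A `"namespace_graph"`.
#' @param start A node of `g`.
#' @param targets Character vector of target nodes; must contain `g$root`
#'   so that every start has at least one hit.
#' @return Data frame with columns `term_id`, `relation`.
#' @export
first_slim_hits <- function(g, start, targets) {
  stopifnot(inherits(g, "namespace_graph"))
  if (!start %in% g$nodes) {
    stop("start term ", start, " is not in the graph", call. = FALSE)
  }
  missing <- setdiff(targets, g$nodes)
  if (length(missing)) {
    stop("target(s) not in the graph: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!g$root %in% targets) {
    stop("targets must include the namespace root ", g$root, call. = FALSE)
  }
  first_hits_impl(g, start, targets, include_self = TRUE)
}

#' Dump a graph's edges as a TSV edge list
#'
#' Debug helper: writes `child<TAB>parent<TAB>relation` lines.
#'
#' @param g A `"namespace_graph"`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "namespace_graph"))
  utils::write.table(g$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Depth of each node (root = 0, otherwise 1 + max parent depth), used by the
# annotation generator's leaf-skew sampling.
node_depths <- function(g) {
  depth <- stats::setNames(numeric(g$t), g$nodes)
  for (n in g$topo) {
    prow <- g$parents_of[[n]]
    if (!is.null(prow) && nrow(prow)) {
      depth[n] <- 1 + max(depth[prow$parent])
    }
  }
  depth
}
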