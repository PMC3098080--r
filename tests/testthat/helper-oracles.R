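# Independent oracles used across the suite. These deliberately re-derive
# quantities by the most literal method available (full recursion without
# memoization, exhaustive path enumeration, exhaustive draw enumeration) so
# they share no code with the implementation paths they check.

# beta by naive recursion: re-walks the whole subtree for every node, with
# no memoization, mirroring the recursive definition verbatim.
brute_beta <- function(g, variant = "leaf_zero_root_exempt") {
  rec <- function(n) {
    ch <- g$children_of[[n]]
    if (length(ch) == 0L) {
      return(switch(variant,
        leaf_zero_root_exempt = if (identical(n, g$root)) g$A[[n]] else 0,
        literal_leaf_zero = 0,
        subtree_sum = g$A[[n]],
        direct_only = g$A[[n]]))
    }
    if (variant == "direct_only") return(g$A[[n]])
    g$A[[n]] + sum(vapply(ch, rec, numeric(1)))
  }
  vapply(stats::setNames(g$nodes, g$nodes), rec, numeric(1))
}

brute_log_rule <- function(alpha, k) {
  if (k == 1) 1 else if (alpha == 1) 0 else log(alpha) / log(k)
}

# Full I table from first principles, independent of compute_*().
brute_information <- function(g, lambda = 1,
                              variant = "leaf_zero_root_exempt",
                              child_score = "direct_plus_beta") {
  beta <- brute_beta(g, variant)
  total <- sum(g$A)
  p <- lambda * beta / total
  theta <- vapply(stats::setNames(g$nodes, g$nodes), function(n) {
    ch <- g$children_of[[n]]
    if (!length(ch)) return(0)
    s <- if (child_score == "direct_plus_beta") {
      (g$A[ch] + beta[ch]) / total
    } else {
      beta[ch] / total
    }
    lambda * sum(s) * brute_log_rule(length(ch), g$k)
  }, numeric(1))
  list(beta = beta, p = p, theta = theta, info = p - theta)
}

# All directed paths from `start` to the root, as lists of edge sequences;
# exponential, only for tiny graphs.
enumerate_root_paths <- function(g, start) {
  walk <- function(node) {
    prow <- g$parents_of[[node]]
    if (is.null(prow) || nrow(prow) == 0L) return(list(list()))
    out <- list()
    for (i in seq_len(nrow(prow))) {
      for (tail in walk(prow$parent[i])) {
        out[[length(out) + 1L]] <- c(
          list(list(from = node, to = prow$parent[i],
                    relation = prow$relation[i])), tail)
      }
    }
    out
  }
  walk(start)
}

# first_slim_hits oracle: for every full path to the root take the first
# target on it (with the edge types up to that point), then union.
brute_first_hits <- function(g, start, targets) {
  if (start %in% targets) {
    return(data.frame(term_id = start, relation = "is_a",
                      stringsAsFactors = FALSE))
  }
  pure <- list()
  for (path in enumerate_root_paths(g, start)) {
    all_is_a <- TRUE
    for (edge in path) {
      all_is_a <- all_is_a && edge$relation == "is_a"
      if (edge$to %in% targets) {
        pure[[edge$to]] <- isTRUE(pure[[edge$to]]) || all_is_a
        break
      }
    }
  }
  ids <- sort(names(pure))
  data.frame(term_id = ids,
             relation = unname(ifelse(vapply(pure[ids], isTRUE, logical(1)),
                                      "is_a", "part_of")),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws
# from a population whose first K members are successes.
enum_hypergeom_upper <- function(N, K, n, x) {
  if (n == 0L) return(if (x == 0L) 1 else 0)
  draws <- utils::combn(N, n)
  successes <- colSums(draws <= K)
  mean(successes >= x)
}

# Single-namespace graph built directly from an edge table, bypassing the
# OBO layer, for randomized property tests.
graph_from_edges <- function(nodes, edges, A = NULL) {
  terms <- lapply(nodes, function(n) {
    idx <- which(edges$child == n)
    ontology_term(n, n, "testns",
                  parents = data.frame(parent = edges$parent[idx],
                                       relation = edges$relation[idx],
                                       stringsAsFactors = FALSE))
  })
  g <- build_namespace_graph(ontology_document(terms), "testns")
  if (!is.null(A)) g <- attach_counts(g, A)
  g
}

# Random rooted tree / DAG over n nodes (node 1 is the root); parents are
# always earlier nodes, so the result is acyclic by construction.
random_dag_edges <- function(n, p_extra_parent = 0.3, part_of_frac = 0.3) {
  nodes <- sprintf("N%03d", seq_len(n))
  child <- character(); parent <- character(); relation <- character()
  for (i in seq_len(n)[-1]) {
    n_par <- if (i > 2 && stats::runif(1) < p_extra_parent) 2L else 1L
    pars <- sample(seq_len(i - 1L), n_par)
    child <- c(child, rep(nodes[i], n_par))
    parent <- c(parent, nodes[pars])
    relation <- c(relation, ifelse(stats::runif(n_par) < part_of_frac,
                                   "part_of", "is_a"))
  }
  list(nodes = nodes,
       edges = data.frame(child = child, parent = parent,
                          relation = relation, stringsAsFactors = FALSE))
}

random_tree_graph <- function(n, seed) {
  withr::with_seed(seed, {
    ed <- random_dag_edges(n, p_extra_parent = 0, part_of_frac = 0.3)
    A <- stats::setNames(stats::rpois(n, 1.2), ed$nodes)
    if (sum(A) == 0) A[sample(n, 1)] <- 1
    graph_from_edges(ed$nodes, ed$edges, A)
  })
}

random_dag_graph <- function(n, seed) {
  withr::with_seed(seed, {
    ed <- random_dag_edges(n, p_extra_parent = 0.4, part_of_frac = 0.3)
    A <- stats::setNames(stats::rpois(n, 1.2), ed$nodes)
    if (sum(A) == 0) A[sample(n, 1)] <- 1
    graph_from_edges(ed$nodes, ed$edges, A)
  })
}

# Convenience: the worked example with its graph and counts attached.
worked_graph <- function() {
  fx <- worked_example()
  g <- build_namespace_graph(fx$document, "demo")
  counts <- count_direct_annotations(fx$annotations, "demo",
                                     aspect_map = fx$aspect_map)
  fx$graph <- attach_counts(g, counts)
  fx
}
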