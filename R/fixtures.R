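#' Frozen worked example: five-term ontology with five annotated genes
#'
#' A small fixed ontology (one namespace, `demo`) used throughout the
#' documentation and tests: root `R` (GO:0000001) with children `A1`
#' (GO:0000002, is_a) and `A2` (GO:0000003, is_a); `B1` (GO:0000004) is_a
#' `A1` and part_of `A2`; `B2` (GO:0000005) is_a `A1`. Five genes annotate
#' it: g1 and g2 to B1, g3 to B2, g4 to A2, g5 to A1. The expected
#' information-content table at `lambda = 1` under the default variants is
#' included (it satisfies `I = P - Theta` exactly and has been verified
#' against an independent brute-force recursion).
#'
#' The fixture is frozen in code — never regenerated — so documentation
#' examples cannot drift.
#'
#' @return A list with `document` ([ontology_document()]), `annotations`
#'   ([annotation_set()]), `ids` (named shorthand -> accession), and
#'   `expected` (data frame `term_id`/`A`/`beta`/`P`/`theta`/`I`).
#' @export
worked_example <- function() {
  ids <- c(R = "GO:0000001", A1 = "GO:0000002", A2 = "GO:0000003",
           B1 = "GO:0000004", B2 = "GO:0000005")
  ns <- "demo"
  pe <- function(parent, relation) {
    data.frame(parent = parent, relation = relation, stringsAsFactors = FALSE)
  }
  terms <- list(
    ontology_term(ids[["R"]], "root", ns),
    ontology_term(ids[["A1"]], "branch one", ns, pe(ids[["R"]], "is_a")),
    ontology_term(ids[["A2"]], "branch two", ns, pe(ids[["R"]], "is_a")),
    ontology_term(ids[["B1"]], "leaf one", ns,
                  pe(c(ids[["A1"]], ids[["A2"]]), c("is_a", "part_of"))),
    ontology_term(ids[["B2"]], "leaf two", ns, pe(ids[["A1"]], "is_a"))
  )
  doc <- ontology_document(terms)

  genes <- c("g1", "g2", "g3", "g4", "g5")
  terms_used <- ids[c("B1", "B1", "B2", "A2", "A1")]
  rec <- data.frame(
    db = "DEMO", object_id = genes, symbol = genes, qualifier = "",
    term_id = unname(terms_used), reference = "REF:0000001",
    evidence = "IEA", with_from = "", aspect = "P",
    object_name = "", synonym = "", object_type = "protein",
    taxon = "taxon:0", date = "20100101", assigned_by = "demo",
    stringsAsFactors = FALSE
  )
  ann <- annotation_set(rec, comments = "!gaf-version: 2.0",
                        source_label = "worked example")

  expected <- data.frame(
    term_id = unname(ids[c("B1", "B2", "A1", "A2", "R")]),
    label = c("B1", "B2", "A1", "A2", "R"),
    A = c(2, 1, 1, 1, 0),
    beta = c(0, 0, 1, 1, 2),
    P = c(0, 0, 0.2, 0.2, 0.4),
    theta = c(0, 0, 0.6, 0, 0.8),
    I = c(0, 0, -0.4, 0.2, -0.4),
    stringsAsFactors = FALSE
  )
  list(document = doc, annotations = ann, ids = ids, expected = expected,
       aspect_map = c(P = "demo"))
}

#' Fixture generator parameters
#'
#' @param n_terms Terms per namespace (including the root).
#' @param max_children Soft cap on children per term; parents are sampled
#'   preferentially among earlier terms still under the cap.
#' @param part_of_fraction Probability that a generated parent link is
#'   `part_of` rather than `is_a`.
#' @param n_genes Number of synthetic gene products.
#' @param annotations_per_gene Annotations drawn per gene.
#' @param depth_skew Leafward skew of term usage: sampling weight is
#'   `exp(depth_skew * depth)`, so 0 gives uniform usage and larger values
#'   concentrate annotation on specific/deep terms, as in real GO corpora.
#' @param seed Integer seed; generators are pure functions of
#'   `(params, seed)`.
#' @return A list of class `"fixture_params"`.
#' @export
fixture_params <- function(n_terms = 60, max_children = 6,
                           part_of_fraction = 0.2, n_genes = 40,
                           annotations_per_gene = 3, depth_skew = 0.8,
                           seed = 1L) {
  stopifnot(n_terms >= 1, max_children >= 1,
            part_of_fraction >= 0, part_of_fraction <= 1,
            n_genes >= 0, annotations_per_gene >= 0)
  structure(list(n_terms = as.integer(n_terms),
                 max_children = as.integer(max_children),
                 part_of_fraction = part_of_fraction,
                 n_genes = as.integer(n_genes),
                 annotations_per_gene = as.integer(annotations_per_gene),
                 depth_skew = depth_skew,
                 seed = as.integer(seed)), class = "fixture_params")
}

#' Generate a random multi-namespace DAG ontology
#'
#' Each namespace is a rooted DAG of `n_terms` terms: every non-root term
#' receives one or two parents sampled among earlier-generated terms
#' (guaranteeing acyclicity by construction), each link typed `part_of`
#' with probability `part_of_fraction` and `is_a` otherwise. Deterministic
#' under a fixed seed.
#'
#' @param params A [fixture_params()].
#' @param namespaces Character vector of namespace labels.
#' @return An [ontology_document()].
#' @export
generate_ontology <- function(params = fixture_params(),
                              namespaces = "biological_process") {
  stopifnot(inherits(params, "fixture_params"))
  withr::with_seed(params$seed, {
    terms <- list()
    counter <- 0L
    for (ns in namespaces) {
      ns_ids <- sprintf("GO:%07d", counter + seq_len(params$n_terms))
      counter <- counter + params$n_terms
      child_load <- stats::setNames(integer(params$n_terms), ns_ids)
      terms[[length(terms) + 1L]] <-
        ontology_term(ns_ids[1], paste0(ns, " root"), ns)
      for (i in seq_len(params$n_terms - 1L) + 1L) {
        earlier <- ns_ids[seq_len(i - 1L)]
        open <- earlier[child_load[earlier] < params$max_children]
        pool <- if (length(open)) open else earlier
        n_par <- if (length(pool) >= 2L && stats::runif(1) < 0.3) 2L else 1L
        parents <- sample(pool, n_par)
        child_load[parents] <- child_load[parents] + 1L
        rel <- ifelse(stats::runif(n_par) < params$part_of_fraction,
                      "part_of", "is_a")
        terms[[length(terms) + 1L]] <- ontology_term(
          ns_ids[i], paste0("term ", ns_ids[i]), ns,
          parents = data.frame(parent = parents, relation = rel,
                               stringsAsFactors = FALSE))
      }
    }
    ontology_document(terms)
  })
}

#' Generate a synthetic GAF annotation set over an ontology
#'
#' Each of `n_genes` synthetic gene products is annotated to
#' `annotations_per_gene` terms sampled (without replacement per gene,
#' where possible) with weight `exp(depth_skew * depth)`, emulating the
#' leafward concentration of real annotation. Terms are drawn from all
#' namespaces pooled; aspect letters follow the supplied map.
#'
#' @param doc An [ontology_document()].
#' @param params A [fixture_params()].
#' @param aspect_map Named vector, aspect letter -> namespace label; must
#'   cover every namespace of `doc`.
#' @return An [annotation_set()].
#' @export
generate_annotations <- function(doc, params = fixture_params(),
                                 aspect_map = default_aspect_map()) {
  stopifnot(inherits(doc, "ontology_document"),
            inherits(params, "fixture_params"))
  rev_map <- stats::setNames(names(aspect_map), aspect_map)
  uncovered <- setdiff(doc$namespaces, names(rev_map))
  if (length(uncovered)) {
    stop("aspect_map does not cover namespace(s): ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  term_ids <- character(); weights <- numeric(); aspects <- character()
  for (ns in doc$namespaces) {
    g <- build_namespace_graph(doc, ns)
    d <- node_depths(g)
    term_ids <- c(term_ids, g$nodes)
    weights <- c(weights, exp(params$depth_skew * d[g$nodes]))
    aspects <- c(aspects, rep(rev_map[[ns]], g$t))
  }
  names(aspects) <- term_ids

  withr::with_seed(params$seed, {
    rows <- vector("list", params$n_genes)
    for (gi in seq_len(params$n_genes)) {
      gene <- sprintf("g%04d", gi)
      k <- min(params$annotations_per_gene, length(term_ids))
      picked <- if (k > 0) {
        sample(term_ids, k, prob = weights)
      } else character()
      if (!length(picked)) next
      rows[[gi]] <- data.frame(
        db = "SYNTH", object_id = gene, symbol = gene, qualifier = "",
        term_id = picked, reference = "REF:0000001", evidence = "IEA",
        with_from = "", aspect = unname(aspects[picked]),
        object_name = "", synonym = "", object_type = "protein",
        taxon = "taxon:0", date = "20100101", assigned_by = "ontoslim",
        stringsAsFactors = FALSE)
    }
    rec <- do.call(rbind, rows)
    if (is.null(rec)) {
      rec <- data.frame(matrix(character(), nrow = 0, ncol = 15,
                               dimnames = list(NULL, GAF_COLUMNS[1:15])),
                        stringsAsFactors = FALSE)
    }
    annotation_set(rec, comments = "!gaf-version: 2.0",
                   source_label = sprintf("synthetic seed=%d", params$seed))
  })
}

#' Plant obsolescence events between two ontology versions
#'
#' Produces a new ontology version that differs from `doc` by exactly the
#' requested number of planted inconsistency events, each applied to a
#' distinct leaf term: class 1 demotes the leaf's id to an `alt_id` of its
#' parent; class 2 obsoletes it with `replaced_by` its parent; class 3
#' obsoletes it with a single `consider` (the parent); class 4 with two
#' `consider` entries; class 5 obsoletes it bare. The returned `planted`
#' map is the ground-truth key for validating [synchronize()].
#'
#' @param doc An [ontology_document()] (the old version).
#' @param counts Named vector/list, class (`"1"`..`"5"`) -> number of
#'   events to plant.
#' @param seed Integer seed for choosing the affected leaves.
#' @return A list `old_doc`, `new_doc`, `planted` (named integer vector,
#'   term id -> class).
#' @export
generate_obsolescence <- function(doc, counts, seed = 1L) {
  stopifnot(inherits(doc, "ontology_document"))
  want <- stats::setNames(integer(5), as.character(1:5))
  for (k in names(counts)) want[k] <- as.integer(counts[[k]])
  total <- sum(want)

  has_children <- unique(unlist(lapply(doc$terms, function(t)
    t$parents$parent), use.names = FALSE))
  eligible <- names(doc$terms)[vapply(doc$terms, function(t)
    !t$is_obsolete && nrow(t$parents) > 0L, logical(1))]
  eligible <- setdiff(eligible, has_children)
  if (length(eligible) < total) {
    stop("need ", total, " eligible leaf terms but only ",
         length(eligible), " available", call. = FALSE)
  }

  withr::with_seed(seed, {
    chosen <- sample(eligible, total)
  })
  classes <- rep(1:5, times = want)
  planted <- stats::setNames(classes, chosen)

  new_terms <- doc$terms
  safe_targets <- setdiff(names(doc$terms), chosen)
  for (i in seq_along(chosen)) {
    id <- chosen[i]
    old <- new_terms[[id]]
    parent <- intersect(old$parents$parent, safe_targets)[1]
    if (is.na(parent)) parent <- safe_targets[1]
    second <- setdiff(safe_targets, parent)[1]
    new_terms[[id]] <- switch(as.character(classes[i]),
      "1" = NULL,
      "2" = ontology_term(id, old$name, old$namespace,
                          is_obsolete = TRUE, replaced_by = parent),
      "3" = ontology_term(id, old$name, old$namespace,
                          is_obsolete = TRUE, consider = parent),
      "4" = ontology_term(id, old$name, old$namespace,
                          is_obsolete = TRUE,
                          consider = c(parent, second)),
      "5" = ontology_term(id, old$name, old$namespace, is_obsolete = TRUE)
    )
    if (classes[i] == 1L) {
      host <- new_terms[[parent]]
      host$alt_ids <- sort(unique(c(host$alt_ids, id)))
      new_terms[[parent]] <- host
    }
  }
  new_terms <- new_terms[!vapply(new_terms, is.null, logical(1))]
  new_doc <- ontology_document(unname(new_terms), header = doc$header,
                               subsetdefs = doc$subsetdefs,
                               opaque_stanzas = doc$opaque_stanzas)
  list(old_doc = doc, new_doc = new_doc, planted = planted)
}
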