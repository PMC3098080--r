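test_that("threshold selection uses strict inequality on I", {
  fx <- worked_graph()
  res <- compute_information(fx$graph, ic_config(lambda_scale = 1))
  expect_equal(select_slim_terms(res, 0.1), unname(fx$ids[["A2"]]))
  expect_equal(select_slim_terms(res, max(res$info)), character(0))
  expect_setequal(select_slim_terms(res, min(res$info) - 1), fx$graph$nodes)
  # a term sitting exactly at tau is excluded
  expect_false(fx$ids[["A2"]] %in% select_slim_terms(res, 0.2))
})

test_that("close_paths adds exactly the ancestors needed for completeness", {
  fx <- worked_graph()
  ids <- fx$ids
  frag <- close_paths(fx$graph, ids[["A2"]])
  expect_equal(frag$closure, unname(ids[["R"]]))
  expect_setequal(frag$all_terms, unname(ids[c("A2", "R")]))
  expect_equal(close_paths(fx$graph, fx$graph$root)$closure, character(0))
  expect_equal(close_paths(fx$graph, character(0))$all_terms, character(0))
})

test_that("build_slim composes the per-namespace pipeline and labels the OBO", {
  fx <- worked_example()
  slim <- build_slim(fx$document, fx$annotations,
                     config = ic_config(lambda_scale = 1), tau = 0.1,
                     name = "goslim_demo", aspect_map = fx$aspect_map)
  frag <- slim$namespaces$demo
  expect_setequal(frag$all_terms, unname(fx$ids[c("A2", "R")]))
  txt <- write_obo(slim$document)
  expect_length(grep("^subsetdef: goslim_demo ", txt), 1L)
  expect_length(grep("^subset: goslim_demo$", txt), 2L)

  # below-minimum threshold keeps the whole used sub-graph
  all_slim <- build_slim(fx$document, fx$annotations,
                         config = ic_config(lambda_scale = 1), tau = -2,
                         aspect_map = fx$aspect_map)
  expect_setequal(all_slim$namespaces$demo$all_terms,
                  frag$graph$nodes)
})

test_that("a namespace without annotations is skipped with a warning", {
  fx <- worked_example()
  extra <- ontology_document(c(unname(fx$document$terms), list(
    ontology_term("GO:0000010", "lonely root", "empty_ns"))))
  expect_warning(
    slim <- build_slim(extra, fx$annotations,
                       config = ic_config(lambda_scale = 1), tau = 0.1,
                       aspect_map = c(fx$aspect_map, X = "empty_ns")),
    "no annotations")
  expect_named(slim$namespaces, "demo")
})

test_that("slims shrink monotonically as the threshold rises", {
  params <- fixture_params(n_terms = 40, n_genes = 30,
                           annotations_per_gene = 3, seed = 11)
  doc <- generate_ontology(params)
  ann <- generate_annotations(doc, params)
  taus <- seq(0, 1, by = 0.1)
  slims <- lapply(taus, function(tau)
    build_slim(doc, ann, ic_config(lambda_scale = 1), tau = tau))
  ns <- "biological_process"
  sizes <- vapply(slims, function(s)
    length(s$namespaces[[ns]]$all_terms), integer(1))
  expect_true(all(diff(sizes) <= 0))
  for (i in seq_along(taus)[-1]) {
    hi <- slims[[i]]$namespaces[[ns]]
    lo <- slims[[i - 1]]$namespaces[[ns]]
    expect_true(all(hi$selected %in% lo$selected))
    expect_true(all(hi$all_terms %in% lo$all_terms))
  }
})

test_that("the slim sub-graph is well-formed: acyclic and root-connected", {
  params <- fixture_params(n_terms = 40, n_genes = 30, seed = 5)
  doc <- generate_ontology(params)
  ann <- generate_annotations(doc, params)
  slim <- build_slim(doc, ann, ic_config(lambda_scale = 1), tau = 0.05,
                     name = "s")
  frag <- slim$namespaces$biological_process
  g <- frag$graph
  for (term in frag$all_terms) {
    hits <- first_hits <- ontoslim::first_slim_hits(g, term, frag$all_terms)
    expect_gte(nrow(hits), 1L)
  }
  # extractable as a standalone OBO that rebuilds into a rooted DAG
  slim_doc <- extract_slim_document(slim$document, "s")
  g2 <- build_namespace_graph(slim_doc, "biological_process")
  expect_setequal(g2$nodes, frag$all_terms)
})

test_that("map_annotations reproduces the worked-example mapping", {
  fx <- worked_example()
  ids <- fx$ids
  slim <- build_slim(fx$document, fx$annotations,
                     config = ic_config(lambda_scale = 1), tau = 0.1,
                     aspect_map = fx$aspect_map)
  frag <- slim$namespaces$demo
  m <- map_annotations(frag$graph, frag, frag$used_terms)
  expect_equal(m$map[[ids[["B1"]]]],
               data.frame(term_id = unname(ids[c("R", "A2")]),
                          relation = c("is_a", "part_of"),
                          stringsAsFactors = FALSE))
  expect_equal(m$map[[ids[["B2"]]]]$term_id, unname(ids[["R"]]))
  expect_equal(m$map[[ids[["A2"]]]],
               data.frame(term_id = unname(ids[["A2"]]), relation = "is_a",
                          stringsAsFactors = FALSE))
  expect_equal(m$map[[ids[["A1"]]]]$term_id, unname(ids[["R"]]))
})

test_that("a root-only slim maps every term to the root", {
  g <- random_dag_graph(15, 9)
  m <- map_annotations(g, g$root, g$nodes)
  for (a in g$nodes) {
    expect_equal(m$map[[a]]$term_id,
                 if (identical(a, g$root)) a else g$root)
  }
})

test_that("mapping targets are never proper descendants of the source", {
  for (seed in 1:5) {
    g <- random_dag_graph(20, seed)
    withr::with_seed(seed + 50, {
      targets <- union(g$root, sample(g$nodes, 5))
    })
    m <- map_annotations(g, targets, g$nodes)
    for (a in g$nodes) {
      anc <- union(a, ontoslim:::ancestors_of(g, a))
      expect_true(all(m$map[[a]]$term_id %in% anc))
    }
  }
})

test_that("remap expands records per target and collapses duplicates", {
  fx <- worked_example()
  ids <- fx$ids
  slim <- build_slim(fx$document, fx$annotations,
                     config = ic_config(lambda_scale = 1), tau = 0.1,
                     aspect_map = fx$aspect_map)
  frag <- slim$namespaces$demo
  m <- map_annotations(frag$graph, frag, frag$used_terms)
  out <- remap_annotation_set(fx$annotations, m)

  g1 <- out$records[out$records$object_id == "g1", "term_id"]
  expect_setequal(g1, unname(ids[c("A2", "R")]))
  # two genes on B1 -> 2 x 2 remapped records
  b1genes <- out$records[out$records$term_id %in% ids[c("A2", "R")] &
                           out$records$object_id %in% c("g1", "g2"), ]
  expect_equal(nrow(b1genes), 4L)
  # a record already on a slim term keeps it
  expect_true(ids[["A2"]] %in%
                out$records[out$records$object_id == "g4", "term_id"])
  # completeness: every gene product retains at least one annotation
  expect_setequal(unique(out$records$object_id),
                  unique(fx$annotations$records$object_id))
  # all remapped terms are slim terms
  expect_true(all(out$records$term_id %in% frag$all_terms))

  expect_error(remap_annotation_set(fx$annotations,
                                    slim_map_table(list())),
               "missing from the slim mapping")
})

test_that("remapping preserves every gene on random fixtures", {
  params <- fixture_params(n_terms = 50, n_genes = 25, seed = 23)
  doc <- generate_ontology(params)
  ann <- generate_annotations(doc, params)
  slim <- build_slim(doc, ann, ic_config(lambda_scale = 1), tau = 0.1)
  frag <- slim$namespaces$biological_process
  m <- map_annotations(frag$graph, frag, frag$used_terms)
  out <- remap_annotation_set(ann, m)
  expect_setequal(unique(out$records$object_id),
                  unique(ann$records$object_id))
  expect_true(all(out$records$term_id %in% frag$all_terms))
})

test_that("compare_slims reports sizes, intersection and percentage", {
  expect_equal(compare_slims(c("a", "b"), c("a", "b"))$overlap_pct, 100)
  expect_equal(compare_slims(c("a", "b"), c("c"))$overlap_pct, 0)
  r <- compare_slims(c("a", "b", "c", "d"), c("a", "b", "x"))
  expect_equal(r$size_a, 4L)
  expect_equal(r$size_b, 3L)
  expect_equal(r$intersection, 2L)
  expect_equal(r$overlap_pct, 50)
})
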