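test_that("parse_obo captures the core term grammar", {
  doc <- parse_obo(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root", "namespace: ns", "",
    "[Term]", "id: GO:0000002", "name: child", "namespace: ns",
    "is_a: GO:0000001 ! root"))
  expect_length(doc$terms, 2L)
  expect_equal(doc$terms[["GO:0000002"]]$parents,
               data.frame(parent = "GO:0000001", relation = "is_a",
                          stringsAsFactors = FALSE))
  expect_equal(doc$namespaces, "ns")
})

test_that("obsolete stanzas carry replaced_by and no parents", {
  doc <- parse_obo(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000002", "name: current", "namespace: ns", "",
    "[Term]", "id: GO:0000001", "name: gone", "namespace: ns",
    "is_obsolete: true", "replaced_by: GO:0000002"))
  t <- doc$terms[["GO:0000001"]]
  expect_true(t$is_obsolete)
  expect_equal(t$replaced_by, "GO:0000002")
  expect_equal(nrow(t$parents), 0L)
})

test_that("malformed stanzas raise parse errors naming the position", {
  expect_error(parse_obo(c("format-version: 1.2", "",
                           "[Term]", "name: no id here")),
               "no id tag")
  expect_error(parse_obo(c("format-version: 1.2", "",
                           "[Term]", "id: GO:0000001", "namespace: ns", "",
                           "[Term]", "id: GO:0000001", "namespace: ns")),
               "duplicate")
})

test_that("unknown tags and non-Term stanzas survive a round trip", {
  lines <- c("format-version: 1.2", "",
             "[Term]", "id: GO:0000001", "name: root", "namespace: ns",
             "created_by: someone", "comment: opaque line kept verbatim", "",
             "[Typedef]", "id: part_of", "name: part of")
  doc <- parse_obo(lines)
  expect_equal(doc$terms[["GO:0000001"]]$opaque,
               c("created_by: someone", "comment: opaque line kept verbatim"))
  expect_length(doc$opaque_stanzas, 1L)
  expect_equal(parse_obo(write_obo(doc)), doc)
})

test_that("regulates-style relationships are preserved but not parents", {
  doc <- parse_obo(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: a", "namespace: ns", "",
    "[Term]", "id: GO:0000002", "name: b", "namespace: ns",
    "is_a: GO:0000001",
    "relationship: regulates GO:0000001"))
  t <- doc$terms[["GO:0000002"]]
  expect_equal(t$other_relationships$relation, "regulates")
  expect_equal(t$parents$relation, "is_a")
  expect_equal(parse_obo(write_obo(doc)), doc)
})

test_that("write/parse round trip is field-identical and byte-idempotent", {
  fx <- worked_example()
  txt <- write_obo(fx$document)
  doc2 <- parse_obo(txt)
  expect_equal(doc2, fx$document)
  expect_identical(write_obo(doc2), txt)
})

test_that("write_obo refuses unresolved parent references before output", {
  t1 <- ontology_term("GO:0000001", "root", "ns")
  t2 <- ontology_term("GO:0000002", "child", "ns",
                      parents = data.frame(parent = "GO:9999999",
                                           relation = "is_a",
                                           stringsAsFactors = FALSE))
  doc <- ontology_document(list(t1, t2))
  expect_error(write_obo(doc), "unresolved parent")
})

test_that("apply_subset_labels defines the subset and labels exactly the set", {
  fx <- worked_example()
  ids <- fx$ids
  doc <- apply_subset_labels(fx$document, "goslim_demo", "demo slim",
                             c(ids[["R"]], ids[["A2"]]))
  expect_equal(unname(doc$subsetdefs["goslim_demo"]), "demo slim")
  labelled <- names(doc$terms)[vapply(doc$terms, function(t)
    "goslim_demo" %in% t$subsets, logical(1))]
  expect_setequal(labelled, c(ids[["R"]], ids[["A2"]]))

  txt <- write_obo(doc)
  expect_length(grep("^subsetdef:", txt), 1L)
  expect_length(grep("^subset: goslim_demo$", txt), 2L)

  # idempotent, and structure untouched
  doc2 <- apply_subset_labels(doc, "goslim_demo", "demo slim",
                              c(ids[["R"]], ids[["A2"]]))
  expect_equal(doc2, doc)
  expect_length(doc$terms, length(fx$document$terms))
  expect_equal(lapply(doc$terms, `[[`, "parents"),
               lapply(fx$document$terms, `[[`, "parents"))

  # relabelling with a different set moves the label
  doc3 <- apply_subset_labels(doc, "goslim_demo", "demo slim", ids[["A1"]])
  labelled3 <- names(doc3$terms)[vapply(doc3$terms, function(t)
    "goslim_demo" %in% t$subsets, logical(1))]
  expect_equal(labelled3, unname(ids[["A1"]]))

  empty <- apply_subset_labels(fx$document, "goslim_demo", "d", character())
  expect_true("goslim_demo" %in% names(empty$subsetdefs))
  expect_false(any(vapply(empty$terms, function(t)
    "goslim_demo" %in% t$subsets, logical(1))))

  expect_error(apply_subset_labels(fx$document, "s", "d", "GO:9999999"),
               "GO:9999999")
})

test_that("extract_slim_document rewires parents to nearest labelled ancestors", {
  fx <- worked_example()
  ids <- fx$ids
  doc <- apply_subset_labels(fx$document, "goslim_demo", "d",
                             c(ids[["R"]], ids[["A2"]]))
  slim <- extract_slim_document(doc, "goslim_demo")
  expect_setequal(names(slim$terms), c(ids[["R"]], ids[["A2"]]))
  expect_equal(slim$terms[[ids[["A2"]]]]$parents,
               data.frame(parent = unname(ids[["R"]]), relation = "is_a",
                          stringsAsFactors = FALSE))
  expect_equal(nrow(slim$terms[[ids[["R"]]]]$parents), 0L)
})

test_that("a pure is_a route wins the rewired relation type", {
  # B1 reaches R both via A1 (is_a only) and via A2 (part_of edge):
  # the surviving link must be is_a.
  fx <- worked_example()
  ids <- fx$ids
  doc <- apply_subset_labels(fx$document, "s", "d",
                             c(ids[["R"]], ids[["B1"]]))
  slim <- extract_slim_document(doc, "s")
  expect_equal(slim$terms[[ids[["B1"]]]]$parents,
               data.frame(parent = unname(ids[["R"]]), relation = "is_a",
                          stringsAsFactors = FALSE))
})

test_that("labelling every term keeps the full edge structure", {
  fx <- worked_example()
  doc <- apply_subset_labels(fx$document, "s", "d", names(fx$document$terms))
  slim <- extract_slim_document(doc, "s")
  expect_setequal(names(slim$terms), names(fx$document$terms))
  expect_equal(lapply(slim$terms, `[[`, "parents"),
               lapply(fx$document$terms, `[[`, "parents"))
  # result is acyclic and root-connected
  g <- build_namespace_graph(slim, "demo")
  expect_equal(g$t, 5L)
})

test_that("an unclosed subset (missing root) is rejected", {
  fx <- worked_example()
  doc <- apply_subset_labels(fx$document, "s", "d", fx$ids[["A2"]])
  expect_error(extract_slim_document(doc, "s"), "not path-closed")
  expect_error(extract_slim_document(fx$document, "nope"), "not defined")
})
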