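#' Construct an ontology term
#'
#' Low-level constructor for a single ontology term as held inside an
#' [ontology_document()]. Most users obtain terms from [parse_obo()] or the
#' fixture generators rather than building them by hand.
#'
#' Only `is_a` and `part_of` links populate `parents`; any other relationship
#' (e.g. `regulates`) is kept verbatim in `other_relationships` and is never
#' traversed by the graph machinery, because only `is_a`/`part_of` are
#' transitive and therefore safe to propagate annotations along.
#'
#' @param term_id Primary accession string (e.g. `"GO:0008150"`).
#' @param name Human-readable term name.
#' @param namespace Namespace label the term belongs to.
#' @param parents Data frame with columns `parent`, `relation`
#'   (`"is_a"` or `"part_of"`); empty for roots and obsolete terms.
#' @param alt_ids Character vector of alternative (merged) accessions.
#' @param is_obsolete Logical flag; obsolete terms must have no parents.
#' @param replaced_by Character vector of authoritative successor accessions
#'   (only meaningful when obsolete).
#' @param consider Character vector of suggested successor accessions
#'   (only meaningful when obsolete).
#' @param subsets Character vector of subset labels the term is a member of.
#' @param other_relationships Data frame with columns `relation`, `target`
#'   for non-transitive relationship lines, preserved but never traversed.
#' @param opaque Character vector of unrecognised stanza lines kept verbatim
#'   so unknown OBO tags survive a parse/write round trip.
#' @return A list of class `"ontology_term"`.
#' @export
ontology_term <- function(term_id, name = "", namespace = NA_character_,
                          parents = empty_parents(), alt_ids = character(),
                          is_obsolete = FALSE, replaced_by = character(),
                          consider = character(), subsets = character(),
                          other_relationships = empty_other_rels(),
                          opaque = character()) {
  stopifnot(is.character(term_id), length(term_id) == 1L, nzchar(term_id))
  if (is_obsolete && nrow(parents) > 0L) {
    stop("obsolete term '", term_id, "' must not have parents", call. = FALSE)
  }
  if (!is_obsolete && (length(replaced_by) || length(consider))) {
    stop("term '", term_id,
         "' carries replaced_by/consider but is not obsolete", call. = FALSE)
  }
  parents <- canonical_parents(parents)
  structure(list(
    term_id = term_id,
    name = name,
    namespace = namespace,
    parents = parents,
    alt_ids = sort(unique(as.character(alt_ids))),
    is_obsolete = isTRUE(is_obsolete),
    replaced_by = as.character(replaced_by),
    consider = as.character(consider),
    subsets = sort(unique(as.character(subsets))),
    other_relationships = other_relationships,
    opaque = as.character(opaque)
  ), class = "ontology_term")
}

empty_parents <- function() {
  data.frame(parent = character(), relation = character(),
             stringsAsFactors = FALSE)
}

empty_other_rels <- function() {
  data.frame(relation = character(), target = character(),
             stringsAsFactors = FALSE)
}

canonical_parents <- function(parents) {
  stopifnot(is.data.frame(parents),
            all(c("parent", "relation") %in% names(parents)))
  bad <- setdiff(unique(parents$relation), c("is_a", "part_of"))
  if (length(bad)) {
    stop("parents may only use is_a/part_of, got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  parents <- unique(parents[c("parent", "relation")])
  parents <- parents[order(parents$relation, parents$parent), , drop = FALSE]
  rownames(parents) <- NULL
  parents
}

#' Construct an ontology document
#'
#' @param terms List of [ontology_term()] objects (any order; stored sorted
#'   by id).
#' @param header Data frame of header tag/value pairs (order preserved;
#'   `subsetdef` lines are held separately in `subsetdefs`).
#' @param subsetdefs Named character vector mapping subset name to its
#'   description.
#' @return A list of class `"ontology_document"` with elements `header`,
#'   `subsetdefs`, `terms` (named by id, sorted), `namespaces` and
#'   `opaque_stanzas`.
#' @export
ontology_document <- function(terms = list(),
                              header = default_obo_header(),
                              subsetdefs = character(),
                              opaque_stanzas = character()) {
  ids <- vapply(terms, function(t) t$term_id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate primary term id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  names(terms) <- ids
  terms <- terms[order(ids)]
  ns <- unique(vapply(terms, function(t) t$namespace, character(1)))
  subsetdefs <- unlist(subsetdefs)
  if (is.null(subsetdefs) || !length(subsetdefs)) {
    subsetdefs <- stats::setNames(character(), character())
  }
  subsetdefs <- subsetdefs[order(names(subsetdefs))]
  doc <- structure(list(
    header = header,
    subsetdefs = subsetdefs,
    terms = terms,
    namespaces = sort(ns[!is.na(ns)]),
    opaque_stanzas = as.character(opaque_stanzas)
  ), class = "ontology_document")
  validate_ontology_document(doc)
  doc
}

default_obo_header <- function() {
  data.frame(tag = "format-version", value = "1.2", stringsAsFactors = FALSE)
}

validate_ontology_document <- function(doc) {
  ids <- names(doc$terms)
  alt <- unlist(lapply(doc$terms, function(t) t$alt_ids), use.names = FALSE)
  clash <- intersect(alt, ids)
  if (length(clash)) {
    stop("alt_id collides with a primary id: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  used_subsets <- unique(unlist(lapply(doc$terms, function(t) t$subsets),
                                use.names = FALSE))
  undef <- setdiff(used_subsets, names(doc$subsetdefs))
  if (length(undef)) {
    stop("subset label(s) used without a subsetdef: ",
         paste(undef, collapse = ", "), call. = FALSE)
  }
  invisible(doc)
}

#' @export
print.ontology_document <- function(x, ...) {
  cat("<ontology_document> ", length(x$terms), " terms, ",
      length(x$namespaces), " namespace(s): ",
      paste(x$namespaces, collapse = ", "), "\n", sep = "")
  if (length(x$subsetdefs)) {
    cat("  subsets: ", paste(names(x$subsetdefs), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

strip_obo_comment <- function(value) {
  sub("\\s*!.*$", "", value)
}

#' Parse an OBO 1.2 flat file
#'
#' Reads an OBO ontology into an [ontology_document()]. The tags `id`,
#' `name`, `namespace`, `alt_id`, `is_a`, `relationship`, `is_obsolete`,
#' `replaced_by`, `consider` and `subset` are interpreted; every other tag
#' line inside a `[Term]` stanza, and every non-`[Term]` stanza (e.g.
#' `[Typedef]`), is preserved verbatim so that unknown constructs survive a
#' round trip. `relationship: part_of` lines become typed parent links; all
#' other relationship types are retained but never traversed.
#'
#' @param x Path to an OBO file, or a character vector of lines.
#' @return An [ontology_document()].
#' @examples
#' lines <- c("format-version: 1.2", "",
#'            "[Term]", "id: GO:0000001", "name: root",
#'            "namespace: demo", "",
#'            "[Term]", "id: GO:0000002", "name: child",
#'            "namespace: demo", "is_a: GO:0000001 ! root")
#' doc <- parse_obo(lines)
#' length(doc$terms)
#' @export
parse_obo <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  n <- length(lines)
  stanza_starts <- grep("^\\[", lines)
  header_end <- if (length(stanza_starts)) stanza_starts[1] - 1L else n

  header_tags <- character()
  header_vals <- character()
  subsetdefs <- character()
  for (i in seq_len(header_end)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    kv <- split_tag_line(line, i)
    if (kv$tag == "subsetdef") {
      m <- regmatches(kv$value,
                      regexec('^(\\S+)\\s+"(.*)"\\s*$', kv$value))[[1]]
      if (length(m) != 3L) {
        stop("malformed subsetdef at line ", i, ": ", line, call. = FALSE)
      }
      subsetdefs[m[2]] <- m[3]
    } else {
      header_tags <- c(header_tags, kv$tag)
      header_vals <- c(header_vals, kv$value)
    }
  }

  terms <- list()
  opaque_stanzas <- character()
  idx <- seq_along(stanza_starts)
  for (si in idx) {
    from <- stanza_starts[si]
    to <- if (si < length(stanza_starts)) stanza_starts[si + 1L] - 1L else n
    block <- lines[from:to]
    while (length(block) && !nzchar(trimws(block[length(block)]))) {
      block <- block[-length(block)]
    }
    if (trimws(block[1]) != "[Term]") {
      opaque_stanzas <- c(opaque_stanzas, paste(block, collapse = "\n"))
      next
    }
    terms[[length(terms) + 1L]] <- parse_term_stanza(block[-1], from)
  }

  ids <- vapply(terms, function(t) t$term_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate primary term id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  ontology_document(
    terms = terms,
    header = data.frame(tag = header_tags, value = header_vals,
                        stringsAsFactors = FALSE),
    subsetdefs = subsetdefs,
    opaque_stanzas = opaque_stanzas
  )
}

split_tag_line <- function(line, lineno) {
  pos <- regexpr(":", line, fixed = TRUE)
  if (pos < 1L) {
    stop("malformed tag line at line ", lineno, ": ", line, call. = FALSE)
  }
  list(tag = substr(line, 1L, pos - 1L),
       value = trimws(substr(line, pos + 1L, nchar(line))))
}

parse_term_stanza <- function(body, start_line) {
  id <- NULL
  name <- ""
  namespace <- NA_character_
  parent_ids <- character(); parent_rels <- character()
  alt_ids <- character(); subsets <- character()
  replaced_by <- character(); consider <- character()
  other_rel <- character(); other_tgt <- character()
  is_obsolete <- FALSE
  opaque <- character()

  for (j in seq_along(body)) {
    line <- body[j]
    if (!nzchar(trimws(line))) next
    kv <- split_tag_line(line, start_line + j)
    val <- kv$value
    switch(kv$tag,
      id = { id <- strip_obo_comment(val) },
      name = { name <- val },
      namespace = { namespace <- strip_obo_comment(val) },
      alt_id = { alt_ids <- c(alt_ids, strip_obo_comment(val)) },
      is_a = {
        parent_ids <- c(parent_ids, strip_obo_comment(val))
        parent_rels <- c(parent_rels, "is_a")
      },
      relationship = {
        parts <- strsplit(strip_obo_comment(val), "\\s+")[[1]]
        if (length(parts) < 2L) {
          stop("malformed relationship at line ", start_line + j, ": ", line,
               call. = FALSE)
        }
        if (parts[1] == "part_of") {
          parent_ids <- c(parent_ids, parts[2])
          parent_rels <- c(parent_rels, "part_of")
        } else {
          other_rel <- c(other_rel, parts[1])
          other_tgt <- c(other_tgt, parts[2])
        }
      },
      is_obsolete = { is_obsolete <- identical(strip_obo_comment(val), "true") },
      replaced_by = { replaced_by <- c(replaced_by, strip_obo_comment(val)) },
      consider = { consider <- c(consider, strip_obo_comment(val)) },
      subset = { subsets <- c(subsets, strip_obo_comment(val)) },
      { opaque <- c(opaque, line) }
    )
  }
  if (is.null(id)) {
    stop("term stanza starting at line ", start_line, " has no id tag",
         call. = FALSE)
  }
  ontology_term(
    term_id = id, name = name, namespace = namespace,
    parents = data.frame(parent = parent_ids, relation = parent_rels,
                         stringsAsFactors = FALSE),
    alt_ids = alt_ids, is_obsolete = is_obsolete,
    replaced_by = replaced_by, consider = consider, subsets = subsets,
    other_relationships = data.frame(relation = other_rel, target = other_tgt,
                                     stringsAsFactors = FALSE),
    opaque = opaque
  )
}

#' Serialize an ontology document to OBO text
#'
#' Emits the header (including one `subsetdef:` line per defined subset),
#' then one `[Term]` stanza per term sorted by id for deterministic diffs,
#' then any preserved non-term stanzas. The output re-parses to a document
#' equal to the input, and writing is idempotent byte-for-byte.
#'
#' @param doc An [ontology_document()].
#' @param path Optional file path; if `NULL` the lines are returned invisibly.
#' @return Character vector of output lines, invisibly.
#' @export
write_obo <- function(doc, path = NULL) {
  stopifnot(inherits(doc, "ontology_document"))
  ids <- names(doc$terms)
  for (t in doc$terms) {
    unresolved <- setdiff(t$parents$parent, ids)
    if (length(unresolved)) {
      stop("term '", t$term_id, "' references unresolved parent(s): ",
           paste(unresolved, collapse = ", "), call. = FALSE)
    }
  }
  validate_ontology_document(doc)

  out <- character()
  if (nrow(doc$header)) {
    out <- c(out, paste0(doc$header$tag, ": ", doc$header$value))
  }
  sdefs <- doc$subsetdefs[order(names(doc$subsetdefs))]
  out <- c(out, sprintf('subsetdef: %s "%s"', names(sdefs), unname(sdefs)))

  for (t in doc$terms) {
    out <- c(out, "", "[Term]", format_term_stanza(t))
  }
  for (st in doc$opaque_stanzas) {
    out <- c(out, "", st)
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

tag_lines <- function(tag, values) {
  if (length(values)) paste0(tag, values) else character(0)
}

format_term_stanza <- function(t) {
  s <- c(paste0("id: ", t$term_id), paste0("name: ", t$name))
  if (!is.na(t$namespace)) s <- c(s, paste0("namespace: ", t$namespace))
  s <- c(s, tag_lines("alt_id: ", t$alt_ids))
  if (t$is_obsolete) s <- c(s, "is_obsolete: true")
  isa <- t$parents$parent[t$parents$relation == "is_a"]
  po <- t$parents$parent[t$parents$relation == "part_of"]
  s <- c(s, tag_lines("is_a: ", isa),
         tag_lines("relationship: part_of ", po))
  if (nrow(t$other_relationships)) {
    s <- c(s, paste0("relationship: ", t$other_relationships$relation, " ",
                     t$other_relationships$target))
  }
  s <- c(s, tag_lines("subset: ", t$subsets),
         tag_lines("replaced_by: ", t$replaced_by),
         tag_lines("consider: ", t$consider),
         t$opaque)
  s
}

#' Label a set of terms as a named subset
#'
#' Adds a `subsetdef` for `subset_name` and makes exactly the listed terms
#' carry the label (the label is removed from any other term; unrelated
#' subset labels are untouched). Idempotent.
#'
#' @param doc An [ontology_document()].
#' @param subset_name Subset label to define/apply.
#' @param description Free-text description stored in the `subsetdef` header.
#' @param term_ids Character vector of primary ids to label (may be empty).
#' @return The modified document.
#' @export
apply_subset_labels <- function(doc, subset_name, description, term_ids) {
  stopifnot(inherits(doc, "ontology_document"))
  term_ids <- unique(as.character(term_ids))
  unknown <- setdiff(term_ids, names(doc$terms))
  if (length(unknown)) {
    stop("unknown term id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  doc$subsetdefs[subset_name] <- description
  doc$subsetdefs <- doc$subsetdefs[order(names(doc$subsetdefs))]
  for (id in names(doc$terms)) {
    subs <- setdiff(doc$terms[[id]]$subsets, subset_name)
    if (id %in% term_ids) subs <- c(subs, subset_name)
    doc$terms[[id]]$subsets <- sort(unique(subs))
  }
  doc
}

#' Extract a standalone slim ontology document
#'
#' Restricts a document to the terms carrying a subset label and rewires
#' parent links that pointed outside the subset to the nearest labelled
#' ancestor reachable through unlabelled terms. A rewired link is typed
#' `is_a` when at least one purely-`is_a` route to that ancestor exists and
#' `part_of` otherwise, the same relation-typing rule used when mapping
#' annotations onto a slim. The subset must be path-closed: the namespace
#' root of every labelled term must itself be labelled.
#'
#' @param doc An [ontology_document()].
#' @param subset_name A subset defined in `doc`.
#' @return A new [ontology_document()] containing only the labelled terms.
#' @export
extract_slim_document <- function(doc, subset_name) {
  stopifnot(inherits(doc, "ontology_document"))
  if (!subset_name %in% names(doc$subsetdefs)) {
    stop("subset '", subset_name, "' is not defined in the document",
         call. = FALSE)
  }
  labelled <- names(doc$terms)[vapply(doc$terms, function(t)
    subset_name %in% t$subsets, logical(1))]
  keep <- doc$terms[labelled]
  ns_of <- vapply(keep, function(t) t$namespace, character(1))

  for (ns in unique(ns_of[!vapply(keep, function(t) t$is_obsolete,
                                  logical(1))])) {
    g <- build_namespace_graph(doc, ns)
    in_ns <- intersect(labelled, g$nodes)
    if (!g$root %in% in_ns) {
      stop("subset '", subset_name, "' is not path-closed: namespace root ",
           g$root, " (", ns, ") is not labelled", call. = FALSE)
    }
    for (id in setdiff(in_ns, g$root)) {
      hits <- first_hits_impl(g, id, in_ns, include_self = FALSE)
      if (!nrow(hits)) {
        stop("labelled term ", id, " reaches no labelled ancestor",
             call. = FALSE)
      }
      keep[[id]]$parents <- canonical_parents(
        data.frame(parent = hits$term_id, relation = hits$relation,
                   stringsAsFactors = FALSE))
    }
    keep[[g$root]]$parents <- empty_parents()
  }

  sdef <- doc$subsetdefs[subset_name]
  keep <- lapply(keep, function(t) {
    t$subsets <- intersect(t$subsets, subset_name)
    t
  })
  ontology_document(
    terms = unname(keep),
    header = doc$header,
    subsetdefs = sdef
  )
}
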