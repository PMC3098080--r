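#' Select slim terms by thresholding information content
#'
#' Keeps the terms with `I` strictly greater than `tau`. An empty result is
#' permitted (a very high threshold simply yields an empty slim for that
#' namespace).
#'
#' @param result An `"ic_result"`.
#' @param tau Real threshold.
#' @return Character vector of selected term ids (sorted).
#' @export
select_slim_terms <- function(result, tau) {
  stopifnot(inherits(result, "ic_result"), is.numeric(tau))
  sort(names(result$info)[result$info > tau])
}

#' Complete paths from selected terms to the namespace root
#'
#' Adds every ancestor of every selected term (the union of all paths back
#' to the root), so the slim has no orphan terms: each member has at least
#' one complete path to the root lying entirely inside the slim.
#'
#' @param g A `"namespace_graph"`.
#' @param selected Character vector of selected term ids.
#' @return A list (one namespace's slim fragment) with `selected`,
#'   `closure` (added ancestors) and `all_terms`.
#' @export
close_paths <- function(g, selected) {
  stopifnot(inherits(g, "namespace_graph"))
  selected <- sort(unique(as.character(selected)))
  missing <- setdiff(selected, g$nodes)
  if (length(missing)) {
    stop("selected term(s) not in graph: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  closure <- if (length(selected)) {
    sort(setdiff(ancestors_of(g, selected), selected))
  } else character()
  list(selected = selected, closure = closure,
       all_terms = sort(union(selected, closure)))
}

#' Build a slim from an ontology and an annotation set
#'
#' Runs the full per-namespace pipeline: count direct annotations, extract
#' the annotation-induced sub-graph (used terms plus all their ancestors),
#' compute information content, select terms with `I > tau`, and close
#' paths to the root. Namespaces are processed independently; a namespace
#' with no annotations is skipped with a warning. The returned document is
#' the input ontology with a `subsetdef` header and per-term `subset`
#' labels applied for the slim.
#'
#' The annotation set is expected to be synchronized against `doc` first
#' (see [synchronize()]); a used term that does not resolve in the
#' ontology is an error.
#'
#' @param doc An [ontology_document()].
#' @param annotations An [annotation_set()].
#' @param config An [ic_config()].
#' @param tau Selection threshold on `I` (strict inequality). The working
#'   default pairs `tau = 0.3` with `lambda_scale = 100`.
#' @param name Subset label for the slim.
#' @param aspect_map Aspect-letter to namespace mapping.
#' @param evidence_exclude Evidence codes excluded from counting.
#' @return A list of class `"slim_definition"` (`name`, `threshold`,
#'   `namespaces`: per-namespace fragments with `selected`, `closure`,
#'   `all_terms`, the sub-`graph` and the `ic` result), plus the labelled
#'   `document`.
#' @export
build_slim <- function(doc, annotations, config = ic_config(), tau = 0.3,
                       name = "goslim_auto",
                       aspect_map = default_aspect_map(),
                       evidence_exclude = character()) {
  stopifnot(inherits(doc, "ontology_document"),
            inherits(annotations, "annotation_set"))
  fragments <- list()
  for (ns in doc$namespaces) {
    counts <- count_direct_annotations(annotations, ns,
                                       aspect_map = aspect_map,
                                       evidence_exclude = evidence_exclude)
    if (!length(counts)) {
      warning("namespace '", ns, "' has no annotations; skipped",
              call. = FALSE)
      next
    }
    g <- build_namespace_graph(doc, ns)
    sub <- extract_annotation_subgraph(g, names(counts))
    sub <- attach_counts(sub, counts)
    ic <- compute_information(sub, config)
    frag <- close_paths(sub, select_slim_terms(ic, tau))
    frag$graph <- sub
    frag$ic <- ic
    frag$used_terms <- sort(names(counts))
    fragments[[ns]] <- frag
  }
  all_terms <- sort(unique(unlist(lapply(fragments, `[[`, "all_terms"),
                                  use.names = FALSE)))
  labelled <- apply_subset_labels(
    doc, name,
    sprintf("Slim selected at I > %g (lambda = %g)", tau,
            config$lambda_scale),
    all_terms)
  structure(list(
    name = name, threshold = tau, config = config,
    namespaces = fragments, document = labelled
  ), class = "slim_definition")
}

#' @export
print.slim_definition <- function(x, ...) {
  cat("<slim_definition> '", x$name, "' at I > ", x$threshold, "\n", sep = "")
  for (ns in names(x$namespaces)) {
    f <- x$namespaces[[ns]]
    cat("  ", ns, ": ", length(f$selected), " selected + ",
        length(f$closure), " closure = ", length(f$all_terms),
        " terms\n", sep = "")
  }
  invisible(x)
}

slim_terms_of <- function(slim, namespace = NULL) {
  if (inherits(slim, "slim_definition")) {
    if (is.null(namespace)) {
      stop("namespace required when passing a slim_definition", call. = FALSE)
    }
    frag <- slim$namespaces[[namespace]]
    if (is.null(frag)) {
      stop("slim has no fragment for namespace '", namespace, "'",
           call. = FALSE)
    }
    frag$all_terms
  } else if (is.list(slim) && !is.null(slim$all_terms)) {
    slim$all_terms
  } else {
    unique(as.character(slim))
  }
}

#' Map annotation terms onto a slim
#'
#' For every used annotation term, finds the slim term(s) in closest
#' proximity on the paths toward the root ([first_slim_hits()]); a term
#' that is itself in the slim maps to itself. Mapped relations are typed:
#' `is_a` when some qualifying path uses only `is_a` edges, `part_of` when
#' every qualifying path crosses a `part_of` edge. Redundant ancestors
#' among the targets are deliberately kept (a term may map both to a slim
#' term and to that term's own slim ancestor when distinct paths make both
#' "nearest"); no minimisation pass is applied.
#'
#' @param g The `"namespace_graph"` the slim was built on.
#' @param slim A `"slim_definition"`, a per-namespace fragment, or a plain
#'   character vector of slim term ids. Must be path-closed and contain the
#'   root of `g`.
#' @param used_terms Annotation terms to map (all in `g`).
#' @return A list of class `"slim_mapping"` with `map` (term id -> data
#'   frame `term_id`/`relation`), `slim_terms` and `namespace`.
#' @export
map_annotations <- function(g, slim, used_terms) {
  stopifnot(inherits(g, "namespace_graph"))
  targets <- slim_terms_of(slim, g$namespace)
  if (!length(targets)) {
    stop("slim is empty for namespace '", g$namespace, "'", call. = FALSE)
  }
  used_terms <- unique(as.character(used_terms))
  map <- lapply(used_terms, function(a) first_slim_hits(g, a, targets))
  names(map) <- used_terms
  structure(list(map = map, slim_terms = targets,
                 namespace = g$namespace), class = "slim_mapping")
}

#' Flatten a slim mapping to a table
#'
#' @param mapping A `"slim_mapping"` (or a list of them, one per
#'   namespace).
#' @return Data frame with columns `source_term`, `slim_term`, `relation`.
#' @export
slim_map_table <- function(mapping) {
  mappings <- if (inherits(mapping, "slim_mapping")) list(mapping) else mapping
  rows <- lapply(mappings, function(m) {
    do.call(rbind, lapply(names(m$map), function(a) {
      data.frame(source_term = a, slim_term = m$map[[a]]$term_id,
                 relation = m$map[[a]]$relation, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(source_term = character(), slim_term = character(),
                      relation = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Rewrite an annotation set onto slim terms
#'
#' Each record is replaced by one record per mapped slim term (only the
#' term id changes; every other column is preserved). Duplicate
#' gene-product/slim-term pairs arising from the collapse are reduced to
#' one record, keeping the columns of the first contributing record.
#'
#' @param set An [annotation_set()].
#' @param mapping A `"slim_mapping"`, a list of them, or a data frame as
#'   produced by [slim_map_table()]. Every term used in `set` must be
#'   present in the mapping.
#' @return A new [annotation_set()] on slim terms.
#' @export
remap_annotation_set <- function(set, mapping) {
  stopifnot(inherits(set, "annotation_set"))
  tab <- if (is.data.frame(mapping)) mapping else slim_map_table(mapping)
  targets <- split(tab$slim_term, tab$source_term)
  rec <- set$records
  unmapped <- setdiff(unique(rec$term_id), names(targets))
  if (length(unmapped)) {
    stop("annotation term(s) missing from the slim mapping: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  per_rec <- targets[rec$term_id]
  times <- lengths(per_rec)
  idx <- rep(seq_len(nrow(rec)), times)
  out <- rec[idx, , drop = FALSE]
  out$term_id <- unlist(per_rec, use.names = FALSE)
  keep <- !duplicated(paste(out$object_id, out$term_id, sep = "\r"))
  out <- out[keep, , drop = FALSE]
  annotation_set(out, comments = set$comments,
                 source_label = paste0(set$source_label,
                                       if (nzchar(set$source_label)) " ",
                                       "(slim-remapped)"),
                 line_ncol = set$line_ncol[idx][keep])
}

#' Compare two slims by term overlap
#'
#' @param a,b Character vectors of term ids.
#' @return Data frame with `size_a`, `size_b`, `intersection` and
#'   `overlap_pct` (the intersection as a percentage of `a`).
#' @export
compare_slims <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  inter <- length(intersect(a, b))
  data.frame(size_a = length(a), size_b = length(b), intersection = inter,
             overlap_pct = if (length(a)) 100 * inter / length(a) else NA_real_)
}
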