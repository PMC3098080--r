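# Lookup tables for fast status classification: primary ids, obsolete flags,
# alt_id -> primary, replaced_by / consider payloads.
term_status_index <- function(doc) {
  ids <- names(doc$terms)
  obsolete <- vapply(doc$terms, function(t) t$is_obsolete, logical(1))
  alt_pairs <- lapply(doc$terms, function(t) {
    if (length(t$alt_ids)) {
      stats::setNames(rep(t$term_id, length(t$alt_ids)), t$alt_ids)
    } else NULL
  })
  alt_map <- unlist(unname(alt_pairs))
  list(ids = ids, obsolete = stats::setNames(obsolete, ids),
       alt_map = if (is.null(alt_map)) character() else alt_map,
       terms = doc$terms)
}

classify_with_index <- function(term_id, idx) {
  if (term_id %in% idx$ids) {
    t <- idx$terms[[term_id]]
    if (!t$is_obsolete) {
      return(list(term_id = term_id, status = "current",
                  successors = character(), evidence = "primary id"))
    }
    if (length(t$replaced_by) >= 1L) {
      # GO curation style: replaced_by is authoritative; a single entry is
      # the normal case, multiple entries are treated like the first.
      return(list(term_id = term_id, status = "replaced",
                  successors = t$replaced_by,
                  evidence = "is_obsolete + replaced_by"))
    }
    if (length(t$consider) == 1L) {
      return(list(term_id = term_id, status = "consider_single",
                  successors = t$consider,
                  evidence = "is_obsolete + single consider"))
    }
    if (length(t$consider) > 1L) {
      return(list(term_id = term_id, status = "consider_multiple",
                  successors = t$consider,
                  evidence = "is_obsolete + multiple consider"))
    }
    return(list(term_id = term_id, status = "removed",
                successors = character(),
                evidence = "is_obsolete, no successor"))
  }
  if (term_id %in% names(idx$alt_map)) {
    return(list(term_id = term_id, status = "alt_id",
                successors = unname(idx$alt_map[[term_id]]),
                evidence = "alt_id tag"))
  }
  list(term_id = term_id, status = "removed", successors = character(),
       evidence = "absent from document")
}

#' Classify a term identifier against an ontology version
#'
#' Determines which of the five inconsistency classes (if any) applies to a
#' term id used in annotation: `current` (a primary, non-obsolete id),
#' `alt_id` (class 1: alternative id of a current term), `replaced`
#' (class 2: obsolete with an authoritative `replaced_by` successor),
#' `consider_single` / `consider_multiple` (classes 3-4: obsolete with one
#' or several advisory `consider` successors), or `removed` (class 5:
#' obsolete with no successor, or absent from the document entirely).
#'
#' @param term_id Accession string.
#' @param doc An [ontology_document()].
#' @return A list with `term_id`, `status`, `successors` and `evidence`
#'   (which OBO tags produced the classification).
#' @export
classify_term_status <- function(term_id, doc) {
  stopifnot(inherits(doc, "ontology_document"))
  classify_with_index(term_id, term_status_index(doc))
}

STATUS_CLASS <- c(alt_id = 1L, replaced = 2L, consider_single = 3L,
                  consider_multiple = 4L, removed = 5L)

#' Synchronize an annotation set against an ontology version
#'
#' Resolves each record's term id against the document:
#' class 1 (alternative id) and class 2 (`replaced_by`) records are
#' rewritten in place with the primary/successor id — chains of
#' replacements are followed transitively up to `max_chain_depth` steps;
#' classes 3 and 4 (advisory `consider` successors) are moved, untouched,
#' to a quarantine set for supervised resolution; class 5 (removed
#' concepts) records are dropped. Every input record lands in exactly one
#' of the three outputs.
#'
#' @param set An [annotation_set()].
#' @param doc An [ontology_document()].
#' @param max_chain_depth Maximum number of alt_id/replaced_by hops to
#'   follow before quarantining the record with a `chain_too_deep` flag.
#' @return A list of class `"sync_outcome"`: `updated`, `quarantined` and
#'   `dropped` annotation sets, plus `report` with per-class record counts
#'   and a per-term substitution log.
#' @export
synchronize <- function(set, doc, max_chain_depth = 5L) {
  stopifnot(inherits(set, "annotation_set"),
            inherits(doc, "ontology_document"))
  idx <- term_status_index(doc)
  rec <- set$records
  n <- nrow(rec)

  # Resolve each distinct term id once.
  uniq <- unique(rec$term_id)
  res <- lapply(uniq, function(id) resolve_term(id, idx, max_chain_depth))
  names(res) <- uniq

  fate <- vapply(res, `[[`, character(1), "fate")[rec$term_id]
  final <- vapply(res, `[[`, character(1), "final_id")[rec$term_id]
  klass <- vapply(res, `[[`, integer(1), "class")[rec$term_id]

  upd_idx <- which(fate == "updated")
  quar_idx <- which(fate == "quarantined")
  drop_idx <- which(fate == "dropped")

  updated <- subset_annotation_set(set, upd_idx)
  updated$records$term_id <- unname(final[upd_idx])

  counts <- c(current = sum(klass == 0L, na.rm = TRUE),
              stats::setNames(vapply(1:5, function(k)
                sum(klass == k, na.rm = TRUE), integer(1)),
                as.character(1:5)),
              chain_too_deep = sum(klass == -1L, na.rm = TRUE))

  subs <- do.call(rbind, lapply(res, function(r) {
    if (r$fate == "updated" && r$final_id != r$term_id) {
      data.frame(from = r$term_id, to = r$final_id, class = r$class,
                 stringsAsFactors = FALSE)
    } else NULL
  }))
  if (is.null(subs)) {
    subs <- data.frame(from = character(), to = character(),
                       class = integer(), stringsAsFactors = FALSE)
  }
  rownames(subs) <- NULL

  structure(list(
    updated = updated,
    quarantined = subset_annotation_set(set, quar_idx),
    dropped = subset_annotation_set(set, drop_idx),
    report = list(n_input = n, counts = counts, substitutions = subs)
  ), class = "sync_outcome")
}

# Follow alt_id/replaced_by links until a terminal status is reached.
# Returns fate ("updated"/"quarantined"/"dropped"), the final id, and the
# inconsistency class of the terminal step (0 = already current,
# -1 = chain too deep).
resolve_term <- function(term_id, idx, max_chain_depth) {
  id <- term_id
  klass <- 0L
  for (depth in 0:max_chain_depth) {
    st <- classify_with_index(id, idx)
    switch(st$status,
      current = return(list(term_id = term_id, final_id = id,
                            fate = "updated", class = klass)),
      alt_id = ,
      replaced = {
        klass <- STATUS_CLASS[[st$status]]
        id <- st$successors[1L]
      },
      consider_single = return(list(term_id = term_id, final_id = id,
                                    fate = "quarantined", class = 3L)),
      consider_multiple = return(list(term_id = term_id, final_id = id,
                                      fate = "quarantined", class = 4L)),
      removed = return(list(term_id = term_id, final_id = id,
                            fate = "dropped", class = 5L))
    )
  }
  list(term_id = term_id, final_id = id, fate = "quarantined", class = -1L)
}

#' @export
print.sync_outcome <- function(x, ...) {
  cat("<sync_outcome> ", x$report$n_input, " records: ",
      nrow(x$updated$records), " updated, ",
      nrow(x$quarantined$records), " quarantined, ",
      nrow(x$dropped$records), " dropped\n", sep = "")
  cat("  class counts:",
      paste(names(x$report$counts), x$report$counts, sep = "=",
            collapse = " "), "\n")
  invisible(x)
}
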