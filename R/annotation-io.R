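# GAF 2.x column names; files may carry 15 (GAF 2.0 core) to 17 columns.
GAF_COLUMNS <- c("db", "object_id", "symbol", "qualifier", "term_id",
                 "reference", "evidence", "with_from", "aspect",
                 "object_name", "synonym", "object_type", "taxon", "date",
                 "assigned_by", "extension", "isoform")

#' Default aspect-letter to namespace mapping
#'
#' GAF column 9 codes the namespace with one letter; this is the standard
#' GO mapping. Pass a different named vector to the counting functions to
#' use other ontologies/namespaces.
#' @export
default_aspect_map <- function() {
  c(P = "biological_process", F = "molecular_function",
    C = "cellular_component")
}

#' Construct an annotation set
#'
#' @param records Data frame with the GAF columns (character); records keep
#'   their input order as provenance.
#' @param comments Character vector of `!`-prefixed header lines.
#' @param source_label Free-text provenance label.
#' @param line_ncol Integer vector giving the column count of each input
#'   line (so 15- and 17-column files both round-trip byte-identically).
#' @return A list of class `"annotation_set"`.
#' @export
annotation_set <- function(records, comments = character(),
                           source_label = "", line_ncol = NULL) {
  stopifnot(is.data.frame(records))
  miss <- setdiff(GAF_COLUMNS[1:15], names(records))
  if (length(miss)) {
    for (m in miss) records[[m]] <- rep("", nrow(records))
  }
  records <- records[intersect(GAF_COLUMNS, names(records))]
  rownames(records) <- NULL
  if (is.null(line_ncol)) line_ncol <- rep(ncol(records), nrow(records))
  structure(list(
    records = records,
    comments = as.character(comments),
    source_label = source_label,
    line_ncol = as.integer(line_ncol)
  ), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set> ", nrow(x$records), " records",
      if (nzchar(x$source_label)) paste0(" [", x$source_label, "]"),
      "\n", sep = "")
  invisible(x)
}

#' Parse a GAF (Gene Association File)
#'
#' Lines beginning `!` are kept as a comment header; every other line must
#' have at least 15 tab-separated columns. All columns are preserved
#' verbatim for lossless round-tripping.
#'
#' @param x Path to a GAF file, or a character vector of lines.
#' @param source_label Optional provenance label.
#' @return An [annotation_set()].
#' @export
parse_gaf <- function(x, source_label = "") {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  is_comment <- startsWith(lines, "!")
  data_idx <- which(!is_comment & nzchar(lines))
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  short <- ncols < 15L
  if (any(short)) {
    stop("GAF line ", data_idx[which(short)[1]], " has ",
         ncols[which(short)[1]], " columns (need >= 15)", call. = FALSE)
  }
  width <- if (length(ncols)) max(ncols) else 15L
  mat <- matrix("", nrow = length(fields), ncol = width)
  for (i in seq_along(fields)) mat[i, seq_len(ncols[i])] <- fields[[i]]
  records <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(records) <- GAF_COLUMNS[seq_len(width)]
  annotation_set(records, comments = lines[is_comment],
                 source_label = source_label, line_ncol = ncols)
}

#' Write an annotation set as GAF
#'
#' Comment header first, then the records in their stored order,
#' tab-separated, each line with its original column count.
#'
#' @param set An [annotation_set()].
#' @param path Optional output path; if `NULL` lines are returned invisibly.
#' @return Character vector of lines, invisibly.
#' @export
write_gaf <- function(set, path = NULL) {
  stopifnot(inherits(set, "annotation_set"))
  rec <- set$records
  lines <- vapply(seq_len(nrow(rec)), function(i) {
    paste(unlist(rec[i, seq_len(set$line_ncol[i]), drop = TRUE]),
          collapse = "\t")
  }, character(1))
  out <- c(set$comments, lines)
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

# Keep a subset of records (by row index), preserving order and per-line
# column counts.
subset_annotation_set <- function(set, idx, source_label = set$source_label) {
  annotation_set(set$records[idx, , drop = FALSE],
                 comments = set$comments,
                 source_label = source_label,
                 line_ncol = set$line_ncol[idx])
}

qualifier_tokens <- function(qualifier) {
  strsplit(qualifier, "|", fixed = TRUE)
}

#' Count distinct gene products directly annotated to each term
#'
#' Direct counts only: no propagation to ancestors happens here (upward
#' accumulation is the job of the information-content recursion). A
#' gene-product/term pair is counted once however many records assert it;
#' records carrying the `NOT` qualifier are excluded (they assert
#' non-membership); records whose evidence code is listed in
#' `evidence_exclude` are excluded. Terms left with no records are absent
#' from the result.
#'
#' @param set An [annotation_set()].
#' @param namespace Namespace label selecting records via their aspect code.
#' @param aspect_map Named vector, aspect letter -> namespace label.
#' @param evidence_exclude Character vector of evidence codes to drop
#'   (default none: all evidence is counted).
#' @return Named integer vector, term id -> count of distinct gene products.
#' @export
count_direct_annotations <- function(set, namespace,
                                     aspect_map = default_aspect_map(),
                                     evidence_exclude = character()) {
  stopifnot(inherits(set, "annotation_set"))
  rec <- set$records
  unknown <- setdiff(unique(rec$aspect), names(aspect_map))
  if (length(unknown)) {
    stop("unknown aspect code(s) in GAF: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- aspect_map[rec$aspect] == namespace
  keep <- keep & !vapply(qualifier_tokens(rec$qualifier),
                         function(q) "NOT" %in% q, logical(1))
  if (length(evidence_exclude)) {
    keep <- keep & !(rec$evidence %in% evidence_exclude)
  }
  rec <- rec[keep, , drop = FALSE]
  if (!nrow(rec)) return(stats::setNames(integer(0), character(0)))
  pairs <- unique(rec[c("object_id", "term_id")])
  counts <- table(pairs$term_id)
  stats::setNames(as.integer(counts), names(counts))
}

# gene -> set-of-terms map for enrichment (direct annotations, NOT excluded).
gene_term_map <- function(set, namespace,
                          aspect_map = default_aspect_map(),
                          evidence_exclude = character()) {
  rec <- set$records
  unknown <- setdiff(unique(rec$aspect), names(aspect_map))
  if (length(unknown)) {
    stop("unknown aspect code(s) in GAF: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- aspect_map[rec$aspect] == namespace
  keep <- keep & !vapply(qualifier_tokens(rec$qualifier),
                         function(q) "NOT" %in% q, logical(1))
  if (length(evidence_exclude)) {
    keep <- keep & !(rec$evidence %in% evidence_exclude)
  }
  rec <- rec[keep, , drop = FALSE]
  lapply(split(rec$term_id, rec$object_id), unique)
}
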