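#' Upper-tail hypergeometric probability
#'
#' `P(X >= x)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `x` annotated genes when `n` genes are drawn without
#' replacement from a population of `N` genes of which `K` carry the term.
#' Computed through the survival function of [stats::phyper()] (log-gamma
#' based), numerically stable over the whole support.
#'
#' @param N Population size.
#' @param K Number of successes (genes carrying the term) in the population.
#' @param n Study-set size (number of draws).
#' @param x Observed successes in the study set.
#' @return The upper-tail probability, exactly 1 when `x = 0`.
#' @export
hypergeom_upper_tail <- function(N, K, n, x) {
  if (!(N >= 0 && K >= 0 && K <= N && n >= 0 && n <= N &&
        x >= 0 && x <= min(K, n))) {
    stop("invalid hypergeometric parameters: need 0 <= K <= N, ",
         "0 <= n <= N, 0 <= x <= min(K, n)", call. = FALSE)
  }
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Uncapped Bonferroni correction
#'
#' Multiplies every p-value by the number of tested hypotheses `m`. Values
#' are deliberately not capped at 1, so the severity of the correction
#' stays visible (a corrected value of 10 means the raw p-value would need
#' to be ten-fold smaller to survive at the nominal level).
#'
#' @param p Numeric vector of raw p-values.
#' @param m Number of hypotheses tested (must be supplied explicitly and be
#'   at least `length(p)`).
#' @return `p * m`, same order as input.
#' @export
bonferroni <- function(p, m) {
  stopifnot(is.numeric(p))
  if (!is.numeric(m) || length(m) != 1L || m <= 0 || m != floor(m)) {
    stop("m must be a positive integer count of tested hypotheses",
         call. = FALSE)
  }
  if (m < length(p)) {
    stop("m (", m, ") is smaller than the number of p-values (",
         length(p), ")", call. = FALSE)
  }
  p * m
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Standard FDR step-up: with p-values sorted ascending,
#' `q_i = min_{j >= i} (m * p_j / j)`, capped at 1, returned in the input
#' order. Monotone non-decreasing along the sorted order and never smaller
#' than the raw p-value.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in input order.
#' @export
benjamini_hochberg <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- pmin(1, rev(cummin(rev(ranked))))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Hypergeometric term over-representation test
#'
#' Tests every term used in the population (direct annotations: a term is
#' testable when at least one population gene carries it) for
#' over-representation in the study set, and attaches the uncapped
#' Bonferroni and the Benjamini-Hochberg corrections with `m` equal to the
#' number of testable terms. Running on slim-remapped annotations uses the
#' identical code path — the smaller slim vocabulary simply yields a
#' smaller `m`, which is the mechanism by which slims raise the power of
#' corrected tests.
#'
#' @param study_genes Character vector of study gene ids (a subset of the
#'   population).
#' @param population Named list, gene id -> character vector of term ids
#'   (direct annotations in the tested namespace), e.g. from a parsed GAF.
#' @param alpha Nominal significance level used only to flag rows.
#' @return Data frame (one row per testable term) with columns `term_id`,
#'   `x`, `n`, `K`, `N`, `p_value`, `bonferroni`, `bh`, `rank`,
#'   `significant_bh`; rows sorted by ascending p-value.
#' @export
enrich <- function(study_genes, population, alpha = 0.05) {
  study_genes <- unique(as.character(study_genes))
  if (!length(study_genes)) {
    stop("study gene set is empty", call. = FALSE)
  }
  if (is.null(names(population)) || !is.list(population)) {
    stop("population must be a named list gene -> term ids", call. = FALSE)
  }
  population <- lapply(population, unique)
  population <- population[lengths(population) > 0L]
  outside <- setdiff(study_genes, names(population))
  if (length(outside)) {
    stop("study gene(s) absent from the annotated population: ",
         paste(outside, collapse = ", "), call. = FALSE)
  }
  N <- length(population)
  n <- length(study_genes)

  K_tab <- table(unlist(population, use.names = FALSE))
  terms <- names(K_tab)
  m <- length(terms)
  x_tab <- table(unlist(population[study_genes], use.names = FALSE))
  x <- stats::setNames(integer(m), terms)
  x[names(x_tab)] <- as.integer(x_tab)

  p <- vapply(seq_len(m), function(i)
    hypergeom_upper_tail(N, as.integer(K_tab[[i]]), n, x[[i]]), numeric(1))

  out <- data.frame(
    term_id = terms,
    x = unname(x),
    n = n,
    K = as.integer(K_tab),
    N = N,
    p_value = p,
    bonferroni = bonferroni(p, m),
    bh = benjamini_hochberg(p),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$significant_bh <- out$bh <= alpha
  rownames(out) <- NULL
  out
}
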