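#' Configuration of the information-content calculation
#'
#' The per-term score is `I_n = P_n - Theta_n`, where `P_n` is the
#' annotation mass retained if term `n` stays in the slim and `Theta_n`
#' penalises the coverage lost when the children of `n` are collapsed into
#' it. Both are rescaled by `lambda_scale` (the raw ratios are tiny on
#' sparse real ontologies; 100 is the conventional working scale, while
#' `lambda_scale = 1` puts tree-shaped graphs on the interpretable
#' `[-1, 1]` range).
#'
#' The `beta_variant` and `theta_child_score` switches select how the
#' upward accumulation and the penalty's per-child score are evaluated; the
#' defaults (`leaf_zero_root_exempt`, `direct_plus_beta`) are the unique
#' combination that reproduces all three boundary values of the metric
#' (see the methods vignette). The alternatives are kept selectable for
#' sensitivity analysis:
#' \describe{
#'   \item{leaf_zero_root_exempt}{childless non-root terms get `beta = 0`;
#'     every other term gets `A_n` plus the sum of its children's betas.
#'     A childless root keeps `beta = A_root` so a one-term graph scores
#'     `P = 1` at `lambda = 1`.}
#'   \item{literal_leaf_zero}{the leaf-zero rule applies to the root too.}
#'   \item{subtree_sum}{no leaf-zero rule; every term gets `A_n` plus its
#'     children's betas.}
#'   \item{direct_only}{`beta_n = A_n`, no accumulation.}
#' }
#' `theta_child_score` is the per-child score summed inside the penalty:
#' `direct_plus_beta` uses `(A_i + beta_i) / sum(A)` (a child's full
#' annotation mass), `beta_only` uses `beta_i / sum(A)`.
#'
#' The log rule of the penalty is fixed: `log_k(alpha)` with `k` the number
#' of children of the root; by convention the value is 1 whenever `k = 1`
#' (so the two-term chain scores `Theta = 1`) and 0 when `alpha = 1` with
#' `k > 1` (collapsing a single child is unpenalised).
#'
#' @param lambda_scale Positive rescaling constant (default 100).
#' @param beta_variant One of `"leaf_zero_root_exempt"` (default),
#'   `"literal_leaf_zero"`, `"subtree_sum"`, `"direct_only"`.
#' @param theta_child_score One of `"direct_plus_beta"` (default),
#'   `"beta_only"`.
#' @return A list of class `"ic_config"`.
#' @export
ic_config <- function(lambda_scale = 100,
                      beta_variant = c("leaf_zero_root_exempt",
                                       "literal_leaf_zero",
                                       "subtree_sum", "direct_only"),
                      theta_child_score = c("direct_plus_beta",
                                            "beta_only")) {
  stopifnot(is.numeric(lambda_scale), length(lambda_scale) == 1L,
            lambda_scale > 0)
  structure(list(
    lambda_scale = lambda_scale,
    beta_variant = match.arg(beta_variant),
    theta_child_score = match.arg(theta_child_score)
  ), class = "ic_config")
}

#' Accumulated annotation mass beta per term
#'
#' Evaluated in a single reverse-topological sweep (children before
#' parents), which is equivalent to the memoized recursion: on a DAG a
#' multi-parent child contributes its beta to each of its parents.
#'
#' @param g A `"namespace_graph"` with counts attached.
#' @param variant See [ic_config()].
#' @return Named numeric vector over `g$nodes`.
#' @export
compute_beta <- function(g, variant = "leaf_zero_root_exempt") {
  stopifnot(inherits(g, "namespace_graph"))
  variant <- match.arg(variant, c("leaf_zero_root_exempt",
                                  "literal_leaf_zero",
                                  "subtree_sum", "direct_only"))
  if (variant == "direct_only") return(g$A)
  beta <- stats::setNames(numeric(g$t), g$nodes)
  for (n in rev(g$topo)) {
    ch <- g$children_of[[n]]
    if (length(ch) == 0L) {
      beta[n] <- switch(variant,
        leaf_zero_root_exempt = if (identical(n, g$root)) g$A[[n]] else 0,
        literal_leaf_zero = 0,
        subtree_sum = g$A[[n]])
    } else {
      beta[n] <- g$A[[n]] + sum(beta[ch])
    }
  }
  beta
}

#' Retained-information score P per term
#'
#' `P_n = lambda * beta_n / sum(A)` over the sub-graph's direct annotation
#' total. A graph with no annotations has no defined P; this is an error,
#' never a silent division by zero.
#'
#' @param g A `"namespace_graph"`.
#' @param beta Output of [compute_beta()].
#' @param lambda_scale Positive rescaling constant.
#' @return Named numeric vector over `g$nodes`.
#' @export
compute_p <- function(g, beta, lambda_scale = 100) {
  stopifnot(inherits(g, "namespace_graph"))
  if (g$total_annotations <= 0) {
    stop("no annotations in namespace '", g$namespace, "'", call. = FALSE)
  }
  lambda_scale * beta[g$nodes] / g$total_annotations
}

# log_k(alpha) with the fixed conventions: 1 whenever k = 1; 0 when
# alpha = 1 and k > 1; otherwise the literal log ratio.
log_rule <- function(alpha, k) {
  if (k == 1) return(1)
  if (alpha == 1) return(0)
  log(alpha) / log(k)
}

#' Collapse penalty Theta per term
#'
#' `Theta_n = 0` for childless terms; otherwise
#' `lambda * (sum of per-child scores) * log_k(alpha)` with `alpha` the
#' child count of `n` and `k` the root's child count. The per-child score
#' is controlled by `config$theta_child_score` (see [ic_config()]).
#'
#' @param g A `"namespace_graph"`.
#' @param beta Output of [compute_beta()].
#' @param config An [ic_config()].
#' @return Named numeric vector over `g$nodes`.
#' @export
compute_theta <- function(g, beta, config = ic_config()) {
  stopifnot(inherits(g, "namespace_graph"), inherits(config, "ic_config"))
  if (g$total_annotations <= 0) {
    stop("no annotations in namespace '", g$namespace, "'", call. = FALSE)
  }
  total <- g$total_annotations
  theta <- stats::setNames(numeric(g$t), g$nodes)
  for (n in g$nodes) {
    ch <- g$children_of[[n]]
    alpha <- length(ch)
    if (alpha == 0L) next
    s <- switch(config$theta_child_score,
      direct_plus_beta = (g$A[ch] + beta[ch]) / total,
      beta_only = beta[ch] / total)
    theta[n] <- config$lambda_scale * sum(s) * log_rule(alpha, g$k)
  }
  theta
}

#' Information content I per term
#'
#' Composes [compute_beta()], [compute_p()] and [compute_theta()] and
#' returns `I = P - Theta` nodewise (an exact identity, not an
#' approximation).
#'
#' @param g A `"namespace_graph"` with counts attached and
#'   `total_annotations > 0`.
#' @param config An [ic_config()].
#' @return A list of class `"ic_result"` with named per-node vectors
#'   `beta`, `p`, `theta`, `info`, plus `config` and the `graph`.
#' @examples
#' fx <- worked_example()
#' g <- build_namespace_graph(fx$document, "demo")
#' g <- attach_counts(g, count_direct_annotations(fx$annotations, "demo",
#'                                                aspect_map = c(P = "demo")))
#' res <- compute_information(g, ic_config(lambda_scale = 1))
#' round(res$info, 3)
#' @export
compute_information <- function(g, config = ic_config()) {
  stopifnot(inherits(g, "namespace_graph"), inherits(config, "ic_config"))
  beta <- compute_beta(g, config$beta_variant)
  p <- compute_p(g, beta, config$lambda_scale)
  theta <- compute_theta(g, beta, config)
  structure(list(
    beta = beta, p = p, theta = theta, info = p - theta,
    config = config, graph = g
  ), class = "ic_result")
}

#' @export
print.ic_result <- function(x, ...) {
  cat("<ic_result> ", x$graph$namespace, ": ", x$graph$t,
      " terms, lambda = ", x$config$lambda_scale,
      ", I in [", signif(min(x$info), 4), ", ", signif(max(x$info), 4),
      "]\n", sep = "")
  invisible(x)
}

#' Convert an IC result to a per-term table
#'
#' @param x An `"ic_result"`.
#' @param ... Unused.
#' @return Data frame with columns `term_id`, `A`, `beta`, `P`, `theta`,
#'   `I`, sorted by term id.
#' @export
as.data.frame.ic_result <- function(x, ...) {
  ids <- sort(x$graph$nodes)
  data.frame(term_id = ids, A = unname(x$graph$A[ids]),
             beta = unname(x$beta[ids]), P = unname(x$p[ids]),
             theta = unname(x$theta[ids]), I = unname(x$info[ids]),
             stringsAsFactors = FALSE)
}

#' Frequency distribution of information-content values
#'
#' Bins the per-term `I` values into half-open bins `[edge, edge + width)`
#' with edges at integer multiples of `bin_width`; the counts partition the
#' term set. Useful for choosing a selection threshold: on real data most
#' terms sit in a narrow band near zero and the slim size stabilises once
#' the threshold passes the bulk of the distribution.
#'
#' @param result An `"ic_result"`.
#' @param bin_width Positive bin width.
#' @return Data frame with columns `bin_lower`, `count`.
#' @export
ic_histogram <- function(result, bin_width) {
  stopifnot(inherits(result, "ic_result"),
            is.numeric(bin_width), bin_width > 0)
  idx <- floor(result$info / bin_width)
  tab <- table(idx)
  data.frame(bin_lower = as.numeric(names(tab)) * bin_width,
             count = as.integer(tab))
}
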