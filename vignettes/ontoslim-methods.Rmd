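---
title: "Generating data-driven ontology slims: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating data-driven ontology slims: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoslim)
```

## The problem

Large DAG-structured ontologies such as the Gene Ontology (GO) contain tens
of thousands of terms, most of them far more specific than any one analysis
needs. *Slims* are reduced, high-level subsets onto which detailed
annotations are collapsed, making annotation summaries readable and — because
far fewer terms are tested — making multiple-testing corrections far less
punishing in enrichment analysis. Slims are traditionally curated by hand.
`ontoslim` instead derives a slim *from the annotated dataset itself*: terms
are scored by an information-content metric that combines the annotation
mass they cover with a penalty for the structure that collapsing their
children would destroy, and the slim is the set of terms scoring above a
user-chosen threshold, completed with the ancestors needed to keep every
path to the namespace root intact.

Each namespace of the ontology (for GO: biological process, cellular
component, molecular function) is a rooted DAG over the transitive
relations `is_a` and `part_of`; other relation types (e.g. `regulates`) are
not transitive, so they are carried through file round trips untouched but
never traversed.

## The information-content metric

All computation happens on the **annotation-induced sub-graph** of a
namespace: the terms actually used in the dataset's annotations, plus every
term on any path from a used term back to the root. Each term $n$ carries a
direct annotation count $A_n$, the number of *distinct* gene products
annotated exactly to $n$ (no ancestor propagation; `NOT`-qualified records
are excluded because they assert non-membership). With $t$ terms in the
sub-graph and $\sum_{i=1}^{t} A_i$ the total direct count, each term is
scored

$$ I_n = P_n - \Theta_n $$

**Retained information.** $P_n = \lambda\,\beta_n / \sum_i A_i$, where
$\beta_n$ accumulates the annotation mass at and below $n$:

$$
\beta_n =
\begin{cases}
0 & n \text{ childless, } n \neq \text{root}\\[2pt]
A_n + \sum_{i \in \mathrm{children}(n)} \beta_i & \text{otherwise.}
\end{cases}
$$

The leaf-zero rule encodes that retaining a leaf in a slim buys nothing
beyond what its parent already summarises. A childless **root** is exempt
(it keeps $\beta = A$), so a one-term graph scores $P = 1$ at $\lambda = 1$
— the metric's attainable maximum. On a DAG, a multi-parent child
contributes its $\beta$ to *each* parent; this follows the summation
literally and means the $[-1, 1]$ range below is guaranteed only for trees.

**Collapse penalty.** With $\alpha$ the number of children of $n$ and $k$
the number of children of the *sub-graph's* root,

$$
\Theta_n =
\begin{cases}
0 & \alpha = 0\\[2pt]
\lambda \left[\sum_{i \in \mathrm{children}(n)}
  \frac{A_i + \beta_i}{\sum_j A_j}\right] \log_k(\alpha) & \alpha \ge 1,
\end{cases}
$$

with the conventions $\log_k(\alpha) = 1$ whenever $k = 1$, and
$\log_k(1) = 0$ for $k > 1$ (collapsing a single child loses no branching
structure, so it is unpenalised). The per-child score $(A_i + \beta_i)$ is
the child's full annotation mass — its own direct annotations plus
everything below it — which is what is lost from view when the child is
collapsed into $n$.

**Boundary values** (at $\lambda = 1$, the interpretable scale): a one-term
graph has $I = 1$; a two-term chain with an unannotated parent above a
fully annotated leaf has $P_\text{parent} = 0$ and, because $k = 1$ forces
$\log_k(\alpha) = 1$ and the child's score is $A/\!\sum A = 1$,
$\Theta_\text{parent} = 1$, hence $I_\text{parent} = -1$. These extremes
are what `scripts/acceptance.R` recomputes.

### Why the variant switches exist

The accumulation and penalty formulas admit several literal readings that
disagree on the boundary cases (a leaf-zero rule applied to a childless
root would force $P = 0$ on a one-term graph; a penalty score of $\beta_i$
alone would zero the two-term chain's penalty). The defaults above —
root-exempt leaf zeroing and the $(A_i + \beta_i)$ child score — are the
unique combination among the implemented variants that reproduces all
three boundary values simultaneously. The alternatives remain selectable
through `ic_config()` (`beta_variant`, `theta_child_score`) so their effect
can be measured rather than argued about:

```{r variants}
fx <- worked_example()
g <- build_namespace_graph(fx$document, "demo")
g <- attach_counts(g, count_direct_annotations(fx$annotations, "demo",
                                               aspect_map = fx$aspect_map))
as.data.frame(compute_information(g, ic_config(lambda_scale = 1)))
```

This five-term fixture (root `GO:0000001`; two intermediate terms; two
leaves, one with two parents through an `is_a` and a `part_of` edge; five
annotated genes) is frozen in code as `worked_example()` together with its
expected score table, so documentation and tests cannot drift apart.

### Parameters that matter

* **`lambda_scale`** ($\lambda$, default 100, dimensionless): pure
  rescaling, applied identically to $P$ and $\Theta$, so $I$ is linear in
  it. Raw ratios on sparse real ontologies are inconveniently small; 100
  is the conventional working scale. Use $\lambda = 1$ when you want the
  $[-1,1]$ interpretation.
* **`tau`** ($\tau$, default 0.3 at $\lambda = 100$): the selection
  threshold; terms with $I > \tau$ (strictly) enter the slim. Raising
  $\tau$ can only shrink the selected set — `ic_histogram()` shows where
  the bulk of the $I$ distribution sits and therefore how aggressive a
  given $\tau$ is.
* **`k`** is *not* tunable: it is read off the extracted sub-graph's root,
  not the full namespace, because the score is defined per sub-graph. A
  sub-graph whose root has one child therefore uses the $k=1$ convention.

## From scores to a slim, and back onto the data

1. **Selection**: $\{n : I_n > \tau\}$ per namespace, independently.
2. **Path closure**: all ancestors of selected terms are added, so every
   slim term has a complete in-slim path to the root (no orphans). We
   report selected and closure counts separately, since a "slim size" can
   reasonably mean either.
3. **Emission**: the slim is recorded in the OBO file itself as a
   `subsetdef:` header plus one `subset:` tag per member term, the
   standard subset idiom; `extract_slim_document()` can also produce a
   standalone slim ontology, rewiring each parent link to the nearest
   labelled ancestor (typed `is_a` only if some purely-`is_a` route
   exists, else `part_of`).
4. **Mapping**: every annotation term maps to the slim term(s) *closest*
   to it — each target reachable by some path whose interior contains no
   other slim term. All such targets are kept, including an ancestor of
   another target when distinct paths make both "nearest"; in the least
   informative case the target is the namespace root, so every gene
   product is guaranteed to retain at least one annotation after
   remapping. The search runs over (node, pure-`is_a`-so-far) states, so
   it is linear in the graph even when the number of distinct root paths
   is exponential; the test suite checks it against exhaustive path
   enumeration on small random DAGs.

Annotation sets are first **synchronized** against the ontology version:
alternative identifiers and `replaced_by` successors are substituted
automatically (chains followed to depth 5, a guard against pathological
cycles of obsolescence; deeper chains are quarantined with a flag),
`consider`-style suggestions are quarantined for supervised resolution
(advisory successors must not be applied blindly), and removed concepts
are dropped. The three outputs are complete GAF files that partition the
input exactly, so quarantined records can be hand-edited and re-merged.

## Enrichment on full versus slim vocabularies

`enrich()` performs the upper-tail hypergeometric test per term over
*direct* gene–term assignments (no ancestor propagation — the tested
vocabulary is the set of terms actually used, which matches how term
counts are usually reported; a closure-based population can be emulated by
remapping first). Corrections: Bonferroni is reported *uncapped*
($p \times m$), keeping the severity of a full-vocabulary correction
visible, while Benjamini–Hochberg is the standard capped step-up. Running
the identical code path on slim-remapped annotations shrinks $m$, and
every Bonferroni-corrected value shrinks by exactly $m_\text{slim}/m_\text{full}$
at fixed raw $p$ — this, not any change in the test, is the mechanism by
which slims buy statistical power.

## Synthetic fixtures

The generators exist so every stage is testable without downloading live
ontology releases. `generate_ontology()` grows each namespace as a rooted
DAG in which every non-root term takes 1–2 parents among earlier-generated
terms — acyclic by construction, no cycle-check loop — with `part_of`
edges at a configurable fraction (default 0.2, a rough reflection of how
`part_of` is the minority relation in real GO). `generate_annotations()`
samples terms per gene with weight $e^{\text{skew} \cdot \text{depth}}$
(default skew 0.8), emulating the leafward concentration of real
annotation; skew 0 gives uniform usage. Default sizes (60 terms, 40 genes,
3 annotations/gene) keep each randomized test case small enough that the
brute-force oracles (full path enumeration, unmemoized recursion,
exhaustive draw enumeration) stay exact and fast; the acceptance checks
run 100 such seeded graphs per property. `generate_obsolescence()` plants
a requested number of each of the five inconsistency classes on leaf
terms, using the leaf's parent as the alt-id host or successor so the
ground truth is always recoverable.

What these fixtures do **not** emulate: real GO's term-name semantics, its
depth profile beyond the single skew parameter, cross-namespace usage
imbalance, and curation artefacts such as co-annotation structure. Passing
tests therefore demonstrate correctness of the algorithms under the stated
model, not that any particular published slim will be reproduced —
published slim sizes also depend on the archived ontology and annotation
revisions they were computed from.

## Numerical and degenerate-input choices

* `I = P − Θ` is computed as exactly that subtraction; the identity holds
  to machine precision by construction and is asserted, not approximated.
* A namespace with zero annotations has no defined $P$; scoring it is an
  explicit error, while `build_slim()` skips such a namespace with a
  warning (an annotation file legitimately may not cover all namespaces).
* Annotation counts on terms absent from the graph are an error rather
  than being silently dropped — it is the signature of an
  unsynchronized annotation set.
* Histogram bins are half-open `[edge, edge + width)` with edges at
  multiples of the width, so counts always partition the term set.
* Ties at the threshold are excluded (`I > τ` is strict).
* OBO emission sorts term stanzas by id and subset definitions by name, so
  output is deterministic and `write -> parse -> write` is byte-stable.

## Known limitations

* The $[-1, 1]$ range of $I$ at $\lambda = 1$ is a theorem for trees in
  which no node has more children than the root; on DAGs, multi-parent
  children are counted once per parent and scores can leave that range.
  This is documented behaviour, not an error.
* `consider`-based obsolescence (classes 3 and 4) is never auto-resolved;
  that is a design position, not a missing feature.
* Only `is_a` and `part_of` are traversed; ontologies whose semantics
  hinge on other transitive relations would need those added to the
  parser's traversal set.
* GAF column 16 (annotation extensions) is preserved verbatim but its
  semantics are ignored.
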