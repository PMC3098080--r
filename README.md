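# ontoslim

Automatic, data-driven generation of ontology slims.

Ontology *slims* are reduced, high-level subsets of a DAG-structured
ontology (such as the Gene Ontology) onto which detailed annotations are
collapsed. They make annotation summaries readable and — because far fewer
terms are tested — greatly soften multiple-testing corrections in
enrichment analysis. Slims are traditionally curated by hand; `ontoslim`
derives one objectively from an annotated dataset, so the slim reflects the
terms the data actually uses. It is aimed at anyone maintaining annotated
gene-product datasets: it also keeps old annotation files current as the
ontology evolves, and runs enrichment on either the full or the slimmed
vocabulary.

## The core metric

Every term *n* of a namespace's annotation-induced sub-graph is scored

```
I_n = P_n − Θ_n
```

* `P_n = λ·β_n / ΣA` — the annotation mass retained if *n* stays:
  `β_n` is 0 for childless non-root terms (a leaf adds nothing beyond its
  parent) and otherwise `A_n + Σ β_child`, where `A_n` counts the distinct
  gene products annotated directly to *n*.
* `Θ_n = λ · [Σ_child (A_i + β_i)/ΣA] · log_k(α)` — the information lost
  if the `α` children of *n* are collapsed into it, with `k` the root's
  child count (`Θ_n = 0` for leaves; `log_k := 1` when `k = 1`;
  `log_k(1) := 0` otherwise).

Terms with `I > τ` are selected, ancestors are added so every path to the
root is complete, the slim is written into the OBO file as a
`subsetdef:`/`subset:` subset, and each original annotation is mapped to
its *nearest* slim term(s), with the mapped relation typed `is_a` or
`part_of` from the edges along the path. At `λ = 1`, `I` spans `[−1, 1]`
on trees: a one-term graph scores +1, an unannotated parent over a fully
annotated leaf scores −1.

Before scoring, annotation files are synchronized against the current
ontology version: alternative ids and `replaced_by` successors are
substituted automatically, obsolete terms with only advisory `consider`
successors are quarantined for supervised resolution, and removed concepts
are dropped — the three outputs partition the input exactly.

## Worked example

The package ships a frozen five-term fixture (`worked_example()`): root
`GO:0000001` with children `GO:0000002` and `GO:0000003`; `GO:0000004` has
both an `is_a` parent (`GO:0000002`) and a `part_of` parent (`GO:0000003`);
`GO:0000005` is a second leaf under `GO:0000002`. Five genes annotate it.

```r
library(ontoslim)
fx <- worked_example()
g  <- build_namespace_graph(fx$document, "demo")
g  <- attach_counts(g, count_direct_annotations(fx$annotations, "demo",
                                                aspect_map = fx$aspect_map))
as.data.frame(compute_information(g, ic_config(lambda_scale = 1)))
#>      term_id A beta   P theta    I
#> 1 GO:0000001 0    2 0.4   0.8 -0.4
#> 2 GO:0000002 1    1 0.2   0.6 -0.4
#> 3 GO:0000003 1    1 0.2   0.0  0.2
#> 4 GO:0000004 2    0 0.0   0.0  0.0
#> 5 GO:0000005 1    0 0.0   0.0  0.0
```

Reading the table: the two leaves score 0 (nothing is retained by keeping
a leaf, nothing lost by collapsing below it — it has no children).
`GO:0000003` scores +0.2: it retains a fifth of the annotation mass and
pays no penalty because collapsing its single child is free
(`log_2(1) = 0`). The root and `GO:0000002` score −0.4: each retains mass
but would destroy a two-way branch covering most of the data. At
`τ = 0.1` only `GO:0000003` is selected, and the root joins by path
closure:

```r
slim <- build_slim(fx$document, fx$annotations, ic_config(lambda_scale = 1),
                   tau = 0.1, name = "goslim_demo", aspect_map = fx$aspect_map)
slim
#> <slim_definition> 'goslim_demo' at I > 0.1
#>   demo: 1 selected + 1 closure = 2 terms

frag <- slim$namespaces$demo
slim_map_table(map_annotations(frag$graph, frag, frag$used_terms))
#>   source_term  slim_term relation
#> 1  GO:0000002 GO:0000001     is_a
#> 2  GO:0000003 GO:0000003     is_a
#> 3  GO:0000004 GO:0000001     is_a
#> 4  GO:0000004 GO:0000003  part_of
#> 5  GO:0000005 GO:0000001     is_a
```

`GO:0000004` maps to *two* slim terms — `GO:0000003` through its `part_of`
path and the root through its pure-`is_a` path — illustrating that every
nearest slim term on every path is kept, with the relation typed from the
edges traversed. `remap_annotation_set()` then rewrites a GAF onto these
targets, and `enrich()` runs the hypergeometric test (uncapped Bonferroni
and Benjamini–Hochberg corrections) on either vocabulary.

## Command line

A thin wrapper (`exec/ontoslim`) exposes the pipeline as subcommands:

```sh
ontoslim simulate --terms 60 --genes 40 --seed 7 --out-obo onto.obo --out-gaf ann.gaf
ontoslim sync     --obo onto.obo --gaf old.gaf --out-updated u.gaf \
                  --out-quarantine q.gaf --out-dropped d.gaf --report sync.json
ontoslim slim     --obo onto.obo --gaf ann.gaf --tau 0.3 --lambda 100 \
                  --name goslim_auto --out-obo slim.obo --out-mapping map.tsv
ontoslim map      --mapping map.tsv --gaf ann.gaf --out slim.gaf
ontoslim enrich   --gaf ann.gaf --study study.txt --namespace biological_process \
                  [--mapping map.tsv] --out enrich.tsv
ontoslim compare  --slim-a a.txt --slim-b b.txt
```

## Documentation

The methods vignette (`vignettes/ontoslim-methods.Rmd`) derives the metric,
explains the variant switches and boundary conventions, documents the
synthetic-fixture model and what passing tests do and do not show about
real data, and lists known limitations.
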