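# bioevex

Corpus-agnostic biomedical **event extraction** over dependency-parsed
interaction graphs, for text-mining researchers working with BioNLP
Shared Task style corpora and for anyone who needs to learn the
annotation rules of an event corpus automatically.

Biomedical events are typed n-ary relations anchored to trigger words —
`Phosphorylation(Theme: STAT3, Cause: JAK2, Site: Tyr705)` — whose
arguments may themselves be events. bioevex represents all such
annotation in one graph: entities and triggers are nodes bound to their
syntactic head tokens, relations and event arguments are typed directed
edges, and an event is a trigger node plus a subset of its outgoing
edges. On top of that representation the package provides:

* **Standoff ↔ graph conversion** — lossless reading/writing of the
  `.txt`/`.a1`/`.a2` standoff triplet and an Interaction XML corpus
  format, including equivalence-group expansion, the unified
  Site/SiteParent/`siteOf` representation of site arguments, and
  recursive duplicate-event removal on the way back.
* **Annotation scheme induction** — `learn_scheme()` deterministically
  learns, from any annotated corpus, the entity/relation/event/modifier
  definitions with per-role and overall argument-count limits
  `[min,max]`, licensed target types, site primary roles and prediction
  targets; `is_valid_edge()` / `is_valid_event_structure()` answer the
  structural-validity queries that drive candidate filtering.
* **The four-step extraction pipeline** — entity detection → recall
  adjustment (a multiplier `beta ∈ [0,1]` on the negative-class
  confidence) → edge detection → unmerging (pulling merged events apart
  by classifying structurally valid argument subsets) → modifier
  detection, with pluggable classifier back-ends (sparse multinomial
  logistic regression, random forests with impurity feature
  importances, and an always-correct oracle for component ablation).
* **Evaluation and diagnostics** — micro-averaged event-level F with
  recursive argument matching, ablation tables, scheme-driven
  validation and repair of standoff output, a synthetic corpus
  generator covering nesting, shared triggers, sites, equivalences,
  modifiers and cross-sentence arguments, and a GraphViz dot exporter
  for sentence annotation graphs.

Results come back as tibbles with `tidy()` / `glance()` / `autoplot()`
methods, so they drop into ordinary dplyr/ggplot2 workflows.

## Worked example

Generate a small gold corpus, learn its annotation scheme, and measure
the all-oracle extraction ceiling:

```r
library(bioevex)

g <- generate_corpus(generator_spec(n_documents = 30, seed = 1,
                                    site_rate = 0.5, nesting_rate = 0.3))
scheme <- learn_scheme(g$corpus)
scheme
#> # annotation scheme v1
#> ENTITY   Entity
#> ENTITY   Protein
#> EVENT    Binding [1,4]          Site {Theme} [0,2] Entity / Theme [1,2] Protein
#> EVENT    Gene_expression [1,1]  Theme [1,1] Protein
#> EVENT    Phosphorylation [1,3]  Cause [0,1] Protein / Site {Theme} [0,1] Entity / Theme [1,1] Protein
#> EVENT    Regulation [1,2]       Cause [0,1] Protein / Theme [1,1] Binding, Gene_expression, Phosphorylation, Protein, Regulation
#> RELATION SiteParent, directed   Arg1(Entity) / Arg2(Protein)
#> MODIFIER negation               Binding, Gene_expression, Phosphorylation
#> MODIFIER speculation            Binding, Phosphorylation, Regulation
#> TARGET   ENTITY                 Binding, Entity, Gene_expression, Phosphorylation, Regulation
#> TARGET   INTERACTION            Cause, Site, SiteParent, Theme
```

Each `EVENT` row reads: overall argument-count limits after the type,
then per role `Role {site primary roles} [min,max] licensed targets`.
`Binding [1,4]` with `Theme [1,2]` and `Site {Theme} [0,2]` means a
Binding carries one or two Themes, up to two Sites whose primary
argument must be a Theme, and one to four arguments in total — all
induced from the corpus, not hand-written.

The generated documents are ordinary standoff files:

```r
out <- write_st_document(g$st_documents[[1]])
cat(out$a2, sep = "\n")
#> T5  Regulation 0 9  regulates
#> T6  Gene_expression 16 26   expression
#> T7  Phosphorylation 39 53   phosphorylates
#> E1  Regulation:T5 Theme:T1
#> E2  Gene_expression:T6 Theme:T2
#> E3  Phosphorylation:T7 Cause:T3 Theme:T4
```

Running the pipeline with the always-correct oracle at every step
measures the ceiling imposed by the representation itself (100% here
because the corpus has no cross-sentence arguments):

```r
b <- oracle_bundle(scheme)
pred <- predict_corpus(g$corpus, b,
                       oracle_steps = c("entity", "edge", "unmerging",
                                        "modifier"))
gold <- lapply(g$corpus$documents, graph_to_st, scheme = scheme)
evaluate_micro_f(pred$st_documents, gold)
#> <event_eval event> P 100.00 / R 100.00 / F 100.00 (matched 123, spurious 0, missed 0)
```

The matched/spurious/missed counts are event-level: an event counts as
matched only if its type, trigger span and all arguments — recursively,
with roles — agree with a gold event. Training real models instead of
the oracle is `train_pipeline(train, devel, pipeline_config())`;
swapping only some steps to the oracle (`ablate_components()`) shows how
much each learned component costs.

A thin command-line front end (`exec/bioevex`) exposes `train`,
`classify`, `learn-scheme`, `convert`, `evaluate`, `ablate`,
`visualize` and `generate` subcommands over the same functions.

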