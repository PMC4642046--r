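---
title: "Graph-based biomedical event extraction: model, scheme induction and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based biomedical event extraction: model, scheme induction and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioevex)
```

## The model

Biomedical events are typed n-ary relations anchored to a trigger word:
`Phosphorylation(Theme: STAT3, Cause: JAK2, Site: Tyr705)` is one event,
and arguments may themselves be events (`Regulation(Theme: <that
Phosphorylation>)`), producing nested structures. bioevex represents all
such annotation as a graph bound to a dependency-parsed sentence: named
entities and triggers are nodes (each bound to one token, the syntactic
head of its span), and binary relations and event arguments are typed,
directed edges. A single event is a trigger node plus a subset of its
outgoing edges; when several events share a trigger the graph holds the
*merged* union of their argument edges, and a separate record of event
memberships keeps the grouping recoverable.

Extraction is decomposed into four consecutive multiclass classification
steps over this graph:

1. **Entity detection** — one example per token not already covered by a
   given entity; classes are node types, with overlapping nodes handled as
   merged classes (`Phosphorylation---Regulation`) that are split after
   classification.
2. **Edge detection** — one example per candidate node pair; classes are
   edge types. Candidates are restricted to pairs between which the
   annotation scheme licenses at least one edge type, which removes the
   bulk of the can-only-ever-be-negative examples (about two thirds under
   the synthetic study conditions; the reduction is reported by
   `edge_filter_stats()`).
3. **Unmerging** — one example per trigger node per *structurally valid*
   subset of its outgoing argument edges; a binary classifier decides
   which subsets are real events, pulling merged events apart.
4. **Modifier detection** — one example per trigger of a
   modifier-capable type, classifying negation/speculation.

Between steps 1 and 2 sits **recall adjustment**: the negative-class
confidence of every entity prediction is multiplied by a parameter
`beta` in `[0, 1]` and the argmax recomputed. `beta = 1` is the identity
and `beta = 0` forces every token to its best positive class, so the
number of predicted nodes is non-increasing in `beta` — a dial that
trades entity precision for downstream event recall, tuned against
development-set performance rather than entity-step accuracy.

## Automatic annotation scheme learning

The rules that earlier systems hard-coded per corpus are induced from the
data by `learn_scheme()`, a fully deterministic, rule-based pass over a
gold corpus (conventionally train plus devel). Five definition kinds are
learned:

* **Entities** — node types that never carry the event flag and never
  have outgoing event-argument edges. (Relation edges do not make their
  source an event: anaphora with outgoing coreference links stay
  entities.)
* **Events** — node types with the event flag or outgoing argument
  edges. Every trigger node carries the event flag even when the event
  takes no arguments, so zero-argument event types are learned as events
  with overall limits `[0,0]` rather than misclassified as entities.
* For each event type, per-role argument-count intervals `[min,max]`,
  the licensed target types per role, and **overall** argument-count
  limits (the observed extremes of instance totals), so an event whose
  arguments are all individually optional can still be required to have
  at least one argument.
* **Relations**, with directedness, end roles and endpoint type sets.
* **Modifiers** and **prediction targets** (everything not `given`).

Site arguments get a unified representation: the Site edge attaches to
the trigger like any other argument, a `SiteParent` relation links the
site entity to its protein, and on gold data a `siteOf` attribute on the
Site edge names its primary argument's edge. `siteOf` is what lets the
learner record *which* roles may carry a site (`Site {Theme}`), including
the self-regulation case where Cause and Theme point at the same protein
and SiteParent alone cannot disambiguate. On predicted data, where
`siteOf` does not exist, conversion back to standoff attaches each site
through its SiteParent link to the primary argument whose protein occurs
first in document order, attaches each site to at most one primary,
discards a site when its primary already has one, and removes events made
identical by these operations recursively until none remain (the event
count strictly decreases, so the recursion terminates). The companion
repair procedure `validate_and_repair()` makes any standoff document
scheme-valid by renaming a single invalid argument to a missing required
role when both conditions hold, else removing invalid arguments, else
removing the event, and finally removing events that reference removed
events, recursively.

A learned scheme is "reverse engineered" from the corpus and may be
stricter than the official guidelines: if a corpus never shows a Binding
with three Themes, the learned maximum is two. No relaxation mechanism is
provided — the learned scheme is exactly the observed annotation
behaviour.

## Features

All steps share a sparse binary feature vocabulary built from the parse
(collapsed dependency scheme) and the token stream. Naming conventions,
with the defaults in parentheses:

* token (`txt_`, `POS_`) and subtoken features: a suffix-stripping stem
  (`stem_`), lowercase character duplets `dt_` and triplets `tt_`;
* linear context at signed offsets within ±3 tokens (`linear_-1_txt_…`);
* dependency context by breadth-first distance ≤ 3 (`dist_2_POS_…`,
  `dist_3_annType_Protein`), direction-annotated label chains
  (`chain_dist_dist_2-rev_appos…`) and head-out dependencies
  (`t1HOut_neg_RB`);
* shortest undirected dependency path between the two heads of an edge
  candidate: per-step labels with traversal direction
  (`dep_Reverse_dobj`), position-coded path tokens
  (`tok_FFtxt_phosphorylation`), a whole-path signature (`tokenPath_…`),
  label n-grams of length 2–4, bucketed path length, and a `noPath`
  indicator when the tokens are disconnected;
* unmerging examples combine role-prefixed edge features of the included
  arguments (`argTheme_dep_Reverse_prep_of`), trigger features under
  `trg_`, a bag of words over the event's linear span, dependency labels
  leaving that span (`context_dep_`), and argument-count features
  (`numArgs_2`, `numTheme_2`) — without the counts, a two-Theme subset
  and its one-Theme restriction to the farther Theme can be feature-wise
  identical;
* modifier examples add matches against a small configurable speculation
  word list (`spec_word_possibly`; see `speculation_words()`).

The exact surface codes follow the conventions sketched above rather
than any external system byte-for-byte; where a code's semantics were
open (duplets/triplets, chain syntax), the interpretation implemented
here is the one documented in this section. Feature values are binary
presence; counts are never accumulated. Among equally short dependency
paths the one with the lexicographically smallest label sequence is
taken, and merged classes join their alphabetically sorted members with
`---` (types themselves may contain hyphens, so a bare hyphen would be
ambiguous). The feature space is frozen at training time: names unseen
then are ignored at prediction time, never appended.

## Classifiers

No learning algorithm is implemented here; classification goes through a
pluggable adapter contract (`classifier_adapter()`) with three shipped
back-ends:

* `adapter_glmnet()` — sparse multinomial logistic regression; the
  default trainable step classifier. Its regularization `lambda` is the
  tuned hyperparameter, searched on a log grid (default `10^(-3..0)`,
  the scale at which a ridge-penalized linear model on these binary
  features moves from interpolation to heavy shrinkage). Fits run along
  a decreasing lambda path for convergence, and classes observed only
  once are duplicated so no observed class is unlearnable.
* `adapter_forest()` — a probability forest whose impurity importances
  (total decrease in node impurity averaged over trees) drive
  `rank_feature_importances()`, the per-group importance report
  (`tidy()` gives quartile summaries per feature group, `autoplot()` the
  box plot).
* `adapter_oracle()` — returns the annotated class with confidence 1,
  and errors on unlabelled examples. Replacing any subset of pipeline
  steps with the oracle (`ablate_components()`) measures how much each
  learned component contributes and what the ceiling of the remaining
  ones is.

Recall adjustment is implemented as multiplicative scaling of the
negative-class score. Multiplication is chosen over subtraction because
it is invariant to the score scale of the back-end (decision values and
probabilities behave alike) and gives exact identity/extreme endpoints
at `beta` 1 and 0. `tune_parameters()` grids hyperparameters × beta;
ties resolve toward the largest beta, then the smallest regularization
value, then grid order, so re-runs are reproducible. Beta can be tuned
against entity-step micro-F (`objective = "step"`) or, by default,
against end-to-end event F on the development corpus
(`objective = "event"`), since the entity threshold only matters through
the events it enables.

## Evaluation

`evaluate_micro_f()` implements micro-averaged precision/recall/F,
reported as percentages to two decimals. At event level, events match on
type, exact trigger span, and recursively matched arguments with roles —
a mismatched child fails its parent — after expanding equivalence groups
on both sides, which makes the comparison invariant to whether a
document stores an equivalence group collapsed or expanded. Example-level
mode pools counts over all positive classes. Approximate-span matching
(the relaxations of official evaluators) is deliberately not the
default; the synthetic data has exact spans, and relaxations would only
mask alignment bugs.

## The synthetic study conditions

`generate_corpus()` realizes gold corpora from templated
subject-verb-object sentences with simple projective parses, so the
whole pipeline is testable without external data or a parser. The
generator's defaults are the package's reference conditions: documents
of 2 sentences, 1–2 events per sentence over the GENIA-flavoured
`demo_scheme()` (given Proteins; predicted Entity sites; four event
types covering required/optional/multiple arguments, sites with Theme
primaries, and event-valued nesting), nesting probability 0.25 per
eligible slot, shared-trigger rate 0.15, equivalence rate 0.1, site rate
0.3, negation/speculation rates 0.1, and no cross-sentence arguments
unless requested. Entity mentions draw from small cycling name pools
(ten protein names, five site names) so lexical features generalize
across mentions instead of memorizing one-off strings. Cross-sentence
arguments, when enabled, are realized as a pronoun token whose
annotation points into the preceding sentence — the argument edge is
flagged and excluded from example generation, which is exactly what
makes the all-oracle ceiling computable in closed form from
reachable-event counts: with `n` gold events of which `k` are
unreachable, oracle precision is 1 and the ceiling is
`2(n−k)/(2n−k)`.

A saturation mode ignores the rates and deterministically realizes every
constraint boundary of the generating scheme — per-role minima and
maxima, overall extremes, every licensed target type, every site
primary role, every modifier target, standalone mentions of every
entity type — which is what makes `learn_scheme()` provably able to
recover a scheme exactly, and what the recovery tests exercise over
random schemes. `perturb_predictions()` injects controlled structural
errors (role corruption, dropped/extra arguments, duplicated events,
multi-parent SiteParent links) to drive the evaluator and repair tests.

What the generator does **not** emulate: natural lexical variety,
attachment ambiguity from real parses, parse errors, discontinuous or
multi-token entity spans (every mention is one token, so exact-span and
head-token matching coincide), and annotation noise. Passing tests
therefore demonstrate the *mechanics* — conversions, filtering,
enumeration, validation, tuning — not performance on real corpora.
Two inherent ambiguities of the representation do appear and are worth
knowing about: a sentence like "binds A and B" is surface-identical as
one two-Theme event or two one-Theme events sharing a trigger, and an
event with two sites over two themes pairs them arbitrarily. Test
conditions asserting perfect trained performance exclude these
(shared-trigger rate 0, single-site events); conditions measuring
realistic behaviour include them and expect F below 100.

## Numerical and design notes

* Offsets are 0-based half-open, sentence-scoped in the graph with
  explicit sentence-to-document offsets; the standoff side is
  document-scoped and the conversion is a plain shift.
* Head selection for a multi-token span: among overlapping tokens,
  prefer those none of whose governors lies inside the span (a parse
  root qualifies); of several, take the rightmost; if a dependency cycle
  leaves none, take the rightmost overlapping token. The rule is a
  deterministic stand-in close to common head-percolation practice.
* Standoff writing renumbers deterministically — `T` records by (given,
  start, end, type), `E` records topologically so arguments precede the
  events referencing them — so diffs are stable and reading back
  recovers the document up to renumbering.
* Modifier flags live on trigger nodes. A gold corpus in which two
  events share a trigger but differ in negation cannot be represented
  node-level; the generator applies modifiers per trigger, and the
  conversion emits one `M` line per surviving event on a flagged
  trigger (equivalence-expanded copies each get one, matching the
  expand-then-collapse invariant).
* Unmerging enumeration is capped (default 1024 subsets per trigger);
  beyond the cap the first edges in deterministic id order are kept with
  a warning. Triggers whose subsets are all classified negative are
  dropped together with their now-dangling edges, which preserves
  precision and guarantees the emitted standoff validates with an empty
  repair log.
* Relations whose endpoint is an event trigger (or an event id) cannot
  be represented distinctly from the event in the graph and are skipped
  at load with a logged warning, retrievable via `conversion_log()`.
* Problem sizes in the shipped tests and in `scripts/acceptance.R` —
  1000 documents for round-trip integrity, 20 random schemes for
  recovery, roughly 500 sentences for the filter-equivalence checks,
  corpora of 10–60 documents elsewhere — were chosen once as the
  smallest sizes at which every structural phenomenon occurs repeatedly.

## Limitations

Beyond the generator's idealizations above: the pipeline is strictly
intra-sentence (cross-sentence gold is preserved in the data model and
quantified in the ceiling, never predicted); ontology-scale label sets
and multi-token entity boundary detection are out of scope; and the
standoff dialect implemented is the tab-separated `T`/`E`/`R`/`M`/Equiv
core — task-specific extensions beyond it are not parsed.
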