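---
title: "Assessing ontology alignments: references, top-level hierarchies, and consensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing ontology alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontalign)
```

## The problem

Biomedical data sources annotate their records with different ontologies —
one registry may code a rare disease in ORDO, another in SNOMED CT, a third
in the NCI Thesaurus. Querying across such sources requires *alignments*:
sets of mappings, each a triple ⟨e, e′, r⟩ linking a class e of ontology O
to a class e′ of O′ by a relation r (here, equivalence), optionally with a
confidence. Automated matching systems produce such alignments, but their
quality must be assessed, and complete gold standards do not exist for
large clinical terminologies. This package implements an assessment
toolbox built around three ideas:

1. **Reference-based scoring.** An alignment A is compared with a
   (possibly incomplete) reference alignment R by classifying each mapping
   over (source, target) identity: TP = A ∩ R, FP = A ∖ R, FN = R ∖ A,
   then precision = TP/(TP+FP), recall = TP/(TP+FN), and the F-measure as
   their harmonic mean. True negatives are never computed — no reference
   enumerates all correct mappings. Two kinds of references are supported:
   a *silver standard* built from UMLS Concept Unique Identifiers (every
   cross-ontology class pair sharing at least one CUI becomes a reference
   mapping) and any externally supplied alignment file (e.g. a
   BioPortal/LOOM lexical baseline), which is typically highly incomplete.

2. **Top-level hierarchy consistency.** Matchers lean heavily on lexical
   similarity and therefore mate classes such as *Aneurysmal Bone Cyst*
   (a disease) with *Aneurysmal bone cyst (morphologic abnormality)* (a
   body structure). Because even very large ontologies have few top-level
   classes (SNOMED CT and NCIt both have 19), the pairs of semantically
   equivalent top-level classes can be curated by hand. A mapping is then
   *hierarchy-consistent* when some pair formed from the top-level
   ancestors of its two classes is in that curated set. Inconsistent
   mappings that are a true positive of **no** available reference are
   discarded and precision/F-measure recomputed; mappings that any
   reference confirms are kept regardless. This works with *no* reference
   at all (then it is purely descriptive) and guarantees two properties
   that the test suite asserts on every run: recall is unchanged by
   filtering, and precision never decreases.

3. **Consensus voting.** Mappings proposed by at least k of n matchers
   form the vote-≥k consensus alignment; raising k trades recall for
   precision.

Around these sit the supporting stages: a rooted-DAG ontology model with
readers for an RDF/XML OWL dialect and a TSV fixture dialect, Alignment
API RDF input/output, seed-signature module extraction, and report
generation.

## The ontology model and its deliberate limits

An `ontology()` is a rooted DAG of named classes with labels, synonyms,
and CUI annotations. Only subclass-of edges are modelled: every procedure
in the package consumes the class hierarchy, labels, and CUIs, so object
properties, equivalence axioms, and complex class expressions are ignored
by the OWL reader. Multiple inheritance is allowed (SNOMED CT relies on
it); `ancestors()` is a transitive closure over the DAG, not a tree walk.
Files with several parentless classes get a synthetic root so that every
class has at least one top-level ancestor; a top-level class is its own
top-level ancestor, so directly mapped top-level pairs classify as
consistent. Loading rejects cycles and duplicate identifiers outright
rather than repairing them.

Module extraction follows hierarchy semantics over this DAG: *top* = seed
plus descendants, *bottom* = seed plus ancestors, *star* = the
intersection of the two class sets, with the root always retained and
orphaned classes re-attached to it so a module is itself a valid
ontology. True syntactic-locality modules are defined over full axiom
semantics and computed as a fixpoint of alternating top/bottom
extractions; this package implements the plain hierarchy reading
(intersection, single pass), which is what the downstream evaluation
needs, and extends seeds with all ancestors (`extend_seed_with_ancestors()`)
so the whole top-level hierarchy is present in a module. Property-style
tests assert star ⊆ top, star ⊆ bottom, seed ⊆ module, and monotonicity
in the seed on random DAGs.

## Decisions where the design was genuinely open

* **Undefined scores are `NA`, not 0.** Precision of an empty alignment
  (or recall against an empty reference) is reported as a distinct
  undefined marker; scoring it 0 would silently corrupt aggregated means.
  `aggregate_means()` excludes the markers and says how many it dropped.
* **Mean-of-scores aggregation.** Group summaries average the
  per-alignment scores rather than re-scoring pooled counts, matching how
  mean results per ontology pair or per matcher are usually reported.
* **Mapping identity ignores confidence and orientation.** Matching A to
  B is equivalent to matching B to A, so `normalize_alignment()`
  reorients everything to a fixed pair order first, drops non-equivalence
  relations, and collapses duplicates keeping the maximum confidence;
  voting then counts (source, target) pairs only. Confidence thresholds
  are never applied anywhere — matchers are assessed on what they output
  under their default configuration — and 1:n/n:1 mappings are retained.
* **Existential consistency rule.** With multiple inheritance a class can
  have several top-level ancestors; a mapping counts as consistent when
  *any* ancestor pair is curated as equivalent. This is the conservative
  choice: a mapping with one plausible category match is never discarded.
* **Unresolvable mappings are a separate bucket.** A mapping whose class
  is missing from the supplied ontology (version skew, truncated module)
  is reported as unresolvable, not silently classified.
* **Rounding for reports.** Scores print to two decimals and percentages
  to the nearest integer — except values below 1%, which keep one decimal
  (a 0.4% module would otherwise print as 0%). Ties round away from zero
  (`round_half_up()`); raw floating-point values stay on the R objects.

## What the synthetic generator emulates — and what it does not

The licensed inputs of a real assessment (SNOMED CT, NCIt distributions,
the UMLS Metathesaurus) cannot be shipped, so `generate_scenario()`
builds scenarios that reproduce the *statistical shape* of the task. The
defaults are chosen once to mirror that shape: 19 top-level categories
per ontology (the SNOMED CT/NCIt count), 13 of 19 category pairs
manually matched (the size of the curated NCIt–SNOMED CT top-level
mapping set), 40 classes per category in trees up to depth 4 with a few
multi-parent diamond edges, half the classes of each matched category
shared with the other ontology, CUI coverage 0.85 of shared concepts (a
silver standard is incomplete), simulated matcher recall 0.66 and 200
planted false mappings (yielding precision near 0.5, the regime reported
for real matchers on these pairs), a fifth of them cross-category.

Two generator choices are made for testability. The fraction γ of planted
false mappings that join *unmatched* category pairs is applied as an
exact count (round half up), not by per-mapping sampling, so the
hierarchy filter's behaviour on a scenario is exactly predictable: all
and only the cross-category plants are flagged, because same-category
plants share a matched top-level pair by construction. And every
generator is a pure function of (configuration, seed), so scenarios are
reproducible element for element.

What the generator does **not** model: lexical matching itself (matcher
errors are planted at the error-rate level; labels exist, including
case-variant near-duplicates, but play no computational role), reference
incoherence (degraded references are Bernoulli thinnings of the ground
truth, never *wrong*), classes whose CUI sets overlap by accident, and
top-level category sets of very different granularity. Passing tests
therefore demonstrate the correctness of the machinery — set algebra,
traversals, score arithmetic, filter guarantees — not that any particular
real matcher will achieve particular scores on real terminologies.

## Numerical and scale choices

Problem sizes are kept modest so the whole suite runs in well under a
minute of CPU: property tests use random DAGs of at most 50 nodes checked
against a brute-force reachability oracle, classification is compared
with a set-algebra oracle on a thousand random alignment pairs of up to
100 mappings, and the parameter-recovery check plants 2,000 ground-truth
mappings (10 categories × 400 classes at 50% sharing) so that measured
recall can be tested against the exact binomial 99% interval around the
configured recall while precision equals tp/(tp + planted) exactly.
Alignment files are written deterministically (mappings sorted by source
then target, confidences serialized at full precision) so reruns are
byte-identical and outputs diffable; the pipeline writes a manifest of
input digests for the same reason.

## Known limitations

* The OWL reader handles the RDF/XML named-class dialect only — no
  reasoning, no OWL profile validation, no property hierarchies, no
  Turtle/functional syntax.
* Star modules are hierarchy intersections, not locality-based modules;
  no self-containment of entailments is guaranteed.
* The curated top-level mapping table is itself a judgment call and may
  be incomplete; the filter inherits any of its blind spots, and
  top-level pairs cannot be discovered automatically.
* Semantic precision/recall (crediting mappings that are close to, but
  not identical with, a reference mapping) is out of scope; a mapping
  absent from the reference is a false positive by definition.
* Reference mappings confirmed as true positives are never questioned,
  even when their top-level hierarchies disagree — such cases are worth
  reporting to the reference maintainers, not silently removing.

## A worked example

```{r example, eval = FALSE}
library(ontalign)

cfg <- synthetic_config(seed = 7)
scenario <- generate_scenario(cfg)
pair <- c("ONTA", "ONTB")

al <- normalize_alignment(simulate_matcher(scenario, cfg, seed = 8), pair)
silver <- normalize_alignment(
  build_cui_reference(scenario$cui_a, scenario$cui_b), pair)

evaluate_alignment(al, silver)

analysis <- analyze_alignment(al, scenario$ontology_a, scenario$ontology_b,
                              scenario$top_level_mappings)
analysis
rr <- filter_and_reevaluate(al, analysis, list(silver = silver))
rr$summary
```
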