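---
title: "Mining class-association rules for metabolic pathway annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining class-association rules for metabolic pathway annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathwayrules)
```

## The problem

Manually curated protein databases annotate only a fraction of known
prokaryotic proteins with the metabolic pathways they participate in,
while the volume of uncharacterised sequence grows much faster than
curation can follow. `pathwayrules` learns *class-association rules* from
the annotated fraction — implications whose antecedent is a set of
protein attributes (InterPro signature identifiers and taxonomic lineage
nodes) and whose consequent is a single pathway label — and aggregates
the best rules into per-pathway prediction models that can be applied to
unannotated entries.

Each protein entry is converted to a *transaction* of namespaced items:
one `TAXON:<name>` item per lineage node (most general first), one
`IPR:<id>` item per InterPro signature, and one `PATHWAY:<label>` item
per evidenced pathway annotation. Pathway labels are hierarchical
strings, `super-pathway; pathway; sub-pathway: step i/n`; the *full*
canonical string (step suffix included) is the prediction target, and the
hierarchy is used only when comparing predictions against another
system's annotations (identical / similar / distinct).

Only manually asserted annotations enter learning: a pathway annotation
is kept when its evidence set intersects the six ECO codes for manual
assertion (experimental evidence, non-traceable author statement,
curator inference, sequence similarity, sequence model, combinatorial
evidence), and entries left without pathway annotations are dropped.
Entries that keep annotations but carry no attributes still count in the
database size N — N is defined as the number of transactions, and such
entries legitimately dilute relative support even though they can never
fire or support a rule.

## Rule mining

Mining is level-wise Apriori restricted to the class-association shape:
antecedents contain only attribute items, consequents are single pathway
items (every published model clause has this shape). Defaults follow the
reference parameterisation:

| parameter | default | meaning |
|---|---|---|
| `min_support_abs` | 20 | minimum antecedent support, absolute transactions |
| `min_conf` | 1.0 | minimum confidence; only exact rules are kept |
| `max_size` | 4 | maximum antecedent size |
| `ref_min_count` | 20 | reference-set threshold for evaluation |

Rule *support* uses the antecedent-support convention: `supp(R) =
supp(X)`, the number of transactions in which the rule is applicable.
Confidence is `supp(X ∪ Y)/supp(X)`, lift is confidence divided by the
consequent's baseline rate `supp(Y)/N`, and significance is the G-test
(likelihood-ratio) p-value of the 2×2 contingency table of X and Y with
one degree of freedom, no continuity or Williams correction, and the
`0·ln 0 = 0` convention. The G statistic is computed cell-wise as
`2·Σ O·ln(O·N/(row·col))`: writing the ratio this way keeps G exactly
zero on integer tables at exact independence, where forming the expected
counts first would round and — because the χ² density is singular at
zero — perturb the p-value far beyond double-precision noise.

The antecedent-size cap (default 4, configurable) is not part of the
method's definition; it bounds the level-wise search on wide databases.
No redundancy pruning happens at mining time: all filtering is left to
the selection stage.

## Rule selection

Each rule is scored by a normalised metric vector on the unit hypercube,

m = (support_rel, confidence, lift/N, 1 − p),

every component clamped to [0, 1], and by its Euclidean distance to the
ideal point (1, 1, 1, 1), which ranges from 0 (ideal) to 2. The lift
normaliser N makes the third component of a confidence-1 rule equal
`1/supp_abs(Y)` — the reciprocal of the consequent's absolute support —
which is the scale on which published clause vectors are expressed.
`1 − p` makes 1.0 ideal for vanishing p-values.

Two rules are *comparable* when they share the consequent and their
antecedents overlap; rule r' *dominates* r when the two are meant to be
compared and r' is componentwise ≥ with at least one strict component.
Selection proceeds in two stages so that only undominated and
incomparable rules are left:

1. every rule dominated by some comparable rule is removed;
2. iteratively, the remaining candidate closest to the ideal point is
   selected as a representative and every remaining candidate comparable
   to it is discarded.

The first stage is not cosmetic. Comparability is not transitive, so the
bare iterative procedure could select a rule whose comparable dominator
was itself discarded earlier as comparable to an even better rule;
property testing over random candidate sets surfaces such cases
reliably. With the pre-filter, every representative is undominated by
any comparable input rule, the representatives are pairwise
incomparable, and each non-dominated input rule is either selected or
comparable to a representative at smaller-or-equal distance (a dominated
rule is accounted for by its dominator instead).

Ties on distance are broken lexicographically on the consequent and then
on the sorted antecedent items, making selection invariant to input
order. We select by *minimal* distance — the rule closest to the ideal
point, which is provably undominated within its comparability class.

## Prediction models

Representatives sharing a consequent are aggregated into one disjunctive
model, `A OR B ⇒ C`, with clauses ordered by ascending distance. Models
serialise to JSON (validated on read, with JSON-pointer error locations)
and to a human-readable block format:

```
[PREDICT] PATHWAY:...
[IF] [items] support–confidence–lift–p → distance
OR [items] ... → distance
[END]
```

Numbers are printed at full precision (shortest round-tripping decimal),
so render → parse → render is a fixed point and distances survive a JSON
write/read cycle bit-for-bit.

A model fires on an entry when some clause's antecedent is contained in
the entry's attribute items; each (entry, pathway) pair yields at most
one prediction with `best_distance` the minimum over firing clauses. The
prediction score used for ROC analysis is `2 − best_distance`, so any
firing clause scores positive and non-predictions implicitly score 0.
This score convention is this package's own choice — the reference
evaluation does not define the score it thresholded, which is why the
published AUC is not treated as a reproduction target here.

## Evaluation

Evaluation is pair-level over proteins × reference pathways, the
reference set being the pathways annotated in at least 20 entries of the
full learning database (computed once, not per fold). A predicted and
annotated pair is a TP, predicted-only an FP, annotated-only an FN,
neither a TN; a protein annotated with two pathways of which one is
predicted contributes one TP and one FN.

`cross_validate()` runs two rounds of five-fold cross-validation (both
counts configurable). Folds are uniform random partitions at the protein
level, sizes differing by at most one, without stratification; the
second round derives its seed from the first (`seed + 1`) so the two
rounds split differently yet the whole report is reproducible. Per
round, fold confusion matrices are averaged cell-wise; the global matrix
is the mean of the round matrices with a deviation of half the absolute
difference between rounds. Precision, recall and F1 are computed from
the averaged matrices with the no-error convention for degenerate
denominators (0/0 → 1 for precision and recall; F1 = 0 when P + R = 0),
and reported values are truncated — not rounded — to three decimals,
the only rule consistent with reproducing the published metric table
from its confusion matrix. AUC is the rank-based (Mann–Whitney) statistic
with tie correction over all held-out pairs, averaged over folds; a fold
whose pairs are single-class contributes no AUC term.

## Synthetic data

Because the learning corpus cannot be shipped, the package generates
synthetic entry collections with planted structure
(`synthetic_spec()` / `generate_entries()`):

* each *planted rule* gives `carrier_count` entries carrying its full
  antecedent, of which `⌈(1 − contamination)·carrier_count⌉` are
  annotated with its pathway under experimental evidence — contamination
  0 plants the rule at confidence exactly 1, contamination c at 1 − c;
* contaminated carriers are annotated with a decoy pathway rather than
  left unannotated: the learning-mode evidence filter would otherwise
  remove them and silently restore the rule's confidence to 1,
  defeating negative controls;
* background entries carry a lineage (depth 6 by default, matching
  typical prokaryotic lineage lengths; a configurable number of leaf
  clades) and independent noise InterPro items, drawn from a vocabulary
  disjoint from planted antecedents so recovery assertions are exact;
  they carry no pathway annotation;
* generation is a pure function of the spec seed and restores the
  caller's RNG state.

The generator emulates the statistical structure the mining stage
assumes — co-occurrence of attribute itemsets with pathway labels at
controlled support and confidence — not the correlation structure of
real InterPro signatures (domain architectures co-occur highly
non-independently) nor realistic taxonomic imbalance. Passing tests
therefore demonstrate correctness of the mining, selection and
evaluation machinery, not expected performance on real annotation
corpora.

Problem sizes used in the shipped tests (a few hundred entries, item
vocabularies of tens, two planted pathways at 80 carriers for the
cross-validated recovery check) were chosen so that planted antecedents
retain at least the default support-20 in every 4/5 training split, and
so the exhaustive oracles (power-set mining enumeration, all 2×2 tables
with N ≤ 40, pairwise AUC counts) remain exact rather than sampled.

## Numerical and design notes

* Whitespace in pathway levels and taxon names is normalised (ends
  trimmed, internal runs collapsed, case preserved); item identity is
  the canonical `NAMESPACE:value` string.
* "Similar" between two pathway labels means one level list is a strict
  prefix of the other (steps ignored), or the level lists are equal and
  exactly one side carries a step indicator; two different steps of the
  same sub-pathway are distinct annotations. This operational definition
  is a package decision — the comparison category was described but
  never formally defined in the reference evaluation.
* Confidence thresholding uses a 1e-12 tolerance so `min_conf = 1` is
  not defeated by floating-point division.
* Deviations in the evaluation report are half-ranges over rounds, the
  reading consistent with "± d from the observed values of the two
  runs".
* Known limitations: mining is in-memory and level-wise (no prefix-tree
  counting), intended for desk-scale corpora of up to a few thousand
  entries; the UniProt flat-file reader parses only the `AC`, `OC`,
  `DR InterPro` and `CC PATHWAY` line types; no network retrieval.

## A worked run

```{r}
entries <- generate_entries(synthetic_spec(
  n_entries = 120,
  planted = list(
    planted_rule("IPR:IPR100001", "Alpha metabolism; synthesis A", 40),
    planted_rule(c("IPR:IPR100002", "IPR:IPR100003"),
                 "Beta metabolism; synthesis B", 40, contamination = 0.2)),
  n_noise_ipr = 6, noise_item_rate = 0.05, seed = 1))

fit <- learn_models(entries, min_support_abs = 20, min_conf = 1.0)
nrow(fit$rules)
print(fit$models[[1]])
```

The contaminated rule (confidence 0.8) is absent at `min_conf = 1`,
while the clean rule survives selection and aggregation. The same
pipeline runs from the command line via the `inst/cli/pathwayrules`
script (`learn`, `predict`, `evaluate`, `simulate`, `compare`).
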