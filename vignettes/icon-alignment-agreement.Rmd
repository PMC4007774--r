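---
title: "Measuring inter-alignment agreement for a compositional icon language"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring inter-alignment agreement for a compositional icon language}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iconcord)
```

## The problem

Medical terminologies such as MeSH (a poly-hierarchic thesaurus) and
ICD10 (a mono-hierarchic classification) can be aligned to a
compositional iconic language, in which every concept is represented by
an icon built from a small inventory of graphical primitives — colours,
shapes and pictograms — arranged in a shallow hierarchy. Alignment is a
subjective expert task, and alignment errors propagate into any clinical
interface that displays the icons. When the *same* underlying concept is
reachable from two terminologies (via shared cross identifiers, CUIs in
the UMLS sense), the two independently produced icons for it can be
compared: high agreement between the two alignments is evidence that
each is of usable quality. `iconcord` implements that evaluation
pipeline end to end, together with a synthetic-world generator that
makes every stage testable without the proprietary terminology content.

## Data model

* **Components** are the icon's slots: central colour, shape, central
  pictogram, top-right colour and top-right pictogram. Central colour
  and shape are required; the rest may be empty. Whether a slot admits
  several primitives is configuration (`component_table()`), since the
  real language's multi-valued slots are not enumerated publicly.
* **Primitives** form a rooted tree at most six levels deep (about 221
  nodes in the modelled language). A single virtual root spans all
  components, so primitives of different components share only the
  root. Each primitive has exactly one parent; poly-hierarchy is a
  property of terminologies, not of the primitive hierarchy.
* **Icons** map components to sets of primitives. `Pr(I)`, the
  flattened union, is the unit of comparison.
* **Terminologies** carry concepts with one parent (mono) or several
  (poly), optional cross identifiers, and concept-to-icon alignment
  records flagged `manual` or `automatic`.

## The three metrics

For a pair of icons $I_1, I_2$:

* **Concordance** is binary: the per-component primitive sets are
  exactly equal or they are not. No semantic tolerance is applied.
* **Crude Dice**
  $\mathrm{DSC}_{crude} = \dfrac{2\,|Pr(I_1) \cap Pr(I_2)|}{|Pr(I_1)| + |Pr(I_2)|}$
  counts exact primitive overlap.
* **Semantic Dice** replaces each membership test by the best semantic
  match:
  $\mathrm{DSC}_{semantic} = \dfrac{\sum_i \max_j sim(Pr_i, Pr_j) + \sum_j \max_i sim(Pr_i, Pr_j)}{|Pr(I_1)| + |Pr(I_2)|}$,
  where $sim$ is the Lin information-content similarity
  $sim(Pr_i, Pr_j) = \max_{Pr \in S(Pr_i, Pr_j)} \dfrac{2 \log p(Pr)}{\log p(Pr_i) + \log p(Pr_j)}$
  over the shared ancestors $S(Pr_i, Pr_j)$.

Because ancestor closures are self-inclusive, $sim(x, x) = 1$ falls out
of the formula, and because the virtual root has probability 1,
$sim = 0$ exactly when the root is the only common ancestor. Any
similarity source with $sim(x,x) = 1$ and $sim \ge 0$ makes
$\mathrm{DSC}_{semantic} \ge \mathrm{DSC}_{crude}$, and a concordant
pair scores 1 on all three metrics; both properties are enforced by the
test suite.

### The information-content model

`p(Pr)` is estimated from the alignment relations themselves: every
alignment record contributes one occurrence of each primitive of its
icon (an icon aligned to $k$ concepts counts $k$ times; the
`per_icon` weighting that counts each distinct icon once is available,
since the corpus definition at relation vs icon level is a genuinely
open choice). Counting is cumulative: an occurrence increments the
primitive and all its ancestors, which is the only scheme under which
the root's probability is exactly 1 and the stated Lin limits hold.
Add-one smoothing on the direct counts keeps every $\log p$ finite;
natural logarithms are used internally, and the ratio makes the result
base-free (verified against a base-10 oracle).

Degenerate cases are fixed by continuity: when both arguments have
probability 1 the formula's $0/0$ resolves to 1 for identical
primitives and 0 otherwise.

### Worked-example mode

The exact corpus behind the published pairwise similarities (0.85 for
endocrine system vs thyroid, 0.35 for disease vs inflammation) is not
recoverable, so those values are *inputs*: `fixture_sim_fun()` injects
a pairwise table (symmetric closure applied, identity 1, unlisted pairs
0) and `worked_example()` reproduces the published pair exactly —
crude Dice $4/7$, semantic Dice $6.05/7$. Unlisted pairs default to 0
rather than erroring because the worked example's cross-component
pairs are implicit zeros; a strict mode (`missing = "error"`) exists
for curated tables.

## Closest-ancestor inheritance

In the poly-hierarchic terminology only a subset of concepts is
manually aligned. Every other concept inherits the icons of its
*closest* manually aligned ancestor(s), distance being the number of
parent edges walked upward breadth-first over all parents. Design
choices the procedure pins down:

* only manual records are inheritance sources — automatic records
  never chain;
* ties between equally close manual ancestors inherit the
  deduplicated union of their icon sets (deterministic, loses no
  information);
* the result is a pure function of the manual records, so the
  procedure is idempotent and never alters manual records.

The implementation is an explicit upward BFS; tests cross-check it
against shortest-path distances from `igraph` on random
poly-hierarchies of up to 200 concepts.

## Evaluation pipeline

`run_full_evaluation()` (or `evaluate_world()` on an in-memory world)
chains: load → inherit → pair by shared cross ids (cartesian per id,
deduplicated, sorted) → drop any pair in which either side carries
more than one icon → score the three metrics per retained pair →
stratify by the poly-side provenance. Summaries use:

* Wald (normal-approximation) 95% CIs for proportions — this is the
  interval that reproduces the published bounds for the manual
  stratum's concordance (392/528 → 74.2% [70.5–78.0]), which is how
  the CI method was identified;
* normal-approximation CIs for the mean Dice coefficients (a bootstrap
  alternative was considered and rejected as unnecessary at these
  sample sizes);
* Fisher's exact test for the manual-vs-automatic 2×2 concordance
  table and two-sided Wilcoxon rank-sum tests for each Dice metric.
  When both strata carry identical all-tied values the rank-sum
  p-value is reported as 1 (the no-evidence reading of a degenerate
  comparison).

Printed reports round percentages to one decimal and Dice values to
two, mirroring conventional reporting; the JSON rendering keeps full
precision and round-trips losslessly.

`worst_case_sensitivity()` answers "what if every excluded multi-icon
pair had been fully discordant": the concordant count is held fixed
while the denominator grows, and the means are diluted by the same
factor. Integer concordant counts can be recovered from printed
percentages as `round(p * n)`.

## The synthetic generator

`generate_world()` emulates the study conditions so that the pipeline
can be validated by parameter recovery:

* a 221-primitive, ≤6-level hierarchy over the five components, with
  colour inventories small and pictogram inventories large;
* a poly-hierarchic terminology (depth ≤ 11, second parents with
  probability 0.15) in which manual alignments sit on anchor concepts
  and the remaining cross-linked concepts hang beneath an anchor in
  short chains — so the pipeline's own `inherit_icons()` run, not the
  generator, produces their records;
* a shallower strictly mono-hierarchic terminology whose cross-linked
  concepts are manually aligned to a copy of the shared true icon;
* per-pair discordance: with probability $\delta$ the mono-side copy
  has one primitive substituted, either by a random sibling
  (`sibling_swap`) or by its parent (`parent_generalization`); either
  way the replacement stays in the same component, so arity is never
  violated and the perturbed icon remains valid;
* a multi-icon fraction (default 0.077 per side) gives some aligned
  concepts a second icon, so the single-icon filter removes about 15%
  of pairs, matching the exclusion level observed at the cross-link
  level in the real data;
* icons are sampled leaf-biased (annotation practice favours specific
  primitives), with both required slots always filled.

Defaults (800 + 800 concepts, cross-link fraction 0.8 → ~640 pairs,
manual fraction 0.33 as in the evaluated manual stratum, δ = 0.25 ≈
the observed manual discordance) keep a full pipeline run around a
second; the sweep sizes (~500+ retained pairs per rate) were chosen so
that Monte-Carlo noise on the means is well below the effects being
checked.

Randomness uses one integer seed with fixed per-stage derived
sub-seeds, so adding a stage never silently shifts downstream draws and
identical seeds reproduce identical worlds byte-for-byte.

### What passing synthetic tests does and does not show

The generator reproduces the *structure* of the evaluation — two
hierarchies, provenance strata, partial cross-links, multi-icon
exclusions, controlled discordance — but not real annotation
behaviour: discrepancies in real alignments cluster by concept family
and reviewer, multi-icon alignments are not independent of concept
complexity, and cross-identifier links can themselves be wrong (a
documented error source). Recovery of $\delta = 0$ as perfect agreement
and monotone decay of all metrics in $\delta$ validates the pipeline's
arithmetic, not the quality of any real alignment.

Because each sweep rate runs on an independent world, the mean metrics
are monotone in $\delta$ only up to Monte-Carlo noise;
`sweep_monotonicity_violations()` therefore allows adjacent increases
within two combined standard errors of the compared means.

## Known limitations

* The real primitive hierarchy, icon grammar and alignment content are
  proprietary; the packaged fixture and the generator are synthetic
  stand-ins with the published scale constants.
* Icon validity is checked structurally (arity, nullability,
  referential integrity); the combinatory grammar that forbids
  nonsensical primitive combinations is out of scope.
* Pairs with multiple icons on either side are excluded, as in the
  modelled evaluation; the worst-case analysis bounds, but does not
  estimate, their effect.
* Alternative information-content similarity estimators (Resnik,
  Jiang–Conrath) are not provided.
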