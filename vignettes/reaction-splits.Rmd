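---
title: "Out-of-distribution splits for reaction product prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Out-of-distribution splits for reaction product prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Reaction corpora extracted from the patent and journal literature are not
collections of independent observations. Authors come together to write
documents, and a document typically reports a *substrate-scope series*:
one transformation applied to many closely related substrates. When such
a corpus is split into training and test sets uniformly at random, most
test reactions have near-duplicates — same document, same scope series —
in the training set, and the measured top-*k* accuracy of a reaction
product predictor is an overestimate of what a user would see on
genuinely new chemistry.

`rxnsplits` provides the split families that remove this leakage, the
metrics to score ranked product predictions, and the diagnostics to
quantify how far each test reaction sits from the training set:

* **Record-level (random) splits** — the overoptimistic baseline.
* **Document splits** — every reaction of a document on one side.
* **Author splits** — connected components of the author–document
  co-occurrence graph assigned wholesale, so no author (and hence no
  document) straddles the partition.
* **Time splits** — one held-out test set per year, plus a family of
  training sets restricted to publication years at or below a cutoff,
  optionally subsampled to a fixed size so that accuracy differences
  across cutoffs reflect the time gap rather than the data volume.
* **Reaction-class hold-outs** — removal of a class (by hierarchical
  code prefix, `"3.1"` matching `"3.1.2"` on dot boundaries) from
  training; a companion baseline moves a fixed number of class examples
  (1000 by default) back into training to measure the class's intrinsic
  difficulty, so the gap between the two isolates extrapolation
  difficulty.

Every splitter's guarantees are re-checked by an independent auditor
(`audit_split()`, `audit_time_series()`) that rescans the corpus rather
than trusting the splitter's bookkeeping: record- and canonical-key-level
disjointness, document/author integrity, year bounds, exact size
control, and class-exclusion contracts.

## Canonicalization and deduplication

All reaction comparisons are string comparisons after molecule
canonicalization, which is delegated to OpenBabel's canonical SMILES
writer (via ChemmineOB); the canonicalizer's identity is recorded in the
corpus object so corpora keyed with a different routine are detectable.
The canonical reaction key is `"R>A>P"` with each part's molecules
canonicalized, lexicographically sorted and dot-joined. Agents
participate in the key: two reactions differing only in conditions are
kept distinct, because conditions can change the product.

Deduplication keeps one record per canonical key, choosing the
earliest-year record (the first disclosure — the natural choice for time
splits), breaking remaining ties by smallest document id and then record
id, which makes the operation deterministic and idempotent.

## Matching policies and top-k accuracy

Ground truth is the record's full product set; candidates and truth are
compared as product multisets after canonical deduplication within each
side. Three nested policies are provided:

* `strict` — canonical SMILES set equality;
* `stereo_agnostic` — strict equality after deleting tetrahedral (`@`)
  and double-bond (`/`, `\`) annotations from both sides, so E/Z pairs
  and enantiomers collapse;
* `formula_level` — equality of molecular-formula multisets, which
  counts regioisomeric products as correct. This deliberately also
  accepts other constitutional isomers; an operational definition of
  "regioisomer only" would require an arbitrary notion of attachment
  position, so the slight over-relaxation is documented rather than
  hidden.

Matches imply each other left to right, so the three accuracies are
ordered at every *k*; both this relaxation chain and monotonicity in *k*
are property-tested. Duplicate candidates (which arise naturally when a
ranked list collapses under stereo stripping) are merged keeping their
best rank before the *k* cutoff, so collisions neither inflate nor
deflate top-*k*. An unparseable candidate counts as a miss; an
unparseable ground truth is a hard error. The default ranking depth is
5, matching the beam width most sequence-based predictors report.

`iterate_predict()` supports multi-round prediction: the top-1 product
of round *r* is fed back as a reactant for round *r + 1* under a carry
rule. The default, `replace_largest`, substitutes the product for the
heavy-atom-largest reactant and keeps the remaining reactants and agents
— modelling a reagent present in excess, such as the second Grignard
equivalent in a double addition. Whether the real experiment retains the
reagent or feeds the bare intermediate is not observable from the data,
so the carry rule is an explicit argument rather than a constant.

## Fingerprints and shift diagnostics

Distribution shift is quantified per split as the mean cosine distance
from each test record to its `m = 5` nearest training records, in one of
two spaces:

* **reactant space** — the sum of per-reactant counted circular
  fingerprints (substrate novelty);
* **reaction space** — the *difference* fingerprint, product counts
  minus reactant counts, which cancels the unchanged scaffold and
  encodes the transform (transform novelty).

The fingerprint is a counted (not binary) hashed circular-substructure
vector computed on the OpenBabel molecule graph: every atom contributes
one hashed environment identifier per radius 0..r, folded into 2048
bins. Defaults are radius 3 and width 2048 — the ECFP6-style setting.
Radius 2 is available, but on the compact substrate grammar of the
synthetic generator (below) radius-2 difference fingerprints are too
coarse: the atoms a transform changes then see only the first atom of
each ring substituent, so distinct substrate series produce identical
difference vectors and nearest-neighbor distances collapse to zero.
Radius 3 reaches the substituent interiors and restores resolution;
with richer real-world molecules either setting is informative.

Cosine distance on nonnegative reactant vectors lies in [0, 1]. The
difference vector is signed, so reaction-space distances lie in [0, 2];
a test transform anti-correlated with everything in training is simply
"farther than orthogonal", and we keep the honest range rather than
clamping. Two all-zero vectors (two null transforms) are defined to be
at distance 0, and a zero against a nonzero vector at distance 1.
Neighbor search is exact — corpora at desk scale make the blocked
quadratic scan cheap — and ties are broken by a stable sort on
(distance, training record id), so profiles are invariant to training
set ordering.

## The synthetic corpus generator

The generator exists so that every splitter, metric and diagnostic can
be exercised end to end without proprietary data. It emulates the
*structure* of a literature corpus, not its chemistry:

* **Substrate grammar.** Five aryl cores (two benzene substitution
  patterns, pyridine, thiophene, furan), each carrying a reactive-site
  prefix (halide, boronate, ester, acid chloride, benzylic alcohol), a
  document-level *series* decoration placed ortho to the site, and a
  per-reaction *scope* decoration. The series decoration is a composite
  group assembled from two primitives, giving roughly 600 distinct
  series identities — about one per document — so distinct documents
  almost always study distinct substrate series, while reactions within
  a document differ only in the scope decoration and reagent.
* **Transforms.** Ten substructure-rewrite templates spanning three
  top-level classes: three halide couplings that are siblings differing
  only in the leaving group (3.1.1/3.1.2/3.1.3), a late-introduced
  amination (3.2.1, introduction year 2010), Grignard addition to aryl
  esters as a single/double-addition pair (1.1.1/1.2.1) in which the
  double addition is exactly the composition of two single additions,
  N- and O-acylation of acid chlorides (2.1.1/2.1.2), an aryl ether
  synthesis (2.2.1), and an uncategorized benzylic oxidation ("0.0").
  Template application is deterministic and refuses non-matching
  substrates rather than emitting a wrong product.
* **Ambiguity by construction.** Some reactant sets admit more than one
  template: every ester + Grignard query matches both the single- and
  double-addition templates, and an acid chloride with the bifunctional
  amino alcohol (`NCCO`) matches both acylation templates. For such
  records the correct product is not determined by the reactants alone
  — the predictor must exploit similarity to training data, which is
  exactly what out-of-distribution splits degrade.
* **Literature structure.** 180 authors in 90 two-person labs; teams
  are drawn within a lab, with a 6% chance of a co-author from the
  lab's fixed partner lab (so co-authorship components merge at most
  lab pairs and the author split always has many components). Labs
  specialize: a balanced portfolio of one preferred class per top-level
  family (allocated systematically in proportion to within-family
  popularity, so the class mix of any subset of labs tracks the
  schedule), two preferred cores, a small decoration pool, and two
  *signature* series decorations dealt from a globally shuffled deck —
  no two labs study the same substrate series, and a lab returns to its
  signatures across documents (85% of documents), which is what makes
  author-level hold-out strictly harder than document-level hold-out.
  Documents get a uniform year in 1998–2022, a class drawn from the
  lab's preferences (p = 0.6) or the year's popularity schedule, and
  6–16 reactions applying mostly one template across scope decorations;
  10% of reactions are off-series with their own class and substrate
  context.
* **Popularity drift.** Class weights interpolate linearly between a
  start and end weight and are zero before the introduction year. The
  defaults make the amination class appear in 2010 and rise steeply,
  the single addition fall as the double addition rises, and one
  coupling sibling decline — so the reaction-type distribution of later
  years differs from earlier ones, which is what makes time-based
  extrapolation hard.

What the generator does **not** emulate: real reagent and condition
diversity, yields, atom-mapping noise, class frequencies of any real
corpus, or molecular complexity (all molecules are small decorated
aryls). Passing the trend tests therefore shows that the splits,
metrics and baseline interact as designed on a corpus with the right
*dependence structure*; it says nothing about absolute accuracies on
real data, which require a real corpus and a trained model.

## The template-retrieval baseline

The baseline predictor stores the distinct transforms seen in training
together with their support (the reactant fingerprints of the records
that used them). At query time it applies every applicable stored
template and ranks candidates by

```
score = max cosine(query reactant fp, support fps) * log(1 + support count)
```

with ties broken by canonical product string. It cannot emit a
transform it never saw — precisely the extrapolation failure mode the
class hold-outs probe — and its ambiguity resolution degrades as the
nearest same-transform training example gets farther, which is what the
document and author splits induce. It is deliberately simple: it reads
the generator's planted transform strings instead of inducing templates
by atom mapping, because template induction is a research problem in
itself and the subject here is the evaluation methodology, not the
predictor.

## Numerical and design choices

* Group assignment for document/author splits shuffles groups by seed
  and adds a group to the test side only when that brings the test
  count strictly closer to the target, stopping at the target. This
  "closest-achievable greedy" variant prevents a large first group from
  overshooting a small target; the residual deviation is reported in
  the split's params.
* Author identity is exact string match of author names — no
  disambiguation data exists for synthetic corpora; recorded as a
  limitation for real data.
* Size-controlled training sets are sampled independently per cutoff
  (not nested); nesting is not required by any invariant and
  independence keeps each training set uniform over its pool.
* Test-year sets are sampled before any training pool is formed, so a
  record can never appear on both sides of any cutoff/test-year pair.
* The in-distribution context test set for class-holdout plots is drawn
  from the non-held-out classes with a record-level split at a
  configurable fraction (default 0.1).
* Ranking-depth default 5; accuracy is reported at k = 1, 3, 5.
* Degenerate inputs: an empty candidate list is a legal miss; a
  predictor returning nothing at an intermediate round of
  `iterate_predict()` truncates the iteration and flags it; a corpus
  with a single document (or a single co-authorship component) cannot
  be group-split and errors with a diagnostic.

## Problem sizes used in the shipped checks

The package's own end-to-end checks run on generated corpora: fifty
~2,000-reaction corpora for the leakage audits, one ~5,000-reaction /
600-document corpus (25 years, 10 classes) for the trend
demonstrations, and 100-fixture batches for the metric oracles. These
sizes were chosen so the full suite exercises every code path on a
single desktop core in a few minutes while keeping every statistical
check comfortably powered.

## Known limitations

* OpenBabel's canonical SMILES is the single canonicalization routine;
  corpora canonicalized with a different toolkit must be re-keyed on
  read (automatic, since keys are recomputed) before mixing.
* The toy grammar concentrates structural diversity in a few substituent
  positions; fingerprint hyperparameters tuned on it (radius 3) are a
  reasonable general default but not a finding about real corpora.
* The author split treats co-authorship components as the unit; very
  dense real co-authorship graphs can collapse into one giant component,
  in which case the splitter refuses rather than silently producing a
  leaky partition.
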