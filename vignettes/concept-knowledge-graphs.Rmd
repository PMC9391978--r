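---
title: "Concept knowledge graphs from annotated corpora: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concept knowledge graphs from annotated corpora: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conceptkg)
```

## The problem

Families of people with neurodevelopmental conditions such as autism
spectrum disorder (ASD) or attention deficit hyperactivity disorder (ADHD)
talk about those conditions in online health forums; clinicians and
researchers write about them in the scientific literature. The two groups
do not necessarily prioritise the same concepts. `conceptkg` turns two
concept-annotated corpora — e.g. forum posts and PubMed abstracts run
through a UMLS entity linker — into ranked, semantically grouped concept
maps ("mental models") for each stakeholder group, and classifies every
shared concept as being of similar or divergent priority between them.

The package works entirely from pre-annotated input: one JSON record per
document, each carrying its linker mentions (concept id, preferred name,
ordered semantic-type list, confidence score). Scraping, text
preprocessing and entity linking are upstream concerns and deliberately
out of scope; a small dictionary annotator (`annotate_with_dictionary()`)
exists only to build fixtures from raw text.

## The model

### Filtering

Documents are first restricted to those mentioning a target condition,
after merging synonym concepts into the canonical condition id (for ASD,
the Asperger-syndrome and autistic-disorder concepts are folded in via
`condition_merge_map`). The concept vocabulary is then built with four
filters, in order:

1. **Score cutoff** — mentions survive only with linker score strictly
   greater than `score_cutoff` (default 0.7). The strictness follows the
   rule's usual statement ("greater than"); a score of exactly 0.7 is
   excluded.
2. **First semantic type** — a concept's type is the first entry of its
   ordered type list; context-sensitive type selection is not attempted.
3. **Type allowlist** — the first type must sit in
   `allowed_semantic_types`; the default is a curated set of 26 UMLS
   types relevant to neurodevelopmental conditions (behaviour, findings,
   signs and symptoms, procedures, care organisations, ...), shipped as
   plain text and overridable. A `blocklist` of concept ids stands in for
   a manual false-positive review.
4. **Document frequency** — concepts must appear in at least
   `min_doc_count` distinct documents (default 10). Multiple mentions in
   one document count once; repeated mentions should not inflate either
   frequency or co-occurrence.

Condition concepts bypass the type and count filters: they are what the
corpus was filtered *on*, and the graph cannot exist without its anchor.
Vocabulary indices are assigned by descending document count with ties
broken by concept id, so a vocabulary is a deterministic function of its
corpus and configuration.

### Embeddings

Co-occurrence is counted at document level (a "global context"): entry
$(i,j)$ of the co-occurrence matrix is the number of documents containing
both concepts, presence-based. The matrix is transformed to positive
pointwise mutual information with document-proportion probability
estimates $p(c_i) = n_i/N$, $p(c_i,c_j) = n_{ij}/N$:

$$\mathrm{PMI}(c_i,c_j) = \log\frac{p(c_i,c_j)}{p(c_i)\,p(c_j)},\qquad
  \mathrm{PPMI} = \max(\mathrm{PMI}, 0).$$

Pairs that never co-occur map to 0 rather than $-\infty$, keeping the
matrix sparse. The PPMI matrix is factorized by truncated SVD,
$M \approx U_k S_k V_k^T$, and each concept's vector is the corresponding
row of $U_k S_k$ — exactly that product, not $U_k$ alone nor
$U_k S_k^{1/2}$. The default dimension is $k = 300$, a conventional size
for count-based embeddings; when the vocabulary is smaller than $k$, the
effective dimension clamps to the number of numerically positive singular
values and is reported in the run manifest.

Relatedness between concepts is the cosine of their vectors, clipped to
$[-1,1]$ against rounding. Cosine is invariant to any positive rescaling
of the PPMI matrix, so the base of the logarithm is pure convention
(natural log here); this invariance is asserted by a test that rescales
the matrix by 7.3 and checks every relatedness to $10^{-9}$.

### The graph

For each source, concepts are ranked by relatedness to the condition
within each semantic type, and the top 25 per type (ties broken by
concept id; the condition itself excluded) are materialized as a property
graph:

* a **condition** node (frequency 1);
* one **semantic-type** node per type, frequency = arithmetic mean of its
  selected concepts' frequencies, linked to the condition by an
  unweighted `isRelatedTo` edge;
* one **concept** node per selected concept, carrying its frequency (the
  proportion of condition-mentioning documents that also mention it),
  linked to its type by an `isA` edge weighted by relatedness.

Two single-source graphs are merged by adding exactly one unweighted
`sameAs` edge per concept selected in *both* graphs — undirected in
meaning, stored once. Node ids are namespaced by source so the same
concept id can appear on both sides. `validate_kg()` enforces every
schema invariant and is run before any export; GraphML and CSV node/edge
exports round-trip exactly, with absent (not zero) weight attributes on
unweighted edges.

### Comparing corpora

For every concept scored in both corpora the score difference is
$\mathrm{diff} = FR - PR$ (first source minus second). With $\mu$ and
$\sigma$ the mean and population standard deviation of the differences,
a concept is a first-source priority if $\mathrm{diff} > \mu + 2\sigma$,
a second-source priority if $\mathrm{diff} < \mu - 2\sigma$, and of
similar relevance otherwise — boundaries inclusive on the similar side,
since the priority rules are strict inequalities. Under normally
distributed differences the similar band covers about 95.4% of concepts,
which the test suite checks on 10,000 simulated differences.

Three choices here were genuinely open and are worth recording:

* $\mu$ and $\sigma$ are computed over the **intersection** of the two
  vocabularies; a concept absent from one corpus has no difference to
  contribute. Source-exclusive concepts are reported separately,
  uncategorized.
* The standard deviation uses divisor $n$ (population form); with
  thousands of shared concepts the distinction from $n-1$ is immaterial,
  but it is documented and fixed for reproducibility.
* By default the comparison is restricted to the union of both top-25
  selections (`restrict_comparison = TRUE`), since the selections are
  what the graphs display; the full-vocabulary comparison is one flag
  away.

## The synthetic-data generator

`synthetic_spec()` / `generate_corpus()` produce corpora with *planted*
structure so that every downstream stage has a known right answer: each
document draws one latent topic, members of that topic are emitted
independently with probability 0.8, members of other topics leak in with
probability 0.02, and each topic is anchored by its own condition
concept. The defaults — 1000 documents, two topics of eight concepts
plus their anchors — are the reference conditions used by the test suite
and the acceptance script, where the in-topic concepts must outrank all
others for the condition.

Two design points deserve emphasis:

* **Two condition anchors are structural, not decorative.** The document
  filter keeps only condition-mentioning documents, so a single-condition
  corpus would have the condition in *every* retained document; its PPMI
  row would then be identically zero (co-occurrence with everything is
  exactly at chance) and it would have no direction to measure cosine
  against. Real corpora of this kind span at least two conditions, and
  the generator mirrors that.
* **Always-on background concepts are adversarial for PPMI.** Clamping
  negative PMI at zero biases all vectors into the positive orthant, so a
  concept emitted indiscriminately in every document can acquire a
  spuriously high cosine to the condition from sampling noise alone. The
  generator therefore plants no background concepts by default; the
  `background` field exists to construct exactly this stress case.

What the generator does *not* emulate: natural-language text, reply
threads, linker errors correlated with context, concept polysemy, or the
heavy-tailed document-length and concept-frequency distributions of real
forums. Passing the planted-recovery property shows the pipeline
faithfully recovers co-occurrence structure it can see; it does not show
that a UMLS linker's annotations of real posts contain such structure.

## Numerical choices

* PPMI diagonal zeroed before SVD (`keep_diagonal = FALSE`), the common
  practice, so a vector reflects a concept's neighbourhood rather than
  its own frequency.
* Exact LAPACK SVD up to `exact_limit = 2000` concepts; beyond that a
  seeded Gaussian-sketch randomized SVD (10 oversamples, 4 power
  iterations). Singular-vector signs follow the
  largest-magnitude-entry-positive convention, so results are
  reproducible bit-for-bit for a fixed seed.
* Ranking ties broken lexicographically by concept id, with radix
  ordering so results do not depend on the locale.
* Degenerate inputs fail loudly: empty vocabularies, conditions absent
  after filtering, zero-norm vectors and all-zero PPMI matrices are
  errors naming the offending object, never silent zeros.
* Manifests contain no timestamps and hash the configuration, so two
  runs of the same config and seed are byte-identical — asserted
  end-to-end in the tests.

## Problem sizes used in validation

The test suite and acceptance script run at deliberately modest scale:
vocabularies up to 50 concepts for the PPMI oracle equivalence (100
random corpora against a scalar-loop oracle), 1000-document corpora for
the planted-ranking property (20 seeds), 10,000 simulated differences
for classification coverage, and 400-500-document corpora for the
end-to-end determinism and self-comparison checks. These sizes exercise
every code path, including sparse-matrix handling, while keeping a full
run in the order of a minute.

## Limitations

Relatedness is contextual association, not synonymy or any specific
clinical relation; an `isA` edge records only that a concept was typed
under a semantic category and found related to the condition. The
comparison inherits all biases of its corpora — who posts in forums,
what gets published — and the package makes no attempt to correct them.
Concepts below the document-frequency floor in either corpus simply do
not exist for the comparison, which matters for rare but important
topics.
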