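---
title: "Matching methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harmonizr)
```

This vignette explains what each matcher computes, why the defaults are what
they are, which parts of the design were genuinely open and how they were
decided, and what the synthetic fixtures do and do not demonstrate.

## The problem and the data model

Harmonizing a tabular biomedical dataset against a target means discovering a
correspondence between source columns and target attributes (schema
matching), aligning each matched column's values with the target attribute's
permissible values (value matching), and applying the resulting
transformations (materialization). harmonizr represents the source as a
`HarmonTable` — a rectangular table of text cells in which the sentinels
`""`, `NA`, `NaN`, `null` (case-insensitive) denote missingness — and any
target as a `TargetSchema`: attributes with optional permissible values and
metadata. A plain table becomes a `TargetSchema` by taking each column's
distinct non-missing values (first-occurrence order) as the permissible set,
while a data-model standard exposes the same view through the four-accessor
interface (`getAttributes`, `getAttributeValues`, `getAttributeMetadata`,
`getTableRepresentation`). All matchers see only this uniform view, so
adding a standard is a data exercise (a YAML or JSON file), not a code
change.

Columns are typed by a simple rule: *numeric* when at least 95% of
non-missing cells parse as finite numbers (integer, decimal, or scientific
notation; thousands separators deliberately rejected as ambiguous), *unknown*
when everything is missing, *text* otherwise. The 95% tolerance absorbs the
occasional stray annotation ("n/a (lost)") in otherwise numeric clinical
columns without letting genuinely mixed columns masquerade as numeric.
Date-times are treated as text: their harmonization semantics (time zones,
precision, calendars) are out of scope.

## Schema matchers

All matchers return similarities in $[0,1]$ by construction — no post-hoc
rescaling — so meta-matchers can combine them, and all ties are broken
lexicographically by target attribute name so every ranking is reproducible.
Because each matcher consumes distinct-value sets or value distributions,
results are invariant to the row order of the source table; this forces one
deviation noted below.

**`composite_name`** is the unweighted mean of four string similarities on
the attribute names: normalized Levenshtein ($1 - d/\max(|a|,|b|)$),
Jaro–Winkler (prefix weight 0.1, prefix cap 4), token-set Jaccard after
snake/camel/space tokenization and case folding, and character 3-gram cosine.
Four cheap views of the same pair make the mean robust to any single
metric's blind spot (`Tumor_Focality` vs `tumor_focality` scores 1 because
every case-folded component agrees).

**`similarity_flooding`** turns each schema into a small directed graph
(schema node → column nodes, labeled *column*; column node → kind node,
labeled *kind*), pairs same-labeled edges into the pairwise-connectivity
graph, and iterates the basic fixpoint
$\sigma^{i+1}(p) = \sigma^i(p) + \sum_{q \to p} \sigma^i(q)\,w(q,p)$
followed by normalization by the maximum, where $w$ is one over the
out-degree per (node, label, direction). Initial similarities are
`composite_name` for column pairs and equality for schema/kind pairs.
Defaults: $\varepsilon = 10^{-4}$, `max_iter = 100`. The algorithm family
admits many variants; flat tables need no tree structure, so the graph stays
deliberately minimal. Setting $\varepsilon = \infty$ performs zero
iterations and reproduces the initial name-based ranking — useful for
isolating the effect of propagation. Hitting the iteration cap emits a
`NonConvergenceWarning` and returns the last iterate rather than failing:
a slightly unconverged ranking is still informative.

**`distribution_based`** compares what the columns *contain* rather than
what they are called. Numeric pairs: both samples are min–max scaled over
their pooled range and compared by the 1-D Earth mover's distance, which for
empirical distributions equals $\int |F_x - F_y|$; similarity is $1 -
\mathrm{EMD}$, which is 1 exactly when the distributions coincide. Text
pairs: $1 -$ total-variation distance between the frequency vectors over the
union of exact values. Kind-mismatched pairs score 0. When the target is a
plain table its observed value frequencies are carried along
(`valueCounts`); a standard enumerates permissible values without
frequencies, so those are weighted uniformly. A column with fewer than two
observed values has no usable distribution: the pair scores 0 under an
`InsufficientDataWarning` instead of fabricating a similarity.

**`jaccard_distance`** builds a fuzzy intersection by greedily pairing
distinct values in ascending normalized Levenshtein distance, keeping pairs
at distance $\le \theta$ (default 0.2 — tight enough that `male`/`female`,
at distance 0.33, never merge, loose enough for suffix variants), and scores
$|I| / (|U_s| + |U_t| - |I|)$. At $\theta = 0$ this is exact Jaccard, and it
is monotone non-decreasing in $\theta$. Greedy pairing is quadratic and
deterministic; the tests cross-check it against exhaustive optimal pairing
on small sets, where it attains the optimum in the large majority of cases
(greedy can be suboptimal when an early cheap pair blocks two distinct
later pairs).

**`magneto_zs_bp` / `magneto_zs_llm`** serialize each column as
`"name: <name>. values: v1, …, v15"` and embed it. The 15-value cap bounds
the serialization of high-cardinality columns (identifiers would otherwise
dominate the text); the serialized values are the *sorted* first 15 distinct
values — a deliberate choice so the embedding, and hence the whole matcher,
is invariant to row order, which an occurrence-ordered serialization cannot
be. Candidate targets are retrieved per source column by cosine (candidate
pool `candidate_k`, default `max(top_k, 10)`), then a maximum-weight
bipartite assignment over the union candidate set enforces one-to-one
matches; sources whose optimum lands on a zero-padding column fall back to
their top cosine candidate. In the ranked output the assignment winner is
listed first and reported with the maximum candidate cosine for that source,
the remainder following in cosine order — reranking by assignment reorders
but must not produce an increasing similarity sequence, so the winner
inherits the top score rather than keeping a lower cosine above a higher
one. The `_llm` variant replaces the assignment with a chat-adapter choice,
with the bipartite path as the offline fallback on adapter failure.

**`two_phase`** prunes with one matcher (`prune_k` candidates, default
`top_k`) and rescores the survivors with another, ranking by the phase-2
score with phase-1 as tie-break; with `prune_k = 1` phase 2 is irrelevant by
construction. **`max_val_sim`** is the value-informed special case: each
candidate is rescored by the mean, over the source's distinct values, of its
best value-match similarity against the candidate's permissible values
(default value matcher: tfidf). Candidates without enumerable values cannot
be value-scored; they keep their phase-1 score damped by 0.5 — retained but
ranked below any candidate with genuine value agreement. The rerank is
purely by value score (phase-1 as tie-break) rather than a blend: a blend
weight would be one more arbitrary constant, and the phase-1 evidence
already chose the candidate pool.

**`llm`** offers each source column's candidates — names, descriptions, and
up to five sample values — to a `ChatAdapter`. Adapter answers outside the
offered candidate set are rejected (the ranking falls back to the composite
ordering), adapter exceptions fall back to `composite_name` under an
`AdapterFallbackWarning`, and abstention likewise yields the composite
ranking. Non-winning candidates are reported at
$\min(\text{composite}, \text{confidence})$ so the ranked similarities stay
non-increasing.

### The assignment core

The bipartite rerank solves the assignment problem exactly with an
$O(n^3)$ Hungarian algorithm on the zero-padded square matrix. Among
equal-cost optima, the assignment preferring lexicographically smaller
target names for earlier sources is selected by adding a secondary
preference scaled to $10^{-9}$ of the score range — far below any genuine
score difference on the grids the package produces, but enough to make ties
deterministic. The strict one-to-one assignment (before fallback) is
attached to the result as the `"assignment"` attribute.

## Value matchers

Case folding precedes all text similarity, so matches differing only in
capitalization score exactly 1 under every matcher without any model call.
`tfidf` uses `#`-padded character 3-grams, IDF $\ln\frac{1+N}{1+df} + 1$
fitted over the union vocabulary of sources and targets, L2-normalized
vectors, cosine similarity, and forces exact case-insensitive equality to 1
(two very short equal strings could otherwise score below 1 purely through
IDF weighting). `edit_distance` is $1 - \mathrm{lev}/\max(|s|,|t|)$ with
`("", "")` defined as 1; a user-supplied scorer is contract-checked to the
$[0,1]$ range. `embedding` maps encoder cosine from $[-1,1]$ to $[0,1]$ via
$(x+1)/2$, so orthogonal vectors sit at 0.5 rather than 0.

`matchValues` emits, per distinct source value, its top-1 candidate when the
similarity reaches $\tau$ (default 0.3) and reports the value as unmatched
otherwise; matched and unmatched rows together always cover all distinct
source values. $\tau = 0.3$ sits comfortably below the scores of genuine
lexical variants under 3-gram tfidf while cutting most cross-category
accidents; it is a reviewable floor, not a verdict — the triage rules, not
$\tau$, decide acceptance.

Numeric transforms are affine, `value * scale + offset` with optional
rounding, validated to `scale != 0`; applying a transform and then its
algebraic inverse recovers the input to within $10^{-9}$ relative error
(before rounding). Inference is deliberately conservative: a fixed
conversion table keyed by unit hints (years→days = 365.25 with floor
rounding, the Julian-year convention matching how ages in days are recorded
in clinical CDMs; years→months = 12; the inverses; kg↔g), an optional
adapter proposal restricted to the candidate scale set
$\{12, 365.25, 1/12, 1/365.25, 1000, 1/1000, 1\}$, and otherwise the
identity tagged `"no-evidence"` — a wrong silent unit conversion is worse
than none.

## The harmonization specification

The specification is a JSON document (`version`, `mappings`; each mapping:
`source_attribute`, `target_attribute`, `mapper`, optional `similarity`,
`provenance`) with stable key order, 2-space indentation and full-precision
numbers, so diffs are meaningful and `readSpec(writeSpec(s))` is the
identity. Mappers are `identity`, `dictionary` (with `unmatched_policy`
`null` — the default, because silently passing through values outside the
target domain is the more dangerous failure — or `passthrough`), `affine`,
and `custom`. Custom routines serialize by *name only* and are re-registered
at run time: the document stays declarative and free of executable content.

One source attribute may feed several targets (one-to-many); two sources
feeding one target (many-to-one, e.g. deriving BMI from weight and height)
are rejected at construction with a `ManyToOneError` — supporting them would
require reasoning over attribute combinations, a different problem.
`mergeMappings` gives user entries precedence keyed by source attribute: a
user entry replaces *all* automatic entries for that source, surviving
automatic entries keep their order, and user-only entries are appended; the
merge is idempotent in its user argument. `validateSpec` reports findings
(unknown attributes, dictionary values outside the target domain,
many-to-one collisions) rather than raising, since a draft specification
under review is expected to be imperfect.

## Match triage

`evaluateSchemaMatches` applies ordered rules, first hit wins: R1 accepts
normalized-name equality backed by value-set agreement (or no enumerable
values to contradict it); R2 accepts value sets equal after case/punctuation
normalization even when names disagree; R3 accepts similarity ≥ 0.9 with
fuzzy value overlap ≥ 0.5; R4 rejects similarity < 0.4, or the combination
of zero value overlap with zero name-token overlap; R5 marks everything else
for review. The 0.9/0.4 (schema) and 0.8/0.4 (value) bands are package
choices: the label vocabulary is fixed, but no principled universal
thresholds exist for heterogeneous similarity scales, so the bands are set
wide enough that only strongly-evidenced matches bypass review. Every label
carries the rule id and a templated explanation naming the evidence. An
adapter may only refine `needs_review` outcomes — it can never flip an
accept or reject — keeping the deterministic rule core authoritative. The
template-based explanations are the deterministic contract; free-text
model-authored explanations are a pluggable extra, not the default.

## Offline backends

The default encoder hashes case-folded character 3-grams into a
512-dimension vector with a sign drawn from a second hash (signed hashing
cancels collision bias in expectation) and L2-normalizes. The two
polynomial hash functions are fixed constants of the package — seedless, so
vectors are stable across runs and platforms — and the encoder is checked
against an independent reimplementation in the tests. The mock chat adapter
ranks candidates by token-overlap fraction with the query, breaking ties by
3-gram cosine and then lexicographically, and abstains at zero overlap; the
cosine tie-break matters because candidate sets like `CNV_L`/`CNV_H` tie on
whole tokens while differing clearly at the n-gram level. The entire test
suite runs with only these two backends — no network, no model downloads.

## Synthetic fixtures: what they demonstrate

`generateFixture` draws a target table from a fixed pool of ten
clinical-flavored attributes (gender, race, ethnicity, vital status, tumor
focality, CNV class, assay, species, BMI, age at diagnosis) and derives the
source by seeded perturbations: header case changes, snake→camel renaming,
fixed-table abbreviations, one adjacent-character typo per column,
deterministic value recodes (upper-snake forms; CNV classes expand to their
spelled-out variants), a years→days unit switch on the age column, and an
unmapped distractor column. All draws come from one RNG seeded once, so the
same seed reproduces byte-identical tables and ground truth. Default size is
40 rows: enough for stable value frequencies, small enough that the whole
recovery study (20 seeds × match + value-match + materialize) runs in
seconds.

The fixtures emulate the *lexical and structural* heterogeneity of cohort
tables — renamed headers, recoded categories, unit changes — with exact
ground truth. They do not emulate semantic synonymy without lexical overlap
(`sex` vs `gender`), missing-data mechanisms, label noise, or the sheer
attribute counts of production CDMs (hundreds of attributes, thousands of
permissible values). Passing the recovery tests therefore shows the
machinery is correct and well-calibrated for lexical variation, not that
hash-encoder retrieval matches a pretrained encoder's semantic reach on
real CDM-scale matching.

## Numerical choices and degenerate inputs

Tie-breaks are lexicographic (C locale, radix order) everywhere a score
ties. Zero-row tables are valid and flow through name-based matchers; a
zero-column table can arise only from materializing an empty specification.
Empty strings have no 3-grams and hash to the zero vector (cosine 0, i.e.
embedding similarity 0.5); exact-equality forcing handles `"" == ""`.
Distribution comparison of two point masses at the same value is similarity
1 (zero distance) rather than 0/0. The EMD integral is computed on the
pooled breakpoint grid, exact for step CDFs — no binning parameter exists.
Similarity-flooding normalization divides by the iterate maximum, which is
bounded away from zero by the schema-pair node's initial 1.

## Limitations

Single-table inputs only (merge multi-file datasets upstream); no data
cleaning or imputation; no many-to-one mappings; no ontology-code lookup
(ICD/SNOMED) behind value matching; date-times as text; the bundled
standards are small synthetic stand-ins for real CDMs, and the plugin
interface — not the bundled content — is the supported path to production
data models. Matches are proposals: the triage labels and the merge-with-
override workflow exist precisely because no automatic matcher is reliable
enough to skip human review.
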