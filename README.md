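# harmonizr

Schema and value matching for biomedical data harmonization in R.

Clinical and omics datasets describing the same thing rarely share a schema:
one cohort table says `CNV_class` with values `CNV_LOW`/`CNV_HIGH`, the next
says `CNV_status` with `CNV_L`/`CNV_H`; ages come in years here and days
there. Aligning a source table to a target table — or to a common data model
(CDM) with controlled attributes and permissible values — means solving two
problems: **schema matching** (which source column corresponds to which
target attribute?) and **value matching** (which source value corresponds to
which permissible target value, and through what transformation?). harmonizr
provides a composable suite of matchers for both, compiles the result into a
declarative, reusable **harmonization specification**, triages every proposed
match into accept / needs review / reject with an explanation, and
materializes the harmonized dataset. It is aimed at data scientists and
clinical researchers integrating cohort tables or standardizing datasets
against a CDM.

## Methods at a glance

Schema matchers (all return per-column similarities in [0, 1], top-1 or
ranked top-k):

| method | idea |
|---|---|
| `composite_name` | mean of normalized Levenshtein, Jaro–Winkler, token-set Jaccard, and character 3-gram cosine on the attribute names |
| `similarity_flooding` | both schemas become directed graphs; initial name similarities are propagated through the pairwise-connectivity graph until the fixpoint σ⁺(p) = norm(σ(p) + Σ_q σ(q)·w(q,p)) stabilizes |
| `distribution_based` | numeric columns: 1 − EMD of the min–max-scaled empirical distributions (EMD = ∫|ΔCDF|); categorical: 1 − total-variation distance of the value frequencies |
| `jaccard_distance` | fuzzy Jaccard \|I\|/(\|Uₛ\|+\|Uₜ\|−\|I\|) where I pairs values greedily under a normalized-Levenshtein threshold θ |
| `magneto_zs_bp` | columns serialized as `"name: …. values: …"` and embedded (deterministic signed feature hashing by default); cosine retrieval of candidates, then a maximum-weight bipartite assignment (Hungarian algorithm) reranks them one-to-one |
| `magneto_zs_llm` | same retrieval, with a chat adapter picking the winner instead of the assignment |
| `two_phase` | any matcher prunes to top-k, a second matcher rescores the survivors |
| `max_val_sim` | top-k candidates reranked by mean best value-match similarity |
| `llm` | a pluggable chat adapter chooses among candidates (deterministic token-overlap mock by default; no network) |

Value matchers: `edit_distance` (1 − lev/max length, customizable scorer),
`tfidf` (case-folded, `#`-padded character 3-grams, smoothed IDF
ln((1+N)/(1+df))+1, cosine), `embedding` (encoder cosine mapped to [0, 1]),
`llm` (adapter with abstention), plus affine numeric-transform inference for
unit conversions (years → days uses 365.25 with floor rounding).

Everything runs offline: the default encoder is seedless signed feature
hashing, and the default chat adapter is a deterministic token-overlap rule.
Real models are drop-in replacements behind the `TextEncoder` / `ChatAdapter`
contracts.

## Worked example

```r
library(harmonizr)

src <- harmonTable(data.frame(
  Gender    = c("Female", "Male", "Female"),
  CNV_class = c("CNV_LOW", "CNV_HIGH", "CNV_LOW"),
  Age       = c("61", "47", "55"),
  check.names = FALSE), "cohort_2020")

matches <- matchSchema(src, "toy_cdm", method = "magneto_zs_bp")
matches
#>   source_attribute target_attribute similarity
#> 1           Gender           gender  0.8913130
#> 2        CNV_class       cnv_status  0.8171207
#> 3              Age              bmi  0.5938157
```

`Gender` and `CNV_class` land on the right CDM attributes; `Age` (three bare
numbers, a name matching nothing well) is mis-ranked at similarity 0.59 — the
kind of low-confidence match a user reviews and overrides. Value matching on
the two good pairs:

```r
vm <- matchValues(src, "toy_cdm", matches[matches$source_attribute != "Age", ],
                  method = "tfidf")
vm
#>   source_attribute target_attribute source_value target_value similarity
#> 1           Gender           gender       Female       female  1.0000000
#> 2           Gender           gender         Male         male  1.0000000
#> 3        CNV_class       cnv_status      CNV_LOW        CNV_L  0.4372585
#> 4        CNV_class       cnv_status     CNV_HIGH        CNV_H  0.3950183
```

Case-only differences score exactly 1; the CNV spelling variants are aligned
by their shared 3-grams. Build the specification, merge a user override for
`Age` (user entries always take precedence), and materialize:

```r
spec <- buildSpec(matches[matches$source_attribute != "Age", ], vm)
user <- harmonizationSpec(list(mappingEntry(
  "Age", "age_at_diagnosis",
  affineMapper(numericTransform(365.25, 0, "floor", "unit-hint")))))
merged <- mergeMappings(spec, user)

asDataFrame(materialize(src, merged))
#>   gender cnv_status age_at_diagnosis
#> 1 female      CNV_L            22280
#> 2   male      CNV_H            17166
#> 3 female      CNV_L            20088
```

The output has exactly the target attributes, values substituted through the
dictionary mappers, and ages converted from years to days
(61 × 365.25 → 22280, floored). `writeSpec(merged, "spec.json")` saves the
specification for reuse on any table with the same source schema, and
`evaluateSchemaMatches(src, "toy_cdm", matches)` attaches an
accept / needs_review / reject label and an explanation to every match.

A thin command-line front end with the same operations (subcommands
`match-schema`, `rank-schema`, `match-values`, `build-spec`, `merge`,
`materialize`, `evaluate`, `fixture`) lives at `inst/cli/harmonize.R`.

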