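Package: harmonizr
Title: Schema and Value Matching for Biomedical Data Harmonization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A composable suite of schema-matching and value-matching
    algorithms that align a tabular source dataset to a target table or a
    common-data-model standard. Matchers include composite name similarity,
    similarity flooding, Earth mover's distance column-distribution
    comparison, fuzzy Jaccard with Levenshtein pairing, embedding-based
    candidate retrieval with maximum-weight bipartite reranking, two-phase
    pruning, and value-informed reranking; value matchers include edit
    distance, TF-IDF over character n-grams, embeddings, and pluggable
    chat-model adapters with deterministic offline implementations.
    Discovered matches are compiled into a declarative, serializable
    harmonization specification with user-override merging, rule-based match
    triage (accept / needs review / reject), and materialization of the
    harmonized dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'string-similarity.R'
    'AllClasses.R'
    'AllGenerics.R'
    'core-model.R'
    'standards.R'
    'backends.R'
    'assignment.R'
    'similarity-flooding.R'
    'schema-matching.R'
    'value-matching.R'
    'spec-engine.R'
    'match-review.R'
    'fixtures.R'
    'cli.R'
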