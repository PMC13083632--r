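# Schema matcher dispatch, the individual matchers, and their shared
# invariants.

allSchemaMethods <- c("composite_name", "similarity_flooding",
                      "distribution_based", "jaccard_distance",
                      "magneto_zs_bp", "magneto_zs_llm", "two_phase",
                      "max_val_sim", "llm")

test_that("dispatch rejects unknown methods and empty targets", {
  tbl <- harmonTable(data.frame(a = "1"), "t")
  expect_error(matchSchema(tbl, tbl, method = "cupid"), class = "UnknownMethodError")
  empty <- targetSchema(character(0))
  expect_error(matchSchema(tbl, empty), class = "EmptySchemaError")
})

test_that("matchSchema returns one top-1 match per source attribute", {
  fx <- generateFixture(2, nRows = 20, nColumns = 4)
  one <- targetSchema("only_attr", permissibleValues = list(c("x", "y")))
  m <- matchSchema(fx$target, one, method = "composite_name")
  expect_equal(nrow(m), 4L)
  expect_true(all(m$target_attribute == "only_attr"))  # forced
  expect_true(all(m$similarity >= 0 & m$similarity <= 1))
})

test_that("rankings clamp to the target size and agree with matchSchema at top_k = 1", {
  fx <- generateFixture(4, nRows = 20, nColumns = 6)
  tbl <- fx$target
  r <- rankSchemaMatches(tbl, tbl, method = "composite_name", topK = 100L)
  expect_equal(as.integer(table(r$source_attribute)), rep(6L, 6))  # clamp to |target|
  r1 <- rankSchemaMatches(tbl, tbl, method = "composite_name", topK = 1L)
  m <- matchSchema(tbl, tbl, method = "composite_name")
  expect_equal(r1$target_attribute, m$target_attribute)
  expect_equal(r1$similarity, m$similarity)
  # per source attribute: similarity non-increasing with rank
  for (d in split(r, r$source_attribute)) {
    expect_true(all(diff(d$similarity[order(d$rank)]) <= 1e-12))
  }
})

test_that("every matcher self-matches a 10-column fixture perfectly", {
  fx <- generateFixture(6, nRows = 30)
  tbl <- fx$target
  for (method in allSchemaMethods) {
    m <- matchSchema(tbl, asTargetSchema(tbl), method = method)
    expect_equal(mean(m$target_attribute == m$source_attribute), 1.0,
                 info = method)
    expect_true(all(m$similarity >= 0 & m$similarity <= 1), info = method)
  }
})

test_that("matchers are invariant to source row order", {
  fx <- generateFixture(8, nRows = 24, nColumns = 6)
  df <- asDataFrame(fx$target)
  shuffled <- harmonTable(df[rev(seq_len(nrow(df))), , drop = FALSE], "shuffled")
  for (method in c("composite_name", "distribution_based", "jaccard_distance",
                   "magneto_zs_bp")) {
    # free-valued standard attributes legitimately warn under
    # distribution_based; the invariance property is what is under test here
    m1 <- suppressWarnings(matchSchema(fx$target, "toy_cdm", method = method))
    m2 <- suppressWarnings(matchSchema(shuffled, "toy_cdm", method = method))
    expect_equal(m1$target_attribute, m2$target_attribute, info = method)
    expect_equal(m1$similarity, m2$similarity, tolerance = 1e-12, info = method)
  }
})

# --- distribution-based ------------------------------------------------------

test_that("distribution similarity matches the cumulative-difference oracle", {
  # identical numeric columns: zero distance
  a <- harmonTable(data.frame(x = c("0", "0", "1", "1")), "a")
  expect_equal(matchSchema(a, a, method = "distribution_based")$similarity, 1.0)

  # worked example: [0,0,1,1] vs [0,1,1,1]
  b <- harmonTable(data.frame(x = c("0", "1", "1", "1")), "b")
  sim <- matchSchema(a, b, method = "distribution_based")$similarity
  expect_equal(sim, 1 - oracleEmdEqualN(c(0, 0, 1, 1), c(0, 1, 1, 1)),
               tolerance = 1e-12)

  # 100 random equal-size histogram pairs against the closed-form oracle
  set.seed(7)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    x <- round(stats::runif(n, 0, 10), 2)
    y <- round(stats::runif(n, 0, 10), 2)
    ta <- harmonTable(data.frame(v = as.character(x)), "ta")
    tb <- harmonTable(data.frame(v = as.character(y)), "tb")
    sim <- matchSchema(ta, tb, method = "distribution_based")$similarity
    expect_equal(sim, 1 - oracleEmdEqualN(x, y), tolerance = 1e-9, info = i)
  }
})

test_that("categorical columns use total variation; mismatched kinds score 0", {
  # disjoint categorical value sets: TV = 1, similarity 0
  a <- harmonTable(data.frame(x = c("p", "q", "p")), "a")
  b <- harmonTable(data.frame(x = c("r", "s", "r")), "b")
  expect_equal(matchSchema(a, b, method = "distribution_based")$similarity, 0)
  # identical distributions: similarity 1 exactly
  expect_equal(matchSchema(a, a, method = "distribution_based")$similarity, 1)
  # symmetric
  c1 <- harmonTable(data.frame(x = c("p", "q", "q", "q")), "c")
  s1 <- matchSchema(a, c1, method = "distribution_based")$similarity
  s2 <- matchSchema(c1, a, method = "distribution_based")$similarity
  expect_equal(s1, s2)
  # numeric vs text scores 0
  num <- harmonTable(data.frame(x = c("1", "2", "3")), "n")
  expect_equal(matchSchema(num, a, method = "distribution_based")$similarity, 0)
})

test_that("columns with under two observed values warn and score 0", {
  thin <- harmonTable(data.frame(x = c("1", NA, "")), "thin")
  full <- harmonTable(data.frame(x = c("1", "2", "3")), "full")
  expect_warning(
    m <- matchSchema(thin, full, method = "distribution_based"),
    class = "InsufficientDataWarning")
  expect_equal(m$similarity, 0)
})

# --- fuzzy Jaccard -----------------------------------------------------------

test_that("theta = 0 reduces to exact Jaccard on random value-set pairs", {
  set.seed(13)
  vocab <- c("alpha", "beta", "gamma", "delta", "eps", "zeta", "eta", "theta")
  for (i in 1:100) {
    a <- sample(vocab, sample(1:6, 1))
    b <- sample(vocab, sample(1:6, 1))
    exact <- length(intersect(a, b)) / length(union(a, b))
    expect_equal(jaccardLevenshteinSimilarity(a, b, theta = 0), exact, info = i)
  }
})

test_that("fuzzy Jaccard pairs CNV spellings and is monotone in theta", {
  expect_equal(jaccardLevenshteinSimilarity(c("CNV_LOW", "CNV_HIGH"),
                                            c("CNV_L", "CNV_H"), theta = 0.5), 1.0)
  # distances verified by the brute-force oracle
  expect_equal(oracleLevenshtein("cnv_low", "cnv_l") / 7, 2 / 7)
  expect_equal(oracleLevenshtein("cnv_high", "cnv_h") / 8, 3 / 8)
  set.seed(21)
  vocab <- c("male", "mal", "female", "fem", "unknown", "unk")
  for (i in 1:30) {
    a <- sample(vocab, sample(2:5, 1))
    b <- sample(vocab, sample(2:5, 1))
    thetas <- c(0, 0.2, 0.4, 0.8, 1)
    sims <- vapply(thetas, function(th) jaccardLevenshteinSimilarity(a, b, th),
                   numeric(1))
    expect_true(all(diff(sims) >= -1e-12), info = i)
  }
})

test_that("greedy pairing agrees with exhaustive pairing on small sets", {
  set.seed(33)
  vocab <- c("ab", "abc", "abcd", "xy", "xyz", "wxyz")
  agree <- 0; total <- 0
  for (i in 1:50) {
    a <- sample(vocab, sample(2:5, 1))
    b <- sample(vocab, sample(2:5, 1))
    greedy <- nrow(harmonizr:::greedyFuzzyPairs(a, b, 0.5))
    optimal <- oracleMaxFuzzyPairs(a, b, 0.5)
    expect_lte(greedy, optimal)
    total <- total + 1
    if (greedy == optimal) agree <- agree + 1
  }
  # greedy should achieve the optimum in the overwhelming majority of cases
  expect_gte(agree / total, 0.9)
})

# --- magneto -----------------------------------------------------------------

test_that("magneto reranking enforces one-to-one on competing sources", {
  # two source columns with identical content compete for one target
  src <- harmonTable(data.frame(gender = c("female", "male"),
                                gender_copy = c("female", "male"),
                                check.names = FALSE), "s")
  tgt <- harmonTable(data.frame(gender = c("female", "male"),
                                other = c("x", "y"), check.names = FALSE), "t")
  m <- matchSchema(src, tgt, method = "magneto_zs_bp")
  expect_equal(sum(m$target_attribute == "gender"), 1L)
})

test_that("magneto recovers perturbed headers with the hash encoder", {
  hits <- 0; total <- 0
  for (s in 1:5) {
    fx <- generateFixture(s, perturbations = c("case_change", "snake_camel"))
    m <- matchSchema(fx$source, fx$target, method = "magneto_zs_bp")
    gt <- fx$groundTruth$attributeMap
    hits <- hits + sum(gt[m$source_attribute] == m$target_attribute)
    total <- total + nrow(m)
  }
  expect_gte(hits / total, 0.9)
})

test_that("column serialization caps at 15 values and embeds to unit norm", {
  txt <- harmonizr:::serializeColumn("bmi", sprintf("v%02d", 20:1))
  expect_match(txt, "^name: bmi\\. values: v01, v02")
  expect_false(grepl("v16", txt))
  # serialization (hence the embedding) is invariant to value order
  expect_identical(txt, harmonizr:::serializeColumn("bmi", sprintf("v%02d", 1:20)))
  v <- embedColumn("bmi", c("22.1", "30.4"), hashEncoder())
  expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-12)
  expect_equal(embedColumn("empty", character(0), hashEncoder()),
               as.numeric(encodeText(hashEncoder(), "name: empty. values:")))
})

# --- two-phase and value-informed reranking ----------------------------------

test_that("two_phase with equal phases or prune_k = 1 degenerates to phase 1", {
  fx <- generateFixture(9, nRows = 20, nColumns = 5)
  tbl <- fx$target
  same <- rankSchemaMatches(tbl, tbl, method = "two_phase",
                            methodArgs = list(phase1 = "composite_name",
                                              phase2 = "composite_name"))
  plain <- rankSchemaMatches(tbl, tbl, method = "composite_name")
  expect_equal(same[same$rank == 1, "target_attribute"],
               plain[plain$rank == 1, "target_attribute"])

  k1 <- rankSchemaMatches(tbl, tbl, method = "two_phase",
                          methodArgs = list(phase1 = "composite_name",
                                            phase2 = "jaccard_distance",
                                            prune_k = 1))
  expect_equal(k1$target_attribute, plain[plain$rank == 1, "target_attribute"])
})

test_that("two_phase lets value evidence overrule misleading names", {
  # names point to status_code, values agree with condition_class
  src <- harmonTable(data.frame(status = c("CNV_LOW", "CNV_HIGH", "CNV_LOW")), "s")
  tgt <- targetSchema(c("status_code", "condition_class"),
                      permissibleValues = list(c("9001", "9002"),
                                               c("CNV_LOW", "CNV_HIGH")))
  m <- matchSchema(src, tgt, method = "two_phase",
                   methodArgs = list(phase1 = "composite_name",
                                     phase2 = "jaccard_distance", prune_k = 5))
  expect_equal(m$target_attribute, "condition_class")
})

test_that("max_val_sim reranks by how well values match", {
  geo <- geoSourceTable()
  r <- rankSchemaMatches(geo, "toy_geo", method = "max_val_sim", topK = 4)
  assay <- r[r$source_attribute == "Assay Type" & r$rank == 1, ]
  expect_equal(assay$target_attribute, "Assay")
  organism <- r[r$source_attribute == "Organism" & r$rank == 1, ]
  expect_equal(organism$target_attribute, "Species")

  # candidate with an identical value set scores exactly 1
  src <- harmonTable(data.frame(cnv = c("CNV_L", "CNV_H")), "s")
  tgt <- targetSchema(c("cnv_status", "noise"),
                      permissibleValues = list(c("CNV_L", "CNV_H"), c("a", "b")))
  m <- rankSchemaMatches(src, tgt, method = "max_val_sim", topK = 2)
  expect_equal(m$similarity[m$target_attribute == "cnv_status"], 1.0)

  # value scores equal the independent mean-of-best-similarity oracle
  svals <- c("CNV_LOW", "CNV_HIGH")
  for (cand in list(c("CNV_L", "CNV_H"), c("a", "b"))) {
    sim <- valueTfidf(svals, cand)
    oracle <- mean(vapply(seq_along(svals), function(i) {
      max(vapply(seq_along(cand), function(j) {
        oracleTfidfCosine(svals[i], cand[j], c(svals, cand))
      }, numeric(1)))
    }, numeric(1)))
    expect_equal(mean(apply(sim, 1, max)), oracle, tolerance = 1e-9)
  }
})

# --- chat-model matcher -------------------------------------------------------

test_that("the mock-adapter matcher solves the clinical worked example", {
  rcc <- rccSourceTable()
  m <- matchSchema(rcc, "toy_cdm", method = "llm")
  expect_equal(m$target_attribute[m$source_attribute == "Gender"], "gender")
  expect_equal(m$target_attribute[m$source_attribute == "Race"], "race")
})

test_that("adapter failures fall back to composite_name with a warning", {
  setClass("ThrowingAdapter", contains = "ChatAdapter",
           where = environment())
  setMethod("selectCandidate", "ThrowingAdapter",
            function(adapter, candidates, query) stop("backend down"),
            where = environment())
  bad <- new("ThrowingAdapter", name = "bad", modelId = "none")
  tbl <- harmonTable(data.frame(gender = c("f", "m")), "t")
  expect_warning(
    m <- matchSchema(tbl, "toy_cdm", method = "llm",
                     methodArgs = list(adapter = bad)),
    class = "AdapterFallbackWarning")
  comp <- matchSchema(tbl, "toy_cdm", method = "composite_name")
  expect_equal(m$target_attribute, comp$target_attribute)
})

test_that("out-of-candidate-set adapter answers are rejected", {
  setClass("RogueAdapter", contains = "ChatAdapter", where = environment())
  setMethod("selectCandidate", "RogueAdapter",
            function(adapter, candidates, query) {
              list(choice = "made_up_attribute", confidence = 0.99)
            }, where = environment())
  rogue <- new("RogueAdapter", name = "rogue", modelId = "none")
  tbl <- harmonTable(data.frame(gender = c("f", "m")), "t")
  m <- matchSchema(tbl, "toy_cdm", method = "llm",
                   methodArgs = list(adapter = rogue))
  expect_false("made_up_attribute" %in% m$target_attribute)
  # falls back to the next-best (composite) candidate
  comp <- matchSchema(tbl, "toy_cdm", method = "composite_name")
  expect_equal(m$target_attribute, comp$target_attribute)
})
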