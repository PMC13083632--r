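# Value matchers and numeric-transform inference.

test_that("edit-distance similarity matches the textbook oracle", {
  expect_equal(valueEditDistance("kitten", "kitten"), 1.0)
  expect_equal(valueEditDistance("kitten", "sitting"), 1 - 3 / 7)
  expect_equal(oracleLevenshtein("kitten", "sitting"), 3)
  expect_equal(valueEditDistance("a", ""), 0.0)
  expect_equal(valueEditDistance("", ""), 1.0)
  # case-insensitive equality scores 1 under the default scorer
  expect_equal(valueEditDistance("Female", "female"), 1.0)
})

test_that("custom scorers are contract-checked", {
  expect_equal(valueEditDistance("ab", "cd", scorer = function(s, t) 0.25), 0.25)
  expect_error(valueEditDistance("ab", "cd", scorer = function(s, t) 2),
               class = "ScorerContractError")
  expect_error(valueEditDistance("ab", "cd", scorer = function(s, t) -0.1),
               class = "ScorerContractError")
})

test_that("tfidf matches an independent oracle and forces equality to 1", {
  expect_equal(valueTfidf("x", "x")[1, 1], 1.0)
  expect_equal(valueTfidf("RNA-Seq", "RNA-seq")[1, 1], 1.0)  # case-insensitive

  m <- valueTfidf(c("CNV_LOW", "CNV_HIGH"), c("CNV_L", "CNV_H"))
  expect_equal(colnames(m)[apply(m, 1, which.max)], c("CNV_L", "CNV_H"))

  # full matrix against the independently coded oracle on a toy vocabulary
  sources <- c("abx", "aby")
  targets <- c("abz", "qrs")
  got <- valueTfidf(sources, targets)
  docs <- c(sources, targets)
  for (i in 1:2) {
    for (j in 1:2) {
      expect_equal(got[i, j], oracleTfidfCosine(sources[i], targets[j], docs),
                   tolerance = 1e-9)
    }
  }
  # symmetry in the two string arguments
  expect_equal(valueTfidf("abx", "abz")[1, 1], valueTfidf("abz", "abx")[1, 1])
})

test_that("embedding similarity maps cosine into [0, 1]", {
  expect_equal(valueEmbedding("Female", "female")[1, 1], 1.0)
  # oracle cosine of hashed n-gram vectors
  enc <- hashEncoder(64L)
  got <- valueEmbedding("Female", "male", enc)[1, 1]
  oracle <- (sum(oracleHashVector("Female", 64) * oracleHashVector("male", 64)) + 1) / 2
  expect_equal(got, oracle, tolerance = 1e-12)
  # the empty string hashes to the zero vector: zero cosine maps to 0.5
  expect_equal(valueEmbedding("", "anything", enc)[1, 1], 0.5)
})

test_that("matchValues aligns the CNV worked example and applies tau", {
  src <- harmonTable(data.frame(CNV_class = c("CNV_LOW", "CNV_HIGH", "CNV_LOW")), "s")
  tgt <- harmonTable(data.frame(CNV_status = c("CNV_L", "CNV_H")), "t")
  pairs <- data.frame(source_attribute = "CNV_class", target_attribute = "CNV_status")
  vm <- matchValues(src, tgt, pairs, method = "tfidf")
  expect_equal(vm$target_value[vm$source_value == "CNV_LOW"], "CNV_L")
  expect_equal(vm$target_value[vm$source_value == "CNV_HIGH"], "CNV_H")
  expect_true(all(!is.na(vm$target_value)))

  # identical value sets: everything matches at 1.0
  vm2 <- matchValues(tgt, tgt,
                     data.frame(source_attribute = "CNV_status",
                                target_attribute = "CNV_status"))
  expect_true(all(vm2$similarity == 1.0))

  # tau = 1 with disjoint sets: all unmatched, but all values covered
  far <- harmonTable(data.frame(CNV_status = c("zzz", "qqq")), "f")
  vm3 <- matchValues(far, tgt,
                     data.frame(source_attribute = "CNV_status",
                                target_attribute = "CNV_status"), tau = 1.0)
  expect_true(all(is.na(vm3$target_value)))
  expect_setequal(vm3$source_value, c("zzz", "qqq"))
})

test_that("value rankings surface near-misses like truncated identifiers", {
  # "131" among channel labels: "131N" is the only label containing it
  src <- harmonTable(data.frame(channel = c("131", "130C")), "s")
  tgt <- targetSchema("ReporterName",
                      permissibleValues = list(c("131N", "130C", "129N",
                                                 "128C", "127N", "126")))
  pairs <- data.frame(source_attribute = "channel", target_attribute = "ReporterName")
  for (method in c("tfidf", "edit_distance")) {
    r <- rankValueMatches(src, tgt, pairs, method = method, topK = 3)
    top <- r[r$source_value == "131" & r$rank == 1, ]
    expect_equal(top$target_value, "131N", info = method)
  }
  # top_k clamps to the candidate count
  r <- rankValueMatches(src, tgt, pairs, method = "tfidf", topK = 50)
  expect_equal(max(r$rank), 6L)
})

test_that("value matching errors on attributes without permissible values", {
  src <- harmonTable(data.frame(age = c("1", "2")), "s")
  tgt <- targetSchema("age_at_index")  # free numeric, no values
  expect_error(
    matchValues(src, tgt, data.frame(source_attribute = "age",
                                     target_attribute = "age_at_index")),
    class = "MissingValuesError")
  expect_error(
    matchValues(src, tgt, data.frame(source_attribute = "age",
                                     target_attribute = "age_at_index"),
                method = "nope"),
    class = "UnknownMethodError")
})

test_that("the adapter value matcher honors abstention and set membership", {
  src <- harmonTable(data.frame(CNV_class = c("CNV_LOW", "CNV_HIGH")), "s")
  tgt <- harmonTable(data.frame(CNV_status = c("CNV_L", "CNV_H")), "t")
  pairs <- data.frame(source_attribute = "CNV_class", target_attribute = "CNV_status")

  # mock adapter reproduces the tfidf worked example on the CNV pair
  vmMock <- matchValues(src, tgt, pairs, method = "llm")
  vmTfidf <- matchValues(src, tgt, pairs, method = "tfidf")
  expect_equal(vmMock$target_value, vmTfidf$target_value)

  # an always-abstaining adapter leaves every value unmatched
  setClass("AbstainAdapter", contains = "ChatAdapter", where = environment())
  setMethod("selectCandidate", "AbstainAdapter",
            function(adapter, candidates, query) NULL, where = environment())
  vmAbstain <- matchValues(src, tgt, pairs, method = "llm",
                           methodArgs = list(adapter = new("AbstainAdapter",
                                                           name = "a", modelId = "")))
  expect_true(all(is.na(vmAbstain$target_value)))

  # out-of-set answers are rejected; the next-best candidate is used
  setClass("RogueValueAdapter", contains = "ChatAdapter", where = environment())
  setMethod("selectCandidate", "RogueValueAdapter",
            function(adapter, candidates, query) {
              list(choice = "NOT_A_VALUE", confidence = 1)
            }, where = environment())
  vmRogue <- matchValues(src, tgt, pairs, method = "llm",
                         methodArgs = list(adapter = new("RogueValueAdapter",
                                                         name = "r", modelId = "")))
  expect_equal(vmRogue$target_value, vmTfidf$target_value)
})

test_that("numeric transforms follow unit hints", {
  tr <- inferNumericTransform(c("25", "61", "47"), list(unit = "days"),
                              sourceUnit = "years")
  expect_equal(tr@scale, 365.25)
  expect_equal(tr@rounding, "floor")
  expect_equal(applyNumericTransform(tr, 25), 9131)

  tr2 <- inferNumericTransform(c("25", "61", "47"), list(unit = "months"),
                               sourceUnit = "years")
  expect_equal(tr2@scale, 12)

  same <- inferNumericTransform(c("25", "61", "47"), list(unit = "years"),
                                sourceUnit = "years")
  expect_equal(same@scale, 1)
  expect_equal(same@offset, 0)

  none <- inferNumericTransform(c("25", "61", "47"), list())
  expect_equal(none@provenance, "no-evidence")
  expect_equal(none@scale, 1)

  expect_error(inferNumericTransform(c("a", "b", "c"), list(unit = "days")),
               class = "NotNumericError")
  expect_error(inferNumericTransform(c("1", "2"), list(unit = "days")),
               class = "NotNumericError")
})

test_that("a transform composed with its inverse recovers the input", {
  set.seed(5)
  for (scale in c(12, 365.25, 1 / 12, 1000, 0.5)) {
    tr <- numericTransform(scale, offset = stats::runif(1, -10, 10))
    x <- stats::runif(20, -100, 100)
    back <- applyNumericTransform(invertNumericTransform(tr),
                                  applyNumericTransform(tr, x))
    expect_equal(back, x, tolerance = 1e-9)
  }
})
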