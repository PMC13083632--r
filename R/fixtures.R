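# Synthetic fixture generator: clinical-flavored source/target table pairs
# with known ground truth, used by the tests and the acceptance checks. The
# attribute pool and its perturbations emulate the renamings, case changes,
# value recodings and unit conversions seen when aligning published cohort
# tables to a common data model.

# Fixed attribute pool (target side). Each generator draws from the shared
# RNG stream so fixtures are reproducible from the seed alone.
.fixturePool <- list(
  gender = list(kind = "text",
                gen = function(n) sample(c("female", "male", "unknown"), n, TRUE,
                                         prob = c(0.48, 0.48, 0.04))),
  race = list(kind = "text",
              gen = function(n) sample(c("white", "black or african american",
                                         "asian", "other"), n, TRUE,
                                       prob = c(0.55, 0.2, 0.15, 0.1))),
  ethnicity = list(kind = "text",
                   gen = function(n) sample(c("hispanic or latino",
                                              "not hispanic or latino"), n, TRUE,
                                            prob = c(0.2, 0.8))),
  vital_status = list(kind = "text",
                      gen = function(n) sample(c("alive", "dead"), n, TRUE,
                                               prob = c(0.7, 0.3))),
  tumor_focality = list(kind = "text",
                        gen = function(n) sample(c("unifocal", "multifocal"), n, TRUE,
                                                 prob = c(0.75, 0.25))),
  CNV_status = list(kind = "text",
                    gen = function(n) sample(c("CNV_L", "CNV_H"), n, TRUE)),
  Assay = list(kind = "text", gen = function(n) rep("RNA-seq", n)),
  Species = list(kind = "text", gen = function(n) rep("Homo sapiens", n)),
  bmi = list(kind = "numeric",
             gen = function(n) as.character(round(stats::runif(n, 18, 45), 1))),
  age_at_diagnosis = list(kind = "numeric",
                          gen = function(n) as.character(sample(30:90, n, TRUE)))
)

# Fixed, versioned abbreviation table (header truncations).
.fixtureAbbreviations <- c(
  age_at_diagnosis = "age",
  tumor_focality = "focality",
  vital_status = "vital",
  ethnicity = "ethn",
  CNV_status = "CNV"
)

.fixturePerturbations <- c("case_change", "snake_camel", "abbreviation",
                           "typo", "value_recode", "unit_scale",
                           "distractor_column")

# Value recode: upper-snake form of the target value; CNV classes expand to
# their spelled-out variants (the lexical variation the value matchers are
# expected to bridge).
.recodeValue <- function(attr, v) {
  if (attr == "CNV_status") {
    return(c(CNV_L = "CNV_LOW", CNV_H = "CNV_HIGH")[[v]])
  }
  toupper(gsub("[ -]+", "_", v))
}

.snakeToCamel <- function(x) {
  parts <- strsplit(x, "_", fixed = TRUE)[[1]]
  paste(toupper(substring(parts, 1, 1)), substring(parts, 2), sep = "", collapse = "")
}

.titleCase <- function(x) {
  gsub("(^|[_ -])([a-z])", "\\1\\U\\2", x, perl = TRUE)
}

# Adjacent-character transposition at a seeded position.
.typoValue <- function(v) {
  n <- nchar(v)
  if (n < 3) return(v)
  i <- sample(seq_len(n - 1L), 1L)
  paste0(substring(v, 1, i - 1), substring(v, i + 1, i + 1),
         substring(v, i, i), substring(v, i + 2, n))
}

#' Generate a synthetic source/target fixture with ground truth
#'
#' Draws a target table from a fixed clinical-flavored attribute pool
#' (gender, race, ethnicity, vital_status, tumor_focality, CNV_status,
#' Assay, Species, bmi, age_at_diagnosis) and derives the source table by
#' applying the requested perturbations. The returned ground truth records
#' the source-to-target attribute map, the per-attribute value maps (source
#' value to target value), and any numeric transforms, so matching accuracy
#' can be measured exactly. Regenerating with the same seed reproduces
#' byte-identical tables and ground truth.
#'
#' @param seed Integer RNG seed.
#' @param nRows Number of rows (>= 1; default 40).
#' @param perturbations Subset of \code{case_change}, \code{snake_camel},
#'   \code{abbreviation}, \code{typo}, \code{value_recode},
#'   \code{unit_scale}, \code{distractor_column}.
#' @param nColumns Number of pool attributes to use (default: all 10).
#' @return List with elements \code{source} and \code{target}
#'   (\linkS4class{HarmonTable}s) and \code{groundTruth} (list with
#'   \code{attributeMap}, \code{valueMaps}, \code{transforms}).
#' @examples
#' fx <- generateFixture(7, perturbations = "case_change")
#' fx$groundTruth$attributeMap
#' @export
generateFixture <- function(seed, nRows = 40L, perturbations = character(0),
                            nColumns = length(.fixturePool)) {
  stopifnot(nRows >= 1)
  bad <- setdiff(perturbations, .fixturePerturbations)
  if (length(bad) > 0) {
    stopHarmonizr("UnknownMethodError",
                  sprintf("unknown perturbations: %s", paste(bad, collapse = ", ")))
  }
  oldSeed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(oldSeed)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", oldSeed, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  pool <- .fixturePool[seq_len(min(nColumns, length(.fixturePool)))]
  target <- lapply(names(pool), function(a) pool[[a]]$gen(nRows))
  names(target) <- names(pool)

  # per text column: map target value -> current source form
  sourceForm <- lapply(names(pool), function(a) {
    vals <- unique(target[[a]])
    stats::setNames(vals, vals)
  })
  names(sourceForm) <- names(pool)
  touched <- stats::setNames(rep(FALSE, length(pool)), names(pool))
  transforms <- list()

  # unit_scale: source keeps years, target switches to days
  unitScaled <- "unit_scale" %in% perturbations && "age_at_diagnosis" %in% names(pool)
  sourceAge <- target$age_at_diagnosis
  if (unitScaled) {
    years <- as.numeric(target$age_at_diagnosis)
    target$age_at_diagnosis <- as.character(floor(years * 365.25))
    transforms$age_at_diagnosis <- numericTransform(365.25, 0, "floor",
                                                    provenance = "unit-hint")
  }

  if ("value_recode" %in% perturbations) {
    for (a in names(pool)) {
      if (pool[[a]]$kind != "text") next
      sourceForm[[a]][] <- vapply(names(sourceForm[[a]]),
                                  function(v) .recodeValue(a, v), character(1))
      touched[a] <- TRUE
    }
  }

  if ("case_change" %in% perturbations) {
    for (a in names(pool)) {
      if (pool[[a]]$kind != "text" || touched[a]) next
      if (sample(c(TRUE, FALSE), 1L)) {
        sourceForm[[a]][] <- .titleCase(sourceForm[[a]])
        touched[a] <- TRUE
      }
    }
  }

  if ("typo" %in% perturbations) {
    for (a in names(pool)) {
      if (pool[[a]]$kind != "text") next
      forms <- sourceForm[[a]]
      pick <- sample(length(forms), 1L)
      typo <- .typoValue(forms[pick])
      if (!typo %in% forms) {
        sourceForm[[a]][pick] <- typo
        touched[a] <- TRUE
      }
    }
  }

  # assemble source cells
  source <- lapply(names(pool), function(a) {
    if (pool[[a]]$kind == "text") {
      unname(sourceForm[[a]][target[[a]]])
    } else if (a == "age_at_diagnosis" && unitScaled) {
      sourceAge
    } else {
      target[[a]]
    }
  })
  names(source) <- names(pool)

  # header perturbations, applied in a fixed order
  srcNames <- names(pool)
  newNames <- srcNames
  if ("abbreviation" %in% perturbations) {
    hit <- intersect(names(.fixtureAbbreviations), newNames)
    newNames[match(hit, srcNames)] <- unname(.fixtureAbbreviations[hit])
  }
  if ("snake_camel" %in% perturbations) {
    newNames <- vapply(newNames, .snakeToCamel, character(1))
  }
  if ("case_change" %in% perturbations) {
    styles <- sample(c("upper", "title"), length(newNames), TRUE)
    newNames <- vapply(seq_along(newNames), function(i) {
      if (styles[i] == "upper") toupper(newNames[i]) else .titleCase(newNames[i])
    }, character(1))
  }
  names(source) <- newNames

  attributeMap <- stats::setNames(names(pool), newNames)
  valueMaps <- list()
  for (a in names(pool)) {
    if (pool[[a]]$kind == "text" && touched[a]) {
      valueMaps[[newNames[match(a, srcNames)]]] <-
        stats::setNames(names(sourceForm[[a]]), unname(sourceForm[[a]]))
    }
  }
  if (length(transforms) > 0) {
    names(transforms) <- newNames[match(names(transforms), srcNames)]
  }

  if ("distractor_column" %in% perturbations) {
    source$free_text_notes <- replicate(nRows, paste(
      sample(letters, 8, TRUE), collapse = ""))
  }

  list(
    source = harmonTable(as.data.frame(source, check.names = FALSE,
                                       stringsAsFactors = FALSE),
                         name = sprintf("fixture_source_%d", seed)),
    target = harmonTable(as.data.frame(target, check.names = FALSE,
                                       stringsAsFactors = FALSE),
                         name = sprintf("fixture_target_%d", seed)),
    groundTruth = list(attributeMap = attributeMap, valueMaps = valueMaps,
                       transforms = transforms)
  )
}
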