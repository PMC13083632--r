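#' @import methods
NULL

#' HarmonTable: a validated tabular dataset
#'
#' The universal input/output container: a named table whose cells are text,
#' numbers (stored as their text form), or missing. Column names must be
#' unique and non-empty; all columns have identical length. Cells are stored
#' as character; missing cells are \code{NA} (the sentinels \code{""},
#' \code{"NA"}, \code{"NaN"}, \code{"null"} are normalized to \code{NA} on
#' construction).
#'
#' @slot name Text label for the table.
#' @slot data A data.frame of character columns holding the cells.
#' @export
setClass("HarmonTable", representation(
  name = "character",
  data = "data.frame"
))

setValidity("HarmonTable", function(object) {
  nm <- colnames(object@data)
  # zero columns are allowed (e.g. materializing an empty specification);
  # harmonTable() rejects them for parsed input
  if (ncol(object@data) == 0) return(TRUE)
  if (any(!nzchar(nm)) || anyNA(nm)) return("column names must be non-empty")
  if (anyDuplicated(nm)) return("column names must be unique")
  if (!all(vapply(object@data, is.character, logical(1)))) {
    return("all columns must be stored as character vectors")
  }
  TRUE
})

#' TargetSchema: a uniform view over a table or data-model standard
#'
#' Attributes with optional permissible values and metadata. When the schema
#' originates from a table, each attribute's permissible values are the
#' distinct non-missing values of the corresponding column (first-occurrence
#' order) and \code{valueCounts} records how often each permissible value
#' occurred, so distribution-aware matchers can compare frequencies.
#'
#' @slot attributes Attribute names (unique).
#' @slot descriptions Parallel character vector of descriptions.
#' @slot permissibleValues Named list (by attribute) of character vectors,
#'   possibly empty (free-valued attributes).
#' @slot valueCounts Named list of numeric vectors parallel to
#'   \code{permissibleValues} (empty for standards, where values are
#'   enumerated without frequencies).
#' @slot metadata Named list (by attribute) of key->text maps; always
#'   contains a \code{description} key.
#' @slot origin \code{"table"} or \code{"standard:<name>"}.
#' @export
setClass("TargetSchema", representation(
  attributes = "character",
  descriptions = "character",
  permissibleValues = "list",
  valueCounts = "list",
  metadata = "list",
  origin = "character"
))

setValidity("TargetSchema", function(object) {
  n <- length(object@attributes)
  if (anyDuplicated(object@attributes)) return("attribute names must be unique")
  if (length(object@descriptions) != n) return("descriptions length mismatch")
  if (length(object@permissibleValues) != n) return("permissibleValues length mismatch")
  if (length(object@metadata) != n) return("metadata length mismatch")
  dup <- vapply(object@permissibleValues, anyDuplicated, integer(1))
  if (any(dup > 0)) return("permissible values must contain no duplicates")
  TRUE
})

#' StandardModel: a pluggable data-model standard
#'
#' A named common-data-model standard exposing the four-accessor interface
#' (\code{\link{getAttributes}}, \code{\link{getAttributeValues}},
#' \code{\link{getAttributeMetadata}}, \code{\link{getTableRepresentation}}).
#'
#' @slot name Standard name (e.g. \code{"toy_cdm"}).
#' @slot schema The \linkS4class{TargetSchema} holding its attributes.
#' @slot provenance File path the standard was loaded from, or
#'   \code{"builtin"}.
#' @export
setClass("StandardModel", representation(
  name = "character",
  schema = "TargetSchema",
  provenance = "character"
))

#' NumericTransform: an affine numeric value conversion
#'
#' \code{value * scale + offset}, followed by optional rounding. Used for
#' unit conversions such as age in years to age in days.
#'
#' @slot scale Multiplicative factor (non-zero).
#' @slot offset Additive offset.
#' @slot rounding One of \code{"none"}, \code{"floor"}, \code{"nearest"}.
#' @slot provenance How the transform was inferred (e.g. \code{"unit-hint"},
#'   \code{"adapter"}, \code{"no-evidence"}).
#' @export
setClass("NumericTransform", representation(
  scale = "numeric",
  offset = "numeric",
  rounding = "character",
  provenance = "character"
))

setValidity("NumericTransform", function(object) {
  if (length(object@scale) != 1 || object@scale == 0) return("scale must be a single non-zero number")
  if (!object@rounding %in% c("none", "floor", "nearest")) {
    return("rounding must be one of none, floor, nearest")
  }
  TRUE
})

#' HarmonizationSpec: the declarative harmonization specification
#'
#' An ordered list of mapping entries, each tying a source attribute to a
#' target attribute through a mapper (identity, dictionary, affine, or a
#' named custom routine). One-to-one and one-to-many mappings are allowed
#' (the same source may feed several targets); many-to-one mappings (two
#' sources feeding one target) are rejected.
#'
#' @slot version Document version string.
#' @slot entries List of entries; each entry is a list with elements
#'   \code{source_attribute}, \code{target_attribute}, \code{mapper},
#'   \code{similarity} (may be \code{NA}), \code{provenance}.
#' @export
setClass("HarmonizationSpec", representation(
  version = "character",
  entries = "list"
))

setValidity("HarmonizationSpec", function(object) {
  if (length(object@entries) == 0) return(TRUE)
  src <- vapply(object@entries, function(e) e$source_attribute, character(1))
  tgt <- vapply(object@entries, function(e) e$target_attribute, character(1))
  if (anyDuplicated(paste0(src, "\r", tgt))) {
    return("duplicate (source_attribute, target_attribute) entries")
  }
  collide <- tapply(src, tgt, function(s) length(unique(s)))
  if (any(collide > 1)) {
    bad <- names(collide)[collide > 1][1]
    return(sprintf("many-to-one mapping onto target '%s' is not supported", bad))
  }
  for (e in object@entries) {
    m <- e$mapper
    if (!m$type %in% c("identity", "dictionary", "affine", "custom")) {
      return(sprintf("unknown mapper type '%s'", m$type))
    }
    if (m$type == "dictionary" && anyDuplicated(names(m$map))) {
      return("dictionary keys must be unique")
    }
    if (m$type == "affine" && m$transform@scale == 0) return("affine scale must be non-zero")
  }
  TRUE
})

#' TextEncoder: contract for deterministic text embedding backends
#'
#' Encoders turn texts into fixed-dimension unit-norm vectors via
#' \code{\link{encodeText}}. The bundled \linkS4class{HashTextEncoder} is a
#' deterministic offline implementation; pretrained encoders can be plugged
#' in behind the same contract.
#'
#' @slot name Backend name.
#' @slot dimension Output dimensionality.
#' @export
setClass("TextEncoder", representation(
  name = "character",
  dimension = "integer",
  "VIRTUAL"
))

#' HashTextEncoder: signed feature-hashing text encoder
#'
#' Character 3-gram counts are feature-hashed with signed hashing into
#' \code{dimension} buckets and L2-normalized. Seedless and stable across
#' runs and platforms.
#'
#' @export
setClass("HashTextEncoder", contains = "TextEncoder")

setValidity("HashTextEncoder", function(object) {
  if (object@dimension < 16L) return("dimension must be >= 16")
  TRUE
})

#' ChatAdapter: contract for chat-style model backends
#'
#' Adapters answer candidate-selection queries via
#' \code{\link{selectCandidate}}; responses are validated against the
#' offered candidate set and abstention is an allowed response.
#'
#' @slot name Backend name.
#' @slot modelId Identifier of the underlying model.
#' @export
setClass("ChatAdapter", representation(
  name = "character",
  modelId = "character",
  "VIRTUAL"
))

#' MockChatAdapter: deterministic offline chat adapter
#'
#' Picks the candidate maximizing token overlap with the query context;
#' confidence is the overlap fraction; abstains when the overlap is zero;
#' ties go to the lexicographically smallest candidate.
#'
#' @export
setClass("MockChatAdapter", contains = "ChatAdapter")
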