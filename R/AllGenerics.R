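# Generics for the four-accessor standard interface, encoders and adapters.

#' @rdname standards-accessors
#' @export
setGeneric("getAttributes", function(x) standardGeneric("getAttributes"))

#' @rdname standards-accessors
#' @export
setGeneric("getAttributeValues", function(x, attribute) standardGeneric("getAttributeValues"))

#' @rdname standards-accessors
#' @export
setGeneric("getAttributeMetadata", function(x, attribute) standardGeneric("getAttributeMetadata"))

#' @rdname standards-accessors
#' @export
setGeneric("getTableRepresentation", function(x) standardGeneric("getTableRepresentation"))

#' Encode texts into unit-norm vectors
#'
#' @param encoder A \linkS4class{TextEncoder}.
#' @param texts Character vector.
#' @return Numeric matrix with one unit-norm row per text.
#' @export
setGeneric("encodeText", function(encoder, texts) standardGeneric("encodeText"))

#' Ask a chat adapter to select a candidate
#'
#' @param adapter A \linkS4class{ChatAdapter}.
#' @param candidates A data.frame with at least a \code{name} column and an
#'   optional \code{context} column (descriptions / sample values).
#' @param query Character context describing what to match.
#' @return \code{list(choice=, confidence=)} or \code{NULL} to abstain.
#' @export
setGeneric("selectCandidate", function(adapter, candidates, query) standardGeneric("selectCandidate"))

#' @rdname HarmonTable-accessors
#' @export
setGeneric("tableName", function(x) standardGeneric("tableName"))

#' @rdname HarmonTable-accessors
#' @export
setGeneric("columnNames", function(x) standardGeneric("columnNames"))

#' @rdname HarmonTable-accessors
#' @export
setGeneric("columnCells", function(x, column) standardGeneric("columnCells"))

#' @rdname HarmonTable-accessors
#' @export
setGeneric("distinctValues", function(x, column) standardGeneric("distinctValues"))

#' @rdname HarmonTable-accessors
#' @export
setGeneric("columnKind", function(x, column) standardGeneric("columnKind"))

#' Convert an object to a TargetSchema
#'
#' @param x Object to convert.
#' @return A \linkS4class{TargetSchema}.
#' @export
setGeneric("asTargetSchema", function(x) standardGeneric("asTargetSchema"))

#' @rdname TargetSchema-accessors
#' @export
setGeneric("attributeNames", function(x) standardGeneric("attributeNames"))

#' @rdname TargetSchema-accessors
#' @export
setGeneric("permissibleValues", function(x, attribute) standardGeneric("permissibleValues"))

#' @rdname TargetSchema-accessors
#' @export
setGeneric("attributeMetadata", function(x, attribute) standardGeneric("attributeMetadata"))

#' @rdname HarmonizationSpec-accessors
#' @export
setGeneric("specEntries", function(x) standardGeneric("specEntries"))
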