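# Core data model: validated tables, column-kind inference, target schemas.

#' Construct a HarmonTable from a data.frame
#'
#' Cells are coerced to character; missing-value sentinels (\code{""},
#' \code{"NA"}, \code{"NaN"}, \code{"null"}, case-insensitive) become
#' \code{NA}. Column names must be unique and non-empty.
#'
#' @param data A data.frame (or object coercible to one).
#' @param name Table label.
#' @return A \linkS4class{HarmonTable}.
#' @examples
#' tbl <- harmonTable(data.frame(CNV_status = c("CNV_L", "CNV_H")), "target")
#' distinctValues(tbl, "CNV_status")
#' @export
harmonTable <- function(data, name = "table") {
  data <- as.data.frame(data, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(data) == 0) {
    stopHarmonizr("EmptyTableError", "table has no columns")
  }
  nm <- colnames(data)
  if (anyDuplicated(nm)) {
    dup <- unique(nm[duplicated(nm)])
    stopHarmonizr("DuplicateColumnError",
                  sprintf("duplicate column names: %s", paste(dup, collapse = ", ")))
  }
  if (any(!nzchar(nm)) || anyNA(nm)) {
    stopHarmonizr("DuplicateColumnError", "column names must be non-empty")
  }
  for (j in seq_along(data)) {
    cells <- as.character(data[[j]])
    cells[isMissingCell(cells)] <- NA_character_
    data[[j]] <- cells
  }
  new("HarmonTable", name = name, data = data)
}

#' Read a delimited file into a HarmonTable
#'
#' Reads an RFC 4180 style delimited UTF-8 file with a header row. Duplicate
#' header names are rejected; a header-only file yields columns of length 0.
#'
#' @param path File path.
#' @param delim Field delimiter (default comma).
#' @param name Table label (defaults to the file's base name).
#' @return A \linkS4class{HarmonTable}.
#' @export
readTable <- function(path, delim = ",", name = NULL) {
  if (!file.exists(path)) {
    stopHarmonizr("EmptyTableError", sprintf("file not found: %s", path))
  }
  df <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(0), fileEncoding = "UTF-8",
                          comment.char = "", blank.lines.skip = TRUE)
  harmonTable(df, name = if (is.null(name)) basename(path) else name)
}

#' Write a HarmonTable to a delimited file
#'
#' @param x A \linkS4class{HarmonTable}.
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return Invisibly, \code{path}.
#' @export
writeTable <- function(x, path, delim = ",") {
  utils::write.table(x@data, path, sep = delim, quote = TRUE, na = "",
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Infer the kind of a column
#'
#' A column is \code{numeric} when at least 95\% of its non-missing cells
#' parse as finite numbers (integer, decimal, or scientific notation) and at
#' least one non-missing cell exists; \code{unknown} when all cells are
#' missing; otherwise \code{text}. Deterministic and invariant to row order.
#'
#' @param cells Character vector of cell values.
#' @return One of \code{"text"}, \code{"numeric"}, \code{"unknown"}.
#' @examples
#' inferColumnKind(c("1", "2", "3"))
#' inferColumnKind(c("CNV_LOW", "CNV_HIGH"))
#' @export
inferColumnKind <- function(cells) {
  cells <- as.character(cells)
  obs <- cells[!isMissingCell(cells)]
  if (length(obs) == 0) return("unknown")
  frac <- mean(!is.na(parseNumericStrict(obs)))
  if (frac >= 0.95) "numeric" else "text"
}

# HarmonTable accessors -------------------------------------------------------

#' Accessors for HarmonTable
#'
#' @param x A \linkS4class{HarmonTable}.
#' @param column Column name.
#' @name HarmonTable-accessors
NULL

#' @rdname HarmonTable-accessors
#' @export
setMethod("tableName", "HarmonTable", function(x) x@name)

#' @rdname HarmonTable-accessors
#' @export
setMethod("columnNames", "HarmonTable", function(x) colnames(x@data))

.getColumn <- function(x, column) {
  if (!column %in% colnames(x@data)) {
    stopHarmonizr("UnknownAttributeError",
                  sprintf("no column named '%s' in table '%s'", column, x@name))
  }
  x@data[[column]]
}

#' @rdname HarmonTable-accessors
#' @export
setMethod("columnCells", "HarmonTable", function(x, column) .getColumn(x, column))

#' @rdname HarmonTable-accessors
#' @export
setMethod("distinctValues", "HarmonTable", function(x, column) {
  cells <- .getColumn(x, column)
  obs <- cells[!isMissingCell(cells)]
  unique(obs)  # first-occurrence order
})

#' @rdname HarmonTable-accessors
#' @export
setMethod("columnKind", "HarmonTable", function(x, column) {
  inferColumnKind(.getColumn(x, column))
})

#' @describeIn HarmonTable-accessors Number of rows and columns.
#' @export
setMethod("dim", "HarmonTable", function(x) dim(x@data))

#' @export
setMethod("show", "HarmonTable", function(object) {
  cat(sprintf("HarmonTable '%s': %d rows x %d columns\n",
              object@name, nrow(object@data), ncol(object@data)))
  kinds <- vapply(colnames(object@data), function(cn) columnKind(object, cn), character(1))
  cat("  columns:", paste(sprintf("%s<%s>", names(kinds), kinds), collapse = ", "), "\n")
})

#' Extract the underlying data.frame of a HarmonTable
#'
#' @param x A \linkS4class{HarmonTable}.
#' @return A data.frame of character columns.
#' @export
asDataFrame <- function(x) {
  stopifnot(is(x, "HarmonTable"))
  x@data
}

# TargetSchema -----------------------------------------------------------------

#' Build a TargetSchema from explicit components
#'
#' @param attributes Attribute names.
#' @param descriptions Optional descriptions (recycled "" by default).
#' @param permissibleValues Named or unnamed list of character vectors.
#' @param valueCounts Optional list of counts parallel to permissibleValues.
#' @param metadata Optional list of key->text maps.
#' @param origin Origin label.
#' @return A \linkS4class{TargetSchema}.
#' @export
targetSchema <- function(attributes, descriptions = NULL, permissibleValues = NULL,
                         valueCounts = NULL, metadata = NULL, origin = "table") {
  n <- length(attributes)
  if (is.null(descriptions)) descriptions <- rep("", n)
  if (is.null(permissibleValues)) permissibleValues <- rep(list(character(0)), n)
  if (is.null(valueCounts)) valueCounts <- rep(list(numeric(0)), n)
  if (is.null(metadata)) metadata <- rep(list(list()), n)
  metadata <- lapply(metadata, function(m) {
    if (is.null(m$description)) m$description <- ""
    m
  })
  names(permissibleValues) <- attributes
  names(valueCounts) <- attributes
  names(metadata) <- attributes
  new("TargetSchema", attributes = attributes, descriptions = descriptions,
      permissibleValues = permissibleValues, valueCounts = valueCounts,
      metadata = metadata, origin = origin)
}

#' @describeIn asTargetSchema One attribute per column; permissible values are
#'   the column's distinct non-missing values; value counts record observed
#'   frequencies; origin is \code{"table"}.
#' @export
setMethod("asTargetSchema", "HarmonTable", function(x) {
  attrs <- columnNames(x)
  pv <- lapply(attrs, function(cn) distinctValues(x, cn))
  vc <- lapply(seq_along(attrs), function(i) {
    cells <- columnCells(x, attrs[i])
    obs <- cells[!isMissingCell(cells)]
    as.numeric(table(factor(obs, levels = pv[[i]])))
  })
  md <- lapply(attrs, function(cn) {
    list(description = "", type = columnKind(x, cn))
  })
  targetSchema(attributes = attrs,
               descriptions = rep("", length(attrs)),
               permissibleValues = pv, valueCounts = vc,
               metadata = md, origin = "table")
})

#' @describeIn asTargetSchema Identity.
#' @export
setMethod("asTargetSchema", "TargetSchema", function(x) x)

#' Accessors for TargetSchema
#'
#' @param x A \linkS4class{TargetSchema}.
#' @param attribute Attribute name.
#' @name TargetSchema-accessors
NULL

#' @rdname TargetSchema-accessors
#' @export
setMethod("attributeNames", "TargetSchema", function(x) x@attributes)

.checkAttribute <- function(x, attribute) {
  if (!attribute %in% x@attributes) {
    stopHarmonizr("UnknownAttributeError",
                  sprintf("unknown attribute '%s' (available: %s)", attribute,
                          paste(x@attributes, collapse = ", ")))
  }
}

#' @rdname TargetSchema-accessors
#' @export
setMethod("permissibleValues", "TargetSchema", function(x, attribute) {
  .checkAttribute(x, attribute)
  x@permissibleValues[[attribute]]
})

#' @rdname TargetSchema-accessors
#' @export
setMethod("attributeMetadata", "TargetSchema", function(x, attribute) {
  .checkAttribute(x, attribute)
  x@metadata[[attribute]]
})

# Kind of a target attribute: declared metadata type if present, otherwise
# inferred from its permissible values.
targetAttributeKind <- function(schema, attribute) {
  md <- attributeMetadata(schema, attribute)
  if (!is.null(md$type) && nzchar(md$type)) return(md$type)
  inferColumnKind(permissibleValues(schema, attribute))
}

#' @export
setMethod("show", "TargetSchema", function(object) {
  cat(sprintf("TargetSchema (%s): %d attributes\n", object@origin,
              length(object@attributes)))
  cat(" ", paste(object@attributes, collapse = ", "), "\n")
})
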