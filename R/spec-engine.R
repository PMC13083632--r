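# Declarative harmonization specification: build from discovered matches,
# merge with user overrides (user precedence), serialize to JSON, validate,
# and materialize the harmonized dataset.
#
# Document grammar (version "1"):
# {"version": "1",
#  "mappings": [
#    {"source_attribute": ..., "target_attribute": ...,
#     "mapper": {"type": "identity" | "dictionary" | "affine" | "custom",
#                "map": {...},                      # dictionary only
#                "scale": , "offset": , "rounding": , "transform_provenance": ,
#                "routine_name": ,                  # custom only (never code)
#                "unmatched_policy": "null" | "passthrough"},
#     "similarity": <number or null>, "provenance": "auto:<method>" | "user"}
#  ]}

# Registry for custom mapper routines (registered by name at runtime; the
# spec document stores only the name, never executable content).
.mapperRegistry <- new.env(parent = emptyenv())

#' Register a custom mapper routine
#'
#' @param name Routine name referenced by custom mappers.
#' @param fn Function taking a character vector of cell values and returning
#'   a same-length character vector.
#' @return Invisibly, \code{name}.
#' @export
registerMapperRoutine <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .mapperRegistry)
  invisible(name)
}

# Mapper constructors ---------------------------------------------------------

#' Mapper constructors
#'
#' Mappers define how a source column's values are transformed at
#' materialization: \code{identityMapper} copies values; \code{dictionaryMapper}
#' substitutes via a value-to-value table (values absent from the dictionary
#' follow \code{unmatchedPolicy}: \code{"null"} emits missing,
#' \code{"passthrough"} keeps the source value); \code{affineMapper} applies a
#' \linkS4class{NumericTransform}; \code{customMapper} applies a routine
#' registered with \code{\link{registerMapperRoutine}}.
#'
#' @param map Named character vector (names: source values, values: target
#'   values).
#' @param transform A \linkS4class{NumericTransform}.
#' @param routineName Registered routine name.
#' @param unmatchedPolicy \code{"null"} or \code{"passthrough"}.
#' @return A mapper (list with a \code{type} element).
#' @name mappers
NULL

#' @rdname mappers
#' @export
identityMapper <- function() list(type = "identity", unmatched_policy = "passthrough")

#' @rdname mappers
#' @export
dictionaryMapper <- function(map, unmatchedPolicy = "null") {
  map <- unlist(map)
  if (anyDuplicated(names(map))) {
    stopHarmonizr("SpecFormatError", "dictionary keys must be unique")
  }
  stopifnot(unmatchedPolicy %in% c("null", "passthrough"))
  list(type = "dictionary", map = map, unmatched_policy = unmatchedPolicy)
}

#' @rdname mappers
#' @export
affineMapper <- function(transform) {
  stopifnot(is(transform, "NumericTransform"))
  list(type = "affine", transform = transform, unmatched_policy = "null")
}

#' @rdname mappers
#' @export
customMapper <- function(routineName) {
  list(type = "custom", routine_name = routineName, unmatched_policy = "null")
}

# Spec construction -----------------------------------------------------------

.specEntry <- function(source_attribute, target_attribute, mapper,
                       similarity = NA_real_, provenance = "user") {
  list(source_attribute = source_attribute, target_attribute = target_attribute,
       mapper = mapper, similarity = similarity, provenance = provenance)
}

#' Construct a HarmonizationSpec from entries
#'
#' @param entries List of entries (see \code{\link{mappingEntry}}).
#' @param version Document version (default \code{"1"}).
#' @return A \linkS4class{HarmonizationSpec}.
#' @export
harmonizationSpec <- function(entries = list(), version = "1") {
  src <- vapply(entries, function(e) e$source_attribute, character(1))
  tgt <- vapply(entries, function(e) e$target_attribute, character(1))
  collide <- tapply(src, tgt, function(s) length(unique(s)))
  if (length(collide) && any(collide > 1)) {
    bad <- names(collide)[collide > 1][1]
    stopHarmonizr("ManyToOneError",
                  sprintf("two source attributes map to target '%s'; many-to-one mappings are not supported", bad))
  }
  new("HarmonizationSpec", version = version, entries = entries)
}

#' Create a single mapping entry
#'
#' @param sourceAttribute,targetAttribute Attribute names.
#' @param mapper A mapper (see \link{mappers}); default identity.
#' @param similarity Optional similarity score.
#' @param provenance \code{"user"} or \code{"auto:<method>"}.
#' @return A mapping entry (list).
#' @export
mappingEntry <- function(sourceAttribute, targetAttribute,
                         mapper = identityMapper(), similarity = NA_real_,
                         provenance = "user") {
  .specEntry(sourceAttribute, targetAttribute, mapper, similarity, provenance)
}

#' @rdname HarmonizationSpec-accessors
#' @param x A \linkS4class{HarmonizationSpec}.
#' @export
setMethod("specEntries", "HarmonizationSpec", function(x) x@entries)

#' @export
setMethod("show", "HarmonizationSpec", function(object) {
  cat(sprintf("HarmonizationSpec v%s: %d entries\n", object@version,
              length(object@entries)))
  for (e in object@entries) {
    cat(sprintf("  %s -> %s [%s, %s]\n", e$source_attribute, e$target_attribute,
                e$mapper$type, e$provenance))
  }
})

#' Build a harmonization specification from discovered matches
#'
#' Per attribute match: a dictionary mapper is compiled from its value
#' matches; when every matched value maps to itself and nothing is unmatched,
#' or when no values matched but the attribute names align after
#' normalization, the identity mapper is used instead. Provenance is
#' \code{"auto:<method>"}; similarities are carried through.
#'
#' @param matches data.frame from \code{\link{matchSchema}}.
#' @param valueMatches Optional data.frame from \code{\link{matchValues}}.
#' @return A \linkS4class{HarmonizationSpec}.
#' @export
buildSpec <- function(matches, valueMatches = NULL) {
  method <- attr(matches, "method")
  provenance <- paste0("auto:", if (is.null(method)) "unknown" else method)
  entries <- lapply(seq_len(nrow(matches)), function(r) {
    sa <- matches$source_attribute[r]
    ta <- matches$target_attribute[r]
    sim <- if ("similarity" %in% colnames(matches)) matches$similarity[r] else NA_real_
    mapper <- identityMapper()
    if (!is.null(valueMatches)) {
      vm <- valueMatches[valueMatches$source_attribute == sa &
                         valueMatches$target_attribute == ta, , drop = FALSE]
      if (nrow(vm) > 0) {
        matched <- vm[!is.na(vm$target_value), , drop = FALSE]
        if (nrow(matched) == 0) {
          mapper <- if (normalizeLabel(sa) == normalizeLabel(ta)) {
            identityMapper()
          } else {
            dictionaryMapper(character(0))
          }
        } else if (nrow(matched) == nrow(vm) &&
                   all(matched$source_value == matched$target_value)) {
          mapper <- identityMapper()
        } else {
          mapper <- dictionaryMapper(stats::setNames(matched$target_value,
                                                     matched$source_value))
        }
      }
    }
    .specEntry(sa, ta, mapper, similarity = sim, provenance = provenance)
  })
  harmonizationSpec(entries)
}

#' Merge automatic and user-provided mappings (user precedence)
#'
#' Any user entry for a source attribute replaces all automatic entries for
#' that source attribute; user-only entries are appended. Surviving automatic
#' entries keep their order. The merged result is re-checked for many-to-one
#' collisions.
#'
#' @param auto,user \linkS4class{HarmonizationSpec} objects.
#' @return The merged \linkS4class{HarmonizationSpec}.
#' @export
mergeMappings <- function(auto, user) {
  stopifnot(is(auto, "HarmonizationSpec"), is(user, "HarmonizationSpec"))
  userSrc <- vapply(user@entries, function(e) e$source_attribute, character(1))
  keep <- Filter(function(e) !e$source_attribute %in% userSrc, auto@entries)
  harmonizationSpec(c(keep, user@entries), version = auto@version)
}

# Materialization --------------------------------------------------------------

.applyMapper <- function(mapper, cells) {
  miss <- isMissingCell(cells)
  out <- switch(mapper$type,
    identity = cells,
    dictionary = {
      mapped <- unname(mapper$map[cells])
      policy <- if (is.null(mapper$unmatched_policy)) "null" else mapper$unmatched_policy
      if (policy == "passthrough") {
        ifelse(is.na(mapped), cells, mapped)
      } else {
        mapped
      }
    },
    affine = {
      x <- parseNumericStrict(cells)
      y <- applyNumericTransform(mapper$transform, x)
      out <- as.character(y)
      out[is.na(x)] <- NA_character_
      out
    },
    custom = {
      if (!exists(mapper$routine_name, envir = .mapperRegistry)) {
        stopHarmonizr("UnresolvedRoutineError",
                      sprintf("custom routine '%s' is not registered", mapper$routine_name))
      }
      fn <- get(mapper$routine_name, envir = .mapperRegistry)
      res <- as.character(fn(cells))
      if (length(res) != length(cells)) {
        stopHarmonizr("UnresolvedRoutineError",
                      sprintf("routine '%s' changed the number of rows", mapper$routine_name))
      }
      res
    }
  )
  out[miss] <- NA_character_
  out
}

#' Materialize a harmonized dataset
#'
#' Applies the specification to the source table: the output has exactly the
#' spec's target attributes, in entry order; the row count is preserved;
#' source columns not referenced by the spec are dropped.
#'
#' @param source A \linkS4class{HarmonTable}.
#' @param spec A \linkS4class{HarmonizationSpec}.
#' @return The harmonized \linkS4class{HarmonTable}.
#' @examples
#' src <- harmonTable(data.frame(CNV_class = c("CNV_LOW", "CNV_HIGH", "CNV_LOW")), "src")
#' spec <- harmonizationSpec(list(mappingEntry(
#'   "CNV_class", "CNV_status",
#'   dictionaryMapper(c(CNV_LOW = "CNV_L", CNV_HIGH = "CNV_H")))))
#' asDataFrame(materialize(src, spec))
#' @export
materialize <- function(source, spec) {
  stopifnot(is(source, "HarmonTable"), is(spec, "HarmonizationSpec"))
  missingSrc <- setdiff(vapply(spec@entries, function(e) e$source_attribute, character(1)),
                        columnNames(source))
  if (length(missingSrc) > 0) {
    stopHarmonizr("MissingSourceAttributeError",
                  sprintf("source attributes missing from table: %s",
                          paste(unique(missingSrc), collapse = ", ")))
  }
  n <- nrow(asDataFrame(source))
  cols <- lapply(spec@entries, function(e) {
    .applyMapper(e$mapper, columnCells(source, e$source_attribute))
  })
  names(cols) <- vapply(spec@entries, function(e) e$target_attribute, character(1))
  df <- if (length(cols) == 0) {
    as.data.frame(matrix(nrow = n, ncol = 0))
  } else {
    as.data.frame(cols, check.names = FALSE, optional = TRUE,
                  stringsAsFactors = FALSE)
  }
  new("HarmonTable", name = paste0(tableName(source), "_harmonized"), data = df)
}

# Serialization -----------------------------------------------------------------

.mapperToDoc <- function(m) {
  doc <- list(type = m$type)
  if (m$type == "dictionary") doc$map <- as.list(m$map)
  if (m$type == "affine") {
    doc$scale <- m$transform@scale
    doc$offset <- m$transform@offset
    doc$rounding <- m$transform@rounding
    doc$transform_provenance <- m$transform@provenance
  }
  if (m$type == "custom") doc$routine_name <- m$routine_name
  doc$unmatched_policy <- m$unmatched_policy
  doc
}

.mapperFromDoc <- function(doc) {
  if (is.null(doc$type)) stopHarmonizr("SpecFormatError", "mapper missing 'type'")
  policy <- if (is.null(doc$unmatched_policy)) "null" else doc$unmatched_policy
  switch(doc$type,
    identity = list(type = "identity", unmatched_policy = policy),
    dictionary = {
      map <- vapply(doc$map, as.character, character(1))
      dictionaryMapper(map, unmatchedPolicy = policy)
    },
    affine = {
      tp <- if (is.null(doc$transform_provenance)) "user" else doc$transform_provenance
      m <- affineMapper(numericTransform(doc$scale, doc$offset, doc$rounding, tp))
      m$unmatched_policy <- policy
      m
    },
    custom = {
      m <- customMapper(doc$routine_name)
      m$unmatched_policy <- policy
      m
    },
    stopHarmonizr("SpecFormatError", sprintf("unknown mapper type '%s'", doc$type))
  )
}

#' Write a harmonization specification to JSON
#'
#' UTF-8, 2-space indent, stable key ordering (diff-friendly). Custom
#' mappers serialize their routine name only, never code.
#'
#' @param spec A \linkS4class{HarmonizationSpec}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeSpec <- function(spec, path) {
  stopifnot(is(spec, "HarmonizationSpec"))
  doc <- list(
    version = spec@version,
    mappings = lapply(spec@entries, function(e) {
      list(source_attribute = e$source_attribute,
           target_attribute = e$target_attribute,
           mapper = .mapperToDoc(e$mapper),
           similarity = if (is.na(e$similarity)) NULL else e$similarity,
           provenance = e$provenance)
    })
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2, digits = NA,
                           null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read a harmonization specification from JSON
#'
#' @param path Spec file path.
#' @return A \linkS4class{HarmonizationSpec}; \code{readSpec(writeSpec(s))}
#'   reproduces \code{s}.
#' @export
readSpec <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) {
                    stopHarmonizr("SpecFormatError",
                                  sprintf("not a valid JSON document: %s", conditionMessage(e)))
                  })
  if (is.null(doc$mappings)) {
    stopHarmonizr("SpecFormatError", "spec document is missing the 'mappings' key")
  }
  entries <- lapply(seq_along(doc$mappings), function(i) {
    m <- doc$mappings[[i]]
    for (fld in c("source_attribute", "target_attribute", "mapper")) {
      if (is.null(m[[fld]])) {
        stopHarmonizr("SpecFormatError",
                      sprintf("mapping %d is missing field '%s'", i, fld))
      }
    }
    .specEntry(as.character(m$source_attribute), as.character(m$target_attribute),
               .mapperFromDoc(m$mapper),
               similarity = if (is.null(m$similarity)) NA_real_ else as.numeric(m$similarity),
               provenance = if (is.null(m$provenance)) "user" else as.character(m$provenance))
  })
  harmonizationSpec(entries,
                    version = if (is.null(doc$version)) "1" else as.character(doc$version))
}

#' Validate a specification against a source table and target schema
#'
#' Returns findings (not exceptions): unknown source attributes, unknown
#' target attributes, dictionary values outside the target's permissible
#' values, and many-to-one collisions.
#'
#' @param spec A \linkS4class{HarmonizationSpec}.
#' @param source Optional \linkS4class{HarmonTable}.
#' @param target Optional target (table/schema/standard).
#' @return data.frame with columns \code{code}, \code{entry}, \code{message};
#'   zero rows when fully consistent.
#' @export
validateSpec <- function(spec, source = NULL, target = NULL) {
  findings <- list()
  add <- function(code, entry, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      code = code, entry = entry, message = message, stringsAsFactors = FALSE)
  }
  schema <- if (!is.null(target)) resolveTargetSchema(target) else NULL
  tgt <- vapply(spec@entries, function(e) e$target_attribute, character(1))
  src <- vapply(spec@entries, function(e) e$source_attribute, character(1))
  collide <- tapply(src, tgt, function(s) length(unique(s)))
  for (bad in names(collide)[collide > 1]) {
    add("many-to-one", NA_integer_,
        sprintf("multiple source attributes map to target '%s'", bad))
  }
  for (i in seq_along(spec@entries)) {
    e <- spec@entries[[i]]
    if (!is.null(source) && !e$source_attribute %in% columnNames(source)) {
      add("unknown-source-attribute", i,
          sprintf("source attribute '%s' not found in table", e$source_attribute))
    }
    if (!is.null(schema)) {
      if (!e$target_attribute %in% schema@attributes) {
        add("unknown-target-attribute", i,
            sprintf("target attribute '%s' not found in schema", e$target_attribute))
      } else if (e$mapper$type == "dictionary") {
        pv <- permissibleValues(schema, e$target_attribute)
        if (length(pv) > 0) {
          out <- setdiff(unname(e$mapper$map), pv)
          if (length(out) > 0) {
            add("value-out-of-domain", i,
                sprintf("dictionary values outside permissible set of '%s': %s",
                        e$target_attribute, paste(out, collapse = ", ")))
          }
        }
      }
    }
  }
  if (length(findings) == 0) {
    return(data.frame(code = character(0), entry = integer(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, findings)
  rownames(out) <- NULL
  out
}
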