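# Pluggable data-model standards. A standard is a YAML (or JSON) document:
#   name: <standard name>
#   attributes:
#     - name: <attribute>
#       description: <text>
#       values: [v1, v2, ...]        # optional; empty for free-valued
#       metadata: {unit: ..., type: ...}
# All modules reach standards exclusively through the four accessors.

.standardsDir <- function() {
  system.file("extdata", "standards", package = "harmonizr")
}

#' List available data-model standards
#'
#' Builtin standards bundled with the package plus any \code{.yaml},
#' \code{.yml} or \code{.json} files in the directory named by
#' \code{options(harmonizr.standards.dir=)}.
#'
#' @return Character vector of standard names.
#' @export
availableStandards <- function() {
  dirs <- c(getOption("harmonizr.standards.dir"), .standardsDir())
  dirs <- dirs[!vapply(dirs, is.null, logical(1))]
  files <- unlist(lapply(dirs, function(d) {
    list.files(d, pattern = "\\.(yaml|yml|json)$", full.names = FALSE)
  }))
  sort(unique(sub("\\.(yaml|yml|json)$", "", files)))
}

.findStandardFile <- function(name) {
  dirs <- c(getOption("harmonizr.standards.dir"), .standardsDir())
  dirs <- dirs[!vapply(dirs, is.null, logical(1))]
  for (d in dirs) {
    for (ext in c(".yaml", ".yml", ".json")) {
      f <- file.path(d, paste0(name, ext))
      if (file.exists(f)) return(f)
    }
  }
  NULL
}

.parseStandardDoc <- function(doc, provenance) {
  if (is.null(doc$name) || is.null(doc$attributes)) {
    stopHarmonizr("SpecFormatError",
                  "standard document must have 'name' and 'attributes' keys")
  }
  attrs <- vapply(doc$attributes, function(a) as.character(a$name), character(1))
  desc <- vapply(doc$attributes, function(a) {
    if (is.null(a$description)) "" else as.character(a$description)
  }, character(1))
  pv <- lapply(doc$attributes, function(a) {
    if (is.null(a$values)) character(0) else as.character(unlist(a$values))
  })
  md <- lapply(seq_along(doc$attributes), function(i) {
    a <- doc$attributes[[i]]
    m <- if (is.null(a$metadata)) list() else lapply(a$metadata, as.character)
    m$description <- desc[i]
    m
  })
  schema <- targetSchema(attributes = attrs, descriptions = desc,
                         permissibleValues = pv, metadata = md,
                         origin = paste0("standard:", doc$name))
  new("StandardModel", name = as.character(doc$name), schema = schema,
      provenance = provenance)
}

#' Load a data-model standard
#'
#' \code{name} is either a registered standard name (see
#' \code{\link{availableStandards}}) or a path to a YAML/JSON standard file.
#'
#' @param name Standard name or file path.
#' @return A \linkS4class{StandardModel}.
#' @examples
#' cdm <- loadStandard("toy_cdm")
#' getAttributes(cdm)
#' @export
loadStandard <- function(name) {
  path <- if (file.exists(name) && grepl("\\.(yaml|yml|json)$", name)) {
    name
  } else {
    .findStandardFile(name)
  }
  if (is.null(path)) {
    stopHarmonizr("UnknownStandardError",
                  sprintf("unknown standard '%s' (available: %s)", name,
                          paste(availableStandards(), collapse = ", ")))
  }
  doc <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  provenance <- if (!is.null(.findStandardFile(name)) && identical(path, .findStandardFile(name)) &&
                    dirname(path) == .standardsDir()) "builtin" else path
  .parseStandardDoc(doc, provenance)
}

#' Four-accessor interface of data-model standards
#'
#' Every module interacts with a standard exclusively through these methods:
#' \code{getAttributes} (attribute names, deterministic order),
#' \code{getAttributeValues} (deduplicated permissible values, possibly empty
#' for free-valued attributes), \code{getAttributeMetadata} (key->text map,
#' always containing \code{description}), and \code{getTableRepresentation}
#' (the standard as a \linkS4class{TargetSchema}).
#'
#' @param x A \linkS4class{StandardModel}.
#' @param attribute Attribute name.
#' @name standards-accessors
NULL

#' @rdname standards-accessors
#' @export
setMethod("getAttributes", "StandardModel", function(x) x@schema@attributes)

#' @rdname standards-accessors
#' @export
setMethod("getAttributeValues", "StandardModel", function(x, attribute) {
  permissibleValues(x@schema, attribute)
})

#' @rdname standards-accessors
#' @export
setMethod("getAttributeMetadata", "StandardModel", function(x, attribute) {
  attributeMetadata(x@schema, attribute)
})

#' @rdname standards-accessors
#' @export
setMethod("getTableRepresentation", "StandardModel", function(x) x@schema)

#' @describeIn asTargetSchema The standard's table representation.
#' @export
setMethod("asTargetSchema", "StandardModel", function(x) getTableRepresentation(x))

#' @export
setMethod("show", "StandardModel", function(object) {
  cat(sprintf("StandardModel '%s' (%s): %d attributes\n", object@name,
              object@provenance, length(object@schema@attributes)))
})
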