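# The semantic document tree.
#
# Every stage of the conversion stack produces and consumes `sem_node` trees:
# plain R lists with fields
#   name     - element name in the document dialect (module, scalar, array, ...)
#   attrs    - named character vector of attributes, canonical local names,
#              original order preserved
#   value    - payload tokens (character) for scalar/array/matrix/comment and
#              for opaque leaf elements; NULL otherwise
#   children - ordered list of sem_node
#
# Numeric payloads are kept as their printed decimal strings; typed access
# parses on demand.  Serialization therefore never changes printed precision.

KNOWN_KINDS <- c(
  "module", "list", "parameterList", "parameter", "propertyList", "property",
  "scalar", "array", "matrix", "table", "molecule", "atom", "bond", "formula",
  "comment"
)

DATATYPES <- c("xsd:string", "xsd:integer", "xsd:double", "xsd:date")

# attributes that have dedicated meaning; everything else is carried opaquely
CANONICAL_ATTRS <- c(
  "id", "dictRef", "units", "dataType", "size", "rows", "columns",
  "delimiter", "convention", "temp", "templateRef", "section"
)

#' Construct a semantic document node
#'
#' @param name Element name, e.g. `"module"`, `"scalar"`, `"array"`.
#' @param ... Attributes as named strings (`dictRef = "cc:natoms"`,
#'   `dataType = "xsd:integer"`, ...).  The temporary label used during
#'   parsing is `temp`, the originating template is `templateRef`.
#' @param value Payload: a single string for `scalar`, a character vector of
#'   tokens for `array`/`matrix`, raw text for `comment`.
#' @param children List of child nodes.
#' @return A `sem_node`.
#' @export
#' @examples
#' n <- sem_node("scalar", dictRef = "cc:natoms", dataType = "xsd:integer",
#'               value = "5")
#' scalar_value(n)
sem_node <- function(name, ..., value = NULL, children = list()) {
  attrs <- c(...)
  if (length(attrs) && (is.null(names(attrs)) || any(names(attrs) == ""))) {
    qc_abort("all node attributes must be named", "qc_integrity_error")
  }
  structure(
    list(name = name, attrs = as.character(attrs) |> stats::setNames(names(attrs)),
         value = if (is.null(value)) NULL else as.character(value),
         children = children),
    class = "sem_node"
  )
}

#' @export
is.sem_node <- function(x) inherits(x, "sem_node")

#' Node kind
#'
#' Returns the element name when it belongs to the document vocabulary and
#' `"opaque"` otherwise (unknown content is preserved but not interpreted).
#'
#' @param node A `sem_node`.
#' @return A string.
#' @export
sem_kind <- function(node) {
  if (node$name %in% KNOWN_KINDS) node$name else "opaque"
}

#' Get a node attribute
#'
#' @param node A `sem_node`.
#' @param name Attribute name (canonical local form, e.g. `"dictRef"`,
#'   `"temp"`, `"templateRef"`).
#' @return The attribute value or `NULL`.
#' @export
sem_attr <- function(node, name) {
  if (!name %in% names(node$attrs)) return(NULL)
  v <- node$attrs[[name]]
  if (is.null(v) || is.na(v)) NULL else v
}

#' Set (or drop) a node attribute, returning the modified node
#'
#' @param node A `sem_node`.
#' @param name Attribute name.
#' @param value New value, or `NULL` to remove the attribute.
#' @return The modified node.
#' @export
sem_set_attr <- function(node, name, value) {
  if (is.null(value)) {
    node$attrs <- node$attrs[names(node$attrs) != name]
  } else {
    node$attrs[[name]] <- as.character(value)
  }
  node
}

#' @rdname sem_attr
#' @export
sem_children <- function(node) node$children

qname_ok <- function(x) grepl("^[^:[:space:]]+:[^:[:space:]]+$", x)

qname_prefix <- function(x) sub(":.*$", "", x)
qname_local <- function(x) sub("^[^:]*:", "", x)

#' Typed payload of a scalar node
#'
#' @param node A `sem_node` of kind `scalar`.
#' @return The payload parsed according to the node's `dataType`
#'   (`xsd:integer` -> integer, `xsd:double` -> double, otherwise character).
#' @export
scalar_value <- function(node) {
  if (node$name != "scalar") {
    qc_abort(sprintf("expected a scalar node, got <%s>", node$name),
             "qc_type_error")
  }
  parse_payload(node$value, sem_attr(node, "dataType"))
}

#' Typed payload of an array (or matrix) node
#'
#' @param node A `sem_node` of kind `array` or `matrix`.
#' @return Vector of payload values parsed per the node's `dataType`.
#' @export
array_values <- function(node) {
  if (!node$name %in% c("array", "matrix")) {
    qc_abort(sprintf("expected an array/matrix node, got <%s>", node$name),
             "qc_type_error")
  }
  parse_payload(node$value, sem_attr(node, "dataType"))
}

parse_payload <- function(tokens, dataType) {
  if (is.null(tokens)) return(NULL)
  if (is.null(dataType)) dataType <- "xsd:string"
  switch(dataType,
    "xsd:integer" = {
      v <- suppressWarnings(as.integer(tokens))
      if (anyNA(v) && !anyNA(tokens)) {
        qc_abort(sprintf("payload '%s' does not parse as xsd:integer",
                         paste(tokens[is.na(v)], collapse = " ")),
                 "qc_integrity_error")
      }
      v
    },
    "xsd:double" = {
      v <- suppressWarnings(as.numeric(gsub("[dD]", "E", tokens)))
      if (anyNA(v) && !anyNA(tokens)) {
        qc_abort(sprintf("payload '%s' does not parse as xsd:double",
                         paste(tokens[is.na(v)], collapse = " ")),
                 "qc_integrity_error")
      }
      v
    },
    tokens
  )
}

node_path_of <- function(node) {
  id <- sem_attr(node, "id")
  dr <- sem_attr(node, "dictRef")
  sprintf("<%s%s%s>", node$name,
          if (!is.null(id)) paste0(" id=", id) else "",
          if (!is.null(dr)) paste0(" dictRef=", dr) else "")
}

#' Check structural invariants of a tree
#'
#' Verifies, recursively: scalars hold exactly one payload and no children;
#' a declared `size` equals the array payload length; `rows * columns` equals
#' the matrix payload length; any `dictRef`/`units` is a `prefix:local`
#' qualified name with nonempty parts; atom ids are unique within a molecule
#' and every bond endpoint names an existing atom.
#'
#' @param node A `sem_node`.
#' @param path Path prefix used in error messages.
#' @return `TRUE` invisibly; signals a `qc_integrity_error` otherwise.
#' @export
validate_node <- function(node, path = "") {
  here <- paste0(path, "/", node$name,
                 if (!is.null(sem_attr(node, "id"))) paste0("[", sem_attr(node, "id"), "]") else "")
  for (a in c("dictRef", "units")) {
    v <- sem_attr(node, a)
    if (!is.null(v) && !qname_ok(v)) {
      qc_abort(sprintf("%s: %s '%s' is not a prefix:local qualified name", here, a, v),
               "qc_integrity_error")
    }
  }
  if (node$name == "scalar") {
    if (length(node$children)) {
      qc_abort(paste0(here, ": scalar must not have children"), "qc_integrity_error")
    }
    if (length(node$value) != 1) {
      qc_abort(paste0(here, ": scalar must hold exactly one payload value"),
               "qc_integrity_error")
    }
  }
  if (node$name == "array") {
    sz <- sem_attr(node, "size")
    if (!is.null(sz) && as.integer(sz) != length(node$value)) {
      qc_abort(sprintf("%s: declared size %s but payload length %d",
                       here, sz, length(node$value)), "qc_integrity_error")
    }
  }
  if (node$name == "matrix") {
    r <- sem_attr(node, "rows"); cc <- sem_attr(node, "columns")
    if (!is.null(r) && !is.null(cc) &&
        as.integer(r) * as.integer(cc) != length(node$value)) {
      qc_abort(sprintf("%s: rows*columns = %s*%s but payload length %d",
                       here, r, cc, length(node$value)), "qc_integrity_error")
    }
  }
  if (node$name == "molecule") validate_molecule(node, here)
  dt <- sem_attr(node, "dataType")
  if (!is.null(dt) && node$name %in% c("scalar", "array", "matrix")) {
    parse_payload(node$value, dt)  # errors if tokens do not parse
  }
  for (ch in node$children) validate_node(ch, here)
  invisible(TRUE)
}

validate_molecule <- function(node, here) {
  atoms <- collect_named(node, "atom")
  ids <- vapply(atoms, function(a) sem_attr(a, "id") %||% "", "")
  if (anyDuplicated(ids[ids != ""])) {
    qc_abort(sprintf("%s: duplicate atom id '%s'", here,
                     ids[duplicated(ids)][1]), "qc_integrity_error")
  }
  bonds <- collect_named(node, "bond")
  for (b in bonds) {
    refs <- strsplit(sem_attr(b, "atomRefs2") %||% "", "\\s+")[[1]]
    if (!all(refs %in% ids)) {
      qc_abort(sprintf("%s: bond endpoint '%s' names no atom", here,
                       paste(setdiff(refs, ids), collapse = " ")),
               "qc_integrity_error")
    }
  }
  for (f in collect_named(node, "formula")) {
    con <- sem_attr(f, "concise")
    if (!is.null(con) &&
        !grepl("^([A-Z][a-z]? [0-9]+)( [A-Z][a-z]? [0-9]+)*( -?[0-9]+)?$", con)) {
      qc_abort(sprintf("%s: concise formula '%s' is not element/count pairs",
                       here, con), "qc_integrity_error")
    }
  }
  invisible(TRUE)
}

collect_named <- function(node, name) {
  out <- list()
  for (ch in node$children) {
    if (ch$name == name) out <- c(out, list(ch))
    out <- c(out, collect_named(ch, name))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total number of nodes in a tree
#' @param node A `sem_node`.
#' @return Integer count including the node itself.
#' @export
node_count <- function(node) {
  1L + sum(vapply(node$children, node_count, 1L))
}

# --- structural comparison ---------------------------------------------------

# Attributes that are engine scaffolding: they drive parsing and job
# restructuring but are not part of a document's semantics.
SCAFFOLD_ATTRS <- c("temp", "section", "jobstart")

#' Report the first structural difference between two trees
#'
#' Comparison covers node names, attributes (minus `ignore`), payloads and
#' child order.  Payloads declared `xsd:double`/`xsd:integer` on either side
#' are compared numerically, so `1.0938` equals `1.09380`.
#'
#' @param a,b `sem_node` trees.
#' @param ignore Attribute names excluded from comparison.
#' @param path Internal; path accumulator for messages.
#' @return `NULL` when structurally equal, else a string naming the first
#'   difference and its path.
#' @export
sem_diff <- function(a, b, ignore = character(), path = "") {
  here <- paste0(path, "/", a$name)
  if (a$name != b$name) {
    return(sprintf("%s: element <%s> vs <%s>", path, a$name, b$name))
  }
  aa <- a$attrs[setdiff(names(a$attrs), ignore)]
  ba <- b$attrs[setdiff(names(b$attrs), ignore)]
  keys <- union(names(aa), names(ba))
  for (k in keys) {
    av <- if (k %in% names(aa)) aa[[k]] else NULL
    bv <- if (k %in% names(ba)) ba[[k]] else NULL
    if (!identical(av, bv)) {
      return(sprintf("%s: attribute %s = '%s' vs '%s'", here, k,
                     av %||% "<absent>", bv %||% "<absent>"))
    }
  }
  dt <- sem_attr(a, "dataType") %||% sem_attr(b, "dataType") %||% "xsd:string"
  if (!is.null(a$value) || !is.null(b$value)) {
    if (length(a$value) != length(b$value)) {
      return(sprintf("%s: payload length %d vs %d", here,
                     length(a$value), length(b$value)))
    }
    if (dt %in% c("xsd:double", "xsd:integer")) {
      av <- parse_payload(a$value, dt); bv <- parse_payload(b$value, dt)
      if (!isTRUE(all(av == bv))) {
        i <- which(av != bv)[1]
        return(sprintf("%s: payload[%d] %s vs %s", here, i, a$value[i], b$value[i]))
      }
    } else if (!identical(a$value, b$value)) {
      i <- which(a$value != b$value)[1]
      return(sprintf("%s: payload[%d] '%s' vs '%s'", here, i, a$value[i], b$value[i]))
    }
  }
  if (length(a$children) != length(b$children)) {
    return(sprintf("%s: %d children vs %d", here,
                   length(a$children), length(b$children)))
  }
  for (i in seq_along(a$children)) {
    d <- sem_diff(a$children[[i]], b$children[[i]], ignore,
                  paste0(here, "[", i, "]"))
    if (!is.null(d)) return(d)
  }
  NULL
}

#' Structural equality of two trees
#'
#' @inheritParams sem_diff
#' @return `TRUE`/`FALSE`.
#' @export
sem_equal <- function(a, b, ignore = character()) {
  is.null(sem_diff(a, b, ignore))
}

#' @export
print.sem_node <- function(x, ..., depth = 0, max_depth = 3L) {
  pad <- strrep("  ", depth)
  at <- if (length(x$attrs)) {
    paste0(" ", paste(names(x$attrs), shQuote(x$attrs), sep = "=", collapse = " "))
  } else ""
  pv <- if (!is.null(x$value)) {
    v <- paste(utils::head(x$value, 5), collapse = " ")
    if (length(x$value) > 5) v <- paste0(v, " ... [", length(x$value), "]")
    paste0(" = ", v)
  } else ""
  cat(pad, "<", x$name, ">", at, pv, "\n", sep = "")
  if (depth < max_depth) {
    for (ch in x$children) print(ch, depth = depth + 1, max_depth = max_depth)
  } else if (length(x$children)) {
    cat(pad, "  ... ", length(x$children), " children\n", sep = "")
  }
  invisible(x)
}
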