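# Reading and writing the XML dialect of the semantic documents.
#
# Namespace prefixes (cml default, cmlx, cc, g, nonsi, u, x, ...) are treated
# as opaque strings on qualified names: no URI resolution is performed, and
# equality of two dictRefs never consults a namespace table.  The writer
# redeclares a fixed prefix set on the root so that prefixed attribute names
# survive a read -> write -> read cycle.

NS_TABLE <- c(
  "xmlns"            = "http://www.xml-cml.org/schema",
  "xmlns:cmlx"       = "http://www.xml-cml.org/schema/cmlx",
  "xmlns:convention" = "http://www.xml-cml.org/convention/",
  "xmlns:cc"         = "http://www.xml-cml.org/dictionary/compchem/",
  "xmlns:compchem"   = "http://www.xml-cml.org/dictionary/compchem/",
  "xmlns:g"          = "http://www.xml-cml.org/dictionary/gaussian/",
  "xmlns:x"          = "http://www.xml-cml.org/dictionary/unassigned/",
  "xmlns:xsd"        = "http://www.w3.org/2001/XMLSchema",
  "xmlns:nonsi"      = "http://www.xml-cml.org/unit/nonSi/",
  "xmlns:si"         = "http://www.xml-cml.org/unit/si/",
  "xmlns:u"          = "http://www.xml-cml.org/unit/"
)

# attributes serialized with a cmlx: prefix
CMLX_ATTRS <- c("temp", "templateRef", "section", "jobstart")

#' Read a semantic document from XML text
#'
#' Unknown elements and attributes are preserved as opaque content.  Numeric
#' payloads are kept as printed (no precision loss) and additionally checked
#' to parse under their declared `dataType`.
#'
#' @param text XML text, a length-one string, or a file path.
#' @return The root `sem_node`.
#' @export
#' @examples
#' doc <- read_document("<module><scalar dataType='xsd:integer'>5</scalar></module>")
#' scalar_value(doc$children[[1]])
read_document <- function(text) {
  xml <- tryCatch(
    xml2::read_xml(if (length(text) == 1 && file.exists(text)) text else paste(text, collapse = "\n")),
    error = function(e) {
      qc_abort(paste0("XML parse error: ", conditionMessage(e)), "qc_parse_error")
    }
  )
  root <- xml_to_sem(xml)
  validate_node(root)
  root
}

xml_to_sem <- function(x) {
  name <- xml2::xml_name(x)
  attrs <- xml2::xml_attrs(x)
  attrs <- attrs[!grepl("^xmlns", names(attrs))]
  # canonicalize prefixed attribute local names (xml2 already strips declared
  # prefixes; also strip a literal "cmlx:" left by undeclared prefixes)
  names(attrs) <- sub("^cmlx:", "", names(attrs))
  kids <- xml2::xml_children(x)
  value <- NULL
  children <- list()
  if (length(kids) == 0) {
    txt <- xml2::xml_text(x)
    if (name %in% c("scalar")) {
      value <- trimws(txt)
    } else if (name %in% c("array", "matrix")) {
      value <- split_payload(txt, if ("delimiter" %in% names(attrs)) attrs[["delimiter"]] else NULL)
    } else if (name == "comment") {
      value <- txt
    } else if (nzchar(trimws(txt))) {
      value <- trimws(txt)
    }
  } else {
    children <- lapply(kids, xml_to_sem)
    if (name == "comment") value <- xml2::xml_text(x)
  }
  n <- sem_node(name, value = value, children = children)
  n$attrs <- attrs
  n
}

split_payload <- function(txt, delimiter) {
  if (is.null(delimiter) || is.na(delimiter) || delimiter == "") {
    toks <- strsplit(trimws(txt), "\\s+")[[1]]
    toks[nzchar(toks)]
  } else {
    toks <- strsplit(txt, delimiter, fixed = TRUE)[[1]]
    toks <- trimws(toks)
    toks[nzchar(toks)]  # enclosing delimiters yield empty edge fields: dropped
  }
}

xml_escape_text <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

xml_escape_attr <- function(x) {
  gsub("\"", "&quot;", xml_escape_text(x), fixed = TRUE)
}

#' Serialize a semantic document to XML text
#'
#' Inverse of [read_document()]: `read_document(write_document(x))` is
#' structurally equal to `x` (node names, attributes, payloads, child order).
#' Payload strings are emitted verbatim, so printed numeric precision is
#' preserved bit for bit.
#'
#' @param root The root `sem_node`.
#' @param declare_ns Declare the standard namespace prefixes on the root
#'   (default `TRUE`).
#' @return A single XML string.
#' @export
write_document <- function(root, declare_ns = TRUE) {
  validate_node(root)
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             sem_to_xml(root, 0L, declare_ns))
  paste(lines, collapse = "\n")
}

sem_to_xml <- function(node, depth, declare_ns = FALSE) {
  pad <- strrep("  ", depth)
  attrs <- node$attrs
  if (length(attrs)) {
    shown <- ifelse(names(attrs) %in% CMLX_ATTRS,
                    paste0("cmlx:", names(attrs)), names(attrs))
    astr <- paste0(" ", shown, "=\"", xml_escape_attr(attrs), "\"", collapse = "")
  } else astr <- ""
  if (declare_ns) {
    astr <- paste0(astr,
                   paste0(" ", names(NS_TABLE), "=\"", NS_TABLE, "\"", collapse = ""))
  }
  open <- paste0(pad, "<", node$name, astr)
  if (is.null(node$value) && !length(node$children)) {
    return(paste0(open, "/>"))
  }
  if (!is.null(node$value) && !length(node$children)) {
    return(paste0(open, ">", xml_escape_text(join_payload(node)),
                  "</", node$name, ">"))
  }
  body <- unlist(lapply(node$children, sem_to_xml, depth = depth + 1L))
  c(paste0(open, ">"), body, paste0(pad, "</", node$name, ">"))
}

join_payload <- function(node) {
  if (node$name %in% c("array", "matrix")) {
    d <- sem_attr(node, "delimiter")
    if (is.null(d) || d == "") {
      paste(node$value, collapse = " ")
    } else {
      paste0(d, paste(node$value, collapse = d), d)
    }
  } else {
    paste(node$value, collapse = " ")
  }
}

#' Extract a uniquely identified scalar value
#'
#' Finds the single scalar below `root` whose effective dictionary reference
#' equals `dictRef`.  A scalar's effective reference is its own `dictRef` or,
#' when wrapped in a `parameter`/`property` element (the compchem pattern),
#' the wrapper's `dictRef`.
#'
#' @param root A `sem_node`.
#' @param dictRef Qualified term, e.g. `"cc:hfenergy"`.
#' @return `list(value = <typed value>, units = <string or NULL>)`.
#' @export
extract_scalar <- function(root, dictRef) {
  hits <- find_scalars_by_ref(root, dictRef, path = "")
  if (length(hits) == 0) {
    qc_abort(sprintf("no scalar with dictRef '%s' found", dictRef), "qc_not_found")
  }
  if (length(hits) > 1) {
    qc_abort(sprintf("dictRef '%s' is ambiguous: %s", dictRef,
                     paste(vapply(hits, `[[`, "", "path"), collapse = ", ")),
             "qc_ambiguous")
  }
  n <- hits[[1]]$node
  list(value = scalar_value(n), units = sem_attr(n, "units"))
}

find_scalars_by_ref <- function(node, dictRef, path = "", inherited = NULL) {
  here <- paste0(path, "/", node$name,
                 if (!is.null(sem_attr(node, "id"))) paste0("[", sem_attr(node, "id"), "]") else "")
  out <- list()
  if (node$name == "scalar") {
    eff <- sem_attr(node, "dictRef") %||% inherited
    if (!is.null(eff) && ref_match(eff, dictRef)) {
      out <- list(list(node = node, path = here))
    }
    return(out)
  }
  pass <- if (node$name %in% c("parameter", "property")) {
    sem_attr(node, "dictRef") %||% inherited
  } else NULL
  for (ch in node$children) {
    out <- c(out, find_scalars_by_ref(ch, dictRef, here, pass))
  }
  out
}

# dictRef comparison through the prefix alias table (cc and compchem denote
# the same dictionary); falls back to exact match for unknown prefixes.
ref_match <- function(a, b) {
  if (identical(a, b)) return(TRUE)
  qname_local(a) == qname_local(b) &&
    alias_prefix(qname_prefix(a)) == alias_prefix(qname_prefix(b))
}

PREFIX_ALIASES <- c(cc = "compchem", compchem = "compchem",
                    g = "gaussian", x = "unassigned-temporary")

alias_prefix <- function(p) {
  if (p %in% names(PREFIX_ALIASES)) PREFIX_ALIASES[[p]] else p
}
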