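# Dictionaries: term definitions against which every dictRef in a document is
# resolved and type-checked.
#
# Prefix aliasing: documents use both `cc:` and `compchem:` for the compchem
# dictionary and `g:` for code-specific (Gaussian) terms; `x:` marks
# unassigned temporaries.  Aliases resolve, the canonical prefix on output is
# `cc:`.  Unknown `g:`/`x:` terms are always warnings, never errors: the
# code-specific vocabulary is allowed to float ahead of the dictionary.

#' Load a dictionary from its XML dialect
#'
#' @param text XML text or a file path.
#' @param on_duplicate What to do when two entries share an id: `"flag"`
#'   (default) keeps the first entry and records the duplicate in
#'   `$duplicates`, `"error"` aborts naming the id.  The shipped compchem
#'   dictionary intentionally preserves one upstream duplicate
#'   (`zpe.sumelectthermal`), which must be surfaced rather than silently
#'   collapsed.
#' @return A `qc_dictionary`: list with `prefix`, `title`, `entries`
#'   (named list of entry records), `contributors`, `duplicates`.
#' @export
load_dictionary <- function(text, on_duplicate = c("flag", "error")) {
  on_duplicate <- match.arg(on_duplicate)
  xml <- tryCatch(
    xml2::read_xml(if (length(text) == 1 && file.exists(text)) text else paste(text, collapse = "\n")),
    error = function(e) qc_abort(paste0("XML parse error: ", conditionMessage(e)),
                                 "qc_parse_error")
  )
  if (xml2::xml_name(xml) != "dictionary") {
    qc_abort("root element is not <dictionary>", "qc_parse_error")
  }
  prefix <- xml2::xml_attr(xml, "dictionaryPrefix")
  title <- xml2::xml_attr(xml, "title")
  entries <- list()
  duplicates <- character(0)
  contributors <- character(0)
  pos <- 0L
  for (ch in xml2::xml_children(xml)) {
    pos <- pos + 1L
    nm <- xml2::xml_name(ch)
    if (nm == "contributor") {
      contributors <- c(contributors, xml2::xml_text(ch))
    } else if (nm == "entry") {
      e <- parse_dict_entry(ch, pos)
      if (e$id %in% names(entries)) {
        if (on_duplicate == "error") {
          qc_abort(sprintf("duplicate dictionary entry id '%s'", e$id),
                   "qc_duplicate_id")
        }
        duplicates <- c(duplicates, e$id)
        qc_log(sprintf("dictionary: duplicate entry id '%s' kept first, flagged", e$id))
      } else {
        entries[[e$id]] <- e
      }
    }
  }
  structure(
    list(prefix = prefix, title = title, entries = entries,
         contributors = contributors, duplicates = duplicates),
    class = "qc_dictionary"
  )
}

parse_dict_entry <- function(x, pos) {
  id <- xml2::xml_attr(x, "id")
  if (is.na(id) || !nzchar(id) || grepl("\\s", id)) {
    qc_abort(sprintf("dictionary entry #%d lacks a valid id attribute", pos),
             "qc_parse_error")
  }
  grab <- function(a) {
    v <- xml2::xml_attr(x, a)
    if (is.na(v)) NULL else v
  }
  text_of <- function(el) {
    hit <- xml2::xml_find_first(x, paste0("./*[local-name()='", el, "']"))
    if (inherits(hit, "xml_missing")) "" else trimws(gsub("\\s+", " ", xml2::xml_text(hit)))
  }
  examples <- vapply(
    xml2::xml_find_all(x, ".//*[local-name()='p'][@class='example']"),
    function(p) trimws(gsub("\\s+", " ", xml2::xml_text(p))), ""
  )
  list(
    id = id,
    term = grab("term") %||% id,
    dataType = grab("dataType"),
    unitType = grab("unitType"),
    units = grab("units"),
    definition = text_of("definition"),
    description = text_of("description"),
    examples = examples
  )
}

#' @export
print.qc_dictionary <- function(x, ...) {
  cat(sprintf("<qc_dictionary '%s': %d entries%s>\n", x$prefix,
              length(x$entries),
              if (length(x$duplicates)) paste0(", ", length(x$duplicates),
                                               " duplicate id(s) flagged") else ""))
  invisible(x)
}

#' The shipped compchem dictionary
#'
#' @return The packaged computational-chemistry dictionary, loaded once and
#'   cached for the session.
#' @export
compchem_dictionary <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- load_dictionary(
        system.file("extdata", "dict", "compchem.xml", package = "qchemlog",
                    mustWork = TRUE)
      )
    }
    cache
  }
})

#' Resolve a qualified term against a set of dictionaries
#'
#' @param ref Qualified name, e.g. `"cc:hfenergy"`.
#' @param dicts A `qc_dictionary` or list of them; defaults to the shipped
#'   compchem dictionary.
#' @return The entry record.
#' @export
dict_resolve <- function(ref, dicts = list(compchem_dictionary())) {
  if (inherits(dicts, "qc_dictionary")) dicts <- list(dicts)
  if (!qname_ok(ref)) {
    qc_abort(sprintf("'%s' is not a prefix:local qualified name", ref),
             "qc_unresolved_prefix")
  }
  want <- alias_prefix(qname_prefix(ref))
  for (d in dicts) {
    if (alias_prefix(d$prefix) == want) {
      local <- qname_local(ref)
      e <- d$entries[[local]]
      if (is.null(e)) {
        qc_abort(sprintf("term '%s' not found in dictionary '%s'", local, d$prefix),
                 "qc_unresolved_term")
      }
      return(e)
    }
  }
  qc_abort(sprintf("no dictionary for prefix '%s'", qname_prefix(ref)),
           "qc_unresolved_prefix")
}

# --- validation reports ------------------------------------------------------

new_report <- function() {
  structure(list(findings = data.frame(
    severity = character(0), path = character(0), code = character(0),
    message = character(0), stringsAsFactors = FALSE
  )), class = "qc_report")
}

add_finding <- function(report, severity, path, code, message) {
  report$findings <- rbind(report$findings, data.frame(
    severity = severity, path = path, code = code, message = message,
    stringsAsFactors = FALSE
  ))
  report
}

#' Count of error-severity findings in a report
#' @param report A `qc_report`.
#' @return Integer.
#' @export
report_errors <- function(report) sum(report$findings$severity == "error")

#' @rdname report_errors
#' @export
report_warnings <- function(report) sum(report$findings$severity == "warning")

#' A report is valid when it holds no error-severity findings
#' @param report A `qc_report`.
#' @return `TRUE`/`FALSE`.
#' @export
report_valid <- function(report) report_errors(report) == 0L

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report: %d error(s), %d warning(s)>\n",
              report_errors(x), report_warnings(x)))
  if (nrow(x$findings)) print(x$findings, row.names = FALSE)
  invisible(x)
}

#' Check every dictionary reference in a document
#'
#' Walks the tree; every node whose `dictRef` does not resolve is reported as
#' a warning (code-specific `g:` and temporary `x:` terms are expected to
#' float ahead of the dictionaries).  A resolved node whose declared
#' `dataType` disagrees with the dictionary entry is an error.  Nodes that do
#' not declare a `dataType` are never type-errors: absence means string in
#' the document dialect but laconic logfile fields are not re-typed here.
#'
#' @param root A `sem_node`.
#' @param dicts Dictionary or list of dictionaries.
#' @return A `qc_report`.
#' @export
validate_refs <- function(root, dicts = list(compchem_dictionary())) {
  if (inherits(dicts, "qc_dictionary")) dicts <- list(dicts)
  report <- new_report()
  walk <- function(node, path) {
    here <- paste0(path, "/", node$name,
                   if (!is.null(sem_attr(node, "id"))) paste0("[", sem_attr(node, "id"), "]") else "")
    ref <- sem_attr(node, "dictRef")
    if (!is.null(ref)) {
      entry <- tryCatch(dict_resolve(ref, dicts), qc_error = function(e) e)
      if (inherits(entry, "qc_error")) {
        report <<- add_finding(report, "warning", here, "unresolved",
                               sprintf("dictRef '%s': %s", ref, conditionMessage(entry)))
      } else {
        dt <- sem_attr(node, "dataType")
        if (!is.null(dt) && !is.null(entry$dataType) && dt != entry$dataType) {
          report <<- add_finding(report, "error", here, "type-mismatch",
                                 sprintf("dictRef '%s' declares %s but dictionary says %s",
                                         ref, dt, entry$dataType))
        }
      }
    }
    for (ch in node$children) walk(ch, here)
  }
  walk(root, "")
  report
}
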