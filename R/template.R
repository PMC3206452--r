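# Template compilation: field specifiers, line records, and the template XML
# dialect.
#
# A field specifier is a bracketed capture declaration inside a record
# pattern: `{COUNT?TYPE, REF}` with COUNT an integer or `min_max` range
# (absent count means 1) and TYPE one of
#   F  floating point (Fortran D exponents accepted, normalized to E)
#   I  integer
#   X  string token (single, trimmed)
#   A  rest of line
# Each specifier compiles to exactly one regex capture group.  F/I groups are
# alternation-free fixed-count fragments with optional tails, so matching is
# linear in the line length (concatenating naive per-value regexes is the
# classic way such parsers go exponential on long lines).

FLOAT_RE <- "[+-]?(?:[0-9]+\\.[0-9]*|\\.[0-9]+|[0-9]+)(?:[EeDd][+-]?[0-9]+)?"
INT_RE <- "[+-]?[0-9]+"

FIELD_SPEC_RE <- "^\\{\\s*([0-9]+(?:_[0-9]+)?)?([FIXA])\\s*,\\s*([^}[:space:]]+)\\s*\\}$"

#' Compile a field specifier
#'
#' @param spec_text The bracketed text, e.g. `"{1_5F, g:eigen}"`.
#' @return A `qc_field_spec`: min/max counts, value type, temporary
#'   reference, and the regex fragment (one capture group).
#' @export
#' @examples
#' compile_field_spec("{1_5F, g:eigen}")
compile_field_spec <- function(spec_text) {
  m <- regexec(FIELD_SPEC_RE, trimws(spec_text))[[1]]
  if (m[1] == -1) {
    qc_abort(sprintf("malformed field specifier '%s'", spec_text),
             "qc_template_error")
  }
  parts <- regmatches(trimws(spec_text), list(m))[[1]]
  count <- parts[2]; type <- parts[3]; ref <- parts[4]
  if (count == "") {
    min_count <- max_count <- 1L
  } else if (grepl("_", count)) {
    mm <- as.integer(strsplit(count, "_", fixed = TRUE)[[1]])
    min_count <- mm[1]; max_count <- mm[2]
  } else {
    min_count <- max_count <- as.integer(count)
  }
  if (type %in% c("X", "A") && (min_count != 1L || max_count != 1L)) {
    qc_abort(sprintf("field '%s': X and A always have count 1", spec_text),
             "qc_template_error")
  }
  if (min_count < 1L || max_count < min_count) {
    qc_abort(sprintf("field '%s': invalid count range", spec_text),
             "qc_template_error")
  }
  atom <- switch(type, F = FLOAT_RE, I = INT_RE, X = NULL, A = NULL)
  regex <- switch(type,
    X = "(.*?)",
    A = "(.*)",
    {
      tail <- if (max_count > 1L) {
        sprintf("(?:\\s+%s){%d,%d}", atom, min_count - 1L, max_count - 1L)
      } else ""
      paste0("(\\s*", atom, tail, ")")
    }
  )
  structure(
    list(min_count = min_count, max_count = max_count, value_type = type,
         temp_ref = ref, regex = regex),
    class = "qc_field_spec"
  )
}

#' Compile a record into a single-line matcher
#'
#' The record pattern interleaves literal regex segments with field
#' specifiers.  Brace groups that do not parse as field specifiers (such as
#' regex quantifiers `{2,3}`) are kept as literal regex.
#'
#' @param id Record id.
#' @param pattern The record pattern text.
#' @param repeat_ Repeat declaration (`"once"`, `"*"`, `"+"`, or a count);
#'   recorded for documentation, the template line loop provides repetition.
#' @return A `qc_record` with the compiled regex (anchored at line start) and
#'   the ordered field list.
#' @export
compile_record <- function(id, pattern, repeat_ = "once") {
  fields <- list()
  regex <- "^"
  rest <- pattern
  while (nzchar(rest)) {
    m <- regexpr("\\{[^{}]*\\}", rest)
    if (m == -1) {
      regex <- paste0(regex, rest)
      break
    }
    lit <- substr(rest, 1L, m - 1L)
    brace <- regmatches(rest, m)
    regex <- paste0(regex, lit)
    if (grepl(FIELD_SPEC_RE, brace)) {
      fs <- compile_field_spec(brace)
      fields <- c(fields, list(fs))
      regex <- paste0(regex, fs$regex)
    } else {
      regex <- paste0(regex, brace)  # literal regex quantifier
    }
    rest <- substr(rest, m + attr(m, "match.length"), nchar(rest))
  }
  ok <- tryCatch({ grepl(regex, "", perl = TRUE); TRUE },
                 error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) {
    qc_abort(sprintf("record '%s': pattern does not compile: %s", id, pattern),
             "qc_template_error")
  }
  structure(
    list(id = id, repeat_ = repeat_, pattern = pattern, fields = fields,
         regex = regex),
    class = "qc_record"
  )
}

normalize_exponent <- function(tok) {
  sub("([0-9.])[dD]([+-]?[0-9]+)$", "\\1E\\2", tok)
}

#' Match one line against a compiled record
#'
#' @param rec A `qc_record`.
#' @param line One input line.
#' @return `NULL` when the line does not match; otherwise a list of raw
#'   `sem_node`s, one per field specifier (scalar for count 1, array for
#'   larger counts), each labelled with its temporary reference.
#' @export
match_record <- function(rec, line) {
  m <- regexpr(rec$regex, line, perl = TRUE)
  if (m == -1) return(NULL)
  cs <- attr(m, "capture.start"); cl <- attr(m, "capture.length")
  nodes <- list()
  for (i in seq_along(rec$fields)) {
    fs <- rec$fields[[i]]
    raw <- substr(line, cs[i], cs[i] + cl[i] - 1L)
    if (fs$value_type %in% c("X", "A")) {
      nodes <- c(nodes, list(
        sem_node("scalar", temp = fs$temp_ref, value = trimws(raw))
      ))
    } else {
      toks <- strsplit(trimws(raw), "\\s+")[[1]]
      toks <- toks[nzchar(toks)]
      if (fs$value_type == "F") toks <- vapply(toks, normalize_exponent, "", USE.NAMES = FALSE)
      dt <- if (fs$value_type == "F") "xsd:double" else "xsd:integer"
      if (fs$max_count > 1L) {
        nodes <- c(nodes, list(
          sem_node("array", dataType = dt, size = as.character(length(toks)),
                   temp = fs$temp_ref, value = toks)
        ))
      } else {
        nodes <- c(nodes, list(
          sem_node("scalar", dataType = dt, temp = fs$temp_ref, value = toks[1])
        ))
      }
    }
  }
  nodes
}

# --- template XML dialect ----------------------------------------------------

#' Load a template from its XML dialect
#'
#' Template elements carry `pattern` (start regex matched against a full
#' line), optional `endPattern` (regex for the first line NOT consumed),
#' `repeat`, and the engine extensions `section` (which compchem job module
#' the chunk belongs to), `jobstart` (chunk opens a new job), `strict`
#' (back-track to the next template when no interior line matched) and
#' `molecule` (assemble captured atom rows into a molecule node).  Children
#' are `record` elements, nested `template`s, `transform` steps, and
#' `comment class="example.input"/"example.output"` pairs: embedded examples
#' double as unit tests.
#'
#' @param text XML text or file path.
#' @return A `qc_template`.
#' @export
load_template <- function(text) {
  xml <- tryCatch(
    xml2::read_xml(if (length(text) == 1 && file.exists(text)) text else paste(text, collapse = "\n")),
    error = function(e) qc_abort(paste0("template XML parse error: ", conditionMessage(e)),
                                 "qc_template_error")
  )
  if (xml2::xml_name(xml) != "template") {
    qc_abort("root element is not <template>", "qc_template_error")
  }
  parse_template_el(xml)
}

parse_template_el <- function(x) {
  grab <- function(a) {
    v <- xml2::xml_attr(x, a)
    if (is.na(v)) NULL else v
  }
  id <- grab("id") %||% "anonymous"
  pattern <- grab("pattern")
  if (is.null(pattern)) {
    qc_abort(sprintf("template '%s' lacks a start pattern", id), "qc_template_error")
  }
  children <- list()
  transforms <- list()
  examples_in <- list()
  examples_out <- list()
  for (ch in xml2::xml_children(x)) {
    nm <- xml2::xml_name(ch)
    if (nm == "record") {
      rid <- xml2::xml_attr(ch, "id")
      rrep <- xml2::xml_attr(ch, "repeat")
      children <- c(children, list(compile_record(
        if (is.na(rid)) "anonymous" else rid,
        xml2::xml_text(ch),
        if (is.na(rrep)) "once" else rrep
      )))
    } else if (nm == "template") {
      children <- c(children, list(parse_template_el(ch)))
    } else if (nm == "transform") {
      transforms <- c(transforms, list(parse_transform_el(ch)))
    } else if (nm == "comment") {
      cls <- xml2::xml_attr(ch, "class")
      cid <- xml2::xml_attr(ch, "id")
      if (identical(cls, "example.input")) {
        txt <- xml2::xml_text(ch)
        lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
        while (length(lines) && !nzchar(trimws(lines[1]))) lines <- lines[-1]
        while (length(lines) && !nzchar(trimws(lines[length(lines)]))) lines <- lines[-length(lines)]
        examples_in[[if (is.na(cid)) paste0("ex", length(examples_in) + 1L) else cid]] <- lines
      } else if (identical(cls, "example.output")) {
        el <- xml2::xml_find_first(ch, "./*")
        if (!inherits(el, "xml_missing")) {
          examples_out[[if (is.na(cid)) paste0("ex", length(examples_out) + 1L) else cid]] <- xml_to_sem(el)
        }
      }
    }
  }
  examples <- lapply(names(examples_in) %||% character(0), function(k) {
    list(id = k, input = examples_in[[k]],
         expected = if (k %in% names(examples_out)) examples_out[[k]] else NULL)
  })
  structure(
    list(id = id,
         start_pattern = pattern,
         end_pattern = grab("endPattern"),
         repeat_ = grab("repeat") %||% "once",
         strict = identical(grab("strict"), "true"),
         section = grab("section"),
         jobstart = identical(grab("jobstart"), "true"),
         molecule = identical(grab("molecule"), "true"),
         children = children,
         transforms = transforms,
         examples = examples),
    class = "qc_template"
  )
}

#' @export
print.qc_template <- function(x, ...) {
  cat(sprintf("<qc_template '%s': %d child(ren), %d transform(s), %d example(s)>\n",
              x$id, length(x$children), length(x$transforms), length(x$examples)))
  invisible(x)
}

#' Load an ordered template pack from a directory
#'
#' Files are loaded in lexicographic order; the order is the claim priority
#' used by [match_chunks()].
#'
#' @param dir Directory of template XML files.
#' @return List of `qc_template`.
#' @export
load_template_pack <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.xml$", full.names = TRUE))
  if (!length(files)) {
    qc_abort(sprintf("no template files found in '%s'", dir), "qc_template_error")
  }
  lapply(files, load_template)
}

#' The shipped Gaussian-style template pack
#'
#' @return Ordered list of templates covering the block types emitted by
#'   [generate_logfile()] (and the common blocks of real Gaussian-style
#'   logs: eigenvalue tables, orientation tables, SCF and thermochemistry
#'   summaries, job chaining markers).
#' @export
gaussian_pack <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- load_template_pack(
        system.file("extdata", "templates", "gaussian", package = "qchemlog",
                    mustWork = TRUE)
      )
    }
    cache
  }
})
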