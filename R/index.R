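# Desk-scale index of converted calculations.
#
# Storage is a single plain-text JSON file plus an in-memory list; no server
# and no external database -- the store targets the individual-researcher
# scale.  Each ingested job becomes one entry record indexed on the four
# compchem criteria: environment (program, hostname), initialization
# (formula, method, basis, atom count), calculation and finalization
# (numeric properties with units).  Ingest is deliberately content-blind to
# duplicates: re-ingesting identical content under a new id is permitted.

QUERY_FIELDS <- c("formula", "method", "basis", "program", "hostname",
                  "natoms", "entry_id", "source_path")

# conversions to the canonical unit per unit type (energies -> hartree)
UNIT_TO_CANONICAL <- list(
  "unitType:energy" = c(
    "nonsi:hartree" = 1,
    "u:jmol-1"      = 1 / 2625499.62,
    "u:kjmol-1"     = 1 / 2625.49962,
    "u:kcalmol-1"   = 1 / 627.509474,
    "nonsi:ev"      = 1 / 27.211386245988
  )
)

#' Open (or create) an index store
#'
#' @param path Path of the store file (JSON); created empty when absent.
#' @return A `qc_store` environment.
#' @export
store_open <- function(path) {
  st <- new.env(parent = emptyenv())
  st$path <- path
  st$records <- list()
  st$counter <- 0L
  if (file.exists(path)) {
    blob <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    st$records <- blob$records %||% list()
    st$counter <- blob$counter %||% length(st$records)
  }
  class(st) <- "qc_store"
  st
}

store_save <- function(store) {
  jsonlite::write_json(
    list(records = store$records, counter = store$counter),
    store$path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(store)
}

#' @export
print.qc_store <- function(x, ...) {
  cat(sprintf("<qc_store '%s': %d entries>\n", x$path, length(x$records)))
  invisible(x)
}

first_param <- function(job, term) {
  hits <- find_scalars_by_ref(job, term)
  if (!length(hits)) return(NULL)
  scalar_value(hits[[1]]$node)
}

job_formula <- function(job) {
  for (role in c("initialization", "finalization")) {
    mods <- Filter(function(ch) identical(role_of(ch), role), job$children)
    for (m in mods) {
      for (f in find_nodes(m, ".//formula")) {
        con <- sem_attr(f, "concise")
        if (!is.null(con)) return(con)
      }
    }
  }
  NULL
}

job_properties <- function(job) {
  out <- list()
  fin <- Filter(function(ch) identical(role_of(ch), "finalization"), job$children)
  grab <- function(node, inherited = NULL) {
    eff <- sem_attr(node, "dictRef") %||% inherited
    if (node$name %in% c("scalar", "array")) {
      if (!is.null(eff) && identical(sem_attr(node, "dataType"), "xsd:double") &&
          length(node$value) == 1L) {
        key <- canonical_ref(eff)
        if (is.null(out[[key]])) {
          out[[key]] <<- list(value = parse_payload(node$value, "xsd:double"),
                              units = sem_attr(node, "units"))
        }
      }
      return(invisible(NULL))
    }
    pass <- if (node$name %in% c("property", "parameter")) eff else NULL
    for (ch in node$children) grab(ch, pass)
  }
  for (m in fin) {
    for (pl in Filter(function(x) x$name == "propertyList", m$children)) grab(pl)
  }
  out
}

entry_hash <- function(job) {
  tf <- tempfile(fileext = ".xml")
  on.exit(unlink(tf))
  writeLines(write_document(job, declare_ns = FALSE), tf)
  unname(tools::md5sum(tf))
}

#' Ingest a compchem document into the store
#'
#' The document must validate against the convention with zero errors; an
#' invalid document is rejected with its validation report attached to the
#' condition.  One entry record is created per job.
#'
#' @param store A `qc_store`.
#' @param doc A compchem `sem_node` document.
#' @param source_path Provenance string recorded on the entries.
#' @return The list of new entry records, invisibly.
#' @export
store_ingest <- function(store, doc, source_path = "<memory>") {
  report <- validate_convention(doc)
  if (!report_valid(report)) {
    qc_abort(sprintf("document rejected: %d convention error(s)",
                     report_errors(report)),
             "qc_invalid_document", report = report)
  }
  jobs <- find_nodes(doc, ".//module[@dictRef='cc:job']")
  new_records <- list()
  for (job in jobs) {
    store$counter <- store$counter + 1L
    rec <- list(
      entry_id = sprintf("e%04d-%s", store$counter, entry_hash(job)),
      source_path = source_path,
      formula_concise = job_formula(job) %||% "",
      program = first_param(job, "cc:program"),
      hostname = first_param(job, "cc:hostname"),
      method = first_param(job, "cc:method"),
      basis = first_param(job, "cc:basis"),
      natoms = first_param(job, "cc:natoms"),
      properties = job_properties(job),
      created = store$counter
    )
    store$records[[rec$entry_id]] <- rec
    new_records <- c(new_records, list(rec))
  }
  store_save(store)
  invisible(new_records)
}

canonical_value <- function(prop, term) {
  entry <- tryCatch(dict_resolve(term), qc_error = function(e) NULL)
  ut <- if (!is.null(entry)) entry$unitType else NULL
  tab <- if (!is.null(ut)) UNIT_TO_CANONICAL[[ut]] else NULL
  if (is.null(tab)) return(prop$value)  # no canonical unit for this type
  u <- prop$units
  if (is.null(u)) return(prop$value)    # unitless value taken as canonical
  if (!u %in% names(tab)) {
    qc_abort(sprintf("no unit conversion for '%s' (%s)", u, ut), "qc_query_error")
  }
  prop$value * tab[[u]]
}

#' Query the store
#'
#' Criteria are conjunctive: exact field matches plus numeric ranges over
#' property terms.  Range bounds are interpreted in the canonical unit of
#' the term's unit type (energies in hartree); stored values are converted
#' via a fixed table, and a unit outside the table is a query error, never a
#' silent miss.
#'
#' @param store A `qc_store`.
#' @param fields Named list of exact matches, e.g.
#'   `list(formula = "C 1 H 4")`.
#' @param ranges Named list of length-2 numeric bounds per term, e.g.
#'   `list("cc:hfenergy" = c(-41, -40))`.
#' @return List of entry records ordered by creation then id.
#' @export
store_query <- function(store, fields = list(), ranges = list()) {
  bad <- setdiff(names(fields), QUERY_FIELDS)
  if (length(bad)) {
    qc_abort(sprintf("unknown query field(s): %s", paste(bad, collapse = ", ")),
             "qc_query_error")
  }
  hits <- Filter(function(rec) {
    for (f in names(fields)) {
      v <- rec[[if (f == "formula") "formula_concise" else f]]
      if (is.null(v) || as.character(v) != as.character(fields[[f]])) return(FALSE)
    }
    for (term in names(ranges)) {
      prop <- rec$properties[[term]]
      if (is.null(prop)) return(FALSE)
      cv <- canonical_value(prop, term)
      if (is.null(cv)) return(FALSE)
      lohi <- ranges[[term]]
      if (!(cv >= lohi[1] && cv <= lohi[2])) return(FALSE)
    }
    TRUE
  }, store$records)
  ord <- order(vapply(hits, function(r) r$created, 1),
               vapply(hits, function(r) r$entry_id, ""))
  unname(hits[ord])
}

#' Export the triples of one entry
#'
#' @param store A `qc_store`.
#' @param entry_id Entry id.
#' @return Data frame of triples (`subject`, `predicate`, `object`,
#'   `units`), deterministically sorted, one triple per indexed field.
#' @export
store_triples <- function(store, entry_id) {
  rec <- store$records[[entry_id]]
  if (is.null(rec)) {
    qc_abort(sprintf("no entry '%s' in store", entry_id), "qc_not_found")
  }
  rows <- list(
    data.frame(subject = rec$entry_id, predicate = "x:sourcePath",
               object = rec$source_path, units = NA, stringsAsFactors = FALSE),
    data.frame(subject = rec$entry_id, predicate = "x:created",
               object = as.character(rec$created), units = NA, stringsAsFactors = FALSE),
    data.frame(subject = rec$entry_id, predicate = "cc:formula",
               object = rec$formula_concise, units = NA, stringsAsFactors = FALSE)
  )
  for (f in c("program", "hostname", "method", "basis", "natoms")) {
    if (!is.null(rec[[f]])) {
      rows <- c(rows, list(data.frame(
        subject = rec$entry_id, predicate = paste0("cc:", f),
        object = as.character(rec[[f]]), units = NA, stringsAsFactors = FALSE)))
    }
  }
  for (term in names(rec$properties)) {
    p <- rec$properties[[term]]
    rows <- c(rows, list(data.frame(
      subject = rec$entry_id, predicate = term,
      object = format(p$value, digits = 15),
      units = p$units %||% NA, stringsAsFactors = FALSE)))
  }
  out <- do.call(rbind, rows)
  out[order(out$predicate, out$object), , drop = FALSE]
}

#' Format triples as N-Triples-style text lines
#'
#' @param triples Data frame from [store_triples()].
#' @return Character vector of lines `<subject> <predicate> "object" .`
#' @export
format_triples <- function(triples) {
  sprintf('<%s> <%s> "%s"%s .', triples$subject, triples$predicate,
          triples$object,
          ifelse(is.na(triples$units), "", paste0("^^<", triples$units, ">")))
}

#' Rebuild an entry record from its triples
#'
#' Round-trip counterpart of [store_triples()]: the reconstruction equals
#' the stored record on all indexed fields.
#'
#' @param triples Data frame from [store_triples()].
#' @return An entry record list.
#' @export
triples_to_record <- function(triples) {
  get1 <- function(pred) {
    i <- which(triples$predicate == pred)
    if (!length(i)) NULL else triples$object[i[1]]
  }
  props <- list()
  core <- c("x:sourcePath", "x:created", "cc:formula", "cc:program",
            "cc:hostname", "cc:method", "cc:basis", "cc:natoms")
  for (i in seq_len(nrow(triples))) {
    pred <- triples$predicate[i]
    if (pred %in% core) next
    props[[pred]] <- list(
      value = as.numeric(triples$object[i]),
      units = if (is.na(triples$units[i])) NULL else triples$units[i]
    )
  }
  rec <- list(
    entry_id = triples$subject[1],
    source_path = get1("x:sourcePath"),
    formula_concise = get1("cc:formula") %||% "",
    program = get1("cc:program"),
    hostname = get1("cc:hostname"),
    method = get1("cc:method"),
    basis = get1("cc:basis"),
    natoms = if (is.null(get1("cc:natoms"))) NULL else as.integer(get1("cc:natoms")),
    properties = props[order(names(props))],
    created = as.numeric(get1("x:created"))
  )
  rec
}
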