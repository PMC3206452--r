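# Restructuring parsed trees into the compchem convention
# (jobList -> job -> environment/initialization/calculation/finalization)
# and validating conformance.
#
# Role assignment is rule-driven: each chunk module carries the `section`
# its template declared, and a new job begins at each program-restart marker
# (`jobstart` templates), in source order.  Content that fits no role is
# collected under a cc:userDefinedModule per job, with a warning -- never
# dropped.

JOB_ROLES <- c("environment", "initialization", "calculation", "finalization")

#' Restructure a raw parsed document into a compchem document
#'
#' @param raw Raw document from [match_chunks()] (`$doc`).
#' @param rules Optional transform program applied to `raw` first.
#' @return A compchem document: root module with
#'   `convention="convention:compchem"` holding one `cc:jobList` of
#'   `cc:job` modules.  A `qc_report` of restructuring warnings is attached
#'   as attribute `"report"`.  The operation conserves content: every
#'   scalar/array payload of the input appears exactly once in the output.
#' @export
restructure <- function(raw, rules = NULL) {
  report <- new_report()
  if (!is.null(rules) && length(rules)) raw <- apply_program(raw, rules)
  items <- raw$children
  # split into jobs at restart markers
  jobs_items <- list()
  cur <- list()
  for (it in items) {
    if (identical(sem_attr(it, "jobstart"), "true") && length(cur)) {
      jobs_items <- c(jobs_items, list(cur))
      cur <- list()
    }
    cur <- c(cur, list(it))
  }
  if (length(cur) || !length(jobs_items)) jobs_items <- c(jobs_items, list(cur))

  jobs <- list()
  for (jn in seq_along(jobs_items)) {
    built <- build_job(jobs_items[[jn]], jn, report)
    jobs <- c(jobs, list(built$job))
    report <- built$report
  }
  doc <- sem_node(
    "module", convention = "convention:compchem",
    children = list(
      sem_node("module", id = "jobList1", dictRef = "cc:jobList", children = jobs)
    )
  )
  attr(doc, "report") <- report
  doc
}

strip_scaffold <- function(node) {
  for (a in SCAFFOLD_ATTRS) node <- sem_set_attr(node, a, NULL)
  node
}

# effective term of a captured value node: assigned dictRef, else its
# temporary label when that is a qualified name
value_ref <- function(node) {
  sem_attr(node, "dictRef") %||% {
    t <- sem_attr(node, "temp")
    if (!is.null(t) && qname_ok(t)) t else NULL
  }
}

build_job <- function(items, jobno, report) {
  secs <- vapply(items, function(it) sem_attr(it, "section") %||% "", "")
  job <- sem_node("module", dictRef = "cc:job", id = paste0("job", jobno))

  env_items <- items[secs == "environment"]
  if (length(env_items)) {
    job$children <- c(job$children, list(
      build_role_module("environment", "cc:environment", env_items,
                        wrap = "parameter")
    ))
  }
  init_items <- items[secs == "initialization"]
  if (length(init_items)) {
    job$children <- c(job$children, list(
      build_role_module("initialization", "cc:initialization", init_items,
                        wrap = "parameter")
    ))
  }
  calc_items <- items[secs == "calculation"]
  if (length(calc_items)) {
    inner <- unlist(lapply(calc_items, function(it) {
      lapply(it$children, strip_scaffold)
    }), recursive = FALSE)
    job$children <- c(job$children, list(
      sem_node("module", id = "calculation", dictRef = "cc:calculation",
               children = list(
                 sem_node("module", id = "otherComponents",
                          dictRef = "cc:userDefinedModule",
                          children = inner %||% list())
               ))
    ))
  }
  final_items <- items[secs == "finalization"]
  if (length(final_items)) {
    job$children <- c(job$children, list(
      build_role_module("finalization", "cc:finalization", final_items,
                        wrap = "property")
    ))
  }
  stray <- items[!secs %in% c(JOB_ROLES)]
  if (length(stray)) {
    job$children <- c(job$children, list(
      sem_node("module", id = "otherComponents", dictRef = "cc:userDefinedModule",
               children = lapply(stray, strip_scaffold))
    ))
    report <- add_finding(
      report, "warning", paste0("/job", jobno), "unassigned-content",
      sprintf("%d chunk module(s) fit no job role; kept under cc:userDefinedModule",
              length(stray))
    )
  }
  list(job = job, report = report)
}

# Merge section chunk modules into one role module.  Captured scalars (and,
# in finalization, labelled arrays) become parameter/property entries; the
# wrapper takes the term, molecules sit directly under the role module, and
# everything else is preserved under a cc:userDefinedModule.
build_role_module <- function(id, dictRef, items, wrap) {
  wrapped <- list()
  molecules <- list()
  rest <- list()
  for (it in items) {
    for (ch in it$children) {
      ref <- value_ref(ch)
      if (ch$name == "scalar" && !is.null(ref)) {
        clean <- sem_set_attr(sem_set_attr(ch, "temp", NULL), "dictRef", NULL)
        wrapped <- c(wrapped, list(
          sem_node(wrap, dictRef = canonical_ref(ref), children = list(clean))
        ))
      } else if (ch$name == "array" && wrap == "property" && !is.null(ref)) {
        clean <- sem_set_attr(ch, "temp", NULL)
        clean <- sem_set_attr(clean, "dictRef", canonical_ref(ref))
        wrapped <- c(wrapped, list(
          sem_node(wrap, dictRef = canonical_ref(ref), children = list(clean))
        ))
      } else if (ch$name == "molecule") {
        molecules <- c(molecules, list(ch))
      } else {
        rest <- c(rest, list(strip_scaffold(ch)))
      }
    }
  }
  children <- list()
  if (length(wrapped)) {
    children <- c(children, list(
      sem_node(if (wrap == "parameter") "parameterList" else "propertyList",
               children = wrapped)
    ))
  }
  children <- c(children, molecules)
  if (length(rest)) {
    children <- c(children, list(
      sem_node("module", id = "otherComponents", dictRef = "cc:userDefinedModule",
               children = rest)
    ))
  }
  sem_node("module", id = id, dictRef = dictRef, children = children)
}

# canonical output prefix is cc:
canonical_ref <- function(ref) {
  if (alias_prefix(qname_prefix(ref)) == "compchem") {
    paste0("cc:", qname_local(ref))
  } else ref
}

# --- convention validation ---------------------------------------------------

role_of <- function(node) {
  ref <- sem_attr(node, "dictRef")
  if (is.null(ref) || node$name != "module") return(NULL)
  local <- qname_local(ref)
  if (alias_prefix(qname_prefix(ref)) == "compchem" && local %in% JOB_ROLES) {
    local
  } else NULL
}

#' Validate a document against the compchem convention
#'
#' Errors: missing `cc:jobList` root, more than one module of a role per
#' job, missing initialization or finalization, molecule invariant
#' violations.  Warnings: parameters outside a `parameterList`, property
#' lists inside initialization (and the converse misplacements), stray
#' content in the job list, final molecules without a formula.
#'
#' @param doc A `sem_node`.
#' @return A `qc_report`; the document is valid iff [report_valid()] holds.
#' @export
validate_convention <- function(doc) {
  report <- new_report()
  joblist <- NULL
  if (identical_ref(sem_attr(doc, "dictRef"), "cc:jobList")) {
    joblist <- doc
  } else {
    hits <- Filter(function(ch) identical_ref(sem_attr(ch, "dictRef"), "cc:jobList"),
                   doc$children)
    if (length(hits) == 1L) joblist <- hits[[1]]
  }
  if (is.null(joblist)) {
    return(add_finding(report, "error", "/", "no-joblist",
                       "document root does not hold a cc:jobList module"))
  }
  jobs <- Filter(function(ch) identical_ref(sem_attr(ch, "dictRef"), "cc:job"),
                 joblist$children)
  if (length(jobs) < length(joblist$children)) {
    report <- add_finding(report, "warning", "/jobList", "stray-content",
                          "jobList holds content other than cc:job modules")
  }
  if (!length(jobs)) {
    report <- add_finding(report, "error", "/jobList", "no-jobs",
                          "jobList holds no cc:job module")
  }
  for (ji in seq_along(jobs)) {
    job <- jobs[[ji]]
    jpath <- paste0("/jobList/job[", ji, "]")
    roles <- vapply(job$children, function(ch) role_of(ch) %||% "", "")
    for (r in JOB_ROLES) {
      k <- sum(roles == r)
      if (k > 1L) {
        report <- add_finding(report, "error", jpath, "duplicate-role",
                              sprintf("job has %d %s modules", k, r))
      }
    }
    for (r in c("initialization", "finalization")) {
      if (!any(roles == r)) {
        report <- add_finding(report, "error", jpath, "missing-role",
                              sprintf("job lacks a %s module", r))
      }
    }
    report <- check_placement(job, jpath, roles, report)
  }
  # molecule invariants anywhere in the document
  report <- check_molecules(doc, "", report)
  report
}

identical_ref <- function(a, b) {
  !is.null(a) && ref_match(a, b)
}

check_placement <- function(job, jpath, roles, report) {
  for (i in seq_along(job$children)) {
    ch <- job$children[[i]]
    r <- role_of(ch) %||% ""
    if (r == "initialization") {
      if (length(find_nodes(ch, ".//propertyList")) > 0) {
        report <- add_finding(report, "warning", paste0(jpath, "/initialization"),
                              "misplaced-property",
                              "propertyList inside initialization")
      }
    }
    if (r == "finalization") {
      if (length(find_nodes(ch, ".//parameterList")) > 0) {
        report <- add_finding(report, "warning", paste0(jpath, "/finalization"),
                              "misplaced-parameter",
                              "parameterList inside finalization")
      }
      for (mol in find_nodes(ch, ".//molecule")) {
        if (!any(vapply(mol$children, function(x) x$name == "formula", TRUE))) {
          report <- add_finding(report, "warning", paste0(jpath, "/finalization"),
                                "missing-formula",
                                "final molecule carries no formula node")
        }
      }
    }
  }
  # every parameter/property must sit inside its list container
  report <- check_wrappers(job, jpath, report, "parameter", "parameterList")
  report <- check_wrappers(job, jpath, report, "property", "propertyList")
  report
}

check_wrappers <- function(node, path, report, elem, container,
                           inside_container = FALSE, inside_molecule = FALSE) {
  here <- paste0(path, "/", node$name)
  if (node$name == elem && !inside_container && !inside_molecule) {
    report <- add_finding(report, "warning", here, paste0("misplaced-", elem),
                          sprintf("%s outside a %s", elem, container))
  }
  for (ch in node$children) {
    report <- check_wrappers(
      ch, here, report, elem, container,
      inside_container = inside_container || node$name == container,
      inside_molecule = inside_molecule || node$name %in% c("molecule", "atom")
    )
  }
  report
}

check_molecules <- function(node, path, report) {
  here <- paste0(path, "/", node$name)
  if (node$name == "molecule") {
    bad <- tryCatch({ validate_molecule(node, here); NULL },
                    qc_error = function(e) conditionMessage(e))
    if (!is.null(bad)) {
      report <- add_finding(report, "error", here, "molecule-invariant", bad)
    }
  }
  for (ch in node$children) report <- check_molecules(ch, here, report)
  report
}

# every scalar/array/matrix payload as a multiset signature, for the content
# conservation property of restructure()
payload_signature <- function(node) {
  out <- character(0)
  if (node$name %in% c("scalar", "array", "matrix")) {
    out <- paste(node$name, paste(node$value, collapse = " "))
  }
  for (ch in node$children) out <- c(out, payload_signature(ch))
  out
}
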