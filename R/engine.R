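# Chunk recognition and template execution.
#
# The engine scans a logfile top to bottom.  At each line the FIRST template
# (in pack order) whose start pattern matches the full line claims a chunk;
# claimed lines are consumed and never re-offered to other templates.  Lines
# claimed by no template accumulate into unparsed ranges.  Parsed chunks and
# unparsed ranges tile the input exactly (the partition property), so
# "which sections have been parsed and which have not" is always auditable
# and a strange document degrades to residue instead of crashing the run.

full_match <- function(pattern, line) {
  grepl(paste0("^(?:", pattern, ")$"), line, perl = TRUE)
}

split_lines <- function(text) {
  # \r stripped; trailing newline remembered by the caller
  gsub("\r", "", strsplit(text, "\n", fixed = TRUE)[[1]], fixed = TRUE)
}

# extent (inclusive end index) of the chunk claimed by tpl starting at i
chunk_extent <- function(lines, i, tpl) {
  n <- length(lines)
  if (!is.null(tpl$end_pattern)) {
    j <- i + 1L
    while (j <= n && !full_match(tpl$end_pattern, lines[j])) j <- j + 1L
    return(j - 1L)
  }
  # no end pattern: maximal munch, chunk ends at the last line consumed by a
  # child record or nested template
  j <- i
  while (j < n) {
    nxt <- lines[j + 1L]
    hit <- FALSE
    for (ch in tpl$children) {
      if (inherits(ch, "qc_record")) {
        if (!is.null(match_record(ch, nxt))) { hit <- TRUE; break }
      } else if (inherits(ch, "qc_template")) {
        if (full_match(ch$start_pattern, nxt)) { hit <- TRUE; break }
      }
    }
    if (!hit) break
    j <- j + 1L
  }
  j
}

# Label promotion: reproduces the published record idiom where a leading
# string capture names the numeric capture of the same line ("the trailing
# part of the line is captured into an array and named with the leading
# string").  Applied only to two-field records [X, F/I]; records with more
# fields keep every capture as its own labelled node.
promote_labels <- function(nodes, rec) {
  types <- vapply(rec$fields, `[[`, "", "value_type")
  if (length(types) == 2L && types[1] == "X" && types[2] %in% c("F", "I")) {
    label <- trimws(nodes[[1]]$value)
    nodes[[2]] <- sem_set_attr(nodes[[2]], "temp", label)
    return(nodes[2])
  }
  nodes
}

unparsed_node <- function(line) {
  sem_node("comment", class = "unparsed", value = line)
}

is_unparsed_node <- function(node) {
  node$name == "comment" && identical(sem_attr(node, "class"), "unparsed")
}

#' Apply a template to a slice of lines
#'
#' @param lines Character vector: the chunk, whose first line matches the
#'   template's start pattern.
#' @param tpl A `qc_template`.
#' @param transforms Apply the template's own transform steps to the chunk
#'   module (default `TRUE`).
#' @return A `module` node labelled with the template id.  Lines matching no
#'   child record degrade to unparsed text children; a mismatch never
#'   errors.
#' @export
apply_template <- function(lines, tpl, transforms = TRUE) {
  mod <- sem_node("module", templateRef = tpl$id)
  if (!is.null(tpl$section)) mod <- sem_set_attr(mod, "section", tpl$section)
  if (tpl$jobstart) mod <- sem_set_attr(mod, "jobstart", "true")
  i <- 1L
  n <- length(lines)
  matches <- 0L
  while (i <= n) {
    line <- lines[i]
    handled <- FALSE
    for (ch in tpl$children) {
      if (inherits(ch, "qc_template")) {
        if (full_match(ch$start_pattern, line)) {
          k <- min(chunk_extent(lines, i, ch), n)
          sub <- apply_template(lines[i:k], ch, transforms = transforms)
          mod$children <- c(mod$children, list(sub))
          i <- k + 1L
          matches <- matches + 1L
          handled <- TRUE
          break
        }
      } else if (inherits(ch, "qc_record")) {
        nodes <- match_record(ch, line)
        if (!is.null(nodes)) {
          mod$children <- c(mod$children, promote_labels(nodes, ch))
          i <- i + 1L
          matches <- matches + 1L
          handled <- TRUE
          break
        }
      }
    }
    if (!handled) {
      mod$children <- c(mod$children, list(unparsed_node(line)))
      qc_log(sprintf("template '%s': line %d unmatched inside chunk", tpl$id, i))
      i <- i + 1L
    }
  }
  attr(mod, "n_matches") <- matches
  if (tpl$molecule) mod <- assemble_molecule(mod)
  if (transforms && length(tpl$transforms)) {
    mod <- apply_program(mod, tpl$transforms)
  }
  mod
}

#' Scan a logfile and claim chunks with an ordered template list
#'
#' @param text Full logfile text (or a character vector of lines).
#' @param templates Ordered list of `qc_template`; earlier templates win.
#' @return A list:
#'   * `doc` — raw document (`module` root, one child module per chunk),
#'   * `chunks` — data frame with `template_id`, `start_line`, `end_line`
#'     (0-based half-open line indices),
#'   * `unparsed` — data frame of unclaimed ranges, same indexing,
#'   * `lines` — the split input lines,
#'   * `trailing_newline` — whether the input text ended with a newline.
#'   Chunk lines plus unparsed lines tile the input exactly.
#' @export
match_chunks <- function(text, templates) {
  if (inherits(templates, "qc_template")) templates <- list(templates)
  if (length(text) == 1L) {
    trailing <- grepl("\n$", text)
    lines <- split_lines(text)
  } else {
    trailing <- FALSE
    lines <- as.character(text)
  }
  n <- length(lines)
  doc <- sem_node("module", id = "parse.root")
  chunks <- list()
  unparsed <- list()
  open_unparsed <- NA_integer_
  flush_unparsed <- function(upto) {
    if (!is.na(open_unparsed)) {
      unparsed[[length(unparsed) + 1L]] <<- c(open_unparsed, upto)
      open_unparsed <<- NA_integer_
    }
  }
  i <- 1L
  while (i <= n) {
    claimed <- FALSE
    for (tpl in templates) {
      if (!full_match(tpl$start_pattern, lines[i])) next
      k <- chunk_extent(lines, i, tpl)
      mod <- apply_template(lines[i:k], tpl, transforms = FALSE)
      if (tpl$strict && attr(mod, "n_matches") == 0L) {
        # bounded back-tracking: rewind and offer the line to later templates
        qc_log(sprintf("template '%s': strict chunk at line %d rejected, backtracking",
                       tpl$id, i))
        next
      }
      if (length(tpl$transforms)) mod <- apply_program(mod, tpl$transforms)
      flush_unparsed(i - 1L)
      chunks[[length(chunks) + 1L]] <- list(template_id = tpl$id,
                                            start = i, end = k)
      doc$children <- c(doc$children, list(mod))
      i <- k + 1L
      claimed <- TRUE
      break
    }
    if (!claimed) {
      if (is.na(open_unparsed)) open_unparsed <- i
      i <- i + 1L
    }
  }
  flush_unparsed(n)
  chunk_df <- if (length(chunks)) {
    data.frame(
      template_id = vapply(chunks, `[[`, "", "template_id"),
      start_line = vapply(chunks, function(c0) c0$start, 1L) - 1L,
      end_line = vapply(chunks, function(c0) c0$end, 1L),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(template_id = character(0), start_line = integer(0),
               end_line = integer(0), stringsAsFactors = FALSE)
  }
  unparsed_df <- if (length(unparsed)) {
    data.frame(
      start_line = vapply(unparsed, `[[`, 1L, 1L) - 1L,
      end_line = vapply(unparsed, `[[`, 1L, 2L)
    )
  } else {
    data.frame(start_line = integer(0), end_line = integer(0))
  }
  list(doc = doc, chunks = chunk_df, unparsed = unparsed_df, lines = lines,
       trailing_newline = isTRUE(trailing))
}

#' Reassemble the input from a parse result
#'
#' Concatenates chunk lines and unparsed lines back in order.  By the
#' partition property the result is byte-identical to the input text.
#'
#' @param parse Result of [match_chunks()].
#' @return Single string.
#' @export
reassemble_text <- function(parse) {
  ranges <- rbind(
    if (nrow(parse$chunks)) parse$chunks[, c("start_line", "end_line")] else NULL,
    parse$unparsed
  )
  n_covered <- if (is.null(ranges) || !nrow(ranges)) 0L else sum(ranges$end_line - ranges$start_line)
  if (n_covered != length(parse$lines)) {
    qc_abort(sprintf("partition violated: %d lines covered of %d",
                     n_covered, length(parse$lines)), "qc_integrity_error")
  }
  out <- character(length(parse$lines))
  if (!is.null(ranges) && nrow(ranges)) {
    for (r in seq_len(nrow(ranges))) {
      idx <- (ranges$start_line[r] + 1L):ranges$end_line[r]
      out[idx] <- parse$lines[idx]
    }
  }
  paste0(paste(out, collapse = "\n"), if (parse$trailing_newline) "\n" else "")
}

#' Run the embedded self-tests of templates
#'
#' Templates may embed an example input together with its expected output
#' tree; the example doubles as a unit test of the template and its
#' transforms.  Comparison is structural; parsing scaffolding attributes
#' (temporary labels, job-section tags) are excluded.
#'
#' @param templates A `qc_template` or list of them.
#' @return Data frame: `template_id`, `example_id`, `status`
#'   (`pass`/`fail`/`untested`), `detail` (first difference path on failure).
#' @export
run_embedded_tests <- function(templates) {
  if (inherits(templates, "qc_template")) templates <- list(templates)
  rows <- list()
  for (tpl in templates) {
    if (!length(tpl$examples)) {
      rows[[length(rows) + 1L]] <- data.frame(
        template_id = tpl$id, example_id = NA_character_,
        status = "untested", detail = "no embedded examples",
        stringsAsFactors = FALSE)
      next
    }
    for (ex in tpl$examples) {
      if (is.null(ex$expected)) {
        rows[[length(rows) + 1L]] <- data.frame(
          template_id = tpl$id, example_id = ex$id,
          status = "untested", detail = "no expected output",
          stringsAsFactors = FALSE)
        next
      }
      got <- apply_template(ex$input, tpl)
      d <- sem_diff(got, ex$expected, ignore = SCAFFOLD_ATTRS)
      rows[[length(rows) + 1L]] <- data.frame(
        template_id = tpl$id, example_id = ex$id,
        status = if (is.null(d)) "pass" else "fail",
        detail = d %||% "", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# --- molecule assembly -------------------------------------------------------

ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr"
)

# Collapse captured orientation-table rows (atomic number scalar + xyz array)
# into a molecule node with a concise formula (C first, H second, remaining
# elements alphabetical -- the Hill convention used by concise formulas).
assemble_molecule <- function(mod) {
  zs <- character(0)
  atoms <- list()
  rest <- list()
  pending_z <- NULL
  for (ch in mod$children) {
    t <- sem_attr(ch, "temp") %||% ""
    if (ch$name == "scalar" && qname_local(t) == "atomicnum") {
      pending_z <- scalar_value(ch)
    } else if (ch$name == "array" && qname_local(t) == "xyz" && !is.null(pending_z)) {
      sym <- if (pending_z >= 1 && pending_z <= length(ELEMENTS)) {
        ELEMENTS[pending_z]
      } else paste0("Z", pending_z)
      zs <- c(zs, sym)
      atoms[[length(atoms) + 1L]] <- sem_node(
        "atom", id = paste0("a", length(atoms) + 1L), elementType = sym,
        x3 = ch$value[1], y3 = ch$value[2], z3 = ch$value[3]
      )
      pending_z <- NULL
    } else if (ch$name == "scalar" &&
               qname_local(t) %in% c("center", "atype")) {
      # layout columns of the orientation table: not retained
    } else {
      rest <- c(rest, list(ch))
    }
  }
  if (!length(atoms)) return(mod)
  mol <- sem_node(
    "molecule", id = paste0("mol.", sem_attr(mod, "templateRef") %||% "orient"),
    children = c(
      list(sem_node("atomArray", children = atoms)),
      list(sem_node("formula", formalCharge = "0",
                    concise = concise_formula(zs), dictRef = "cc:formula"))
    )
  )
  mod$children <- c(rest, list(mol))
  mod
}

concise_formula <- function(symbols) {
  tab <- table(symbols)
  els <- names(tab)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste(vapply(ord, function(e) paste(e, tab[[e]]), ""), collapse = " ")
}
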