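# Second-phase declarative normalization.
#
# A transform program is an ordered list of steps, each naming a process and
# a path expression.  A step whose path matches nothing is a silent
# (logged) no-op: a strange document must not crash the run.  Only hard type
# conflicts abort, and then with the step index.

TRANSFORM_PROCESSES <- c(
  "addDictRef", "addUnits", "setDataType", "joinArrays", "delete",
  "deleteHierarchy", "rename", "move", "groupSiblings", "annotateModule"
)

#' Construct a transform step
#'
#' @param process One of `addDictRef`, `addUnits`, `setDataType`,
#'   `joinArrays`, `delete`, `deleteHierarchy`, `rename`, `move`,
#'   `groupSiblings`, `annotateModule`.
#' @param path Path expression selecting target nodes.
#' @param value Process argument (new dictRef, units, dataType, name, ...).
#' @param extra Named list of additional arguments (e.g. `to` for `move`,
#'   `role`/`id` for `annotateModule`).
#' @return A `qc_transform_step`.
#' @export
transform_step <- function(process, path, value = NULL, extra = list()) {
  if (!process %in% TRANSFORM_PROCESSES) {
    qc_abort(sprintf("unknown transform process '%s'", process),
             "qc_transform_error")
  }
  structure(list(process = process, path = path, value = value, extra = extra),
            class = "qc_transform_step")
}

parse_transform_el <- function(x) {
  at <- xml2::xml_attrs(x)
  names(at) <- sub("^cmlx:", "", names(at))
  process <- at[["process"]]
  path <- if ("xpath" %in% names(at)) at[["xpath"]] else at[["path"]]
  value <- if ("value" %in% names(at)) at[["value"]] else NULL
  extra <- as.list(at[setdiff(names(at), c("process", "xpath", "path", "value"))])
  transform_step(process, path, value, extra)
}

#' Load a standalone transform program
#'
#' @param text XML text or file path; every `<transform>` element below the
#'   root becomes one step, in document order.
#' @return List of `qc_transform_step`.
#' @export
load_transforms <- function(text) {
  xml <- tryCatch(
    xml2::read_xml(if (length(text) == 1 && file.exists(text)) text else paste(text, collapse = "\n")),
    error = function(e) qc_abort(paste0("transform XML parse error: ", conditionMessage(e)),
                                 "qc_transform_error")
  )
  lapply(xml2::xml_find_all(xml, ".//*[local-name()='transform']"),
         parse_transform_el)
}

#' Apply one transform step
#'
#' Semantics per process:
#' * `addDictRef` sets `dictRef` on every match and consumes the temporary
#'   label; `addUnits` sets `units`; `setDataType` sets `dataType` (the
#'   payload must parse under the new type).
#' * `joinArrays` concatenates each run of consecutive sibling arrays
#'   matching the path with equal `dictRef`/label into the first of the run,
#'   summing sizes and deleting the rest.
#' * `delete` removes matches; `deleteHierarchy` replaces a matched module
#'   by its children in place.
#' * `groupSiblings` wraps each matched run in a new module with the given
#'   `dictRef`; `annotateModule` sets label/id; `rename` changes the element
#'   name; `move` appends matches to the first node matching `extra$to`.
#'
#' Zero matches is a silent no-op.
#'
#' @param root A `sem_node`.
#' @param step A `qc_transform_step`.
#' @return The transformed tree.
#' @export
apply_step <- function(root, step) {
  ids <- find_node_ids(root, step$path)
  if (!length(ids)) {
    qc_log(sprintf("transform %s on '%s': no match (no-op)",
                   step$process, step$path))
    return(root)
  }
  switch(step$process,
    addDictRef = {
      for (id in ids) {
        n <- node_at(root, id)
        n <- sem_set_attr(n, "dictRef", step$value)
        n <- sem_set_attr(n, "temp", NULL)
        root <- poke_node(root, id, n)
      }
      root
    },
    addUnits = {
      for (id in ids) {
        root <- poke_node(root, id, sem_set_attr(node_at(root, id), "units", step$value))
      }
      root
    },
    setDataType = {
      for (id in ids) {
        n <- sem_set_attr(node_at(root, id), "dataType", step$value)
        parse_payload(n$value, step$value)  # signals on unparseable payload
        root <- poke_node(root, id, n)
      }
      root
    },
    delete = {
      for (id in rev(ids)) root <- poke_node(root, id, NULL)
      root
    },
    deleteHierarchy = {
      for (id in rev(ids)) {
        root <- poke_node(root, id, node_at(root, id)$children)
      }
      root
    },
    rename = {
      for (id in ids) {
        n <- node_at(root, id)
        n$name <- step$value
        root <- poke_node(root, id, n)
      }
      root
    },
    move = {
      to <- step$extra$to %||% qc_abort("move requires a 'to' path", "qc_transform_error")
      moved <- lapply(ids, node_at, root = root)
      for (id in rev(ids)) root <- poke_node(root, id, NULL)
      tid <- find_node_ids(root, to)
      if (!length(tid)) {
        qc_log(sprintf("transform move: target '%s' not found (no-op)", to))
        return(root)
      }
      tgt <- node_at(root, tid[[1]])
      tgt$children <- c(tgt$children, moved)
      poke_node(root, tid[[1]], tgt)
    },
    groupSiblings = {
      runs <- sibling_runs(ids)
      for (run in rev(runs)) {
        parent_id <- run$parent
        parent <- node_at(root, parent_id)
        seg <- parent$children[run$from:run$to]
        wrapper <- sem_node("module", dictRef = step$value, children = seg)
        if (!is.null(step$extra$id)) wrapper <- sem_set_attr(wrapper, "id", step$extra$id)
        parent$children <- append(parent$children[-(run$from:run$to)],
                                  list(wrapper), after = run$from - 1L)
        root <- poke_node(root, parent_id, parent)
      }
      root
    },
    annotateModule = {
      for (id in ids) {
        n <- node_at(root, id)
        if (!is.null(step$extra$role)) n <- sem_set_attr(n, "temp", step$extra$role)
        if (!is.null(step$extra$id)) n <- sem_set_attr(n, "id", step$extra$id)
        if (!is.null(step$value)) n <- sem_set_attr(n, "temp", step$value)
        root <- poke_node(root, id, n)
      }
      root
    },
    joinArrays = join_arrays(root, ids)
  )
}

# group matched ids into runs of consecutive siblings
sibling_runs <- function(ids) {
  runs <- list()
  cur <- NULL
  for (id in ids) {
    parent <- id[-length(id)]
    pos <- id[length(id)]
    if (!is.null(cur) && identical(cur$parent, parent) && pos == cur$to + 1L) {
      cur$to <- pos
    } else {
      if (!is.null(cur)) runs <- c(runs, list(cur))
      cur <- list(parent = parent, from = pos, to = pos)
    }
  }
  if (!is.null(cur)) runs <- c(runs, list(cur))
  runs
}

join_arrays <- function(root, ids) {
  ids <- Filter(function(id) node_at(root, id)$name == "array", ids)
  if (!length(ids)) return(root)
  runs <- sibling_runs(ids)
  for (run in rev(runs)) {
    parent <- node_at(root, run$parent)
    # split the run further on label equality: only arrays sharing
    # dictRef/temp are stitched together
    seg_ids <- run$from:run$to
    grp_start <- seg_ids[1]
    groups <- list()
    key_of <- function(i) {
      n <- parent$children[[i]]
      paste(sem_attr(n, "dictRef") %||% "", trimws(sem_attr(n, "temp") %||% ""))
    }
    for (i in seg_ids[-1]) {
      if (key_of(i) != key_of(grp_start)) {
        groups <- c(groups, list(grp_start:(i - 1L)))
        grp_start <- i
      }
    }
    groups <- c(groups, list(grp_start:seg_ids[length(seg_ids)]))
    for (grp in rev(groups)) {
      if (length(grp) < 2L) next
      first <- parent$children[[grp[1]]]
      for (i in grp[-1]) {
        nxt <- parent$children[[i]]
        dt1 <- sem_attr(first, "dataType") %||% "xsd:string"
        dt2 <- sem_attr(nxt, "dataType") %||% "xsd:string"
        if (dt1 != dt2) {
          qc_abort(sprintf("joinArrays: dataType conflict between %s (%s) and %s (%s)",
                           node_path_of(first), dt1, node_path_of(nxt), dt2),
                   "qc_transform_error")
        }
        first$value <- c(first$value, nxt$value)
      }
      first <- sem_set_attr(first, "size", as.character(length(first$value)))
      parent$children[[grp[1]]] <- first
      parent$children <- parent$children[-grp[-1]]
    }
    root <- poke_node(root, run$parent, parent)
  }
  root
}

#' Apply a transform program
#'
#' Steps run strictly in order; a no-match step never aborts the program.
#'
#' @param root A `sem_node`.
#' @param steps List of `qc_transform_step`.
#' @return Transformed tree.
#' @export
apply_program <- function(root, steps) {
  for (k in seq_along(steps)) {
    root <- tryCatch(
      apply_step(root, steps[[k]]),
      qc_transform_error = function(e) {
        qc_abort(sprintf("transform step %d (%s): %s", k, steps[[k]]$process,
                         conditionMessage(e)), "qc_transform_error")
      }
    )
  }
  root
}
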