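# Restricted path language used by find_nodes() and the transform layer.
#
# Grammar (deliberately small; every path printed in shipped templates fits):
#   path      := step+
#   step      := ("//" | "/") nametest predicate*
#   nametest  := NAME | PREFIX ":" NAME | "*"
#   predicate := "[@" attr "='" value "']"
# A leading "." is accepted and ignored.  Attributes are restricted to
# dictRef, role (cmlx:temp), templateRef and id; predicates are conjunctive.
# Evaluation works on child-index paths, visits each node once, and returns
# matches in document order.

#' Parse a path expression
#'
#' @param path Path string such as `".//array[@dictRef='cc:frequency']"`.
#' @return A `qc_path` object (list of steps).
#' @export
parse_path <- function(path) {
  src <- path
  p <- sub("^\\.", "", trimws(path))
  steps <- list()
  while (nzchar(p)) {
    m <- regexpr("^(//|/)([A-Za-z0-9_.*:-]+)", p)
    if (m == -1) {
      qc_abort(sprintf("malformed path expression '%s' near '%s'", src, p),
               "qc_path_error")
    }
    tok <- regmatches(p, m)
    axis <- if (startsWith(tok, "//")) "descendant" else "child"
    name <- sub("^/+", "", tok)
    name <- sub("^[A-Za-z0-9_]+:", "", name)  # strip prefix: cml:array -> array
    p <- substr(p, attr(m, "match.length") + 1L, nchar(p))
    preds <- list()
    while (grepl("^\\[@", p)) {
      pm <- regexpr("^\\[@([A-Za-z0-9_:.-]+)=(?:'([^']*)'|\"([^\"]*)\")\\]", p, perl = TRUE)
      if (pm == -1) {
        qc_abort(sprintf("malformed predicate in path '%s' near '%s'", src, p),
                 "qc_path_error")
      }
      cs <- attr(pm, "capture.start"); cl <- attr(pm, "capture.length")
      attr_name <- substr(p, cs[1], cs[1] + cl[1] - 1L)
      vi <- if (cs[2] > 0) 2L else 3L
      attr_val <- substr(p, cs[vi], cs[vi] + cl[vi] - 1L)
      attr_name <- canonical_pred_attr(attr_name, src)
      preds <- c(preds, list(list(attr = attr_name, value = attr_val)))
      p <- substr(p, attr(pm, "match.length") + 1L, nchar(p))
    }
    steps <- c(steps, list(list(axis = axis, name = name, preds = preds)))
  }
  if (!length(steps)) {
    qc_abort(sprintf("empty path expression '%s'", src), "qc_path_error")
  }
  structure(list(steps = steps, src = src), class = "qc_path")
}

canonical_pred_attr <- function(a, src) {
  a <- switch(a,
    "cmlx:temp" = "temp", "role" = "temp",
    "cmlx:templateRef" = "templateRef",
    a
  )
  if (!a %in% c("dictRef", "temp", "templateRef", "id")) {
    qc_abort(sprintf("unsupported predicate attribute '%s' in path '%s'", a, src),
             "qc_path_error")
  }
  a
}

node_matches_step <- function(node, step) {
  if (step$name != "*" && node$name != step$name) return(FALSE)
  for (pr in step$preds) {
    v <- sem_attr(node, pr$attr)
    if (is.null(v)) return(FALSE)
    ok <- switch(pr$attr,
      temp = trimws(v) == trimws(pr$value),
      dictRef = {
        if (identical(v, pr$value)) {
          TRUE
        } else if (qname_local(v) == qname_local(pr$value)) {
          # shipped templates mix dictionary prefixes for one concept
          # (e.g. g:alphaocc vs cc:alphaocc): resolve on the local name
          qc_log(sprintf("dictRef predicate '%s' matched '%s' across prefixes",
                         pr$value, v))
          TRUE
        } else FALSE
      },
      identical(v, pr$value)
    )
    if (!ok) return(FALSE)
  }
  TRUE
}

# --- index-path plumbing -----------------------------------------------------

node_at <- function(root, id) {
  n <- root
  for (i in id) n <- n$children[[i]]
  n
}

# replace the node at `id` with `value`; `value = NULL` deletes it, a list of
# nodes splices them in place (used by deleteHierarchy)
poke_node <- function(root, id, value) {
  if (length(id) == 0) {
    if (is.sem_node(value)) return(value)
    qc_abort("cannot delete or splice the document root", "qc_transform_error")
  }
  i <- id[[1]]
  if (length(id) == 1) {
    if (is.null(value)) {
      root$children[[i]] <- NULL
    } else if (is.sem_node(value)) {
      root$children[[i]] <- value
    } else {
      root$children <- append(root$children[-i], value, after = i - 1L)
    }
  } else {
    root$children[[i]] <- poke_node(root$children[[i]], id[-1], value)
  }
  root
}

descendant_ids <- function(node, base = integer(0)) {
  out <- list()
  for (i in seq_along(node$children)) {
    id <- c(base, i)
    out <- c(out, list(id), descendant_ids(node$children[[i]], id))
  }
  out
}

id_key <- function(id) paste(id, collapse = ".")

# document order: lexicographic on index vectors
order_ids <- function(ids) {
  if (length(ids) < 2) return(ids)
  keys <- vapply(ids, function(id) paste(sprintf("%08d", id), collapse = "."), "")
  ids[order(keys)]
}

#' Find index paths of nodes matching a path expression
#'
#' Positions are child-index vectors relative to `root`; they remain valid
#' until the tree is modified.  Used by the transform interpreter.
#'
#' @inheritParams find_nodes
#' @return List of integer vectors in document order.
#' @export
find_node_ids <- function(root, path) {
  if (!inherits(path, "qc_path")) path <- parse_path(path)
  frontier <- list(integer(0))
  for (step in path$steps) {
    seen <- character(0)
    nxt <- list()
    for (base in frontier) {
      node <- node_at(root, base)
      cand <- if (step$axis == "descendant") {
        descendant_ids(node, base)
      } else {
        lapply(seq_along(node$children), function(i) c(base, i))
      }
      for (id in cand) {
        if (id_key(id) %in% seen) next
        if (node_matches_step(node_at(root, id), step)) {
          seen <- c(seen, id_key(id))
          nxt <- c(nxt, list(id))
        }
      }
    }
    frontier <- order_ids(nxt)
    if (!length(frontier)) return(list())
  }
  frontier
}

#' Find nodes matching a path expression
#'
#' @param root A `sem_node`.
#' @param path A path string or a parsed `qc_path`.
#' @return List of matching nodes in document order (empty when none match;
#'   a no-match is not an error).
#' @export
#' @examples
#' doc <- read_document("<module><array dictRef='cc:frequency'>1 2</array></module>")
#' length(find_nodes(doc, ".//array[@dictRef='cc:frequency']"))
find_nodes <- function(root, path) {
  lapply(find_node_ids(root, path), node_at, root = root)
}
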