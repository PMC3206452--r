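# Shared fixtures, built in code or read from packaged plain-text data.

ch4_doc_path <- function() {
  system.file("extdata", "docs", "ch4-two-jobs.xml", package = "qchemlog",
              mustWork = TRUE)
}

ch4_doc <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_document(ch4_doc_path())
    cache
  }
})

eigen_template <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- load_template(system.file(
        "extdata", "templates", "gaussian", "30-eigenvalues.xml",
        package = "qchemlog", mustWork = TRUE))
    }
    cache
  }
})

eigen_example_lines <- function() eigen_template()$examples[[1]]$input

# random small sem tree for round-trip properties
random_tree <- function(depth = 0) {
  kind <- sample(c("module", "scalar", "array", "list"), 1,
                 prob = if (depth >= 3) c(0, .4, .4, .2) else c(.4, .2, .2, .2))
  if (kind == "scalar") {
    if (stats::runif(1) < 0.5) {
      sem_node("scalar", dictRef = "cc:temp", dataType = "xsd:double",
               value = sprintf("%.5f", stats::rnorm(1)))
    } else {
      sem_node("scalar", value = paste0("tok", sample(99, 1)))
    }
  } else if (kind == "array") {
    n <- sample(0:6, 1)
    sem_node("array", dataType = "xsd:double", size = as.character(n),
             value = sprintf("%.4f", stats::rnorm(n)))
  } else {
    kids <- lapply(seq_len(sample(0:3, 1)), function(i) random_tree(depth + 1))
    sem_node(kind, id = paste0("n", sample(999, 1)), children = kids)
  }
}

# a one-record template plus its brute-force oracle, for equivalence checks
val_template <- function() {
  load_template('<template id="valblock" pattern="\\s*VAL:.*" repeat="*">
    <record id="val" repeat="*">\\s*VAL:{1_3F, g:v}</record>
  </template>')
}

oracle_scan <- function(lines) {
  is_val <- grepl("^\\s*VAL:", lines)
  runs <- rle(is_val)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  chunks <- list()
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) next
    vals <- lapply(starts[i]:ends[i], function(j) {
      body <- sub("^\\s*VAL:", "", lines[j])
      toks <- regmatches(body,
        gregexpr("[+-]?[0-9]*\\.?[0-9]+(?:[Ee][+-]?[0-9]+)?", body,
                 perl = TRUE))[[1]]
      as.numeric(utils::head(toks, 3))
    })
    chunks[[length(chunks) + 1L]] <- list(start = starts[i], end = ends[i],
                                          values = vals)
  }
  list(chunks = chunks, unparsed = which(!is_val))
}
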