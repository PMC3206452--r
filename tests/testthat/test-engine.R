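# Chunk recognition, template application, partition property.

test_that("the eigenvalue template reproduces its embedded expected output", {
  res <- run_embedded_tests(eigen_template())
  expect_identical(res$status, "pass")
  mod <- apply_template(eigen_example_lines(), eigen_template())
  occ <- find_nodes(mod, ".//array[@dictRef='cc:alphaocc']")
  virt <- find_nodes(mod, ".//array[@dictRef='cc:alphavirt']")
  expect_length(occ, 1)
  expect_length(virt, 1)
  expect_length(array_values(occ[[1]]), 5)
  expect_length(array_values(virt[[1]]), 18)
  expect_identical(array_values(occ[[1]])[1], -10.17514)
  expect_identical(array_values(virt[[1]])[18], 4.16488)
})

test_that("an embedded test with a wrong expectation fails naming the node", {
  txt <- paste(readLines(system.file("extdata", "templates", "gaussian",
                                     "30-eigenvalues.xml", package = "qchemlog")),
               collapse = "\n")
  # drop one value from the expected occupied array: deliberately wrong size
  tpl <- load_template(sub(">-10.17514 -0.68437 -0.38581 -0.38581 -0.38581<",
                           ">-10.17514 -0.68437 -0.38581 -0.38581<",
                           txt, fixed = TRUE))
  res <- run_embedded_tests(tpl)
  expect_identical(res$status, "fail")
  expect_match(res$detail, "array")
  no_ex <- load_template('<template id="t" pattern="x"><record id="r">x</record></template>')
  expect_identical(run_embedded_tests(no_ex)$status, "untested")
})

test_that("interior garbage degrades to unparsed text children", {
  lines <- eigen_example_lines()
  lines[3] <- "*** intruding line ***"
  mod <- apply_template(lines, eigen_template(), transforms = FALSE)
  kinds <- vapply(mod$children, function(x) x$name, "")
  expect_identical(sum(kinds == "array"), 4L)  # promoted records
  expect_identical(sum(kinds == "comment"), 1L)
  expect_identical(mod$children[[3]]$value, "*** intruding line ***")
})

test_that("match_chunks partitions header + block + footer", {
  text <- paste(c("Some header line",
                  eigen_example_lines(),
                  " End of file."), collapse = "\n")
  parse <- match_chunks(text, list(eigen_template()))
  expect_identical(nrow(parse$chunks), 1L)
  expect_identical(nrow(parse$unparsed), 2L)
  expect_identical(parse$chunks$start_line, 1L)
  expect_identical(parse$chunks$end_line, 6L)
  expect_identical(reassemble_text(parse), text)
  empty <- match_chunks("", list(eigen_template()))
  expect_identical(nrow(empty$chunks), 0L)
  expect_length(empty$doc$children, 0)
})

test_that("claimed lines are never re-offered and every parse terminates", {
  blocks <- paste(rep(paste(eigen_example_lines(), collapse = "\n"), 50),
                  collapse = "\n")
  parse <- match_chunks(blocks, list(eigen_template()))
  # eigenvalue lines all match the start pattern, so with no terminator in
  # between consecutive blocks coalesce under the endPattern rule; every
  # line is consumed exactly once
  covered <- sum(parse$chunks$end_line - parse$chunks$start_line) +
    sum(parse$unparsed$end_line - parse$unparsed$start_line)
  expect_identical(covered, length(parse$lines))
  expect_identical(reassemble_text(parse), blocks)
})

test_that("parsing is deterministic", {
  gen <- generate_logfile(log_spec(seed = 9L))
  p1 <- match_chunks(gen$text, gaussian_pack())
  p2 <- match_chunks(gen$text, gaussian_pack())
  expect_null(sem_diff(p1$doc, p2$doc))
  expect_identical(p1$chunks, p2$chunks)
})

test_that("partition holds on randomized line soups", {
  gen <- generate_logfile(log_spec(jobs = c("opt", "freq"), seed = 3L))
  pool <- c(strsplit(gen$text, "\n", fixed = TRUE)[[1]],
            "garbage !!", "", "   ", "12 34 not a block")
  set.seed(42)
  for (i in 1:40) {
    lines <- sample(pool, sample(3:25, 1), replace = TRUE)
    text <- paste0(paste(lines, collapse = "\n"), "\n")
    parse <- match_chunks(text, gaussian_pack())
    expect_identical(reassemble_text(parse), text)
    idx <- unlist(c(
      lapply(seq_len(nrow(parse$chunks)), function(r)
        (parse$chunks$start_line[r] + 1L):parse$chunks$end_line[r]),
      lapply(seq_len(nrow(parse$unparsed)), function(r)
        (parse$unparsed$start_line[r] + 1L):parse$unparsed$end_line[r])
    ))
    expect_identical(sort(idx), seq_along(parse$lines))  # no line twice
  }
})

test_that("single-record matching agrees with a brute-force scanner", {
  set.seed(7)
  tpl <- val_template()
  for (i in 1:50) {
    lines <- vapply(seq_len(sample(2:15, 1)), function(j) {
      if (stats::runif(1) < 0.5) {
        paste(" VAL:", paste(sprintf("%.4f", stats::rnorm(sample(1:3, 1))),
                             collapse = "  "))
      } else {
        sample(c("noise", " other 1.5", "", "VALUE: 3"), 1)
      }
    }, "")
    parse <- match_chunks(paste(lines, collapse = "\n"), list(tpl))
    oracle <- oracle_scan(lines)
    expect_identical(nrow(parse$chunks), length(oracle$chunks))
    for (k in seq_along(oracle$chunks)) {
      expect_identical(parse$chunks$start_line[k] + 1L, oracle$chunks[[k]]$start)
      expect_identical(parse$chunks$end_line[k], oracle$chunks[[k]]$end)
      arrays <- Filter(function(x) x$name %in% c("array", "scalar"),
                       parse$doc$children[[k]]$children)
      got <- lapply(arrays, function(a) as.numeric(a$value))
      expect_equal(got, oracle$chunks[[k]]$values)
    }
  }
})

test_that("strict templates back-track to later templates", {
  strict_tpl <- load_template('<template id="greedy" pattern="BLOCK.*" strict="true">
    <record id="r">BLOCK body {1F, g:v}</record>
  </template>')
  loose_tpl <- load_template('<template id="fallback" pattern="BLOCK.*">
    <record id="r">BLOCK header {X, g:t}\\s*</record>
  </template>')
  parse <- match_chunks("BLOCK header alpha", list(strict_tpl, loose_tpl))
  expect_identical(parse$chunks$template_id, "fallback")
})
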