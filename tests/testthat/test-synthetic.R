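# The synthetic-log generator, mutator and ground-truth recovery.

test_that("the methane default spec produces the expected shapes", {
  gen <- generate_logfile(log_spec(jobs = "opt", seed = 42L))
  lines <- strsplit(gen$text, "\n", fixed = TRUE)[[1]]
  expect_identical(gen$truth[["cc:natoms"]][[1]], 5L)
  expect_identical(gen$truth[["cc:alphae"]][[1]], 5L)
  expect_identical(gen$truth[["cc:formula"]][[1]], "C 1 H 4")
  # 5 occupied + 18 virtual eigenvalues wrap 5 per line: 1 + 4 lines
  expect_identical(sum(grepl("Alpha occ\\. eigenvalues", lines)), 1L)
  expect_identical(sum(grepl("Alpha virt\\. eigenvalues", lines)), 4L)
})

test_that("generation is deterministic and job chains emit one section per job", {
  s <- log_spec(jobs = c("opt", "freq"), seed = 17L)
  expect_identical(generate_logfile(s)$text, generate_logfile(s)$text)
  lines <- strsplit(generate_logfile(s)$text, "\n", fixed = TRUE)[[1]]
  expect_identical(sum(grepl("^ #N ", lines)), 2L)
  expect_identical(sum(grepl("Normal termination", lines)), 2L)
  expect_identical(sum(grepl("Link1:", lines)), 1L)
})

test_that("invalid specs are rejected", {
  expect_error(log_spec(multiplicity = 0), class = "qc_spec_error")
  expect_error(log_spec(jobs = "banana"), class = "qc_spec_error")
  expect_error(log_spec(molecule = "unobtainium"), class = "qc_spec_error")
})

test_that("every ground-truth key resolves in the compchem dictionary", {
  for (s in c(1L, 2L, 3L)) {
    gen <- generate_logfile(random_log_spec(s))
    for (k in names(gen$truth)) {
      expect_no_error(dict_resolve(k))
    }
  }
})

test_that("recovery is total on clean output and graded on damaged output", {
  gen <- generate_logfile(log_spec(jobs = c("opt", "freq"), seed = 23L))
  cv <- convert_text(gen$text)
  expect_identical(recovery_score(gen$truth, cv$doc), 1.0)
  # empty parse scores zero
  expect_identical(recovery_score(gen$truth, sem_node("module")), 0.0)
  # deleting the frequency block loses exactly those terms
  lines <- strsplit(gen$text, "\n", fixed = TRUE)[[1]]
  cut <- lines[!grepl("Frequencies|Red\\. masses|IR Inten|Harmonic", lines)]
  cv2 <- convert_text(paste0(paste(cut, collapse = "\n"), "\n"))
  s <- recovery_score(gen$truth, cv2$doc)
  expect_gt(s, 0)
  expect_lt(s, 1)
})

test_that("mutations are deterministic, non-trivial, and survivable", {
  gen <- generate_logfile(log_spec(jobs = c("opt", "freq"), seed = 31L))
  for (m in c("truncate_tail", "inject_error_message", "shuffle_whitespace",
              "duplicate_block")) {
    m1 <- mutate_logfile(gen$text, m, seed = 4L)
    expect_identical(m1, mutate_logfile(gen$text, m, seed = 4L))
    expect_false(identical(m1, gen$text))
    cv <- convert_text(m1)  # must terminate normally
    expect_identical(reassemble_text(cv), m1)
  }
  # whitespace jitter must not cost any captured concept
  shuf <- mutate_logfile(gen$text, "shuffle_whitespace", seed = 8L)
  expect_identical(recovery_score(gen$truth, convert_text(shuf)$doc), 1.0)
})

test_that("an injected error line lands in the unparsed residue", {
  gen <- generate_logfile(log_spec(jobs = "opt", seed = 2L))
  mut <- mutate_logfile(gen$text, "inject_error_message", seed = 6L)
  cv <- convert_text(mut)
  residue <- unlist(lapply(seq_len(nrow(cv$unparsed)), function(r) {
    cv$lines[(cv$unparsed$start_line[r] + 1L):cv$unparsed$end_line[r]]
  }))
  expect_true(any(grepl("Error termination", residue)))
})
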