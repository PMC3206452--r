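# The desk-scale index: ingest, query, triple export.

fresh_store <- function() store_open(tempfile(fileext = ".json"))

test_that("ingesting the reference document yields one entry per job", {
  st <- fresh_store()
  recs <- store_ingest(st, ch4_doc(), "ch4-two-jobs.xml")
  expect_length(recs, 2)
  r1 <- recs[[1]]
  expect_identical(r1$method, "RB3LYP")
  expect_identical(r1$basis, "6-31G(d)")
  expect_identical(r1$formula_concise, "C 1 H 4")
  expect_identical(r1$natoms, 5L)
  expect_identical(r1$properties[["cc:hfenergy"]]$value, -40.5183892)
  expect_identical(r1$properties[["cc:hfenergy"]]$units, "nonsi:hartree")
  # re-ingest of identical content under new ids is permitted by design
  store_ingest(st, ch4_doc(), "ch4-two-jobs.xml")
  expect_length(st$records, 4)
  expect_identical(anyDuplicated(names(st$records)), 0L)
})

test_that("the store persists to its file and reloads", {
  st <- fresh_store()
  store_ingest(st, ch4_doc())
  st2 <- store_open(st$path)
  expect_identical(length(st2$records), length(st$records))
  expect_identical(names(st2$records), names(st$records))
})

test_that("convention-invalid documents are rejected and the store unchanged", {
  st <- fresh_store()
  bad <- read_document("<module><scalar>1</scalar></module>")
  expect_error(store_ingest(st, bad), class = "qc_invalid_document")
  expect_length(st$records, 0)
})

test_that("queries combine field and range criteria conjunctively", {
  st <- fresh_store()
  store_ingest(st, ch4_doc())
  expect_length(store_query(st, fields = list(formula = "C 1 H 4")), 2)
  expect_length(store_query(st, ranges = list("cc:hfenergy" = c(-41, -40))), 2)
  expect_length(store_query(st, ranges = list("cc:hfenergy" = c(0, 1))), 0)
  # zpe is stored in J/mol; the bound is in the canonical unit (hartree)
  expect_length(store_query(st, ranges = list("cc:zpe" = c(0.04, 0.05))), 1)
  both <- store_query(st, fields = list(method = "RB3LYP"),
                      ranges = list("cc:hfenergy" = c(-41, -40)))
  expect_length(both, 1)
  expect_length(store_query(fresh_store(), fields = list(formula = "C 1 H 4")), 0)
  expect_error(store_query(st, fields = list(flavour = "strange")),
               class = "qc_query_error")
})

test_that("adding a criterion never enlarges the result set", {
  st <- fresh_store()
  store_ingest(st, ch4_doc())
  gen <- generate_logfile(log_spec(jobs = "opt", seed = 13L))
  store_ingest(st, convert_text(gen$text)$doc, "synthetic.log")
  all_recs <- store_query(st)
  expect_length(all_recs, 3)
  narrowed <- store_query(st, fields = list(formula = "C 1 H 4"))
  expect_lte(length(narrowed), length(all_recs))
  more <- store_query(st, fields = list(formula = "C 1 H 4", method = "RB3LYP"))
  expect_lte(length(more), length(narrowed))
})

test_that("triple export is deterministic, complete, and reversible", {
  st <- fresh_store()
  recs <- store_ingest(st, ch4_doc(), "ch4-two-jobs.xml")
  r1 <- recs[[1]]
  tr <- store_triples(st, r1$entry_id)
  expect_identical(tr, store_triples(st, r1$entry_id))
  expect_true(all(c("cc:basis", "cc:method", "cc:formula") %in% tr$predicate))
  expect_identical(tr$object[tr$predicate == "cc:basis"], "6-31G(d)")
  lines <- format_triples(tr)
  expect_match(lines[grep("cc:basis", lines)], '"6-31G\\(d\\)" \\.$')
  back <- triples_to_record(tr)
  norm <- r1
  if (!is.null(norm$natoms)) norm$natoms <- as.integer(norm$natoms)
  norm$created <- as.numeric(norm$created)
  norm$properties <- norm$properties[order(names(norm$properties))]
  for (p in names(norm$properties)) {
    norm$properties[[p]]$value <-
      as.numeric(format(norm$properties[[p]]$value, digits = 15))
  }
  expect_equal(back, norm)
  expect_error(store_triples(st, "missing"), class = "qc_not_found")
})
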