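# Semantic document tree: reading, writing, search, typed access.

test_that("reading the reference document yields the expected structure", {
  doc <- ch4_doc()
  expect_identical(sem_attr(doc$children[[1]], "dictRef"), "cc:jobList")
  expect_length(find_nodes(doc, ".//module[@dictRef='cc:job']"), 2)
  freq <- find_nodes(doc, ".//array[@dictRef='cc:frequency']")
  expect_length(freq, 1)
  expect_identical(sem_attr(freq[[1]], "size"), "9")
  expect_length(array_values(freq[[1]]), 9)
})

test_that("typed payloads parse per dataType and keep printed precision", {
  doc <- read_document(
    "<module><scalar dataType='xsd:integer'>5</scalar>
       <scalar dataType='xsd:double'>-40.5183892</scalar>
       <scalar>plain</scalar></module>")
  expect_identical(scalar_value(doc$children[[1]]), 5L)
  expect_identical(scalar_value(doc$children[[2]]), -40.5183892)
  expect_identical(scalar_value(doc$children[[3]]), "plain")
  expect_identical(doc$children[[2]]$value, "-40.5183892")
  empty <- read_document("<module/>")
  expect_identical(sem_kind(empty), "module")
  expect_length(empty$children, 0)
})

test_that("delimited arrays drop empty edge fields and round-trip", {
  doc <- read_document("<module><array delimiter='|' size='9'>|T2|T2|T2|E|E|A1|T2|T2|T2|</array></module>")
  a <- doc$children[[1]]
  expect_identical(a$value, c("T2", "T2", "T2", "E", "E", "A1", "T2", "T2", "T2"))
  expect_true(sem_equal(doc, read_document(write_document(doc))))
  expect_match(write_document(doc), "\\|T2\\|T2\\|T2\\|E\\|E\\|A1\\|T2\\|T2\\|T2\\|")
})

test_that("integrity violations are rejected with classed errors", {
  expect_error(read_document("<module><array size='3'>1 2</array></module>"),
               class = "qc_integrity_error")
  expect_error(read_document("<module><scalar dictRef='noprefix'>1</scalar></module>"),
               class = "qc_integrity_error")
  expect_error(read_document("<module><matrix rows='2' columns='2'>1 2 3</matrix></module>"),
               class = "qc_integrity_error")
  expect_error(read_document("<module><scalar>"), class = "qc_parse_error")
  # size 0 with empty content is legal
  ok <- read_document("<module><array size='0'></array></module>")
  expect_length(ok$children[[1]]$value, 0)
})

test_that("write/read round-trip is the identity on random trees", {
  set.seed(101)
  for (i in 1:25) {
    tree <- sem_node("module", id = "root",
                     children = lapply(1:3, function(j) random_tree()))
    back <- read_document(write_document(tree))
    expect_null(sem_diff(tree, back))
  }
})

test_that("find_nodes returns document order and empty on no match", {
  doc <- ch4_doc()
  jobs <- find_nodes(doc, ".//module[@dictRef='cc:job']")
  expect_identical(sem_attr(jobs[[1]], "id"), "job1")
  expect_identical(sem_attr(jobs[[2]], "id"), "job2")
  expect_length(find_nodes(doc, ".//array[@dictRef='cc:doesnotexist']"), 0)
  expect_length(find_nodes(read_document("<module/>"), ".//scalar"), 0)
  # child-axis steps and chained steps
  top <- find_nodes(doc, "./module[@dictRef='cc:jobList']/module[@id='job1']")
  expect_length(top, 1)
})

test_that("extract_scalar returns typed value with units and classed errors", {
  doc <- ch4_doc()
  jobs <- find_nodes(doc, ".//module[@dictRef='cc:job']")
  e <- extract_scalar(jobs[[1]], "cc:hfenergy")
  expect_identical(e$value, -40.5183892)
  expect_identical(e$units, "nonsi:hartree")
  z <- extract_scalar(doc, "cc:zpe")
  expect_identical(z$value, 118752.0)
  expect_identical(z$units, "u:jmol-1")
  expect_error(extract_scalar(doc, "cc:absent"), class = "qc_not_found")
  # cc:natoms occurs in both parameterList and calculation of job1
  expect_error(extract_scalar(jobs[[1]], "cc:natoms"), class = "qc_ambiguous")
})

test_that("molecule invariants are enforced", {
  expect_error(read_document(
    "<module><molecule><atomArray>
       <atom id='a1' elementType='C'/><atom id='a1' elementType='H'/>
     </atomArray></molecule></module>"), class = "qc_integrity_error")
  expect_error(read_document(
    "<module><molecule><atomArray><atom id='a1' elementType='C'/></atomArray>
      <bondArray><bond atomRefs2='a1 a9' order='S'/></bondArray>
     </molecule></module>"), class = "qc_integrity_error")
  expect_error(read_document(
    "<module><molecule><formula concise='C1H4'/></molecule></module>"),
    class = "qc_integrity_error")
})
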