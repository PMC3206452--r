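# Restructuring into the compchem convention and validating conformance.

payload_multiset <- function(node) sort(qchemlog:::payload_signature(node))

test_that("two chained jobs restructure into a two-job jobList", {
  gen <- generate_logfile(log_spec(jobs = c("opt", "freq"), seed = 5L))
  parse <- match_chunks(gen$text, gaussian_pack())
  doc <- restructure(parse$doc)
  expect_identical(sem_attr(doc, "convention"), "convention:compchem")
  jobs <- find_nodes(doc, ".//module[@dictRef='cc:job']")
  expect_length(jobs, 2)
  # the second job's initialization carries the route keywords
  init2 <- find_nodes(jobs[[2]], "./module[@dictRef='cc:initialization']")
  expect_length(init2, 1)
  kw <- find_nodes(init2[[1]], ".//parameter[@dictRef='g:keyword']")
  expect_gt(length(kw), 0)
  expect_identical(report_errors(validate_convention(doc)), 0L)
})

test_that("restructuring conserves every scalar/array payload", {
  gen <- generate_logfile(log_spec(jobs = c("opt", "freq"), seed = 11L))
  parse <- match_chunks(gen$text, gaussian_pack())
  doc <- restructure(parse$doc)
  expect_identical(payload_multiset(doc), payload_multiset(parse$doc))
})

test_that("roleless content is kept under a userDefinedModule with a warning", {
  raw <- sem_node("module", id = "parse.root", children = list(
    apply_template(eigen_example_lines(),
                   load_template(sub(' section="calculation"', "",
                                     paste(readLines(system.file(
                                       "extdata", "templates", "gaussian",
                                       "30-eigenvalues.xml", package = "qchemlog")),
                                       collapse = "\n"), fixed = TRUE))),
    sem_node("module", templateRef = "another", children = list())
  ))
  doc <- restructure(raw)
  jobs <- find_nodes(doc, ".//module[@dictRef='cc:job']")
  expect_length(jobs, 1)
  udm <- find_nodes(jobs[[1]], "./module[@dictRef='cc:userDefinedModule']")
  expect_length(udm, 1)
  expect_length(udm[[1]]$children, 2)
  rep <- attr(doc, "report")
  expect_true("unassigned-content" %in% rep$findings$code)
  # the eigenvalue payloads survived relocation
  expect_length(find_nodes(doc, ".//array[@dictRef='cc:alphaocc']"), 1)
})

test_that("the reference document validates with zero errors", {
  rep <- validate_convention(ch4_doc())
  expect_identical(report_errors(rep), 0L)
  expect_true(report_valid(rep))
})

test_that("removing a finalization module yields exactly one error", {
  doc <- ch4_doc()
  ids <- find_node_ids(doc, ".//module[@dictRef='cc:job']/module[@dictRef='cc:finalization']")
  doc2 <- qchemlog:::poke_node(doc, ids[[1]], NULL)
  rep <- validate_convention(doc2)
  expect_identical(report_errors(rep), 1L)
  expect_identical(rep$findings$code[rep$findings$severity == "error"],
                   "missing-role")
})

test_that("duplicate roles and misplaced lists are reported", {
  doc <- ch4_doc()
  job1 <- find_nodes(doc, ".//module[@dictRef='cc:job']")[[1]]
  fin <- find_nodes(job1, "./module[@dictRef='cc:finalization']")[[1]]
  job_dup <- job1
  job_dup$children <- c(job_dup$children, list(fin))
  wrapped <- sem_node("module", convention = "convention:compchem", children = list(
    sem_node("module", dictRef = "cc:jobList", children = list(job_dup))
  ))
  rep <- validate_convention(wrapped)
  expect_true("duplicate-role" %in% rep$findings$code[rep$findings$severity == "error"])

  mis <- read_document(
    "<module convention='convention:compchem'><module dictRef='cc:jobList'>
       <module dictRef='cc:job'>
         <module dictRef='cc:initialization'>
           <propertyList><property dictRef='cc:hfenergy'><scalar>1</scalar></property></propertyList>
         </module>
         <module dictRef='cc:finalization'><propertyList/></module>
       </module></module></module>")
  rep2 <- validate_convention(mis)
  expect_identical(report_errors(rep2), 0L)
  expect_true("misplaced-property" %in% rep2$findings$code)
})

test_that("a job missing its roles fails validation", {
  bare <- read_document(
    "<module convention='convention:compchem'><module dictRef='cc:jobList'>
       <module dictRef='cc:job'/></module></module>")
  rep <- validate_convention(bare)
  expect_identical(report_errors(rep), 2L)  # no initialization, no finalization
  no_jl <- read_document("<module><scalar>1</scalar></module>")
  expect_identical(validate_convention(no_jl)$findings$code, "no-joblist")
})
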