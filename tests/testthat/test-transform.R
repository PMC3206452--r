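# The declarative normalization layer.

raw_eigen_module <- function() {
  apply_template(eigen_example_lines(), eigen_template(), transforms = FALSE)
}

test_that("addDictRef relabels matches and consumes the temporary label", {
  mod <- raw_eigen_module()
  out <- apply_step(mod, transform_step(
    "addDictRef", ".//array[@role='Alpha occ.']", "cc:alphaocc"))
  hits <- find_nodes(out, ".//array[@dictRef='cc:alphaocc']")
  expect_length(hits, 1)
  expect_null(sem_attr(hits[[1]], "temp"))
  expect_identical(node_count(out), node_count(mod))
  # idempotent
  again <- apply_step(out, transform_step(
    "addDictRef", ".//array[@dictRef='cc:alphaocc']", "cc:alphaocc"))
  expect_null(sem_diff(out, again))
})

test_that("joinArrays stitches consecutive same-label runs, conserving order", {
  mod <- raw_eigen_module()
  mod <- apply_step(mod, transform_step(
    "addDictRef", ".//array[@cmlx:temp='Alpha virt.']", "cc:alphavirt"))
  before <- unlist(lapply(find_nodes(mod, ".//array[@dictRef='cc:alphavirt']"),
                          array_values))
  out <- apply_step(mod, transform_step(
    "joinArrays", ".//array[@dictRef='g:alphavirt']"))  # alias across prefixes
  joined <- find_nodes(out, ".//array[@dictRef='cc:alphavirt']")
  expect_length(joined, 1)
  expect_identical(array_values(joined[[1]]), before)
  expect_identical(sem_attr(joined[[1]], "size"), "18")
  # single array: identity
  one <- apply_step(out, transform_step("joinArrays", ".//array[@dictRef='cc:alphavirt']"))
  expect_null(sem_diff(out, one))
})

test_that("joinArrays refuses mixed dataTypes, naming both nodes", {
  mod <- sem_node("module", children = list(
    sem_node("array", dictRef = "cc:x", dataType = "xsd:double",
             size = "1", value = "1.0"),
    sem_node("array", dictRef = "cc:x", dataType = "xsd:integer",
             size = "1", value = "2")
  ))
  expect_error(apply_step(mod, transform_step("joinArrays", ".//array[@dictRef='cc:x']")),
               class = "qc_transform_error")
})

test_that("delete and deleteHierarchy strictly decrease node count", {
  mod <- raw_eigen_module()
  n0 <- node_count(mod)
  del <- apply_step(mod, transform_step("delete", ".//array[@role='Alpha virt.']"))
  expect_lt(node_count(del), n0)
  wrapped <- sem_node("module", children = list(mod))
  flat <- apply_step(wrapped, transform_step(
    "deleteHierarchy", ".//module[@templateRef='l601.alphabetaeigen']"))
  expect_identical(node_count(flat), node_count(wrapped) - 1L)
  expect_length(flat$children, length(mod$children))
  # no-match delete is the identity
  same <- apply_step(mod, transform_step("delete", ".//array[@dictRef='cc:nope']"))
  expect_null(sem_diff(mod, same))
})

test_that("groupSiblings wraps runs; annotateModule and rename relabel", {
  mod <- raw_eigen_module()
  grp <- apply_step(mod, transform_step(
    "groupSiblings", ".//array[@role='Alpha virt.']", "cc:virtblock"))
  wrap <- find_nodes(grp, ".//module[@dictRef='cc:virtblock']")
  expect_length(wrap, 1)
  expect_length(wrap[[1]]$children, 4)
  ann <- apply_step(grp, transform_step(
    "annotateModule", ".//module[@dictRef='cc:virtblock']",
    extra = list(role = "virtual orbitals", id = "virt1")))
  m <- find_nodes(ann, ".//module[@id='virt1']")
  expect_length(m, 1)
  expect_identical(sem_attr(m[[1]], "temp"), "virtual orbitals")
  rn <- apply_step(ann, transform_step("rename", ".//module[@id='virt1']", "list"))
  expect_length(find_nodes(rn, ".//list[@id='virt1']"), 1)
})

test_that("programs run in order and no-match steps are silent no-ops", {
  mod <- raw_eigen_module()
  steps <- eigen_template()$transforms
  with_noop <- append(steps, list(transform_step("delete", ".//table[@id='none']")),
                      after = 2)
  a <- apply_program(mod, steps)
  b <- apply_program(mod, with_noop)
  expect_null(sem_diff(a, b))
  expect_null(sem_diff(apply_program(mod, list()), mod))
  expect_error(transform_step("explode", ".//x"), class = "qc_transform_error")
})

test_that("the published four-step program reproduces the expected tree", {
  mod <- raw_eigen_module()
  out <- apply_program(mod, eigen_template()$transforms)
  expected <- eigen_template()$examples[[1]]$expected
  expect_null(sem_diff(out, expected, ignore = c("temp", "section", "jobstart")))
})
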