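# End-to-end conversion: parse -> transform -> restructure -> validate.

#' Convert one logfile text to a compchem document
#'
#' @param text Logfile text.
#' @param templates Ordered template pack (default: the shipped
#'   Gaussian-style pack).
#' @param dicts Dictionaries for reference validation.
#' @param transforms Optional standalone transform program applied to the
#'   raw parse before restructuring.
#' @return A list:
#'   * `doc` — the compchem document,
#'   * `raw` — the raw parse tree,
#'   * `chunks`, `unparsed`, `lines`, `trailing_newline` — the partition
#'     (see [match_chunks()]),
#'   * `convention` — [validate_convention()] report,
#'   * `dictionary` — [validate_refs()] report,
#'   * `restructure` — restructuring warnings,
#'   * `unparsed_fraction` — share of input lines in the residue.
#' @export
convert_text <- function(text, templates = gaussian_pack(),
                         dicts = list(compchem_dictionary()),
                         transforms = NULL) {
  parse <- match_chunks(text, templates)
  doc <- restructure(parse$doc, rules = transforms)
  n <- length(parse$lines)
  res <- sum(parse$unparsed$end_line - parse$unparsed$start_line)
  list(
    doc = doc,
    raw = parse$doc,
    chunks = parse$chunks,
    unparsed = parse$unparsed,
    lines = parse$lines,
    trailing_newline = parse$trailing_newline,
    convention = validate_convention(doc),
    dictionary = validate_refs(doc, dicts),
    restructure = attr(doc, "report"),
    unparsed_fraction = if (n > 0L) res / n else 0
  )
}

#' Path to a packaged example document
#'
#' @param file File name under the package's `extdata/docs`; with no
#'   argument, lists the available files.
#' @return File path (or vector of names).
#' @export
qchemlog_example <- function(file = NULL) {
  base <- system.file("extdata", "docs", package = "qchemlog", mustWork = TRUE)
  if (is.null(file)) list.files(base) else file.path(base, file)
}
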