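---
title: "Declarative conversion of quantum-chemistry logfiles: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Declarative conversion of quantum-chemistry logfiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qchemlog)
```

## The problem

A quantum-chemistry logfile is the byproduct of record-oriented formatted
writes: eigenvalue tables, coordinate blocks, SCF summaries, thermochemistry
sections, interleaved with banners, convergence chatter and occasional error
messages.  The information content is high but the format is incidental —
it varies between codes, versions and even runs.  General parsing
technologies (grammars, parser generators, machine learning) struggle here
because the input is not a language: it is a concatenation of loosely
structured fragments with irregularities that must degrade gracefully, not
abort a batch of thousands of files.

`qchemlog` therefore treats a logfile as a sequence of *chunks*, each
produced by one output routine, and describes each chunk with a declarative
*template*.  Everything downstream — normalization, document structure,
dictionary semantics, indexing — is data, not code, so the set of parsed
concepts can grow without touching the engine.

## The template model

A template declares a start pattern (a regex that must match a full line),
an optional end pattern (the first line *not* consumed), and an ordered
list of single-line records.  A record interleaves literal regex with typed
field specifiers:

| specifier | meaning | emitted node |
|---|---|---|
| `{F, ref}` / `{3F, ref}` / `{1_5F, ref}` | fixed count or range of floats | scalar (count 1) or array |
| `{I, ref}` … | integers, same counting | scalar/array, `xsd:integer` |
| `{X, ref}` | one string token (trimmed) | scalar |
| `{A, ref}` | rest of line | scalar |

Each specifier compiles to exactly one capture group, and numeric groups
are emitted as *alternation-free* fragments — a fixed head plus a bounded
optional tail (`(\s*F(?:\s+F){0,4})`).  This construction is what keeps
matching linear in the line length; naively concatenating per-value
regexes with alternation is the classic route to exponential backtracking
on long lines, and it is the reason a per-line time budget is unnecessary
here.  Fortran `D` exponents (`1.0D-05`) are accepted wherever floats are
and normalized to `E` on storage.

### Label promotion

Eigenvalue-style records use a leading string capture to *name* the numeric
capture of the same line (`Alpha occ.` vs `Alpha virt.`).  The engine
applies this promotion exactly when a record's fields are `[X, F-or-I]`:
the trimmed `X` value becomes the temporary label (`cmlx:temp`) of the
numeric node and the `X` scalar itself is not emitted.  Records with any
other field shape (for example an SCF summary capturing method, energy and
cycle count) emit one labelled node per field.  The narrow trigger keeps
the convenient idiom without surprising multi-field records.

### Chunking semantics

Scanning is single-pass, top to bottom.  At each line the first template in
pack order whose start pattern matches claims a chunk:

* with an end pattern, the chunk runs to the first line matching it
  (exclusive), or end of file;
* without one, the chunk extends while the next line matches a child record
  or nested template (maximal munch).

Claimed lines are consumed and never re-offered.  A template marked
`strict` whose chunk matched no interior line rewinds and offers the line
to later templates — a bounded, predictable form of back-tracking.  Lines
claimed by nobody accumulate into unparsed ranges, and interior lines of a
chunk that match no record are preserved as unparsed text children.  Two
invariants follow and are enforced by property tests: chunks plus residue
tile the input byte for byte, and no line index is ever claimed twice.
Parse failures are therefore *silent but auditable*: `qc_logging(TRUE)`
emits one line per unmatched chunk line and per no-op transform.

Templates may embed an example input together with its expected output
tree; `run_embedded_tests()` replays them, so every shipped template is
self-testing.  Comparison is structural, with typed payloads compared
numerically (so a reformatted `1.0938` equals `1.09380`) and parsing
scaffolding attributes excluded.

## The transform layer

Second-phase normalization is an ordered program of steps, each a process
name plus a restricted path expression (`.//name[@attr='v']` forms only,
conjunctive predicates over `dictRef`, `role`, `templateRef`, `id`).  The
process vocabulary is closed: `addDictRef`, `addUnits`, `setDataType`,
`joinArrays`, `delete`, `deleteHierarchy`, `rename`, `move`,
`groupSiblings`, `annotateModule`.  A step whose path matches nothing is a
logged no-op — a strange document must not crash the run — and only hard
type conflicts (joining arrays of different dataType) abort, naming the
step index.

`joinArrays` stitches *consecutive sibling* arrays with equal labels,
concatenating payloads in order and summing sizes; non-adjacent merging
requires an explicit `groupSiblings` first.  Dictionary prefixes are
compared through an alias table (`cc` and `compchem` denote the same
dictionary), and a predicate that matches across prefixes on the local name
is honoured and logged — published template sets mix `g:` and `cc:` for
one concept mid-program, and refusing the match would silently break them.

## Document tree and fidelity

Every stage exchanges `sem_node` trees mirroring the document vocabulary
(module, scalar, array, matrix, table, molecule, …).  Three fidelity rules:

* numeric payloads are stored as their printed decimal strings and parsed
  on demand, so serialization never changes printed precision;
* namespace prefixes are opaque strings — no URI resolution, which keeps
  equality bit-faithful even for documents whose namespace declarations
  are themselves inconsistent;
* `read_document(write_document(x))` is structurally identical to `x`,
  enforced by a property test over randomized trees.

Arrays with a non-whitespace delimiter (`|T2|T2|…|`) drop the empty edge
fields produced by enclosing delimiters on read and re-emit them on write.
Dates are normalized to ISO-8601 with a trailing `Z`.  Mixed element/text
content is not supported (no logfile dialect needs it).

## The compchem convention and dictionary

A valid document is `jobList → job → environment? initialization
calculation? finalization`, with parameters under a `parameterList`,
properties under a `propertyList`, and molecules carrying unique atom ids,
resolvable bond endpoints and element/count concise formulas.  The
environment module is optional: it describes the machine, not the model,
and upstream documentation is contradictory on this point — the dictionary
prose (OPTIONAL) wins over a stray comment labelling it mandatory.
Structural violations (missing initialization/finalization, duplicated
roles, molecule defects) are errors; placement issues (a propertyList
inside initialization) are warnings.

The shipped dictionary carries ~80 code-independent terms with data types
and unit types.  Reference validation resolves every `dictRef` through the
alias table; unresolved code-specific (`g:`) and temporary (`x:`) terms are
warnings by design — the code vocabulary is expected to float ahead of the
dictionary — and a type error fires only when a node *declares* a dataType
that disagrees with its entry.  The dictionary transcription intentionally
preserves one upstream duplicate id (`zpe.sumelectthermal`, used for two
different thermal corrections); the loader keeps the first entry and flags
the duplicate rather than silently picking one, with a strict mode
available.

Restructuring into the convention is rule-driven: each template declares
the job section its chunk belongs to, and a new job begins at each
program-restart marker.  Captured scalars become parameters/properties
(wrapper takes the term, canonical prefix `cc:`), molecules sit directly
under their role module, and anything unassignable is kept — never dropped
— under a `cc:userDefinedModule` with a warning.  The operation is
content-conserving: every scalar/array payload of the raw tree appears
exactly once in the output, checked as a multiset invariant.

## The synthetic generator: what it emulates, and what not

The generator emits the block shapes of Gaussian-style logs — banner, route
line, charge/multiplicity, orientation table, basis/electron counts, SCF
summary, eigenvalue blocks wrapped five per line, frequency and
thermochemistry tables, termination line, `Link1` restart markers for
chained jobs — with a machine-readable ground truth mapping every planted
dictionary term to its expected values in document order.  Defaults are a
methane-like five-atom molecule, 5 occupied and 18 virtual orbitals, and an
optimization-plus-frequency job chain; randomized specs draw from five
small molecules, four methods and four basis sets, with multiplicity
occasionally above 1.

No quantum chemistry is computed: energies are negative values drawn from
seeded uniform ranges, frequencies fall in 100–4000 cm⁻¹, occupied
eigenvalues are negative and sorted below the virtual ones.  Electron
counts do follow the molecule (sum of atomic numbers minus charge, split by
multiplicity), so cross-field consistency that a parser could exploit is
preserved.  Two deliberate simplifications: chained jobs re-print their
initialization blocks, and the frequency table is grouped per quantity
rather than interleaved in three-column blocks, which keeps the shipped
stitching transforms within the consecutive-sibling semantics.  Passing
the recovery property on generator output therefore demonstrates the
engine, transform, restructuring and extraction machinery end to end — it
does not demonstrate coverage of every real-world Gaussian block, which is
exactly the gap the template pack is designed to close incrementally.

The mutator injects four irregularity classes (tail truncation, an error
line at a random position, interior whitespace jitter, duplicated line
blocks).  Robustness means: the pipeline terminates normally, the partition
property holds, and whitespace jitter specifically costs no captured
concept (templates are written with `\s+`/`\s*` at every gap the generator
may widen).

## Numerical and interface choices

* Ground-truth doubles are compared at 1e-9 relative tolerance; the
  generator records values re-parsed from their printed form, so clean
  recovery is exact.
* Range queries convert stored property values to a canonical unit per
  unit type (energies to hartree: J/mol, kJ/mol, kcal/mol, eV in the
  table); a unit outside the table is a query error, never a silent miss.
* Entry ids combine an ingest counter with a content hash of the job's
  canonical serialization, so duplicate content is storable (by design)
  while ids stay unique and deterministic.  The `created` field is the
  ingest sequence number, keeping conversion and indexing byte-reproducible.
* The index store is a single plain-text JSON file with an in-memory
  record list — adequate for the thousands of entries a desk-scale
  repository holds, trivially inspectable, and free of binary state.
* Exit codes: `convert` fails a batch only per its `fail_on` policy
  (default `never` — a damaged file yields warnings and residue, not a
  failure); `validate` fails on any error-severity finding or unreadable
  file.

## Problem sizes in the test suite

The suite exercises: 100 seeded random specifications through the full
pipeline with total concept recovery required; 1000 randomized line soups
for the partition property; 500 randomized inputs for equivalence of the
engine with a brute-force single-record scanner; 25 randomized trees for
the serialization round-trip; plus the reference methane document for
extraction, validation and index round-trips.  These sizes make the
complete suite run in well under a minute on one CPU while every property
is exercised across hundreds of independent draws.

## Known limitations

* The shipped template pack is demonstrative, not exhaustive: it covers the
  generator's block vocabulary (a realistic but small subset of real
  Gaussian output).  Production template sets for the major codes run to
  hundreds of templates; the engine is designed for exactly that growth.
* Beta-spin eigenvalue blocks parse (the record captures any
  `Alpha|Beta … occ|virt` line) but no shipped transform assigns them
  dictionary terms, mirroring the omission in the published template this
  pack's eigenvalue template follows.
* Record `repeat` declarations are recorded but repetition is provided by
  the engine's line loop (first matching record wins per line); sequenced
  record grammars with overlapping patterns would need ordered-cursor
  semantics the shipped pack does not require.
* Molecule assembly from orientation tables emits atoms and a concise
  formula (Hill convention) but no bonds, and records a formal charge of
  zero; bond perception and charge assignment are out of scope.
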