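# Deterministic generator of Gaussian-style logfiles with machine-readable
# ground truth, plus a mutator injecting realistic irregularities.
#
# The generator emulates the block shapes of real logs (program banner,
# route line, orientation table, SCF summary, 5-per-line eigenvalue blocks,
# frequency/thermochemistry tables, termination line) but computes no
# quantum chemistry: numeric values are drawn from seeded uniform ranges
# plausible for each term (energies are negative hartrees, frequencies
# 100-4000 cm^-1).  The artifact under test is parsing fidelity, not
# physics.  The literal sentinels emitted here are exactly the ones the
# shipped template pack matches; generator and pack are maintained together
# so they cannot drift apart.

MOLECULES <- list(
  ch4 = data.frame(
    element = c("C", "H", "H", "H", "H"),
    x = c(0, 0, 1.049347, -0.524673, -0.524673),
    y = c(0, 0, 0, -0.908761, 0.908761),
    z = c(0, 1.113, -0.371, -0.371, -0.371)
  ),
  h2o = data.frame(
    element = c("O", "H", "H"),
    x = c(0, 0.7586, -0.7586), y = c(0, 0, 0), z = c(0.1173, -0.4692, -0.4692)
  ),
  nh3 = data.frame(
    element = c("N", "H", "H", "H"),
    x = c(0, 0.9377, -0.4689, -0.4689),
    y = c(0, 0, 0.8121, -0.8121), z = c(0.1173, -0.2737, -0.2737, -0.2737)
  ),
  co2 = data.frame(
    element = c("C", "O", "O"),
    x = c(0, 0, 0), y = c(0, 0, 0), z = c(0, 1.1621, -1.1621)
  ),
  c2h6 = data.frame(
    element = c("C", "C", "H", "H", "H", "H", "H", "H"),
    x = c(0, 0, 1.0191, -0.5095, -0.5095, -1.0191, 0.5095, 0.5095),
    y = c(0, 0, 0, 0.8825, -0.8825, 0, 0.8825, -0.8825),
    z = c(0.7680, -0.7680, 1.1573, 1.1573, 1.1573, -1.1573, -1.1573, -1.1573)
  )
)

Z_OF <- stats::setNames(seq_along(ELEMENTS), ELEMENTS)

#' Specify a synthetic calculation log
#'
#' @param molecule Data frame with columns `element`, `x`, `y`, `z`
#'   (Angstrom), or the name of a built-in molecule
#'   (`"ch4"`, `"h2o"`, `"nh3"`, `"co2"`, `"c2h6"`).
#' @param charge Total charge (echoed on the charge/multiplicity line).
#' @param multiplicity Spin multiplicity, >= 1.
#' @param method,basis Model chemistry echoed on the route line.
#' @param jobs Ordered job types, subset of `"opt"`, `"freq"`, `"sp"`.
#' @param n_occ,n_virt Numbers of occupied/virtual orbital eigenvalues.
#' @param seed Integer seed; fixes every random draw.
#' @return A `qc_log_spec`.
#' @export
log_spec <- function(molecule = "ch4", charge = 0L, multiplicity = 1L,
                     method = "B3LYP", basis = "6-31G(d)",
                     jobs = c("opt", "freq"), n_occ = 5L, n_virt = 18L,
                     seed = 42L) {
  if (is.character(molecule)) {
    if (!molecule %in% names(MOLECULES)) {
      qc_abort(sprintf("unknown built-in molecule '%s'", molecule), "qc_spec_error")
    }
    molecule <- MOLECULES[[molecule]]
  }
  if (multiplicity < 1L) qc_abort("multiplicity must be >= 1", "qc_spec_error")
  if (n_occ < 0L || n_virt < 0L) qc_abort("orbital counts must be >= 0", "qc_spec_error")
  if (!length(jobs) || !all(jobs %in% c("opt", "freq", "sp"))) {
    qc_abort("jobs must be a nonempty subset of opt/freq/sp", "qc_spec_error")
  }
  if (!all(molecule$element %in% ELEMENTS)) {
    qc_abort("molecule contains an element outside the supported range", "qc_spec_error")
  }
  structure(
    list(molecule = molecule, charge = as.integer(charge),
         multiplicity = as.integer(multiplicity), method = method,
         basis = basis, jobs = jobs, n_occ = as.integer(n_occ),
         n_virt = as.integer(n_virt), seed = as.integer(seed)),
    class = "qc_log_spec"
  )
}

#' Draw a randomized log specification
#'
#' @param seed Integer seed (also becomes the spec's seed).
#' @return A `qc_log_spec` with molecule, model chemistry, job chain and
#'   orbital counts sampled from realistic small-molecule ranges.
#' @export
random_log_spec <- function(seed) {
  with_seed(seed, {
    mol <- sample(names(MOLECULES), 1)
    jobs <- sample(list("sp", "opt", "freq", c("opt", "freq"), c("sp", "freq")), 1)[[1]]
    log_spec(
      molecule = mol,
      charge = sample(c(-1L, 0L, 0L, 0L, 1L), 1),
      multiplicity = sample(c(1L, 1L, 1L, 2L, 3L), 1),
      method = sample(c("B3LYP", "HF", "MP2", "PBE0"), 1),
      basis = sample(c("6-31G(d)", "6-311+G(2d,p)", "STO-3G", "cc-pVDZ"), 1),
      jobs = jobs,
      n_occ = sample(1:12, 1),
      n_virt = sample(0:25, 1),
      seed = seed
    )
  })
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

fmtnum <- function(x, fmt) {
  s <- sprintf(fmt, x)
  list(text = s, value = as.numeric(s))
}

#' Generate a synthetic logfile with ground truth
#'
#' Deterministic for a fixed spec (including its seed).  The ground truth
#' maps dictionary terms to the expected value occurrences, in document
#' order; every key resolves in the shipped compchem dictionary.
#'
#' @param spec A `qc_log_spec`.
#' @return `list(text = <logfile text>, truth = <named list of value lists>)`.
#' @export
generate_logfile <- function(spec) {
  if (!inherits(spec, "qc_log_spec")) qc_abort("not a qc_log_spec", "qc_spec_error")
  with_seed(spec$seed, generate_logfile_impl(spec))
}

generate_logfile_impl <- function(spec) {
  truth <- list()
  note <- function(term, value) {
    truth[[term]] <<- c(truth[[term]], list(value))
  }
  lines <- character(0)
  emit <- function(...) lines <<- c(lines, paste0(...))
  mol <- spec$molecule
  natoms <- nrow(mol)
  pg <- sample(c("C1", "CS", "C2V", "TD", "D*H"), 1)

  for (jn in seq_along(spec$jobs)) {
    jtype <- spec$jobs[jn]
    # --- environment -----------------------------------------------------
    if (jn == 1L) {
      emit(" Entering Gaussian System, Link 0=g03")
      emit(" Gaussian 03:  x86-Linux-G03RevB.04 2-Jun-2003")
      note("cc:program", "Gaussian 03")
      note("cc:version", "x86-Linux-G03RevB.04")
    } else {
      emit(sprintf(" Link1:  Proceeding to internal job step number  %d.", jn))
    }
    # --- initialization ---------------------------------------------------
    kw <- switch(jtype, opt = "Opt", freq = "Freq", sp = "SP")
    emit(sprintf(" #N %s/%s %s", spec$method, spec$basis, kw))
    note("cc:method", spec$method)
    note("cc:basis", spec$basis)
    emit(sprintf(" Charge =  %d Multiplicity = %d", spec$charge, spec$multiplicity))
    note("cc:formalCharge", spec$charge)
    note("cc:multiplicity", spec$multiplicity)
    emit(sprintf(" NAtoms=  %3d NActive=  %3d", natoms, natoms))
    note("cc:natoms", natoms)
    note("cc:nactiveatoms", natoms)
    nbasis <- natoms * 4L + sample(0:20, 1)
    nprim <- nbasis * 2L + sample(0:30, 1)
    nelec <- sum(Z_OF[mol$element]) - spec$charge
    nalpha <- (nelec + spec$multiplicity - 1L) %/% 2L
    nbeta <- nelec - nalpha
    emit(sprintf("  %4d basis functions,  %4d primitive gaussians", nbasis, nprim))
    note("cc:basiscount", nbasis)
    emit(sprintf("  %4d alpha electrons  %4d beta electrons", nalpha, nbeta))
    note("cc:alphae", nalpha)
    note("cc:betae", nbeta)
    emit(sprintf(" Full point group                 %s", pg))
    note("cc:pointgroup", pg)
    if (jtype %in% c("opt", "sp")) {
      emit("                         Standard orientation:")
      rule <- paste0(" ", strrep("-", 69))
      emit(rule)
      emit(" Center     Atomic      Atomic             Coordinates (Angstroms)")
      emit(" Number     Number       Type             X           Y           Z")
      emit(rule)
      jitter <- stats::runif(natoms * 3, -0.02, 0.02)
      for (a in seq_len(natoms)) {
        xyz <- fmtnum(c(mol$x[a], mol$y[a], mol$z[a]) + jitter[(3 * a - 2):(3 * a)],
                      "%11.6f")
        emit(sprintf("   %4d       %4d           0     %s %s %s",
                     a, Z_OF[[mol$element[a]]],
                     xyz$text[1], xyz$text[2], xyz$text[3]))
      }
      emit(rule)
      note("cc:formula", concise_formula(mol$element))
    }
    # --- calculation ------------------------------------------------------
    nr <- fmtnum(stats::runif(1, 5, 300), "%.10f")
    emit(sprintf(" nuclear repulsion energy  %s Hartrees.", nr$text))
    note("cc:nucrepener", nr$value)
    scf <- fmtnum(-stats::runif(1, 20, 500), "%.7f")
    emit(sprintf(" SCF Done:  E(R%s) =  %s     A.U. after   %2d cycles",
                 spec$method, scf$text, sample(5:20, 1)))
    note("cc:hfenergy", scf$value)
    if (jtype %in% c("opt", "sp") && spec$n_occ + spec$n_virt > 0L) {
      occ <- fmtnum(sort(-stats::runif(spec$n_occ, 0.2, 12)), "%.5f")
      virt <- fmtnum(sort(stats::runif(spec$n_virt, 0.05, 5)), "%.5f")
      emit_eigen <- function(label, toks) {
        idx <- seq_along(toks)
        for (grp in split(idx, ceiling(idx / 5))) {
          emit(sprintf(" Alpha %s. eigenvalues --%s", label,
                       paste0(sprintf(" %10s", toks[grp]), collapse = "")))
        }
      }
      if (spec$n_occ > 0L) {
        emit_eigen("occ", occ$text)
        note("cc:alphaocc", occ$value)
      }
      if (spec$n_virt > 0L) {
        emit_eigen("virt", virt$text)
        note("cc:alphavirt", virt$value)
      }
    }
    # --- finalization -----------------------------------------------------
    if (jtype == "freq") {
      nfreq <- max(1L, 3L * natoms - 6L)
      fr <- fmtnum(sort(stats::runif(nfreq, 100, 4000)), "%.4f")
      rm_ <- fmtnum(stats::runif(nfreq, 1, 15), "%.4f")
      ir <- fmtnum(stats::runif(nfreq, 0, 80), "%.4f")
      emit(" Harmonic frequencies (cm**-1), IR intensities (KM/Mole)")
      idx <- seq_len(nfreq)
      grps <- split(idx, ceiling(idx / 3))
      for (grp in grps) {
        emit(sprintf(" Frequencies --%s",
                     paste0(sprintf(" %10s", fr$text[grp]), collapse = " ")))
      }
      for (grp in grps) {
        emit(sprintf(" Red. masses --%s",
                     paste0(sprintf(" %10s", rm_$text[grp]), collapse = " ")))
      }
      for (grp in grps) {
        emit(sprintf(" IR Inten    --%s",
                     paste0(sprintf(" %10s", ir$text[grp]), collapse = " ")))
      }
      note("cc:frequency", fr$value)
      note("cc:redmass", rm_$value)
      note("cc:irintensity", ir$value)
      tt <- fmtnum(298.150, "%.3f"); pp <- fmtnum(1.0, "%.5f")
      emit(sprintf(" Temperature  %s Kelvin.  Pressure  %s Atm.", tt$text, pp$text))
      note("cc:temp", tt$value)
      note("cc:press", pp$value)
      zpe <- fmtnum(stats::runif(1, 5e4, 3e5), "%.1f")
      emit(sprintf(" Zero-point vibrational energy  %s (Joules/Mol)", zpe$text))
      note("cc:zpe", zpe$value)
      zc <- fmtnum(stats::runif(1, 0.01, 0.2), "%.6f")
      emit(sprintf(" Zero-point correction=  %s (Hartree/Particle)", zc$text))
      note("cc:zpe.correction", zc$value)
      sz <- fmtnum(scf$value + zc$value, "%.6f")
      emit(sprintf(" Sum of electronic and zero-point Energies=  %s", sz$text))
      note("cc:zpe.sumelectzpe", sz$value)
    }
    emit(" Normal termination of Gaussian 03 at Mon Nov 20 14:40:23 2006.")
  }
  list(text = paste0(paste(lines, collapse = "\n"), "\n"), truth = truth)
}

#' Inject a realistic irregularity into a logfile
#'
#' Modes: `truncate_tail` drops trailing lines (a killed job);
#' `inject_error_message` inserts an error line at a random position;
#' `shuffle_whitespace` resizes interior runs of blanks (format jitter across
#' program versions) without touching leading whitespace or single spaces;
#' `duplicate_block` repeats a random contiguous slice.
#'
#' @param text Logfile text.
#' @param mode One of the four modes.
#' @param seed Integer seed; the mutation is deterministic.
#' @return Mutated text.
#' @export
mutate_logfile <- function(text,
                           mode = c("truncate_tail", "inject_error_message",
                                    "shuffle_whitespace", "duplicate_block"),
                           seed = 1L) {
  mode <- match.arg(mode)
  lines <- split_lines(text)
  n <- length(lines)
  if (n == 0L) return(text)
  with_seed(seed, {
    lines <- switch(mode,
      truncate_tail = {
        k <- sample(seq_len(max(1L, min(10L, n - 1L))), 1)
        lines[seq_len(n - k)]
      },
      inject_error_message = {
        pos <- sample(0:n, 1)
        append(lines, " Error termination via Lnk1e in /disk/g03/l9999.exe.",
               after = pos)
      },
      shuffle_whitespace = {
        vapply(lines, function(l) {
          lead <- regmatches(l, regexpr("^\\s*", l))
          body <- substr(l, nchar(lead) + 1L, nchar(l))
          m <- gregexpr(" {2,}", body)[[1]]
          if (m[1] != -1) {
            reps <- vapply(seq_along(m), function(i) strrep(" ", sample(1:4, 1)), "")
            regmatches(body, gregexpr(" {2,}", body)) <- list(reps)
          }
          paste0(lead, body)
        }, "", USE.NAMES = FALSE)
      },
      duplicate_block = {
        from <- sample(seq_len(n), 1)
        to <- min(n, from + sample(0:5, 1))
        append(lines, lines[from:to], after = to)
      }
    )
    paste0(paste(lines, collapse = "\n"), "\n")
  })
}

# --- ground-truth recovery ---------------------------------------------------

# collect all payload values for a term, in document order; a node's
# effective reference is its own dictRef or the enclosing parameter/property
# wrapper's; formula nodes contribute their concise attribute
collect_by_ref <- function(node, ref, inherited = NULL) {
  out <- list()
  own <- sem_attr(node, "dictRef")
  eff <- own %||% inherited
  if (node$name %in% c("scalar", "array", "matrix")) {
    if (!is.null(eff) && ref_match(eff, ref)) {
      v <- parse_payload(node$value, sem_attr(node, "dataType"))
      return(list(v))
    }
    return(out)
  }
  if (node$name == "formula") {
    if (!is.null(own) && ref_match(own, ref)) {
      return(list(sem_attr(node, "concise")))
    }
    return(out)
  }
  pass <- if (node$name %in% c("parameter", "property")) eff else NULL
  for (ch in node$children) {
    out <- c(out, collect_by_ref(ch, ref, pass))
  }
  out
}

values_match <- function(expected, got) {
  if (length(expected) != length(got)) return(FALSE)
  if (is.numeric(expected)) {
    got <- suppressWarnings(as.numeric(got))
    if (anyNA(got)) return(FALSE)
    denom <- pmax(abs(expected), 1e-300)
    return(all(abs(got - expected) / denom <= 1e-9 | got == expected))
  }
  identical(as.character(expected), trimws(as.character(got)))
}

#' Fraction of ground-truth values recovered from a parsed document
#'
#' A term counts as recovered when the document yields the same number of
#' occurrences, in order, each matching (doubles to within 1e-9 relative).
#'
#' @param truth Ground truth from [generate_logfile()].
#' @param parsed A `sem_node` (raw or restructured document).
#' @return Fraction in `[0, 1]`.
#' @export
recovery_score <- function(truth, parsed) {
  if (!length(truth)) return(1.0)
  hits <- vapply(names(truth), function(term) {
    got <- collect_by_ref(parsed, term)
    exp <- truth[[term]]
    length(got) == length(exp) &&
      all(vapply(seq_along(exp), function(i) values_match(exp[[i]], got[[i]]), TRUE))
  }, TRUE)
  mean(hits)
}
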