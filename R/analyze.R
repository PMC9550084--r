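# High-level workflows: whole-file analysis and the disulfide-fragment
# profiling workflow.

#' Analyze a structure file: unit status plus fragment statuses
#'
#' The standard workflow: load the structure, select the structural unit,
#' reduce to effective atoms, fit the Gaussian field, compute the unit-level
#' RD / K-scan / RD_Kopt, then the status of each requested fragment
#' (typically IDRs) under the unit's field.
#'
#' @param path Structure file (PDB or mmCIF).
#' @param chains Chain ids (`NULL` = all).
#' @param unit_range Optional author-number range defining the structural
#'   unit (e.g. a domain); `NULL` = whole selection.
#' @param fragments Named or unnamed list of inclusive author-number ranges
#'   `c(start, end)` to profile as fragments of the unit.
#' @param scale,cutoff,k_grid,margin See [fod_analyze()].
#' @param ... Passed to [load_structure()] (format, model, altloc, ...).
#' @return List with `unit` (a `fod_result` with the field attached),
#'   `fragments` (list of `fod_result`), `atoms`, and `field`.
#' @export
analyze_structure <- function(path, chains = NULL, unit_range = NULL,
                              fragments = list(),
                              scale = default_scale(), cutoff = 9,
                              k_grid = seq(0, 5, by = 0.1), margin = 0,
                              ...) {
  st <- load_structure(path, ...)
  sel <- select_unit(st, chains = chains, residue_range = unit_range)
  atoms <- effective_atoms(st, sel)
  unit <- fod_analyze(atoms, scale = scale, cutoff = cutoff,
                      k_grid = k_grid, margin = margin,
                      unit_label = st$id)
  field <- attr(unit, "field")
  frs <- lapply(seq_along(fragments), function(i) {
    fr <- fragments[[i]]
    lab <- names(fragments)[i]
    if (is.null(lab) || !nzchar(lab))
      lab <- paste0(fr[1], "-", fr[2])
    fragment_status(atoms, field, as.numeric(fr), scale = scale,
                    cutoff = cutoff, k_grid = k_grid,
                    unit_label = st$id, fragment_label = lab)
  })
  names(frs) <- vapply(frs, function(r) r$fragment_label, character(1))
  list(unit = unit, fragments = frs, atoms = atoms, field = field)
}

#' Profile the chain fragments covered by disulfide bonds
#'
#' Detects all SS bonds in the structure and computes the FOD-M status (RD,
#' optimal K) of each inclusive fragment between the bonded cysteines,
#' under the structural unit's Gaussian field -- the workflow used to ask
#' whether disulfide-closed segments conform to the centric hydrophobic
#' core.
#'
#' @param path Structure file.
#' @param chains Chain ids (`NULL` = all).
#' @param threshold SG--SG distance threshold in Angstrom (default 2.3).
#' @param scale,cutoff,k_grid,margin See [fod_analyze()].
#' @param ... Passed to [load_structure()].
#' @return List with `bonds` (data frame from [detect_disulfides()]),
#'   `unit` (`fod_result`) and `fragments` (list of `fod_result`, one per
#'   bond fragment).
#' @export
ss_fragment_status <- function(path, chains = NULL, threshold = 2.3,
                               scale = default_scale(), cutoff = 9,
                               k_grid = seq(0, 5, by = 0.1), margin = 0,
                               ...) {
  st <- load_structure(path, ...)
  bonds <- detect_disulfides(st, threshold = threshold)
  frags <- if (nrow(bonds)) {
    lapply(seq_len(nrow(bonds)), function(i)
      c(bonds$frag_start[i], bonds$frag_end[i]))
  } else list()
  names(frags) <- if (nrow(bonds))
    paste0(bonds$frag_start, "-", bonds$frag_end) else NULL
  res <- analyze_structure(path, chains = chains, fragments = frags,
                           scale = scale, cutoff = cutoff,
                           k_grid = k_grid, margin = margin, ...)
  list(bonds = bonds, unit = res$unit, fragments = res$fragments)
}
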