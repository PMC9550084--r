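# Structure reading, unit/fragment selection, effective-atom reduction,
# disulfide detection. Parsing is delegated to bio3d (PDB + mmCIF).

.water_names <- c("HOH", "WAT", "DOD", "H2O")

#' Load a protein structure from PDB or mmCIF
#'
#' Reads a structure file into a light atom-table representation. Only the
#' requested model of a multi-model (e.g. NMR) file is kept -- model 1 by
#' default -- unless `average_models = TRUE`, in which case coordinates are
#' averaged over the ensemble. Alternate locations are reduced to a single
#' conformer (blank or "A" altloc). Author residue numbering and insertion
#' codes are preserved throughout.
#'
#' @param path Path to a PDB (fixed-column) or mmCIF file.
#' @param format `"auto"` (by file extension), `"pdb"` or `"mmcif"`.
#' @param model Model index to keep for multi-model files (default 1).
#' @param average_models Average coordinates over all models instead of
#'   selecting one. Intended for NMR ensembles; off by default.
#' @param altloc Alternate-location policy: keep blank altloc plus this
#'   conformer id (default `"A"`).
#' @return A `fod_structure`: list with `id` (file stem), `atoms` (data frame
#'   with columns type, eleno, elety, altloc, resid, chain, resno, insert,
#'   x, y, z) and `nmodels`.
#' @export
load_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           model = 1L, average_models = FALSE,
                           altloc = "A") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  multi <- isTRUE(average_models) || model > 1L
  parsed <- tryCatch(
    withCallingHandlers(
      if (format == "mmcif") bio3d::read.cif(path, multi = multi)
      else bio3d::read.pdb(path, multi = multi),
      warning = function(w) {
        # bio3d advisory warnings, not data problems
        if (grepl("beta version|helix/sheet|PDB has ALT records",
                  conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0L)
    stop("empty structure: no atom records in ", path)

  nmodels <- if (is.matrix(parsed$xyz)) nrow(parsed$xyz) else 1L
  if (multi && nmodels >= 1L) {
    if (average_models) {
      xyz <- colMeans(parsed$xyz)
    } else {
      if (model > nmodels)
        stop("model ", model, " requested but file has ", nmodels, " models")
      xyz <- parsed$xyz[model, ]
    }
    m <- matrix(xyz, ncol = 3L, byrow = TRUE)
    at$x <- m[, 1L]; at$y <- m[, 2L]; at$z <- m[, 3L]
  }

  alt <- at$alt
  alt[is.na(alt)] <- ""
  keep <- alt == "" | alt == altloc
  at <- at[keep, , drop = FALSE]

  ch <- at$chain
  ch[is.na(ch)] <- ""
  ins <- at$insert
  ins[is.na(ins)] <- ""
  atoms <- data.frame(
    type = at$type, eleno = at$eleno, elety = at$elety,
    altloc = alt[keep], resid = toupper(at$resid), chain = ch,
    resno = at$resno, insert = ins,
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad)) atoms <- atoms[!bad, , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop("empty structure: no atoms with finite coordinates in ", path)

  structure(list(
    id = tools::file_path_sans_ext(basename(sub("\\.gz$", "", path))),
    atoms = atoms,
    nmodels = nmodels
  ), class = "fod_structure")
}

#' @export
print.fod_structure <- function(x, ...) {
  rk <- .residue_table(x$atoms)
  cat("Structure", x$id, "-", nrow(rk), "residues,",
      nrow(x$atoms), "atoms,", length(unique(rk$chain)), "chain(s)\n")
  invisible(x)
}

# Ordered table of distinct residues (chain, resno, insert, resid) in file
# order; polymer residues only unless keep_het.
.residue_table <- function(atoms, keep_het = FALSE, mapping = NULL) {
  a <- atoms[!(atoms$resid %in% .water_names), , drop = FALSE]
  if (!keep_het) {
    ok <- a$type == "ATOM" |
      (!is.null(mapping) & a$resid %in% names(mapping))
    a <- a[ok, , drop = FALSE]
  }
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             insert = a$insert[first], resid = a$resid[first],
             key = key[first], stringsAsFactors = FALSE)
}

#' Select a structural unit
#'
#' Resolves a chain set and optional author-numbered residue range into an
#' ordered residue selection -- the structural unit over which the Gaussian
#' hydrophobicity field is fitted, or a fragment of one. Domains are
#' expressed as explicit residue ranges. Ranges are inclusive in author
#' numbering; author numbers present in the range bounds but unresolved in
#' the structure are skipped and reported via a message and the `skipped`
#' attribute.
#'
#' @param structure A `fod_structure`.
#' @param chains Character vector of chain ids; `NULL` selects all chains.
#' @param residue_range Optional inclusive `c(start, end)` in author
#'   numbering, applied to every selected chain.
#' @param residue_mapping Optional named character vector mapping modified
#'   residue names (HETATM) to their standard parent (e.g. `c(MSE = "MET")`);
#'   mapped residues are included in the selection.
#' @return A `fod_unit`: list with `structure_id`, `chains`, `residue_range`
#'   and `residues` (ordered data frame chain/resno/insert/resid).
#' @export
select_unit <- function(structure, chains = NULL, residue_range = NULL,
                        residue_mapping = NULL) {
  stopifnot(inherits(structure, "fod_structure"))
  rt <- .residue_table(structure$atoms, mapping = residue_mapping)
  avail <- unique(rt$chain)
  if (is.null(chains)) chains <- avail
  unknown <- setdiff(chains, avail)
  if (length(unknown))
    stop("unknown chain(s) ", paste(unknown, collapse = ", "),
         "; available: ", paste(avail, collapse = ", "))
  rt <- rt[rt$chain %in% chains, , drop = FALSE]

  skipped <- integer(0)
  if (!is.null(residue_range)) {
    if (length(residue_range) != 2L || residue_range[1] > residue_range[2])
      stop("residue_range must be c(start, end) with start <= end")
    within <- rt$resno >= residue_range[1] & rt$resno <= residue_range[2]
    for (endp in residue_range)
      if (!any(rt$resno == endp))
        stop("range endpoint ", endp, " not present in author numbering; ",
             "available residues span ",
             min(rt$resno), "..", max(rt$resno))
    rt <- rt[within, , drop = FALSE]
    skipped <- setdiff(seq(residue_range[1], residue_range[2]),
                       unique(rt$resno))
    if (length(skipped))
      message("select_unit: ", length(skipped),
              " residue number(s) in range unresolved in structure: ",
              paste(skipped, collapse = ", "))
  }
  if (nrow(rt) < 2L)
    stop("selection resolves to ", nrow(rt),
         " residue(s); a structural unit needs at least 2")
  out <- structure(list(
    structure_id = structure$id,
    chains = chains,
    residue_range = residue_range,
    residues = rt[, c("chain", "resno", "insert", "resid")]
  ), class = "fod_unit")
  attr(out, "skipped") <- skipped
  out
}

#' @export
print.fod_unit <- function(x, ...) {
  rng <- if (is.null(x$residue_range)) "full" else
    paste(x$residue_range, collapse = "-")
  cat("Unit of", x$structure_id, "- chains",
      paste(x$chains, collapse = ","), "range", rng, ":",
      nrow(x$residues), "residues\n")
  invisible(x)
}

#' Reduce residues to effective atoms
#'
#' Each residue is represented by a single effective atom located at the
#' unweighted arithmetic mean of all of its atom coordinates (side chain
#' included; hydrogens included when present in the file). Waters are
#' excluded; HETATM residues are included only when mapped to a standard
#' parent via `residue_mapping`.
#'
#' @param structure A `fod_structure`.
#' @param selection Optional `fod_unit` restricting the residues; `NULL`
#'   uses every polymer residue.
#' @param residue_mapping Named character vector mapping modified residue
#'   names to standard parents (also applied to the stored residue names so
#'   downstream hydrophobicity lookup works).
#' @return A `fod_atoms`: list with `xyz` (N x 3 matrix, Angstrom), `resid`
#'   (residue names), `chain`, `resno`, `insert`, `ids` ("chain:resno"
#'   labels) and `n`.
#' @export
effective_atoms <- function(structure, selection = NULL,
                            residue_mapping = NULL) {
  stopifnot(inherits(structure, "fod_structure"))
  if (is.null(selection))
    selection <- select_unit(structure, residue_mapping = residue_mapping)
  stopifnot(inherits(selection, "fod_unit"))
  res <- selection$residues
  a <- structure$atoms
  akey <- paste(a$chain, a$resno, a$insert, sep = "\r")
  rkey <- paste(res$chain, res$resno, res$insert, sep = "\r")

  xyz <- matrix(NA_real_, nrow = nrow(res), ncol = 3L,
                dimnames = list(NULL, c("x", "y", "z")))
  for (i in seq_len(nrow(res))) {
    sel <- akey == rkey[i]
    if (!any(sel)) stop("residue ", res$chain[i], ":", res$resno[i],
                        res$insert[i], " has no atoms")
    xyz[i, ] <- c(mean(a$x[sel]), mean(a$y[sel]), mean(a$z[sel]))
  }
  resid <- res$resid
  if (!is.null(residue_mapping)) {
    hit <- resid %in% names(residue_mapping)
    resid[hit] <- unname(residue_mapping[resid[hit]])
  }
  structure(list(
    xyz = xyz, resid = resid, chain = res$chain, resno = res$resno,
    insert = res$insert,
    ids = paste0(res$chain, ":", res$resno, res$insert),
    n = nrow(res)
  ), class = "fod_atoms")
}

#' @export
print.fod_atoms <- function(x, ...) {
  cat("Effective atoms:", x$n, "residues\n")
  invisible(x)
}

#' Detect disulfide bonds
#'
#' Finds all cysteine SG--SG pairs within a distance threshold and reports
#' each bond together with the inclusive residue fragment (min, max author
#' number) that it covers, the notation used when profiling disulfide-closed
#' chain fragments.
#'
#' @param structure A `fod_structure`.
#' @param threshold SG--SG distance threshold in Angstrom (default 2.3,
#'   standard disulfide geometry).
#' @return Data frame with one row per bond: `chain_a`, `res_a`, `chain_b`,
#'   `res_b`, `sg_distance`, `frag_start`, `frag_end`. Zero rows if no
#'   disulfides.
#' @export
detect_disulfides <- function(structure, threshold = 2.3) {
  stopifnot(inherits(structure, "fod_structure"))
  a <- structure$atoms
  sg <- a[a$resid == "CYS" & trimws(a$elety) == "SG", , drop = FALSE]
  empty <- data.frame(chain_a = character(0), res_a = integer(0),
                      chain_b = character(0), res_b = integer(0),
                      sg_distance = numeric(0),
                      frag_start = integer(0), frag_end = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(sg) < 2L) return(empty)
  out <- empty
  for (i in seq_len(nrow(sg) - 1L)) {
    for (j in seq(i + 1L, nrow(sg))) {
      d <- sqrt(sum((c(sg$x[i], sg$y[i], sg$z[i]) -
                     c(sg$x[j], sg$y[j], sg$z[j]))^2))
      if (d <= threshold) {
        out <- rbind(out, data.frame(
          chain_a = sg$chain[i], res_a = sg$resno[i],
          chain_b = sg$chain[j], res_b = sg$resno[j],
          sg_distance = d,
          frag_start = min(sg$resno[i], sg$resno[j]),
          frag_end = max(sg$resno[i], sg$resno[j]),
          stringsAsFactors = FALSE))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Write effective atoms as a CA-only PDB file
#'
#' Debug/interchange output: one CA record per residue at the effective-atom
#' position. Round-trips through [load_structure()] + [effective_atoms()]
#' to the same coordinates at PDB precision (1e-3 Angstrom).
#'
#' @param atoms A `fod_atoms`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_effective_pdb <- function(atoms, path) {
  stopifnot(inherits(atoms, "fod_atoms"))
  ch <- atoms$chain
  ch[!nzchar(ch)] <- "A"
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(atoms$xyz)),
                   type = rep("ATOM", atoms$n),
                   resno = atoms$resno,
                   resid = atoms$resid,
                   chain = ch,
                   eleno = seq_len(atoms$n),
                   elety = rep("CA", atoms$n))
  invisible(path)
}
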