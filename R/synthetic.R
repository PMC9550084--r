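# Synthetic effective-atom point clouds with controlled hydrophobicity
# arrangements and known ground-truth FOD behavior.

#' Specification for a synthetic structural unit
#'
#' Describes a generated effective-atom cloud with a controlled
#' hydrophobicity arrangement:
#' * `core_sorted` -- intrinsic hydrophobicities assigned by descending rank
#'   of the theoretical profile T: the most hydrophobic residues sit at the
#'   center (ideal micelle; expect RD < 0.5, small K).
#' * `inverted` -- ascending rank: hydrophobic residues on the surface,
#'   polar in the center (membrane-like inversion; expect RD > 0.5, K >= 1).
#' * `shuffled` -- random assignment (expect intermediate RD).
#' * `k_target` -- the observed profile is manufactured directly as
#'   `M(K = k_target)` from the cloud's T profile, optionally perturbed by
#'   Dirichlet noise, so the optimal-K search has a known ground truth.
#'
#' @param n Residue count (>= 4).
#' @param geometry `"gaussian_cloud"` (isotropic 3D normal, sd
#'   `cloud_sd` Angstrom) or `"helix_like_curve"` (alpha-helical CA-trace
#'   geometry: radius 2.3 A, rise 1.5 A, 100 degrees per residue).
#' @param assignment One of `"core_sorted"`, `"inverted"`, `"shuffled"`,
#'   `"k_target"`.
#' @param k_target Ground-truth K for the `k_target` assignment.
#' @param noise Positional jitter sd in Angstrom added to the geometry
#'   (default 0).
#' @param dirichlet Dirichlet concentration for the `k_target` observed
#'   profile: alpha_i = dirichlet * O_i. `Inf` (default) means no noise;
#'   5e5 is the documented "small noise" level at which K recovery stays
#'   within one grid step (the per-entry noise sd `sqrt(1/(n*conc))` then
#'   sits below half the per-entry one-grid-step change of M, which is
#'   about `0.1 / ((1 + K) * n)`).
#' @param cloud_sd Gaussian-cloud sd in Angstrom (default 6, a compact
#'   globular-domain scale).
#' @param seed Integer seed fixing all randomness.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 60,
                           geometry = c("gaussian_cloud",
                                        "helix_like_curve"),
                           assignment = c("core_sorted", "inverted",
                                          "shuffled", "k_target"),
                           k_target = NULL, noise = 0, dirichlet = Inf,
                           cloud_sd = 6, seed = 1L) {
  geometry <- match.arg(geometry)
  assignment <- match.arg(assignment)
  if (n < 4L) stop("n must be >= 4")
  if (assignment == "k_target" &&
      (is.null(k_target) || k_target < 0))
    stop("k_target assignment requires a nonnegative k_target")
  structure(list(n = as.integer(n), geometry = geometry,
                 assignment = assignment, k_target = k_target,
                 noise = noise, dirichlet = dirichlet,
                 cloud_sd = cloud_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Dirichlet draw with alpha = conc * p, renormalized; Inf returns p.
.dirichlet_perturb <- function(p, conc) {
  if (!is.finite(conc)) return(p)
  y <- stats::rgamma(length(p), shape = conc * p)
  if (sum(y) <= 0) return(p)
  y / sum(y)
}

#' Generate a synthetic structural unit
#'
#' Samples effective-atom positions for the spec's geometry, fits the
#' Gaussian field, and assigns intrinsic hydrophobicities per the spec's
#' arrangement. Residue names are chosen as the nearest-value residue under
#' the scale (so the set survives a PDB round trip); the exact assigned
#' hydrophobicities are returned alongside to avoid quantization.
#'
#' Same seed, same spec: bit-identical output.
#'
#' @param spec A `synthetic_spec`.
#' @param scale A `hydro_scale` supplying the pool of intrinsic values and
#'   the residue-name encoding (default [default_scale()]).
#' @return List with `atoms` (`fod_atoms`), `hydrophobicity` (assigned
#'   per-residue intrinsic values), `o_profile` (`hydro_profile`, only for
#'   the `k_target` assignment, else `NULL`), and `truth` (list: regime,
#'   k_target, seed).
#' @export
generate_synthetic <- function(spec, scale = default_scale()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(spec$seed)

  n <- spec$n
  xyz <- switch(spec$geometry,
    gaussian_cloud = matrix(stats::rnorm(3L * n, sd = spec$cloud_sd),
                            ncol = 3L),
    helix_like_curve = {
      t <- seq_len(n) - 1
      th <- t * 100 * pi / 180
      cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * t)
    })
  if (spec$noise > 0)
    xyz <- xyz + matrix(stats::rnorm(3L * n, sd = spec$noise), ncol = 3L)
  colnames(xyz) <- c("x", "y", "z")

  field <- fit_gaussian(xyz)
  tvals <- .gauss_eval(field, xyz)

  pool <- sort(unname(sample(scale$values, n, replace = TRUE)))  # ascending
  h <- numeric(n)
  o_prof <- NULL
  if (spec$assignment == "core_sorted") {
    h[order(tvals, decreasing = TRUE)] <- rev(pool)
  } else if (spec$assignment == "inverted") {
    h[order(tvals, decreasing = TRUE)] <- pool
  } else if (spec$assignment == "shuffled") {
    h <- sample(pool)
  } else {                                  # k_target
    h <- sample(pool)
    T_ <- hydro_profile(tvals, role = "T")
    o <- m_profile(T_, spec$k_target)$values
    o <- .dirichlet_perturb(o, spec$dirichlet)
    o_prof <- hydro_profile(o, role = "O")
  }

  near <- vapply(h, function(v)
    names(scale$values)[which.min(abs(scale$values - v))], character(1))
  atoms <- structure(list(
    xyz = xyz, resid = near, chain = rep("A", n),
    resno = seq_len(n), insert = rep("", n),
    ids = paste0("A:", seq_len(n)), n = n
  ), class = "fod_atoms")

  list(atoms = atoms, hydrophobicity = h, o_profile = o_prof,
       truth = list(regime = spec$assignment, k_target = spec$k_target,
                    seed = spec$seed))
}

#' Write a synthetic unit to disk
#'
#' Emits a CA-only PDB (residue names encode the assigned hydrophobicity by
#' nearest scale value), a sidecar CSV with the exact assigned values, and
#' a ground-truth JSON.
#'
#' @param syn Output of [generate_synthetic()].
#' @param path Output PDB path; the sidecar CSV and JSON take the same stem
#'   with `.csv` / `.json` extensions.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_synthetic_pdb <- function(syn, path) {
  write_effective_pdb(syn$atoms, path)
  stem <- tools::file_path_sans_ext(path)
  csv <- paste0(stem, ".csv")
  utils::write.csv(data.frame(residue_id = syn$atoms$resno,
                              resname = syn$atoms$resid,
                              hydrophobicity = syn$hydrophobicity),
                   csv, row.names = FALSE)
  js <- paste0(stem, ".json")
  jsonlite::write_json(syn$truth, js, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(pdb = path, csv = csv, json = js))
}
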