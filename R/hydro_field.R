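# 3D Gaussian hydrophobicity field and the per-residue T / O / R profiles.

#' Per-residue hydrophobicity profile
#'
#' A `hydro_profile` is a normalized nonnegative per-residue weight vector
#' (sums to 1) with a role tag: `"T"` (theoretical, Gaussian), `"O"`
#' (observed, Levitt pairwise), `"R"` (uniform reference) or `"M"`
#' (environment-modified).
#'
#' @param values Nonnegative numeric weights; normalized to sum 1.
#' @param role One of `"T"`, `"O"`, `"R"`, `"M"`.
#' @param ids Optional residue labels aligned with `values`.
#' @return A `hydro_profile`.
#' @export
hydro_profile <- function(values, role = c("T", "O", "R", "M"), ids = NULL) {
  role <- match.arg(role)
  if (length(values) < 1L) stop("profile needs at least one residue")
  if (any(!is.finite(values)) || any(values < 0))
    stop("profile values must be finite and nonnegative")
  s <- sum(values)
  if (s <= 0) stop("degenerate profile: all values are zero")
  values <- unname(as.numeric(values))
  structure(list(values = values / s, role = role,
                 ids = ids %||% as.character(seq_along(values))),
            class = "hydro_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hydro_profile <- function(x, ...) {
  cat("Hydro profile [", x$role, "], n =", length(x$values),
      ", sum =", format(sum(x$values)), "\n")
  invisible(x)
}

#' @export
as.numeric.hydro_profile <- function(x, ...) x$values

#' Fit the 3D Gaussian hydrophobicity field to a structural unit
#'
#' The field encodes the idealized micelle-like hydrophobic core: highest
#' hydrophobicity at the center of the molecule, decaying outward. Its
#' parameters are taken from the unit itself: the center is the mean of the
#' effective-atom positions; the axes are the principal components of the
#' centered point cloud; each sigma is the maximum absolute coordinate along
#' its principal axis divided by 3 (plus an optional margin added to the
#' extent first), so the molecule spans three standard deviations of its
#' own field.
#'
#' @param atoms A `fod_atoms` (or plain N x 3 coordinate matrix).
#' @param margin Padding in Angstrom added to the max extent along each axis
#'   before division by 3. Default 0.
#' @return A `gaussian_field`: list with `center` (length-3), `rotation`
#'   (3 x 3 orthonormal, world -> principal frame via `x %*% rotation`) and
#'   `sigma` (length-3, positive).
#' @export
fit_gaussian <- function(atoms, margin = 0) {
  xyz <- if (inherits(atoms, "fod_atoms")) atoms$xyz else as.matrix(atoms)
  if (nrow(xyz) < 3L) stop("Gaussian fit needs at least 3 residues")
  center <- colMeans(xyz)
  cen <- sweep(xyz, 2L, center)
  cv <- crossprod(cen) / nrow(cen)
  eg <- eigen(cv, symmetric = TRUE)
  rot <- eg$vectors
  # deterministic axis signs: largest-|loading| component positive
  for (j in 1:3) {
    k <- which.max(abs(rot[, j]))
    if (rot[k, j] < 0) rot[, j] <- -rot[, j]
  }
  pc <- cen %*% rot
  ext <- apply(abs(pc), 2L, max)
  if (any(ext + margin <= 0))
    stop("degenerate point cloud: zero extent along a principal axis")
  sigma <- (ext + margin) / 3
  if (min(sigma) < 1e-9 * max(sigma))
    stop("degenerate (collinear or coincident) point cloud")
  structure(list(center = center, rotation = rot, sigma = sigma),
            class = "gaussian_field")
}

#' @export
print.gaussian_field <- function(x, ...) {
  cat("3D Gaussian field: center (",
      paste(sprintf("%.2f", x$center), collapse = ", "),
      ") A, sigma (", paste(sprintf("%.2f", x$sigma), collapse = ", "),
      ") A\n", sep = "")
  invisible(x)
}

# Unnormalized Gaussian density at each effective atom, in the field's
# principal frame.
.gauss_eval <- function(field, xyz) {
  pc <- sweep(xyz, 2L, field$center) %*% field$rotation
  exp(-pc[, 1L]^2 / (2 * field$sigma[1L]^2)) *
    exp(-pc[, 2L]^2 / (2 * field$sigma[2L]^2)) *
    exp(-pc[, 3L]^2 / (2 * field$sigma[3L]^2))
}

#' Theoretical hydrophobicity profile (T)
#'
#' Evaluates the fitted 3D Gaussian at every effective atom and normalizes
#' to sum 1. A residue at the field center attains the profile maximum; the
#' profile decays toward the surface -- the idealized centric hydrophobic
#' core.
#'
#' @param field A `gaussian_field` fitted on the same unit.
#' @param atoms A `fod_atoms`.
#' @return A `hydro_profile` with role `"T"`.
#' @export
theoretical_profile <- function(field, atoms) {
  stopifnot(inherits(field, "gaussian_field"))
  xyz <- if (inherits(atoms, "fod_atoms")) atoms$xyz else as.matrix(atoms)
  hydro_profile(.gauss_eval(field, xyz), role = "T",
                ids = if (inherits(atoms, "fod_atoms")) atoms$ids else NULL)
}

#' Levitt pairwise hydrophobic interaction weight
#'
#' Distance taper for pairwise hydrophobic contacts:
#' `w(r) = 1 - 1/2 (7(r/c)^2 - 9(r/c)^4 + 5(r/c)^6 - (r/c)^9)` for
#' `r <= c` and 0 beyond the cutoff. `w(0) = 1` and `w(c) = 0`.
#'
#' @param r Distances in Angstrom (vectorized).
#' @param cutoff Cutoff distance c in Angstrom (default 9).
#' @return Weights in \[0, 1\].
#' @export
levitt_weight <- function(r, cutoff = 9) {
  if (cutoff <= 0) stop("cutoff must be positive")
  q <- r / cutoff
  w <- 1 - 0.5 * (7 * q^2 - 9 * q^4 + 5 * q^6 - q^9)
  w[r > cutoff] <- 0
  w
}

#' Observed hydrophobicity profile (O)
#'
#' Collects, for each residue, the Levitt pairwise hydrophobic interactions
#' with all other residues within the cutoff:
#' `O_i` is proportional to `sum_{j != i} (H_i + H_j) w(r_ij)` where `H`
#' are intrinsic hydrophobicities from the scale and `w` is
#' [levitt_weight()]. The vector is floored at a tiny epsilon (so the
#' Kullback--Leibler divergence downstream stays finite) and normalized to
#' sum 1. A warning is emitted whenever the floor is actually triggered.
#'
#' @param atoms A `fod_atoms`.
#' @param scale A `hydro_scale` (default [default_scale()]).
#' @param cutoff Interaction cutoff c in Angstrom (default 9).
#' @param hydrophobicity Optional numeric vector of per-residue intrinsic
#'   hydrophobicities overriding the scale lookup (used by the synthetic
#'   generator, where the assignment is exact rather than residue-name
#'   mediated).
#' @param eps Floor applied to entries before normalization (default 1e-12).
#' @return A `hydro_profile` with role `"O"`.
#' @export
observed_profile <- function(atoms, scale = default_scale(), cutoff = 9,
                             hydrophobicity = NULL, eps = 1e-12) {
  xyz <- if (inherits(atoms, "fod_atoms")) atoms$xyz else as.matrix(atoms)
  n <- nrow(xyz)
  h <- if (!is.null(hydrophobicity)) {
    if (length(hydrophobicity) != n)
      stop("hydrophobicity vector length != residue count")
    hydrophobicity
  } else {
    scale_lookup(scale, atoms$resid)
  }
  d <- as.matrix(stats::dist(xyz))
  w <- levitt_weight(d, cutoff)
  diag(w) <- 0                      # pairwise contacts only: j != i
  hs <- outer(h, h, `+`)
  o <- rowSums(hs * w)
  if (all(o <= 0))
    stop("degenerate observed profile: all pairwise contributions are zero")
  if (any(o < eps)) {
    warning("epsilon floor (", format(eps),
            ") applied to ", sum(o < eps), " observed-profile entries")
    o <- pmax(o, eps)
  }
  hydro_profile(o, role = "O",
                ids = if (inherits(atoms, "fod_atoms")) atoms$ids else NULL)
}

#' Uniform reference profile (R)
#'
#' The no-structure reference: every residue carries hydrophobicity 1/N.
#'
#' @param n Residue count (>= 1), or a `fod_atoms` / `hydro_profile` whose
#'   length is used.
#' @return A `hydro_profile` with role `"R"`.
#' @export
uniform_profile <- function(n) {
  if (inherits(n, "fod_atoms")) n <- n$n
  if (inherits(n, "hydro_profile")) n <- length(n$values)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("residue count must be >= 1")
  hydro_profile(rep(1 / n, n), role = "R")
}

#' Per-residue profile table
#'
#' Assembles the standard per-residue output: residue id, chain, residue
#' name, T, O, optionally M, and |T - O|.
#'
#' @param atoms A `fod_atoms`.
#' @param t_prof,o_prof,m_prof `hydro_profile`s (M optional).
#' @return A data frame, one row per residue.
#' @export
profile_table <- function(atoms, t_prof, o_prof, m_prof = NULL) {
  stopifnot(inherits(atoms, "fod_atoms"))
  df <- data.frame(
    residue_id = atoms$resno,
    chain = atoms$chain,
    resname = atoms$resid,
    T = t_prof$values,
    O = o_prof$values,
    stringsAsFactors = FALSE
  )
  if (!is.null(m_prof)) df$M <- m_prof$values
  df$abs_T_minus_O <- abs(df$T - df$O)
  df
}
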