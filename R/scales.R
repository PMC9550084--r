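# Intrinsic per-residue hydrophobicity scales.

# Kyte & Doolittle (1982) hydropathy values for the 20 standard residues.
.kd_raw <- c(
  ALA =  1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS =  2.5,
  GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE =  4.5,
  LEU =  3.8, LYS = -3.9, MET =  1.9, PHE =  2.8, PRO = -1.6,
  SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL =  4.2
)

#' Intrinsic hydrophobicity scale
#'
#' Constructs a `hydro_scale`: a named map from 3-letter residue names to
#' intrinsic hydrophobicity values on the closed interval \[0, 1\]. The
#' intrinsic value of residue *i* enters the observed hydrophobicity profile
#' through the Levitt pairwise interaction term (see
#' [observed_profile()]).
#'
#' The default scale is the Kyte--Doolittle hydropathy index min--max
#' normalized to \[0, 1\] (so ILE = 1, ARG = 0). Any user scale covering the
#' 20 standard residues can be supplied instead, either as a named numeric
#' vector or via [read_hydro_scale()].
#'
#' @param values Named numeric vector: 3-letter residue names (upper case)
#'   to values in \[0, 1\]. Must cover the 20 standard residues.
#' @param name Character label for the scale.
#' @return An object of class `hydro_scale`.
#' @examples
#' sc <- default_scale()
#' sc["ILE"]  # 1: most hydrophobic under Kyte-Doolittle
#' @export
hydro_scale <- function(values, name = "custom") {
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("hydrophobicity scale values must be named by 3-letter residue code")
  nm <- toupper(names(values))
  missing <- setdiff(names(.kd_raw), nm)
  if (length(missing))
    stop("scale does not cover the 20 standard residues; missing: ",
         paste(missing, collapse = ", "))
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1))
    stop("scale values must be finite and within [0, 1]")
  v <- as.numeric(values)
  names(v) <- nm
  structure(list(name = name, values = v), class = "hydro_scale")
}

#' @rdname hydro_scale
#' @export
default_scale <- function() {
  v <- (.kd_raw - min(.kd_raw)) / (max(.kd_raw) - min(.kd_raw))
  hydro_scale(v, name = "kyte-doolittle-minmax")
}

#' Read a hydrophobicity scale from a two-column text file
#'
#' File format: whitespace-separated columns `<3-letter residue> <value>`,
#' `#` starts a comment. Values must already lie in \[0, 1\] unless
#' `normalize = TRUE`, in which case they are min--max rescaled.
#'
#' @param path Path to the scale file.
#' @param name Scale label; defaults to the file name.
#' @param normalize Min--max rescale the values to \[0, 1\].
#' @return A `hydro_scale`.
#' @export
read_hydro_scale <- function(path, name = basename(path), normalize = FALSE) {
  if (!file.exists(path)) stop("scale file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("resid", "value"),
                           colClasses = c("character", "numeric"))
  v <- tab$value
  names(v) <- toupper(tab$resid)
  if (anyDuplicated(names(v)))
    stop("duplicated residue names in scale file: ", path)
  if (normalize) v <- (v - min(v)) / (max(v) - min(v))
  hydro_scale(v, name = name)
}

#' @export
print.hydro_scale <- function(x, ...) {
  cat("Hydrophobicity scale:", x$name, "\n")
  print(round(x$values, 3))
  invisible(x)
}

# Intrinsic hydrophobicity for a vector of residue names. Unknown residue
# names (non-standard, unmapped HETATM parents) are an error unless a
# mapping resolves them first.
scale_lookup <- function(scale, resnames, mapping = NULL) {
  stopifnot(inherits(scale, "hydro_scale"))
  rn <- toupper(resnames)
  if (!is.null(mapping)) {
    hit <- rn %in% names(mapping)
    rn[hit] <- unname(mapping[rn[hit]])
  }
  unknown <- setdiff(unique(rn), names(scale$values))
  if (length(unknown))
    stop("residues not covered by scale '", scale$name, "': ",
         paste(unknown, collapse = ", "),
         " (supply a residue-name mapping for modified residues)")
  unname(scale$values[rn])
}
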