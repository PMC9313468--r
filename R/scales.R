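#' Intrinsic hydrophobicity scales
#'
#' The model evaluates every residue at an intrinsic hydrophobicity
#' \eqn{H^r \in [0,1]}. The default is the Kyte-Doolittle hydropathy index
#' min-max normalised to that range, \eqn{(h + 4.5)/9}, so ILE maps to 1 and
#' ARG to 0. Any named vector covering the 20 standard 3-letter codes with
#' values in \eqn{[0,1]} can be used instead (the scale is a required,
#' documented choice of every analysis: published absolute RD/K values depend
#' on it).
#'
#' @return Named numeric vector over the 20 standard residues.
#' @examples
#' s <- kyteDoolittleScale()
#' s[["ILE"]]  # 1
#' s[["ARG"]]  # 0
#' @export
kyteDoolittleScale <- function() {
  kd <- c(
    ILE =  4.5, VAL =  4.2, LEU =  3.8, PHE =  2.8, CYS =  2.5,
    MET =  1.9, ALA =  1.8, GLY = -0.4, THR = -0.7, SER = -0.8,
    TRP = -0.9, TYR = -1.3, PRO = -1.6, HIS = -3.2, GLU = -3.5,
    GLN = -3.5, ASP = -3.5, ASN = -3.5, LYS = -3.9, ARG = -4.5
  )
  (kd + 4.5) / 9
}

#' Default alias table for nonstandard residue names
#'
#' Maps common modified/nonstandard 3-letter codes to the standard residue
#' whose scale value they take (e.g. selenomethionine to MET). Used by
#' [assignScale()]; residues found in neither the scale nor the alias table
#' raise a coverage error.
#'
#' @return Named character vector (alias -> standard code).
#' @export
defaultAliases <- function() {
  c(MSE = "MET", SEC = "CYS", PYL = "LYS", HYP = "PRO",
    CSO = "CYS", SEP = "SER", TPO = "THR", PTR = "TYR", MLY = "LYS")
}

standardResidues <- function() names(kyteDoolittleScale())

checkScale <- function(scale) {
  if (is.null(names(scale)) || !is.numeric(scale))
    stop("scale must be a named numeric vector of 3-letter codes")
  missing <- setdiff(standardResidues(), names(scale))
  if (length(missing))
    stop("scale does not cover the 20 standard residues; missing: ",
         paste(missing, collapse = ", "))
  if (any(scale < 0 | scale > 1))
    stop("scale values must lie in [0, 1]")
  invisible(scale)
}
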