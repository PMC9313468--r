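#' @import methods
NULL

## Central S4 containers. Residue-level data are kept as plain data.frames
## inside the objects (one row per residue or per atom); accessors below are
## the supported interface, slots are internal.

#' FodStructure: a parsed macromolecular structure
#'
#' Holds the polymer heavy atoms, per-residue effective atoms (the mean heavy
#' atom position at which all hydrophobicity fields are evaluated), ligand
#' (het-group) atoms, disulfide bonds and beta-sheet ranges of one deposited
#' or synthetic structure. Waters are discarded at parse time; ions and other
#' non-polymer components are ligands, never residues.
#'
#' @slot atoms data.frame of polymer heavy atoms: chain, resno, resid, elety,
#'   x, y, z.
#' @slot residues data.frame with one row per resolved residue: chain, resno
#'   (author numbering), resid (3-letter code), x, y, z (effective atom, A),
#'   h (intrinsic hydrophobicity in [0,1]; NA until [assignScale()]).
#' @slot ligands data.frame of het-group heavy atoms: name, chain, resno,
#'   x, y, z.
#' @slot ssBonds data.frame of cysteine pairs: chain1, resno1, chain2, resno2.
#' @slot sheets data.frame of beta-strand ranges: chain, start, end.
#' @slot sourceId character label (e.g. a PDB accession or generator tag).
#' @export
setClass("FodStructure",
  representation(
    atoms = "data.frame",
    residues = "data.frame",
    ligands = "data.frame",
    ssBonds = "data.frame",
    sheets = "data.frame",
    sourceId = "character"
  )
)

setValidity("FodStructure", function(object) {
  msg <- character()
  need <- c("chain", "resno", "resid", "x", "y", "z", "h")
  if (!all(need %in% names(object@residues)))
    msg <- c(msg, "residues must have columns chain, resno, resid, x, y, z, h")
  if (nrow(object@residues) == 0L)
    msg <- c(msg, "structure contains no polymer residues")
  if (nrow(object@ssBonds) > 0L) {
    cys <- paste(object@residues$chain, object@residues$resno)
    ok <- paste(object@ssBonds$chain1, object@ssBonds$resno1) %in% cys &
      paste(object@ssBonds$chain2, object@ssBonds$resno2) %in% cys
    if (!all(ok)) msg <- c(msg, "ss bond members must be residues of the structure")
  }
  ## residues within a chain ordered by author number
  spl <- split(object@residues$resno, object@residues$chain)
  if (!all(vapply(spl, function(v) !is.unsorted(v, strictly = TRUE), logical(1))))
    msg <- c(msg, "residues must be strictly ordered by resno within each chain")
  if (length(msg)) msg else TRUE
})

#' StructureUnit: the residue set spanned by one Gaussian field
#'
#' An ordered residue list (whole complex, single chain, or fragment) with
#' contiguous sequential indices 1..N. Sequential indices ignore gaps in the
#' author numbering: unresolved positions are simply absent, and profile plots
#' are indexed by position in the unit, not by deposition numbering.
#'
#' @slot residues data.frame: seqIndex (1..N), chain, resno, resid, x, y, z, h.
#' @slot label character label of the unit.
#' @export
setClass("StructureUnit",
  representation(residues = "data.frame", label = "character")
)

setValidity("StructureUnit", function(object) {
  r <- object@residues
  if (nrow(r) < 2L) return("a structural unit needs at least 2 residues")
  if (!identical(r$seqIndex, seq_len(nrow(r))))
    return("seqIndex must be contiguous 1..N")
  key <- paste(r$chain, r$resno)
  if (anyDuplicated(key)) return("(chain, resno) pairs must be unique")
  TRUE
})

#' GaussianField: the fitted 3D Gaussian of the theoretical distribution
#'
#' @slot center numeric(3), field centre in A.
#' @slot axes 3x3 matrix whose columns are the right-handed orthonormal
#'   principal axes of the effective-atom cloud (descending variance).
#' @slot sigmas numeric(3), strictly positive standard deviations (A) along
#'   the axes.
#' @export
setClass("GaussianField",
  representation(center = "numeric", axes = "matrix", sigmas = "numeric")
)

setValidity("GaussianField", function(object) {
  if (length(object@center) != 3L) return("center must be length 3")
  if (!all(dim(object@axes) == c(3L, 3L))) return("axes must be 3x3")
  if (any(object@sigmas <= 0)) return("sigmas must be strictly positive")
  if (max(abs(crossprod(object@axes) - diag(3))) > 1e-8)
    return("axes must be orthonormal")
  if (det(object@axes) < 0) return("axes must form a right-handed basis")
  TRUE
})

#' HydroProfile: a normalised per-residue hydrophobicity distribution
#'
#' One of the four distributions of the model: theoretical T (3D Gaussian),
#' observed O (pairwise aggregation), uniform reference R, or membrane-modified
#' M(K). Values are non-negative and sum to 1.
#'
#' @slot values numeric, one value per residue of the unit.
#' @slot kind one of "T", "O", "R", "M".
#' @slot unitLabel label of the unit the profile belongs to.
#' @slot k the membrane-participation coefficient (only meaningful for
#'   kind "M"; NA otherwise).
#' @export
setClass("HydroProfile",
  representation(values = "numeric", kind = "character",
                 unitLabel = "character", k = "numeric")
)

setValidity("HydroProfile", function(object) {
  if (!object@kind %in% c("T", "O", "R", "M")) return("kind must be T, O, R or M")
  if (length(object@values) < 1L) return("empty profile")
  if (any(object@values < 0)) return("profile values must be non-negative")
  if (abs(sum(object@values) - 1) > 1e-9) return("profile must sum to 1")
  if (object@kind == "M" && is.na(object@k)) return("M profile requires k")
  TRUE
})

#' FodResult: divergence statistics for one unit or residue subset
#'
#' @slot unitLabel,subsetLabel labels of the scored unit and subset.
#' @slot n number of residues entering the statistics.
#' @slot dklOT Kullback-Leibler divergence D_KL(O|T), bits.
#' @slot dklOR D_KL(O|R), bits.
#' @slot dklOM D_KL(O|M(K_opt)), bits.
#' @slot rd relative distance D_KL(O|T) / (D_KL(O|T) + D_KL(O|R)); values
#'   below 0.5 indicate a centric hydrophobic core.
#' @slot kOpt grid-optimal membrane coefficient K.
#' @slot rdKopt relative distance with M(K_opt) replacing R.
#' @export
setClass("FodResult",
  representation(unitLabel = "character", subsetLabel = "character",
                 n = "integer", dklOT = "numeric", dklOR = "numeric",
                 dklOM = "numeric", rd = "numeric", kOpt = "numeric",
                 rdKopt = "numeric")
)

setValidity("FodResult", function(object) {
  if (!is.na(object@rd) && (object@rd < 0 || object@rd > 1))
    return("rd must lie in [0, 1]")
  if (!is.na(object@kOpt) && object@kOpt < 0) return("kOpt must be >= 0")
  TRUE
})

#' SubsetSpec: a labelled residue subset of a unit
#'
#' @slot label subset label (e.g. "P-P", "No P-P", "SS:1", "zone:membrane",
#'   "sheet:2", "custom").
#' @slot mask integer sequential indices (into the unit) of the subset.
#' @slot params list of the thresholds/settings that produced the mask.
#' @export
setClass("SubsetSpec",
  representation(label = "character", mask = "integer", params = "list")
)

#' FodReport: the output of one pipeline run
#'
#' @slot label run label.
#' @slot results data.frame of per-unit and per-subset statistics.
#' @slot profiles named list (by unit label) of profile data.frames.
#' @slot decisions character log of every default/threshold the run relied on.
#' @slot inputHash named character, md5 of each input file.
#' @export
setClass("FodReport",
  representation(label = "character", results = "data.frame",
                 profiles = "list", decisions = "character",
                 inputHash = "character")
)

## ---- show methods -------------------------------------------------------

setMethod("show", "FodStructure", function(object) {
  ch <- table(object@residues$chain)
  cat("FodStructure", sQuote(object@sourceId), "\n")
  cat(" ", length(ch), "chain(s):",
      paste(sprintf("%s (%d aa)", names(ch), as.integer(ch)), collapse = ", "), "\n")
  nl <- length(unique(paste(object@ligands$chain, object@ligands$resno,
                            object@ligands$name)))
  cat(" ", nl, "ligand(s),", nrow(object@ssBonds), "disulfide bond(s),",
      nrow(object@sheets), "sheet range(s)\n")
  cat("  hydrophobicity scale:",
      if (all(is.na(object@residues$h))) "not assigned" else "assigned", "\n")
})

setMethod("show", "StructureUnit", function(object) {
  cat("StructureUnit", sQuote(object@label), "with",
      nrow(object@residues), "residues over",
      length(unique(object@residues$chain)), "chain(s)\n")
})

setMethod("show", "GaussianField", function(object) {
  cat("GaussianField: center (",
      paste(sprintf("%.2f", object@center), collapse = ", "),
      ") A; sigma (", paste(sprintf("%.2f", object@sigmas), collapse = ", "),
      ") A\n", sep = "")
})

setMethod("show", "HydroProfile", function(object) {
  cat("HydroProfile ", object@kind,
      if (object@kind == "M") sprintf(" (K = %.2f)", object@k) else "",
      ": N = ", length(object@values),
      ", unit ", sQuote(object@unitLabel), "\n", sep = "")
})

setMethod("show", "FodResult", function(object) {
  cat(sprintf("FodResult %s / %s (N = %d)\n", object@unitLabel,
              object@subsetLabel, object@n))
  cat(sprintf("  RD = %.3f  K_opt = %.1f  RD_Kopt = %.3f\n",
              object@rd, object@kOpt, object@rdKopt))
  cat(sprintf("  D_KL(O|T) = %.4f  D_KL(O|R) = %.4f  D_KL(O|M) = %.4f bits\n",
              object@dklOT, object@dklOR, object@dklOM))
  cat("  hydrophobic core:", if (!is.na(object@rd) && object@rd < 0.5)
    "present (RD < 0.5)" else "absent (RD >= 0.5)", "\n")
})

setMethod("show", "SubsetSpec", function(object) {
  cat("SubsetSpec", sQuote(object@label), "with", length(object@mask),
      "residues\n")
})

setMethod("show", "FodReport", function(object) {
  cat("FodReport", sQuote(object@label), "\n")
  cat(" ", nrow(object@results), "result rows,", length(object@profiles),
      "profile table(s)\n")
})
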