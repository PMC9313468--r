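#' @include AllClasses.R
NULL

#' Accessors for fodm objects
#'
#' Small accessor generics for the S4 containers; prefer these over direct
#' slot access.
#'
#' @param x a fodm object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))
#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))
#' @rdname accessors
#' @export
setGeneric("unitLabel", function(x) standardGeneric("unitLabel"))
#' @rdname accessors
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))
#' @rdname accessors
#' @export
setGeneric("ligands", function(x) standardGeneric("ligands"))
#' @rdname accessors
#' @export
setGeneric("ssBonds", function(x) standardGeneric("ssBonds"))
#' @rdname accessors
#' @export
setGeneric("sheetRanges", function(x) standardGeneric("sheetRanges"))
#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setGeneric("profileKind", function(x) standardGeneric("profileKind"))
#' @rdname accessors
#' @export
setGeneric("membraneK", function(x) standardGeneric("membraneK"))
#' @rdname accessors
#' @export
setGeneric("subsetMask", function(x) standardGeneric("subsetMask"))
#' @rdname accessors
#' @export
setGeneric("subsetLabel", function(x) standardGeneric("subsetLabel"))

#' @rdname accessors
#' @export
setMethod("residues", "FodStructure", function(x) x@residues)
#' @rdname accessors
#' @export
setMethod("residues", "StructureUnit", function(x) x@residues)
#' @rdname accessors
#' @export
setMethod("nResidues", "FodStructure", function(x) nrow(x@residues))
#' @rdname accessors
#' @export
setMethod("nResidues", "StructureUnit", function(x) nrow(x@residues))
#' @rdname accessors
#' @export
setMethod("unitLabel", "StructureUnit", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("unitLabel", "HydroProfile", function(x) x@unitLabel)
#' @rdname accessors
#' @export
setMethod("sourceId", "FodStructure", function(x) x@sourceId)
#' @rdname accessors
#' @export
setMethod("ligands", "FodStructure", function(x) x@ligands)
#' @rdname accessors
#' @export
setMethod("ssBonds", "FodStructure", function(x) x@ssBonds)
#' @rdname accessors
#' @export
setMethod("sheetRanges", "FodStructure", function(x) x@sheets)
#' @rdname accessors
#' @export
setMethod("profileValues", "HydroProfile", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("profileKind", "HydroProfile", function(x) x@kind)
#' @rdname accessors
#' @export
setMethod("membraneK", "HydroProfile", function(x) x@k)
#' @rdname accessors
#' @export
setMethod("subsetMask", "SubsetSpec", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("subsetLabel", "SubsetSpec", function(x) x@label)

#' Length of a profile or subset
#' @param x a [HydroProfile-class] or [SubsetSpec-class].
#' @export
setMethod("length", "HydroProfile", function(x) length(x@values))
#' @rdname length-HydroProfile-method
#' @export
setMethod("length", "SubsetSpec", function(x) length(x@mask))

#' Coerce a FodResult (or list of them) to a one-row-per-result data.frame
#'
#' Columns: unit_label, subset_label, n, rd, k_opt, rd_kopt, dkl_ot, dkl_or,
#' dkl_om -- the machine-readable form of the result tables.
#'
#' @param x a [FodResult-class] or a list of them.
#' @return data.frame.
#' @export
resultsTable <- function(x) {
  if (methods::is(x, "FodResult")) x <- list(x)
  stopifnot(all(vapply(x, methods::is, logical(1), "FodResult")))
  do.call(rbind, lapply(x, function(r) {
    data.frame(unit_label = r@unitLabel, subset_label = r@subsetLabel,
               n = r@n, rd = r@rd, k_opt = r@kOpt, rd_kopt = r@rdKopt,
               dkl_ot = r@dklOT, dkl_or = r@dklOR, dkl_om = r@dklOM,
               stringsAsFactors = FALSE)
  }))
}
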