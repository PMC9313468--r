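#' @include AllClasses.R
NULL

newSubset <- function(label, mask, params = list()) {
  methods::new("SubsetSpec", label = label,
               mask = sort(unique(as.integer(mask))), params = params)
}

## heavy atoms of the unit's residues, tagged with the unit's seqIndex
unitAtoms <- function(structure, unit) {
  at <- structure@atoms
  key <- paste(at$chain, at$resno)
  ukey <- paste(unit@residues$chain, unit@residues$resno)
  idx <- match(key, ukey)
  at <- at[!is.na(idx), , drop = FALSE]
  at$seqIndex <- idx[!is.na(idx)]
  at
}

## residues of `unit` with any heavy atom within `cutoff` of `targetXyz`;
## a coarse effective-atom prefilter keeps the atom-level check small
contactMask <- function(structure, unit, targetXyz, cutoff, prefilterPad = 12) {
  if (nrow(targetXyz) == 0L) return(integer())
  ua <- unitAtoms(structure, unit)
  eff <- as.matrix(unit@residues[, c("x", "y", "z")])
  tg <- as.matrix(targetXyz)
  hits <- integer()
  for (i in seq_len(nrow(eff))) {
    d2 <- colSums((t(tg) - eff[i, ])^2)
    if (min(d2) > (cutoff + prefilterPad)^2) next
    near <- tg[d2 <= (cutoff + prefilterPad)^2, , drop = FALSE]
    ai <- as.matrix(ua[ua$seqIndex == i, c("x", "y", "z"), drop = FALSE])
    dmin <- min(vapply(seq_len(nrow(ai)),
                       function(k) min(colSums((t(near) - ai[k, ])^2)),
                       numeric(1)))
    if (dmin <= cutoff^2) hits <- c(hits, i)
  }
  hits
}

#' Inter-chain interface residues (P-P) and their complement
#'
#' A residue is part of the protein-protein interface iff any of its heavy
#' atoms lies within `cutoff` of a heavy atom belonging to a different chain
#' of the unit. The 5 A heavy-atom default spans hydrogen bonds and van der
#' Waals contacts. The two subsets partition the unit exactly.
#'
#' @param structure the [FodStructure-class] the unit was built from.
#' @param unit a [StructureUnit-class].
#' @param cutoff heavy-atom contact distance in A (default 5).
#' @return list with elements `pp` and `noPp` ([SubsetSpec-class], labels
#'   "P-P" and "No P-P"). A single-chain unit gives an empty interface with
#'   a warning.
#' @export
interchainInterface <- function(structure, unit, cutoff = 5.0) {
  res <- unit@residues
  params <- list(cutoff = cutoff)
  if (length(unique(structure@residues$chain)) < 2L) {
    warning("single-chain structure: interface is empty")
    return(list(pp = newSubset("P-P", integer(), params),
                noPp = newSubset("No P-P", res$seqIndex, params)))
  }
  ## partners are the other chains of the whole structure, so a single-chain
  ## unit is scored against its neighbours in the assembly
  at <- structure@atoms
  hits <- integer()
  for (ch in unique(res$chain)) {
    sub <- makeUnitSubsetChain(unit, ch)
    other <- at[at$chain != ch, c("x", "y", "z"), drop = FALSE]
    m <- contactMask(structure, sub$unitView, other, cutoff)
    hits <- c(hits, sub$origIndex[m])
  }
  pp <- sort(unique(hits))
  list(pp = newSubset("P-P", pp, params),
       noPp = newSubset("No P-P", setdiff(res$seqIndex, pp), params))
}

## a chain's residues presented as a pseudo-unit view + their original indices
makeUnitSubsetChain <- function(unit, chain) {
  keep <- unit@residues$chain == chain
  r <- unit@residues[keep, , drop = FALSE]
  orig <- r$seqIndex
  r$seqIndex <- seq_len(nrow(r))
  rownames(r) <- NULL
  u <- methods::new("StructureUnit", residues = r, label = unit@label)
  list(unitView = u, origIndex = orig)
}

#' Ligand-contact residues (P-Ligand) and their complement
#'
#' A residue is in contact with a ligand iff any heavy atom lies within
#' `cutoff` of any heavy atom of a (optionally name-filtered) ligand.
#' For membrane channels the typical ligands are the membrane-mimicking
#' lipids/detergents of the deposition.
#'
#' @param structure the [FodStructure-class].
#' @param unit a [StructureUnit-class].
#' @param cutoff heavy-atom contact distance in A (default 5).
#' @param ligandNames optional character filter on ligand component codes.
#' @return list with elements `pLigand` and `noLigand`
#'   ([SubsetSpec-class], labels "P-Ligand" and "No Ligand"). No ligands
#'   gives an empty contact set with a warning.
#' @export
ligandContacts <- function(structure, unit, cutoff = 5.0, ligandNames = NULL) {
  res <- unit@residues
  params <- list(cutoff = cutoff, ligandNames = ligandNames)
  lig <- structure@ligands
  if (!is.null(ligandNames)) lig <- lig[lig$name %in% ligandNames, , drop = FALSE]
  if (nrow(lig) == 0L) {
    warning("no ligands ", if (!is.null(ligandNames)) "matching the filter ",
            "in the structure: P-Ligand is empty")
    hits <- integer()
  } else {
    hits <- contactMask(structure, unit, lig[, c("x", "y", "z")], cutoff)
  }
  list(pLigand = newSubset("P-Ligand", hits, params),
       noLigand = newSubset("No Ligand", setdiff(res$seqIndex, hits), params))
}

#' Disulfide-delimited segments
#'
#' For every disulfide bond whose two cysteines are both in the unit, the
#' segment is the contiguous sequential-index interval between them
#' (inclusive) -- the stretch of chain the bond closes. One subset per bond,
#' ordered by start index.
#'
#' @param structure the [FodStructure-class] (source of the bonds).
#' @param unit a [StructureUnit-class].
#' @return list of [SubsetSpec-class] labelled "SS:1", "SS:2", ...; empty
#'   list when the structure has no disulfides. Bonds with a member outside
#'   the unit are skipped with a warning.
#' @export
ssSegments <- function(structure, unit) {
  b <- structure@ssBonds
  if (!nrow(b)) return(list())
  key <- paste(unit@residues$chain, unit@residues$resno)
  segs <- list()
  for (i in seq_len(nrow(b))) {
    i1 <- match(paste(b$chain1[i], b$resno1[i]), key)
    i2 <- match(paste(b$chain2[i], b$resno2[i]), key)
    if (is.na(i1) || is.na(i2)) {
      warning("disulfide ", b$chain1[i], b$resno1[i], "-", b$chain2[i],
              b$resno2[i], " spans outside the unit; skipped")
      next
    }
    segs[[length(segs) + 1L]] <- range(c(i1, i2))
  }
  if (!length(segs)) return(list())
  segs <- segs[order(vapply(segs, `[`, numeric(1), 1))]
  lapply(seq_along(segs), function(k) {
    newSubset(paste0("SS:", k), seq(segs[[k]][1], segs[[k]][2]),
              list(bond = segs[[k]]))
  })
}

#' Membrane / cytoplasmic / external zone assignment
#'
#' Assigns each residue to one of three zones by projecting its effective
#' atom onto the membrane normal: inside the slab \[zLo, zHi\] -> membrane;
#' beyond the slab on the external side -> external; otherwise cytoplasmic.
#' The slab is a required configuration input -- membrane placement is a
#' judgement made on the structure, not something inferred automatically.
#' The three masks are pairwise disjoint and cover the unit.
#'
#' @param unit a [StructureUnit-class].
#' @param axis numeric(3) membrane normal (normalised internally); default
#'   the z axis.
#' @param zLo,zHi slab bounds (A) along the axis, zLo < zHi.
#' @param externalSide "+" if the extracellular side is at projections
#'   above zHi, "-" if below zLo.
#' @return list with elements `cytoplasmic`, `membrane`, `external`
#'   ([SubsetSpec-class], labels "zone:...").
#' @export
zoneAssignment <- function(unit, axis = c(0, 0, 1), zLo, zHi,
                           externalSide = c("+", "-")) {
  externalSide <- match.arg(externalSide)
  if (zLo >= zHi) stop("config error: zLo must be < zHi")
  axis <- axis / sqrt(sum(axis^2))
  proj <- as.matrix(unit@residues[, c("x", "y", "z")]) %*% axis
  inSlab <- proj >= zLo & proj <= zHi
  ext <- if (externalSide == "+") proj > zHi else proj < zLo
  cyt <- !inSlab & !ext
  params <- list(axis = axis, zLo = zLo, zHi = zHi, externalSide = externalSide)
  idx <- unit@residues$seqIndex
  list(cytoplasmic = newSubset("zone:cytoplasmic", idx[cyt], params),
       membrane = newSubset("zone:membrane", idx[inSlab], params),
       external = newSubset("zone:external", idx[ext], params))
}

#' Beta-sheet strand segments and their union
#'
#' One subset per beta strand (from deposited SHEET annotations, or from an
#' explicit override of residue ranges) plus the union of all strands -- the
#' whole-sheet row of the result tables. No secondary structure is
#' recomputed: deposited annotations or the override only.
#'
#' @param structure the [FodStructure-class].
#' @param unit a [StructureUnit-class].
#' @param override optional data.frame with columns chain, start, end
#'   (author numbering, inclusive) replacing the deposited annotation.
#' @return list of [SubsetSpec-class]: "sheet:1", ..., plus "sheet:union".
#' @export
sheetSegments <- function(structure, unit, override = NULL) {
  src <- if (!is.null(override)) {
    override <- as.data.frame(override)
    stopifnot(all(c("chain", "start", "end") %in% names(override)))
    override
  } else structure@sheets
  if (is.null(src) || nrow(src) == 0L)
    stop("no SHEET annotation in the structure and no override given")
  res <- unit@residues
  strands <- list()
  for (i in seq_len(nrow(src))) {
    m <- res$seqIndex[res$chain == src$chain[i] &
                      res$resno >= src$start[i] & res$resno <= src$end[i]]
    if (length(m)) strands[[length(strands) + 1L]] <- m
  }
  if (!length(strands))
    stop("no sheet strand overlaps the unit")
  out <- lapply(seq_along(strands), function(k)
    newSubset(paste0("sheet:", k), strands[[k]], list(range = src[k, ])))
  out$union <- newSubset("sheet:union", unlist(strands), list(src = src))
  out
}
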