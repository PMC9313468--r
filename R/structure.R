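#' @include AllClasses.R
NULL

WATER_NAMES <- c("HOH", "DOD", "WAT", "H2O")

#' Effective atom of a residue
#'
#' The effective atom is the unweighted arithmetic mean of a residue's heavy
#' atom coordinates; every hydrophobicity field in the model is evaluated at
#' this single point. Hydrogens are excluded upstream at parse time.
#'
#' @param coords numeric matrix with one row per heavy atom and columns
#'   x, y, z (Angstrom).
#' @return numeric(3) coordinate.
#' @examples
#' effectiveAtom(rbind(c(0, 0, 0), c(2, 0, 0)))  # (1, 0, 0)
#' @export
effectiveAtom <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0L)
    stop("degenerate residue: no heavy atoms")
  if (ncol(coords) != 3L) stop("coords must have 3 columns")
  colMeans(coords)
}

isHydrogen <- function(elety, elesy = NULL) {
  if (!is.null(elesy)) {
    known <- !is.na(elesy) & nzchar(trimws(elesy))
    out <- rep(NA, length(elety))
    out[known] <- trimws(elesy[known]) %in% c("H", "D")
    miss <- !known
  } else {
    out <- rep(NA, length(elety))
    miss <- rep(TRUE, length(elety))
  }
  out[miss] <- grepl("^[0-9]*[HD]", trimws(elety[miss]))
  out
}

parseSsbondRecords <- function(lines) {
  ss <- lines[startsWith(lines, "SSBOND")]
  if (!length(ss)) {
    return(data.frame(chain1 = character(), resno1 = integer(),
                      chain2 = character(), resno2 = integer(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    chain1 = trimws(substr(ss, 16, 16)),
    resno1 = as.integer(trimws(substr(ss, 18, 21))),
    chain2 = trimws(substr(ss, 30, 30)),
    resno2 = as.integer(trimws(substr(ss, 32, 35))),
    stringsAsFactors = FALSE
  )
}

## geometric disulfide detection: CYS SG-SG pairs within maxDist
detectSsBonds <- function(atoms, maxDist = 2.5) {
  sg <- atoms[atoms$resid %in% c("CYS", "SEC") & trimws(atoms$elety) %in% c("SG", "SE"), ]
  out <- data.frame(chain1 = character(), resno1 = integer(),
                    chain2 = character(), resno2 = integer(),
                    stringsAsFactors = FALSE)
  if (nrow(sg) < 2L) return(out)
  d <- as.matrix(stats::dist(sg[, c("x", "y", "z")]))
  idx <- which(upper.tri(d) & d <= maxDist, arr.ind = TRUE)
  if (!nrow(idx)) return(out)
  data.frame(chain1 = sg$chain[idx[, 1]], resno1 = sg$resno[idx[, 1]],
             chain2 = sg$chain[idx[, 2]], resno2 = sg$resno[idx[, 2]],
             stringsAsFactors = FALSE)
}

normalizeBonds <- function(b) {
  if (!nrow(b)) return(b)
  flip <- b$chain2 < b$chain1 | (b$chain1 == b$chain2 & b$resno2 < b$resno1)
  b[flip, c("chain1", "resno1", "chain2", "resno2")] <-
    b[flip, c("chain2", "resno2", "chain1", "resno1")]
  b <- b[b$chain1 != b$chain2 | b$resno1 != b$resno2, , drop = FALSE]
  unique(b)
}

#' Load a protein structure from PDB or mmCIF
#'
#' Parses a structure file into a [FodStructure-class]: polymer residues with
#' their heavy atoms and effective atoms, ligands (every non-water het group,
#' ions included), disulfide bonds, and beta-sheet ranges. Hydrogens are
#' dropped, waters discarded, and for alternate locations only the
#' highest-occupancy conformer is kept so every residue has a single
#' effective atom. Disulfides come from SSBOND records where the format
#' carries them, supplemented by any cysteine SG-SG pair within `ssMaxDist`.
#' Unresolved residues are never imputed; downstream profiles run over the
#' resolved residues with contiguous sequential indexing.
#'
#' @param path file path.
#' @param format "pdb", "mmcif" or "auto" (by extension, default).
#' @param aliases named character vector mapping nonstandard residue codes to
#'   the standard residue they should be treated as (kept as polymer even when
#'   deposited as HETATM). See [defaultAliases()].
#' @param ssMaxDist geometric fallback distance (A) for disulfide detection.
#' @return A [FodStructure-class].
#' @export
loadStructure <- function(path, format = c("auto", "pdb", "mmcif"),
                          aliases = defaultAliases(), ssMaxDist = 2.5) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE,
                                          verbose = FALSE)),
    error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- parsed$atom
  at$elety <- trimws(at$elety)
  at$resid <- trimws(at$resid)
  at$chain[is.na(at$chain) | !nzchar(trimws(at$chain))] <- "A"
  at$o[is.na(at$o)] <- 1

  at <- at[!isHydrogen(at$elety, at$elesy), , drop = FALSE]
  at <- at[!at$resid %in% WATER_NAMES, , drop = FALSE]

  ## alternate locations: highest occupancy, then alt label for determinism
  altkey <- paste(at$chain, at$resno, at$resid, at$elety)
  ord <- order(match(altkey, unique(altkey)), -at$o, as.character(at$alt))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$resid, at$elety)), ,
           drop = FALSE]

  polymer <- at$type == "ATOM" | at$resid %in% names(aliases)
  pat <- at[polymer, c("chain", "resno", "resid", "elety", "x", "y", "z")]
  lat <- at[!polymer, c("resid", "chain", "resno", "x", "y", "z")]
  names(lat)[1] <- "name"

  if (!nrow(pat)) stop("empty structure: no polymer residues in ", path)

  ## order chain-by-chain (file order), then by author residue number
  chainOrder <- unique(pat$chain)
  pat <- pat[order(match(pat$chain, chainOrder), pat$resno), , drop = FALSE]
  rkey <- paste(pat$chain, pat$resno)
  eff <- do.call(rbind, lapply(split(seq_len(nrow(pat)),
                                     match(rkey, unique(rkey))), function(i) {
    data.frame(chain = pat$chain[i[1]], resno = pat$resno[i[1]],
               resid = pat$resid[i[1]],
               x = mean(pat$x[i]), y = mean(pat$y[i]), z = mean(pat$z[i]),
               stringsAsFactors = FALSE)
  }))
  eff$h <- NA_real_
  rownames(eff) <- NULL
  rownames(pat) <- NULL
  rownames(lat) <- NULL

  bonds <- detectSsBonds(pat, ssMaxDist)
  if (format == "pdb") {
    rec <- tryCatch(parseSsbondRecords(readLines(path, warn = FALSE)),
                    error = function(e) NULL)
    if (!is.null(rec) && nrow(rec)) bonds <- rbind(rec, bonds)
  }
  bonds <- normalizeBonds(bonds)
  if (nrow(bonds)) {
    present <- paste(bonds$chain1, bonds$resno1) %in% rkey &
      paste(bonds$chain2, bonds$resno2) %in% rkey
    bonds <- bonds[present, , drop = FALSE]
  }

  sheets <- data.frame(chain = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)
  sh <- parsed$sheet
  if (!is.null(sh) && length(sh$start)) {
    sheets <- data.frame(chain = as.character(sh$chain),
                         start = as.integer(sh$start),
                         end = as.integer(sh$end), stringsAsFactors = FALSE)
  }

  methods::new("FodStructure", atoms = pat, residues = eff, ligands = lat,
               ssBonds = bonds, sheets = sheets,
               sourceId = sub("\\.(pdb|ent|cif|mmcif)$", "",
                              basename(path), ignore.case = TRUE))
}

#' Write a structure as a PDB file
#'
#' Writes polymer atoms (ATOM) and ligand atoms (HETATM), with optional
#' REMARK header lines (used by the synthetic generators to record their
#' provenance). Output is deterministic for identical input.
#'
#' @param structure a [FodStructure-class].
#' @param path output file.
#' @param remarks character vector of header comment lines (written as
#'   REMARK 999 records).
#' @return `path`, invisibly.
#' @export
writeStructurePDB <- function(structure, path, remarks = character()) {
  pa <- structure@atoms
  la <- structure@ligands
  n <- nrow(pa) + nrow(la)
  xyz <- c(t(as.matrix(rbind(pa[, c("x", "y", "z")], la[, c("x", "y", "z")]))))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = c(rep("ATOM", nrow(pa)), rep("HETATM", nrow(la))),
    resno = c(pa$resno, la$resno),
    resid = c(pa$resid, la$name),
    chain = c(pa$chain, la$chain),
    elety = c(pa$elety, rep("C1", nrow(la))),
    eleno = seq_len(n), o = rep(1, n), b = rep(0, n))
  if (length(remarks)) {
    body <- readLines(path, warn = FALSE)
    writeLines(c(sprintf("REMARK 999 %s", remarks), body), path)
  }
  invisible(path)
}

#' Build a structural unit
#'
#' A structural unit is the ordered residue set over which one 3D Gaussian
#' field is spanned: the whole complex (default), a chain subset, or residue
#' ranges. Residues are ordered chain-by-chain and then by author number, and
#' re-indexed contiguously 1..N (deposition gaps do not create index gaps).
#'
#' @param structure a [FodStructure-class].
#' @param chains optional character vector of chain ids.
#' @param ranges optional data.frame with columns chain, start, end (author
#'   numbering, inclusive) selecting residue ranges.
#' @param label unit label; a default is derived from the selection.
#' @return A [StructureUnit-class].
#' @export
makeUnit <- function(structure, chains = NULL, ranges = NULL, label = NULL) {
  res <- structure@residues
  keep <- rep(TRUE, nrow(res))
  if (!is.null(chains)) {
    unknown <- setdiff(chains, unique(res$chain))
    if (length(unknown))
      stop("selection error: no such chain(s): ", paste(unknown, collapse = ", "))
    keep <- keep & res$chain %in% chains
  }
  if (!is.null(ranges)) {
    ranges <- as.data.frame(ranges)
    stopifnot(all(c("chain", "start", "end") %in% names(ranges)))
    inAny <- rep(FALSE, nrow(res))
    for (i in seq_len(nrow(ranges))) {
      inAny <- inAny | (res$chain == ranges$chain[i] &
                        res$resno >= ranges$start[i] &
                        res$resno <= ranges$end[i])
    }
    keep <- keep & inAny
  }
  sel <- res[keep, , drop = FALSE]
  if (nrow(sel) == 0L) stop("selection error: selector matched no residues")
  if (nrow(sel) < 2L) stop("selection error: a unit needs at least 2 residues")
  sel <- sel[order(match(sel$chain, unique(res$chain)), sel$resno), , drop = FALSE]
  sel <- cbind(seqIndex = seq_len(nrow(sel)), sel)
  rownames(sel) <- NULL
  if (is.null(label)) {
    label <- if (is.null(chains) && is.null(ranges)) "complex"
    else if (!is.null(chains) && is.null(ranges))
      paste0("chain_", paste(chains, collapse = ""))
    else "selection"
  }
  methods::new("StructureUnit", residues = sel, label = label)
}

#' Sequential index map of a unit
#'
#' The bijection between sequential indices 1..N and (chain, author residue
#' number) pairs of a unit.
#'
#' @param unit a [StructureUnit-class].
#' @return data.frame with columns seqIndex, chain, resno.
#' @export
indexMap <- function(unit) {
  unit@residues[, c("seqIndex", "chain", "resno")]
}

#' Assign an intrinsic hydrophobicity scale
#'
#' Sets every residue's intrinsic hydrophobicity from a named scale over the
#' 3-letter codes; nonstandard residues are resolved through the alias table
#' first. Any residue covered by neither raises a coverage error: unknown
#' chemistry must be an explicit decision, not a silent default.
#'
#' @param structure a [FodStructure-class].
#' @param scale named numeric vector covering the 20 standard residues,
#'   values in \[0,1\]. Default [kyteDoolittleScale()].
#' @param aliases named character vector, nonstandard -> standard code.
#' @return The structure with intrinsic hydrophobicities assigned.
#' @export
assignScale <- function(structure, scale = kyteDoolittleScale(),
                        aliases = defaultAliases()) {
  checkScale(scale)
  nm <- structure@residues$resid
  resolved <- ifelse(nm %in% names(scale), nm,
                     unname(aliases[match(nm, names(aliases))]))
  bad <- is.na(resolved) | !(resolved %in% names(scale))
  if (any(bad))
    stop("scale-coverage error: residue name(s) not in scale or alias table: ",
         paste(unique(nm[bad]), collapse = ", "))
  structure@residues$h <- unname(scale[resolved])
  structure
}
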