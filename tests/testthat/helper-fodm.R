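## shared fixtures and independent oracles; everything is built in code

## minimal StructureUnit from coordinates and intrinsic hydrophobicities
mkUnit <- function(xyz, h = rep(0.5, nrow(xyz)), chain = "A",
                   label = "toy") {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  res <- data.frame(seqIndex = seq_len(n),
                    chain = rep_len(chain, n),
                    resno = stats::ave(seq_len(n), rep_len(chain, n),
                                       FUN = seq_along),
                    resid = "ALA", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    h = h, stringsAsFactors = FALSE)
  methods::new("StructureUnit", residues = res, label = label)
}

## naive double-loop evaluation of the observed distribution, straight from
## the printed pairwise formula; deliberately independent of the package path
oracleObserved <- function(unit, cutoff = 9, exponent = 8) {
  r <- residues(unit)
  n <- nrow(r)
  xyz <- as.matrix(r[, c("x", "y", "z")])
  raw <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      rij <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (rij > cutoff) next
      x <- rij / cutoff
      w <- 1 - 0.5 * (7 * x^2 - 9 * x^4 + 5 * x^6 - x^exponent)
      acc <- acc + (r$h[i] + r$h[j]) * w
    }
    raw[i] <- acc
  }
  raw[raw <= 0] <- 1e-12
  raw / sum(raw)
}

## direct evaluation of the membrane blend formula
oracleMembrane <- function(tv, k) {
  inv <- max(tv) - tv
  raw <- tv + k * inv / sum(inv)
  raw / sum(raw)
}

randomSimplex <- function(n) {
  v <- stats::runif(n, 0.01, 1)
  v / sum(v)
}

## random non-degenerate unit: uniform coordinates in a ball, residue
## hydrophobicities drawn from the default scale
randomUnit <- function(n, seed) {
  set.seed(seed)
  radius <- 3 * n^(1 / 3) + 3
  dir <- matrix(stats::rnorm(3 * n), n, 3)
  dir <- dir / sqrt(rowSums(dir^2))
  xyz <- dir * radius * stats::runif(n)^(1 / 3)
  h <- sample(kyteDoolittleScale(), n, replace = TRUE)
  mkUnit(xyz, unname(h))
}

pdbAtomLine <- function(serial, name, resn, chain, resno, x, y, z,
                        occ = 1, b = 0, record = "ATOM", alt = " ",
                        elem = substr(name, 1, 1)) {
  paste0(sprintf("%-6s", record), sprintf("%5d", serial), " ",
         sprintf("%-4s", name), alt, sprintf("%3s", resn), " ", chain,
         sprintf("%4d", resno), "    ",
         sprintf("%8.3f%8.3f%8.3f", x, y, z),
         sprintf("%6.2f%6.2f", occ, b), "          ",
         sprintf("%2s", elem))
}

## hand-built PDB exercising chains, gaps, MSE, altlocs, waters, a ligand,
## a disulfide (record + geometry) and a SHEET record
writeToyPdb <- function(path) {
  ln <- character()
  ln <- c(ln, sprintf("SSBOND %3d CYS %1s %4d    CYS %1s %4d", 1L, "A", 6L, "B", 3L))
  ln <- c(ln, "SHEET    1   A 2 ALA A   2  GLY A   4  0")
  s <- 0L
  addAtom <- function(...) { s <<- s + 1L; pdbAtomLine(s, ...) }
  ## chain A: resno 1,2,4 (gap at 3), CYS 6, MSE 8 as HETATM
  ln <- c(ln, addAtom("N",  "ALA", "A", 1, 0, 0, 0, elem = "N"))
  ln <- c(ln, addAtom("CA", "ALA", "A", 1, 2, 0, 0))
  ln <- c(ln, addAtom("CA", "ALA", "A", 2, 4, 0, 0))
  ## altloc pair: B conformer has the higher occupancy and must win
  ln <- c(ln, addAtom("CA", "GLY", "A", 4, 8, 0, 0, occ = 0.3, alt = "A"))
  ln <- c(ln, addAtom("CA", "GLY", "A", 4, 9, 0, 0, occ = 0.7, alt = "B"))
  ln <- c(ln, addAtom("CA", "CYS", "A", 6, 12, 0, 0))
  ln <- c(ln, addAtom("SG", "CYS", "A", 6, 12, 2, 0, elem = "S"))
  ln <- c(ln, addAtom("CA", "MSE", "A", 8, 16, 0, 0, record = "HETATM"))
  ## hydrogen must be dropped
  ln <- c(ln, addAtom("H",  "ALA", "A", 1, 0, 5, 0, elem = "H"))
  ## chain B: 1,2 and CYS 3 close to A's CYS 6
  ln <- c(ln, addAtom("CA", "VAL", "B", 1, 0, 8, 0))
  ln <- c(ln, addAtom("CA", "TRP", "B", 2, 4, 8, 0))
  ln <- c(ln, addAtom("CA", "CYS", "B", 3, 12, 6, 0))
  ln <- c(ln, addAtom("SG", "CYS", "B", 3, 12, 4, 0, elem = "S"))
  ## ligand + waters
  ln <- c(ln, addAtom("C1", "LBN", "L", 1, 20, 0, 0, record = "HETATM"))
  ln <- c(ln, addAtom("O",  "HOH", "W", 1, 30, 0, 0, record = "HETATM", elem = "O"))
  ln <- c(ln, "END")
  writeLines(ln, path)
  path
}

## two-chain toy: chains A and B as short strands a controllable gap apart
twoChainToy <- function(gap, n = 4) {
  xyzA <- cbind(seq(0, by = 4, length.out = n), 0, 0)
  xyzB <- cbind(seq(0, by = 4, length.out = n), gap, 0)
  res <- data.frame(chain = rep(c("A", "B"), each = n),
                    resno = rep(seq_len(n), 2), resid = "GLY",
                    x = c(xyzA[, 1], xyzB[, 1]), y = c(xyzA[, 2], xyzB[, 2]),
                    z = c(xyzA[, 3], xyzB[, 3]), h = 0.5,
                    stringsAsFactors = FALSE)
  atoms <- res[, c("chain", "resno", "resid", "x", "y", "z")]
  atoms$elety <- "CA"
  emptyLig <- data.frame(name = character(), chain = character(),
                         resno = integer(), x = numeric(), y = numeric(),
                         z = numeric(), stringsAsFactors = FALSE)
  methods::new("FodStructure", atoms = atoms, residues = res,
               ligands = emptyLig,
               ssBonds = data.frame(chain1 = character(), resno1 = integer(),
                                    chain2 = character(), resno2 = integer(),
                                    stringsAsFactors = FALSE),
               sheets = data.frame(chain = character(), start = integer(),
                                   end = integer(), stringsAsFactors = FALSE),
               sourceId = "toy")
}

## minimal mmCIF (atom_site loop only) for the cif reading path
writeToyCif <- function(path) {
  hdr <- c("data_toy", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  row <- function(id, resn, chain, resno, x, y, z)
    sprintf("ATOM %d C CA . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s CA 1",
            id, resn, chain, resno, x, y, z, resno, resn, chain)
  writeLines(c(hdr,
               row(1, "ALA", "A", 1, 0, 0, 0),
               row(2, "GLY", "A", 2, 3.8, 0, 0),
               row(3, "VAL", "B", 1, 0, 5, 0),
               "#"), path)
  path
}
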