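test_that("PDB parsing separates chains, ligands, waters and bonds", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeToyPdb(f)
  st <- loadStructure(f)

  r <- residues(st)
  expect_setequal(unique(r$chain), c("A", "B"))
  expect_equal(sum(r$chain == "A"), 5)           # 1, 2, 4, 6, MSE 8
  expect_equal(sum(r$chain == "B"), 3)
  expect_true("MSE" %in% r$resid)                # aliased het kept as polymer
  expect_false(any(r$resid %in% c("HOH", "LBN")))

  lg <- ligands(st)
  expect_equal(unique(lg$name), "LBN")           # waters discarded
  expect_equal(nrow(lg), 1)

  ## disulfide A6-B3 found (record and geometric fallback agree, deduped)
  b <- ssBonds(st)
  expect_equal(nrow(b), 1)
  expect_equal(unname(unlist(b[1, ])), c("A", "6", "B", "3"))

  ## SHEET record captured
  sh <- sheetRanges(st)
  expect_equal(nrow(sh), 1)
  expect_equal(sh$start, 2)
  expect_equal(sh$end, 4)

  ## altloc: highest-occupancy conformer kept -> GLY 4 CA at x = 9
  g4 <- r[r$chain == "A" & r$resno == 4, ]
  expect_equal(g4$x, 9)

  ## hydrogens excluded: ALA 1 effective atom = mean of N and CA only
  a1 <- r[r$chain == "A" & r$resno == 1, ]
  expect_equal(c(a1$x, a1$y, a1$z), c(1, 0, 0))
})

test_that("parse errors are reported as such", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("this is not a structure", f)
  expect_error(loadStructure(f), "cannot parse|empty structure")
  expect_error(loadStructure("/nonexistent/file.pdb"), "not found")
})

test_that("effective atom is the unweighted heavy-atom mean", {
  expect_equal(effectiveAtom(rbind(c(0, 0, 0), c(2, 0, 0))), c(1, 0, 0))
  expect_equal(effectiveAtom(matrix(c(1, 2, 3), 1)), c(1, 2, 3))
  expect_equal(effectiveAtom(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))),
               c(1, 1, 1))
  expect_error(effectiveAtom(matrix(numeric(), 0, 3)), "degenerate")
})

test_that("units index resolved residues contiguously and bijectively", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeToyPdb(f)
  st <- loadStructure(f)

  u <- makeUnit(st)
  expect_equal(unitLabel(u), "complex")
  expect_equal(nResidues(u), 8)
  ## contiguous despite the resno gap in chain A
  expect_equal(residues(u)$seqIndex, 1:8)

  ## bijection: inverse lookup recovers every (chain, resno)
  im <- indexMap(u)
  expect_equal(nrow(unique(im[, c("chain", "resno")])), nrow(im))
  expect_equal(im$seqIndex, seq_len(nrow(im)))

  ua <- makeUnit(st, chains = "A")
  expect_equal(nResidues(ua), 5)
  expect_equal(unique(residues(ua)$chain), "A")

  ur <- makeUnit(st, ranges = data.frame(chain = "A", start = 1, end = 4))
  expect_equal(residues(ur)$resno, c(1, 2, 4))

  expect_error(makeUnit(st, chains = "Z"), "selection error")
  expect_error(makeUnit(st, ranges = data.frame(chain = "A", start = 100,
                                                end = 200)),
               "selection error")
})

test_that("scale assignment covers aliases and rejects unknown residues", {
  expect_equal(unname(kyteDoolittleScale()["ILE"]), 1)
  expect_equal(unname(kyteDoolittleScale()["ARG"]), 0)

  f <- withr::local_tempfile(fileext = ".pdb")
  writeToyPdb(f)
  st <- loadStructure(f)

  st2 <- assignScale(st)
  expect_false(any(is.na(residues(st2)$h)))
  ## MSE resolved through the alias table to MET's value
  mse <- residues(st2)[residues(st2)$resid == "MSE", ]
  expect_equal(mse$h, unname(kyteDoolittleScale()["MET"]))

  ## scale missing a residue present in the structure -> coverage error
  expect_error(assignScale(st, kyteDoolittleScale(), aliases = character()),
               "scale-coverage")
  broken <- kyteDoolittleScale()
  broken <- broken[names(broken) != "TRP"]
  expect_error(assignScale(st, broken), "20 standard")

  ## all-GLY structure under a GLY -> 0 scale
  g <- syntheticGlobule(n = 20, seed = 1)
  g@residues$resid <- "GLY"
  sc <- kyteDoolittleScale()
  sc[] <- 0.5
  sc["GLY"] <- 0
  g <- assignScale(g, sc)
  expect_true(all(residues(g)$h == 0))
})

test_that("PDB round-trip preserves counts, order and effective atoms", {
  st <- syntheticGlobule(n = 40, seed = 11)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructurePDB(st, f)
  st2 <- loadStructure(f)
  expect_equal(nResidues(st2), 40)
  expect_equal(residues(st2)$resid, residues(st)$resid)
  expect_equal(residues(st2)$resno, residues(st)$resno)
  expect_lt(max(abs(as.matrix(residues(st2)[, c("x", "y", "z")]) -
                    as.matrix(residues(st)[, c("x", "y", "z")]))), 1e-3)

  ## multi-chain + ligand fixture survives too
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeToyPdb(f2)
  a <- loadStructure(f2)
  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeStructurePDB(a, f3)
  b <- loadStructure(f3)
  expect_equal(residues(b)[, c("chain", "resno", "resid")],
               residues(a)[, c("chain", "resno", "resid")])
  expect_equal(nrow(ligands(b)), nrow(ligands(a)))
})

test_that("mmCIF atom records parse through the same surface", {
  f <- withr::local_tempfile(fileext = ".cif")
  writeToyCif(f)
  st <- loadStructure(f)                      # format by extension
  expect_setequal(unique(residues(st)$chain), c("A", "B"))
  expect_equal(nResidues(st), 3)
  expect_equal(residues(st)$resid, c("ALA", "GLY", "VAL"))
  expect_equal(residues(st)$x, c(0, 3.8, 0))
  st2 <- loadStructure(f, format = "mmcif")
  expect_equal(residues(st2), residues(st))
})

test_that("subset masks round-trip through the BED-like TSV", {
  s1 <- fodm:::newSubset("P-P", c(1:5, 9L, 20:22))
  s2 <- fodm:::newSubset("zone:membrane", c(2:8))
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- exportSubsets(list(s1, s2), "complex", f)
  ## contiguous runs, 1-based inclusive
  expect_equal(tab$start_index[tab$label == "P-P"], c(1, 9, 20))
  expect_equal(tab$end_index[tab$label == "P-P"], c(5, 9, 22))
  back <- importSubsets(f)
  expect_setequal(names(back), c("P-P", "zone:membrane"))
  expect_equal(subsetMask(back[["P-P"]]), subsetMask(s1))
  expect_equal(subsetMask(back[["zone:membrane"]]), subsetMask(s2))
})
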