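#' @include AllClasses.R
NULL

## run expr with a locally seeded RNG, restoring the caller's stream
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

## sequential dart-throwing with a minimum separation; proposal() returns one
## candidate coordinate per call
packPoints <- function(n, proposal, minSep, maxAttempts = 500L * n) {
  pts <- matrix(NA_real_, n, 3)
  placed <- 0L
  for (a in seq_len(maxAttempts)) {
    p <- proposal()
    if (placed > 0L) {
      d2 <- colSums((t(pts[seq_len(placed), , drop = FALSE]) - p)^2)
      if (min(d2) < minSep^2) next
    }
    placed <- placed + 1L
    pts[placed, ] <- p
    if (placed == n) return(pts)
  }
  stop("infeasible packing: could not place ", n, " points at ", minSep,
       " A separation; enlarge the volume or reduce n")
}

## map a 0..1 target ladder (plus optional Gaussian noise) to the residue
## whose scale value is nearest -- rank-matching hydrophobicity to geometry
rankMatchResidues <- function(target, noise, scale) {
  if (noise > 0) target <- target + stats::rnorm(length(target), 0, noise)
  target <- pmin(pmax(target, 0), 1)
  names(scale)[vapply(target, function(v) which.min(abs(scale - v)), integer(1))]
}

## monotone ladder following the Gaussian radial decay of the theoretical
## field (sigma = extent/3), rescaled onto [0, 1]: the centre reaches the
## scale's hydrophobic extreme, the outermost shell its polar extreme
gaussianLadder <- function(r, extent, inverted = FALSE) {
  t <- exp(-r^2 / (2 * (extent / 3)^2))
  if (inverted) t <- 1 - t
  (t - min(t)) / (max(t) - min(t))
}

buildSynthetic <- function(xyz, resid, chain, sourceId, scale) {
  n <- nrow(xyz)
  atoms <- data.frame(chain = chain, resno = stats::ave(seq_len(n), chain,
                                                        FUN = seq_along),
                      resid = resid, elety = "CA",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  residues <- atoms[, c("chain", "resno", "resid", "x", "y", "z")]
  residues$h <- NA_real_
  s <- methods::new("FodStructure", atoms = atoms, residues = residues,
                    ligands = data.frame(name = character(), chain = character(),
                                         resno = integer(), x = numeric(),
                                         y = numeric(), z = numeric(),
                                         stringsAsFactors = FALSE),
                    ssBonds = data.frame(chain1 = character(), resno1 = integer(),
                                         chain2 = character(), resno2 = integer(),
                                         stringsAsFactors = FALSE),
                    sheets = data.frame(chain = character(), start = integer(),
                                        end = integer(), stringsAsFactors = FALSE),
                    sourceId = sourceId)
  assignScale(s, scale)
}

writeSyntheticPDB <- function(structure, file, kind, seed, params) {
  remarks <- c(
    sprintf("fodm synthetic %s structure", kind),
    sprintf("seed %d rng Mersenne-Twister", seed),
    sprintf("params %s", paste(names(params), unlist(params), sep = "=",
                               collapse = " ")))
  writeStructurePDB(structure, file, remarks = remarks)
}

#' Synthetic micelle-like globule
#'
#' Generates a single-chain pseudo-structure with the statistical
#' organisation of a water-soluble globule: one pseudo-atom (CA) per residue,
#' positions sampled quasi-uniformly in a ball with a minimum separation, and
#' residue identities rank-matched so intrinsic hydrophobicity decreases from
#' the centre outwards, following the same Gaussian radial decay the
#' theoretical field assumes (a perfect centric core in the noise-free limit).
#' Such units are the positive control of the model: RD below 0.5 and a small
#' optimal K.
#'
#' @param n number of residues (>= 20 for stable statistics).
#' @param radius ball radius in A; default scales as the cube root of n with
#'   roughly one residue per 120 A^3 (protein-like point density).
#' @param noise sd of the Gaussian perturbation added to the hydrophobicity
#'   ladder before rank-matching (0 = perfect core).
#' @param seed integer; fully determines the output.
#' @param minSep minimum inter-residue separation in A (default 4).
#' @param scale hydrophobicity scale used for rank-matching and assignment.
#' @param file optional path: write the structure as PDB (with REMARK
#'   provenance lines recording generator, seed and parameters).
#' @return A [FodStructure-class] with hydrophobicities assigned.
#' @export
syntheticGlobule <- function(n = 200, radius = NULL, noise = 0, seed = 1,
                             minSep = 4, scale = kyteDoolittleScale(),
                             file = NULL) {
  if (n < 20) stop("n must be >= 20")
  if (is.null(radius)) radius <- (3 * n * 120 / (4 * pi))^(1 / 3)
  st <- withSeed(seed, {
    proposal <- function() {
      v <- stats::rnorm(3)
      v / sqrt(sum(v^2)) * radius * stats::runif(1)^(1 / 3)
    }
    xyz <- packPoints(n, proposal, minSep)
    r <- sqrt(rowSums(xyz^2))
    ## closest to centre -> most hydrophobic, decaying like the field itself
    resid <- rankMatchResidues(gaussianLadder(r, radius), noise, scale)
    buildSynthetic(xyz, resid, rep("A", n),
                   sprintf("synthetic-globule-seed%d", seed), scale)
  })
  if (!is.null(file))
    writeSyntheticPDB(st, file, "globule", seed,
                      list(n = n, radius = round(radius, 2), noise = noise))
  st
}

#' Synthetic channel-like oligomer
#'
#' Generates `nChains` identical chains arranged with C_n symmetry around the
#' z axis, forming a hollow cylinder: residues occupy an annular wedge and
#' the whole assembly leaves a polar lumen. Hydrophobicity increases with
#' radial distance from the axis (lumen polar, outer surface hydrophobic) --
#' the inverted organisation of a membrane channel. Such units are the
#' negative control: RD above 0.5 and a large optimal K.
#'
#' @param nChains number of chains (>= 3).
#' @param perChain residues per chain.
#' @param innerRadius,outerRadius annulus radii in A (lumen wall and outer
#'   surface).
#' @param height cylinder height in A.
#' @param noise sd of the hydrophobicity ladder perturbation.
#' @param seed integer; fully determines the output.
#' @param minSep minimum separation within a chain in A.
#' @param scale hydrophobicity scale.
#' @param file optional PDB output path.
#' @return A [FodStructure-class] with hydrophobicities assigned.
#' @export
syntheticChannel <- function(nChains = 6, perChain = 60, innerRadius = 8,
                             outerRadius = 24, height = 60, noise = 0,
                             seed = 1, minSep = 4,
                             scale = kyteDoolittleScale(), file = NULL) {
  if (nChains < 3) stop("a channel needs at least 3 chains")
  if (nChains * perChain < 20) stop("total residue count must be >= 20")
  if (innerRadius <= 0 || outerRadius <= innerRadius)
    stop("need 0 < innerRadius < outerRadius")
  wedge <- 2 * pi / nChains
  margin <- (minSep / 2) / innerRadius   # keep rotated copies separated too
  if (wedge - 2 * margin <= 0) stop("too many chains for the inner radius")
  st <- withSeed(seed, {
    proposal <- function() {
      ang <- stats::runif(1, margin, wedge - margin)
      rr <- sqrt(stats::runif(1, innerRadius^2, outerRadius^2))
      c(rr * cos(ang), rr * sin(ang),
        stats::runif(1, -height / 2, height / 2))
    }
    xyz1 <- packPoints(perChain, proposal, minSep)
    rad <- sqrt(xyz1[, 1]^2 + xyz1[, 2]^2)
    ## closest to the axis -> most polar (inverted field organisation)
    resid1 <- rankMatchResidues(gaussianLadder(rad, outerRadius,
                                               inverted = TRUE),
                                noise, scale)
    xyz <- do.call(rbind, lapply(seq_len(nChains) - 1L, function(k) {
      a <- k * wedge
      rot <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
      xyz1 %*% t(rot)
    }))
    buildSynthetic(xyz, rep(resid1, nChains),
                   rep(LETTERS[seq_len(nChains)], each = perChain),
                   sprintf("synthetic-channel-seed%d", seed), scale)
  })
  if (!is.null(file))
    writeSyntheticPDB(st, file, "channel", seed,
                      list(nChains = nChains, perChain = perChain,
                           innerRadius = innerRadius,
                           outerRadius = outerRadius, height = height,
                           noise = noise))
  st
}

#' Randomised control structure
#'
#' Globule geometry with residue identities shuffled independently of
#' position: the multiset of intrinsic hydrophobicities of the matching
#' globule is preserved but carries no spatial organisation. The null
#' control against the uniform reference.
#'
#' @inheritParams syntheticGlobule
#' @return A [FodStructure-class] with hydrophobicities assigned.
#' @export
syntheticRandom <- function(n = 200, radius = NULL, noise = 0, seed = 1,
                            minSep = 4, scale = kyteDoolittleScale(),
                            file = NULL) {
  st <- syntheticGlobule(n = n, radius = radius, noise = noise, seed = seed,
                         minSep = minSep, scale = scale)
  st <- withSeed(seed + 1L, {
    perm <- sample.int(nResidues(st))
    st@atoms$resid <- st@atoms$resid[perm]
    st@residues$resid <- st@residues$resid[perm]
    st@residues$h <- st@residues$h[perm]
    st@sourceId <- sprintf("synthetic-random-seed%d", seed)
    st
  })
  if (!is.null(file))
    writeSyntheticPDB(st, file, "random", seed,
                      list(n = n, noise = noise))
  st
}
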