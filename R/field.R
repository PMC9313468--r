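#' @include AllClasses.R
NULL

newProfile <- function(values, kind, unitLabel = "", k = NA_real_) {
  methods::new("HydroProfile", values = as.numeric(values), kind = kind,
               unitLabel = unitLabel, k = k)
}

#' Fit the 3D Gaussian field of a structural unit
#'
#' The theoretical ("oil drop") field is a separable 3D Gaussian in the
#' molecule's own frame: centred on the mean of the effective atoms, aligned
#' with the principal axes of the effective-atom cloud (descending variance),
#' with each sigma set from the molecular extent along that axis --
#' `max |projection| / sigmaDivisor`, floored at 1 A. The default divisor 3
#' is the three-sigma-encapsulation convention: the molecule's furthest
#' residue sits at three standard deviations.
#'
#' @param unit a [StructureUnit-class] with at least 3 residues.
#' @param sigmaDivisor positive divisor of the axis extent (default 3).
#' @param center "mean" (default) centres on the mean effective atom;
#'   "midpoint" on the bounding-box midpoint in the principal frame.
#' @return A [GaussianField-class].
#' @export
fitField <- function(unit, sigmaDivisor = 3, center = c("mean", "midpoint")) {
  center <- match.arg(center)
  xyz <- as.matrix(unit@residues[, c("x", "y", "z")])
  if (nrow(xyz) < 3L) stop("field-fit error: need at least 3 residues")
  mu <- colMeans(xyz)
  cc <- sweep(xyz, 2, mu)
  eg <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  if (eg$values[2] < 1e-8)
    stop("field-fit error: degenerate geometry (effective atoms collinear)")
  axes <- eg$vectors
  if (det(axes) < 0) axes[, 3] <- -axes[, 3]
  proj <- cc %*% axes
  if (center == "midpoint") {
    mid <- (apply(proj, 2, max) + apply(proj, 2, min)) / 2
    mu <- mu + as.numeric(axes %*% mid)
    proj <- sweep(proj, 2, mid)
  }
  ## degenerate principal variances (e.g. symmetric ring oligomers) leave the
  ## in-subspace axis orientation arbitrary; share one isotropic sigma from
  ## the radial extent of the whole subspace so the fit stays well-defined
  ## and rotation-invariant
  ev <- eg$values
  grp <- cumsum(c(1, diff(ev) < -1e-4 * (ev[1] + 1e-12)))
  sig <- numeric(3)
  for (g in unique(grp)) {
    ax <- which(grp == g)
    ext <- max(sqrt(rowSums(proj[, ax, drop = FALSE]^2)))
    sig[ax] <- max(ext / sigmaDivisor, 1.0)
  }
  methods::new("GaussianField", center = as.numeric(mu), axes = axes,
               sigmas = as.numeric(sig))
}

#' Theoretical hydrophobicity distribution T
#'
#' Evaluates the fitted 3D Gaussian at every effective atom (in the field's
#' axis frame) and normalises to sum 1. T is the idealised distribution of a
#' water-soluble globule: a centric hydrophobic core decaying outwards. All
#' values are strictly positive.
#'
#' @param unit a [StructureUnit-class].
#' @param field a [GaussianField-class] fitted on the same unit
#'   (default: fit now).
#' @return A [HydroProfile-class] of kind "T".
#' @export
theoreticalProfile <- function(unit, field = fitField(unit)) {
  xyz <- as.matrix(unit@residues[, c("x", "y", "z")])
  proj <- sweep(xyz, 2, field@center) %*% field@axes
  lg <- -rowSums(sweep(proj^2, 2, 2 * field@sigmas^2, "/"))
  t <- exp(lg)
  newProfile(t / sum(t), "T", unit@label)
}

## distance-dependent contact weight of the pairwise aggregation
levittWeight <- function(r, cutoff = 9, exponent = 8) {
  x <- r / cutoff
  w <- 1 - 0.5 * (7 * x^2 - 9 * x^4 + 5 * x^6 - x^exponent)
  w[r > cutoff] <- 0
  w
}

#' Observed hydrophobicity distribution O
#'
#' Aggregates pairwise inter-residue hydrophobic interactions: each residue
#' collects `(H_i^r + H_j^r) * w(r_ij)` over all other residues within the
#' cutoff, where `w` is a distance-dependent contact polynomial equal to 1 at
#' contact and 0 at the cutoff, and `r_ij` is the effective-atom distance.
#' The result is normalised to sum 1. The final polynomial term uses
#' `(r/c)^exponent`; exponent 8 (even-power form) is the default, 9 is
#' accepted for cross-checks -- both vanish at the cutoff so the difference
#' is small. The self term (j = i) is excluded by default: O aggregates
#' inter-residue interactions, and the self contribution is a constant
#' per-residue offset that distorts normalisation.
#'
#' @param unit a [StructureUnit-class] with intrinsic hydrophobicities
#'   assigned (see [assignScale()]).
#' @param cutoff contact cutoff c in A (default 9).
#' @param exponent final polynomial power, 8 or 9.
#' @param includeSelf include the j = i term (for cross-checks only).
#' @return A [HydroProfile-class] of kind "O". Residues with zero raw
#'   aggregate (isolated beyond the cutoff) are floored at 1e-12 before
#'   normalisation, with a warning.
#' @export
observedProfile <- function(unit, cutoff = 9, exponent = 8,
                            includeSelf = FALSE) {
  h <- unit@residues$h
  if (any(is.na(h)))
    stop("intrinsic hydrophobicities not assigned; run assignScale() first")
  if (cutoff <= 0) stop("cutoff must be positive")
  xyz <- as.matrix(unit@residues[, c("x", "y", "z")])
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  w <- levittWeight(d, cutoff, exponent)
  if (!includeSelf) diag(w) <- 0 else diag(w) <- levittWeight(0, cutoff, exponent)
  ## sum_j (h_i + h_j) w_ij = h_i * rowSums(w) + w %*% h
  o <- h * rowSums(w) + as.numeric(w %*% h)
  if (any(o <= 0)) {
    warning(sum(o <= 0), " residue(s) with zero observed aggregate; ",
            "floored at 1e-12 before normalisation")
    o[o <= 0] <- 1e-12
  }
  newProfile(o / sum(o), "O", unit@label)
}

#' Uniform reference distribution R
#'
#' The no-structure reference: every residue carries 1/N. Comparing the
#' observed distribution's divergence from T against its divergence from R
#' asks whether the molecule looks more like a centric globule or like a
#' profile with no hydrophobicity differentiation at all.
#'
#' @param n number of residues (>= 1).
#' @param unitLabel optional label.
#' @return A [HydroProfile-class] of kind "R".
#' @export
uniformProfile <- function(n, unitLabel = "") {
  if (n < 1) stop("n must be >= 1")
  newProfile(rep(1 / n, n), "R", unitLabel)
}

#' Membrane-modified distribution M(K)
#'
#' Blends the theoretical distribution with its normalised inversion:
#' `M = [T + K * (T_max - T)_n]_n`, where the subscript n denotes
#' normalisation to sum 1. K = 0 recovers T (fully aqueous environment);
#' increasing K weights the inverted, membrane-like component until the
#' central maximum of T is replaced by a minimum, the organisation seen in
#' membrane channels.
#'
#' @param t a [HydroProfile-class] of kind "T" (any normalised profile is
#'   accepted for fragment work).
#' @param k membrane-participation coefficient, >= 0.
#' @return A [HydroProfile-class] of kind "M". If T is exactly uniform the
#'   inverted component is undefined and M is defined as T itself (with a
#'   message).
#' @export
membraneProfile <- function(t, k) {
  if (k < 0) stop("k must be >= 0")
  tv <- profileValues(t)
  inv <- max(tv) - tv
  s <- sum(inv)
  if (s <= 0) {
    message("all-equal T: inverted component undefined, M defined as T")
    return(newProfile(tv, "M", unitLabel(t), k = k))
  }
  raw <- tv + k * inv / s
  newProfile(raw / sum(raw), "M", unitLabel(t), k = k)
}

#' Tabulate the profiles of a unit
#'
#' Serialises T/O/R (and optionally M at a given K) as one data.frame, the
#' format behind the per-residue profile plots and TSV exports.
#'
#' @param unit a [StructureUnit-class].
#' @param t,o profiles computed on the unit (defaults computed now).
#' @param k optional K at which to add an M column.
#' @param file optional TSV path to write.
#' @return data.frame with columns sequential_index, chain_id, seq_id,
#'   residue_name, T, O, R and optionally M.
#' @export
profileTable <- function(unit, t = theoreticalProfile(unit),
                         o = observedProfile(unit), k = NULL, file = NULL) {
  r <- unit@residues
  out <- data.frame(sequential_index = r$seqIndex, chain_id = r$chain,
                    seq_id = r$resno, residue_name = r$resid,
                    T = profileValues(t), O = profileValues(o),
                    R = 1 / nrow(r), stringsAsFactors = FALSE)
  if (!is.null(k)) out$M <- profileValues(membraneProfile(t, k))
  if (!is.null(file))
    utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
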