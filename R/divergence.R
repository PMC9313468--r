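#' @include AllClasses.R
NULL

asValues <- function(p) if (methods::is(p, "HydroProfile")) profileValues(p) else as.numeric(p)

#' Kullback-Leibler divergence (bits)
#'
#' `D_KL(P|Q) = sum_i P_i log2(P_i / Q_i)`, with the 0 log 0 = 0 convention
#' for zero entries of P. Q must be strictly positive wherever P is positive,
#' otherwise the divergence is infinite and an error is raised.
#'
#' @param p,q profiles ([HydroProfile-class] or numeric vectors of equal
#'   length); p non-negative, q positive where p > 0, both summing to 1.
#' @return Non-negative divergence in bits; 0 iff p equals q.
#' @examples
#' klDivergence(c(1, 0), c(0.5, 0.5))  # 1 bit
#' @export
klDivergence <- function(p, q) {
  p <- asValues(p); q <- asValues(q)
  if (length(p) != length(q))
    stop("length mismatch: profiles have ", length(p), " and ", length(q),
         " values")
  if (any(p < 0)) stop("p must be non-negative")
  if (any(q <= 0 & p > 0))
    stop("infinite divergence: q has zero mass where p is positive")
  pos <- p > 0
  sum(p[pos] * log2(p[pos] / q[pos]))
}

#' Relative distance RD
#'
#' `RD = D_KL(O|T) / (D_KL(O|T) + D_KL(O|R))` locates the observed
#' distribution between the centric-globule ideal T and the structureless
#' uniform reference R. RD < 0.5 (the cut-off) means O is closer to T than
#' to R: a centric hydrophobic core is present.
#'
#' @param o,t profiles of equal length; `r` defaults to the uniform profile
#'   of the same length.
#' @param r optional reference profile.
#' @return RD in \[0, 1\]. If both divergences are zero (O = T = R) RD is
#'   defined as 0, with a message.
#' @export
relativeDistance <- function(o, t, r = uniformProfile(length(asValues(o)))) {
  dot <- klDivergence(o, t)
  dor <- klDivergence(o, r)
  if (dot + dor == 0) {
    message("O, T and R identical: RD defined as 0")
    return(0)
  }
  dot / (dot + dor)
}

#' Grid optimisation of the membrane coefficient K
#'
#' Scans K over a regular grid and returns the K minimising
#' `D_KL(O | M(K))`, the weight of the membrane-like inverted component that
#' best explains the observed distribution. Ties break toward smaller K (the
#' weaker-modification explanation). The default ceiling of 10 comfortably
#' covers reported channel values (up to ~3), and the 0.1 step matches the
#' one-decimal resolution at which K is conventionally reported.
#'
#' @param o,t observed and theoretical profiles of equal length.
#' @param kMax grid ceiling (default 10).
#' @param step grid step (default 0.1), > 0.
#' @return list with elements `kOpt`, `dkl` (the minimum divergence, bits)
#'   and `curve` (data.frame k, dkl for inspection/plotting).
#' @export
optimizeK <- function(o, t, kMax = 10, step = 0.1) {
  if (step <= 0) stop("step must be > 0")
  ks <- seq(0, kMax, by = step)
  dk <- vapply(ks, function(k) klDivergence(o, membraneProfile(t, k)),
               numeric(1))
  i <- which.min(dk)   # first minimum = smallest K on ties
  list(kOpt = ks[i], dkl = dk[i], curve = data.frame(k = ks, dkl = dk))
}

#' Relative distance against the optimised membrane distribution
#'
#' `RD_Kopt = D_KL(O|T) / (D_KL(O|T) + D_KL(O|M_opt))`: the analogue of
#' [relativeDistance()] with M(K_opt) replacing the uniform reference.
#'
#' @param o,t profiles of equal length.
#' @param mOpt the membrane profile at the optimal K.
#' @return RD_Kopt in \[0, 1\] (0 if both divergences vanish, with a message).
#' @export
rdKopt <- function(o, t, mOpt) {
  dot <- klDivergence(o, t)
  dom <- klDivergence(o, mOpt)
  if (dot + dom == 0) {
    message("O, T and M identical: RD_Kopt defined as 0")
    return(0)
  }
  dot / (dot + dom)
}

## assemble the full statistics for one (already normalised) T/O pair
fodStats <- function(tv, ov, unitLabel = "", subsetLabel = "whole",
                     kMax = 10, step = 0.1) {
  t <- newProfile(tv, "T", unitLabel)
  o <- newProfile(ov, "O", unitLabel)
  r <- uniformProfile(length(tv), unitLabel)
  opt <- optimizeK(o, t, kMax = kMax, step = step)
  m <- membraneProfile(t, opt$kOpt)
  methods::new("FodResult", unitLabel = unitLabel, subsetLabel = subsetLabel,
               n = length(tv), dklOT = klDivergence(o, t),
               dklOR = klDivergence(o, r), dklOM = opt$dkl,
               rd = relativeDistance(o, t, r), kOpt = opt$kOpt,
               rdKopt = rdKopt(o, t, m))
}

#' Full divergence statistics of a unit
#'
#' Convenience wrapper: computes T and O on the unit and returns the complete
#' [FodResult-class] (divergences, RD, K_opt, RD_Kopt).
#'
#' @param unit a [StructureUnit-class] with hydrophobicities assigned.
#' @param cutoff,exponent passed to [observedProfile()].
#' @param sigmaDivisor passed to [fitField()].
#' @param kMax,step passed to [optimizeK()].
#' @return A [FodResult-class].
#' @export
fodStatus <- function(unit, cutoff = 9, exponent = 8, sigmaDivisor = 3,
                      kMax = 10, step = 0.1) {
  t <- theoreticalProfile(unit, fitField(unit, sigmaDivisor))
  o <- observedProfile(unit, cutoff, exponent)
  fodStats(profileValues(t), profileValues(o), unit@label, "whole",
           kMax, step)
}

#' Status of a fragment or residue subset by renormalisation
#'
#' The contribution of a subset to its parent unit is scored by excising the
#' subset's T and O values from the profiles computed on the whole unit
#' (never refitting a new Gaussian on the fragment), renormalising each to
#' sum 1, and computing RD against a uniform reference over the fragment
#' length together with the K optimisation on the excised pair. RD < 0.5
#' again marks participation in the hydrophobic core.
#'
#' @param t,o profiles computed on the parent unit.
#' @param mask integer sequential indices of the subset (or a
#'   [SubsetSpec-class]); at least 2.
#' @param subsetLabel label for the result (defaults to the SubsetSpec label
#'   when one is given).
#' @param unitLabel unit label for the result (defaults to the label carried
#'   by `t` when it is a profile object).
#' @param kMax,step passed to [optimizeK()].
#' @return A [FodResult-class] labelled with the subset.
#' @export
fragmentStatus <- function(t, o, mask, subsetLabel = NULL,
                           unitLabel = NULL, kMax = 10, step = 0.1) {
  if (is.null(unitLabel))
    unitLabel <- if (methods::is(t, "HydroProfile")) t@unitLabel else ""
  if (methods::is(mask, "SubsetSpec")) {
    if (is.null(subsetLabel)) subsetLabel <- subsetLabel(mask)
    mask <- subsetMask(mask)
  }
  if (is.null(subsetLabel)) subsetLabel <- "custom"
  mask <- sort(unique(as.integer(mask)))
  tv <- asValues(t); ov <- asValues(o)
  if (length(mask) < 2L) stop("fragment mask must select at least 2 residues")
  if (any(mask < 1L | mask > length(tv)))
    stop("fragment mask outside the unit's 1..N index range")
  tf <- tv[mask]; of <- ov[mask]
  fodStats(tf / sum(tf), of / sum(of), unitLabel, subsetLabel, kMax, step)
}

#' Pearson correlation between two profile segments
#'
#' Compares the shapes of two (possibly unequal-length) profile segments,
#' e.g. analogous fragments of two different proteins. When lengths differ,
#' the longer segment is linearly resampled to the shorter length before the
#' Pearson correlation.
#'
#' @param a,b numeric vectors or [HydroProfile-class] segments, each of
#'   length >= 3.
#' @return Pearson r in \[-1, 1\].
#' @export
profileCorrelation <- function(a, b) {
  a <- asValues(a); b <- asValues(b)
  if (length(a) < 3L || length(b) < 3L)
    stop("segments must have at least 3 values")
  n <- min(length(a), length(b))
  resample <- function(v, n) {
    if (length(v) == n) v
    else stats::approx(seq(0, 1, length.out = length(v)), v,
                       xout = seq(0, 1, length.out = n))$y
  }
  a <- resample(a, n); b <- resample(b, n)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: zero variance in a segment")
  stats::cor(a, b)
}
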