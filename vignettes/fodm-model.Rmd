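---
title: "The fuzzy-oil-drop model and its membrane-modified extension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fuzzy-oil-drop model and its membrane-modified extension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fodm)
```

## The model

A water-soluble protein folds in polar water, which drives hydrophobic
residues inward and polar residues outward: a micelle-like globule with a
centric hydrophobic core. The fuzzy-oil-drop (FOD) model idealises this
organisation as a 3D Gaussian "drop" of hydrophobicity spanned over the
molecule. For a structural unit of $N$ residues, each residue $i$ is reduced
to its *effective atom* (the unweighted mean of its heavy-atom coordinates)
and three per-residue distributions are compared:

* **T (theoretical)** — the separable 3D Gaussian evaluated at the effective
  atoms in the molecule's own principal-axis frame, normalised to sum 1:
  $$T_i \propto
    \exp\!\Big(-\tfrac{\tilde x_i^2}{2\sigma_x^2}\Big)
    \exp\!\Big(-\tfrac{\tilde y_i^2}{2\sigma_y^2}\Big)
    \exp\!\Big(-\tfrac{\tilde z_i^2}{2\sigma_z^2}\Big).$$
* **O (observed)** — pairwise aggregation of hydrophobic inter-residue
  interactions. With intrinsic hydrophobicities $H^r \in [0,1]$ and
  effective-atom distances $r_{ij}$,
  $$O_i \propto \sum_{j \ne i,\; r_{ij} \le c}
      (H_i^r + H_j^r)\,w(r_{ij}/c), \qquad c = 9\,\text{Å},$$
  where $w$ is a contact polynomial equal to 1 at contact and 0 at the
  cutoff.
* **R (uniform)** — the structureless reference, $R_i = 1/N$.

The Kullback–Leibler divergence $D_{KL}(P|Q) = \sum_i P_i \log_2 (P_i/Q_i)$
(bits) compares them, condensed into the *relative distance*

$$RD = \frac{D_{KL}(O|T)}{D_{KL}(O|T) + D_{KL}(O|R)} .$$

$RD < 0.5$ means O is closer to the centric ideal than to the uniform
reference: a hydrophobic core is present.

Membrane proteins invert this organisation — hydrophobic surface, polar
channel lumen. The membrane-modified model (FOD-M) blends the Gaussian with
its normalised inversion,

$$M(K) = \big[\,T + K\,(T_{max} - T)_n\,\big]_n ,$$

where $(\cdot)_n$ denotes normalisation to sum 1. $K = 0$ recovers T;
large $K$ replaces the central maximum by a minimum. The optimal $K$ is the
grid minimiser of $D_{KL}(O|M(K))$ and measures the participation of the
non-aqueous environment: soluble proteins sit in $0 \le K \le 0.4$, membrane
channels well above 1. A companion statistic
$RD_{K_{opt}} = D_{KL}(O|T) / (D_{KL}(O|T) + D_{KL}(O|M_{opt}))$ replaces R
by the optimised membrane distribution.

Fragments and residue subsets (interfaces, ligand contacts,
disulfide-delimited segments, membrane zones, sheet strands) are scored by
*renormalisation*: their T and O values are excised from the parent unit's
profiles — never refitted — renormalised to sum 1, and scored against a
uniform reference of the fragment length. This measures the subset's
contribution to the parent organisation rather than its standalone shape.

## Parameters that matter

* **Intrinsic hydrophobicity scale.** The published FOD analyses do not
  print their scale, so absolute RD/K values are scale-dependent. The
  package default is the Kyte–Doolittle index min-max normalised to
  $[0,1]$ ($(h+4.5)/9$; ILE $=1$, ARG $=0$). The scale is a required,
  documented choice of every run and any named vector can be supplied.
* **Sigma rule** (`sigmaDivisor`, default 3). The Gaussian widths are left
  open in the model's statement; the package uses the three-sigma
  encapsulation convention: $\sigma$ = (maximal absolute principal-frame
  coordinate)/3, floored at 1 Å. The field is centred on the mean effective
  atom (a bounding-box midpoint option exists). When principal variances are
  degenerate — exactly the case for $C_n$-symmetric oligomers, whose in-plane
  second moments are equal by symmetry — the in-subspace axis orientation is
  arbitrary, so the package assigns the whole degenerate subspace one
  isotropic sigma from its radial extent. This keeps the fit well defined
  and the T profile rotation-invariant.
* **Contact polynomial exponent** (`levittExponent`, default 8). The final
  term of the contact weight is $(r/c)^8$ by default (the even-power form of
  the original interaction function); the printed variant with $(r/c)^9$ is
  available as a config switch. Both vanish at $r = c$; the printed
  odd-power form dips very slightly negative just inside the cutoff and is
  evaluated as written, without clamping.
* **Self term.** O aggregates *inter*-residue interactions; the $j = i$ term
  is a constant per-residue offset that only flattens the normalised profile
  and is excluded by default (a flag includes it for cross-checks).
* **K grid** (`kMax = 10`, `step = 0.1`). Reported K values carry one
  decimal and reach ~3 in channels; 10 is a safe ceiling. Ties break toward
  smaller K — the weaker-modification explanation — making the optimiser
  deterministic.
* **Contact cutoffs** (5 Å heavy-atom) define interface and ligand-contact
  subsets; the membrane slab for zone assignment must come from
  configuration, because membrane placement is a judgement made on the
  structure — guessing it automatically would fabricate methodology.

## Numerical choices and degenerate inputs

* Profiles are normalised to sum 1 within $10^{-9}$; T is strictly positive
  by construction, so $D_{KL}(O|T)$ and $D_{KL}(O|M)$ are always finite.
* A residue whose raw observed aggregate is zero (isolated beyond the
  cutoff, or a fully polar neighbourhood on a synthetic structure) is
  floored at $10^{-12}$ before normalisation, with a warning; zero-mass
  entries of the left profile follow the $0 \log 0 = 0$ convention.
* An all-equal T has no defined inversion; $M(K)$ is then defined as T
  itself (logged). If O, T and R coincide, RD is defined as 0 (logged).
* Alternate locations keep the highest-occupancy conformer; hydrogens are
  excluded; waters are discarded; unresolved residues are never imputed —
  all profiles run over resolved residues with contiguous sequential
  indexing, so plot positions are unit indices, not deposition numbers.
* Disulfides come from SSBOND records where present, supplemented by any
  cysteine SG–SG pair within 2.5 Å (standard disulfide geometry upper
  bound); records take precedence and duplicates are merged.
* The disulfide "segment" is the inclusive sequence interval between the
  bonded cysteines. Unequal-length profile segments are compared by linearly
  resampling the longer one before the Pearson correlation.

## The synthetic generators

Real depositions cannot ship with the package, so the test surface is built
on seeded generators that emulate the two organisations the statistics must
separate:

* `syntheticGlobule()` — one pseudo-atom per residue, quasi-uniform
  positions in a ball (4 Å minimum separation, ~120 Å³ per residue, a
  protein-like point density), residue identities rank-matched so intrinsic
  hydrophobicity decays from the centre following the same Gaussian radial
  profile the theoretical field assumes. In the noise-free limit the
  aggregated O tracks T closely (the micelle ideal, $O \approx T$), making
  the $RD < 0.5$, $K \le 0.4$ recovery assertion sharp. Gaussian noise on
  the hydrophobicity ladder (sd = `noise`) degrades the core monotonically.
* `syntheticChannel()` — $n$ identical chains arranged with $C_n$ symmetry
  around a hollow cylinder; hydrophobicity *increases* with radial distance
  (polar lumen, hydrophobic outer surface). This inverts T by design: such
  units score $RD > 0.5$ and drive the K scan toward its ceiling, the
  fully-membrane limit.
* `syntheticRandom()` — globule geometry with residue identities shuffled:
  the null control, conserving composition but not organisation.

What these generators do *not* emulate: covalent chain connectivity and
secondary structure, full side chains (the effective atom equals the placed
point), realistic packing heterogeneity, and the idiosyncratic mixture of
core, interface and surface signals of real proteins. Passing the recovery
suite therefore shows that the statistics separate the two organisations the
model is about — not that any particular deposited structure will reproduce
published values, which additionally depend on the (unpublished) intrinsic
scale.

Default problem sizes — 200-residue globules, 6 × 60 channels, 20 seeds per
ensemble — give stable statistics (RD fluctuates by well under 0.05 across
seeds) while keeping a full recovery sweep in the order of seconds.

## A worked example

```{r globule}
glob <- syntheticGlobule(n = 200, seed = 1)
res <- fodStatus(makeUnit(glob, label = "globule"))
res

chan <- syntheticChannel(nChains = 6, perChain = 60, seed = 1)
fodStatus(makeUnit(chan, label = "channel"))
```

The globule sits deep in the soluble regime; the channel is far from the
centric ideal with the K scan at its membrane limit.

Fragment scoring reuses the parent profiles:

```{r fragment}
u <- makeUnit(chan, label = "channel")
t <- theoreticalProfile(u)
o <- observedProfile(u)
rad <- sqrt(residues(u)$x^2 + residues(u)$y^2)
lumen <- residues(u)$seqIndex[rad <= 12]
fragmentStatus(t, o, lumen, subsetLabel = "lumen")
```

## Design choices where the design was open

* **Effective atom over all heavy atoms** (backbone + side chain), the
  literal reading of "the atoms that make up the residue"; hydrogens are
  excluded because depositions carry them inconsistently.
* **Principal-axis alignment before evaluating the separable Gaussian** —
  the formula assumes a molecule-aligned frame; refitting per unit makes T
  invariant under rigid motion.
* **Fragment reference R is uniform over the fragment length**, consistent
  with the renormalisation of T and O.
* **Interface partners are the other chains of the whole assembly**, so a
  single-chain unit is scored against its neighbours in the complex.
* **The analysis interface is the function surface plus a thin CLI**
  (`inst/cli/fodm.R`, verbs `analyze`/`compare`/`synth`/`plot`) over YAML
  configurations; every run logs the defaults it relied on and an md5 of
  each input.

## Known limitations

* Absolute RD/K values are intrinsic-scale-dependent; comparisons across
  scales are not meaningful. Published values can be approached but not
  guaranteed without the original scale.
* The K optimiser is an exhaustive grid, not analytic; resolution is the
  grid step (0.1 by default).
* Zone assignment is purely geometric (slab along a configured axis); no
  automatic membrane detection is attempted.
* No structure repair, hydrogen placement, assembly generation, or
  secondary-structure recomputation: deposited annotations (or explicit
  overrides) are used as-is.
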