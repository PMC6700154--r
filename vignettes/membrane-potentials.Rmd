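---
title: "Membrane statistical potentials: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane statistical potentials: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mempot)
```

## The model

`mempot` derives knowledge-based, distance-dependent residue pair
potentials separately from the transmembrane (TM) and extramembrane
(EM) regions of membrane-protein structures.  The underlying
assumption is the usual inverse-Boltzmann one: frequencies of
observation of a structural feature in a database behave like Boltzmann
probabilities of an effective energy, so

$$\Delta W(s_1, s_2, d) = -k_BT \,\ln
  \frac{n(s_1,s_2,d)\,n}{n(s_1,s_2)\,n(d)},$$

and analogously $\Delta W(s,d)$ with single-type marginals.  The
feature here is the distance $d$ between the *side-chain geometric
centers* of two residues more than one position apart along the chain;
$d$ is discretized into 23 bins of 0.3 Å covering $[3.0, 9.9)$ Å plus
one overflow bin for everything beyond.  Deriving the same potential
twice — once from TM residue pairs, once from EM pairs — captures how
the lipid and water environments reweight each interaction type.

Because both regions carry all terms of the formula ($n(d)$ and $n$
included), each potential is internally referenced against its own
region's distance distribution; TM and EM tables are therefore
directly comparable bin by bin.

### Units and temperature

$k_BT$ defaults to 0.5925 kcal/mol ($T = 298.15$ K).  The temperature
only scales the energy axis; it is configurable in every derivation
function.  These are *effective statistical* energies: no claim is
made that they match calorimetric folding free energies.

## Coping with sparse counts

Membrane-protein datasets are small, and splitting them into TM and EM
parts makes the occurrence tables sparse.  Two layers address this.

**Occurrence threshold.** A bin whose occurrence count is below 10 is
set to zero and masked; masked bins contribute exactly zero to every
downstream energy.

**Neighborhood smoothing.** Counts in each regular bin are replaced by
a weighted sum over the four neighboring bins on each side with
weights $(3/4)^i$, truncated at the boundaries.  The overflow bin is
excluded from the neighborhood in both directions: it aggregates an
unbounded distance range, and mixing it with 0.3 Å bins would distort
the tail of every curve.

**Ordering of the two layers.** The threshold is evaluated on the
*raw* counts by default (`threshold_on = "raw"`).  The two layers do
not commute, and the choice matters: smoothing spreads kernel tails
into bins that contain essentially no genuine observations, so a
threshold applied to smoothed counts would trust bins whose entire
content is leakage from a neighbor four bins away.  In practice this
shows up as spurious deep minima at the short-distance edge of group
potentials, where the reference $n(d)$ is small; thresholding raw
occurrences masks exactly those bins.  The alternative
(`threshold_on = "smoothed"`) is retained as an option because the
smoothed counts are the numbers the potential formula actually
consumes, and on dense tables the two choices agree.

## Group potentials

Amino acids with similar physicochemistry (the seven groups: Lys/Arg,
Glu/Asp, Phe/Tyr/Trp, Ile/Val/Leu, Gln/Asn/Ser/Thr, Gly/Ala, Cys/Met)
can be pooled into a single potential.  Pooling respects size: the
distance of each pair is shifted down by the side-chain-radius excess
of both members over the smallest member of their group before
binning, so a Lys–Glu and an Arg–Asp salt bridge land in the same bin.

Side-chain radii (mean distance of side-chain heavy atoms to their
centroid) are estimated from the input structures when full-atom
detail is available (`estimate_residue_radii()`), with shipped
defaults computed from the package's idealized side-chain templates.

One design point deserves emphasis: for a pooled group pair the
numerator $n(g_1,g_2,d)$ and the pair marginal $n(g_1,g_2)$ come from
the shifted pooled counts, but the reference $n(d)$ and $n$ come from
the full, unshifted all-pair counts of the same region (smoothed with
the same kernel).  Using marginals of the pooled table itself would be
degenerate — with a single group pair, $n(d)$ would equal
$n(g_1,g_2,d)$ and the potential would vanish identically — so the
full-dataset distance distribution is the only consistent reference.

## Energies and the localization index

The folding free energy of a structure is the half-sum of the
potential over all eligible ordered pairs, and the per-residue
contribution $\Delta G^{i}$ is residue $i$'s half-share of every pair
it participates in; by construction $\sum_i \Delta G^{i} = \Delta W$
exactly, which the tests assert to $10^{-9}$ relative.  Per-residue
sums run over *all* partners in the structure regardless of the
partner's region label, because the classifier must score every
residue under both the TM and the EM tables.

Pairs are intra-chain by default (the energy sums index a single
sequence); an `inter_chain` flag includes all cross-chain pairs for
oligomeric bundles, and tables remember which policy produced them so
energies cannot silently mix policies.

Residue localization combines the four per-residue energies with a
log-length term and an intercept,

$$I^i = \alpha_1\Delta G^{i,TM}_{sd} + \alpha_2\Delta G^{i,TM}_{sds}
      + \alpha_3\Delta G^{i,EM}_{sd} + \alpha_4\Delta G^{i,EM}_{sds}
      + \alpha_5 \ln N + \alpha_6,$$

smoothed along the chain over a five-residue window with a $1/2$
prefactor, $I^i_{sm} = \tfrac12\sum_{k=-2}^{2} I^{i+k}$.  The
prefactor is implemented literally rather than as a $1/5$ average; the
scale difference is absorbed by the threshold $\alpha_0$.  Windows
never cross chain boundaries, and at chain termini the truncated
window of $m$ residues is rescaled by $5/m$ so terminal indices stay
on the interior scale.  The natural log is used for the length term
(any base would be absorbed by $\alpha_5$).

### Fitting the seven parameters

Balanced accuracy is piecewise constant in the weights, so direct
seven-parameter BACC maximization is ill-posed (flat plateaus,
gradient-free jumps).  The fit is therefore two-stage: logistic
regression of the TM label on the five features pins the direction of
the index (coefficients negated so that low index ⇒ TM), and the
threshold $\alpha_0$ is then set by an exhaustive sweep over the
sorted unique smoothed-index values, maximizing training BACC with
ties broken towards the most balanced sensitivity/specificity and the
final threshold placed at the midpoint between neighboring scores.
The sweep is exact — a property test checks it against brute force on
$10^4$ residues.  An optional Nelder–Mead refinement of all seven
parameters on a sigmoid-smoothed BACC surrogate exists but is off by
default; on every dataset we generate it does not improve on the
two-stage fit.

### Strict leave-one-out

Evaluation removes the scored protein from *every* stage: its raw
counts are subtracted from the pooled tables before smoothing and
thresholding (subtraction must precede the threshold, which is not
linear; the tests verify bin-for-bin identity with full
recomputation), and the localization parameters are refitted on the
other proteins only.  Training proteins' features are computed under
their own leave-one-out potentials — the same protocol used for their
folding energies — so no protein's counts ever touch its own score.

## The synthetic generator

The generator emulates the statistical structure the method feeds on,
with no physical realism beyond it:

* **Geometry.** TM segments are ideal helices (1.5 Å rise, 100°/turn
  per residue) spanning a virtual slab, packed at 11.0 Å axis spacing
  with side-chain centers 4.0 Å off-axis, so facing centers of
  adjacent helices approach ~3 Å and the pair-distance distribution
  covers the whole binning range; β-barrel mode places strands on a
  cylinder.  EM segments are compact helical mini-bundles above and
  below the slab.  Gaussian noise (σ = 0.25 Å) is added to every
  center.
* **Composition.** Residue types are drawn i.i.d. from region-specific
  tables (aliphatic/aromatic-enriched in TM, charged/polar-enriched in
  EM) chosen to mirror the qualitative TM-vs-EM contrast of real
  membrane proteins.
* **Planted contacts.** Type–distance correlations are created by
  re-sampling residue types at spatially pre-selected close pairs
  (geometry is never distorted to force a contact).  Planted target
  distances are *group-frame*: a planted $(s_1,s_2)$ pair is placed at
  center distance $\text{target} + \delta(s_1) + \delta(s_2)$, since a
  salt bridge's contact geometry is fixed while the center distance
  grows with side-chain size.  Defaults plant aliphatic packing and
  salt bridges in TM and polar contacts and salt bridges in EM.
* **Determinism.** Every output is a pure function of (config, seed);
  per-protein seeds are derived from the dataset seed.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: backbone connectivity constraints between
segments, rotamer-level side-chain geometry, solvent accessibility
gradients, interface-depth composition gradients, sequence
correlation along the chain beyond segment labels, and real datasets'
redundancy structure.  Performance numbers on synthetic data
characterize the *pipeline*, not expected accuracy on OPM-annotated
structures; the benchmark machinery (`run_loo_benchmark`, the
`benchmark` CLI subcommand) reproduces the full protocol on any real
dataset the user supplies.

## Numerical choices and degenerate inputs

* Bin edges are guarded with a $10^{-9}$ Å epsilon so exact edge
  distances (e.g. 3.3 Å) land in the mathematically correct half-open
  bin despite floating-point subtraction.
* The smoothing weights are computed as $(3/4)^i$, which is exact in
  double precision; the impulse response is asserted bit-exactly.
* Sub-3 Å distances clamp into the first bin by default (clash
  artifacts should not silently vanish); a `discard` policy is
  available.  The same policy applies to group-shifted distances.
* Zero denominators or zero counts mask a bin rather than producing
  infinities; masked bins are exact zeros everywhere downstream.
* A dataset of one protein, held out, yields a fully masked zero
  potential; a held-out protein with no counts in a region leaves that
  region's table untouched.
* altLoc conformers resolve to highest occupancy (ties toward 'A');
  insertion codes flatten into consecutive per-chain indices; MSE/SEC
  and a few other common modified residues map to their parents, other
  het-residues are skipped; residues with no resolvable side-chain
  atoms fall back to Cα and are flagged.
* Unannotated residues default to EM — membrane proteins are annotated
  by their membrane-embedded segments, so the remainder is
  extramembrane by construction; `strict = TRUE` errors instead.
  Segment boundaries are taken at face value from the annotation.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
data: 50-protein datasets (~150 residues each, ~7,700 residues pooled)
for the leave-one-out classification studies, 200 proteins for
group-potential recovery of planted salt bridges, $10^6$ pair events
for the independence null, and 8–10-protein sets for the exactness
properties.  These sizes put every headline quantity in a regime where
its expected behavior is unambiguous while the full suite completes in
well under a minute of compute.

## Known limitations

* Potentials are pairwise and distance-only: no orientation terms
  (aromatic ring angles, cation–π geometry), no torsion or
  solvent-accessibility potentials.
* The TM/EM split is binary; interface regions inherit whichever label
  the annotation gives them, and the EM side pools cytoplasmic and
  extracellular residues.
* Counts from different proteins are pooled without weighting;
  redundancy control is the responsibility of the input list.
* The localization model is linear in the four energies; systematic
  curvature (e.g. barrel-specific interaction strengths) is only
  addressed by deriving topology-restricted potentials from a filtered
  input list.
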