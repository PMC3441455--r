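---
title: "Methods: equilibrium folding-binding landscapes on a homodimeric receptor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: equilibrium folding-binding landscapes on a homodimeric receptor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Intrinsically disordered peptides often fold only upon binding a partner
protein. For a symmetric homodimeric receptor with two equivalent binding
pockets — the situation of calcium-loaded S100B binding its disordered
targets — the equilibrium picture of this coupled folding-binding process
can be characterised with a small set of per-frame observables, free-energy
surfaces over those observables, a three-way state classification
(bound / intermediate / unbound), probabilistic residue contact maps per
state, and structural clustering of the intermediate ensemble. `bindscape`
implements that entire analysis stack, together with a coarse-grained
Metropolis Monte Carlo sampler that produces genuine reversible
binding/unbinding trajectories to feed it, and a synthetic-data generator
with planted ground truth so every stage is testable without downloads.

# Observables

For a frame with peptide heavy-atom, mass-weighted center of mass $r_p$ and
the two symmetry-related reference center-of-mass points $c_1, c_2$ (the
bound-pose peptide COM at each pocket), the site distance is

$$\Delta = \min_s \lVert r_p - c_s \rVert,$$

with the displacement taken under the minimum-image convention when the
simulation box is periodic. Two residues are *in contact* when at least two
heavy-atom pairs are separated by strictly less than 4.5 Å; the pocket
contact count $N_c$ sums contacts between peptide residues and the declared
pocket positions on either monomer (a compact peptide cannot straddle both
pockets of the dimer at once; frames are nonetheless counted against both
copies so the symmetry is never broken by bookkeeping).

Helical content is assigned from backbone dihedrals: a residue is helical
iff $\phi \in (-100^\circ, -30^\circ)$ and $\psi \in (-80^\circ, -5^\circ)$;
terminal residues, whose $\phi$ or $\psi$ is undefined, are excluded from
the denominator. This window covers the core of the $\alpha$/3$_{10}$/$\pi$
classes that hydrogen-bond-pattern assigners group as "helix", but it does
not detect turns, which such assigners often fold into the helix class —
helicity values here are therefore slightly conservative relative to a
STRIDE/DSSP-based analysis of the same frames.

Structural similarity uses two deviations: `rmsd_optimized()` is the
least-squares superposed RMSD (Kabsch, proper rotations only — verified in
the tests against an independent quaternion implementation and `bio3d`),
and `rmsd_nonoptimized()` is the plain coordinate RMSD with no fitting.
The optimized value never exceeds the non-optimized one; this inequality is
exercised as a property test. Ensemble diversity is the mean optimized RMSD
over all unordered pairs of members.

# The sampler

## Resolution and degrees of freedom

The engine represents each residue by four beads: backbone N, CA, C and a
CB pseudo-side-chain bead. Three beads per residue would suffice for
residue-level contacts, but the standard $\phi/\psi$ dihedrals — on which
both the helix observable and the helix-propensity energy are defined —
require the backbone carbonyl carbon, so the backbone is kept complete and
the side chain is the single pseudo-atom. The peptide is fully flexible
(rigid-body moves plus single-dihedral pivot moves with ideal bond lengths
and angles and a planar trans peptide bond); the receptor moves by small
per-residue rigid jiggles and is held near its native reference by the
restraint below.

## Energy function

The energy is an explicitly declared toy model, not a reimplementation of
any published force field; it exists so the analysis stages can consume
trajectories with genuine reversible binding. Terms, all in reduced units
of $k_B T_\mathrm{ref}$:

* **Excluded volume**: $\varepsilon_{ev}[(\sigma/r)^{12} - 1]$ for
  $r < \sigma$ (default $\sigma = 3$ Å), capped at a finite value below a
  hard core of 1.5 Å. Overlaps that reach the cap are counted and reported,
  never infinite.
* **Native wells (Gō-type)**: Gaussian wells
  $-\varepsilon_{go}\, d_k\, e^{-(r - r_{0,k})^2 / 2 w_k^2}$ on an explicit
  pair list with per-pair depth factors $d_k$ and widths $w_k$, where
  $r_{0,k}$ is the pair distance in the bound reference. Pairs found
  against one monomer are mirrored onto the symmetry-equivalent atoms of
  the other, so both pockets carry identical wells.
* **Helix propensity**: $-\varepsilon_h$ per interior peptide residue whose
  $(\phi,\psi)$ lies in the helical window (the same window as the
  observable).
* **Screened Coulomb**:
  $\varepsilon_c\, q_i q_j\, e^{-r/\lambda}/r$ between charged CB beads
  (Lys/Arg $+1$, Asp/Glu $-1$), screening length $\lambda = 8$ Å, cutoff
  25 Å.
* **Receptor restraint**: $k_r \sum_i \lVert r_i - r_i^{ref} \rVert^2$ over
  receptor CA atoms only — i.e. $k_r M\,\mathrm{RMSD}^2_\mathrm{non-opt}$ —
  never applied to the peptide. The quadratic form is the natural convex
  realisation of a non-optimized-RMSD penalty. With the default
  $k_r = 2$ the restraint contributes well under a quarter of the total
  energy magnitude on the default system while the receptor CA deviation
  stays below ~1 Å; both properties are asserted in the acceptance tests.

The receptor additionally carries internal native wells between its own
CA/CB beads (depth factor 2), which keep the homodimer folded while backbone
and side chains stay flexible and give the physical energy a magnitude
against which the restraint share is meaningful.

## The binding funnel: sparse anchors

The peptide-receptor well list defaults to a *sparse anchor* construction
rather than a dense contact map: the two peptide beads nearest the pocket
(around the 1/3 and 2/3 chain positions) are each tied to their few nearest
pocket beads with broad wells ($w = 3$ Å, depth factor 4). Dense
residue-level wells were rejected deliberately: satisfying tens of wells
simultaneously requires the full native orientation and helicity, an
entropic bottleneck so severe that a desk-scale run never exchanges between
bound and unbound states. Sparse anchors keep rotation about the anchor
axis and the tail conformations free in the bound state, which is what
makes binding *reversible* in $10^7$ Monte Carlo steps — the property the
analysis relies on. A dense `mode = "contact"` list remains available for
experiments. A consequence of the anchors-only default, combined with the
entropic weight of the large simulation volume (a 150 Å periodic cube),
is that the landscape is intermediate-rich: the equilibrium fraction of
frames with $\Delta \le 5$ Å peaks well below one half. The temperature
selection protocol therefore scans a short ladder and, when no ladder
temperature reaches a 50% bound fraction, runs at the ladder temperature
whose bound fraction comes closest — the reversibility requirement, not
the exact 0.5 occupancy, is what the analysis needs.

## Moves, acceptance and reproducibility

Move types and default weights: peptide rigid translation (0.25, Gaussian
step 1.5 Å), rigid rotation (0.15), *teleport* — re-insertion at a uniform
random box position with a random orientation (0.10; a symmetric proposal
that makes the large box ergodically tractable), pivot of a single
$\phi$ or $\psi$ (0.25, Gaussian 25°), and receptor residue jiggle (0.25).
Energies are updated incrementally per move; a full recomputation is
asserted against the running value (relative tolerance $10^{-8}$) at fixed
intervals and the cache is refreshed. All randomness flows through R's RNG,
so a seed reproduces the accept/reject sequence, the trajectory, and every
downstream table bit for bit.

Simulated tempering for free peptides is a composite kernel: fixed-
temperature engine segments alternate with Metropolis temperature moves
$P(k \to k') = \min(1, e^{-(\beta_{k'} - \beta_k)E + (g_{k'} - g_k)})$.
Weights $g_k$ are adapted during burn-in from running per-temperature mean
energies via the trapezoidal free-energy estimate and frozen for
production. With a single rung the algorithm reduces exactly to fixed-
temperature sampling. The same acceptance/weight logic is validated in the
tests on a 1D harmonic potential where $\langle E \rangle = 1/(2\beta)$ is
known in closed form.

# Landscapes and errors

Free-energy surfaces are plain equilibrium histograms,
$F_b = -k_BT \ln(n_b/N)$, shifted so the minimum over occupied bins is
zero. Empty bins are masked, never interpolated or smoothed; samples
outside the bin range are clamped into the edge bins and counted. Default
bin widths: 1 Å in $\Delta$, 1 contact in $N_c$, 0.05 in helix fraction.
Statistical errors are delete-one jackknife over independent runs (the
resampling unit is the run, never the frame, since frames within a run are
correlated): $\sqrt{(m-1)/m \sum_i (\theta_{(-i)} - \bar\theta)^2}$. For a
linear estimator this reduces algebraically to the classical standard
error of the mean, which the tests assert exactly; a Monte Carlo
calibration against the known sampling error of a Gaussian mean is also
part of the acceptance suite. A single run yields missing-flagged errors,
never zero.

# States, contact maps, involvement

A frame is **bound** iff $\Delta \le \Delta_b$ and $N_c \ge n_b$,
**unbound** iff $\Delta \ge \Delta_u$, and **intermediate** otherwise —
the intermediate state is defined by exclusion, as everything neither
unbound nor fully bound. Defaults $(\Delta_b, n_b, \Delta_u) =
(5\,\text{Å}, 20, 25\,\text{Å})$ sit in the descriptive ranges reported
for such systems; all three are explicit configuration entries, and the
synthetic generator carries its own matched thresholds. Classification is
monotone in $\Delta_b$ (a property test) and refuses frames with missing
$\Delta$ rather than silently dropping them.

Per-state contact maps give, for every (peptide residue, pocket position)
pair, the fraction of state frames in contact; the two monomers' pocket
copies are merged by OR into one row set, which is order-independent under
the site-label swap. Pocket involvement summarises, per pocket position,
the mean number of peptide residues it contacts, with jackknife errors
when run identifiers are available. Residue labels use the original
author/PDB numbering carried through `orig_resno`, so outputs read like
the field's figures.

# Clustering

State ensembles are clustered by agglomerative complete linkage under an
RMSD metric, merging while the inter-cluster maximum distance is strictly
below the cutoff. This guarantees that within every returned cluster all
pairwise distances are below the cutoff — asserted post hoc on every
output. Ties are broken by smaller linkage distance, then smaller lower
cluster index, making the partition deterministic and reorder-invariant up
to relabeling. The default clustering distance is the peptide backbone
RMSD after superposing each frame on the receptor CA reference (no peptide
superposition), so clusters separate both binding location and peptide
conformation; pairwise peptide superposition and raw-coordinate variants
are switchable. Medoids minimise the summed distance to other members,
ties to the lowest frame index. The implementation is cross-checked in the
tests against both a brute-force $O(n^3)$ agglomerative oracle and
`stats::hclust`.

# The synthetic generator

The generator emulates the *statistical* structure of a folding-binding
study: a homodimeric receptor built from two identical helical monomers
related by an exact two-fold rotation, two symmetry-related site reference
points, a declared pocket (positions spaced two apart so that planted
bridges never graze an adjacent pocket member), and trajectories drawn
i.i.d. from a three-state mixture with planted occupancies (defaults 0.5 /
0.3 / 0.2). Bound frames dock a freshly built chain (per-residue Bernoulli
helicity) at site 1 or 2 with the site distance held inside the bound
threshold; intermediate frames sit in a peripheral zone between the
thresholds; unbound frames are uniform in the box beyond the unbound
threshold and away from the receptor. Planted contacts are realised
geometrically by bridging the peptide residue's CB bead just beyond the
partner pocket CB (guaranteeing the two-pair rule); untouched CBs stay on
the peptide, out of reach. A keep-out plane (with a flip about the chain
axis, which changes no dihedral) prevents coil kinks from creating
incidental contacts, so recovered probabilities equal the generator's own
Bernoulli bookkeeping up to binomial noise. Frames are i.i.d. rather than
Markovian because every analysis here is equilibrium-frequency based.

What the generator does *not* emulate: physical dynamics, solvent,
realistic side-chain packing (a bridged CB is geometrically detached from
its backbone), or correlated frames. Passing the end-to-end recovery tests
therefore demonstrates correctness of the analysis bookkeeping — state
definitions, merging, frequency estimation, error bars — not force-field
realism.

# Numerical choices and degenerate inputs

* PDB coordinates round-trip at the format's 10⁻³ Å precision; rereads of
  written files are exact fixed points. Observable tables round-trip
  bit-exactly through TSV with `NA` sentinels.
* The contact rule uses strict inequality at 4.5 Å; a pair at exactly the
  threshold never counts.
* Missing references yield missing observables (`NA`), never zeros; a
  single run yields missing jackknife errors, never zeros.
* Superposition uses SVD with the determinant correction, so reflections
  are never returned even for degenerate point sets.
* Empty states produce missing-flagged maps with a warning; empty
  selections, non-symmetric distance matrices, mismatched atom counts and
  non-ergodic move weights are hard errors.
* Problem sizes used throughout the test and acceptance runs — a 20-residue
  monomer, 12-residue peptide, $2\,000$–$4\,000$-frame synthetic
  trajectories in 10 run blocks, $10^6$–$10^7$-step Monte Carlo chains —
  were chosen as the smallest sizes at which every statistical check is
  comfortably resolved; all of them are configuration, not constants.

# Known limitations

* The toy energy is a declared stand-in: absolute free energies,
  temperatures and bound-pose geometries carry no physical meaning beyond
  the reduced-unit model; only the statistical machinery around them is
  meant to transfer to real force fields.
* Helicity by dihedral windows omits turns (see above).
* No reweighting across temperatures (WHAM/MBAR) is attempted; surfaces
  are single-temperature histograms.
* Kinetics are out of reach by construction — teleport moves scramble any
  notion of physical time, and state assignment is purely equilibrium.
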