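---
title: "Linking flavin-pocket dynamics to vibronic spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking flavin-pocket dynamics to vibronic spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lovpocket)
```

## The scientific problem

LOV-based fluorescent proteins (iLOV and its relatives) carry a flavin
mononucleotide (FMN) chromophore whose photophysics is tuned by the protein
pocket around the isoalloxazine ring. Two pocket features matter for
fluorescence. First, the conserved glutamine and asparagine side chains that
hydrogen-bond the ring are mobile: on the hundreds-of-nanoseconds scale they
exchange between an *in* orientation (heavy-atom donor–acceptor distance
below 4 Å) and an *out* orientation (above 5 Å), and the mix of these pocket
conformations modulates the vertical excitation energy. Second, apolar side
chains can pack ("crowd") against the ring after a rotamer flip, rigidifying
the chromophore and slightly reducing the intermolecular reorganization that
sets the Stokes shift.

`lovpocket` implements the post-simulation analysis that connects these two
observations: geometric observables from trajectory coordinates, density
clustering of pocket conformations, a van der Waals pseudo-density overlap
metric for crowding, and vibronic absorption spectra and Stokes-shift tables
from per-structure electronic energies. A synthetic-data generator with
known ground truth replaces microsecond MD and QM/MM outputs, so every
stage is testable end to end.

## Geometric observables

The trajectory container is a `frameset`: a fixed atom roster plus an
`n_frames × 3·n_atoms` coordinate matrix (Å), read from multi-model PDB
(via bio3d) or plain XYZ. Three observables are computed from it:

* **Labeled distances** (`compute_distances`): Euclidean heavy-atom
  distances for a user-supplied table of (residue number, atom name) pairs,
  the d1–d22 style map of the pocket H-bond network. The atom pairs are
  input data, not hard-coded: the map is structure-specific, and the same
  code must run on toy systems.
* **Side-chain dihedrals** (`compute_dihedral`): the standard signed
  torsion (bio3d's convention, verified against the cross-product
  definition). A frame with a collinear atom triple yields a flagged
  missing value rather than an abort — long trajectories should survive
  isolated pathologies.
* **Ring RMSD** (`compute_ring_rmsd`): least-squares rigid superposition
  (rotation + translation, reflections excluded) of a *fit* set onto a
  reference, RMSD evaluated over a *target* set without refitting. This is
  the "align on the backbone, measure the ring" scheme used for
  chromophore mobility.

## Pocket conformations

`classify_states` applies the two thresholds: *in* below 4 Å, *out* above
5 Å, *intermediate* in the gap. A frame is **OUT** when any tracked residue
is out, **IN** when all are in, and unassigned when an intermediate residue
blocks the decision. Frames in the 4–5 Å gap are excluded from in/out
population statistics: only the two outer regimes are physically defined.

Clustering happens in two stages, in the order PCA then density clustering:

1. `fit_pca` performs a mean-centered covariance eigendecomposition of the
   selected distance columns. Features are used **unstandardized**: they
   share units (Å), and standardizing would inflate the near-constant
   persistent H-bonds relative to the switching ones. The default variance
   target is 0.9; with two-state features the leading components saturate
   quickly, and 0.9 keeps the switching structure while discarding noise
   dimensions. Both the target and the retained count are recorded on the
   model object.
2. `cluster_density` runs a hierarchical density-based clustering with a
   noise label: mutual-reachability distances (core distance = distance to
   the `min_samples`-th nearest neighbor), a single-linkage hierarchy
   (`stats::hclust`), a condensed tree at `min_cluster_size`, and
   excess-of-mass cluster selection. Two deliberate choices:
   * The hierarchy **root is selectable**, so degenerate inputs (one tight
     blob, or all points identical) return a single cluster covering all
     points instead of all-noise.
   * Heights of zero (duplicated points) are handled by flooring the
     height at 10^-6 of the smallest positive merge height before taking
     λ = 1/h, which keeps stabilities finite.

   `min_cluster_size` defaults to 1% of the frames at the pipeline level,
   and clusters whose population falls below `min_population = 0.01` are
   dissolved into noise after clustering — sub-1% conformations are too
   poorly sampled to characterize. Cluster ids are reassigned by
   decreasing population (0 = largest) for determinism; populations are
   fractions of *all* frames, so retained + noise + excluded sums to 1.

`label_clusters` applies a majority vote of frame classes (ties are
unassigned), and `sample_representatives` draws a uniform, seed-reproducible
sample without replacement (default 10 per cluster) — the structures a
subsequent electronic-structure step would consume.

## Crowding metric

Each fragment's pseudo-electronic density is a sum of **unit-normalized**
isotropic 3-D Gaussians on its heavy atoms, with σ equal to the element's
van der Waals radius (Bondi set by default: C 1.70, N 1.55, O 1.52, S 1.80,
P 1.80 Å; overridable by CSV). Unit normalization makes the overlap
integral well-defined; hydrogens are excluded throughout. The raw overlap
of two fragments has the closed form

$$ O_{AB} = \sum_{i \in A}\sum_{j \in B}
   \bigl(2\pi(\sigma_i^2+\sigma_j^2)\bigr)^{-3/2}
   \exp\!\left(-\frac{d_{ij}^2}{2(\sigma_i^2+\sigma_j^2)}\right), $$

which the tests verify against brute-force 3-D grid quadrature to 10^-6
relative. The default reported quantity is the Carbó-style normalized index
$O_{AB}/\sqrt{O_{AA}O_{BB}} \in [0,1]$, comparable across fragments of
different atom counts; raw values are also emitted since the corresponding
published distributions could be either.

## Vibronic lineshapes and spectra

The homogeneous absorption lineshape uses the second-order cumulant
expansion in the displaced harmonic oscillator (DHO) formalism, for which
it is exact. With Huang–Rhys factors $S_k$ and frequencies $\omega_k$,

$$ g(t) = \sum_k S_k\left[\coth\!\frac{\hbar\omega_k}{2k_BT}
   (1-\cos\omega_k t) + i\sin\omega_k t\right],\qquad
   \sigma(\omega) \propto \mathrm{Re}\!\int_0^\infty
   e^{i(\omega-\omega_{00})t - g(t) - \Gamma t}\,dt. $$

Numerical choices:

* The time integral is evaluated by FFT. The time step is set to four
  times the Nyquist requirement of the widest grid frequency, and the
  transform length grows until the Lorentzian damping has decayed
  (`Γ·t_max ≥ 30`); an undamped tail raises a warning.
* The grid is **relative to the 0-0 origin**; the vertical excitation
  energy sits at +λ. Since ensemble spectra are anyway rigidly shifted and
  max-normalized for plotting, the absolute-position convention is free
  and is recorded in the metadata.
* The analytic total area of the half-Fourier transform is π (because
  g(0) = 0), which gives a cheap coverage check: if the on-grid area falls
  below 99% of π the grid is too narrow and the call errors rather than
  silently clipping Lorentzian tails. The default grid spans
  [-8000, λ+8000] cm^-1 for this reason.
* Temperature defaults to 300 K (the simulation temperature); `T = 0`
  gives the zero-temperature limit used by the Franck–Condon oracle tests,
  where single-mode peak areas must follow the Poisson progression
  $e^{-S}S^n/n!$. Homogeneous broadening is Lorentzian with
  Γ = 100 cm^-1 by default (not stated by any reference convention;
  configurable and logged in the metadata).

`huang_rhys_from_gradient` implements the vertical-gradient route
$S_k = g_k^2/(2\hbar\omega_k^3)$ (atomic units internally; frequencies
supplied in cm^-1), with the two-route identity
$\Delta_k = g_k/\omega_k^2$, $S_k = \omega_k\Delta_k^2/2$ used as an
independent oracle in the tests. Huang–Rhys factors are computed once per
system and shared across snapshots.

`ensemble_spectrum` sums $|\mu_{01}^{(j)}|^2\,\sigma(\omega-\omega_{01}^{(j)})$
over records (1 eV = 8065.544 cm^-1); dipole units are arbitrary but must
be consistent, since spectra are normalized downstream.
`weighted_average_spectra` forms the population-weighted average on a
common grid, and `normalize_and_shift` applies the plotting convention
(maximum exactly 1, rigid shift, both recorded in metadata).

`stokes_table` computes per-record shifts `(EXC−EMI)·8065.544`, averages
within clusters **before any rounding**, and adds a population-weighted
row; `format_stokes_table` applies the display convention (2-decimal eV,
integer cm^-1). `stokes_consistency` checks the rounding-bound invariant:
a reported integer shift can differ from the shift recomputed from rounded
eV entries by at most ≈ 81 cm^-1 (0.01 eV).

## The synthetic generator

`synthetic_config` defines the study conditions; its defaults are fixed
once:

* Side-chain dynamics: discrete-time Markov chains on the frame grid
  (exponential dwell approximation), mean dwell 250 ns per state at 1 ns
  spacing — the simplest process matching the observed 200–300 ns
  switching. In planted-class mode a single hidden chain over
  conformational classes has exactly the configured populations as its
  stationary distribution (`P(c→c') = α·pop(c')`), which is how the
  parameter-recovery tests plant 78/17/5% mixtures. Population-recovery
  tests shorten the class dwell (4–10 ns) so that a few thousand frames
  contain many independent residence periods; with 250 ns dwells the
  standard error of an empirical population at 5000 frames would exceed
  the recovery tolerance for purely statistical reasons.
* Distances: state-conditional Gaussians truncated at 1.5 Å (no
  unphysical overlaps); in-state 2.9 ± 0.2 Å, out-state 6.5 ± 0.8 Å,
  straddling the 4/5 Å thresholds with a clear gap. Two always-formed
  "stable" H-bond columns pad the feature set the way persistent pocket
  contacts do.
* Embedding: acceptor pseudo-atoms on a fixed scaffold, donors displaced
  along an axis, so the distance ↔ coordinate round trip is exact and
  files stay tiny.
* Energies: class-conditional Gaussians (default IN 3.22/2.82 eV,
  OUT 3.27/2.88 eV, sd 0.02 eV), anchoring the ~0.05 eV (~400 cm^-1)
  blue shift on loss of the glutamine H-bond; records are redrawn until
  excitation exceeds emission.
* Modes: 250, 1360 and 1560 cm^-1 with S = 0.35, 0.45, 0.25 — a compact
  flavin-like set producing the characteristic two-band vibronic envelope
  (≈ 2000 cm^-1 apart) with λ ≈ 1090 cm^-1.
* `generate_crowding_frames` builds a planar fused-ring stand-in plus an
  apolar fragment; a crowded pocket is emulated by a small separation
  (3.5 Å) *and* small ring jitter (0.3 Å), a loose one by 5.0 Å and
  0.6 Å. The coupling is planted by construction — it encodes the
  crowding hypothesis (tighter packing, stiffer ring) rather than
  deriving it from forces.

What the generator does **not** emulate: force-field realism, water
bridging, correlated multi-residue rearrangements, anharmonicity, or
conformation-dependent transition dipoles. Passing tests therefore
demonstrate that the analysis recovers known structure from data with the
right statistical shape — not that it would resolve every feature of real
microsecond trajectories, where cluster counts and populations depend on
sampling.

## Pipeline

`validate_config`/`run_pipeline` orchestrate the stages from one YAML
config (defaults filled, unknown keys rejected by name). One config drives
all variants so the comparison uses identical parameters, and by default
the variants share the RNG seed: the comparison is then paired (common
random numbers), and planted mean differences — e.g. a 90 cm^-1 Stokes
offset — are recovered essentially exactly rather than within sampling
noise. Every output file carries the config MD5 hash. Distances are always
recomputed from the emitted coordinates rather than taken from the
generator, exercising the same path real trajectories would.

The test and example problem sizes (hundreds to a few thousand frames,
150-frame crowding series, 5000-frame clustering recovery) were chosen so
that statistical tolerances are met with comfortable margins at desk
scale; they are stated in the tests alongside the standard errors they
imply.

## Known limitations

* The density clustering is quadratic in frames (full distance matrix);
  beyond ~10^4 frames one would subsample or stride the trajectory first.
* No emission lineshape is computed (absorption only); Stokes shifts come
  from vertical energies, not from relaxed emission spectra.
* The in/out classification is threshold-based by design; borderline
  dynamics (persistent 4–5 Å distances) land in the unassigned pool
  rather than being modeled.
* XYZ input carries no residue information, so selector-based analyses
  need the PDB route or an explicit roster.
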