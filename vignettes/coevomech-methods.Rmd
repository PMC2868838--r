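---
title: "Connecting sequence coevolution to coarse-grained protein mechanics"
author: "coevomech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connecting sequence coevolution to coarse-grained protein mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevomech)
```

## The problem

Mutual information (MI) between columns of a multiple sequence alignment is a
standard signal of residue coevolution, but it says nothing about *why* two
positions coevolve.  One biophysically grounded explanation is mechanics: if
the contact between two residues carries a disproportionate share of the
molecule's native-state dynamics, sequence changes there are under selective
pressure.  `coevomech` quantifies that mechanical share with a reduced model
— a sequence-specific anisotropic network model (ANM) of the C-alpha trace —
and annotates every high-MI contact with the change in the model's covariance
matrix when that single contact is removed.  Plotting MI against this
mechanical impact separates contacts into four interpretable classes.

## Sequence layer

For alignment columns $i$ and $j$ with symbol frequencies $p_i(x)$, $p_j(y)$
and joint frequencies $p_{ij}(x,y)$,

$$ MI_{ij} \;=\; \sum_{x,y} p_{ij}(x,y)\,
   \log_2 \frac{p_{ij}(x,y)}{p_i(x)\,p_j(y)} . $$

Design choices:

* **Base 2.** All entropies and MI are in bits; the convention in the
  MI-coevolution literature.
* **Alphabet.** The 20 standard amino acids, plus the gap `-` as a full 21st
  symbol and one marker `X` collapsing every nonstandard residue (22 symbols
  total).  Treating the gap as a symbol means strongly gapped column pairs
  can carry MI through shared gap structure; that is deliberate and matches
  the expanded-symbol-set convention.
* **Plug-in estimator.** MI is computed from relative frequencies via
  $MI_{ij} = H_i + H_j - H_{ij}$, which is exact for plug-in frequencies and
  numerically cheaper than the double sum (the two are verified to agree in
  the test suite).
* **Null model.** The plug-in estimator is biased upward at finite sample
  size (roughly $(K-1)^2 / (2S\ln 2)$ bits for $K$ symbols and $S$
  sequences).  `mi_null_model()` estimates this bias empirically: each of
  `n_shuffles` (default 100) replicates permutes every column independently,
  destroying inter-column correlation while preserving the marginals, and
  the per-pair mean and standard deviation of MI over replicates are
  reported.  The permutation scheme is this package's contract for the null
  model; with one shuffle the standard deviation is undefined and reported
  as `NA`.

## Structure layer

Each residue is one bead at its C-alpha position.  Sequence-adjacent beads
within a chain interact through springs of strength $\alpha$ (default 82);
all remaining pairs within the distance cutoff (squared cutoff default
$169\,\mathrm{\AA^2}$, i.e. 13 Å) interact through springs
$\kappa_{ij}$ read from 20×20 amino-acid contact-strength tables — the
Miyazawa–Jernigan contact-energy magnitudes for intra-chain pairs and an
inter-chain table for pairs across chains, optionally averaged.  The
potential is harmonic in the deviations of pair distances from their native
values, so the Hessian has off-diagonal $3\times 3$ blocks
$-(\kappa_{ij}/s_{ij}^{0\,2})\, \mathbf{d}\mathbf{d}^T$
(with $\mathbf d$ the native separation vector), which is identically
$-\kappa_{ij}\hat{\mathbf u}\hat{\mathbf u}^T$ for the unit separation
$\hat{\mathbf u}$ — the two parameterizations sometimes described separately
are the same matrix.  Diagonal blocks cancel the row sums, so rigid
translations and rotations cost nothing and a connected structure has
exactly six vanishing eigenvalues.

The covariance matrix is the Moore–Penrose pseudo-inverse obtained from the
eigendecomposition by skipping the six rigid-body modes,

$$ M \;=\; \sum_{k>6} \lambda_k^{-1}\, v_k v_k^T , $$

and isotropic B-factors are the diagonal block traces
$B_i = \tfrac{8\pi^2}{3}\,(M^{ii}_{xx}+M^{ii}_{yy}+M^{ii}_{zz})$.  The
$8\pi^2/3$ prefactor is the crystallographic convention; it is isolated in a
single constant, and every relative profile is independent of it.

Numerical choices:

* The decomposition runs through `eigen(symmetric = TRUE)`; for a symmetric
  positive-semidefinite Hessian this coincides with the singular value
  decomposition.  Matrices are dense: $N$ is in the hundreds here, where
  dense decompositions are the honest baseline.
* Exactly the six smallest modes are skipped, but they are also asserted to
  be below $10^{-8}\lambda_{\max}$; a violation warns (disconnected or
  pre-stressed model) rather than fails, because the downstream SCPCP solver
  legitimately produces such states.
* Table entries are stored as magnitudes and validated positive, so
  $\kappa_{ij}>0$ always; nonstandard residues take the table's column
  means, which keeps the Hessian defined for e.g. selenomethionine without
  inventing chemistry.
* Sign convention and provenance of the shipped tables: the MJ file is a
  transcription of the published 1996 contact energies stored as absolute
  values.  The shipped inter-chain table is a clearly labelled **synthetic
  stand-in** — the MJ magnitudes scaled by 0.9 — because the published
  inter-chain table could not be redistributed here; it preserves the MJ
  rank ordering while mimicking uniformly weaker cross-chain contacts, and
  users with the published table can supply it as a custom matrix.

## Perturbation protocol

The mechanical weight of a contact $(a,b)$ is scored by removing that single
spring, recomputing the covariance $M^{(a,b)}$ by a full rebuild and
re-decomposition (a full rebuild; no low-rank updates), and taking

$$ f^{(a,b)} \;=\; \lVert M^{\mathrm{wt}} - M^{(a,b)} \rVert_F
   \;=\; \sqrt{\textstyle\sum_{kl} (M^{\mathrm{wt}}-M^{(a,b)})^2_{kl}} , $$

optionally restricted to the $3\times3$ blocks of a residue subset.  Point
mutations reuse the same machinery: only the residue identity changes, so
only the spring constants touching that site differ.

The batch protocol ranks the non-covalent contacts by MI (alignment columns
map to residues by chain-local position, so a homo-dimer's two chains read
the same columns; a user-supplied position map overrides this), breaks the
top $n$ one at a time, and classifies each pair after min–max normalizing MI
and $f$ over the batch by the nearest of the four corners (1,1), (0,1),
(0,0), (1,0) — labelled by their polar angles 45°, 135°, 225°, 315°.  Ties in
MI ranking are broken lexicographically by pair index, exact corner-distance
ties by the higher-MI then higher-FN corner, and a degenerate axis (zero
range over the batch) normalizes to 0.5; all three rules exist purely for
determinism.  Results are a pure function of (structure, parameters, pair
list): worker counts change wall time, never output, and this is tested.

## SCPCP thermodynamic extension

The self-consistent pair contact probability (SCPCP) approach of Micheletti
and co-workers makes the contact set thermodynamic: each non-covalent
contact carries an occupancy probability $p_{ij}$, springs are weighted
$\kappa_{ij} p_{ij}$, and the probabilities are determined by the model's
own fluctuations.  The original work leaves room for variants (weighting
the energy versus the spring constant; the exact occupancy functional).
This package fixes the following concrete scheme and isolates the update
rule in one replaceable function:

1. Build the Hessian with springs $\kappa_{ij} p_{ij}$ (covalent springs
   are never weighted — the backbone does not break).
2. Compute $M$ by pseudo-inversion.  If the weakened network has more than
   six vanishing modes, all of them are skipped (generalized
   pseudo-inverse) and the state is flagged *disconnected* — reported, not
   raised, because it is the physically meaningful unfolding signal.
3. Read off each contact's relative mean-square displacement per unit
   $k_BT$, $g_{ij} = \mathrm{tr}\,M^{ii} + \mathrm{tr}\,M^{jj} -
   2\,\mathrm{tr}\,M^{ij}$, and update with the two-state Boltzmann
   occupancy
   $$ p_{ij} \leftarrow
      \frac{1}{1 + \exp(-\beta\kappa_{ij} + \kappa_{ij} g_{ij}/2)} , $$
   the closed state (contact energy $-\kappa_{ij}$) weighed against the
   fluctuation penalty $\beta\kappa_{ij}\sigma^2_{ij}/2$ with
   $\sigma^2_{ij} = g_{ij}/\beta$, in which $\beta$ cancels out of the
   penalty term.  The logistic form keeps $p \in (0,1)$ at every sweep by
   construction — no clipping anywhere.
4. Mix old and new probabilities with damping weight 0.5 (conservative
   mixing avoids fixed-point oscillation) and iterate until the maximum
   probability change falls below `tol` ($10^{-6}$ by default, at most 200
   sweeps), starting from all probabilities 1.

Large $\beta$ (cold, stable) drives every $p_{ij}\to 1$ and the model
degenerates to the plain ANM — this is exact when probabilities are frozen
at 1, and tested at $10^{-10}$ relative tolerance.  Lowering $\beta$ lets
weak contacts soften the network, which inflates $g$ for their neighbours
and melts them too: a positive feedback that produces a sharp, finite-size
analogue of an unfolding transition in the mean contact probability.  The
transition point depends on the structure and sequence; `beta_scan()`
therefore warm-starts each point from the previous one to track a single
solution branch, and demonstration scans place their endpoints deep inside
the folded and melted regimes (e.g. $\beta = 50$ and $\beta = 0.2$ for the
30-residue-scale fixtures) rather than near the fixture-dependent
transition.  Near the transition the damped iteration can fail to settle
within the sweep limit; the state then reports `converged = FALSE` with its
residual rather than pretending.

## Synthetic fixtures, and what they do and do not show

`make_structure()` generates C-alpha traces with exact, seedable geometry:

* `chain` — collinear beads along x.  **Deliberately degenerate**: all
  spring directions are parallel, so the Hessian has $3N-(N-1)$ vanishing
  modes, not six.  It exists for format and round-trip work; the test suite
  asserts its degenerate mode count as documentation of the physics.
* `helix` — alpha-helical geometry (2.3 Å radius, 1.5 Å rise, 100°/residue,
  rescaled to the 3.8 Å C-alpha spacing): the minimal generically rigid
  "chain-like" fixture.
* `ring` — a closed ring with an alternating ±0.5 Å out-of-plane pucker (a
  flat ring would leave all spring directions in a plane, giving $N$ free
  out-of-plane modes).  Note the ring-closing pair enters as a non-covalent
  contact, not a covalent one.
* `dimer` — two parallel helical chains A and B, 8 Å apart, for interchain
  and chain-selection work, including a 99-residues-per-chain instance at
  the scale of the HIV-1 protease homo-dimer (the coordinates are
  synthetic; analyzing the real structure requires the user to download
  it).
* `globule` — self-avoiding random growth at 3.8 Å steps with a 3.5 Å
  minimum separation, biased toward the centroid, accepted only if the
  contact graph at the default cutoff is connected.

`make_alignment()` draws columns independently and uniformly over the 20
amino acids except for planted pairs, where with probability `coupling` the
second column is a fixed permutation image of the first.  At coupling 1 the
planted MI equals the column entropy (≈ 4.3 bits at large $S$), far above
the finite-sample bias floor, and top-1 MI contact selection recovers the
planted contact in essentially every replicate at $S = 500$.

These fixtures validate the *machinery*: mode counts, pseudo-inverse
identities, estimator algebra, determinism, recovery of planted signal.
They do not emulate real evolutionary data — no phylogenetic correlation,
no conservation gradients, no gaps, no structural realism beyond spacing
and excluded volume — so passing tests demonstrate correctness of the
computation, not biological performance of MI as a coevolution detector.

## Problem sizes

The shipped tests and the acceptance script run on 5–30-residue fixtures
(plus the 99-per-chain dimer for parsing), 20-column alignments of up to
2000 sequences, batches of ~10 broken contacts, and 20-replicate recovery
experiments; at these sizes the full suite completes in seconds.  The
same code paths scale to the hundreds of residues and tens of thousands of
sequences of a real protease study; the batch protocol parallelizes over
contacts with fork-based workers.

## Known limitations

* The inter-chain table shipped is a synthetic stand-in (see above).
* No APC or phylogenetic correction of MI; the shuffle null model addresses
  finite-sample bias only.
* Full re-decomposition per perturbation is $O(N^3)$ per contact; no
  low-rank updates.
* The SCPCP update rule is one defensible member of a family; its
  quantitative outputs should not be read as reproducing any particular
  published SCPCP number.
* PDB parsing is C-alpha-only by design; no mmCIF, no biological-assembly
  expansion.
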