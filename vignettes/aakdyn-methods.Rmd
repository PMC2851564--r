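---
title: "Coarse-grained dynamics and communication analysis with aakdyn"
author: "aakdyn maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained dynamics and communication analysis with aakdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aakdyn)
```

## Scope and models

`aakdyn` implements the coarse-grained dynamics toolchain used to study
amino acid kinases such as the *E. coli* NAGK homodimer: elastic-network
normal mode analysis at C-alpha resolution, comparison of intrinsic modes
with crystallographic conformational changes, a Markov model of
intramolecular signalling, and subsystem normal mode analysis for
comparing slow modes across protein-family members. Every stage runs on
either real PDB structures or deterministic toy structures with known
mechanics, so the whole pipeline is testable offline.

### Gaussian network model (GNM)

The protein is a network of nodes at the C-alpha positions. Node pairs
within a cutoff distance $R_c$ are joined by springs of uniform constant
$\gamma$. The $N \times N$ Kirchhoff (connectivity) matrix $\Gamma$ has
$\Gamma_{ij} = -\gamma$ for contacting pairs and a diagonal fixed by zero
row sums. Eigen-decomposition $\Gamma = \sum_k \lambda_k u_k u_k^\top$
yields one zero mode on a connected network; the mean-square fluctuation
of node $i$ is

$$\langle \Delta R_i^2 \rangle \;=\; c \sum_{k \ge 1} \lambda_k^{-1}
  (u_k)_i^2 , \qquad c = 3 k_B T / \gamma,$$

and cross-correlations replace $(u_k)_i^2$ by $(u_k)_i (u_k)_j$. Predicted
B-factors are $8\pi^2/3$ times the MSF, uniformly rescaled so their mean
matches the experimental mean; the Pearson correlation reported alongside
is scale-invariant, so the unknown $\gamma$ never matters.

### Anisotropic network model (ANM)

The ANM penalizes changes of the scalar inter-node distance. Its
$3N \times 3N$ Hessian has $3 \times 3$ off-diagonal super-elements
$-\gamma\, \hat r_{ij} \hat r_{ij}^\top$ for contacting pairs (unit
inter-node vector $\hat r_{ij}$) and diagonal blocks fixed by zero block
row sums. A non-degenerate structure has exactly six zero modes (rigid
translations and rotations) and $3N-6$ internal modes with directional
information. Mode numbering throughout the package excludes zero modes:
"mode 1" is always the slowest internal mode.

### Overlap with observed conformational changes

Given open and closed conformations, the deformation vector $\Delta r$ is
the 3M difference over mapped C-alphas after least-squares rigid
superposition (Kabsch, proper rotation enforced), which removes the six
external degrees of freedom. The agreement of mode $k$ with the observed
change is the correlation cosine
$\cos\theta_k = u_k \cdot \Delta r / (|u_k| |\Delta r|)$ and the
cumulative overlap of the $m$ slowest modes is

$$\mathrm{CO}(m) = \Big( \sum_{k=1}^m \cos^2\theta_k \Big)^{1/2},$$

which is non-decreasing and reaches 1 over the complete internal basis.
For a random deformation the expected $\cos^2\theta_k$ is $1/(3M-6)$,
which the test suite verifies by simulation; values far above that line
indicate that the structure is predisposed to its functional transition.
Conformers along a mode are generated as
$R^\pm = R^0 \pm s_k \lambda_k^{-1/2} u_k$; by default $s_k$ is chosen so
the C-alpha RMSD from $R^0$ is 1 Å. When an all-atom source structure is
supplied, all atoms of a residue are displaced rigidly by the residue's
C-alpha component; no energy minimization is attempted (that step belongs
to an external MD package and is out of scope here).

### Markov model of communication

Residue interactions are weighted by heavy-atom contact counts:
$a_{ij} = N_{ij} / \sqrt{N_i N_j}$, where $N_{ij}$ counts atom pairs
within 4 Å and $N_i$ is the heavy-atom count of node $i$. Hydrogens are
ignored everywhere; ligand nodes (one per non-water hetero residue)
participate exactly like residues when enabled. With degrees
$d_j = \sum_i a_{ij}$, the transition matrix $m_{ij} = a_{ij}/d_j$ is
column-stochastic, and the hitting time from node $i$ to node $j$ follows
spectrally from the pseudoinverse $G$ of the weighted Laplacian
$\tilde\Gamma = D - A$:

$$H(j|i) = \sum_k d_k \left( G_{ki} - G_{ji} - G_{kj} + G_{jj} \right),$$

with the commute time
$\tau_{ij} = H(j|i) + H(i|j) = \mathrm{Vol}\,(G_{ii} + G_{jj} - 2G_{ij})$,
$\mathrm{Vol} = \sum_k d_k$: communication is slow exactly where
inter-residue distance fluctuations are large. The implementation is
pinned by three independent oracles in the tests — first-step-analysis
linear systems, the electrical commute identity
$\tau = \mathrm{Vol} \cdot R_\mathrm{eff}$, and seeded Monte-Carlo walks.

Two per-node summaries are available. The *receiver* convention (default)
averages, over source nodes, the time to hit the profiled node; its minima
are the most efficient signal receivers, and on toy graphs they coincide
with the best-connected nodes. The *broadcast* convention averages over
targets instead. Both are exposed because the two conventions genuinely
differ on directed summaries of the same symmetric chain, and reports name
the convention used.

The hitting time splits into a "self" part $\mathrm{Vol}\cdot G_{jj}$
carried by the target's own mean-square fluctuation — typically the
dominant term — and a "cross" remainder carried by fluctuation
cross-correlations. Difference maps of the cross part between states
(e.g. open versus closed+ligands) highlight couplings gained upon closure
and ligand binding. Optimal signalling routes are Dijkstra shortest paths
under the edge cost $-\log m_{ij}$, i.e. maximum-likelihood paths; among
equal-cost routes the one with fewer hops is preferred (implemented as an
infinitesimal per-hop cost that cannot perturb strict comparisons).

### Subsystem modes and family comparison

To compare family members whose structures align only partially, the
aligned positions form the subsystem S and the remainder the environment
E. The Hessian is partitioned into $H_{SS}, H_{SE}, H_{ES}, H_{EE}$ and
the effective Hessian

$$\tilde H = H_{SS} - H_{SE} H_{EE}^{+} H_{ES}$$

folds the elastic coupling into S; $u^\top \tilde H u$ equals the minimum
full elastic energy over environment placements, which the tests verify
against a direct linear solve. The environment block is pseudo-inverted
with the same relative zero threshold used everywhere
($\lambda \le 10^{-10} \lambda_{max}$). Note that rigid motions of the
subsystem remain zero-energy — the relaxed environment simply follows —
so the effective Hessian retains a six-dimensional null space and internal
numbering again starts beyond it. Modes of two structures are compared,
after rigid superposition over mapped C-alphas, by absolute correlation
cosines restricted to the mapped nodes (each slice re-normalized); the
family summary averages $\mathrm{CO}$ over the first 10 modes of the
reference and reports a percentage. The structural alignment itself is an
input (a two-column pair list, 0-based on disk as external aligners emit
it); computing alignments is out of scope.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| GNM cutoff | 10 | Å | community-standard C-alpha GNM contact radius |
| ANM cutoff | 15 | Å | community-standard C-alpha ANM contact radius |
| spring constant $\gamma$, scale $c$ | 1 | — | all profiles are relative; B-factor mean-matching absorbs scale |
| affinity threshold | 4 | Å | heavy-atom contact distance for the communication model |
| zero-mode threshold | $10^{-10}\lambda_{max}$ | relative | robust across problem sizes |
| conformer amplitude | 1 Å RMSD | Å | conformational excursions on the scale of crystallographic differences |
| walks per pair | 20000 | — | Monte-Carlo standard error small enough for 3-sigma checks |

The defaults above are the values in common use for C-alpha elastic
networks and are configurable everywhere; because published overlap
values for specific proteins depend somewhat on the cutoff choice,
reproduction checks on crystallographic inputs carry a ±0.05 band.

## The synthetic-data generators

`make_toy()` produces deterministic structures whose mechanics are known
by construction: a 3-bead chain (the exactly solvable path-graph fixture
used across the documentation and tests), rings and helices
(the simplest connected and non-degenerate 3-D topologies), a two-lobe
dumbbell with a helical linker (known hinge at the bridge, slowest ANM
mode = inter-lobe motion), and a C2-symmetric two-chain dimer of 2×258
residues matching the size of the NAGK homodimer (3N−6 = 1542 internal
modes). Nodes carry deterministic pseudo heavy atoms (four tetrahedral
satellites within 1.5 Å of the node), so heavy-atom contact counting is
exercised without side chains; synthetic B-factors mimic the empirical
anticorrelation between mobility and packing density, with seeded noise.
Geometry is fully deterministic; the only randomness anywhere in the
package (B-factor noise, deformation noise, random walks) flows from
stated integer seeds.

Two linker choices in the dumbbell are deliberate and worth knowing
about: the linker is helically offset from the lobe–lobe axis (otherwise
each lobe could rotate freely about that axis — an exact zero-energy
mechanism), and its pitch is 3 Å so that middle linker nodes reach both
lobes (fewer than six independent cross constraints would likewise leave
floppy lobe-versus-lobe mechanisms). With these choices the dumbbell has
exactly six ANM zero modes at the default cutoff.

What the toys do *not* emulate: real side-chain packing, heterogeneous
contact densities, crystal contacts, missing residues and experimental
B-factor artefacts. Passing tests on toys therefore validate the
mathematics and the code paths, not the biological accuracy of
elastic-network models on any particular protein; reproduction of
published protein numbers additionally needs the corresponding PDB
structures, which are inputs, not package data.

## Numerical choices and degenerate inputs

* Contacts use a closed interval (distance exactly at the cutoff counts).
* Alternate locations resolve to the highest occupancy, ties to the first
  record in the file; waters are always excluded; hydrogens are ignored.
* Zero modes are counted with a relative threshold; a connected GNM must
  produce exactly one (otherwise a disconnected-network error lists the
  components), a non-degenerate ANM exactly six (otherwise a degeneracy
  warning, e.g. for collinear toys where a 2-bead system has five).
* Superposition requires at least three non-collinear mapped pairs and
  always returns a proper rotation (reflections are repaired via the SVD
  sign convention).
* With partial alignments, mode vectors are sliced to mapped nodes and
  re-normalized before cosines are taken; deformation vectors exist only
  on mapped nodes.
* A deformation below 1e-10 Å total norm is treated as "no conformational
  change" and refused rather than normalized into noise.
* Hinges are sign changes of a slow GNM mode shape between sequence
  neighbours on the same chain (the partner with the smaller amplitude is
  reported; ties go to the lower index), plus strict interior minima of
  the squared shape inside the lowest-mobility decile.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated
structures: path graphs of 3 nodes, random graphs up to 50 nodes, helices
of 10–16 residues, dumbbells of 24–100 residues, and one 516-residue
two-chain dimer for the 1542-mode count. These sizes keep every stage
exactly solvable or independently verifiable (dense linear algebra
oracles, exhaustive path enumeration, 20k-walk simulations) while
exercising the same code paths a 500-residue crystal structure would.

## Known limitations

* Uniform spring constants only; distance-weighted or residue-specific
  ENM variants are out of scope.
* The GNM/ANM temperature factor scale is not fitted; only relative
  profiles and scale-free correlations are reported.
* All-atom conformers are rigid per-residue displacements without energy
  minimization.
* Structural alignments are consumed, never computed.
* Oligomeric context beyond the modelled chains (e.g. hexamer interfaces)
  is not represented unless those chains are included in the input.
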