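---
title: "Molecular signatures of missense variants: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular signatures of missense variants: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# Scope

`alloscan` profiles phenotype-labelled single-residue protein variants
(control / mild / severe) with fourteen molecular signatures spanning four
levels of description, contrasts the phenotype groups statistically,
classifies variants with a random forest, and traces how a mutation
re-routes allosteric communication through residue interaction networks.
The motivating application is a homodimeric metalloenzyme in which
loss-of-function missense variants produce clinical phenotypes of graded
severity, but every component operates on generic inputs: an aligned
protein MSA (FASTA), a one- or two-chain structure (PDB), a variant table
(CSV/TSV/XLSX), and optionally a coordinate ensemble (multi-model PDB).

# The feature set

**Sequence.** Per-column Shannon entropy
$S(i) = -\sum_{a=1}^{20} P(a_i)\,\ln P(a_i)$ uses natural logarithms: the
entropy of a uniform 20-type column is $\ln 20 \approx 2.9957$ nats, which
is why the profile is bounded by 3.0. Gap characters are excluded from the
entropy and the probabilities renormalized over the observed amino acids;
a column of only gaps is `NA`, never 0. Mutual information
$I(i,j) = \sum_{x,y} P(x_i, y_j) \ln \frac{P(x_i,y_j)}{P(x_i)P(y_j)}$ is
computed over 21 states with the gap as the 21st type. The asymmetry
between the two conventions (20 states for entropy, 21 for MI) is
deliberate and preserved from the method the package re-implements; a
per-residue coevolution summary is the row mean of the MI matrix
excluding the diagonal. No finite-sample MI correction is applied by
default; an average-product correction sits behind `apc = TRUE`. When no
externally computed conservation grade is importable, an entropy
surrogate bins columns into grades 1–9 (lowest-entropy nonuple = 9) and
the column provenance is recorded as "computed" rather than "imported".

**Structure.** Accessible surface area uses a hand-written Shrake–Rupley
sampler (no installed R package provides SASA): a deterministic Fibonacci
point lattice (default 960 points/atom, probe 1.4 Å) over element-typed
van der Waals spheres. Relative accessibility divides by the published
theoretical Gly-X-Gly maxima (Tien et al. 2013), and the three-class rule
is buried < 5%, semi-exposed 5–30% (both boundaries included), exposed
> 30%. RASA is computed on the full assembly (both chains) because the
physiological unit of the motivating system is the dimer; on
coarse-grained synthetic structures only Cα/Cβ pseudo-atoms exist, so
absolute RASA values are depressed and should be read comparatively.

**Stability.** ΔΔG (kcal/mol, positive = destabilizing) is consumed as an
input column only; the package never computes folding energetics.

**Contact network.** The residue graph connects residues whose
representative atoms (Cβ; Cα for glycine) lie within 8.0 Å, excluding
sequence neighbours $|i-j|\le 1$ within a chain. The analyses this package re-implements defer
their contact rule to an external tool without stating it, so this
default is recorded in the network object and in all outputs — it is the
main reproduction risk when comparing against deposited per-mutation
values. Edge weights are environment-dependent contact energies
$e_{ij} = -\ln\frac{N_{ij} N_{00} C_{i0} C_{j0}}
{N_{i0} N_{j0} C_{ij} C_{00}}$ from observed ($N$) versus random-mixing
reference ($C$) contact counts over the 20 types plus a solvent class 0.
The published count tables behind the original energies are not
reproduced in the text, so the package evaluates the formula on its own
mixing-model count table by default and accepts any user-supplied
$20\times 20$ energy matrix through the same hook.

Centralities follow the standard combinatorial definitions: degree,
betweenness normalized by the $(n-1)(n-2)/2$ node pairs, closeness as the
reciprocal mean shortest-path length, and the local clustering
coefficient (0 for degree < 2). Paths are unweighted by default. The
mutation operator is a *type-swap proxy* when no mutant structure is
given: contacts are kept and only the energies incident to the mutated
node are recomputed. Under that proxy unweighted centralities cannot
move, so the per-mutation deltas (ΔDC, ΔBC, ΔCC, ΔC) are read from the
weighted mode (`deltaWeighted = TRUE`: node strength for DC, edge length
$1/|e|$ for BC/CC); ΔC remains 0 under the proxy because the triangle
structure is contact-determined. With mutant structures supplied, all
four deltas respond. Both signed and absolute deltas are emitted because
published per-mutation profiles do not always disambiguate the
convention.

**Elastic-network dynamics.** The GNM Kirchhoff matrix uses a 7 Å Cα
cutoff, the ANM Hessian 13 Å, spring constant γ = 1 and $k_BT/\gamma = 1$:
all five dynamics features are used comparatively, so the absolute scale
is configurable but immaterial. Where the two defining
potentials are stated with swapped labels in parts of the literature,
the implementation follows the standard GNM/ANM forms. Zero modes
are those with $\lambda < 10^{-8}\lambda_{max}$ (one per connected
component for GNM, six for a connected non-degenerate ANM) and are
excluded from every sum. MSF is $3(k_BT/\gamma)[\Gamma^+]_{ii}$.
Perturbation response scanning is computed from the ANM pseudoinverse
covariance: the mean-square displacement of residue $j$ under random unit
forces at $i$ is $\tfrac13\lVert C_{ji}\rVert_F^2$, normalized by the
self-response, giving PRS$(i,i) = 1$; effectiveness and sensitivity are
the row and column means excluding the diagonal. Published PRS variants differ in their
normalization, so this convention is recorded here and in the
configuration. The mechanical bridging score deletes a
node's springs and measures the normalized *absolute* change of total
compliance (sum of reciprocal nonzero eigenvalues) on the largest
remaining component. The verbal definition it re-implements speaks of a
compliance *increase*, but that quantity is not sign-definite once
deletion disconnects the graph and the spectrum is restricted to the
largest component (a P5 middle node *decreases* it; a C4 node increases
it); the absolute change satisfies the properties the score is meant to
have — nonnegative, 0 for an isolated node, bridges above leaves, equal
on vertex-transitive graphs. Stiffness is the effective pairwise force
constant $\kappa_{ij} = [\sum_k \lambda_k^{-1}((U_k(j)-U_k(i))\cdot
\hat r_{ij})^2]^{-1}$ over nonzero ANM modes, with the per-residue value
its row mean.

**Trajectories and paths.** RMSD uses Kabsch superposition per frame;
RMSF superposes all frames to their mean with two refinement passes
(the mean is the stable reference convention) and ΔRMSF is mutant − wild type. Dynamic residue
networks connect Cβ (Gly: Cα) nodes within 6.5 Å per frame; betweenness
is frame-averaged; the consensus graph for path extraction keeps edges
with occupancy ≥ 0.5 (how per-frame networks are reduced before path
finding is an open choice — the threshold is configurable and always
recorded, and paths can equally be run on a single
representative frame by passing a two-frame static ensemble). Shortest
paths come from a hand-written Floyd–Warshall over the dense hop-count
matrix (the named algorithm of the method; cross-checked against
Dijkstra), with deterministic ties: among equal-length paths the
lexicographically smallest node-key sequence is returned. Path
comparison reports hop differences, shared nodes, and per-domain node
counts when functional annotations are given.

**Statistics and classification.** Group contrasts use the two-sided
Wilcoxon rank-sum test at α = 0.01: analyses of this kind sometimes name the
signed-rank test while comparing independent groups of unequal sizes,
so rank-sum is the defensible default and signed-rank is available for genuinely paired
inputs. No multiplicity correction is applied by default (each test is read
at its own α); Benjamini–Hochberg is available. AUCs are
rank-based concordance probabilities with ties counted half, reported in
the raw orientation (severity as positive class, feature value as score)
with the flipped value alongside, so either orientation convention can
be read off for features that decrease with severity.
The random forest uses 500 trees and √p features per split under
stratified 10-fold × 5-repeat cross-validation; importance is the mean
decrease in held-out accuracy under feature permutation, averaged over 5
permutation draws per fold to stabilize the estimator on small folds.
Every report carries its seed.

# The synthetic-data generators

The generators define the conditions under which the pipeline is tested;
they are pure functions of a `SyntheticSpec` (identical spec ⇒ identical
bytes).

* **MSA** — each column draws from a two-component distribution (one
  peaked type, uniform remainder) whose mixing weight is solved by
  `uniroot` to hit the column's entropy target in closed form; counts are
  quota-sampled so the empirical entropy tracks the target to
  $O(\text{types}/n)$, far inside the ±0.15 nat tolerance at n ≥ 500.
  This replaces a Dirichlet-concentration scheme considered at design
  time: the closed-form family gives exact, monotone control of the
  target with no per-column numerical variability. Coevolving pairs copy
  column $i$ into $j$ per sequence with probability $c$ (identical
  columns at $c = 1$, hence $I(i,j) = S_{21}(i)$).
* **Dimer** — each chain is a compact self-avoiding Cα walk (steps of
  exactly 3.8 Å, non-consecutive pairs ≥ 3.5 Å, confined to a globular
  radius of ≈113 Å³/residue); connectivity of the 7 Å GNM graph is
  guaranteed because consecutive residues are always in contact. The
  second chain is a reflected copy docked along x until ≥ 10 inter-chain
  pairs sit within 8 Å without clashes; pseudo-Cβ atoms are placed
  1.53 Å from the Cα along the local backbone normal (absent for Gly).
  Residue types come from the alignment reference row (homodimer: both
  chains share the sequence).
* **Mutation sets** — sites are drawn from chain A with class-directional
  weights: positive class effects on `S_i` and `RASA` pull severe
  mutations toward conserved, buried sites and control mutations toward
  variable, exposed sites, mild in between; the ΔΔG surrogate is
  Gaussian with control mean 0.5 kcal/mol, SD 1, severity shift
  `classEffect["ddG"]`. With all effects zero the classes are
  exchangeable by construction. Default conditions: 30 mutations per
  class, effects (S_i = 1, RASA = 1, ddG = 1.5) — moderate,
  direction-matched shifts.
* **Feature tables** — a distribution-level companion generator emits a
  mutations × features table of standard Gaussians with named per-feature
  class shifts; it is the instrument for the null-calibration
  (all effects 0) and parameter-recovery (two designated features at
  effect 2.0) experiments.
* **Trajectories** — frames are the mean structure plus independent
  Gaussian mode amplitudes of variance `temperatureScale`/λ per axis, so
  the empirical RMSF² converges to the analytic elastic-network MSF and
  doubling the temperature scales RMSF by √2; Cβ atoms ride rigidly with
  their Cα.
* **Count tables** — multinomial samples of unordered typed contacts
  (25% solvent) under optional pairwise enrichment; the reference counts
  use the random-mixing model with the *observed* marginals, so marginals
  agree by construction and the un-enriched, noise-free variant
  (`sampled = FALSE`) makes every contact energy exactly zero.

What the generators deliberately do not emulate: force-field energetics,
side-chain rotamers, sequence evolution along a phylogeny, and
non-harmonic conformational transitions. Tests passing on these
synthetics therefore demonstrate algorithmic correctness and calibration,
not biological realism of any particular feature value on real
structures.

# Numerical and experimental choices

* Problem sizes: the packaged experiments use 60-residue chains (20–50
  for single-purpose fixtures), 1000 × 60 alignments, 5000-frame
  ensembles for the sampling-consistency check, 100 random graphs of
  ≤ 10 nodes for the centrality oracle and ≤ 50 nodes for the
  Floyd–Warshall/Dijkstra cross-check, 200 synthetic nulls for type-I
  calibration, and 10 repetitions of the recovery experiment at 60
  mutations per class. The recovery experiment is sized above the
  generator default because permutation importance of two correlated
  informative features is masking-limited at 30/class.
* The PRS force oracle is Monte-Carlo (500 random directions per
  residue), so agreement is asserted on the mean relative deviation
  (≈1.7% at N = 20) rather than per entry.
* The type-I check compares against the *attained* level of the exact
  rank-sum test at n = m = 20 (0.00995, not 0.01): the test statistic is
  discrete.
* Altloc resolution: highest occupancy, ties to label "A". Insertion
  codes are rejected, not renumbered. Mismatches between mutation table,
  alignment and structure are reported, never repaired.
* Tie-breaks: conservation grades use average ranks (an all-equal
  profile maps to grade 5); shortest-path ties return the
  lexicographically smallest node-key sequence; top-k feature selection
  breaks importance ties by column order.
* Degenerate inputs: a constant feature in both groups returns p = 1
  with a flag; an empty contact network is an error suggesting cutoff
  review; nodes whose deletion disconnects the GNM graph are flagged in
  the MBS output; unreachable path targets are reported, not fatal.

# Limitations

* The type-swap network proxy cannot change contact topology; ΔDC under
  the proxy reflects energy (strength) changes only and ΔC is
  identically zero. Supplying mutant structures restores the full
  behaviour.
* Contact energies default to a synthetic mixing-model table; quantitative
  comparison with analyses built on published count statistics requires
  supplying that energy matrix.
* The conservation surrogate approximates an external grading service
  only up to monotone transformation of column entropy.
* Coarse-grained synthetic structures depress absolute RASA values; the
  three-class rule is calibrated for all-atom structures.
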