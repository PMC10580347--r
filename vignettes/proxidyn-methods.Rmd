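---
title: "Models and methods behind proxidyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind proxidyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxidyn)
```

`proxidyn` chains four analyses that together make up a network-based drug
repositioning study: a proximity screen on a protein–protein interaction
(PPI) network, post-simulation trajectory analytics, MM-PBSA energy
aggregation, and expression-based target validation. This vignette states
each model, its assumptions, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## 1. The weighted proximity screen

### Model

For disease gene set $S$ and drug target set $T$ on an undirected,
unweighted PPI graph,

$$d(S,T) \;=\; \frac{1}{|T|}\sum_{t\in T}\Big[\min_{s\in S} d(s,t) + w(t)\Big],
\qquad
w(t) = \begin{cases}-\ln(D_t+1) & t \in S\\ 0 & \text{otherwise}\end{cases}$$

with $d(s,t)$ the shortest-path (hop) distance and $D_t$ the degree of $t$.
The minimum is taken over all of $S$ including $t$ itself, so a target that
is a disease gene contributes $0 - \ln(D_t+1)$: hitting a well-connected
disease gene pulls the score below zero. This is what makes the selection
rule — **keep drugs with $d(S,T) < 0$** — meaningful on the raw score, and
it is why selection uses the raw weighted distance rather than the z-score.
The z-score against a size-matched random reference (below) is computed and
reported as supplementary evidence, not as the selection statistic.

### Reference distribution and z-scores

For each distinct mapped-target count $k$, `proximity_screen()` draws
`n_samples` (default 1000) pseudo-drugs of $k$ distinct nodes uniformly from
the whole network — size-matched only, not degree-matched, because the
screen's null is "a random protein set of this size", and degree binning
would build part of the signal into the null. A sampled node that happens
to be a disease gene receives its weight, exactly as a real target would.
Then $z = (d - \mu_{\text{ref}})/\sigma_{\text{ref}}$.

### Edge cases, by decision

* Targets absent from the network are dropped and logged; a drug with no
  mapped target is *unscorable*, never scored 0 (a silent zero would
  fabricate maximal proximity).
* Unreachable $(s,t)$ pairs are skipped inside the minimum; a target
  unreachable from every disease gene is dropped with a warning; if all
  targets drop, the drug is unscorable. Disconnected distances are `NA`
  sentinels throughout — downstream code must decide, nothing substitutes a
  large finite number.
* Results are ranked ascending by distance with ties broken
  lexicographically by drug id, so output is a pure function of inputs,
  thresholds and seed, independent of input row order.
* Gene identifiers are case-sensitive exact strings; alias resolution is a
  database concern and out of scope.

## 2. Trajectory analytics

All metrics operate on an `md_trajectory`: frames of labelled 3-D
coordinates (Å) at fixed spacing `dt` (ns), with declarative atom masks
(`"all"`, `"backbone"`, `"heavy"`, `"calpha"`, plus 1-based residue
ranges).

* **Superposition** is a proper Kabsch fit (SVD with determinant
  correction; reflections never slip through). Fewer than three masked
  atoms, or collinear geometry, is an error.
* **RMSD** uses frame 0 as reference (the convention of the common MD
  toolchains), fitting each frame on the mask before measuring it, so the
  series starts at exactly 0.
* **RMSF, DCCM and PCA** use the mean structure as reference, iterated
  once: align to frame 0, form the mean, re-align to the mean. Per-residue
  RMSF aggregates atom RMSFs by root-mean-square.
* **DCCM** represents each residue by the unweighted centroid of its masked
  atoms (degrades gracefully for ligands); pass `selection = "calpha"` for
  the Cα-only convention. $C_{ij} = \langle \Delta r_i\!\cdot\!\Delta r_j
  \rangle / \sqrt{\langle|\Delta r_i|^2\rangle\langle|\Delta r_j|^2\rangle}$,
  clipped to $[-1,1]$; zero-variance residues get zeroed off-diagonals and a
  flag rather than NaN.
* **PCA** eigendecomposes the $3N\times3N$ covariance of the fitted masked
  coordinates; rank deficiency is natural (trailing zero eigenvalues), and
  variance fractions are $\lambda_k/\sum\lambda$.
* **Free-energy landscape**: 2-D histogram of two collective coordinates
  (typically PC1/PC2, the conformational axes), then
  $F = -k_B T \ln(P/P_{\max})$ so the fullest bin sits at exactly 0 and
  empty bins are masked. Defaults: 50×50 bins, $T = 310$ K (body
  temperature, the simulation condition), $k_B = 0.0019872$ kcal/mol/K.
* **Convergence window**: the trailing $\lceil f\cdot n\rceil$ frames,
  default $f = 0.2$ — the converged last fifth of a run (frames 80–99 of
  100) — used before energy averaging and landscapes. The same ceiling rule
  applies to per-frame energy tables in `summarize_energy_series()`.

A quantity reported as "overall motility" of the first two components is
taken as PC1+PC2 cumulative variance (`glance()` reports it); it is
descriptive, not a validated threshold.

## 3. Energy aggregation and strength bands

$\Delta G_{\text{bind}} = \Delta E_{\text{vdw}} + \Delta E_{\text{ele}} +
\Delta G_{\text{pol}} + \Delta G_{\text{np}}$ (kcal/mol), full precision
kept internally, two decimals for display. Computing the components (PB
solver, SASA, entropy) is explicitly out of scope; they are inputs.

The published strength bands (Weak −1.36…−5.46, Medium −6.83…−8.19, Strong
−9.56…−12.29, Very strong −13.66…−16.39 kcal/mol) are gapped and do not
cover every realistic value, so `binding_strength()` makes the map total
without inventing thresholds: inside a band, its label; in a gap or beyond
the strongest band, the label of the *nearest band boundary* with an
"(extrapolated)" qualifier; weaker than −1.36, "negligible". The resulting
map is monotone — more negative never classifies weaker.

## 4. Drug-likeness and expression screens

Rule-of-five violations count {MW > 500 Da, LogP > 5, HBD > 5, HBA > 10};
pass means ≤ 1 violation (the standard usage; no threshold is stated in the
source analysis). Descriptors are inputs — structure-to-descriptor needs a
cheminformatics toolkit and is deliberately a documented hook, and the PAINS
flag is an externally supplied boolean because substructure screening is out
of scope.

The expression screen tests each gene with a **two-sided Welch t-test**
(robust default when group variances are unknown) and **pooled-SD Cohen's
d**, selecting $p < 0.05$ and $|d| > 0.8$. Direction is kept in the output;
the gate uses magnitude. **No multiple-testing correction by default**,
mirroring the stated thresholds exactly; `adjust = TRUE` switches the gate
to BH-adjusted p-values for users who want FDR control. At $n = 10/10$ the
$p$-gate binds ($p<0.05$ implies $|d| \gtrsim 0.94$), so the null selection
fraction sits at the Welch size (≈ 0.048 at this $n$); at larger $n$ the
$d$-gate takes over and the rate drops below $\alpha$.

## 5. What the generators emulate — and what they do not

All generators are pure functions of scenario + seed and restore the
caller's RNG state.

**Networks** (`make_network`): preferential attachment (`n_nodes = 200`,
`m = 2`) mimics PPI degree heterogeneity — important because the
$-\ln(D+1)$ weight is only consequential when hubs exist; a
configuration-model rewiring of the same degree sequence is available as a
control. The disease module is a connected BFS ball of 20 genes grown from
a maximum-eccentricity (peripheral) node — peripheral placement keeps nodes
≥ 3 hops away available so the "remote" drug class is realizable; scenarios
that still cannot place a class fail loudly rather than degrade. Drug
classes are constructive guarantees, not tendencies: `proximal_weighted`
targets are disease genes of degree ≥ 1 (each term $0-\ln(D+1)<0$, so the
distance is negative by construction), `proximal_unweighted` targets are
non-disease first neighbours (distance exactly 1), `remote` targets sit at
least 3 hops out. Not emulated: edge confidence scores, directionality,
real module topology.

**Trajectories** (`make_trajectory`): one CA pseudo-atom per residue
fluctuating around a compact tethered-random-walk chain (~3.8 Å steps with
a pull to the origin). `sigma` is the *target per-residue RMSF* in Å (total
3-D amplitude; per-axis SD is $\sigma/\sqrt3$), so `rmsf_per_residue()`
reads back the planted value directly. Correlation blocks plant residue
cross-correlations exactly equal to `rho` by sampling each axis from a
multivariate normal with the block-structured correlation matrix (validated
PSD before sampling). A compact reference matters: rigid-body fitting
removes ~6 degrees of freedom of apparent motion, and on an extended chain
that loss concentrates on high-leverage end residues. Two residual,
well-understood biases remain and set the validation scenario sizes below:
superposition absorbs part of any *coherent* block's common-mode motion (an
effect of order block-size/system-size), and ~$6/(3N)$ of total variance is
removed overall. `make_mode_trajectory` plants orthonormal principal modes
explicitly orthogonalised against the six rigid-body motions of the
reference, so PCA variance fractions recover the planted split cleanly. Not
emulated: real protein topology, solvent, force-field physics, time
correlation between frames.

**Expression** (`make_expression`): per-gene Gaussian noise; signal genes'
case means shift by $d\cdot\text{SD}$, so the planted $d$ is the population
effect size. Not emulated: count noise, library-size effects,
gene–gene correlation — so passing tests show calibration and power of the
selection rule under its own model, not robustness to RNA-seq artefacts.

## 6. Validation scenario sizes

The shipped validation (test suite and `scripts/acceptance.R`) uses:
100 random graphs of ≤ 60 nodes for brute-force equality of the weighted
distance (tolerance 1e−12); 20 planted network scenarios with a 1000-sample
reference for screening soundness and z-centring; 2000-frame trajectories —
120 residues (block-free) for RMSF recovery within 5%, 250 residues for
block-correlation recovery within ±0.05, 50 residues for the 9:1 mode split
within ±0.02; the analytic two-bin landscape at 310 K
($\Delta F = k_B\,310\,\ln 3 \approx 0.677$ kcal/mol); and 100 null + 500
signal expression matrices at $n=10/10$ for calibration and power. These
sizes were chosen so the known superposition biases above stay inside each
tolerance while the whole validation remains desk-scale.

## 7. Known limitations

* The proximity screen treats the interactome as given; no confidence
  filtering, no ID mapping, and headline numbers of any particular study
  (gene-list sizes, candidate counts) depend on database versions and are
  not reproducible from the method alone.
* Superposition-based metrics carry the rigid-body-fit biases described in
  §5; interpret per-residue RMSF of small, strongly correlated systems with
  that in mind.
* The energy module aggregates; it does not validate component physics, and
  the strength bands extrapolate outside their published anchors (the
  qualifier makes that visible).
* The expression screen is per-gene and uncorrected by default — by design
  a threshold-faithful filter, not an FDR-controlled discovery procedure.
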