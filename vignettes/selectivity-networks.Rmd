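---
title: "Estimating binding selectivity from free-energy difference networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating binding selectivity from free-energy difference networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsfenet)
```

## The estimation problem

A ligand's selectivity between two receptors is quantified by the
selectivity coefficient — the ratio of its binding constants — or
equivalently by the binding selectivity free energy (BSFE), the
difference of its standard binding free energies for the two receptors:
$\Delta G_h(L) = \Delta G^\circ_b(R_B L) - \Delta G^\circ_b(R_A L)$,
with $s = e^{-\Delta G_h / k_B T}$. Alchemical simulations deliver this
information piecewise, as free-energy *differences*: relative binding
free energies (RBFE) between ligand pairs on one receptor, hopping free
energies (RHFE) that transfer one ligand between receptors, and swapping
free energies (RSFE) that exchange a ligand pair across receptors. Each
measurement constrains a difference of the underlying per-complex (or
per-ligand) free energies; none fixes their absolute values.

`bsfenet` represents a campaign as a directed graph whose nodes carry
the unknowns and whose edges carry the measurements, with the uniform
sign convention `value = x(head) − x(tail)`. Complex-mode networks
estimate per-complex binding free energies from RBFE and RHFE edges;
selectivity-mode networks estimate per-ligand BSFEs for one ordered
receptor pair directly from RSFE edges. The absolute scale comes from
anchors: reference nodes with known values (one measured ABFE, or one
reference BSFE).

## The maximum-likelihood solver

We model each edge as the true difference plus independent Gaussian
noise with the edge's reported standard deviation. The log-likelihood is
then (up to constants) the negative of

$$ F(x) \;=\; \sum_{e}\frac{\left(x_{h(e)} - x_{t(e)} - d_e\right)^2}{\sigma_e^2}, $$

and the maximum-likelihood node values minimize $F$ subject to the
anchors. This is the DiffNet estimate, generalized in two directions:
hopping edges carry terms that couple the per-receptor RBFE subnetworks
into one system, putting both receptors' affinities on a common scale,
and the same machinery applied to BSFE nodes with RSFE edges yields
selectivities without ever estimating individual affinities.

The normal equations of $F$ form a weighted graph Laplacian. With hard
anchors (the default), anchored nodes are substituted and eliminated,
and the reduced system — symmetric positive definite exactly when every
connected component contains an anchor — is solved by Cholesky
factorization. Solvability is decided structurally *before*
factorization (`validate_network()` reports anchor-less components), and
there is no pseudo-inverse fallback: an under-determined network is an
error, never a silently gauge-fixed answer. The condition number is
estimated and a warning is raised above $10^{12}$.

Per-node variances are the diagonal of the inverse reduced precision
matrix. Two conventions matter here:

* **2σ reporting.** Published free-energy tables report uncertainties as
  twice the standard deviation; `bsfenet` stores and propagates on that
  scale (quadrature is scale invariant) and converts to
  $\sigma = u/2$ only where variances are needed — solver weights, z
  tests. A global rescaling of all variances does not move the
  minimizer, so central estimates are insensitive to this convention;
  only reported uncertainties depend on it. Published DiffNet
  uncertainty columns were produced by an estimator whose conventions
  are not fully documented, so our 2σ values agree with them in
  magnitude (0.1–0.2 kcal/mol on the benchmark) but not digit-for-digit.
* **Hard versus soft anchors.** The benchmark analyses use a single
  exact reference ("only the binding free energy of the reference
  complex"), which hard anchoring reproduces: the anchor is eliminated
  and reports its own input uncertainty. When several uncertain
  references should be *fused* rather than trusted, `anchor_mode =
  "soft"` adds Gaussian prior terms $(x_a - v_a)^2/\sigma_a^2$ instead;
  it requires every anchor to carry a positive uncertainty.

Degenerate weights: an edge with zero uncertainty would have infinite
weight, and `fe_objective()` rejects it — exact constraints belong in
anchors. The one exception is a network in which *every* edge is exact
(noiseless synthetic data); the solver then uses unit weights, under
which the consistent system is solved exactly, rather than refusing.

## Identities and diagnostics

The identity algebra (`difference()`, `rhfe_from_abfes()`,
`rsfe_from_rbfes()`, `rsfe_from_bsfes()`) implements the closed
thermodynamic cycles connecting the four measurement kinds; the swap
free energy computed via ABFEs, via RBFEs and via BSFEs agrees to
machine precision by construction, and the test suite asserts this on
random affinity tables. Orientation conventions are fixed once: hops are
$A \to B$, and a swap labelled $(L_1, L_2)$ starts from $L_1$ bound to
the first-listed receptor, so $\Delta G_s = \Delta G_h(L_1) - \Delta
G_h(L_2)$. Note the exponential maps are orientation-sensitive: the
coefficient $s$ is "B over A" while the swap ratio
$e^{+\Delta G_s/k_BT}$ compares the ligands "A over B"; the package
never infers a sign from context.

Diagnostics answer "are these measurements mutually consistent?":

* `compare_measurements()` refers a direct-vs-indirect discrepancy to
  its combined σ with a two-sided z test — the large-sample limit of the
  t test, the natural choice under the Gaussian error model (the exact
  degrees of freedom of published analyses are unknowable from the
  tables). Default α = 0.05, no multiple-testing correction, matching
  field practice. Comparisons between routes sharing inputs ignore their
  covariance, as quadrature columns do; this overstates σ slightly.
* `cycle_closure()` sums edges around each fundamental cycle of a
  spanning forest; a state function must close every cycle to zero
  within the quadrature uncertainty.
* `hysteresis()` checks a forward/reverse pair via $|f + r|$ — the two
  directions traverse one closed cycle, so their sum must vanish.
* RMSD aggregation over a table of pairs (`fe_rmsd()`,
  `consistency_report()`). When DiffNet estimates are compared against
  direct measurements, the reference node is excluded from the RMSD (its
  deviation is identically zero under hard anchoring); this convention
  is applied uniformly.

## The synthetic generator

`generate_truth()` draws a receptor × ligand ABFE table uniformly from a
stated range (default −12 to 0 kcal/mol, spanning typical host–guest
affinities); `sample_network()` adds independent $N(0, \sigma^2)$ noise
to exact ground-truth differences and records each edge's uncertainty as
$2\sigma$, anchoring the first node at its true value. Noise is applied
to *edges*, not nodes, matching the error model implicit in
per-calculation uncertainties. Topologies: `all_pairs` (the benchmark
design), `star`, `chain`. A fixed seed reproduces a network exactly.

This emulates precisely the statistical structure the solver assumes —
and nothing more. Real campaigns violate it in known ways: errors
correlate across edges sharing an end state, force-field bias does not
average away, and poorly converged simulations report optimistic
uncertainties. Passing recovery tests therefore demonstrates the
estimator's correctness and calibration under its own model, not the
accuracy of any simulation protocol.

`recovery_experiment()` runs replicate solves and reports bias, RMSE and
empirical 2σ coverage. Under the model the estimator is exactly unbiased
and Gaussian, so coverage should sit at 95.4%; the test suite checks
|bias| < 0.02 at σ = 0.2 over 200 replicates and coverage within 93–97%
over more than 1000 node-replicates. Problem sizes (2 receptors × 5–6
ligands, 60–200 replicates) were chosen to make these Monte-Carlo bands
tight while keeping the default suite fast.

## Numerical choices and limitations

* Values are stored at full precision; display rounds half-to-even at
  0.01 kcal/mol, matching table precision. Reported derived
  uncertainties can differ from published quadrature columns by ±0.01
  because published tables propagated unrounded inputs.
* Benchmark regression tolerance is ±0.05 kcal/mol on central network
  estimates: the reference implementation's internal conventions are not
  fully specified, and the packaged inputs are rounded to 0.01.
* Parallel edges (replicates, forward/reverse runs) all enter the
  objective; they are never pre-averaged.
* Anchors conflicting on the same node are rejected; duplicate
  consistent anchors collapse to one.
* Temperature enters only the exponential maps (coefficients, pKi and
  $K_b$ conversions): kB = 0.0019872041 kcal/(mol·K), default T = 300 K
  (the simulation thermostat value). Experimental-affinity conversions
  should pass `thermo_context(298.15)`. One published experimental entry
  (the thrombin relative affinity, 0.41 kcal/mol) is not derivable from
  the printed pKi values at any reasonable temperature — the source
  presumably used unrounded inhibition constants — and is therefore not
  asserted anywhere.
* Out of scope by design: estimating free energies from simulation
  samples, optimal edge-selection/experiment design, correlated-error
  models, and chemistry-aware input formats. Node ids are opaque
  strings.

## A complete analysis in six lines

```{r example, eval = FALSE}
fit <- solve_network(sampl8_network())          # ABFEs of 10 complexes
sel <- solve_selectivity(sampl8_selectivity_network())  # BSFEs of 5 guests
cycle_closure(sampl8_network())                 # consistency of the inputs
selectivity_coefficient(measurement(5.46, 0.34))  # BSFE -> coefficient
truth <- generate_truth(2, 5, seed = 1)
recovery_experiment(truth, edge_sigma = 0.2, n_replicates = 200, seed = 2)
```
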