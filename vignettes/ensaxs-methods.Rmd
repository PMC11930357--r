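---
title: "Ensemble reweighting and structural analysis of coarse-grained SAXS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble reweighting and structural analysis of coarse-grained SAXS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensaxs)
```

## The problem

Flexible multi-domain proteins -- the motivating case is an HP1-family
chromatin protein, a dimer of chromodomain (CD) and chromo shadow domain
(CSD) cores joined by a disordered hinge, with a phosphorylatable
disordered N-tail -- do not adopt a single structure in solution. A SAXS
measurement of such a protein reports a population average, and a simulated
conformational ensemble rarely reproduces it out of the box: force fields
over- or under-compact disordered regions, and the simulated populations
need not match the solution populations.

`ensaxs` implements the standard remedy. Starting from a conformer
ensemble with prior weights $w^0$ (uniform for simulation snapshots), it

1. computes a theoretical SAXS profile per conformer (Debye formula,
   one bead per residue),
2. reweights the ensemble against a measured profile by Bayesian maximum
   entropy (BME),
3. characterizes the reweighted ensemble: residue--residue contact
   probability maps, weight-modified GROMOS clustering with representative
   structures, Guinier / $P(r)$ / $D_{max}$ statistics, and a genetic
   algorithm that selects small sub-ensembles fitting the data
   (ensemble-optimization style), and
4. ships a synthetic-ensemble generator with known ground truth, used to
   validate every stage.

A small NMR module computes amide chemical-shift perturbations
$\Delta\delta = \sqrt{\Delta\delta_H^2 + (\Delta\delta_N/5)^2}$ with
per-segment summaries, for the common companion experiment.

## Profile calculation

For bead coordinates $r_i$ with forward scattering factors $f_i(0)$ the
Debye formula gives

$$ I(q) = \sum_i \sum_j f_i(q)\, f_j(q)\, \frac{\sin(q r_{ij})}{q r_{ij}}. $$

At one bead per residue, atomic-level excluded-volume and hydration
corrections cannot be applied verbatim; the package uses a documented
two-parameter analogue that preserves their roles:

$$ f_i(q) = f_i(0)\, e^{-(q \sigma_b c_1)^2/2} + c_2\, h_i\, e^{-(q \sigma_w)^2/2}, $$

where $c_1 \in [0.95, 1.05]$ adjusts the effective bead width
($\sigma_b = 3$ Å by default, roughly a residue radius), $c_2 \in [-2, 4]$
scales a hydration-layer term carried by exposed beads, and
$h_i = 1 - \min(n_i, 12)/12$ is a deterministic exposure proxy from the
7 Å neighbour count $n_i$ -- a cheap stand-in for solvent accessibility.
The bounds follow the convention of the atomic-level programs that
introduced $(c_1, c_2)$ as opaque per-snapshot fit parameters.

Because $c_1$ and $c_2$ only enter through the two Gaussian envelopes, the
intensity decomposes as
$I(q) = g_1^2 A(q) + c_2 g_1 g_2 B(q) + c_2^2 g_2^2 C(q)$
with conformer-specific basis sums $A, B, C$ that are independent of
$(c_1, c_2)$. `debyeBasis()` computes these once per conformer; fitting
$(c_1, c_2)$ (coarse grid plus golden-section refinement) and the
protocol's profile recomputation are then essentially free. At one-bead
resolution $(c_1, c_2, \text{scale})$ are strongly correlated; their
individual values matter less than the fitting-and-averaging protocol
below, which is why they are treated as nuisance parameters.

A free multiplicative scale is always fitted (closed-form weighted least
squares): absolute intensity calibration is meaningless for synthetic
data and rarely trustworthy for measured data. A constant offset is
available but off by default.

## Bayesian maximum-entropy reweighting

Weights minimize

$$ L(w) = \frac{\chi^2(w)}{2} - \theta S(w), \qquad
\chi^2(w) = \sum_{i=1}^{M} \left( \frac{s\sum_j w_j I_{j,i} - I_{\exp,i}}
{\sigma_i} \right)^2, \qquad
S(w) = -\sum_j w_j \log\frac{w_j}{w_j^0}, $$

subject to the simplex constraints. $\theta$ trades data fit against
deviation from the prior; the effective ensemble fraction
$\varphi_{\mathrm{eff}} = e^{S(w)}$ summarizes how much of the prior
survives.

The solver works in the convex dual with one multiplier per data point
($w_j \propto w_j^0 e^{-\lambda^\top F_j}$), which is cheap when the
ensemble is much larger than the profile. We minimize the
$\theta$-normalized dual (gradient $-\langle F\rangle_w + y' + \theta\lambda$)
so the problem is equally well scaled at $\theta = 10^{-2}$ and
$\theta = 10^9$, by BFGS followed by Newton polishing with backtracking
(gradient norm below $10^{-10}$ in normalized units). Initialization is
always $\lambda = 0$, i.e. $w = w^0$; there is no randomness.

The scale $s$ is refit to the weighted average after each dual solve and
the two steps alternate. In weakly regularized regimes this alternation
crawls along a nearly flat valley ($s$ and $w$ can compensate each
other), so after 60 alternations the solver switches to Brent
minimization of the scale-profiled objective, which converges regardless.

`thetaScan()` tabulates $(\theta, \chi^2, S, \varphi_{\mathrm{eff}})$ over
a grid; both $\chi^2(\theta)$ and $\varphi_{\mathrm{eff}}(\theta)$ are
non-decreasing (a frontier property of the trade-off that the tests
check). `selectTheta()` automates the choice as the maximum-curvature
elbow of the $\chi^2$--$\varphi_{\mathrm{eff}}$ L-curve on normalized
log-log axes; the traditional manual criterion (smallest $\theta$ with
$\varphi_{\mathrm{eff}}$ above a threshold, default 0.7) is available as
`method = "phiEff"`. For measured data of this protein family values
around $\theta \approx 20$ with $\varphi_{\mathrm{eff}} > 0.7$ are
typical, but $\theta$ must be rechosen for every data set -- the package
never assumes a transferred value.

`iterativeBME()` implements the five-step protocol: per-snapshot
$(c_1, c_2)$ fits against the target; BME; weight-averaging
$\bar c = \sum_j w_j c_j$; recomputation of all profiles at the fixed
$\bar c$; and a second BME round. Both rounds are logged, and the second
round must not degrade the fit (tested with 5% slack).

## Ensemble characterization

**Contact maps.** Two residues interact in a conformer when their beads
are within 11 Å (the bead-level interaction criterion for this
resolution). The map entry is the weighted fraction of conformers with the
contact. Intra-chain maps are averaged over the chains of a multimer;
inter-chain maps combine both subunit pairings symmetrized -- the
labelling of identical subunits is arbitrary, so reporting one ordering
would be ill-defined.

**Weighted GROMOS clustering.** Classic GROMOS clustering repeatedly
picks the structure with the most neighbours within an RMSD cutoff. After
reweighting, the member count is the wrong centrality measure; the
weighted variant scores each candidate by the *summed weight* of its
unassigned neighbours (itself included, the standard convention) and
otherwise proceeds identically, so uniform weights reduce exactly to the
classic algorithm (verified against a brute-force oracle). Ties go to the
lowest index; scores are compared with a $10^{-9}$ tolerance so that
floating-point summation order cannot flip a tie. The distance measure is
`subsetRMSD()`: superposition on a stated selection (e.g. the CSD core),
RMSD over another (tails, CD, basic segments), with an optional chain-swap
minimum over the two subunit labelings. Default cutoffs follow the
systems they were designed for: 20 Å for the dimer, 10 Å for the
two-molecule monomer system.

**Guinier analysis.** Linear fit of $\ln I$ vs $q^2$;
$R_g = \sqrt{-3\,\mathrm{slope}}$. Automated range-finding rules differ
between programs and are rarely published in reproducible form, so the
package states its own: start from the full positive-intensity low-q run,
fit, trim to $q_{max} R_g \le 1.3$, refit until stable, require at least
5 points. A monotone-increasing profile has no Guinier regime and errors.

**$P(r)$ and $D_{max}$.** The coordinate route (`prFromCoordinates()`,
the exact scattering-weighted pair-distance histogram) serves as the
oracle for the profile route (`prFromProfile()`): regularized
non-negative least squares on a 101-node basis linked by
$I(q) = 4\pi\sum_r P(r)\,\mathrm{sinc}(qr)\,\Delta r$, second-difference
smoothness penalty $\alpha$, endpoints pinned to zero. $\alpha$ defaults
to a 10-point logarithmic scan minimizing the generalized
cross-validation score of the unconstrained ridge path; the constrained
solve uses L-BFGS-B with the exact quadratic gradient. `dmaxScan()`
scores candidate $D_{max}$ values by fit $\chi^2$ plus a penalty on mass
stranded in the last 5% of bins. Because an oversized $D_{max}$ is
essentially unpenalized (the regularized solution simply decays early),
the estimate is the smallest candidate within 5% of the plateau minimum
-- the score drops steeply below the true dimension and plateaus above
it.

**GA sub-ensemble selection.** Chromosomes are multisets of $K$ pool
indices (repetition allowed, matching ensemble-optimization practice);
fitness is the $\chi^2$ of the scale-fitted uniform average of the $K$
profiles. Tournament selection (size 2), single-point crossover (rate
0.8), per-gene mutation to a random pool index (rate 0.02), elitism (2).
These hyperparameters are declared desk-scale defaults, not inferred from
any published tool. Elitism makes the best-fitness trace monotone;
fixed seeds make runs bit-reproducible. `distributionReport()` produces
the standard before/after histograms of $D_{max}$ or $R_g$.

## The synthetic generator

The generator stands in for coarse-grained MD production: it emulates the
*kind* of ensemble such simulations produce, not their energetics.

* **Topologies.** `hp1DimerTopology()`: two 191-residue chains, rigid CD
  (19--74) per chain, one rigid CSD-dimer body (113--173 of both chains)
  bridging the subunits. `deltaCSDTopology()`: 120-residue monomer(s)
  with a rigid CD, as one- or two-molecule systems. Charged segments
  alternate along the sequence (a1--a7 acidic at $-1$, b1--b7 basic at
  $+1$, phosphoserines 11--14 at $-2$ when phosphorylated). The segment
  positions anchored by the protein family's landmarks (b4 = 68--72 at
  the CD end, b6 = 89--92 and b7 = 102--105 in the hinge) are exact;
  the remaining ranges are plausible placements internal to the emulator.
* **Rigid domains** are compact self-avoiding 3.8 Å-bond chains accepted
  only if all non-bonded beads are $\ge 4$ Å apart and
  $R_g \le 0.9 \cdot 3.8\,n^{0.33}$ (compact-globule scaling). Templates
  are generated once per topology, so domain-internal geometry is
  identical across all samples, emulating an elastic-network core.
* **Tails and linkers** grow as excluded-volume random walks (bond
  3.8 Å, exclusion 4.0 Å -- standard C$\alpha$-trace geometry). The
  compaction bias $\kappa \ge 0$ emulates phosphorylation-driven
  tail/basic-segment association: growth candidates are
  Boltzmann-weighted by $e^{\kappa g}$ and the grown molecule is refined
  by Metropolis pivot moves under the same score, where $g$ is a
  Cauchy-smoothed contact score $\sum 1/(1 + (d/8\,\text{Å})^2)$ over
  phosphoserine/basic bead pairs. The smoothing is deliberate: a hard
  8 Å indicator provides no gradient at the 20--40 Å separations where
  tails actually wander, and produces no measurable compaction. With the
  smoothed score, $\kappa = 5$ lowers the mean $R_g$ of the 120-residue
  monomer from $\approx 18.8$ Å to $\approx 15.7$ Å; $\kappa = 0$
  remains the exact unbiased walk.
* **Two-molecule systems** place the second molecule at a centroid
  separation above 60 Å and then relax it by rigid-body Monte Carlo
  under the inter-molecular contact score, so dynamic dimerization
  appears at $\kappa > 0$.
* **Mixtures** allocate subpopulation counts by the largest-remainder
  rule (ties to the lowest index), record ground-truth labels and use
  uniform prior weights.
* **Targets** are weighted Debye averages with
  $\sigma(q) = \text{noise} \cdot I(q)(1 + q/q_{max})$ Gaussian errors --
  the mild high-q error inflation typical of radially averaged detector
  data. The default q-grid is 60 log-spaced points on 0.01--0.30 Å$^{-1}$,
  a typical usable SEC-SAXS range; the default noise fraction is 0.02.

What passing tests on these ensembles shows: the reweighting machinery
recovers known populations (a 500-conformer 70/30 compact/extended
mixture at 1% noise is recovered to a weighted mean $R_g$ well within 5%
and a compact weight within $\pm 0.1$), and every analysis stage agrees
with an independent oracle. What it does not show: force-field realism,
solvent effects, phosphate chemistry, or the sampling breadth of
microsecond simulations -- none of which the generator models. Every
generator is a pure function of (specification, seed).

## Desk-scale sizes

The shipped defaults are sized for an ordinary workstation session:
synthetic ensembles of 80 (pipeline) to 500 (validation) conformers
rather than the thousands of snapshots a production simulation yields, a
60-point q-grid, GA pools equal to the ensemble, population 60--100 over
120--200 generations. All are configuration values, stated in
`defaultPipelineConfig()`, and scale up unchanged.

## Known limitations

* The one-bead Debye calculator is not an atomic-level predictor; it is
  internally consistent (and exact for its own model, to the $10^{-10}$
  oracle tests) but not comparable in absolute terms with atomic
  form-factor programs.
* $(c_1, c_2)$ are nearly degenerate with the scale at this resolution;
  interpret them only through the averaging protocol.
* The GCV-selected $\alpha$ for $P(r)$ can over-smooth sharply bimodal
  distance distributions; pass `alpha` explicitly when the shape is known.
* Chain-swap minimization enumerates the two labelings of a dimer;
  systems with more than two equivalent chains are rejected rather than
  guessed.
* Synthetic excluded-volume ensembles are much more conformationally
  diverse than molecular-dynamics snapshot ensembles; at the stated
  clustering cutoffs (10/20 Å) they fragment into many small clusters,
  whereas MD snapshots sampled every few nanoseconds form large ones.
* The NMR module computes perturbations from assigned peak lists; it does
  not process spectra or transfer assignments, and residues missing from
  either list are reported absent, never imputed as zero.
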