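# ensaxs

Ensemble reweighting and structural analysis of coarse-grained SAXS data.

## What it is for

Small-angle X-ray scattering (SAXS) of a flexible, multi-domain protein —
the motivating system is an HP1-family chromatin protein: folded
chromodomain (CD) and chromo shadow domain (CSD) cores joined by a
disordered hinge, with a phosphorylatable disordered N-tail — measures a
population average over many coexisting conformations. Simulated
conformer ensembles rarely reproduce such a measurement as-is, so the
standard analysis *reweights* the ensemble against the data and then asks
what the reweighted population looks like.

`ensaxs` provides that workflow end to end, for one-bead-per-residue
(Cα-trace) conformers:

* **SAXS calculator** — Debye formula
  `I(q) = Σᵢ Σⱼ fᵢ(q) fⱼ(q) sinc(q rᵢⱼ)` with a documented two-parameter
  form factor (`c1` effective excluded volume, `c2` hydration amplitude on
  exposed beads) and closed-form scale fitting.
* **Bayesian maximum-entropy (BME) reweighting** — weights minimize
  `L(w) = χ²(w)/2 − θ·S(w)` with `χ²(w) = Σᵢ ((Σⱼ wⱼ Iⱼᵢ − I_exp,i)/σᵢ)²`
  and relative entropy `S(w) = −Σⱼ wⱼ log(wⱼ/w⁰ⱼ)`, solved in the convex
  dual; θ scans with L-curve selection, effective-fraction
  `φ_eff = exp(S(w))` reporting, and the iterative protocol that averages
  per-snapshot `(c1, c2)` under the BME weights and reweights again.
* **Ensemble characterization** — weighted residue–residue
  contact-probability maps (11 Å bead criterion, intra-/inter-subunit),
  weight-modified GROMOS clustering (neighbour *weight sums* instead of
  counts) with representative structures, Guinier analysis, pair-distance
  distribution P(r) with regularized indirect Fourier transform, Dmax
  scanning, and EOM-style genetic-algorithm sub-ensemble selection with
  pool-versus-selected Dmax/Rg distributions.
* **Synthetic ensembles with known ground truth** — rigid domains joined
  by excluded-volume tails, phosphoserine/basic-segment compaction bias,
  one- and two-molecule systems, mixtures with known weights, and noisy
  target profiles; used to validate every stage.
* **NMR chemical-shift perturbations** —
  `Δδ = sqrt(ΔδH² + (ΔδN/5)²)` with per-segment (a1–a7 / b1–b7 style)
  summaries.

## Worked example

Build a 60-conformer synthetic mixture of a CSD-deletion-like monomer
(rigid CD, disordered tails; half compact under a phospho-contact bias,
half extended), synthesize a noisy target, and recover the population by
BME:

```r
library(ensaxs)

top  <- deltaCSDTopology(1)                      # 120-residue monomer
spec <- mixtureSpec(c(compact = 0.5, extended = 0.5),
                    kappas = c(5, 0), N = 60, topology = top, seed = 11)
mix  <- makeMixtureEnsemble(spec)

q      <- defaultQGrid()                         # 60 pts, 0.01-0.30 1/A
target <- makeTargetProfile(mix$ensemble, initialWeights(mix$ensemble),
                            qGrid = q, noiseFrac = 0.01, seed = 3)

scan  <- thetaScan(lapply(conformers(mix$ensemble), debyeProfile, qGrid = q),
                   target, 10^seq(-1, 4, length.out = 10))
theta <- selectTheta(scan)                       # L-curve elbow
res   <- iterativeBME(mix$ensemble, target, theta)
res

rg <- vapply(conformers(mix$ensemble), radiusOfGyration, 0)
cat(sprintf("true mean Rg %.2f A, reweighted %.2f A, compact weight %.3f\n",
            mean(rg), sum(ensembleWeights(res) * rg),
            sum(ensembleWeights(res)[mix$labels == 1])))
```

```
ReweightResult (Bayesian maximum entropy)
  theta = 4.64159, chi2 = 42.5 (reduced 0.708), S(w) = -0.0864
  phi_eff = 0.917, scale = 1.024, c1 = 1.014, c2 = -0.030
true mean Rg 17.50 A, reweighted 17.30 A, compact weight 0.511
```

The reweighted mean radius of gyration matches the ground truth to about
1%, the compact subpopulation keeps its true 50% share, the reduced χ² is
compatible with the 1% noise level, and `φ_eff ≈ 0.92` says the data
needed almost no departure from the prior — as it should when the prior
already matches the truth. `contactProbability()`,
`gromosClusterWeighted()`, `prFromProfile()`/`dmaxScan()` and
`gaSelect()` then characterize the reweighted ensemble; `runPipeline()`
chains all stages and writes TSV/JSON/PDB artifacts plus a manifest.

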