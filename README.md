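# bursteR

Quantification of transcriptional bursting from single-molecule and
live-cell imaging, for labs studying how a gene's promoter switches
between active and silent states — e.g. an estrogen-responsive locus
whose expression is heterogeneous across an MCF7 population because a
subset of alleles sits in a long-lived repressive chromatin state.

The package covers four readouts of the same two-state (telegraph)
promoter model, in which a unit switches

```
inactive  --kon-->  active      active  --koff-->  inactive
```

so the active fraction obeys dA/dt = kon − (kon + koff)·A, relaxing at
rate λ = kon + koff toward the equilibrium A_eq = kon/λ:

A(t) = A_eq + (A0 − A_eq)·e^(−λ(t−t0))

- **smFISH spot analysis** — iterative 2D Gaussian-mask localization
  with local background subtraction (`callSpots()`), cell/compartment
  assignment from label masks (`assignCompartment()`).
- **Transcription sites and burst size** — intron–exon colocalization
  within 5 px (`callTranscriptionSites()`), nascent-RNA counts by
  single-molecule median normalization (`burstSizes()`), population
  summaries (`populationSummaries()`).
- **Live-cell traces** — two-state Gaussian HMM segmentation of MS2
  transcription-site traces (`fitTelegraphHMM()`, `decodeStates()`)
  and censoring-aware dwell-time statistics (`extractDwells()`).
- **Sorted-population kinetics** — joint relaxation-to-equilibrium fits
  with bootstrap confidence intervals (`fitRelaxation()`,
  `bootstrapRelaxationCI()`), plus gene-set overlap and
  expression-variability statistics (`hypergeometricOverlap()`,
  `cvByGroup()`).

Every stage has a ground-truthed synthetic generator
(`simulateTelegraphTrace()`, `simulateSmfishField()`,
`simulatePopulationTrajectories()`, `simulateGeneUniverse()`), so the
full pipeline runs and is tested without any external data. See the
vignette `vignettes/bursting-dynamics.Rmd` for the models, assumptions
and numerical choices.

## Worked example: how fast do sorted populations re-equilibrate?

Cells sorted into high- and low-expressing fractions drift back toward
the bulk equilibrium as alleles switch states. Fitting both
trajectories jointly recovers the switching rates:

```r
library(bursteR)

traj <- simulatePopulationTrajectories(
  kon = 0.052, koff = 0.2385,            # per day
  a0ByPopulation = c(high = 0.45, low = 0.06),
  sampleDays = c(1, 4, 6, 10),
  nCellsPerPoint = 500, nReplicates = 3, seed = 42
)
fit <- fitRelaxation(traj, mode = "fitted_equilibrium", seed = 1)
fit
#> TwoStateFit (fitted_equilibrium)
#>   kon  = 0.04931 /d   koff = 0.239 /d   lambda = 0.2883 /d
#>   A_eq = 0.171 (17.1% transcribing at equilibrium)
#>   A0[high] = 0.428
#>   A0[low] = 0.072
#>   RSS = 0.007101
```

The fitted equilibrium (17.1% of cells transcribing) and rates match
the generating values (A_eq = 17.9%, kon = 0.052/d) to within the
binomial sampling noise of 500 cells per point. The derived quantities
have direct kinetic meaning: `meanResidenceTime(0.052)` ≈ 19.2 days is
the mean time an allele stays repressed, and

```r
timeToEquilibrium(a0 = 0.06, aEq = 0.179, lambda = 0.2905, tol = 0.005)
#> [1] 10.91
```

is how long the low-sorted population needs to come within half a
percentage point of equilibrium. `bootstrapRelaxationCI()` adds 95%
percentile intervals by resampling replicates within each
(population, day) and refitting.

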