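---
title: "Quantifying transcriptional bursting across imaging modalities"
author: "bursteR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcriptional bursting across imaging modalities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bursteR)
```

# The biological problem

Many genes are not transcribed continuously: the promoter switches
between an active state, during which polymerases initiate in quick
succession, and an inactive state that can last from minutes to days.
The resulting "bursts" of nascent RNA can be observed directly at a
single locus — in fixed cells by single-molecule RNA FISH (smFISH),
where a transcription site (TS) appears as a bright nuclear focus in
which intron and exon probe signals colocalize, and in live cells by
MS2 stem-loop tagging, where the TS fluorescence fluctuates as the
promoter turns on and off. At a longer timescale, sorting a cell
population by expression level and following each sorted fraction's
percentage of transcribing cells over days measures how fast cells
exchange between expression states.

bursteR implements the quantitative layer for all three readouts, plus
the gene-set statistics used to connect expression heterogeneity to
chromatin state. Every analysis stage has a matched synthetic-data
generator with known ground truth, so the whole pipeline is testable
without any external data.

# The two-state (telegraph) model

Both the live-cell and the population analyses rest on the same
abstraction. A promoter (or a cell) is either active or inactive and
switches with first-order rates:

$$ \mathrm{inactive} \underset{k_\mathrm{off}}{\overset{k_\mathrm{on}}
   {\rightleftharpoons}} \mathrm{active} $$

The fraction of active units $A(t)$ obeys

$$ \frac{dA}{dt} = k_\mathrm{on}(1 - A) - k_\mathrm{off} A
   = k_\mathrm{on} - \lambda A, \qquad \lambda = k_\mathrm{on} + k_\mathrm{off}, $$

whose unique solution relaxes exponentially toward the equilibrium
$A_\mathrm{eq} = k_\mathrm{on}/\lambda$:

$$ A(t) = A_\mathrm{eq} + (A_0 - A_\mathrm{eq})\, e^{-\lambda (t - t_0)}. $$

`relaxFraction()` implements this solution and the test suite verifies
it against direct numerical integration of the ODE (deSolve, tolerance
1e-8 over 50 days), so the closed form and the differential form are
interchangeable. Dwell times in each state are exponential with means
$1/k_\mathrm{off}$ (active) and $1/k_\mathrm{on}$ (inactive);
`meanResidenceTime()` is that reciprocal.

# smFISH spot analysis

`detectCandidates()` selects 8-connected local maxima exceeding a robust
threshold (median + `thresholdSd` × MAD, default 5), suppressing
secondary maxima within 3 px of a brighter one — noise on a bright
spot's flank otherwise produces duplicate candidates that the fit would
collapse anyway. `fitGaussianMask()` refines each candidate with the
fixed-width iterative Gaussian-mask estimator: the local window's
background (median of its border pixels) is subtracted, then the
centroid is recomputed under Gaussian weights of sd `psfSigma` until the
shift drops below 1e-3 px (at most 100 iterations). Integrated
intensity comes from regressing the windowed signal on the
unit-amplitude mask with an intercept; the intercept absorbs any
residual constant background (inside small windows the border median
sits on the spot flank and would otherwise bias photometry low by
~10%), and the slope times $2\pi\sigma^2$ is the integrated intensity.
Candidates that fail to converge, drift out of their window, or carry
no positive signal are rejected with a reason code.

Defaults the data do not pin down — the candidate threshold (5 robust
sds) and the fitting window (4·`psfSigma` rounded up to odd) — follow
common practice for diffraction-limited spot calling and are exposed as
parameters. Coordinates are 0-based (row, col) pixel centres and all
distances are Euclidean pixels, one convention used consistently so
that the 5-px colocalization rule below is unambiguous.

`assignCompartment()` maps each spot to segmentation label images
(0 = background, k = cell k): the cytoplasm label at the rounded
position gives the cell, the nucleus mask decides nuclear versus
cytoplasmic, and background spots are excluded from per-cell
statistics.

# Transcription sites and burst size

A TS is a nuclear intron spot paired with a nuclear exon spot of the
same cell at Euclidean distance ≤ 5 px (boundary inclusive). Pairing is
one-to-one and greedy in order of increasing distance, with ties broken
by intron intensity then input order; the greedy rule (the matching the
data supports is almost always unambiguous at TS densities of a few per
nucleus) is verified in the tests against an independent repeated-argmin
implementation and against brute-force minimum-distance matching on
small instances. The TS position is the intron spot's (introns are
spliced co-transcriptionally, so they mark nascent RNA); the exon
member supplies the intensity.

Burst size is the TS exon intensity divided by the median intensity of
that cell's cytoplasmic exon spots, which are single mRNA molecules.
Cells with fewer than 5 cytoplasmic exon spots give an undefined (NA)
burst size — the single-molecule calibration is too unreliable — never
zero. `populationSummaries()` reports the percentage of transcribing
cells (≥ 1 TS), a TS-per-cell histogram with bins 0–4 and "5+" (MCF7
cells are aneuploid and can carry five or more alleles), and burst
sizes both pooled across eligible TS and as per-cell medians, since
either pooling convention is defensible for a population figure.

# Live-cell trace segmentation

`fitTelegraphHMM()` fits one two-state hidden Markov model with
Gaussian emissions per population, pooling all alleles: per-trace fits
at 512 frames would leave emission parameters noisy, and alleles of a
sorted population are exchangeable for this purpose. Initialization
thresholds the pooled intensities at their 70th percentile (k-means
fallback if that split is degenerate); EM stops when the log-likelihood
gains less than 1e-6 or at 500 iterations. The state with the larger
emission mean is always labelled active. Decoding uses the Viterbi
path — dwell statistics need contiguous runs, which posterior
thresholding does not guarantee — with per-frame posteriors reported
alongside.

`extractDwells()` converts maximal constant-state runs to minutes
(`frames × dt / 60`, dt defaulting to the 100-s frame interval of a
512-frame, 14.2-h movie). Runs touching either end of a trace are
censored: their true length is unknown, and including them would bias
the long inactive dwells downward. Censored runs are excluded from the
medians and counted explicitly, and medians are pooled over all alleles
of a population (per-allele medians are available from the dwell
table). A four-frame active run is 6.67 min and a 26-frame run
43.33 min, the printed precision of the medians this kind of experiment
reports.

# Relaxation fitting and uncertainty

`fitRelaxation()` jointly fits the relaxation solution to all sorted
populations: one shared $\lambda$ and $A_\mathrm{eq}$, one $A_0$ per
population, minimizing unweighted squared residuals on fractions (an
inverse-binomial-variance weighting is available but off by default —
the observed fractions have nearly constant variance over the fitted
range, and unweighted least squares is the more transparent default).
In `fixed_equilibrium` mode $A_\mathrm{eq}$ is pinned (default 0.20,
the bulk-population equilibrium); in `fitted_equilibrium` mode it is
free. $k_\mathrm{on} = A_\mathrm{eq}\lambda$ and
$k_\mathrm{off} = \lambda - k_\mathrm{on}$ are derived, so the
identities $\lambda = k_\mathrm{on} + k_\mathrm{off}$ and
$A_\mathrm{eq} = k_\mathrm{on}/\lambda$ hold by construction.
Optimization is L-BFGS-B with box constraints
($\lambda \in [10^{-4}, 10]$ /d, fractions in $[0,1]$) from 20 seeded
multi-starts with $\lambda$ drawn log-uniformly on (0.01, 2) /d; flat
data (no variance across observations) or populations observed on
fewer than two distinct days are rejected as unidentifiable.

`bootstrapRelaxationCI()` gives 95% percentile intervals by resampling
replicate measurements with replacement within each (population, day)
cell and refitting (warm-started from the point estimate plus two
perturbed starts). Whole-trajectory resampling is available by flag;
with few replicate trajectories it is coarser. A caveat worth stating:
with only three replicates per cell, the nonparametric bootstrap's
plug-in variance underestimates sampling variance by the classic
$(n-1)/n$ factor, so percentile intervals run narrow and their
empirical coverage sits in the mid-80s rather than at 95%; coverage
approaches nominal as replicates grow (the test suite measures this).
Interval widths at three replicates should therefore be read as
slightly optimistic.

`timeToEquilibrium()` inverts the exponential: the time until
$|A(t) - A_\mathrm{eq}| \le \mathrm{tol}$ is
$\ln(|A_0 - A_\mathrm{eq}|/\mathrm{tol})/\lambda$, floored at zero. The
tolerance defining "converged" is the user's to choose; at
$\lambda \approx 0.29$/d a 0.5-percentage-point tolerance puts a
population starting at 6% within ~11 days of its equilibrium.

# Overlap and variability statistics

`normalizeBackground()` intersects the universes of two gene sets
(upper-casing symbols first — symbol dialects differ) because an
overlap is only interpretable against genes both assays could have
reported. `hypergeometricOverlap()` reports the overlap as a percentage
of set A and an upper-tail hypergeometric p-value $P(X \ge k)$, the
standard enrichment convention with the observed value included; the
implementation is checked exactly against exhaustive enumeration of all
draws for small universes. The p-value depends on the universe
supplied: the same 380-gene overlap of a 934-gene set against 1913 DEGs
is 40.7% regardless, but its significance is only meaningful for the
universe actually used.

`cvByGroup()` computes per-gene coefficients of variation across cells
(sample sd over mean; zero-mean genes are excluded and counted, not
given infinite CV) and compares two gene groups with a Welch two-sided
t-test. Raw counts are the default; a CPM flag rescales columns first,
since published single-cell matrices come in both conventions. Under
the null (both groups drawn from one expression distribution) the
test's p-values are uniform; the suite checks this calibration over 500
simulated matrices.

# Synthetic data: what it emulates, and what it does not

`simulateTelegraphTrace()` draws exact exponential dwell sequences
(event-driven, Gillespie-style) and samples the state at frame
midpoints, avoiding the aliasing bias that on-frame sampling introduces
for dwells near the frame interval. Active-frame intensity is constant
at `meanNascent × intensityPerRNA` plus Gaussian noise — deliberately
no birth–death of individual nascent transcripts, which suffices for
validating segmentation but understates intra-burst intensity
fluctuation of real MS2 traces. The complete event-level dwells are
returned too; their means match $1/k$ closed forms (tested at 2%),
bearing in mind that complete dwells inside a finite window are
slightly short on average (inspection paradox, bias ~ mean²/window), so
the closed-form check uses windows long relative to the dwells.

`simulateSmfishField()` builds disjoint axis-aligned cells with
elliptical nuclei (label-image convention), places TS in nuclei —
same position in both channels, exon intensity `nascent ×
singleRnaIntensity` — and single-molecule cytoplasmic spots in the exon
channel, each rendered as a 2D Gaussian of sd `psfSigma` on a constant
background with additive Gaussian noise. The microscope's real noise is
Poisson-dominated with structured background and out-of-focus light;
additive Gaussian noise is a deliberate simplification, so passing
detection tests bounds algorithmic error, not real-world imaging error.
Spots are kept ≥ 4·`psfSigma` apart by default; performance on closer
spots is untested by design.

`simulatePopulationTrajectories()` evaluates the relaxation solution
exactly and adds binomial sampling noise
(`Binomial(nCells, A(t))/nCells`), which is the correct observation
model for "fraction of n cells transcribing". `simulateGeneUniverse()`
plants an exact overlap between two sets in a labelled universe. All
generators are pure functions of their arguments and a spec-level seed,
with per-trace child seeds split deterministically.

# Problem sizes and numerical choices

The test suite sizes its simulations to be decisive yet quick: dwell
closed-forms use 100 traces of 8192 frames (~27,000 complete dwells per
state); HMM recovery uses the study geometry, 50 alleles × 512 frames
at SNR 5, over 10 seeds; relaxation recovery uses 500 cells/point with
3 replicates (the study design) and bootstrap calibration 200 outer
replications × 200 resamples; smFISH accuracy uses 9–20-cell fields at
SNR ~10. Optimizer tolerances (L-BFGS-B `factr` 10 for point fits, 1e3
for bootstrap refits), the EM tolerance (1e-6), the Gaussian-mask
convergence rule (1e-3 px), and an emission-sd floor (1e-4 of the
intensity range) are fixed in code and documented at the call sites.

# Known limitations

- Maximum-intensity projections only; no 3D fitting, tracking,
  chromatic correction or photobleaching model.
- The HMM has exactly two states with Gaussian emissions; multi-state
  promoters or strongly non-Gaussian noise require a different model.
- Dwell medians are quantized to the frame interval. When the median
  dwell is only a few frames, Viterbi's (optimal) suppression of
  single-frame blips can move the pooled median by half a frame — a
  ~17% shift at a 3-frame median — even at ~99.9% frame accuracy; mean
  dwells from the transition matrix (`hmmDwellMeans()`) are smoother.
- Bootstrap intervals are optimistic at very small replicate counts
  (see above).
- The hypergeometric p-value is only as meaningful as the background
  universe supplied; the package never invents one.
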