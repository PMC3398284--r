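---
title: "Competitive fitness profiling of hemizygote pools: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competitive fitness profiling of hemizygote pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemipool)
```

## The experimental system

A pool of several thousand hemizygous yeast deletion strains — diploids each
carrying one deleted and one intact copy of a single gene — competes in a
continuous culture. In a **chemostat** the dilution rate $D$ is set by the
operator and, at steady state, equals the population's mean specific growth
rate. In a **turbidostat** the dilution rate is feedback-controlled to hold
biomass constant, so the culture settles at the pool's maximum achievable
growth rate and $D$ drifts upward as faster strains take over.

The abundance $X_i$ of strain $i$ obeys

$$\frac{dX_i}{dt} = \mu_i X_i - D\,X_i,$$

so the log abundance is linear in time with slope $\mu_i - D$. Because $D$
equals the population mean growth rate, the slope of $\ln$ *relative*
abundance measures each strain's growth-rate deviation from the population
average. That slope is the **modified flux control coefficient** (FCC′): a
scaled surrogate for the metabolic-control-analysis flux control coefficient
of the halved gene, measured for the copy-number perturbation $2 \to 1$.
Strains with a significantly negative FCC′ are **haploinsufficient** (HI);
significantly positive ones are **haploproficient** (HP). The
`deviation_index()` helper rescales a slope into the deviation index
$DI = (c/D)\,(\mu - D)$ with $c$ the initial copy number; note the sign
convention: an HI strain (negative FCC′) indicates *positive* flux control by
the gene when its copy number is raised from one to two.

## The simulator

`simulate_proportions()` propagates strain *proportions* under replicator
dynamics,

$$p_i(t) = \frac{p_i(0)\,e^{\mu_i t}}{\sum_j p_j(0)\,e^{\mu_j t}},$$

evaluated in log space for numerical stability. Working on proportions rather
than absolute cell numbers removes the unobservable total-biomass scale:
under the steady-state closure the proportion trajectories are identical in
chemostat and turbidostat mode, and the two modes differ only in the reported
dilution-rate trace (fixed versus the population mean
$\sum_i \mu_i p_i(t)$). The closed form satisfies the pairwise law
$d\ln(p_i/p_j)/dt = \mu_i - \mu_j$ exactly, and the test suite checks it
against fourth-order numerical integration of the ODE.

`sample_pool()` draws per-strain growth rates $\mu_i = \mu_\mathrm{ref} +
\epsilon_i$ from a spike-and-tails effect distribution: by default 50% of
strains have exactly zero effect, 25% carry negative half-normal effects with
scale 0.02 h⁻¹ and 25% positive half-normal effects with scale 0.01 h⁻¹,
truncated so $\mu_i \ge 0$. The asymmetry (wide deleterious tail, narrow
beneficial tail) mirrors the empirically HI-heavy spectrum of hemizygote
fitness effects. The default $\mu_\mathrm{ref} = 0.32$ h⁻¹ matches the rate
at which a turbidostat culture of such a pool stabilises; the corresponding
chemostat comparisons in this package's examples use fixed rates between
0.07 and 0.3 h⁻¹ (doubling times of roughly 10 h down to 2.3 h;
`doubling_time()` converts). A typical design — the package default — takes
five continuous-culture samples at 24 h intervals with two biological and two
technical replicates, which at 0.32 h⁻¹ spans about 30 population doublings
over 65 h (`generations_elapsed()`).

`observe()` turns true proportions into measured abundances in two stages:
multinomial sampling of `depth` cells per measurement (counting noise,
including dropout zeros at low depth), then multiplicative lognormal noise
with unit mean and coefficient of variation `noise_cv` (default 0.2),
standing in for hybridisation/measurement variability. No published error
model exists for the tag-array measurements this emulates, so the default CV
is a calibration placeholder the user should adjust to their platform. Each
biological replicate receives an independent noise seed spawned
deterministically from the single base seed, making every dataset exactly
reproducible.

What the generator deliberately omits: substrate (Monod) kinetics and
nutrient-specific physiology, strain-specific lag phases, batch/preculture
dynamics before the continuous phase, tag-specific hybridisation biases, and
cross-hybridisation between tags. Passing recovery tests on these synthetic
data therefore demonstrates the statistical machinery, not robustness to
array-specific artefacts.

## FCC′ estimation and classification

`fit_fitness()` normalises each sample to relative abundance after adding a
pseudocount of 0.5 (keeping zero counts finite under the log), then fits, per
strain and experiment, an ordinary least-squares regression of $\ln$ relative
abundance on time with one intercept per replicate series (biological ×
technical) and a single shared slope. Keeping technical replicates as
separate rows rather than averaging preserves residual degrees of freedom;
with the default design (20 samples, 4 series) the slope has 15. Samples
where the raw count is zero are dropped from that strain's regression, and
strains with fewer than three nonzero samples are flagged insufficient
(`NA`). Two-sided P-values for slope ≠ 0 use the t distribution with the
residual degrees of freedom — deliberately not the normal approximation,
since designs with as few as four time points are common. P-values are
adjusted per experiment with the Benjamini–Hochberg step-up rule and strains
are classified HP (positive slope, FDR < α), HI (negative slope, FDR < α) or
NS, with α = 0.05 by default. An exactly zero slope classifies as NS: the
sign rule is undefined at zero and the case has measure zero in noisy data.

The per-strain regression is computed in closed form (within-series
centering) simultaneously for all strains, which makes a 5,800-strain,
200-seed null calibration run in seconds; the test suite verifies the
vectorised path is numerically identical to the per-strain linear model.

Two designed properties anchor the statistics. First, on fully neutral pools
(all effects zero) the realized fraction of strains called HI or HP stays
below α on average — BH control under the complete null; the acceptance
script measures this over 200 seeded pools. Second, slope confidence
intervals achieve nominal coverage: a −0.03 h⁻¹ effect embedded in an
otherwise neutral 1,000-strain pool is covered by the 95% CI in 95% ± 3% of
500 seeded runs. The neutral background matters for interpreting that check:
in a pool with many selected strains the population mean itself drifts, so
the estimand is the time-averaged deviation $\mu_i - \bar\mu(t)$ rather than
$\mu_i - \bar\mu(0)$. For the same reason the rank-agreement check
(Spearman ρ > 0.9 between estimated FCC′ and true $\mu_i - \bar\mu$) uses a
pool with a fully continuous effect distribution: with the default 50% spike
at zero, half the true values are tied and the rank correlation measures tie
handling rather than recovery.

## Gene-set enrichment and overlap statistics

`lr_enrichment()` tests each gene set by logistic regression of the
membership indicator on the per-gene FCC′, standardised to unit variance. A
signed gene-level statistic is essential here: the coefficient's sign then
reads directly as direction of enrichment — positive among haploproficient
genes, negative among haploinsufficient ones — which a transformed P-value
could not provide. The reported odds ratio is $e^\beta$ per standard
deviation of FCC′; Wald P-values are BH-adjusted across all tested sets. Sets
are tested one at a time with a single predictor, minimum size 3 and no
maximum (terms with over a thousand members are legitimately testable).
Perfect separation — possible when a set coincides with an extreme tail of
the score distribution — is detected from the fitted probabilities and
flagged, and the affected set is refitted with a lightly ridge-penalised
logistic regression (penalty 0.01 on the slope only) so a finite coefficient
and standard error are still reported.

`hypergeom_overlap()` provides exact hypergeometric tails for overlap
(upper) and depletion (lower) questions, and `class_frequency_table()`
applies it per category of a gene partition against the universe-wide HI/HP
frequencies. The canonical worked example: in a universe of 5,713 scored
genes of which 1,932 (34%) are HI, a 123-gene category containing 31 HI
genes (25%) has a depletion probability
$P(X \le 31) = 0.0239$ — mild underrepresentation rather than outright
depletion.

## Cross-experiment comparison

`correlation_matrix()` computes Spearman rank correlations between all pairs
of experiments over the pairwise-complete gene set of each pair (experiments
score different strain subsets, so a per-cell n is reported rather than
imposing listwise deletion). `cluster_experiments()` then clusters the
experiments by complete-linkage agglomeration on the Euclidean distances
between *rows of the correlation matrix* — each experiment is represented by
its vector of correlations to all experiments, not by its raw gene profile.
Rows are ordered lexicographically by label before clustering so merge order
is deterministic under ties. Dendrograms export to Newick via
`dendrogram_newick()`. `covariate_correlation()` correlates FCC′ with any
user-supplied per-gene covariate (expression fold change, protein abundance,
dosage compensation, interaction degree, …) on the shared gene set.

## Dean–Jett–Fox DNA-content fitting

`djf_fit()` decomposes a flow-cytometry DNA-content histogram into a G1
Gaussian, a G2/M Gaussian and an S-phase component modelled as a
second-degree polynomial event density over DNA content between the G1 and
G2 means, convolved with the proportional measurement Gaussian — the classic
Dean–Jett parameterisation. The G2/G1 mean ratio is constrained to
[1.85, 2.15] rather than fixed at 2.0, absorbing instrument linearity drift
while keeping the fit identifiable. Shape parameters (G1 mean, the two CVs,
the ratio) are optimised by bounded L-BFGS-B; for any shape the component
amplitudes solve a linear least-squares problem, with negative Gaussian
amplitudes zeroed and refitted. Initialisation takes the two largest
smoothed local maxima with a position ratio near two; if no plausible G2
peak exists the fit falls back to a single Gaussian and is flagged
degenerate. Phase fractions are component areas as percentages of the total
model area, so they sum to 100 by construction. Because "two peaks" can also
be read as a G1+G2-only model, a `two_gauss` variant is provided; the full
model is the default and never fits worse in residual terms.

On synthetic 20,000-event histograms with 5% CV, recovered %G1 is accurate
to within about two percentage points across a grid of true fractions; the
acceptance suite requires mean absolute error ≤ 3 points. Doublets and
debris are not modelled — histograms are assumed pre-gated — and input is a
plain two-column TSV (bin centre, count); an FCS reader is a documented
extension point, not a dependency.

## Pipeline and reproducibility

`run_pipeline()` chains simulate → fit → classify → enrich → compare from a
single nested configuration (an R list or YAML file), writing TSV outputs
plus a JSON run report. All paths are validated before any stage runs. One
base seed drives every random draw, so identical configurations produce
byte-identical outputs; the package's functions are the primary interface,
with the pipeline as a convenience orchestrator.

## Problem sizes and numerical choices

The bundled checks use: 200 neutral 5,800-strain pools for the
false-call-rate calibration; 500 seeded 1,000-strain pools for CI coverage;
one 5,800-strain pool for rank agreement; exhaustive hypergeometric
enumeration up to universe size 25; BH brute-force vectors up to length 20;
and a %G1 recovery grid of 14 histograms at 20,000 events. Replicator
arithmetic is done in log space with a column-wise max shift;
regression sums of squares are guarded against cancellation (residual sums
clipped at zero, standard errors below 10⁻¹² treated as noiseless fits).

## Known limitations

Slopes are plain OLS — no hierarchical shrinkage, no outlier-robust loss —
so single aberrant samples propagate into the estimate. The noise model is
multiplicative-lognormal on multinomial counts; overdispersion beyond that
(e.g. PCR jackpots) is not modelled. Enrichment assumes the supplied gene
sets are already propagated through any ontology graph. The simulator's
neutral-pool FDR calibration says nothing about miscalibration caused by
array-specific normalisation artefacts in real data.
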