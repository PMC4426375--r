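---
title: "Models and methods behind riailmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind riailmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riailmap)
```

riailmap implements a complete quantitative-genetics workflow for two-parent
recombinant inbred advanced intercross line (RIAIL) panels of the kind used
in *C. elegans*: a breeding-design simulator, a two-state genotype caller
with HMM imputation, extraction of fecundity and body-size traits from
large-particle-sorter event tables, and linkage mapping with a
correlation-based LOD statistic, permutation false-discovery-rate control
and variance decomposition. This vignette explains each model, its
assumptions, and the numerical choices that were genuinely open.

## The breeding simulator

`simulate_cross()` runs the advanced-intercross design forward: reciprocal
crosses between an N2-background strain and CB4856 give four F1 classes that
differ in mitochondrial and X-chromosome origin; `n_intercross_gens`
(default 10) generations of random single-pair mating follow, and finally
`n_selfing_gens` (default 10) generations of selfing of one hermaphrodite
per line.

Modelling assumptions:

* **Meiosis** uses the Haldane model: crossover counts are Poisson with mean
  equal to the chromosome's genetic length in Morgans, positions uniform, no
  interference. Nothing in the design motivates an interference model, and
  Haldane keeps the map algebra exact.
* **Sex chromosome**: males are X0; the male X is transmitted intact (no
  recombination) or not at all, which determines offspring sex.
  Hermaphrodite X pairs recombine normally. Mitochondria are maternal and
  tracked for fidelity to the reciprocal design, but nothing downstream uses
  them.
* **Equal contribution**: each generation randomly re-pairs males with
  hermaphrodites and every pair leaves exactly one hermaphrodite and one
  male in the next generation. This is the literal reading of an
  equal-contribution AIL protocol and fixes the effective population size at
  twice the pair count.
* **Incompatibility**: a one-locus sperm-parent toxin/zygotic antidote
  element (the *peel-1*/*zeel-1* pattern) is modelled as death, with
  probability `incompatibility_penetrance`, of embryos homozygous CB at the
  locus whose sperm parent is heterozygous there. The same rule applies
  during outcrossing and selfing, so one penetrance knob spans the range
  from the full incompatibility to a residual skew. Offspring are resampled
  until viable, with an attempt cap guarding degenerate settings.
* **Residual heterozygosity** after the selfing phase is resolved by a fair
  coin per contiguous heterozygous run, because the downstream encoding is
  strictly two-state. Selfing halves per-locus heterozygosity each
  generation, so ten generations leave about `2^-10` of the intercross-phase
  heterozygosity; the simulator records both quantities as attributes so
  tests can check the decay directly. Because surviving heterozygous cells
  cluster in linked runs, that check uses a map of many short chromosomes,
  where counts are nearly binomial.

The panel used throughout the tests is 357 lines on a 1454-marker map with
six 50-cM chromosomes whose physical sizes mirror the *C. elegans* genome —
the size of panel this design is built to produce.

## Synthetic phenotypes and sorter events

`simulate_phenotypes()` plants additive QTL on a unit-variance scale: a
locus with variance fraction `ve` has effect `sqrt(ve)` on the +1/−1
genotype code, a polygenic strain effect tops genetic variance up to the
target broad-sense heritability `h2`, and replicates add residual noise with
variance `1 - h2`. Genotype codes in an unselected panel have variance very
close to 1, so realized marker r² matches `ve` up to sampling error
(sd ≈ 0.035 at 357 lines).

`sim_trait_panel()` emulates the 25-trait structure of a sorter assay
(fecundity plus eight summary statistics of each of three size parameters).
Traits are organised in blocks; within a block they share a latent factor
with variance 0.8, reflecting both shared biology and shared measurement
(a block's statistics summarise the same animals in the same wells).
Planted loci act at the block level: a locus that changes a size parameter
moves every summary statistic of that parameter, which is exactly why real
panels detect one locus many times across correlated traits. Five default
loci on chromosomes I–V explain 8–12% of variance each.

`simulate_well_events()` generates the sorter's flat event table. Each well
draws an offspring count (Poisson, mean shifted by the strain's fecundity
value), each animal a developmental stage from a five-class occupancy
distribution, TOF from the stage's normal, and EXT proportional to TOF with
per-animal thickness variation and additive noise. A stage-QTL shift
redistributes occupancy only between the two oldest classes, so it moves
the upper quantiles of the length distribution while leaving the lower ones
untouched — the pattern that distinct loci acting on distinct developmental
stages produce. Bubbles are injected at a contamination rate with the
signature that matters to the classifier: they are optically thin for their
size (EXT ≈ 0.15·TOF against ≈ 1.2·TOF for animals). Wash wells contain
only bubbles; when the contamination rate is zero they are empty, so a
bubble-free simulation emits animals only.

What the generator does **not** model: dauer or starvation physiology, male
mating, temperature, instrument drift within a run, or fluorescence signal
(channels are carried but near-constant). Passing tests therefore show that
the pipeline recovers what this generative model plants, not that it is
robust to every artefact of real sorter data.

## Genotype calling

`em_two_component()` fits a univariate two-component Gaussian mixture by EM
(convergence when the log-likelihood improves by < 1e-8, at most 500
iterations; the trace is returned and tested for monotonicity). The
components share one variance: allele clusters on a one-dimensional
intensity axis are comparably tight, and the homoscedastic model prevents a
lone mid-gap value from being absorbed into an artificially widened cluster
— which would otherwise give it a confident, arbitrary call. The lower-mean
component is labelled N2 unless anchor strains (parental controls present
in the plate) say otherwise.

`call_genotypes()` assigns the max-posterior genotype and sets calls with
winning posterior below 0.95 to NA. The cutoff is not printed anywhere
authoritative; 0.95 yields a ~1% NA rate on GoldenGate-like simulated data,
matching the scale of NA calls such platforms produce. Markers whose
non-missing allele frequency exceeds 65% N2 or 60% CB are blanked entirely
(`allele_frequency_filter()`, strict inequalities) but kept as map
positions so imputation can bridge them; filtering happens before
imputation so a systematic skew cannot propagate.

`hmm_impute()` runs a two-state forward–backward pass per chromosome.
Transition probabilities are the empirical discordance rates between
adjacent observed calls across strains — robust to the panel's actual
(intercross-expanded) recombination density without committing to a map
expansion formula — smoothed with an add-half pseudo-count and clamped to
[1e-4, 0.45]. Emission error is `epsilon` (default 0.01); NA is
uninformative. Missing calls take the max-posterior state. Observed calls
are overturned only when their posterior falls below `1 - epsilon` *and*
the alternative state's posterior exceeds 0.8: an isolated discordant call
is mathematically indistinguishable from a genuine double recombinant
(both give posteriors near 0.5 at sparse marker spacing), and flipping on a
bare argmax would erase real recombination events — on noise-free input the
caller-plus-imputer is exactly the identity, which is one of the package's
invariant tests. The margin separates confident contradictions (posterior
≈ 0.95 at GoldenGate density) from ambiguous singletons.

## Sorter-event processing

`read_events()` joins flat CSV event rows to a plate layout and logs
malformed rows; `hardware_filter()` applies the instrument acquisition
minimums EXT ≥ 50 and TOF ≥ 20 (inclusive). `train_bubble_classifier()`
fits a linear support-vector machine (hinge loss, L2 penalty, cost fixed at
1) on standardized (TOF, EXT, EXT/TOF); the learned weights expose that the
density-for-length features dominate, matching how bubbles differ from
animals. `summarize_wells()` computes, per non-wash well, the animal count
`n` (every object in a well is an offspring of its founding hermaphrodite)
and eight statistics — mean, variance, IQR, and the 10/25/50/75/90th
quantiles — for TOF, EXT and per-animal EXT/TOF: 25 trait columns. Numerical
conventions are pinned for reproducibility: type-7 (linear interpolation)
quantiles, n−1 variance with NA below two animals, and EXT/TOF computed per
animal before summarising (the ratio of summaries is not the summary of
ratios).

## Trait construction

`regress_nuisance()` removes assay plate, row and column main effects per
trait by OLS (no interactions: the smallest model matching "plate and
position"), `aggregate_replicates()` averages replicate wells (the
variance-minimizing choice; the protocol does not dictate one),
`scale_traits()` z-scores with the population (n) denominator so "variance
of one" is literal, and `condition_residuals()` regresses each treatment
trait on its control counterpart across strains and re-scales the
residuals, isolating treatment-specific variation. Missing strain-condition
cells stay missing; mapping deletes them pairwise.

## Linkage mapping

The mapping statistic for marker–trait correlation `r` over `n` complete
pairs is

$$\mathrm{LOD} = -\,n\,\frac{\ln(1-r^2)}{2\ln 10} \;=\; \frac{n}{2}\log_{10}\frac{1}{1-r^2},$$

invariant to genotype label swaps and affine trait transforms (both are
test invariants, and the two algebraic forms agree to 1e-12 in a dedicated
check). `iterative_scan()` runs up to three passes: after each pass the
per-chromosome maxima above threshold become peaks, the trait is
residualized on all peak genotypes, and the residual is rescanned, keeping
the per-marker maximum across passes. A literal re-run of an identical
deterministic scan would be vacuous; the conditional reading is the one
under which "three iterations" does work, letting a second linked QTL
emerge once the first is absorbed.

`permutation_fdr()` estimates the 5% FDR threshold jointly over all
(trait, chromosome) peaks: each permutation applies one shared row
permutation to the whole trait matrix, preserving inter-trait correlation,
and reruns the per-chromosome-max scan. FDR(T) is the permutation-mean peak
count at T divided by the observed count; the selected threshold is the
smallest point on a 0.01-LOD grid (1–6) with defined FDR ≤ 5%, escalating
above the largest observed peak when no point qualifies. Two consequences
are worth knowing. First, the expected count is linear in the number of
(trait, chromosome) pairs whatever the correlation structure, so trait
correlation enters only through the observed counts. Second, the threshold
therefore depends on signal density: with ~30 true (trait, chromosome)
peaks across a correlated 25-trait panel the selected threshold sits near
LOD 3, while a single-trait scan with one QTL selects a similar value from
the null tail alone. Confidence intervals are 1.5-LOD-drop: the maximal
contiguous marker run containing the peak within 1.5 LOD of it. Variance
explained is r² at the peak on the scaled trait, and its ratio to
broad-sense heritability (capped at 1, warned — winner's curse can inflate
r² past it, which is logged rather than corrected) gives the fraction of
heritable variance assigned to the QTL. Ties for a chromosome maximum break
to the lowest physical position, deterministically.

## Heritability

`estimate_h2()` fits the random-intercept model
\(y_{ij} = \mu + s_i + e_{ij}\) by REML (via lme4) and reports
\(H^2 = \sigma^2_s/(\sigma^2_s + \sigma^2_e)\), the fraction of phenotypic
variance explained by strain. Replicates enter after nuisance regression,
so no further fixed effects are warranted. A one-way ANOVA
method-of-moments estimator is the fallback when REML fails and the
cross-check in balanced designs, where the two coincide when the moment
estimate is interior. Negative or boundary strain-variance estimates are
truncated at zero and flagged, keeping \(H^2 \in [0,1]\) as the
variance-explained divisor requires. Parents and RIAILs, when both present,
enter one joint model.

## Problem sizes used by the test suite

The acceptance-level tests run the study-sized configuration: a 357 × 1454
panel; 100 simulation seeds for detection, localization (< 1 Mb median
peak offset) and interval coverage of a 12%-variance QTL at 1000
permutations each; 50 null-panel seeds at 200 permutations for FDR
calibration; 3 seeds at 1000 permutations for the threshold's plausibility
band [2.5, 3.5]; ten seeds per heritability level; and a 300-line,
20-chromosome selfing check. Unit tests use 60–357-line panels on 120–1454
markers. These sizes were chosen so every stochastic check has the
statistical resolution its tolerance implies.

## Known limitations

* The incompatibility model cannot distinguish residual toxin activity from
  linked incompatibility loci — both fold into one penetrance parameter.
* Intensity simulation is one-dimensional; real two-channel array data are
  reduced to a single axis upstream of the caller, and the caller does not
  model heteroscedastic or overlapping clusters beyond what the shared
  variance allows.
* The sparse-map regime makes isolated-call correction genuinely ambiguous;
  the imputer prefers preserving possible recombinants over correcting
  possible errors there.
* The bubble classifier is trained on simulated labels; the printed
  training-accuracy figure of a real instrument's classifier is not
  reproducible without its labelled objects.
* Fecundity counts treat every retained object as one offspring; clumps,
  larvae lost to the hardware minimums, and carcasses are not modelled.
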