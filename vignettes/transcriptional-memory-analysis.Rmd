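---
title: "Models and methods for quantifying transcriptional memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for quantifying transcriptional memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimem)
library(tibble)
```

Epigenetic transcriptional memory primes recently repressed genes (such as
yeast *INO1*) for faster reactivation over several mitotic generations. Its
study rests on a handful of quantitative readouts: pooled-strain competitive
fitness measured from Sanger chromatogram peak ratios, ChIP-qPCR time courses
of the H3K4me2 mark after repression, peripheral-localization counts from
microscopy, and delta-Ct qPCR arithmetic. This vignette describes the models
behind each of the package's components, the tunable parameters, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## Chromatogram allele quantification

Two competing strains are distinguished by a single A/C SNP carried on an
integrated plasmid. Sequencing a mixed population yields a four-channel
chromatogram in which the two allele peaks at the SNP position have heights
(and areas) proportional to the strains' relative abundance.

The quantification pipeline is:

1. **Locate** the SNP basecall by matching the locus flanks against the
   called-base string with the SNP treated as a wildcard
   (`locate_snp_peak()`); zero or multiple matches are errors, never guesses.
2. **Integrate** each allele channel over the window reaching from the
   midpoint to the previous peak up to the midpoint to the next peak
   (clamped at the trace ends), after subtracting the channel's
   within-window minimum (`quantify_allele_fraction()`). The fraction of
   strain A is the primary-channel share of the summed baseline-corrected
   areas.
3. **Calibrate** against a mixing series of known proportions
   (`fit_standard_curve()`, `calibrate_fraction()`). The calibration is a
   straight line of measured on true fraction, inverted and clamped to
   [0, 1].

Two of these choices are genuinely open and are this package's own:
the *inter-peak-midpoint window* (deterministic and parameter-free, robust
to modest peak-width variation) and the *within-window minimum baseline*
(prevents a cross-channel fluorescence floor from inflating the minor
allele's area). Both are stated here because chromatogram software differs
on exactly these points. The calibration is linear only; the standard curve
for this assay is empirically straight across 0–100%.

A practical consequence of the window definition: bases immediately
adjacent to the SNP should not be A or C (the allele channels), or their
Gaussian tails leak into the window and compress the measured fraction
toward 0.5. The bundled fixtures therefore place G/T bases on both sides of
the SNP. With real primers this is a design constraint worth checking.

Fractions are reported on [0, 1] throughout; percentages appear only in
reporting layers.

```{r}
design <- c(0, .05, .25, .40, .50, .60, .75, .90, 1)
measured <- vapply(design, function(f) {
  tr <- simulate_trace("GTCATTGGTAGTCTTACGT", 9, f,
    noise_sd = 0.05, seed = 1 + round(100 * f)
  )
  quantify_allele_fraction(
    tr, snp_locus("A", "C", "TTGGT", "GTCTT")
  )$fraction_primary
}, 0)
glance(fit_standard_curve(
  tibble(true_fraction = design, measured_fraction = measured)
))
```

## Competitive fitness as a log2 odds ratio

Two strains mixed ~1:1 are grown competitively; samples at 0 and 3 hr are
quantified as above. The abundance ratio of strain A to B in a sample with
A-fraction $f$ is the odds $f/(1-f)$, and the fitness readout per replicate
is

$$\log_2\frac{f_t/(1-f_t)}{f_0/(1-f_0)},$$

the change in log2 odds normalized to the starting mix
(`log2_abundance_ratio()`). Odds — not raw fractions — make the readout
exactly antisymmetric under swapping strain labels and independent of a
slightly unequal start. Replicates are summarized as mean ± SEM
(`estimate_fitness()`); with the culture doubling time supplied, the mean is
also expressed per generation. Fractions of exactly 0 or 1 are errors: at
measurement resolution one strain is extinct or fixed and the odds ratio is
unbounded; this regime is far from the assay's intended range and
pseudo-counting would silently bias it.

## Persistence of a chromatin mark after deposition stops

Each S phase distributes pre-existing nucleosomes randomly between the two
daughter duplexes, so a mark that is neither re-deposited nor actively
removed loses half its ChIP signal per doubling time $T_d$: the dashed
"perfect retention, diluted by replication" expectation with half-life equal
to $T_d$. A reader–writer loop (SET3C recognizing H3K4me2 and recruiting the
Spp1-less COMPASS that re-dimethylates neighbouring nucleosomes) can restore
diluted marks; a demethylase can strip them faster than dilution.

The package formalizes this verbally stated model as

$$f(t) = \left(\frac{1+m}{2}\right)^{t/T_d} e^{-kt},$$

where $m \in [0,1]$ is the per-division probability that a position which
lost its mark at replication is re-marked, and $k \ge 0$ is an active
removal rate per minute. The parametrization nests the two printed limiting
cases: $m=0,k=0$ is pure dilution (half-life $= T_d$) and $m=1,k=0$ is
perfect inheritance. Replication is treated as a continuous rate (exponent
$t/T_d$) to match the smooth expectation curve drawn through asynchronous
culture data; the matching discrete per-division simulator
(`simulate_locus_divisions()`) exists as an independent oracle, and its mean
trajectory equals $((1+m)/2)^g$ because re-marking applies to positions
that lost their mark at that division (templated by the retained sister
copies), not to positions that were never marked. The expected ChIP signal
is `background + s0 * f(t)`, which assumes recovery is linear in the
marked-nucleosome fraction — an assumption of the assay, not a measured
fact.

### Fitting and identifiability

`fit_decay()` fits three nested models by least squares: `dilution_only`
($m=k=0$), `maintenance` ($m$ free) and `maintenance_plus_removal` ($m$ and
$k$ free). $T_d$ is always supplied from culture data, never fitted. A
structural fact drives the implementation: $m$ and $k$ enter the model only
through the net decay rate

$$\lambda = \frac{\ln(2/(1+m))}{T_d} + k,$$

so they are not jointly identifiable from a single time course. The fit
therefore profiles the linear parameters ($s_0$, background) in closed form,
optimizes $\lambda$ over a deterministic grid (the images of
$m = 0, 0.1, \ldots, 1$ and of a removal-rate grid up to 0.1/min) with local
refinement, and reports the parsimonious point on the $m$–$k$ ridge: decay
at or below the dilution rate is attributed to (possibly maintained)
dilution with $k = 0$; only the excess over the dilution rate is called
active removal, with $m = 0$. Equivalently, ties in fit quality resolve to
the smallest $m$, then the smallest $k$. Users should read the fitted $m$
and $k$ with this convention in mind.

### Classification

`classify_heritability()` fits all three models, selects by small-sample
corrected AIC, and calls the regime `heritable` when the selected $m \ge
0.5$ (at least half of diluted marks restored per division), otherwise
`active_removal` when the selected $k > 0$ with half-life below $T_d$,
otherwise `passive_dilution`.

Two defaults differ from a bare `fit_decay()` call, for reasons that
simulation made unambiguous:

* **The background is anchored at the negative-control locus** (the mean of
  the `control` column, e.g. repressed *PRM1* recovery) when one is present.
  With ~6 timepoints and a *free* background, a pure-dilution curve that
  decays onto a high plateau is nearly indistinguishable from a slowly
  decaying maintained mark: the whole-curve difference is a fraction of the
  assay noise, and no information criterion can recover what the data do not
  contain. Anchoring the background — which every ChIP-qPCR experiment
  measures anyway — removes the degeneracy.
* **Model selection fits unweighted.** Per-timepoint SEMs estimated from
  ~3 replicates carry about two degrees of freedom each; occasional
  near-zero SEMs produce enormous weights that dominate the residual sum of
  squares and make selection erratic. `fit_decay()` itself defaults to
  1/SEM² weights (appropriate for parameter estimation); classification
  overrides this for robustness.

AICc uses the number of free mean parameters per model, the known-variance
form ($\chi^2 + 2k$ + correction) for weighted fits and the
estimated-variance form ($n\log(\mathrm{RSS}/n) + 2k$ + correction)
otherwise. With these defaults, classification accuracy on simulated time
courses (6 timepoints over 4 doubling times, 5% multiplicative noise, 3
replicates, $s_0{:}\mathrm{background} = 10{:}1$) is at least 95% for all
three regimes — the acceptance suite re-measures this on every run.

```{r}
truth <- mark_decay_params(
  s0 = 10, background = 1, doubling_time = 120, maintenance_prob = 0.9
)
tc <- simulate_chip_timecourse(truth, seq(0, 480, 96), noise_sd = 0.05, seed = 7)
glance(classify_heritability(tc, doubling_time = 120))
```

### Persistence in generations

`persistence_generations()` reports the last timepoint at which
`signal - SEM` is at or above `background + threshold`, divided by $T_d$.
The "mean minus one SEM above the control level" rule is a documented
default, not a community standard: published persistence statements ("~4
generations") rarely state their detection rule, so this one is explicit
and overridable (`threshold`, `sem_multiplier`). The comparison is
non-strict (≥), so a signal sitting exactly at the detection limit still
counts as detected.

## Peripheral localization baseline

A gene with no targeting signal still colocalizes with the nuclear envelope
in a substantial minority of cells simply because the nuclear volume near
the envelope is large. Modeling the nucleus as a sphere and scoring a locus
as peripheral when it lies within a shell of thickness $f \cdot R$:

$$P(\text{peripheral}) = 1 - (1 - f)^3,$$

which is 0.271 at the default $f = 0.1$ — the familiar ~27% dashed line.
The shell fraction is an explicit parameter because the prior literature it
comes from does not print one; 0.1 reproduces the quoted baseline. Whether
the published baseline derives from a 3D-volume or a 2D-optical-section
argument is not stated in the sources this package follows; the 3D shell
model is used here and labeled as such. A Monte-Carlo estimator
(`peripheral_baseline_mc()`) cross-checks the closed form and is tested to
agree within three binomial standard errors.

Enrichment tests (`enrichment_test()`) operate on *replicate-level
percentages* — never on pooled cells — matching how such data are reported
(average of ≥3 biological replicates ± SEM, each replicate ≥30 cells), with
one-tailed one-sample (vs the baseline) or Welch two-sample forms. Constant
replicate values at the null are a legal boundary case and return t = 0,
p = 0.5.

## qPCR arithmetic

`relative_expression()` implements the delta-Ct ratio
$E^{(Ct_\mathrm{ref} - Ct_\mathrm{target})}$ with amplification efficiency
$E$ defaulting to 2 (perfect doubling; efficiencies are rarely reported
with published Ct values). `chip_recovery()` scales the IP/input delta-Ct
ratio by the saved input fraction. `one_tailed_t()` wraps Welch's t-test
with the degenerate constant-data boundary handled explicitly.

## Synthetic data: what it emulates, and what it does not

Every generator is deterministic under a seed and attaches its ground truth
as an attribute (or a sidecar manifest for `make_fixture_suite()`), so
downstream estimates can be scored without the data files leaking the
answer.

* `simulate_trace()` — Gaussian peaks (spacing 10 scans, sd 2, amplitude
  100 by default) with multiplicative peak-height noise (default 5%) and an
  optional constant baseline. At the SNP the allele channels split the
  amplitude by the true fraction. Not emulated: dye blobs, mobility shifts,
  basecall errors, quality scores — real trace pathology that would sit in
  front of this package's scope.
* `simulate_competition()` — deterministic exponential growth of both
  strains with additive Gaussian assay noise (default sd 0.02) on measured
  fractions, clamped inside (0, 1). Selection enters as extra log2 odds per
  generation. Not emulated: lag phases, density dependence, PCR bias.
* `simulate_chip_timecourse()` — multiplicative noise (default 5%) around
  the model curve, 3 replicates per point summarized as mean ± SEM, and a
  negative-control locus column drawn at the background level. Noise that
  is correlated across timepoints (culture batch effects) is not emulated.
* `simulate_localization_counts()` — binomial counts per replicate
  (default 30 cells, the scoring convention's minimum).

Because the generators draw from the same model families the estimators
assume, passing tests demonstrate *self-consistency and correct
implementation*, not robustness to the mis-specification real data carry.
The noise defaults (5% multiplicative; 0.02 on fractions) were chosen once
as realistic for well-run assays of these kinds and are exposed as
arguments rather than constants.

## Numerical choices and degenerate inputs, in one place

* All coordinates are 0-based (scan positions, basecall indices), matching
  the on-disk TSV dialect.
* Negative intensities are a read-time *error*, never silently clamped.
* Both allele areas zero → degenerate-signal error; fraction 0/1 in a
  competition → unbounded-ratio error; fewer timepoints than free
  parameters → identifiability error; < 2 replicates in a t-test →
  insufficient-replication error.
* Curve inversion clamps to [0, 1] and flags the clamp.
* Decay fits are deterministic: fixed grids, golden-section refinement,
  ties to the simpler model / smaller $m$ / smaller $k$.
* Monte-Carlo and simulation scales in the test suite (e.g. 10⁶ points for
  the shell baseline, 100 time courses per regime, 200 pipeline
  competitions, 300 × 200-nucleosome division runs) were sized so that
  three-sigma Monte-Carlo bands are decisive for the quantities under test.

## Known limitations

* Two-allele loci only; no indel or multi-allele support.
* $m$ and $k$ are reported under a parsimony convention, not jointly
  estimated — distinguishing a maintained-but-removed mark from a plain
  diluted one requires perturbation data, not curve shape.
* The spherical-shell baseline ignores optical sectioning and nuclear
  envelope irregularity.
* ChIP linearity in marked-nucleosome fraction is assumed.
* No multiple-testing correction: the replicate t-tests mirror per-comparison
  reporting conventions.
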