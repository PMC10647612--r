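---
title: "Validation statistics for targeted steviol-glycoside quantitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validation statistics for targeted steviol-glycoside quantitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweetval)
library(dplyr)
```

## The problem

Steviol glycosides — stevioside, the rebaudiosides A–F, rubusoside,
dulcoside A and steviolbioside — are the diterpene glycoside sweeteners of
*Stevia rebaudiana*. They are quantified in foods and beverages by targeted
LC-MS/MS: each compound is monitored as a selected-reaction-monitoring (SRM)
transition set (a deprotonated precursor ion, one quantifier product ion, and
qualifier product ions that confirm identity), and concentrations are read off
a linear calibration of peak area against concentration. Before such a method
is used on real samples, a single-laboratory validation establishes that it is
specific, linear, precise, accurate and sensitive enough for its intended
range — here 0.2–1.0 mg L⁻¹ spiked into three representative food matrices
(a non-alcoholic beverage, yogurt and a snack).

`sweetval` implements the statistics of that validation as composable,
data-frame-first functions, together with a seeded generator of
instrument-like data so every stage can be exercised and tested without
access to an instrument.

## The statistics

All functions operate on the long observation table (one row per replicate
measurement, with `analyte`, `matrix`, `role`, `level_mg_per_L`, `replicate`,
`value`, `value_unit`) and return tibbles.

**Specificity.** Retention-time agreement between an observed peak and the
standard is scored as the relative percent difference
$\%RPD = 100\,|RT_1 - RT_2|\,/\,\tfrac{1}{2}(RT_1+RT_2)$, accepted below 5%
(the usual identification-window criterion). The same quantity drives the RT
gate in peak assignment, which makes the two stages consistent by
construction.

**Linearity.** Ordinary least squares of area on concentration over all
replicate points, intercept always included. Replicates enter as individual
points rather than level means so the per-level %RSD of responses (accepted
below 15%) is preserved alongside the fit. A series is linear when
$R^2 > 0.99$ and every level's %RSD is in band. $R^2$ is computed as
$1-\mathrm{SSE}/\mathrm{SST}$; a flat series (SST $=0$) is defined to have
$R^2 = 0$, since it carries no concentration information.

**Matrix effect.** Ionization suppression or enhancement is the absolute
matrix effect $\%ME_A = 100\,A_{matrix}/A_{solvent}$, the signal of a
post-extraction spike relative to the same amount in solvent; 80–120% is
accepted. Per level, the reported mean is the ratio of mean signals
$100\,\overline{A}_{matrix}/\overline{A}_{solvent}$ — the level's "signal
response" is its mean response, and a ratio of means avoids the small upward
bias ($\approx CV^2$) a mean of per-replicate ratios carries — while the
reported SD is that of the per-replicate ratios, describing replicate
scatter the conventional mean ± SD table shows.

**Precision.** Repeatability is $\%RSD = 100\,SD/\bar{x}$ with the sample SD
($n-1$), accepted below 20%. Reproducibility is summarised by the Horwitz
ratio $HorRat = RSD/PRSD$ with $PRSD = 2^{(1-0.5\log_{10} C)}$ and $C$ the
concentration as a mass fraction; values below 2 are accepted. Two choices
are worth stating. First, the logarithm is base 10, the standard form of the
Horwitz function. Second, $C$ defaults to the *found* mean concentration
(configurable to the added level); at these trace levels the difference is
negligible against the acceptance band. Concentrations in mg L⁻¹ convert to
mass fractions as $c \times 10^{-6}$, taking aqueous extracts at unit
density; the density is an argument for other solvents.

**Accuracy.** Spike recovery
$100\,(\bar{x}' - \bar{x})/x_{spike}$, blank-corrected, accepted within
70–120%. The blank mean defaults to 0 because validation blanks are
sweetener-free; when blank rows are present their back-calculated mean is
used.

**Detection capability.** The replicate-SD method: with $S_0$ the sample SD
of the lowest-level spike replicates and $S_0' = S_0/\sqrt{n}$ (where $n$ is
the number of replicates averaged when a result is reported, default 1),
$LOD = 3S_0'$ and $LOQ = 10S_0'$. The $\sqrt{n}$ divisor is the standard
error of a reported mean, which is what the limits should scale with; a
plain-$n$ divisor is available as `divisor = "n"` for compatibility with
texts that print it that way. The identity $LOQ = \tfrac{10}{3}LOD$ holds
exactly before rounding and is used as an internal-consistency check on
reported limit tables (`check_limit_ratio()`): a pair rounded to 3 decimals
must agree with the ratio within its rounding radius.

**Left-censored results.** Results below LOD/LOQ are substituted under three
exposure-assessment scenarios: lower bound (0), middle bound (half the
limit), upper bound (the limit). The three totals are ordered
lower ≤ middle ≤ upper for any limits, a property the tests enforce.

**Steviol equivalents.** Regulatory comparisons are made on the common
steviol backbone: $[SE] = CF \times [SG]$. The package's default conversion
factors are molecular-weight ratios steviol/glycoside computed from each
analyte's formula (0.40 for stevioside, 0.33 for rebaudioside A, …). They
are defaults, not authoritative values; a laboratory's own CF table can be
supplied as a CSV. One formula in the shipped transition table deserves a
note: steviolbioside is carried as C32H50O13 (MW 642.7, consistent with its
precursor m/z of 641.4), the compound's accepted formula.

## Peak assignment

`match_peaks()` assigns raw SRM observations to analytes when precursor and
product m/z both fall within `mz_tol` (default 0.5, unit resolution on a
triple quadrupole) and the RT %RPD against the reference is at most
`rt_tol_percent` (default 5). Ties are broken by smallest RT difference,
then smallest precursor difference, then analyte name — a total order, so
assignment is deterministic and independent of input order, and shrinking
either tolerance can only remove assignments. The panel contains a genuine
isobaric pair (stevioside and rebaudioside B, both precursor 803.458 with
product ions 0.1 m/z apart) that only the RT gate separates; a dedicated
test keeps that separation honest. Identity is confirmed by the *presence*
of at least one qualifier transition; quantifier-only hits remain
quantifiable with a flag. Qualifier ion-ratio banding is deliberately not
the default, since presence-only confirmation is what the acceptance
criteria encode.

## What the generator emulates

`sim_config()` fixes the study design: nine analytes × three matrices,
calibration at 0.2/0.3/0.4/0.5/0.8/1.0 mg L⁻¹ in triplicate, spikes at
0.2/0.5/1.0 mg L⁻¹ in seven replicates, matrix-effect pairs in seven
replicates (the replicate counts the validation design prescribes). The
detector model is

$$A = f_{ME}\,(a\,c\,f_{rec} + b)(1+\varepsilon),\qquad
  \varepsilon \sim N(0, CV),$$

with per-analyte true slopes $a$ and intercepts $b$ of realistic
triple-quadrupole magnitude (slopes ~2×10⁴–8×10⁴ area units per mg L⁻¹).
Two structural choices matter and were made deliberately:

* the matrix-effect factor $f_{ME}$ multiplies the *whole* signal, because
  ionization suppression acts on the detector response — this makes the
  $\%ME_A$ estimator exactly unbiased for $f_{ME}$;
* the recovery factor $f_{rec}$ scales the *analyte amount*, because
  extraction loss happens before detection — with matrix-matched
  quantitation the back-calculation then returns $c \cdot f_{rec}$ exactly
  in the noiseless limit, so recovery estimates target $f_{rec}$ alone.

Matrix-effect rows are post-extraction additions (no recovery loss), the
standard design for isolating pure ionization effects; spike rows pass
through recovery loss. Blanks are the same model at $c=0$, i.e. background
signal with proportional noise, so their back-calculated concentrations are
centred on zero. Noise is multiplicative (constant CV, default 0.03 —
mid-range of the 1–9% repeatability a validated method of this kind shows)
because the acceptance criteria are all relative; an additive noise floor
(`noise_floor_sd`) is available for low-signal realism. Retention times
jitter around the reference by `rt_jitter_sd` (default 0.01 min, well below
the 5% window). Default matrix factors (mild enhancement in the beverage,
~12% suppression and ~13% recovery loss in yogurt, near-neutral snack)
reflect the qualitative pattern such matrices show.

What the generator does **not** emulate: chromatographic peak shapes and
integration, retention drift and carryover, heteroscedasticity beyond the
constant-CV/additive-floor model, between-day effects, interferences that
produce false SRM peaks (decoys are available but are placed at unmatched
m/z), and real matrix chemistry. Passing tests on synthetic data therefore
demonstrate the *statistics and plumbing* are right, not that any particular
instrument will meet the bands.

## Quantitation-path choices

Spike and sample areas can be quantified against the matrix-matched curve
(`calibration = "matrix"`, the default for validation statistics — matrix
effects cancel, so recovery isolates extraction loss) or against the solvent
curve (`calibration = "solvent"`, the default in `run_survey()`, matching
the common practice of external calibration for survey work once the matrix
effect has been shown to be in band). Negative back-calculated
concentrations are passed through rather than clipped: they are censoring
candidates, and clipping them would bias blank means upward.

## Numerical conventions

* Reported values round *half away from zero* (2.075 → 2.08), the
  convention of analytical tables — base R's banker's rounding would turn
  boundary cells the other way; 2 decimals for concentrations and
  percentages, 3 for detection limits.
* Occurrence summaries (`summarize_found()`, `run_survey()`) use detected
  samples only, with SD reported only for $n \ge 2$ and "ND" when nothing
  was detected.
* Degenerate inputs return defined values where the mathematics permits
  (constant replicates give LOD 0; a single replicate gives a mean with SD
  absent) and classed errors (`sweetval_invalid_input`,
  `sweetval_config_error`) otherwise.
* Verdicts for multi-level criteria are decided by the worst value, which is
  also the value the report carries, so a failing row always shows the
  offending number.

## Test design and problem sizes

The oracle tests recompute every statistic from explicit sums on fixtures of
at most five replicates and require agreement to 1e-12 relative; OLS is
checked against the closed-form normal equations. Monte Carlo parameter
recovery runs a reduced one-analyte design over a 3×3 grid of
(matrix-effect, recovery) factors with 100 seeds per cell, asserting the
grid means hit the true factors within ±2 and ±3 percentage points
respectively and that the aggregate Monte Carlo z-scores stay within 2× the
Monte Carlo standard error; the reduced panel keeps the whole grid around a
minute while leaving Monte Carlo error the dominant term. The LOD-scaling
property (doubling the noise CV doubles the limit) uses paired seeds, which
makes the ratio nearly deterministic. Noiseless-limit identities
($R^2 = 1$, recovery and matrix effect exactly 100%, full identification
recall) are exact and tested as such.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
data <- simulate_validation_data(cfg)
peaks <- simulate_peak_list(cfg)

report <- run_validation(data, peaks = peaks, seed = 1)
report
glance(report)

# occurrence-style survey with censoring
cfg_s <- sim_config(seed = 1, n_samples = 10)
data_s <- simulate_validation_data(cfg_s)
fits <- fit_calibrations(data_s)
limits <- assess_detection_limits(data_s, fits)
survey <- run_survey(data_s, fits, limits, scenario = "lower")
survey$summary
```

## Known limitations

* Only simple linear (optionally 1/x-weighted) calibration; no segmented or
  quadratic fits, and no calibration-curve-residual detection limits — the
  replicate-SD method is the one implemented.
* HorRat is the only reproducibility statistic; no inter-laboratory designs
  and no low-concentration modification of the Horwitz function.
* No uncertainty budgets; $R^2$ and level RSDs are the only calibration
  diagnostics.
* The peak list is the entry point: no raw chromatogram processing, peak
  picking or vendor/mzML readers.
* Regulatory maxima are report annotations for the user; there is no rule
  engine comparing results against jurisdictional limits.
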