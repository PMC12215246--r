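---
title: "Diurnal rhythms in DNA methylation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diurnal rhythms in DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methRhythm)
```

# The experiment this package models

Fifteen subjects spend consecutive days in a sleep laboratory; blood is
drawn every 3 hours for 45 hours starting at 15:00, spanning a normal
sleep/wake day (lights out 23:00–07:00) and a night of total sleep
deprivation. Each subject contributes 16 samples. Methylation is measured
on an array and summarized as beta values (proportion methylated, in
[0,1]). Two questions drive the analysis: which CpG sites oscillate with
the 24-hour day, and what one night of continual wakefulness does to those
oscillations and to methylation levels per se.

The 45-hour axis is split into two *overlapping* 24-hour windows — the
first nine samples (baseline) and the last nine (sleep deprivation), which
share sampling indices 8 and 9. The overlap is the price of having two
complete day cycles with equal sample counts. `splitConditions()`
implements this; the sample sheet's `condition` column, by contrast,
records each sample's physical period (indices 1–8 baseline, 9–16
deprivation), which is what the paired differential-methylation contrast
uses.

# Cosinor model

For one probe, observations $y_i$ at clock times $t_i$ (subjects pooled as
replicates at each timepoint):

$$y_i = M + \beta_c \cos(\omega t_i) + \beta_s \sin(\omega t_i) +
\varepsilon_i,\quad \omega = 2\pi/\text{period}.$$

The fit is closed-form least squares. Amplitude is
$A=\sqrt{\beta_c^2+\beta_s^2}$ and the acrophase,
$\varphi = (\text{period}/2\pi)\,\mathrm{atan2}(\beta_s,\beta_c) \bmod
\text{period}$, is the clock time at which the fitted curve peaks — so a
statement like "this site peaks at 21:00" is directly readable from
$\varphi$. When $A$ is numerically zero the acrophase is undefined and
flagged rather than reported. Rhythm significance uses the zero-amplitude
F test, $F=((RSS_0-RSS)/2)/(RSS/(n-3))$ on $(2, n-3)$ degrees of freedom;
an exact fit ($RSS=0$) is flagged and assigned $p=0$.

Two properties worth knowing: shifting all clock times by $\Delta$ shifts
$\varphi$ by $\Delta$ (mod 24) and changes nothing else; negating the data
moves $\varphi$ by 12 h. The default period is 24 h and the package
deliberately fits a single harmonic — no period scanning, no higher
harmonics.

Following the source pipeline's convention, acrophases are taken from the
z-scored matrix and amplitudes from the unscaled one (`runPipeline()` does
both; z-scoring leaves $\varphi$ untouched anyway for any probe with
nonzero variance).

# Five-model rhythm classification

Per probe, five nested least-squares models are fitted to the pooled
two-window data (condition-specific intercepts throughout): `arrhy` (means
only), `same` (one shared harmonic), `loss` (harmonic in baseline only),
`gain` (harmonic in deprivation only), `change` (condition-specific
harmonics). Mean-parameter counts are 2/4/4/4/6; the information criterion
charges one more for the residual variance:

$$\mathrm{AIC}_m = n\ln(RSS_m/n) + 2(k_m+1).$$

Scores become Akaike weights $w_m \propto e^{-\Delta_m/2}$. The best model
is accepted only if $\max_m w_m \ge 0.6$ (the `weight_cutoff`), otherwise
the probe is `unclassified`. An eligibility pre-filter (on by default)
additionally requires the cosinor F test, BH-adjusted across probes at
`fdr_alpha = 0.05`, to pass in at least one window; ineligible probes are
assigned `arrhy`. Exact fits (RSS = 0) take all the weight, ties among
exact fits going to the most parsimonious model. Zero-variance probes are
flagged and assigned `arrhy`.

Tunables (`classifierConfig()`): `period` (24 h), `criterion`
(`aic` default; `aicc`, `bic` available), `weight_cutoff` (0.6),
`fdr_alpha` (0.05), `prefilter` (TRUE). No minimum-amplitude filter is
applied: the windows are z-scored, which makes absolute amplitude
thresholds arbitrary.

## The loss/gain recall ceiling under AIC

A point that matters when interpreting classification output: for a probe
whose truth is the *smaller* model of a nested pair (e.g. truth `loss`
inside `change`), the larger model always captures some noise —
asymptotically a $\chi^2_2$ worth of residual reduction against a fixed
AIC penalty of 4. This gives AIC selection a signal-strength-independent
error floor: simulation at the study geometry (270 observations) puts
best-model accuracy for `loss`/`gain` near 0.86 in the idealized i.i.d.
case, and the 0.6 weight cutoff lowers accepted-call recall to roughly
0.80; under the full pipeline (subject heterogeneity inflates RSS and
dilutes the spurious capture) recall lands around 0.85–0.95 depending on
the realized subject spread. Raising the signal-to-noise ratio does **not**
help — it mildly hurts, because z-scoring shrinks the rhythmic window's
residuals and makes the two free parameters of `change` relatively
cheaper. With `criterion = "bic"` (penalty $\ln n$ per parameter) selection
is consistent and recall reaches ~1.0 at strong signal; `aic` remains the
default because that is the method this pipeline mirrors. A related effect
touches `same`: per-window z-scoring rescales the two windows by slightly
different factors, so at very high signal-to-noise the forced-equal
amplitude of `same` misfits in proportion to $A/\sigma$ and `change` starts
to win legitimately. Large unclassified fractions are therefore expected
behaviour of this method, not a defect of an individual run.

# Cell composition

Counts for 13 non-exclusive white-blood-cell classes (totals are sums of
their subsets; see `wbcClasses()`) are imputed at missing timepoints by
averaging the two adjacent timepoints of the same subject and class — a
rule that is undefined at a series' first/last timepoint or for two
consecutive gaps, which are rejected rather than guessed. Normalization
divides each methylation value by the subject's same-timepoint count of
one class, yielding 13 normalized matrices that can be re-classified to
gauge how much apparent rhythmicity rides on cell-count rhythms.

The composition-correlation screen takes the final timepoint (maximum
sampling index), forms relative proportions (class count / total WBC
count), and correlates each probe's methylation with each class's
proportion across subjects (Pearson by default, Spearman via config). With
$\alpha = 0.05$, 1000 probes and 13 classes, chance alone predicts
$0.05 \times 1000 \times 13 = 650$ significant correlations; the report
shows observed versus expected and the BH-surviving count. The total-WBC
"proportion" is identically 1 and is skipped with a flag (so 12 classes are
actually tested); the expected-count arithmetic intentionally keeps the
13-class bookkeeping of the design it mirrors. Dependence among the
non-exclusive classes — and subject-level intercepts shared across probes —
inflate the *variance* of the observed count, not its mean, so only means
are compared in tests.

# Paired differential methylation

Each deprivation sample is paired with the baseline sample at the same
clock time 24 h earlier within subject, giving eight pair contrasts with
cumulative time awake 8, 11, …, 29 h. Differences are computed on the
*unstandardized* matrix: the contrast should measure methylation change,
not within-window standardization. Per pair, probe-level variances of the
paired differences are shrunk toward a scaled-F prior,

$$\tilde s^2 = \frac{d_0 s_0^2 + d s^2}{d_0 + d},\qquad
\tilde t = \frac{\bar\Delta}{\tilde s/\sqrt n}\ \text{on } d_0+d\ \text{df},$$

with $(d_0, s_0^2)$ from closed-form moments of the log sample variances
(trigamma inversion by Newton's method). If the log-variances are no more
dispersed than chi-square sampling noise, $d_0=\infty$ (complete pooling)
with a warning. A joint moderated F over the eight pairs uses the pooled
per-probe variance; with a single pair it reduces to $\tilde t^2$.

Direction is `hypo` iff the mean paired difference is negative. DMP counts
accumulate over the grid $5\times10^{-8} \dots 5\times10^{-2}$ (they are
monotone by construction), with the hypo/hyper split reported at the
headline threshold $5\times10^{-4}$. Top-N selection orders by ascending
p, then larger $|\bar\Delta|$, then probe ID — a deterministic rule chosen
because none is inherited. Over-representation of the mapped genes uses
the one-sided hypergeometric tail per gene set against a universe
defaulting to all manifest genes covering analysed probes; hypergeometric
p-values are discrete and therefore conservative.

# The synthetic-data generator

Signal is built on the M-value (logit-beta) scale — additive Gaussian
structure on (0,1) would violate the range — and mapped through the
logistic, which is monotone, so planted orderings survive the transform:

$$m_{ijs} = \mu_i + b_j + A_i\cos\!\big(\tfrac{2\pi}{24}(t_s-\varphi_i)\big)
\cdot \mathrm{mask}_{is} + \delta_i r_s + \varepsilon_{ijs}.$$

Defaults (all overridable in `planTruth()`): class proportions follow the
classifiable-site mix the package mirrors (48.1% arrhy / 35.4% same /
7.2% loss / 7.0% gain / 2.3% change); mesor $\mu_i \sim N(0, 1.5^2)$;
amplitude 1 (M units); subject intercepts $b_j \sim N(0, 0.25^2)$; noise
$\sigma = 0.25$ (scalar or per-probe); `change` probes shift acrophase by
6 h with random sign; a fraction `dmp_fraction = 0.05` of probes receives
a drift $\delta_i$ of magnitude 0.5, negative with probability
`hypo_fraction = 0.70`, ramping linearly over samples with ≥ 23 h of
continual wakefulness (the late-wakefulness acceleration). Amplitude and
noise are on the same scale, so their ratio is the per-observation
signal-to-noise used throughout the tests (A/σ = 5 being the standard
strong-signal condition, chosen with σ and the subject SD fixed before any
classifier measurements and not revisited).

Because the two analysis windows share samples 8 and 9, planted classes
are defined *at the window level*: `loss` probes oscillate only in samples
exclusive to the baseline window (indices 1–7), `gain` only in indices
10–16, and `change` switches phase at the physical condition boundary.
Any other convention makes "no rhythm in one window" unsatisfiable.

Cell counts are generated for 8 leaf populations as lognormal diurnal
rhythms (granulocytes peaking in the evening, lymphocyte subsets at
night — the canonical human pattern) and summed into the 5 aggregates, so
the non-exclusive structure holds exactly. Missing timepoints (whole rows)
are planted only at interior, non-adjacent indices because the
neighbor-mean imputation rule is undefined elsewhere.

What the simulator does **not** emulate: array chemistry and probe-level
artefacts (detection failures, cross-reactivity), genomic autocorrelation
between neighbouring CpGs, realistic bimodal mesor distributions,
amplitude heterogeneity across probes, gradual (rather than masked)
rhythm loss, or correlated methylation/cell-count structure. Passing tests
therefore certify the *statistical machinery* — estimation, selection,
calibration, bookkeeping — not biological fidelity of any particular real
dataset.

# Numerical conventions and degenerate inputs

* All phase arithmetic is modulo 24; circular differences are folded into
  (−12, 12].
* Z-scoring is per probe across all subject × timepoint entries of one
  window (subjects pooled, preserving between-subject phase agreement);
  zero-variance rows become zeros with a flag. Z-scoring per window was
  applied before batch options, and both orders are reachable through the
  function-level API.
* Covariate residualization (off by default) is per-probe fixed-effects
  least squares on batch, batch position and age, returning residuals plus
  the grand mean; a mixed model with probe-level random effects across
  hundreds of thousands of probes is not reproducible machinery, and a
  randomized plate layout makes the fixed-effects adjustment the
  transparent counterpart.
* The moment estimate $d_0 \le 0$ falls back to complete pooling with a
  warning; all-zero variances are an error.
* Exact-fit ties in model selection resolve to the fewest parameters;
  top-DMP ties resolve by $|\bar\Delta|$ then probe ID; acrophase-ordered
  heatmaps break ties by probe ID.
* Sizes used by the test-suite simulations (500–5000 probes, 15 subjects)
  were chosen so each property is measured with usefully small binomial
  error while the whole suite stays quick to run.

# Known limitations

* The loss/gain recall ceiling under AIC weights described above.
* The pre-filter ties classification eligibility to the pooled-replicate
  cosinor F test, which ignores within-subject correlation; its p-values
  are calibrated under the generator's exchangeable noise but would be
  optimistic for strongly autocorrelated residuals.
* The moderated F pools variance across pairs and assumes a common prior;
  heteroscedasticity across time-awake levels is not modelled.
* Enrichment replicates no external service's background conventions; the
  universe is the manifest restricted to analysed probes.
* No reference-based cell deconvolution from methylation itself; counts
  must be measured.
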