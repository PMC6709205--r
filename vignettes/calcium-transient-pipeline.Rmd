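---
title: "Quantifying GCaMP6s line-scan calcium transients: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying GCaMP6s line-scan calcium transients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catrace)
```

## The measurement problem

Dorsal root ganglion (DRG) proprioceptors expressing the genetically
encoded calcium indicator GCaMP6s report electrical activity as slow
fluorescence transients. A line scan across the cytosol, acquired 20,000
times over 28.16 s (sampling above 700 Hz), trades spatial coverage for
the temporal resolution needed to resolve a transient evoked by a brief
nerve stimulus: 5 s of pre-stimulus baseline, then a 0.5-s train of 0.1-ms
pulses at 50 Hz (25 action potentials). Each cell is recorded three times
and the sweeps averaged.

Five quantities summarise each transient:

* **resting fluorescence** — mean raw intensity over the first 100 ms of
  the sweep (detector a.u.);
* **peak amplitude** — maximal percent dF/F after stimulus onset;
* **RT (rise time)** — interval from stimulus onset to the peak;
* **DT1 (decay constant)** — time for the fitted decay to lose
  $1 - e^{-1}$ (~63%) of its peak amplitude;
* **DT2 (residual recovery time)** — additional time after DT1 until 90%
  recovery: $DT2 = T_{90} - DT1$.

The slope of the rising phase (maximum derivative of a polynomial fit) is
carried along as a sixth variable; across populations it is nearly
collinear with peak amplitude.

## Processing chain

`extract_parameters()` applies, in order: spatial average over the line,
average over the three repeats, zero-phase Butterworth low-pass (order 4,
cutoff 10 Hz), iterative moving-average smoothing (15-sample window, ~21 ms,
3 passes, reflected edges), then conversion to percent dF/F against the
mean of the 0.5–4.5 s pre-stimulus window. The order is a design choice —
the sources describing this style of analysis do not fix it — and
denoising once, after averaging, is both cheaper and statistically
efficient. Two distinct baselines are intentional: resting fluorescence
uses only the first 100 ms of the raw trace (a property of the cell),
while the dF/F denominator uses the long pre-stimulus window (a property
of the sweep).

Numerical details worth knowing:

* The Butterworth filter is applied forward and backward (zero phase, so
  peak times do not shift). The trace is extended by odd reflection before
  filtering, and the linear trend between the endpoints bypasses the filter
  entirely, which makes the DC gain exactly one.
* The rising phase is fitted with a degree-3 polynomial (captures the
  sigmoid rise without ringing); the reported slope is the maximum of the
  fitted derivative over the rise window, since no convention fixes where
  on the rise it should be read.
* The decay is fitted with a bounded bi-exponential
  $a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2} + c$ ($a_i \ge 0$,
  $\tau_i \in [0.05, 60]$ s) by Levenberg–Marquardt from five deterministic
  starting points, keeping the best residual. The fit window stops ~25%
  past the point where the trace first falls below 2% of its peak value:
  the recovered baseline carries no shape information and, if included,
  drags both components toward a common intermediate time constant.
  Windows longer than 2,000 samples are decimated evenly.
* DT1 is found by root-finding on the fitted (offset-free) curve at the
  exact $e^{-1}$ level. This reconciles two circulating definitions of a
  "decay constant" — the reciprocal of a fitted rate versus the 63% decay
  time — in a way that is exact for mono-exponentials and well defined for
  bi-exponentials. $T_{90}$ is the 10%-of-peak-amplitude crossing (i.e.
  90% recovery toward the dF/F baseline of zero, not 10% of the raw
  resting intensity, which would not be reachable). Crossings that fall
  beyond the sweep are reported as censored (`NA` with a flag), which is
  why DT2 has a smaller n than the other parameters in real datasets.
* A transient counts as a responder when its peak exceeds 5% dF/F;
  non-responders keep their resting fluorescence and peak but no rise or
  decay parameters. Ties in the peak search (plateau-shaped transients
  after very long trains) resolve to the earliest sample.

## The forward simulator

No recordings are distributed with the kind of study this package serves,
so the generator is a first-class, tested component: it defines the
conditions under which everything else is validated.

A single cytosolic compartment carries free calcium $c$ with two linear
clearance pathways and instantaneous influx per action potential:

$$\frac{dc}{dt} = -k_{\mathrm{SERCA}}\,(c - c_0) - k_{\mathrm{PMCA}}\,c + L,
\qquad c \mathrel{+}= a \cdot \beta \text{ at each pulse,}$$

where $L = k^{\mathrm{nom}}_{\mathrm{PMCA}} c_0$ is a constant inward leak
fixed when the cell is created and $\beta$ is the bath-calcium factor. At
nominal rates this is exactly first-order relaxation to $c_0$ with rate
$k_{\mathrm{SERCA}} + k_{\mathrm{PMCA}}$. The two pathways are written
asymmetrically on purpose: SERCA exchange is referenced to the resting
level, so blocking it (thapsigargin reduces $k_{\mathrm{SERCA}}$ to 10% of
nominal) slows clearance without moving the resting point, whereas PMCA
extrusion works against the fixed leak, so blocking it (pH 8.8 reduces
$k_{\mathrm{PMCA}}$ to 20%) raises resting calcium — and with it resting
fluorescence — reversibly. This is the simplest single-compartment
structure that reproduces the directional pharmacology: TG lengthens RT
and DT1 with unchanged resting fluorescence; pH 8.8 raises all five
parameters and recovers on return to pH 7.3.

The indicator binds cooperatively and first-order:

$$\frac{db}{dt} = k_{on}\, c^{n}\,(B_{tot} - b) - k_{off}\, b,
\qquad F(t) = F_{rest} + g\, b(t).$$

Each pixel row of the synthetic line scan is $F(t)$ plus i.i.d. Gaussian
noise (PMT read noise dominates at these intensities; a Poisson mode is
not provided), clipped to the 12-bit range and quantised to integer
counts.

Integration is classical RK4 at the recording sampling interval
(~1.41 ms); the dynamics live on time scales of hundreds of milliseconds
and slower, so this step is conservative (the test suite holds the
integrator to 0.5% sup-norm agreement with a 100x-finer explicit-Euler
oracle). Pulses land on the nearest sample.

### Default parameters

Defaults live in `inst/extdata/default_config.yaml`, not in code. The
kinetic constants are tuned targets, not measurements — the studies this
pipeline serves do not report pump rates or indicator expression levels —
chosen once so that the standard sweep produces population summaries near
the field's reported values: resting ~438 a.u., median peak ~60% dF/F,
RT ~1.3 s, DT1 ~2.6 s.

| parameter | default | units | role |
|---|---|---|---|
| `baseline_ca` | 0.15 | norm. conc. | resting free calcium |
| `influx_per_ap` | 0.033 | norm. conc. | increment per pulse (log-normal across cells, sdlog 0.7) |
| `k_serca` | 0.20 | 1/s | ER sequestration rate |
| `k_pmca` | 0.42 | 1/s | plasma-membrane extrusion rate |
| `indicator_kon` | 1.0 | 1/(conc$^n$ s) | binding rate |
| `indicator_koff` | 0.75 | 1/s | unbinding rate |
| `hill_n` | 2 | — | binding cooperativity |
| `f_rest`, `f_gain` | 411, 950 | a.u. | fluorescence offset and gain |
| `noise_sd` | 25 | a.u. | per-pixel read noise |

The across-cell log-normal influx produces the strongly right-skewed
peak-amplitude distribution seen in real populations while every
parameter remains unimodal; the moderate indicator saturation
(Hill $n = 2$, $K_d = k_{off}/k_{on}$) makes slope almost perfectly
collinear with peak ($R^2 \approx 0.9$) yet leaves DT1 essentially
independent of peak ($R^2 < 0.1$), the same dissociation the population
statistics are designed to detect.

### What the simulator does not reproduce

* **DT2 ~ 9 s.** Real transients recover with a long residual tail
  (reported DT2 means near 9 s against DT1 near 2.6 s, a $T_{90}/DT1$
  ratio of ~4.5). A single compartment with linear clearance and
  first-order unbinding has at most two eigenvalues; producing a 63%
  crossing at 2.6 s *and* a 10% crossing near 11.7 s would require a slow
  ~17-s mode carrying ~20% of the amplitude, which this model cannot
  supply without also dragging DT1 out. Simulated DT2 therefore lands at
  ~1.3–1.6x DT1 (about 3.5 s). The long tail in real cells plausibly
  reflects mitochondrial handling and sodium–calcium exchange, which are
  deliberately outside the model. Tests that quantify DT2 recovery use
  mono-exponential synthetic transients, where the closed form
  $DT2 = \tau(\ln 10 - 1)$ holds.
* Indicator buffering of calcium (binding does not deplete $c$), dye
  bleaching, motion, and saturable (Michaelis–Menten) clearance are all
  absent; clearance stays linear by design.
* Noise is Gaussian per pixel-sample; real PMT noise has a signal-dependent
  component.

Passing tests on these simulations therefore validate the *estimators*
(their accuracy, invariances, and directional sensitivity), not any claim
that real DRG calcium handling is this simple.

## Population statistics

`population_statistics()` reproduces the battery applied to per-cell
tables: all pairwise simple regressions among the six variables (closed
form OLS; two-sided t with $n-2$ df), Holm's step-down correction with
the single-step Bonferroni family threshold reported alongside (published
analyses often quote the fixed $\alpha/m$ threshold while citing the
step-down procedure; both are provided and the step-down decisions are
the operative ones), Freedman–Diaconis histogram bin widths
($2\,\mathrm{IQR}\,n^{-1/3}$, type-7 quantiles, square-root fallback when
the IQR vanishes), and paired t tests with mean percent change for drug
comparisons. Peak amplitude is natural-log transformed only as an export
column (`log_peak_pct`) for downstream mixed-effects modelling, which
this package does not perform.

### The dip test

Hartigan's dip — the minimum over all unimodal distribution functions of
the sup-distance to the empirical CDF — is implemented exactly, in
compiled code. For each candidate mode (a sample point carrying the
allowed atom), feasibility of a distance $d$ reduces to
greatest-convex-minorant / least-concave-majorant conditions on either
side of the mode plus a junction condition where the convex branch meets
the concave one; two amortised convex-hull passes give per-mode
thresholds, and the rare modes where the junction binds are refined by a
Newton iteration on the active linear constraints. The implementation is
held, in the test suite, to exact agreement with an independent
linear-programming formulation over piecewise-linear unimodal CDFs on
hundreds of small samples, including every multiset of size 4–6 from a
fixed grid.

P-values are Monte-Carlo: the fraction of reference-null samples of the
same size whose dip is at least the observed one, fully seeded. The
default reference is the uniform distribution — the convention behind the
published dip tables, and the least favourable unimodal case. A
consequence worth stating plainly: against the uniform reference the test
is *conservative* for lighter-tailed data (for Gaussian samples of
n = 100 the achieved level at nominal $\alpha = 0.05$ is well below
0.01). The calibration study in the test suite therefore draws its
Monte-Carlo null from the same Gaussian family that generates the data,
which is the appropriate way to verify that the p-value machinery attains
its nominal level; applied analyses keep the conservative uniform
default.

## Pipeline, formats, reproducibility

`run_pipeline()` streams the synthetic population one cell at a time
(generate, quantify, discard), so memory stays flat at any population
size, and writes the parameter table, summary, regression and dip-test
CSVs plus a JSON manifest recording the seed, configuration hash and
exclusion counts. Damaged-cell exclusion — done by eye in practice — is
made reproducible as a rule: cells whose resting brightness or
pre-stimulus dF/F variability exceed configurable population quantiles
(default 99.5%) are flagged with a logged reason. All CSV numbers are
written with fixed formatting, so identical seeds give byte-identical
files.

Recordings are stored as 16-bit TIFF with a JSON sidecar carrying the
sampling interval, pixel pitch, stimulus and labels; the round trip is
lossless for detector-range integers, and missing metadata fields raise
errors naming the field.

### Problem sizes

The shipped analyses and checks use sizes chosen to exercise every code
path at full fidelity where it matters: the example recording and the
noise-recovery study run at the native 76 x 20,000 resolution; population
runs use 100–200 cells at 8–16 pixels per line (the spatial average at 8
pixels is already far above the fit noise floor); paired pharmacology
uses 16 (TG) and 22 (pH) cells, matching the scale of such experiments;
dip calibration uses 500 replicates of n = 100 with 500 bootstrap samples
each. `scripts/acceptance.R` re-derives the headline quantities from
scratch at these sizes from a single command-line seed.

## Known limitations

* DT2 is structurally shorter than in real cells (see above); treat
  simulated DT2 as a consistency check on the estimator, not a
  physiological value.
* The simulator's rise times vary less across cells than real ones
  (indicator kinetics are shared; only clearance and influx vary), so
  population RT spread is narrower than in vivo.
* The bi-exponential decay model is an approximation to the simulator's
  (and presumably the cell's) nonlinear decay; the fitted-curve DT1
  agrees with the empirical 63% crossing to within a few percent on
  noiseless transients, and that residual model error is part of any
  reported DT1.
* The dip test's Monte-Carlo p-values inherit the reference-family
  caveat above; with n below ~20 the dip has little power regardless.
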