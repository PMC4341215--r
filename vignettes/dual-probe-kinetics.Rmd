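---
title: "Dual-probe rinse kinetics: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-probe rinse kinetics: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualprobe)
```

## The measurement and the model

A resected tissue specimen is stained for `stain_duration` (default 10)
minutes with an equimolar mixture (default 150 pM each) of a
receptor-targeted probe and an untargeted isotype-control probe, then
rinsed repeatedly; probe concentrations are read out before and after
each of `n_rinses` (default 10) rinses, at `rinse_interval` (default 0.5
min) spacing. Measurement $i$ (0-based, $i=0$ the pre-rinse reading)
occurs at $t = i \cdot \Delta t$ after the end of staining.

Both probes follow a linear three-compartment system over free,
specifically bound, and nonspecifically bound probe:

$$
\begin{aligned}
\dot C_f &= -(F + k_3 + k_5)\,C_f + k_4 C_b + k_6 C_{ns} \\
\dot C_b &= k_3 C_f - k_4 C_b \\
\dot C_{ns} &= k_5 C_f - k_6 C_{ns}
\end{aligned}
$$

with $k_3 = k_4 = 0$ for the untargeted probe (the control is assumed
ideal: it shares $F$, $k_5$, $k_6$ with the targeted probe) and the
washout term $-F C_f$ active only during the rinse phase. The measured
quantity is the total $C_f + C_b + C_{ns}$. The target parameter is the
binding potential $BP = k_3/k_4$, the equilibrium bound:free ratio,
proportional to available receptor concentration.

Washout is modeled as *continuous* first-order clearance at rate $F$
rather than as discrete removal events: the data are smooth concentration
curves indexed by rinse number, and a single rinse-rate parameter fits
them well. The solution is computed exactly. The generator is a Metzler
matrix whose exchange edges are reversible, so it is symmetrizable by the
diagonal scaling $D = \mathrm{diag}(1, \sqrt{k_3/k_4}, \sqrt{k_5/k_6})$;
the compiled fitting core exploits this (a symmetric eigenproblem cannot
be defective, so degenerate spectra need no special casing), while the
R-level `solve_compartments()` uses a plain eigendecomposition with a
scaling-and-squaring fallback when eigenvalue gaps fall below `1e-10`.
Both agree with generic numerical ODE integration to `1e-6` relative
error over random rate draws (enforced in the test suite).

## Estimators

**Ratio.** $BP_{Ratio} = (T - U)/U$ at the final rinse. It is exact when
the curves are proportional, $T = (1+BP)U$, and requires no fit. Under
the compartment model it is systematically biased: with fast specific
exchange the noiseless ratio after a rinse time $t$ is
$e^{F t\,BP/(1+BP)} - 1$, which equals $BP$ only at one particular
washout extent and *underestimates* badly when nonspecific binding
retains untargeted probe. It is reported anyway, as the fast, model-free
comparator. When the untargeted reference falls below `epsilon` (default
`1e-6` pM) the ratio is undefined and an error is raised; the sweep
machinery records such iterations as `NA`.

**DPM.** Two-step fit without the nonspecific compartment: the untargeted
curve is fit as $A e^{-Ft}$ (profiled 1-D search over $F$, closed-form
non-negative amplitude), then the targeted curve is fit for
$k_3, k_4 \ge 0$ with $F$ fixed, amplitudes by non-negative least
squares. On data with nonspecific binding its BP is biased in a
non-monotone, washout-dependent way — the estimator exists to demonstrate
exactly this failure.

**DPM-NS.** The same two steps on the full model: the untargeted curve
estimates $F, k_5, k_6$; the targeted curve then estimates $k_3, k_4$
with those fixed.

### Identifiability and the amplitude anchor

A biexponential curve carries four degrees of freedom. If the untargeted
DPM-NS fit searches three rates *and* two free initial amplitudes, the
rates are identified only up to the eigenvalue pair they produce: a
continuum of $(F, k_5, k_6)$ triples fits noiseless data exactly (we
verified residuals at machine precision along the trace/determinant-
preserving family), and the downstream BP inherits the arbitrariness.
The package therefore anchors the rinse-phase initial state to the
staining kinetics by default (`amplitude_mode = "stain"`): a unit of
applied probe is propagated through the known stain duration under the
candidate rates, and only the overall scale is solved linearly — the
one-column limit of the Kaczmarz–Tikhonov solve, used without a ridge
since a single coefficient is perfectly conditioned. This leaves four
parameters for four degrees of freedom and restores exact round-trip
recovery. The same anchor is used for the targeted fit, where the
free-amplitude parameterization makes BP itself near-unidentifiable (the
noiseless residual profile is flat to ~`1e-6` across BP from 0.6 to 2).
`amplitude_mode = "free"` retains the free-amplitude variant, with the
multi-coefficient amplitudes solved by the randomized column
Kaczmarz–Tikhonov iteration (default $\lambda = 10^{-4}\,
\mathrm{tr}(B^\top B)/k$); its limitations are as stated above, and on
strongly collinear exponential bases the coordinate-action iteration
also converges slowly, so results there should be treated as
regularization-dependent.

### Nonlinear search

Rates are searched on the log scale by Nelder–Mead from 8 deterministic
starting points log-spaced over $[0.01, 1]$ min$^{-1}$ (all rates set to
the start value), each polished by up to two simplex restarts (plain
Nelder–Mead can stall in the narrow curved valleys of exponential fits);
the best residual wins and near-ties (relative `1e-10`) break toward
smaller BP. Rates above 100 min$^{-1}$ are rejected. When $k_4$ is
estimated, values below `k4_floor` (default `1e-6` min$^{-1}$) are
reported at the floor with `converged = FALSE`, since BP diverges as
$k_4 \to 0$.

`k4_fixed`: the targeted fits optionally hold $k_4$ at a known value and
profile only $k_3$ (1-D golden-section plus an explicit comparison with
the no-specific-binding limit). The Monte-Carlo study uses
`k4_fixed = 0.1` min$^{-1}$, treating the specific dissociation rate as
a known constant of the simulated system, consistent with taking it from
the receptor-binding literature. This choice matters: with $k_4$ free,
the near-null level ($BP = 5\times 10^{-4}$) produces unbounded BP
estimates whenever noise drives $k_4$ to its floor, and the
no-NS-model estimator explodes similarly. The default of 0.1 min$^{-1}$
itself is a literature-consistent order of magnitude, not a verified
value; it is exposed in `simulation_config()`.

## The synthetic-data generator

`simulate_dual_probe()` reproduces the acquisition: explicit stain phase
(no washout) from $(C_{app}, 0, 0)$, then the rinse phase sampled on the
schedule grid. Defaults are the study conditions: 150 pM applied, 10 min
stain, 11 measurements at 0.5 min spacing, $k_5 = 0.16$,
$k_6 = 0.06$ min$^{-1}$ (nonspecific ratio 2.67), $k_4 = 0.1$
min$^{-1}$, BP levels $5\times10^{-4}$ / 1 / 3 for healthy-, U251- and
A431-like tissue, and i.i.d. Gaussian noise with
$\sigma = 0.48\% \cdot \mathrm{RMS}(\text{clean curve})$ per point
(negative noisy values are retained; file ingest clamps negatives, which
arise from spectral demultiplexing, to zero with a warning). The noise
is defined against the pooled curve RMS because the matching noise
*estimator* (`estimate_noise_percent()`) is the pooled relative L2
residual $100\,\lVert d - c\rVert_2 / \lVert c \rVert_2$; per-point
relative noise is the main alternative and would concentrate information
in the late, low-concentration points.

The washout rate is not a measured constant of the system; we set
$F = 2$ min$^{-1}$ so that one 0.5-min rinse cycle removes
$1 - e^{-1} \approx 63\%$ of free probe, i.e. each rinse removes a
significant portion of unbound probe, which matches how the procedure is
described and gives curves whose decay actually informs the fit. This
choice has consequences documented below.

What the generator does *not* emulate: spatial diffusion of probe into
tissue, receptor depletion/saturation (binding is linear), photobleaching,
rinse-to-rinse variability in rinse efficacy, and instrument effects
beyond additive Gaussian noise. Passing tests therefore demonstrate
estimator behavior under the stated kinetic model, not robustness to
those real-data effects.

## The Monte-Carlo study

`run_recovery()` simulates `n_iterations` (default 100) noisy replicate
experiments at each BP level and applies the ratiometric and DPM-NS
estimators; `run_ns_sweep()` holds BP at 2.17 and sweeps $k_5/k_6$ over
$\{0, 0.5, 1, 1.5, 2, 2.67, 3.5, 5\}$, applying all three estimators.
One root seed spawns a fixed per-(condition, iteration) seed matrix, so
results are bitwise reproducible and sweep points are independent.

Observed behavior at the defaults (seeds as in the test suite): DPM-NS
recovers all three levels (null mean below 0.1; biases at 1 and 3 within
a few percent) with relative precision around 6% at $BP = 1$; the ratio
underestimates severely (means ~0.11 at 1, ~0.22 at 3) with relative
precision around 8–9%; DPM's absolute error under nonspecific binding is
large but varies non-monotonically with $k_5/k_6$ at this washout rate.
Two regime caveats, both consequences of $F = 2$: at the zero-NS sweep
point the untargeted reference washes to ~0.01 pM, far below the noise
floor, so the ratio there is undefined (recorded as `NA`) and the
DPM-NS error is noise-dominated; and at much weaker washout
($F \approx 0.3$, where $e^{Ft} - 1 \approx 1 + BP$) the ratio becomes
nearly unbiased at zero NS and the DPM error becomes monotone in
$k_5/k_6$ — but the untargeted rates are then so weakly identified under
0.48% noise that DPM-NS precision collapses to tens of percent. No
single washout rate reproduces both regimes; the package's conditions
favor the precision regime, and the sweep's monotonicity claim for DPM
should be read with that in mind.

## Spectral demultiplexing

`dcls_unmix()` solves spectrum $\approx \sum_i w_i \cdot$ref$_i + w_b
\cdot$background by (non-negative, by default) least squares. The tissue
background is co-fit as an extra component with a free weight rather
than pre-subtracted — co-fitting is robust to intensity scaling of the
background between acquisitions — with a subtract-first mode available;
optional polynomial baseline columns (order 1–2) are off by default
since the synthetic fixtures have no baseline drift. Reference libraries
are validated for a shared channel grid and for conditioning (condition
number above `1e8` names the most collinear pair). Fixtures use 400
channels over 600–1800 cm$^{-1}$ and Lorentzian fingerprint lines;
they emulate the *structure* of narrow-band fingerprint spectra, not any
proprietary chemistry. `calibrate()` converts weights to pM against a
stock measurement of known concentration (default 150 pM), one scale per
flavor.

## Group statistics

`compare_groups()` mirrors the SPSS workflow used for tissue cohorts:
one-way ANOVA; Levene's homogeneity test centered on the mean (the SPSS
default); Shapiro–Wilk per group; and a post-hoc branch gated at
`levene_P < 0.05` — Bonferroni (pairwise t on the pooled ANOVA error
term, $P$ multiplied by the number of pairs, capped at 1) under
homogeneity, Tamhane's T2 otherwise. T2 is implemented as pairwise Welch
tests with the Šidák-type correction $1 - (1-p)^m$; SPSS computes its
critical values from a Studentized-range-like distribution, so the two
agree closely but not exactly for small $m$ — treat the Tamhane P-values
as a standard approximation.

## Known limitations

* The three-compartment structure, while standard for reference-tissue
  binding models, is a reconstruction; the washout rate and the fitting
  parameterization (amplitude anchoring, fixed $k_4$ in the simulation
  study) are package design choices with the rationales given above.
* The free-amplitude mode is retained for completeness but is not
  identifiable; do not use it to estimate rates.
* Tamhane P-values are Šidák-approximate (above).
* The ratio estimator needs a usable untargeted reference; at strong
  washout with no nonspecific binding there is none.
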