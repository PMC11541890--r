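---
title: "Voltammetric screening of synthetic cathinones: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voltammetric screening of synthetic cathinones: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voltscreen)
```

## The screening model

Synthetic cathinones (SCs) share a β-keto phenethylamine core whose
reduction chemistry on a boron-doped diamond electrode produces two
cathodic processes, R1 (−1.4 to −1.2 V vs Ag/AgCl) and R2 (−1.6 to
−1.45 V), at pH 8.0 in Britton–Robinson buffer. Because no common
adulterant or co-seized drug reduces in those windows, R1/R2 work as a
class fingerprint, and the package's positivity rule is deliberately
simple:

> a sample is SC-positive **iff** a reduction peak is found inside the R1
> window on the cathodic scan.

R2 is recorded when present but never required — it is the less sensitive
of the two processes and drops below the detection limit first. Samples
showing neither process are negative.

Positive samples are then assigned one of six structural groups from the
*anodic* scan. The oxidation chemistry tracks the substituents: the
3,4-methylenedioxy ring contributes a ~+0.60 V oxidation, progressive
N-substitution adds processes between +0.7 and +1.3 V, and the thiophene
analogue uniquely oxidizes below 0 V. That yields a decision table on the
count *n* of oxidation peaks in (+0.45, +1.40] V, evaluated top-down:

1. any oxidation in (−0.40, −0.10] V → G6 (thiophene marker);
2. n = 5 → G4; n = 4 → G3; n = 3 → G2;
3. n = 2 with both peaks in the +0.90/+1.0 V band and no +0.60 V process
   → G5;
4. n ≤ 1 → G1 (one G1 member shows no anodic oxidation at all in DPV);
5. anything else → no group, while the sample stays positive.

Mixtures of SCs are reported as the candidate group with the larger
expected anodic count (`resolve_mixture()`); ties go to the lower group
index, an arbitrary but deterministic convention.

### Interferent flags

Three evidence patterns are flagged without affecting positivity:
caffeine (anodic ~+1.30 V), MDMA/MDEA (cathodic reductions at both
~−0.70 and ~−0.50 V), and paracetamol (−0.24 V reduction plus +0.21 V
oxidation). The caffeine window collides with the terminal oxidation of
the methylenedioxy groups (G2–G4 end at +1.25/+1.19 V), and nothing in
the underlying chemistry disambiguates a lone co-located pair. The
package uses a two-route heuristic: flag caffeine when the +1.30 V peak
appears **without** the +0.60 V methylenedioxy companion, or when it
towers over the next-largest anodic peak by a configurable factor
(`caffeine_factor`, default 1.5 — caffeine is usually the bulk excipient,
so its peak dominates). Only the first route removes the peak from the
anodic count; under the second route a methylenedioxy SC may legitimately
co-own the window. Samples with anodic activity that no SC or known
interferent pattern explains are flagged `other`.

## The synthetic-data generator

No raw voltammograms accompany the published fingerprints, so the package
generates its own data with the statistical structure the analysis
assumes:

\[
I(E) = \mathrm{baseline}(E) + \sum_{\text{peaks}} s \cdot k_A \, c \, a
\exp\!\left(-\frac{(E - E_p - \delta)^2}{2\sigma^2}\right) + \varepsilon(E)
\]

with sign *s* (+1 oxidation, −1 reduction), amplitude constant
`amplitude_scale` \(k_A\) = 0.05 µA/(µmol/L), concentration *c*, relative
amplitude *a*, and per-peak potential jitter \(\delta\). The baseline is
a cubic polynomial plus exponential rises at both window edges that mimic
solvent discharge. Defaults, and why:

| Parameter | Default | Rationale |
|---|---|---|
| `step_potential` | 0.010 V | the instrument's step potential; sets the grid |
| peak width (FWHM) | 0.07 V | typical DPV half-width; interpreting the width as FWHM (σ ≈ 30 mV) lets every adjacent pair of library processes (e.g. +0.90/+1.01 V) resolve, as the published voltammograms do |
| `rel_amplitude` | R1 = 1.0, R2 = 0.6, oxidations = 0.8 | relative intensities are not published; R1 is the reference process and R2 is explicitly the less sensitive one |
| `noise_sd_fraction` | 0.02 | keeps 5-replicate repeatability within the published bounds (I_p RSD < 13%, E_p RSD < 1%), with room to spare |
| `noise_floor` | 0.05 µA | instrument background noise exists even in blanks; without it an SC-free trace would be an exact polynomial and negative-sample screening would be vacuous |
| `potential_jitter_sd` | 5 mV | run-to-run drift; together with the 10 mV grid it keeps E_p RSD ≈ 0.4% |
| `pH_shift_slope` | −59 mV/pH | peak potentials move negative with pH; the magnitude is the Nernstian 1e⁻/1H⁺ slope, applied relative to the working pH 8.0 |

The 46-sample panel fixture reproduces the composition of a real seized
panel at the level the published account states it: 42 SC-positive samples
(two of them SC mixtures, samples 8 and 28; six with R2 suppressed below
detection, samples 7, 26, 27, 30, 32, 40), 4 negatives, caffeine in 14
named samples and MDMA in two. Per-sample SC identities beyond that are
not public, so the generator fills them round-robin over the 15 library
SCs, and places the negatives at samples 10, 22, 44, 46 (cocaine-,
paracetamol-, ketamine- and MDMA-only — sample 46 is one of the two named
MDMA samples, hence an MDMA-only negative). SC and interferent
concentrations are drawn uniformly from 50–150 µmol/L per sample, a
realistic working range after the method's 800-fold extract dilution.

**What the generator does not emulate:** electrode kinetics and scan-rate
effects, capacitive currents, peak asymmetry and tailing, inter-electrode
variability, matrix effects from excipients, and analyte-specific
amplitude differences. Passing tests therefore demonstrate that the
decision rules, preprocessing and statistics are implemented correctly
and behave sensibly under realistic noise — not that the method would
achieve the same figures on new instrument data.

## Numerical choices

* **Baseline subtraction** (`correct_baseline()`): iterative polynomial
  fit, order 3, on an orthogonal-polynomial basis. Points deviating from
  the current fit by more than 2.5 × MAD are excluded and the fit is
  repeated (50 iterations max). Convergence is declared when the fitted
  baseline moves less than 1e-4 of the trace's current span — a
  shift-invariant scale, so adding a constant current provably leaves the
  corrected trace unchanged — or when the clip set stabilizes (including
  2-cycles, which noise can induce). The published workflow used
  interactive polynomial fitting in a commercial tool; order 3 and
  crop-before-correct are this package's choices, and both are
  configurable. Corrected + baseline reconstructs the input exactly.
* **Peak detection** (`detect_peaks()`): local extrema of the signed
  current; oxidations are maxima, reductions minima, with no
  rectification. A peak must clear *both* thresholds: topographic
  prominence ≥ 5% of max |I|, and signed height ≥ the same threshold —
  the latter because the saddle between two deep reduction valleys is
  topographically prominent yet is not an oxidation process. Width at
  half prominence must reach 0.02 V, which suppresses single-point noise
  spikes on the 10 mV grid.
* **Window matching** (`match_peaks()`): windows are half-open (lo, hi];
  the R1/R2 windows share the −1.45 V boundary, which belongs to R2.
  Each window takes its largest-|I| in-window peak; ties break toward the
  window centre.
* **Observed-process threshold**: the classifier and the calibration
  extractor ignore peaks below `min_height` = 0.3 µA. This is the
  package's answer to "how big must a current be to count as a process",
  which the underlying method leaves to the analyst's eye: 0.3 µA sits
  ~6× above the blank noise floor and ~8× below the R1 current of a
  50 µmol/L SC.
* **Calibration**: σ in LOD = 3.3σ/S is the regression's residual
  standard deviation (n − 2 denominator). "Standard deviation of the
  response" is ambiguous between residual SD, blank SD and intercept SE;
  the residual SD is the only one computable from the calibration line
  alone. The linear-range search prefers the widest qualifying span and,
  among equals, spans containing the top level, since real calibrations
  lose the *low* end to the detection limit. r² is computed in closed
  form; a zero-variance (flat) span scores 0.
* **PCA/HCA** (`run_pca()`, `run_hca()`): PCA is column-mean-centred and
  unscaled (rows are already normalized traces; autoscaling is available
  behind a flag), with component signs fixed so each loading's
  largest-magnitude entry is positive. HCA defaults to Ward linkage
  (ward.D2) on Euclidean distances; dendrogram heights are also reported
  on a 100 × (1 − d/d_max) similarity scale for comparability with
  published dendrograms.

## Known limitations

* **Gap-based cluster-number selection is fragile on this library.**
  Cutting the 15-standard dendrogram at a *fixed* k = 6 recovers the six
  designed groups exactly (the test suite checks this for Ward linkage).
  But selecting k via the largest merge-height gap (`cut_by_gap()`) does
  not land on 6: with all anodic relative amplitudes equal, G3 and G4
  differ by a single extra oxidation (+0.78 V) plus a 0.83→0.90 V shift,
  so their inter-group distance falls below G1's internal spread
  (mephedrone's O1 at +1.19 V vs 4-MPD's at +1.10 V vs ethcathinone's
  none). The largest gap therefore always sits above the G3+G4 merge,
  whatever the linkage or metric. Real voltammograms carry
  analyte-specific intensity differences that the equal-amplitude
  generator deliberately omits; with such contrast the gap statistic may
  well behave. Use `cut_k()` when the group count is known.
* The caffeine-vs-methylenedioxy +1.30 V collision is resolved
  heuristically (above); a caffeinated G1 or G5 sample keeps its group
  because the attributed peak is removed from the count, but a sample
  whose caffeine peak merges with a G2–G4 terminal oxidation retains it,
  and the flag then depends on the dominance factor.
* A sample with exactly two anodic processes including +0.60 V matches no
  library pattern and is reported positive with no group, as is any
  pattern with six or more counted oxidations.
* Group assignment uses the anodic scan only; an anodic-less sample
  degrades gracefully to a cathodic-only positivity call.
* LOD/LOQ figures computed from synthetic traces characterize the
  generator plus pipeline, not any physical electrode.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data
at the sizes the analysis itself uses: 46-sample panels (two 361–401
point traces per sample), 15 × 3 standards matrices (45 × 682 features),
and 21-trace calibrations. A full panel screen takes ~1.5 s on one core;
the whole suite runs in well under a minute.
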