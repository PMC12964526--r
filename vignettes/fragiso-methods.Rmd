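---
title: "Methods: fragment-specific isotope-ratio processing for ESI-Orbitrap-MS"
author: "fragiso maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragment-specific isotope-ratio processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragiso)
```

## The measurement model

Sulfamethoxazole (SMX, C₁₀H₁₁N₃O₃S) ionized by positive ESI and fragmented
by HCD yields two fragment ions: F92 (C₆H₆N⁺, the aniline part) and F99
(C₄H₇N₂O⁺, the 3-amino-5-methylisoxazole part). Six isotopologues are
monitored — for each fragment the unsubstituted base peak, the singly
¹⁵N-substituted and the singly ¹³C-substituted species — giving four
measurement channels: F92-C, F92-N, F99-C, F99-N. The theoretical m/z of
every species is the sum of exact nuclide masses minus one electron mass
per charge (`monoisotopic_mz()`); recomputed values agree with typically
printed instrument masses within ±0.001 u, the tolerance used throughout
(printed masses may be observed centroids rather than theoretical values).

The chain from scan tables to calibrated Δδ values is:

1. **Ion counts.** Orbitrap intensities are converted to estimated ion
   counts per scan, N_IO = (S/N)·(C_N/z)·√(R_N/R)·√μ, with the empirical
   noise-band constant C_N = 3 and reference resolution R_N = 240 000.
   μ, R and z are read per scan from the table (not from config), so files
   with mixed microscan settings are processed correctly.
2. **Window ratios.** Over the usable time window, Rⁱ = Σ N_IO(i) / Σ
   N_IO(base). This is the ion-count-weighted mean of per-scan ratios,
   not the unweighted mean — at low signal the two differ, and the
   weighted form is the one with Poisson-efficient weighting. Under the
   *stochastic distribution assumption* (heavy isotopes independently and
   uniformly distributed over equivalent positions), the expected
   singly-substituted/base ratio is n_atoms × r, with r the element's
   per-atom isotope ratio, so ratio-of-ratios quantities inherit the
   element's δ directly; the atom count cancels in δ.
3. **Bracketing.** The timeline is cut into alternating reference/sample
   blocks (reference first; the canonical LC sequence is 5 reference + 4
   sample blocks of 18 min, i.e. a 162-min timeline; the first 3 min of
   each block are discarded for valve switching). Each sample block is
   referenced to the arithmetic mean of its two neighbouring reference
   ratios, δ = (R_s/R̄_ref − 1)·1000, with the working standard's δ set
   to 0 ‰ — so all results are Δδ values on the working-standard scale
   and any common instrument gain cancels exactly.
4. **Uncertainty.** The SEM of the sample ratio and the bracketing-mean
   uncertainty σ_ref = √((σ₁/2)² + (σ₂/2)²) propagate to
   σ_δ = 1000·√((σ_s/R̄_ref)² + (R_s·σ_ref/R̄_ref²)²). The n bracket
   sigmas aggregate to a 95 % CI as √(Σσᵢ²/n) · t_{0.05,n−1}.
5. **Calibration.** Per (fragment, element), measured Δδ of labeled
   standards regress on their mass-balance expected values Δδ_calc;
   samples are inverse-mapped through the fitted line (two-point when only
   two standards are available, OLS otherwise), with σ scaled by 1/|slope|.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `data_window_min` | 15 | min | direct-infusion data window |
| `block_duration_min` | 18 | min | LC bracketing block length |
| `switch_discard_min` | 3 | min | valve-switch settling discard |
| `agc_target` | 3 × 10⁶ | ions | the AGC setting used for final measurements (1.0/1.5/3.0 × 10⁶ tested) |
| `c_n`, `r_n` | 3, 240 000 | –, – | S/N→ion-count constants |
| `t_alpha` | 0.05 | – | two-sided CI level |
| `sem_method` | `"scan"` | – | per-scan ratio dispersion / √n; `"bootstrap"` resamples scans |
| `ci_method` | `"rms_t"` | – | the method's RMS × t rule; `"replicate_sd"` is the conventional mean-CI |

## Estimator choices (where the design was open)

**SEM of the window ratio.** A standard error for the window ratio can be
defined several ways and bracketing conventions rarely pin one down.
Default: SD of per-scan ratios / √n_scans, with the sum-based ratio kept
as the point estimate; a scan-resampling bootstrap (B = 200) is available
via `sem_method`. Scans with an undetected numerator contribute
zero counts rather than being dropped — dropping would bias ratios upward
at low signal.

**The RMS × t confidence interval.** The CI rule √(Σσᵢ²/n)·t carries no
1/√n for the mean of the n brackets; it is therefore conservative by
roughly √n relative to a conventional CI of the mean (empirical null
coverage ≈ 100 % on 4-bracket sequences). It is kept as the default out
of fidelity to the bracketing convention; `ci_method = "replicate_sd"`
provides the conventional estimator, and results carry an `estimator`
column so the two are never confused. For a single bracket (n = 1, where
the t-rule is undefined) the CI is 1.96 × σ_δ; this z-interval is
calibrated (measured null coverage 0.92–0.96 per channel over 200 seeded
runs) and is what the package's coverage acceptance test checks.

**Reference averaging in ratio space.** Brackets average R, not δ —
the error-propagation form (quadrature of ratio SEMs halved) implies
ratio-space averaging. Nearest-two bracketing is used in direct-infusion
sequences (which of several possible reference injections to use was not
fully specified).

**Unweighted OLS calibration.** Unweighted OLS is the default; 1/σ²
weighting is available. Calibration models are strictly per (fragment, element) and per
measurement sequence — slopes differ between fragments and between
measurement days. EA-IRMS true-value error is excluded from calibrated
sigmas by default (optional quadrature inclusion), since the working-
standard scale absorbs common offsets.

**Standard-series semantics.** A spike target of x ‰ for a labeled
standard is interpreted as the target enrichment of the labeled
*fragment*; the bulk value follows by atom-count dilution
(×n_frag/n_mol, e.g. 200 ‰ at F99-C → 80 ‰ bulk). For fragments holding a
single atom of the element (F92-N) fragment and position enrichment
coincide — the typical preparation case (on the order of 100 ‰ from a
1 mg spike into 1 g). The mixing calculator treats labeled and
unlabeled SMX as isobaric (the 0.1 % molar-mass difference of a single
substitution is negligible at mg/g spikes) and defaults to natural atom
fractions 0.0107 (¹³C) and 0.003663 (¹⁵N); with a 99 atom % label the
1 mg/1 g spike evaluates to ≈ 92.5 ‰.

## What the simulator emulates — and what it does not

`simulate_scan_table()` draws, per scan, Poisson counts around
AGC × transfer-efficiency expected ions, split across F92/F99 and across
isotopologues by the stochastic-model abundances implied by the configured
true Δδ (after an optional δ-space linear instrument response), modulated
by a smooth multiplicative drift applied equally to all isotopologues.
Intensities are back-computed from counts at constant peak noise, so the
ion-count conversion is exactly invertible on synthetic rows.

Emulated: shot-noise-limited precision and its 1/√(total ions) scaling;
the ~3× worse nitrogen vs carbon precision (fewer minor-isotopologue
ions); drift cancellation by bracketing; slope-≠-1 calibration lines.

Not emulated: space charge and ion coalescence (the physical mechanism
behind AGC-dependent bias — only its δ-space phenomenology via the
response slope/intercept), isobaric interferences, chromatographic peak
shape and the mixing-chamber homogenization, retention-time drift, and
detector nonlinearity. A green simulation test therefore establishes the
*statistical* correctness of the estimators under the stated noise model,
not instrument accuracy.

Defaults with no instrument-reported counterpart, chosen once at
realistic orders of magnitude and flagged in run logs: ion transfer
efficiency 0.5 (AGC fill → detected fragment ions; transmission and
fragmentation yields are not observable from the exports), scan period 2 s (10 microscans at R = 90 000, giving ~450
scans per 15-min window), drift RSD 0.05 (under the < 8 % spray-stability
criterion), EA-IRMS replicate SD 0.3 ‰ (the homogeneity level). Tests use
desk-scale reductions (shorter blocks, lower AGC) where many seeded
repetitions are needed; the structure, not the scale, is what those tests
assert.

## Numerical choices and degenerate inputs

- Time windows are half-open [start, end); block k of duration d is
  usable on [kd + s, (k+1)d).
- A trailing partial block is dropped with a warning; a final sample
  block without a following reference is flagged and skipped; fewer than
  3 complete blocks is an error (no complete bracket).
- Zero base-peak sums, non-positive reference ratios, negative sigmas,
  degenerate calibration abscissae and |slope| < 0.05 are hard errors,
  not NaNs.
- Peak matching at 20 ppm separates the ¹⁵N/¹³C isobars at nominal m/z 93
  and 100 (6.7 mu apart); two catalog hits within tolerance raise an
  ambiguity error rather than picking the closer one silently.
- δ mass balance is first-order (delta-linear); the exact ratio-space
  balance is kept as an internal oracle and agrees within < 0.1 ‰ for
  |δ| ≤ 100 ‰.

## Known limitations

- Only singly substituted isotopologues are modeled; clumped species are
  ignored (their natural abundance is ~10⁻⁴ of the base peak, far below
  the shot-noise floor at these ion loads).
- The isotopologue weight normalization truncates the distribution to the
  monitored species; the induced bias is common to sample and reference
  and cancels in Δδ.
- No drift correction across sequences and no anchoring to international
  scales (VPDB/air): all results are Δδ vs the working standard by
  construction.
- Eq-style RMS × t CIs are conservative on multi-bracket sequences (see
  above); comparisons of "significant change" at 2 × CI inherit that
  conservatism.
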