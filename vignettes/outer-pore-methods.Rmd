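---
title: "Methods: synthetic patch clamp and outer-pore analyses for TRPA1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic patch clamp and outer-pore analyses for TRPA1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trpa1pore)
```

This vignette is the package's account of its science: what each model
assumes, which parameters matter and why they default to what they do, what
the synthetic generator does and does not emulate, and where the numerical
choices were genuinely open.

## Why a synthetic pipeline

The analyses here — event idealization, amplitude histograms, averaged
open-channel I–V relations, voltage-dependent block fits, surface-potential
arithmetic, organic-cation sizing — are conventional patch-clamp analyses of
the TRPA1 outer pore. No raw recordings are distributed with the study they
quantify, so each analysis stage is instead driven by a generator whose truth
is known exactly. That turns every estimator into a parameter-recovery
problem: a passing test means *this analysis code recovers what the
generator put in under realistic recording statistics*. It does not certify
behavior on real recordings, whose artifacts the generator deliberately
omits (below).

## The synthetic recording generator

A sweep is rendered in three layers:

1. **Gating.** A continuous-time two-state Markov chain (closed ⇌ open) with
   exponential dwells, sampled on the acquisition grid. Each opening enters
   the smaller of two conductance levels with probability `p_small`,
   otherwise the larger. The initial state is drawn from the stationary
   distribution, so the long-run open fraction is
   `open_rate/(open_rate + close_rate)` without burn-in.
2. **Currents.** `I = γ(state)·(V − V_rev)·10⁻³ + g_leak·V·10⁻³` with γ in
   pS, V in mV and I in pA. Inward current is negative; the reversal
   potential is 0 mV in the symmetrical solutions all fixtures represent.
3. **Noise.** White Gaussian noise shaped by a 4-pole low-pass Bessel
   approximation of the recording filter (analog prototype poles, bilinear
   transform), then calibrated so the post-filter RMS equals `noise_rms_pA`.
   At the standard acquisition settings (10 kHz sampling, 5 kHz cutoff) the
   cutoff sits at Nyquist — there the physical filter was analog and
   pre-digitizer, a digital stand-in would be an identity, and the noise is
   left white at the calibrated RMS.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `open_rate`, `close_rate` | 50 s⁻¹ each | the analyses use amplitudes, not kinetics; rates only need to produce many resolvable (≫0.5 ms) events per sweep |
| `p_small` | 0.3 | both levels always present, the larger dominant, the smaller sometimes rare — a middle-of-road mixing fraction fixed once |
| `noise_rms_pA` | 1 | makes the standard 3 pA analysis threshold a ≈3σ cut |
| `leak_pS` | 20 | a visible but ordinary seal leak; leak subtraction must remove it exactly |
| temperature | 298.15 K | RT/F = 25.69 mV, consistent with the 180 mV·Å screened-Coulomb prefactor used in the electrostatics |

The fixture registry pins the per-condition truths: wild type in 150 mM
symmetric Cs⁺ at 251/170 pS, 500 mM at 345/215 pS, 150 mM + 100 µM Ba²⁺ at
161/89 pS, and E920A at 172/99 pS. Rectifying mutants carry *branch
conductances* — separate negative/positive-branch slopes used when rendering
ramps (E920A at 54%/85% of wild type, D915E at 63%/62%, D915A at 10%/50% of
the 500 mM wild type). This is deliberately phenomenological: the study
reports branch conductances, not a mechanistic rectification model, so the
generator encodes exactly what is reported and nothing more. Where a truth
is not printed (the E920A positive branch is only "slightly less" than wild
type; the high-salt negative branches are "not significantly different") a
single representative value was fixed a priori (85% and 95%).

The generator does **not** emulate: desensitization, multi-channel patches,
capacitance transients or series-resistance error, flicker block,
baseline drift, or state-dependent pore dilation. Passing tests therefore
say nothing about analyses that would have to contend with those.

## Single-channel analysis

**Leak subtraction** is a pointwise difference against a paired control
sweep (the nearest sweep with no openings), which removes leak exactly but
doubles the noise variance — downstream thresholds account for the √2.

**Event detection** re-implements a commercial single-channel search as
something auditable: maximal runs of consecutive samples with |I| ≥ 3 pA
lasting at least 0.5 ms (≈ the recording filter risetime; 5 samples at
10 kHz). The boundary convention keeps points exactly at threshold
("removing points *below* 3 pA"). A per-sample brute-force scan is the test
oracle; the run-length implementation must match it exactly. With 1 pA RMS
noise the false-event rate is negligible (a ≥5-sample excursion beyond
~2.1σ of the subtracted trace has probability ≈ 4·10⁻⁸ per sample).

**Amplitude histograms** are built from open-channel *points* (all samples
inside detected events), not per-event means: point amplitudes have
homogeneous recording-noise variance, whereas event means are a scale
mixture (variance shrinks with event length) that confounds mixture model
selection. One- versus two-component Gaussian mixtures are compared by BIC;
a two-component solution is only reported when the means are separated by
at least twice the wider component SD, since "levels" closer than the noise
resolution are not resolvable open states. With very large point counts the
sample is thinned deterministically to 50 000 points — BIC on larger samples
starts splitting trivial non-Gaussianity.

**Averaged open-channel I–V curves** pool event samples from leak-subtracted
ramps, bin them in 5 mV bins, and average. Samples within the noise band are
discarded with the events, which produces the characteristic gap around the
reversal potential: an ohmic γ channel has empty bins wherever |γV| < 3 pA.
Branch slope conductances are ordinary least-squares slopes on the negative
and positive branches separately. The default fit window |V| > 20 mV clears
the gap for conductances ≥ ~170 pS; for smaller conductances the window must
widen, and the package computes the clearance voltage explicitly as
`(threshold + 2σ)/γ` (`gap_clear_voltage()`). The wild-type/E920A
negative-branch comparison uses the window implied by the mutant's 135 pS
branch (|V| ≳ 43 mV); fitting it at the default window would fold
noise-censoring bias into the mutant slope. Ramp ensembles destined for
slope estimation are rendered with openings at the larger level only,
mirroring the convention of measuring only the main open state in I–V
analyses; sub-level mixing would otherwise shift both slopes by the mixing
fraction.

## Voltage-dependent block

The two-barrier Woodhull expression for a permeant blocker,

$$K_D(V) = \frac{k_{-1}}{k_1}e^{\delta z F V/RT}
         + \frac{k_2}{k_1}e^{(\delta-\tfrac12) z F V/RT},$$

places the entry barrier halfway between the outside and the binding site,
which forces the (δ − ½) exponent on the permeation term. Only the rate
*ratios* `K_out = k₋₁/k₁` and `K_through = k₂/k₁` are identifiable;
K_D(0) = K_out + K_through. The packaged wild-type truth splits the 0.6 mM
zero-voltage constant evenly (0.3 + 0.3 mM) — the split is a fixture choice,
as only the sum's behavior is constrained — with δ = 0.5 and a Hill
coefficient of 0.6 (inside the reported 0.34–0.63 range for divalent block).
Mutant truths scale affinity by the reported fold changes: 3× weaker
(E920A), 10× weaker (D915A), 3× stronger (D915E).

Fitting is global: one parameter set across all concentrations of a family
of normalized I–V curves (normalization at the highest ramp voltage, where
block is weakest, cancels the unblocked conductance). Rate ratios and the
Hill coefficient are optimized in log space, δ bounded to [0, 1], by
Levenberg–Marquardt from four starting points with the best optimum kept.
Losses are unweighted least squares on normalized currents. Noiseless
families are inverted to ≤10⁻⁴ relative error (and checked against an
exhaustive grid-search oracle); at 2% multiplicative noise δ is recovered
within ±0.05 in most families, while K_D(0) is the softest direction (a
shallow Hill slope lets K_D trade against n) and can deviate ~20% in a
single five-concentration family. Simulated study conditions: concentrations
0.3/1/3/10/30 mM over −110 to +70 mV, 2% lognormal noise — the
concentration ladder spans K_D(0) up to deep block with the reported 30 mM
maximum.

## Surface potentials

Boltzmann accumulation links a potential change at the pore mouth to
measurable ratios: `Δφ = (RT/zF)·ln(K_D,mut/K_D,wt)` from blocker affinity,
and the same form on conductance ratios if conductance is proportional to
the local permeant concentration. Sign convention (made explicit because
the study reports magnitudes): Δφ is the mutant-minus-wild-type change,
positive when a negative charge is removed. The E920A neutralization gives
Δφ ≈ 15.8 mV from the 54% conductance ratio and ≈ 14.1 mV from a three-fold
divalent affinity loss — the agreement is the argument that the blocker
binds at the limiting site for permeation.

The bottom-up counterpart is screened-Coulomb superposition,
`φ = d·Σ zᵢ·A·e^{-rᵢ/λ}/rᵢ`, with A = 180 mV·Å in water, λ = 8 Å at 150 mM
ionic strength (the package computes λ from first principles; 7.9 Å at
298 K), and an optional doubling factor d for charges at a
water/low-dielectric interface. Four glutamate charges 11 Å from the pore
axis sum to 16.5 mV *without* doubling; applying the interface doubling
there would give ~33 mV, inconsistent with the measurement-derived ~16 mV,
so the four-charge figure is computed undoubled and the doubling is exposed
as an explicit parameter rather than a buried assumption. Full continuum
Poisson–Boltzmann electrostatics on the cryo-EM structure are out of scope;
published such calculations run several-fold higher than the
measurement-derived potentials, which is precisely why the analytic model
is kept separate and auditable.

## Organic-cation sizing

The vertex method computes, for every pair of vertex atoms, the
internuclear distance plus both van der Waals radii (Bondi set), and
averages over pairs; a single-vertex species degenerates to twice its vdW
radius. Two design choices were genuinely open:

- **Conformer.** Energy-minimized 3-D embeddings of flexible onium ions
  collapse to compact gauche conformers, which undershoot the accepted
  caliper diameters of these ions (tetraethylammonium ≈ 8.1 Å) by 0.5–1.3 Å.
  Chemical-drawing-tool structures, by contrast, are fully extended. The
  package therefore builds extended (all-*anti*) conformers from idealized
  internal coordinates (tetrahedral centers, standard bond lengths,
  180° torsions, natural-extension-reference-frame placement). The
  construction is exactly reproducible, so the embedding seed is accepted
  for interface stability but has no effect.
- **Vertices.** The vertex of each substituent arm is its distal tip atom —
  the terminal *anti* hydrogen of an alkyl or hydroxymethyl arm. Terminal
  heavy atoms alone cannot reproduce the accepted diameters (the terminal
  carbon of an ethyl arm sits only 2.47 Å from the central nitrogen, capping
  a three-arm mean pair distance at 7.7 Å including radii, below
  triethylammonium's 8.08 Å). Hydrogen substituents on the central atom
  count as vertices only for mono-substituted ions, where no heavy-arm pair
  exists.

With these choices the panel spans methylammonium (4.5 Å) to
tetrabutylammonium (12.0 Å), with triethylammonium at 7.96 Å,
tetrapropylammonium at 9.91 Å and tetrakis(hydroxymethyl)phosphonium at
8.10 Å. Permeation is classified from relative current at −80 mV
(test cation / Na⁺) with a 2% leak threshold; the relative-current values
shipped with the package are a synthetic stand-in (the measured values exist
only graphically), but the permeant/impermeant split they encode is the
reported one. The cutoff — the largest permeant diameter — is a *lower
bound* on the pore diameter: a permeant blocker can carry little current for
reasons other than size, and the bracketing impermeant diameter (9.9 Å) is
reported alongside. N-methyl-D-glucamine illustrates why the bound is
one-sided: extended, it measures ~11.8 Å here, yet flexible chains make its
effective size conformation-dependent, and different embedding conventions
put it anywhere between ~9 and ~12 Å. Mutant panels (a smaller cutoff for
D915E, a much larger one for D915A) are represented only qualitatively by
their fixtures; their printed panels are graphical and are not encoded as
quantitative truths.

## Problem sizes and reproducibility

The packaged analyses and tests use 40–200 sweeps per condition (0.2–0.3 s
each at 10 kHz), 50-replicate identifiability checks for the block fit, and
five-concentration block families on a 2 mV voltage grid — sizes at which
every stochastic recovery sits several standard errors inside its tolerance
while the whole suite runs in well under a minute. All randomness flows
through explicit integer seeds into a private RNG stream that restores the
caller's state; identical (fixture, protocol, seed) triples reproduce
identical traces, and the pipeline writes a config hash into every output
table.

## Known limitations

- Two-state gating with per-opening sub-level choice is a statistical,
  not mechanistic, model; whether the two conductance levels are sub-states
  of one channel or distinct populations is left open, and dwell-time
  analyses are out of scope.
- Exact event counts are not a validation target — they depend on search
  conventions — only amplitudes and conductances are.
- K_D(0) from a single noisy block family is soft (±20%); conclusions about
  affinity fold changes should rest on replicate families.
- The permeation classifier trusts its relative-current inputs; it flags
  known blockers but cannot detect block it is not told about.
- The screened-Coulomb model assumes point charges, a uniform dielectric
  and linear superposition; it is a consistency check on measured
  potentials, not a substitute for structure-based electrostatics.
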