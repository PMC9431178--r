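---
title: "Stereochemistry enumeration and NMR fingerprint matching for cyclic lipodepsipeptides"
author: "clipmatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stereochemistry enumeration and NMR fingerprint matching for cyclic lipodepsipeptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clipmatch)
```

## The problem

Cyclic lipodepsipeptides (CLiPs) from *Pseudomonas* are nonribosomal
oligopeptides of 8–25 residues, N-acylated by a fatty acid and partly
cyclized through an ester bond between the C-terminal carboxyl and an
upstream side-chain hydroxyl (Ser/Thr). Many residues are d-configured,
produced by dual condensation/epimerization (C/E) domains of the NRPS
assembly line. Full structure elucidation routinely stalls at the
stereochemistry: Marfey's analysis of the total hydrolysate yields d/l
*counts* per amino acid but destroys positional information, so any amino
acid occurring more than once with both configurations ("configurational
heterogeneity") leaves a combinatorial set of candidate diastereomers.

`clipmatch` implements the two halves of the workflow that resolves such
dead-ends:

1. **Constraint-based enumeration.** Combine the Marfey counts with the
   hard constraints implied by the NRPS condensation-domain architecture to
   enumerate exactly the admissible diastereomers.
2. **HSQC (C–H)α fingerprint matching.** Decide identity between a
   compound and references by quantitative comparison of the
   ¹H-¹³C HSQC cross-peaks of the backbone Cα–Hα groups (plus the
   fatty-acyl CHβ), which are exquisitely sensitive reporters of local
   stereochemistry: a single d/l inversion visibly displaces the nearby
   cross-peaks.

## The (l:m) classification

`classifyLM()` labels a CLiP by its total residue count $l$ and macrocycle
size $m = l - p + 1$, where $p$ is the ester-donor position. The macrocycle
includes both the donor and the C-terminal residue; bananamides are (8:6),
orfamides (10:8), xantholysins (14:8).

```{r}
classifyLM(bananamideSWRI103()$sequence)
```

## Configuration prediction and the soft/hard asymmetry

With modules indexed 1..$l$ (module 1 carries the fatty-acid-loading
Cstart domain), residue $i$ is predicted **d** when module $i+1$ carries a
C/E domain and **l** when it carries an LCL domain; the final residue is
always l. The central modeling commitment is an asymmetry in how far these
predictions can be trusted:

* A **C/E domain's epimerization can be cryptically inactive**, so
  d predictions are *soft* — overridable by Marfey evidence.
* An **LCL domain has no epimerization machinery at all**, so the residue
  preceding it — and the final residue, which no downstream module can
  touch — are *hard* l constraints (`hardConstraints()`).

```{r}
arch <- bananamideSWRI103()$architecture
predictConfigs(arch)
hardConstraints(arch)
```

Enumeration (`enumerateCandidates()`) distributes each class's d/l budget
over its free positions (those not fixed by unique occurrence, prior
knowledge, or hard constraints), giving
$\prod_c \binom{n_{\mathrm{free},c}}{d_{\mathrm{free},c}}$ candidates.
On the three benchmark systems this reproduces the published funnel:
bananamide 6 → 3, orfamide 8 → 2, xantholysin 50 → 15. Once the true
structure is settled, `inferInactiveEpimerization()` reads off which C/E
modules must be epimerization-inactive (modules 5, 2 and {2, 7}
respectively).

Decisions taken where the design was genuinely open:

* **Glx merging.** Acid hydrolysis converts Gln to Glu before Marfey
  derivatization, so Glu/Gln positions are pooled into one `"Glx"` class
  whenever the constraint carries that class; nothing is merged silently.
* **Ratios vs counts.** Printed d:l ratios convert to integer counts via
  `ratioToCounts()`, which flags splits that do not reproduce the ratio
  exactly (e.g. 2:1 over five positions) and warns; explicit integer
  counts always take precedence. The xantholysin leucine budget is
  therefore encoded as the explicit 2 d : 3 l of the elucidated structure.
* **allo handling.** d-*allo* labels (aThr) count within the d budget and
  are carried through for display; they are configuration labels on the
  parent code, not separate residue codes.
* **Ordering and naming.** Output is sorted lexicographically by config
  string for reproducibility. When exactly one class remains heterogeneous
  over its free positions, candidates get the field's "(l:m)-Lx" names
  (position(s) of the elusive l residue); otherwise the config string is
  the name.
* **The fatty-acid C3 center** is not part of the enumeration (it is
  assumed R, the rule for *Pseudomonas* CLiPs); it is a separate attribute
  probed by fingerprint matching.

The xantholysin domain architecture encoded in `xantholysinBW11M1()` is a
reconstruction: the elongation modules are C/E except modules 12 and 13
(LCL), the unique assignment consistent with the elucidated structure's
forced-l set {11, 12, 14} and inactive modules {2, 7}. The genome
annotation itself lives in the primary genome reports and is consumed
here as given, per the package's scope (no A-domain or C-domain calling
from sequence data).

## Fingerprint matching

Two fingerprints recorded under compatible conditions (identical solvent,
temperature within ±2 K — chemical shifts are not transferable across
solvents, so cross-condition comparisons return verdict `incomparable`
rather than a number) are compared as follows:

1. **Pairing.** Fully assigned peak sets pair by label; otherwise a
   minimum-total-cost one-to-one assignment under the composite distance
   is used (weighted bipartite matching; verified against the exhaustive
   permutation minimum in the tests). Peaks are put in canonical
   (δC, δH) order first, so results are invariant under input permutation
   and cost ties break deterministically.
2. **Composite distance.** Per pair,
   $d = \sqrt{\Delta\delta_H^2 + (w_C\,\Delta\delta_C)^2}$ with
   $w_C = 0.25$ by default — the standard composite chemical-shift
   perturbation form, reflecting that ¹³C Cα dispersion is roughly four
   times the ¹H one.
3. **Verdict.** `match` iff every peak is paired and no pair exceeds the
   overlap threshold (default 0.025 ppm composite, about an HSQC
   linewidth/digital resolution); `mismatch` when at least
   `mismatchMinPeaks` (default 1) pairs exceed it; `ambiguous` otherwise.
   Optional global offset correction (subtract the median Δδ per axis
   before scoring, applied offsets reported) is off by default and exists
   for literature shift tables with different referencing conventions.

`screenLibrary()` ranks a reference library by verdict class then rmsd and
decides `known` / `novel` / `inconclusive`. Skipped
(condition-incompatible) records are always reported, and a "novel"
decision reached while references had to be skipped is downgraded to
`inconclusive`. A query matching a stereochemically elucidated reference
inherits its configuration string — dereplication settles stereochemistry
without any new chemistry.

## The synthetic fingerprint generator

No deposited experimental peak lists accompany the benchmark systems, so
validation uses simulated assigned fingerprints whose *decision-relevant
statistical structure* mimics real (C–H)α fingerprints; the absolute
simulated shifts are not claimed to approximate real CLiP spectra.

Each residue's peak sits at a per-code random-coil-style base position
(only *differences* carry information, so the base table is a documented
free choice), displaced by

* a **deterministic stereo term**: a seeded, counter-based hash of the
  residue's local environment — codes and configurations within
  `window` (default 1) residues, plus the fatty-acyl C3 configuration for
  residues near the N-terminus — mapped to uniform deviates in [−1, 1]
  and scaled by `stereoEffect` (defaults 0.4 ppm ¹³C, 0.08 ppm ¹H, the
  order of magnitude of the "prominent" shifts a d/l inversion causes).
  The hash uses fixed-precision integer arithmetic, so the perturbation
  field is bit-reproducible across platforms and touches no global RNG
  state. Locality is exact by construction: inverting one center displaces
  only peaks whose window covers it.
* **Gaussian measurement noise** (`noise`, seeded separately per
  simulated spectrum).

**Noise calibration.** The defaults are σ = 0.01 ppm (¹³C) and 0.002 ppm
(¹H), the reproducibility of peak positions on re-measurement of the same
sample on the same instrument with careful referencing. This calibration
is load-bearing: with both query and reference noisy, per-pair composite
differences are ~Rayleigh with scale
$\sqrt{2}\sqrt{\sigma_H^2 + (w_C \sigma_C)^2} \approx 0.0045$ ppm, putting
the 0.025 ppm overlap threshold at ≈ 5.5 of these units, so a same-stereo
re-simulation of a 15-peak fingerprint passes with probability
≈ 1 − 4·10⁻⁶, while a single d/l inversion (effect 16–40× the noise)
pushes at least one affected peak over threshold with probability
> 0.997 even in the worst two-affected-peak geometry. A substantially
noisier setting (e.g. σ_H ≈ 0.008 ppm, as for spectra referenced only
loosely) would make the per-peak false-alarm rate ~15% and destroy match
reliability at this threshold — that regime calls for offset correction
and a relaxed threshold, not for pretending the defaults cover it.

`makeFixtureBundle()` packages, per benchmark system, the constrained
candidate set, a simulated reference library (one fingerprint per
candidate, each under its own noise seed) and a simulated "natural" query
from the elucidated structure. What passing recovery tests show is that
the matching machinery separates diastereomers whose spectral differences
exceed measurement noise by an order of magnitude — they do not show that
real CLiP diastereomers always separate this cleanly (real effect sizes
vary per site, conformational effects can amplify or mute them, and real
spectra add overlap and artifacts the generator does not emulate).

## Numerical choices and degenerate inputs

* Shift plausibility windows: δH ∈ [−2, 12] ppm, δC ∈ [0, 220] ppm;
  violations are row-level errors carrying the line number, and parsers
  never silently drop rows.
* Round-trips (peak lists, shift tables, library JSON) are exact to
  1e-4 ppm (writers emit 4 decimals).
* Zero paired peaks (disjoint label sets) give `rmsd = NA`, coverage 0 and
  verdict `ambiguous`, never a crash; an empty library screens to `novel`
  with an explicit warning.
* Enumeration with an empty Marfey constraint is legal when every position
  is already determined (one candidate); unknown positions without counts
  are an error naming the class, as are budgets that conflict with hard
  constraints.
* `ratioToCounts()` ties (e.g. 1:1 over an odd class) resolve to the
  smaller d count, documented and deterministic.

## Problem sizes used in the validation suite

The test suite runs the full enumeration oracle (a 2^l brute-force filter)
on all three benchmark systems (l up to 14) and on 50 random instances
with l ≤ 12; assignment optimality is verified exhaustively for up to 7
unlabeled peaks; recovery statistics use 200 noise seeds per system.
These sizes keep the whole suite under a minute on one CPU while leaving
the oracles exact rather than sampled.

## Known limitations

* The quantitative similarity statistic is this package's own composite
  form; report fields are structured so an alternative statistic can sit
  alongside without breaking the schema.
* No re-referencing across solvents or temperatures is attempted — ever.
  Dereplication across conditions requires re-measurement, not modeling.
* No A-domain substrate prediction, no BGC parsing, no a priori prediction
  of *which* C/E domains are inactive (only post hoc inference), no
  atom-level molecular graphs, and no MS beyond the neutral monoisotopic
  formula-mass utility (`monoisotopicMass()`), which deliberately reports
  the neutral mass only and leaves adduct arithmetic to the caller.
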