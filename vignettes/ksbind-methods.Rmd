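---
title: "Methods: native-contact stability, patch classification, and energetic decomposition in ksbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: native-contact stability, patch classification, and energetic decomposition in ksbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ksbind)
```

## The scientific problem

Type II polyketide synthases elongate a poly-β-ketone chain tethered, via a
phosphopantetheine arm, to an acyl carrier protein; the ketoreductase (KR)
then reduces one specific carbonyl. How a KR recognises intermediates of
different chain lengths — and whether the pantetheine arm and its phosphate
are required for binding at all — is a question usually probed by docking
and molecular-dynamics (MD) simulation of KR–ligand complexes. Two residue
clusters on the KR surface act as opposite entrances of the substrate
channel: a *front-patch* of arginines (R38, R65, R93 in ActKR numbering)
that grips the phosphopantetheine phosphate, and a *back-patch*
(Q149, R220, N260).

`ksbind` implements the analysis layer of such a study as a reusable,
tested pipeline: a framewise native-contact **stability score** for MD
trajectories; classification of docking poses against the two patches;
MM-PBSA energy decomposition with framewise correlation; and grouped
Welch-test comparisons with the conventional significance-star scheme. It
does **not** run MD, docking, or a Poisson–Boltzmann solver — those
artifacts are inputs — and ships seeded synthetic generators so the whole
pipeline is exercisable without them.

## The stability score

For a trajectory with frames $t = 0, 1, \dots$, let $N$ be the set of
*native pairs*: receptor–ligand heavy-atom pairs $(i, j)$ with
$\lVert x_i - x_j \rVert \le c$ in the reference frame ($c = 7$ Å by
default). The stability score of frame $t$ is

$$\mathrm{SS}(t) \;=\; \frac{\lvert \{ (i,j) \in N : \lVert x_i(t) - x_j(t)
\rVert \le c \} \rvert}{\lvert N \rvert}.$$

$\mathrm{SS}$ lies in $[0, 1]$, equals 1 at the reference frame by
construction, and decays to 0 as the ligand leaves its original site. Three
choices here were genuinely open, and we fixed them as follows:

* **Cross pairs only.** The score measures the stability of the
  receptor–ligand interaction; intra-molecular pairs are excluded because
  they would dilute the signal with internal packing that never breaks.
* **Closed boundary.** "Within $c$" is read inclusively ($\le$) for both
  the reference and subsequent frames. The choice only matters on a
  measure-zero set of configurations, but fixing it makes the brute-force
  oracle comparison in the tests exact rather than approximate.
* **Reference frame = first analysed frame.** Whether one anchors on the
  minimised structure or the first production frame is a modelling choice;
  we use the first frame of whatever trajectory is analysed, and expose
  `reference_frame` for re-analysis of windows.

Frame indices are 0-based in all outputs (frame 0 = reference, time 0 ns),
matching MD snapshot conventions; the default `frame_interval_ns = 1`
corresponds to snapshots extracted every nanosecond.

### Window extraction, replicate selection, exit detection

All statistics run on the *production window*, the suffix starting at
$\lfloor f \cdot n \rfloor$ with $f = 0.5$ — the last 100 ns of a
200-frame/200-ns trajectory. The floor rule makes odd-length windows
deterministic (7 frames at $f = 0.5$ → frames 3..6).

Among replicate trajectories of one complex, energetic analysis uses the
replicate with the highest window-mean SS; exact ties go to the lowest
index with a message, so reruns are reproducible.

A ligand "exit" is qualitative in visual trajectory inspection; we
operationalise it as SS staying below 0.1 for 10 consecutive frames
(both configurable). Short dips that recover are not exits. `detect_exit()`
returns the 0-based frame where the sustained sub-threshold run begins, or
`NA`.

### Numerical guards

No periodic-boundary imaging is performed; inputs are assumed imaged,
whole molecules. As a tripwire for wrapping artifacts, ligand atom pairs
bonded in the reference frame (≤ 2 Å) that stretch by more than 3 Å beyond
their reference length trigger a one-time warning. The stretch is measured
relative to the reference length rather than against a fixed absolute
bond-length bound because the package's own synthetic jitter (below) moves
atoms independently: thermal-scale jitter on a 1.4 Å bond can cross an
absolute 3 Å bound occasionally, while a +3 Å jump in a single frame is
the signature of a wrapped coordinate in any realistic input.

## Patch classification

The study this pipeline supports classified docking poses by visual
assessment; `ksbind` replaces that with a reproducible rule. Each pose is
reduced to a reference point — the first phosphorus atom when present
(the phosphate anchors the observed front-patch interaction), else the
heavy-atom centroid with a warning — and labelled with the nearer patch
centroid provided that distance is within `threshold_A` (default 8 Å);
otherwise `other`, which also absorbs exact ties (< 1e-6 Å). `other`
deliberately lumps together low-frequency and interface-buried sites
rather than enumerating them. Percentages are reported to one decimal
place, the field's reporting precision. The 8 Å threshold cannot be
validated against published percentages without the co-crystal
coordinates, which are not deposited; it is therefore a configurable
surrogate, and the shipped `inst/extdata/patches.yaml` carries the patch
residue lists exactly as published.

## Energetic decomposition

From per-frame MM-PBSA output the package computes

$$\Delta G_{vdw} = \mathrm{VDWAALS} + \mathrm{ENPOLAR}, \qquad
\Delta G_{ele} = \mathrm{EEL} + \mathrm{EPB}, \qquad
\Delta G_{total} = \Delta G_{vdw} + \Delta G_{ele},$$

all in kcal/mol. EPB and ENPOLAR are parsed, never computed: a PB solver
is out of scope, and any TOTAL column in the input is ignored and
recomputed (derived fields are never trusted from input). Framewise
Pearson correlations between components use the standard product-moment
test (two-sided, $n-2$ df); by default they run over the same production
window as the t-tests, since the source analyses do not state otherwise.

The bundled Lennard-Jones + Coulomb calculator is a desk-scale stand-in
for the molecular-mechanics *cross* terms only, so the decomposition
pipeline can be exercised end-to-end on synthetic structures:
Lorentz–Berthelot combining, hard truncation at 10 Å (no switching
function — the aim is a clean testable contract, not reproducing a
production force field), Coulomb constant 332.0637 kcal·Å/(mol·e²) and
vacuum dielectric. Pair distances below 0.1 Å raise an "atomic clash"
error rather than overflowing. The internal dielectric of 4 used by
PB-stage calculations in charged active sites applies to a stage this
package does not implement and is carried as config metadata only.

## Grouped statistics

The test family for window comparisons is Welch's unequal-variance,
two-sided, unpaired t-test: replicate windows have no natural pairing and
equal variances are not guaranteed across KR types. A pooled Student
variant sits behind `var_equal = TRUE`. Degenerate inputs follow fixed
conventions: two identical constant samples give $p = 1$ (no evidence of a
difference); two different constant samples are an error. Cells with fewer
than two values are skipped with a warning.

Stars follow the conventional scheme — `ns` for $p > 0.05$, then `*`,
`**`, `***`, `****` at $p \le 0.05, 0.01, 0.001, 0.0001$, boundaries
inclusive toward more stars. No multiple-testing correction is applied by
default, matching per-panel star reporting; Benjamini–Hochberg is
available behind `p_adjust = "BH"`.

Framewise values within one trajectory are autocorrelated; treating frames
as observations nevertheless follows the field's convention and is the
default. `block_average()` provides a conservative pre-step for users who
want effective-sample-size protection, and the grouping default pools
production-window frames across all replicates per cell (the alternative —
only the representative replicate — is available by filtering the input
data frame).

Ligand codes parse as `[m-]{tet|oct}[-p|-pp]`: `m` = isoxazole mimic,
`tet`/`oct` = tetra-/octaketide body, `p`/`pp` =
pantetheine/phosphopantetheine arm; unknown codes are rejected rather than
guessed.

## What the synthetic generators emulate — and what they do not

The generators reproduce the *statistical structure* the analysis layer
assumes, at the study's stated scale (200 frames × 1 ns, triplicates,
200-pose sets):

* **Bound trajectories**: rigid receptor, each ligand atom redrawn per
  frame as initial + isotropic Gaussian (default σ = 0.5 Å); frame 0 is
  the initial structure exactly.
* **Unbinding trajectories**: bound behaviour until `exit_frame`, then a
  linear drift along a fixed random unit vector (default 1 Å/frame). At
  that rate every ≤ 7 Å native pair is cleared within ~15 frames of the
  switch.
* **Energy tables**: $(\Delta G_{vdw}, \Delta G_{ele})$ drawn from a
  bivariate normal. Means come from the term means (defaults −40, −5,
  −30, +60 kcal/mol, i.e. $\Delta G_{vdw} = -45$, $\Delta G_{ele} = +30$);
  component sds default to (10, 2), making the packing term dominate the
  variance of the total, which is the regime the correlation-ordering
  analysis probes. Optional correlation targets are solved through the sum
  constraint $\sigma_t = r_{vt}\sigma_v + r_{et}\sigma_e$; mutually
  consistent targets (satisfying
  $(r_{vt}\sigma_v)^2 - (r_{et}\sigma_e)^2 = \sigma_v^2 - \sigma_e^2$) are
  matched exactly, inconsistent ones to first order, and targets implying
  a non-positive-definite covariance raise an error reporting the
  determinant. The four terms are back-filled by fixed splits
  (VDWAALS:ENPOLAR = 9:1; EEL = $\Delta G_{ele}/2 - 45$,
  EPB = $\Delta G_{ele}/2 + 45$, sign-opposed) so tables round-trip
  through parsing and decomposition.
* **Pose sets**: counts per label follow the weights *deterministically*
  (largest remainder), so a 200-pose set at weights (0.01, 0.98, 0.01)
  always tabulates to 1.0 % / 98.0 % / 1.0 % — the generator's stated job
  is to emulate printed frequencies, and leaving the counts multinomial
  would make that reproduction a coin flip. Patch-pose offsets are drawn
  from an isotropic Gaussian truncated at 4σ, so a pose generated *for* a
  motif always lies in that motif's region (with the default σ = 2 Å the
  truncation radius coincides numerically with the default 8 Å acceptance
  threshold, but it is defined generator-side as 4σ). "Other" poses are
  placed uniformly 15–30 Å from both centroids.

None of this is physically realistic dynamics: there is no internal
protein motion, no explicit water, no force-field energetics behind the
trajectories, and the jitter model does not preserve bond lengths. Passing
tests therefore demonstrate that the *analysis* is correct — the scoring,
windowing, classification, decomposition and testing machinery — not that
any biological conclusion transfers to real systems. Analyses of real MD
output exercise exactly the same code paths through the multi-model-PDB
and CSV readers.

## I/O conventions

The canonical trajectory dialect is multi-model PDB: self-contained,
plain-text, testable without binary fixtures (binary formats can be
converted externally). Residue numbering is preserved exactly as printed
— patch definitions cite crystal-structure numbering. Hydrogens are read
and retained; heavy-atom filtering happens downstream, keeping I/O
lossless. Blank element columns are inferred from atom names (standard
residues: first letter after stripping digits; hetero residues: known
two-letter symbols first). Energy tables are comma-, tab- or
whitespace-delimited with case-insensitive headers; no unit conversion is
applied (kcal/mol assumed, as emitted by MM-PBSA post-processors). The
per-frame CSV contract is this package's normalisation — MM-PBSA tools do
not share a single on-disk format.

## Problem sizes and determinism

The test suite runs its property checks at deliberately small scale —
random systems of ≤ 30 atoms and ≤ 20 frames against brute-force oracles,
200-frame trajectories for the definitional and exit-recovery checks, 100
seeded tables for the correlation-ordering property, 1000 replications
for type-I-error control — sizes at which the oracles are exact and the
whole suite completes in seconds. Every stochastic step is seeded;
generators are pure functions of (spec, seed), and the demo pipeline's CSV
outputs are bit-identical across reruns with the same configuration.

## Known limitations

* The patch-membership threshold is a surrogate for visual assessment and
  is not validated against undeposited co-crystal structures.
* Frame-level inference ignores autocorrelation unless block averaging is
  requested; no mixed-effects alternative is provided.
* The LJ/Coulomb stand-in truncates hard at the cutoff and omits
  long-range electrostatics; it is not comparable to production MM
  energies.
* Entropy corrections to binding free energies are out of scope, as in
  the analyses this package reproduces.
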