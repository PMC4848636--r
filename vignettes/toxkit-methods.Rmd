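---
title: "Methods behind toxkit: tight-binding kinetics, channel block and Kunitz motif analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind toxkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxkit)
```

toxkit packages the quantitative workflow used to characterize dual-function
Kunitz/BPTI-type peptides — sea-anemone proteins that simultaneously inhibit
serine proteases and block Shaker-family voltage-gated potassium (Kv1)
channels. This vignette is the package's own account of the models it fits,
the conventions and defaults it adopts, what its synthetic data do and do not
emulate, and the known limitations.

## Tight-binding inhibition kinetics

### The Morrison model

Classical steady-state inhibition analysis assumes free inhibitor ≈ total
inhibitor. For inhibitors with $K_i$ in the nanomolar range assayed at
nanomolar enzyme, that assumption fails: a substantial fraction of the
inhibitor is bound. Solving the 1:1 binding equilibrium with explicit mass
balance gives the quadratic (Morrison) expression for the fractional
activity,

$$
\frac{v_i}{v_0} \;=\; 1-\frac{\left(E_0+I_0+K_i^{app}\right)-
\sqrt{\left(E_0+I_0+K_i^{app}\right)^2-4E_0I_0}}{2E_0},
$$

implemented by `morrison_fraction()`. Numerically the textbook form cancels
catastrophically when the fraction is small, so the implementation evaluates
the algebraically equivalent expression $2K_i^{app}/(q+c)$ with
$c=I_0+K_i^{app}-E_0$ and $q=\sqrt{c^2+4E_0K_i^{app}}$ whenever $c\ge 0$.
The test suite pins this against an independent bisection solver of the
binding polynomial over six decades of each parameter; agreement is at
machine precision, far inside the 1e-8 relative bound asserted.

`fit_morrison()` estimates a single parameter, $K_i^{app}$, by unweighted
nonlinear least squares (Levenberg–Marquardt via minpack.lm, bounded
positive), with the total enzyme concentration fixed at its independently
titrated value — co-fitting $E_0$ is available as a diagnostic flag but is
not the default, because $E_0$ is measured, not inferred. The initial guess
is the interpolated inhibitor concentration at half activity (falling back
to the median of the grid); for a one-parameter monotone model this is
robust across the $K_i^{app}/E_0$ range of 0.01–100 exercised in the tests.

Curves with all activities ≈ 1 raise "no inhibition detected" rather than
returning an unconstrained estimate, and a curve that never drops below 0.8
keeps its fit but carries an explicit warning.

### Substrate correction and classification

Assays are run at finite substrate, so the fitted constant is apparent.
Under a purely competitive mechanism
$K_i = K_i^{app} / (1 + S_0/K_M)$, implemented by `correct_ki()`. The
competitive assumption is recorded in every `ki_result()` row rather than
silently applied. A missing $K_M$ is an error — returning the uncorrected
value silently would bias every downstream classification. The operational
tight-binding definition, $K_i \le 10^{-7}$ M with an inclusive boundary, is
`classify_tight_binding()`.

### Titration and reversibility

Active-site titration (`fit_titration()`) assumes the stoichiometric regime
$[E_0]/K_i \ge 100$: activity declines linearly to zero at the equivalence
point. The active concentration is the x-intercept of a least-squares line
through the points with fractional activity in [0.15, 0.85] — the default
window trims both the curved toe near the equivalence point that appears
when the regime is only approximate, and saturated points. Below the ratio
of 100 the result is still returned but carries a validity warning.

`assess_reversibility()` encodes two qualitative diagnostics: fractional
activity must increase with substrate (0.5, 1, 2 × $K_M$) by more than 2
percentage points per step, and must be stable across preincubation times
within 5 percentage points. The defaults exceed typical triplicate
spectrophotometric noise and are configurable. A series still falling with
preincubation time is classified "equilibrium_not_reached" before any
substrate-competition claim is made.

## Kv-channel block and gating

Percent block is $100(1 - I_{toxin}/I_{control})$ from steady-state currents
at a fixed test potential; values outside [0, 100] are clamped with a
warning rather than propagated. Concentration–response data are fitted with
the Hill equation

$$ y = \frac{100}{1+\left(\mathrm{IC}_{50}/[\mathrm{toxin}]\right)^h}, $$

with $h$ free by default (`fix_h = 1` reproduces a one-site fit). Curves
whose plateau never reaches 50% block are flagged "extrapolated" instead of
failing, because screening data frequently stop below half-block.

Gating analysis converts IV series to conductance through the ohmic driving
force $G = I/(V-E_{rev})$, excluding points within 5 mV of the reversal
potential where the quotient is ill-conditioned, and fits the Boltzmann
$G = G_{max}/(1+\exp((V_{1/2}-V)/k))$. The reversal potential is taken from
the recording solutions when known (−90 mV for potassium under standard
low-K bath) or interpolated from the control IV zero-crossing.
`compare_v_half()` applies a paired two-sided t test to replicate midpoints;
"no shift" at $p \ge 0.05$ supports pore occlusion over gating modification.
`voltage_dependence_of_block()` calls block voltage independent when the
spread of mean block across a grid spanning at least 40 mV stays within 5
percentage points (roughly run-to-run two-electrode voltage-clamp
variability at $n \ge 3$) or a linear trend test is non-significant.

## Kunitz framework motifs and compensated substitutions

The Kunitz/BPTI fold carries six framework cysteines (Cys I–VI). Toxins of
this fold that block Kv channels show two short sequence windows flanking
them: an N-terminal window [Xa−2 Xa−1 CysI Xa+1 Xa+2 Xa+3] and a C-terminal
window [CysV Xb+1 Xb+2 Xb+3 CysVI]. `find_cysteine_framework()` requires
exactly six alignment columns with cysteine conservation ≥ 0.9 (configurable
above 0.5); a record lacking a cysteine at a framework column is flagged
individually instead of failing the whole alignment.

Windows are extracted in each record's own ungapped coordinates anchored on
its own cysteines, not on alignment columns. This is deliberate: an
insertion between Cys V and Cys VI then produces an explicit per-record
"non-canonical C-window" flag rather than silently misassigned residues.
Published (UniProt-style) residue numbers are reproduced through per-record
numbering offsets.

Profiles use four physicochemical classes — negative (D, E), positive
(K, R, H), polar uncharged (S, T, N, Q, C, Y), hydrophobic (G, A, V, L, I,
P, F, M, W). Histidine is grouped with the positives (treated as protonated
at the relevant interfaces) and proline and glycine with the hydrophobics;
the mapping is a single replaceable table (`RESIDUE_CLASSES`). Unknown
letters map to an explicit "unclassifiable" marker that can never support a
match.

Only fully solvent-exposed positions enter profiles: relative accessibility
strictly greater than 50%, or, when no accessibility table is available, the
canonical exposed set {Xa−2, Xa+1, Xa+3, Xb+1, Xb+2} with its provenance
recorded. The buried/partially exposed positions (Xa−1, Xa+2, Xb+3 and the
cysteines themselves) are carried in reports but never compared.

`detect_compensation()` compares two profiles per window: identical when the
class vectors agree; compensated when every class change is matched by the
reciprocal change at another position of the same window, i.e. the changes
decompose into class swaps and the window's class multiset is preserved;
non-compensated otherwise. Compensation is restricted to intra-window swaps
— the motivating example is the Xa+1/Xa+3 hydrophobic/positive exchange
between dendrotoxin paralogs — and substitution sets that preserve the
class multiset only across windows are reported as a note without softening
the verdict. The overall verdict is the worse window.

`group_specificities()` offers both readings found in the literature on
equivalent-position conservation: strict mode groups toxins with identical
exposed class vectors; compensated mode (default) also links compensated
pairs. The pairwise compensated relation is not transitive (a chain of
single swaps can accumulate a class 3-cycle), so groups are its transitive
closure and a closure that merges a non-compensated pair is flagged and
warned about rather than hidden.

## Solvent accessibility from coordinates

`shrake_rupley()` implements sphere-sampling accessibility: each heavy atom
is expanded by the probe radius (default 1.4 Å, water) and sampled with a
golden-spiral point set (default 960 points — deterministic, quasi-uniform);
the accessible fraction times the expanded-sphere area is the atom's ASA.
Defaults were chosen once as field-standard values. The per-atom error
against closed forms is below 0.5% at 960 points for an isolated sphere and
below 1% for overlapping pairs (spherical-cap oracle), and totals change by
under 1% when the point count is quadrupled.

Relative accessibility (`relative_asa()`) divides a residue's ASA in the
full structure by the ASA of the same residue extracted alone in its
observed conformation — a residue "in a vacuum". An alternative convention
normalizes by the residue in an extended Gly-X-Gly tripeptide; the isolated
residue reading was adopted as the closest literal reading of a
vacuum-reference definition, and the convention is written into the result
attributes so externally computed tables under other conventions can be
substituted deliberately. Fully exposed means strictly above 50%.

`interatomic_contacts()` lists atom pairs from different residues within a
cutoff (default 4.0 Å, heavy atoms), labelled backbone/side-chain by atom
name (N, CA, C, O are backbone). It is validated against a naive O(n²) scan.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the statistical structure the analyses assume, at
the designs under which the original measurements were made:

* `gen_morrison_curve()` — 12-point curves at an enzyme-to-Ki ratio of 10,
  log-spaced inhibitor grid including zero, 2% multiplicative noise by
  default;
* `gen_titration()` — linear decline to a sharp equivalence point, then
  zero;
* `gen_dose_response()` — 8 log-spaced concentrations over 2 decades
  centred on the IC50, 5% multiplicative noise by default;
* `gen_gv_family()` — Boltzmann-gated ohmic currents over −40..+40 mV in
  10-mV steps from a −90 mV reversal potential, toxin series scaled
  uniformly (voltage-independent block by construction);
* `gen_kunitz_msa()` — ungapped alignments with a planted six-cysteine
  framework, planted window classes, swap-compensated and single-change
  variants, a consistent accessibility table, and the intended groupings as
  ground truth.

Multiplicative (signal-proportional) Gaussian noise was chosen because
photometric rate errors and voltage-clamp current errors both scale with
signal. Every generator takes a mandatory seed, is bit-reproducible, and
leaves the caller's RNG stream untouched.

What passing tests on these data do **not** show: real inhibition curves can
contain slow-binding drift and substrate depletion; real oocyte recordings
have leak, rundown and series-resistance artifacts that the steady-state
summaries here deliberately do not model; and real toxin alignments contain
indels, truncated termini and phylogenetic correlation, none of which the
planted-truth alignments imitate. The motif machinery is exercised on real
indel behaviour only through its explicit flag paths.

## Numerical choices and degenerate inputs

* All fits use Levenberg–Marquardt with positivity bounds on scale
  parameters; non-convergence returns a flagged object (`converged =
  FALSE`) rather than an error, so batch analyses can proceed.
* Zero-noise round trips recover generating parameters to better than 1e-6
  relative for $K_i^{app}$, IC50, $h$, $V_{1/2}$, $k$ and the titrated
  active concentration.
* Interval calibration: ±2·SE intervals cover the generating $K_i^{app}$ in
  ≈ 99% of seeded 2%-noise replicates (tested). For the multi-parameter
  Hill and Boltzmann fits under signal-proportional noise, unweighted
  least-squares standard errors are anticonservative (measured coverage
  ≈ 0.88 for IC50 and far lower for $V_{1/2}$, where normalizing by the
  maximum additionally correlates the points). This is a property of the
  estimator/noise-model pair, not a defect of the optimizer; point-estimate
  recovery rates (15% for $K_i$, 20% for IC50) are nevertheless met in
  ≥ 95% / ≥ 90% of replicates. Weighted fits would restore calibration but
  would depart from the unweighted fitting convention standard in this
  assay literature, so they were not adopted.
* Tie-breaks and edge rules are explicit: the tight-binding boundary is
  inclusive; the exposure threshold is strict; exactly-flat preincubation
  series count as time-stable; a titration series that never drops below
  0.9 activity has "no titration signal".

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
the sizes stated above: 200-replicate noise studies for the calibration
properties, 100 seeded alignments for planted-truth recovery, 100 random
clusters for the contact oracle, and 960-point accessibility sampling.
These sizes were chosen as the smallest at which the Monte-Carlo acceptance
rates are stable to re-seeding.

## Known limitations

* Kinetics: no progress-curve or slow-binding analysis; $K_M$ is an input,
  never estimated; enzymes quantified only in activity units support only a
  qualitative no-inhibition report.
* Electrophysiology: steady-state summaries only — no kinetic modelling of
  block on/off rates and no raw-trace processing.
* Motifs: alignments are consumed, not constructed; the analysis does not
  attempt to predict potency from profiles, only to partition predicted
  specificity.
* Structure: no electrostatics, no secondary-structure assignment, no
  structural superposition; the relative-ASA convention differs from
  tripeptide-based scales and the two should not be mixed in one table.
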