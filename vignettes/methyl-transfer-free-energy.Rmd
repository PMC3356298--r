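---
title: "Methods: free-energy analysis of methyl-transfer product specificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-energy analysis of methyl-transfer product specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylpmf)
```

## The problem

SET-domain protein lysine methyltransferases transfer one, two or three
methyl groups from AdoMet to the ε-amino nitrogen (Nζ) of a target histone
lysine. Which methylation state an enzyme stops at — its *product
specificity* — is an energetic question: if the free-energy barrier of a
later transfer is much higher than that of the first, the chain stops
there. `methylpmf` implements the analysis layer of this picture: it turns
trajectory snapshots and umbrella-sampling time series into
reactive-configuration statistics, potentials of mean force (PMFs),
per-step barriers, and a mono/di/tri specificity call. The simulation
engine itself (QM/MM molecular dynamics) is outside the package; a
synthetic-data module generates statistically controlled stand-ins for its
outputs so every stage is testable end to end.

Units are fixed globally: ångström, kcal/mol, degrees, kelvin, with
k~B~ = 1.987204259 × 10⁻³ kcal mol⁻¹ K⁻¹. The default temperature is
283.15 K, the simulation temperature of the trajectories this analysis is
designed for.

## Reactive-configuration statistics

An SN2 methyl transfer is facile when the acceptor lone pair is aligned
with the donor. Per frame the package computes (see `compute_geometry()`):

* `r_cn` = r(C~M~…Nζ), the acceptor distance;
* `r_cs` = r(C~M~…Sδ), the donor distance;
* the reaction coordinate `R = r_cs − r_cn` (negative in the reactant,
  where the methyl is still bonded to sulfur; positive in the product);
* `theta`, the angle between the Nζ lone-pair direction and the
  C~M~ → Sδ vector. `theta = 0` is perfect in-line attack.

**Lone-pair construction.** The lone-pair direction is not a quantity the
input files carry, so it is constructed geometrically as
`u = −normalize(Σᵢ normalize(pᵢ − p_N))` over the three Nζ substituents
(Cε plus, depending on methylation state, hydrogens or methyl carbons).
For an ideal sp³ nitrogen this is exactly the missing tetrahedral vertex —
the three unit vertices of a regular tetrahedron sum to minus the fourth —
and it degrades gracefully under distortion. A planar nitrogen (unit bond
vectors summing to < 10⁻⁸) has no defined lone pair and raises an error
rather than returning noise. An electronic-structure definition of the
lone pair would differ slightly for distorted geometries; for
near-tetrahedral amines the two coincide, which is why the geometric
construction is used and documented rather than made configurable.

**Distributions and Boltzmann inversion.** Ensembles of (r, θ) are binned
on half-open `[low, high)` bins (last bin closed, ties on interior edges
go up) — the convention is asserted in the tests because off-by-one
binning is a classic silent error. Defaults are r ∈ [2, 6] Å in 0.05-Å
bins and θ ∈ [0°, 180°] in 5° bins, matching the granularity at which such
distributions are usually displayed; both are arguments. Free energy per
cell is `F = −k_B T ln(n/n_max)`, so the modal cell is exactly 0.
Zero-count cells are masked, never given a pseudo-count: a pseudo-count
biases exactly the sparsely sampled high-F cells one is most tempted to
read. (A `pseudocount` option exists for plotting continuity only and is
excluded from every quantitative path and test.) Marginal profiles sum
counts first, then invert.

**Hydrogen bonds.** Occupancy of, e.g., the tyrosine–Nζ or water–Nζ
hydrogen bonds uses the standard geometric criterion D…A ≤ 3.5 Å and
D–H…A ≥ 120°, both configurable, since the trajectories carry no
electronic information to do better.

## PMF estimation by WHAM

`wham_solve()` implements the standard self-consistent WHAM estimator on a
uniform grid over R (default [−2.5, 2.5] Å, 0.05-Å bins):

$$P(b) = \frac{\sum_i n_i(b)}{\sum_i N_i\,e^{(f_i - w_i(b))/k_BT}},
\qquad
f_i = -k_BT \ln \sum_b P(b)\,e^{-w_i(b)/k_BT},$$

iterated as a plain fixed point until `max |Δf_i| < 10⁻⁶ kcal/mol`
(cap 10⁵ iterations). No damping is used: at the window overlaps produced
by force constants in the 50–400 kcal mol⁻¹ Å⁻² range the plain iteration
converges in a few hundred to a couple of thousand steps. All
accumulations run in log space, so strong biases far from a window's
centre underflow harmlessly instead of poisoning the denominators.
Non-convergence is never hidden: the profile is returned with
`converged = FALSE` and a warning, and the pipeline manifest records it.

**Bias convention.** The harmonic bias is `w(R) = k (R − R₀)²` — *no* ½
prefactor, the umbrella convention of the CHARMM program whose force
constants (50–400 kcal mol⁻¹ Å⁻²) set the scale here. Because the other
convention is equally common, the prefactor is an explicit property of
every `umbrella_window()` (`half_k`), the generator stamps it on the
windows it makes, and `wham_solve()` hard-errors on a mixture rather than
silently combining incompatible biases.

**Anchoring and orientation.** The reactant (methyl on the donor sulfur)
sits at R < 0. Profiles are anchored so the reactant-side minimum is
exactly 0; a `"global"` anchor is available for degenerate cases such as
single-window checks.

**Barrier extraction.** `extract_barrier()` applies no smoothing: the
reactant state is the lowest defined bin on the reactant side, the product
state the lowest defined bin on the product side, and the transition state
the highest defined bin strictly between them. A monotone profile raises a
no-barrier error instead of reporting 0. Masked bins are skipped, never
interpolated across; a gap wider than 3 bins between reactant and TS
triggers a data-quality warning. On a 0.05-Å grid the quantisation error
of the barrier is bounded by the profile curvature at the stationary
points (a few hundredths of a kcal/mol for barriers up to ~22 kcal/mol),
which is far below the statistical noise of any realistic window set.

**Empirical correction.** Semi-empirical QM/MM energies for bond
making/breaking are often corrected against a higher-level reference;
`apply_correction()` adds a user-supplied tabulated ΔE(R) through a
monotone cubic (Fritsch–Carlson) interpolant and re-anchors. Fitting such
a curve is out of scope — the package ships only the zero curve as a
default, and refuses to extrapolate beyond the knot span. Whether
published barriers derive from raw or corrected profiles is treated as the
upstream pipeline's concern: barriers are accepted as final values, and
the correction is an explicit, visible step.

**Uncertainty.** The estimator reports no error bars by default (matching
how such PMFs are usually published); `wham_bootstrap()` provides an
optional within-window resampling diagnostic (50 resamples by default,
seeded).

## Triplets and the specificity call

Per-step barriers ΔF‡₁, ΔF‡₂, ΔF‡₃ are summarised two ways
(`compute_triplet()`):

* the **triplet**, each barrier minus the *wild-type first-step* barrier —
  the cross-enzyme summary, whose first element is exactly 0 for the wild
  type;
* the **within-enzyme deltas**, each barrier minus *that enzyme's own*
  first-step barrier — the quantity that says whether the enzyme's later
  steps are blocked relative to its first.

Both appear in all output, clearly labelled, because the two references
differ by the mutant's first-barrier shift and conflating them changes
calls near threshold. Printing is at one decimal, with missing steps shown
as `"x"` and propagated as missing, never as numbers.

`classify_specificity()` scans steps 2 then 3: the first step whose
within-enzyme delta reaches the threshold blocks (mono if step 2, di if
step 3; tri if nothing blocks across three present steps). When the set
ends before step 3 without a block, the call is the state reachable from
the present steps and is flagged `undetermined_beyond` — an
uncharacterised step is evidence of nothing.

**The threshold.** No published numeric blocking threshold exists; it is
inferred from worked examples in which within-enzyme deltas of 2.0 and 2.4
kcal/mol do *not* block while 3.6 and 8.7 do.
`specificity_threshold_band()` computes the exact interval of thresholds
consistent with a set of calls — for the three bundled enzymes it is
(2.4, 3.6] kcal/mol — and the default of 3.0 kcal/mol is the approximate
midpoint of that band. The default is a documented inference, not a
measured constant, and is a first-class argument everywhere.

## What the synthetic-data module emulates — and what it does not

`make_potential()` provides closed-form 1D potentials (harmonic, quartic
double well, piecewise cubic) with *exactly* known minima, TS and barrier:
for the quartic, the derivative is `a (R−R_a)(R−R_t)(R−R_b)`, the TS
location is solved from the barrier/offset ratio and the scale then makes
`U(R_t) − U(R_a)` equal the programmed barrier to rounding error. Default
minima are −1.4 and +1.2 Å, the S→N transfer range the reaction-coordinate
geometry implies.

`gen_umbrella_windows()` draws i.i.d. samples from the biased Boltzmann
density by inverse CDF on a dense grid (4096 cells over the declared
range, uniform within a cell). Inverse-CDF sampling was chosen over a
Langevin integrator deliberately: it has *no* timestep, friction or
autocorrelation parameters to justify, it samples the exact target
density up to grid discretisation, and it is bitwise reproducible from the
seed. The cost is realism — real umbrella time series are autocorrelated,
so real windows carry fewer effective samples than nominal ones. Passing
the recovery tests therefore shows the estimator chain is correct and
converged, not that any particular MD protocol was long enough.

`umbrella_protocol()` places 20 centres evenly between the minima and sets
each force constant to `|U′(c)| / spacing`, clipped to [50, 400]
kcal mol⁻¹ Å⁻² — soft restraints on flat regions, stiff ones on steep
flanks, which keeps adjacent windows overlapping along the whole path with
the published window count and force-constant range.

`gen_frames()` builds minimal six-atom frames (Sδ, C~M~, Nζ plus three
substituents) whose per-frame geometry equals the drawn values *exactly*:
r and θ are truncated normals (r > 1.5 Å, θ ∈ [0°, 180°]), the tetrahedral
cap is rotated so the lone pair makes exactly the drawn θ with the attack
axis, and the azimuth about that axis is uniform (θ is azimuth-invariant).
The closure `compute_geometry(gen_frames(spec)) = drawn values` to 10⁻⁶ is
the module's master invariant. Two presets ship: `reactive_wt_like`
(mean r 3.0 Å, mean θ 30°) and `nonreactive_wt3_like` (mean r 4.5 Å,
broad large-angle θ, di-methylated acceptor). The preset *means* are the
reported ensemble characteristics these presets emulate; the *spreads*
(0.15 Å / 12° reactive; 0.30 Å / 30° non-reactive) are representative
choices — published distribution panels constrain them only visually — and
must not be read as fitted values. The frames contain no protein, water or
full AdoMet, so nothing downstream of the (r, θ, R) statistics should be
inferred from them.

Truncating θ at 0° shifts the mean of a N(30°, 12°) draw to ≈ 30.2°; the
recovery tests and the acceptance script compare against this truncated
mean, not the nominal one.

## Numerical and degenerate-input choices

* Ties on interior bin edges go to the higher bin; the last bin is closed.
* WHAM gauge is fixed at `f₁ = 0`; a constant added to every bias shifts
  all `f_i` and cancels in the anchored profile (tested to 10⁻⁸).
* A window with force constant 0 is a legal unbiased window; a single such
  window makes WHAM degenerate exactly to Boltzmann inversion of its
  histogram (tested to 10⁻⁸).
* An infeasible truncated-normal spec (acceptance region < 1% of the
  distribution) errors out instead of looping.
* Empty window files, non-numeric rows (with line number), metadata/file
  count mismatches, unresolvable roles (with role and frame), and
  inconsistent atom counts each raise specific, named errors.
* Text output is locale-independent (`.` decimal); coordinates and window
  samples are written at full double precision (`%.17g`), so write/read
  round trips are exact.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen to keep
statistical tolerances meaningful: barrier-recovery checks use 20 windows
× 5000 samples at barriers 5 / 13.4 / 22 kcal/mol (recovery within ±0.3
kcal/mol), ensemble-statistic checks use 10⁴ frames (means within 3
standard errors), distribution-level identities use 10⁵ draws, and
replicate/convergence properties use 6–9 seeds at 500–5000 samples per
window. The analysis scripts under `analysis/` regenerate everything from
fixed seeds; raw samples go to `scratch/`, summary tables to `results/`.

## Known limitations

* WHAM here is 1D; free-energy surfaces in (r, θ) come from direct
  Boltzmann inversion of unbiased ensembles, not from 2D umbrella data.
* Barrier extraction does not smooth or interpolate; with very sparse
  windows the TS bin estimate is noisy, and the bootstrap diagnostic is
  the intended way to see that.
* The specificity call is thermodynamic-kinetic shorthand (barrier
  differences against a threshold); no rate theory or processivity model
  is attached.
* The synthetic generators validate the analysis chain, not any MD
  protocol: autocorrelation, incomplete equilibration and anharmonic
  solvent coupling in real data are outside what passing tests
  demonstrate.
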