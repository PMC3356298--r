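# methylpmf

Free-energy analysis of SN2 methyl transfer in protein lysine
methyltransferases (PKMTs): from trajectory snapshots and
umbrella-sampling time series to potentials of mean force, per-step
barriers, and a mono/di/tri product-specificity call.

PKMTs transfer up to three methyl groups from AdoMet to the ε-amino
nitrogen (Nζ) of a target histone lysine. Whether an enzyme stops at
mono-, di- or tri-methylation is controlled, at least in part, by the
relative free-energy barriers of the successive transfers — a later
barrier much higher than the first stops the chain. This package is for
computational chemists and structural bioinformaticians who run (or read)
QM/MM umbrella-sampling studies of such systems and want the analysis
layer — geometry statistics, WHAM, barrier calculus — as tested, reusable
code rather than one-off scripts. The MD engine itself is out of scope; a
synthetic-data module generates statistically controlled stand-ins for
its outputs, so the entire chain is verifiable without a supercomputer.

## What it computes

**Reactive-configuration statistics.** Per frame: the acceptor distance
r(C<sub>M</sub>…Nζ), donor distance r(C<sub>M</sub>…Sδ), the reaction
coordinate

> R = r(C<sub>M</sub>…Sδ) − r(C<sub>M</sub>…Nζ)

(negative in the reactant, positive in the product), and θ, the angle
between the Nζ lone-pair direction and the C<sub>M</sub>→Sδ vector
(θ = 0° is perfect in-line SN2 alignment). Ensembles become 2D (r, θ)
histograms and Boltzmann-inverted free-energy surfaces,
F = −k<sub>B</sub>T ln(n/n<sub>max</sub>), plus 1D marginals and
hydrogen-bond occupancies.

**PMF by WHAM.** Harmonically biased umbrella windows
(w<sub>i</sub>(R) = k<sub>i</sub>(R − R<sub>i</sub>)², CHARMM convention,
no ½ — switchable) are combined by the standard self-consistent WHAM
equations, iterated in log space to a 10⁻⁶ kcal/mol tolerance on the
window shifts, anchored so the reactant-side minimum is 0. Barriers are
read off without smoothing; an optional tabulated empirical correction
ΔE(R) can be applied by monotone cubic interpolation.

**Specificity calculus.** Per-step barriers are summarised as free-energy
triplets (each barrier minus the wild-type first-step barrier) and
within-enzyme deltas (each barrier minus the enzyme's own first-step
barrier). The first within-enzyme delta that reaches the blocking
threshold (default 3.0 kcal/mol) stops the chain: blocked at step 2 →
mono, at step 3 → di, never → tri. A diagnostic reports the full interval
of thresholds consistent with a set of calls.

**Synthetic data.** Analytic double-well potentials with exactly known
barriers, umbrella windows drawn by inverse CDF from the biased Boltzmann
density, and coordinate frames whose (r, θ) statistics are controlled to
the drawn values exactly — all bitwise reproducible from a seed.

## Worked example

Feed the published per-step barriers of GLP and its two active-site
mutants to the specificity calculus:

```r
library(methylpmf)

wt      <- barrier_set("WT",     c(13.4, 15.8, 22.1))   # kcal/mol
f1209y  <- barrier_set("F1209Y", c(13.8, 17.4, NA))     # step 3 not characterised
y1124f  <- barrier_set("Y1124F", c(13.9, 15.9, 13.3))

compute_triplet(wt, f1209y)
#> <triplet_result> F1209Y
#>   triplet (vs WT step 1):     (0.4, 4.0, x)
#>   within-enzyme deltas:       (0.0, 3.6, x)

classify_specificity(wt)$call       # "di"
classify_specificity(f1209y)$call   # "mono"
classify_specificity(y1124f)$call   # "tri"

specificity_threshold_band(list(wt, f1209y, y1124f),
                           c("di", "mono", "tri"))[c("lower", "upper")]
#> $lower: 2.4    $upper: 3.6
```

The triplets — (0.0, 2.4, 8.7) for WT, (0.4, 4.0, x) for F1209Y,
(0.5, 2.5, −0.1) for Y1124F — say that the wild type pays 8.7 kcal/mol
extra at the third transfer (a di-methyltransferase), F1209Y already pays
3.6 at the second (mono), and Y1124F pays essentially nothing extra
anywhere (tri). Every blocking threshold in (2.4, 3.6] kcal/mol yields
the same three calls; the default 3.0 sits mid-band.

And a full synthetic round trip — program a barrier, sample umbrella
windows, recover it by WHAM:

```r
pot     <- make_potential("quartic_double_well", barrier = 13.4,
                          r_a = -1.4, r_b = 1.2)
proto   <- umbrella_protocol(pot)            # 20 windows, k in 50-400
windows <- gen_umbrella_windows(pot, proto$centers, proto$force_constants,
                                n_per_window = 5000, seed = 1)
extract_barrier(wham_solve(windows))$barrier
#> [1] 13.3595
```

## The analysis workflow

Numbered drivers under `analysis/` rerun the whole study from seeds:

| script | what it does |
|---|---|
| `01_simulate.R` | synthetic umbrella windows for every enzyme/step (programmed with the published barriers) and the reactive / non-reactive frame ensembles; raw samples under `scratch/` |
| `02_geometry.R` | (r, θ) statistics, surfaces and marginals of the ensembles; summaries under `results/geometry_*` |
| `03_pmf.R` | WHAM + barrier extraction for every window set; `results/pmf/barriers_recovered.csv` |
| `04_specificity.R` | triplets, calls and the threshold band, from both published and recovered barriers; `results/specificity/` |

On the bundled seeds the recovered barriers sit within 0.13 kcal/mol of
the programmed ones across all eight profiles, and the calls from
recovered barriers match those from the published values.

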