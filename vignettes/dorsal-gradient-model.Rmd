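---
title: "Modeling the Dorsal nuclear gradient: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the Dorsal nuclear gradient: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The dorso-ventral (DV) axis of the early *Drosophila* embryo is patterned by
a ventral-to-dorsal gradient of nuclear Dorsal (Dl), an NF-κB-family
transcription factor. In the syncytial blastoderm, cytoplasmic Dl is held
out of nuclei by the IκB-family inhibitor Cactus (Cact); Toll receptor
signaling, maximal at the ventral midline, triggers dissociation of the
Dl-Cact complex and frees Dl to shuttle into nuclei.

`dlgradient` models one DV cross-section of the embryo as a ring of `n`
cytoplasmic compartments, each containing one nucleus. Per compartment `j`
at centre angle `theta_j` (measured from the ventral midline), four species
are tracked: cytoplasmic free Dl (`d`), free Cact (`c`), the Dl-Cact complex
(`dc`) and nuclear Dl (`dn`). With binding flux
`B_j = k_b d_j c_j − k_D(theta_j) dc_j` and nuclear shuttling flux
`N_j = k_i A_nuc d_j − k_e A_nuc dn_j` (an amount per minute through the
nuclear surface `A_nuc`):

```
d'_j  = −B_j − N_j / V_cyt + Γ (d_{j−1} − 2 d_j + d_{j+1})
c'_j  = −B_j + P_Cact − k_Deg c_j + Γ (c_{j−1} − 2 c_j + c_{j+1})
dc'_j =  B_j + Γ (dc_{j−1} − 2 dc_j + dc_{j+1})
dn'_j =  N_j / V_nuc
```

with periodic indices (the whole cross-section is modeled, so no boundary
conditions are needed). The discrete Laplacian with a single rate `Γ`
applies identically to the three cytoplasmic species; nuclear Dl does not
move between compartments. Dl itself is neither produced nor degraded, so
the volume-weighted total `Σ (d + dc) V_cyt + dn V_nuc` is conserved — this
invariant anchors the test suite. Free Cact is produced at `P_Cact` and
degraded at `k_Deg`; Cact in complex is protected, consistent with the
observation that Dl stabilizes Cact. The model deliberately excludes
alternative Dl nuclear-translocation pathways, other IκB species, and any
second DV polarizing signal.

### Toll activation

Toll signaling enters only through the space-dependent dissociation rate

```
k_D(theta) = R exp(−S |theta/pi|^ξ)
```

an even function peaking at the ventral midline with amplitude `R`, whose
spatial reach is set by `S` and `ξ`. This functional form is the package's
own closed form honoring the documented qualitative contract — even, peaked
at the midline, monotone in `|theta|`, linear in `R` — and it is isolated
behind `toll_dissociation_rate()` so an alternative body can be substituted
without touching any caller. All downstream behavior depends only on the
contract. With the published values (`R ≈ 15000`, `S ≈ 4000`, `ξ ≈ 2.5`)
activation decays by three orders of magnitude within about 8% of the
half-circumference, a fact with consequences discussed under *Limitations*.

Across species, the amplitude is assumed linear in the measured mesodermal
*sna* percent arc-length: `scale_R_by_arclength(15000, 21, a)` truncates
`15000 · a / 21` to an integer, reproducing the published adjusted values
12142 / 19285 / 18571 for 17% / 27% / 26% exactly (truncation, rather than
rounding, is what reproduces all three printed numbers).

### Geometry

The cortical layer is modeled as an annular cylindrical shell of length
`2 El`, outer radius `Er` and depth `Eh`, partitioned equally among all `Tn`
nuclei; one DV ring holds `n` of them as circular trapezoids, so

```
V_comp = 2 El π (Er² − (Er − Eh)²) / Tn,   V_nuc = (4/3) π r³,   A_nuc = 4 π r²
```

This uses the four published morphology parameters exactly as the parameter
tables vary them. Construction fails loudly when a nucleus would not fit in
its compartment (`V_nuc ≥ V_comp`) — in sensitivity scans such grid points
become recorded error cells rather than failures. The effective diffusion
coefficient of compartment hopping is `D = Γ w_arc²` with `w_arc` the arc
width at mid-cortex radius `Er − Eh/2`; at `Γ = 2 min⁻¹` this gives
75 µm²/min for the wild-type geometry, rising to ~109 µm²/min for the
largest species geometry — transport increases with embryo size at fixed
`Γ` and `n`.

Compartment 1 sits exactly on the ventral midline (`theta = 0`), indices
increase counter-clockwise, and the ring wraps. The 30-most-ventral window
therefore spans positions −15..+14 with the midline between the two central
nuclei of an even window; since simulated rings are mirror-symmetric, this
parity choice cannot bias fits.

## Simulation modes

**Final cycle** (`simulate_final_cycle()`): from spatially uniform
cytoplasmic concentrations `Dl0`, `Cact0`, `DlCact0` and empty nuclei
(`dn = 0` — nuclear envelopes re-form after mitosis, and the published onset
concentrations are explicitly cytoplasmic), the equations are integrated
over the final interphase `t` with `deSolve::lsoda`. The right-hand side
exists twice: a plain-R reference (`dl_rhs()`) and a C implementation with
an analytic Jacobian used by default; their equivalence is tested, and the
adaptive solution is additionally checked against an independent fixed-step
explicit-Euler integration on a small 12-compartment instance whose rate
constants are chosen a priori so that Euler at `dt = 1e−4` min is well
inside its stability and accuracy regime.

**Multicycle** (`simulate_multicycle()`): cycles nc10..final are integrated
in sequence. Ring nuclei double by a factor √2 per cycle
(`nuclei_at_cycle()`, rounded), total nuclei double, and the nuclear radius
follows per-cycle piecewise-linear anchors (defaults ramp from `0.75 r` at
nc10 to `r` at the final cycle; the final shape is demonstrably insensitive
to ±25% changes in the early anchors, so the defaults only need
plausibility). Within a cycle the nuclear pool is integrated as an *amount*
(`m = dn · V_nuc`), so a growing nucleus dilutes its contents without
creating mass. At each mitosis, nuclear Dl returns to the parent
compartment's cytoplasm and all cytoplasmic amounts are redistributed onto
the finer ring by conservative arc-overlap weighting
(`ring_overlap_matrix`, whose columns sum to one) — total Dl is carried
across divisions to machine precision. Default early interphase durations
are 9, 10, 12 and 16 minutes for nc10–nc13 (standard cleavage timings); the
final cycle takes its duration from the parameter set.

## The analysis pipeline

Simulated profiles are reduced to the 30 most ventral nuclei
(`extract_ventral_window()`), min-max normalized onto [0, 1]
(`normalize_profile()`; a peak-only mode that preserves the baseline is
available for cross-cycle shape comparisons), and compared by the fit
distance `sqrt(Σ_j (a_j − b_j)²)` — the Euclidean metric, with no averaging
over window length. Replicate cohorts get per-position Student-t confidence
intervals (`mean ± t_{(1+level)/2, n−1} · sd/√n`; the t construction is the
natural choice at n ≈ 5, and the interval formula is cross-checked against
`stats::t.test` in the tests).

Two-parameter sensitivity scans (`sensitivity_scan()`) re-simulate the
gradient over a grid in two named parameters and record the fit distance to
the wild-type baseline; `contour_levels()` produces the evenly spaced
levels (default 0.01) used to read the landscape. Infeasible grid points
(geometry violations) are recorded as labeled error cells. Scans are serial
and deterministic: repeated runs are bitwise identical.

## Synthetic cohorts

No embryo quantifications are distributed, so `generate_cohort()` fabricates
replicate "embryos": the base normalized profile plus independent Gaussian
noise (`noise_sd`, default 0.05 in normalized units — chosen once to
resemble typical replicate spread in this kind of quantification), each
replicate re-normalized on its own window, mimicking per-embryo
normalization before averaging. `reference_profile()` freezes one such
cohort per genotype/species label (n = 5, fixed per-label seed, generated
from the best-fitting packaged parameter set for that label).

What this emulates: the replicate-to-replicate spread and per-embryo
normalization of real quantifications. What it does not: imaging artifacts
(background, bleaching), position-correlated noise, or biological
variability in gradient width. Passing recovery tests therefore show the
pipeline discriminates parameter sets at realistic noise, not that it would
do so against every feature of real data. Two further caveats are inherent
to the noise model and worth knowing:

- Per-embryo min-max re-normalization makes replicates slightly *biased*
  estimators of the base profile (extremes are pinned to 0 and 1). The
  unbiasedness of the raw noise can be checked with `renormalize = FALSE`;
  the cohort mean is re-normalized before fitting (`cohort_profile()`),
  which removes the linear part of the bias.
- Parameter-set variants that the underlying study itself found to fit a
  species *equally well* (e.g. the alternatives that change `k_Deg` versus
  `k_b` by compensating amounts) produce normalized profiles separated by
  less than this bias-plus-noise floor at `noise_sd = 0.05`, `n = 5`. Cohort
  recovery reliably identifies the generating set against morphology-only
  variants, but cannot — and should not be expected to — separate
  near-degenerate alternatives. This mirrors the study's own conclusion
  that several distinct Toll-pathway adjustments are observationally
  equivalent.

## Numerical choices

- Solver: `lsoda`, `rtol = 1e−8`, `atol = 1e−10` (overridable). The complex
  dissociation at the midline (`k_D ≈ 15000 min⁻¹`) makes the system stiff;
  the analytic Jacobian keeps full-size simulations at ~0.3 s.
- Negative concentrations: values above −1e−9 are clipped to zero (solver
  undershoot); anything more negative aborts with an integration error.
- Conservation: total-Dl drift over a final-cycle run is ~1e−15 relative
  (tested against a 1e−6 bound); division bookkeeping is exact to 1e−12.
- Degenerate inputs: constant profiles cannot be min-max normalized
  (explicit error); windows larger than the ring, inverted sampling bounds,
  unknown parameter names and infeasible geometries all fail with typed
  messages rather than propagating NaN.
- Problem sizes: tests run full-size rings (92–142 compartments) for the
  headline checks, a 12-compartment instance for oracle comparisons, and a
  20 × 20 grid (400 simulations, repeated for determinism) for the scan
  self-consistency check.

## Known limitations

Two qualitative behaviors reported for the *original nondimensional* model
do not transfer to the dimensional parameter tables this package works
with, and the package makes no attempt to force them:

1. **Cross-cycle shape conservation.** With the published `R`, `S`, `ξ`,
   the Toll activation front spans well under one early-cycle compartment
   (nc10 has ~23 nuclei on the ring), so the compartment-resolved front
   position necessarily shifts as the ring refines across divisions; with
   the revised `Γ = 2`, diffusive broadening accumulates over developmental
   time on top of that. Measured peak-normalized pairwise deviations
   between nc11–nc14 profiles are 0.06–0.26 (on a common angular grid;
   conservative binning and longer interphases do not change the
   conclusion). `multicycle_shape_deviation()` reports these numbers rather
   than hiding them.
2. **Flattening by nuclear radius.** With `k_i = 4`, `k_e = 1` (or 0.44),
   nuclear shuttling equilibrates within minutes, so `dn ≈ (k_i/k_e) d` and
   the *normalized* shape equals the free-Dl shape — independent of nuclear
   radius. Increasing `r` changes the normalized value at the 15th nucleus
   by under 2% (slightly negative). Radius-driven flattening requires an
   import-limited shuttling regime that the dimensional parameter tables do
   not occupy. Flattening by nuclear *density* (`n`), by contrast, is
   strong and robust.

Relatedly, the haploid > wild-type > triploid ordering of absolute peak
nuclear Dl emerges in multicycle mode (1443 > 1052 > 758 in model units for
the revised parameter sets at each genotype's last cycle) but nearly
vanishes in the single-final-cycle mode, whose uniform onset concentrations
equalize the genotypes' available Dl per compartment.

## Parameters at a glance

| Field | Meaning | Units |
|---|---|---|
| `El`, `Er`, `Eh` | embryo half-length, radius, cortical depth | µm |
| `Tn` | total nuclei in the embryo | count |
| `R`, `S`, `ξ` | Toll activation amplitude / shape / exponent | model units |
| `Γ` | inter-compartment transport rate (cytoplasmic species) | min⁻¹ |
| `k_i`, `k_e` | nuclear import / export rate constants | min⁻¹ |
| `P_Cact`, `k_Deg` | Cact production / degradation | model units |
| `k_b` | Dl-Cact binding rate constant | model units |
| `Dl0`, `DlCact0`, `Cact0` | cytoplasmic onset concentrations | model units |
| `r`, `n`, `t` | final-cycle nuclear radius, ring nuclei, interphase | µm, count, min |

Rate-constant and concentration units are deliberately left as "model
units" (time in minutes, length in µm): the published tables state none,
and no SI conversion is attempted. Thirty parameter sets are packaged as
YAML fixtures (`list_parameter_sets()`), one per published table column;
the original representative column leaves `P_Cact`, `k_b`, `Dl0`,
`DlCact0` undetermined (they were lost in the original
nondimensionalization), and the fixture substitutes the adjusted-set
values so every fixture is runnable.
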