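---
title: "Modelling functional capillary rarefaction in skeletal muscle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling functional capillary rarefaction in skeletal muscle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caprare)
```

`caprare` simulates and analyses the loss of *perfused* (functional)
capillaries in fast skeletal muscle and its consequence for fatigue
resistance. This vignette is the package's own account of the model: what
is simulated, which parameters matter, which conventions were chosen where
the field leaves latitude, and what the synthetic data can and cannot tell
you about real muscle.

## 1. The system being modelled

Rat extensor digitorum longus (EDL) is a fast, predominantly glycolytic
muscle (~75% type IIb/IIx fibres) with anatomical capillary density around
600–700 mm⁻² and ~1.5 capillaries per fibre. Microspheres of ~10 µm
injected into the femoral artery lodge in terminal arterioles — the
smallest arteriolar branches, each feeding a cluster of capillaries (a
*supply unit*) — and silence the whole cluster while leaving bulk femoral
flow and arterial pressure essentially unchanged. Fatigue resistance is
quantified by a twitch protocol: 30 s of 1 Hz twitches to activate the
metabolic machinery, then 180 s of 10 Hz stimulation; the fatigue index
(FI) is the mean of the final five twitch amplitudes over the mean of the
five around the early peak.

## 2. The synthetic-data generator

### Fibre mosaic and capillary placement

Fibres are cells of a Voronoi tessellation of a jitter-perturbed hexagonal
lattice (jitter SD = 0.12 × lattice spacing), each shrunk about its
centroid so its area equals a type-specific CSA draw. Fibre types are
multinomial with the group's composition; CSA draws are rank-matched to
cell areas (stratified into boundary vs interior cells) so that realised
type means stay on target even at the ~97% packing the overload groups
require, without piling small types along the section edge. The shrink gap
is the interstitial space; capillaries are placed at fibre polygon corners
(the anatomical position, at fibre boundary junctions), jittered < 0.5 µm,
thinned to a 3 µm minimum separation, and selected with spatial
stratification over ~200 µm blocks so realised density is uniform. Supply
units are grown around random seeds by nearest-neighbour accretion with
truncated-Poisson sizes (mean 6, minimum 2) — small enough that blockade
produces localised ischaemic pockets, large enough that a few hundred
units cover a section.

### Calibration of the control preset

The control targets are capillary density (CD) 617 mm⁻², C:F 1.47, mean
capillary domain area (CDA) 1399 µm², 74.8% IIb/IIx. One reconciliation
was needed: inside a fully tessellated counting frame the identity
CD × mean CDA = 10⁶ µm²·mm⁻² holds *exactly*, so CD 617 and CDA 1399
cannot both be realised by any tessellation-based measurement (10⁶/617 =
1621). The published values come from image-analysis software with its own
edge conventions and do not satisfy the identity. The generator therefore
defaults to `target_capillary_density = 665 mm⁻²`, the value that splits
the discrepancy: realised CD (~665) is 7.8% above 617 and realised CDA
(~1504) is 7.5% above 1399, both inside the 10% calibration band. The
other group presets keep their printed CDs, since only their recordings
(not their domain areas) feed calibrated outputs.

A consequence of matching CD, C:F and the printed fibre CSAs
simultaneously is an interstitial space fraction (~30% in control) larger
than histological reality; it does not affect any computed morphometric
index, which are all defined on capillary positions and fibre counts.

### Physiology recordings

Twitches are half-sines (60 ms) whose amplitude during the fatigue phase
decays as A(t) = A_end + (A₀ − A_end)·exp(−t/τ) with τ = 50 s. The ratio
A_end/A₀ is solved in closed form so that the *measured* 5-twitch FI
equals the target exactly at zero noise. The target FI is the group's
unimpaired baseline scaled by the perfusion linkage (below), with
between-animal SD from the group statistics (0.09 control, 0.03 chronic
MS). Trace noise (default 1 kHz sampling, tension SD 2 mN) adds a small
positive bias to extracted amplitudes (< 0.01 in FI).

Femoral flow is pulsatile: per cardiac cycle (default 360 min⁻¹,
configurable) the waveform is min + amp·((1+cos φ)/2)^k, with k solved per
cycle so the cycle mean, peak and amplitude match the group's printed
rest/end-stimulation values (means ramp exponentially, time constant 45 s,
during stimulation). Pressure is a sine with the printed MAP and pulse
pressure; published values exist for the control/acute state only, so all
chronic presets reuse them (reported MAPs are similar across groups).
Ligation flow presets (10% of control) are invented, since no ipsilateral
ligation flow could be measured.

No within- vs between-animal variance decomposition is published, so
the split here — one common per-animal factor for the flow profile,
independent draws for MAP/pulse pressure, trace noise on top — is the
package's invention; only group-level means and SDs are calibrated.

### The perfusion–fatigue linkage

relFI(p) is a monotone Fritsch–Carlson interpolation through anchors
(0, 0.30), (0.30, 0.30), (0.755, 0.77), (0.90, 1.0), (1, 1.0): ~10%
rarefaction is tolerated without deficit; the chronic microsphere state
(perfused/anatomical = 420/556 ≈ 0.755 with FI 0.36/0.47 ≈ 0.77) pins the
middle; and the floor 0.3 encodes the ligation limit. Group presets whose
printed FI exceeds the control baseline (overload groups) store the
printed FI and back out an "unimpaired" baseline FI = printed/relFI(p), so
the linkage still modulates if you vary p.

## 3. Microsphere occlusion model

Each sphere independently lodges in the modelled tissue with probability
`f_edl`; conditional on lodging it lands in a supply unit with probability
proportional to the unit's capillary count (flow-weighted); occluded units
stay occluded. The expected occluded-unit count has the closed form
Σᵤ (1 − (1 − f·sᵤ/S)ⁿ), used as the Monte-Carlo oracle.

`f_edl` represents capture by the *modelled region* and scales with
section area (2.0 × 10⁻⁴ for the default 2.56 mm² control section), so
dose–response curves do not depend on how much tissue one simulates. The
default was derived analytically so the printed dose range spans ~8% to
~66% occlusion: at the top printed dose of 1.4 × 10⁶ spheres the expected
lodging events per unit is ≈ 1.0, giving mean occlusion ≈ 0.66, below the
reported ≤ 70% ceiling. This endpoint anchoring means the mid-dose
(350,000 spheres) maps to perfusion ≈ 0.75 and linked relFI ≈ 0.77, i.e. a
~23% FI deterioration — somewhat smaller than the ~30% the acute
regression would predict. Both requirements cannot hold under any
memoryless occupancy model; the package keeps the hard endpoint.

Ligation is phenomenological: units are occluded in random order until the
perfused fraction falls to the collateral fraction (default 0.30).
Dose–response sweeps use nested sphere streams, so the perfusion index is
non-increasing in dose pathwise, not just in expectation.

## 4. Morphometry conventions

- **Counting frames**: 475 × 475 µm, three per section, spaced
  equidistantly along the medial–lateral axis with one random common
  offset (systematic random sampling).
- **Edge rule**: Gundersen convention — capillaries on the left/bottom
  (exclusion) edges are dropped, right/top (inclusion) kept; fibres are
  counted by their centroid under the same rule.
- **Domains**: planar Euclidean Voronoi cells of the admitted capillaries,
  clipped to the frame — the standard capillary-domain definition. Domain
  areas therefore sum exactly to the frame area, and an independent
  0.25 µm pixel nearest-capillary oracle agrees within 1% per domain.
- **logSD**: SD of log₁₀ of equivalent domain radii √(A/π). This
  convention reproduces the printed 0.096–0.127 range on realistic
  sections (the generator lands near 0.11); base and radius-vs-area are
  switchable in `log_sd()`.
- **Perfused statistics**: recomputed by re-tessellating from the perfused
  subset alone, not by masking anatomical domains — the published perfused
  CDA exceeding anatomical CDA implies re-tessellation.
- **Perfusion index**: perfused/total (the proportion semantics). The
  ratio variant perfused/unperfused appears as `perfusion_ratio`, since
  the two definitions circulate in the literature and they disagree.

## 5. Oxygen transport

Steady state over a counting frame:

∇·[(Dα + D_Mb·C_Mb·S′(P)) ∇P] = M₀·P/(P + P_crit), S(P) = P/(P + P₅₀)

| parameter | default | units |
|---|---|---|
| capillary radius r_c | 2.0 × 10⁻⁴ (range 1.8–2.5 × 10⁻⁴) | cm |
| maximal demand M₀ | 15.7 × 10⁻⁵ | ml O₂ ml⁻¹ s⁻¹ |
| rest demand | 0.1 × M₀ | — |
| Mb O₂ capacity C_Mb | 10.2 × 10⁻³ | ml O₂ ml⁻¹ |
| O₂ solubility α | 3.89 × 10⁻⁵ | ml O₂ ml⁻¹ mmHg⁻¹ |
| O₂ diffusivity D | 1.73 × 10⁻⁷ | cm² s⁻¹ |
| Mb diffusivity D_Mb | 1.0 × 10⁻⁷ | cm² s⁻¹ |
| Mb P₅₀ | 5.3 | mmHg |
| consumption P_crit | 0.5 | mmHg |
| capillary PO₂ P_cap | 40 | mmHg |
| hypoxia threshold | 0.5 | mmHg |

The five parameters in the upper block are the values stated for this
muscle preparation; the remainder (Mb kinetics, boundary PO₂, rest
scaling, Dirichlet capillary condition) are literature-typical defaults
exposed in `transport_params()` — the original modelling software's
unpublished settings cannot be recovered, and no fidelity to them is
claimed. All validation relies on properties independent of these
defaults: a zero-demand identity, discrete flux balance (< 1%), the
maximum principle, facilitation and sink-removal monotonicity, and the
Krogh–Erlang closed form for the radial solver.

Numerics: finite volumes on a uniform grid (spacing ≤ 2 µm), capillaries
as fixed-value discs (nearest node when the disc under-resolves the grid),
no-flux outer boundary; Picard iteration with the sink linearised as
M₀/(P_old + P_crit)·P (keeps the system an M-matrix, hence positivity and
the maximum principle), diffusivity frozen at P_old, under-relaxation 0.7,
convergence at max|ΔP| < 10⁻⁶ mmHg, iteration cap 300 with the residual
history attached to any failure. Zero perfused capillaries yield a defined
all-hypoxic field with a warning rather than an error. Grid-refinement
order is ≈ 2 when the capillary disc is resolved; with 2 µm discs on a
2 µm grid the disc rasterisation limits the observable order, which is why
the refinement test uses an 8 µm disc.

## 6. Physiology metrics conventions

- Twitch amplitudes are extracted per stimulation cycle (the timeline is
  known, so no blind peak detection): in-cycle maximum minus the quiet
  late-cycle baseline.
- "Peak tension at the start" is the maximum 5-twitch running mean within
  the first 30 s of the 10 Hz phase — tension often potentiates before
  declining — with a strict first-five option.
- Analysis windows: rest = last 10 s before the 1 Hz phase;
  end-stimulation = last 10 s of the 10 Hz phase (both configurable).
- Relative FI is post/pre (< 1 = impairment). The protocol text's literal
  "pre/post" reading is available via `direction = "pre_over_post"`; the
  default matches the dose–response presentation where relative FI falls
  below 1 with dose.

## 7. Statistics conventions

Curved fits default to degree 2 (the lowest curved polynomial; the degree
is an argument). Confidence bands are pointwise t-based at 95%. ANOVA uses
Tukey HSD at α = 0.05 with an insert-and-absorb compact letter display; no
multiplicity correction beyond Tukey is applied. Repeated limbs within an
animal are *not* modelled as random effects — a known limitation, kept for
comparability with the original analysis design.

## 8. Problem sizes and tolerances used in the tests

Unit tests run on 600–900 µm sections and 60–200 µm oxygen frames; the
acceptance suite uses 20 replicate 1600 µm control sections × 3 frames for
morphometric calibration, 20 recordings per preset for the physiology
means, 1000 Monte-Carlo replicates for the occupancy oracle, 100 cohorts
(n = 25, noise SD 0.05) for linkage-coverage, and 200 replicates for the
top-dose occlusion endpoint. These sizes were chosen so that Monte-Carlo
standard errors sit well inside each calibration band.

## 9. What passing tests do and do not show

The generator emulates group-level statistical structure: capillarity and
fibre-type targets inside counting frames, supply-unit clustering,
dose-dependent perfusion loss, and trace statistics (twitch decay,
pulsatile flow, MAP). It does not emulate staining or imaging noise,
capillary tortuosity or 3-D geometry, red-blood-cell flux heterogeneity,
within-animal repeated-measures correlation beyond a shared baseline, or
the angiogenic remodelling mechanism itself (overload groups are presets,
not predictions). Passing calibration therefore demonstrates that the
analysis chain is correct and self-consistent on data with the assumed
structure — not that real sections satisfy those assumptions.

## 10. Known limitations

- The dose→occlusion curve is anchored only at its endpoints; per-dose
  perfusion indices for acute animals are not published, so the middle of
  the curve is a model choice.
- The oxygen model is 2-D and intravascular resistance-free; capillary
  PO₂ is uniform at P_cap.
- The compact letter display uses the standard insert–absorb heuristic,
  which can be conservative for pathological significance patterns.
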