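---
title: "Deriving proton RSP from dual-energy CT maps: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving proton RSP from dual-energy CT maps: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dectrsp)
```

## The problem

Proton treatment planning needs the relative stopping power (RSP) of every
voxel — the ratio of a material's proton stopping power to that of water —
because RSP integrates into proton range. Dual-energy CT (DECT) scanners can
decompose their two-spectrum acquisition into voxel-matched maps of effective
atomic number (Zeff) and relative electron density (RED), from which RSP
follows directly from the Bethe–Bloch ratio, instead of the less specific
single-energy CT-number calibration. This package implements that conversion
and the phantom-based protocol used to quantify its accuracy: tissue-surrogate
plugs with known references are scanned, circular ROIs are scored by percent
error, and errors are aggregated by tissue class. Because scanner exports are
not generally available, a synthetic-phantom module generates Zeff/RED volumes
with the benchmark geometries, reference values and tabulated noise levels, so
the full chain is testable on any machine.

## Physics model

For a voxel with relative electron density $\rho_{e}$ and material mean
excitation energy $I_m$,

$$\mathrm{RSP} \;=\; \rho_{e}\,
\frac{\ln\!\frac{2 m_e c^2 \beta^2}{1-\beta^2} - \beta^2 - \ln I_m}
     {\ln\!\frac{2 m_e c^2 \beta^2}{1-\beta^2} - \beta^2 - \ln I_w},$$

with $I_w = 75.3$ eV. When $I_m = I_w$ the bracket ratio cancels and
RSP $=$ RED to machine precision — `bethe_bloch_rsp(red, 75.3, T)` returns
`red` exactly, a property the tests exercise across the therapeutic range.

Reference values for materials of known composition use:

* **Mayneord effective atomic number**
  $Z_\mathrm{eff} = \left[\sum_i w_i (Z_i/A_i) Z_i^{\,n} \big/ \sum_i w_i
  (Z_i/A_i)\right]^{1/n}$ with $n = 3.21$;
* **theoretical RED**
  $\rho_e = \rho N_A \sum_i w_i Z_i/A_i \,/\, \rho_{e,w}$, linear in mass
  density and self-normalizing for water;
* **Bragg additivity**
  $\ln I_m = \sum_j w_j (Z_j/A_j) \ln I_j \big/ \sum_j w_j (Z_j/A_j)$.

The bundled elemental $I$-values are the condensed-phase set standard in
stoichiometric proton-therapy calibration (H 19.2, C 81, N 82, O 106 eV, ...),
chosen because Bragg additivity on water then reproduces the 75.3 eV water
convention exactly. Note that direct Mayneord evaluation of water gives
$Z_\mathrm{eff} \approx 7.46$ while the benchmark tabulates 7.42; tabulated
values are treated as authoritative references, the formula as the
computational definition.

### Key parameters

| Parameter | Default | Why |
|---|---|---|
| Proton kinetic energy $T$ | 100 MeV | mid-therapeutic; RSP changes < 1 % over 80–200 MeV, so the choice is immaterial at the benchmark's precision |
| $\beta^2$ | $1-(M_p/(T+M_p))^2$, $M_p = 938.272$ MeV | relativistic kinematics |
| Mayneord exponent $n$ | 3.21 | the photoelectric-weighted convention of the benchmark |
| Water $I_w$ | 75.3 eV | fixed by convention |
| ROI area fraction | 0.60 | concentric circle at exactly 60 % of the plug area ("at least 60 %" in the protocol); configurable upward |
| Tissue bins (RED) | air/lung 0.28–0.44, fat 0.93–0.97, water 0.99–1.00, muscle 1.02–1.08, bone 1.09–1.78 | values outside all bins map to the nearest boundary, so the 0.200 sinus plug is air/lung and the 1.875 enamel plug is bone — the assignment that makes the published category arithmetic close |

## The Zeff → I correlation

Clinical RSP maps require $I_m$ per voxel, but only Zeff is measured; the two
are empirically correlated. `calibrate_correlation()` computes
$(Z_\mathrm{eff}, \ln I)$ for each calibration material and supports two
functional forms:

* `"interp"` — piecewise-linear interpolation through the material nodes
  (clamped outside the node range). It reproduces every calibration material
  exactly and is the right tool for noise-free reference work.
* `"quadratic"` (the pipeline default) — a least-squares quadratic of
  $\ln I$ on Zeff, tabulated on a fine grid with linear end-segments.

The default is smooth for a quantitative reason. The tissue data have an
elbow: $\ln I$ rises steeply with Zeff through soft tissue
(slope $\approx 0.1$ below Zeff 8) and flattens into the bone range. A kinked
interpolant passed over a noisy Zeff map *rectifies* zero-mean noise into a
systematic $\ln I$ shift of order $|\Delta\text{slope}|\,\sigma/\sqrt{2\pi}$ —
up to $\sim$0.016 at the widest tabulated noise ($\sigma_{Z_\mathrm{eff}}
= 0.636$), i.e. an RSP bias of $\sim$0.002 that a mean over a few thousand ROI
voxels resolves easily. The quadratic's only rectification is its constant
curvature ($a\sigma^2 \lesssim 4\times10^{-4}$ in $\ln I$ at the same noise),
which keeps noisy ROI means unbiased within the recovery budget. The
calibration set spans adipose through cortical bone and is extended with
hydroxyapatite and elemental calcium anchors (Zeff up to 20) so that no
benchmark insert — enamel at 17.2 included — sits at a clamped end of the
correlation, where one-sided clamping would likewise bias noisy means.
Queried at water's Zeff the default correlation returns $I \approx 70$ eV,
within 10 % of the 75.3 eV convention; for recovery studies only consistency
between the noisy and noiseless pipeline matters, and both share the
correlation.

## The synthetic phantoms

`preset_phantom()` builds the five benchmark phantoms with their published
insert complements and reference values, and `build_label_volume()` /
`render_property_maps()` voxelize them into piecewise-constant Zeff/RED
volumes (voxel-center-in-shape rule, labels constant across slices).
Default grid: 1 mm in-plane, 2.5 mm slices (the scanning thickness), 10
slices, phantom centered, origin at the phantom center.

Geometry honors every published distance: ring radii are quoted
center-to-plug-edge; neighbors are placed at the exact printed chord spacing
(sequential placement — the leftover closing gap of a ring is unconstrained,
angular start positions are arbitrary). In the 33 cm phantom both rings share
the angular increment set by the outer ring's 5 cm gaps and are interleaved by
a half step, which lands the inner-ring gaps and the closest outer–inner
distance within half a voxel of the printed 1.4 cm and 3 cm. Plug diameters
are not published; the default is 2.8 cm (the size of the central noise-ROI
protocol), except the custom head phantom, whose eight plugs only fit the
printed 3.3 cm spacings on a ring 7 cm from the center of an 18 cm outline if
they are 2.0 cm. Its sinus plug sits between enamel and cortical bone, 1.6 cm
from each plug edge. Background materials are solid water for the commercial
phantoms and a wax-like RED 0.96 / Zeff 6.2 for the custom pair; outside the
outline, voxels get air values with a RED floor of 0.001 to avoid downstream
division by zero.

Noise is additive, independent, zero-mean Gaussian, spatially uniform, at the
per-phantom/dose standard deviations of the bundled noise table, applied to
the Zeff and RED maps before conversion (`add_noise`, seeded and
bit-reproducible). `add_highz_bias()` adds an optional exponential
$\text{amplitude} \cdot e^{-d/\text{decay}}$ in-plane field to emulate
scatter from high-density structures; its amplitude defaults to zero and it
is off in all study conditions.

**What the generator does not emulate** — and hence what passing tests do not
show about real scanners: beam hardening and bowtie-filter effects, spatially
correlated noise texture, reconstruction-kernel blur and partial-volume
edges, decomposition cross-talk between the Zeff and RED maps, and the
proprietary projection-space decomposition itself, which is treated as an
opaque upstream source. The synthetic studies validate that *this package's
evaluation chain adds no systematic error*; they cannot revalidate the
scanner.

## Evaluation statistics

Percent error is $100(\text{ROI mean} - X_\text{ref})/X_\text{ref}$; the
residual is its numerator; MAPE is the mean absolute percent error over
inserts. Aggregation is always on unrounded values; report files round RSP to
3 decimals and percent errors to 2, mirroring the benchmark tables. SDs use
the $n-1$ denominator. Noise is measured as the sample SD of a 2.8 cm circle
at the phantom center (1 cm inside the central solid-water plug where the
center is occupied). The Head-vs-Body comparison is a two-sided paired
Student's t-test on per-insert RSP means; identical sequences return $p = 1$
by convention, and zero-variance differences with non-zero mean raise an
error rather than fabricating a p-value.

The bundled benchmark carries the published per-insert values. Its percent
errors were computed by the original authors from unrounded ROI means, so
recomputing aggregates from the rounded columns reproduces the published
summary cells at their printed precision but not beyond: the bone-category
MAPE computes to 1.126 against a printed 1.12, and the paired test on rounded
RSP means gives $p = 0.70$ against a published 0.61 — both consistent at the
resolution the inputs allow, which is how the acceptance tests assert them.

## Study sizes and numerical choices

The recovery study simulates all five phantoms at their Body-scan noise
levels, 100 independent realizations each, on the default 1 mm / 10-slice
grid (labels and noiseless maps computed once per phantom and reused), and
checks each insert's RSP ROI mean against the noiseless pipeline value within
3 standard errors (ROI voxel SD$/\sqrt{N}$); the per-insert pass criterion is
95 % of realizations, against a nominal 99.7 %. The full study runs in about
a minute and a half on one core. Noise recovery is checked at all eight
tabulated phantom/dose settings for all three quantities; with $\gtrsim 6000$
circle voxels the sampling error of the SD is $\sim$1 %, well inside the 10 %
criterion. RED voxels driven non-positive by noise (possible only in near-air
regions) are clamped to the 0.001 floor with a logged count.

## Limitations

* Per-insert Zeff/RED accuracy of the scanner cannot be reproduced: the
  benchmark publishes only category-level Zeff/RED aggregates, so the bundled
  per-insert table (and everything derived from it) is RSP-only.
* The correlation used by the actual scanner software is proprietary; the
  package's calibrated correlation is a documented, physically motivated
  stand-in, adequate because all synthetic comparisons are internally
  consistent.
* The exponential proximity-bias model is a phenomenological knob for
  sensitivity studies, not a scatter simulation.
* No DICOM I/O; volumes are exchanged as NIfTI with the quantity recorded in
  the header description.
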