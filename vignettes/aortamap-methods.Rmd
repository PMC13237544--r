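---
title: "Methods: per-vertex aortic wall displacement, WSS and atlas mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-vertex aortic wall displacement, WSS and atlas mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`aortamap` quantifies regional biomechanics and hemodynamics of the
thoracic aorta from two time-resolved 3D inputs per subject: binary
lumen segmentations over the cardiac cycle (as produced by automatic
segmentation of cine bSSFP acquisitions) and a 3-component velocity
field (4D flow CMR). From these it derives, per subject,

* a per-vertex **3D wall displacement map** — the Euclidean distance
  between each end-diastolic surface point and its position after
  non-rigid registration to every other cardiac phase, with the frame
  of maximal average displacement kept for analysis;
* per-vertex **wall shear stress (WSS) vectors** at peak systole, from
  the wall-normal velocity gradient;
* the global **pulse wave velocity** (PWV) from plane-wise flow
  waveforms;
* regional averages over four thoracic regions of interest (proximal
  and distal ascending, proximal and distal descending aorta), station
  diameters and diameter-adjusted variants.

At the cohort level, control subjects define per-vertex normal-value
**atlases** (mean, SD and mean ± 1.96 SD maps; mean WSS directions).
Projecting the atlas onto a patient geometry classifies each patient
vertex as normal, increased or decreased (or abnormally directed, for
vectors), giving **heatmaps**; mapping the binary abnormality
indicators of many patients to a shared patient template gives
**incidence maps**. Regional summaries feed standard group statistics
(ANOVA with Tukey HSD under a Bonferroni-corrected omnibus threshold,
rank-sum tests for abnormal surface areas, Pearson correlations,
univariable logistic regression).

Because suitable public 4D datasets are scarce and reference values are
population-specific, the package ships a **synthetic cohort generator**
with analytic ground truth; every stage is validated against it.

# The synthetic aortic cohort

The generator builds a "candy-cane" aorta: a half-torus arch (default
radius 35 mm) joined to a straight descending limb (default 120 mm),
with a lumen radius tapering from 15 mm at the root to 10 mm at the
diaphragm, plus smooth low-frequency radial perturbations that emulate
between-subject shape variability. Landmarks (annulus,
pulmonary-artery-bifurcation level, brachiocephalic trunk, left
subclavian artery, diaphragm) are emitted as exact arclengths, mirroring
the manual placement a reader would perform.

Wall motion follows `r(s, t) = r0(s) + amp(s) w(t)` where `w` is a
raised-cosine systolic bump over the first 40% of the cycle (smooth,
with a single unambiguous peak) and `amp(s)` interpolates per-region
peak excursions. Velocity is a near-parabolic profile along the local
tangent, `v = t(s) v_peak(s) (1 - (rho/r)^2) w(t - s/c)`, with the
traveling-wave delay `s/c` active only when a wave speed `c` is set.
The analytic WSS ground truth is the Poiseuille wall value
`2 mu v_max / r`.

Default regional values (displacement, velocity, PWV, and their
between-subject SDs) are typical of healthy adults and of Marfan
patients with and without aortic root surgery; `cohort_reference()`
returns them. Cohort draws add normal between-subject jitter truncated
at physiologic floors, and localized abnormality patches (a region,
an arclength span, optionally an angular sector around the outer
curvature, and a multiplier) are assigned to patients by Bernoulli
draws at a controlled prevalence — this is the ground truth that
incidence maps are validated against.

The generator emulates geometry, motion and flow, **not** MRI physics:
no velocity-encoding noise, no phase wraps, no segmentation errors.
Passing tests therefore demonstrate correctness of the analysis chain,
not robustness to acquisition artifacts.

Defaults: 30 cardiac phases per 1000 ms cycle and 1.0 mm isotropic
voxels, matching typical reconstructed cine resolutions. Tests and the
acceptance script use coarser spacings (2–3 mm) and fewer phases for
most scenarios; the problem sizes used are stated where they are used
and were chosen so the whole validation suite runs on a single CPU in
minutes. All voxel grids place voxel centers at 0-based integer
coordinates times the spacing, in world millimetres.

# Surface extraction and geometry

Masks become surfaces by Gaussian pre-smoothing (sigma 0.8 voxel) of
the binary volume, marching-tetrahedra isosurfacing at the 0.5 level,
retention of the largest connected component, and five
shrink-compensated (Taubin lambda/mu) Laplacian iterations. Outward
orientation is verified against the mask interior. Per-vertex areas are
one third of the incident triangle areas, so they sum exactly to the
surface area. A vertex-clustering decimation (`decimate_mesh`) brings
meshes to registration size; validation shows sphere and cylinder areas
within 5% of the analytic values.

Centerlines are distance-transform-weighted shortest paths between an
inlet and an outlet voxel: edge costs multiply step length by the
inverse *squared* distance-to-boundary (the squared weighting stops the
path from cutting the inner curvature of the arch: on a half-torus
phantom the recovered arc length is ~3.5% short with linear weighting
and within 2.5% with squared weighting), followed by moving-average
smoothing and 1 mm resampling.

Regions of interest are assigned per vertex from the arclength of its
nearest centerline point: annulus to PA-bifurcation level (pAAo),
to the brachiocephalic trunk (dAAo), the arch between brachiocephalic
and left subclavian is excluded, left subclavian to the PA level on the
descending limb (pDAo) and down to the diaphragm (dDAo). The descending
split is found by matching the axial height of the PA-bifurcation
station on the descending limb; for degenerate geometries with no
matching height (e.g. straight validation tubes) it falls back to the
descending midpoint. Vertices before the annulus or past the diaphragm
(end caps) are excluded.

Diameters are measured on the mesh cross-section perpendicular to the
centerline: area-equivalent (`2 sqrt(A/pi)`) by default, maximum chord
("cusp-to-cusp") at the root. The slice keeps only the local loop —
planes through a curved vessel also cut the opposite limb — and flags
open or multi-loop slices.

# Non-rigid registration

Surface correspondence uses a Gaussian-kernel regularized point-set
registration of coherent-point-drift type: the displacement field is an
affine part plus a Gaussian radial-basis expansion anchored at
farthest-point-sampled control nodes (default 250, kernel width
10 mm), fitted by iterating closest-point-on-surface matching with an
annealed ridge penalty on the radial-basis weights. Two details matter
in practice and were fixed by validation:

* **Translation-first.** A translation-only stage precedes the field
  fit, so a bulk shift is explained by the constant term. (A full
  affine first stage let the strong root dilation bleed into distal
  regions; translation-only does not.)
* **Point-to-surface matching.** Matching to the nearest target
  *vertex* leaves a coherent tangential drift of ~0.5 mm when source
  and target tessellations differ — visible as a spurious displacement
  floor on identical shapes. Matching to the closest point on the
  target triangulation removes it (floor ≈ 0.03 mm).

The kernel width trades regional independence against smoothness: it
must be well below the ascending-to-descending limb distance (~40 mm),
or motion of one limb contaminates the other, and above the vertex
spacing. Identity input returns the identity; a 5 mm translation and a
1 mm inflation are recovered within 0.2 and 0.15 mm. Non-convergence
(residual above tolerance) flags the result rather than failing
silently, and flagged registrations are excluded (and logged) from
atlas building and incidence mapping.

Template selection minimizes the mean symmetric nearest-neighbour
vertex-to-surface distance to all other geometries, ties to the lowest
index. Scalar fields travel between meshes by inverse-distance-weighted
(k = 3, power 2) interpolation at the mapped positions; vectors
componentwise with optional renormalization; binary indicators by
nearest-neighbour transfer so incidence counts stay integer multiples
of 1/n.

# Displacement, WSS, PWV

**Displacement.** The end-diastolic mesh (generator-designated phase,
or user-supplied index on real data) is registered to every other
phase; the map value is the Euclidean distance to the mapped position
(correspondence distance, not distance-to-surface). The analysis frame
is the one maximizing the unweighted vertex mean (area-weighted mean
available), ties to the earliest phase. In the pipeline the
registration targets stay at full mesh resolution while the
end-diastolic source mesh is decimated: decimating the targets
quantizes the matches and biases small displacements upward. On
synthetic cohorts the per-region means recover the generator amplitudes
within 15%.

**WSS.** Peak systole is the phase with the highest spatially averaged
velocity magnitude in the lumen. Per vertex, the local lumen diameter
D is twice the distance to the nearest centerline point; velocity is
sampled at 0, D/4 and D/2 along the inward normal (trilinear), the wall
sample is forced to zero (no-slip; boundary voxels mix wall and lumen
signal), and the unique quadratic through the three samples is
differentiated at the wall. WSS is the dynamic viscosity times the
tangential part of the gradient. Viscosity defaults to 3.2e-3 Pa s, a
standard blood value, and is recorded in the output. Velocities are
converted to m/s and distances to m, so magnitudes are in Pa. Sample
points that exit the lumen flag the vertex out of regional averages.
For exact parabolic flow the three-point quadratic is exact: the
validation tube reads 0.64 Pa against the closed form 2 mu v_max / r
with r = 10 mm, v_max = 100 cm/s.

**PWV.** Flow waveforms are integrated on planes perpendicular to the
centerline at equal arclength spacing and resampled to 20 ms. Arrival
times come either from the systolic-upstroke foot (intersection of the
20–80% upslope regression with baseline) or from the lag maximizing
cross-correlation against the most proximal plane, refined by parabolic
interpolation around the peak (20 ms sampling is coarse relative to
aortic transit times, so sub-sample refinement is required). PWV is the
inverse slope of arrival time against arclength; non-positive or
non-finite slopes are flagged failures, never numbers. The
cross-correlation method is the default; wave speeds of 2–12 m/s are
recovered within 10%.

# Atlases, heatmaps, incidence maps

Scalar atlases use the **sample** SD (n − 1; control cohorts are
small) and the exact multiplier 1.96 for the normal interval. Patient
vertices strictly above/below the projected bounds are
increased/decreased; boundary values are normal. Zero-SD vertices fall
back to exact equality with the mean and are flagged. Vector atlases
average **unit** vectors (zero vectors excluded); the resultant length
measures coherence and vertices below 1e-6 are flagged undefined. A
patient vector is abnormally directed when its angle to the projected
mean direction strictly exceeds 120 degrees; the comparison uses a
1e-9 guard on the cosine so vectors at exactly the threshold stay
normal under floating-point round-off. Incidence maps transfer binary
indicators by nearest neighbour, so proportions are exact multiples of
1/n_patients.

Abnormal-area percentages are area-weighted (vertex counts are not
comparable on irregular meshes); flagged and undefined vertices are
excluded from both numerator and denominator and reported. The
pre/post-registration audit compares per-subject regional means before
and after projection to the template with a paired t interval.

# Statistics

Regional parameters are compared by one-way ANOVA at the
Bonferroni-corrected threshold 0.0125 (four regions), with Tukey HSD
pairwise contrasts computed only after a significant omnibus and
declared at 0.05. Abnormal-area percentages between the two patient
groups use the two-sample rank-sum (Mann–Whitney) test — the
signed-rank variant sometimes named in clinical reports cannot apply to
independent groups of unequal size, and the variant used is recorded in
the run metadata — exact when untied, normal approximation with
continuity correction otherwise, with "median (IQR: q1–q3)"
summaries. Correlations are Pearson with Fisher-z 95% intervals;
logistic regression is a standard ML fit reporting the odds ratio with
Wald interval, flagging complete separation. All tests are two-sided.

# Validation design for the group-effect study

The statistical-workflow property — a 40% proximal-ascending
displacement reduction in the surgical group, n = 20/group, detected
through the gated ANOVA + Tukey workflow in at least 90% of replicates
— is validated in two parts. One replicate runs the full image path
(voxelized subjects, surface extraction, registration, ROI averaging)
and must show the significant pAAo surgical-vs-control contrast with a
non-significant distal-ascending contrast. The replicate frequency is
then estimated over 50 cohorts drawn at the measurement level by
`draw_cohort_params()` — the same per-subject parameter distributions
the voxelizer consumes, without the imaging stage — because processing
3000 voxelized subjects per run is disproportionate to what the
property tests (the statistical workflow), and the imaging stage's
unbiasedness is established separately by the displacement-recovery
and single-replicate checks.

# Known limitations

* The registration is surface-based; no voxelwise image registration.
* The generator's wall motion is purely radial; circumferential twist
  is not simulated, so tangential-displacement recovery is untested.
* Local lumen diameter (for the WSS sampling depth) assumes a roughly
  tubular lumen; it is biased at bifurcations, which the geometry does
  not include.
* WSS is computed only at peak systole (no time-resolved WSS), and the
  three-point quadratic underestimates gradients for profiles far from
  parabolic (e.g. plug flow).
* End caps of the synthetic tubes are excluded via the annulus and
  diaphragm stations; real data should crop analogously.
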