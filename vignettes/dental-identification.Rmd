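---
title: "Comparing segmentation strategies for 3D dental identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing segmentation strategies for 3D dental identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odontomatch)
```

## The identification problem

Forensic dental identification compares an antemortem (AM) dental record with
a postmortem (PM) one and asks whether they plausibly come from the same
person. When both records are 3D surface scans of the dentition, the
comparison can be made objective: register one scan onto the other with the
iterative closest point (ICP) algorithm and report the root-mean-square (RMS)
of the closest-point distances, in millimetres. Scans of the same dentition
register to a small RMS; scans of different dentitions do not, and a decision
threshold on RMS separates the two.

The catch is extraneous geometry. Intra-oral scanners capture gingiva and
other soft tissue along with the teeth, and soft tissue is far less stable
than dental hard tissue — between visits, between an impression-derived cast
and the mouth itself, and after death. Unequal soft-tissue capture inflates
the RMS of a true match. Practitioners therefore segment scans before
comparison, classically in one of two ways: *gingival reduction* (trimming
along the gum margin into the interdental spaces, leaving only tooth
surfaces) or a *planar slice* (one cut through the arch that discards
everything below the plane, leaving the interdental papillae intact).
Both are applied to each scan individually, before registration.

This package implements and compares five strategies:

| Method | Segmentation | When applied |
|---|---|---|
| `M1_NONE` | none (control) | — |
| `M2_SEMI_AUTO_GINGIVAL` | gingival reduction retaining a small collar | per scan, pre-registration |
| `M3_MANUAL_GINGIVAL` | full gingival reduction to tooth surfaces | per scan, pre-registration |
| `M4_PLANAR` | an individual planar slice per scan | per scan, pre-registration |
| `M5_JOINT_PLANAR` | one joint planar slice of the superimposed pair | after initial registration |

Method 5 is the interesting one: the two untrimmed scans are registered
first, a *single* plane is fitted to the superimposed pair and applied to
both point clouds at once, and a secondary registration of the trimmed
clouds produces the final RMS. It removes one manual segmentation step per
scan and keeps the two clouds' retained regions consistent by construction.

## The comparison engine

Registration is trimmed point-to-point ICP (`icp_register()`): alternate
nearest-neighbour correspondence (kd-tree), discard the `trim_fraction`
(default 10%) worst correspondences, and update the pose with the
least-squares rigid fit (Kabsch/SVD, reflection-corrected). Trimming bounds
the influence of capture regions present in only one scan; `trim_fraction =
0` recovers classical ICP, which the registration tests use. Convergence is
declared when the trimmed RMS improves by less than `rel_tolerance`
(default `1e-6`) relative — a scale-free criterion. With this update order
the trimmed RMS is provably non-increasing, which the test suite checks on
noisy cohort pairs.

Initialisation matters for ICP. Rather than rely on the scans arriving
roughly aligned, registration pre-aligns deterministically: centroids are
matched, principal axes aligned, and among the four proper-rotation sign
assignments of the axes the one with the lowest initial RMS wins. The
arch's three principal extents (width, depth, height) are well separated,
so this is stable; it also makes the whole pipeline invariant to how the PM
scan happened to be placed in space, a property tested explicitly.

The reported RMS is one-directional — PM onto AM, over the retained
correspondences of the final iteration. RMS is not symmetric for partially
overlapping clouds, so the direction is fixed and documented rather than
left to chance.

### The decision threshold

`fit_rms_cutoff()` fits the match/non-match threshold. On perfectly
separated data the logistic-regression maximum-likelihood estimate diverges
(the likelihood increases without bound as the coefficient grows), so the
logistic mode detects separation explicitly, reports `separable = TRUE`,
and falls back to the midpoint of the gap between the largest matching and
smallest non-matching RMS. This is deliberate: a diverging coefficient is
not a reproducible statistic, the midpoint of the separating gap is. When
the classes overlap, the midpoint mode scans all candidate thresholds for
maximal training accuracy (ties to the smaller threshold) and the logistic
mode reports the RMS at predicted probability one half. Classification is
conservative at the boundary: an RMS exactly at the cutoff is called a
non-match, never an identification.

`boxcox_lambda()` profiles the Box-Cox power family over λ ∈ [−3, 3] in
steps of 0.01 (including the Jacobian term), the transformation diagnostic
used when the comparison table is carried into regression modelling.
`pairwise_bonferroni()` provides Welch two-sample contrasts between methods
within the matching and non-matching strata, with p-values multiplied by
the number of comparisons and capped at one. Mixed-effects modelling of the
full replicate structure is intentionally out of scope: the comparison
table (`run_study()`) is a plain long-format data frame that `lme4` or
`emmeans` can consume directly.

## The synthetic cohort

No real scans ship with the package; a generator (`make_cohort()`)
emulates the study conditions: six participants, upper and lower arches,
one direct AM scan and one cast-derived PM scan each — 24 scans.

`generate_arch()` builds an arch as 14 superellipsoid crowns (second molar
to second molar) placed along a parabolic arch curve, embedded in a
continuous gingival band with raised interdental papillae between adjacent
crowns. Dimensions default to adult values in millimetres: 50 mm arch
width, 42 mm depth, 6.5 mm mean mesio-distal crown width scaled
anatomically from incisors to molars, 8 mm crown height, a 5 mm gingival
ridge, 1.2 mm papillae. Individualising anatomy comes from seeded jitter
(`shape_jitter`, default 5% of each dimension) on crown sizes, roundness
exponents, positions, and — through a shared participant-level size factor,
since tooth and arch size covary — the arch proportions themselves. The
superellipsoid family is not tooth anatomy; it is a smooth, distinguishable
shape family, which is all the registration-based comparison relies on.

`degrade_to_pm()` turns an AM mesh into its PM counterpart with four
effects: a smooth low-frequency displacement field (three random sinusoidal
modes per axis, total amplitude bounded by `deform_amplitude`, default
0.2 mm, wavelength ~40 mm — impression and cast distortion is smooth, not
per-vertex), i.i.d. vertex noise (`noise_sd`, default 0.05 mm), *extra*
noise on gingiva vertices (`gingiva_extra_sd`, default 0.1 mm — soft tissue
varies more than hard tissue, which is precisely why segmentation helps),
and an arbitrary rigid placement (rotation up to 30°, translation up to
20 mm) whose inverse is returned as the ground-truth PM-to-AM transform.
The capture-noise magnitudes are not measured quantities — the study the
conditions emulate reports no scanner error figures — so they are defaults
chosen to reproduce the qualitative RMS separation, and every one is
exposed as a parameter.

### Sampling and the correspondence floor

Registration operates on point clouds sampled area-uniformly from the mesh
surfaces (`sample_surface()`). At the default 5000 points over a
~3800 mm² arch, two *independent* samplings of the same surface sit
~0.4 mm apart point-to-point (the Poisson nearest-neighbour floor
1/(2√λ)), which would drown the 0.05–0.1 mm capture differences the
comparison measures. Real scans do not have this problem — they carry
hundreds of thousands of points, and commercial tools report
cloud-to-mesh distances. To emulate that regime at simulation scale,
`sample_surface()` accepts a `template` mesh: face-selection probabilities
are computed from the template's areas, so two topology-identical meshes
(an AM scan and the PM mesh derived from it) sampled with the same seed
yield parametrically corresponding points, and the RMS between the clouds
measures true surface deviation. `run_study()` applies this whenever the
two meshes share a face matrix. This is a modelling choice to note when
interpreting results: passing tests show the *method pipeline* behaves
correctly on clouds whose RMS reflects surface deviation; they do not
certify behaviour on sparse, independently sampled clouds.

### Plane placement and operator variability

The study's operators placed slicing planes by eye on anatomical
landmarks; a simulation needs a deterministic rule. `fit_slicing_plane()`
fits the least-squares plane of the cloud, orients the normal occlusally
(toward the tooth-labelled mass, or toward the skewed tail for unlabelled
clouds — crowns protrude), and sets the offset at the estimated
tooth–gingiva boundary height (midpoint between the lower tail of tooth
heights and the upper tail of gingiva heights along the normal), lowered
by `plane_drop` (default 0, which keeps papillae above the cut). Operator
variability is modelled as seeded jitter on the plane: `plane_jitter_sd`
gives the standard deviations of a random offset shift (mm) and normal
tilt (degrees). Replicates, sessions and operators in `run_study()` differ
*only* through this jitter stream (each cell gets an independent seeded
stream via stable hashing, so any cell is replayable in isolation); the
scan geometry itself is fixed, as it is when the same scans are
re-segmented. Consequently the gingival-reduction methods, which use no
plane, have zero replicate spread, and the planar methods (M4, M5) show
the wider SD distributions — the qualitative pattern the acceptance suite
asserts. In the acceptance check the jitter is set to 0.2 mm / 1°, a
plausible landmark-selection error at arch scale.

Two deliberate conventions: boundary points (signed distance exactly zero)
are retained by `plane_slice()`, and Method 5 chooses its joint plane in
the AM frame, restores the PM cloud to its native frame afterwards, and
warm-starts the secondary registration from the initial transform — so the
secondary ICP is a genuine re-registration, not a no-op, mirroring the
sequential workflow. Whether Method 4's planes should be placed
independently per image or copied between images is ambiguous; they are
independent here (with distinct jitter streams), which is exactly what
distinguishes M4 from M5.

## What an analysis looks like

```{r study, eval = FALSE}
cohort <- make_cohort(6, dentition_params(), degradation_params(), seed = 1L)
design <- study_design(methods = segmentation_methods(),
                       replicates_per_cell = 1L, sessions = 1L,
                       operators = 1L, seed = 1L)
tab <- run_study(cohort, design, icp = icp_params(sample_size = 5000L),
                 n_points = 5000L)
summarize_groups(tab)

seg <- tab[tab$method != "M1_NONE", ]
fit_rms_cutoff(seg$rms, seg$is_match, mode = "midpoint")
```

On these defaults the matching comparisons land near 0.08–0.12 mm RMS
(highest without segmentation, lowest for manual gingival reduction, the
planar methods slightly above it since they retain papillae), non-matching
comparisons near 0.4–1.2 mm, and a single fitted threshold classifies all
segmented comparisons correctly — the numbers themselves are computed by
`scripts/acceptance.R` and the test suite, not quoted here from elsewhere.

## Numerical choices and degenerate inputs

* Vertices within 1e-9 mm are welded when reading STL (the format stores a
  triangle soup); the binary dialect stores float32, so round-tripping
  full-size coordinates is exact only to ~4e-6 mm — the label sidecar is
  therefore keyed to the welded vertex order the reader reconstructs, at
  float32 resolution for binary output.
* `estimate_rigid()` refuses fewer than 3 points or a collinear
  configuration (second singular value ≈ 0), and corrects reflections via
  the sign of the smallest singular vector.
* Nearest-neighbour distance ties resolve to the lowest target index, the
  same convention as the brute-force oracles in the tests.
* Empty slice results are allowed but logged; ICP refuses clouds that trim
  below 3 correspondences.
* All randomness flows through `with_seed()`, which restores the caller's
  RNG state; nothing in the package perturbs the user's session RNG.

## Limitations

The generator supplies what the comparison method relies on — smooth,
individually distinguishable hard-tissue geometry with less-stable soft
tissue around it — and nothing more. It does not model occlusal fissure
anatomy, restorations or orthodontic appliances (excluded from the emulated
study population), time-dependent biological change between AM and PM
records, scanner-specific artefacts, or partial scans. Accuracy figures on
synthetic cohorts therefore characterise the pipeline, not expected field
performance; validating the thresholds on real AM/PM material remains the
necessary next step before any forensic use.
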