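# odontomatch

Segmentation and registration strategies for 3D forensic dental
identification.

Forensic odontologists compare an antemortem (AM) dental record against a
postmortem (PM) one. With 3D surface scans the comparison can be made
objective: register the PM scan onto the AM scan with the iterative closest
point (ICP) algorithm and report the root-mean-square closest-point
deviation,

RMS = sqrt( (1/n) Σᵢ ‖ R pᵢ + t − qᵢ ‖² )   [mm],

where (R, t) is the fitted rigid transform and qᵢ the nearest AM point to
the transformed PM point pᵢ. Same-person scan pairs register to a small
RMS, different-person pairs do not, and a threshold on RMS classifies
match vs non-match. Because scanners also capture unstable soft tissue that
inflates the RMS of true matches, scans are segmented first. This package
implements the five strategies compared in that workflow:

1. **M1** no segmentation (control);
2. **M2** semi-automatic gingival reduction (tooth surfaces plus a small
   gingival collar), per scan, before registration;
3. **M3** manual gingival reduction (tooth surfaces only), per scan, before
   registration;
4. **M4** an individual planar slice per scan, before registration;
5. **M5** a **joint planar slice**: register the untrimmed scans first, cut
   both superimposed clouds with a single plane, then re-register — fewer
   steps, and the cut is consistent between the two scans by construction.

Around that core the package provides trimmed ICP with deterministic
principal-axes pre-alignment (`icp_register`), STL mesh I/O with a JSON
label sidecar (`read_stl`/`write_stl`), area-uniform surface sampling
(`sample_surface`), a synthetic dentition generator producing labelled
AM/PM cohorts with ground-truth transforms (`make_cohort`), the full
matching/non-matching study pipeline (`run_study`), and the decision
statistics (`fit_rms_cutoff`, `classify_match`, `boxcox_lambda`,
`pairwise_bonferroni`).

## A worked example

Generate a two-participant cohort (each participant contributes an upper
and lower arch, scanned as AM and as a degraded, arbitrarily placed PM
copy), compare one matching pair under the joint planar method, then run a
small study and fit the decision threshold:

```r
library(odontomatch)

cohort <- make_cohort(2, dentition_params(), degradation_params(), seed = 7L)
am <- cohort[[1]]; pm <- cohort[[2]]   # participant 1, upper arch, AM and PM

a <- sample_surface(am$mesh, 5000, seed = 7L)
b <- sample_surface(pm$mesh, 5000, seed = 7L, template = am$mesh)
compare_pair(a, b, "M5_JOINT_PLANAR", segmentation_params(),
             icp_params(sample_size = 5000L))
#> M5_JOINT_PLANAR: final RMS 0.0801 mm (4 iterations)

design <- study_design(methods = c("M1_NONE", "M3_MANUAL_GINGIVAL",
                                   "M5_JOINT_PLANAR"),
                       replicates_per_cell = 1L, sessions = 1L,
                       operators = 1L, seed = 7L)
tab <- run_study(cohort, design, icp = icp_params(sample_size = 5000L),
                 n_points = 5000L)
summarize_groups(tab)[, c("method", "is_match", "mean_rms")]
#>               method is_match mean_rms
#> 1            M1_NONE    FALSE   0.7381
#> 4            M1_NONE     TRUE   0.1107
#> 2 M3_MANUAL_GINGIVAL    FALSE   0.7620
#> 5 M3_MANUAL_GINGIVAL     TRUE   0.0757
#> 3    M5_JOINT_PLANAR    FALSE   0.7122
#> 6    M5_JOINT_PLANAR     TRUE   0.0854

seg <- tab[tab$method != "M1_NONE", ]
fit <- fit_rms_cutoff(seg$rms, seg$is_match)
fit
#> RMS cutoff 0.3335 mm (midpoint mode, perfectly separable), training accuracy 100.0%
classify_match(c(0.09, 0.52), fit$cutoff)
#> [1] "match"     "non-match"
```

Reading the numbers: matching pairs register to ~0.08–0.11 mm RMS —
highest without segmentation, since the PM gingiva is noisier than the
teeth; lowest for manual gingival reduction; the joint planar method close
behind (it keeps the stable papillae). Non-matching pairs sit near
0.7 mm, an order of magnitude above, so a single threshold in the gap
separates the classes perfectly and `classify_match` applies it (an RMS
exactly at the cutoff is conservatively a non-match).

A command-line front end for the same workflow ships in
`inst/cli/odontomatch` (`generate`, `compare`, `study`, `analyze`). The
methods vignette (`vignettes/dental-identification.Rmd`) documents the
model, the synthetic-cohort assumptions, and every tunable parameter.

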