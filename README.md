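# octburnscore

Assessing how deep a pediatric hand burn goes is one of the hardest calls
in burn care: superficial partial-thickness wounds heal under dressings
within two weeks, while full-thickness wounds need skin grafting, and the
clinical eye alone gets this wrong in both directions. Optical coherence
tomography (OCT) images the injured skin in cross-section to ~2 mm depth,
and dynamic OCT (D-OCT) maps blood flow in the papillary plexus — together
they reveal four morphological features that track burn depth.

`octburnscore` implements an additive 0–6 burn depth score built from
those four OCT/D-OCT features, plus everything needed to evaluate and
stress-test it without patient data:

| Feature | Grades |
|---|---|
| Surface irregularity | 0 smooth / 1 irregular |
| Loss of epidermis (dark band absent) | 0 / 1 |
| Dermal pattern — skin lines (glabrous) or papillary spots (hair-bearing) | 0 / 1 partial / 2 absent |
| Perfusion / microvascular network | 0 / 1 minor damage / 2 truncated vessels |

The score is the plain sum `S = s_surf + s_epi + s_dermal + s_vasc`:
0 is healthy skin, 6 a deep burn with destroyed dermal structure and
absent plexus. Scores 0–2 read as healthy/epidermal, 3–4 as
partial-thickness healing spontaneously, 5–6 as full-thickness needing a
graft; management is predicted by the threshold *score ≤ 4 → spontaneous
healing*.

The package has four layers:

* **Score model** — validated item grades, the additive score, depth
  bands, management threshold (`feature_grades()`, `compute_score()`,
  `classify_depth()`, `predict_management()`).
* **Cohort evaluation** — 2×2 confusion tables against the healing
  course, PPV/NPV/sensitivity/specificity/agreement with Wilson or exact
  (Clopper–Pearson) intervals, threshold sweeps, cohort summaries and
  inter-observer agreement with Cohen's κ (`build_confusion()`,
  `diagnostic_stats()`, `threshold_sweep()`, `interobserver_agreement()`).
* **Synthetic cohorts** — wound cohorts with a configurable score
  distribution, score-conditional outcomes and two-observer grading noise
  (`cohort_config()`, `generate_cohort()`).
* **OCT phantoms** — synthetic structural + vascular volumes with known
  ground-truth grades (rough surface, epidermal dark band, skin lines or
  papillary spots at the 0.3 mm en-face level, an arborizing vessel
  tree), and automated graders that close the loop from image to score
  (`phantom_spec()`, `generate_phantom()`, `grade_volume()`).

## Worked example

```r
library(octburnscore)

g <- feature_grades(1, 1, 2, 1, "glabrous")
g
#> OCT feature grades (glabrous skin): surface=1 epidermis=1 dermal=2 vascular=1 -> score 5
classify_depth(compute_score(g))
#> [1] "deep_graft"

coh <- read_cohort(system.file("extdata", "example_cohort.csv",
                               package = "octburnscore"))
cohort_summary(coh)
#> Cohort: 12 wounds in 11 patients
#> Scores 0-6: 0 0 1 3 5 2 1
#> Outcomes: healed_spontaneously=10  grafted=2  deep_refused_graft=0

diagnostic_stats(build_confusion(coh, threshold = 4))
#>        metric  estimate     lower     upper  x  n
#> 1         ppv 0.6666667 0.2076596 0.9385081  2  3
#> 2         npv 1.0000000 0.7008550 1.0000000  9  9
#> 3 sensitivity 1.0000000 0.3423802 1.0000000  2  2
#> 4 specificity 0.9000000 0.5958500 0.9821238  9 10
#> 5   agreement 0.9166667 0.6461201 0.9851349 11 12
```

Here 3 of 12 wounds scored above the threshold (predicted graft
candidates); 2 of those were actually grafted (PPV 0.67), all 9 wounds
predicted to heal did heal (NPV 1.00), and prediction agreed with the
healing course in 11/12 wounds (92%), each with its Wilson 95% interval.

The phantom loop works the same way in images:

```r
spec <- phantom_spec(skin_type = "hair_bearing", surface_roughness_um = 40,
                     epidermis_present = FALSE, dermal_pattern_level = 2,
                     vascular_level = 2, seed = 1,
                     field_mm = c(3, 3), depth_mm = 0.88,
                     voxel_um = c(dz = 8, dy = 24, dx = 24))
grade_volume(generate_phantom(spec), "hair_bearing")$score
#> [1] 6
```

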