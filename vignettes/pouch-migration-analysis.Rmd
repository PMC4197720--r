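---
title: "Quantifying pouch-cell migration and pharyngeal skeletal phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pouch-cell migration and pharyngeal skeletal phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pouchtrack)
```

## The biological problem

Zebrafish pharyngeal pouches form by collective lateral migration
("outpocketing") of endodermal epithelial cells: the first two pouches are
in place by 20 hpf and the remaining ones follow at roughly one per 4 h.
Each posterior ceratobranchial (CB) cartilage requires a neighbouring
pouch, so failed outpocketing propagates into missing or reduced facial
cartilage. Two kinds of quantitative readout attach to this system:

1. **cell tracks** from time-lapse recordings (centroid positions every
   10 min over a 6–7 h window), summarized per cell as velocity,
   directional persistence, and the distribution of deviation angles; and
2. **phenotype scores** per embryo side: the number of intact pouches
   (0–5 on a 0/1-per-pouch rubric) and the CB total (0–5.0 on a
   0/0.5/1.0 rubric with 1.5 per fusion of two adjacent elements).

This vignette describes the models and numerical conventions behind each
stage of the package's pipeline, the design choices taken where the
procedure was genuinely open, and what the synthetic-data tests do and do
not establish about real recordings.

## Track metrics

For a track with positions $p_1,\dots,p_n$ at times $t_1 < \dots < t_n$:

- **velocity** $= \sum_{i<n} \lVert p_{i+1}-p_i\rVert / (t_n - t_1)$,
  total distance traveled over elapsed time, in μm/min;
- **persistence** $= \lVert p_n - p_1 \rVert / \sum_{i<n}
  \lVert p_{i+1}-p_i \rVert$, net over total displacement, dimensionless
  in $[0,1]$ (1 = perfectly straight). A stationary cell makes the ratio
  0/0: such tracks return `NA`, are excluded from group summaries, and are
  counted in the summary's `n_persistence_excluded` attribute — stationary
  frames are real in epithelial data and silently scoring them 0 or 1
  would bias group means;
- **deviation angles**: the signed angle from each displacement vector to
  the next, iterating one position forward at a time, reported in degrees
  in $(-180, 180]$ with counter-clockwise positive and reversals mapped to
  $+180$. Triples containing a zero-length displacement carry no
  direction; they are skipped and counted rather than interpolated.

Only cells trackable through the whole analysis window are analysed:
`filter_complete_tracks()` keeps tracks with a point at or before the
window start and at or after its end and with no internal sampling gap
exceeding 1.5× the nominal interval, then crops them to the window. The
default window is 0–360 min (the 6 h filter); a 7 h window is a matter of
passing `window_end_min = 420`, since published figure legends and methods
for this kind of recording disagree between 6 and 7 h and the package
asserts neither.

Angle histograms use eight 45° bins on the half-open $(lo, hi]$ convention
(a boundary angle belongs to the bin it closes). Eight is conventional for
rose plots, divides 360, and keeps expected counts comfortably large for
the chi-square comparison; it is a default, not a constant. Signed angles
are kept so left/right turning asymmetry remains visible; `absolute =
TRUE` folds the sign for the common unsigned presentation. Deviation
angles are pooled across all cells of a group for histograms and the
chi-square test — per-cell aggregation before testing is available by
summarizing `deviation_angle_table()` yourself, as the field's wording on
this point ("number of cells moving in a particular direction") is
ambiguous either way.

All metrics are invariant under rigid motions of the field of view
(rotation + translation), which the test suite checks to 1e-9; this is
the basic sanity requirement for measurements made on an arbitrarily
oriented confocal section.

## The synthetic track generator

No tracking data ships with the package, so a seeded generator provides
tracks with the statistical structure the metrics assume. Each cell takes
steps of length $\max(0, \mathcal N(\mu_s, \sigma_s)) \cdot \Delta t$ (the
clamp at 0 being the simplest non-negative choice; default
$\mu_s = 0.3$ μm/min, $\sigma_s = 0.1$, free parameters rather than
calibrated claims, chosen to put 6 h path lengths at the ~100 μm scale of
pouch cell movements). Headings follow a biased persistent random walk:
the heading at each step has log-density

$$\kappa_p \cos(\theta - \theta_{\text{prev}}) + \kappa_b \cos(\theta - \theta_{\text{goal}}),$$

a von Mises law whose mean direction and concentration come from vector
addition of the persistence and bias pulls. The first heading is uniform.
This model was chosen because its two concentrations are independently
interpretable — $\kappa_b = 0$ removes directed migration while leaving
step-to-step smoothness intact, which is exactly the contrast between
mutant and wild-type pouch cells — and because its limits are clean:
$\kappa_p \to \infty$ with $\sigma_s = 0$ gives straight lines
(persistence $\to 1$ like $1 - O(1/\kappa_p)$ through residual heading
diffusion, so the test suite checks the limit at $\kappa_p = 10^8$), and
$\kappa_p = \kappa_b = 0$ is the isotropic random walk, cross-checked
against an independently coded oracle. Coordinates are 2D (recordings are
analysed as confocal sections) in mathematical convention: y up, angles
counter-clockwise, degrees.

Per-cell dropout truncates a track at a uniformly drawn interior time
point, emulating cells that cannot be reliably followed, so that the
complete-track filter has genuine work to do in tests and in the analysis
scripts.

Default class parameters for the analysis scripts put $\kappa_b = 5$
(wild type) against $\kappa_b = 0$ (mutant) at equal speeds, encoding the
observed phenotype — similar velocities, collapsed directionality — rather
than any measured concentration; 30 cells per group matches the scale of
cells tracked across two embryos per genotype.

## Phenotype scoring and its generator

The pouch rubric is binary per pouch (missing or >50% reduced = 0,
mis-shapen or normal = 1; the >50% judgment happens upstream at
annotation time — records arrive categorized). The CB rubric is 1.0 /
0.5 / 0 per element with a fused pair of adjacent elements contributing
1.5 **in total**: this reading keeps the wild-type maximum at 5.0 and
makes fusing two normal elements a net penalty of 0.5. Totals therefore
live on $\{0, 0.5, \dots, 5.0\}$. The embryo is the default unit of
analysis (left and right sides averaged first), matching how group sizes
are counted in this literature; `unit = "side"` is available.

The generator draws each pouch and CB state independently from
per-genotype categorical distributions. The four shipped classes encode
the printed group descriptions: wild type all normal; *tbx1* keeps only
p1 and loses all CBs; the single-mutant class survives p2–p5 each with
probability 0.75 (expected pouch score $1 + 4 \times 0.75 = 4$); the
double-mutant class with probability 0.25 (expected score 2), with CB
survival 0.375 targeting the "two to three ceratobranchials" mean of 2.5.
These probabilities were chosen once to match the printed group means
exactly in expectation and are overridable via
`phenotype_class_params()`.

Pouch-formation timelines are deterministic by default: p1 at 16 hpf, p2
at 20 (only the bound "by 20 hpf" is published for p1–p2; the 4 h spacing
is extended backward for consistency and is config-overridable), then 24,
28, 32, 36. The *tbx1* timeline contains only p1, so any recording window
from 26 hpf onward — the standard 26 + 10 h window — is empty, the
timeline analogue of arrested outpocketing.

## Statistics

- **Welch one-tailed *t***: `stats::t.test` with unequal variances and
  Welch–Satterthwaite df. The tail is the caller's statement of the
  directional hypothesis (the analysis scripts pass mutant first with
  `one_tailed_less`); it is a parameter, not a constant. The degenerate
  both-samples-constant case returns p = 0.5 (equal means, flagged) or a
  0/1 p (separated means) instead of erroring, so pipelines over many
  simulated groups never die on a corner case.
- **Chi-square independence** (`stats::chisq.test`, no continuity
  correction anywhere — simpler and directly checkable against the
  textbook formula). For two angle histograms the counts are stacked
  2 × bins and bins empty in both groups are dropped first, reducing the
  df, to avoid 0/0 expected counts.
- **Fisher's exact test**: in-package hypergeometric enumeration. The
  two-tailed p sums all tables (same margins) whose probability does not
  exceed the observed table's, with a relative tolerance of 1e-7 in the
  comparison so floating-point ties count as ties — the probability-mass
  convention. The suite checks exact agreement with `stats::fisher.test`
  for every 2×2 table with grand total ≤ 40.
- **Tukey–Kramer**: in-package studentized-range comparisons,
  $q = |\bar y_a - \bar y_b| / \sqrt{\mathrm{MSE}/2\,(1/n_a + 1/n_b)}$
  on the pooled within-group MSE with $N - k$ df, p-values from
  `stats::ptukey` (numerical studentized-range integration, accurate to
  well below 1e-6). Validated three ways: the k = 2 identity with the
  pooled two-sided *t*-test, equality with `TukeyHSD`, and a
  max-studentized-range permutation oracle on fixed unbalanced vectors.

## Test problem sizes and what passing shows

The suite calibrates the statistics at desk scale: 2,000 null replicates
for the Welch size check (one-tailed rejection at $\alpha = 0.05$ within
0.03–0.07), 200 same-parameter simulation pairs for the chi-square
angle-test size (rejection rate within 0.02–0.09), 100 replicates for the
bias-vs-no-bias persistence contrast (Welch p < 0.01 in ≥ 95%), 1,000
random tracks against brute-force metric oracles at 1e-9, and phenotype
round trips at n = 200 embryos within 3 standard errors of the
closed-form class means.

Passing these shows the pipeline is internally correct and calibrated
under the generator's assumptions — independent cells, stationary step
law, homogeneous groups, categorical phenotype states drawn
independently per element. Real recordings violate several of these
(cells interact mechanically, speeds drift with developmental stage,
annotation error correlates along a track, pouch states within an embryo
are not independent), so the tests certify the measurement and inference
machinery, not any biological effect size. Where a published quantity is
exact — the rubric arithmetic, the 4 h timeline spacing, the fused-pair
score of 1.5 — the tests assert it exactly.

## Known limitations

- Tracks are 2D; no 3D metrics, no track linking or gap closing, and no
  image processing — centroid annotation is upstream.
- The generator's speed scale is a free parameter; only contrasts
  (bias vs none) are meaningful, not absolute velocities.
- Tukey–Kramer is the only multiplicity correction provided, matching
  the scoring workflow it serves.
- The angle chi-square treats pooled steps as independent observations;
  within-cell correlation of consecutive angles makes it anticonservative
  for strongly persistent walks, which is why the null-calibration test
  simulates matched persistence in both groups.
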