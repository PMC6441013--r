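---
title: "Quantifying spheroid and single-cell electrotaxis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spheroid and single-cell electrotaxis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spherotax)
```

This vignette records the model, the numerical choices, and the design
decisions behind `spherotax`, in enough detail to re-derive every computed
quantity by hand.

## 1. Field configuration and quality control

A direct-current field in a microfluidic channel is applied by a current
source, so the controlled quantity is current, not field. For a channel of
height $h$ and width $w$ (cross-section $A = h\,w$) filled with medium of
conductivity $\sigma$, Ohm's law in a uniform conductor gives the set
current for a target field $E$:

$$ I_\mathrm{set} = E\,\sigma\,A . $$

Defaults: $h = 202\ \mu\mathrm{m}$, $w = 5\ \mathrm{mm}$,
$\sigma = 1.5\ \mathrm{S/m}$, so $E = 250\ \mathrm{V/m}$ requires
$378.75\ \mu\mathrm{A}$ and $E = 100\ \mathrm{V/m}$ requires
$151.5\ \mu\mathrm{A}$. `implied_field()` inverts the same relation to
convert a logged current back to a field.

`check_field_drift()` screens a time-stamped current log: each consecutive
pair of readings is converted to implied fields and the field change is
scaled to a per-4-h rate (a change of $\Delta E$ over $\Delta t$ hours counts
as $\Delta E \cdot 4/\Delta t$). An experiment fails QC if any interval
exceeds the threshold (default $20\ \mathrm{V/m}$ per $4\ \mathrm{h}$). The
per-pair scaling makes the verdict invariant to how often the log was
sampled, rather than rewarding sparse logging.

## 2. Single-cell tracking statistics

Tracks are tidy tables (`cell_id`, `time_h`, `x_um`, `y_um`) under the
anode-at-left convention: the unit field axis $\mathbf{u}$ points toward the
cathode (default $(1, 0)$), and the orthogonal axis is $\mathbf{u}$ rotated
$+90^\circ$, i.e. $(-u_y, u_x)$.

For consecutive positions $\mathbf{p}_{i}, \mathbf{p}_{i+1}$ the segment
vector $\mathbf{A} = \mathbf{p}_{i+1} - \mathbf{p}_{i}$ contributes the
scalar projection $\mathbf{A}\cdot\mathbf{u} = |\mathbf{A}|\cos\theta$, a
signed cathode-positive displacement. Two per-cell metrics:

- **mean projected rate**: each segment's projection divided by its duration,
  averaged over the cell's segments ($\mu\mathrm{m/h}$). Zero-length segments
  (a stationary cell between frames) are retained with projection 0 — a cell
  that does not move is evidence, not missing data.
- **net displacement**: $(\mathbf{p}_\mathrm{last} -
  \mathbf{p}_\mathrm{first})\cdot\mathbf{u}$, which by telescoping equals the
  sum of segment projections; the test suite asserts this identity to
  $10^{-9}$ on random tracks.

Cohort summaries (`glance()` on `cohort_metrics()`) report mean, SD, SEM and
$n$ per metric. Rotation equivariance (rotating tracks and axis together
leaves projections unchanged) and axis-flip antisymmetry are tested
properties, not assumptions.

## 3. Spheroid image pipeline

Each timepoint is a grayscale matrix with rows along the orthogonal axis and
columns along the field axis (column index increases toward the cathode).
The pipeline is registration → segmentation → frontiers → biases.

### 3.1 Registration

Stage drift between timepoints is modelled as a pure integer translation.
`register_timepoints()` computes the circular cross-correlation of the
mean-removed images by FFT, takes the top five candidate shifts, re-scores
each by exact normalized cross-correlation over the actual overlap region,
and returns the best. Sub-pixel registration is deliberately out of scope:
frontier positions are pixel quantized anyway, and integer shifts keep the
mirror-symmetry properties of the whole pipeline exact.

**The registration window matters.** If the whole frame is registered, the
correlation peak locks onto the aggregate itself — which is the largest,
brightest structure — and the estimated "drift" absorbs the aggregate's own
electrotactic translation, the very signal being measured. Registration must
therefore be restricted (via `fiducial_region`) to a window containing only
static structures: fiducial marks, channel walls, or debris fixed to the
substrate. The synthetic generator renders corner fiducial marks and returns
a suitable window in `truth$fiducial_region`. A featureless window (zero
variance, so NCC is undefined for every candidate) raises a
`spherotax_registration_failure` condition rather than silently returning a
garbage shift.

### 3.2 Segmentation

`segment_aggregate()` smooths with a separable Gaussian (default
$\sigma = 2$ px, replicate borders), thresholds with Otsu's method, applies a
morphological closing (disc, default radius 2) to seal boundary noise, and
keeps the largest connected component at or above `min_area_px` (default 50,
rejecting specks and single cells). The mask records whether it touches the
frame border, since frontiers of a clipped aggregate are lower bounds. A flat
image raises `spherotax_segmentation_failure`.

The Gaussian blur is hand-written rather than delegated: the symmetric
weight pairs are added innermost ($w_0 m + \sum_j w_j (m_{-j} + m_{+j})$),
which makes the result bit-exact under left–right and top–bottom mirror
reflection (IEEE addition is commutative; FFT-based filtering is not exactly
mirror-symmetric). The acceptance suite exploits this: mirroring a whole
image series negates the matching bias under `expect_identical`, not a
tolerance.

### 3.3 Frontiers and biases

From a mask, the four frontiers are the extreme occupied pixel coordinates,
converted to micrometres with 0-based pixel indexing: cathodal = maximum
column, anodal = minimum column, orthogonal / orthogonal′ = maximum / minimum
row. Shifts relative to $t = 0$ are **outward-positive** on every side
(cathodal: $c_t - c_0$; anodal: $a_0 - a_t$; similarly for rows), so uniform
growth gives four equal positive shifts. The directional metrics are

$$ \mathrm{bias}_\mathrm{cath} = \mathrm{shift}_\mathrm{cath} -
   \mathrm{shift}_\mathrm{anod}, \qquad
   \mathrm{bias}_\mathrm{orth} = \mathrm{shift}_\mathrm{orth} -
   \mathrm{shift}_\mathrm{orth'}, $$

and the proportional area change $(A_t - A_0)/A_0$ of the frontier bounding
box (width $\times$ height). A pure translation by $d$ toward the cathode
yields bias $2d$ and area change 0; these identities are unit tests. A
non-positive box extent raises `spherotax_degenerate_box`.

`analyze_series()` chains the stages over an image list and returns one row
per later timepoint, carrying QC columns (registration shift, mask area,
border contact) alongside the metrics.

## 4. Statistics

- `two_sample_ttest()`: pooled-variance two-tailed Student $t$ by default
  (the classical small-$n$ choice for matched experimental designs); Welch
  behind `welch = TRUE`.
- `holm_sidak_adjust()`: step-down Holm–Šidák. With sorted p-values
  $p_{(1)} \le \dots \le p_{(m)}$, the $k$-th adjusted value is
  $1 - (1 - p_{(k)})^{m - k + 1}$, enforced monotone by a running maximum,
  then unsorted. Hand-implemented because base R's `p.adjust` offers Holm
  (Bonferroni-style) but not the Šidák variant; a literal brute-force
  implementation is the test oracle.
- `bh_adjust()`: Benjamini–Hochberg via `stats::p.adjust`, verified against
  the literal step-up formula in tests.
- `frontier_comparison()`: two-factor linear model
  `value ~ frontier * condition` with Type II sums of squares (`car::Anova`);
  Type II is appropriate because the design is (near-)balanced and the
  interaction is itself a quantity of interest, not a nuisance. Per-frontier
  condition contrasts come from `emmeans`, unadjusted, then Holm–Šidák is
  applied across the whole contrast family at once (one family per
  comparison, not per frontier). Significance stars follow the
  \*\*\*\*/\*\*\*/\*\*/\*/ns convention at $10^{-4}, 10^{-3}, 10^{-2}, 0.05$.
  Under pure noise the condition effect's empirical false-positive rate over
  500 replicates is required to fall in $[0.02, 0.09]$ at $\alpha = 0.05$.

## 5. DE ranking

`filter_de()` keeps records with $q < 0.05$ (strict) and fold change
$\ge$ 2 (i.e. $|\log_2 \mathrm{FC}| \ge 1$; boundary kept). When several
transcripts map to one gene symbol, `collapse_by_symbol()` keeps the one
with the lowest raw p-value, breaking ties lexicographically on transcript
ID so the result is deterministic; records with empty symbols are set aside
with a warning. `signed_rank_scores()` emits
$\mathrm{sign}(\log_2\mathrm{FC}) \cdot (-\log_{10} q)$; a reported $q = 0$
(an artefact of finite precision in upstream tools) is floored to half the
smallest nonzero $q$ in the table so the score stays finite while remaining
the most extreme. Base 10 keeps scores interpretable as orders of magnitude.
`write_rnk()` writes the GSEA `.rnk` convention: two tab-separated columns,
no header. `shared_de_correlation()` filters and collapses two tables,
intersects on symbol, and reports Pearson $r$ over shared
$\log_2\mathrm{FC}$, erroring (`spherotax_insufficient_overlap`) below 3
shared genes.

## 6. Synthetic generators

The generators exist to give every pipeline stage a ground truth; defaults
mirror the intended study conditions and are **not** tuned to the analysis.

- `simulate_tracks()`: Brownian steps (SD `step_noise_sd` = 2 µm per 0.25 h
  frame) plus deterministic cathodal drift (`drift_um_h` = 13) over 2 h,
  $n = 20$ cells. Truth includes the expected net cathodal displacement.
- `simulate_spheroid_series()`: an ellipse with half-width
  $r_0 + g t$, half-height $r_0 + (g - \rho)t$, and centre drifting
  cathodally at $b$ µm/h, so the true cathodal bias is exactly $2bt$ and the
  true frontiers are analytic. The boundary gets per-vertex radial noise,
  the polygon is rasterized by an even-odd scanline rule, the frame gets a
  per-timepoint global translation (simulated stage drift) applied to scene
  *and* fiducial marks, plus Gaussian intensity noise. Defaults
  ($r_0 = 100$ µm, $g = 2$, $b = 1.4$, pixel 2 µm, frames 0/8/24 h) produce a
  24-h cathodal bias of 67.2 µm. What it does **not** emulate: rotation or
  scale drift, uneven illumination, out-of-focus frames, aggregates
  splitting or merging.
- `simulate_de_tables()`: planted significant genes
  ($q \in [10^{-6}, 0.04]$, $|\log_2\mathrm{FC}| \ge 1.2$) against a null
  background ($q \in [0.06, 1]$, $|\log_2\mathrm{FC}| < 0.9$), with
  multi-transcript collisions whose non-best transcripts have inflated p,
  and optionally a paired second table with fold changes correlated at
  `cross_correlation` (default 0.94).
- `simulate_current_log()`: implied-field drift at a chosen rate per 4-h
  window, for exercising the QC criterion from both sides.

All generators take a `seed` and are reproducible via `withr::with_seed`.

## 7. Validation scope and limitations

Problem sizes used in validation: masks up to $64 \times 64$ against a
brute-force frontier scan (100 random cases); a bias grid of
$\{-40, \dots, 40\}$ µm $\times$ 10 seeds recovered within 2 px with
monotone means and $\ge 95\%$ sign accuracy; 100 registration trials at
shifts up to $\pm 10$ px under 5%-of-range noise with $\ge 95\%$ within
1 px; 500-replicate ANOVA size checks; 1000-gene DE tables with exact
planted-set recovery.

Known limitations: translation-only, integer-pixel registration; frontier
metrics reduce the mask to its bounding extremes and ignore shape;
segmentation assumes a single dominant aggregate brighter than background;
the drift QC assumes conductivity is constant over the experiment; border-
touching masks are flagged but not corrected.
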