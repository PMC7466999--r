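---
title: "Methods: dynamic colony-fitness screening with growscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic colony-fitness screening with growscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, the parameters
that matter, the numerical choices behind them, and what the bundled
simulator does and does not establish about real data.

## The measurement model

A plate of arrayed colonies is photographed at 5-minute intervals. For each
frame, the pipeline:

1. **Smooths** the image with Perona–Malik anisotropic diffusion
   (`smooth_image()`): intensity is exchanged between 4-neighbors with
   conductivity $g(d) = \exp(-(d/\kappa)^2)$ on the intensity difference
   $d$. The update is written in flux form (equal and opposite exchange
   across each pixel edge, Neumann boundaries), so the total image
   intensity is conserved exactly — important because the downstream
   quantity is a *sum* of pixel intensities. Defaults: 5 iterations,
   $\lambda = 0.25$, and $\kappa$ = 10% of the frame's dynamic range. The
   $\kappa$ default matters: colony borders on a dense plate contribute a
   non-trivial share of all gradients, so a percentile-based $\kappa$ can
   land *on* the border gradients and smear edges (we measured ~8% of
   colony mass leaking into the surround); a dynamic-range fraction stays
   three orders of magnitude below border gradients while remaining far
   above pixel-noise gradients.
2. **Segments** each colony by half-mode-max thresholding
   (`segment_colony()`): threshold $T = m + (\max - m)/2$, where $m$ is the
   background mode of the integer-binned intensity histogram. The mode is
   estimated once per *frame*: in a 9×9 window on a 6144-density array a
   mature colony occupies about half the pixels and its flat plateau wins
   the window histogram, which silently inverts the rule; background always
   dominates the whole frame. The mask is the 4-connected component
   containing the window center (nearest component if the center pixel is
   below threshold; ties go to the larger component — deterministic). A
   flat window yields an empty mask, not an error.
3. **Measures** area (pixel count) and intensity (sum of member pixel
   values, no background subtraction), per `measure_colony()`.

Grid placement is manual by design (`fit_grid()`): four corner anchors per
plate, bilinearly interpolated to an $n_r \times n_c$ lattice, fitted once
and reused for all frames. Automatic gridding is a non-goal.

### Spatial plate-effect correction

`spatial_correct()` removes two artifacts multiplicatively. *Border stage*:
colonies in the outermost two rows/columns overgrow (extra nutrient
access); they are rescaled by `median(interior)/median(border)`, which by
construction restores the border median exactly. *Spatial stage*: a smooth
surface $S$ is the 9×9 moving median (edge-truncated) of the
border-adjusted matrix, and each value becomes $v \cdot \mathrm{med}(S) /
S$. The correction is multiplicative because the dominant physical effects
(illumination, agar thickness) scale intensity; normalizing to the plate
median preserves the plate's location (within 1%) and makes the operation
idempotent on smooth fields up to edge-window bias. A 9×9 median tracks
plate-scale gradients while ignoring minority structure; note the corollary
that a *single* anomalous row is a minority in every window and is
deliberately not "corrected" — it is signal, not a plate artifact. An
all-zero matrix is returned unchanged with a warning flag. `NA` entries
(positions without a colony) pass through.

In the curve-level pipeline (`compute_growth_metrics()`), correction
factors are estimated once per plate from the final retained frame — where
colonies are brightest and the field is best resolved — and applied to the
whole trajectory. For a bias field that is static in time (the case the
correction targets) this equals per-frame correction at a fraction of the
cost; per-frame `spatial_correct()` remains available at the image stage.

## From trajectories to metrics

Per colony, in order (the order matters and is fixed):

1. **Truncation** to the first 40 h (`max_hours`): overgrowth corrupts
   later frames. With 5-minute frames that keeps 481 timepoints.
2. **Robust smoothing** (`smooth_curve()`): LOWESS — locally weighted
   linear regression over a centered, edge-truncated window of 48
   timepoints (4 h) with bisquare robustness iterations, which down-weight
   transient artifacts such as reflections or condensation. Backed by
   `stats::lowess`; the wrapper short-circuits to the non-robust fit when
   the initial fit's residual scale is ~0 (the robustness pass of the
   underlying routine degenerates on exactly-zero residuals). Local linear
   fits are exact on linear data; `window = 1` is the identity.
3. **Zero-normalization**: subtract the first smoothed value; clip
   negatives to 0. The first value is used (not the minimum) because the
   intent is "intensity zero at the start of imaging".
4. **Colony fitness** = the final value of this curve.
5. **Dead-colony rule**: colonies whose final value is below
   `min_final_frac` (default 1%) of the plate median final intensity never
   grew; they are flagged and excluded from the reference and the metric
   table (reducing replicate counts upstream of the replicate filter).
6. **Endpoint normalization**: divide by the final value (exactly 1 at the
   end) — progress as a fraction of final intensity.
7. **Reference curve**: the per-timepoint median over the plate's
   endpoint-normalized curves, per plate and condition. The median is taken
   in normalized space because the deviations are formed there; a raw-space
   median would conflate size with dynamics.
8. **lagVstall**: the *signed* (not absolute) sum of per-timepoint
   deviations from the reference, with no $\Delta t$ weighting — with
   uniform 5-minute spacing a trapezoid integral differs only by a constant
   factor, and the sum convention keeps the printed magnitudes in
   "timepoint" units. Signedness is what lets lag (negative) and stall
   (positive) be distinguished.

Growth rates (`growth_rate()`, dPI/dT in intensity per minute) use central
differences on the smoothed curve, one-sided at the edges.

## Differential screening

`differential_screen()` is the fitting-style entry point and returns a
classed object with `print`/`summary`/`plot` methods.

* **Replicate pooling and filtering**: colonies of a strain at several
  plate positions are extra replicates (`merge_duplicates()`); strains with
  fewer than `min_reps = 6` replicates in *either* condition are removed
  entirely (`filter_replicates()`).
* **Robust Z-scores** (`robust_z()`): $(x - \mathrm{median})/\mathrm{MAD}$
  with the unscaled MAD (no 1.4826 factor) — the scored population has
  median exactly 0 and MAD exactly 1. Scoring is per plate × condition,
  which absorbs plate effects; each strain is summarized by the median of
  its replicate Z-scores, and `delta_z` is the treated minus untreated
  median Z.
* **The test**: a pooled-variance, two-sided, two-sample t-test per strain
  and metric (`two_sample_t()`), with explicit degenerate handling (zero
  pooled variance: p = 1 for equal means, p = 0 flagged otherwise). The
  test runs on *plate-median-centered* values whose per-strain contrasts
  are additionally centered at the across-strain median contrast. Both
  centerings address measured artifacts of population-relative metrics:
  (i) when responder strains reshape the treated population, the treated
  reference curve and plate median shift, handing every null strain an
  identical spurious contrast; plate-median centering removes the additive
  part and the median-contrast centering removes the residual that leaks
  through the plate median itself. A per-condition MAD *rescale* inside the
  test statistic is deliberately avoided: condition-specific scale
  estimates differ systematically under composition change and would
  multiply each strain's persistent offset into a spurious contrast, while
  the t statistic is invariant to any common rescaling anyway. The null
  hypothesis actually tested is therefore "this strain responds like the
  typical strain" — which is the screening question. Z-scores remain the
  reporting scale (`delta_z`, direction).
* **Storey q-values** (`storey_qvalues()`): $\pi_0$ estimated from
  $\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))$ on $\lambda = 0,
  0.01, \ldots, 0.90$, smoothed with a natural cubic smoothing spline (3
  df) and evaluated at the largest $\lambda$, clipped to $(0, 1]$. A cubic
  *polynomial* was considered and rejected: fitted to the hockey-stick
  shape of $\pi_0(\lambda)$ under strong signal it undershoots the plateau
  at the boundary (measured 0.85 against a true 0.94), making q-values
  anti-conservative. The step-up construction $q_{(i)} = \min_{j \ge i}
  \pi_0 m p_{(j)}/j$ is monotone and reduces exactly to Benjamini–Hochberg
  when $\pi_0 = 1$ (a test oracle). q-values are computed separately per
  metric — each metric is its own hypothesis family, and nominations are
  reported per metric.
* **Nomination**: strains with q < 0.05 per metric; the union,
  intersection, and exclusive counts are all reported, since a union of two
  level-$q$ families controls FDR only at about $2q$ — the per-family sets
  are the ones with the nominal guarantee.
* **Percentile tails** (`tail_select()`): tail size
  $\lceil p/100 \cdot N \rceil$, ties broken by strain identifier —
  deterministic by construction.

## The synthetic experiment generator

`simulate_curves()` produces fully labeled experiments with the statistical
structure the pipeline assumes; it is first-class, tested code, not a
fixture. Colonies grow logistically,
$I(t) = K/(1 + e^{-r(t - t_m)})$, evaluated piecewise in closed form
between breakpoints (treatment pause, stall onset), so noiseless
trajectories are analytically exact. Defaults mirror the screening
protocol: 5-minute frames for 48 h (577 frames), treatment immediately
after frame 48 (4 h), 11 replicate plates per condition, 16×24 plates;
reference-class parameters $K = 10^5$ intensity units, $r = 0.008$/min,
$t_m = 1000$ min — the reference saturates comfortably inside the 40-hour
window, as real arrays do before overgrowth.

Class phenotypes (`phenotype_specs()`):

* **lag**: rate halved, midpoint +240 min — below the population
  throughout, negative lagVstall.
* **stall**: growth rate multiplied by `post_stall_rate_fraction` = 0.02
  from `stall_time` = 1000 min. The fraction is deliberately near zero: in
  a saturating regime, a milder collapse (say 0.2) leaves enough post-stall
  growth that the endpoint-normalized curve is *not* consistently above the
  reference and the lagVstall sign becomes indeterminate — the
  near-plateau is what produces the canonical "tracks the population, then
  stalls" shape. The stall is intrinsic to colony progress (resource
  exhaustion), so a treatment pause occurring before it delays it by the
  pause duration; anchoring it to wall clock would turn every stall strain
  into a spurious treatment responder.
* **uvr_sensitive**: a 600-min growth pause after treatment plus a treated
  carrying-capacity factor of 0.6 (the UV-killed cell fraction). The
  capacity term is needed on first principles: once curves saturate within
  the window, a pure time shift leaves the 40-h endpoint essentially
  unchanged, so a pause alone cannot produce the negative colony-fitness
  response that defines sensitivity.
* **uvr_resistant_stall**: a stall strain whose post-stall rate fraction
  rises to 0.3 under treatment — treatment releases the stall. The release
  *raises* treated colony fitness (positive CF response) and *lowers*
  treated lagVstall: the higher final intensity deflates the early
  fractions of the endpoint-normalized curve. Both signs are mechanically
  forced by endpoint normalization and are asserted against noiseless
  closed-form curves in the tests.

Non-responder classes have **no** treatment response (pause 0, identical
parameters in both conditions): a strain labeled non-responder must have
the same data-generating distribution under both conditions, otherwise the
labels cannot serve as statistical ground truth for recall/FDR evaluation.
An earlier design with a universal post-UV "shock" pause was removed for
exactly this reason.

Heterogeneity and noise: strain-level jitter ($t_m$ sd 30 min, $\log K$ sd
0.05, shared by all replicates of a strain in both conditions),
replicate-level jitter ($t_m$ sd 15 min, $\log K$ sd 0.03), multiplicative
lognormal measurement noise per timepoint ($\sigma = 0.05$), and a smooth
random low-order polynomial multiplicative bias field per plate (amplitude
0.10). All randomness derives from one seed through substreams keyed by
stable string hashes of (plate, row, col) or strain id, so layouts can
change without reshuffling unrelated colonies, and identical seeds give
bit-identical output.

`render_plate_images()` draws each colony as a flat disk (radius 3.5 px at
10 px spacing) whose pixel values sum exactly to the programmed intensity
(noiseless truth × plate bias), over a constant background (default 2) with
optional Gaussian pixel noise (default sd 20). Flat disks rather than
Gaussian blobs: half-mode-max thresholding keeps the entire plateau of a
flat profile, so segmentation loss is not confounded with profile shape.

### What the simulator does and does not establish

It emulates: logistic-family dynamics with lag/stall/treatment phenotypes,
replicate structure across plates, plate-level multiplicative spatial bias,
multiplicative measurement noise, and image formation as additive disks
plus Gaussian noise. It does **not** emulate: colony morphology and
merging, lid reflections or condensation, camera vignetting or focus drift,
pinning failures, agar drying, diauxic-shift rate structure beyond the
two-phase approximation, or position-dependent nutrient competition.
Passing tests therefore demonstrate that the *pipeline arithmetic* recovers
programmed truth under the stated noise model — not that the method is
robust to every artifact of a physical imaging rig.

## Numerical choices and degenerate inputs

* Curve tables must share a uniform time grid; violations raise an
  alignment error rather than silently interpolating.
* `endpoint_normalize()` refuses division by ~0 via the dead-colony flag;
  `robust_z()` raises a degenerate-scale error when the MAD is 0;
  correlation on zero-variance input is an error, not `NA`.
* Coordinates are 0-based row-major internally; all written files use
  1-based rows/columns (bench convention).
* CSV writers print doubles with `%.17g`, so round-trips are lossless; all
  outputs carry a `# config_hash:` header (the hash excludes the output
  directory, so re-running into a different folder is byte-identical).
* Tie-breaks are deterministic everywhere (segmentation components by area,
  percentile tails by strain id).

## Problem sizes used in the tests

The test-suite experiments use 1000 strains × 11 replicates per condition
for the statistical end-to-end checks (two independent experiments, pooled,
for FDR estimation — single-experiment FDR estimates on ~50 responders
have a standard error of several points), a 16×24 plate × 50 frames for the
image round trip, and smaller plates (24–48 strains) for mechanical unit
checks. These sizes give stable estimates at interactive runtimes; the
pipeline itself has no size limits beyond memory.

## Known limitations

* lagVstall is population-relative: treatment effects common to the whole
  plate cancel by construction, and composition changes among responders
  leak slightly into every strain's score (mitigated, not eliminated, by
  the contrast centering described above).
* Endpoint normalization makes "grows better late" *lower* the metric —
  the lagVstall sign of a treatment response is not monotone in "healthier"
  (the resistant-stall class is the worked example).
* The hypergeometric enrichment treats gene sets as fixed and flat; no
  ontology propagation (GMT input only), no term-size weighting.
* Pooled-variance t-tests assume comparable replicate variances across
  conditions; with 6–11 replicates per side this is adequate but not
  robust to gross variance changes under treatment.
* The image stage assumes a fixed grid per plate series and colonies that
  stay within their windows; colony merging at very late timepoints is the
  reason for the 40-hour truncation, not something the segmenter handles.
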