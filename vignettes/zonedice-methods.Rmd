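---
title: "Methods: tolerant Dice, zone repair and the phantom cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tolerant Dice, zone repair and the phantom cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zonedice)
```

## Scope and data model

`zonedice` evaluates volumetric binary segmentation masks of prostate-cancer
lesions. Its mask currency is the `binary_volume`: a 3-D logical array plus
the physical voxel spacing in millimetres and any header metadata carried
through from NIfTI. Prostate MRI grids are strongly anisotropic — in-slice
spacing of roughly 0.4–0.8 mm against 2.5 mm between slices — so every
physical-unit operation weights each axis by its spacing. Two masks are
compatible only when shape and spacing match exactly; nothing in the package
ever resamples silently. Coordinates are voxel centres at 0-based indices
scaled by spacing; all reported volumes are voxel counts times the voxel
volume in mm³.

## The tolerant Dice Score Coefficient

For predicted mask $P$ and ground truth $G$, with voxel counts
$TP = |P \cap G|$, $FP = |P \setminus G|$, $FN = |G \setminus P|$:

$$\mathrm{DSC} = \frac{2\,TP}{2\,TP + FP + FN}, \qquad
\mathrm{DSC}_\tau = \frac{2\,TP}{2\,TP + FN_\tau + FP_\tau}$$

where $FN_\tau = |G \setminus \delta_\tau(P)|$ and
$FP_\tau = |P \setminus \delta_\tau(G)|$, and $\delta_\tau$ dilates a mask by
the physical tolerance $\tau$. The error terms forgive boundary disagreement
within $\tau$; $TP$ stays strict, so proximity is never rewarded as overlap.
Immediate consequences, all enforced as tests: $FP_\tau \le FP$ and
$FN_\tau \le FN$; $\mathrm{DSC}_\tau \ge \mathrm{DSC}$ wherever defined, with
exact equality at $\tau = 0$; $\mathrm{DSC}_\tau$ is non-decreasing in $\tau$;
and both metrics are symmetric under swapping $P$ and $G$ (the tolerant error
terms exchange roles).

**Default tolerance.** $\tau = 5$ mm, the pitch of the standard biopsy grid
whose placement error motivates tolerating boundary disagreement of that
magnitude. It is a per-run parameter.

**Corner cases.** When both masks are empty the denominator of either metric
is zero and the value is undefined (`NA`); such patients are excluded from
metric aggregation and instead counted by the false-positive-patient rate.
When $TP = 0$ but both tolerant error terms vanish — disjoint masks closer
than $\tau$ — $\mathrm{DSC}_\tau$ is defined as 0: a complete miss stays a
miss, preserving the strict reading of detection. The alternative (scoring 1)
would reward predictions that never touch the lesion; we consider that
indefensible for a detection-oriented metric, and flag the choice here
because the convention is not forced by the formula.

## Morphology on anisotropic grids

The dilation inside the metric is implemented as a threshold on the
anisotropic Euclidean distance transform (squared distances, separable
lower-envelope algorithm, linear time in the voxel count, compiled): a voxel
belongs to $\delta_\tau(M)$ iff its centre lies within $\tau$ of some
foreground voxel centre. For solid regions this is exactly "make the region
wider by $\tau$" and avoids committing to any particular discrete kernel; an
explicit structuring-element path (`structuring_element()`,
`dilate_with_element()`, ball or annulus) is retained for A/B comparison and
agrees with the distance-transform path on solid masks.

Ties at exactly $\tau$ are included ($\le$), the natural reading of "within a
5 mm radius". At the binary-fraction spacings of these grids (0.5, 2.5 mm)
the squared distances are exact in double precision, so the inclusive
threshold involves no floating-point ambiguity; the test suite checks exact
integer agreement with an all-pairs brute-force oracle across hundreds of
random grids.

Zone post-processing instead uses *voxel-unit* ball kernels, because the
upstream zone-segmentation workflow states its kernels in pixels on
isotropically resampled grids: `dilate_voxel()` and `closing_voxel()` ignore
spacing by design. Closing emulates the operator on an unbounded lattice by
padding the grid internally by the kernel radius; this keeps closing
extensive and idempotent instead of eroding in from the image border, the
usual artifact of finite-grid implementations. Stand-alone `erode_voxel()`
treats outside-the-grid as background (a voxel survives only if its whole
ball is foreground), the conservative convention.

Connected components default to 26-connectivity — the full 3-D
neighbourhood, the natural notion of "one lesion" for blobby structures; 6
and 18 are available wherever components are computed.

## Zone-mask repair

Upstream TZ/PZ segmentations leave gaps between the zones and overlap each
other. The repair composes three set operations per zone, with ball kernels
of radius 5 (dilation) and 10 (closing) voxels by default — empirically
chosen sizes that fill small inter-zone gaps without deforming the anatomy:

$$f_{PZ}(PZ, TZ) = \mathrm{dilate}(PZ) \wedge \mathrm{closing}(PZ \vee TZ)
  \wedge \lnot TZ$$
$$f_{TZ}(PZ, TZ) = \mathrm{dilate}(TZ) \wedge \mathrm{closing}(PZ \vee TZ)
  \wedge \lnot f_{PZ}(PZ, TZ)$$

The dilation fills gaps toward the other zone; conjunction with the closing
of the zone union confines the filling to the space *between* the zones; the
final negation makes the outputs disjoint. The negated term in $f_{TZ}$ is
the *processed* PZ, so precedence is PZ-first: a contested voxel goes to the
repaired PZ, and the repaired TZ takes what remains. Four properties follow
algebraically and are asserted on random faulty phantoms: $f_{PZ}$ never
intersects the raw TZ; $f_{TZ}$ never intersects $f_{PZ}$; the raw TZ
survives into $f_{TZ}$; and the output union stays inside the closing of the
input union. Refinement against the gland mask (`refine_with_prostate()`,
plain intersection) is kept separate because the upstream workflow uses
refined zones for training but unrefined ones for evaluation.

## Biopsy-confirmed ground truth

The evaluation ground truth is the subset of manually delineated lesions
(connected components of the manual mask) confirmed by a malignant biopsy,
under two rules: the lesion intersects a malignant biopsy mask, or a
malignant biopsy voxel lies within 5 mm of the lesion. Benign and
undetermined biopsies never confirm. The 5 mm radius again encodes the biopsy
grid pitch; setting it to 0 reduces confirmation to pure intersection. The
distance is measured voxel centre to voxel centre against the lesion's
nearest voxel (surface, not centroid — the natural reading of "around the
lesion"), inclusive at the boundary. Confirmation never adds voxels: the
ground truth is always a subset of the manual delineation.

A case is flagged *inconsistent* when an unconfirmed delineation coexists
with malignant biopsies elsewhere — the pattern used to exclude a patient
during cohort construction; the flag is reported and exclusion left to the
caller.

Lesions are assigned to the zone holding the majority of their voxels. Exact
ties break toward PZ, the zone with the substantially higher prior lesion
prevalence (roughly four in five lesions arise there); both overlap counts
are reported so callers can resolve ties differently.

## Ensembles and lesion-level accounting

Zone-specific models receive zone-masked inputs (`apply_region_mask()`), and
ensembles combine member outputs by voxelwise disjunction: `ensemble1` =
`tz_t2 ∨ pz_adc_dwi`, `ensemble2` = `tz_all ∨ pz_all`, `ensemble3` =
`tz_all ∨ pz_all ∨ prostate_all_zones`, `ensemble4` =
`pz_all ∨ prostate_all_zones`, against the whole-gland `baseline`. Because
the member sets of ensemble 3 ⊇ ensemble 4 ⊇ {baseline}, the outputs form a
voxelwise superset chain, so per-patient missed-lesion counts are
non-increasing and spurious-focus counts non-decreasing along it — the
structural reason disjunction ensembles accumulate false positives. A
majority-vote combiner is included as an explicitly labelled extension;
disjunction is the evaluated scheme. Whether member outputs should be hard
clipped to their zone before combination is not settled upstream; both
behaviours are supported (`clip=`), default off.

Lesion matching is overlap-based with a 1-voxel threshold (the literal
criterion; a configurable minimum exists): a ground-truth lesion overlapped
by no predicted component is *missed*, a predicted component overlapping no
ground-truth lesion is a *spurious focus*, and the number of predicted
components overlapping one lesion is its *fragmentation* (reported, not
penalized). A single predicted component spanning two lesions detects both
and is not spurious. The false-positive-patient rate divides by the
lesion-free subcohort only; missed-lesion percentages divide by the
lesion-bearing subcohort; spurious-focus percentages by the whole cohort.

## Statistical comparison

Patients are blocks, methods are treatments, one observation per cell — an
unreplicated complete block design, assembled by `metric_matrix()` after
listwise dropping patients with undefined metrics. The Friedman test uses
the tie-corrected statistic
$T_2 = (k-1)\sum_j (R_j - n(k+1)/2)^2 / (A_1 - C_1)$ with $A_1$ the sum of
squared within-block ranks and $C_1 = nk(k+1)^2/4$, referred to
$\chi^2_{k-1}$; without ties this reduces to the classical
$\frac{12}{nk(k+1)}\sum_j R_j^2 - 3n(k+1)$, and the suite verifies exact
agreement with `stats::friedman.test` there. Ties matter here because Dice
values tie at 0 whenever several methods miss a patient entirely, which is
why the corrected form is the default rather than base R's uncorrected one.

The Conover post hoc for this design compares rank sums pairwise with

$$t_{ij} = \frac{|R_i - R_j|}
  {\sqrt{\dfrac{2n(A_1 - C_1)}{(n-1)(k-1)}
         \left(1 - \dfrac{T_2}{n(k-1)}\right)}}$$

on $(n-1)(k-1)$ degrees of freedom, with Benjamini–Hochberg adjustment of the
two-sided p-values by default. Degenerate inputs are handled explicitly:
identical columns give statistic 0 and all pairwise p-values 1; perfect
separation (the variance factor reaching 0 with a nonzero rank difference)
gives p → 0. The suite checks the implementation against an independently
coded scalar reference to 10⁻⁹.

Fold assignment stratifies by lesion-bearing status: positives are dealt
round-robin into a seeded random fold order, and negatives then top folds up
to totals that differ by at most one. For the default cohort of 42 positives
and 77 negatives at $k = 5$ this yields fold sizes 24, 24, 24, 24, 23 with
positives split 9/9/8/8/8. The protocol runs on per-patient values pooled
across folds (the blocked-by-patient reading); per-fold aggregation is
available through the per-fold columns of the reports.

## The phantom cohort

Clinical prostate datasets of this kind are private, so the package ships a
generator that emulates the study conditions end to end. Defaults, chosen
once as the conditions the pipeline is meant to face:

* **Cohort composition**: 119 patients — 77 lesion-free, 36 with one lesion,
  6 with two (42 lesion-bearing in all).
* **Geometry**: 96×96×20 voxels at 0.5×0.5×2.5 mm (a 48×48×50 mm field of
  view), an ellipsoidal gland of ~18×15×14 mm semi-axes jittered ±10% per
  patient, an inner-ellipsoid TZ at 50–60% of the gland's linear size with
  the PZ as the surrounding shell. The grid size is the package's choice of a
  desk-scale working volume that still holds a realistic gland and a 5 mm
  biopsy grid.
* **Zone faults**: a gap of 2 mm between TZ and PZ in the superior half and a
  2 mm overlap in the inferior half by default; both widths are parameters,
  and width 0 gives an exact partition — the fixture contract the zone-repair
  tests rely on.
* **Lesions**: blobby unions of spheres, 250–4000 mm³ targets (the scale of
  clinically significant lesions; sizes shrink when a large lesion cannot fit
  its zone), ~20% placed in TZ per the epidemiological zone imbalance,
  pairwise disjoint as 26-connected components by construction.
* **Biopsies**: grid nodes at 5 mm pitch in-plane and every other slice
  (5 mm at 2.5 mm slices), jittered origin, trimmed to the gland and thinned
  to ~15 per patient; nodes inside true lesions are malignant, the rest
  benign or (10%) undetermined. Every true lesion is guaranteed at least one
  interior malignant biopsy, so planted truth is exactly recoverable; decoy
  delineations (unconfirmed lesions added to the manual mask for 25% of
  lesion-bearing cases) keep more than the confirmation radius away from all
  malignant biopsies.
* **Predictions**: each of five simulated methods degrades the truth with
  per-lesion boundary jitter (magnitude drawn between half and all of the
  method's jitter parameter, so a nonzero setting always moves at least one
  voxel at these spacings), whole-lesion drops, zone restriction for
  zone-specific methods, and spurious blobs drawn from a per-case pool of
  well-separated candidate sites shared across methods. The shared pool
  keeps every planted blob its own connected component even after ensembles
  take unions — the property that makes lesion-level counts exactly
  checkable. The baseline profile drops more lesions but plants fewer
  spurious foci, mimicking an under-detecting but specific whole-gland
  model.

Determinism: each case derives its stream from `(seed, case_index)` by
integer mixing, so generation is bit-reproducible and order-independent, and
every stochastic entry point restores the caller's RNG state.

**What the phantom does not emulate** — and hence what passing tests do not
show about clinical data: MR intensities and their artifacts (the phantom
produces masks, never images), registration error between biopsy and MRI
spaces, inter-observer delineation variability beyond simple geometric
jitter, anatomically realistic zone shapes (ellipsoids stand in for the true
anterior fibromuscular and apex/base geometry), and correlated errors
between methods (the simulated methods err independently given the shared
spurious sites). Metric behaviour, set algebra, counting and protocol
correctness transfer; absolute performance numbers do not.

## Numerical choices and limitations

* Inclusive thresholds everywhere a radius is compared (`≤`), with exact
  squared-distance arithmetic at binary-fraction spacings.
* Voxel-unit kernels in zone repair assume the upstream isotropic resampling;
  on native anisotropic grids the 5/10-pixel defaults are grid-dependent and
  should be rechosen.
* The tolerant metric is volumetric; surface metrics (surface Dice, added
  path length) and detection scores (FROC, average precision) are out of
  scope.
* Probabilistic predictions are binarized before evaluation
  (`read_mask(..., binarize_threshold=)`); no soft-overlap support.
* The Conover variance factor assumes a complete block matrix; incomplete
  designs are rejected rather than imputed.
* Problem sizes in the test suite (grids up to 16×16×8 voxels for oracle
  equivalence, hundreds of random pairs, the default 119-case cohort for the
  end-to-end script) are the package's chosen balance of coverage against
  desk-scale runtimes.
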