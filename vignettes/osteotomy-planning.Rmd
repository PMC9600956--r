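---
title: "Wedge geometry in medial opening-wedge HTO planning: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wedge geometry in medial opening-wedge HTO planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(owhtoplan)
```

## The clinical question

Medial opening-wedge high tibial osteotomy (mOWHTO) treats medial
unicompartmental knee osteoarthritis in varus legs by opening a medially
based bone wedge in the proximal tibia, shifting the weight-bearing line
(WBL, the hip-centre-to-ankle-centre or Mikulicz line) laterally. Planning
is done on a standing long-leg radiograph: the surgeon chooses a medial
entry point (here 3 or 4 cm below the medial plateau), a lateral hinge
(here 5, 10 or 15 mm medial to the lateral cortical wall, at the fibular
head level where hinge fractures are least likely), and opens the wedge
until the WBL crosses the tibial plateau at a target fraction of its width
— 55% from the medial edge, the classical slight lateral overcorrection at
the lateral intercondylar spine.

The question this package quantifies: if the hinge or the entry height used
in theatre differs from the planned one, how much does the required wedge
width change, and how large is the resulting over- or under-correction?

## The model

A limb is a 2D coronal-plane landmark set (`make_leg()`): knee centre at
the origin, femoral mechanical axis vertical, joint line horizontal with
the knee centre at the plateau midpoint, and the ankle rotated medially
from the vertical by the varus angle, so the entire deformity sits in the
proximal tibia with its apex at the knee. This matches what mOWHTO corrects
and what a single mechanical femorotibial angle (mFTA) can encode; femoral
deformity and joint-line obliquity are deliberately not modelled, since
only the overall mFTA, not the partial angles, is specified for the cohort.

Planning one condition (`plan_osteotomy()`) is pure rigid geometry:

1. entry point on the medial cortex at the chosen height; hinge at the
   chosen offset from the lateral wall, 15 mm below the joint line;
2. the distal fragment (operationally: the ankle centre) rotates about the
   hinge by the correction angle $\alpha$ solved so that the new hip–ankle
   line crosses the joint line at the target fraction (Miniaci's method);
3. the wedge width is the chord between the entry point and its rotated
   image:
   $$w = 2\,L\,\sin(\alpha/2),$$
   where $L$ is the osteotomy length from entry to hinge.

$\alpha$ is found by bracketing on $[0^\circ, 45^\circ]$ with
`stats::uniroot()` at an angle tolerance of $10^{-13}$ degrees; the
residual of the achieved fraction is checked against $10^{-10}$ and the
fixed point (re-evaluating the WBL fraction on the corrected leg returns
the target to within $10^{-8}$) is asserted on every emitted plan. A leg
already at or lateral to the target returns a zero correction with a
warning (configurable to an error).

### What the geometry implies for the hinge position

Two facts follow directly from the construction and are worth stating
because they are easy to get backwards:

- **The correction angle is almost hinge-independent.** Moving the hinge
  10 mm medially changes the lever arm from hinge to ankle by well under
  1%, so $\alpha$ changes by hundredths of a degree (asserted < 0.3° across
  hinge offsets 5–15 mm).
- **The wedge therefore tracks the osteotomy length.** A hinge 10 mm more
  medial shortens the cut by about 10 mm, so at a typical correction of
  $\alpha \approx 7^\circ$ the wedge *shrinks* by
  $2 \cdot 10 \cdot \sin(3.7^\circ) \approx 1.2$ mm. Conversely, executing
  a planned wedge at a *more lateral* hinge than planned under-corrects,
  because the same chord on a longer cut subtends a smaller angle — exactly
  the under-correction scenario of the worked example below. The
  often-quoted rule of thumb of "about 2 mm per centimetre of hinge shift"
  corresponds to corrections near $11.5^\circ$
  ($2 \cdot 10 \cdot \sin(\alpha/2) = 2 \Rightarrow \alpha = 11.5^\circ$),
  i.e. to more severe deformity than this cohort's mean.

Changing the osteotomy *height* at a fixed hinge only tilts the cut: $L$
changes by a few percent and the condition means differ by about 0.3 mm —
the medial sawing point allows intraoperative flexibility, the hinge does
not.

```{r worked-case}
leg <- make_leg(6, femoral_length = 475, tibial_length = 372.6,
                plateau_width = 79.5)
plan <- plan_osteotomy(leg, height_below_plateau = 40, dist_from_lateral = 15)
plan
# the same wedge executed with the hinge 10 mm more lateral under-corrects:
achieved_fraction(leg, plan$wedge_width, 40, 5)
```

## The synthetic cohort

`generate_cohort()` emulates the 55-knee study population. Varus angles are
assigned *exactly* from the printed frequency table (15×3°, 10×4°, 4×5°,
8×6°, 2×7°, 5×8°, 6×9°, 3×12°, 1×13°, 1×17°), which removes one source of
sampling variance and pins the cohort mean at 327/55 = 5.945°. Plateau
width (79.5 ± 6.9 mm), femoral length (475.0 ± 34.5 mm) and tibial length
(372.6 ± 30.2 mm) are drawn independently from normals truncated at ±3 SD
(no covariance between them is reported anywhere, so independence is
assumed — a stated limitation, not a finding). Sides are 31 right / 24 left
as metadata; mirroring provably changes no measure. Everything is seeded
and reproducible, and the generator restores the caller's RNG state.

What a green test on this cohort does *not* establish: anything about
per-patient covariance between deformity severity and plateau size, about
osteophytes or soft tissue (the model has neither), or about reading error
on real radiographs — observer behaviour enters only through the explicit
noise overlay below.

## Observer noise and reliability

`simulate_raters()` overlays `true + bias[rater] + noise` on any planned
quantity, with one systematic bias per rater and independent cell noise.
Defaults (bias SD 0.1 mm, noise SD 0.3 mm) were chosen once to land in the
near-perfect agreement regime reported for landmark-based digital planning
software — with between-knee wedge SDs around 4 mm, a 0.3 mm reading error
yields ICC(A,2) above 0.98 — and were not tuned afterwards. `icc_ak()`
implements the two-way absolute-agreement average-measures intraclass
correlation from the table's mean squares,
$(MS_R - MS_E)\,/\,(MS_R + (MS_C - MS_E)/n)$, with the McGraw–Wong F-based
confidence interval (single-measure interval with Satterthwaite degrees of
freedom, stepped up by Spearman–Brown). Intra-rater reproducibility uses
sessions as columns; inter-rater reliability uses the raters' first
sessions. Which F-interval variant legacy SPSS used is not documented, so
the interval is reported but never used as a pass/fail quantity.

## Statistics

The six conditions are compared with a one-way fixed-effects ANOVA followed
by Tukey's HSD (studentized range, Tukey–Kramer for unbalanced input),
mirroring the original analysis even though knees are paired across
conditions — statistically conservative for detecting condition effects,
and the paired information is used where it matters, in the per-knee
difference rates (`pairwise_differences()`, clinical relevance threshold
2 mm). Pearson correlations check that wedge width carries no bone-length
signal. Agreement grades use the Landis-style bins (poor < 0 ≤ slight ≤
0.2 < fair ≤ 0.4 < moderate ≤ 0.6 < substantial ≤ 0.8 < almost perfect),
with the printed gaps between bin edges resolved by half-up rounding to two
decimals.

## Numerical and design choices

- **Hinge depth** defaults to 15 mm below the joint line for "fibular head
  tip level"; no millimetre value is printed anywhere, and $L$ varies by
  under 2% over plausible depths.
- **Rotation centre** is the hinge, matching opening-wedge mechanics; the
  relative geometry (and hence $\alpha$ and $w$) is identical whichever
  fragment is viewed as moving.
- **Wedge width is the chord**, not the gap along the cortex normal; the
  two differ by under 2% at these angles and no measurement convention is
  documented.
- **Saw kerf** is an optional additive allowance (default 0); **cortex
  flare** tilts the medial cortex line (default vertical).
- Degenerate inputs fail loudly: zero-length axes, a WBL parallel to the
  joint line, hinge offsets outside the plateau, frequency tables that do
  not sum to the cohort size, zero between-subject variance in the ICC.

## Known limitations

Strictly coronal and rigid: no tibial slope or sagittal effects, no hinge
fracture or plastic deformation, no soft-tissue correction loss, no image
processing or calibration. The simulation reproduces the study's worked
single-knee example and the magnitude and near-equality of the
height-condition means, but its hinge-offset *ordering* is the one rigid
geometry dictates (wedge decreasing as the hinge moves medially); the
summary tables it is compared against in the acceptance suite print the
opposite ordering, which cannot be produced by any rigid rotation about the
hinge with a fixed medial entry — see the repository's acceptance notes for
the quantitative comparison left deliberately red.
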