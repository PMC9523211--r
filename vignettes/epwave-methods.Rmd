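---
title: "Measuring endometrial peristalsis: model, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring endometrial peristalsis: model, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement model

Endometrial peristalsis appears in transvaginal cine loops as a slow
transverse undulation travelling along the endometrial stripe. `epwave`
measures it through a chain of five observable quantities:

1. **Tracked displacements.** An aligned grid of feature points (spacing
   15 px) inside a user-drawn rectangle is tracked frame to frame with
   sparse pyramidal Lucas–Kanade optical flow. The unit time is the
   inter-frame interval, so a point's velocity is simply its per-frame
   displacement. Points without local texture (ill-conditioned gradient
   matrix), with a large matching residual, or leaving the frame are
   marked invalid from that frame on and never re-seeded; re-seeding
   would splice unrelated tissue into one trajectory and corrupt the row
   fits downstream.
2. **Row curvature τ.** Points sharing an initial transverse coordinate
   form a row running along the organ's long axis. A single point's
   wiggle says little; the coherent bending of a whole row is the
   macroscopic signature of a passing wave. Each row's tracked transverse
   positions are fitted with a degree-2 polynomial of axial position; τ is
   the signed second derivative (twice the quadratic coefficient). This is
   a curvature *proxy*, proportional to true curvature for the small
   slopes seen here, which is all the detector needs. A rigid translation
   of the whole region keeps every row straight, so τ ≡ 0: probe slip is
   structurally invisible, which is the method's central advantage over
   frame differencing.
3. **Lagged variation Δτ.** Static curvature (an anatomically bent
   stripe) carries no motion information, so the detector uses
   Δτ(f) = τ(f) − τ(f − lag) with a 5-frame lag; frames with fewer than
   `lag` predecessors subtract the first frame, and the first frame has
   Δτ = 0. The value is stored split into magnitude (wave strength) and
   sign.
4. **Salience.** Magnitudes are min–max normalized over the whole clip,
   y0 ∈ [0, 1], then thresholded: y1 = y0 − α, with salience defined by
   the strict inequality y0 > α. The sigmoid weight
   y2 = 1/(1 + exp(−β·y1)) drives the colour overlay: sub-threshold rows
   (y2 ≤ 0.5) contribute exactly zero after rescaling, so quiescent tissue
   keeps its grey value.
5. **Motion graph and events.** Per frame, salient rows are split into
   forward movers (`n_+`) and backward movers (`n_-`), where forward is
   image-left for a horizontal uterus and image-down for a vertical one.
   Runs of `max(n_+, n_-) >= min_count` active frames become wave events;
   the peak pattern inside an event classifies its direction, and the
   declared cervix side maps forward/backward onto CF/FC (a wave moving
   toward the cervix is fundus-to-cervix).

## Design decisions that were genuinely open

**Which axis is a "row".** Rows are defined along the endometrial long
axis (the ROI's long dimension, selected by the declared orientation), and
curvature is measured on transverse displacement as a function of axial
position. A travelling transverse wave bends such rows maximally; rows
along the short axis would barely deform.

**The direction datum.** The sign of Δτ tells whether a row's curvature is
increasing or decreasing, but any scalar fitted to a whole row is
unchanged when the image is mirrored along the axis — so that sign cannot
distinguish a left-going from a right-going wave, and a detector relying
on it would break the elementary consistency requirement that mirroring
the video and re-declaring the cervix side must not change the report.
The motion graph therefore splits salient rows by a *propagation* sign:
the lagged drift of each row's |transverse-displacement|-weighted axial
centroid. This quantity follows the wave's travel, flips under mirroring
and under time reversal, and reduces to "no direction" (sign 0) when the
row shows no activity (peak displacement below 0.3 px or drift below
0.5 px per lag). The algebraic sign of Δτ is still computed and stored —
it retains the identity Δτ = sign · |Δτ| and the antisymmetry under
flipping the transverse axis — but it is a bookkeeping field, not the
direction datum.

**Event merging.** |Δτ| of a single wave necessarily passes through zero
in mid-crossing: τ(t) rises to its extremum and falls again, so its lagged
difference changes sign and the salient run has an intrinsic dip. A fixed
merge gap cannot bridge this dip, whose length scales with the wave's
crossing time. Runs are therefore merged not only across gaps shorter
than `merge_gap_s` but also across gaps whose every frame keeps
sub-salient displacement activity — at least `min_count` rows displaced
beyond 25% of the clip's peak transverse displacement. During a wave's
dip the tissue is still displaced; between distinct waves it is at rest,
so the rule separates exactly the cases that need separating. Merging
runs before discarding short ones (rather than after) keeps a fragmented
wave's pieces eligible for merging. A mixed CF+FC episode merges into
*one* event by construction, reproducing the automated counting behaviour
in which a reflected wave is a single peristalsis while a visual reader
tends to count two.

**Degenerate normalization.** When every |Δτ| in a clip is equal
(max = min), y0 is defined as 0 everywhere: a clip with no curvature
change contains no peristalsis to rank.

**Intensity scales.** The weak/moderate/strong criteria compare the
peristaltic range (maximal fraction of simultaneously salient rows) and
amplitude (peak motion-graph count over countable entries) against the
value 1. The units that make "1" the boundary are not fixed by the
criteria themselves, so both axes carry explicit scale parameters
(`range_scale`, `amp_scale`, default 2 each), placing the boundary at
half of the rows participating. Both scales are exposed rather than
hidden because no desk-scale experiment can pin them down.

**Velocity.** Velocity is a path length over a time: the
activity-weighted axial centroid of the salient rows is followed through
the event and a straight line is fitted to centroid-versus-time; the
slope magnitude times the pixel spacing is the speed in mm/s. The first
and last 20% of the salient frames are trimmed before fitting, because
the wave's entry into and exit from the rectangle compress the centroid
toward the borders and bias the slope low. The secondary shape
descriptor — the wave-peak to wavelength ratio — is reported separately
as `shape_ratio` = amplitude / range.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `grid_spacing` | 15 | px | feature-point interval |
| `lk_window`, `lk_levels` | 21, 3 | px, – | Lucas–Kanade window and pyramid depth |
| `temporal_window`, `spatial_window` | 5, 3 | frames, cells | boxcar smoothing (shrinks at borders; invalid points excluded) |
| `lag` | 5 | frames | curvature-variation lag |
| `alpha` | 0.6 | – | salience threshold on y0, strict |
| `beta` | 10 | – | sigmoid slope for rendering weights |
| `min_count` | 3 | rows | active-frame threshold and peak noise floor |
| `min_duration_s` | 2 | s | minimum event duration |
| `merge_gap_s` | 1 | s | unconditional merge gap |
| `range_scale`, `amp_scale` | 2, 2 | – | intensity axis scales |

Grid spacing, lag, and α are the algorithm's published operating point;
the rest are this package's defaults with the rationales above. All are
overridable per run and echoed into every report, so two reports with
different configurations are never compared silently.

## What the phantom emulates — and what it does not

`generate_peristalsis_clip()` warps a seeded, low-pass-filtered speckle
texture with a purely transverse displacement field whose cos²-shaped
envelope (amplitude default 4 px, wavelength 48 px) travels axially at a
known speed, tapered across the band thickness by a raised cosine;
additive Gaussian intensity noise (σ = 2) is drawn per frame. A
mixed-direction wave is a forward pass whose reflection re-enters before
the forward bump has fully left, so the episode's activity is continuous.
`generate_translation_clip()` provides the rigid-drift control for the
straight-line-immunity property.

The default conditions — 128×128 px, 2 frames/s, 100 s (200 frames), band
56 px thick, speeds 6–12 px/s at 0.1 mm/px — scale the clinic's 2-minute,
~0.15 mm/s waves down to a desk-sized problem: waves cross in ~20 s of
clip time rather than minutes, so a 200-frame clip can hold up to four
events. The validation draw (`sample_study_spec()`) samples 1–4 waves per
clip with a *clip-level* amplitude (uniform 3–5 px shared by the clip's
waves, as contractions within one recording share the uterus's momentary
tone) and per-wave speeds uniform in 8–12 px/s.

The phantom does **not** emulate: multiplicative speckle decorrelation
(noise is additive), out-of-plane motion, shadowing or attenuation
artifacts, breathing or bowel motion, anatomically curved stripes,
multi-focal or irregular waves, or amplitude envelopes that grow and die
along the organ. Passing the recovery suite therefore shows that the
chain — tracking, curvature, salience, segmentation, classification,
calibration — is implemented correctly and is well-conditioned at
realistic signal-to-noise, not that clinical performance is guaranteed.

## Known limitations

- **Relative salience.** Per-clip min–max normalization with α = 0.6
  means a wave weaker than about 60% of the clip's strongest motion
  cannot cross threshold; clips with strongly heterogeneous wave
  amplitudes will be under-counted. This mirrors the automated method's
  tendency to count fewer waves than visual readers.
- **Uncompressed I/O only.** The package reads and writes uncompressed
  RIFF/AVI and multi-frame TIFF; compressed containers must be
  re-exported upstream. AVI/TIFF carry no calibration, so pixel spacing
  (and for TIFF the frame rate) are required inputs.
- **User-drawn ROI and declared orientation.** Automatic endometrium
  segmentation and automatic cervix-side inference are out of scope; the
  rectangle and the orientation are inputs, as the image alone cannot
  supply the anatomy.
- **Lost points stay lost.** Long clips with intermittent occlusion
  erode the grid over time; the detector requires at least three valid
  points per row to fit a curvature.

## Numerical notes

- All smoothing windows shrink at borders instead of padding, avoiding
  fabricated motion at sequence and grid edges.
- Curvature fits use centered axial coordinates; rows whose valid points
  are axially degenerate are flagged unfittable rather than producing an
  unstable coefficient.
- Peak detection inside events uses local maxima with height ≥
  `min_count` and prominence ≥ `min_count`/2; plateau peaks count once.
- The ICC is the two-way random-effects, absolute-agreement,
  single-measure form computed from ANOVA mean squares; an all-constant
  table returns 1 (perfect agreement) by definition rather than a 0/0
  ratio. Reported agreement fractions round half-up to 2 decimals by
  default, configurably.
- `analyze_clip()` contains no randomness: reports are bit-reproducible
  for fixed inputs and parameters.
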