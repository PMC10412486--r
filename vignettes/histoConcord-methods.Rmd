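---
title: "Methods: quantifying interobserver concordance of whole-mount prostatectomy annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying interobserver concordance of whole-mount prostatectomy annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoConcord)
```

## The measurement problem

Two pathologists independently draw polygon regions on the serial
whole-mount slides of a radical-prostatectomy specimen (RPS): pure Gleason
patterns, mixed Gleason-score areas (when patterns are too interwoven to
separate), a cribriform-growth / intraductal-carcinoma (CG/IDC) layer, and
benign mimics. The package answers three questions about such paired
annotation sets: how well do the drawn *surfaces* overlap, how often do the
two observers make the same *per-slide call*, and do they localize and
grade the same *index lesion*?

Coordinates are physical millimetres in a per-slide frame. Cross-slide
alignment is assumed given: serial sections of one specimen share a frame,
and no registration is attempted — registration is an imaging problem, not
an annotation-concordance problem.

## Surface overlap: the weighted Dice coefficient

For one slide and one category the Dice similarity coefficient is
$\mathrm{DSC} = 2\,|X \cap Y| / (|X| + |Y|)$, with $X$, $Y$ the two
observers' merged surfaces. Per specimen, each slide's DSC is weighted by
$(X + Y)/2Z$, where $Z$ is the mean area the two observers annotated over
all the specimen's slides. The weights sum to 1 and the weighted sum
collapses algebraically to the pooled form
$2\sum_s |X_s \cap Y_s| \,/\, (\sum_s X_s + \sum_s Y_s)$ — an identity the
test suite asserts to $10^{-12}$ on randomly generated specimens.

Three boundary conventions matter and are deliberate:

* slides where **neither** observer annotated the category have weight 0
  and are *excluded*, never scored as DSC 1 — counting absent-vs-absent as
  agreement would inflate concordance;
* slides where only **one** observer annotated get DSC 0 with positive
  weight, as the formula forces;
* an undefined DSC (no area anywhere) is reported as `NA`, never as 0.

**Cross-specimen pooling** uses the same scheme: each specimen enters with
weight proportional to its combined annotated area, so the cohort value is
again the all-slides pooled form. This choice was genuinely open — the
alternative is an unweighted mean of the per-specimen values — and was
settled by internal consistency: area weighting is the only scheme under
which cohort-level and specimen-level pooling are the same operation, and
it is what the package's aggregation of the bundled study tables uses.

## The label taxonomy and Gleason composition

Labels serialize as a closed, greppable set: `GP3`, `GP4`, `GP5`,
`GS3+4<20`, `GS3+4_20-50`, `GS4+3_50-80`, `GS4+3>80`, `CGIDC`,
`PROSTATITIS`, `HGPIN`. Mixed labels carry a percentage bin for the
high-grade pattern; bins below 50% are only legal when the high-grade
pattern is secondary (3+4), bins of 50% and above only when it is primary
(4+3). The parser accepts any `GS{a}+{b}` pair under these rules, so the
taxonomy is extensible (e.g. 4+5) even though the default set reflects the
protocol it was built for.

Category membership, per observer and slide:

* `any_pca` — every Gleason region (pattern 3 or higher);
* `cspca` — every Gleason region containing pattern ≥ 4, *with its full
  area*: mixed regions are kept whole because the protocol uses them
  precisely where patterns cannot be separated spatially;
* `gp3`/`gp4`/`gp5` — regions whose label *contains* the pattern, pure or
  mixed. This reading is supported by the bundled study's slide-call
  counts, where the GP4 row equals the csPCa row;
* `cg_idc`, `prostatitis`, `hgpin` — their own layers; CG/IDC may overlap
  Gleason regions of the same observer and contributes to no Gleason
  category.

**Composition** (primary/secondary pattern, Grade Group) works on
per-pattern *areas*. Mixed regions are split between their two patterns at
the bin midpoint — `<20%` → 0.10, `20–50%` → 0.35, `50–80%` → 0.65,
`>80%` → 0.90 of the high-grade pattern. Attributing a mixed region wholly
to its primary pattern was considered and rejected: it cannot reproduce the
canonical translation example in which a GS 4+3 (50–80% GP 4) area plus a
pure GP 4 area yields Grade Group 3 — wholesale attribution loses the
secondary pattern 3 and lands on GG 4. The bin-midpoint split keeps
composition total, scale-invariant, and faithful to that example (it is a
unit test).

Rules on top of the areas:

* primary pattern = largest area, ties broken toward the *higher* pattern
  (conservative);
* secondary pattern = second-largest area; a pattern *higher* than the
  primary qualifies only when it holds ≥ 5% of the tumour area, and the
  highest such pattern overrides the second-largest. A sub-5% pattern 5 is
  never secondary; it raises the `minor pattern 5` flag instead and does
  not upgrade the Grade Group;
* a single pattern doubles as its own secondary (3+3 convention).

Grade Group translation is the standard ISUP map: 3+3 → 1, 3+4 → 2,
4+3 → 3, 4+4/3+5/5+3 → 4, else 5.

## Per-slide agreement: Fleiss' kappa

Per-slide calls (presence booleans, primary/secondary pattern, minor
pattern 5) feed Fleiss' multi-rater kappa with both observers pooled into
the chance model. For two raters and binary calls this reduces to a 2×2
closed form, which the tests verify exhaustively over all small tables.
When both observers use a single category everywhere the statistic is 0/0;
agreement is then perfect and kappa is reported as 1 with a degeneracy
flag. Primary and secondary pattern are treated as nominal multi-category
variables over the slides where *both* observers call tumour present —
tumour-free slides carry no pattern and would otherwise dominate the
statistic.

Confidence intervals are percentile bootstrap over subjects (slides),
default 2000 resamples, seeded and recorded. The method is assumption-light
and reproducible; a closed-form kappa variance was rejected because its
small-sample behaviour is poor at the near-degenerate tables this data
produces. Verbal bands use the conventional cutpoints (≤0 poor, to 0.20
slight, to 0.40 fair, to 0.60 moderate, to 0.80 substantial, above
almost perfect).

## The index lesion

The study protocol speaks of "lesions" without operationalizing them, so
the package fixes an assembly rule: per slide, an observer's Gleason
regions group into connected components under an adjacency tolerance of
**0.5 mm** — half-millimetre gaps are below the protocol's own precision
floor, so polygons drawn that close belong to one focus; components on
consecutive slides merge when their footprints overlap in the shared frame
(a slide gap breaks the lesion). Lesion area sums the per-slide footprint
union areas; volume multiplies by the slice thickness (default 4 mm).

The index lesion is the highest-Grade-Group lesion with total area
≥ 0.5 cm², ties broken by volume. The threshold is read as *summed over
slides* — the natural meaning of a lesion's surface area in a serially
sectioned specimen — and when nothing reaches it the same ranking applies
to all lesions with an explicit flag. Index lesions are matched by index
status (each observer's index against the other's), and their localization
DSC is computed on the lesion-restricted footprints over the union of
slides either lesion touches — not on whole-slide tumour surfaces, which
would credit overlap contributed by non-index foci.

## Geometry engine

No polygon-clipping library is part of the package's dependency footprint;
boolean *areas* are computed exactly by a slab sweep. The x-axis is cut at
every vertex and every pairwise edge-crossing abscissa; within a slab no
edges cross, so sorting them by height at the slab midline produces a stack
of trapezoids whose even-odd membership per polygon is constant. Summing
trapezoid areas by membership yields $|A|$, $|B|$ and $|A \cap B|$ in one
pass, in double precision. Conventions: coordinate tolerance $10^{-9}$ mm;
polygons may carry holes (even-odd within a polygon, union across a set's
polygons); exactly vertical edges contribute no area and are excluded from
slab interiors; regions below $10^{-6}$ cm² are dropped with a warning as
sub-precision artefacts.

The independent check is a rasterization oracle: counting grid-cell centres
inside the set. At 0.01 mm cells the two routes agree within 0.5% on random
star-shaped polygon pairs (tested); during development the sweep was also
cross-checked against an external computational-geometry library to
~$10^{-13}$ mm². Distances for the adjacency rule come from exact
segment–segment distance plus containment tests.

## The synthetic cohort generator

The generator exists so that every pipeline stage runs, and is testable,
without patient data. Its defaults are the study conditions the pipeline
targets: 2 observers, 10 specimens, 6–9 slides each (≈74 slides per ten
specimens), 4 mm slices, 1–3 tumour foci per specimen with base radii
2.5–8 mm. Truth lesions are star-shaped polygons — radial Fourier
perturbations of ellipses at 48 control points — spanning up to three
contiguous slides; CG/IDC sub-regions sit inside high-grade lesions;
benign mimics appear per specimen with mild probability.

Observers see the truth through separable noise channels:

* **boundary jitter** — radial Gaussian noise on the control points,
  circularly smoothed (window 5, variance-normalized so the marginal s.d.
  equals the nominal sigma). Default sigma 0.5 mm, the protocol's stated
  precision scale;
* **label confusion** — a row-stochastic matrix over the taxonomy; the
  default concentrates mass where observers genuinely disagree
  (neighbouring bins, pure-vs-mixed sharing a pattern, CG/IDC vs plain
  GP 4) and `identityConfusion()` switches it off;
* **style difference** — with probability 0.1 an observer redraws a mixed
  region as two pure-pattern halves over the same footprint, reproducing
  the documented phenomenon of depressed DSC without substantive
  disagreement.

Because the channels separate, the tests can isolate them: zero noise
reproduces truth exactly through the entire pipeline (all weighted DSCs 1,
all kappas 1, index agreement 100%); label confusion alone leaves
tumour-localization DSC at 1 while degrading category kappas; jitter alone
degrades DSC monotonically in sigma, and the pipeline's DSC under jitter
matches a Monte-Carlo rasterization oracle within sampling error. What the
generator does *not* emulate — prostate anatomy, stain appearance,
correlated errors between neighbouring slides, more than two observers —
bounds what passing tests can say about real data: they validate the
*computation*, not the clinical variability model.

## Problem sizes and determinism

All randomness flows from explicit integer seeds (generator config, kappa
bootstrap), and the pipeline's CSV outputs are byte-identical under a fixed
seed; display values round half-even to 2 decimals with unrounded
companions always emitted. The test suite sizes its simulations for
desk-scale runs: the weighted-DSC identity on 100+ random specimens, the
sweep-vs-oracle comparison on a handful of star pairs at 0.01 mm cells,
kappa-bootstrap coverage on 80 independence datasets of 60 slides, and
jitter monotonicity with 80 replicate pairs per sigma level — sizes chosen
as the smallest at which the asserted effects are unambiguous.

## Known limitations

* The per-specimen aggregation of *rounded* published rows cannot always
  recover values computed from unrounded slide-level data; the bundled
  study tables reproduce their printed totals for the tumour and CG/IDC
  columns, but the overall csPCa weighted DSC is knowably irrecoverable
  from its rounded rows and is therefore not asserted anywhere.
* The bootstrap kappa intervals are not meant to match any particular
  closed-form or software-specific interval.
* Mixed-label bins are taken as annotated; the package never re-estimates
  percent pattern 4 from geometry.
* Surfaces are polygon interiors; the 0.2 mm stroke width of the upstream
  annotation tool is treated as a property of annotation, not enforced or
  modelled here.
* Exactly two observers per specimen; multi-observer designs would need a
  different matching layer (the kappa core already accepts more raters).
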