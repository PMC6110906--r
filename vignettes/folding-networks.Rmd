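---
title: "Testing gyral versus sulcal signal representation in intrinsic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing gyral versus sulcal signal representation in intrinsic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question

The cerebral cortex folds into convex gyri and concave sulci, and a
growing body of structural and functional evidence suggests the two play
different roles: gyri appear to act as global hubs wired to distant
regions by dense long-range fibers, while sulci behave more like local
processing units. If that picture is right, then within an intrinsic
functional network — a set of spatially separated regions whose BOLD
activity is temporally coupled — gyral vertices should carry more of the
*globally shared* signal than sulcal vertices do.

`foldnet` operationalizes that prediction. Every vertex's task-fMRI time
series is expressed in a basis of temporal "atoms" learned from the whole
brain at once; how well a vertex's signal is reconstructed from that
shared basis (its *representation accuracy*) then measures how much the
vertex participates in globally coherent activity. The hypothesis becomes
a one-sided statistical comparison: accuracy on gyri exceeds accuracy on
sulci within each network region.

## The model and procedure

**Sparse factorization.** Signals are normalized per vertex to zero mean
and unit (population) standard deviation and collected into
$X \in \mathbb{R}^{t \times n}$ (timepoints by vertices). We factorize

$$\min_{D \in \mathcal{C},\, \alpha}\; \tfrac{1}{2}\lVert X - D\alpha
\rVert_F^2 + \lambda \lVert \alpha \rVert_{1,1},
\qquad
\mathcal{C} = \{D : \lVert d_i \rVert_2 \le 1 \ \forall i\},$$

with an online learner: atoms are initialized from randomly chosen data
columns, each mini-batch is sparse-coded by cyclic coordinate descent
(compiled; solutions satisfy the lasso KKT conditions to $10^{-6}$), and
accumulated sufficient statistics $A \mathrel{+}= \alpha\alpha^\top$,
$B \mathrel{+}= X\alpha^\top$ drive a block coordinate-descent atom
update projected onto the unit ball. The statistics are decayed by 0.5
per epoch so codes computed against stale dictionaries lose influence —
without this forgetting the learner visibly stalls in local optima (the
planted-recovery test drops from 20/20 to 8/20 recovered atoms). Atoms
unused for a full epoch are re-seeded from the worst-reconstructed
signal.

**Network identification.** Each row of $\alpha$, mapped back to
vertices, is an atom's spatial map. Maps are binarized (default: nonzero
support, since the lasso already zeroes irrelevant vertices; a z-score
rule is available for dense maps) and compared to template vertex sets by
the overlap rate $R(S,T) = |S \cap T| / |T|$; each template takes the
argmax atom, ties to the lower atom index. A nearest-vertex mapping is
provided for templates that arrive as volume-space voxel coordinates.

**Accuracy and folding.** Per vertex, $P_v = \mathrm{corr}(x_v, D\alpha_v)$.
Regions are split by the sign of principal curvature — `pcurv >= 0` is
gyral (the boundary is assigned to gyri), `pcurv < 0` sulcal. Raw Pearson
values are retained, negatives included: the claim sometimes seen that
this quantity "ranges from 0 to 1" is an empirical observation about
well-fit data, not a transform, and clamping would bias the group means
we test.

**Inference.** Per region: pooled-variance one-tailed two-sample t-test
(gyri > sulci), Bonferroni-corrected over the regions of the network
(Welch available by argument). Per network: a one-sided label-permutation
test of the pooled mean difference, 1,000 relabelings, add-one estimator
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_{\mathrm{perm}} + 1)$.
Per network, FA-like scalars are correlated with accuracy (Pearson, $t$
transform). A cohort runner aggregates per-subject flags into
proportion-of-significant-subjects tables. The choice of Bonferroni
family is genuinely underdetermined in this literature; we correct
per-region tests over the regions within the network and pooled
per-network tests over the number of networks, and both families are
plain arguments.

## The synthetic world

There is no bundled neuroimaging data; the generator *is* the testbed,
and its defaults are fixed choices, not dials.

- **Surface**: a rectangular triangulated sheet whose height and signed
  curvature follow $\sin(2\pi x / \text{fold\_period})$ (period 8 mm,
  spacing 1 mm, default 48 x 40 vertices). The curvature field is the
  analytic sine value rather than an estimate from the discrete mesh, so
  gyrus/sulcus labels carry no discretization noise.
- **Paradigm**: TR = 0.72 s, 176 volumes; six 21 s blocks (3 s cue + six
  3 s trials), alternating face- and shape-matching, three of each.
- **HRF**: double-gamma with mode exactly at the nominal peak (gamma
  shape = peak + 1 at rate 1; peak 6 s, undershoot 16 s, ratio 1/6) —
  the field-standard canonical shape; the source study does no
  simulation, so this is our choice.
- **Networks**: K = 5 planted networks, each the union of 2 disjoint
  4 mm balls placed by rejection sampling (with restarts) so that every
  ball contains both gyral and sulcal vertices. Network time courses mix
  the HRF-convolved task regressor with low-pass (0.1 Hz) intrinsic
  fluctuation at weight 0.5 each; networks sharing a task condition are
  therefore genuinely correlated, which is the realistic hard case for
  the matcher.
- **The folding effect**: vertex $v$ of network $k$ receives
  $x_v = w_v a_k + s_v \eta_v + \sigma \varepsilon_v$ with loading
  $w_v \sim U(0.8, 1.2)$, white noise $\sigma = 0.5$, and a
  vertex-specific nuisance series whose amplitude is $s_v = \delta$ on
  sulci and $0$ on gyri. The sulcal disadvantage is *unshareable signal*,
  not reduced amplitude, matching the interpretation of sulci as local
  functional units. Under independence
  $\mathrm{corr}(x_v, a_k) = w/\sqrt{w^2 + s_v^2 + \sigma^2}$, so
  $\delta$ maps onto the accuracy gap in closed form. The default
  $\delta = 0.45$ was set from that formula to produce a gap of about
  0.06 — mirroring, deliberately not reproducing, the roughly
  0.82-vs-0.76 contrast reported on real cohort data — and was chosen
  before any test was run against it.
- **FA**: $\mathrm{FA}_v = \mathrm{clamp}(0.3 + 0.3\,\rho_v +
  \mathcal{N}(0, 0.05^2), 0, 1)$ where $\rho_v$ is the closed-form
  representability. With the narrow default loading range the observed
  FA-accuracy correlations sit around 0.1-0.3 per network; wider loading
  spreads push them into the 0.3-0.6 band. We kept the narrow range
  because group variance in $w$ trades directly against per-region test
  power, and the FA coupling is a qualitative feature here.

What a green test does *not* establish: the generator has no spatial
autocorrelation in its noise, no motion or drift, no registration error,
no realistic folding geometry, and its networks are disjoint by
construction. Significance on this world validates the machinery and its
calibration, not the empirical claim on human data.

## Numerical choices

- λ = 1.5 at the default scale. The timepoint count (176) and unit
  signal variance match the whole-brain setting this value was published
  for, and calibration confirmed in-network loadings (|d'x| ≈ 10) sit
  far above the threshold, so the value transfers; the desk-scale change
  is only m = 50 atoms instead of 400.
- Coordinate descent runs to a 1e-10 coefficient-change tolerance for
  final codes (1e-7 inside mini-batches, where speed matters and the
  dictionary is about to move anyway).
- Zero-variance vertices are excluded at normalization (their
  correlation-based accuracy is undefined) and logged; constant
  reconstructions likewise yield NA accuracy and are dropped with
  counts.
- Ties: template matching takes the lowest atom index; volume-to-surface
  mapping takes the lowest vertex index; the gyral/sulcal boundary
  (pcurv = 0) goes to gyri.
- Vertex indices are 1-based everywhere, including serialized artifacts.
  A 0-based convention was considered for interoperability but rejected:
  in an R package every off-by-one bridge is a defect waiting to happen,
  and the plain-text artifact headers document the convention instead.
- Permutation p-values use the add-one estimator, so they are never 0
  and never below 1/(n_perm + 1).

## Scaling of the test batteries

The acceptance-style batteries are sized to run on one CPU in minutes:
the effect battery is 20 independent runs of the default configuration
(~8 s each), and the null calibration battery is 200 runs of a reduced
configuration (24 x 24 sheet, K = 2 networks, m = 20 atoms, 3 epochs,
200 permutations, ~0.6 s each). The reduction is purely computational;
the null world is the same generative model with δ = 0.

## Known limitations

- The learner's objective trace is only monitored on a fixed subsample
  of 500 columns; it is a trend diagnostic, not the exact batch
  objective.
- Networks that share a task condition can split across atoms when the
  intrinsic component is weak; the matcher reports the per-template
  argmax and its overlap rather than enforcing exclusivity, so such
  splits are visible in the match table (R noticeably below 1).
- Degenerate regions (all-gyral or all-sulcal after exclusions) are
  flagged and reported as untestable rather than silently skipped.
- The pipeline assumes template and data are in the same space; no
  registration is attempted.
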