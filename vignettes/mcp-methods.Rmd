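---
title: "The modified chin point: geometry, statistics, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The modified chin point: geometry, statistics, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chinpoint)
```

## The problem

Steiner's S line (columella midpoint to soft-tissue pogonion) and Ricketts'
E line (pronasale to soft-tissue pogonion) are the standard references for
judging lip protrusion in profile analysis, and lip positions within about
±2 mm of them are consistently rated most aesthetic in the population this
method was calibrated for. Both lines, however, are anchored at the chin:
in skeletal Class II and III patients the pogonion itself is displaced, and
the lines lose their meaning.

The modified chin point (MCP) repairs this by *standardizing the chin*
before the lines are drawn. The angle of facial convexity — the interior
angle ∠G′–Sn′–Pog′ at subnasale between the rays to glabella and to
pogonion — is highly consistent (about 170°, in males 170.3° ± 3.2 and in
females 170.1° ± 3.2) in aesthetically balanced profiles of the reference
population. The MCP is the point obtained by horizontally projecting the
actual chin point (ACP, the soft-tissue pogonion in the midsagittal plane)
onto the ray from subnasale that makes exactly 170° with the
glabella–subnasale line. S and E lines drawn to the MCP instead of the ACP
are then comparable across skeletal classes, and the signed horizontal
offset `x = MCP − ACP` measures how far the chin deviates from the
aesthetic criterion.

## The construction

All geometry happens in a 2D sagittal frame:

1. **Midsagittal frame.** The total-least-squares plane through the seven
   midline landmarks (G′, Sn′, Pn′, Col, UL, LL, ACP) minimizes the summed
   squared out-of-plane distances, with all landmarks weighted equally. The
   superior axis is the in-plane direction best aligned with Sn′→G′, the
   anterior axis is its in-plane orthogonal complement signed so that
   pronasale is anterior, and the origin is Sn′. This operationalizes
   natural head position for coordinates delivered in an arbitrary scanner
   frame; every measurement downstream is therefore invariant under rigid
   motion of the input. The reference data are acquired in natural head
   position, and the source method does not state how its own software
   defines the sagittal axes; the TLS-plane-plus-Sn′→G′ convention is this
   package's choice.
2. **Line A** through G′ and Sn′.
3. **Line M**: the ray from Sn′ at the target angle (default 170°,
   configurable, identical for both sexes) from the ray Sn′→G′, rotated to
   the *posterior* side of line A and pointing inferiorly. Convexity angles
   below 180° describe a chin behind the G′–Sn′ line, and the typical
   pre-surgery pattern (MCP-based lip distances exceeding ACP-based ones)
   requires a posterior MCP, so the posterior branch is the meaningful one;
   anterior chins then produce negative offsets naturally through the
   signed intersection. Line M is treated as an infinite line: whether it
   is clipped at chin level is immaterial to the horizontal intersection.
4. **MCP**: the intersection of the horizontal line through the ACP with
   line M; `x = a(MCP) − a(ACP)` is stored signed (anterior-positive) and
   reported unsigned where distances are tabulated. The construction's
   defining property — the convexity angle measured to the MCP equals the
   target to within 1e-6° — is exercised directly by the test suite.

Degenerate inputs are rejected rather than guessed at: coincident line
anchors, collinear landmark sets, target angles outside (90°, 180°], and a
line M within 1° of horizontal (where the horizontal intersection becomes
ill-conditioned) all raise structured errors.

## Lip measurement

For each pogonion source (ACP and MCP) the S line is drawn from Col and the
E line from Pn′ to that chin point, and the four signed distances (UL and
LL against S and E) are perpendicular point-to-line distances in the
sagittal plane, positive on the anterior side — a lip ahead of its
reference line measures positive, matching the sign pattern of the
published tables. Perpendicular distance is the standard cephalometric
convention; because the source method says only "distance relative to each
reference line", a `method = "horizontal"` switch provides pure
anteroposterior offsets for sensitivity analysis, with no claim about which
convention the original software used. The ±2 mm aesthetic window is a
closed interval and configurable, since "approximately ±2 mm" is inherently
soft.

Quality control mirrors the cohort's exclusion rule for facial asymmetry: a
record fails when the ACP lies strictly more than 3 mm (configurable) off
the fitted midsagittal plane; failing subjects are excluded in full and
logged.

## Statistics

The validation layer reproduces the published analysis structure:

* paired t tests between ACP- and MCP-based lip distances at each timepoint
  (two-sided; differences that vanish to numerical precision return the
  degenerate convention t = 0, p = 1);
* a paired Wilcoxon signed-rank test comparing |x| before and after
  surgery. The published analysis names a "Wilcoxon ranked sum test"; the
  signed-rank test is the correct dependent-samples analogue and that label
  is kept in output. Zeros are dropped, ties receive average ranks, and the
  null distribution is computed *exactly* for up to 25 nonzero differences
  by convolving the generating function over doubled ranks (so it remains
  exact under ties, where the standard tabulated distribution does not
  apply); above that a continuity-corrected normal approximation with
  tie-corrected variance is used;
* mean error and mean absolute error of ACP-minus-MCP at T1 with SD, min
  and max. MAE is the standard non-negative mean |d| — which is ≥ |ME| by
  construction — even though some published agreement tables print negative
  "MAE" values whose formula is unknowable from the text;
* Pearson correlations between ACP(T1) and MCP(T1) and between MCP(T0) and
  MCP(T1) per variable;
* Welch's unequal-variance t (a robust default; the source is silent on the
  variance assumption) for the sex comparison of T1 MCP-based positions;
* Shapiro–Wilk normality checks, computed and logged as a gate but not used
  to switch tests automatically, since no switching rule is stated;
* the Bonferroni decision threshold. The published decision rule divides
  0.05 by four tests and rounds the result down to 0.01;
  `mode = "published"` reproduces that printed 0.01 while `mode = "exact"`
  exposes the unrounded alpha/n (0.0125).

All tests are two-sided. Where an installed routine implements the textbook
test (`t.test`, `cor.test`, `shapiro.test`) it is called directly; the
test suite checks every statistic against independent closed-form or
enumeration oracles to 1e-12.

## The synthetic cohort generator

No landmark data are distributed with the method, so the generator emulates
the *statistical structure* of the validation cohort: 68 subjects (28 male,
40 female), each with a pre- (T0) and post-surgery (T1) record.

Per subject and timepoint the generator draws, from truncated Gaussians:

* a **signed chin angle** θ from the downward vertical (the configured
  convexity mean maps to the posterior side; anterior chins arise through
  the spread; truncation keeps convexity above 120°),
* a **chin depth** (vertical Sn′-to-chin distance, default 60 ± 5 mm,
  truncated above 20 mm),
* four **ACP-based lip offsets** with per-sex means and SDs.

It then constructs coordinates that realize those draws exactly: Sn′ at the
origin, G′ vertically above at a fixed 65 mm face height, nose anchors at
fixed offsets (Pn′ (18, 10) mm, Col (10, 4) mm — plausible constants,
config-exposed, since no nasal coordinates are published; lip placement
depends only on the line constraints), the ACP on the drawn ray, and each
lip at the unique intersection of the two lines offset from the ACP-based S
and E lines by the drawn distances (a 2×2 solve; near-parallel offset lines
trigger resampling up to a retry cap). Isotropic landmark jitter
(default 0.25 mm, the scale of landmark annotation error) and out-of-plane
lateral noise (default 0.5 mm) are added last. T0 and T1 draws share a
subject-level random effect (correlation 0.5 by default): the published
design implies but never quantifies within-subject correlation, so it is
surfaced as a configuration knob rather than buried.

**Chin-angle calibration.** The published chin tables report the unsigned
distance |x| (8.53 ± 5.37 mm at T0, 3.87 ± 2.58 mm at T1), while the
generator needs a signed-angle distribution. Signed-x parameters are
obtained by moment-matching a folded normal to the printed mean and SD,
then converted to angle space through `x = −D(tan 10° + tan θ)` with
first-order variance propagation (the chin-depth contribution is
subtracted). At T0 the unconstrained fit (signed mean ≈ −7.6 mm, MCP
posterior of ACP) reproduces the printed pattern of significantly larger
MCP-based lip distances before surgery. At T1 the unconstrained fit
(≈ −3.4 mm) would contradict the near-zero mean errors and non-significant
ACP-vs-MCP differences the same study reports, so the signed mean is pinned
near zero (−0.2 mm, the scale of the printed ME) and only the folded mean
is matched; the implied |x| SD is then about 2.9 mm against the printed
2.58 — an internal tension between the published chin-distance SD and the
agreement tables that a Gaussian generator cannot resolve both ways. The
headline validity results were given priority.

**What the generator does not emulate.** Lip heights are not controlled:
solving lip positions from the two distance constraints places each lip at
whatever height realizes its drawn offsets, so individual lips can sit
implausibly high or low, and the ACP-vs-MCP contrast for lips landing near
or above the line anchors is attenuated or sign-flipped relative to lips in
mid-face position. Consequently the generator reproduces chin-distance
summaries and post-surgery lip/agreement structure well but only
qualitatively reproduces the pre-surgery ACP-vs-MCP contrasts. There is
also no mesh, no landmark-detector error structure (jitter is isotropic
Gaussian), and no model of soft-tissue response to surgery: T1 is a fresh
draw correlated with T0, not a simulated osteotomy. Passing tests therefore
demonstrate correctness of the geometry and statistics and calibration of
the simulation, not clinical validity on real scans.

```{r}
cfg <- study_default_config(seed = 1)
cfg
```

## Numerical choices

* Angles are handled in degrees at the interfaces, radians internally, with
  dot products clamped to [−1, 1] before `acos`.
* Frame axes are orthonormal to 1e-9; collinearity is detected from the
  second singular value.
* The anterior-pointing line normal breaks ties (exactly horizontal
  normals) toward positive superior.
* Paired differences below 1e-12 mm — far below measurement resolution —
  are treated as zero so that the degenerate-cohort convention p = 1
  applies instead of amplifying floating-point noise.
* Output CSVs carry full precision (`%.15g`); rounding is left to the
  human-readable report.

## Problem sizes

The test suite exercises the geometric fixed point on 1,000 random
configurations, rigid invariance on 100 random 3D motions, statistical
oracles on 1,000 random datasets plus full 2^n Wilcoxon enumeration up to
n = 12, generator/measurer inversion on 500 noiseless records, and
calibration on 200 replicates of the 68-subject cohort — sizes at which
Monte-Carlo bands are tight enough to be informative while the whole suite
runs in a few minutes on one core.

```{r}
sim <- generate_cohort(cfg)
res <- run_validation(sim$cohort, quiet = TRUE)
res
```

## Known limitations

* The midsagittal frame convention (TLS plane, Sn′→G′ vertical) is a
  reasoned reconstruction, not a published specification; measurements on
  real exports from other software may differ by the frame choice.
* The seven midline landmarks are nearly collinear in the anterior
  direction, so the fitted plane's azimuth is the least stable frame
  component under lateral noise (the suite checks it against linearized
  error propagation rather than an optimistic fixed bound).
* Sex is modelled as a two-level factor with per-sex lip targets only;
  convexity and chin-depth distributions are shared across sexes, as the
  published sex difference in convexity (0.2°) is negligible.
* The ±2 mm aesthetic window and the 170° criterion are calibrated on
  Chinese profiles; neither is population-universal.
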