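# chinpoint

Soft-tissue cephalometric analysis of orthognathic-surgery profiles built
around the **modified chin point (MCP)**.

## The problem

Lip protrusion is conventionally judged against Steiner's *S* line (columella
midpoint Col → soft-tissue pogonion Pog′) and Ricketts' *E* line (pronasale
Pn′ → Pog′), with positions within about ±2 mm of either line rated most
aesthetic. Both lines are anchored at the chin, so in skeletal Class II/III
patients — the very patients planned for orthognathic surgery — the displaced
pogonion invalidates them. The MCP standardizes the chin first: the angle of
facial convexity ∠G′–Sn′–Pog′ (interior angle at subnasale between the rays
to glabella and to pogonion) is highly consistent at ≈170° in aesthetically
balanced profiles, so the MCP is defined by **horizontally projecting the
actual chin point (ACP) onto the ray from Sn′ that makes a 170° convexity
angle with the G′–Sn′ line**. Writing A for the G′–Sn′ line and M for that
ray, the signed horizontal offset

    x = a(MCP) − a(ACP)        (anterior-positive, mm)

quantifies the chin's deviation from the aesthetic criterion, and S/E lines
drawn to the MCP become comparable across skeletal classes.

The package implements, for seven midline 3D landmarks (G′, Sn′, Pn′, Col,
UL, LL, ACP ≡ Pog′) per subject and timepoint (T0 pre-, T1 post-surgery):

* midsagittal frame fitting (total-least-squares plane, Sn′→G′ vertical),
  projection, convexity angles, signed point-to-line distances;
* the line A / line M / MCP construction and the offset `x`;
* the four signed lip distances (UL, LL × S, E) under both ACP- and
  MCP-based reference lines, with the ±2 mm aesthetic flag and a >3 mm
  chin-deviation quality check;
* the method-validation statistics: descriptives with 95% CIs, paired t,
  exact Wilcoxon signed-rank (tie-exact by convolution), ME/MAE agreement,
  Pearson correlations, Welch t between sexes, Shapiro–Wilk gate,
  Bonferroni threshold (printed-rule and exact modes);
* a synthetic paired-cohort generator with known ground truth emulating the
  validation study's statistical structure (68 subjects, 28 male), for
  end-to-end testing and parameter-recovery experiments.

## Worked example

```r
library(chinpoint)

# one subject, already in sagittal coordinates (a anterior, s superior, mm)
cc <- chin_construct(g = c(0, 65), sn = c(0, 0), acp = c(4.2, -58),
                     target_angle = 170)
cc
#> Modified chin point construction (target convexity 170 deg)
#>   ACP: (4.200, -58.000) mm
#>   MCP: (-10.227, -58.000) mm
#>   horizontal offset x = -14.427 mm (|x| = 14.427)
```

The chin sits 4.2 mm anterior of the G′–Sn′ line (a protrusive, Class
III-type profile): its convexity angle is well above 170°, so the MCP lands
14.4 mm posterior of the ACP and reference lines drawn to it pivot backwards.

A full synthetic validation run:

```r
sim <- generate_cohort(study_default_config(seed = 1))
res <- run_validation(sim$cohort, quiet = TRUE)
res
#> Modified-chin-point validation: 68 paired subjects (threshold p < 0.01)
#>
#> ACP-to-MCP distance |x| (mm):
#>  timepoint  n mean   sd median iqr_25 iqr_75 wilcoxon_p
#>         T0 68 8.86 5.11   7.92   4.70  12.63   1.96e-07
#>         T1 68 4.16 3.70   2.89   1.53   6.19   1.96e-07
#>
#> Lip position ACP vs MCP (paired t):
#>  timepoint       label acp_mean mcp_mean        p
#>         T0 UL / S line    0.772    4.099 2.81e-05
#>         T0 LL / S line    5.651   10.328 1.41e-06
#>         T0 UL / E line   -3.230    0.475 8.27e-07
#>         T0 LL / E line    3.535    8.348 1.13e-07
#>         T1 UL / S line    1.050    1.529 2.95e-01
#>         T1 LL / S line    2.101    1.846 6.43e-01
#>         T1 UL / E line   -2.476   -2.081 3.64e-01
#>         T1 LL / E line   -0.346   -0.591 6.33e-01
#>
#> Method agreement at T1 (ACP - MCP):
#>        label me_mean me_sd mae_mean mae_sd
#>  UL / S line  -0.480  3.75     2.13   3.11
#>  LL / S line   0.255  4.51     2.58   3.69
#>  UL / E line  -0.396  3.57     2.00   2.98
#>  LL / E line   0.245  4.21     2.48   3.40
```

Read it as the method intends: before surgery the chin deviates strongly
from the 170° criterion (|x| ≈ 8.9 mm) and MCP-based lip distances differ
significantly from ACP-based ones (all p < 0.01); after surgery the chin has
moved toward the criterion (|x| ≈ 4 mm, Wilcoxon p < 0.01 for the T0 vs T1
drop), ACP- and MCP-based lip positions no longer differ significantly, and
the mean errors are near zero — the pattern that validates MCP as a
predictor of the post-surgery profile. `write_results(res, "out/")` writes
the tables as CSV plus a JSON summary; `sim$ground_truth` holds the drawn
values each estimate should recover.

A thin command-line front end ships in `inst/cli/chinpoint.R`
(`simulate`, `measure`, `validate`, `report` subcommands; see the file
header), and the methods vignette (`vignettes/mcp-methods.Rmd`) documents
the geometry, statistical conventions, generator calibration and
limitations.

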