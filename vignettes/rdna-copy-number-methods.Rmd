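---
title: "Measuring rDNA copy number and hypermethylated-copy content: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring rDNA copy number and hypermethylated-copy content: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnacn)
```

## The biological problem

The diploid human genome carries roughly 400 copies of a 43-kb ribosomal
DNA (rDNA) repeat, tandemly arrayed in the nucleolar organizer regions of
the five acrocentric chromosome pairs. Each unit contains a 13.3-kb region
coding for the 18S, 5.8S and 28S rRNAs plus an intergenic spacer. Copies
occur in three chromatin states: transcriptionally active hypomethylated
copies (fraction 1), inactive copies with methylation at some
promoter-region CpG sites (fraction 2), and hypermethylated,
heterochromatic copies (fraction 3). Two population-level observations
motivate this package: elderly cohorts show the same mean rDNA copy number
(CN) but a much narrower range and variance than younger cohorts, and
elderly genomes contain almost no hypermethylated copies; cultured
fibroblasts lose exactly their hypermethylated copies during replicative
senescence. `rdnacn` implements the full analytical chain behind those
observations as testable, seeded simulation plus estimation code.

## Coordinate model of the repeat unit

`rdna_unit()` represents one repeat on a continuous, TSS-relative axis:
position 0 is the transcription initiation point, upstream positions are
negative, and interval length is defined as `end - start`. The unit spans
`[-515, 42485)`. This convention reproduces the published probe-window
lengths exactly: p(ETS-18S) runs from -515 to 5321 (5836 bp ~ 5.8 kb) and
p(28S) from 8289 to 10702 (2413 bp). Exact restriction-site coordinates
inside the unit are published only graphically, so the default site table
is an explicitly schematic placement chosen to give four probe-detected
Csp6I fragments (two per probe window); it can be replaced wholesale via
`site_config`, and every downstream computation depends only on the site
table, never on sequence. Because the repeats are tandem, a single unit is
digested as a circle: the segment downstream of the last cut joins the
segment upstream of the first, avoiding artificial terminal fragments.

## Methylation-sensitive digestion

Csp6I (GT^AC) cuts irrespective of methylation; MspI cuts every CCGG;
HpaII cuts CCGG only when the internal cytosine is unmethylated. A
`methylation_profile` assigns each CCGG site a methylation probability:
fraction 1 uses 0 everywhere, fraction 3 uses 1 everywhere, and fraction 2
uses 0.8 at sites inside a promoter window of -200..+100 (the published
description names "some CpG sites in the promoter region" without
coordinates; both the window and the 0.8 are package defaults, stated once
here). Per-copy methylation states are seeded Bernoulli draws, so
partially methylated groups are representable and digestion is
bit-reproducible. `digest_genome()` aggregates per-fraction digests with
copy weights; fractions 1 and 3 are deterministic at the default profiles
and are digested once with the full fraction weight.

## The methylation index M and the retention model

Experimentally, M is the ratio of hybridization signals of the
(HpaII + Csp6I) and (MspI + Csp6I) digests of the same DNA, probed with
p(ETS-18S). MspI always reduces the array to small fragments; HpaII leaves
hypermethylated copies as large Csp6I-only fragments. For the ratio to
exceed 1 the membrane must respond differently to large and small
fragments; the literature gives the ratio but not the mechanism. The
package therefore makes the mechanism an explicit, documented assumption:
fragment retention on the membrane is a logistic function of log fragment
length. The half-retention length is calibrated numerically (against the
deterministic digest spectra of an unmethylated unit) so that the
effective gain

\[ g = \frac{\text{probe-weighted signal of the Csp6I-only spectrum}}
           {\text{probe-weighted signal of the fully cut spectrum}} \]

equals 22/3 (about 7.33). Under the three-fraction model with no
fraction-2 interference this yields the closed form

\[ M = 1 + f_{\mathrm{hyper}}\,(g - 1), \]

which pins both published anchors at once: \(f = 0.10\) gives
\(M \approx 1.63\), inside the published 2M band (1.3-1.7), and
\(f = 0.30\) gives \(M = 2.9\), the published 3M maximum. The inversion
`estimate_hyper_fraction()` is the same line solved for \(f\), clipped to
[0, 1]. Fraction-2 copies perturb M only through promoter-site blocking
inside the p(ETS-18S) window; simulation bounds the perturbation below
0.1 for 40% fraction-2 content (see the test suite). Classification uses
thresholds 1.3 and 1.8 placed in the gaps between the published group
ranges, with boundary values assigned upward.

`compute_M()` has two modes: `closed_form` evaluates the signal ratio
directly from spectra; `membrane` runs the full forward model (spotting
both hydrolysates, rendering with noise, densitometric quantification) and
averages three simulated experiments, matching the experimental practice
of reporting M as a mean of three.

## Membrane forward model and densitometry

A membrane carries 4-6 replicate dots per sample, six calibration
standards of known CN (defaults 200-700; the published standards' values
are not printed), and lambda-phage control dots that report nonspecific
signal. Dots are rendered as 2-D Gaussians truncated at 3 sigma over a
linear background gradient, with multiplicative dot-to-dot noise,
additive pixel noise, and a 16-bit saturation ceiling; a ground-truth
ledger records every dot's realized integral.

Quantification mirrors a densitometry program: intensity-weighted
centroid refinement within one pitch (displacements beyond 0.35 pitch are
flagged off-grid), local background as the median of an annulus at
1.5-2.5 aperture radii with pixels inside neighbouring apertures excluded
(the annulus widens once before flagging), background-subtracted integral
floored at zero, and saturation flags. Calibration subtracts the
mean lambda integral (the nonspecific floor) from all dots, then
estimates the slope as the mean of per-standard ratios
\((y_i - \text{floor})/(\text{copies}_i \times \text{ng}_i)\) - the
through-origin weighted least-squares solution appropriate for
multiplicative (constant-relative-error) noise. Two numerical findings
drove this choice, both visible in the development tests: a free-intercept
ordinary least-squares line under this noise has ~17% slope scatter whose
\(1/\text{slope}\) inversion biases CN upward by several percent, and
subtracting the fitted intercept during inversion makes per-sample
relative errors unstable. The OLS line is still fitted and reported as a
diagnostic. Standards are spotted in four replicate dots per level
(six levels, per the membrane design) for the same reason: single-dot
standards make the slope heavy-tailed. Per-dot copy number is
\((y - \text{floor})/(\text{slope} \times \text{ng})\); replicates are
averaged, and the replicate standard error and relative SE are reported.
Flagged dots never enter averages; a sample with no usable replicate is
explicitly missing, never zero.

### Noise calibration

The published replicate error of the method is a relative standard error
of 11 +/- 8%. The forward model's free parameter is the multiplicative
dot-to-dot coefficient of variation; a grid search over it, running the
full render-and-quantify pipeline (6 replicates, replicated standards),
gave mean relative SEs of 7.3%, 8.3%, 9.2%, 10.2%, 10.8% and 11.1% at
CVs of 0.18-0.28, so the default preset freezes `dot_cv = 0.28`. The
other preset components (background 300 counts, 15% gradient, pixel SD 8,
per-ng nonspecific signal 200) are plausibility choices, not fitted.

## Synthetic cohorts

The non-elderly (NE, ages 17-71, n = 525) CN distribution must satisfy
five published constraints simultaneously: support 200-711, mean 419,
SD 110, median 410, 10% below 272 and 15% above 541 copies. No common
parametric family does (a normal with the printed moments puts ~13%, not
15%, above 541), so the generator uses a monotone piecewise-linear
quantile function with knots at p = (0, .10, .25, .50, .70, .85, .95, 1);
the three free knot values were fitted once, offline, to reproduce the
printed mean and SD to machine precision, and are frozen in the package.
Sampling is inverse-transform, so all constraints hold by construction up
to Monte-Carlo error.

The elderly group (E, ages 72-91, n = 126) is modelled as survivors of
the NE distribution. Hard mode resamples the NE pool inside the observed
E support [272, 541]; soft mode uses logistic survival weights. Hard
truncation is the default because the published data pin exactly the
bounds and the hypothesis is qualitative; it yields an E-group CV of
about 0.17 versus the printed 0.16 without any fitted parameter.
Methylation groups are assigned with probabilities (0.50, 0.20, 0.30) in
NE and (0.90, 0.05, 0.05) in E, reproducing the published 20-of-40 versus
4-of-40 carrier counts in expectation; the published survey does not
print the NE 2M/3M split, so 30% 3M follows the statement that about 30%
of younger genomes carry considerable hypermethylated content, and 2M
takes the remainder. Hypermethylated fractions are uniform within 0-0.02
(1M), 0.05-0.12 (2M) and 0.13-0.30 (3M). Ages are uniform within group
ranges and sex is drawn at the published 545:106 ratio; no age or sex
dependence of CN is modelled because none is reported.

## Cohort statistics

Descriptive summaries report the CV unrounded (conventionally presented
at 2 decimal places). Group contrasts use the Mann-Whitney U test (exact
below nine observations without ties, tie-corrected normal approximation
otherwise) and the two-sample Kolmogorov-Smirnov test, both via the
standard library implementations. The published dispersion p-value is
reported without a named test, so the package supplies its own
construction - a pooled label-permutation test of the CV or range
difference with \(p = (1 + \#\{|T^\ast| \ge |T|\})/(B + 1)\) - and makes
no claim to reproduce the printed p-value exactly. Age-binned dispersion
profiles use 5-year bins in NE and 2-year bins in E, as published.

The survivor-truncation fit estimates hard bounds from the E-sample
extremes with the order-statistic endpoint correction
\(\hat a = x_{(1)} - (x_{(2)} - x_{(1)})\) (exactly unbiased for locally
uniform densities); simulation at the published cohort sizes recovers the
generating bounds with mean absolute error under 10 copies. The soft
variant fits logistic weight centres and a common scale by matching the E
mean and SD; centres are fitted rather than fixed at the sample extremes
because a soft-selected sample has tails beyond its logistic centres.

## Replicative senescence

A fibroblast line starts at passage 5 with its donor's leukocyte CN and
M (both are unchanged at passage 5 experimentally); M inverts to a
hypermethylated-copy count. Each passage, every hypermethylated copy is
lost independently with probability lambda; other copies are never
touched. Only endpoint observations are published, so geometric decay is
an assumption; the default lambda = 0.1 makes expected residual
hypermethylated content below 1% by the final passage even for the
shortest-lived line (final passages 45-66, parsed from the line names)
starting at the maximal 30%. Consequences, verified in tests: lines with
M ~ 1 keep a constant CN; high-M lines lose CN by `CN x f_hyper` in
expectation and their final M falls into the 1M band. Published
final-passage CN values exist only as figures, so simulations are
validated against the arithmetic of complete loss, not figure-read
numbers. Change calls compare passage 5 and the final passage with a
two-sigma criterion on the difference using the published measurement
SEs as defaults.

## What the synthetic data do and do not establish

The generators emulate the *statistical structure* of the published
cohorts and membranes: replicate-error magnitude, quantile constraints,
carrier frequencies, survivor truncation. They do not emulate sequence
context (no U13369 nucleotides are used), rDNA rearrangements, scanner
optics, or chemistry kinetics, and the retention mechanism behind g is an
assumption pinned only at two published (f, M) anchor pairs. A green test
therefore establishes internal consistency of the published numbers with
the package's models, not an independent measurement of any genome.

## Numerical and degenerate-input choices

Seeds flow through a single integer per entry point; any derived seed is
reduced modulo 2^31 - 2. Digestion with no cut sites returns one
full-length fragment. Calibration requires at least three usable
standards with positive spread and a positive slope, else the membrane is
rejected with an error. A constant sample has CV 0 and a degenerate flag.
Boundary M values classify upward. `estimate_hyper_fraction()` clips to
[0, 1]. The fraction-2 copy count is rounded to an integer number of
simulated copies with weights preserving the exact fractional total.

## Known limitations

Single-membrane CN estimates scatter with the full ~11% replicate error,
so individual worked examples can sit 10-20% from truth; population
statements in the tests always average over many membranes. The retention
gain is identifiable only up to the two published anchors; if the true
signal-loss mechanism differs (wash-off versus binding efficiency), f
estimates for intermediate M remain consistent with the anchors but are
model-dependent. The E-group generator reproduces the published support
exactly and the CV approximately; it does not model mortality dynamics.
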