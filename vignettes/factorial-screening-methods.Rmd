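---
title: "Methods: simulating and analyzing 2^4 factorial screening experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing 2^4 factorial screening experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mostscreen)
```

# The design and its analysis model

A MOST screening experiment crosses $k$ binary intervention components into
$2^k$ arms and estimates each component's *marginal* effect — the contrast
between all arms with the component on and all with it off — plus selected
interactions. `mostscreen` implements the $k = 4$ case used in digital
smoking-cessation research: personalization (P), website/text integration
(IG), dynamic tailoring (T), and message intensity (IS; "on" = tapered
schedule, "off" = abrupt drop-off). Arms are numbered so arm 1 is all-off
and arm 16 all-on, with IS varying fastest.

Two generalized linear models carry the whole analysis:

* **Binary outcomes** (each interactive feature; the dichotomized
  engagement metrics): logistic regression on the factorial design.
* **Feature-use count** (0–6): quasi-Poisson regression with log link and
  scale parameter $\varphi$ estimated by Pearson $\chi^2 / (n-p)$, which
  absorbs both over- *and* under-dispersion. A sum of six correlated
  Bernoullis is typically under-dispersed relative to Poisson
  ($\varphi < 1$); nothing in the machinery assumes $\varphi \ge 1$.

The inferential model uses interaction order 2 — four main effects and six
two-way interactions, third and fourth order excluded a priori — matching
the multiplicity budget of the design's power calculation. Arm-level
summaries instead use the saturated order-4 model, whose fitted arm means
equal the observed cell statistics exactly; that identity is property-tested
on random data.

Factor coding is dummy (0/1, off/abrupt = reference), so coefficients read
as conditional log odds ratios. Marginal on/off means are *not* read off
coefficients: `marginal_effects()` standardizes (g-computation) — every
participant's outcome is predicted with the factor forced on, averaged,
then forced off — which coincides with raw level means in the balanced
saturated case and generalizes beyond it.

# Effect sizes and their intervals

Standardized mean differences use the two study-specific formulas:

$$d_{\text{bin}} = \frac{p_1 - p_2}{\sqrt{p_1 q_1 + p_2 q_2}}, \qquad
  d_{\text{count}} = \frac{\mu_1 - \mu_2}{\sqrt{\varphi(\mu_1 + \mu_2)}}.$$

Both degenerate when the variance term vanishes ($p \in \{0,1\}$; both
$\mu = 0$); the package rejects those inputs with a distinct condition
class rather than returning `Inf`.

Confidence intervals for marginal means, raw differences and SMDs come
from a **parametric percentile bootstrap**: draw $B$ coefficient vectors
from $\mathrm{MVN}(\hat\beta, \hat\Sigma)$, evaluate the functional on each
draw, and take empirical percentiles (quantile type 7 throughout). The
source study cites a general percentile-bootstrap reference without
spelling out the resampling law; taking the asymptotic normal of the
coefficient estimates as the parametric model is the conventional reading
and is what the package does. The default $B = 10^6$ matches the study;
tests and interactive work use $10^3$–$10^5$. Draws on which a functional
is undefined are rejected and redrawn, with a warning above 1% rejections.
The count-SMD dispersion $\varphi$ is held at its point estimate across
draws — $\varphi$ enters only as a scale factor, and the study provides no
sampling model for it. Coverage of the interval for a marginal difference
is property-tested at 93–97% over 500 simulated trials.

# Between-arm comparison: the overlap rule

Comparing all 16 arms pairwise with individual 95% intervals is
conservative, because both interval centres are uncertain. The package
calibrates the individual confidence level so that *non-overlap* of two
equal-SE normal intervals is equivalent to a two-sided $z$-test at level
$\alpha$:

$$\gamma(\alpha) = 2\Phi\!\left(\frac{z_{1-\alpha/2}}{\sqrt2}\right) - 1,$$

giving $\gamma(.05) = 0.8342$. The study rounds this to "about 83.5%"; the
package computes $\gamma$ exactly from $\alpha$ rather than hard-coding
83.5, and reports the value used in the manifest. Arm CIs are built on the
linear-predictor scale ($\hat\eta \pm z_{(1+\gamma)/2}\,\mathrm{SE}$) and
back-transformed, so proportions never leave $[0,1]$. The overlap/z-test
equivalence is exact only in the equal-SE case; simulation shows $\ge 99\%$
agreement across unequal-mean pairs, which is the property the tests pin.

Degenerate cells (an arm with 0 or all events) have an infinite linear
predictor; for *display only* the package substitutes a continuity-adjusted
interval (half an event and non-event added), flags the arm, and leaves the
point estimate at the observed 0 or 1. Arm summaries from the study's
tables sit an alternative route (bootstrap of arm means) away; the
saturated-GLM route is the default and only route here, since the two
coincide to Monte-Carlo error and the GLM route is deterministic.

# Design calculator

The a-priori calculation is reproduced in closed form. For a standardized
outcome, the main-effect contrast compares $n/2$ versus $n/2$ participants
(SE $= 2/\sqrt n$); the two-way interaction contrast is a four-cell
difference-of-differences whose SE is exactly twice that. With Bonferroni
adjustment $\alpha' = \alpha/m$,

$$d_{\min} = (z_{1-\alpha'/2} + z_{1-\beta}) \cdot \mathrm{SE}, \qquad
  \text{power}(d) = \Phi(d/\mathrm{SE} - z_{1-\alpha'/2}) +
                    \Phi(-d/\mathrm{SE} - z_{1-\alpha'/2}).$$

At $n = 864$, $\alpha = .05/10$, power 80%: $d_{\min} = 0.248$ for main
effects (the planned 0.25) and exactly twice that, 0.497 ≈ 0.50, for
two-way interactions; the power for $d = 0.25$ is 80.7%. The original
calculation was framed on a composite engagement score whose weights were
never published; the calculator therefore takes any standardized outcome,
which is the natural generalization. $z$ (not $t$) quantiles are used,
matching the published numbers. A raw-data Monte-Carlo oracle (100,000
simulated trials) confirms the power formula within 1%.

# What the generator emulates — and what it does not

`default_scenario()` states the world the tests assume. Its defaults are
the study-wide summaries, fixed once from the published values and not
revisited:

| quantity | default | source of the value |
|---|---|---|
| feature base rates | .858, .554, .370, .334, .153, .127 | observed usage rates |
| feature-count mean / SD | 2.40 / 1.41 | observed moments |
| latent loading $\lambda$ | 1.2555 | solved so count SD = 1.41 |
| page views | NB($\mu$=24.42, size=0.536) | fits P(≥15)=.450, P(≥25)=.322 |
| minutes on site | logN(1.884, 1.554) | fits Q55=8 min, P(≥15)=.298 |
| return visits | NB($\mu$=0.749, size=0.6) | fits P(≥1)=.385 |
| mobile fraction | 0.834 | 721/864 enrolled mobile |
| completion / unenrollment | 53.5%; logN(log 8, 1.477) | median day 8, IQR 3–22 |

Design choices where the source is silent:

* **Randomization**: permuted blocks of 16 within device stratum, with the
  final partial block completed against running overall totals — this
  yields the exact 54-per-arm balance the published tables imply whenever
  $16 \mid n$, and within-stratum imbalance $\le 1$ always.
* **Feature dependence**: the six indicators share one Gaussian latent
  propensity ($\lambda Z_i$ on the logit). Independent Bernoullis cap the
  count SD near 1.03, far below the observed 1.41, so *some* dependence
  structure is forced; a single factor is the most parsimonious. The
  feature–feature correlation matrix it implies is a modeling choice the
  study cannot confirm. Per-arm intercepts are calibrated by root finding
  so marginal probabilities equal their targets *exactly* — effects are
  stated and recovered on the marginal scale, and the latent factor only
  induces within-person correlation.
* **Skewed metrics**: log-normal minutes and negative-binomial page
  views/return visits, matched to the published dichotomization
  prevalences; only those quantiles are authoritative, not the full shapes.
* **Attrition** is descriptive (an unenrollment day per participant) and
  never censors outcomes, because the analysis includes all randomized
  participants.

A green simulation-based test therefore establishes calibration against
these stated moments and internal consistency of the estimators — not that
real engagement data follow log-normal/NB laws or a one-factor dependence.

# Numerical conventions

* Dichotomization picks the observed cut whose high fraction is nearest
  the target (default 1/3), ties toward the smaller cut; percentile sweeps
  use "nearest observed value at or above the target rank", so cuts are
  attainable thresholds of integer metrics.
* IRLS via `stats::glm`, tolerance $10^{-8}$, max 100 iterations; rank
  deficiency is an error naming the collinear terms; possible separation
  (fitted probabilities at machine 0/1 with extreme coefficients) is a
  flagged warning, not silent.
* Bootstrap and empirical quantiles are type 7 everywhere.
* Every simulating or resampling function takes an integer `seed`;
  `run_pipeline()` derives per-stage streams from one root seed and
  records all of them, with $\gamma$, $\varphi$ estimator, cut points and
  $B$, in its JSON manifest. Reruns are byte-identical.
* Whether the enrollment-device stratum entered the study's analysis
  models is unstated; `fit_factorial(stratum_adjust =)` exposes it, off by
  default.

# Known limitations

* SMD trailing digits computed from *published, rounded* marginal
  percentages can differ from published SMDs by one unit in the last digit;
  the package asserts the formula, not third decimals of rounded inputs.
* The overlap rule is calibrated for equal SEs; with a degenerate and a
  regular arm the equivalence to the $z$-test loosens.
* No nonparametric (case-resampling) bootstrap and no exact small-sample
  intervals are provided.
* The abandoned composite engagement score (unpublished weights) is out of
  scope; the calculator's standardized-outcome framing covers its design
  role.
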