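---
title: "Methods: from activity counts to mediated decision competence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from activity counts to mediated decision competence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`sednet` implements a complete observational-neuroscience analysis chain:
minute-epoch accelerometry is reduced to daily sedentary and
moderate-to-vigorous physical activity (MVPA) exposures; regional
resting-state BOLD time series are turned into weighted functional
connectivity matrices; weighted graph efficiency summarizes each intrinsic
connectivity network; a six-test decision-making competence battery is
scored; and a three-step mediation analysis with percentile bootstrap
confidence intervals asks whether network efficiency carries part of the
exposure–outcome association. A seeded synthetic-cohort generator with
planted effects makes the whole chain testable without participant data.

This vignette is the package's own account of the models, conventions and
design choices; every empirical statement here is one the test suite or the
acceptance script computes.

# Accelerometer processing

Counts are consumed on a strict 60-second epoch grid. Processing follows the
standard count-based conventions:

* **Non-wear**: every epoch inside a maximal run of at least 60 consecutive
  zero-count minutes. The rule is strict by default (a single nonzero epoch
  breaks the run); a `spike_tolerance` parameter optionally coalesces runs
  separated by one or two isolated nonzero epochs, in the style of the older
  interruption-tolerant conventions. Detection operates on the continuous
  per-subject series, so runs spanning midnight are found as one run and
  only split by calendar day for the daily accounting.
* **Intensity cut-points**: a wear epoch is sedentary below 100 counts per
  minute and MVPA at or above 2020 CPM; everything between is light. The
  boundaries are closed exactly as written (99 is sedentary, 100 light;
  2019 light, 2020 MVPA), and the tests pin these boundaries.
* **Validity rules**: a day is valid with at least 600 minutes (10 h) of
  wear; a participant is included with at least 4 valid days. Participant
  means are computed over valid days only, and a participant with no valid
  day gets missing (never zero) means.
* **Guidelines flag**: weekly moderate-equivalent MVPA of at least 150
  minutes. Count-processed MVPA cannot reliably be split into moderate and
  vigorous, so all MVPA minutes count as moderate-equivalent; this is a
  documented convention, not a claim about the underlying behavior.
* **Wear-time covariate**: the mean wear minutes over valid days, carried
  into every regression as an adjustment variable.

# Connectivity matrices

For each subject the recipe is: Pearson correlations between all regional
time series; Fisher z transformation (`atanh`); standardization by the
sampling standard deviation $\sigma = 1/\sqrt{n-3}$ with $n$ volumes;
Bonferroni thresholding over the $p(p-1)/2$ unique node pairs with all
negative and sub-threshold entries set to zero; rescaling of the surviving
scores to $[0,1]$ weights; and extraction of per-network principal
submatrices from a node-to-network assignment table.

Three conventions here were genuinely open and are resolved as follows:

* **Standardization direction.** Dividing the Fisher z values by $\sigma$
  (i.e. $Z = z\sqrt{n-3}$) makes $Z$ approximately standard normal under the
  null, which is what makes a normal-quantile Bonferroni threshold
  meaningful. The opposite reading (multiplying by $\sigma$) shrinks the
  values and is available as `literal_sigma = TRUE`, but it is not used in
  any default path.
* **Sidedness.** The Bonferroni threshold uses the two-sided quantile at
  $\alpha/(2m)$ and retains positive survivors only, matching the
  retain-significant-positive / drop-negative recipe; a one-sided option is
  exposed.
* **Rescaling.** "Rescaled to 0–1" is implemented as division by the
  per-subject whole-brain maximum surviving score, applied before network
  extraction, so the strongest surviving connection in a subject's brain has
  weight 1 and relative edge strengths are preserved within subject.

Motion diagnostics follow the DVARS boxplot rule: the framewise
root-mean-square signal change is flagged as an outlier above
$Q_3 + 1.5\,\mathrm{IQR}$, with quartiles computed by linear interpolation
(R quantile type 7 — one definition had to be fixed; it is recorded in the
provenance sidecar). Flags are reported only; frame censoring belongs to
image preprocessing, which is out of scope.

# Weighted graph efficiency

Connection weights $w_{ij} \in [0,1]$ are converted to lengths
$L_{ij} = 1/w_{ij}$ (the standard map for connectivity weights; $-\log w$
is available but excluded from default analyses), and shortest weighted
path lengths $d^w_{ij}$ are computed exactly by Dijkstra's algorithm.

**Global efficiency** of an $n$-node network is

$$E^w_{glob} = \frac{1}{n}\sum_{i} \frac{\sum_{j \ne i} (d^w_{ij})^{-1}}{n-1},$$

with unreachable pairs contributing zero. Because weights are at most 1,
every distance is at least 1 and $E^w_{glob} \in [0,1]$, reaching exactly 1
on the complete unit-weight graph; multiplying all weights by $s \in (0,1]$
scales it by exactly $s$. These closed forms are pinned in the tests.

**Local efficiency** of node $i$ uses its neighbor set $N_i$
($w_{ij} > 0$), with shortest paths restricted to the subgraph induced by
$N_i$:

$$E^w_{loc}(i) = \frac{\sum_{j \ne h \in N_i} w_{ij} w_{ih}
\left[d^w_{jh}(N_i)\right]^{-1}}{k_i (k_i - 1)},$$

and the network value is the mean over nodes. Two resolutions, both
supported by tests against definition-literal oracles:

* $k_i$ is the **binary degree** (the number of links). A weighted-degree
  denominator cannot guarantee the documented 0–1 range; the number-of-links
  reading does, and matches the verbal gloss of the quantity.
* The default `"product"` variant uses the plain product
  $w_{ij} w_{ih} (d^w_{jh})^{-1}$; the `"rubinov_sporns"` variant applies
  the cube root to each term, which is the form standard in the weighted
  connectivity-measures literature. Both are first-class; the default
  follows the printed equation.

Nodes with fewer than two neighbors have local efficiency 0.

# Competence battery scoring

The six test scores, each pinned to its documented range:

| Test | Score | Range |
|---|---|---|
| Resistance to framing | $5 - \overline{|gain - loss|}$ over frame pairs | 0–5 |
| Resistance to sunk cost | mean keyed rating (6 = full discounting) | 1–6 |
| Consistency in risk perception | fraction of coherent probability judgments | 0–1 |
| Recognizing social norms | Spearman correlation of estimated vs cohort endorsement rates | −1–1 |
| Applying decision rules | fraction of problems solved per the keyed rule | 0–1 |
| Over/underconfidence | $1 - |\overline{conf} - \overline{acc}|$ | 0–1 |

Notes on the contested readings: the sunk-cost description ("number of
times … on a 1–6 scale") is scored as the mean keyed rating, the only
reading consistent with a 1–6 item scale; calibration is mapped so that
higher is better on 0–1; the coherence predicates cover the three rule
families (subset/superset, complement sum, union bound) with a complement
tolerance of 1e-8 — exact up to the floating-point representation of
probabilities that have passed through delimited text; and the "actual"
norm endorsement rates are computed within the analyzed cohort, since
external peer base rates are not available to the package. An all-tied
norms vector has no rank correlation and is flagged missing, never zero.

The composite index is the unweighted mean of the six per-test cohort
z-scores; a test with zero cohort variance is dropped from the index with a
warning.

# Statistical chain

Skewed variables are normalized before modeling: negatively skewed scores
are reflected ($x \mapsto \max(x)+1-x$, so reflected coefficients reverse
sign — the transform table flags this) and then power-transformed;
positively skewed ones are power-transformed directly. The Tukey ladder
exponent is chosen from the grid $\lambda \in [-3,3]$ in steps of 0.05 by
maximizing the Shapiro–Wilk statistic, with $x^\lambda$ for positive
$\lambda$, $\log x$ at 0, and $-x^\lambda$ for negative $\lambda$ so the
map stays monotone increasing. The selection criterion is a convention
(only the transform family is canonical); `transform = "none"` disables the
whole step, and the automatic rule only fires at |skewness| > 0.5.

Associations are ordinary least squares with classical standard errors;
standardized coefficients are reported as
$\beta^{std} = \hat\beta \cdot sd(x)/sd(y)$, and each predictor's
contribution as $\Delta R^2$ against the covariate-only model. Rank
deficiency is an error that names the collinear columns, never a silent
drop. False-discovery-rate control is Benjamini–Hochberg, applied within
each analysis step's family (all step-1 screens form one family, all step-2
screens another); the family layout is configurable and recorded, since
finer guidance is not available.

**Mediation** is the three-regression decomposition with shared covariates:
$a$ from $M \sim X + C$, $b$ and $c'$ from $Y \sim X + M + C$, $c$ from
$Y \sim X + C$, indirect effect $ab$, and the exact identity
$c = c' + ab$ (asserted to 1e-10 on every fit). Inference on $ab$ uses
case-resampling percentile bootstrap confidence intervals (default 10,000
resamples), significant when the interval excludes zero — the default
behavior of the common macro implementations; a bias-corrected variant is
deliberately not part of the default analysis. Step-3 mediation models are
fitted only for exposure–mediator–outcome triples whose step-1 and step-2
screens both pass at the FDR-corrected level.

# The synthetic cohort

The generator plants a full exposure → mediator → outcome structure and is
itself a tested module. Its defaults emulate the cohort the pipeline is
designed for: daily sedentary time N(603.6, 119.2) minutes, MVPA
N(41.3, 24.8), wear windows of about 06:30–22:30 with one planted 90-minute
non-wear block per day, seven days of wear, 300-volume ROI series, seven
networks, and covariates (age, sex, education, BMI, IQ, fitness) drawn
independently with realistic means — no confounding by default, so
parameter recovery has a clean baseline.

Counts are lognormal within each cut-point band, clamped to the band; wear
sedentary counts are floored at 1 so that zero runs occur exactly where
non-wear is planted, and the daily wear-window jitter is clamped so
boundary zero runs always exceed the 60-minute rule. Together these make
the planted daily band minutes *exactly* recoverable, which the acceptance
suite requires.

Two modes separate unit-level from integration-level checks:

* **Tabular** mode bypasses the time-series and graph stages. The exposure
  enters standardized, the mediator is the planted latent
  $M = a X^{std} + \varepsilon_m$, and the outcome is
  $Y = b M + c' X^{std} + \gamma'C + \varepsilon_y$ with defaults
  $a = -0.5$, $b = -0.4$, $c' = 0.3$ and unit noise — exact ground truth
  for the statistics module.
* **Full** mode drives within-network coupling from sedentary minutes,
  $\lambda_i = 1 - 0.0006\,(sed_i - 603.6) + \varepsilon$
  ($\varepsilon \sim N(0, 0.08)$), with the within-network correlation
  $\mathrm{clip}(0.40\,\lambda_i,\ 0,\ 0.95)$ for the four cognitive
  networks. The three sensory networks keep a fixed coupling of 1.25 so the
  per-subject whole-brain rescale maximum is stable and does not cancel the
  planted effect. The mediator entering the outcome model is the dorsal
  attention network's global efficiency *as computed by the package's own
  connectivity and graph stages*, with planted $b = 10$ per efficiency unit
  and $c' = 0.003$ per sedentary minute — moderate-to-strong standardized
  effects (roughly 0.3–0.5) chosen once so the chain is detectable at
  cohort sizes of 100–200. The latent outcome then drives the item-level
  battery responses, each of whose six scores increases in the latent
  ability in expectation.

What the generator does **not** emulate: motion and physiological
artifacts, non-Gaussian BOLD features, confounded covariates (switchable
on), heavy-tailed count distributions across days, or item-level content
effects. Green tests therefore certify the pipeline's algebra, conventions
and error control — not robustness to real-data pathologies.

# Numerical choices and degenerate inputs

* Shortest paths: exact Dijkstra through `igraph`; test oracles use an
  independent Floyd–Warshall and, for local efficiency, a literal
  double-loop over restricted-subgraph distances.
* A thresholded matrix with no surviving edge rescales to the all-zero
  matrix with a warning; efficiency of an edgeless network is 0, not an
  error; a 1-node network has no global efficiency (error).
* Perfectly correlated nodes (|r| = 1) are rejected at the Fisher step —
  degenerate synthetic inputs must be fixed upstream, not silently clipped.
* Bootstrap resamples that happen to be rank-deficient are dropped (and
  counted); percentile endpoints use linear-interpolation quantiles.
* Seed policy: one integer seed drives cohort generation; analysis-level
  bootstrap seeds are derived deterministically per mediation so that
  reruns are byte-identical end to end.

# Problem sizes used by the checks

The test and acceptance workloads are sized for a single CPU: 100 random
graphs (up to 30 nodes) for the shortest-path oracle and 40-graph batches
for the local-efficiency oracles; 200 null subjects at 50 nodes x 300
volumes for the family-wise error check; 200 replications at n = 200 with
1,000 bootstrap resamples for mediation recovery and coverage; and 50
seeded full-mode cohorts at n = 150, 40 nodes, 300 volumes for end-to-end
sign recovery. The demo pipeline configuration (20 subjects, 28 nodes)
completes in well under five minutes.

# Known limitations

* The per-subject rescaling ties efficiency values to the subject's
  strongest connection; cohort-wide rescaling is available but untested
  against planted effects.
* Observational mediation identifies a decomposition, not causation; the
  package fits the model and reports it, nothing more.
* The battery item designs are stand-ins with the documented scoring
  contracts, not reproductions of the original instruments.
* Raw-acceleration-to-counts conversion, image preprocessing and atlas
  construction are explicitly out of scope; their outputs are this
  package's inputs.
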