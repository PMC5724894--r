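---
title: "Three-group expression patterns in polar coordinates: methods and design"
author: "TriComp package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-group expression patterns in polar coordinates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TriComp)
```

## The problem

RNA-seq of cells sorted into the three cell-cycle phases G1, S and G2/M
yields, per gene, three expression levels. Pairwise fold changes describe
such a triple awkwardly: three ratios, two of them redundant, none of
which says directly *when* in the cycle the gene peaks. TriComp collapses
each triple into two interpretable numbers: an angle $\theta \in [0,
360)$ degrees that encodes the *relative pattern* of expression across
the ordered phases, and a radius $r \geq 0$ (log2 units) that encodes the
*magnitude* of that pattern. Genes peaking at the same point of the cycle
share $\theta$ regardless of expression level; flat genes have $r = 0$
and no defined angle.

## The transform

Write $e_1, e_2, e_3 > 0$ for the linear-scale expression levels in G1,
S and G2/M, and

$$d_{21} = \log_2 \frac{e_2}{e_1}, \qquad d_{31} = \log_2 \frac{e_3}{e_1}.$$

The centered log2 profile $(c_1, c_2, c_3)$, $\sum_i c_i = 0$, is placed
on three unit axes 120° apart — G1 at 30°, S at 150°, G2/M at 270°,
angles measured clockwise from straight up — and the three vectors are
summed. In closed form,

$$p = \tfrac{1}{2} d_{21} - d_{31}, \qquad
  q = -\tfrac{\sqrt{3}}{2}\, d_{21},$$

$$r = \sqrt{p^2 + q^2} = \sqrt{d_{21}^2 + d_{31}^2 - d_{21} d_{31}},
  \qquad \theta = \operatorname{atan2}(p, q) \bmod 360°,$$

with $\theta$ read clockwise from "up". The calibration is fixed by two
anchors: the triple $(1\,|\,2\,|\,4)$ — and any triple with the middle
group exactly halfway on the log scale, such as $(1\,|\,10\,|\,100)$ —
maps to $\theta = 240°$, and a gene peaking purely in G1/S/G2M maps to
30°/150°/270°. Categories are the six half-open 60° sectors,
$\mathrm{cat} = \lfloor \theta / 60 \rfloor + 1$; odd categories are
single-phase peaks (1 = G1, 3 = S, 5 = G2/M), even ones are highs in two
consecutive phases (2 = G1+S, 4 = S+G2/M, 6 = G2/M+G1). A boundary angle
belongs to the higher-numbered category, so 60° is category 2.

This projection is the unique (up to reflection) linear map of centered
log profiles that satisfies both anchors simultaneously; the package
implements only this canonical form. Useful consequences, all tested as
invariants: scaling a triple by any $c > 0$ leaves $(\theta, r)$
unchanged; cyclically permuting the phases rotates $\theta$ by 120°;
swapping S and G2/M reflects $\theta \mapsto (60 - \theta) \bmod 360$;
and $r = 0$ exactly when the triple is flat, in which case $\theta$ is
reported as `NA` and the category as `NA` rather than forced to a value.
Any fold-change filter above 1 removes these degenerate genes before
they reach downstream statistics.

```{r example}
res <- triComp(rbind(g1 = c(1, 2, 4), g2 = c(1, 10, 100),
                     g3 = c(5, 5, 5)))
as.data.frame(res)
```

## Where the fold changes come from

Two input routes are supported, and they matter to interpretation:

* **Counts**: given a count matrix and a phase design,
  `triComp()` uses differences of phase means of
  $\log_2(\mathrm{CPM} + 0.5)$. The pseudo-count of 0.5 is the
  conventional guard against $\log 0$; CPM rescales each sample to one
  million so library size cancels.
* **A precomputed differential-expression table** (e.g. an edgeR-style
  negative-binomial GLM analysis read with `readDETable()`): its two
  log2 fold-change columns are used verbatim. This is the route that
  reproduces published statistics exactly; everything downstream of the
  fold changes is identical.

`computeRPKM()` implements the per-sample-rescaled variant of
length-normalised expression — counts divided by transcript length, then
rescaled so each sample sums to one million — rather than classic RPKM,
because that is the convention the supported workflow uses for reporting
expression levels. It plays no role in the transform itself.

## The built-in significance screen

`phaseDE()` tests, per gene, whether expression differs across the three
phases: a one-way ANOVA of $\log_2(\mathrm{CPM}+0.5)$ with
Benjamini–Hochberg correction across genes. Two design points deserve
explanation.

**Variance moderation (default on).** With two or three replicates per
phase the per-gene residual variance has only 3–6 degrees of freedom,
and a plain per-gene F-test is then essentially powerless at stringent
FDR cut-offs such as 0.001: the smallest attainable p-values are orders
of magnitude too large, whatever the effect size. All standard RNA-seq
frameworks solve this by sharing variance information across genes, and
`phaseDE()` does the same: per-gene variances are shrunk toward a
mean-expression trend by empirical Bayes (`limma::squeezeVar`), and the
moderated F uses the posterior variance with augmented denominator
degrees of freedom. `moderate = FALSE` gives the textbook per-gene
ANOVA, which remains the reference for the hand-checkable examples and
for null-calibration tests (both paths give uniform p-values under the
null; both are verified by simulation in the test suite). Genes whose
within-group variance is exactly zero while means differ are flagged
(`degenerate`) and reported at the smallest positive double rather than
crashing or silently claiming $p = 0$.

**Batch handling.** With `batch` labels and `batchCenter = TRUE`, each
gene is mean-centered within batch (grand mean restored) before testing
and the residual degrees of freedom are reduced by (number of batches −
1). This is the additive two-way ANOVA treatment of a batch term — an
approximation chosen for transparency, not a GLM; confounded designs
(phase imbalanced across batches) are the user's responsibility.

**Stringency filter.** `stringencyFilter()` applies the three-way cut
used to call a gene significantly oscillating — FDR ≤ 0.001, mean
log2 CPM ≥ 1, maximal pairwise fold change ≥ 1.5 by default — and
reports per-criterion attrition counts. The fold-change criterion is
evaluated on the fitted phase means (`max_fc = 2^{\max_i m_i - \min_i
m_i}`), equivalently the largest pairwise |log2 FC|.

## Distribution statistics on the circle

`binTheta()` tallies genes into the six categories. Two tests compare a
gene subset's category distribution with a background:

* `gTestSubset()` — the log-likelihood-ratio (G) statistic
  $2\sum_k O_k \ln(O_k/E_k)$ with expected counts proportional to the
  background, $p$ from the $\chi^2$ upper tail at 5 df. Bins empty in
  both observed and expected are dropped (reducing df); an observation
  in a bin of zero background probability is impossible under the null
  and returns $p = 0$ with a warning.
* `exactMultinomialP()` — the exact multinomial test under likelihood
  ordering: the total null probability of all outcomes no more likely
  than the observed one. Full enumeration of compositions up to
  $n = 30$ (≈ 325k compositions at the cut-off); beyond that a seeded
  Monte-Carlo estimate with its standard error. The tie tolerance on
  log-probabilities is $10^{-7}$, so equal-probability outcomes count as
  ties rather than falling on either side by rounding.

`geneSetThetaProfile()` runs both tests for a named gene set. By default
set members are removed from the background first, so subset and
background are disjoint samples; `removeSubset = FALSE` gives the
alternative convention of testing against the full distribution
(including the subset), which is what one needs to mirror analyses that
test a subset against the complete oscillating set. When the set covers
the whole background the removal is skipped and the test degenerates to
$p = 1$.

`compareDatasets()` joins two per-gene polar tables and reports the
fraction of shared genes whose angles differ by less than a threshold
(default 60°, one category width), using the wrap-around circular
difference. `externalPhaseToTheta()` maps any periodic descriptor — a
circadian time in hours (period 24, 15°/h), a sinusoidal fit peak in
radians — linearly onto the $\theta$ circle; the rotation direction and
offset are explicit parameters, defaulting to $+1$ and 0°, because the
alignment between an external clock and the phase circle is a property
of the datasets being compared, not of the transform.

## The simulator and what it does (not) emulate

`simulateCycleCounts()` generates phase-sorted RNA-seq with known truth,
so that every pipeline stage is exercisable without any download. The
model, per gene: a baseline log2 expression drawn from
$N(\texttt{baselineLog2Mean}, \texttt{baselineLog2SD})$; for oscillating
genes a pattern angle $\theta^\*$ and a centered log2 phase profile
$c_i = s\,\cos(\theta^\* - \text{axis}_i)$ scaled so that
$\max c - \min c$ equals the configured amplitude (the inverse of the
transform: `archetypeMeans()` round-trips to $\theta^\*$ exactly, and at
category centers $r$ equals the amplitude); an additive per-(batch,
gene) Gaussian shift; expected counts proportional to expression ×
gene length, scaled to a log-normal per-sample library size; counts
negative-binomial with variance $\mu + \phi\mu^2$ (Poisson at
$\phi = 0$). The oscillating set has exactly
$\mathrm{round}(n \cdot \mathrm{frac})$ members, so truth tables are
deterministic given the seed.

Default parameters are the package's reference condition: 2000 genes,
30 % oscillating, amplitude 1.5 (log2 max−min, i.e. a maximal
fold change of ~2.8), dispersion 0.05, three replicates per phase in one
batch, library sizes ~2 million with CV 0.2, baseline
$N(5, 2)$ on the log2 scale, gene lengths uniform on 500–5000 bp. The
unstated-by-construction choices (baseline distribution, library sizes,
lengths) were fixed once at values typical of bulk RNA-seq of sorted
cell populations. What the simulator deliberately does **not** emulate:
sorting impurity between phases (real sorted fractions are mixtures),
tagwise dispersion variation, correlated gene modules, or single-cell
sparsity. Passing the recovery tests therefore demonstrates that the
pipeline's inference machinery is correct and calibrated under the
stated generative model — not that real sorted data will reach the same
sensitivity.

At the reference condition the full pipeline (CPM → moderated test → BH
→ stringency filter → transform) detects ≈ 89 % of truly oscillating
genes at FDR ≤ 0.001 with FC ≥ 1.5, with a median angular error around
7° among detections and essentially all detections in the true or an
adjacent category; these figures are recomputed by the test suite. The
~11 % misses are a power boundary, not a defect: under this generator
the same sensitivity ceiling is reached by full negative-binomial GLM
pipelines, because at three replicates per phase an amplitude-1.5 gene
sits near the detection limit implied by a BH cut-off of 0.001 across
2000 genes.

## Numerical and interface conventions

* $\theta$ in degrees, $[0, 360)$; `NA` (never 0 or 360) encodes
  "undefined"; files write `NA` literally and carry $\theta$ with four
  decimals.
* Half-open category bins; the boundary goes to the higher-numbered
  bin.
* Log base 2 everywhere a log is taken.
* TSV is the canonical table format; CSV is accepted on read by
  delimiter sniffing. Gene identifiers match by exact string equality
  after whitespace trimming — no alias resolution.
* Readers validate and refuse to coerce (duplicate gene ids,
  non-integer counts, unknown phase labels and short GMT lines are
  errors that name the offending row or line).
* All stochastic functionality (simulation, Monte-Carlo p-values,
  jitter in strip plots) takes an explicit seed and restores the
  caller's RNG state.
* Plots use the same orientation as the transform (0° at the top,
  clockwise), so polar figures read directly in phase order G1 → S →
  G2/M; tests assert on the plot's stored data coordinates, never on
  rendered pixels.

## Problem sizes used by the test suite

The suite verifies symmetries on 10,000 random triples, the exact
multinomial test against brute-force enumeration for every composition
up to $n = 5$ under three probability vectors, G-test type-I error on
10,000 null subsets of size 50, null uniformity of the ANOVA on a
1000-gene null simulation, and end-to-end recovery on the 2000-gene
reference simulation — sizes chosen to make the checks statistically
meaningful while keeping a full run comfortably fast on a laptop.

## Known limitations

* The built-in screen is a moderated ANOVA on log-CPM, not a count GLM;
  for published-grade differential testing import an edgeR-style table
  and let the package take over from the fold changes onward.
* Exactly three ordered groups; no pseudotime, no more-than-three-phase
  designs.
* Transcript-level quantification and splice variants are out of scope;
  one row is one gene.
* The G test relies on the $\chi^2$ approximation; for small subsets
  (tens of genes) prefer the exact test, which is also provided.
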