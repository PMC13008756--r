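---
title: "Methods: Delphi consensus statistics and the hierarchical quality index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Delphi consensus statistics and the hierarchical quality index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delphiqi)
```

## The problem

National food-safety standard frameworks (NFSSF) — the full set and structure
of a country's mandatory food-safety standards — are hard to evaluate with
cost-effectiveness or cost-benefit analysis: confounders abound and benefits
resist monetisation. An alternative is a multi-criteria evaluation instrument:
a three-layer indicator tree (first-layer *dimensions*, second-layer
*criteria*, third-layer *items*) built and weighted by a structured expert
consensus (Delphi) process, scored by a competency-weighted survey, and
validated psychometrically. `delphiqi` implements that whole chain as reusable,
tested functions plus an `analysis/` workflow that runs it end to end on
simulated data.

## The expert competency model

Each expert receives a 100-point competency score over four capped dimensions:
background (10), know-how and skill set (20), anchored behavior — familiarity
with the standard framework — (60), and survey engagement (10). The score has
two roles:

* **inclusion filter** — only experts with scores *strictly above* 50 enter
  the panel (`select_panel()`); the strict comparison matches an observed
  minimum included score of 51;
* **rating weight** — an included expert's score is their weight $W_i$ in
  every weighted mean.

Sub-scores are real-valued; the caps are enforced, but no within-dimension
rubric is prescribed (none is standard), so the simulator simply draws
sub-scores uniformly within configurable per-dimension bounds.

## Per-indicator Delphi statistics and screening

Ratings are integers on a 10-point importance scale; a rating of 0 is a
*deletion vote*, excluded from the importance statistics and tallied
separately (their arithmetic treatment is otherwise unspecified, and mixing
"delete" with "unimportant" would bias the means). Per indicator $j$ with
ratings $C_{ij}$:

* mean $M_j = \frac{1}{m_j}\sum_i C_{ij}$;
* weighted mean $\bar X_j = \sum_i W_i C_{ij} / \sum_i W_i$;
* full-mark rate $K_j$ = fraction of experts rating 10 (concentration);
* coefficient of variation $V_j = \sigma_j / \bar X_j$ with the sample
  standard deviation ($n-1$) in the numerator (dispersion; lower = better
  expert coordination). The weighted mean is used as the denominator because
  it is the quantity the screening rule compares; with an unweighted
  denominator all packaged checks would change only in the third decimal.

**Screening.** An indicator is retained iff $\bar X_j \ge 7$ *and*
$V_j < 0.25$, otherwise excluded with the violated criterion recorded. The
rule as usually stated ("excluded if the weighted mean fell below 7 and
$V_j$ below 0.25") is self-contradictory when read literally alongside its
retention clause; this conjunction is the only reading under which both
clauses are consistent, and it makes screening monotone (raising $\bar X_j$
or lowering $V_j$ can never flip retain to exclude).

**Cascade deletion.** If all third-layer items under a criterion are deleted,
the criterion is deleted, and recursively upward; conversely, deleting an
upper node deletes its subtree. Deleted indicators are status-marked, never
removed, so round-over-round diffs are reproducible. Additions between rounds
carry status `added` and count as active.

## Kendall's coefficient of concordance

Panel-level agreement across the $k$ indicators uses the tie-corrected
coefficient of concordance. Each expert's ratings become mid-ranks; with rank
sums $R_j$ and per-expert tie terms $T_i = \sum_{\text{groups}} (t^3 - t)$,

$$W = \frac{12\sum_j R_j^2 - 3b^2k(k+1)^2}{b^2k(k^2-1) - b\sum_i T_i},$$

with $0 \le W \le 1$. Significance uses the chi-square approximation
$\chi^2 = b(k-1)W$ on $k-1$ degrees of freedom (upper tail) — the classical
"dominance test" of concordance. Ten-point ratings of 40+ indicators are
tie-heavy, so the correction matters; a rater who gives every indicator the
same rating contributes zero rank variance and is absorbed by the correction,
but if *every* rater is constant the denominator vanishes and $W$ is
undefined — `kendalls_w()` rejects that case with a diagnostic, while
`compute_round_stats()` records the diagnostic and still reports the (valid)
per-indicator statistics.

## Weights and the quality index

After the final round, weights are set from that round's weighted means
within every *sibling group* (indicators sharing a parent; the first-layer
dimensions form one group):
$W_j = \bar X_{pj} / \sum_{p} \bar X_{pj}$. Whether second-layer weights
should be normalised within their parent or globally is ambiguous in the
usual presentation; the sibling-group reading is adopted because it is the
one that reproduces first-layer weights that sum to exactly 1. Each group's
weights then sum to 1 (to 1e-12), weight ratios equal weighted-mean ratios,
and every aggregate is a convex combination.

Assessment scoring: third-layer final scores are the competency-weighted
means of the assessment ratings (1..10, no deletion votes at this stage);
each upper-layer score is $\sum_{\text{children}} \text{score} \times
\text{weight}$, and the quality index (QI) is the weighted sum over the
dimensions. Constant leaves give QI equal to that constant exactly; scaling
all leaves scales the QI; raising any leaf never lowers it.

**Rounding.** All arithmetic is done at full precision; only the report layer
rounds, half-up (not banker's), to 2 decimals for scores and 3 for weights
and fit indices.

## Scale validation

**Reliability.** Cronbach's
$\alpha = \frac{p}{p-1}\bigl(1 - \sum_j s_j^2 / s_T^2\bigr)$, flagged below
0.7.

**Construct validity.** A confirmatory factor analysis in which each of the
30 third-layer items loads on exactly one of the three dimensions (simple
structure, correlated factors). Upper layers are aggregates, not items, so
they do not enter the CFA. Identification fixes the factor variances at 1
with all loadings free, which is what makes a full set of standardized
loadings reportable; the marker-item alternative is not used. Items are
treated as continuous and fitted by maximum likelihood — the conventional
choice for 10-point scales.

The fit minimises
$F_{ML} = \ln|\Sigma| + \mathrm{tr}(S\Sigma^{-1}) - \ln|S| - p$ over
$\Sigma(\theta) = \Lambda\Phi\Lambda^\top + \Psi$. Numerical choices:

* error variances optimised as $\log\psi$ and factor correlations through
  $\tanh$, so every iterate is admissible ($\psi > 0$, $|\phi| < 1$) and
  Heywood cases can only appear as boundary flags, not as negative variances;
* BFGS with analytic gradients
  ($\partial F/\partial\Sigma = \Sigma^{-1} - \Sigma^{-1}S\Sigma^{-1}$,
  chained through $\Lambda$, $\Psi$, $\Phi$); start values
  $\lambda_j = 0.5\,\mathrm{sd}_j$, $\psi_j = 0.5\,s_j^2$, $\Phi = I$;
  a second BFGS pass polishes the solution; convergence is declared when the
  gradient max-norm is below 1e-5; iteration cap 1000;
* a non-positive-definite $\Sigma$ during the search returns a large penalty
  value rather than an error;
* the sample covariance uses the $n-1$ denominator, and
  $\mathrm{CMIN} = (n-1)F_{ML}$ (the Wishart convention — the multiplier is
  not universal across software, which is one reason published CMIN values
  are hard to reconstruct without raw data).

**Absolute fit.** $df = p(p+1)/2 - (2p + n_f(n_f-1)/2)$ (402 for 30 items on
three factors). CMIN/df below 3 is classified *acceptable*, below 5
*debatable*, otherwise *poor*. SRMR is the root mean square of
correlation-metric residuals $(s_{ij}-\sigma_{ij})/\sqrt{s_{ii}s_{jj}}$ over
all $p(p+1)/2$ unique elements, diagonal included (diagonal residuals are
negligible when error variances are free). "Close to 0.08 and below" is
operationalised as: acceptable iff SRMR rounds (half-up, 2 d.p.) to at most
the 0.08 threshold, so 0.082 is acceptable and 0.086 is not. Comparative and
parsimony-corrected indices (CFI/TLI, RMSEA) and modification indices are
deliberately out of scope: a Delphi-constructed instrument is validated
against its own theoretical structure, not re-specified post hoc.

## The simulator: what it emulates, and what it does not

`generator_config()` fixes the study conditions: 51 experts with competency
sub-scores drawn uniformly in per-dimension bounds summing into 51..89; true
indicator importances $\mu_j \sim U(8, 9.8)$; ratings
$\mathrm{clamp}(\mathrm{round}(\mu_j + \varepsilon), 1, 10)$ with
$\varepsilon \sim N(0, 0.8^2)$; deletion-vote probability 0; factor-model
loadings $U(0.46, 0.91)$ with inter-dimension correlations 0.6 and, in
standardized mode, $\psi_j = 1 - \lambda_j^2$. The importance range and noise
are chosen so that a consensus panel emerges — every indicator clears the
screening thresholds (weighted means above 7, CVs roughly 0.05–0.12) — which
is the regime the pipeline's round logic is designed around; no distributional
form for expert ratings is standard, so the Gaussian-round-clamp model is a
package convention, not a claim about real panels. Near the top of the scale
the clamp biases the expected rating below $\mu_j$ (about $-0.2$ at
$\mu_j = 9.8$); tests therefore compare generated means against the enumerated
expectation of the clamped, rounded variable rather than against $\mu_j$.
Likert discretisation of the factor responses is off by default because
rounding biases loading recovery; a flag enables it.

What the simulator does **not** emulate: opinion change between rounds
(anchoring, convergence dynamics), item-level floor/ceiling asymmetries,
correlated rater effects beyond the factor structure, and free-text comments.
Passing tests on simulated data therefore demonstrate the *correctness of the
computations* under the stated model, not the behaviour of real expert
panels.

## Problem sizes and determinism

Every generator is a pure function of (config, seed) via `withr::with_seed`;
identical inputs give byte-identical outputs, and the `analysis/` scripts
record seed and config in provenance blocks. The test suite exercises the CFA
at $n = 2000$ (parameter recovery, 9 items), $n = 500$ across 20 replicates
(fit-acceptability regime, 30 items) and $n = 300{-}500$ elsewhere; the
workflow scripts use $n = 500$ respondents for validation and a 51-expert
panel for the Delphi stages — sizes at which the recovery properties hold
comfortably while a full run stays in seconds.

## Known limitations

* The chi-square test for $W$ is an approximation; exact permutation tests
  are not implemented.
* The CFA assumes complete, continuous responses; no categorical (WLSMV) or
  missing-data estimators.
* With $n$ close to $p$ (e.g., 51 respondents on 30 items) the ML fit is
  warned about and can be unstable — a real design limitation of small expert
  panels, not of the optimiser.
* Published headline statistics of any particular study (round-level $W$,
  $\alpha$, CMIN/df on the original raw ratings) are not reproducible without
  those ratings; the package reproduces the *worked* computations (weight
  normalisation, QI aggregation, accounting) and validates everything else
  by construction against oracles.
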