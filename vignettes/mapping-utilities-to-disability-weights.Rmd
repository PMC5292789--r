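---
title: "Mapping EQ-5D utilities to GBD disability weights: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping EQ-5D utilities to GBD disability weights: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eq5dmap)
```

## The problem

Disability weights (DWs) and utilities quantify the same thing — the
severity of a health state — on opposite scales and by different
elicitation traditions. DWs (0 = full health, 1 = worst) come from
large paired-comparison exercises such as the GBD 2010/2013 studies and
feed DALY calculations; utilities (1 = full health, 0 = death, possibly
negative) come from multi-attribute instruments such as the EQ-5D scored
with a national tariff, and feed QALYs. When a burden study needs a DW for
a state the GBD set does not cover, setting DW = 1 − utility is tempting
but not comparable with the GBD scale: respondents systematically judge
severity differently under the two protocols. `eq5dmap` instead *maps*
utilities onto the GBD DW scale using states for which both quantities are
known.

## Scoring model

EQ-5D profiles are ordered 5-tuples of ordinal levels over mobility,
self-care, usual activities, pain/discomfort and anxiety/depression
(D1..D5); the package treats dimension order as strictly positional and
requires readers of delimited files to present named columns
(`mo, sc, ua, pd, ad`), which are mapped to D1..D5 explicitly. Missing
levels are rejected rather than imputed — the package targets surveys with
forced-complete answers, and silent imputation would bias utilities.

Because 3L tariffs remain the best-anchored national value sets, 5L
responses are first translated into the 3L space. Two crosswalk kinds are
supported, since published crosswalks differ in form:

* a **probability matrix** (row-stochastic, one row per 5L profile over
  the 243 3L profiles), under which a response's utility is its expected
  3L utility; and
* a **deterministic level collapse** (1→1, {2,3}→2, {4,5}→3), an
  explicitly labelled stand-in that lets the whole pipeline run with no
  external material. It warns on first use: it is *not* a published
  crosswalk.

The additive tariff is
$$U(\ell) = 1 - c\,[\ell \neq 11111] - \sum_{d=1}^{5}\delta_{d,\ell_d}
 - \sum_j \gamma_j\,[\mathrm{pred}_j(\ell)],$$
with a constant decrement $c$ off full health, per-dimension level
decrements, and named indicator terms (e.g. *any dimension at level 3*).
Value sets are data files (YAML), never code: the packaged
`valueset_synthetic.yaml` is labelled synthetic and exists so that examples
and tests never depend on transcribing a published tariff. Utilities are
deliberately not clipped at zero — "worse than death" valuations are real
data and are carried through all downstream statistics.

## The mapping model

Let $(u_i, w_i)$ be per-state mean utilities and reference DWs. The model
regresses $y_i = \mathrm{logit}(\tilde w_i)$ on $u_i$, where
$\tilde w_i = \min(\max(w_i, \varepsilon), 1-\varepsilon)$, by locally
weighted polynomial regression. At a query $x_0$ the
$q = \lceil \alpha n \rceil$ nearest training utilities (span
$\alpha$; distance ties at the boundary all included, so the neighbourhood
is input-order independent) receive tricube weights
$w_i = (1 - (|u_i - x_0|/d_{\max})^3)^3$, a polynomial of the configured
degree is fit by weighted least squares, its value at $x_0$ is taken, and
the inverse logit returns a DW strictly inside $(0,1)$.

Two **anchor pseudo-observations** — $(u=0, w=1)$ and $(u=1, w=0)$ — pin
the scale ends so that full health maps to a near-zero DW and a
utility-of-death maps to a near-one DW. They enter as ordinary training
points (one each), their DWs clamped by $\varepsilon$ like any other
response, because $\mathrm{logit}(0)$ and $\mathrm{logit}(1)$ are
undefined and nothing in the anchoring idea says the endpoints should
outweigh real data.

Tunable parameters (all dimensionless):

| parameter | default | why |
|---|---|---|
| `span` | 0.75 | the conventional loess default; no value is canonical for this design, so it is configurable |
| `degree` | 2 | conventional loess default; degrees 0–1 supported |
| `epsilon` | 1e-3 | maps the anchors to logit ±6.91, far outside the data range yet finite; smaller values make anchors ever more extreme leverage points |
| `anchors` | on | the anchored model is the method; unanchored fits are available for diagnostics |
| `weights` | tricube | `uniform` supported; with span 1 and degree 0 the fit degenerates to the global transformed mean, a useful closed-form check |

Numerical choices: fitting is lazy (the object stores training pairs and
hyperparameters; every prediction solves its own local weighted
least-squares problem, which is what makes the serialized JSON model
reproduce predictions bit for bit); rank-deficient local designs (too few
distinct utilities in a neighbourhood) drop the unidentifiable
higher-order terms; a span giving fewer than `degree + 1` positive-weight
neighbours is an error, not a silent fallback. Queries outside the
training utility range are permitted — new states may be milder or more
severe than the training set — but the result is flagged and a warning
raised. Utilities outside $[0,1]$ are accepted unchanged as predictors;
only DWs are logit-transformed.

The model is fit on **state means** by default rather than individual
utilities. Both are defensible; state means are the scale on which the
reference DWs exist, and the respondent-level route is available simply by
passing individual $(u, w)$ pairs to `dw_map()`.

A global OLS line of $y$ on $u$ (`logit_linear_fit()`) is kept as the
conventional straight-line comparator drawn beside the local fit in
`plot.dw_map()`.

## Comparison statistics

All comparisons default to state-level inputs (27 states in the packaged
study). Spearman's $\rho$ is the Pearson correlation of midranks; its
p-value uses exact enumeration of all $n!$ permutations for $n \le 8$
(valid under ties) and the usual $t$ approximation with $n-2$ df
otherwise. Paired t-tests compare $1-u$ with the DWs on $n-1$ df;
zero-variance differences yield a flagged degenerate result instead of an
error. All p-values are two-sided. Rank tables use rank 1 = least severe
(lowest DW, highest utility) and midranks for ties, with each ranking
flagged against its own median. These conventions reproduce the packaged
study's printed statistics exactly (ρ = −0.808 with GBD 2010, complement
differences averaging 0.30, extremes 0.645/−0.097, the four-state pilot's
ρ = −1 with exact p = 2/24 ≈ 0.083 and paired-t p ≈ 0.085) — all
recomputed, not stored, by the test suite and `scripts/acceptance.R`. Two
printed GBD 2013 figures (ρ = −0.801 and minimum difference −0.112) do not
recompute exactly from the printed table (−0.802 and −0.119); they were
evidently computed on unrounded means, so the package checks them only to
±0.01.

## The synthetic generator

`simulate_responses()` emulates a valuation survey as a latent-variable
ordinal model: a state with true DW $w$ has latent severity
$s = \mathrm{logit}(\tilde w)$, and respondent $r$'s response on dimension
$d$ is $\mathrm{level} = 1 + \#\{c_k < \lambda_d s + e\}$ with loadings
$\lambda_d$, cutpoints $c_1 < \dots < c_4$ and noise
$e \sim N(0, \sigma^2)$. Expected severity — hence expected derived
utility — is monotone in $w$ by construction.

Defaults are the packaged study's conditions: the 27 reference states with
true DW = the GBD 2010 column and 58 respondents per state (393
respondents rating 4 states each). Loadings default to 1 (no dimension
dominates). Cutpoints $(-3, -0.5, 2, 4.5)$ and $\sigma = 3$ were
calibrated once, by a coarse grid search minimising the squared distance
between simulated per-state mean utilities (scored with the packaged
synthetic value set) and the study's observed 27 mean utilities; the
calibrated generator also reproduces realistic per-state utility SDs
(≈ 0.22 simulated vs 0.13–0.26 observed). One root seed drives per-state
streams derived deterministically from the state id, so adding states
never reshuffles existing ones.

What the generator does *not* emulate: demographic effects on valuations,
order effects across questionnaire versions, respondent-specific response
styles (each rating is independent), and the non-monotone
state-description effects visible in real data (e.g. states whose lay
description overlaps the EQ-5D dimensions). Passing tests on synthetic
data therefore show that the pipeline recovers a *monotone*
utility–severity relation under ordinal measurement noise — not that any
real survey will be monotone, which the packaged study itself was not.

## Problem sizes and runtime

The test suite and acceptance script run on the packaged 27-state table
(seconds) and on simulations of at most 30 states × 200 respondents for
the end-to-end recovery property (Spearman between predicted and true DWs
≥ 0.95; observed ≈ 0.996), keeping the whole suite around ten seconds.
Property tests (profile round-trips, oracle equivalence of the local
regression against a brute-force normal-equations solver at tolerance
1e-8, rank-permutation checks) loop over modest fixed-seed batches.

## Known limitations

* No confidence intervals for predicted DWs, and no cross-validated span
  selection; span/degree defaults are conventions, not optimised choices.
* The deterministic collapse crosswalk is a stand-in; results scored with
  it are for pipeline validation, not publication.
* Exact permutation p-values are limited to $n \le 8$ ($8! = 40320$
  enumerated pairings).
* The mapping is only as good as the monotonicity of the utility–DW
  relation; in the packaged 27-state study that relation is visibly
  non-monotone in the middle of the severity range, and the anchored fit
  will not repair ranking disagreements between the two instruments.
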