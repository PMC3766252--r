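---
title: "Record linkage with conditional dependence: models, diagnostics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Record linkage with conditional dependence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lclink)
```

## The model

A candidate record pair is summarized by a binary agreement vector
$Y = (y_1, \dots, y_K)$ over $K$ comparison fields; missing values are
coded as disagreements. The pair's true match status $M \in \{0, 1\}$ is
latent. `lclink` works with the loglinear parameterization of the two-class
latent mixture: the expected number of pairs with pattern $Y$ and class $M$
is

$$\log m(Y, M) = \lambda + \lambda_M M + \sum_k \lambda_k y_k
  + \sum_k \lambda_{Mk} M y_k,$$

and conditional dependence between a field pair $(j, l)$ is introduced by
adding $\lambda_{jl} y_j y_l + \lambda_{Mjl} M y_j y_l$. The marginal
pattern probability is the normalized two-class cell sum,
$P(Y_d) \propto m(Y_d, 1) + m(Y_d, 0)$, and the multinomial log-likelihood
of a pattern-count table $f_1, \dots, f_D$ ($D = 2^K$) is
$\sum_d f_d \log P(Y_d)$. Without interactions this is exactly the
classical Fellegi–Sunter conditional-independence (CI) model via
$u_k = \operatorname{logit}^{-1}(\lambda_k)$,
$m_k = \operatorname{logit}^{-1}(\lambda_k + \lambda_{Mk})$, and the
prevalence $\pi$ equal to the match-class share of the total cell mass. The
package verifies this equivalence exhaustively for $K \le 5$ in its test
suite.

Four structures are available for each added interaction, differing in
which class carries a free coefficient. Writing $\gamma^{(0)}, \gamma^{(1)}$
for the nonmatch- and match-class interaction coefficients:

| structure       | constraint                                    | free coefficients |
|-----------------|-----------------------------------------------|-------------------|
| `match_only`    | $\gamma^{(0)} = 0$                            | 1                 |
| `nonmatch_only` | $\gamma^{(1)} = 0$                            | 1                 |
| `both_shared`   | $\gamma^{(0)} = \gamma^{(1)}$                 | 1                 |
| `both_distinct` | none                                          | 2                 |

The CI model has $2K + 1$ free parameters; each interaction adds its free
coefficient count. With interactions present the reported $m_k$ and $u_k$
are *class-conditional marginal agreement probabilities* (cell-sum ratios
over the fitted within-class distributions); these reduce to the logistic
identities above exactly for fields involved in no interaction, which is
also how the interpretable estimates are conventionally reported for this
model family.

## Identification and the internal parameterization

The multinomial likelihood is invariant to adding a constant to the
loglinear intercept (it cancels in the normalization), so the cell-mean
parameterization has a flat direction. Internally the package therefore
optimizes the minimal free set: $\operatorname{logit} \pi$, per-class
within-class main effects $a_{0k}, a_{1k}$, and the free $\gamma$'s — one
parameter per degree of freedom, no constraints beyond finiteness. Reported
$\lambda$'s fix the scale so the cell means sum to the observed pair count
$N$, which reproduces the conventional identities exactly.

## Estimation

`fit_ml()` maximizes the log-likelihood by BFGS with an analytic gradient,
multi-start (default 5: one margin-based heuristic start plus seeded
Gaussian jitters of it), and a single restart from the solution to polish
the quasi-Newton approximation. The heuristic start sets $u_k$ to the
field's overall agreement proportion (in blocked data non-matches dominate,
so the margin approximates $u$), $m_k = \min(0.95, u_k + 0.3)$ and
$\pi = 0.01$.

Convergence requires a relative log-likelihood change below `tol` (default
$10^{-10}$) *and* a small gradient. The gradient check is relative —
$\max_i |g_i| < 10^{-6} \cdot \max(1, |\ell|)$ — rather than an absolute
max-norm: the score function is a sum over $N$ record pairs, so its raw
norm scales with the data size, and an absolute cutoff would reject
correctly converged fits on realistic registries (at $N = 5 \times 10^5$ we
observed converged optima with $\max|g| \approx 0.06$ and relative gradient
$8 \times 10^{-8}$).

`fit_em()` is a fully independent implementation of the same estimator,
kept as a cross-checking oracle: posterior class weights in the E-step,
closed-form weighted-proportion updates in the M-step under CI, and damped
inner Newton iterations on the within-class loglinear parameters when a
class carries interactions (the M-step then has no closed form). Step
halving makes every M-step an ascent, so the observed-data log-likelihood
trace is monotone — asserted in the tests, along with agreement of the two
routes' maximized log-likelihoods to $10^{-6}$ relative on randomized
scenarios.

Two-class mixtures are invariant to relabeling the classes. Fits are
reported in the orientation $\sum_k m_k > \sum_k u_k$. For class-symmetric
specs (CI, `both_shared`, `both_distinct`) a swapped optimum is relabeled
exactly; for `match_only`/`nonmatch_only` specs the swapped mode lies
outside the spec's parameter space (the constraint would move to the other
class), so no relabeling is possible — in practice the oriented heuristic
start makes the swapped mode a non-issue, and the fitter warns if one is
ever returned.

Standard errors invert the observed information of the free
parameterization (central differences of the analytic gradient) and
delta-method-transform to the $(\pi, m, u)$ scale; they match a
nonparametric bootstrap within 15% in the test suite and halve when $N$ is
quadrupled. Degenerate fields (agreement proportion exactly 0 or 1) are
rejected before fitting — their logit parameters would diverge.

## The correlation-residual diagnostic

For each field pair the phi correlation
$\mathrm{Corr}_{jl} = (p_{jl} - p_j p_l) / \sqrt{p_j(1-p_j) p_l(1-p_l)}$ is
computed twice: from the observed counts, and from the model-based expected
counts $\hat f_d = N P(Y_d)$ over **all** $2^K$ patterns (the expectation
is model-based, so unobserved patterns contribute). The residual is the
difference. A mixture of two CI classes already induces positive marginal
correlation between informative fields, so the expected correlation is not
zero — the residual isolates dependence *beyond* what the latent class
explains. Pairs with $|\text{residual}| > 0.05$ are flagged; the threshold
is an experience-based guideline, not a derived test, and carries no
sample-size adjustment — at very large $N$ smaller residuals may already be
worth modeling, and at small $N$ noise alone can exceed it. Pairs with a
degenerate margin get an `NA` residual, appear as gaps in the plot, and are
never flagged.

## The stepwise search

`run_stepwise()` starts from the CI fit and iterates: flag the
largest-$|$residual$|$ pair above the threshold (excluding pairs already in
the model), fit all four structures for it, accept the BIC-minimal
converged candidate, recompute residuals. BIC is used because the four
candidate structures are not mutually nested; ties break toward fewer
parameters, then a fixed structure order. Warm starts carry the shared
parameters of the incumbent model into each candidate fit.

Stopping is governed by the residual threshold first: when no remaining
pair exceeds it, the search stops — even if a further term would still
lower BIC. This mirrors the intended reading of the guideline (a residual
of 0.047 does not justify a new term even when the richer model fits
slightly better). `explore_below_threshold = TRUE` overrides the rule and
keeps extending while BIC improves, for examining such borderline models. A
BIC-no-improvement guard and a `max_terms` cap (default 5) bound the search
on pathological data.

## Scoring and classification

The match score of a pattern is
$\log_2 P(Y_d \mid M=1) / P(Y_d \mid M=0)$; under CI it reduces to the
familiar sum of per-field agreement/disagreement weights, which the tests
assert against the closed form. Posterior match probabilities follow by
Bayes' rule and are a monotone transform of the score. Three
classification rules are provided: a posterior threshold (default 0.5, the
canonical Bayes rule), a three-way score-threshold split with an uncertain
zone, and `prevalence_rank`, which declares the highest-scoring patterns
matches until the cumulative pair count first reaches $N \hat\pi$ —
emulating classification "based on the estimated match prevalence" when a
published analysis does not state its threshold convention. Classification
is a function of the agreement pattern only; declared-match totals weight
patterns by their observed counts.

## Synthetic data: what it emulates and what it does not

`simulation_scenario()` states a complete generating world: $\pi$, $m$,
$u$, optional injected within-class interaction coefficients
$(\gamma^{(0)}, \gamma^{(1)})$, and $N$. `sample_table()` makes one seeded
multinomial draw over the $2 \cdot 2^K$ pattern-class cells and
marginalizes the class (optionally retaining the truth split). Within a
class the distribution is exactly the loglinear model the fitter assumes:
main effects at $\operatorname{logit} m_k$ / $\operatorname{logit} u_k$
plus the injected products.

This emulates the *agreement-pattern* level of real registry data —
two-class structure, rare matches, informative and uninformative fields,
pairwise within-class dependence. It deliberately does not emulate:
value-specific agreement weights (a common surname agrees more easily than
a rare one), three-way and higher dependence, heterogeneous blocks,
typo/missingness processes in raw identifiers, or linkage of more than two
classes of pairs. A green parameter-recovery or calibration test therefore
establishes correctness of the estimator and diagnostic *under the model
family*, not robustness of linkage on any particular messy registry.

Default worlds used in the acceptance tests (chosen once, as realistic for
blocked registry de-duplication, and not tuned): match prevalence around
4–5% (blocked candidate pairs are mostly non-matches), $m_k$ spanning
0.4–0.9, $u_k$ spanning 0.01–0.2 with one sex-like field near 0.66,
$K = 7$ fields, $N$ between $5 \times 10^5$ and $10^6$ pairs.

## Numerical choices

- Pattern index order is fixed (field 1 = most significant bit) so tables
  and artifacts are comparable across runs.
- $G^2$ is computed against the saturated multinomial over observed
  patterns; cells with $f_d = 0$ contribute 0. Published deviances for this
  model family may use either the observed-cell or all-cell convention;
  they coincide whenever all patterns are observed (as in large registry
  blocks).
- BIC's sample size is $N$ (record pairs), the units of the multinomial
  sample, not the number of pattern cells.
- EM inner Newton steps are damped by step halving and ridge-regularized at
  $10^{-10}$ when the weighted information is near singular.
- Probabilities in fitted `classical` parameters are clamped away from
  exact 0/1 at $10^{-300}$ / $1 - 10^{-16}$ only to keep the container's
  strict-interval invariant; estimates that near a boundary (e.g. a
  u-probability of $6 \times 10^{-6}$ for SSN-like fields) are reported as
  estimated.
- All randomness is seeded and the caller's RNG state is restored; CLI
  artifacts record the seed and reproduce byte-identically.

## Known limitations

- Only pairwise interactions are modeled; higher-order dependence surfaces
  as residuals the model cannot absorb.
- The residual guideline 0.05 is heuristic (see above).
- Standard errors assume an interior optimum; near-boundary u-probabilities
  make the delta-method SE for those entries less trustworthy than a
  bootstrap.
- `match_only`/`nonmatch_only` fits cannot be label-relabeled (see
  Estimation); extremely weakly separated data could in principle return a
  swapped orientation with a warning.
- The declared-match count of a published analysis depends on its threshold
  convention; with the convention unstated, `prevalence_rank` is the
  closest emulation but exact reproduction is not guaranteed.
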