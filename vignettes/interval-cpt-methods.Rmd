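---
title: "Interval-valued group decisions with cumulative prospect theory: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval-valued group decisions with cumulative prospect theory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cptgdm)
```

## The decision problem

`cptgdm` ranks a small set of response alternatives $A_1,\dots,A_M$ under
risk when both the experts' judgments and the alternatives' consequences are
interval numbers. Each alternative has $N$ mutually exclusive outcomes with
probabilities $p_{m1},\dots,p_{mN}$ (summing to one per alternative), and
each outcome carries an interval value $x_{mnk} = [x^L, x^H]$ on each of $K$
criteria. Criteria are typed *benefit* (more is better) or *cost*, and carry
attribute weights $w_1,\dots,w_K$ summing to one.

The behavioral core is cumulative prospect theory: outcomes are valued as
gains or losses relative to a reference point, losses loom larger than
gains, and probabilities are distorted before entering the aggregation. What
is distinctive here is that the reference point is (a) *elicited from a
panel* of experts rather than fixed, and (b) an *interval* per criterion, so
the gain/loss conversion must handle every relative position of two
intervals.

## Stage 1: consensus reference point

Experts state interval reference points $E_{hk}$. Because criteria live on
different scales, each criterion column is min–max normalized over all
experts' bounds before opinions are compared; benefit criteria keep their
direction, cost criteria are reversed (and the resulting bounds reordered so
lower $\le$ upper — the raw reversal formula alone would produce an inverted
interval). The distance of expert $h$ from the panel mean
$\bar R_k$ on criterion $k$ is the root mean square of the two bound
differences, the expert's similarity score is $d_h = \sum_k (1 - d_{hk})$,
and weights are $w_h = d_h / \sum_h d_h$: the closer an expert sits to the
group's central opinion, the more weight they receive. This is a one-shot
weighting, not an iterative consensus-reaching process — experts are never
asked to revise their inputs.

Two scale conventions matter and are easy to get wrong:

* **Distances are computed on normalized values.** On the unit box each
  $d_{hk} \in [0,1]$, so similarities are comparable across criteria.
* **The collective reference is aggregated on the raw scale**:
  $r_k = \sum_h w_h E_{hk}$ bound-wise over the *original* intervals. The
  normalized panel exists only to derive weights; the collective reference
  must be commensurate with the raw attribute values it is later compared
  against. Each bound of $r_k$ is therefore a convex combination of the
  experts' corresponding bounds.

Degenerate inputs: a criterion on which every expert states the same crisp
value has zero range; its normalized entries are set to $[0,0]$ so it
contributes no distance and leaves the weighting to the informative
criteria. If every distance equals its maximum (total similarity zero —
only possible in pathological hand-built inputs), there is nothing to
normalize and the package raises an error rather than inventing weights.

## Stage 2: interval payoffs

For an attribute interval $C$ and reference interval $R$ there are six
qualitatively different relations: $C$ entirely below $R$, entirely above,
overlapping from below, overlapping from above, strictly containing $R$,
and nested inside $R$. Payoffs per case (benefit type, midpoint
$\bar C = 0.5(C^L + C^H)$):

| case | relation | gain | loss |
|------|-----------------------------|---------------------|---------------------|
| 1 | $C^H < R^L$ | 0 | $\bar C - R^L$ |
| 2 | $C^L > R^H$ | $\bar C - R^H$ | 0 |
| 3 | overlap, shifted low | 0 | $0.5(C^L - R^L)$ |
| 4 | overlap, shifted high | $0.5(C^H - R^H)$ | 0 |
| 5 | $R$ inside $C$ | $0.5(C^H - R^H)$ | $0.5(C^L - R^L)$ |
| 6 | $C$ inside $R$ | 0 | 0 |

For the separated cases 1–2 the formula is exactly the expectation of
$x - R^{L/H}$ under a uniform density on $C$; the package ships an
independent numerical-integration oracle (`uniform_expected_payoff()`) and
the tests require agreement within $10^{-9}$. The overlap/nesting formulas
(3–6) are *not* uniform-density expectations — they are the conventional
half-differences of the protruding bounds — and are implemented as such; the
oracle is deliberately restricted to cases 1–2.

Cost criteria use the mirror convention: a value below the reference is a
gain. Rather than transcribing sign-ambiguous column layouts, the package
defines cost payoffs as the negate-and-swap of the benefit ones
($\text{gain}_{cost} = -\text{loss}_{benefit}$,
$\text{loss}_{cost} = -\text{gain}_{benefit}$), which guarantees the sign
invariant gain $\ge 0 \ge$ loss for every case and both types; the identity
is property-tested on thousands of random interval pairs.

Boundary equalities (e.g. $C^H = R^L$) are not covered by the strict
inequalities above, so classification uses a fixed precedence: separation
(1, 2) first, then nesting of $C$ in $R$ (6), then containment of $R$ (5),
then the partial overlaps (3, 4). Consequences we consider desirable:
identical intervals are payoff-neutral (case 6), and crisp inputs
$C=[c,c], R=[r,r]$ reduce to the ordinary sign comparison $c - r$.

Case 5 produces both a gain and a loss. The two components are kept
separate through the value function — prospect theory values them
asymmetrically — and summed afterwards; the reported `net` payoff is for
tables only.

## Stage 3: prospect values

Each payoff component passes through the piecewise power value function

$$v(z) = \begin{cases} z^{\alpha} & z \ge 0 \\ -\lambda(-z)^{\beta} & z < 0,\end{cases}$$

then values are normalized per criterion by $v^*_k = \max_{m,n} |v_{mnk}|$
so that criteria on different scales can be aggregated (an all-zero
criterion stays all-zero). The normalizer is taken **after** loss aversion,
i.e. over $|v|$ including the $\lambda$ factor; this is the only reading
under which the worked example's printed normalized table reproduces (its
third-criterion normalizer equals $\lambda$ times the largest raw loss),
and it keeps $|\tilde v| \le 1$ exactly.

Probabilities are distorted by the neo-additive function
$w(p) = \mu p + (1 - \mu)/2$ on $(0,1)$ with $w(0)=0$, $w(1)=1$. It
overweights small and underweights large probabilities with a single slope
parameter, satisfies $w(p) + w(1-p) = 1$, and collapses to the identity at
$\mu = 1$. The inverse-S weighting family is deliberately out of scope.

Decision weights are rank-dependent: per criterion, outcomes are sorted by
normalized value (stable, ties and zero values kept in input order, zeros
grouped with the gains — their contribution vanishes either way); gains
receive differences of $w$ at cumulative probabilities from the best
outcome downward, losses differences from the worst upward. One weighting
function serves both sides. For the neo-additive family the weights
telescope to $\sum \pi^+ + \sum \pi^- = 1$ for any number of outcomes — a
property the tests verify against an independent brute-force enumeration.
The gain/loss partition is per attribute: an outcome may count as a gain on
one criterion and a loss on another. With two outcomes of uniform sign
across criteria this reduces to weighting the per-outcome combined
normalized value — the form used in the worked example — and the tests pin
that equivalence.

Finally $PV_i = \sum_k w_k \sum_n \pi_{nk}\,\tilde v_{ink}$ and alternatives
are ranked by descending $PV$, ties broken by input order.

## Parameters

| parameter | meaning | range | default |
|-----------|--------------------------------|----------|---------|
| $\alpha$ | gain curvature | $(0,1]$ | 1 |
| $\beta$ | loss curvature | $(0,1]$ | 1 |
| $\lambda$ | loss aversion multiplier | $\ge 1$ | 2 |
| $\mu$ | probability-weighting slope | $(0,1]$ | 0.6 |

The defaults are the study setting of the packaged example: linear value
segments, losses weighted twice, moderate probability distortion. At
$\alpha = \beta$ the whole pipeline is scale-invariant per criterion:
multiplying one criterion's attribute values *and* reference points by any
$c > 0$ leaves every prospect value unchanged (property-tested).

Two solver options support comparative analysis: `probability_weighting =
"identity"` replaces $w$ by the identity (objective probabilities), and
`expert_weights` accepts an explicit vector in place of the similarity
weights. The packaged example's published no-distortion variant is only
reproducible with *both* the identity weighting and $\lambda = 1$; the
original presentation does not state the latter, so the two switches are
exposed independently and the reproduction sets both.

```{r}
p <- worked_example()
p$params <- cpt_params(lambda = 1)
p$options$probability_weighting <- "identity"
round(solve_problem(p)$prospect_values, 3)
```

## Numerical conventions

* Internal arithmetic is full double precision throughout; nothing is
  rounded between stages.
* Comparisons against published 3-decimal tables use half a unit in the
  last printed digit ($5\times10^{-4}$) where the published number was
  computed from full-precision inputs, and one unit ($10^{-3}$) where it
  demonstrably passed through rounded intermediates (the published
  consensus chain rounds the normalized panel, weights and collective
  reference to three decimals before reusing them — e.g. the printed expert
  weights sum to 1.001).
* Probability sums are validated to $10^{-9}$; accumulated probabilities
  within $10^{-9}$ of 1 are snapped to 1 inside the decision-weight
  computation so that $w(1) = 1$ fires exactly despite floating-point
  summation.
* Weight vectors (criteria, experts, explicit scenarios) must be
  nonnegative and sum to 1 within $10^{-9}$; violations are errors, not
  silent renormalizations.

## The random problem generator

`generate_problem()` draws seeded, structurally valid problems: interval
reference points and outcome values per criterion from a configurable range
with widths up to a fraction of that range, probabilities uniform on the
simplex (normalized exponentials), and a configurable benefit/cost mix —
cost criteria are generated deliberately because the packaged example is
all-benefit and would otherwise leave the cost branch untested. The
generator restores the caller's RNG state, so it can be used inside larger
seeded workflows.

What it emulates is the *structure* of such decision problems, not their
empirical distribution: real expert panels exhibit correlated opinions,
criterion-specific scales and skewed probabilities that the generator does
not model. Passing property tests on generated problems therefore
demonstrates internal consistency (invariants, determinism, schema
validity), not calibration to real emergency-department data.

## Known limitations

* Cost-type *reference-point* normalization is never exercised by the
  packaged example; the bound-swap convention is our inference from the
  unit-box invariant and is covered by synthetic tests only.
* The overlap-case payoffs (cases 3–6) follow the conventional
  half-difference formulas rather than uniform-density expectations; users
  who want a fully probabilistic payoff model would need a different payoff
  table.
* Prospect values of close alternatives can sit within one print-rounding
  unit of each other (the packaged example's single-expert sensitivity
  scenarios produce such near-ties), so rankings derived from 3-decimal
  tables may differ from full-precision rankings; the package always ranks
  at full precision.
* Problem sizes are desk-scale by design ($M, N, K, H$ in the tens at
  most); nothing is optimized for large simulation sweeps.
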