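---
title: "Regularized latent class models with fused penalties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regularized latent class models with fused penalties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlca)
```

## The model

A latent class model (LCM) represents `I` categorical items
$X_1, \dots, X_I$ by a discrete latent variable $U \in \{1, \dots, C\}$.
Items are conditionally independent given the class, so the observed
distribution is the mixture

$$P(X = x) = \sum_{c=1}^{C} p_c \prod_{i=1}^{I} p_{i x_i c}, \qquad
p_{ikc} = P(X_i = k \mid U = c).$$

Both parameter blocks are estimated on the logit scale. Item `i` with
categories $0, \dots, K_i$ uses the multinomial-logit parameterization

$$p_{ikc} = \frac{\exp(\gamma_{ikc})}{1 + \sum_{h=1}^{K_i} \exp(\gamma_{ihc})},
\qquad \gamma_{i0c} = 0,$$

and the class probabilities use $p_c \propto \exp(\delta_c)$ with
$\delta_1 = 0$. A dichotomous item is simply the $K_i = 1$ case, where
$p_{i1c}$ is the correct-response probability. The saturated
(*exploratory*) LCM therefore has $\sum_i K_i C + C - 1$ free parameters —
quickly a lot: 12 seven-distractor multiple-choice items with five classes
already need 424.

## Fused regularization

The package's core idea is to subtract a fused penalty from the
log-likelihood so that item parameters which the data cannot distinguish
are estimated *exactly equal*, reducing the effective number of parameters
without fixing the equality structure in advance. The penalized objective
is

$$\ell(\gamma, \delta) - N \sum_{i=1}^{I} \mathrm{Pen}(\gamma_i; \lambda),$$

the penalty acting on all pairwise differences of an item's logits. The
scaling by `N` makes $\lambda$ sample-size-free. Five fusion strategies are
available (`penalty_spec()`):

* `fused_classes` — $\sum_k \sum_{c<d} H(\gamma_{ikc} - \gamma_{ikd}; \lambda_1)$,
  merging classes within each category (the only option, with $K_i = 1$,
  for dichotomous items);
* `fused_categories` — $\sum_c \sum_{k<h} H(\gamma_{ikc} - \gamma_{ihc}; \lambda_2)$,
  merging response categories (distractors) within each class;
* `fused_both` — the sum of the two, with a two-dimensional $(\lambda_1,
  \lambda_2)$ grid;
* `group_categories` / `group_classes` — $H$ applied to the *Euclidean
  norm* of a whole profile difference, e.g.
  $H(\lVert \gamma_{ik*} - \gamma_{ih*} \rVert; \lambda_2)$, so a pair of
  categories (classes) merges or stays distinct as one decision.

Three penalty families are implemented (`penalty_value()`): LASSO
$H(x) = \lambda |x|$, SCAD and MCP. SCAD and MCP coincide with the LASSO
near zero but flatten to a constant plateau (at $|x| > a\lambda$ for MCP,
with shape constant $a$), so clearly distinct parameters are not biased
toward each other — the reason MCP is the default family. The defaults
$a = 3$ (MCP) and $a = 3.7$ (SCAD) are the values conventionally used with
these families; the source method cites the families without printing
closed forms or constants, so the standard published forms are used.

Penalizing logits rather than probabilities is an estimation choice with a
consequence worth knowing: differences between extreme probabilities (near
0 or 1) look *larger* on the logit scale, so extreme categories fuse less
readily than mid-scale ones.

## Estimation

`rlca_fit()` maximizes the penalized likelihood with an EM algorithm:

* **E-step** — posterior class memberships $u^*_{nc}$ (`e_step()`).
* **M-step, class block** — closed form, $p_c = \frac{1}{N}\sum_n u^*_{nc}$.
* **M-step, item blocks** — the penalty decomposes over items, so each
  item's logits are updated separately (`m_step_item()`) by BFGS on the
  expected complete-data log-likelihood minus $N \cdot \mathrm{Pen}$, with
  analytic gradients.

The penalty is not differentiable at fused points, so the optimizer works
on a smoothed surrogate with $|x| \approx \sqrt{x^2 + \varepsilon}$.
$\varepsilon$ is annealed geometrically from $10^{-3}$ to a floor of
$10^{-6}$ over the EM iterations: early iterations see a softly rounded
penalty that lets parameters move across the fusion point, late iterations
an essentially exact one that pins fused pairs to within far less than the
fusion tolerance. Because $\varepsilon$ only decreases and the smoothed
penalty is monotone in $\varepsilon$, the smoothed penalized objective is
non-decreasing across iterations (a property the test suite asserts).
Convergence is declared when the objective changes by less than `tol`
(default $10^{-6}$), the logits by less than `gamma_tol` ($10^{-4}$), and
the anneal has reached its floor; `max_iter` defaults to 500.

The likelihood is multimodal, so multiple random starts are used (default
10; $\delta = 0$, item logits drawn as $\mathrm{logit}(p)$ with $p \sim
U(0.2, 0.8)$) and the best run by the exact penalized objective is kept.
Probabilities are clamped to $[10^{-12}, 1 - 10^{-12}]$ before logs, since
regularized and boundary fits push logits to large magnitudes. A class
whose posterior mass vanishes is floored at $10^{-6}$ with a warning
rather than dropped. Missing responses are rejected outright — the methods
here never model missingness, and silent imputation would change the
likelihood.

Because class labels are arbitrary (label switching), comparisons against
a generating design first apply `align_to_design()`, which finds the label
permutation minimizing the total absolute difference of the item
probability tables by exhaustive search over permutations ($C \le 8$).

## Model selection

A fused parameter is not a free parameter. `count_unique_params()` groups
each item's logits by the transitive closure of "absolute difference below
`fuse_tol`" along exactly the pairs the strategy penalizes, so a chain
$a \approx b \approx c$ counts once; `fuse_tol` defaults to 0.01 on the
logit scale, applied after the anneal has tightened fused pairs to
machine-level agreement, and is exposed because the choice is a
convention, not an estimate. AIC and BIC then use the unique count:
$\mathrm{AIC} = -2\ell + 2k$, $\mathrm{BIC} = -2\ell + k \log N$.

`rlca_grid_search()` fits a whole $\lambda$ path (1D, or the Cartesian
product for `fused_both`), from small to large $\lambda$. Each point is
warm-started from the previous solution *and*, as a second candidate, from
the unpenalized fit, keeping the better penalized objective: path-only
warm starts can drag an over-fused solution along the grid, while the
cold-side start cannot reach fusions the penalty only weakly supports, and
the two-sided rule guards against both failure modes. The first grid point
additionally uses random multi-starts. Warm-started points use a shorter
smoothing anneal ($10^{-4}$ down to $10^{-6}$) since they begin near their
solution. `regularization_path()` extracts fitted probabilities along the
grid; merge events appear as coinciding columns.

One consequence of exact fusion counting deserves emphasis when comparing
strategies: unique-parameter groups follow *chains* of fused pairs along
every penalized direction, so under `fused_both` a category-direction link
and a class-direction link can join into one large equal-valued block.
With well-converged fits this lets a weak joint penalty fuse far more
parameters per likelihood point than either single-direction strategy, and
its BIC optimum typically sits at small $(\lambda_1, \lambda_2)$ — a real
property of the penalized objective and the counting rule, not an
optimizer artifact, and one that can reorder strategy comparisons reported
under less aggressive optimization.

Two numerical footnotes. BFGS occasionally halts on a flat objective
change while the gradient is still appreciable; the standalone
`m_step_item()` restarts it (fresh curvature estimate) until the gradient
is small. And with a two-dimensional penalty at large $(\lambda_1,
\lambda_2)$ the *global* penalized optimum can be the fully collapsed
item — this is a property of the objective, not a defect; grids should
therefore start at small values and let the information criterion reject
the collapsed end.

## Class hierarchies

With fused estimates, classes often become comparable: class $c$ is
*below* class $d$ when its correct-response probability is no larger for
every item, and *approximately below* when at most $\iota$ items violate
this (`partial_order()`). Exact ties count as compatible with both
directions, so exactly tied classes are mutually comparable — that is the
weak-inequality definition, kept rather than broken by an arbitrary
tie-rule. At $\iota > 0$ the relation need not be transitive; the package
reports the raw relation and warns, and `order_report()` emits the
transitive reduction (Hasse edges) of the strict part, annotating edges
with their violating items. For polytomous multiple-choice fits the
ordering uses the correct-response category (category 0; category 1 for
dichotomous scorings), the one scale on which "stronger class" is
well-defined.

## The built-in simulation designs

`fixture_design()` returns the two generating designs used throughout the
package's tests, both with 12 items, four classes, and class probabilities
$(0.30, 0.20, 0.10, 0.40)$; parameters are specified for six items and
duplicated for items 7–12, and the classes are constructed to be partially
ordered (class 1 weakest everywhere, class 4 strongest).

* `table1_dichotomous`: correct-response probabilities with extensive
  equality across classes — per item only 2–3 distinct values, 26 unique
  item parameters (plus 3 class parameters) instead of 48.
* `table5_polytomous`: four-category items whose distractor probabilities
  are additionally equal within and across classes in structured blocks
  (e.g. all distractors of items 1 and 5 behave identically).

What passing the simulation tests shows — and what it does not: the
generator draws items independently given class, with exactly the stated
probabilities. Real item-response data bring local dependence, person
covariates, missingness and misfit of the class structure itself; recovery
under the designs says the estimator works under its own assumptions, not
that those assumptions hold for any particular dataset. Sample sizes in
the tests follow the designs' `N = 1000`; smaller toys are used where only
an algebraic property is being checked. Grid resolutions in the test suite
are coarsened (e.g. steps of 0.03 on the dichotomous path) relative to the
0.01-step grids the fitting functions default to; the selected models sit
well inside the grids, so resolution affects runtime, not conclusions.

## Multiple-choice recoding

For distractor analysis, raw option codes are rescored per item
(`recode_by_distractor_frequency()`): the keyed correct option becomes
category 0 and distractors become categories $1, \dots, K_i$ by decreasing
selection frequency, so "category 1" always means "most attractive
distractor". Frequency ties are broken by ascending original option code —
a deterministic convention, logged in the returned mapping table, chosen
because published frequency tables rarely tie and any rule must be a
bijection. Distractors declared in the key's option set but never observed
get the highest categories with frequency zero. `dichotomize()` scores
correct as 1 and pools all distractors; the correct-indicator is the same
whichever recoding runs first, and the test suite checks that
commutativity. The bundled `spmls_option_frequencies()` table (12-item
SPM-LS administration, N = 499) drives the recoding examples;
`spmls_class_profile()` carries a published five-class solution for the
dichotomized data, used as a worked example for the partial-order tools.
The real SPM-LS response-level dataset is not redistributed with the
package; analyses of it require obtaining the data separately.

## Known limitations

* No standard errors or tests on fused parameters — selection by
  information criteria only.
* Identifiability of the particular restricted LCM a fusion pattern
  implies is not checked.
* The reference-category parameterization ties regularization to the
  choice of category 0; applications without a natural reference category
  would need a sum-constraint variant, which is out of scope here.
* 2D grids are searched exhaustively; no adaptive refinement.
* The EM with many starts and a 100-point grid is a desk-scale
  computation (minutes), not instantaneous.
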