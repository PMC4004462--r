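---
title: "Logic-constrained kernel machines for multi-level interaction prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logic-constrained kernel machines for multi-level interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlpip)
```

## The problem

Physical protein-protein interactions are hierarchical: two proteins bind
through specific *domains*, and two bound domains touch through a patch of
interface *residues*. Interaction data is abundant at the protein level
(high-throughput screens) but scarce below it, because domain- and
residue-level evidence requires a solved complex structure. `mlpip` treats
the three levels as one collective prediction problem: a binary classifier
per level over object *pairs*, tied together by first-order logic
consistency rules — if two proteins are bound, at least one pair of their
domains is bound; if two domains are bound, at least `n` of their residue
cross-pairs are bound (an interface is never a single residue contact);
and, upward, bound children imply bound parents.

## Model

### Pairwise kernel machines

Each level's predictor is a kernel expansion over pairs,
`f(x, x') = sum_i w_i K2((x, x'), (x_i, x_i'))`, where the pair kernel is
built from an object-level kernel `K` by the symmetric tensor-product
transformation

    K2((i, j), (k, l)) = K(i, k) K(j, l) + K(i, l) K(j, k).

This transform preserves positive semidefiniteness and is invariant to the
order of the members inside each pair (`pairwise_gram()`; a property test
verifies PSD-ness on random PSD bases). A variant that multiplies row-pair
entries only (`variant = "printed"`) is retained for reference; it is not a
symmetric pair similarity — exchanging the two pairs changes its value — so
the symmetric form is the default. Per-level kernels from multiple feature
sources are combined additively (`sum_grams()`); `normalize_gram()` applies
cosine normalization, which we recommend whenever margins must live on the
±1 scale consumed by the logic bridge (below).

### From logic to penalties

Rules are expressed over the predicates `boundp/boundd/boundr` (targets)
and the crisp structural predicates (`parentpd`, `parentdr`, `parentpr`,
plus the precomputed guards `hasdom`, `hasres`, `hasres_p`). A rule such as

    forall (p,q): hasdom(p) & hasdom(q) =>
        ( boundp(p,q) => exists (d,e): boundd(d,e) & parentpd(p,d) & parentpd(q,e) )

is relaxed to a continuous penalty with the product t-norm: conjunction is
`a*b`, disjunction `a+b-ab`, negation `1-a`, and implication the *minimum
t-norm residuum* — 1 when the consequent is at least as true as the
antecedent, otherwise the consequent's value. The residuum makes
enforcement one-directional: a violated implication pulls its consequent
up and never pushes its antecedent down, which is exactly the
information-propagation reading of the rules. A universal quantifier sums
one minus the body value over its groundings (vacuously satisfied over an
empty set); an existential takes the maximum body value; the
n-existential takes the n-th largest body value, which is 1 exactly when
at least `n` groundings are fully true, reduces to the existential at
`n = 1` and to the universal (as a top-level violation) at `n = |S|`.
These two reductions are the anchor we chose when the two plausible
readings of the top-level n-existential relaxation disagreed: the default
sums the `n` *smallest* per-grounding violations (the reading consistent
with both reductions); the literal alternative (summing the `n` largest)
is available behind `literal_exists_n = TRUE` for comparison. With fewer
than `n` groundings each missing grounding counts as a full violation.

Inner quantifiers range over the cross-pairs of the two parents' children
(`grounding_children()`): any other grounding is annihilated by the crisp
parent conjuncts, so nothing is lost and the grounding sets stay small. An
inner universal evaluates as the minimum (Gödel reading); no shipped rule
uses it, it is an extension point.

Constraints are *compiled* once against the hierarchy
(`compile_constraint()`): grounding frames are expanded, crisp atoms are
folded into constants, and target atoms keep index vectors, so one
evaluation is a handful of vectorized operations. A reverse sweep returns
an exact subgradient with respect to every target value; ties in max /
top-n selections break deterministically toward the canonically first
grounding, and the residuum contributes zero subgradient in its satisfied
region and in its antecedent everywhere. Finite-difference tests check the
subgradient at random non-kink points; an exhaustive property test checks
that zero violation coincides with classical satisfaction (via
`boolean_oracle()`) on crisp assignments over small random hierarchies.

### Margins, truth values, and the objective

Kernel-machine margins are bridged to truth values by the linear clamp
`squash(m) = clip((m + 1)/2, 0, 1)`: margin -1 is false, +1 true, 0 the
0.5 decision boundary. The clamp keeps the standard hinge geometry and
piecewise-linear subgradients (1/2 on the closed interval `[-1, 1]`, 0
outside). The training objective over levels `k` is

    lambda_r * sum_k w_k' K_k w_k          (regularizer)
  + sum_k sum_labeled hinge(y, m)          (loss)
  + lambda_c * sum_h violation_h(squash(m))  (penalty),

with defaults `lambda_r = 0.1` and `lambda_c = 1`. Labeled pairs enter the
loss and the penalty; unlabeled query pairs (the candidate closure of the
labeled pairs, plus any held-out pairs supplied explicitly) enter only the
penalty — enforcement is transductive and semi-supervised.

### Two-stage training

Stage 1 ignores the constraints (`lambda_c = 0`); each level's problem is
then a convex regularized hinge-loss machine, solved exactly in its dual
by cyclic coordinate ascent to a small duality gap (`stage1_fit()`), so
the stage-1 result is initialization-independent. We deliberately use an
exact dual solver rather than primal subgradient descent here: the stage
is convex, and the later acceptance checks compare its margins against an
independent interior-point QP reference at 1e-3, a tolerance plain
subgradient iterations reach only unreliably.

Stage 2 starts from the stage-1 solution and runs full-batch subgradient
descent on the complete objective with a backtracking line search
(halving; a step is accepted only if the objective decreases, so the
accepted-iterate objective is non-increasing), growing the step moderately
after each acceptance, with `max_iters = 500` and a relative-change
tolerance of 1e-5 by default. Penalty selections (max, top-n, residuum
branches) are recomputed at every evaluation, so the gradient is exact
for the current objective. Two details matter in practice:

* **Kinks.** The objective is piecewise smooth; at a kink the chosen
  subgradient need not be a descent direction at any step size. When the
  line search fails we take a small bounded non-monotone step to move off
  the kink (at most eight, geometrically shrinking) and keep the best
  iterate seen; training returns the best iterate.
* **Label-penalty conflicts.** An upward rule may push a labeled negative
  pair up against its hinge, whose slope (1) exceeds the penalty slope
  (lambda_c/2 at default); a naive subgradient direction mixes these
  blocked components with profitable ones and can stall the whole
  descent. At hinge kinks we therefore use the minimal-norm element of
  the subdifferential — the hinge coefficient in `[0, 1]` that best
  cancels the penalty push — which removes exactly the blocked
  components from the direction (steepest-descent kink handling).

With `lambda_c = 0` or an empty rule set, stage 2 returns its input
unchanged, so the whole pipeline is convex and reproducible in the
unconstrained setting. All of training is deterministic given the
configuration; no randomness enters `fit()`.

## The rule set and experiments

`build_rule()` constructs the six rules (`P->D`, `D->P`, `D->R`, `R->D`,
`P->R`, `R->P`); downward rules carry the guard conjunction
(`hasdom`/`hasres`/`hasres_p`) so objects without children leave them
vacuously satisfied, and the residue-directed downward rules optionally
use the n-existential with `n = 5` by default — interfaces in real
complexes span several residues, five being a typical lower bound.
`build_experiment()` maps the standard settings (independent,
unidirectional, bidirectional, full) to rule lists; the full setting
activates `P->D`, `D->P`, `D->R`, `R->D` and omits the direct
protein-residue rules, which are implied by the others. The protein-level
residue guard needed by `P->R` is unnamed in the usual formulation; we
call it `hasres_p`.

## Synthetic data

`generate()` produces a hierarchy, features, gold labels and a fully
consistent planted truth. Binding is decided at the domain level: every
domain draws one of `n_types` latent families, and a global symmetric
family-compatibility relation (density calibrated so the protein-pair
binding rate approximates `protein_interaction_rate`) declares
compatible-family cross-pairs bound. Protein binding is the upward
closure; each bound domain pair hosts an interface of exactly
`interface_size` residue cross-pairs, the most compatible ones under a
residue-type affinity. Features are the object's family/type direction
plus isotropic noise (`noise_sigma`, per level if desired), scaled by
`1/sqrt(feature_dim)`; a protein's feature is the sum of its domains'
family directions. Two design points deserve emphasis:

* An earlier design pulled the two members of each bound pair toward a
  *per-pair* prototype. That makes the members' direct dot product
  informative, but the tensor pairwise kernel compares a candidate pair
  with *other pairs*, and distinct pairs shared no structure — held-out
  ranking stayed at chance. Learnability under the pairwise kernel
  requires bound pairs to share latent structure across pairs, which is
  what the family-compatibility model provides (and what domain families
  provide in real interactomes).
* Real gold standards are heavily under-characterized below the protein
  level (only solved complexes yield domain/residue labels). The
  `dropout` parameter (per level) thins the lower-level gold labels while
  leaving the planted truth complete, emulating that missingness;
  negatives are re-balanced against the retained positives.

What passing tests on this generator do *not* show: robustness to
label noise in the gold standard itself (planted labels are correct by
construction), to non-blocky interaction structure, or to the feature
heterogeneity of real data sources; the generator's hierarchy is also
shallow and uniform compared with real proteomes.

`verify_consistency()` re-checks every rule (with the n-existential at
`n = interface_size`) on the planted truth through the logic module — the
generator and the rule compiler validate each other.

## Evaluation protocol

`auc()` is the rank (Mann-Whitney) statistic with half-weight ties;
`roc_points()` returns one point per distinct threshold and integrates to
the AUC; `f1_score()` uses the fixed margin-0 threshold (squashed 0.5) —
the comparable published numbers do not state their threshold, a known
comparability caveat. `make_folds()` partitions labeled protein pairs at
random and forces every labeled domain/residue pair whose ancestor protein
pair is labeled into that ancestor's fold, so the consistency rules cannot
leak information from a training fold into a test fold; lower-level pairs
without a labeled ancestor pair are assigned uniformly. `cross_validate()`
trains on the remaining folds with the held-out pairs present only as
unlabeled transductive groundings, then scores them; per-fold AUC/F1 and
the ROC over collated test scores are reported.

## Numerical choices and degenerate inputs

* Ties in max / top-n selections and in the residuum (`a == b`, treated
  as satisfied) break deterministically; groundings are enumerated in a
  fixed canonical order.
* Empty grounding sets: universal rules are vacuously satisfied; a
  top-level existential over an empty set is fully violated; an
  n-existential with fewer than `n` groundings counts each missing
  grounding as a full violation.
* `stage1_fit()` handles a PSD-singular kernel (zero-diagonal dual
  coordinates fall back to bound values); it refuses a level without
  labels — in `fit()` such a level keeps zero stage-1 weights and is
  driven by the constraints alone.
* A pair's truth value can be clamped (`clamped =`), fixing it during
  penalty evaluation and excluding it from gradients; this supports
  conditioning experiments (e.g. forcing a domain pair bound and watching
  the induced residue interface).
* The objective breakdown identity `total = regularizer + loss +
  lambda_c * penalty` is asserted to 1e-9 in the tests.

## Problem sizes used by the shipped experiments

The packaged consistency-benefit experiment uses 60 proteins, one to two
domains per protein, two to three residues per domain, an expected
protein-pair binding rate of 0.06, interface size 2, feature dimension 16,
8 latent families, cosine-normalized linear kernels, and 3-fold
cross-validation over 5 generator seeds; lower-level supervision is
thinned (dropout 0.75 for domain labels, 0.4 for residue labels) to
mirror the supervision profile of real multi-level datasets, and the
domain-level noise is set so the unconstrained domain AUC sits near 0.70.
These sizes keep a full run in minutes on one core while preserving the
regime of interest — strong protein predictions, weak domain baseline,
scarce lower-level supervision.

## Known limitations

* The residuum's one-directional pull means rules never *lower* a
  prediction; consistency violations of the "bound children under unbound
  parents" kind are resolved by raising the parent, not by suppressing
  the children.
* The linear clamp saturates outside `[-1, 1]`; targets whose margins are
  pushed far outside that range by their own level's fit stop receiving
  penalty gradients. Cosine-normalizing kernels keeps margins near the
  meaningful scale and is recommended.
* Collective classification is implemented as transductive penalty
  minimization over continuous outputs followed by thresholding, not as a
  discrete search over labelings.
* Dense pair Gram matrices bound the practical problem size (tens of
  thousands of query pairs per level on a laptop-class machine).
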