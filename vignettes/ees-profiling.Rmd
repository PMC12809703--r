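---
title: "Predicting efficient-enantioseparation mobile-phase profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting efficient-enantioseparation mobile-phase profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eesprofiler)
```

## The problem

Developing a chiral HPLC method means finding a mobile phase on which the
two enantiomers of a compound separate *usefully*: with enough resolution
to quantify each peak, and fast enough to be practical. On a polysaccharide
chiral stationary phase screened against a series of buffer/acetonitrile
mobile phases, both requirements fight each other — lowering the organic
fraction usually improves resolution but inflates retention. This package
models that trade-off end to end: it learns, from molecular descriptors,
the full profile of separation quality across a nine-point acetonitrile
gradient (30, 40, 50, 60, 70, 80, 90, 95, 98 % v/v, indexed MP 1–9).

## The EES metric

The response being modeled is the Efficient Enantioseparation value

$$\mathrm{EES} = R_s - p \cdot \max(0,\; k_2 - k_2^{lim})$$

where $R_s$ is the enantioresolution, $k_2$ the retention factor of the
more-retained enantiomer, $p$ a dimensionless penalty factor and
$k_2^{lim}$ the largest acceptable retention factor. Four practical rules
accompany the formula, applied in this order by `compute_ees()`:

1. $R_s$ and $k_2$ are rounded to one decimal (half away from zero, the
   convention of chromatographic reporting; configurable via `decimals`);
2. $R_s$ is capped at 6 and $k_2$ truncated at 30 — beyond those values
   differences carry no practical information;
3. the penalized formula is evaluated with $p = 45$, $k_2^{lim} = 20$;
4. results below −1 are floored at −1.

The practical EES range is therefore $[-1, 6]$, EES equals the capped
$R_s$ whenever the rounded $k_2 \le 20$, and EES $\ge 1.3$ (the usual
"acceptable resolution" threshold, boundary inclusive) marks a usable
condition. A compound with complete resolution ($R_s = 3.1$) but $k_2 =
51.2$ scores EES $= -1$: the condition is rejected on retention grounds
alone.

```{r}
compute_ees(3.1, 51.2)
compute_ees(2.0, 10.0)
```

### Choosing the penalty factor

$p$ controls how sharply over-retained conditions are punished. Too small
a $p$ lets a strongly resolved but slow condition sneak over the 1.3
threshold — a *false positive* in the EES sense. `simulate_false_positive_rate()`
quantifies this by exhaustively enumerating every one-decimal pair
$R_s \in [0, 6]$, $k_2 \in [0, 30]$ ($61 \times 301 = 18361$ cells) and
counting cells with EES $\ge 1.3$ despite rounded $k_2 > 20$. The
enumeration is exact and deterministic; a uniform Monte-Carlo mode over the
same grids is available for comparison. `select_penalty_factor()` returns
the smallest integer $p$ meeting a false-positive bound; at a 0.02 % bound
this yields $p = 45$ (3 of 18361 cells, 0.016 %), which is the package
default.

The underlying distribution of "computer-generated" test values is a
modeling choice: we enumerate the one-decimal grids implied by the rounding
and capping rules, which makes the simulation exact and reproducible. The
false-positive condition uses the *rounded* $k_2$, and the boundary
$k_2 = 20.0$ is not a false positive.

## From chromatograms to targets

`build_target_matrix()` turns a table of per-compound, per-mobile-phase
$(R_s, k_2)$ records into the $n \times 9$ EES target matrix, insisting on
exactly one record per compound and mobile phase. The recorded $k_1$
(least-retained enantiomer) is stored for completeness but plays no role in
EES. Descriptor and target matrices are autoscaled column-wise before
modeling — centered by the mean and scaled by the sample ($n-1$) standard
deviation, the conventional definition; a population-variance scaler would
differ by a factor irrelevant after back-transformation, and the choice is
exposed only through the scaler implementation. Constant columns (common in
targets: a mobile phase at which nothing separates) are mapped to zeros
with their scale recorded as 0, so back-transformation restores the
constant exactly rather than dividing by zero or dropping the column.
Scaling is fitted on the full compound set, mirroring the global
autoscaling of the original workflow; fitting on the training subset only
would avoid a (mild) information leak but changes none of the package's
semantics, and the scaler is attached to each model so either protocol can
be applied by the caller.

## The network and its objective

Each candidate model is a feed-forward network with one or two tanh hidden
layers ($N_1 \in [1, 30]$, $N_2 \in [0, 30]$ with $N_2 = 0$ meaning a
single hidden layer) and a linear 9-output head. Training minimizes mean
squared error on the training subset with full-batch Adam (step size 0.02,
at most 500 epochs by default); the validation subset drives early
stopping — after 20 epochs without improvement training halts and the
best-validation weights are restored — and the internal-test subset is
never touched during fitting. Weight initialization is Xavier-uniform drawn
under the configured seed, so training is reproducible bit for bit. The
training loop is compiled (RcppArmadillo); one candidate evaluation on the
default-sized dataset takes a few milliseconds, which is what makes
population search affordable. The exact gradient method is a pragmatic
choice: the objective contract (MSE on Tr, early stop on Va, seeded
determinism) is what the framework's semantics depend on, not the
optimizer brand.

Model quality is scored per subset by the penalized determination index

$$Q = R \cdot |R| - |1 - b_1| - |b_0|$$

with $R$ the Pearson correlation between predictions and targets and
$b_1, b_0$ the slope and intercept of the prediction-on-target regression:
$Q = 1$ only for a strong *and unbiased* fit. If a subset's predictions or
targets are constant, $Q$ is undefined; such candidates receive a
configured worst value (−3, the minimum attainable by the formula at
$|R| = 1$) so the optimizer can still compare them instead of crashing.
Across the three subsets,

$$pQ = 100\,(m_Q - p_{overfit}\, s_Q), \qquad p_{overfit} = 2,$$

penalizes subset-to-subset instability ($s_Q$ is the sample standard
deviation of the three $Q$). Errors are graded per prediction cell on the
descaled EES scale — Level 1: $0.2 < |e| < 0.4$; Level 2:
$0.4 \le |e| < 0.6$; Level 3: $|e| \ge 0.6$ — and combined with heavier
weights for the held-out subsets:

$$pE = 0.1(Tr_1{+}Va_1{+}IT_1) + 0.2\,Tr_2 + 0.3\,Tr_3 + 1\,Va_2 + 1.5\,Va_3 + 2\,IT_2 + 3\,IT_3.$$

Two interpretive decisions deserve a note. First, the combined objective is
implemented as $F_{obj} = W \cdot pQ - (1-W)\cdot pE$ (default $W = 0.5$):
$pE$ enters as a penalty, which is the only sign convention under which a
maximized $F_{obj}$ rewards low error; the additive form is available via
`fobj(..., pe_sign = "literal")` for comparison. Second, error levels are
counted per compound-by-mobile-phase *cell* rather than per compound: each
compound contributes nine predictions, and cell-wise counting is the
interpretation under which the 0.2/0.4/0.6 thresholds are meaningful for
every prediction. Both metrics are computed on descaled EES units, where
those thresholds and the 1.3 decision cutoff live.

## The 74-gene encoding and the optimizer

A candidate solution bundles three decisions: which compounds to hold out,
what topology to use, and which descriptors to feed the network. All three
are encoded in a continuous genome of length $10 + 2 + 62 = 74$, each gene
in $[0, 1]$:

* genes 1–10: hold-out slots. Each maps to a compound index by
  $\lfloor g \cdot n \rfloor$; collisions are repaired forward-cyclically
  (the next free index is taken), so any genome decodes to a valid,
  disjoint split. The first seven slots form the validation subset, the
  last three the internal test, and the remaining $n - 10$ compounds train
  the network. Whether the slot order is "validation first" is a
  convention; it is fixed here and immaterial to the search.
* genes 11–12: topology, mapped linearly with rounding to
  $N_1 = 1 + \mathrm{round}(29 g)$ and $N_2 = \mathrm{round}(30 g)$.
* genes 13–74: descriptor switches, binarized at 0.8 (gene $\ge 0.8$ means
  the descriptor is used). If no switch passes, the strongest one is
  included — a one-descriptor model is degenerate but comparable, an empty
  one is not.

The optimizer is a population search in $[0,1]^{74}$ combining four
ingredients: attraction toward the population best (scaled per gene by a
uniform draw), a chaotic perturbation driven by per-gene logistic maps
($z \leftarrow 4z(1-z)$), pairwise competitive replacement, and elitism.
Each iteration the population is randomly paired; the winner of each pair
proposes a refinement (small chaotic kicks on a shrinking random subset of
genes, amplitude decaying quadratically from 0.5 to 0.02), while the loser
additionally gets pulled toward its winner and has genes replaced outright
by the chaotic state with probability 0.25. The logistic map's invariant
density piles up near 0 and 1, so loser jumps can flip a descriptor switch
across the 0.8 cutoff at any stage of the run — without them the switch
configuration freezes once the kick amplitude drops below the cutoff gap,
which measurably stalls feature selection. Proposals replace their parent
only if they score at least as well, a failed loser is occasionally
regenerated at random (probability 0.05), and the incumbent best is never
displaced, so the best-so-far trajectory is non-decreasing by
construction. The original chaotic competitive-learning formulation this
reconstructs is defined behind a pluggable interface (`objective_fn`), so
any maximizer over $[0,1]^D$ can be swapped in without touching the
evaluation path; the framework's scientific content lives in the encoding
and the objective, not in one metaheuristic's constants. The search
constants above were fixed once during development against a sphere
surrogate (known optimum) and the synthetic benchmark's average behavior
across several generator seeds.

Full-scale study conditions are population 250, 500 iterations, and 70
independent runs; those are the package defaults for `optimizer_config()`
and `run_batch()`. Desk-scale work (examples, tests) uses population
15–30, 20–30 iterations and 5–7 runs, which one CPU completes in seconds
to minutes.

## Consensus

`rank_models()` orders archived networks by misclassification count
against the EES = 1.3 threshold, breaking ties by descending $F_{obj}$,
then ascending $pE$, then archive position. The original workflow also
used visual inspection of validation plots at this step; a deterministic
tiebreak chain replaces it so rankings are reproducible. The
misclassification count is taken over all compounds by default (the
criterion the counts are most stable under); `subset = "va"` or `"it"`
restricts it. `build_consensus()` keeps the top $k$ (default 5, minimum
2 — a single model has no spread), and `consensus_predict()` reports, per
compound and mobile phase, the member median, the MADe
($1.4826 \times$ median absolute deviation, the scaling that makes MAD a
consistent standard-deviation estimator for normal data; even member
counts use the midpoint median), a feasibility call (median $\ge 1.3$) and
the nominated mobile phase (highest feasible median, ties to the lowest
index — the cheaper, more aqueous condition). User-facing predictions are
clipped to the practical range $[-1, 6]$; objective computations use
unclipped values so gradients of quality are not masked.

## The synthetic benchmark

Real screening data are campaign-specific, so the package ships a seeded
generator (`generate_dataset()`) whose defaults emulate the structure of
such a campaign: 76 compounds, 62 descriptors (a mix of small-integer
counts, binary flags and continuous values, echoing topological counts
around a chiral center alongside global descriptors), 5 of which are
informative, and a resolved fraction of 0.3 — screening data on a single
chiral column are dominated by unresolved compounds, and 30 % resolvable
reflects that imbalance without a precise literature figure.

Two latent scores, both linear in the informative descriptors with latent
weights whose magnitudes are drawn from $U(0.6, 1.4)$ (bounded away from
zero so every nominally informative descriptor actually carries signal),
drive the chromatography: a retention score and a chiral-recognition
score. Retention follows a classical reversed-phase law — log-linear decay
with acetonitrile fraction — so low-ACN mobile phases show long retention
and a tail of compounds exceeds the $k_2 = 20$ limit there (producing
genuine floor cases), while high-ACN phases elute quickly. Resolution is
gated at compound level: the top 30 % by chiral-recognition score get an
Rs profile proportional to a retention hump (vanishing as $k_2 \to 0$,
rolling off at very long retention), the rest get near-zero Rs. Values are
rounded to one decimal like real reports. The generator does *not* emulate
descriptor correlation structures of real chemotypes, biphasic retention
behavior that polysaccharide phases can show, or the EES distribution of
any real dataset — so passing tests demonstrate that the machinery
recovers planted structure under realistic noise and imbalance, not that
it will reach any particular accuracy on laboratory data.

```{r}
ds <- generate_dataset(fixture_config(seed = 1))
dim(ds$descriptors)
table(apply(unclass(ds$target), 1, max) >= 1.3)
```

## Numerical choices

* After rounding, the EES formula is evaluated and snapped to nine
  decimals before the floor and threshold comparisons. Inputs on the
  one-decimal grid produce EES values that are exact multiples of 0.1 in
  decimal arithmetic but not in binary; without the snap,
  $4.3 - 10\,(20.3 - 20)$ evaluates to $1.2999\ldots93 < 1.3$ and
  boundary cells are misclassified.
* Error-level boundaries are applied to errors snapped the same way, so a
  constructed error of exactly 0.4 lands in Level 2 as defined.
* `q_index()` requires at least three paired values; degenerate (constant)
  inputs return the configured worst value with a `degenerate` attribute.
* Seeded operations (`generate_dataset()`, `simulate_false_positive_rate()`
  Monte-Carlo mode, `cclnna_optimize()`, weight initialization) restore the
  caller's RNG state, so library calls do not perturb user scripts.
* `run_batch()` derives run seeds as `base_seed + 1000 (r-1)`; keep the
  base seed modest so derived seeds stay within integer range.

## Limitations

* The optimizer is a documented reconstruction of a chaotic
  competitive-learning search, not a constant-for-constant port of any
  particular implementation; its contract (attraction, chaotic
  perturbation, competitive replacement, elitism, monotone best) is what
  the package tests.
* Training at full study scale (250 × 500 × 70) is hours of CPU; all
  shipped examples and tests run reduced configurations and state their
  sizes.
* MADe is the only uncertainty measure; no formal prediction intervals or
  conformal calibration are attempted.
* Descriptor computation from chemical structures is out of scope: the
  package consumes numeric descriptor tables.
* Predictions are only meaningful within the chemotype space spanned by
  the training compounds (the applicability-domain caveat of any QSRR
  model); the package does not currently quantify that domain.
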