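---
title: "Methods: cooperative co-evolutionary optimization of GMA pathway models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cooperative co-evolutionary optimization of GMA pathway models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its science: the model class,
the optimizer, the numerical choices, and the design decisions that were
genuinely open — with the reasoning behind each.

## 1. Model class and objectives

A generalized mass action (GMA) model describes a pathway as
`dX/dt = S v(x)` where every reaction rate is a single power-law term
`v_i = gamma_i * prod_j x_j^(f_ij)`.  The kinetic order `f_ij` is the
local log-log sensitivity of rate `i` to variable `j`; `gamma_i` is the
rate constant.  The package takes models as given (no estimation of
`gamma`/`f` from data, no time integration, no SBML) and exposes:

* `evaluate_fluxes()` — power-law rates, accumulated as sums of
  logarithms so that extreme kinetic orders (the glycogen branch of the
  yeast model carries an exponent of 8.6107) cannot overflow;
* `steady_state_residuals()` — the pool derivatives `S v(x)`, zero
  exactly at a steady state;
* `residual_jacobian()` — analytic derivatives, in linear space
  (`f_ij v_i / x_j`) or log space (`f_ij v_i`), verified against central
  finite differences in the test suite;
* `production_fold()` (F1) and `concentration_total()` (F2), the two
  objectives.

F1 is dimensionless: the target flux at a candidate state divided by
the same flux at an explicitly stored reference state.  Reference
states are part of each problem configuration, never inferred, because
fold-change claims are meaningless without them.

## 2. The bundled benchmarks and transcription decisions

Two published benchmark problems ship as data files in the package's
JSON model dialect, transcribed digit-for-digit from their printed rate
equations; numbers are stored as decimal strings so the printed
constants survive round-tripping exactly.

**Case 1, ethanol production in *S. cerevisiae*.**  Five metabolite
pools, eight fluxes, thirteen variables.  The model is used in
normalized coordinates (all basal values 1): recomputing the published
best record as `V_PK(solution)/V_PK(all-ones)` reproduces its published
production fold of 52.91 (to 0.03 %, the rounding of the 4-decimal
printed solution), which settles the coordinate question empirically.
Two transcription subtleties are recorded in the model metadata rather
than silently resolved:

* The printed rate equations attach enzyme `Y6` to the ATPase flux,
  `Y7` to the glycogen branch and `Y8` to the glycerol branch, while
  the accompanying component table swaps these labels.  The bundled
  model follows the rate equations, because only then does the tuned
  enzyme set `Y1–Y6` include ATPase, matching the published best
  solutions.  The table's mapping is kept in `metadata`.
* The glycerol and pyruvate-kinase rate laws are printed with identical
  functional forms (`X3^0.05 X4^0.533 X5^-0.0822`), unlike the
  classical formulation of this pathway.  They are transcribed
  verbatim; the duplication is flagged in `metadata`.

The published F2 for case 1 (294.80) is reproduced only by summing the
five metabolites and the six tuned enzymes; the bundled objective uses
that subset.

**Case 2, tryptophan biosynthesis in *E. coli*.**  Three pools (mRNA,
enzyme, tryptophan), eight fluxes, thirteen variables; the first three
variables are normalized to basal 1, the rest stay in model units.
`X13` is listed among the components with value 0 but appears in no
rate law; it is stored as fixed and inert (the positivity requirement
applies only to variables with a nonzero kinetic order somewhere).
The published component range for `X5` is [5, 10], yet the published
best solution (4.0172) and the comparator solutions (4.0) lie below
it.  The bundled search bounds open `X5` to [4, 10] so that the
published optimum is admissible; `validate_solution()` always reports
against the published [5, 10] — it flags exactly that one violation in
the published record — and `build_case2(x5_published_bounds = TRUE)`
restores the published range for the search too.

## 3. Steady-state handling: penalty by default, Newton refinement as an option

Evaluated under the printed equations, the published best records are
not steady states — not even approximately.  The case-1 record has a
residual max-norm near 200 (its first pool alone receives ~40 units of
influx against ~142 of consumption), and the case-2 record one near 55.
These numbers are computed by the package itself (`validate_solution()`
reports the residual vector) and are asserted in the test suite.  Either
the original optimizer modified variables before reporting, or the
printed equations contain typos; the printed artifacts do not say.

This forces a design decision.  Two candidate-scoring modes are
provided:

* **penalty** (default): a candidate's score is
  `F1 − penalty_weight * max|S v(x)|` with `penalty_weight = 10`;
  out-of-bounds states rank below every in-bounds state.  The
  steady-state condition acts as a pressure, and the optimizer's best
  solutions end up *near* steady states of the printed equations
  (case-1 residual norms of order 0.01–0.5) — closer to steady state
  than the published records themselves, at comparable production
  folds.  This mode can reproduce the published performance levels;
  strict enforcement cannot, since the published winners would be
  infeasible.
* **refine**: the textbook reading — each candidate's solved-variable
  subset is refined by the Newton solver from the GA-proposed values;
  non-convergence, or a refined value outside its bounds, makes the
  record infeasible (ranked by violation magnitude).  The solved-set
  convention is: case 1 solves the five metabolites with enzymes at GA
  values; case 2 solves the three normalized pools.  The GA-proposed
  values of solved variables double as Newton starting points, which is
  why the solved variables may also be tunable.

The residual norm is capped (at 1e12) before weighting so that wild
but in-bounds states still rank above out-of-bounds ones, and a state
is *feasible* when its residual max-norm is below the Newton tolerance
and all bounds hold.

## 4. The Newton solver

`newton_solve()` iterates in log-concentration space (`u = ln x` over
the solved subset), which guarantees positivity without projection and
makes kinetic orders the natural Jacobian entries.  Each row's flux sum
is split into its production part `P_k` and consumption part `N_k`
(both strictly positive for any positive state), and the iteration
drives `g_k = ln P_k − ln N_k` to zero.  Dividing through like this has
a useful exactness property: for S-system-form rows (one production and
one consumption term) `g` is *linear* in `u`, so a single undamped step
lands on the root — the test suite verifies one-iteration convergence
against an independent direct log-linear solve on 50 generated models.

Convergence is always certified on the raw residual max-norm
`max|S v(x)|` (the quantity the steady-state condition constrains),
with the benchmark settings as defaults: tolerance `1e-6`, at most 50
iterations.  A cap on the log-space step max-norm (default 5.0) tames
the wild starting points a genetic algorithm proposes; damping is
available but defaults to full steps.  Rank-deficiency (condition
estimate beyond 1e12) and domain failures are reported as result
statuses, not exceptions, because inside an optimizer loop a failed
candidate is information, not an error.  Step-norm stopping exists
behind a flag (`step_norm_stop`) but is off: the contract is about
residuals, not about step sizes.

## 5. Binary encoding and genetic operators

Each tunable variable is encoded as a fixed-length bit string decoded
affinely onto its bounds: `lo + int(bits)/(2^L − 1) * (hi − lo)`, most
significant bit first, so the all-zero and all-one strings hit the
bounds exactly.  Choices worth stating:

* **16 bits per variable**: resolution `(hi − lo)/65535`, about 7.6e-4
  on a [0, 50] enzyme range — finer than the 4-decimal precision of the
  published solutions.
* **Crossover points**: the benchmark presets list crossover settings
  of "2.0" and "1.0"; these are read as the *number* of crossover
  points (two-point and one-point crossover), treating the decimal
  formatting as a typesetting artifact — a crossover *rate* of 2.0
  would be meaningless.
* **Mutation rate is per-individual**: with probability `rate` a
  chromosome has exactly one uniformly chosen bit flipped.  A per-bit
  rate of 0.3 would randomize a 16-bit chromosome every generation and
  destroy convergence.
* **Standard binary encoding** as the simplest reading of "binary
  representation"; Gray decoding is available behind a flag.
* **Random immigrants** (`immigrant_fraction`, default 0.05): a small
  fraction of every new generation is replaced by fresh uniform-random
  chromosomes.  Without them, sub-populations collapse onto one value
  and the cooperative engine's collaborator draws can no longer explore
  distant joint moves; set the fraction to 0 for a pure
  crossover-mutation cycle.

All stochastic operators draw from R's global RNG stream; a run seeds
it once (`config$seed`), making every result bit-reproducible.

## 6. The cooperative engine

Each tunable variable evolves in its own sub-population.  The
*sub-chromosome fitness* is the decoded concentration value — lower is
fitter.  This is the first level of the two-level evaluation and the
source of all F2 pressure; the second level is the cooperative score of
assembled full solutions.

**How cooperative chromosomes are formed.**  Generations sweep the
sub-populations round-robin.  In a generation, every member of the
evolving sub-population is assembled with *representatives* of the
others and scored.  The representative context is the incumbent best
solution's coordinates; a fraction of the roster
(`context_exploration`, default 0.95, dropping to 0 for the final tenth
of the budget) has one randomly chosen collaborator coordinate redrawn
uniformly within its bounds.  Scores are credited to the tested
members; reproduction then runs inside the evolving sub-population
only: a binary tournament on credit (near-ties resolved toward the
lower decoded concentration), a mating pool ordered ascending by
sub-chromosome fitness and paired adjacently, k-point crossover,
per-individual mutation, random immigrants, and elitism.

Two design iterations preceded this engine, and both are worth
recording because they *failed measurably*:

1. *Rank-paired quantile rosters* (the i-th roster entry combines the
   i-th lowest-valued member of every sub-population) cannot represent
   mixed-quantile combinations at all — every candidate has all its
   variables at the same quantile.  On the bundled problems the good
   solutions are strongly mixed (one enzyme near 50, its neighbor near
   1), and this scheme stalled at a few percent of the attainable
   production fold.
2. *Pure incumbent-context evaluation* is exact coordinate ascent.  On
   the grid-enumerable toy problems it demonstrably stops at states
   where **no single-coordinate move improves the score** while a much
   better joint optimum exists — the classic diagonal-ridge pathology
   of greedy cooperative co-evolution.  The exploration entries (one
   collaborator redrawn per entry) restore pairwise joint moves and
   eliminated those traps in the toy-problem suite.

**Tie-breaking (the F2 rule).**  Wherever two records score within a
relative 1e-6 of each other — the best-so-far update, the roster's
selected entry, tournament comparisons, elitism — the lower
concentration total wins.  This is how "minimize F2" is realized
without making F2 part of the score: variables with no effect on the
penalized score (case 2's `X5` is one) are driven to their lower
bounds, and score-neutral slack is trimmed everywhere else.

**Representative selection modes.**  `"fitness"` is the scheme above.
`"random"` is the ablation arm: each generation, one representative per
sub-population is drawn uniformly and shared by the whole roster (a
shared context keeps within-generation credits comparable; independent
per-entry draws reduce credit to noise and collapse the search
entirely).  Each generation also records the concentration total of the
*nominated representative set* — under the fitness rule the
lowest-valued member of each sub-population, under the random rule a
uniform draw.  That trajectory is the quantity on which the two-level
concept is judged (see §8).

**Termination.**  Runs stop at the generation budget, or early once the
best record is feasible and unimproved (relative 1e-6) for
`stall_generations` (default 50) generations.  In penalty mode on the
bundled benchmarks the feasibility threshold (residual below 1e-6) is
never reached — there is no in-bounds steady state of the printed
equations — so benchmark runs always use the full budget.

**The baseline.**  `run_baseline_ga()` is the single-chromosome
comparator: one population whose individuals concatenate all tunable
bit strings (176 bits for case 1).  Evaluation, scoring, budget
(population-size evaluations per generation) and elitism are identical;
selection is a binary tournament on the score with random mate pairing
— a plain generational GA.

## 7. Synthetic models: what they do and do not emulate

`generate_planted_model()` draws random power-law fluxes and mixed-sign
stoichiometric rows, picks a random positive root, and rescales each
row's negative terms by the ratio of its positive to negative flux sums
at the root — so the root is exact to machine precision by
construction, with all rate constants positive.  Degenerate draws are
redrawn: rows whose coefficients share one sign (no root can exist),
and models whose solved-subsystem Jacobian at the root is
ill-conditioned after row normalization (reciprocal condition below
1e-2).  The latter filter exists because a near-rank-deficient
subsystem loses its root under tiny perturbations of the fixed
variables, which defeats the purpose of planting one: the solver would
be asked to find a root that no longer exists.

`generate_toy_problem()` builds a three-variable, one-row planted model
with two tunables on narrow bounds and a 6-bit encoding, so the genetic
search space is exactly a 64 x 64 grid that `toy_grid_optimum()`
enumerates exhaustively with the same scoring — a ground-truth oracle
for the optimizer.

These generators produce smooth, box-bounded, low-dimensional
landscapes with known roots.  They say nothing about measurement noise,
model misspecification, or the combinatorial scale of genome-wide
networks; a passing optimizer here demonstrates correct mechanics and
sane search behavior, not performance on real pathway models beyond the
two bundled benchmarks.

## 8. What the experiments show — and what they do not

Problem sizes are the package's own desk-scale choices: 20 seeded runs
per benchmark experiment (the original study averaged 100; pass
`n_runs = 100` to mirror it), 10 seeds for the toy-optimality check, 10
same-seed pairs per ablation.

* **Benchmark performance.**  Across 20 preset runs the best case-1
  production fold lands in the mid-50s — above the weakest published
  comparator (52.0843) and above the published best record (52.91) —
  with residual norms orders of magnitude smaller than the published
  record's.  Case 2 converges essentially every run to the box-corner
  optimum of its penalized score (fold about 4.57, against a weakest
  comparator of 3.0620).  The run-level mean/sd statistics of the
  original study are not reproducible quantities — they depend on
  undocumented optimizer internals — so the package's tests bound
  performance instead of matching those statistics.
* **Two-level evaluation ablation.**  Fitness-based representative
  selection beats random selection on best F1 in nearly every same-seed
  case-1 pair, and the nominated-representative concentration trajectory
  ends lower in at least 7 of 10 pairs (the acceptance threshold; 10 of
  10 in the measured configurations).  One honest caveat: under the
  printed equations the *best-record* F2 tracks F1 (higher production
  needs more enzyme), so a worse-optimizing arm necessarily shows a
  lower best-record F2; the representative trajectory, not the best
  record, is the meaningful F2 comparison, and it is also the quantity
  the original study's trajectory figures display.
* **Representation ablation.**  On the grid-enumerable toy problems the
  cooperative representation matches or beats the single-chromosome
  baseline in at least 7 of 10 same-seed pairs, and reaches at least
  95% of the exhaustive grid optimum on every seed.  On the bundled
  benchmarks the two representations are statistically equivalent at
  equal budget: both reach the mid-50s on case 1 with overlapping
  spreads (the cooperative engine wins roughly half the pairs), and
  both converge to case 2's corner optimum with the baseline a final
  fraction of a percent sharper.  The package therefore makes the
  representation claim only where ground truth exists (the toy suite)
  and reports benchmark equivalence as a finding: with a competent
  traditional GA as the comparator, the cooperative decomposition's
  advantage on these two problems is not detectable at this budget.

## 9. Numerical details and degenerate inputs

* Flux evaluation clamps states at the smallest positive double before
  taking logs: a tunable sitting exactly on a lower bound of 0 yields
  fluxes that degrade smoothly to 0 (positive exponent) or a huge value
  (negative exponent) instead of NaN; the public `evaluate_fluxes()`
  rejects non-positive values for variables with nonzero kinetic
  orders, naming the variable.
* Out-of-bounds candidates score `−1e15 − violation`, strictly below
  any in-bounds candidate (whose residual penalty is capped); failed
  refine-mode evaluations rank by violation magnitude.
* The near-tie width for all F2 tie-breaking is relative 1e-6 — the
  same width as the early-stop improvement test — so "equal score"
  means equal beyond any quantity the optimizer can resolve.
* Model JSON stores every number as the shortest decimal string that
  round-trips to the same double, making `load(save(m))` bit-exact.

## 10. Known limitations

* The printed benchmark equations are internally inconsistent with
  their printed best solutions (§3); all reproduction targets here are
  therefore production folds and concentration totals of printed
  vectors, plus performance bounds for the optimizer — not solution
  vectors.
* Penalty-mode solutions are near-steady, not exactly steady; refine
  mode enforces steady states exactly but cannot reproduce the
  published records for the reason above.
* The cooperative engine's round-robin/incumbent design is one of many
  reasonable readings of the original flow description, which leaves
  the sub-chromosome fitness function, the encoding, and the
  credit-assignment rule unspecified; every inference made is stated
  in §5–6 as a package decision.
* Wall-clock comparisons are hardware-bound and are deliberately out of
  scope; `run_experiment()` records per-run generation counts instead.
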