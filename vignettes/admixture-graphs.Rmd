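---
title: "f-statistics and admixture graphs with admixkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{f-statistics and admixture graphs with admixkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixkit)
```

## The statistics

For biallelic SNP frequencies $p$ the package estimates

$$ f_4(A,B;C,D) = \mathrm{E}\big[(p_A - p_B)(p_C - p_D)\big], $$

averaged over SNPs, together with its special cases
$f_2(A,B) = f_4(A,B;A,B)$ and $f_3(A;B,C) = f_4(A,B;A,C)$, and the
normalized D-statistic (same numerator, ABBA–BABA denominator
$\sum (p_A + p_B - 2p_Ap_B)(p_C + p_D - 2p_Cp_D)$, so D has the sign of
$f_4$ on a bounded scale).  If four populations are related by an
unadmixed tree $((A,B),(C,D))$ then $f_4(A,B;C,D)$ has expectation zero;
when all three permutations of a quartet are significantly non-zero, at
least one population must be admixed (`quartet_report()`), and a
significantly negative $f_3(A;B,C)$ can only arise if $A$ is admixed
(three-population test).

Standard errors come from a weighted delete-one-block jackknife over
contiguous genomic blocks, which is robust to linkage between nearby
SNPs.  The default block policy is 5-Mb windows by position (500-SNP
chunks when positions are absent); the simulator uses an explicit count
of equal blocks.  The same leave-one-block-out replicates give the full
covariance matrix of any set of statistics (`jackknife_covariance()`),
which is what graph fitting needs.

Two estimator options deserve comment:

* **Bias correction** (`estimator_options(bias_correction = TRUE)`).
  The plain average for $f_2$ and $f_3$ is inflated by within-population
  sampling noise, by $h/n$ per population that appears twice in the
  statistic, with $h = p(1-p)\,n/(n-1)$ and $n$ the observed allele
  count.  With few individuals this term is large — at 10 diploids it is
  roughly $0.2/20 = 0.01$ in f-units, comparable to real admixture
  signals — and it is exactly what can turn a genuinely negative
  $f_3$ positive.  The correction is therefore recommended (and used by
  all worked scenarios in this package) whenever sample sizes are small.
  It is **off by default** because only the uncorrected estimators
  satisfy the exact linear identities
  ($f_4(A,B;C,D) = f_3(A;B,D) - f_3(A;B,C)$ and friends) that the
  identity test-suite checks, and because $f_4$ over four distinct
  populations needs no correction.  The effect of leaving it off during
  fitting is benign in one specific sense: the inflation acts exactly
  like extra terminal drift, so topologies and mixture proportions are
  unaffected; only terminal branch lengths absorb it.
* **Missing data** are handled by complete cases: each analysis is
  restricted to SNPs with data in every population involved (for graph
  fitting, in *all* model populations, so every statistic uses one SNP
  set — f-statistics depend on the absolute frequency spectrum, and
  comparing statistics computed on different SNP sets biases them).  A
  per-statistic maximal-overlap mode exists but is experimental and
  excluded from fitting defaults, as it can make large-magnitude basis
  statistics unstable.
* **Monomorphic sites are retained** by default: fixed sites carry
  information about the absolute scale of f-statistics (adding them
  shrinks every statistic proportionally, which is why SNP sets must
  match).  `polymorphic_only = TRUE` filters them.

## Expected f-statistics on a graph

An admixture graph is a rooted DAG: drift edges carry lengths in
f-statistic units; an admixture node has two parents with proportions
$\alpha$ and $1-\alpha$.  For every leaf and drift edge,
`branch_weights()` computes the probability that a lineage sampled from
the leaf traverses the edge (a sum over ancestry routes of products of
mixture proportions).  Expected f-statistics are then linear in the
branch lengths:

$$ \mathrm{E}\,f_4(A,B;C,D) \;=\; \sum_e (w_{A,e}-w_{B,e})(w_{C,e}-w_{D,e})\,\ell_e . $$

This reproduces the familiar path-overlap pictures: zero for a
concordant quartet, the internal branch length $y$ for a discordant one,
and $(1-\alpha)\,y$ when one population is admixed so that only the
$1-\alpha$ route crosses the overlap.  The implementation is a rootward
dynamic program; the test suite checks it against brute-force route
enumeration on hundreds of random graphs, and checks invariance under
re-rooting along drift edges (`reroot_graph()`).

## Fitting

With $n$ populations all f-statistics span a space of dimension
$\binom{n}{2}$; `build_basis()` uses the $n-1$ statistics $f_2(b, X)$
plus $\binom{n-1}{2}$ statistics $f_3(b; X, Y)$ anchored at a base
population $b$.  `fit_graph()` minimizes the score

$$ S(G) = \tfrac12\,(\mathbf g-\mathbf f)^{\top} Q^{-1} (\mathbf g-\mathbf f), $$

with $\mathbf f$ the observed basis vector, $\mathbf g$ the model
prediction and $Q$ the jackknife covariance — the negative
log-likelihood up to a constant under multivariate normal errors.
Because $\mathbf g$ is linear in the branch lengths at fixed
proportions, the inner problem is solved exactly by non-negative
generalized least squares (an active-set solver whose inner least-squares
steps use an SVD pseudoinverse; see *Numerical choices*), and the
proportions are optimized outside by a bounded derivative-free search
(grid scan plus Brent refinement for one proportion, Nelder–Mead with
seeded restarts for several; 10 restarts by default).  A plain
least-squares mode (`lsq_fit()`) replaces $Q$ by the identity; its score
is in different units, treats correlated statistics as independent, and
is provided only for completeness.

Diagnostics follow the standard workflow:

* `residual_report()` recomputes **every** f-statistic on the model
  populations (all $\binom n2$ f2, $3\binom n3$ f3, $3\binom n4$ f4),
  compares observed against predicted and reports Z-scores sorted by
  magnitude.  The SE of a residual is approximated by the observed
  statistic's jackknife SE (the model-prediction uncertainty is not
  propagated; this is conservative for well-fitting models and is
  documented output, not an inferential claim).  There is no general
  threshold for a "significant" residual — many correlated statistics
  are tested at once — so the full sorted table is always emitted.
* `trifurcation_scan()` flags internal branches fitted at (numerically)
  zero length, the characteristic signature of a misspecified split
  order: the optimizer pushes populations as close as possible to their
  correct positions and the blocked branch collapses.  Edges out of the
  root are excluded (only their sum is root-invariant), as are stub
  edges into unsampled admixture sources, which belong to compound
  parameters and may legitimately be zero.
* `compare_models()` reports the score difference between fits on the
  same basis, preferring the lower score.  Naive chi-squared p-values
  for such comparisons are not well calibrated (the equations are
  heavily correlated), so none are produced; with unequal numbers of
  admixture events even the degrees-of-freedom change is ambiguous and
  the difference is only reported.
* `profile_parameter()` re-fits with one parameter fixed along a grid,
  giving profile-likelihood curves: a flat stretch is a non-identifiable
  interval, a clean minimum an identified parameter.

## Identifiability

A graph with $n$ leaves and $a$ admixture events has $2n+2a-3$ free
parameters against $\binom n2$ constraints.  Even when the global
counting is favorable, individual parameters can be undetermined: the
three branches around an admixture event with unsampled sources form
the single compound parameter $\alpha^2 x + (1-\alpha)^2 y + z$, and
phylogenetically equivalent populations (sister leaves) contribute
redundant equations.  `identifiability_report()` handles this
numerically: it evaluates the Jacobian of the predicted basis vector
with respect to every length and proportion at a random interior point
(lengths in $[0.01, 0.05]$, proportions in $[0.2, 0.8]$, seeded — a
fixed "nice" point could sit on a measure-zero coincidence) and reports
its numerical rank, the null-space directions as readable parameter
combinations, and the structurally detected compound patterns.  Rank
below $2n+2a-3$ flags an underdetermined model.  On the worked
topologies this yields rank 6 < 7 for the single-admixture quartet (any
of the four populations can be modeled as admixed, with the proportion
flat over an interval), rank 9 = 9 for the five-population model with a
distinctly placed fifth population (unique optimum), and rank 8 for the
sister-pair variant (the sister adds no independent constraint).  The
exceptional case where several populations share the same two sources
in different proportions — making the surrounding branches individually
solvable — is detected by the same rank computation rather than a
closed-form rule.

## The simulator

`simulate_panel()` draws, per SNP, a root frequency $p_0$ (default
Uniform(0.25, 0.75); a Beta option exists), evolves it along every
drift edge by an independent Normal increment with variance
$\ell\,p_0(1-p_0)/H$ where $H = \mathrm{E}[p_0(1-p_0)]$, mixes parental
frequencies at admixture nodes, clips to $[0,1]$, and finally draws
binomial samples of $2 \times$ (diploids) allele copies per leaf
(default 10 diploids; `Inf` records exact frequencies).  The
$p_0(1-p_0)$ factor makes per-SNP drift proportional to heterozygosity,
as under genetic drift; the $1/H$ normalization puts branch lengths in
the same units as the sample statistics, so that every f-statistic's
expectation equals its path-overlap expression with unit slope — the
property the Monte-Carlo tests assert.  SNPs are split into contiguous
equal jackknife blocks (default 100) and are independent across blocks,
so jackknife SEs can be validated against the true sampling spread.

What the generator deliberately does **not** emulate: linkage
disequilibrium within blocks, mutation, ascertainment bias, fixation
(clipping is kept below 1% of SNP-by-branch draws for all shipped
scenarios, and a warning fires when total root-to-leaf drift exceeds
0.2, where the Gaussian small-drift approximation degrades), sequencing
error and ancient-DNA artifacts.  Passing tests therefore demonstrate
the estimators and the fitting machinery under the model's own
assumptions, not robustness to those real-data complications.

The canned scenarios (`scenario_spec()`) are variations on one
human-like history: an African outgroup ("Baka"), a western Eurasian
("French"), an eastern Eurasian ("Han") and a Native-American-like
population ("Mixe") with 70% eastern / 30% western ancestry; "Kyrgyz"
replaces Mixe for a recent 50/50 admixture with short terminal drift
(negative $f_3$); "Ulchi" splits between Han and the eastern source
(making $\alpha$ identifiable); "Hungarian" is a sister of French
(adding no constraint).  Branch lengths (root-to-leaf totals around
0.03 f-units) were frozen once so that the scenarios reproduce the
qualitative Z-score orderings of such histories at 200,000 SNPs with
100 blocks and 10 diploids per population — the problem size used by
the package's acceptance analyses; they are package constants, not
estimates from any real data set.  `masking_scenario()` constructs a
two-admixture history in which the second proportion is solved in
closed form (expected $f_4$ is affine in it) so that one quartet
statistic is exactly masked while other permutations still reveal the
admixture.

## Numerical choices

* **Ridge on $Q$.**  `diag_reg` (default $10^{-4}$) is a *relative*
  ridge: `diag_reg * mean(diag(Q))` is added to the diagonal.  An
  absolute addend of $10^{-4}$ — a working value quoted for software
  whose statistics live on a different internal scale — would exceed
  the jackknife variances here by orders of magnitude, flattening the
  score surface; the dimensionless form stabilizes $Q^{-1}$ without
  destroying the score's likelihood units.
* **Non-negative GLS.**  The design matrix is generically
  rank-deficient (compound-parameter columns are exactly proportional;
  the two root edges are identical columns), so the active-set NNLS
  performs its inner least-squares solves with an SVD pseudoinverse,
  giving minimum-norm solutions on degenerate subsets instead of
  failing.  Reported scores are exact; the *distribution* of length
  among members of a compound is arbitrary and should be read through
  `identifiability_report()`.
* **Rank tolerance.**  Singular values below $10^{-9}$ of the largest
  count as zero.
* **Ties.**  Restart results within $10^{-12}$ of the best score are
  resolved by the lexicographically smallest parameter vector, making
  fits reproducible under flat directions.
* **Degenerate inputs.**  A statistic computed on a single block gets
  `se = NA` rather than a fabricated error; identical frequency columns
  give exact zeros; an empty SNP intersection is an explicit error
  naming the populations.

## Limitations

Branch lengths are f-statistic units throughout; no conversion to
generations, effective sizes or $F_{ST}$ scaling is attempted.
Topology search is out of scope: the user supplies the graph, and the
diagnostics (residuals, trifurcations, profiles, score comparisons)
guide manual revision.  Scores of models with different numbers of
admixture events are reported but deliberately not tested against any
threshold.
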