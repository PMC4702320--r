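---
title: "Donor splice-site prediction by di-nucleotide association and SAE scoring"
author: "donorSAE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Donor splice-site prediction by di-nucleotide association and SAE scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(donorSAE)
```

## The problem

Donor (5′) splice sites mark the exon–intron boundary and are conserved
with the di-nucleotide GT at the start of the intron. Nearly all of the
discriminative information separating real donor sites from the vastly
more numerous decoy GT occurrences lives in a handful of bases around
the junction. donorSAE models that signal from *short* aligned windows
— short enough to be usable on next-generation sequencing reads — and
without the numeric encoding step that machine-learning classifiers
need.

Throughout, a window is written `(-e ~ +i)`: `e` exonic bases 5′ of the
GT and `i` intronic bases 3′ of it, with the GT itself excised from the
modeled positions. A "9 bp" window with geometry `(-3 ~ +6)` therefore
spans 11 nt of genome. `scanDonorCandidates()` reports 1-based inclusive
coordinates over the full 11 nt motif; `MotifSet` objects hold the 9
modeled core positions.

## The association measure

For `N` aligned motifs of length `P`, let `n_i(s)` count base `s` at
position `i` and `n_ij(s,t)` count the co-occurrence of `s` at `i` with
`t` at `j`. The association between the two base-position units is

$$a_{i,j}(s,t) = \frac{n_{ij}(s,t)}{\sqrt{n_i(s)\,n_j(t)}}, \qquad i \ne j,$$

which is 0 when the bases never co-occur and 1 when each always implies
the other (complete association). Within one position the aligned
column is a tetranomial sample, and the indicator correlation gives

$$a_{i,i}(s,t) = \begin{cases} 1 & s = t\\[2pt]
-\sqrt{\dfrac{n_i(s)\,n_i(t)}{(N-n_i(s))(N-n_i(t))}} & s \ne t,\end{cases}$$

a value in $[-1, 0]$ for distinct bases. `associationMatrix()` assembles
all $4P \times 4P$ unit pairs, using the unit index
$u = 4(\mathrm{pos}-1) + \mathrm{rank}$ with base order A, T, G, C, so a
20-position window yields an 80 × 80 matrix in which position 8 spans
units 29–32. Because `n_ij(s,t) = n_ji(t,s)`, only 10 of the 16 ordered
base-pair sub-matrices are independent; the other 6 are transposes.
Plotted as a heat map, the block of mutually associated units around
the junction motivates the compact default window; window size remains
a user parameter — the package does not pick it automatically.

Two numerical guards, both documented on the help pages:

* if `n_i(s) = 0` or `n_j(t) = 0`, the off-diagonal ratio is 0/0 and is
  defined as 0 (the numerator is necessarily zero), with a
  data-sparsity warning;
* if a base occupies an entire column, the same-position formula
  divides by zero; the cell is NA and exports as a blank field.

## The SAE classifier

The observed indicator of base `s` at position `i` is predicted from
every other position through the class-conditional proportion

$$p(s_i \mid t_j) = \frac{n_{ij}(s,t) + \alpha}{n_j(t) + 4\alpha},$$

with pseudocount $\alpha = 0$ reproducing the plain count ratio. The
sum of absolute errors at position `i` collapses algebraically to
$SAE_i = 2\sum_{j \ne i} (1 - p(s_i \mid t_j))$, and over all positions
to $SAE_{ap} = 2P(P-1) - 2\sum_i \sum_{j\ne i} p(s_i \mid t_j)$, bounded
by $[0, 2P(P-1)]$. A candidate motif is scored under both class tables:

$$dSAE = SAE_{ap}^{TSS} - SAE_{ap}^{FSS},$$

computed literally as this difference (the constants cancel and the
conditional sums enter with a negative sign; an expanded form that
keeps the sums positive circulates, but it contradicts the SAE algebra
and is not used here). Mutually predictable TSS-like motifs get low
$SAE^{TSS}$, hence negative dSAE. The decision rule is strict:

* `dSAE < ε` → TSS,
* `dSAE ≥ ε` → FSS (the boundary goes to FSS).

Reported scores are `-dSAE`, so higher = stronger TSS; a threshold
`ε = -7.16` is equivalently "score ≥ 7.16 ⇒ not TSS" being false, i.e.
sites at or above 7.16 on the score scale are rejected as TSS only at
the boundary.

### Pseudocount

$\alpha = 0$ is the faithful estimator and the default. Cells with an
unseen conditioning base are then undefined: they are stored as NaN
with a warning at fit time, and scoring a motif through one raises an
error directing the user to $\alpha > 0$. The fit itself is allowed to
succeed because single-motif and tiny training sets are legitimate for
the defined cells. Laplace-style smoothing ($+\alpha$ on joints,
$+4\alpha$ on the conditioning marginal) is used throughout the test
suite's small fixtures, typically $\alpha = 0.5$.

### Threshold estimation

`estimateThreshold()` follows a five-step procedure: (I) draw a
stratified random 60 % of each class; (II) divide it into `k = 10`
non-overlapping folds with near-equal class composition; (III–IV) for
each fold, train on the other nine, score the held-out fold, and sweep
candidate thresholds for the sensitivity = specificity crossing;
(V) average the ten fold-level thresholds into ε.

The candidate set is the observed held-out dSAE values plus midpoints
between consecutive sorted values, which makes the crossing
deterministic and reproducible from the seed. During the sweep each
class counts a boundary instance in its own favor (sensitivity uses
`dSAE ≤ c`, specificity `dSAE ≥ c`): this symmetric convention makes
the tie-averaged crossing exactly equivariant under class swap and
places it at the midpoint for symmetrically separated scores, while
the *prediction* rule stays strict. Ties in
$|\mathrm{sens} - \mathrm{spec}|$ are resolved by averaging the tied
candidates.

Because sensitivity and specificity are class-conditional rates and
the $\alpha = 0$ conditionals are ratios of class-wise counts, the
estimate is invariant to the FSS:TSS ratio once the folds are fixed —
duplicating every FSS motif within its fold changes nothing. Note that
$\alpha > 0$ deliberately breaks this exact scale invariance
($\,(mn+\alpha)/(mN+4\alpha) \ne (n+\alpha)/(N+4\alpha)$), which is why
the invariance property is stated for the pure-proportion estimator.

## Baselines

`fitWmm`/`scoreWmm` implement the weight-matrix method: per-position
probabilities per class and the score
$\sum_i \log_2 p_i^{TSS}(x_i) / p_i^{FSS}(x_i)$. `fitMm1`/`scoreMm1`
implement a position-specific first-order Markov chain and score the
log2 likelihood ratio. Both are trained on the same TSS/FSS windows as
the SAE model, with log base 2 and the FSS model as the denominator —
a deliberate design so all three methods see identical data. External
scoring servers for these classical models use their own background
models; score *values* are not comparable across tools, only ranking
behavior. Default $\alpha = 0.5$ for the baselines, which are
routinely fit on small synthetic sets.

## Evaluation

`rocCurve()` sweeps every distinct score as a threshold, grouping ties
on a single vertex, so the trapezoidal AUC equals the normalised
Mann–Whitney statistic (ties counted ½) for any tie structure. Its
standard error uses the Hanley–McNeil formula with
$Q_1 = \theta/(2-\theta)$ and $Q_2 = 2\theta^2/(1+\theta)$, which
vanishes as $\theta \to 1$.

`prCurve()` builds precision–recall curves from the achievable
(TP, FP) path with Davis–Goadrich interpolation: intermediate TP counts
between two achievable points gain false positives linearly at the
local skew $(FP_B - FP_A)/(TP_B - TP_A)$. AUC-PR integrates the
interpolated curve by trapezoid (the interpolation is prescribed; the
integrator is this package's choice). The recall-0 anchor takes the
limiting precision of the first TP-increasing segment — $1/(1+skew)$
when that segment leaves the origin — so a perfect scorer attains
AUC-PR exactly 1 without inventing unreachable points.

AUC-ROC is exactly invariant to duplicating the negative class (both
curve vertices and area), while precision at fixed recall strictly
degrades; both behaviors are asserted in the test suite, mirroring the
method's intended use under class imbalance. `crossValidate()` pools
held-out scores across stratified folds into one ROC/PR pair (pooling,
not fold-averaging, and labeled as such) and reports per-fold
sensitivity/specificity at a supplied threshold.

## Preprocessing

`dedupeMotifs()` removes exact duplicates within each class first and
then removes from the FSS any motif text present among the unique TSS
("duplicate" = identity over the modeled core window). Percent
identity between aligned fixed-length motifs is Hamming identity
(`percentIdentity`, e.g. 5 matches over 10 positions = 50 %); no
alignment is performed because the windows are position-aligned by
construction. `similarityProfile()` bins all-vs-all identities at the
discrete levels $100k/P$. `sampleImbalanced()` draws
`round(ratio × N_TSS)` FSS uniformly without replacement under a seed.

## The synthetic generator

`synthSpec()`/`simulateMotifs()` emulate what the method assumes about
real data: TSS motifs have position-specific base preferences *plus*
pairwise dependencies; FSS motifs are compositionally unremarkable.
TSS positions are drawn independently from a 4 × P profile, then each
coupling `(i, j, map, λ)` overwrites position `j` with `map(base at i)`
with probability λ — the simplest mechanism with tunable, analytically
checkable pairwise dependence (association at the coupled pair rises
monotonically with λ; permutation maps leave uniform marginals intact,
which is how the tests isolate the dependency signal from the marginal
signal). FSS motifs are i.i.d. from a single background composition.

The default profile (`defaultDonorProfile()`) is loosely shaped after
the MAG|gt|RAGT donor consensus — strong G at −1, A-rich +4, G-rich +5,
T-leaning +6, decaying to background at +7/+8 — with two moderate
(λ = 0.3) identity couplings between intronic consensus positions. The
`strength` argument sharpens or flattens the profile on a log-linear
scale (0 = uniform, 1 = default, 2 = a "strong-consensus" site
population). These numbers are an arbitrary realistic choice for
simulation, not fitted to any dataset. What the generator does *not*
emulate: empirical genomic composition, higher-than-pairwise
dependencies, and positional correlation structure of real decoy GTs —
so passing tests demonstrate correctness of the machinery and the
qualitative behavior of the statistics, not field performance on real
genomes.

`simulateGenes()` plants full 11 nt windows into background genes at
recorded coordinates and returns the ground-truth table; background GT
decoys remain, as they would in real sequence.

## Problem sizes and reproducibility

The shipped tests run the full pipeline at deliberately modest sizes —
training sets of 150–1000 motifs per class, 9 bp windows, 50 planted
genes of 400 bp — chosen so the whole suite completes in well under a
minute while keeping Monte-Carlo margins comfortable (e.g. held-out
AUC ≈ 0.95 against a 0.9 bound on coupled data). Every stochastic step
(sampling, fold assignment, simulation) takes an explicit seed and
restores the caller's RNG state, so results are bit-reproducible.

## Known limitations

* Forward strand only; reverse-complement and rescan for the other
  strand.
* Probabilities are defined over {A, C, G, T} alone; candidate windows
  containing ambiguity codes are skipped and counted, and strict
  loaders reject them.
* Window size is a user parameter; the association heat map informs
  the choice but no automatic selection is attempted.
* Maximum-entropy and dependency-decomposition donor models are out of
  scope; the WMM/MM1 baselines here are not score-compatible with
  external servers.
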