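---
title: "Grouping miRNA seeds with a mixture of position weight matrices"
author: "seedmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grouping miRNA seeds with a mixture of position weight matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedmix)
```

## The model and its assumptions

`seedmix` clusters fixed-length miRNA seed sequences — the 6-mers at
nucleotide positions 2–7 of the mature miRNA — with a multinomial
mixture of position weight matrices (PWMs). Each of N seeds is assumed
to be generated by one of k latent components; component i is a 4 × L
column-stochastic matrix W_i of per-position base probabilities with
mixing weight λ_i. Under a component, positions are independent, so

$$P(X_m) = \sum_{i=1}^{k} \lambda_i \prod_{v=1}^{L} W_i[X_{mv}, v],
  \qquad \sum_i \lambda_i = 1,\ \lambda_i \ge 0 .$$

Column independence is the standard PWM assumption; it is adequate for
6-mers that act mostly through exact complementarity, but it cannot
represent covarying positions. The mixture is over sequences, one
component per seed: seeds shared by many miRNAs are deliberately kept
as separate records so that group sizes count miRNAs, not unique
6-mers.

Parameters are estimated by EM. The E-step computes responsibilities
$z_{mi} = \lambda_i P(X_m \mid W_i) / \sum_j \lambda_j P(X_m \mid
W_j)$; the M-step sets $\hat\lambda_i = \frac1N \sum_m z_{mi}$ and
rebuilds each $\hat W_i$ from pseudocount-smoothed,
responsibility-weighted base counts. After convergence each seed is
hard-assigned to its maximum-responsibility component (ties to the
lowest index); empty groups are permitted and reported.

### The two M-step variants

The responsibility-weighted count update (`variant = "standard"`) is
the exact maximizer of the expected complete-data log-likelihood, so
with no smoothing the marginal log-likelihood is non-decreasing at
every iteration — a property the test suite checks on a hundred seeded
instances. An alternative update (`variant = "literal"`) additionally
weights every count by the current matrix entry before renormalizing
each column. It is retained as one defensible algebraic reading of
self-weighted updates seen in the motif-discovery literature, but it
does not maximize the stated objective and carries no ascent
guarantee; it is for fidelity experiments only.

### Smoothing and the ascent guarantee

The default pseudocount (1e-4 per matrix cell) exists to keep every
PWM entry positive so no sequence can receive zero likelihood under
every component. Strictly, smoothing turns the M-step into a MAP
update under a Dirichlet prior, whose ascent target is the penalized —
not the marginal — likelihood; in practice the default is small enough
that observed trajectory decreases are on the order of 1e-6 on
log-likelihoods of hundreds, and with `pseudocount = 0` ascent is
exact. Setting the pseudocount to 0 is allowed, at the cost that a
zero entry touched by a sequence surfaces as an explicit error (the
per-sequence log-likelihood uses a −Inf sentinel, never a crash).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `seedStart`, `seedLength` | 2, 6 | 1-based inclusive seed window, positions 2–7 |
| `pseudocount` | 1e-4 | per-cell Dirichlet smoothing in the M-step |
| `tol` | 1e-8 | relative marginal log-likelihood change at which EM stops |
| `maxIter` | 500 | EM iteration cap |
| `restarts` | 10 | independent initializations per k; max-likelihood fit kept |
| `matchWeight` | 0.7 | probability on the observed base when a drawn 6-mer window is converted to a starting PWM |
| `initMode` | from_sequences | starting PWMs from data windows; `dirichlet` draws columns from Dirichlet(1) |

Initialization draws k length-L windows uniformly from a background
pool. The pool defaults to the input seeds themselves: initialization
only needs diverse realizable windows, and this keeps the package
self-contained; a `background` argument accepts longer sequences (for
example genomic fragments) for users who prefer genome-drawn starts.
The 0.7 conversion weight is an exposed choice, not an estimate: any
value comfortably above the uniform 0.25 and below 1 yields distinct,
non-degenerate starting points.

Restart seeds are derived deterministically from the master seed, k
and the restart index, so a whole `scanK()` is reproducible end to end
and no hidden RNG state leaks between calls (every seeded function
restores the caller's RNG state).

### Choosing k

`scanK()` deliberately applies no complexity penalty: the raw
(k, best log-likelihood) table is returned so the user can inspect its
shape. The marginal likelihood is non-decreasing in k for nested fits,
so the raw argmax over a range tends to sit at the top of the range;
the table's elbow, not the argmax alone, is the informative output.
Penalties of BIC type are a poor fit here because the parameter count
(k(4−1)L + k − 1) grows so fast that they collapse everything into few
clusters.

## Validation scores

**Score_S** is the silhouette with Hamming distance:
$(\beta - \alpha)/\max(\alpha, \beta)$, where α is the mean distance
to co-members (excluding self) and β the minimum over other non-empty
groups of the mean distance to that group. Conventions: a singleton's
score is 0 (α undefined); α = β = 0 also gives 0; fewer than two
non-empty groups is an error, and per-group summaries then report the
silhouette column as NA.

**Score_M** is the information-weighted match score
$$\mathrm{Score}_M(X) = \frac{\sum_v I(v) f_{v,b(v)} - \sum_v I(v) f_v^{\min}}
 {\sum_v I(v) f_v^{\max} - \sum_v I(v) f_v^{\min}},
 \qquad I(v) = \sum_b f_{v,b} \log(4 f_{v,b}),$$
with natural logarithms and the 0·log 0 = 0 convention. The
frequencies f are the **raw empirical base frequencies of the group's
member seeds**, not the learned smoothed PWM: the score's origin is
frequency-matrix matching, reference families have no learned PWM, and
unsmoothed counts let perfectly conserved groups reach exactly 1.
A profile whose columns are all uniform has a zero denominator; the
score is then 0 and the profile is flagged degenerate. Baselines are a
uniform random grouping and average-linkage (UPGMA) agglomeration on
Hamming distances cut at the same k — linkage and metric are this
package's own choice of a standard, deterministic baseline, so its
scores are comparators, not reproductions of any external analysis.

## The simulator

`sampleMixture()` draws from exactly the generative model above, so
recovery tests compare the estimator against a known truth. Planted
mode builds k PWMs from distinct consensus 6-mers (pairwise Hamming
≥ 3, match probability 0.85); random mode draws columns from a
symmetric Dirichlet. `writeFixtureFasta()` pads each seed to a 22-mer
with uniform random flanks, seed at positions 2–7, so fixtures
exercise the full FASTA → extraction → fit pipeline. What the
simulator does **not** emulate about real miRNA data: unbalanced and
heavy-tailed family sizes, shared evolutionary history (duplicated
seeds differing at one position), species structure, and any signal
outside the seed window. Passing recovery tests therefore demonstrate
correctness of the estimator under its own model, not performance on a
real miRNA complement.

An intrinsic limit is worth stating plainly: with consensus strings at
pairwise Hamming distance 3 and match probability 0.85, components
overlap enough that even the Bayes-optimal classifier under the *true*
parameters mislabels a few percent of records (chance-adjusted label
agreement around 0.90–0.94 at k = 5). Recovered *parameters* are much
tighter than recovered *labels*: per-column total-variation distance
to the true PWMs is typically ~0.02 at N = 2000. Larger consensus
separations or match probabilities push label agreement toward 1.

## Numerical choices

* All likelihood arithmetic is in natural-log space; mixtures use
  log-sum-exp, so N up to 1e5 cannot underflow.
* Base order is fixed as (A, C, G, U) everywhere, including the model
  JSON (`base_order` field); consensus ties break A < C < G < U;
  argmax ties in assignment break to the lowest group index.
* Convergence: relative marginal log-likelihood change below 1e-8, cap
  500 iterations (the model records whether the cap was hit).
* A component with zero total responsibility and no pseudocount keeps
  its previous PWM and logs a warning (plain maximum-likelihood
  behavior; no reinjection).
* Model JSON is written with 17 significant digits, so
  write → read → write round trips are byte-identical.
* Group indices are 1-based inside R and 0-based in every written
  file; the conversion happens only at the I/O boundary. A
  `groupPrefix` display option renders 1-based labels such as `c10`.

## Problem sizes in the test suite

The suite validates ascent on 100 random instances (N in [50, 500],
k in 2–6), oracle equivalence of the log-space engine against plain
brute-force arithmetic on 200+ small instances, parameter recovery at
N = 2000 / k = 5 with 10 restarts, model-selection sanity over 20
trials at N = 200, and byte-level reproducibility of a full scan run
twice. These sizes were chosen so each property is tested at a scale
where its failure modes (underflow, label switching, local maxima) are
actually reachable while the whole suite stays quick to run.

## Known limitations

* Hard assignment discards the posterior's soft information; the
  responsibility matrix is exposed (and its maximum written per
  record) for users who want overlap-aware downstream analyses.
* The likelihood surface is multimodal; restarts mitigate but do not
  eliminate local maxima, so reported groupings at large k depend on
  the restart budget.
* Ambiguity codes (N, R, Y, …) have no slot in a 4-row PWM: records
  containing them are an error by default, or dropped with a warning
  via `skipAmbiguous` — never silently coerced.
* Species selection is an id-prefix whitelist, not a taxonomy.
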