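---
title: "Exact allele-age moments for absorbing Wright-Fisher chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact allele-age moments for absorbing Wright-Fisher chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wfage)
```

## The problem

The age of an allele — the number of generations a mutant has been
segregating since its founding mutation — is a basic quantity in population
genetics: a rare allele may be rare because it is deleterious or simply
because it is young, so inference about selection is confounded with age.
Classical treatments approximate the age of an allele observed at a given
population frequency with diffusion theory, which requires weak selection,
weak mutation and other simplifying assumptions. `wfage` instead computes the
moments of the allele-age distribution *exactly* (to machine precision) for
any finite absorbing Markov chain over allele copy number, instantiated here
for a biallelic diploid Wright-Fisher model with selection, dominance and
bidirectional recurrent mutation. This makes non-classical regimes — e.g.
population-scaled mutation rates $\theta = 4 N_e \mu$ approaching 1, as
reported for several bacteria and viruses — directly computable, where
classical theory is unreliable.

## Model

A population of $N_e$ diploids carries $i \in \{0, \dots, 2N_e\}$ copies of
a mutant allele; $0$ (extinction) and $2N_e$ (fixation) are absorbing. With
selection coefficient $s$ and dominance $h$, genotype fitnesses are $1$,
$1 + sh$, $1 + s$. One generation applies selection, then mutation (rates
$u$: wild-type $\to$ mutant, $v$: reverse), then binomial resampling: the
expected post-selection, post-mutation mutant frequency from frequency $q$
is

$$\psi(q) = \psi^*(q)\,(1 - v) + \bigl(1 - \psi^*(q)\bigr)\,u,\qquad
\psi^*(q) = \frac{(1+s)q^2 + (1+sh)q(1-q)}{(1+s)q^2 + 2(1+sh)q(1-q) + (1-q)^2},$$

and row $i$ of the transition matrix $P$ is
$\mathrm{Binomial}(2N_e, \psi(i/2N_e))$. The selection-then-mutation order is
a convention (the alternative order differs only at $O(uv)$); it is pinned by
the regression values the test suite asserts. Entries below a `cutoff`
(default $10^{-12}$) are dropped *without* renormalizing, leaving a per-row
deficit below $(2N_e + 1)\cdot\text{cutoff}$; this treats sub-machine-precision
entries as exact zeros and is what makes $Q$ sparse. The test suite verifies
that moving the cutoff from $10^{-12}$ to $10^{-14}$ leaves age moments
unchanged to at least six significant digits.

## Exact age moments

Let $Q$ be the transient-to-transient block of $P$. For an allele founded at
$p$ copies and observed at $x$ copies, the age $t$ has distribution

$$f_{p,x}(t) = \frac{Q^t_{p,x}}{[(I-Q)^{-1}]_{p,x}},$$

whose raw moments are matrix expressions, e.g.
$\mu_1 = [Q(I-Q)^{-2}]_{p,x} / [(I-Q)^{-1}]_{p,x}$ and
$\mu_2 = [Q(I+Q)(I-Q)^{-3}]_{p,x} / [(I-Q)^{-1}]_{p,x}$; in general $\mu_k$
involves the negative-order polylogarithm $\mathrm{Li}_{-k}(Q)$, whose
numerator polynomial has Eulerian-number coefficients
(`eulerian_coefficients()`). Age counts generations since the founding
mutation: $t = 0$ (observation in the founding generation) carries positive
probability when $p = x$.

Everything is computed from **one sparse LU factorization** of $(I-Q)^\top$:

1. solve $(I-Q)^\top M_1 = e_p$; then $M_1[x]$ is the normalizer and
   $M_1$ is the $p$-row of the fundamental matrix $N = (I-Q)^{-1}$;
2. iterate $(I-Q)^\top M_{k+1} = M_k$, so $M_{k+1}$ is the $p$-row of
   $(I-Q)^{-(k+1)}$;
3. dot $M_{k+1}$ with the $x$-th column of $Q\,A_k(Q)$, assembled by sparse
   matrix-*vector* products only (a Horner scheme on $e_x$).

No matrix-matrix product, matrix power or explicit inverse appears anywhere
in the solve path; the factorization is immutable and shared by every
downstream operation (moments, absorption, sojourn, reversed chain). Each
triangular solve is residual-checked at $10^{-8}$ in the max norm, scaled by
the right-hand-side magnitude (the iterated solves have RHS norms that grow
with each resolvent power), with one step of iterative refinement before a
hard failure.

Systems in the *untransposed* orientation $(I-Q)x = b$ — needed for the
absorption vectors $B = NR$ — are solved through the same factors: if
$(I-Q)^\top = P^\top L U Q_\pi$, then two triangular solves against
$U^\top, L^\top$ plus the permutations solve the transposed system. This
keeps the "factor once" design intact at zero extra cost.

## Absorption, conditional times and sojourns

From the same machinery the package reports classical absorbing-chain
summaries: absorption probabilities $B_{p,\cdot}$, the unconditional
expected absorption time $\sum_j N_{p,j}$, and endpoint-conditional
quantities such as
$\mathbb{E}[\text{time at } j \mid \text{extinction}] = N_{p,j} B_{j,\mathrm{ext}} / B_{p,\mathrm{ext}}$.
`sojourn_difference()` contrasts a selected against a neutral chain — the
lens through which the stochastic-slowdown phenomenon is visible: under
strong bidirectional mutation ($\theta$ near 1), weak selection *against* a
rare recessive allele lengthens its conditional extinction time, because
prolonged residency at low copy numbers outweighs the shortened residency at
high ones. A conditional time whose conditioning event has probability zero
is reported as `NA` and flagged, never as `NaN`.

When an absorption summary accompanies an observed allele, the conditional
times default to starting from the observed count $x$ (the state actually
known); starting from the founding count $p$ is available via
`absorption_start = "p"` in `age_sweep()`. The choice matters little for
rare observed alleles but is stated explicitly because either convention is
defensible.

## Founding copy number

Under strong recurrent mutation a mutation may plausibly enter the
population in several copies at once; `starting_copy_prior()` models the
founding count as $p \sim \mathrm{Poisson}(\lambda = \theta/2)$ conditioned
on $p \ge 1$ (a founding count of zero leaves no allele to observe — the
conditioning is this package's choice, and it makes the prior degenerate to
the conventional $p = 1$ as the inclusion threshold $\varepsilon \to 1$).
Counts with unconditioned Poisson probability below $\varepsilon$ (default
$10^{-5}$) are dropped and the weights renormalized. Because the LU
factorization does not depend on $p$, integrating over $p$ costs one start
vector instead of one solve per $p$. At $\theta \le 0.1$ the integrated and
single-copy means agree to better than $10^{-3}$ relative (asserted in the
tests).

## Reversed-chain simulation

As an independent Monte-Carlo check, `reversed_chain()` builds the
time-reversed chain
$Q'_{j,k} = Q_{k,j} N_{p,k} / N_{p,j}$, with a stop transition of
probability $1/N_{p,p}$ out of the founding state (the probability that the
current visit to $p$ is the founding one). A walk started at the observed
count $x$ and run until the stop transition draws from exactly the
allele-age distribution; `simulate_allele_ages()` runs the replicate loop in
compiled code, driven by R's RNG so that a seed fully determines the result.
States unreachable backward from the anchor ($N_{p,j} = 0$) are pruned
before normalization to avoid $0/0$. Per-row sampling tables renormalize the
retained transitions plus the stop probability over their sum, folding the
cutoff-induced deficit (below $(2N_e+1)\cdot 10^{-12}$ per row) back
proportionally. The replicate loop is deliberately serial: with a
single-stream RNG the determinism contract is trivial, and walk generation,
not parallel throughput, dominates runtime at the replicate counts used
here. Replicates exceeding `max_steps` (default $10^9$, a guard against
corrupted inputs rather than a practical limit) are flagged and reported,
never silently dropped.

## Neutral diffusion baseline

`kimura_ohta_age()` implements the classical neutral diffusion
approximation $\mathbb{E}[\text{age}] = -4 N_e \frac{q}{1-q}\ln q$ for an
allele observed at frequency $q$. It is an *independent* closed form used to
sanity-check the exact method: across the neutral comparisons in the test
suite the diffusion value exceeds the exact mean by a few generations
(under 5% relative), the known direction and size of the discretization
gap.

## A worked example

```{r example}
model <- wf_model(1000, theta = 0.01)        # neutral, symmetric mutation
ts <- transient_system(wf_transition_matrix(model))
f <- transient_factorization(ts)

allele_age_moments(ts, x = 10, p = 1, f = f)

rc <- reversed_chain(ts, p = 1, f = f)
simulate_allele_ages(rc, x = 10, replicates = 2e4, seed = 1)

kimura_ohta_age(1000, x = 10)
```

The exact mean (106.39 generations) sits a few generations below the
diffusion value (106.50); the simulated mean agrees with the exact one
within its Monte-Carlo standard error. The distribution is extremely
long-tailed (standard deviation near 390 for a mean near 106), which is why
the exact expectation is preferable to a maximum-likelihood point estimate
of age.

## Numerical choices and problem sizes

* **Cutoff** $10^{-12}$ balances sparsity against accuracy; rows are never
  renormalized, so conservation violations stay below
  $(2N_e+1)\cdot\text{cutoff}$ and are tracked, not hidden.
* **Binomial windows.** Each transition row is evaluated on a window of
  $\pm 9$ binomial standard deviations (plus a fixed margin) around its
  mean; mass outside the window is orders of magnitude below the cutoff.
* **Residual bound** $10^{-8}$ per solve, one refinement step, hard failure
  afterwards — errors surface instead of propagating.
* **Degenerate inputs.** An observed state unreachable from the start
  (normalizer zero) raises an explicit error; the full-distribution routine
  refuses state spaces above 2001 states and points to the moment routine.
* **Problem sizes.** The regression suite exercises dense oracles at
  $N_e \le 20$, full Wright-Fisher systems at $N_e$ = 1000-10,000, and
  Monte-Carlo checks at $10^5$ replicates; these sizes keep the whole suite
  within a few minutes on one CPU while covering the regimes (weak and
  strong mutation, selection of both signs, recessive through dominant)
  where the interesting phenomena live. The stochastic-slowdown critical
  point at $N_e = 10{,}000$ is a deliberately long computation (many
  LU factorizations of a $19{,}999$-state system) and ships as
  `scripts/extinction_time_maximum.R` rather than as a default test.

## What the synthetic conditions do and do not show

All inputs here are model-generated: the Wright-Fisher chain itself is the
object of study, so "synthetic data" means the transition systems built from
parameter values, and the Monte-Carlo walker provides the only
sampling-noise element. Passing tests therefore demonstrate correctness of
the computation under the stated model — constant population size,
equilibrium demography, a single biallelic locus, free recombination
(no linkage), and error-free observation of the population frequency. They
do not validate the Wright-Fisher model against real populations: sampling
error in observed frequencies, demographic change, and linked selection are
all outside the model class, and ages inferred for real variants inherit
those assumptions. The general `transient_system_from_matrices()` entry
point accepts any user-built absorbing chain (e.g. a Moran or
demography-modulated variant) in MatrixMarket form, but only the
Wright-Fisher instantiation is tested here.

## Limitations

* Runtime and memory are dominated by the sparse LU; Wright-Fisher systems
  beyond $N_e \approx 10^5$ states become expensive. Sparser models (Moran)
  would scale further but are not instantiated here.
* Higher moments are supported through $\mu_4$; the Eulerian-coefficient
  path documents the extension but the surface stops there.
* The full distribution (not just moments) is only feasible for small state
  spaces and is guarded accordingly.
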