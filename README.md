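# wfage

Exact allele-age moments, absorption analyses and reversed-chain simulation
for absorbing Wright-Fisher Markov chains.

## The problem

How old is an allele observed at a given population frequency? The question
matters because frequency confounds age with selection — an allele can be
rare because it is deleterious or because it is young. Classical answers use
diffusion approximations that assume weak selection and effectively zero
recurrent mutation. `wfage` computes the expectation, variance and higher
moments of the allele-age distribution **exactly** (to machine precision)
under a biallelic diploid Wright-Fisher model with selection coefficient
*s*, dominance *h*, and bidirectional mutation — including the
"non-classical" regime where the population-scaled mutation rate
θ = 4·Nₑ·μ approaches 1 — and, through a generic entry point, under any
finite absorbing Markov chain the user supplies.

## The method

Let *Q* be the transient block of the transition matrix. For an allele
founded at *p* copies and observed at *x* copies, the age *t* is distributed
as

    f(t) = Qᵗ[p, x] / N[p, x],      N = (I − Q)⁻¹

and its raw moments are matrix identities, e.g.

    μ₁ = [Q (I − Q)⁻²]_{p,x} / N[p,x]
    μ₂ = [Q (I + Q) (I − Q)⁻³]_{p,x} / N[p,x]

with the general *k*-th moment given by the negative-order polylogarithm
Li₋ₖ(Q), whose numerator polynomial has Eulerian-number coefficients. All of
it is evaluated from a **single sparse LU factorization** of (I − Q)ᵀ by
repeated triangular solves and sparse matrix–vector products — never a
matrix–matrix multiplication — which makes populations up to Nₑ ≈ 10⁵
copy-number states tractable on a workstation. The same factorization also
yields absorption probabilities, conditional extinction/fixation times and
endpoint-conditional sojourn times, a Poisson prior over the founding copy
number, and the time-reversed chain used for Monte-Carlo validation. The
Kimura–Ohta neutral diffusion age −4Nₑ (q/(1−q)) ln q is included as an
independent baseline.

## Worked example

```r
library(wfage)

model <- wf_model(1000, theta = 0.01)   # neutral, symmetric recurrent mutation
ts    <- transient_system(wf_transition_matrix(model))
f     <- transient_factorization(ts)

allele_age_moments(ts, x = 10, p = 1, f = f)
#> Allele age (generations): mean = 106.39352 , sd = 389.57381
#>   variance = 151767.76 , normalizer N[p, x] = 0.20590049

rc <- reversed_chain(ts, p = 1, f = f)
simulate_allele_ages(rc, x = 10, replicates = 20000, seed = 7)
#> Simulated allele ages: 20000 replicates (seed 7 )
#>   mean = 105.1778, sd = 373.3822, se = 2.6402 generations

kimura_ohta_age(1000, x = 10)
#> [1] 106.4988
```

Read: a neutral allele seen in 10 of 2000 chromosomes under θ = 0.01 has an
expected age of 106.39 generations with a very long tail (sd ≈ 390). The
reversed-chain simulation agrees within its Monte-Carlo standard error, and
the diffusion approximation overestimates the exact value by about a tenth
of a percent at this population size.

Sweeps over selection/dominance/mutation grids (`age_sweep()`), TSV/JSON
reports (`write_report()`), and a thin command-line front end
(`inst/cli/wfage.R`, subcommands `age`, `pmf`, `simulate`, `absorption`,
`sojourn`, `sweep`, `diffusion-age`) are provided for scripted use:

```sh
Rscript inst/cli/wfage.R age --Ne 1000 --theta 0.96 --two-Ne-s -3 --h 0 --x 10
```

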