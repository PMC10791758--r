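---
title: "Animal-model REML for dairy fertility traits"
author: "fertREML"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Animal-model REML for dairy fertility traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fertREML)
```

## The model

Fertility traits of dairy cattle — calving interval (CI), days open (DO),
calving to first insemination (CTFS), first insemination to conception
(FSTC), gestation length (GL), age at first service (AFS) and first calving
(AFC), number of services (NS) and the 56-day non-return rate (NRR) — are
lowly heritable and strongly shaped by herd management. The standard tool
for estimating their genetic parameters is the pedigree-based animal model

$$ y = Xb + \sum_i Z_i u_i + e $$

where $b$ collects composite fixed effects (region x birth year x birth
month, insemination-month and calving-age classes, calf sex, parity), and
the random terms are the additive genetic effect $a \sim N(0, A\sigma^2_a)$
for every animal in the pedigree, a herd-year effect
$HY \sim N(0, I\sigma^2_{hy})$, for GL and NRR a service-sire effect
$SS \sim N(0, A_{SS}\sigma^2_{ss})$ with $A_{SS}$ the relationship matrix
among the bulls used for insemination, and a residual
$e \sim N(0, I\sigma^2_e)$. Heritability is reported against the full
phenotypic variance,

$$ h^2 = \frac{\sigma^2_a}
        {\sigma^2_a + \sigma^2_{hy} + \sigma^2_{ss} + \sigma^2_e}, $$

with the service-sire term present only where it is fitted. Including the
herd-year variance in the denominator is deliberate: it is the convention
under which the published component tables for this trait family reproduce
their printed heritabilities exactly, and it treats the contemporary-group
variance as part of the phenotypic variance a breeder faces.

The same trait recorded before first calving (heifer) and after (cow) is
treated as two potentially distinct traits. A two-trait model with additive
covariance $G \otimes A$ (2x2 $G$), analogous herd-year, service-sire and
residual structures, estimates the genetic correlation
$r_g = G_{12}/\sqrt{G_{11}G_{22}}$ between the stages; $r_g$ near one
justifies pooling the stages into a single trait (`mergeTraits()`).

The binary non-return outcome and the count of services are analysed with
the *linear* model on the observed scale. For a non-extreme binary trait
the difference against threshold-model analysis is small, and linear
analysis keeps the machinery identical across traits; this is a known
trade-off, not an oversight.

## Pedigree machinery

`pedigree()` validates and topologically sorts animal/sire/dam triples
(ties broken by input order, so the result is reproducible), adds parents
seen only in the sire or dam column as founders, rejects cycles with the
offending chain, and enforces sex consistency. `inbreeding()` implements
the Meuwissen-Luo traversal of each animal's ancestor closure — $O(n)$
memory, no dense matrix. `aMatrix()` is the tabular recursion, guarded at
5,000 animals because the estimation path never needs dense $A$:
`aInverse()` assembles Henderson's sparse inverse with the inbreeding
(Quaas) adjustment, $d_i = 1/2 - (F_s + F_d)/4$ for two known parents,
$3/4 - F_p/4$ for one, 1 for none. Unknown parents are treated as
unrelated, non-inbred founders; no genetic groups are fitted (the source
population gives no grouping information). `subsetRelationship()` obtains
$A_{SS}$ by sparse solves against $A^{-1}$, so service-sire relationships
are always propagated through the complete pedigree.

## Data editing and trait derivation

The editing pipeline mirrors common practice for raw farm uploads, in the
fixed order merge/dedup, then trait derivation, then pedigree matching,
then outlier removal:

* `mergeDedup()` collapses byte-identical duplicate rows and drops *all*
  rows of a cow x parity key whose duplicates disagree (e.g. two birth
  dates for one identity) — with no way to tell which record is right, the
  identity is discarded.
* `deriveTraits()` computes the interval traits in integer days from the
  episode's dates (an episode runs from the previous calving — or from
  birth, for the heifer episode — to the calving it produces). FSTC may be
  exactly 0 (conception at first service); NS counts inseminations up to
  and including the conceiving one.
* `codeNRR()` codes 1 = no further insemination within 56 days. The window
  is anchored at the first insemination by default — that is what
  "non-return rate after first insemination" means in the trait's
  literature — with the previous calving available as an alternative
  anchor, because source descriptions of this trait are not always
  consistent about the anchor point. Both the window length and the anchor
  are arguments, not constants.
* `filterOutliers()` keeps $|y_i - \bar y| \le k\,s$ with $k = 4$ and the
  $n-1$ standard deviation, applied once, two-sided, per trait x stage.
  One-sided and iterated variants exist in the wild; single-pass two-sided
  was chosen because it is deterministic and order-free. A zero-variance
  vector is left untouched.
* `buildEffectClasses()` joins composite fixed-effect labels from their
  components. Calving-age classes are binned in whole months (30.4375
  days). Classes with fewer than 3 records are pooled into a per-effect
  "OTHER" level — without pooling, singleton classes make the fixed block
  rank-deficient; any residual aliasing across composite effects is
  removed by a pivoted QR on the design.

## REML estimation

`estimateReml()` maximises the restricted likelihood with a safeguarded
Newton iteration on the average-information (AI) matrix:

* The likelihood is evaluated through the sparse mixed-model equations
  (Matrix/CHOLMOD): $-2\ell_R = \log|R| + \log|G| + \log|C| + y'Py$ up to
  the REML constant, using the log-determinant of the Cholesky factor.
  The symbolic factorisation is computed once and reused, so an
  evaluation costs one numeric refactorisation and one solve. The dense
  covariance matrix $V$ is never formed in the estimation path; a dense
  implementation exists in the test suite as an independent oracle and
  agrees to 10 significant digits on small instances.
* The AI matrix is exact, via the working-vector identity
  $\mathrm{AI}_{ij} = \tfrac12 f_i' P f_j$ with $f_i = Z_i u_i/\sigma^2_i$
  and $f_e = \hat e/\sigma^2_e$; each $Pf$ is one extra MME solve.
  Gradients are forward finite differences of the sparse likelihood —
  analytic REML gradients need traces of inverse blocks of $C$, which
  would require a sparse-inverse-subset routine, and the finite-difference
  gradient is accurate to ~1e-7 relative at these problem sizes. For the
  same reason the classical EM-REML warm start is not used: its updates
  need the same traces. Robustness is provided instead by monotone
  step-halving (a step is only accepted if $-2\ell_R$ does not increase),
  a trust-region cap on the relative step length, and a steepest-descent
  fallback, so the iteration cannot diverge.
* Variance components are floored at $10^{-8}$ of the phenotypic variance
  and flagged (`floored:a`) instead of being allowed to go negative —
  the behaviour expected of mixed-model software in this field when a
  trait's additive variance is effectively zero.
* Start values are 10% of the phenotypic variance per random component.
  Convergence is declared at relative parameter change below `tol`
  (default 1e-8) or a change in $-2\ell_R$ below 1e-10; hitting the
  iteration cap flags the fit as non-converged.
* Standard errors are square roots of the inverse AI matrix; $h^2$ and its
  SE follow by the delta method. Fixed effects use intercept +
  drop-first-level coding; REML is invariant to that choice (verified in
  the tests by relabelling).

`estimateBivariateReml()` runs the same loop over the stacked two-trait
system. Each 2x2 block ($G$, $HY$, optional $SS$, $R$) is projected back to
positive semi-definiteness after every accepted step by eigenvalue
clipping at $10^{-8}$ of the geometric mean of its diagonal — near-unit
genetic correlations are boundary solutions, and clipping keeps the
iteration inside the parameter space without hiding the boundary (the
estimate is flagged `near-boundary-rg` when $|r_g| > 0.98$ or its SE
exceeds 1). The residual covariance is identified only by animals with
records at both stages; with fewer than 30 such animals it is fixed at 0
and flagged. Starting values default to the converged single-trait fits;
explicit starts can be supplied to skip those fits.

A caution on near-zero heritabilities: when both stages have $h^2$ of a
few thousandths, the admissible range of $G_{12}$
($\pm\sqrt{G_{11}G_{22}}$, a few $10^{-4}$ on the 0/1 scale) is far below
the sampling noise of any cross-stage covariance a feasible dataset can
measure, so with the residual covariance freely estimated the *sign* of
$r_g$ is not identified — replicate simulations land on either boundary,
and the restricted likelihoods of the two boundary solutions differ by
hundredths of a unit. The near-unit boundary estimate reported for such
traits arises under the conventional treatment of stage-sequential
records, residual covariance fixed at zero: an animal's heifer and cow
records are never contemporaneous, the within-animal cross-stage
covariance then has nowhere to go but the genetic term, and the fit is
driven to $r_g \approx 1$ with a standard error that honestly reports the
lack of information. The package supports both treatments (via
`minOverlap`); the batch validation runs use the fixed-at-zero protocol
and flag the boundary, which is exactly the behaviour a practitioner
should expect to see — and should interpret with the flags, not the point
estimate.

## What the simulator emulates — and what it does not

`simulatePedigree()` builds discrete generations with a configurable
number of heavily reused breeding males, reproducing the large paternal
half-sib families of AI dairy populations; inbreeding accumulates because
the population is closed. `simulateBreedingValues()` samples additive
values by the Mendelian recursion ($a_i$ = parent average + Mendelian
deviation with variance $\sigma^2_a(1/2 - (F_s+F_d)/4)$), which realises
$a \sim N(0, A\sigma^2_a)$ exactly in linear time; the test suite checks
its covariance against dense $A$ on small pedigrees.

Two phenotype generators serve different purposes. The model-based
generator (`simulateTraitDataset()`, `simulateBivariate()`) draws directly
from the fitted model and is used for parameter-recovery checks; its
defaults reproduce the variance magnitudes typical of the trait family
(AFC-like: $\sigma^2_a = 1137$, $\sigma^2_{hy} = 1300$, $\sigma^2_e =
3462$ days$^2$, $h^2 \approx 0.19$, 200 herd-years; near-zero CI-like
$h^2 \approx 0.012$; non-return-like components of a few $10^{-4}$ to
$10^{-1}$ on the 0/1 scale). The event-level generator
(`simulateEvents()`) places actual calendar dates: conception is decided
service by service from a Gaussian liability (so the binary non-return
outcome arises on the liability scale but is *analysed* linearly, exactly
as the real trait is), failed services repeat one 21-day oestrous cycle
later, gestation length carries its own genetic component, and duplicate
or corrupted rows are injected at configurable rates to exercise the
editing rules. Every interval value used to place dates is returned, so
`deriveTraits()` can be checked for *exact* reconstruction.

The simulator does not emulate culling and survival, seasonal heat-stress
trajectories, missing-not-at-random recording, or selection on the traits
themselves. Passing recovery tests therefore demonstrates correctness of
the estimation machinery under the stated model, not robustness to those
real-data features.

## Numerical choices and problem sizes

Tolerances and caps live in `remlOptions()`. The dense-A guard is 5,000
animals. Recovery checks in the test suite use one fixed pedigree design
(100 sires, 2,500 founder dams, 5,000 phenotyped females, 200 herd-years)
with phenotypes redrawn per replicate — 50 replicates for each single-trait
scenario and 20 for the bivariate scenario at 10,000 records, sizes chosen
so the full suite runs comfortably on a single CPU; the acceptance script
re-runs the same analyses at 10 and 5 replicates respectively. Bivariate
fits in these batch runs use fixed-fraction starts and `tol = 1e-5`, which
is ample for correlation estimates whose asymptotic SE is orders of
magnitude larger.

## Worked example

```{r example, eval = FALSE}
fx <- fixtureSmall()                        # deterministic 50-animal dataset
rec <- mergeDedup(fx$records)
ds <- deriveTraits(rec)
ped <- pruneToAncestors(fx$pedigree, unique(rec$cow_id))
ainv <- aInverse(ped)
gl <- matchPedigree(filterTraitOutliers(ds$GL.heifer), ped)
fit <- estimateReml(gl, defaultModelSpec("GL", "heifer"), ainv)
fit
```

## Known limitations

* Threshold-model REML for categorical traits is out of scope; NRR and NS
  are fitted linearly by design.
* No genetic groups for unknown parents; no genomic relationships; no
  models beyond two traits.
* The AI iteration reports but does not resolve flat-likelihood
  identifiability problems (e.g. a genetic correlation with SE in the
  units digit); the flags and the iteration trace are the diagnostic.
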