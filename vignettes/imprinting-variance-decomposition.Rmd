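---
title: "Variance decomposition, inbreeding and selection response at an imprinted locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance decomposition, inbreeding and selection response at an imprinted locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintQG)
```

## The model

A gene is imprinted when its expression depends on the sex of the parent it
was inherited from, so the two reciprocal heterozygotes at a diallelic locus
can have different mean phenotypes. `imprintQG` implements the standard
one-locus, two-allele quantitative-genetic treatment of this situation.
Genotypes are always *ordered* pairs, maternal allele written first; no
unordered genotype exists anywhere in the package, which prevents reciprocal
heterozygotes from ever being silently merged. On the trait scale used
throughout, the genotypic values are

| genotype | value |
|---|---|
| A1A1 | 0 |
| A2A1 (maternal A2) | $a(1+k_1)$ |
| A1A2 (paternal A2) | $a(1+k_2)$ |
| A2A2 | $2a$ |

with $k_1, k_2 \in [-1, 1]$. The boundary cases organise the biology:
$k_1=k_2=0$ is pure additivity, $k_1=k_2=k\neq 0$ ordinary dominance with
Mendelian expression, $k_1=-k_2$ imprinting without dominance (the
heterozygote *mean* sits at the midpoint), and $|k_1|=|k_2|=1$ with opposite
signs complete silencing of one parental copy. The scale is deliberately not
re-centred: A1A1 is pinned at 0 and A2A2 at $2a$.

With allele frequencies $p_1$, $p_2 = 1-p_1$ under random mating, the mean is
$\mu = a p_2 (2 + p_1(k_1+k_2))$ and the total genetic variance
$\sigma^2_G = p_1 p_2(\alpha_f^2 + \alpha_m^2 + a^2 p_1 p_2 (k_1+k_2)^2)$,
where $\alpha_f = a(1 + k_1 p_1 - k_2 p_2)$ and
$\alpha_m = a(1 + k_2 p_1 - k_1 p_2)$ are the female (maternal) and male
(paternal) average-effect composites. They obey
$\alpha_f - \alpha_m = a(k_1 - k_2)$ identically, one of the package's
standing test invariants.

## Five decomposition approaches

The interesting — and historically confusing — question is how to split
$\sigma^2_G$ into additive and dominance parts when imprinting is acting.
The package implements five constructions, labelled `A1`, `A2a`, `A2b`,
`A3a`, `A3b`:

* **A1** defines breeding values through offspring means derived from mating
  tables, separately for each parental sex.
* **A2a** assigns each allele an average effect conditional on its parental
  origin; reciprocal heterozygotes get different breeding values.
* **A2b** refines A2a with separate female and male (generation-aware)
  additive and dominance terms; its output is identical to A1, which the
  tests assert.
* **A3a** is a least-squares regression of genotypic value on the count of
  A2 alleles (one slope).
* **A3b** regresses on separate maternal-origin and paternal-origin A2
  indicators (two slopes).

All five agree on every output when $k_1 = k_2$ (tested as the "Mendelian
collapse" invariant) and always partition the same total variance. Under
imprinting they disagree: only the sex-specific pair A1/A2b recovers the
covariance between additive and dominance terms,
$\sigma_{AD_f} = a p_1 p_2 \alpha_f (k_2-k_1)$ and
$\sigma_{AD_m} = a p_1 p_2 \alpha_m (k_1-k_2)$, whose sum
$-a^2 p_1 p_2 (k_1-k_2)^2$ is never positive, although imprinting (unlike
inbreeding) can make one sex's covariance positive.

Two design choices deserve a note.

First, because the procedural definition of the offspring-mean approach is
a derivation rather than code, A1 is implemented **twice**: once from the
closed forms and once by exhaustive enumeration
(`oracle_breeding_values_A1()`, using the standard doubling convention,
breeding value = 2 × (mean offspring − $\mu$)); tests require the two routes
to agree to $10^{-12}$. Likewise the regression approaches are realised both
as closed forms and as explicit weighted `lm()` fits
(`regression_breeding_values()`), and the two must coincide. The design
matrices (allele count for A3a; two origin indicators for A3b) are our
reconstruction, validated against the closed-form tables.

Second, the full-sib and half-sib covariances for the pooled approaches
(`A2a`/`A3b` and `A3a`) are computed from the standard kinship identities
$\mathrm{cov}_{FS} = \tfrac12\sigma^2_A + \tfrac14\sigma^2_D$ and
$\mathrm{cov}_{HS} = \tfrac14\sigma^2_A$ applied to each approach's own
components. Some published tabulations of these rows interchange the
full-sib and half-sib columns (and garble a coefficient in the single-
regression row); the identity-based forms used here reproduce the standard
two-scenario numerical reference table cell for cell and agree with
exhaustive mating-table enumeration, so we treat them as the intended
values and do not reproduce the transposition.

## The enumeration oracle

Everything in `R/oracle.R` is deliberately *independent* of the closed
forms: it knows only genotype frequencies, Mendelian ½–½ segregation,
random mating and fitness weighting. `build_mating_table()` enumerates the
4×4×4 joint distribution of (mother, father, offspring);
`oracle_relative_covariances()` derives parent–offspring, full-sib and
half-sib covariances from it (half sibs share exactly one parent, the other
parent drawn independently; maternal half sibs share the mother, matching
the sex-split closed forms); `oracle_selection_response()` runs the exact
fitness-weighted one-generation recursion. The oracle's own correctness
rests on total-probability checks, fixation limits and Mendelian marginal
consistency, all asserted in the tests. Every closed form in the package is
required to match its oracle counterpart to $10^{-12}$ on a 1000-point
random parameter grid (`validate_identities()`).

## Inbreeding

Inbreeding is modelled exactly as the two-group mixture: proportion $1-f$
in Hardy–Weinberg proportions, proportion $f$ fully homozygous, with $f$
held stable across generations; no identity-by-descent recursion or mating
system is modelled, and the Monte Carlo sampler draws genotypes directly
from the mixture frequencies. Only the sex-specific (A2b) construction is
extended to $f>0$, because only it generalises: additive effects become
conditional means given the inherited allele
(`inbred_additive_effects()`), and the six components
(`inbred_variance_components()`) reduce exactly to the A1/2b values at
$f=0$. Under inbreeding the *dominance* variance becomes sex-specific —
a genuinely new feature relative to either force alone — and the AD
covariances pick up a strictly negative inbreeding contribution,
$-2a^2 f p_1 p_2 (1+f+k(1-f)(p_1-p_2))^2$ when $k_1=k_2=k$.

Without dominance ($k_1 = -k_2$) the total variance is linear in $f$; with
dominance it is quadratic — it is dominance, not imprinting, that controls
the shape. The worked selfing examples at $a=p_1=p_2=\tfrac12$,
$k_1=-k_2$: the total variance is 0.203125 (printed 0.20) at
$f=\tfrac12, k_1=\tfrac12$ and pinned at 0.25 for $k_1=1$ at every $f$;
0.18 at $f=\tfrac14$ and 0.23 at $f=\tfrac34$ for $k_1=\tfrac12$. All are
recomputed by `scripts/acceptance.R` and by the test suite. Covariances
between relatives are *not* provided for $f>0$: the mixture is a marginal
genotype model, not a mating system, so they are not derivable from it.

## Response to selection

Selection enters through the linear fitness function
$\varphi_{ij} = 1 + G_{ij} t$; the admissible range of $t$ is enforced as
all four $\varphi_{ij} > 0$, the weakest condition keeping relative
fitnesses meaningful. Mean fitness is $\bar\varphi = 1 + t\mu$. The exact
one-generation response is

$$\Delta\mu = \frac{t\,\gamma\,(\bar\varphi - \tfrac12 t \psi)}{\bar\varphi^2},
\qquad
\gamma = \tfrac12(\sigma^2_{A_f} + \sigma_{AD_f} + \sigma^2_{A_m} + \sigma_{AD_m}),
\qquad
\psi = a p_1 p_2 (k_1 + k_2),$$

identical for maternal and paternal accounting. A numerical subtlety: the
component sum $\sigma^2_D + \sigma_{AD_f} + \sigma_{AD_m}$ equals $\psi^2$,
not $\psi$; with $\psi^2$ in place of $\psi$ the formula does *not* match
the exact recursion, so the package defines $\psi$ as the signed linear
composite above, which agrees with enumeration to machine precision on the
random grid. The response depends on $k_1, k_2$ only through their sum:
replacing both by their average leaves $\Delta\mu$ unchanged (tested),
even though the sexes then transmit identically — offspring means of
unselected mothers and fathers still differ by
$\tfrac12 a p_1 p_2 t (k_2-k_1)(\alpha_f+\alpha_m)/\bar\varphi$.

The breeder's equation predicts $h^2 S = t\sigma^2_{A(1)}/\bar\varphi$ with
$\sigma^2_{A(1)} = \tfrac12(\sigma^2_{A_f}+\sigma^2_{A_m})$ (the
Approach-1/2b additive variance — the pooled approaches would give a
different, wrong, heritability). Exactly,

$$\text{prediction} - \text{truth} =
  \frac{t(\sigma^2_{A(1)} - \gamma)}{\bar\varphi} +
  \frac{t^2\,\gamma\,\psi}{2\bar\varphi^2},$$

whose first term is $\tfrac12 a^2 p_1 p_2 (k_1-k_2)^2 t/\bar\varphi \ge 0$
for $t>0$. Consequences, all tested: with imprinting and no dominance
($k_1=-k_2$) the ratio prediction/truth is exactly $1+k_1^2$ — double at
complete inactivation; with dominance and no imprinting the prediction
overshoots precisely when $a k t > 0$ (dominance aligned with the selected
direction) and undershoots otherwise, so no global inequality is asserted;
and with both forces and $|k_1-k_2|$ small the sign of the discrepancy can
flip. A published alternative that adds half an "imprinting variance" to
$h^2$ is left as a documented stub (`devries_prediction()`): that variance
has no computable definition within this model.

Multi-generation iteration (`iterate_selection()`) applies the
one-generation closed form repeatedly, re-deriving the components at the
updated allele frequency each step. The single step is the exact result;
iteration is offered as a convenience and is off (one generation) by
default.

## Monte Carlo sampler

`sample_population()` draws i.i.d. ordered genotypes from the (possibly
inbred) mixture frequencies — it emulates genotype sampling only, not
pedigrees, linkage, drift or environmental noise, so passing tests say
nothing about estimating these components from real, noisy, related data.
`empirical_components()` applies the A2b construction to the *empirical*
distribution (conditional-mean additive effects, residual dominance
deviations, weighted sample moments); on the exact distribution this is
exactly the closed forms, a tested identity. The reference Monte Carlo
check uses 20 replicates of $n = 10^6$ individuals under the
paternal-inactivation scenario and requires every component's replicate
mean to sit within four standard errors of the printed reference values;
with these sizes the standard errors are ≈$10^{-4}$, comfortably resolving
all five distinct component values while keeping the whole suite (≈4000
assertions, including the 1000-point identity grid) around twenty seconds.

## Numerical conventions and limitations

* All closed forms are evaluated in double precision; identity tests use
  an absolute tolerance of $10^{-12}$, golden-value tests half a unit in
  the last printed decimal.
* Printed reference values are reproduced with ties rounded away from zero
  (`render_table6()`), which is how the one exact tie (0.03125 → 0.0313)
  appears in the reference; raw doubles are available via `digits = NA`
  or the CLI's `--json`.
* `p1` ∈ {0, 1} is allowed with a warning (degenerate, zero variance);
  the regression construction additionally requires $0 < p_1 < 1$.
* Out of scope: multiple alleles or loci, maternal genetic effects,
  environmental variance, covariances between relatives under inbreeding,
  nonlinear or frequency-dependent fitness, mutation/migration/drift, and
  estimation from observed pedigrees (REML etc.).

## Session info

```{r}
sessionInfo()
```
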