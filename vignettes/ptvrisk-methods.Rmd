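---
title: "Methods: rare-variant case-control analysis and risk projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant case-control analysis and risk projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptvrisk)
```

`ptvrisk` covers the analytical chain of a rare-variant
susceptibility-gene study: variant classification and QC, discovery
ranking with gene-set enrichment, carrier-based case-control
association, a rare-missense admixture burden test, power calculation,
and projection of relative risks onto absolute cumulative-risk curves.
This vignette is the package's account of the underlying models, the
parameters that matter, and the choices made where the design was
genuinely open.

## Variant classification and calling

A variant is *protein-truncating* when its consequence is nonsense or
frameshift, or when it is a splice-site variant whose splice score
drops by more than 40% relative to the consensus score,
$(s_{\mathrm{ref}} - s_{\mathrm{var}})/|s_{\mathrm{ref}}| > 0.40$.
Classification uses annotation only and is deliberately orthogonal to
read evidence; splice scores are inputs (from a maximum-entropy splice
model or similar), never computed here. Two conventions needed fixing:

* a zero reference score makes the relative drop indeterminate; such
  variants return `NA` from `spliceDisruptive()` and are *excluded*
  from the deleterious set rather than guessed either way;
* for negative reference scores (weak sites) the denominator is
  $|s_{\mathrm{ref}}|$, keeping the "40% drop" interpretable; whether a
  signed denominator is ever preferable is left flagged rather than
  silently decided.

Two calling-rule profiles are provided. The *exome* profile requires
depth ≥ 40 reads, alternate allele ratio ≥ 30% and population MAF ≤ 5%.
The *targeted* profile is tiered: minimum coverage 15, with minimum
alternate-allele fractions of 30% (depth 15–30), 20% (30–250), 15%
(250–500) and 10% (≥ 500) — deeper coverage supports calling at lower
fractions. All thresholds are inclusive (`>=`), matching their
definitions; the alternate-allele fraction is `alt_reads/depth` at the
locus, and zero depth never calls. Sample-level QC fails a sample when
fewer than 80% of its target bases reach 15× (exactly 80% passes).

The recurrence filter feeding the discovery ranking removes variants
carried by more than 8 of 412 cases; for other cohort sizes the rule is
generalized to the equivalent fraction (count/n > 8/412 ≈ 0.5%
carrier frequency is excluded, the boundary retained). Open-reading-frame
placeholder genes are dropped from the ranking universe by the
case-insensitive symbol pattern `digits + "orf" + digits`; no curated
list is needed. Missense variants are *damaging* when more than one of
three predictors votes damaging (SIFT < 0.05 strict; PolyPhen-2
probably damaging/damaging; Provean ≤ −2.5 inclusive). When fewer than
two predictors are available the call is indeterminate and counted as
not damaging — conservative toward the null — and reported via a
warning.

## Discovery ranking and gene-set enrichment

Longer genes accumulate more truncating mutations for their length
alone, so genes are ranked by the *residual* of an ordinary
least-squares regression (with intercept) of mutation count on coding
length. An intercept is the standard choice; a through-origin variant
would change residuals only slightly and is noted as a sensitivity
item. Exact residual ties are broken lexicographically by symbol so the
ranking is total and reproducible; residuals within $10^{-8}$ (scaled
by the count magnitude) of zero are treated as exactly zero so that a
perfect fit yields a pure lexicographic order rather than floating-point
noise. If all lengths are identical the regression is degenerate: the
function warns and ranks on raw counts.

Enrichment uses the classic weighted Kolmogorov–Smirnov walk: members
increment the running sum by $|m|^p$ normalized over the set, non-members
decrement by $1/(N-|S|)$, and the enrichment score is the signed maximum
deviation from zero. The weight is $p = 1$ (the conventional default;
$p = 0$ reduces to the unweighted KS statistic). When the maximum and
minimum deviations tie in magnitude — which happens on exact symmetric
walks — the positive extreme wins, deterministically, with a $10^{-12}$
tolerance so that different but algebraically equivalent accumulation
orders agree.

The null distribution comes from random gene sets of the same size
drawn from the ranked universe: the standard surrogate for phenotype
permutation when only a pre-ranked list exists. The nominal p-value is
one-sided on the observed sign with the +1 correction,
$p = (1 + \#\{\text{same-sign null}, |ES_0| \ge |ES|\}) /
(1 + \#\{\text{same-sign null}\})$, so p is never zero; its attainable
floor is $1/(1+\#\text{same-sign})$, which is always at least
$1/(n_{\mathrm{perm}}+1)$. NES divides the observed ES by the mean
|ES| of same-sign null values. Within `gseaPreranked()` the null is
generated once per distinct set size and shared by all sets of that
size — the shared permutation machinery the FDR estimator assumes, with
the side benefit that duplicated sets get identical results under a
fixed seed. FDR is the sign-stratified observed-versus-null tail-ratio
estimator on the NES scale, clipped to [0, 1]. Set sizes are restricted
to 15–500 after intersection with the universe.

## Case-control association

The unit of analysis is the per-gene carrier 2×2 table, optionally
stratified by region. The crude odds ratio is the cross-product ratio;
when any cell is zero the Haldane–Anscombe 0.5 correction is applied to
all four cells before the estimate and its Wald interval (a whole
margin of zeros leaves the OR undefined and is an error). Both a Wald
and a Fisher exact p are always reported; Fisher is the headline
because the small carrier counts make the normal approximation the
weaker of the two. Frequencies are reported as percentages at two
decimals (round-half-even), odds ratios at one decimal, matching the
conventions of published tables.

The primary adjusted estimator is Mantel–Haenszel over strata with the
Robins–Breslow–Greenland variance: it is fully determined by the
counts, reduces *exactly* to the crude estimator for a single stratum,
and for rare carriers agrees closely with the logistic regression
(case status on carrier status plus stratum indicators) that is offered
as a method option. Positional clustering of mutations along the cDNA
is compared between cases and controls by a Wilcoxon rank-sum test,
exact for small untied samples. `reclassifyAndRefit()` recodes carriers
whose only qualifying variant is a named (typically recurrent) allele
and re-estimates, the standard probe for a low-penetrance recurrent
variant diluting a gene-level estimate.

## Rare-missense admixture burden test

Variants eligible for burden testing are missense with MAF ≤ 1%, call
rate > 80%, and Hardy–Weinberg exact p > 10⁻⁵ computed in *controls
only* (cases may deviate under association). The HWE test enumerates
the conditional distribution of heterozygote counts given allele
counts exactly.

The burden model is an admixture maximum likelihood: each variant is
risk-associated with probability $\pi$; associated variants share the
log odds ratio $\beta$ (either sign); the likelihood is
$\sum_v \ln[\pi L_v(\beta) + (1-\pi) L_v(0)]$ with $L_v$ the product of
case and control binomial likelihoods of carrier counts (dominant
coding — with sub-percent carrier frequencies homozygotes are
negligible). The per-variant nuisance control frequency is profiled out
in closed form: under a fixed odds ratio $\psi$, the constrained MLE of
the control frequency solves the quadratic
$N_0(\psi-1)f^2 + [N_1\psi + N_0 - m(\psi-1)]f - m = 0$ with
$m = a_v + c_v$, taking the root in the unit interval. For fixed
$\beta$ the mixture log-likelihood is concave in $\pi$, so $\pi$ is
profiled by a clamped Newton solve; the remaining one-dimensional
profile in $\beta$ — which can be bimodal, with risk and protective
modes — is scanned on a 33-point grid over $|\beta| \le 8$ and every
local grid maximum is refined by golden-section search. At $\pi = 0$
the likelihood equals the null exactly, so the LRT is non-negative by
construction.

Because the mixture LRT has a non-standard null distribution (the null
lies on the boundary and $\beta$ is unidentified at $\pi = 0$),
p-values come from case/control label permutation, never from an
asymptotic mixture-χ² approximation, with the +1 correction and a
floor of $1/(n_{\mathrm{perm}}+1)$. This is an admixture ML test in the
spirit of the rare-admixture family of burden tests — combining
information across variants and allowing effects of either sign — and
is documented as such, not as a reproduction of any specific published
likelihood. With very rare variants the mixture parameters are only
weakly identified at realistic sample sizes: $\hat\pi$ is biased
upward in finite samples (validated parameter-recovery settings show
the truth well inside the simulation spread, with $\hat\beta$ centred
close to the true log OR), which is why the *test* is calibrated by
permutation rather than by the fit's nominal curvature.

## Power

For control carrier frequency $p_0$ and odds ratio $r$, the case
frequency is the exact odds conversion
$p_1 = p_0 r / (1 - p_0 + p_0 r)$, and
$n = (z_{\alpha} + z_{1-\beta})^2\,[1/(p_0 q_0) + 1/(p_1 q_1)] /
(\ln r)^2$ per group, rounded *up* to the nearest 100 (reporting
granularity). The uncorrected Woolf-style log-OR variance and one-sided
$\alpha$ are the defaults: continuity-corrected and arcsine variants
differ by several percent, and no single textbook formula is canonical
here, so the choice is documented rather than hidden — `powerAtN()`
inverts the same approximation so the pair is self-consistent, and the
analytic power is validated against Fisher-test simulation to within
two percentage points at the sample sizes involved.

## Absolute-risk projection

Population incidence $\lambda_{\mathrm{pop}}(a)$ in age bands is an
*average* over carriers and non-carriers, so a carrier curve cannot be
obtained by multiplying population hazards by $r$ directly: that would
double-count the carriers already in the average. Instead the
non-carrier hazard is solved band-by-band from
$$\lambda_{\mathrm{pop}}(a) = \lambda_{nc}(a)\,
\frac{f S_c(a) r + (1-f) S_{nc}(a)}{f S_c(a) + (1-f) S_{nc}(a)},$$
updating the carrier and non-carrier survivor fractions sequentially
from age 0. The mixture of the resulting carrier and non-carrier
incidence curves, weighted by surviving carrier prevalence, reproduces
the input incidence identically (to ~10⁻¹⁶ per band; the tests assert
10⁻¹⁰). Cumulative risk is pure cumulative incidence,
$F_c(T) = 1 - \exp(-\sum_{a<T} r \lambda_{nc}(a) w_a)$ — no competing
mortality, a documented limitation (the flag structure reserves room
for a competing-hazard table). The relative risk is assumed
age-constant, as a single-OR analysis implies. Under a constant hazard
the implementation agrees with the closed form $1 - e^{-r\lambda T}$
to 10⁻¹².

Confidence bands propagate only the uncertainty in the log relative
risk: the band curves re-run the *entire* projection (including the
baseline solve) at $\exp(\theta \mp z_\gamma s)$. The 80% level is the
display default, following the convention that 80% limits are more
appropriate for clinical cumulative-risk communication; 95% is
available and nests the 80% band at every age. Uncertainty in the
incidence table itself is not propagated.

The polygenic/lifestyle modifier is log-normal with unit mean,
$m(q) = \exp(\sigma \Phi^{-1}(q) - \sigma^2/2)$ with
$\sigma^2 = \sigma_{pg}^2 + \sigma_{ls}^2$ — the standard log-additive
construction — and applies to carriers and non-carriers alike. The
population constraint is re-imposed by discretizing the modifier into
at least 32 (default 64) equal-mass quantile points and solving the
band-wise baseline over all carrier-status × modifier strata, so the
discretized population average reproduces the input incidence to well
under 10⁻⁶ relative error. $\sigma$ is supplied by configuration: the
per-allele effect sizes that would pin it down are not part of this
package's inputs. At $\sigma = 0$ the centile curve collapses onto the
average-carrier curve; at the median the multiplier is
$e^{-\sigma^2/2} < 1$, slightly below average, as the log-normal mean
constraint requires.

## The synthetic-data module

The generators define the validation conditions and are first-class,
tested code:

* **Cohorts** — `defaultCohortDesign()` is a 12-site, four-region
  case-control layout totalling 4,508 cases (3,017 high-grade serous)
  and 3,368 controls, with several case-only clinical-trial/registry
  sites and per-site age ranges; ages are uniform decoration with no
  effect on carrier status (carrier and non-carrier diagnosis ages are
  assumed equal). Per-site totals are reproduced exactly.
* **Carrier status** — controls carry with probability $f_0$; cases by
  the exact odds conversion per subtype. Dominant single-carrier model,
  independent across genes; a configurable fraction of carriers hold a
  designated recurrent allele at a fixed 3′ position, the rest private
  alleles at uniform cDNA positions.
* **Read evidence** — depth is negative-binomial (default mean 300,
  size 8 — overdispersed amplicon-style coverage); true heterozygotes
  draw a latent allele fraction from a normal centred at 0.5 (sd 0.05,
  truncated to [0, 1]), non-carriers sit at a 1% background error
  fraction; alternate reads are binomial at the latent fraction. No
  published read model exists for this assay class, so the spread is a
  free parameter chosen to make tier behaviour realistic (deep
  carriers essentially always called, background essentially never).
* **Gene universes** — log-normal coding lengths (median ≈ 1.5 kb),
  Poisson mutation counts with expectation
  $n_{\mathrm{cases}} \cdot \mu \cdot \mathrm{length} \cdot
  \mathrm{multiplier}$, the multiplier exceeding 1 only inside
  designated enriched sets ($\mu$ default $2 \times 10^{-6}$ per
  coding base per case, giving realistic per-gene counts for a
  412-case discovery series).
* **Incidence tables** — 5-year bands to age 80 with an
  age-increasing power-law shape (exponent 5, an ovarian-cancer-like
  steepness) scaled so the cumulative risk matches the target exactly
  (default 1.8%; the calibration identity $1-e^{-\sum \lambda w}$ is
  checked to 10⁻⁶).

What the generators do **not** emulate: linkage disequilibrium,
pedigree structure, sequencing-error haplotypes, somatic data,
population stratification beyond the region labels, and age effects on
penetrance within the cohort. Passing recovery tests therefore
demonstrates estimator correctness under the stated model, not
robustness to those real-data complications.

## Reproducibility, problem sizes and numerical conventions

Every random procedure takes an explicit integer seed and identical
seeds reproduce outputs byte-for-byte. cDNA coordinates are 1-based
inclusive; age bands are half-open $[lo, hi)$. The validation suite
runs at deliberately chosen sizes: burden type-I error over 500 null
genes of 5–20 variants at 1,500 cases/1,500 controls with 100
permutations each; burden parameter recovery over 100 replicates of 30
variants at 5,000/5,000; association CI coverage over 1,000 tables at
the full study margins; end-to-end odds-ratio recovery over 200
replicates of the complete 7,876-subject design; enrichment p-value
uniformity over 1,000 null sets in a 200-gene universe; exhaustive
brute-force ES checks over all subsets of size ≤ 4 in universes up to
12 genes. The pipeline orchestrator records package version, seeds and
per-file MD5 digests in a JSON manifest and validates its configuration
before any computation.

## Known limitations

* No competing mortality in risk projection; curves are interpretable
  as cumulative incidence in the absence of other causes of death.
* Band uncertainty covers the log-OR only, not incidence rates or the
  modifier variance.
* The admixture burden test shares one $\beta$ across associated
  variants; heterogeneous effect sizes within a gene are absorbed into
  the $\pi/\beta$ compromise.
* The Mantel–Haenszel default assumes stratum-common odds ratios;
  with strong effect heterogeneity across regions the logistic option
  (or stratified reporting) is preferable.
* Carrier calling treats observations independently; no joint
  genotype-likelihood model across samples is attempted.
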