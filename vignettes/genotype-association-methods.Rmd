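---
title: "Case-control SNP association from genotype counts: models and methods"
author: "genoCaseControl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-control SNP association from genotype counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genoCaseControl)
```

## The setting

A single-SNP case-control association study reduces, for each biallelic
variant, to a 2 x 3 contingency table: cases and controls tallied over the
three genotypes (major homozygote, heterozygote, minor homozygote).
`genoCaseControl` works directly on these exact counts — the
`GenotypeCounts` class — rather than on per-individual data, which keeps
every statistic reproducible from a published genotype table. Individuals
whose genotype could not be called (`nMissing`) are carried for display
denominators but excluded from every frequency and every model fit.

Three analyses are built on this container:

1. **Population comparison** — does the genotype distribution of a SNP
   differ between populations (e.g. between a national control panel and
   reference European subpopulations)?
2. **Inheritance-model association** — is the SNP associated with case
   status, and under which genetic model?
3. **MAF perturbation** — how fragile is a (non-)significant result to a
   small shift in the minor allele frequency of one group?

## Allele bookkeeping

The minor allele frequency of a tally with counts $(n_{AA}, n_{Aa},
n_{aa})$ is $q = (2 n_{aa} + n_{Aa}) / (2n)$ with $n$ the non-missing
total; the constructor relabels alleles whenever the allele marked minor
exceeds frequency 0.5, breaking exact ties alphabetically, so `maf()` is
always in $[0, 0.5]$. When two groups are paired (`CaseControlCounts`) or
several populations are read from one file, the major/minor assignment is
made on the *pooled* counts and held fixed for every group: this keeps the
regression coding consistent even when a group's internal frequency
crosses 0.5, at the price that a single group's label may then disagree
with its own internal minor allele. Counts are stored as integers and
frequencies are never rounded internally; the two-decimal values seen in
reports are applied at print time only.

`hweChisq()` is a 1-df Pearson test against the Hardy–Weinberg
expectations $p^2, 2pq, q^2$ computed from the sample allele frequencies.
It is a quality-control device (and a calibration check on the synthetic
generator); a monomorphic SNP returns the defined result (statistic 0,
$P = 1$) with a `monomorphic` flag rather than an error.

## Population comparison

`chisqGenotypeTest()` computes the Pearson statistic (optionally the
$G$-deviance) on the 2 x k genotype table, with k = 3 reduced only when a
genotype category is empty in *both* groups; no continuity correction is
used. A smallest-expected-cell value below 5 sets `flag_low_expected`
but deliberately does not switch to an exact test — the flag lets the
analyst decide, and the default behaviour matches how such comparisons
are usually reported. `pairwiseScan()` applies the test to every
unordered population pair, ordered deterministically (SNP, then
lexicographic pair). By default p values are unadjusted — the convention
of single-candidate-gene reports with a fixed $\alpha$ of 0.05 — and
`adjust = "holm"` or `"bonferroni"` (via `stats::p.adjust`) is available
when a familywise guarantee is wanted.

## Inheritance models

For genotypes coded against an effect allele $e$, the five classical
models enter the logistic regression
$\operatorname{logit} P(\text{case}) = \beta_0 + \beta^\top x(g)$ as:

| model        | $x(g)$                                                  | df |
|--------------|---------------------------------------------------------|----|
| additive     | dose of $e$: 0/1/2                                      | 1  |
| dominant     | carrier of $\ge 1$ copy of $e$                          | 1  |
| recessive    | homozygote for $e$                                      | 1  |
| overdominant | heterozygote                                            | 1  |
| codominant   | two indicators (het, major hom; minor hom as reference) | 2  |

The fit is maximum likelihood on the grouped counts
(Newton–Raphson/IRLS, zero start, log-likelihood tolerance $10^{-10}$,
cap 100 iterations — deterministic). The reported quantities follow the
conventions of the SNPStats family of tools: $\text{OR} = e^{\beta}$ with
a Wald 95% interval $e^{\beta \pm 1.96\,\mathrm{SE}}$ (SE from the
observed information), a likelihood-ratio $P$ against the intercept-only
model (not Wald, not Pearson — the distinction is visible in the third
decimal on small tables), and $\mathrm{AIC} = 2k - 2\ell$ with $k$
counting the intercept. The log-likelihood is the individual-level
Bernoulli form $\sum_g y_g \log p_g + (n_g - y_g)\log(1-p_g)$, so AIC is
comparable across models regardless of how categories collapse.

**Odds-ratio orientation.** Published tables are not consistent about
which group sits in the numerator. The package uses one rule throughout:
for single-column models the *reference* is the genotype group that does
not contain the major-allele homozygote, and the codominant reference is
the minor homozygote. Under this rule the overdominant OR is
homozygotes-vs-heterozygotes, the recessive OR (minor effect allele) is
$\{$major hom, het$\}$-vs-minor-hom, and every single-column OR equals
the cross-product ratio of the collapsed 2 x 2 table — which is also the
closed form the test suite checks against. The additive effect allele
defaults to the minor allele and is configurable (`effectAllele = "C"`
or `"major"`), and every report names the contrast explicitly, so no
reader has to guess the orientation.

A genotype group empty on one side makes the MLE odds ratio infinite
(or zero); the fit still converges in likelihood, the unbounded OR is
reported as `Inf`/`0` with a warning, and *no* continuity correction is
applied silently. Monomorphic inputs are flagged `degenerate` rather
than fitted. `selectModel()` picks the minimum-AIC converged model; ties
(within $10^{-8}$) go to the model with fewer parameters, then to the
fixed order additive, dominant, recessive, overdominant, codominant —
a deterministic rule, since symmetric tables genuinely tie.

## MAF perturbation

`perturbScan()` adds individuals of chosen genotype categories to the
*case* tally one at a time — the control tally is never touched — and
recomputes the case-control test at each step. The default test is the
genotypic Pearson chi-square on the 2 x 3 table, consistent with the
population-comparison module; `"allelic"` (2 x 2 on allele counts) and
`"lrt"` are alternatives, and the test identity is recorded in every
step row. Steps are enumerated lexicographically by (added minor
homozygotes, added heterozygotes, optionally added major homozygotes),
i.e. the heterozygote-only series first — the layout of published
perturbation tables. `minimalFlip()` returns the significant step with
the fewest added individuals (ties: fewest minor homozygotes, then
enumeration order); `mafDeltaReport()` tabulates the MAF change from
baseline, both exact and as the difference of the two-decimal printed
values, since "a 0.02 MAF change" in a report refers to the printed
precision.

The bundled demonstration pair (`mafSimFixture()`) couples the published
simulation case dataset (AA = 1, AG = 39, GG = 73; MAF 0.18) with a
**reconstructed** control dataset. The original control counts were
never published, so the package ships a 96-individual tally (AA = 1,
AG = 21, GG = 74) chosen by grid search such that the baseline genotypic
$P$ lies in $[0.12, 0.14]$ and the heterozygote-only series crosses
$\alpha = 0.05$ between five and six added individuals, reproducing the
qualitative trajectory of the published table. Its $P$ values are a
property of the reconstruction, not recovered data — only the MAF column
and the crossing behaviour are faithful. (The full two-axis grid flips
earlier via minor-homozygote additions, which move two alleles per
individual; the six-heterozygote statement concerns the het-only
series.)

## The synthetic generator

`genPopulationPanel()` draws, per population and SNP, an allele
frequency from the Balding–Nichols beta distribution with mean equal to
the ancestral MAF $m$ and shapes $m(1-F)/F$ and $(1-m)(1-F)/F$
($F$ = `fst`; $F = 0$ is a point mass, handled without division), then
multinomial genotypes under HWE. `genCaseControl()` places a logistic
disease model on the prospectively coded genotype (slope $\log$ OR,
intercept from the baseline prevalence in major homozygotes), inverts it
by Bayes' rule against the HWE genotype distribution, and samples cases
and controls multinomially from the resulting conditional distributions
— retrospective sampling without rejection loops, exact in expectation
and fast enough for thousands of replicates. Retrospective sampling
preserves the odds ratio, so the additive slope recovered from such
cohorts estimates the ground-truth $\log$ OR.

Defaults were fixed once to emulate the study conditions the package is
built around: a four-population panel of 96/99/91/107 individuals
(labels SLO/CEU/GBR/IBS), ancestral MAF 0.2, `fst = 0.01` (a typical
magnitude for intra-European differentiation), and a cohort of 153 cases
against 96 controls at baseline prevalence 0.1 with OR 1. Seeding is a
single integer from which each generator stage derives its own
substream, so identical configs give byte-identical TSVs and adding one
stage never shifts another's draws.

What the generator does *not* emulate: linkage disequilibrium between
SNPs (all SNPs independent), admixture or relatedness within a
population, genotyping error, and missingness mechanisms. Calibration
results obtained on it (type-I error of the additive LRT at
$0.05 \pm 0.01$, HWE rejection near 5%, rising pairwise rejection with
`fst`) therefore validate the statistical machinery, not the behaviour
of the methods on structured real cohorts.

## Numerical and design notes

* Fits start at $\beta = 0$ with step-halving, so results carry no
  dependence on initialization; all orderings (scan output, model order,
  population pairs) are fixed, making every artifact re-run
  bit-identical.
* Test sizes were chosen to keep the full suite under a minute on one
  core: 200–1000 random tables for the closed-form oracle checks, 2000
  replicates for type-I calibration at $n = 500 + 500$, 500 replicates
  at $n = 2000 + 2000$ for effect recovery, panels of 500–2000 SNPs for
  the HWE and differentiation checks.
* One published footnote defines the dominant model as "a single copy of
  the *frequent* variant"; the package uses the standard definition
  (≥ 1 copy of the effect allele) and treats the footnote wording as a
  typo for the rare variant.
* Published genotype *percentages* for case groups are not always exact
  quotients of the printed counts; `frequencyReport()` always computes
  exact percentages over all enrolled individuals (including
  undetermined genotypes), which reproduces the control-group
  percentages exactly.

## A worked example

```{r example}
cc <- pvrCohortCounts()[["rs1800629"]]
cc
res <- fitAllModels(cc)
res[, c("model", "contrast", "or", "ci_low", "ci_high", "p_value", "aic")]
selectModel(res)$model[1]
```

```{r perturb}
fx <- mafSimFixture()
scan <- perturbScan(fx$case, fx$control, maxAdded = 6, categories = "het")
round(scan[, c("added_het", "maf", "p_value")], 3)
attr(mafDeltaReport(scan), "minimal_flip")$maf_delta_2dp
```
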