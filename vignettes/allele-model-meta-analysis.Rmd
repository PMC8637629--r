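---
title: "Allele-model meta-analysis of genotype-count studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-model meta-analysis of genotype-count studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelemeta)
```

# The problem

Candidate-SNP case–control studies are usually published as genotype-count
tables: for a biallelic variant with reference allele C and effect allele
T, each arm reports how many individuals were CC, CT and TT. When several
such studies exist for the same variant — here, the *GAK* rs1564282
polymorphism and Parkinson's disease in Chinese populations — the natural
synthesis is an allele-model meta-analysis: collapse each study to a 2×2
table of T vs C allele counts in cases vs controls, estimate a per-study
odds ratio, and pool.

`allelemeta` implements that pipeline end to end on plain data frames, so
every intermediate quantity is inspectable and pipeable.

# The model

## Per-study effects

Under the additive (allele) model an arm with genotype counts
$(n_{CC}, n_{CT}, n_{TT})$ contributes $a = n_{CT} + 2 n_{TT}$ effect
alleles and $b = 2 n_{CC} + n_{CT}$ reference alleles. For the 2×2 table
with case alleles $(a, b)$ and control alleles $(c, d)$,

$$\widehat{OR} = \frac{ad}{bc}, \qquad
  \mathrm{SE}(\log \widehat{OR}) = \sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d},$$

the Woolf standard error. Treating the two alleles of one individual as
independent is itself an assumption — it holds exactly when genotypes are
in Hardy–Weinberg proportions, which is why the HWE screen accompanies the
model.

A zero cell makes the log OR infinite; `study_effects()` therefore applies
the Haldane–Anscombe continuity correction (add 0.5 to **all four** cells
of that study, flagging it in the `corrected` column) — but only when a
zero occurs, so tables without zeros (including the bundled dataset) are
untouched. `correction = "none"` turns the correction into an error
instead, for workflows that must not silently modify counts.

## Hardy–Weinberg screen

With estimated effect-allele frequency $\hat q = (n_{CT} + 2n_{TT})/2n$,
expected genotype counts are $n(1-\hat q)^2$, $2n\hat q(1-\hat q)$,
$n\hat q^2$. The default test is the Pearson goodness-of-fit $\chi^2$ on
the three classes with **1** degree of freedom (three classes, minus one
for the total, minus one estimated parameter), no continuity correction;
classes with zero expectation (monomorphic arms) contribute nothing. The
screen runs on control arms because deviation there suggests genotyping
error or population substructure; cases may legitimately deviate when the
variant is causal. Failing studies are *flagged with a warning, never
dropped* — exclusion is an analyst's decision, and published per-study HWE
p-values are often produced by heterogeneous tests in the source
publications, so they are treated as annotations rather than quantities
this package should reproduce. For small arms the asymptotic test is
anti-conservative, so `method = "exact"` provides the conditional exact
test (enumeration of heterozygote counts given the allele counts, summing
outcomes no more likely than the observed one).

## Heterogeneity and model choice

With inverse-variance weights $w_i = 1/se_i^2$ and the fixed-effect pooled
log OR $\hat\theta$, Cochran's
$Q = \sum_i w_i(\theta_i - \hat\theta)^2 \sim \chi^2_{k-1}$ under
homogeneity. The descriptive companion is
$I^2 = \max\{0, (Q - (k-1))/Q\} \times 100\%$, and the DerSimonian–Laird
between-study variance is
$\hat\tau^2 = \max\{0, (Q - (k-1)) / (\sum w_i - \sum w_i^2 / \sum w_i)\}$.
Both are floored at zero, so whenever $Q \le k-1$ the random-effects model
collapses exactly onto the fixed-effect one.

`select_model()` chooses random effects only when the Q-test p-value is
below 0.1 **and** $I^2 > 50\%$ — a deliberate conjunction: Q is
underpowered at small $k$ (hence the lenient 0.1), while $I^2$ guards
against declaring heterogeneity from a barely-significant Q with trivial
inconsistency. Otherwise pooling is fixed-effect with weights $1/se_i^2$;
random-effects pooling replaces them with $1/(se_i^2 + \hat\tau^2)$. The
pooled estimate is tested with a two-sided Z test at $\alpha = 0.05$.

Pooling is inverse-variance on the log-OR scale rather than
Mantel–Haenszel: Q, $I^2$, $\tau^2$ and the Z test are all defined on
inverse-variance weights, so the estimator and its diagnostics stay
internally consistent. A Mantel–Haenszel estimator with
Robins–Breslow–Greenland variance is exported (`or_mantel_haenszel()`) as
an independent cross-check; on the bundled data both round to 1.28.

## Sensitivity and publication bias

`leave_one_out()` omits each study in turn and re-runs the *entire*
downstream pipeline — including the fixed/random selection rule — on the
remaining $k-1$ studies. Re-selecting the model inside each subset, rather
than freezing the full-data choice, is the conservative reading: a single
study can be the sole source of heterogeneity, and freezing would hide
that.

`egger_test()` uses the classic precision form of Egger's regression:
unweighted OLS of the standardized effect $z_i = \theta_i / se_i$ on the
precision $x_i = 1/se_i$, with a two-sided t test of the intercept on
$k-2$ df. This is the canonical variant when a publication does not say
which it used; the weighted variant (`variant = "weighted"`) is available.
The intercept, not the slope, carries the small-study signal: under no
bias $z_i = \theta x_i$ passes through the origin. The bias call defaults
to the stringent $\alpha = 0.01$, appropriate for a test with known size
distortion at small $k$. `funnel_points()` emits the plot-ready
coordinates (effect vs SE of log OR, y inverted) plus the pseudo-95%
boundary $\hat\theta \pm 1.959964\, se$ over an SE grid.

# Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `alpha` (CI / Z test) | 0.05 | two-sided level | conventional; z quantile hard-coded to 1.959964 at this level for cross-platform reproducibility |
| `hwe_threshold` | 0.001 | p-value | screens only gross genotyping failure; ordinary sampling noise in small controls should not flag |
| `q_p_threshold` | 0.1 | p-value | lenient because Q is underpowered at small k |
| `i2_threshold` | 50 | percent | the usual boundary between moderate and substantial inconsistency |
| `egger_alpha` | 0.01 | p-value | stringent because the intercept test over-rejects at small k |
| `correction` | add 0.5 iff a zero cell | counts | keeps the pipeline total on sparse data without perturbing complete tables |

# The simulator

`simulate_studies()` draws, for each study, control genotypes
multinomially from HWE proportions at frequency $q$, and case genotypes
from the tilted distribution $p_g \propto \mathrm{HWE}_g(q)\,\psi^g$,
$g \in \{0,1,2\}$ — the additive odds model, under which the allele-level
case–control OR converges to $\psi$ as arms grow. The tilt is sampled as a
closed-form multinomial rather than by rejection sampling: exact, fast,
and it makes $\psi$ the true allele-level odds parameter in the large-$n$
limit. Between-study heterogeneity enters only through
$\log\psi_i \sim N(\log\psi, \tau^2)$, not through $q$ — the simplest
generative model matching the DerSimonian–Laird framework under test. Each
study draws from its own substream seeded deterministically from
`(seed, study index)`, so study $i$ is identical whether it is simulated
alone or as part of a larger table, and identical `(config, seed)` pairs
are byte-reproducible.

What the simulator does *not* emulate: linkage disequilibrium, covariates,
population stratification, genotyping error, or selective publication.
Passing calibration tests therefore certify the statistical machinery —
test size, CI coverage, parameter recovery under the stated generative
model — not robustness of real meta-analyses to those confounders.

# Numerical choices and degenerate inputs

- All pooling arithmetic is on the log-OR scale; exponentiation happens
  only at the reporting boundary, so `or` always equals `exp(log_or)`
  exactly.
- $I^2$ and $\tau^2$ are floored at zero, and $Q = 0$ (all studies
  identical) yields $I^2 = 0$ rather than 0/0.
- A single study is poolable (`pool_effects` returns it unchanged);
  heterogeneity needs $k \ge 2$, Egger and leave-one-out need $k \ge 3$
  ($k-2$ df must be positive, and each reduced set must still support a
  heterogeneity assessment). The pipeline runs on $k < 3$ and marks those
  blocks as absent.
- A whole arm with zero alleles is an error, not a correction candidate.
- Egger's regression refuses exactly degenerate inputs (all precisions and
  effects identical) rather than returning an arbitrary fit.
- Reported tables round OR/CI to 2 decimals, $I^2$ to integer percent and
  p-values to 2 significant figures; `report.json` keeps full precision,
  and p-values below 1e-15 are shown as "< 1e-15" in text only.

# The bundled dataset

The packaged table transcribes the genotype counts of the seven published
rs1564282 case–control studies (Tang 2012, Li 2011, Chen 2013, Lin 2013,
the two Tseng 2013 arms, Yu 2015). One source publication's narrative
reports Yu 2015 as 534 cases / 435 controls, while its genotype counts sum
to 529 / 421; the bundled table follows the genotype cells, which are
internally consistent and reproduce the collection-wide totals of 4,055
cases and 3,826 controls. Population labels are metadata only — nothing
computes on them.

```{r}
meta_analysis("bundled")
```

# What the tests establish

The test suite pins the bundled analysis (pooled OR 1.28, 95% CI
1.16–1.42, fixed-effect pathway, all control arms in HWE at 0.001, every
leave-one-out CI excluding 1, non-significant Egger intercept) and
validates the machinery against independent brute-force recomputation to
1e-9 on randomized tables, against `metafor` where available, and against
the simulator: type-I error of the pooled Z test within exact binomial
99% bounds of 0.05 over 1000 null replicates at the bundled studies' arm
sizes, recovery of $\psi = 1.3$ by the pooled OR over 200 replicates of
seven studies with 20,000 per arm, and approximate nominal size of the
Egger test over 1000 no-bias replicates of ten studies. Those problem
sizes keep the full suite to a couple of minutes while leaving Monte Carlo
error well inside the asserted bands.

# Known limitations

- Only the additive allele model is implemented; dominant, recessive and
  genotypic contrasts would need new effect constructors (the study-table
  schema already carries everything they need).
- The allele-level 2×2 treats alleles within an individual as independent;
  under strong HWE deviation the Woolf SE is misstated.
- No meta-regression, subgroup analysis, Hartung–Knapp adjustment,
  trim-and-fill or Begg test.
- The DerSimonian–Laird $\tau^2$ is the classical moment estimator; REML
  alternatives are out of scope.
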