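---
title: "Predicting the relative accuracy of polygenic scores across ancestries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the relative accuracy of polygenic scores across ancestries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

A polygenic score (PGS) built from genome-wide significant (GWS) SNPs of
a discovery GWAS loses predictive accuracy when transferred to a target
sample of different ancestry, even when the causal variants and their
effects are shared. The loss is driven by between-population differences
in (i) linkage disequilibrium (LD) between GWS SNPs and the causal
variants they tag, (ii) allele frequencies at both, (iii) causal effect
sizes (cross-ancestry effect correlation $\rho_b$), and (iv) trait
heritability. `pgsra` implements a deterministic model of the *relative
accuracy*

$$\mathrm{RA} = R_2^2 / R_1^2,$$

the ratio of the squared score-trait correlation in the target ancestry
(population 2) over that in an independent sample of the discovery
ancestry (population 1). Modelling the ratio rather than either $R^2$
sidesteps the need to know the number of causal variants, which cancels.

## The model

Let $p_{k,l}$ be the frequency of the counted (minor) allele of the
$k$-th PGS SNP in population $l$, $\hat\beta_k$ its estimated effect in
the discovery GWAS, and $r_{jk,l}$ the signed genotype correlation
between causal variant $j$ and PGS SNP $k$ in population $l$. With $M_T$
quasi-independent GWS SNPs the model is

$$
\mathrm{RA} \;\approx\; \frac{\rho_b^2\,h_2^2}{h_1^2}
\times\left(
\frac{\sum_k \sqrt{\tfrac{p_{k,2}(1-p_{k,2})}{p_{k,1}(1-p_{k,1})}}\,
      \sum_j r_{jk,1} r_{jk,2}}
     {\sum_k \sum_j r_{jk,1}^2}
\right)^2
\times \frac{\mathrm{var}(\mathrm{PGS}_1)}{\mathrm{var}(\mathrm{PGS}_2)},
$$

a product of three interpretable terms — effect-correlation and
heritability; LD and MAF; and the PGS-variance ratio, for which we use
the closed form $\sum_k p_{k,l}(1-p_{k,l})\hat\beta_k^2$ so that
predictions require only summary statistics and reference panels.
`predict_relative_accuracy()` returns the product and the three factors
(`term_effect`, `term_ldmaf`, `term_varpgs`); the `autoplot()` method
draws them.

Three estimators of the middle term are provided:

* **known** — the sums over $j$ run over the true causal variants
  within 100 kb of each PGS SNP (simulation mode; the window mirrors
  fine-mapping evidence that causal variants lie within 100 kb of the
  lead SNP ~90% of the time).
* **heuristic** — causal variants are unknown; each PGS SNP's
  candidates are the reference variants within 100 kb whose LD
  $r^2 > 0.45$ with it in the discovery-ancestry panel, and the sums
  are replaced by per-SNP *means* over candidates. A SNP with no
  qualifying neighbour falls back to itself ($r = 1$).
* **naive** — the PGS SNPs are treated as the causal variants
  ($r_{jk,l} = 1$), leaving only the heterozygosity ratio; this ignores
  LD decay in the target population and overestimates RA, increasingly
  so with genetic distance.

A deliberate design choice: in known mode we keep the per-SNP *sums*
(the closed form above), while heuristic mode uses per-SNP *means* as
the candidate-set estimator. The two coincide whenever every PGS SNP
has the same number of pairs (the count cancels in the ratio), which is
also the regime in which the mode-equivalence test operates.

When per-SNP sums and means are taken over the same pair sets in the
identification panel (discovery ancestry) and the target panel, the
candidate map is the bridge: `find_candidate_causals()` identifies
pairs by discovery LD — GWS SNPs arise from discovery LD, so candidacy
is defined there — and then measures $r_{jk,2}$ for the identified
pairs in the target panel.

When target phenotype data are unavailable, $\rho_b$, $h_1^2$ and
$h_2^2$ default to 1 and the prediction quantifies only the fraction of
RA attributable to LD and MAF differences. The loss of accuracy is
$\mathrm{LOA} = (1-\mathrm{RA})\times 100\%$, and
`loa_explained()` reports the proportion of observed LOA explained by
the LD+MAF prediction, $100\% \times (1-\mathrm{RA_{pred}})/(1-\mathrm{RA_{obs}})$.

## Empirical side

`run_gwas()` fits per-variant simple linear regression (slope, SE,
two-sided p from the $t$ distribution with $n-2$ df — at GWAS sample
sizes the normal approximation is indistinguishable, but the choice is
fixed for reproducibility). `clump()` is greedy PLINK-style clumping
with defaults p1 = p2 = 5e-8, 2000 kb, $r^2 \le 0.01$; ties on p-value
break by (chromosome, bp), making the output invariant to row order.
`score_pgs()` sums counted-allele dosages times $\hat\beta$, aligning
allele codings and mean-imputing missing genotypes as $2p$.
`observed_r2()` is the squared Pearson correlation; `liability_r2()`
applies the Lee transformation with prevalence $K$ and case fraction
$P$ (for a population-based cohort $P=K$ and the factor reduces to
$K(1-K)/z^2$). `relative_accuracy()` attaches a nonparametric bootstrap
SE (default 1,000 resamples of individuals in each cohort,
independently); averages across scenarios use leave-one-out jackknife.
The bootstrap replaces an analytic SE derivation that is not available
to us; a delta-method cross-check on simulated data agrees within ~20%.

## The synthetic two-population study

The validation machinery needs genotypes with realistic structure but
no external data. `simulate_two_populations()` uses a two-stage
block-mosaic model:

1. **Ancestral pool.** Each of `n_blocks` blocks carries a pool of
   `pool_size` (default 20) ancestral haplotypes whose alleles follow a
   first-order Markov chain along variants (adjacent correlation
   `pool_step_r`, default 0.97). The ancestral frequency is drawn per
   block (uniform on `ancestral_maf_range`, default 0.05–0.5);
   variant-level MAF spread arises from finite-pool sampling and drift.
2. **Populations.** Each population gets (a) its own block haplotype
   weights by Balding–Nichols (Dirichlet) drift with parameter
   calibrated to `target_fst`, and (b) its own mosaic switch rate:
   individual haplotypes are mosaics of pool haplotypes with per-step
   switch probability `switch_rate` (default 0.06) in population 1 and
   `switch_rate * (1 + ld_divergence * target_fst)` in population 2.

Both MAF and LD divergence are therefore controlled by the single
`target_fst` knob and vanish together at `target_fst = 0`, which is
what makes the identical-populations check (`RA = 1`) meaningful. LD is
parameterised per variant *step*, so physical positions only affect
windowing — rescaling coordinates does not change genotypes.

The LD defaults were anchored to descriptive features of common-SNP
panels in human data, not to any downstream test quantity: mean
adjacent-variant $r^2 \approx 0.85$ at ~5 kb spacing decaying to
$\approx 0.2$ by 50 kb and near zero past 150 kb; a target/discovery
LD-decay-rate ratio of ~2 at $F_{ST} = 0.14$ (the African/European
contrast), giving `ld_divergence = 7`; and a drift calibration factor
of 1.02 compensating the slight attenuation of realized $F_{ST}$ by the
per-population MAF floor (0.01, mirroring the common-variant filter).
Because drift acts on block weights, realized $F_{ST}$ has block-level
granularity: tight at the default 100 blocks, coarse in small toy
configurations.

Causal effects follow the negative-selection architecture
$\mathrm{var}(\beta_{jl}) = \sigma_l^2\,[2p_{jl}(1-p_{jl})]^{S_l}$ with
$\sigma_l^2$ normalised so the expected explained variance is $h_l^2$;
$S = -1$ (default) makes every causal variant explain equal variance
and recovers $\mathrm{var}(\beta) = h^2/(2p(1-p)M_C)$. Pairs
$(\beta_{j1}, \beta_{j2})$ are bivariate normal with correlation
$\rho_b$; at $\rho_b = 1$ with equal $S$, $\beta_2$ is an exact
deterministic rescaling of $\beta_1$ — the reading we adopt of a
per-population variance statement that is only self-consistent under
rescaling. Phenotypes are $y = g + e$, $e \sim N(0, 1-h^2)$, so
$\mathrm{var}(y) \approx 1$.

`run_scenario()` wires the whole study per replicate: simulate
discovery, validation (independent same-ancestry draw) and target
cohorts; draw effects and phenotypes; GWAS with causal variants
excluded (so GWS SNPs are imperfect taggers, as in real data); clump;
score; observed RA = $R^2_{target}/R^2_{validation}$; and the three
predictions with the discovery cohort as population-1 reference and
the target cohort as population-2 reference. Replicate seeds are
`seed + replicate - 1`; within a replicate, cohort phenotype seeds are
drawn from the seeded stream itself (nearby integer seeds give
correlated Mersenne–Twister streams, which would couple GWAS noise to
target noise and bias RA upward — we found and removed exactly this
artefact). `run_grid()` shares the genotype layer across trait
architectures that differ only in $h^2$, $M_C$ or $\rho_b$, since
panels depend only on the replicate seed.

```{r example}
library(pgsra)

cfg <- sim_config(seed = 1)           # the default study conditions
records <- run_scenario(cfg, n_replicates = 30)
summarize_bias(records)
plot_ra_replicates(records)
```

## Validation design and problem sizes

The full-scale synthetic study uses 10,000 variants in 100 blocks of
500 kb, a 10,000-sample discovery cohort, 2,000-sample validation and
target cohorts, $M_C = 200$ causal variants, $h^2 = 0.5$ and target
$F_{ST} = 0.10$, with 30 replicates — sizes chosen so each causal
variant has an association NCP near 25, yielding tens of GWS SNPs per
replicate and stable RA estimates within minutes on one CPU. The
scenario grid crosses $h^2 \in \{0.25, 0.5\}$ with
$M_C \in \{100, 200, 500\}$; note that at this discovery size the
weakest cells (per-causal NCP below ~10) find almost no GWS SNPs, which
is the expected behaviour of the thresholded design, and such
replicates are flagged (`m_t = 0`) and excluded from bias summaries.
Reduced configurations (2,000 variants, 4,000/1,000/1,000 samples,
$M_C = 50$) drive the property checks: RA = 1 for identical
populations; multiplicative recovery of $\rho_b^2 h_2^2/h_1^2$;
monotone decay of observed RA across $F_{ST} \in \{0.02, 0.06, 0.14\}$;
naive $\ge$ heuristic at $F_{ST} > 0$; and independence of RA from
discovery sample size.

## What the generator does and does not emulate

It does emulate: blocky LD decaying with distance; population-specific
LD; diverged MAF spectra with a common-variant floor; selection-aware
effect architectures; shared causal variants with correlated effects.
It does not emulate: admixture, rare variants, variable recombination
within blocks, genuine coalescent haplotype sharing, or a reference
panel denser than the GWAS panel. The last point matters for the
candidate heuristic: with candidates drawn from the study panel itself
(5 kb spacing), the index SNP tags its causal variant very tightly
(median 1–2 steps) while $r^2 > 0.45$ candidates spread over ~5 steps,
so the candidate mean over-weights pairs that decay faster in the
target population and the heuristic *underestimates* RA by roughly
5–11% (relative) at $F_{ST} = 0.10$ under the default conditions — a
conservative bias, consistent in direction with dense-panel results but
somewhat larger in magnitude. Passing property tests on this generator
therefore support the internal consistency of the theory and pipeline;
they do not by themselves establish accuracy margins on real human LD.

## Numerical conventions

* Windows are closed intervals in bp; positions 1-based.
* The counted allele is the minor allele in the discovery panel; all
  panels are aligned to that orientation, and every statistic is
  invariant (or equivariant, for signed LD) under allele-coding flips.
* Hudson's $F_{ST}$ uses the ratio-of-averages form with finite-sample
  correction based on allele counts; which estimator the original
  analysis used is not stated, so this standard, nearly unbiased
  two-population choice is fixed here and results at other estimators
  may differ by their usual small offsets.
* LD is genotype (unphased) correlation with pairwise-complete
  observations; frequencies use all non-missing genotypes.
* Monomorphic variants: skipped with a warning in GWAS; an error in
  pairwise LD; excluded from $F_{ST}$ when unusable.
* `liability_r2` applies the general Lee formula; `P = K` is the
  population-based special case.
* Known-mode fallback when no causal variant lies within the window:
  the PGS SNP itself, keeping the estimator defined at the cost of a
  small upward pull toward the naive value (warned about).
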