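---
title: "Screening for variants with opposite effects on cancer and autoimmune disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for variants with opposite effects on cancer and autoimmune disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(pleioscan)
```

## The problem

Germline alleles near some immune-checkpoint genes raise the risk of
autoimmune or autoinflammatory disease while *lowering* the risk of
cancer — the antagonistic-pleiotropy pattern seen at *CTLA4* and the
CD200 axis. Such variants are interesting because the biology that makes
an allele autoimmune-promoting (a stronger immune response) is the same
biology one wants to recruit against a tumor, so the genes they point at
are candidate immunotherapy targets.

`pleioscan` implements a screen for this pattern over pairs of GWAS
summary-statistic tables — one cancer trait, one autoimmune trait — and
the downstream target-nomination steps: LD clumping of the combined
signal into lead SNPs, nearest-gene mapping, immune gene-list and
pathway-enrichment annotation, correlation of candidate-gene tumor
expression with immune infiltration markers, and alignment of each lead
SNP's cancer-risk allele with its eQTL direction of effect. A seeded
synthetic-data generator produces every input the pipeline consumes, so
all of its operating characteristics can be measured under a known
truth.

## The statistical core

For a SNP with per-trait estimates $(\hat\beta_A, se_A)$ and
$(\hat\beta_B, se_B)$ on the log-odds scale, the fixed-effect
inverse-variance-weighted combination is

$$
\hat\beta_{meta} = \frac{w_A\hat\beta_A + w_B\hat\beta_B}{w_A + w_B},
\qquad
se_{meta} = (w_A + w_B)^{-1/2},
\qquad w_i = se_i^{-2},
$$

with $Z = \hat\beta_{meta}/se_{meta}$ and a two-sided normal p-value. A
common-effect combination *rewards agreement*: a variant whose effects
on the two traits point in opposite directions is penalized, not
discovered. The screen therefore negates the autoimmune trait's
$\hat\beta$ (keeping its effect allele, standard error and p-value
unchanged) before combining. After this sign flip, opposite-direction
variants look concordant and can reach combined genome-wide
significance, while genuinely concordant variants cancel.

Cochran's Q,

$$
Q = w_A(\hat\beta_A - \hat\beta_{meta})^2 +
    w_B(\hat\beta_B - \hat\beta_{meta})^2
\sim \chi^2_1 \text{ under homogeneity},
$$

computed on the same flipped scale, removes variants whose effect
*magnitudes* are incompatible. Note an implication of the two-study
algebra: any concordant variant strong enough to pass the per-trait
filters is, after the flip, also maximally heterogeneous
($Q = 2z^2$ at equal weights), so the Q filter and the meta-significance
filter are jointly — and redundantly — protective against the unwanted
pattern; both are applied.

A retained SNP must satisfy all of:

| filter | default | meaning |
|---|---|---|
| per-trait p | $< 10^{-3}$ in both traits | nominally associated with each disorder |
| heterogeneity | $p_{het} \ge 0.05$ | effect sizes compatible after the flip |
| combined p | $< 5\times10^{-8}$ | genome-wide significant jointly |

Filters are applied in that fixed order (per-trait screen, then
meta-analysis and Q on the survivors); the retained set is
order-invariant but the per-stage counts in the screen log are not,
which is why the order is documented.

Because extreme signals underflow double precision ($p$ below about
$10^{-308}$ prints as 0), every meta p-value is also carried as
$-\log_{10}p$ computed in log space, and lead selection during clumping
uses it to break $p = 0$ ties before the deterministic position/rsid
tie-break.

## Allele harmonization

Before any combination the two tables are joined on (rsid, chromosome,
position) and trait B is re-expressed on trait A's effect allele:
swapped effect/other alleles negate $\hat\beta_B$ and reflect its EAF;
reverse-complement pairs are relabelled (strand flip) and re-checked.
Palindromic SNPs (A/T, C/G) whose EAF lies in (0.4, 0.6) on either
side — or is missing — are dropped as strand-unresolvable; outside that
window their orientation is inferred from EAF agreement. The window is
configurable; the default is common GWAS practice. QC mirrors the
source-study conventions: records with minor-allele frequency below
0.5% or imputation quality below 0.3 are excluded, with both boundaries
inclusive (a record *at* the threshold passes) and records lacking a
metric passing that filter, since some consortia do not publish EAF or
INFO.

## Clumping and cross-pair accounting

Lead SNPs are chosen greedily: the most significant unassigned SNP
becomes a lead and absorbs every unassigned same-chromosome SNP with
$r^2 \ge 0.1$ to it. After exhaustion, clump spans within 1 Mb of each
other on the same chromosome are merged into one region (locus) while
each clump's lead survives as a distinct lead SNP — merging affects
region bookkeeping, not lead counting. Cross-pair uniqueness of leads is
by rsid identity, matching how "unique, independent lead variants" are
counted across the 7 × 7 trait-pair grid. Only the single $r^2 = 0.1$
threshold is used (no second "independent significant SNP" level), and
the 1 Mb parameter governs only merging, measured between clump
boundaries rather than between lead positions.

## Gene annotation and enrichment

Each lead SNP maps to the gene minimizing distance to its body
(0 inside the gene, otherwise distance to the nearer edge; ties resolved
by distance to the gene start, then symbol, so runs are reproducible).
Nearest genes are flagged against a curated immune gene list, and the
full nearest-gene set is tested for pathway overrepresentation with the
exact hypergeometric tail
$P(X \ge k),\, X \sim \mathrm{Hypergeom}(N, K, n)$, ranked by raw p
(Benjamini–Hochberg values are reported but do not drive ranking,
because the downstream rule is rank-based). Within each pathway
database, the top 10 sets are inspected and those whose names match a
configurable immune keyword list (interferon, TCR, cytokine, …)
contribute their driver genes. This keyword list operationalizes what is
otherwise a manual curation step; it is a reproducible proxy, not a
reconstruction. The universe defaults to the annotation table's gene
count.

## Expression prioritization and direction of effect

Candidate genes are correlated (Spearman, mid-ranks for ties,
pairwise-complete) with four infiltration markers — CD4, CD8A, CD11B
(HGNC: *ITGAM*) and CD45 (HGNC: *PTPRC*) — in each tumor expression
cohort. A gene is prioritized iff in *every* cohort its best marker
correlation strictly exceeds 0.5; a gene missing from any cohort is
never prioritized. Finally, each prioritized lead SNP's *cancer-risk
allele* (the effect allele when the cancer $\hat\beta > 0$, else the
other allele) is harmonized to the allele of a cis-eQTL record for the
nearest gene, negating the eQTL Z on an allele swap, and the sign of the
harmonized Z classifies the SNP as
`risk_allele_increases_expression` / `..._decreases_expression`;
palindromic records are `unresolvable` because strand orientation cannot
be verified from labels.

## What the synthetic data emulates

`simulate_ld_genotypes()` builds haplotypes from a first-order Markov
allele-copying process per LD block: the first allele is Bernoulli(MAF)
and each subsequent allele copies its left neighbour with probability
$\rho$ (`block_rho`), otherwise it is a fresh draw. MAF is constant
within a block. This makes the genotype correlation at within-block
distance $d$ exactly $\rho^d$ in population — $\rho = 0.9$ adjacent
pairs give $r^2 = 0.81$ — and 0 across blocks. A thresholded latent
Gaussian AR(1) was implemented first and discarded: naive thresholding
attenuates the genotype correlation below the nominal $\rho$, and
correcting the latent correlation (tetrachoric inversion) repairs
adjacent pairs at the cost of grossly inflating long-range correlation
relative to $\rho^d$, which collapses distinct signals into a single
clump. The copying model delivers the controllable $r^2$ structure the
pipeline needs with none of that distortion.

Summary statistics default to an analytic mode: each SNP's estimate is
drawn as
$\hat\beta \sim N(\beta_{marginal},\, se^2)$ with
$se = 1/\sqrt{2\,n_{eff}\,p(1-p)}$ and
$n_{eff} = 4/(1/n_{cases} + 1/n_{controls})$, where $\beta_{marginal}$
propagates each planted causal effect through the empirical within-block
LD ($r \times \sqrt{\mathrm{var\ ratio}} \times \beta_{causal}$). This
is distributionally exact under the usual GWAS asymptotics and fast
enough to calibrate on $10^5$ SNPs in seconds. An opt-in phenotype mode
instead draws binary outcomes from a logistic model whose intercept hits
the configured case fraction and estimates per-SNP effects with the
one-step score statistic. Two deliberate simplifications: trait A and
trait B cohorts are independent (no sample overlap — the assumption the
fixed-effect combination itself makes), and in analytic mode the
sampling noise is independent *across SNPs*, whereas real single-cohort
noise is LD-correlated; this slightly disperses the noise in a clump but
does not move its expectation. Planted causal SNPs are always assigned
non-palindromic allele pairs so that harmonization's ambiguity filter
cannot silently delete a planted locus — a generator guarantee, not a
property of real data.

Planted effect classes cover the patterns the screen must separate:
`opposite` ($\beta_A\beta_B < 0$, the target), `concordant`
($\beta_A\beta_B > 0$, cancelled by the flip), `heterogeneous`
(opposite but incompatible magnitudes, removed by Q), `a_only`/`b_only`
and `null`. Expression matrices get one latent infiltration factor per
cohort; marker and driven genes load on it with `infiltration_loading`
($\lambda$), other genes are noise, and every row is Z-scored. Two genes
sharing the factor correlate at $\lambda^2$ (0.81 at the default 0.9);
the rank transform attenuates this to about
$\tfrac{6}{\pi}\arcsin(\lambda^2/2) \approx 0.80$, comfortably above the
0.5 rule at 500 samples.

Defaults describe the regime the screen targets: 50,000 cases and
50,000 controls per trait (biobank-scale case-control GWAS), planted
$|\beta| = 0.15$ (odds ratio $\approx 1.16$, typical of the stronger
pleiotropic GWAS hits), MAF 0.05–0.5, adjacent-SNP LD 0.9, 40 blocks of
15 SNPs on one 250 Mb synthetic chromosome, and four expression cohorts
of 500 samples. Block size is kept at ~15 SNPs so that every block
member stays within $r^2 \ge 0.1$ of its block's lead; with much larger
blocks the $\rho^d$ decay itself fragments one planted locus into
several legitimate clumps, which is realistic but makes
one-lead-per-locus accounting ambiguous.

What passing tests on these data do **not** show: robustness to real
human LD (long-range, variable-rate, population-structured), to
mis-specified or build-mismatched positions, to overlapping control
sets between traits (which inflates the combined Z), or to the many
idiosyncrasies of real expression cohorts (batch effects, tumor purity,
normal-sample admixture). The generator is a calibration instrument,
not a population-genetics simulator; X chromosomes, imputation and
relatedness are out of scope.

## Numerical and degenerate-input choices

* Normal and $\chi^2$ tails are taken from R's `pnorm`/`pchisq`;
  meta p-values additionally in log space (`mlog10p`) so ranking
  survives underflow.
* A missing p-value on input is recomputed as $2\Phi(-|\beta/se|)$;
  duplicate rsids keep the smaller p; non-positive $se$, out-of-range
  p/EAF/INFO and non-ACGT alleles are rejected and counted by reason.
* `ivw_meta()` and `cochran_q()` refuse non-positive standard errors;
  $z = 0$ maps to $p = 1$; Q of equal betas is exactly 0.
* Spearman correlation of a constant vector (zero rank variance) is
  returned as `NA` with a warning rather than silently 0; fewer than 3
  complete pairs likewise.
* All tie-breaks (clump leads, nearest genes) are total orders, so
  identical inputs give byte-identical outputs; every generator is a
  pure function of `(config, seed)`.
* A double flip of the autoimmune sign is a state error, guarded by an
  attribute on the flipped table.

## Problem sizes used by the test suite

The packaged tests run the screen at the full configured sample sizes
but desk-scale SNP panels: $10^5$ analytic null SNPs for calibration
(heterogeneity rejection $0.05 \pm 0.007$, zero full-screen
pass-throughs), 600 SNPs / 2000 reference individuals for the planted
40-locus recovery run, 200 random $\le$15-SNP instances against a
brute-force clumping oracle, $10^4$ random pairs against the IVW/Q
closed form at $10^{-10}$ relative error, and 4 cohorts × 500 samples ×
32 candidates for prioritization. These sizes were chosen so the whole
suite completes in well under a minute while keeping every Monte-Carlo
band at least three standard errors wide.

## A worked micro-example

```{r example}
cfg <- simulation_config(seed = 1, n_snps = 150, n_blocks = 10)
cfg$planted_effects <- plant_block_effects(
  cfg, c("opposite", "concordant", "heterogeneous"), beta = 0.15)
g <- simulate_ld_genotypes(cfg, n_individuals = 1000)
ss <- simulate_pair_sumstats(g$genotypes, g$snp_map, cfg)

pair <- harmonize_pair(apply_qc_filters(ss$a), apply_qc_filters(ss$b))
pair$b <- flip_sign(pair$b, "autoimmune")
scr <- screen_pair(pair)
screen_log(scr)

leads <- ld_clump(scr, compute_r2(g$genotypes),
                  pair_label = "cancer|autoimmune")
leads[, c("lead_rsid", "pos", "p_meta", "n_members")]
```

Only the opposite-effect block survives: the concordant block cancels
after the flip and the heterogeneous block fails the Q test. The lead
SNP is the planted causal variant (or a tight LD proxy of it).

## Known limitations

* Two studies per combination by design; the 7 × 7 pair grid is an
  iteration over pairs, not a joint model, and no correction for
  overlapping controls across pairs is attempted.
* The pathway step reproduces hypergeometric ranking but not any
  proprietary enrichment score; "immune-related" pathway classification
  is keyword-based.
* eQTL direction takes one user-supplied record per (SNP, gene) and does
  not arbitrate between tissues or sources.
* rsid identity is the cross-table join key throughout; no liftover or
  dbSNP resolution is performed, and indels are rejected at parse time.
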