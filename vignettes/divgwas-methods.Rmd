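---
title: "Methods: bivariate BayesB GWAS for pleiotropic regions in divergent selection lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bivariate BayesB GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`divgwas` fits a Bayesian multiple-marker regression for one or two traits
jointly. For animal $i$ and trait $t \in \{1,2\}$:

$$y_{it} = \mathbf{x}_i'\mathbf{b}_t + c_{\ell(i),t} + u_{it} +
  \sum_{j=1}^{k} z_{ij}\,\delta_{jt}\,\alpha_{jt} + e_{it}$$

* **Fixed effects** $\mathbf{b}_t$: month (5 levels), sex (2), parity order
  (2), with a flat prior. The intercept is absorbed in the month factor.
* **Common litter** $c_{\ell,t}$: one draw per litter (dam × parity),
  shared by full sibs; $\mathbf{c} \sim N(0, I \otimes C)$ with $C$ a
  $2\times2$ covariance matrix.
* **Polygenic** $u_{it}$: pedigree-based, $\mathbf{u} \sim N(0, A \otimes U)$
  where $A$ is the numerator relationship matrix over the full pedigree.
  This term absorbs genetic variance not captured by the marker mixture.
* **Markers**: $z_{ij} \in \{0,1,2\}$ dosages, column-centered before
  sampling (a pure location shift absorbed by the month factor; it improves
  mixing and leaves window variances and correlations unchanged).
  $\delta_{jt}$ is a binary inclusion indicator; the pair
  $(\delta_{j1},\delta_{j2})$ has four configurations with prior mass
  $\pi_{00} = 0.9982$ on the joint null and $(1-\pi_{00})/3 = 0.0006$ on
  each of the other three. Univariate runs use a two-state indicator with
  $\pi = 0.9988$, so the marginal per-trait inclusion prior (0.0012) is the
  same in both model forms. Included effects are
  $\alpha_j \sim N(0, G_j)$ with a locus-specific $2\times2$ covariance.
* **Residuals**: $\mathbf{e} \sim N(0, I \otimes R)$.

All covariance matrices ($C$, $U$, $R$, $G$) have inverse-Wishart priors.
The degrees of freedom default to $\nu = t + 2$, the smallest value at which
the prior mean exists and equals the supplied scale matrix — the natural
choice when the matrices come from an external variance-component analysis,
as they do in the intended workflow.

## The Gibbs sampler

All updates are single-site Gibbs draws; there is no Metropolis step.

* **Fixed effects and litter effects** are drawn per level as $t$-variate
  normals ($2\times2$ solves).
* **Polygenic effects** use single-site updates with the *sparse inverse*
  of $A$, built directly from the pedigree by Henderson's rules with
  inbreeding coefficients taken from the tabular $A$. We chose this over
  jointly factorizing the polygenic full conditional: a joint draw would
  need a $2n \times 2n$ factorization per iteration, which is not viable at
  tens of thousands of iterations, while the sparse-inverse form costs
  $O(n)$ per sweep and is exact. The dense tabular $A$ and its matrix
  square root remain available (`build_numerator_relationship`,
  `factor_relationship`) for direct use and for validation against a
  gene-dropping Monte-Carlo oracle.
* **Marker effects**: for each locus the effect is integrated analytically
  under each indicator configuration, the configuration is drawn from the
  resulting 4-category (or 2-category) conditional, and the active effect
  components are then drawn from their Gaussian full conditional. This
  avoids reversible-jump machinery and is the standard construction for
  BayesB-type samplers. Because the integrated likelihood of a nested null
  configuration has expectation one under the null, the posterior inclusion
  rate under pure-noise data matches the prior mass — a property the test
  suite checks directly.
* **Locus covariances** $G_j$: the inactive components of $\alpha_j$ are
  augmented from their conditional prior given the active ones, after which
  $G_j \mid \alpha_j \sim IW(\nu+1, \Psi + \alpha_j\alpha_j')$. A
  `shared` mode (one $G$ for all loci, updated with $\nu + k$ degrees of
  freedom) is provided because the per-locus reading of the effect-variance
  notation is not the only sensible one; per-locus is the default as it is
  the classic BayesB structure.
* **Missing records** for one trait are handled by residual augmentation:
  the missing trait's residual is drawn from its conditional normal given
  the observed trait's residual, so bivariate analyses can use trait-wise
  unequal record counts.
* **Covariance updates** are inverse-Wishart full conditionals; for $U$ the
  scale accumulates $\mathbf{u}' A^{-1} \mathbf{u}$ through the sparse
  triplets.

The default schedule is 470,000 iterations, 70,000 burn-in, thinning 40
(10,000 saved draws) — a production schedule for a real dataset. All
analyses in the test suite and acceptance script use scaled-down schedules
(typically 12,000–20,000 iterations, 300 animals, 800–2,000 SNPs), which the
strong simulated signals make sufficient; the same code path runs at any
scale. Every random draw comes from R's RNG stream, so a single `set.seed`
(or the `seed` field of `mcmc_config`) makes runs byte-reproducible.

## Windows, regions, correlations

Windows are **SNP-anchored**: every SNP anchors one window spanning the
half-open interval $[p, p + 1\,\mathrm{Mb})$ on its chromosome. This
produces slightly fewer distinct windows than SNPs (end-of-chromosome
attrition, co-located anchors are flagged as duplicates), which is the
only construction consistent with panels where window counts fall just
short of SNP counts.

Per saved draw $s$ and trait, the window share is
$\mathrm{Var}_i(g_w^{(s)})/\mathrm{Var}_i(g^{(s)}_{\mathrm{tot}}) \times 100$
where $g_w$ sums members' $z_j\alpha_j$ and $g_{\mathrm{tot}}$ sums over all
SNPs. The denominator is marker-only by default; a
`markers_plus_polygenic` mode adds the draw's polygenic values, since
"genetic variance" can be read either way. Draws with zero total variance
are skipped. For orthogonal covariates the shares of disjoint windows sum
to exactly 100% (checked algebraically in the tests); with real LD the sum
exceeds 100% through covariance terms, which is inherent to window-share
summaries.

A window is associated when its posterior-mean share is **at least 0.75%**;
overlapping associated windows on a chromosome merge into one region whose
coordinates span the member SNPs, whose variance is the member-window
maximum, and whose PPA we define as the fraction of saved draws in which at
least one member SNP is included for the trait — the published tables print
a region PPA without defining it, so this any-member definition is a
documented choice, not a reconstruction. The window genetic correlation is
the per-draw Pearson correlation across individuals of the two traits'
window breeding values, summarised by mean and SD over the draws where both
variances are positive (the contributing-draw count is reported; a window
in which one trait never has an included SNP is flagged undefined rather
than erroring).

## The synthetic-data generator

`simulate_divergent_lines` emulates the data-generating situation the
analysis is built for: a base population at linkage equilibrium with
allele frequencies uniform on a configurable band, split into two lines;
within each line, parents (8 sires, 40 dams per generation by default, with
six progeny per dam, i.e. ~240 phenotyped progeny per line and generation)
are truncation-selected on trait 2's phenotype, upward in line H and
downward in line L; gametes recombine under a Haldane map at 1 cM/Mb (a
standard neutral default — no attempt is made to match any species' linkage
map); phenotypes follow exactly the model above, with trait heritabilities
0.43/0.49 and litter fractions 0.14/0.17 by default — values typical of
fat-depot and IMF-type traits. Months are assigned to litters cycling over
five levels, so the slaughter-batch factor varies *within* a generation and
remains estimable in a single-cohort analysis; sex is Bernoulli(½) and
parity order has two levels.

QTL are placed on existing SNPs (observed-QTL regime; a `hidden_qtl` mode
drops the causal columns to emulate LD-only detection) and segregate at a
base frequency of 0.4 regardless of the neutral frequency band: a
low-frequency causal allele driven toward loss by selection would carry
only a fraction of its configured variance share, silently breaking the
scenario the QTL specification states. Effects are
deterministic given the configured variance shares: a single locus can only
give a within-window genetic correlation of ±1, so intermediate
correlations are planted with `qtl_window_pair`, a two-locus loading
construction (locus A loads $(1, \rho)$, locus B $(0, \sqrt{1-\rho^2})$)
whose window correlation is $\rho$ at linkage equilibrium. The polygenic
recursion uses Mendelian-sampling variance $U/2$ without the inbreeding
correction — over the few generations simulated the bias is negligible, and
the gene-dropped genotypes themselves carry the real drift and inbreeding.

What the generator does **not** emulate: real linkage maps and LD decay,
mutation, genotyping error, non-additive gene action, maternal genetic
effects, selection on an index of relatives' records (selection acts on own
phenotype), and overlapping generations. Passing tests therefore validate
the statistical machinery under the assumed model, not robustness to
model misspecification.

Selection intensities per generation are free parameters
(`n_sires_per_line`, `n_dams_per_line`, `progeny_per_dam`), as no
generation-by-generation intensities are fixed by the design being
emulated.

## Numerical and edge-case choices

* Thresholds follow their printed inequality directions: call rate and MAF
  keep at the boundary (≥), animal missingness removes strictly above 3%,
  the window threshold keeps at 0.75%, divergence criterion 2 is strict
  (> 0.65), and "fixed" means a frequency of exactly 1.0 among called
  samples — with ~10 sequenced sires per line exact fixation is attainable,
  and the strict reading is what excludes the boundary case of an allele
  fixed in one line but at frequency 0.6 in the other.
* The Mendelian test statistic is the per-animal rate of opposing-homozygote
  conflicts against each genotyped parent (threshold 1% by default); the
  upstream convention only names the test, so the statistic and threshold
  are configurable and recorded in the QC report.
* The QC cascade re-applies the SNP filters after animal removal
  (`recheck_maf`), which is what makes it idempotent.
* Coordinates are 1-based bp in all I/O; window arithmetic is half-open
  internally; region intersection is inclusive on both ends.
* Cholesky factorization of $A$ falls back to a symmetric-eigen square root
  with eigenvalue clipping for semi-definite cases (duplicated genotypes,
  clones).
* A zero-variance phenotype, an unfactorizable prior matrix, an
  all-missing SNP, and a non-finite residual covariance during sampling are
  hard errors, not warnings.
* Single-marker imputation (`naive_impute`) is deliberately simple —
  expected dosage rounded, or a Hardy–Weinberg draw — and warns that it is
  not haplotype-based imputation; it exists so the sampler can require
  complete dosages.

## Known limitations

A phenomenon worth singling out: after several generations of strong
divergent selection a QTL's genotype becomes nearly collinear with lineage,
and the pedigree polygenic term — whose covariance $A$ encodes exactly that
lineage structure — can absorb the whole QTL signal (we have observed the
polygenic variance posterior inflating well above its prior while the
marker's inclusion probability collapses, and recovering fully when the
polygenic term is dropped). This is correct behavior of the joint model,
not a sampler defect, but it means marker-based detection power falls as
between-line divergence at the causal locus grows; validation scenarios in
the tests and the acceptance script therefore use two selected generations,
where marker and polygenic signal remain separable.

* The sampler's RNG stream is consumed in locus order, so permuting SNP
  columns changes the realized draws (the posterior is exchangeable across
  loci, but realizations are not permutation-equivariant).
* Dense $A$ construction is $O(n^2)$ memory; the package targets pedigrees
  up to a few thousand animals.
* Window shares are posterior means of ratios; with very sparse inclusion
  the estimates for unassociated windows are noisy near zero.
* No maternal-effect model, no estimation of π from the data, and no
  Bayes-factor single-marker thresholds — association calling is by window
  share only, with per-SNP PPAs reported descriptively.
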