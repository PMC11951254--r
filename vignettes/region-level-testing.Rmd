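---
title: "Region-level association testing with LD-bin contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-level association testing with LD-bin contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regionassoc)
```

## The problem

Single-variant genome-wide association scans are powerful when one common
variant carries a large marginal effect, but lose power when a region
harbors several weaker, partially correlated signals. Region-level testing
aggregates all variants in a pre-defined genomic interval — ideally an
LD-adaptive block with high within-region and low between-region
correlation — into a single joint hypothesis test. Because adjacent
LD-adaptive regions are quasi-independent, a genome-wide scan over K regions
can use the Bonferroni threshold `alpha / K`, far less stringent than the
single-variant 5e-8 convention (`bonferroni_threshold()`).

No single region-level statistic dominates across regional architectures:
regression tests are robust but pay a degrees-of-freedom price; score
tests are efficient for diffuse signals; minP tests win with a single
strong variant. `regionassoc` therefore computes eight region-level tests
per region and combines them with a Cauchy combination, so a scan can be
read test-by-test or through a single omnibus column.

## Per-region processing

For each region the pipeline (`run_regscan()`):

1. **Extracts genotypes** from the VCF (`read_vcf_region()`). Each
   (site, ALT) pair becomes one dosage column in `[0, 2]`; multiallelic
   records are split per ALT allele with ids `<id>_<ALT>`. Missing
   genotypes are mean-imputed per column; a column whose missing fraction
   exceeds `miss_max` (default 0.05) is excluded instead.
2. **Filters and recodes** (`filter_variants()`): monomorphic columns and
   columns with MAF below `maf_min` (default 0.01; the threshold is
   inclusive for keeping) are logged out; surviving columns are recoded so
   the counted allele is the minor allele.
3. **LD-prunes** (`ld_prune()`): a greedy scan in position order removes a
   variant whose squared correlation with any kept variant exceeds
   `prune_r2` (default 0.98). The default removes only near-duplicates —
   enough to keep the joint regression full-rank without dissolving the
   bin structure a lower threshold would destroy.
4. **Assigns LD bins** (`clique_bins()`): variants are vertices of a graph
   with an edge where `r^2 >= bin_r2` (default 0.5, the usual clique-binning
   convention for common variants); the largest maximal clique is removed
   as a bin, repeatedly; leftovers become singletons. Ties among equal-size
   cliques go to the lexicographically smallest member-index tuple, which
   makes the binning deterministic across platforms and enumeration orders.
5. **Sign-recodes** (`recode_bins_positive()`): within each bin the
   lowest-index variant anchors sign +1 and every other member takes the
   sign of its correlation with the anchor (`2 - dosage` when negative),
   so within-bin correlations are positive and bin sums act as local
   burden scores. For an exchangeable-correlation bin this anchor rule also
   maximizes the sum of pairwise correlations over sign patterns.

Every excluded variant appears in the prune log with a machine-readable
reason (`MONOMORPHIC`, `MAF_BELOW_MIN`, `MISSINGNESS_ABOVE_MAX`,
`LD_PRUNED`, `DUPLICATE`), and per region the analyzed and logged variants
always sum to the VCF slice after multiallelic splitting. A variant falling
on the shared boundary of two regions is analyzed in the earlier region
and logged as `DUPLICATE` in the later one.

## The tests

Let `beta_hat` be the coefficient vector of the joint regression of the
phenotype on all m analyzed variants (plus covariates) and `V` its
covariance. With the B x m contrast matrix `W` whose row b averages bin b
(`W[b, j] = 1/|bin b|` for members of b, after sign recoding):

* **Wald** — `T = beta_hat' V^-1 beta_hat` on m df: the full multiple
  regression test.
* **MLC** — `L = W beta_hat`, `S = W V W'`, `T = L' S^-1 L` on B df: the
  reduced-df multiple-linear-combination test on LD-bin contrasts. With
  identity contrasts it is exactly the Wald test, and it is invariant to
  positive rescaling of W's rows. Each bin also gets a 1-df test of
  `L_b / sqrt(S_bb)`, reported in the bin-level file.
* **LC** — MLC with a single all-variant bin after global positive
  recoding: a 1-df burden-type test.
* **PC80** — joint test of the fewest principal components of the
  standardized genotype matrix explaining at least `pc_var` (default 0.8)
  of the variance.
* **SKAT** — variance-component score test
  `Q = (y - mu0)' G W^2 G' (y - mu0)` against the weighted-kernel null
  (gaussian residual scale divided out); the reference distribution is a
  weighted sum of 1-df chi-squares.
* **SKAT-O** — minimum p over the burden–SKAT family
  `R_rho = (1 - rho) I + rho 11'` on the grid
  `{0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1}`, with the omnibus p from the
  published one-dimensional integration; the result is additionally capped
  at the Bonferroni bound over the grid.
* **simpleM** — Sidak-corrects the minimum single-variant p by the
  effective number of tests `M_eff`, the number of leading eigenvalues of
  the variant correlation matrix reaching 99.5% of the total.
* **GATES** — extended Simes: `min_j Me(all) p_(j) / Me(top j)` with
  effective test numbers from eigenvalues of the p-value correlation
  submatrices. The correlation between two variants' p-values is derived
  from their genotype correlation through the published sixth-degree
  polynomial fit (with |r| = 1 mapped to exactly 1 so duplicated variants
  count once). Using the raw genotype correlation here instead is
  anti-conservative under strong LD — our null simulations pushed the
  empirical type-I error above the exact binomial band — which is why the
  polynomial form is used.

`MINP_RAW` (the unadjusted minimum single-variant p among analyzed
variants) and `ACAT_P` (the equal-weight Cauchy combination of the eight
region-level p-values) complete the region-level file. The Cauchy
combination is valid under arbitrary dependence among the inputs; p-values
are clipped to `[1e-15, 1 - 1e-15]` before the tangent transform.

For gaussian traits the Wald/MLC/LC/PC80 statistics use F reference
distributions (`T/df ~ F(df, n - m - c - 1)`), the exact small-sample
calibration; for binomial traits they use chi-square references. Bin-level
1-df tests use the chi-square reference in both families.

### Binary traits and Firth penalization

Binomial joint fits use IRLS maximum likelihood. With `firth = TRUE` — or
automatically when IRLS fails to converge, e.g. under separation at low
minor-allele counts — the Jeffreys-prior penalized likelihood is maximized
instead: the modified score `sum_i (y_i - pi_i + h_i(1/2 - pi_i)) x_i = 0`
(`h_i` the weighted-hat-matrix leverage) is solved by Newton iteration with
step-halving, to gradient norm below 1e-8 within 100 iterations. The
penalty guarantees finite estimates under complete separation and reduces
small-sample bias for unbalanced case/control ratios; in the
intercept-only case the fitted probability is exactly `(y + 1/2)/(n + 1)`.

## Numerical choices

* **Chi-square mixture tails** (SKAT, SKAT-O): exact characteristic-
  function inversion by Imhof's formula via adaptive quadrature
  (`pchisum()`, absolute tolerance 1e-12), with the Liu et al. non-central
  chi-square moment matching as fallback when the inversion fails or
  returns a value outside `[0, 1]`. Inside the SKAT-O omnibus integral the
  remainder tail uses the moment-matched form directly — it enters only
  through a smooth one-dimensional average, where the cheap tail is
  accurate and avoids nested quadrature.
* **SKAT-O grid endpoint**: rho is capped at 0.999 inside the omnibus
  integration (the `1 - rho` denominator), while the per-rho p-value at
  rho = 1 is computed exactly through the rank-1 kernel.
* **Singular systems**: a singular `V` or `S` yields an NA p-value rather
  than an error; a rank-deficient joint design is a hard error directing
  the user to pruning; a singular correlation matrix makes VIFs NA with a
  warning.
* **Determinism**: pruning scans ascending position (ties by variant id);
  clique ties break lexicographically; regions are processed as
  independent tasks and merged in region order, so outputs are
  byte-identical for any worker count.

## The synthetic-fixture generator

`simulate_genotypes()` draws a latent multivariate normal with
block-exchangeable correlation and thresholds each variant at the
Hardy–Weinberg genotype quantiles implied by its allele frequency
(`P(0) = (1-p)^2`, `P(2) = p^2`) — the simplest copula that respects the
marginal MAF. Thresholding attenuates the latent correlation, so a latent
rho of 0.9 yields dosage correlations around 0.75–0.9.
`simulate_phenotype()` adds gaussian noise at a stated residual variance,
or draws binary outcomes from a logistic model whose intercept is solved
numerically so the expected case fraction matches a target within 0.005 —
the mechanism for emulating unbalanced designs. `write_fixture()` writes
the block as plain-text VCF 4.2 with matching region and phenotype tables
that round-trip exactly through the readers.

What the generator does **not** emulate: coalescent haplotype structure,
recombination-rate variation, population stratification or admixture,
genotyping or imputation error, and long-range LD leakage across region
boundaries. Tests passing on these fixtures therefore validate the
statistical machinery and the file contracts, not robustness to
confounding — on real data, covariates such as genotype principal
components remain the analyst's responsibility.

Default fixtures use regions of a few dozen variants; genome-scale
regions of 50–100 variants are the design point of the engine and are
exercised by the same code paths.

## Calibration checks

The test suite verifies, among other properties: exact binomial-interval
type-I error control of all eight tests at alpha = 0.05 under a gaussian
null with 500 samples, 20 variants in LD blocks and 1000 replicates;
equality of the clique binning with a brute-force Bron–Kerbosch oracle on
all random graphs up to 8 vertices over 200 seeds; agreement of the SKAT
tail with a 1e6-draw Monte-Carlo mixture oracle within two Monte-Carlo
standard errors; the Firth closed form; and byte-identical pipeline output
across worker counts. These sizes keep the default suite to a few minutes
on one CPU while leaving the binomial confidence intervals tight enough to
detect miscalibration of a few percentage points.

## Known limitations

* Common-variant orientation: default flat SKAT weights
  (`skat_weights = "beta"` switches to Beta(1, 25) MAF weights for
  rare-variant use).
* No mixed-model or kinship adjustment, GEE, interaction or conditional
  analysis; related samples must be handled upstream.
* Autosomal dosage model only; no phased-haplotype LD (bin edges use
  composite-genotype r^2, not haplotype D').
* The GATES p-value correlation uses a polynomial fit derived for
  two-sided normal statistics; it is an approximation, and very small
  regions with extreme LD may still show mild miscalibration.
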