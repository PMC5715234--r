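---
title: "Methods: comparing two gene pools from a biallelic SNP panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing two gene pools from a biallelic SNP panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

soypopdiv compares two gene pools of a mostly inbred diploid crop —
the motivating case is cultivated soybean panels from two breeding
programs — using a biallelic SNP panel. This vignette documents the
statistical models, the tunable parameters and their defaults, the
numerical conventions, and the design decisions that were genuinely
open; it is the authoritative account of *why* the package computes what
it computes. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself recompute.

## Data model

A `genotype_panel` stores a samples × loci matrix of alt-allele dosages
(0/1/2, `NA` for a missing call), locus coordinates (1-based positions,
VCF convention), and a population label per sample. Heterozygote call
dialects ("0/1", "1|0", "AT", "TA") all map to dosage 1; multi-allelic
records are dropped (or rejected) at load time. All intervals elsewhere
in the package (windows, annotations) are half-open `[start, end)`.

The missingness filter removes a locus when its missing fraction is
*strictly* greater than the threshold (default 0.20): a locus at exactly
20% missing is retained. The strict inequality mirrors the convention of
excluding markers with missing data in "more than" a stated share of
samples, and it is what makes the arithmetic 5,361 − 166 = 5,195
(96.90% retained) come out exactly.

## Diversity statistics

With allele frequencies $p$ and $q = 1-p$ estimated from called
genotypes only:

* gene diversity (expected heterozygosity) $= 1 - (p^2 + q^2)$, maximal
  at 0.5 for $p = 0.5$;
* PIC $= 1 - (p^2+q^2) - 2p^2q^2$ (the Botstein biallelic reduction, as
  implemented in PowerMarker-style tools), maximal at 0.375;
* observed heterozygosity = fraction of called genotypes with dosage 1;
* MAF $= \min(p, q)$, recomputed per analysis scope, because the minor
  allele of a subpopulation need not be the panel-wide minor allele.

Loci with no called genotype in a group are flagged undefined and
excluded from group means — never zero-filled, which would bias every
mean downward. The pooled ("combined") summary is recomputed from the
pooled genotypes, not averaged from subgroup summaries: pooling two
diverged pools adds a between-pool variance component, so combined
diversity legitimately exceeds both subgroup values.

## Linkage disequilibrium

`pairwise_r2()` uses the composite genotypic estimator: squared Pearson
correlation of dosage vectors over pairwise-complete samples. The choice
is deliberate. The inputs are unphased genotypes of near-fully inbred
lines, for which the composite estimator is essentially equal to the
haplotype-frequency $r^2$ while requiring no EM phase reconstruction.
Significance uses the standard allelic-association approximation
$\chi^2 = n r^2$ on 1 df.

`ld_decay()` bins pairs by physical distance (default bin width 500 kb)
and reports the decay distance at a threshold (default $r^2 = 0.1$) as
the midpoint of the first bin whose mean $r^2$ falls below the threshold
*and stays below it* in every later non-empty bin; a transient dip
followed by a rebound does not count. The decay distance is therefore a
bin-resolution quantity, and a profile that never crosses the threshold
is reported as "beyond observed range" rather than extrapolated.

## Distance, kinship, trees

The Rogers distance uses individual allele-frequency vectors (dosage/2):
$D_{ij} = \frac{1}{L}\sum_l \sqrt{\tfrac12 \sum_a (p_{ila}-p_{jla})^2}$
over pairwise-complete loci. For biallelic loci this reduces exactly to
the mean absolute dosage difference divided by 2, and the allele-sharing
distance $1 - \text{shared}/(2L)$ reduces to the same quantity; both
method tags are kept so scripts state their intent.

Loiselle kinship is
$K_{ij} = \sum_l \sum_a \left[(p_{ila}-p_{la})(p_{jla}-p_{la}) +
\frac{p_{la}(1-p_{la})}{n_l - 1}\right] \big/ \sum_l \sum_a
p_{la}(1-p_{la})$,
with reference frequencies $p_{la}$ taken from the full panel (the
natural reading of "reference sample" when no external reference
exists), $n_l$ the number of non-missing alleles at locus $l$, and the
$1/(n_l-1)$ term the small-sample bias correction. Negative pairwise
values — pairs less related than random draws from the reference — are
truncated to zero *after* summation across loci, not per locus; per-locus
truncation would systematically inflate every estimate. No rescaling to
[0, 1] is applied: marker-based kinship of this form can legitimately
exceed 1 for highly related inbred pairs.

Neighbor joining delegates the Saitou–Nei agglomeration to
`ape::nj()`; negative branch lengths (an NJ artifact on noisy
distances) are clamped to zero with the deficit transferred to an
adjacent branch so path lengths through the node are approximately
preserved. No bootstrap is attached.

## Structure summaries

`panel_pca()` mean-imputes missing dosages per locus (the standard SNP
PCA convention — imputation at the mean contributes zero to the centered
covariance), centers, and by default applies the
$1/\sqrt{p(1-p)}$ scaling that gives each locus equal expected
contribution under pure drift. Axis signs are fixed by making each
axis's largest-magnitude loading positive, so results are reproducible
across platforms.

`evanno_delta_k()` post-processes log-likelihoods from an external
model-based clustering run (e.g. STRUCTURE):
$\Delta K = \text{mean}(|L''(K)|)/\text{sd}(L(K))$ over replicates,
defined only at interior $K$ with positive replicate sd. The Bayesian
MCMC itself is out of scope; assignments for the cross-tabulation come
from an external run or from thresholding a structure axis (PCA or
EigenGWAS eigenvector 1), which the tests use as a documented surrogate.

## Differentiation

`wc_fst()` implements the Weir–Cockerham (1984) two-level moment
estimator from per-group allele frequencies, observed heterozygosities,
and called sample sizes, returning the variance components $a$ (among
populations), $b$ (among individuals within), $c$ (within individuals),
and $\theta = a/(a+b+c)$. Negative per-locus components are retained in
sums — clamping would bias the multilocus aggregate — and per-locus
$\theta$ may be negative. The multilocus estimate is the ratio of sums
$\sum a / \sum(a+b+c)$, not the mean of per-locus ratios; the two differ
whenever locus denominators differ, and only the ratio of sums is the
standard consistent aggregate.

Sliding windows (default 100 kb window, 10 kb step) tile each
chromosome from position 1; a locus at position $P$ belongs to every
window $[s, s + 100\,000)$ with $s \le P < s + 100\,000$. Window
$\theta$ is again a ratio of sums over member loci. The window anchor is
implementation-defined in the tools this mirrors, so the package fixes
and documents its own convention. Outlier windows are those with
$\theta$ at or above the $k$-th largest value, $k = \lceil n \cdot
\text{top fraction} \rceil$ (default 5%), with all cutoff ties included.

AMOVA is the two-level distance-based analysis on squared Euclidean
distances between dosage vectors, normalised per pairwise-complete
locus. Variance components follow the standard sums-of-squares
partition; $\Phi_{ST} = \sigma^2_a/(\sigma^2_a + \sigma^2_w)$, and the
permutation P-value is the add-one-corrected fraction of group-label
permutations with $\Phi_{ST}$ at least the observed value (default
1,000 permutations, seeded). On fully observed inbred panels
$\Phi_{ST}$ and the multilocus Weir–Cockerham $\theta$ agree closely
(the suite checks within 0.01).

## Selection scan

Three statistics, by design partially redundant — concordance across
them is itself evidence:

1. **Allele-frequency t statistic.**
   $t = (f_1 - f_2)\big/\sqrt{(\tfrac{1}{2n_1} + \tfrac{1}{2n_2})\,
   f_{exp}(1-f_{exp})}$ with
   $f_{exp} = (f_1 n_1 + f_2 n_2)/(n_1+n_2)$. The reference distribution
   is Student t with $2n_1 + 2n_2 - 2$ df (allele counts minus two); at
   these sample sizes the t and normal references agree to printing
   precision except in the extreme tail, so both are exposed and the df
   is a parameter rather than a baked-in convention. All
   tail probabilities are evaluated in log space
   (`pt(..., log.p = TRUE)`), so $-\log_{10} P$ beyond the
   double-precision underflow point (~308) remains finite and accurate;
   the suite pins values against 60-digit arbitrary-precision references.
   Note the statistic's variance term assumes $2n$ independent alleles;
   for near-fully inbred material the effective allele count is closer to
   $n$, so the test is mildly anti-conservative — visible as a stray
   borderline locus per few thousand at the $10^{-6}$ threshold under a
   null simulation with inbreeding 0.95.

2. **Population-specific alleles.** An allele with frequency exactly 0
   in one pool, positive in the other, and a t-test P below 0.001. Both
   alleles of each locus are examined, so ref-allele specificity is
   detected symmetrically. The significance gate is what keeps
   singletons (frequency $1/2n$) out.

3. **EigenGWAS.** (i) GRM from standardised dosages
   $z = (d - 2p)/\sqrt{2p(1-p)}$; (ii) top eigenpairs; (iii) per-locus
   regression of the focal eigenvector (default the first, the axis of
   two-pool divergence) on dosage, $\chi^2 = (\hat\beta/se)^2$, genomic
   control $\lambda_{GC} = \text{median}(\chi^2)/0.4549$, corrected
   P-values from $\chi^2/\lambda_{GC}$ on 1 df in log space.

   The association step is leave-one-chromosome-out (LOCO) by default:
   the eigenvector tested against each chromosome's loci is recomputed
   from all other chromosomes. This matters. A global eigenvector is a
   linear combination of the very loci being tested, which inflates the
   null median $\chi^2$ by the GRM's top eigenvalue — about
   $(1+\sqrt{n/m})^2$ even with no structure at all (about 1.7 at
   $n/m = 0.1$), so $\lambda_{GC}$ would conflate self-fitting with
   structure. LOCO removes the self-fit term (the same reasoning as
   proximal-contamination avoidance in mixed-model association), leaving
   $\lambda_{GC} \approx 1$ under the null and interpretable as
   divergence otherwise. `loco = FALSE` restores the global path.

Candidates are ranked by the best (minimum) of the three per-statistic
ranks, ties broken by (chromosome, position), and can be annotated with
user-supplied QTL intervals (half-open containment). The curation of
QTL literature itself is out of scope; intervals are plain BED-like
input.

## The synthetic generator

`simulate_panel()` draws, per locus, an ancestral frequency
$p \sim U(0.05, 0.95)$ and two population frequencies
$\sim \text{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$ — the Balding–Nichols
model, chosen because its single parameter *is* the expected
$F_{ST}$, which keeps recovery targets analytic. Defaults are the study
conditions the package is built to emulate: $n_1 = 277$, $n_2 = 300$
diploids, 5,195 loci on 20 chromosomes of 50 Mb, background
$F = 0.1933$ (the estimated between-pool $F_{ST}$), inbreeding 0.95
(cultivar panels show observed heterozygosity near 0.07), 5% admixed
individuals (the observed cross-assignment rate is ~6–7%), 3%
missing calls (panels are filtered at 20%), and 50 planted selected
loci at $F = 0.8$.

Two modelling notes:

* **Planted loci are conditioned on realized divergence.** At
  $F = 0.8$ the Beta draws are strongly U-shaped, and two *independent*
  draws fix the *same* allele about half the time — a planted "outlier"
  with no realized signal, which no scan could or should recover. A
  planted locus models selection pulling the pools toward opposite
  alleles, so its frequency pair is redrawn until $|p_1 - p_2| > 0.5$.
  Background loci are never conditioned.
* **No linkage disequilibrium is simulated.** Loci are exchangeable
  given their chromosome assignment; LD decay behaviour is exercised on
  separately constructed correlated fixtures in the tests. Passing tests
  therefore demonstrate correctness of the estimators under the
  two-pool drift model, not robustness to real LD structure, ascertainment
  bias of chip markers, or call-error processes.

Genotypes are fully inbred calls ($2 \times$ Bernoulli) with probability
equal to the inbreeding coefficient, Hardy–Weinberg binomial draws
otherwise; admixed individuals use the 50/50 mixture frequency at every
locus while keeping their nominal label. Everything is reproducible from
one integer seed, and `write_fixture()` round-trips through the VCF
reader byte-identically.

## Problem sizes and numerical choices

The test suite runs its recovery checks at 5,000 loci × 577 samples
(the study scale — a few seconds each with vectorised linear algebra)
and its calibration loops at a few hundred samples; these sizes were
chosen so that Monte-Carlo error is comfortably below the tolerances
being asserted (e.g. multilocus $\theta$ within ±0.01 of the generating
$F$). Degenerate inputs are handled explicitly rather than by NaN
propagation: monomorphic loci are excluded from FST sums, the GRM and
the LD pair set; all-missing loci are flagged undefined; zero pooled
variance in the t statistic can only occur with $f_1 = f_2$ and reports
$t = 0$, $P = 1$; sample pairs sharing no called locus are an error in
strict mode and `NA` otherwise.

## Known limitations

* The AMOVA is two-level only (no hierarchical region/population
  nesting).
* The t statistic inherits the $2n$-allele variance assumption discussed
  above; with near-complete inbreeding its P-values are mildly
  anti-conservative. Effective sample sizes and df are exposed as
  parameters rather than silently adjusted.
* Composite-LD $r^2$ and haplotype $r^2$ diverge for outbred
  heterozygous material; the default is appropriate for inbred panels.
* STRUCTURE-style admixture inference is not reimplemented; only its
  log-likelihood output is post-processed.
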