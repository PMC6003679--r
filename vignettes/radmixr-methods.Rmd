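---
title: "Methods: species boundaries from RAD/GBS loci with radmixr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: species boundaries from RAD/GBS loci with radmixr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radmixr)
```

## The problem

Recently radiated plant groups — the motivating case is a rainforest tree
radiation where dozens of described species collapse into a handful of
genomic clusters — are hard to delimit because lineages are young,
incompletely sorted, and still exchanging genes. Reduced-representation
sequencing (RAD/GBS) gives thousands of short (~75 bp) loci across
samples, but with heavy, uneven missingness and a real risk of paralog
contamination. `radmixr` implements the analysis layer between an
assembled locus set and species-level conclusions: filtering, SNP
extraction, introgression tests, quartet species trees, clustering-run
summarization, and conversion of coalescent parameters to natural units —
plus a coalescent simulator so every stage can be exercised on data with
known truth.

## Locus model and filters

A locus is a short multiple alignment of diploid consensus sequences;
heterozygous sites carry two-fold IUPAC codes (R, Y, S, W, K, M). A
two-fold code contributes both alleles at dosage one each; three- and
four-fold codes, `N` and `-` are treated as missing at that site, which
matches the consensus semantics of RAD assemblers. A sample without data
at a locus is simply absent from its alignment block.

The filters mirror standard assembly practice:

* `trim_edges()` (default 5 bp) removes terminal alignment positions
  where alignment error concentrates.
* `filter_max_snps()` (default ≤ 10 SNPs) removes over-variable loci —
  the signature of under-split paralog clusters. A "SNP" is a variable
  column among non-missing characters after ambiguity expansion.
* `filter_shared_hets()` (default ≤ 4 samples) removes loci where one
  site is heterozygous in many samples at once, the other classic
  paralog signature.
* `filter_min_coverage()` produces the nested coverage tiers (min4,
  min10, min20, min30); tier results are monotone by construction and
  tested as such.
* `filter_taxon_coverage()` and `filter_min_pis()` implement the
  locus-selection rules used before coalescent model fitting: at least
  `k` individuals with data per taxon (all of them for taxa smaller than
  `k`) and a minimum number of parsimony-informative sites (an allele
  counts as "informative" when carried by ≥ 2 samples, so a heterozygote
  contributes each of its alleles once).

All filters are idempotent, append one provenance line, and are checked
against naive per-column loop oracles in the test suite.

SNP extraction keeps biallelic columns only; columns with three or more
observed alleles are dropped and counted (the downstream statistics are
defined on biallelic patterns). The reference allele at a site is the
lexicographically smallest observed allele — a deterministic,
outgroup-independent choice; biological polarization happens in the
D-statistic, not here. Coordinates are 1-based internally (the R
convention) and in VCF output. `sample_unlinked_snps()` draws one site
per locus uniformly, the standard preparation for model-based clustering
which assumes unlinked markers.

## Pooled-frequency ABBA-BABA D-statistics

For a four-group test (((P1, P2), P3), O) each usable biallelic site
contributes

$$\mathrm{ABBA}_j = (1-\hat p_{1j})\,\hat p_{2j}\,\hat p_{3j}\,(1-\hat p_{4j}),
\qquad
\mathrm{BABA}_j = \hat p_{1j}\,(1-\hat p_{2j})\,\hat p_{3j}\,(1-\hat p_{4j}),$$

$$D = \frac{\sum_j(\mathrm{ABBA}_j - \mathrm{BABA}_j)}
           {\sum_j(\mathrm{ABBA}_j + \mathrm{BABA}_j)},$$

where $\hat p_{ij}$ is the derived-allele frequency of pool $i$ at site
$j$. Gene flow between P3 and P2 inflates ABBA ($D>0$); between P3 and
P1 it inflates BABA ($D<0$).

Design choices that the literature leaves open, resolved here:

* **Polarization.** The derived allele is the minor allele in the
  outgroup pool. At an exact 50:50 outgroup tie the reference allele is
  used; the $(1-\hat p_4)$ factor already downweights
  polymorphic-outgroup sites symmetrically, so the tie rule has no
  leverage.
* **Usability.** A site is used when every pool has at least one called
  allele; heterozygotes contribute each allele at dosage one half.
* **Significance.** The bootstrap resamples *loci* (not sites) with
  replacement, 1000 replicates by default, respecting within-locus
  linkage; $Z = |D|/\mathrm{sd}_{boot}$ (the unsigned convention — a
  negative D with a large positive Z), and a test is flagged significant
  when $Z$ exceeds 3.5 bootstrap standard deviations, exposed as
  `z_threshold`.
* **Degeneracies.** Zero ABBA+BABA mass is reported as an undefined D
  (never a silent 0); a bootstrap replicate with zero mass is redrawn
  and counted; zero bootstrap SD with nonzero D reports an infinite Z
  with a warning.

## Quartets and the supertree

Each 4-set of samples is resolved by the SVD flattening criterion: the
site-pattern counts over the quartet's jointly-called sites form a
$4^4$ tensor; for each of the three splits the corresponding
$16 \times 16$ flattening has rank ≤ 10 under the multispecies
coalescent when the split is true, so each split is scored by
$\sqrt{\sum_{i>10}\sigma_i^2}$ and the minimum wins. This uses every
site at which just the four samples are called, which is what makes the
approach robust to GBS missingness. Heterozygotes are resolved to one
allele uniformly at random under the run seed (frequency-preserving in
expectation, reproducible); quartets whose two best scores tie at
relative tolerance 1e-9 are marked unresolved and contribute no
supertree weight.

Quartets are amalgamated by recursive max-cut: a taxon set is split by
the bipartition that (lexicographically) minimizes violated quartets
then maximizes satisfied ones, with the far side contracted to a
representative taxon in each recursive call. Cut search is exhaustive up
to 15 taxa per level and a 20-start single-move hill climb above. When
the input is the complete induced quartet set of a binary tree, the only
nontrivial zero-violation cuts are that tree's splits, so the recursion
returns the tree exactly — that contract (round-trip Robinson–Foulds
distance 0) is the correctness test, rather than byte-equivalence with
any particular external amalgamation tool whose weighting scheme is not
published. Bootstrap support resamples loci with replacement, draws one
SNP per resampled locus, rebuilds the tree, and annotates each internal
edge of the full-data tree with the percentage of replicates containing
its bipartition.

## Clustering-run summarization

Replicate ancestry estimates with the same K differ by label switching
and by convergence failures. `convergence_filter()` excludes replicates
whose log-likelihood variance exceeds 100× the minimum at that K. The
source description of "variance in log likelihood scores" is ambiguous
between within-run and across-run variance; both are implemented
(`mode = "trace"`, the default, uses the within-run variance of the
post-burn-in trace; `mode = "summary"` uses each replicate's squared
deviation from the per-K median of mean lnL when only summary values
exist) and neither is asserted to be the original. `align_replicates()`
finds, per replicate, the column permutation best matching the first
kept replicate by exact assignment (exhaustive over permutations for
K ≤ 8, greedy above — exact in the permutation-plus-noise regime the
tests cover) and averages the aligned matrices. `evanno()` computes
$\Delta K = |L(K+1) - 2L(K) + L(K-1)| / \mathrm{sd}(K)$ with the ends of
the K range undefined and a flat profile reported as indeterminate
rather than forced to a best K.

## Coalescent units

Multispecies-coalescent parameters are dimensionless in sequence units:
$\tau$ (divergence) and $\theta = 4 N_e \mu$ are expected substitutions
per site. With a per-generation per-site mutation rate $\mu$ and a
generation time $g$,

$$t = \frac{\tau}{\mu}\, g \ \text{years}, \qquad
N_e = \frac{\theta}{4\mu} \ \text{individuals}.$$

Uncertainty in $\mu$ and $g$ is propagated by Monte Carlo: gamma priors
are parameterized by their central 95% interval (defaults 8–16 years
and 5e-8–5e-7 per site per generation, the latter read as ascending
bounds although sources sometimes print the interval descending), with
the gamma shape recovered by monotone root finding on the quantile
ratio — reproducing the interval bounds to 1e-6 relative error.
Posterior draws and prior draws are paired independently, point-mass
priors are supported for closed-form checks, and the reported interval
is the equal-tailed 2.5–97.5 percentile interval in millions of years
(τ) or thousands of individuals (θ).

## The simulator: what it emulates, and what it does not

`simulate_loci()` draws one genealogy per locus under the structured
coalescent on an ultrametric species tree with branch lengths in
generations: $k$ lineages in a population of diploid size $N$ coalesce
at rate $k(k-1)/(4N)$; at a speciation time daughter populations merge;
at a pulse (donor, recipient, time, γ) each recipient lineage moves into
the donor with probability γ, backwards in time — the forward reading is
that a fraction γ of the recipient's genome traces to the donor.
Mutations are Jukes–Cantor finite-sites; multiple hits are tolerated and
handled by the biallelic-site policy downstream. Two haplotypes per
diploid collapse to an IUPAC consensus, and whole loci drop out per
sample at the configured rate. `simulate_hybrid()` builds an F1 by
pairing one allele from each parent pool per site, so fixed differences
become heterozygous sites. The engine is validated against the neutral
closed form (mean per-site diversity $= 4N_e\mu$ within 3 standard
errors) rather than against an external simulator.

Default study conditions, fixed before the validation experiments were
run: the four-population D-test demography uses $N_e = 5\times 10^4$
diploids on every branch, split times of 1, 2 and 4 coalescent units
(of $2N_e$ generations), a pulse midway along the P2 branch,
$\mu = 2\times 10^{-8}$ per site per generation (per-site
$\theta = 0.004$, a few SNPs per 75 bp locus), 4 diploids per ingroup
population and 2 outgroup diploids, 2000 loci, and a 30% per-sample
locus dropout — the low end of the 33–67% missingness regime typical of
published GBS assemblies, so that min4-style filtering leaves usable
data at desk scale. Validation uses 20 seeds per experiment; property
tests use smaller sizes (200–800 loci, 3–12 seeds) chosen to keep the
default suite fast while the acceptance checks run the full conditions.

What the simulator does **not** emulate: sequencing error and read-level
artifacts, allele dropout correlated with divergence (a real RAD
phenomenon that biases missingness non-randomly), selection, linkage
between loci, recombination within loci, and assembly-induced paralog
merging. Passing tests therefore demonstrate the statistical machinery
under a clean coalescent regime, not robustness to every artifact of
real libraries — the filters exist precisely because real assemblies
violate these assumptions.

## Numerical choices and degenerate inputs

* Tie-breaking: quartet score ties → unresolved; outgroup 50:50 ties →
  reference allele treated as derived; equal max-cut scores → first
  valid cut in mask order (deterministic).
* `gamma_from_ci()` root-finds on the log-shape over a very wide bracket
  and verifies the reproduced quantiles, erroring loudly rather than
  returning a drifted solution; near-degenerate intervals (ratio
  1.001) are part of the test suite.
* Empty inputs error explicitly (`missingness()` on an empty set, D on
  zero usable sites, supertree on < 4 taxa); an all-missing replicate in
  tree bootstrap is redrawn and logged.
* All stochastic functions take a seed, save and restore the caller's
  RNG state, and are bit-reproducible; a battery or table run derives
  per-item seeds as `seed + i - 1`.

## Known limitations

* The pooled-frequency D treats sites within a locus as exchangeable;
  the locus bootstrap absorbs within-locus linkage but not between-locus
  correlation (absent in the simulator, possible in real data).
* The supertree heuristic is exact on compatible complete quartet sets
  and tested to tolerate 10% random quartet noise at 12 taxa, but offers
  no global optimality guarantee on heavily conflicting inputs; the
  conflict report exposes how much input weight the returned tree
  violates.
* The clustering summarizer consumes replicate outputs; it does not
  implement the admixture-model MCMC itself, and the Evanno criterion
  inherits its known inability to evaluate K = 1.
* Unit conversion assumes the posterior is expressed per site and the
  mutation rate per site per generation; rate priors are shared across
  nodes (no branch-specific rates).
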