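---
title: "Evaluating low-density-to-sequence imputation in a pedigreed breeding population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating low-density-to-sequence imputation in a pedigreed breeding population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Genomic selection in a breeding programme improves with marker density, but
sequencing every candidate is not affordable in the early stages of genomic
resource development. A practical compromise is to genotype the whole
population on a low-density SNP chip, sequence a small set of nodal
individuals of the pedigree (the *reference panel*), and statistically
impute all remaining individuals from chip density up to sequence density.
Whether that imputation can be trusted — for which markers, and for which
individuals — is an empirical question that can be answered from the
reference panel alone by *leave-one-out masking cross-validation* (LOO):
each reference individual in turn has its sequence genotypes masked down to
chip density and is re-imputed from the others, so imputed and true
genotypes can be compared.

`pedimpute` implements that whole evaluation as a reusable pipeline for a
population shaped like a forest-tree breeding programme: two mating sets
(an almost-complete factorial and a multiple-pair design), about a thousand
progenies, a few dozen sequenced individuals, and a handful of unrelated
wild accessions. Because no such dataset can be redistributed, the package
carries a first-class synthetic-data generator that emulates the design,
and every stage — variant filtering, imputation, evaluation metrics,
per-SNP explanatory factors, linkage disequilibrium (LD) profiling and
annotation profiling — is exercised against it.

# The synthetic generator and what it emulates

`sim_config()` holds the study conditions. The defaults are the conditions
every test and the acceptance run use:

* **Pedigree** (`study_design()`): a 4♀ × 4♂ factorial with 14 of 16
  crosses and 413 F1; a multiple-pair set of 8♀ × 7♂ in 21 crosses with
  598 F1, two of whose dams are themselves factorial progenies; 6 unrelated
  accessions; one grandparent recorded as the single known parent of a
  factorial male. That yields 1039 distinct individuals. The sequenced
  reference of 43 comprises the grandparent, all 23 parents (including the
  two dual-role females), 13 further progenies chosen greedily so that
  every parent has a sequenced offspring, and the 6 unrelated accessions.
* **Genome scale**: 2 chromosomes × 50 Mb × 20,000 sequence-density sites,
  with `chip_fraction = 0.005` — the ~1:200 chip/sequence marker ratio of
  the emulated programme (7.5 K chip markers against ~1.4 M sequence
  variants). This desk scale keeps a full 10-replicate evaluation inside a
  test run; the site count is a size knob, not part of the science.
* **Founder haplotypes**: per-site alternative-allele frequencies are
  Beta(0.4, 0.4) (a U-shaped site-frequency spectrum, as sequence data
  shows), and each haplotype follows a first-order latent chain: the latent
  uniform is copied from the previous site with probability
  `ld_rho = 0.998`, else redrawn. This gives exactly `D' = ld_rho^k` in
  expectation over `k` intervening sites — a tunable, monotone LD decay
  (half-decay ≈ 0.9 Mb at the default site spacing, strong LD of the kind a
  closed breeding population shows) without the cost of a coalescent
  simulator. A coalescent demography is deliberately out of scope: the
  imputation strategy only requires that LD exist and decay.
* **Transmission**: Haldane crossovers — Poisson with mean
  `recomb_rate × L(Mb) / 100` per gamete (default 2 cM/Mb), breakpoints
  uniform, no interference. Gene dropping is therefore Mendelian-consistent
  at every site by construction, which the filter tests exploit.
* **Chip**: per chromosome the genome is cut into one bin per requested
  marker and the highest-MAF site with MAF ≥ `maf_floor = 0.1` per bin is
  taken — a "carefully selected set of highly polymorphic, regularly
  spaced" markers. `maf_floor = 0.1` is our choice; the emulated chip's MAF
  distribution is not published. Bin widths are jittered with coefficient
  of variation `chip_density_jitter = 1`, because a gene-enriched
  production array is markedly uneven along the genome and the
  chip/sequence density ratio can only explain imputation quality if it
  varies.
* **Depth and quality**: per-individual mean depth is a shifted gamma
  bounded to 4–52X with mean 13X; per-cell depth is Poisson around it;
  QUAL is Gamma(shape 4, scale 15), so ~14 % of sites fall below the
  Phred-30 filter and the quality step has work to do.
* **Errors**: sequence genotypes are flipped with probability
  `error_rate = 0.005`, independently for the two simulated caller sets
  (standing in for a joint and a per-individual caller). The chip carries
  `missing_rate_chip = 0.01` missingness and, by default, no genotype
  errors (`chip_error_rate = 0`): a production array that survived design
  QC is essentially error-free, and its stated residual imperfection is the
  ~1 % missing data that the first-round imputation removes. With chip
  errors at the sequence rate, the strict any-trio Mendelian chip QC would
  discard nearly every marker across a 1000-progeny pedigree — clearly not
  the situation of the emulated programme.

What the generator does **not** model: reference-genome mapping bias,
genotype-likelihood-level uncertainty, statistical phasing (synthetic data
is phased by construction), selection, or demographic history. Tests that
pass on this generator show that the pipeline's statistics and algorithms
behave as specified under a realistic breeding design; they do not certify
accuracy levels on any real dataset.

# Filtering

`run_filter_cascade()` applies, in order: the quality/allele filter
(QUAL ≥ 30, mean depth ≥ 2, 2–3 alleles, no missing genotypes) to each
caller set, monomorphism removal (including all-alternative sites that
differ only from the external reference genome — triallelic records are
kept because mapping to another species' genome can leave two alternative
alleles and no reference allele), positional intersection of the two
callers, a per-site genotype-concordance filter (fraction of samples with
identical unordered allele pairs, kept at ≥ 0.95, genotypes taken from the
designated caller), and the Mendelian-segregation filter. The Mendelian
rule works on allele identity, not dosage, so triallelic sites are handled
exactly: a trio is consistent when the child's two alleles can be split so
that each parent carries one of them; duos require one shared allele; any
missing member makes the trio uninformative at that site (conservative —
missing data cannot trigger removal). The chip gets its own QC:
missingness > 90 % (strict) then the same Mendelian filter. Every step is
idempotent, and the report preserves the in − removed = out accounting at
each step.

# Imputers

Three imputers share one interface (`imputation_task()` →
`imputation_result`):

* `fill_chip_missing()` — the first-round chip pre-pass: unambiguous
  Mendelian deduction from parents (and from offspring when they force both
  alleles), iterated to a fixed point, then within-chip allele-frequency
  fill.
* `frequency_fill_impute()` — the lower bound: each allele drawn
  Bernoulli(p) from the reference alternative-allele frequency. Allele
  draws (not genotype draws) are the default because the mode it mirrors is
  frequency-based at the allele level; a genotype-frequency variant sits
  behind `by_genotype = TRUE` since the chance term of the corrected
  concordance is defined on genotype frequencies.
* `family_ld_impute()` — a windowed pedigree/LD imputer, a documented
  stand-in for pedigree-aware rolling-window software whose internals are
  not published. Per chromosome it (1) phases the target's chip sites where
  parent genotypes allow, (2) slides windows of `window_sizes = c(64, 16,
  4)` chip markers (largest first, `overlap = 0.5`) and searches reference
  haplotype *pairs* that exactly match the target's dosages and known
  phase, relatives first (parents, then grandparents, then all), and copies
  the matched haplotypes' sequence alleles over the window span, (3)
  resolves conflicts between overlapping windows by majority vote, ties by
  the smallest window size, then by relative-derived votes, and (4)
  frequency-fills anything never covered. Two design details matter
  numerically: the first and last window of each size extend their span to
  the chromosome ends (otherwise sites outside the outermost chip markers
  could never be copied), and within a priority tier candidates are tried
  in order of how often they already matched for this target. That
  *continuity* preference keeps the two haplotype slots consistent across
  windows; without it, short windows can out-vote a correct
  whole-chromosome match with copies taken from the other parent, and the
  guarantee that a child of two reference parents is recovered exactly
  under zero recombination would be lost. Matching is exact (tolerance 0);
  the window sizes and overlap are configuration, not anchored estimates,
  because the emulated study does not report the ones it used.

`run_external_imputer()` adapts any command-line imputer through
VCF/pedigree files and placeholder substitution, so the built-in stand-in
can be swapped for the real thing outside this sandbox.

# Evaluation metrics

For each LOO fold the held-out individual's imputed dosages are compared
with the truth. Per individual and chromosome: `Propi`, the proportion of
sites with identical dosage (an allele-level variant giving half credit to
one-allele matches is available via `mode = "allele"`; dosage equality is
the default match definition), and `Cori`, the Pearson correlation of
dosage vectors (undefined and reported NA when either vector is constant).
Per SNP across individuals: `Props` with `Ni` the number of individuals
with called truth, `Cors` (frequently undefined at rare sites — the count
is reported), and the chance-corrected

`cProps = (Props − chance) / (1 − chance)`,
`chance = Σ_g p_ref(g) · q_val(g)`

with reference genotype frequencies taken from the reference-panel truth
and validation frequencies from the imputed genotypes of the evaluated
folds. `cProps` is not floored at zero — worse-than-chance sites stay
negative — and is undefined when both panels are fixed. The random-fill
imputer run through the identical LOO scheme yields `lbPropi` and
`lbProps`. Genome-wide per-individual values are site-weighted means of the
per-chromosome values. High-quality SNPs are selected with strict
`Props > 0.90` **and** `cProps > 0.80`; sites with undefined `cProps` are
excluded and counted.

The 6 unrelated accessions are reference members like the others and are
evaluated as LOO folds; an `extra_targets` mechanism can impute additional
non-reference individuals, once, against the full reference (re-imputing an
identical task once per fold would only repeat the same computation).

# Per-SNP factors

`snp_factors()` computes FreqOri (minor allele frequency on the reference
truth), hweOri (exact Hardy–Weinberg test), DEPTH (summed site depth), QUAL
(pass-through), and RatioDensity (chip/sequence marker counts in
non-overlapping 500-kb windows anchored at coordinate 1 per chromosome —
the anchor is our fixed choice, stated for reproducibility; windows are
`[k·500kb + 1, (k+1)·500kb]`, and chip counts are taken after chip QC).
The HWE test is the standard two-sided exact test conditional on allele
counts (not mid-p): probabilities of all compatible heterozygote counts are
computed by the numerically stable recurrence from the distribution's mode,
and the p-value sums those not exceeding the observed count's probability
(with a 1 + 1e−12 slack against ties lost to floating point); monomorphic
sites return 1. `assemble_factor_table()` joins factors to the per-SNP
quality table and merges an optional externally computed per-SNP LD weight.
Factor-importance inference (random-forest wrappers, PCA) is out of scope;
`factor_ranking()` provides an in-package Spearman ranking for the
qualitative check that the density ratio is the dominant marker-level
covariate.

# Linkage disequilibrium

`dprime()` implements Lewontin's D′ from haplotype frequencies, reporting
|D′| (the sign only reflects allele labelling); monomorphic columns are
undefined. `pairwise_ld()` enumerates within-chromosome pairs up to a
distance cap, optionally restricted to the high-quality SNP selection, and
`weighted_mean_dprime()` bins pairs into consecutive 500-kb distance
windows with the mean weighted by the product of the two MAFs. That
weighting is our reading of "weighted by frequencies" — the MAF product is
the only frequency quantity attached to a pair elsewhere in the analysis —
and a `uniform` option is provided because the original weighting is not
defined precisely. `maf_product_profile()` grids weighted mean D′ over
distance × MAF-product bins.

A known, deliberate limitation: in this generator the *true* D′ equals
`ld_rho^k` regardless of allele frequencies, but the finite-sample estimate
of |D′| is inflated at low MAF (absent haplotype classes force the estimate
to 1). The chip is by construction the high-MAF subset, so the imputed
sequence panel — even restricted to well-imputed sites — shows *higher*
estimated D′ than the chip at matched distances; the small attenuation
that residual imputation errors cause at well-imputed sites does not
reverse that (computing D′ on the true haplotypes at the same selected
sites shows the gap is compositional, not an imputation artefact). A study
that phases statistically and imputes ~1000 distantly related targets adds
switch and imputation noise this generator does not model; its observed
drop of sequence-panel LD below chip LD should therefore not be expected
from these simulations, and the corresponding acceptance check documents
exactly that.

# Annotation

`read_gene_models()` parses GFF3 transcripts (deriving UTRs from exon/CDS
geometry when absent); `classify_region()` assigns one region label per
position with precedence exonic > splicing > UTR > intronic >
upstream/downstream > intergenic, `splice_bp = 2` on the intron side
(`exonic;splicing` on the exon side), `upstream_bp = 1000` strand-aware
flanks, and compound labels (`UTR5;UTR3`, `upstream;downstream`) where
opposite-strand transcripts overlap. `classify_coding_effect()` translates
SNVs strand-aware through the standard codon table (synonymous /
non-synonymous / stop gain / stop loss) and classifies simple indels by
length modulo 3; complex substitutions are counted `unclassified`.
Percentages are reported against both all positions and annotated
positions, since the two denominators answer different questions.

# Numerical choices and problem sizes

All randomness flows from a single integer seed per entry point; derived
seeds are small fixed offsets, and the pipeline's outputs are byte-identical
across runs with the same seed. Missing genotypes are `NA`, never 0, and
every statistic skips them explicitly. Ties in the window vote are broken
smallest-window-first, then by relative-derived votes, then the cell falls
back to frequency fill. The test suite runs the full 1039-individual,
2 × 20,000-site design over 10 seeds for the qualitative checks and
reduced sizes (2,000–3,000 sites, a 72-individual design) where the
property under test — determinism, filter accounting, oracle equality — is
scale-free. Exact-arithmetic checks (metrics, HWE, D′, Mendelian rule) are
asserted to 1e−12 against independent enumeration oracles.
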