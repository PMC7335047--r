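---
title: "Methods: expansion detection, duplicate typing, pan-genomes, selection and clade signatures"
author: "benthoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expansion detection, duplicate typing, pan-genomes, selection and clade signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benthoscan)
```

benthoscan implements the comparative-genomics computations used to
characterise the gene repertoire of a benthic diatom and its population:
gene-family expansion detection, tandem/block/dispersed duplicate typing,
pan-genome classification across resequenced strains, per-gene
nucleotide-diversity estimation ($\pi_N$, $\pi_S$), clade homology
signatures, and hypergeometric family enrichment with pleiotropy and
expression-divergence calls. Every stage can be exercised on synthetic
inputs with planted ground truth, so the whole pipeline is testable
without sequencing data. This vignette records the models, the parameters
that matter, and the design choices made where the underlying definitions
were genuinely open.

## Family expansion from copy-number profiles

The input is a families $\times$ species copy-count matrix. A family is
called expanded in the focal species when

* the population variance of its copy counts across all included species
  exceeds 2, and
* the focal species' standard score exceeds 3.

The standard score is computed leave-one-out:
$z = (c_\mathrm{focal} - \bar c_\mathrm{others}) /
\max(\mathrm{sd}_\mathrm{others}, 1)$, with the population standard
deviation over the non-focal species and a floor of one copy. The
leave-one-out form is a deliberate choice: if the focal species is
included in the mean and standard deviation, the largest attainable score
for a single-species outlier in an $n$-species profile is $\sqrt{n-1}$
(population sd), which is exactly 3 at $n = 10$ and below 3 for the nine
included diatom genomes this criterion is designed for — the stated
threshold could never fire. The sd floor handles constant backgrounds
(sd 0) without producing infinite scores; one copy is the smallest
meaningful copy-number scale. Both cutoffs, and the floor, are arguments
of `detect_expansions()`. Allodiploid genomes whose counts are doubled
should be passed through `excluded=`.

```{r}
m <- matrix(c(rep(1, 8), 9), nrow = 1,
            dimnames = list("F1", paste0("sp0", 1:9)))
detect_expansions(m, focal = "sp09")
```

Family ages (`assign_age_classes()`) are the deepest taxonomy stratum
containing every species with at least one copy — standard
phylostratification; a family confined to one species is
species-specific. Zero counts are treated as absence, not missing data,
because family tables encode absence as zero.

## Duplicate typing

Tandem arrays (`find_tandem_arrays()`) are maximal transitive chains of
same-family, same-scaffold genes whose gene-order ranks differ by at most
`tandem_gap` (default 15, read as "rank difference $\le$ 15"; the
parameter is exposed).

Collinear blocks (`find_collinear_blocks()`) require at least
`min_anchors = 3` anchor pairs, where an anchor joins two genes of one
family, consecutive anchors may be separated by at most `gap_size = 15`
genes on both scaffolds, and nearby chains on one scaffold pair are
merged under `cluster_gap = 15`. Three details are this package's own
choices, mirroring standard collinearity-detector practice:

* tandem arrays are collapsed to their lowest-rank member before anchor
  enumeration, so a single array cannot fabricate three anchors and pass
  `min_anchors` spuriously;
* chains are extracted best-first — the longest valid chain (dynamic
  programme over anchors sorted along one axis, both orientations
  allowed, strictly monotone on both axes), ties broken by smaller total
  rank span then lexicographic anchor identifiers; extracted anchors are
  removed and the search repeats;
* merging close same-orientation chains happens *before* the
  `min_anchors` filter, which makes the retained block count monotone in
  `min_anchors`. Within-scaffold self-comparison is permitted (excluding
  the self-diagonal), so duplicated segments on one scaffold are found.

The test suite holds this implementation to exact agreement with an
exhaustive-search oracle (all chains enumerated by depth-first search) on
100 seeded catalogs.

`classify_duplicates()` applies the precedence tandem > block >
dispersed to multi-copy genes; family singletons are `single`; every gene
receives exactly one type.

## Pan-genome classification

Presence is called from horizontal exon coverage: a gene is absent from a
strain when coverage across all of its exons is below 5%
(`call_presence()`, threshold configurable; coverage is consumed as a
precomputed table — read alignment stays upstream). Core genes are
present in all strains; the rest is the dispensable fraction, within
which softcore genes are present in at least
$\lceil 0.95\,n_\mathrm{strains} \rceil$ strains. Two conventions matter
and are fixed here:

* softcore is reported as a labeled subset of the dispensable fraction,
  so the headline split is core vs dispensable and the core percentage
  range runs from core to core + softcore;
* the 95% cutoff is resolved with a ceiling on strain counts
  (at 49 strains, $\lceil 46.55 \rceil = 47$); whether the original
  analysis rounded up or down at this point is not documented, so the
  fraction is an argument.

`accumulation_curves()` reports mean ± sd of cumulative pan (union) and
core (intersection) sizes over random strain orderings (default 100
permutations, seeded). `dedup_de_novo_genes()` reproduces the greedy
longest-first 95%-identity deduplication used for de novo gene sets, and
`cluster_strains()` provides the coverage-profile dendrogram that should
recover population clades.

## Nucleotide diversity and selection

Sites are counted with the unweighted Nei–Gojobori scheme under the
standard nuclear code: each coding position contributes $k/3$ synonymous
sites when $k$ of its three possible single-base changes are synonymous
(mutations to stop codons count as nonsynonymous), restricted to callable
positions, so $L_N + L_S$ equals the callable CDS length exactly. The
original analysis does not name its counting scheme; Nei–Gojobori was
chosen because it is standard and verifiable against brute-force codon
enumeration.

Per SNP, "correcting for the allele frequency" is realised as the
unbiased frequency-based heterozygosity
$h = \frac{n}{n-1}\, 2p(1-p)$ with $p$ the alternate-allele frequency and
$n$ the called chromosome count at that site (multi-allelic sites use
$\frac{n}{n-1}(1 - \sum_k p_k^2)$). This is algebraically identical to
the mean pairwise difference over all $\binom{n}{2}$ chromosome pairs,
and the tests assert that identity exactly. Then
$\pi_S = \sum_\mathrm{syn} h / L_S$ and likewise $\pi_N$; the per-gene
ratio is undefined when $\pi_S = 0$. The genome-wide summary reports the
ratio two ways — ratio of means (the headline convention, giving
$0.003/0.022 \approx 0.14$ at the published averages) and mean of
defined per-gene ratios.

`compare_groups()` contrasts per-gene ratios between gene groups with
two-sided Wilcoxon rank-sum tests; `flag_positive_candidates()` takes
genes with ratio $\ge$ 1 (the cutoff defining "elevated" ratios is not
documented in the source analysis and is exposed as an argument) and
tests their enrichment in condition-upregulated sets.

## Clade signatures

From a gene $\times$ species homolog hit table with clade labels, each
gene's clade score is its hit-species count divided by the clade census
(defaults: 32 pennate, 56 centric, 18 raphid, 14 araphid, 8 benthic,
73 planktonic; ambiguous and ice-associated species stay unlabeled on the
benthic/planktonic axis). Signatures are
$\log_2(\mathrm{score}_\mathrm{numerator}/\mathrm{score}_\mathrm{denominator})$
on the pennate/centric, raphid/araphid and benthic/planktonic axes.

Zero denominators give signed-infinity sentinels, and $+\infty$ passes
the threshold: a gene absent from every species of the sister clade is
maximal evidence for clade specificity, not missing data. High-signature
calls require signature $\ge$ 3 plus a validation rule — genomic family
support for the pennate/raphid axes, at least two benthic hit species for
the benthic axis (transcriptome collections cannot prove absence).
`robustness_control()` measures, for genes flagged under a stringent hit
table, the fraction keeping a positive signature under a relaxed one.

## Enrichment and expression

A gene is expressed at TPM $\ge$ 2 in any sample and retained for
differential-expression work at CPM $>$ 1 in at least three samples.
Enrichment is the upper-tail hypergeometric probability $P(X \ge k)$
with Benjamini–Hochberg q-values over the labels tested in a run
(the source analysis says "q-value" without naming a method; BH is the
conventional realisation), requiring $q < 0.05$ and at least two hits.
Families enriched in upregulated genes under $\ge$ 7 conditions are
pleiotropic; $\le$ 2 conditions, condition-specific.

Expression divergence on a rooted family gene tree evaluates every
internal node whose two child clades both contain expressed leaves: the
node is divergent when the Pearson correlation between the child clades'
mean $\log_2(\mathrm{TPM}+1)$ condition profiles falls below 0.5, and a
family's divergence is the percentage of divergent nodes (families under
4 members are not evaluated). The node test, the pseudocount and the
cutoff are this package's construction — the original criterion lives in
supplementary material not reproduced here — so divergence output is
qualitative (direction and ordering), not a reproduction of printed
percentages. With a pseudocount of 0 on strictly positive TPM the calls
are exactly invariant to per-gene multiplicative rescaling, since a
per-gene factor only shifts the clade-mean log profile by a constant.

## The synthetic-data generators

`generate_gene_catalog()`, `generate_copy_matrix()`,
`generate_strain_matrix()`, `generate_cds_set()`/`generate_variants()`,
`generate_hit_table()` and `generate_expression()` produce every input
the pipeline consumes, with planted ground truth and all randomness
routed through a single explicit seed (the global RNG state is saved and
restored; identical seeds give byte-identical serialized outputs).
Defaults the underlying study does not specify were fixed once at values
a practitioner would call realistic and are exposed as arguments:

* copy-number background: $1 + \mathrm{Poisson}(0.5)$ — low-copy families
  with occasional duplicates; planted expansions multiply the focal
  species' count by the expansion multiplier (study condition:
  9 species, 10% planted families, multiplier 8);
* coverage: present genes draw horizontal coverage in $[0.8, 1]$, absent
  genes below 0.05; dispensable-gene losses are clade-correlated; the
  first strain is the reference with coverage 1 (study condition: 49
  strains in three clades of 16/16/17);
* allele frequencies: Beta(1,3) folded to the minor allele — a
  monotonically decreasing frequency spectrum; SNP counts per gene are
  Poisson with mean $\pi_\mathrm{target} L / E[h]$, where $E[h]$ is
  computed exactly from the Beta CDF, making the estimated $\pi$ unbiased
  for the target; synonymous SNPs are placed only at positions with a
  synonymous alternate allele (study condition: 96 chromosomes,
  $\pi_S = 0.022$, $\pi_N = 0.003$);
* CDS lengths: multiples of 3 in 300–3000 nt, keeping valid codon
  framing;
* expression: negative-binomial counts with dispersion 0.1 around
  log-normal baselines; planted (family, condition) effects multiply the
  mean by $2^{\mathrm{lfc}}$, and the differential-expression call table
  is produced by thresholding the *true* effects at
  $|\log_2 \mathrm{FC}| > 1$ — deliberately not by model fitting, which
  is out of scope;
* background gene families in catalogs are reused only beyond the tandem
  gap on a scaffold (so no unplanned tandem array can arise) and at most
  twice overall (scattered dispersed duplicates), with fresh singleton
  families elsewhere.

What the generators do *not* emulate: read-level noise, mapping bias,
assembly artefacts, annotation errors, linkage between SNPs, and
phylogenetic correlation between species in the hit tables. Passing
recovery tests therefore demonstrates the correctness of the
computations under their stated models, not robustness to every
real-data pathology.

## Problem sizes and numerical choices

The test suite runs the oracle-equivalence checks on 100 seeded catalogs
of 40 genes, recovery checks over 5 seeds at the study conditions above
(with 100–500 genes per run), and exact-identity checks for the
$\pi$ estimator on up to 8 chromosomes; these sizes were chosen so the
whole suite completes in about a minute while leaving the combinatorial
oracles exhaustive. Planted-group signature recovery is judged at group
level (the group's mean signature reaching the threshold), matching how
gene sets, rather than single genes, are interpreted in practice;
per-gene flags at a (1.0, 0.1) presence contrast sit near 80%
sensitivity by construction of the binomial sampling noise, and
individual gene calls are validated separately by their exact
worked-example arithmetic.

Degenerate inputs are rejected rather than patched: fewer than three
included species for a Z-score, single-strain pan-genomes, CDS with
internal stops or broken frames, coverage outside $[0,1]$, chromosome
counts below 2 for $\pi$. Ties in the de novo deduplication length order
fall back to lexicographic gene order, making the greedy clustering
deterministic.
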