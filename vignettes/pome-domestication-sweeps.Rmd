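---
title: "Methods: sweep scanning, insertion-allele surveys and association in pomesweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sweep scanning, insertion-allele surveys and association in pomesweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pomesweep)
```

`pomesweep` implements the population-genomic inference chain used to argue
that weak MYB alleles — a transposable-element insertion truncating an apple
MYB proanthocyanidin (PA) regulator, and a 57-bp promoter insertion silencing
the pear *MYBPA1* ortholog — were selected when bitter wild pomes were
domesticated into palatable fruit. This vignette documents the statistical
models, the tunable parameters, the synthetic-data generator, and the
numerical conventions the package commits to, including the places where
the underlying methods leave genuine design freedom.

## Windowed diversity and the θπ ratio

The sweep statistic is the ratio of windowed nucleotide diversity between a
wild and a cultivated pool. For a window of length $L$ bp,

$$\hat\pi = \frac{1}{L} \sum_{\text{sites } j \in \text{window}} h_j,
\qquad
h_j = \frac{n_j^2 - \sum_i n_{ij}^2}{n_j (n_j - 1)},$$

where $n_{ij}$ is the count of allele $i$ among the $n_j$ non-missing called
alleles at site $j$. $h_j$ is the unbiased estimator of expected
heterozygosity (the mean pairwise-difference indicator over all
$\binom{n_j}{2}$ allele pairs), so $\hat\pi$ is a per-bp rate in which
monomorphic positions count as zero — the convention of standard windowed-π
tools. Multi-allelic sites contribute their full multi-allele
heterozygosity; sites with fewer than two called alleles contribute nothing.
The test suite checks the identity between the closed form and the explicit
pair enumeration exhaustively for all biallelic configurations up to 12
alleles and on every window of a simulated study.

Windows are 50 kb advancing by 5 kb, anchored at position 1 on each
chromosome with no trailing partial window; chromosomes shorter than one
window get a single whole-chromosome window. The scan statistic is
$\theta_\pi(\text{wild}) / \theta_\pi(\text{cultivated})$ per window: large
values mark candidate domestication sweeps, where cultivated diversity has
collapsed.

Three conventions had to be fixed where common practice varies:

* **Quantile.** "Top 5%" is implemented as the nearest-rank empirical
  quantile (the $\lceil 0.95 N \rceil$-th smallest ok-ratio) with *strict*
  exceedance. For $N$ distinct ratios this calls exactly
  $\lfloor 0.05 N \rfloor$ windows; with heavy ties it degenerates safely to
  calling nothing rather than everything.
* **Zero denominators.** Windows with $\hat\pi_{\text{cult}} = 0$ are
  flagged `undefined_denominator` and excluded from the quantile rather than
  mapped to infinity, which would otherwise dominate the threshold.
* **Gene intersection.** Called windows that overlap or abut are merged into
  maximal intervals; a gene is a hit iff its overlap with the *union* of
  intervals is at least `min_overlap` (default 0.10) of the gene length,
  boundary inclusive — the minimum-overlap-fraction semantics of standard
  interval-intersection tools.

The 5% threshold is computed genome-wide (not per chromosome), and windows
are anchored at 1 with no masking of assembly gaps; both are deliberate
simplifications for reproducibility.

Site-level filters precede the scan: sites with missing-call fraction
strictly above 20% or minor allele frequency strictly below 5% are removed,
with MAF computed over non-missing alleles only (for multi-allelic sites,
the combined frequency of non-major alleles). Filters are applied jointly
over the cohort, not per pool. Both inequalities are strict, so a site at
MAF exactly 0.05 survives — the boundary semantics are pinned by tests.

## Insertion characterisation and in-silico PCR

Two allele sequences differing by one contiguous insertion are decomposed by
longest-common-prefix/suffix; the insertion is placed at the rightmost
compatible point and the target-site duplication (TSD) is the longest
$k \le 20$ for which the $k$ bases ending at the insertion point equal the
last $k$ bases of the inserted block — the footprint structure
(TSD–element–TSD) of a transposition event, like the 8-bp `TTCCTAGT`
duplication flanking the 411-bp apple element. Coding consequences are
classified by translating the mutated CDS: out-of-frame lengths are
frameshifts, in-frame insertions are scanned for a premature stop, and
promoter insertions are labelled regulatory.

Diagnostic genotyping mimics the published presence/absence PCR: a primer
pair must match the template exactly and uniquely (forward on the plus
strand, reverse-complement downstream), and the product length is the
inclusive span of the two primer sites. Exact matching is a policy choice:
the assay's information is a size difference (244 vs 655 bp in apple, 550
vs 607 bp in pear), so mismatch tolerance adds nothing at this scale. A
diploid's genotype class follows from its two allele products; any
amplification failure gives `failed`, and failed samples are excluded from
survey denominators.

Per-group allele frequencies are $p = (2 n_{\text{hom}} + n_{\text{het}}) /
2n$, reported both exactly and as percentages rounded half-up to two
decimals (the printed-table convention; base R's round-half-even would
differ at exact ties). Because the source surveys do not name their Fst
estimator, three are implemented and labelled — Hudson's two-population
estimator, Weir–Cockerham θ for two demes (using observed heterozygote
counts), and Nei's $G_{ST}$ with unweighted subpopulation means — and
results always carry the estimator label. Negative estimates are preserved;
at a locus monomorphic and identical in both groups Fst is undefined (`NA`).
Note that the parametric identities ($F = 0$ at equal frequencies, $F = 1$
at fixed differences) hold exactly for $G_{ST}$, while the finite-sample
corrected estimators deviate by $O(1/n)$ terms at equal frequencies — the
tests assert accordingly.

## MYB subgroup classification

Candidate proteins are classified against reference R2R3 MYBs (subgroups
SG5 and SG47, the PA-pathway regulators) by distance-based phylogenetics:
p-distance on the aligned proteins (gapped columns dropped pairwise),
classic Saitou–Nei neighbor joining, and bootstrap support from column
resampling. The distance model is fixed to p-distance as the simplest
defensible choice for closely related proteins; the module consumes an
existing alignment (alignment construction is out of scope). The upstream
study additionally reports a minimum-evolution test of its trees; this
package implements NJ + bootstrap only and records that as a known
discrepancy rather than guessing at the variant intended.

NJ needed two determinism commitments: ties in the $Q$ criterion are broken
on the lexicographically smallest pair of member ids (making output
invariant to input order), and negative branch lengths are clamped to zero
with a flag, keeping downstream clade logic valid. On additive matrices NJ
is exact; the suite verifies topology recovery (Robinson–Foulds = 0)
against 200 random tree metrics and cross-checks against an independent NJ
implementation.

A query is assigned subgroup X iff the smallest bipartition side containing
it and at least one reference contains only X-labelled references;
mixed-reference sides leave it `unassigned`. This is deliberately
conservative — placement between subgroups is not evidence of membership.

## Genotype–phenotype association

PA content by indel genotype class (TT / Tt / tt) is tested by one-way
fixed-effects ANOVA with Fisher's LSD at $\alpha = 0.05$: groups $i, j$
differ iff $|\bar y_i - \bar y_j| > t_{1-\alpha/2, N-k}
\sqrt{\mathrm{MSE} (1/n_i + 1/n_j)}$, with pooled MSE (standard Fisher's
LSD; the per-pair $1/n_i + 1/n_j$ form handles the unbalanced 12/18/15
design). Letters come from insert-and-absorb on the means sorted
decreasing, so sharing a letter always implies non-significance. Degenerate
inputs are defined rather than erroring: zero residual variance with equal
means gives one shared letter; classes with fewer than two observations are
excluded with a warning. Because the source figures print no numeric PA
values, association claims are property-based: type-I error calibration
(2000 null datasets, binomial 99% bounds) and separation power on
synthetic phenotypes with the observed qualitative structure
(tt ≪ Tt ≈ TT).

## The synthetic-data generator

`simulate_domestication()` produces the complete study bundle — reference
FASTA, VCF, GFF3, panel, phenotypes, truth record — from a forward
Wright–Fisher model of domestication:

* a wild population of 200 diploids evolving neutrally;
* a cultivated lineage founded by a single bottleneck generation of 50
  diploids sampled from the wild founders, which then recovers to the wild
  census size (a domestication bottleneck followed by expansion; the
  post-bottleneck size is a design choice, made so that neutral variation
  is shaped mainly by the founding event rather than erased by 200
  generations at the bottleneck size);
* additive selection $s$ (genotype fitnesses $1, 1+s/2, 1+s$; default
  $s = 0.1$) on the focal insertion allele in cultivars for 200
  generations, with a retry (up to 100, recorded) if the allele is lost;
* 30 + 30 sampled diploids written as the genotype panel.

The neutral background does not track full ancestry. The chromosome is
organised into 50-kb linkage blocks; each block carries one *anchor*
variant riding a young haplotype that carries no other variation, a
fraction (default 0.7) of the block's SNPs segregate only on the non-anchor
background (complete linkage), and the rest drift independently
(recombined). The focal block's anchor *is* the diagnostic insertion
(emitted in the VCF as a REF/ALT pair with the full 411-bp inserted
sequence, TSD included — no symbolic alleles). Fixing the insertion
therefore erases the linked fraction of the block's diversity in cultivars,
which is exactly the hitchhiking footprint the θπ-ratio scan looks for.
Anchor founder frequencies are drawn from $U(0.1, 0.4)$ — a moderate wild
insertion frequency consistent with the wild-panel surveys — and SNP
density is ~1 segregating site per kb.

Two properties of this design are load-bearing. First, every block has
identical structure, so with $s = 0$ the focal window is statistically
exchangeable with the rest of the genome: the top-5% calling rate of the
focal window is the nominal 5% by construction, which is what makes the
neutral-calibration test meaningful. Second, determinism: one seed drives
everything, and identical config + seed gives byte-identical output files.

What the generator does *not* emulate: recombination gradients (linkage is
block-wise all-or-nothing), gene flow between wild and cultivated pools
(present in the real history of both crops), population structure within
pools, and coalescent-faithful allele-frequency spectra. Passing tests on
this generator therefore demonstrate that the statistics behave correctly
under a controlled caricature of domestication, not that the pipeline would
reproduce any particular empirical scan.

Phenotypes are class mean plus Gaussian noise, defaults
$\mu_{tt} = 2, \mu_{Tt} = 9, \mu_{TT} = 10$ mg/g with SD 1.5 — a large gap
between the insertion homozygote and carriers of the functional allele,
and near-dominance of the functional allele, matching the qualitative
structure of the published association.

## Evaluation problem sizes

The power and calibration properties are evaluated on a 5-Mb chromosome
tiled with non-overlapping 50-kb windows (100 windows), rather than on the
500-kb default used elsewhere. Both choices are deliberate: 100 windows
make the genome-wide top-5% set non-degenerate under the nearest-rank rule
(5 called windows), and non-overlapping tiling makes "the window containing
the selected locus" unique and the windows mutually independent, so the
neutral calling rate has a clean binomial reference. Power is measured over
50 seeded replicates at $s = 0.1$ (bar: ≥ 80% detection) and calibration
over 200 neutral replicates (binomial test against 5% at α = 0.01). The
demonstration pipeline (`run_demo()`) keeps the 500-kb default with the
standard overlapping 50 kb / 5 kb grid, where the selected block's windows
dominate the called tail and the focal MYB-like gene surfaces among the
sweep gene hits.

## Worked example

```{r demo, eval = FALSE}
study <- simulate_domestication(simulation_config(), seed = 7)
scan  <- pi_ratio_scan(study$genotypes, study$panel)
calls <- call_sweeps(scan)
genes_in_sweeps(calls, study$genes)
autoplot(calls)

fit <- anova_lsd(study$phenotypes)
tidy(fit)
autoplot(fit, data = study$phenotypes)
```

## Known limitations

* Sweep detection is θπ-ratio only; no XP-CLR, Fst-window or
  haplotype-based statistics.
* Upstream read processing, variant calling and the associated hard filters
  are out of scope — the pipeline starts at a genotyped VCF.
* The published genome-scale sweep coordinates and the printed locus-level
  Fst values (0.30 apple, 0.18 pear) are not reproduction targets: the
  former require the original resequencing panels, and the latter are not
  derivable from the published genotype-count tables under any of the three
  implemented estimators (the package reports all three rather than
  asserting agreement).
* In-silico PCR is exact-match by design and does not model primer
  thermodynamics or amplification artefacts.
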