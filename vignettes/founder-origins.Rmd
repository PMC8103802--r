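---
title: "Tracing founding ancestral genomes in a polyploid crop: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing founding ancestral genomes in a polyploid crop: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triorigin)
```

## The problem

Modern sugarcane cultivars (*Saccharum* spp.) are high polyploids and
aneuploids with roughly 120 chromosomes. When all hom(oe)ologous
haplotypes of a genomic region are sequenced from one cultivar, they
fall into a small number of diverged groups — a large group (A, nine or
ten copies) and two minor groups (B and C, one or two copies each) —
suggesting that several distinct founding genomes were combined by
ancient hybridization and polyploidization. The question this package
addresses is: *which present-day germplasm pool contributed each
haplotype group?*

The inference chain is:

1. **Genotype calling** — presence/absence of each variant in each
   accession, from per-site allele depths against a monoploid
   reference (`call_genotype()`, `call_matrix()`, `read_ad_vcf()`).
2. **Ordination and hybrid screening** — principal coordinates of an
   SNP dissimilarity matrix separate the two germplasm pools
   (*S. officinarum*/*S. robustum* vs *S. spontaneum*); accessions
   lying between the pools are flagged as putative hybrids and excluded
   from the pool representatives (`snp_dissimilarity()`,
   `pcoa_ordination()`, `flag_intermediates()`).
3. **Reciprocal specificity analyses** — SNPs specific to one haplotype
   group are scored for which pool carries them, and SNPs specific to
   one pool are scored for which haplotype groups carry them; agreement
   between the two cross-tabulations assigns each group a founding pool
   (`group_specific_snps()`, `pool_specific_snps()`, `infer_origin()`).
4. **Divergence dating** — Nei–Gojobori (1986) synonymous substitution
   rates between homoeologous gene copies, converted to time by a
   strict molecular clock (`ks_pairwise()`, `divergence_time()`).
5. **Alignment-free phylogeny** — 30-mer profiles of the haplotype
   segments, symmetric-difference distances and a neighbour-joining
   tree confirm the grouping (`kmer_profile()`, `nj_tree()`).

A simulator of diverging founder genomes and polyploid accession
mixtures (`simulate_founders()` and friends) makes the whole chain
testable end to end with no external data, and `run_pipeline()` wires
the stages together reproducibly.

## Genotype-coding rules

At each site and accession, with total depth $d$ and alternate-read
count $a$:

* **missing** if $d < 30$;
* **variant present** if $a \ge 2$ and $a/d \ge 4\,\%$;
* **variant absent** if $a = 0$, or $a = 1$ with $a/d < 1\,\%$
  (a lone read treated as sequencing error);
* anything else is ambiguous and coded **missing**.

All four thresholds are `genotype_config()` parameters. Boundary
semantics are deliberate: depth and the presence thresholds are
inclusive, the error-frequency bound is strict, so the partition of the
$(a, d)$ grid is exhaustive and unambiguous (this is property-tested
over every cell with $0 \le a \le d \le 300$). The frequency
denominator is total site depth by default; `freq_denominator =
"refalt"` restricts it to ref + alt reads, since published descriptions
of such rules rarely state the convention.

## Specificity and the origin verdict

A SNP is **group-specific** when every group has at least one covered
haplotype at the site and the variant occurs in one or more haplotypes
of exactly one group ("all or some haplotypes from a single group" is
read as $\ge 1$; the per-SNP carrier fraction is reported so stricter
readings can be applied downstream). Uncovered haplotypes do not veto a
call, but the per-group coverage minimum must hold — this mirrors how a
variant seen where one of two group-B haplotypes lacks data must not be
declared group-A-specific.

A SNP is **pool-specific** when carried by at least `min_carriers`
(default 2) accessions of one pool and by none of the other, with data
in at least `min_pool_data` accessions of both pools (default 5; the
parameter exists precisely because sparsely covered regions warrant
relaxing it, e.g. to 3). A group-specific SNP carried by both pools is
classed *ancestral* — older than the pools' separation — and supports
neither origin.

The verdict rule: each group is assigned the pool with the strictly
greater supporting count in each informative analysis, tolerating up to
`max_exceptions` contradicting SNPs (default 1, since real data showed
a single exception); the two reciprocal analyses must agree, and ties
or larger contradictions give `unresolved`. An analysis with zero
supporting SNPs for a group is uninformative for that group rather than
contradictory. In the pool-by-group table, SNPs carried by both A and B
haplotypes support A and B alike; combinations outside {A, B, A∧B, C}
are reported in an explicit `other` column, never silently dropped.

## Ks dating

Homoeologous coding pairs are compared codon-wise (`backtranslate()`
reconstructs codon alignments from aligned proteins, expanding each
protein gap to a 3-base gap). Per codon, the synonymous site count is
the sum over positions of synonymous one-step neighbours divided by
viable (non-stop) one-step neighbours; differences of two or three
positions are averaged over all orderings of single-base steps,
excluding pathways through stop codons, with equal weights (the
classical counting method, no weighting variants). Codon columns with
gaps, ambiguity or stops are masked pairwise, not alignment-wide, so a
stop in one pair does not discard the column for other pairs. The
synonymous difference proportion $p_s = S_d/S$ is corrected for
multiple hits by Jukes–Cantor, $K_s = -\tfrac34\log(1 - \tfrac43 p_s)$,
with $p_s \ge 3/4$ a hard saturation error rather than a silent `NaN`.

Times follow the strict clock $T = K_s / (2\mu)$ with
$\mu = 6.5\times10^{-9}$ substitutions·site⁻¹·year⁻¹, reported in Mya
rounded **half-up** to two decimals (base R's round-half-to-even would
disagree with conventionally printed tables at exact half-cents; e.g. a
mean Ks of 0.0513 gives 3.946 Mya, which prints as 3.95 under half-up).
Group-pair summaries report the pooled mean over all gene pairs as well
as per-region means: published per-region/overall mean triples are not
always the arithmetic mean of the region values (they appear weighted
by unprinted gene-pair counts), so the package does not force that
reconciliation — both quantities are emitted.

The implementation is table-driven (per-codon sites and 64×64
pathway-averaged difference counts built once per session) and is
verified against an independently coded brute-force enumeration to
1e-12, plus the exhaustive identities $s + n = 3$ per codon and
$s_d + n_d = $ Hamming distance per codon pair.

## Alignment-free phylogeny

Each haplotype segment is reduced to its set of distinct 30-mers;
windows containing `N` are skipped and homopolymeric k-mers (a single
repeated base) are discarded — read as the plain meaning; a dust-like
low-complexity filter is out of scope. The pairwise distance is the raw
symmetric-difference count, matching the "number of k-mers that
differed" description rather than any logarithmic transform; a
normalized variant ($|p \triangle q|/(|p|+|q|)$) is available behind a
flag. Because the tree-building algorithm applied to such matrices is
typically unstated, neighbour joining (Saitou–Nei criterion,
Studier–Keppler updates, via `ape::nj`) is used and recorded as an
assumption; negative branch lengths are clamped to zero with the
deficit logged. Strand canonicalization is off by default (haplotype
segments are co-oriented); a flag folds reverse complements for
unoriented input.

## Ordination

The SNP dissimilarity is the simple mismatch proportion over co-typed
sites — the simplest convention consistent with presence/absence calls;
the exact formula used by legacy distance programs is generally
unstated, so this choice is recorded in output metadata. Factor
analysis of a distance table is realized as classical metric
multidimensional scaling (principal coordinates): double-centred Gower
matrix, eigendecomposition, coordinates scaled by the root of each
positive eigenvalue. Euclidean configurations re-embed exactly
(tested to 1e-9); negative-eigenvalue axes are dropped with their
magnitude reported; missing pairs are imputed by row/column means and
logged. Hybrid flagging is advisory: accessions whose first-axis
coordinate falls strictly between the two pools' envelopes are
returned as a review list, and exclusion is an explicit user decision
fed back to the specificity stage — a reproducible replacement for
drawing a rectangle on a scatter plot by hand.

## The simulator: what it emulates and what it does not

`sim_config()` encodes the study conditions:

| parameter | default | meaning |
|---|---|---|
| `mu` | 6.5e-9 | substitutions·site⁻¹·year⁻¹ |
| `t_split_ab` | 0.84e6 y | (A,B) split |
| `t_split_abc` | 1.29e6 y | ((A,B),C) split |
| `t_split_ref` | 0.34e6 y | reference–A pairwise divergence |
| `genome_length` | 100 kb | simulated segment |
| `pool_sizes` | 5+3 vs 8 (+1 cultivar) | accessions per class |
| `ploidy_spec` | see below | haplotype multisets |
| `within_pool_theta` | 0.002 | within-pool variant site fraction |
| `depth_mean`, `depth_dispersion` | 100, 0.1 | negative-binomial depth |
| `error_rate` | 1e-3 | per-read per-site |

Three founder lineages diverge on the fixed topology ((A,B),C) under
Jukes–Cantor substitutions with Poisson branch counts — adequate at the
$K_s \le 0.1$ scales involved; saturation is an error, not a model.
Coding genes evolve on the same topology under a stop-avoiding codon
model whose move set matches the viable-neighbour convention of the
NG86 site counts, so the planted clock is recovered without bias.

The monoploid reference is modelled as a *second A-lineage individual*,
splitting from the panel A haplotype `t_split_ref` years ago (default
matching the observed within-A divergence of 0.34 My). This reflects
the real situation — the reference is cultivar-derived and identical to
no single BAC haplotype — and it is what makes group-A-specific
variants possible at all: a reference exactly equal to the A haplotype
could never reveal a variant private to A. The truth registry is
reference-relative: per (position, alternate allele), the set of
lineages carrying the non-reference allele, rebuilt by diffing the
final sequences so that multiple hits and homoplasy are bookkept
exactly.

Accessions are haplotype multisets: officinarum/robustum {A:6, B:2}
(8x, with the A:B ratio seen in sequenced regions), spontaneum {C:8}
(autopolyploid 8x), and a cultivar {A:9, B:2, C:1} matching the 9–10 :
1–2 : 1 copy pattern of a typical modern cultivar. Pool sizes (8 + 8
plus the cultivar) keep the default five-accessions-with-data
requirement comfortably satisfiable at negative-binomial depth with
mean 100 (deep, capture-like coverage). Within-pool polymorphism is
added as extra variant sites private to one pool and lineage, carried
by a random subset of that pool's copies; their positions avoid sites
already segregating between founders so the founder truth registry
stays exact. `within_pool_theta = 0.002` puts within-pool diversity on
the same scale as the observed within-A divergence.

Not modelled: recombination between haplotypes (mosaic haplotypes are
real but out of scope), aneuploidy dynamics, selection, indels,
read-level artefacts beyond a symmetric per-read error, and reference
mosaicism beyond the single A-lineage individual. Passing recovery
tests on these simulations therefore shows the *rules* are implemented
and internally consistent — not that real capture data are free of the
mapping, paralogy and dosage complications the simulator omits.

## Numerical choices and degenerate inputs

* Half-up rounding for reported Mya (see above); raw values retained
  in all tables.
* `call_genotype()` treats a zero denominator as frequency 0; sites
  with depth 0 are missing by the depth rule anyway.
* Multi-allelic VCF records are decomposed into independent biallelic
  presence/absence tests; indels and symbolic alleles are skipped with
  a logged count. Coordinates are 1-based in all interfaces.
* `ks_pairwise()` errors on zero unmasked codons, zero synonymous
  sites, and saturation; codon pairs whose substitution pathways all
  pass through stops are masked with a message (no such pair exists
  under the standard code, but the guard is kept for robustness).
* `nj_tree()` requires symmetry within 1e-8 and at least three taxa;
  `pcoa_ordination()` truncates with a warning when more axes are
  requested than positive eigenvalues exist.
* `flag_intermediates()` warns and flags nothing when the pool
  envelopes overlap on axis 1 — a between-pool gap is a precondition
  for the notion of "intermediate" to make sense.
* One seed yields bit-identical outputs everywhere; the three
  simulator stages draw from seeds `seed`, `seed + 1`, `seed + 2` so
  each stage is individually reproducible.

## Problem sizes used by the test suite

The package's own validation uses sizes chosen to exercise the
statistics without waste: specificity recovery on twenty 100-kb clean
studies (error and within-pool polymorphism off, so dosage alone
decides every call; precision and recall against the truth registry
must be exactly 1 and the verdicts A→offrob, B→offrob, C→spont in all
seeds); clock round-trips on ~100-kb coding pairs at the 0.84- and
1.29-My planted splits, fifty replicates each, with the mean required
within three standard errors of the planted value; forty 25-kb
neighbour-joining replicates requiring ≥95 % recovery of the A-group
clade with C outermost; and exhaustive or 200-replicate oracle
comparisons for the discrete primitives. The published cross-tabulation
totals themselves (e.g. 188/60 specific SNPs) depend on the real
accession panels and are not reproducible from simulations; the
recovery properties above are the testable surface.

## Limitations

Known limitations beyond the simulator's scope: no dosage (copy
number) estimation — calls are presence/absence, as the downstream
analyses require; no phasing or recombination-breakpoint detection;
no maximum-likelihood trees or bootstrap supports (the distance tree
stands in for tree building); no admixture modelling beyond the
axis-1 interval heuristic; and the verdict rule is a counting rule,
not a statistical test — with few informative SNPs it returns
`unresolved` rather than a confidence statement.
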