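---
title: "Methods: posterior-based HLA class I typing from amplicon reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: posterior-based HLA class I typing from amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlacaller)
```

## The problem

Classical HLA class I genes (HLA-A, -B, -C) are the most polymorphic loci in
the human genome.  Clinical and population-genetic applications need
*4-digit* genotypes — the protein-level allele pair an individual carries at
each locus — but most of the identifying variation is concentrated in exons
2 and 3, which can be PCR-amplified and sequenced as short amplicons from
many pooled, barcoded samples at once.  `hlacaller` turns such pooled
amplicon reads into per-sample genotype calls with calibrated posterior
probabilities, and ships a read simulator so the entire pipeline can be
exercised, tested and benchmarked without any external sequence data.

## The model

For one sample at one locus, every unordered pair of dictionary alleles
$(a_i, a_j)$ is scored by three independent components, multiplied and
normalized:

$$P_\text{combined}(a_i,a_j) \propto
  P_\text{genotype}(a_i,a_j)\;
  P_\text{phase}(a_i,a_j)\;
  P_\text{frequency}(a_i,a_j).$$

**Genotype concordance.**  At each alignment column, the 10 unordered
diploid base genotypes $\{x,y\}$ are scored against the pileup of read bases
$b$ with Phred qualities $Q$ (error probability $e = 10^{-Q/10}$), assuming
independent reads and symmetric sequencing error:

$$\Pr(b \mid \{x,y\}) = \tfrac12 P(b\mid x) + \tfrac12 P(b\mid y),
\qquad P(b \mid a) = \begin{cases}1-e & b = a\\ e/3 & b \ne a.\end{cases}$$

Column likelihoods are normalized across the 10 genotypes (a uniform
genotype prior), and $P_\text{genotype}$ is the product over all sequenced
columns of the normalized probability of the genotype the allele pair
implies there.  Iterating over *all* columns rather than only
pair-discriminating ones changes every pair's score by the same factor, so
the ranking — and the normalized posterior — is unaffected; columns where
either allele carries a gap or unknown base are skipped.

**Phase consistency.**  Genotypes alone cannot distinguish cis from trans
configurations of two heterozygous sites, but a read spanning both sites
can.  For each pair of *adjacent* polymorphic columns within one exon
(consecutive entries of the polymorphic-column index; no amplicon read
spans exons), the candidate pair predicts at most two two-site haplotypes.
With $k$ of $n$ informative spanning reads matching either predicted
haplotype, the site pair contributes a binomial likelihood
$\binom{n}{k}(1-P_\text{err})^k P_\text{err}^{\,n-k}$ with a single assumed
read error rate $P_\text{err} = 1\%$ (per-site errors are deliberately not
compounded; one binomial per site pair keeps the score interpretable and
conservative).  Reads matching neither predicted haplotype count in $n$ but
not $k$ — they are evidence against the candidate; reads with an unknown or
low-quality base at either site are excluded from both.  When both alleles
agree at both sites the single predicted haplotype is scored with the same
formula, so fully homozygous regions still penalise candidates that
contradict the data.

**Frequency prior.**  With known ancestry, the prior for a pair is the
plain product of its two population allele frequencies $f_i f_j$ — exactly
the stated formula, without the Hardy–Weinberg heterozygote factor of 2;
`hwe = TRUE` adds the factor for users who prefer it (it changes
het/hom trade-offs only when the data are nearly uninformative).  Alleles
missing from the frequency table receive a configurable floor
(default $10^{-5}$): frequencies act as priors, never as exclusion.  With
unknown ancestry the prior is uniform and cancels.

**Reporting.**  Scores for all $n(n+1)/2$ pairs are combined in log space
(with max-subtraction before exponentiation) and normalized to sum to 1.
Two results are reported: the *matching set* — all pairs attaining the
maximal $P_\text{genotype} \times P_\text{phase}$ within relative tolerance
$10^{-9}$, i.e. everything the sequence alone cannot distinguish — and the
*best guess*, the maximal posterior once frequency information is added.
Posterior ties are broken by allele-name order so repeated runs are
byte-identical; the full per-pair score table is always returned, so tie
information is never lost.

## Upstream processing

*Demultiplexing* matches 6–9 bp molecular barcodes exactly at the read
start (manifests are validated to be unique and prefix-free; an optional
single-mismatch mode exists but is off by default, since strict matching is
what the achievable parse rates imply).  *Locus assignment* matches 18–21 bp
primers with IUPAC degeneracy and at most one mismatch by default — strict
enough to avoid cross-locus misassignment over 18+ bases, tolerant enough
that a single sequencing error does not discard the read.  Reads matching a
reverse-orientation primer are reverse-complemented so all downstream
processing sees reference-oriented inserts.  Reads matching two primers
equally well are set aside as ambiguous rather than guessed.

*Alignment* can come from any external aligner via SAM/BAM against the
dictionary's exported ungapped consensus references
(`write_consensus_fasta()`, `ingest_alignments()`); indel-containing and
secondary records are skipped and counted, because the caller uses a
substitution-only model — the discriminating differences between 4-digit
alleles at these exons are substitutions.  The built-in `plumbing_align()`
is intentionally minimal (gap-free sliding match/mismatch score, acceptance
at 75% of read length) and exists so the pipeline and its tests have no
external alignment dependency; it is not a contribution and production use
at scale should prefer a real aligner.

*Misalignment filtering* removes reads whose best agreement with any
dictionary allele, computed **over the polymorphic columns the read
covers**, falls below 75%.  The denominator is covered polymorphic sites,
not all sites: a read is judged only on positions it actually observes.
Reads covering fewer than two usable polymorphic columns cannot
meaningfully fail a 75% threshold and are kept — they still contribute
genotype evidence.  Bases below Phred 5 are treated as unknown throughout
(guarding against low-quality tails); the floor is configurable.

## Quality flags

`low_coverage` fires when mean exon depth is below 20 reads, the empirical
minimum for reliable typing — unbalanced allelic coverage below that depth
is the dominant source of false homozygote calls.  `possible_contamination`
fires on evidence of more than two chromosomes: either ≥ 2 well-covered
columns with ≥ 3 bases each at ≥ 10% of reads, or ≥ 2 adjacent-site pairs
with ≥ 3 two-site haplotypes each at ≥ 10% of spanning reads.  The second
form is needed because strictly biallelic polymorphic columns (common in
practice, universal in the toy dictionaries) can never show three bases,
while a mixture of two diploid samples still shows three or four distinct
haplotypes.  Flags annotate; they never auto-correct a call.

## The simulator and what it does (not) show

`sim_config()` defaults encode the regime the caller targets: 95 pooled
samples, 3 loci × 2 exons of ~270 bp, 20 known alleles per locus with
polymorphic-column density 0.05, mean 100 reads per sample per exon
(Poisson), read length 350 ± 40 bp so that inserts usually span the whole
exon, 1% per-base substitution error applied over the entire read —
barcode and primer included, which is why the default parse rate lands
near 92% rather than 100% — and half the reads in reverse orientation.
Base qualities are written as the Phred equivalent of the error rate, so
the likelihood model's assumptions are exactly satisfiable.

Each toy dictionary embeds the two constructed hard cases: a *twin* pair,
identical over the sequenced exons (a rare variant of a common allele, in
the same 2-digit group, fixed at 0.5% population share) that only the
frequency prior can resolve; and a pair differing at exactly one column (a
single diagnostic substitution).  Frequencies are drawn from a skewed Gamma
(shape 0.5) and normalized per locus, mimicking the strong skew of real
HLA frequency tables.  Coverage imbalance (`imbalance = r` gives one
chromosome $r/(1+r)$ of the reads) reproduces the false-homozygote failure
mode; `contamination` replaces a fraction of reads with another sample's
chromosomes, reproducing the multi-haplotype mixture signature.

What the simulator does **not** model, and hence what green tests do not
establish for real data: homopolymer-driven indel sequencing errors
(454-style flowgram artifacts), gapped alignment, quality-score
miscalibration, PCR chimeras, and real IMGT allele sequence structure
(shared motifs, recombinant alleles, many-to-one exon identities beyond
the single constructed twin).  Real-data accuracy therefore has to be
established against a gold standard, not inferred from simulation.

## Numerical and design choices

- All pair scoring is in log space; posteriors are exponentiated after
  max-subtraction.  Per-column normalization keeps magnitudes bounded.
- Empty pileup columns are uninformative: every genotype gets likelihood 1,
  contributing an equal constant to every pair.
- Zero kept reads at a locus produce an explicit `no_call` status, never an
  exception; the acceptance threshold of the homology filter is *attained*
  (a read agreeing at exactly 75% of covered sites is kept).
- Alignment columns are indexed 1-based internally; externally reported
  positions use the dictionary's per-column reference labels, carried as
  opaque annotations (e.g. genomic coordinates) rather than interpreted.
- Evidence at a locus is summed across both sequenced exons of a sample —
  exons are separate amplicons but score the same allele pair.
- Tie-breaking everywhere is lexicographic, making runs reproducible;
  simulation randomness is fully determined by the configuration seed.

## Problem sizes used in the test suite

The recovery benchmark simulates 200 diploid samples at 50 reads per exon
with 1% error (the caller's well-powered regime) and checks ≥ 98% 4-digit
and ≥ 99% 2-digit allele accuracy; residual errors are rare-twin
resolutions, the designed irreducible ambiguity.  The unbalanced regime
(ratio 9:1 at 30 reads per exon, 60 samples) checks that essentially all
miscalls are false homozygotes of the covered chromosome.  Coverage
monotonicity is checked on matched seeds at 5 versus 20 reads per exon.
Oracle equivalence compares the full posterior table against a
direct-probability brute-force enumeration (no log-space arithmetic) on a
5-allele dictionary with ≤ 50 reads, at $10^{-9}$ per pair.

## Known limitations

Substitution-only model (no indel genotyping, no gap-aware alignment);
two-exon evidence cannot separate alleles identical over exons 2–3 except
by frequency; no novel-allele discovery — reads from an allele absent from
the dictionary will be attributed to its nearest known neighbour; class II
loci and 6/8-digit resolution are out of scope; contamination is flagged,
not deconvolved.
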