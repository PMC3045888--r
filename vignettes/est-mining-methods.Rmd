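---
title: "EST mining with estmine: models, parameters and design choices"
author: "estmine authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EST mining with estmine: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estmine)
```

# Scope

`estmine` reconstructs the classic EST-survey analysis stack: single-pass
5' cDNA reads from many tissue/condition libraries are trimmed, clustered
into contigs, annotated for ORF structure and codon composition, screened
for within-contig polymorphism, and compared across libraries by exact
count statistics. This vignette explains each model, the tunable
parameters and their defaults, the synthetic data generator that the test
suite is built on, and the places where a design decision was genuinely
open — together with what was chosen and why.

# Trimming and contaminant screening

`trimRead()` applies the standard EST cleanup rules: a leading
adapter/vector remnant (up to 2 substitutions, searched in the first 50
bases — 5' remnants only), a 3' clip at the first sliding window (width
10) whose mean quality falls below the floor (default 15; skipped without
qualities), and removal of terminal mononucleotide runs of at least 8
bases (3' polyA, and 5' polyT for reversed clones). Reads below 100 nt
after trimming are rejected with a reason code, matching the shortest
cluster length a survey of this kind would retain.

The rules iterate to a **fixed point**, which makes trimming idempotent by
construction — the property the tests assert. A consequence worth knowing:
a 7-nt adapter at 2 tolerated mismatches will near-match random sequence
in a 50-base window roughly half the time, so with very short adapters the
fixed-point loop can nibble real sequence. Real vector remnants are
longer; use the full remnant sequence, not a minimal tag.

Bacterial contamination is decided from a 12-column similarity hit table:
a cluster is a contaminant when some hit has **e-value ≤ 1e-40 and
identity > 80%**. Screens of this kind are sometimes written with the
e-value inequality inverted; requiring the *more* significant side is the
only biologically coherent reading (a weaker hit cannot be stronger
evidence of contamination), and `flagWeakerHits = TRUE` restores the
other direction for anyone who wants it.

# Overlap clustering

`clusterEsts()` is a greedy seed-and-extend clusterer honouring the two
parameters that define this kind of assembly: **minimum overlap 40
bases** and **minimum identity 90%**. Reads are taken longest-first; each
read joins the first existing cluster (in creation order — the
deterministic tie-break) whose consensus it overlaps at or above both
thresholds, otherwise it founds a new cluster. Candidate clusters are
proposed by shared 12-mers; the overlap itself is an ends-free pairwise
alignment with affine gaps (open 5, extend 1), and identity is matches
over alignment length. The alignment engine is the standard
Biostrings dynamic-programming aligner rather than a hand-written banded
DP: the published thresholds, not the aligner internals, are what the
method specifies, and an exact aligner can only be more accurate than a
banded one. Consensus is the column-wise majority with ties broken
alphabetically (A<C<G<T); reverse-complement joining is attempted when
the forward orientation fails (clone orientation can flip even in
5'-sequenced sets) and can be disabled. All coordinates are 0-based,
half-open.

Full overlap-graph assembly (scaffolding, chimera splitting,
quality-weighted consensus) is deliberately out of scope; on zero-error
simulated reads the greedy rule provably recovers the gene-of-origin
partition, which is the oracle the tests use.

# ORF annotation and GC3

`predictCds()` scans all six frames for ORFs that start at ATG and end at
a stop (or the sequence end) and keeps the longest — the right heuristic
when no protein database is available. A **guide channel**
(`guide = list(frame, strand)`) accepts an externally derived frame, e.g.
from protein similarity, and then expands 5' to the nearest upstream
in-frame ATG and 3' to the next in-frame stop. Sequences with no ATG in
any frame are annotated with their longest stop-free frame and reason
`"no_atg"`.

`gcMetrics()` reports overall GC and GC3 (the G+C fraction of third codon
positions). The terminal stop codon is excluded from GC3 by default —
its third position is constrained by the genetic code, not by
mutational pressure — and `includeStop = TRUE` restores it.
`smoothedHistogram()` bins composition values into 100 equal classes and
smooths with a three-class moving average; the edge classes average the
two available neighbours (a deliberate choice over replicate-padding:
it never manufactures mass outside the observed range, at the cost of
not conserving the raw total exactly at the edges).

# SNP detection

`detectSnps()` works on the read-by-position alignment matrix of one
contig (built by `contigAlignment()`) and applies three filters:

1. **Candidate columns** need at least two observed alleles; bases below
   the quality floor (default 20) support nothing when qualities exist,
   and ambiguity codes never support an allele.
2. **Haplotype filter** — reads are partitioned by their allele vector
   over the candidate columns; haplotypes carried by a single read are
   removed. An isolated single-read allele therefore can never be
   called; a support-1 minor allele survives only when its carrier read
   belongs to a surviving haplotype defined by other called SNPs.
3. **Confidence** — `conf = (1 - 1/d) * 2*minor/d` with `d` the column
   depth, a score that increases with redundancy and allele balance;
   calls below 0.2 are dropped. The upstream tool this emulates does not
   publish its exact score, so this is a declared surrogate with the
   same monotonicity; at the default 4-read, 2+2 configuration it equals
   0.75 and passes comfortably.

Contigs need at least 4 reads (two expected copies per allele) — applied
uniformly to every dataset. A contig whose two largest haplotype groups
show more than 3 fixed differences per 100 aligned bases is flagged as a
collapsed paralog pair and excluded from SNP summaries by the pipeline
(both thresholds configurable): allelic haplotypes of one locus differ at
a handful of sites, diverged paralogs at several percent of them.

Synonymy labelling substitutes each alternate allele into its codon;
KA/KS uses per-codon **fractional site counting** (each position
contributes the fraction of its three possible changes that are
synonymous, so S + N = 3 × codons exactly) and uncorrected proportions —
within-contig allelic divergence is far too small for multiple-hit
correction to matter, so a substitution-model menu would add parameters
without information. `ratio` is `NA` when KS = 0, never infinity.

# Digital differential expression

`acPvalue()` evaluates the exact conditional probability of seeing `y`
tags in one library given `x` in another, in log space (log-gamma
factorials; no overflow for counts up to 1e6), and doubles the smaller
tail for a two-sided p-value, truncating the upper tail when terms fall
below 1e-16 of the running sum. Two numerical notes:

* At `x = y` with equal library sizes the lower tail is exactly 1/2 (an
  odd-binomial symmetry), so the function returns exactly 1 rather than
  1 minus accumulated rounding.
* The tail-doubling convention is *not* invariant under swapping the two
  libraries except at `x = y`: the two orientations aggregate different
  tail terms (the point probabilities themselves are symmetric). The
  tests assert exact symmetry at `x = y` and order-of-magnitude
  agreement elsewhere; this is a property of the convention, not a bug.

`rStatistic()` is the multi-library log-likelihood ratio with
`0·ln(0) = 0`; p-values use the asymptotic `2R ~ chi-square(m-1)` null —
the method's original description reports R without a p-value mapping,
and standard likelihood-ratio theory is the reproducible, oracle-checkable
choice. R is returned alongside p so users can rank by either.

`selectDeContigs()` chains the canonical filters: optional library
merging (libraries from one tissue pooled before testing), removal of
libraries under 300 ESTs (small libraries destabilize digital expression
estimates) and contigs under 3 ESTs, the R test at the
Bonferroni-corrected threshold `alpha / contigs tested` (the correction
attaches to the R test only, with the contig count — not contigs ×
library pairs — as divisor), the AC test on all library pairs with the
**union rule**: a contig is AC-significant when at least one library
beats 0.05 against every other library. The AC threshold is
per-comparison by default (configurable): the union rule's
all-other-libraries quantifier is already a strong filter, and stacking a
multiplicity correction on top of it would change the operating
characteristics the method is known for.

`profileCluster()` divides each selected contig's counts by its total,
uses 1 − Pearson correlation as the distance and average linkage
(unstated in the method's usual descriptions; average linkage is the
least shape-biased default for correlation distances). A zero-variance
profile is uncorrelated with everything by convention (distance 1).

# Enrichment and prevalence

`hypergeomTermTest()` returns both tails of the hypergeometric law via
the stable distribution functions in base R; `termEnrichment()` adds
Benjamini–Hochberg FDRs alongside the raw p-values (an addition, not a
replacement — classic term screens reported raw tails).
`domainPrevalence()` normalizes term counts to the total annotated
clusters per dataset, clusters with several terms counting once per term.

`familyPrevalenceScreen()` formalizes the narrative notion of
"species-specific or prominent" families in a family × species matrix:
*specific* means ≥ `minFocal` (3) members summed over the focal species
and none elsewhere; *prominent* additionally tolerates up to `maxOther`
(1) members in any single other species provided the focal sum is at
least `prominentRatio` (3×) the largest non-focal count. The thresholds
were calibrated once against the bundled coffee orthologous-family table
(`inst/extdata/coffea_orthomcl_families.tsv`) so that cystatin-like
expansions come out prominent, the invertase-inhibitor family specific,
and the large ubiquitous kinase families background; all three knobs are
exposed.

# The synthetic data generator

The generator exists so every stage can be tested against known truth;
its defaults *are* the study conditions of the test suite.

`generateTranscriptome()` builds gene models with 5'UTR/CDS/3'UTR
structure. Length defaults — 5'UTR ~160 nt, CDS ~280 codons, 3'UTR
~240 nt (truncated normals) — sit at the medians reported for dicot EST
contig sets. Codons are sampled per amino acid with the third position
steered to hit a per-gene GC3 target drawn from a configurable mixture of
modes, so unimodal and bimodal GC3 profiles can be emulated; Met and Trp
(G-only third positions) are compensated by the free positions, making
the realized mode centers accurate to a few hundredths at realistic gene
counts. Two deliberate idealizations:

* 5'UTRs are generated **free of ATG** triplets, mirroring the scarcity
  of upstream start codons in real 5'UTRs and keeping the longest-ORF
  annotation anchored at the true start; with random 5'UTRs roughly a
  quarter of genes would acquire a spurious upstream in-frame start, and
  the CDS-recovery oracle would measure that artifact instead of the
  annotator.
* Planted allelic variants (default 3 linked SNPs per chosen gene, two
  haplotypes at 50/50) are placed within the first 400 transcript bases
  so that 5'-anchored reads of typical length cover them.

Paralog pairs are diverged full-length duplicates (default 4% of
positions, transition-biased, never creating an internal stop).

`simulateEstLibraries()` produces 5'-anchored reads: truncated-normal
lengths (mean 650, sd 150, floor 100 — the scale of classic EST
surveys), optional adapter prefix, polyA run where a read crosses the 3'
end, substitution errors at a per-design rate (indels deliberately off by
default so alignment/consensus oracles stay exact), contaminants from a
random-composition pool, and optional qualities with a 3' decay so the
quality trimmer is exercised. `conditionDesigns()` builds the balanced
development/stress designs used throughout: planted DE genes are shifted
`fold`-fold up in one condition, half in each direction, so expression
profiles form two anticorrelated blocks that profile clustering should
separate.

What the generator does **not** emulate: chimeric clones, alternative
splicing, chromatogram-level noise, coverage biases along the transcript,
or homopolymer indel errors. Green tests therefore certify the
algorithms under their stated assumptions — not robustness to every
artifact of historical sequencing chemistry.

# Problem sizes and determinism

The test suite and the acceptance script run entirely on generated data
at sizes chosen to make every check sharp but quick: count-statistic
oracles on exhaustive small grids (all counts 0–20; every hypergeometric
configuration up to N = 25), 10,000-contig null simulations for test
size, a 200-gene / 8-library / 20-planted-genes design for DE recovery,
a 100-gene zero-error library at depth 1200 for assembly recovery, and
1,000 genes for the GC3 bimodality control. A single global seed is
expanded into per-stage substreams (`runPipeline()` does the same), so
stages rerun identically in isolation; all results in this vignette and
the README are reproduced by the suite and by
`scripts/acceptance.R --seed <int>`.

# Known limitations

* The greedy clusterer examines candidates in creation order and commits
  immediately; pathological read orders could in principle split a gene
  that full overlap-graph assembly would join. At survey-scale error
  rates this does not occur in practice (the tests check exact
  partition recovery).
* The R-statistic p-value is asymptotic; for very small counts the
  chi-square tail is conservative (the null simulations quantify this).
* Minus-strand CDS annotations report coordinates in the orientation of
  the reverse complement; `extractCds()` abstracts this away, but
  downstream consumers of raw coordinates should note it.
* KA/KS from within-contig SNPs counts segregating sites, not fixed
  substitutions; it is an indicator of selective constraint on the
  sampled alleles, not a between-species rate estimate.

```{r session}
sessionInfo()
```
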