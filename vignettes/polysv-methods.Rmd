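---
title: "Methods: structural variation, introgression and population genetics in polysv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural variation, introgression and population genetics in polysv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polysv)
```

# Scope

`polysv` implements a comparative-genomics and population-genetics workflow
for pairs of closely related plant genome assemblies — the setting in which
large inversions and translocations between two cultivars of an
allotetraploid crop (such as upland cotton) segregate in a diversity panel
and suppress recombination across the rearranged region.  The package
covers:

* a minimal whole-genome aligner (unique k-mer anchors, greedy collinear
  chaining, base-level gap closure) plus import of external aligner output;
* one-to-one and global-collinear block filtering, the allelic/non-allelic
  partition, inversion/translocation classification and merging, and
  SNP/small-indel calling with a buffering filter;
* presence–absence variation (PAV) calling from unaligned regions with a
  category taxonomy and a coverage/identity rejection filter;
* homoeologous-introgression scoring of 5-kb subgenome bins against two
  ancestor genomes;
* an orthologous-gene structural-variation taxonomy (conserved /
  large-effect / large structural variation);
* panel-scale statistics: site filtering, inversion-breakpoint genotyping
  from mate-pair mappings, windowed π, Weir–Cockerham F<sub>ST</sub>,
  haplotype diversity, private SNPs, neighbor-joining grouping, and
  recombination-rate windows from a RIL map;
* Kimura two-parameter divergence and LTR insertion-time dating.

Every stage is exercisable on synthetic genomes with known truth, generated
by the package itself; nothing requires external downloads.

# Coordinates and containers

All internal coordinates are 0-based half-open.  Conversion to the 1-based
inclusive convention of text formats (the `show-coords` dialect, VCF, GFF3)
happens only in the readers and writers; PAF and BED are natively 0-based
and pass through unchanged.  Reverse-orientation alignment blocks always
store ascending coordinates plus an orientation flag — a single
representation, never descending coordinates.

Genome sequences live in a light `genome_set` container (named uppercase
strings); every analytic result — alignment blocks, rearranged regions, PAV
regions, introgression bins, variant calls, window statistics, ortholog
calls — is a tibble, so results chain through dplyr verbs and plot with the
provided `plot_*()` functions.

# The aligner

Anchors are maximal exact matches seeded at k-mers (default k = 21, a free
parameter in 15–31) that occur exactly once in the reference; both query
strands are scanned.  The uniqueness requirement suppresses repeat noise
without a repeat masker — adequate because the synthetic genomes are mostly
unique sequence, and real repeat handling is delegated to imported
alignment tables, which the pipeline accepts interchangeably with its own
blocks.

Anchors chain greedily by diagonal proximity: a new anchor joins the open
chain with the smallest combined reference/query gap and diagonal shift,
provided both gaps are at most `max_anchor_gap` (default 100 bp) and the
orientation is consistent.  Gaps larger than that split blocks, leaving the
intervening sequence unaligned — which is exactly where PAV calling looks.
Inter-anchor gaps inside a chain are closed by global alignment (match +1,
mismatch −1, gap −2); block identity is the match-column fraction of the
block's own base alignment, so it is self-consistent by construction.
Blocks shorter than `min_block` (default 200 bp on the reference) are
discarded.

Maximal anchor extension can spill a few bases across a rearrangement
junction (the base just beyond a breakpoint matches by chance with
probability 1/4 per base).  Adjacent blocks may therefore overlap by a few
bp.  Both filtering modes tolerate up to 25 bp of overlap — comfortably
above the expected spill, comfortably below any real signal — instead of
forcing an exclusive choice that would discard a whole block.

`filter_one_to_one()` is two-pass weighted interval scheduling (weight =
reference length × identity): an exact dynamic program on the reference
pass, repeated on the query pass, with ties resolved toward longer blocks
and then smaller start.  `filter_global()` finds, per reference chromosome,
the maximum-weight chain of forward blocks strictly increasing in both
genomes (weighted longest-increasing-subsequence), against the best-scoring
query chromosome only.  Restricting each reference chromosome to a single
chain partner mirrors the one-homologue-per-chromosome structure of a
global alignment and prevents a lone translocated block from being its own
trivial "chain" on another chromosome pair.

# Rearrangement calling

A one-to-one block is *allelic* when at least 50% of its reference span is
covered by the global collinear chain of its chromosome pair and its
orientation is forward; all other blocks are non-allelic.  The 50% rule
resolves an ambiguity the procedure leaves open (whether partial chain
overlap counts): a block must be majority-supported by the collinear
backbone to be orthologous.

Each non-allelic block is classified from its flanking allelic context on
the reference chromosome: a query chromosome different from the flanks'
mapping target makes an inter-chromosomal translocation; otherwise reverse
orientation makes an inversion and forward orientation an intra-chromosomal
translocation (order-inconsistent placement).  Blocks with no allelic
neighbour fall back to the chromosome-level majority context and are
flagged low-confidence.  Reciprocal translocations are reported as two
inter-chromosomal records; pairing is left to reporting.

Same-kind regions on the same chromosome pair merge when reference and
query gaps are both at most `join_gap`.  The merge threshold is necessarily
ours (the original procedure merged interspecific fragments manually); the
default is 50 kb, exposed as a parameter, and merged counts are monotone
non-increasing in it.

# Variant calling and the buffering rule

SNPs and short indels are read off the alignment columns of allelic
blocks.  SNPs and 1-bp indels are retained only when the distance to the
nearest other variant and to the block edge is at least `buffer_min`
(default 20 bp).  This interprets "buffering" as the BUFF-column semantics
of standard whole-genome-aligner SNP output: distance to the nearest other
variant or alignment edge.  Indels of 2–100 bp are additionally emitted
from the gap-length difference between mutually consistent adjacent allelic
blocks (the GAP class of unaligned regions); longer events belong to PAV
calling.  Multi-base indels that the base-level alignment resolves inside a
block are also reported (up to 100 bp) — they are genuine calls the
column walk sees directly.

# Presence–absence variation

Unaligned regions are the complement of the one-to-one aligned spans on
each carrier chromosome.  Categories are decided specific-before-generic —
GAP, INV, SEQ, JMP, DUP, BRK — from the flanking blocks: GAP between two
mutually consistent allelic flanks; INV/SEQ/JMP when a flank is a
rearranged block (inverted / inter-chromosomal / intra-chromosomal); DUP
when the allelic flanks re-use overlapping reference sequence; BRK
otherwise.  Regions of at most 100 bp are dropped before filtering (the
PAV length floor is applied first; the alternative order is noted as
unresolved in the source procedure).

The rejection filter aligns each region's sequence to the **counterpart**
genome: a presence region unique to one cultivar must be absent from the
other, so the filter tests the counterpart, not the carrier itself (the
source wording "their respective genome" is ambiguous; this is the reading
that makes the uniqueness claim testable).  A region is non-unique —
`retained = FALSE` — only when best-alignment coverage exceeds 50% *and*
identity exceeds 90%.  Coverage is the chained-span fraction of the region
covered by exact seed matches (≥ 20 bp, chained across ≤ 200 bp gaps);
identity is the matched-base fraction within that span.  A gene is a PAV
gene when at least 80% of its CDS length lies in retained regions —
a membership threshold the source never defines, so it is ours, documented
and configurable.

# Introgression bins

Each 5-kb bin of a subgenome is scored against both ancestor genomes using
exact seed matches of at least `min_seed` bp (default 50, the word size of
the original BLAST screen).  Two coverage notions are kept deliberately
separate:

* **span coverage** — the fraction of the bin inside chained seed spans
  (gaps ≤ 500 bp bridged) — is the retention measure: a bin must reach 70%
  span coverage against at least one ancestor to be scored at all;
* **match coverage** — the fraction of the bin inside the exact matches
  themselves — feeds the ratio test (other/own ≥ 1.5 ⇒ introgressed).

The distinction matters because a fully chained-and-gap-closed alignment
saturates near 100% coverage against both a 2%-diverged and a 5%-diverged
ancestor, erasing the signal the ratio is meant to capture, whereas the
expected exact-match coverage at per-bp divergence *d* with seed length *L*
is approximately (1 + dL)e^(−dL) — about 0.74 at 2% and 0.29 at 5% — giving
a ratio near 2.6 inside introgressed segments and 0.4 outside.  A bin with
zero own-coverage but high other-coverage is called introgressed and flagged
distinctly: an undefined ratio with a zero denominator is the strongest
possible signal, not a missing value.  Terminal short bins are scored but
flagged; all-N bins are unresolved.

# Orthologous-gene taxonomy

Gene pairs (pairing is supplied by the caller or the simulator — orthology
inference is an external tool's job, not this package's) are aligned
globally over the gene body plus up to 2 kb of each flank, in forward gene
orientation.  Variants are assigned to sub-regions (flanks, CDS exon, UTR,
intron) of gene A.  Effects come from translating both CDS and comparing
the models: synonymous/missense substitutions; CDS indels in-frame (length
≡ 0 mod 3) or frameshifting; start-codon loss; stop-codon change (premature
gain or terminal loss, one label with a sub-flag); splice-site changes at
canonical GT/AG boundaries (non-canonical reference introns are flagged,
not classified); unequal exon counts; and CDS segments ≥ 80% absent from
the counterpart alignment (`cds_missing`).

Categories follow a strict precedence: exon-count change or missing CDS ⇒
large structural variation; else frameshift/start/stop/splice ⇒ large
effect; else structurally conserved ("deletion of some codons" — in-frame
indels — is compatible with conservation).  The report gives counts and
column percentages to two decimals per syntenic status and subgenome, in
both a nested and a flat view, because effect labels can co-occur and the
nested sub-counts need not sum to their parent.

# Panel statistics

Sites are filtered on MAF ≥ 0.05, heterozygote fraction ≤ 10% and
missingness ≤ 10%, thresholds applied over non-missing calls.  Accessions
are treated as inbred-like diploids (dosage 0/1/2), matching highly
homozygous cotton cultivars; a `ploidy = 1` mode supports haploid coding.

*Breakpoint genotyping.*  A mate pair spans a breakpoint when its mates map
on opposite sides.  Inward orientation with an implied insert within
mean ± 4 SD is reference-like evidence; same-strand mates or out-of-range
separation is inversion-allele evidence.  An allele is assigned only on
unanimous evidence with at least 2 supporting pairs (conservative, matching
the "unsigned" class of ambiguous accessions); per-breakpoint calls are
reported separately plus a combined per-accession call that labels
disagreement explicitly as `conflict`.

*Windows.*  π uses per-site unbiased heterozygosity 2p̂q̂·n/(n−1) over
non-missing allele counts, summed per 1-Mb window (10-kb step) and divided
by window width.  F<sub>ST</sub> is the Weir–Cockerham two-population
estimator as a ratio of summed variance components per 1-Mb window (100-kb
step); the estimator may go slightly negative near zero differentiation.
Haplotype diversity clusters accessions by identical genotype vectors in
10-kb windows — a missing call matches nothing, so incomplete accessions
form singletons — computes (n/(n−1))(1 − Σf²) per window, and averages
cluster windows within 1-Mb windows (100-kb step).  The explicit
(n/(n−1))(1 − Σf²) form is this package's concretization of the
identical-genotype-cluster definition.

*Private SNPs.*  The larger group is down-sampled to the smaller's size
(seeded), then segregating sites partition exactly into common and
group-private.

*NJ grouping.*  Distance is the proportion of differing non-missing
genotype codes; the tree is canonical neighbor joining (`ape::nj`), and the
two-group cut is the bipartition of the longest internal branch — an
automatic stand-in for the visual two-clade cut of a published tree.

*Recombination.*  Cumulative cM is treated as piecewise-linear in physical
position; 1-Mb windows (0.5-Mb step) report accumulated cM per Mb with
partial inter-bin intervals pro-rated linearly; `mean_cm_per_bin` is total
map cM over bin count.

# TE dating

K2P distance is K = −½ ln((1 − 2P − Q)√(1 − 2Q)) with P and Q the
transition and transversion proportions over columns free of gaps and Ns;
pairs with 1 − 2P − Q ≤ 0 or 1 − 2Q ≤ 0 are flagged saturated rather than
given a distance.  Insertion time is t = K/(2r) with r = 7 × 10⁻⁹
substitutions per site per year, the conventional rate for cotton.  The
divergence landscape bins copies by K against their family consensus,
length-weighted (bp per bin) with a copy-count histogram alongside, since
whether published landscapes weight by length or count is not stated;
saturated copies fall into an overflow bin.  Only the Kimura correction is
offered — the dating rule specifies it, so a Jukes–Cantor alternative would
only invite silent inconsistency.

# The synthetic generator

`simulate_genome_pair()` builds genome A as random DNA at 35% GC (the
ballpark of plant nuclear genomes) and derives genome B by applying the
requested inversions (reverse-complement in place), translocations and PAV
events, then planting point mutations and 1–10 bp indels (uniform lengths —
a simple stand-in for the 1-bp-dominant indel spectrum of real cultivar
pairs) at the given rates.  Planted variants are excluded from engineered
spans plus a 100-bp margin so truth breakpoints stay exact and recoverable
by direct string comparison; indels keep 30 bp of mutual separation so each
planted event is individually identifiable.  PAV insertions are random DNA
at 40% GC — no TE library is modelled.  One global seed feeds a named
substream per operation, so outputs are byte-identical under call
reordering.

`simulate_panel()` defaults mirror the published panel structure: 66
reference-like and 348 alternative-allele accessions, one 10-Mb inversion
on a 50-Mb chromosome, 2,000 sites (a desk-scale stand-in for the 315,868
real SNPs; the statistics are per-site, so site count changes power, not
correctness).  Inside the inversion, each group's allele frequency is
(1 − w)·p + w·d with w = 1 − `inside_inversion_diversity_scale` and d a
per-group side draw: at scale 1 both groups share one frequency vector (the
null), at scale 0 inside sites are monomorphic within groups, and the
default 0.2 produces strong differentiation with reduced within-group
diversity.  A fraction (default 0.3) of inside sites is private to one
group.  Heterozygosity enters as residual heterozygosity of alt-carrying
calls (2%), and 2% of calls are missing.

`simulate_introgression_set()` diverges the two ancestors from the
subgenome at 2% and 5% point-mutation rates, with the rates exchanged
inside swap spans.  `simulate_mate_pairs()` draws fragments around
breakpoints and maps both mates back to reference coordinates analytically
through the inversion (position reflected, strand flipped), redrawing reads
that would cross a junction, as a mapper would clip them.
`simulate_ril_map()` is deterministic given its parameters — evenly spaced
bins, increments scaled inside the suppressed span — so window statistics
have exact expectations.

What the generator does **not** emulate: repeat families and TE evolution,
sequencing error and read qualities, Hi-C contacts, population structure
beyond the two inversion groups, linkage disequilibrium decay within
groups, and real indel/SV length spectra.  Passing tests therefore
demonstrate algorithmic correctness on clean truth, not robustness to
repeat-rich real assemblies — on real data the aligner's unique-seed
strategy defers to imported alignments from a production aligner.

# Problem sizes and numerical choices

The validation suite runs on 2 × 5-Mb genome pairs for structural-variant
recovery (six engineered events over 10 Mb of genome, 1% SNP divergence),
1–2-Mb pairs for PAV and variant-caller checks, a 1.5-Mb subgenome for
introgression, the 414-accession default panel, and ~500 random gene pairs
across the mutation classes for effect-annotation oracles — sizes chosen so
the whole suite completes in minutes while every property is exercised at
non-trivial scale.  Window functions return 0 (π) or NA (F<sub>ST</sub>,
haplotype diversity) for windows without usable sites, and degenerate
inputs (empty block sets, all-N regions, saturated distances, monomorphic
matrices) are handled explicitly rather than erroring.  Tie-breaks are
deterministic throughout: interval scheduling prefers longer blocks then
smaller starts, and the NJ two-cut breaks zero-branch ties by accession
order.

# Known limitations

* The internal aligner targets desk-scale (tens of Mb) genomes; chromosome-
  scale assemblies should be aligned externally and imported via
  `read_alignment_table()`.
* The PAV rejection filter and introgression scoring build on exact seed
  matches; they are calibrated for the few-percent divergence regime and
  would need tuning for much more distant comparisons.
* Ortholog pairing, repeat annotation and LTR discovery are out of scope by
  design; the package consumes their outputs.
* Published genome-scale counts from real assemblies are not reproducible
  from synthetic data and are not targets of the test suite; the suite
  validates the rules and arithmetic that produced them.
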