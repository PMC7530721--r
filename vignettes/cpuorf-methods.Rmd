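---
title: "Methods: how cpuorf finds conserved peptide uORFs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how cpuorf finds conserved peptide uORFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its models, parameters and
numerical choices. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The problem and the model

An upstream ORF (uORF) is an ATG-to-stop reading frame inside a transcript's
5′-UTR. The package's working hypothesis is the standard comparative one: if
the *amino-acid sequence* encoded by a uORF has been preserved across
taxonomic orders far beyond what neutral nucleotide divergence would leave
behind, the peptide itself is functional (typically a cis-regulator of
downstream translation). The pipeline therefore combines three independent
kinds of evidence before calling a CPuORF:

* **presence** of the uORF peptide in transcript records of other species
  (translated homology search),
* **orthology** of the carrier transcript (the downstream region must match
  the query's main ORF), and
* **selection** (pairwise Ka/Ks against per-order representatives, with an
  empirical significance test).

## Transcript models and uORF extraction

GFF3 coordinates are 1-based inclusive; everything internal is 0-based
half-open, converted exactly once at parse time. Exons are spliced in
transcription order and minus-strand transcripts reverse-complemented, so
every stored sequence reads 5′→3′. The GFF3 `phase` of the first CDS segment
is honoured by trimming the mORF 5′ end; CDS sets that are not a codon
multiple after that adjustment are skipped with a warning rather than
silently truncated. Annotated non-ATG starts are retained (a counter tracks
them): initiation-codon annotation is the annotator's call, not ours.
`five_prime_UTR` features are only cross-checked; the UTR inferred from
exon/CDS structure always wins on conflict, because Ensembl dialects differ
in whether those features are present and complete.

uORF scanning pairs every UTR ATG with its *nearest* in-frame stop. Both
codons must lie entirely within the UTR: an ATG whose reading frame runs
into the mORF is not a uORF here (it cannot be separated from the main
protein by this kind of evidence). The minimum length is two codons
including the stop — a bare Met "peptide" — configurable via `min_codons`.
Codons containing N never act as start or stop; uORFs spanning internal Ns
are kept but flagged. For counting, uORF records of a gene that share a
genomic start codon *or* a genomic stop codon merge into one unit (connected
components of the share graph, computed on genomic codon coordinates so
splice variants with different UTR lengths still merge); the records
themselves are never deleted.

## The search engine

All homology steps go through a pluggable engine. The default builtin is a
deliberately BLAST-shaped miniature: a query/subject(frame) pair is examined
only when it shares an exact amino-acid word (default length 3); seeded
pairs get a Smith–Waterman local alignment (BLOSUM62, gap open 11 / extend
1, stop and X rows added to the matrix so alignments never silently cross
stops); raw scores become E-values through Karlin–Altschul
\(E = K m N e^{-\lambda S}\) with gapped BLOSUM62 constants
(\(\lambda = 0.267\), \(K = 0.041\)) and \(N\) the *total translated length
of the collection searched*, as in a real database search.

Two of these choices matter and are easy to get wrong:

* At the pipeline's permissive cutoff (E ≤ 2000) a pure score threshold is
  vacuous — for short peptides against a small collection, even score 0
  gives E < 2000. The word seed is what separates "alignable at all" from
  "no hit", exactly as BLAST's seeding does in practice at such cutoffs.
* Scoring E against a single subject instead of the whole collection makes
  chance cross-gene alignments look significant (E ~ 10⁻³ for scores a real
  search would call E ~ 0.5); the mORF-confirmation step at E < 0.1 then
  accepts junk. The engine therefore pools the search space, and the
  pipeline passes the pooled downstream-region size into each per-record
  mORF confirmation.

`blast_engine()` wraps NCBI BLAST+ (`tblastn`/`blastp`,
`-seg no -word_size 2 -matrix BLOSUM62 -comp_based_stats F` — the reference
configuration for very short queries at permissive cutoffs). The test suite
checks that both engines report the same hit set at E ≤ 10⁻³ on fixture
homologs; scores and E-values are not expected to match numerically.

## Fusion ratio

A uORF that is really the 5′ fragment of the main protein will appear fused
to the mORF in transcript records of other species. For RefSeq-class
records matching both the uORF (E ≤ 2000 side) and the downstream mORF
(E < 0.1 side, mORF HSP downstream of the uORF HSP with a one-codon
tolerance), a record is *fused* when some uORF-HSP/mORF-HSP pair lies in
the same subject frame with no stop codon between them. uORFs whose fusion
ratio (fused / matching) is ≥ 0.3 are discarded; the boundary value is
discarded. Records with no matches leave the ratio undefined and the uORF
in play — absence of evidence is not evidence of fusion.

## Putative uORFs and mORF confirmation

From each translated-search hit, the putative uORF is the maximal stop-free
codon segment containing the HSP, bounded 5′ by the segment's most upstream
in-frame ATG at or before the HSP start and 3′ by the first in-frame stop
after the HSP. ESTs are frequently 5′-truncated, so a segment that reaches
the subject's 5′ end without an ATG is kept as 5′-partial (flagged); a
segment with no ATG and no truncation yields nothing. Confirmation then
searches the query's mORF peptide against the region strictly downstream of
the putative uORF; the best hit must have E < 0.1 (strict). Hits from
records whose lineage lies outside Metazoa, carries a species/lineage
conflict flag from the collection builder, or is missing are removed as
contaminants.

## Ka/Ks and the permutation test

Pairs are built per taxonomic order: among a uORF's confirmed hits in an
order, the representative is the lowest mORF-confirmation E (ties: longer
putative peptide, then lexicographic record id). Identical-sequence uORFs
from splice variants of one gene collapse first (lowest median
uORF-search E; ties to the lexicographically smaller transcript).

Each original uORF / putative uORF pair is aligned at the peptide level
(Needleman–Wunsch, BLOSUM62, affine gaps) and back-translated to codons;
gap, stop and ambiguous columns are dropped from counting. Ka and Ks follow
Nei–Gojobori (1986): per-codon synonymous site fractions (mutations to stop
codons count as nonsynonymous), substitution counts averaged over all
minimal mutational pathways excluding those through stop codons, and
Jukes–Cantor correction of both proportions. Degenerate outcomes are
explicit: an identical pair has ratio 0 (perfect conservation is the
strongest purifying signal); Ks = 0 with Ka > 0 leaves the ratio undefined
and the pair non-informative; a saturated correction (proportion ≥ 3/4)
gives Ks = ∞ (ratio 0) or Ka = ∞ (undefined), always flagged.

Significance comes from an empirical null: each sequence's codon order is
shuffled independently (composition preserved), columns re-paired by index,
and the pair statistic recomputed; \(p = (1 + \#\{null \le obs\}) /
(n_{perm} + 1)\), deterministic under a seed. One numerical choice is
essential here: shuffled pairings are nearly random codon pairs, whose
nonsynonymous proportion almost always exceeds the Jukes–Cantor saturation
bound, so the *corrected* ratio cannot order the null. Observed and null
values are therefore compared on the uncorrected proportion ratio
\(p_N/p_S\) (total order: 0 when both are 0, +∞ when only \(p_S\) is 0),
which agrees in order with Ka/Ks wherever the correction exists. Reported
Ka/Ks values remain NG86 + JC.

The null hypothesis this permutation embodies is *absence of pairing
structure* — "no more conserved than amino-acid/codon composition
predicts" — not neutrality. A moderately diverged neutrally evolving pair
is genuinely more similar than shuffled pairings and will earn a small p;
such pairs are screened out by the Ka/Ks < 0.5 threshold, not by q. This is
why the selection rule requires both conditions. Type-I error of the test
is controlled, and checked in the acceptance suite, under its own null
(independent random coding sequences), where exchangeability makes p
exactly super-uniform.

p-values are Benjamini–Hochberg adjusted across all pairs of a run.
Per-uORF aggregation takes the *median* ratio and *median* q across the
per-order representative pairs (robust to one aberrant order; a uORF whose
every pair is undefined can never be a candidate); candidates need median
ratio < 0.5 and median q < 0.05, both strict.

## Taxonomic ranges

The 20 metazoan categories form a ladder of "clade X minus already-claimed
inner clades" rules; testing them in order assigns every metazoan lineage
exactly one category (property-tested for exhaustiveness and disjointness).
Ctenophora stays in the code and is simply expected to be empty on real
data. Per category the pipeline counts *distinct orders* with representative
hits — duplicate records within an order never change a profile. The range
label is the non-empty category whose backbone chain shares the fewest
clades with the query's own chain (distality along the cladogram, not ladder
position); ties at equal depth are broken by the fixed ladder order, and the
full profile is always reported alongside, since a single label cannot
express patchy conservation. After manual alignment review, a removal list
(uORF, record) re-derives profiles and ranges, and uORFs that fall below
two other orders are discarded.

## Families and HG numbers

CPuORF-containing genes are grouped into ortholog groups ("mORF clusters")
by all-vs-all protein search of their longest mORF peptides: connected
components of the reciprocal-hit graph at E < 10⁻³ — a deliberately simple
stand-in satisfying the same partition contract as a dedicated
ortholog-grouping engine. Within each group, uORF peptides are compared
pairwise at E < 2000; the binary distance (0 = hit in either direction,
1 = no hit) is clustered with single linkage and cut at h = 0.5, which for
0/1 distances provably equals connected components of the hit graph (the
generic `hclust`/`cutree` route is used, and the equivalence is
property-tested). Families are sorted by descending range distality, then
descending total order count, then smallest member gene id; ortholog groups
take their number from their best family, and families within a group get
sub-numbers in the same order — `HG0004.1`, `HG0004.2`. The sort key is
total, so numbering is invariant to input order.

Overlapping splice-variant uORFs of one gene are resolved with the declared
precedence: same reading frame → longest conserved region (the number of
peptide positions where at least half of the representatives agree with the
original — a stated proxy for by-eye curation), ties and different-frame
overlaps → lowest median Ka/Ks.

## The synthetic world

`make_fixture()` emits a complete toy input set (genome, GFF3, collection,
taxonomy, truth table) that is a pure function of its spec. The default
states the world the tests assume: 20 genes of a human-like query
(Primates/Euarchontoglires); 24-residue uORFs and 60-codon mORFs; homolog
divergence simulated by per-site substitution proposals (rate 0.4 for
uORFs, 0.15 for mORFs) accepted always if synonymous and with probability
ω otherwise (ω = 0.05 for conserved plants, 1 for neutral plants, 0.2 for
mORFs) — this accept/reject scheme makes ω the true dN/dS of the process,
which is the quantity the parameter-recovery checks are stated in, and maps
monotonically onto a "synonymous bias" parameterisation. Half of a fusion
plant's RefSeq records are fused. Structural features exercised by design:
one gene with two splice variants sharing an identical uORF, one uORF start
codon split by an intron, one minus-strand gene, two paralog gene pairs
(shared mORF family, dissimilar uORFs) that must surface as `HGxxxx.1/.2`.

Deliberate unrealisms, hence what a green end-to-end test does *not*
establish: UTRs are scrubbed of unplanned ATGs (real UTRs are full of
spurious uORFs — those are exercised by the randomized oracle tests
instead); non-fused records carry a spacer with stop codons in all three
frames so chance HSP placement cannot fake a fusion; intergenic sequence,
intron length and record structure are minimal; there is no sequencing
error, no alternative transcription start beyond the one designed pair, and
collection sizes are ~60 records, not millions. Green means the machinery
is correct, not that desk-scale counts transfer to genome-scale inputs.

## Runtime and determinism

Every stochastic step takes a seed: the fixture is byte-identical under its
spec, permutation p-values are reproducible, per-pair seeds derive
deterministically from the run seed after a canonical sort, and HG labels
are invariant to input permutation. Heavy search steps are cached in the
output directory when one is configured; re-runs reuse caches unless
forced. The default fixture pipeline completes in well under a minute on
one CPU with the builtin engine.

## Known limitations

* The builtin engine is exact Smith–Waterman per seeded pair — fine for
  fixtures and small collections, not for million-record databases; use the
  BLAST+ engine there.
* NG86 with JC correction underestimates at high divergence and ignores
  transition/transversion bias; the estimator is pluggable by design, and
  maximum-likelihood codon models are out of scope.
* The ortholog-group fallback is reciprocal-hit components, not a full
  tree-aware orthology method.
* Fusion detection operationalises "fused" as same-frame with no
  intervening stop between HSPs; gapped HSP edge cases wobble by a codon,
  absorbed by the stated one-codon tolerance.
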