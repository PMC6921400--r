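---
title: "Variation-aware read alignment with dynamic variation trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variation-aware read alignment with dynamic variation trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varatree)
```

## The problem

Short-read aligners that map against a single linear reference are biased
toward the reference allele: a read that carries a known insertion or
deletion either fails to align, aligns with its variant-spanning portion
soft-clipped, or aligns with a spurious novel-variant call. Full genome
graphs solve this in principle but at substantial index cost, since every
variant multiplies the number of paths the index must represent.

`varatree` takes the middle road: the index stays linear, and variation is
brought in **locally and lazily**, only at seed-extension time. Known SNPs
are folded into the reference encoding itself, so they cost nothing; known
INDELs are kept in a positional side table and assembled, per seed, into a
small trie of local haplotypes over which the extension alignment runs
simultaneously.

## The reference encoding

Each reference position is a 4-bit site code over `{A, C, G, T}` (bits 1, 2,
4, 8). Loading a FASTA sets exactly the reference base's bit; integrating a
SNP ORs in the alternate's bit. A read base matches a site iff its bit is
set in the code, so SNP-tolerant matching is a single `bitwAnd` — one test
regardless of how many SNPs are recorded at the site. The reference base bit
is never cleared, and decoding a site always reproduces the original base,
so the encoding is lossless.

Two policy decisions are ours (the underlying method leaves them open):
non-ACGT reference characters (N, IUPAC codes) are encoded with all four
bits set — they accept any read base but are excluded from k-mer seeding —
while a read `N` matches nothing. Permissive-reference/strict-read avoids
inflating mapping quality on undetermined reference sites. Multi-allelic
VCF records are split into independent variant records, and anchored VCF
INDEL notation (`REF=A, ALT=ATT`) is normalized once, on input, to
anchorless insertions/deletions at the base after the anchor; all internal
coordinates are 0-based half-open, converted back only at the SAM boundary.

## The variation tree

For one seed, the extension windows on either side (plus, when mate
anchoring is involved, windows from several candidate loci) are inserted
into a radix trie: nodes are maximal fragments shared by the windows,
compared as (site code, reference base) pairs; children of a node are
ordered alphabetically by leading reference base. SNPs live inside node
labels through the site codes and never branch the tree; only INDELs create
optional variant edges, attached to the node covering their position. A
deletion whose end lies beyond the window creates a *pseudo node* carrying
the out-of-window deleted bases, so that the deletion has a well-defined
end point in the tree. With one window and no variants the tree degenerates
to a single chain.

Haplotype *paths* — one choice of non-overlapping INDELs per window — are
enumerated up-front with deterministic ids: windows in input order, and
within a window a depth-first recursion over variants sorted by position
(ties by variant id) that explores the variant-free branch before the
variant-taking branch, so the all-reference path of the first window always
has id 1. Paths realizing identical haplotype strings are deduplicated
keeping the smallest id, with all source windows kept as provenance. Two
insertions at the same point, or a variant strictly inside another's
reference interval, are not combined on one path: their composition order
would be ambiguous, and the realized-string deduplication would only mask
the ambiguity.

Enumeration is capped (`path_cap`, default 256 per tree) and raises a typed
error instructing the caller to prune rather than silently truncating.

## Traversal and the generalized Landau-Vishkin

The classical Landau-Vishkin algorithm iterates edit count `e` and diagonal
`d`, storing per `(e, d)` only the farthest-reaching match; each round seeds
a diagonal from its three neighbours (mismatch, insertion, deletion) and
then slides along exact matches in `O(e·n)` total work.

`varatree` generalizes both ingredients:

* the *slide* becomes **VATR**, a queue-driven breadth-first traversal of
  the tree. A queue entry groups all live paths at the same tree locus with
  the same read cursor, so matching against a shared node label is done once
  per entry. Entries split at variant decision points (paths taking an
  insertion edge match the allele exactly — no SNP codes exist inside
  alternate alleles; paths taking a deletion edge consume zero read bases
  and resume at the deletion's end node) and at node boundaries (per-path
  successors). Every live path stops exactly once: mismatch, read exhausted,
  or haplotype exhausted.
* the *matrix* becomes a per-path collection of farthest states. After each
  VATR round, hits are merged keeping, per path and diagonal, the longest
  extension (ties: smaller resume cursor).

A candidate is emitted whenever a path consumes the entire read; the
iteration stops at the least `e` with an emission (or runs to `e_max` in
exhaustive mode). Ties among equal-`e` candidates break by fewest taken
variants, then smallest path id — determinism plus parsimony in variant
usage.

**Diagonal bookkeeping.** Candidates report a reference-relative diagonal:
read consumed minus reference consumed, so novel insertions push `d`
positive, deletions negative, and taken INDEL edges shift `d` at zero edit
cost. Internally, however, states are merged on the read-vs-*haplotype*
diagonal. The reference-relative quantity is flat across an insertion
allele (an insertion consumes haplotype but no reference), so it is not
injective over traversal states and would merge a state inside an allele
with a distinct state beyond it, losing the better continuation. The
haplotype diagonal is injective per trajectory and makes the classical
"longest wins on a diagonal" argument sound path by path.

**Costs.** Known variant edges are free; unindexed differences pay unit
Levenshtein costs. That asymmetry is the entire point of variation-aware
extension: a read spanning a known 3 bp deletion aligns at `e = 0` on the
deletion-taking path, while a linear aligner must either spend 3 edits or
clip.

**Pruning.** The optional speed heuristic terminates a path once it carries
more than `ceiling(3 × read_len / 100)` *large* variants (default length
threshold 4 bp; both knobs exposed in `vara_config()`), reflecting how
unlikely it is for a short read to genuinely span many large variants. The
heuristic deliberately sacrifices completeness; tests that assert exact
equivalence with the brute-force path enumeration therefore disable it, and
its boundary behaviour (4 large variants on a 100 bp read pruned, 3 kept)
is asserted separately. The edit budget defaults to
`e_max = ceiling(0.06 × read_len)`: Illumina error rates plus small
unindexed variants comfortably fit in 6%, and the budget is configurable.

## CIGAR restoration

Extension alignments are expressed against a realized haplotype ("ALT
coordinates"). For SAM output they are composed with the
haplotype-to-reference map induced by the taken variants (match blocks,
insertion segments consuming haplotype only, deletion segments consuming
reference only). Canonicalization then collapses adjacent
insertion/deletion runs — in either order — into match-or-mismatch `M`
(leftmost pairing, `M` before the leftover op). The four boundary
situations fall out of this algebra rather than being special-cased: a 1 bp
ALT deletion inside a 1 bp insertion variant cancels to `M`; a 1 bp ALT
insertion at a 1 bp deletion junction collapses to `M`; an ALT deletion
inside a longer insertion variant leaves a reference insertion; an ALT
insertion at a longer deletion junction leaves a shortened deletion plus
`M` (possibly mismatching — `M` is the SAM match-or-mismatch dialect
throughout, and SNP-tolerant matches stay `M`). Leading/trailing reference
deletions move into the reported position, which is the leftmost reference
base consumed; an alignment starting inside an insertion variant reports
the base after the insertion anchor. Soft clips pass through unchanged.

The test suite verifies restoration against an independent base-level
oracle: expand both the ALT alignment and the variant map to per-base
correspondences, pair adjacent read-only/reference-only bases greedily
leftmost (blocked by aligned pairs), and require the restored CIGAR to
replay to exactly that correspondence, on the four rule cases and on 500
random compositions.

## The mapper

Seeding is deliberately plain — a k-mer hash (default `k = 16`) over every
reference position with a repeat cap (64) and stride-8 sampling of read
k-mers on both strands — because the variation-aware contribution lives in
the extension stage, and seeding sensitivity is dominated by the flanking
variant-free sequence anyway. The batch fast path counts SNP-tolerant
mismatches along every candidate diagonal for all reads at once; ends fully
explained within the edit budget pair directly. An end that plain extension
cannot explain (typically an INDEL-spanning read) enters the VARA path: the
exact diagonal run around the seed is backed off by up to 6 bp — so that
chance matches at a variant junction cannot push the extension window past
the variant — and left/right extension trees are built and aligned, the
left side on reflected coordinates so the seed-adjacent end stays pinned
(semiglobal extension; the far ends are free). Side results are spliced
with the exact block and restored to reference coordinates.

Ends without any seed hit are anchored through the mate under the insert
model: a window `[pos + mean − w·sd − read_len, pos + mean + w·sd +
read_len]` on the appropriate side and opposite strand (defaults: mean 500,
sd 25, `w = 4`) is scanned by diagonal, with VARA as fallback. Pair
selection minimizes summed edit distance under proper orientation and an
insert-size gate (`mean ± w·sd` plus a 50 bp slack for spanned INDELs).
Mapping quality is a gap score, `40·(e2 − e1)/max(1, e2)` capped at 60 and
0 on ties, where `e1`, `e2` are the best and second-best pair scores — the
method itself does not prescribe a mapping-quality formula, so a monotone
gap-based score was chosen and is config-exposed. If the best candidate
explains less than the full read within the budget, the unexplained
terminal run is emitted as a soft clip.

## The simulator and what passing tests mean

`simulate_genome()` draws a uniform random genome; `simulate_variants()`
plants SNPs (default rate 1e-3) and INDELs (1e-4 each, geometric lengths
with p = 0.25 capped at 20 bp) with a 25 bp minimum spacing;
`simulate_reads()` draws fragments from the **variant-applied** genome with
normal insert sizes (500 ± 25), FR orientation, randomized read-1/read-2
assignment, and i.i.d. substitution errors (default 0.2%), then lifts truth
positions back to original reference coordinates — so variant-spanning
reads are exactly the stress case, and accuracy is judged in reference
coordinates with a 10 bp tolerance (the tolerance is a parameter; published
accuracy metrics of this kind do not state one). An `mhc_like` preset adds
a 5 kb sub-region at 10× variant density as a desk-scale analogue of a
dense, complex region.

The default validation sizes are a 200 kb genome with 20,000 pairs of
100 bp reads and 10,000 pairs of 250 bp reads — large enough that
accuracy is measured on tens of thousands of ends and hundreds of ends
span INDELs, small enough that the whole suite runs on one CPU in minutes.

The simulator emulates the geometry of the problem, not the chemistry of
the instrument: uniform base composition (no repeat families beyond chance,
so seeding is easier than on a real genome), i.i.d. substitution errors
(no quality decay, no indel errors), uniform coverage, haploid variants,
and all planted variants present in the index. Passing tests therefore
demonstrate the correctness of the encoding/tree/extension/restoration
machinery and the *relative* value of variant knowledge (the ablation runs
strip it and must strictly increase soft-clipped plus unmapped ends); they
do not predict absolute accuracy on real sequencing data, where unindexed
variation, error correlation and genomic repeats all bite.

## Numerical and degenerate-input choices

* k-mer codes are packed into doubles (`4^16 < 2^53`, exact).
* Empty windows, unknown chromosomes/paths, malformed CIGARs, reference
  mismatches in variant records and index-format mismatches raise typed
  conditions (`varatree_error_*`); per-record problems (a variant whose
  reference allele does not match) reject that record with a count rather
  than failing the batch.
* Reads shorter than `k` cannot be seeded and error out explicitly.
* A read ending inside an insertion allele is a legitimate ran-to-end;
  partially consumed insertions are trimmed to their consumed suffix when
  the alignment is restored.
* Deletion edges at the exact boundary of a consumed region count as not
  taken (a trailing deletion would be meaningless in SAM).
* The insert-size gate and anchor windows are clamped at chromosome edges;
  extension windows truncated at an edge are flagged but still usable.

## Limitations

Single-end mapping exists only as the mate-rescue fallback; there is no
BAM/CRAM output, no affine-gap or base-quality-aware scoring, no
multi-mapping reporting beyond the best pair, and structural variants other
than simple insertions/deletions are out of scope. Path enumeration is
exponential in the number of co-windowed INDELs and relies on the cap plus
the pruning heuristic; extremely variant-dense regions (beyond the
`mhc_like` preset's 10× density) may exceed the cap and fall back to
pruned, flagged results. Mapping is single-threaded.
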