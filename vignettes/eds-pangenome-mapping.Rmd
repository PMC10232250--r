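---
title: "Mapping short reads to an elastic-degenerate pangenome"
author: "edsmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping short reads to an elastic-degenerate pangenome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edsmap)
```

## The representation

A pangenome collects the genomes of many individuals of one species. Mapping
reads against a single linear reference penalizes reads that carry common
non-reference alleles (reference bias); mapping against a general sequence
graph removes the bias but pays for it with index complexity. `edsmap` takes
a middle road: variation that is local — SNPs, small insertions and
deletions, multi-allelic alternatives — is written *into the sequence* using
elastic-degenerate string (EDS) syntax, and only structural variation
becomes graph topology.

An ED symbol is a finite set of alternative strings, written
`(u1|...|um)`; a bare base is a singleton symbol and `N` abbreviates
`(A|C|T|G)`. An EDS is a sequence of ED symbols, and a plain string matches
it by choosing one alternative per symbol:

```{r}
s <- parse_eds("NG(A|)CA(AT|TA)GA")
s
head(sort(enumerate_matches(s)))
```

The length of an EDS is the length of its textual form, so every character
— syntax included — has a coordinate. A pattern *occurs* at position `p`
when it matches a prefix of what can be read from `p` onwards; this
per-base notion of occurrence is what lets a positional index address bases
inside long alternatives:

```{r}
find_occurrences("GACA", s)
occurs_at("ATGA", s, 10)
```

Structural variants cannot be written in place. A copy-number variant over
a reference span splits the EDS into three nodes — prefix, repeated unit,
suffix — with a self-loop on the middle node; a large deletion adds a
bypass edge over the deleted node; a large insertion becomes an optional
node with a bypass edge around it. Node labels, concatenated in reference
order and separated by `#`, form the linearized string G^; an edge
`(v, v')` is stored as the separator-number pair `sep(v)+1 -> sep(v')`,
together with its transpose for backward traversal. Consecutive nodes of a
chain are connected by explicitly stored edges of the same form, so forward
reading is uniformly edge-driven: at a separator the next readable bases
are exactly those behind the separators its edges point to.

```{r}
g <- eds_graph("TT#NG(A|)CA(AT|TA)GA#T",
               edges = rbind(c(1, 1), c(2, 1), c(2, 2)))
successors_after_separator(g, 2)
```

### Coordinates

G^ itself is the coordinate system: the coordinate of a base is its
position in the string. On cycle-free matches coordinates increase
strictly, and when a walk takes a jump edge the coordinate sequence shows a
single descent:

```{r}
coords_of_match("TTAGACATAGAT", g)
```

A bit-vector `I` marks which characters of G^ originate from the linear
reference (reference bases outside symbols, and the reference alternative —
always written first — inside symbols). For a reference-origin base at
position `p`, its linear coordinate is `rank(I, p)`, the number of ones up
to `p`; rank is served in constant time from precomputed prefix popcounts.
Non-reference bases have no linear coordinate of their own: they are
reported at the nearest preceding reference base and flagged, because SAM
emission needs a total map. This is a deliberate extension — projection is
only exact on reference-origin bases — and records written from such
positions carry an `ar:i:1` tag.

## The minimizer index

A `(w,k)`-minimizer is the k-mer of smallest hash among all k-mers starting
in a window of `w` consecutive positions. Unlike a plain string, an EDS
position can carry many k-mers (one per combination of alternatives within
reach). A single right-to-left scan computes, for every position `p`, the
set `K_p` of strings readable from `p` (truncated at length `k`), using two
auxiliary sets: at a symbol's right bracket the set after the symbol is
saved as `K_r`, each alternative prepends onto `K_r`, alternative start
sets accumulate into `K_l`, and `K_l` is released at the left bracket. `N`
stays literal during the scan and is expanded only when the per-position
minimum is taken; k-mers with more than two `N`s are skipped (expansion is
then at most 16-fold, and such k-mers are uninformative seeds).

For a graph, each node's scan is seeded with the k-mers starting at its
successors, so k-mers continuing over a jump edge shape the sets near node
ends and are reported at their start positions — including across the
self-loop of a copy-number node. Windows slide over the whole linearized
string; separator and bracket positions simply contribute no k-mer. Ties
within a window go to the leftmost position.

```{r}
idx <- build_index(g, k = 3, w = 4, mode = "lex")
idx$postings
```

Two hash modes exist. `"lex"` uses the lexicographic rank itself (exact in
doubles up to k = 26) and is pinned in every worked example and test, so
expected minimizers can be read off by eye. `"mix"`, the default, folds the
bases through a 31-bit multiplicative congruential mix — all arithmetic
stays below 2^53 and therefore exact in doubles — so minimizer choice is
decorrelated from base composition. Over-frequent minimizers are trimmed:
postings lists longer than `trim_threshold` (default 512) are dropped,
removing repetitive seeds that cost time without aiding placement.

Defaults are `(w, k) = (5, 20)`. Larger `k` makes seeds more specific,
larger `w` samples fewer of them; (5,20) keeps enough matching minimizers
per 100 bp read to place it while storing roughly one posting per five
positions.

## Mapping

Mapping a read proceeds in three stages.

**Seeding.** The read's own minimizers (same `(w,k)` and hash mode as the
index, both orientations) are looked up, giving pairs
`(read position i, G^ position j)`.

**Chaining.** Pairs are ranked by the length of a maximum colinear chain
ending at them — strictly increasing in both coordinates — computed as a
longest-increasing-subsequence over read positions with a prefix-maximum
tree. Chains are confined to batches whose G^ span stays below `lambda`
(default twice the read length), so only minimizers close together in the
pangenome chain together.

**Alignment.** From the best seed `(i*, j*)` a semi-global alignment is
computed under unit edit costs with error bound `d` (default 10% of the
read length, rounded up): the whole read must align — no clipping — to a
substring of G^, with `r[i*]` pinned to `G^[j*]`. The pin splits the
problem into independent forward and backward halves; a forward distance
`d'` leaves `d - d'` for the backward half, and the two optima add. The
table is computed column-wise along G^. Base columns use the standard
match/mismatch/insertion/deletion recurrence (insertions within a column
are resolved by a min-plus prefix scan, so a column is a handful of
vectorized operations). At `(` and `|` the column is a copy of the column
immediately preceding the symbol; at `)` it is the element-wise minimum
over the columns ending each alternative (both cached during the scan); at
`#` the computation branches to every successor position over the jump
edges, each branch inheriting the current column. Cells above the bound —
and, with pruning on, cells that can no longer beat the best complete
alignment found so far — are discarded; pruning never changes the optimum,
which the test suite checks by running both ways.

Two consequences of the column discipline are worth noting. A dead column
*inside* a symbol must not kill the branch, because sibling alternatives
cached in the accumulator may still be alive; the scan therefore only
abandons a branch on a dead column outside symbols. And a seed may pin a
base *inside* an alternative, in which case the walk is committed to that
alternative and the scan skips the symbol's remaining alternatives.

Branching at separators is depth-first with the shared bound. No
memoization is performed: every node label contributes at least one base
column, each base column advances the band, and the band dies after at
most `|read| + d` base columns, so even self-loops unwind in bounded
depth. (A design note: a memo on separator and remaining budget was
considered and dropped — at short-read scale the bound kills duplicate
work faster than a memo lookup would.)

Seeds are tried in descending chain score (forward strand first, then
leftmost position on ties); the first seed reaching a total distance of at
most `d` is reported, since its two halves are individually optimal given
the pin. A read with no such seed is reported unmapped — an outcome, not
an error. Traceback over the column DAG yields the edit script; `=`/`X`
collapse to `M` in the CIGAR, and the NM tag carries the distance.

```{r}
map_read("TTAGAATCGA", g, idx, d = 3)[c("distance", "lo", "hi", "cigar")]
```

## The read sampler and what passing tests mean

`sample_reads()` emulates the evaluation protocol: a start position uniform
over the base positions of G^, one alternative chosen uniformly at every ED
symbol (an `N` likewise becomes a uniform base), a jump edge chosen
uniformly at every separator, and then per-base errors — substitution,
insertion and deletion are read as three independent per-base channels,
each at the stated rate (0.1% by default; the sentence defining the error
model is ambiguous between per-type and total, and the per-type reading is
documented here). Insertions add a uniform base after the current one;
substitutions draw from the three other bases. Walks that reach a sink
early are redrawn, so start positions are effectively uniform over
positions that can complete a read.

The sampler tracks the truth coordinate of every read, and `evaluate()`
scores mapping rate and the fraction of reads placed within a tolerance
(default ±10 G^ positions — the accuracy notion "starting position equal or
very close" is otherwise unquantified) of their truth position.

The generator emulates uniform sampling and a memoryless error process. It
does not emulate sequencer error profiles (quality-dependent error rates,
homopolymer artifacts), coverage biases, paired ends, or contamination; a
passing recovery test shows that the index-chain-align pipeline inverts the
generator's own process on a variation-dense graph, not that real-library
artifacts are handled.

## Problem sizes and numerical choices

The test suite runs everything at desk scale, chosen so the full suite
finishes in about a minute: worked examples on the 22-character running
graph; oracle equivalence (occurrence semantics, k-mer sets, forward DP,
chain scores) on hundreds of random graphs of up to 3 nodes and a few
dozen bases, against brute-force enumeration; and parameter recovery of
500 length-100 reads at 1% per-channel error from a 10 kb synthetic
pangenome carrying 250 SNPs, ten 1-4 bp indels and one 300 bp copy-number
variant, indexed at the default (5,20) — the recovery criterion is at
least 95% of reads within ±10 of truth, and the observed value is
comfortably above it.

Numerical details that matter: all hash arithmetic is kept below 2^53 so R
doubles are exact; lexicographic mode therefore caps k at 26, the mixing
mode at 32. Equal window hashes resolve to the leftmost position; equal
alignment distances resolve to the smaller start coordinate and then the
forward strand. The structural-variant cutoff — indels with at least 20 bp
length difference become graph edges, shorter ones stay in place — is a
documented default in the spirit of small-indel support in linear-graph
aligners, not a value taken from elsewhere. Overlapping variants are
dropped left-to-right keep-first, small variants before structural ones,
and small variants whose symbol would straddle a node split are dropped so
splits always fall between symbols.

## Known limitations

Inversions and mobile-element insertions are recognized in the VCF and
counted, but not represented. Clipping, paired-end mapping, mapping
quality, secondary alignments and affine gap penalties beyond unit costs
are out of scope; copy-number bounds of CNV records are not enforced
during alignment (the self-loop encodes repetition, not multiplicity).
Projection of alignments starting on non-reference bases is approximate by
construction, as described above. The implementation is single-threaded;
per-read results are independent, so any outer parallelism reproduces the
same output.
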