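# edsmap

Short-read mapping to a pangenome represented as a graph of
elastic-degenerate strings (EDS), for people who want pangenomic mapping —
reduced reference bias, structural variants in the index — without the
machinery of a general sequence-graph aligner.

## The representation and the method

A pangenome is built from a reference FASTA and a VCF. Local variation is
written directly into the sequence with a regular-expression-like syntax:
an ED symbol `(u1|...|um)` is a set of alternative strings (`(A|)` is an
optional `A`, `N` abbreviates `(A|C|T|G)`), and an EDS is a sequence of
such symbols — a string matches it by choosing one alternative per symbol.
Structural variation becomes topology: a copy-number variant over a span
splits the EDS into three nodes with a self-loop on the repeated unit, a
large deletion adds a bypass edge, a large insertion an optional node.

Node labels joined by `#` form one linearized string G^, which doubles as
the coordinate system: every base has a 1-based position, and jump edges
are stored as separator-number pairs `sep(v)+1 → sep(v')` plus their
transpose. A bit-vector *I* marks reference-origin characters, so a graph
coordinate *p* projects to linear-reference coordinate rank(*I*, *p*) in
constant time.

Mapping a read *r*:

1. **Index** — for every position of G^, the minimum-hash k-mer among all
   k-mers occurring there is found by one right-to-left scan maintaining
   the per-position k-mer sets K_p with two auxiliary sets K_r and K_l;
   a window of w consecutive positions marks its smallest entry as a
   (w,k)-minimizer (default (5,20)), and over-frequent minimizers are
   trimmed.
2. **Seed & chain** — minimizers of *r* (both strands) are looked up,
   giving pairs (i, j); each pair is scored with the length of a maximum
   colinear chain ending at it (an LIS computation), confined to a window
   j-span < λ (default 2|r|).
3. **Align** — from the best seed (i\*, j\*), a banded semi-global edit
   distance D is computed column-wise along G^ with r[i\*] pinned to
   G^[j\*] and bound d (default ⌈0.1|r|⌉): copies of the pre-symbol column
   at `(` and `|`, element-wise minima over alternative ends at `)`, and
   branching over jump edges at `#`. Forward and backward halves are
   independent and their optima add. The result is projected to reference
   coordinates and written as SAM (NM = distance, `gp` = G^ coordinate).

A truth-tracked read sampler (uniform start, uniform alternative and edge
choice, independent per-base substitution/insertion/deletion channels) and
an evaluator close the loop for end-to-end accuracy testing.

## Worked example

The running example throughout the documentation: reference `TTNGACAATGAT`
with a deleted A, an AT/TA alternative, and a copy-number variant over the
middle span.

```r
library(edsmap)

g <- eds_graph("TT#NG(A|)CA(AT|TA)GA#T",
               edges = rbind(c(1, 1), c(2, 1), c(2, 2)))
idx <- build_index(g, k = 3, w = 4, mode = "lex")
idx$postings
#> $AAG
#> [1] 20
#> $AAT
#> [1] 11
#> $ACA
#> [1] 7
#> $AGA
#> [1]  4 17
#> $ATG
#> [1] 13

coords_of_match("TTAGACATAGAT", g)
#>  [1]  1  2  4  5  7 10 11 16 17 19 20 22

res <- map_read("TTAGAATCGA", g, idx, d = 3)
res[c("distance", "lo", "hi", "strand", "cigar")]
#> $distance
#> [1] 2
#> $lo
#> [1] 1
#> $hi
#> [1] 20
#> $strand
#> [1] "+"
#> $cigar
#> [1] "4M1D3M1I2M"
```

The read maps from G^ position 1 to 20 with edit distance 2: the chain
score ranks seed (5,11) first, the forward half aligns `AATCGA` with one
inserted base, and the backward half spans the `#` with one deletion.

A full pipeline is also available as functions (`cmd_build`, `cmd_index`,
`cmd_map`, `cmd_sample`, `cmd_evaluate`) and as a thin command-line script:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/edsmap.R", package = "edsmap"))')
Rscript $CLI build  --fasta ref.fa --vcf vars.vcf --out pg
Rscript $CLI index  --graph pg --out pg.idx.json
Rscript $CLI map    --index pg.idx.json --graph pg --fastq reads.fq --out out.sam
```

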