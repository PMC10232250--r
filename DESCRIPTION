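Package: edsmap
Title: Short-Read Mapping to Pangenomes Represented as Elastic-Degenerate
    String Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Represents a pangenome as a linearized graph of
    elastic-degenerate strings (EDS) built from a FASTA reference and a VCF
    of variants: SNPs and small indels are encoded in place with a
    regular-expression-like syntax, while copy-number variants and large
    indels become node splits with jump edges. The linearized string is
    indexed with (w,k)-minimizers computed by a single right-to-left
    k-mer-set scan, and short reads are mapped by colinear seed chaining
    followed by a banded semi-global edit-distance dynamic program that
    traverses separators via jump edges. Alignments are projected onto
    linear-reference coordinates through a rank-supported indicator
    bit-vector and reported as SAM. Includes a truth-tracked read sampler
    and an accuracy evaluator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
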