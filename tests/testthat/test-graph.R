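test_that("variant classification separates in-place and structural classes", {
  rec <- data.frame(
    CHROM = "c", POS = c(10, 20, 30, 40, 50, 60, 70),
    ID = ".",
    REF = c("A", "T", "C", "G", paste0("G", strrep("A", 50)), "A", "A"),
    ALT = c("G", "<INV>", "<DUP>", "<INS:ME:ALU>", "G", "AT", ""),
    QUAL = ".", FILTER = ".",
    INFO = c("", "SVTYPE=INV", "SVTYPE=DUP;END=120", "SVTYPE=INS",
             "", "", ""),
    stringsAsFactors = FALSE)
  cls <- classify_variants(rec)
  expect_equal(cls$class,
               c("snp", "skipped", "cnv", "skipped", "large-deletion",
                 "small", "skipped"))
  expect_equal(cls$reason[2], "inversion")
  expect_equal(cls$reason[4], "mobile-element")
  expect_equal(cls$end[3], 120L)
  expect_equal(cls$end[5], 100L)  # pos + nchar(REF) - 1 = 50 + 51 - 1
})

test_that("a 50 bp deletion crosses the structural threshold, a 5 bp one does not", {
  rec <- data.frame(CHROM = "c", POS = c(5, 100), ID = ".",
                    REF = c(paste0("A", strrep("C", 50)), "GAAAAA"),
                    ALT = c("A", "G"), QUAL = ".", FILTER = ".", INFO = "",
                    stringsAsFactors = FALSE)
  cls <- classify_variants(rec)
  expect_equal(cls$class, c("large-deletion", "small"))
})

test_that("in-place EDS construction reproduces the worked example", {
  small <- data.frame(chrom = "ref", pos = c(4, 8), ref = c("GA", "AT"),
                      alt = c("G", "TA"), stringsAsFactors = FALSE)
  built <- build_eds("TTNGACAATGAT", small)
  expect_equal(as.character(built$eds), "TTNG(A|)CA(AT|TA)GAT")
  # reference-origin flags cover exactly the reference characters
  expect_equal(sum(built$flags), 12L)
  expect_equal(built$ref2text[1:4], 1:4)
})

test_that("variant-free construction is the identity with all-ones flags", {
  built <- build_eds("ACGTTACG")
  expect_equal(as.character(built$eds), "ACGTTACG")
  expect_true(all(built$flags == 1L))
  expect_equal(built$ref2text, 1:8)
})

test_that("multi-allelic records fold into one symbol; overlaps drop greedily", {
  one_rec <- build_eds("AAGAA", data.frame(pos = 3, ref = "G", alt = "C,T"))
  expect_equal(as.character(one_rec$eds), "AA(G|C|T)AA")
  expect_warning(
    two_rec <- build_eds("AAGAA",
                         data.frame(pos = c(3, 3), ref = c("G", "G"),
                                    alt = c("C", "T"))),
    "overlapping")
  expect_equal(as.character(two_rec$eds), "AA(G|C)AA")
})

test_that("REF mismatches are skipped with a warning, never fatal", {
  expect_warning(b <- build_eds("AAAA", data.frame(pos = 2, ref = "G",
                                                   alt = "C")),
                 "mismatch")
  expect_equal(as.character(b$eds), "AAAA")
})

test_that("graph construction encodes the copy-number variant as a self-loop", {
  cls <- classify_variants(fig_vcf_records())
  g <- build_graph(fig_ref(), cls)$graph
  expect_equal(g$gstring, "TT#NG(A|)CA(AT|TA)GA#T")
  expect_equal(nchar(g$gstring), 22L)
  expect_setequal(apply(g$edges, 1, paste, collapse = ","),
                  c("1,1", "2,2", "2,1"))
  expect_equal(rank1(g$indicator, g$n), 12L)
  expect_equal(g$indicator$bits,
               as.integer(strsplit("1101101001101100001101", "")[[1]]))
})

test_that("a variant-free build yields a single node without separators", {
  g <- build_graph(c(chr = "ACGTACGT"))$graph
  expect_equal(g$gstring, "ACGTACGT")
  expect_equal(nrow(g$edges), 0L)
  expect_equal(length(g$sep_pos), 0L)
})

test_that("large deletions get a bypass edge; insertions an optional node", {
  set.seed(5)
  ref <- c(c1 = random_dna(60))
  del <- data.frame(CHROM = "c1", POS = 10, ID = ".", REF = "N", ALT = "<DEL>",
                    QUAL = ".", FILTER = ".", INFO = "SVTYPE=DEL;END=40",
                    stringsAsFactors = FALSE)
  del$REF <- substr(ref, 10, 10)
  g <- build_graph(ref, classify_variants(del))$graph
  expect_equal(nrow(g$nodes), 3L)
  expect_setequal(apply(g$edges, 1, paste, collapse = ","),
                  c("1,1", "2,2", "1,2"))
  # the deletion path spells reference minus the deleted span
  spelled <- paste0(substr(ref, 1, 10), substr(ref, 41, 60))
  expect_equal(coords_of_match(spelled, g)[11], g$nodes$label_start[3])

  ins <- data.frame(CHROM = "c1", POS = 30, ID = ".",
                    REF = substr(ref, 30, 30),
                    ALT = paste0(substr(ref, 30, 30), random_dna(25)),
                    QUAL = ".", FILTER = ".", INFO = "",
                    stringsAsFactors = FALSE)
  g2 <- build_graph(ref, classify_variants(ins))$graph
  expect_equal(nrow(g2$nodes), 3L)
  expect_setequal(apply(g2$edges, 1, paste, collapse = ","),
                  c("1,1", "2,2", "1,2"))
  # both with and without the insertion match the graph
  with_ins <- paste0(substr(ref, 1, 30),
                     substr(g2$gstring, g2$nodes$label_start[2],
                            g2$nodes$label_end[2]),
                     substr(ref, 31, 60))
  expect_silent(coords_of_match(with_ins, g2))
  expect_silent(coords_of_match(unname(ref), g2))
})

test_that("separator successors follow the stored jump edges", {
  g <- fig_graph()
  expect_equal(successors_after_separator(g, 2L), c(4L, 22L))
  expect_equal(successors_after_separator(g, 1L), 4L)
  expect_error(successors_after_separator(g, 9L), "unknown")
  expect_equal(predecessors_before_separator(g, 1L), c(2L, 20L))
  # three-node chain: one natural continuation through the middle separator
  chain <- eds_graph("AAA#CCC#GGG")
  expect_equal(successors_after_separator(chain, 1L), 5L)
  expect_equal(successors_after_separator(chain, 2L), 9L)
})

test_that("node labels joined by '#' reproduce the gstring", {
  set.seed(41)
  for (r in 1:10) {
    g <- random_graph()
    labels <- vapply(seq_len(nrow(g$nodes)), function(v)
      substr(g$gstring, g$nodes$label_start[v], g$nodes$label_end[v]),
      character(1))
    expect_equal(paste(labels, collapse = "#"), g$gstring)
    for (lab in labels) expect_silent(parse_eds(lab))
  }
})

test_that("strings spelled along walks match the graph (enumeration oracle)", {
  set.seed(47)
  for (r in 1:15) {
    g <- random_graph()
    enum <- tryCatch(h_enum_graph(g, max_visits = 2L, limit = 200L),
                     error = function(e) NULL)
    if (is.null(enum)) next
    for (e in enum[seq_len(min(5L, length(enum)))]) {
      if (nchar(e$str) == 0L) next
      expect_silent(coords_of_match(e$str, g))
    }
  }
})

test_that("multiple chromosomes stay unconnected", {
  g <- build_graph(c(a = "ACGTACGTAA", b = "TTGGCCAATT"))$graph
  expect_equal(nrow(g$nodes), 2L)
  expect_equal(length(g$sep_pos), 1L)
  expect_equal(nrow(g$edges), 0L)
  expect_equal(project(g, 1L)$chrom, "a")
  expect_equal(project(g, 12L)$chrom, "b")
  expect_equal(project(g, 12L)$linear, 1L)
})

test_that("graph serialization round-trips", {
  cls <- classify_variants(fig_vcf_records())
  g <- build_graph(fig_ref(), cls)$graph
  pre <- file.path(withr::local_tempdir(), "g")
  write_graph(g, pre)
  g2 <- read_graph(pre)
  expect_equal(g2$gstring, g$gstring)
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$indicator$bits, g$indicator$bits)
  expect_equal(g2$chroms$ref_len, g$chroms$ref_len)
  expect_equal(g2$nodes, g$nodes)
})
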