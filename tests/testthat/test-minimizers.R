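test_that("hashing is deterministic and lexicographic mode is the rank", {
  expect_equal(kmer_hash("AAA", "lex"), 0)
  expect_lt(kmer_hash("AGA", "lex"), kmer_hash("TGC", "lex"))
  expect_equal(kmer_hash("AGA", "lex"), 0 * 16 + 2 * 4 + 0)  # base-4 digits
  expect_identical(kmer_hash(c("ACGT", "ACGT"), "mix")[1],
                   kmer_hash("ACGT", "mix"))
  expect_error(kmer_hash("ANG", "lex"), "no N")
  expect_error(kmer_hash(c("AA", "AAA")), "one length")
})

test_that("N expansion picks the minimum over concrete k-mers", {
  m <- min_kmer_with_N("NGA", 3L, "lex")
  expect_equal(m$kmer, "AGA")
  expect_equal(min_kmer_with_N("AAA", 3L, "lex")$kmer, "AAA")
  expect_null(min_kmer_with_N("NNNN", 4L, "lex"))     # over the N cap
  expect_null(min_kmer_with_N("AC", 3L, "lex"))       # shorter than k
  expect_equal(min_kmer_with_N(c("TTT", "NGA"), 3L, "lex")$kmer, "AGA")
})

test_that("the right-to-left scan reproduces the tabulated k-mer sets", {
  s <- parse_eds("CA(AT|TA)GA")
  res <- position_minima(s, 3L, mode = "lex", return_sets = TRUE)
  sets <- attr(res, "sets")
  expect_setequal(sets[[1]], c("CAT", "CAA"))   # CAA in K1
  expect_setequal(sets[[2]], c("ATA", "AAT"))   # AAT in K2
  expect_equal(sets[[5]], "TGA")                # K5 from Kr (= K10)
  expect_equal(sets[[8]], "AGA")                # K8 from Kr
  expect_setequal(sets[[3]], c("TAG", "ATG"))   # Kl released at '('
})

test_that("variant-free minima are the plain per-position k-mers", {
  set.seed(71)
  s <- random_dna(40)
  res <- position_minima(parse_eds(s), 5L, mode = "lex")
  expect_equal(res$pos, 1:36)
  expect_equal(res$kmer, substring(s, 1:36, 5:40))
})

test_that("scan sets equal path-prefix enumeration on random instances", {
  set.seed(73)
  for (r in 1:40) {
    txt <- random_eds_text(sample(2:4, 1L))
    s <- parse_eds(txt)
    if (s$length == 0L) next
    enum <- tryCatch(h_enum_eds(s, limit = 200L), error = function(e) NULL)
    if (is.null(enum)) next
    k <- sample(2:4, 1L)
    res <- position_minima(s, k, mode = "lex", return_sets = TRUE)
    sets <- attr(res, "sets")
    for (p in which(s$meta$type == "base")) {
      oracle <- unique(unlist(lapply(enum, function(e) {
        t0 <- which(e$pos == p)
        if (length(t0) == 0L) return(character(0))
        substr(e$str, t0, min(t0 + k - 1L, nchar(e$str)))
      })))
      # keep only full-length k-mers on both sides
      oracle <- oracle[nchar(oracle) == k]
      got <- sets[[p]]
      got <- got[nchar(got) == k]
      got <- as.character(unique(unlist(lapply(got, edsmap:::.expand_N))))
      expect_setequal(got, as.character(oracle))
    }
  }
})

test_that("graph minima handle edge-spanning k-mers as in the worked example", {
  g <- fig_graph()
  gm <- graph_position_minima(g, 3L, mode = "lex")
  expect_equal(gm$kmer[gm$pos == 4], "AGA")
  expect_equal(gm$kmer[gm$pos == 1], "TTA")   # TT + N over the first edge
  expect_equal(gm$kmer[gm$pos == 20], "AAG")  # A + NG over the self-loop
  expect_equal(gm$kmer[gm$pos == 13], "ATG")
  # no k-mer is reported at separator positions
  expect_false(any(gm$pos %in% g$sep_pos))
})

test_that("single-node graphs reduce to the plain EDS scan", {
  txt <- "AC(GT|C)ATG"
  g <- eds_graph(txt)
  expect_equal(graph_position_minima(g, 3L, mode = "lex"),
               position_minima(parse_eds(txt), 3L, mode = "lex"))
})

test_that("sets near a node end reflect the successor label", {
  # two-node chain: k-mers spanning '#' occur at their start positions
  g <- eds_graph("ACGT#TTTT")
  gm <- graph_position_minima(g, 3L, mode = "lex")
  expect_equal(gm$kmer[gm$pos == 3], "GTT")
  expect_equal(gm$kmer[gm$pos == 4], "TTT")
  ctx_occurrences <- vapply(seq_len(nrow(gm)), function(r)
    occurs_at(gm$kmer[r], g, gm$pos[r]), logical(1))
  expect_true(all(ctx_occurrences))
})

test_that("window selection reproduces the (4,3)-minimizers of the example", {
  g <- fig_graph()
  gm <- graph_position_minima(g, 3L, mode = "lex")
  sel <- select_minimizers(gm, 4L, g$n)
  expect_equal(paste0(sel$kmer, "@", sel$pos),
               c("AGA@4", "ACA@7", "AAT@11", "ATG@13", "AGA@17", "AAG@20"))
  # w = 1 marks every position's minimum
  sel1 <- select_minimizers(gm, 1L, g$n)
  expect_equal(sel1$pos, gm$pos)
})

test_that("variant-free selection equals a naive string minimizer scan", {
  set.seed(79)
  for (r in 1:20) {
    s <- random_dna(sample(20:60, 1L))
    k <- sample(3:6, 1L); w <- sample(2:6, 1L)
    g <- eds_graph(s)
    gm <- graph_position_minima(g, k, mode = "lex")
    sel <- select_minimizers(gm, w, g$n)
    oracle <- h_minimizers_string(s, k, w, "lex")
    expect_equal(sel$pos, oracle$pos)
    expect_equal(sel$kmer, oracle$kmer)
  }
})

test_that("index construction, trimming, lookup and the empty graph", {
  g <- fig_graph()
  idx <- build_index(g, k = 3L, w = 4L, mode = "lex")
  expect_equal(idx$postings,
               list(AAG = 20L, AAT = 11L, ACA = 7L, AGA = c(4L, 17L),
                    ATG = 13L))
  expect_equal(lookup_index(idx, "AGA"), c(4L, 17L))
  expect_equal(lookup_index(idx, "CCC"), integer(0))
  trimmed <- build_index(g, k = 3L, w = 4L, trim_threshold = 1L, mode = "lex")
  expect_false("AGA" %in% names(trimmed$postings))
  expect_setequal(names(trimmed$postings), c("AAG", "AAT", "ACA", "ATG"))
  empty <- build_index(eds_graph("A"), k = 3L, w = 4L, mode = "lex")
  expect_equal(length(empty$postings), 0L)
})

test_that("index serialization round-trips bit-exactly", {
  g <- fig_graph()
  idx <- build_index(g, k = 3L, w = 4L, mode = "lex")
  f <- withr::local_tempfile(fileext = ".json")
  write_index(idx, f)
  idx2 <- read_index(f)
  expect_equal(idx2, idx)
})
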