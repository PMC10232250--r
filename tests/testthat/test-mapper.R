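test_that("read minimizers match the running example and a naive scan", {
  rm <- read_minimizers("TTAGAATCGA", 3L, 4L, "lex")
  expect_equal(paste0(rm$kmer, "@", rm$i),
               c("AGA@3", "AAT@5", "ATC@6", "CGA@8"))
  expect_equal(nrow(read_minimizers("AC", 3L, 4L, "lex")), 0L)
  set.seed(107)
  for (r in 1:20) {
    s <- random_dna(sample(15:40, 1L))
    k <- sample(3:5, 1L); w <- sample(2:5, 1L)
    got <- read_minimizers(s, k, w, "lex")
    oracle <- h_minimizers_string(s, k, w, "lex")
    expect_equal(got$i, oracle$pos)
    expect_equal(got$kmer, oracle$kmer)
  }
})

test_that("homopolymer reads yield ascending repeated minimizers", {
  rm <- read_minimizers(strrep("A", 12L), 3L, 4L, "lex")
  expect_true(all(rm$kmer == "AAA"))
  expect_true(all(diff(rm$i) > 0))
})

test_that("pair collection merges postings sorted by graph position", {
  g <- fig_graph()
  idx <- build_index(g, k = 3L, w = 4L, mode = "lex")
  rm <- read_minimizers("TTAGAATCGA", 3L, 4L, "lex")
  pr <- collect_pairs(rm, idx)
  expect_equal(pr$i, c(3L, 5L, 3L))
  expect_equal(pr$j, c(4L, 11L, 17L))
  # no minimizer in the index
  rm0 <- data.frame(kmer = "CCC", i = 1L, hash = 0)
  expect_equal(nrow(collect_pairs(rm0, idx)), 0L)
  # two minimizers sharing a posting position both yield pairs
  tiny <- structure(list(k = 3L, w = 1L, trim_threshold = 10L, mode = "lex",
                         postings = list(AAA = 5L, AAC = 5L),
                         n_gstring = 10L, graph_checksum = 0),
                    class = "minimizer_index")
  rm2 <- data.frame(kmer = c("AAA", "AAC"), i = c(2L, 4L), hash = c(0, 1))
  pr2 <- collect_pairs(rm2, tiny)
  expect_equal(pr2$j, c(5L, 5L))
  expect_equal(pr2$i, c(2L, 4L))  # equal j ordered by ascending i
})

test_that("chain scores follow the colinearity definition", {
  pr <- data.frame(i = c(3L, 5L, 3L), j = c(4L, 11L, 17L))
  sc <- chain_scores(pr, 20)
  expect_equal(sc$score, c(1L, 2L, 1L))
  expect_equal(chain_scores(data.frame(i = 1L, j = 1L), 10)$score, 1L)
  # a tight window prevents chaining distant pairs
  sc2 <- chain_scores(data.frame(i = c(1L, 5L), j = c(1L, 100L)), 50)
  expect_equal(sc2$score, c(1L, 1L))
})

test_that("chain scores equal the quadratic oracle with an open window", {
  set.seed(109)
  for (r in 1:10) {
    x <- 50L
    pr <- data.frame(i = sample.int(30L, x, replace = TRUE),
                     j = sort(sample.int(500L, x, replace = TRUE)))
    pr <- pr[order(pr$j, pr$i), , drop = FALSE]
    rownames(pr) <- NULL
    got <- chain_scores(pr, Inf)$score
    expect_equal(got, h_chain_scores_quadratic(pr$i, pr$j))
  }
})

test_that("scores are stable under permutations of equal-j pairs", {
  pr <- data.frame(i = c(2L, 7L, 4L, 9L, 1L), j = c(5L, 5L, 5L, 9L, 9L))
  pr <- pr[order(pr$j, pr$i), , drop = FALSE]
  sc1 <- chain_scores(pr, Inf)
  # feed the same multiset in a different (still j-sorted) order
  pr2 <- pr[c(3, 1, 2, 5, 4), , drop = FALSE]
  pr2 <- pr2[order(pr2$j, pr2$i), , drop = FALSE]
  sc2 <- chain_scores(pr2, Inf)
  key <- function(d) d$score[order(d$i, d$j)]
  expect_equal(key(sc1), key(sc2))
})

test_that("the running example maps through seed (5,11)", {
  g <- fig_graph()
  idx <- build_index(g, k = 3L, w = 4L, mode = "lex")
  res <- map_read("TTAGAATCGA", g, idx, d = 3L)
  expect_true(res$mapped)
  expect_equal(unname(res$seed), c(5L, 11L))
  expect_equal(res$strand, "+")
  # total distance equals the oracle: forward + backward parts at the pin
  enum <- h_enum_graph(g, max_visits = 2L, limit = 1024L)
  want <- h_oracle_forward("TTAGAATCGA", enum, 5L, 11L) +
    h_oracle_backward("TTAGAATCGA", enum, 5L, 11L)
  expect_equal(res$distance, want)
  expect_equal(sum(res$ops %in% c("=", "X", "I")), 10L)  # whole read, no clipping
  expect_match(res$cigar, "^[0-9MID]+$")
})

test_that("error-free reads from a variant-free reference map exactly", {
  set.seed(113)
  s <- random_dna(300)
  g <- eds_graph(s)
  idx <- build_index(g, k = 11L, w = 4L, mode = "lex")
  for (start in c(1L, 57L, 150L, 290L - 19L)) {
    read <- substr(s, start, start + 19L)
    res <- map_read(read, g, idx)
    expect_true(res$mapped)
    expect_equal(res$distance, 0)
    expect_equal(res$lo, start)
    expect_equal(res$projection$linear, start)
  }
})

test_that("reverse-complement reads map to the forward locus", {
  set.seed(127)
  s <- random_dna(200)
  g <- eds_graph(s)
  idx <- build_index(g, k = 9L, w = 4L, mode = "lex")
  read <- substr(s, 41, 80)
  res <- map_read(revcomp(read), g, idx)
  expect_true(res$mapped)
  expect_equal(res$strand, "-")
  expect_equal(res$lo, 41L)
  expect_equal(res$distance, 0)
})

test_that("reads absent from the graph are reported unmapped", {
  set.seed(131)
  g <- eds_graph(random_dna(120))
  idx <- build_index(g, k = 9L, w = 4L, mode = "lex")
  res <- map_read(strrep("ACGT", 10L), g, idx, d = 2L)
  expect_false(res$mapped)
  # too short for the k-mer size
  expect_false(map_read("ACGT", g, idx)$mapped)
})

test_that("reads spanning the copy-number loop map across the jump", {
  set.seed(137)
  left <- random_dna(60); unit <- random_dna(30); right <- random_dna(60)
  g <- eds_graph(paste(left, unit, right, sep = "#"),
                 edges = rbind(c(1, 1), c(2, 1), c(2, 2)))
  idx <- build_index(g, k = 9L, w = 4L, mode = "lex")
  # read covering two copies of the repeated unit
  read <- paste0(substr(left, 41, 60), unit, unit, substr(right, 1, 20))
  res <- map_read(read, g, idx)
  expect_true(res$mapped)
  expect_equal(res$distance, 0)
  expect_equal(res$lo, 41L)
  expect_equal(sum(res$ops %in% c("=", "X", "I")), nchar(read))
})
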