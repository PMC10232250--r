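# Read mapping: compute the read's minimizers, look their positions up in
# the index, rank seed pairs by colinear-chain length within a lambda-window,
# and align from the best seeds with the EDS-adapted banded DP.

#' Reverse complement
#' @param s String over `A,C,G,T,N`.
#' @return The reverse complement.
#' @export
revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         vapply(s, function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                     collapse = ""), character(1),
                USE.NAMES = FALSE))
}

#' (w,k)-minimizers of a read
#'
#' Standard single-string minimizers, with the same window semantics and
#' hash mode as the graph index: a window is `w` consecutive read positions,
#' and the minimum-hash k-mer per window is marked (leftmost on ties). k-mers
#' with more than two `N`s are skipped; others are expanded as in the index.
#'
#' @param read Read sequence.
#' @param k,w Minimizer parameters (must match the index).
#' @param mode Hash mode.
#' @return data.frame with columns `kmer`, `i` (1-based read position),
#'   `hash`; empty when the read is shorter than `k`.
#' @export
read_minimizers <- function(read, k, w, mode = c("mix", "lex")) {
  mode <- match.arg(mode)
  L <- nchar(read)
  if (L < k) {
    return(data.frame(kmer = character(0), i = integer(0), hash = numeric(0)))
  }
  starts <- seq_len(L - k + 1L)
  kms <- substring(read, starts, starts + k - 1L)
  hasN <- grepl("N", kms, fixed = TRUE)
  pos <- integer(0); kmer <- character(0); hash <- numeric(0)
  if (any(!hasN)) {
    h <- kmer_hash(kms[!hasN], mode)
    pos <- starts[!hasN]; kmer <- kms[!hasN]; hash <- h
  }
  for (p in starts[hasN]) {
    m <- min_kmer_with_N(substring(read, p, p + k - 1L), k, mode)
    if (!is.null(m)) {
      pos <- c(pos, p); kmer <- c(kmer, m$kmer); hash <- c(hash, m$hash)
    }
  }
  o <- order(pos)
  minima <- data.frame(pos = pos[o], kmer = kmer[o], hash = hash[o],
                       stringsAsFactors = FALSE)
  sel <- select_minimizers(minima, w, L)
  data.frame(kmer = sel$kmer, i = sel$pos, hash = sel$hash,
             stringsAsFactors = FALSE)
}

#' Collect seed pairs from index postings
#'
#' One pair `(i, j)` per occurrence of a read minimizer in the graph,
#' obtained by merging the (already sorted) postings lists; ascending in
#' `j`, ties broken by ascending `i`.
#'
#' @param rmins Output of [read_minimizers()].
#' @param index A `minimizer_index` (same `k`, `w`, hash mode).
#' @return data.frame with columns `i`, `j`.
#' @export
collect_pairs <- function(rmins, index) {
  iv <- integer(0); jv <- integer(0)
  for (r in seq_len(nrow(rmins))) {
    js <- lookup_index(index, rmins$kmer[r])
    if (length(js) > 0L) {
      iv <- c(iv, rep(rmins$i[r], length(js)))
      jv <- c(jv, js)
    }
  }
  o <- order(jv, iv)
  data.frame(i = iv[o], j = jv[o])
}

# Fenwick tree prefix-maximum, used for the longest-increasing-subsequence
# scoring inside one chaining batch.
.bit_new <- function(n) numeric(n)
.bit_update <- function(bit, pos, val) {
  n <- length(bit)
  while (pos <= n) {
    if (bit[pos] < val) bit[pos] <- val
    pos <- pos + bitwAnd(pos, -pos)
  }
  bit
}
.bit_query <- function(bit, pos) {
  best <- 0
  while (pos >= 1L) {
    if (bit[pos] > best) best <- bit[pos]
    pos <- pos - bitwAnd(pos, -pos)
  }
  best
}

#' Colinear-chain scores of seed pairs
#'
#' Two pairs are colinear when both coordinates strictly increase; the score
#' of a pair is the length of a maximum colinear chain ending at it. Chains
#' are restricted to a window: for each leading pair `l`, scores are computed
#' over the maximal batch of pairs whose gstring positions span less than
#' `lambda`. Within a batch the scores are a longest-increasing-subsequence
#' computation over read positions (prefix-maximum tree, O(x log x)).
#'
#' @param pairs data.frame (i, j) sorted by j (ties by i), as produced by
#'   [collect_pairs()].
#' @param lambda Window width on gstring positions (e.g. twice the read
#'   length); `Inf` disables the restriction.
#' @return `pairs` with an added integer column `score`.
#' @export
chain_scores <- function(pairs, lambda) {
  x <- nrow(pairs)
  pairs$score <- integer(x)
  if (x == 0L) return(pairs)
  j <- pairs$j; i <- pairs$i
  ends <- vapply(seq_len(x), function(l) {
    max(which(j - j[l] < lambda))
  }, integer(1))
  score <- integer(x)
  prev_end <- 0L
  for (l in seq_len(x)) {
    if (l > 1L && ends[l] <= prev_end) next   # batch contained in an earlier one
    b <- l:ends[l]
    prev_end <- ends[l]
    ib <- i[b]; jb <- j[b]
    ranks <- match(ib, sort(unique(ib)))
    bit <- .bit_new(max(ranks))
    sc <- integer(length(b))
    t <- 1L
    while (t <= length(b)) {
      grp <- which(jb == jb[t])
      for (g in grp) {
        q <- if (ranks[g] > 1L) .bit_query(bit, ranks[g] - 1L) else 0
        sc[g] <- q + 1L
      }
      for (g in grp) bit <- .bit_update(bit, ranks[g], sc[g])
      t <- max(grp) + 1L
    }
    score[b] <- pmax(score[b], sc)
  }
  pairs$score <- as.integer(score)
  pairs
}

#' Map one read to the graph
#'
#' Minimizers of both the read and its reverse complement are looked up in
#' the index; seed pairs are ranked by chain score and tried in descending
#' order (forward strand first on ties, then ascending gstring position).
#' For each seed a forward alignment bounded by `d` and a backward alignment
#' bounded by the remainder are computed; the first seed achieving a total
#' distance of at most `d` is reported, since the two half-alignments are
#' individually optimal given the pinned seed cell.
#'
#' @param read Read sequence over `A,C,G,T,N`.
#' @param graph An `eds_graph`.
#' @param index The graph's `minimizer_index`.
#' @param lambda Chaining window; default `2 * nchar(read)`.
#' @param d Error bound; default `ceiling(0.1 * nchar(read))`.
#' @param max_seeds Maximum number of seeds tried. Default 10.
#' @param prune Forwarded to the aligner.
#' @return A list: `mapped` (logical); when mapped also `distance`, `lo`,
#'   `hi` (gstring span), `strand` (`"+"`/`"-"`), `cigar`, `ops`, `seed`
#'   (`c(i, j)`), `projection` (see [project()]).
#' @export
map_read <- function(read, graph, index, lambda = NULL, d = NULL,
                     max_seeds = 10L, prune = TRUE) {
  read <- toupper(read)
  L <- nchar(read)
  if (is.null(lambda)) lambda <- 2L * L
  if (is.null(d)) d <- ceiling(0.1 * L)
  unmapped <- list(mapped = FALSE)
  if (L < index$k) return(unmapped)
  seeds <- NULL
  oriented <- c("+" = read, "-" = revcomp(read))
  for (strand in names(oriented)) {
    rm <- read_minimizers(oriented[[strand]], index$k, index$w, index$mode)
    if (nrow(rm) == 0L) next
    pairs <- collect_pairs(rm, index)
    if (nrow(pairs) == 0L) next
    pairs <- chain_scores(pairs, lambda)
    pairs$strand <- strand
    seeds <- rbind(seeds, pairs)
  }
  if (is.null(seeds) || nrow(seeds) == 0L) return(unmapped)
  o <- order(-seeds$score, seeds$strand != "+", seeds$j, seeds$i)
  seeds <- seeds[o, , drop = FALSE]
  seeds <- utils::head(seeds, max_seeds)
  for (r in seq_len(nrow(seeds))) {
    sq <- oriented[[seeds$strand[r]]]
    i_star <- seeds$i[r]; j_star <- seeds$j[r]
    fwd <- align_forward(sq, graph, i_star, j_star, d, prune = prune)
    if (!is.finite(fwd$distance)) next
    bwd <- align_backward(sq, graph, i_star, j_star, d - fwd$distance,
                          prune = prune)
    if (!is.finite(bwd$distance)) next
    ops <- c(bwd$ops, fwd$ops)
    return(list(mapped = TRUE,
                distance = fwd$distance + bwd$distance,
                lo = bwd$lo, hi = fwd$hi,
                strand = seeds$strand[r],
                cigar = ops_to_cigar(ops), ops = ops,
                seed = c(i = i_star, j = j_star),
                projection = project(graph, bwd$lo)))
  }
  unmapped
}

#' Collapse an edit script into a CIGAR string
#'
#' `=` and `X` both become `M`; insertions (`I`) consume read only,
#' deletions (`D`) reference only. The script always consumes the whole
#' read: no clipping is performed.
#' @param ops Character vector over `=,X,I,D`.
#' @return CIGAR string.
#' @export
ops_to_cigar <- function(ops) {
  if (length(ops) == 0L) return("*")
  cig <- ifelse(ops %in% c("=", "X"), "M", ops)
  r <- rle(cig)
  paste0(r$lengths, r$values, collapse = "")
}
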