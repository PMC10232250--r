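# Truth-tracked synthetic reads. A read is a substring of the pangenome
# starting at a base position drawn uniformly at random; at every ED symbol
# one alternative is chosen uniformly (an N likewise becomes a uniform
# base), and at every separator a jump edge is chosen uniformly. Sequencing
# errors are then layered on: per emitted base, deletion, substitution and
# insertion each strike independently with the given per-base rate.

# Walk `len` bases forward from base position `start`; returns the emitted
# characters (possibly fewer when the walk reaches a sink first).
.sample_walk <- function(graph, start, len) {
  ctx <- .graph_ctx(graph)
  out <- character(len)
  got <- 0L
  p <- start
  while (got < len) {
    c0 <- ctx$chars[p]
    got <- got + 1L
    out[got] <- if (c0 == "N") sample(c("A", "C", "G", "T"), 1L) else c0
    if (got == len) break
    q <- p + 1L
    # resolve the head to the next base, choosing uniformly where branching
    repeat {
      if (q > ctx$n) return(out[seq_len(got)])
      tp <- ctx$type[q]
      if (tp == "base") { p <- q; break }
      if (tp == "pipe" || tp == "close") { q <- ctx$close_pos[q] + 1L; next }
      if (tp == "open") {
        cp <- ctx$close_pos[q]
        alt_starts <- c(q + 1L, which(ctx$chars[q:cp] == "|") + q)
        pick <- alt_starts[sample.int(length(alt_starts), 1L)]
        if (ctx$type[pick] == "base") { p <- pick; break }
        q <- cp + 1L  # empty alternative: skip the symbol
        next
      }
      # separator
      s <- ctx$sep_at[q]
      targets <- .edges_from(ctx, s)
      if (length(targets) == 0L) return(out[seq_len(got)])
      t <- targets[sample.int(length(targets), 1L)]
      q <- .pos_after_sep(ctx, t)
    }
  }
  out[seq_len(got)]
}

#' Sample truth-tracked reads from the graph
#'
#' Start positions are uniform over base positions of the linearized string;
#' the walk picks alternatives and jump edges uniformly. Each emitted base is
#' then independently deleted, substituted (uniform among the three other
#' bases) or followed by an inserted uniform base, each with probability
#' `error_rate`. Fully reproducible from `rng_seed`.
#'
#' @param graph An `eds_graph`.
#' @param n Number of reads requested.
#' @param length Read length before errors.
#' @param error_rate Per-base, per-error-type probability (default 0.001).
#' @param rng_seed Integer seed, or `NULL` to use the current RNG state.
#' @param max_tries Resampling attempts per read when a walk ends early.
#' @return data.frame with columns id, sequence, truth_gpos, truth_chrom,
#'   truth_linear, n_errors. Fewer than `n` rows (with a warning) when the
#'   graph is too short for the requested length.
#' @export
sample_reads <- function(graph, n, length, error_rate = 0.001,
                         rng_seed = NULL, max_tries = 50L) {
  stopifnot(inherits(graph, "eds_graph"), n >= 1L, length >= 1L,
            error_rate >= 0, error_rate < 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  base_pos <- which(graph$meta$type == "base")
  if (length(base_pos) == 0L) stop("graph has no bases", call. = FALSE)
  ids <- character(0); seqs <- character(0)
  gpos <- integer(0); chroms <- character(0); linear <- integer(0)
  nerr <- integer(0)
  for (r in seq_len(n)) {
    clean <- NULL; start <- NA_integer_
    for (try in seq_len(max_tries)) {
      start <- base_pos[sample.int(length(base_pos), 1L)]
      walk <- .sample_walk(graph, start, length)
      if (base::length(walk) == length) { clean <- walk; break }
    }
    if (is.null(clean)) next
    # error channels
    bases <- c("A", "C", "G", "T")
    keep <- stats::runif(length) >= error_rate          # deletions
    subs <- stats::runif(length) < error_rate           # substitutions
    ins <- stats::runif(length) < error_rate            # insertions (after)
    errs <- sum(!keep) + sum(subs & keep) + sum(ins)
    out <- character(0)
    for (t in seq_len(length)) {
      if (keep[t]) {
        b <- clean[t]
        if (subs[t]) b <- sample(setdiff(bases, b), 1L)
        out <- c(out, b)
      }
      if (ins[t]) out <- c(out, sample(bases, 1L))
    }
    if (base::length(out) == 0L) next
    pr <- project(graph, start)
    ids <- c(ids, sprintf("read%06d", r))
    seqs <- c(seqs, paste(out, collapse = ""))
    gpos <- c(gpos, start)
    chroms <- c(chroms, pr$chrom)
    linear <- c(linear, pr$linear)
    nerr <- c(nerr, errs)
  }
  if (base::length(ids) < n) {
    warning(sprintf("only %d of %d reads sampled (graph too short for length %d?)",
                    base::length(ids), n, length))
  }
  data.frame(id = ids, sequence = seqs, truth_gpos = gpos,
             truth_chrom = chroms, truth_linear = linear, n_errors = nerr,
             stringsAsFactors = FALSE)
}

#' Evaluate mappings against sampling truth
#'
#' A mapping is accurate when its reported gstring start is within
#' `tolerance` of the position the read was sampled from. The mapping rate
#' is the fraction of reads with any alignment; the accuracy is the fraction
#' of all reads mapped within tolerance.
#'
#' @param truth [sample_reads()] output (id, truth_gpos).
#' @param mappings data.frame with columns id, mapped (logical), gpos.
#' @param tolerance Maximum |reported - truth| counted as accurate.
#'   Default 10.
#' @return A list: n, n_mapped, mapping_rate, n_accurate, accuracy.
#' @export
evaluate <- function(truth, mappings, tolerance = 10L) {
  stopifnot(is.data.frame(truth), is.data.frame(mappings))
  if (!setequal(truth$id, mappings$id))
    stop("read ids of truth and mappings differ", call. = FALSE)
  m <- mappings[match(truth$id, mappings$id), , drop = FALSE]
  mapped <- !is.na(m$mapped) & m$mapped
  ok <- mapped & !is.na(m$gpos) & abs(m$gpos - truth$truth_gpos) <= tolerance
  list(n = nrow(truth),
       n_mapped = sum(mapped),
       mapping_rate = mean(mapped),
       n_accurate = sum(ok),
       accuracy = mean(ok))
}
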