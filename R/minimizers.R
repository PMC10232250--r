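# (w,k)-minimizer index over the linearized graph. Unlike a plain string,
# several k-mers can occur at one position of an EDS; a single right-to-left
# scan maintains the set K_p of strings (length <= k) readable from each
# position, using two auxiliary sets: K_r, the set saved at the right
# boundary of the open ED symbol, and K_l, the accumulating union over its
# alternatives. Per position the minimum-hash k-mer is kept; a window of w
# consecutive positions then marks its smallest entry as a minimizer.

#' Hash k-mers
#'
#' Two modes. `"lex"` returns the lexicographic rank itself (base-4 value
#' with A=0, C=1, G=2, T=3; exact for `k <= 26`), so the smallest hash is the
#' lexicographically smallest k-mer -- the mode used in all worked examples.
#' `"mix"` (default) folds the bases through a 31-bit multiplicative
#' congruential mix, decorrelating minimizer choice from base composition.
#'
#' @param kmers Character vector of k-mers over `A,C,G,T` (no `N`; expand
#'   first, see [min_kmer_with_N()]).
#' @param mode `"lex"` or `"mix"`.
#' @return Numeric vector of non-negative hash values.
#' @export
kmer_hash <- function(kmers, mode = c("mix", "lex")) {
  mode <- match.arg(mode)
  if (length(kmers) == 0L) return(numeric(0))
  k <- unique(nchar(kmers))
  if (length(k) != 1L) stop("k-mers must share one length", call. = FALSE)
  if (any(grepl("[^ACGT]", kmers)))
    stop("k-mers must be over A,C,G,T (no N)", call. = FALSE)
  codes <- c(A = 0, C = 1, G = 2, T = 3)
  if (mode == "lex") {
    if (k > 26L) stop("lexicographic mode requires k <= 26", call. = FALSE)
    h <- numeric(length(kmers))
    for (i in seq_len(k)) {
      h <- h * 4 + codes[substr(kmers, i, i)]
    }
    return(unname(h))
  }
  h <- numeric(length(kmers))
  for (i in seq_len(k)) {
    h <- (h * 69069 + codes[substr(kmers, i, i)] + 1) %% 2147483648
  }
  unname(h)
}

#' Minimum-hash k-mer of a set, expanding N
#'
#' `N` is kept literally while the per-position sets are built; only when the
#' minimum is taken is every `N` replaced by each base and the hash computed
#' over the expansions. Strings containing more than `n_cap` `N`s are
#' considered uninformative and skipped.
#'
#' @param kmers Character vector over `A,C,G,T,N` (strings shorter than `k`
#'   are ignored).
#' @param k k-mer length.
#' @param mode Hash mode, see [kmer_hash()].
#' @param n_cap Maximum number of `N`s tolerated per k-mer. Default 2.
#' @return `NULL` if no eligible k-mer, else `list(kmer=, hash=)` where
#'   `kmer` is the winning concrete (N-free) k-mer.
#' @export
min_kmer_with_N <- function(kmers, k, mode = c("mix", "lex"), n_cap = 2L) {
  mode <- match.arg(mode)
  kmers <- kmers[nchar(kmers) == k]
  if (length(kmers) == 0L) return(NULL)
  ncounts <- nchar(kmers) - nchar(gsub("N", "", kmers, fixed = TRUE))
  kmers <- kmers[ncounts <= n_cap]
  if (length(kmers) == 0L) return(NULL)
  expanded <- unique(unlist(lapply(kmers, .expand_N), use.names = FALSE))
  h <- kmer_hash(expanded, mode)
  best <- which(h == min(h))
  if (length(best) > 1L) best <- best[order(expanded[best])][1L]
  list(kmer = expanded[best], hash = h[best])
}

# Right-to-left scan over one label (or plain EDS). `chars`/`type` are the
# slices for the label; `offset` converts local to global positions;
# `boundary` is K at one past the label end (k-mers starting behind the
# label, i.e. at successors). Returns the per-position minima and optionally
# the raw sets.
.kscan <- function(chars, type, k, boundary = character(0),
                   offset = 0L, mode = "mix", n_cap = 2L,
                   return_sets = FALSE) {
  n <- length(chars)
  cur <- boundary           # K_{p+1} while visiting p
  Kr <- character(0)
  Kl <- character(0)
  pos <- integer(0); kmer <- character(0); hash <- numeric(0)
  sets <- if (return_sets) vector("list", n) else NULL
  prepend <- function(c, s) {
    if (length(s) == 0L) c else unique(substr(paste0(c, s), 1L, k))
  }
  for (p in seq.int(n, 1L)) {
    tp <- type[p]
    if (tp == "base") {
      cur <- prepend(chars[p], cur)
      m <- min_kmer_with_N(cur, k, mode, n_cap)
      if (!is.null(m)) {
        pos <- c(pos, p + offset); kmer <- c(kmer, m$kmer); hash <- c(hash, m$hash)
      }
    } else if (tp == "close") {
      Kr <- cur; Kl <- character(0); cur <- Kr
    } else if (tp == "pipe") {
      Kl <- unique(c(Kl, cur)); cur <- Kr
    } else if (tp == "open") {
      Kl <- unique(c(Kl, cur)); cur <- Kl
    } else {
      stop("unexpected separator inside a label scan", call. = FALSE)
    }
    if (return_sets) sets[[p]] <- cur
  }
  res <- data.frame(pos = rev(pos), kmer = rev(kmer), hash = rev(hash),
                    stringsAsFactors = FALSE)
  if (return_sets) attr(res, "sets") <- sets
  res
}

#' Per-position minimum k-mers of a plain EDS
#'
#' For every base position the minimum-hash k-mer among all k-mers occurring
#' there, computed by the single right-to-left scan with the `K_p`/`K_r`/
#' `K_l` propagation rules (simple prepend-and-truncate; copy from the
#' symbol's right boundary at alternative ends; union of alternatives
#' released at the symbol's left boundary).
#'
#' @param eds An `eds` object.
#' @param k k-mer length.
#' @param boundary Character vector: K at one past the EDS end (used when the
#'   EDS is a node label; empty otherwise).
#' @param mode Hash mode.
#' @param return_sets Attach the raw K_p sets as attribute `"sets"` (tests).
#' @return data.frame with columns pos, kmer, hash, ascending in pos.
#' @export
position_minima <- function(eds, k, boundary = character(0),
                            mode = c("mix", "lex"), return_sets = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(eds, "eds"), k >= 1L)
  .kscan(eds$chars, eds$meta$type, k, boundary, 0L, mode,
         return_sets = return_sets)
}

# All strings (length <= k) readable starting at the head position `q`,
# following alternatives and jump edges; N kept literally. Used to seed a
# node scan with the k-mers starting at its successors.
.spell_from <- function(ctx, q, k, max_states = 20000L) {
  out <- character(0)
  # BFS over states (position of the base about to be consumed, string so far)
  level <- lapply(.starts_at(ctx, q), function(b) list(b = b, s = ""))
  nstates <- 0L
  while (length(level) > 0L) {
    nxt <- list()
    for (st in level) {
      nstates <- nstates + 1L
      if (nstates > max_states) stop("spell budget exceeded", call. = FALSE)
      s2 <- paste0(st$s, ctx$chars[st$b])
      if (nchar(s2) == k) { out <- c(out, s2); next }
      cont <- .starts_at(ctx, st$b + 1L)
      if (length(cont) == 0L) { out <- c(out, s2); next }  # path ends short
      for (b2 in cont) nxt[[length(nxt) + 1L]] <- list(b = b2, s = s2)
    }
    # dedupe states to tame combinatorial alternatives
    if (length(nxt) > 1L) {
      keys <- vapply(nxt, function(x) paste0(x$b, ":", x$s), character(1))
      nxt <- nxt[!duplicated(keys)]
    }
    level <- nxt
  }
  unique(out)
}

#' Per-position minimum k-mers of the whole graph
#'
#' Each node label is scanned right-to-left as in [position_minima()],
#' seeded with the union of the k-mer sets starting at its successor nodes,
#' so k-mers that continue across jump edges shape the sets near node ends
#' and are reported at their start positions. Separator positions carry no
#' k-mer.
#'
#' @param graph An `eds_graph`.
#' @param k k-mer length.
#' @param mode Hash mode.
#' @return data.frame with columns pos, kmer, hash, ascending in pos.
#' @export
graph_position_minima <- function(graph, k, mode = c("mix", "lex")) {
  mode <- match.arg(mode)
  stopifnot(inherits(graph, "eds_graph"), k >= 1L)
  ctx <- .graph_ctx(graph)
  out <- vector("list", nrow(graph$nodes))
  for (v in seq_len(nrow(graph$nodes))) {
    ls <- graph$nodes$label_start[v]; le <- graph$nodes$label_end[v]
    if (le < ls) next
    key <- graph$nodes$sep[v] + 1L
    targets <- graph$fwd[[as.character(key)]]
    boundary <- character(0)
    if (!is.null(targets) && length(targets) > 0L) {
      for (t in targets) {
        boundary <- c(boundary, .spell_from(ctx, .pos_after_sep(ctx, t), k))
      }
      boundary <- unique(boundary)
    }
    idx <- ls:le
    out[[v]] <- .kscan(graph$chars[idx], graph$meta$type[idx], k,
                       boundary, offset = ls - 1L, mode = mode)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(pos = integer(0), kmer = character(0), hash = numeric(0))
  }
  res <- res[order(res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Select (w,k)-minimizers by sliding window
#'
#' A window is an interval of `w` consecutive gstring positions (syntax
#' positions contribute no k-mer); within each window the entry with the
#' smallest hash is marked, ties going to the leftmost position. Every
#' marked entry is a minimizer.
#'
#' @param minima data.frame (pos, kmer, hash) sorted by pos, as produced by
#'   [position_minima()] or [graph_position_minima()].
#' @param w Window size (positions).
#' @param n_positions Total number of positions of the scanned string.
#' @return Subset of `minima` rows that are marked, ascending in pos.
#' @export
select_minimizers <- function(minima, w, n_positions) {
  stopifnot(is.data.frame(minima), w >= 1L)
  if (nrow(minima) == 0L) return(minima)
  H <- rep(Inf, n_positions)
  H[minima$pos] <- minima$hash
  if (n_positions <= w) {
    starts <- 1L
    w <- n_positions
  } else {
    starts <- seq_len(n_positions - w + 1L)
  }
  # windowed minimum via shifted pmin, then leftmost argmin per window
  winmin <- rep(Inf, length(starts))
  for (o in 0:(w - 1L)) winmin <- pmin(winmin, H[starts + o])
  argoff <- rep(NA_integer_, length(starts))
  for (o in 0:(w - 1L)) {
    hit <- is.na(argoff) & H[starts + o] == winmin & is.finite(winmin)
    argoff[hit] <- o
  }
  marked <- unique(starts[!is.na(argoff)] + argoff[!is.na(argoff)])
  minima[minima$pos %in% marked, , drop = FALSE]
}

#' Build the minimizer index of a graph
#'
#' Computes per-position minima, marks (w,k)-minimizers, collects postings
#' (k-mer -> ascending gstring positions) and trims k-mers occurring at more
#' positions than `trim_threshold`, which removes repetitive seeds that slow
#' mapping without helping placement.
#'
#' @param graph An `eds_graph`.
#' @param k k-mer length (default 20).
#' @param w Window size (default 5).
#' @param trim_threshold Maximum postings length retained (default 512).
#' @param mode Hash mode; `"lex"` reproduces the worked examples.
#' @return An object of class `minimizer_index`.
#' @examples
#' g <- eds_graph("TT#NG(A|)CA(AT|TA)GA#T",
#'                edges = rbind(c(1, 1), c(2, 1), c(2, 2)))
#' idx <- build_index(g, k = 3, w = 4, mode = "lex")
#' idx$postings[["ATG"]]   # 13
#' @export
build_index <- function(graph, k = 20L, w = 5L, trim_threshold = 512L,
                        mode = c("mix", "lex")) {
  mode <- match.arg(mode)
  stopifnot(k >= 1L, w >= 1L, trim_threshold >= 1L)
  minima <- graph_position_minima(graph, k, mode)
  sel <- select_minimizers(minima, w, graph$n)
  postings <- list()
  if (nrow(sel) > 0L) {
    postings <- lapply(split(sel$pos, sel$kmer), function(p) sort(unique(p)))
    keep <- vapply(postings, length, integer(1)) <= trim_threshold
    postings <- postings[keep]
    postings <- postings[order(names(postings))]
  }
  structure(list(k = as.integer(k), w = as.integer(w),
                 trim_threshold = as.integer(trim_threshold), mode = mode,
                 postings = postings, n_gstring = graph$n,
                 graph_checksum = graph_checksum(graph)),
            class = "minimizer_index")
}

#' @export
print.minimizer_index <- function(x, ...) {
  cat(sprintf("<minimizer_index> (w,k) = (%d,%d), %d k-mers, %d postings, mode %s\n",
              x$w, x$k, length(x$postings),
              sum(vapply(x$postings, length, integer(1))), x$mode))
  invisible(x)
}

#' Postings of one k-mer
#' @param index A `minimizer_index`.
#' @param kmer k-mer string.
#' @return Ascending integer positions (empty if absent or trimmed).
#' @export
lookup_index <- function(index, kmer) {
  v <- index$postings[[kmer]]
  if (is.null(v)) integer(0) else v
}

#' Checksum binding an index to its graph
#'
#' A small FNV-style fold over the gstring and edge list; [cmd_map()] refuses
#' to combine an index with a different graph.
#' @param graph An `eds_graph`.
#' @return Integer-valued numeric.
#' @export
graph_checksum <- function(graph) {
  v <- utf8ToInt(graph$gstring)
  h <- 2166136261
  for (chunk in split(v, ceiling(seq_along(v) / 4096))) {
    h <- (h * 16777 + sum(chunk * (seq_along(chunk) %% 97 + 1))) %% 2147483647
  }
  if (nrow(graph$edges) > 0L) {
    h <- (h + sum(graph$edges[, 1L] * 31 + graph$edges[, 2L] * 17)) %% 2147483647
  }
  h
}
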