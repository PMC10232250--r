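# Independent brute-force oracles. These deliberately avoid the package's
# scan/DP machinery: enumeration works from the parsed symbol table and the
# node/edge lists alone, alignment is the classic quadratic DP on plain
# strings.

# Enumerate all (string, coords) pairs matching a plain EDS, coordinates
# being the text position of every character. Cartesian product over the
# symbol table; N expands to every base (keeping its single position).
h_enum_eds <- function(eds, offset = 0L, limit = 4096L) {
  per_symbol <- lapply(eds$symbols, function(sym) {
    outs <- list()
    # alternative start positions inside the textual form
    if (sym$end == sym$start) {
      starts <- sym$start
    } else {
      body <- eds$chars[sym$start:sym$end]
      delim <- which(body == "|") + sym$start - 1L
      starts <- c(sym$start + 1L, delim + 1L)
    }
    for (ai in seq_along(sym$alternatives)) {
      alt <- sym$alternatives[ai]
      if (nchar(alt) == 0L) {
        outs[[length(outs) + 1L]] <- list(str = "", pos = integer(0))
        next
      }
      chs <- strsplit(alt, "", fixed = TRUE)[[1]]
      pos <- starts[ai] + seq_along(chs) - 1L
      # expand N
      variants <- list(character(0))
      for (c0 in chs) {
        reps <- if (c0 == "N") c("A", "C", "G", "T") else c0
        variants <- unlist(lapply(variants, function(v)
          lapply(reps, function(r) c(v, r))), recursive = FALSE)
      }
      for (v in variants) {
        outs[[length(outs) + 1L]] <-
          list(str = paste(v, collapse = ""), pos = pos)
      }
    }
    outs
  })
  acc <- list(list(str = "", pos = integer(0)))
  for (sym_outs in per_symbol) {
    nxt <- list()
    for (a in acc) for (o in sym_outs) {
      nxt[[length(nxt) + 1L]] <-
        list(str = paste0(a$str, o$str), pos = c(a$pos, o$pos))
      if (length(nxt) > limit) stop("oracle enumeration too large")
    }
    acc <- nxt
  }
  lapply(acc, function(a) list(str = a$str, pos = a$pos + offset))
}

# All source-to-sink node walks with a per-node visit cap.
h_walks <- function(graph, max_visits = 2L) {
  nn <- nrow(graph$nodes)
  tgt <- unique(graph$edges[, 2L])
  sources <- which(!(graph$nodes$sep %in% tgt))
  out_edges <- lapply(seq_len(nn), function(v) {
    key <- graph$nodes$sep[v] + 1L
    tg <- graph$edges[graph$edges[, 1L] == key, 2L]
    match(tg, graph$nodes$sep)
  })
  sinks <- which(vapply(out_edges, length, integer(1)) == 0L)
  walks <- list()
  rec <- function(path, visits) {
    v <- path[length(path)]
    if (v %in% sinks) walks[[length(walks) + 1L]] <<- path
    for (v2 in out_edges[[v]]) {
      if (visits[v2] < max_visits) {
        visits2 <- visits; visits2[v2] <- visits2[v2] + 1L
        rec(c(path, v2), visits2)
      }
    }
  }
  for (s in sources) {
    visits <- integer(nn); visits[s] <- 1L
    rec(s, visits)
  }
  walks
}

# Enumerate (string, coords) pairs matching the graph (full walks).
h_enum_graph <- function(graph, max_visits = 2L, limit = 4096L) {
  per_node <- lapply(seq_len(nrow(graph$nodes)), function(v) {
    ls <- graph$nodes$label_start[v]; le <- graph$nodes$label_end[v]
    if (le < ls) return(list(list(str = "", pos = integer(0))))
    lab <- substr(graph$gstring, ls, le)
    h_enum_eds(parse_eds(lab), offset = ls - 1L, limit = limit)
  })
  res <- list()
  for (walk in h_walks(graph, max_visits)) {
    acc <- list(list(str = "", pos = integer(0)))
    for (v in walk) {
      nxt <- list()
      for (a in acc) for (o in per_node[[v]]) {
        nxt[[length(nxt) + 1L]] <-
          list(str = paste0(a$str, o$str), pos = c(a$pos, o$pos))
        if (length(nxt) > limit) stop("oracle enumeration too large")
      }
      acc <- nxt
    }
    res <- c(res, acc)
  }
  # dedupe identical (string, coords)
  keys <- vapply(res, function(a) paste(a$str, paste(a$pos, collapse = ","),
                                        sep = "!"), character(1))
  res[!duplicated(keys)]
}

# Classic edit-distance DP with a free end in the second string:
# min over j of D(|a|, j).
h_edit_free_end <- function(a, b) {
  m <- nchar(a); n <- nchar(b)
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  prev <- 0:n
  best <- if (m == 0L) 0 else Inf
  for (i in seq_len(m)) {
    cur <- numeric(n + 1L)
    cur[1L] <- i
    for (j in seq_len(n)) {
      cur[j + 1L] <- min(prev[j] + (av[i] != bv[j]),
                         prev[j + 1L] + 1, cur[j] + 1)
    }
    prev <- cur
  }
  if (m > 0L) best <- min(prev)
  best
}

# Brute-force pinned forward distance: min over all enumerated matching
# strings and all pin positions t with coords[t] == j_star of
# mismatch(r[i*], M[t]) + free-end edit of the remaining suffixes.
h_oracle_forward <- function(read, enum, i_star, j_star) {
  rv <- strsplit(read, "", fixed = TRUE)[[1]]
  best <- Inf
  for (e in enum) {
    ts <- which(e$pos == j_star)
    for (t in ts) {
      mv <- strsplit(e$str, "", fixed = TRUE)[[1]]
      cost <- as.numeric(rv[i_star] != mv[t]) +
        h_edit_free_end(paste(rv[-seq_len(i_star)], collapse = ""),
                        paste(mv[-seq_len(t)], collapse = ""))
      best <- min(best, cost)
    }
  }
  best
}

# Same for the backward part (prefix before the pin, reversed).
h_oracle_backward <- function(read, enum, i_star, j_star) {
  rv <- strsplit(read, "", fixed = TRUE)[[1]]
  best <- Inf
  for (e in enum) {
    ts <- which(e$pos == j_star)
    for (t in ts) {
      mv <- strsplit(e$str, "", fixed = TRUE)[[1]]
      a <- paste(rev(rv[seq_len(i_star - 1L)]), collapse = "")
      b <- paste(rev(mv[seq_len(t - 1L)]), collapse = "")
      best <- min(best, h_edit_free_end(a, b))
    }
  }
  best
}

# O(x^2) colinear chaining scores (lambda = Inf semantics).
h_chain_scores_quadratic <- function(i, j) {
  x <- length(i)
  sc <- integer(x)
  for (t in seq_len(x)) {
    best <- 0L
    for (s in seq_len(x)) {
      if (i[s] < i[t] && j[s] < j[t]) best <- max(best, sc[s])
    }
    sc[t] <- best + 1L
  }
  sc
}

# Naive (w,k)-minimizers of a plain string.
h_minimizers_string <- function(s, k, w, mode = "lex") {
  L <- nchar(s)
  if (L < k) return(data.frame(kmer = character(0), pos = integer(0)))
  starts <- seq_len(L - k + 1L)
  kms <- substring(s, starts, starts + k - 1L)
  h <- kmer_hash(kms, mode)
  H <- rep(Inf, L); H[starts] <- h
  marked <- integer(0)
  win <- if (L <= w) list(1:L) else lapply(seq_len(L - w + 1L),
                                           function(s0) s0:(s0 + w - 1L))
  for (idx in win) {
    vals <- H[idx]
    if (all(is.infinite(vals))) next
    marked <- c(marked, idx[which.min(vals)])
  }
  marked <- sort(unique(marked))
  data.frame(kmer = substring(s, marked, marked + k - 1L), pos = marked,
             stringsAsFactors = FALSE)
}

h_rank_naive <- function(bits, p) if (p == 0L) 0L else sum(bits[seq_len(p)])
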