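#' @keywords internal
"_PACKAGE"

# Character classes of the EDS / linearized-graph alphabet.
.EDS_BASES <- c("A", "C", "G", "T", "N")

.char_type <- function(chars) {
  type <- rep("base", length(chars))
  type[chars == "("] <- "open"
  type[chars == "|"] <- "pipe"
  type[chars == ")"] <- "close"
  type[chars == "#"] <- "sep"
  type
}

# Structural metadata shared by plain EDS texts and linearized graph strings.
# Validates syntax (balanced, unnested parentheses; '|' only inside them;
# legal characters) and precomputes, for every position inside a parenthesized
# symbol, the positions of its delimiters.
.seq_meta <- function(chars, allow_sep = FALSE) {
  n <- length(chars)
  allowed <- c(.EDS_BASES, "(", "|", ")", if (allow_sep) "#")
  bad <- which(!(chars %in% allowed))
  if (length(bad) > 0L) {
    stop(sprintf("illegal character '%s' at position %d", chars[bad[1L]], bad[1L]),
         call. = FALSE)
  }
  type <- .char_type(chars)

  opens <- cumsum(chars == "(")
  closes <- cumsum(chars == ")")
  depth <- opens - closes        # depth *after* processing each position
  over <- which(depth < 0L)
  if (length(over) > 0L) {
    stop(sprintf("unbalanced ')' at position %d", over[1L]), call. = FALSE)
  }
  # depth before a '(' is the depth at the previous position
  prev_depth <- c(0L, depth)[seq_len(n)]
  nest <- which(chars == "(" & prev_depth > 0L)
  if (length(nest) > 0L) {
    stop(sprintf("nested '(' at position %d", nest[1L]), call. = FALSE)
  }
  if (n > 0L && depth[n] != 0L) {
    stop(sprintf("unbalanced '(' at position %d", max(which(chars == "("))),
         call. = FALSE)
  }
  stray <- which(chars == "|" & depth == 0L)
  if (length(stray) > 0L) {
    stop(sprintf("'|' outside parentheses at position %d", stray[1L]), call. = FALSE)
  }
  if (allow_sep) {
    insep <- which(chars == "#" & depth > 0L)
    if (length(insep) > 0L) {
      stop(sprintf("'#' inside parentheses at position %d", insep[1L]), call. = FALSE)
    }
  }

  # delimiter positions for every position belonging to a symbol
  open_pos <- rep(NA_integer_, n)
  close_pos <- rep(NA_integer_, n)
  if (any(chars == "(")) {
    op <- which(chars == "(")
    cp <- which(chars == ")")
    # op and cp pair up in order because there is no nesting
    for (s in seq_along(op)) {
      idx <- op[s]:cp[s]
      open_pos[idx] <- op[s]
      close_pos[idx] <- cp[s]
    }
  }
  list(n = n, chars = chars, type = type,
       open_pos = open_pos, close_pos = close_pos)
}

#' Parse an elastic-degenerate string
#'
#' An elastic-degenerate string (EDS) is written over the alphabet
#' `{A,C,G,T,N,(,|,)}`: a parenthesized group `(u1|...|um)` is one ED symbol
#' with alternatives `u1..um` (empty alternatives are allowed, e.g. `(A|)` is
#' an optional `A`), a bare base is a singleton symbol, and `N` abbreviates
#' `(A|C|T|G)` but is stored literally. The length of an EDS is the length of
#' its textual form, so every character -- bases and syntax alike -- has a
#' 1-based coordinate.
#'
#' @param text A single string over `A,C,G,T,N,(,|,)`.
#' @return An object of class `eds` with elements `text`, `length`, and
#'   `symbols` (a list with `alternatives`, `start`, `end` per ED symbol).
#' @examples
#' s <- parse_eds("NG(A|)CA(AT|TA)GA")
#' s$length                       # 17, counted on the textual form
#' eds_alternatives(s, 3)         # c("A", "")
#' @export
parse_eds <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  meta <- .seq_meta(chars, allow_sep = FALSE)
  symbols <- .extract_symbols(chars, meta)
  structure(list(text = text, chars = chars, meta = meta,
                 symbols = symbols, length = meta$n),
            class = "eds")
}

# One symbol per plain base, one per parenthesized group.
.extract_symbols <- function(chars, meta) {
  n <- meta$n
  symbols <- list()
  p <- 1L
  while (p <= n) {
    if (meta$type[p] == "base") {
      symbols[[length(symbols) + 1L]] <-
        list(alternatives = chars[p], start = p, end = p)
      p <- p + 1L
    } else if (meta$type[p] == "open") {
      cp <- meta$close_pos[p]
      inner <- if (cp > p + 1L) paste(chars[(p + 1L):(cp - 1L)], collapse = "") else ""
      npipe <- sum(chars[p:cp] == "|")
      alts <- strsplit(inner, "|", fixed = TRUE)[[1]]
      if (length(alts) == 0L) alts <- ""
      while (length(alts) < npipe + 1L) alts <- c(alts, "")
      symbols[[length(symbols) + 1L]] <-
        list(alternatives = alts, start = p, end = cp)
      p <- cp + 1L
    } else {
      stop(sprintf("unexpected '%s' at position %d", chars[p], p), call. = FALSE)
    }
  }
  symbols
}

#' @export
print.eds <- function(x, ...) {
  cat(sprintf("<eds> %d symbols, length %d\n  %s\n",
              length(x$symbols), x$length, x$text))
  invisible(x)
}

#' @export
as.character.eds <- function(x, ...) x$text

#' Alternatives of one ED symbol
#' @param eds An `eds` object.
#' @param i Symbol index (1-based).
#' @return Character vector of alternatives, in textual order.
#' @export
eds_alternatives <- function(eds, i) {
  stopifnot(inherits(eds, "eds"), i >= 1L, i <= length(eds$symbols))
  eds$symbols[[i]]$alternatives
}

#' Re-serialize a parsed EDS from its symbol list
#'
#' Singleton symbols are written bare; all others parenthesized with `|`
#' between alternatives. `format_eds(parse_eds(x)) == x` on valid inputs.
#' @param eds An `eds` object.
#' @return The textual EDS.
#' @export
format_eds <- function(eds) {
  stopifnot(inherits(eds, "eds"))
  parts <- vapply(eds$symbols, function(sym) {
    a <- sym$alternatives
    if (length(a) == 1L && nchar(a) > 0L && sym$end == sym$start) a
    else paste0("(", paste(a, collapse = "|"), ")")
  }, character(1))
  paste(parts, collapse = "")
}

# ---- walking contexts ------------------------------------------------------
# A context bundles the character/type arrays plus (for graphs) jump edges,
# so that matching, sampling and coordinate walks share one movement rule.

.eds_ctx <- function(eds) {
  list(n = eds$meta$n, chars = eds$chars, type = eds$meta$type,
       open_pos = eds$meta$open_pos, close_pos = eds$meta$close_pos,
       sep_at = NULL, fwd = NULL, sep_pos = integer(0))
}

# Base positions at which reading can continue when the head is at `q`
# (before consuming anything). Handles empty alternatives and, in graph
# contexts, '#' jumps. `visited` guards degenerate cycles through empty
# node labels.
.starts_at <- function(ctx, q, visited = integer(0)) {
  if (q > ctx$n || q < 1L) return(integer(0))
  tp <- ctx$type[q]
  if (tp == "base") return(q)
  if (tp == "pipe" || tp == "close") {
    return(.starts_at(ctx, ctx$close_pos[q] + 1L, visited))
  }
  if (tp == "open") {
    cp <- ctx$close_pos[q]
    alt_starts <- q + 1L
    pipes <- which(ctx$chars[q:cp] == "|") + q - 1L
    alt_starts <- c(alt_starts, pipes + 1L)
    out <- integer(0)
    for (s in alt_starts) {
      if (ctx$type[s] == "base") out <- c(out, s)
      else out <- c(out, .starts_at(ctx, cp + 1L, visited))  # empty alternative
    }
    return(sort(unique(out)))
  }
  # separator
  if (is.null(ctx$fwd)) stop("'#' outside a graph context", call. = FALSE)
  if (q %in% visited) return(integer(0))
  s <- ctx$sep_at[q]
  targets <- .edges_from(ctx, s)
  out <- integer(0)
  for (t in targets) {
    out <- c(out, .starts_at(ctx, .pos_after_sep(ctx, t), c(visited, q)))
  }
  sort(unique(out))
}

.edges_from <- function(ctx, key) {
  v <- ctx$fwd[[as.character(key)]]
  if (is.null(v)) integer(0) else v
}

.pos_after_sep <- function(ctx, s) {
  if (s == 0L) 1L else ctx$sep_pos[s] + 1L
}

# TRUE when, with the head at q, the end of a walk can be reached without
# consuming another base: end of string on a sink, a sink's separator, or a
# chain of empty alternatives leading there.
.can_end <- function(ctx, q, visited = integer(0)) {
  if (q > ctx$n && is.null(ctx$fwd)) return(TRUE)
  if (q <= ctx$n && ctx$type[q] == "base") return(FALSE)
  if (q <= ctx$n && ctx$type[q] %in% c("pipe", "close")) {
    return(.can_end(ctx, ctx$close_pos[q] + 1L, visited))
  }
  if (q <= ctx$n && ctx$type[q] == "open") {
    cp <- ctx$close_pos[q]
    alt_starts <- c(q + 1L, which(ctx$chars[q:cp] == "|") + q)
    for (s in alt_starts) {
      if (ctx$type[s] != "base" && .can_end(ctx, cp + 1L, visited)) return(TRUE)
    }
    return(FALSE)
  }
  # separator (or past the end): the walk may stop when the finished node is
  # a sink, or continue over a jump edge through nodes that consume no
  # further bases (empty alternatives) and end at a sink there
  s <- if (q > ctx$n) length(ctx$sep_pos) + 1L else ctx$sep_at[q]
  targets <- .edges_from(ctx, s)
  if (length(targets) == 0L) return(TRUE)
  if (q %in% visited) return(FALSE)
  for (t in targets) {
    if (.can_end(ctx, .pos_after_sep(ctx, t), c(visited, q))) return(TRUE)
  }
  FALSE
}

# ---- matching semantics ----------------------------------------------------

.expand_N <- function(s) {
  hits <- gregexpr("N", s, fixed = TRUE)[[1]]
  if (hits[1L] == -1L) return(s)
  out <- s
  for (p in hits) {
    out <- unlist(lapply(out, function(x) {
      vapply(c("A", "C", "G", "T"), function(b) {
        substr(x, p, p) <- b
        x
      }, character(1))
    }), use.names = FALSE)
  }
  unique(out)
}

#' Enumerate all strings matching an EDS
#'
#' A string matches an EDS when it can be spelled by choosing one alternative
#' per ED symbol. `N` is expanded to each of A, C, G, T. Intended as a
#' brute-force reference for small instances; the number of combinations is
#' bounded by `limit`.
#'
#' @param eds An `eds` object.
#' @param limit Maximum number of combinations the enumeration may touch.
#' @return Character vector (a set) of all matching strings.
#' @examples
#' sort(enumerate_matches(parse_eds("(A|C)(G|T)")))  # AG AT CG CT
#' @export
enumerate_matches <- function(eds, limit = 10000L) {
  stopifnot(inherits(eds, "eds"))
  alt_sets <- lapply(eds$symbols, function(sym) {
    unique(unlist(lapply(sym$alternatives, .expand_N), use.names = FALSE))
  })
  total <- prod(vapply(alt_sets, length, integer(1)))
  if (total > limit) {
    stop(sprintf("instance too large for enumeration: %.0f > limit %d",
                 total, limit), call. = FALSE)
  }
  out <- ""
  for (set in alt_sets) {
    out <- as.vector(outer(out, set, paste0))
  }
  unique(out)
}

#' Does a pattern occur at a position?
#'
#' A pattern `P` occurs at position `p` when `p` addresses a base (never a
#' syntax character) and `P` matches a prefix of what can be read from `p`
#' onwards: the remainder of the current alternative, then any choice of
#' alternatives in the following symbols (following jump edges in a graph).
#' `N` in the reference matches any pattern base.
#'
#' @param pattern A string over `A,C,G,T`.
#' @param x An `eds` or `eds_graph` object.
#' @param p 1-based position in the textual form.
#' @return `TRUE` or `FALSE`.
#' @examples
#' s <- parse_eds("NG(A|)CA(AT|TA)GA")
#' occurs_at("GACA", s, 2)   # TRUE
#' occurs_at("ATGA", s, 10)  # TRUE
#' @export
occurs_at <- function(pattern, x, p) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nchar(pattern) >= 1L)
  if (grepl("[^ACGT]", pattern)) {
    stop("pattern must be over A,C,G,T", call. = FALSE)
  }
  ctx <- .as_ctx(x)
  if (p < 1L || p > ctx$n) stop(sprintf("position %d out of range", p), call. = FALSE)
  if (ctx$type[p] != "base") return(FALSE)
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  .occ_rec(ctx, p, 1L, pat, new.env(parent = emptyenv()))
}

.occ_rec <- function(ctx, p, t, pat, memo) {
  key <- paste0(p, ":", t)
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  cp <- ctx$chars[p]
  ok <- (cp == "N") || (cp == pat[t])
  res <- FALSE
  if (ok) {
    if (t == length(pat)) {
      res <- TRUE
    } else {
      for (q in .starts_at(ctx, p + 1L)) {
        if (.occ_rec(ctx, q, t + 1L, pat, memo)) { res <- TRUE; break }
      }
    }
  }
  memo[[key]] <- res
  res
}

.as_ctx <- function(x) {
  if (inherits(x, "eds")) return(.eds_ctx(x))
  if (inherits(x, "eds_graph")) return(.graph_ctx(x))
  if (is.character(x) && length(x) == 1L) return(.eds_ctx(parse_eds(x)))
  stop("expected an 'eds' or 'eds_graph' object", call. = FALSE)
}

#' All positions where a pattern occurs
#'
#' Exhaustive application of [occurs_at()] over every base position.
#'
#' @inheritParams occurs_at
#' @return Ascending integer vector of positions (possibly empty).
#' @examples
#' find_occurrences("GCAT", parse_eds("NG(A|)CA(AT|TA)GA"))  # 2
#' @export
find_occurrences <- function(pattern, x) {
  ctx <- .as_ctx(x)
  base_pos <- which(ctx$type == "base")
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  if (grepl("[^ACGT]", pattern)) stop("pattern must be over A,C,G,T", call. = FALSE)
  memo <- new.env(parent = emptyenv())
  hits <- vapply(base_pos, function(p) .occ_rec(ctx, p, 1L, pat, memo), logical(1))
  base_pos[hits]
}
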