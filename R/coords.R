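# Coordinate system on the linearized graph string: every character of G^
# has a 1-based coordinate, and an indicator bit-vector I (1 = the character
# originates from the linear reference) projects graph coordinates onto
# linear-reference coordinates via rank queries.

#' Reference-indicator bit-vector with rank support
#'
#' Prefix popcounts are precomputed once, so [rank1()] answers in constant
#' time. The number of ones equals the linear-reference length: every
#' reference base appears in the linearized string exactly once, either as a
#' plain character or as part of the reference alternative of an ED symbol.
#'
#' @param bits Integer/logical 0-1 vector over the linearized string.
#' @return An object of class `ref_indicator`.
#' @export
ref_indicator <- function(bits) {
  bits <- as.integer(bits)
  stopifnot(all(bits %in% c(0L, 1L)))
  structure(list(bits = bits, csum = cumsum(bits), n = length(bits)),
            class = "ref_indicator")
}

#' @export
print.ref_indicator <- function(x, ...) {
  cat(sprintf("<ref_indicator> length %d, %d ones\n", x$n, sum(x$bits)))
  invisible(x)
}

#' Number of ones up to position p
#'
#' @param indicator A [ref_indicator()].
#' @param p Position, `0 <= p <= length`; `p = 0` returns 0.
#' @return Integer count (vectorized over `p`).
#' @export
rank1 <- function(indicator, p) {
  stopifnot(inherits(indicator, "ref_indicator"))
  if (any(p < 0L | p > indicator$n)) stop("p out of range", call. = FALSE)
  out <- integer(length(p))
  nz <- p > 0L
  out[nz] <- indicator$csum[p[nz]]
  out
}

#' Project a graph coordinate onto the linear reference
#'
#' A reference-origin base at position `p` maps to reference offset
#' `rank(I, p)` within its chromosome. A non-reference base (part of an
#' alternate allele or an inserted node) has no reference coordinate of its
#' own; it is reported at the offset of the nearest preceding reference base
#' with `on_reference = FALSE`, which gives SAM emission a total map.
#'
#' @param graph An `eds_graph`.
#' @param p Position of a base (never a syntax character) in the gstring.
#' @return A list: `gpos`, `chrom`, `linear` (1-based reference offset),
#'   `on_reference`.
#' @export
project <- function(graph, p) {
  stopifnot(inherits(graph, "eds_graph"), length(p) == 1L)
  if (p < 1L || p > graph$n) stop("p out of range", call. = FALSE)
  if (graph$meta$type[p] != "base")
    stop(sprintf("position %d holds syntax symbol '%s'", p, graph$chars[p]),
         call. = FALSE)
  ci <- which(graph$chroms$gstart <= p & graph$chroms$gend >= p)[1]
  r <- rank1(graph$indicator, p) - graph$chroms$ones_before[ci]
  list(gpos = p, chrom = graph$chroms$name[ci],
       linear = as.integer(r),
       on_reference = graph$indicator$bits[p] == 1L)
}

#' Coordinate sequence of a string matching the graph
#'
#' A string matches the graph when some walk from a source to a sink spells
#' it, choosing one alternative per ED symbol along the concatenated node
#' labels. This returns the gstring coordinate of each character along such a
#' walk; when several walks exist the lexicographically smallest coordinate
#' sequence is reported. Coordinates are strictly increasing whenever the
#' walk uses no cycle.
#'
#' @param S A string over `A,C,G,T`.
#' @param graph An `eds_graph`.
#' @param max_steps Safety bound on explored states.
#' @return Integer vector of length `nchar(S)`.
#' @examples
#' g <- eds_graph("TT#NG(A|)CA(AT|TA)GA#T",
#'                edges = rbind(c(1, 1), c(2, 1), c(2, 2)))
#' coords_of_match("TTAGACATAGAT", g)
#' @export
coords_of_match <- function(S, graph, max_steps = 1e6) {
  stopifnot(inherits(graph, "eds_graph"), is.character(S), length(S) == 1L)
  if (grepl("[^ACGT]", S)) stop("S must be over A,C,G,T", call. = FALSE)
  ctx <- .graph_ctx(graph)
  pat <- strsplit(S, "", fixed = TRUE)[[1]]
  steps <- new.env(parent = emptyenv()); steps$left <- max_steps
  rec <- function(head, t) {
    steps$left <- steps$left - 1L
    if (steps$left < 0L) stop("search budget exceeded", call. = FALSE)
    if (t > length(pat)) {
      return(if (.can_end(ctx, head)) integer(0) else NULL)
    }
    for (b in .starts_at(ctx, head)) {
      cb <- ctx$chars[b]
      if (cb == "N" || cb == pat[t]) {
        sub <- rec(b + 1L, t + 1L)
        if (!is.null(sub)) return(c(b, sub))
      }
    }
    NULL
  }
  for (v in .source_nodes(graph)) {
    res <- rec(graph$nodes$label_start[v], 1L)
    if (!is.null(res)) return(res)
  }
  stop("S does not match the graph", call. = FALSE)
}
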