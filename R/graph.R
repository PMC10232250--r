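# Pangenome graph construction: a FASTA reference plus VCF variants become a
# directed graph whose nodes are labeled with ED strings. Small variants are
# encoded in place as ED symbols; copy-number variants and large indels split
# the EDS into nodes connected by jump edges. The node labels, concatenated in
# linear-reference order and separated by '#', form the linearized string G^.

#' Classify VCF records into variant classes
#'
#' Small variants (SNPs, indels and alternatives whose allele-length
#' difference stays below `sv_threshold`) are encoded in place as ED symbols;
#' DUP/CNV records and indels at or above the threshold become graph
#' structure. Inversions and mobile-element insertions are counted and
#' skipped, as are malformed records; classification never aborts.
#'
#' @param records A data.frame with columns CHROM, POS, REF, ALT and
#'   optionally INFO (as read from a VCF, e.g. via [read_vcf()]).
#' @param sv_threshold Allele-length difference (bp) at which an indel is
#'   treated as structural rather than in-place. Default 20.
#' @return A data.frame with one row per record: chrom, pos, ref, alt
#'   (comma-joined), class (one of snp, small, cnv, large-deletion,
#'   large-insertion, skipped), end (for symbolic SVs) and reason for skips.
#' @export
classify_variants <- function(records, sv_threshold = 20L) {
  stopifnot(is.data.frame(records))
  cn <- toupper(names(records))
  names(records) <- cn
  need <- c("CHROM", "POS", "REF", "ALT")
  if (!all(need %in% cn)) stop("records must have CHROM, POS, REF, ALT", call. = FALSE)
  info <- if ("INFO" %in% cn) as.character(records$INFO) else rep("", nrow(records))
  n <- nrow(records)
  out <- data.frame(chrom = as.character(records$CHROM),
                    pos = as.integer(as.character(records$POS)),
                    ref = toupper(as.character(records$REF)),
                    alt = toupper(as.character(records$ALT)),
                    class = rep("small", n), end = rep(NA_integer_, n),
                    reason = rep("", n), stringsAsFactors = FALSE)
  svtype <- sub(".*SVTYPE=([A-Za-z:]+).*", "\\1", info)
  svtype[!grepl("SVTYPE=", info)] <- ""
  endf <- vapply(info, function(s) {
    m <- regmatches(s, regexpr("(^|;)END=[0-9]+", s))
    if (length(m) == 0L) NA_integer_ else as.integer(sub(".*END=", "", m))
  }, integer(1), USE.NAMES = FALSE)
  for (r in seq_len(n)) {
    ref <- out$ref[r]; alt <- out$alt[r]; st <- toupper(svtype[r])
    symbolic <- grepl("[<>\\[\\]]", alt)
    if (is.na(out$pos[r]) || ref == "" || alt == "" || alt == ".") {
      out$class[r] <- "skipped"; out$reason[r] <- "malformed"; next
    }
    if (st == "INV" || grepl("<INV", alt, fixed = TRUE)) {
      out$class[r] <- "skipped"; out$reason[r] <- "inversion"; next
    }
    if (grepl("<INS:ME", alt, fixed = TRUE)) {
      out$class[r] <- "skipped"; out$reason[r] <- "mobile-element"; next
    }
    if (st %in% c("DUP", "CNV") || grepl("^<(DUP|CN[0-9])", alt)) {
      if (is.na(endf[r])) {
        out$class[r] <- "skipped"; out$reason[r] <- "cnv-without-END"
      } else {
        out$class[r] <- "cnv"; out$end[r] <- endf[r]
      }
      next
    }
    if (st == "DEL" || alt == "<DEL>") {
      if (is.na(endf[r])) {
        out$class[r] <- "skipped"; out$reason[r] <- "del-without-END"
      } else if (endf[r] - out$pos[r] >= sv_threshold) {
        out$class[r] <- "large-deletion"; out$end[r] <- endf[r]
      } else {
        out$class[r] <- "skipped"; out$reason[r] <- "symbolic-small-del"
      }
      next
    }
    if (symbolic || st == "INS" && grepl("<", alt, fixed = TRUE)) {
      out$class[r] <- "skipped"; out$reason[r] <- "symbolic-unsupported"; next
    }
    alts <- strsplit(alt, ",", fixed = TRUE)[[1]]
    if (grepl("[^ACGTN]", ref) || any(grepl("[^ACGTN]", alts))) {
      out$class[r] <- "skipped"; out$reason[r] <- "malformed"; next
    }
    diffs <- abs(nchar(alts) - nchar(ref))
    if (max(diffs) >= sv_threshold) {
      big <- alts[which.max(diffs)]
      if (nchar(big) < nchar(ref)) {
        out$class[r] <- "large-deletion"
        out$end[r] <- out$pos[r] + nchar(ref) - 1L
      } else {
        out$class[r] <- "large-insertion"
      }
      out$alt[r] <- big
    } else if (nchar(ref) == 1L && all(nchar(alts) == 1L)) {
      out$class[r] <- "snp"
    } else {
      out$class[r] <- "small"
    }
  }
  out
}

# Build the EDS text for one chromosome from in-place (small) variants.
# Returns the text, per-character reference-origin flags, and for every
# reference base the text position holding its character. Overlapping
# variants are dropped left-to-right (keep-first); so are records whose REF
# does not match the reference.
.build_eds_chrom <- function(ref, variants) {
  rchars <- strsplit(ref, "", fixed = TRUE)[[1]]
  L <- length(rchars)
  pieces <- character(0)
  flags <- list()
  ref2text <- integer(L)
  cursor <- 1L       # next unwritten reference position
  written <- 0L      # characters emitted so far
  dropped_overlap <- 0L; dropped_mismatch <- 0L
  emit <- function(txt, flg) {
    pieces[[length(pieces) + 1L]] <<- txt
    flags[[length(flags) + 1L]] <<- flg
    written <<- written + nchar(txt)
  }
  if (!is.null(variants) && nrow(variants) > 0L) {
    variants <- variants[order(variants$pos), , drop = FALSE]
    for (r in seq_len(nrow(variants))) {
      pos <- variants$pos[r]
      refa <- variants$ref[r]
      alts <- strsplit(variants$alt[r], ",", fixed = TRUE)[[1]]
      span_end <- pos + nchar(refa) - 1L
      if (pos < cursor) { dropped_overlap <- dropped_overlap + 1L; next }
      if (span_end > L ||
          substr(ref, pos, span_end) != refa) {
        dropped_mismatch <- dropped_mismatch + 1L
        next
      }
      if (pos > cursor) {
        seg <- (cursor):(pos - 1L)
        emit(paste(rchars[seg], collapse = ""), rep(1L, length(seg)))
        ref2text[seg] <- written - rev(seq_along(seg)) + 1L
      }
      # strip the shared leading prefix (VCF left padding)
      while (nchar(refa) > 0L && all(nchar(alts) > 0L) &&
             all(substr(alts, 1L, 1L) == substr(refa, 1L, 1L))) {
        emit(substr(refa, 1L, 1L), 1L)
        ref2text[pos] <- written
        pos <- pos + 1L
        refa <- substr(refa, 2L, nchar(refa))
        alts <- substr(alts, 2L, nchar(alts))
      }
      alts <- setdiff(unique(alts), refa)
      if (length(alts) == 0L) {        # pure padding record
        if (nchar(refa) > 0L) {
          seg <- pos:span_end
          emit(refa, rep(1L, nchar(refa)))
          ref2text[seg] <- written - rev(seq_along(seg)) + 1L
        }
        cursor <- span_end + 1L
        next
      }
      body <- paste(c(refa, alts), collapse = "|")
      flg <- c(0L, rep(1L, nchar(refa)),
               rep(0L, nchar(body) - nchar(refa)), 0L)
      emit(paste0("(", body, ")"), flg)
      if (nchar(refa) > 0L) {
        seg <- pos:span_end
        # ref alternative sits right after '('
        ref2text[seg] <- written - nchar(body) - 1L + seq_len(nchar(refa))
      }
      cursor <- span_end + 1L
    }
  }
  if (cursor <= L) {
    seg <- cursor:L
    emit(paste(rchars[seg], collapse = ""), rep(1L, length(seg)))
    ref2text[seg] <- written - rev(seq_along(seg)) + 1L
  }
  list(text = paste(pieces, collapse = ""),
       flags = unlist(flags, use.names = FALSE),
       ref2text = ref2text,
       dropped_overlap = dropped_overlap,
       dropped_mismatch = dropped_mismatch)
}

#' Build an EDS from a reference sequence and small variants
#'
#' Encodes SNPs and small indels in place: the reference allele becomes the
#' first alternative of an ED symbol, further alternatives follow in VCF
#' order. The shared leading base of REF/ALT (VCF left padding) is emitted as
#' plain reference text, so a deletion `GA>G` serializes as `G(A|)`.
#' Overlapping variants are dropped left-to-right (keep-first); records whose
#' REF disagrees with the reference are skipped with a warning.
#'
#' @param ref Reference sequence (single string over A,C,G,T,N).
#' @param variants `NULL` or a data.frame with columns pos, ref, alt
#'   (comma-separated alternates), all on this one sequence, sorted by pos.
#' @return A list: `eds` (parsed [parse_eds()] object), `flags`
#'   (reference-origin indicator per text character), `ref2text` (text
#'   position of every reference base).
#' @export
build_eds <- function(ref, variants = NULL) {
  stopifnot(is.character(ref), length(ref) == 1L)
  res <- .build_eds_chrom(toupper(ref), variants)
  if (res$dropped_overlap > 0L)
    warning(sprintf("%d overlapping variant(s) dropped", res$dropped_overlap))
  if (res$dropped_mismatch > 0L)
    warning(sprintf("%d variant(s) with REF mismatch skipped", res$dropped_mismatch))
  list(eds = parse_eds(res$text), flags = res$flags, ref2text = res$ref2text)
}

# ---- the linearized graph --------------------------------------------------

.graph_meta <- function(chars) .seq_meta(chars, allow_sep = TRUE)

#' Construct a linearized EDS graph directly
#'
#' Low-level constructor used by tests, worked examples and deserialization.
#' `gstring` is the concatenation of node labels separated by `#`; separators
#' are numbered 1..S left to right and `sep(v)` is the number of the
#' separator immediately before node `v` (0 for the first node). A graph edge
#' `(v, v')` is stored as the pair `sep(v)+1 -> sep(v')`; consecutive nodes
#' of a chain are connected explicitly the same way, so traversal is uniform.
#'
#' @param gstring Linearized text over `A,C,G,T,N,(,|,),#`.
#' @param edges `NULL` for a plain left-to-right chain, or a two-column
#'   matrix/data.frame of `(from_key, to_sep)` pairs.
#' @param indicator Optional 0/1 vector over `gstring` marking
#'   reference-origin characters. By default bases outside parentheses and
#'   bases of each symbol's first alternative are flagged as reference.
#' @param chrom Chromosome name used for coordinate projection.
#' @return An object of class `eds_graph`.
#' @examples
#' g <- eds_graph("TT#NG(A|)CA(AT|TA)GA#T",
#'                edges = rbind(c(1, 1), c(2, 1), c(2, 2)))
#' successors_after_separator(g, 2)   # positions 4 and 22
#' @export
eds_graph <- function(gstring, edges = NULL, indicator = NULL, chrom = "ref") {
  stopifnot(is.character(gstring), length(gstring) == 1L)
  chars <- strsplit(gstring, "", fixed = TRUE)[[1]]
  meta <- .graph_meta(chars)
  sep_pos <- which(chars == "#")
  S <- length(sep_pos)
  if (is.null(edges)) {
    edges <- if (S > 0L) cbind(seq_len(S), seq_len(S)) else
      matrix(integer(0), ncol = 2L)
  }
  edges <- matrix(as.integer(as.matrix(edges)), ncol = 2L)
  if (nrow(edges) > 0L) {
    if (any(edges[, 1L] < 1L | edges[, 1L] > S + 1L) ||
        any(edges[, 2L] < 0L | edges[, 2L] > S)) {
      stop("edge keys out of range for this gstring", call. = FALSE)
    }
  }
  if (is.null(indicator)) indicator <- .default_indicator(chars, meta)
  stopifnot(length(indicator) == length(chars))
  nodes <- .derive_nodes(chars, sep_pos, chrom)
  chroms <- data.frame(name = chrom,
                       gstart = 1L, gend = length(chars),
                       ref_len = sum(indicator),
                       ones_before = 0L, stringsAsFactors = FALSE)
  .new_graph(gstring, chars, meta, sep_pos, edges, indicator, nodes, chroms)
}

.default_indicator <- function(chars, meta) {
  bits <- integer(length(chars))
  base <- meta$type == "base"
  outside <- base & is.na(meta$open_pos)
  bits[outside] <- 1L
  inside <- which(base & !is.na(meta$open_pos))
  for (p in inside) {
    op <- meta$open_pos[p]
    # first alternative = between '(' and the first '|' (or ')')
    seg <- chars[(op + 1L):(p - 1L)]
    if (p == op + 1L || !any(seg == "|")) bits[p] <- 1L
  }
  bits
}

.derive_nodes <- function(chars, sep_pos, chrom) {
  n <- length(chars)
  bounds <- c(0L, sep_pos, n + 1L)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L] - 1L
  data.frame(chrom = rep(chrom, length.out = length(starts)),
             label_start = starts, label_end = ends,
             sep = seq_along(starts) - 1L, stringsAsFactors = FALSE)
}

.new_graph <- function(gstring, chars, meta, sep_pos, edges, indicator,
                       nodes, chroms) {
  S <- length(sep_pos)
  fwd <- vector("list", 0L)
  bwd <- vector("list", 0L)
  if (nrow(edges) > 0L) {
    edges <- unique(edges)
    fwd <- lapply(split(edges[, 2L], edges[, 1L]), function(v) sort(unique(v)))
    bwd <- lapply(split(edges[, 1L], edges[, 2L]), function(v) sort(unique(v)))
  }
  sep_at <- rep(NA_integer_, length(chars))
  if (S > 0L) sep_at[sep_pos] <- seq_len(S)
  g <- structure(list(
    gstring = gstring, chars = chars, meta = meta, n = length(chars),
    sep_pos = sep_pos, sep_at = sep_at,
    edges = edges, fwd = fwd, bwd = bwd,
    nodes = nodes, chroms = chroms,
    indicator = ref_indicator(indicator)
  ), class = "eds_graph")
  g
}

#' @export
print.eds_graph <- function(x, ...) {
  cat(sprintf("<eds_graph> %d nodes, %d separators, %d edges, |G^| = %d\n",
              nrow(x$nodes), length(x$sep_pos), nrow(x$edges), x$n))
  cat(sprintf("  reference: %d bp over %d sequence(s)\n",
              sum(x$chroms$ref_len), nrow(x$chroms)))
  if (x$n <= 120L) cat("  ", x$gstring, "\n", sep = "")
  invisible(x)
}

.graph_ctx <- function(graph) {
  list(n = graph$n, chars = graph$chars, type = graph$meta$type,
       open_pos = graph$meta$open_pos, close_pos = graph$meta$close_pos,
       sep_at = graph$sep_at, fwd = graph$fwd, sep_pos = graph$sep_pos)
}

#' Positions reachable after a separator
#'
#' When forward reading encounters separator number `s`, the next characters
#' are those immediately behind separator `sep(v')` for every stored edge
#' `s -> sep(v')`.
#'
#' @param graph An `eds_graph`.
#' @param s Separator number, `1 <= s <= S`.
#' @return Sorted integer vector of gstring positions (possibly empty).
#' @export
successors_after_separator <- function(graph, s) {
  stopifnot(inherits(graph, "eds_graph"))
  if (s < 1L || s > length(graph$sep_pos) + 1L)
    stop(sprintf("unknown separator %d", s), call. = FALSE)
  targets <- graph$fwd[[as.character(s)]]
  if (is.null(targets)) return(integer(0))
  sort(vapply(targets, function(t) if (t == 0L) 1L else graph$sep_pos[t] + 1L,
              integer(1)))
}

#' Positions reachable before a separator, reading backwards
#'
#' The mirror of [successors_after_separator()]: when backward reading leaves
#' the node behind separator number `s`, continuation points are the last
#' label characters of all predecessor nodes.
#'
#' @inheritParams successors_after_separator
#' @param s Separator number of the node being left (its `sep(v')`), `0..S`.
#' @export
predecessors_before_separator <- function(graph, s) {
  stopifnot(inherits(graph, "eds_graph"))
  keys <- graph$bwd[[as.character(s)]]
  if (is.null(keys)) return(integer(0))
  S <- length(graph$sep_pos)
  sort(vapply(keys, function(a) {
    if (a <= S) graph$sep_pos[a] - 1L else graph$n
  }, integer(1)))
}

# Nodes with no incoming / outgoing edges (walk starts and ends).
.source_nodes <- function(graph) {
  tgt <- unique(graph$edges[, 2L])
  which(!(graph$nodes$sep %in% tgt))
}
.sink_nodes <- function(graph) {
  src <- unique(graph$edges[, 1L])
  which(!((graph$nodes$sep + 1L) %in% src))
}

#' Build the pangenome graph from reference sequences and classified variants
#'
#' Small variants are first folded into per-chromosome ED strings
#' ([build_eds()]); then each copy-number variant over reference span
#' `[i, j]` splits the EDS into three nodes (prefix, repeated unit, suffix)
#' with a self-loop on the middle node, a large deletion adds a bypass edge
#' over the deleted span, and a large insertion becomes an optional node
#' between split points with a bypass edge. Chromosomes are independent node
#' chains inside one linearized string; no edges cross them. Small variants
#' whose ED symbol would straddle a split boundary are dropped first so all
#' boundaries are syntactically legal, and a structural variant overlapping
#' an earlier one is skipped with a warning.
#'
#' @param ref_seqs Named character vector of reference sequences.
#' @param variants Classified variants ([classify_variants()] output), or
#'   `NULL` for a variant-free graph.
#' @return A list: `graph` (an `eds_graph`) and `stats` (drop counters).
#' @export
build_graph <- function(ref_seqs, variants = NULL) {
  stopifnot(is.character(ref_seqs), length(ref_seqs) >= 1L)
  if (is.null(names(ref_seqs)) || any(names(ref_seqs) == ""))
    stop("ref_seqs must be named by chromosome", call. = FALSE)
  stats <- c(sv_overlap = 0L, small_at_boundary = 0L)
  all_labels <- character(0)
  all_flags <- list()
  node_rows <- list()
  chrom_rows <- list()
  edge_rows <- list()
  sep_count <- 0L
  gpos <- 0L
  ones_before <- 0L
  for (ci in seq_along(ref_seqs)) {
    chrom <- names(ref_seqs)[ci]
    ref <- toupper(ref_seqs[[ci]])
    L <- nchar(ref)
    v <- if (is.null(variants)) NULL else
      variants[variants$chrom == chrom, , drop = FALSE]
    small <- sv <- NULL
    if (!is.null(v) && nrow(v) > 0L) {
      small <- v[v$class %in% c("snp", "small"), , drop = FALSE]
      sv <- v[v$class %in% c("cnv", "large-deletion", "large-insertion"), ,
              drop = FALSE]
      sv <- sv[order(sv$pos), , drop = FALSE]
    }
    # structural variants -> split plan on reference coordinates
    cuts <- integer(0)     # "cut after reference position x"
    plan <- list()
    if (!is.null(sv) && nrow(sv) > 0L) {
      occupied_end <- 0L
      for (r in seq_len(nrow(sv))) {
        cls <- sv$class[r]
        if (cls == "cnv" || cls == "large-deletion") {
          i <- sv$pos[r] + 1L   # POS is the padding base before the event
          j <- sv$end[r]
          if (cls == "large-deletion" && is.na(j))
            j <- sv$pos[r] + nchar(sv$ref[r]) - 1L
          if (i > j || j > L) { stats["sv_overlap"] <- stats["sv_overlap"] + 1L; next }
          if (i <= occupied_end + 1L && occupied_end > 0L && i <= occupied_end) {
            stats["sv_overlap"] <- stats["sv_overlap"] + 1L; next
          }
          if (i - 1L < occupied_end) { stats["sv_overlap"] <- stats["sv_overlap"] + 1L; next }
          plan[[length(plan) + 1L]] <- list(class = cls, i = i, j = j)
          cuts <- c(cuts, i - 1L, j)
          occupied_end <- j
        } else {  # large-insertion: literal alleles, padding base at POS
          p <- sv$pos[r]
          if (p < occupied_end) { stats["sv_overlap"] <- stats["sv_overlap"] + 1L; next }
          ins <- substr(sv$alt[r], nchar(sv$ref[r]) + 1L, nchar(sv$alt[r]))
          if (nchar(ins) == 0L) { stats["sv_overlap"] <- stats["sv_overlap"] + 1L; next }
          plan[[length(plan) + 1L]] <- list(class = cls, p = p, seq = ins)
          cuts <- c(cuts, p)
          occupied_end <- max(occupied_end, p)
        }
      }
    }
    cuts <- sort(unique(cuts[cuts >= 1L & cuts < L]))
    # drop small variants whose REF span straddles a cut
    if (!is.null(small) && nrow(small) > 0L && length(cuts) > 0L) {
      spans_cut <- vapply(seq_len(nrow(small)), function(r) {
        a <- small$pos[r]; b <- a + nchar(small$ref[r]) - 1L
        any(cuts >= a & cuts < b)
      }, logical(1))
      stats["small_at_boundary"] <- stats["small_at_boundary"] + sum(spans_cut)
      small <- small[!spans_cut, , drop = FALSE]
    }
    built <- .build_eds_chrom(ref, small)
    if (built$dropped_overlap > 0L)
      warning(sprintf("%s: %d overlapping small variant(s) dropped",
                      chrom, built$dropped_overlap))
    if (built$dropped_mismatch > 0L)
      warning(sprintf("%s: %d variant(s) with REF mismatch skipped",
                      chrom, built$dropped_mismatch))
    text <- built$text
    tchars <- strsplit(text, "", fixed = TRUE)[[1]]
    tmeta <- .seq_meta(tchars, allow_sep = FALSE)
    # text cut point for "after reference position x"
    cut_text <- vapply(cuts, function(x) {
      tp <- built$ref2text[x]
      if (!is.na(tmeta$close_pos[tp])) tmeta$close_pos[tp] else tp
    }, integer(1))
    seg_bounds <- c(0L, sort(unique(cut_text)), nchar(text))
    seg_start <- seg_bounds[-length(seg_bounds)] + 1L
    seg_end <- seg_bounds[-1L]
    # map: reference cut x -> segment index ending at that cut
    cut_of_seg <- sort(unique(cuts))
    # chromosome-local node list: labels of base segments, possibly with
    # insertion nodes spliced in
    segs <- lapply(seq_along(seg_start), function(s) {
      list(label = substr(text, seg_start[s], seg_end[s]),
           flags = built$flags[seg_start[s]:seg_end[s]],
           after_ref = if (s < length(seg_start)) cut_of_seg[s] else NA_integer_,
           kind = "ref")
    })
    # splice insertion nodes after their segment
    for (ev in plan) {
      if (ev$class != "large-insertion") next
      at <- which(vapply(segs, function(s)
        identical(s$after_ref, ev$p) && s$kind == "ref", logical(1)))[1]
      node <- list(label = ev$seq, flags = rep(0L, nchar(ev$seq)),
                   after_ref = ev$p, kind = "ins")
      segs <- append(segs, list(node), after = at)
    }
    # local node indices + edges
    nseg <- length(segs)
    first_sep_local <- sep_count           # sep of first node in this chrom
    loc_sep <- first_sep_local + seq_len(nseg) - 1L
    # consecutive chain edges
    if (nseg > 1L) {
      for (s in seq_len(nseg - 1L)) {
        edge_rows[[length(edge_rows) + 1L]] <- c(loc_sep[s] + 1L, loc_sep[s + 1L])
      }
    }
    # structural edges
    ref_seg_idx <- which(vapply(segs, function(s) s$kind == "ref", logical(1)))
    seg_end_ref <- vapply(segs[ref_seg_idx], function(s)
      if (is.na(s$after_ref)) L else s$after_ref, integer(1))
    find_seg_ending <- function(x) ref_seg_idx[match(x, seg_end_ref)]
    for (ev in plan) {
      if (ev$class == "cnv") {
        m <- find_seg_ending(ev$j)
        edge_rows[[length(edge_rows) + 1L]] <- c(loc_sep[m] + 1L, loc_sep[m])
      } else if (ev$class == "large-deletion") {
        m <- find_seg_ending(ev$j)          # segment holding the deleted span
        if (m > 1L && m < nseg) {           # bypass over the deleted node
          edge_rows[[length(edge_rows) + 1L]] <-
            c(loc_sep[m - 1L] + 1L, loc_sep[m + 1L])
        }
      } else {  # large-insertion: bypass edge skipping the inserted node
        ins_idx <- which(vapply(segs, function(s)
          s$kind == "ins" && identical(s$after_ref, ev$p), logical(1)))[1]
        if (ins_idx < nseg) {
          edge_rows[[length(edge_rows) + 1L]] <-
            c(loc_sep[ins_idx - 1L] + 1L, loc_sep[ins_idx + 1L])
        }
      }
    }
    # append labels / node bookkeeping
    chrom_gstart <- gpos + 1L
    for (s in seq_len(nseg)) {
      if (gpos > 0L) {   # every node except the very first is preceded by '#'
        all_labels <- c(all_labels, "#")
        all_flags[[length(all_flags) + 1L]] <- 0L
        gpos <- gpos + 1L
      }
      lab <- segs[[s]]$label
      all_labels <- c(all_labels, lab)
      all_flags[[length(all_flags) + 1L]] <- segs[[s]]$flags
      node_rows[[length(node_rows) + 1L]] <-
        data.frame(chrom = chrom, label_start = gpos + 1L,
                   label_end = gpos + nchar(lab), sep = loc_sep[s],
                   stringsAsFactors = FALSE)
      gpos <- gpos + nchar(lab)
    }
    sep_count <- sep_count + nseg
    chrom_rows[[length(chrom_rows) + 1L]] <-
      data.frame(name = chrom, gstart = chrom_gstart, gend = gpos,
                 ref_len = L, ones_before = ones_before,
                 stringsAsFactors = FALSE)
    ones_before <- ones_before + L
  }
  gstring <- paste(all_labels, collapse = "")
  chars <- strsplit(gstring, "", fixed = TRUE)[[1]]
  meta <- .graph_meta(chars)
  sep_pos <- which(chars == "#")
  # flags aligned with gstring: labels and '#'s were appended in order
  flat <- integer(0)
  for (f in all_flags) flat <- c(flat, f)
  stopifnot(length(flat) == length(chars))
  edges <- if (length(edge_rows) > 0L) do.call(rbind, edge_rows) else
    matrix(integer(0), ncol = 2L)
  nodes <- do.call(rbind, node_rows)
  chroms <- do.call(rbind, chrom_rows)
  g <- .new_graph(gstring, chars, meta, sep_pos, edges, flat, nodes, chroms)
  if (stats["sv_overlap"] > 0L)
    warning(sprintf("%d structural variant(s) overlapping earlier ones skipped",
                    stats["sv_overlap"]))
  list(graph = g, stats = stats)
}
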