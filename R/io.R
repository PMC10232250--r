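# Standard-format I/O (FASTA, FASTQ, VCF, SAM) and the documented text
# serialization of the graph and the minimizer index.

#' Read a (multi-record) FASTA file
#' @param path File path.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Read VCF records
#'
#' Fixed columns only; genotypes are not used.
#' @param path VCF file (plain or gzipped).
#' @return data.frame with CHROM, POS, ID, REF, ALT, QUAL, FILTER, INFO.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  as.data.frame(v@fix, stringsAsFactors = FALSE)
}

#' Read a FASTQ file
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write reads as FASTQ (constant quality)
#' @param ids,seqs Read names and sequences.
#' @param path Output path.
#' @export
write_fastq <- function(ids, seqs, path) {
  qual <- vapply(nchar(seqs), function(n) paste(rep("I", n), collapse = ""),
                 character(1))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), path)
  invisible(path)
}

.format_version <- "edsmap/1"

#' Serialize a graph to text files
#'
#' Writes `<prefix>.gstring.txt` (the linearized string, one line),
#' `<prefix>.edges.tsv` (tab-separated `src_key dst_sep` pairs),
#' `<prefix>.indicator.txt` (the 0/1 reference indicator as one line) and
#' `<prefix>.meta.json` (format version, chromosome table, checksum).
#'
#' @param graph An `eds_graph`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_graph <- function(graph, prefix) {
  stopifnot(inherits(graph, "eds_graph"))
  writeLines(graph$gstring, paste0(prefix, ".gstring.txt"))
  e <- graph$edges
  writeLines(c("src_key\tdst_sep",
               if (nrow(e) > 0L) paste(e[, 1L], e[, 2L], sep = "\t")),
             paste0(prefix, ".edges.tsv"))
  writeLines(paste(graph$indicator$bits, collapse = ""),
             paste0(prefix, ".indicator.txt"))
  meta <- list(format = .format_version,
               chroms = graph$chroms,
               checksum = graph_checksum(graph))
  jsonlite::write_json(meta, paste0(prefix, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Load a serialized graph
#' @param prefix Path prefix used by [write_graph()].
#' @return An `eds_graph`.
#' @export
read_graph <- function(prefix) {
  gstring <- readLines(paste0(prefix, ".gstring.txt"), warn = FALSE)[1]
  etab <- utils::read.table(paste0(prefix, ".edges.tsv"), header = TRUE,
                            sep = "\t", colClasses = "integer")
  bits <- as.integer(strsplit(readLines(paste0(prefix, ".indicator.txt"),
                                        warn = FALSE)[1], "")[[1]])
  meta <- jsonlite::read_json(paste0(prefix, ".meta.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$format, .format_version))
    stop("unsupported graph file format", call. = FALSE)
  chars <- strsplit(gstring, "", fixed = TRUE)[[1]]
  smeta <- .graph_meta(chars)
  sep_pos <- which(chars == "#")
  chroms <- as.data.frame(meta$chroms, stringsAsFactors = FALSE)
  chroms$gstart <- as.integer(chroms$gstart)
  chroms$gend <- as.integer(chroms$gend)
  chroms$ref_len <- as.integer(chroms$ref_len)
  chroms$ones_before <- as.integer(chroms$ones_before)
  # nodes re-derived from the gstring; chromosome of a node from its span
  nodes <- .derive_nodes(chars, sep_pos, chroms$name[1])
  for (ci in seq_len(nrow(chroms))) {
    hit <- nodes$label_start >= chroms$gstart[ci] &
      nodes$label_start <= chroms$gend[ci]
    nodes$chrom[hit] <- chroms$name[ci]
  }
  edges <- if (nrow(etab) > 0L)
    cbind(etab$src_key, etab$dst_sep) else matrix(integer(0), ncol = 2L)
  g <- .new_graph(gstring, chars, smeta, sep_pos, edges, bits, nodes, chroms)
  if (!isTRUE(all.equal(graph_checksum(g), as.numeric(meta$checksum))))
    stop("graph checksum mismatch: corrupted files?", call. = FALSE)
  g
}

#' Serialize a minimizer index
#'
#' A JSON document: a header (k, w, trim threshold, hash mode, graph
#' checksum) followed by the sorted postings. Round-trips losslessly.
#' @param index A `minimizer_index`.
#' @param path Output path.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "minimizer_index"))
  doc <- list(format = .format_version,
              k = index$k, w = index$w,
              trim_threshold = index$trim_threshold,
              mode = index$mode, n_gstring = index$n_gstring,
              graph_checksum = index$graph_checksum,
              postings = index$postings)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a minimizer index
#' @param path Path written by [write_index()].
#' @return A `minimizer_index`.
#' @export
read_index <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, .format_version))
    stop("unsupported index file format", call. = FALSE)
  postings <- lapply(doc$postings, as.integer)
  if (length(postings) > 0L) postings <- postings[order(names(postings))]
  structure(list(k = as.integer(doc$k), w = as.integer(doc$w),
                 trim_threshold = as.integer(doc$trim_threshold),
                 mode = doc$mode, postings = postings,
                 n_gstring = as.integer(doc$n_gstring),
                 graph_checksum = as.numeric(doc$graph_checksum)),
            class = "minimizer_index")
}

# ---- SAM -------------------------------------------------------------------

.sam_header <- function(graph, pg_args = "") {
  c("@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", graph$chroms$name, graph$chroms$ref_len),
    sprintf("@PG\tID:edsmap\tPN:edsmap\tVN:%s\tCL:%s",
            as.character(utils::packageVersion("edsmap")), pg_args))
}

# One SAM line for a map_read() result.
.sam_record <- function(id, read, res) {
  if (!isTRUE(res$mapped)) {
    return(paste(id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L, read, "*",
                 sep = "\t"))
  }
  flag <- if (res$strand == "-") 16L else 0L
  seq <- if (res$strand == "-") revcomp(read) else read
  pr <- res$projection
  pos <- max(pr$linear, 1L)
  tags <- c(sprintf("NM:i:%d", as.integer(res$distance)),
            sprintf("gp:i:%d", as.integer(res$lo)),
            if (!pr$on_reference) "ar:i:1")
  paste(id, flag, pr$chrom, pos, 255L, res$cigar, "*", 0L, 0L, seq, "*",
        paste(tags, collapse = "\t"), sep = "\t")
}

#' Parse mapping results back out of a SAM file
#'
#' Reads the records written by [cmd_map()]; the custom `gp` tag carries the
#' gstring coordinate of the alignment start used by [evaluate()].
#' @param path SAM file path.
#' @return data.frame with id, mapped, chrom, pos, gpos, nm.
#' @export
read_sam_mappings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(data.frame(id = character(0), mapped = logical(0),
                      chrom = character(0), pos = integer(0),
                      gpos = integer(0), nm = integer(0)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  get_tag <- function(fields, tag) {
    hit <- grep(paste0("^", tag, ":i:"), fields[-(1:11)], value = TRUE)
    if (length(hit) == 0L) NA_integer_ else
      as.integer(sub(paste0(tag, ":i:"), "", hit[1]))
  }
  data.frame(
    id = vapply(f, `[[`, character(1), 1L),
    mapped = bitwAnd(as.integer(vapply(f, `[[`, character(1), 2L)), 4L) == 0L,
    chrom = vapply(f, `[[`, character(1), 3L),
    pos = as.integer(vapply(f, `[[`, character(1), 4L)),
    gpos = vapply(f, get_tag, integer(1), "gp"),
    nm = vapply(f, get_tag, integer(1), "NM"),
    stringsAsFactors = FALSE)
}
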