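# Shared fixtures, all built in code.

# The running worked example: reference TTNGACAATGAT with a deleted A at 5,
# an AT/TA alternative at 8-9, and a copy-number variant over [3, 11].
fig_graph <- function() {
  eds_graph("TT#NG(A|)CA(AT|TA)GA#T",
            edges = rbind(c(1, 1), c(2, 1), c(2, 2)))
}

fig_eds <- function() parse_eds("NG(A|)CA(AT|TA)GA")

fig_vcf_records <- function() {
  data.frame(CHROM = "ref", POS = c(2, 4, 8), ID = ".",
             REF = c("T", "GA", "AT"), ALT = c("<DUP>", "G", "TA"),
             QUAL = ".", FILTER = ".",
             INFO = c("SVTYPE=DUP;END=11", "", ""),
             stringsAsFactors = FALSE)
}

fig_ref <- function() c(ref = "TTNGACAATGAT")

# Random plain EDS text: a few symbols, alternatives of length 0-3.
random_eds_text <- function(n_symbols = 4L, p_group = 0.5, with_N = FALSE) {
  bases <- c("A", "C", "G", "T", if (with_N) "N")
  parts <- vapply(seq_len(n_symbols), function(s) {
    if (stats::runif(1) < p_group) {
      nalt <- sample(2:3, 1L)
      alts <- vapply(seq_len(nalt), function(a) {
        paste(sample(bases, sample(0:3, 1L), replace = TRUE), collapse = "")
      }, character(1))
      paste0("(", paste(alts, collapse = "|"), ")")
    } else {
      paste(sample(bases, sample(1:3, 1L), replace = TRUE), collapse = "")
    }
  }, character(1))
  paste(parts, collapse = "")
}

# Random small graph: 1-3 nodes, optional self-loop on the middle node and
# an optional skip edge, mirroring how structural variants are encoded.
random_graph <- function(max_nodes = 3L, with_N = FALSE) {
  nn <- sample.int(max_nodes, 1L)
  labels <- vapply(seq_len(nn), function(v)
    random_eds_text(sample(2:3, 1L), with_N = with_N), character(1))
  # avoid empty labels
  labels[nchar(gsub("[(|)]", "", labels)) == 0L] <- "A"
  edges <- NULL
  if (nn > 1L) {
    edges <- cbind(seq_len(nn - 1L), seq_len(nn - 1L))
    if (nn == 3L && stats::runif(1) < 0.4) edges <- rbind(edges, c(2L, 1L))
    if (nn == 3L && stats::runif(1) < 0.3) edges <- rbind(edges, c(1L, 2L))
  }
  eds_graph(paste(labels, collapse = "#"), edges = edges)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Synthetic pangenome under the study conditions: 10 kb reference, SNPs at
# roughly 1 per 40 bp, ten 1-4 bp indels, one ~300 bp copy-number variant.
synth_pangenome <- function(seed = 7L, L = 10000L, n_snp = 250L,
                            n_indel = 10L) {
  set.seed(seed)
  ref <- random_dna(L)
  snp_pos <- sort(sample(2:(L - 1L), n_snp))
  rows <- lapply(snp_pos, function(p) {
    r <- substr(ref, p, p)
    data.frame(CHROM = "chr1", POS = p, ID = ".", REF = r,
               ALT = sample(setdiff(c("A", "C", "G", "T"), r), 1L),
               QUAL = ".", FILTER = ".", INFO = "",
               stringsAsFactors = FALSE)
  })
  ind_pos <- sort(sample(setdiff(2:(L - 10L), snp_pos), n_indel))
  rows2 <- lapply(ind_pos, function(p) {
    r <- substr(ref, p, p)
    if (stats::runif(1) < 0.5) {
      data.frame(CHROM = "chr1", POS = p, ID = ".",
                 REF = substr(ref, p, p + sample(1:4, 1L)), ALT = r,
                 QUAL = ".", FILTER = ".", INFO = "",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(CHROM = "chr1", POS = p, ID = ".", REF = r,
                 ALT = paste0(r, random_dna(sample(1:4, 1L))),
                 QUAL = ".", FILTER = ".", INFO = "",
                 stringsAsFactors = FALSE)
    }
  })
  cnv <- data.frame(CHROM = "chr1", POS = round(L / 2), ID = ".",
                    REF = substr(ref, round(L / 2), round(L / 2)),
                    ALT = "<DUP>", QUAL = ".", FILTER = ".",
                    INFO = sprintf("SVTYPE=DUP;END=%d", round(L / 2) + 300L),
                    stringsAsFactors = FALSE)
  vcf <- do.call(rbind, c(rows, rows2, list(cnv)))
  list(ref = c(chr1 = ref), vcf = vcf[order(vcf$POS), ])
}

# Write the running example as FASTA + VCF files (plain text).
write_fig_fixture <- function(dir) {
  fa <- file.path(dir, "ref.fa")
  writeLines(c(">ref", unname(fig_ref())), fa)
  vcf <- file.path(dir, "vars.vcf")
  rec <- fig_vcf_records()
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
    "##contig=<ID=ref,length=12>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t%s\t%s\t%s\t%s\t%s\t%s", rec$CHROM, rec$POS, rec$ID,
            rec$REF, rec$ALT, rec$QUAL, rec$FILTER,
            ifelse(rec$INFO == "", ".", rec$INFO))), vcf)
  list(fasta = fa, vcf = vcf)
}
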