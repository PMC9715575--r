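# VCF 4.2 export/import of nonredundant PAV loci and the
# presence/absence matrix. Deletions are written as symbolic <DEL> with
# END/SVLEN; insertions are sequence-resolved when the inserted payload
# is known and symbolic <INS> otherwise. One sample column per
# accession; GT 1 means the accession carries the non-pivot allele.

vcf_header <- function(pivot, accessions) {
  contigs <- sprintf("##contig=<ID=%s,length=%d>",
                     names(pivot$chrom_lengths),
                     unname(pivot$chrom_lengths))
  c("##fileformat=VCFv4.2",
    "##source=pansv",
    contigs,
    "##ALT=<ID=DEL,Description=\"Deletion relative to the pivot\">",
    "##ALT=<ID=INS,Description=\"Insertion relative to the pivot\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant on the pivot\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Signed length difference of the alternate allele\">",
    "##INFO=<ID=BP0,Number=1,Type=Integer,Description=\"0-based insertion breakpoint on the pivot\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", accessions), collapse = "\t"))
}

#' Write PAV loci and their presence/absence matrix as VCF 4.2
#'
#' Each locus becomes one record anchored one base left of the event
#' (or at position 1 with the base after the event when the locus
#' starts at the chromosome edge). Writing, re-reading with
#' [read_pav_vcf()], and writing again is byte-identical.
#'
#' @param loci `"pav_loci"` object.
#' @param matrix presence/absence matrix from [build_pa_matrix()].
#' @param pivot `"pansv_pivot"` object (anchor bases and contig
#'   lengths).
#' @param path output file.
#' @export
write_pav_vcf <- function(loci, matrix, pivot, path) {
  ldf <- loci$loci
  if (nrow(ldf) != nrow(matrix) ||
      !identical(rownames(matrix), ldf$locus_id))
    stop("matrix rows do not match loci")
  accs <- colnames(matrix)
  seqs <- pivot$sequences
  lines <- vcf_header(pivot, accs)
  gt <- matrix(".", nrow(matrix), ncol(matrix))
  gt[matrix == "present"] <- "1"
  gt[matrix == "absent"] <- "0"
  for (i in seq_len(nrow(ldf))) {
    l <- ldf[i, ]
    chr_seq <- seqs[[l$chrom]]
    base_at <- function(pos0)
      as.character(Biostrings::subseq(chr_seq, pos0 + 1L, pos0 + 1L))
    if (l$sv_type == "DEL") {
      anchor0 <- if (l$start > 0L) l$start - 1L else l$end
      pos <- anchor0 + 1L
      ref <- base_at(anchor0)
      alt <- "<DEL>"
      info <- sprintf("SVTYPE=DEL;END=%d;SVLEN=-%d", l$end,
                      l$end - l$start)
    } else {
      anchor0 <- if (l$start > 0L) l$start - 1L else l$start
      pos <- anchor0 + 1L
      ref <- base_at(anchor0)
      alt <- if (nzchar(l$payload)) {
        if (l$start > 0L) paste0(ref, l$payload) else
          paste0(l$payload, ref)
      } else "<INS>"
      info <- sprintf("SVTYPE=INS;END=%d;SVLEN=%d;BP0=%d", pos,
                      l$rep_size, l$start)
    }
    lines <- c(lines, paste(c(
      l$chrom, pos, l$locus_id, ref, alt, ".", "PASS", info, "GT",
      gt[i, ]), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

info_field <- function(info, key) {
  v <- sub(sprintf(".*(?:^|;)%s=([^;]*).*", key), "\\1", info)
  ifelse(grepl(sprintf("(^|;)%s=", key), info), v, NA_character_)
}

#' Read a PAV VCF written by [write_pav_vcf()]
#'
#' @param path VCF file.
#' @return list with `loci` (a `"pav_loci"`-compatible locus table;
#'   member calls are not recoverable from a VCF and are returned as
#'   presence-derived entries) and `matrix`.
#' @export
read_pav_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[grepl("^#CHROM", lines)]
  accs <- strsplit(hdr, "\t", fixed = TRUE)[[1]][-(1:9)]
  body <- lines[!grepl("^#", lines)]
  loci <- data.frame(locus_id = character(), chrom = character(),
                     start = integer(), end = integer(),
                     sv_type = character(), rep_size = integer(),
                     n_members = integer(), payload = character(),
                     stringsAsFactors = FALSE)
  m <- matrix(character(), 0, length(accs),
              dimnames = list(NULL, accs))
  rows <- list(); gts <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    info <- f[8]
    svtype <- info_field(info, "SVTYPE")
    pos <- as.integer(f[2])
    svlen <- as.integer(info_field(info, "SVLEN"))
    if (svtype == "DEL") {
      end0 <- as.integer(info_field(info, "END"))
      start0 <- end0 + svlen  # svlen negative
      payload <- ""
      size <- -svlen
    } else {
      start0 <- as.integer(info_field(info, "BP0"))
      end0 <- start0
      size <- svlen
      alt <- f[5]
      payload <- if (alt == "<INS>") "" else {
        if (start0 > 0L) substring(alt, 2L) else
          substring(alt, 1L, nchar(alt) - 1L)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      locus_id = f[3], chrom = f[1], start = start0, end = end0,
      sv_type = svtype, rep_size = size, payload = payload,
      stringsAsFactors = FALSE)
    gts[[length(gts) + 1L]] <- f[-(1:9)]
  }
  if (length(rows)) {
    ldf <- do.call(rbind, rows)
    g <- do.call(rbind, gts)
    state <- matrix("missing", nrow(g), ncol(g),
                    dimnames = list(ldf$locus_id, accs))
    state[g == "1"] <- "present"
    state[g == "0"] <- "absent"
    ldf$n_members <- rowSums(g == "1")
    loci <- ldf[, c("locus_id", "chrom", "start", "end", "sv_type",
                    "rep_size", "n_members", "payload")]
    m <- state
  }
  members <- if (nrow(loci)) {
    idx <- which(m == "present", arr.ind = TRUE)
    data.frame(locus_id = rownames(m)[idx[, 1]],
               accession = colnames(m)[idx[, 2]],
               chrom = loci$chrom[idx[, 1]],
               start = loci$start[idx[, 1]],
               end = loci$end[idx[, 1]],
               size = loci$rep_size[idx[, 1]],
               stringsAsFactors = FALSE)
  } else data.frame(locus_id = character(), accession = character(),
                    chrom = character(), start = integer(),
                    end = integer(), size = integer(),
                    stringsAsFactors = FALSE)
  list(loci = structure(list(loci = loci, members = members),
                        class = "pav_loci"),
       matrix = m)
}
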