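# Shared text-format I/O. All tables use the package-wide 0-based
# half-open convention internally; 1-based inclusive coordinates appear
# only inside GFF3, VCF and SyRI files, converted at the boundary.

assemblytics_header <- paste("#reference", "ref_start", "ref_stop", "ID",
                             "size", "strand", "type", "ref_gap_size",
                             "query_gap_size", "query_coordinates",
                             "method", sep = "\t")

#' Write caller records in the Assemblytics BED dialect
#'
#' Columns: reference, ref_start, ref_stop (0-based half-open BED), ID,
#' size, strand, type, ref_gap_size, query_gap_size, query_coordinates
#' (`chrom:start-end:strand`, 0-based half-open), method.
#'
#' @param records caller-record data.frame (see [emit_caller_calls()]).
#' @param path output file.
#' @export
write_assemblytics <- function(records, path) {
  qc <- sprintf("%s:%d-%d:+", records$query_chrom, records$query_start,
                records$query_end)
  lines <- c(assemblytics_header,
             if (nrow(records)) sprintf(
               "%s\t%d\t%d\t%s\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
               records$ref_chrom, records$ref_start, records$ref_end,
               records$id, records$size, "+", records$annotation,
               records$ref_end - records$ref_start,
               records$query_end - records$query_start,
               qc, "between_alignments"))
  writeLines(lines, path)
  invisible(path)
}

#' Parse an Assemblytics-dialect BED file
#'
#' @param path file written by [write_assemblytics()] or an external
#'   file with the same columns.
#' @param caller,direction provenance recorded on the records.
#' @return caller-record data.frame (0-based half-open in both frames).
#'   Unknown `type` labels are kept with a warning.
#' @export
parse_assemblytics <- function(path, caller = "assemblytics",
                               direction = "pairwise") {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(empty_records())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 11L)
  if (length(bad))
    stop("malformed Assemblytics line ", bad[1], " in ", path,
         " (expected 11 columns)")
  m <- do.call(rbind, parts)
  qc <- regmatches(m[, 10], regexec("^(.+):(\\d+)-(\\d+):([+-])$", m[, 10]))
  qbad <- which(lengths(qc) != 5L)
  if (length(qbad))
    stop("malformed query_coordinates on Assemblytics line ", qbad[1],
         " in ", path)
  qc <- do.call(rbind, qc)
  suppressWarnings({
    rs <- as.integer(m[, 2]); re <- as.integer(m[, 3])
    sz <- as.integer(m[, 5])
    qs <- as.integer(qc[, 3]); qe <- as.integer(qc[, 4])
  })
  nbad <- which(is.na(rs) | is.na(re) | is.na(sz) | is.na(qs) | is.na(qe))
  if (length(nbad))
    stop("non-numeric coordinate on Assemblytics line ", nbad[1],
         " in ", path)
  unknown <- setdiff(unique(m[, 7]), assemblytics_vocab)
  if (length(unknown))
    warning("unknown Assemblytics type label(s) retained: ",
            paste(unknown, collapse = ", "))
  data.frame(caller = caller, direction = direction,
             ref_chrom = m[, 1], ref_start = rs, ref_end = re,
             query_chrom = qc[, 2], query_start = qs, query_end = qe,
             annotation = m[, 7], size = sz, id = m[, 4],
             stringsAsFactors = FALSE)
}

#' Write caller records in the SyRI TSV dialect
#'
#' Nine tab-separated columns without header: ref_chrom, ref_start,
#' ref_end, query_chrom, query_start, query_end, id, parent, annotation.
#' Coordinates are 1-based inclusive; a zero-length (insertion
#' breakpoint) interval is written with end = start - 1.
#'
#' @param records caller-record data.frame.
#' @param path output file.
#' @export
write_syri <- function(records, path) {
  to1 <- function(s, e) list(start = s + 1L, end = as.integer(e))
  r <- to1(records$ref_start, records$ref_end)
  q <- to1(records$query_start, records$query_end)
  lines <- if (nrow(records)) sprintf(
    "%s\t%d\t%d\t%s\t%d\t%d\t%s\t%s\t%s",
    records$ref_chrom, r$start, r$end,
    records$query_chrom, q$start, q$end,
    records$id, "-", records$annotation) else character()
  writeLines(lines, path)
  invisible(path)
}

syri_used_annotations <- c("INS", "DEL", "HDR", "INVAL", "SNP", "DUPAL",
                           "CPL")

#' Parse a SyRI-dialect TSV file
#'
#' Rows with annotations outside INS/DEL/HDR/INVAL/SNP/DUPAL/CPL (for
#' example SYN blocks) are skipped; their number is returned in the
#' `"ignored"` attribute.
#'
#' @param path SyRI-style TSV (see [write_syri()] for the column layout).
#' @param caller,direction provenance recorded on the records.
#' @return caller-record data.frame with attribute `ignored` (count of
#'   skipped rows).
#' @export
parse_syri <- function(path, caller = "syri", direction = "pairwise") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (length(lines) == 0L) {
    out <- empty_records()
    attr(out, "ignored") <- 0L
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 9L)
  if (length(bad))
    stop("malformed SyRI line ", bad[1], " in ", path,
         " (expected 9 columns)")
  m <- do.call(rbind, parts)
  suppressWarnings({
    rs <- as.integer(m[, 2]); re <- as.integer(m[, 3])
    qs <- as.integer(m[, 5]); qe <- as.integer(m[, 6])
  })
  nbad <- which(is.na(rs) | is.na(re) | is.na(qs) | is.na(qe))
  if (length(nbad))
    stop("non-numeric coordinate on SyRI line ", nbad[1], " in ", path)
  keep <- m[, 9] %in% syri_used_annotations
  ignored <- sum(!keep)
  m <- m[keep, , drop = FALSE]
  rs <- rs[keep]; re <- re[keep]; qs <- qs[keep]; qe <- qe[keep]
  # 1-based inclusive -> 0-based half-open (end = start - 1 means empty)
  rs0 <- rs - 1L; re0 <- pmax(re, rs - 1L)
  qs0 <- qs - 1L; qe0 <- pmax(qe, qs - 1L)
  out <- data.frame(caller = caller, direction = direction,
                    ref_chrom = m[, 1], ref_start = rs0, ref_end = re0,
                    query_chrom = m[, 4], query_start = qs0,
                    query_end = qe0,
                    annotation = m[, 9],
                    size = pmax(re0 - rs0, qe0 - qs0),
                    id = m[, 7], stringsAsFactors = FALSE)
  attr(out, "ignored") <- ignored
  out
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, exon and CDS features (one exon per gene; the CDS
#' runs from the start codon to the far gene end minus a short UTR).
#' Coordinates convert to 1-based inclusive on output.
#'
#' @param genes gene-model data.frame from [simulate_pivot()].
#' @param path output file.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    s1 <- g$start + 1L; e1 <- g$end
    if (g$strand == "+") {
      cs1 <- g$cds_start + 1L; ce1 <- g$end
    } else {
      cs1 <- g$start + 1L; ce1 <- g$cds_start + 1L
    }
    lines <- c(lines, sprintf(
      "%s\tpansv\t%s\t%d\t%d\t.\t%s\t%s\t%s",
      g$chrom,
      c("gene", "mRNA", "exon", "CDS"),
      c(s1, s1, s1, cs1), c(e1, e1, e1, ce1),
      g$strand, c(".", ".", ".", "0"),
      c(sprintf("ID=%s", g$gene_id),
        sprintf("ID=%s.t1;Parent=%s", g$gene_id, g$gene_id),
        sprintf("ID=%s.t1.e1;Parent=%s.t1", g$gene_id, g$gene_id),
        sprintf("ID=%s.t1.c1;Parent=%s.t1", g$gene_id, g$gene_id))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Uses `gene` features for intervals and infers each gene's start-codon
#' position from the strand-appropriate extremity of its CDS features
#' (leftmost CDS base for `+` genes, rightmost for `-`). Genes without
#' CDS are kept with `cds_start = NA` and a warning; such genes are
#' excluded from 5' upstream classification.
#'
#' @param path GFF3 file.
#' @return gene-model data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `cds_start`; 0-based half-open).
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (!length(lines))
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), cds_start = integer(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 9L)
  if (length(bad))
    stop("malformed GFF3 line ", bad[1], " in ", path)
  m <- do.call(rbind, parts)
  typ <- m[, 3]
  attr_field <- function(attrs, key) {
    v <- sub(sprintf(".*(?:^|;)%s=([^;]*).*", key), "\\1", attrs)
    ifelse(grepl(sprintf("(^|;)%s=", key), attrs), v, NA_character_)
  }
  genes <- which(typ == "gene")
  gid <- attr_field(m[genes, 9], "ID")
  gdf <- data.frame(gene_id = gid, chrom = m[genes, 1],
                    start = as.integer(m[genes, 4]) - 1L,
                    end = as.integer(m[genes, 5]),
                    strand = m[genes, 7], cds_start = NA_integer_,
                    stringsAsFactors = FALSE)
  cds <- which(typ == "CDS")
  if (length(cds)) {
    parent <- attr_field(m[cds, 9], "Parent")
    cds_gene <- sub("\\.t\\d+$", "", parent)
    cs <- as.integer(m[cds, 4]) - 1L
    ce <- as.integer(m[cds, 5])
    for (i in seq_len(nrow(gdf))) {
      j <- which(cds_gene == gdf$gene_id[i])
      if (!length(j)) next
      gdf$cds_start[i] <- if (gdf$strand[i] == "+") min(cs[j])
                          else max(ce[j]) - 1L
    }
  }
  if (anyNA(gdf$cds_start) && nrow(gdf))
    warning(sum(is.na(gdf$cds_start)),
            " gene(s) without CDS: start codon undefined, excluded from",
            " 5' upstream classification")
  sort_genomic(gdf)
}

#' Write intervals as BED
#'
#' BED6 when `name`/`score`/`strand`-like extra columns are supplied via
#' `extra`; BED3 otherwise. Input must be 0-based half-open (native BED).
#'
#' @param df data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand` columns.
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  cols <- c("name", "score", "strand")
  have <- cols[cols %in% names(df)]
  out <- df[, c("chrom", "start", "end"), drop = FALSE]
  if (length(have)) {
    defaults <- list(name = ".", score = 0L, strand = ".")
    for (cn in cols) out[[cn]] <- df[[cn]] %||% defaults[[cn]]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED6 file
#'
#' Unsorted input is sorted on load with a warning.
#'
#' @param path BED file.
#' @return data.frame `chrom`, `start`, `end` (+ `name`, `score`,
#'   `strand` for BED6).
#' @export
read_bed <- function(path) {
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, comment.char = "#",
               stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(df))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 6L) names(df)[4:6] <- c("name", "score", "strand")
  if (!is.numeric(df$start) || !is.numeric(df$end))
    stop("non-numeric coordinates in BED file ", path)
  o <- order(chrom_rank(df$chrom), df$start, df$end)
  if (!identical(o, seq_len(nrow(df)))) {
    warning("BED file ", path, " was unsorted; sorted on load")
    df <- df[o, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write harmonized SV calls as a sorted BED-like TSV
#'
#' Columns: chrom, start, end, accession, sv_class, size, support,
#' source_ids (0-based half-open).
#'
#' @param calls SV-call data.frame.
#' @param path output file.
#' @export
write_calls <- function(calls, path) {
  calls <- calls[order(chrom_rank(calls$chrom), calls$start, calls$end,
                       calls$accession), , drop = FALSE]
  out <- calls[, c("chrom", "start", "end", "accession", "sv_class",
                   "size", "support", "source_ids"), drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read harmonized SV calls written by [write_calls()]
#' @param path TSV file.
#' @return SV-call data.frame.
#' @export
read_calls <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  for (cn in c("chrom", "accession", "support", "source_ids"))
    df[[cn]] <- as.character(df[[cn]])
  if (is.null(df$payload)) df$payload <- rep("", nrow(df))
  df
}

#' Write a phenotype/group table
#' @param pheno data.frame from [simulate_phenotypes()].
#' @param path output file.
#' @export
write_phenotypes <- function(pheno, path) {
  write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/group table
#' @param path TSV with columns accession, group, trait, label, code.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = c(accession = "character"))
}
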