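# Genomic context of SVs relative to gene models, gene content of
# region sets, and protein-domain ranking.

upstream_window <- function(genes, upstream) {
  # strand-aware 1-kb (default) window immediately upstream of the
  # start codon, 0-based half-open
  s <- ifelse(genes$strand == "+", genes$cds_start - upstream,
              genes$cds_start + 1L)
  e <- ifelse(genes$strand == "+", genes$cds_start,
              genes$cds_start + 1L + upstream)
  data.frame(chrom = genes$chrom, start = pmax(0L, as.integer(s)),
             end = as.integer(e), gene_id = genes$gene_id,
             stringsAsFactors = FALSE)
}

overlaps_iv <- function(s1, e1, s2, e2) {
  # >= 1 bp overlap for intervals; a zero-width breakpoint hits an
  # interval when it falls strictly inside it
  n <- max(length(s1), length(s2))
  s1 <- rep_len(s1, n); e1 <- rep_len(e1, n)
  s2 <- rep_len(s2, n); e2 <- rep_len(e2, n)
  ifelse(e1 > s1, s1 < e2 & s2 < e1, s2 < s1 & s1 < e2)
}

#' Classify the genomic context of SVs
#'
#' An SV is `genic` when its interval overlaps any gene interval by at
#' least one bp (insertions count via their breakpoint position);
#' otherwise `five_prime` when it overlaps the strand-aware window
#' within `upstream` bp of a gene's start codon; otherwise
#' `intergenic`. Genic takes precedence over five_prime, so the three
#' labels are mutually exclusive and exhaustive. All qualifying gene
#' ids are reported.
#'
#' @param svs SV-call data.frame (`chrom`, `start`, `end`).
#' @param genes gene-model data.frame (`gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `cds_start`); genes with `NA` `cds_start` are
#'   excluded from five_prime logic.
#' @param upstream upstream window size in bp (default 1000).
#' @return `svs` with added columns `context` and `genes`
#'   (comma-separated qualifying gene ids).
#' @export
classify_sv_context <- function(svs, genes, upstream = 1000L) {
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  n <- nrow(svs)
  context <- rep("intergenic", n)
  hit_genes <- character(n)
  if (n && nrow(genes)) {
    collect <- function(tab) {
      # returns per-sv comma-joined gene ids with >=1 match
      out <- character(n)
      for (ch in unique(svs$chrom)) {
        si <- which(svs$chrom == ch)
        gi <- which(tab$chrom == ch)
        if (!length(si) || !length(gi)) next
        for (i in si) {
          hit <- overlaps_iv(svs$start[i], svs$end[i],
                             tab$start[gi], tab$end[gi])
          if (any(hit))
            out[i] <- paste(sort(tab$gene_id[gi][hit]), collapse = ",")
        }
      }
      out
    }
    genic <- collect(genes)
    up <- upstream_window(genes[!is.na(genes$cds_start), , drop = FALSE],
                          as.integer(upstream))
    five <- collect(up)
    context[five != ""] <- "five_prime"
    hit_genes[five != ""] <- five[five != ""]
    context[genic != ""] <- "genic"
    hit_genes[genic != ""] <- genic[genic != ""]
  }
  out <- svs
  out$context <- context
  out$genes <- hit_genes
  out
}

#' Genes overlapping each region of a region set
#'
#' @param regions region data.frame (`chrom`, `start`, `end`).
#' @param genes gene-model data.frame.
#' @return list parallel to `regions` rows: sorted, deduplicated gene
#'   id vectors; also a flattened unique gene id vector in the
#'   `"all_genes"` attribute.
#' @export
genes_in_regions <- function(regions, genes) {
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    gi <- genes$chrom == regions$chrom[i] &
      genes$start < regions$end[i] & regions$start[i] < genes$end
    out[[i]] <- sort(unique(genes$gene_id[gi]))
  }
  attr(out, "all_genes") <- sort(unique(unlist(out)))
  out
}

#' Rank protein domains by gene content of a region set
#'
#' Counts, for each domain, the number of distinct genes inside the
#' regions that carry it; ranks descending with ties broken by domain
#' id.
#'
#' @param regions region data.frame.
#' @param genes gene-model data.frame.
#' @param gene2domain data.frame with columns `gene`, `domain`.
#' @param top_n ranks returned (default 10; fewer if fewer domains).
#' @return data.frame `domain`, `gene_count`.
#' @export
domain_ranking <- function(regions, genes, gene2domain, top_n = 10L) {
  gset <- attr(genes_in_regions(regions, genes), "all_genes")
  g2d <- gene2domain[gene2domain$gene %in% gset, , drop = FALSE]
  if (nrow(g2d) == 0L) {
    warning("no annotated genes in the regions; empty ranking")
    return(data.frame(domain = character(), gene_count = integer(),
                      stringsAsFactors = FALSE))
  }
  cnt <- tapply(g2d$gene, g2d$domain, function(x) length(unique(x)))
  out <- data.frame(domain = names(cnt),
                    gene_count = as.integer(cnt),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$gene_count, out$domain), , drop = FALSE]
  rownames(out) <- NULL
  head(out, top_n)
}

#' Read a two-column gene-to-attribute TSV (domains, GO terms)
#'
#' @param path TSV with header columns named e.g. `gene`, `domain` or
#'   `gene`, `term`.
#' @return data.frame with the file's two columns.
#' @export
read_gene_map <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a two-column gene map TSV
#' @param df data.frame (two columns).
#' @param path output file.
#' @export
write_gene_map <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
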