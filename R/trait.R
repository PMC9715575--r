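# Trait co-segregation: candidate-gene PAV tables, Fisher exact
# co-segregation statistics, genotype-group phenotype summaries, and
# the Bonferroni threshold utility.

#' PAV loci at a candidate gene, with per-accession presence
#'
#' Reports every PAV locus overlapping the gene interval extended by
#' `flank` bp on each side, its presence vector across accessions, and
#' an overlap class: `genic` (gene body only), `promoter` (the 1-kb
#' strand-aware upstream window only), `promoter+genic` (both) or
#' `flank` (neither, within the flank only).
#'
#' @param gene a gene id (looked up in `genes`) or a list/one-row
#'   data.frame with `chrom`, `start`, `end`, `strand`, `cds_start`.
#' @param genes gene-model data.frame (needed when `gene` is an id).
#' @param loci `"pav_loci"` object.
#' @param matrix presence/absence matrix from [build_pa_matrix()].
#' @param flank search flank in bp (default 2000).
#' @param upstream promoter window size in bp (default 1000).
#' @return data.frame with one row per (locus, accession):
#'   `locus_id`, `sv_type`, `overlap_class`, `accession`, `state`;
#'   zero rows when no locus is near the gene.
#' @export
locate_gene_sv <- function(gene, genes = NULL, loci, matrix,
                           flank = 2000L, upstream = 1000L) {
  if (is.character(gene)) {
    if (is.null(genes)) stop("gene id lookup requires a gene table")
    row <- genes[genes$gene_id == gene, , drop = FALSE]
    if (nrow(row) == 0L) stop("gene id not found: ", gene)
    gene <- row[1, ]
  }
  ldf <- loci$loci
  near <- ldf$chrom == gene$chrom &
    overlaps_iv_vec(ldf$start, ldf$end,
                    gene$start - flank, gene$end + flank)
  ldf <- ldf[near, , drop = FALSE]
  if (nrow(ldf) == 0L)
    return(data.frame(locus_id = character(), sv_type = character(),
                      overlap_class = character(),
                      accession = character(), state = character(),
                      stringsAsFactors = FALSE))
  up <- upstream_window(data.frame(gene_id = "g", chrom = gene$chrom,
                                   start = gene$start, end = gene$end,
                                   strand = gene$strand,
                                   cds_start = gene$cds_start,
                                   stringsAsFactors = FALSE),
                        as.integer(upstream))
  in_gene <- overlaps_iv_vec(ldf$start, ldf$end, gene$start, gene$end)
  in_prom <- overlaps_iv_vec(ldf$start, ldf$end, up$start, up$end)
  oc <- ifelse(in_gene & in_prom, "promoter+genic",
               ifelse(in_gene, "genic",
                      ifelse(in_prom, "promoter", "flank")))
  rows <- lapply(seq_len(nrow(ldf)), function(i)
    data.frame(locus_id = ldf$locus_id[i], sv_type = ldf$sv_type[i],
               overlap_class = oc[i], accession = colnames(matrix),
               state = matrix[ldf$locus_id[i], ],
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# element-wise intervals (possibly zero-width) against one interval
overlaps_iv_vec <- function(s1, e1, s2, e2) {
  overlaps_iv(s1, e1, s2, e2)
}

#' Co-segregation of a presence vector with a binary phenotype
#'
#' Concordance is the better of the two carrier-to-phenotype
#' polarities (fraction of accessions on which presence predicts the
#' phenotype); significance is the two-sided Fisher exact p-value of
#' the 2x2 presence-by-phenotype table (probabilities no larger than
#' the observed table's are summed over the hypergeometric
#' distribution with fixed margins).
#'
#' @param presence logical (or "present"/"absent" character) vector.
#' @param phenotype logical vector aligned on the same accessions
#'   (e.g. `code == 1` for erect).
#' @return list: `concordance`, `p`, `table` (2x2), `degenerate`
#'   (TRUE when either margin is constant, in which case `p = 1`).
#' @export
cosegregation_test <- function(presence, phenotype) {
  if (is.character(presence)) presence <- presence == "present"
  stopifnot(length(presence) == length(phenotype))
  keep <- !is.na(presence) & !is.na(phenotype)
  presence <- presence[keep]; phenotype <- phenotype[keep]
  conc <- max(mean(presence == phenotype), mean(presence != phenotype))
  tab <- table(factor(presence, levels = c(TRUE, FALSE)),
               factor(phenotype, levels = c(TRUE, FALSE)))
  degenerate <- length(unique(phenotype)) < 2L ||
    length(unique(presence)) < 2L || length(presence) < 2L
  p <- if (degenerate) 1 else fisher.test(tab)$p.value
  list(concordance = conc, p = p, table = tab, degenerate = degenerate)
}

#' Phenotype summary per genotype class
#'
#' Boxplot-ready summary of numeric phenotype codes (the 1/3/6
#' erect/intermediate/pendent scale) per genotype class.
#'
#' @param genotype named character vector (accession -> class, e.g.
#'   "A"/"B").
#' @param codes named numeric vector (accession -> phenotype code);
#'   accessions without a code are excluded with a warning.
#' @return data.frame: `genotype`, `n`, `mean`, `median`, `q25`, `q75`.
#' @export
genotype_group_summary <- function(genotype, codes) {
  miss <- setdiff(names(genotype), names(codes))
  if (length(miss)) {
    warning("accession(s) without phenotype excluded: ",
            paste(miss, collapse = ", "))
    genotype <- genotype[!names(genotype) %in% miss]
  }
  x <- codes[names(genotype)]
  rows <- lapply(sort(unique(genotype)), function(g) {
    v <- x[genotype == g]
    data.frame(genotype = g, n = length(v), mean = mean(v),
               median = median(v),
               q25 = unname(quantile(v, 0.25)),
               q75 = unname(quantile(v, 0.75)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bonferroni genome-wide significance threshold
#'
#' Returns `-log10(alpha / n_markers)`, the horizontal significance
#' line of a Manhattan plot under Bonferroni correction.
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param n_markers number of tested markers (>= 1).
#' @return numeric threshold on the -log10(p) scale.
#' @examples
#' bonferroni_threshold(0.05, 1)      # 1.30103
#' bonferroni_threshold(0.05, 13146)  # 5.4199
#' @export
bonferroni_threshold <- function(alpha, n_markers) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_markers < 1) stop("n_markers must be >= 1")
  -log10(alpha / n_markers)
}
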