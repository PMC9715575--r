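# Synthetic downstream-input tables: orthogroup counts, gene->domain
# and gene->GO maps, and GWAS intervals.

#' Simulate an orthogroup gene-count table
#'
#' Families are drawn as core (present in every accession), non-core
#' (present in a random subset of 2 to n-1) or accession-specific, in
#' proportions echoing a crop pan-genome (roughly 45/50/5); present
#' cells carry 1-3 paralogs.
#'
#' @param config a [sim_config()].
#' @param n_families number of gene families.
#' @param proportions length-3 numeric (core, non_core, specific).
#' @return `"orthogroup_table"`.
#' @export
simulate_orthogroups <- function(config, n_families = 400L,
                                 proportions = c(0.45, 0.5, 0.05)) {
  validate_sim_config(config)
  accs <- config$accessions
  n <- length(accs)
  with_seed(config$seed + 3L, {
    type <- sample(c("core", "non_core", "specific"), n_families,
                   replace = TRUE, prob = proportions)
    counts <- matrix(0L, n_families, n,
                     dimnames = list(sprintf("OG%06d", seq_len(n_families)),
                                     accs))
    for (i in seq_len(n_families)) {
      pres <- switch(type[i],
                     core = seq_len(n),
                     specific = sample.int(n, 1L),
                     non_core = sample.int(n, sample_range(c(2L, n - 1L))))
      counts[i, pres] <- sample(1:3, length(pres), replace = TRUE)
    }
    orthogroup_table(counts)
  })
}

#' Write an orthogroup table as OrthoFinder-style gene-count TSV
#' @param table `"orthogroup_table"`.
#' @param path output file.
#' @export
write_orthogroups <- function(table, path) {
  df <- data.frame(Orthogroup = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pfam_pool <- c("PF00078", "PF00665", "PF17917", "PF17921", "PF00931",
               "PF00069", "PF00067", "PF13966", "PF00560", "PF03732")
go_pool <- c("GO:0005515", "GO:0003676", "GO:0016787", "GO:0006259",
             "GO:0004518", "GO:0009058", "GO:0065007", "GO:0010467")

#' Simulate gene-to-domain and gene-to-GO maps for the pivot genes
#'
#' Each gene draws 0-3 Pfam-like domains and 0-3 GO-like terms from
#' small pools (retroelement-flavoured domains are over-weighted, so
#' repeat-dense regions rank them highly, as real PAV hotspot regions
#' do).
#'
#' @param genes gene-model data.frame.
#' @param seed integer seed.
#' @return list with data.frames `gene2domain` (`gene`, `domain`) and
#'   `gene2term` (`gene`, `term`).
#' @export
simulate_gene_maps <- function(genes, seed = 1L) {
  with_seed(seed, {
    w <- c(4, 3, 2, 2, 1, 1, 1, 1, 1, 1)
    g2d <- lapply(genes$gene_id, function(g) {
      k <- sample(0:3, 1L)
      if (k == 0L) return(NULL)
      data.frame(gene = g,
                 domain = sample(pfam_pool, k, prob = w),
                 stringsAsFactors = FALSE)
    })
    g2t <- lapply(genes$gene_id, function(g) {
      k <- sample(0:3, 1L)
      if (k == 0L) return(NULL)
      data.frame(gene = g, term = sample(go_pool, k),
                 stringsAsFactors = FALSE)
    })
    list(gene2domain = do.call(rbind, g2d) %||%
           data.frame(gene = character(), domain = character()),
         gene2term = do.call(rbind, g2t) %||%
           data.frame(gene = character(), term = character()))
  })
}

#' Synthetic GWAS intervals
#'
#' One interval per group-enrichment directive (centred on the planted
#' region) plus `n_background` random intervals, emulating previously
#' reported trait-associated regions to overlap with high-PAV regions.
#'
#' @param config a [sim_config()].
#' @param n_background random background intervals.
#' @param width interval width in bp.
#' @return data.frame `chrom`, `start`, `end`, `name`.
#' @export
simulate_gwas_regions <- function(config, n_background = 3L,
                                  width = 200000L) {
  validate_sim_config(config)
  chroms <- sprintf("chr%02d", seq_len(config$n_chromosomes))
  with_seed(config$seed + 4L, {
    rows <- list()
    for (d in config$group_enrichment) {
      mid <- (d$start + d$end) %/% 2L
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = d$chrom, start = max(0L, mid - width %/% 2L),
        end = min(config$chrom_length, mid + width %/% 2L),
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_background)) {
      ch <- sample(chroms, 1L)
      s <- sample.int(max(1L, config$chrom_length - width), 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = s, end = s + width,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out$name <- sprintf("gwas%02d", seq_len(nrow(out)))
    sort_genomic(out)
  })
}
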