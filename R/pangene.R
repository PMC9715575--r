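# Pan-gene family analysis: core/non-core/specific classification,
# pan/core accumulation curves, presence patterns and hypergeometric
# term enrichment.

#' Build an orthogroup table
#'
#' @param counts family x accession matrix of non-negative gene counts
#'   (rownames = family ids, colnames = accession names).
#' @param gene_members optional named list mapping family id to gene id
#'   vector; lengths must equal the family row sums.
#' @return list of class `"orthogroup_table"`.
#' @export
orthogroup_table <- function(counts, gene_members = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) < 1))
    stop("every family must have total count >= 1")
  if (!is.null(gene_members)) {
    if (!setequal(names(gene_members), rownames(counts)))
      stop("gene_members names must match family ids")
    bad <- rowSums(counts)[names(gene_members)] !=
      lengths(gene_members)
    if (any(bad))
      stop("gene_members lengths inconsistent with counts for: ",
           paste(names(gene_members)[bad], collapse = ", "))
  }
  structure(list(counts = counts, gene_members = gene_members),
            class = "orthogroup_table")
}

#' Read an OrthoFinder-style gene-count TSV
#'
#' First column the orthogroup id, one column per accession, optional
#' trailing `Total` column (dropped).
#'
#' @param path TSV file.
#' @return `"orthogroup_table"`.
#' @export
read_orthogroups <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if ("Total" %in% colnames(m))
    m <- m[, colnames(m) != "Total", drop = FALSE]
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  orthogroup_table(m)
}

#' Classify gene families into core, non-core and specific sets
#'
#' A family is present in an accession when its gene count there is at
#' least one (paralog counts do not affect the class). Families present
#' in all `n_genomes` accessions are core, in exactly one specific, and
#' otherwise non-core. The `softcore_threshold` generalization reports
#' families present in at least that many genomes (e.g. `n - 1` for the
#' "at least 11 of 12" convention).
#'
#' @param table `"orthogroup_table"`.
#' @param n_genomes number of genomes defining "core"; defaults to the
#'   number of accession columns.
#' @param softcore_threshold presence threshold for the softcore count.
#' @return list of class `"pan_classification"`: `class` (named factor
#'   per family), `family_counts`, `gene_counts` (per class; gene
#'   totals use the count matrix), `softcore_threshold`,
#'   `n_softcore_families`.
#' @export
classify_families <- function(table, n_genomes = ncol(table$counts),
                              softcore_threshold = n_genomes - 1L) {
  counts <- table$counts
  if (nrow(counts) == 0L) {
    return(structure(list(
      class = factor(character(),
                     levels = c("core", "non_core", "specific")),
      family_counts = c(core = 0L, non_core = 0L, specific = 0L),
      gene_counts = c(core = 0L, non_core = 0L, specific = 0L),
      softcore_threshold = softcore_threshold,
      n_softcore_families = 0L), class = "pan_classification"))
  }
  presence <- rowSums(counts >= 1L)
  cls <- factor(ifelse(presence >= n_genomes, "core",
                       ifelse(presence == 1L, "specific", "non_core")),
                levels = c("core", "non_core", "specific"))
  names(cls) <- rownames(counts)
  genes <- rowSums(counts)
  structure(list(
    class = cls,
    family_counts = vapply(levels(cls), function(l)
      sum(cls == l), integer(1)),
    gene_counts = vapply(levels(cls), function(l)
      as.integer(sum(genes[cls == l])), integer(1)),
    softcore_threshold = softcore_threshold,
    n_softcore_families = sum(presence >= softcore_threshold)),
    class = "pan_classification")
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
    }
  }
  out
}

#' Pan- and core-family accumulation curves
#'
#' For each random ordering of the accessions, `pan(k)` is the number
#' of families present in at least one of the first `k` genomes and
#' `core(k)` the number present in all of them; means and standard
#' deviations over orderings are returned. When `exhaustive = TRUE`
#' (or `n_permutations >= n!` for up to 8 genomes) all orderings are
#' enumerated instead of sampled.
#'
#' @param table `"orthogroup_table"`.
#' @param n_permutations number of sampled orderings (default 100).
#' @param seed RNG seed for the sampled orderings.
#' @param exhaustive enumerate all orderings.
#' @return data.frame: `k`, `pan_mean`, `pan_sd`, `core_mean`,
#'   `core_sd`, plus attribute `per_ordering` (list of per-ordering
#'   pan/core matrices is not retained; monotonicity is guaranteed
#'   per ordering by construction).
#' @export
accumulation_curves <- function(table, n_permutations = 100L,
                                seed = 1L, exhaustive = FALSE) {
  stopifnot(n_permutations >= 1L)
  pres <- table$counts >= 1L
  n <- ncol(pres)
  if (n <= 8L && (exhaustive || n_permutations >= factorial(n))) {
    orders <- all_permutations(n)
  } else {
    orders <- with_seed(seed, replicate(n_permutations, sample.int(n),
                                        simplify = FALSE))
  }
  pan <- matrix(0L, length(orders), n)
  core <- matrix(0L, length(orders), n)
  for (r in seq_along(orders)) {
    ord <- orders[[r]]
    acc_pan <- rep(FALSE, nrow(pres))
    acc_core <- rep(TRUE, nrow(pres))
    for (k in seq_len(n)) {
      col <- pres[, ord[k]]
      acc_pan <- acc_pan | col
      acc_core <- acc_core & col
      pan[r, k] <- sum(acc_pan)
      core[r, k] <- sum(acc_core)
    }
  }
  data.frame(k = seq_len(n),
             pan_mean = colMeans(pan),
             pan_sd = apply(pan, 2, sd),
             core_mean = colMeans(core),
             core_sd = apply(core, 2, sd))
}

#' Families shared by at least a minimum number of genomes, by pattern
#'
#' Groups qualifying families by their exact presence pattern across
#' accessions; patterns are sorted by family count (descending), then
#' lexicographically.
#'
#' @param table `"orthogroup_table"`.
#' @param min_genomes minimum presence (default `n - 1`, the "at least
#'   11 of 12" convention).
#' @return data.frame: `pattern` (e.g. `"110...`", one character per
#'   accession in column order), `n_present`, `n_families`.
#' @export
shared_pattern <- function(table,
                           min_genomes = ncol(table$counts) - 1L) {
  pres <- table$counts >= 1L
  if (min_genomes > ncol(pres)) stop("min_genomes exceeds genome count")
  keep <- rowSums(pres) >= min_genomes
  pres <- pres[keep, , drop = FALSE]
  if (nrow(pres) == 0L)
    return(data.frame(pattern = character(), n_present = integer(),
                      n_families = integer(), stringsAsFactors = FALSE))
  pat <- apply(pres, 1, function(x) paste(as.integer(x), collapse = ""))
  tab <- table(pat)
  out <- data.frame(pattern = names(tab),
                    n_present = vapply(strsplit(names(tab), ""),
                                       function(x) sum(x == "1"),
                                       integer(1)),
                    n_families = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_families, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric term enrichment with BH adjustment
#'
#' One-sided upper-tail hypergeometric test per term for
#' over-representation of the term among `gene_set` relative to
#' `universe`, with Benjamini-Hochberg adjustment across the tested
#' terms. Terms with fewer than `min_genes` members in the set are
#' skipped.
#'
#' @param gene_set character vector, a subset of `universe`.
#' @param universe character vector of all genes.
#' @param gene2term data.frame with columns `gene`, `term`.
#' @param min_genes minimum set members per tested term (default 3).
#' @return data.frame: `term`, `set_count`, `universe_count`, `fold`,
#'   `p`, `q`, sorted by `p`.
#' @export
term_enrichment <- function(gene_set, universe, gene2term,
                            min_genes = 3L) {
  if (length(universe) == 0L) stop("empty universe")
  if (!all(gene_set %in% universe))
    stop("gene_set must be a subset of universe")
  g2t <- gene2term[gene2term$gene %in% universe, , drop = FALSE]
  N <- length(unique(universe))
  n <- length(unique(gene_set))
  terms <- unique(g2t$term)
  rows <- lapply(terms, function(tm) {
    tg <- unique(g2t$gene[g2t$term == tm])
    K <- length(tg)
    k <- length(intersect(tg, gene_set))
    if (k < min_genes) return(NULL)
    data.frame(term = tm, set_count = k, universe_count = K,
               fold = (k / n) / (K / N),
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(term = character(), set_count = integer(),
                      universe_count = integer(), fold = numeric(),
                      p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Closed-form expected accumulation curves
#'
#' Exact expectations of `pan(k)` and `core(k)` over uniformly random
#' orderings: a family present in `m` of `n` genomes is absent from a
#' random subset of size `k` with probability `C(n-m, k) / C(n, k)` and
#' present in all of it with probability `C(m, k) / C(n, k)`.
#' Independent cross-check for [accumulation_curves()].
#'
#' @param table `"orthogroup_table"`.
#' @return data.frame `k`, `pan_mean`, `core_mean`.
#' @export
expected_curves <- function(table) {
  pres <- table$counts >= 1L
  n <- ncol(pres)
  m <- rowSums(pres)
  ks <- seq_len(n)
  pan <- vapply(ks, function(k)
    sum(1 - choose(n - m, k) / choose(n, k)), numeric(1))
  core <- vapply(ks, function(k)
    sum(choose(m, k) / choose(n, k)), numeric(1))
  data.frame(k = ks, pan_mean = pan, core_mean = core)
}
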