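# Independent brute-force oracles (plain nested/vectorized arithmetic,
# no interval-tree machinery) used to cross-check the fast paths.

# greedy one-to-one matching from an exhaustively enumerated O(n^2)
# candidate list, mirroring the documented scoring and tie-breaks
brute_match <- function(a, b, params = match_params()) {
  rows <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      a_bp <- a$end[i] == a$start[i]
      b_bp <- b$end[j] == b$start[j]
      if (a_bp != b_bp) next
      if (a_bp) {
        d <- abs(a$start[i] - b$start[j])
        sr <- min(a$size[i], b$size[j]) / max(a$size[i], b$size[j], 1)
        if (d <= params$max_breakpoint_dist &&
            sr >= params$min_size_ratio)
          rows[[length(rows) + 1L]] <- data.frame(
            a_idx = i, b_idx = j,
            score = 1 - d / (params$max_breakpoint_dist + 1))
      } else {
        ov <- max(0, min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]))
        ro <- min(ov / (a$end[i] - a$start[i]),
                  ov / (b$end[j] - b$start[j]))
        if (ro >= params$min_reciprocal_overlap)
          rows[[length(rows) + 1L]] <- data.frame(
            a_idx = i, b_idx = j, score = ro)
      }
    }
  }
  cand <- do.call(rbind, rows)
  if (is.null(cand))
    return(data.frame(a_idx = integer(), b_idx = integer(),
                      score = numeric()))
  o <- order(-cand$score, a$start[cand$a_idx], a$id[cand$a_idx],
             b$start[cand$b_idx], b$id[cand$b_idx])
  cand <- cand[o, , drop = FALSE]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used_a[cand$a_idx[k]] && !used_b[cand$b_idx[k]]) {
      keep[k] <- TRUE
      used_a[cand$a_idx[k]] <- TRUE
      used_b[cand$b_idx[k]] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# single-linkage components by repeated flood fill over an O(n^2)
# adjacency matrix
brute_cluster <- function(x, recip_overlap, max_dist) {
  n <- nrow(x)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || x$chrom[i] != x$chrom[j]) next
      bp_i <- x$end[i] == x$start[i]
      bp_j <- x$end[j] == x$start[j]
      if (bp_i != bp_j) next
      if (bp_i) {
        adj[i, j] <- abs(x$start[i] - x$start[j]) <= max_dist
      } else {
        ov <- max(0, min(x$end[i], x$end[j]) -
                    max(x$start[i], x$start[j]))
        adj[i, j] <- ov / (x$end[i] - x$start[i]) >= recip_overlap &&
          ov / (x$end[j] - x$start[j]) >= recip_overlap
      }
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    frontier <- s
    while (length(frontier)) {
      comp[frontier] <- cid
      nxt <- unique(unlist(lapply(frontier, function(i)
        which(adj[i, ] & is.na(comp)))))
      frontier <- nxt
    }
  }
  comp
}

brute_genes_in_regions <- function(regions, genes) {
  lapply(seq_len(nrow(regions)), function(i) {
    hits <- character()
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] == regions$chrom[i] &&
          genes$start[j] < regions$end[i] &&
          regions$start[i] < genes$end[j])
        hits <- c(hits, genes$gene_id[j])
    }
    sort(unique(hits))
  })
}

brute_gwas_overlap_bp <- function(regions, gwas, flank) {
  # overlap of each gwas interval with the (merged) flank-extended
  # region union, by per-base scanning logic expressed via pmin/pmax
  # over all pairs then de-double-counting through interval union
  vapply(seq_len(nrow(gwas)), function(i) {
    segs <- list()
    for (j in seq_len(nrow(regions))) {
      if (regions$chrom[j] != gwas$chrom[i]) next
      s <- max(gwas$start[i], max(0, regions$start[j] - flank))
      e <- min(gwas$end[i], regions$end[j] + flank)
      if (e > s) segs[[length(segs) + 1L]] <- c(s, e)
    }
    if (!length(segs)) return(0)
    segs <- segs[order(vapply(segs, `[`, numeric(1), 1))]
    tot <- 0; cur <- segs[[1]]
    for (sg in segs[-1]) {
      if (sg[1] <= cur[2]) cur[2] <- max(cur[2], sg[2])
      else { tot <- tot + cur[2] - cur[1]; cur <- sg }
    }
    tot + cur[2] - cur[1]
  }, numeric(1))
}

# context by exhaustive per-gene checks
brute_context <- function(svs, genes, upstream = 1000L) {
  vapply(seq_len(nrow(svs)), function(i) {
    s <- svs$start[i]; e <- svs$end[i]; ch <- svs$chrom[i]
    hit <- function(ws, we) {
      if (e > s) s < we && ws < e else ws < s && s < we
    }
    genic <- FALSE; five <- FALSE
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != ch) next
      if (hit(genes$start[j], genes$end[j])) genic <- TRUE
      if (!is.na(genes$cds_start[j])) {
        if (genes$strand[j] == "+") {
          ws <- genes$cds_start[j] - upstream; we <- genes$cds_start[j]
        } else {
          ws <- genes$cds_start[j] + 1L
          we <- genes$cds_start[j] + 1L + upstream
        }
        if (hit(max(0, ws), we)) five <- TRUE
      }
    }
    if (genic) "genic" else if (five) "five_prime" else "intergenic"
  }, character(1))
}

# two-sided Fisher p by explicit hypergeometric enumeration
fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x)
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1), numeric(1))
  obs <- choose(c1, tab[1, 1]) * choose(n - c1, r1 - tab[1, 1]) /
    choose(n, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

random_intervals <- function(n, chroms = c("chr01", "chr02"),
                             L = 1e6, max_len = 5000L) {
  s <- sample.int(L - max_len, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = s, end = s + len,
             size = len, id = sprintf("iv%04d", seq_len(n)),
             stringsAsFactors = FALSE)
}
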