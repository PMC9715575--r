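# Dual-caller consensus harmonization: parse both caller dialects in
# both alignment directions, project reciprocal calls onto the pivot
# frame, and classify consensus PAV / CNV / small-indel / INV / SNP
# calls per accession.

#' Matching parameters for call comparison
#'
#' "Common calls" between two record sets are defined here: interval-type
#' calls match at `min_reciprocal_overlap` reciprocal overlap;
#' breakpoint-type calls (insertions, zero-width reference intervals)
#' match within `max_breakpoint_dist` bp when their size ratio
#' (min/max) is at least `min_size_ratio`.
#'
#' @param min_reciprocal_overlap fraction in (0, 1].
#' @param max_breakpoint_dist bp.
#' @param min_size_ratio fraction in (0, 1].
#' @param pav_min_size minimum PAV size in bp (the 5-49 bp bin below it
#'   is the small-indel class).
#' @param small_indel_range inclusive bp range of the small-indel class.
#' @param inv_min_size minimum inversion size in bp.
#' @return list of class `"match_params"`.
#' @export
match_params <- function(min_reciprocal_overlap = 0.5,
                         max_breakpoint_dist = 100L,
                         min_size_ratio = 0.5,
                         pav_min_size = 50L,
                         small_indel_range = c(5L, 49L),
                         inv_min_size = 1000L) {
  stopifnot(min_reciprocal_overlap > 0, min_reciprocal_overlap <= 1,
            max_breakpoint_dist >= 0, min_size_ratio > 0,
            min_size_ratio <= 1)
  structure(list(min_reciprocal_overlap = min_reciprocal_overlap,
                 max_breakpoint_dist = as.integer(max_breakpoint_dist),
                 min_size_ratio = min_size_ratio,
                 pav_min_size = as.integer(pav_min_size),
                 small_indel_range = as.integer(small_indel_range),
                 inv_min_size = as.integer(inv_min_size)),
            class = "match_params")
}

#' Project reciprocal-direction caller records onto the pivot frame
#'
#' Swaps the reference and query intervals and exchanges
#' direction-dependent labels (Deletion/Insertion, DEL/INS,
#' expansion/contraction, CPL/DUPAL), so that records from the
#' accession-as-reference alignment can be compared with pairwise
#' records on pivot coordinates. Applying the operation twice is the
#' identity.
#'
#' @param records caller-record data.frame carrying both frames.
#' @return caller-record data.frame in the pivot frame; `direction` is
#'   retained as provenance.
#' @export
reciprocalize <- function(records) {
  if (nrow(records) == 0L) return(records)
  if (any(is.na(records$query_start) | is.na(records$query_end) |
          is.na(records$query_chrom)))
    stop("records lacking query coordinates cannot be reciprocalized")
  out <- records
  out$ref_chrom <- records$query_chrom
  out$ref_start <- records$query_start
  out$ref_end <- records$query_end
  out$query_chrom <- records$ref_chrom
  out$query_start <- records$ref_start
  out$query_end <- records$ref_end
  out$annotation <- flip_annotation(records$annotation)
  out
}

norm_iv <- function(x) {
  if ("ref_chrom" %in% names(x)) {
    data.frame(chrom = x$ref_chrom, start = x$ref_start, end = x$ref_end,
               size = x$size, id = x$id, stringsAsFactors = FALSE)
  } else {
    id <- x$id %||% x$source_ids %||% as.character(seq_len(nrow(x)))
    data.frame(chrom = x$chrom, start = x$start, end = x$end,
               size = x$size, id = id, stringsAsFactors = FALSE)
  }
}

#' Match two call sets on the pivot frame
#'
#' One-to-one greedy matching of calls in `a` against calls in `b`.
#' Interval calls pair when on the same chromosome with reciprocal
#' overlap at least `params$min_reciprocal_overlap`; breakpoint calls
#' (zero-width intervals, i.e. insertions) pair when their breakpoints
#' are within `params$max_breakpoint_dist` bp and their size ratio
#' (min/max) is at least `params$min_size_ratio`. Pairs are accepted
#' greedily by decreasing score (reciprocal overlap, or
#' `1 - dist/(max_dist + 1)` for breakpoints), with ties broken by
#' smaller `a` start then smaller `a` id, then `b` start and id.
#'
#' @param a,b caller-record or SV-call data.frames (columns `chrom`,
#'   `start`, `end`, `size`, `id`, or the `ref_`-prefixed equivalents).
#' @param params a [match_params()] object.
#' @return data.frame with `a_idx`, `b_idx` (row indices into `a`, `b`)
#'   and `score`.
#' @export
match_calls <- function(a, b, params = match_params()) {
  A <- norm_iv(a); B <- norm_iv(b)
  if (nrow(A) == 0L || nrow(B) == 0L)
    return(data.frame(a_idx = integer(), b_idx = integer(),
                      score = numeric()))
  pairs <- list()
  a_bp <- A$end == A$start
  b_bp <- B$end == B$start
  # interval-vs-interval candidates via overlap query
  ai <- which(!a_bp); bi <- which(!b_bp)
  if (length(ai) && length(bi)) {
    lv <- unique(c(A$chrom[ai], B$chrom[bi]))
    gra <- as_granges0(A$chrom[ai], A$start[ai], A$end[ai], lv)
    grb <- as_granges0(B$chrom[bi], B$start[bi], B$end[bi], lv)
    hits <- GenomicRanges::findOverlaps(gra, grb)
    if (length(hits)) {
      i <- ai[S4Vectors::queryHits(hits)]
      j <- bi[S4Vectors::subjectHits(hits)]
      ro <- reciprocal_overlap(A$start[i], A$end[i], B$start[j], B$end[j])
      keep <- ro >= params$min_reciprocal_overlap
      if (any(keep))
        pairs$iv <- data.frame(a_idx = i[keep], b_idx = j[keep],
                               score = ro[keep])
    }
  }
  # breakpoint-vs-breakpoint candidates via padded overlap query
  ai <- which(a_bp); bi <- which(b_bp)
  if (length(ai) && length(bi)) {
    pad <- params$max_breakpoint_dist
    lv <- unique(c(A$chrom[ai], B$chrom[bi]))
    gra <- as_granges0(A$chrom[ai], pmax(0L, A$start[ai] - pad),
                       A$start[ai] + pad + 1L, lv)
    grb <- as_granges0(B$chrom[bi], B$start[bi], B$start[bi] + 1L, lv)
    hits <- GenomicRanges::findOverlaps(gra, grb)
    if (length(hits)) {
      i <- ai[S4Vectors::queryHits(hits)]
      j <- bi[S4Vectors::subjectHits(hits)]
      d <- abs(A$start[i] - B$start[j])
      sr <- pmin(A$size[i], B$size[j]) / pmax(A$size[i], B$size[j], 1)
      keep <- d <= pad & sr >= params$min_size_ratio
      if (any(keep))
        pairs$bp <- data.frame(a_idx = i[keep], b_idx = j[keep],
                               score = 1 - d[keep] / (pad + 1))
    }
  }
  cand <- do.call(rbind, pairs)
  if (is.null(cand) || nrow(cand) == 0L)
    return(data.frame(a_idx = integer(), b_idx = integer(),
                      score = numeric()))
  o <- order(-cand$score, A$start[cand$a_idx], A$id[cand$a_idx],
             B$start[cand$b_idx], B$id[cand$b_idx])
  cand <- cand[o, , drop = FALSE]
  used_a <- logical(nrow(A)); used_b <- logical(nrow(B))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$a_idx[k]; j <- cand$b_idx[k]
    if (!used_a[i] && !used_b[j]) {
      keep[k] <- TRUE; used_a[i] <- TRUE; used_b[j] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

support_str <- function(records) {
  paste(sort(unique(paste(records$caller, records$direction, sep = ":"))),
        collapse = ",")
}

# Merge a caller's pairwise and (already reciprocalized) reciprocal
# candidate sets into one pivot-frame set with per-record support.
# require_both = TRUE keeps only records seen in both directions.
merge_directions <- function(fwd, recip, params, require_both = FALSE) {
  empty <- cbind(empty_records(),
                 data.frame(support = character(),
                            source_ids = character(),
                            stringsAsFactors = FALSE))
  decorate <- function(x) {
    x$support <- paste(x$caller, x$direction, sep = ":")
    x$source_ids <- x$id
    x
  }
  fwd <- decorate(fwd); recip <- decorate(recip)
  if (nrow(fwd) == 0L && nrow(recip) == 0L) return(empty)
  m <- match_calls(fwd, recip, params)
  if (nrow(m)) {
    fwd$support[m$a_idx] <- paste(fwd$support[m$a_idx],
                                  recip$support[m$b_idx], sep = ",")
    fwd$source_ids[m$a_idx] <- paste(fwd$source_ids[m$a_idx],
                                     recip$source_ids[m$b_idx], sep = ",")
  }
  if (require_both) {
    out <- fwd[unique(m$a_idx), , drop = FALSE]
  } else {
    out <- rbind(fwd, recip[setdiff(seq_len(nrow(recip)), m$b_idx), ,
                            drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

pivot_class <- function(annotation) {
  ifelse(annotation %in% c("Insertion", "INS"), "INS", "DEL")
}

# Shared two-caller consensus for indel-type classes (PAV and small
# indel differ only in the size filter).
consensus_indel <- function(assem_fwd, assem_recip, syri_fwd, syri_recip,
                            params, size_min, size_max, class_prefix,
                            accession, exclude_ids = character()) {
  filt <- function(x, anns) {
    x <- x[x$annotation %in% anns & x$size >= size_min &
             x$size <= size_max & !(x$id %in% exclude_ids), ,
           drop = FALSE]
    rownames(x) <- NULL
    x
  }
  a_fwd <- filt(assem_fwd, c("Insertion", "Deletion"))
  a_rec <- filt(assem_recip, c("Insertion", "Deletion"))
  s_fwd <- filt(syri_fwd, c("INS", "DEL", "HDR"))
  s_rec <- filt(syri_recip, c("INS", "DEL", "HDR"))
  a_cand <- merge_directions(a_fwd, a_rec, params)
  s_cand <- merge_directions(s_fwd, s_rec, params)
  m <- match_calls(a_cand, s_cand, params)
  if (nrow(m) == 0L) return(empty_calls())
  am <- a_cand[m$a_idx, , drop = FALSE]
  sm <- s_cand[m$b_idx, , drop = FALSE]
  cls <- pivot_class(am$annotation)
  out <- data.frame(
    accession = accession,
    sv_class = if (class_prefix == "PAV") paste0("PAV_", cls)
               else "SMALL_INDEL",
    chrom = am$ref_chrom, start = am$ref_start, end = am$ref_end,
    size = am$size,
    support = vapply(seq_len(nrow(am)), function(i)
      paste(sort(unique(unlist(strsplit(
        paste(am$support[i], sm$support[i], sep = ","), ",")))),
        collapse = ","), character(1)),
    source_ids = paste(am$source_ids, sm$source_ids, sep = ","),
    payload = "", stringsAsFactors = FALSE)
  dedupe_calls(out, params)
}

# Keep one call per cluster of mutually matching calls of the same
# class: largest support, then largest size, then smallest start.
dedupe_calls <- function(calls, params) {
  if (nrow(calls) <= 1L) return(sort_genomic(calls))
  out <- list()
  for (cl in unique(calls$sv_class)) {
    x <- calls[calls$sv_class == cl, , drop = FALSE]
    comp <- cluster_calls(x, params)
    nsup <- vapply(strsplit(x$support, ","), length, integer(1))
    for (g in split(seq_len(nrow(x)), comp)) {
      best <- g[order(-nsup[g], -x$size[g], x$start[g])][1]
      out[[length(out) + 1L]] <- x[best, , drop = FALSE]
    }
  }
  sort_genomic(do.call(rbind, out))
}

# Single-linkage components under the match criterion (union-find).
cluster_calls <- function(x, params, recip_overlap = NULL) {
  n <- nrow(x)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  p <- params
  if (!is.null(recip_overlap)) p$min_reciprocal_overlap <- recip_overlap
  bp <- x$end == x$start
  iv <- which(!bp)
  if (length(iv) > 1L) {
    gr <- as_granges0(x$chrom[iv], x$start[iv], x$end[iv])
    hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                        drop.redundant = TRUE)
    for (k in seq_len(length(hits))) {
      i <- iv[S4Vectors::queryHits(hits)[k]]
      j <- iv[S4Vectors::subjectHits(hits)[k]]
      ro <- reciprocal_overlap(x$start[i], x$end[i], x$start[j], x$end[j])
      if (ro >= p$min_reciprocal_overlap) union_(i, j)
    }
  }
  bpi <- which(bp)
  if (length(bpi) > 1L) {
    pad <- p$max_breakpoint_dist
    gr <- as_granges0(x$chrom[bpi], pmax(0L, x$start[bpi] - pad),
                      x$start[bpi] + pad + 1L)
    hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                        drop.redundant = TRUE)
    for (k in seq_len(length(hits))) {
      i <- bpi[S4Vectors::queryHits(hits)[k]]
      j <- bpi[S4Vectors::subjectHits(hits)[k]]
      if (abs(x$start[i] - x$start[j]) <= pad) union_(i, j)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Consensus presence-absence variants from both callers
#'
#' Per caller, the candidate set is the union of its pairwise and
#' reciprocalized records annotated Insertion/Deletion (Assemblytics
#' dialect) or INS/DEL/HDR (SyRI dialect) with size at least
#' `params$pav_min_size`; records seen in both directions collapse into
#' one candidate carrying both supports. Only candidates matched across
#' the two callers are emitted; coordinates come from the Assemblytics
#' member and the class (`PAV_DEL` / `PAV_INS`) from its pivot-frame
#' label.
#'
#' @param assem_fwd,assem_recip,syri_fwd,syri_recip caller-record
#'   data.frames, all already on the pivot frame (reciprocal inputs
#'   passed through [reciprocalize()]).
#' @param params [match_params()].
#' @param accession accession name stamped on the calls.
#' @param exclude_ids source record ids to ignore (used by the pipeline
#'   to keep the emitted classes disjoint).
#' @return SV-call data.frame (classes `PAV_DEL`, `PAV_INS`).
#' @export
consensus_pav <- function(assem_fwd, assem_recip, syri_fwd, syri_recip,
                          params = match_params(), accession = "query",
                          exclude_ids = character()) {
  consensus_indel(assem_fwd, assem_recip, syri_fwd, syri_recip, params,
                  params$pav_min_size, .Machine$integer.max, "PAV",
                  accession, exclude_ids)
}

#' Consensus small indels (5-49 bp) from both callers
#'
#' Identical logic to [consensus_pav()] with the size filter restricted
#' to `params$small_indel_range` (default 5-49 bp).
#'
#' @inheritParams consensus_pav
#' @return SV-call data.frame (class `SMALL_INDEL`).
#' @export
extract_small_indels <- function(assem_fwd, assem_recip, syri_fwd,
                                 syri_recip, params = match_params(),
                                 accession = "query",
                                 exclude_ids = character()) {
  consensus_indel(assem_fwd, assem_recip, syri_fwd, syri_recip, params,
                  params$small_indel_range[1], params$small_indel_range[2],
                  "SMALL_INDEL", accession, exclude_ids)
}

#' Consensus copy-number variants from both callers
#'
#' Assemblytics CNV candidates are records annotated Deletion or
#' Tandem_contraction present in both the pairwise and reciprocalized
#' alignment directions; SyRI CNV candidates are records annotated
#' DUPAL, HDR or CPL present in both directions. Cross-caller matches of
#' the two candidate sets are emitted as CNVs with coordinates from the
#' Assemblytics member.
#'
#' @inheritParams consensus_pav
#' @return SV-call data.frame (class `CNV`).
#' @export
consensus_cnv <- function(assem_fwd, assem_recip, syri_fwd, syri_recip,
                          params = match_params(), accession = "query",
                          exclude_ids = character()) {
  filt <- function(x, anns) {
    x <- x[x$annotation %in% anns & !(x$id %in% exclude_ids), ,
           drop = FALSE]
    rownames(x) <- NULL
    x
  }
  a_fwd <- filt(assem_fwd, c("Deletion", "Tandem_contraction"))
  a_rec <- filt(assem_recip, c("Deletion", "Tandem_contraction"))
  s_fwd <- filt(syri_fwd, c("DUPAL", "HDR", "CPL"))
  s_rec <- filt(syri_recip, c("DUPAL", "HDR", "CPL"))
  a_cand <- merge_directions(a_fwd, a_rec, params, require_both = TRUE)
  s_cand <- merge_directions(s_fwd, s_rec, params, require_both = TRUE)
  m <- match_calls(a_cand, s_cand, params)
  if (nrow(m) == 0L) return(empty_calls())
  am <- a_cand[m$a_idx, , drop = FALSE]
  sm <- s_cand[m$b_idx, , drop = FALSE]
  out <- data.frame(
    accession = accession, sv_class = "CNV",
    chrom = am$ref_chrom, start = am$ref_start, end = am$ref_end,
    size = am$size,
    support = vapply(seq_len(nrow(am)), function(i)
      paste(sort(unique(unlist(strsplit(
        paste(am$support[i], sm$support[i], sep = ","), ",")))),
        collapse = ","), character(1)),
    source_ids = paste(am$source_ids, sm$source_ids, sep = ","),
    payload = "", stringsAsFactors = FALSE)
  dedupe_calls(out, params)
}

#' Inversions and SNPs from the SyRI pairwise calls
#'
#' INVAL records with span at least `params$inv_min_size` (default 1 kb)
#' become `INV` calls; smaller INVAL records are dropped and counted in
#' the `"dropped_inval"` attribute. SNP records become `SNP` calls.
#' Single-caller support is accepted for both classes.
#'
#' @param syri_fwd pivot-frame SyRI pairwise records.
#' @param params [match_params()].
#' @param accession accession name stamped on the calls.
#' @return SV-call data.frame with attribute `dropped_inval`.
#' @export
extract_inv_snp <- function(syri_fwd, params = match_params(),
                            accession = "query") {
  inval <- syri_fwd[syri_fwd$annotation == "INVAL", , drop = FALSE]
  span <- inval$ref_end - inval$ref_start
  dropped <- sum(span < params$inv_min_size)
  inval <- inval[span >= params$inv_min_size, , drop = FALSE]
  snp <- syri_fwd[syri_fwd$annotation == "SNP", , drop = FALSE]
  mk <- function(x, cls) {
    if (nrow(x) == 0L) return(empty_calls())
    data.frame(accession = accession, sv_class = cls,
               chrom = x$ref_chrom, start = x$ref_start, end = x$ref_end,
               size = x$ref_end - x$ref_start,
               support = paste(x$caller, x$direction, sep = ":"),
               source_ids = x$id, payload = "", stringsAsFactors = FALSE)
  }
  out <- sort_genomic(rbind(mk(inval, "INV"), mk(snp, "SNP")))
  rownames(out) <- NULL
  attr(out, "dropped_inval") <- dropped
  out
}

#' Harmonize one accession's four caller files into classified SV calls
#'
#' Runs the full per-accession classification: reciprocalizes the
#' reciprocal-direction records, then extracts consensus PAVs, small
#' indels, CNVs, and SyRI inversions/SNPs. Source records consumed by an
#' earlier class are excluded from later classes, so no input record
#' contributes to more than one emitted class.
#'
#' @param assem_fwd,assem_recip,syri_fwd,syri_recip caller-record
#'   data.frames as parsed from the four input files (reciprocal inputs
#'   still in their native accession-reference frame), or file paths.
#' @param params [match_params()].
#' @param accession accession name.
#' @return SV-call data.frame covering all classes, sorted by position.
#' @export
harmonize_accession <- function(assem_fwd, assem_recip, syri_fwd,
                                syri_recip, params = match_params(),
                                accession = "query") {
  if (is.character(assem_fwd))
    assem_fwd <- parse_assemblytics(assem_fwd, direction = "pairwise")
  if (is.character(assem_recip))
    assem_recip <- parse_assemblytics(assem_recip,
                                      direction = "reciprocal")
  if (is.character(syri_fwd))
    syri_fwd <- parse_syri(syri_fwd, direction = "pairwise")
  if (is.character(syri_recip))
    syri_recip <- parse_syri(syri_recip, direction = "reciprocal")
  assem_rp <- reciprocalize(assem_recip)
  syri_rp <- reciprocalize(syri_recip)
  used <- character()
  pav <- consensus_pav(assem_fwd, assem_rp, syri_fwd, syri_rp, params,
                       accession)
  used <- c(used, unlist(strsplit(pav$source_ids, ",")))
  si <- extract_small_indels(assem_fwd, assem_rp, syri_fwd, syri_rp,
                             params, accession, exclude_ids = used)
  used <- c(used, unlist(strsplit(si$source_ids, ",")))
  cnv <- consensus_cnv(assem_fwd, assem_rp, syri_fwd, syri_rp, params,
                       accession, exclude_ids = used)
  invsnp <- extract_inv_snp(syri_fwd, params, accession)
  out <- sort_genomic(rbind(pav, si, cnv, invsnp))
  rownames(out) <- NULL
  out
}
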