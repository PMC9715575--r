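# Sliding-window PAV density, hotspot and differential regions, GWAS
# overlap, and TE association.

#' Sliding-window grid over the pivot chromosomes
#'
#' Default geometry is a 1-Mb window advanced in 200-kb steps, so every
#' interior base lies in exactly `window_size / step` (5) windows.
#' Terminal windows shorter than `window_size` are kept and flagged.
#'
#' @param chrom_lengths named integer vector.
#' @param window_size window width in bp.
#' @param step increment in bp; must not exceed `window_size`.
#' @return list of class `"window_grid"`: `window_size`, `step`,
#'   `chrom_lengths`, `windows` (data.frame `chrom`, `start`, `end`,
#'   `terminal`).
#' @export
window_grid <- function(chrom_lengths, window_size = 1e6, step = 2e5) {
  if (any(chrom_lengths <= 0)) stop("zero-length chromosome in grid")
  if (step > window_size) stop("step must be <= window_size")
  window_size <- as.integer(window_size); step <- as.integer(step)
  rows <- lapply(names(chrom_lengths), function(ch) {
    L <- as.integer(chrom_lengths[[ch]])
    starts <- seq.int(0L, max(0L, L - 1L), by = step)
    starts <- starts[starts < L]
    ends <- pmin(starts + window_size, L)
    data.frame(chrom = ch, start = starts, end = ends,
               terminal = ends - starts < window_size,
               stringsAsFactors = FALSE)
  })
  structure(list(window_size = window_size, step = step,
                 chrom_lengths = chrom_lengths,
                 windows = do.call(rbind, rows)),
            class = "window_grid")
}

#' Per-window variant counts
#'
#' Under the default `midpoint` rule a variant is counted in every
#' window containing its interval midpoint (the breakpoint for
#' zero-width insertions), so each variant contributes identical track
#' mass regardless of size. The `overlap` rule counts a variant in
#' every window its interval overlaps.
#'
#' @param calls SV-call data.frame on pivot coordinates.
#' @param grid a [window_grid()].
#' @param assignment `"midpoint"` or `"overlap"`.
#' @param by `NULL` for one pooled count column, or `"accession"` for
#'   one column per accession.
#' @param accessions column set for `by = "accession"`; defaults to the
#'   accessions present in `calls` (pass the full cohort to keep
#'   zero-call accessions as all-zero columns).
#' @return list of class `"density_track"`: `grid`, `values` (matrix
#'   windows x columns), `label`.
#' @export
window_counts <- function(calls, grid,
                          assignment = c("midpoint", "overlap"),
                          by = NULL, accessions = NULL) {
  assignment <- match.arg(assignment)
  stopifnot(inherits(grid, "window_grid"))
  w <- grid$windows
  cols <- if (is.null(by)) "count" else
    accessions %||% sort(unique(calls$accession))
  values <- matrix(0L, nrow(w), length(cols),
                   dimnames = list(NULL, cols))
  if (nrow(calls)) {
    if (assignment == "midpoint") {
      pos <- ifelse(calls$end > calls$start,
                    (calls$start + calls$end) %/% 2L, calls$start)
      grc <- as_granges0(calls$chrom, pos, pos + 1L,
                         unique(c(w$chrom, calls$chrom)))
    } else {
      s <- calls$start
      e <- pmax(calls$end, calls$start + 1L)  # insertions as 1 bp
      grc <- as_granges0(calls$chrom, s, e,
                         unique(c(w$chrom, calls$chrom)))
    }
    grw2 <- as_granges0(w$chrom, w$start, w$end,
                        unique(c(w$chrom, calls$chrom)))
    hits <- GenomicRanges::findOverlaps(grc, grw2)
    wi <- S4Vectors::subjectHits(hits)
    ci <- S4Vectors::queryHits(hits)
    col <- if (is.null(by)) rep(1L, length(ci)) else
      match(calls$accession[ci], cols)
    for (k in seq_along(wi))
      values[wi[k], col[k]] <- values[wi[k], col[k]] + 1L
  }
  structure(list(grid = grid, values = values,
                 label = if (is.null(by)) "count" else "count_by_accession"),
            class = "density_track")
}

track_vector <- function(track, column = NULL) {
  v <- track$values
  if (!is.null(column)) return(v[, column])
  if (ncol(v) == 1L) v[, 1] else rowSums(v)
}

region_set <- function(df, provenance) {
  out <- merge_intervals(df)
  attr(out, "provenance") <- provenance
  out
}

#' PAV hotspot regions (top-quantile windows, merged)
#'
#' Windows whose count reaches the genome-wide empirical upper quantile
#' (ties included, i.e. `>=` the type-1 quantile) are selected and
#' overlapping/adjacent selected windows are merged into maximal
#' regions. The quantile is taken over all windows jointly, not per
#' chromosome.
#'
#' @param track a `"density_track"`; multi-column tracks are summed.
#' @param quantile selection quantile (default 0.99, the top 1%).
#' @param column optional track column to use.
#' @return merged region data.frame (`chrom`, `start`, `end`) with a
#'   `provenance` attribute.
#' @export
hotspots <- function(track, quantile = 0.99, column = NULL) {
  v <- track_vector(track, column)
  if (any(!is.finite(v))) stop("track values must be finite")
  if (length(v) < 100 && quantile >= 0.99)
    warning("fewer than 100 windows: the ", quantile,
            " quantile threshold is degenerate")
  thr <- stats::quantile(v, probs = quantile, type = 1, names = FALSE)
  sel <- track$grid$windows[v >= thr, c("chrom", "start", "end"),
                            drop = FALSE]
  region_set(sel, sprintf("hotspots(quantile=%g, threshold=%g)",
                          quantile, thr))
}

#' Group-differential PAV frequency track
#'
#' Per window, the gap between the two group means of per-accession
#' PAV counts: `mean(groupA) - mean(groupB)` (signed), plus its
#' absolute value.
#'
#' @param track per-accession `"density_track"` (from
#'   `window_counts(..., by = "accession")`).
#' @param groupA,groupB non-empty accession name vectors.
#' @return `"density_track"` with columns `signed` and `abs`.
#' @export
group_differential <- function(track, groupA, groupB) {
  if (length(groupA) == 0L || length(groupB) == 0L)
    stop("both groups must be non-empty")
  miss <- setdiff(c(groupA, groupB), colnames(track$values))
  if (length(miss))
    stop("accessions missing from track: ", paste(miss, collapse = ", "))
  a <- rowMeans(track$values[, groupA, drop = FALSE])
  b <- rowMeans(track$values[, groupB, drop = FALSE])
  structure(list(grid = track$grid,
                 values = cbind(signed = a - b, abs = abs(a - b)),
                 label = "group_differential"),
            class = "density_track")
}

#' Top-fraction regions of a track
#'
#' Same selection and merge semantics as [hotspots()], parameterized by
#' the selected fraction; applied to the absolute differential by
#' default (`signed = TRUE` selects on the signed score).
#'
#' @param track `"density_track"`; for differential tracks the `abs`
#'   (default) or `signed` column is used.
#' @param fraction selected fraction of windows (default 0.05, the top
#'   5%).
#' @param signed use the signed score of a differential track.
#' @return merged region data.frame with `provenance` attribute.
#' @export
top_fraction_regions <- function(track, fraction = 0.05,
                                 signed = FALSE) {
  column <- if ("abs" %in% colnames(track$values)) {
    if (signed) "signed" else "abs"
  } else NULL
  v <- track_vector(track, column)
  if (any(!is.finite(v))) stop("track values must be finite")
  thr <- stats::quantile(v, probs = 1 - fraction, type = 1,
                         names = FALSE)
  sel <- track$grid$windows[v >= thr, c("chrom", "start", "end"),
                            drop = FALSE]
  region_set(sel, sprintf("top_fraction(fraction=%g, threshold=%g)",
                          fraction, thr))
}

#' Overlap of GWAS intervals with flank-extended regions
#'
#' Each GWAS interval is labelled `contained` (fully inside the
#' flank-extended region union), `overlapping` (partial) or `disjoint`.
#'
#' @param regions region data.frame (e.g. from
#'   [top_fraction_regions()]).
#' @param gwas data.frame of GWAS intervals (`chrom`, `start`, `end`).
#' @param flank symmetric extension of the regions in bp (default 1
#'   Mb).
#' @return list: `intervals` (gwas rows + `overlap_bp`, `label`),
#'   `jaccard` (bp Jaccard index between the extended region union and
#'   the GWAS union), `total_overlap_bp`.
#' @export
gwas_overlap <- function(regions, gwas, flank = 1e6) {
  ext <- if (nrow(regions)) merge_intervals(data.frame(
    chrom = regions$chrom, start = pmax(0L, regions$start - as.integer(flank)),
    end = regions$end + as.integer(flank), stringsAsFactors = FALSE))
  else regions
  ov_bp <- integer(nrow(gwas))
  if (nrow(gwas) && nrow(ext)) {
    for (i in seq_len(nrow(gwas))) {
      e <- ext[ext$chrom == gwas$chrom[i], , drop = FALSE]
      if (nrow(e))
        ov_bp[i] <- sum(pmax(0L, pmin(e$end, gwas$end[i]) -
                               pmax(e$start, gwas$start[i])))
    }
  }
  width <- gwas$end - gwas$start
  label <- ifelse(ov_bp == 0L, "disjoint",
                  ifelse(ov_bp >= width, "contained", "overlapping"))
  inter <- sum(ov_bp)
  union_bp <- sum(ext$end - ext$start) +
    sum(merge_intervals(gwas)$end - merge_intervals(gwas)$start) - inter
  list(intervals = cbind(gwas, overlap_bp = ov_bp, label = label),
       jaccard = if (union_bp > 0) inter / union_bp else NA_real_,
       total_overlap_bp = inter)
}

#' Transposable-element association of PAV density
#'
#' Per window: pooled PAV count, total TE bp fraction and per-class TE
#' fractions; Spearman rank correlation between PAV count and total TE
#' fraction over all windows and, when `regions` is supplied,
#' restricted to windows overlapping those regions. Repeat intervals
#' extending past a chromosome end are clipped with a warning.
#'
#' @param pav_track pooled `"density_track"`.
#' @param repeats repeat data.frame (`chrom`, `start`, `end`, `class`).
#' @param classes repeat classes to tabulate separately.
#' @param regions optional region data.frame for the restricted
#'   correlation.
#' @return list: `table` (per-window data.frame), `cor_overall`,
#'   `cor_regions` (NA when `regions` is NULL), `degenerate` (TRUE when
#'   a correlation is undefined, e.g. zero TE coverage).
#' @export
te_pav_association <- function(pav_track, repeats,
                               classes = c("LTR", "DNA"),
                               regions = NULL) {
  grid <- pav_track$grid
  w <- grid$windows
  lens <- grid$chrom_lengths[repeats$chrom]
  if (any(repeats$end > lens | repeats$start < 0)) {
    warning("repeat interval(s) off chromosome; clipped")
    repeats$start <- pmax(0L, repeats$start)
    repeats$end <- pmin(repeats$end, as.integer(lens))
    repeats <- repeats[repeats$end > repeats$start, , drop = FALSE]
  }
  count <- track_vector(pav_track)
  frac_for <- function(rep_df) {
    out <- numeric(nrow(w))
    if (!nrow(rep_df)) return(out)
    lv <- unique(c(w$chrom, rep_df$chrom))
    grw <- as_granges0(w$chrom, w$start, w$end, lv)
    grr <- as_granges0(rep_df$chrom, rep_df$start, rep_df$end, lv)
    hits <- GenomicRanges::findOverlaps(grw, grr)
    if (length(hits)) {
      wi <- S4Vectors::queryHits(hits); ri <- S4Vectors::subjectHits(hits)
      ov <- pmin(w$end[wi], rep_df$end[ri]) -
        pmax(w$start[wi], rep_df$start[ri])
      agg <- tapply(ov, wi, sum)
      out[as.integer(names(agg))] <- as.numeric(agg)
    }
    out / (w$end - w$start)
  }
  tab <- data.frame(w[, c("chrom", "start", "end")], pav_count = count,
                    te_frac = frac_for(repeats),
                    stringsAsFactors = FALSE)
  for (cl in classes)
    tab[[paste0("te_frac_", cl)]] <-
      frac_for(repeats[repeats$class == cl, , drop = FALSE])
  degenerate <- sd(tab$te_frac) == 0 || sd(count) == 0
  cor_overall <- if (degenerate) NA_real_ else
    cor(count, tab$te_frac, method = "spearman")
  cor_regions <- NA_real_
  if (!is.null(regions) && nrow(regions)) {
    lv <- unique(c(w$chrom, regions$chrom))
    grw <- as_granges0(w$chrom, w$start, w$end, lv)
    grr <- as_granges0(regions$chrom, regions$start, regions$end, lv)
    inr <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(grw, grr)))
    if (length(inr) >= 3 && sd(tab$te_frac[inr]) > 0 &&
        sd(count[inr]) > 0)
      cor_regions <- cor(count[inr], tab$te_frac[inr],
                         method = "spearman")
  }
  list(table = tab, cor_overall = cor_overall,
       cor_regions = cor_regions, degenerate = degenerate)
}

#' Write a density track as bedGraph
#' @param track `"density_track"`.
#' @param path output file.
#' @param column column to export (default first).
#' @export
write_bedgraph <- function(track, path, column = 1L) {
  w <- track$grid$windows
  lines <- sprintf("%s\t%d\t%d\t%g", w$chrom, w$start, w$end,
                   track$values[, column])
  writeLines(lines, path)
  invisible(path)
}
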