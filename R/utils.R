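#' @importFrom stats quantile median rnorm rpois rbinom runif setNames
#'   complete.cases cor fisher.test p.adjust phyper sd
#' @importFrom utils read.table write.table head modifyList
NULL

# Internal coordinate convention: 0-based, half-open [start, end).
# 1-based inclusive coordinates appear only at GFF3/VCF/SyRI file boundaries.

#' Convert 0-based half-open intervals to a GRanges object
#'
#' Zero-width intervals (insertion breakpoints) become zero-width ranges.
#'
#' @param chrom,start,end vectors of equal length; `start`/`end` 0-based
#'   half-open.
#' @param levels optional seqlevel universe; supply the union of both
#'   sets before a cross-set overlap query so seqinfo merging is exact.
#' @return A [GenomicRanges::GRanges] with 1-based coordinates.
#' @keywords internal
as_granges0 <- function(chrom, start, end, levels = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = factor(as.character(chrom),
                      levels = levels %||% unique(as.character(chrom))),
    ranges = IRanges::IRanges(start = start + 1L, end = as.integer(end))
  )
  gr
}

#' Natural ordering of chromosome names
#'
#' Orders "chr2" before "chr10" by splitting a trailing integer off the name.
#'
#' @param x character vector of chromosome names.
#' @return integer ranks usable with `order()`.
#' @keywords internal
chrom_rank <- function(x) {
  x <- as.character(x)
  u <- unique(x)
  num <- suppressWarnings(as.integer(sub("^.*?(\\d+)$", "\\1", u)))
  pre <- sub("\\d+$", "", u)
  match(x, u[order(pre, num, u, na.last = TRUE)])
}

#' Sort a genomic table by (chrom, start, end)
#' @param df data.frame with `chrom`, `start`, `end` columns.
#' @keywords internal
sort_genomic <- function(df) {
  if (nrow(df) == 0L) return(df)
  df[order(chrom_rank(df$chrom), df$start, df$end), , drop = FALSE]
}

#' Reciprocal overlap fraction of two interval vectors
#'
#' Returns `min(ov / len_a, ov / len_b)` where `ov` is the overlap length;
#' 0 when either interval has zero length.
#' @keywords internal
reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  w1 <- e1 - s1
  w2 <- e2 - s2
  out <- ifelse(w1 > 0 & w2 > 0, pmin(ov / pmax(w1, 1), ov / pmax(w2, 1)), 0)
  out[w1 == 0 | w2 == 0] <- 0
  out
}

#' Merge overlapping or bookended intervals
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @return merged, sorted, non-overlapping intervals.
#' @keywords internal
merge_intervals <- function(df) {
  if (nrow(df) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  out <- lapply(split(df, df$chrom), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    s <- d$start; e <- d$end
    ms <- s[1]; me <- e[1]
    rs <- integer(); re <- integer()
    if (length(s) > 1L) {
      for (i in 2:length(s)) {
        if (s[i] <= me) {            # overlap or bookended
          me <- max(me, e[i])
        } else {
          rs <- c(rs, ms); re <- c(re, me)
          ms <- s[i]; me <- e[i]
        }
      }
    }
    rs <- c(rs, ms); re <- c(re, me)
    data.frame(chrom = d$chrom[1], start = rs, end = re,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  sort_genomic(out)
}

#' Empty SV call table
#' @keywords internal
empty_calls <- function() {
  data.frame(accession = character(), sv_class = character(),
             chrom = character(), start = integer(), end = integer(),
             size = integer(), support = character(),
             source_ids = character(), payload = character(),
             stringsAsFactors = FALSE)
}

#' Empty caller-record table
#' @keywords internal
empty_records <- function() {
  data.frame(caller = character(), direction = character(),
             ref_chrom = character(), ref_start = integer(),
             ref_end = integer(), query_chrom = character(),
             query_start = integer(), query_end = integer(),
             annotation = character(), size = integer(), id = character(),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
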