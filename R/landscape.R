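# Pan-genome PAV landscape: nonredundant loci across accessions and the
# presence/absence matrix.

#' Convert a planted truth table to pivot-frame SV calls
#'
#' Utility for building truth-derived call sets (payloads retained),
#' e.g. to construct a pan-genome graph whose accession paths can be
#' checked against the simulated sequences.
#'
#' @param truth `"pansv_truth"` object or its truth data.frame.
#' @param classes SV classes to keep.
#' @return SV-call data.frame.
#' @export
truth_to_calls <- function(truth,
                           classes = c("PAV_DEL", "PAV_INS")) {
  tt <- if (inherits(truth, "pansv_truth")) truth$truth else truth
  tt <- tt[tt$sv_class %in% classes, , drop = FALSE]
  out <- data.frame(
    accession = tt$accession, sv_class = tt$sv_class, chrom = tt$chrom,
    start = tt$pivot_start, end = tt$pivot_end,
    size = pmax(tt$pivot_end - tt$pivot_start, tt$alt_length),
    support = "truth:pairwise", source_ids = tt$id,
    payload = tt$payload, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  sort_genomic(out)
}

#' Merge per-accession PAV calls into nonredundant pan-genome loci
#'
#' Single-linkage clustering of PAV calls across accessions, separately
#' per variant type: deletions cluster at `merge_overlap` reciprocal
#' overlap (default 0.8, stricter than the within-accession consensus
#' because all calls share the pivot frame); insertions cluster within
#' `params$max_breakpoint_dist` bp. The locus representative is the
#' member with median size (lower median; ties broken by smaller start),
#' and loci are sorted and numbered by (chrom, start).
#'
#' @param calls SV-call data.frame restricted to classes `PAV_DEL` /
#'   `PAV_INS` (mixed other classes raise an error); typically the
#'   concatenated output of [harmonize_accession()] over accessions.
#' @param params [match_params()].
#' @param merge_overlap reciprocal-overlap threshold for deletion loci.
#' @return list of class `"pav_loci"`: `loci` (data.frame `locus_id`,
#'   `chrom`, `start`, `end`, `sv_type`, `rep_size`, `n_members`,
#'   `payload`) and `members` (data.frame `locus_id`, `accession`,
#'   `chrom`, `start`, `end`, `size`).
#' @export
merge_nonredundant <- function(calls, params = match_params(),
                               merge_overlap = 0.8) {
  if (!all(calls$sv_class %in% c("PAV_DEL", "PAV_INS")))
    stop("merge_nonredundant accepts PAV_DEL/PAV_INS calls only; got: ",
         paste(setdiff(unique(calls$sv_class),
                       c("PAV_DEL", "PAV_INS")), collapse = ", "))
  if (nrow(calls) == 0L) {
    return(structure(list(
      loci = data.frame(locus_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        sv_type = character(), rep_size = integer(),
                        n_members = integer(), payload = character(),
                        stringsAsFactors = FALSE),
      members = data.frame(locus_id = character(),
                           accession = character(), chrom = character(),
                           start = integer(), end = integer(),
                           size = integer(), stringsAsFactors = FALSE)),
      class = "pav_loci"))
  }
  if (is.null(calls$payload)) calls$payload <- ""
  loci_rows <- list()
  member_rows <- list()
  for (tp in c("PAV_DEL", "PAV_INS")) {
    x <- calls[calls$sv_class == tp, , drop = FALSE]
    if (nrow(x) == 0L) next
    rownames(x) <- NULL
    comp <- cluster_calls(x, params, recip_overlap = merge_overlap)
    for (g in split(seq_len(nrow(x)), comp)) {
      if (length(unique(x$accession[g])) < length(g)) {
        # keep at most one member per accession: largest then leftmost
        g <- unlist(lapply(split(g, x$accession[g]), function(gg)
          gg[order(-x$size[gg], x$start[gg])][1]), use.names = FALSE)
      }
      o <- g[order(x$size[g], x$start[g], x$accession[g])]
      rep_i <- o[floor((length(o) + 1) / 2)]
      loci_rows[[length(loci_rows) + 1L]] <- data.frame(
        chrom = x$chrom[rep_i], start = x$start[rep_i],
        end = x$end[rep_i],
        sv_type = if (tp == "PAV_DEL") "DEL" else "INS",
        rep_size = x$size[rep_i], n_members = length(g),
        payload = x$payload[rep_i], .members = I(list(g)),
        stringsAsFactors = FALSE)
      member_rows[[length(member_rows) + 1L]] <- data.frame(
        accession = x$accession[g], chrom = x$chrom[g],
        start = x$start[g], end = x$end[g], size = x$size[g],
        stringsAsFactors = FALSE)
    }
  }
  loci <- do.call(rbind, loci_rows)
  o <- order(chrom_rank(loci$chrom), loci$start, loci$end, loci$sv_type)
  loci <- loci[o, , drop = FALSE]
  loci$locus_id <- sprintf("PAV%05d", seq_len(nrow(loci)))
  members <- do.call(rbind, lapply(seq_along(o), function(k)
    cbind(data.frame(locus_id = loci$locus_id[k],
                     stringsAsFactors = FALSE),
          member_rows[[o[k]]])))
  loci$.members <- NULL
  rownames(loci) <- rownames(members) <- NULL
  structure(list(loci = loci[, c("locus_id", "chrom", "start", "end",
                                 "sv_type", "rep_size", "n_members",
                                 "payload")],
                 members = members),
            class = "pav_loci")
}

#' Build the locus-by-accession presence/absence matrix
#'
#' A locus is `"present"` in an accession that contributed a member
#' call, `"absent"` in a called accession without one, and `"missing"`
#' for accessions with no call set at all.
#'
#' @param loci a `"pav_loci"` object from [merge_nonredundant()].
#' @param accessions ordered accession names (matrix columns).
#' @param called_accessions accessions for which call sets existed;
#'   defaults to all of `accessions`.
#' @return character matrix (loci x accessions) over
#'   \{"present", "absent", "missing"\}.
#' @export
build_pa_matrix <- function(loci, accessions,
                            called_accessions = accessions) {
  stopifnot(inherits(loci, "pav_loci"))
  unknown <- setdiff(unique(loci$members$accession), accessions)
  if (length(unknown))
    stop("member accession(s) not in accession list: ",
         paste(unknown, collapse = ", "))
  m <- matrix("absent", nrow = nrow(loci$loci), ncol = length(accessions),
              dimnames = list(loci$loci$locus_id, accessions))
  m[, setdiff(accessions, called_accessions)] <- "missing"
  if (nrow(loci$members))
    m[cbind(loci$members$locus_id, loci$members$accession)] <- "present"
  m
}

#' Write nonredundant loci as BED
#' @param loci `"pav_loci"` object.
#' @param path output file.
#' @export
write_locus_bed <- function(loci, path) {
  df <- loci$loci
  write_bed(data.frame(chrom = df$chrom, start = df$start, end = df$end,
                       name = sprintf("%s|%s|%d", df$locus_id,
                                      df$sv_type, df$rep_size),
                       score = df$n_members, strand = ".",
                       stringsAsFactors = FALSE), path)
}

#' Write the presence/absence matrix as TSV
#' @param matrix character matrix from [build_pa_matrix()].
#' @param path output file.
#' @export
write_pa_matrix <- function(matrix, path) {
  df <- data.frame(locus_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a presence/absence matrix TSV
#' @param path file written by [write_pa_matrix()].
#' @return character matrix with locus rownames.
#' @export
read_pa_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
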