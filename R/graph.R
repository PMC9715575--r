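# Sequence-graph pan-genome: pivot backbone split at PAV breakpoints,
# alternate allele nodes, and per-accession paths.

#' Construct the graph pan-genome from pivot sequences and PAV loci
#'
#' The pivot backbone of each chromosome is split at every locus
#' breakpoint (deletion start/end, insertion breakpoint). Each deletion
#' locus adds a bypass edge joining the backbone nodes flanking the
#' deleted segment; each insertion locus adds an alternate node holding
#' the inserted sequence between its flanking backbone nodes. The pivot
#' path traverses all backbone nodes; each accession path is derived
#' from the presence/absence matrix (carriers skip deleted nodes and
#' traverse insertion nodes).
#'
#' Nested loci are linearized: when one locus lies inside another, the
#' larger is kept and the smaller dropped (reported in the
#' `dropped_loci` attribute).
#'
#' @param pivot a `"pansv_pivot"` object (or a
#'   [Biostrings::DNAStringSet]).
#' @param loci a `"pav_loci"` object.
#' @param matrix presence/absence matrix from [build_pa_matrix()]; may
#'   be `NULL` to build only the backbone and allele structure.
#' @return list of class `"pansv_graph"`: `nodes` (data.frame
#'   `node_id`, `chrom`, `start`, `end`, `seq`, `type` in
#'   \{"backbone", "alt"\}), `edges` (data.frame `from`, `to`), `paths`
#'   (named list of node-id vectors, one per chromosome for the pivot
#'   plus one per accession-chromosome), and `chroms`.
#' @export
build_graph <- function(pivot, loci, matrix = NULL) {
  seqs <- if (inherits(pivot, "pansv_pivot")) pivot$sequences else pivot
  ldf <- loci$loci
  bad <- !(ldf$chrom %in% names(seqs)) |
    ldf$end > Biostrings::width(seqs)[match(ldf$chrom, names(seqs))]
  if (any(bad))
    stop("locus breakpoint beyond chromosome end: ",
         paste(ldf$locus_id[bad], collapse = ", "))
  dropped <- character()
  # linearize nested/overlapping deletion loci: keep the larger
  keep <- rep(TRUE, nrow(ldf))
  del <- which(ldf$sv_type == "DEL")
  if (length(del) > 1L) {
    gr <- as_granges0(ldf$chrom[del], ldf$start[del], ldf$end[del])
    hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                        drop.redundant = TRUE)
    for (k in seq_along(hits)) {
      i <- del[S4Vectors::queryHits(hits)[k]]
      j <- del[S4Vectors::subjectHits(hits)[k]]
      drop_i <- if (ldf$end[i] - ldf$start[i] >=
                    ldf$end[j] - ldf$start[j]) j else i
      keep[drop_i] <- FALSE
    }
  }
  ins <- which(ldf$sv_type == "INS")
  if (length(ins) && length(del)) {
    for (i in ins) {
      inside <- ldf$chrom[del] == ldf$chrom[i] &
        ldf$start[del] < ldf$start[i] & ldf$end[del] > ldf$start[i] &
        keep[del]
      if (any(inside)) keep[i] <- FALSE
    }
  }
  dropped <- ldf$locus_id[!keep]
  ldf <- ldf[keep, , drop = FALSE]

  nodes <- list(); edges <- list(); paths <- list()
  chroms <- names(seqs)
  node_of_start <- list()  # per chrom: backbone node starting at pos
  for (ch in chroms) {
    L <- Biostrings::width(seqs)[match(ch, names(seqs))]
    lc <- ldf[ldf$chrom == ch, , drop = FALSE]
    bps <- sort(unique(c(0L, L,
                         lc$start[lc$sv_type == "DEL"],
                         lc$end[lc$sv_type == "DEL"],
                         lc$start[lc$sv_type == "INS"])))
    bps <- bps[bps >= 0L & bps <= L]
    starts <- bps[-length(bps)]
    ends <- bps[-1]
    nz <- ends > starts
    starts <- starts[nz]; ends <- ends[nz]
    ids <- sprintf("%s.b%04d", ch, seq_along(starts))
    seq_str <- as.character(seqs[[ch]])
    nodes[[ch]] <- data.frame(
      node_id = ids, chrom = ch, start = starts, end = ends,
      seq = substring(seq_str, starts + 1L, ends), type = "backbone",
      stringsAsFactors = FALSE)
    if (length(ids) > 1L)
      edges[[ch]] <- data.frame(from = ids[-length(ids)], to = ids[-1],
                                stringsAsFactors = FALSE)
    paths[[paste0("pivot.", ch)]] <- ids
    node_of_start[[ch]] <- setNames(ids, starts)
    # allele structure
    for (k in seq_len(nrow(lc))) {
      loc <- lc[k, ]
      prev_id <- if (loc$start > 0L)
        ids[which(ends == loc$start)] else NA_character_
      if (loc$sv_type == "DEL") {
        next_id <- if (loc$end < L)
          ids[which(starts == loc$end)] else NA_character_
        if (!is.na(prev_id) && !is.na(next_id))
          edges[[paste0(loc$locus_id, ".bypass")]] <-
            data.frame(from = prev_id, to = next_id,
                       stringsAsFactors = FALSE)
      } else {
        alt_id <- paste0(loc$locus_id, ".alt")
        alt_seq <- if (nzchar(loc$payload)) loc$payload else
          strrep("N", loc$rep_size)
        nodes[[alt_id]] <- data.frame(
          node_id = alt_id, chrom = ch, start = loc$start,
          end = loc$start, seq = alt_seq, type = "alt",
          stringsAsFactors = FALSE)
        next_id <- if (loc$start < L)
          ids[which(starts == loc$start)] else NA_character_
        e <- list()
        if (!is.na(prev_id))
          e[[1]] <- data.frame(from = prev_id, to = alt_id,
                               stringsAsFactors = FALSE)
        if (!is.na(next_id))
          e[[length(e) + 1L]] <- data.frame(from = alt_id, to = next_id,
                                            stringsAsFactors = FALSE)
        if (length(e))
          edges[[paste0(loc$locus_id, ".ins")]] <- do.call(rbind, e)
      }
    }
  }
  nodes <- do.call(rbind, nodes)
  edges <- unique(do.call(rbind, edges))
  rownames(nodes) <- rownames(edges) <- NULL

  if (!is.null(matrix)) {
    for (acc in colnames(matrix)) {
      carried <- rownames(matrix)[matrix[, acc] == "present"]
      lacc <- ldf[ldf$locus_id %in% carried, , drop = FALSE]
      for (ch in chroms) {
        bb <- nodes[nodes$type == "backbone" & nodes$chrom == ch, ,
                    drop = FALSE]
        lc <- lacc[lacc$chrom == ch, , drop = FALSE]
        dels <- lc[lc$sv_type == "DEL", , drop = FALSE]
        inss <- lc[lc$sv_type == "INS", , drop = FALSE]
        path <- character()
        for (r in seq_len(nrow(bb))) {
          s <- bb$start[r]
          hit_ins <- inss$start == s
          if (any(hit_ins))
            path <- c(path,
                      paste0(inss$locus_id[hit_ins][1], ".alt"))
          in_del <- any(dels$start <= s & bb$end[r] <= dels$end)
          if (!in_del) path <- c(path, bb$node_id[r])
        }
        L <- Biostrings::width(seqs)[match(ch, names(seqs))]
        hit_ins <- inss$start == L
        if (any(hit_ins))
          path <- c(path, paste0(inss$locus_id[hit_ins][1], ".alt"))
        paths[[paste(acc, ch, sep = ".")]] <- path
      }
    }
  }
  structure(list(nodes = nodes, edges = edges, paths = paths,
                 chroms = chroms, dropped_loci = dropped),
            class = "pansv_graph")
}

#' Spell the sequence along a stored graph path
#'
#' Concatenates the node sequences of a path; for a pivot path this
#' reproduces the pivot chromosome exactly, and for an accession path
#' built from truth-derived loci it reproduces the simulated accession
#' chromosome.
#'
#' @param graph `"pansv_graph"` object.
#' @param path path name (e.g. `"pivot.chr01"` or `"acc01.chr01"`).
#' @return character string.
#' @export
spell_path <- function(graph, path) {
  ids <- graph$paths[[path]]
  if (is.null(ids)) stop("unknown path: ", path)
  paste(graph$nodes$seq[match(ids, graph$nodes$node_id)], collapse = "")
}

#' Export a pan-genome graph as minimal GFA 1.0
#'
#' Emits H, S, L and P lines (all orientations `+`, overlaps `0M`/`*`).
#'
#' @param graph `"pansv_graph"` object.
#' @param path output file.
#' @export
write_gfa <- function(graph, path) {
  lines <- c("H\tVN:Z:1.0",
             sprintf("S\t%s\t%s", graph$nodes$node_id, graph$nodes$seq),
             if (nrow(graph$edges))
               sprintf("L\t%s\t+\t%s\t+\t0M", graph$edges$from,
                       graph$edges$to),
             if (length(graph$paths))
               sprintf("P\t%s\t%s\t*", names(graph$paths),
                       vapply(graph$paths, function(p)
                         paste0(p, "+", collapse = ","), character(1))))
  writeLines(lines, path)
  invisible(path)
}

#' Read a minimal GFA 1.0 file written by [write_gfa()]
#'
#' @param path GFA file.
#' @return `"pansv_graph"`-like list with `nodes` (`node_id`, `seq`),
#'   `edges` and `paths`; re-exporting with [write_gfa()] is
#'   byte-identical.
#' @export
read_gfa <- function(path) {
  lines <- readLines(path)
  tag <- substr(lines, 1, 1)
  sp <- strsplit(lines[tag == "S"], "\t", fixed = TRUE)
  nodes <- data.frame(node_id = vapply(sp, `[`, character(1), 2),
                      seq = vapply(sp, `[`, character(1), 3),
                      stringsAsFactors = FALSE)
  lp <- strsplit(lines[tag == "L"], "\t", fixed = TRUE)
  edges <- if (length(lp)) data.frame(
    from = vapply(lp, `[`, character(1), 2),
    to = vapply(lp, `[`, character(1), 4), stringsAsFactors = FALSE)
  else data.frame(from = character(), to = character(),
                  stringsAsFactors = FALSE)
  pp <- strsplit(lines[tag == "P"], "\t", fixed = TRUE)
  paths <- setNames(lapply(pp, function(x)
    sub("\\+$", "", strsplit(x[3], ",", fixed = TRUE)[[1]])),
    vapply(pp, `[`, character(1), 2))
  structure(list(nodes = nodes, edges = edges, paths = paths),
            class = "pansv_graph")
}
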