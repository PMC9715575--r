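# Synthetic pan-genome cohort: pivot genome, planted SVs, caller emissions.

#' Evaluate an expression under a temporary RNG seed
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# uniform integer draw from an inclusive range; safe for min == max
sample_range <- function(rng) {
  if (rng[1] >= rng[2]) rng[1] else
    rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
}

#' Simulate the pivot genome with gene models and repeat annotation
#'
#' Generates a multi-chromosome pivot assembly (uniform A/C/G/T
#' composition), non-overlapping strand-aware gene models with marked
#' start codons, and repeat intervals covering approximately
#' `repeat_fraction` of the genome, split into LTR-like and DNA-transposon
#' classes. All placement is slot-based, so genes never overlap and the
#' planted repeat fraction is accurate to within a few percent.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `"pansv_pivot"` with elements `sequences`
#'   (a [Biostrings::DNAStringSet]), `chrom_lengths` (named integer),
#'   `genes` (data.frame: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `cds_start`; 0-based half-open, `cds_start` is the 0-based position
#'   of the first base of the start codon), and `repeats` (data.frame:
#'   `chrom`, `start`, `end`, `class`).
#' @examples
#' piv <- simulate_pivot(sim_config(seed = 1, chrom_length = 2e5,
#'                                  n_genes = 20))
#' @export
simulate_pivot <- function(config) {
  validate_sim_config(config)
  L <- config$chrom_length
  n_chr <- config$n_chromosomes
  chroms <- sprintf("chr%02d", seq_len(n_chr))
  gene_len_range <- c(2000L, 6000L)
  genes_per_chr <- diff(round(seq(0, config$n_genes, length.out = n_chr + 1)))
  slot_w <- L / max(genes_per_chr, 1)
  if (config$n_genes > 0 && slot_w < gene_len_range[2] * 2)
    stop("chrom_length too small to host ", config$n_genes,
         " non-overlapping genes")
  with_seed(config$seed, {
    seqs <- Biostrings::DNAStringSet(vapply(chroms, function(ch)
      random_dna(L), character(1)))
    names(seqs) <- chroms

    gene_rows <- list()
    gid <- 0L
    for (i in seq_len(n_chr)) {
      k <- genes_per_chr[i]
      if (k == 0L) next
      slot <- L / k
      for (j in seq_len(k)) {
        gid <- gid + 1L
        glen <- sample(gene_len_range[1]:gene_len_range[2], 1L)
        lo <- floor((j - 1) * slot)
        hi <- floor(j * slot) - glen - 1L
        s <- if (hi > lo) sample(lo:hi, 1L) else lo
        e <- s + glen
        strand <- sample(c("+", "-"), 1L)
        utr5 <- sample(100:300, 1L)
        cds_start <- if (strand == "+") s + utr5 else e - utr5 - 1L
        gene_rows[[gid]] <- data.frame(
          gene_id = sprintf("GENE%04d", gid), chrom = chroms[i],
          start = s, end = e, strand = strand, cds_start = cds_start,
          stringsAsFactors = FALSE)
      }
    }
    genes <- if (length(gene_rows)) do.call(rbind, gene_rows) else
      data.frame(gene_id = character(), chrom = character(),
                 start = integer(), end = integer(), strand = character(),
                 cds_start = integer(), stringsAsFactors = FALSE)

    rep_rows <- list()
    if (config$repeat_fraction > 0) {
      mean_rep <- 2000L
      for (i in seq_len(n_chr)) {
        m <- max(1L, round(config$repeat_fraction * L / mean_rep))
        slot <- L / m
        for (j in seq_len(m)) {
          rlen <- round(config$repeat_fraction * slot *
                          runif(1, 0.85, 1.15))
          rlen <- min(rlen, floor(slot) - 2L)
          lo <- floor((j - 1) * slot)
          hi <- floor(j * slot) - rlen - 1L
          s <- if (hi > lo) sample(lo:hi, 1L) else lo
          rep_rows[[length(rep_rows) + 1L]] <- data.frame(
            chrom = chroms[i], start = s, end = s + rlen,
            class = sample(c("LTR", "DNA"), 1L, prob = c(0.7, 0.3)),
            stringsAsFactors = FALSE)
        }
      }
    }
    repeats <- if (length(rep_rows)) do.call(rbind, rep_rows) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 class = character(), stringsAsFactors = FALSE)
    structure(list(sequences = seqs,
                   chrom_lengths = setNames(rep(L, n_chr), chroms),
                   genes = sort_genomic(genes),
                   repeats = sort_genomic(repeats)),
              class = "pansv_pivot")
  })
}

sv_class_names <- c(pav_deletion = "PAV_DEL", pav_insertion = "PAV_INS",
                    cnv = "CNV", inversion = "INV",
                    small_indel = "SMALL_INDEL", snp = "SNP")

#' Plant structural variants and derive accession genomes
#'
#' For each accession, draws per-class event counts from Poisson rates
#' (events per Mb), places the events without overlap on the pivot (10-bp
#' guard bands between events), applies them to the pivot sequence, and
#' records every event in a truth table carrying both pivot-frame and
#' accession-frame coordinates.
#'
#' Event semantics on the accession sequence: `PAV_DEL` and `CNV`
#' (copy-loss) remove the pivot interval; `PAV_INS` inserts `payload` at
#' the breakpoint; `INV` reverse-complements the interval; `SMALL_INDEL`
#' is a 5-49 bp deletion or insertion (`indel_type`); `SNP` substitutes
#' one base. `group_enrichment` directives plant additional events of one
#' class inside a region for one accession group (or all accessions),
#' which is how group-differential PAV clusters and PAV hotspots are
#' planted.
#'
#' The variant loci form a shared pool on the pivot (drawn at
#' `sv_rates / carrier_prob` so that each accession's expected event
#' rate equals `sv_rates`), placed without overlap genome-wide; each
#' accession then carries each pool variant independently with
#' probability `carrier_prob` (pool loci that draw no carrier are
#' assigned one at random). Variants planted by a `group_enrichment`
#' directive are carried by every accession of the targeted group,
#' making them perfectly group-specific. Insertion payloads and SNP
#' alleles are shared by all carriers of a locus, as for real
#' segregating variants.
#'
#' @param pivot result of [simulate_pivot()].
#' @param config the same [sim_config()].
#' @return A list of class `"pansv_truth"`: `sequences` (DNAStringSet of
#'   accession chromosomes named `accession.chrom`), `truth` (data.frame
#'   with `id`, `accession`, `sv_class`, `chrom`, `pivot_start`,
#'   `pivot_end`, `acc_start`, `acc_end`, `alt_length`, `indel_type`,
#'   `payload`), and `config`.
#' @export
plant_svs <- function(pivot, config) {
  stopifnot(inherits(pivot, "pansv_pivot"))
  validate_sim_config(config)
  chroms <- names(pivot$chrom_lengths)
  pivot_chars <- setNames(as.character(pivot$sequences), chroms)
  n_acc <- length(config$accessions)
  with_seed(config$seed + 1L, {
    # shared non-overlapping pool of variant loci
    pool <- list()
    for (ch in chroms) {
      Lc <- pivot$chrom_lengths[[ch]]
      occ_s <- integer(); occ_e <- integer()
      # the guard band keeps planted events further apart than the
      # 100-bp insertion-matching window, so distinct events can never
      # alias into one consensus call
      guard <- 150L
      place <- function(len, lo, hi) {
        for (try in 1:200) {
          s <- floor(runif(1, lo, max(lo + 1, hi - len)))
          if (!any(s - guard < occ_e & occ_s < s + len + guard)) {
            occ_s <<- c(occ_s, s); occ_e <<- c(occ_e, s + max(len, 1L))
            return(s)
          }
        }
        NA_integer_
      }
      want <- list()
      for (cl in names(config$sv_rates)) {
        n <- rpois(1L, config$sv_rates[[cl]] / config$carrier_prob *
                     Lc / 1e6)
        if (n > 0)
          want[[length(want) + 1L]] <- list(class = cl, lo = 0L,
                                            hi = Lc, n = n,
                                            group = NA_character_)
      }
      for (d in config$group_enrichment) {
        if (d$chrom != ch) next
        n <- rpois(1L, d$rate * (d$end - d$start) / 1e6)
        if (n > 0)
          want[[length(want) + 1L]] <- list(class = d$sv_class,
                                            lo = as.integer(d$start),
                                            hi = as.integer(d$end),
                                            n = n, group = d$group)
      }
      for (w in want) {
        rng <- config$size_ranges[[w$class]]
        for (k in seq_len(w$n)) {
          len <- sample_range(rng)
          itype <- if (w$class == "small_indel")
            sample(c("DEL", "INS"), 1L) else NA_character_
          ins_like <- w$class == "pav_insertion" ||
            (w$class == "small_indel" && itype == "INS")
          footprint <- if (ins_like) 1L else len
          s <- place(footprint, w$lo, w$hi)
          if (is.na(s))
            stop("SV density unsatisfiable without overlap on ", ch)
          payload <- if (ins_like) random_dna(len) else ""
          if (w$class == "snp") {
            ref <- substr(pivot_chars[[ch]], s + 1L, s + 1L)
            payload <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
          }
          carriers <- if (is.na(w$group)) {
            hit <- runif(n_acc) < config$carrier_prob
            if (!any(hit)) hit[sample.int(n_acc, 1L)] <- TRUE
            config$accessions[hit]
          } else if (w$group == "all") {
            config$accessions
          } else {
            config$accessions[config$group_labels[config$accessions] ==
                                w$group]
          }
          pool[[length(pool) + 1L]] <- list(
            class = w$class, chrom = ch, start = s, len = len,
            indel_type = itype, payload = payload, carriers = carriers)
        }
      }
    }
    truth_all <- lapply(config$accessions, function(acc) {
      events <- Filter(function(ev) acc %in% ev$carriers, pool)
      build_accession(pivot_chars, events, acc)
    })
    truth <- do.call(rbind, lapply(truth_all, `[[`, "truth"))
    rownames(truth) <- NULL
    seqs <- unlist(unname(lapply(truth_all, `[[`, "seqs")))
    dna <- Biostrings::DNAStringSet(unlist(seqs))
    structure(list(sequences = dna, truth = truth, config = config),
              class = "pansv_truth")
  })
}

# Apply one accession's event list to the pivot chromosomes; returns
# truth rows (with both coordinate frames) and spliced sequences.
build_accession <- function(pivot_chars, events, acc) {
  rows <- list()
  seqs <- list()
  idx <- 0L
  by_chr <- split(events, vapply(events, `[[`, character(1), "chrom"))
  for (ch in names(pivot_chars)) {
    evs <- by_chr[[ch]] %||% list()
    if (length(evs)) {
      o <- order(vapply(evs, `[[`, numeric(1), "start"))
      evs <- evs[o]
    }
    src <- pivot_chars[[ch]]
    parts <- character()
    cur <- 0L   # pivot cursor, 0-based
    shift <- 0L # accession minus pivot coordinate offset
    for (ev in evs) {
      idx <- idx + 1L
      cl <- ev$class; s <- ev$start; len <- ev$len
      sv <- sv_class_names[[cl]]
      del_like <- cl %in% c("pav_deletion", "cnv") ||
        (cl == "small_indel" && ev$indel_type == "DEL")
      ins_like <- cl == "pav_insertion" ||
        (cl == "small_indel" && ev$indel_type == "INS")
      if (ins_like) {
        payload <- ev$payload
        parts <- c(parts, substr(src, cur + 1L, s), payload)
        row <- data.frame(sv_class = sv, chrom = ch, pivot_start = s,
                          pivot_end = s, acc_start = s + shift,
                          acc_end = s + shift + len, alt_length = len,
                          indel_type = if (cl == "small_indel") "INS"
                                       else NA_character_,
                          payload = payload, stringsAsFactors = FALSE)
        shift <- shift + len
        cur <- s
      } else if (del_like) {
        parts <- c(parts, substr(src, cur + 1L, s))
        row <- data.frame(sv_class = sv, chrom = ch, pivot_start = s,
                          pivot_end = s + len, acc_start = s + shift,
                          acc_end = s + shift, alt_length = 0L,
                          indel_type = if (cl == "small_indel") "DEL"
                                       else NA_character_,
                          payload = "", stringsAsFactors = FALSE)
        shift <- shift - len
        cur <- s + len
      } else if (cl == "inversion") {
        seg <- substr(src, s + 1L, s + len)
        rc <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(seg)))
        parts <- c(parts, substr(src, cur + 1L, s), rc)
        row <- data.frame(sv_class = sv, chrom = ch, pivot_start = s,
                          pivot_end = s + len, acc_start = s + shift,
                          acc_end = s + shift + len, alt_length = len,
                          indel_type = NA_character_, payload = "",
                          stringsAsFactors = FALSE)
        cur <- s + len
      } else { # snp
        alt <- ev$payload
        parts <- c(parts, substr(src, cur + 1L, s), alt)
        row <- data.frame(sv_class = sv, chrom = ch, pivot_start = s,
                          pivot_end = s + 1L, acc_start = s + shift,
                          acc_end = s + shift + 1L, alt_length = 1L,
                          indel_type = NA_character_, payload = alt,
                          stringsAsFactors = FALSE)
        cur <- s + 1L
      }
      row <- cbind(data.frame(id = sprintf("%s_sv%04d", acc, idx),
                              accession = acc, stringsAsFactors = FALSE),
                   row)
      rows[[length(rows) + 1L]] <- row
    }
    parts <- c(parts, substr(src, cur + 1L, nchar(src)))
    seqs[[paste(acc, ch, sep = ".")]] <- paste(parts, collapse = "")
  }
  truth <- if (length(rows)) do.call(rbind, rows) else data.frame(
    id = character(), accession = character(), sv_class = character(),
    chrom = character(), pivot_start = integer(), pivot_end = integer(),
    acc_start = integer(), acc_end = integer(), alt_length = integer(),
    indel_type = character(), payload = character(),
    stringsAsFactors = FALSE)
  list(truth = truth, seqs = seqs)
}

assemblytics_vocab <- c("Insertion", "Deletion", "Tandem_expansion",
                        "Tandem_contraction", "Repeat_expansion",
                        "Repeat_contraction")
syri_vocab <- c("INS", "DEL", "HDR", "INVAL", "SNP", "DUPAL", "CPL")

# (annotation, deletion-like?) emitted per truth class in the pairwise
# (pivot-as-reference) direction, by dialect. Assemblytics reports only
# indel-type variation; inversions and SNPs come from the SyRI dialect.
emission_annotation <- function(sv_class, indel_type, dialect) {
  if (dialect == "assemblytics") {
    switch(sv_class,
           PAV_DEL = "Deletion", PAV_INS = "Insertion",
           CNV = "Tandem_contraction",
           SMALL_INDEL = if (indel_type == "DEL") "Deletion" else "Insertion",
           NA_character_)
  } else {
    switch(sv_class,
           PAV_DEL = "DEL", PAV_INS = "INS", CNV = "CPL",
           SMALL_INDEL = if (indel_type == "DEL") "DEL" else "INS",
           INV = "INVAL", SNP = "SNP")
  }
}

# Label exchange applied when the alignment direction is reversed.
flip_annotation <- function(x) {
  map <- c(Insertion = "Deletion", Deletion = "Insertion",
           Tandem_expansion = "Tandem_contraction",
           Tandem_contraction = "Tandem_expansion",
           Repeat_expansion = "Repeat_contraction",
           Repeat_contraction = "Repeat_expansion",
           INS = "DEL", DEL = "INS", CPL = "DUPAL", DUPAL = "CPL",
           HDR = "HDR", INVAL = "INVAL", SNP = "SNP")
  out <- unname(map[x])
  out[is.na(out)] <- x[is.na(out)]
  out
}

#' Emit caller call files from planted truth
#'
#' Converts the truth table for one accession into the native record set
#' of one caller dialect and one alignment direction. In the `pairwise`
#' direction the reference frame is the pivot genome and the query frame
#' the accession; in the `reciprocal` direction the frames are swapped
#' and deletion/insertion-type labels are exchanged, exactly as a caller
#' run on the swapped alignment would report them. Noise (applied in this
#' order, seeded) drops records at the false-negative rate, jitters
#' breakpoints with rounded Gaussian offsets, and relabels annotations at
#' the confusion rate.
#'
#' @param truth a `"pansv_truth"` object or its `truth` data.frame.
#' @param dialect `"assemblytics"` or `"syri"`.
#' @param direction `"pairwise"` or `"reciprocal"`.
#' @param accession accession name to emit; required when `truth` covers
#'   several accessions.
#' @param noise list with `fn_rate`, `jitter_sd`, `confusion_rate`
#'   (all default 0).
#' @param seed integer seed for the noise process.
#' @param path optional output path; when given, the records are written
#'   in the dialect's native file format (see [write_assemblytics()] /
#'   [write_syri()]).
#' @return A caller-record data.frame (columns `caller`, `direction`,
#'   `ref_chrom`, `ref_start`, `ref_end`, `query_chrom`, `query_start`,
#'   `query_end`, `annotation`, `size`, `id`; 0-based half-open),
#'   invisibly when `path` is given.
#' @export
emit_caller_calls <- function(truth,
                              dialect = c("assemblytics", "syri"),
                              direction = c("pairwise", "reciprocal"),
                              accession = NULL,
                              noise = list(fn_rate = 0, jitter_sd = 0,
                                           confusion_rate = 0),
                              seed = 0L, path = NULL) {
  dialect <- match.arg(dialect)
  direction <- match.arg(direction)
  tt <- if (inherits(truth, "pansv_truth")) truth$truth else truth
  if (!is.null(accession)) tt <- tt[tt$accession == accession, , drop = FALSE]
  if (length(unique(tt$accession)) > 1L)
    stop("emit_caller_calls works on one accession at a time")
  anns <- vapply(seq_len(nrow(tt)), function(i)
    emission_annotation(tt$sv_class[i], tt$indel_type[i], dialect),
    character(1))
  keep <- !is.na(anns)
  tt <- tt[keep, , drop = FALSE]
  anns <- anns[keep]
  if (nrow(tt) == 0L) {
    rec <- empty_records()
    if (!is.null(path)) {
      if (dialect == "assemblytics") write_assemblytics(rec, path)
      else write_syri(rec, path)
      return(invisible(rec))
    }
    return(rec)
  }
  acc_chrom <- if (nrow(tt)) paste(tt$accession, tt$chrom, sep = ".") else
    character()
  if (direction == "pairwise") {
    rec <- data.frame(
      caller = dialect, direction = direction,
      ref_chrom = tt$chrom, ref_start = tt$pivot_start,
      ref_end = tt$pivot_end,
      query_chrom = acc_chrom, query_start = tt$acc_start,
      query_end = tt$acc_end,
      annotation = anns,
      size = pmax(tt$pivot_end - tt$pivot_start, tt$alt_length),
      id = tt$id, stringsAsFactors = FALSE)
  } else {
    rec <- data.frame(
      caller = dialect, direction = direction,
      ref_chrom = acc_chrom, ref_start = tt$acc_start,
      ref_end = tt$acc_end,
      query_chrom = tt$chrom, query_start = tt$pivot_start,
      query_end = tt$pivot_end,
      annotation = flip_annotation(anns),
      size = pmax(tt$pivot_end - tt$pivot_start, tt$alt_length),
      id = tt$id, stringsAsFactors = FALSE)
  }
  noise <- modifyList(list(fn_rate = 0, jitter_sd = 0, confusion_rate = 0),
                      as.list(noise))
  rec <- with_seed(seed, apply_caller_noise(rec, noise, dialect))
  rec <- rec[order(chrom_rank(rec$ref_chrom), rec$ref_start, rec$id), ,
             drop = FALSE]
  rownames(rec) <- NULL
  if (!is.null(path)) {
    if (dialect == "assemblytics") write_assemblytics(rec, path)
    else write_syri(rec, path)
    return(invisible(rec))
  }
  rec
}

apply_caller_noise <- function(rec, noise, dialect) {
  n <- nrow(rec)
  if (n == 0L) return(rec)
  if (noise$fn_rate > 0) {
    keep <- runif(n) >= noise$fn_rate
    rec <- rec[keep, , drop = FALSE]
    n <- nrow(rec)
  }
  if (n > 0L && noise$jitter_sd > 0) {
    jitter_frame <- function(s, e) {
      zero_w <- e == s
      js <- as.integer(round(rnorm(n, 0, noise$jitter_sd)))
      je <- as.integer(round(rnorm(n, 0, noise$jitter_sd)))
      ns <- pmax(0L, s + js)
      ne <- ifelse(zero_w, ns, pmax(ns + 1L, e + je))
      list(start = ns, end = as.integer(ne))
    }
    rf <- jitter_frame(rec$ref_start, rec$ref_end)
    qf <- jitter_frame(rec$query_start, rec$query_end)
    rec$ref_start <- rf$start; rec$ref_end <- rf$end
    rec$query_start <- qf$start; rec$query_end <- qf$end
  }
  if (n > 0L && noise$confusion_rate > 0) {
    vocab <- if (dialect == "assemblytics") assemblytics_vocab else syri_vocab
    hit <- runif(n) < noise$confusion_rate
    if (any(hit)) {
      rec$annotation[hit] <- vapply(rec$annotation[hit], function(a)
        sample(setdiff(vocab, a), 1L), character(1))
    }
  }
  rec
}

phenotype_levels <- c(erect = 1L, intermediate = 3L, pendent = 6L)

#' Numeric encoding of fruit-orientation phenotypes
#'
#' Maps `"erect"` to 1, `"intermediate"` to 3 and `"pendent"` to 6 (the
#' standard field-scoring convention for pepper fruit position).
#'
#' @param label character vector of phenotype labels.
#' @return integer codes.
#' @examples
#' encode_phenotype(c("erect", "pendent"))  # 1 6
#' @export
encode_phenotype <- function(label) {
  if (!all(label %in% names(phenotype_levels)))
    stop("unknown phenotype label(s): ",
         paste(setdiff(label, names(phenotype_levels)), collapse = ", "))
  unname(phenotype_levels[label])
}

#' Simulate accession phenotypes, optionally co-segregating with a PAV
#'
#' Without a directive, each accession draws an independent random
#' phenotype from \{erect, intermediate, pendent\}. With a co-segregation
#' directive, accessions carrying a planted event in the directive region
#' (or, with the `group` form, members of the named group) are scored
#' `"erect"` (code 1) and all others `"pendent"` (code 6), giving a
#' perfectly co-segregating trait.
#'
#' @param config a [sim_config()].
#' @param truth optional `"pansv_truth"` (needed for region directives).
#' @param coseg `NULL`, `list(group = "groupA")`, or
#'   `list(chrom =, start =, end =, sv_class =)` designating the causal
#'   planted PAV region.
#' @param seed seed for the no-directive random draw.
#' @return data.frame: `accession`, `group`, `trait`, `label`, `code`.
#' @export
simulate_phenotypes <- function(config, truth = NULL, coseg = NULL,
                                seed = NULL) {
  validate_sim_config(config)
  accs <- config$accessions
  if (is.null(coseg)) {
    lab <- with_seed(seed %||% (config$seed + 7L),
                     sample(names(phenotype_levels), length(accs),
                            replace = TRUE))
  } else if (!is.null(coseg$group)) {
    if (!coseg$group %in% c("groupA", "groupB"))
      stop("unknown group in co-segregation directive: ", coseg$group)
    lab <- ifelse(config$group_labels[accs] == coseg$group,
                  "erect", "pendent")
  } else {
    if (is.null(truth)) stop("region directive requires the truth set")
    tt <- if (inherits(truth, "pansv_truth")) truth$truth else truth
    if (!all(tt$accession %in% accs))
      stop("truth contains accessions not in the configuration")
    hit <- tt$chrom == coseg$chrom & tt$pivot_start < coseg$end &
      tt$pivot_end > coseg$start
    if (!is.null(coseg$sv_class)) hit <- hit & tt$sv_class == coseg$sv_class
    carriers <- unique(tt$accession[hit])
    lab <- ifelse(accs %in% carriers, "erect", "pendent")
  }
  data.frame(accession = accs,
             group = unname(config$group_labels[accs]),
             trait = "fruit_orientation", label = lab,
             code = encode_phenotype(lab), stringsAsFactors = FALSE)
}
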