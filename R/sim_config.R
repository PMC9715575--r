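#' Simulation configuration for the synthetic pan-genome cohort
#'
#' Builds and validates the configuration driving the synthetic-data
#' generator: a multi-chromosome pivot genome, derived accession genomes
#' carrying planted structural variants, a two-group accession structure
#' (a pungency-like "hot" vs "sweet" split), and noisy emissions in two
#' caller dialects.
#'
#' The default SV rates give roughly 20 planted events per Mb per
#' accession, split across presence-absence deletions and insertions,
#' copy-number contractions, inversions, small indels (net size 5-49 bp)
#' and SNPs. Size conventions follow the field's usage: PAVs are at least
#' 50 bp, small indels fall in the 5-49 bp bin and inversions are at
#' least 1 kb.
#'
#' @param seed integer seed; identical seed and configuration give
#'   byte-identical outputs.
#' @param n_chromosomes number of pivot chromosomes.
#' @param chrom_length length of each pivot chromosome in bp.
#' @param n_accessions number of derived accessions.
#' @param group_labels named character vector mapping accession names to
#'   `"groupA"` / `"groupB"`; defaults to the first half in groupA
#'   ("hot"-like) and the rest in groupB ("sweet"-like).
#' @param sv_rates named numeric vector: expected planted events per Mb
#'   for `pav_deletion`, `pav_insertion`, `cnv`, `inversion`,
#'   `small_indel`, `snp`.
#' @param size_ranges named list of `c(min, max)` bp per class.
#' @param n_genes number of non-overlapping gene models on the pivot.
#' @param repeat_fraction target fraction of the pivot covered by
#'   annotated repeat intervals.
#' @param carrier_prob probability that an accession carries a given
#'   pool variant; the per-accession event rate stays at `sv_rates`
#'   because the pool is drawn at `sv_rates / carrier_prob`.
#' @param group_enrichment list of directives, each a list with fields
#'   `chrom`, `start`, `end`, `sv_class` (rate-table name), `group`
#'   (`"groupA"`, `"groupB"` or `"all"`), and `rate` (additional events
#'   per Mb planted inside the region for the targeted accessions).
#' @param caller_noise list with per-caller elements `assemblytics` and
#'   `syri`, each a list of `fn_rate` (false-negative probability per
#'   emitted file), `jitter_sd` (breakpoint jitter standard deviation,
#'   bp) and `confusion_rate` (probability of relabelling a record with
#'   another annotation from the same dialect).
#' @return A validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(seed = 1, n_chromosomes = 2, chrom_length = 1e6)
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 5e6,
                       n_accessions = 8L,
                       group_labels = NULL,
                       sv_rates = c(pav_deletion = 4, pav_insertion = 4,
                                    cnv = 2, inversion = 1,
                                    small_indel = 6, snp = 3),
                       size_ranges = list(
                         pav_deletion = c(50L, 5000L),
                         pav_insertion = c(50L, 5000L),
                         cnv = c(100L, 2000L),
                         inversion = c(1000L, 10000L),
                         small_indel = c(5L, 49L),
                         snp = c(1L, 1L)),
                       n_genes = 200L,
                       repeat_fraction = 0.3,
                       carrier_prob = 0.5,
                       group_enrichment = list(),
                       caller_noise = list(
                         assemblytics = list(fn_rate = 0, jitter_sd = 0,
                                             confusion_rate = 0),
                         syri = list(fn_rate = 0, jitter_sd = 0,
                                     confusion_rate = 0))) {
  accessions <- sprintf("acc%02d", seq_len(n_accessions))
  if (is.null(group_labels)) {
    half <- ceiling(n_accessions / 2)
    group_labels <- setNames(
      c(rep("groupA", half), rep("groupB", n_accessions - half)),
      accessions)
  }
  cfg <- structure(list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_accessions = as.integer(n_accessions),
    accessions = accessions,
    group_labels = group_labels,
    sv_rates = sv_rates,
    size_ranges = lapply(size_ranges, as.integer),
    n_genes = as.integer(n_genes),
    repeat_fraction = repeat_fraction,
    carrier_prob = carrier_prob,
    group_enrichment = group_enrichment,
    caller_noise = caller_noise
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#' @param cfg object returned by [sim_config()].
#' @return `cfg`, invisibly; stops on violation.
#' @keywords internal
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  classes <- c("pav_deletion", "pav_insertion", "cnv", "inversion",
               "small_indel", "snp")
  if (!all(classes %in% names(cfg$sv_rates)))
    stop("sv_rates must name all classes: ",
         paste(setdiff(classes, names(cfg$sv_rates)), collapse = ", "))
  if (any(cfg$sv_rates < 0)) stop("all sv_rates must be >= 0")
  for (cl in classes) {
    r <- cfg$size_ranges[[cl]]
    if (is.null(r) || length(r) != 2L || r[1] > r[2])
      stop("size_ranges[['", cl, "']] must be c(min, max) with min <= max")
  }
  si <- cfg$size_ranges$small_indel
  if (si[1] < 5L || si[2] > 49L)
    stop("small_indel size range must lie within [5, 49] bp")
  if (cfg$size_ranges$pav_deletion[1] < 50L ||
      cfg$size_ranges$pav_insertion[1] < 50L)
    stop("PAV size ranges must start at >= 50 bp")
  if (cfg$size_ranges$inversion[1] < 1000L)
    stop("inversion size range must start at >= 1000 bp")
  if (cfg$repeat_fraction < 0 || cfg$repeat_fraction > 0.9)
    stop("repeat_fraction must be in [0, 0.9]")
  if (cfg$carrier_prob <= 0 || cfg$carrier_prob > 1)
    stop("carrier_prob must be in (0, 1]")
  if (!all(cfg$group_labels %in% c("groupA", "groupB")))
    stop("group_labels values must be 'groupA' or 'groupB'")
  if (!all(names(cfg$group_labels) %in% cfg$accessions))
    stop("group_labels names must be accession names")
  for (cn in cfg$caller_noise) {
    if (cn$fn_rate < 0 || cn$fn_rate > 1)
      stop("caller fn_rate must be in [0, 1]")
    if (cn$jitter_sd < 0) stop("jitter_sd must be >= 0")
    if (cn$confusion_rate < 0 || cn$confusion_rate > 1)
      stop("confusion_rate must be in [0, 1]")
  }
  for (d in cfg$group_enrichment) {
    need <- c("chrom", "start", "end", "sv_class", "group", "rate")
    if (!all(need %in% names(d)))
      stop("group_enrichment directives need fields: ",
           paste(need, collapse = ", "))
    if (!d$group %in% c("groupA", "groupB", "all"))
      stop("directive group must be 'groupA', 'groupB' or 'all'")
  }
  invisible(cfg)
}
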