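# Run configuration and the end-to-end pipeline:
# simulate -> harmonize -> pangenome -> windows -> annotate -> trait,
# with a content-hash manifest for reproducibility checks.

run_config_defaults <- function() {
  list(seed = 1L,
       out_dir = "pansv_run",
       stages = c("simulate", "harmonize", "pangenome", "windows",
                  "pangene", "annotate", "trait"),
       sim = list(),
       match = list(),
       merge_overlap = 0.8,
       window_size = 1e6, step = 2e5,
       hotspot_quantile = 0.99, diff_fraction = 0.05,
       gwas_flank = 1e6,
       upstream = 1000L, domain_top_n = 10L,
       coseg = list(group = "groupA"),
       alpha = 0.05)
}

#' Build or load a validated run configuration
#'
#' Unknown keys are rejected; omitted keys take the documented
#' defaults. The `sim` block holds [sim_config()] arguments and the
#' `match` block [match_params()] arguments.
#'
#' @param path optional YAML file to load.
#' @param ... overrides of the default keys.
#' @return validated configuration list of class `"run_config"`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- run_config_defaults()
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  user <- modifyList(user, list(...))
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown run-config key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, user)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

stage_file <- function(dir, ...) file.path(dir, ...)

#' Run the full pipeline into an output directory
#'
#' Executes the requested stages in dependency order on a fully
#' synthetic cohort, writing every artifact under `config$out_dir` and
#' finishing with `manifest.tsv` (relative path and MD5 content hash of
#' every output). Reruns with an identical configuration produce
#' identical hashes. On stage failure a `FAILED` marker naming the
#' stage is left in the output directory and the error is re-raised.
#'
#' @param config a [run_config()].
#' @return invisible list with the in-memory stage results and the
#'   manifest data.frame.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  current_stage <- NA_character_
  withCallingHandlers({
    scfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
    params <- do.call(match_params, config$match)

    if ("simulate" %in% config$stages) {
      current_stage <- "simulate"
      res$sim <- write_simulation(stage_file(out, "sim"), scfg)
    }
    sim <- res$sim %||% simulate_cohort(scfg)

    if ("harmonize" %in% config$stages) {
      current_stage <- "harmonize"
      dir.create(stage_file(out, "calls"), showWarnings = FALSE)
      calls <- lapply(scfg$accessions, function(acc) {
        cc <- harmonize_accession(
          emit_caller_calls(sim$truth, "assemblytics", "pairwise", acc,
                            scfg$caller_noise$assemblytics,
                            seed = scfg$seed + emission_seed(acc, 1L)),
          emit_caller_calls(sim$truth, "assemblytics", "reciprocal", acc,
                            scfg$caller_noise$assemblytics,
                            seed = scfg$seed + emission_seed(acc, 2L)),
          emit_caller_calls(sim$truth, "syri", "pairwise", acc,
                            scfg$caller_noise$syri,
                            seed = scfg$seed + emission_seed(acc, 3L)),
          emit_caller_calls(sim$truth, "syri", "reciprocal", acc,
                            scfg$caller_noise$syri,
                            seed = scfg$seed + emission_seed(acc, 4L)),
          params, accession = acc)
        write_calls(cc, stage_file(out, "calls",
                                   paste0(acc, ".calls.tsv")))
        cc
      })
      res$calls <- do.call(rbind, calls)
      write_calls(res$calls, stage_file(out, "calls", "all.calls.tsv"))
    }

    if ("pangenome" %in% config$stages) {
      current_stage <- "pangenome"
      pav <- res$calls[res$calls$sv_class %in% c("PAV_DEL", "PAV_INS"), ]
      res$loci <- merge_nonredundant(pav, params, config$merge_overlap)
      res$matrix <- build_pa_matrix(res$loci, scfg$accessions)
      dir.create(stage_file(out, "pangenome"), showWarnings = FALSE)
      write_locus_bed(res$loci, stage_file(out, "pangenome", "loci.bed"))
      write_pa_matrix(res$matrix,
                      stage_file(out, "pangenome", "pa_matrix.tsv"))
      write_pav_vcf(res$loci, res$matrix, sim$pivot,
                    stage_file(out, "pangenome", "pav.vcf"))
      graph <- build_graph(sim$pivot, res$loci, res$matrix)
      write_gfa(graph, stage_file(out, "pangenome", "graph.gfa"))
    }

    if ("windows" %in% config$stages) {
      current_stage <- "windows"
      dir.create(stage_file(out, "windows"), showWarnings = FALSE)
      grid <- window_grid(sim$pivot$chrom_lengths, config$window_size,
                          config$step)
      pav <- res$calls[res$calls$sv_class %in% c("PAV_DEL", "PAV_INS"), ]
      pooled <- window_counts(pav, grid)
      byacc <- window_counts(pav, grid, by = "accession",
                             accessions = scfg$accessions)
      write_bedgraph(pooled, stage_file(out, "windows",
                                        "pav_density.bedgraph"))
      res$hotspots <- hotspots(pooled, config$hotspot_quantile)
      write_bed(res$hotspots, stage_file(out, "windows", "hotspots.bed"))
      ga <- names(scfg$group_labels)[scfg$group_labels == "groupA"]
      gb <- names(scfg$group_labels)[scfg$group_labels == "groupB"]
      diff <- group_differential(byacc, ga, gb)
      res$differential <- top_fraction_regions(diff, config$diff_fraction)
      write_bed(res$differential,
                stage_file(out, "windows", "differential_top.bed"))
      res$gwas <- gwas_overlap(res$differential, sim$gwas,
                               config$gwas_flank)
      write.table(res$gwas$intervals,
                  stage_file(out, "windows", "gwas_overlap.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      res$te <- te_pav_association(pooled, sim$pivot$repeats,
                                   regions = res$differential)
      write.table(res$te$table,
                  stage_file(out, "windows", "te_association.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }

    if ("pangene" %in% config$stages) {
      current_stage <- "pangene"
      dir.create(stage_file(out, "pangene"), showWarnings = FALSE)
      cls <- classify_families(sim$orthogroups)
      write.table(data.frame(family = names(cls$class),
                             class = as.character(cls$class)),
                  stage_file(out, "pangene", "classification.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      curves <- accumulation_curves(sim$orthogroups, seed = config$seed)
      write.table(curves, stage_file(out, "pangene", "curves.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      res$pangene <- list(classification = cls, curves = curves)
    }

    if ("annotate" %in% config$stages) {
      current_stage <- "annotate"
      dir.create(stage_file(out, "annotate"), showWarnings = FALSE)
      pav <- res$calls[res$calls$sv_class %in% c("PAV_DEL", "PAV_INS"), ]
      ctx <- classify_sv_context(pav, sim$pivot$genes, config$upstream)
      write.table(ctx[, c("chrom", "start", "end", "accession",
                          "sv_class", "context", "genes")],
                  stage_file(out, "annotate", "sv_context.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      rank <- domain_ranking(res$hotspots, sim$pivot$genes,
                             sim$maps$gene2domain, config$domain_top_n)
      write.table(rank, stage_file(out, "annotate",
                                   "hotspot_domains.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      res$annotate <- list(context = ctx, domains = rank)
    }

    if ("trait" %in% config$stages) {
      current_stage <- "trait"
      dir.create(stage_file(out, "trait"), showWarnings = FALSE)
      pheno <- simulate_phenotypes(scfg, sim$truth, config$coseg)
      write_phenotypes(pheno, stage_file(out, "trait", "phenotypes.tsv"))
      erect <- setNames(pheno$code == 1L, pheno$accession)
      stats <- lapply(rownames(res$matrix), function(lid) {
        ct <- cosegregation_test(
          res$matrix[lid, pheno$accession], erect[pheno$accession])
        data.frame(locus_id = lid, concordance = ct$concordance,
                   p = ct$p, degenerate = ct$degenerate,
                   stringsAsFactors = FALSE)
      })
      stats <- do.call(rbind, stats)
      stats <- stats[order(stats$p, stats$locus_id), ]
      write.table(stats, stage_file(out, "trait", "cosegregation.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      res$trait <- stats
    }
  }, error = function(e) {
    writeLines(paste("stage:", current_stage),
               stage_file(out, "FAILED"))
  })

  files <- sort(setdiff(list.files(out, recursive = TRUE),
                        "manifest.tsv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out, files))),
    stringsAsFactors = FALSE)
  write.table(manifest, stage_file(out, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  res$manifest <- manifest
  invisible(res)
}

emission_seed <- function(accession, slot) {
  100L * as.integer(sub("\\D+", "", accession)) + slot
}

#' Generate the full synthetic cohort in memory
#'
#' @param scfg a [sim_config()].
#' @return list: `pivot`, `truth`, `orthogroups`, `maps`, `gwas`.
#' @export
simulate_cohort <- function(scfg) {
  pivot <- simulate_pivot(scfg)
  truth <- plant_svs(pivot, scfg)
  list(pivot = pivot, truth = truth,
       orthogroups = simulate_orthogroups(scfg),
       maps = simulate_gene_maps(pivot$genes, scfg$seed + 5L),
       gwas = simulate_gwas_regions(scfg))
}

#' Write the complete synthetic input set to a directory
#'
#' Emits pivot and accession FASTA, GFF3 gene models, repeat BED, the
#' truth table, all four caller files per accession, the phenotype
#' table, orthogroup TSV, gene-to-domain/GO maps and GWAS BED.
#'
#' @param dir output directory.
#' @param scfg a [sim_config()].
#' @return invisible cohort list (as [simulate_cohort()]).
#' @export
write_simulation <- function(dir, scfg) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(scfg)
  Biostrings::writeXStringSet(sim$pivot$sequences,
                              file.path(dir, "pivot.fa"))
  dir.create(file.path(dir, "accessions"), showWarnings = FALSE)
  for (acc in scfg$accessions) {
    keep <- startsWith(names(sim$truth$sequences), paste0(acc, "."))
    Biostrings::writeXStringSet(
      sim$truth$sequences[keep],
      file.path(dir, "accessions", paste0(acc, ".fa")))
  }
  write_gff3(sim$pivot$genes, file.path(dir, "genes.gff3"))
  write_bed(data.frame(chrom = sim$pivot$repeats$chrom,
                       start = sim$pivot$repeats$start,
                       end = sim$pivot$repeats$end,
                       name = sim$pivot$repeats$class,
                       score = 0L, strand = ".",
                       stringsAsFactors = FALSE),
            file.path(dir, "repeats.bed"))
  write.table(sim$truth$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  dir.create(file.path(dir, "calls"), showWarnings = FALSE)
  for (acc in scfg$accessions) {
    emit_caller_calls(sim$truth, "assemblytics", "pairwise", acc,
                      scfg$caller_noise$assemblytics,
                      seed = scfg$seed + emission_seed(acc, 1L),
                      path = file.path(dir, "calls",
                                       paste0(acc, ".assemblytics.pairwise.bed")))
    emit_caller_calls(sim$truth, "assemblytics", "reciprocal", acc,
                      scfg$caller_noise$assemblytics,
                      seed = scfg$seed + emission_seed(acc, 2L),
                      path = file.path(dir, "calls",
                                       paste0(acc, ".assemblytics.reciprocal.bed")))
    emit_caller_calls(sim$truth, "syri", "pairwise", acc,
                      scfg$caller_noise$syri,
                      seed = scfg$seed + emission_seed(acc, 3L),
                      path = file.path(dir, "calls",
                                       paste0(acc, ".syri.pairwise.tsv")))
    emit_caller_calls(sim$truth, "syri", "reciprocal", acc,
                      scfg$caller_noise$syri,
                      seed = scfg$seed + emission_seed(acc, 4L),
                      path = file.path(dir, "calls",
                                       paste0(acc, ".syri.reciprocal.tsv")))
  }
  write_phenotypes(simulate_phenotypes(scfg),
                   file.path(dir, "phenotypes.tsv"))
  write_orthogroups(sim$orthogroups, file.path(dir, "orthogroups.tsv"))
  write_gene_map(sim$maps$gene2domain, file.path(dir, "gene2domain.tsv"))
  write_gene_map(sim$maps$gene2term, file.path(dir, "gene2go.tsv"))
  write_bed(sim$gwas, file.path(dir, "gwas.bed"))
  invisible(sim)
}
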