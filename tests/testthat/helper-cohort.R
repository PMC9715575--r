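# Shared small synthetic cohorts, built once per test run.

.cohort_cache <- new.env(parent = emptyenv())

tiny_config <- function(seed = 42L, ...) {
  sim_config(seed = seed, n_chromosomes = 2L, chrom_length = 1e6,
             n_accessions = 4L, n_genes = 40L, ...)
}

tiny_cohort <- function(seed = 42L, key = paste0("c", seed), ...) {
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  cfg <- tiny_config(seed, ...)
  pivot <- simulate_pivot(cfg)
  truth <- plant_svs(pivot, cfg)
  .cohort_cache[[key]] <- list(cfg = cfg, pivot = pivot, truth = truth)
  .cohort_cache[[key]]
}

emit4 <- function(truth, acc, noise = list(), seed = 0L) {
  list(
    af = emit_caller_calls(truth, "assemblytics", "pairwise", acc,
                           noise, seed = seed + 1L),
    ar = emit_caller_calls(truth, "assemblytics", "reciprocal", acc,
                           noise, seed = seed + 2L),
    sf = emit_caller_calls(truth, "syri", "pairwise", acc,
                           noise, seed = seed + 3L),
    sr = emit_caller_calls(truth, "syri", "reciprocal", acc,
                           noise, seed = seed + 4L))
}

harmonize_cohort <- function(truth, cfg, noise = list(), seed = 0L,
                             params = match_params()) {
  out <- lapply(cfg$accessions, function(acc) {
    e <- emit4(truth, acc, noise,
               seed + 10L * match(acc, cfg$accessions))
    harmonize_accession(e$af, e$ar, e$sf, e$sr, params, accession = acc)
  })
  do.call(rbind, out)
}

# exact (accession, class, chrom, start, end) keys
call_keys <- function(chrom, start, end, cls, acc) {
  paste(acc, cls, chrom, start, end, sep = "|")
}

truth_keys <- function(tt) {
  call_keys(tt$chrom, tt$pivot_start, tt$pivot_end, tt$sv_class,
            tt$accession)
}
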