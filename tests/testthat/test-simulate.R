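# Synthetic-data generator: determinism, construction constraints,
# sequence conservation, noise statistics, phenotypes.

test_that("pivot simulation is deterministic and respects sizing", {
  cfg <- sim_config(seed = 1, n_chromosomes = 2, chrom_length = 1e6,
                    n_accessions = 2, n_genes = 50)
  p1 <- simulate_pivot(cfg)
  p2 <- simulate_pivot(cfg)
  expect_identical(as.character(p1$sequences), as.character(p2$sequences))
  expect_identical(p1$genes, p2$genes)
  expect_equal(unname(Biostrings::width(p1$sequences)), c(1e6, 1e6))
  expect_equal(nrow(p1$genes), 50)
  # genes never overlap
  g <- p1$genes[order(p1$genes$chrom, p1$genes$start), ]
  same <- g$chrom[-1] == g$chrom[-nrow(g)]
  expect_true(all(g$start[-1][same] >= g$end[-nrow(g)][same]))
  # strand-aware start codon lies inside the gene
  expect_true(all(g$cds_start >= g$start & g$cds_start < g$end))
})

test_that("planted repeat fraction is close to the target", {
  cfg <- sim_config(seed = 3, n_chromosomes = 1, chrom_length = 1e6,
                    n_accessions = 2, n_genes = 10,
                    repeat_fraction = 0.3)
  piv <- simulate_pivot(cfg)
  frac <- sum(piv$repeats$end - piv$repeats$start) / 1e6
  expect_gt(frac, 0.25)
  expect_lt(frac, 0.35)
})

test_that("zero SV rates give truth-free accessions identical to pivot", {
  cfg <- sim_config(seed = 5, n_chromosomes = 1, chrom_length = 2e5,
                    n_accessions = 2, n_genes = 5,
                    sv_rates = c(pav_deletion = 0, pav_insertion = 0,
                                 cnv = 0, inversion = 0,
                                 small_indel = 0, snp = 0))
  piv <- simulate_pivot(cfg)
  tr <- plant_svs(piv, cfg)
  expect_equal(nrow(tr$truth), 0)
  expect_identical(as.character(tr$sequences[["acc01.chr01"]]),
                   as.character(piv$sequences[["chr01"]]))
})

test_that("a planted deletion shortens the accession by its exact size", {
  cfg <- sim_config(seed = 7, n_chromosomes = 1, chrom_length = 2e5,
                    n_accessions = 1, n_genes = 5,
                    sv_rates = c(pav_deletion = 5, pav_insertion = 0,
                                 cnv = 0, inversion = 0,
                                 small_indel = 0, snp = 0),
                    size_ranges = list(pav_deletion = c(2570L, 2570L),
                                       pav_insertion = c(50L, 100L),
                                       cnv = c(100L, 200L),
                                       inversion = c(1000L, 2000L),
                                       small_indel = c(5L, 49L),
                                       snp = c(1L, 1L)))
  piv <- simulate_pivot(cfg)
  tr <- plant_svs(piv, cfg)
  n_del <- nrow(tr$truth)
  expect_gt(n_del, 0)
  expect_true(all(tr$truth$pivot_end - tr$truth$pivot_start == 2570))
  expect_equal(nchar(as.character(tr$sequences[["acc01.chr01"]])),
               2e5 - 2570 * n_del)
})

test_that("re-applying the truth set reconstructs each accession exactly", {
  co <- tiny_cohort()
  src <- as.character(co$pivot$sequences)
  for (acc in co$cfg$accessions) {
    tt <- co$truth$truth[co$truth$truth$accession == acc, ]
    for (ch in names(co$pivot$chrom_lengths)) {
      ev <- tt[tt$chrom == ch, ]
      ev <- ev[order(ev$pivot_start), ]
      # independent reconstruction with plain substr splicing
      out <- ""
      cur <- 0L
      for (i in seq_len(nrow(ev))) {
        out <- paste0(out, substr(src[[ch]], cur + 1L, ev$pivot_start[i]))
        cls <- ev$sv_class[i]
        if (cls %in% c("PAV_INS") ||
            (cls == "SMALL_INDEL" && ev$indel_type[i] == "INS")) {
          out <- paste0(out, ev$payload[i])
          cur <- ev$pivot_start[i]
        } else if (cls %in% c("PAV_DEL", "CNV") ||
                   (cls == "SMALL_INDEL" && ev$indel_type[i] == "DEL")) {
          cur <- ev$pivot_end[i]
        } else if (cls == "INV") {
          seg <- substr(src[[ch]], ev$pivot_start[i] + 1L, ev$pivot_end[i])
          comp <- chartr("ACGT", "TGCA", seg)
          out <- paste0(out, paste(rev(strsplit(comp, "")[[1]]),
                                   collapse = ""))
          cur <- ev$pivot_end[i]
        } else { # SNP
          out <- paste0(out, ev$payload[i])
          cur <- ev$pivot_end[i]
        }
      }
      out <- paste0(out, substr(src[[ch]], cur + 1L, nchar(src[[ch]])))
      expect_identical(out,
                       as.character(co$truth$sequences[[paste(acc, ch,
                                                              sep = ".")]]),
                       label = paste("reconstruction of", acc, ch))
    }
  }
})

test_that("false-negative noise drops records at the binomial rate", {
  co <- tiny_cohort()
  tt <- co$truth$truth[co$truth$truth$accession == "acc01", ]
  n_events <- sum(!is.na(vapply(seq_len(nrow(tt)), function(i)
    pansv:::emission_annotation(tt$sv_class[i], tt$indel_type[i],
                                "syri"), character(1))))
  fnr <- 0.2
  counts <- vapply(1:20, function(s)
    nrow(emit_caller_calls(tt, "syri", "pairwise", "acc01",
                           noise = list(fn_rate = fnr), seed = s)),
    numeric(1))
  expected <- n_events * (1 - fnr)
  tol <- 3 * sqrt(n_events * fnr * (1 - fnr)) / sqrt(20)
  expect_lt(abs(mean(counts) - expected), max(tol, 3))
})

test_that("emission is deterministic and frame-symmetric", {
  co <- tiny_cohort()
  a1 <- emit_caller_calls(co$truth, "assemblytics", "pairwise", "acc02",
                          seed = 9)
  a2 <- emit_caller_calls(co$truth, "assemblytics", "pairwise", "acc02",
                          seed = 9)
  expect_identical(a1, a2)
  # a pivot-frame deletion is an insertion-type record reciprocally
  r <- emit_caller_calls(co$truth, "assemblytics", "reciprocal", "acc02")
  tt <- co$truth$truth
  dels <- tt$id[tt$accession == "acc02" & tt$sv_class == "PAV_DEL"]
  expect_true(all(r$annotation[r$id %in% dels] == "Insertion"))
  expect_true(all(r$query_start[r$id %in% dels] ==
                    tt$pivot_start[match(dels, tt$id)]))
})

test_that("phenotype encoding and co-segregation directives work", {
  expect_equal(encode_phenotype("erect"), 1)
  expect_equal(encode_phenotype("intermediate"), 3)
  expect_equal(encode_phenotype("pendent"), 6)
  expect_error(encode_phenotype("sideways"), "unknown")
  cfg <- tiny_config()
  ph <- simulate_phenotypes(cfg, coseg = list(group = "groupA"))
  expect_true(all(ph$code[ph$group == "groupA"] == 1))
  expect_true(all(ph$code[ph$group == "groupB"] == 6))
  # no directive: deterministic under seed, labels from the scale
  p1 <- simulate_phenotypes(cfg)
  p2 <- simulate_phenotypes(cfg)
  expect_identical(p1, p2)
  expect_true(all(p1$label %in% c("erect", "intermediate", "pendent")))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(size_ranges = list(
    pav_deletion = c(50L, 5000L), pav_insertion = c(50L, 5000L),
    cnv = c(100L, 2000L), inversion = c(1000L, 10000L),
    small_indel = c(3L, 49L), snp = c(1L, 1L))), "small_indel")
  expect_error(sim_config(sv_rates = c(pav_deletion = -1,
                                       pav_insertion = 4, cnv = 2,
                                       inversion = 1, small_indel = 6,
                                       snp = 3)), "sv_rates")
  expect_error(sim_config(caller_noise = list(
    assemblytics = list(fn_rate = 1.4, jitter_sd = 0,
                        confusion_rate = 0),
    syri = list(fn_rate = 0, jitter_sd = 0, confusion_rate = 0))),
    "fn_rate")
})
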