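# Nonredundant locus merging, presence/absence matrix, pan-graph, and
# VCF/GFA round-trips.

mk_call <- function(acc, cls, s, e, size = e - s, payload = "") {
  data.frame(accession = acc, sv_class = cls, chrom = "chr01",
             start = as.integer(s), end = as.integer(e),
             size = as.integer(size), support = "truth:pairwise",
             source_ids = paste0(acc, s), payload = payload,
             stringsAsFactors = FALSE)
}

test_that("identical calls across accessions collapse to one locus", {
  calls <- do.call(rbind, lapply(sprintf("a%d", 1:5), function(a)
    mk_call(a, "PAV_DEL", 1000, 3570)))
  loci <- merge_nonredundant(calls)
  expect_equal(nrow(loci$loci), 1)
  expect_equal(loci$loci$n_members, 5)
  expect_equal(loci$loci$rep_size, 2570)
})

test_that("low-overlap deletions stay separate loci", {
  calls <- rbind(mk_call("a1", "PAV_DEL", 0, 1000),
                 mk_call("a2", "PAV_DEL", 900, 1900))
  expect_equal(nrow(merge_nonredundant(calls)$loci), 2)
  expect_error(merge_nonredundant(mk_call("a1", "CNV", 0, 100)),
               "PAV_DEL/PAV_INS")
})

test_that("jittered multi-accession loci match the brute-force clustering", {
  set.seed(202)
  n_loci <- 60
  base_s <- cumsum(sample(5000:12000, n_loci, replace = TRUE))
  base_len <- sample(100:2000, n_loci, replace = TRUE)
  accs <- sprintf("acc%02d", 1:6)
  rows <- list()
  for (a in accs) {
    carry <- runif(n_loci) < 0.7
    if (a == accs[1]) carry <- rep(TRUE, n_loci)  # every locus carried
    for (i in which(carry)) {
      j <- as.integer(round(rnorm(1, 0, 10)))
      rows[[length(rows) + 1L]] <- mk_call(
        a, "PAV_DEL", base_s[i] + j, base_s[i] + base_len[i] + j)
    }
  }
  calls <- do.call(rbind, rows)
  loci <- merge_nonredundant(calls)
  expect_equal(nrow(loci$loci), n_loci)
  # cluster assignments equal the brute-force single-linkage oracle
  comp_fast <- pansv:::cluster_calls(calls, match_params(),
                                     recip_overlap = 0.8)
  comp_brute <- brute_cluster(calls, 0.8, 100L)
  expect_equal(length(unique(comp_fast)), length(unique(comp_brute)))
  expect_true(all(tapply(comp_brute, comp_fast, function(x)
    length(unique(x))) == 1))
})

test_that("no two merged loci of one type still satisfy the criterion", {
  co <- tiny_cohort()
  loci <- merge_nonredundant(truth_to_calls(co$truth))$loci
  for (tp in c("DEL", "INS")) {
    l <- loci[loci$sv_type == tp, ]
    if (nrow(l) < 2) next
    iv <- data.frame(chrom = l$chrom, start = l$start, end = l$end,
                     size = l$rep_size, id = l$locus_id,
                     stringsAsFactors = FALSE)
    comp <- brute_cluster(iv, 0.8, 100L)
    expect_equal(length(unique(comp)), nrow(l))
  }
})

test_that("presence/absence matrix states follow membership", {
  calls <- rbind(mk_call("A", "PAV_DEL", 100, 400),
                 mk_call("B", "PAV_DEL", 100, 400))
  loci <- merge_nonredundant(calls)
  m <- build_pa_matrix(loci, c("A", "B", "C"),
                       called_accessions = c("A", "B"))
  expect_equal(unname(m[1, ]), c("present", "present", "missing"))
  m2 <- build_pa_matrix(loci, c("A", "B", "C"))
  expect_equal(unname(m2[1, ]), c("present", "present", "absent"))
  expect_error(build_pa_matrix(loci, c("A")), "not in accession list")
  # planted group-specific PAV equals the group indicator
  co <- tiny_cohort()
  tc <- truth_to_calls(co$truth)
  lo <- merge_nonredundant(tc)
  mm <- build_pa_matrix(lo, co$cfg$accessions)
  one <- lo$members[lo$members$locus_id == lo$loci$locus_id[1], ]
  expect_equal(sort(colnames(mm)[mm[lo$loci$locus_id[1], ] == "present"]),
               sort(one$accession))
})

test_that("empty input yields an empty locus set and 0-row matrix", {
  loci <- merge_nonredundant(pansv:::empty_calls())
  expect_equal(nrow(loci$loci), 0)
  m <- build_pa_matrix(loci, c("A", "B"))
  expect_equal(dim(m), c(0L, 2L))
})

test_that("graph construction handles the no-locus and one-DEL cases", {
  piv <- structure(list(
    sequences = Biostrings::DNAStringSet(c(chr01 = strrep("ACGT", 25))),
    chrom_lengths = c(chr01 = 100L)), class = "pansv_pivot")
  empty <- merge_nonredundant(pansv:::empty_calls())
  g0 <- build_graph(piv, empty)
  expect_equal(nrow(g0$nodes), 1)
  expect_identical(spell_path(g0, "pivot.chr01"), strrep("ACGT", 25))
  loci <- merge_nonredundant(mk_call("A", "PAV_DEL", 20, 60))
  m <- build_pa_matrix(loci, c("A", "B"))
  g1 <- build_graph(piv, loci, m)
  bb <- g1$nodes[g1$nodes$type == "backbone", ]
  expect_equal(nrow(bb), 3)
  expect_equal(nrow(g1$edges), 3)  # two adjacencies + one bypass
  expect_identical(spell_path(g1, "A.chr01"),
                   paste0(substr(strrep("ACGT", 25), 1, 20),
                          substr(strrep("ACGT", 25), 61, 100)))
  expect_identical(spell_path(g1, "B.chr01"), strrep("ACGT", 25))
  bad <- loci
  bad$loci$end <- 200L
  expect_error(build_graph(piv, bad), "beyond chromosome end")
})

test_that("accession paths spell the simulated genomes for PAV-only cohorts", {
  cfg <- sim_config(seed = 31, n_chromosomes = 2, chrom_length = 5e5,
                    n_accessions = 4, n_genes = 10,
                    sv_rates = c(pav_deletion = 6, pav_insertion = 6,
                                 cnv = 0, inversion = 0,
                                 small_indel = 0, snp = 0))
  piv <- simulate_pivot(cfg)
  tr <- plant_svs(piv, cfg)
  loci <- merge_nonredundant(truth_to_calls(tr))
  m <- build_pa_matrix(loci, cfg$accessions)
  g <- build_graph(piv, loci, m)
  for (acc in cfg$accessions) {
    for (ch in names(piv$chrom_lengths)) {
      expect_identical(spell_path(g, paste(acc, ch, sep = ".")),
                       as.character(tr$sequences[[paste(acc, ch,
                                                        sep = ".")]]),
                       label = paste("path", acc, ch))
    }
  }
})

test_that("VCF export round-trips and encodes genotypes correctly", {
  cfg <- sim_config(seed = 33, n_chromosomes = 1, chrom_length = 2e5,
                    n_accessions = 3, n_genes = 5,
                    sv_rates = c(pav_deletion = 10, pav_insertion = 10,
                                 cnv = 0, inversion = 0,
                                 small_indel = 0, snp = 0))
  piv <- simulate_pivot(cfg)
  tr <- plant_svs(piv, cfg)
  loci <- merge_nonredundant(truth_to_calls(tr))
  m <- build_pa_matrix(loci, cfg$accessions)
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_pav_vcf(loci, m, piv, f1)
  rt <- read_pav_vcf(f1)
  expect_equal(rt$loci$loci$start, loci$loci$start)
  expect_equal(rt$loci$loci$end, loci$loci$end)
  expect_equal(rt$loci$loci$sv_type, loci$loci$sv_type)
  expect_identical(rt$matrix, m)
  write_pav_vcf(rt$loci, rt$matrix, piv, f2)
  expect_identical(readLines(f1), readLines(f2))
  # single-carrier deletion has GT 1 only for the carrier
  lid <- loci$loci$locus_id[loci$loci$n_members == 1][1]
  if (!is.na(lid)) {
    line <- grep(lid, readLines(f1), value = TRUE, fixed = TRUE)
    gt <- strsplit(line, "\t")[[1]][-(1:9)]
    expect_equal(sum(gt == "1"), 1)
  }
})

test_that("written VCF parses with an independent VCF reader", {
  skip_if_not_installed("VariantAnnotation")
  cfg <- sim_config(seed = 34, n_chromosomes = 1, chrom_length = 2e5,
                    n_accessions = 3, n_genes = 5,
                    sv_rates = c(pav_deletion = 8, pav_insertion = 8,
                                 cnv = 0, inversion = 0,
                                 small_indel = 0, snp = 0))
  piv <- simulate_pivot(cfg)
  tr <- plant_svs(piv, cfg)
  loci <- merge_nonredundant(truth_to_calls(tr))
  m <- build_pa_matrix(loci, cfg$accessions)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_pav_vcf(loci, m, piv, f)
  v <- VariantAnnotation::readVcf(f)
  expect_equal(nrow(v), nrow(loci$loci))
  expect_equal(sort(colnames(v)), sort(cfg$accessions))
  pos <- BiocGenerics::start(SummarizedExperiment::rowRanges(v))
  expect_equal(length(pos), nrow(loci$loci))
})

test_that("GFA round-trip is byte-identical", {
  piv <- structure(list(
    sequences = Biostrings::DNAStringSet(c(chr01 = strrep("AC", 50))),
    chrom_lengths = c(chr01 = 100L)), class = "pansv_pivot")
  loci <- merge_nonredundant(rbind(
    mk_call("A", "PAV_DEL", 10, 70),
    mk_call("B", "PAV_INS", 80, 80, size = 6, payload = "TTTTTT")))
  m <- build_pa_matrix(loci, c("A", "B"))
  g <- build_graph(piv, loci, m)
  f1 <- withr::local_tempfile(fileext = ".gfa")
  f2 <- withr::local_tempfile(fileext = ".gfa")
  write_gfa(g, f1)
  write_gfa(read_gfa(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})
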