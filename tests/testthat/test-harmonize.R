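# Caller parsing, reciprocal projection, matching, and consensus
# classification.

test_that("Assemblytics dialect parses field-for-field", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    paste("#reference", "ref_start", "ref_stop", "ID", "size", "strand",
          "type", "ref_gap_size", "query_gap_size", "query_coordinates",
          "method", sep = "\t"),
    "chr01\t1000\t3570\tsv1\t2570\t+\tDeletion\t2570\t0\tacc.chr01:1000-1000:+\tbetween_alignments"),
    f)
  rec <- parse_assemblytics(f)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$annotation, "Deletion")
  expect_equal(rec$ref_end - rec$ref_start, 2570)
  expect_equal(rec$query_start, 1000)
})

test_that("header-only and malformed Assemblytics files are handled", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("#reference\tref_start\tref_stop", f)
  expect_equal(nrow(parse_assemblytics(f)), 0)
  writeLines(c("chr01\t10\t20"), f)
  expect_error(parse_assemblytics(f), "line 1")
})

test_that("SyRI dialect parses and skips non-variant rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "chr01\t5001\t10000\tacc.chr01\t5001\t10000\tid1\t-\tINVAL",
    "chr01\t1\t4999\tacc.chr01\t1\t4999\tid2\t-\tSYN"), f)
  rec <- parse_syri(f)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$annotation, "INVAL")
  expect_equal(rec$ref_end - rec$ref_start, 5000)
  expect_equal(attr(rec, "ignored"), 1)
  writeLines("chr01\tX\t10\ta\t1\t10\tid\t-\tDEL", f)
  expect_error(parse_syri(f), "line 1")
})

test_that("emitted files round-trip through the parsers losslessly", {
  co <- tiny_cohort()
  acc <- "acc03"
  tt <- co$truth$truth[co$truth$truth$accession == acc, ]
  for (spec in list(list("assemblytics", "pairwise"),
                    list("assemblytics", "reciprocal"),
                    list("syri", "pairwise"),
                    list("syri", "reciprocal"))) {
    f <- withr::local_tempfile()
    rec <- emit_caller_calls(co$truth, spec[[1]], spec[[2]], acc,
                             path = f)
    parsed <- if (spec[[1]] == "assemblytics")
      parse_assemblytics(f, direction = spec[[2]])
    else parse_syri(f, direction = spec[[2]])
    expect_equal(nrow(parsed), nrow(rec))
    expect_equal(parsed$ref_start, rec$ref_start)
    expect_equal(parsed$ref_end, rec$ref_end)
    expect_equal(parsed$annotation, rec$annotation)
    expect_equal(parsed$query_start, rec$query_start)
  }
})

test_that("reciprocalize swaps frames, exchanges labels, and is an involution", {
  rec <- data.frame(caller = "syri", direction = "reciprocal",
                    ref_chrom = "acc.chr01", ref_start = 5000L,
                    ref_end = 7000L, query_chrom = "chr01",
                    query_start = 7000L, query_end = 7000L,
                    annotation = "DEL", size = 2000L, id = "x",
                    stringsAsFactors = FALSE)
  rp <- reciprocalize(rec)
  expect_equal(rp$ref_chrom, "chr01")
  expect_equal(rp$ref_start, 7000)
  expect_equal(rp$ref_end, 7000)
  expect_equal(rp$annotation, "INS")
  expect_identical(reciprocalize(rp), rec)
  rec$query_start <- NA_integer_
  expect_error(reciprocalize(rec), "query coordinates")
  # expansion/contraction labels exchange as well
  expect_equal(pansv:::flip_annotation(c("Tandem_expansion",
                                         "Repeat_contraction", "HDR")),
               c("Tandem_contraction", "Repeat_expansion", "HDR"))
})

test_that("match_calls agrees exactly with the brute-force oracle", {
  set.seed(101)
  for (rep in 1:8) {
    a <- random_intervals(80)
    b <- a
    jit <- as.integer(round(rnorm(nrow(b), 0, 10)))
    b$start <- pmax(0L, b$start + jit)
    b$end <- pmax(b$start + 1L, b$end + jit)
    b <- b[sample(nrow(b), 60), ]
    rownames(b) <- NULL
    m <- match_calls(a, b)
    o <- brute_match(a, b)
    expect_identical(m[order(m$a_idx), c("a_idx", "b_idx")],
                     o[order(o$a_idx), c("a_idx", "b_idx")])
  }
})

test_that("match_calls obvious cases behave", {
  a <- data.frame(chrom = "chr01", start = 0L, end = 100L, size = 100L,
                  id = "a1", stringsAsFactors = FALSE)
  b1 <- a; b1$id <- "b1"
  expect_equal(nrow(match_calls(a, b1)), 1)
  b2 <- data.frame(chrom = "chr01", start = 200L, end = 300L,
                   size = 100L, id = "b2", stringsAsFactors = FALSE)
  expect_equal(nrow(match_calls(a, b2)), 0)
  expect_equal(nrow(match_calls(a[0, ], b1)), 0)
})

test_that("consensus requires both callers and takes Assemblytics coordinates", {
  params <- match_params()
  mk <- function(caller, dir, ann, s, e, size, id)
    data.frame(caller = caller, direction = dir, ref_chrom = "chr01",
               ref_start = s, ref_end = e, query_chrom = "q",
               query_start = 0L, query_end = 0L, annotation = ann,
               size = size, id = id, stringsAsFactors = FALSE)
  af <- mk("assemblytics", "pairwise", "Deletion", 1000L, 3000L, 2000L,
           "a1")
  sf <- mk("syri", "pairwise", "DEL", 1010L, 2990L, 1980L, "s1")
  none <- pansv:::empty_records()
  both <- consensus_pav(af, none, sf, none, params, "acc")
  expect_equal(nrow(both), 1)
  expect_equal(both$sv_class, "PAV_DEL")
  expect_equal(both$start, 1000)   # Assemblytics member wins
  expect_equal(both$end, 3000)
  expect_true(grepl("assemblytics:pairwise", both$support))
  expect_true(grepl("syri:pairwise", both$support))
  # SyRI-only candidate is not emitted
  expect_equal(nrow(consensus_pav(none, none, sf, none, params, "acc")),
               0)
})

test_that("size boundaries split PAV from small indel correctly", {
  params <- match_params()
  mk <- function(caller, ann, s, size, id)
    data.frame(caller = caller, direction = "pairwise",
               ref_chrom = "chr01", ref_start = s,
               ref_end = s + size, query_chrom = "q", query_start = 0L,
               query_end = 0L, annotation = ann, size = size, id = id,
               stringsAsFactors = FALSE)
  none <- pansv:::empty_records()
  for (sz in c(4L, 49L, 50L)) {
    af <- mk("assemblytics", "Deletion", 100L, sz, "a")
    sf <- mk("syri", "DEL", 100L, sz, "s")
    pav <- consensus_pav(af, none, sf, none, params, "acc")
    si <- extract_small_indels(af, none, sf, none, params, "acc")
    if (sz == 50L) {
      expect_equal(pav$sv_class, "PAV_DEL")
      expect_equal(nrow(si), 0)
    } else if (sz == 49L) {
      expect_equal(nrow(pav), 0)
      expect_equal(si$sv_class, "SMALL_INDEL")
    } else {
      expect_equal(nrow(pav), 0)
      expect_equal(nrow(si), 0)
    }
  }
})

test_that("CNV candidates need both directions in both callers", {
  params <- match_params()
  mk <- function(caller, dir, ann, id)
    data.frame(caller = caller, direction = dir, ref_chrom = "chr01",
               ref_start = 1000L, ref_end = 1500L, query_chrom = "q",
               query_start = 0L, query_end = 0L, annotation = ann,
               size = 500L, id = id, stringsAsFactors = FALSE)
  none <- pansv:::empty_records()
  af <- mk("assemblytics", "pairwise", "Tandem_contraction", "a1")
  ar <- mk("assemblytics", "reciprocal", "Tandem_contraction", "a2")
  sf <- mk("syri", "pairwise", "CPL", "s1")
  sr <- mk("syri", "reciprocal", "CPL", "s2")
  expect_equal(consensus_cnv(af, ar, sf, sr, params, "acc")$sv_class,
               "CNV")
  # pairwise-only Assemblytics candidate is insufficient
  expect_equal(nrow(consensus_cnv(af, none, sf, sr, params, "acc")), 0)
  # Assemblytics-only evidence is insufficient
  expect_equal(nrow(consensus_cnv(af, ar, none, none, params, "acc")), 0)
})

test_that("INVAL and SNP extraction honors the inversion size floor", {
  mk <- function(ann, s, e, id)
    data.frame(caller = "syri", direction = "pairwise",
               ref_chrom = "chr01", ref_start = s, ref_end = e,
               query_chrom = "q", query_start = s, query_end = e,
               annotation = ann, size = e - s, id = id,
               stringsAsFactors = FALSE)
  recs <- rbind(mk("INVAL", 0L, 3750000L, "i1"),
                mk("INVAL", 10L, 810L, "i2"),
                mk("SNP", 999L, 1000L, "s1"))
  out <- extract_inv_snp(recs, accession = "acc")
  expect_equal(sort(out$sv_class), c("INV", "SNP"))
  expect_equal(out$size[out$sv_class == "INV"], 3750000)
  expect_equal(attr(out, "dropped_inval"), 1)
})

test_that("noiseless harmonization recovers every class exactly", {
  co <- tiny_cohort()
  calls <- harmonize_cohort(co$truth, co$cfg)
  tt <- co$truth$truth
  tk <- truth_keys(tt)
  hk <- call_keys(calls$chrom, calls$start, calls$end, calls$sv_class,
                  calls$accession)
  for (cl in unique(tt$sv_class)) {
    expect_equal(mean(tk[tt$sv_class == cl] %in% hk), 1,
                 label = paste("recall", cl))
    expect_equal(mean(hk[calls$sv_class == cl] %in% tk), 1,
                 label = paste("precision", cl))
  }
  # class partition: no source record feeds two classes
  ids <- unlist(strsplit(calls$source_ids, ","))
  cls_of <- rep(calls$sv_class, lengths(strsplit(calls$source_ids, ",")))
  expect_true(all(tapply(cls_of, ids, function(x)
    length(unique(x))) == 1))
})

test_that("raising the overlap threshold never adds consensus calls", {
  co <- tiny_cohort()
  acc <- "acc01"
  noise <- list(jitter_sd = 15)
  e <- emit4(co$truth, acc, noise, seed = 77)
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9), function(f) {
    p <- match_params(min_reciprocal_overlap = f)
    nrow(consensus_pav(e$af, reciprocalize(e$ar), e$sf,
                       reciprocalize(e$sr), p, acc))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
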