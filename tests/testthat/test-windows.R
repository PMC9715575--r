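# Window geometry, hotspot/differential selection, GWAS overlap and TE
# association.

mk_track <- function(values, L = 1e6, window = 1e6, step = 2e5) {
  grid <- window_grid(c(chr01 = L), window, step)
  stopifnot(length(values) == nrow(grid$windows))
  structure(list(grid = grid,
                 values = matrix(values, ncol = 1,
                                 dimnames = list(NULL, "count")),
                 label = "count"), class = "density_track")
}

pav_call <- function(s, e, acc = "a1", chrom = "chr01") {
  data.frame(accession = acc, sv_class = "PAV_DEL", chrom = chrom,
             start = as.integer(s), end = as.integer(e),
             size = as.integer(e - s), support = "x", source_ids = "x",
             payload = "", stringsAsFactors = FALSE)
}

test_that("window geometry puts interior midpoints in exactly 5 windows", {
  grid <- window_grid(c(chr01 = 5e6))
  expect_error(window_grid(c(chr01 = 0)), "zero-length")
  expect_error(window_grid(c(chr01 = 1e6), 1e5, 2e5), "step")
  # enumerated expectation: window starts in (mp - W, mp]
  for (mp in c(1e6, 2500000, 3999999)) {
    tr <- window_counts(pav_call(mp - 50, mp + 50), grid)
    expect_equal(sum(tr$values), 5, label = paste("midpoint", mp))
  }
  # first 200 kb: exactly 1 window
  tr <- window_counts(pav_call(100, 300), grid)
  expect_equal(sum(tr$values), 1)
  w <- tr$grid$windows
  expect_equal(unname(tr$values[w$start == 0, 1]), 1)
  # terminal windows are clipped, kept and flagged
  expect_true(all(w$end <= 5e6))
  expect_equal(sum(w$terminal), 4)
  expect_equal(w$end[nrow(w)] - w$start[nrow(w)], 2e5)
  # no calls -> all-zero track
  expect_true(all(window_counts(pav_call(1, 2)[0, ], grid)$values == 0))
})

test_that("every variant contributes identical interior track mass", {
  co <- tiny_cohort()
  grid <- window_grid(co$pivot$chrom_lengths, 2e5, 4e4)
  calls <- truth_to_calls(co$truth)
  # keep variants whose midpoint is interior (>= W from both ends)
  mp <- ifelse(calls$end > calls$start,
               (calls$start + calls$end) %/% 2, calls$start)
  interior <- mp >= 2e5 & mp < 1e6 - 2e5
  tr <- window_counts(calls[interior, ], grid)
  expect_equal(sum(tr$values), sum(interior) * 5)
})

test_that("hotspot selection keeps ties and merges adjacent windows", {
  v <- rep(3, 25)
  expect_warning(h <- hotspots(mk_track(v, L = 5e6)), "fewer than 100")
  # constant track: every window ties at the threshold
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 0)
  expect_equal(h$end, 5e6)
  # top-1% of 6000 windows selects at least 60
  set.seed(9)
  v <- rpois(6000, 5)
  grid <- window_grid(c(chr01 = 6000 * 2e5))
  tr <- structure(list(grid = grid,
                       values = matrix(v, ncol = 1,
                                       dimnames = list(NULL, "count")),
                       label = "count"), class = "density_track")
  thr <- quantile(v, 0.99, type = 1)
  expect_gte(sum(v >= thr), 60)
})

test_that("quantile monotonicity: higher quantile, fewer selected windows", {
  set.seed(10)
  v <- rpois(500, 4)
  grid <- window_grid(c(chr01 = 500 * 2e5))
  tr <- structure(list(grid = grid,
                       values = matrix(v, ncol = 1,
                                       dimnames = list(NULL, "count")),
                       label = "count"), class = "density_track")
  n_sel <- vapply(c(0.5, 0.8, 0.95, 0.99), function(q) {
    thr <- quantile(v, q, type = 1)
    sum(v >= thr)
  }, numeric(1))
  expect_true(all(diff(n_sel) <= 0))
  r1 <- hotspots(tr, 0.95)
  r2 <- hotspots(tr, 0.99)
  expect_lte(sum(r2$end - r2$start), sum(r1$end - r1$start))
})

test_that("group differential is the gap of group means", {
  grid <- window_grid(c(chr01 = 4e5))
  vals <- cbind(a1 = c(2, 0), a2 = c(4, 0), b1 = c(1, 0), b2 = c(1, 0),
                b3 = c(1, 0))
  tr <- structure(list(grid = grid, values = vals, label = "x"),
                  class = "density_track")
  d <- group_differential(tr, c("a1", "a2"), c("b1", "b2", "b3"))
  expect_equal(unname(d$values[1, "signed"]), 2)
  expect_equal(unname(d$values[1, "abs"]), 2)
  expect_equal(unname(d$values[2, "signed"]), 0)
  expect_error(group_differential(tr, character(), "b1"), "non-empty")
  # identical groups give an all-zero differential
  d0 <- group_differential(tr, c("b1", "b2"), c("b3"))
  expect_true(all(d0$values[, "signed"] == 0))
})

test_that("top-fraction selection spans the genome at fraction 1", {
  v <- c(5, 1, 2, 0, 3)
  tr <- mk_track(v, L = 5 * 2e5)
  all_r <- top_fraction_regions(tr, fraction = 1)
  expect_equal(nrow(all_r), 1)
  expect_equal(all_r$end - all_r$start, 5 * 2e5)
})

test_that("planted hotspot and differential regions are recovered", {
  cfg <- sim_config(
    seed = 55, n_chromosomes = 1, chrom_length = 5e6,
    n_accessions = 6, n_genes = 10,
    group_enrichment = list(
      list(chrom = "chr01", start = 2.0e6, end = 2.4e6,
           sv_class = "pav_deletion", group = "all", rate = 72)))
  piv <- simulate_pivot(cfg)
  calls <- truth_to_calls(plant_svs(piv, cfg))
  grid <- window_grid(piv$chrom_lengths)
  pooled <- window_counts(calls, grid)
  suppressWarnings(hs <- hotspots(pooled, 0.99))
  covered <- any(hs$chrom == "chr01" & hs$start <= 2.0e6 &
                   hs$end >= 2.4e6)
  expect_true(covered, label = "hotspot region covers planted cluster")
  cfg_d <- sim_config(
    seed = 56, n_chromosomes = 1, chrom_length = 5e6,
    n_accessions = 6, n_genes = 10,
    group_enrichment = list(
      list(chrom = "chr01", start = 3.6e6, end = 4.0e6,
           sv_class = "pav_deletion", group = "groupA", rate = 72)))
  piv_d <- simulate_pivot(cfg_d)
  calls_d <- truth_to_calls(plant_svs(piv_d, cfg_d))
  byacc <- window_counts(calls_d, window_grid(piv_d$chrom_lengths),
                         by = "accession",
                         accessions = cfg_d$accessions)
  ga <- names(cfg_d$group_labels)[cfg_d$group_labels == "groupA"]
  gb <- names(cfg_d$group_labels)[cfg_d$group_labels == "groupB"]
  diff <- group_differential(byacc, ga, gb)
  top <- top_fraction_regions(diff, 0.05)
  expect_true(any(top$chrom == "chr01" & top$start <= 3.6e6 &
                    top$end >= 4.0e6),
              label = "differential region covers planted cluster")
  # the planted windows maximize the absolute gap
  w <- window_grid(piv_d$chrom_lengths)$windows
  expect_true(w$start[which.max(diff$values[, "abs"])] >= 2.8e6)
})

test_that("gwas overlap labels match the brute-force overlap oracle", {
  regions <- data.frame(chrom = "chr01", start = 2e6, end = 3e6,
                        stringsAsFactors = FALSE)
  gwas <- data.frame(chrom = "chr01",
                     start = c(1.5e6, 3.95e6, 4.5e6),
                     end = c(1.6e6, 4.2e6, 4.6e6),
                     stringsAsFactors = FALSE)
  ov <- gwas_overlap(regions, gwas, flank = 1e6)
  expect_equal(ov$intervals$label,
               c("contained", "overlapping", "disjoint"))
  ov0 <- gwas_overlap(regions, gwas[3, ], flank = 0)
  expect_equal(ov0$intervals$label, "disjoint")
  set.seed(77)
  for (rep in 1:5) {
    rg <- random_intervals(40, L = 5e6, max_len = 3e5)
    gw <- random_intervals(30, L = 5e6, max_len = 2e5)
    res <- gwas_overlap(rg[, c("chrom", "start", "end")],
                        gw[, c("chrom", "start", "end")], flank = 1e5)
    brute <- brute_gwas_overlap_bp(rg, gw, 1e5)
    expect_equal(res$intervals$overlap_bp, brute)
  }
})

test_that("TE association flags degenerate input and finds construction", {
  grid <- window_grid(c(chr01 = 2e6))
  calls <- do.call(rbind, lapply(seq(1e5, 1.9e6, 1e5), function(s)
    pav_call(s, s + 100)))
  tr <- window_counts(calls, grid)
  # zero repeat coverage -> NA correlation with flag
  r0 <- te_pav_association(tr, data.frame(chrom = character(),
                                          start = integer(),
                                          end = integer(),
                                          class = character()))
  expect_true(r0$degenerate)
  expect_true(is.na(r0$cor_overall))
  expect_true(all(r0$table$te_frac == 0))
  # repeats co-located with PAVs -> positive correlation
  reps <- data.frame(chrom = "chr01",
                     start = as.integer(seq(1e5, 9e5, 1e5)) - 50000L,
                     end = as.integer(seq(1e5, 9e5, 1e5)) + 50000L,
                     class = "LTR", stringsAsFactors = FALSE)
  calls2 <- do.call(rbind, lapply(seq(1e5, 9e5, 1e5), function(s)
    rbind(pav_call(s, s + 100), pav_call(s + 10, s + 90))))
  tr2 <- window_counts(calls2, grid)
  r2 <- te_pav_association(tr2, reps)
  expect_gt(r2$cor_overall, 0.5)
  # window fully covered by one repeat has fraction 1
  full <- te_pav_association(tr, data.frame(chrom = "chr01", start = 0L,
                                            end = 2e6,
                                            class = "LTR",
                                            stringsAsFactors = FALSE))
  expect_true(all(full$table$te_frac == 1))
  # off-chromosome repeats are clipped with a warning
  expect_warning(te_pav_association(tr, data.frame(
    chrom = "chr01", start = 1.5e6, end = 2.5e6, class = "LTR",
    stringsAsFactors = FALSE)), "clipped")
})
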