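test_that("fisher_exact reproduces worked tables and the dhyper oracle", {
  flat <- fisher_exact(10, 10, 10, 10)
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$p_value, 1)

  t2 <- fisher_exact(8, 2, 1, 5)
  expect_equal(t2$odds_ratio, (8 * 5) / (2 * 1))
  expect_equal(t2$p_value, oracle_fisher_p(8, 2, 1, 5))

  t3 <- fisher_exact(0, 5, 5, 0)
  expect_equal(t3$odds_ratio, 0)
  expect_equal(t3$p_value, oracle_fisher_p(0, 5, 5, 0))

  expect_equal(fisher_exact(5, 0, 0, 5)$odds_ratio, Inf)
  expect_error(fisher_exact(0, 0, 0, 0), "all-zero")
  expect_error(fisher_exact(-1, 1, 1, 1), "non-negative")

  set.seed(111)
  for (i in 1:50) {
    cells <- as.integer(rmultinom(1, sample(5:60, 1), runif(4, 0.05, 1)))
    got <- fisher_exact(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got$p_value,
                 oracle_fisher_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
    # p also agrees with stats::fisher.test (same extremity rule)
    expect_equal(got$p_value,
                 stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("genome tiling is half-open with the partial tile kept", {
  t1 <- tile_genome(c(chr1 = 10000L))
  expect_length(t1, 10L)
  t2 <- tile_genome(c(chr1 = 1500L))
  expect_equal(GenomicRanges::width(t2), c(1000L, 500L))
  expect_equal(GenomicRanges::start(t2), c(1L, 1001L))
  expect_length(tile_genome(c(chr1 = 0L)), 0L)
})

test_that("tile enrichment detects planted proximity and rejects degeneracy", {
  truth <- data.table(chrom = "chr1",
                      start = c(100000L, 400000L, 700000L),
                      end = c(100700L, 400700L, 700700L))
  f <- simulate_feature_tracks(truth, c(chr1 = 1000000L),
                               enrichment_factor = 20,
                               background_density = 2e-4, seed = 3)
  e <- tile_enrichment(f, truth, c(chr1 = 1000000L))
  expect_lt(e$p_value, 0.01)
  expect_gt(e$odds_ratio, 1)

  all_feat <- data.table(chrom = "chr1", start = 0L, end = 1000000L)
  expect_error(tile_enrichment(all_feat, truth, c(chr1 = 1000000L)),
               "degenerate")
  expect_error(tile_enrichment(f[0], truth, c(chr1 = 1e6L)), "empty feature")
})

test_that("CpG weighting changes the tile table denominator", {
  regions <- data.table(chrom = "chr1", start = 5000L, end = 6000L)
  feats <- data.table(chrom = "chr1", start = c(5500L, 50000L),
                      end = c(5600L, 50100L))
  cpgs <- data.table(chrom = "chr1", pos = sample.int(100000L, 3000L))
  e <- tile_enrichment(feats, regions, c(chr1 = 100000L), cpg_pos = cpgs)
  expect_true(e$cpg_weighted)
  expect_equal(sum(e$table), nrow(cpgs))
})

test_that("proximity profile uses interval gaps with inclusive thresholds", {
  reg <- data.table(chrom = "chr1", start = 100L, end = 200L)
  feat <- data.table(chrom = "chr1", start = 300L, end = 400L)
  pp <- proximity_profile(reg, feat)
  expect_equal(pp$proportion, c(0, 1, 1))   # gap 100: not at 0, yes at 1 kb

  ov <- proximity_profile(reg, data.table(chrom = "chr1", start = 150L,
                                          end = 160L))
  expect_equal(ov$proportion, c(1, 1, 1))

  # exact boundary: gap of exactly d counts at threshold d
  b <- proximity_profile(reg, data.table(chrom = "chr1", start = 1200L,
                                         end = 1300L),
                         thresholds = c(0L, 999L, 1000L))
  expect_equal(b$proportion, c(0, 0, 1))
})

test_that("proximity profile equals the brute-force gap scan and is monotone", {
  set.seed(121)
  gap1 <- function(s1, e1, s2, e2)
    if (s1 < e2 && s2 < e1) 0L else max(s2 - e1, s1 - e2)
  for (i in 1:8) {
    reg <- data.table(chrom = sample(c("chr1", "chr2"), 25, TRUE),
                      start = sample.int(50000L, 25))
    reg[, end := start + sample.int(500L, 25)]
    feat <- data.table(chrom = sample(c("chr1", "chr2"), 12, TRUE),
                       start = sample.int(50000L, 12))
    feat[, end := start + sample.int(500L, 12)]
    th <- c(0L, 500L, 5000L)
    pp <- proximity_profile(reg, feat, th)
    want <- vapply(th, function(d) {
      hits <- vapply(seq_len(nrow(reg)), function(r) {
        ff <- feat[chrom == reg$chrom[r]]
        if (!nrow(ff)) return(FALSE)
        gaps <- vapply(seq_len(nrow(ff)), function(j)
          gap1(reg$start[r], reg$end[r], ff$start[j], ff$end[j]), integer(1))
        if (d == 0) any(gaps == 0L &
                          ff$start < reg$end[r] & reg$start[r] < ff$end)
        else any(gaps <= d)
      }, logical(1))
      mean(hits)
    }, numeric(1))
    expect_equal(pp$proportion, want)
    expect_true(all(diff(pp$proportion) >= 0))
  }
})

test_that("chromatin-state overlap collapses states and conserves mass", {
  segs <- data.table(chrom = "chr1",
                     start = c(0L, 4000L, 7000L),
                     end = c(4000L, 7000L, 10000L),
                     label = c("TssA", "Quies", "Enh"))
  inside <- data.table(chrom = "chr1", start = 1000L, end = 2000L)
  ov <- chromhmm_overlap(inside, segs, chrom_sizes = c(chr1 = 10000L))
  expect_equal(ov[group == "TSS", region_prop], 1)
  expect_equal(sum(ov$genome_prop), 1, tolerance = 1e-9)

  straddle <- data.table(chrom = "chr1", start = 3000L, end = 5000L)
  ov2 <- chromhmm_overlap(straddle, segs, chrom_sizes = c(chr1 = 10000L))
  expect_equal(ov2[group == "TSS", region_prop], 0.5)
  expect_equal(ov2[group == "Quiescent", region_prop], 0.5)
  expect_equal(sum(ov2$region_prop), 1, tolerance = 1e-9)

  bad <- copy(segs)[1, label := "NotAState"]
  expect_error(chromhmm_overlap(inside, bad), "unmapped")
})

test_that("mQTL enrichment recovers planted odds ratios and the null", {
  regions <- data.table(chrom = "chr1",
                        start = seq(0L, 900000L, 100000L),
                        end = seq(0L, 900000L, 100000L) + 10000L)
  gen <- function(or_boost, seed) {
    set.seed(seed)
    n <- 10000L
    pos <- sample.int(1000000L, n)
    inside <- pos_in <- vapply(pos, function(p)
      any(p >= regions$start & p < regions$end), logical(1))
    base <- 0.05
    p_m <- ifelse(inside, pmin(base * or_boost, 0.9), base)
    data.table(chrom = "chr1", pos = pos, mqtl = runif(n) < p_m,
               reliable = TRUE)
  }
  planted <- mqtl_enrichment(regions, gen(6, 1))
  expect_gt(planted$odds_ratio, 4)
  expect_lt(planted$odds_ratio, 9)
  expect_lt(planted$p_value, 1e-6)

  ors <- vapply(1:15, function(s)
    mqtl_enrichment(regions, gen(1, s))$odds_ratio, numeric(1))
  expect_lt(abs(mean(log(ors))), 0.25)    # null centred on OR 1
  expect_error(mqtl_enrichment(regions, data.table(chrom = character(),
                                                   pos = integer(),
                                                   mqtl = logical(),
                                                   reliable = logical())),
               "empty")
})

test_that("variance-explained summaries report median and IQR", {
  regions <- data.table(chrom = "chr1", start = 0L, end = 1000L)
  tbl <- data.table(chrom = "chr1", pos = c(10L, 20L, 30L),
                    prop = c(0.1, 0.23, 0.5))
  s <- variance_explained_summary(tbl, regions)
  expect_equal(s$median, 0.23)
  expect_equal(s$n, 3L)

  one <- variance_explained_summary(tbl[1], regions)
  expect_equal(one$median, 0.1)
  expect_equal(one$iqr, c(0.1, 0.1))

  set.seed(131)
  u <- data.table(chrom = "chr1", pos = sample.int(999L, 800L),
                  prop = runif(800))
  su <- variance_explained_summary(u, regions)
  expect_equal(su$median, 0.5, tolerance = 0.06)
  expect_equal(su$iqr, c(0.25, 0.75), tolerance = 0.06)
  expect_error(variance_explained_summary(tbl, data.table(chrom = "chr9",
                                                          start = 0L,
                                                          end = 10L)),
               "no variance-table CpGs")
})

test_that("region-overlap enrichment counts overlaps and matches the oracle", {
  cs <- c(chr1 = 100000L)
  q <- data.table(chrom = "chr1", start = c(1000L, 50000L),
                  end = c(2000L, 51000L))
  t_far <- data.table(chrom = "chr1", start = 80000L, end = 81000L)
  disjoint <- region_overlap_enrichment(q, t_far, cs)
  expect_equal(disjoint$overlap_count, 0L)

  nested <- region_overlap_enrichment(q, copy(q)[, `:=`(start = start - 100L,
                                                        end = end + 100L)],
                                      cs)
  expect_equal(nested$overlap_count, nrow(q))

  tiles <- tile_genome(cs)
  qf <- IRanges::overlapsAny(tiles, mescan:::as_granges(q))
  tf <- IRanges::overlapsAny(tiles, mescan:::as_granges(t_far))
  expect_equal(disjoint$p_value,
               oracle_fisher_p(sum(qf & tf), sum(qf & !tf),
                               sum(!qf & tf), sum(!qf & !tf)))
  expect_error(region_overlap_enrichment(q[0], t_far, cs), "empty")
})
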