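test_that("metastability verdicts reproduce the worked two-individual case", {
  co <- make_exact_cohort(list(A = c(t1 = 0.30, t2 = 0.32),
                               B = c(t1 = 0.50, t2 = 0.52)))
  v <- detect_me_cpgs(co)
  expect_equal(v$d_inter, rep(0.20, 2), tolerance = 1e-12)
  expect_equal(v$d_intra, rep(0.02, 2), tolerance = 1e-12)
  expect_true(all(v$passes))   # 0.20 >= 0.15 and 0.02 <= 0.20 / 3
})

test_that("identical methylation across samples never passes", {
  co <- make_exact_cohort(list(A = c(t1 = 0.4, t2 = 0.4),
                               B = c(t1 = 0.4, t2 = 0.4)))
  v <- detect_me_cpgs(co)
  expect_equal(v$d_inter, rep(0, 2))
  expect_false(any(v$passes))
})

test_that("verdicts match the brute-force inequality oracle on random grids", {
  set.seed(31)
  depth <- 1000L
  for (rep_ in 1:25) {
    n_ind <- sample(2:4, 1L); n_tis <- sample(2:3, 1L)
    m <- matrix(round(runif(n_ind * n_tis), 3), n_ind, n_tis,
                dimnames = list(paste0("I", seq_len(n_ind)),
                                paste0("t", seq_len(n_tis))))
    fr <- lapply(seq_len(n_ind), function(i) setNames(m[i, ], colnames(m)))
    names(fr) <- rownames(m)
    co <- make_exact_cohort(fr, pos = 100L, depth = depth)
    v <- detect_me_cpgs(co)
    o <- oracle_verdict(m)
    expect_equal(v$d_inter, o$d_inter, tolerance = 1e-9)
    expect_equal(v$d_intra, o$d_intra, tolerance = 1e-9)
    expect_equal(v$passes, o$passes)
  }
})

test_that("screen requires at least two individuals and two tissues", {
  expect_error(detect_me_cpgs(make_exact_cohort(
    list(A = c(t1 = 0.2, t2 = 0.4)))), ">= 2 individuals")
})

test_that("only fully covered CpGs are assessed", {
  co <- make_exact_cohort(list(A = c(t1 = 0.1, t2 = 0.1),
                               B = c(t1 = 0.9, t2 = 0.9)),
                          pos = c(100L, 200L))
  co$samples[[1]] <- co$samples[[1]][pos != 200L]   # drop coverage
  expect_equal(detect_me_cpgs(co)$pos, 100L)
})

test_that("SNP proximity filter is inclusive at the window boundary", {
  cpgs <- data.table(chrom = "chr1", pos = 1000L)
  snps_at <- function(p) data.table(chrom = "chr1", pos = p)
  expect_equal(nrow(filter_snp_proximal(cpgs, snps_at(1060L))), 0L)
  expect_equal(nrow(filter_snp_proximal(cpgs, snps_at(1061L))), 1L)
  expect_equal(nrow(filter_snp_proximal(cpgs, snps_at(940L))), 0L)
  expect_equal(filter_snp_proximal(cpgs, NULL), cpgs, ignore_attr = TRUE)
})

test_that("SNP filter equals the all-pairs distance oracle", {
  set.seed(41)
  for (rep_ in 1:10) {
    cp <- data.table(chrom = sample(c("chr1", "chr2"), 80, TRUE),
                     pos = sample.int(20000L, 80))
    sp <- data.table(chrom = sample(c("chr1", "chr2"), 15, TRUE),
                     pos = sample.int(20000L, 15))
    got <- filter_snp_proximal(cp, sp)
    keep <- !vapply(seq_len(nrow(cp)), function(i)
      any(oracle_snp_hit(cp$pos[i], sp[chrom == cp$chrom[i], pos])),
      logical(1))
    expect_equal(got[order(chrom, pos)],
                 cp[keep][order(chrom, pos)], ignore_attr = TRUE)
  }
})

test_that("dataset combination follows set semantics", {
  s1 <- data.table(chrom = "chr1", pos = c(1L, 2L, 3L))
  s2 <- data.table(chrom = "chr1", pos = c(2L, 3L, 4L))
  expect_equal(combine_datasets(list(s1, s2), "intersection")$pos, c(2L, 3L))
  expect_equal(combine_datasets(list(s1, s2), "union")$pos, 1:4)
  empty <- data.table(chrom = character(), pos = integer())
  expect_equal(nrow(combine_datasets(list(s1, empty), "intersection")), 0L)
  expect_error(combine_datasets(list(s1, s2), "xor"), "arg")
})

test_that("clustering chains by gap and enforces the member minimum", {
  one <- cluster_cpgs(data.table(chrom = "chr1", pos = c(0L, 250L, 500L, 750L)))
  expect_equal(nrow(one), 1L)
  expect_equal(one[, .(start, end, n_me_cpg)],
               data.table(start = 0L, end = 752L, n_me_cpg = 4L))
  none <- cluster_cpgs(data.table(chrom = "chr1",
                                  pos = c(0L, 400L, 800L, 1200L)))
  expect_equal(nrow(none), 0L)
})

test_that("clustering equals the quadratic single-linkage oracle", {
  set.seed(51)
  for (rep_ in 1:15) {
    pos <- sort(sample.int(10000L, sample(10:60, 1L)))
    got <- cluster_cpgs(data.table(chrom = "chrX", pos = pos))
    want <- oracle_cluster(pos)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$start, vapply(want, min, integer(1)))
      expect_equal(got$end, vapply(want, max, integer(1)) + 2L)
      expect_equal(got$n_me_cpg, lengths(want))
    }
  }
})

test_that("purity filter applies the 2:1 ME to non-ME rule", {
  me_pos <- c(0L, 100L, 200L, 300L)
  cl <- cluster_cpgs(data.table(chrom = "chr1", pos = me_pos))
  cov_with <- function(extra) data.table(chrom = "chr1",
                                         pos = sort(c(me_pos, extra)))
  expect_equal(nrow(purity_filter(cl, cov_with(c(50L, 150L)))), 1L)  # 4 >= 4
  expect_equal(nrow(purity_filter(cl, cov_with(c(50L, 150L, 250L)))), 0L)
  kept <- purity_filter(cl, cov_with(integer()))
  expect_equal(kept$n_non_me_cpg, 0L)                                # 4 >= 0
})

test_that("raising the interindividual threshold never adds ME-CpGs", {
  sim <- simulate_cohort(sim_config(chrom_sizes = c(chr1 = 300000L),
                                    n_me_regions = 6L, seed = 17))
  counts <- vapply(c(0.05, 0.15, 0.3, 0.5), function(th)
    sum(detect_me_cpgs(sim$cohorts$dsA, inter_threshold = th)$passes),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("control sampling matches the ME joint histogram and avoids MEs", {
  # covered CpGs laid out as many well-separated clusters of varied shape
  set.seed(61)
  n_cl <- 400L
  starts <- cumsum(rep(3000L, n_cl))
  sizes <- sample(4:12, n_cl, replace = TRUE)
  spacing <- sample(c(30L, 60L, 90L), n_cl, replace = TRUE)
  covered <- rbindlist(lapply(seq_len(n_cl), function(i)
    data.table(chrom = "chr1",
               pos = starts[i] + spacing[i] * (seq_len(sizes[i]) - 1L))))
  me <- cluster_cpgs(covered[pos < starts[40L]])    # first ~40 clusters
  me[, role := "ME"]
  ctl <- suppressWarnings(
    generate_control_clusters(covered, me, n_controls = 200L, seed = 5))
  expect_equal(nrow(ctl), 200L)
  expect_false(any(IRanges::overlapsAny(mescan:::as_granges(ctl),
                                        mescan:::as_granges(me))))
  # chi-squared GOF of the sampled joint histogram against the scaled ME one
  brk_s <- mescan:::bin_breaks(me$end - me$start, 5L)
  brk_c <- mescan:::bin_breaks(me$n_me_cpg, 5L)
  cells <- sort(unique(mescan:::joint_cell(me$end - me$start, me$n_me_cpg,
                                           brk_s, brk_c)))
  me_n <- table(factor(mescan:::joint_cell(me$end - me$start, me$n_me_cpg,
                                           brk_s, brk_c), cells))
  ctl_n <- table(factor(mescan:::joint_cell(ctl$end - ctl$start, ctl$n_cpg,
                                            brk_s, brk_c), cells))
  gof <- suppressWarnings(stats::chisq.test(as.integer(ctl_n),
                                            p = as.integer(me_n) / sum(me_n)))
  expect_gt(gof$p.value, 0.01)
  # determinism and caps
  expect_identical(ctl, suppressWarnings(
    generate_control_clusters(covered, me, n_controls = 200L, seed = 5)))
  expect_error(generate_control_clusters(covered, me[0], 10L), "empty ME")
  w <- testthat::capture_warnings(
    big <- generate_control_clusters(covered, me, n_controls = 10000L,
                                     seed = 1))
  expect_true(any(grepl("capping", w)))
  expect_lte(nrow(big), nrow(cluster_cpgs(covered)))
})

test_that("the full screen is deterministic and labels roles", {
  sim <- simulate_cohort(sim_config(chrom_sizes = c(chr1 = 300000L),
                                    n_me_regions = 8L, seed = 23))
  a <- run_me_screen(sim$cohorts, sim$snps)
  b <- run_me_screen(sim$cohorts, sim$snps)
  expect_identical(a$me_clusters, b$me_clusters)
  expect_true(all(a$me_clusters$role == "ME"))
  expect_warning(run_me_screen(sim$cohorts, NULL), "SNP filter skipped")
})
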