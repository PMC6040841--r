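# The generator is first-class code: these tests pin its distributional
# contracts so downstream recovery claims are interpretable.

small_cfg <- function(...) {
  args <- list(chrom_sizes = c(chr1 = 200000L), n_me_regions = 4L)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

test_that("identical seeds give bit-identical cohorts; truth is emitted", {
  a <- simulate_cohort(small_cfg(seed = 3))
  b <- simulate_cohort(small_cfg(seed = 3))
  expect_identical(a, b)
  expect_equal(nrow(a$truth), 4L)
  expect_true(all(c("chrom", "start", "end", "label") %in% names(a$truth)))
  # no planted regions -> empty truth
  none <- simulate_cohort(small_cfg(seed = 3, n_me_regions = 0L))
  expect_equal(nrow(none$truth), 0L)
})

test_that("planted per-individual means concentrate on the latent levels", {
  sim <- simulate_cohort(small_cfg(seed = 9, depth_mean = 100))
  lv <- attr(sim$truth, "latent_levels")
  cpgs <- sim$cpgs
  for (d in names(sim$cohorts)) {
    co <- sim$cohorts[[d]]
    for (ind in unique(co$meta$individual)) {
      sids <- co$meta[individual == ind, sample_id]
      for (r in seq_len(nrow(sim$truth))) {
        reg <- sim$truth[r]
        obs <- rbindlist(lapply(sids, function(s)
          co$samples[[s]][chrom == reg$chrom & pos >= reg$start &
                            pos < reg$end]))
        p <- lv[r, paste(d, ind, sep = ":")]
        # 3 binomial SDs on the pooled count
        tol <- 3 * sqrt(p * (1 - p) / sum(obs$n_total))
        expect_lt(abs(sum(obs$n_meth) / sum(obs$n_total) - p), tol)
      }
    }
  }
})

test_that("each planted region has both epigenotype groups in every dataset", {
  sim <- simulate_cohort(small_cfg(seed = 21, n_me_regions = 10L))
  lv <- attr(sim$truth, "latent_levels")
  ds <- sub(":.*", "", colnames(lv))
  for (d in unique(ds)) {
    sub_ <- lv[, ds == d, drop = FALSE]
    expect_true(all(apply(sub_, 1, max) - apply(sub_, 1, min) > 0.2))
  }
})

test_that("stage series tracks the configured background mean", {
  cfg <- small_cfg(
    seed = 5, n_me_regions = 0L,
    stage_trajectory = data.frame(stage = "s1", bg_mean = 0.8, me_mean = 0.4,
                                  intermediate_frac = 0, n_replicates = 2L,
                                  post_gastrulation = FALSE))
  stg <- simulate_stage_series(cfg)
  s <- stage_summary(stg$stages$s1, min_depth = 10)
  expect_lt(abs(s$mean - 0.8), 0.02)
})

test_that("replicates are distinct but distributionally matched", {
  stg <- simulate_stage_series(small_cfg(seed = 8))
  r1 <- stg$stages$ICM[[1]]; r2 <- stg$stages$ICM[[2]]
  expect_false(identical(r1$n_meth, r2$n_meth))
  f1 <- r1[n_total >= 10, n_meth / n_total]
  f2 <- r2[n_total >= 10, n_meth / n_total]
  # deterministic jitter breaks the depth-induced ties for the KS test
  set.seed(1)
  ks <- stats::ks.test(f1 + runif(length(f1), -1e-4, 1e-4),
                       f2 + runif(length(f2), -1e-4, 1e-4))
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate intermediate fraction leaves only the extreme-Beta tail", {
  traj <- default_stage_trajectory()
  traj$intermediate_frac <- 0
  stg <- simulate_stage_series(small_cfg(seed = 6, stage_trajectory = traj,
                                         depth_mean = 100))
  s <- stage_summary(stg$stages$embryonic_liver, regions = stg$truth,
                     min_depth = 50)
  # me_mean 0.45 mixes two extreme Betas; their mass inside [0.1, 0.9]
  sh <- small_cfg()$stage_extreme_shape
  tail_mass <- stats::pbeta(0.9, sh[1], sh[2]) - stats::pbeta(0.1, sh[1], sh[2])
  expect_lt(s$intermediate_frac, tail_mass + 0.1)
})

test_that("homogeneous clusters have zero transitions; mosaic match closed form", {
  r_hom <- simulate_cluster_reads(cpg_pos = seq(0, 250, 50), n_reads = 100,
                                  read_model = list(n_cpgs_mean = 6,
                                                    p_homog = 1,
                                                    p_missing = 0),
                                  mean_methylation = 0.5, seed = 2)
  expect_equal(count_transitions(r_hom), 0L)

  r_mos <- simulate_cluster_reads(cpg_pos = seq(0, 250, 50), n_reads = 400,
                                  read_model = list(n_cpgs_mean = 6,
                                                    p_homog = 0,
                                                    p_missing = 0),
                                  mean_methylation = 0.5, seed = 3)
  dt <- data.table::as.data.table(r_mos)
  n_pairs <- sum(pmax(dt[, .N, by = read_id]$N - 1L, 0L))
  # at m = 0.5 adjacent mismatch indicators are uncorrelated:
  # transitions ~ Binomial(n_pairs, 1/2)
  expect_lt(abs(count_transitions(r_mos) - n_pairs * 0.5),
            3 * sqrt(n_pairs * 0.25))
})

test_that("cluster read simulation validates its inputs", {
  expect_error(simulate_cluster_reads(cpg_pos = 1:5, n_reads = 0), "n_reads")
  expect_error(simulate_cluster_reads(cpg_pos = integer(), n_reads = 5),
               "no CpGs")
  r <- simulate_cluster_reads(cpg_pos = seq(0, 250, 50), n_reads = 50,
                              read_model = list(n_cpgs_mean = 5,
                                                p_homog = 0.5,
                                                p_missing = 0.3),
                              mean_methylation = 0.5, seed = 4)
  expect_gt(sum(r$call == "."), 0L)
})

test_that("feature tracks obey density and determinism contracts", {
  truth <- data.table(chrom = "chr1", start = 50000L, end = 51000L)
  expect_equal(nrow(simulate_feature_tracks(truth, c(chr1 = 100000L),
                                            background_density = 0)), 0L)
  a <- simulate_feature_tracks(truth, c(chr1 = 100000L),
                               enrichment_factor = 5,
                               background_density = 1e-3, seed = 12)
  b <- simulate_feature_tracks(truth, c(chr1 = 100000L),
                               enrichment_factor = 5,
                               background_density = 1e-3, seed = 12)
  expect_identical(a, b)
  expect_error(simulate_feature_tracks(truth, c(chr1 = 1e5L),
                                       enrichment_factor = 0.5),
               "enrichment_factor")
})

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(depth_mean = 0), "depth_mean")
  expect_error(sim_config(read_model = list(n_cpgs_mean = 6, p_homog = 1.2,
                                            p_missing = 0)),
               "probabilities")
  expect_error(sim_config(chrom_sizes = c(100L)), "named")
})
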