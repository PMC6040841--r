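# Synthetic bisulfite-seq data with planted truth. The generator emulates
# the statistical structure the screen and the read-level statistic assume:
# a bimodal genome-wide methylation background, planted regions with
# systemic (cross-tissue, within-individual) interindividual variation,
# stage series with demethylation/remethylation trajectories and a
# post-gastrulation excess of intermediate methylation, and read-level call
# sets mixing molecule-specific (homogeneous) and mosaic reads.

#' Simulation configuration
#'
#' Defaults describe a small two-dataset cohort mirroring the screen's
#' design (dataset A: 2 individuals x peripheral blood + hair follicle;
#' dataset B: 3 individuals x fat + small bowel), sequenced to ~30x at CpG
#' dyads spaced ~150 bp genome-wide, with denser CpGs (~50 bp) inside
#' planted metastable regions. Planted regions follow a switch-like
#' (bimodal) epigenotype model: each individual's latent level is either
#' hypomethylated (`me_low_range`) or hypermethylated (`me_high_range`),
#' shared across its tissues, mirroring the near-extreme interindividual
#' contrasts real metastable epialleles display; the implied
#' interindividual spread (>= 0.6 by default) clears the 0.2 minimum the
#' recovery claims assume.
#'
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param cpg_spacing_mean mean background CpG spacing (bp).
#' @param datasets named list; each element has `individuals` (character)
#'   and `tissues` (character).
#' @param depth_mean mean sequencing depth per CpG (Poisson).
#' @param n_me_regions number of planted metastable regions.
#' @param me_region_cpgs CpGs per planted region.
#' @param me_region_spacing mean CpG spacing inside planted regions (bp).
#' @param me_low_range,me_high_range uniform ranges for the latent
#'   methylation level of the hypo- and hypermethylated individual groups
#'   of planted regions.
#' @param background_mix two-component Beta mixture for background
#'   methylation: list with `weight` (P(hypomethylated component)),
#'   `shape1`, `shape2` (length-2, hypo then hyper component).
#' @param snp_density per-bp SNP rate (per dataset).
#' @param stage_trajectory data.frame with columns `stage`, `bg_mean`,
#'   `me_mean`, `intermediate_frac`, `n_replicates`; see
#'   [default_stage_trajectory()].
#' @param stage_extreme_shape length-2 shape of the extreme Beta used for
#'   per-site stage methylation: hypomethylated sites draw from
#'   `Beta(shape[1], shape[2])`, hypermethylated from the mirror
#'   `Beta(shape[2], shape[1])`. The stage mean sets the mixing weight, so
#'   stage methylomes are bimodal with a small intrinsic intermediate tail.
#' @param read_model list with `n_cpgs_mean` (mean CpGs per read),
#'   `p_homog` (probability a molecule is epigenetically homogeneous) and
#'   `p_missing` (probability a call is uncalled).
#' @param seed master seed; all child seeds derive from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(chrom_sizes = c(chr1 = 1000000L, chr2 = 1000000L),
                       cpg_spacing_mean = 150,
                       datasets = list(
                         dsA = list(individuals = c("A1", "A2"),
                                    tissues = c("PBL", "HF")),
                         dsB = list(individuals = c("B1", "B2", "B3"),
                                    tissues = c("FT", "SB"))),
                       depth_mean = 30,
                       n_me_regions = 50L,
                       me_region_cpgs = 14L,
                       me_region_spacing = 50,
                       me_low_range = c(0.02, 0.12),
                       me_high_range = c(0.80, 0.95),
                       background_mix = list(weight = 0.35,
                                             shape1 = c(0.8, 16),
                                             shape2 = c(16, 0.8)),
                       snp_density = 5e-4,
                       stage_trajectory = default_stage_trajectory(),
                       stage_extreme_shape = c(0.8, 25),
                       read_model = list(n_cpgs_mean = 6, p_homog = 0.9,
                                         p_missing = 0.05),
                       seed = 1L) {
  cfg <- list(chrom_sizes = chrom_sizes, cpg_spacing_mean = cpg_spacing_mean,
              datasets = datasets, depth_mean = depth_mean,
              n_me_regions = as.integer(n_me_regions),
              me_region_cpgs = as.integer(me_region_cpgs),
              me_region_spacing = me_region_spacing,
              me_low_range = me_low_range, me_high_range = me_high_range,
              background_mix = background_mix, snp_density = snp_density,
              stage_trajectory = as.data.table(stage_trajectory),
              stage_extreme_shape = stage_extreme_shape,
              read_model = read_model, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$background_mix$weight, cfg$read_model$p_homog,
             cfg$read_model$p_missing, cfg$me_low_range, cfg$me_high_range,
             cfg$stage_trajectory$bg_mean, cfg$stage_trajectory$me_mean,
             cfg$stage_trajectory$intermediate_frac)
  if (any(probs < 0 | probs > 1))
    stop_mescan("simulation probabilities must lie in [0, 1]")
  if (cfg$depth_mean < 1) stop_mescan("depth_mean must be >= 1")
  if (is.null(names(cfg$chrom_sizes)) || any(cfg$chrom_sizes <= 0))
    stop_mescan("chrom_sizes must be a named vector of positive lengths")
  invisible(cfg)
}

#' Default developmental-stage trajectory
#'
#' Nine stages from gametes through cleavage to post-gastrulation tissue.
#' Background means trace the canonical demethylation (fertilization to
#' blastocyst) and remethylation (post-gastrulation) wave; planted
#' metastable-region means sit below background at every stage; the
#' intermediate fraction (methylation drawn uniformly on [0.1, 0.9]) is
#' nonzero only post-gastrulation, where it is ~0.5 inside metastable
#' regions, emulating the observed post-implantation excess of intermediate
#' methylation states.
#'
#' @return a `data.table` with columns `stage`, `bg_mean`, `me_mean`,
#'   `intermediate_frac`, `n_replicates`, `post_gastrulation`.
#' @export
default_stage_trajectory <- function() {
  data.table(
    stage = c("MII_oocyte", "sperm", "zygote", "two_cell", "four_cell",
              "eight_cell", "morula", "ICM", "embryonic_liver"),
    bg_mean = c(0.52, 0.82, 0.55, 0.48, 0.42, 0.38, 0.34, 0.32, 0.76),
    me_mean = c(0.25, 0.40, 0.28, 0.24, 0.20, 0.18, 0.16, 0.15, 0.45),
    intermediate_frac = c(0, 0, 0, 0, 0, 0, 0, 0, 0.5),
    n_replicates = c(2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 3L),
    post_gastrulation = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                          FALSE, TRUE))
}

# CpG dyad positions: background positions from exponential spacings, then
# background CpGs inside planted regions replaced by a denser planted set.
sim_cpg_map <- function(cfg) {
  bg <- rbindlist(lapply(names(cfg$chrom_sizes), function(ch) {
    len <- cfg$chrom_sizes[[ch]]
    n_guess <- ceiling(len / cfg$cpg_spacing_mean * 1.3) + 50L
    pos <- cumsum(2L + as.integer(rexp(n_guess, 1 / cfg$cpg_spacing_mean)))
    data.table(chrom = ch, pos = pos[pos < len - 1L])
  }))
  truth <- plant_regions(cfg)
  if (nrow(truth)) {
    keep <- !pos_in_regions(bg$chrom, bg$pos, truth)
    span_cap <- ceiling(cfg$me_region_cpgs * cfg$me_region_spacing * 2) - 2L
    me <- rbindlist(lapply(seq_len(nrow(truth)), function(i) {
      repeat {   # resample the rare overshoot so regions stay in their slot
        offs <- cumsum(c(0L, 2L + as.integer(
          rexp(cfg$me_region_cpgs - 1L, 1 / cfg$me_region_spacing))))
        if (offs[length(offs)] <= span_cap) break
      }
      data.table(chrom = truth$chrom[i], pos = truth$start[i] + offs,
                 region = i)
    }))
    truth[, end := me[, max(pos) + 2L, by = region]$V1]
    cpgs <- rbind(bg[keep][, region := 0L], me)
  } else {
    cpgs <- bg[, region := 0L]
  }
  setorderv(cpgs, c("chrom", "pos"))
  list(cpgs = cpgs[], truth = truth)
}

plant_regions <- function(cfg) {
  n <- cfg$n_me_regions
  if (n == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), label = character()))
  span_guess <- ceiling(cfg$me_region_cpgs * cfg$me_region_spacing * 2)
  per_chrom <- apportion(rep(1, length(cfg$chrom_sizes)), n)
  out <- rbindlist(lapply(seq_along(cfg$chrom_sizes), function(ci) {
    k <- per_chrom[ci]
    if (k == 0L) return(NULL)
    len <- cfg$chrom_sizes[[ci]]
    lo <- floor(len * 0.05)
    hi <- len - span_guess - floor(len * 0.02)
    if (hi - lo < (k - 1L) * 2L * span_guess)
      stop_mescan("chromosome %s too short for %d planted regions",
                  names(cfg$chrom_sizes)[ci], k)
    # one region per equal-width cell, jittered within its cell so regions
    # stay separated and inside the chromosome
    cell <- (hi - lo) / k
    slots <- floor(lo + cell * (seq_len(k) - 1L))
    jit <- as.integer(runif(k, 0, max(1, cell - 2 * span_guess)))
    data.table(chrom = names(cfg$chrom_sizes)[ci],
               start = as.integer(slots + jit))
  }))
  out[, end := start + span_guess]  # refined after CpG placement
  out[, label := sprintf("ME_%03d", seq_len(.N))]
  out[]
}

#' Simulate a multi-individual, multi-tissue methylation cohort
#'
#' Outside planted regions, each CpG has one latent methylation level drawn
#' from the background Beta mixture and shared by every sample (no
#' interindividual signal). Inside a planted region, each individual draws
#' one latent level -- shared across its tissues, so the variation is
#' systemic -- with individuals split into a low and a high group separated
#' by the region's spread. Counts are Binomial(depth, level) with Poisson
#' depths. SNPs are placed uniformly at `snp_density` per dataset, which at
#' the default density also lands some SNPs within 60 bp of planted
#' ME-CpGs, exercising the proximity filter.
#'
#' @param cfg a [sim_config()].
#' @return a list with `cohorts` (named list of [meth_cohort()], one per
#'   dataset), `snps` (named list of SNP position tables per dataset),
#'   `truth` (planted region table with per-individual latent levels as an
#'   attribute), `cpgs` (the CpG map).
#' @export
simulate_cohort <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(child_seed(cfg$seed, 1L), {
    map <- sim_cpg_map(cfg)
    cpgs <- map$cpgs
    truth <- map$truth
    if (nrow(truth) &&
        any(truth$end > cfg$chrom_sizes[truth$chrom] | truth$start < 0L))
      stop_mescan("planted region outside chrom_sizes")
    n_sites <- nrow(cpgs)

    mix <- cfg$background_mix
    comp <- 1L + (runif(n_sites) > mix$weight)
    bg_level <- rbeta(n_sites, mix$shape1[comp], mix$shape2[comp])

    inds <- unlist(lapply(names(cfg$datasets), function(d)
      paste(d, cfg$datasets[[d]]$individuals, sep = ":")))
    lv <- me_latent_levels(cfg, truth, inds)

    cohorts <- list(); snps <- list()
    for (d in names(cfg$datasets)) {
      ds <- cfg$datasets[[d]]
      meta <- CJ(individual = ds$individuals, tissue = ds$tissues,
                 sorted = FALSE)
      meta[, `:=`(dataset = d,
                  sample_id = paste(d, individual, tissue, sep = "_"))]
      samples <- list()
      for (i in seq_len(nrow(meta))) {
        key <- paste(d, meta$individual[i], sep = ":")
        level <- bg_level
        if (nrow(truth)) {
          idx <- cpgs$region > 0L
          level[idx] <- lv[cbind(cpgs$region[idx],
                                 match(key, colnames(lv)))]
        }
        depth <- rpois(n_sites, cfg$depth_mean)
        nm <- rbinom(n_sites, depth, level)
        samples[[meta$sample_id[i]]] <-
          cpg_sites(cpgs$chrom, cpgs$pos, nm, depth)[n_total > 0L]
      }
      cohorts[[d]] <- meth_cohort(samples, meta)
      snps[[d]] <- rbindlist(lapply(names(cfg$chrom_sizes), function(ch) {
        k <- rpois(1L, cfg$chrom_sizes[[ch]] * cfg$snp_density)
        data.table(chrom = ch,
                   pos = sort(sample.int(cfg$chrom_sizes[[ch]], k)) - 1L)
      }))
    }
    truth_out <- truth[, .(chrom, start, end, label)]
    setattr(truth_out, "latent_levels", lv)
    list(cohorts = cohorts, snps = snps, truth = truth_out, cpgs = cpgs)
  })
}

# matrix [region x individual] of latent levels; every dataset gets at
# least one low and one high individual per region so the signal is
# detectable under the intersection combination rule.
me_latent_levels <- function(cfg, truth, inds) {
  if (!nrow(truth)) return(matrix(numeric(), 0, length(inds),
                                  dimnames = list(NULL, inds)))
  ds_of <- sub(":.*$", "", inds)
  lv <- matrix(NA_real_, nrow(truth), length(inds),
               dimnames = list(truth$label, inds))
  for (r in seq_len(nrow(truth))) {
    lo <- runif(1L, cfg$me_low_range[1L], cfg$me_low_range[2L])
    hi <- runif(1L, cfg$me_high_range[1L], cfg$me_high_range[2L])
    grp <- logical(length(inds))  # TRUE = high group
    for (d in unique(ds_of)) {
      j <- which(ds_of == d)
      g <- runif(length(j)) < 0.5
      if (all(g)) g[sample(length(j), 1L)] <- FALSE
      if (!any(g)) g[sample(length(j), 1L)] <- TRUE
      grp[j] <- g
    }
    base <- ifelse(grp, hi, lo)
    lv[r, ] <- pmin(pmax(base + rnorm(length(inds), 0, 0.015), 0.01), 0.99)
  }
  lv
}

#' Simulate a developmental stage series
#'
#' Per stage and replicate, each CpG draws a latent level from a
#' two-component extreme-Beta mixture: with probability equal to the
#' stage's mean methylation the hypermethylated component
#' `Beta(shape[2], shape[1])`, otherwise the hypomethylated mirror -- so
#' the stage methylome is bimodal and its mean tracks the configured
#' trajectory. CpGs inside planted regions use the stage's ME mean as the
#' mixing weight instead, and for stages flagged post-gastrulation a
#' fraction `intermediate_frac` of region CpGs draws its level uniformly
#' on [0.1, 0.9] (the planted excess of intermediate methylation). Counts
#' are Binomial with Poisson depths. Replicates differ only through the
#' RNG stream.
#'
#' @param cfg a [sim_config()].
#' @return list with `stages` (named list; per stage a list of replicate
#'   CpG site tables), `truth` (planted regions), `trajectory`.
#' @export
simulate_stage_series <- function(cfg) {
  validate_sim_config(cfg)
  traj <- cfg$stage_trajectory
  if (!nrow(traj)) stop_mescan("stage_trajectory is empty")
  with_seed(child_seed(cfg$seed, 2L), {
    map <- sim_cpg_map(cfg)
    cpgs <- map$cpgs
    in_me <- cpgs$region > 0L
    n <- nrow(cpgs)
    sh <- cfg$stage_extreme_shape
    # draw from the extreme mixture so E[level] = the target mean
    draw_mix <- function(k, target_mean) {
      mu_lo <- sh[1L] / sum(sh); mu_hi <- sh[2L] / sum(sh)
      w <- pmin(pmax((target_mean - mu_lo) / (mu_hi - mu_lo), 0), 1)
      hyper <- runif(k) < w
      lvl <- rbeta(k, sh[1L], sh[2L])
      lvl[hyper] <- rbeta(sum(hyper), sh[2L], sh[1L])
      lvl
    }
    stages <- list()
    for (s in seq_len(nrow(traj))) {
      reps <- list()
      for (r in seq_len(traj$n_replicates[s])) {
        level <- draw_mix(n, traj$bg_mean[s])
        if (any(in_me)) {
          level[in_me] <- draw_mix(sum(in_me), traj$me_mean[s])
          pg <- isTRUE(traj$post_gastrulation[s]) ||
            (is.null(traj$post_gastrulation) && traj$intermediate_frac[s] > 0)
          if (pg && traj$intermediate_frac[s] > 0) {
            flip <- in_me & (runif(n) < traj$intermediate_frac[s])
            level[flip] <- runif(sum(flip), 0.1, 0.9)
          }
        }
        depth <- rpois(n, cfg$depth_mean)
        nm <- rbinom(n, depth, level)
        reps[[paste0("rep", r)]] <-
          cpg_sites(cpgs$chrom, cpgs$pos, nm, depth)[n_total > 0L]
      }
      stages[[traj$stage[s]]] <- reps
    }
    list(stages = stages, truth = map$truth[, .(chrom, start, end, label)],
         trajectory = traj)
  })
}

#' Simulate reads overlapping one cluster
#'
#' With probability `p_homog` a molecule is epigenetically homogeneous:
#' fully methylated (with probability `mean_methylation`) or fully
#' unmethylated. Otherwise every call is an independent
#' Bernoulli(`mean_methylation`) (mosaic). A fraction `p_missing` of calls
#' is uncalled. Reads cover a contiguous run of the cluster's CpGs with a
#' random start, emulating short reads that may clip the cluster edges.
#'
#' @param region list/row with `chrom`, `start`, `end`, or `NULL` when
#'   `cpg_pos` is given.
#' @param n_reads number of molecules (>= 1).
#' @param read_model list with `n_cpgs_mean`, `p_homog`, `p_missing`.
#' @param mean_methylation cluster-level mean methylation.
#' @param seed integer seed.
#' @param cpg_pos optional explicit CpG dyad positions; defaults to a
#'   ~50 bp-spaced grid inside `region`.
#' @param chrom chromosome name used when `cpg_pos` is given.
#' @return a [read_calls()] table.
#' @export
simulate_cluster_reads <- function(region = NULL, n_reads,
                                   read_model = list(n_cpgs_mean = 6,
                                                     p_homog = 0.9,
                                                     p_missing = 0.05),
                                   mean_methylation = 0.5, seed = 1L,
                                   cpg_pos = NULL, chrom = NULL) {
  if (n_reads < 1L) stop_mescan("n_reads must be >= 1")
  if (is.null(cpg_pos)) {
    if (is.null(region)) stop_mescan("give either region or cpg_pos")
    chrom <- as.character(region$chrom)
    cpg_pos <- seq(region$start, region$end - 2L, by = 50L)
  }
  chrom <- chrom %||% "chr1"
  cpg_pos <- sort(as.integer(cpg_pos))
  n_cpg <- length(cpg_pos)
  if (n_cpg == 0L) stop_mescan("region contains no CpGs")
  p_hom <- read_model$p_homog %||% 0
  p_mis <- read_model$p_missing %||% 0
  len_mean <- read_model$n_cpgs_mean %||% 6
  with_seed(seed, {
    out <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      len <- min(n_cpg, 1L + rpois(1L, max(0, len_mean - 1)))
      start <- sample.int(n_cpg - len + 1L, 1L)
      idx <- start:(start + len - 1L)
      if (runif(1L) < p_hom) {
        calls <- rep(if (runif(1L) < mean_methylation) "M" else "U", len)
      } else {
        calls <- ifelse(runif(len) < mean_methylation, "M", "U")
      }
      calls[runif(len) < p_mis] <- "."
      out[[i]] <- data.table(read_id = sprintf("r%05d", i), chrom = chrom,
                             pos = cpg_pos[idx], call = calls)
    }
    validate_read_calls(rbindlist(out))
  })
}

#' Simulate a feature track with planted proximity enrichment
#'
#' Features follow a Poisson point process at `background_density` per bp,
#' with the rate multiplied by `enrichment_factor` within `window` bp of
#' the truth regions (implemented by thinning a process at the elevated
#' rate outside the enriched zone).
#'
#' @param truth_regions region table the enrichment is anchored to.
#' @param chrom_sizes named chromosome lengths.
#' @param enrichment_factor rate multiplier near truth regions (>= 1).
#' @param background_density per-bp feature rate away from truth regions.
#' @param feature_width feature length in bp.
#' @param window enrichment halo around truth regions (bp).
#' @param seed integer seed.
#' @return interval `data.table` (chrom, start, end, label).
#' @export
simulate_feature_tracks <- function(truth_regions, chrom_sizes,
                                    enrichment_factor = 1,
                                    background_density = 1e-4,
                                    feature_width = 200L,
                                    window = 10000L, seed = 1L) {
  if (enrichment_factor < 1) stop_mescan("enrichment_factor must be >= 1")
  empty <- data.table(chrom = character(), start = integer(),
                      end = integer(), label = character())
  if (background_density <= 0) return(empty)
  halo <- as.data.table(truth_regions)[, .(chrom, start = pmax(0L, start - window),
                                           end = end + window)]
  with_seed(seed, {
    out <- rbindlist(lapply(names(chrom_sizes), function(ch) {
      len <- chrom_sizes[[ch]]
      k <- rpois(1L, len * background_density * enrichment_factor)
      if (k == 0L) return(NULL)
      pos <- sort(sample.int(len, k, replace = TRUE)) - 1L
      near <- if (nrow(halo)) pos_in_regions(rep(ch, k), pos, halo)
              else rep(FALSE, k)
      keep <- near | (runif(k) < 1 / enrichment_factor)
      if (!any(keep)) return(NULL)
      data.table(chrom = ch, start = pos[keep],
                 end = pmin(pos[keep] + feature_width, len))
    }))
    if (is.null(out) || !nrow(out)) return(empty)
    out[, label := sprintf("feat_%04d", seq_len(.N))]
    setorderv(out, c("chrom", "start"))
    out[]
  })
}
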