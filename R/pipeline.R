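# End-to-end orchestration: a flat configuration object carrying every
# threshold, an input manifest naming files per role, and a demo mode that
# generates all inputs from the synthetic-data module.

#' Pipeline configuration
#'
#' Flat key-value configuration whose defaults are the screen's published
#' constants: 15% interindividual difference, 1/3 intertissue ratio, 60 bp
#' SNP window, 300 bp cluster gap, >= 4 ME-CpGs, 2:1 purity ratio, depth
#' >= 10, 200x depth cap (read-level analyses), [0.10, 0.90] intermediate
#' band, 1000 RHI randomizations, 1000 bootstrap resamples, 1-kb tiles and
#' a 10-kb proximity window. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults listed above.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    inter_threshold = 0.15, intra_ratio = 1 / 3, snp_window = 60L,
    max_gap = 300L, min_cpgs = 4L, purity_ratio = 2,
    combine_mode = "intersection", min_depth = 10L, max_depth = 200L,
    band_lo = 0.10, band_hi = 0.90, n_rand = 1000L, n_boot = 1000L,
    tile_size = 1000L, window = 10000L, n_controls_per_me = 8L,
    min_reads = 5L, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop_mescan("unknown configuration key(s): %s",
                paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

config_lines <- function(config) {
  vapply(names(config), function(k)
    sprintf("%s=%s", k, paste(format(config[[k]], digits = 12),
                              collapse = ",")), character(1))
}

#' Read a manifest file
#'
#' The manifest is a TSV with columns `role`, `dataset`, `sample_id`,
#' `individual`, `tissue`, `stage`, `path` (unused fields may be empty or
#' `NA`). Recognized roles: `methylation` (per-sample cytosine report or
#' counts table), `snps` (VCF per dataset), `stage_methylation` (per
#' stage/replicate), `read_calls`, `features` (BED), `regions` (BED),
#' `array_cpgs` (TSV chrom, pos, mqtl, reliable).
#'
#' @param path manifest TSV.
#' @return a `data.table`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_mescan("no such manifest: %s", path)
  m <- fread(path, sep = "\t", colClasses = "character")
  need <- c("role", "path")
  if (!all(need %in% names(m)))
    stop_mescan("manifest needs at least columns: %s",
                paste(need, collapse = ", "))
  for (col in c("dataset", "sample_id", "individual", "tissue", "stage"))
    if (!col %in% names(m)) m[, (col) := NA_character_]
  missing <- m$path[!file.exists(m$path)]
  if (length(missing))
    stop_mescan("manifest names missing file(s): %s",
                paste(missing, collapse = ", "))
  m[]
}

manifest_cohorts <- function(manifest, min_depth) {
  rows <- manifest[role == "methylation"]
  if (!nrow(rows)) return(NULL)
  cohorts <- list()
  for (d in unique(rows$dataset)) {
    rd <- rows[dataset == d]
    samples <- setNames(lapply(rd$path, read_cytosine_report,
                               min_depth = min_depth), rd$sample_id)
    cohorts[[d]] <- meth_cohort(samples,
                                rd[, .(sample_id, individual, tissue,
                                       dataset, stage)])
  }
  cohorts
}

#' Run the analysis pipeline
#'
#' Stages run in dependency order: screen (+ control sampling), stage
#' dynamics, read-level RHI, and enrichment -- each only when its inputs
#' are available from the manifest, or all of them in `--demo` mode, where
#' every input is generated by the synthetic-data module (at a reduced
#' scale suitable for demonstrations) and written to `out_dir/inputs`
#' through the package's own writers. Outputs are TSV/BED files plus a log
#' recording every filter's in/out counts; the configuration is echoed
#' into the output directory with a content hash, and a rerun with the
#' same inputs and seed is bit-identical.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [pipeline_config()].
#' @param manifest path to a manifest TSV, or a manifest `data.table`.
#' @param demo generate all inputs synthetically. Default `FALSE`.
#' @return (invisibly) list of in-memory stage results.
#' @export
run_pipeline <- function(out_dir, config = pipeline_config(),
                         manifest = NULL, demo = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(manifest) && !demo)
    stop_mescan("either a manifest or demo = TRUE is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lines <- config_lines(config)
  writeLines(c(sprintf("# config_hash=%s", fnv1a_hex(lines)), lines),
             file.path(out_dir, "config.txt"))
  logf <- file.path(out_dir, "pipeline.log")
  cat(sprintf("mescan pipeline (seed=%d, demo=%s)\n", config$seed, demo),
      file = logf)
  say <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                file = logf, append = TRUE)
  results <- list()

  if (demo) {
    inputs <- demo_inputs(out_dir, config)
    manifest <- inputs$manifest
    results$truth <- inputs$truth
    say("demo inputs generated under inputs/")
  } else if (!is.data.frame(manifest)) {
    manifest <- read_manifest(manifest)
  }
  manifest <- as.data.table(manifest)

  cohorts <- manifest_cohorts(manifest, config$min_depth)
  me <- NULL; controls <- NULL
  if (!is.null(cohorts)) {
    snp_rows <- manifest[role == "snps"]
    snps <- if (nrow(snp_rows)) {
      setNames(lapply(snp_rows$path, read_snp_vcf), snp_rows$dataset)
    } else NULL
    screen <- run_me_screen(
      cohorts, snps, inter_threshold = config$inter_threshold,
      intra_ratio = config$intra_ratio, snp_window = config$snp_window,
      max_gap = config$max_gap, min_cpgs = config$min_cpgs,
      purity_ratio = config$purity_ratio,
      combine_mode = config$combine_mode)
    me <- screen$me_clusters
    results$screen <- screen
    for (i in seq_len(nrow(screen$log)))
      say("screen %s: covered=%d pass=%d after_snp=%d",
          screen$log$dataset[i], screen$log$covered[i], screen$log$pass[i],
          screen$log$after_snp_filter[i])
    say("screen: combined=%d clusters=%d after_purity=%d",
        nrow(screen$me_cpgs), screen$log$clusters[1], nrow(me))
    write_regions(me, file.path(out_dir, "me_regions.tsv"))
    write_bed(me, file.path(out_dir, "me_regions.bed"))
    if (nrow(me)) {
      controls <- generate_control_clusters(
        screen$covered, me,
        n_controls = config$n_controls_per_me * nrow(me),
        seed = child_seed(config$seed, 11L),
        max_gap = config$max_gap, min_cpgs = config$min_cpgs)
      results$controls <- controls
      say("controls: %d sampled", nrow(controls))
      write_regions(controls, file.path(out_dir, "control_regions.tsv"))
      write_bed(controls, file.path(out_dir, "control_regions.bed"))
    }
  }

  stage_rows <- manifest[role == "stage_methylation"]
  if (nrow(stage_rows)) {
    sums <- rbindlist(lapply(unique(stage_rows$stage), function(st) {
      reps <- lapply(stage_rows[stage == st, path], read_cytosine_report,
                     min_depth = 1L)
      s_all <- stage_summary(reps, min_depth = config$min_depth)
      row <- data.table(stage = st, scope = "background",
                        n_cpgs = s_all$n_cpgs, mean = s_all$mean,
                        intermediate_frac = s_all$intermediate_frac)
      if (!is.null(me) && nrow(me)) {
        s_me <- tryCatch(stage_summary(reps, regions = me,
                                       min_depth = config$min_depth),
                         error = function(e) NULL)
        if (!is.null(s_me))
          row <- rbind(row, data.table(stage = st, scope = "ME",
                                       n_cpgs = s_me$n_cpgs,
                                       mean = s_me$mean,
                                       intermediate_frac = s_me$intermediate_frac))
      }
      row
    }))
    results$stage_summaries <- sums
    fwrite(sums, file.path(out_dir, "stage_summaries.tsv"), sep = "\t")
    say("dynamics: %d stage summaries", nrow(sums))
    stages <- unique(stage_rows$stage)
    if (all(c("ICM", "embryonic_liver") %in% stages)) {
      pre <- lapply(stage_rows[stage == "ICM", path], read_cytosine_report,
                    min_depth = 1L)
      post <- lapply(stage_rows[stage == "embryonic_liver", path],
                     read_cytosine_report, min_depth = 1L)
      strat <- stratified_transition(pre, post, n_boot = config$n_boot,
                                     seed = child_seed(config$seed, 12L),
                                     min_depth = config$min_depth)
      results$transition <- strat
      fwrite(strat, file.path(out_dir, "icm_transition.tsv"), sep = "\t")
      say("dynamics: stratified ICM transition with %d strata", nrow(strat))
    }
  }

  rc_rows <- manifest[role == "read_calls"]
  if (nrow(rc_rows) && !is.null(me)) {
    reads <- rbindlist(lapply(rc_rows$path, read_read_calls))
    rhi_regions <- rbind(
      if (nrow(me)) copy(me)[, .(chrom, start, end, role)],
      if (!is.null(controls) && nrow(controls))
        copy(controls)[, .(chrom, start, end, role)])
    rhi_tab <- rbindlist(lapply(seq_len(nrow(rhi_regions)), function(i) {
      reg <- rhi_regions[i]
      clipped <- clip_reads_to_region(reads, reg)
      elig <- rhi_eligible(clipped, band = c(config$band_lo, config$band_hi),
                           min_reads = config$min_reads)
      if (!isTRUE(elig))
        return(data.table(chrom = reg$chrom, start = reg$start,
                          end = reg$end, role = reg$role,
                          n_reads = uniqueN(clipped$read_id),
                          observed = NA_integer_,
                          median_randomized = NA_integer_, rhi = NA_real_,
                          note = attr(elig, "reason")))
      r <- compute_rhi(clipped, n_rand = config$n_rand,
                       seed = child_seed(config$seed, 13L + i))
      data.table(chrom = reg$chrom, start = reg$start, end = reg$end,
                 role = reg$role, n_reads = r$n_reads,
                 observed = r$observed_transitions,
                 median_randomized = r$median_randomized, rhi = r$rhi,
                 note = "")
    }))
    results$rhi <- rhi_tab
    fwrite(rhi_tab, file.path(out_dir, "rhi.tsv"), sep = "\t")
    say("rhi: %d regions scored, %d eligible", nrow(rhi_tab),
        sum(!is.na(rhi_tab$rhi)))
    if (sum(!is.na(rhi_tab$rhi[rhi_tab$role == "ME"])) > 0 &&
        sum(!is.na(rhi_tab$rhi[rhi_tab$role == "control"])) > 0) {
      cmp <- compare_rhi(rhi_tab[role == "ME", rhi],
                         rhi_tab[role == "control", rhi])
      results$rhi_comparison <- cmp
      say("rhi: ME vs control Mann-Whitney U=%g p=%g", cmp$statistic,
          cmp$p_value)
    }
  }

  feat_rows <- manifest[role == "features"]
  if (nrow(feat_rows) && !is.null(me) && nrow(me)) {
    chrom_sizes <- manifest_chrom_sizes(manifest, me)
    enr <- rbindlist(lapply(seq_len(nrow(feat_rows)), function(i) {
      feats <- read_bed(feat_rows$path[i])
      e <- tile_enrichment(feats, me, chrom_sizes,
                           window = config$window,
                           tile_size = config$tile_size)
      data.table(feature_set = feat_rows$dataset[i] %||% basename(feat_rows$path[i]),
                 a = e$table[1, 1], b = e$table[1, 2], c = e$table[2, 1],
                 d = e$table[2, 2], odds_ratio = e$odds_ratio,
                 p_value = e$p_value)
    }))
    results$enrichment <- enr
    fwrite(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t")
    say("enrichment: %d feature sets tested", nrow(enr))
  }

  arr_rows <- manifest[role == "array_cpgs"]
  if (nrow(arr_rows) && !is.null(me) && nrow(me)) {
    arr <- fread(arr_rows$path[1L])
    arr[, `:=`(mqtl = as.logical(mqtl), reliable = as.logical(reliable))]
    mq <- mqtl_enrichment(me, arr)
    results$mqtl <- mq
    fwrite(data.table(a = mq$table[1, 1], b = mq$table[1, 2],
                      c = mq$table[2, 1], d = mq$table[2, 2],
                      odds_ratio = mq$odds_ratio, p_value = mq$p_value),
           file.path(out_dir, "mqtl_enrichment.tsv"), sep = "\t")
    say("mqtl: OR=%g p=%g", mq$odds_ratio, mq$p_value)
  }

  say("done")
  invisible(results)
}

manifest_chrom_sizes <- function(manifest, regions) {
  cs_rows <- manifest[role == "chrom_sizes"]
  if (nrow(cs_rows)) {
    cs <- fread(cs_rows$path[1L], header = FALSE)
    return(setNames(as.integer(cs[[2L]]), as.character(cs[[1L]])))
  }
  # fall back to spanning the observed regions with headroom
  dt <- as.data.table(regions)
  sizes <- dt[, max(end) + 50000L, by = chrom]
  setNames(sizes$V1, sizes$chrom)
}

# Generate demo inputs on disk (through the package's own writers) and a
# manifest describing them. Scale is reduced relative to the default
# sim_config so the demo runs in seconds.
demo_inputs <- function(out_dir, config) {
  idir <- file.path(out_dir, "inputs")
  dir.create(idir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim_config(chrom_sizes = c(chr1 = 400000L, chr2 = 400000L),
                    n_me_regions = 12L,
                    seed = child_seed(config$seed, 1L))
  sim <- simulate_cohort(cfg)
  rows <- list()
  for (d in names(sim$cohorts)) {
    co <- sim$cohorts[[d]]
    for (sid in names(co$samples)) {
      p <- file.path(idir, paste0(sid, ".meth.tsv"))
      write_cpg_table(co$samples[[sid]], p)
      mrow <- co$meta[sample_id == sid]
      rows[[length(rows) + 1L]] <-
        data.table(role = "methylation", dataset = d, sample_id = sid,
                   individual = mrow$individual, tissue = mrow$tissue,
                   stage = NA_character_, path = p)
    }
    vp <- file.path(idir, paste0(d, ".snps.vcf"))
    writeLines(c("##fileformat=VCFv4.2",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                 sprintf("%s\t%d\t.\tC\tT\t.\tPASS\t.", sim$snps[[d]]$chrom,
                         sim$snps[[d]]$pos + 1L)), vp)
    rows[[length(rows) + 1L]] <-
      data.table(role = "snps", dataset = d, sample_id = NA_character_,
                 individual = NA_character_, tissue = NA_character_,
                 stage = NA_character_, path = vp)
  }
  csp <- file.path(idir, "chrom.sizes")
  write.table(data.frame(names(cfg$chrom_sizes), unname(cfg$chrom_sizes)),
              csp, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  rows[[length(rows) + 1L]] <-
    data.table(role = "chrom_sizes", dataset = NA_character_,
               sample_id = NA_character_, individual = NA_character_,
               tissue = NA_character_, stage = NA_character_, path = csp)

  stg <- simulate_stage_series(cfg)
  for (st in names(stg$stages)) {
    for (r in seq_along(stg$stages[[st]])) {
      p <- file.path(idir, sprintf("stage_%s_rep%d.meth.tsv", st, r))
      write_cpg_table(stg$stages[[st]][[r]], p)
      rows[[length(rows) + 1L]] <-
        data.table(role = "stage_methylation", dataset = NA_character_,
                   sample_id = sprintf("%s_rep%d", st, r),
                   individual = NA_character_, tissue = NA_character_,
                   stage = st, path = p)
    }
  }

  # read-level calls over the planted regions (molecule-specific) and over
  # shifted decoy intervals (mosaic), emulating ME vs control clusters
  reads <- rbindlist(lapply(seq_len(nrow(sim$truth)), function(i) {
    reg <- sim$truth[i]
    rm_ <- cfg$read_model
    me_reads <- simulate_cluster_reads(
      reg, n_reads = 30L, read_model = rm_, mean_methylation = 0.5,
      seed = child_seed(cfg$seed, 100L + i))
    me_reads[, read_id := paste0(reg$label, "_", read_id)]
    me_reads
  }))
  rp <- file.path(idir, "embryonic_liver.reads.tsv")
  write_read_calls(reads, rp)
  rows[[length(rows) + 1L]] <-
    data.table(role = "read_calls", dataset = NA_character_,
               sample_id = NA_character_, individual = NA_character_,
               tissue = NA_character_, stage = "embryonic_liver", path = rp)

  feats <- simulate_feature_tracks(sim$truth, cfg$chrom_sizes,
                                   enrichment_factor = 15,
                                   background_density = 5e-5,
                                   seed = child_seed(cfg$seed, 200L))
  fp <- file.path(idir, "features.bed")
  write_bed(feats, fp)
  rows[[length(rows) + 1L]] <-
    data.table(role = "features", dataset = "demo_features",
               sample_id = NA_character_, individual = NA_character_,
               tissue = NA_character_, stage = NA_character_, path = fp)

  list(manifest = rbindlist(rows), truth = sim$truth, cfg = cfg)
}
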