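# Interval enrichment statistics: Fisher's exact test from the
# hypergeometric distribution, 1-kb genome tiling, proximity profiles,
# chromatin-state overlap, mQTL enrichment and region-overlap tests.

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value from the conditional hypergeometric distribution
#' (tables at least as extreme as observed, i.e. with probability not
#' exceeding the observed table's, up to a relative tolerance of 1e-7).
#' The odds ratio is the sample odds ratio `(a d) / (b c)`, reported as
#' `Inf` when `b c = 0` with `a d > 0`, `0` when `a d = 0` with `b c > 0`,
#' and `NA` when both vanish.
#'
#' @param a,b,c,d cell counts (row = feature status, column = region
#'   status), or a 2x2 matrix as `a`.
#' @return list with `odds_ratio`, `p_value`, `table`.
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2L))
    d <- a[2L, 2L]; c <- a[2L, 1L]; b <- a[1L, 2L]; a <- a[1L, 1L]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells)))
    stop_mescan("table cells must be non-negative integers")
  if (sum(cells) == 0) stop_mescan("all-zero contingency table")
  ad <- as.numeric(a) * d; bc <- as.numeric(b) * c
  or <- if (bc > 0) ad / bc else if (ad > 0) Inf else NA_real_
  r1 <- a + b; c1 <- a + c; N <- sum(cells)
  lo <- max(0L, c1 - (N - r1)); hi <- min(r1, c1)
  k <- lo:hi
  logp <- lchoose(r1, k) + lchoose(N - r1, c1 - k) - lchoose(N, c1)
  p_obs <- logp[k == a]
  p <- sum(exp(logp[logp <= p_obs + log(1 + 1e-7)]))
  list(odds_ratio = or, p_value = min(1, p),
       table = matrix(cells, 2L, 2L, byrow = TRUE))
}

#' Divide a genome into fixed-size tiles
#'
#' Half-open tiles `[k s, (k+1) s)`; the final partial tile of each
#' chromosome is kept. Zero-length chromosomes produce no tiles.
#'
#' @param chrom_sizes named vector of chromosome lengths.
#' @param tile_size tile width in bp. Default 1000.
#' @return a `GRanges` of tiles.
#' @export
tile_genome <- function(chrom_sizes, tile_size = 1000L) {
  if (tile_size <= 0) stop_mescan("tile_size must be positive")
  sz <- chrom_sizes[chrom_sizes > 0L]
  if (!length(sz)) return(GenomicRanges::GRanges())
  GenomicRanges::tileGenome(setNames(as.integer(sz), names(sz)),
                            tilewidth = as.integer(tile_size),
                            cut.last.tile.in.chrom = TRUE)
}

new_enrichment_result <- function(table, or, p, test, window = NA,
                                  extra = list()) {
  structure(c(list(table = table, odds_ratio = or, p_value = p,
                   test = test, window = window), extra),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %s: OR=%.3g p=%.3g\n", x$test,
              x$odds_ratio, x$p_value))
  print(x$table)
  invisible(x)
}

#' Tile-based enrichment of features near regions
#'
#' Divides the genome into tiles and crosses each tile's feature-overlap
#' status with its region-proximity status (tile intersects a region
#' expanded by `window` bp), then applies Fisher's exact test. With
#' `cpg_pos` supplied, each tile contributes its CpG count instead of 1
#' (CpG-count weighting, adjusting for the genomic distribution of CpGs).
#'
#' @param features,regions interval tables (`chrom`, `start`, `end`).
#' @param chrom_sizes named chromosome lengths.
#' @param window proximity window in bp. Default 10000.
#' @param tile_size tile width. Default 1000.
#' @param cpg_pos optional table with `chrom`, `pos` for CpG weighting.
#' @return an `enrichment_result` (cells: a = feature+ proximal+, b =
#'   feature+ distal, c = feature- proximal+, d = feature- distal).
#' @export
tile_enrichment <- function(features, regions, chrom_sizes,
                            window = 10000L, tile_size = 1000L,
                            cpg_pos = NULL) {
  features <- as.data.table(features); regions <- as.data.table(regions)
  if (!nrow(features)) stop_mescan("empty feature set")
  if (!nrow(regions)) stop_mescan("empty region set")
  tiles <- tile_genome(chrom_sizes, tile_size)
  fgr <- as_granges(features)
  halo <- regions[, .(chrom, start = pmax(0L, start - as.integer(window)),
                      end = end + as.integer(window))]
  f <- IRanges::overlapsAny(tiles, fgr)
  r <- IRanges::overlapsAny(tiles, as_granges(halo))
  w <- if (is.null(cpg_pos)) rep(1L, length(tiles)) else {
    cp <- as.data.table(cpg_pos)
    S4Vectors::countQueryHits(
      GenomicRanges::findOverlaps(
        tiles, GenomicRanges::GRanges(cp$chrom,
                                      IRanges::IRanges(cp$pos + 1L, width = 1L))))
  }
  cells <- c(a = sum(w[f & r]), b = sum(w[f & !r]),
             c = sum(w[!f & r]), d = sum(w[!f & !r]))
  if (cells["a"] + cells["b"] == 0 || cells["c"] + cells["d"] == 0 ||
      cells["a"] + cells["c"] == 0 || cells["b"] + cells["d"] == 0)
    stop_mescan("degenerate tile table (a zero margin): %s",
                paste(cells, collapse = ","))
  ft <- fisher_exact(cells["a"], cells["b"], cells["c"], cells["d"])
  new_enrichment_result(ft$table, ft$odds_ratio, ft$p_value,
                        test = "tile FET", window = window,
                        extra = list(tile_size = tile_size,
                                     cpg_weighted = !is.null(cpg_pos)))
}

#' Proportion of regions with a feature within given distances
#'
#' Distance 0 means exact interval overlap; a positive distance `d` counts
#' regions whose minimum interval gap to any feature is at most `d`
#' (inclusive). Proportions are therefore non-decreasing in the threshold.
#'
#' @param regions,features interval tables.
#' @param thresholds distances in bp. Default `c(0, 1000, 10000)`.
#' @return `data.table`: `threshold`, `n_regions`, `n_within`,
#'   `proportion`.
#' @export
proximity_profile <- function(regions, features,
                              thresholds = c(0L, 1000L, 10000L)) {
  regions <- as.data.table(regions); features <- as.data.table(features)
  n <- nrow(regions)
  if (n == 0L)
    return(data.table(threshold = thresholds, n_regions = 0L,
                      n_within = 0L, proportion = NA_real_))
  rgr <- as_granges(regions)
  if (!nrow(features)) {
    return(data.table(threshold = thresholds, n_regions = n, n_within = 0L,
                      proportion = 0))
  }
  fgr <- as_granges(features)
  ov <- IRanges::overlapsAny(rgr, fgr)
  dtn <- GenomicRanges::distanceToNearest(rgr, fgr)
  gap <- rep(Inf, n)
  gap[S4Vectors::queryHits(dtn)] <- S4Vectors::mcols(dtn)$distance
  rbindlist(lapply(sort(thresholds), function(th) {
    hit <- if (th == 0) ov else (ov | gap <= th)
    data.table(threshold = th, n_regions = n, n_within = sum(hit),
               proportion = mean(hit))
  }))
}

#' Default 15-state to 8-group chromatin-state collapse
#'
#' Maps the 15 chromHMM core-model states onto eight groups of similar
#' genomic features (TSS, enhancer, transcription, ZNF/repeats,
#' heterochromatin, bivalent, repressed-Polycomb, quiescent).
#'
#' @return named character vector (state label -> group).
#' @export
default_state_map <- function() {
  c(TssA = "TSS", TssAFlnk = "TSS",
    Enh = "Enhancer", EnhG = "Enhancer",
    Tx = "Transcription", TxWk = "Transcription", TxFlnk = "Transcription",
    `ZNF/Rpts` = "ZNF", Het = "Heterochromatin",
    TssBiv = "Bivalent", BivFlnk = "Bivalent", EnhBiv = "Bivalent",
    ReprPC = "Repressed-Polycomb", ReprPCWk = "Repressed-Polycomb",
    Quies = "Quiescent")
}

#' Chromatin-state overlap of regions
#'
#' Collapses segment state labels through `state_map` and reports, per
#' collapsed group, the proportion of region base pairs -- and of genome
#' base pairs -- assigned to that group. When the segmentation tiles the
#' genome the proportions sum to 1.
#'
#' @param regions interval table.
#' @param state_segments interval table with a `label` column of state
#'   names.
#' @param state_map named vector mapping each state label to a group.
#'   Default [default_state_map()].
#' @param chrom_sizes optional named lengths for the genome denominator;
#'   defaults to the total segment span.
#' @return `data.table`: `group`, `region_bp`, `region_prop`, `genome_bp`,
#'   `genome_prop`.
#' @export
chromhmm_overlap <- function(regions, state_segments,
                             state_map = default_state_map(),
                             chrom_sizes = NULL) {
  regions <- as.data.table(regions)
  seg <- as.data.table(state_segments)
  if (!nrow(seg)) stop_mescan("empty state segmentation")
  unknown <- setdiff(unique(seg$label), names(state_map))
  if (length(unknown))
    stop_mescan("unmapped chromatin state label(s): %s",
                paste(unknown, collapse = ", "))
  seg[, group := unname(state_map[label])]
  groups <- unique(unname(state_map))
  rgr <- GenomicRanges::reduce(as_granges(regions))
  region_bp <- sum(as.numeric(GenomicRanges::width(rgr)))
  genome_bp <- if (!is.null(chrom_sizes)) sum(as.numeric(chrom_sizes))
               else sum(as.numeric(seg$end - seg$start))
  out <- rbindlist(lapply(groups, function(g) {
    ggr <- GenomicRanges::reduce(as_granges(seg[group == g]))
    gbp <- sum(as.numeric(GenomicRanges::width(ggr)))
    rb <- sum(as.numeric(GenomicRanges::width(
      GenomicRanges::intersect(rgr, ggr, ignore.strand = TRUE))))
    data.table(group = g, region_bp = rb,
               region_prop = if (region_bp > 0) rb / region_bp else NA_real_,
               genome_bp = gbp, genome_prop = gbp / genome_bp)
  }))
  out[]
}

#' Enrichment of mQTL-associated CpGs inside regions
#'
#' Restricts an array CpG table to the union of mQTL-associated (at any
#' time point) and "reliable" CpGs, then crosses region membership with
#' mQTL association in a Fisher's exact test.
#'
#' @param me_regions region table.
#' @param array_cpg_table table with `chrom`, `pos`, `mqtl` (logical,
#'   associated at any time point), `reliable` (logical).
#' @return an `enrichment_result` (a = inside & mQTL, b = inside &
#'   non-mQTL, c = outside & mQTL, d = outside & non-mQTL).
#' @export
mqtl_enrichment <- function(me_regions, array_cpg_table) {
  tbl <- as.data.table(array_cpg_table)
  if (!nrow(tbl)) stop_mescan("empty array CpG table")
  tbl <- tbl[mqtl | reliable]
  if (!nrow(tbl)) stop_mescan("no mQTL-associated or reliable CpGs")
  inside <- pos_in_regions(tbl$chrom, tbl$pos, as.data.table(me_regions))
  if (!any(inside)) stop_mescan("no array CpGs inside the regions")
  ft <- fisher_exact(sum(inside & tbl$mqtl), sum(inside & !tbl$mqtl),
                     sum(!inside & tbl$mqtl), sum(!inside & !tbl$mqtl))
  new_enrichment_result(ft$table, ft$odds_ratio, ft$p_value,
                        test = "mQTL FET",
                        extra = list(n_inside = sum(inside)))
}

#' Methylation variance explained by mQTL within regions
#'
#' @param variance_table table with `chrom`, `pos`, `prop` (proportion of
#'   methylation variance explained, in `[0, 1]`).
#' @param regions region table.
#' @return list with `median`, `iqr` (25th and 75th percentiles), `n`.
#' @export
variance_explained_summary <- function(variance_table, regions) {
  tbl <- as.data.table(variance_table)
  if (any(tbl$prop < 0 | tbl$prop > 1))
    stop_mescan("variance proportions must lie in [0, 1]")
  inside <- pos_in_regions(tbl$chrom, tbl$pos, as.data.table(regions))
  if (!any(inside)) stop_mescan("no variance-table CpGs overlap the regions")
  x <- tbl$prop[inside]
  list(median = median(x),
       iqr = quantile(x, c(0.25, 0.75), names = FALSE), n = length(x))
}

#' Tile-based overlap enrichment between two region sets
#'
#' Crosses, per genome tile, overlap with the query set against overlap
#' with the target set (Fisher's exact test), and reports the raw count of
#' query regions intersecting at least one target region.
#'
#' @param query_regions,target_regions interval tables.
#' @param chrom_sizes named chromosome lengths.
#' @param tile_size tile width. Default 1000.
#' @return an `enrichment_result` with extra field `overlap_count`.
#' @export
region_overlap_enrichment <- function(query_regions, target_regions,
                                      chrom_sizes, tile_size = 1000L) {
  query <- as.data.table(query_regions)
  target <- as.data.table(target_regions)
  if (!nrow(query) || !nrow(target)) stop_mescan("empty region input")
  tiles <- tile_genome(chrom_sizes, tile_size)
  q <- IRanges::overlapsAny(tiles, as_granges(query))
  t_ <- IRanges::overlapsAny(tiles, as_granges(target))
  ft <- fisher_exact(sum(q & t_), sum(q & !t_), sum(!q & t_), sum(!q & !t_))
  n_ov <- sum(IRanges::overlapsAny(as_granges(query), as_granges(target)))
  new_enrichment_result(ft$table, ft$odds_ratio, ft$p_value,
                        test = "region-overlap tile FET",
                        extra = list(overlap_count = n_ov,
                                     tile_size = tile_size))
}
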