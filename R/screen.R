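# The metastable-epiallele screen: per-CpG metastability verdicts,
# SNP-proximity masking, cross-dataset combination, single-linkage
# clustering, purity filtering, and matched control-cluster sampling.

#' Per-CpG metastability verdicts
#'
#' For every CpG dyad covered in *all* samples of the cohort, computes
#' `d_inter` -- the maximum absolute difference between individuals'
#' tissue-averaged methylation fractions -- and `d_intra` -- the maximum
#' absolute within-individual between-tissue difference. A CpG passes when
#' `d_inter >= inter_threshold` (default 15% absolute difference) and
#' `d_intra <= d_inter * intra_ratio` (default one third): systemic
#' interindividual variation with intertissue concordance. With more than
#' two individuals or tissues the maxima over pairs are used, which reduces
#' to the plain differences in the two-by-two design.
#'
#' @param cohort a [meth_cohort()] (one dataset; >= 2 individuals and
#'   >= 2 tissues).
#' @param inter_threshold minimum interindividual difference. Default 0.15.
#' @param intra_ratio maximum allowed ratio of intertissue to
#'   interindividual difference. Default 1/3.
#' @return keyed `data.table`: `chrom`, `pos`, `d_inter`, `d_intra`,
#'   `passes`.
#' @export
detect_me_cpgs <- function(cohort, inter_threshold = 0.15,
                           intra_ratio = 1 / 3) {
  stopifnot(inherits(cohort, "meth_cohort"))
  meta <- cohort$meta
  if (uniqueN(meta$individual) < 2L || uniqueN(meta$tissue) < 2L)
    stop_mescan("the screen needs >= 2 individuals and >= 2 tissues")
  long <- rbindlist(lapply(names(cohort$samples), function(sid)
    cohort$samples[[sid]][, .(chrom, pos, frac = n_meth / n_total,
                              sample_id = sid)]))
  long <- merge(long, meta[, .(sample_id, individual, tissue)],
                by = "sample_id")
  n_samples <- nrow(meta)
  long[, n_cov := .N, by = .(chrom, pos)]
  long <- long[n_cov == n_samples]
  if (!nrow(long))
    return(data.table(chrom = character(), pos = integer(),
                      d_inter = numeric(), d_intra = numeric(),
                      passes = logical(), key = c("chrom", "pos")))
  per_ind <- long[, .(ind_mean = mean(frac),
                      tis_range = max(frac) - min(frac)),
                  by = .(chrom, pos, individual)]
  v <- per_ind[, .(d_inter = max(ind_mean) - min(ind_mean),
                   d_intra = max(tis_range)),
               by = .(chrom, pos)]
  v[, passes := d_inter >= inter_threshold & d_intra <= d_inter * intra_ratio]
  setkeyv(v, c("chrom", "pos"))
  v[]
}

#' Remove CpGs within a window of a SNP
#'
#' Guards the screen against methylation variation driven by proximal
#' genetic variants (e.g. allele-specific methylation): a CpG is dropped if
#' any SNP of the same dataset lies within `window` bp (inclusive
#' boundary), applied per dataset before cross-dataset combination.
#'
#' @param cpgs table with `chrom`, `pos`.
#' @param snps SNP position table (`chrom`, `pos`, 0-based), e.g. from
#'   [read_snp_vcf()]; `NULL` is treated as no SNPs.
#' @param window distance in bp. Default 60.
#' @return `cpgs` without SNP-proximal rows; the number removed is attached
#'   as attribute `n_removed`.
#' @export
filter_snp_proximal <- function(cpgs, snps, window = 60L) {
  cpgs <- as.data.table(cpgs)
  if (is.null(snps) || !nrow(snps) || !nrow(cpgs)) {
    setattr(cpgs, "n_removed", 0L)
    return(cpgs[])
  }
  snps <- as.data.table(snps)
  hit <- rep(FALSE, nrow(cpgs))
  for (ch in unique(cpgs$chrom)) {
    i <- which(cpgs$chrom == ch)
    sp <- sort(snps[chrom == ch, pos])
    if (!length(sp)) next
    p <- cpgs$pos[i]
    below <- findInterval(p, sp)            # nearest SNP at or below
    d_lo <- ifelse(below >= 1L, p - sp[pmax(below, 1L)], Inf)
    d_hi <- ifelse(below < length(sp), sp[pmin(below + 1L, length(sp))] - p,
                   Inf)
    hit[i] <- pmin(d_lo, d_hi) <= window
  }
  out <- cpgs[!hit]
  setattr(out, "n_removed", sum(hit))
  out[]
}

#' Combine per-dataset CpG sets
#'
#' @param sets list of tables with `chrom`, `pos`.
#' @param mode `"intersection"` (a CpG must qualify in every dataset) or
#'   `"union"`.
#' @return combined keyed `data.table` (`chrom`, `pos`).
#' @export
combine_datasets <- function(sets, mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  sets <- lapply(sets, function(s)
    unique(as.data.table(s)[, .(chrom, pos)]))
  out <- if (mode == "union") {
    unique(rbindlist(sets))
  } else {
    Reduce(function(a, b) merge(a, b, by = c("chrom", "pos")), sets)
  }
  setkeyv(out, c("chrom", "pos"))
  out[]
}

#' Single-linkage clustering of CpG positions
#'
#' Chains consecutive CpGs no more than `max_gap` bp apart, then keeps
#' chains with at least `min_cpgs` members. The cluster interval spans the
#' first to the last member CpG; the exclusive end is the last position + 2
#' so the final dyad is covered.
#'
#' @param cpgs table with `chrom`, `pos`.
#' @param max_gap maximum gap between consecutive members (bp). Default 300.
#' @param min_cpgs minimum members per cluster. Default 4.
#' @return region `data.table`: `chrom`, `start`, `end`, `n_me_cpg`, and a
#'   list-column `me_pos` of member positions.
#' @export
cluster_cpgs <- function(cpgs, max_gap = 300L, min_cpgs = 4L) {
  cpgs <- unique(as.data.table(cpgs)[, .(chrom, pos)])
  if (!nrow(cpgs))
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), n_me_cpg = integer(),
                      me_pos = list()))
  setorderv(cpgs, c("chrom", "pos"))
  cpgs[, grp := cumsum(c(TRUE, diff(pos) > max_gap)), by = chrom]
  cl <- cpgs[, .(start = min(pos), end = max(pos) + 2L, n_me_cpg = .N,
                 me_pos = list(pos)), by = .(chrom, grp)]
  cl <- cl[n_me_cpg >= min_cpgs][, grp := NULL]
  setorderv(cl, c("chrom", "start"))
  cl[]
}

#' Purity filter on clusters
#'
#' Keeps clusters with at least `min_ratio` times as many ME-CpGs as
#' non-ME-CpGs, where non-ME-CpGs are covered CpGs inside the cluster
#' interval that did not qualify as ME-CpGs.
#'
#' @param clusters output of [cluster_cpgs()].
#' @param covered_cpgs table of all covered CpGs (`chrom`, `pos`).
#' @param min_ratio required ME:non-ME ratio. Default 2.
#' @return surviving clusters with an added `n_non_me_cpg` column.
#' @export
purity_filter <- function(clusters, covered_cpgs, min_ratio = 2) {
  clusters <- as.data.table(clusters)
  if (!nrow(clusters)) {
    clusters[, n_non_me_cpg := integer()]
    return(clusters[])
  }
  covered <- as.data.table(covered_cpgs)
  n_in <- vapply(seq_len(nrow(clusters)), function(i)
    covered[chrom == clusters$chrom[i] & pos >= clusters$start[i] &
              pos < clusters$end[i], .N], integer(1))
  clusters[, n_non_me_cpg := pmax(n_in - n_me_cpg, 0L)]
  out <- clusters[n_me_cpg >= min_ratio * n_non_me_cpg]
  out[]
}

#' Sample control clusters matched on size and CpG count
#'
#' Applies the ME clustering parameters to *all* covered CpGs
#' (irrespective of methylation), removes candidates overlapping an ME
#' cluster, and draws a stratified sample without replacement from the 2-D
#' bins of (span quintile x CpG-count quintile), quantiles computed on the
#' ME set, with cell counts proportional to the ME joint histogram. When a
#' cell's candidate pool is exhausted its shortfall is reallocated
#' proportionally to the remaining cells, with a warning.
#'
#' @param covered_cpgs all covered CpGs (`chrom`, `pos`).
#' @param me_clusters the ME cluster table.
#' @param n_controls number of controls wanted; default 8 per ME cluster.
#' @param seed integer seed; the sample is deterministic given it.
#' @param max_gap,min_cpgs clustering parameters (identical to the ME run).
#' @param n_bins marginal bin count for the joint histogram. Default 5
#'   (quintiles).
#' @return control cluster table with `role = "control"`.
#' @export
generate_control_clusters <- function(covered_cpgs, me_clusters,
                                      n_controls = NULL, seed = 1L,
                                      max_gap = 300L, min_cpgs = 4L,
                                      n_bins = 5L) {
  me <- as.data.table(me_clusters)
  if (!nrow(me)) stop_mescan("empty ME cluster set: nothing to match")
  n_controls <- as.integer(n_controls %||% (8L * nrow(me)))
  pool <- cluster_cpgs(covered_cpgs, max_gap = max_gap, min_cpgs = min_cpgs)
  if (nrow(pool)) {
    ov <- IRanges::overlapsAny(as_granges(pool), as_granges(me))
    pool <- pool[!ov]
  }
  if (!nrow(pool)) stop_mescan("no control candidates after ME exclusion")
  if (nrow(pool) < n_controls) {
    warning(sprintf("candidate pool (%d) smaller than n_controls (%d); capping",
                    nrow(pool), n_controls))
    n_controls <- nrow(pool)
  }
  brk_span <- bin_breaks(me$end - me$start, n_bins)
  brk_cpg <- bin_breaks(me$n_me_cpg, n_bins)
  me_cell <- joint_cell(me$end - me$start, me$n_me_cpg, brk_span, brk_cpg)
  pool[, cell := joint_cell(end - start, n_me_cpg, brk_span, brk_cpg)]
  cells <- sort(unique(me_cell))
  want <- apportion(tabulate(factor(me_cell, cells)), n_controls)
  names(want) <- cells
  supply <- pool[, .N, keyby = cell]
  take <- setNames(integer(length(cells)), cells)
  remaining <- want
  repeat {
    avail <- setNames(rep(0L, length(cells)), cells)
    got <- supply[cell %in% cells]
    avail[got$cell] <- got$N
    grant <- pmin(remaining, pmax(avail - take, 0L))
    take <- take + grant
    short <- sum(remaining - grant)
    if (short == 0L) break
    open <- avail - take > 0L
    if (!any(open)) {
      warning(sprintf("control pool exhausted; %d short of target", short))
      break
    }
    warning("some control bins under-supplied; reallocating proportionally")
    remaining <- setNames(rep(0L, length(cells)), cells)
    remaining[open] <- apportion(want[open] + 1e-9, short)
  }
  # also allow draws from cells outside the ME support if still short
  picked <- with_seed(seed, {
    idx <- unlist(lapply(cells[take > 0L], function(cl) {
      cand <- which(pool$cell == cl)
      cand[sample.int(length(cand), take[[cl]])]
    }))
    deficit <- n_controls - length(idx)
    if (deficit > 0L) {
      rest <- setdiff(seq_len(nrow(pool)), idx)
      idx <- c(idx, rest[sample.int(length(rest), min(deficit, length(rest)))])
    }
    idx
  })
  out <- pool[sort(picked)][, cell := NULL]
  setnames(out, "n_me_cpg", "n_cpg")
  out[, role := "control"]
  out[]
}

bin_breaks <- function(x, n_bins) {
  b <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                       names = FALSE, type = 7))
  if (length(b) < 2L) return(c(-Inf, Inf))  # all values identical: one bin
  b[1L] <- -Inf
  b[length(b)] <- Inf
  b
}

joint_cell <- function(span, n_cpg, brk_span, brk_cpg) {
  paste(cut(span, brk_span, labels = FALSE, include.lowest = TRUE),
        cut(n_cpg, brk_cpg, labels = FALSE, include.lowest = TRUE),
        sep = ":")
}

#' Run the full metastable-epiallele screen
#'
#' Per dataset: per-CpG metastability verdicts on fully covered CpGs, then
#' SNP-proximity masking. The per-dataset passing sets are combined
#' (`intersection` by default: a locus must show metastability in every
#' dataset), clustered by single linkage, and purity-filtered against the
#' set of CpGs covered in every sample of at least one dataset.
#'
#' @param cohorts named list of [meth_cohort()], one per dataset.
#' @param snps named list of SNP tables aligned with `cohorts` (or `NULL`
#'   to skip the SNP filter with a warning).
#' @param inter_threshold,intra_ratio see [detect_me_cpgs()].
#' @param snp_window see [filter_snp_proximal()].
#' @param max_gap,min_cpgs see [cluster_cpgs()].
#' @param purity_ratio see [purity_filter()].
#' @param combine_mode see [combine_datasets()].
#' @return object of class `me_screen`: list with `me_clusters` (with
#'   `role = "ME"`), `covered` (the purity-filter denominator set),
#'   `per_dataset` (verdicts and counts) and `log` (stage in/out counts).
#' @export
run_me_screen <- function(cohorts, snps = NULL, inter_threshold = 0.15,
                          intra_ratio = 1 / 3, snp_window = 60L,
                          max_gap = 300L, min_cpgs = 4L, purity_ratio = 2,
                          combine_mode = "intersection") {
  if (inherits(cohorts, "meth_cohort")) cohorts <- list(ds1 = cohorts)
  log <- list()
  per_dataset <- list()
  passing <- list()
  covered_all <- list()
  if (is.null(snps)) warning("no SNP sets supplied; SNP filter skipped")
  for (d in names(cohorts)) {
    v <- detect_me_cpgs(cohorts[[d]], inter_threshold, intra_ratio)
    pass <- v[passes == TRUE, .(chrom, pos)]
    filt <- filter_snp_proximal(pass, snps[[d]], snp_window)
    per_dataset[[d]] <- list(verdicts = v, n_covered = nrow(v),
                             n_pass = nrow(pass),
                             n_snp_removed = attr(filt, "n_removed"))
    passing[[d]] <- filt
    covered_all[[d]] <- v[, .(chrom, pos)]
    log[[d]] <- data.table(dataset = d, covered = nrow(v),
                           pass = nrow(pass),
                           after_snp_filter = nrow(filt))
  }
  me_cpgs <- combine_datasets(passing, combine_mode)
  covered <- combine_datasets(covered_all, "union")
  clusters <- cluster_cpgs(me_cpgs, max_gap, min_cpgs)
  me <- purity_filter(clusters, covered, purity_ratio)
  me[, role := "ME"]
  structure(list(
    me_clusters = me[], covered = covered, per_dataset = per_dataset,
    me_cpgs = me_cpgs,
    log = rbindlist(log)[, `:=`(combined = nrow(me_cpgs),
                                clusters = nrow(clusters),
                                after_purity = nrow(me))]),
    class = "me_screen")
}

#' @export
print.me_screen <- function(x, ...) {
  cat(sprintf("<me_screen> %d ME clusters from %d qualifying CpGs\n",
              nrow(x$me_clusters), nrow(x$me_cpgs)))
  print(x$log)
  invisible(x)
}

#' Compare detected clusters with planted truth
#'
#' @param detected,truth region tables.
#' @return list with `sensitivity` (truth regions overlapped by a detected
#'   cluster), `fdp` (detected clusters overlapping no truth region),
#'   `n_detected`, `n_truth`.
#' @export
screen_recovery <- function(detected, truth) {
  detected <- as.data.table(detected); truth <- as.data.table(truth)
  if (!nrow(truth)) stop_mescan("empty truth set")
  if (!nrow(detected))
    return(list(sensitivity = 0, fdp = NA_real_, n_detected = 0L,
                n_truth = nrow(truth)))
  hit_truth <- IRanges::overlapsAny(as_granges(truth), as_granges(detected))
  hit_det <- IRanges::overlapsAny(as_granges(detected), as_granges(truth))
  list(sensitivity = mean(hit_truth), fdp = mean(!hit_det),
       n_detected = nrow(detected), n_truth = nrow(truth))
}
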