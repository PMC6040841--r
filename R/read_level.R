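# Read-level methylation and the read homogeneity index (RHI). The RHI
# asks whether intermediate methylation at a cluster is molecule-specific
# (reads are internally homogeneous: few adjacent-call transitions) or
# mosaic (methylated calls scattered across reads). It compares the
# observed transition count with the median count after randomly
# redistributing the same number of methylated calls across the cluster's
# called positions, preserving read structure and missing calls.

#' Per-read methylation level
#'
#' A read's methylation is the fraction of its called CpGs that are
#' methylated; reads with fewer than `min_cpgs` called CpGs are excluded
#' (used for read-level methylation distributions -- the RHI deliberately
#' keeps short reads).
#'
#' @param reads a [read_calls()] table.
#' @param min_cpgs minimum called CpGs per read. Default 4.
#' @return `data.table`: `read_id`, `n_called`, `methylation`, `excluded`.
#' @export
read_methylation <- function(reads, min_cpgs = 4L) {
  dt <- as.data.table(reads)
  if (!nrow(dt))
    return(data.table(read_id = character(), n_called = integer(),
                      methylation = numeric(), excluded = logical()))
  out <- dt[call != ".", .(n_called = .N, methylation = mean(call == "M")),
            by = read_id]
  out[, excluded := n_called < min_cpgs]
  out[excluded == TRUE, methylation := NA_real_]
  out[]
}

#' Clip reads to a region
#'
#' Calls at positions outside `[start, end)` are removed; reads left with
#' no called in-region CpG are dropped.
#'
#' @param reads a [read_calls()] table.
#' @param region list/row with `chrom`, `start`, `end`.
#' @return clipped [read_calls()] table.
#' @export
clip_reads_to_region <- function(reads, region) {
  dt <- as.data.table(reads)
  dt <- dt[chrom == as.character(region$chrom) & pos >= region$start &
             pos < region$end]
  keep <- dt[call != ".", unique(read_id)]
  dt <- dt[read_id %in% keep]
  validate_read_calls(dt)
}

# index pairs of adjacent called CpGs within reads (missing calls are
# bridged, not breaking the read), over rows of `called` ordered by
# (read_id, pos)
adjacent_pairs <- function(called) {
  n <- nrow(called)
  if (n < 2L) return(list(i = integer(), j = integer()))
  same <- called$read_id[-n] == called$read_id[-1L]
  list(i = which(same), j = which(same) + 1L)
}

#' Count adjacent-call methylation transitions
#'
#' A transition is any instance of two adjacent CpGs on the same read with
#' different methylation calls. Adjacency is between consecutive *called*
#' CpGs: missing calls are skipped and do not break the read.
#'
#' @param reads a [read_calls()] table (clip to a region first if needed).
#' @return total transition count over all reads (integer).
#' @export
count_transitions <- function(reads) {
  called <- as.data.table(reads)[call != "."]
  if (!nrow(called)) return(0L)
  setorderv(called, c("read_id", "pos"))
  pr <- adjacent_pairs(called)
  sum(called$call[pr$i] != called$call[pr$j])
}

#' Normalize an RHI from its transition counts
#'
#' The read homogeneity index is the median randomized transition count
#' divided by the observed transition count; an observed count of zero
#' leaves the index undefined (`NA`).
#'
#' @param observed observed transition count.
#' @param median_randomized median transition count over randomizations.
#' @return the ratio, or `NA` when `observed` is 0.
#' @export
rhi_normalize <- function(observed, median_randomized) {
  stopifnot(observed >= 0, median_randomized >= 0)
  if (observed == 0) return(NA_real_)
  median_randomized / observed
}

#' Compute the read homogeneity index for one cluster
#'
#' All reads overlapping the cluster are combined and clipped to it. The
#' observed transition count is compared against `n_rand` randomizations
#' that permute the multiset of all called values uniformly across all
#' called positions in the cluster (cluster-wide permutation; read
#' locations and missing positions are preserved, and every randomization
#' carries exactly the observed number of methylated calls). The RHI is
#' the median randomized count (lower median for even `n_rand`, so worked
#' examples are stable integers) divided by the observed count. Values
#' above 1 indicate molecule-specific (homogeneous-read) methylation.
#'
#' @param reads a [read_calls()] table.
#' @param region optional region to clip to.
#' @param n_rand number of randomizations. Default 1000.
#' @param seed integer seed (`NULL` uses the current RNG stream).
#' @return object of class `rhi_result`: `region`, `observed_transitions`,
#'   `randomized_transitions`, `median_randomized`, `rhi`, `n_reads`,
#'   `n_called_positions`.
#' @export
compute_rhi <- function(reads, region = NULL, n_rand = 1000L, seed = NULL) {
  dt <- as.data.table(reads)
  if (!is.null(region)) dt <- clip_reads_to_region(dt, region)
  called <- dt[call != "."]
  if (!nrow(called)) stop_mescan("no called CpGs in the cluster")
  setorderv(called, c("read_id", "pos"))
  pr <- adjacent_pairs(called)
  if (!length(pr$i))
    stop_mescan("no read with >= 2 called in-region CpGs: no adjacency exists")
  v <- called$call == "M"
  obs <- sum(v[pr$i] != v[pr$j])
  n <- length(v)
  rand <- with_seed(seed, vapply(seq_len(n_rand), function(k) {
    p <- v[sample.int(n)]
    sum(p[pr$i] != p[pr$j])
  }, integer(1)))
  med <- lower_median(rand)
  structure(list(region = region, observed_transitions = obs,
                 randomized_transitions = rand, median_randomized = med,
                 rhi = rhi_normalize(obs, med),
                 n_reads = uniqueN(called$read_id),
                 n_called_positions = n),
            class = "rhi_result")
}

#' @export
print.rhi_result <- function(x, ...) {
  cat(sprintf("<rhi_result> observed=%d median_randomized=%d RHI=%s (%d reads, %d called CpGs)\n",
              x$observed_transitions, x$median_randomized,
              if (is.na(x$rhi)) "NA" else sprintf("%.2f", x$rhi),
              x$n_reads, x$n_called_positions))
  invisible(x)
}

#' Exact null distribution of the transition count
#'
#' Enumerates every arrangement of the observed number of methylated calls
#' across the cluster's called positions (all `choose(n, M)` of them) and
#' tabulates the transition count of each. Feasible for small clusters
#' only; serves as the exact reference the sampled randomization is
#' checked against.
#'
#' @param reads a [read_calls()] table.
#' @param region optional region to clip to.
#' @param max_positions refuse enumeration beyond this many called
#'   positions. Default 16.
#' @return integer vector of transition counts, one per arrangement.
#' @export
rhi_exact_null <- function(reads, region = NULL, max_positions = 16L) {
  dt <- as.data.table(reads)
  if (!is.null(region)) dt <- clip_reads_to_region(dt, region)
  called <- dt[call != "."]
  setorderv(called, c("read_id", "pos"))
  n <- nrow(called)
  if (n == 0L) stop_mescan("no called CpGs")
  if (n > max_positions)
    stop_mescan("%d called positions exceed enumeration limit %d", n,
                max_positions)
  pr <- adjacent_pairs(called)
  M <- sum(called$call == "M")
  if (M == 0L || M == n) return(0L)
  combos <- utils::combn(n, M)
  apply(combos, 2L, function(ix) {
    p <- logical(n); p[ix] <- TRUE
    sum(p[pr$i] != p[pr$j])
  })
}

#' Eligibility of a cluster for RHI analysis
#'
#' Intermediately methylated clusters with enough reads: pooled mean
#' methylation of called CpGs within `band` and at least `min_reads` reads.
#'
#' @param reads a [read_calls()] table (already clipped).
#' @param band closed methylation band. Default `c(0.1, 0.9)`.
#' @param min_reads minimum read count. Default 5.
#' @return logical scalar with attribute `reason` when `FALSE`.
#' @export
rhi_eligible <- function(reads, band = c(0.1, 0.9), min_reads = 5L) {
  called <- as.data.table(reads)[call != "."]
  if (!nrow(called))
    return(structure(FALSE, reason = "no called CpGs"))
  m <- mean(called$call == "M")
  nr <- uniqueN(called$read_id)
  if (nr < min_reads)
    return(structure(FALSE, reason = sprintf("only %d reads", nr)))
  if (m < band[1L] || m > band[2L])
    return(structure(FALSE,
                     reason = sprintf("pooled methylation %.2f outside band", m)))
  TRUE
}

#' Compare two sets of RHI values
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. For small samples
#' (`choose(n1 + n2, n1) <= exact_limit`) the exact permutation
#' distribution of the rank-sum is enumerated, which handles ties;
#' otherwise the tie-corrected normal approximation is used. `NA` values
#' are removed first.
#'
#' @param rhi_a,rhi_b numeric vectors of RHI values.
#' @param exact_limit enumeration budget. Default 10000 combinations.
#' @return list with `statistic` (Mann-Whitney U of the first set),
#'   `p_value`, `method`, `n_a`, `n_b`.
#' @export
compare_rhi <- function(rhi_a, rhi_b, exact_limit = 10000) {
  a <- rhi_a[!is.na(rhi_a)]; b <- rhi_b[!is.na(rhi_b)]
  if (!length(a) || !length(b))
    stop_mescan("both RHI sets must be non-empty after NA removal")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (choose(N, n1) <= exact_limit) {
    combos <- utils::combn(N, n1)
    Us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation with tie correction"
  }
  list(statistic = U, p_value = p, method = method, n_a = n1, n_b = n2)
}
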