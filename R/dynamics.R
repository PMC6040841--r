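# Stage-wise methylation summaries across developmental series: per-stage
# means/histograms, intermediate-methylation fractions, and the stratified
# pre/post-gastrulation transition analysis with bootstrap CIs.

#' Summarize methylation at one developmental stage
#'
#' Each covered CpG contributes once per replicate in which it is covered
#' (replicate occurrences are counted separately). Coverage means total
#' depth from both strands of at least `min_depth`; an optional `max_depth`
#' cap excludes highly overrepresented CpGs (used in read-level work, off
#' by default here).
#'
#' @param replicates list of CpG site tables, one per replicate.
#' @param regions optional region table; restrict to CpGs inside them.
#' @param min_depth minimum depth. Default 10.
#' @param max_depth optional maximum depth (e.g. 200); `NULL` disables.
#' @param bins number of equal histogram bins on `[0, 1]`. Default 10; the
#'   final bin is right-closed.
#' @return object of class `stage_summary`: list with `n_cpgs`, `mean`,
#'   `histogram` (probability masses), `breaks`, `intermediate_frac`,
#'   `values`.
#' @export
stage_summary <- function(replicates, regions = NULL, min_depth = 10L,
                          max_depth = NULL, bins = 10L) {
  if (inherits(replicates, "data.frame")) replicates <- list(replicates)
  vals <- unlist(lapply(replicates, function(r) {
    r <- as.data.table(r)[n_total >= min_depth]
    if (!is.null(max_depth)) r <- r[n_total <= max_depth]
    if (!is.null(regions) && nrow(r))
      r <- r[pos_in_regions(chrom, pos, as.data.table(regions))]
    r[, n_meth / n_total]
  }))
  if (!length(vals)) stop_mescan("no covered CpGs at this stage")
  breaks <- seq(0, 1, length.out = bins + 1L)
  h <- hist_closed(vals, breaks)
  structure(list(n_cpgs = length(vals), mean = mean(vals),
                 histogram = h / length(vals), breaks = breaks,
                 intermediate_frac = intermediate_fraction(vals),
                 values = vals),
            class = "stage_summary")
}

# counts per bin; intervals [a, b) except the final bin which is [a, b]
hist_closed <- function(x, breaks) {
  idx <- findInterval(x, breaks, rightmost.closed = TRUE)
  idx[idx == 0L] <- 1L
  tabulate(idx, nbins = length(breaks) - 1L)
}

#' @export
print.stage_summary <- function(x, ...) {
  cat(sprintf("<stage_summary> n=%d mean=%.3f intermediate=%.3f\n",
              x$n_cpgs, x$mean, x$intermediate_frac))
  invisible(x)
}

#' Fraction of sites with intermediate methylation
#'
#' Intermediate means a methylation fraction between `lo` and `hi`
#' inclusive (default 10% to 90%).
#'
#' @param values methylation fractions in `[0, 1]`.
#' @param lo,hi closed-interval boundaries. Defaults 0.10 and 0.90.
#' @return proportion in `[0, 1]`.
#' @export
intermediate_fraction <- function(values, lo = 0.10, hi = 0.90) {
  if (!length(values)) stop_mescan("empty value set")
  if (any(values < 0 | values > 1)) stop_mescan("values must lie in [0, 1]")
  mean(values >= lo & values <= hi)
}

#' Post-stage methylation stratified by pre-stage methylation
#'
#' For every combination of one pre-stage and one post-stage replicate,
#' each CpG covered (depth >= `min_depth`) in both contributes one
#' (pre, post) observation. Observations are stratified by pre-stage
#' methylation into `strata_breaks` bins (left-closed; final bin closed),
#' and each stratum is summarized by its post-stage median with a
#' percentile bootstrap confidence interval.
#'
#' @param pre_reps,post_reps lists of CpG site tables (replicates of the
#'   pre- and post-transition stage).
#' @param strata_breaks stratum boundaries on pre-stage methylation.
#'   Default quartiles `c(0, .25, .5, .75, 1)`.
#' @param n_boot bootstrap resamples. Default 1000.
#' @param seed integer seed for the bootstrap.
#' @param min_depth coverage threshold. Default 10.
#' @param conf confidence level. Default 0.95.
#' @param regions optional region restriction.
#' @return `data.table`: `stratum`, `n`, `median`, `ci_lo`, `ci_hi`, plus
#'   the observation table as attribute `observations`. Empty strata get
#'   `NA` summaries and a message.
#' @export
stratified_transition <- function(pre_reps, post_reps,
                                  strata_breaks = c(0, 0.25, 0.5, 0.75, 1),
                                  n_boot = 1000L, seed = 1L,
                                  min_depth = 10L, conf = 0.95,
                                  regions = NULL) {
  if (inherits(pre_reps, "data.frame")) pre_reps <- list(pre_reps)
  if (inherits(post_reps, "data.frame")) post_reps <- list(post_reps)
  prep <- function(r) {
    r <- as.data.table(r)[n_total >= min_depth]
    if (!is.null(regions) && nrow(r))
      r <- r[pos_in_regions(chrom, pos, as.data.table(regions))]
    r[, .(chrom, pos, frac = n_meth / n_total)]
  }
  obs <- rbindlist(lapply(seq_along(pre_reps), function(i) {
    a <- prep(pre_reps[[i]])
    rbindlist(lapply(seq_along(post_reps), function(j) {
      b <- prep(post_reps[[j]])
      m <- merge(a, b, by = c("chrom", "pos"), suffixes = c("_pre", "_post"))
      if (nrow(m)) m[, `:=`(pre_rep = i, post_rep = j)]
      m
    }))
  }))
  if (!nrow(obs)) stop_mescan("no CpGs covered in both stages")
  nb <- length(strata_breaks) - 1L
  obs[, stratum := {
    s <- findInterval(frac_pre, strata_breaks, rightmost.closed = TRUE)
    pmin(pmax(s, 1L), nb)
  }]
  alpha <- (1 - conf) / 2
  out <- with_seed(seed, {
    rbindlist(lapply(seq_len(nb), function(s) {
      x <- obs[stratum == s, frac_post]
      if (!length(x)) {
        message(sprintf("stratum %d is empty; CI undefined", s))
        return(data.table(stratum = s, n = 0L, median = NA_real_,
                          ci_lo = NA_real_, ci_hi = NA_real_))
      }
      boot_med <- vapply(seq_len(n_boot), function(k)
        median(x[sample.int(length(x), replace = TRUE)]), numeric(1))
      data.table(stratum = s, n = length(x), median = median(x),
                 ci_lo = quantile(boot_med, alpha, names = FALSE),
                 ci_hi = quantile(boot_med, 1 - alpha, names = FALSE))
    }))
  })
  setattr(out, "observations", obs[])
  setattr(out, "strata_breaks", strata_breaks)
  out[]
}

#' Chi-squared test for a difference in two proportions
#'
#' Standard 2x2 chi-squared test without continuity correction (the
#' correction can be enabled).
#'
#' @param k1,n1,k2,n2 successes and totals of the two groups.
#' @param correct apply Yates continuity correction. Default `FALSE`.
#' @return list with `statistic`, `p_value`, `p1`, `p2`.
#' @export
two_proportion_test <- function(k1, n1, k2, n2, correct = FALSE) {
  if (n1 <= 0 || n2 <= 0) stop_mescan("group totals must be positive")
  if (k1 > n1 || k2 > n2 || k1 < 0 || k2 < 0)
    stop_mescan("need 0 <= k <= n in both groups")
  obs <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  exp <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  if (any(exp == 0)) stop_mescan("degenerate table (a margin is zero)")
  dev <- abs(obs - exp)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / exp)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       p1 = k1 / n1, p2 = k2 / n2)
}
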