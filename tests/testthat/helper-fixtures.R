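# Fixture builders and independent oracles shared across the suite.
library(data.table)

# cohort with exact methylation fractions: one sample per (individual,
# tissue); `fracs` is a named list individual -> named numeric vector
# tissue -> fraction, applied to every position in `pos`.
make_exact_cohort <- function(fracs, pos = c(100L, 200L), depth = 100L,
                              dataset = "ds1", chrom = "chr1") {
  meta <- rbindlist(lapply(names(fracs), function(ind)
    data.table(individual = ind, tissue = names(fracs[[ind]]))))
  meta[, `:=`(dataset = dataset,
              sample_id = paste(dataset, individual, tissue, sep = "_"))]
  samples <- lapply(seq_len(nrow(meta)), function(i) {
    f <- fracs[[meta$individual[i]]][[meta$tissue[i]]]
    cpg_sites(rep(chrom, length(pos)), pos,
              as.integer(round(f * depth)), rep(depth, length(pos)))
  })
  names(samples) <- meta$sample_id
  meth_cohort(samples, meta)
}

# brute-force oracle for the metastability inequalities on a single CpG:
# `m` is a matrix individual x tissue of fractions
oracle_verdict <- function(m, inter_threshold = 0.15, intra_ratio = 1 / 3) {
  ind_means <- rowMeans(m)
  d_inter <- max(outer(ind_means, ind_means, function(a, b) abs(a - b)))
  d_intra <- max(apply(m, 1L, function(r)
    max(outer(r, r, function(a, b) abs(a - b)))))
  list(d_inter = d_inter, d_intra = d_intra,
       passes = d_inter >= inter_threshold & d_intra <= d_inter * intra_ratio)
}

# quadratic single-linkage clustering oracle
oracle_cluster <- function(pos, max_gap = 300L, min_cpgs = 4L) {
  pos <- sort(unique(pos))
  if (!length(pos)) return(list())
  grp <- cumsum(c(TRUE, diff(pos) > max_gap))
  out <- split(pos, grp)
  Filter(function(p) length(p) >= min_cpgs, unname(out))
}

# all-pairs SNP proximity oracle
oracle_snp_hit <- function(cpg_pos, snp_pos, window = 60L) {
  vapply(cpg_pos, function(p) any(abs(p - snp_pos) <= window), logical(1))
}

# two-sided Fisher p from stats::dhyper (independent of the package's
# lchoose-based implementation)
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  x <- lo:hi
  dens <- stats::dhyper(x, m, n, k)
  sum(dens[dens <= dens[x == a] * (1 + 1e-7)])
}

# random small read-call sets for permutation-oracle checks; returns a set
# with >= 1 adjacent pair and a mixed multiset of calls
random_small_cluster <- function(max_positions = 12L) {
  repeat {
    n_reads <- sample(2:4, 1L)
    rows <- rbindlist(lapply(seq_len(n_reads), function(r) {
      len <- sample(2:5, 1L)
      calls <- sample(c("M", "U", "."), len, replace = TRUE,
                      prob = c(0.4, 0.4, 0.2))
      data.table(read_id = paste0("r", r), chrom = "chr1",
                 pos = sort(sample.int(500L, len)), call = calls)
    }))
    called <- rows[call != "."]
    if (nrow(called) < 2L || nrow(called) > max_positions) next
    n_m <- sum(called$call == "M")
    if (n_m == 0L || n_m == nrow(called)) next
    per_read <- called[, .N, by = read_id]
    if (all(per_read$N < 2L)) next
    return(mescan:::validate_read_calls(rows))
  }
}

# compact read builder: one string of M/U/. per read, positions 50, 100, ...
mk_reads <- function(...) {
  specs <- list(...)
  mescan:::validate_read_calls(rbindlist(lapply(seq_along(specs), function(i) {
    calls <- strsplit(specs[[i]], "")[[1]]
    data.table(read_id = paste0("r", i), chrom = "chr1",
               pos = seq_along(calls) * 50L, call = calls)
  })))
}

# per-read transition count oracle (explicit loop over called neighbours)
oracle_transitions <- function(reads) {
  dt <- as.data.table(reads)[call != "."]
  total <- 0L
  for (id in unique(dt$read_id)) {
    calls <- dt[read_id == id][order(pos), call]
    if (length(calls) >= 2L)
      total <- total + sum(calls[-1] != calls[-length(calls)])
  }
  total
}
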