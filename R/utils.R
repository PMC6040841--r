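#' @import data.table
#' @importFrom stats rbinom rpois rbeta runif rexp quantile median pchisq
#'   pnorm setNames
#' @importFrom utils head tail write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' One master seed drives every stochastic component; per-component seeds are
#' derived with a fixed affine rule so components are reproducible
#' independently of each other. All arithmetic stays below 2^31.
#'
#' @param seed master seed (integer).
#' @param stream integer stream index (>= 0).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  m <- 2147483647
  as.integer(((abs(seed) %% m) * 48271 + stream * 7919 + 1) %% m)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
# A NULL seed leaves the global RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Lower median of an integer vector
#'
#' For an even-length vector the lower of the two central order statistics is
#' returned, so permutation-median worked examples are stable integers.
#'
#' @param x numeric vector.
#' @return a single element of `x`.
#' @export
lower_median <- function(x) {
  stopifnot(length(x) > 0)
  sort(x)[floor((length(x) + 1) / 2)]
}

# ---- interval plumbing -------------------------------------------------

# Internal convention: 0-based half-open [start, end). GRanges is 1-based
# closed, so conversion adds 1 to start only.
as_granges <- function(x, chrom_sizes = NULL) {
  if (methods::is(x, "GRanges")) return(x)
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  si <- NULL
  if (!is.null(chrom_sizes)) {
    si <- GenomeInfoDb::Seqinfo(seqnames = names(chrom_sizes),
                                seqlengths = unname(chrom_sizes))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    seqinfo = si)
  if ("label" %in% names(x)) gr$label <- x$label
  gr
}

granges_to_dt <- function(gr) {
  dt <- data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr))
  if (!is.null(gr$label)) dt[, label := gr$label]
  dt[]
}

# Positions (0-based points) falling inside 0-based half-open regions.
# Returns a logical vector along pos.
pos_in_regions <- function(chrom, pos, regions) {
  stopifnot(length(chrom) == length(pos))
  if (nrow(regions) == 0L || length(pos) == 0L)
    return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))
  # disjoint seqlevels (no shared chromosome) is a legitimate "no overlap"
  suppressWarnings(IRanges::overlapsAny(q, as_granges(regions)))
}

# FNV-1a over a character scalar; hex string. Used only to fingerprint the
# echoed configuration in output directories.
fnv1a_hex <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}

stop_mescan <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# largest-remainder apportionment of `total` into integer counts ~ weights
apportion <- function(weights, total) {
  if (sum(weights) == 0) return(rep(0L, length(weights)))
  raw <- weights / sum(weights) * total
  out <- floor(raw)
  rem <- total - sum(out)
  if (rem > 0) {
    idx <- order(raw - out, decreasing = TRUE)[seq_len(rem)]
    out[idx] <- out[idx] + 1
  }
  as.integer(out)
}
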