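# On-disk formats. One internal convention everywhere: coordinates are
# 0-based half-open, and a CpG dyad is addressed by the position of the C on
# the plus strand. Bismark reports are 1-based: plus-strand rows shift by 1,
# minus-strand rows (the G's C on the other strand, one base downstream)
# shift by 2 so both strands land on the same dyad coordinate.

#' Construct a CpG site table
#'
#' The package-wide container for per-sample CpG methylation: one row per
#' CpG dyad with methylated and total read counts (both strands combined).
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector, 0-based position of the plus-strand C.
#' @param n_meth methylated read counts.
#' @param n_total total read depths.
#' @return a keyed `data.table` with columns `chrom`, `pos`, `n_meth`,
#'   `n_total`.
#' @export
cpg_sites <- function(chrom = character(), pos = integer(),
                      n_meth = integer(), n_total = integer()) {
  dt <- data.table(chrom = as.character(chrom), pos = as.integer(pos),
                   n_meth = as.integer(n_meth), n_total = as.integer(n_total))
  validate_cpg_sites(dt)
}

validate_cpg_sites <- function(dt) {
  if (nrow(dt)) {
    if (anyNA(dt)) stop_mescan("CpG site table contains missing values")
    if (any(dt$n_meth < 0L) || any(dt$n_total < 0L))
      stop_mescan("negative methylation counts")
    if (any(dt$n_meth > dt$n_total))
      stop_mescan("n_meth exceeds n_total at %d site(s)",
                  sum(dt$n_meth > dt$n_total))
  }
  setkeyv(dt, c("chrom", "pos"))
  dt[]
}

#' Read a Bismark-style cytosine report or counts bedGraph
#'
#' Two dialects are accepted and auto-detected. A Bismark CpG cytosine
#' report (tab-separated: chrom, 1-based position, strand, methylated count,
#' unmethylated count, context, trinucleotide) has its plus- and
#' minus-strand rows of the same CpG dyad merged by summing counts. A
#' 4-column counts table (chrom, 0-based dyad position, methylated count,
#' total depth) is taken as already strand-merged.
#'
#' Strand merging happens before depth filtering, so `min_depth` applies to
#' the total depth from both strands.
#'
#' @param path input file.
#' @param min_depth minimum merged depth; shallower dyads are dropped.
#'   Default 10.
#' @return a CpG site table (see [cpg_sites()]).
#' @export
read_cytosine_report <- function(path, min_depth = 10L) {
  if (!file.exists(path)) stop_mescan("no such file: %s", path)
  if (file.size(path) == 0L) return(cpg_sites())
  raw <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
               colClasses = list(character = 1L))
  if (ncol(raw) >= 5L && all(raw[[3L]] %in% c("+", "-"))) {
    dt <- parse_bismark_report(raw)
  } else if (ncol(raw) == 4L) {
    dt <- data.table(chrom = as.character(raw[[1L]]),
                     pos = suppressWarnings(as.integer(raw[[2L]])),
                     n_meth = suppressWarnings(as.integer(raw[[3L]])),
                     n_total = suppressWarnings(as.integer(raw[[4L]])))
    bad <- which(!complete.cases(dt))
    if (length(bad))
      stop_mescan("malformed counts line %d in %s", bad[1L], path)
  } else {
    stop_mescan("unrecognized methylation table dialect in %s (%d columns)",
                path, ncol(raw))
  }
  if (any(dt$n_meth < 0L) || any(dt$n_total < 0L))
    stop_mescan("negative counts in %s", path)
  merged <- dt[, .(n_meth = sum(n_meth), n_total = sum(n_total)),
               by = .(chrom, pos)]
  merged <- merged[n_total >= min_depth]
  validate_cpg_sites(merged)
}

parse_bismark_report <- function(raw) {
  pos1 <- suppressWarnings(as.integer(raw[[2L]]))
  meth <- suppressWarnings(as.integer(raw[[4L]]))
  unmeth <- suppressWarnings(as.integer(raw[[5L]]))
  bad <- which(is.na(pos1) | is.na(meth) | is.na(unmeth))
  if (length(bad)) stop_mescan("malformed cytosine-report line %d", bad[1L])
  strand <- raw[[3L]]
  # plus-strand C: 1-based pos -> 0-based dyad pos - 1
  # minus-strand C sits one base 3' of the dyad's plus C: subtract 2
  data.table(chrom = as.character(raw[[1L]]),
             pos = pos1 - ifelse(strand == "+", 1L, 2L),
             n_meth = meth, n_total = meth + unmeth)
}

#' Write a CpG site table as a 4-column counts file
#'
#' @param sites a CpG site table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cpg_table <- function(sites, path) {
  fwrite(sites[, .(chrom, pos, n_meth, n_total)], path, sep = "\t",
         col.names = FALSE)
  invisible(path)
}

#' Read SNP positions from a VCF
#'
#' Only CHROM and POS are consumed (the screen needs SNP proximity, not
#' genotypes). Positions are converted to the internal 0-based convention.
#'
#' @param path VCF 4.x file (plain text).
#' @return a keyed `data.table` with columns `chrom`, `pos`.
#' @export
read_snp_vcf <- function(path) {
  if (!file.exists(path)) stop_mescan("no such file: %s", path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) return(data.table(chrom = character(), pos = integer()))
  fields <- tstrsplit(body, "\t", fixed = TRUE)
  if (length(fields) < 2L) stop_mescan("not a tab-separated VCF: %s", path)
  pos1 <- suppressWarnings(as.integer(fields[[2L]]))
  if (anyNA(pos1))
    stop_mescan("non-integer POS at VCF data line %d", which(is.na(pos1))[1L])
  dt <- data.table(chrom = as.character(fields[[1L]]), pos = pos1 - 1L)
  setkeyv(dt, c("chrom", "pos"))
  unique(dt)[]
}

# ---- read-level calls --------------------------------------------------

CALL_LEVELS <- c("M", "U", ".")

#' Construct a read-call table
#'
#' One row per (read, CpG position) with call `"M"` (methylated), `"U"`
#' (unmethylated) or `"."` (missing/uncalled). Positions must be strictly
#' increasing within a read.
#'
#' @param read_id,chrom,pos,call equal-length vectors.
#' @return a `data.table` with class `read_calls`.
#' @export
read_calls <- function(read_id, chrom, pos, call) {
  dt <- data.table(read_id = as.character(read_id),
                   chrom = as.character(chrom),
                   pos = as.integer(pos), call = as.character(call))
  validate_read_calls(dt)
}

validate_read_calls <- function(dt) {
  if (nrow(dt)) {
    bad <- !dt$call %in% CALL_LEVELS
    if (any(bad))
      stop_mescan("unknown methylation call symbol '%s'",
                  dt$call[which(bad)[1L]])
    chk <- dt[, .(ok = all(diff(pos) > 0L)), by = read_id]
    if (any(!chk$ok))
      stop_mescan(paste0("positions not strictly increasing within read",
                         " '%s' (unordered or duplicate)"),
                  chk$read_id[which(!chk$ok)[1L]])
  }
  setattr(dt, "class", unique(c("read_calls", class(dt))))
  dt[]
}

#' Read per-read CpG methylation calls
#'
#' Dialect: tab-separated `read_id`, `chrom`, then a comma-separated list of
#' `pos:call` tokens with 0-based positions and call in `{M, U, .}`.
#'
#' @param path input TSV.
#' @return a [read_calls()] table.
#' @export
read_read_calls <- function(path) {
  if (!file.exists(path)) stop_mescan("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(read_calls(character(), character(), integer(), character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L))
    stop_mescan("malformed read-call line %d (expected 3 fields, got %d)",
                which(nf != 3L)[1L], nf[nf != 3L][1L])
  toks <- strsplit(vapply(parts, `[[`, "", 3L), ",", fixed = TRUE)
  n_tok <- lengths(toks)
  flat <- unlist(toks, use.names = FALSE)
  m <- regmatches(flat, regexec("^([0-9]+):([MU.])$", flat))
  ok <- lengths(m) == 3L
  if (any(!ok)) {
    line <- findInterval(which(!ok)[1L], cumsum(n_tok), left.open = TRUE) + 1L
    stop_mescan("malformed pos:call token '%s' at line %d", flat[!ok][1L],
                line)
  }
  read_calls(
    read_id = rep(vapply(parts, `[[`, "", 1L), n_tok),
    chrom = rep(vapply(parts, `[[`, "", 2L), n_tok),
    pos = as.integer(vapply(m, `[[`, "", 2L)),
    call = vapply(m, `[[`, "", 3L))
}

#' Write read calls in the `read_read_calls()` dialect
#'
#' @param reads a [read_calls()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_read_calls <- function(reads, path) {
  if (!nrow(reads)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  dt <- as.data.table(reads)[, .(
    chrom = chrom[1L],
    tok = paste(sprintf("%d:%s", pos, call), collapse = ",")),
    by = read_id]
  writeLines(sprintf("%s\t%s\t%s", dt$read_id, dt$chrom, dt$tok), path)
  invisible(path)
}

# ---- intervals ---------------------------------------------------------

#' Read a BED3/BED6 file
#'
#' @param path BED file (0-based half-open per the BED standard).
#' @return a keyed `data.table` with columns `chrom`, `start`, `end`,
#'   `label` (name column or `NA`), sorted by (chrom, start, end).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_mescan("no such file: %s", path)
  if (file.size(path) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), label = character()))
  raw <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
  dt <- data.table(chrom = as.character(raw[[1L]]),
                   start = suppressWarnings(as.integer(raw[[2L]])),
                   end = suppressWarnings(as.integer(raw[[3L]])),
                   label = if (ncol(raw) >= 4L) as.character(raw[[4L]])
                           else NA_character_)
  if (anyNA(dt$start) || anyNA(dt$end))
    stop_mescan("malformed BED line %d in %s",
                which(is.na(dt$start) | is.na(dt$end))[1L], path)
  if (any(dt$start >= dt$end))
    stop_mescan("BED interval with start >= end at line %d",
                which(dt$start >= dt$end)[1L])
  if (any(dt$start < 0L)) stop_mescan("negative BED start")
  setorderv(dt, c("chrom", "start", "end"))
  dt[]
}

#' Write intervals as BED
#'
#' @param regions data.table/data.frame with `chrom`, `start`, `end` and
#'   optionally `label`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  dt <- as.data.table(regions)
  setorderv(dt, c("chrom", "start", "end"))
  cols <- c("chrom", "start", "end", if ("label" %in% names(dt)) "label")
  fwrite(dt[, cols, with = FALSE], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a region table with per-region CpG statistics
#'
#' Emits a TSV with the interval, role, ME/non-ME CpG counts (when present)
#' and, if a cohort is supplied, one column per sample holding the mean
#' methylation fraction over covered CpGs inside each region.
#'
#' @param regions region table (e.g. from [run_me_screen()]).
#' @param path output path.
#' @param cohort optional [meth_cohort()] for per-sample region means.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path, cohort = NULL) {
  dt <- as.data.table(regions)
  keep <- intersect(c("chrom", "start", "end", "role", "n_me_cpg",
                      "n_non_me_cpg", "n_cpg"), names(dt))
  out <- dt[, keep, with = FALSE]
  if (!is.null(cohort)) {
    for (sid in names(cohort$samples)) {
      s <- cohort$samples[[sid]]
      out[[paste0("mean_", sid)]] <- vapply(seq_len(nrow(dt)), function(i) {
        x <- s[chrom == dt$chrom[i] & pos >= dt$start[i] & pos < dt$end[i]]
        if (!nrow(x)) NA_real_ else mean(x$n_meth / x$n_total)
      }, numeric(1))
    }
  }
  setorderv(out, c("chrom", "start", "end"))
  fwrite(out, path, sep = "\t")
  invisible(path)
}

# ---- cohorts -----------------------------------------------------------

#' Bundle per-sample CpG tables with sample metadata
#'
#' @param samples named list of CpG site tables; names are sample ids.
#' @param meta data.frame with columns `sample_id`, `individual`, `tissue`,
#'   `dataset` and optionally `stage`. The (individual, tissue, dataset)
#'   triple must be unique.
#' @return an object of class `meth_cohort`.
#' @export
meth_cohort <- function(samples, meta) {
  meta <- as.data.table(meta)
  need <- c("sample_id", "individual", "tissue", "dataset")
  if (!all(need %in% names(meta)))
    stop_mescan("cohort metadata needs columns: %s", paste(need, collapse = ", "))
  if (!"stage" %in% names(meta)) meta[, stage := NA_character_]
  if (anyDuplicated(meta[, .(individual, tissue, dataset)]))
    stop_mescan("(individual, tissue, dataset) triples must be unique")
  if (!setequal(names(samples), meta$sample_id))
    stop_mescan("sample list names and metadata sample_id disagree")
  samples <- lapply(samples, function(s) validate_cpg_sites(as.data.table(s)))
  structure(list(samples = samples[meta$sample_id], meta = meta[]),
            class = "meth_cohort")
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat(sprintf("<meth_cohort> %d samples, %d individuals, %d tissues, %d dataset(s)\n",
              length(x$samples), uniqueN(x$meta$individual),
              uniqueN(x$meta$tissue), uniqueN(x$meta$dataset)))
  print(x$meta)
  invisible(x)
}
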