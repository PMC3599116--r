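## Genome scan for CpG sites, isolated-CpG selection, and strand-aware
## read-start counting around isolated sites.
##
## Coordinates are 0-based half-open internally and in all TSV/BED output;
## GRanges objects returned to the user are 1-based as usual.  A CpG is
## the two bases [pos, pos + 2) with pos the forward-strand C.

#' Scan a genome for CpG dinucleotides
#'
#' Reports every exact forward-strand "CG" match (case-insensitive); IUPAC
#' ambiguity codes never match.  CpG is its own reverse complement, so the
#' forward scan covers both strands.
#'
#' @param genome a `Biostrings::DNAStringSet`, a named character vector of
#'   sequences, or the path to a FASTA file.
#' @param include_softmasked if `FALSE` and the genome was supplied as
#'   character or FASTA, CpGs whose bases are lowercase (soft-masked
#'   repeats) are dropped.  `DNAStringSet` input has no case information.
#' @return a `GenomicRanges::GRanges` of width-2 ranges on "+", sorted,
#'   with `seqlengths` set from the genome.
#' @examples
#' scan_cpg_sites(c(chr1 = "ACGTTTCGA"))
#' @export
scan_cpg_sites <- function(genome, include_softmasked = TRUE) {
  chars <- NULL
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    dna <- Biostrings::readDNAStringSet(genome)
    names(dna) <- sub("\\s.*$", "", names(dna))
    if (!include_softmasked) chars <- as.character(dna)
  } else if (is.character(genome)) {
    if (is.null(names(genome))) stop("character genome must be named")
    if (!include_softmasked) chars <- genome
    dna <- Biostrings::DNAStringSet(toupper(genome))
    names(dna) <- names(genome)
  } else if (is(genome, "DNAStringSet")) {
    dna <- genome
  } else stop("unsupported genome input")

  lens <- Biostrings::width(dna)
  names(lens) <- names(dna)
  hits <- Biostrings::vmatchPattern("CG", dna, fixed = TRUE)
  gr_list <- lapply(seq_along(dna), function(i) {
    st <- BiocGenerics::start(hits[[i]])
    if (!is.null(chars) && length(st)) {
      dinuc <- substring(chars[[i]], st, st + 1L)
      st <- st[dinuc == "CG"]  # drop soft-masked (lowercase) matches
    }
    GenomicRanges::GRanges(rep(names(dna)[i], length(st)),
                           IRanges::IRanges(start = st, width = 2),
                           strand = rep("+", length(st)))
  })
  gr <- suppressWarnings(do.call(c, gr_list))
  GenomeInfoDb::seqlengths(gr) <- lens[GenomeInfoDb::seqlevels(gr)]
  sort(gr)
}

#' Select isolated CpG sites
#'
#' An isolated CpG is a site C whose interval \[C - d, C + d\] contains no
#' other CpG; d must exceed the longest plausible fragment size (and the
#' read length) so that every read within d of an isolated site can be
#' attributed to that single site.  Sites whose counting window would be
#' truncated by a chromosome end are dropped by default, since truncated
#' windows bias the read-start count curve.
#'
#' @param sites `GRanges` from [scan_cpg_sites()] (sorted per chromosome).
#' @param d isolation radius in bp.
#' @param drop_ends drop sites with `pos < d` or `pos + 1 + d` beyond the
#'   chromosome end (requires `seqlengths`; default `TRUE`).
#' @return the isolated subset of `sites`.
#' @export
select_isolated <- function(sites, d, drop_ends = TRUE) {
  stopifnot(is(sites, "GRanges"), d >= 1)
  if (length(sites) == 0) return(sites)
  pos <- BiocGenerics::start(sites) - 1L  # 0-based C
  chr <- as.character(GenomicRanges::seqnames(sites))
  keep <- logical(length(sites))
  for (cc in unique(chr)) {
    i <- which(chr == cc)
    p <- pos[i]
    if (is.unsorted(p)) stop("sites must be sorted within chromosome")
    gap_prev <- c(Inf, diff(p))
    gap_next <- c(diff(p), Inf)
    keep[i] <- gap_prev > d & gap_next > d
  }
  if (drop_ends) {
    sl <- GenomeInfoDb::seqlengths(sites)[chr]
    if (any(is.na(sl)))
      stop("drop_ends = TRUE requires seqlengths on 'sites'")
    keep <- keep & pos >= d & (pos + 1L + d) < sl
  }
  sites[keep]
}

#' Count read starts around isolated CpGs
#'
#' Pools, over all isolated sites and both strands, the (weighted) number
#' of reads starting at each distance r = 0..d from the site.  For a
#' forward read with 0-based leftmost position p assigned to site C the
#' distance is r = C - p; for a reverse read the start is its 5' end
#' q = start + read_length - 1 (highest genomic coordinate) and
#' r = q - (C + 1).  Because isolated sites are more than d apart, a read
#' matches at most one site; reads near no isolated site are ignored, and
#' reads on unknown chromosomes are skipped with a message.
#'
#' @param reads data.frame with columns `chrom`, `start` (0-based leftmost),
#'   `strand` ("+"/"-"), `read_length`, and optionally `weight` (default 1).
#' @param isolated `GRanges` of isolated CpGs ([select_isolated()]).
#' @param d isolation radius (bp).
#' @param read_length representative read length recorded in the result
#'   (default: most common value in `reads`).
#' @param keep_strands also record per-strand count vectors (diagnostic).
#' @return object of class `read_start_counts`: list with `counts`
#'   (length d + 1, index r + 1), `d`, `read_length`, `n_reads_total`
#'   (weighted reads counted), `n_sites`.
#' @export
count_read_starts <- function(reads, isolated, d, read_length = NULL,
                              keep_strands = FALSE) {
  stopifnot(is.data.frame(reads), is(isolated, "GRanges"))
  w <- if ("weight" %in% names(reads)) reads$weight else rep(1, nrow(reads))
  site_chr <- as.character(GenomicRanges::seqnames(isolated))
  site_pos <- BiocGenerics::start(isolated) - 1L
  known <- reads$chrom %in% unique(site_chr)
  n_skip <- sum(!known)
  if (n_skip > 0)
    message(n_skip, " reads on chromosomes without isolated sites skipped")

  cnt_f <- numeric(d + 1)
  cnt_r <- numeric(d + 1)
  for (cc in unique(site_chr)) {
    pos <- site_pos[site_chr == cc]
    sel <- which(reads$chrom == cc)
    if (length(sel) == 0) next
    fwd <- sel[reads$strand[sel] == "+"]
    if (length(fwd)) {
      p <- reads$start[fwd]
      idx <- findInterval(p - 0.5, pos) + 1L  # first site with pos >= p
      ok <- idx <= length(pos)
      r <- ifelse(ok, pos[pmin(idx, length(pos))] - p, NA_integer_)
      use <- ok & !is.na(r) & r >= 0 & r <= d
      if (any(use))
        cnt_f <- cnt_f + as.numeric(
          tapply2(w[fwd][use], r[use] + 1L, d + 1L))
    }
    rev <- sel[reads$strand[sel] == "-"]
    if (length(rev)) {
      q <- reads$start[rev] + reads$read_length[rev] - 1L  # 5' end
      idx <- findInterval(q - 1L + 0.5, pos)  # last site with pos <= q - 1
      ok <- idx >= 1
      r <- ifelse(ok, q - (pos[pmax(idx, 1L)] + 1L), NA_integer_)
      use <- ok & !is.na(r) & r >= 0 & r <= d
      if (any(use))
        cnt_r <- cnt_r + as.numeric(
          tapply2(w[rev][use], r[use] + 1L, d + 1L))
    }
  }
  counts <- cnt_f + cnt_r
  if (is.null(read_length)) {
    tab <- table(reads$read_length)
    read_length <- if (length(tab)) as.integer(names(tab)[which.max(tab)])
                   else NA_integer_
  }
  out <- read_start_counts(counts, d = d, read_length = read_length,
                           n_sites = length(isolated))
  if (keep_strands) {
    out$counts_forward <- cnt_f
    out$counts_reverse <- cnt_r
  }
  out
}

## weighted tabulate: sum weights w by integer bin (1..nbins)
tapply2 <- function(w, bin, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, bin)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Container for pooled read-start counts
#'
#' @param counts numeric vector of length `d + 1`; `counts[r + 1]` is the
#'   (weighted) number of reads starting r bp from an isolated CpG.
#' @param d isolation radius used.
#' @param read_length read length in bp.
#' @param n_sites number of isolated CpGs contributing.
#' @export
read_start_counts <- function(counts, d, read_length, n_sites = NA_integer_) {
  stopifnot(length(counts) == d + 1, all(counts >= 0))
  structure(list(counts = as.numeric(counts), d = as.integer(d),
                 read_length = as.integer(read_length),
                 n_reads_total = sum(counts),
                 n_sites = as.integer(n_sites)),
            class = "read_start_counts")
}

#' @export
print.read_start_counts <- function(x, ...) {
  cat(sprintf(paste0("<read_start_counts> d = %d, read_length = %d, ",
                     "%.0f reads over %s sites\n"),
              x$d, x$read_length, x$n_reads_total,
              ifelse(is.na(x$n_sites), "?", x$n_sites)))
  invisible(x)
}

#' Suggest the isolation radius d from a count curve
#'
#' Automates the visual rule "choose d a little past where the read-start
#' counts stop decreasing and fluctuate around the noise level".  Counts
#' computed with a provisional large d are scanned with trailing 50-bp
#' windows; a window is flat when the OLS slope of counts on position is
#' statistically indistinguishable from zero (the two-sided test is
#' Bonferroni-corrected across windows at family level 0.01, so chance
#' fluctuations deep in the noise region do not masquerade as decay).
#' The change point r* is the smallest position from which every
#' subsequent window is flat, and the recommendation adds a 10% safety
#' margin.
#'
#' @param counts a `read_start_counts` computed with a provisional large d.
#' @param window trailing window width in bp (default 50).
#' @param margin relative safety margin added to r* (default 0.10).
#' @return list with `r_star`, `recommended_d`, and `table`
#'   (data.frame r / count / smoothed, for plotting).
#' @export
suggest_d <- function(counts, window = 50, margin = 0.10) {
  stopifnot(inherits(counts, "read_start_counts"))
  y <- counts$counts
  d <- counts$d
  n <- length(y)
  if (n < window + 1) stop("count vector shorter than one window")
  r <- 0:d
  smoothed <- kernel_smooth(y, m = min(31, 2 * (n %/% 4) + 1))
  starts <- 0:(n - window)
  xs <- seq_len(window)
  xc <- xs - mean(xs)
  sxx <- sum(xc^2)
  crit <- stats::qt(1 - 0.005 / length(starts), df = window - 2)
  flat <- vapply(starts, function(s0) {
    yy <- y[s0 + xs]
    b <- sum(xc * yy) / sxx
    res <- yy - mean(yy) - b * xc
    se <- sqrt(sum(res^2) / (window - 2) / sxx)
    is.na(se) || se == 0 && b == 0 || abs(b) < crit * se
  }, logical(1))
  if (!flat[length(flat)] || !any(flat)) {
    warning("count curve never flattens; returning the provisional d")
    r_star <- d
  } else {
    ok_from <- rev(cumprod(rev(flat))) == 1  # all windows from here on flat
    r_star <- starts[which(ok_from)[1]]
  }
  if (r_star == 0)
    warning("counts are flat everywhere (pure noise?); r* = 0")
  list(r_star = as.integer(r_star),
       recommended_d = as.integer(min(d, ceiling(r_star * (1 + margin)))),
       table = data.frame(r = r, count = y, smoothed = smoothed))
}

#' Truncate a read-start count table to a smaller d
#'
#' Counting with a generous provisional d and re-fitting with the
#' [suggest_d()] recommendation avoids feeding the estimator a long
#' all-noise tail, where clipped sampling noise would otherwise
#' accumulate into spurious fragment mass.
#'
#' @param counts a `read_start_counts`.
#' @param d_new new radius, `<= counts$d`.
#' @export
truncate_counts <- function(counts, d_new) {
  stopifnot(inherits(counts, "read_start_counts"), d_new <= counts$d,
            d_new >= 1)
  read_start_counts(counts$counts[seq_len(d_new + 1)], d = d_new,
                    read_length = counts$read_length,
                    n_sites = counts$n_sites)
}

#' Write isolated CpG sites as BED6
#'
#' 0-based half-open intervals `chrom  pos  pos+2  CpG_<i>  0  +`.
#'
#' @param sites `GRanges` of CpG sites.
#' @param path output path.
#' @export
write_sites_bed <- function(sites, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(sites)),
                   start = BiocGenerics::start(sites) - 1L,
                   end = BiocGenerics::start(sites) + 1L,
                   name = sprintf("CpG_%d", seq_along(sites)),
                   score = 0L, strand = "+")
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of CpG sites into GRanges
#'
#' @param path BED3+ file (0-based half-open).
#' @export
read_sites_bed <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#")
  GenomicRanges::GRanges(df[[1]],
                         IRanges::IRanges(start = df[[2]] + 1L,
                                          end = df[[3]]),
                         strand = "+")
}

#' Write / read a read-start count table
#'
#' TSV `r  count` with metadata header lines `# d=`, `# read_length=`,
#' `# n_sites=`.
#'
#' @param counts a `read_start_counts`.
#' @param path file path.
#' @export
write_counts_tsv <- function(counts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# d=%d", counts$d),
               sprintf("# read_length=%d", counts$read_length),
               sprintf("# n_sites=%d", counts$n_sites),
               "r\tcount"), con)
  writeLines(sprintf("%d\t%s", 0:counts$d,
                     formatC(counts$counts, digits = 10, format = "g")), con)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  hdr <- readLines(path, n = 3)
  meta <- function(key) as.integer(sub(paste0("# ", key, "="), "",
                                       grep(key, hdr, value = TRUE)[1]))
  df <- read.delim(path, comment.char = "#")
  read_start_counts(df$count, d = meta("d"),
                    read_length = meta("read_length"),
                    n_sites = meta("n_sites"))
}
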