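## Genome-wide per-CpG coverage: fragment-probability method, read-count
## baselines, between-sample standardization, and track comparison.

#' Coverage track container
#'
#' Per-CpG coverage values for one sample, keyed by (chrom, pos) with pos
#' the 0-based C of the CpG.
#'
#' @param df data.frame with columns `chrom`, `pos`, `value` (>= 0).
#' @param method one of `"fragment"`, `"read_count"`,
#'   `"read_count_extended"`, `"paired_end_truth"`.
#' @param sample_id sample identifier.
#' @param standardized has the track been multiplied by a standardization
#'   factor.
#' @param factor the factor applied (`NA` if none).
#' @export
coverage_track <- function(df, method, sample_id = "sample",
                           standardized = FALSE, factor = NA_real_) {
  stopifnot(all(c("chrom", "pos", "value") %in% names(df)),
            all(df$value >= 0))
  method <- match.arg(method, c("fragment", "read_count",
                                "read_count_extended", "paired_end_truth"))
  structure(df[c("chrom", "pos", "value")],
            class = c("coverage_track", "data.frame"),
            method = method, sample_id = sample_id,
            standardized = standardized, factor = factor)
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s, sample %s, %d CpGs, mean %.3f%s\n",
              attr(x, "method"), attr(x, "sample_id"), nrow(x),
              mean(x$value),
              if (isTRUE(attr(x, "standardized"))) " (standardized)" else ""))
  invisible(x)
}

## strand-aware read -> CpG distance pairs within distance < s.
## Returns data.frame(site = index into sites, r, weight).
read_site_hits <- function(reads, sites, s) {
  chr_s <- as.character(GenomicRanges::seqnames(sites))
  pos <- BiocGenerics::start(sites) - 1L   # 0-based C
  w <- if ("weight" %in% names(reads)) reads$weight else rep(1, nrow(reads))
  res <- list()
  for (str in c("+", "-")) {
    i <- which(reads$strand == str)
    if (!length(i)) next
    if (str == "+") {
      ## r = pos - start in [0, s-1]  =>  1-based window [start+1, start+s]
      q_start <- reads$start[i] + 1L
    } else {
      ## 5' end q = start + len - 1; r = q - (pos + 1) in [0, s-1]
      ## =>  pos in [q - s, q - 1]  =>  1-based window [q - s + 1, q]
      q5 <- reads$start[i] + reads$read_length[i] - 1L
      q_start <- q5 - s + 1L
    }
    qgr <- GenomicRanges::GRanges(reads$chrom[i],
                                  IRanges::IRanges(start = q_start, width = s))
    sgr <- GenomicRanges::GRanges(chr_s, IRanges::IRanges(pos + 1L, width = 1))
    ov <- GenomicRanges::findOverlaps(qgr, sgr, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    r <- if (str == "+") pos[sh] - reads$start[i][qh]
         else (reads$start[i][qh] + reads$read_length[i][qh] - 1L) -
              (pos[sh] + 1L)
    res[[str]] <- data.frame(site = sh, r = r, weight = w[i][qh])
  }
  out <- do.call(rbind, res)
  if (is.null(out)) data.frame(site = integer(), r = integer(),
                               weight = numeric())
  else out[out$r >= 0 & out$r < s, , drop = FALSE]
}

#' Fragment-probability coverage of every CpG
#'
#' For each CpG, sums over all reads starting within s bp (strand-aware
#' 5'-distance r) the probability `weight * G(r)` that the read's fragment
#' covers the site.  A read may contribute to every CpG within s of its
#' start: the enrichment source is unknown, so coverage is additive over
#' reads.  Multi-read weights keep each read's total contribution across
#' loci at most 1.
#'
#' @param reads data.frame with `chrom`, `start` (0-based), `strand`,
#'   `read_length`, optional `weight`.
#' @param sites `GRanges` of all CpGs ([scan_cpg_sites()]).
#' @param G a [coverage_fn()] (support s = `length(G)`).
#' @param sample_id recorded on the track.
#' @return a [coverage_track()] with one row per CpG (zero-coverage CpGs
#'   included).
#' @export
fragment_coverage <- function(reads, sites, G, sample_id = "sample") {
  if (missing(G) || is.null(G)) stop("a coverage function G is required")
  stopifnot(inherits(G, "coverage_fn"))
  track_from_hits(reads, sites, unclass(G), "fragment", sample_id)
}

#' Read-count coverage baselines
#'
#' The traditional approximation: count reads starting within
#' `effective_length` bp of the CpG -- the special case of
#' [fragment_coverage()] with an indicator coverage function.
#' `effective_length = read_length` gives the raw read count;
#' `effective_length =` expected fragment length gives the "extended"
#' variant.
#'
#' @inheritParams fragment_coverage
#' @param effective_length window in bp (>= 1).
#' @export
readcount_coverage <- function(reads, sites, effective_length,
                               sample_id = "sample") {
  stopifnot(effective_length >= 1)
  rl <- unique(reads$read_length)
  method <- if (length(rl) == 1 && effective_length > rl[1])
    "read_count_extended" else "read_count"
  track_from_hits(reads, sites, rep(1, effective_length), method, sample_id)
}

track_from_hits <- function(reads, sites, gvals, method, sample_id) {
  hits <- read_site_hits(reads, sites, length(gvals))
  vals <- numeric(length(sites))
  if (nrow(hits)) {
    contrib <- hits$weight * gvals[hits$r + 1L]
    agg <- rowsum(contrib, hits$site)
    vals[as.integer(rownames(agg))] <- agg[, 1]
  }
  coverage_track(data.frame(
    chrom = as.character(GenomicRanges::seqnames(sites)),
    pos = BiocGenerics::start(sites) - 1L,
    value = vals), method, sample_id)
}

#' Standardize a coverage track between samples
#'
#' Multiplies every value by the sample's standardization factor
#' ([standardization_factors()]), removing between-sample differences
#' driven by fragment-size distributions rather than methylation.
#' Re-standardizing an already standardized track is an error.
#'
#' @param track a [coverage_track()].
#' @param factor positive scalar.
#' @export
standardize <- function(track, factor) {
  stopifnot(inherits(track, "coverage_track"), is.finite(factor), factor > 0)
  if (isTRUE(attr(track, "standardized")))
    stop("track is already standardized")
  track$value <- track$value * factor
  attr(track, "standardized") <- TRUE
  attr(track, "factor") <- factor
  track
}

#' Compare two coverage tracks
#'
#' Summary in the shape of a method-comparison table: per-track mean and
#' SD, the ratio of means as a percentage (a / b), and the Pearson
#' correlation over shared CpGs.
#'
#' @param a,b [coverage_track()]s over the same CpG key set.
#' @return data.frame with columns `mean_a`, `sd_a`, `mean_b`, `sd_b`,
#'   `ratio_pct`, `correlation`, `n_cpgs`.
#' @export
compare_tracks <- function(a, b) {
  stopifnot(inherits(a, "coverage_track"), inherits(b, "coverage_track"))
  m <- merge(as.data.frame(a), as.data.frame(b), by = c("chrom", "pos"),
             suffixes = c("_a", "_b"))
  if (nrow(m) == 0) stop("tracks share no CpGs")
  if (nrow(m) != nrow(a) || nrow(m) != nrow(b))
    warning("tracks do not cover identical CpG sets; comparing overlap")
  va <- m$value_a; vb <- m$value_b
  data.frame(method_a = attr(a, "method"), method_b = attr(b, "method"),
             mean_a = mean(va), sd_a = sd(va),
             mean_b = mean(vb), sd_b = sd(vb),
             ratio_pct = 100 * mean(va) / mean(vb),
             correlation = if (sd(va) > 0 && sd(vb) > 0) cor(va, vb)
                           else NA_real_,
             n_cpgs = nrow(m))
}

#' Write a coverage track as bedGraph (+ JSON sidecar)
#'
#' bedGraph rows `chrom  pos  pos+2  value` (0-based half-open) and
#' `<path>.json` recording method, sample, standardization factor and
#' provenance.
#'
#' @param track a [coverage_track()].
#' @param path output path.
#' @param g_provenance free-form note on where G came from.
#' @export
write_track_bedgraph <- function(track, path, g_provenance = NULL) {
  df <- data.frame(track$chrom, track$pos, track$pos + 2L, track$value)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  meta <- list(method = attr(track, "method"),
               sample = attr(track, "sample_id"),
               standardized = isTRUE(attr(track, "standardized")),
               factor = attr(track, "factor"),
               g_provenance = g_provenance,
               tool = paste0("fragcov ", packageVersion("fragcov")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
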