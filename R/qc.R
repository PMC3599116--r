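## Read-level quality control applied before counting and coverage:
## multi-read selection/weighting and duplicate-read collapse.
##
## Order of operations: multi-read filtering first (producing weights),
## then duplicate collapse on the weighted reads -- so a 10-locus
## multi-read cannot masquerade as 10 duplicates.

#' QC configuration
#'
#' Defaults follow the published rules for 50-bp MBD-seq reads; all
#' overridable.
#'
#' @param max_loci reads mapping to more than this many loci are excluded
#'   entirely (default 10).
#' @param score_window a locus qualifies when its alignment score is within
#'   this many points of the best score, inclusive (default 5).
#' @param max_kept_alignments a multi-read is kept only if at most this
#'   many loci qualify (default 4, i.e. "fewer than five").
#' @param mismatch_penalty score = read_length - penalty * mismatches
#'   (default 3).
#' @param dup_hard_cap more than this many reads at one position always
#'   collapse to 1 (default 3).
#' @param dup_neighborhood radius (bp) searched for corroborating reads
#'   when 2-3 duplicates share a start (default 25).
#' @return list of class `qc_config`.
#' @export
qc_config <- function(max_loci = 10, score_window = 5,
                      max_kept_alignments = 4, mismatch_penalty = 3,
                      dup_hard_cap = 3, dup_neighborhood = 25) {
  structure(list(max_loci = max_loci, score_window = score_window,
                 max_kept_alignments = max_kept_alignments,
                 mismatch_penalty = mismatch_penalty,
                 dup_hard_cap = dup_hard_cap,
                 dup_neighborhood = dup_neighborhood),
            class = "qc_config")
}

#' Alignment score
#'
#' `read_length - penalty * mismatches`.  Scores may go negative; only
#' their ordering matters.
#'
#' @param read_length read length (bp).
#' @param mismatches mismatch count (>= 0).
#' @param penalty per-mismatch penalty (default 3).
#' @export
alignment_score <- function(read_length, mismatches, penalty = 3) {
  stopifnot(all(mismatches >= 0))
  read_length - penalty * mismatches
}

#' Multi-read selection and weighting
#'
#' For the candidate alignments of one read: if it maps to more than
#' `max_loci` loci it is excluded.  Otherwise let B be the best alignment
#' score and K the loci scoring at least B - `score_window`: a unique
#' qualifying locus is kept at weight 1; 2..`max_kept_alignments`
#' qualifying loci are all kept, each at weight 1/|K|; more qualifying
#' loci exclude the read.  Kept weights always sum to 1.
#'
#' @param group data.frame of one read's alignments with columns `chrom`,
#'   `start`, `strand`, `read_length`, `mismatches`.
#' @param config a [qc_config()].
#' @return the kept alignments with a `weight` column (0 rows if excluded).
#' @export
filter_multireads <- function(group, config = qc_config()) {
  stopifnot(nrow(group) >= 1)
  empty <- cbind(group[0, , drop = FALSE], weight = numeric(0))
  if (nrow(group) > config$max_loci) return(empty)
  score <- alignment_score(group$read_length, group$mismatches,
                           config$mismatch_penalty)
  qual <- score >= max(score) - config$score_window
  k <- sum(qual)
  if (k > config$max_kept_alignments) return(empty)
  out <- group[qual, , drop = FALSE]
  out$weight <- rep(1 / k, k)
  out
}

## Vectorized multi-read filter over a whole alignment table (grouped by
## read_id).  use_multireads = FALSE keeps only uniquely-mapping reads.
filter_multireads_all <- function(aln, config = qc_config(),
                                  use_multireads = TRUE) {
  id <- as.character(aln$read_id)
  nloci <- stats::ave(seq_len(nrow(aln)), id, FUN = length)
  if (!use_multireads) {
    out <- aln[nloci == 1, , drop = FALSE]
    out$weight <- rep(1, nrow(out))
    return(out)
  }
  score <- alignment_score(aln$read_length, aln$mismatches,
                           config$mismatch_penalty)
  best <- stats::ave(score, id, FUN = max)
  qual <- score >= best - config$score_window
  k <- stats::ave(as.numeric(qual), id, FUN = sum)
  keep <- nloci <= config$max_loci & qual & k <= config$max_kept_alignments
  out <- aln[keep, , drop = FALSE]
  out$weight <- 1 / k[keep]
  out
}

#' Duplicate-read collapse rule for one position
#'
#' Reads starting at the identical (chrom, start, strand) may be PCR
#' artifacts or genuine chance overlaps in an enriched library.  The rule:
#' 1 read keeps count 1; more than `dup_hard_cap` reads reset to 1;
#' 2 or 3 reads keep their count only if at least one other read starts
#' within +/- `dup_neighborhood` bp (on either strand, excluding the
#' duplicate position itself), else reset to 1.  With weighted reads the
#' effective contribution is `min(summed weight, rule count)`.
#'
#' @param n number of duplicate reads at the position.
#' @param has_neighbor logical: any other read start within the
#'   neighborhood.
#' @param total_weight summed multi-read weight at the position
#'   (default `n`, i.e. unweighted).
#' @param config a [qc_config()].
#' @return effective (weighted) count for the position.
#' @export
collapse_duplicates <- function(n, has_neighbor, total_weight = n,
                                config = qc_config()) {
  stopifnot(n >= 1)
  rule <- if (n > config$dup_hard_cap) 1
          else if (n >= 2 && !has_neighbor) 1
          else n
  min(total_weight, rule)
}

## Dataset-level duplicate handling.  mode:
##   "collapse" - the published rule (collapse_duplicates at each position)
##   "strict"   - classical dedup: every position capped at count/weight 1
##   "none"     - leave duplicates untouched
dedup_reads <- function(reads, config = qc_config(),
                        mode = c("collapse", "strict", "none")) {
  mode <- match.arg(mode)
  if (mode == "none" || nrow(reads) == 0) {
    attr(reads, "dup_positions_collapsed") <- 0L
    return(reads)
  }
  key <- paste(reads$chrom, reads$start, reads$strand, sep = "\r")
  first <- !duplicated(key)
  n <- as.vector(table(key)[key])       # dup count per row
  wsum <- stats::ave(reads$weight, key, FUN = sum)
  out <- reads[first, , drop = FALSE]
  n1 <- n[first]; w1 <- wsum[first]
  if (mode == "strict") {
    out$weight <- pmin(w1, 1)
    attr(out, "dup_positions_collapsed") <- sum(n1 > 1)
    return(out)
  }
  ## neighborhood: any distinct read-start coordinate (either strand)
  ## within +/- dup_neighborhood on the same chromosome
  need <- which(n1 >= 2 & n1 <= config$dup_hard_cap)
  has_nb <- rep(TRUE, nrow(out))
  if (length(need)) {
    for (cc in unique(out$chrom[need])) {
      starts_all <- sort(unique(reads$start[reads$chrom == cc]))
      i <- need[out$chrom[need] == cc]
      p <- out$start[i]
      lo <- findInterval(p - config$dup_neighborhood - 0.5, starts_all)
      hi <- findInterval(p + config$dup_neighborhood + 0.5, starts_all)
      ## window holds (hi - lo) distinct coordinates incl. p itself
      has_nb[i] <- (hi - lo) >= 2
    }
  }
  eff <- vapply(seq_len(nrow(out)), function(i)
    collapse_duplicates(n1[i], has_nb[i], w1[i], config), numeric(1))
  out$weight <- eff
  attr(out, "dup_positions_collapsed") <- sum(eff < w1 - 1e-12)
  out
}

#' Apply full read QC
#'
#' Multi-read filtering/weighting followed by duplicate collapse; the four
#' regimes (with/without multi-reads, with/without the duplicate rule) are
#' all reachable through the two flags.
#'
#' @param aln alignment table: data.frame with columns `read_id`, `chrom`,
#'   `start` (0-based), `strand`, `read_length`, `mismatches` (one row per
#'   candidate alignment).
#' @param config a [qc_config()].
#' @param use_multireads keep qualifying multi-reads at weight 1/k
#'   (`TRUE`, default) or only uniquely-mapping reads (`FALSE`).
#' @param duplicate_mode `"collapse"` (published rule, default),
#'   `"strict"` (cap every position at 1) or `"none"`.
#' @return list with `reads` (weighted, one row per kept position-strand)
#'   and `summary` (data.frame of funnel tallies).
#' @export
apply_read_qc <- function(aln, config = qc_config(), use_multireads = TRUE,
                          duplicate_mode = c("collapse", "strict", "none")) {
  duplicate_mode <- match.arg(duplicate_mode)
  stopifnot(all(c("read_id", "chrom", "start", "strand",
                  "read_length", "mismatches") %in% names(aln)))
  n_in <- length(unique(aln$read_id))
  kept <- filter_multireads_all(aln, config, use_multireads)
  n_kept_reads <- length(unique(kept$read_id))
  n_kept_multi <- length(unique(kept$read_id[kept$weight < 1]))
  final <- dedup_reads(kept, config, duplicate_mode)
  summary <- data.frame(
    stage = c("reads_in", "excluded_multireads", "kept_multireads",
              "dup_positions_collapsed", "effective_reads_out"),
    value = c(n_in, n_in - n_kept_reads, n_kept_multi,
              attr(final, "dup_positions_collapsed"),
              round(sum(final$weight), 3)))
  list(reads = final, summary = summary)
}
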