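## Synthetic-data generator reproducing the statistical structure the
## estimator assumes: non-normal fragment-size pmfs on roughly 50-300 bp
## support, uniform read-start placement on fragments, a uniform
## background of noise reads from imperfect enrichment, and per-sample
## pmf variation.

#' Construct a fragment-size pmf of a stated shape
#'
#' Three shape families emulate empirically observed paired-end
#' fragment-size distributions: `"skewed"` (positively skewed: discretized
#' gamma shifted to the minimum size -- the easiest case for the
#' estimator), `"kurtotic"` (bell truncated sharply at an upper cutoff
#' around 240 bp, mimicking aggressive upper size selection -- the hardest
#' case), and `"bell"` (intermediate discretized normal).  All are
#' truncated to `[min_size, max_size]` and renormalized.
#'
#' @param shape `"skewed"`, `"kurtotic"` or `"bell"`; ignored when `probs`
#'   is supplied.
#' @param min_size,max_size support bounds in bp (defaults 50, 300).
#' @param cutoff upper truncation for the kurtotic shape (default 240).
#' @param probs explicit probabilities (passthrough to [fragment_pmf()]).
#' @param sizes sizes matching `probs`.
#' @return a [fragment_pmf()].
#' @export
make_fragment_pmf <- function(shape = c("skewed", "kurtotic", "bell"),
                              min_size = 50, max_size = 300, cutoff = 240,
                              probs = NULL, sizes = NULL) {
  if (!is.null(probs)) return(fragment_pmf(probs, sizes = sizes))
  shape <- match.arg(shape)
  stopifnot(min_size >= 1, max_size > min_size)
  xs <- seq_len(max_size)
  dens <- switch(shape,
    skewed   = dgamma(xs - min_size, shape = 2.5, scale = 35),
    kurtotic = ifelse(xs <= cutoff, dnorm(xs, mean = 185, sd = 55), 0),
    bell     = dnorm(xs, mean = 160, sd = 35))
  dens[xs < min_size | xs > max_size] <- 0
  if (sum(dens) <= 0) stop("empty support")
  fragment_pmf(dens / sum(dens))
}

#' Simulate read starts around isolated CpGs
#'
#' Signal reads: fragment size x drawn from `f`, read start uniform on the
#' x positions of the fragment, so the distance r from the CpG is uniform
#' on 0..x-1.  Noise reads (imperfect enrichment): r uniform on 0..d.
#' Tallied into a [read_start_counts()].
#'
#' @param f a [fragment_pmf()] with support <= d.
#' @param n_reads total reads.
#' @param noise_fraction fraction of uniform noise reads (default 0.15).
#' @param d isolation radius (default 350).
#' @param read_length read length recorded (default 50).
#' @param seed optional seed for reproducibility.
#' @export
simulate_read_starts <- function(f, n_reads, noise_fraction = 0.15,
                                 d = 350, read_length = 50, seed = NULL) {
  stopifnot(inherits(f, "fragment_pmf"), length(f) <= d,
            noise_fraction >= 0, noise_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  n_noise <- round(noise_fraction * n_reads)
  n_sig <- n_reads - n_noise
  r <- integer(0)
  if (n_sig > 0) {
    x <- sample.int(length(f), n_sig, replace = TRUE, prob = unclass(f))
    r <- c(r, as.integer(floor(runif(n_sig) * x)))
  }
  if (n_noise > 0)
    r <- c(r, sample.int(d + 1L, n_noise, replace = TRUE) - 1L)
  read_start_counts(tabulate(r + 1L, nbins = d + 1L), d = d,
                    read_length = read_length, n_sites = 1L)
}

## background sequence with no CG dinucleotide: iid ACGT, then every G
## preceded by C is replaced with A (one pass suffices; replacements
## cannot create a new CG)
random_seq_no_cpg <- function(n) {
  x <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  i <- which(x[-1] == "G" & x[-n] == "C")
  if (length(i)) x[i + 1] <- "A"
  x
}

#' Simulate a genome, methylation profile and single-end reads
#'
#' End-to-end fixture with known truth.  A toy chromosome is built with
#' CpGs planted at regular spacing (no accidental CpGs elsewhere);
#' methylated CpGs emit fragments (sizes from `f`, the fragment placed so
#' the read-start distance is uniform on the fragment, strand fair-coin),
#' noise reads land uniformly, and multi-reads / duplicate reads can be
#' planted for QC testing.  The truth track is the exact number of
#' fragments overlapping each CpG dinucleotide.
#'
#' @param f a [fragment_pmf()].
#' @param n_cpgs number of planted CpGs (default 20).
#' @param spacing CpG spacing in bp; must exceed 2 * d for isolation
#'   (default 800).
#' @param methylated logical vector (length `n_cpgs`) or a single fraction
#'   of methylated CpGs (default 0.7).
#' @param depth mean fragments per methylated CpG, Poisson (default 100).
#' @param noise_fraction fraction of uniformly placed noise reads added on
#'   top of signal reads (default 0.15).
#' @param read_length bp (default 50).
#' @param plant_multireads fraction of reads given decoy extra alignments
#'   (default 0).
#' @param plant_duplicates fraction of reads duplicated in place
#'   (default 0).
#' @param placement fragment placement model.  `"covering"` (default):
#'   every fragment contains the methylated CpG that enriched it (the
#'   capture model; read-start counts then decay per the read-start pmf,
#'   and per-read coverage contributions average E(cov)).  `"uniform"`:
#'   fragment 5' read-side distance uniform on 0..s-1 with size drawn
#'   independently, emulating the locally homogeneous fragment field of a
#'   dense methylome, under which the probabilistic coverage measure is
#'   exactly unbiased for the number of covering fragments.
#' @param chrom chromosome name (default "chrSim").
#' @param seed optional seed.
#' @return list: `genome` (`DNAStringSet`), `sites` (`GRanges` of planted
#'   CpGs), `methylated`, `alignments` (data.frame read_id/chrom/start/
#'   strand/read_length/mismatches), `truth` ([coverage_track()]),
#'   `config`.
#' @export
simulate_genome_sample <- function(f, n_cpgs = 20, spacing = 800,
                                   methylated = 0.7, depth = 100,
                                   noise_fraction = 0.15, read_length = 50,
                                   plant_multireads = 0,
                                   plant_duplicates = 0,
                                   placement = c("covering", "uniform"),
                                   chrom = "chrSim", seed = NULL) {
  placement <- match.arg(placement)
  stopifnot(inherits(f, "fragment_pmf"))
  if (!is.null(seed)) set.seed(seed)
  s <- length(f)
  margin <- spacing
  chrlen <- margin * 2L + spacing * n_cpgs
  letters <- random_seq_no_cpg(chrlen)
  cpg_pos <- margin + spacing * (seq_len(n_cpgs) - 1L)  # 0-based C
  ## planting CG cannot create a second CpG at the seams: the preceding
  ## base followed by C and G followed by anything never spell "CG"
  letters[cpg_pos + 1L] <- "C"
  letters[cpg_pos + 2L] <- "G"
  genome <- Biostrings::DNAStringSet(paste(letters, collapse = ""))
  names(genome) <- chrom

  if (length(methylated) == 1 && !is.logical(methylated))
    methylated <- runif(n_cpgs) < methylated
  stopifnot(length(methylated) == n_cpgs)

  frag <- list()
  for (i in which(methylated)) {
    n_i <- rpois(1, depth)
    if (n_i == 0) next
    x <- sample.int(s, n_i, replace = TRUE, prob = unclass(f))
    r <- if (placement == "covering") as.integer(floor(runif(n_i) * x))
         else sample.int(s, n_i, replace = TRUE) - 1L
    fwd <- runif(n_i) < 0.5
    ## forward: fragment [p, p+x) with read at its left end, p = C - r
    ## reverse: 5' end q = C + 1 + r, fragment [q - x + 1, q + 1)
    frag_start <- ifelse(fwd, cpg_pos[i] - r, cpg_pos[i] + 1L + r - x + 1L)
    frag[[length(frag) + 1]] <- data.frame(
      start = frag_start, size = x, strand = ifelse(fwd, "+", "-"),
      r = r)
  }
  frag <- if (length(frag)) do.call(rbind, frag)
          else data.frame(start = integer(), size = integer(),
                          strand = character(), r = integer())
  n_noise <- round(noise_fraction * nrow(frag))
  if (n_noise > 0) {
    x <- sample.int(s, n_noise, replace = TRUE, prob = unclass(f))
    st <- as.integer(floor(runif(n_noise) * (chrlen - s)))
    frag <- rbind(frag, data.frame(start = st, size = x,
                                   strand = sample(c("+", "-"), n_noise,
                                                   replace = TRUE),
                                   r = NA_integer_))
  }
  ## single-end read from the fragment's 5' end on its own strand
  read_start <- ifelse(frag$strand == "+", frag$start,
                       frag$start + frag$size - read_length)
  aln <- data.frame(read_id = sprintf("read_%d", seq_len(nrow(frag))),
                    chrom = rep(chrom, nrow(frag)),
                    start = as.integer(read_start),
                    strand = as.character(frag$strand),
                    read_length = rep(as.integer(read_length), nrow(frag)),
                    mismatches = rep(0L, nrow(frag)),
                    n_alignments = rep(1L, nrow(frag)))

  if (plant_duplicates > 0 && nrow(aln)) {
    pick <- which(runif(nrow(aln)) < plant_duplicates)
    if (length(pick)) {
      k <- sample(c(1L, 3L), length(pick), replace = TRUE,
                  prob = c(0.7, 0.3))  # extra copies: 2 or 4 total
      dup <- aln[rep(pick, k), , drop = FALSE]
      dup$read_id <- sprintf("dup_%d", seq_len(nrow(dup)))
      aln <- rbind(aln, dup)
    }
  }
  if (plant_multireads > 0 && nrow(aln)) {
    pick <- which(runif(nrow(aln)) < plant_multireads)
    if (length(pick)) {
      decoy <- aln[pick, , drop = FALSE]
      decoy$start <- as.integer((decoy$start + chrlen %/% 2) %% (chrlen - s))
      extra <- rbind(aln[pick, , drop = FALSE], decoy)
      extra$n_alignments <- 2L
      aln$n_alignments[pick] <- 2L
      aln <- rbind(aln[-pick, , drop = FALSE], extra)
    }
  }

  sites <- GenomicRanges::GRanges(chrom,
                                  IRanges::IRanges(cpg_pos + 1L, width = 2))
  GenomeInfoDb::seqlengths(sites) <- stats::setNames(chrlen, chrom)
  ## truth: fragments overlapping the CpG dinucleotide [pos, pos+1]
  truth_vals <- numeric(n_cpgs)
  if (nrow(frag)) {
    fgr <- GenomicRanges::GRanges(chrom,
                                  IRanges::IRanges(frag$start + 1L,
                                                   width = frag$size))
    ov <- GenomicRanges::countOverlaps(sites, fgr)
    truth_vals <- as.numeric(ov)
  }
  truth <- coverage_track(data.frame(chrom = chrom, pos = cpg_pos,
                                     value = truth_vals),
                          "paired_end_truth")
  list(genome = genome, sites = sites, methylated = methylated,
       alignments = aln, truth = truth,
       config = list(n_cpgs = n_cpgs, spacing = spacing, depth = depth,
                     placement = placement,
                     noise_fraction = noise_fraction,
                     read_length = read_length, s = s, seed = seed))
}

#' Precision experiment: estimator error versus read depth
#'
#' For each fragment-size shape and read count, repeatedly simulate
#' read-start counts, run [estimate_coverage()], and compare the estimated
#' coverage function with the truth position by position over r = 0..d-1
#' (truth extended with zeros beyond its support).  Per replicate the
#' signed differences and absolute differences are averaged over
#' positions; across replicates the mean difference (bias), its SD
#' (variability) and the mean absolute difference (overall precision) are
#' reported.
#'
#' Noise reads default to 0 here: the uniform background cancels in the
#' estimator by construction, and the depth conditions refer to reads
#' attributable to isolated CpGs.
#'
#' @param shapes character vector of [make_fragment_pmf()] shapes.
#' @param n_reads read-depth conditions
#'   (default `c(10000, 25000, 50000, 75000, 100000)`).
#' @param n_replicates replicates per condition (default 200).
#' @param noise_fraction uniform noise-read fraction (default 0).
#' @param d isolation radius (default 350).
#' @param read_length bp (default 50).
#' @param spec a [smoother_spec()].
#' @param seed base seed; per-replicate seeds are derived deterministically
#'   so every condition is independently reproducible.
#' @return data.frame with one row per (shape, n_reads): `mean_diff`,
#'   `sd_diff`, `mean_abs_diff`, `n_replicates`.
#' @export
precision_experiment <- function(shapes = c("skewed", "kurtotic", "bell"),
                                 n_reads = c(10000, 25000, 50000, 75000,
                                             100000),
                                 n_replicates = 200, noise_fraction = 0,
                                 d = 350, read_length = 50,
                                 spec = smoother_spec(), seed = 1) {
  res <- list()
  for (sh in shapes) {
    f <- make_fragment_pmf(sh)
    gt <- c(unclass(coverage_fn(f)), numeric(d - length(f)))
    for (n in n_reads) {
      md <- ad <- numeric(n_replicates)
      for (rep_i in seq_len(n_replicates)) {
        rep_seed <- (seed + 7919 * (rep_i - 1) +
                     match(sh, shapes) * 131071 +
                     match(n, n_reads) * 524287) %% .Machine$integer.max
        cnt <- simulate_read_starts(f, n, noise_fraction, d, read_length,
                                    seed = rep_seed)
        est <- suppressWarnings(estimate_coverage(cnt, spec))
        dif <- unclass(est$coverage) - gt
        md[rep_i] <- mean(dif)
        ad[rep_i] <- mean(abs(dif))
      }
      res[[length(res) + 1]] <- data.frame(
        shape = sh, n_reads = n, mean_diff = mean(md), sd_diff = sd(md),
        mean_abs_diff = mean(ad), n_replicates = n_replicates)
    }
  }
  do.call(rbind, res)
}
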