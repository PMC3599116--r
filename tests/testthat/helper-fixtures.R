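# shared fixture builders -- all fixtures are generated in code

# random proper pmf on sizes 1..s (sparse support of k sizes)
random_pmf <- function(s, k = 12) {
  k <- max(1, min(k, s))
  sizes <- sort(sample.int(s, k))
  w <- rexp(k)
  fragment_pmf(w / sum(w), sizes = sizes)
}

# minimal single-end SAM text for an alignment table (0-based starts in,
# 1-based POS out); NM/NH tags carry mismatches and locus counts
write_sam <- function(aln, chrlens, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrlens), chrlens))
  flag <- ifelse(aln$strand == "-", 16L, 0L)
  rows <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d\tNH:i:%d",
                  aln$read_id, flag, aln$chrom, aln$start + 1L,
                  aln$read_length,
                  strrep("A", aln$read_length),
                  aln$mismatches,
                  if ("n_alignments" %in% names(aln)) aln$n_alignments
                  else rep(1L, nrow(aln)))
  writeLines(c(hdr, rows), path)
  path
}

# genome string of length n with no CpG, as named character
blank_genome <- function(n, name = "chrT") {
  stats::setNames(paste(rep("ACTT", ceiling(n / 4)), collapse = "") |>
                    substr(1, n), name)
}

# plant CG dinucleotides at 0-based positions in a genome string
plant_cpgs <- function(genome, pos0) {
  g <- strsplit(unname(genome), "")[[1]]
  g[pos0 + 1] <- "C"
  g[pos0 + 2] <- "G"
  stats::setNames(paste(g, collapse = ""), names(genome))
}
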