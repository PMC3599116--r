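# multi-read selection/weighting and duplicate collapse

aln_group <- function(scores, read_length = 50) {
  # build a group whose alignment scores are as requested (score = len - 3mm)
  mm <- (read_length - scores) / 3
  stopifnot(all(mm == round(mm)), all(mm >= 0))
  data.frame(chrom = "chr1", start = seq_along(scores) * 1000L,
             strand = "+", read_length = read_length, mismatches = mm)
}

test_that("alignment score is read length minus 3 per mismatch", {
  expect_equal(alignment_score(50, 0), 50)
  expect_equal(alignment_score(50, 2), 44)
  expect_equal(alignment_score(35, 12), -1)
  expect_error(alignment_score(50, -1))
})

test_that("multi-read filter applies loci cap, score window and weights", {
  # more than 10 loci: excluded outright
  g12 <- aln_group(rep(50, 12))
  expect_equal(nrow(filter_multireads(g12)), 0)
  # three alignments within 5 points of the best: kept at weight 1/3
  g3 <- filter_multireads(aln_group(c(50, 47, 47)))
  expect_equal(g3$weight, rep(1 / 3, 3))
  # second alignment outside the window: unique best kept at weight 1
  g2 <- filter_multireads(aln_group(c(50, 41)))
  expect_equal(nrow(g2), 1)
  expect_equal(g2$weight, 1)
  expect_equal(g2$start, 1000L)
  # window is inclusive: a score exactly best-5 still qualifies
  gedge <- filter_multireads(data.frame(
    chrom = "chr1", start = c(1000L, 2000L), strand = "+",
    read_length = c(50, 45), mismatches = 0))
  expect_equal(gedge$weight, c(0.5, 0.5))
  # five or more qualifying alignments: excluded
  g5 <- filter_multireads(aln_group(rep(50, 5)))
  expect_equal(nrow(g5), 0)
  g4 <- filter_multireads(aln_group(rep(50, 4)))
  expect_equal(g4$weight, rep(0.25, 4))
})

test_that("kept multi-read weights always sum to 1", {
  set.seed(301)
  for (i in 1:25) {
    k <- sample(1:12, 1)
    scores <- 50 - 3 * sample(0:6, k, replace = TRUE)
    out <- filter_multireads(aln_group(scores))
    expect_true(nrow(out) == 0 || abs(sum(out$weight) - 1) < 1e-12)
  }
})

test_that("duplicate collapse follows the published decision table", {
  # n = 1 always kept as-is
  expect_equal(collapse_duplicates(1, FALSE), 1)
  expect_equal(collapse_duplicates(1, TRUE), 1)
  # 2 or 3 duplicates: kept only with a corroborating neighbor
  expect_equal(collapse_duplicates(2, TRUE), 2)
  expect_equal(collapse_duplicates(2, FALSE), 1)
  expect_equal(collapse_duplicates(3, TRUE), 3)
  expect_equal(collapse_duplicates(3, FALSE), 1)
  # more than 3: always reset to 1, neighbors irrelevant
  expect_equal(collapse_duplicates(4, TRUE), 1)
  expect_equal(collapse_duplicates(5, FALSE), 1)
  # weighted variant: min(summed weight, rule count)
  expect_equal(collapse_duplicates(2, TRUE, total_weight = 0.5), 0.5)
  expect_equal(collapse_duplicates(5, TRUE, total_weight = 2.5), 1)
})

mk_aln <- function(starts, strand = "+", id = NULL, mm = 0) {
  n <- length(starts)
  data.frame(read_id = if (is.null(id)) sprintf("r%d", seq_len(n)) else id,
             chrom = "chr1", start = starts, strand = strand,
             read_length = 50, mismatches = mm)
}

test_that("full QC is the identity on unique non-duplicated reads", {
  aln <- mk_aln(c(100, 260, 530, 900))
  out <- apply_read_qc(aln)
  expect_equal(out$reads$start, aln$start)
  expect_equal(out$reads$weight, rep(1, 4))
  expect_equal(out$summary$value[out$summary$stage == "excluded_multireads"], 0)
})

test_that("dataset-level duplicate handling uses the neighborhood rule", {
  # 5 duplicates, no neighbor: collapses to 1
  out <- apply_read_qc(mk_aln(rep(500, 5)))
  expect_equal(out$reads$weight, 1)
  # 2 duplicates with a read 10 bp away: kept at 2
  out <- apply_read_qc(mk_aln(c(500, 500, 510)))
  expect_equal(out$reads$weight[out$reads$start == 500], 2)
  # 3 duplicates, nearest other read 30 bp away (> 25): reset to 1
  out <- apply_read_qc(mk_aln(c(500, 500, 500, 530)))
  expect_equal(out$reads$weight[out$reads$start == 500], 1)
  # neighbor on the opposite strand still corroborates
  aln <- rbind(mk_aln(c(500, 500), id = c("a", "b")),
               mk_aln(490, strand = "-", id = "c"))
  out <- apply_read_qc(aln)
  expect_equal(out$reads$weight[out$reads$start == 500 &
                                out$reads$strand == "+"], 2)
  # same-coordinate opposite-strand reads are not duplicates of each
  # other, but the shared coordinate does not count as a neighbor either
  aln <- rbind(mk_aln(c(700, 700), id = c("a", "b")),
               mk_aln(700, strand = "-", id = "c"))
  out <- apply_read_qc(aln)
  expect_equal(nrow(out$reads), 2)                      # one per strand
  expect_equal(out$reads$weight[out$reads$strand == "+"], 1)
  # "strict" mode caps every position at 1
  out <- apply_read_qc(mk_aln(c(500, 500, 510)), duplicate_mode = "strict")
  expect_equal(out$reads$weight, c(1, 1))
})

test_that("the four QC regimes order read retention as expected", {
  set.seed(302)
  # plant genuine reads + multireads + duplicate stacks
  base <- mk_aln(sample(1:100000, 400))
  multi <- do.call(rbind, lapply(1:60, function(i) {
    k <- sample(2:4, 1)
    data.frame(read_id = sprintf("m%d", i), chrom = "chr1",
               start = sample(1:100000, k), strand = "+",
               read_length = 50, mismatches = 0)
  }))
  dups <- do.call(rbind, lapply(1:40, function(i) {
    n <- sample(2:5, 1)
    data.frame(read_id = sprintf("d%d_%d", i, 1:n), chrom = "chr1",
               start = rep(sample(1:100000, 1), n), strand = "+",
               read_length = 50, mismatches = 0)
  }))
  aln <- rbind(base, multi, dups)
  tot <- function(um, dm) sum(apply_read_qc(aln, use_multireads = um,
                                            duplicate_mode = dm)$reads$weight)
  t_md <- tot(TRUE, "collapse");  t_m <- tot(TRUE, "strict")
  t_d <- tot(FALSE, "collapse");  t_n <- tot(FALSE, "strict")
  expect_true(t_md >= t_m && t_m >= t_n)
  expect_true(t_md >= t_d && t_d >= t_n)
  expect_gt(t_md, t_n)
})
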