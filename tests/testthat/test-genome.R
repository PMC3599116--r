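# CpG scanning, isolation selection, strand-aware read-start counting

pos0 <- function(gr) BiocGenerics::start(gr) - 1L

test_that("scan_cpg_sites finds exact CG dinucleotides only", {
  expect_equal(pos0(scan_cpg_sites(c(chr1 = "ACGT"))), 1L)
  expect_equal(pos0(scan_cpg_sites(c(chr1 = "CGCG"))), c(0L, 2L))
  expect_length(scan_cpg_sites(c(chr1 = "ACNGT")), 0)
  expect_length(scan_cpg_sites(c(chr1 = "ANNNT")), 0)
  # case-insensitive by default; soft-masked excluded on request
  expect_equal(pos0(scan_cpg_sites(c(chr1 = "AcgT"))), 1L)
  expect_length(scan_cpg_sites(c(chr1 = "AcgTACGT"),
                               include_softmasked = FALSE), 1)
  # multiple chromosomes, ascending positions, seqlengths recorded
  gr <- scan_cpg_sites(c(a = "ACGTTTTTTT", b = "TTTTCGT"))
  expect_equal(as.character(GenomicRanges::seqnames(gr)), c("a", "b"))
  expect_equal(unname(GenomeInfoDb::seqlengths(gr)), c(10L, 7L))
})

test_that("select_isolated keeps sites with no CpG neighbor within d", {
  g <- plant_cpgs(blank_genome(1001), 500)
  s <- scan_cpg_sites(g)
  expect_equal(pos0(select_isolated(s, 350)), 500L)

  g2 <- plant_cpgs(blank_genome(200), c(100, 105))
  expect_length(select_isolated(scan_cpg_sites(g2), 10), 0)

  g3 <- plant_cpgs(blank_genome(1100), c(0, 400, 800))
  iso <- select_isolated(scan_cpg_sites(g3), 350)
  expect_equal(pos0(iso), 400L)   # 0 and 800 have truncated windows
  # without end-dropping all three sites are mutually > d apart
  iso2 <- select_isolated(scan_cpg_sites(g3), 350, drop_ends = FALSE)
  expect_equal(pos0(iso2), c(0L, 400L, 800L))
})

test_that("select_isolated agrees with a brute-force neighbor scan", {
  set.seed(201)
  for (i in 1:5) {
    n <- 4000
    g <- blank_genome(n)
    pos <- sort(sample(0:(n - 3), 25))
    pos <- pos[c(TRUE, diff(pos) > 1)]       # no overlapping plants
    g <- plant_cpgs(g, pos)
    sites <- scan_cpg_sites(g)
    d <- sample(50:400, 1)
    got <- pos0(select_isolated(sites, d, drop_ends = FALSE))
    p <- pos0(sites)
    want <- p[vapply(seq_along(p), function(j)
      all(abs(p[-j] - p[j]) > d), logical(1))]
    expect_equal(got, want)
  }
})

test_that("isolation is symmetric under reverse complement", {
  set.seed(202)
  g <- plant_cpgs(blank_genome(3000), c(300, 1500, 1560, 2600))
  sites <- scan_cpg_sites(g)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(unname(g))))
  sites_rc <- scan_cpg_sites(stats::setNames(rc, "chrT"))
  d <- 200
  iso <- pos0(select_isolated(sites, d, drop_ends = FALSE))
  iso_rc <- pos0(select_isolated(sites_rc, d, drop_ends = FALSE))
  # CpG is its own reverse complement: positions mirror as L - pos - 2
  expect_equal(sort(3000 - iso - 2), sort(iso_rc))
})

test_that("count_read_starts measures strand-aware 5' distances", {
  g <- plant_cpgs(blank_genome(2001), 1000)
  iso <- select_isolated(scan_cpg_sites(g), 350)
  mk <- function(start, strand) data.frame(
    chrom = "chrT", start = start, strand = strand, read_length = 50)
  # forward read starting exactly at C -> r = 0
  cnt <- count_read_starts(mk(1000, "+"), iso, 350)
  expect_equal(cnt$counts[1], 1)
  # reverse read with 5' end at C+1 (start0 = C+1 - 49) -> r = 0
  cnt <- count_read_starts(mk(1001 - 49, "-"), iso, 350)
  expect_equal(cnt$counts[1], 1)
  # forward read 120 bp upstream -> r = 120; reverse 120 downstream
  cnt <- count_read_starts(rbind(mk(880, "+"), mk(1121 - 49, "-")), iso, 350)
  expect_equal(cnt$counts[121], 2)
  # reads beyond d or on unknown chromosomes are not counted
  far <- data.frame(chrom = c("chrT", "chrT", "chrX"),
                    start = c(1000, 600, 1000),
                    strand = "+", read_length = 50)
  expect_message(cnt <- count_read_starts(far, iso, 350), "skipped")
  expect_equal(cnt$n_reads_total, 1)  # r = 400 > d dropped, chrX skipped
})

test_that("deterministic uniform placement gives flat counts", {
  g <- plant_cpgs(blank_genome(2001), 1000)
  iso <- select_isolated(scan_cpg_sites(g), 350)
  reads <- data.frame(chrom = "chrT",
                      start = 1000 - rep(0:199, each = 5),
                      strand = "+", read_length = 50)
  cnt <- count_read_starts(reads, iso, 350)
  expect_equal(cnt$counts[1:200], rep(5, 200))
  expect_equal(cnt$n_reads_total, 1000)
  # weights accumulate instead of unit counts
  reads$weight <- 0.25
  cnt <- count_read_starts(reads, iso, 350)
  expect_equal(cnt$counts[1:200], rep(1.25, 200))
})

test_that("suggest_d finds the flattening point of the count curve", {
  # counts decaying until ~240 then flat noise, as in enrichment data
  fK <- make_fragment_pmf("kurtotic", cutoff = 240)
  cnt <- simulate_read_starts(fK, 2e5, noise_fraction = 0.15, d = 500,
                              seed = 205)
  res <- suggest_d(cnt)
  expect_true(res$recommended_d >= 250 && res$recommended_d <= 300)
  # perfectly flat counts: r* = 0 with a warning
  flat <- read_start_counts(rep(100, 501), d = 500, read_length = 50)
  expect_warning(res <- suggest_d(flat), "flat")
  expect_equal(res$r_star, 0L)
  # exact single-size-150 counts, zero noise: change point at ~150
  pr <- unclass(read_start_pmf(fragment_pmf(1, sizes = 150)))
  cnt150 <- read_start_counts(c(pr, numeric(351 - 150)) * 1e6, d = 350,
                              read_length = 50)
  res <- suggest_d(cnt150)
  expect_true(abs(res$r_star - 150) <= 25)
})

test_that("counts and sites round-trip through their text formats", {
  cnt <- read_start_counts(c(5, 3, 0, 2.5), d = 3, read_length = 2,
                           n_sites = 7L)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(cnt, tmp)
  back <- read_counts_tsv(tmp)
  expect_equal(back$counts, cnt$counts)
  expect_equal(back$d, 3L)
  expect_equal(back$read_length, 2L)
  expect_equal(back$n_sites, 7L)

  g <- plant_cpgs(blank_genome(900), c(200, 600))
  sites <- scan_cpg_sites(g)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_sites_bed(sites, bed)
  back <- read_sites_bed(bed)
  expect_equal(BiocGenerics::start(back), BiocGenerics::start(sites))
})
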