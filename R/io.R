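## Alignment input: SAM/BAM via Rsamtools, or a minimal TSV dialect
##   chrom  start0  strand  readlen  mismatches  n_alignments
## All coordinates are converted to 0-based on ingest.

#' Read an alignment table
#'
#' Returns a standardized data.frame with columns `read_id`, `chrom`,
#' `start` (0-based leftmost aligned base), `strand`, `read_length`,
#' `mismatches`, `n_alignments` -- one row per candidate alignment.
#'
#' SAM/BAM: parsed with Rsamtools (SAM converted on the fly); mismatches
#' from the NM tag (0 when absent), locus count from NH (1 when absent);
#' unmapped records dropped.  TSV: tab-separated with the columns above
#' (header optional); an optional leading `read_id` column groups the
#' candidate alignments of multi-reads, otherwise each row is its own
#' read.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"tsv"`, `"sam"` or `"bam"`.
#' @export
read_alignments <- function(path, format = c("auto", "tsv", "sam", "bam")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("sam", "bam")) ext else "tsv"
  }
  if (format == "tsv") return(read_alignments_tsv(path))
  bam <- if (format == "sam")
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  else path
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "qwidth"),
    tag = c("NM", "NH"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  nm <- b$tag$NM
  nh <- b$tag$NH
  n <- length(b$pos)
  data.frame(read_id = b$qname,
             chrom = as.character(b$rname),
             start = b$pos - 1L,
             strand = as.character(b$strand),
             read_length = b$qwidth,
             mismatches = if (is.null(nm)) rep(0L, n) else
               ifelse(is.na(nm), 0L, nm),
             n_alignments = if (is.null(nh)) rep(1L, n) else
               ifelse(is.na(nh), 1L, nh))
}

read_alignments_tsv <- function(path) {
  canonical <- c("chrom", "start", "strand", "read_length", "mismatches",
                 "n_alignments")
  first <- readLines(path, n = 1)
  has_header <- grepl("chrom", first)
  df <- read.delim(path, header = has_header, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (!has_header) {
    names(df) <- if (ncol(df) == 7) c("read_id", canonical)
                 else if (ncol(df) == 6) canonical
                 else stop("TSV alignments need 6 or 7 columns")
  } else {
    names(df) <- sub("^start0$", "start", sub("^readlen$", "read_length",
                                              names(df)))
  }
  if (!"read_id" %in% names(df)) df$read_id <- sprintf("row_%d", seq_len(nrow(df)))
  miss <- setdiff(canonical, names(df))
  if (length(miss)) stop("TSV alignments missing columns: ",
                         paste(miss, collapse = ", "))
  df[c("read_id", canonical)]
}

#' Write an alignment table in the TSV dialect
#'
#' @param aln standardized alignment data.frame.
#' @param path output path.
#' @export
write_alignments_tsv <- function(aln, path) {
  cols <- c("read_id", "chrom", "start", "strand", "read_length",
            "mismatches", "n_alignments")
  if (!"n_alignments" %in% names(aln)) aln$n_alignments <- 1L
  write.table(aln[intersect(cols, names(aln))], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fragment sizes from paired-end alignments (benchmark utility)
#'
#' Subtracts mate start positions to recover observed fragment sizes --
#' the paired-end benchmark against which single-end estimates can be
#' compared.  Proper pairs only; returns a [fragment_pmf()].
#'
#' @param bam coordinate-anything BAM/SAM path.
#' @param max_size fragments longer than this are dropped (default 1000).
#' @export
paired_end_fragment_pmf <- function(bam, max_size = 1000) {
  if (tolower(tools::file_ext(bam)) == "sam")
    bam <- Rsamtools::asBam(bam, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = "isize",
    flag = Rsamtools::scanBamFlag(isProperPair = TRUE,
                                  isFirstMateRead = TRUE))
  isz <- abs(Rsamtools::scanBam(bam, param = p)[[1]]$isize)
  isz <- isz[!is.na(isz) & isz >= 1 & isz <= max_size]
  if (length(isz) == 0) stop("no proper pairs found")
  tab <- tabulate(isz, nbins = max(isz))
  fragment_pmf(tab / sum(tab))
}
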