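## Discrete probability model linking fragment sizes, read-start positions
## and CpG coverage.  All distributions are dense numeric vectors on an
## integer grid: a fragment-size pmf over sizes x = 1..s, a read-start pmf
## and a coverage function over distances r = 0..s-1.

PMF_SUM_TOL <- 1e-9

#' Fragment-size probability mass function
#'
#' Construct (or extract by inversion, see [read_start_pmf()]) the discrete
#' distribution Pr(X = x) of sequenced DNA fragment sizes, the central
#' estimand of the package.  Stored as a dense vector over x = 1..s bp.
#'
#' @param x either a numeric vector of probabilities (dense over sizes
#'   `1:length(x)` unless `sizes` is given), or a `read_start_pmf` to invert.
#' @param sizes optional integer vector of fragment sizes (bp) matching `x`;
#'   probabilities at unlisted sizes are zero.
#' @param ... passed to methods.
#' @return an object of class `fragment_pmf`: numeric vector `p` with
#'   `p[x] == Pr(X = x)` and `s = length(p)` the maximum fragment size.
#' @examples
#' f <- fragment_pmf(c(0.5, 0.5), sizes = c(2, 4))
#' support(f)
#' @export
fragment_pmf <- function(x, ...) UseMethod("fragment_pmf")

#' @rdname fragment_pmf
#' @export
fragment_pmf.numeric <- function(x, sizes = NULL, ...) {
  if (!is.null(sizes)) {
    stopifnot(length(sizes) == length(x), all(sizes == as.integer(sizes)),
              all(sizes >= 1), !anyDuplicated(sizes))
    p <- numeric(max(sizes))
    p[sizes] <- x
  } else {
    p <- as.numeric(x)
  }
  if (length(p) == 0) stop("empty probability mass function")
  ## s is the largest size with mass: trailing zeros are not support
  last <- max(which(p > 0), 1L)
  new_pmf(p[seq_len(last)], "fragment_pmf")
}

#' @rdname fragment_pmf
#' @export
fragment_pmf.default <- function(x, ...) fragment_pmf.numeric(as.numeric(x), ...)

#' Read-start distance probability mass function
#'
#' The distribution Pr(R = r) of the distance r between a read's 5' start
#' and the isolated CpG that caused the enrichment.  Given a fragment-size
#' pmf it is computed from the model: a fragment of size x carries a read
#' starting uniformly at one of its x positions, so
#' \deqn{\Pr(R=r) = \sum_{x=r+1}^{s} \Pr(x)/x, \quad r = 0,\dots,s-1.}
#'
#' @param x a `fragment_pmf` (computes the model pmf) or a numeric vector
#'   of probabilities over r = 0..s-1 (validates and wraps).
#' @param ... passed to methods.
#' @return object of class `read_start_pmf`: numeric vector `p` with
#'   `p[r + 1] == Pr(R = r)`.
#' @examples
#' read_start_pmf(fragment_pmf(c(1), sizes = 2))  # uniform on {0, 1}
#' @seealso [fragment_pmf.read_start_pmf()] for the exact algebraic inverse.
#' @export
read_start_pmf <- function(x, ...) UseMethod("read_start_pmf")

#' @rdname read_start_pmf
#' @export
read_start_pmf.fragment_pmf <- function(x, ...) {
  s <- length(x)
  w <- unclass(x) / seq_len(s)
  new_pmf(rev(cumsum(rev(w))), "read_start_pmf")
}

#' @rdname read_start_pmf
#' @export
read_start_pmf.numeric <- function(x, ...) new_pmf(as.numeric(x), "read_start_pmf")

#' Invert a read-start pmf into a fragment-size pmf
#'
#' The exact algebraic inverse of [read_start_pmf()]: telescoping the
#' tail-sum relation gives
#' \deqn{\Pr(X = x) = (\Pr(R = x-1) - \Pr(R = x)) \cdot x,}
#' with Pr(R = s) taken as 0.  Empirical inputs need not be monotone, so
#' negative masses produced by sampling noise are clipped to zero and the
#' result renormalized; if the clipped mass exceeds `tol` a warning reports
#' the total.
#'
#' @param x a `read_start_pmf`.
#' @param tol clipped-mass tolerance before warning (default 1e-8).
#' @param ... ignored.
#' @export
fragment_pmf.read_start_pmf <- function(x, tol = 1e-8, ...) {
  p <- unclass(x)
  s <- length(p)
  q <- (p - c(p[-1], 0)) * seq_len(s)
  neg <- -sum(q[q < 0])
  if (neg > tol)
    warning(sprintf("non-monotone read-start pmf: clipped negative mass %.3g",
                    neg))
  q[q < 0] <- 0
  fragment_pmf.numeric(q / sum(q))
}

#' Coverage function Pr(X > r)
#'
#' The probability that a fragment tagged by a read starting r bases away
#' from a CpG is long enough to cover it: the complement of the cumulative
#' fragment-size distribution, \eqn{G(r) = \sum_{x>r} \Pr(x)}.  G is
#' monotone non-increasing with G(r) = 0 for r >= s.
#'
#' @param x a `fragment_pmf` (computes G) or a numeric vector of values
#'   over r = 0..s-1 (validated: within \[0, 1\] and non-increasing).
#' @param ... passed to methods.
#' @return object of class `coverage_fn`: numeric `G` with
#'   `G[r + 1] == Pr(X > r)`.
#' @examples
#' coverage_fn(fragment_pmf(c(0.5, 0.5), sizes = c(2, 4)))
#' @export
coverage_fn <- function(x, ...) UseMethod("coverage_fn")

#' @rdname coverage_fn
#' @export
coverage_fn.fragment_pmf <- function(x, ...) {
  structure(rev(cumsum(rev(unclass(x)))), class = "coverage_fn")
}

#' @rdname coverage_fn
#' @export
coverage_fn.numeric <- function(x, ...) {
  g <- as.numeric(x)
  if (length(g) == 0) stop("empty coverage function")
  if (any(!is.finite(g)) || any(g < -PMF_SUM_TOL) || any(g > 1 + 1e-6))
    stop("coverage function values must lie in [0, 1]")
  if (any(diff(g) > 1e-9))
    stop("coverage function must be monotone non-increasing")
  structure(pmin(pmax(g, 0), 1), class = "coverage_fn")
}

#' Expected coverage contribution of one random read
#'
#' E(cov): the probability that a randomly chosen read's fragment covers
#' the CpG it was enriched for, combining the read-start distribution with
#' the coverage function:
#' \deqn{E(cov) = \sum_{r=0}^{s-1} \Pr(R = r)\,\Pr(X > r).}
#' Depends only on the fragment-size pmf, hence is a lab artifact that
#' differs between samples and motivates [standardization_factors()].
#' Equals 1 exactly when all fragments have a single size.
#'
#' @param f a `fragment_pmf`.
#' @return scalar in (0, 1].
#' @examples
#' expected_contribution(fragment_pmf(c(0.5, 0.5), sizes = c(2, 4)))  # 0.875
#' @export
expected_contribution <- function(f) {
  stopifnot(inherits(f, "fragment_pmf"))
  sum(unclass(read_start_pmf(f)) * unclass(coverage_fn(f)))
}

#' Between-sample coverage standardization factors
#'
#' For each sample, the across-sample mean of the expected read
#' contributions divided by that sample's own E(cov).  Multiplying a
#' sample's coverage track by its factor removes between-sample bias driven
#' purely by fragment-size differences: factor_i * ecov_i equals the
#' across-sample mean E(cov) for every sample.
#'
#' @param ecovs named numeric vector (or named list) of per-sample E(cov)
#'   values, all in (0, 1].
#' @return named numeric vector of positive factors.
#' @examples
#' standardization_factors(c(A = 0.875, B = 1))
#' @export
standardization_factors <- function(ecovs) {
  e <- unlist(ecovs)
  if (length(e) < 1) stop("need at least one sample")
  if (any(!is.finite(e)) || any(e <= 0))
    stop("all expected contributions must be positive")
  mean(e) / e
}

## -- internal constructor / validation ------------------------------------

new_pmf <- function(p, class) {
  if (length(p) == 0) stop("empty probability mass function")
  if (any(!is.finite(p)) || any(p < -PMF_SUM_TOL))
    stop("probabilities must be finite and non-negative")
  p <- pmax(p, 0)
  if (abs(sum(p) - 1) > PMF_SUM_TOL)
    stop(sprintf("probabilities must sum to 1 (got %.12g)", sum(p)))
  structure(as.numeric(p), class = class)
}

#' Support of a distribution object
#'
#' Integer grid the vector is indexed by: fragment sizes `1:s` for a
#' `fragment_pmf`, distances `0:(s-1)` for a `read_start_pmf` or
#' `coverage_fn`.
#'
#' @param x a distribution object.
#' @export
support <- function(x) {
  if (inherits(x, "fragment_pmf")) seq_len(length(x))
  else if (inherits(x, c("read_start_pmf", "coverage_fn"))) seq_along(x) - 1L
  else stop("not a fragcov distribution object")
}

#' @export
print.fragment_pmf <- function(x, ...) {
  nz <- which(unclass(x) > 0)
  cat(sprintf("<fragment_pmf> s = %d bp, support [%d, %d], E[X] = %.1f bp\n",
              length(x), min(nz), max(nz),
              sum(unclass(x) * seq_along(x))))
  invisible(x)
}

#' @export
print.read_start_pmf <- function(x, ...) {
  cat(sprintf("<read_start_pmf> r in [0, %d]\n", length(x) - 1L))
  invisible(x)
}

#' @export
print.coverage_fn <- function(x, ...) {
  cat(sprintf("<coverage_fn> r in [0, %d], G(0) = %.4f\n",
              length(x) - 1L, x[1]))
  invisible(x)
}

## -- serialization ---------------------------------------------------------

dist_type <- function(x) {
  switch(class(x)[1],
         fragment_pmf = "fragment_pmf",
         read_start_pmf = "readstart_pmf",
         coverage_fn = "coverage_function",
         stop("not a serializable distribution"))
}

#' Write / read a distribution as two-column TSV
#'
#' Format: a header line `# type=fragment_pmf|readstart_pmf|coverage_function`
#' followed by tab-separated (index, probability) rows, probabilities at 10
#' significant digits.  The index is the fragment size for a pmf and the
#' read-start distance for the other types.
#'
#' @param x distribution object.
#' @param path file path.
#' @export
write_distribution <- function(x, path) {
  idx <- support(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# type=%s", dist_type(x)), con)
  writeLines(sprintf("%d\t%s", idx, formatC(unclass(x), digits = 10,
                                            format = "g")), con)
  invisible(path)
}

#' @rdname write_distribution
#' @export
read_distribution <- function(path) {
  first <- readLines(path, n = 1)
  type <- sub("^# type=", "", first)
  df <- read.delim(path, comment.char = "#", header = FALSE,
                   col.names = c("index", "prob"))
  switch(type,
         fragment_pmf = fragment_pmf(df$prob, sizes = df$index),
         readstart_pmf = read_start_pmf(df$prob),
         coverage_function = coverage_fn(df$prob),
         stop("unknown distribution type: ", type))
}
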