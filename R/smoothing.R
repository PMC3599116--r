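## Steps 2-3 of the estimation procedure: smooth the read-start counts,
## invert to a fragment-size pmf by first differences, form the coverage
## function, and enforce monotonicity.

#' Smoother specification
#'
#' @param method `"kernel_nw"` (Nadaraya-Watson nearest-neighbor kernel
#'   average, the default) or `"cubic_spline"` (smoothing spline with
#'   GCV-chosen penalty).
#' @param m window size for the kernel method: number of nearest
#'   neighbors, odd and >= 3 (default 31, a bias/variance compromise at
#'   typical isolated-CpG read depths of 10k-100k reads).
#' @param kernel weighting function for the kernel method: `"box"`
#'   (default) or `"normal"`.
#' @param spar optional smoothing parameter for the spline method
#'   (default: generalized cross-validation).
#' @return list of class `smoother_spec`.
#' @export
smoother_spec <- function(method = c("kernel_nw", "cubic_spline"), m = 31,
                          kernel = c("box", "normal"), spar = NULL) {
  method <- match.arg(method)
  kernel <- match.arg(kernel)
  if (method == "kernel_nw" && (m < 3 || m %% 2 == 0))
    stop("kernel window m must be odd and >= 3")
  structure(list(method = method, m = m, kernel = kernel, spar = spar),
            class = "smoother_spec")
}

#' Nadaraya-Watson kernel smoothing of a count vector
#'
#' Each position is replaced by the kernel-weighted mean of its m nearest
#' neighbors (box kernel: plain windowed mean).  Endpoints use truncated
#' windows.  Thin wrapper around [stats::ksmooth()] on the integer grid.
#'
#' @param y numeric vector of counts (or a `read_start_counts`).
#' @param m window size (odd, >= 3).
#' @param kernel `"box"` or `"normal"`.
#' @param x grid positions (default `0:(length(y)-1)`).
#' @param x.out positions at which to evaluate (default `x`).
#' @return numeric vector of smoothed values at `x.out`.
#' @export
kernel_smooth <- function(y, m = 31, kernel = "box", x = NULL, x.out = NULL) {
  if (inherits(y, "read_start_counts")) y <- y$counts
  if (is.null(x)) x <- seq_along(y) - 1
  if (is.null(x.out)) x.out <- x
  stopifnot(m >= 3, m <= length(y))
  out <- ksmooth(x, y, kernel = kernel, bandwidth = m, x.points = x.out)$y
  if (anyNA(out)) out <- fill_na_nearest(out)
  out
}

#' Cubic smoothing spline on a count vector
#'
#' Fits [stats::smooth.spline()] to (position, count) pairs and evaluates
#' at the requested grid; the smoothing parameter is chosen by generalized
#' cross-validation unless given.  Degenerate all-equal input returns the
#' constant.
#'
#' @inheritParams kernel_smooth
#' @param spar optional smoothing parameter passed through.
#' @export
spline_smooth <- function(y, spar = NULL, x = NULL, x.out = NULL) {
  if (inherits(y, "read_start_counts")) y <- y$counts
  if (is.null(x)) x <- seq_along(y) - 1
  if (is.null(x.out)) x.out <- x
  stopifnot(length(y) >= 10)
  if (sd(y) == 0) return(rep(y[1], length(x.out)))
  fit <- if (is.null(spar)) smooth.spline(x, y, cv = FALSE)
         else smooth.spline(x, y, spar = spar)
  predict(fit, x.out)$y
}

fill_na_nearest <- function(v) {
  idx <- which(!is.na(v))
  if (length(idx) == 0) stop("smoother produced no values")
  nai <- which(is.na(v))
  v[nai] <- v[vapply(nai, function(i) idx[which.min(abs(idx - i))],
                     numeric(1))]
  v
}

#' Monotonize a raw coverage curve
#'
#' The true coverage function is monotone non-increasing, but a curve
#' assembled from smoothed empirical counts need not be.  The default is a
#' kernel-smoothed decreasing rearrangement (Dette-style): the smoothed
#' empirical "upper level set size" M(u) = (1/N) sum_i Phi((g_i - u)/h) is
#' inverted at equispaced quantile levels, which for h -> 0 reduces to the
#' exact descending sort of the values.  An isotonic-regression
#' (pool-adjacent-violators) fallback is selectable.  Inputs that are
#' already monotone non-increasing are returned unchanged (clipped to
#' \[0, 1\]).
#'
#' @param g numeric vector of raw coverage values in \[0, 1 + eps\].
#' @param method `"rearrangement"` (default) or `"isotonic"`.
#' @param bandwidth value-axis bandwidth h of the smoothed rearrangement;
#'   `NULL` ties it to the count-smoother window (`m/(4N)` of the value
#'   range); `0` gives the exact descending sort.
#' @param m count-smoother window used for the default bandwidth.
#' @return a [coverage_fn()] (monotone non-increasing, clipped to \[0,1\]).
#' @export
monotonize <- function(g, method = c("rearrangement", "isotonic"),
                       bandwidth = NULL, m = 31) {
  method <- match.arg(method)
  g <- as.numeric(g)
  if (any(g < -1e-9) || any(g > 1 + 1e-6))
    stop("raw coverage values must lie in [0, 1]")
  if (all(diff(g) <= 1e-12))  # already monotone: no-op
    return(coverage_fn(pmin(pmax(g, 0), 1)))
  n <- length(g)
  out <- if (method == "isotonic") {
    rev(isoreg(seq_len(n), rev(g))$yf)  # LS non-increasing fit
  } else {
    h <- if (is.null(bandwidth)) m / (4 * n) * diff(range(g)) else bandwidth
    if (h <= 0) {
      sort(g, decreasing = TRUE)
    } else {
      ug <- seq(min(g) - 4 * h, max(g) + 4 * h, length.out = max(512, 4 * n))
      M <- vapply(ug, function(u) mean(pnorm((g - u) / h)), numeric(1))
      tau <- (seq_len(n) - 0.5) / n
      ## M is decreasing in u; invert by interpolation
      approx(rev(M), rev(ug), xout = tau, rule = 2)$y
    }
  }
  out <- cummin(pmin(pmax(out, 0), 1))  # guard interpolation round-off
  coverage_fn(out)
}

#' Estimate the coverage function from read-start counts
#'
#' The full three-step estimator.  (1) The first positions
#' (0..`outlier_max`, default 4) show systematic outliers and are dropped;
#' the smoother imputes them.  (2) Counts are smoothed per `spec`.  The
#' region below `r_lo` (default the read length) is treated as flat at the
#' fitted level -- under the model the read-start pmf is constant there,
#' so the fragment pmf gets no mass below `r_lo`.  (3) First differences
#' of the smoothed curve times position give the fragment-size pmf
#' (negatives clipped and the pmf renormalized; the clipped fraction is
#' reported as a fit-quality metric), whose tail sums give the coverage
#' function, finally monotonized.
#'
#' Because the pmf is built from *differences* of adjacent counts, a
#' uniform background of noise reads from imperfect enrichment cancels and
#' does not bias the estimate.
#'
#' @param counts a [read_start_counts()] pooled over isolated CpGs.
#' @param spec a [smoother_spec()].
#' @param r_lo lower bound of the fit region (default
#'   `counts$read_length`).  Lower it if fragments shorter than the read
#'   length are expected (adaptor-trimmed reads); a diagnostic warns when
#'   the count curve already decays before `r_lo`.
#' @param outlier_max last position of the excluded outlier region
#'   (default 4).
#' @param monotonize_method passed to [monotonize()].
#' @param min_reads warn below this many reads (default 1000; precision
#'   degrades below the smallest validated depth).
#' @return object of class `estimated_curves`: list with
#'   `smoothed_counts` (data.frame r/count/smoothed), `fragment_pmf`,
#'   `coverage` (a `coverage_fn` over r = 0..d-1), `fit_region`,
#'   `flat_level`, `clipped_mass`, `spec`.
#' @export
estimate_coverage <- function(counts, spec = smoother_spec(), r_lo = NULL,
                              outlier_max = 4,
                              monotonize_method = "rearrangement",
                              min_reads = 1000) {
  stopifnot(inherits(counts, "read_start_counts"),
            inherits(spec, "smoother_spec"))
  y <- counts$counts
  d <- counts$d
  if (all(y == 0)) stop("all read-start counts are zero")
  if (counts$n_reads_total < min_reads)
    warning(sprintf("only %.0f reads; estimates will be imprecise",
                    counts$n_reads_total))
  if (is.null(r_lo)) r_lo <- counts$read_length
  if (is.na(r_lo) || r_lo <= outlier_max + 1 || r_lo >= d)
    stop("invalid fit-region lower bound r_lo")

  rfit <- (outlier_max + 1):d          # positions entering the smoother
  smoothed <- if (spec$method == "kernel_nw")
    kernel_smooth(y[rfit + 1], m = spec$m, kernel = spec$kernel,
                  x = rfit, x.out = 0:d)
  else
    spline_smooth(y[rfit + 1], spar = spec$spar, x = rfit, x.out = 0:d)

  flat_idx <- (outlier_max + 1):(r_lo - 1)
  flat_level <- mean(smoothed[flat_idx + 1])
  ## pre-read-length decay diagnostic: OLS slope on the raw flat region
  if (length(flat_idx) >= 10) {
    fit <- lm(y[flat_idx + 1] ~ flat_idx)
    sl <- suppressWarnings(coef(summary(fit)))
    if (nrow(sl) == 2 && !is.na(sl[2, 2]) && sl[2, 2] > 0 &&
        sl[2, 1] < -2 * sl[2, 2])
      warning(paste("read-start counts decay before r_lo; fragments",
                    "shorter than the read length suspected -- consider",
                    "lowering r_lo"))
  }
  chat <- smoothed
  chat[seq_len(r_lo)] <- flat_level    # positions 0..r_lo-1 held flat

  xs <- r_lo:d
  q <- numeric(d)
  q[xs] <- (chat[xs] - chat[xs + 1]) * xs  # chat[x] is c(x-1), chat[x+1] is c(x)
  pos_mass <- sum(q[q > 0])
  if (pos_mass <= 0) stop("degenerate fit: no positive fragment mass")
  clipped <- abs(sum(q[q < 0])) / pos_mass
  q[q < 0] <- 0
  f <- fragment_pmf(q / sum(q))
  ## coverage over the full domain r = 0..d-1 (zero beyond the support)
  g_raw <- c(rev(cumsum(rev(unclass(f)))), numeric(d - length(f)))
  g <- monotonize(g_raw, method = monotonize_method, m = spec$m)

  structure(list(
    smoothed_counts = data.frame(r = 0:d, count = y, smoothed = smoothed),
    fragment_pmf = f,
    coverage = g,
    fit_region = c(r_lo, d),
    flat_level = flat_level,
    clipped_mass = clipped,
    spec = spec), class = "estimated_curves")
}

#' @export
print.estimated_curves <- function(x, ...) {
  cat(sprintf(paste0("<estimated_curves> %s fit on r in [%d, %d], ",
                     "clipped mass %.3g, E(cov) = %.4f\n"),
              x$spec$method, x$fit_region[1], x$fit_region[2],
              x$clipped_mass, expected_contribution(x$fragment_pmf)))
  invisible(x)
}

#' Serialize estimated curves
#'
#' Writes `<prefix>_smoothed_counts.tsv`, `<prefix>_fragment_pmf.tsv`,
#' `<prefix>_coverage_function.tsv` plus a JSON sidecar
#' `<prefix>_meta.json` with the smoother spec, fit region, clipped mass
#' and seed.
#'
#' @param curves an `estimated_curves`.
#' @param prefix output path prefix.
#' @param seed seed recorded in the sidecar (if any).
#' @export
write_curves <- function(curves, prefix, seed = NULL) {
  write.table(curves$smoothed_counts,
              paste0(prefix, "_smoothed_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_distribution(curves$fragment_pmf,
                     paste0(prefix, "_fragment_pmf.tsv"))
  write_distribution(curves$coverage,
                     paste0(prefix, "_coverage_function.tsv"))
  meta <- list(spec = unclass(curves$spec), fit_region = curves$fit_region,
               flat_level = curves$flat_level,
               clipped_mass = curves$clipped_mass, seed = seed,
               tool = paste0("fragcov ", packageVersion("fragcov")))
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(prefix)
}
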