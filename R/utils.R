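# Shared interval helpers. All coordinates in this package are 0-based,
# half-open [start, end) -- BED native. GRanges is 1-based closed, so the
# conversion start+1 happens here and nowhere else.

peaks_to_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' Flag intervals that overlap any interval in another set
#'
#' Overlap means at least `min_overlap` shared base pairs under the package's
#' 0-based half-open convention.
#'
#' @param query,subject Data frames with `chrom`, `start`, `end` columns.
#' @param min_overlap Minimum shared base pairs (default 1).
#' @return Logical vector along the rows of `query`.
#' @export
overlaps_any <- function(query, subject, min_overlap = 1L) {
  if (nrow(query) == 0) return(logical(0))
  if (is.null(subject) || nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  hits <- GenomicRanges::countOverlaps(
    peaks_to_gr(query), peaks_to_gr(subject),
    minoverlap = as.integer(min_overlap)
  )
  hits > 0
}

# All (query_row, subject_row) index pairs with >= min_overlap shared bp.
overlap_pairs <- function(query, subject, min_overlap = 1L) {
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(tibble(query = integer(0), subject = integer(0)))
  }
  h <- GenomicRanges::findOverlaps(
    peaks_to_gr(query), peaks_to_gr(subject),
    minoverlap = as.integer(min_overlap)
  )
  tibble(query = S4Vectors::queryHits(h), subject = S4Vectors::subjectHits(h))
}

interval_mid <- function(start, end) (start + end) / 2

check_intervals <- function(x, what = "interval") {
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0) {
    abort(sprintf("%s %d violates 0 <= start < end (start=%s, end=%s)",
                  what, bad[1], x$start[bad[1]], x$end[bad[1]]))
  }
  if (any(!nzchar(x$chrom))) abort("empty chromosome name")
  invisible(x)
}

# Vectorised row-wise Welch t-test on two matrices (rows = regions).
# Returns statistic (y vs x), df, and two-sided p. Degenerate rows with zero
# pooled variance get p = 1 when the means agree and p = 0 otherwise.
row_welch <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  stat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(abs(stat), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
    stat[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 0, Inf)
    df[degenerate] <- n1 + n2 - 2
  }
  list(statistic = stat, df = df, p_value = p)
}

# von Mises sampler, Best & Fisher (1979) rejection scheme; mu in radians.
# kappa = 0 degenerates to the circular uniform.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return((runif(n, -pi, pi) + mu) %% (2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}
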