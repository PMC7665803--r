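# Internal numerical helpers shared across modules.

#' Analytic signal of a real series
#'
#' Frequency-domain construction: positive frequencies doubled, negative
#' frequencies zeroed, so the result has the original series as its real
#' part and its quadrature as the imaginary part. The instantaneous
#' amplitude is `Mod()` and the instantaneous phase `Arg()` of the result.
#'
#' @param x numeric vector, finite values.
#' @return complex vector of the same length.
#' @keywords internal
#' @noRd
analytic_signal <- function(x) {
  n <- length(x)
  stopifnot(n >= 2L, all(is.finite(x)))
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' One-way ANOVA F statistic over equal-occupancy bins, vectorised
#'
#' Computes the classical between/within F for one response vector, or one F
#' per column when `y` is a matrix (used for shuffle null distributions).
#' Agreement with `stats::oneway.test(var.equal = TRUE)` is asserted in the
#' test suite.
#'
#' @param y numeric vector or matrix (rows = observations).
#' @param g integer group labels, length `nrow(y)`.
#' @return numeric vector of F statistics (NaN where within-variance is 0).
#' @keywords internal
#' @noRd
oneway_f <- function(y, g) {
  y <- as.matrix(y)
  n <- nrow(y)
  g <- as.integer(g)
  k <- length(unique(g))
  ng <- tabulate(g)
  sums <- rowsum(y, g, reorder = TRUE)
  means <- sums / ng
  grand <- colSums(y) / n
  ss_between <- colSums(ng * (sweep(means, 2L, grand))^2)
  ss_total <- colSums(sweep(y, 2L, grand)^2)
  ss_within <- ss_total - ss_between
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

#' Spike counts with a target Fano factor
#'
#' Poisson for Fano = 1, negative binomial for Fano > 1 and binomial
#' (n = ceiling(mu / (1 - F)), p = mu / n) for Fano < 1, giving
#' variance/mean close to `fano` at moderate means.
#'
#' @param mu vector of expected counts (recycled against `fano`).
#' @param fano target Fano factor, > 0.
#' @return integer vector of counts.
#' @keywords internal
#' @noRd
rcount_fano <- function(mu, fano = 1) {
  stopifnot(all(fano > 0), all(mu >= 0))
  m <- length(mu)
  fano <- rep_len(fano, m)
  out <- integer(m)
  pois <- abs(fano - 1) < 1e-8 | mu == 0
  if (any(pois)) out[pois] <- rpois(sum(pois), mu[pois])
  over <- !pois & fano > 1
  if (any(over)) {
    size <- mu[over] / (fano[over] - 1)
    out[over] <- rnbinom(sum(over), size = size, mu = mu[over])
  }
  under <- !pois & fano < 1
  if (any(under)) {
    ntr <- pmax(1L, ceiling(mu[under] / (1 - fano[under])))
    out[under] <- rbinom(sum(under), size = ntr, prob = mu[under] / ntr)
  }
  out
}

#' Partition n sorted observations into k bins of equal occupancy
#'
#' Bin sizes differ by at most one; the first `n %% k` bins take the extra
#' observation. Returns the bin index for each of the n sorted positions.
#' @keywords internal
#' @noRd
equal_occupancy_bins <- function(n, k) {
  stopifnot(n >= k)
  base <- n %/% k
  extra <- n %% k
  rep.int(seq_len(k), times = base + (seq_len(k) <= extra))
}

# Merge short gaps and drop short runs in a logical vector (1 sample = 1 ms).
tidy_runs <- function(flag, merge_gap = 50L, min_run = 50L) {
  r <- rle(flag)
  gap <- !r$values & r$lengths < merge_gap
  # interior gaps only: never bridge across series ends
  if (length(r$values) > 2L) {
    interior <- seq_along(r$values) > 1L & seq_along(r$values) < length(r$values)
    r$values[gap & interior] <- TRUE
  }
  flag <- inverse.rle(r)
  r <- rle(flag)
  r$values[r$values & r$lengths < min_run] <- FALSE
  inverse.rle(r)
}

# Runs of TRUE as (start, end) sample indices (1-based, inclusive).
runs_to_epochs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(start = starts[keep], end = ends[keep])
}

# Circular distance between two angles in radians, in [0, pi].
circular_distance <- function(a, b) {
  abs(atan2(sin(a - b), cos(a - b)))
}

# argmax with ties broken toward the lowest index, rowwise on a matrix.
row_argmax <- function(m) {
  max.col(m, ties.method = "first")
}
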