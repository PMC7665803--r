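#' Overlap of whisking and touch tuning versus the independence prediction
#'
#' Given per-neuron tuning flags computed on the same neuron set, reports
#' the marginal tuned proportions, the observed co-tuned proportion, and
#' the proportion expected if the two representations were independently
#' distributed (the product of the marginals). All values in percent.
#'
#' @param records tibble with logical columns `tuned_whisking`,
#'   `tuned_touch` (one row per neuron).
#' @return one-row tibble: `n`, `p_whisking`, `p_touch`,
#'   `p_cotuned_observed`, `p_cotuned_expected` (percent).
#' @examples
#' overlap_statistics(tibble::tibble(
#'   tuned_whisking = rep(c(TRUE, FALSE), c(54, 61)),
#'   tuned_touch = rep(c(TRUE, FALSE, TRUE, FALSE), c(22, 32, 20, 41))
#' ))
#' @export
overlap_statistics <- function(records) {
  if (!nrow(records)) abort("empty record set.")
  stopifnot(all(c("tuned_whisking", "tuned_touch") %in% names(records)))
  pw <- mean(records$tuned_whisking)
  pt <- mean(records$tuned_touch)
  obs <- mean(records$tuned_whisking & records$tuned_touch)
  tibble(
    n = nrow(records),
    p_whisking = 100 * pw,
    p_touch = 100 * pt,
    p_cotuned_observed = 100 * obs,
    p_cotuned_expected = 100 * pw * pt
  )
}

# resample two curves onto the intersection of their stimulus supports and
# min-max normalise each to [0, 1]
common_grid_curves <- function(cw, ct, n_grid = 20) {
  lo <- max(min(cw$stimulus), min(ct$stimulus))
  hi <- min(max(cw$stimulus), max(ct$stimulus))
  if (hi <= lo) return(NULL)
  grid <- seq(lo, hi, length.out = n_grid)
  yw <- approx(cw$stimulus, cw$response, xout = grid)$y
  yt <- approx(ct$stimulus, ct$response, xout = grid)$y
  norm01 <- function(v) {
    if (max(v) == min(v)) return(rep(0.5, length(v)))
    (v - min(v)) / (max(v) - min(v))
  }
  list(w = norm01(yw), t = norm01(yt))
}

#' Shape correlation between whisking- and touch-tuning curves
#'
#' For each neuron with both curves, computes the Pearson correlation
#' between the min-max-normalised curves resampled to a common 20-point
#' grid on the overlap of their stimulus supports. The null distribution
#' comes from randomly re-pairing whisking and touch curves across
#' neurons (`n_shuffles` permutations), which preserves each marginal
#' curve set exactly; a two-sample Kolmogorov-Smirnov test compares the
#' observed and shuffled correlation distributions.
#'
#' @param curves tibble with `neuron_id` and list-columns
#'   `curve_whisking`, `curve_touch`, each a tibble with `stimulus`,
#'   `response` (e.g. the `bin`-level tuning curve).
#' @param n_shuffles re-pairings.
#' @param n_grid grid points on the common support.
#' @param seed seed.
#' @return list: `observed` (tibble `neuron_id`, `r`), `shuffled`
#'   (numeric vector of null correlations), `permutations` (the
#'   re-pairings used, neurons x shuffles; every column is a permutation,
#'   so each shuffle uses each whisking and each touch curve exactly
#'   once), `ks_statistic`, `p_value`, `skipped` (neuron ids without
#'   overlapping support).
#' @export
shape_correlation_test <- function(curves, n_shuffles = 1000, n_grid = 20,
                                   seed = 1) {
  stopifnot(all(c("neuron_id", "curve_whisking", "curve_touch") %in%
                  names(curves)))
  pairs <- lapply(seq_len(nrow(curves)), function(i) {
    common_grid_curves(curves$curve_whisking[[i]], curves$curve_touch[[i]],
                       n_grid)
  })
  ok <- !vapply(pairs, is.null, logical(1))
  skipped <- curves$neuron_id[!ok]
  if (length(skipped)) {
    inform(sprintf("skipping %d neuron(s) with non-overlapping supports.",
                   length(skipped)))
  }
  pairs <- pairs[ok]
  ids <- curves$neuron_id[ok]
  n <- length(pairs)
  if (n < 3) abort("need at least 3 neurons with overlapping curve supports.")
  wmat <- vapply(pairs, `[[`, numeric(n_grid), "w")
  tmat <- vapply(pairs, `[[`, numeric(n_grid), "t")
  obs <- vapply(seq_len(n), function(i) cor(wmat[, i], tmat[, i]), numeric(1))
  perms <- withr::with_seed(seed, {
    vapply(seq_len(n_shuffles), function(s) sample.int(n), integer(n))
  })
  shuffled <- as.numeric(vapply(seq_len(n_shuffles), function(s) {
    p <- perms[, s]
    vapply(seq_len(n), function(i) cor(wmat[, i], tmat[, p[i]]), numeric(1))
  }, numeric(n)))
  ks <- suppressWarnings(ks.test(obs, shuffled))
  list(
    observed = tibble(neuron_id = ids, r = obs),
    shuffled = shuffled,
    permutations = perms,
    ks_statistic = unname(ks$statistic),
    p_value = unname(ks$p.value),
    skipped = skipped
  )
}

#' Displacement between whisking and touch preferred stimuli
#'
#' For co-tuned neurons, the distance of the (whisking preference, touch
#' preference) points from the identity line: `|pref_touch -
#' pref_whisking|` in degrees for angle preferences, or the circular
#' distance in radians for phase preferences. Tests the mean distance
#' against 0 with a one-sample t test and reports the Pearson correlation
#' between the two preferences.
#'
#' @param records tibble with numeric columns `pref_whisking`,
#'   `pref_touch` (co-tuned neurons only).
#' @param circular use circular distance (phase preferences, radians).
#' @return list: `distances`, `mean`, `sd`, `t_statistic`, `df`,
#'   `p_value` (`NA` with fewer than 3 neurons), `pearson_r`.
#' @export
preference_displacement <- function(records, circular = FALSE) {
  pw <- records$pref_whisking
  pt <- records$pref_touch
  ok <- is.finite(pw) & is.finite(pt)
  pw <- pw[ok]; pt <- pt[ok]
  d <- if (circular) circular_distance(pt, pw) else abs(pt - pw)
  if (length(d) >= 3 && sd(d) > 0) {
    tt <- t.test(d, mu = 0)
    tstat <- unname(tt$statistic); df <- unname(tt$parameter)
    p <- unname(tt$p.value)
  } else {
    tstat <- NA_real_; df <- NA_real_; p <- NA_real_
  }
  r <- if (length(d) >= 3 && sd(pw) > 0 && sd(pt) > 0) cor(pw, pt) else NA_real_
  list(distances = d, mean = mean(d), sd = sd(d),
       t_statistic = tstat, df = df, p_value = p, pearson_r = r)
}
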