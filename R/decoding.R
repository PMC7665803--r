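#' Assemble the Poisson-resampled decoding design
#'
#' Each included neuron's object-location tuning curve (expected spike
#' count per touch, 20 equal-occupancy bins) is interpolated to 40 bins
#' at 0.25-mm spacing with a monotone (Fritsch-Carlson) piecewise cubic,
#' clipped at 0; these interpolated means are the Poisson lambdas. At each
#' of the 40 location bins, `samples_per_bin` (default 50) counts are
#' drawn per neuron, giving a 2,000-row design matrix (rows =
#' location-bin samples, columns = neurons). Only neurons with at least
#' `min_touches` touches that sampled at least `min_coverage` of the
#' binned pole locations are included.
#'
#' @param curves named list of `tuning_curve` objects built on spike
#'   counts versus pole location (one per neuron).
#' @param pole_range mm interval of presented locations.
#' @param n_location_bins number of decoded bins (default 40, i.e.
#'   0.25-mm resolution over 10 mm).
#' @param samples_per_bin Poisson draws per bin per neuron.
#' @param min_touches,min_coverage inclusion criteria.
#' @param seed draw seed.
#' @return object of class `decoder_design`: list with `lambda`
#'   (bins x neurons matrix of Poisson means), `x` (design matrix), `y`
#'   (location-bin labels), `locations` (bin centres, mm), `neurons`
#'   (included names), `excluded` (tibble of exclusions with reasons).
#' @export
build_design <- function(curves, pole_range = c(0, 10),
                         n_location_bins = 40, samples_per_bin = 50,
                         min_touches = 75, min_coverage = 0.8, seed = 1) {
  stopifnot(length(curves) >= 1)
  if (is.null(names(curves))) {
    names(curves) <- sprintf("n%03d", seq_along(curves))
  }
  bin_w <- diff(range(pole_range)) / n_location_bins
  centers <- pole_range[1] + (seq_len(n_location_bins) - 0.5) * bin_w
  keep <- character(0)
  excluded <- list()
  lambda <- matrix(0, n_location_bins, 0)
  for (nm in names(curves)) {
    tc <- curves[[nm]]
    smp <- attr(tc, "samples")
    n_t <- nrow(smp)
    cov <- length(unique(pmin(pmax(
      floor((smp$stimulus - pole_range[1]) / bin_w) + 1L, 1L),
      n_location_bins))) / n_location_bins
    if (n_t < min_touches || cov < min_coverage) {
      excluded[[nm]] <- tibble(
        neuron = nm, n_touches = n_t, coverage = cov,
        reason = if (n_t < min_touches) "too few touches" else "coverage"
      )
      next
    }
    f <- splinefun(tc$stimulus, tc$response, method = "monoH.FC")
    x <- pmin(pmax(centers, min(tc$stimulus)), max(tc$stimulus))
    lam <- pmax(f(x), 0)
    lambda <- cbind(lambda, lam)
    keep <- c(keep, nm)
  }
  if (!length(keep)) abort("no neurons pass the inclusion criteria.")
  colnames(lambda) <- keep
  x <- withr::with_seed(seed, {
    apply(lambda, 2, function(l) {
      rpois(n_location_bins * samples_per_bin,
            rep(l, each = samples_per_bin))
    })
  })
  y <- rep(seq_len(n_location_bins), each = samples_per_bin)
  structure(
    list(lambda = lambda, x = x, y = y, locations = centers,
         bin_mm = bin_w, neurons = keep,
         excluded = bind_rows(excluded)),
    class = "decoder_design"
  )
}

#' Build a decoder design directly from known Poisson means
#'
#' Bypasses curve estimation: the supplied bins-by-neurons matrix of
#' expected spike counts is taken as the Poisson lambda of each location
#' bin, and `samples_per_bin` counts are drawn per bin per neuron. Used
#' for oracle benchmarking where the population is defined by its tuning
#' functions rather than by recorded sessions.
#'
#' @param lambda numeric matrix, location bins x neurons, nonnegative.
#' @param pole_range mm interval spanned by the rows.
#' @param samples_per_bin Poisson draws per bin per neuron.
#' @param seed draw seed.
#' @return a `decoder_design` (see [build_design()]).
#' @export
design_from_lambda <- function(lambda, pole_range = c(0, 10),
                               samples_per_bin = 50, seed = 1) {
  lambda <- as.matrix(lambda)
  stopifnot(all(lambda >= 0))
  k <- nrow(lambda)
  if (is.null(colnames(lambda))) {
    colnames(lambda) <- sprintf("n%03d", seq_len(ncol(lambda)))
  }
  bin_w <- diff(range(pole_range)) / k
  centers <- pole_range[1] + (seq_len(k) - 0.5) * bin_w
  x <- withr::with_seed(seed, {
    apply(lambda, 2, function(l) {
      rpois(k * samples_per_bin, rep(l, each = samples_per_bin))
    })
  })
  structure(
    list(lambda = lambda, x = x, y = rep(seq_len(k), each = samples_per_bin),
         locations = centers, bin_mm = bin_w,
         neurons = colnames(lambda), excluded = tibble()),
    class = "decoder_design"
  )
}

#' @exportS3Method base::print
print.decoder_design <- function(x, ...) {
  cat(sprintf("<decoder_design: %d neurons x %d rows (%d bins x %d samples)>\n",
              length(x$neurons), nrow(x$x), length(x$locations),
              nrow(x$x) / length(x$locations)))
  if (nrow(x$excluded)) {
    cat(sprintf("  excluded %d neuron(s): %s\n", nrow(x$excluded),
                paste(x$excluded$neuron, x$excluded$reason,
                      sep = ": ", collapse = "; ")))
  }
  invisible(x)
}

#' Fit the multinomial lasso location decoder
#'
#' Multinomial logistic regression with lasso-weighted elastic-net
#' regularisation (mixing 0.95), fitted with glmnet; the regularisation
#' strength is chosen by cross-validation on the training split. Each of
#' `n_iter` iterations (default 10) draws a random 70/30 train/test split
#' stratified by location bin; accuracy and the row-normalised confusion
#' matrix are averaged over iterations. Class probabilities are softmax;
#' the predicted bin is the argmax (ties toward the lower bin).
#'
#' @param design a `decoder_design`.
#' @param n_iter split iterations.
#' @param train_frac training fraction.
#' @param alpha elastic-net mixing (1 = pure lasso).
#' @param nfolds folds for the internal lambda cross-validation.
#' @param seed seed for splits and cross-validation folds.
#' @param redraw if `TRUE`, re-draw the Poisson design from `lambda` at
#'   every iteration instead of only re-splitting (both readings of the
#'   iteration scheme are supported; re-split only is the default).
#' @return object of class `decoder_model`: confusion (40 x 40,
#'   row-normalised over true bins), `accuracy` (mean over iterations),
#'   `accuracy_sd`, per-iteration accuracies, the first iteration's
#'   coefficients (`a0`, `beta`) and test set (for coefficient-subsetting
#'   analyses), bin geometry, and `go_bins` (posterior half).
#' @export
fit_decoder <- function(design, n_iter = 10, train_frac = 0.7,
                        alpha = 0.95, nfolds = 4, seed = 1,
                        redraw = FALSE) {
  stopifnot(inherits(design, "decoder_design"))
  k <- length(design$locations)
  if (length(unique(design$y)) < 2) abort("labels are degenerate (single class).")
  confusion <- matrix(0, k, k)
  acc <- numeric(n_iter)
  first <- NULL
  withr::with_seed(seed, {
    for (it in seq_len(n_iter)) {
      x <- design$x
      if (redraw && it > 1) {
        x <- apply(design$lambda, 2, function(l) {
          rpois(length(design$y), l[design$y])
        })
      }
      train <- unlist(lapply(split(seq_along(design$y), design$y),
                             function(i) sample(i, round(train_frac * length(i)))),
                      use.names = FALSE)
      test <- setdiff(seq_along(design$y), train)
      yf <- factor(design$y, levels = seq_len(k))
      # glmnet requires >= 2 predictors; pad a zero column for 1-neuron pools
      pad <- ncol(x) < 2L
      xf <- if (pad) cbind(x, 0) else x
      # counts share a natural scale, so no standardization (rescaling by
      # noisy column SDs destabilises the path); the grouped multinomial
      # penalty keeps the 40-class coordinate descent numerically stable
      # where the ungrouped variant diverges on occasional draws
      cvfit <- glmnet::cv.glmnet(
        xf[train, , drop = FALSE], yf[train], family = "multinomial",
        alpha = alpha, nfolds = nfolds, nlambda = 25,
        lambda.min.ratio = 0.002, maxit = 5e5, thresh = 3e-6,
        standardize = FALSE, type.multinomial = "grouped"
      )
      prob <- predict(cvfit, xf[test, , drop = FALSE], s = "lambda.min",
                      type = "response")[, , 1]
      pred <- row_argmax(prob)
      truth <- design$y[test]
      acc[it] <- mean(pred == truth)
      for (i in seq_along(pred)) {
        confusion[truth[i], pred[i]] <- confusion[truth[i], pred[i]] + 1
      }
      if (it == 1L) {
        cf <- coef(cvfit, s = "lambda.min")
        a0 <- vapply(cf, function(m) m[1, 1], numeric(1))
        beta <- do.call(cbind, lapply(cf, function(m) m[-1, 1, drop = TRUE]))
        beta <- matrix(beta, ncol = k)[seq_len(ncol(x)), , drop = FALSE]
        first <- list(a0 = a0, beta = beta, x_test = x[test, , drop = FALSE],
                      y_test = truth)
      }
    }
  })
  rs <- rowSums(confusion)
  confusion <- confusion / ifelse(rs == 0, 1, rs)
  structure(
    list(confusion = confusion, accuracy = mean(acc), accuracy_sd = sd(acc),
         accuracy_iter = acc, a0 = first$a0, beta = first$beta,
         x_test = first$x_test, y_test = first$y_test,
         locations = design$locations, bin_mm = design$bin_mm,
         neurons = design$neurons,
         go_bins = seq_len(k %/% 2)),
    class = "decoder_model"
  )
}

#' @exportS3Method base::print
print.decoder_model <- function(x, ...) {
  cat(sprintf(
    "<decoder_model: %d neurons, %d bins; accuracy %.1f%% +/- %.1f%%, resolution(<=0.5 mm) %.1f%%>\n",
    length(x$neurons), length(x$locations), 100 * x$accuracy,
    100 * x$accuracy_sd,
    100 * resolution_curve(x$confusion)$fraction[3]))
  invisible(x)
}

# softmax class probabilities from linear predictors
softmax_prob <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# predictions from a coefficient-subset model on a design subset
predict_from_coef <- function(a0, beta, x) {
  z <- sweep(x %*% beta, 2, a0, "+")
  row_argmax(z)  # softmax is monotone; argmax on z suffices
}

# confusion counts -> resolution curve
resolution_curve <- function(confusion) {
  k <- nrow(confusion)
  p <- confusion / ifelse(rowSums(confusion) == 0, 1, rowSums(confusion))
  offs <- 0:(k - 1)
  frac <- vapply(offs, function(nb) {
    m <- abs(row(p) - col(p)) <= nb
    sum(p[m]) / k
  }, numeric(1))
  tibble(n_bins = offs, fraction = frac)
}

#' Decoding accuracy as a function of sampled pool size
#'
#' Re-evaluates the fitted decoder using pools of neurons sampled with
#' replacement from the included units (`n_draws` draws per pool size,
#' default 500). Each draw restricts both the design columns and the
#' corresponding learned coefficients (no refit) and recomputes accuracy,
#' resolution within 2 bins (0.5 mm), and the neurometric curve.
#'
#' @param model a `decoder_model`.
#' @param pool_sizes integer vector of pool sizes (all > 0).
#' @param n_draws draws per pool size.
#' @param seed seed.
#' @param keep_neurometric keep per-draw neurometric curves (needed for
#'   psychometric comparison).
#' @return tibble per pool size with mean/SD accuracy and resolution;
#'   when `keep_neurometric`, attribute `neurometric` holds a tibble of
#'   per-draw lick probabilities by true location.
#' @export
subsample_population <- function(model, pool_sizes, n_draws = 500, seed = 1,
                                 keep_neurometric = FALSE) {
  stopifnot(inherits(model, "decoder_model"))
  if (any(pool_sizes < 1)) abort("pool sizes must be positive.")
  j <- nrow(model$beta)
  k <- length(model$locations)
  neuro <- list()
  res <- withr::with_seed(seed, {
    bind_rows(lapply(pool_sizes, function(s) {
      accs <- numeric(n_draws)
      res2 <- numeric(n_draws)
      nm <- if (keep_neurometric) matrix(NA_real_, n_draws, k) else NULL
      for (d in seq_len(n_draws)) {
        idx <- sample.int(j, s, replace = TRUE)
        pred <- predict_from_coef(model$a0, model$beta[idx, , drop = FALSE],
                                  model$x_test[, idx, drop = FALSE])
        truth <- model$y_test
        accs[d] <- mean(pred == truth)
        res2[d] <- mean(abs(pred - truth) <= 2)
        if (keep_neurometric) {
          cm <- matrix(0, k, k)
          for (i in seq_along(pred)) {
            cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1
          }
          cm <- cm / ifelse(rowSums(cm) == 0, 1, rowSums(cm))
          nm[d, ] <- rowSums(cm[, model$go_bins, drop = FALSE])
        }
      }
      if (keep_neurometric) {
        neuro[[as.character(s)]] <<- tibble(
          pool_size = s,
          draw = rep(seq_len(n_draws), each = k),
          location_mm = rep(model$locations, n_draws),
          lick_prob = as.numeric(t(nm))
        )
      }
      tibble(pool_size = s,
             accuracy_mean = mean(accs), accuracy_sd = sd(accs),
             resolution2_mean = mean(res2), resolution2_sd = sd(res2))
    }))
  })
  if (keep_neurometric) attr(res, "neurometric") <- bind_rows(neuro)
  res
}

#' Decoding resolution and neurometric curve of a fitted decoder
#'
#' Resolution(n) is the fraction of predictions within n bins of the
#' confusion-matrix diagonal (each bin 0.25 mm; n = 2 corresponds to
#' <= 0.5 mm). The neurometric curve is the summed predicted mass over
#' the go half of the confusion matrix (posterior locations) for each
#' true location; the simulated choice licks wherever that probability
#' exceeds 50%.
#'
#' @param model a `decoder_model`.
#' @return list with `resolution` (tibble `n_bins`, `mm`, `fraction`) and
#'   `neurometric` (tibble `location_mm`, `lick_prob`, `lick`).
#' @export
resolution_and_neurometric <- function(model) {
  stopifnot(inherits(model, "decoder_model"))
  res <- resolution_curve(model$confusion)
  res$mm <- res$n_bins * model$bin_mm
  lick_prob <- rowSums(model$confusion[, model$go_bins, drop = FALSE])
  list(
    resolution = select(res, "n_bins", "mm", "fraction"),
    neurometric = tibble(location_mm = model$locations,
                         lick_prob = lick_prob,
                         lick = lick_prob > 0.5)
  )
}

#' Brute-force Bayes classifier from the true Poisson rates
#'
#' Maximum-likelihood location decoding with the exact Poisson
#' likelihoods of the generating lambdas; the performance oracle against
#' which the fitted decoder is benchmarked.
#'
#' @param lambda bins x neurons matrix of Poisson means.
#' @param x design matrix (rows = samples, columns = neurons).
#' @return integer vector of predicted bin indices.
#' @export
bayes_location_decoder <- function(lambda, x) {
  lam <- pmax(lambda, 1e-9)
  ll <- x %*% t(log(lam))
  ll <- sweep(ll, 2, rowSums(lam), "-")
  row_argmax(ll)
}

#' Compare neurometric draws to a psychometric reference
#'
#' Per-location two-sample (Welch) t test between the neurometric lick
#' probabilities across decoder draws and a supplied psychometric
#' reference given as mean +/- SD per location (with its number of
#' subjects). Mismatched location grids are linearly interpolated with a
#' warning.
#'
#' @param neurometric tibble `location_mm`, `lick_prob` with one row per
#'   draw and location (e.g. the `neurometric` attribute of
#'   [subsample_population()]).
#' @param psychometric tibble `location_mm`, `mean_lick_prob`, `sd`, and
#'   optionally `n` (default 15 subjects).
#' @param alpha significance level.
#' @return tibble per location with both means, the Welch t statistic,
#'   p value and a `significant` flag.
#' @export
compare_to_psychometric <- function(neurometric, psychometric, alpha = 0.05) {
  if (!all(c("location_mm", "lick_prob") %in% names(neurometric))) {
    abort("`neurometric` needs columns location_mm, lick_prob.")
  }
  if (is.null(psychometric$n)) psychometric$n <- 15
  locs <- sort(unique(neurometric$location_mm))
  if (!all(locs %in% psychometric$location_mm)) {
    warn("psychometric grid differs from neurometric grid; interpolating.")
  }
  pm <- approx(psychometric$location_mm, psychometric$mean_lick_prob,
               xout = locs, rule = 2)$y
  ps <- approx(psychometric$location_mm, psychometric$sd, xout = locs,
               rule = 2)$y
  pn <- approx(psychometric$location_mm, psychometric$n, xout = locs,
               rule = 2)$y
  out <- lapply(seq_along(locs), function(i) {
    v <- neurometric$lick_prob[neurometric$location_mm == locs[i]]
    m1 <- mean(v); s1 <- sd(v); n1 <- length(v)
    se2 <- s1^2 / n1 + ps[i]^2 / pn[i]
    tstat <- (m1 - pm[i]) / sqrt(se2)
    df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (ps[i]^2 / pn[i])^2 / (pn[i] - 1))
    p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
    tibble(location_mm = locs[i], neuro_mean = m1, neuro_sd = s1,
           psych_mean = pm[i], psych_sd = ps[i], t = tstat, df = df,
           p_value = p, significant = p < alpha)
  })
  bind_rows(out)
}
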