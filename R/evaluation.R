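# Discrimination and calibration metrics, and the presence partitions used
# for tuning: random 75/25 split, spatial block quadrants, leave-one-out
# jackknife, and bootstrap replicates.

#' Rank-based AUC of presences vs background
#'
#' Mann-Whitney statistic: the probability a random presence scores above a
#' random background cell, with ties counting 1/2.
#'
#' @param presence_scores,background_scores Nonempty numeric vectors.
#' @return AUC in [0, 1].
#' @export
compute_auc <- function(presence_scores, background_scores) {
  if (!length(presence_scores) || !length(background_scores))
    stop("score vectors must be nonempty")
  np <- length(presence_scores); nb <- length(background_scores)
  r <- rank(c(presence_scores, background_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' 10% training omission rate (OR10)
#'
#' The threshold is the order statistic excluding the lowest 10% of training
#' presence scores (the (floor(0.1 n) + 1)-th smallest); OR10 is the
#' fraction of test presences scoring strictly below it. Values well above
#' 0.1 indicate overfitting to the training localities.
#'
#' @param train_presence_scores,test_presence_scores Numeric vectors.
#' @return Omission rate in [0, 1].
#' @export
compute_or10 <- function(train_presence_scores, test_presence_scores) {
  stopifnot(length(train_presence_scores) >= 1, length(test_presence_scores) >= 1)
  n <- length(train_presence_scores)
  tau <- sort(train_presence_scores)[floor(0.1 * n) + 1L]
  mean(test_presence_scores < tau)
}

#' Continuous Boyce index (CBI)
#'
#' Calibration measure for presence-only predictions: the Spearman rank
#' correlation between the predicted-to-expected presence ratio P/E in
#' moving suitability windows and the window midpoint. 1 means monotone
#' calibration, 0 no better than random, negative values a miscalibrated
#' model.
#'
#' @param test_presence_scores Presence suitabilities in [0, 1].
#' @param background_scores Background suitabilities in [0, 1].
#' @param n_windows Number of window centers spanning [0, 1] (default 101).
#' @param window_width Window width (default 0.1).
#' @return CBI in [-1, 1].
#' @export
compute_cbi <- function(test_presence_scores, background_scores,
                        n_windows = 101, window_width = 0.1) {
  stopifnot(all(test_presence_scores >= 0 & test_presence_scores <= 1),
            all(background_scores >= 0 & background_scores <= 1))
  centers <- seq(0, 1, length.out = n_windows)
  P <- E <- numeric(n_windows)
  half <- window_width / 2
  for (i in seq_len(n_windows)) {
    lo <- centers[i] - half; hi <- centers[i] + half
    P[i] <- mean(test_presence_scores >= lo & test_presence_scores <= hi)
    E[i] <- mean(background_scores >= lo & background_scores <= hi)
  }
  ok <- E > 0
  if (sum(ok) < 2) stop("fewer than 2 windows contain background mass")
  suppressWarnings(stats::cor(P[ok] / E[ok], centers[ok], method = "spearman"))
}

#' Small-sample Akaike information criterion for a fitted model
#'
#' lnL is the presence log-likelihood under the raw distribution
#' (normalized to sum to 1 over the full background); k counts nonzero
#' coefficients. AICc = 2k - 2 lnL + 2k(k+1)/(n-k-1) with n presences.
#' Undefined (NA) when k >= n - 1, which disqualifies the combination from
#' model selection.
#'
#' @param model A `maxent_model`.
#' @param presence_env Presence covariate matrix.
#' @return List with `aicc`, `k`, `lnL` (`aicc` is NA when undefined).
#' @export
compute_aicc <- function(model, presence_env) {
  k <- sum(model$beta != 0)
  n <- nrow(as.matrix(presence_env))
  raw <- predict(model, presence_env, transform = "raw", clamp = TRUE)
  lnL <- sum(log(raw))
  list(aicc = aicc_value(k, n, lnL), k = k, lnL = lnL)
}

#' Small-sample AIC from its components
#'
#' @param k Number of (nonzero) model parameters.
#' @param n Number of presences.
#' @param lnL Presence log-likelihood.
#' @return AICc, or NA when k >= n - 1 (correction undefined).
#' @export
aicc_value <- function(k, n, lnL) {
  if (k >= n - 1) return(NA_real_)
  2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
}

#' Partition presences for cross-validation
#'
#' Schemes: `random_split` (seeded 75/25, the test quarter forms one fold),
#' `block` (4 spatial folds split at the median longitude and latitude;
#' points on a median go to the west/south side), `jackknife` (n
#' leave-one-out folds, used when n < 25), `bootstrap_replicate`
#' (`n_replicates` with-replacement resamples; out-of-bag points are the
#' test set).
#'
#' @param occ Presence coordinates: an `occurrence_set` or data.frame with
#'   `lon`, `lat`.
#' @param scheme Partition scheme.
#' @param seed RNG seed.
#' @param train_fraction Training share for `random_split` (default 0.75).
#' @param n_replicates Bootstrap replicate count (default 10).
#' @return Object of class `presence_partition`: list of folds, each with
#'   `train` and `test` index vectors into `occ`.
#' @export
make_partition <- function(occ, scheme = c("random_split", "block",
                                           "jackknife", "bootstrap_replicate"),
                           seed = 1, train_fraction = 0.75, n_replicates = 10) {
  scheme <- match.arg(scheme)
  n <- nrow(occ)
  stopifnot(n >= 2)
  folds <- switch(scheme,
    random_split = {
      set.seed(seed)
      tr <- sort(sample.int(n, round(train_fraction * n)))
      list(list(train = tr, test = setdiff(seq_len(n), tr)))
    },
    block = {
      if (n < 4) stop("block partition needs at least 4 presences")
      mlon <- stats::median(occ$lon); mlat <- stats::median(occ$lat)
      q <- 1L + (occ$lon > mlon) + 2L * (occ$lat > mlat)
      lapply(sort(unique(q)), function(f)
        list(train = which(q != f), test = which(q == f)))
    },
    jackknife = lapply(seq_len(n), function(i)
      list(train = setdiff(seq_len(n), i), test = i)),
    bootstrap_replicate = {
      set.seed(seed)
      lapply(seq_len(n_replicates), function(r) {
        tr <- sort(sample.int(n, n, replace = TRUE))
        te <- setdiff(seq_len(n), unique(tr))
        if (!length(te)) te <- seq_len(n)
        list(train = tr, test = te)
      })
    })
  structure(list(scheme = scheme, folds = folds, n = n, seed = seed),
            class = "presence_partition")
}

#' Evaluate one model configuration under a partition
#'
#' Fits the model on each fold's training presences (full background),
#' scores held-out presences, and averages the metrics over folds with
#' equal weight. AICc comes from a full-data fit.
#'
#' @param presence_env,background_env Covariate matrices.
#' @param fc Feature-class string.
#' @param rm Regularization multiplier.
#' @param partition A `presence_partition` from [make_partition()].
#' @param ... Passed to [fit_maxent()] (e.g. `hinge_knots`).
#' @return List of class `evaluation_report`: `auc_train`, `auc_test`,
#'   `auc_diff`, `or10`, `cbi`, `aicc`, `k`, `lnL`, plus the full-data
#'   `model`.
#' @export
evaluate <- function(presence_env, background_env, fc, rm, partition, ...) {
  presence_env <- as.matrix(presence_env)
  per_fold <- lapply(partition$folds, function(f) {
    tr <- presence_env[f$train, , drop = FALSE]
    te <- presence_env[f$test, , drop = FALSE]
    fit <- fit_maxent(tr, background_env, fc = fc, rm = rm, ...)
    s_tr <- predict(fit, tr, transform = "cloglog")
    s_te <- predict(fit, te, transform = "cloglog")
    s_bg <- predict(fit, background_env, transform = "cloglog")
    c(auc_train = compute_auc(s_tr, s_bg),
      auc_test = compute_auc(s_te, s_bg),
      or10 = compute_or10(s_tr, s_te),
      cbi = tryCatch(compute_cbi(s_te, s_bg), error = function(e) NA_real_))
  })
  fm <- do.call(rbind, per_fold)
  full <- fit_maxent(presence_env, background_env, fc = fc, rm = rm, ...)
  ic <- compute_aicc(full, presence_env)
  structure(list(auc_train = mean(fm[, "auc_train"]),
                 auc_test = mean(fm[, "auc_test"]),
                 auc_diff = mean(fm[, "auc_train"] - fm[, "auc_test"]),
                 or10 = mean(fm[, "or10"]),
                 cbi = mean(fm[, "cbi"], na.rm = TRUE),
                 aicc = ic$aicc, k = ic$k, lnL = ic$lnL,
                 n_folds = length(partition$folds),
                 scheme = partition$scheme,
                 model = full),
            class = "evaluation_report")
}
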