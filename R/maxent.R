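# The presence-background maximum-entropy model: a Gibbs distribution
# exp(beta.f(x)) over background cells, fitted by maximizing the
# L1-penalized log gain with cyclic coordinate descent + soft-thresholding.

# Published per-feature-class default regularization values, interpolated
# on the number of presences m (piecewise-linear, clamped at the ends).
maxent_default_beta <- function(class, m) {
  interp <- function(sizes, betas) {
    if (m <= sizes[1]) return(betas[1])
    if (m >= sizes[length(sizes)]) return(betas[length(betas)])
    stats::approx(sizes, betas, xout = m)$y
  }
  switch(class,
         linear = ,
         quadratic = ,
         product = interp(c(0, 10, 30, 100), c(1, 1, 0.2, 0.05)),
         forward_hinge = ,
         reverse_hinge = 0.5,
         threshold = interp(c(0, 100), c(2, 1)),
         stop("unknown feature class: ", class))
}

log_mean_exp <- function(x) {
  mx <- max(x)
  mx + log(mean(exp(x - mx)))
}

#' Fit a maximum-entropy presence-background model
#'
#' Maximizes the penalized log gain
#' \deqn{G(\beta) = \overline{\beta^T f}_{presence} -
#'   \ln \overline{e^{\beta^T f}}_{background} - \sum_j \lambda_j |\beta_j|}
#' by cyclic coordinate descent with soft-thresholding and backtracking, so
#' the penalized gain is non-decreasing across iterations. The per-feature
#' penalties default to \eqn{\lambda_j = rm \cdot \beta_{class}(m) \cdot
#' s_j/\sqrt{m}} with \eqn{m} presences, \eqn{s_j} the presence standard
#' deviation of feature j (floored at the background s.d. / sqrt(m)) and
#' \eqn{\beta_{class}} the published per-class sample-size interpolation.
#'
#' @param presence_env Covariate matrix at presence cells (named columns).
#' @param background_env Covariate matrix at background cells.
#' @param features Feature set from [build_features()]; if NULL, built here
#'   from `fc`.
#' @param fc Feature-class string used when `features` is NULL.
#' @param rm Regularization multiplier (the tuning knob; larger = sparser).
#' @param lambda Optional explicit per-feature penalty vector (recycled),
#'   overriding the rm-based defaults.
#' @param max_iter Maximum number of coordinate-descent sweeps (default 1000).
#' @param tol Convergence tolerance on the penalized gain (default 1e-5).
#' @param hinge_knots,threshold_knots Passed to [build_features()].
#' @param transform Default output transform for predictions.
#' @return A `maxent_model`: features, `beta`, `log_partition` (log mean
#'   exp over training background), `entropy_H` (entropy in nats of the
#'   fitted distribution over background), `clamp_ranges`, percent
#'   `contributions` per variable, and a `trace` (penalized gain per sweep).
#' @export
fit_maxent <- function(presence_env, background_env, features = NULL,
                       fc = "LQH", rm = 1, lambda = NULL,
                       max_iter = 1000, tol = 1e-5,
                       hinge_knots = 30, threshold_knots = 30,
                       transform = "cloglog") {
  presence_env <- as.matrix(presence_env)
  background_env <- as.matrix(background_env)
  stopifnot(nrow(presence_env) >= 2, nrow(background_env) >= 2)
  if (is.null(features)) {
    features <- build_features(presence_env, background_env, fc,
                               hinge_knots = hinge_knots,
                               threshold_knots = threshold_knots)
    fc_str <- toupper(fc)
  } else {
    cls <- vapply(features, `[[`, character(1), "class")
    lk <- c(linear = "L", quadratic = "Q", product = "P",
            forward_hinge = "H", reverse_hinge = "H", threshold = "T")
    fc_str <- paste(intersect(c("L", "Q", "H", "P", "T"),
                              unique(lk[cls])), collapse = "")
  }
  Xp <- design_matrix(features, presence_env)
  Xb <- design_matrix(features, background_env)
  m <- nrow(Xp); N <- nrow(Xb); J <- ncol(Xp)
  if (is.null(lambda)) {
    s_pres <- apply(Xp, 2, stats::sd)
    s_bg <- apply(Xb, 2, stats::sd)
    s <- pmax(s_pres, s_bg / sqrt(m))
    bdef <- vapply(features, function(f) maxent_default_beta(f$class, m),
                   numeric(1))
    lambda <- rm * bdef * s / sqrt(m)
  } else {
    lambda <- rep_len(lambda, J)
  }
  pbar <- colMeans(Xp)
  beta <- numeric(J)
  eta_b <- numeric(N)
  pen_gain <- function(beta, eta_b)
    sum(beta * pbar) - log_mean_exp(eta_b) - sum(lambda * abs(beta))
  gain_now <- pen_gain(beta, eta_b)
  trace <- gain_now
  vcredit <- stats::setNames(numeric(ncol(presence_env)), colnames(presence_env))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    for (j in seq_len(J)) {
      w <- exp(eta_b - max(eta_b)); w <- w / sum(w)
      xj <- Xb[, j]
      Ef <- sum(w * xj)
      h <- max(sum(w * xj^2) - Ef^2, 1e-12)
      g <- pbar[j] - Ef
      z <- beta[j] + g / h
      bnew <- sign(z) * max(abs(z) - lambda[j] / h, 0)
      d <- bnew - beta[j]
      if (d == 0) next
      # backtracking: the quadratic model can overshoot for log-partition
      repeat {
        cand_eta <- eta_b + d * xj
        cand_beta <- beta; cand_beta[j] <- beta[j] + d
        cand_gain <- pen_gain(cand_beta, cand_eta)
        if (cand_gain >= gain_now - 1e-12 || abs(d) < 1e-12) break
        d <- d / 2
      }
      if (cand_gain > gain_now) {
        inc <- cand_gain - gain_now
        fv <- features[[j]]$vars
        vcredit[fv] <- vcredit[fv] + inc / length(fv)
        beta <- cand_beta; eta_b <- cand_eta; gain_now <- cand_gain
      }
    }
    trace <- c(trace, gain_now)
    if (gain_now - trace[length(trace) - 1L] < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    if (max(abs(beta)) > 30)
      warning("fit did not converge; possible separation (unbounded gain)")
    else
      warning("fit reached max_iter without meeting tolerance")
  }
  lz <- log_mean_exp(eta_b)
  p <- exp(eta_b - lz) / N            # raw distribution over background
  H <- -sum(p * log(p))
  contributions <-
    if (sum(vcredit) > 0) 100 * vcredit / sum(vcredit)
    else stats::setNames(rep(100 / length(vcredit), length(vcredit)),
                         names(vcredit))
  comb <- rbind(presence_env, background_env)
  clamp_ranges <- rbind(min = apply(comb, 2, min), max = apply(comb, 2, max))
  structure(list(features = features, beta = stats::setNames(beta, names(features)),
                 log_partition = lz, entropy_H = H, rm = rm,
                 fc = fc_str,
                 n_background = N, n_presence = m,
                 lambda = stats::setNames(lambda, names(features)),
                 clamp_ranges = clamp_ranges,
                 presence_means = colMeans(presence_env),
                 contributions = contributions,
                 transform = transform,
                 trace = trace, converged = converged),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("maxent_model: %d features (%d nonzero), rm = %g, H = %.4f nats\n",
              length(x$beta), sum(x$beta != 0), x$rm, x$entropy_H))
  invisible(x)
}

#' Training gain of a fitted model
#'
#' The unpenalized log gain at the fitted coefficients, evaluated on an
#' arbitrary presence sample against the model's feature space and a
#' background sample (training gain when called with the training data,
#' test gain with held-out presences). The null model has gain 0.
#'
#' @param model A `maxent_model`.
#' @param presence_env Presence covariate matrix.
#' @param background_env Background covariate matrix.
#' @return Scalar gain in nats.
#' @export
model_gain <- function(model, presence_env, background_env) {
  ep <- design_matrix(model$features, as.matrix(presence_env)) %*% model$beta
  eb <- design_matrix(model$features, as.matrix(background_env)) %*% model$beta
  mean(ep) - log_mean_exp(as.numeric(eb))
}

clamp_env <- function(env, ranges) {
  for (v in colnames(env)) {
    if (v %in% colnames(ranges)) {
      env[, v] <- pmin(pmax(env[, v], ranges["min", v]), ranges["max", v])
    }
  }
  env
}

#' Predict habitat suitability
#'
#' Applies the fitted Gibbs model to new covariates. `raw` is the density
#' normalized by the training background partition (training raws sum to 1);
#' `cloglog` (default) and `logistic` squash the raw density into [0, 1]
#' suitability using the fitted distribution's entropy H:
#' cloglog = 1 - exp(-e^H raw), logistic = e^H raw / (1 + e^H raw).
#'
#' @param object A `maxent_model`.
#' @param newdata Covariate matrix or an [env_stack()].
#' @param transform One of "raw", "cloglog", "logistic".
#' @param clamp Truncate covariates to their training ranges first
#'   (default TRUE).
#' @param ... Unused.
#' @return Numeric vector (matrix input) or suitability [env_raster()]
#'   (stack input) with nodata propagated.
#' @export
predict.maxent_model <- function(object, newdata,
                                 transform = object$transform,
                                 clamp = TRUE, ...) {
  transform <- match.arg(transform, c("raw", "cloglog", "logistic"))
  if (inherits(newdata, "env_stack")) {
    cells <- valid_cells(newdata)
    env <- extract_env(newdata, cells, feature_variables(object$features))
    v <- predict(object, env, transform = transform, clamp = clamp)
    out <- matrix(NA_real_, newdata$grid$n_rows, newdata$grid$n_cols)
    out[cells] <- v
    return(env_raster(newdata$grid, out))
  }
  env <- as.matrix(newdata)
  miss <- setdiff(feature_variables(object$features), colnames(env))
  if (length(miss)) stop("missing variable(s): ", paste(miss, collapse = ", "))
  if (clamp) env <- clamp_env(env, object$clamp_ranges)
  eta <- as.numeric(design_matrix(object$features, env) %*% object$beta)
  raw <- exp(eta - object$log_partition) / object$n_background
  switch(transform,
         raw = raw,
         cloglog = 1 - exp(-exp(object$entropy_H) * raw),
         logistic = {
           q <- exp(object$entropy_H) * raw
           q / (1 + q)
         })
}

#' Response curve of one variable
#'
#' Sweeps a variable across its training range while holding all other
#' variables at their presence-sample means, and returns the transformed
#' prediction — the standard marginal response plot.
#'
#' @param model A `maxent_model`.
#' @param variable Variable name (must be used by the model).
#' @param n_points Number of sweep points (default 100).
#' @param transform Output transform (default the model's).
#' @return data.frame with columns `value` and `prediction`.
#' @export
response_curve <- function(model, variable, n_points = 100,
                           transform = model$transform) {
  used <- feature_variables(model$features)
  if (!variable %in% used) stop("variable '", variable, "' not used by model")
  rng <- model$clamp_ranges[, variable]
  vals <- seq(rng["min"], rng["max"], length.out = n_points)
  env <- matrix(rep(model$presence_means[used], each = n_points),
                nrow = n_points, dimnames = list(NULL, used))
  env[, variable] <- vals
  data.frame(value = vals,
             prediction = predict(model, env, transform = transform,
                                  clamp = TRUE))
}

#' Jackknife test of variable importance
#'
#' For each variable, refits the model (i) with only that variable and
#' (ii) with all variables except it, reporting the training gain
#' (unpenalized gain at the fitted coefficients), the test gain on held-out
#' presences, and the held-out AUC of the only-variable model, alongside the
#' all-variables model's gains.
#'
#' @param presence_env,background_env Covariate matrices.
#' @param fc Feature-class string.
#' @param rm Regularization multiplier.
#' @param train_idx Indices of training presences; the rest are the test
#'   split. Default: seeded 75% sample.
#' @param seed RNG seed for the default split.
#' @param ... Passed to [fit_maxent()].
#' @return List with `table` (one row per variable) and `all_variables`
#'   (gains of the full model).
#' @export
jackknife_importance <- function(presence_env, background_env, fc = "LQH",
                                 rm = 1, train_idx = NULL, seed = 1, ...) {
  presence_env <- as.matrix(presence_env)
  vars <- colnames(presence_env)
  stopifnot(length(vars) >= 2)
  n <- nrow(presence_env)
  if (is.null(train_idx)) {
    set.seed(seed)
    train_idx <- sort(sample.int(n, max(2, round(0.75 * n))))
  }
  test_idx <- setdiff(seq_len(n), train_idx)
  if (!length(test_idx)) test_idx <- train_idx
  tr <- presence_env[train_idx, , drop = FALSE]
  te <- presence_env[test_idx, , drop = FALSE]
  fit_on <- function(v) fit_maxent(tr[, v, drop = FALSE],
                                   background_env[, v, drop = FALSE],
                                   fc = fc, rm = rm, ...)
  full <- fit_on(vars)
  rows <- lapply(vars, function(v) {
    only <- fit_on(v)
    without <- fit_on(setdiff(vars, v))
    sc_p <- predict(only, te[, v, drop = FALSE], transform = "raw")
    sc_b <- predict(only, background_env[, v, drop = FALSE], transform = "raw")
    data.frame(variable = v,
               gain_with_only = model_gain(only, tr[, v, drop = FALSE],
                                           background_env[, v, drop = FALSE]),
               test_gain_with_only = model_gain(only, te[, v, drop = FALSE],
                                                background_env[, v, drop = FALSE]),
               gain_without = model_gain(without,
                                         tr[, setdiff(vars, v), drop = FALSE],
                                         background_env[, setdiff(vars, v), drop = FALSE]),
               auc_with_only = compute_auc(sc_p, sc_b))
  })
  list(table = do.call(rbind, rows),
       all_variables = data.frame(
         gain = model_gain(full, tr, background_env),
         test_gain = model_gain(full, te, background_env)))
}

## ---- serialization -----------------------------------------------------

#' Serialize a model to JSON
#' @param model A `maxent_model`.
#' @param path Optional file path; if NULL the JSON string is returned.
#' @return Path (invisibly) or JSON string.
#' @export
maxent_to_json <- function(model, path = NULL) {
  doc <- list(
    features = lapply(model$features, function(f)
      list(class = f$class, vars = f$vars, knot = f$knot,
           scale_min = f$scale_min, scale_max = f$scale_max)),
    beta = as.list(model$beta),
    log_partition = model$log_partition, entropy_H = model$entropy_H,
    rm = model$rm, fc = model$fc,
    n_background = model$n_background, n_presence = model$n_presence,
    clamp_ranges = list(min = as.list(model$clamp_ranges["min", ]),
                        max = as.list(model$clamp_ranges["max", ])),
    presence_means = as.list(model$presence_means),
    contributions = as.list(model$contributions),
    transform = model$transform)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Load a model from JSON
#' @param path File path or JSON string from [maxent_to_json()].
#' @return A `maxent_model`.
#' @export
maxent_from_json <- function(path) {
  txt <- if (file.exists(path)) paste(readLines(path), collapse = "\n") else path
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  feats <- lapply(doc$features, function(f)
    new_feature(f$class, unlist(f$vars), if (is.null(f$knot)) NA_real_ else f$knot,
                f$scale_min, f$scale_max))
  names(feats) <- vapply(feats, feature_label, character(1))
  class(feats) <- "maxent_features"
  vars <- names(doc$presence_means)
  cr <- rbind(min = unlist(doc$clamp_ranges$min)[vars],
              max = unlist(doc$clamp_ranges$max)[vars])
  colnames(cr) <- vars
  structure(list(features = feats,
                 beta = unlist(doc$beta),
                 log_partition = doc$log_partition, entropy_H = doc$entropy_H,
                 rm = doc$rm, fc = doc$fc,
                 n_background = doc$n_background, n_presence = doc$n_presence,
                 clamp_ranges = cr,
                 presence_means = unlist(doc$presence_means),
                 contributions = unlist(doc$contributions),
                 transform = doc$transform,
                 trace = NULL, converged = NA),
            class = "maxent_model")
}
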