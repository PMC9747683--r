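# Feature expansion for the maximum-entropy model. Each feature maps raw
# covariate values to [0, 1] using scaling bounds frozen at training time,
# so projection onto new climates is well-defined (with optional clamping).

FEATURE_CLASSES <- c("linear", "quadratic", "product",
                     "forward_hinge", "reverse_hinge", "threshold")

new_feature <- function(class, vars, knot = NA_real_, scale_min, scale_max) {
  stopifnot(class %in% FEATURE_CLASSES)
  list(class = class, vars = vars, knot = knot,
       scale_min = scale_min, scale_max = scale_max)
}

feature_label <- function(f) {
  base <- paste(f$vars, collapse = "*")
  switch(f$class,
         linear = base,
         quadratic = paste0(base, "^2"),
         product = base,
         forward_hinge = sprintf("h+(%s@%.4g)", base, f$knot),
         reverse_hinge = sprintf("h-(%s@%.4g)", base, f$knot),
         threshold = sprintf("t(%s@%.4g)", base, f$knot))
}

# raw (unscaled) feature value from a covariate matrix
feature_raw <- function(f, env) {
  x <- env[, f$vars[1]]
  switch(f$class,
         linear = x,
         quadratic = x^2,
         product = x * env[, f$vars[2]],
         forward_hinge = pmax(0, (x - f$knot) / (f$scale_max - f$knot)),
         reverse_hinge = pmax(0, (f$knot - x) / (f$knot - f$scale_min)),
         threshold = as.numeric(x > f$knot))
}

feature_value <- function(f, env) {
  v <- feature_raw(f, env)
  if (f$class %in% c("linear", "quadratic", "product")) {
    rng <- f$scale_max - f$scale_min
    if (rng <= 0) rng <- 1
    v <- (v - f$scale_min) / rng
  }
  v
}

#' Build the feature set for a feature-class combination
#'
#' Expands raw covariates into the model's feature space. Classes follow the
#' standard single-letter notation: L linear, Q quadratic, H hinge (forward
#' and reverse piecewise ramps at empirical background quantile knots),
#' P product (all distinct variable pairs), T threshold (step indicators at
#' the same quantile knots). Linear/quadratic/product features are min-max
#' scaled to [0, 1] with bounds taken from the combined presence +
#' background sample; hinge and threshold features are [0, 1] by
#' construction. Features constant over the combined sample are dropped.
#'
#' @param presence_env Matrix of covariates at presence cells (named cols).
#' @param background_env Matrix of covariates at background cells.
#' @param fc Feature-class string, e.g. "LQH" (subset of "LQHPT").
#' @param hinge_knots Knots per direction per variable (default 30).
#' @param threshold_knots Threshold knots per variable (default 30).
#' @return List of feature definitions (class `maxent_features`).
#' @export
build_features <- function(presence_env, background_env, fc = "LQH",
                           hinge_knots = 30, threshold_knots = 30) {
  letters_fc <- strsplit(toupper(fc), "")[[1]]
  unknown <- setdiff(letters_fc, c("L", "Q", "H", "P", "T"))
  if (length(unknown))
    stop("unknown feature class letter(s): ", paste(unknown, collapse = ", "))
  if (!length(letters_fc)) stop("fc must be a nonempty subset of LQHPT")
  stopifnot(nrow(background_env) >= 2)
  vars <- colnames(presence_env)
  stopifnot(!is.null(vars), identical(vars, colnames(background_env)))
  comb <- rbind(presence_env, background_env)
  feats <- list()
  add <- function(f) feats[[length(feats) + 1L]] <<- f
  for (v in vars) {
    x <- comb[, v]
    lo <- min(x); hi <- max(x)
    if ("L" %in% letters_fc) add(new_feature("linear", v, NA, lo, hi))
    if ("Q" %in% letters_fc) add(new_feature("quadratic", v, NA, min(x^2), max(x^2)))
    if (any(c("H", "T") %in% letters_fc)) {
      bg <- background_env[, v]
      if ("H" %in% letters_fc) {
        ks <- unique(stats::quantile(bg, probs = seq_len(hinge_knots) /
                                       (hinge_knots + 1), names = FALSE))
        for (k in ks) {
          if (k < hi) add(new_feature("forward_hinge", v, k, lo, hi))
          if (k > lo) add(new_feature("reverse_hinge", v, k, lo, hi))
        }
      }
      if ("T" %in% letters_fc) {
        ks <- unique(stats::quantile(bg, probs = seq_len(threshold_knots) /
                                       (threshold_knots + 1), names = FALSE))
        for (k in ks) add(new_feature("threshold", v, k, lo, hi))
      }
    }
  }
  if ("P" %in% letters_fc && length(vars) >= 2) {
    for (i in seq_len(length(vars) - 1)) for (j in (i + 1):length(vars)) {
      pr <- comb[, vars[i]] * comb[, vars[j]]
      add(new_feature("product", c(vars[i], vars[j]), NA, min(pr), max(pr)))
    }
  }
  # drop features constant over the combined sample
  keep <- vapply(feats, function(f) {
    v <- feature_value(f, comb)
    max(v) - min(v) > 0
  }, logical(1))
  feats <- feats[keep]
  names(feats) <- vapply(feats, feature_label, character(1))
  structure(feats, class = "maxent_features")
}

#' Evaluate features into a design matrix
#' @param features A `maxent_features` list from [build_features()].
#' @param env Covariate matrix (named columns covering all used variables).
#' @return Numeric matrix, one column per feature.
#' @export
design_matrix <- function(features, env) {
  used <- unique(unlist(lapply(features, `[[`, "vars")))
  miss <- setdiff(used, colnames(env))
  if (length(miss)) stop("missing variable(s): ", paste(miss, collapse = ", "))
  X <- vapply(features, feature_value, numeric(nrow(env)), env = env)
  matrix(X, nrow = nrow(env), dimnames = list(NULL, names(features)))
}

feature_variables <- function(features)
  unique(unlist(lapply(features, `[[`, "vars")))
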