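# Synthetic study system: smooth correlated "bioclim-like" environmental
# stacks, a known truth model, presence-only samples from it, and
# period/GCM scenario variants — the statistical structure the analysis
# assumes, at desk scale, with no downloads.

# smooth low-frequency random surface: sum of Gaussian bumps on the unit
# square, evaluated at cell centers
bump_field <- function(n_rows, n_cols, n_bumps = 25) {
  gx <- (seq_len(n_cols) - 0.5) / n_cols
  gy <- (seq_len(n_rows) - 0.5) / n_rows
  f <- matrix(0, n_rows, n_cols)
  cx <- stats::runif(n_bumps); cy <- stats::runif(n_bumps)
  amp <- stats::rnorm(n_bumps)
  sig <- stats::runif(n_bumps, 0.08, 0.3)
  X <- outer(rep(1, n_rows), gx); Y <- outer(gy, rep(1, n_cols))
  for (k in seq_len(n_bumps))
    f <- f + amp[k] * exp(-((X - cx[k])^2 + (Y - cy[k])^2) / (2 * sig[k]^2))
  f
}

# bioclim-flavoured location/scale per layer index, so synthetic layers
# live on plausible ranges (degC, seasonality, mm ...)
synth_layer_scale <- function(i) {
  presets <- list(c(15, 6), c(9, 2.5), c(40, 10), c(600, 150),
                  c(1200, 500), c(50, 30))
  presets[[(i - 1) %% length(presets) + 1]]
}

#' Generate a correlated synthetic environmental stack
#'
#' Builds `n_layers` smooth spatial fields (sums of seeded Gaussian bumps),
#' empirically whitens them and mixes with the Cholesky factor of the
#' target correlation matrix, so the cross-layer sample correlation matches
#' the target; each layer is then placed on a bioclim-plausible
#' location/scale. An `elevation` layer (0-3000 m) is appended for terrain
#' operations. Deterministic given the seed.
#'
#' @param grid A [grid_spec()].
#' @param n_layers Number of bioclim-like layers (named `Bio1`...).
#' @param correlation_target Scalar (equicorrelation) or an
#'   `n_layers` x `n_layers` positive-definite correlation matrix.
#' @param seed RNG seed.
#' @param n_bumps Gaussian bumps per field (default 25; more bumps = more
#'   effective degrees of freedom per field).
#' @return An [env_stack()] with layers `Bio1..Bio<n>` and `elevation`.
#' @export
make_env_stack <- function(grid, n_layers = 6, correlation_target = 0,
                           seed = 1, n_bumps = 25) {
  set.seed(seed)
  if (length(correlation_target) == 1) {
    C <- matrix(correlation_target, n_layers, n_layers)
    diag(C) <- 1
  } else {
    C <- as.matrix(correlation_target)
    stopifnot(all(dim(C) == n_layers))
  }
  L <- tryCatch(chol(C), error = function(e)
    stop("correlation target is not positive definite"))
  nc_cells <- grid$n_rows * grid$n_cols
  raw <- vapply(seq_len(n_layers),
                function(i) as.numeric(bump_field(grid$n_rows, grid$n_cols,
                                                  n_bumps)),
                numeric(nc_cells))
  raw <- scale(raw)  # center/unit variance per field
  # empirical whitening, then impose the target correlation exactly
  W <- chol(stats::cov(raw))
  mixed <- raw %*% backsolve(W, diag(n_layers)) %*% L
  layers <- lapply(seq_len(n_layers), function(i) {
    ls <- synth_layer_scale(i)
    matrix(ls[1] + ls[2] * mixed[, i], grid$n_rows, grid$n_cols)
  })
  names(layers) <- paste0("Bio", seq_len(n_layers))
  elev <- bump_field(grid$n_rows, grid$n_cols, n_bumps)
  elev <- (elev - min(elev)) / (max(elev) - min(elev)) * 3000
  layers$elevation <- elev
  env_stack(grid, layers, period = "current", gcm = "none", scenario = "none")
}

#' Define a known truth model over a stack
#'
#' The true suitability is a cloglog-style squash of a linear predictor in
#' standardized layers, rescaled to [0, 1]; the generating coefficients are
#' kept so parameter-recovery tests can compare fitted and true surfaces.
#'
#' Forms: `linear` (eta = sum c_i z_i), `linear+quadratic` (each informative
#' variable contributes c_i z_i - q_i (z_i - o_i)^2, giving an interior
#' optimum), `hinge` (c_i max(0, z_i - o_i)).
#'
#' @param stack An [env_stack()].
#' @param form Response form.
#' @param vars Informative layer names (default the first two bioclim
#'   layers).
#' @param coef Linear coefficients, one per informative variable
#'   (default 2).
#' @param quad Quadratic curvatures (linear+quadratic form; default 1.5).
#' @param optimum Optima on the standardized scale (default 0.5).
#' @return List of class `synthetic_truth`: `suitability` raster in [0, 1],
#'   `vars`, coefficients, and the standardization constants.
#' @export
make_truth <- function(stack, form = c("linear+quadratic", "linear", "hinge"),
                       vars = names(stack$layers)[1:2],
                       coef = rep(2, length(vars)),
                       quad = rep(1.5, length(vars)),
                       optimum = rep(0.5, length(vars))) {
  form <- match.arg(form)
  miss <- setdiff(vars, names(stack$layers))
  if (length(miss)) stop("unknown variable(s): ", paste(miss, collapse = ", "))
  cells <- valid_cells(stack)
  env <- extract_env(stack, cells, vars)
  mu <- colMeans(env); sdev <- apply(env, 2, stats::sd)
  z <- sweep(sweep(env, 2, mu), 2, sdev, "/")
  eta <- numeric(length(cells))
  for (i in seq_along(vars)) {
    eta <- eta + switch(form,
      linear = coef[i] * z[, i],
      `linear+quadratic` = coef[i] * z[, i] - quad[i] * (z[, i] - optimum[i])^2,
      hinge = coef[i] * pmax(0, z[, i] - optimum[i]))
  }
  s <- 1 - exp(-exp(eta - max(eta) + 1))  # bounded squash, peak near 1-e^-e
  s <- (s - min(s)) / (max(s) - min(s))
  vals <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
  vals[cells] <- s
  structure(list(suitability = env_raster(stack$grid, vals),
                 form = form, vars = vars, coef = coef, quad = quad,
                 optimum = optimum, center = mu, scale = sdev),
            class = "synthetic_truth")
}

#' Sample presence records from a truth surface
#'
#' Cells are drawn with replacement with probability proportional to true
#' suitability times spherical cell area; one record is emitted at each
#' drawn cell's center (duplicates collapse under grid thinning, as with
#' real herbarium records).
#'
#' @param truth A `synthetic_truth`.
#' @param n Number of records (>= 1).
#' @param seed RNG seed.
#' @param species Species label for the records.
#' @return An `occurrence_set`.
#' @export
sample_presences <- function(truth, n, seed = 1, species = "Synthspora demo") {
  stopifnot(n >= 1)
  g <- truth$suitability$grid
  v <- truth$suitability$values
  idx <- which(!is.na(v))
  w <- v[idx] * area_matrix(g)[idx]
  if (sum(w) <= 0) stop("all-zero suitability surface")
  set.seed(seed)
  draw <- sample(idx, n, replace = TRUE, prob = w)
  rc <- arrayInd(draw, c(g$n_rows, g$n_cols))
  ctr <- cell_center(g, rc[, 1], rc[, 2])
  occurrence_set(data.frame(species = species, lon = ctr$lon, lat = ctr$lat,
                            source = "synthetic"))
}

#' Generate period / climate-model variants of a stack
#'
#' Emulates paleo and future climate stacks: each period applies a
#' deterministic per-layer offset (e.g. a glacial cooling), and each GCM
#' within a period adds a seeded smooth noise field of standard deviation
#' `noise_sd`, mimicking between-model disagreement.
#'
#' @param stack Baseline [env_stack()].
#' @param periods Named list: period label -> named numeric vector of
#'   per-layer offsets (missing layers shift 0).
#' @param n_gcms Number of GCM variants per period.
#' @param noise_sd Standard deviation of the GCM noise fields.
#' @param seed RNG seed.
#' @return Flat list of [env_stack()]s with period/gcm labels.
#' @export
make_scenario_series <- function(stack, periods, n_gcms = 3, noise_sd = 0.5,
                                 seed = 1) {
  stopifnot(length(periods) >= 1, n_gcms >= 1)
  out <- list()
  for (p in names(periods)) {
    shift <- periods[[p]]
    for (g in seq_len(n_gcms)) {
      set.seed(derive_seed(seed, "scenario", p, g))
      layers <- stack$layers
      for (nm in names(layers)) {
        sh <- if (nm %in% names(shift)) shift[[nm]] else 0
        noise <- if (noise_sd > 0)
          noise_sd * bump_field(stack$grid$n_rows, stack$grid$n_cols, 15)
        else 0
        layers[[nm]] <- layers[[nm]] + sh + noise
      }
      out[[paste(p, paste0("gcm", g), sep = ":")]] <-
        env_stack(stack$grid, layers, period = p, gcm = paste0("gcm", g),
                  scenario = stack$scenario)
    }
  }
  out
}

# deterministic sub-seed from a master seed and string labels (kept < 2^31)
derive_seed <- function(master, ...) {
  key <- paste(c(master, ...), collapse = ":")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}
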