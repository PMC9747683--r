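# Shared fixtures and independent oracles, built in code at test time.

toy_grid <- function(n_rows = 20, n_cols = 20, cell_size = 2.5,
                     west = 100, north = 25)
  grid_spec(west, north, cell_size, n_rows, n_cols)

# deterministic small stack for fitting tests
toy_stack <- function(seed = 7, n_layers = 4, n = 30, corr = 0)
  make_env_stack(toy_grid(n, n), n_layers = n_layers,
                 correlation_target = corr, seed = seed)

# the 4-cell single-linear-feature instance with a closed-form optimum
four_cell_instance <- function() {
  list(presence = matrix(c(1, 1), ncol = 1, dimnames = list(NULL, "x")),
       background = matrix(c(1, 1, 0, 0), ncol = 1,
                           dimnames = list(NULL, "x")))
}

# independent oracle: penalized gain of a fitted coefficient vector on
# given design matrices (no reuse of the package's fitting path)
oracle_pen_gain <- function(beta, Xp, Xb, lambda) {
  etab <- as.numeric(Xb %*% beta)
  mean(Xp %*% beta) - (max(etab) + log(mean(exp(etab - max(etab))))) -
    sum(lambda * abs(beta))
}

# dense grid-search maximizer of the penalized gain, refined to ~1e-4
oracle_grid_search <- function(Xp, Xb, lambda, lim = 5) {
  J <- ncol(Xp)
  center <- rep(0, J); width <- lim
  for (round in 1:8) {
    axes <- lapply(seq_len(J), function(j)
      seq(center[j] - width, center[j] + width, length.out = 21))
    grid <- as.matrix(expand.grid(axes))
    vals <- apply(grid, 1, oracle_pen_gain, Xp = Xp, Xb = Xb, lambda = lambda)
    center <- grid[which.max(vals), ]
    width <- width / 5
  }
  center
}

# brute-force AUC by pairwise concordance
brute_auc <- function(p, b) {
  s <- 0
  for (x in p) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(p) * length(b))
}

# analytic spherical band area for one cell (degrees in, km^2 out)
analytic_cell_area <- function(lat_top_deg, lat_bot_deg, dlon_deg) {
  R <- 6371
  R^2 * (dlon_deg * pi / 180) *
    (sin(lat_top_deg * pi / 180) - sin(lat_bot_deg * pi / 180))
}

random_binary_pair <- function(grid, seed) {
  set.seed(seed)
  a <- matrix(rbinom(grid$n_rows * grid$n_cols, 1, 0.4),
              grid$n_rows, grid$n_cols)
  b <- matrix(rbinom(grid$n_rows * grid$n_cols, 1, 0.4),
              grid$n_rows, grid$n_cols)
  na <- sample(length(a), round(0.05 * length(a)))
  a[na] <- NA; b[na] <- NA
  mk <- function(m) {
    r <- env_raster(grid, m)
    attr(r, "threshold") <- 0.5
    class(r) <- c("binary_map", class(r))
    r
  }
  list(before = mk(a), after = mk(b))
}

# recovery fixture shared by maxent tests and the acceptance suite
recovery_fixture <- function(seed, n_rows = 100, n_presence = 200,
                             n_background = 2000, n_layers = 6) {
  g <- grid_spec(98, 30, 2.5, n_rows, n_rows)
  st <- make_env_stack(g, n_layers = n_layers, correlation_target = 0,
                       seed = seed)
  tr <- make_truth(st, "linear+quadratic", vars = c("Bio1", "Bio2"))
  occ <- sample_presences(tr, n_presence, seed = seed + 1000)
  bio <- paste0("Bio", seq_len(n_layers))
  pe <- extract_env(st, cell_index(g, occ$lon, occ$lat)$cell, bio)
  bg <- sample_background(st, n_background, seed = seed + 2000)
  be <- extract_env(st, bg, bio)
  list(grid = g, stack = st, truth = tr, presence_env = pe,
       background_env = be, bg_cells = bg)
}
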