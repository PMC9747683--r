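test_that("stack generation is seed-deterministic and hits correlation targets", {
  g <- grid_spec(98, 30, 2.5, 40, 40)
  s1 <- make_env_stack(g, n_layers = 4, correlation_target = 0.5, seed = 3)
  s2 <- make_env_stack(g, n_layers = 4, correlation_target = 0.5, seed = 3)
  expect_identical(s1$layers, s2$layers)
  s3 <- make_env_stack(g, n_layers = 4, correlation_target = 0.5, seed = 4)
  expect_false(identical(s1$layers$Bio1, s3$layers$Bio1))
  # empirical correlation of the designated pair inside the stated band
  cm <- correlation_matrix(s1)[paste0("Bio", 1:4), paste0("Bio", 1:4)]
  expect_true(all(cm[upper.tri(cm)] > 0.4 & cm[upper.tri(cm)] < 0.6))
  C <- diag(4); C[1, 2] <- C[2, 1] <- 0.9
  s4 <- make_env_stack(g, n_layers = 4, correlation_target = C, seed = 5)
  r <- correlation_matrix(s4)["Bio1", "Bio2"]
  expect_true(r >= 0.8 && r <= 0.97)
  # independent target: near-zero empirical correlation
  s5 <- make_env_stack(g, n_layers = 4, correlation_target = 0, seed = 6)
  cm5 <- correlation_matrix(s5)[paste0("Bio", 1:4), paste0("Bio", 1:4)]
  expect_lt(max(abs(cm5[upper.tri(cm5)])), 0.1)
  # infeasible target rejected
  Cbad <- matrix(0.99, 3, 3) * (1 - diag(3)) * -1 + diag(3)
  expect_error(make_env_stack(g, n_layers = 3, correlation_target = Cbad),
               "positive definite")
  expect_true("elevation" %in% names(s1$layers))
})

test_that("truth surfaces follow the generating form", {
  st <- toy_stack(seed = 2, n_layers = 3, n = 40)
  # zero coefficients: constant suitability is rejected by rescaling;
  # use the linear form to check monotonicity instead
  tr_lin <- make_truth(st, "linear", vars = "Bio1", coef = 2)
  cells <- valid_cells(st)
  x <- st$layers$Bio1[cells]
  s <- tr_lin$suitability$values[cells]
  expect_gt(cor(x, s, method = "spearman"), 0.999)
  expect_true(all(s >= 0 & s <= 1))
  # quadratic form: 1-D response peaks at the stated optimum
  tr_q <- make_truth(st, "linear+quadratic", vars = "Bio1", coef = 0,
                     quad = 2, optimum = 0.5)
  z <- (x - tr_q$center) / tr_q$scale
  peak_z <- z[which.max(tr_q$suitability$values[cells])]
  dz <- stats::median(abs(diff(sort(z))))  # grid resolution on z scale
  expect_lt(abs(peak_z - 0.5), max(10 * dz, 0.05))
  expect_error(make_truth(st, vars = "Bio99"), "Bio99")
})

test_that("presence sampling is proportional, seeded and collapses degenerately", {
  st <- toy_stack(seed = 12, n_layers = 2, n = 20)
  tr <- make_truth(st, "linear", vars = "Bio1")
  o1 <- sample_presences(tr, 50, seed = 5)
  o2 <- sample_presences(tr, 50, seed = 5)
  expect_identical(o1, o2)
  # truth concentrated on one cell puts every record there
  v <- matrix(0, 20, 20); v[7, 9] <- 1
  conc <- tr; conc$suitability <- env_raster(st$grid, v)
  oc <- sample_presences(conc, 25, seed = 1)
  expect_equal(nrow(unique(oc[, c("lon", "lat")])), 1)
  expect_equal(cell_index(st$grid, oc$lon[1], oc$lat[1])$row, 7)
  # all-zero truth errors
  zero <- tr; zero$suitability <- env_raster(st$grid, matrix(0, 20, 20))
  expect_error(sample_presences(zero, 5), "all-zero")
  # uniform truth: chi-square goodness of fit does not reject uniformity
  unif <- tr; unif$suitability <- env_raster(st$grid, matrix(1, 20, 20))
  ou <- sample_presences(unif, 10000, seed = 3)
  cells <- cell_index(st$grid, ou$lon, ou$lat)$cell
  counts <- tabulate(cells, nbins = 400)
  exp_p <- as.numeric(area_matrix(st$grid)) / sum(area_matrix(st$grid))
  pval <- suppressWarnings(stats::chisq.test(counts, p = exp_p)$p.value)
  expect_gt(pval, 0.001)
})

test_that("scenario series applies shifts and seeded GCM noise", {
  st <- toy_stack(seed = 8, n_layers = 2, n = 15)
  # zero shift, zero noise: identical stacks back
  s0 <- make_scenario_series(st, list(p1 = list()), n_gcms = 2, noise_sd = 0)
  expect_equal(s0[["p1:gcm1"]]$layers, st$layers)
  # a -2 shift moves the layer mean by -2
  s1 <- make_scenario_series(st, list(lgm = list(Bio1 = -2)), n_gcms = 1,
                             noise_sd = 0)
  expect_equal(mean(s1[["lgm:gcm1"]]$layers$Bio1),
               mean(st$layers$Bio1) - 2, tolerance = 1e-9)
  # GCM ensemble mean approaches the shifted stack as noise vanishes
  for (sd_ in c(0.5, 0.05)) {
    ss <- make_scenario_series(st, list(lgm = list(Bio1 = -2)), n_gcms = 4,
                               noise_sd = sd_, seed = 2)
    em <- ensemble_mean(lapply(ss, function(s) stack_layer(s, "Bio1")))
    dev <- max(abs(em$values - (st$layers$Bio1 - 2)))
    if (sd_ == 0.05) expect_lt(dev, 0.2)
  }
  # determinism
  a <- make_scenario_series(st, list(lgm = list(Bio1 = -2)), 2, 0.3, seed = 9)
  b <- make_scenario_series(st, list(lgm = list(Bio1 = -2)), 2, 0.3, seed = 9)
  expect_identical(a, b)
})

test_that("a period shift moves the predicted centroid along the gradient", {
  # sign test over seeds: cooling the optimal layer pushes the suitable
  # range toward cells whose layer value compensates the shift
  agree <- 0L; n_seeds <- 6L
  for (s in seq_len(n_seeds)) {
    fx <- recovery_fixture(200 + s, n_rows = 40, n_presence = 60,
                           n_background = 400, n_layers = 2)
    fit <- fit_maxent(fx$presence_env, fx$background_env, fc = "LQ", rm = 1)
    shift <- -1 * stats::sd(fx$stack$layers$Bio1)
    shifted <- make_scenario_series(fx$stack, list(sh = list(Bio1 = shift)),
                                    n_gcms = 1, noise_sd = 0)[[1]]
    s_now <- predict(fit, fx$stack)
    s_sh <- predict(fit, shifted)
    b_now <- to_binary(s_now, 0.3); b_sh <- to_binary(s_sh, 0.3)
    if (sum(b_now$values, na.rm = TRUE) == 0 ||
        sum(b_sh$values, na.rm = TRUE) == 0) next
    c_now <- centroid(b_now); c_sh <- centroid(b_sh)
    # correlation of Bio1 with the movement direction: the new centroid
    # should sit at cells with higher Bio1 (compensating the cooling)
    v_now <- fx$stack$layers$Bio1[cell_index(fx$grid, c_now$lon, c_now$lat)$cell]
    v_sh <- fx$stack$layers$Bio1[cell_index(fx$grid, c_sh$lon, c_sh$lat)$cell]
    agree <- agree + (v_sh >= v_now)
  }
  expect_gte(agree, ceiling(n_seeds * 0.6))
})
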