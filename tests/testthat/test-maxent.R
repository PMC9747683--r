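test_that("the 4-cell instance matches its closed form and the grid oracle", {
  inst <- four_cell_instance()
  fit <- fit_maxent(inst$presence, inst$background, fc = "L", lambda = 0.25)
  expect_equal(unname(fit$beta), log(3), tolerance = 1e-3)
  raw <- predict(fit, inst$background, transform = "raw")
  expect_equal(raw, c(3, 3, 1, 1) / 8, tolerance = 1e-3)
  # independent oracle: dense grid search on the penalized gain
  f <- fit$features
  oracle <- oracle_grid_search(design_matrix(f, inst$presence),
                               design_matrix(f, inst$background), 0.25)
  expect_equal(unname(fit$beta), unname(oracle), tolerance = 1e-3)
  # subgradient condition at zero: lambda >= gradient magnitude keeps beta 0
  fit0 <- fit_maxent(inst$presence, inst$background, fc = "L", lambda = 0.5)
  expect_identical(unname(fit0$beta), 0)
  fit0b <- fit_maxent(inst$presence, inst$background, fc = "L", lambda = 0.9)
  expect_identical(unname(fit0b$beta), 0)
})

test_that("coordinate descent matches the grid-search oracle on 2 features", {
  set.seed(21)
  for (rep in 1:3) {
    b <- matrix(runif(60), 30, 2, dimnames = list(NULL, c("u", "v")))
    p <- matrix(runif(16, 0.3, 1), 8, 2, dimnames = list(NULL, c("u", "v")))
    lam <- c(0.02, 0.05)
    fit <- fit_maxent(p, b, fc = "L", lambda = lam, tol = 1e-9)
    oracle <- oracle_grid_search(design_matrix(fit$features, p),
                                 design_matrix(fit$features, b), lam)
    expect_equal(unname(fit$beta), unname(oracle), tolerance = 1e-3)
  }
})

test_that("raw probabilities normalize and entropy is bounded after fits", {
  fx <- recovery_fixture(3, n_rows = 30, n_presence = 40,
                         n_background = 300, n_layers = 3)
  for (fc in c("L", "LQ", "LQH")) {
    fit <- fit_maxent(fx$presence_env, fx$background_env, fc = fc, rm = 1,
                      hinge_knots = 8)
    raw <- predict(fit, fx$background_env, transform = "raw")
    expect_equal(sum(raw), 1, tolerance = 1e-8)
    expect_gte(fit$entropy_H, 0)
    expect_lte(fit$entropy_H, log(nrow(fx$background_env)) + 1e-9)
  }
})

test_that("unpenalized linear fits satisfy KKT moment matching", {
  set.seed(31)
  b <- matrix(rnorm(100), 50, 2, dimnames = list(NULL, c("x", "y")))
  p <- matrix(rnorm(30, mean = 0.6), 15, 2, dimnames = list(NULL, c("x", "y")))
  fit <- fit_maxent(p, b, fc = "L", lambda = 0, tol = 1e-10)
  Xb <- design_matrix(fit$features, b)
  w <- exp(Xb %*% fit$beta); w <- w / sum(w)
  gap <- colMeans(design_matrix(fit$features, p)) - as.numeric(t(w) %*% Xb)
  expect_lt(max(abs(gap)), 1e-4)
})

test_that("penalized gain is non-decreasing and rm shrinks the fit", {
  fx <- recovery_fixture(5, n_rows = 30, n_presence = 40,
                         n_background = 300, n_layers = 3)
  fit <- fit_maxent(fx$presence_env, fx$background_env, fc = "LQ", rm = 1)
  expect_true(all(diff(fit$trace) >= -1e-12))
  # L1 norm non-increasing in rm; huge rm gives the uniform model
  l1 <- vapply(c(0.5, 1, 2, 4), function(rm)
    sum(abs(fit_maxent(fx$presence_env, fx$background_env, fc = "LQ",
                       rm = rm)$beta)), numeric(1))
  expect_true(all(diff(l1) <= 1e-8))
  hug <- fit_maxent(fx$presence_env, fx$background_env, fc = "LQ", rm = 1e6)
  expect_true(all(hug$beta == 0))
  expect_equal(hug$entropy_H, log(nrow(fx$background_env)), tolerance = 1e-9)
})

test_that("output transforms follow their formulas and clamping truncates", {
  inst <- four_cell_instance()
  # null model: uniform raw, known entropy
  fit <- fit_maxent(inst$presence, inst$background, fc = "L", lambda = 10)
  raw <- predict(fit, inst$background, transform = "raw")
  expect_equal(raw, rep(0.25, 4))
  expect_equal(fit$entropy_H, log(4))
  # raw = 1/N corresponds to cloglog 1 - exp(-1) at that cell
  cll <- predict(fit, inst$background, transform = "cloglog")
  expect_equal(cll, rep(1 - exp(-1), 4))
  lgs <- predict(fit, inst$background, transform = "logistic")
  expect_equal(lgs, rep(0.5, 4))
  # clamped projection beyond the training max equals the boundary value
  fit2 <- fit_maxent(inst$presence, inst$background, fc = "L", lambda = 0.25)
  hi <- matrix(5, 1, 1, dimnames = list(NULL, "x"))
  at_max <- matrix(1, 1, 1, dimnames = list(NULL, "x"))
  expect_equal(predict(fit2, hi, clamp = TRUE),
               predict(fit2, at_max, clamp = TRUE))
  expect_error(predict(fit2, matrix(1, 1, 1, dimnames = list(NULL, "z"))),
               "x")
})

test_that("response curves behave for monotone, null and bounded models", {
  set.seed(41)
  b <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("x", "y")))
  p <- matrix(rnorm(40, mean = 1), 20, 2, dimnames = list(NULL, c("x", "y")))
  fit <- fit_maxent(p, b, fc = "L", rm = 1)
  rc <- response_curve(fit, "x")
  expect_true(all(diff(rc$prediction) >= -1e-12))  # positive linear term
  expect_true(all(rc$prediction >= 0 & rc$prediction <= 1))
  null <- fit_maxent(p, b, fc = "L", lambda = 10)
  rcn <- response_curve(null, "x")
  expect_equal(diff(range(rcn$prediction)), 0)
  expect_error(response_curve(fit, "nope"), "nope")
})

test_that("jackknife importance separates informative from noise variables", {
  fx <- recovery_fixture(8, n_rows = 40, n_presence = 60,
                         n_background = 400, n_layers = 3)
  # Bio3 is uninformative by construction (truth uses Bio1, Bio2)
  jk <- jackknife_importance(fx$presence_env, fx$background_env, fc = "L",
                             rm = 1, seed = 2)
  tab <- jk$table
  noise_gain <- tab$gain_with_only[tab$variable == "Bio3"]
  expect_lt(noise_gain, 0.2)
  expect_gt(max(tab$gain_with_only[tab$variable != "Bio3"]), noise_gain)
  # duplicated variable: dropping the duplicate loses no gain
  pe <- cbind(fx$presence_env[, c("Bio1", "Bio2")],
              dup = fx$presence_env[, "Bio1"])
  be <- cbind(fx$background_env[, c("Bio1", "Bio2")],
              dup = fx$background_env[, "Bio1"])
  jk2 <- jackknife_importance(pe, be, fc = "L", rm = 1, seed = 2)
  expect_equal(jk2$table$gain_without[jk2$table$variable == "dup"],
               jk2$all_variables$gain, tolerance = 0.05)
})

test_that("model JSON serialization round-trips predictions", {
  fx <- recovery_fixture(9, n_rows = 30, n_presence = 30,
                         n_background = 200, n_layers = 3)
  fit <- fit_maxent(fx$presence_env, fx$background_env, fc = "LQH", rm = 1.5,
                    hinge_knots = 5)
  p <- tempfile(fileext = ".json")
  maxent_to_json(fit, p)
  back <- maxent_from_json(p)
  expect_equal(predict(back, fx$background_env),
               predict(fit, fx$background_env), tolerance = 1e-10)
  expect_equal(back$rm, fit$rm)
  expect_equal(back$fc, fit$fc)
  unlink(p)
})

test_that("synthetic truth is recovered by the fitted model", {
  fx <- recovery_fixture(1)
  fit <- fit_maxent(fx$presence_env, fx$background_env, fc = "LQ", rm = 1)
  rho <- cor(fx$truth$suitability$values[fx$bg_cells],
             predict(fit, fx$background_env), method = "spearman")
  expect_gt(rho, 0.9)
  rk <- rank(-variable_contributions(fit))[c("Bio1", "Bio2")]
  expect_true(all(rk <= 2))
})
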