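test_that("cell indexing follows the half-open boundary convention", {
  g <- grid_spec(100, 25, 60, 4, 4)  # 1-degree cells for easy arithmetic
  # interior point
  i <- cell_index(g, 100.5, 24.5)
  expect_equal(c(i$row, i$col), c(1L, 1L))
  # east boundary belongs to the next column, south boundary to next row
  i <- cell_index(g, 101, 24)
  expect_equal(c(i$row, i$col), c(2L, 2L))
  # northern grid edge belongs to row 1
  i <- cell_index(g, 100.5, 25)
  expect_equal(i$row, 1L)
  # outside -> NA
  expect_true(is.na(cell_index(g, 99, 24)$cell))
  # center round-trips to its own cell
  ctr <- cell_center(g, 3, 2)
  i <- cell_index(g, ctr$lon, ctr$lat)
  expect_equal(c(i$row, i$col), c(3L, 2L))
})

test_that("ESRI ASCII grid round-trip preserves values and nodata", {
  g <- toy_grid(6, 5)
  set.seed(3)
  v <- matrix(rnorm(30), 6, 5)
  v[2, 3] <- NA; v[5, 1] <- NA
  r <- env_raster(g, v)
  p <- tempfile(fileext = ".asc")
  write_asc(r, p)
  r2 <- read_asc(p)
  expect_equal(r2$values, v, tolerance = 1e-7)
  expect_identical(is.na(r2$values), is.na(v))
  expect_equal(r2$grid$west, g$west)
  expect_equal(r2$grid$cell_size, g$cell_size)
  unlink(p)
})

test_that("stack .asc directory round-trip recovers every layer", {
  st <- toy_stack(seed = 11, n = 10)
  d <- tempfile("stackdir")
  write_stack_asc(st, d)
  st2 <- read_stack_asc(d)
  expect_setequal(names(st2$layers), names(st$layers))
  for (nm in names(st$layers))
    expect_equal(st2$layers[[nm]], st$layers[[nm]], tolerance = 1e-7)
  unlink(d, recursive = TRUE)
})

test_that("occurrence CSV loading validates and filters", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("species,lon,lat,extra",
               "P. axillaris,113.2,23.1,x",
               "P. speciosa,101.0,24.0,y",
               "P. speciosa,102.0,25.0,z"), p)
  occ <- load_occurrences(p)
  expect_equal(nrow(occ), 3)
  expect_equal(occ$lon[1], 113.2)
  occ_f <- load_occurrences(p, species_filter = "P. speciosa")
  expect_equal(nrow(occ_f), 2)
  # out-of-range latitude names the row
  writeLines(c("species,lon,lat", "X,10,95"), p)
  expect_error(load_occurrences(p), "row")
  # missing column is a format error
  writeLines(c("species,longitude,lat", "X,10,20"), p)
  expect_error(load_occurrences(p), "lon")
  unlink(p)
})

test_that("thinning keeps the first record per cell and is idempotent", {
  g <- toy_grid()
  occ <- occurrence_set(data.frame(
    species = "S",
    lon = c(100.01, 100.011, 100.012, 100.5, 100.01),
    lat = c(24.99, 24.99, 24.99, 24.5, 24.99),
    source = letters[1:5]))
  th <- thin_occurrences(occ, g)
  # three identical-cell records collapse to the first; 1 degree apart kept
  expect_equal(nrow(th), 2)
  expect_equal(th$source[1], "a")
  # idempotence and output order = input order
  expect_identical(thin_occurrences(th, g), th)
  # never two outputs in one cell (recompute indices)
  ci <- cell_index(g, th$lon, th$lat)$cell
  expect_false(any(duplicated(ci)))
  # records outside the grid are dropped with a warning
  occ2 <- occurrence_set(data.frame(species = "S", lon = c(100.1, 50),
                                    lat = c(24.5, 24.5)))
  expect_warning(th2 <- thin_occurrences(occ2, g), "outside")
  expect_equal(nrow(th2), 1)
  # empty input passes through
  expect_equal(nrow(thin_occurrences(occ[0, ], g)), 0)
})

test_that("align_stack is identity on the same grid and exact on a ramp", {
  st <- toy_stack(seed = 5, n = 12)
  out <- align_stack(st, st$grid)
  expect_equal(out$layers, st$layers)
  # constant layer stays constant under any resampling
  g <- st$grid
  cst <- env_stack(g, list(c1 = matrix(5, g$n_rows, g$n_cols)))
  tgt <- grid_spec(g$west + 0.01, g$north - 0.01, g$cell_size / 2, 14, 14)
  res <- align_stack(cst, tgt, "bilinear")
  expect_true(all(abs(res$layers$c1 - 5) < 1e-12, na.rm = TRUE))
  # linear ramp: bilinear interpolation reproduces the plane exactly
  ramp <- outer(seq_len(g$n_rows), seq_len(g$n_cols),
                function(r, c) 2 * c + 3 * r)
  rst <- env_stack(g, list(ramp = ramp))
  tgt2 <- grid_spec(g$west, g$north, g$cell_size / 2,
                    2 * g$n_rows, 2 * g$n_cols)
  res2 <- align_stack(rst, tgt2, "bilinear")
  # predicted plane value at each target center (cols/rows in source units)
  d_s <- g$cell_size / 60
  ctr <- cell_center(tgt2, 5, 7)
  cs <- (ctr$lon - g$west) / d_s + 0.5    # fractional source column
  rs <- (g$north - ctr$lat) / d_s + 0.5   # fractional source row
  expect_equal(res2$layers$ramp[5, 7], 2 * cs + 3 * rs, tolerance = 1e-9)
  # no-overlap target errors
  expect_error(align_stack(st, grid_spec(0, 0, 2.5, 5, 5)), "overlap")
})

test_that("paleo temperature rescaling divides only the listed layers", {
  g <- toy_grid(4, 4)
  st <- env_stack(g, list(Bio1 = matrix(215, 4, 4),
                          Bio6 = matrix(-53, 4, 4),
                          Bio12 = matrix(800, 4, 4)))
  out <- scale_paleo_temperature(st, c("Bio1", "Bio6"))
  expect_equal(out$layers$Bio1[1, 1], 21.5)
  expect_equal(out$layers$Bio6[1, 1], -5.3)
  expect_equal(out$layers$Bio12, st$layers$Bio12)
  expect_error(scale_paleo_temperature(st, "Bio99"), "Bio99")
})

test_that("terrain derivation follows Horn's method on analytic surfaces", {
  g <- toy_grid(8, 8)
  # constant surface: zero slope, flat aspect flag
  flat <- derive_terrain(env_raster(g, matrix(100, 8, 8)))
  expect_true(all(flat$slope$values[2:7, 2:7] == 0))
  expect_true(all(flat$aspect$values[2:7, 2:7] == -1))
  expect_true(all(is.na(flat$slope$values[1, ])))  # border is nodata
  # plane rising eastward: downhill aspect 270, slope atan(gradient)
  d_m <- (g$cell_size / 60) * 111195 * cos(cell_center(g, 4, 4)$lat * pi / 180)
  grad <- 0.1  # rise per metre
  z <- outer(rep(1, 8), seq_len(8)) * grad * d_m
  ter <- derive_terrain(env_raster(g, z))
  expect_equal(ter$aspect$values[4, 4], 270)
  expect_equal(ter$slope$values[4, 4], atan(grad) * 180 / pi, tolerance = 1e-6)
  # a masked interior cell knocks out its 8 neighbours
  z[4, 4] <- NA
  ter2 <- derive_terrain(env_raster(g, z))
  expect_true(all(is.na(ter2$slope$values[3:5, 3:5])))
  expect_false(is.na(ter2$slope$values[2, 2]))
  expect_error(derive_terrain(env_raster(grid_spec(0, 0, 2.5, 2, 5),
                                         matrix(0, 2, 5))), "3x3")
})

test_that("ensemble mean averages cellwise with strict nodata propagation", {
  g <- toy_grid(3, 3)
  m1 <- env_raster(g, matrix(0.2, 3, 3))
  m2 <- env_raster(g, matrix(0.4, 3, 3))
  m3v <- matrix(0.6, 3, 3); m3v[2, 2] <- NA
  m3 <- env_raster(g, m3v)
  out <- ensemble_mean(list(m1, m2, m3))
  expect_equal(out$values[1, 1], 0.4)
  expect_true(is.na(out$values[2, 2]))
  # single member is the identity
  expect_equal(ensemble_mean(list(m1))$values, m1$values)
  # permutation invariance and member min/max bounds
  out2 <- ensemble_mean(list(m3, m1, m2))
  expect_equal(out$values, out2$values)
  expect_true(all(out$values >= 0.2 & out$values <= 0.6, na.rm = TRUE))
  expect_error(ensemble_mean(list(m1, env_raster(toy_grid(4, 4), 1))),
               "grids")
})
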