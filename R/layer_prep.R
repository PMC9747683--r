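# Layer preparation: resampling to the analysis grid, paleo temperature
# unit fixes, terrain derivatives, and climate-model ensemble means.

METERS_PER_DEGREE <- 111195  # spherical Earth, R = 6371 km

#' Resample a stack onto a target grid
#'
#' Aligns every layer of a stack to a common analysis grid (the standard
#' workflow resamples all covariates to one 2.5' grid before modelling).
#' Continuous layers default to bilinear interpolation; layers named in
#' `categorical` (e.g. vegetation class, aspect) are forced to
#' nearest-neighbour.
#'
#' @param stack An [env_stack()].
#' @param target Target [grid_spec()] (WGS84, like the source).
#' @param method "bilinear" (default for continuous layers) or "nearest".
#' @param categorical Layer names always resampled nearest-neighbour.
#' @return An [env_stack()] on the target grid.
#' @export
align_stack <- function(stack, target, method = c("bilinear", "nearest"),
                        categorical = c("vegetation", "aspect")) {
  method <- match.arg(method)
  sg <- stack$grid
  sd_ <- grid_deg(sg); td <- grid_deg(target)
  s_east <- sg$west + sg$n_cols * sd_; s_south <- sg$north - sg$n_rows * sd_
  t_east <- target$west + target$n_cols * td; t_south <- target$north - target$n_rows * td
  if (t_east <= sg$west || target$west >= s_east ||
      target$north <= s_south || t_south >= sg$north)
    stop("no spatial overlap between source and target grids")
  if (grid_equal(sg, target)) {
    return(env_stack(target, stack$layers, period = stack$period,
                     gcm = stack$gcm, scenario = stack$scenario))
  }
  tc <- expand.grid(row = seq_len(target$n_rows), col = seq_len(target$n_cols))
  ctr <- cell_center(target, tc$row, tc$col)
  # fractional position in source cell-center coordinates
  fx <- (ctr$lon - (sg$west + sd_ / 2)) / sd_
  fy <- ((sg$north - sd_ / 2) - ctr$lat) / sd_
  resample_one <- function(m, meth) {
    out <- matrix(NA_real_, target$n_rows, target$n_cols)
    if (meth == "nearest") {
      col <- round(fx) + 1L; row <- round(fy) + 1L
      ok <- col >= 1L & col <= sg$n_cols & row >= 1L & row <= sg$n_rows
      out[cbind(tc$row[ok], tc$col[ok])] <- m[cbind(row[ok], col[ok])]
    } else {
      x0 <- floor(fx); y0 <- floor(fy)
      wx <- fx - x0; wy <- fy - y0
      # clamp to the edge so target centers between the border cell center
      # and the grid edge still interpolate (degenerate weight 0/1)
      cl <- function(v, lo, hi) pmin(pmax(v, lo), hi)
      inside <- fx >= -0.5 & fx <= sg$n_cols - 0.5 &
        fy >= -0.5 & fy <= sg$n_rows - 0.5
      x0c <- cl(x0, 0, sg$n_cols - 1L); x1c <- cl(x0 + 1L, 0, sg$n_cols - 1L)
      y0c <- cl(y0, 0, sg$n_rows - 1L); y1c <- cl(y0 + 1L, 0, sg$n_rows - 1L)
      v00 <- m[cbind(y0c + 1L, x0c + 1L)]; v01 <- m[cbind(y0c + 1L, x1c + 1L)]
      v10 <- m[cbind(y1c + 1L, x0c + 1L)]; v11 <- m[cbind(y1c + 1L, x1c + 1L)]
      val <- (1 - wy) * ((1 - wx) * v00 + wx * v01) +
        wy * ((1 - wx) * v10 + wx * v11)
      val[!inside] <- NA_real_
      out[cbind(tc$row, tc$col)] <- val
    }
    out
  }
  layers <- lapply(names(stack$layers), function(nm) {
    meth <- if (nm %in% categorical) "nearest" else method
    resample_one(stack$layers[[nm]], meth)
  })
  names(layers) <- names(stack$layers)
  env_stack(target, layers, period = stack$period, gcm = stack$gcm,
            scenario = stack$scenario)
}

#' Rescale paleoclimate temperature layers from tenths of a degree
#'
#' Paleoclimate bioclim distributions store temperature variables in tenths
#' of degrees Celsius; dividing by 10 puts them on the same scale as
#' current/future layers. Precipitation and other layers are untouched.
#'
#' @param stack An [env_stack()].
#' @param temp_layer_names Names of the temperature layers (default the 11
#'   temperature bioclims present in the stack, `Bio1`..`Bio11`).
#' @return The stack with listed layers divided by 10.
#' @export
scale_paleo_temperature <- function(stack,
                                    temp_layer_names = intersect(paste0("Bio", 1:11),
                                                                 names(stack$layers))) {
  miss <- setdiff(temp_layer_names, names(stack$layers))
  if (length(miss)) stop("layer(s) not in stack: ", paste(miss, collapse = ", "))
  for (nm in temp_layer_names) stack$layers[[nm]] <- stack$layers[[nm]] / 10
  stack
}

#' Slope and aspect from an elevation raster
#'
#' Horn's 3x3 finite-difference operator on a geographic grid. Cell size is
#' converted to metres at 111,195 m/degree, scaled by cos(latitude) for the
#' east-west spacing. Slope is returned in degrees; aspect as the compass
#' bearing of the downhill direction (0 = north, 90 = east), with flat cells
#' flagged -1. Border cells and cells with any masked neighbour are nodata.
#'
#' @param elevation An [env_raster()] of elevation in metres.
#' @return List with `slope` and `aspect` rasters.
#' @export
derive_terrain <- function(elevation) {
  g <- elevation$grid
  if (g$n_rows < 3 || g$n_cols < 3) stop("grid must be at least 3x3")
  z <- elevation$values
  nr <- g$n_rows; nc <- g$n_cols
  d <- grid_deg(g)
  slope <- matrix(NA_real_, nr, nc)
  aspect <- matrix(NA_real_, nr, nc)
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  # 3x3 neighbourhood as shifted sub-matrices (a..i, row-major from NW)
  a <- z[ri - 1, ci - 1]; b <- z[ri - 1, ci]; cc <- z[ri - 1, ci + 1]
  dd <- z[ri,     ci - 1];                    f  <- z[ri,     ci + 1]
  gg <- z[ri + 1, ci - 1]; h <- z[ri + 1, ci]; i2 <- z[ri + 1, ci + 1]
  lat <- g$north - (ri - 0.5) * d
  dx <- d * METERS_PER_DEGREE * cos(lat * pi / 180)  # per row
  dy <- d * METERS_PER_DEGREE
  p <- ((cc + 2 * f + i2) - (a + 2 * dd + gg)) / (8 * matrix(dx, length(ri), length(ci)))
  q <- ((a + 2 * b + cc) - (gg + 2 * h + i2)) / (8 * dy)
  sl <- atan(sqrt(p^2 + q^2)) * 180 / pi
  asp <- (atan2(-p, -q) * 180 / pi) %% 360
  asp[p == 0 & q == 0] <- -1
  bad <- is.na(a) | is.na(b) | is.na(cc) | is.na(dd) | is.na(z[ri, ci]) |
    is.na(f) | is.na(gg) | is.na(h) | is.na(i2)
  sl[bad] <- NA_real_; asp[bad] <- NA_real_
  slope[ri, ci] <- sl; aspect[ri, ci] <- asp
  list(slope = env_raster(g, slope), aspect = env_raster(g, aspect))
}

#' Cellwise arithmetic mean of rasters
#'
#' Used to average projections across climate models (GCMs) before
#' thresholding, so one map represents each period/scenario. A cell is
#' nodata if it is nodata in any member, keeping all ensembles on a common
#' support.
#'
#' @param maps List of [env_raster()]s on one grid.
#' @return An [env_raster()].
#' @export
ensemble_mean <- function(maps) {
  stopifnot(length(maps) >= 1)
  g <- maps[[1]]$grid
  for (m in maps[-1]) if (!grid_equal(m$grid, g)) stop("mismatched grids")
  acc <- maps[[1]]$values
  if (length(maps) > 1)
    for (m in maps[-1]) acc <- acc + m$values  # NA propagates
  env_raster(g, acc / length(maps))
}
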