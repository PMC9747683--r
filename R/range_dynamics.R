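# Downstream range analytics on suitability rasters: 4-class suitability
# maps, binary presence/absence maps, spherical area accounting, change
# maps between periods, range centroids and shifts, multi-species overlap
# stacking and glacial refugium inference.

EARTH_RADIUS_KM <- 6371

#' Spherical area of every cell in one column of a grid
#'
#' Cells in one row share the same area on a geographic grid:
#' A = R^2 * dlambda * (sin(phi_top) - sin(phi_bottom)), R = 6371 km.
#'
#' @param grid A [grid_spec()].
#' @return Numeric vector of cell areas (km^2), one per row.
#' @export
cell_areas_km2 <- function(grid) {
  d <- grid_deg(grid) * pi / 180
  r <- seq_len(grid$n_rows)
  top <- (grid$north - (r - 1) * grid_deg(grid)) * pi / 180
  bot <- (grid$north - r * grid_deg(grid)) * pi / 180
  EARTH_RADIUS_KM^2 * d * (sin(top) - sin(bot))
}

area_matrix <- function(grid)
  matrix(cell_areas_km2(grid), grid$n_rows, grid$n_cols)

#' Classify a suitability map into four suitability grades
#'
#' Standard grading: unsuitable [0, 0.1), low [0.1, 0.3), moderate
#' [0.3, 0.5), high [0.5, 1]. Bins are half-open upward (0.3 is moderate,
#' 0.5 is high).
#'
#' @param s Suitability [env_raster()] with values in [0, 1].
#' @param thresholds Strictly increasing class boundaries in (0, 1)
#'   (default c(0.1, 0.3, 0.5)).
#' @return `env_raster` with integer classes 0-3 (class `classified_map`).
#' @export
classify_suitability <- function(s, thresholds = c(0.1, 0.3, 0.5)) {
  stopifnot(length(thresholds) == 3, all(diff(thresholds) > 0),
            all(thresholds > 0 & thresholds < 1))
  v <- s$values
  if (any(v < 0 | v > 1, na.rm = TRUE)) stop("suitability outside [0, 1]")
  cl <- (v >= thresholds[1]) + (v >= thresholds[2]) + (v >= thresholds[3])
  out <- env_raster(s$grid, cl)
  attr(out, "thresholds") <- thresholds
  class(out) <- c("classified_map", class(out))
  out
}

#' Threshold a suitability map into presence/absence
#'
#' @param s Suitability [env_raster()].
#' @param threshold Value in (0, 1); presence where suitability >=
#'   threshold. 0.5 is the fixed threshold conventionally used for range
#'   dynamics; 0.1 for multi-species stacking of any suitable habitat.
#' @return `env_raster` of 0/1 (class `binary_map`).
#' @export
to_binary <- function(s, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  out <- env_raster(s$grid, (s$values >= threshold) * 1)
  attr(out, "threshold") <- threshold
  class(out) <- c("binary_map", class(out))
  out
}

#' Area per class of a classified or binary map
#'
#' @param map `env_raster` of integer classes (e.g. from
#'   [classify_suitability()] or [to_binary()]).
#' @return data.frame with `class` and `area_km2`, summed with the
#'   spherical cell-area formula.
#' @export
class_areas <- function(map) {
  am <- area_matrix(map$grid)
  v <- map$values
  ok <- !is.na(v)
  agg <- tapply(am[ok], v[ok], sum)
  data.frame(class = as.numeric(names(agg)), area_km2 = as.numeric(agg))
}

#' Change map between two binary range maps
#'
#' Categories: `absent` (absent in both), `stable` (present in both),
#' `contraction` (present before only), `expansion` (present after only).
#'
#' @param before,after `binary_map`s on one grid.
#' @return List with `map` (`env_raster`, codes 0 absent / 1 stable /
#'   2 expansion / 3 contraction) and `areas` (km^2 per category).
#' @export
change_map <- function(before, after) {
  if (!grid_equal(before$grid, after$grid)) stop("mismatched grids")
  b <- before$values; a <- after$values
  code <- matrix(NA_real_, nrow(b), ncol(b))
  code[b == 0 & a == 0] <- 0
  code[b == 1 & a == 1] <- 1
  code[b == 0 & a == 1] <- 2
  code[b == 1 & a == 0] <- 3
  m <- env_raster(before$grid, code)
  am <- area_matrix(before$grid)
  ok <- !is.na(code)
  area_of <- function(k) sum(am[ok & code == k])
  list(map = m,
       areas = data.frame(category = c("absent", "stable", "expansion",
                                       "contraction"),
                          area_km2 = c(area_of(0), area_of(1),
                                       area_of(2), area_of(3))))
}

#' Range centroid of a binary map
#'
#' Area-weighted mean of present-cell centers (weights = spherical cell
#' areas); longitudes averaged arithmetically, adequate for ranges not
#' spanning the antimeridian. Optionally samples an elevation raster at the
#' centroid cell.
#'
#' @param map A `binary_map` with at least one present cell.
#' @param elevation Optional elevation [env_raster()] on the same grid.
#' @return List with `lon`, `lat` and (if given) `elevation_m`.
#' @export
centroid <- function(map, elevation = NULL) {
  idx <- which(map$values == 1)
  if (!length(idx)) stop("empty range: no present cells")
  g <- map$grid
  rc <- arrayInd(idx, c(g$n_rows, g$n_cols))
  ctr <- cell_center(g, rc[, 1], rc[, 2])
  w <- cell_areas_km2(g)[rc[, 1]]
  out <- list(lon = sum(w * ctr$lon) / sum(w),
              lat = sum(w * ctr$lat) / sum(w))
  if (!is.null(elevation)) {
    ci <- cell_index(elevation$grid, out$lon, out$lat)
    out$elevation_m <- elevation$values[ci$row, ci$col]
  }
  out
}

#' Great-circle shift between two centroids
#'
#' Haversine distance (spherical Earth, R = 6371 km) and initial compass
#' bearing from the first to the second centroid.
#'
#' @param from,to Lists/rows with `lon` and `lat` (degrees).
#' @return List with `distance_km` and `bearing_deg` (0 = north, 90 = east).
#' @export
centroid_shift <- function(from, to) {
  p1 <- c(from$lon, from$lat); p2 <- c(to$lon, to$lat)
  list(distance_km = geosphere::distHaversine(p1, p2,
                                              r = EARTH_RADIUS_KM * 1000) / 1000,
       bearing_deg = geosphere::bearing(p1, p2) %% 360)
}

#' Stack binary range maps across species
#'
#' Per-cell count of species present, the raster behind multi-species
#' overlap analyses (richness of suitable habitat; during glacial periods
#' the cells with maximum overlap are candidate differentiation centers).
#'
#' @param maps Named list of `binary_map`s on one grid (names = species).
#' @return List with `counts` (`env_raster`), `species`, `max_count` and
#'   `max_cells` (linear indices achieving the maximum).
#' @export
stack_species <- function(maps) {
  stopifnot(length(maps) >= 1)
  g <- maps[[1]]$grid
  for (m in maps[-1]) if (!grid_equal(m$grid, g)) stop("mismatched grids")
  acc <- matrix(0, g$n_rows, g$n_cols)
  anyna <- matrix(FALSE, g$n_rows, g$n_cols)
  for (m in maps) {
    v <- m$values
    anyna <- anyna | is.na(v)
    v[is.na(v)] <- 0
    acc <- acc + v
  }
  acc[anyna & acc == 0] <- NA
  mx <- max(acc, na.rm = TRUE)
  list(counts = env_raster(g, acc), species = names(maps),
       max_count = mx, max_cells = which(acc == mx))
}

#' Infer candidate glacial refugia
#'
#' Cells suitable in both the glacial-period and current maps (the stable
#' category of the change map): habitat persisting through the glaciation.
#'
#' @param lgm,current `binary_map`s on one grid.
#' @return A `binary_map` of the intersection.
#' @export
infer_refugium <- function(lgm, current) {
  if (!grid_equal(lgm$grid, current$grid)) stop("mismatched grids")
  out <- env_raster(lgm$grid, lgm$values * current$values)
  attr(out, "threshold") <- attr(lgm, "threshold")
  class(out) <- c("binary_map", class(out))
  out
}
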