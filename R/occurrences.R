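# Occurrence ingest and grid thinning.

#' Load occurrence records from CSV
#'
#' Expects a header with at least `species`, `lon`, `lat` (extra columns are
#' ignored; an optional `source` column is kept). Coordinates are validated
#' against WGS84 bounds.
#'
#' @param path CSV file path (UTF-8, "." decimal separator).
#' @param species_filter Optional species name; only matching rows returned.
#' @return A data.frame of class `occurrence_set` with columns `species`,
#'   `lon`, `lat`, `source`, in file order.
#' @export
load_occurrences <- function(path, species_filter = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("species", "lon", "lat")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("occurrence file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  if (!"source" %in% names(df)) df$source <- NA_character_
  df <- df[, c("species", "lon", "lat", "source")]
  df$lon <- as.numeric(df$lon); df$lat <- as.numeric(df$lat)
  bad <- which(is.na(df$lon) | is.na(df$lat) |
                 df$lon < -180 | df$lon > 180 | df$lat < -90 | df$lat > 90)
  if (length(bad))
    stop("invalid coordinates at row(s): ", paste(bad, collapse = ", "))
  if (!is.null(species_filter)) df <- df[df$species == species_filter, ]
  occurrence_set(df)
}

#' Construct an occurrence set
#' @param df data.frame with columns `species`, `lon`, `lat` (and optionally
#'   `source`).
#' @return The data.frame with class `occurrence_set` prepended.
#' @export
occurrence_set <- function(df) {
  stopifnot(all(c("species", "lon", "lat") %in% names(df)))
  if (!"source" %in% names(df)) df$source <- NA_character_
  rownames(df) <- NULL
  class(df) <- c("occurrence_set", "data.frame")
  df
}

#' Write an occurrence set to CSV
#' @param occ An `occurrence_set`.
#' @param path Output path.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Thin occurrences to one record per grid cell
#'
#' Reduces spatial autocorrelation before model fitting by keeping at most
#' one record per cell of the analysis grid. The first record (in input
#' order) in each occupied cell is kept; output preserves input order.
#' Records falling outside the grid are dropped with a warning.
#'
#' @param occ An `occurrence_set`.
#' @param grid The analysis [grid_spec()] (conventionally the 2.5'
#'   environmental grid).
#' @return Thinned `occurrence_set`.
#' @export
thin_occurrences <- function(occ, grid) {
  if (nrow(occ) == 0) return(occ)
  idx <- cell_index(grid, occ$lon, occ$lat)
  outside <- is.na(idx$cell)
  if (any(outside)) {
    warning(sum(outside), " record(s) outside the grid dropped")
    occ <- occ[!outside, , drop = FALSE]
    idx <- idx[!outside, , drop = FALSE]
  }
  if (nrow(occ) == 0) return(occurrence_set(occ))
  keep <- !duplicated(paste(occ$species, idx$cell))
  occurrence_set(occ[keep, , drop = FALSE])
}
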