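#' Georeferenced presence points for one range
#'
#' @param lon,lat numeric vectors of WGS84 decimal-degree coordinates.
#' @param range_label text identifier ("native", "invasive", ...).
#' @param env optional matrix/data.frame of per-point predictor values
#'   (one row per point).
#' @return an object of class `occurrence_set`.
#' @export
occurrence_set <- function(lon, lat, range_label = "unlabelled", env = NULL) {
  stopifnot(length(lon) == length(lat))
  if (!is.null(env)) {
    env <- as.matrix(env)
    stopifnot(nrow(env) == length(lon))
  }
  structure(list(range_label = range_label,
                 points = data.frame(lon = as.numeric(lon),
                                     lat = as.numeric(lat)),
                 env = env),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat("<occurrence_set> '", x$range_label, "': ", nrow(x$points),
      " point(s)", sep = "")
  if (!is.null(x$env))
    cat(", env: ", paste(colnames(x$env), collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.occurrence_set <- function(x) nrow(x$points)

subset_occ <- function(occ, keep) {
  occurrence_set(occ$points$lon[keep], occ$points$lat[keep],
                 occ$range_label,
                 if (!is.null(occ$env)) occ$env[keep, , drop = FALSE])
}

#' Read occurrence records from a delimited text file
#'
#' Rows with non-numeric or missing coordinates are skipped with a message;
#' exact duplicate coordinates are retained (spatial rarefaction is a
#' separate, explicit step, see [rarefy_occurrences()]).
#'
#' @param path path to a CSV file with a header.
#' @param range_label label attached to the returned set.
#' @param lon_col,lat_col,species_col header names of the coordinate and
#'   species columns (`species_col` may be absent, it is not used).
#' @return an [occurrence_set]; the number of skipped rows is attached as
#'   attribute `"n_skipped"`.
#' @export
read_occurrences <- function(path, range_label = "unlabelled",
                             lon_col = "longitude", lat_col = "latitude",
                             species_col = "species") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c(lon_col, lat_col) %in% names(df)))
    stop("occurrence file ", path, " lacks required column(s): ",
         paste(setdiff(c(lon_col, lat_col), names(df)), collapse = ", "))
  lon <- suppressWarnings(as.numeric(df[[lon_col]]))
  lat <- suppressWarnings(as.numeric(df[[lat_col]]))
  ok <- is.finite(lon) & is.finite(lat)
  if (any(!ok))
    message("read_occurrences: skipped ", sum(!ok),
            " row(s) with non-numeric or missing coordinates")
  out <- occurrence_set(lon[ok], lat[ok], range_label)
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Write an occurrence set as CSV (species, longitude, latitude)
#'
#' @param occ an [occurrence_set]. @param path output path.
#' @param species species name written in the first column.
#' @export
write_occurrences <- function(occ, path, species = "synthetic_species") {
  utils::write.csv(data.frame(species = species,
                              longitude = occ$points$lon,
                              latitude = occ$points$lat),
                   path, row.names = FALSE)
  invisible(path)
}
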