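#' Spatially rarefy presences to one point per raster cell
#'
#' Emulates the common "one record per grid cell" thinning: at the native
#' 30 arc-second resolution one cell is approximately 1 km^2, so thinning on
#' the predictor grid itself removes within-cell duplicates. The first point
#' (input order) in each cell is kept; points outside the raster extent are
#' dropped with a message. Idempotent.
#'
#' @param occ an [occurrence_set].
#' @param stack the [env_stack] whose grid defines the thinning cells.
#' @return a thinned [occurrence_set].
#' @export
rarefy_occurrences <- function(occ, stack) {
  ids <- cell_id(stack, occ$points$lon, occ$points$lat)
  outside <- is.na(ids)
  if (any(outside))
    message("rarefy_occurrences: dropped ", sum(outside),
            " point(s) outside the raster extent")
  keep <- !outside & !duplicated(ids)
  subset_occ(occ, keep)
}

#' Sample background points from the accessible area
#'
#' Draws cell centers uniformly at random from the masked-in cells: without
#' replacement when `n` does not exceed the number of accessible cells,
#' otherwise with replacement (with a warning).
#'
#' @param stack an [env_stack] with a non-empty mask.
#' @param n number of background points.
#' @param seed integer seed (NULL = use current RNG state).
#' @param range_label label of the returned set.
#' @return an [occurrence_set] of cell-center points.
#' @export
sample_background <- function(stack, n, seed = NULL,
                              range_label = "background") {
  rc <- masked_cells(stack)
  m <- nrow(rc)
  if (m == 0) stop("sample_background: the accessible-area mask is empty")
  idx <- with_seed(seed, {
    if (n <= m) sample.int(m, n)
    else {
      warning("sample_background: n (", n, ") exceeds accessible cells (",
              m, "); sampling with replacement")
      sample.int(m, n, replace = TRUE)
    }
  })
  xy <- cell_center(stack, rc[idx, 1], rc[idx, 2])
  occurrence_set(xy[, "lon"], xy[, "lat"], range_label,
                 env = cell_values(stack, rc[idx, 1], rc[idx, 2]))
}

#' Attach environmental values to points by nearest-cell lookup
#'
#' Points falling on masked-out or no-data cells (or outside the extent)
#' are removed with a message.
#'
#' @param occ an [occurrence_set]. @param stack an [env_stack].
#' @return the [occurrence_set] with `env` filled.
#' @export
extract_env <- function(occ, stack) {
  rc <- cell_index(stack, occ$points$lon, occ$points$lat)
  ok <- !is.na(rc[, 1])
  ok[ok] <- stack$mask[rc[ok, , drop = FALSE]]
  if (any(!ok))
    message("extract_env: removed ", sum(!ok),
            " point(s) on masked-out, no-data or out-of-extent cells")
  vals <- cell_values(stack, rc[ok, 1], rc[ok, 2])
  out <- occurrence_set(occ$points$lon[ok], occ$points$lat[ok],
                        occ$range_label, env = vals)
  attr(out, "n_removed") <- sum(!ok)
  out
}

#' Greedy low-collinearity variable selection
#'
#' Walks the candidate variables in a caller-supplied priority order and
#' drops any variable whose absolute Pearson correlation with an
#' already-kept variable exceeds the cutoff (|r| <= cutoff is retained).
#' Zero-variance variables are dropped with reason `"zero variance"`.
#'
#' @param sample matrix/data.frame of predictor values used to evaluate
#'   correlations (>= 10 rows).
#' @param cutoff absolute Pearson correlation threshold (default 0.75).
#' @param priority character vector ordering the candidates; defaults to
#'   column order.
#' @return object of class `variable_selection`: `cutoff`, `kept` (ordered
#'   names), `dropped` (data.frame of name, reason).
#' @export
select_variables <- function(sample, cutoff = 0.75, priority = NULL) {
  sample <- as.matrix(sample)
  if (ncol(sample) < 2) stop("select_variables: need >= 2 candidate variables")
  if (nrow(sample) < 10) stop("select_variables: need >= 10 sample rows")
  priority <- priority %||% colnames(sample)
  stopifnot(setequal(priority, colnames(sample)))
  kept <- character(0)
  dropped <- data.frame(name = character(0), reason = character(0))
  for (v in priority) {
    x <- sample[, v]
    if (stats::sd(x) == 0) {
      dropped <- rbind(dropped, data.frame(name = v, reason = "zero variance"))
      next
    }
    clash <- NULL
    for (k in kept) {
      if (abs(stats::cor(x, sample[, k])) > cutoff) { clash <- k; break }
    }
    if (is.null(clash)) kept <- c(kept, v)
    else dropped <- rbind(dropped, data.frame(name = v, reason = clash))
  }
  structure(list(cutoff = cutoff, kept = kept, dropped = dropped),
            class = "variable_selection")
}

#' @export
print.variable_selection <- function(x, ...) {
  cat("<variable_selection> cutoff |r| <=", x$cutoff, "\n kept:",
      paste(x$kept, collapse = ", "), "\n")
  if (nrow(x$dropped))
    cat(" dropped:", paste(x$dropped$name, "(", x$dropped$reason, ")",
                           collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a variable selection as JSON
#' @param x a `variable_selection`. @param path output path.
#' @export
write_variable_selection <- function(x, path) {
  jsonlite::write_json(list(cutoff = x$cutoff, kept = x$kept,
                            dropped = x$dropped),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
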