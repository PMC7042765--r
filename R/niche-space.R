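#' Fit the shared environmental ordination (PCA-env)
#'
#' Principal component analysis of the pooled, z-score standardized
#' background environments of both ranges. The first two axes define the
#' 2-D environmental space in which all niche grids, overlap statistics and
#' permutation tests operate. Axis signs are fixed so the largest-magnitude
#' loading of each axis is positive (deterministic orientation).
#'
#' @param background_env_native,background_env_invasive matrices with the
#'   same column set (the kept predictor variables).
#' @return object of class `pca_env`: `means`, `scales` (pooled per-variable
#'   centering/scaling constants), `loadings` (variables x 2, orthonormal),
#'   `explained_fraction` (first two axes), `explained_all` (all axes).
#' @export
fit_pca_env <- function(background_env_native, background_env_invasive) {
  a <- as.matrix(background_env_native)
  b <- as.matrix(background_env_invasive)
  if (!setequal(colnames(a), colnames(b)))
    stop("fit_pca_env: the two backgrounds must share the same variables")
  b <- b[, colnames(a), drop = FALSE]
  pooled <- rbind(a, b)
  if (ncol(pooled) < 2) stop("fit_pca_env: need >= 2 variables")
  if (nrow(pooled) < 10) stop("fit_pca_env: need >= 10 pooled rows")
  mu <- colMeans(pooled)
  sc <- apply(pooled, 2, stats::sd)
  if (any(sc == 0)) stop("fit_pca_env: zero-variance variable in background")
  z <- sweep(sweep(pooled, 2, mu), 2, sc, `/`)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  load <- pc$rotation[, 1:2, drop = FALSE]
  for (j in 1:2) {                         # deterministic sign convention
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(means = mu, scales = sc, loadings = load,
                 explained_fraction = frac[1:2], explained_all = frac),
            class = "pca_env")
}

#' @export
print.pca_env <- function(x, ...) {
  cat("<pca_env> ", nrow(x$loadings), " variables; first two axes explain ",
      round(100 * sum(x$explained_fraction), 2), "% of variance\n", sep = "")
  invisible(x)
}

#' Project environmental values into the 2-D niche space
#'
#' @param model a [fit_pca_env()] result.
#' @param env matrix/data.frame with the training variables.
#' @return n x 2 matrix of scores.
#' @export
project_env <- function(model, env) {
  env <- as.matrix(env)
  miss <- setdiff(rownames(model$loadings), colnames(env))
  if (length(miss))
    stop("project_env: missing variable(s): ", paste(miss, collapse = ", "))
  env <- env[, rownames(model$loadings), drop = FALSE]
  z <- sweep(sweep(env, 2, model$means), 2, model$scales, `/`)
  s <- z %*% model$loadings
  colnames(s) <- c("PC1", "PC2")
  s
}

#' @export
predict.pca_env <- function(object, newdata, ...) project_env(object, newdata)

#' Shared axis bounds over pooled background scores
#'
#' Both ranges' occupancy grids must share identical axis vectors so cells
#' are comparable; bounds are the pooled background min/max with no margin.
#'
#' @param ... one or more score matrices (n x 2).
#' @return list with `x = c(min, max)`, `y = c(min, max)`.
#' @export
niche_grid_bounds <- function(...) {
  s <- do.call(rbind, list(...))
  list(x = range(s[, 1]), y = range(s[, 2]))
}

silverman_bw <- function(x) {
  bw <- stats::bw.nrd0(x)
  if (!is.finite(bw) || bw <= 0) bw <- max(1e-6, stats::sd(x) * 1e-3, 1e-6)
  bw
}

## Product-Gaussian KDE of (x, y) points evaluated at the R x R cell
## centers implied by `bounds`. MASS::kde2d divides its `h` by 4, so the
## call below evaluates the kernel with per-axis sd exactly `bw`.
kde_on_grid <- function(x, y, bounds, R, bw) {
  dx <- diff(bounds$x) / R
  dy <- diff(bounds$y) / R
  k <- MASS::kde2d(x, y, h = 4 * c(bw[1], bw[2]), n = R,
                   lims = c(bounds$x[1] + dx / 2, bounds$x[2] - dx / 2,
                            bounds$y[1] + dy / 2, bounds$y[2] - dy / 2))
  k  # list(x = centers, y = centers, z = R x R density, x index first)
}

#' Build the kernel-smoothed occupancy grid for one range
#'
#' Occurrence and background scores are smoothed with a product-Gaussian
#' kernel on an `R` x `R` grid spanning `bounds`; the occupancy corrected
#' for availability is `z = o / e` on cells with available environment,
#' normalized to sum to one. Each density is smoothed with Silverman's
#' rule computed on its own scores (occurrences for `o`, background for
#' `e`), times `bw_mult`. Scores outside the bounds are clamped to the
#' boundary cell.
#'
#' @param scores_occ n x 2 matrix of occurrence scores (>= 1 row).
#' @param scores_bg m x 2 matrix of background scores for this range.
#' @param bounds shared axis bounds from [niche_grid_bounds()].
#' @param R grid resolution per axis (default 100).
#' @param bandwidth length-2 kernel sd per axis for the occurrence
#'   density; default Silverman's rule on the occurrence scores.
#' @param bw_mult scalar bandwidth multiplier (default 1).
#' @param availability optional precomputed availability component (the
#'   `availability` element of another `niche_grid` on the same bounds and
#'   resolution); permutation tests use this to rebuild only the
#'   occurrence density.
#' @return object of class `niche_grid`: axis centers `x`, `y`; matrices
#'   `o` (occurrence density), `e` (availability density), `z` (corrected
#'   occupancy, sums to 1), `z_uncor` (`o / max(o)`, in `[0, 1]`);
#'   `occ_cells` (linear grid indices of the occurrence scores, used for
#'   data-driven niche support thresholds).
#' @export
build_niche_grid <- function(scores_occ, scores_bg, bounds, R = 100,
                             bandwidth = NULL, bw_mult = 1,
                             availability = NULL) {
  scores_occ <- as.matrix(scores_occ)
  if (nrow(scores_occ) < 1) stop("build_niche_grid: zero occurrences")
  clamp <- function(v, r) pmin(pmax(v, r[1]), r[2])
  ox <- clamp(scores_occ[, 1], bounds$x); oy <- clamp(scores_occ[, 2], bounds$y)
  if (is.null(bandwidth))
    bandwidth <- c(silverman_bw(ox), silverman_bw(oy)) * bw_mult
  if (length(bandwidth) == 1) bandwidth <- rep(bandwidth, 2)
  if (is.null(availability)) {
    scores_bg <- as.matrix(scores_bg)
    bx <- clamp(scores_bg[, 1], bounds$x); by <- clamp(scores_bg[, 2], bounds$y)
    bw_e <- c(silverman_bw(bx), silverman_bw(by)) * bw_mult
    ke <- kde_on_grid(bx, by, bounds, R, bw_e)
    e <- ke$z
    ## Availability support: a smoothed density is positive almost
    ## everywhere, and dividing occupancy by its far tails would blow the
    ## corrected occupancy up on environments that do not really exist in
    ## the range. Cells less dense than the sparsest cell actually holding
    ## a background point are treated as unavailable.
    dx <- diff(bounds$x) / R; dy <- diff(bounds$y) / R
    bi <- pmin(pmax(floor((bx - bounds$x[1]) / dx) + 1, 1), R)
    bj <- pmin(pmax(floor((by - bounds$y[1]) / dy) + 1, 1), R)
    e[e < min(e[(bj - 1L) * R + bi])] <- 0
    availability <- list(e = e, bandwidth = bw_e, R = R, bounds = bounds)
  } else {
    if (!identical(availability$R, R))
      stop("build_niche_grid: availability resolution mismatch")
  }
  ko <- kde_on_grid(ox, oy, bounds, R, bandwidth)
  o <- ko$z; e <- availability$e
  z <- matrix(0, R, R)
  pos <- e > 0
  z[pos] <- o[pos] / e[pos]
  s <- sum(z)
  if (s > 0) z <- z / s
  dx <- diff(bounds$x) / R; dy <- diff(bounds$y) / R
  ci <- pmin(pmax(floor((ox - bounds$x[1]) / dx) + 1, 1), R)
  cj <- pmin(pmax(floor((oy - bounds$y[1]) / dy) + 1, 1), R)
  structure(list(R = R, x = ko$x, y = ko$y, o = o, e = e, z = z,
                 z_uncor = o / max(o), bandwidth = bandwidth,
                 bounds = bounds, availability = availability,
                 occ_cells = (cj - 1L) * R + ci),
            class = "niche_grid")
}

#' @export
print.niche_grid <- function(x, ...) {
  cat("<niche_grid> ", x$R, "x", x$R, " cells, bandwidth (",
      signif(x$bandwidth[1], 3), ", ", signif(x$bandwidth[2], 3),
      ")\n", sep = "")
  invisible(x)
}
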