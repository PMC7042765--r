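#' Configuration of a synthetic paired-range scenario
#'
#' Defaults describe the study conditions the package is exercised under:
#' two 100 x 100-cell ranges with four correlated, spatially smooth
#' climate-like layers (a temperature-like pair correlated at 0.6 and a
#' precipitation-like pair at 0.5, near-zero across pairs), a Gaussian
#' niche of sd `sigma = 0.5` (in standardized climate units), 79 native and
#' 6579 invasive occurrences, and a configurable shift `delta` of the
#' occupied-niche centroid between ranges (in climate units; multiples of
#' `sigma` are the natural scale).
#'
#' @param nrow,ncol grid shape per range.
#' @param n_vars number of climate layers (default 4).
#' @param cor_target target pairwise correlation matrix (positive
#'   definite); default the 2-block structure above.
#' @param smoothness number of low-frequency cosine components per field
#'   wavelengths (maximum cycles across the extent; default 3 - larger is
#'   rougher).
#' @param centroid native niche centroid in climate units (default -0.5 per
#'   variable: the species occupies a displaced portion of the available
#'   climate, giving presence-background contrast as in real ranges).
#' @param sigma niche breadth (sd of the isotropic Gaussian niche).
#' @param delta niche-centroid shift between ranges (>= 0).
#' @param shift_dir unit vector giving the shift direction (normalized
#'   internally; default equal weight on all variables).
#' @param n_native,n_invasive occurrence counts (defaults 79 and 6579).
#' @param n_background background points for SDM fitting (default 10000).
#' @param border masked-out border width in cells (default 3).
#' @param shared_landscape use one landscape realization for both ranges
#'   (the exactly-exchangeable null condition; default FALSE).
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(nrow = 100, ncol = 100, n_vars = 4,
                             cor_target = NULL, smoothness = 3,
                             centroid = NULL, sigma = 0.5, delta = 0,
                             shift_dir = NULL,
                             n_native = 79, n_invasive = 6579,
                             n_background = 10000, border = 3,
                             shared_landscape = FALSE) {
  if (is.null(cor_target)) {
    cor_target <- diag(n_vars)
    if (n_vars >= 2) cor_target[1, 2] <- cor_target[2, 1] <- 0.6
    if (n_vars >= 4) cor_target[3, 4] <- cor_target[4, 3] <- 0.5
  }
  if (any(eigen(cor_target, symmetric = TRUE, only.values = TRUE)$values
          <= 1e-10))
    stop("synthetic_config: correlation target is not positive definite")
  centroid <- centroid %||% rep(-0.5, n_vars)
  shift_dir <- shift_dir %||% rep(1, n_vars)
  shift_dir <- shift_dir / sqrt(sum(shift_dir^2))
  stopifnot(delta >= 0, sigma > 0, n_native >= 1, n_invasive >= 1)
  structure(list(nrow = nrow, ncol = ncol, n_vars = n_vars,
                 cor_target = cor_target, smoothness = smoothness,
                 centroid = centroid, sigma = sigma, delta = delta,
                 shift_dir = shift_dir, n_native = n_native,
                 n_invasive = n_invasive, n_background = n_background,
                 border = border, shared_landscape = shared_landscape),
            class = "synthetic_config")
}

## One smooth random field: a sum of low-frequency cosine components.
smooth_field <- function(nrow, ncol, smoothness, n_comp = 40) {
  x <- matrix(rep(seq_len(ncol) / ncol, each = nrow), nrow)
  y <- matrix(rep(seq_len(nrow) / nrow, times = ncol), nrow)
  f <- matrix(0, nrow, ncol)
  for (i in seq_len(n_comp)) {
    fx <- stats::runif(1, -smoothness, smoothness)
    fy <- stats::runif(1, -smoothness, smoothness)
    ph <- stats::runif(1, 0, 2 * pi)
    f <- f + stats::rnorm(1) * cos(2 * pi * (fx * x + fy * y) + ph)
  }
  f
}

#' Generate one synthetic range landscape
#'
#' Climate layers are smooth spatial fields (random low-frequency cosine
#' bases), orthonormalized over cells and mixed by the Cholesky factor of
#' the target correlation matrix, so the cell-wise sample correlations hit
#' the target (up to border masking). Layers are standardized: mean 0,
#' sd 1 over cells. The mask is the full extent minus a border.
#'
#' @param config a [synthetic_config()].
#' @param range_index 1 (native) or 2 (invasive); offsets the geographic
#'   extent so ranges do not overlap in space.
#' @param seed integer seed.
#' @return an [env_stack] with layers `var1..varN`.
#' @export
make_landscape <- function(config, range_index = 1, seed = NULL) {
  nr <- config$nrow; nc <- config$ncol; nv <- config$n_vars
  raw <- with_seed(seed, {
    vapply(seq_len(nv),
           function(i) as.vector(smooth_field(nr, nc, config$smoothness)),
           numeric(nr * nc))
  })
  raw <- scale(raw, center = TRUE, scale = FALSE)
  q <- qr.Q(qr(raw))                       # exactly orthogonal smooth bases
  q <- scale(q, center = TRUE, scale = TRUE)
  mixed <- q %*% chol(config$cor_target)
  mixed <- scale(mixed, center = TRUE, scale = TRUE)
  layers <- lapply(seq_len(nv), function(i) matrix(mixed[, i], nr, nc))
  names(layers) <- paste0("var", seq_len(nv))
  mask <- matrix(TRUE, nr, nc)
  b <- config$border
  if (b > 0) {
    mask[c(seq_len(b), nr - seq_len(b) + 1), ] <- FALSE
    mask[, c(seq_len(b), nc - seq_len(b) + 1)] <- FALSE
  }
  cs <- 1 / 120                            # 30 arc-seconds in degrees
  env_stack(layers, xll = (range_index - 1) * (nc * cs + 1), yll = 0,
            cellsize = cs, mask = mask)
}

#' Sample species occurrences from a Gaussian climate niche
#'
#' Cell suitability is the (unnormalized) Gaussian density of the cell's
#' climate vector at `(centroid, breadth)`; accessible cells are sampled
#' with replacement with probability proportional to suitability and
#' points jittered uniformly within their cell.
#'
#' @param stack an [env_stack].
#' @param centroid niche centroid in climate units (length = layers).
#' @param breadth niche sd (scalar, isotropic) or covariance matrix.
#' @param n number of occurrences. @param seed integer seed.
#' @param range_label label of the returned set.
#' @return an [occurrence_set] (without env values; see [extract_env()]).
#' @export
sample_species <- function(stack, centroid, breadth, n, seed = NULL,
                           range_label = "unlabelled") {
  rc <- masked_cells(stack)
  X <- cell_values(stack, rc[, 1], rc[, 2])
  S <- if (is.matrix(breadth)) breadth else diag(breadth^2, ncol(X))
  d2 <- stats::mahalanobis(X, centroid, S)
  suit <- exp(-0.5 * (d2 - min(d2)))       # shift for numerical stability
  if (all(exp(-0.5 * d2) == 0) || sum(suit) == 0)
    stop("sample_species: suitability is zero everywhere")
  pts <- with_seed(seed, {
    idx <- sample.int(nrow(rc), n, replace = TRUE, prob = suit)
    jx <- stats::runif(n, -0.5, 0.5) * stack$cellsize
    jy <- stats::runif(n, -0.5, 0.5) * stack$cellsize
    ctr <- cell_center(stack, rc[idx, 1], rc[idx, 2])
    cbind(ctr[, "lon"] + jx, ctr[, "lat"] + jy)
  })
  occurrence_set(pts[, 1], pts[, 2], range_label)
}

#' Build a full paired-range scenario with a programmed niche shift
#'
#' Generates native and invasive landscapes, places the invasive niche
#' centroid at `centroid + delta * shift_dir`, samples both occurrence
#' sets, and records the analytic ground truth, including the
#' Bhattacharyya coefficient of the two occupied Gaussians
#' (`exp(-delta^2 / (8 sigma^2))` for equal isotropic breadth).
#'
#' @param config a [synthetic_config()]. @param seed integer seed.
#' @return object of class `synthetic_scenario`: `native` and `invasive`
#'   (each a list with `stack` and `occ`), `truth`, and the `config`.
#' @export
make_scenario <- function(config, seed = NULL) {
  s_gen <- derive_seed(seed, "generator")
  s_sp <- derive_seed(seed, "species")
  stack1 <- make_landscape(config, 1, s_gen)
  stack2 <- if (config$shared_landscape) {
    s2 <- stack1
    s2$xll <- stack1$xll + config$ncol * stack1$cellsize + 1
    s2
  } else make_landscape(config, 2, if (is.null(s_gen)) NULL else s_gen + 1L)
  mu1 <- config$centroid
  mu2 <- mu1 + config$delta * config$shift_dir
  occ1 <- sample_species(stack1, mu1, config$sigma, config$n_native,
                         s_sp, "native")
  occ2 <- sample_species(stack2, mu2, config$sigma, config$n_invasive,
                         if (is.null(s_sp)) NULL else s_sp + 1L, "invasive")
  bc <- exp(-config$delta^2 / (8 * config$sigma^2))
  structure(list(native = list(stack = stack1, occ = occ1),
                 invasive = list(stack = stack2, occ = occ2),
                 truth = list(centroid_native = mu1, centroid_invasive = mu2,
                              sigma = config$sigma, delta = config$delta,
                              overlap_bhattacharyya = bc),
                 config = config, seed = seed),
            class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("<synthetic_scenario> delta = ", x$truth$delta, " (",
      round(x$truth$delta / x$truth$sigma, 2), " sigma), ",
      length(x$native$occ), " native / ", length(x$invasive$occ),
      " invasive occurrence(s)\n", sep = "")
  invisible(x)
}

#' Write a scenario to disk in the formats the pipeline reads
#'
#' Layers and masks as ESRI ASCII grids, occurrences as CSV, ground truth
#' as JSON.
#'
#' @param scenario a [make_scenario()] result. @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rg in c("native", "invasive")) {
    st <- scenario[[rg]]$stack
    for (v in names(st$layers))
      write_ascii_grid(st$layers[[v]], file.path(dir, paste0(rg, "_", v, ".asc")),
                       st$xll, st$yll, st$cellsize)
    write_ascii_grid(st$mask + 0, file.path(dir, paste0(rg, "_mask.asc")),
                     st$xll, st$yll, st$cellsize)
    write_occurrences(scenario[[rg]]$occ,
                      file.path(dir, paste0(rg, "_occurrences.csv")))
  }
  jsonlite::write_json(scenario$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
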