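# Small in-code fixtures shared across tests.

# A tiny env_stack with known values: `nr` x `nc` cells, layers filled by
# deterministic functions of (row, col) unless supplied.
tiny_stack <- function(nr = 10, nc = 10, layers = NULL, mask = NULL,
                       xll = 0, yll = 0, cellsize = 1) {
  if (is.null(layers)) {
    layers <- list(
      temp = outer(seq_len(nr), seq_len(nc), function(r, c) r + c / 100),
      prec = outer(seq_len(nr), seq_len(nc), function(r, c) 10 * c + r / 100))
  }
  env_stack(layers, xll = xll, yll = yll, cellsize = cellsize, mask = mask)
}

# Write a temporary occurrence CSV; returns the path.
occ_csv <- function(df, file = tempfile(fileext = ".csv")) {
  write.csv(df, file, row.names = FALSE)
  file
}

# A small-but-real synthetic scenario for pipeline-level tests.
small_scenario <- function(delta = 0, seed = 42, n_native = 50,
                           n_invasive = 150, shared = FALSE, ...) {
  cfg <- synthetic_config(n_native = n_native, n_invasive = n_invasive,
                          delta = delta, n_background = 1000,
                          shared_landscape = shared, ...)
  make_scenario(cfg, seed = seed)
}

# Project a scenario into niche-space scores (occurrences and backgrounds).
scenario_scores <- function(sc, rarefy = FALSE) {
  nat <- nicheshift:::prepare_range(sc$native$stack, sc$native$occ, rarefy)
  inv <- nicheshift:::prepare_range(sc$invasive$stack, sc$invasive$occ, rarefy)
  pca <- fit_pca_env(nat$background_env, inv$background_env)
  out <- list(
    occ1 = project_env(pca, nat$occ$env),
    occ2 = project_env(pca, inv$occ$env),
    bg1 = project_env(pca, nat$background_env),
    bg2 = project_env(pca, inv$background_env),
    pca = pca)
  out$bounds <- niche_grid_bounds(out$bg1, out$bg2)
  out
}

# Random environmental matrices for SDM unit tests.
random_env <- function(n, n_vars = 4, mean = 0, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(n * n_vars, mean, sd), ncol = n_vars,
         dimnames = list(NULL, paste0("var", seq_len(n_vars))))
}
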