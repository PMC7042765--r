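grid_surface <- function(g, corrected = TRUE) {
  if (inherits(g, "niche_grid")) {
    if (corrected) g$z else g$z_uncor
  } else as.matrix(g)
}

normalize_grid <- function(z, warn = TRUE, label = "grid") {
  s <- sum(z)
  if (s <= 0) stop(label, " has zero total mass")
  if (abs(s - 1) > 1e-6) {
    if (warn) warning(label, " does not sum to 1; normalizing internally")
    z <- z / s
  } else z <- z / s
  z
}

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum(|z1 - z2|)` on occupancy grids normalized to sum to
#' one; ranges from 0 (no overlap) to 1 (identical niches). Symmetric.
#'
#' @param z1,z2 normalized occupancy grids ([build_niche_grid()] objects or
#'   matrices of the same shape). Non-normalized input is normalized with a
#'   warning.
#' @param corrected use the availability-corrected occupancy (`z`, default)
#'   or the uncorrected one (`z_uncor`) when grids are `niche_grid` objects.
#' @return a number in `[0, 1]`.
#' @export
schoener_D <- function(z1, z2, corrected = TRUE) {
  a <- grid_surface(z1, corrected); b <- grid_surface(z2, corrected)
  if (!identical(dim(a), dim(b))) stop("schoener_D: grid shape mismatch")
  a <- normalize_grid(a, label = "z1"); b <- normalize_grid(b, label = "z2")
  1 - 0.5 * sum(abs(a - b))
}

#' Warren's I niche overlap (Hellinger-based)
#'
#' `I = 1 - 0.5 * sum((sqrt(z1) - sqrt(z2))^2)`; same contract as
#' [schoener_D()].
#'
#' @inheritParams schoener_D
#' @return a number in `[0, 1]`.
#' @export
warren_I <- function(z1, z2, corrected = TRUE) {
  a <- grid_surface(z1, corrected); b <- grid_surface(z2, corrected)
  if (!identical(dim(a), dim(b))) stop("warren_I: grid shape mismatch")
  a <- normalize_grid(a, label = "z1"); b <- normalize_grid(b, label = "z2")
  1 - 0.5 * sum((sqrt(a) - sqrt(b))^2)
}

#' Both overlap metrics of two niche grids
#' @inheritParams schoener_D
#' @return list with elements `D` and `I`.
#' @export
niche_overlap <- function(z1, z2, corrected = TRUE) {
  list(D = schoener_D(z1, z2, corrected), I = warren_I(z1, z2, corrected))
}

perm_result <- function(kind, obs, null_D, null_I, p_D, p_I, n_reps,
                        direction = NA_character_) {
  structure(list(kind = kind, observed = obs,
                 null_D = null_D, null_I = null_I,
                 p_D = p_D, p_I = p_I, n_reps = n_reps,
                 direction = direction,
                 reject_D_CI = if (kind == "equivalency")
                   obs$D < stats::quantile(null_D, 0.025)
                 else obs$D > stats::quantile(null_D, 0.975),
                 reject_I_CI = if (kind == "equivalency")
                   obs$I < stats::quantile(null_I, 0.025)
                 else obs$I > stats::quantile(null_I, 0.975)),
            class = "niche_perm_test")
}

#' @export
print.niche_perm_test <- function(x, ...) {
  cat("<niche_perm_test> ", x$kind,
      if (!is.na(x$direction)) paste0(" (", x$direction, ")"), "\n",
      sep = "")
  cat(sprintf("  observed D = %.4f (p = %.4g), I = %.4f (p = %.4g), %d reps\n",
              x$observed$D, x$p_D, x$observed$I, x$p_I, x$n_reps))
  invisible(x)
}

#' Niche equivalency test
#'
#' Pools the occurrence scores of both ranges and, for each repetition,
#' randomly re-splits them into pseudo-sets of the original sizes; the
#' occupancy grids are rebuilt against each range's original background and
#' D and I recomputed. The p-value is lower-tailed,
#' `p = (count(null <= observed) + 1) / (n_reps + 1)`: equivalency is
#' rejected when the observed overlap is lower than random relabelling
#' allows. A 95%-CI rejection flag is also reported.
#'
#' @param occ1,occ2 occurrence score matrices (n x 2) of the two ranges.
#' @param bg1,bg2 background score matrices of the two ranges.
#' @param bounds shared axis bounds. @param R grid resolution.
#' @param bandwidth,bw_mult passed to [build_niche_grid()] (bandwidth is
#'   recomputed per pseudo-set by Silverman's rule when NULL).
#' @param n_reps number of permutations (default 1000).
#' @param seed integer seed. @param corrected overlap on corrected grids.
#' @return a `niche_perm_test` (kind `"equivalency"`).
#' @export
niche_equivalency_test <- function(occ1, occ2, bg1, bg2, bounds, R = 100,
                                   bandwidth = NULL, bw_mult = 1,
                                   n_reps = 1000, seed = NULL,
                                   corrected = TRUE) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  occ1 <- as.matrix(occ1); occ2 <- as.matrix(occ2)
  n1 <- nrow(occ1); n2 <- nrow(occ2)
  g1 <- build_niche_grid(occ1, bg1, bounds, R, bandwidth, bw_mult)
  g2 <- build_niche_grid(occ2, bg2, bounds, R, bandwidth, bw_mult)
  obs <- niche_overlap(g1, g2, corrected)
  pooled <- rbind(occ1, occ2)
  null_D <- numeric(n_reps); null_I <- numeric(n_reps)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      pick <- sample.int(n1 + n2, n1)
      ## availability surfaces are fixed; only occurrence densities rebuilt
      p1 <- build_niche_grid(pooled[pick, , drop = FALSE], NULL, bounds, R,
                             bandwidth, bw_mult, availability = g1$availability)
      p2 <- build_niche_grid(pooled[-pick, , drop = FALSE], NULL, bounds, R,
                             bandwidth, bw_mult, availability = g2$availability)
      ov <- niche_overlap(p1, p2, corrected)
      null_D[r] <- ov$D; null_I[r] <- ov$I
    }
  })
  perm_result("equivalency", obs, null_D, null_I,
              p_D = (sum(null_D <= obs$D) + 1) / (n_reps + 1),
              p_I = (sum(null_I <= obs$I) + 1) / (n_reps + 1),
              n_reps = n_reps)
}

## Translate a density surface by whole cells. Under "clip", mass shifted
## off the grid is dropped and the result renormalized (zero surface stays
## zero); under "wrap" the translation is toroidal and mass-preserving.
shift_grid <- function(z, dr, dc, edge = "clip") {
  R <- nrow(z); C <- ncol(z)
  if (edge == "wrap") {
    ri <- ((seq_len(R) - 1 - dr) %% R) + 1
    ci <- ((seq_len(C) - 1 - dc) %% C) + 1
    return(z[ri, ci, drop = FALSE])
  }
  out <- matrix(0, R, C)
  sr <- max(1, 1 + dr):min(R, R + dr)
  sc <- max(1, 1 + dc):min(C, C + dc)
  if (length(sr) && length(sc))
    out[sr, sc] <- z[sr - dr, sc - dc, drop = FALSE]
  s <- sum(out)
  if (s > 0) out <- out / s
  out
}

grid_centroid_cell <- function(z) {
  s <- sum(z)
  rw <- rowSums(z); cw <- colSums(z)
  c(round(sum(seq_along(rw) * rw) / s), round(sum(seq_along(cw) * cw) / s))
}

#' Niche similarity (background) test
#'
#' Compares the observed overlap with the overlap obtained when the target
#' range's occupancy surface is relocated at random within its own
#' available environment: per repetition a center cell is drawn uniformly
#' from the target background's occupied cells (`e > 0`), the whole surface
#' is translated there (clipped to the grid and renormalized) and the
#' overlap with the untouched source niche recomputed. Upper-tailed p-value
#' `p = (count(null >= observed) + 1) / (n_reps + 1)`: a small p means the
#' two niches are more similar than chance.
#'
#' @param source a [build_niche_grid()] result (the untouched niche).
#' @param target a [build_niche_grid()] result (the randomized niche).
#' @param n_reps repetitions (default 1000). @param seed integer seed.
#' @param direction label recording which range was randomized.
#' @param corrected overlap on corrected grids.
#' @param edge `"clip"` (default: relocated mass falling off the grid is
#'   dropped and the surface renormalized) or `"wrap"` (toroidal
#'   translation).
#' @return a `niche_perm_test` (kind `"similarity"`).
#' @export
niche_similarity_test <- function(source, target, n_reps = 1000, seed = NULL,
                                  direction = "source->target",
                                  corrected = TRUE,
                                  edge = c("clip", "wrap")) {
  edge <- match.arg(edge)
  if (n_reps < 1) stop("n_reps must be >= 1")
  zs <- grid_surface(source, corrected)
  zt <- grid_surface(target, corrected)
  zs <- normalize_grid(zs, warn = FALSE, label = "source")
  zt <- normalize_grid(zt, warn = FALSE, label = "target")
  obs <- list(D = schoener_D(zs, zt), I = warren_I(zs, zt))
  occ_cells <- which(target$e > 0, arr.ind = TRUE)
  if (nrow(occ_cells) == 0)
    stop("niche_similarity_test: target background is empty")
  ctr <- grid_centroid_cell(zt)
  null_D <- numeric(n_reps); null_I <- numeric(n_reps)
  with_seed(seed, {
    picks <- sample.int(nrow(occ_cells), n_reps, replace = TRUE)
    for (r in seq_len(n_reps)) {
      dest <- occ_cells[picks[r], ]
      zr <- shift_grid(zt, dest[1] - ctr[1], dest[2] - ctr[2], edge)
      if (sum(zr) == 0) { null_D[r] <- 0; null_I[r] <- 0; next }
      null_D[r] <- schoener_D(zs, zr)
      null_I[r] <- warren_I(zs, zr)
    }
  })
  perm_result("similarity", obs, null_D, null_I,
              p_D = (sum(null_D >= obs$D) + 1) / (n_reps + 1),
              p_I = (sum(null_I >= obs$I) + 1) / (n_reps + 1),
              n_reps = n_reps, direction = direction)
}

#' Niche expansion / stability / unfilling decomposition
#'
#' Each range's occupied cell set is defined by a data-driven support
#' threshold: the `quantile_threshold` quantile of the occupancy values at
#' the cells actually containing occurrences (default 0: the minimum, so
#' every cell at least as dense as the sparsest occupied cell counts). A
#' kernel-smoothed surface is positive almost everywhere, so thresholding
#' at the observed occupancy level - rather than at zero - is what gives
#' the occupied set a finite support; plain matrices without occurrence
#' information fall back to `z > 0`. Expansion `E` is the share of
#' invasive occupancy on cells outside the native occupied set, stability
#' `S = 1 - E`, and unfilling `U` is the share of native occupancy on
#' cells outside the invasive occupied set. With `analogue_only = TRUE`
#' the computation is restricted to cells whose environment is available
#' in both ranges (`e > 0` in both).
#'
#' @param z_native,z_invasive [build_niche_grid()] results on shared
#'   geometry (or plain matrices).
#' @param quantile_threshold quantile in `[0, 1)` of the occupancy at
#'   occurrence cells defining the niche support (default 0).
#' @param analogue_only restrict to mutually analogue environments.
#' @param corrected use corrected occupancy surfaces.
#' @return object of class `niche_dynamics` with `expansion`, `stability`,
#'   `unfilling`, plus the settings used.
#' @export
niche_dynamics <- function(z_native, z_invasive, quantile_threshold = 0,
                           analogue_only = FALSE, corrected = TRUE) {
  zn <- grid_surface(z_native, corrected)
  zi <- grid_surface(z_invasive, corrected)
  if (!identical(dim(zn), dim(zi))) stop("niche_dynamics: shape mismatch")
  zn <- normalize_grid(zn, warn = FALSE, label = "native")
  zi <- normalize_grid(zi, warn = FALSE, label = "invasive")
  analogue <- if (analogue_only) {
    if (!inherits(z_native, "niche_grid") || !inherits(z_invasive, "niche_grid"))
      stop("analogue_only requires niche_grid inputs (availability surfaces)")
    z_native$e > 0 & z_invasive$e > 0
  } else matrix(TRUE, nrow(zn), ncol(zn))
  occupied <- function(z, g) {
    supp <- z > 0 & analogue
    cells <- if (inherits(g, "niche_grid")) g$occ_cells else NULL
    if (!is.null(cells)) {
      th <- stats::quantile(z[cells], quantile_threshold, names = FALSE)
      supp & z >= th
    } else if (quantile_threshold == 0) supp
    else {
      pos <- z[supp]
      if (!length(pos)) stop("niche_dynamics: empty occupied set")
      supp & z >= stats::quantile(pos, quantile_threshold)
    }
  }
  on <- occupied(zn, z_native); oi <- occupied(zi, z_invasive)
  if (!any(on) || !any(oi)) stop("niche_dynamics: empty occupied set")
  E <- sum(zi[oi & !on]) / sum(zi[oi])
  U <- sum(zn[on & !oi]) / sum(zn[on])
  structure(list(expansion = E, stability = 1 - E, unfilling = U,
                 quantile_threshold = quantile_threshold,
                 analogue_only = analogue_only),
            class = "niche_dynamics")
}

#' @export
print.niche_dynamics <- function(x, ...) {
  cat(sprintf("<niche_dynamics> E = %.4f, S = %.4f, U = %.4f%s\n",
              x$expansion, x$stability, x$unfilling,
              if (x$analogue_only) " (analogue environments only)" else ""))
  invisible(x)
}

#' Export niche-shift results in the standard one-row table layout
#'
#' Columns: equivalency D/I with p-values, similarity in both directions,
#' and the expansion / stability / unfilling proportions.
#'
#' @param equivalency a `niche_perm_test` of kind `"equivalency"`.
#' @param similarity_ni,similarity_in similarity tests (native->invasive and
#'   invasive->native).
#' @param dynamics a [niche_dynamics()] result.
#' @param path optional CSV output path.
#' @return the table as a data.frame (invisibly written to `path` if given).
#' @export
niche_shift_table <- function(equivalency, similarity_ni, similarity_in,
                              dynamics, path = NULL) {
  df <- data.frame(
    metric = c("D", "I"),
    equivalency = c(equivalency$observed$D, equivalency$observed$I),
    equivalency_p = c(equivalency$p_D, equivalency$p_I),
    similarity_nat_to_inv = c(similarity_ni$observed$D, similarity_ni$observed$I),
    similarity_nat_to_inv_p = c(similarity_ni$p_D, similarity_ni$p_I),
    similarity_inv_to_nat = c(similarity_in$observed$D, similarity_in$observed$I),
    similarity_inv_to_nat_p = c(similarity_in$p_D, similarity_in$p_I),
    expansion = dynamics$expansion,
    stability = dynamics$stability,
    unfilling = dynamics$unfilling)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
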