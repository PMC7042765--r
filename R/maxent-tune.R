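#' Spatial block partition into four geographic quadrants
#'
#' Presences are split at their median latitude; each half is split at its
#' own median longitude ("block" partitioning for spatially independent
#' evaluation). Background points are assigned by the same three
#' boundaries. The assignment is a deterministic function of the
#' coordinates. Blocks are numbered 1 = lower-left, 2 = lower-right,
#' 3 = upper-left, 4 = upper-right.
#'
#' @param presences data.frame/matrix with columns `lon`, `lat` (>= 4 rows).
#' @param background same layout for background points (may be NULL).
#' @return object of class `block_partition`: `presence_block`,
#'   `background_block`, and the three split coordinates.
#' @export
block_partition <- function(presences, background = NULL) {
  p <- as.data.frame(presences)
  if (nrow(p) < 4) stop("block_partition: need >= 4 presences")
  if (length(unique(p$lat)) == 1 && length(unique(p$lon)) == 1)
    stop("block_partition: degenerate (all-equal) coordinates")
  lat_split <- stats::median(p$lat)
  lower <- p$lat <= lat_split
  lon_split_lower <- stats::median(p$lon[lower])
  lon_split_upper <- stats::median(p$lon[!lower])
  assign_block <- function(lon, lat) {
    low <- lat <= lat_split
    ifelse(low,
           ifelse(lon <= lon_split_lower, 1L, 2L),
           ifelse(lon <= lon_split_upper, 3L, 4L))
  }
  pb <- assign_block(p$lon, p$lat)
  bb <- if (!is.null(background)) {
    b <- as.data.frame(background)
    assign_block(b$lon, b$lat)
  }
  structure(list(presence_block = pb, background_block = bb,
                 lat_split = lat_split,
                 lon_split_lower = lon_split_lower,
                 lon_split_upper = lon_split_upper),
            class = "block_partition")
}

#' Small-sample corrected AIC of a maxent model
#'
#' `k` counts nonzero coefficients (|lambda| > 1e-8); the log-likelihood is
#' the sum over presences of the log raw probability normalized over the
#' training background; `AICc = 2k - 2 logL + 2k(k+1)/(n - k - 1)`.
#' Candidates with `n <= k + 1` are flagged invalid (AICc undefined).
#'
#' @param model a [fit_maxent()] model.
#' @param presence_env presence predictor matrix.
#' @return list with `k`, `logL`, `AICc`, `valid`.
#' @export
maxent_aicc <- function(model, presence_env) {
  F <- evaluate_features(model$feature_set, presence_env)
  logp <- drop(F %*% model$lambda) - model$logZ
  k <- sum(abs(model$lambda) > 1e-8)
  n <- nrow(F)
  logL <- sum(logp)
  if (n <= k + 1)
    return(list(k = k, logL = logL, AICc = NA_real_, valid = FALSE))
  list(k = k, logL = logL,
       AICc = 2 * k - 2 * logL + 2 * k * (k + 1) / (n - k - 1),
       valid = TRUE)
}

#' The standard feature-class tuning grid
#' @return list of character vectors: L, H, LQ, LQH, LQHP, LQHPT.
#' @export
default_class_combos <- function() {
  list(L = "L", H = "H", LQ = c("L", "Q"), LQH = c("L", "Q", "H"),
       LQHP = c("L", "Q", "H", "P"), LQHPT = c("L", "Q", "H", "P", "T"))
}

#' Tune feature classes and regularization multiplier
#'
#' Fits every (feature-class combo) x (regularization multiplier) candidate
#' on the full data and scores it by AICc; optionally also refits each
#' candidate per spatial block (trained on three blocks, evaluated by AUC
#' on the held-out block's presences against its background). The selected
#' candidate is the lowest-AICc valid model (within the Delta-AICc < 2 set
#' by construction), ties broken by fewer nonzero coefficients, then lower
#' RM.
#'
#' @param presence_env,background_env predictor matrices.
#' @param class_combos list of feature-class vectors
#'   (default [default_class_combos()]: 6 combos).
#' @param RMs regularization multipliers (default 0.5..4 by 0.5: 8 values;
#'   6 x 8 = 48 candidates).
#' @param knots hinge/threshold knots per variable.
#' @param presence_coords,background_coords coordinates (`lon`, `lat`) for
#'   block cross-validation; both required when `cv = TRUE`.
#' @param cv run 4-fold spatial-block AUC evaluation (default TRUE when
#'   coordinates are supplied).
#' @param seed integer seed (solver is deterministic; kept for interface
#'   stability and recorded).
#' @return object of class `maxent_tuning`: `table` (one row per candidate:
#'   classes, RM, k, logL, AICc, delta_AICc, mean_test_auc, valid),
#'   `selected` (row index), `models` not retained (refit via
#'   [fit_maxent()] with the selected settings).
#' @export
tune_maxent <- function(presence_env, background_env,
                        class_combos = default_class_combos(),
                        RMs = seq(0.5, 4, by = 0.5), knots = 20,
                        presence_coords = NULL, background_coords = NULL,
                        cv = !is.null(presence_coords), seed = NULL) {
  if (cv && (is.null(presence_coords) || is.null(background_coords)))
    stop("tune_maxent: cv requires presence and background coordinates")
  if (is.null(names(class_combos)))
    names(class_combos) <- vapply(class_combos, paste, "", collapse = "")
  part <- if (cv) block_partition(presence_coords, background_coords)
  rows <- list()
  for (ci in seq_along(class_combos)) {
    fs <- build_features(background_env, class_combos[[ci]], knots)
    for (rm in RMs) {
      fit <- fit_maxent(presence_env, background_env, fs, RM = rm)
      ic <- maxent_aicc(fit, presence_env)
      auc_cv <- NA_real_
      if (cv) {
        aucs <- numeric(0)
        for (blk in 1:4) {
          tr_p <- part$presence_block != blk
          te_p <- !tr_p
          tr_b <- part$background_block != blk
          te_b <- !tr_b
          if (sum(te_p) == 0 || sum(tr_p) < 2 || sum(te_b) == 0) next
          m <- fit_maxent(presence_env[tr_p, , drop = FALSE],
                          background_env[tr_b, , drop = FALSE], fs, RM = rm)
          aucs <- c(aucs, eval_auc(
            predict(m, presence_env[te_p, , drop = FALSE], type = "raw"),
            predict(m, background_env[te_b, , drop = FALSE], type = "raw")))
        }
        if (length(aucs)) auc_cv <- mean(aucs)
      }
      rows[[length(rows) + 1]] <- data.frame(
        classes = paste(class_combos[[ci]], collapse = ""),
        RM = rm, k = ic$k, logL = ic$logL, AICc = ic$AICc,
        mean_test_auc = auc_cv, valid = ic$valid)
    }
  }
  tab <- do.call(rbind, rows)
  if (!any(tab$valid)) stop("tune_maxent: all candidates invalid for AICc")
  best_aicc <- min(tab$AICc[tab$valid])
  tab$delta_AICc <- tab$AICc - best_aicc
  cand <- which(tab$valid & tab$delta_AICc < 2)
  cand <- cand[order(tab$AICc[cand], tab$k[cand], tab$RM[cand])]
  structure(list(table = tab, selected = cand[1],
                 knots = knots, seed = seed),
            class = "maxent_tuning")
}

#' @export
print.maxent_tuning <- function(x, ...) {
  s <- x$table[x$selected, ]
  cat("<maxent_tuning> ", nrow(x$table), " candidate(s); selected {",
      s$classes, "} RM ", s$RM, " (AICc ", round(s$AICc, 2), ", k ", s$k,
      ")\n", sep = "")
  invisible(x)
}

#' Selected settings of a tuning run
#' @param tuning a [tune_maxent()] result.
#' @return list with `classes` (character vector), `RM`, `knots`.
#' @export
selected_settings <- function(tuning) {
  s <- tuning$table[tuning$selected, ]
  list(classes = strsplit(s$classes, "")[[1]], RM = s$RM,
       knots = tuning$knots)
}
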