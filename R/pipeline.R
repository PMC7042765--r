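## Prepare one range for analysis: extract occurrence env, rarefy,
## collect background env (all accessible cells by default).
prepare_range <- function(stack, occ, rarefy = TRUE) {
  if (rarefy) occ <- rarefy_occurrences(occ, stack)
  occ <- extract_env(occ, stack)
  list(stack = stack, occ = occ, background_env = background_env(stack))
}

#' Run the full niche-shift analysis
#'
#' Executes ingestion, rarefaction, variable selection, the shared 2-D
#' ordination, kernel occupancy grids, overlap statistics, both permutation
#' tests (equivalency; similarity in both directions) and the expansion /
#' stability / unfilling decomposition.
#'
#' @param scenario a [make_scenario()] result, or any list with `native`
#'   and `invasive` elements each holding `stack` (an [env_stack]) and
#'   `occ` (an [occurrence_set]).
#' @param R grid resolution (default 100).
#' @param bw_mult bandwidth multiplier (default 1).
#' @param n_reps permutation repetitions (default 1000).
#' @param quantile_threshold,analogue_only passed to [niche_dynamics()].
#' @param cor_cutoff collinearity cutoff for [select_variables()].
#' @param priority variable priority order for the collinearity filter.
#' @param rarefy spatially thin occurrences first (default TRUE).
#' @param corrected use availability-corrected occupancy (default TRUE).
#' @param seed root seed; permutation streams are derived from it.
#' @param out_dir optional output directory (writes the one-row summary
#'   CSV, a JSON result file and niche-space PNG plots).
#' @return list with `overlap`, `equivalency`, `similarity_nat_to_inv`,
#'   `similarity_inv_to_nat`, `dynamics`, `pca`, `grids`, `selection`.
#' @export
run_niche_analysis <- function(scenario, R = 100, bw_mult = 1,
                               n_reps = 1000, quantile_threshold = 0,
                               analogue_only = FALSE, cor_cutoff = 0.75,
                               priority = NULL, rarefy = TRUE,
                               corrected = TRUE, seed = NULL,
                               out_dir = NULL) {
  nat <- prepare_range(scenario$native$stack, scenario$native$occ, rarefy)
  inv <- prepare_range(scenario$invasive$stack, scenario$invasive$occ, rarefy)
  if (length(nat$occ) < 1 || length(inv$occ) < 1)
    stop("run_niche_analysis: a range has no usable occurrences")

  sel <- select_variables(rbind(nat$background_env, inv$background_env),
                          cutoff = cor_cutoff, priority = priority)
  keep <- sel$kept
  bg_n <- nat$background_env[, keep, drop = FALSE]
  bg_i <- inv$background_env[, keep, drop = FALSE]
  pca <- fit_pca_env(bg_n, bg_i)
  sb_n <- project_env(pca, bg_n)
  sb_i <- project_env(pca, bg_i)
  so_n <- project_env(pca, nat$occ$env[, keep, drop = FALSE])
  so_i <- project_env(pca, inv$occ$env[, keep, drop = FALSE])
  bounds <- niche_grid_bounds(sb_n, sb_i)
  g_n <- build_niche_grid(so_n, sb_n, bounds, R, bw_mult = bw_mult)
  g_i <- build_niche_grid(so_i, sb_i, bounds, R, bw_mult = bw_mult)

  overlap <- niche_overlap(g_n, g_i, corrected)
  equiv <- niche_equivalency_test(so_n, so_i, sb_n, sb_i, bounds, R,
                                  bw_mult = bw_mult, n_reps = n_reps,
                                  seed = derive_seed(seed, "permutation"),
                                  corrected = corrected)
  sim_ni <- niche_similarity_test(g_n, g_i, n_reps = n_reps,
                                  seed = derive_seed(seed, "similarity"),
                                  direction = "native->invasive",
                                  corrected = corrected)
  sim_in <- niche_similarity_test(g_i, g_n, n_reps = n_reps,
                                  seed = derive_seed(seed, "similarity"),
                                  direction = "invasive->native",
                                  corrected = corrected)
  dyn <- niche_dynamics(g_n, g_i, quantile_threshold, analogue_only,
                        corrected)
  out <- list(overlap = overlap, equivalency = equiv,
              similarity_nat_to_inv = sim_ni,
              similarity_inv_to_nat = sim_in, dynamics = dyn,
              pca = pca, grids = list(native = g_n, invasive = g_i),
              selection = sel, seed = seed)
  if (!is.null(out_dir)) write_niche_outputs(out, out_dir)
  out
}

write_niche_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  niche_shift_table(res$equivalency, res$similarity_nat_to_inv,
                    res$similarity_inv_to_nat, res$dynamics,
                    file.path(out_dir, "niche_shift_table.csv"))
  jsonlite::write_json(list(
    overlap = res$overlap,
    equivalency = list(p_D = res$equivalency$p_D, p_I = res$equivalency$p_I),
    similarity = list(
      native_to_invasive = list(p_D = res$similarity_nat_to_inv$p_D,
                                p_I = res$similarity_nat_to_inv$p_I),
      invasive_to_native = list(p_D = res$similarity_inv_to_nat$p_D,
                                p_I = res$similarity_inv_to_nat$p_I)),
    dynamics = list(expansion = res$dynamics$expansion,
                    stability = res$dynamics$stability,
                    unfilling = res$dynamics$unfilling),
    explained_fraction = res$pca$explained_fraction,
    kept_variables = res$selection$kept,
    seed = res$seed),
    file.path(out_dir, "niche_results.json"), auto_unbox = TRUE, digits = NA)
  grDevices::png(file.path(out_dir, "niche_space.png"), 900, 480)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2))
  for (rg in c("native", "invasive")) {
    g <- res$grids[[rg]]
    graphics::image(g$x, g$y, g$z, main = paste(rg, "occupancy"),
                    xlab = "PC1", ylab = "PC2", col = grDevices::hcl.colors(64))
  }
  invisible(out_dir)
}

#' Run the reciprocal distribution modelling stage
#'
#' Rarefies presences, samples background points per range, tunes feature
#' classes and regularization by AICc, fits the selected model per range,
#' projects all four train x eval combinations and evaluates each with
#' AUC, CBI and TSS.
#'
#' @param scenario as in [run_niche_analysis()].
#' @param n_background background points per range (default 10000).
#' @param class_combos,RMs,knots tuning grids (defaults: the standard
#'   6 x 8 = 48-candidate grid).
#' @param cv use spatial-block AUC cross-validation during tuning
#'   (default FALSE; AICc drives selection either way).
#' @param settings optional fixed settings (list with `classes`, `RM`,
#'   `knots`) to skip tuning.
#' @param rarefy spatially thin occurrences first (default TRUE).
#' @param seed root seed.
#' @param out_dir optional output directory (wide report CSV, tuning
#'   tables, suitability ASCII grids, JSON manifest).
#' @return list with `report` (an `evaluation_report`), `tunings` (per
#'   range, NULL if `settings` supplied), and the per-range `settings`.
#' @export
run_reciprocal_sdm <- function(scenario, n_background = 10000,
                               class_combos = default_class_combos(),
                               RMs = seq(0.5, 4, by = 0.5), knots = 20,
                               cv = FALSE, settings = NULL, rarefy = TRUE,
                               seed = NULL, out_dir = NULL) {
  ranges <- list()
  tunings <- list()
  used <- list()
  for (i in 1:2) {
    rg <- c("native", "invasive")[i]
    st <- scenario[[rg]]$stack
    occ <- scenario[[rg]]$occ
    if (rarefy) occ <- rarefy_occurrences(occ, st)
    occ <- extract_env(occ, st)
    bg <- sample_background(st, n_background,
                            seed = derive_seed(seed, "background"),
                            range_label = rg)
    ranges[[rg]] <- list(presence_env = occ$env, background_env = bg$env,
                         presence_coords = occ$points,
                         background_coords = bg$points, stack = st)
    if (is.null(settings)) {
      tunings[[rg]] <- tune_maxent(occ$env, bg$env, class_combos, RMs, knots,
                                   presence_coords = occ$points,
                                   background_coords = bg$points, cv = cv,
                                   seed = seed)
      used[[rg]] <- selected_settings(tunings[[rg]])
    } else used[[rg]] <- settings
  }
  ## One model per range with its own selected settings; evaluation uses a
  ## common report so the four projections share the schema.
  rep_settings <- used$native
  if (!identical(used$native, used$invasive)) {
    ## ranges may select different candidates; the report refits each range
    ## with its own settings via two calls and merges
    rep1 <- reciprocal_report(ranges$native[1:2], ranges$invasive[1:2],
                              used$native)
    rep2 <- reciprocal_report(ranges$native[1:2], ranges$invasive[1:2],
                              used$invasive)
    tab <- rbind(rep1$table[rep1$table$train_range == "native", ],
                 rep2$table[rep2$table$train_range == "invasive", ])
    report <- structure(list(table = tab,
                             models = list(native = rep1$models$native,
                                           invasive = rep2$models$invasive),
                             settings = used),
                        class = "evaluation_report")
  } else {
    report <- reciprocal_report(ranges$native[1:2], ranges$invasive[1:2],
                                rep_settings)
  }
  out <- list(report = report,
              tunings = if (length(tunings)) tunings else NULL,
              settings = used, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    report_table(report, file.path(out_dir, "evaluation_table.csv"))
    for (rg in names(tunings))
      utils::write.csv(tunings[[rg]]$table,
                       file.path(out_dir, paste0("tuning_", rg, ".csv")),
                       row.names = FALSE)
    for (tr in c("native", "invasive")) for (ev in c("native", "invasive")) {
      st <- ranges[[ev]]$stack
      suit <- matrix(NA_real_, st$nrow, st$ncol)
      rc <- masked_cells(st)
      suit[rc] <- predict(report$models[[tr]],
                          cell_values(st, rc[, 1], rc[, 2]))
      write_ascii_grid(suit,
                       file.path(out_dir, paste0("suitability_", tr, "_on_",
                                                 ev, ".asc")),
                       st$xll, st$yll, st$cellsize)
    }
    jsonlite::write_json(list(
      seed = seed,
      n_candidates = if (length(tunings))
        lapply(tunings, function(t) nrow(t$table)) else NULL,
      settings = used,
      table = report$table),
      file.path(out_dir, "sdm_manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Read a run configuration file (YAML)
#'
#' Validates that all referenced paths exist. The config mirrors the
#' arguments of [run_niche_analysis()] / [run_reciprocal_sdm()] plus
#' per-range input paths (`occurrences`, named raster `layers`, `mask`).
#'
#' @param path YAML file path.
#' @return the config list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (rg in c("native", "invasive")) {
    r <- cfg$ranges[[rg]]
    if (is.null(r)) stop("config: missing ranges$", rg)
    paths <- c(r$occurrences, unlist(r$layers), r$mask)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("config: missing file(s): ", paste(missing, collapse = ", "))
  }
  class(cfg) <- "run_config"
  cfg
}

#' Load the two ranges referenced by a run configuration
#'
#' @param cfg a [read_run_config()] result.
#' @return a scenario-shaped list accepted by [run_niche_analysis()].
#' @export
load_ranges <- function(cfg) {
  out <- list()
  for (rg in c("native", "invasive")) {
    r <- cfg$ranges[[rg]]
    stack <- read_env_stack(unlist(r$layers), mask_path = r$mask)
    occ <- read_occurrences(r$occurrences, range_label = rg)
    out[[rg]] <- list(stack = stack, occ = occ)
  }
  out
}
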