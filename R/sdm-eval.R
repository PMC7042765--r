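#' Area under the ROC curve for presence vs background scores
#'
#' Rank-based (Mann-Whitney) estimate of the probability that a randomly
#' chosen presence outscores a randomly chosen background point, ties
#' counted one half.
#'
#' @param presence_scores,background_scores numeric vectors (non-empty).
#' @return AUC in `[0, 1]`.
#' @export
eval_auc <- function(presence_scores, background_scores) {
  n <- length(presence_scores); m <- length(background_scores)
  if (n == 0 || m == 0) stop("eval_auc: empty input")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(n)]) - n * (n + 1) / 2) / (n * m)
}

#' Continuous Boyce index
#'
#' Slides `n_windows` overlapping windows of width
#' `window_width_fraction * score range` across the score range; in each
#' window the predicted-to-expected ratio `P/E` is the fraction of
#' presences over the fraction of background points falling inside
#' (windows without background are skipped, and consecutive windows with
#' an identical ratio are collapsed to one, the conventional treatment of
#' the flat stretches produced by overlapping windows). The index is the
#' Spearman rank correlation between window midpoint and `P/E`: +1 when
#' presences concentrate monotonically at high scores, 0 for a random
#' model, -1 for counter-predictions.
#'
#' @param presence_scores,background_scores numeric vectors.
#' @param n_windows number of window positions (default 101).
#' @param window_width_fraction window width as a fraction of the score
#'   range (default 0.1).
#' @return CBI in `[-1, 1]`.
#' @export
boyce_index <- function(presence_scores, background_scores,
                        n_windows = 101, window_width_fraction = 0.1) {
  all <- c(presence_scores, background_scores)
  lo <- min(all); hi <- max(all)
  if (hi <= lo) stop("boyce_index: degenerate score range")
  W <- window_width_fraction * (hi - lo)
  mids <- seq(lo + W / 2, hi - W / 2, length.out = n_windows)
  P <- E <- numeric(n_windows)
  for (i in seq_len(n_windows)) {
    a <- mids[i] - W / 2; b <- mids[i] + W / 2
    P[i] <- mean(presence_scores >= a & presence_scores <= b)
    E[i] <- mean(background_scores >= a & background_scores <= b)
  }
  ok <- E > 0
  if (sum(ok) < 3) stop("boyce_index: undefined index (< 3 valid windows)")
  mids <- mids[ok]; pe <- P[ok] / E[ok]
  keep <- c(TRUE, diff(pe) != 0)     # collapse consecutive duplicate ratios
  mids <- mids[keep]; pe <- pe[keep]
  if (length(pe) < 2) return(0)      # constant ratio: no better than random
  stats::cor(mids, pe, method = "spearman")
}

#' True skill statistic with max-sum thresholding
#'
#' Background points are treated as pseudo-absences. When no threshold is
#' supplied, all midpoints between consecutive distinct observed scores
#' (plus one cut below the minimum and one above the maximum) are scanned
#' and the threshold maximizing `sensitivity + specificity - 1` is
#' returned with the statistic; a supplied threshold evaluates TSS at that
#' cut (used for threshold transfer between ranges).
#'
#' @param presence_scores,background_scores numeric vectors.
#' @param threshold optional fixed threshold.
#' @return list with `tss` and `threshold`.
#' @export
tss_stat <- function(presence_scores, background_scores, threshold = NULL) {
  if (!length(presence_scores) || !length(background_scores))
    stop("tss_stat: empty input")
  tss_at <- function(t)
    mean(presence_scores >= t) - mean(background_scores >= t)
  if (!is.null(threshold))
    return(list(tss = tss_at(threshold), threshold = threshold))
  s <- sort(unique(c(presence_scores, background_scores)))
  cuts <- if (length(s) == 1) s else
    c(s[1] - 1, (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1)
  vals <- vapply(cuts, tss_at, 0)
  i <- which.max(vals)
  list(tss = vals[i], threshold = cuts[i])
}

#' Reciprocal distribution modelling report
#'
#' Fits one maxent model per range with the supplied settings and predicts
#' all four train-range x eval-range combinations; each projection is
#' evaluated with AUC, the continuous Boyce index and TSS against the
#' evaluation range's presences and background. TSS is reported both with
#' the threshold optimized on the evaluation data (`tss`) and with the
#' threshold transferred from the training range's local evaluation
#' (`tss_transferred`).
#'
#' @param native_data,invasive_data lists with elements `presence_env` and
#'   `background_env` (matrices of the shared predictor variables).
#' @param settings list with `classes`, `RM` and optionally `knots`
#'   (e.g. from [selected_settings()]).
#' @return object of class `evaluation_report`: `table` (one row per
#'   train/eval pair), and the two fitted models.
#' @export
reciprocal_report <- function(native_data, invasive_data,
                              settings = list(classes = c("L", "Q", "H"),
                                              RM = 1, knots = 20)) {
  knots <- settings$knots %||% 20
  ranges <- list(native = native_data, invasive = invasive_data)
  models <- lapply(names(ranges), function(rg) {
    d <- ranges[[rg]]
    fs <- build_features(d$background_env, settings$classes, knots)
    fit_maxent(d$presence_env, d$background_env, fs, RM = settings$RM,
               range_label = rg)
  })
  names(models) <- names(ranges)
  local_thresholds <- list()
  rows <- list()
  for (tr in names(ranges)) for (ev in names(ranges)) {
    m <- models[[tr]]
    ps <- predict(m, ranges[[ev]]$presence_env)
    bs <- predict(m, ranges[[ev]]$background_env)
    ts <- tss_stat(ps, bs)
    if (tr == ev) local_thresholds[[tr]] <- ts$threshold
    rows[[paste(tr, ev)]] <- data.frame(
      train_range = tr, eval_range = ev,
      auc = eval_auc(ps, bs),
      cbi = boyce_index(ps, bs),
      tss = ts$tss, tss_threshold = ts$threshold,
      n_presence = nrow(as.matrix(ranges[[ev]]$presence_env)),
      n_background = nrow(as.matrix(ranges[[ev]]$background_env)))
  }
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  tab$tss_transferred <- NA_real_
  for (i in seq_len(nrow(tab))) {
    tr <- tab$train_range[i]; ev <- tab$eval_range[i]
    m <- models[[tr]]
    tab$tss_transferred[i] <- tss_stat(
      predict(m, ranges[[ev]]$presence_env),
      predict(m, ranges[[ev]]$background_env),
      threshold = local_thresholds[[tr]])$tss
  }
  structure(list(table = tab, models = models, settings = settings),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(x$table[, c("train_range", "eval_range", "auc", "cbi", "tss",
                    "tss_transferred")], row.names = FALSE, digits = 3)
  invisible(x)
}

#' Export an evaluation report in the wide metric-by-projection layout
#'
#' Rows are AUC, Boyce index and TSS; columns the four train->eval
#' projections (native->native, native->invasive, invasive->invasive,
#' invasive->native).
#'
#' @param report an [reciprocal_report()] result.
#' @param path optional CSV output path.
#' @param transferred_tss report the transferred-threshold TSS in the TSS
#'   row (default FALSE: evaluation-optimized threshold).
#' @return the wide data.frame.
#' @export
report_table <- function(report, path = NULL, transferred_tss = FALSE) {
  tb <- report$table
  key <- paste0(tb$train_range, "->", tb$eval_range)
  ord <- c("native->native", "native->invasive",
           "invasive->invasive", "invasive->native")
  idx <- match(ord, key)
  tss_col <- if (transferred_tss) tb$tss_transferred else tb$tss
  out <- data.frame(metric = c("AUC", "Boyce index", "TSS"),
                    rbind(tb$auc[idx], tb$cbi[idx], tss_col[idx]))
  names(out)[-1] <- gsub("->", "_to_", ord)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
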