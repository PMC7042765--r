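#' Build a maxent feature set from an environmental sample
#'
#' Variables are rescaled to `[0, 1]` using the sample's per-variable range
#' (out-of-range values at prediction time are clamped, the usual "clamping"
#' rule for cross-range projection). Feature classes:
#' \describe{
#'   \item{L}{the rescaled variable itself}
#'   \item{Q}{its square}
#'   \item{P}{pairwise products of rescaled variables}
#'   \item{H}{forward and reverse hinges at `knots` evenly spaced knots per
#'     variable, rescaled to `[0, 1]`}
#'   \item{T}{step (threshold) indicators at the same knots}
#' }
#' Constant variables keep their (constant-zero) linear feature but their
#' nonlinear features are dropped with a warning.
#'
#' @param env_sample matrix/data.frame defining per-variable min/max.
#' @param classes character vector, subset of `c("L","Q","H","P","T")`.
#' @param knots knots per variable for hinge/threshold features (default 20).
#' @return object of class `feature_set` with a `defs` table (kind, var1,
#'   var2, knot) and the rescaling ranges.
#' @export
build_features <- function(env_sample, classes = c("L", "Q", "H"),
                           knots = 20) {
  classes <- match.arg(classes, c("L", "Q", "H", "P", "T"), several.ok = TRUE)
  env_sample <- as.matrix(env_sample)
  vars <- colnames(env_sample)
  lo <- apply(env_sample, 2, min)
  hi <- apply(env_sample, 2, max)
  const <- hi == lo
  if (any(const) && any(classes != "L"))
    warning("build_features: dropping nonlinear features of constant ",
            "variable(s): ", paste(vars[const], collapse = ", "))
  defs <- data.frame(kind = character(0), var1 = character(0),
                     var2 = character(0), knot = numeric(0))
  add <- function(kind, var1, var2 = NA_character_, knot = NA_real_)
    rbind(defs, data.frame(kind = kind, var1 = var1, var2 = var2, knot = knot))
  kn <- if (knots > 0) seq_len(knots) / (knots + 1) else numeric(0)
  for (v in vars) {
    if ("L" %in% classes) defs <- add("L", v)
    if (const[[v]]) next
    if ("Q" %in% classes) defs <- add("Q", v)
    if ("H" %in% classes) for (k in kn) {
      defs <- add("HF", v, knot = k); defs <- add("HR", v, knot = k)
    }
    if ("T" %in% classes) for (k in kn) defs <- add("T", v, knot = k)
  }
  if ("P" %in% classes && length(vars) >= 2) {
    for (i in seq_len(length(vars) - 1)) for (j in (i + 1):length(vars)) {
      if (const[i] || const[j]) next
      defs <- add("P", vars[i], vars[j])
    }
  }
  if (nrow(defs) == 0) stop("build_features: empty feature set")
  structure(list(classes = sort(unique(classes)), knots = knots,
                 vars = vars, lo = lo, hi = hi, defs = defs),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set> classes {", paste(x$classes, collapse = ""), "}, ",
      length(x$vars), " variable(s), ", nrow(x$defs), " feature(s)\n",
      sep = "")
  invisible(x)
}

#' Evaluate a feature set on environmental data
#'
#' Values are clamped to the training range before rescaling, so every
#' feature maps into `[0, 1]` for any input.
#'
#' @param fs a [build_features()] result.
#' @param env matrix/data.frame containing the training variables.
#' @return n x n_features numeric matrix.
#' @export
evaluate_features <- function(fs, env) {
  env <- as.matrix(env)
  miss <- setdiff(fs$vars, colnames(env))
  if (length(miss))
    stop("evaluate_features: missing variable(s): ",
         paste(miss, collapse = ", "))
  n <- nrow(env)
  x01 <- matrix(0, n, length(fs$vars), dimnames = list(NULL, fs$vars))
  for (v in fs$vars) {
    rng <- fs$hi[[v]] - fs$lo[[v]]
    if (rng == 0) { x01[, v] <- 0; next }
    x01[, v] <- pmin(pmax((env[, v] - fs$lo[[v]]) / rng, 0), 1)
  }
  F <- matrix(0, n, nrow(fs$defs))
  for (j in seq_len(nrow(fs$defs))) {
    d <- fs$defs[j, ]
    x <- x01[, d$var1]
    F[, j] <- switch(d$kind,
      L = x,
      Q = x^2,
      P = x * x01[, d$var2],
      HF = pmax(0, x - d$knot) / (1 - d$knot),
      HR = pmax(0, d$knot - x) / d$knot,
      T = as.numeric(x > d$knot))
  }
  colnames(F) <- feature_names(fs)
  F
}

feature_names <- function(fs) {
  d <- fs$defs
  ifelse(d$kind == "P", paste0("P:", d$var1, "*", d$var2),
         ifelse(is.na(d$knot), paste0(d$kind, ":", d$var1),
                paste0(d$kind, ":", d$var1, "@", signif(d$knot, 4))))
}

## Class of each feature for penalty lookup (hinge variants share "H").
feature_class <- function(fs) {
  k <- fs$defs$kind
  ifelse(k %in% c("HF", "HR"), "H", k)
}
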