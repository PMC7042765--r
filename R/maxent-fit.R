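#' Per-class base L1 penalties
#'
#' The effective penalty of feature `j` is
#' `beta_j = RM * base[class_j] * sd_j / sqrt(n_presence)`, where `RM` is
#' the regularization multiplier and `sd_j` the feature's standard
#' deviation over the training background (floored at 1e-3), so the
#' penalty is commensurate with the feature's scale. The base constants
#' are patterned on published maxent practice (hinge features are
#' penalized at half the rate of the others since they come in large
#' correlated families): L = 1, Q = 1, P = 1, H = 0.5, T = 1.
#'
#' @return named numeric vector of base penalties.
#' @export
maxent_penalties <- function() c(L = 1, Q = 1, P = 1, H = 0.5, T = 1)

#' Fit a presence-background maximum entropy model
#'
#' Minimizes the convex objective
#' `-mean(lambda . f(presence)) + log Z(lambda) + sum(beta_j |lambda_j|)`
#' where `Z` sums `exp(lambda . f)` over the background points (the Gibbs
#' distribution of maximum entropy subject to L1-relaxed feature-mean
#' constraints). Solved by proximal coordinate descent: each coordinate
#' takes a soft-thresholded Newton step (exact first and second derivative
#' under the current Gibbs weights) with objective-decrease safeguarding,
#' cycling over an active set with periodic full sweeps; convergence is
#' declared when every coefficient satisfies its KKT box condition within
#' `tol`. Deterministic for given inputs.
#'
#' @param presence_env,background_env matrices of predictor values.
#' @param feature_set a [build_features()] result.
#' @param RM regularization multiplier (default 1).
#' @param base_penalties per-class base penalties, see [maxent_penalties()].
#' @param max_iter iteration cap (default 10000).
#' @param tol KKT tolerance (default 1e-7).
#' @param seed unused by this deterministic solver; accepted for interface
#'   stability.
#' @param range_label label stored in the fitted model's metadata.
#' @return object of class `maxent_model`: `lambda`, `beta`, `logZ`
#'   (log-normalizer over the training background), `entropy` (of the
#'   fitted distribution over the background), `feature_set`, fit metadata.
#' @export
fit_maxent <- function(presence_env, background_env, feature_set,
                       RM = 1, base_penalties = maxent_penalties(),
                       max_iter = 10000, tol = 1e-7, seed = NULL,
                       range_label = "unlabelled") {
  Fp <- evaluate_features(feature_set, presence_env)
  Fb <- evaluate_features(feature_set, background_env)
  np <- nrow(Fp); nb <- nrow(Fb)
  if (np < 2) stop("fit_maxent: need >= 2 presences")
  if (nb < 10) stop("fit_maxent: need >= 10 background points")
  fbar <- colMeans(Fp)
  sd_b <- pmax(apply(Fb, 2, stats::sd), 1e-3)
  beta <- RM * base_penalties[feature_class(feature_set)] * sd_b / sqrt(np)
  J <- ncol(Fb)
  lambda <- numeric(J)

  kkt_violation <- function(l, g) {
    on0 <- l == 0
    max(pmax(0, abs(g[on0]) - beta[on0]),
        abs(g[!on0] + beta[!on0] * sign(l[!on0])), 0)
  }
  soft <- function(x, t) sign(x) * pmax(0, abs(x) - t)

  eta <- numeric(nb)                    # Fb %*% lambda, kept incrementally
  penalty <- function(l) sum(beta * abs(l))
  obj_from_eta <- function(eta, l) logsumexp(eta) - sum(fbar * l) + penalty(l)
  obj <- obj_from_eta(eta, lambda)
  converged <- FALSE
  update_coord <- function(j, p) {
    ## soft-thresholded Newton step on coordinate j under Gibbs weights p
    fj <- Fb[, j]
    m1 <- sum(p * fj)
    g <- m1 - fbar[j]
    h <- sum(p * fj * fj) - m1 * m1
    if (h < 1e-12) return(FALSE)
    target <- soft(lambda[j] - g / h, beta[j] / h)
    delta <- target - lambda[j]
    if (abs(delta) < 1e-10 * (1 + abs(lambda[j]))) return(FALSE)
    for (bt in 1:20) {                  # objective-decrease safeguard
      l_new <- lambda; l_new[j] <- lambda[j] + delta
      eta_new <- eta + delta * fj
      o_new <- obj_from_eta(eta_new, l_new)
      if (o_new <= obj + 1e-14) {
        lambda <<- l_new; eta <<- eta_new; obj <<- o_new
        return(TRUE)
      }
      delta <- delta / 2
    }
    FALSE
  }
  sweep_count <- 0
  repeat {
    sweep_count <- sweep_count + 1
    if (sweep_count > max_iter) {
      kv <- kkt_violation(lambda,
                          drop(crossprod(Fb, exp(eta - logsumexp(eta)))) - fbar)
      stop("fit_maxent: no convergence within ", max_iter,
           " sweeps (KKT residual ", signif(kv, 3), ")")
    }
    ## full sweep: visit every coordinate
    for (j in seq_len(J)) {
      w <- exp(eta - max(eta)); p <- w / sum(w)
      update_coord(j, p)
    }
    ## inner active-set cycles until stable (bounded; progress-gated)
    for (cycle in 1:50) {
      active <- which(lambda != 0)
      if (!length(active)) break
      obj_before <- obj
      changed <- FALSE
      for (j in active) {
        w <- exp(eta - max(eta)); p <- w / sum(w)
        changed <- update_coord(j, p) || changed
      }
      if (!changed || obj_before - obj < 1e-12 * (1 + abs(obj))) break
    }
    p <- exp(eta - logsumexp(eta))
    g_full <- drop(crossprod(Fb, p)) - fbar
    if (kkt_violation(lambda, g_full) <= tol) { converged <- TRUE; break }
  }
  eta_b <- drop(Fb %*% lambda)
  logZ <- logsumexp(eta_b)
  p <- exp(eta_b - logZ)
  H <- -sum(ifelse(p > 0, p * log(p), 0))
  structure(list(lambda = stats::setNames(lambda, colnames(Fb)),
                 beta = beta, RM = RM, logZ = logZ, entropy = H,
                 feature_set = feature_set,
                 n_presence = np, n_background = nb,
                 range_label = range_label, converged = converged,
                 kkt_residual = kkt_violation(lambda, g_full),
                 presence_feature_means = fbar),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat("<maxent_model> '", x$range_label, "': classes {",
      paste(x$feature_set$classes, collapse = ""), "}, RM ", x$RM, ", ",
      sum(x$lambda != 0), "/", length(x$lambda), " nonzero coefficients\n",
      sep = "")
  cat(sprintf("  n presence %d, n background %d, entropy %.4f\n",
              x$n_presence, x$n_background, x$entropy))
  invisible(x)
}

#' Predict habitat suitability from a fitted maxent model
#'
#' `raw` is the Gibbs probability normalized over the training background
#' (sums to 1 when predicting the training background itself); `cloglog`
#' is the complementary log-log transform
#' `1 - exp(-exp(H) * raw)` mapping raw output to a `[0, 1]` occurrence
#' probability scale. Out-of-range predictors are clamped to the training
#' range.
#'
#' @param object a [fit_maxent()] model.
#' @param newdata matrix/data.frame of predictor values.
#' @param type `"cloglog"` (default) or `"raw"`.
#' @param ... unused.
#' @return numeric vector of suitabilities.
#' @export
predict.maxent_model <- function(object, newdata, type = c("cloglog", "raw"),
                                 ...) {
  type <- match.arg(type)
  F <- evaluate_features(object$feature_set, newdata)
  raw <- exp(drop(F %*% object$lambda) - object$logZ)
  if (type == "raw") return(raw)
  pmin(pmax(1 - exp(-exp(object$entropy) * raw), 0), 1)
}

#' Serialize a maxent model as JSON
#' @param model a `maxent_model`. @param path output path.
#' @export
write_maxent_model <- function(model, path) {
  fs <- model$feature_set
  jsonlite::write_json(list(
    classes = fs$classes, knots = fs$knots, vars = fs$vars,
    lo = as.list(fs$lo), hi = as.list(fs$hi),
    features = fs$defs, lambda = as.list(model$lambda),
    beta = as.list(model$beta), RM = model$RM, logZ = model$logZ,
    entropy = model$entropy, n_presence = model$n_presence,
    n_background = model$n_background, range_label = model$range_label),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
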