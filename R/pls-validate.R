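#' Orthogonalized PLS (O-PLS)
#'
#' Separates response-predictive from response-orthogonal variation in X:
#' an A-component PLS1 model is re-expressed as one predictive latent
#' variable plus A-1 orthogonal components (Trygg-Wold orthogonal signal
#' correction). Predictions are unchanged (within numerical tolerance);
#' interpretation improves because all response covariance is concentrated
#' on LV1.
#'
#' @param model a fitted `pls_model`, or an X matrix (with `y` supplied),
#'   in which case a plain PLS fit with `ncomp` components is built first.
#' @param y,ncomp,... passed to [pls_fit()] when `model` is a matrix.
#' @return A `pls_model` whose `weights`/`loadings`/`scores`/`y_loadings`
#'   describe the single predictive component, with `orthogonal` holding
#'   the orthogonal component weights, loadings and scores. The parent
#'   model's VIP vector is retained.
#' @examples
#' set.seed(2)
#' X <- matrix(rnorm(30 * 6), 30, 6)
#' y <- X[, 1] + rnorm(30, 0, 0.2)
#' om <- orthogonalize(pls_fit(X, y, ncomp = 2))
#' @export
orthogonalize <- function(model, y = NULL, ncomp = 1, ...) {
  if (is.matrix(model)) model <- pls_fit(model, y, ncomp = ncomp, ...)
  stopifnot(inherits(model, "pls_model"))
  if (!is.null(model$orthogonal)) return(model)
  A <- model$ncomp
  X <- model$X_scaled
  ys <- (model$y - model$y_center) / model$y_scale
  p <- ncol(X)
  n_ortho <- A - 1L
  Wo <- matrix(0, p, max(n_ortho, 0))
  Po <- matrix(0, p, max(n_ortho, 0))
  To <- matrix(0, nrow(X), max(n_ortho, 0))
  Xd <- X
  w <- crossprod(X, ys); w <- w / sqrt(sum(w^2))
  if (n_ortho > 0) for (k in seq_len(n_ortho)) {
    t <- Xd %*% w
    pv <- crossprod(Xd, t) / sum(t^2)
    wo <- pv - as.numeric(crossprod(w, pv)) * w
    nw <- sqrt(sum(wo^2))
    if (nw < 1e-12) { n_ortho <- k - 1L; break }
    wo <- wo / nw
    to <- Xd %*% wo
    po <- crossprod(Xd, to) / sum(to^2)
    Xd <- Xd - tcrossprod(to, po)
    Wo[, k] <- wo; Po[, k] <- po; To[, k] <- to
  }
  Wo <- Wo[, seq_len(n_ortho), drop = FALSE]
  Po <- Po[, seq_len(n_ortho), drop = FALSE]
  To <- To[, seq_len(n_ortho), drop = FALSE]
  eng <- pls1_engine(Xd, ys, 1L)
  out <- model
  out$weights <- eng$weights; out$loadings <- eng$loadings
  out$scores <- eng$scores; out$y_loadings <- eng$y_loadings
  out$coef <- eng$coef; out$ncomp <- 1L
  # X_scaled keeps the unfiltered training matrix: predict() applies the
  # orthogonal filtering itself, for training and new data alike.
  out$orthogonal <- list(weights = Wo, loadings = Po, scores = To)
  out   # VIP of the parent predictive fit is retained
}

#' Fold count rule for cross-validation
#'
#' k = 3 when the sample count exceeds 30, k = 5 otherwise (the boundary
#' n = 30 uses 5, keeping more data in each training fold).
#'
#' @param n number of samples (must be at least 6).
#' @return 3 or 5.
#' @export
choose_k <- function(n) {
  if (n < 6) stop("need at least 6 samples for cross-validation")
  if (n > 30) 3L else 5L
}

# Random k-fold assignment of n samples; for PLS-DA both classes must
# appear in every training fold, otherwise the partition is redrawn.
make_folds <- function(n, k, y = NULL, da = FALSE, max_tries = 100) {
  for (try in seq_len(max_tries)) {
    f <- sample(rep_len(seq_len(k), n))
    if (!da) return(list(folds = f, reshuffled = try - 1L))
    ok <- all(vapply(seq_len(k), function(i)
      length(unique(y[f != i])) == 2 && sum(f == i) > 0, logical(1)))
    if (ok) return(list(folds = f, reshuffled = try - 1L))
  }
  stop("could not build folds with both classes in every training fold")
}

# One repeat of k-fold CV: out-of-fold predictions for each candidate A.
# Returns RMSECV (PLSR) or accuracy (PLS-DA) per candidate.
cv_once <- function(X, y, candidates, k, da, global_scaling = FALSE) {
  n <- nrow(X)
  fl <- make_folds(n, k, y = y, da = da)
  f <- fl$folds
  stat <- numeric(length(candidates))
  preds <- matrix(NA_real_, n, length(candidates))
  for (i in seq_len(k)) {
    test <- f == i
    Xtr <- X[!test, , drop = FALSE]; ytr <- y[!test]
    Xte <- X[test, , drop = FALSE]
    for (ci in seq_along(candidates)) {
      A <- min(candidates[ci], sum(!test) - 1L, ncol(X))
      m <- if (global_scaling)
        pls_fit_prescaled(Xtr, ytr, A) else pls_fit(Xtr, ytr, ncomp = A)
      preds[test, ci] <- predict(m, Xte)
    }
  }
  yn <- if (da) ifelse(as.integer(factor(y)) == 2, 1, -1) else y
  for (ci in seq_along(candidates)) {
    stat[ci] <- if (da) mean(sign(preds[, ci]) == sign(yn))
                else sqrt(mean((preds[, ci] - yn)^2))
  }
  list(stat = stat, reshuffled = fl$reshuffled)
}

# PLS fit on data scaled once globally (compatibility path: skips refitting
# the z-scoring inside the fold).
pls_fit_prescaled <- function(X, y, A) {
  n <- nrow(X)
  da <- is.factor(y) || is.character(y)
  yn <- if (da) ifelse(as.integer(factor(y)) == 2, 1, -1) else as.numeric(y)
  eng <- pls1_engine(X, yn - mean(yn), A)
  m <- structure(c(eng, list(
    x_center = rep(0, ncol(X)), x_scale = rep(1, ncol(X)),
    y_center = mean(yn), y_scale = 1,
    levels = if (da) levels(factor(y)) else NULL, da = da, y = yn,
    X_scaled = X, var_names = colnames(X), orthogonal = NULL)),
    class = "pls_model")
  m$vip <- vip_scores(m)
  m
}

#' Repeated k-fold cross-validation for LV selection
#'
#' Runs `repeats` independent random k-fold partitions; in each, candidate
#' models with 1, 2 and 3 latent variables are fitted on the training folds
#' (z-scoring refit inside each training fold) and evaluated on the held-out
#' folds: RMSECV for regression, classification accuracy for PLS-DA. The
#' chosen LV count minimizes the mean RMSECV (or maximizes mean accuracy);
#' ties break toward fewer LVs.
#'
#' @param X samples x predictors matrix.
#' @param y response (numeric, or two-level factor for PLS-DA).
#' @param candidates candidate LV counts.
#' @param repeats number of independent CV repeats.
#' @param k fold count; default from [choose_k()].
#' @param seed integer seed for the fold randomness.
#' @param global_scaling use one global z-scoring instead of refitting per
#'   training fold (compatibility flag; default FALSE, leakage-safe).
#' @return A `cv_result`: `stats` (repeats x candidates matrix), `mean`
#'   per candidate, `chosen_A`, `k`, `metric` ("rmsecv" or "accuracy"),
#'   `reshuffles` (PLS-DA fold redraws).
#' @export
cross_validate <- function(X, y, candidates = 1:3, repeats = 100,
                           k = choose_k(nrow(X)), seed = 1L,
                           global_scaling = FALSE) {
  X <- as.matrix(X)
  da <- is.factor(y) || is.character(y) || is.logical(y)
  if (da) y <- factor(y)
  if (global_scaling) X <- zscore_fit_apply(X)$X
  with_seed(seed, {
    stats <- matrix(NA_real_, repeats, length(candidates))
    resh <- 0L
    for (r in seq_len(repeats)) {
      one <- cv_once(X, y, candidates, k, da, global_scaling)
      stats[r, ] <- one$stat
      resh <- resh + one$reshuffled
    }
    mu <- colMeans(stats)
    best <- if (da) which(mu == max(mu))[1] else which(mu == min(mu))[1]
    structure(list(stats = stats, mean = mu, candidates = candidates,
                   chosen_A = candidates[best], k = k,
                   metric = if (da) "accuracy" else "rmsecv",
                   repeats = repeats, reshuffles = resh),
              class = "cv_result")
  })
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Cross-validation (%d repeats, %d folds): mean %s per LV count\n",
              x$repeats, x$k, x$metric))
  print(setNames(round(x$mean, 4), paste0("A=", x$candidates)))
  cat(sprintf("Chosen number of LVs: %d\n", x$chosen_A))
  invisible(x)
}

#' Permutation significance of a cross-validated PLS model
#'
#' Builds a null distribution by shuffling the response and recomputing the
#' same cross-validated statistic (RMSECV or accuracy) with the chosen LV
#' count, then standardizes the observed statistic:
#' \deqn{Z = (x_{Model} - \mu_{Null}) / \sigma_{Null}}
#' The p-value is the standard-normal tail probability in the favorable
#' direction (lower RMSECV / higher accuracy is better).
#'
#' @param X,y data as in [cross_validate()].
#' @param chosen_A latent-variable count of the reported model.
#' @param n_perm number of permutations.
#' @param cv_repeats CV repeats used for the statistic (both observed and
#'   per permutation).
#' @param k fold count; default from [choose_k()].
#' @param seed integer seed.
#' @return A `permutation_result`: `x_model`, `mu_null`, `sigma_null`, `Z`,
#'   `p`, `null` (the null statistics), `n_perm`, `metric`.
#' @export
permutation_test <- function(X, y, chosen_A, n_perm = 1000,
                             cv_repeats = 10, k = choose_k(nrow(X)),
                             seed = 1L) {
  X <- as.matrix(X)
  da <- is.factor(y) || is.character(y) || is.logical(y)
  if (da) y <- factor(y)
  with_seed(seed, {
    obs <- mean(vapply(seq_len(cv_repeats), function(r)
      cv_once(X, y, chosen_A, k, da)$stat, numeric(1)))
    null <- vapply(seq_len(n_perm), function(b) {
      yp <- sample(y)
      mean(vapply(seq_len(cv_repeats), function(r)
        cv_once(X, yp, chosen_A, k, da)$stat, numeric(1)))
    }, numeric(1))
    perm_zscore(obs, null, if (da) "accuracy" else "rmsecv", n_perm)
  })
}

# Z and normal-tail p from an observed statistic and its null sample.
perm_zscore <- function(x_model, null, metric, n_perm = length(null)) {
  mu <- mean(null); s <- sd(null)
  if (s < 1e-12) {
    return(structure(list(x_model = x_model, mu_null = mu, sigma_null = s,
                          Z = NA_real_, p = NA_real_, undefined = TRUE,
                          null = null, n_perm = n_perm, metric = metric),
                     class = "permutation_result"))
  }
  Z <- (x_model - mu) / s
  p <- if (metric == "accuracy") pnorm(Z, lower.tail = FALSE) else pnorm(Z)
  structure(list(x_model = x_model, mu_null = mu, sigma_null = s, Z = Z,
                 p = p, undefined = FALSE, null = null, n_perm = n_perm,
                 metric = metric),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  if (x$undefined) {
    cat("Permutation test: degenerate null (sigma = 0); Z undefined\n")
  } else {
    cat(sprintf("Permutation test (%d permutations, %s): observed %.4g, null %.4g +/- %.4g\n",
                x$n_perm, x$metric, x$x_model, x$mu_null, x$sigma_null))
    cat(sprintf("  Z = %.3f, p = %.4g\n", x$Z, x$p))
  }
  invisible(x)
}

#' Cytokine signature report
#'
#' Ranks analytes whose VIP exceeds the threshold, with the signed loading
#' of the first (predictive) latent variable: positive loadings rise with
#' the response (up-regulated with age/disease), negative fall.
#'
#' @param model an orthogonalized `pls_model` (see [orthogonalize()]; a
#'   plain model is accepted and orthogonalized first).
#' @param threshold VIP threshold (default 1: greater-than-average
#'   contribution).
#' @return data.frame: analyte, vip, lv1_loading, direction ("up"/"down"),
#'   ordered by decreasing VIP.
#' @export
signature_report <- function(model, threshold = 1) {
  stopifnot(inherits(model, "pls_model"))
  if (is.null(model$orthogonal)) model <- orthogonalize(model)
  keep <- which(model$vip > threshold)
  load1 <- model$loadings[, 1]
  out <- data.frame(analyte = model$var_names[keep],
                    vip = model$vip[keep],
                    lv1_loading = load1[keep],
                    direction = ifelse(load1[keep] >= 0, "up", "down"))
  out <- out[order(-out$vip), ]
  rownames(out) <- NULL
  out
}
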