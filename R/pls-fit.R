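#' Z-scoring fitted on training data
#'
#' Columns are centered and scaled to unit variance using statistics of the
#' training matrix; the same statistics are applied to any other matrix
#' (leakage-safe cross-validation scaling).
#'
#' @param X_train numeric training matrix (rows = samples).
#' @param X_apply matrix to transform with the training statistics;
#'   defaults to `X_train`.
#' @return list with `X` (scaled `X_apply`), `center`, `scale`, and
#'   `unscale(Z)` to invert.
#' @export
zscore_fit_apply <- function(X_train, X_apply = X_train) {
  X_train <- as.matrix(X_train); X_apply <- as.matrix(X_apply)
  mu <- colMeans(X_train)
  sdv <- apply(X_train, 2, sd)
  bad <- sdv < 1e-12
  if (any(bad))
    stop("constant column(s) in training data: ",
         paste(colnames(X_train)[bad] %||% which(bad), collapse = ", "))
  Z <- sweep(sweep(X_apply, 2, mu), 2, sdv, "/")
  list(X = Z, center = mu, scale = sdv,
       unscale = function(z) sweep(sweep(z, 2, sdv, "*"), 2, -mu))
}

# Minimal PLS1 engine on pre-scaled X and centered y. For a univariate
# response the NIPALS inner loop converges in a single step, so each
# component is computed in closed form: w = X'y/||X'y||, t = Xw,
# p = X't/t't, q = y't/t't, then X and y are deflated.
pls1_engine <- function(X, y, A) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  q <- numeric(A)
  Xd <- X; yd <- y
  for (a in seq_len(A)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { # no covariance left; zero-pad remaining components
      A <- a - 1L
      break
    }
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    pv <- crossprod(Xd, t) / tt
    qv <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, pv)
    yd <- yd - qv * t
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t; q[a] <- qv
  }
  if (A == 0) stop("response has no covariance with any predictor")
  W <- W[, seq_len(A), drop = FALSE]; P <- P[, seq_len(A), drop = FALSE]
  Tm <- Tm[, seq_len(A), drop = FALSE]; q <- q[seq_len(A)]
  # regression coefficients on the scaled scale: B = W (P'W)^-1 q
  B <- W %*% solve(crossprod(P, W), q)
  list(weights = W, loadings = P, scores = Tm, y_loadings = q, coef = B,
       ncomp = A)
}

#' Partial least squares regression / discriminant analysis
#'
#' From-scratch NIPALS PLS1 for a univariate response: age in months for
#' regression (PLSR) or a two-level class for discrimination (PLS-DA, coded
#' -1/+1 internally with class assignment by sign). Predictors are z-scored
#' (training statistics stored in the model) and the response is centered
#' (and, for PLSR, scaled).
#'
#' @param X numeric samples x predictors matrix.
#' @param y numeric response, or a factor/character with two levels
#'   (PLS-DA).
#' @param ncomp number of latent variables (A), at most `min(n - 1, p)`.
#' @param scale_y scale the response to unit variance (PLSR only).
#' @return A `pls_model` with components `weights`, `loadings` (X),
#'   `scores`, `y_loadings`, `coef`, `vip`, scaling parameters, and for
#'   PLS-DA the class `levels`. Methods: [print.pls_model()],
#'   [summary.pls_model()], `coef`, `predict`, `fitted`, `residuals`,
#'   `plot`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40 * 8), 40, 8)
#' y <- X[, 1] - X[, 2] + rnorm(40, 0, 0.1)
#' m <- pls_fit(X, y, ncomp = 2)
#' summary(m)
#' @export
pls_fit <- function(X, y, ncomp = 1, scale_y = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  da <- is.factor(y) || is.character(y) || is.logical(y)
  levels <- NULL
  if (da) {
    y <- factor(y)
    if (nlevels(y) != 2) stop("PLS-DA supports exactly two classes")
    levels <- levels(y)
    yn <- ifelse(as.integer(y) == 2, 1, -1)
  } else yn <- as.numeric(y)
  n <- nrow(X)
  if (length(yn) != n) stop("length(y) must equal nrow(X)")
  if (ncomp > min(n - 1, ncol(X)))
    stop("ncomp exceeds min(n - 1, ncol(X))")
  sc <- zscore_fit_apply(X)
  y_center <- mean(yn)
  y_scale <- if (!da && scale_y) sd(yn) else 1
  if (y_scale < 1e-12) stop("constant response")
  ys <- (yn - y_center) / y_scale
  eng <- pls1_engine(sc$X, ys, ncomp)
  m <- structure(c(eng, list(
    x_center = sc$center, x_scale = sc$scale,
    y_center = y_center, y_scale = y_scale,
    levels = levels, da = da, y = yn, X_scaled = sc$X,
    var_names = colnames(X), orthogonal = NULL)),
    class = "pls_model")
  m$vip <- vip_scores(m)
  m
}

#' Variable importance in projection
#'
#' Wold VIP over the predictive components:
#' \deqn{VIP_f = \sqrt{p \, \frac{\sum_a SSY_a (w_{fa}/\|w_a\|)^2}{\sum_a SSY_a}}}
#' where `SSY_a = q_a^2 t_a' t_a` is the response variance explained by
#' component a. The mean squared VIP is identically 1.
#'
#' @param model a fitted `pls_model`.
#' @return Named numeric VIP vector (one per predictor).
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  W <- model$weights
  ssy <- model$y_loadings^2 * colSums(model$scores^2)
  wn2 <- sweep(W^2, 2, colSums(W^2), "/")
  p <- nrow(W)
  v <- sqrt(p * as.vector(wn2 %*% ssy) / sum(ssy))
  names(v) <- model$var_names
  v
}

#' @export
print.pls_model <- function(x, ...) {
  kind <- if (x$da) "PLS-DA" else "PLSR"
  if (!is.null(x$orthogonal))
    kind <- paste0("orthogonalized ", kind,
                   sprintf(" (1 predictive + %d orthogonal)",
                           ncol(x$orthogonal$scores)))
  cat(sprintf("%s model: %d samples, %d predictors, %d latent variable(s)\n",
              kind, nrow(x$scores), length(x$x_center), x$ncomp))
  cat(sprintf("  %d predictor(s) with VIP > 1\n", sum(x$vip > 1)))
  invisible(x)
}

#' @export
summary.pls_model <- function(object, ...) {
  ssy <- object$y_loadings^2 * colSums(object$scores^2)
  tot <- sum(((object$y - object$y_center) / object$y_scale)^2)
  comp <- data.frame(LV = seq_len(object$ncomp),
                     R2Y_cum = cumsum(ssy) / tot)
  fit <- fitted(object)
  out <- list(components = comp, vip = sort(object$vip, decreasing = TRUE),
              da = object$da)
  if (object$da) out$accuracy <- mean(fit == object$levels[
    ifelse(object$y > 0, 2, 1)])
  else out$rmse <- sqrt(mean((fit - object$y)^2))
  class(out) <- "summary.pls_model"
  out
}

#' @export
print.summary.pls_model <- function(x, ...) {
  cat("Latent variables:\n"); print(x$components, row.names = FALSE)
  if (x$da) cat(sprintf("Training accuracy: %.3f\n", x$accuracy))
  else cat(sprintf("Training RMSE: %.3f\n", x$rmse))
  cat("Top VIP predictors:\n")
  print(round(head(x$vip, 8), 3))
  invisible(x)
}

#' @export
coef.pls_model <- function(object, ...) {
  # coefficients on the original predictor scale
  b <- as.vector(object$coef) * object$y_scale / object$x_scale
  names(b) <- object$var_names
  b
}

#' Predict from a PLS model
#'
#' @param object a `pls_model`.
#' @param newdata samples x predictors matrix (training data when omitted).
#' @param type "response" (numeric prediction; the latent regression value
#'   for PLS-DA) or "class" (PLS-DA only: nearest coded class by sign).
#' @param ... unused.
#' @return Numeric predictions or a factor of classes.
#' @export
predict.pls_model <- function(object, newdata = NULL,
                              type = c("response", "class"), ...) {
  type <- match.arg(type)
  Z <- if (is.null(newdata)) object$X_scaled
       else sweep(sweep(as.matrix(newdata), 2, object$x_center), 2,
                  object$x_scale, "/")
  if (!is.null(object$orthogonal)) {
    o <- object$orthogonal
    for (k in seq_len(ncol(o$scores))) {
      t_o <- Z %*% o$weights[, k]
      Z <- Z - tcrossprod(t_o, o$loadings[, k])
    }
  }
  yhat <- as.vector(Z %*% object$coef) * object$y_scale + object$y_center
  if (type == "class") {
    if (!object$da) stop("type = 'class' requires a PLS-DA model")
    return(factor(object$levels[ifelse(yhat > 0, 2, 1)],
                  levels = object$levels))
  }
  yhat
}

#' @export
fitted.pls_model <- function(object, ...) {
  if (object$da) predict(object, type = "class") else predict(object)
}

#' @export
residuals.pls_model <- function(object, ...) {
  if (object$da) stop("residuals are defined for PLSR models only")
  object$y - predict(object)
}

#' Scores plot of a PLS model
#'
#' Plots the first two latent-variable scores (or score vs response for
#' one-component models), colored by class for PLS-DA.
#'
#' @param x a `pls_model`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pls_model <- function(x, ...) {
  t1 <- x$scores[, 1]
  col <- if (x$da) ifelse(x$y > 0, "firebrick", "steelblue") else "black"
  if (x$ncomp >= 2) {
    graphics::plot(t1, x$scores[, 2], xlab = "LV1 scores",
                   ylab = "LV2 scores", col = col, pch = 19, ...)
  } else {
    graphics::plot(t1, x$y, xlab = "LV1 scores", ylab = "response",
                   col = col, pch = 19, ...)
  }
  invisible(x)
}
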