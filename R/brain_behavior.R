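#' Symptom prediction from network deviations
#'
#' Network-level deviations (covariate-residualized) predict a symptom
#' subscore through an L2-regularized linear support vector regression,
#' evaluated by leave-one-out cross-validation. The model minimizes
#' 0.5 ||w||^2 + C sum_i max(0, |w.x_i + b - y_i| - eps). Significance is a
#' permutation test: targets are shuffled, the whole LOOCV is rerun, and p
#' is the fraction of permuted correlations R_p exceeding the observed R.
#'
#' @name brain_behavior
NULL

#' Fit a linear epsilon-SVR
#'
#' @param x numeric subjects x features matrix.
#' @param y numeric targets.
#' @param cost regularization constant C (default 1).
#' @param epsilon insensitive-tube half width (default 0.1).
#' @return list with `w` (named weight vector) and `b` (intercept).
#' @export
fit_svr <- function(x, y, cost = 1, epsilon = 0.1) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 subjects")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in features or targets")
  fit <- e1071::svm(x, y, type = "eps-regression", kernel = "linear",
                    cost = cost, epsilon = epsilon, scale = FALSE,
                    fitted = FALSE)
  if (is.null(fit$coefs) || nrow(fit$coefs) == 0L) {
    # every residual inside the epsilon tube: flat model at the tube center
    w <- rep(0, ncol(x))
    b <- if (length(fit$rho)) -fit$rho else mean(y)
  } else {
    w <- drop(t(fit$coefs) %*% fit$SV)
    if (length(w) != ncol(x)) w <- rep(0, ncol(x))
    b <- -fit$rho
  }
  names(w) <- colnames(x)
  list(w = w, b = b)
}

svr_predict <- function(model, x) drop(as.matrix(x) %*% model$w + model$b)

#' Leave-one-out cross-validated SVR prediction
#'
#' Each subject is predicted by a model trained on the remaining n-1; the
#' training fold is standardized (mean/sd of the training subjects only)
#' and the held-out subject transformed with the training statistics, so no
#' information leaks. R is the Pearson correlation of observed vs
#' out-of-fold predictions; weights are averaged over the n fold models (on
#' the standardized scale).
#'
#' @inheritParams fit_svr
#' @param standardize standardize features within each training fold.
#' @return list (class `prediction_result`) with `observed`, `predicted`,
#'   `r`, `weights`, and the hyperparameters.
#' @export
loocv_predict <- function(x, y, cost = 1, epsilon = 0.1, standardize = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L) stop("LOOCV needs at least 3 subjects")
  if (stats::sd(y) == 0) stop("zero-variance targets: R is undefined")
  pred <- numeric(n)
  wsum <- numeric(ncol(x))
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]; ytr <- y[-i]
    xte <- x[i, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(xtr); sdev <- apply(xtr, 2L, stats::sd)
      sdev[sdev == 0] <- 1
      xtr <- sweep(sweep(xtr, 2L, mu), 2L, sdev, "/")
      xte <- sweep(sweep(xte, 2L, mu), 2L, sdev, "/")
    }
    m <- fit_svr(xtr, ytr, cost, epsilon)
    pred[i] <- svr_predict(m, xte)
    wsum <- wsum + m$w
  }
  structure(list(observed = y, predicted = pred,
                 r = stats::cor(y, pred),
                 weights = stats::setNames(wsum / n, colnames(x)),
                 cost = cost, epsilon = epsilon,
                 standardize = standardize),
            class = "prediction_result")
}

#' Permutation test of the LOOCV correlation
#'
#' Targets are shuffled `n_perm` times; the full LOOCV is rerun on each
#' shuffle to obtain the null correlations R_p. The reported p is the
#' literal ratio #(R_p > R) / n_perm; the (b+1)/(n+1) estimator is also
#' returned, and `p_zero` flags an exact zero.
#'
#' @inheritParams loocv_predict
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for the shuffles.
#' @return list (class `prediction_result`) extending [loocv_predict()]'s
#'   with `p_perm`, `p_perm_plus1`, `p_zero`, `n_perm`, `r_perm`.
#' @export
permutation_test <- function(x, y, cost = 1, epsilon = 0.1,
                             standardize = TRUE, n_perm = 1000L,
                             seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  obs <- loocv_predict(x, y, cost, epsilon, standardize)
  set.seed(seed)
  r_perm <- vapply(seq_len(n_perm), function(b) {
    yp <- sample(y)
    if (stats::sd(yp) == 0) return(NA_real_)
    loocv_predict(x, yp, cost, epsilon, standardize)$r
  }, numeric(1))
  exceed <- sum(r_perm > obs$r, na.rm = TRUE)
  obs$r_perm <- r_perm
  obs$n_perm <- as.integer(n_perm)
  obs$p_perm <- exceed / n_perm
  obs$p_perm_plus1 <- (exceed + 1) / (n_perm + 1)
  obs$p_zero <- exceed == 0L
  obs$seed <- seed
  obs
}
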