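# REML variance components for the polygenic mixed models.
#
# Model: y = X b + sum_k u_k + e, u_k ~ N(0, s2_k K_k), e ~ N(0, s2_e I).
# One kinship (additive model): solved by spectral decomposition of K and
# 1-D optimisation of the variance ratio. Two kinships (additive+dominance):
# bounded derivative-free optimisation over the two log variance ratios with
# multiple starts.

# Restricted log-likelihood (Harville) profiled over s2_e, at given ratios.
# Returns list(loglik_reml, loglik_ml, s2e, beta).
reml_profile <- function(d_or_H, yt, Xt, n, p, logdet_XtX, chol_mode = FALSE) {
  if (!chol_mode) {
    d <- d_or_H
    W <- 1 / d
    XtWX <- crossprod(Xt, W * Xt)
    XtWy <- crossprod(Xt, W * yt)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
    r <- yt - Xt %*% beta
    q <- sum(W * r^2)
    logdet_H <- sum(log(d))
    logdet_XtWX <- 2 * sum(log(diag(ch)))
  } else {
    H <- d_or_H
    chH <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(chH)) return(NULL)
    Hi_y <- backsolve(chH, forwardsolve(t(chH), yt))
    Hi_X <- backsolve(chH, forwardsolve(t(chH), Xt))
    XtWX <- crossprod(Xt, Hi_X)
    XtWX <- (XtWX + t(XtWX)) / 2
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xt, Hi_y)))
    r <- yt - Xt %*% beta
    Hi_r <- backsolve(chH, forwardsolve(t(chH), r))
    q <- sum(r * Hi_r)
    logdet_H <- 2 * sum(log(diag(chH)))
    logdet_XtWX <- 2 * sum(log(diag(ch)))
  }
  s2e <- q / (n - p)
  if (!is.finite(s2e) || s2e <= 0) return(NULL)
  ll_reml <- -0.5 * ((n - p) * (log(2 * pi * s2e) + 1) + logdet_H +
                       logdet_XtWX - logdet_XtX)
  if (!is.finite(ll_reml)) return(NULL)
  ll_ml <- -0.5 * (n * log(2 * pi * s2e) + logdet_H + q / s2e)
  list(loglik_reml = ll_reml, loglik_ml = ll_ml, s2e = s2e, beta = beta)
}

#' REML variance components for a polygenic mixed model
#'
#' Estimates the variance components of `y = X b + u_a (+ u_d) + e` with
#' `u_a ~ N(0, sigma_a2 K_a)`, optionally `u_d ~ N(0, sigma_d2 K_d)` and
#' `e ~ N(0, sigma_e2 I)`, by restricted maximum likelihood. With one
#' kinship the restricted likelihood is profiled on the spectral
#' decomposition of `K_a` and maximised over the variance ratio by 1-D
#' optimisation; with two kinships it is maximised over both log variance
#' ratios by Nelder-Mead from 4 starting points.
#'
#' @param y Numeric phenotype vector.
#' @param X Fixed-effect design matrix (including the intercept). A plain
#'   intercept is used when `NULL`.
#' @param kinships List of one ([kinship()] additive) or two (additive then
#'   dominance) kinship objects or matrices.
#' @param eig Optional precomputed `eigen()` of the single kinship matrix
#'   (ignored with two kinships).
#' @return A `beet_vc` object: list with `sigma_a2`, `sigma_d2`, `sigma_e2`,
#'   `loglik_reml`, `loglik_ml`, `beta`, `n`, `p`.
#' @export
fit_reml <- function(y, X = NULL, kinships, eig = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != n) rlang::abort("`X` and `y` sizes disagree.")
  p <- ncol(X)
  if (qr(X)$rank < p) rlang::abort("Singular fixed-effect design.")
  if (n <= p) rlang::abort("Need more observations than fixed effects.")
  if (inherits(kinships, "beet_kinship")) kinships <- list(kinships)
  Ks <- lapply(kinships, function(k) if (inherits(k, "beet_kinship")) k$K else as.matrix(k))
  for (K in Ks) {
    if (nrow(K) != n) rlang::abort("Kinship dimension disagrees with `y`.")
    # PSD check deferred to the spectral/Cholesky step for speed
  }
  logdet_XtX <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)
  floor_s2e <- 1e-8 * max(var(y), .Machine$double.eps)

  if (length(Ks) == 1L) {
    ev <- eig %||% eigen(Ks[[1]], symmetric = TRUE)
    lam <- ev$values
    if (min(lam) < -1e-8 * max(sum(lam), 1)) {
      rlang::abort("Kinship matrix is not positive semidefinite.")
    }
    lam <- pmax(lam, 0)
    yt <- crossprod(ev$vectors, y)
    Xt <- crossprod(ev$vectors, X)
    obj <- function(log_ratio) {
      pr <- reml_profile(exp(log_ratio) * lam + 1, yt, Xt, n, p, logdet_XtX)
      if (is.null(pr)) return(-1e100)
      pr$loglik_reml
    }
    op <- optimize(obj, interval = c(-25, 25), maximum = TRUE, tol = 1e-9)
    cand <- c(op$maximum, -25, 25)
    vals <- vapply(cand, obj, numeric(1))
    best <- cand[which.max(vals)]
    ratio <- exp(best)
    pr <- reml_profile(ratio * lam + 1, yt, Xt, n, p, logdet_XtX)
    s2e <- pr$s2e
    warned <- FALSE
    if (s2e < floor_s2e) {
      s2e <- floor_s2e
      warned <- TRUE
      rlang::warn("Residual variance hit its positivity floor.")
    }
    out <- list(sigma_a2 = ratio * s2e, sigma_d2 = 0, sigma_e2 = s2e,
                loglik_reml = pr$loglik_reml, loglik_ml = pr$loglik_ml,
                beta = setNames(as.vector(pr$beta), colnames(X)), n = n, p = p,
                floored = warned)
  } else if (length(Ks) == 2L) {
    Ka <- Ks[[1]]; Kd <- Ks[[2]]
    obj <- function(lr) {
      if (any(!is.finite(lr)) || any(abs(lr) > 30)) return(-1e100)
      H <- exp(lr[1]) * Ka + exp(lr[2]) * Kd + diag(1, n)
      pr <- reml_profile(H, y, X, n, p, logdet_XtX, chol_mode = TRUE)
      if (is.null(pr)) return(-1e100)
      pr$loglik_reml
    }
    # coarse log-grid screen, then Nelder-Mead polish from the best corners
    coarse <- c(-10, -6, -3, -1, 1, 3)
    grid_pts <- expand.grid(a = coarse, d = coarse)
    grid_val <- vapply(seq_len(nrow(grid_pts)), function(i) {
      obj(c(grid_pts$a[i], grid_pts$d[i]))
    }, numeric(1))
    top <- order(grid_val, decreasing = TRUE)[1:2]
    starts <- c(lapply(top, function(i) c(grid_pts$a[i], grid_pts$d[i])),
                list(c(-4, -4), c(0, 0)))
    best <- NULL
    for (st in starts) {
      op <- tryCatch(
        optim(st, obj, method = "Nelder-Mead",
              control = list(fnscale = -1, reltol = 1e-10, maxit = 500)),
        error = function(e) NULL)
      if (!is.null(op) && (is.null(best) || op$value > best$value)) best <- op
    }
    if (is.null(best)) rlang::abort("Two-kinship REML failed to converge.")
    # one refinement pass from the incumbent
    op2 <- tryCatch(
      optim(best$par, obj, method = "Nelder-Mead",
            control = list(fnscale = -1, reltol = 1e-12, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(op2) && op2$value > best$value) best <- op2
    lr <- pmin(pmax(best$par, -30), 30)
    pr <- NULL
    for (k in 0:20) {
      H <- exp(lr[1]) * Ka + exp(lr[2]) * Kd + diag(1, n)
      pr <- reml_profile(H, y, X, n, p, logdet_XtX, chol_mode = TRUE)
      if (!is.null(pr)) break
      lr <- lr * 0.8
    }
    if (is.null(pr)) rlang::abort("Two-kinship REML failed to converge.")
    s2e <- pr$s2e
    warned <- FALSE
    if (s2e < floor_s2e) {
      s2e <- floor_s2e
      warned <- TRUE
      rlang::warn("Residual variance hit its positivity floor.")
    }
    out <- list(sigma_a2 = exp(lr[1]) * s2e, sigma_d2 = exp(lr[2]) * s2e,
                sigma_e2 = s2e,
                loglik_reml = pr$loglik_reml, loglik_ml = pr$loglik_ml,
                beta = setNames(as.vector(pr$beta), colnames(X)), n = n, p = p,
                floored = warned)
  } else {
    rlang::abort("`kinships` must hold one or two kinship matrices.")
  }
  structure(out, class = "beet_vc")
}

#' @export
print.beet_vc <- function(x, ...) {
  cat(sprintf("<beet_vc> sigma_a2 = %.4g, sigma_d2 = %.4g, sigma_e2 = %.4g, REML loglik = %.3f\n",
              x$sigma_a2, x$sigma_d2, x$sigma_e2, x$loglik_reml))
  invisible(x)
}

#' @export
tidy.beet_vc <- function(x, ...) {
  tibble::tibble(component = c("sigma_a2", "sigma_d2", "sigma_e2"),
                 estimate = c(x$sigma_a2, x$sigma_d2, x$sigma_e2))
}
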