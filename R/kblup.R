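#' Fit a multi-kernel linear mixed model by REML
#'
#' Fits y = 1*mu + sum_c u_c + e with u_c ~ N(0, K_c sigma2_c) and
#' e ~ N(0, I sigma2_e), estimating the variance components by restricted
#' maximum likelihood with the intercept profiled out. This one engine
#' covers GBLUP (one genomic kernel), TBLUP (one transcriptomic kernel),
#' GTBLUP, GTIBLUP (genomic + transcriptomic + Hadamard interaction), and
#' the GO-partitioned two- and four-kernel models.
#'
#' Single-kernel models are maximized exactly on the heritability-proportion
#' profile after a one-time eigendecomposition of the kernel. Multi-kernel
#' models use average-information REML steps with step-halving and an EM
#' fallback whenever a step leaves the feasible region or degrades the
#' restricted likelihood; components are constrained to be non-negative and
#' clamps at zero are flagged, so every fitted covariance matrix is a valid
#' covariance.
#'
#' @param y named numeric vector of phenotypes (training lines).
#' @param kernels a single \code{omni_kernel}, a (optionally named) list of
#'   them, or plain n x n matrices with line-id dimnames; each is aligned to
#'   \code{names(y)}.
#' @param tol convergence tolerance on the relative change in restricted
#'   log-likelihood (default 1e-8).
#' @param max_iter maximum REML iterations (default 200).
#' @return an object of class \code{"kblup"}: list with \code{sigma2}
#'   (named per-kernel variance estimates), \code{sigma2_e}, \code{mu_hat}
#'   (GLS intercept), \code{restricted_loglik}, \code{converged},
#'   \code{n_iter}, \code{boundary} (per-component zero-clamp flags),
#'   \code{y}, \code{kernels} (training blocks), \code{line_ids}.
#' @seealso \code{\link{blup_predict}}, \code{\link{variance_proportions}},
#'   \code{\link{run_model_cv}}
#' @examples
#' set.seed(1)
#' W <- matrix(sample(c(0, 2), 50 * 80, TRUE), 50,
#'             dimnames = list(paste0("L", 1:50), NULL))
#' K <- linear_kernel(standardize_columns(W))
#' y <- setNames(rnorm(50), rownames(W))
#' fit <- kblup(y, K)
#' summary(fit)
#' @export
kblup <- function(y, kernels, tol = 1e-8, max_iter = 200) {
  if (is.null(names(y))) stop_ob("'y' must be named by line id")
  y <- y[!is.na(y)]
  n <- length(y)
  if (n < 3) stop_ob("need at least 3 phenotyped lines")
  if (stats::var(y) <= 0) stop_ob("'y' has zero sample variance")
  ks <- as_kernel_list(kernels, names(y))
  Ks <- lapply(ks, function(k) k$values[names(y), names(y)])
  labels <- names(ks)

  if (length(Ks) == 1) {
    fit <- reml_single_kernel(y, Ks[[1]], tol)
  } else {
    fit <- reml_ai(y, Ks, tol, max_iter)
  }
  names(fit$sigma2) <- labels
  names(fit$boundary) <- labels
  structure(c(fit, list(y = y, line_ids = names(y), kernels = ks,
                        kernel_labels = labels, n = n)),
            class = "kblup")
}

#' @rdname kblup
#' @export
reml_fit <- function(y, kernels, tol = 1e-8, max_iter = 200) {
  kblup(y, kernels, tol = tol, max_iter = max_iter)
}

# normalize kernel input to a named list of omni_kernel aligned to ids
as_kernel_list <- function(kernels, ids) {
  if (inherits(kernels, "omni_kernel")) kernels <- list(kernels)
  if (inherits(kernels, "kernel_set")) kernels <- unclass(kernels)
  stopifnot(is.list(kernels), length(kernels) >= 1)
  kernels <- lapply(kernels, function(k) {
    if (inherits(k, "omni_kernel")) return(k)
    k <- as.matrix(k)
    if (is.null(rownames(k))) stop_ob("kernel matrices need line-id dimnames")
    new_kernel(k, NA_integer_, "K")
  })
  if (is.null(names(kernels)) || any(!nzchar(names(kernels))))
    names(kernels) <- make.unique(
      vapply(kernels, function(k) k$label, character(1)))
  for (k in kernels) {
    missing <- setdiff(ids, rownames(k$values))
    if (length(missing))
      stop_ob("kernel '%s' lacks lines: %s", k$label,
              paste(utils::head(missing, 5), collapse = ", "))
  }
  kernels
}

# restricted log-likelihood (with constant) for V = sum theta_c K_c + theta_e I
reml_loglik_direct <- function(theta, y, Ks) {
  n <- length(y)
  V <- diag(theta[length(theta)], n)
  for (c in seq_along(Ks)) V <- V + theta[c] * Ks[[c]]
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  logdetV <- 2 * sum(log(diag(R)))
  Vi1 <- backsolve(R, forwardsolve(t(R), rep(1, n)))
  Viy <- backsolve(R, forwardsolve(t(R), y))
  a <- sum(Vi1)
  if (a <= 0) return(-Inf)
  yPy <- sum(y * Viy) - sum(Vi1 * y)^2 / a
  -0.5 * ((n - 1) * log(2 * pi) + logdetV + log(a) + yPy)
}

# exact single-kernel REML via eigendecomposition + 1-D profile over the
# genetic proportion phi = sigma2_g / (sigma2_g + sigma2_e)
reml_single_kernel <- function(y, K, tol) {
  n <- length(y)
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  yt <- drop(crossprod(eg$vectors, y))
  xt <- drop(crossprod(eg$vectors, rep(1, n)))
  prof <- function(phi) {
    v <- phi * d + (1 - phi)
    a <- sum(xt^2 / v)
    yPy0 <- sum(yt^2 / v) - sum(xt * yt / v)^2 / a
    s2 <- yPy0 / (n - 1)
    list(ll = -0.5 * ((n - 1) * (log(2 * pi) + log(s2) + 1) +
                        sum(log(v)) + log(a)),
         s2 = s2)
  }
  opt <- stats::optimize(function(p) prof(p)$ll, c(0, 1 - 1e-8),
                         maximum = TRUE, tol = 1e-10)
  # the interior optimum can sit at the boundary; compare explicitly
  phi <- opt$maximum
  cand <- c(0, phi)
  lls <- vapply(cand, function(p) prof(p)$ll, numeric(1))
  phi <- cand[which.max(lls)]
  pr <- prof(phi)
  list(sigma2 = phi * pr$s2, sigma2_e = (1 - phi) * pr$s2,
       mu_hat = gls_intercept(y, list(K), c(phi * pr$s2, (1 - phi) * pr$s2)),
       restricted_loglik = pr$ll, converged = TRUE, n_iter = 1L,
       boundary = phi < 1e-7)
}

gls_intercept <- function(y, Ks, theta) {
  n <- length(y)
  V <- diag(theta[length(theta)], n)
  for (c in seq_along(Ks)) V <- V + theta[c] * Ks[[c]]
  R <- chol(V)
  Vi1 <- backsolve(R, forwardsolve(t(R), rep(1, n)))
  sum(Vi1 * y) / sum(Vi1)
}

# average-information REML with EM fallback and zero clamping
reml_ai <- function(y, Ks, tol, max_iter) {
  n <- length(y)
  nc <- length(Ks)
  vy <- stats::var(y)
  # each kernel component and the residual starts at var(y)/(n_kernels + 1),
  # so the initial total variance equals the sample variance of y
  theta <- rep(vy / (nc + 1), nc + 1)
  floor_e <- 1e-10 * vy

  eval_state <- function(theta) {
    V <- diag(theta[nc + 1], n)
    for (c in seq_len(nc)) V <- V + theta[c] * Ks[[c]]
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    Vi <- chol2inv(R)
    Vi1 <- Vi %*% rep(1, n)
    a <- sum(Vi1)
    P <- Vi - tcrossprod(Vi1) / a
    Py <- drop(P %*% y)
    yPy <- sum(y * Py)
    ll <- -0.5 * ((n - 1) * log(2 * pi) + 2 * sum(log(diag(R))) +
                    log(a) + yPy)
    list(P = P, Py = Py, ll = ll)
  }

  st <- eval_state(theta)
  if (is.null(st)) stop_ob("non-finite restricted likelihood at initialization")
  ll_old <- st$ll
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    P <- st$P; Py <- st$Py
    q <- vector("list", nc + 1)
    trPK <- numeric(nc + 1)
    for (c in seq_len(nc)) {
      q[[c]] <- drop(Ks[[c]] %*% Py)
      trPK[c] <- sum(P * Ks[[c]])
    }
    q[[nc + 1]] <- Py
    trPK[nc + 1] <- sum(diag(P))
    score <- 0.5 * (vapply(q, function(qc) sum(Py * qc), numeric(1)) - trPK)
    # active set: components clamped at a boundary (zero, or the residual
    # floor) whose score pushes further outward stay fixed this iteration
    # (KKT condition)
    active <- c(theta[seq_len(nc)] > 0 | score[seq_len(nc)] > 0,
                theta[nc + 1] > 2 * floor_e | score[nc + 1] > 0)
    if (!any(active)) {          # every component at its boundary optimum
      converged <- TRUE
      break
    }
    aidx <- which(active)
    AI <- matrix(0, length(aidx), length(aidx))
    Pq <- lapply(q[aidx], function(qc) drop(P %*% qc))
    for (ci in seq_along(aidx))
      for (di in ci:length(aidx))
        AI[ci, di] <- AI[di, ci] <- 0.5 * sum(q[[aidx[ci]]] * Pq[[di]])
    delta_a <- tryCatch(
      solve(AI + diag(1e-12 * max(diag(AI)), length(aidx)), score[aidx]),
      error = function(e) NULL)

    step_ok <- FALSE
    if (!is.null(delta_a)) {
      delta <- numeric(nc + 1)
      delta[aidx] <- delta_a
      lambda <- 1
      for (half in 1:15) {
        cand <- theta + lambda * delta
        cand[seq_len(nc)] <- pmax(cand[seq_len(nc)], 0)
        cand[nc + 1] <- max(cand[nc + 1], floor_e)
        st_new <- eval_state(cand)
        if (!is.null(st_new) && is.finite(st_new$ll) &&
            st_new$ll >= ll_old - 1e-12) {
          theta <- cand; st <- st_new; step_ok <- TRUE
          break
        }
        lambda <- lambda / 2
      }
    }
    if (!step_ok) {
      # EM update: guaranteed ascent, slow near the optimum
      em <- theta
      for (c in seq_len(nc + 1))
        em[c] <- theta[c] + theta[c]^2 * (sum(Py * q[[c]]) - trPK[c]) / n
      em[seq_len(nc)] <- pmax(em[seq_len(nc)], 0)
      em[nc + 1] <- max(em[nc + 1], floor_e)
      st_new <- eval_state(em)
      if (is.null(st_new) || !is.finite(st_new$ll)) {
        break
      }
      theta <- em; st <- st_new
    }
    # converged when the likelihood is flat AND no interior score remains
    kkt <- max(abs(score[aidx])) < 1e-5 * (abs(ll_old) + 1)
    if (abs(st$ll - ll_old) < tol * (abs(ll_old) + 1) && (step_ok || kkt)) {
      converged <- TRUE
      ll_old <- st$ll
      break
    }
    ll_old <- st$ll
  }
  if (!is.finite(st$ll)) stop_ob("non-finite restricted likelihood")
  list(sigma2 = theta[seq_len(nc)], sigma2_e = theta[nc + 1],
       mu_hat = gls_intercept(y, Ks, theta),
       restricted_loglik = st$ll, converged = converged, n_iter = iter,
       boundary = theta[seq_len(nc)] <= 1e-8 * vy)
}

#' Per-component variance proportions
#'
#' Each fitted component's variance divided by the total (all kernel
#' components plus residual), the training-set variance partition reported
#' for every model; the residual proportion is included so proportions sum
#' to 1.
#'
#' @param fit a \code{\link{kblup}} fit.
#' @return named numeric vector of proportions (components then
#'   \code{"residual"}), summing to 1.
#' @export
variance_proportions <- function(fit) {
  stopifnot(inherits(fit, "kblup"))
  if (!fit$converged)
    warn_ob("variance proportions from a non-converged fit")
  tot <- sum(fit$sigma2) + fit$sigma2_e
  p <- c(fit$sigma2, residual = fit$sigma2_e) / tot
  p
}

#' BLUP prediction of held-out lines
#'
#' Computes yhat_test = mu + C V^-1 (y_train - mu) where
#' V = sum_c sigma2_c K_c[train, train] + sigma2_e I,
#' C = sum_c sigma2_c K_c[test, train], and mu is the GLS intercept under
#' V — the conditional mean of the test phenotypes under the fitted
#' multivariate-normal model. If V is numerically singular its diagonal is
#' jittered by 1e-8 tr(V)/n with a warning.
#'
#' @param fit a \code{\link{kblup}} fit (defines the variance components).
#' @param kernels_full kernels on all lines (same structure and order as
#'   those used in the fit).
#' @param train_ids,test_ids disjoint line-id vectors; \code{train_ids}
#'   defaults to the fit's lines.
#' @param y_train training phenotypes, default the fit's \code{y}.
#' @return named numeric vector of predictions for \code{test_ids}.
#' @export
blup_predict <- function(fit, kernels_full, test_ids,
                         train_ids = fit$line_ids, y_train = fit$y) {
  stopifnot(inherits(fit, "kblup"))
  if (length(intersect(train_ids, test_ids)))
    stop_ob("test and training lines overlap")
  ks <- as_kernel_list(kernels_full, c(train_ids, test_ids))
  if (length(ks) != length(fit$sigma2))
    stop_ob("kernel structure differs from the fitted model")
  nt <- length(train_ids)
  V <- diag(fit$sigma2_e, nt)
  C <- matrix(0, length(test_ids), nt)
  for (c in seq_along(ks)) {
    V <- V + fit$sigma2[c] * ks[[c]]$values[train_ids, train_ids]
    C <- C + fit$sigma2[c] * ks[[c]]$values[test_ids, train_ids, drop = FALSE]
  }
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) {
    warn_ob("training covariance numerically singular; jittering diagonal")
    V <- V + diag(1e-8 * sum(diag(V)) / nt, nt)
    R <- chol(V)
  }
  y_train <- y_train[train_ids]
  Vi1 <- backsolve(R, forwardsolve(t(R), rep(1, nt)))
  mu <- sum(Vi1 * y_train) / sum(Vi1)
  alpha <- backsolve(R, forwardsolve(t(R), y_train - mu))
  stats::setNames(drop(mu + C %*% alpha), test_ids)
}

#' @method print kblup
#' @export
print.kblup <- function(x, ...) {
  cat(sprintf("Multi-kernel BLUP fit (REML), n = %d lines\n", x$n))
  comp <- c(x$sigma2, residual = x$sigma2_e)
  cat("Variance components:\n")
  for (i in seq_along(comp))
    cat(sprintf("  %-12s %.6g%s\n", names(comp)[i], comp[i],
                if (i <= length(x$boundary) && isTRUE(x$boundary[i]))
                  " (at boundary)" else ""))
  cat(sprintf("Intercept: %.6g   restricted logLik: %.4f   %s (%d iter)\n",
              x$mu_hat, x$restricted_loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' @method summary kblup
#' @export
summary.kblup <- function(object, ...) {
  props <- variance_proportions(object)
  out <- list(fit = object, proportions = props)
  class(out) <- "summary.kblup"
  out
}

#' @method print summary.kblup
#' @export
print.summary.kblup <- function(x, ...) {
  print(x$fit)
  cat("Variance proportions (training set):\n")
  for (i in seq_along(x$proportions))
    cat(sprintf("  %-12s %.3f\n", names(x$proportions)[i], x$proportions[i]))
  invisible(x)
}

#' @method coef kblup
#' @export
coef.kblup <- function(object, ...) {
  c("(Intercept)" = object$mu_hat, object$sigma2,
    sigma2_e = object$sigma2_e)
}

#' @method logLik kblup
#' @export
logLik.kblup <- function(object, ...) {
  structure(object$restricted_loglik,
            df = length(object$sigma2) + 2, nobs = object$n,
            class = "logLik")
}

#' @method fitted kblup
#' @export
fitted.kblup <- function(object, ...) {
  n <- object$n
  ids <- object$line_ids
  V <- diag(object$sigma2_e, n)
  Csum <- matrix(0, n, n)
  for (c in seq_along(object$kernels)) {
    Kc <- object$kernels[[c]]$values[ids, ids]
    V <- V + object$sigma2[c] * Kc
    Csum <- Csum + object$sigma2[c] * Kc
  }
  r <- object$y - object$mu_hat
  stats::setNames(drop(object$mu_hat + Csum %*% solve(V, r)), ids)
}

#' @method residuals kblup
#' @export
residuals.kblup <- function(object, ...) {
  object$y - fitted(object)
}

#' @method predict kblup
#' @export
predict.kblup <- function(object, kernels_full = object$kernels,
                          test_ids = NULL, ...) {
  if (is.null(test_ids)) return(fitted(object))
  blup_predict(object, kernels_full, test_ids)
}

#' @method simulate kblup
#' @export
simulate.kblup <- function(object, nsim = 1, seed = NULL, ...) {
  n <- object$n
  ids <- object$line_ids
  V <- diag(object$sigma2_e, n)
  for (c in seq_along(object$kernels))
    V <- V + object$sigma2[c] * object$kernels[[c]]$values[ids, ids]
  R <- chol(V + diag(1e-10 * sum(diag(V)) / n, n))
  draw <- function() stats::setNames(
    object$mu_hat + drop(crossprod(R, stats::rnorm(n))), ids)
  runs <- if (is.null(seed)) replicate(nsim, draw(), simplify = FALSE)
    else with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
  out <- as.data.frame(runs, col.names = paste0("sim_", seq_len(nsim)))
  rownames(out) <- ids
  out
}

#' @method plot kblup
#' @export
plot.kblup <- function(x, ...) {
  props <- variance_proportions(x)
  graphics::barplot(props, ylab = "proportion of phenotypic variance",
                    main = "REML variance partition", ylim = c(0, 1), ...)
  invisible(x)
}
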