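# Independent oracles and small fixture builders shared across tests.
# These deliberately avoid the package's REML/BLUP code paths: the
# likelihood is evaluated by direct dense linear algebra and maximized by a
# coarse grid refined with Nelder-Mead, and conditional means come from the
# partitioned multivariate-normal formula.

# direct restricted log-likelihood for V = sum theta_c K_c + theta_e I,
# intercept-only fixed effects (includes the normalizing constant)
oracle_reml_ll <- function(theta, y, K_list) {
  n <- length(y)
  V <- diag(theta[length(theta)], n)
  for (c in seq_along(K_list)) V <- V + theta[c] * K_list[[c]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-1e10)
  Vi <- chol2inv(ch)
  a <- sum(Vi)
  if (a <= 0) return(-1e10)
  P <- Vi - tcrossprod(rowSums(Vi)) / a
  -0.5 * ((n - 1) * log(2 * pi) + 2 * sum(log(diag(ch))) + log(a) +
            sum(y * (P %*% y)))
}

# maximize the restricted likelihood by coarse grid + Nelder-Mead refinement
oracle_reml_max <- function(y, K_list, n_starts = 3) {
  vy <- var(y)
  levels <- vy * c(0.02, 0.2, 1, 3)
  grid <- do.call(expand.grid, rep(list(levels), length(K_list) + 1))
  ll <- apply(grid, 1, function(th) oracle_reml_ll(as.numeric(th), y, K_list))
  starts <- grid[order(-ll)[seq_len(n_starts)], , drop = FALSE]
  best <- -Inf
  for (i in seq_len(nrow(starts))) {
    o <- optim(log(as.numeric(starts[i, ])),
               function(lt) -oracle_reml_ll(exp(lt), y, K_list),
               method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-13))
    best <- max(best, -o$value)
  }
  best
}

# conditional mean of test phenotypes by assembling the joint covariance
oracle_conditional_mean <- function(theta, mu, y_train, K_list_full,
                                    train_idx, test_idx) {
  n <- nrow(K_list_full[[1]])
  Sigma <- matrix(0, n, n)
  for (c in seq_along(theta[-length(theta)]))
    Sigma <- Sigma + theta[c] * K_list_full[[c]]
  V_full <- Sigma + diag(theta[length(theta)], n)
  # cov(y_test, y_train) has no residual part because test and train lines
  # are distinct, so the off-diagonal block of V_full is exactly it
  drop(mu + V_full[test_idx, train_idx, drop = FALSE] %*%
         solve(V_full[train_idx, train_idx], y_train - mu))
}

# random PSD kernel on n lines from p standardized features
toy_kernel <- function(n, p, seed, label = "K") {
  M <- omniblup::simulate_genotypes(n_lines = n, p_variants = p,
                                    ld_block_size = 1, seed = seed)
  omniblup::linear_kernel(omniblup::standardize_columns(M$dosages), label)
}

toy_ids <- function(n) sprintf("line_%03d", seq_len(n))

# small coherent bundle for pipeline-level tests
tiny_bundle <- function(seed = 1, n_lines = 60, p_variants = 300,
                        n_genes = 150, n_terms = 12,
                        architecture = "transcript_mediated",
                        h2 = 0.6, ...) {
  omniblup::simulate_bundle(n_lines = n_lines, p_variants = p_variants,
                            n_genes = n_genes, n_terms = n_terms,
                            architecture = architecture, h2_target = h2,
                            term_size_range = c(5, min(30, floor(n_genes / 2))),
                            seed = seed, ...)
}
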