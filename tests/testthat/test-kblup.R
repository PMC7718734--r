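test_that("identity kernel reduces REML to the i.i.d. closed form", {
  set.seed(21)
  n <- 35
  ids <- paste0("L", 1:n)
  y <- setNames(rnorm(n, 5, 2), ids)
  I_k <- omniblup:::new_kernel(diag(1, n, n) |>
                                 `dimnames<-`(list(ids, ids)), n, "I")
  fit <- kblup(y, I_k)
  # only the total is identified; it must equal the sample variance
  expect_equal(fit$sigma2 + fit$sigma2_e, var(y), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(fit$mu_hat, mean(y), tolerance = 1e-8)
})

test_that("multi-kernel REML attains the derivative-free oracle maximum", {
  for (seed in 1:4) {
    set.seed(seed * 100)
    n <- 50
    K1 <- toy_kernel(n, 80, seed)
    K2 <- toy_kernel(n, 80, seed + 50)
    g <- drop(chol(K1$values + diag(1e-6, n)) %*% rnorm(n)) * 0.8
    y <- setNames(g + rnorm(n), toy_ids(n))
    fit <- kblup(y, list(A = K1, B = K2))
    expect_true(fit$converged)
    oracle <- oracle_reml_max(y, list(K1$values, K2$values))
    expect_gt(fit$restricted_loglik, oracle - 1e-4)
    # and the engine never reports a likelihood above the true surface
    expect_equal(fit$restricted_loglik,
                 oracle_reml_ll(c(fit$sigma2, fit$sigma2_e), y,
                                list(K1$values, K2$values)),
                 tolerance = 1e-8)
  }
})

test_that("single-kernel profile fit agrees with the multi-kernel iterator", {
  set.seed(31)
  n <- 60
  K <- toy_kernel(n, 150, 7)
  g <- drop(chol(K$values + diag(1e-6, n)) %*% rnorm(n))
  y <- setNames(g + rnorm(n), toy_ids(n))
  fast <- kblup(y, K)
  slow <- omniblup:::reml_ai(y, list(K$values[names(y), names(y)]),
                             tol = 1e-12, max_iter = 500)
  expect_equal(fast$restricted_loglik, slow$restricted_loglik,
               tolerance = 1e-6)
  expect_equal(unname(fast$sigma2), slow$sigma2,
               tolerance = 1e-3 * (fast$sigma2 + fast$sigma2_e))
})

test_that("BLUP matches the partitioned-normal conditional mean", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(15:30, 1)
    K1 <- toy_kernel(n, 60, seed + 10)
    K2 <- toy_kernel(n, 60, seed + 90)
    ids <- toy_ids(n)
    y <- setNames(rnorm(n), ids)
    test_idx <- sort(sample(n, 5))
    train_idx <- setdiff(seq_len(n), test_idx)
    fit <- kblup(y[train_idx], list(A = K1, B = K2))
    pred <- blup_predict(fit, list(A = K1, B = K2), ids[test_idx])
    theta <- c(fit$sigma2, fit$sigma2_e)
    V_tr <- theta[1] * K1$values[train_idx, train_idx] +
      theta[2] * K2$values[train_idx, train_idx] +
      diag(theta[3], length(train_idx))
    Vi1 <- solve(V_tr, rep(1, length(train_idx)))
    mu <- sum(Vi1 * y[train_idx]) / sum(Vi1)
    oracle <- oracle_conditional_mean(theta, mu, y[train_idx],
                                      list(K1$values, K2$values),
                                      train_idx, test_idx)
    expect_equal(unname(pred), unname(oracle), tolerance = 1e-8)
  }
})

test_that("all-zero components predict the training mean everywhere", {
  n <- 20
  ids <- toy_ids(n)
  K <- toy_kernel(n, 40, 3)
  y <- setNames(rnorm(n), ids)
  fit <- kblup(y[1:15], K)
  fit$sigma2[] <- 0
  fit$sigma2_e <- 1
  pred <- blup_predict(fit, K, ids[16:20], train_ids = ids[1:15],
                       y_train = y[1:15])
  expect_equal(unname(pred), rep(mean(y[1:15]), 5), tolerance = 1e-10)
})

test_that("a duplicated line is predicted at its phenotype as noise vanishes", {
  # 3 training lines plus a test line whose kernel row copies line 1
  ids <- c("t1", "t2", "t3", "probe")
  Kv <- matrix(c(1.0, 0.2, 0.1, 1.0,
                 0.2, 1.0, 0.3, 0.2,
                 0.1, 0.3, 1.0, 0.1,
                 1.0, 0.2, 0.1, 1.0), 4, 4, dimnames = list(ids, ids))
  K <- omniblup:::new_kernel(Kv, 10, "toy")
  y_train <- c(t1 = 2.0, t2 = -1.0, t3 = 0.5)
  fake <- structure(list(sigma2 = c(toy = 1), sigma2_e = 1e-10,
                         mu_hat = 0, line_ids = names(y_train),
                         y = y_train, converged = TRUE),
                    class = "kblup")
  pred <- blup_predict(fake, K, "probe")
  expect_equal(unname(pred), y_train[["t1"]], tolerance = 1e-3)
})

test_that("predictions are equivariant under shift and positive scaling", {
  set.seed(8)
  n <- 40
  K <- toy_kernel(n, 100, 12)
  ids <- toy_ids(n)
  g <- drop(chol(K$values + diag(1e-6, n)) %*% rnorm(n))
  y <- setNames(g + rnorm(n, sd = 0.5), ids)
  train <- ids[1:32]; test <- ids[33:40]
  base <- blup_predict(kblup(y[train], K), K, test)
  shifted <- blup_predict(kblup(y[train] + 7, K), K, test)
  expect_equal(shifted, base + 7, tolerance = 1e-6)
  scaled <- blup_predict(kblup(y[train] * 3, K), K, test)
  expect_equal(scaled, base * 3, tolerance = 1e-5)
})

test_that("restricted likelihood is monotone over nested kernel sets", {
  set.seed(41)
  n <- 45
  K1 <- toy_kernel(n, 90, 1)
  K2 <- toy_kernel(n, 90, 2)
  g <- drop(chol(K1$values + diag(1e-6, n)) %*% rnorm(n))
  y <- setNames(g + rnorm(n), toy_ids(n))
  ll1 <- kblup(y, K1)$restricted_loglik
  ll2 <- kblup(y, list(A = K1, B = K2))$restricted_loglik
  expect_gte(ll2, ll1 - 1e-6)
})

test_that("variance proportions follow the printed formula and sum to one", {
  fake <- structure(list(sigma2 = c(GRM = 3), sigma2_e = 1, converged = TRUE),
                    class = "kblup")
  expect_equal(unname(variance_proportions(fake)), c(0.75, 0.25))
  fake2 <- structure(list(sigma2 = c(g = 1, t = 1, i = 1), sigma2_e = 1,
                          converged = TRUE), class = "kblup")
  p <- variance_proportions(fake2)
  expect_equal(unname(p), rep(0.25, 4))
  expect_equal(sum(p), 1)
  fake3 <- structure(list(sigma2 = c(g = 0), sigma2_e = 2, converged = TRUE),
                     class = "kblup")
  expect_equal(unname(variance_proportions(fake3)), c(0, 1))
})

test_that("fit object supports the standard modelling methods", {
  set.seed(5)
  n <- 30
  K <- toy_kernel(n, 60, 9, label = "GRM")
  g <- drop(chol(K$values + diag(1e-6, n)) %*% rnorm(n))
  y <- setNames(g + rnorm(n, sd = 0.3), toy_ids(n))
  fit <- kblup(y, K)
  expect_output(print(fit), "Variance components")
  expect_output(print(summary(fit)), "Variance proportions")
  expect_named(coef(fit), c("(Intercept)", "GRM", "sigma2_e"))
  expect_equal(fitted(fit) + residuals(fit), y)
  expect_equal(as.numeric(logLik(fit)), fit$restricted_loglik)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(n, 3))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 1))
})

test_that("genomic proportion is recovered without material bias", {
  # compact version of the recovery study; the acceptance suite runs the
  # full 50-seed grid
  G <- simulate_genotypes(n_lines = 150, p_variants = 500, seed = 17)
  K <- linear_kernel(standardize_columns(G$dosages))
  props <- vapply(1:12, function(s) {
    ph <- simulate_phenotype(G = G, architecture = "variant_additive",
                             h2_target = 0.5, n_causal_variants = 500,
                             seed = s)
    variance_proportions(kblup(trait_values(ph$phenotype, "trait"), K))[1]
  }, numeric(1))
  expect_lt(abs(mean(props) - 0.5), 0.12)
})
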