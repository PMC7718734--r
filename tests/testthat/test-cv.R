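variance_proportions_cols <- function(m) {
  cols <- grep("^prop_", names(m$mean_props), value = TRUE)
  unlist(m$mean_props[cols])
}

test_that("cv design partitions every line once per replicate", {
  ids <- paste0("L", 1:11)
  cv <- make_cv_design(ids, k = 5, n_reps = 4, seed = 3)
  for (r in 1:4) {
    sizes <- table(cv$assignment[r, ])
    expect_equal(sum(sizes), 11)
    expect_equal(sort(as.integer(sizes), decreasing = TRUE),
                 c(3, 2, 2, 2, 2))
  }
  # every line tested exactly n_reps times across the design
  expect_true(all(rowSums(cv$assignment > 0) == 11))
  # reproducibility
  cv2 <- make_cv_design(ids, k = 5, n_reps = 4, seed = 3)
  expect_identical(cv$assignment, cv2$assignment)
  cv3 <- make_cv_design(ids, k = 5, n_reps = 4, seed = 4)
  expect_false(identical(cv$assignment, cv3$assignment))
  expect_error(make_cv_design(paste0("L", 1:9), k = 5), "at least")
})

test_that("ten lines in five folds give folds of two", {
  cv <- make_cv_design(paste0("L", 1:10), k = 5, n_reps = 2, seed = 1)
  expect_true(all(table(cv$assignment[1, ]) == 2))
})

test_that("pearson accuracy handles perfect, inverted and degenerate cases", {
  expect_equal(as.numeric(pearson_accuracy(1:3, c(2, 4, 6))), 1)
  expect_equal(as.numeric(pearson_accuracy(1:3, c(3, 2, 1))), -1)
  flat <- pearson_accuracy(1:4, rep(2, 4))
  expect_equal(as.numeric(flat), 0)
  expect_true(attr(flat, "degenerate"))
  expect_error(pearson_accuracy(1:3, 1:4), "mismatch")
})

test_that("summarize_cv computes mean and SEM over non-missing folds", {
  s <- summarize_cv(c(0.1, 0.2, 0.3))
  expect_equal(unname(s["mean"]), 0.2)
  expect_equal(unname(s["sem"]), sd(c(.1, .2, .3)) / sqrt(3))
  expect_equal(unname(summarize_cv(rep(0.4, 6))["sem"]), 0)
  s2 <- summarize_cv(c(0.1, NA, 0.3))
  expect_equal(unname(s2["mean"]), 0.2)
  expect_error(summarize_cv(c(NA_real_, NA_real_)), "non-missing")
})

test_that("null phenotypes give null GBLUP accuracy", {
  b <- tiny_bundle(seed = 2, h2 = 0, architecture = "variant_additive",
                   n_lines = 80, p_variants = 300, n_genes = 50)
  y <- trait_values(b$phenotype, "trait")
  cv <- make_cv_design(sort(names(y)), k = 5, n_reps = 4, seed = 5)
  m <- run_model_cv("GBLUP", y, genotypes = b$genotypes, cv = cv)
  expect_lt(abs(m$mean_r), 2.5 * m$sem_r + 0.05)
})

test_that("a noiseless transcript-driven phenotype is recovered by TBLUP", {
  b <- tiny_bundle(seed = 3, h2 = 1, architecture = "transcript_mediated",
                   n_lines = 200, p_variants = 100, n_genes = 150)
  y <- trait_values(b$phenotype, "trait")
  cv <- make_cv_design(sort(names(y)), k = 5, n_reps = 2, seed = 6)
  m <- run_model_cv("TBLUP", y, expression = b$expression, cv = cv)
  expect_gt(m$mean_r, 0.9)
})

test_that("cross-validation metrics are deterministic given the seed", {
  b <- tiny_bundle(seed = 4, n_lines = 60, p_variants = 150, n_genes = 80)
  y <- trait_values(b$phenotype, "trait")
  cv <- make_cv_design(sort(names(y)), k = 5, n_reps = 2, seed = 7)
  m1 <- run_model_cv("GTBLUP", y, genotypes = b$genotypes,
                     expression = b$expression, cv = cv)
  m2 <- run_model_cv("GTBLUP", y, genotypes = b$genotypes,
                     expression = b$expression, cv = cv)
  expect_identical(m1$per_fold, m2$per_fold)
  expect_equal(sum(variance_proportions_cols(m1)), 1, tolerance = 1e-8)
})

test_that("fold gene selection depends only on training lines and seed", {
  b <- tiny_bundle(seed = 5, n_lines = 60, p_variants = 100, n_genes = 150)
  y <- trait_values(b$phenotype, "trait")
  ids <- sort(names(y))
  Z <- standardize_columns(b$expression$abundances)
  train_ids <- ids[1:48]
  test_ids <- ids[49:60]
  # permute the test phenotypes; the selected gene sets must not move
  y_perm <- y
  y_perm[test_ids] <- sample(y[test_ids])
  for (type in c("TWAS_TBLUP", "RANDOM_GENES")) {
    params <- list(p_max = 0.1, k_genes = 20)
    sel1 <- with(list(), {
      if (type == "TWAS_TBLUP")
        select_genes(twas_scan(y[train_ids], Z), params$p_max)
      else random_gene_set(Z$feature_ids, params$k_genes, 99)
    })
    sel2 <- with(list(), {
      if (type == "TWAS_TBLUP")
        select_genes(twas_scan(y_perm[train_ids], Z), params$p_max)
      else random_gene_set(Z$feature_ids, params$k_genes, 99)
    })
    expect_identical(sort(as.character(sel1)), sort(as.character(sel2)))
  }
  # and the full CV runs are reproducible end to end
  cv <- make_cv_design(ids, k = 5, n_reps = 2, seed = 11)
  m1 <- run_model_cv("TWAS_TBLUP", y, expression = b$expression, cv = cv,
                     params = list(p_max = 0.1))
  m2 <- run_model_cv("TWAS_TBLUP", y, expression = b$expression, cv = cv,
                     params = list(p_max = 0.1))
  expect_identical(m1$per_fold, m2$per_fold)
})

test_that("an empty TWAS selection degrades to zero-accuracy folds", {
  b <- tiny_bundle(seed = 6, h2 = 0, n_lines = 60, p_variants = 100,
                   n_genes = 60)
  y <- trait_values(b$phenotype, "trait")
  cv <- make_cv_design(sort(names(y)), k = 5, n_reps = 1, seed = 2)
  m <- run_model_cv("TWAS_TBLUP", y, expression = b$expression, cv = cv,
                    params = list(p_max = 1e-12))
  expect_true(all(m$per_fold$r == 0))
  expect_true(all(m$per_fold$degenerate))
})

test_that("GBLUP accuracy increases with heritability", {
  G <- simulate_genotypes(n_lines = 120, p_variants = 400, seed = 31)
  K <- linear_kernel(standardize_columns(G$dosages))
  accs <- vapply(c(0.1, 0.4, 0.7), function(h2) {
    ph <- simulate_phenotype(G = G, architecture = "variant_additive",
                             h2_target = h2, n_causal_variants = 400,
                             seed = 77)
    y <- trait_values(ph$phenotype, "trait")
    cv <- make_cv_design(sort(names(y)), k = 5, n_reps = 3, seed = 13)
    run_model_cv("GBLUP", y, genotypes = G, cv = cv)$mean_r
  }, numeric(1))
  expect_true(all(diff(accs) > 0))
  expect_gt(accs[3], 0)
})
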