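test_that("simulated genotypes are homozygous with the requested MAF band", {
  G <- simulate_genotypes(n_lines = 200, p_variants = 400, seed = 1)
  expect_true(all(G$dosages %in% c(0, 2)))
  f <- maf(G)
  expect_true(all(f >= 0 & f <= 0.5))
  # MAF pinned at 0.5: empirical frequencies concentrate around 0.5
  G5 <- simulate_genotypes(n_lines = 400, p_variants = 200,
                           maf_range = c(0.5, 0.5), ld_block_size = 1,
                           seed = 2)
  expect_lt(abs(mean(maf(G5)) - 0.5), 0.02)
  expect_gt(min(maf(G5)), 0.5 - 4 * sqrt(0.25 / 400))
})

test_that("block size one removes adjacent-variant correlation", {
  G <- simulate_genotypes(n_lines = 300, p_variants = 1001,
                          ld_block_size = 1, seed = 3)
  d <- G$dosages
  rs <- vapply(seq_len(1000), function(j) {
    suppressWarnings(cor(d[, j], d[, j + 1]))
  }, numeric(1))
  expect_lt(abs(mean(rs, na.rm = TRUE)), 0.05)
  # and with blocks, neighbours inside a block are strongly correlated
  Gb <- simulate_genotypes(n_lines = 300, p_variants = 1000,
                           ld_block_size = 10, ld_rho = 0.8, seed = 4)
  within <- vapply(seq(2, 990), function(j) {
    if ((j - 1) %% 10 == 0) return(NA_real_)  # block boundary
    suppressWarnings(cor(Gb$dosages[, j - 1], Gb$dosages[, j]))
  }, numeric(1))
  expect_gt(mean(within, na.rm = TRUE), 0.4)
})

test_that("expression honours its target genetic fraction", {
  G <- simulate_genotypes(n_lines = 200, p_variants = 300, seed = 5)
  ex <- simulate_expression(G, n_genes = 500, eqtl_per_gene = 5,
                            genetic_fraction = 0.5, seed = 6)
  expect_false(anyNA(ex$expression$abundances))
  expect_lt(abs(mean(ex$truth$genetic_fraction_realized) - 0.5), 0.05)
  expect_true(all(abs(ex$truth$genetic_fraction_realized - 0.5) < 0.1 + 1e-9))
  # zero genetic control: transcripts uncorrelated with their eQTLs
  ex0 <- simulate_expression(G, n_genes = 50, genetic_fraction = 0, seed = 7)
  cors <- vapply(seq_len(50), function(j) {
    v <- ex0$truth$eqtl[[j]][1]
    abs(cor(ex0$expression$abundances[, j], G$dosages[, v]))
  }, numeric(1))
  expect_lt(mean(cors), 0.1)
  # full genetic control: exact linear function of the eQTL dosages
  ex1 <- simulate_expression(G, n_genes = 20, genetic_fraction = 1, seed = 8)
  j <- 5
  X <- G$dosages[, ex1$truth$eqtl[[j]], drop = FALSE]
  pred <- drop(X %*% ex1$truth$effects[[j]])
  resid <- ex1$expression$abundances[, j] - pred
  expect_lt(max(abs(resid - mean(resid))), 1e-10)
  expect_error(simulate_expression(G, 10, eqtl_per_gene = 1000), "exceeds")
})

test_that("phenotype architectures hit their target signal fraction", {
  G <- simulate_genotypes(n_lines = 200, p_variants = 300, seed = 9)
  E <- simulate_expression(G, n_genes = 300, seed = 10)$expression
  for (arch in c("variant_additive", "transcript_mediated", "mixed", "gxt")) {
    h2s <- vapply(1:5, function(s) {
      simulate_phenotype(G, E, arch, h2_target = 0.6,
                         seed = s)$truth$h2_realized
    }, numeric(1))
    expect_lt(max(abs(h2s - 0.6)), 0.05)
  }
  ph0 <- simulate_phenotype(G, E, "transcript_mediated", h2_target = 0,
                            seed = 1)
  expect_equal(ph0$truth$h2_realized, 0)
  ph1 <- simulate_phenotype(G, E, "transcript_mediated", h2_target = 1,
                            seed = 1)
  expect_equal(ph1$truth$h2_realized, 1)
  expect_error(simulate_phenotype(G = NULL, E = E, "variant_additive"),
               "needs genotypes")
  expect_error(simulate_phenotype(G = G, E = NULL, "gxt"), "needs expression")
})

test_that("simulated annotation honours sizes, spans and the causal term", {
  genes <- sprintf("gene_%03d", 1:60)
  ann <- simulate_annotation(genes, n_terms = 8, size_range = c(5, 5),
                             causal_term = list(term = "GO:0009999",
                                                genes = genes[1:7]),
                             seed = 11)
  t_all <- enumerate_go_terms(ann, genes, min_genes = 1)
  non_causal <- t_all[t_all$term != "GO:0009999", ]
  expect_true(all(non_causal$n_genes == 5))
  expect_setequal(t_all$genes[[which(t_all$term == "GO:0009999")]],
                  genes[1:7])
  expect_equal(ann$gene_spans$gene, genes)
  expect_true(all(ann$gene_spans$start <= ann$gene_spans$end))
  expect_error(simulate_annotation(genes, n_terms = 5,
                                   size_range = c(5, 10),
                                   causal_term = list(
    term = "GO:0000001", genes = "nope")), "not in gene_ids")
  expect_error(simulate_annotation(genes[1:4], n_terms = 2,
                                   size_range = c(5, 10)),
               "exceeds")
})

test_that("bundles are pure functions of configuration and seed", {
  b1 <- tiny_bundle(seed = 42, n_lines = 40, p_variants = 80, n_genes = 60,
                    n_terms = 6)
  b2 <- tiny_bundle(seed = 42, n_lines = 40, p_variants = 80, n_genes = 60,
                    n_terms = 6)
  expect_identical(b1$genotypes$dosages, b2$genotypes$dosages)
  expect_identical(b1$expression$abundances, b2$expression$abundances)
  expect_identical(b1$phenotype$data, b2$phenotype$data)
  b3 <- tiny_bundle(seed = 43, n_lines = 40, p_variants = 80, n_genes = 60,
                    n_terms = 6)
  expect_false(identical(b1$phenotype$data$trait, b3$phenotype$data$trait))
})

test_that("default bundle kernels satisfy the relationship-matrix invariants", {
  b <- tiny_bundle(seed = 44, n_lines = 100, p_variants = 500, n_genes = 300,
                   n_terms = 10)
  for (layer in list(b$genotypes$dosages, b$expression$abundances)) {
    K <- linear_kernel(standardize_columns(layer))
    expect_lt(max(abs(rowSums(K$values))), 1e-8)
    expect_equal(mean(diag(K$values)), 1, tolerance = 1e-10)
    off <- K$values[upper.tri(K$values)]
    expect_lt(abs(mean(off)), 0.05)
  }
})

test_that("bundle round-trips through plain-text files", {
  b <- tiny_bundle(seed = 45, n_lines = 30, p_variants = 40, n_genes = 25,
                   n_terms = 4)
  dir <- tempfile("bundle")
  write_bundle(b, dir)
  G <- read_genotypes(file.path(dir, "genotypes.tsv"), "dosage_tsv")
  expect_equal(G$dosages, b$genotypes$dosages,
               ignore_attr = FALSE, tolerance = 0)
  E <- read_matrix_table(file.path(dir, "expression.tsv"), "expression")
  expect_equal(E$abundances, b$expression$abundances, tolerance = 1e-6)
  ann <- read_annotation(file.path(dir, "gene2go.tsv"),
                         file.path(dir, "gene_spans.tsv"))
  expect_setequal(names(ann$gene_to_terms), names(b$annotation$gene_to_terms))
})
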