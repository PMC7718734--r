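#' Simulate genotypes for a fully homozygous inbred panel
#'
#' Dosages are in {0, 2}. Each variant's allele frequency is drawn
#' uniformly from \code{maf_range}; within an LD block each variant copies
#' the previous variant's allele with probability \code{ld_rho} (a
#' first-order copying process) and otherwise draws a fresh allele, the
#' first variant of each block always drawing fresh. Variants are placed at
#' regular positions along a single toy chromosome so variant-to-gene
#' mapping can be exercised.
#'
#' @param n_lines number of lines (default 200).
#' @param p_variants number of biallelic variants.
#' @param maf_range allele-frequency range, default c(0.05, 0.5).
#' @param ld_block_size variants per LD block; 1 means full independence.
#' @param ld_rho within-block copying probability (default 0.8).
#' @param seed integer seed.
#' @param chrom chromosome name for the toy map (default "chrS").
#' @param pos_step base pairs between adjacent variants (default 200).
#' @return a \code{\link{genotype_matrix}} with coding "0/2".
#' @export
simulate_genotypes <- function(n_lines = 200, p_variants = 5000,
                               maf_range = c(0.05, 0.5), ld_block_size = 10,
                               ld_rho = 0.8, seed = 1, chrom = "chrS",
                               pos_step = 200) {
  stopifnot(p_variants >= 1, n_lines >= 2, ld_block_size >= 1,
            ld_rho >= 0, ld_rho <= 1)
  with_seed(seed, {
    f <- stats::runif(p_variants, maf_range[1], maf_range[2])
    fresh <- matrix(stats::rbinom(n_lines * p_variants, 1,
                                  rep(f, each = n_lines)),
                    n_lines, p_variants)
    copy <- matrix(stats::runif(n_lines * p_variants) < ld_rho,
                   n_lines, p_variants)
    A <- fresh
    block_start <- ((seq_len(p_variants) - 1) %% ld_block_size) == 0
    for (j in seq_len(p_variants)[-1]) {
      if (block_start[j]) next
      A[, j] <- ifelse(copy[, j], A[, j - 1], fresh[, j])
    }
    dos <- 2 * A
    rownames(dos) <- sprintf("line_%03d", seq_len(n_lines))
    ids <- sprintf("%s:%d", chrom, seq_len(p_variants) * pos_step)
    colnames(dos) <- ids
    variants <- data.frame(id = ids, chrom = chrom,
                           pos = seq_len(p_variants) * pos_step,
                           ref = "A", alt = "T", stringsAsFactors = FALSE)
    genotype_matrix(dos, variants, coding = "0/2")
  })
}

#' Simulate expression partially under genetic (eQTL) control
#'
#' Each gene is a linear combination of \code{eqtl_per_gene} randomly
#' chosen variants' dosages plus Gaussian noise, with the noise scaled to
#' the gene's realized genetic variance so the genetic fraction of each
#' gene's variance matches \code{genetic_fraction}; a per-gene baseline
#' shifts values onto a log2FPKM-like scale.
#'
#' @param G a \code{\link{genotype_matrix}} (complete dosages).
#' @param n_genes number of genes.
#' @param eqtl_per_gene eQTLs per gene (default 5).
#' @param genetic_fraction target fraction of each gene's variance that is
#'   genetic, in [0, 1] (default 0.5).
#' @param seed integer seed.
#' @return list with \code{expression} (an \code{expression_matrix}) and
#'   \code{truth} (per-gene eQTL ids, effects, and realized genetic
#'   fractions).
#' @export
simulate_expression <- function(G, n_genes = 2000, eqtl_per_gene = 5,
                                genetic_fraction = 0.5, seed = 1) {
  stopifnot(inherits(G, "genotype_matrix"),
            genetic_fraction >= 0, genetic_fraction <= 1)
  p <- ncol(G$dosages)
  if (eqtl_per_gene > p)
    stop_ob("eqtl_per_gene (%d) exceeds the number of variants (%d)",
            eqtl_per_gene, p)
  n <- nrow(G$dosages)
  with_seed(seed, {
    E <- matrix(0, n, n_genes)
    eqtl <- vector("list", n_genes)
    effects <- vector("list", n_genes)
    realized <- numeric(n_genes)
    baseline <- stats::rnorm(n_genes, mean = 3, sd = 2)
    pvar <- function(x) mean((x - mean(x))^2)
    for (j in seq_len(n_genes)) {
      idx <- sample.int(p, eqtl_per_gene)
      b <- stats::rnorm(eqtl_per_gene)
      gpart <- drop(G$dosages[, idx, drop = FALSE] %*% b)
      vg <- pvar(gpart)
      if (genetic_fraction == 0 || vg == 0) {
        gpart <- gpart * 0
        vg <- 0
      }
      if (genetic_fraction >= 1 && vg > 0) {
        noise <- rep(0, n)
      } else {
        target_ve <- if (vg > 0) vg * (1 - genetic_fraction) / genetic_fraction
                     else 1
        noise <- stats::rnorm(n)
        noise <- noise - mean(noise)
        if (vg > 0) {     # orthogonalize so the realized fraction is exact
          gc <- gpart - mean(gpart)
          noise <- noise - sum(noise * gc) / sum(gc^2) * gc
        }
        noise <- noise * sqrt(target_ve / pvar(noise))
      }
      E[, j] <- baseline[j] + gpart + noise
      eqtl[[j]] <- colnames(G$dosages)[idx]
      effects[[j]] <- b
      tot <- pvar(E[, j])
      realized[j] <- if (tot > 0) vg / tot else 0
    }
    rownames(E) <- rownames(G$dosages)
    colnames(E) <- sprintf("gene_%04d", seq_len(n_genes))
    names(eqtl) <- names(effects) <- colnames(E)
    list(expression = expression_matrix(E),
         truth = list(eqtl = eqtl, effects = effects,
                      genetic_fraction_target = genetic_fraction,
                      genetic_fraction_realized = realized, seed = seed))
  })
}

#' Simulate a line-mean phenotype under a chosen architecture
#'
#' Architectures: \code{variant_additive} (sum of causal-variant effects),
#' \code{transcript_mediated} (sum of causal-transcript effects),
#' \code{mixed} (both, equal variance shares), and \code{gxt} (mixed plus
#' pairwise products of paired causal variants and transcripts). Effects
#' are N(0, 1) draws applied to centered-and-standardized features so every
#' causal feature contributes equal expected variance; Gaussian noise is
#' scaled so the realized signal fraction equals \code{h2_target} on the
#' simulated sample.
#'
#' @param G a \code{\link{genotype_matrix}} (or NULL for purely
#'   transcript-mediated architectures).
#' @param E an \code{\link{expression_matrix}} (or NULL for
#'   variant_additive).
#' @param architecture one of \code{"variant_additive"},
#'   \code{"transcript_mediated"}, \code{"mixed"}, \code{"gxt"}.
#' @param h2_target target fraction of phenotypic variance that is signal.
#' @param n_causal_variants,n_causal_genes causal feature counts.
#' @param causal_go_genes optional gene ids causal transcripts are drawn
#'   from (e.g. one GO term's genes).
#' @param trait trait column name (default "trait").
#' @param seed integer seed.
#' @return list with \code{phenotype} (a \code{\link{phenotype_table}}) and
#'   \code{truth} (causal ids, effects, target and realized signal
#'   fractions, seed).
#' @export
simulate_phenotype <- function(G = NULL, E = NULL,
                               architecture = c("variant_additive",
                                                "transcript_mediated",
                                                "mixed", "gxt"),
                               h2_target = 0.5, n_causal_variants = 100,
                               n_causal_genes = 50, causal_go_genes = NULL,
                               trait = "trait", seed = 1) {
  architecture <- match.arg(architecture)
  stopifnot(h2_target >= 0, h2_target <= 1)
  need_g <- architecture %in% c("variant_additive", "mixed", "gxt")
  need_e <- architecture %in% c("transcript_mediated", "mixed", "gxt")
  if (need_g && is.null(G))
    stop_ob("architecture '%s' needs genotypes", architecture)
  if (need_e && is.null(E))
    stop_ob("architecture '%s' needs expression", architecture)
  ids <- if (!is.null(G)) rownames(G$dosages) else rownames(E$abundances)
  if (!is.null(G) && !is.null(E))
    stopifnot(identical(rownames(G$dosages), rownames(E$abundances)))
  n <- length(ids)
  pvar <- function(x) mean((x - mean(x))^2)
  std <- function(M) {
    mu <- colMeans(M); v <- colMeans(M^2) - mu^2
    keep <- v > 1e-12
    sweep(sweep(M[, keep, drop = FALSE], 2, mu[keep], `-`), 2,
          sqrt(v[keep]), `/`)
  }
  with_seed(seed, {
    sig_parts <- list()
    truth <- list(architecture = architecture, h2_target = h2_target,
                  seed = seed)
    if (need_g) {
      Ws <- std(G$dosages)
      nv <- min(n_causal_variants, ncol(Ws))
      vi <- sample(colnames(Ws), nv)
      bv <- stats::rnorm(nv)
      sig_parts$variant <- drop(Ws[, vi, drop = FALSE] %*% bv)
      truth$causal_variants <- vi
      truth$variant_effects <- bv
    }
    if (need_e) {
      Zs <- std(E$abundances)
      pool <- colnames(Zs)
      if (!is.null(causal_go_genes)) {
        pool <- intersect(pool, causal_go_genes)
        if (!length(pool)) stop_ob("no causal GO genes present in expression")
      }
      ng <- min(n_causal_genes, length(pool))
      gi <- sample(pool, ng)
      bg <- stats::rnorm(ng)
      sig_parts$transcript <- drop(Zs[, gi, drop = FALSE] %*% bg)
      truth$causal_genes <- gi
      truth$gene_effects <- bg
    }
    if (architecture == "gxt") {
      npair <- min(length(truth$causal_variants), length(truth$causal_genes))
      Wp <- std(G$dosages[, truth$causal_variants[seq_len(npair)],
                          drop = FALSE])
      Zp <- std(E$abundances[, truth$causal_genes[seq_len(npair)],
                             drop = FALSE])
      bi <- stats::rnorm(ncol(Wp))
      sig_parts$interaction <- drop((Wp[, seq_len(ncol(Wp)), drop = FALSE] *
                                     Zp[, seq_len(ncol(Wp)), drop = FALSE]) %*% bi)
      truth$interaction_effects <- bi
    }
    # equal variance share per architecture component, then scale to h2
    parts <- lapply(sig_parts, function(s) {
      v <- pvar(s); if (v > 0) (s - mean(s)) / sqrt(v) else s
    })
    signal <- if (length(parts)) Reduce(`+`, parts) / sqrt(length(parts))
              else rep(0, n)
    vs <- pvar(signal)
    if (h2_target == 0 || vs == 0) {
      signal <- signal * 0
      vs <- 0
    }
    noise <- stats::rnorm(n)
    noise <- noise - mean(noise)
    if (vs > 0) {         # orthogonalize so the realized fraction is exact
      sc <- signal - mean(signal)
      noise <- noise - sum(noise * sc) / sum(sc^2) * sc
    }
    if (h2_target >= 1 && vs > 0) {
      noise <- noise * 0
    } else {
      target_ve <- if (vs > 0) vs * (1 - h2_target) / h2_target else 1
      noise <- noise * sqrt(target_ve / pvar(noise))
    }
    yv <- signal + noise
    tot <- pvar(yv)
    truth$h2_realized <- if (tot > 0) vs / tot else 0
    dat <- data.frame(line_id = ids, stringsAsFactors = FALSE)
    dat[[trait]] <- yv
    list(phenotype = phenotype_table(dat, traits = trait), truth = truth)
  })
}

#' Simulate a GO annotation with gene spans on a toy chromosome
#'
#' Terms are drawn by sampling gene sets (overlap between terms allowed);
#' an optional causal term contains exactly the specified genes. Gene spans
#' are laid end to end on one chromosome (1-based inclusive) so the variant
#' mapping machinery is exercised.
#'
#' @param gene_ids gene ids to annotate.
#' @param n_terms number of GO terms.
#' @param size_range min/max genes per term (default c(5, 200)).
#' @param causal_term optional list(term = "GO:NNNNNNN", genes = ids).
#' @param seed integer seed.
#' @param chrom chromosome name for the spans (default "chrS").
#' @param gene_length,gene_gap span geometry in bp.
#' @return an \code{\link{annotation_map}}.
#' @export
simulate_annotation <- function(gene_ids, n_terms = 100,
                                size_range = c(5, 200), causal_term = NULL,
                                seed = 1, chrom = "chrS",
                                gene_length = 1000, gene_gap = 500) {
  ng <- length(gene_ids)
  if (size_range[2] > ng)
    stop_ob("term size range exceeds the number of genes")
  if (!is.null(causal_term)) {
    stopifnot(is.list(causal_term), !is.null(causal_term$term),
              !is.null(causal_term$genes))
    bad <- setdiff(causal_term$genes, gene_ids)
    if (length(bad))
      stop_ob("causal term genes not in gene_ids: %s",
              paste(utils::head(bad, 5), collapse = ", "))
  }
  with_seed(seed, {
    term_ids <- sprintf("GO:%07d", seq_len(n_terms))
    size_pool <- seq(size_range[1], size_range[2])
    sizes <- size_pool[sample.int(length(size_pool), n_terms, replace = TRUE)]
    sets <- lapply(sizes, function(s) sample(gene_ids, s))
    names(sets) <- term_ids
    if (!is.null(causal_term)) {
      ct <- causal_term$term
      if (!ct %in% term_ids) {
        sets <- c(sets, stats::setNames(list(character(0)), ct))
      }
      sets[[ct]] <- unique(causal_term$genes)
    }
    long <- data.frame(term = rep(names(sets), lengths(sets)),
                       gene = unlist(sets, use.names = FALSE),
                       stringsAsFactors = FALSE)
    gene_to_terms <- split(long$term, long$gene)
    noterm <- setdiff(gene_ids, names(gene_to_terms))
    if (length(noterm))
      gene_to_terms <- c(gene_to_terms,
                         stats::setNames(rep(list(character(0)),
                                             length(noterm)), noterm))
    gene_to_terms <- gene_to_terms[gene_ids]
    start <- (seq_len(ng) - 1) * (gene_length + gene_gap) + 1
    spans <- data.frame(gene = gene_ids, chrom = chrom, start = start,
                        end = start + gene_length - 1,
                        stringsAsFactors = FALSE)
    annotation_map(gene_to_terms, spans)
  })
}

#' Simulate a complete inbred-panel bundle
#'
#' Convenience wrapper coordinating genotypes, eQTL-controlled expression,
#' annotation and a phenotype under one architecture, with all sub-seeds
#' derived from a single seed, so a bundle is a pure function of its
#' configuration and seed.
#'
#' @param n_lines,p_variants,n_genes,n_terms bundle dimensions (defaults
#'   200 lines, 5000 variants, 2000 genes, 100 GO terms).
#' @param architecture,h2_target,n_causal_variants,n_causal_genes passed to
#'   \code{\link{simulate_phenotype}}.
#' @param genetic_fraction,eqtl_per_gene passed to
#'   \code{\link{simulate_expression}}.
#' @param causal_term_id when non-NULL, the causal transcripts are confined
#'   to this GO term, whose gene set is exactly the causal genes.
#' @param term_size_range passed to \code{\link{simulate_annotation}}.
#' @param ld_block_size,maf_range passed to
#'   \code{\link{simulate_genotypes}}.
#' @param seed master seed.
#' @return list with \code{genotypes}, \code{expression}, \code{phenotype},
#'   \code{annotation}, and \code{truth}.
#' @export
simulate_bundle <- function(n_lines = 200, p_variants = 5000,
                            n_genes = 2000, n_terms = 100,
                            architecture = "transcript_mediated",
                            h2_target = 0.5, n_causal_variants = 100,
                            n_causal_genes = 50, genetic_fraction = 0.5,
                            eqtl_per_gene = 5, causal_term_id = NULL,
                            term_size_range = c(5, 200), ld_block_size = 10,
                            maf_range = c(0.05, 0.5), seed = 1) {
  G <- simulate_genotypes(n_lines, p_variants, maf_range, ld_block_size,
                          seed = derive_seed(seed, 1))
  ex <- simulate_expression(G, n_genes, eqtl_per_gene, genetic_fraction,
                            seed = derive_seed(seed, 2))
  E <- ex$expression
  causal_genes <- NULL
  causal_term <- NULL
  if (!is.null(causal_term_id)) {
    causal_genes <- with_seed(derive_seed(seed, 3),
                              sample(colnames(E$abundances), n_causal_genes))
    causal_term <- list(term = causal_term_id, genes = causal_genes)
  }
  ann <- simulate_annotation(colnames(E$abundances), n_terms,
                             term_size_range, causal_term,
                             seed = derive_seed(seed, 4))
  ph <- simulate_phenotype(G, E, architecture, h2_target,
                           n_causal_variants, n_causal_genes,
                           causal_go_genes = causal_genes,
                           seed = derive_seed(seed, 5))
  truth <- c(ph$truth, list(expression = ex$truth,
                            causal_term = causal_term_id))
  list(genotypes = G, expression = E, phenotype = ph$phenotype,
       annotation = ann, truth = truth)
}

#' Write a simulated bundle to plain-text files
#'
#' Emits dosage TSV, expression TSV, phenotype TSV, gene-to-GO TSV, span
#' TSV and a truth JSON under \code{dir}.
#'
#' @param bundle a \code{\link{simulate_bundle}} result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  G <- bundle$genotypes
  wtsv(data.frame(line_id = rownames(G$dosages), G$dosages,
                  check.names = FALSE), "genotypes.tsv")
  E <- bundle$expression
  wtsv(data.frame(line_id = rownames(E$abundances), E$abundances,
                  check.names = FALSE), "expression.tsv")
  wtsv(bundle$phenotype$data, "phenotype.tsv")
  g2t <- bundle$annotation$gene_to_terms
  long <- data.frame(gene = rep(names(g2t), lengths(g2t)),
                     term = unlist(g2t, use.names = FALSE))
  utils::write.table(long, file.path(dir, "gene2go.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(bundle$annotation$gene_spans,
                     file.path(dir, "gene_spans.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  truth <- bundle$truth
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
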