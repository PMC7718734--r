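#' Enumerate GO terms eligible for partitioned-kernel models
#'
#' A term is eligible when at least \code{min_genes} of its genes fall in
#' the feature universe (e.g. the expressed genes for transcript models, or
#' the genes any variant maps to for variant models). The GO hierarchy is
#' not propagated: a gene belongs only to the terms listed in the input map.
#'
#' @param ann an \code{\link{annotation_map}}.
#' @param feature_universe gene ids available to the model.
#' @param min_genes minimum gene count per term, inclusive (default 5).
#' @return data.frame with columns \code{term}, \code{n_genes}, and a list
#'   column \code{genes} (the term's genes within the universe).
#' @export
enumerate_go_terms <- function(ann, feature_universe, min_genes = 5) {
  stopifnot(inherits(ann, "annotation_map"))
  g2t <- ann$gene_to_terms[names(ann$gene_to_terms) %in% feature_universe]
  if (!length(g2t))
    return(data.frame(term = character(0), n_genes = integer(0)))
  long <- data.frame(
    gene = rep(names(g2t), lengths(g2t)),
    term = unlist(g2t, use.names = FALSE), stringsAsFactors = FALSE)
  by_term <- split(unique(long)$gene, unique(long)$term)
  sizes <- lengths(by_term)
  keep <- sizes >= min_genes
  out <- data.frame(term = names(by_term)[keep],
                    n_genes = unname(sizes[keep]),
                    stringsAsFactors = FALSE)
  out$genes <- unname(by_term[keep])
  out[order(out$term), , drop = FALSE]
}

#' Per-GO-term partitioned-kernel prediction scan
#'
#' For every term, the feature set of a layer is split into in-term and
#' out-of-term kernels (\code{\link{partition_kernels}}) and a two-kernel
#' (GO-GBLUP: variant layer; GO-TBLUP: transcript layer) or four-kernel
#' (GO-GTBLUP: both layers) REML model is run through the shared
#' cross-validation design; the in-term training variance proportion is
#' sigma2_GO over the total of all components plus residual. All terms
#' reuse one design, so accuracies are paired across terms and modes.
#'
#' @param mode \code{"GO-GBLUP"}, \code{"GO-TBLUP"}, or \code{"GO-GTBLUP"}.
#' @param y named phenotype vector.
#' @param terms a data.frame from \code{\link{enumerate_go_terms}} (term,
#'   genes).
#' @param cv a \code{\link{make_cv_design}} design on the phenotyped lines.
#' @param genotypes genotype layer (matrix, \code{genotype_matrix} or
#'   standardized features) for the variant-side modes.
#' @param expression expression layer for the transcript-side modes.
#' @param variant_map a \code{\link{map_variants_to_genes}} result
#'   (required by the variant-side modes).
#' @param baseline compute the matching non-GO model's mean accuracy
#'   (GBLUP / TBLUP / GTBLUP) on the same design (default TRUE).
#' @return an object of class \code{"go_scan"}: data.frame with one row per
#'   scanned term (\code{term}, \code{mode}, \code{n_genes},
#'   \code{n_features}, \code{mean_r}, \code{sem_r}, \code{prop_in} — summed
#'   over the in-term components for GO-GTBLUP — plus per-component
#'   columns), with attributes \code{baseline_r} and \code{skipped}.
#' @export
run_go_scan <- function(mode = c("GO-GBLUP", "GO-TBLUP", "GO-GTBLUP"),
                        y, terms, cv, genotypes = NULL, expression = NULL,
                        variant_map = NULL, baseline = TRUE) {
  mode <- match.arg(mode)
  y <- y[!is.na(y)]
  use_g <- mode %in% c("GO-GBLUP", "GO-GTBLUP")
  use_t <- mode %in% c("GO-TBLUP", "GO-GTBLUP")
  if (use_g && (is.null(genotypes) || is.null(variant_map)))
    stop_ob("%s needs genotypes and a variant-to-gene map", mode)
  if (use_t && is.null(expression)) stop_ob("%s needs expression", mode)
  W <- if (use_g) as_standardized(genotypes) else NULL
  Z <- if (use_t) as_standardized(expression) else NULL
  ids <- names(y)
  for (S in list(W, Z)) if (!is.null(S)) ids <- intersect(ids, rownames(S$values))
  ids <- sort(ids)
  y <- y[ids]
  if (!setequal(cv$line_ids, ids))
    stop_ob("CV design lines differ from the phenotyped lines with data")

  # variant ids per gene, inverted once from the variant->gene map
  gene_variants <- NULL
  if (use_g) {
    vm <- variant_map$map
    long <- data.frame(variant = rep(names(vm), lengths(vm)),
                       gene = unlist(vm, use.names = FALSE),
                       stringsAsFactors = FALSE)
    gene_variants <- split(long$variant, long$gene)
  }

  base_r <- NA_real_
  if (baseline) {
    base_type <- switch(mode, "GO-GBLUP" = "GBLUP", "GO-TBLUP" = "TBLUP",
                        "GO-GTBLUP" = "GTBLUP")
    bm <- run_model_cv(base_type, y, genotypes = W, expression = Z, cv = cv)
    base_r <- bm$mean_r
  }

  rows <- list(); skipped <- character(0)
  for (i in seq_len(nrow(terms))) {
    term <- terms$term[i]
    genes <- terms$genes[[i]]
    kernels <- list()
    n_feat <- 0L
    ok <- TRUE
    if (use_g) {
      v_in <- unique(unlist(gene_variants[genes], use.names = FALSE))
      v_in <- intersect(v_in, W$feature_ids)
      if (!length(v_in) || length(v_in) >= W$n_features_used) ok <- FALSE
      else {
        pk <- partition_kernels(W, v_in, paste0(term, "-g-in"),
                                paste0(term, "-g-out"))
        kernels$g_GO <- pk$K_in; kernels$g_notGO <- pk$K_out
        n_feat <- n_feat + length(v_in)
      }
    }
    if (ok && use_t) {
      t_in <- intersect(genes, Z$feature_ids)
      if (!length(t_in) || length(t_in) >= Z$n_features_used) ok <- FALSE
      else {
        pk <- partition_kernels(Z, t_in, paste0(term, "-t-in"),
                                paste0(term, "-t-out"))
        kernels$t_GO <- pk$K_in; kernels$t_notGO <- pk$K_out
        n_feat <- n_feat + length(t_in)
      }
    }
    if (!ok) {
      warn_ob("term %s skipped (empty or full feature partition)", term)
      skipped <- c(skipped, term)
      next
    }
    acc <- prop_in <- numeric(0)
    comp_props <- NULL
    for (r in seq_len(cv$n_reps)) {
      fold_of <- cv$assignment[r, ids]
      for (f in seq_len(cv$k)) {
        test_ids <- ids[fold_of == f]
        train_ids <- ids[fold_of != f]
        fit <- tryCatch(kblup(y[train_ids], kernels),
                        error = function(e) NULL)
        if (is.null(fit) || !fit$converged) {
          acc <- c(acc, NA_real_); prop_in <- c(prop_in, NA_real_)
          next
        }
        pred <- blup_predict(fit, kernels, test_ids)
        acc <- c(acc, as.numeric(pearson_accuracy(y[test_ids], pred)))
        pr <- variance_proportions(fit)
        in_names <- grep("_GO$", names(pr), value = TRUE)
        prop_in <- c(prop_in, sum(pr[in_names]))
        comp_props <- rbind(comp_props, pr)
      }
    }
    sr <- summarize_cv(acc)
    mp <- if (is.null(comp_props)) NULL else colMeans(comp_props, na.rm = TRUE)
    row <- data.frame(term = term, mode = mode, n_genes = length(genes),
                      n_features = n_feat, mean_r = sr[["mean"]],
                      sem_r = sr[["sem"]],
                      prop_in = mean(prop_in, na.rm = TRUE),
                      baseline_r = base_r, stringsAsFactors = FALSE)
    if (!is.null(mp))
      for (nmp in names(mp)) row[[paste0("prop_", nmp)]] <- mp[[nmp]]
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows))
    stop_ob("no scannable terms")
  out <- do.call(rbind, rows)
  attr(out, "baseline_r") <- base_r
  attr(out, "skipped") <- skipped
  class(out) <- c("go_scan", "data.frame")
  out
}

#' Rank scanned GO terms by prediction accuracy
#'
#' Descending mean accuracy; ties broken by larger mean in-term variance
#' proportion, then lexicographic term id. The \code{top_k} best terms are
#' labelled.
#'
#' @param summaries a \code{\link{run_go_scan}} result.
#' @param top_k number of terms to label (default 3).
#' @return the summaries reordered, with columns \code{rank} and
#'   \code{top} (logical).
#' @export
rank_go_terms <- function(summaries, top_k = 3) {
  stopifnot(nrow(summaries) >= 1)
  ord <- order(-summaries$mean_r, -summaries$prop_in, summaries$term)
  out <- summaries[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$top <- out$rank <= top_k
  out
}

#' GO scan diagnostics: accuracy vs term size and explained variance
#'
#' Pearson correlation of per-term mean accuracy with (i) the number of
#' in-kernel features and (ii) the mean in-term training variance
#' proportion. Under an infinitesimal architecture the size correlation
#' should be near zero, while a strong accuracy-proportion correlation
#' indicates the models capture signal rather than overfit noise.
#'
#' @param summaries a \code{\link{run_go_scan}} result with >= 3 terms.
#' @return list with \code{r_accuracy_size} and
#'   \code{r_accuracy_proportion}; degenerate (constant) inputs give a
#'   flagged 0 per the accuracy convention.
#' @export
go_scan_diagnostics <- function(summaries) {
  if (nrow(summaries) < 3) stop_ob("need at least 3 term summaries")
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      return(structure(0, degenerate = TRUE))
    structure(stats::cor(a, b), degenerate = FALSE)
  }
  list(r_accuracy_size = safe_cor(summaries$mean_r, summaries$n_features),
       r_accuracy_proportion = safe_cor(summaries$mean_r, summaries$prop_in))
}

#' @method plot go_scan
#' @export
plot.go_scan <- function(x, which = c("size", "proportion"), ...) {
  which <- match.arg(which)
  xv <- if (which == "size") x$n_features else x$prop_in
  xl <- if (which == "size") "in-term features" else
    "mean in-term variance proportion (training)"
  graphics::plot(xv, x$mean_r, xlab = xl, ylab = "mean test r",
                 main = sprintf("%s scan", x$mode[1]), ...)
  graphics::abline(stats::lm(x$mean_r ~ xv), col = "grey40")
  bl <- attr(x, "baseline_r")
  if (is.finite(bl)) graphics::abline(h = bl, lty = 2)
  invisible(x)
}
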