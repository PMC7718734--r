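#' Transcriptome-wide association scan
#'
#' Regresses the phenotype on each gene's abundance one at a time (ordinary
#' least squares on line means, intercept plus that gene), with a two-sided
#' t test on the slope at n - 2 degrees of freedom. Covariate adjustment is
#' assumed to have happened upstream on the line means, so no further
#' covariates enter the per-gene model. Constant genes get p = 1.
#'
#' @param y_train named phenotype vector (training lines, >= 10).
#' @param E_train an \code{expression_matrix}, a standardized-features
#'   object, or a plain lines x genes matrix covering the training lines.
#' @return an object of class \code{"twas_result"}: data.frame with one row
#'   per gene (\code{gene}, \code{slope}, \code{se}, \code{t}, \code{p},
#'   \code{n}).
#' @export
twas_scan <- function(y_train, E_train) {
  if (is.null(names(y_train))) stop_ob("'y_train' must be named by line id")
  y <- y_train[!is.na(y_train)]
  n <- length(y)
  if (n < 10) stop_ob("TWAS needs at least 10 training lines, have %d", n)
  X <- if (inherits(E_train, "standardized_features")) E_train$values
       else raw_feature_matrix(E_train)
  missing <- setdiff(names(y), rownames(X))
  if (length(missing))
    stop_ob("expression lacks lines: %s",
            paste(utils::head(missing, 5), collapse = ", "))
  X <- X[names(y), , drop = FALSE]
  yc <- y - mean(y)
  Xc <- sweep(X, 2, colMeans(X), `-`)
  Sxx <- colSums(Xc^2)
  Sxy <- drop(crossprod(Xc, yc))
  Syy <- sum(yc^2)
  ok <- Sxx > 1e-12 * n
  slope <- ifelse(ok, Sxy / Sxx, NA_real_)
  rss <- pmax(Syy - ifelse(ok, Sxy^2 / Sxx, 0), 0)
  se <- ifelse(ok, sqrt(rss / (n - 2) / Sxx), NA_real_)
  tstat <- ifelse(ok & se > 0, slope / se,
                  ifelse(ok, sign(slope) * Inf, NA_real_))
  p <- ifelse(ok, 2 * stats::pt(-abs(tstat), df = n - 2), 1)
  p[ok & !is.finite(tstat)] <- 0   # exact fit
  structure(data.frame(gene = colnames(X), slope = slope, se = se,
                       t = tstat, p = p, n = n, stringsAsFactors = FALSE),
            class = c("twas_result", "data.frame"))
}

#' Select genes below a TWAS p-value threshold
#'
#' Genes with p strictly less than \code{p_max}; an empty selection is
#' permitted (and flagged by the \code{"empty"} attribute), letting the
#' caller degrade to an intercept-only prediction at stringent thresholds.
#'
#' @param res a \code{\link{twas_scan}} result.
#' @param p_max p-value threshold, exclusive (the scan thresholds raw
#'   p-values; typical values 0.5, 0.1, 1e-2, ..., 1e-6).
#' @return character vector of selected gene ids.
#' @export
select_genes <- function(res, p_max) {
  stopifnot(inherits(res, "twas_result"), is.numeric(p_max),
            length(p_max) == 1)
  sel <- res$gene[!is.na(res$p) & res$p < p_max]
  structure(sel, empty = length(sel) == 0L)
}

#' Draw a random gene set
#'
#' Uniform sample of k genes without replacement, reproducible from the
#' seed — the control analysis contrasting TWAS-selected genes with
#' arbitrary ones of the same count.
#'
#' @param gene_ids candidate gene ids.
#' @param k number of genes to draw (typical values 5, 50, 500, 1000, 5000).
#' @param seed integer seed.
#' @return character vector of k distinct gene ids.
#' @export
random_gene_set <- function(gene_ids, k, seed) {
  if (k > length(gene_ids))
    stop_ob("cannot draw %d genes from %d", k, length(gene_ids))
  with_seed(seed, sample(gene_ids, k))
}
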