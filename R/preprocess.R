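#' Filter variants on minor allele frequency and call rate
#'
#' Retains exactly the variants with MAF strictly greater than
#' \code{maf_min} and call rate strictly greater than \code{call_rate_min}
#' (both inequalities strict), preserving column order. MAF is computed on
#' non-missing calls.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param maf_min minimum minor allele frequency (exclusive), default 0.05.
#' @param call_rate_min minimum call rate (exclusive), default 0.8.
#' @return the filtered \code{genotype_matrix}.
#' @export
filter_variants <- function(G, maf_min = 0.05, call_rate_min = 0.8) {
  stopifnot(inherits(G, "genotype_matrix"))
  keep <- maf(G) > maf_min & call_rate(G) > call_rate_min
  keep[is.na(keep)] <- FALSE
  if (!any(keep))
    stop_ob("no variants survive MAF > %g and call rate > %g; relax the thresholds",
            maf_min, call_rate_min)
  G$dosages <- G$dosages[, keep, drop = FALSE]
  G$variants <- G$variants[keep, , drop = FALSE]
  G
}

#' Mean-impute residual missing genotype calls
#'
#' Each missing dosage is replaced by its variant's mean dosage over
#' non-missing calls, leaving a complete matrix for standardization.
#' Intended to run after \code{\link{filter_variants}}, which guarantees
#' every variant has a positive call rate.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @return the \code{genotype_matrix} with no missing dosages (coding widens
#'   to \code{"0/1/2"}-style real values; the imputed object is only meant
#'   for kernel construction).
#' @export
impute_missing <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- G$dosages
  miss <- is.na(d)
  if (any(miss)) {
    cm <- colMeans(d, na.rm = TRUE)
    stopifnot(all(is.finite(cm)))  # all-missing variants cannot pass the filter
    idx <- which(miss, arr.ind = TRUE)
    d[miss] <- cm[idx[, 2]]
    G$dosages <- d
  }
  G
}

#' Filter genes on mean expression
#'
#' Retains genes whose mean abundance across lines is strictly greater than
#' \code{mean_threshold}. The default threshold (-1.828 log2FPKM) is the
#' boundary between the unexpressed and expressed modes of a bimodal
#' abundance distribution, taken as a configuration parameter.
#'
#' @param E an \code{\link{expression_matrix}}.
#' @param mean_threshold minimum across-line mean, exclusive.
#' @return the filtered \code{expression_matrix}.
#' @export
filter_expressed_genes <- function(E, mean_threshold = -1.828) {
  stopifnot(inherits(E, "expression_matrix"))
  keep <- colMeans(E$abundances) > mean_threshold
  if (!any(keep))
    stop_ob("no genes with mean expression > %g", mean_threshold)
  E$abundances <- E$abundances[, keep, drop = FALSE]
  E$genes <- E$genes[keep, , drop = FALSE]
  E
}

#' Adjust line-mean phenotypes for covariates
#'
#' Each trait is replaced by the residuals of an ordinary least squares fit
#' on an intercept plus the named covariates, with the trait's grand mean
#' added back, so adjusted values stay in trait units. Lines missing any
#' covariate are dropped and reported in \code{dropped_lines}; aliased
#' (rank-deficient) covariate columns are dropped with a warning.
#'
#' @param pheno a \code{\link{phenotype_table}}.
#' @param covariate_names covariate columns to adjust for; empty vector
#'   returns the input unchanged.
#' @return an adjusted \code{phenotype_table}.
#' @export
adjust_phenotypes <- function(pheno, covariate_names = pheno$covariates) {
  stopifnot(inherits(pheno, "phenotype_table"))
  if (!length(covariate_names)) return(pheno)
  missing_cov <- setdiff(covariate_names, names(pheno$data))
  if (length(missing_cov))
    stop_ob("covariates not in table: %s", paste(missing_cov, collapse = ", "))
  dat <- pheno$data
  cov_ok <- stats::complete.cases(dat[, covariate_names, drop = FALSE])
  dropped <- dat$line_id[!cov_ok]
  dat <- dat[cov_ok, , drop = FALSE]
  fml <- stats::as.formula(paste("~", paste(sprintf("`%s`", covariate_names),
                                            collapse = " + ")))
  X <- stats::model.matrix(fml, data = dat)
  for (tr in pheno$traits) {
    y <- dat[[tr]]
    ok <- !is.na(y)
    if (sum(ok) < 2) next
    fit <- stats::lm.fit(X[ok, , drop = FALSE], y[ok])
    if (any(is.na(fit$coefficients))) {
      aliased <- names(fit$coefficients)[is.na(fit$coefficients)]
      warn_ob("aliased covariate column(s) dropped for trait '%s': %s",
              tr, paste(aliased, collapse = ", "))
    }
    dat[[tr]][ok] <- fit$residuals + mean(y[ok])
  }
  out <- phenotype_table(dat, traits = pheno$traits,
                         covariates = pheno$covariates)
  out$dropped_lines <- dropped
  out
}

#' Map variants to genes by genomic position
#'
#' A variant maps to gene g iff its position lies in
#' [start - window_bp, end + window_bp] on the same chromosome (1-based
#' inclusive); variants hitting several overlapping genes map to all of
#' them, and unmapped variants are simply absent from the map.
#'
#' @param G a \code{\link{genotype_matrix}} with chrom/pos metadata.
#' @param ann an \code{\link{annotation_map}} with gene spans.
#' @param window_bp flanking window in base pairs (default 1000).
#' @return an object of class \code{"variant_gene_map"}: list with
#'   \code{map} (named list variant id -> gene ids) and \code{window_bp}.
#' @export
map_variants_to_genes <- function(G, ann, window_bp = 1000) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(ann, "annotation_map"),
            window_bp >= 0)
  spans <- ann$gene_spans
  if (is.null(spans)) stop_ob("annotation has no gene spans")
  v <- G$variants
  map <- vector("list", 0)
  for (chr in unique(v$chrom[!is.na(v$chrom)])) {
    vi <- which(v$chrom == chr & !is.na(v$pos))
    si <- which(spans$chrom == chr)
    if (!length(vi) || !length(si)) next
    lo <- spans$start[si] - window_bp
    hi <- spans$end[si] + window_bp
    for (k in vi) {
      hit <- si[v$pos[k] >= lo & v$pos[k] <= hi]
      if (length(hit))
        map[[v$id[k]]] <- unique(spans$gene[hit])
    }
  }
  structure(list(map = map, window_bp = window_bp),
            class = "variant_gene_map")
}
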