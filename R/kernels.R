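#' Center and standardize feature columns
#'
#' Each column is centered by its mean and scaled by its population
#' (divisor-n) standard deviation, the convention under which the mean
#' diagonal of the derived linear kernel is exactly 1. Zero-variance columns
#' are dropped and reported.
#'
#' @param M numeric matrix, lines x features, no missing values; rownames
#'   are line ids.
#' @return an object of class \code{"standardized_features"}: list with
#'   \code{values} (standardized matrix), \code{feature_ids},
#'   \code{dropped_features}, and \code{n_features_used}.
#' @export
standardize_columns <- function(M) {
  M <- as.matrix(M)
  if (anyNA(M)) stop_ob("standardize_columns requires a complete matrix")
  if (is.null(colnames(M))) colnames(M) <- paste0("f", seq_len(ncol(M)))
  n <- nrow(M)
  mu <- colMeans(M)
  v <- colMeans(M^2) - mu^2          # population variance (divisor n)
  v[v < 0] <- 0
  keep <- v > 1e-12 * pmax(1, mu^2)
  if (!any(keep)) stop_ob("all feature columns have zero variance")
  W <- sweep(M[, keep, drop = FALSE], 2, mu[keep], `-`)
  W <- sweep(W, 2, sqrt(v[keep]), `/`)
  structure(list(values = W, feature_ids = colnames(M)[keep],
                 dropped_features = colnames(M)[!keep],
                 n_features_used = sum(keep)),
            class = "standardized_features")
}

#' @method print standardized_features
#' @export
print.standardized_features <- function(x, ...) {
  cat(sprintf("standardized_features: %d lines x %d features (%d dropped)\n",
              nrow(x$values), x$n_features_used, length(x$dropped_features)))
  invisible(x)
}

new_kernel <- function(values, n_features_used, label) {
  structure(list(values = values, n_features_used = n_features_used,
                 label = label),
            class = "omni_kernel")
}

#' @method print omni_kernel
#' @export
print.omni_kernel <- function(x, ...) {
  cat(sprintf("kernel '%s': %d x %d, built from %d features\n",
              x$label, nrow(x$values), ncol(x$values), x$n_features_used))
  invisible(x)
}

#' Linear relationship kernel from standardized features
#'
#' Computes W W' / p where W is the standardized feature matrix and p the
#' number of retained features — the GRM when features are variants, the
#' TRM when features are transcripts.
#'
#' @param F a \code{\link{standardize_columns}} result.
#' @param label kernel label (e.g. \code{"GRM"}, \code{"TRM"}).
#' @return an object of class \code{"omni_kernel"} with fields
#'   \code{values} (n x n symmetric), \code{n_features_used}, \code{label}.
#' @export
linear_kernel <- function(F, label = "GRM") {
  stopifnot(inherits(F, "standardized_features"))
  if (F$n_features_used < 1) stop_ob("no retained features")
  K <- tcrossprod(F$values) / F$n_features_used
  K <- (K + t(K)) / 2
  new_kernel(K, F$n_features_used, label)
}

#' Hadamard interaction kernel
#'
#' Element-wise product of two kernels on the same lines; models the
#' genome-by-transcriptome interaction covariance (IRM). By the Schur
#' product theorem the result of two PSD kernels is PSD.
#'
#' @param K1,K2 \code{omni_kernel} objects with identical line ids in
#'   identical order.
#' @param label kernel label, default \code{"IRM"}.
#' @return an \code{omni_kernel}; \code{n_features_used} is the product of
#'   the inputs' feature counts.
#' @export
interaction_kernel <- function(K1, K2, label = "IRM") {
  stopifnot(inherits(K1, "omni_kernel"), inherits(K2, "omni_kernel"))
  if (!identical(rownames(K1$values), rownames(K2$values)))
    stop_ob("kernels have mismatched line ids")
  new_kernel(K1$values * K2$values,
             K1$n_features_used * K2$n_features_used, label)
}

#' Partition a feature set into in-term and out-of-term kernels
#'
#' Features are standardized once on the full set; the in-kernel uses the
#' columns named in \code{in_ids} (divisor |in|) and the out-kernel the
#' complement (divisor |out|), so that
#' |in| K_in + |out| K_out = p K_full exactly.
#'
#' @param F a \code{\link{standardize_columns}} result over all features.
#' @param in_ids feature ids forming the in-set (e.g. variants or
#'   transcripts of one GO term).
#' @param label_in,label_out kernel labels.
#' @return list with elements \code{K_in} and \code{K_out}.
#' @export
partition_kernels <- function(F, in_ids, label_in = "GO-in",
                              label_out = "GO-out") {
  stopifnot(inherits(F, "standardized_features"))
  in_set <- F$feature_ids %in% in_ids
  n_in <- sum(in_set)
  n_out <- sum(!in_set)
  if (n_in == 0) stop_ob("empty in-partition for %s", label_in)
  if (n_out == 0) stop_ob("empty out-partition (in-set %s covers all features)",
                          label_in)
  Wi <- F$values[, in_set, drop = FALSE]
  Wo <- F$values[, !in_set, drop = FALSE]
  list(K_in = new_kernel(tcrossprod(Wi) / n_in, n_in, label_in),
       K_out = new_kernel(tcrossprod(Wo) / n_out, n_out, label_out))
}

#' Subset a kernel to a set of lines
#'
#' @param K an \code{omni_kernel}.
#' @param rows,cols line ids.
#' @return plain numeric matrix \code{K[rows, cols]}.
#' @export
kernel_block <- function(K, rows, cols = rows) {
  stopifnot(inherits(K, "omni_kernel"))
  K$values[rows, cols, drop = FALSE]
}

# kernels entering one model, all sharing identical line ids and order
kernel_set <- function(...) {
  ks <- list(...)
  if (length(ks) == 1 && is.list(ks[[1]]) && !inherits(ks[[1]], "omni_kernel"))
    ks <- ks[[1]]
  stopifnot(length(ks) >= 1, all(vapply(ks, inherits, logical(1), "omni_kernel")))
  ids <- rownames(ks[[1]]$values)
  for (k in ks)
    if (!identical(rownames(k$values), ids))
      stop_ob("kernel set with mismatched line ids")
  if (is.null(names(ks)) || any(!nzchar(names(ks))))
    names(ks) <- vapply(ks, function(k) k$label, character(1))
  structure(ks, class = "kernel_set")
}
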