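#' Replicated k-fold cross-validation design
#'
#' Per replicate, a fresh seeded shuffle of the lines is partitioned into k
#' folds whose sizes differ by at most one; every line is tested exactly
#' once per replicate. The design is a pure function of the line ids, k,
#' the number of replicates and the seed, so folds can be shared across
#' models for paired comparisons.
#'
#' @param line_ids character vector of line ids.
#' @param k number of folds (default 5).
#' @param n_reps number of replicates (default 30).
#' @param seed integer seed.
#' @return an object of class \code{"cv_design"}: list with
#'   \code{assignment} (n_reps x n_lines integer matrix of fold indices),
#'   \code{line_ids}, \code{k}, \code{n_reps}, \code{seed}.
#' @export
make_cv_design <- function(line_ids, k = 5, n_reps = 30, seed = 1) {
  n <- length(line_ids)
  if (anyDuplicated(line_ids)) stop_ob("duplicate line ids")
  if (n < 2 * k)
    stop_ob("need at least 2k = %d lines for %d-fold CV, have %d", 2 * k, k, n)
  assignment <- matrix(NA_integer_, n_reps, n,
                       dimnames = list(NULL, line_ids))
  folds <- rep(seq_len(k), length.out = n)
  for (r in seq_len(n_reps)) {
    ord <- with_seed(derive_seed(seed, r), sample.int(n))
    assignment[r, ord] <- folds
  }
  structure(list(assignment = assignment, line_ids = line_ids, k = k,
                 n_reps = n_reps, seed = seed),
            class = "cv_design")
}

#' @method print cv_design
#' @export
print.cv_design <- function(x, ...) {
  cat(sprintf("cv_design: %d lines, %d-fold x %d replicates (seed %d)\n",
              length(x$line_ids), x$k, x$n_reps, x$seed))
  invisible(x)
}

#' Pearson prediction accuracy
#'
#' Sample Pearson correlation between observed and predicted phenotypes.
#' If the predictions have zero variance (e.g. an all-clamped fit predicting
#' the training mean everywhere) the accuracy is defined as 0 and flagged
#' via the \code{"degenerate"} attribute, keeping aggregation total.
#'
#' @param y_true,y_pred numeric vectors of equal length >= 3.
#' @return correlation in [-1, 1], with attribute \code{degenerate}.
#' @export
pearson_accuracy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop_ob("length mismatch: %d vs %d", length(y_true), length(y_pred))
  if (length(y_true) < 3) stop_ob("need at least 3 pairs")
  if (stats::sd(y_pred) == 0 || stats::sd(y_true) == 0)
    return(structure(0, degenerate = TRUE))
  structure(stats::cor(y_true, y_pred), degenerate = FALSE)
}

#' Mean and standard error over fold-level values
#'
#' @param values numeric vector of per-(replicate, fold) values; \code{NA}s
#'   (failed folds) are excluded from both mean and SEM denominators.
#' @return named vector \code{c(mean, sem)}.
#' @export
summarize_cv <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2) stop_ob("need at least 2 non-missing values")
  c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)))
}

#' Run one prediction model through replicated cross-validation
#'
#' For every (replicate, fold) of the design: variance components are
#' estimated on the training lines only — including any within-fold TWAS
#' scan or random gene draw — and the fold's held-out lines are predicted by
#' BLUP; Pearson accuracy and training variance proportions are recorded and
#' aggregated over all k x n_reps folds. Kernels are built once on all lines
#' from globally standardized features; only variance-component estimation
#' and gene selection are restricted to the training lines.
#'
#' Model types:
#' \describe{
#'   \item{GBLUP}{one genomic kernel (GRM).}
#'   \item{TBLUP}{one transcriptomic kernel (TRM).}
#'   \item{GTBLUP}{GRM + TRM.}
#'   \item{GTIBLUP}{GRM + TRM + Hadamard interaction kernel (IRM).}
#'   \item{TWAS_TBLUP}{per fold, a TWAS scan on the training lines selects
#'     genes with p < \code{params$p_max}; a trait-specific TRM is built
#'     from them. An empty selection degrades to an intercept-only
#'     prediction (fold r = 0, flagged).}
#'   \item{RANDOM_GENES}{per fold, \code{params$k_genes} genes drawn at
#'     random (seeded by replicate and fold) build the TRM — the control
#'     for TWAS selection.}
#'   \item{RF}{Random Forest on raw expression values.}
#' }
#'
#' @param type model type, see above.
#' @param y named phenotype vector; lines with missing values are dropped
#'   before fold assignment.
#' @param genotypes a \code{genotype_matrix}, standardized-features object,
#'   or NULL if the model needs no genomic layer.
#' @param expression an \code{expression_matrix}, standardized-features
#'   object, or NULL.
#' @param cv a \code{\link{make_cv_design}} design; defaults to 5-fold,
#'   30 replicates seeded with \code{seed}.
#' @param params list of model parameters (\code{p_max}, \code{k_genes},
#'   \code{n_trees}, \code{m_try}).
#' @param seed seed used when \code{cv} is NULL and for per-fold draws.
#' @return an object of class \code{"cv_metrics"}: list with
#'   \code{per_fold} (data.frame: replicate, fold, n_test, r, degenerate,
#'   converged, and one \code{prop_*} column per variance component),
#'   \code{mean_r}, \code{sem_r}, \code{mean_props}, \code{sem_props},
#'   \code{model}, \code{n_failed}.
#' @export
run_model_cv <- function(type = c("GBLUP", "TBLUP", "GTBLUP", "GTIBLUP",
                                  "TWAS_TBLUP", "RANDOM_GENES", "RF"),
                         y, genotypes = NULL, expression = NULL, cv = NULL,
                         params = list(), seed = 1) {
  type <- match.arg(type)
  y <- y[!is.na(y)]
  need_g <- type %in% c("GBLUP", "GTBLUP", "GTIBLUP")
  need_e <- type %in% c("TBLUP", "GTBLUP", "GTIBLUP", "TWAS_TBLUP",
                        "RANDOM_GENES", "RF")
  if (need_g && is.null(genotypes)) stop_ob("%s needs a genomic layer", type)
  if (need_e && is.null(expression)) stop_ob("%s needs an expression layer", type)

  W <- if (need_g) as_standardized(genotypes) else NULL
  Z <- if (need_e) as_standardized(expression) else NULL
  Eraw <- if (type == "RF") raw_feature_matrix(expression) else NULL
  ids0 <- names(y)
  for (S in list(W, Z))
    if (!is.null(S)) ids0 <- intersect(ids0, rownames(S$values))
  ids <- sort(ids0)
  y <- y[ids]
  if (is.null(cv)) cv <- make_cv_design(ids, seed = seed)
  if (!setequal(cv$line_ids, ids))
    stop_ob("CV design lines differ from phenotyped lines with data")

  kernels <- switch(type,
    GBLUP = list(GRM = linear_kernel(W, "GRM")),
    TBLUP = list(TRM = linear_kernel(Z, "TRM")),
    GTBLUP = list(GRM = linear_kernel(W, "GRM"),
                  TRM = linear_kernel(Z, "TRM")),
    GTIBLUP = {
      G <- linear_kernel(W, "GRM"); T <- linear_kernel(Z, "TRM")
      list(GRM = G, TRM = T, IRM = interaction_kernel(G, T))
    },
    NULL)

  rows <- list()
  comp_names <- NULL
  for (r in seq_len(cv$n_reps)) {
    fold_of <- cv$assignment[r, ids]
    for (f in seq_len(cv$k)) {
      test_ids <- ids[fold_of == f]
      train_ids <- ids[fold_of != f]
      res <- cv_one_fold(type, y, train_ids, test_ids, kernels, Z, Eraw,
                         params, derive_seed(cv$seed, r, f))
      comp_names <- comp_names %||% names(res$props)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, fold = f, n_test = length(test_ids), r = res$r,
        degenerate = res$degenerate, converged = res$converged,
        t(res$props %||% stats::setNames(numeric(0), character(0))),
        check.names = FALSE)
    }
  }
  per_fold <- do.call(rbind, rows)
  prop_cols <- setdiff(names(per_fold),
                       c("replicate", "fold", "n_test", "r", "degenerate",
                         "converged"))
  n_failed <- sum(is.na(per_fold$r))
  if (n_failed)
    warn_ob("%d of %d folds failed to converge and are excluded from means",
            n_failed, nrow(per_fold))
  sr <- summarize_cv(per_fold$r)
  mean_props <- sem_props <- NULL
  if (length(prop_cols)) {
    mp <- vapply(prop_cols, function(cn) summarize_cv(per_fold[[cn]]),
                 numeric(2))
    mean_props <- stats::setNames(mp["mean", ], prop_cols)
    sem_props <- stats::setNames(mp["sem", ], prop_cols)
  }
  structure(list(per_fold = per_fold, mean_r = sr[["mean"]],
                 sem_r = sr[["sem"]], mean_props = mean_props,
                 sem_props = sem_props, model = type, params = params,
                 n_failed = n_failed, cv = cv),
            class = "cv_metrics")
}

# fit + predict one fold; returns r, proportions, convergence
cv_one_fold <- function(type, y, train_ids, test_ids, kernels, Z, Eraw,
                        params, fold_seed) {
  y_train <- y[train_ids]
  if (type == "RF") {
    model <- fit_forest(y_train, Eraw[train_ids, , drop = FALSE],
                        n_trees = params$n_trees %||% 1000,
                        m_try = params$m_try,
                        seed = fold_seed)
    pred <- predict_forest(model, Eraw[test_ids, , drop = FALSE])
    r <- pearson_accuracy(y[test_ids], pred)
    return(list(r = as.numeric(r), degenerate = attr(r, "degenerate"),
                converged = TRUE, props = NULL))
  }
  if (type %in% c("TWAS_TBLUP", "RANDOM_GENES")) {
    genes <- if (type == "TWAS_TBLUP") {
      scan <- twas_scan(y_train, Z)
      select_genes(scan, params$p_max %||% 0.01)
    } else {
      random_gene_set(Z$feature_ids, params$k_genes %||% 500, fold_seed)
    }
    if (!length(genes)) {
      # intercept-only degradation: every test line predicted at the
      # training mean, accuracy 0 by the degenerate convention
      return(list(r = 0, degenerate = TRUE, converged = TRUE,
                  props = c(prop_TRM = 0, prop_residual = 1)))
    }
    Wsel <- F_subset(Z, genes)
    kernels <- list(TRM = linear_kernel(Wsel, "TRM"))
  }
  fit <- tryCatch(kblup(y_train, kernels), error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    return(list(r = NA_real_, degenerate = NA,
                converged = FALSE,
                props = stats::setNames(
                  rep(NA_real_, length(kernels) + 1),
                  paste0("prop_", c(names(kernels), "residual")))))
  }
  pred <- blup_predict(fit, kernels, test_ids)
  r <- pearson_accuracy(y[test_ids], pred)
  props <- variance_proportions(fit)
  list(r = as.numeric(r), degenerate = attr(r, "degenerate"),
       converged = TRUE,
       props = stats::setNames(props, paste0("prop_", names(props))))
}

# restrict a standardized-features object to a feature subset (columns were
# standardized once on the full set; divisor is the subset size downstream)
F_subset <- function(F, ids) {
  keep <- F$feature_ids %in% ids
  structure(list(values = F$values[, keep, drop = FALSE],
                 feature_ids = F$feature_ids[keep],
                 dropped_features = F$dropped_features,
                 n_features_used = sum(keep)),
            class = "standardized_features")
}

as_standardized <- function(x) {
  if (inherits(x, "standardized_features")) return(x)
  standardize_columns(raw_feature_matrix(x))
}

raw_feature_matrix <- function(x) {
  if (inherits(x, "genotype_matrix")) {
    if (anyNA(x$dosages))
      stop_ob("genotypes contain missing calls; run impute_missing() first")
    return(x$dosages)
  }
  if (inherits(x, "expression_matrix")) return(x$abundances)
  if (is.matrix(x)) return(x)
  stop_ob("cannot extract a feature matrix from class %s",
          paste(class(x), collapse = "/"))
}

#' @method print cv_metrics
#' @export
print.cv_metrics <- function(x, ...) {
  cat(sprintf("%s cross-validation: %d-fold x %d replicates\n", x$model,
              x$cv$k, x$cv$n_reps))
  cat(sprintf("  mean r = %.3f +/- %.3f (SEM over %d folds%s)\n", x$mean_r,
              x$sem_r, sum(!is.na(x$per_fold$r)),
              if (x$n_failed) sprintf(", %d failed", x$n_failed) else ""))
  if (!is.null(x$mean_props))
    for (i in seq_along(x$mean_props))
      cat(sprintf("  %-14s %.3f +/- %.3f\n", names(x$mean_props)[i],
                  x$mean_props[i], x$sem_props[i]))
  invisible(x)
}

#' @method plot cv_metrics
#' @export
plot.cv_metrics <- function(x, ...) {
  graphics::boxplot(r ~ replicate, data = x$per_fold,
                    xlab = "replicate", ylab = "fold Pearson r",
                    main = sprintf("%s prediction accuracy", x$model), ...)
  graphics::abline(h = x$mean_r, lty = 2)
  invisible(x)
}
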