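#' Fit the Random Forest comparison model
#'
#' An ensemble of S regression trees, each grown on a bootstrap sample of
#' the training lines and choosing splits from a random subset of m_try
#' transcripts per node; predictions average the trees with equal weight
#' 1/S. Backed by the randomForest package with the documented regression
#' defaults (m_try = floor(m/3), minimum node size 5) and 1000 trees.
#' Feature columns are ordered by id before fitting so results do not
#' depend on column order.
#'
#' @param y_train named phenotype vector (>= 10 training lines).
#' @param X_train lines x transcripts matrix of expression values covering
#'   the training lines.
#' @param n_trees number of trees S (default 1000).
#' @param m_try features tried per split; default \code{floor(m/3)}.
#' @param node_size minimum terminal node size (default 5).
#' @param seed integer seed; fixing it makes fits and predictions
#'   bitwise-reproducible.
#' @return an object of class \code{"forest_model"}.
#' @export
fit_forest <- function(y_train, X_train, n_trees = 1000, m_try = NULL,
                       node_size = 5, seed = 1) {
  if (is.null(names(y_train))) stop_ob("'y_train' must be named by line id")
  y <- y_train[!is.na(y_train)]
  if (length(y) < 10) stop_ob("need at least 10 training lines")
  X <- as.matrix(X_train)
  missing <- setdiff(names(y), rownames(X))
  if (length(missing))
    stop_ob("feature matrix lacks lines: %s",
            paste(utils::head(missing, 5), collapse = ", "))
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  ord <- order(colnames(X))
  X <- X[names(y), ord, drop = FALSE]
  m <- ncol(X)
  if (is.null(m_try)) m_try <- max(1, floor(m / 3))
  rf <- with_seed(seed,
    randomForest::randomForest(x = X, y = y, ntree = n_trees,
                               mtry = min(m_try, m), nodesize = node_size))
  structure(list(rf = rf, feature_ids = colnames(X), n_trees = n_trees,
                 m_try = min(m_try, m), seed = seed,
                 y_range = range(y)),
            class = "forest_model")
}

#' @method print forest_model
#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf("forest_model: %d trees, m_try = %d, %d transcripts\n",
              x$n_trees, x$m_try, length(x$feature_ids)))
  invisible(x)
}

#' Predict from a fitted forest
#'
#' Mean over the S trees' predictions; features are matched by id, so
#' column order of the test matrix is irrelevant.
#'
#' @param model a \code{\link{fit_forest}} model.
#' @param X_test lines x transcripts matrix containing every training
#'   feature column.
#' @return named numeric vector of predictions, guaranteed to lie within
#'   the training response range.
#' @export
predict_forest <- function(model, X_test) {
  stopifnot(inherits(model, "forest_model"))
  X <- as.matrix(X_test)
  missing <- setdiff(model$feature_ids, colnames(X))
  if (length(missing))
    stop_ob("missing feature column(s): %s",
            paste(utils::head(missing, 5), collapse = ", "))
  X <- X[, model$feature_ids, drop = FALSE]
  p <- stats::predict(model$rf, newdata = X)
  stats::setNames(as.numeric(p), rownames(X))
}
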