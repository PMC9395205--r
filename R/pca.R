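# Principal component analysis and the loading-based rule that selects the
# original features carrying the most weight in the leading components.

#' Fit a principal component analysis
#'
#' Centers the data and eigendecomposes its sample covariance. When the number
#' of rows is smaller than the number of features the dual (dot-product/Gram
#' matrix) route is used: the eigenvectors of `X %*% t(X)` are mapped back via
#' `U = t(X) %*% V %*% Lambda^(-1/2)`, which yields the same leading
#' components at lower cost. Components are sorted by non-increasing variance,
#' so the first principal component has the largest variance.
#'
#' @param table Data frame or matrix; non-numeric columns are dropped.
#' @param n_components Number of components to keep (default
#'   `min(n_features, n_rows - 1)`).
#' @return An object of class `pca_model`: `mean` (column means), `rotation`
#'   (features x components orthonormal loading matrix), `eigenvalues`
#'   (component variances, non-increasing), `explained_variance_ratio`, and
#'   `feature_names`.
#' @export
fit_pca <- function(table, n_components = NULL) {
  if (is.data.frame(table)) {
    table <- table[vapply(table, is.numeric, logical(1))]
  }
  x <- as.matrix(table)
  n <- nrow(x); f <- ncol(x)
  if (n < 2) stop("PCA needs at least 2 rows", call. = FALSE)
  if (!all(is.finite(x))) {
    stop("PCA input contains non-finite values; check the feature table ",
         "for degenerate rows", call. = FALSE)
  }
  if (is.null(n_components)) n_components <- min(f, n - 1)
  if (n_components < 1 || n_components > min(f, n - 1)) {
    stop("`n_components` must lie in [1, min(n_features, n_rows - 1)]",
         call. = FALSE)
  }
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  total_var <- sum(xc^2) / (n - 1)

  if (n < f) {
    # dual route: eigenanalysis of the (n x n) Gram matrix
    gram <- xc %*% t(xc) / (n - 1)
    eg <- eigen(gram, symmetric = TRUE)
    keep <- seq_len(n_components)
    lambda <- pmax(eg$values[keep], 0)
    u <- t(xc) %*% eg$vectors[, keep, drop = FALSE]
    u <- sweep(u, 2, sqrt(pmax(lambda, .Machine$double.eps)) * sqrt(n - 1),
               "/")
  } else {
    cv <- crossprod(xc) / (n - 1)
    eg <- eigen(cv, symmetric = TRUE)
    keep <- seq_len(n_components)
    lambda <- pmax(eg$values[keep], 0)
    u <- eg$vectors[, keep, drop = FALSE]
  }
  dimnames(u) <- list(colnames(x), paste0("PC", seq_len(n_components)))
  structure(list(mean = mu,
                 rotation = u,
                 eigenvalues = lambda,
                 explained_variance_ratio = lambda / total_var,
                 feature_names = colnames(x)),
            class = "pca_model")
}

#' Select original features by summed absolute loadings
#'
#' Scores each original feature by the sum of the absolute values of its
#' loadings on the leading components (signed sums would cancel and degenerate
#' the ranking) and returns the top-scoring features. Ties are broken by
#' original column order. The selection returns named original features, not
#' component scores, so downstream models stay interpretable in terms of the
#' measured quantities.
#'
#' @param model A [fit_pca()] model.
#' @param n_lead_components Number of leading components summed (default 5).
#' @param n_keep Number of features to return (default 10).
#' @return Character vector of `n_keep` feature names, ordered by decreasing
#'   score.
#' @export
select_features <- function(model, n_lead_components = 5, n_keep = 10) {
  stopifnot(inherits(model, "pca_model"))
  k <- ncol(model$rotation)
  if (n_lead_components < 1 || n_lead_components > k) {
    stop("`n_lead_components` must lie in [1, ", k, "]", call. = FALSE)
  }
  f <- nrow(model$rotation)
  if (n_keep < 1 || n_keep > f) {
    stop("`n_keep` must lie in [1, ", f, "]", call. = FALSE)
  }
  score <- rowSums(abs(model$rotation[, seq_len(n_lead_components),
                                      drop = FALSE]))
  ord <- order(-score, seq_len(f))
  model$feature_names[ord[seq_len(n_keep)]]
}

#' Project data onto the principal components
#'
#' Computes `Y = t(U) %*% (x - mean)` per row: the centered data expressed in
#' the component basis. Transforming the model mean itself gives the zero
#' vector.
#'
#' @param model A [fit_pca()] model.
#' @param table Data frame or matrix with the model's feature columns.
#' @return Matrix of component scores with `n_components` columns.
#' @export
pca_transform <- function(model, table) {
  stopifnot(inherits(model, "pca_model"))
  if (is.data.frame(table)) table <- table[model$feature_names]
  x <- as.matrix(table)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  sweep(x, 2, model$mean) %*% model$rotation
}

#' Persist a PCA model as JSON and read it back
#'
#' @param model A [fit_pca()] model.
#' @param path File path.
#' @return `read_pca_json()` returns the reconstructed `pca_model`.
#' @export
write_pca_json <- function(model, path) {
  stopifnot(inherits(model, "pca_model"))
  jsonlite::write_json(list(mean = model$mean,
                            rotation = model$rotation,
                            eigenvalues = model$eigenvalues,
                            explained_variance_ratio =
                              model$explained_variance_ratio,
                            feature_names = model$feature_names),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_pca_json
#' @export
read_pca_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rot <- as.matrix(j$rotation)
  dimnames(rot) <- list(j$feature_names, paste0("PC", seq_len(ncol(rot))))
  structure(list(mean = setNames(as.numeric(j$mean), j$feature_names),
                 rotation = rot,
                 eigenvalues = as.numeric(j$eigenvalues),
                 explained_variance_ratio =
                   as.numeric(j$explained_variance_ratio),
                 feature_names = j$feature_names),
            class = "pca_model")
}
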