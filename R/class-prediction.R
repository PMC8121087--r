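#' Random-forest Gini importance ranking
#'
#' Ranks proteins as class predictors with a random forest at default
#' engine settings, returning the Gini mean-decrease importance together
#' with the out-of-bag and per-class error rates. Two labelling tasks of
#' the factorial design are built in: root-zone classification and cold
#' versus all other treatments.
#'
#' @param x numeric matrix, samples in rows, proteins in columns.
#' @param labels factor of class labels (one per row of `x`), or NULL to
#'   derive labels from `meta` and `task`.
#' @param meta optional sample metadata (used with `task`).
#' @param task `"zone"` or `"cold_vs_rest"` when deriving labels.
#' @param n_trees number of trees (default 500, the engine default).
#' @param seed integer seed.
#' @return List of class `importance_table`: data.frame `importance`
#'   (`protein_id`, `gini_mean_decrease`, sorted descending), `oob_error`,
#'   `class_error` (named), `seed`.
#' @export
rf_importance <- function(x, labels = NULL, meta = NULL,
                          task = c("zone", "cold_vs_rest"),
                          n_trees = 500, seed = 1L) {
  x <- as.matrix(x)
  if (is.null(labels)) {
    task <- match.arg(task)
    if (is.null(meta)) stop("supply labels or meta")
    labels <- switch(task,
      zone = meta$zone,
      cold_vs_rest = ifelse(meta$treatment == "cold", "cold", "rest"))
  }
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("need at least two classes")
  if (any(table(labels) < 2)) stop("every class needs >= 2 samples")
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = labels, ntree = n_trees)
  gini <- rf$importance[, "MeanDecreaseGini"]
  err <- rf$err.rate[n_trees, ]
  imp <- data.frame(protein_id = colnames(x),
                    gini_mean_decrease = unname(gini),
                    stringsAsFactors = FALSE)
  imp <- imp[order(-imp$gini_mean_decrease), ]
  structure(list(importance = imp,
                 oob_error = unname(err["OOB"]),
                 class_error = err[setdiff(names(err), "OOB")],
                 seed = seed),
            class = "importance_table")
}

#' PLS-DA with VIP scores (NIPALS PLS2)
#'
#' Fits a partial least squares discriminant analysis on column-centered
#' data against the one-hot (dummy) class matrix using the NIPALS PLS2
#' algorithm, and scores each protein by its variable importance in
#' projection: `VIP_j = sqrt(p * sum_a SSY_a * (w_aj / ||w_a||)^2 /
#' sum_a SSY_a)` where `SSY_a` is the Y-variance explained by component
#' `a`. The mean of squared VIP over retained proteins equals 1 by
#' construction.
#'
#' @param x numeric matrix, samples in rows, proteins in columns.
#' @param labels factor of class labels.
#' @param n_components number of PLS components (default 2).
#' @param max_iter,tol NIPALS iteration controls.
#' @return List of class `vip_table`: data.frame `vip` (`protein_id`,
#'   `vip`, sorted descending; dropped zero-variance proteins carry NA),
#'   `n_components`, `ssy` (variance of Y explained per component).
#' @export
pls_da_vip <- function(x, labels, n_components = 2, max_iter = 500,
                       tol = 1e-10) {
  x <- as.matrix(x)
  labels <- droplevels(as.factor(labels))
  Y <- stats::model.matrix(~ labels - 1)
  ids <- colnames(x)
  sds <- apply(x, 2, stats::sd)
  dropped <- sds == 0
  if (any(dropped)) {
    warning(sum(dropped), " zero-variance protein(s) dropped")
    x <- x[, !dropped, drop = FALSE]
  }
  X <- scale(x, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  p <- ncol(X)
  if (n_components > qr(X)$rank) stop("n_components exceeds the rank of X")
  W <- matrix(0, p, n_components)
  ssy <- numeric(n_components)
  for (a in seq_len(n_components)) {
    u <- Yc[, which.max(colSums(Yc^2))]
    w <- t_score <- NULL
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(X, u))
      w <- w / sqrt(sum(w^2))
      t_score <- drop(X %*% w)
      q <- drop(crossprod(Yc, t_score)) / sum(t_score^2)
      u_new <- drop(Yc %*% q) / sum(q^2)
      if (sum((u_new - u)^2) < tol * sum(u_new^2)) { u <- u_new; break }
      u <- u_new
    }
    pl <- drop(crossprod(X, t_score)) / sum(t_score^2)
    q <- drop(crossprod(Yc, t_score)) / sum(t_score^2)
    ssy[a] <- sum(t_score^2) * sum(q^2)
    X <- X - tcrossprod(t_score, pl)
    Yc <- Yc - tcrossprod(t_score, q)
    W[, a] <- w
  }
  vip <- sqrt(p * drop(W^2 %*% ssy) / sum(ssy))
  out <- data.frame(protein_id = ids,
                    vip = NA_real_, stringsAsFactors = FALSE)
  out$vip[!dropped] <- vip
  out <- out[order(-out$vip, na.last = TRUE), ]
  structure(list(vip = out, n_components = n_components, ssy = ssy),
            class = "vip_table")
}
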