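#' Pearson-correlation distance between matrix rows
#'
#' `d(x, y) = 1 - pearson(x, y)`: symmetric, zero diagonal, range
#' `[0, 2]`. Rows with zero variance have no defined correlation; by
#' default this is an error, but during bootstrap resampling such pairs
#' are assigned the neutral distance 1.
#'
#' @param x numeric matrix; distances are between rows.
#' @param na_action `"error"` (default) or `"unit"` (constant-row pairs
#'   get distance 1).
#' @return A symmetric distance matrix.
#' @export
correlation_distance <- function(x, na_action = c("error", "unit")) {
  na_action <- match.arg(na_action)
  x <- as.matrix(x)
  d <- 1 - suppressWarnings(stats::cor(t(x)))
  if (anyNA(d)) {
    if (na_action == "error") stop("constant row: correlation undefined")
    d[is.na(d)] <- 1
  }
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerates on a distance matrix using mean inter-cluster distance;
#' merge heights are non-decreasing. Ties are resolved deterministically
#' by the agglomeration engine's ascending-index rule.
#'
#' @param d square distance matrix or `dist` object.
#' @return An `hclust` object.
#' @export
hca_average <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (nrow(d) != ncol(d)) stop("distance matrix must be square")
    d <- stats::as.dist(d)
  }
  stats::hclust(d, method = "average")
}

# Member index sets of every internal node of an hclust tree, in merge
# order. Element j holds the sorted leaf indices merged at step j.
hclust_member_sets <- function(hc) {
  n <- length(hc$order)
  sets <- vector("list", n - 1)
  for (j in seq_len(n - 1)) {
    members <- integer(0)
    for (kk in hc$merge[j, ]) {
      members <- c(members, if (kk < 0) -kk else sets[[kk]])
    }
    sets[[j]] <- sort(members)
  }
  sets
}

node_signatures <- function(sets) {
  vapply(sets, paste, character(1), collapse = ",")
}

#' Multiscale bootstrap of a hierarchical clustering
#'
#' Reclusters the rows of `x` on resampled columns at several resampling
#' scales: at scale `r`, `round(ncol(x) * r)` columns are drawn with
#' replacement, the rows are reclustered (correlation distance, average
#' linkage), and for every internal node of the observed dendrogram the
#' number of bootstrap trees containing exactly that member set is
#' counted. Set `axis = "columns"` to cluster the samples instead
#' (resampling rows).
#'
#' @param x numeric matrix; clustered entities in rows by default.
#' @param scales resampling scale factors (default 0.5 to 1.4 by 0.1).
#' @param B bootstrap replicates per scale (scalar or per-scale vector).
#' @param seed integer seed.
#' @param axis `"rows"` (cluster rows, resample columns) or `"columns"`.
#' @return List of class `multiscale_boot`: `hclust` (observed tree),
#'   `member_sets`, `counts` (nodes x scales), `B`, `scales`, `labels`.
#' @export
multiscale_bootstrap <- function(x, scales = seq(0.5, 1.4, by = 0.1),
                                 B = 1000, seed = 1L,
                                 axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  x <- as.matrix(x)
  if (axis == "columns") x <- t(x)
  B <- as.integer(rep_len(B, length(scales)))
  if (any(B < 1)) stop("B must be >= 1 for every scale")
  m <- ncol(x)
  sizes <- round(m * scales)
  if (any(sizes < 2)) stop("a scale resamples fewer than 2 columns")
  hc <- hca_average(correlation_distance(x, na_action = "unit"))
  sets <- hclust_member_sets(hc)
  sigs <- node_signatures(sets)
  sig_index <- stats::setNames(seq_along(sigs), sigs)
  counts <- matrix(0L, length(sets), length(scales))
  set.seed(seed)
  for (s in seq_along(scales)) {
    for (b in seq_len(B[s])) {
      cols <- sample.int(m, sizes[s], replace = TRUE)
      d <- correlation_distance(x[, cols, drop = FALSE], na_action = "unit")
      hb <- hca_average(d)
      bs <- node_signatures(hclust_member_sets(hb))
      hit <- sig_index[bs]
      hit <- hit[!is.na(hit)]
      counts[hit, s] <- counts[hit, s] + 1L
    }
  }
  structure(list(hclust = hc, member_sets = sets, counts = counts,
                 B = B, scales = scales, labels = rownames(x)),
            class = "multiscale_boot")
}

#' Approximately unbiased support from multiscale bootstrap counts
#'
#' Fits the multiscale-bootstrap model for one dendrogram node. Per scale
#' `r`, the bootstrap proportion `BP_r = count / B_r` is clamped to
#' `[1/(B_r + 1), B_r/(B_r + 1)]` and transformed to
#' `z_r = qnorm(1 - BP_r)`; a weighted least-squares fit of
#' `z_r = v * sqrt(r) + c / sqrt(r)` with weights
#' `B_r * dnorm(z_r)^2 / (BP_r * (1 - BP_r))` yields the signed distance
#' `v` and curvature `c`, from which `au = 1 - pnorm(v - c)` and
#' `bp = 1 - pnorm(v + c)`. Only scales with counts strictly between 0
#' and `B_r` enter the fit; when fewer than two such scales exist the
#' support is undefined and the boundary limit (0 or 1) is reported with
#' `degenerate = TRUE`.
#'
#' @param counts per-scale counts of bootstrap trees containing the node.
#' @param B bootstrap replicates per scale (scalar or vector).
#' @param scales the resampling scales.
#' @return List with `v`, `c`, `au`, `bp`, `bp_raw` (the per-scale raw
#'   proportions) and `degenerate`.
#' @export
au_from_counts <- function(counts, B, scales) {
  B <- rep_len(B, length(scales))
  stopifnot(length(counts) == length(scales))
  bp_raw <- counts / B
  interior <- counts > 0 & counts < B
  if (sum(interior) < 2) {
    lim <- as.numeric(mean(bp_raw) >= 0.5)
    return(list(v = NA_real_, c = NA_real_, au = lim, bp = lim,
                bp_raw = bp_raw, degenerate = TRUE))
  }
  bp <- pmin(pmax(bp_raw, 1 / (B + 1)), B / (B + 1))
  r <- scales[interior]
  z <- stats::qnorm(1 - bp[interior])
  w <- B[interior] * stats::dnorm(z)^2 / (bp[interior] * (1 - bp[interior]))
  Xm <- cbind(sqrt(r), 1 / sqrt(r))
  fit <- stats::lm.wfit(Xm, z, w)
  v <- unname(fit$coefficients[1])
  cc <- unname(fit$coefficients[2])
  list(v = v, c = cc, au = 1 - stats::pnorm(v - cc),
       bp = 1 - stats::pnorm(v + cc), bp_raw = bp_raw, degenerate = FALSE)
}

#' Bootstrapped hierarchical clustering with AU support
#'
#' Convenience wrapper: runs [multiscale_bootstrap()] and
#' [au_from_counts()] for every internal node of the observed tree. The
#' root node has support 1 by construction.
#'
#' @inheritParams multiscale_bootstrap
#' @return List of class `au_hclust`: the `multiscale_boot` fields plus a
#'   data.frame `support` with one row per internal node (`node`, `size`,
#'   `au`, `bp`, `v`, `c`, `degenerate`).
#' @export
au_cluster <- function(x, scales = seq(0.5, 1.4, by = 0.1), B = 1000,
                       seed = 1L, axis = c("rows", "columns")) {
  mb <- multiscale_bootstrap(x, scales = scales, B = B, seed = seed,
                             axis = axis)
  n_nodes <- length(mb$member_sets)
  rows <- lapply(seq_len(n_nodes), function(j) {
    if (j == n_nodes) {   # root: all items, support 1 by convention
      return(data.frame(node = j, size = length(mb$member_sets[[j]]),
                        au = 1, bp = 1, v = NA_real_, c = NA_real_,
                        degenerate = TRUE))
    }
    a <- au_from_counts(mb$counts[j, ], mb$B, mb$scales)
    data.frame(node = j, size = length(mb$member_sets[[j]]),
               au = a$au, bp = a$bp, v = a$v, c = a$c,
               degenerate = a$degenerate)
  })
  mb$support <- do.call(rbind, rows)
  class(mb) <- c("au_hclust", class(mb))
  mb
}

#' K-means partition with greedy (k-means++ style) seeding
#'
#' Runs Lloyd iterations from a k-means++ style greedy seeding, repeated
#' `restarts` times, and keeps the solution with the lowest total
#' within-cluster sum of squares. Deterministic given the seed.
#'
#' @param x numeric matrix; rows are partitioned.
#' @param k number of clusters (default 5).
#' @param restarts number of seeding restarts.
#' @param seed integer seed.
#' @return List of class `kmeans_result`: `assignments` (named), `centers`,
#'   `inertia`, `k`, `seed`.
#' @export
kmeans_partition <- function(x, k = 5, restarts = 10, seed = 1L) {
  x <- as.matrix(x)
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(x)) stop("k must not exceed the number of rows")
  set.seed(seed)
  best <- NULL
  for (rs in seq_len(restarts)) {
    centers <- matrix(NA_real_, k, ncol(x))
    centers[1, ] <- x[sample.int(nrow(x), 1), ]
    if (k > 1) {
      for (j in 2:k) {
        d2 <- apply(x, 1, function(row) {
          min(colSums((t(centers[seq_len(j - 1), , drop = FALSE]) - row)^2))
        })
        if (all(d2 == 0)) stop("fewer distinct rows than clusters")
        centers[j, ] <- x[sample.int(nrow(x), 1, prob = d2), ]
      }
    }
    km <- suppressWarnings(stats::kmeans(x, centers = centers,
                                         iter.max = 100,
                                         algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  structure(list(assignments = stats::setNames(best$cluster, rownames(x)),
                 centers = best$centers, inertia = best$tot.withinss,
                 k = k, seed = seed),
            class = "kmeans_result")
}

#' High-confidence sub-clusters from AU support
#'
#' Returns the maximal dendrogram nodes whose AU support complement
#' `(1 - au)` is below `complement_threshold` and whose size lies within
#' the stated bounds; a qualifying node nested inside a larger qualifying
#' node is not reported separately.
#'
#' @param au an `au_hclust` from [au_cluster()].
#' @param min_size,max_size member-count bounds (defaults 2 and 12).
#' @param complement_threshold AU complement cutoff (default 0.01, i.e.
#'   au >= 0.99).
#' @return List of character vectors, one per reported node, holding the
#'   member labels; names give the node index.
#' @export
high_confidence_subclusters <- function(au, min_size = 2, max_size = 12,
                                        complement_threshold = 0.01) {
  stopifnot(inherits(au, "au_hclust"))
  sup <- au$support
  qual <- which((1 - sup$au) < complement_threshold &
                  sup$size >= min_size & sup$size <= max_size)
  if (!length(qual)) return(list())
  keep <- qual
  for (j in qual) {
    for (a in qual) {
      if (a != j &&
          length(au$member_sets[[j]]) < length(au$member_sets[[a]]) &&
          all(au$member_sets[[j]] %in% au$member_sets[[a]])) {
        keep <- setdiff(keep, j)
        break
      }
    }
  }
  out <- lapply(keep, function(j) au$labels[au$member_sets[[j]]])
  names(out) <- paste0("node", keep)
  out
}

#' Export a dendrogram as Newick with AU node labels
#'
#' Internal nodes are labelled `au|bp|size` (au and bp as percentages to
#' one decimal); branch lengths derive from the merge heights.
#'
#' @param au an `au_hclust` from [au_cluster()].
#' @param path optional file path; when given the tree is written there.
#' @return The Newick string, invisibly when written to a file.
#' @export
dendrogram_newick <- function(au, path = NULL) {
  stopifnot(inherits(au, "au_hclust"))
  hc <- au$hclust
  labels <- if (is.null(hc$labels)) as.character(seq_along(hc$order)) else hc$labels
  sup <- au$support
  node_label <- sprintf("%.1f|%.1f|%d", 100 * sup$au, 100 * sup$bp, sup$size)
  subtree <- function(kk, parent_h) {
    if (kk < 0) {
      sprintf("%s:%.6g", labels[-kk], parent_h)
    } else {
      h <- hc$height[kk]
      kids <- vapply(hc$merge[kk, ], subtree, character(1), parent_h = h)
      sprintf("(%s,%s)%s:%.6g", kids[1], kids[2], node_label[kk],
              parent_h - h)
    }
  }
  n <- length(hc$height)
  kids <- vapply(hc$merge[n, ], subtree, character(1),
                 parent_h = hc$height[n])
  nwk <- sprintf("(%s,%s)%s;", kids[1], kids[2], node_label[n])
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
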