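test_that("correlation distance matches the covariance-formula oracle", {
  set.seed(12)
  x <- matrix(rnorm(24), 4, 6)
  d <- correlation_distance(x)
  # independent evaluation straight from the covariance formula
  for (i in 1:4) for (j in 1:4) {
    xi <- x[i, ]; xj <- x[j, ]
    r <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    expect_equal(d[i, j], 1 - r, tolerance = 1e-12)
  }
  expect_equal(diag(d), rep(0, 4))
  expect_equal(d, t(d))
  # anti-correlated rows are at distance 2
  expect_equal(correlation_distance(rbind(c(1, 2, 3), c(3, 2, 1)))[1, 2], 2)
  expect_error(correlation_distance(rbind(c(1, 1, 1), c(1, 2, 3))),
               "constant")
})

test_that("UPGMA agglomerates by hand-checkable average distances", {
  d <- matrix(c(0, 1, 4,
                1, 0, 4,
                4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- hca_average(d)
  expect_equal(hc$height, c(1, 4))
  sets <- protacclim:::hclust_member_sets(hc)
  expect_equal(sets[[1]], c(1, 2))   # {A, B} merged first
  # identical items merge at height zero
  x <- rbind(a = c(1, 2, 3, 1), b = c(1, 2, 3, 1), c = c(9, 1, 2, 4))
  hc2 <- hca_average(correlation_distance(x))
  expect_equal(hc2$height[1], 0)
  expect_error(hca_average(matrix(0, 2, 3)), "square")
})

test_that("AU fit recovers the closed-form (v, c) construction", {
  r <- c(0.25, 1, 4)
  v_true <- 1; c_true <- 0.5
  bp <- 1 - pnorm(v_true * sqrt(r) + c_true / sqrt(r))
  B <- 1e9   # counts exact to the available precision
  out <- au_from_counts(round(bp * B), B, r)
  expect_equal(out$v, 1, tolerance = 1e-4)
  expect_equal(out$c, 0.5, tolerance = 1e-4)
  expect_equal(out$au, 1 - pnorm(0.5), tolerance = 1e-4)
  expect_equal(round(out$au, 4), 0.3085)
  # no curvature: au = bp by formula symmetry
  bp0 <- 1 - pnorm(1 * sqrt(r))
  out0 <- au_from_counts(round(bp0 * B), B, r)
  expect_equal(out0$au, out0$bp, tolerance = 1e-6)
  # boundary: always recovered -> au 1 with degenerate flag
  outb <- au_from_counts(c(1000, 1000, 1000), 1000, r)
  expect_equal(outb$au, 1)
  expect_true(outb$degenerate)
  expect_equal(au_from_counts(c(0, 0, 0), 1000, r)$au, 0)
})

test_that("forced block structure is recovered in every bootstrap replicate", {
  set.seed(77)
  # two groups of duplicated columns separating two row groups
  base <- cbind(matrix(2, 4, 6), matrix(-2, 4, 6))
  x <- rbind(base, -base) + matrix(rnorm(8 * 12, 0, 0.05), 8, 12)
  rownames(x) <- paste0("P", 1:8)
  mb <- multiscale_bootstrap(x, scales = c(0.8, 1, 1.2), B = 50, seed = 1)
  sigs <- vapply(mb$member_sets, paste, character(1), collapse = ",")
  true_node <- match("1,2,3,4", sigs)
  expect_false(is.na(true_node))
  expect_equal(unname(mb$counts[true_node, ]), rep(50L, 3))
  # white-noise matrix: node recovery well below 1
  noise <- matrix(rnorm(8 * 12), 8, 12)
  mbn <- multiscale_bootstrap(noise, scales = 1, B = 50, seed = 2)
  small <- lengths(mbn$member_sets) < 8
  expect_lt(max(mbn$counts[small, 1]) / 50, 1)
  expect_error(multiscale_bootstrap(x, B = 0), "B must be")
  expect_error(multiscale_bootstrap(x, scales = 0.05), "fewer than 2")
})

test_that("AU support rises with block separation", {
  au_at <- function(s) {
    set.seed(5)
    base <- cbind(matrix(s, 4, 8), matrix(-s, 4, 8))
    x <- rbind(base, -base) + matrix(rnorm(8 * 16), 8, 16)
    rownames(x) <- paste0("P", 1:8)
    au <- au_cluster(x, scales = c(0.6, 0.8, 1, 1.2), B = 100, seed = 3)
    sigs <- vapply(au$member_sets, paste, character(1), collapse = ",")
    j <- match("1,2,3,4", sigs)
    if (is.na(j)) 0 else au$support$au[j]
  }
  sup <- vapply(c(0.3, 1, 3), au_at, numeric(1))
  expect_true(all(diff(sup) >= -0.02))   # non-decreasing up to MC noise
  expect_gt(sup[3], 0.95)
})

test_that("k-means recovers well-separated blobs and degenerate cases", {
  set.seed(14)
  hits <- replicate(50, {
    x <- rbind(matrix(rnorm(20 * 4, 0), 20, 4),
               matrix(rnorm(20 * 4, 8), 20, 4))
    km <- kmeans_partition(x, k = 2, seed = sample.int(1e6, 1))
    cluster_accuracy(km$assignments, rep(1:2, each = 20)) == 1
  })
  expect_equal(mean(hits), 1)
  # k = n gives zero inertia
  x <- matrix(rnorm(12), 4, 3)
  expect_equal(kmeans_partition(x, k = 4, seed = 1)$inertia, 0)
  # duplicate rows always land together
  xd <- rbind(a = c(0, 0), b = c(0, 0), c = c(9, 9), d = c(9.1, 9))
  km <- kmeans_partition(xd, k = 2, seed = 1)
  expect_equal(km$assignments[["a"]], km$assignments[["b"]])
  expect_error(kmeans_partition(x, k = 0), "k must be")
  expect_error(kmeans_partition(x, k = 9), "exceed")
})

test_that("high-confidence sub-clusters are maximal qualifying nodes", {
  au <- structure(list(
    member_sets = list(c(1, 2), c(1, 2, 3), c(4, 5), c(1, 2, 3, 4, 5)),
    support = data.frame(node = 1:4, size = c(2, 3, 2, 5),
                         au = c(0.999, 0.995, 0.5, 0.999)),
    labels = paste0("P", 1:5)), class = c("au_hclust", "multiscale_boot"))
  out <- high_confidence_subclusters(au)
  # nodes 1 and 2 nest inside the qualifying root-sized node 4, so only
  # the largest qualifying level is reported
  expect_named(out, "node4")
  expect_equal(out$node4, paste0("P", 1:5))
  # a 5-member node with au = 0.995 inside a failing parent is reported
  au$support$au[4] <- 0.5
  expect_named(high_confidence_subclusters(au), "node2")
  # nothing qualifies -> empty list
  au$support$au <- 0.5
  expect_equal(high_confidence_subclusters(au), list())
})

test_that("Newick export carries au|bp|size labels and parses", {
  skip_if_not_installed("ape")
  set.seed(6)
  base <- cbind(matrix(2, 3, 6), matrix(-2, 3, 6))
  x <- rbind(base, -base) + matrix(rnorm(6 * 12, 0, 0.1), 6, 12)
  rownames(x) <- paste0("P", 1:6)
  au <- au_cluster(x, scales = c(0.8, 1, 1.2), B = 30, seed = 1)
  nwk <- dendrogram_newick(au)
  tree <- ape::read.tree(text = nwk)
  expect_equal(sort(tree$tip.label), paste0("P", 1:6))
  expect_equal(tree$Nnode, 5)
  expect_match(nwk, "\\d+\\.\\d\\|\\d+\\.\\d\\|\\d")
})
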