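test_that("design matrix encodes treatment contrasts against the references", {
  meta <- factorial_meta(2)
  X <- build_design_matrix(meta)
  expect_equal(colnames(X), regressor_names())
  ref <- X[meta$zone == "tip_adjacent" & meta$treatment == "control", ][1, ]
  expect_equal(unname(ref), c(1, 0, 0, 0, 0, 0, 0, 0))
  tc <- X[meta$zone == "tip" & meta$treatment == "cold", ][1, ]
  expect_equal(unname(tc), c(1, 1, 0, 0, 1, 0, 0, 1))
  expect_equal(qr(X)$rank, 8)
  expect_error(build_design_matrix(data.frame(sample_id = "s", zone = "leaf",
                                              treatment = "control")),
               "unknown zone")
})

test_that("gaussian/identity GLM equals the least-squares oracle", {
  set.seed(8)
  meta <- factorial_meta(3)
  X <- build_design_matrix(meta)
  y <- drop(X %*% c(1, 1.5, 0, 0, -1, 0, 0, 2)) + rnorm(nrow(X), 0, 0.3)
  fit <- fit_glm_row(y, X)
  ols <- lm.fit(X, y)
  expect_equal(unname(fit$coef), unname(ols$coefficients),
               tolerance = 1e-10)
  # matrix-wide fast path agrees with the row fit
  m <- intensity_matrix(rbind(P1 = y), meta)
  da <- fit_da(m)
  expect_equal(unname(da$coef[1, ]), unname(fit$coef), tolerance = 1e-10)
  expect_equal(unname(da$p[1, ]), unname(fit$p), tolerance = 1e-10)
})

test_that("planted coefficients are recovered by the GLM", {
  eff <- matrix(0, 50, 7, dimnames = list(NULL, regressor_names()[-1]))
  eff[, "tip"] <- 1.5
  spec <- simulation_spec(50, effects = eff, noise_sd = 0.3, seed = 21)
  sim <- generate_intensity_matrix(spec)
  da <- fit_da(sim$matrix)
  est <- da$coef[, "tip"]
  se <- da$se[, "tip"]
  expect_gt(mean(abs(est - 1.5) < 3 * se), 0.95)
})

test_that("gamma/log GLM recovers known coefficients", {
  set.seed(30)
  meta <- factorial_meta(5)
  X <- build_design_matrix(meta)
  beta <- c(2, 0.8, 0, 0, -0.5, 0, 0, 1.0)
  errs <- replicate(50, {
    mu <- exp(drop(X %*% beta))
    y <- rgamma(length(mu), shape = 50, rate = 50 / mu)
    fit <- fit_glm_row(y, X, "gamma", "log", "none")
    abs(fit$coef[c("tip", "cold", "tip:cold")] -
          beta[c(2, 5, 8)]) / abs(beta[c(2, 5, 8)])
  })
  expect_lt(median(errs), 0.1)
})

test_that("BH q-values follow the step-up rule", {
  # hand evaluation of the step-up rule
  expect_equal(adjust_fdr_bh(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(adjust_fdr_bh(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(adjust_fdr_bh(0.037), 0.037)
  # NA propagates and shrinks the family size m
  expect_equal(adjust_fdr_bh(c(0.01, NA, 0.04)), c(0.02, NA, 0.04))
  expect_error(adjust_fdr_bh(c(0.5, 1.2)), "0, 1")
  # permutation invariance of the multiset of q-values
  set.seed(2)
  p <- runif(50)^2
  q1 <- sort(adjust_fdr_bh(p))
  q2 <- sort(adjust_fdr_bh(sample(p)))
  expect_equal(q1, q2)
  # q >= p componentwise
  expect_true(all(adjust_fdr_bh(p) >= p))
})

test_that("response classes follow the significance and direction rules", {
  eff <- matrix(0, 3, 7, dimnames = list(NULL, regressor_names()[-1]))
  eff[1, "tip"] <- 3          # class 1 only
  eff[2, "cold"] <- 3         # class 2 only
  eff[3, "tip"] <- 3          # class 1 and class 3
  eff[3, "tip:cold"] <- 3
  spec <- simulation_spec(3, effects = eff, noise_sd = 0.2, seed = 4)
  sim <- generate_intensity_matrix(spec)
  da <- fit_da(sim$matrix)
  cls <- classify_response(da)
  expect_equal(cls$class1, c(TRUE, FALSE, TRUE))
  expect_equal(cls$class2, c(FALSE, TRUE, FALSE))
  expect_equal(cls$class3[3], TRUE)
  expect_true(all(cls$differential))

  # a negative main effect is not class 1 when direction is required
  eff_neg <- matrix(0, 1, 7, dimnames = list(NULL, regressor_names()[-1]))
  eff_neg[1, "tip"] <- -3
  simn <- generate_intensity_matrix(
    simulation_spec(1, effects = eff_neg, noise_sd = 0.2, seed = 5))
  dan <- fit_da(simn$matrix)
  expect_false(classify_response(dan)$class1[1])
  expect_true(classify_response(dan, require_direction = FALSE)$class1[1])
})

test_that("null matrices keep the differential fraction controlled", {
  fr <- vapply(1:5, function(s) {
    sim <- generate_intensity_matrix(
      simulation_spec(500, noise_sd = 0.5, seed = 700 + s))
    mean(classify_response(fit_da(sim$matrix))$differential)
  }, numeric(1))
  expect_lte(mean(fr), 0.07)
})

test_that("Fisher enrichment equals the hypergeometric tail", {
  background <- sprintf("B%03d", 1:100)
  selected <- background[1:10]
  term_map <- data.frame(protein_id = c(background[c(1:5, 11:15)]),
                         term = "GO:0006412", stringsAsFactors = FALSE)
  out <- fisher_enrichment(selected, background, term_map)
  # oracle: enumerate the hypergeometric pmf for P(X >= 5)
  p_oracle <- sum(dhyper(5:10, 10, 90, 10))
  expect_equal(out$p, p_oracle, tolerance = 1e-12)
  expect_error(fisher_enrichment(character(0), background, term_map),
               "empty")
  expect_error(fisher_enrichment(c("nope"), background, term_map),
               "subset")
})

test_that("group median profiles match a sort-and-pick oracle", {
  meta <- factorial_meta(2)
  set.seed(9)
  v <- matrix(rnorm(3 * nrow(meta)), 3,
              dimnames = list(c("P1", "P2", "P3"), NULL))
  m <- intensity_matrix(v, meta)
  prof <- group_median_profile(m, list(g = c("P1", "P2", "P3")))
  cell <- meta$zone == "tip" & meta$treatment == "cold"
  cm <- sort(rowMeans(v[, cell]))
  expect_equal(prof$median_intensity[prof$zone == "tip" &
                                       prof$treatment == "cold"],
               unname(cm[2]))   # middle of three
  # single-protein group: medians equal that protein's cell means
  p1 <- group_median_profile(m, list(g = "P1"))
  expect_equal(p1$median_intensity[p1$zone == "tip" & p1$treatment == "cold"],
               mean(v[1, cell]))
  expect_error(group_median_profile(m, list(g = "absent")), "no measured")
})
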