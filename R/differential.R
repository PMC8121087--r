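#' Build the eight-regressor design matrix of the two-factor model
#'
#' Treatment-contrast (dummy) coding with zone `tip_adjacent` and treatment
#' `control` as references: intercept, the `tip` main effect, the `chitin`,
#' `chitosan` and `cold` main effects, and the three `tip:treatment`
#' interaction columns (elementwise products). For a complete 2 x 4
#' factorial the matrix has full rank 8.
#'
#' @param sample_meta data.frame with `zone` and `treatment` columns
#'   (non-pool samples).
#' @return Numeric matrix, one row per sample, columns
#'   `regressor_names()`.
#' @export
build_design_matrix <- function(sample_meta) {
  zone <- sample_meta$zone
  trt <- sample_meta$treatment
  bad_zone <- setdiff(unique(zone), zone_levels())
  bad_trt <- setdiff(unique(trt), treatment_levels())
  if (length(bad_zone)) stop("unknown zone level: ", paste(bad_zone, collapse = ", "))
  if (length(bad_trt)) stop("unknown treatment level: ", paste(bad_trt, collapse = ", "))
  tip <- as.numeric(zone == "tip")
  chitin <- as.numeric(trt == "chitin")
  chitosan <- as.numeric(trt == "chitosan")
  cold <- as.numeric(trt == "cold")
  X <- cbind(intercept = 1, tip = tip, chitin = chitin, chitosan = chitosan,
             cold = cold, "tip:chitin" = tip * chitin,
             "tip:chitosan" = tip * chitosan, "tip:cold" = tip * cold)
  rownames(X) <- sample_meta$sample_id
  X
}

# Shift a response above zero for gamma-family fits: pooled-normalized
# log2 ratios are routinely negative, which breaks the gamma
# parametrization, so the fit is carried out on y + shift.
shift_for_family <- function(y, transform) {
  if (transform %in% c("shift", "log_shift") && any(y <= 0)) {
    -min(y) + 1e-6 * diff(range(y))
  } else {
    0
  }
}

#' Fit one generalized linear model row
#'
#' IRLS fit of a single protein's intensity vector against the factorial
#' design, with the family/link selected from its distribution
#' fingerprint. Gamma-family responses are shifted above zero first (the
#' shift is reported); lognormal-classified responses are fitted gaussian
#' on the log of the shifted data. Gaussian/identity fits coincide exactly
#' with ordinary least squares. Wald p-values are the standard IRLS output
#' (t statistics under estimated dispersion).
#'
#' @param y numeric response vector.
#' @param X design matrix from [build_design_matrix()].
#' @param glm_family `"gaussian"` or `"gamma"`.
#' @param link link function name (`"identity"` or `"log"`).
#' @param transform `"none"`, `"shift"` or `"log_shift"` (from the
#'   catalog entry).
#' @return List with `coef`, `se`, `p`, `family`, `link`, `shift`,
#'   `converged`.
#' @export
fit_glm_row <- function(y, X, glm_family = "gaussian", link = "identity",
                        transform = "none") {
  stopifnot(length(y) == nrow(X))
  shift <- shift_for_family(y, transform)
  y_fit <- y + shift
  if (transform == "log_shift") {
    y_fit <- log(y_fit)
    glm_family <- "gaussian"; link <- "identity"
  }
  fam <- switch(glm_family,
                gaussian = stats::gaussian(link = link),
                gamma = stats::Gamma(link = link),
                stop("unsupported GLM family: ", glm_family))
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y_fit, family = fam,
                                    control = list(maxit = 50))),
    error = function(e) NULL)
  p <- ncol(X)
  if (is.null(fit) || !fit$converged || fit$rank < p) {
    return(list(coef = rep(NA_real_, p), se = rep(NA_real_, p),
                p = rep(NA_real_, p), family = glm_family, link = link,
                shift = shift, converged = FALSE))
  }
  df_res <- fit$df.residual
  disp <- sum((fit$weights * fit$residuals^2)) / df_res
  Rinv <- backsolve(qr.R(fit$qr), diag(p))
  cov_unscaled <- Rinv %*% t(Rinv)
  se <- sqrt(disp * diag(cov_unscaled))
  tval <- fit$coefficients / se
  pval <- 2 * stats::pt(-abs(tval), df_res)
  list(coef = stats::setNames(fit$coefficients, colnames(X)),
       se = stats::setNames(se, colnames(X)),
       p = stats::setNames(pval, colnames(X)),
       family = glm_family, link = link, shift = shift, converged = TRUE)
}

#' Differential abundance across an intensity matrix
#'
#' Fits the eight-regressor two-factor GLM to every protein, using each
#' protein's fingerprint-selected family and link (or plain
#' gaussian/identity when no fingerprint table is supplied), then adjusts
#' Wald p-values to Benjamini-Hochberg q-values per coefficient across
#' proteins (one BH family per regressor). Gaussian/identity proteins are
#' fitted in one closed-form least-squares pass; other families go through
#' IRLS row by row. Proteins whose fit does not converge are excluded from
#' the q-value pool.
#'
#' @param matrix an [intensity_matrix] (non-pool samples only).
#' @param fingerprints optional data.frame from [fingerprint_matrix()].
#' @return Object of class `da_result`: list with matrices `coef`, `se`,
#'   `p`, `q` (proteins x 8 regressors) and vectors `family`, `link`,
#'   `shift`, `converged`.
#' @export
fit_da <- function(matrix, fingerprints = NULL) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  meta <- matrix$sample_meta
  keep <- !meta$is_pool
  Y <- matrix$values[, keep, drop = FALSE]
  X <- build_design_matrix(meta[keep, , drop = FALSE])
  ids <- rownames(Y)
  m <- length(ids); p <- ncol(X)
  if (is.null(fingerprints)) {
    glm_family <- rep("gaussian", m); link <- rep("identity", m)
    transform <- rep("none", m)
  } else {
    idx <- match(ids, fingerprints$protein_id)
    if (any(is.na(idx))) stop("fingerprints missing some proteins")
    glm_family <- fingerprints$glm_family[idx]
    link <- fingerprints$link[idx]
    transform <- fingerprints$transform[idx]
  }
  coef_m <- se_m <- p_m <- matrix(NA_real_, m, p,
                                  dimnames = list(ids, colnames(X)))
  shift <- numeric(m); converged <- logical(m)

  gauss <- glm_family == "gaussian" & link == "identity" & transform == "none"
  if (any(gauss)) {
    XtXinv <- solve(crossprod(X))
    B <- Y[gauss, , drop = FALSE] %*% X %*% XtXinv
    resid <- Y[gauss, , drop = FALSE] - B %*% t(X)
    df_res <- nrow(X) - p
    s2 <- rowSums(resid^2) / df_res
    se <- sqrt(outer(s2, diag(XtXinv)))
    tval <- B / se
    coef_m[gauss, ] <- B
    se_m[gauss, ] <- se
    p_m[gauss, ] <- 2 * stats::pt(-abs(tval), df_res)
    converged[gauss] <- TRUE
  }
  for (i in which(!gauss)) {
    fit <- fit_glm_row(Y[i, ], X, glm_family[i], link[i], transform[i])
    coef_m[i, ] <- fit$coef; se_m[i, ] <- fit$se; p_m[i, ] <- fit$p
    shift[i] <- fit$shift; converged[i] <- fit$converged
  }
  q_m <- p_m
  for (j in seq_len(ncol(p_m))) q_m[, j] <- adjust_fdr_bh(p_m[, j])
  structure(list(protein_id = ids, coef = coef_m, se = se_m, p = p_m,
                 q = q_m, family = glm_family, link = link, shift = shift,
                 converged = converged, design = X),
            class = "da_result")
}

#' Benjamini-Hochberg step-up q-values
#'
#' Step-up FDR adjustment: p-values are sorted ascending,
#' `q(i) = min_{j >= i} p(j) * m / j`, then restored to input order and
#' capped at 1. `NA`/`NaN` entries propagate and are excluded from `m`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Numeric vector of q-values, same length and order.
#' @export
adjust_fdr_bh <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify per-protein response patterns
#'
#' Flags the three response classes of the factorial analysis:
#' class 1 - the `tip` zone main effect is significant (q below
#' `q_threshold`) and positive; class 2 - the `cold` main effect is
#' significant and positive; class 3 - the `tip:cold` interaction has raw
#' p below `interaction_p_threshold` and the tip+cold linear combination
#' (`tip + cold + tip:cold`) is positive, i.e. cold-modulated
#' tip-accumulated proteins. Classes may overlap. `differential` flags
#' proteins with any non-intercept q below `q_threshold`.
#'
#' @param da a `da_result` from [fit_da()].
#' @param q_threshold q-value cutoff for main-effect classes.
#' @param interaction_p_threshold raw p cutoff for the interaction class.
#' @param require_direction require the positive direction (default TRUE).
#' @return data.frame with `protein_id`, logical `class1`, `class2`,
#'   `class3`, `differential`.
#' @export
classify_response <- function(da, q_threshold = 0.05,
                              interaction_p_threshold = 0.05,
                              require_direction = TRUE) {
  stopifnot(inherits(da, "da_result"))
  dir1 <- if (require_direction) da$coef[, "tip"] > 0 else TRUE
  dir2 <- if (require_direction) da$coef[, "cold"] > 0 else TRUE
  sum3 <- da$coef[, "tip"] + da$coef[, "cold"] + da$coef[, "tip:cold"]
  dir3 <- if (require_direction) sum3 > 0 else TRUE
  class1 <- da$q[, "tip"] < q_threshold & dir1
  class2 <- da$q[, "cold"] < q_threshold & dir2
  class3 <- da$p[, "tip:cold"] < interaction_p_threshold & dir3
  tested <- setdiff(colnames(da$q), "intercept")
  differential <- apply(da$q[, tested, drop = FALSE] < q_threshold, 1, any)
  data.frame(protein_id = da$protein_id,
             class1 = unname(class1 & !is.na(class1)),
             class2 = unname(class2 & !is.na(class2)),
             class3 = unname(class3 & !is.na(class3)),
             differential = unname(differential & !is.na(differential)),
             stringsAsFactors = FALSE)
}

#' One-sided Fisher over-representation test per term
#'
#' For every annotation term, tests whether the selected protein set is
#' enriched for the term relative to the background via the one-sided
#' (greater) Fisher exact test on the 2 x 2 membership table; p-values are
#' BH-adjusted across terms. The reported odds ratio is the sample odds
#' ratio of the table.
#'
#' @param selected character vector of selected protein ids (subset of
#'   `background`, non-empty).
#' @param background character vector of background protein ids.
#' @param term_map data.frame with columns `protein_id` and `term`
#'   (long format, one row per annotation).
#' @return data.frame with `term`, `n_selected`, `n_background`,
#'   `odds_ratio`, `p`, `q`, sorted by p.
#' @export
fisher_enrichment <- function(selected, background, term_map) {
  if (!length(selected)) stop("empty selected set")
  if (length(setdiff(selected, background))) {
    stop("selected must be a subset of background")
  }
  term_map <- term_map[term_map$protein_id %in% background, , drop = FALSE]
  terms <- unique(term_map$term)
  if (!length(terms)) stop("no annotation term overlaps the background")
  n_sel <- length(unique(selected))
  n_bg <- length(unique(background))
  rows <- lapply(terms, function(tm) {
    in_term <- unique(term_map$protein_id[term_map$term == tm])
    a <- sum(selected %in% in_term)
    b <- n_sel - a
    c <- length(in_term) - a
    d <- n_bg - n_sel - c
    p <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                            alternative = "greater")$p.value
    or <- (a * d) / (b * c)
    data.frame(term = tm, n_selected = a, n_background = length(in_term),
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- adjust_fdr_bh(out$p)
  out[order(out$p), ]
}

#' Median intensity profile per protein functional group
#'
#' For each functional group, the median over member proteins of the
#' per-cell mean intensity (cell = zone x treatment), reproducing the
#' group-level summary table of pooled-normalized log2 abundances.
#'
#' @param matrix an [intensity_matrix].
#' @param protein_groups named list mapping group name to member protein
#'   ids (each group non-empty and measured).
#' @return data.frame with `group`, `zone`, `treatment`,
#'   `median_intensity`.
#' @export
group_median_profile <- function(matrix, protein_groups) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  meta <- matrix$sample_meta
  keep <- !meta$is_pool
  v <- matrix$values[, keep, drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  cells <- unique(meta[, c("zone", "treatment")])
  rows <- list()
  for (g in names(protein_groups)) {
    members <- intersect(protein_groups[[g]], rownames(v))
    if (!length(members)) stop("group with no measured member: ", g)
    for (i in seq_len(nrow(cells))) {
      cols <- meta$zone == cells$zone[i] & meta$treatment == cells$treatment[i]
      cell_means <- rowMeans(v[members, cols, drop = FALSE])
      rows[[length(rows) + 1]] <- data.frame(
        group = g, zone = cells$zone[i], treatment = cells$treatment[i],
        median_intensity = stats::median(cell_means),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
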