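#' Names of the eight regressors of the two-factor model
#'
#' Treatment-contrast coding against zone `tip_adjacent` and treatment
#' `control`: intercept, the zone main effect, the three treatment main
#' effects and the three zone-by-treatment interactions.
#' @return Character vector of length 8.
#' @export
regressor_names <- function() {
  c("intercept", "tip", "chitin", "chitosan", "cold",
    "tip:chitin", "tip:chitosan", "tip:cold")
}

#' Specification of a synthetic TMT-style experiment
#'
#' Defines everything the intensity-matrix generator needs: the factorial
#' design size, per-protein true coefficients, per-protein residual
#' distribution families, a 5-group cluster assignment with a tunable
#' within-cluster correlation, and the residual scale. Effects and noise are
#' in log2 units, matching pooled-normalized reporter-ion ratios.
#'
#' @param n_proteins number of proteins to simulate.
#' @param replicates_per_cell biological replicates per design cell
#'   (default 5, must be >= 2).
#' @param effects numeric matrix `n_proteins x 7` of non-intercept
#'   coefficients, columns named as `regressor_names()[-1]`; defaults to all
#'   zero. A single-row matrix or named vector is recycled.
#' @param beta0 intercept per protein (default 0, recycled).
#' @param families character vector of residual families per protein, each
#'   one of `"normal"`, `"gamma"`, `"lognormal"`, `"uniform"` (recycled).
#' @param family_params list of per-family shape parameters:
#'   `gamma_shape` (default 2) and `lognormal_sigma` (default 0.5).
#' @param clusters integer cluster labels in 1..5 per protein (recycled;
#'   default cycles 1..5).
#' @param within_cluster_correlation common correlation induced between
#'   proteins of one cluster by a shared Gaussian latent factor; in `[0, 1)`.
#' @param noise_sd residual standard deviation in log2 units.
#' @param seed integer seed; every generator call seeds its own stream.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_proteins,
                            replicates_per_cell = 5,
                            effects = NULL,
                            beta0 = 0,
                            families = "normal",
                            family_params = list(gamma_shape = 2,
                                                 lognormal_sigma = 0.5),
                            clusters = NULL,
                            within_cluster_correlation = 0,
                            noise_sd = 0.5,
                            seed = 1L) {
  stopifnot(n_proteins >= 1, replicates_per_cell >= 2)
  if (within_cluster_correlation < 0 || within_cluster_correlation >= 1) {
    stop("within_cluster_correlation must lie in [0, 1)")
  }
  eff_names <- regressor_names()[-1]
  if (is.null(effects)) {
    effects <- matrix(0, n_proteins, 7, dimnames = list(NULL, eff_names))
  } else {
    if (is.vector(effects)) effects <- matrix(effects, nrow = 1,
                                              dimnames = list(NULL, names(effects)))
    if (is.null(colnames(effects)) && ncol(effects) == 7) {
      colnames(effects) <- eff_names
    }
    bad <- setdiff(colnames(effects), eff_names)
    if (length(bad)) stop("unknown regressor in effects: ", paste(bad, collapse = ", "))
    full <- matrix(0, nrow(effects), 7, dimnames = list(NULL, eff_names))
    full[, colnames(effects)] <- effects
    effects <- full[rep_len(seq_len(nrow(full)), n_proteins), , drop = FALSE]
  }
  if (!all(is.finite(effects))) stop("effect sizes must be finite")
  families <- rep_len(families, n_proteins)
  bad_fam <- setdiff(unique(families), c("normal", "gamma", "lognormal", "uniform"))
  if (length(bad_fam)) stop("unknown residual family: ", paste(bad_fam, collapse = ", "))
  if (is.null(clusters)) clusters <- rep_len(1:5, n_proteins)
  clusters <- rep_len(as.integer(clusters), n_proteins)
  structure(list(
    n_proteins = as.integer(n_proteins),
    replicates_per_cell = as.integer(replicates_per_cell),
    effects = effects,
    beta0 = rep_len(beta0, n_proteins),
    families = families,
    family_params = family_params,
    clusters = clusters,
    within_cluster_correlation = within_cluster_correlation,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "simulation_spec")
}

# Zero-mean, unit-sd residual draw from one family; location-shifted so
# values may be negative, as for pooled-normalized log2 ratios.
sample_residuals <- function(n, family, params) {
  switch(family,
    normal = stats::rnorm(n),
    uniform = stats::runif(n, -sqrt(3), sqrt(3)),
    gamma = {
      k <- params$gamma_shape %||% 2
      (stats::rgamma(n, shape = k, rate = 1) - k) / sqrt(k)
    },
    lognormal = {
      s <- params$lognormal_sigma %||% 0.5
      mu <- exp(s^2 / 2)
      (stats::rlnorm(n, 0, s) - mu) / sqrt((exp(s^2) - 1) * exp(s^2))
    },
    stop("unknown residual family: ", family)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic intensity matrix with known ground truth
#'
#' Builds the complete 2 (zone) x 4 (treatment) factorial with
#' `replicates_per_cell` replicates per cell. Cell means are the design
#' matrix times each protein's true coefficient vector; residuals are drawn
#' from the protein's distribution family, centered to mean zero and scaled
#' to `noise_sd`, so that the (squared skewness, kurtosis) fingerprint of
#' the family is preserved while values may be negative. Proteins of one
#' cluster share a per-sample Gaussian latent factor inducing the requested
#' pairwise correlation.
#'
#' @param spec a [simulation_spec].
#' @return A list with elements `matrix` (an [intensity_matrix]) and
#'   `truth` (a list with the per-protein true 8-coefficient matrix `beta`,
#'   `clusters`, and `families`).
#' @export
generate_intensity_matrix <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  r <- spec$replicates_per_cell
  cells <- expand.grid(replicate = seq_len(r),
                       treatment = treatment_levels(),
                       zone = zone_levels(),
                       stringsAsFactors = FALSE)
  n_samp <- nrow(cells)
  meta <- data.frame(
    sample_id = sprintf("%s_%s_r%d", cells$zone, cells$treatment, cells$replicate),
    zone = cells$zone,
    treatment = cells$treatment,
    replicate = cells$replicate,
    plex = cells$replicate,   # one plex per replicate block
    is_pool = FALSE,
    stringsAsFactors = FALSE
  )
  X <- build_design_matrix(meta)
  beta <- cbind(intercept = spec$beta0, spec$effects)
  mu <- beta %*% t(X)                                   # n_proteins x n_samp

  rho <- spec$within_cluster_correlation
  latent <- matrix(stats::rnorm(5L * n_samp), 5L, n_samp) # one factor per cluster
  resid <- matrix(0, spec$n_proteins, n_samp)
  for (i in seq_len(spec$n_proteins)) {
    e <- sample_residuals(n_samp, spec$families[i], spec$family_params)
    if (rho > 0) {
      e <- sqrt(rho) * latent[spec$clusters[i], ] + sqrt(1 - rho) * e
    }
    resid[i, ] <- spec$noise_sd * e
  }
  values <- mu + resid
  rownames(values) <- sprintf("HORVU_SIM%04d", seq_len(spec$n_proteins))
  rownames(beta) <- rownames(values)
  list(matrix = intensity_matrix(values, meta),
       truth = list(beta = beta,
                    clusters = stats::setNames(spec$clusters, rownames(values)),
                    families = stats::setNames(spec$families, rownames(values))))
}

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

mutate_sequence <- function(seq_chars, rate) {
  n <- length(seq_chars)
  hit <- stats::runif(n) < rate
  if (any(hit)) {
    for (j in which(hit)) {
      seq_chars[j] <- sample(setdiff(AA20, seq_chars[j]), 1)
    }
  }
  seq_chars
}

#' Generate a paralog-structured reference/query proteome pair
#'
#' Emulates the cross-species ribosomal-protein mapping problem: the
#' reference proteome holds `n_families` families of `paralogs_per_family`
#' closely related sequences (paralogs differ by a small number of point
#' substitutions); the query proteome holds one mutated copy of each
#' reference sequence, substituted at `substitution_rate` per residue.
#'
#' @param n_families number of protein families.
#' @param paralogs_per_family paralogs per family.
#' @param substitution_rate per-residue substitution probability for the
#'   query copies, in `[0, 0.5]`.
#' @param seq_length residue length of generated sequences (> 0).
#' @param paralog_divergence per-residue substitution probability between
#'   paralogs of a family (default 0.02).
#' @param seed integer seed.
#' @return A list with `query` and `reference` (each a [fasta_db]) and
#'   `truth`, a data.frame mapping each query to its source reference
#'   sequence and family.
#' @export
generate_proteome_pair <- function(n_families, paralogs_per_family,
                                   substitution_rate, seq_length = 60,
                                   paralog_divergence = 0.02, seed = 1L) {
  if (substitution_rate < 0 || substitution_rate > 0.5) {
    stop("substitution_rate must lie in [0, 0.5]")
  }
  if (seq_length < 1) stop("zero-length sequences requested")
  set.seed(seed)
  ref_ids <- character(0); ref_seqs <- character(0)
  families <- character(0)
  for (f in seq_len(n_families)) {
    base <- sample(AA20, seq_length, replace = TRUE)
    fam <- sprintf("FAM%02d", f)
    for (p in seq_len(paralogs_per_family)) {
      s <- if (p == 1) base else mutate_sequence(base, paralog_divergence)
      ref_ids <- c(ref_ids, sprintf("%s_P%d", fam, p))
      ref_seqs <- c(ref_seqs, paste(s, collapse = ""))
      families <- c(families, fam)
    }
  }
  qry_ids <- paste0("Q_", ref_ids)
  qry_seqs <- vapply(ref_seqs, function(s) {
    paste(mutate_sequence(strsplit(s, "")[[1]], substitution_rate), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  reference <- fasta_db(ref_ids, ref_seqs,
                        desc = sprintf("synthetic ribosomal protein %s", ref_ids))
  query <- fasta_db(qry_ids, qry_seqs,
                    desc = sprintf("synthetic ribosomal protein query of %s", ref_ids))
  truth <- data.frame(query_id = qry_ids, reference_id = ref_ids,
                      family = families, stringsAsFactors = FALSE)
  list(query = query, reference = reference, truth = truth)
}

#' Generate a synthetic BCA plate
#'
#' Emulates a bicinchoninic-acid protein assay: BSA standards across the
#' stated concentration series plus unknown wells whose absorbance follows
#' `intercept + slope * concentration + noise`, where the unknown
#' concentration derives from the true tissue protein content, the fresh
#' weight and the extract volume. Blank wells carry the intercept alone.
#'
#' @param true_contents true protein contents of the unknowns, ug/mg fresh
#'   weight (may be empty for a standards-only plate).
#' @param fw_mg fresh weights (mg) of the unknowns, positive, recycled.
#' @param curve numeric `c(slope, intercept)` of the absorbance response
#'   (absorbance per ug/cm^3, absorbance).
#' @param noise_sd absorbance noise standard deviation (>= 0).
#' @param standards BSA standard concentrations in ug/cm^3.
#' @param extract_volume extract volume in cm^3.
#' @param dilution dilution factor applied to unknowns.
#' @param seed integer seed.
#' @return A list with `plate` (data.frame of wells: `well_type`,
#'   `sample_id`, `concentration`, `absorbance`, `fw_mg`), and the assay
#'   geometry (`extract_volume`, `dilution`) plus `truth` (the inputs).
#' @export
generate_bca_plate <- function(true_contents, fw_mg, curve = c(0.002, 0.05),
                               noise_sd = 0, standards = c(0, 25, 125, 250,
                                                           500, 750, 1000,
                                                           1500, 2000),
                               extract_volume = 0.2, dilution = 1, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n_unk <- length(true_contents)
  fw_mg <- rep_len(fw_mg, max(n_unk, 1))[seq_len(n_unk)]
  if (n_unk && any(fw_mg <= 0)) stop("fresh weights must be positive")
  set.seed(seed)
  slope <- curve[1]; intercept <- curve[2]
  std <- data.frame(
    well_type = "standard",
    sample_id = sprintf("STD%02d", seq_along(standards)),
    concentration = standards,
    absorbance = intercept + slope * standards +
      stats::rnorm(length(standards), 0, noise_sd),
    fw_mg = NA_real_, stringsAsFactors = FALSE)
  blank <- data.frame(
    well_type = "blank", sample_id = c("BLK1", "BLK2"),
    concentration = 0,
    absorbance = intercept + stats::rnorm(2, 0, noise_sd),
    fw_mg = NA_real_, stringsAsFactors = FALSE)
  plate <- rbind(std, blank)
  if (n_unk) {
    conc <- true_contents * fw_mg / (extract_volume * dilution)
    unk <- data.frame(
      well_type = "unknown",
      sample_id = sprintf("UNK%02d", seq_len(n_unk)),
      concentration = NA_real_,
      absorbance = intercept + slope * conc +
        stats::rnorm(n_unk, 0, noise_sd),
      fw_mg = fw_mg, stringsAsFactors = FALSE)
    plate <- rbind(plate, unk)
  }
  list(plate = plate, extract_volume = extract_volume, dilution = dilution,
       truth = list(contents = true_contents, fw_mg = fw_mg, curve = curve))
}
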