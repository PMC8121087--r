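#' Build a pipeline run configuration
#'
#' Collects every tunable of the end-to-end synthetic run: problem sizes,
#' significance thresholds, bootstrap scales and counts, K-means k and
#' the output directory. A seed is mandatory because several stages are
#' stochastic.
#'
#' @param seed integer seed (mandatory).
#' @param outdir output directory (created if absent).
#' @param n_proteins,replicates_per_cell simulated experiment size.
#' @param effect_fraction fraction of proteins given a `tip:cold`
#'   interaction effect.
#' @param effect_size interaction effect, log2 units.
#' @param noise_sd residual sd, log2 units.
#' @param q_threshold,interaction_p_threshold significance thresholds.
#' @param boot_scales,boot_B multiscale-bootstrap scales and per-scale
#'   replicates (protein-axis clustering).
#' @param kmeans_k number of K-means clusters.
#' @param au_complement AU complement threshold for sub-cluster calls.
#' @param align_threshold alignment acceptance score.
#' @param n_families,paralogs_per_family,substitution_rate synthetic
#'   proteome-pair parameters.
#' @param rf_trees random-forest tree count.
#' @return List of class `run_config`.
#' @export
pipeline_config <- function(seed, outdir = tempfile("protacclim_run_"),
                            n_proteins = 80, replicates_per_cell = 5,
                            effect_fraction = 0.1, effect_size = 2,
                            noise_sd = 0.5, q_threshold = 0.05,
                            interaction_p_threshold = 0.05,
                            boot_scales = seq(0.5, 1.4, by = 0.1),
                            boot_B = 200, kmeans_k = 5,
                            au_complement = 0.01, align_threshold = 10,
                            n_families = 4, paralogs_per_family = 2,
                            substitution_rate = 0.05, rf_trees = 200) {
  if (missing(seed) || is.null(seed)) {
    stop("config error: a seed is mandatory for stochastic stages")
  }
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "run_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes simulate, fingerprint, differential abundance, clustering
#' (K-means and AU-supported HCA), class prediction, homology mapping and
#' the content assay on synthetic inputs, writing every tabular output as
#' TSV (dendrogram as Newick) plus a JSON manifest of seeds, parameters
#' and per-file MD5 checksums. Rerunning with the same configuration
#' reproduces every output bit-identically.
#'
#' @param config a [pipeline_config()].
#' @return The manifest (list), invisibly; written to
#'   `<outdir>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$seed)) stop("config error: seed missing")
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  out_file <- function(name) {
    f <- file.path(outdir, name); files[[length(files) + 1]] <<- f; f
  }

  # -- simulate ------------------------------------------------------------
  sim <- pipeline_stage("simulate", {
    n_eff <- max(1, round(config$effect_fraction * config$n_proteins))
    effects <- matrix(0, config$n_proteins, 7,
                      dimnames = list(NULL, regressor_names()[-1]))
    effects[seq_len(n_eff), "tip:cold"] <- config$effect_size
    spec <- simulation_spec(config$n_proteins,
                            replicates_per_cell = config$replicates_per_cell,
                            effects = effects, noise_sd = config$noise_sd,
                            seed = config$seed)
    generate_intensity_matrix(spec)
  })
  write_intensity_matrix(sim$matrix, out_file("intensities.tsv"),
                         out_file("samples.csv"))

  # -- fingerprint ---------------------------------------------------------
  fp <- pipeline_stage("fingerprint", {
    fingerprint_matrix(sim$matrix, B_levene = 200, seed = config$seed + 1L)
  })
  utils::write.csv(fp, out_file("fingerprints.csv"), row.names = FALSE)

  # -- differential abundance ----------------------------------------------
  da <- pipeline_stage("diffabund", fit_da(sim$matrix, fingerprints = fp))
  classes <- classify_response(da, q_threshold = config$q_threshold,
                               interaction_p_threshold =
                                 config$interaction_p_threshold)
  da_table <- data.frame(protein_id = da$protein_id, da$coef,
                         p = da$p, q = da$q, family = da$family,
                         check.names = FALSE)
  utils::write.table(da_table, out_file("differential.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(classes, out_file("classes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # -- clustering ----------------------------------------------------------
  clust <- pipeline_stage("cluster", {
    km <- kmeans_partition(sim$matrix$values, k = config$kmeans_k,
                           seed = config$seed + 2L)
    au <- au_cluster(sim$matrix$values, scales = config$boot_scales,
                     B = config$boot_B, seed = config$seed + 3L)
    list(km = km, au = au,
         subclusters = high_confidence_subclusters(
           au, complement_threshold = config$au_complement))
  })
  utils::write.table(
    data.frame(protein_id = names(clust$km$assignments),
               kmeans_cluster = unname(clust$km$assignments)),
    out_file("kmeans.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  dendrogram_newick(clust$au, out_file("dendrogram.nwk"))

  # -- class prediction ----------------------------------------------------
  pred <- pipeline_stage("predict", {
    xs <- t(sim$matrix$values)
    meta <- sim$matrix$sample_meta
    list(rf = rf_importance(xs, meta = meta, task = "zone",
                            n_trees = config$rf_trees,
                            seed = config$seed + 4L),
         vip = pls_da_vip(xs, meta$treatment))
  })
  utils::write.table(pred$rf$importance, out_file("rf_importance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pred$vip$vip, out_file("vip.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # -- homology ------------------------------------------------------------
  hom <- pipeline_stage("homology", {
    pair <- generate_proteome_pair(config$n_families,
                                   config$paralogs_per_family,
                                   config$substitution_rate,
                                   seed = config$seed + 5L)
    scores <- align_all(pair$query, pair$reference)
    fam_map <- stats::setNames(pair$truth$family, pair$truth$reference_id)
    list(pair = pair, scores = scores,
         assign = assign_paralogs(scores, fam_map,
                                  threshold = config$align_threshold))
  })
  write_fasta_db(hom$pair$query, out_file("query.fasta"))
  write_fasta_db(hom$pair$reference, out_file("reference.fasta"))
  utils::write.table(as.data.frame(hom$assign), out_file("paralogs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # -- content assay -------------------------------------------------------
  content <- pipeline_stage("content", {
    truth <- c(9.57, 4.15, 7.39, 6.00)   # tip contents across treatments
    plate <- generate_bca_plate(rep(truth, each = 5),
                                fw_mg = 40, noise_sd = 0.002,
                                seed = config$seed + 6L)
    rec <- recover_bca_contents(plate)
    rec$zone <- "tip"
    rec$treatment <- rep(treatment_levels()[c(1, 4, 2, 3)], each = 5)
    list(recovered = rec,
         comparison = compare_contents(rec, seed = config$seed + 7L))
  })
  utils::write.table(content$recovered, out_file("contents.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # -- manifest ------------------------------------------------------------
  cfg_for_hash <- unclass(config)
  cfg_for_hash$outdir <- NULL
  cfg_json <- jsonlite::toJSON(cfg_for_hash, auto_unbox = TRUE, digits = NA)
  cfg_file <- tempfile(fileext = ".json")
  writeLines(cfg_json, cfg_file)
  checksums <- tools::md5sum(unlist(files))
  names(checksums) <- basename(names(checksums))
  manifest <- list(
    package = "protacclim",
    version = as.character(utils::packageVersion("protacclim")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    parameters = cfg_for_hash,
    outputs = as.list(checksums)
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
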