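#' Protein x sample intensity container
#'
#' Holds a log2-scale, pooled-channel-normalized protein abundance matrix
#' together with the factorial sample metadata of the experiment: a
#' two-level root-zone factor (`tip`, `tip_adjacent`) and a four-level
#' treatment factor (`control`, `cold`, `chitin`, `chitosan`), plus
#' replicate index, TMT plex and a pool-channel flag.
#'
#' @param values numeric matrix, proteins in rows (unique rownames are the
#'   protein ids), samples in columns.
#' @param sample_meta data.frame with one row per column of `values`, with
#'   columns `sample_id`, `zone`, `treatment`, `replicate`, `plex` and
#'   optionally `is_pool` (defaults to `FALSE`).
#' @return An object of class `intensity_matrix`: a list with elements
#'   `values` and `sample_meta`.
#' @export
intensity_matrix <- function(values, sample_meta) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    stop("`values` must have rownames (protein ids)")
  }
  if (anyDuplicated(rownames(values))) {
    stop("protein ids must be unique")
  }
  if (nrow(sample_meta) != ncol(values)) {
    stop("`sample_meta` must have one row per sample column")
  }
  if (is.null(sample_meta$is_pool)) sample_meta$is_pool <- FALSE
  required <- c("sample_id", "zone", "treatment", "replicate", "plex")
  missing <- setdiff(required, names(sample_meta))
  if (length(missing)) {
    stop("sample_meta lacks columns: ", paste(missing, collapse = ", "))
  }
  nonpool <- !sample_meta$is_pool
  bad_zone <- setdiff(unique(sample_meta$zone[nonpool]), zone_levels())
  bad_trt <- setdiff(unique(sample_meta$treatment[nonpool]), treatment_levels())
  if (length(bad_zone)) stop("unknown zone level: ", paste(bad_zone, collapse = ", "))
  if (length(bad_trt)) stop("unknown treatment level: ", paste(bad_trt, collapse = ", "))
  colnames(values) <- sample_meta$sample_id
  structure(list(values = values, sample_meta = sample_meta),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d proteins x %d samples\n",
              nrow(x$values), ncol(x$values)))
  np <- !x$sample_meta$is_pool
  cat("  zones:     ", paste(names(table(x$sample_meta$zone[np])), collapse = ", "), "\n")
  cat("  treatments:", paste(names(table(x$sample_meta$treatment[np])), collapse = ", "), "\n")
  invisible(x)
}

#' Factor levels of the two-factor design
#'
#' The reference levels come last in the model (treatment-contrast coding is
#' against `tip_adjacent` and `control`); these helpers fix the canonical
#' ordering used throughout.
#' @return Character vector of levels.
#' @export
zone_levels <- function() c("tip_adjacent", "tip")

#' @rdname zone_levels
#' @export
treatment_levels <- function() c("control", "chitin", "chitosan", "cold")

#' Read and write intensity matrices as TSV + sample sheet CSV
#'
#' The on-disk dialect is a TSV with proteins in rows and a first column
#' `protein_id`, paired with a CSV sample sheet holding the columns
#' `sample_id`, `zone`, `treatment`, `replicate`, `plex`, `is_pool`.
#'
#' @param x an [intensity_matrix].
#' @param values_path path of the TSV intensity table.
#' @param meta_path path of the CSV sample sheet.
#' @return `write_intensity_matrix` returns the paths invisibly;
#'   `read_intensity_matrix` returns an [intensity_matrix].
#' @export
write_intensity_matrix <- function(x, values_path, meta_path) {
  stopifnot(inherits(x, "intensity_matrix"))
  df <- data.frame(protein_id = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.table(df, values_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(x$sample_meta, meta_path, row.names = FALSE)
  invisible(c(values_path, meta_path))
}

#' @rdname write_intensity_matrix
#' @export
read_intensity_matrix <- function(values_path, meta_path) {
  df <- utils::read.delim(values_path, check.names = FALSE)
  meta <- utils::read.csv(meta_path)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$protein_id
  intensity_matrix(values, meta)
}
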