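#' Log2-transform raw intensities and normalize to pooled channels
#'
#' Reporter-ion intensities are log2 transformed and expressed relative to
#' the pooled reference channel(s) of the same plex, which makes abundances
#' comparable across plexes. When a plex carries several pool channels the
#' reference is the arithmetic mean of their log2 intensities. Pool columns
#' are removed from the output.
#'
#' @param raw an [intensity_matrix] of strictly positive raw intensities,
#'   whose `sample_meta$is_pool` flags the pooled channels.
#' @return An [intensity_matrix] of log2 ratios to the plex pool, without
#'   the pool columns.
#' @export
log2_normalize_to_pool <- function(raw) {
  stopifnot(inherits(raw, "intensity_matrix"))
  v <- raw$values
  meta <- raw$sample_meta
  if (any(v[is.finite(v)] <= 0)) stop("raw intensities must be positive")
  if (!any(meta$is_pool)) stop("no pool channel present")
  lv <- log2(v)
  for (px in unique(meta$plex)) {
    in_plex <- meta$plex == px
    pool_cols <- which(in_plex & meta$is_pool)
    if (!length(pool_cols)) stop("plex ", px, " has no pool channel")
    ref <- rowMeans(lv[, pool_cols, drop = FALSE])
    lv[, in_plex] <- lv[, in_plex, drop = FALSE] - ref
  }
  keep <- !meta$is_pool
  intensity_matrix(lv[, keep, drop = FALSE], meta[keep, , drop = FALSE])
}

#' Filter proteins on identification evidence
#'
#' Removes reverse-database hits, proteins identified by fewer than
#' `min_peptides` razor + unique peptides, and any protein with a
#' non-finite value in a retained sample (complete-case filtering keeps the
#' factorial design balanced). Row order of survivors is preserved; the
#' operation is idempotent.
#'
#' @param matrix an [intensity_matrix].
#' @param evidence data.frame with columns `protein_id`,
#'   `razor_unique_peptides`, `is_reverse` and optionally `description`,
#'   `go_terms`; must cover every protein of `matrix`.
#' @param min_peptides minimum razor + unique peptide count (default 2).
#' @return The filtered [intensity_matrix].
#' @export
filter_evidence <- function(matrix, evidence, min_peptides = 2) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  ids <- rownames(matrix$values)
  missing <- setdiff(ids, evidence$protein_id)
  if (length(missing)) {
    stop("evidence missing protein ids: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  ev <- evidence[match(ids, evidence$protein_id), ]
  keep <- !ev$is_reverse &
    ev$razor_unique_peptides >= min_peptides &
    apply(is.finite(matrix$values), 1, all)
  intensity_matrix(matrix$values[keep, , drop = FALSE], matrix$sample_meta)
}

#' Volcano-plot quantities for one treatment-versus-control contrast
#'
#' Computes, per protein, the log2 ratio between a treatment and the
#' control within one root zone (difference of cell means on the log2
#' scale) and pairs it with `-log10` of the supplied adjusted p-values.
#'
#' @param matrix an [intensity_matrix].
#' @param qvalues named numeric vector of adjusted p-values in `(0, 1]`,
#'   covering every protein of `matrix`.
#' @param treatment contrast treatment level.
#' @param zone root zone within which the contrast is taken.
#' @return data.frame with `protein_id`, `log2_ratio`, `neg_log10_q`.
#' @export
volcano_table <- function(matrix, qvalues, treatment, zone = "tip") {
  stopifnot(inherits(matrix, "intensity_matrix"))
  meta <- matrix$sample_meta
  trt_cols <- meta$zone == zone & meta$treatment == treatment & !meta$is_pool
  ctl_cols <- meta$zone == zone & meta$treatment == "control" & !meta$is_pool
  if (!any(trt_cols) || !any(ctl_cols)) stop("empty contrast cells")
  ids <- rownames(matrix$values)
  q <- qvalues[ids]
  if (any(is.na(q)) || any(q <= 0) || any(q > 1)) {
    stop("qvalues must cover all proteins and lie in (0, 1]")
  }
  ratio <- rowMeans(matrix$values[, trt_cols, drop = FALSE]) -
    rowMeans(matrix$values[, ctl_cols, drop = FALSE])
  data.frame(protein_id = ids, log2_ratio = unname(ratio),
             neg_log10_q = unname(-log10(q)), stringsAsFactors = FALSE)
}
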