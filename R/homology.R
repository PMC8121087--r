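#' A small FASTA-backed protein sequence collection
#'
#' Sequences are amino acids over the 20-letter alphabet plus `X`
#' (unknown residue). Reading and writing go through standard FASTA with
#' 60-character wrapping.
#'
#' @param ids unique sequence identifiers.
#' @param seqs amino-acid sequence strings.
#' @param desc optional description lines (defaults to the ids).
#' @return data.frame of class `fasta_db` with columns `id`, `seq`,
#'   `desc`.
#' @export
fasta_db <- function(ids, seqs, desc = ids) {
  if (anyDuplicated(ids)) stop("sequence ids must be unique")
  if (any(nchar(seqs) == 0)) stop("zero-length sequence")
  structure(data.frame(id = ids, seq = toupper(seqs), desc = desc,
                       stringsAsFactors = FALSE),
            class = c("fasta_db", "data.frame"))
}

#' @rdname fasta_db
#' @param path FASTA file path.
#' @export
read_fasta_db <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  full <- names(ss)
  ids <- sub("\\s.*$", "", full)
  fasta_db(ids, as.character(ss), desc = full)
}

#' @rdname fasta_db
#' @param db a `fasta_db`.
#' @export
write_fasta_db <- function(db, path) {
  headers <- ifelse(db$desc == db$id, db$id, paste(db$id, db$desc))
  ss <- Biostrings::AAStringSet(stats::setNames(db$seq, headers))
  Biostrings::writeXStringSet(ss, path, width = 60)
  invisible(path)
}

#' Alignment scoring scheme with affine gap penalties
#'
#' Either simple match/mismatch scoring or a named substitution matrix
#' (BLOSUM62). A gap run of length `L` costs
#' `gap_opening + L * gap_extension`. Under simple scoring the unknown
#' residue `X` scores 0 against everything.
#'
#' @param type `"simple"` or `"blosum62"`.
#' @param match,mismatch simple-scheme scores.
#' @param gap_opening,gap_extension non-negative gap costs.
#' @return List of class `scoring_scheme` with a full substitution
#'   matrix.
#' @export
scoring_scheme <- function(type = c("blosum62", "simple"), match = 1,
                           mismatch = -1, gap_opening = 10,
                           gap_extension = 4) {
  type <- match.arg(type)
  if (gap_opening < 0 || gap_extension < 0) stop("gap costs must be >= 0")
  if (type == "simple") {
    alphabet <- c(LETTERS)
    S <- matrix(mismatch, length(alphabet), length(alphabet),
                dimnames = list(alphabet, alphabet))
    diag(S) <- match
    S["X", ] <- 0; S[, "X"] <- 0
  } else {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    S <- e$BLOSUM62
  }
  structure(list(type = type, substitution = S, gap_opening = gap_opening,
                 gap_extension = gap_extension),
            class = "scoring_scheme")
}

#' Needleman-Wunsch global alignment with affine gaps
#'
#' Three-state dynamic program (match, gap-in-a, gap-in-b) maximizing the
#' global alignment score under the given [scoring_scheme()]; the
#' reported aligned pair attains the score. Opening a gap of length `L`
#' costs `gap_opening + L * gap_extension`.
#'
#' @param a,b non-empty sequence strings.
#' @param scoring a [scoring_scheme()].
#' @return List with `score`, `aligned_a`, `aligned_b`.
#' @export
nw_align <- function(a, b, scoring = scoring_scheme()) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  n <- length(av); m <- length(bv)
  if (n == 0 || m == 0) stop("sequences must be non-empty")
  S <- scoring$substitution
  bad <- setdiff(unique(c(av, bv)), rownames(S))
  if (length(bad)) stop("illegal residue character: ", paste(bad, collapse = ""))
  go <- scoring$gap_opening; ge <- scoring$gap_extension
  NEG <- -1e18
  # M: a_i aligned to b_j; Ia: a_i against gap; Ib: b_j against gap
  M <- Ia <- Ib <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (n >= 1) Ia[2:(n + 1), 1] <- -(go + (1:n) * ge)
  if (m >= 1) Ib[1, 2:(m + 1)] <- -(go + (1:m) * ge)
  tb_M <- tb_Ia <- tb_Ib <- matrix(0L, n + 1, m + 1)  # 1=M, 2=Ia, 3=Ib
  tb_Ia[2, 1] <- 1L
  if (n > 1) tb_Ia[3:(n + 1), 1] <- 2L
  tb_Ib[1, 2] <- 1L
  if (m > 1) tb_Ib[1, 3:(m + 1)] <- 3L
  sub <- matrix(S[av, bv], n, m)
  open_cost <- go + ge
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      prev <- c(M[i - 1, j - 1], Ia[i - 1, j - 1], Ib[i - 1, j - 1])
      k <- which.max(prev)
      M[i, j] <- prev[k] + sub[i - 1, j - 1]
      tb_M[i, j] <- k
      # a gap may open from either other state (adjacent opposite-sequence
      # gaps are legal alignments and win when gap costs are small)
      cand_a <- c(M[i - 1, j] - open_cost, Ia[i - 1, j] - ge,
                  Ib[i - 1, j] - open_cost)
      ka <- which.max(cand_a)
      Ia[i, j] <- cand_a[ka]; tb_Ia[i, j] <- ka
      cand_b <- c(M[i, j - 1] - open_cost, Ia[i, j - 1] - open_cost,
                  Ib[i, j - 1] - ge)
      kb <- which.max(cand_b)
      Ib[i, j] <- cand_b[kb]; tb_Ib[i, j] <- kb
    }
  }
  finals <- c(M[n + 1, m + 1], Ia[n + 1, m + 1], Ib[n + 1, m + 1])
  state <- which.max(finals)
  score <- finals[state]
  out_a <- character(0); out_b <- character(0)
  i <- n + 1; j <- m + 1
  while (i > 1 || j > 1) {
    if (state == 1L) {
      out_a <- c(av[i - 1], out_a); out_b <- c(bv[j - 1], out_b)
      state <- tb_M[i, j]; i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      out_a <- c(av[i - 1], out_a); out_b <- c("-", out_b)
      state <- tb_Ia[i, j]; i <- i - 1
    } else {
      out_a <- c("-", out_a); out_b <- c(bv[j - 1], out_b)
      state <- tb_Ib[i, j]; j <- j - 1
    }
  }
  list(score = score, aligned_a = paste(out_a, collapse = ""),
       aligned_b = paste(out_b, collapse = ""))
}

#' All-vs-all global alignment of two FASTA collections
#'
#' Computes the complete query x reference score matrix with
#' [nw_align()]; deterministic.
#'
#' @param query,reference [fasta_db] objects (non-empty).
#' @param scoring a [scoring_scheme()].
#' @return Numeric matrix of scores, queries in rows.
#' @export
align_all <- function(query, reference, scoring = scoring_scheme()) {
  if (!nrow(query) || !nrow(reference)) stop("both collections must be non-empty")
  scores <- matrix(NA_real_, nrow(query), nrow(reference),
                   dimnames = list(query$id, reference$id))
  for (i in seq_len(nrow(query))) {
    for (j in seq_len(nrow(reference))) {
      scores[i, j] <- nw_align(query$seq[i], reference$seq[j], scoring)$score
    }
  }
  scores
}

#' Assign query proteins to reference families and paralogs
#'
#' Per query, the candidate paralogs are the reference entries whose
#' score lies within `tie_eps` of the query's best score; the assignment
#' is accepted iff the best score exceeds `threshold` (default 10), the
#' family is the best candidate's family, and the evidence class is
#' `certain` when at least one of the query's peptides maps uniquely to a
#' single paralog, else `potential`.
#'
#' @param scores query x reference score matrix from [align_all()].
#' @param family_map named character vector: reference id -> family label;
#'   must cover every reference column.
#' @param peptide_evidence optional data.frame with `query_id`, `peptide`,
#'   `is_unique`; queries absent from it fall back to `potential` with a
#'   warning.
#' @param threshold acceptance score threshold (default 10, strict
#'   inequality).
#' @param tie_eps score tolerance for listing tied candidates (default 0:
#'   exact equality).
#' @return data.frame of class `paralog_assignment`: one row per query
#'   with `query_id`, `family`, `candidates` (semicolon-separated),
#'   `best_score`, `accepted`, `evidence`. The attributes
#'   `n_certain`/`n_potential` hold the accepted counts per class.
#' @export
assign_paralogs <- function(scores, family_map, peptide_evidence = NULL,
                            threshold = 10, tie_eps = 0) {
  missing <- setdiff(colnames(scores), names(family_map))
  if (length(missing)) {
    stop("family_map missing reference ids: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  has_unique <- character(0)
  if (!is.null(peptide_evidence)) {
    agg <- tapply(peptide_evidence$is_unique, peptide_evidence$query_id, any)
    has_unique <- names(agg)[agg]
    absent <- setdiff(rownames(scores), peptide_evidence$query_id)
    if (length(absent)) {
      warning(length(absent),
              " query(ies) absent from peptide evidence; classed potential")
    }
  }
  rows <- lapply(rownames(scores), function(qid) {
    s <- scores[qid, ]
    best <- max(s)
    cand <- names(s)[s >= best - tie_eps]
    data.frame(query_id = qid,
               family = unname(family_map[cand[1]]),
               candidates = paste(cand, collapse = ";"),
               best_score = best,
               accepted = best > threshold,
               evidence = if (qid %in% has_unique) "certain" else "potential",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("paralog_assignment", "data.frame")
  attr(out, "n_certain") <- sum(out$accepted & out$evidence == "certain")
  attr(out, "n_potential") <- sum(out$accepted)
  out
}

#' Select translation-related proteins
#'
#' A protein is translation-related when its GO annotation intersects the
#' whitelist, or its description contains "translation", "ribosome" or
#' "ribosomal" as a case-insensitive substring.
#'
#' @param evidence data.frame with `protein_id`, `description` and
#'   optionally `go_terms` (semicolon-separated GO ids).
#' @param go_whitelist character vector of GO ids (may be empty).
#' @return Character vector of selected protein ids.
#' @export
select_translation_related <- function(evidence, go_whitelist = character(0)) {
  kw <- grepl("translation|ribosome|ribosomal", evidence$description,
              ignore.case = TRUE)
  go_hit <- rep(FALSE, nrow(evidence))
  if (length(go_whitelist) && !is.null(evidence$go_terms)) {
    go_hit <- vapply(strsplit(ifelse(is.na(evidence$go_terms), "",
                                     evidence$go_terms), ";"),
                     function(g) length(intersect(g, go_whitelist)) > 0,
                     logical(1))
  }
  evidence$protein_id[kw | go_hit]
}
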