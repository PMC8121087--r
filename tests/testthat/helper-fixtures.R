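# Shared fixtures and independent oracles, built in code at test time.

# Full-factorial sample sheet for r replicates per design cell.
factorial_meta <- function(r = 2) {
  cells <- expand.grid(replicate = seq_len(r),
                       treatment = treatment_levels(),
                       zone = zone_levels(),
                       stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("%s_%s_r%d", cells$zone, cells$treatment,
                                 cells$replicate),
             zone = cells$zone, treatment = cells$treatment,
             replicate = cells$replicate, plex = cells$replicate,
             is_pool = FALSE, stringsAsFactors = FALSE)
}

toy_intensity_matrix <- function(n_proteins = 4, r = 2, seed = 1) {
  set.seed(seed)
  meta <- factorial_meta(r)
  v <- matrix(rnorm(n_proteins * nrow(meta)), n_proteins,
              dimnames = list(sprintf("P%02d", seq_len(n_proteins)), NULL))
  intensity_matrix(v, meta)
}

# Brute-force global alignment oracle: enumerates every alignment path and
# scores gap runs as opening + length * extension. Independent of the
# dynamic program it checks.
enum_align_score <- function(a, b, scoring) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  S <- scoring$substitution
  go <- scoring$gap_opening
  ge <- scoring$gap_extension
  score_moves <- function(moves) {
    i <- 0; j <- 0; total <- 0
    runs <- rle(moves)
    for (k in seq_along(runs$lengths)) {
      mv <- runs$values[k]; len <- runs$lengths[k]
      if (mv == "M") {
        for (s in seq_len(len)) {
          i <- i + 1; j <- j + 1
          total <- total + S[av[i], bv[j]]
        }
      } else if (mv == "A") {
        i <- i + len
        total <- total - (go + len * ge)
      } else {
        j <- j + len
        total <- total - (go + len * ge)
      }
    }
    total
  }
  best <- -Inf
  rec <- function(i, j, moves) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score_moves(moves))
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) rec(i + 1, j + 1, c(moves, "M"))
    if (i <= length(av)) rec(i + 1, j, c(moves, "A"))
    if (j <= length(bv)) rec(i, j + 1, c(moves, "B"))
  }
  rec(1, 1, character(0))
  best
}

# Best label-permutation accuracy for a clustering against truth.
cluster_accuracy <- function(assign, truth) {
  k <- max(truth)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- 0
  for (p in perms(seq_len(k))) {
    best <- max(best, mean(p[assign] == truth))
  }
  best
}
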