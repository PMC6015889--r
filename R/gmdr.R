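#' Covariate-adjusted residual scores for the GMDR pre-scan
#'
#' Centers the trait by its per-environment mean, the quantitative-trait
#' score used by generalized multifactor dimensionality reduction: within
#' each environment the scores average zero, so cell labels reflect genetic
#' signal rather than environment means.
#'
#' @param ph [phenotype_table()].
#' @param trait trait name.
#' @return data.frame (line, env, score), one row per observation of the
#'   trait, in the phenotype table's record order.
#' @export
gmdr_residual_score <- function(ph, trait) {
  recs <- ph[ph$trait == trait, , drop = FALSE]
  if (nrow(recs) < 2L) stop("need at least 2 observations to score")
  mu <- stats::ave(recs$value, recs$env)
  data.frame(line = recs$line, env = recs$env, score = recs$value - mu,
             stringsAsFactors = FALSE)
}

# deterministic stratified round-robin fold assignment within environment
gmdr_folds <- function(env, folds, seed) {
  set.seed(seed)
  fold <- integer(length(env))
  for (h in unique(env)) {
    ix <- which(env == h)
    ix <- ix[sample.int(length(ix))]
    fold[ix] <- rep_len(seq_len(folds), length(ix))
  }
  fold
}

# genotype cell index (1..3 per locus, MISSING grouped with Qq)
gmdr_cell <- function(calls) {
  z <- match(calls, c("qq", "Qq", "QQ"))
  z[calls == "MISSING"] <- 2L
  z
}

# cross-validated testing accuracy of one candidate's cell classification
gmdr_cv_accuracy <- function(cell, score, fold, folds) {
  pos <- as.numeric(score > 0)
  ncell <- max(cell)
  S <- rowsum(score, cell, reorder = FALSE)
  # align sums/counts to cell index 1..ncell
  Sv <- numeric(ncell)
  Sv[as.integer(rownames(S))] <- S[, 1L]
  Nv <- tabulate(cell, ncell)
  acc <- numeric(folds)
  for (f in seq_len(folds)) {
    te <- fold == f
    Sf <- numeric(ncell); Nf <- numeric(ncell)
    if (any(te)) {
      Sx <- rowsum(score[te], cell[te], reorder = FALSE)
      Sf[as.integer(rownames(Sx))] <- Sx[, 1L]
      Nf <- tabulate(cell[te], ncell)
    }
    trS <- Sv - Sf; trN <- Nv - Nf
    gmean <- sum(trS) / max(sum(trN), 1)
    cmean <- ifelse(trN > 0, trS / pmax(trN, 1), gmean)
    high <- cmean > 0                      # ties at exactly 0 -> low risk
    match_ok <- (pos[te] == 1) == high[cell[te]]
    acc[f] <- if (any(te)) mean(match_ok) else NA_real_
  }
  acc
}

#' GMDR-style cross-validated scan for candidate loci and pairs
#'
#' For every locus (1D) or locus pair (2D) the observations are partitioned
#' into multilocus genotype cells; a cell is labelled high-risk when its
#' training-fold mean score is positive.  Testing accuracy is the held-out
#' proportion of observations whose score sign matches the cell label,
#' averaged over folds; candidates are ranked by it.  The 2D pair universe is
#' restricted to the top `pair_universe_m` 1D loci unless
#' `exhaustive_pairs = TRUE`.
#'
#' @param gm [genotype_matrix()].
#' @param scores data.frame from [gmdr_residual_score()].
#' @param dim 1 (single loci) or 2 (pairs).
#' @param folds number of cross-validation folds (default 10).
#' @param top_k number of candidates returned.
#' @param seed seed controlling the fold assignment.
#' @param pair_universe_m size of the 1D short-list from which 2D pairs are
#'   formed (default 20).
#' @param exhaustive_pairs evaluate all marker pairs instead (quadratic).
#' @return object of class `candidate_set`: list with `candidates`
#'   (data.frame marker1, marker2, accuracy, consistency, rank) and
#'   `settings`.
#' @export
gmdr_scan <- function(gm, scores, dim = 1, folds = 10, top_k = 10, seed = 1L,
                      pair_universe_m = 20, exhaustive_pairs = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!dim %in% c(1, 2)) stop("dim must be 1 or 2")
  if (folds < 2) stop("folds must be >= 2")
  if (top_k <= 0) stop("top_k must be positive")
  li <- match(scores$line, rownames(gm$calls))
  if (anyNA(li)) stop("scored line absent from genotype matrix")
  fold <- gmdr_folds(scores$env, folds, seed)
  sc <- scores$score
  markers <- colnames(gm$calls)

  eval_cells <- function(cell) gmdr_cv_accuracy(cell, sc, fold, folds)

  if (dim == 1) {
    accs <- matrix(NA_real_, length(markers), folds)
    for (j in seq_along(markers)) {
      accs[j, ] <- eval_cells(gmdr_cell(gm$calls[li, markers[j]]))
    }
    cand <- data.frame(marker1 = markers, marker2 = NA_character_,
                       stringsAsFactors = FALSE)
  } else {
    if (exhaustive_pairs) {
      univ <- markers
    } else {
      one <- gmdr_scan(gm, scores, dim = 1, folds = folds,
                       top_k = min(pair_universe_m, length(markers)), seed = seed)
      univ <- one$candidates$marker1
    }
    if (length(univ) < 2L) stop("need at least 2 loci for a 2D scan")
    cmb <- utils::combn(sort(match(univ, markers)), 2L)
    cand <- data.frame(marker1 = markers[cmb[1L, ]], marker2 = markers[cmb[2L, ]],
                       stringsAsFactors = FALSE)
    accs <- matrix(NA_real_, nrow(cand), folds)
    for (j in seq_len(nrow(cand))) {
      c1 <- gmdr_cell(gm$calls[li, cand$marker1[j]])
      c2 <- gmdr_cell(gm$calls[li, cand$marker2[j]])
      accs[j, ] <- eval_cells(c1 + 3L * (c2 - 1L))
    }
  }
  mean_acc <- rowMeans(accs, na.rm = TRUE)
  # CV consistency: fraction of folds in which the candidate attains the
  # fold-wise maximum accuracy
  best_per_fold <- apply(accs, 2L, max, na.rm = TRUE)
  consistency <- rowMeans(sweep(accs, 2L, best_per_fold, ">=") , na.rm = TRUE)
  ord <- order(-mean_acc, cand$marker1, cand$marker2)
  keep <- utils::head(ord, top_k)
  out <- cand[keep, , drop = FALSE]
  out$accuracy <- mean_acc[keep]
  out$consistency <- consistency[keep]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(list(candidates = out,
                 settings = list(dim = dim, folds = folds, top_k = top_k,
                                 seed = seed)),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %dD scan, %d candidates (folds=%d)\n",
              x$settings$dim, nrow(x$candidates), x$settings$folds))
  print(utils::head(x$candidates, 10))
  invisible(x)
}

#' Serialize a candidate set as TSV
#' @param cs `candidate_set`.
#' @param path output path.
#' @export
write_candidate_set <- function(cs, path) {
  utils::write.table(cs$candidates, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
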