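# resolve a term/group specification to column names of the flattened design
resolve_group <- function(design, group, cols_avail = NULL) {
  allcols <- c(colnames(design$X), unlist(lapply(design$Z, colnames), use.names = FALSE))
  out <- character()
  for (g in group) {
    if (g %in% colnames(design$X)) {
      out <- c(out, g)
    } else if (g %in% names(design$Z)) {
      out <- c(out, colnames(design$Z[[g]]))
    } else if (g %in% design$registry$kind) {
      out <- c(out, design$registry$column[design$registry$kind == g])
    } else {
      stop("unknown term or block: '", g, "'")
    }
  }
  out <- intersect(allcols, unique(out))
  if (!length(out)) stop("empty term group")
  if (!is.null(cols_avail)) out <- intersect(out, cols_avail)  # may be empty
  out
}

design_matrix_all <- function(design) {
  if (length(design$Z)) cbind(design$X, do.call(cbind, unname(design$Z)))
  else design$X
}

# Flattened matrix used by the Henderson-III reductions: each random block's
# E per-environment slices sum to the block's parent fixed column, so the
# first slice is omitted (the column span is unchanged, the redundancy is
# not).  The Gibbs sampler keeps all E slices; its priors identify them.
testing_matrix <- function(design) {
  if (!length(design$Z)) return(design$X)
  Zr <- lapply(design$Z, function(b) b[, -1L, drop = FALSE])
  cbind(design$X, do.call(cbind, unname(Zr)))
}

# Interaction slices that are children of the tested fixed columns.  A fixed
# term's own G-by-E slices span it, so reductions for the term are computed
# in the submodel without them (marginality: main effects are fitted below
# their interactions); the fullest model still supplies the denominator.
child_block_cols <- function(design, cols) {
  reg <- design$registry
  fixed <- reg[match(cols, reg$column), , drop = FALSE]
  fixed <- fixed[!is.na(fixed$kind) & fixed$kind %in% FIXED_KINDS, , drop = FALSE]
  if (!nrow(fixed)) return(character())
  child <- vapply(seq_len(nrow(fixed)), function(i) {
    sub("^[a-z]+:", paste0(kind_to_env_kind(fixed$kind[i]), ":"),
        fixed$column[i])
  }, "")
  unlist(lapply(intersect(child, names(design$Z)),
                function(b) colnames(design$Z[[b]])), use.names = FALSE)
}

#' Henderson method III F-test for a term group
#'
#' Method-of-fitting-constants test: the reduction in sums of squares gained
#' by the tested group, given all other terms, over the residual mean square
#' of the fullest model.  Random genotype-by-environment blocks are absorbed
#' as fitted columns for the reduction, their degrees of freedom charged to
#' the denominator, so the statistic is the classical partial F when the
#' design has fixed effects only.
#'
#' @param design [build_design()] output.
#' @param group character vector naming the tested group: fixed column names
#'   (`"a:S1_100"`), random block names (`"ae:S1_100"`), or effect kinds
#'   (`"a"`, `"dd"`, ... selects every column of that kind).
#' @return list with `F`, `df1`, `df2`, `p_point`, `dropped` (collinear
#'   columns excluded from the design), `degenerate` (TRUE when the tested
#'   group carries no rank).
#' @export
henderson3_f <- function(design, group) {
  A <- testing_matrix(design)
  cols <- resolve_group(design, group, cols_avail = colnames(A))
  y <- design$y
  n <- length(y)
  if (!length(cols)) {
    warning("degenerate term group (no testable columns): ",
            paste(group, collapse = ", "))
    return(list(F = NA_real_, df1 = 0L, df2 = NA_integer_, p_point = NA_real_,
                dropped = character(), degenerate = TRUE))
  }
  qa <- qr(A)
  rank_full <- qa$rank
  df2 <- n - rank_full
  if (df2 <= 0) stop("no residual degrees of freedom (df2 <= 0)")
  dropped <- character()
  if (rank_full < ncol(A)) {
    keep <- qa$pivot[seq_len(rank_full)]
    dropped <- colnames(A)[-keep]
    if (length(dropped)) {
      warning("collinear column(s) dropped: ", paste(dropped, collapse = ", "))
    }
  }
  sse_full <- sum(qr.resid(qa, y)^2)
  kids <- child_block_cols(design, cols)
  test_cols <- setdiff(colnames(A), kids)
  qr_test <- qr(A[, test_cols, drop = FALSE])
  sse_test <- sum(qr.resid(qr_test, y)^2)
  red <- A[, setdiff(test_cols, cols), drop = FALSE]
  qr_red <- qr(red)
  sse_red <- sum(qr.resid(qr_red, y)^2)
  df1 <- qr_test$rank - qr_red$rank
  if (df1 == 0L) {
    warning("degenerate term group (df1 = 0): ", paste(group, collapse = ", "))
    return(list(F = NA_real_, df1 = 0L, df2 = df2, p_point = NA_real_,
                dropped = dropped, degenerate = TRUE))
  }
  Fval <- max(0, (sse_red - sse_test) / df1) / (sse_full / df2)
  list(F = Fval, df1 = df1, df2 = df2,
       p_point = stats::pf(Fval, df1, df2, lower.tail = FALSE),
       dropped = dropped, degenerate = FALSE)
}

# --- joint-scan machinery ---------------------------------------------------
# Every candidate group is tested by the Henderson-III reduction in the full
# design: the numerator gain is the squared projection of the response onto
# span(A) minus span(A without the group), the denominator the full-model
# residual mean square.  Projections are pre-computed once, so a permutation
# costs two matrix products.

build_scan_projections <- function(design, groups) {
  y <- design$y
  n <- length(y)
  base <- design$X[, design$base_cols, drop = FALSE]
  qb <- qr(base)
  ytil <- qr.resid(qb, y)          # permutation operates on this vector
  A <- testing_matrix(design)
  qa <- qr(A)
  rank_full <- qa$rank
  QA <- qr.Q(qa)[, seq_len(rank_full), drop = FALSE]
  Qs <- list(); r <- integer(length(groups))
  for (k in seq_along(groups)) {
    cols <- resolve_group(design, groups[[k]], cols_avail = colnames(A))
    kids <- child_block_cols(design, cols)
    test_cols <- setdiff(colnames(A), kids)
    keep <- setdiff(test_cols, cols)
    qm <- qr(A[, keep, drop = FALSE])
    C <- A[, cols, drop = FALSE]
    Ct <- qr.resid(qm, C)
    # a tested column fully spanned by the conditioning set carries no df
    live <- sqrt(colSums(Ct^2)) > 1e-8 * pmax(sqrt(colSums(C^2)), 1)
    Ct <- Ct[, live, drop = FALSE]
    qc <- qr(Ct)
    rk <- if (ncol(Ct)) qc$rank else 0L
    if (rk == 0L) {
      Qs[[k]] <- matrix(0, n, 0L)
    } else {
      Qs[[k]] <- qr.Q(qc)[, seq_len(rk), drop = FALSE]
    }
    r[k] <- rk
  }
  list(Q = do.call(cbind, Qs), gidx = rep(seq_along(groups), r), r = r,
       QA = QA, ytil = ytil, n = n, rank_full = rank_full,
       env = design$env, line = design$line)
}

scan_f_stats <- function(proj, ytil) {
  yss <- sum(ytil^2)
  sse_full <- yss - sum(crossprod(proj$QA, ytil)^2)
  df2 <- proj$n - proj$rank_full
  qty <- crossprod(proj$Q, ytil)          # sum(r) x 1
  gains <- rep(0, length(proj$r))
  if (length(qty)) gains[sort(unique(proj$gidx))] <-
      rowsum(qty^2, proj$gidx)[, 1L]
  Fv <- (gains / proj$r) / (sse_full / df2)
  Fv[proj$r == 0L] <- NA_real_
  list(F = Fv, df1 = proj$r, df2 = rep(df2, length(proj$r)))
}

# permute residualized responses: one line permutation, applied within each
# environment by relative order, so a line's whole phenotype vector moves as
# a unit on balanced data and the within-environment multiset is preserved
permute_within_env <- function(ytil, env, line) {
  lines <- unique(line)
  sigma <- sample(lines)
  out <- ytil
  for (h in unique(env)) {
    ix <- which(env == h)
    present <- line[ix]
    # order present lines by their position in sigma; the induced permutation
    # is the same in every environment with the same line set, so a line's
    # whole phenotype vector moves as one unit on balanced data
    ord <- order(match(present, sigma))
    out[ix] <- ytil[ix][ord]
  }
  out
}

#' Permutation experiment-wise critical F values
#'
#' Shuffles phenotypes across lines within environment (genotypes fixed),
#' records the maximum marginal F over all candidate term groups per
#' permutation, and returns the empirical `(1 - alpha_EW)` quantile of that
#' max-F null as the experiment-wise critical value.  The experiment-wise p
#' of an observed F is the smoothed proportion of permutation maxima at or
#' above it, `(1 + #{max >= F}) / (n_perm + 1)`.  Per-df1 term families also
#' receive their own family-wise critical value.
#'
#' @param design [build_design()] output.
#' @param groups list of term groups (see [henderson3_f()]), one candidate
#'   term per element.
#' @param n_perm number of permutations (>= 100; the reference analysis used
#'   2,000).
#' @param alpha_EW experiment-wise type I error rate.
#' @param seed integer seed; fixed seed gives bit-identical results.
#' @return list with `critical_F` (overall), `family_critical_F` (named by
#'   df1), `max_null` (the permutation maxima), `observed` (data.frame
#'   group, F, df1, df2, p_point, p_EW, passes_EW), `alpha_EW`, `n_perm`.
#' @export
permutation_threshold <- function(design, groups, n_perm = 2000,
                                  alpha_EW = 0.05, seed = 1L) {
  if (n_perm < 100) stop("n_perm too small; use at least 100")
  if (alpha_EW <= 0 || alpha_EW > 1) stop("alpha_EW must be in (0, 1]")
  if (!length(groups)) stop("no candidate groups")
  if (is.null(names(groups))) {
    names(groups) <- vapply(groups, function(g) paste(g, collapse = "+"), "")
  }
  proj <- build_scan_projections(design, groups)
  obs <- scan_f_stats(proj, proj$ytil)
  set.seed(seed)
  ok <- proj$r > 0L
  fam <- proj$r
  maxF <- matrix(NA_real_, n_perm, length(unique(fam[ok])))
  fams <- sort(unique(fam[ok]))
  max_null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    yp <- permute_within_env(proj$ytil, proj$env, proj$line)
    Fp <- scan_f_stats(proj, yp)$F
    max_null[b] <- max(Fp[ok])
    for (j in seq_along(fams)) maxF[b, j] <- max(Fp[ok & fam == fams[j]])
  }
  qidx <- max(1L, ceiling((1 - alpha_EW) * n_perm))
  critical_F <- sort(max_null)[qidx]
  family_critical_F <- apply(maxF, 2L, function(v) sort(v)[qidx])
  names(family_critical_F) <- fams
  p_EW <- vapply(obs$F, function(f) {
    if (is.na(f)) NA_real_ else (1 + sum(max_null >= f)) / (n_perm + 1)
  }, numeric(1))
  observed <- data.frame(group = names(groups), F = obs$F, df1 = obs$df1,
                         df2 = obs$df2,
                         p_point = ifelse(obs$df1 > 0,
                                          stats::pf(obs$F, obs$df1, obs$df2,
                                                    lower.tail = FALSE), NA),
                         p_EW = p_EW,
                         passes_EW = !is.na(obs$F) & obs$F > critical_F,
                         stringsAsFactors = FALSE)
  rownames(observed) <- NULL
  list(critical_F = critical_F, family_critical_F = family_critical_F,
       max_null = max_null, observed = observed,
       alpha_EW = alpha_EW, n_perm = n_perm)
}

#' Scan candidate loci and pairs under the mixed model
#'
#' Tests every candidate's fixed genetic term group marginally (locus: its
#' `a`/`d` columns; pair: its four epistasis columns) against the
#' permutation experiment-wise threshold, then refits the selected terms
#' jointly and prunes backwards: while any selected group's joint-model F
#' falls below the critical value, the weakest (largest p) droppable group is
#' removed and the joint model refit.  Locus groups referenced by a surviving
#' pair are not droppable.
#'
#' @param gm [genotype_matrix()].
#' @param ph [phenotype_table()].
#' @param trait trait name.
#' @param candidates list with `loci` (character) and optional `pairs`
#'   (2-column matrix of marker IDs).
#' @param model `"full"` or `"additive"`.
#' @param n_perm,alpha_EW,seed permutation settings.
#' @param highly_significant_cutoff `-log10 p_EW` above which a term is
#'   flagged highly significant (default 5); capped at `log10(n_perm + 1)`.
#' @return list of class `scan_result`: `results` (per-candidate data.frame
#'   with F, df, p_point, p_EW, neg_log10_p_EW, passes_EW, highly_significant,
#'   selected), `selected` (list loci/pairs), `critical_F`, `threshold`
#'   (the [permutation_threshold()] object).
#' @export
scan_candidates <- function(gm, ph, trait, candidates,
                            model = c("full", "additive"),
                            n_perm = 2000, alpha_EW = 0.05, seed = 1L,
                            highly_significant_cutoff = 5) {
  model <- match.arg(model)
  loci <- candidates$loci
  pairs <- candidates$pairs
  if (is.null(loci) || !length(loci)) stop("no candidate loci")
  if (!is.null(pairs)) {
    pairs <- as.matrix(pairs)
    loci <- union(loci, as.vector(pairs))
  }
  design <- build_design(gm, ph, trait, loci = loci, pairs = pairs, model = model)
  groups <- list()
  gmeta <- list()
  for (m in loci) {
    nm <- paste0("locus:", m)
    groups[[nm]] <- design$registry$column[
      design$registry$kind %in% c("a", "d") & design$registry$marker1 == m &
        is.na(design$registry$block)]
    gmeta[[nm]] <- list(type = "locus", m1 = m, m2 = NA_character_)
  }
  if (!is.null(pairs) && nrow(pairs)) {
    # use canonical order as stored in the design
    for (k in seq_len(nrow(design$pairs))) {
      m1 <- design$pairs[k, 1L]; m2 <- design$pairs[k, 2L]
      nm <- paste0("pair:", m1, ":", m2)
      groups[[nm]] <- design$registry$column[
        design$registry$kind %in% c("aa", "ad", "da", "dd") &
          design$registry$marker1 == m1 & design$registry$marker2 == m2 &
          is.na(design$registry$block)]
      gmeta[[nm]] <- list(type = "pair", m1 = m1, m2 = m2)
    }
  }
  thr <- permutation_threshold(design, groups, n_perm = n_perm,
                               alpha_EW = alpha_EW, seed = seed)
  res <- thr$observed
  cap <- log10(n_perm + 1)
  res$neg_log10_p_EW <- pmin(-log10(res$p_EW), cap)
  res$at_cap <- !is.na(res$p_EW) & (-log10(res$p_EW) >= cap)
  res$highly_significant <- !is.na(res$neg_log10_p_EW) &
    res$neg_log10_p_EW > min(highly_significant_cutoff, cap) & res$passes_EW
  res$selected <- res$passes_EW & res$p_EW < alpha_EW

  # ---- backward pruning in the joint model --------------------------------
  sel <- res$group[res$selected]
  repeat {
    if (!length(sel)) break
    meta <- gmeta[sel]
    sel_loci <- unique(c(
      vapply(meta[vapply(meta, function(x) x$type == "locus", TRUE)],
             function(x) x$m1, ""),
      unlist(lapply(meta[vapply(meta, function(x) x$type == "pair", TRUE)],
                    function(x) c(x$m1, x$m2)))))
    sel_pairs <- do.call(rbind, lapply(
      meta[vapply(meta, function(x) x$type == "pair", TRUE)],
      function(x) c(x$m1, x$m2)))
    jd <- build_design(gm, ph, trait, loci = sel_loci, pairs = sel_pairs,
                       model = model)
    stats_j <- lapply(sel, function(nm) {
      cols <- intersect(groups[[nm]], colnames(jd$X))
      if (!length(cols)) return(list(F = NA_real_, df1 = 0L, p_point = NA_real_))
      suppressWarnings(henderson3_f(jd, cols))
    })
    Fj <- vapply(stats_j, function(s) if (is.null(s$F)) NA_real_ else s$F, 0)
    pj <- vapply(stats_j, function(s) if (is.null(s$p_point)) NA_real_ else s$p_point, 0)
    fail <- is.na(Fj) | Fj <= thr$critical_F
    # pair-protected loci are not droppable
    pair_members <- unlist(lapply(meta[vapply(meta, function(x) x$type == "pair", TRUE)],
                                  function(x) c(x$m1, x$m2)))
    droppable <- vapply(seq_along(sel), function(i) {
      m <- gmeta[[sel[i]]]
      !(m$type == "locus" && m$m1 %in% pair_members)
    }, TRUE)
    cand_drop <- which(fail & droppable)
    if (!length(cand_drop)) break
    # weakest first: largest p (NA treated as worst), ties by position
    pj_drop <- pj[cand_drop]
    pj_drop[is.na(pj_drop)] <- Inf
    drop_i <- cand_drop[which.max(pj_drop)]
    sel <- sel[-drop_i]
  }
  res$selected <- res$group %in% sel
  meta_sel <- gmeta[sel]
  sel_pairs <- do.call(rbind, lapply(
    meta_sel[vapply(meta_sel, function(x) x$type == "pair", TRUE)],
    function(x) c(x$m1, x$m2)))
  sel_loci <- unique(c(
    vapply(meta_sel[vapply(meta_sel, function(x) x$type == "locus", TRUE)],
           function(x) x$m1, ""),
    as.vector(sel_pairs)))
  structure(list(results = res,
                 selected = list(loci = sel_loci, pairs = sel_pairs),
                 critical_F = thr$critical_F, threshold = thr,
                 design = design, model = model),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("scan_result: %d candidates, %d selected (critical F = %.3f)\n",
              nrow(x$results), sum(x$results$selected), x$critical_F))
  invisible(x)
}
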