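rinvgamma1 <- function(shape, scale) 1 / stats::rgamma(1L, shape = shape, rate = scale)

#' Gibbs sampler for the full-model mixed linear model
#'
#' Normal--inverse-gamma Gibbs cycle over the fixed genetic effects (flat
#' prior), the random genotype-by-environment effect levels (one variance
#' component per term), and the variances (weakly-informative
#' inverse-gamma(0.001, 0.001) priors).  All conditional draws work from
#' cached cross-products, so iteration cost is independent of the number of
#' observations.
#'
#' @param design [build_design()] output.
#' @param n_iter total Gibbs iterations (reference analysis: 20,000).
#' @param burn_in iterations discarded (default 2,000).
#' @param thin thinning interval (default 5).
#' @param seed integer seed.
#' @return object of class `gibbs_fit`: posterior draw matrices (`beta`,
#'   `u`, `sigma2`, `sigma2_e`), posterior summaries (`coef` data.frame with
#'   mean/sd per column, joined to the design registry), `rhat` split-chain
#'   diagnostic for the residual variance, and the `design` registry.
#' @export
gibbs_fit <- function(design, n_iter = 20000, burn_in = 2000, thin = 5,
                      seed = 1L) {
  stopifnot(n_iter > burn_in, thin >= 1)
  y <- design$y
  n <- length(y)
  X <- design$X
  Zs <- design$Z
  set.seed(seed)

  # drop collinear / empty fixed columns (e.g. an epistasis coefficient with
  # no informative observations) and random blocks with no support
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- sort(qx$pivot[seq_len(qx$rank)])
    dropped <- colnames(X)[-keep]
    warning("dropping rank-deficient fixed column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
    design$X <- X
  }
  if (length(Zs)) {
    live <- vapply(Zs, function(b) sum(b^2) > 0, TRUE)
    if (!all(live)) {
      Zs <- Zs[live]
      design$Z <- Zs
    }
  }

  W <- design_matrix_all(design)
  P <- ncol(W)
  p <- ncol(X)
  C <- crossprod(W)
  cy <- drop(crossprod(W, y))
  yss <- sum(y^2)
  vy <- stats::var(y)
  if (!is.finite(vy)) vy <- 1

  ix <- seq_len(p)
  iu <- vector("list", length(Zs))
  off <- p
  for (t in seq_along(Zs)) {
    q <- ncol(Zs[[t]])
    iu[[t]] <- off + seq_len(q)
    off <- off + q
  }
  names(iu) <- names(Zs)

  # parent fixed column of each random block ("ae:S1_1" -> "a:S1_1"): the
  # block's slices sum to that column, so the mean of the block's levels is
  # swept into the parent each iteration (sum-to-zero identification of the
  # interaction deviations; a likelihood-invariant reparameterization)
  r2f <- c(ae = "a", de = "d", aae = "aa", ade = "ad", dae = "da", dde = "dd")
  parent <- integer(length(Zs))
  for (t in seq_along(Zs)) {
    bn <- names(Zs)[t]
    pk <- r2f[[sub(":.*$", "", bn)]]
    pcol <- sub("^[a-z]+:", paste0(pk, ":"), bn)
    parent[t] <- match(pcol, colnames(X))
  }

  Cxx <- C[ix, ix, drop = FALSE]
  # fixed-block Cholesky; drop collinear columns if necessary
  eg <- eigen(Cxx, symmetric = TRUE, only.values = TRUE)$values
  if (min(eg) < max(eg) * 1e-10) {
    stop("fixed block is rank deficient after pruning; remove collinear terms")
  }
  Rxx <- chol(Cxx)

  a0 <- 0.001; b0 <- 0.001
  theta <- numeric(P)
  sig2 <- rep(vy / 4, length(Zs))
  sig2e <- max(vy / 2, 1e-8)

  n_keep <- floor((n_iter - burn_in) / thin)
  beta_draws <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, colnames(X)))
  u_draws <- if (P > p) matrix(NA_real_, n_keep, P - p,
                               dimnames = list(NULL, colnames(W)[-ix])) else NULL
  sig2_draws <- if (length(Zs)) matrix(NA_real_, n_keep, length(Zs),
                                       dimnames = list(NULL, names(Zs))) else NULL
  sig2e_draws <- numeric(n_keep)
  kept <- 0L

  diag_idx <- lapply(iu, function(ii) diag(C)[ii])
  guard <- vy * 1e12 + 1e6

  for (it in seq_len(n_iter)) {
    # fixed effects | rest
    resid_cross <- cy[ix] - C[ix, -ix, drop = FALSE] %*% theta[-ix]
    if (P == p) resid_cross <- cy[ix]
    mean_b <- backsolve(Rxx, forwardsolve(t(Rxx), resid_cross))
    theta[ix] <- drop(mean_b) + sqrt(sig2e) *
      backsolve(Rxx, stats::rnorm(p))
    # random blocks | rest (block crossproducts are diagonal: env slices)
    for (t in seq_along(Zs)) {
      ii <- iu[[t]]
      r <- cy[ii] - drop(C[ii, , drop = FALSE] %*% theta) + diag_idx[[t]] * theta[ii]
      prec <- diag_idx[[t]] / sig2e + 1 / sig2[t]
      mu_u <- (r / sig2e) / prec
      theta[ii] <- mu_u + stats::rnorm(length(ii)) / sqrt(prec)
      if (!is.na(parent[t])) {             # sweep block mean into parent
        mt <- mean(theta[ii])
        theta[parent[t]] <- theta[parent[t]] + mt
        theta[ii] <- theta[ii] - mt
      }
      sig2[t] <- rinvgamma1(a0 + length(ii) / 2, b0 + sum(theta[ii]^2) / 2)
    }
    sse <- yss - 2 * sum(theta * cy) + drop(crossprod(theta, C %*% theta))
    sse <- max(sse, 1e-12)
    sig2e <- rinvgamma1(a0 + n / 2, b0 + sse / 2)
    if (!is.finite(sig2e) || sig2e > guard || any(!is.finite(sig2)) ||
        (length(sig2) && max(sig2) > guard)) {
      stop(sprintf("Gibbs sampler diverged at iteration %d (sigma2_e = %.3g)",
                   it, sig2e))
    }
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      beta_draws[kept, ] <- theta[ix]
      if (!is.null(u_draws)) u_draws[kept, ] <- theta[-ix]
      if (!is.null(sig2_draws)) sig2_draws[kept, ] <- sig2
      sig2e_draws[kept] <- sig2e
    }
  }

  # split-chain Rhat on log residual variance
  half <- floor(n_keep / 2)
  rhat <- NA_real_
  if (half >= 10L) {
    c1 <- log(sig2e_draws[seq_len(half)])
    c2 <- log(sig2e_draws[(n_keep - half + 1L):n_keep])
    m <- c(mean(c1), mean(c2)); v <- c(stats::var(c1), stats::var(c2))
    Wv <- mean(v); Bv <- half * stats::var(m)
    rhat <- if (Wv > 0) sqrt(((half - 1) / half * Wv + Bv / half) / Wv) else 1
  }

  allcols <- colnames(W)
  means <- c(colMeans(beta_draws), if (!is.null(u_draws)) colMeans(u_draws))
  sds <- c(apply(beta_draws, 2L, stats::sd),
           if (!is.null(u_draws)) apply(u_draws, 2L, stats::sd))
  coef <- data.frame(column = allcols, mean = unname(means), sd = unname(sds),
                     stringsAsFactors = FALSE)
  coef <- merge(coef, design$registry, by = "column", all.x = TRUE, sort = FALSE)
  coef <- coef[match(allcols, coef$column), ]
  rownames(coef) <- NULL

  structure(list(beta = beta_draws, u = u_draws, sigma2 = sig2_draws,
                 sigma2_e = sig2e_draws, coef = coef, rhat = rhat,
                 converged = is.na(rhat) || rhat < 1.1,
                 n_iter = n_iter, burn_in = burn_in, thin = thin),
            class = "gibbs_fit")
}

#' @export
print.gibbs_fit <- function(x, ...) {
  cat(sprintf("gibbs_fit: %d kept draws (%d iterations, burn-in %d, thin %d), Rhat(sigma2_e) = %.3f\n",
              nrow(x$beta), x$n_iter, x$burn_in, x$thin, x$rhat))
  invisible(x)
}

#' Posterior credible intervals for fixed genetic effects
#' @param fit [gibbs_fit()] output.
#' @param level credible level (default 0.95).
#' @return data.frame column, mean, lower, upper.
#' @export
credible_intervals <- function(fit, level = 0.95) {
  a <- (1 - level) / 2
  qs <- apply(fit$beta, 2L, stats::quantile, probs = c(a, 1 - a))
  data.frame(column = colnames(fit$beta), mean = colMeans(fit$beta),
             lower = qs[1L, ], upper = qs[2L, ], row.names = NULL,
             stringsAsFactors = FALSE)
}

H2_COMPONENTS <- c(A = "a", D = "d", AA = "aa", AD = "ad", DA = "da", DD = "dd",
                   AE = "ae", DE = "de", AAE = "aae", ADE = "ade", DAE = "dae",
                   DDE = "dde")
H2_DOMINANCE <- c("D", "AD", "DA", "DD", "DE", "ADE", "DAE", "DDE")

#' Construct a heritability partition
#'
#' @param components named numeric vector of percent heritabilities; names
#'   among `A, D, AA, AD, DA, DD, AE, DE, AAE, ADE, DAE, DDE` (absent
#'   components count as 0).  Optional attributes `Aplus`/`Aminus` carry the
#'   signed additive split.
#' @return object of class `heritability_partition`.
#' @export
heritability_partition <- function(components) {
  bad <- setdiff(names(components), names(H2_COMPONENTS))
  if (length(bad)) stop("unknown heritability component(s): ",
                        paste(bad, collapse = ", "))
  if (any(components < 0)) stop("heritability components must be >= 0")
  full <- stats::setNames(numeric(length(H2_COMPONENTS)), names(H2_COMPONENTS))
  full[names(components)] <- components
  structure(as.list(full), class = "heritability_partition")
}

#' Aggregate a heritability partition into its totals
#'
#' `h2_T` is the sum of every component; `h2_Dplus` the sum of the
#' dominance-related components (`D`, `AD`, `DA`, `DD`, `DE` plus the
#' dominance-related environment-interaction kinds when present).
#'
#' @param p [heritability_partition()].
#' @return named numeric vector `c(h2_T, h2_Dplus)`.
#' @export
aggregate_heritability <- function(p) {
  stopifnot(inherits(p, "heritability_partition"))
  v <- unlist(p[names(H2_COMPONENTS)])
  c(h2_T = unname(sum(v)), h2_Dplus = unname(sum(v[H2_DOMINANCE])))
}

#' @export
print.heritability_partition <- function(x, ...) {
  v <- unlist(x[names(H2_COMPONENTS)])
  agg <- aggregate_heritability(x)
  cat("heritability partition (%):\n")
  print(round(v[v > 0 | names(v) %in% c("A", "D")], 2))
  cat(sprintf("h2_T = %.2f, h2_D+ = %.2f\n", agg["h2_T"], agg["h2_Dplus"]))
  invisible(x)
}

#' Partition phenotypic variance into heritability components
#'
#' For each effect kind the fitted contribution over the observations is
#' computed (posterior-mean effects times design coefficients; per-environment
#' interaction kinds use the predicted random-effect levels), and the
#' component heritability is `100 * Var(contribution) / Var(y)`.
#'
#' @param fit a [gibbs_fit()] object, or a named numeric vector of
#'   coefficients covering the design columns (e.g. least-squares estimates).
#' @param design the [build_design()] object the fit used.
#' @return [heritability_partition()] with attributes `Aplus`/`Aminus`
#'   (signed additive split) and `pve` (per-term percent variance explained).
#' @export
partition_heritability <- function(fit, design) {
  y <- design$y
  vy <- stats::var(y)
  if (vy <= 0) stop("zero phenotypic variance")
  W <- design_matrix_all(design)
  if (inherits(fit, "gibbs_fit")) {
    coefs <- stats::setNames(fit$coef$mean, fit$coef$column)
  } else {
    coefs <- fit
  }
  coefs <- coefs[colnames(W)]
  names(coefs) <- colnames(W)   # terms absent from the fit contribute zero
  coefs[is.na(coefs)] <- 0
  reg <- design$registry
  comp <- stats::setNames(numeric(length(H2_COMPONENTS)), names(H2_COMPONENTS))
  pve <- list()
  for (k in seq_along(H2_COMPONENTS)) {
    kind <- H2_COMPONENTS[[k]]
    cols <- reg$column[!is.na(reg$kind) & reg$kind == kind]
    cols <- intersect(cols, colnames(W))
    if (!length(cols)) next
    contrib <- W[, cols, drop = FALSE] %*% coefs[cols]
    comp[k] <- 100 * stats::var(drop(contrib)) / vy
    # per-term percent variance explained, grouped by marker(s)
    sub <- reg[reg$column %in% cols, , drop = FALSE]
    key <- paste(sub$kind, sub$marker1, sub$marker2)
    for (g in unique(key)) {
      cg <- sub$column[key == g]
      cv <- drop(W[, cg, drop = FALSE] %*% coefs[cg])
      pve[[length(pve) + 1L]] <- data.frame(
        kind = sub$kind[key == g][1L], marker1 = sub$marker1[key == g][1L],
        marker2 = sub$marker2[key == g][1L],
        pve_pct = 100 * stats::var(cv) / vy, stringsAsFactors = FALSE)
    }
  }
  p <- heritability_partition(comp)
  # signed additive split
  acols <- reg$column[!is.na(reg$kind) & reg$kind == "a"]
  acols <- intersect(acols, colnames(W))
  if (length(acols)) {
    av <- coefs[acols]
    pos <- acols[av > 0]; neg <- acols[av < 0]
    attr(p, "Aplus") <- if (length(pos))
      100 * stats::var(drop(W[, pos, drop = FALSE] %*% coefs[pos])) / vy else 0
    attr(p, "Aminus") <- if (length(neg))
      100 * stats::var(drop(W[, neg, drop = FALSE] %*% coefs[neg])) / vy else 0
  }
  attr(p, "pve") <- if (length(pve)) do.call(rbind, pve) else NULL
  p
}

#' Heritability-table row for one trait
#'
#' Collapses a partition into the standard reporting layout: nine component
#' columns (the three dominance-related environment-interaction kinds are
#' folded into `hDE2`'s family by convention only when reported separately —
#' here they appear in `hT2`/`hDp2` through the aggregation identity).
#'
#' @param trait trait name.
#' @param p [heritability_partition()].
#' @return one-row data.frame in the heritability-table layout.
#' @export
heritability_row <- function(trait, p) {
  agg <- aggregate_heritability(p)
  data.frame(trait = trait,
             hA2 = p$A, hD2 = p$D, hAA2 = p$AA, hAD2 = p$AD, hDA2 = p$DA,
             hDD2 = p$DD, hAE2 = p$AE,
             hDE2 = p$DE + p$ADE + p$DAE + p$DDE, hAAE2 = p$AAE,
             hT2 = unname(agg["h2_T"]), hDp2 = unname(agg["h2_Dplus"]),
             stringsAsFactors = FALSE)
}

#' Effects table from a fitted model
#'
#' @param fit [gibbs_fit()] object.
#' @param design the design it was fitted on.
#' @param scan optional `scan_result` supplying experiment-wise p-values per
#'   candidate group (attached to each of the group's terms).
#' @return data.frame in effects-table layout, plus a `posterior_tail_p`
#'   column (twice the smaller posterior tail mass of the draws) labeled
#'   distinctly from the permutation `neg_log10_p_ew`; the extra column is
#'   not part of the on-disk effects-table schema.
#' @export
effects_from_fit <- function(fit, design, scan = NULL) {
  p <- partition_heritability(fit, design)
  pve <- attr(p, "pve")
  co <- fit$coef
  gen <- co[!is.na(co$kind), , drop = FALSE]
  gen <- gen[!(gen$column %in% design$base_cols), , drop = FALSE]
  # posterior tail probability (2 x min tail mass of the draws), reported
  # separately from the permutation experiment-wise p
  draws <- cbind(fit$beta, fit$u)
  tailp <- vapply(gen$column, function(cl) {
    if (!cl %in% colnames(draws)) return(NA_real_)
    v <- draws[, cl]
    2 * min(mean(v > 0), mean(v < 0))
  }, numeric(1))
  eff <- data.frame(qts1 = gen$marker1, qts2 = gen$marker2, kind = gen$kind,
                    env = gen$env, estimate = gen$mean, se = gen$sd,
                    neg_log10_p_ew = NA_real_, pve_pct = NA_real_,
                    stringsAsFactors = FALSE)
  eff$posterior_tail_p <- unname(tailp)
  if (!is.null(pve)) {
    key <- paste(eff$kind, eff$qts1, eff$qts2)
    pk <- paste(pve$kind, pve$marker1, pve$marker2)
    eff$pve_pct <- pve$pve_pct[match(key, pk)]
  }
  if (!is.null(scan)) {
    res <- scan$results
    for (i in seq_len(nrow(eff))) {
      g <- if (eff$kind[i] %in% c("a", "d", "ae", "de")) {
        paste0("locus:", eff$qts1[i])
      } else {
        paste0("pair:", eff$qts1[i], ":", eff$qts2[i])
      }
      j <- match(g, res$group)
      if (!is.na(j)) eff$neg_log10_p_ew[i] <- res$neg_log10_p_EW[j]
    }
  }
  eff
}
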