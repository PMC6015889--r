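arch_markers <- function(arch) {
  unique(c(arch$loci$marker, arch$pairs$marker1, arch$pairs$marker2,
           arch$env_loci$marker, arch$env_pairs$marker1, arch$env_pairs$marker2))
}

arch_envs <- function(arch) {
  sort(unique(c(arch$env_loci$env, arch$env_pairs$env)))
}

#' Total genotypic value of a genotype assignment
#'
#' `G = sum a_i xA(g_i) + sum d_i xD(g_i) + pair terms`, with the products of
#' the single-locus codings as epistasis coefficients.  With `env = h` the
#' environment-h interaction effects are added using the same coefficients
#' (`G + GE_h`).  The population mean is never folded in.
#'
#' @param assignment named character vector marker -> genotype code, covering
#'   every marker in the architecture.
#' @param arch [genetic_architecture()].
#' @param env `NULL` for the overall value, or an environment index.
#' @return numeric scalar.
#' @export
total_genotypic_value <- function(assignment, arch, env = NULL) {
  need <- arch_markers(arch)
  miss <- setdiff(need, names(assignment))
  if (length(miss)) stop("assignment missing locus/loci: ",
                         paste(miss, collapse = ", "))
  if (!length(need)) return(0)
  calls <- matrix(assignment[need], 1L, length(need),
                  dimnames = list("plan", need))
  arch_contribution(calls, arch, env = env)[[1L]]
}

new_genotype_plan <- function(assignment, arch, provenance, direction,
                              line = NA_character_) {
  envs <- arch_envs(arch)
  G <- total_genotypic_value(assignment, arch)
  G_env <- vapply(envs, function(h) total_genotypic_value(assignment, arch, h),
                  numeric(1))
  names(G_env) <- paste0("G_GE", envs, recycle0 = TRUE)
  structure(list(assignment = assignment, G = G, G_env = G_env,
                 provenance = provenance, direction = direction, line = line),
            class = "genotype_plan")
}

#' @export
print.genotype_plan <- function(x, ...) {
  cat(sprintf("genotype_plan [%s, direction %s]: G = %.4g", x$provenance,
              x$direction, x$G))
  if (!is.na(x$line)) cat(sprintf(" (line %s)", x$line))
  cat("\n")
  if (length(x$G_env)) print(round(x$G_env, 4))
  invisible(x)
}

#' Best observed line by total genotypic value
#'
#' Evaluates every line's genotypes at the architecture's loci (missing
#' calls contribute through the heterozygote coding) and returns the
#' arg-extremum of the overall total genotypic value; per-environment best
#' lines are recorded in the `per_env` attribute.
#'
#' @param gm [genotype_matrix()].
#' @param arch [genetic_architecture()].
#' @param direction `"+"` (maximize) or `"-"` (minimize).
#' @return `genotype_plan` with provenance `best_line`.
#' @export
best_line <- function(gm, arch, direction = c("+", "-")) {
  direction <- match.arg(direction)
  stopifnot(inherits(gm, "genotype_matrix"))
  need <- arch_markers(arch)
  miss <- setdiff(need, colnames(gm$calls))
  if (length(miss)) stop("architecture loci absent from genotype matrix: ",
                         paste(miss, collapse = ", "))
  if (nrow(gm$calls) == 0L) stop("no lines")
  calls <- gm$calls[, need, drop = FALSE]
  G <- arch_contribution(calls, arch, env = NULL)
  pick <- function(v) {
    opt <- if (direction == "+") max(v) else min(v)
    cand <- rownames(calls)[v == opt]
    sort(cand)[1L]                       # ties -> lexicographically first line
  }
  bl <- pick(G)
  envs <- arch_envs(arch)
  per_env <- character(0)
  if (length(envs)) {
    per_env <- vapply(envs, function(h) {
      pick(arch_contribution(calls, arch, env = h))
    }, "")
    names(per_env) <- paste0("env", envs)
  }
  plan <- new_genotype_plan(stats::setNames(calls[bl, ], need), arch,
                            "best_line", direction, line = bl)
  attr(plan, "per_env") <- per_env
  plan
}

#' Connected components of the epistasis pair graph
#'
#' Loci joined by any (general or environment-specific) epistatic pair form
#' a component; loci in no pair are singletons.  Component-wise optimization
#' is exact because the total genotypic value is additive across components.
#'
#' @param arch [genetic_architecture()].
#' @return list of components, each a list with `markers` and `pairs`
#'   (2-column matrix).
#' @export
epistasis_components <- function(arch) {
  markers <- arch_markers(arch)
  if (!length(markers)) return(list())
  pairs <- unique(rbind(as.matrix(arch$pairs[c("marker1", "marker2")]),
                        as.matrix(arch$env_pairs[c("marker1", "marker2")])))
  # union-find
  parent <- stats::setNames(seq_along(markers), markers)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      i <- find(match(pairs[k, 1L], markers))
      j <- find(match(pairs[k, 2L], markers))
      if (i != j) parent[j] <- i
    }
  }
  root <- vapply(seq_along(markers), find, 0L)
  comps <- split(markers, root)
  lapply(unname(comps), function(ms) {
    keep <- pairs[, 1L] %in% ms & pairs[, 2L] %in% ms
    list(markers = ms, pairs = pairs[keep, , drop = FALSE])
  })
}

# enumerate genotype assignments for one component and return the optimum;
# genotype preference order qq < Qq < QQ (ties resolved toward earlier
# codes at the later loci first through lexicographic enumeration order)
optimize_component <- function(markers, arch, direction, codes,
                               chunk = 200000L) {
  k <- length(markers)
  n_total <- length(codes)^k
  best_val <- if (direction == "+") -Inf else Inf
  best_row <- NULL
  sub <- sub_architecture(arch, markers)
  idx0 <- 0
  while (idx0 < n_total) {
    m <- min(chunk, n_total - idx0)
    ids <- idx0 + seq_len(m) - 1
    # mixed-radix digits, most-significant digit = first marker
    digs <- matrix(0L, m, k)
    rem <- ids
    for (j in k:1) {
      digs[, j] <- rem %% length(codes)
      rem <- rem %/% length(codes)
    }
    calls <- matrix(codes[digs + 1L], m, k,
                    dimnames = list(NULL, markers))
    vals <- arch_contribution(calls, sub, env = NULL)
    opt_i <- if (direction == "+") which.max(vals) else which.min(vals)
    better <- if (direction == "+") vals[opt_i] > best_val else vals[opt_i] < best_val
    if (better) {
      best_val <- vals[opt_i]
      best_row <- calls[opt_i, , drop = TRUE]
    }
    idx0 <- idx0 + m
  }
  list(value = best_val, assignment = stats::setNames(as.character(best_row), markers))
}

sub_architecture <- function(arch, markers) {
  genetic_architecture(
    mu = 0,
    loci = arch$loci[arch$loci$marker %in% markers, , drop = FALSE],
    pairs = arch$pairs[arch$pairs$marker1 %in% markers &
                         arch$pairs$marker2 %in% markers, , drop = FALSE],
    env_loci = empty_env_loci(), env_pairs = empty_env_pairs(),
    residual_sd = arch$residual_sd)
}

#' Optimal genotype plans: superior line and superior hybrid
#'
#' Exact optimization of the total genotypic value over genotype
#' assignments, by exhaustive enumeration within each connected component of
#' the epistasis graph (the value is additive across components).
#' `allowed = "homozygous_only"` searches `{QQ, qq}^k` and yields the
#' superior line; `allowed = "any"` also admits heterozygotes and yields the
#' superior hybrid.  Ties break toward the B73 homozygote `qq`, then by
#' marker order.
#'
#' @param arch [genetic_architecture()].
#' @param direction `"+"` or `"-"`.
#' @param allowed `"homozygous_only"` or `"any"`.
#' @param cap maximum component size enumerated exactly (default 16); a
#'   larger component raises an error suggesting a higher cap.
#' @return `genotype_plan` with provenance `superior_line` or
#'   `superior_hybrid`.
#' @export
superior_plan <- function(arch, direction = c("+", "-"),
                          allowed = c("homozygous_only", "any"), cap = 16) {
  direction <- match.arg(direction)
  allowed <- match.arg(allowed)
  codes <- if (allowed == "homozygous_only") c("qq", "QQ") else c("qq", "Qq", "QQ")
  comps <- epistasis_components(arch)
  assignment <- character(0)
  for (cp in comps) {
    if (length(cp$markers) > cap) {
      stop(sprintf("epistasis component with %d loci exceeds enumeration cap %d; raise `cap`",
                   length(cp$markers), cap))
    }
    opt <- optimize_component(cp$markers, arch, direction, codes)
    assignment <- c(assignment, opt$assignment)
  }
  need <- arch_markers(arch)
  assignment <- assignment[need]
  names(assignment) <- need
  new_genotype_plan(assignment, arch,
                    if (allowed == "homozygous_only") "superior_line" else "superior_hybrid",
                    direction)
}

#' Prediction report in the standard genotypic-value layout
#'
#' Rows for the fixed patterns all-`QQ`, all-`qq`, all-`Qq` (F1) plus the
#' best line, superior line and superior hybrid; columns for the overall `G`
#' and the per-environment `G + GE_h`.  The population mean is reported as
#' an attribute, never folded into the values.  The `sh_vs_sl` attribute
#' lists the loci whose genotypes differ between superior hybrid and
#' superior line.
#'
#' @param plans named list with elements `best_line`, `superior_line`,
#'   `superior_hybrid` ([best_line()] / [superior_plan()] outputs).
#' @param arch [genetic_architecture()].
#' @param E number of environments reported (defaults to those present in
#'   the architecture).
#' @return data.frame with columns `entry`, `G`, `G_GE1` ... `G_GE{E}`.
#' @export
plan_report <- function(plans, arch, E = NULL) {
  envs <- arch_envs(arch)
  if (is.null(E)) E <- if (length(envs)) max(envs) else 0L
  envs <- seq_len(E)
  need <- arch_markers(arch)
  fixed_row <- function(code, label) {
    asg <- stats::setNames(rep(code, length(need)), need)
    g <- total_genotypic_value(asg, arch)
    ge <- vapply(envs, function(h) total_genotypic_value(asg, arch, h), numeric(1))
    stats::setNames(data.frame(label, g, t(ge), stringsAsFactors = FALSE),
                    c("entry", "G", paste0("G_GE", envs)))
  }
  plan_row <- function(plan, label) {
    ge <- vapply(envs, function(h) total_genotypic_value(plan$assignment, arch, h),
                 numeric(1))
    stats::setNames(data.frame(label, plan$G, t(ge), stringsAsFactors = FALSE),
                    c("entry", "G", paste0("G_GE", envs)))
  }
  out <- rbind(fixed_row("QQ", "QQ"), fixed_row("qq", "qq"), fixed_row("Qq", "F1"),
               plan_row(plans$best_line, "Best line"),
               plan_row(plans$superior_line, "Superior line"),
               plan_row(plans$superior_hybrid, "Superior hybrid"))
  rownames(out) <- NULL
  attr(out, "mu") <- arch$mu
  sl <- plans$superior_line$assignment; sh <- plans$superior_hybrid$assignment
  bl <- plans$best_line$assignment
  diff_loci <- need[sh[need] != sl[need]]
  attr(out, "sh_vs_sl") <- data.frame(marker = diff_loci,
                                      best_line = bl[diff_loci],
                                      superior_line = sl[diff_loci],
                                      superior_hybrid = sh[diff_loci],
                                      row.names = NULL, stringsAsFactors = FALSE)
  out
}
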