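# Small in-code fixtures shared across test files.

toy_calls <- function(n = 30, M = 6, seed = 1,
                      codes = c("QQ", "Qq", "qq"), n_chrom = 2) {
  set.seed(seed)
  map <- default_map(M, n_chrom = n_chrom)
  calls <- matrix(sample(codes, n * M, replace = TRUE), n, M,
                  dimnames = list(sprintf("Z%03dE%04d", rep(1:3, length.out = n),
                                          seq_len(n)),
                                  map$id))
  calls
}

toy_gm <- function(n = 30, M = 6, seed = 1, codes = c("QQ", "Qq", "qq")) {
  genotype_matrix(toy_calls(n, M, seed, codes))
}

toy_ph <- function(gm, E = 2, seed = 2, trait = "t",
                   values = NULL) {
  n <- nrow(gm$calls)
  set.seed(seed)
  df <- data.frame(line = rep(rownames(gm$calls), E),
                   env = rep(seq_len(E), each = n), trait = trait,
                   value = if (is.null(values)) stats::rnorm(n * E) else values,
                   stringsAsFactors = FALSE)
  phenotype_table(df, gm)
}

# fixed-effects-only design (random blocks stripped), for OLS oracles
fixed_only <- function(design) { design$Z <- list(); design }

# independent brute-force evaluator of a genotype assignment's total value:
# explicit coefficient lookups, no shared code with the package's evaluator
flat_value <- function(assignment, arch) {
  xa <- c(QQ = 1, Qq = 0, qq = -1)[assignment]
  xd <- c(QQ = 0, Qq = 1, qq = 0)[assignment]
  names(xa) <- names(xd) <- names(assignment)
  v <- 0
  for (k in seq_len(nrow(arch$loci))) {
    m <- arch$loci$marker[k]
    v <- v + arch$loci$a[k] * xa[[m]] + arch$loci$d[k] * xd[[m]]
  }
  for (k in seq_len(nrow(arch$pairs))) {
    p <- arch$pairs[k, ]
    v <- v + p$aa * xa[[p$marker1]] * xa[[p$marker2]] +
      p$ad * xa[[p$marker1]] * xd[[p$marker2]] +
      p$da * xd[[p$marker1]] * xa[[p$marker2]] +
      p$dd * xd[[p$marker1]] * xd[[p$marker2]]
  }
  v
}

# exhaustive optimum over all assignments (oracle for superior_plan)
flat_optimum <- function(arch, direction, codes) {
  need <- unique(c(arch$loci$marker, arch$pairs$marker1, arch$pairs$marker2))
  grid <- expand.grid(rep(list(codes), length(need)), stringsAsFactors = FALSE)
  names(grid) <- need
  vals <- vapply(seq_len(nrow(grid)), function(i) {
    flat_value(stats::setNames(as.character(grid[i, ]), need), arch)
  }, numeric(1))
  if (direction == "+") max(vals) else min(vals)
}

random_architecture <- function(n_loci = 6, n_pairs = 3, seed = 1,
                                with_dominance = TRUE) {
  set.seed(seed)
  mk <- marker_id(1, seq_len(n_loci) * 100)
  loci <- data.frame(marker = mk, a = stats::rnorm(n_loci),
                     d = if (with_dominance) stats::rnorm(n_loci) else 0)
  pairs <- NULL
  if (n_pairs > 0) {
    pr <- t(utils::combn(mk, 2))
    pr <- pr[sample(nrow(pr), n_pairs), , drop = FALSE]
    pairs <- data.frame(marker1 = pr[, 1], marker2 = pr[, 2],
                        aa = stats::rnorm(n_pairs), ad = stats::rnorm(n_pairs),
                        da = stats::rnorm(n_pairs), dd = stats::rnorm(n_pairs))
  }
  genetic_architecture(mu = 0, loci = loci,
                       pairs = if (is.null(pairs))
                         data.frame(marker1 = character(), marker2 = character(),
                                    aa = numeric(), ad = numeric(),
                                    da = numeric(), dd = numeric()) else pairs)
}
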