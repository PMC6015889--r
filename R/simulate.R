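#' Evenly spaced genetic map
#'
#' @param n_markers total marker count, split as evenly as possible across
#'   chromosomes.
#' @param n_chrom number of chromosomes (default 10, the maize karyotype).
#' @param length_cM map length per chromosome in centimorgans.
#' @return data.frame with columns `chrom`, `cM`, `id` (marker IDs encode the
#'   map position).
#' @export
default_map <- function(n_markers, n_chrom = 10, length_cM = 150) {
  stopifnot(n_markers >= 1, n_chrom >= 1)
  chrom <- rep(seq_len(n_chrom), length.out = n_markers)
  chrom <- sort(chrom)
  map <- do.call(rbind, lapply(split(seq_along(chrom), chrom), function(ix) {
    k <- length(ix)
    data.frame(chrom = chrom[ix], cM = seq(0, length_cM, length.out = max(k, 2L))[seq_len(k)])
  }))
  rownames(map) <- NULL
  map$id <- marker_id(map$chrom, round(map$cM * 1e5) + 1)
  map
}

validate_map <- function(map) {
  if (is.null(map) || nrow(map) == 0L) stop("empty genetic map")
  if (!all(c("chrom", "cM", "id") %in% names(map))) {
    stop("map needs columns chrom, cM, id")
  }
  for (ch in unique(map$chrom)) {
    cm <- map$cM[map$chrom == ch]
    if (any(diff(cm) <= 0)) stop("non-increasing cM positions on chromosome ", ch)
  }
  map
}

#' Simulation configuration for a synthetic NAM population
#'
#' Defaults emulate the maize NAM design: 25 biparental families obtained by
#' crossing diverse founders to a common parent (B73) and self-pollinating
#' for five generations, phenotyped in 4 environments, with 23% missing
#' genotype calls.
#'
#' @param n_families number of founder families (default 25).
#' @param lines_per_family RILs per family (default 196, ~4,900 lines total).
#' @param map genetic map as from [default_map()]; created from `n_markers`
#'   when omitted.
#' @param n_markers marker count used when `map` is `NULL`.
#' @param selfing_generations number of selfing generations after the F1
#'   (default 5; residual per-locus heterozygosity is then (1/2)^5 ~ 3.1%).
#' @param missing_rate fraction of calls masked to MISSING (default 0.23).
#' @param missing_mode `"MCAR"` (uniform) or `"het_biased"` (heterozygous
#'   calls masked preferentially with odds `het_odds`).
#' @param het_odds odds multiplier for masking heterozygotes under
#'   `het_biased`; `Inf` masks all heterozygotes first.
#' @param environments number of environments E (default 4).
#' @param architecture [genetic_architecture()] used as the phenotype truth.
#' @param env_sd standard deviation of the environment main effects (drawn
#'   once per environment).
#' @param env_effects optional fixed vector of E environment main effects
#'   (overrides `env_sd`).
#' @param polymorphic_frac fraction of markers polymorphic between each
#'   founder and B73 (default 0.5).
#' @param trait trait name stamped on simulated phenotypes.
#' @param seed integer seed; same seed gives bit-identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_families = 25, lines_per_family = 196,
                       map = NULL, n_markers = 100,
                       selfing_generations = 5,
                       missing_rate = 0.23,
                       missing_mode = c("MCAR", "het_biased"),
                       het_odds = 5,
                       environments = 4,
                       architecture = genetic_architecture(),
                       env_sd = 1, env_effects = NULL,
                       polymorphic_frac = 0.5,
                       trait = "trait", seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  if (is.null(map)) map <- default_map(n_markers)
  map <- validate_map(map)
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            selfing_generations >= 0, environments >= 1,
            polymorphic_frac >= 0, polymorphic_frac <= 1)
  structure(list(n_families = n_families, lines_per_family = lines_per_family,
                 map = map, selfing_generations = selfing_generations,
                 missing_rate = missing_rate, missing_mode = missing_mode,
                 het_odds = het_odds, environments = environments,
                 architecture = architecture, env_sd = env_sd,
                 env_effects = env_effects,
                 polymorphic_frac = polymorphic_frac,
                 trait = trait, seed = as.integer(seed)),
            class = "sim_config")
}

# One meiosis per line: gamete drawn from haplotype pair (H1, H2) with
# Haldane recombination (r = (1 - exp(-2 d_cM / 100)) / 2, no interference).
# H1/H2 are 0/1 matrices (lines x markers), 1 = founder allele Q.
meiosis <- function(H1, H2, map) {
  n <- nrow(H1); M <- ncol(H1)
  pick <- matrix(0L, n, M)
  for (ch in unique(map$chrom)) {
    ix <- which(map$chrom == ch)
    pick[, ix[1L]] <- stats::rbinom(n, 1L, 0.5)
    if (length(ix) > 1L) {
      d <- diff(map$cM[ix])
      r <- (1 - exp(-2 * d / 100)) / 2
      for (j in seq_along(d)) {
        sw <- stats::rbinom(n, 1L, r[j])
        pick[, ix[j + 1L]] <- (pick[, ix[j]] + sw) %% 2L
      }
    }
  }
  pick * H2 + (1L - pick) * H1
}

#' Simulate NAM genotypes
#'
#' Per family, the founder is polymorphic against B73 at a random subset of
#' markers.  Each RIL descends from the family F1 by `selfing_generations`
#' rounds of single-seed selfing with map-based (Haldane) recombination, so
#' residual heterozygosity at polymorphic loci decays as (1/2)^g.  The B73
#' allele is labelled `q`, the founder allele `Q`.  Line IDs follow the
#' `Z{family}E{line}` convention.
#'
#' @param cfg [sim_config()].
#' @return pre-masking [genotype_matrix()].
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  map <- cfg$map
  M <- nrow(map)
  n <- cfg$lines_per_family
  calls <- NULL
  fam_labels <- sprintf("Z%03d", seq_len(cfg$n_families))
  out <- vector("list", cfg$n_families)
  for (f in seq_len(cfg$n_families)) {
    poly <- stats::runif(M) < cfg$polymorphic_frac
    founder <- as.integer(poly)
    # F1: one B73 haplotype, one founder haplotype, replicated per line
    H1 <- matrix(0L, n, M)
    H2 <- matrix(rep(founder, each = n), n, M)
    g <- cfg$selfing_generations
    if (g > 0) {
      for (k in seq_len(g)) {
        G1 <- meiosis(H1, H2, map)
        G2 <- meiosis(H1, H2, map)
        H1 <- G1; H2 <- G2
      }
    }
    s <- H1 + H2
    cm <- matrix("qq", n, M)
    cm[s == 1L] <- "Qq"
    cm[s == 2L] <- "QQ"
    rownames(cm) <- sprintf("%sE%04d", fam_labels[f], seq_len(n))
    out[[f]] <- cm
  }
  calls <- do.call(rbind, out)
  colnames(calls) <- map$id
  genotype_matrix(calls)
}

#' Mask genotype calls to MISSING
#'
#' @param gm [genotype_matrix()].
#' @param rate fraction of calls to mask.
#' @param mode `"MCAR"` masks uniformly at random; `"het_biased"` masks
#'   heterozygous calls preferentially with odds `het_odds` (emulating panels
#'   where apparent heterozygotes were set to missing).
#' @param het_odds relative masking odds for heterozygotes; `Inf` masks all
#'   heterozygotes before any homozygote.
#' @param seed optional integer seed.
#' @return masked [genotype_matrix()].
#' @export
mask_genotypes <- function(gm, rate, mode = c("MCAR", "het_biased"),
                           het_odds = 5, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(gm, "genotype_matrix"), rate >= 0, rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0) return(gm)
  calls <- gm$calls
  N <- length(calls)
  k <- round(rate * N)
  if (k == 0L) return(gm)
  if (mode == "MCAR") {
    idx <- sample.int(N, k)
  } else {
    het <- which(calls == "Qq")
    if (is.infinite(het_odds)) {
      if (k <= length(het)) {
        idx <- sample(het, k)
      } else {
        rest <- setdiff(seq_len(N), het)
        idx <- c(het, sample(rest, k - length(het)))
      }
    } else {
      w <- rep(1, N)
      w[het] <- het_odds
      idx <- sample.int(N, k, prob = w)
    }
  }
  calls[idx] <- "MISSING"
  genotype_matrix(calls, gm$family)
}

# Genetic contribution of an architecture for a set of lines (true calls),
# overall (env = NULL) or for a given environment h.
arch_contribution <- function(calls, arch, env = NULL) {
  n <- nrow(calls)
  g <- rep(0, n)
  if (nrow(arch$loci)) {
    for (k in seq_len(nrow(arch$loci))) {
      m <- arch$loci$marker[k]
      g <- g + arch$loci$a[k] * encode_additive(calls[, m]) +
        arch$loci$d[k] * encode_dominance(calls[, m])
    }
  }
  if (nrow(arch$pairs)) {
    for (k in seq_len(nrow(arch$pairs))) {
      p <- arch$pairs[k, ]
      xa1 <- encode_additive(calls[, p$marker1]); xd1 <- encode_dominance(calls[, p$marker1])
      xa2 <- encode_additive(calls[, p$marker2]); xd2 <- encode_dominance(calls[, p$marker2])
      g <- g + p$aa * xa1 * xa2 + p$ad * xa1 * xd2 + p$da * xd1 * xa2 + p$dd * xd1 * xd2
    }
  }
  if (!is.null(env)) {
    el <- arch$env_loci[arch$env_loci$env == env, , drop = FALSE]
    if (nrow(el)) {
      for (k in seq_len(nrow(el))) {
        m <- el$marker[k]
        g <- g + el$ae[k] * encode_additive(calls[, m]) +
          el$de[k] * encode_dominance(calls[, m])
      }
    }
    ep <- arch$env_pairs[arch$env_pairs$env == env, , drop = FALSE]
    if (nrow(ep)) {
      for (k in seq_len(nrow(ep))) {
        p <- ep[k, ]
        xa1 <- encode_additive(calls[, p$marker1]); xd1 <- encode_dominance(calls[, p$marker1])
        xa2 <- encode_additive(calls[, p$marker2]); xd2 <- encode_dominance(calls[, p$marker2])
        g <- g + p$aae * xa1 * xa2 + p$ade * xa1 * xd2 +
          p$dae * xd1 * xa2 + p$dde * xd1 * xd2
      }
    }
  }
  g
}

#' Simulate phenotypes under a genetic architecture
#'
#' Generates a balanced phenotype table (every line scored in every
#' environment) under the same full-model equation the mapper fits:
#' `y = mu + genetic terms + environment main effect + G-by-E terms + noise`.
#' Genetic coefficients are computed from the calls in `gm` as given — pass
#' the pre-masking matrix to generate truth from the real genotypes.
#'
#' @param gm [genotype_matrix()] providing the causal genotype calls.
#' @param cfg [sim_config()] whose `architecture`, `environments`, `env_sd` /
#'   `env_effects` and `trait` fields drive the generation.
#' @param seed optional seed overriding `cfg$seed + 1`.
#' @return [phenotype_table()].
#' @export
simulate_phenotypes <- function(gm, cfg, seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(cfg, "sim_config"))
  arch <- cfg$architecture
  known <- c(arch$loci$marker, arch$pairs$marker1, arch$pairs$marker2,
             arch$env_loci$marker, arch$env_pairs$marker1, arch$env_pairs$marker2)
  miss <- setdiff(known, colnames(gm$calls))
  if (length(miss)) stop("architecture references unknown marker(s): ",
                         paste(miss, collapse = ", "))
  set.seed(if (is.null(seed)) cfg$seed + 1L else seed)
  E <- cfg$environments
  envf <- if (is.null(cfg$env_effects)) stats::rnorm(E, 0, cfg$env_sd) else {
    stopifnot(length(cfg$env_effects) == E)
    cfg$env_effects
  }
  n <- nrow(gm$calls)
  g_main <- arch_contribution(gm$calls, arch, env = NULL)
  recs <- vector("list", E)
  for (h in seq_len(E)) {
    ge <- arch_contribution(gm$calls, arch, env = h) - g_main
    y <- arch$mu + g_main + ge + envf[h] + stats::rnorm(n, 0, arch$residual_sd)
    recs[[h]] <- data.frame(line = rownames(gm$calls), env = h,
                            trait = cfg$trait, value = y,
                            stringsAsFactors = FALSE)
  }
  phenotype_table(do.call(rbind, recs), gm)
}

#' Build a truth architecture with prescribed variance shares
#'
#' Chooses effect sizes so that each requested term's fitted-contribution
#' variance over the balanced line-by-environment grid equals a prescribed
#' share of a total phenotypic variance.  Effects on near-monomorphic
#' coefficients would need enormous sizes; terms whose coefficient variance
#' falls below `min_var` are dropped with a warning.
#'
#' @param gm [genotype_matrix()] with the causal calls.
#' @param shares data.frame with columns `kind` (one of a, d, aa, ad, da, dd,
#'   ae, de, aae), `marker1`, `marker2` (NA for single-locus kinds), `share`
#'   (fraction of total variance, in (0,1)), and optional `sign` (+1/-1).
#' @param total_var target phenotypic variance (environment main effects and
#'   residual excluded from shares are assigned to residual).
#' @param environments number of environments for the `*e` kinds.
#' @param mu population mean.
#' @param min_var minimum coefficient variance for a term to be usable.
#' @param seed seed for the per-environment deviations of `*e` kinds.
#' @return [genetic_architecture()] whose residual variance absorbs the
#'   unassigned share.
#' @export
architecture_from_shares <- function(gm, shares, total_var = 1, environments = 4,
                                     mu = 0, min_var = 1e-6, seed = 1L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  set.seed(seed)
  calls <- gm$calls
  coef_of <- function(kind, m1, m2) {
    xa1 <- encode_additive(calls[, m1]); xd1 <- encode_dominance(calls[, m1])
    switch(kind,
           a = xa1, d = xd1, ae = xa1, de = xd1,
           aa = , aae = xa1 * encode_additive(calls[, m2]),
           ad = xa1 * encode_dominance(calls[, m2]),
           da = xd1 * encode_additive(calls[, m2]),
           dd = xd1 * encode_dominance(calls[, m2]),
           stop("unsupported kind: ", kind))
  }
  loci <- list(); pairs <- list(); env_loci <- list(); env_pairs <- list()
  used <- 0
  E <- environments
  for (k in seq_len(nrow(shares))) {
    s <- shares[k, ]
    cv <- coef_of(s$kind, s$marker1, s$marker2)
    v <- stats::var(cv) * (length(cv) - 1) / length(cv)
    if (v < min_var) {
      warning("dropping term ", s$kind, " at ", s$marker1,
              ": coefficient variance ", signif(v, 3), " below floor")
      next
    }
    sgn <- if (!is.null(s$sign) && !is.na(s$sign)) s$sign else 1
    if (s$kind %in% c("a", "d", "aa", "ad", "da", "dd")) {
      eff <- sgn * sqrt(s$share * total_var / v)
      if (s$kind %in% c("a", "d")) {
        loci[[length(loci) + 1L]] <- data.frame(marker = s$marker1,
                                                a = if (s$kind == "a") eff else 0,
                                                d = if (s$kind == "d") eff else 0)
      } else {
        row <- data.frame(marker1 = s$marker1, marker2 = s$marker2,
                          aa = 0, ad = 0, da = 0, dd = 0)
        row[[s$kind]] <- eff
        pairs[[length(pairs) + 1L]] <- row
      }
    } else {
      # env-interaction kinds: per-env deviations, centered, scaled so the
      # family's total contribution variance over the balanced grid = share
      dev <- stats::rnorm(E); dev <- dev - mean(dev)
      # contribution per obs: dev[h] * cv; variance over grid =
      # mean_h dev_h^2 * E[cv^2] - (mean_h dev_h * E[cv])^2
      m2 <- mean(cv^2); m1 <- mean(cv)
      raw_v <- mean(dev^2) * m2 - (mean(dev) * m1)^2
      sc <- sqrt(s$share * total_var / raw_v)
      dev <- dev * sc
      if (s$kind %in% c("ae", "de")) {
        env_loci[[length(env_loci) + 1L]] <-
          data.frame(marker = s$marker1, env = seq_len(E),
                     ae = if (s$kind == "ae") dev else 0,
                     de = if (s$kind == "de") dev else 0)
      } else {
        rows <- data.frame(marker1 = s$marker1, marker2 = s$marker2,
                           env = seq_len(E), aae = 0, ade = 0, dae = 0, dde = 0)
        rows[[s$kind]] <- dev
        env_pairs[[length(env_pairs) + 1L]] <- rows
      }
    }
    used <- used + s$share
  }
  if (used >= 1) stop("variance shares sum to >= 1")
  merge_loci <- function(lst) {
    if (!length(lst)) return(data.frame(marker = character(), a = numeric(), d = numeric()))
    df <- do.call(rbind, lst)
    agg <- stats::aggregate(cbind(a, d) ~ marker, data = df, FUN = sum)
    agg
  }
  merge_pairs <- function(lst) {
    if (!length(lst)) return(data.frame(marker1 = character(), marker2 = character(),
                                        aa = numeric(), ad = numeric(),
                                        da = numeric(), dd = numeric()))
    df <- do.call(rbind, lst)
    stats::aggregate(cbind(aa, ad, da, dd) ~ marker1 + marker2, data = df, FUN = sum)
  }
  merge_env_loci <- function(lst) {
    if (!length(lst)) return(empty_env_loci())
    df <- do.call(rbind, lst)
    stats::aggregate(cbind(ae, de) ~ marker + env, data = df, FUN = sum)
  }
  merge_env_pairs <- function(lst) {
    if (!length(lst)) return(empty_env_pairs())
    df <- do.call(rbind, lst)
    stats::aggregate(cbind(aae, ade, dae, dde) ~ marker1 + marker2 + env,
                     data = df, FUN = sum)
  }
  genetic_architecture(mu = mu,
                       loci = merge_loci(loci),
                       pairs = merge_pairs(pairs),
                       env_loci = merge_env_loci(env_loci),
                       env_pairs = merge_env_pairs(env_pairs),
                       residual_sd = sqrt((1 - used) * total_var))
}
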