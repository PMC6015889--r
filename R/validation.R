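#' Heritability partition implied by a known architecture
#'
#' Computes each effect kind's contribution over the observations directly
#' from the architecture and the (true) genotype calls, giving the realized
#' "truth" partition that recovery experiments score estimates against.
#'
#' @param gm [genotype_matrix()] with the causal calls.
#' @param ph [phenotype_table()].
#' @param arch [genetic_architecture()] truth.
#' @param trait trait name.
#' @return [heritability_partition()].
#' @export
true_heritability <- function(gm, ph, arch, trait) {
  recs <- ph[ph$trait == trait, , drop = FALSE]
  if (!nrow(recs)) stop("trait absent")
  vy <- stats::var(recs$value)
  if (vy <= 0) stop("zero phenotypic variance")
  li <- match(recs$line, rownames(gm$calls))
  calls <- gm$calls[li, , drop = FALSE]
  comp <- stats::setNames(numeric(length(H2_COMPONENTS)), names(H2_COMPONENTS))
  kind_arch <- function(kind) {
    a <- genetic_architecture(residual_sd = arch$residual_sd)
    if (kind == "a" && nrow(arch$loci)) a$loci <- transform(arch$loci, d = 0)
    if (kind == "d" && nrow(arch$loci)) a$loci <- transform(arch$loci, a = 0)
    if (kind %in% c("aa", "ad", "da", "dd") && nrow(arch$pairs)) {
      p <- arch$pairs
      for (k in setdiff(c("aa", "ad", "da", "dd"), kind)) p[[k]] <- rep(0, nrow(p))
      a$pairs <- p
    }
    a
  }
  for (kind in c("a", "d", "aa", "ad", "da", "dd")) {
    ka <- kind_arch(kind)
    if ((kind %in% c("a", "d") && nrow(arch$loci)) ||
        (!kind %in% c("a", "d") && nrow(arch$pairs))) {
      v <- arch_contribution(calls, ka, env = NULL)
      comp[toupper(kind)] <- 100 * stats::var(v) / vy
    }
  }
  # environment-interaction kinds: contribution is env-specific deviation
  env_kind <- function(kind) {
    contrib <- numeric(nrow(recs))
    for (h in unique(recs$env)) {
      sel <- recs$env == h
      sub <- calls[sel, , drop = FALSE]
      el <- arch$env_loci[arch$env_loci$env == h, , drop = FALSE]
      ep <- arch$env_pairs[arch$env_pairs$env == h, , drop = FALSE]
      v <- numeric(sum(sel))
      if (kind == "ae" && nrow(el)) {
        for (k in seq_len(nrow(el)))
          v <- v + el$ae[k] * encode_additive(sub[, el$marker[k]])
      }
      if (kind == "de" && nrow(el)) {
        for (k in seq_len(nrow(el)))
          v <- v + el$de[k] * encode_dominance(sub[, el$marker[k]])
      }
      if (kind %in% c("aae", "ade", "dae", "dde") && nrow(ep)) {
        for (k in seq_len(nrow(ep))) {
          x1a <- encode_additive(sub[, ep$marker1[k]])
          x1d <- encode_dominance(sub[, ep$marker1[k]])
          x2a <- encode_additive(sub[, ep$marker2[k]])
          x2d <- encode_dominance(sub[, ep$marker2[k]])
          v <- v + switch(kind,
                          aae = ep$aae[k] * x1a * x2a, ade = ep$ade[k] * x1a * x2d,
                          dae = ep$dae[k] * x1d * x2a, dde = ep$dde[k] * x1d * x2d)
        }
      }
      contrib[sel] <- v
    }
    contrib
  }
  for (kind in RANDOM_KINDS) {
    v <- env_kind(kind)
    if (any(v != 0)) comp[toupper(kind)] <- 100 * stats::var(v) / vy
  }
  heritability_partition(comp)
}

# per-kind experiment-wise term groups for a design's fixed genetic columns
per_term_groups <- function(design) {
  reg <- design$registry
  gen <- reg[is.na(reg$block) & !(reg$column %in% design$base_cols), , drop = FALSE]
  groups <- as.list(gen$column)
  names(groups) <- gen$column
  groups
}

#' Monte-Carlo check of the missing-as-heterozygote policy
#'
#' Emulates the published validation: genotypes are masked, the true calls
#' underlying the masked cells are forced to a scenario (`truth_homozygous`:
#' random QQ/qq, so the data carry no hidden heterozygote signal at masked
#' cells; `truth_heterozygous`: Qq, so they do), phenotypes are generated
#' from the forced truth, and the analysis codes MISSING as a heterozygote.
#' The report records how often each effect kind passes the experiment-wise
#' threshold.
#'
#' @param cfg [sim_config()] whose architecture defines the causal terms.
#' @param scenario `"truth_homozygous"` or `"truth_heterozygous"`.
#' @param reps number of Monte-Carlo replicates (>= 1).
#' @param seed integer seed.
#' @param n_perm permutations per replicate (scaled down from the reference
#'   2,000 for desk use).
#' @param alpha_EW experiment-wise level.
#' @return list of class `recovery_report` with `rates` (data.frame kind,
#'   significance rate, Monte-Carlo SE), `dominance_rate`, `additive_rate`,
#'   `reps`.
#' @export
missing_genotype_experiment <- function(cfg, scenario = c("truth_homozygous",
                                                          "truth_heterozygous"),
                                        reps = 20, seed = 1L, n_perm = 200,
                                        alpha_EW = 0.05) {
  scenario <- match.arg(scenario)
  if (reps < 1) stop("reps must be >= 1")
  arch <- cfg$architecture
  loci <- unique(c(arch$loci$marker, arch$pairs$marker1, arch$pairs$marker2))
  pairs <- if (nrow(arch$pairs)) as.matrix(arch$pairs[c("marker1", "marker2")]) else NULL
  hits <- list()
  for (r in seq_len(reps)) {
    rs <- seed + r * 1000L
    cfg_r <- cfg; cfg_r$seed <- rs
    gm_true <- simulate_genotypes(cfg_r)
    gm_obs <- mask_genotypes(gm_true, cfg$missing_rate, cfg$missing_mode,
                             cfg$het_odds, seed = rs + 1L)
    masked <- gm_obs$calls == "MISSING"
    calls_truth <- gm_true$calls
    set.seed(rs + 2L)
    if (scenario == "truth_homozygous") {
      calls_truth[masked] <- sample(c("QQ", "qq"), sum(masked), replace = TRUE)
    } else {
      calls_truth[masked] <- "Qq"
    }
    gm_forced <- genotype_matrix(calls_truth, gm_true$family)
    ph <- simulate_phenotypes(gm_forced, cfg_r, seed = rs + 3L)
    design <- build_design(gm_obs, ph, cfg$trait, loci = loci, pairs = pairs,
                           model = "full")
    groups <- per_term_groups(design)
    thr <- permutation_threshold(design, groups, n_perm = n_perm,
                                 alpha_EW = alpha_EW, seed = rs + 4L)
    obs <- thr$observed
    kind <- design$registry$kind[match(obs$group, design$registry$column)]
    hits[[r]] <- data.frame(kind = kind, pass = obs$passes_EW,
                            stringsAsFactors = FALSE)
  }
  all_hits <- do.call(rbind, hits)
  rates <- stats::aggregate(pass ~ kind, all_hits, mean)
  nk <- stats::aggregate(pass ~ kind, all_hits, length)
  rates$mc_se <- sqrt(rates$pass * (1 - rates$pass) / nk$pass)
  names(rates)[2L] <- "rate"
  dom <- all_hits$kind %in% DOMINANCE_KINDS
  structure(list(rates = rates,
                 dominance_rate = mean(all_hits$pass[dom]),
                 dominance_n = sum(dom),
                 additive_rate = mean(all_hits$pass[all_hits$kind == "a"]),
                 scenario = scenario, reps = reps, alpha_EW = alpha_EW),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("recovery_report")
  if (!is.null(x$scenario)) cat(" [", x$scenario, "]", sep = "")
  cat(":", x$reps, "replicates\n")
  if (!is.null(x$rates)) print(x$rates)
  if (!is.null(x$effects)) {
    cat("effect recovery:\n"); print(x$effects)
  }
  if (!is.null(x$heritability)) {
    cat("heritability recovery:\n"); print(x$heritability)
  }
  invisible(x)
}

#' End-to-end parameter-recovery experiment
#'
#' For each replicate: simulate genotypes, mask, simulate phenotypes from the
#' truth; test every causal term against the permutation experiment-wise
#' threshold; estimate effects on the full design by Gibbs sampling; and
#' partition heritability under the full and the additive model.  Aggregates
#' per-effect bias, RMSE and credible-interval coverage, selection
#' sensitivity, and heritability recovery.
#'
#' The candidate set defaults to the causal loci and pairs (the pre-scan is
#' exercised separately); pass `prescan = TRUE` to select candidates with the
#' GMDR scan instead.
#'
#' @param cfg [sim_config()].
#' @param reps replicates.
#' @param seed integer seed.
#' @param n_perm permutations per replicate; `0` skips the testing stage
#'   (sensitivity reported as `NA`), useful when only estimation recovery is
#'   wanted.
#' @param alpha_EW experiment-wise level.
#' @param n_iter,burn_in,thin Gibbs settings (scaled down by default).
#' @param prescan run the GMDR 1D scan to choose candidate loci.
#' @param top_k candidates kept by the pre-scan.
#' @param truth_from `"analysis"` (default) generates phenotypes from the
#'   masked matrix the fitter sees — missing calls act as heterozygotes in
#'   the truth too, so recovery is a clean identity test; `"true_calls"`
#'   generates from the unmasked genotypes, confounding recovery with the
#'   missing-data policy (which [missing_genotype_experiment()] studies
#'   directly).
#' @return list of class `recovery_report` with `effects` (truth, mean
#'   estimate, bias, rmse, coverage), `heritability` (truth vs estimate of
#'   h2_T and h2_D+ per replicate), `sensitivity`, and the per-replicate
#'   additive-model h2_T.
#' @export
recovery_experiment <- function(cfg, reps = 20, seed = 1L, n_perm = 200,
                                alpha_EW = 0.05, n_iter = 3000, burn_in = 500,
                                thin = 5, prescan = FALSE, top_k = 10,
                                truth_from = c("analysis", "true_calls")) {
  truth_from <- match.arg(truth_from)
  if (reps < 1) stop("reps must be >= 1")
  arch <- cfg$architecture
  truth_eff <- architecture_to_effects(arch)
  truth_fix <- truth_eff[truth_eff$kind %in% FIXED_KINDS, , drop = FALSE]
  causal_loci <- unique(c(arch$loci$marker, arch$pairs$marker1, arch$pairs$marker2))
  pairs <- if (nrow(arch$pairs)) as.matrix(arch$pairs[c("marker1", "marker2")]) else NULL

  est_list <- list(); her_list <- list(); sens <- numeric(reps)
  for (r in seq_len(reps)) {
    rs <- seed + r * 1000L
    cfg_r <- cfg; cfg_r$seed <- rs
    gm_true <- simulate_genotypes(cfg_r)
    gm_obs <- mask_genotypes(gm_true, cfg$missing_rate, cfg$missing_mode,
                             cfg$het_odds, seed = rs + 1L)
    gm_gen <- if (truth_from == "analysis") gm_obs else gm_true
    ph <- simulate_phenotypes(gm_gen, cfg_r, seed = rs + 2L)

    loci <- causal_loci
    if (prescan) {
      sc <- gmdr_residual_score(ph, cfg$trait)
      cs <- gmdr_scan(gm_obs, sc, dim = 1, top_k = top_k, seed = rs + 3L)
      loci <- union(cs$candidates$marker1, causal_loci)
    }
    design <- build_design(gm_obs, ph, cfg$trait, loci = loci, pairs = pairs,
                           model = "full")
    reg <- design$registry
    truth_cols <- vapply(seq_len(nrow(truth_fix)), function(i) {
      k <- truth_fix$kind[i]
      sel <- reg$kind == k & reg$marker1 == truth_fix$qts1[i] & is.na(reg$block)
      if (!is.na(truth_fix$qts2[i])) sel <- sel & reg$marker2 == truth_fix$qts2[i]
      reg$column[sel][1L]
    }, "")
    if (n_perm > 0) {
      groups <- per_term_groups(design)
      thr <- permutation_threshold(design, groups, n_perm = n_perm,
                                   alpha_EW = alpha_EW, seed = rs + 4L)
      obs <- thr$observed
      # sensitivity: fraction of truth fixed terms whose column passes EW
      sens[r] <- mean(obs$passes_EW[match(truth_cols, obs$group)], na.rm = TRUE)
    } else {
      sens[r] <- NA_real_
    }

    fit <- gibbs_fit(design, n_iter = n_iter, burn_in = burn_in, thin = thin,
                     seed = rs + 5L)
    ci <- credible_intervals(fit)
    est <- merge(data.frame(column = truth_cols, truth = truth_fix$estimate,
                            kind = truth_fix$kind, stringsAsFactors = FALSE),
                 ci, by = "column")
    est$rep <- r
    est$covered <- est$truth >= est$lower & est$truth <= est$upper
    est_list[[r]] <- est

    p_full <- partition_heritability(fit, design)
    p_true <- true_heritability(gm_gen, ph, arch, cfg$trait)
    ad <- build_design(gm_obs, ph, cfg$trait, loci = loci, model = "additive")
    fit_a <- gibbs_fit(ad, n_iter = n_iter, burn_in = burn_in, thin = thin,
                       seed = rs + 6L)
    p_add <- partition_heritability(fit_a, ad)
    her_list[[r]] <- data.frame(
      rep = r,
      h2T_true = unname(aggregate_heritability(p_true)["h2_T"]),
      h2T_full = unname(aggregate_heritability(p_full)["h2_T"]),
      h2T_additive = unname(aggregate_heritability(p_add)["h2_T"]),
      h2Dplus_true = unname(aggregate_heritability(p_true)["h2_Dplus"]),
      h2Dplus_full = unname(aggregate_heritability(p_full)["h2_Dplus"]))
  }
  est_all <- do.call(rbind, est_list)
  eff_sum <- do.call(rbind, lapply(split(est_all, est_all$column), function(g) {
    data.frame(column = g$column[1L], kind = g$kind[1L], truth = g$truth[1L],
               mean_estimate = mean(g$mean), bias = mean(g$mean - g$truth),
               rmse = sqrt(mean((g$mean - g$truth)^2)),
               coverage = mean(g$covered), stringsAsFactors = FALSE)
  }))
  rownames(eff_sum) <- NULL
  her <- do.call(rbind, her_list)
  structure(list(effects = eff_sum, heritability = her,
                 sensitivity = if (all(is.na(sens))) NA_real_ else mean(sens, na.rm = TRUE),
                 reps = reps,
                 overall_coverage = mean(est_all$covered),
                 scenario = NULL, rates = NULL),
            class = "recovery_report")
}
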