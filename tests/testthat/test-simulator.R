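test_that("map validation rejects degenerate maps", {
  expect_error(sim_config(map = data.frame()), "empty genetic map")
  bad <- data.frame(chrom = c(1, 1), cM = c(10, 5), id = marker_id(1, c(1, 2)))
  expect_error(sim_config(map = bad), "non-increasing")
})

test_that("an unselfed F1 population is fully heterozygous at polymorphic loci", {
  cfg <- sim_config(n_families = 2, lines_per_family = 20, n_markers = 10,
                    selfing_generations = 0, polymorphic_frac = 1, seed = 3)
  gm <- simulate_genotypes(cfg)
  expect_true(all(gm$calls == "Qq"))
})

test_that("selfing drives heterozygosity to (1/2)^g and keeps calls Mendelian", {
  g <- 3
  cfg <- sim_config(n_families = 5, lines_per_family = 400,
                    map = default_map(8, n_chrom = 8),  # unlinked loci
                    selfing_generations = g, polymorphic_frac = 1, seed = 5)
  gm <- simulate_genotypes(cfg)
  expect_true(all(gm$calls %in% c("QQ", "Qq", "qq")))  # Mendelian pre-masking
  het <- mean(gm$calls == "Qq")
  p <- 0.5^g
  se <- sqrt(p * (1 - p) / length(gm$calls))
  expect_lt(abs(het - p), 3 * se)
})

test_that("heterozygosity is non-increasing in the selfing generation", {
  hets <- vapply(c(1, 3, 5), function(g) {
    cfg <- sim_config(n_families = 4, lines_per_family = 250,
                      map = default_map(6, n_chrom = 6),
                      selfing_generations = g, polymorphic_frac = 1, seed = 11)
    mean(simulate_genotypes(cfg)$calls == "Qq")
  }, numeric(1))
  expect_true(all(diff(hets) < 0))
})

test_that("family founders are fixed for opposite alleles at polymorphic loci", {
  cfg <- sim_config(n_families = 3, lines_per_family = 150, n_markers = 6,
                    selfing_generations = 6, polymorphic_frac = 0.5, seed = 13)
  gm <- simulate_genotypes(cfg)
  for (f in unique(gm$family)) {
    sub <- gm$calls[gm$family == f, , drop = FALSE]
    mono <- apply(sub, 2, function(v) all(v == "qq"))
    poly <- apply(sub, 2, function(v) any(v == "QQ"))
    # each marker is either fixed qq (founder carried B73 allele) or segregates
    expect_true(all(mono | poly))
  }
})

test_that("simulation is bit-reproducible from the seed", {
  cfg <- sim_config(n_families = 2, lines_per_family = 30, n_markers = 8,
                    architecture = genetic_architecture(mu = 1, residual_sd = 0.5),
                    environments = 2, seed = 99)
  g1 <- simulate_genotypes(cfg); g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  p1 <- simulate_phenotypes(g1, cfg); p2 <- simulate_phenotypes(g2, cfg)
  expect_identical(p1, p2)
  m1 <- mask_genotypes(g1, 0.2, seed = 5); m2 <- mask_genotypes(g2, 0.2, seed = 5)
  expect_identical(m1, m2)
})

test_that("masking hits the target rate and modes behave at their limits", {
  gm <- toy_gm(100, 10, seed = 17)
  expect_identical(mask_genotypes(gm, 0), gm)  # rate 0 is the identity
  masked <- mask_genotypes(gm, 0.23, "MCAR", seed = 7)
  frac <- mean(masked$calls == "MISSING")
  expect_equal(frac, 0.23, tolerance = 1e-6)  # exact count masking
  # het_biased with infinite odds masks heterozygotes first
  n_het <- sum(gm$calls == "Qq")
  rate <- (n_het - 5) / length(gm$calls)
  mb <- mask_genotypes(gm, rate, "het_biased", het_odds = Inf, seed = 8)
  expect_true(all(mb$calls[gm$calls != "Qq"] != "MISSING"))
  # finite odds still prefer heterozygotes
  mf <- mask_genotypes(gm, 0.2, "het_biased", het_odds = 10, seed = 9)
  het_masked <- mean(mf$calls[gm$calls == "Qq"] == "MISSING")
  hom_masked <- mean(mf$calls[gm$calls != "Qq"] == "MISSING")
  expect_gt(het_masked, hom_masked)
})

test_that("null architecture reproduces mean and residual variance", {
  cfg <- sim_config(n_families = 5, lines_per_family = 200, n_markers = 4,
                    architecture = genetic_architecture(mu = 10, residual_sd = 2),
                    environments = 2, env_effects = c(0, 0), seed = 21)
  gm <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(gm, cfg)
  expect_equal(mean(ph$value), 10, tolerance = 0.1)
  expect_equal(stats::var(ph$value), 4, tolerance = 0.3)
})

test_that("a single balanced additive locus yields h2 near 1/2", {
  m <- marker_id(1, 1)
  calls <- matrix(rep(c("QQ", "qq"), each = 500), 1000, 1,
                  dimnames = list(sprintf("Z001E%04d", 1:1000), m))
  gm <- genotype_matrix(calls)
  arch <- genetic_architecture(mu = 0,
                               loci = data.frame(marker = m, a = 1, d = 0),
                               residual_sd = 1)
  cfg <- sim_config(n_families = 1, lines_per_family = 1000, n_markers = 1,
                    architecture = arch, environments = 1, env_effects = 0,
                    seed = 23)
  ph <- simulate_phenotypes(gm, cfg)
  h2 <- stats::var(encode_additive(calls[, 1])) / stats::var(ph$value)
  expect_equal(h2, 0.5, tolerance = 0.05)
  p <- true_heritability(gm, ph, arch, "trait")
  expect_equal(p$A, 50, tolerance = 5)
})

test_that("dominance truth shows up in the variance decomposition despite few heterozygotes", {
  # ~3% heterozygosity, purely dominance-related truth
  set.seed(31)
  m <- marker_id(1, c(1, 2))
  calls <- matrix(sample(c("QQ", "qq", "Qq"), 4000, TRUE, prob = c(.485, .485, .03)),
                  2000, 2, dimnames = list(sprintf("Z001E%04d", 1:2000), m))
  gm <- genotype_matrix(calls)
  arch <- genetic_architecture(
    mu = 0, loci = data.frame(marker = m, a = 0, d = c(3, 0)),
    pairs = data.frame(marker1 = m[1], marker2 = m[2], aa = 0, ad = 0, da = 0,
                       dd = 40),
    residual_sd = 1)
  cfg <- sim_config(n_families = 1, lines_per_family = 2000, n_markers = 2,
                    architecture = arch, environments = 1, env_effects = 0,
                    seed = 33)
  ph <- simulate_phenotypes(gm, cfg)
  p <- true_heritability(gm, ph, arch, "trait")
  agg <- aggregate_heritability(p)
  expect_gt(agg["h2_Dplus"], 10)
  expect_gt(p$DD, 1)
})

test_that("architecture_from_shares hits requested contribution variances", {
  gm <- toy_gm(800, 6, seed = 41, codes = c("QQ", "qq", "QQ", "qq", "Qq"))
  mk <- colnames(gm$calls)
  shares <- data.frame(kind = c("a", "d", "dd", "ae"),
                       marker1 = mk[c(1, 2, 3, 1)],
                       marker2 = c(NA, NA, mk[4], NA),
                       share = c(0.2, 0.1, 0.15, 0.05))
  arch <- architecture_from_shares(gm, shares, total_var = 2, environments = 2,
                                   seed = 5)
  expect_equal(arch$residual_sd, sqrt(0.5 * 2))
  xa <- encode_additive(gm$calls[, mk[1]])
  v <- mean((xa - mean(xa))^2) * arch$loci$a[arch$loci$marker == mk[1]]^2
  expect_equal(v, 0.4, tolerance = 1e-10)
})
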