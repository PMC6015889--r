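test_that("Henderson III equals the two-regression partial-F oracle on fixed designs", {
  set.seed(1)
  gm <- toy_gm(20, 6, seed = 2)
  ph <- toy_ph(gm, E = 3, seed = 3)   # n = 60
  loci <- colnames(gm$calls)[1:3]
  d <- fixed_only(build_design(gm, ph, "t", loci, model = "additive"))
  y <- d$y
  for (m in loci) {
    f <- henderson3_f(d, paste0("a:", m))
    X_full <- d$X
    X_red <- X_full[, setdiff(colnames(X_full), paste0("a:", m)), drop = FALSE]
    rss <- function(X) sum(stats::lm.fit(X, y)$residuals^2)
    rss_f <- rss(X_full); rss_r <- rss(X_red)
    df2 <- length(y) - qr(X_full)$rank
    F_oracle <- (rss_r - rss_f) / (rss_f / df2)
    expect_equal(f$F, F_oracle, tolerance = 1e-8)
    expect_equal(f$df1, 1L)
    expect_equal(f$df2, df2)
    expect_equal(f$p_point, stats::pf(F_oracle, 1, df2, lower.tail = FALSE))
  }
  # joint group of all three loci
  f3 <- henderson3_f(d, paste0("a:", loci))
  X_red <- d$X[, d$base_cols, drop = FALSE]
  rss_f <- sum(stats::lm.fit(d$X, y)$residuals^2)
  rss_r <- sum(stats::lm.fit(X_red, y)$residuals^2)
  df2 <- length(y) - qr(d$X)$rank
  expect_equal(f3$F, ((rss_r - rss_f) / 3) / (rss_f / df2), tolerance = 1e-8)
})

test_that("F vanishes when the response is orthogonal to the tested term", {
  set.seed(4)
  gm <- toy_gm(30, 3, seed = 4)
  ph <- toy_ph(gm, E = 2, seed = 4)
  d <- fixed_only(build_design(gm, ph, "t", colnames(gm$calls)[1],
                               model = "additive"))
  # project noise orthogonal to the whole design: the tested term gains nothing
  d$y <- qr.resid(qr(d$X), stats::rnorm(length(d$y)))
  f <- henderson3_f(d, paste0("a:", colnames(gm$calls)[1]))
  expect_equal(f$F, 0, tolerance = 1e-10)
})

test_that("F is invariant to shifting and rescaling the response", {
  gm <- toy_gm(30, 4, seed = 5)
  ph <- toy_ph(gm, E = 2, seed = 6)
  d <- fixed_only(build_design(gm, ph, "t", colnames(gm$calls)[1:2],
                               model = "additive"))
  g <- paste0("a:", colnames(gm$calls)[1])
  f0 <- henderson3_f(d, g)
  d2 <- d; d2$y <- 5 + 3 * d$y
  f2 <- henderson3_f(d2, g)
  expect_equal(f2$F, f0$F, tolerance = 1e-10)
})

test_that("null F statistics follow the F distribution", {
  set.seed(7)
  gm <- toy_gm(20, 3, seed = 8)
  d0 <- fixed_only(build_design(gm, toy_ph(gm, E = 2), "t",
                                colnames(gm$calls)[1:2], model = "additive"))
  n <- length(d0$y)
  Fs <- replicate(400, {
    d0$y <- stats::rnorm(n)
    henderson3_f(d0, paste0("a:", colnames(gm$calls)[1]))$F
  })
  df2 <- n - qr(d0$X)$rank
  mu <- df2 / (df2 - 2)
  v <- 2 * df2^2 * (1 + df2 - 2) / (1 * (df2 - 2)^2 * (df2 - 4))
  expect_lt(abs(mean(Fs) - mu), 3 * sqrt(v / 400))
})

test_that("degenerate and rank-deficient groups are flagged", {
  gm <- toy_gm(20, 4, seed = 9)
  ph <- toy_ph(gm, E = 2)
  d <- fixed_only(build_design(gm, ph, "t", colnames(gm$calls)[1:2],
                               model = "additive"))
  # duplicate a column to create collinearity within the tested group
  d$X <- cbind(d$X, dup = d$X[, paste0("a:", colnames(gm$calls)[1])])
  d$registry <- rbind(d$registry, data.frame(column = "dup", kind = "a",
                                             marker1 = "dup", marker2 = NA,
                                             env = NA, block = NA))
  f <- suppressWarnings(henderson3_f(d, "dup"))
  expect_true(f$degenerate)
  expect_equal(f$df1, 0L)
  expect_error(henderson3_f(d, "nonexistent:column"), "unknown term")
})

test_that("single-term permutation threshold matches the analytic F quantile", {
  set.seed(11)
  m <- marker_id(1, 1:3)
  calls <- matrix(sample(c("QQ", "qq"), 300, TRUE), 100, 3,
                  dimnames = list(sprintf("Z001E%04d", 1:100), m))
  gm <- genotype_matrix(calls)
  ph <- toy_ph(gm, E = 2, seed = 12)
  d <- fixed_only(build_design(gm, ph, "t", m[1], model = "additive"))
  thr <- permutation_threshold(d, list(a1 = paste0("a:", m[1])),
                               n_perm = 2000, seed = 13)
  df2 <- length(d$y) - qr(d$X)$rank
  q_analytic <- stats::qf(0.95, 1, df2)
  # MC error of the 95th percentile estimated from the F density
  dens <- stats::df(q_analytic, 1, df2)
  se_q <- sqrt(0.95 * 0.05 / 2000) / dens
  expect_lt(abs(thr$critical_F - q_analytic), 4 * se_q)
  # alpha_EW = 1 gives the minimum of the permuted maxima
  thr1 <- permutation_threshold(d, list(a1 = paste0("a:", m[1])),
                                n_perm = 100, alpha_EW = 1, seed = 13)
  expect_equal(thr1$critical_F, min(thr1$max_null))
  expect_error(permutation_threshold(d, list(a1 = paste0("a:", m[1])),
                                     n_perm = 50), "at least 100")
})

test_that("permutations preserve within-environment multisets and are reproducible", {
  gm <- toy_gm(25, 3, seed = 15)
  ph <- toy_ph(gm, E = 2, seed = 16)
  d <- fixed_only(build_design(gm, ph, "t", colnames(gm$calls)[1],
                               model = "additive"))
  g <- list(a1 = paste0("a:", colnames(gm$calls)[1]))
  t1 <- permutation_threshold(d, g, n_perm = 100, seed = 17)
  t2 <- permutation_threshold(d, g, n_perm = 100, seed = 17)
  expect_identical(t1, t2)
  # direct check of the permutation helper
  set.seed(1)
  yp <- qtsmap:::permute_within_env(d$y, d$env, d$line)
  for (h in unique(d$env)) {
    expect_equal(sort(yp[d$env == h]), sort(d$y[d$env == h]))
  }
  # balanced data: a line's phenotype vector moves as one unit
  set.seed(2)
  yp2 <- qtsmap:::permute_within_env(seq_along(d$y), d$env, d$line)
  n <- length(unique(d$line))
  src1 <- yp2[1:n]                 # env-1 sources (positions 1..n)
  src2 <- yp2[(n + 1):(2 * n)] - n # env-2 sources, shifted back
  expect_equal(src1, src2)
})

test_that("p_EW is monotone non-increasing in F and never below p_point", {
  set.seed(19)
  gm <- toy_gm(60, 10, seed = 20)
  arch <- genetic_architecture(
    mu = 0, loci = data.frame(marker = colnames(gm$calls)[1], a = 1, d = 0),
    residual_sd = 1)
  li <- match(rep(rownames(gm$calls), 2), rownames(gm$calls))
  val <- arch$loci$a * encode_additive(gm$calls[li, 1]) + stats::rnorm(120)
  ph <- phenotype_table(data.frame(line = rep(rownames(gm$calls), 2),
                                   env = rep(1:2, each = 60), trait = "t",
                                   value = val), gm)
  d <- fixed_only(build_design(gm, ph, "t", colnames(gm$calls),
                               model = "additive"))
  groups <- as.list(stats::setNames(paste0("a:", colnames(gm$calls)),
                                    colnames(gm$calls)))
  thr <- permutation_threshold(d, groups, n_perm = 200, seed = 21)
  ob <- thr$observed[order(-thr$observed$F), ]
  expect_true(all(diff(ob$p_EW) >= 0))
  expect_true(all(ob$p_EW >= ob$p_point - 1e-12))
})

test_that("scan_candidates recovers planted loci and prunes noise", {
  set.seed(23)
  m <- default_map(12, n_chrom = 3)
  truth <- m$id[c(2, 6, 10)]
  arch <- genetic_architecture(
    mu = 0, loci = data.frame(marker = truth, a = c(1.2, -1, 0.9), d = 0),
    residual_sd = 0.8)
  cfg <- sim_config(n_families = 4, lines_per_family = 80, map = m,
                    environments = 2, architecture = arch,
                    polymorphic_frac = 1, seed = 25)
  gm <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(gm, cfg)
  scan <- scan_candidates(gm, ph, "trait", list(loci = m$id), n_perm = 200,
                          seed = 27)
  sel <- scan$selected$loci
  expect_true(all(truth %in% sel))
  expect_lte(length(setdiff(sel, truth)), 1L)  # at most one false positive
  # highly-significant flag is capped by the permutation resolution
  cap <- log10(201)
  expect_true(all(scan$results$neg_log10_p_EW <= cap + 1e-12))
  # determinism
  scan2 <- scan_candidates(gm, ph, "trait", list(loci = m$id), n_perm = 200,
                           seed = 27)
  expect_equal(scan$results, scan2$results)
})

test_that("the additive model largely misses pure dd truth", {
  set.seed(29)
  m <- default_map(8, n_chrom = 2)
  arch <- genetic_architecture(
    mu = 0, loci = data.frame(marker = m$id[c(1, 5)], a = 0, d = 0),
    pairs = data.frame(marker1 = m$id[1], marker2 = m$id[5],
                       aa = 0, ad = 0, da = 0, dd = 3),
    residual_sd = 1)
  cfg <- sim_config(n_families = 3, lines_per_family = 100, map = m,
                    selfing_generations = 2,  # enough heterozygotes for dd power
                    environments = 2, architecture = arch,
                    polymorphic_frac = 1, seed = 31)
  gm <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(gm, cfg)
  cand <- list(loci = m$id[c(1, 5)], pairs = cbind(m$id[1], m$id[5]))
  full <- scan_candidates(gm, ph, "trait", cand, model = "full",
                          n_perm = 200, seed = 33)
  expect_true(any(grepl("^pair:", full$results$group[full$results$selected])))
  addv <- scan_candidates(gm, ph, "trait", cand, model = "additive",
                          n_perm = 200, seed = 33)
  # additive model has no epistasis terms at all; its locus tests stay weak
  expect_false(any(grepl("^pair:", addv$results$group)))
})
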