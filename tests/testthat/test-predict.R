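test_that("total genotypic value reproduces hand computations", {
  # empty architecture -> 0
  expect_equal(total_genotypic_value(c(S1_1 = "QQ"), genetic_architecture()), 0)
  # 2-locus toy: a1=1, d1=2, a2=-1, aa12=0.5 at (QQ, qq) -> 1.5
  m <- marker_id(1, c(1, 2))
  arch <- genetic_architecture(
    loci = data.frame(marker = m, a = c(1, -1), d = c(2, 0)),
    pairs = data.frame(marker1 = m[1], marker2 = m[2], aa = 0.5,
                       ad = 0, da = 0, dd = 0))
  asg <- stats::setNames(c("QQ", "qq"), m)
  expect_equal(total_genotypic_value(asg, arch), 1.5)
  expect_equal(total_genotypic_value(asg, arch), flat_value(asg, arch))
  # all-Qq assignment: only dominance-coded terms survive
  archd <- genetic_architecture(
    loci = data.frame(marker = m, a = c(3, -2), d = c(0.5, 0.25)),
    pairs = data.frame(marker1 = m[1], marker2 = m[2], aa = 9,
                       ad = 0, da = 0, dd = 1.5))
  allq <- stats::setNames(c("Qq", "Qq"), m)
  expect_equal(total_genotypic_value(allq, archd), 0.5 + 0.25 + 1.5)
  # missing locus errors
  expect_error(total_genotypic_value(c(S1_1 = "QQ"), arch), "missing locus")
})

test_that("per-environment values add the interaction effects with the same coding", {
  m <- marker_id(1, 1)
  arch <- genetic_architecture(
    loci = data.frame(marker = m, a = 1, d = 0),
    env_loci = data.frame(marker = m, env = 1:2, ae = c(0.5, -0.5), de = c(0, 2)))
  expect_equal(total_genotypic_value(c(S1_1 = "QQ"), arch, env = 1), 1.5)
  expect_equal(total_genotypic_value(c(S1_1 = "QQ"), arch, env = 2), 0.5)
  expect_equal(total_genotypic_value(c(S1_1 = "Qq"), arch, env = 2), 2)
})

test_that("best_line equals exhaustive evaluation and uses het coding for MISSING", {
  set.seed(1)
  arch <- random_architecture(4, 2, seed = 2)
  mk <- unique(c(arch$loci$marker, arch$pairs$marker1, arch$pairs$marker2))
  calls <- matrix(sample(c("QQ", "Qq", "qq"), 20 * length(mk), TRUE),
                  20, length(mk),
                  dimnames = list(sprintf("Z001E%04d", 1:20), mk))
  gm <- genotype_matrix(calls)
  for (dir in c("+", "-")) {
    bl <- best_line(gm, arch, dir)
    vals <- vapply(rownames(calls), function(l) {
      flat_value(stats::setNames(calls[l, mk], mk), arch)
    }, numeric(1))
    opt <- if (dir == "+") max(vals) else min(vals)
    expect_equal(bl$G, opt)
    expect_equal(bl$line, sort(names(vals)[vals == opt])[1])
  }
  # MISSING evaluated as heterozygote
  calls2 <- calls; calls2[1, 1] <- "MISSING"
  calls3 <- calls; calls3[1, 1] <- "Qq"
  b2 <- best_line(genotype_matrix(calls2), arch, "+")
  b3 <- best_line(genotype_matrix(calls3), arch, "+")
  expect_equal(b2$G, b3$G)
  # single line -> that line
  one <- genotype_matrix(calls[1, , drop = FALSE])
  expect_equal(best_line(one, arch, "+")$line, rownames(calls)[1])
})

test_that("epistasis components partition the pair graph", {
  mk <- marker_id(1, 1:5)
  arch <- genetic_architecture(
    loci = data.frame(marker = mk, a = 1, d = 0),
    pairs = data.frame(marker1 = mk[c(1, 2)], marker2 = mk[c(2, 3)],
                       aa = 1, ad = 0, da = 0, dd = 0))
  comp <- epistasis_components(arch)
  sizes <- sort(vapply(comp, function(c) length(c$markers), 0L))
  expect_equal(sizes, c(1L, 1L, 3L))
  big <- comp[[which(vapply(comp, function(c) length(c$markers), 0L) == 3L)]]
  expect_setequal(big$markers, mk[1:3])
  # empty pair set -> all singletons
  arch0 <- genetic_architecture(loci = data.frame(marker = mk, a = 1, d = 0))
  expect_true(all(vapply(epistasis_components(arch0),
                         function(c) length(c$markers), 0L) == 1L))
})

test_that("epistasis components agree with an igraph oracle on random graphs", {
  skip_if_not_installed("igraph")
  for (s in 1:5) {
    set.seed(s)
    mk <- marker_id(1, seq_len(30) * 10)
    pr <- t(utils::combn(mk, 2))
    pr <- pr[sample(nrow(pr), 12), , drop = FALSE]
    arch <- genetic_architecture(
      loci = data.frame(marker = mk, a = 1, d = 0),
      pairs = data.frame(marker1 = pr[, 1], marker2 = pr[, 2],
                         aa = 1, ad = 0, da = 0, dd = 0))
    comp <- epistasis_components(arch)
    g <- igraph::graph_from_data_frame(as.data.frame(pr), directed = FALSE,
                                       vertices = mk)
    ref <- igraph::components(g)$membership
    mine <- integer(length(mk)); names(mine) <- mk
    for (i in seq_along(comp)) mine[comp[[i]]$markers] <- i
    # same partition: the cross-tabulation must be a bijection
    expect_equal(length(unique(paste(ref[mk], mine[mk]))),
                 length(unique(ref)))
    expect_equal(length(unique(mine)), length(unique(ref)))
  }
})

test_that("superior plans equal flat enumeration on random architectures", {
  for (s in 1:12) {
    arch <- random_architecture(n_loci = 6, n_pairs = 3, seed = 100 + s)
    for (dir in c("+", "-")) {
      expect_equal(superior_plan(arch, dir, "any")$G,
                   flat_optimum(arch, dir, c("qq", "Qq", "QQ")),
                   tolerance = 1e-10)
      sl <- superior_plan(arch, dir, "homozygous_only")
      expect_equal(sl$G, flat_optimum(arch, dir, c("qq", "QQ")),
                   tolerance = 1e-10)
      expect_false(any(sl$assignment == "Qq"))  # superior line is homozygous
    }
  }
})

test_that("the sign rule governs additive-only superior lines, ties toward qq", {
  mk <- marker_id(1, 1:3)
  arch <- genetic_architecture(
    loci = data.frame(marker = mk, a = c(2, -3, 0), d = 0))
  sp <- superior_plan(arch, "+", "homozygous_only")
  expect_equal(unname(sp$assignment[mk]), c("QQ", "qq", "qq"))  # a=0 -> qq
  # without dominance-related effects the hybrid optimum equals the line optimum
  sh <- superior_plan(arch, "+", "any")
  expect_equal(sh$G, sp$G)
})

test_that("the enumeration cap triggers an explicit error", {
  mk <- marker_id(1, 1:18)
  pr <- cbind(mk[-18], mk[-1])  # one long chain: a single 18-locus component
  arch <- genetic_architecture(
    loci = data.frame(marker = mk, a = 1, d = 0),
    pairs = data.frame(marker1 = pr[, 1], marker2 = pr[, 2],
                       aa = 0.1, ad = 0, da = 0, dd = 0))
  expect_error(superior_plan(arch, "+", "homozygous_only", cap = 16), "cap")
})

test_that("search-space inclusion: SH >= SL >= best homozygous line", {
  for (s in 1:10) {
    arch <- random_architecture(5, 2, seed = 200 + s)
    mk <- unique(c(arch$loci$marker, arch$pairs$marker1, arch$pairs$marker2))
    set.seed(s)
    calls <- matrix(sample(c("QQ", "qq"), 15 * length(mk), TRUE), 15, length(mk),
                    dimnames = list(sprintf("Z001E%04d", 1:15), mk))
    gm <- genotype_matrix(calls)
    bl <- best_line(gm, arch, "+")
    sl <- superior_plan(arch, "+", "homozygous_only")
    sh <- superior_plan(arch, "+", "any")
    expect_gte(sh$G, sl$G - 1e-12)
    expect_gte(sl$G, bl$G - 1e-12)
    # value is additive across components
    comps <- epistasis_components(arch)
    parts <- vapply(comps, function(cp) {
      sub <- qtsmap:::sub_architecture(arch, cp$markers)
      total_genotypic_value(sh$assignment[cp$markers], sub)
    }, numeric(1))
    expect_equal(sum(parts), sh$G, tolerance = 1e-10)
  }
})

test_that("plan_report emits the six-row table and flags SH-vs-SL loci", {
  arch <- genetic_architecture(
    mu = 62.84,
    loci = data.frame(marker = marker_id(1, c(1, 2, 3)),
                      a = c(1, -0.5, 0.2), d = c(0.4, 0, 0)),
    env_loci = data.frame(marker = marker_id(1, 1), env = 1:2,
                          ae = c(0.2, -0.2), de = 0))
  mk <- marker_id(1, c(1, 2, 3))
  set.seed(3)
  calls <- matrix(sample(c("QQ", "qq"), 30, TRUE), 10, 3,
                  dimnames = list(sprintf("Z001E%04d", 1:10), mk))
  gm <- genotype_matrix(calls)
  plans <- list(best_line = best_line(gm, arch, "+"),
                superior_line = superior_plan(arch, "+", "homozygous_only"),
                superior_hybrid = superior_plan(arch, "+", "any"))
  rep_ <- plan_report(plans, arch, E = 2)
  expect_equal(nrow(rep_), 6L)
  expect_equal(ncol(rep_), 1L + 1L + 2L)  # entry, G, G+GE1..2
  expect_equal(rep_$entry, c("QQ", "qq", "F1", "Best line", "Superior line",
                             "Superior hybrid"))
  expect_equal(attr(rep_, "mu"), 62.84)
  # mu never folded into the values: all-additive F1 row is exactly zero
  arch_add <- genetic_architecture(
    mu = 100, loci = data.frame(marker = mk, a = c(1, -2, 3), d = 0))
  plans2 <- list(best_line = best_line(gm, arch_add, "+"),
                 superior_line = superior_plan(arch_add, "+", "homozygous_only"),
                 superior_hybrid = superior_plan(arch_add, "+", "any"))
  r2 <- plan_report(plans2, arch_add, E = 2)
  expect_true(all(unlist(r2[r2$entry == "F1", -1]) == 0))
  # SH vs SL difference list is attributable to heterozygote loci
  d <- attr(rep_, "sh_vs_sl")
  if (nrow(d)) expect_true(all(d$superior_hybrid == "Qq"))
})
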