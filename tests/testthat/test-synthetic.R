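# The Balding-Nichols synthetic-population generator.

test_that("drift vanishes as F approaches zero", {
  cfg <- synthetic_config(
    groups = c("AFR", "EUR"),
    n_loci = c(AFR = 100), n_triallelic = c(AFR = 0),
    divergence = c(AFR = 1e-6, EUR = 1e-6),
    psd_floor = c(AFR = 0, EUR = 0),
    n_samples = c(AFR = 5, EUR = 5), seed = 71)
  ft <- simulate_frequencies(cfg)
  diffs <- vapply(ft$freqs, function(f) max(abs(f[, 1] - f[, 2])), 0)
  expect_lt(mean(diffs), 1e-3)
  expect_lt(max(diffs), 8e-3)
})

test_that("population frequencies follow Balding-Nichols moments", {
  F <- 0.5
  cfg <- synthetic_config(
    groups = c("AFR", "EUR"),
    n_loci = c(AFR = 10000), n_triallelic = c(AFR = 0),
    divergence = c(AFR = F, EUR = F),
    psd_floor = c(AFR = 0, EUR = 0),
    n_samples = c(AFR = 5, EUR = 5), seed = 72)
  ft <- simulate_frequencies(cfg)
  pa <- vapply(ft$freqs, function(f) f[1, "AFR"], 0)
  pb <- vapply(ft$freqs, function(f) f[1, "EUR"], 0)
  # ancestral p ~ U(0.1, 0.9): E[p(1-p)] = 59/300
  epq <- 59 / 300
  expect_equal(mean((pa - pb)^2), 2 * F * epq, tolerance = 0.05)
  # E[p_pop (1 - p_pop)] = (1 - F) E[p(1-p)]
  expect_equal(mean(pa * (1 - pa)), (1 - F) * epq, tolerance = 0.05)
})

test_that("assigned loci respect the divergence floor", {
  cfg <- synthetic_config(seed = 73)
  ft <- simulate_frequencies(cfg)
  prof <- divergence_profile(ft)
  for (g in cfg$groups) {
    own <- prof[prof$target_group == g, paste0("psd_", g)]
    expect_true(all(own >= cfg$psd_floor[[g]] - 1e-12))
  }
  # Eurasian-contrast loci: floor applies to EUR vs its Asian neighbours
  eur12 <- ft$loci$snp_id[ft$loci$target_group == "EURASIA"]
  for (id in eur12) {
    f <- t(ft$freqs[[id]])
    pooled <- colMeans(f[c("SAS", "EAS"), ])
    expect_gte(rosenberg_in(rbind(f["EUR", ], pooled)),
               cfg$psd_floor[["EURASIA"]] - 1e-12)
  }
  expect_error(
    simulate_frequencies(synthetic_config(
      psd_floor = c(AFR = 0.75, EUR = 0.42, EAS = 0.35, SAS = 0.08,
                    OCE = 0.5, AMR = 0.45, EURASIA = 0.25),
      seed = 74)),
    "floor")
})

test_that("genotype sampling is HWE with reproducible seeds", {
  pan <- panel_spec("rs1", alleles = "A/G")
  fixed <- frequency_table(pan, "P", list(rs1 = matrix(
    c(1, 0), 2, 1, dimnames = list(c("A", "G"), "P"))))
  gm <- simulate_genotypes(fixed, c(P = 100), seed = 75)
  expect_true(all(gm$calls == "AA"))

  half <- frequency_table(pan, "P", list(rs1 = matrix(
    c(0.5, 0.5), 2, 1, dimnames = list(c("A", "G"), "P"))))
  gm2 <- simulate_genotypes(half, c(P = 10000), seed = 76)
  expect_equal(mean(gm2$calls == "AG"), 0.5, tolerance = 0.03)

  ft <- small_study(seed = 77)$frequencies
  a <- simulate_genotypes(ft, c(AFR = 10, EUR = 10), seed = 78)
  b <- simulate_genotypes(ft, c(AFR = 10, EUR = 10), seed = 78)
  expect_identical(a$calls, b$calls)
})

test_that("admixed genotypes with q = (1, 0) match unadmixed sampling", {
  ref <- small_study(seed = 79)
  ft <- ref$frequencies
  adm <- simulate_admixed(ft, list(list(q = c(AFR = 1), n = 300,
                                        label = "PURE")), seed = 80)
  gm <- simulate_genotypes(ft, c(AFR = 300), seed = 81)
  # pooled genotype counts across 10 loci: chi-square homogeneity test
  ps <- vapply(1:10, function(j) {
    obs_a <- table(factor(adm$calls[, j],
                          levels = all_genotypes(rownames(ft$freqs[[j]]))))
    obs_b <- table(factor(gm$calls[, j],
                          levels = all_genotypes(rownames(ft$freqs[[j]]))))
    keep <- obs_a + obs_b > 0
    suppressWarnings(stats::chisq.test(rbind(obs_a[keep],
                                             obs_b[keep]))$p.value)
  }, 0)
  expect_gt(min(ps), 0.01 / 10)  # no locus fails at Bonferroni alpha = 0.01

  # 50/50 mixture of fixed-difference populations is heterozygous on
  # average half the time
  ftf <- fixed_difference_table(40)
  mix <- simulate_admixed(ftf, list(list(q = c(POP1 = 0.5, POP2 = 0.5),
                                         n = 200)), seed = 82)
  expect_equal(mean(mix$calls == "AG"), 0.5, tolerance = 0.02)
  expect_true(all(attr(mix, "truth")[c("POP1", "POP2")] == 0.5))
})

test_that("error injection is exact, ledgered and reproducible", {
  ref <- small_study(seed = 83)$reference
  out0 <- inject_errors(ref, 0, 0, seed = 84)
  expect_identical(out0$genotypes$calls, ref$calls)
  expect_equal(nrow(out0$ledger), 0)

  out <- inject_errors(ref, error_rate = 0.02, nocall_rate = 0.03,
                       seed = 85)
  expect_equal(sum(out$ledger$type == "nocall"),
               sum(is.na(out$genotypes$calls)) - sum(is.na(ref$calls)))
  changed <- which(out$genotypes$calls != ref$calls)
  expect_equal(length(changed), sum(out$ledger$type == "error"))
  # errors are always different valid genotypes
  err <- out$ledger[out$ledger$type == "error", ]
  expect_true(all(err$original != err$new))

  again <- inject_errors(ref, error_rate = 0.02, nocall_rate = 0.03,
                         seed = 85)
  expect_identical(again$genotypes$calls, out$genotypes$calls)
  expect_identical(again$ledger, out$ledger)

  cnt <- inject_errors(ref, seed = 86, n_errors = 17, n_nocalls = 5)
  expect_equal(sum(cnt$ledger$type == "error"), 17)
  expect_equal(sum(cnt$ledger$type == "nocall"), 5)
})

test_that("generated tables and matrices satisfy their invariants", {
  ref <- small_study(seed = 87)
  for (f in ref$frequencies$freqs) {
    expect_true(all(f >= 0))
    expect_equal(unname(colSums(f)), rep(1, ncol(f)), tolerance = 1e-9)
  }
  al <- panel_alleles(ref$frequencies$loci)
  for (j in seq_len(ncol(ref$reference$calls))) {
    g <- ref$reference$calls[, j]
    expect_true(all(is.na(g) | g %in% all_genotypes(al[[j]])))
  }
  expect_equal(anyDuplicated(sample_ids(ref$reference)), 0)
})
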