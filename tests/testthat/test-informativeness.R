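# Informativeness statistics and panel balancing.

test_that("rosenberg In matches known values and the scalar oracle", {
  opp <- rbind(c(1, 0), c(0, 1))
  expect_equal(rosenberg_in(opp), log(2))
  same <- rbind(c(0.3, 0.7), c(0.3, 0.7), c(0.3, 0.7))
  expect_equal(rosenberg_in(same), 0)
  two <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  expect_equal(rosenberg_in(two), 0.3680642, tolerance = 1e-6)
  expect_equal(rosenberg_in(two), oracle_in(two))

  set.seed(42)
  for (i in 1:20) {
    K <- sample(2:6, 1); A <- sample(2:3, 1)
    f <- t(vapply(seq_len(K), function(k) {
      v <- stats::runif(A); v / sum(v)
    }, numeric(A)))
    expect_equal(rosenberg_in(f), oracle_in(f), tolerance = 1e-12)
    expect_lte(rosenberg_in(f), log(K) + 1e-12)
    # invariant under population reordering and allele relabeling
    expect_equal(rosenberg_in(f[sample(K), ]), rosenberg_in(f))
    expect_equal(rosenberg_in(f[, sample(A)]), rosenberg_in(f))
  }
})

test_that("PSD is the two-group In against the pooled remainder", {
  f <- rbind(T = c(1, 0), O1 = c(0, 1), O2 = c(0, 1))
  expect_equal(population_specific_divergence(f, "T"), log(2))
  f2 <- rbind(T = c(0.4, 0.6), O1 = c(0.3, 0.7), O2 = c(0.5, 0.5))
  expect_equal(population_specific_divergence(f2, "T"), 0)
  # target 0.8 vs two populations at 0.2: equals In on the (0.8, 0.2) pair
  f3 <- rbind(T = c(0.8, 0.2), O1 = c(0.2, 0.8), O2 = c(0.2, 0.8))
  expect_equal(population_specific_divergence(f3, "T"),
               oracle_in(rbind(c(0.8, 0.2), c(0.2, 0.8))))
  expect_equal(population_specific_divergence(f3, "T"), 0.1927448,
               tolerance = 1e-6)
  expect_error(population_specific_divergence(f3, "NOPE"), "not present")

  set.seed(7)
  for (i in 1:20) {
    K <- sample(3:6, 1)
    f <- t(vapply(seq_len(K), function(k) {
      v <- stats::runif(2); v / sum(v)
    }, numeric(2)))
    rownames(f) <- paste0("P", seq_len(K))
    pooled <- colMeans(f[-1, , drop = FALSE])
    expect_equal(population_specific_divergence(f, "P1"),
                 oracle_in(rbind(f[1, ], pooled)))
  }
})

test_that("delta differential maximizes over alleles", {
  f <- rbind(T = c(0.8, 0.2), O1 = c(0.2, 0.8), O2 = c(0.2, 0.8))
  colnames(f) <- c("A", "G")
  d <- delta_differential(f, "T")
  expect_equal(d$delta, 0.6)
  expect_equal(d$informative_allele, "A")
  expect_equal(delta_differential(rbind(T = c(0.5, 0.5),
                                        O = c(0.5, 0.5)), "T")$delta, 0)
  f3 <- rbind(T = c(0.7, 0.2, 0.1), O1 = c(0.2, 0.4, 0.4),
              O2 = c(0.0, 0.6, 0.4))
  colnames(f3) <- c("A", "C", "G")
  expect_equal(delta_differential(f3, "T")$delta, 0.6)  # allele A: 0.7 - 0.1
  # restricted comparator, as used for South Asian vs European ranking
  expect_equal(delta_differential(f3, "T", comparator = "O1")$delta, 0.5)
  expect_error(delta_differential(f3, "T", comparator = character(0)),
               "empty comparator")
})

test_that("cumulative PSD totals are additive and respect exclusions", {
  ref <- small_study(seed = 14)
  prof <- divergence_profile(ref$frequencies)
  ids <- prof$snp_id
  half1 <- ids[seq(1, length(ids), 2)]
  half2 <- setdiff(ids, half1)
  tot <- cumulative_psd(prof)
  expect_equal(cumulative_psd(prof, subset = half1) +
                 cumulative_psd(prof, subset = half2), tot)
  # per-SNP summation oracle
  expect_equal(unname(tot["AFR"]), sum(prof$psd_AFR))
  eur12 <- prof$snp_id[prof$target_group == "EURASIA"]
  expect_equal(unname(cumulative_psd(prof, exclude = eur12)["AFR"]),
               sum(prof$psd_AFR[!(ids %in% eur12)]))
  # assigned mode credits each SNP only to its own target group
  assigned <- cumulative_psd(prof, by = "assigned")
  expect_equal(unname(assigned["SAS"]),
               sum(prof$psd_SAS[prof$target_group == "SAS"]))
  expect_equal(unname(cumulative_psd(prof, subset = character(0))["EUR"]), 0)
})

make_candidates <- function(n_per_group, groups = c("AFR", "EUR", "EAS"),
                            seed = 1) {
  set.seed(seed)
  data.frame(
    snp_id = sprintf("rs%04d", seq_len(n_per_group * length(groups))),
    group = rep(groups, each = n_per_group),
    psd = stats::runif(n_per_group * length(groups), 0.05, 0.6),
    stringsAsFactors = FALSE)
}

test_that("balance_panel respects budgets, protection and determinism", {
  cand <- make_candidates(20)
  budget <- c(AFR = 5, EUR = 5, EAS = 5)
  protected <- cand$snp_id[c(1, 21)]
  rep1 <- balance_panel(cand, budget, protected = protected)
  rep2 <- balance_panel(cand, budget, protected = protected)
  expect_identical(rep1$selected, rep2$selected)
  got <- table(rep1$selected$group)
  expect_true(all(got[names(budget)] == budget))
  expect_true(all(protected %in% rep1$selected$snp_id))
  expect_equal(unname(rep1$cumulative_after),
               unname(vapply(names(budget), function(g)
                 sum(rep1$selected$psd[rep1$selected$group == g]), 0)))

  expect_error(balance_panel(cand, c(AFR = 5, EUR = 5, EAS = 5, OCE = 2)),
               "OCE")
})

test_that("an already balanced selection within the band is unchanged", {
  cand <- data.frame(
    snp_id = sprintf("rs%02d", 1:9),
    group = rep(c("AFR", "EUR", "EAS"), each = 3),
    psd = c(0.5, 0.4, 0.1, 0.52, 0.38, 0.1, 0.49, 0.42, 0.1))
  initial <- c("rs01", "rs02", "rs04", "rs05", "rs07", "rs08")
  rep <- balance_panel(cand, c(AFR = 2, EUR = 2, EAS = 2),
                       initial = initial, band = 0.05)
  expect_setequal(rep$selected$snp_id, initial)
  expect_equal(nrow(rep$log), 0)
})

test_that("greedy balancing is no worse than a 1000-draw random search", {
  groups <- c("AFR", "EUR", "EAS", "AMR")
  cand <- make_candidates(50, groups = groups, seed = 9)
  budget <- c(AFR = 15, EUR = 15, EAS = 15, AMR = 15)
  rep <- balance_panel(cand, budget)
  spread <- max(rep$cumulative_after) - min(rep$cumulative_after)
  set.seed(99)
  best_random <- Inf
  for (i in 1:1000) {
    sel <- unlist(lapply(groups, function(g) {
      pool <- cand$snp_id[cand$group == g]
      sample(pool, budget[[g]])
    }))
    cums <- vapply(groups, function(g)
      sum(cand$psd[cand$snp_id %in% sel & cand$group == g]), 0)
    best_random <- min(best_random, max(cums) - min(cums))
  }
  expect_lte(spread, best_random)
})
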