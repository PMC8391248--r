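# Percentile comparison, detection summaries, Evanno delta-K, panel audit
# and diplotype recoding.

fake_q <- function(n, seed = 1) {
  set.seed(seed)
  a <- stats::runif(n)
  data.frame(sample = sprintf("S%03d", seq_len(n)),
             AFR = a, EUR = 1 - a, stringsAsFactors = FALSE)
}

test_that("identical estimates give r2 = 1 and identical bin means", {
  qa <- fake_q(40)
  pc <- percentile_compare(qa, qa, sort_component = "AFR")
  expect_true(all(pc$r2 == 1))
  expect_equal(pc$bin_means$mean_a, pc$bin_means$mean_b)
  expect_equal(unique(pc$bin_means$n), 4)
})

test_that("bins are near-equal with remainders to the earliest bins", {
  qa <- fake_q(20)
  pc <- percentile_compare(qa, qa, sort_component = "AFR")
  expect_equal(unique(table(pc$bins$bin)), 2L)
  qa23 <- fake_q(23)
  pc23 <- percentile_compare(qa23, qa23, sort_component = "AFR")
  sizes <- as.vector(table(pc23$bins$bin))
  expect_equal(sizes, c(3, 3, 3, 2, 2, 2, 2, 2, 2, 2))
  expect_warning(percentile_compare(fake_q(6), fake_q(6), "AFR"), "bins")
})

test_that("r2 equals the closed-form squared Pearson correlation", {
  qa <- fake_q(60, seed = 2)
  qb <- qa
  set.seed(3)
  qb$AFR <- pmin(pmax(qa$AFR + stats::rnorm(60, 0, 0.05), 0), 1)
  qb$EUR <- 1 - qb$AFR
  pc <- percentile_compare(qa, qb, sort_component = "AFR")
  expect_equal(unname(pc$r2["AFR"]), stats::cor(qa$AFR, qb$AFR)^2)
  # conservation: weighted bin means average back to the cohort mean
  bm <- pc$bin_means[pc$bin_means$component == "AFR", ]
  expect_equal(sum(bm$mean_b * bm$n) / sum(bm$n), mean(qb$AFR))
})

test_that("detection summaries bin by true proportion", {
  truth <- data.frame(sample = sprintf("S%02d", 1:30),
                      EUR = c(rep(0, 10), rep(0.07, 10), rep(0.2, 10)))
  est <- truth
  d <- detection_summary(est, truth)
  expect_equal(d$detected_fraction[d$bin == ">=10%"], 1)
  expect_equal(d$detected_fraction[d$bin == "<5%"], 0)
  expect_equal(d$n, c(10, 10, 10))
  est2 <- truth; est2$EUR <- 0
  d2 <- detection_summary(est2, truth)
  expect_equal(d2$detected_fraction[d2$bin == ">=10%"], 0)
})

test_that("Evanno delta-K peaks at a constructed kink", {
  # L(K) piecewise linear with a slope change at K = 6; constant spread
  ks <- 2:8
  mean_l <- ifelse(ks <= 6, -5000 + 200 * ks, -5000 + 200 * 6 + 50 * (ks - 6))
  runs <- do.call(rbind, lapply(seq_along(ks), function(i)
    data.frame(K = ks[i], lnP = mean_l[i] + c(-10, 0, 10))))
  tab <- evanno_delta_k(runs)
  expect_equal(attr(tab, "best_k"), 6)
  expect_equal(tab$abs_lpp[tab$K == 6], 150)
  # interior K away from the kink have zero second difference
  expect_equal(tab$delta_k[tab$K %in% c(3, 4, 5, 7)], rep(0, 4))

  # linear L(K): all delta_K zero
  lin <- do.call(rbind, lapply(ks, function(k)
    data.frame(K = k, lnP = -100 * k + c(-1, 1))))
  tab_lin <- evanno_delta_k(lin)
  expect_true(all(tab_lin$delta_k[!is.na(tab_lin$delta_k)] == 0))

  # invariance to adding a constant
  shifted <- runs; shifted$lnP <- shifted$lnP + 1234
  expect_equal(evanno_delta_k(shifted)$delta_k, tab$delta_k)

  # identical replicates: sd = 0 path is flagged
  const <- do.call(rbind, lapply(ks, function(k)
    data.frame(K = k, lnP = rep(-100 * k, 2))))
  expect_warning(tab0 <- evanno_delta_k(const), "sd")
  expect_true(all(is.na(tab0$delta_k)))

  expect_error(evanno_delta_k(data.frame(K = c(2, 2, 4, 4, 5, 5),
                                         lnP = 1:6)), "consecutive")
})

test_that("panel audit reproduces the published composition counts", {
  pan <- bt_binary_panel()
  audit <- panel_audit(pan)
  expect_equal(audit$n_total, 100)
  expect_equal(audit$per_group[["SAS"]], 20)
  expect_equal(audit$per_group[["AFR"]], 7)
  expect_equal(audit$per_group[["EUR"]], 15)
  expect_equal(audit$per_group[["EAS"]], 16)
  expect_equal(audit$per_group[["OCE"]], 13)
  expect_equal(audit$per_group[["AMR"]], 17)
  expect_equal(audit$per_group[["EURASIA"]], 12)
  expect_equal(audit$n_multi_panel, 28)
  expect_equal(audit$n_binary, 100)

  empty <- pan[0, ]
  a0 <- panel_audit(empty)
  expect_equal(a0$n_total, 0)
  expect_equal(a0$n_multi_panel, 0)

  dup <- rbind(pan, pan[1, ])
  expect_error(panel_audit(dup), "duplicate")
})

test_that("diplotype recoding is the alphabetical A/C/G/T map", {
  map <- diplotype_map(c("A", "C"), c("A", "G"))
  expect_equal(map, c(AA = "A", AG = "C", CA = "G", CG = "T"))
  expect_equal(diplotype_encode("AA", "CG", c("A", "C"), c("A", "G")), "AT")
  expect_equal(diplotype_encode("AA", "AA", c("A", "C"), c("A", "G")), "AA")
  expect_error(diplotype_encode("AA", NA, c("A", "C"), c("A", "G")),
               "phase")

  # all 10 unordered diplotype pairs map to distinct pseudo-genotypes
  haps <- names(map)
  pairs <- expand.grid(h1 = haps, h2 = haps, stringsAsFactors = FALSE)
  pairs <- pairs[as.integer(factor(pairs$h1, haps)) <=
                   as.integer(factor(pairs$h2, haps)), ]
  enc <- diplotype_encode(pairs$h1, pairs$h2, c("A", "C"), c("A", "G"))
  expect_equal(length(enc), 10)
  expect_equal(anyDuplicated(enc), 0)
  # decoding recovers the original haplotypes
  inverse <- stats::setNames(names(map), map)
  dec1 <- inverse[substr(enc, 1, 1)]
  dec2 <- inverse[substr(enc, 2, 2)]
  expect_true(all(paste(pmin(dec1, dec2), pmax(dec1, dec2)) ==
                    paste(pmin(pairs$h1, pairs$h2),
                          pmax(pairs$h1, pairs$h2))))

  expect_warning(m3 <- diplotype_map(c("A", "C", "G"), c("A", "T")),
                 "extended")
  expect_equal(length(m3), 6)
  expect_equal(anyDuplicated(m3), 0)
})
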