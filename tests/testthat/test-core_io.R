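# Data model, Snipper grid / STRUCTURE serialization, VCF decoding and
# frequency estimation.

test_that("genotype strings are canonicalized and validated", {
  expect_equal(canonical_genotype(c("GA", "AG", "TT", NA, "NN")),
               c("AG", "AG", "TT", NA, NA))
  gm <- tiny_gm()
  expect_equal(unname(gm$calls["S1", "rs3"]), "CT")
  bad <- rbind(S1 = c("AT", "CT", "AA"))  # T not declared at rs1
  colnames(bad) <- c("rs1", "rs2", "rs3")
  expect_error(genotype_matrix(bad, tiny_panel()), "declared")
  dup <- tiny_gm()$calls[c(1, 1), ]
  expect_error(genotype_matrix(dup, tiny_panel()), "duplicate")
})

test_that("snipper grid round-trips calls, labels and flags", {
  gm <- tiny_gm()
  path <- withr::local_tempfile(fileext = ".csv")
  write_snipper_grid(gm, path)
  first <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_equal(as.integer(first[1:3]), c(4L, 3L, 2L))
  back <- read_snipper_grid(path, panel = tiny_panel())
  expect_identical(back$calls, gm$calls)
  expect_identical(back$population, gm$population)
  expect_identical(back$training, gm$training)
})

test_that("snipper grid round-trips a 520-sample six-group matrix", {
  cfg <- synthetic_config(seed = 11)
  ref <- simulate_reference_set(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_snipper_grid(ref$reference, path)
  back <- read_snipper_grid(path, panel = ref$frequencies$loci)
  expect_identical(back$calls, ref$reference$calls)
  expect_identical(back$population, ref$reference$population)
  expect_identical(back$training, ref$reference$training)
})

test_that("grid header inconsistencies raise format errors", {
  gm <- tiny_gm()
  path <- withr::local_tempfile(fileext = ".csv")
  write_snipper_grid(gm, path)
  lines <- readLines(path)
  lines[1] <- sub("^4", "5", lines[1])  # claim 5 profiles, provide 4
  writeLines(lines, path)
  expect_error(read_snipper_grid(path), "5 profiles.*4 rows")
})

test_that("degenerate grids are handled", {
  empty <- genotype_matrix(
    matrix(character(0), 0, 3,
           dimnames = list(character(0), tiny_panel()$snp_id)),
    tiny_panel())
  path <- withr::local_tempfile(fileext = ".csv")
  write_snipper_grid(empty, path)
  expect_equal(as.integer(strsplit(readLines(path, n = 1), ",")[[1]][1:3]),
               c(0L, 3L, 0L))

  query <- tiny_gm()
  query$training[] <- 0L
  query$population[] <- NA_character_
  write_snipper_grid(query, path)
  expect_equal(as.integer(strsplit(readLines(path, n = 1), ",")[[1]][3]), 0L)
  back <- read_snipper_grid(path, panel = tiny_panel())
  expect_true(all(back$training == 0L))
  expect_true(all(is.na(back$population)))

  nocall <- tiny_gm()
  nocall$calls["S2", ] <- NA_character_
  expect_warning(write_snipper_grid(nocall, path), "S2")
  back <- read_snipper_grid(path, panel = tiny_panel())
  expect_true(all(is.na(back$calls["S2", ])))
})

test_that("structure export round-trips through an independent reader", {
  gm <- tiny_gm()
  path <- withr::local_tempfile()
  write_structure_input(gm, path)
  lines <- readLines(path)
  expect_length(lines, 1 + 2 * nrow(gm$calls))
  # missing cell of S2 at rs3 encoded -9 on both rows
  s2 <- lines[grepl("^S2 ", lines)]
  expect_true(all(grepl(" -9$", s2)))
  back <- read_structure_file(path)
  expect_identical(back$calls, gm$calls)
  expect_identical(unname(back$population), unname(gm$population))
  expect_identical(unname(back$training), unname(gm$training))

  ref <- small_study(seed = 12)$reference
  write_structure_input(ref, path)
  back <- read_structure_file(path)
  expect_identical(back$calls, ref$calls)
  expect_identical(unname(back$population), unname(ref$population))
})

test_that("VCF decoding matches hand-decoded genotypes", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path)
  expect_warning(gm <- read_vcf(path, vcf_test_panel()), "rs6")
  expect_equal(unname(gm$calls["S1", ]),
               c("AA", "GT", NA, "AG", "CC", NA, NA))
  expect_equal(unname(gm$calls["S2", ]),
               c("AG", "CC", "CC", NA, "AA", NA, NA))
  expect_true(all(gm$training == 0L))
})

test_that("frequency estimation follows the pseudo-count formula", {
  calls <- rbind(S1 = "AA", S2 = "AG")
  colnames(calls) <- "rs1"
  pan <- panel_spec("rs1", alleles = "A/G")
  gm <- genotype_matrix(calls, pan, population = c("P", "P"))
  ft0 <- estimate_frequencies(gm, smoothing = 0)
  expect_equal(ft0$freqs$rs1["A", "P"], 0.75)

  # 0 copies of G among 50 samples, s = 1, A = 2 -> 1/102
  calls50 <- matrix("AA", 50, 1,
                    dimnames = list(sprintf("S%02d", 1:50), "rs1"))
  gm50 <- genotype_matrix(calls50, pan, population = rep("P", 50))
  ft1 <- estimate_frequencies(gm50, smoothing = 1)
  expect_equal(ft1$freqs$rs1["G", "P"], 1 / 102)
  expect_true(all(unlist(ft1$freqs) > 0 & unlist(ft1$freqs) < 1))

  # a population with zero called chromosomes is an error only at s = 0
  gm_na <- genotype_matrix(rbind(S1 = NA_character_, S2 = "AG"),
                           pan, population = c("P1", "P2"))
  expect_error(estimate_frequencies(gm_na, smoothing = 0), "P1")
  expect_silent(estimate_frequencies(gm_na, smoothing = 1))
})

test_that("smoothed and unsmoothed estimates converge with sample size", {
  pan <- panel_spec("rs1", alleles = "A/G")
  f <- list(rs1 = matrix(c(0.5, 0.5), 2, 1,
                         dimnames = list(c("A", "G"), "P")))
  ft <- frequency_table(pan, "P", f)
  gm <- simulate_genotypes(ft, c(P = 500), seed = 5)
  p0 <- estimate_frequencies(gm, smoothing = 0)$freqs$rs1["A", "P"]
  p1 <- estimate_frequencies(gm, smoothing = 1)$freqs$rs1["A", "P"]
  expect_lt(abs(p0 - p1), 0.01)
})

test_that("frequency tables round-trip through TSV", {
  ft <- small_study(seed = 13)$frequencies
  path <- withr::local_tempfile(fileext = ".tsv")
  write_frequency_table(ft, path)
  back <- read_frequency_table(path, panel = ft$loci)
  expect_equal(back$freqs, ft$freqs, tolerance = 1e-12)
  expect_identical(back$populations, ft$populations)
})
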