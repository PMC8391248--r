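# Small fixtures built in code.

tiny_panel <- function() {
  panel_spec(
    snp_id = c("rs1", "rs2", "rs3"),
    chromosome = "1",
    position = c(100L, 200L, 300L),
    alleles = c("A/G", "C/T", "A/C/T"),
    target_group = c("AFR", "EUR", "EAS"))
}

tiny_gm <- function() {
  calls <- rbind(
    S1 = c("AA", "CT", "CT"),
    S2 = c("AG", "TT", NA),
    S3 = c("GG", "CC", "AA"),
    S4 = c("AA", "CT", "AC"))
  colnames(calls) <- c("rs1", "rs2", "rs3")
  genotype_matrix(calls, tiny_panel(),
                  population = c("AFR", "AFR", "EUR", NA),
                  training = c(1, 1, 1, 0))
}

# Two-population frequency table with fully opposed fixed alleles at
# `n_loci` biallelic markers (maximally separating panel).
fixed_difference_table <- function(n_loci = 10, eps = 0) {
  pan <- panel_spec(sprintf("rsF%03d", seq_len(n_loci)),
                    alleles = rep("A/G", n_loci),
                    target_group = "NONE")
  freqs <- lapply(seq_len(n_loci), function(i) {
    m <- cbind(POP1 = c(1 - eps, eps), POP2 = c(eps, 1 - eps))
    rownames(m) <- c("A", "G")
    m
  })
  names(freqs) <- pan$snp_id
  frequency_table(pan, c("POP1", "POP2"), freqs)
}

# Write a small hand-decodable VCF with 6 records and 2 samples.
write_test_vcf <- function(path) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT",
                  "\tS1\tS2"))
  rec <- c(
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
    "1\t200\trs2\tC\tT,G\t.\tPASS\t.\tGT\t1/2\t0/0",
    "1\t300\trs3\tT\tC\t.\tPASS\t.\tGT\t./.\t1|1",
    "1\t400\trs4\tG\tA\t.\tPASS\t.\tGT\t0/1\t./.",
    "1\t500\trs5\tA\tC\t.\tPASS\t.\tGT\t1/1\t0/0",
    "1\t600\trs6\tA\tT\t.\tPASS\t.\tGT\t0/1\t0/0")
  writeLines(c(hdr, rec), path)
  path
}

vcf_test_panel <- function() {
  panel_spec(
    snp_id = c("rs1", "rs2", "rs3", "rs4", "rs5", "rs6", "rs7"),
    chromosome = "1",
    position = c(100L, 200L, 300L, 400L, 500L, 600L, 700L),
    alleles = c("A/G", "C/G/T", "C/T", "A/G", "A/C", "A/G", "A/G"))
}

# A compact synthetic study for classifier/co-ancestry tests: scaled-down
# sample sizes, full default panel composition and divergence.
small_study <- function(seed = 101,
                        n_samples = c(AFR = 20, EUR = 20, EAS = 20,
                                      SAS = 20, OCE = 12, AMR = 16)) {
  cfg <- synthetic_config(n_samples = n_samples, seed = seed)
  simulate_reference_set(cfg)
}
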