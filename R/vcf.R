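# VCF genotype import restricted to a panel's loci.

#' Read panel genotypes from a VCF file
#'
#' Loads a VCF (via the vcfR package), matches records to panel loci by
#' chromosome + position first and rsID as a fallback, and decodes GT fields
#' against each record's REF/ALT alleles. Panel loci with no matching record
#' are recorded as missing for all samples. Records carrying an allele
#' outside the panel's declared allele set are flagged with a warning and
#' their calls set missing (no strand flipping is attempted). Phase is
#' discarded: genotypes are stored as unordered pairs.
#'
#' @param path VCF file path (plain or bgzipped).
#' @param panel a [panel_spec()].
#' @return a [genotype_matrix()] with all samples flagged 0 (query).
#' @export
read_vcf <- function(path, panel) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt) %||% character(0)
  al <- panel_alleles(panel)

  calls <- matrix(NA_character_, length(samples), nrow(panel),
                  dimnames = list(samples, panel$snp_id))
  key_pos <- paste(fix[, "CHROM"], fix[, "POS"])
  for (j in seq_len(nrow(panel))) {
    r <- which(key_pos == paste(panel$chromosome[j], panel$position[j]))
    if (!length(r)) r <- which(fix[, "ID"] == panel$snp_id[j])
    if (!length(r)) next   # unmatched locus stays MISSING
    r <- r[1]
    rec_alleles <- c(fix[r, "REF"],
                     strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]])
    rec_alleles <- rec_alleles[!is.na(rec_alleles) & nzchar(rec_alleles)]
    if (!all(rec_alleles %in% al[[j]])) {
      warning("VCF alleles (", paste(rec_alleles, collapse = ","),
              ") at locus ", panel$snp_id[j],
              " are not all in the panel allele set; calls set missing")
      next
    }
    g <- gt[r, ]
    ok <- !is.na(g) & !grepl("\\.", g)
    idx <- strsplit(g[ok], "[/|]")
    bad_len <- lengths(idx) != 2L
    if (any(bad_len)) stop("malformed VCF genotype at ", panel$snp_id[j])
    pairs <- vapply(idx, function(k) {
      a <- rec_alleles[as.integer(k) + 1L]
      if (anyNA(a)) stop("GT index outside ALT alleles at ", panel$snp_id[j])
      paste(sort(a), collapse = "")
    }, "")
    calls[names(g)[ok], j] <- pairs
  }
  genotype_matrix(calls, panel, population = NULL,
                  training = rep(0L, length(samples)))
}
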