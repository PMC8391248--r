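# Panel metadata: the marker table describing each ancestry-informative SNP.

#' Construct a SNP panel specification
#'
#' A panel is a data frame with one row per marker, carrying the rsID,
#' genomic coordinates (1-based, VCF convention), the declared allele set
#' (2 or 3 nucleotides), the population group the marker was selected to
#' differentiate, and the previously published AIM panels it appears in.
#'
#' @param snp_id character rsIDs (unique).
#' @param chromosome chromosome labels.
#' @param position 1-based integer positions.
#' @param alleles slash-separated allele strings, e.g. `"A/G"` or `"C/G/T"`.
#' @param target_group one of `AFR, EUR, EAS, SAS, OCE, AMR, EURASIA, NONE`.
#' @param source_panels semicolon-separated source-panel names (may be `""`).
#' @return a `data.frame` of class `panel_spec` with an `is_triallelic`
#'   logical column derived from the allele count.
#' @export
panel_spec <- function(snp_id, chromosome = NA_character_,
                       position = NA_integer_, alleles,
                       target_group = "NONE", source_panels = "") {
  n <- length(snp_id)
  pan <- data.frame(
    snp_id = as.character(snp_id),
    chromosome = rep_len(as.character(chromosome), n),
    position = rep_len(as.integer(position), n),
    alleles = rep_len(as.character(alleles), n),
    target_group = rep_len(as.character(target_group), n),
    source_panels = rep_len(as.character(source_panels), n),
    stringsAsFactors = FALSE
  )
  al <- split_alleles(pan$alleles)
  sizes <- lengths(al)
  if (any(sizes < 2 | sizes > 3))
    stop("each locus must declare 2 or 3 alleles")
  if (any(vapply(al, anyDuplicated, 0L) > 0))
    stop("declared alleles must be distinct")
  if (!all(unlist(al) %in% NUCLEOTIDES))
    stop("alleles must be nucleotide symbols A/C/G/T")
  if (anyDuplicated(pan$snp_id))
    stop("duplicate snp_id in panel: ",
         paste(unique(pan$snp_id[duplicated(pan$snp_id)]), collapse = ", "))
  bad <- setdiff(unique(pan$target_group), POPULATION_GROUPS)
  if (length(bad))
    stop("unknown target_group: ", paste(bad, collapse = ", "))
  pan$is_triallelic <- sizes == 3L
  class(pan) <- c("panel_spec", "data.frame")
  pan
}

#' Allele sets of a panel
#'
#' @param panel a `panel_spec`.
#' @return named list of character allele vectors, one per locus.
#' @export
panel_alleles <- function(panel) {
  al <- split_alleles(panel$alleles)
  names(al) <- panel$snp_id
  al
}

#' Composition of the published 100-SNP binary forensic ancestry panel
#'
#' The binary ancestry-informative SNPs of the VISAGE Basic Tool with their
#' target population groups and the established forensic AIM panels each was
#' sourced from (Kiddlab, PIAP, gAIMs, LACE, NAME, Eurasiaplex, Shriver,
#' Pacifiplex), packaged for composition audits.
#'
#' @return data frame with columns `snp_id`, `target_group`,
#'   `source_panels` (semicolon-separated) and `is_triallelic` (all FALSE).
#' @export
bt_binary_panel <- function() {
  path <- system.file("extdata", "visage_bt_binary_aims.tsv",
                      package = "aimkit", mustWork = TRUE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  d$is_triallelic <- FALSE
  d
}

#' Read a panel specification from TSV
#'
#' Expects columns `snp_id`, `alleles` and optionally `chromosome`,
#' `position`, `target_group`, `source_panels`.
#'
#' @param path file path.
#' @return a `panel_spec`.
#' @export
read_panel <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  panel_spec(
    snp_id = d$snp_id,
    chromosome = if ("chromosome" %in% names(d)) d$chromosome else NA,
    position = if ("position" %in% names(d)) as.integer(d$position) else NA,
    alleles = d$alleles,
    target_group = if ("target_group" %in% names(d)) d$target_group else "NONE",
    source_panels = if ("source_panels" %in% names(d)) d$source_panels else ""
  )
}
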