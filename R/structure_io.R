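# STRUCTURE two-row raw input export.
#
# One header line of locus names, then two rows per individual:
# <id> <pop-int> <popflag> <allele codes...>, with missing coded -9.
# The allele -> integer and population -> integer mappings are written to a
# sidecar legend TSV (path + ".legend.tsv").

#' Write a genotype matrix as STRUCTURE raw input
#'
#' @param gm a [genotype_matrix()].
#' @param path output path; the allele/population legend is written to
#'   `paste0(path, ".legend.tsv")`.
#' @return `path`, invisibly.
#' @export
write_structure_input <- function(gm, path) {
  al <- panel_alleles(gm$loci)
  pops <- sort(unique(gm$population[!is.na(gm$population)]))
  pop_code <- stats::setNames(seq_along(pops), pops)

  n <- nrow(gm$calls)
  m <- ncol(gm$calls)
  row1 <- matrix("-9", n, m)
  row2 <- matrix("-9", n, m)
  for (j in seq_len(m)) {
    g <- gm$calls[, j]
    ok <- !is.na(g)
    code <- stats::setNames(seq_along(al[[j]]), al[[j]])
    row1[ok, j] <- as.character(code[substr(g[ok], 1, 1)])
    row2[ok, j] <- as.character(code[substr(g[ok], 2, 2)])
  }
  popi <- ifelse(is.na(gm$population), 0L, pop_code[gm$population])
  lines <- character(1L + 2L * n)
  lines[1] <- paste(gm$loci$snp_id, collapse = " ")
  ids <- rownames(gm$calls)
  for (i in seq_len(n)) {
    pre <- paste(ids[i], popi[i], gm$training[i])
    lines[2 * i]     <- paste(pre, paste(row1[i, ], collapse = " "))
    lines[2 * i + 1] <- paste(pre, paste(row2[i, ], collapse = " "))
  }
  writeLines(lines, path)

  legend <- rbind(
    do.call(rbind, lapply(seq_len(m), function(j) {
      data.frame(kind = "allele", locus = gm$loci$snp_id[j],
                 symbol = al[[j]], code = seq_along(al[[j]]),
                 stringsAsFactors = FALSE)
    })),
    if (length(pops))
      data.frame(kind = "population", locus = "", symbol = pops,
                 code = unname(pop_code), stringsAsFactors = FALSE)
  )
  utils::write.table(legend, paste0(path, ".legend.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
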