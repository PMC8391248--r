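# Pairwise genotype-callset concordance auditing.

#' Compare two genotype call sets
#'
#' Samples and loci are matched by id; cells present in only one call set
#' are excluded (and listed). A cell is compared iff it is non-missing in
#' both sets; it is discordant iff the unordered allele multisets differ
#' (phase is ignored; half-calls are treated as no-calls upstream). No-call
#' tallies are per call set over the shared cells. Percentages are reported
#' at full precision with half-up 2-decimal rounding for display.
#'
#' @param a,b [genotype_matrix()] objects.
#' @return an object of class `concordance_report`: list with `per_locus`
#'   (data frame: locus, n_compared, n_discordant, n_nocall_a, n_nocall_b),
#'   `per_sample` (sample, n_discordant), totals, `concordance_pct`,
#'   `nocall_pct_a`, `nocall_pct_b`, a `display` list of rounded
#'   percentages, and the excluded sample/locus ids.
#' @export
compare_callsets <- function(a, b) {
  ss <- intersect(rownames(a$calls), rownames(b$calls))
  sl <- intersect(colnames(a$calls), colnames(b$calls))
  if (!length(ss)) stop("no shared samples between the call sets")
  if (!length(sl)) stop("no shared loci between the call sets")
  ca <- a$calls[ss, sl, drop = FALSE]
  cb <- b$calls[ss, sl, drop = FALSE]
  comparable <- !is.na(ca) & !is.na(cb)
  discordant <- comparable & ca != cb
  per_locus <- data.frame(
    locus = sl,
    n_compared = colSums(comparable),
    n_discordant = colSums(discordant),
    n_nocall_a = colSums(is.na(ca)),
    n_nocall_b = colSums(is.na(cb)),
    stringsAsFactors = FALSE)
  rownames(per_locus) <- NULL
  per_sample <- data.frame(sample = ss,
                           n_discordant = rowSums(discordant),
                           stringsAsFactors = FALSE)
  rownames(per_sample) <- NULL
  total_compared <- sum(comparable)
  total_discordant <- sum(discordant)
  ncells <- length(ca)
  conc <- if (total_compared > 0)
    100 * (1 - total_discordant / total_compared) else NA_real_
  na_a <- 100 * sum(is.na(ca)) / ncells
  na_b <- 100 * sum(is.na(cb)) / ncells
  structure(list(per_locus = per_locus,
                 per_sample = per_sample,
                 total_compared = total_compared,
                 total_discordant = total_discordant,
                 concordance_pct = conc,
                 nocall_pct_a = na_a,
                 nocall_pct_b = na_b,
                 display = list(concordance_pct = round_half_up(conc, 2),
                                nocall_pct_a = round_half_up(na_a, 2),
                                nocall_pct_b = round_half_up(na_b, 2)),
                 excluded_samples_a = setdiff(rownames(a$calls), ss),
                 excluded_samples_b = setdiff(rownames(b$calls), ss),
                 excluded_loci_a = setdiff(colnames(a$calls), sl),
                 excluded_loci_b = setdiff(colnames(b$calls), sl)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("concordance_report:", nrow(x$per_sample), "shared samples x",
      nrow(x$per_locus), "shared loci\n")
  cat("compared:", x$total_compared, " discordant:", x$total_discordant,
      " concordance:", sprintf("%.2f%%", x$display$concordance_pct), "\n")
  cat("no-calls: ", sprintf("%.2f%%", x$display$nocall_pct_a), " (A)  ",
      sprintf("%.2f%%", x$display$nocall_pct_b), " (B)\n", sep = "")
  invisible(x)
}

#' Flag loci with outlying discordance counts
#'
#' @param report a [compare_callsets()] result.
#' @param threshold minimum discordant count to flag.
#' @return data frame of flagged loci sorted by descending discordance
#'   count (ties broken by ascending rsID), with a `discordancy_pct` column
#'   (discordant / compared, full precision).
#' @export
flag_outlier_loci <- function(report, threshold) {
  pl <- report$per_locus
  keep <- pl[pl$n_discordant >= threshold, , drop = FALSE]
  keep <- keep[order(-keep$n_discordant, keep$locus), , drop = FALSE]
  keep$discordancy_pct <- ifelse(keep$n_compared > 0,
                                 100 * keep$n_discordant / keep$n_compared,
                                 NA_real_)
  rownames(keep) <- NULL
  keep
}
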