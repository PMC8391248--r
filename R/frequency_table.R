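# Per-locus, per-population allele-frequency tables.

#' Construct a frequency table
#'
#' @param loci a [panel_spec()].
#' @param populations ordered population labels.
#' @param freqs named list (by `snp_id`) of allele x population matrices;
#'   each column a probability vector over the locus's declared alleles.
#' @param n_chrom loci x population matrix of chromosomes counted (>= 0);
#'   0 is used for theoretical (simulated) frequencies.
#' @return an object of class `frequency_table`.
#' @export
frequency_table <- function(loci, populations, freqs, n_chrom = NULL) {
  populations <- as.character(populations)
  if (length(populations) < 1L) stop("at least one population required")
  if (!identical(names(freqs), loci$snp_id))
    stop("freqs must be a list named by loci$snp_id, in order")
  al <- panel_alleles(loci)
  for (id in loci$snp_id) {
    f <- freqs[[id]]
    if (!is.matrix(f) || !identical(rownames(f), al[[id]]) ||
        !identical(colnames(f), populations))
      stop("freqs[['", id, "']] must be an allele x population matrix with ",
           "rownames the declared alleles and colnames the populations")
    if (any(f < 0) || any(abs(colSums(f) - 1) > 1e-9))
      stop("frequency vectors at ", id,
           " must be non-negative and sum to 1")
  }
  if (is.null(n_chrom))
    n_chrom <- matrix(0, nrow(loci), length(populations),
                      dimnames = list(loci$snp_id, populations))
  stopifnot(all(n_chrom >= 0))
  structure(list(loci = loci, populations = populations, freqs = freqs,
                 n_chrom = n_chrom),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat("frequency_table:", nrow(x$loci), "loci x", length(x$populations),
      "populations (", paste(x$populations, collapse = ", "), ")\n")
  invisible(x)
}

#' Restrict a frequency table to a subset of reference populations
#'
#' Used to run co-ancestry estimation against a reduced reference (e.g.
#' K = 4 continental clusters instead of the full six-group reference).
#'
#' @param ft a [frequency_table()].
#' @param populations populations to keep, in the requested order.
#' @return a [frequency_table()].
#' @export
select_populations <- function(ft, populations) {
  if (!all(populations %in% ft$populations))
    stop("population(s) not in table: ",
         paste(setdiff(populations, ft$populations), collapse = ", "))
  freqs <- lapply(ft$freqs, function(f) f[, populations, drop = FALSE])
  frequency_table(ft$loci, populations, freqs,
                  ft$n_chrom[, populations, drop = FALSE])
}

#' Estimate population allele frequencies from reference genotypes
#'
#' Counts alleles among training samples (flag 1) of each population and
#' converts them to frequencies with an optional pseudo-count per allele:
#' `freq(a) = (count(a) + s) / (2 * N_called + s * A)` where `A` is the
#' number of declared alleles at the locus. With `smoothing = 0` this is the
#' plain maximum-likelihood estimate; any `s > 0` keeps every frequency
#' strictly inside (0, 1), which the naive-Bayes classifier requires.
#' Missing calls are excluded from `N_called`.
#'
#' @param gm a [genotype_matrix()]; every training sample must be labeled.
#' @param smoothing pseudo-count per allele, `s >= 0` (default 0).
#' @return a [frequency_table()].
#' @export
estimate_frequencies <- function(gm, smoothing = 0) {
  stopifnot(smoothing >= 0)
  train <- gm$training == 1L
  if (any(train & is.na(gm$population)))
    stop("every training sample must have a population label")
  if (!any(train))
    stop("no training samples to estimate frequencies from")
  pops <- unique(gm$population[train])
  al <- panel_alleles(gm$loci)
  counts <- allele_counts(gm)
  freqs <- vector("list", nrow(gm$loci))
  names(freqs) <- gm$loci$snp_id
  n_chrom <- matrix(0L, nrow(gm$loci), length(pops),
                    dimnames = list(gm$loci$snp_id, pops))
  for (id in gm$loci$snp_id) {
    cm <- counts[[id]]
    n2 <- colSums(cm)
    n_chrom[id, ] <- n2
    if (smoothing == 0 && any(n2 == 0))
      stop("undefined frequency: population ",
           paste(pops[n2 == 0], collapse = ", "), " has zero called ",
           "chromosomes at locus ", id, " and smoothing is 0")
    A <- length(al[[id]])
    freqs[[id]] <- sweep(cm + smoothing, 2, n2 + smoothing * A, "/")
  }
  frequency_table(gm$loci, pops, freqs, n_chrom)
}

# Allele counts per locus: named list of allele x population integer
# matrices over training samples. Internal.
allele_counts <- function(gm) {
  train <- which(gm$training == 1L)
  pops <- unique(gm$population[train])
  al <- panel_alleles(gm$loci)
  pop_of <- gm$population[train]
  out <- vector("list", nrow(gm$loci))
  names(out) <- gm$loci$snp_id
  for (j in seq_len(ncol(gm$calls))) {
    id <- gm$loci$snp_id[j]
    cm <- matrix(0L, length(al[[id]]), length(pops),
                 dimnames = list(al[[id]], pops))
    g <- gm$calls[train, j]
    ok <- !is.na(g)
    if (any(ok)) {
      a1 <- substr(g[ok], 1, 1)
      a2 <- substr(g[ok], 2, 2)
      tab <- table(factor(c(a1, a2), levels = al[[id]]),
                   factor(rep(pop_of[ok], 2), levels = pops))
      cm <- cm + unclass(tab)
    }
    out[[id]] <- cm
  }
  out
}

#' Write a frequency table as TSV
#'
#' Long format with columns `locus`, `population`, `allele`, `frequency`,
#' `n_chrom`.
#'
#' @param ft a [frequency_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(ft, path) {
  rows <- do.call(rbind, lapply(ft$loci$snp_id, function(id) {
    f <- ft$freqs[[id]]
    data.frame(locus = id,
               population = rep(colnames(f), each = nrow(f)),
               allele = rep(rownames(f), ncol(f)),
               frequency = as.vector(f),
               n_chrom = rep(ft$n_chrom[id, ], each = nrow(f)),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a frequency table from TSV
#'
#' Inverse of [write_frequency_table()]. Loci are reconstructed in file
#' order; panel metadata (coordinates, target groups) not present in the
#' file are left unset unless a `panel` is supplied.
#'
#' @param path TSV path.
#' @param panel optional [panel_spec()] supplying locus metadata.
#' @return a [frequency_table()].
#' @export
read_frequency_table <- function(path, panel = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  loci_ids <- unique(d$locus)
  pops <- unique(d$population)
  if (is.null(panel)) {
    alleles <- vapply(loci_ids, function(id) {
      paste(sort(unique(d$allele[d$locus == id])), collapse = "/")
    }, "")
    panel <- panel_spec(loci_ids, alleles = alleles)
  } else {
    panel <- panel[match(loci_ids, panel$snp_id), , drop = FALSE]
  }
  al <- panel_alleles(panel)
  freqs <- lapply(loci_ids, function(id) {
    sub <- d[d$locus == id, ]
    f <- matrix(0, length(al[[id]]), length(pops),
                dimnames = list(al[[id]], pops))
    f[cbind(sub$allele, sub$population)] <- sub$frequency
    f
  })
  names(freqs) <- loci_ids
  n_chrom <- matrix(0, length(loci_ids), length(pops),
                    dimnames = list(loci_ids, pops))
  first <- d[!duplicated(d[c("locus", "population")]), ]
  n_chrom[cbind(first$locus, first$population)] <- first$n_chrom
  frequency_table(panel, pops, freqs, n_chrom)
}
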