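# The genotype matrix: samples x loci unordered allele pairs with
# population labels and training (POPFLAG) indicators.

#' Construct a genotype matrix
#'
#' Calls are stored as canonical two-character genotype strings (alleles
#' sorted alphabetically, so `"AG"` and `"GA"` are the same genotype) with
#' `NA` for missing. Each sample carries an optional population label and a
#' 0/1 training flag (the POPFLAG convention: 1 marks reference profiles
#' whose genotypes update population allele frequencies, 0 marks queries).
#'
#' @param calls character matrix (samples x loci) of genotype strings;
#'   rownames are sample ids, colnames must match `loci$snp_id`.
#' @param loci a [panel_spec()] describing the loci, in column order.
#' @param population per-sample population label (`NA` = unknown).
#' @param training per-sample 0/1 flag; defaults to 1 where a population
#'   label is present, 0 otherwise.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, loci, population = NULL, training = NULL) {
  stopifnot(is.matrix(calls))
  if (nrow(calls) > 0 && is.null(rownames(calls)))
    stop("calls must have sample ids as rownames")
  if (nrow(calls) == 0 && is.null(rownames(calls)))
    rownames(calls) <- character(0)
  if (anyDuplicated(rownames(calls)))
    stop("duplicate sample ids")
  if (ncol(calls) != nrow(loci))
    stop("calls has ", ncol(calls), " columns but loci describes ",
         nrow(loci), " markers")
  if (is.null(colnames(calls))) colnames(calls) <- loci$snp_id
  if (!identical(colnames(calls), loci$snp_id))
    stop("colnames(calls) must match loci$snp_id in order")

  storage.mode(calls) <- "character"
  calls[] <- canonical_genotype(calls)

  n <- nrow(calls)
  population <- if (is.null(population)) rep(NA_character_, n)
                else as.character(rep_len(population, n))
  population[!is.na(population) & !nzchar(population)] <- NA_character_
  training <- if (is.null(training)) as.integer(!is.na(population))
              else as.integer(rep_len(training, n))
  if (!all(training %in% c(0L, 1L)))
    stop("training flag must be 0 or 1 for every sample")

  al <- panel_alleles(loci)
  for (j in seq_len(ncol(calls))) {
    g <- calls[, j]
    ok <- is.na(g) | g %in% all_genotypes(al[[j]])
    if (!all(ok))
      stop("call with allele outside the declared set at locus ",
           loci$snp_id[j], ": ", paste(unique(g[!ok]), collapse = ", "))
  }

  structure(list(calls = calls, loci = loci,
                 population = stats::setNames(population, rownames(calls)),
                 training = stats::setNames(training, rownames(calls))),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "samples x", ncol(x$calls),
      "loci\n")
  pops <- table(x$population[x$training == 1L], useNA = "no")
  if (length(pops)) {
    cat("reference populations:\n")
    print(pops)
  }
  cat("query profiles (flag 0):", sum(x$training == 0L), "\n")
  cat("missing calls:", sum(is.na(x$calls)), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by samples and/or loci
#'
#' @param x a `genotype_matrix`.
#' @param i sample index (ids, logical or integer).
#' @param j locus index.
#' @param ... unused.
#' @return a `genotype_matrix`.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  calls <- x$calls[i, j, drop = FALSE]
  loci <- x$loci[match(colnames(calls), x$loci$snp_id), , drop = FALSE]
  rownames(loci) <- NULL
  genotype_matrix(calls, loci,
                  population = x$population[rownames(calls)],
                  training = x$training[rownames(calls)])
}

#' Sample ids of a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return character vector.
#' @export
sample_ids <- function(gm) rownames(gm$calls)
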