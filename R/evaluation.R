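# Downstream evaluation: percentile comparison of co-ancestry estimates,
# detection summaries, Evanno delta-K, panel composition audits and 2-SNP
# diplotype recoding.

#' Compare two sets of co-ancestry estimates in 10-percentile bins
#'
#' Samples are sorted by method A's `sort_component` proportion (ties by
#' sample id) and split into `n_bins` near-equal bins (remainders go to the
#' earliest bins). Per-bin means of every component are computed for both
#' methods, and a per-component goodness-of-fit is reported as the r-squared
#' of the ordinary least-squares regression of method B on method A over
#' individuals (the squared Pearson correlation).
#'
#' @param qa,qb data frames from [estimate_admixture()] (or any frame with
#'   a `sample` column and one numeric column per component); same samples.
#' @param sort_component component (column name) to sort on, typically the
#'   cohort's expected major co-ancestry.
#' @param n_bins number of percentile bins (default 10).
#' @return an object of class `percentile_comparison`: list with
#'   `bin_means` (bin x component means for both methods), `r2` (named, per
#'   component), `regression` (per-component OLS slope/intercept of B on A)
#'   and `bins` (per-sample bin assignment).
#' @export
percentile_compare <- function(qa, qb, sort_component, n_bins = 10) {
  comp <- setdiff(intersect(names(qa), names(qb)),
                  c("sample", "method", "converged"))
  if (!sort_component %in% comp)
    stop("sort_component must be a shared component column")
  if (!setequal(qa$sample, qb$sample))
    stop("qa and qb must contain the same samples")
  qb <- qb[match(qa$sample, qb$sample), , drop = FALSE]
  n <- nrow(qa)
  if (n < n_bins)
    warning("fewer samples (", n, ") than bins (", n_bins,
            "): bins of size <= 1")
  ord <- order(qa[[sort_component]], qa$sample)
  sizes <- rep(n %/% n_bins, n_bins)
  rem <- n %% n_bins
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  bin <- rep(seq_len(n_bins), sizes)[seq_len(n)]
  bins <- data.frame(sample = qa$sample[ord], bin = bin,
                     stringsAsFactors = FALSE)
  bin_of <- bins$bin[match(qa$sample, bins$sample)]

  bin_means <- do.call(rbind, lapply(seq_len(n_bins), function(bb) {
    idx <- bin_of == bb
    if (!any(idx)) return(NULL)
    data.frame(bin = bb, component = comp,
               mean_a = vapply(comp, function(cc) mean(qa[[cc]][idx]), 0),
               mean_b = vapply(comp, function(cc) mean(qb[[cc]][idx]), 0),
               n = sum(idx), stringsAsFactors = FALSE)
  }))
  rownames(bin_means) <- NULL

  r2 <- vapply(comp, function(cc) {
    x <- qa[[cc]]; y <- qb[[cc]]
    if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
    stats::cor(x, y)^2
  }, 0)
  regression <- do.call(rbind, lapply(comp, function(cc) {
    x <- qa[[cc]]; y <- qb[[cc]]
    if (stats::var(x) == 0)
      return(data.frame(component = cc, slope = NA_real_,
                        intercept = NA_real_, stringsAsFactors = FALSE))
    fit <- stats::lm(y ~ x)
    data.frame(component = cc, slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               stringsAsFactors = FALSE)
  }))
  structure(list(bin_means = bin_means, r2 = r2, regression = regression,
                 bins = bins),
            class = "percentile_comparison")
}

#' @export
print.percentile_comparison <- function(x, ...) {
  cat("percentile_comparison over", max(x$bins$bin), "bins\n")
  cat("per-component r-squared:\n")
  print(round(x$r2, 4))
  invisible(x)
}

#' Minor co-ancestry detection summary
#'
#' Bins individuals by their true proportion of each component (`< 5%`,
#' `5-10%`, `>= 10%` by default) and reports the fraction whose estimated
#' component reaches the detection threshold. The `>= 10%` bin is the
#' operating range in which small balanced AIM panels are expected to
#' report co-ancestry reliably.
#'
#' @param estimates,truth data frames with a `sample` column and one numeric
#'   column per component; same samples.
#' @param detect_at estimated proportion counted as detected (default 0.05).
#' @param breaks truth-bin boundaries (default `c(0.05, 0.10)`).
#' @return data frame: `component`, `bin`, `n`, `detected_fraction`.
#' @export
detection_summary <- function(estimates, truth, detect_at = 0.05,
                              breaks = c(0.05, 0.10)) {
  comp <- setdiff(intersect(names(estimates), names(truth)),
                  c("sample", "method", "converged"))
  if (!setequal(estimates$sample, truth$sample))
    stop("estimates and truth must contain the same samples")
  truth <- truth[match(estimates$sample, truth$sample), , drop = FALSE]
  labs <- c(paste0("<", 100 * breaks[1], "%"),
            paste0(100 * breaks[1], "-", 100 * breaks[2], "%"),
            paste0(">=", 100 * breaks[2], "%"))
  out <- do.call(rbind, lapply(comp, function(cc) {
    tr <- truth[[cc]]
    bin <- cut(tr, c(-Inf, breaks, Inf), labels = labs, right = FALSE)
    det <- estimates[[cc]] >= detect_at
    agg <- lapply(labs, function(l) {
      idx <- bin == l
      data.frame(component = cc, bin = l, n = sum(idx),
                 detected_fraction = if (any(idx)) mean(det[idx])
                                     else NA_real_,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, agg)
  }))
  rownames(out) <- NULL
  out
}

#' Evanno delta-K from replicate clustering log-probabilities
#'
#' Given replicate log-probabilities `L(K)` for a consecutive range of K,
#' computes the mean and standard deviation per K, the first difference of
#' means `L'(K)`, the absolute second difference `|L''(K)|`, and
#' `delta_K = |L''(K)| / sd(L(K))`, defined for interior K with positive
#' replicate standard deviation. Invariant to adding a constant to all
#' log-probabilities.
#'
#' @param runs data frame with columns `K` (integer) and `lnP` (replicate
#'   log-probability); at least 3 consecutive K values with at least 2
#'   replicates each.
#' @return data frame: `K`, `n_rep`, `mean_lnp`, `sd_lnp`, `lprime`,
#'   `abs_lpp`, `delta_k`; attribute `best_k` is the interior K maximizing
#'   `delta_k`. K values where `sd = 0` get `delta_k = NA` with a warning.
#' @export
evanno_delta_k <- function(runs) {
  stopifnot(all(c("K", "lnP") %in% names(runs)))
  ks <- sort(unique(runs$K))
  if (length(ks) < 3L) stop("at least 3 K values required")
  if (!all(diff(ks) == 1L)) stop("K values must be consecutive")
  n_rep <- vapply(ks, function(k) sum(runs$K == k), 0L)
  if (any(n_rep < 2L)) stop("at least 2 replicates required per K")
  m <- vapply(ks, function(k) mean(runs$lnP[runs$K == k]), 0)
  s <- vapply(ks, function(k) stats::sd(runs$lnP[runs$K == k]), 0)
  nk <- length(ks)
  lprime <- c(NA, diff(m))
  abs_lpp <- rep(NA_real_, nk)
  abs_lpp[2:(nk - 1)] <- abs(m[3:nk] - 2 * m[2:(nk - 1)] + m[1:(nk - 2)])
  delta_k <- abs_lpp / s
  if (any(s == 0 & !is.na(abs_lpp))) {
    warning("sd(L(K)) = 0 at K = ",
            paste(ks[s == 0 & !is.na(abs_lpp)], collapse = ", "),
            ": delta_K undefined there")
    delta_k[s == 0] <- NA_real_
  }
  out <- data.frame(K = ks, n_rep = n_rep, mean_lnp = m, sd_lnp = s,
                    lprime = lprime, abs_lpp = abs_lpp, delta_k = delta_k)
  interior <- which(!is.na(out$delta_k))
  attr(out, "best_k") <- if (length(interior))
    out$K[interior[which.max(out$delta_k[interior])]] else NA_integer_
  out
}

#' Audit the composition of an AIM panel
#'
#' Counts markers per target group, markers selected by two or more source
#' panels, and binary vs tri-allelic totals.
#'
#' @param panel data frame with columns `snp_id`, `target_group`,
#'   `source_panels` (semicolon-separated) and optionally `is_triallelic`.
#' @return list with `per_group` (named counts), `n_multi_panel`, `n_binary`,
#'   `n_triallelic` and `n_total`.
#' @export
panel_audit <- function(panel) {
  if (anyDuplicated(panel$snp_id))
    stop("duplicate rsID in panel: ",
         paste(unique(panel$snp_id[duplicated(panel$snp_id)]),
               collapse = ", "))
  src <- split_panels(panel$source_panels)
  tri <- if ("is_triallelic" %in% names(panel)) panel$is_triallelic
         else lengths(split_alleles(panel$alleles)) == 3L
  per_group <- table(factor(panel$target_group,
                            levels = unique(panel$target_group)))
  list(per_group = stats::setNames(as.integer(per_group),
                                   names(per_group)),
       n_multi_panel = sum(lengths(src) >= 2L),
       n_binary = sum(!tri),
       n_triallelic = sum(tri),
       n_total = nrow(panel))
}

#' Alphabetical diplotype-to-nucleotide recoding map
#'
#' The haplotype combinations of a 2-SNP pair are sorted alphabetically and
#' mapped onto A, C, G, T in order (so for allele sets (A,C) x (A,G):
#' AA -> A, AG -> C, CA -> G, CG -> T). Pairs with more than four
#' combinations (a tri-allelic member) extend the mapping alphabetically
#' through the remaining letters, with a warning.
#'
#' @param alleles1,alleles2 declared allele vectors of the two SNPs.
#' @return named character vector: haplotype combination -> recoded symbol.
#' @export
diplotype_map <- function(alleles1, alleles2) {
  combos <- sort(as.vector(outer(alleles1, alleles2, paste0)))
  symbols <- c("A", "C", "G", "T")
  if (length(combos) > 4L) {
    warning(length(combos), " haplotype combinations: recoding extended ",
            "beyond A/C/G/T alphabetically")
    symbols <- c(symbols, setdiff(LETTERS, symbols))
  }
  stats::setNames(symbols[seq_along(combos)], combos)
}

#' Recode phased 2-SNP diplotypes as pseudo-SNP genotypes
#'
#' Each individual supplies two phased haplotypes, each written as the
#' allele at the first SNP followed by the allele at the second (e.g.
#' `"AG"`). The two haplotypes are recoded through [diplotype_map()] and
#' returned as a canonical unordered pseudo-genotype, so a 2-SNP
#' microhaplotype behaves like a single multi-allelic marker.
#'
#' @param hap1,hap2 character vectors of phased haplotypes (one pair per
#'   individual); `NA` is rejected — phase must be resolved upstream.
#' @param alleles1,alleles2 declared allele vectors of the two SNPs.
#' @return character vector of canonical pseudo-genotypes.
#' @export
diplotype_encode <- function(hap1, hap2, alleles1, alleles2) {
  if (anyNA(hap1) || anyNA(hap2))
    stop("unphased or missing haplotypes: phase must be resolved before ",
         "diplotype encoding")
  map <- diplotype_map(alleles1, alleles2)
  bad <- setdiff(c(hap1, hap2), names(map))
  if (length(bad))
    stop("haplotype(s) not over the declared alleles: ",
         paste(bad, collapse = ", "))
  canonical_genotype(paste0(map[hap1], map[hap2]))
}
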