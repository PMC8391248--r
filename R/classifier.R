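# Snipper-style naive-Bayes ancestry classification.
#
# Under Hardy-Weinberg proportions within each reference population, a
# profile's likelihood for population k is the product over loci of the
# genotype probability (p_a^2 for homozygotes, 2 p_a p_b for
# heterozygotes). Populations are ranked by posterior (uniform priors by
# default) and the strength of assignment is reported as the Bayes
# likelihood ratio between the best and second-best population.

#' Log-likelihood of one genotype under Hardy-Weinberg proportions
#'
#' @param call canonical two-character genotype string (e.g. `"AG"`).
#' @param freq_vector named allele-frequency vector for one population;
#'   every frequency for a called allele must be positive (use smoothed
#'   frequencies).
#' @return scalar log-probability (nats).
#' @export
genotype_log_likelihood <- function(call, freq_vector) {
  a <- c(substr(call, 1, 1), substr(call, 2, 2))
  if (!all(a %in% names(freq_vector)))
    stop("called allele outside the frequency vector's allele set")
  p <- freq_vector[a]
  if (any(p <= 0))
    stop("zero frequency for a called allele; estimate frequencies with ",
         "smoothing > 0 before classifying")
  if (a[1] == a[2]) 2 * log(p[[1]]) else log(2) + log(p[[1]]) + log(p[[2]])
}

# Per-population log-likelihood of a profile (named call vector) over the
# non-missing loci of a frequency table. Internal; vectorized across
# populations.
profile_log_likelihood <- function(calls, ft) {
  pops <- ft$populations
  ll <- stats::setNames(numeric(length(pops)), pops)
  used <- 0L
  for (id in names(calls)) {
    g <- calls[[id]]
    if (is.na(g)) next
    f <- ft$freqs[[id]]
    if (is.null(f)) next
    a1 <- substr(g, 1, 1); a2 <- substr(g, 2, 2)
    p1 <- f[a1, ]; p2 <- f[a2, ]
    if (any(p1 <= 0) || any(p2 <= 0))
      stop("zero frequency for a called allele at ", id,
           "; estimate frequencies with smoothing > 0")
    ll <- ll + if (a1 == a2) 2 * log(p1) else log(2) + log(p1) + log(p2)
    used <- used + 1L
  }
  list(loglik = ll, loci_used = used)
}

# Render the Snipper-style verbose strength statement for a likelihood
# ratio given on the log scale.
verbose_statement <- function(log_lr, best, second) {
  if (log_lr == 0)
    return(paste0("The profile is equally likely to be from ", best,
                  " and ", second, " (likelihood ratio 1)."))
  phrase <- if (log_lr >= log(1e9)) "more than 1 billion times"
    else if (log_lr >= log(1e6)) "more than 1 million times"
    else if (log_lr >= log(1e3)) "more than 1,000 times"
    else paste0(signif(exp(log_lr), 3), " times")
  paste0("The profile is ", phrase, " more likely to be from ", best,
         " than from ", second, ".")
}

#' Classify one profile against reference allele frequencies
#'
#' @param calls named character vector of canonical genotype strings by
#'   snp_id (`NA` = missing); missing loci are skipped and counted.
#' @param ft a smoothed [frequency_table()].
#' @param priors optional named per-population prior probabilities
#'   (default uniform).
#' @return an object of class `classification_result`: list with
#'   `log_likelihood` (per population, nats, priors included), `ranking`,
#'   `best`, `second`, `log_lr`, `lr_best_vs_second`, `loci_used`,
#'   `loci_missing` and `verbose_statement`.
#' @export
classify_profile <- function(calls, ft, priors = NULL) {
  pops <- ft$populations
  if (is.null(priors)) {
    priors <- stats::setNames(rep(1 / length(pops), length(pops)), pops)
  } else {
    if (!all(pops %in% names(priors))) stop("priors must cover all populations")
    priors <- priors[pops] / sum(priors[pops])
  }
  pl <- profile_log_likelihood(calls, ft)
  if (pl$loci_used == 0L) stop("all loci missing: nothing to classify")
  post <- pl$loglik + log(priors)
  ord <- order(-post, pops)
  best <- pops[ord[1]]; second <- pops[ord[2]]
  log_lr <- post[[ord[1]]] - post[[ord[2]]]
  structure(list(log_likelihood = post,
                 ranking = pops[ord],
                 best = best, second = second,
                 log_lr = log_lr,
                 lr_best_vs_second = exp(log_lr),
                 loci_used = pl$loci_used,
                 loci_missing = length(calls) - pl$loci_used,
                 verbose_statement = verbose_statement(log_lr, best, second)),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(x$verbose_statement, "\n")
  cat("loci used:", x$loci_used, " log LR:", round(x$log_lr, 3), "\n")
  invisible(x)
}

#' Classify every sample of a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param ft a smoothed [frequency_table()].
#' @param priors optional named priors (default uniform).
#' @return data frame, one row per sample: per-population log-likelihood
#'   columns (`loglik_<POP>`), `best`, `second`, `log_lr`, `lr`,
#'   `loci_used`, `verbose`.
#' @export
classify <- function(gm, ft, priors = NULL) {
  res <- lapply(sample_ids(gm), function(s) {
    r <- classify_profile(stats::setNames(gm$calls[s, ],
                                          colnames(gm$calls)), ft, priors)
    c(list(sample = s),
      stats::setNames(as.list(r$log_likelihood),
                      paste0("loglik_", names(r$log_likelihood))),
      list(best = r$best, second = r$second, log_lr = r$log_lr,
           lr = r$lr_best_vs_second, loci_used = r$loci_used,
           verbose = r$verbose_statement))
  })
  out <- do.call(rbind, lapply(res, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Leave-one-out cross-validation of a reference dataset
#'
#' For each training sample, population allele frequencies are re-estimated
#' with that sample excluded, the sample is classified against the reduced
#' reference, and the assignments are tallied into a confusion matrix with
#' per-group and overall correct-classification percentages. Deterministic.
#'
#' @param gm a [genotype_matrix()]; every training sample must be labeled
#'   and at least two groups present.
#' @param smoothing pseudo-count per allele used when re-estimating
#'   frequencies (default 1, so folds that empty a group remain computable).
#' @param priors optional named priors (default uniform).
#' @return an object of class `crossval_report`: list with `confusion`
#'   (true x assigned matrix), `per_group_pct`, `overall_pct`, `results`
#'   (per-sample data frame) and `unclassifiable` (sample ids whose fold
#'   errored).
#' @export
loo_crossval <- function(gm, smoothing = 1, priors = NULL) {
  train <- which(gm$training == 1L)
  if (any(is.na(gm$population[train])))
    stop("every training sample must have a population label")
  pops <- sort(unique(gm$population[train]))
  if (length(pops) < 2L) stop("at least two groups required")
  counts <- allele_counts(gm)
  al <- panel_alleles(gm$loci)
  loci_ids <- gm$loci$snp_id

  if (is.null(priors)) {
    priors <- stats::setNames(rep(1 / length(pops), length(pops)), pops)
  } else priors <- priors[pops] / sum(priors[pops])

  # Pre-smooth counts once; per fold only the sample's own column changes.
  freq_full <- lapply(loci_ids, function(id) {
    cm <- counts[[id]][, pops, drop = FALSE]
    sweep(cm + smoothing, 2, colSums(cm) + smoothing * nrow(cm), "/")
  })
  names(freq_full) <- loci_ids

  results <- vector("list", length(train))
  unclassifiable <- character(0)
  for (ii in seq_along(train)) {
    i <- train[ii]
    s <- rownames(gm$calls)[i]
    k <- gm$population[i]
    ll <- stats::setNames(log(priors), pops)
    used <- 0L
    fold_error <- NULL
    for (j in seq_along(loci_ids)) {
      g <- gm$calls[i, j]
      if (is.na(g)) next
      id <- loci_ids[j]
      f <- freq_full[[id]]
      # re-estimate only the sample's own population without its alleles
      cm_k <- counts[[id]][, k]
      a1 <- substr(g, 1, 1); a2 <- substr(g, 2, 2)
      cm_k[a1] <- cm_k[a1] - 1L
      cm_k[a2] <- cm_k[a2] - 1L
      denom <- sum(cm_k) + smoothing * length(cm_k)
      if (denom == 0) {
        fold_error <- paste0("fold for ", s, ": population ", k,
                             " has no reference data left at ", id,
                             " and smoothing is 0")
        break
      }
      fk <- (cm_k + smoothing) / denom
      p1 <- f[a1, ]; p1[k] <- fk[a1]
      p2 <- f[a2, ]; p2[k] <- fk[a2]
      if (any(p1 <= 0) || any(p2 <= 0)) {
        fold_error <- paste0("fold for ", s, ": zero frequency at ", id,
                             "; use smoothing > 0")
        break
      }
      ll <- ll + if (a1 == a2) 2 * log(p1) else log(2) + log(p1) + log(p2)
      used <- used + 1L
    }
    if (!is.null(fold_error) || used == 0L) {
      unclassifiable <- c(unclassifiable, s)
      results[[ii]] <- data.frame(sample = s, true = k,
                                  assigned = NA_character_,
                                  log_lr = NA_real_, loci_used = used,
                                  correct = NA, stringsAsFactors = FALSE)
      next
    }
    ord <- order(-ll, pops)
    results[[ii]] <- data.frame(
      sample = s, true = k, assigned = pops[ord[1]],
      log_lr = ll[[ord[1]]] - ll[[ord[2]]], loci_used = used,
      correct = pops[ord[1]] == k, stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, results)
  classified <- results[!is.na(results$assigned), ]
  confusion <- table(factor(classified$true, levels = pops),
                     factor(classified$assigned, levels = pops))
  names(dimnames(confusion)) <- c("true", "assigned")
  per_group <- 100 * diag(confusion) / pmax(rowSums(confusion), 1L)
  overall <- 100 * sum(diag(confusion)) / sum(confusion)
  structure(list(confusion = confusion,
                 per_group_pct = per_group,
                 overall_pct = overall,
                 results = results,
                 unclassifiable = unclassifiable),
            class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  cat("leave-one-out cross-validation:", nrow(x$results), "folds\n")
  print(x$confusion)
  cat("overall correct:", round(x$overall_pct, 2), "%\n")
  if (length(x$unclassifiable))
    cat("unclassifiable folds:", length(x$unclassifiable), "\n")
  invisible(x)
}
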