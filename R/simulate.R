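# Synthetic populations: a Balding-Nichols (Dirichlet drift) generator for
# population allele frequencies, Hardy-Weinberg genotype sampling, admixed
# individuals with specified co-ancestry simplexes, and injected
# genotyping errors / no-calls. Everything is reproducible under a seed.

#' Configuration for the synthetic study populations
#'
#' Describes six continental-style population groups and an AIM panel whose
#' composition mirrors a small forensic ancestry panel: per-group binary
#' marker counts, a Eurasian-contrast set (markers divergent between Europe
#' and its South/East Asian neighbours rather than target-vs-rest), and a
#' complement of tri-allelic markers. Divergence is controlled per group by
#' the Balding-Nichols drift parameter `F`; group-targeted loci are
#' additionally required to reach a per-group divergence (PSD) floor.
#' Defaults are calibrated so the panel-wide cumulative PSD per group sits
#' on the scale of a balanced ~100-SNP forensic AIM panel (around 9-14 per
#' continental group, with South Asia much lower, near 3, reflecting its
#' weak differentiation from Europe).
#'
#' @param groups ordered population labels.
#' @param n_loci named integer: binary loci per target group; may include
#'   an `EURASIA` entry for the Europe-vs-Asia contrast set.
#' @param n_triallelic named integer: tri-allelic loci per target group.
#' @param divergence named per-group drift `F` in (0, 1).
#' @param psd_floor named per-target-group minimum divergence for assigned
#'   loci (for `EURASIA` loci the floor applies to the two-group In between
#'   EUR and the SAS/EAS mean).
#' @param n_samples named reference sample sizes per group.
#' @param admixture optional list of designs, each
#'   `list(q = <named simplex>, n = <count>, label = <cohort label>)`.
#' @param error_rate,nocall_rate per-cell perturbation rates in `[0, 1]`.
#' @param seed mandatory integer seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    groups = c("AFR", "EUR", "EAS", "SAS", "OCE", "AMR"),
    n_loci = c(AFR = 7, EUR = 15, EAS = 16, SAS = 20, OCE = 13, AMR = 17,
               EURASIA = 12),
    n_triallelic = c(AFR = 2, EUR = 2, EAS = 4, SAS = 2, OCE = 2, AMR = 3),
    divergence = c(AFR = 0.45, EUR = 0.25, EAS = 0.22, SAS = 0.050,
                   OCE = 0.36, AMR = 0.27),
    psd_floor = c(AFR = 0.50, EUR = 0.42, EAS = 0.35, SAS = 0.080,
                  OCE = 0.50, AMR = 0.45, EURASIA = 0.25),
    n_samples = c(AFR = 108, EUR = 99, EAS = 103, SAS = 103, OCE = 28,
                  AMR = 79),
    admixture = NULL,
    error_rate = 0, nocall_rate = 0,
    seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(length(groups) >= 2, !anyDuplicated(groups))
  stopifnot(all(names(n_loci) %in% c(groups, "EURASIA")),
            all(names(n_triallelic) %in% c(groups, "EURASIA")),
            all(groups %in% names(divergence)),
            all(divergence[groups] > 0, divergence[groups] < 1),
            all(names(n_samples) %in% groups),
            error_rate >= 0, error_rate <= 1,
            nocall_rate >= 0, nocall_rate <= 1)
  if (!is.null(admixture)) {
    for (d in admixture) {
      stopifnot(all(names(d$q) %in% groups),
                abs(sum(d$q) - 1) < 1e-6, all(d$q >= 0), d$n >= 1)
    }
  }
  structure(list(groups = groups, n_loci = n_loci,
                 n_triallelic = n_triallelic, divergence = divergence,
                 psd_floor = psd_floor, n_samples = n_samples,
                 admixture = admixture, error_rate = error_rate,
                 nocall_rate = nocall_rate, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Divergence actually constrained by the floor for a target assignment:
# ordinary groups use target-vs-pooled-rest PSD; the Eurasian contrast uses
# the two-group In between EUR and the mean of its Asian neighbours.
target_divergence <- function(pop_freqs, target, groups) {
  if (target == "EURASIA") {
    neigh <- intersect(c("SAS", "EAS"), groups)
    pooled <- colMeans(pop_freqs[neigh, , drop = FALSE])
    rosenberg_in(rbind(pop_freqs["EUR", ], pooled))
  } else {
    population_specific_divergence(pop_freqs, target)
  }
}

#' Simulate population allele frequencies under Balding-Nichols drift
#'
#' Each locus draws an ancestral frequency vector (biallelic
#' `p ~ Uniform(0.1, 0.9)`; tri-allelic from a Dirichlet bounded away from
#' fixation), then each population's vector from a Dirichlet with mean the
#' ancestral vector and concentration `(1 - F) / F`, giving
#' `Var(p_pop) = F p (1 - p)`. Loci assigned to a target group are then
#' boosted toward fixation of their informative allele (in the target
#' population, or in EUR for Eurasian-contrast loci) until the configured
#' divergence floor is met; draws that cannot reach the floor are rejected
#' and redrawn a bounded number of times.
#'
#' @param cfg a [synthetic_config()].
#' @return a [frequency_table()] whose loci carry their target-group
#'   assignments; `n_chrom` is 0 (theoretical frequencies).
#' @export
simulate_frequencies <- function(cfg) {
  with_seed(cfg$seed, {
    targets <- c(rep(names(cfg$n_loci), cfg$n_loci),
                 rep(names(cfg$n_triallelic), cfg$n_triallelic))
    n_alleles <- c(rep(2L, sum(cfg$n_loci)),
                   rep(3L, sum(cfg$n_triallelic)))
    L <- length(targets)
    ids <- sprintf("rs9%06d", seq_len(L))
    allele_sets <- lapply(n_alleles, function(a) sort(sample(NUCLEOTIDES, a)))
    panel <- panel_spec(
      snp_id = ids,
      chromosome = as.character(rep_len(1:22, L)),
      position = 1e6L + 1000L * seq_len(L),
      alleles = vapply(allele_sets, paste, "", collapse = "/"),
      target_group = targets)
    Fg <- cfg$divergence[cfg$groups]
    freqs <- vector("list", L)
    names(freqs) <- ids
    for (l in seq_len(L)) {
      A <- n_alleles[l]
      t <- targets[l]
      floor_t <- if (t %in% names(cfg$psd_floor)) cfg$psd_floor[[t]] else 0
      boosted <- NULL
      for (attempt in seq_len(400L)) {
        anc <- if (A == 2L) {
          p <- stats::runif(1, 0.1, 0.9); c(p, 1 - p)
        } else {
          repeat {
            v <- rdirichlet1(rep(2, 3))
            if (all(v > 0.05)) break
          }
          v
        }
        pf <- t(vapply(cfg$groups, function(g)
          rdirichlet1(anc * (1 - Fg[[g]]) / Fg[[g]]), numeric(A)))
        dimnames(pf) <- list(cfg$groups, allele_sets[[l]])
        if (floor_t > 0) {
          boost_pop <- if (t == "EURASIA") "EUR" else t
          others <- setdiff(cfg$groups, boost_pop)
          for (step in 0:40) {
            if (target_divergence(pf, t, cfg$groups) >= floor_t) break
            inf_allele <- which.max(pf[boost_pop, ] -
                                      colMeans(pf[others, , drop = FALSE]))
            e <- numeric(A); e[inf_allele] <- 1
            pf[boost_pop, ] <- 0.85 * pf[boost_pop, ] + 0.15 * e
          }
        }
        if (floor_t <= 0 ||
            target_divergence(pf, t, cfg$groups) >= floor_t) {
          boosted <- pf
          break
        }
      }
      if (is.null(boosted))
        stop("could not reach the divergence floor ", floor_t,
             " for a locus targeting ", t, "; lower psd_floor")
      freqs[[l]] <- t(boosted)   # allele x population
    }
    frequency_table(panel, cfg$groups, freqs)
  })
}

#' Simulate reference genotypes under Hardy-Weinberg proportions
#'
#' Each sample's genotype at each locus is two independent allele draws
#' from its population's frequency vector. All samples are flagged as
#' training (POPFLAG 1).
#'
#' @param ft a [frequency_table()].
#' @param n_samples named per-population sample counts.
#' @param seed integer seed.
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(ft, n_samples, seed) {
  stopifnot(all(names(n_samples) %in% ft$populations))
  with_seed(seed, {
    pops <- names(n_samples)
    ids <- unlist(lapply(pops, function(g)
      sprintf("%s_%03d", g, seq_len(n_samples[[g]]))))
    pop_of <- rep(pops, unlist(n_samples))
    calls <- matrix(NA_character_, length(ids), nrow(ft$loci),
                    dimnames = list(ids, ft$loci$snp_id))
    for (j in seq_len(nrow(ft$loci))) {
      f <- ft$freqs[[j]]
      col <- character(length(ids))
      off <- 0L
      for (g in pops) {
        n <- n_samples[[g]]
        a <- matrix(sample(rownames(f), 2 * n, replace = TRUE,
                           prob = f[, g]), nrow = 2)
        col[off + seq_len(n)] <- paste0(pmin(a[1, ], a[2, ]),
                                        pmax(a[1, ], a[2, ]))
        off <- off + n
      }
      calls[, j] <- col
    }
    genotype_matrix(calls, ft$loci, population = pop_of,
                    training = rep(1L, length(ids)))
  })
}

#' Simulate admixed individuals with specified co-ancestry
#'
#' Each allele copy independently draws an origin population from the
#' design's co-ancestry simplex `q`, then an allele from that population's
#' frequency vector. Samples are flagged as queries (POPFLAG 0). The true
#' simplex per sample is attached as the `"truth"` attribute (a data frame
#' with one proportion column per population).
#'
#' @param ft a [frequency_table()].
#' @param design list of `list(q = <named simplex>, n = <count>,
#'   label = <optional cohort label>)`.
#' @param seed integer seed.
#' @return a [genotype_matrix()] with a `"truth"` attribute.
#' @export
simulate_admixed <- function(ft, design, seed) {
  with_seed(seed, {
    pops <- ft$populations
    qs <- lapply(design, function(d) {
      q <- stats::setNames(numeric(length(pops)), pops)
      q[names(d$q)] <- d$q
      q / sum(q)
    })
    ns <- vapply(design, function(d) as.integer(d$n), 0L)
    labels <- vapply(seq_along(design), function(i)
      design[[i]]$label %||% paste0("ADM", i), "")
    ids <- unlist(lapply(seq_along(design), function(i)
      sprintf("%s_%03d", labels[i], seq_len(ns[i]))))
    design_of <- rep(seq_along(design), ns)
    n_tot <- length(ids)
    calls <- matrix(NA_character_, n_tot, nrow(ft$loci),
                    dimnames = list(ids, ft$loci$snp_id))
    for (j in seq_len(nrow(ft$loci))) {
      f <- ft$freqs[[j]]
      alleles <- rownames(f)
      draw_copy <- function(q) {
        origin <- sample(pops, n_tot, replace = TRUE, prob = NULL)
        # per-design origin draw
        for (i in seq_along(design)) {
          idx <- design_of == i
          origin[idx] <- sample(pops, sum(idx), replace = TRUE,
                                prob = qs[[i]])
        }
        a <- character(n_tot)
        for (g in pops) {
          idx <- origin == g
          if (any(idx))
            a[idx] <- sample(alleles, sum(idx), replace = TRUE,
                             prob = f[, g])
        }
        a
      }
      a1 <- draw_copy(); a2 <- draw_copy()
      calls[, j] <- paste0(pmin(a1, a2), pmax(a1, a2))
    }
    gm <- genotype_matrix(calls, ft$loci,
                          population = rep(NA_character_, n_tot),
                          training = rep(0L, n_tot))
    truth <- cbind(data.frame(sample = ids, stringsAsFactors = FALSE),
                   do.call(rbind, lapply(design_of, function(i)
                     as.data.frame(as.list(qs[[i]])))))
    rownames(truth) <- NULL
    attr(gm, "truth") <- truth
    gm
  })
}

#' Inject genotyping errors and no-calls into a call set
#'
#' In rate mode, each non-missing cell independently becomes a no-call with
#' probability `nocall_rate`, otherwise is replaced with a different random
#' valid genotype at its locus with probability `error_rate`. In count mode
#' (`n_errors` / `n_nocalls` given), exactly that many cells are perturbed,
#' which builds fixtures matching printed discordance counts exactly. Every
#' change is recorded in a ledger.
#'
#' @param gm a [genotype_matrix()].
#' @param error_rate,nocall_rate per-cell rates (rate mode).
#' @param seed integer seed.
#' @param n_errors,n_nocalls exact perturbation counts (count mode);
#'   overrides the rates.
#' @return list with `genotypes` (the perturbed [genotype_matrix()]) and
#'   `ledger` (data frame: sample, locus, type, original, new).
#' @export
inject_errors <- function(gm, error_rate = 0, nocall_rate = 0, seed,
                          n_errors = NULL, n_nocalls = NULL) {
  with_seed(seed, {
    calls <- gm$calls
    al <- panel_alleles(gm$loci)
    geno_sets <- lapply(al, all_genotypes)
    eligible <- which(!is.na(calls))
    count_mode <- !is.null(n_errors) || !is.null(n_nocalls)
    if (count_mode) {
      n_nc <- n_nocalls %||% 0L
      n_er <- n_errors %||% 0L
      if (n_nc + n_er > length(eligible))
        stop("not enough non-missing cells to perturb")
      picked <- if (n_nc + n_er > 0)
        sample(eligible, n_nc + n_er) else integer(0)
      nc_cells <- picked[seq_len(n_nc)]
      er_cells <- picked[seq_len(n_er) + n_nc]
    } else {
      u <- stats::runif(length(eligible))
      nc_cells <- eligible[u < nocall_rate]
      rest <- eligible[u >= nocall_rate]
      u2 <- stats::runif(length(rest))
      er_cells <- rest[u2 < error_rate]
    }
    cell_info <- function(cells) {
      rc <- arrayInd(cells, dim(calls))
      data.frame(sample = rownames(calls)[rc[, 1]],
                 locus = colnames(calls)[rc[, 2]],
                 stringsAsFactors = FALSE)
    }
    ledger <- list()
    if (length(nc_cells)) {
      info <- cell_info(nc_cells)
      ledger[[1]] <- data.frame(info, type = "nocall",
                                original = calls[nc_cells],
                                new = NA_character_,
                                stringsAsFactors = FALSE)
      calls[nc_cells] <- NA_character_
    }
    if (length(er_cells)) {
      info <- cell_info(er_cells)
      rc <- arrayInd(er_cells, dim(calls))
      old <- calls[er_cells]
      new <- vapply(seq_along(er_cells), function(i) {
        pool <- setdiff(geno_sets[[rc[i, 2]]], old[i])
        if (length(pool) == 1) pool else sample(pool, 1)
      }, "")
      ledger[[2]] <- data.frame(info, type = "error", original = old,
                                new = new, stringsAsFactors = FALSE)
      calls[er_cells] <- new
    }
    ledger <- if (length(ledger)) do.call(rbind, ledger)
      else data.frame(sample = character(), locus = character(),
                      type = character(), original = character(),
                      new = character(), stringsAsFactors = FALSE)
    rownames(ledger) <- NULL
    out <- genotype_matrix(calls, gm$loci, population = gm$population,
                           training = gm$training)
    list(genotypes = out, ledger = ledger)
  })
}

#' Build a complete synthetic reference study
#'
#' Convenience wrapper: simulates population frequencies under the
#' configuration, then the reference genotype matrix, and (if the
#' configuration carries an admixture design) the admixed query cohort.
#' Sub-seeds are derived from `cfg$seed` so the pieces are independently
#' reproducible.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `frequencies` (true generating frequencies),
#'   `reference` (a [genotype_matrix()]) and `admixed` (or `NULL`).
#' @export
simulate_reference_set <- function(cfg) {
  ft <- simulate_frequencies(cfg)
  gm <- simulate_genotypes(ft, cfg$n_samples, seed = cfg$seed + 1L)
  adm <- if (!is.null(cfg$admixture))
    simulate_admixed(ft, cfg$admixture, seed = cfg$seed + 2L)
  list(frequencies = ft, reference = gm, admixed = adm)
}
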