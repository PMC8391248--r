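# Independent oracle implementations, kept deliberately naive (scalar loops,
# probability space) so they share no code path with the package.

# Rosenberg informativeness by direct scalar evaluation of the definition.
oracle_in <- function(freqs) {
  K <- nrow(freqs)
  total <- 0
  for (a in seq_len(ncol(freqs))) {
    pbar <- 0
    for (i in seq_len(K)) pbar <- pbar + freqs[i, a] / K
    term <- if (pbar > 0) -pbar * log(pbar) else 0
    for (i in seq_len(K)) {
      p <- freqs[i, a]
      if (p > 0) term <- term + p * log(p) / K
    }
    total <- total + term
  }
  unname(total)
}

# Brute-force naive-Bayes posterior: product of Hardy-Weinberg genotype
# probabilities in probability space, times the prior.
oracle_posterior <- function(calls, ft, priors) {
  pops <- ft$populations
  post <- numeric(length(pops))
  names(post) <- pops
  for (k in pops) {
    prob <- priors[[k]]
    for (id in names(calls)) {
      g <- calls[[id]]
      if (is.na(g)) next
      f <- ft$freqs[[id]][, k]
      a1 <- substr(g, 1, 1); a2 <- substr(g, 2, 2)
      prob <- prob * if (a1 == a2) f[[a1]]^2 else 2 * f[[a1]] * f[[a2]]
    }
    post[k] <- prob
  }
  post
}

# Allele-sharing distance by explicit multiset intersection per locus.
oracle_distance <- function(gm) {
  n <- nrow(gm$calls)
  D <- matrix(0, n, n, dimnames = list(rownames(gm$calls),
                                       rownames(gm$calls)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- 0; any_joint <- FALSE
    for (l in seq_len(ncol(gm$calls))) {
      gi <- gm$calls[i, l]; gj <- gm$calls[j, l]
      if (is.na(gi) || is.na(gj)) next
      any_joint <- TRUE
      ai <- strsplit(gi, "")[[1]]; aj <- strsplit(gj, "")[[1]]
      shared <- 0
      pool <- aj
      for (a in ai) {
        hit <- match(a, pool)
        if (!is.na(hit)) { shared <- shared + 1; pool <- pool[-hit] }
      }
      d <- d + (2 - shared)
    }
    D[i, j] <- if (any_joint) d else NA_real_
  }
  D
}

# Minimal reader for the STRUCTURE two-row export, using its sidecar legend.
read_structure_file <- function(path) {
  lines <- readLines(path)
  loci <- strsplit(lines[1], " ", fixed = TRUE)[[1]]
  legend <- utils::read.delim(paste0(path, ".legend.tsv"),
                              stringsAsFactors = FALSE)
  body <- strsplit(lines[-1], " ", fixed = TRUE)
  ids <- unique(vapply(body, `[`, "", 1))
  calls <- matrix(NA_character_, length(ids), length(loci),
                  dimnames = list(ids, loci))
  popi <- integer(length(ids)); names(popi) <- ids
  flag <- integer(length(ids)); names(flag) <- ids
  rows_of <- split(seq_along(body), vapply(body, `[`, "", 1))
  for (s in ids) {
    two <- body[rows_of[[s]]]
    stopifnot(length(two) == 2)
    popi[s] <- as.integer(two[[1]][2])
    flag[s] <- as.integer(two[[1]][3])
    for (l in seq_along(loci)) {
      c1 <- two[[1]][3 + l]; c2 <- two[[2]][3 + l]
      if (c1 == "-9" || c2 == "-9") next
      leg <- legend[legend$kind == "allele" & legend$locus == loci[l], ]
      a <- leg$symbol[match(c(as.integer(c1), as.integer(c2)), leg$code)]
      calls[s, l] <- paste(sort(a), collapse = "")
    }
  }
  popleg <- legend[legend$kind == "population", ]
  pop <- rep(NA_character_, length(ids)); names(pop) <- ids
  hit <- popi > 0
  pop[hit] <- popleg$symbol[match(popi[hit], popleg$code)]
  list(calls = calls, population = pop, training = flag)
}
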