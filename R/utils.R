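# Internal helpers shared across modules.

NUCLEOTIDES <- c("A", "C", "G", "T")

POPULATION_GROUPS <- c("AFR", "EUR", "EAS", "SAS", "OCE", "AMR",
                       "EURASIA", "NONE")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Canonicalize two-character genotype strings
#'
#' Genotypes are unordered allele pairs; `"GA"` and `"AG"` denote the same
#' genotype. The canonical form sorts the two allele characters
#' alphabetically. `NA` (missing) is preserved.
#'
#' @param g character vector of two-character genotype strings (or `NA`).
#' @return character vector of canonical genotype strings.
#' @export
canonical_genotype <- function(g) {
  out <- rep(NA_character_, length(g))
  ok <- !is.na(g) & g != "NN"
  if (any(ok)) {
    parts <- strsplit(g[ok], "", fixed = TRUE)
    out[ok] <- vapply(parts, function(a) paste(sort(a), collapse = ""), "")
  }
  out
}

# Evaluate `code` under a fixed RNG seed, restoring prior RNG state on exit.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Round half away from zero (commercial rounding), used only for display
# percentages; full precision is always retained alongside.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# x * log(x) with the 0 * log(0) := 0 convention.
xlogx <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(x[pos])
  out
}

# Dirichlet draws via independent gammas; alpha a positive vector.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) { # numerically degenerate; fall back to the mean
    return(alpha / sum(alpha))
  }
  g / sum(g)
}

# All unordered genotypes over an allele set, canonical strings.
all_genotypes <- function(alleles) {
  n <- length(alleles)
  idx <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  canonical_genotype(paste0(alleles[idx[, "row"]], alleles[idx[, "col"]]))
}

# Split a slash-separated allele string ("A/G") into a character vector.
split_alleles <- function(x) strsplit(x, "/", fixed = TRUE)

# Parse a semicolon-separated source-panel string into a character vector,
# dropping empties.
split_panels <- function(x) {
  lapply(strsplit(x %||% "", ";", fixed = TRUE),
         function(p) p[nzchar(trimws(p))])
}
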