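# The Snipper training-grid worksheet contract, serialized as CSV.
#
# Layout: row 1 carries the three header counts (profiles, markers,
# populations) in its first three cells; row 2 names the columns
# (sample, one column per marker, population, flag); each following row is
# one profile with two-character genotype strings ("AG" == "GA",
# canonicalized alphabetically; missing = "NN"), its population label
# (empty for unknown/query profiles) and the 0/1 training flag in the
# rightmost column.

#' Write a genotype matrix as a Snipper training grid (CSV)
#'
#' @param gm a [genotype_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly. Header counts are computed from content; the
#'   population count is the number of distinct labels among flag-1
#'   profiles. A sample with no calls at any locus is still emitted, with a
#'   warning.
#' @export
write_snipper_grid <- function(gm, path) {
  n <- nrow(gm$calls)
  m <- ncol(gm$calls)
  npop <- length(unique(gm$population[gm$training == 1L & !is.na(gm$population)]))
  width <- m + 3L
  header <- c(n, m, npop, rep("", max(0L, width - 3L)))
  colnames_row <- c("sample", gm$loci$snp_id, "population", "flag")
  empty_rows <- rowSums(!is.na(gm$calls)) == 0L
  if (n > 0 && any(empty_rows))
    warning("sample(s) with no calls at any locus: ",
            paste(rownames(gm$calls)[empty_rows], collapse = ", "))
  lines <- c(paste(header[seq_len(width)], collapse = ","),
             paste(colnames_row, collapse = ","))
  if (n > 0) {
    calls <- gm$calls
    calls[is.na(calls)] <- "NN"
    pop <- gm$population
    pop[is.na(pop)] <- ""
    body <- apply(cbind(rownames(gm$calls), calls, pop,
                        as.character(gm$training)), 1,
                  paste, collapse = ",")
    lines <- c(lines, unname(body))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a Snipper training grid (CSV)
#'
#' Inverse of [write_snipper_grid()]; the round trip is lossless for calls,
#' population labels and training flags. Profiles flagged 0 have unknown
#' population unless a label is present.
#'
#' @param path CSV path.
#' @param panel optional [panel_spec()]; when absent, a minimal panel is
#'   reconstructed from the marker ids and the alleles observed in calls.
#' @return a [genotype_matrix()].
#' @export
read_snipper_grid <- function(path, panel = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("grid format error: fewer than two header rows")
  cells <- strsplit(lines, ",", fixed = TRUE)
  counts <- suppressWarnings(as.integer(cells[[1]][1:3]))
  if (any(is.na(counts)))
    stop("grid format error: header cells 1-3 must hold ",
         "(profiles, markers, populations) counts")
  n_prof <- counts[1]; n_mark <- counts[2]; n_pop <- counts[3]
  cn <- cells[[2]]
  if (length(cn) != n_mark + 3L)
    stop("grid format error: header declares ", n_mark,
         " markers but the column row has ", length(cn) - 3L)
  marker_ids <- cn[seq(2L, length.out = n_mark)]
  body <- cells[-(1:2)]
  body <- body[vapply(body, function(r) any(nzchar(r)), TRUE)]
  if (length(body) != n_prof)
    stop("grid format error: header declares ", n_prof,
         " profiles but the grid contains ", length(body), " rows")
  pad <- function(r) { length(r) <- n_mark + 3L; r }
  rows <- t(vapply(body, pad, character(n_mark + 3L)))
  flags <- rows[, n_mark + 3L]
  if (!all(flags %in% c("0", "1")))
    stop("grid format error: training flag must be 0 or 1")
  calls <- rows[, seq(2L, length.out = n_mark), drop = FALSE]
  calls[calls == "NN" | calls == "" | is.na(calls)] <- NA_character_
  rownames(calls) <- rows[, 1L]
  colnames(calls) <- marker_ids
  pop <- rows[, n_mark + 2L]
  pop[!nzchar(pop) | is.na(pop)] <- NA_character_
  training <- as.integer(flags)
  npop_seen <- length(unique(pop[training == 1L & !is.na(pop)]))
  if (npop_seen != n_pop)
    stop("grid format error: header declares ", n_pop,
         " populations but flag-1 rows carry ", npop_seen)
  if (is.null(panel)) {
    alleles <- apply(calls, 2, function(g) {
      obs <- sort(unique(unlist(strsplit(g[!is.na(g)], ""))))
      if (length(obs) < 2) obs <- union(obs, NUCLEOTIDES)[1:2]
      if (length(obs) > 3)
        stop("more than 3 alleles observed at a marker")
      paste(obs, collapse = "/")
    })
    panel <- panel_spec(marker_ids, alleles = alleles)
  } else {
    if (!all(marker_ids %in% panel$snp_id))
      stop("grid markers missing from panel: ",
           paste(setdiff(marker_ids, panel$snp_id), collapse = ", "))
    panel <- panel[match(marker_ids, panel$snp_id), , drop = FALSE]
    rownames(panel) <- NULL
  }
  genotype_matrix(calls, panel, population = pop, training = training)
}
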