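# Deterministic greedy balancing of per-group cumulative divergence.

#' Balance a panel's per-group cumulative divergence
#'
#' Selects, for each target group, a fixed number (`budget`) of candidate
#' SNPs so that the per-group cumulative PSD totals (each group's sum of its
#' own members' PSD) are as even as possible. The procedure is a
#' deterministic greedy: starting from the protected set (or a supplied
#' initial selection), the group with the lowest cumulative total repeatedly
#' receives its highest-PSD unused candidate until every budget is met; a
#' swap phase then replaces members with unused same-group candidates while
#' any swap strictly reduces the max-minus-min cumulative spread (or until
#' the spread is within `band`). Ties are broken by ascending rsID, so the
#' result is reproducible for a given input.
#'
#' @param candidates data frame with columns `snp_id`, `group` (target
#'   group) and `psd` (the SNP's divergence for that group).
#' @param budget named integer vector: SNPs to select per group.
#' @param protected snp_ids that may never be removed or swapped out.
#' @param initial optional snp_id vector to start from; must respect the
#'   budgets exactly.
#' @param band spread (max - min cumulative PSD) below which no further
#'   swaps are attempted; default 0 (swap while any improvement exists).
#' @return an object of class `balance_report`: list with `selected` (data
#'   frame), `cumulative_before`, `cumulative_after`, and `log` (one row per
#'   greedy/swap action).
#' @export
balance_panel <- function(candidates, budget, protected = character(),
                          initial = NULL, band = 0) {
  stopifnot(all(c("snp_id", "group", "psd") %in% names(candidates)))
  if (anyDuplicated(candidates$snp_id)) stop("duplicate candidate snp_id")
  groups <- names(budget)
  if (is.null(groups)) stop("budget must be a named vector")
  avail <- table(factor(candidates$group, levels = groups))
  short <- groups[avail < budget]
  if (length(short))
    stop("infeasible budget: not enough candidates for group(s) ",
         paste(short, collapse = ", "))
  if (!all(protected %in% candidates$snp_id))
    stop("protected snp_id(s) not among candidates")

  cand <- candidates[order(candidates$snp_id), c("snp_id", "group", "psd")]
  cum_of <- function(sel) {
    vapply(groups, function(g)
      sum(cand$psd[cand$snp_id %in% sel & cand$group == g]), 0)
  }
  log_rows <- list()
  note <- function(action, snp_id, group, sel) {
    cums <- cum_of(sel)
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      action = action, snp_id = snp_id, group = group,
      spread = max(cums) - min(cums), stringsAsFactors = FALSE)
  }

  if (!is.null(initial)) {
    if (!all(initial %in% cand$snp_id))
      stop("initial selection contains unknown snp_id(s)")
    got <- table(factor(cand$group[cand$snp_id %in% initial],
                        levels = groups))
    if (!all(got == budget))
      stop("initial selection does not respect the budgets")
    if (!all(protected %in% initial))
      stop("initial selection must contain all protected SNPs")
    sel <- sort(unique(initial))
  } else {
    sel <- sort(unique(protected))
    pgot <- table(factor(cand$group[cand$snp_id %in% sel], levels = groups))
    if (any(pgot > budget))
      stop("protected SNPs exceed the budget for group(s) ",
           paste(groups[pgot > budget], collapse = ", "))
    repeat {
      got <- table(factor(cand$group[cand$snp_id %in% sel], levels = groups))
      need <- groups[got < budget]
      if (!length(need)) break
      cums <- cum_of(sel)
      g <- need[order(cums[need], need)][1]
      pool <- cand[cand$group == g & !(cand$snp_id %in% sel), ]
      pool <- pool[order(-pool$psd, pool$snp_id), ]
      sel <- c(sel, pool$snp_id[1])
      note("add", pool$snp_id[1], g, sel)
    }
  }
  cumulative_before <- cum_of(sel)

  # Swap phase: within-group replacement that most reduces the spread.
  repeat {
    cums <- cum_of(sel)
    spread <- max(cums) - min(cums)
    if (spread <= band) break
    best <- NULL
    for (g in groups) {
      members <- cand[cand$snp_id %in% sel & cand$group == g &
                        !(cand$snp_id %in% protected), ]
      pool <- cand[cand$group == g & !(cand$snp_id %in% sel), ]
      if (!nrow(members) || !nrow(pool)) next
      for (i in seq_len(nrow(members))) for (k in seq_len(nrow(pool))) {
        new_cums <- cums
        new_cums[g] <- new_cums[g] - members$psd[i] + pool$psd[k]
        new_spread <- max(new_cums) - min(new_cums)
        if (is.null(best) || new_spread < best$spread - 1e-12) {
          best <- list(spread = new_spread, out = members$snp_id[i],
                       into = pool$snp_id[k], group = g)
        }
      }
    }
    if (is.null(best) || best$spread >= spread - 1e-12) break
    sel <- c(setdiff(sel, best$out), best$into)
    note(paste0("swap:", best$out, "->", best$into), best$into,
         best$group, sel)
  }

  selected <- cand[cand$snp_id %in% sel, ]
  selected <- selected[order(selected$group, selected$snp_id), ]
  rownames(selected) <- NULL
  structure(list(selected = selected,
                 cumulative_before = cumulative_before,
                 cumulative_after = cum_of(sel),
                 log = if (length(log_rows)) do.call(rbind, log_rows)
                       else data.frame(action = character(),
                                       snp_id = character(),
                                       group = character(),
                                       spread = numeric())),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("balance_report:", nrow(x$selected), "SNPs selected\n")
  cat("cumulative PSD after balancing:\n")
  print(round(x$cumulative_after, 4))
  cat("spread:", round(max(x$cumulative_after) - min(x$cumulative_after), 4),
      "(", nrow(x$log), "actions )\n")
  invisible(x)
}
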