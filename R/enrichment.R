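# Pre-ranked permutation gene-set enrichment for kinase-substrate (KSEA)
# and ontology collections, run on contrast-result rankings.

#' Rank features for pre-ranked enrichment
#'
#' Orders the features of a contrast result by a chosen metric, descending,
#' with ties broken deterministically by feature id. The returned named
#' vector is the input to [preranked_gsea()].
#'
#' @param r A `contrast_result` (from [synergy_contrast()] or
#'   [sam_one_sample_test()]).
#' @param by Ranking metric column: `"statistic"` (default) or `"log_fc"`.
#' @return Named numeric vector, names = feature ids, sorted descending.
#' @export
rank_features <- function(r, by = c("statistic", "log_fc")) {
  by <- match.arg(by)
  if (nrow(r) == 0) abort("empty contrast result")
  vals <- r[[by]]
  if (any(!is.finite(vals))) abort("ranking metric must be finite")
  ord <- order(-vals, r$feature_id)
  setNames(vals[ord], r$feature_id[ord])
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score (weight
# exponent 1): hits advance by |stat| / sum |stat in set|, misses by
# 1 / (N - set size); ES is the maximum deviation from zero, signed.
running_sum_es <- function(stats, in_set) {
  n <- length(stats)
  n_hit <- sum(in_set)
  w <- abs(stats)
  sum_w <- sum(w[in_set])
  if (sum_w == 0) {
    # degenerate all-zero weights: fall back to equal hit increments
    inc_hit <- ifelse(in_set, 1 / n_hit, 0)
  } else {
    inc_hit <- ifelse(in_set, w / sum_w, 0)
  }
  inc_miss <- ifelse(in_set, 0, 1 / (n - n_hit))
  run <- cumsum(inc_hit - inc_miss)
  i_max <- which.max(abs(run))
  es <- run[i_max]
  list(es = es, peak = i_max, running = run)
}

#' Pre-ranked gene-set enrichment with a gene-sampling permutation null
#'
#' Classic weighted running-sum enrichment on a pre-ranked feature list:
#' walking down the ranking, set members advance the running sum in
#' proportion to the absolute ranking statistic and non-members decrement
#' it uniformly; the enrichment score ES is the signed maximum deviation.
#' The null distribution per set size is built by drawing `n_perm` random
#' member sets of equal size from the ranking. NES divides ES by the mean
#' |null ES| of matching sign, and the one-sided permutation p-value uses
#' the add-one formula `p = (1 + #{null at least as extreme}) / (1 +
#' n_perm)`, so p is never zero. BH adjustment is applied across sets.
#'
#' @param ranking Named numeric vector from [rank_features()].
#' @param sets Named list of character vectors (e.g. kinase -> substrate
#'   ids, or an ontology collection from [read_gmt()]).
#' @param min_size Minimum set size after intersecting with the ranking
#'   (default 3); smaller sets are dropped with a message.
#' @param n_perm Number of random-set permutations (default 1000).
#' @param seed Integer seed.
#' @param fdr Adjusted-p cutoff for the `significant` flag (default 0.1).
#' @return An `enrichment_result` tibble: `set`, `size`, `es`, `nes`,
#'   `p_value`, `adj_p`, `significant`, `leading_edge` (list column).
#' @export
preranked_gsea <- function(ranking, sets, min_size = 3, n_perm = 1000,
                           seed = 1L, fdr = 0.1) {
  stopifnot(is.numeric(ranking), !is.null(names(ranking)))
  ids <- names(ranking)
  n <- length(ranking)
  kept <- lapply(sets, function(s) unique(s[s %in% ids]))
  dropped <- sum(lengths(lapply(sets, unique))) - sum(lengths(kept))
  if (dropped > 0) {
    message(sprintf("%d set member(s) absent from the ranking were dropped", dropped))
  }
  sizes <- lengths(kept)
  use <- sizes >= min_size & sizes < n
  if (!any(use)) abort("all sets fall below min_size after matching the ranking")
  kept <- kept[use]
  sizes <- sizes[use]

  obs <- lapply(kept, function(s) running_sum_es(ranking, ids %in% s))

  null_by_size <- with_seed(seed, {
    out <- list()
    for (k in sort(unique(sizes))) {
      out[[as.character(k)]] <- vapply(seq_len(n_perm), function(b) {
        idx <- sample.int(n, k)
        running_sum_es(ranking, seq_len(n) %in% idx)$es
      }, numeric(1))
    }
    out
  })

  rows <- purrr::imap(kept, function(members, nm) {
    o <- obs[[nm]]
    nulls <- null_by_size[[as.character(length(members))]]
    if (o$es >= 0) {
      same <- nulls[nulls >= 0]
      p <- (1 + sum(same >= o$es)) / (1 + length(same))
      nes <- if (length(same)) o$es / mean(abs(same)) else NA_real_
      lead <- ids[seq_len(o$peak)]
    } else {
      same <- nulls[nulls < 0]
      p <- (1 + sum(same <= o$es)) / (1 + length(same))
      nes <- if (length(same)) o$es / mean(abs(same)) else NA_real_
      lead <- ids[o$peak:n]
    }
    tibble::tibble(set = nm, size = length(members), es = o$es, nes = nes,
                   p_value = p,
                   leading_edge = list(intersect(lead, members)))
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(adj_p = p.adjust(.data$p_value, method = "BH"),
                  significant = .data$adj_p <= fdr) |>
    dplyr::relocate("adj_p", "significant", .after = "p_value")
  attr(out, "params") <- list(min_size = min_size, n_perm = n_perm,
                              seed = seed, fdr = fdr,
                              n_features = n)
  class(out) <- c("enrichment_result", class(out))
  out
}
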