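# Shared fixtures, all built in code at test time.

# small, fast study configuration for unit tests
test_config <- function(seed = 1, ...) {
  synergy_study_config(seed = seed, ...)
}

# a tiny complete omics matrix with hand-set values: n_feat features,
# 6 conditions x 3 replicates, optional per-feature condition means
toy_omics <- function(values) {
  conds <- c("CTRL", "M", "D", "V", "MD", "MDV")
  samples <- tibble::tibble(
    sample = paste0(rep(conds, each = 3), "_", rep(1:3, 6)),
    condition = rep(conds, each = 3),
    replicate = rep(1:3, 6)
  )
  omics_matrix(values, samples, log2_scale = TRUE)
}

# brute-force BH step-up used as the independent multiple-testing oracle
bh_brute_force <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    r <- which(ord == i)  # rank of p[i]
    q[i] <- min(vapply(r:n, function(j) min(1, n * p[ord[j]] / j), numeric(1)))
  }
  q
}

# brute-force weighted running-sum enrichment score (independent oracle)
es_brute_force <- function(stats, members) {
  ids <- names(stats)
  n <- length(stats)
  hit <- ids %in% members
  sum_w <- sum(abs(stats[hit]))
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      run <- run + abs(stats[i]) / sum_w
    } else {
      run <- run - 1 / (n - sum(hit))
    }
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}
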