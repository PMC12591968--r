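# Proteomic statistics: the per-treatment one-sample (SAM-style) analysis
# and the regression-based combination-versus-sum-of-singles contrast with
# empirical-Bayes variance moderation.

OMICS_CONDITIONS <- c("CTRL", "M", "D", "V", "MD", "MDV")

#' Construct an omics intensity matrix
#'
#' Container for a label-free (phospho)proteomics intensity matrix:
#' features x samples, with missing values as NA, per-sample condition
#' labels from the fixed vocabulary CTRL, M, D, V, MD, MDV, and a
#' provenance code per value recording whether it was observed or filled
#' by one of the imputation paths. Imputation never overwrites observed
#' values.
#'
#' @param values Numeric matrix (features in rows, rownames = feature ids;
#'   samples in columns). NA marks missing.
#' @param samples Data frame with columns `sample`, `condition`,
#'   `replicate` matching the matrix columns.
#' @param features Optional data frame with a `feature_id` column plus
#'   annotations (e.g. `site`, `protein`).
#' @param log2_scale Whether `values` are already log2 transformed.
#' @return An `omics_matrix` object.
#' @export
omics_matrix <- function(values, samples, features = NULL, log2_scale = FALSE) {
  stopifnot(is.matrix(values), nrow(samples) == ncol(values))
  if (!all(samples$condition %in% OMICS_CONDITIONS)) {
    abort(sprintf("condition labels must be from {%s}",
                  paste(OMICS_CONDITIONS, collapse = ", ")))
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("F%05d", seq_len(nrow(values)))
  }
  colnames(values) <- samples$sample
  if (is.null(features)) {
    features <- tibble::tibble(feature_id = rownames(values))
  }
  prov <- matrix("observed", nrow(values), ncol(values),
                 dimnames = dimnames(values))
  prov[is.na(values)] <- "missing"
  structure(
    list(values = values, samples = tibble::as_tibble(samples),
         features = tibble::as_tibble(features), provenance = prov,
         log2_scale = isTRUE(log2_scale)),
    class = "omics_matrix"
  )
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf(
    "omics_matrix: %d features x %d samples (%s scale), %.1f%% missing\n",
    nrow(x$values), ncol(x$values),
    if (x$log2_scale) "log2" else "raw",
    100 * mean(is.na(x$values))))
  cat("conditions:", paste(unique(x$samples$condition), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

# Log2 transform raw intensities, treating zeros (and negatives) as
# missing. A no-op on matrices already on the log2 scale.
omics_log2 <- function(m) {
  if (m$log2_scale) return(m)
  v <- m$values
  v[!is.na(v) & v <= 0] <- NA_real_
  m$values <- log2(v)
  m$provenance[is.na(m$values) & m$provenance == "observed"] <- "missing"
  m$log2_scale <- TRUE
  m
}

# Apply a validity filter: keep features with >= min_valid observed values
# in at least one of the given sample groups (named list of column indices).
filter_valid <- function(m, groups, min_valid) {
  obs <- !is.na(m$values)
  keep <- Reduce(`|`, lapply(groups, function(idx) {
    rowSums(obs[, idx, drop = FALSE]) >= min_valid
  }))
  m$values <- m$values[keep, , drop = FALSE]
  m$provenance <- m$provenance[keep, , drop = FALSE]
  m$features <- m$features[keep, , drop = FALSE]
  m
}

#' Perseus-style preprocessing of an intensity matrix
#'
#' Reproduces the classic label-free workflow: log2 transform, filter on a
#' minimum number of valid values within at least one sample group, and
#' global left-shifted normal imputation of the remaining missing values.
#' The default grouping pairs each drug-treatment condition with the
#' control (3 + 3 = 6 samples per group), matching a
#' treatment-versus-control analysis; pass `groups` to override.
#'
#' Imputed values are drawn, per sample column, from a normal distribution
#' whose centre is shifted `shift` column standard deviations below the
#' column mean and whose width is `width` column standard deviations (the
#' conventional down-shifted imputation for left-censored LFQ data;
#' defaults 1.8 and 0.3).
#'
#' @param m An [omics_matrix()] (raw or log2).
#' @param min_valid Minimum observed values in at least one group
#'   (default 4 of a 6-sample group).
#' @param groups Named list of sample-column index vectors; default pairs
#'   each treatment with CTRL.
#' @param shift,width Down-shift and width of the imputation distribution,
#'   in units of the per-column SD.
#' @param seed Integer seed for the imputation draws.
#' @return A filtered, fully imputed `omics_matrix` with provenance
#'   `"imputed_downshift"` on filled values.
#' @export
preprocess_perseus <- function(m, min_valid = 4, groups = NULL,
                               shift = 1.8, width = 0.3, seed = 1L) {
  stopifnot(inherits(m, "omics_matrix"))
  m <- omics_log2(m)
  if (is.null(groups)) {
    ctrl <- which(m$samples$condition == "CTRL")
    treats <- setdiff(unique(m$samples$condition), "CTRL")
    groups <- lapply(treats, function(tr) {
      c(ctrl, which(m$samples$condition == tr))
    })
    names(groups) <- treats
  }
  sizes <- lengths(groups)
  if (any(min_valid > sizes)) {
    abort("min_valid exceeds a group size; grouping inconsistent with labels")
  }
  m <- filter_valid(m, groups, min_valid)
  with_seed(seed, {
    m <- impute_downshift(m, shift, width, "imputed_downshift")
  })
  m
}

# Per-sample left-shifted normal imputation. Columns whose own statistics
# are degenerate (too few observed values) fall back to the global ones.
impute_downshift <- function(m, shift, width, label) {
  g_mu <- mean(m$values, na.rm = TRUE)
  g_sd <- sd(as.vector(m$values), na.rm = TRUE)
  if (!is.finite(g_sd) || g_sd == 0) g_sd <- 1
  for (j in seq_len(ncol(m$values))) {
    col <- m$values[, j]
    miss <- is.na(col)
    if (!any(miss)) next
    mu <- mean(col, na.rm = TRUE)
    s <- sd(col, na.rm = TRUE)
    if (!is.finite(mu)) mu <- g_mu
    if (!is.finite(s) || s == 0) s <- g_sd
    m$values[miss, j] <- rnorm(sum(miss), mu - shift * s, width * s)
    m$provenance[miss, j] <- label
  }
  m
}

#' Regression-path preprocessing: filter, centre, two-stage imputation
#'
#' Prepares an intensity matrix for the linear-model synergy contrast:
#' log2 transform with zeros treated as missing; keep features with at
#' least `min_valid` observed values in at least one condition; median
#' centre each sample; then impute in two stages. Where a feature is
#' quantified in more than half of a condition's samples, missing values
#' in that condition are drawn from the condition's own observed mean and
#' SD (condition-specific imputation); everything still missing afterwards
#' is filled by sample-wise tail-based imputation, a left-shifted normal
#' draw per sample column as in [preprocess_perseus()].
#'
#' By default the per-sample median is computed over observed values only.
#' `center = "zeros_as_values"` instead counts missing values as zeros
#' when computing the medians, mimicking pipelines that reassign NaN to 0
#' before centering; that reading biases the medians and is kept only as
#' a compatibility mode.
#'
#' @param m An [omics_matrix()].
#' @param min_valid Minimum observed values within one condition. The
#'   conventional cutoff is 4; with triplicate conditions use a value
#'   no larger than the replicate count.
#' @param center `"observed"` (default) or `"zeros_as_values"`.
#' @param condition_sd_floor Lower bound on the condition SD used for
#'   condition-specific draws (guards the 2-observed-values case).
#' @param shift,width Tail-imputation parameters as in
#'   [preprocess_perseus()].
#' @param seed Integer seed for the imputation draws.
#' @return A filtered, centred, fully imputed `omics_matrix` with
#'   provenance `"imputed_condition"` / `"imputed_tail"` on filled values.
#' @export
preprocess_regression <- function(m, min_valid = 4,
                                  center = c("observed", "zeros_as_values"),
                                  condition_sd_floor = 0.05,
                                  shift = 1.8, width = 0.3, seed = 1L) {
  stopifnot(inherits(m, "omics_matrix"))
  center <- match.arg(center)
  m <- omics_log2(m)
  conds <- setdiff(unique(m$samples$condition), "CTRL")
  groups <- lapply(conds, function(cc) which(m$samples$condition == cc))
  names(groups) <- conds
  if (any(min_valid > lengths(groups))) {
    warn("min_valid exceeds the replicate count of some condition; those groups can never satisfy the filter")
  }
  m <- filter_valid(m, groups, min_valid)
  if (nrow(m$values) == 0) {
    abort("no feature passes the validity filter")
  }
  # per-sample median centering
  med <- apply(m$values, 2, function(col) {
    if (center == "zeros_as_values") {
      col[is.na(col)] <- 0
      median(col)
    } else {
      median(col, na.rm = TRUE)
    }
  })
  m$values <- sweep(m$values, 2, med)

  all_conds <- unique(m$samples$condition)
  with_seed(seed, {
    # stage 1: condition-specific imputation where > 50% observed
    for (cc in all_conds) {
      idx <- which(m$samples$condition == cc)
      sub <- m$values[, idx, drop = FALSE]
      n_obs <- rowSums(!is.na(sub))
      eligible <- n_obs > length(idx) / 2 & n_obs < length(idx)
      for (f in which(eligible)) {
        row <- sub[f, ]
        mu <- mean(row, na.rm = TRUE)
        s <- max(sd(row, na.rm = TRUE), condition_sd_floor, na.rm = TRUE)
        miss <- which(is.na(row))
        m$values[f, idx[miss]] <- rnorm(length(miss), mu, s)
        m$provenance[f, idx[miss]] <- "imputed_condition"
      }
    }
    # stage 2: sample-wise tail imputation of the remainder
    m <- impute_downshift(m, shift, width, "imputed_tail")
  })
  m
}

#' Normalize phosphosite intensities to total-protein abundance
#'
#' Subtracts, per sample, the parent protein's log2 abundance from each
#' phosphosite's log2 intensity, so site-level changes reflect
#' phosphorylation rather than protein-level regulation. Sites whose
#' parent protein is absent from the protein matrix are passed through
#' unchanged and flagged `unnormalized`.
#'
#' @param phospho An [omics_matrix()] whose `features` table carries a
#'   `protein` column naming each site's parent protein.
#' @param protein An [omics_matrix()] of protein abundances (feature ids =
#'   protein ids) over the same sample columns.
#' @return The phospho `omics_matrix` with normalized values and a logical
#'   `unnormalized` column added to `features`.
#' @export
normalize_phospho_to_protein <- function(phospho, protein) {
  stopifnot(inherits(phospho, "omics_matrix"), inherits(protein, "omics_matrix"))
  if (!identical(phospho$samples$sample, protein$samples$sample)) {
    abort("phospho and protein matrices must share identical sample columns")
  }
  if (!"protein" %in% names(phospho$features)) {
    abort("phospho features need a 'protein' parent-id column")
  }
  phospho <- omics_log2(phospho)
  protein <- omics_log2(protein)
  idx <- match(phospho$features$protein, rownames(protein$values))
  matched <- !is.na(idx)
  v <- phospho$values
  v[matched, ] <- v[matched, , drop = FALSE] -
    protein$values[idx[matched], , drop = FALSE]
  phospho$values <- v
  phospho$features$unnormalized <- !matched
  phospho
}

# SAM-style statistic for one treatment condition against the reference:
# replicate-wise differences against the reference mean, moderated by the
# fudge factor s0 in the denominator.
sam_stat <- function(values, treat_idx, ref_idx, s0) {
  diffs <- values[, treat_idx, drop = FALSE] -
    rowMeans(values[, ref_idx, drop = FALSE])
  n <- ncol(diffs)
  mu <- rowMeans(diffs)
  se <- sqrt(rowSums((diffs - mu)^2) / (n - 1) / n)
  list(stat = mu / (se + s0), mean_diff = mu)
}

#' One-sample SAM-style permutation test of a treatment versus control
#'
#' For each feature, forms the replicate-wise differences between a
#' treatment condition and the reference-condition mean and computes the
#' SAM-type statistic `d = mean(diff) / (SE + s0)`, where the fudge factor
#' `s0` stabilises low-variance features. Significance is assessed by
#' permuting the condition labels between treatment and reference
#' (`n_perm` shuffles, seeded) and q-values follow the SAM permutation-FDR
#' construction: for each observed |d| cutoff, the median number of null
#' exceedances across permutations divided by the observed count, made
#' monotone and capped at 1.
#'
#' @param m A preprocessed (complete) [omics_matrix()].
#' @param condition Treatment condition label.
#' @param reference Reference condition label (default `"CTRL"`).
#' @param s0 Fudge factor added to the per-feature SE (default 0.1).
#' @param fdr q-value cutoff for flagging (default 0.05).
#' @param n_perm Number of label permutations (>= 25; default 250).
#' @param seed Integer seed for the permutations.
#' @return A `contrast_result` tibble: `feature_id`, `log_fc` (mean
#'   difference, log2 units), `statistic`, `q_value`, `significant`; the
#'   run parameters are attached as attributes.
#' @export
sam_one_sample_test <- function(m, condition, reference = "CTRL",
                                s0 = 0.1, fdr = 0.05, n_perm = 250,
                                seed = 1L) {
  stopifnot(inherits(m, "omics_matrix"))
  if (s0 < 0) abort("s0 must be >= 0")
  if (n_perm < 25) abort("need at least 25 permutations")
  if (anyNA(m$values)) abort("matrix must be imputed/complete before testing")
  treat_idx <- which(m$samples$condition == condition)
  ref_idx <- which(m$samples$condition == reference)
  if (length(treat_idx) < 2 || length(ref_idx) < 2) {
    abort("need at least 2 replicates in both the treatment and the reference")
  }
  obs <- sam_stat(m$values, treat_idx, ref_idx, s0)
  pool <- c(treat_idx, ref_idx)
  nt <- length(treat_idx)
  null_abs <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perm <- sample(pool)
      abs(sam_stat(m$values, perm[seq_len(nt)], perm[-seq_len(nt)], s0)$stat)
    }, numeric(nrow(m$values)))
  })
  # permutation FDR: for each observed |d|, median null exceedances over
  # permutations relative to observed exceedances, then monotone in |d|
  a <- abs(obs$stat)
  ord <- order(a, decreasing = TRUE)
  sorted <- a[ord]
  n_obs_exceed <- seq_along(sorted)
  # per permutation, count null |d| >= cutoff for every observed cutoff via
  # one sorted pass, then take the median count across permutations
  counts <- apply(null_abs, 2, function(col) {
    nrow(null_abs) - findInterval(sorted, sort(col), left.open = TRUE)
  })
  n_null_exceed <- apply(counts, 1, median)
  q_sorted <- pmin(n_null_exceed / n_obs_exceed, 1)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(length(a))
  q[ord] <- q_sorted
  out <- tibble::tibble(
    feature_id = rownames(m$values),
    log_fc = unname(obs$mean_diff),
    statistic = unname(obs$stat),
    q_value = unname(q),
    significant = unname(q <= fdr)
  )
  attr(out, "params") <- list(test = "sam_one_sample", condition = condition,
                              reference = reference, s0 = s0, fdr = fdr,
                              n_perm = n_perm, seed = seed)
  class(out) <- c("contrast_result", class(out))
  out
}

#' Fit the per-feature treatment linear model
#'
#' Ordinary least squares of log2 abundance on condition indicators with
#' the control as the reference level (design `~ treatment`): in a
#' balanced design each coefficient is that condition's mean minus the
#' control mean. Residual variance and degrees of freedom are recorded per
#' feature for downstream moderation.
#'
#' @param m A preprocessed, complete [omics_matrix()].
#' @return A `treatment_fit` object: `coefficients` (features x
#'   non-reference conditions), `sigma2`, `df_residual`, `xtx_inv` and the
#'   design metadata.
#' @export
fit_treatment_model <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  if (anyNA(m$values)) abort("matrix must be imputed/complete before fitting")
  cond <- factor(m$samples$condition,
                 levels = intersect(OMICS_CONDITIONS, m$samples$condition))
  if (levels(cond)[1] != "CTRL") abort("the design needs CTRL samples as reference")
  X <- stats::model.matrix(~cond)
  colnames(X) <- sub("^cond", "", colnames(X))
  df <- nrow(X) - ncol(X)
  if (df < 1) abort("fewer than 1 residual degree of freedom")
  xtx_inv <- solve(crossprod(X))
  B <- m$values %*% X %*% t(xtx_inv)  # features x terms
  colnames(B) <- colnames(X)
  resid <- m$values - B %*% t(X)
  sigma2 <- rowSums(resid^2) / df
  structure(
    list(coefficients = B, sigma2 = sigma2, df_residual = df,
         xtx_inv = xtx_inv, terms = colnames(X),
         feature_id = rownames(m$values), n_samples = nrow(X)),
    class = "treatment_fit"
  )
}

#' @export
print.treatment_fit <- function(x, ...) {
  cat(sprintf("treatment_fit: %d features, terms: %s, residual df %d\n",
              nrow(x$coefficients), paste(x$terms, collapse = " "),
              x$df_residual))
  invisible(x)
}

# Newton inversion of the trigamma function (solves trigamma(y) = x), the
# step needed to fit the scaled inverse-chi-square prior by method of
# moments on log residual variances.
trigamma_inverse <- function(x) {
  vapply(x, function(xx) {
    if (!is.finite(xx) || xx <= 0) return(Inf)
    if (xx > 1e7) return(1 / sqrt(xx))
    if (xx < 1e-6) return(1 / xx)
    y <- 0.5 + 1 / xx
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xx) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif) / y < 1e-10) break
    }
    y
  }, numeric(1))
}

# Empirical-Bayes moderation of per-feature variances: fit a scaled
# F/inverse-chi-square prior (d0, v0) to the s^2 distribution by method of
# moments on log s^2, and return posterior (squeezed) variances.
moderate_variances <- function(sigma2, df) {
  z <- log(pmax(sigma2, 1e-300))
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    v0 <- exp(ebar)
    post <- rep(v0, length(sigma2))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    v0 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
    post <- (d0 * v0 + df * sigma2) / (d0 + df)
  }
  list(d0 = d0, v0 = v0, posterior = post)
}

#' Combination-versus-sum-of-singles synergy contrast
#'
#' Tests, per feature, whether the combination treatment effect exceeds
#' the sum of the single-drug effects: with control-referenced
#' coefficients the contrast `L = beta_combo - sum(beta_singles)` equals
#' `mean(combo) - sum(mean(singles)) + (k - 1) * mean(CTRL)` in cell
#' means — for MD vs M + D this is the classic interaction contrast
#' MD - M - D + CTRL, zero whenever the drug effects are additive on the
#' log2 scale. Per-feature residual variances are moderated by empirical
#' Bayes (scaled inverse-chi-square prior fitted by method of moments on
#' the log residual variances), giving a moderated t with `d0 + df`
#' degrees of freedom; p-values are BH-adjusted.
#'
#' @param fit A [fit_treatment_model()] result.
#' @param combo Name of the combination coefficient (e.g. `"MD"`).
#' @param singles Character vector of single-drug coefficients (e.g.
#'   `c("M", "D")`).
#' @return A `contrast_result` tibble: `feature_id`, `log_fc` (the
#'   contrast estimate), `statistic` (moderated t), `p_value`, `adj_p`,
#'   with prior `d0`, `v0` and the contrast definition attached as
#'   attributes.
#' @export
synergy_contrast <- function(fit, combo = "MD", singles = c("M", "D")) {
  stopifnot(inherits(fit, "treatment_fit"))
  terms <- c(combo, singles)
  if (!all(terms %in% fit$terms)) {
    abort(sprintf("unknown coefficient(s): %s",
                  paste(setdiff(terms, fit$terms), collapse = ", ")))
  }
  cvec <- setNames(numeric(length(fit$terms)), fit$terms)
  cvec[combo] <- 1
  cvec[singles] <- cvec[singles] - 1
  L <- drop(fit$coefficients %*% cvec)
  v_unscaled <- drop(t(cvec) %*% fit$xtx_inv %*% cvec)
  mod <- moderate_variances(fit$sigma2, fit$df_residual)
  df_total <- mod$d0 + fit$df_residual
  t_mod <- L / sqrt(v_unscaled * mod$posterior)
  p <- 2 * pt(-abs(t_mod), df = df_total)
  out <- tibble::tibble(
    feature_id = fit$feature_id,
    log_fc = unname(L),
    statistic = unname(t_mod),
    p_value = unname(p),
    adj_p = unname(p.adjust(p, method = "BH"))
  )
  attr(out, "params") <- list(
    test = "moderated_t", contrast = paste0(combo, " - (",
                                            paste(singles, collapse = " + "), ")"),
    d0 = mod$d0, v0 = mod$v0, df_residual = fit$df_residual,
    df_total = df_total
  )
  class(out) <- c("contrast_result", class(out))
  out
}

#' Select a significant up- or down-regulated signature
#'
#' Filters a contrast result to the features with adjusted p strictly
#' below `adj_p_max` and a log fold change strictly above (direction
#' `"up"`) or below (`"down"`) zero, ordered by adjusted p then feature
#' id.
#'
#' @param r A `contrast_result` with an `adj_p` (or `q_value`) column.
#' @param adj_p_max Strict upper bound on the adjusted p (default 0.05).
#' @param direction `"up"` (default) or `"down"`.
#' @return A tibble of selected features in stable order.
#' @export
select_signature <- function(r, adj_p_max = 0.05, direction = c("up", "down")) {
  direction <- match.arg(direction)
  padj <- if ("adj_p" %in% names(r)) r$adj_p else r$q_value
  keep <- padj < adj_p_max &
    if (direction == "up") r$log_fc > 0 else r$log_fc < 0
  r[keep, , drop = FALSE] |>
    dplyr::mutate(.padj = padj[keep]) |>
    dplyr::arrange(.data$.padj, .data$feature_id) |>
    dplyr::select(-".padj")
}
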