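test_that("the 4-of-6 validity rule retains and drops features as printed", {
  conds <- c("CTRL", "M", "D", "V", "MD", "MDV")
  samples <- tibble::tibble(
    sample = paste0(rep(conds, each = 3), "_", rep(1:3, 6)),
    condition = rep(conds, each = 3), replicate = rep(1:3, 6))
  v <- matrix(NA_real_, 3, 18, dimnames = list(c("keep_md", "drop_all", "log2check"),
                                               samples$sample))
  # feature 1: observed CTRL_1 + all MD -> 4 of 6 in the MD group only
  v["keep_md", c("CTRL_1", "MD_1", "MD_2", "MD_3")] <- c(900, 1000, 1100, 1050)
  # feature 2: 3 of 6 in every group (2 CTRL + 1 per treatment)
  v["drop_all", c("CTRL_1", "CTRL_2", "M_1", "D_1", "V_1", "MD_1", "MDV_1")] <-
    c(500, 550, 600, 620, 640, 660, 680)
  # feature 3: fully observed; raw 8 must become exactly log2(8) = 3
  v["log2check", ] <- 8
  m <- omics_matrix(v, samples, log2_scale = FALSE)
  out <- preprocess_perseus(m, min_valid = 4, seed = 2)
  expect_setequal(rownames(out$values), c("keep_md", "log2check"))
  expect_equal(unname(out$values["log2check", ]), rep(3, 18))
  expect_true(all(out$provenance["log2check", ] == "observed"))
  # observed values survive imputation untouched (up to the log2 transform)
  expect_equal(out$values["keep_md", "MD_2"], log2(1100))
  expect_equal(unname(out$provenance["keep_md", "MD_2"]), "observed")
  expect_true(all(out$provenance["keep_md", is.na(v["keep_md", ])] ==
                    "imputed_downshift"))
  expect_false(anyNA(out$values))
})

test_that("regression preprocessing follows the 50% rule and centres medians", {
  om <- simulate_omics_study(test_config(seed = 3, omics = list(n_features = 400)))
  m <- om$matrix
  out <- preprocess_regression(m, min_valid = 2, seed = 9)
  expect_false(anyNA(out$values))
  # observed values: shifted by the per-sample median only, never redrawn
  for (j in c(1, 10, 18)) {
    obs <- out$provenance[, j] == "observed"
    orig <- m$values[match(rownames(out$values), rownames(m$values)), j]
    expect_equal(out$values[obs, j], (orig - median(orig, na.rm = TRUE))[obs],
                 tolerance = 1e-12)
    expect_equal(median(out$values[obs, j]), 0, tolerance = 1e-12)
  }
  # >50% observed in a condition -> condition-specific imputation
  prov <- out$provenance
  vals_obs <- !is.na(m$values[match(rownames(out$values), rownames(m$values)), ])
  for (cc in c("M", "MD")) {
    idx <- which(out$samples$condition == cc)
    n_obs <- rowSums(vals_obs[, idx])
    partial <- which(n_obs == 2)
    if (length(partial)) {
      got <- prov[partial, idx]
      expect_true(all(got[got != "observed"] == "imputed_condition"))
    }
    none <- which(n_obs == 0)
    if (length(none)) {
      expect_true(all(prov[none, idx] == "imputed_tail"))
    }
  }
})

test_that("the zeros-as-values centering compatibility mode shifts medians", {
  om <- simulate_omics_study(test_config(seed = 4, omics = list(n_features = 200)))
  a <- preprocess_regression(om$matrix, min_valid = 2, seed = 1)
  b <- preprocess_regression(om$matrix, min_valid = 2, seed = 1,
                             center = "zeros_as_values")
  expect_false(isTRUE(all.equal(a$values, b$values)))
})

test_that("phospho-to-protein normalization is a per-sample subtraction", {
  conds <- c("CTRL", "M", "D", "V", "MD", "MDV")
  samples <- tibble::tibble(
    sample = paste0(rep(conds, each = 3), "_", rep(1:3, 6)),
    condition = rep(conds, each = 3), replicate = rep(1:3, 6))
  prot <- matrix(rep(c(20, 21), each = 18), 2, 18, byrow = TRUE,
                 dimnames = list(c("PROT1", "PROT2"), samples$sample))
  # PROT2 is shifted +1 in MD only
  prot["PROT2", samples$condition == "MD"] <- 22
  pm <- omics_matrix(prot, samples, log2_scale = TRUE)
  sites <- matrix(15, 3, 18,
                  dimnames = list(c("site_a", "site_b", "orphan"), samples$sample))
  feats <- tibble::tibble(feature_id = c("site_a", "site_b", "orphan"),
                          protein = c("PROT1", "PROT2", "PROTX"))
  ph <- omics_matrix(sites, samples, features = feats, log2_scale = TRUE)
  out <- normalize_phospho_to_protein(ph, pm)
  # constant parent: normalized values differ from raw by a constant
  expect_equal(unname(out$values["site_a", ]), rep(15 - 20, 18))
  # orphan site passes through unchanged and is flagged
  expect_equal(unname(out$values["orphan", ]), rep(15, 18))
  expect_equal(out$features$unnormalized, c(FALSE, FALSE, TRUE))
  # parent +1 in MD only: a flat site shows -1 in MD after normalization
  md <- out$samples$condition == "MD"
  expect_equal(unique(out$values["site_b", md]) -
                 unique(out$values["site_b", out$samples$condition == "CTRL"]),
               -1)
})

test_that("SAM statistic reduces to the one-sample t when s0 = 0", {
  om <- simulate_omics_study(test_config(seed = 6, omics = list(n_features = 80)))
  m <- om$complete
  r <- sam_one_sample_test(m, "MD", s0 = 0, n_perm = 25, seed = 1)
  v <- m$values
  ti <- which(m$samples$condition == "MD")
  ri <- which(m$samples$condition == "CTRL")
  d <- v[, ti] - rowMeans(v[, ri])
  tt <- rowMeans(d) / sqrt(apply(d, 1, var) / 3)
  expect_equal(r$statistic, unname(tt), tolerance = 1e-12)
})

test_that("SAM on identical values gives d = 0 everywhere and no flags", {
  v <- matrix(10, 20, 18)
  m <- toy_omics(v)
  r <- sam_one_sample_test(m, "MD", n_perm = 25, seed = 3)
  expect_equal(r$statistic, rep(0, 20))
  expect_false(any(r$significant))
})

test_that("SAM is deterministic under a fixed seed and validates inputs", {
  om <- simulate_omics_study(test_config(seed = 2, omics = list(n_features = 60)))
  a <- sam_one_sample_test(om$complete, "M", n_perm = 50, seed = 7)
  b <- sam_one_sample_test(om$complete, "M", n_perm = 50, seed = 7)
  expect_identical(a$q_value, b$q_value)
  expect_error(sam_one_sample_test(om$complete, "M", s0 = -1), "s0")
  expect_error(sam_one_sample_test(om$complete, "M", n_perm = 10), "25")
  expect_error(sam_one_sample_test(om$matrix, "M"), "complete")
})

test_that("treatment model recovers condition means and the 6x3 residual df", {
  om <- simulate_omics_study(test_config(seed = 8, omics = list(n_features = 50)))
  m <- om$complete
  fit <- fit_treatment_model(m)
  expect_equal(fit$df_residual, 12)
  md <- rowMeans(m$values[, m$samples$condition == "MD"])
  ctrl <- rowMeans(m$values[, m$samples$condition == "CTRL"])
  expect_equal(unname(fit$coefficients[, "MD"]), unname(md - ctrl),
               tolerance = 1e-10)
  # noiseless constructed means are recovered exactly
  tr <- om$truth
  noiseless <- as.matrix(tr[, c("CTRL", "M", "D", "V", "MD", "MDV")])
  v <- noiseless[, m$samples$condition]
  rownames(v) <- tr$feature_id
  colnames(v) <- m$samples$sample
  f2 <- fit_treatment_model(omics_matrix(v, m$samples, log2_scale = TRUE))
  expect_equal(unname(f2$coefficients[, "M"]), unname(tr$M - tr$CTRL),
               tolerance = 1e-10)
})

test_that("the synergy contrast is the balanced-design interaction in cell means", {
  om <- simulate_omics_study(test_config(seed = 10, omics = list(n_features = 60)))
  m <- om$complete
  ct <- synergy_contrast(fit_treatment_model(m), "MD", c("M", "D"))
  v <- m$values
  cell <- function(cc) rowMeans(v[, m$samples$condition == cc])
  direct <- cell("MD") - cell("M") - cell("D") + cell("CTRL")
  expect_equal(ct$log_fc, unname(direct), tolerance = 1e-10)
})

test_that("the contrast is exactly zero on noiseless additive truth", {
  tr <- simulate_omics_study(test_config(
    seed = 12, omics = list(n_features = 40,
                            combination_specific_fraction = 0)))$truth
  noiseless <- as.matrix(tr[, c("CTRL", "M", "D", "V", "MD", "MDV")])
  v <- noiseless[, rep(c("CTRL", "M", "D", "V", "MD", "MDV"), each = 3)]
  rownames(v) <- tr$feature_id
  m <- toy_omics(v)
  ct <- synergy_contrast(fit_treatment_model(m), "MD", c("M", "D"))
  expect_equal(ct$log_fc, rep(0, 40), tolerance = 1e-10)
})

test_that("equal residual variances give d0 = Inf and posterior = v0", {
  set.seed(5)
  base <- rnorm(18, sd = 0.3)
  v <- matrix(rnorm(30, 20, 2), 30, 1) %*% rep(1, 18) +
    matrix(rep(base, each = 30), 30, 18)
  m <- toy_omics(v)
  ct <- synergy_contrast(fit_treatment_model(m), "MD", c("M", "D"))
  prm <- attr(ct, "params")
  expect_identical(prm$d0, Inf)
  fit <- fit_treatment_model(m)
  expect_equal(unname(fit$sigma2), rep(fit$sigma2[[1]], 30), tolerance = 1e-10)
  # every moderated t uses the same prior variance v0
  cvec <- c(0, -1, -1, 0, 1, 0)
  names(cvec) <- fit$terms
  vL <- drop(t(cvec) %*% fit$xtx_inv %*% cvec)
  expect_equal(ct$statistic, ct$log_fc / sqrt(vL * prm$v0), tolerance = 1e-10)
})

test_that("moderated statistics agree with the limma route", {
  library(limma)
  om <- simulate_omics_study(test_config(seed = 13, omics = list(n_features = 150)))
  m <- om$complete
  ct <- synergy_contrast(fit_treatment_model(m), "MD", c("M", "D"))
  cond <- factor(m$samples$condition, levels = c("CTRL", "M", "D", "V", "MD", "MDV"))
  X <- stats::model.matrix(~cond)
  colnames(X) <- sub("^cond", "", colnames(X))
  cm <- matrix(c(0, -1, -1, 0, 1, 0), ncol = 1,
               dimnames = list(colnames(X), "L"))
  eb <- limma::eBayes(limma::contrasts.fit(limma::lmFit(m$values, X), cm))
  expect_equal(ct$statistic, unname(eb$t[, 1]), tolerance = 1e-9)
  expect_equal(ct$p_value, unname(eb$p.value[, 1]), tolerance = 1e-9)
  expect_equal(attr(ct, "params")$d0, eb$df.prior, tolerance = 1e-9)
})

test_that("BH adjustment matches a brute-force step-up on random p-vectors", {
  set.seed(21)
  for (rep in 1:5) {
    p <- runif(sample(5:20, 1))
    expect_equal(p.adjust(p, "BH"), bh_brute_force(p), tolerance = 1e-12)
  }
})

test_that("signature selection applies strict thresholds in stable order", {
  r <- tibble::tibble(feature_id = c("f1", "f2", "f3"),
                      log_fc = c(1, 2, -1),
                      adj_p = c(0.01, 0.2, 0.03))
  expect_equal(select_signature(r, 0.05, "up")$feature_id, "f1")
  expect_equal(select_signature(r, 0.05, "down")$feature_id, "f3")
  # boundary: adj p exactly at the cutoff is excluded
  r2 <- tibble::tibble(feature_id = "f", log_fc = 1, adj_p = 0.05)
  expect_equal(nrow(select_signature(r2, 0.05)), 0)
  # empty result when nothing passes
  r3 <- tibble::tibble(feature_id = "f", log_fc = -1, adj_p = 0.01)
  expect_equal(nrow(select_signature(r3, 0.05, "up")), 0)
  # stable ordering by adjusted p then feature id
  r4 <- tibble::tibble(feature_id = c("b", "a", "c"),
                       log_fc = c(1, 1, 1), adj_p = c(0.01, 0.01, 0.001))
  expect_equal(select_signature(r4)$feature_id, c("c", "a", "b"))
})
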